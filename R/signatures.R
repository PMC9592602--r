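#' Design matrix for a drug perturbation model
#'
#' Builds the per-drug regression design: an intercept, the drug
#' concentration as a continuous regressor (0 for control samples), and
#' one-hot contrasts for cell line, batch and duration (reference level =
#' first lexicographic level; factors with a single level drop out).
#' Columns that are linearly aliased with earlier columns are removed and
#' reported via the `"dropped"` attribute.
#'
#' @param design data frame with columns `sample_id`, `drug_id`,
#'   `concentration`, `cell_line`, `batch`, `duration`.
#' @param drug_id drug whose samples (treated and controls) are modeled.
#' @param log_concentration if `TRUE` the regressor is `log10(conc + 1)`
#'   instead of the raw concentration.
#' @return The design matrix for the drug's samples, with attributes
#'   `"dropped"` (aliased column names) and `"samples"` (sample ids, row
#'   order).
#' @export
build_design_matrix <- function(design, drug_id, log_concentration = FALSE) {
  need <- c("sample_id", "drug_id", "concentration", "cell_line", "batch",
            "duration")
  if (!all(need %in% names(design)))
    stop("design needs columns: ", paste(need, collapse = ", "))
  d <- design[design$drug_id == drug_id, , drop = FALSE]
  if (!nrow(d)) stop("no samples for drug '", drug_id, "'")
  if (any(d$concentration < 0)) stop("negative concentration for '", drug_id, "'")
  if (!any(d$concentration > 0)) stop("no treated samples for drug '", drug_id, "'")
  if (!any(d$concentration == 0)) stop("no control samples for drug '", drug_id, "'")
  conc <- if (log_concentration) log10(d$concentration + 1) else d$concentration
  X <- cbind(`(Intercept)` = 1, concentration = conc)
  for (v in c("cell_line", "batch", "duration")) {
    lev <- sort(unique(as.character(d[[v]])))
    if (length(lev) < 2L) next
    f <- factor(d[[v]], levels = lev)
    mm <- stats::model.matrix(~f)[, -1L, drop = FALSE]
    colnames(mm) <- paste0(v, lev[-1L])
    X <- cbind(X, mm)
  }
  if (nrow(X) < 2L) stop("fewer than two samples for drug '", drug_id, "'")
  qrX <- qr(X)
  dropped <- character(0)
  if (qrX$rank < ncol(X)) {
    keep <- qrX$pivot[seq_len(qrX$rank)]
    dropped <- colnames(X)[-keep]
    message("drug '", drug_id, "': dropping aliased column(s): ",
            paste(dropped, collapse = ", "))
    X <- X[, sort(keep), drop = FALSE]
  }
  if (!"concentration" %in% colnames(X))
    stop("concentration column aliased away for drug '", drug_id, "'")
  attr(X, "dropped") <- dropped
  attr(X, "samples") <- d$sample_id
  X
}

#' Fit the perturbation model of one drug
#'
#' Per-gene ordinary least squares of expression on the design from
#' [build_design_matrix()]. The effect of interest is the concentration
#' coefficient beta; the standardized coefficient is the t-like ratio
#' beta / SE(beta), a scale-free measure comparable across genes. A gene fit
#' with zero residual variance has SE = 0; its standardized coefficient is
#' capped at `sign(beta) * cap` instead of propagating an infinity.
#'
#' @param expression sample x gene numeric matrix; row names are sample ids.
#' @param design per-sample design data frame (see [build_design_matrix()]).
#' @param drug_id drug to fit.
#' @param cap magnitude assigned to standardized coefficients with SE = 0.
#' @param log_concentration passed to [build_design_matrix()].
#' @return A data frame, one row per gene, columns `gene`, `beta`, `se`,
#'   `beta_std`, plus attribute `"n_samples"`.
#' @export
fit_perturbation_model <- function(expression, design, drug_id, cap = 1e6,
                                   log_concentration = FALSE) {
  X <- build_design_matrix(design, drug_id,
                           log_concentration = log_concentration)
  samples <- attr(X, "samples")
  missing <- setdiff(samples, rownames(expression))
  if (length(missing))
    stop("expression matrix lacks sample(s): ", paste(missing, collapse = ", "))
  Y <- expression[samples, , drop = FALSE]
  n <- nrow(X)
  p <- ncol(X)
  df <- n - p
  if (df < 1L)
    stop("no residual degrees of freedom for drug '", drug_id,
         "' (n = ", n, ", p = ", p, ")")
  fit <- stats::lm.fit(X, Y)
  coefs <- fit$coefficients
  if (is.null(dim(coefs)))  # single-gene input: lm.fit drops to vectors
    coefs <- matrix(coefs, ncol = 1L,
                    dimnames = list(names(coefs), colnames(Y)))
  res <- as.matrix(fit$residuals)
  beta <- coefs["concentration", ]
  xtx_inv <- chol2inv(qr.R(fit$qr))
  piv <- colnames(X)[fit$qr$pivot]
  dimnames(xtx_inv) <- list(piv, piv)
  sigma2 <- colSums(res^2) / df
  ## a numerically perfect fit leaves rounding-level residuals: treat as zero
  zero <- sigma2 <= .Machine$double.eps^1.5 * pmax(colMeans(Y^2), 1)
  sigma2[zero] <- 0
  se <- sqrt(sigma2 * xtx_inv["concentration", "concentration"])
  beta_std <- ifelse(se > 0, beta / se, sign(beta) * cap)
  out <- data.frame(gene = colnames(expression), beta = as.numeric(beta),
                    se = as.numeric(se), beta_std = as.numeric(beta_std),
                    stringsAsFactors = FALSE)
  attr(out, "n_samples") <- n
  out
}

#' Perturbation signatures for a drug panel
#'
#' Applies [fit_perturbation_model()] to each drug; drugs whose model cannot
#' be fit (no controls, no treated samples, no residual degrees of freedom)
#' are dropped with a message and listed in the `dropped` field.
#'
#' @param expression sample x gene numeric matrix.
#' @param design per-sample design data frame.
#' @param drugs drugs to fit; default all treated drugs in the design.
#' @param ... passed to [fit_perturbation_model()].
#' @return A `perturbation_signature` with elements `coefficients` and
#'   `standard_errors` (drug x gene matrices of beta_std and SE),
#'   `sample_counts`, and `dropped` (named character vector of failure
#'   messages).
#' @export
signatures_for_panel <- function(expression, design, drugs = NULL, ...) {
  if (is.null(drugs))
    drugs <- sort(unique(design$drug_id[design$concentration > 0]))
  fits <- list()
  dropped <- character(0)
  for (d in drugs) {
    f <- tryCatch(fit_perturbation_model(expression, design, d, ...),
                  error = function(e) conditionMessage(e))
    if (is.character(f)) {
      message("dropping drug '", d, "': ", f)
      dropped[d] <- f
    } else fits[[d]] <- f
  }
  if (!length(fits)) stop("no drug could be fit")
  genes <- colnames(expression)
  coef <- t(vapply(fits, function(f) f$beta_std, numeric(length(genes))))
  se <- t(vapply(fits, function(f) f$se, numeric(length(genes))))
  dimnames(coef) <- dimnames(se) <- list(names(fits), genes)
  structure(list(coefficients = coef, standard_errors = se,
                 sample_counts = vapply(fits, attr, integer(1L), "n_samples"),
                 dropped = dropped),
            class = "perturbation_signature")
}

#' @export
print.perturbation_signature <- function(x, ...) {
  cat(sprintf("perturbation_signature: %d drugs x %d genes (%d dropped)\n",
              nrow(x$coefficients), ncol(x$coefficients), length(x$dropped)))
  invisible(x)
}
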