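#' Bit fingerprint
#'
#' A hashed substructure fingerprint: a set of on-bit positions over a fixed
#' bit length. Positions are zero-based.
#'
#' @param length positive integer, number of bits.
#' @param on_bits integer vector of on positions in `[0, length)`.
#' @return An object of class `bit_fingerprint` with fields `length` and
#'   `on_bits` (sorted, unique).
#' @export
bit_fingerprint <- function(length, on_bits = integer(0)) {
  length <- as.integer(length)
  if (is.na(length) || length <= 0L) stop("fingerprint length must be positive")
  on_bits <- sort(unique(as.integer(on_bits)))
  if (any(is.na(on_bits)) || any(on_bits < 0L) || any(on_bits >= length))
    stop("on-bit positions must lie in [0, length)")
  structure(list(length = length, on_bits = on_bits),
            class = "bit_fingerprint")
}

#' @export
print.bit_fingerprint <- function(x, ...) {
  cat(sprintf("bit_fingerprint: %d/%d bits on\n", length(x$on_bits), x$length))
  invisible(x)
}

#' Extended-connectivity fingerprint of a SMILES string
#'
#' Computes a hashed circular (ECFP-family) substructure fingerprint via
#' OpenBabel (through the ChemmineOB package): circular environments up to the
#' given radius are enumerated (ECFP diameter = 2 * radius) and the resulting
#' bit vector is folded to `n_bits` by OR-ing positions modulo `n_bits`.
#'
#' @param smiles a SMILES string.
#' @param radius circular neighborhood radius in bonds; the default 2
#'   corresponds to the common ECFP4 convention.
#' @param n_bits folded fingerprint length in bits.
#' @param drug_id optional identifier used in error messages.
#' @return A [bit_fingerprint()] of length `n_bits`.
#' @export
ecfp_fingerprint <- function(smiles, radius = 2L, n_bits = 2048L,
                             drug_id = NULL) {
  if (!requireNamespace("ChemmineOB", quietly = TRUE))
    stop("ChemmineOB is required to compute fingerprints from SMILES; ",
         "supply precomputed fingerprints instead")
  who <- if (is.null(drug_id)) paste0("'", smiles, "'") else drug_id
  if (!is.character(smiles) || length(smiles) != 1L || is.na(smiles) ||
      !nzchar(trimws(smiles)))
    stop("empty or missing SMILES for ", who)
  radius <- as.integer(radius)
  n_bits <- as.integer(n_bits)
  stopifnot(radius >= 0L, n_bits > 0L)
  fptype <- paste0("ECFP", 2L * radius)
  mol <- tryCatch(ChemmineOB::forEachMol("SMILES", smiles, identity),
                  error = function(e)
                    stop("unparseable SMILES for ", who, ": ",
                         conditionMessage(e), call. = FALSE))
  bits <- tryCatch(ChemmineOB::fingerprint_OB(mol, fptype),
                   error = function(e)
                     stop("fingerprint computation failed for ", who, ": ",
                          conditionMessage(e), call. = FALSE))
  bits <- as.numeric(bits)
  on <- which(bits != 0) - 1L
  if (!length(on))
    stop("unparseable SMILES for ", who, ": no substructure bits produced")
  bit_fingerprint(n_bits, unique(on %% n_bits))
}

#' Tanimoto similarity matrix of bit fingerprints
#'
#' T(i, j) = |A intersect B| / |A union B| over on-bit sets. The diagonal is
#' 1; a pair of all-zero fingerprints gets similarity 0 off the diagonal.
#'
#' @param fps named list of [bit_fingerprint()]s of identical length.
#' @return A `similarity_matrix`: square symmetric matrix in `[0, 1]` with
#'   unit diagonal, drug ids as dimnames.
#' @export
tanimoto_matrix <- function(fps) {
  stopifnot(length(fps) >= 1L, !is.null(names(fps)))
  lens <- vapply(fps, function(f) f$length, integer(1L))
  if (length(unique(lens)) != 1L)
    stop("fingerprints have mixed lengths: ",
         paste(unique(lens), collapse = ", "))
  n <- length(fps)
  L <- lens[[1L]]
  B <- matrix(0L, n, L)
  for (i in seq_len(n)) B[i, fps[[i]]$on_bits + 1L] <- 1L
  inter <- tcrossprod(B)
  counts <- rowSums(B)
  union <- outer(counts, counts, "+") - inter
  T <- ifelse(union > 0, inter / union, 0)
  diag(T) <- 1
  dimnames(T) <- list(names(fps), names(fps))
  as_similarity_matrix(T, range = c(0, 1))
}

#' Pairwise-complete Pearson similarity matrix
#'
#' Correlates every pair of drug profiles (rows) over the features both have
#' defined. Degenerate pairs -- fewer than `min_overlap` mutually defined
#' features, or zero variance in either profile over the complete features --
#' get similarity 0, keeping the downstream affinity kernel total. The
#' diagonal is forced to 1.
#'
#' @param profiles drug x feature numeric matrix, `NA` allowed.
#' @param min_overlap minimum number of mutually defined features per pair.
#' @return A `similarity_matrix` in `[-1, 1]` with unit diagonal.
#' @export
correlation_matrix <- function(profiles, min_overlap = 3L) {
  stopifnot(is.matrix(profiles), ncol(profiles) >= 2L)
  defined <- rowSums(!is.na(profiles))
  if (any(defined == 0L))
    stop("drug(s) with all-missing profile: ",
         paste(rownames(profiles)[defined == 0L], collapse = ", "))
  suppressWarnings(
    r <- stats::cor(t(profiles), use = "pairwise.complete.obs"))
  obs <- 1L * !is.na(profiles)
  overlap <- tcrossprod(obs)
  r[overlap < min_overlap] <- 0
  r[!is.finite(r)] <- 0
  diag(r) <- 1
  r <- (r + t(r)) / 2
  dimnames(r) <- list(rownames(profiles), rownames(profiles))
  as_similarity_matrix(r, range = c(-1, 1))
}

#' Restrict a perturbation matrix to a gene set
#'
#' Keeps the columns whose gene symbol belongs to the set, preserving the
#' original column order. Requested genes missing from the matrix are
#' reported via the `"absent"` attribute and a message.
#'
#' @param perturbation drug x gene numeric matrix.
#' @param gs a [gene_set()].
#' @return The column-restricted matrix with attribute `"absent"`.
#' @export
restrict_to_genes <- function(perturbation, gs) {
  stopifnot(inherits(gs, "gene_set"), is.matrix(perturbation))
  keep <- colnames(perturbation) %in% gs$genes
  absent <- setdiff(gs$genes, colnames(perturbation))
  if (!any(keep))
    stop("none of the ", length(gs$genes), " genes of set '", gs$name,
         "' are present in the perturbation matrix")
  if (length(absent))
    message("gene set '", gs$name, "': ", length(absent),
            " gene(s) absent from the perturbation matrix: ",
            paste(absent, collapse = ", "))
  out <- perturbation[, keep, drop = FALSE]
  attr(out, "absent") <- absent
  out
}

## internal: validate + tag a square symmetric similarity matrix
as_similarity_matrix <- function(m, range) {
  stopifnot(is.matrix(m), nrow(m) == ncol(m))
  if (any(!is.finite(m))) stop("similarity matrix has non-finite entries")
  if (max(abs(m - t(m))) > 1e-12) stop("similarity matrix is not symmetric")
  if (min(m) < range[1L] - 1e-12 || max(m) > range[2L] + 1e-12)
    stop("similarity values outside declared range [",
         range[1L], ", ", range[2L], "]")
  attr(m, "range") <- range
  class(m) <- c("similarity_matrix", class(m))
  m
}
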