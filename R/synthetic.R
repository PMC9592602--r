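#' Specification of a synthetic multi-layer drug panel
#'
#' Describes a panel with a planted drug community (a "reference-like"
#' cluster) expressed consistently in all three layers, emulating the
#' structure of a real pharmacogenomic screen: correlated sensitivity
#' profiles across cell lines, gene-wise perturbation coefficients with a
#' planted pathway signal, and bit fingerprints with a shared-substructure
#' core.
#'
#' Defaults describe a strong-signal panel: 60 drugs, a 5-drug community,
#' sensitivity correlation rho = 0.8 within the community, pathway
#' perturbation shift delta = 3 noise-sd units, fingerprint core-bit flip
#' probability 0.05.
#'
#' @param n_drugs,n_cells,n_genes panel dimensions.
#' @param pathway_size number of pathway genes (k).
#' @param cluster_size number of community drugs (m), reference included.
#' @param sensitivity_correlation rho in `[0, 1)`: community drugs share a
#'   common sensitivity factor with loading sqrt(rho).
#' @param perturbation_effect delta >= 0: magnitude of the shared pathway
#'   template added to community drugs' pathway-gene coefficients, in units
#'   of the coefficient noise sd.
#' @param fingerprint_bits fingerprint length.
#' @param fingerprint_core_bits number of shared core on-bits (c) of the
#'   community.
#' @param bit_flip_prob probability q that a community drug loses any given
#'   core bit.
#' @param bit_background_density probability that a non-core position is on
#'   in a community drug; background drugs are fully random at the matched
#'   overall density.
#' @param noise_sd sd of the perturbation coefficient noise.
#' @param seed integer seed; the panel is a pure function of the spec.
#' @return A `panel_spec` list.
#' @export
panel_spec <- function(n_drugs = 60L, n_cells = 30L, n_genes = 300L,
                       pathway_size = 6L, cluster_size = 5L,
                       sensitivity_correlation = 0.8,
                       perturbation_effect = 3,
                       fingerprint_bits = 512L,
                       fingerprint_core_bits = 64L,
                       bit_flip_prob = 0.05,
                       bit_background_density = 0.1,
                       noise_sd = 1, seed = 1L) {
  spec <- list(n_drugs = as.integer(n_drugs), n_cells = as.integer(n_cells),
               n_genes = as.integer(n_genes),
               pathway_size = as.integer(pathway_size),
               cluster_size = as.integer(cluster_size),
               sensitivity_correlation = sensitivity_correlation,
               perturbation_effect = perturbation_effect,
               fingerprint_bits = as.integer(fingerprint_bits),
               fingerprint_core_bits = as.integer(fingerprint_core_bits),
               bit_flip_prob = bit_flip_prob,
               bit_background_density = bit_background_density,
               noise_sd = noise_sd, seed = as.integer(seed))
  with(spec, {
    if (cluster_size > n_drugs) stop("cluster_size exceeds n_drugs")
    if (pathway_size > n_genes) stop("pathway_size exceeds n_genes")
    if (fingerprint_core_bits > fingerprint_bits)
      stop("fingerprint_core_bits exceeds fingerprint_bits")
    if (sensitivity_correlation < 0 || sensitivity_correlation >= 1)
      stop("sensitivity_correlation must lie in [0, 1)")
    if (perturbation_effect < 0) stop("perturbation_effect must be >= 0")
    if (bit_flip_prob < 0 || bit_flip_prob > 1 ||
        bit_background_density < 0 || bit_background_density > 1)
      stop("probabilities must lie in [0, 1]")
    if (noise_sd <= 0) stop("noise_sd must be positive")
    if (n_cells < 2L || n_drugs < 2L) stop("need at least 2 drugs and 2 cells")
  })
  structure(spec, class = "panel_spec")
}

#' Simulate a multi-layer drug panel with a planted community
#'
#' Generates the three layers of a [drug_profile_set()] according to a
#' [panel_spec()], together with the ground truth (community members,
#' designated reference, pathway genes).
#'
#' Sensitivity: community drug i has profile
#' `sqrt(rho) * z_common + sqrt(1 - rho) * e_i` over cell lines; background
#' drugs are independent standard normal. Perturbation: all coefficients are
#' `N(0, noise_sd^2)`; community drugs' pathway-gene columns are shifted by
#' one shared template whose entries are `delta * noise_sd * N(0, 1)`, so the
#' within-community pathway correlation is governed by delta alone.
#' Fingerprints: community drugs share a core on-bit set (each bit
#' independently lost with probability q) plus random background bits;
#' background drugs are uniformly random at the matched expected density, so
#' structure similarity rather than bit count separates the community.
#'
#' @param spec a [panel_spec()].
#' @return A list with `profiles` (a [drug_profile_set()]) and `truth` (list
#'   with `cluster`, `reference`, `pathway_genes`, and a `pathway` gene set).
#' @export
simulate_panel <- function(spec = panel_spec()) {
  stopifnot(inherits(spec, "panel_spec"))
  set.seed(spec$seed)
  n <- spec$n_drugs
  m <- spec$cluster_size
  drug_ids <- sprintf("drug%03d", seq_len(n))
  cell_ids <- sprintf("cell%03d", seq_len(spec$n_cells))
  gene_ids <- sprintf("gene%04d", seq_len(spec$n_genes))
  cluster <- sort(sample(drug_ids, m))
  reference <- cluster[1L]
  pathway <- sort(sample(gene_ids, spec$pathway_size))

  ## sensitivity: one common factor for the community
  rho <- spec$sensitivity_correlation
  z_common <- stats::rnorm(spec$n_cells)
  sens <- matrix(stats::rnorm(n * spec$n_cells), n, spec$n_cells,
                 dimnames = list(drug_ids, cell_ids))
  for (d in cluster)
    sens[d, ] <- sqrt(rho) * z_common +
      sqrt(1 - rho) * stats::rnorm(spec$n_cells)

  ## perturbation: iid noise + shared pathway template for the community
  sigma <- spec$noise_sd
  pert <- matrix(stats::rnorm(n * spec$n_genes, sd = sigma), n, spec$n_genes,
                 dimnames = list(drug_ids, gene_ids))
  ## entries of magnitude delta * sigma with random signs, so the expected
  ## within-community pathway correlation is delta^2 / (delta^2 + 1)
  template <- spec$perturbation_effect * sigma *
    sample(c(-1, 1), spec$pathway_size, replace = TRUE)
  pert[cluster, pathway] <- pert[cluster, pathway] +
    matrix(template, m, spec$pathway_size, byrow = TRUE)

  ## fingerprints: shared noisy core for the community, matched density
  ## elsewhere
  L <- spec$fingerprint_bits
  c_bits <- spec$fingerprint_core_bits
  q <- spec$bit_flip_prob
  p_bg <- spec$bit_background_density
  core <- sample.int(L, c_bits) - 1L
  dens <- (c_bits * (1 - q) + (L - c_bits) * p_bg) / L
  fps <- vector("list", n)
  names(fps) <- drug_ids
  for (d in drug_ids) {
    if (d %in% cluster) {
      kept <- core[stats::runif(c_bits) >= q]
      bg <- setdiff(seq_len(L) - 1L, core)
      on <- c(kept, bg[stats::runif(length(bg)) < p_bg])
    } else {
      on <- (seq_len(L) - 1L)[stats::runif(L) < dens]
    }
    fps[[d]] <- bit_fingerprint(L, on)
  }

  profiles <- drug_profile_set(fps, sens, pert)
  truth <- list(cluster = cluster, reference = reference,
                pathway_genes = pathway,
                pathway = gene_set("planted_pathway", pathway))
  list(profiles = profiles, truth = truth)
}

#' Simulate an expression experiment with known drug effects
#'
#' Generates per-sample expression `y = beta * concentration + cell-line,
#' batch and duration offsets + N(0, noise_sd^2)` for each drug, with half
#' the samples as untreated controls (concentration 0) and half treated at
#' concentration 1. Covariate levels are assigned cyclically so every drug
#' has controls in every cell line.
#'
#' @param n_drugs number of drugs.
#' @param n_genes number of genes.
#' @param samples_per_drug samples per drug (controls + treated); must leave
#'   at least two residual degrees of freedom beyond the covariates.
#' @param true_beta optional drug x gene matrix of concentration effects;
#'   default `N(0, 1)` entries.
#' @param n_cell_lines,n_batches,n_durations covariate level counts.
#' @param noise_sd residual sd.
#' @param seed integer seed.
#' @return A list with `expression` (sample x gene matrix), `design` (the
#'   per-sample data frame of [build_design_matrix()]), and `true_beta`.
#' @export
simulate_expression <- function(n_drugs = 3L, n_genes = 50L,
                                samples_per_drug = 30L, true_beta = NULL,
                                n_cell_lines = 2L, n_batches = 2L,
                                n_durations = 2L, noise_sd = 1, seed = 1L) {
  n_drugs <- as.integer(n_drugs)
  n_genes <- as.integer(n_genes)
  samples_per_drug <- as.integer(samples_per_drug)
  p_cov <- 2L + (n_cell_lines - 1L) + (n_batches - 1L) + (n_durations - 1L)
  if (samples_per_drug < p_cov + 2L)
    stop("samples_per_drug must be at least ", p_cov + 2L,
         " for the requested covariate structure")
  set.seed(as.integer(seed))
  drug_ids <- sprintf("drug%03d", seq_len(n_drugs))
  gene_ids <- sprintf("gene%04d", seq_len(n_genes))
  if (is.null(true_beta)) {
    true_beta <- matrix(stats::rnorm(n_drugs * n_genes), n_drugs, n_genes)
  }
  dimnames(true_beta) <- list(drug_ids, gene_ids)
  cells <- sprintf("cl%02d", seq_len(n_cell_lines))
  batches <- sprintf("b%02d", seq_len(n_batches))
  durations <- sprintf("%dh", 6L * seq_len(n_durations))
  cell_off <- stats::setNames(c(0, stats::rnorm(n_cell_lines - 1L)), cells)
  batch_off <- stats::setNames(c(0, stats::rnorm(n_batches - 1L)), batches)
  dur_off <- stats::setNames(c(0, stats::rnorm(n_durations - 1L)), durations)

  design <- list()
  expr <- list()
  for (d in seq_len(n_drugs)) {
    ns <- samples_per_drug
    ## controls first, treated second, while covariates cycle at short
    ## periods: keeps concentration unaliased with any covariate contrast
    conc <- rep(c(0, 1), each = ceiling(ns / 2))[seq_len(ns)]
    idx <- seq_len(ns)
    dd <- data.frame(
      sample_id = sprintf("%s_s%03d", drug_ids[d], idx),
      drug_id = drug_ids[d],
      concentration = conc,
      cell_line = cells[1L + (idx - 1L) %% n_cell_lines],
      batch = batches[1L + ((idx - 1L) %/% n_cell_lines) %% n_batches],
      duration = durations[1L + ((idx - 1L) %/%
                                   (n_cell_lines * n_batches)) %% n_durations],
      stringsAsFactors = FALSE)
    mu <- outer(conc, true_beta[d, ]) +
      cell_off[dd$cell_line] + batch_off[dd$batch] + dur_off[dd$duration]
    y <- mu + matrix(stats::rnorm(ns * n_genes, sd = noise_sd), ns, n_genes)
    rownames(y) <- dd$sample_id
    colnames(y) <- gene_ids
    design[[d]] <- dd
    expr[[d]] <- y
  }
  list(expression = do.call(rbind, expr),
       design = do.call(rbind, design),
       true_beta = true_beta)
}
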