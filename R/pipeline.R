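#' Configuration of a full screening run
#'
#' Bundles every input path, parameter and threshold of one end-to-end
#' pipeline run so that a run is fully determined by its configuration.
#'
#' @param structure path to a fingerprint TSV (see [read_fingerprints()]) or
#'   a SMILES table (extension `.smi`/`.smiles` or two-column CSV/TSV; see
#'   [read_smiles_table()]).
#' @param sensitivity path to the drug x cell-line z-score matrix.
#' @param perturbation path to the drug x gene perturbation-coefficient
#'   matrix.
#' @param genes path to a GMT file.
#' @param reference reference drug id.
#' @param gene_set_name gene set to use from the GMT; `NULL` = first.
#' @param n_perm,seed,K,t,mu,p_thresh,z_thresh screen and fusion parameters;
#'   see [permutation_screen()] and [select_hits()].
#' @param hit_network whether to compute the hit-network edges (one extra
#'   screen per hit).
#' @param out output directory.
#' @return A `run_config` list.
#' @export
run_config <- function(structure, sensitivity, perturbation, genes,
                       reference, gene_set_name = NULL, n_perm = 999L,
                       seed = 1L, K = 20L, t = 20L, mu = 0.5,
                       p_thresh = 0.05, z_thresh = -1.8,
                       hit_network = TRUE, out = ".") {
  n_perm <- as.integer(n_perm)
  if (n_perm < 1L) stop("n_perm must be at least 1")
  if (!is.numeric(mu) || mu <= 0) stop("mu must be positive")
  if (t < 1L) stop("t must be at least 1")
  structure(list(structure = structure, sensitivity = sensitivity,
                 perturbation = perturbation, genes = genes,
                 reference = reference, gene_set_name = gene_set_name,
                 n_perm = n_perm, seed = as.integer(seed),
                 K = as.integer(K), t = as.integer(t), mu = mu,
                 p_thresh = p_thresh, z_thresh = z_thresh,
                 hit_network = isTRUE(hit_network), out = out),
            class = "run_config")
}

## fingerprints either precomputed (TSV with on_bits column) or from SMILES
read_structure_input <- function(path) {
  if (grepl("\\.(smi|smiles)$", path, ignore.case = TRUE))
    return(read_smiles_table(path))
  head <- readLines(path, n = 1L, warn = FALSE)
  if (grepl("on_bits", head, fixed = TRUE)) read_fingerprints(path)
  else read_smiles_table(path)
}

#' Run the screening pipeline end to end
#'
#' Reads the three layer inputs and the gene set, assembles the aligned
#' profile set, runs the permutation screen against the reference drug,
#' selects hits, decomposes layer contributions, optionally builds the hit
#' network, and writes all artifacts plus a JSON run manifest (parameters,
#' seed, package version, input checksums) into the output directory. On any
#' error, partial outputs are removed.
#'
#' Artifacts written: `screen_results.tsv`, `hits.tsv`,
#' `layer_contributions.tsv`, `hit_network.tsv` + `hit_network.graphml`
#' (when enabled), `fused_network.csv`, `manifest.json`.
#'
#' @param cfg a [run_config()].
#' @return Invisibly, a list with the `screen_result`, hit table, layer
#'   contributions, hit-network edges and manifest.
#' @export
run_screen_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  if (!dir.exists(cfg$out)) dir.create(cfg$out, recursive = TRUE)
  written <- character(0)
  emit <- function(name) {
    p <- file.path(cfg$out, name)
    written[[length(written) + 1L]] <<- p
    p
  }
  tryCatch({
    fps <- read_structure_input(cfg$structure)
    sens <- read_matrix(cfg$sensitivity)
    pert <- read_matrix(cfg$perturbation)
    gs <- read_gene_set(cfg$genes, cfg$gene_set_name)
    profiles <- assemble_profile_set(fps, sens, pert)

    res <- permutation_screen(profiles, cfg$reference, gs,
                              n_perm = cfg$n_perm, seed = cfg$seed,
                              K = cfg$K, t = cfg$t, mu = cfg$mu)
    write_screen_results(res, emit("screen_results.tsv"),
                         p_thresh = cfg$p_thresh, z_thresh = cfg$z_thresh)
    hits <- select_hits(res, cfg$p_thresh, cfg$z_thresh)
    utils::write.table(hits, emit("hits.tsv"), sep = "\t", quote = FALSE,
                       row.names = FALSE)
    contrib <- layer_contribution(res$affinities, cfg$reference)
    utils::write.table(contrib, emit("layer_contributions.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    edges <- NULL
    if (cfg$hit_network && nrow(hits)) {
      edges <- build_hit_network(profiles, cfg$reference, hits$drug_id, gs,
                                 n_perm = cfg$n_perm, seed = cfg$seed,
                                 p_thresh = cfg$p_thresh,
                                 z_thresh = cfg$z_thresh,
                                 K = cfg$K, t = cfg$t, mu = cfg$mu)
      write_network(edges, emit("hit_network.tsv"), "edgelist")
      write_network(edges, emit("hit_network.graphml"), "graphml")
    }
    write_matrix(unclass(res$fused), emit("fused_network.csv"),
                 label = "drug_id")

    inputs <- c(structure = cfg$structure, sensitivity = cfg$sensitivity,
                perturbation = cfg$perturbation, genes = cfg$genes)
    manifest <- list(
      package = "pathdnf",
      version = as.character(utils::packageVersion("pathdnf")),
      reference = cfg$reference,
      gene_set = gs$name, gene_set_size = length(gs$genes),
      n_drugs = length(profiles$drug_ids),
      n_perm = cfg$n_perm, seed = cfg$seed,
      K = cfg$K, t = cfg$t, mu = cfg$mu,
      p_thresh = cfg$p_thresh, z_thresh = cfg$z_thresh,
      inputs = as.list(inputs),
      input_md5 = as.list(tools::md5sum(inputs)))
    jsonlite::write_json(manifest, emit("manifest.json"), auto_unbox = TRUE,
                         pretty = TRUE, digits = NA)
    invisible(list(screen = res, hits = hits, contributions = contrib,
                   edges = edges, manifest = manifest))
  }, error = function(e) {
    unlink(written)
    stop(e)
  })
}

#' Write a complete synthetic input bundle
#'
#' Simulates a panel with [simulate_panel()] and writes it in the exact file
#' formats the pipeline reads: fingerprint TSV, sensitivity CSV, perturbation
#' CSV, a GMT with the planted pathway, and a JSON ground-truth file.
#'
#' @param spec a [panel_spec()].
#' @param out output directory.
#' @return Invisibly, the named vector of files written.
#' @export
write_panel_bundle <- function(spec = panel_spec(), out = ".") {
  if (!dir.exists(out)) dir.create(out, recursive = TRUE)
  sim <- simulate_panel(spec)
  files <- c(structure = file.path(out, "fingerprints.tsv"),
             sensitivity = file.path(out, "sensitivity.csv"),
             perturbation = file.path(out, "perturbation.csv"),
             genes = file.path(out, "pathway.gmt"),
             truth = file.path(out, "truth.json"))
  write_fingerprints(sim$profiles$fingerprints, files[["structure"]])
  write_matrix(sim$profiles$sensitivity, files[["sensitivity"]],
               label = "drug_id")
  write_matrix(sim$profiles$perturbation, files[["perturbation"]],
               label = "drug_id")
  write_gene_sets(sim$truth$pathway, files[["genes"]])
  jsonlite::write_json(
    list(cluster = sim$truth$cluster, reference = sim$truth$reference,
         pathway_genes = sim$truth$pathway_genes,
         spec = unclass(spec)),
    files[["truth"]], auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(files)
}
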