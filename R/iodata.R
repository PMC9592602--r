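#' Read a labeled numeric matrix from delimited text
#'
#' Reads a CSV or TSV file with one header row of column labels and a first
#' column of row labels. The delimiter is chosen from the file extension:
#' comma for `.csv`, tab otherwise. Empty cells become `NA`.
#'
#' @param path file path.
#' @param rows_are_drugs if `FALSE`, the matrix is transposed after reading so
#'   that drugs end up in rows.
#' @return A numeric matrix with row and column names preserved verbatim.
#' @export
read_matrix <- function(path, rows_are_drugs = TRUE) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  raw <- utils::read.table(path, header = TRUE, sep = sep, quote = "\"",
                           check.names = FALSE, colClasses = "character",
                           row.names = NULL, comment.char = "",
                           stringsAsFactors = FALSE)
  if (ncol(raw) < 2L) stop("matrix file needs a label column plus data: ", path)
  rn <- raw[[1L]]
  if (anyDuplicated(rn))
    stop("duplicate row label(s): ",
         paste(unique(rn[duplicated(rn)]), collapse = ", "))
  cn <- colnames(raw)[-1L]
  if (anyDuplicated(cn))
    stop("duplicate column label(s): ",
         paste(unique(cn[duplicated(cn)]), collapse = ", "))
  m <- matrix(NA_real_, nrow(raw), length(cn), dimnames = list(rn, cn))
  for (j in seq_along(cn)) {
    cell <- trimws(raw[[j + 1L]])
    empty <- cell == "" | is.na(cell) | cell == "NA"
    val <- suppressWarnings(as.numeric(cell))
    bad <- !empty & is.na(val)
    if (any(bad)) {
      i <- which(bad)[1L]
      stop(sprintf("non-numeric cell '%s' at row '%s', column '%s' in %s",
                   cell[i], rn[i], cn[j], path))
    }
    m[, j] <- val
  }
  if (!rows_are_drugs) m <- t(m)
  m
}

#' Write a labeled numeric matrix as delimited text
#'
#' Counterpart of [read_matrix()]; values are written with full double
#' precision so that a write/read round trip is lossless.
#'
#' @param m labeled numeric matrix.
#' @param path output path; `.csv` selects comma, anything else tab.
#' @param label name of the row-label header cell.
#' @export
write_matrix <- function(m, path, label = "id") {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- data.frame(rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df) <- c(label, colnames(m))
  ## 17 significant digits round-trips doubles exactly
  num <- vapply(df, is.numeric, logical(1L))
  df[num] <- lapply(df[num], format, digits = 17, trim = TRUE, scientific = NA)
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE,
                     col.names = TRUE, na = "")
  invisible(path)
}

#' Read a two-column drug/SMILES table
#'
#' @param path delimited file (extension picks the separator as in
#'   [read_matrix()]) with a header row and two columns: drug identifier and
#'   SMILES string. SMILES are not validated here; chemistry errors surface
#'   when fingerprints are computed.
#' @return A data frame with columns `drug_id` and `smiles`, in file order.
#' @export
read_smiles_table <- function(path) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep, quote = "\"",
                          check.names = FALSE, colClasses = "character",
                          comment.char = "", stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("SMILES table needs two columns: ", path)
  out <- data.frame(drug_id = df[[1L]], smiles = df[[2L]],
                    stringsAsFactors = FALSE)
  if (anyDuplicated(out$drug_id))
    stop("duplicate drug id(s) in SMILES table: ",
         paste(unique(out$drug_id[duplicated(out$drug_id)]), collapse = ", "))
  out$smiles[is.na(out$smiles)] <- ""
  out
}

#' Read a gene set from a GMT file
#'
#' Standard GMT: one set per line, tab-separated fields `name`, `description`,
#' then gene symbols. Duplicate symbols within a line are removed.
#'
#' @param path GMT file path.
#' @param name set to extract; `NULL` takes the first set in the file.
#' @return A [gene_set()].
#' @export
read_gene_set <- function(path, name = NULL) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty GMT file: ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  set_names <- vapply(fields, `[[`, character(1L), 1L)
  if (is.null(name)) {
    idx <- 1L
  } else {
    idx <- match(name, set_names)
    if (is.na(idx))
      stop("gene set '", name, "' not found in ", path,
           " (available: ", paste(set_names, collapse = ", "), ")")
  }
  f <- fields[[idx]]
  if (length(f) < 3L) stop("gene set '", f[1L], "' is empty")
  gene_set(f[1L], f[-(1:2)])
}

#' Write gene sets to a GMT file
#'
#' @param sets a `gene_set` or list of them.
#' @param path output path.
#' @export
write_gene_sets <- function(sets, path) {
  if (inherits(sets, "gene_set")) sets <- list(sets)
  lines <- vapply(sets, function(s)
    paste(c(s$name, "na", s$genes), collapse = "\t"), character(1L))
  writeLines(lines, path)
  invisible(path)
}

#' Assemble an aligned multi-layer drug profile set
#'
#' Restricts the three layers to the drugs present in all of them, sorted
#' lexicographically, so every downstream matrix shares one deterministic
#' index. Drugs with an entirely missing sensitivity or perturbation row are
#' dropped before intersecting. The intersection size and any dropped drugs
#' are reported via `message()`.
#'
#' @param fingerprints named list of [bit_fingerprint()]s, or a data frame as
#'   returned by [read_smiles_table()] (fingerprints are then computed with
#'   [ecfp_fingerprint()] defaults).
#' @param sensitivity drug x cell-line numeric matrix.
#' @param perturbation drug x gene numeric matrix.
#' @return A [drug_profile_set()] over the common drugs.
#' @export
assemble_profile_set <- function(fingerprints, sensitivity, perturbation) {
  if (is.data.frame(fingerprints)) {
    tab <- fingerprints
    fingerprints <- lapply(seq_len(nrow(tab)), function(i)
      ecfp_fingerprint(tab$smiles[i], drug_id = tab$drug_id[i]))
    names(fingerprints) <- tab$drug_id
  }
  drop_all_na <- function(m, layer) {
    bad <- rowSums(!is.na(m)) == 0L
    if (any(bad))
      message("dropping ", sum(bad), " drug(s) with all-missing ", layer,
              " profile: ", paste(rownames(m)[bad], collapse = ", "))
    m[!bad, , drop = FALSE]
  }
  sensitivity <- drop_all_na(sensitivity, "sensitivity")
  perturbation <- drop_all_na(perturbation, "perturbation")
  common <- sort(Reduce(intersect, list(names(fingerprints),
                                        rownames(sensitivity),
                                        rownames(perturbation))))
  if (!length(common))
    stop("no drugs common to the structure, sensitivity and perturbation layers")
  message("assembled profile set over ", length(common), " common drugs")
  drug_profile_set(fingerprints[common],
                   sensitivity[common, , drop = FALSE],
                   perturbation[common, , drop = FALSE])
}

#' Write permutation-screen results as TSV
#'
#' One row per non-reference drug, sorted by observed rank, with columns
#' `drug_id`, `observed_similarity`, `observed_rank`, `null_mean`, `null_sd`,
#' `zscore`, `pvalue`, `significant`.
#'
#' @param result a `screen_result` from [permutation_screen()].
#' @param path output path.
#' @param p_thresh,z_thresh thresholds defining the `significant` column
#'   (p < `p_thresh` and z < `z_thresh`).
#' @export
write_screen_results <- function(result, path, p_thresh = 0.05,
                                 z_thresh = -1.8) {
  stopifnot(inherits(result, "screen_result"))
  tab <- result$table
  out <- data.frame(
    drug_id = tab$drug_id,
    observed_similarity = format(tab$observed_similarity, digits = 17,
                                 trim = TRUE),
    observed_rank = format(tab$observed_rank, digits = 17, trim = TRUE),
    null_mean = format(tab$null_mean, digits = 17, trim = TRUE),
    null_sd = format(tab$null_sd, digits = 17, trim = TRUE),
    zscore = format(tab$zscore, digits = 17, trim = TRUE),
    pvalue = format(tab$pvalue, digits = 17, trim = TRUE),
    significant = ifelse(tab$pvalue < p_thresh & tab$zscore < z_thresh,
                         "true", "false"),
    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read back a screen-results TSV
#'
#' @param path file written by [write_screen_results()].
#' @return A data frame with numeric columns restored.
#' @export
read_screen_results <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  df$significant <- df$significant == "true"
  df
}

#' Write a drug-drug network
#'
#' @param edges data frame with columns `source`, `target`, `pvalue`.
#' @param path output path.
#' @param format `"edgelist"` for a three-column TSV, `"graphml"` for GraphML
#'   with `pvalue` as an edge attribute.
#' @export
write_network <- function(edges, path, format = c("edgelist", "graphml")) {
  format <- match.arg(format)
  stopifnot(is.data.frame(edges),
            all(c("source", "target", "pvalue") %in% names(edges)))
  if (format == "edgelist") {
    out <- edges[, c("source", "target", "pvalue")]
    out$pvalue <- format(out$pvalue, digits = 17, trim = TRUE)
    utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
    return(invisible(path))
  }
  doc <- xml2::xml_new_root("graphml",
    xmlns = "http://graphml.graphdrawing.org/xmlns")
  key <- xml2::xml_add_child(doc, "key", id = "pvalue", `for` = "edge",
                             attr.name = "pvalue", attr.type = "double")
  g <- xml2::xml_add_child(doc, "graph", id = "G", edgedefault = "undirected")
  nodes <- unique(c(edges$source, edges$target))
  for (n in nodes) xml2::xml_add_child(g, "node", id = n)
  for (i in seq_len(nrow(edges))) {
    e <- xml2::xml_add_child(g, "edge", source = edges$source[i],
                             target = edges$target[i])
    d <- xml2::xml_add_child(e, "data", key = "pvalue")
    xml2::xml_text(d) <- format(edges$pvalue[i], digits = 17, trim = TRUE)
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

#' Read/write precomputed bit fingerprints
#'
#' TSV with columns `drug_id`, `on_bits` (comma-separated zero-based bit
#' positions; empty for an all-zero fingerprint) and `length`. This bypasses
#' chemistry entirely: a panel can be screened without SMILES.
#'
#' @param path file path.
#' @return For `read_fingerprints`, a named list of [bit_fingerprint()]s.
#' @export
read_fingerprints <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          colClasses = "character", stringsAsFactors = FALSE)
  if (!all(c("drug_id", "on_bits", "length") %in% names(df)))
    stop("fingerprint file needs columns drug_id, on_bits, length: ", path)
  if (anyDuplicated(df$drug_id))
    stop("duplicate drug id(s) in fingerprint file")
  fps <- lapply(seq_len(nrow(df)), function(i) {
    bits <- df$on_bits[i]
    on <- if (is.na(bits) || bits == "") integer(0)
          else as.integer(strsplit(bits, ",", fixed = TRUE)[[1L]])
    bit_fingerprint(as.integer(df$length[i]), on)
  })
  names(fps) <- df$drug_id
  fps
}

#' @rdname read_fingerprints
#' @param fps named list of [bit_fingerprint()]s to write.
#' @export
write_fingerprints <- function(fps, path) {
  df <- data.frame(
    drug_id = names(fps),
    on_bits = vapply(fps, function(f) paste(f$on_bits, collapse = ","),
                     character(1L)),
    length = vapply(fps, function(f) f$length, integer(1L)),
    stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
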