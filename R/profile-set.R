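#' Multi-layer drug profile set
#'
#' A `drug_profile_set` holds the three data layers of the pipeline, aligned
#' over one common, lexicographically ordered drug index: bit fingerprints of
#' drug structure, a drug x cell-line sensitivity matrix (z-scores from
#' dose-response screening), and a drug x gene matrix of perturbation
#' coefficients (standardized regression coefficients of drug effect on
#' expression).
#'
#' @param fingerprints named list of [bit_fingerprint()] objects, one per drug.
#' @param sensitivity numeric matrix, drugs in rows, cell lines in columns.
#' @param perturbation numeric matrix, drugs in rows, genes in columns.
#' @return An object of class `drug_profile_set` with elements `drug_ids`,
#'   `fingerprints`, `sensitivity`, `perturbation`, `gene_ids`, `cell_ids`.
#' @seealso [assemble_profile_set()] which intersects and aligns unmatched
#'   layers before calling this constructor.
#' @export
drug_profile_set <- function(fingerprints, sensitivity, perturbation) {
  ids <- names(fingerprints)
  if (is.null(ids) || anyNA(ids) || any(ids == ""))
    stop("fingerprints must be a fully named list")
  if (anyDuplicated(ids))
    stop("duplicate drug ids: ", paste(unique(ids[duplicated(ids)]), collapse = ", "))
  if (!identical(rownames(sensitivity), ids) ||
      !identical(rownames(perturbation), ids))
    stop("sensitivity and perturbation rows must match fingerprint names in order")
  if (anyDuplicated(colnames(sensitivity)))
    stop("duplicate cell-line ids")
  if (anyDuplicated(colnames(perturbation)))
    stop("duplicate gene ids")
  all_na <- function(m) rowSums(!is.na(m)) == 0L
  bad <- all_na(sensitivity) | all_na(perturbation)
  if (any(bad))
    stop("drug(s) with an entirely missing layer: ",
         paste(ids[bad], collapse = ", "))
  structure(
    list(drug_ids = ids,
         fingerprints = fingerprints,
         sensitivity = sensitivity,
         perturbation = perturbation,
         gene_ids = colnames(perturbation),
         cell_ids = colnames(sensitivity)),
    class = "drug_profile_set")
}

#' @export
print.drug_profile_set <- function(x, ...) {
  cat(sprintf("drug_profile_set: %d drugs, %d cell lines, %d genes, %d-bit fingerprints\n",
              length(x$drug_ids), length(x$cell_ids), length(x$gene_ids),
              if (length(x$fingerprints)) x$fingerprints[[1]]$length else 0L))
  invisible(x)
}

#' Subset a drug profile set by drug identifier
#'
#' @param x a `drug_profile_set`.
#' @param drugs character vector of drug ids to keep (original order is
#'   preserved regardless of the order given here).
#' @return A `drug_profile_set` restricted to `drugs`.
#' @export
subset_drugs <- function(x, drugs) {
  stopifnot(inherits(x, "drug_profile_set"))
  missing <- setdiff(drugs, x$drug_ids)
  if (length(missing))
    stop("unknown drug id(s): ", paste(missing, collapse = ", "))
  keep <- x$drug_ids[x$drug_ids %in% drugs]
  drug_profile_set(x$fingerprints[keep],
                   x$sensitivity[keep, , drop = FALSE],
                   x$perturbation[keep, , drop = FALSE])
}

#' Pathway gene set
#'
#' @param name gene-set name.
#' @param genes character vector of gene symbols; duplicates are removed.
#' @return An object of class `gene_set` with fields `name` and `genes`.
#' @export
gene_set <- function(name, genes) {
  genes <- unique(as.character(genes))
  genes <- genes[!is.na(genes) & genes != ""]
  if (!length(genes)) stop("gene set '", name, "' is empty")
  structure(list(name = as.character(name), genes = genes), class = "gene_set")
}

#' @export
print.gene_set <- function(x, ...) {
  cat(sprintf("gene_set '%s': %d genes\n", x$name, length(x$genes)))
  invisible(x)
}

#' The six-gene mevalonate pathway set
#'
#' The mevalonate (MVA) pathway genes present among the L1000 landmark genes:
#' ACLY, ACAT2, HMGCS1, HMGCR, FDFT1 and INSIG1. HMGCR is the rate-limiting
#' enzyme targeted by statins; restricting the perturbation layer to these
#' genes makes the fused network pathway-centric.
#'
#' @return A `gene_set` of the six genes.
#' @export
mva_gene_set <- function() {
  gene_set("MVA", c("ACLY", "ACAT2", "HMGCS1", "HMGCR", "FDFT1", "INSIG1"))
}
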