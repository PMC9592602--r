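test_that("labeled matrices round-trip losslessly, with missing cells", {
  m <- matrix(c(1.25, NA, pi, -2e-7, 0, 1/3), 3, 2,
              dimnames = list(c("a", "b", "c"), c("x", "y")))
  path <- withr::local_tempfile(fileext = ".csv")
  write_matrix(m, path)
  back <- read_matrix(path)
  expect_identical(dimnames(back), dimnames(m))
  expect_equal(back, m)
  expect_equal(sum(is.na(back)), 1L)
  # tab dialect too
  path2 <- withr::local_tempfile(fileext = ".tsv")
  write_matrix(m, path2)
  expect_equal(read_matrix(path2), m)
  # orientation flag transposes
  expect_equal(read_matrix(path, rows_are_drugs = FALSE), t(m))
})

test_that("matrix reader rejects duplicate labels and bad cells by location", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("id,x,y", "a,1,2", "a,3,4"), path)
  expect_error(read_matrix(path), "duplicate row label.*a")
  writeLines(c("id,x,x", "a,1,2"), path)
  expect_error(read_matrix(path), "duplicate column label.*x")
  writeLines(c("id,x,y", "a,1,oops", "b,2,3"), path)
  expect_error(read_matrix(path), "oops.*row 'a', column 'y'")
})

test_that("SMILES tables keep file order, empty fields, and reject duplicates", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("drug,smiles", "aspirin,CC(=O)Oc1ccccc1C(=O)O", "mystery,"),
             path)
  tab <- read_smiles_table(path)
  expect_identical(tab$drug_id, c("aspirin", "mystery"))
  expect_identical(tab$smiles[2], "")
  writeLines(c("drug,smiles", "aspirin,C", "aspirin,CC"), path)
  expect_error(read_smiles_table(path), "duplicate.*aspirin")
})

test_that("GMT parsing extracts, deduplicates and validates gene sets", {
  path <- withr::local_tempfile(fileext = ".gmt")
  writeLines(c("MVA\tdesc\tACLY\tACAT2\tHMGCS1\tHMGCR\tFDFT1\tINSIG1",
               "DUP\tdesc\tTP53\tTP53\tMYC"), path)
  gs <- read_gene_set(path, "MVA")
  expect_s3_class(gs, "gene_set")
  expect_length(gs$genes, 6)
  expect_setequal(gs$genes, mva_gene_set()$genes)
  # first set when no name given
  expect_identical(read_gene_set(path)$name, "MVA")
  # duplicates within a line are removed
  expect_length(read_gene_set(path, "DUP")$genes, 2)
  expect_error(read_gene_set(path, "ABSENT"), "not found")
  writeLines("EMPTY\tdesc", path)
  expect_error(read_gene_set(path, "EMPTY"), "empty")
})

test_that("profile assembly intersects drugs, sorts them, and is idempotent", {
  fp <- function() bit_fingerprint(8, c(0, 1))
  fps <- list(c = fp(), a = fp(), b = fp())
  sens <- matrix(rnorm(8), 4, 2,
                 dimnames = list(c("b", "c", "d", "e"), c("x", "y")))
  pert <- matrix(rnorm(6), 3, 2, dimnames = list(c("c", "b", "z"),
                                                 c("g1", "g2")))
  ps <- suppressMessages(assemble_profile_set(fps, sens, pert))
  expect_identical(ps$drug_ids, c("b", "c"))
  # idempotent: re-assembling its own layers is the identity
  ps2 <- suppressMessages(
    assemble_profile_set(ps$fingerprints, ps$sensitivity, ps$perturbation))
  expect_equal(ps2, ps)
  # intersection size does not depend on which layer carries which universe
  sens2 <- matrix(rnorm(6), 3, 2, dimnames = list(c("c", "b", "z"),
                                                  c("x", "y")))
  pert2 <- matrix(rnorm(8), 4, 2, dimnames = list(c("b", "c", "d", "e"),
                                                  c("g1", "g2")))
  ps3 <- suppressMessages(assemble_profile_set(fps, sens2, pert2))
  expect_identical(ps3$drug_ids, ps$drug_ids)
  # empty intersection errors
  pert_zz <- matrix(rnorm(4), 2, 2, dimnames = list(c("q", "r"),
                                                    c("g1", "g2")))
  expect_error(suppressMessages(assemble_profile_set(fps, sens, pert_zz)),
               "no drugs common")
})

test_that("drugs with an all-missing layer are dropped at assembly", {
  fp <- function() bit_fingerprint(8, 0)
  fps <- list(a = fp(), b = fp(), c = fp())
  sens <- matrix(c(1, 2, NA, NA, 5, 6), 3, 2, byrow = TRUE,
                 dimnames = list(c("a", "b", "c"), c("x", "y")))
  pert <- matrix(rnorm(6), 3, 2, dimnames = list(c("a", "b", "c"),
                                                 c("g1", "g2")))
  expect_message(ps <- assemble_profile_set(fps, sens, pert),
                 "all-missing sensitivity.*b")
  expect_identical(ps$drug_ids, c("a", "c"))
})

test_that("screen results TSV excludes the reference and round-trips", {
  sim <- simulate_panel(small_spec())
  res <- small_screen(sim, n_perm = 9)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_screen_results(res, path)
  back <- read_screen_results(path)
  expect_equal(nrow(back), length(sim$profiles$drug_ids) - 1L)
  expect_false(sim$truth$reference %in% back$drug_id)
  expect_equal(back$zscore, res$table$zscore, tolerance = 1e-15)
  expect_equal(back$pvalue, res$table$pvalue, tolerance = 1e-15)
  expect_identical(back$significant,
                   res$table$pvalue < 0.05 & res$table$zscore < -1.8)
  expect_false(is.unsorted(back$observed_rank))
})

test_that("network writers produce edge lists and valid GraphML", {
  edges <- data.frame(source = c("a", "b"), target = c("b", "c"),
                      pvalue = c(0.01, 0.04))
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_network(edges, tsv, "edgelist")
  back <- utils::read.table(tsv, header = TRUE, sep = "\t")
  expect_equal(nrow(back), 2)
  expect_equal(back$pvalue, edges$pvalue)

  gml <- withr::local_tempfile(fileext = ".graphml")
  write_network(edges, gml, "graphml")
  doc <- xml2::read_xml(gml)  # parse failure would throw
  ns <- xml2::xml_ns(doc)
  expect_length(xml2::xml_find_all(doc, "//d1:node", ns), 3)
  e <- xml2::xml_find_all(doc, "//d1:edge/d1:data", ns)
  expect_equal(as.numeric(xml2::xml_text(e)), edges$pvalue)

  # empty edge set: header-only file, no error
  none <- edges[0, ]
  write_network(none, tsv, "edgelist")
  expect_equal(nrow(utils::read.table(tsv, header = TRUE, sep = "\t")), 0)
  expect_error(write_network(edges, tsv, "dot"), "arg")
})

test_that("precomputed fingerprints round-trip through the TSV format", {
  fps <- list(a = bit_fingerprint(64, c(0, 5, 63)),
              b = bit_fingerprint(64, integer(0)))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_fingerprints(fps, path)
  back <- read_fingerprints(path)
  expect_equal(back, fps)
})
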