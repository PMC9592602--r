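test_that("reference ranking sorts by similarity with average ranks at ties", {
  f <- matrix(c(1, 0.9, 0.1, 0.5,
                0.9, 1, 0.2, 0.5,
                0.1, 0.2, 1, 0.5,
                0.5, 0.5, 0.5, 1), 4, 4,
              dimnames = list(letters[1:4], letters[1:4]))
  rk <- rank_by_reference(f, "a")
  expect_identical(rk$drug_id, c("b", "d", "c"))
  expect_equal(rk$rank, c(1, 2, 3))
  # ties share the average rank
  f2 <- matrix(c(1, 0.5, 0.5, 0.5, 1, 0.1, 0.5, 0.1, 1), 3, 3,
               dimnames = list(letters[1:3], letters[1:3]))
  rk2 <- rank_by_reference(f2, "a")
  expect_equal(rk2$rank, c(1.5, 1.5))
  expect_error(rank_by_reference(f, "zzz"), "unknown reference")
})

test_that("the permutation screen is bit-reproducible given its seed", {
  sim <- simulate_panel(small_spec())
  r1 <- small_screen(sim, n_perm = 11, seed = 5)
  r2 <- small_screen(sim, n_perm = 11, seed = 5)
  expect_identical(r1$table, r2$table)
  r3 <- small_screen(sim, n_perm = 11, seed = 6)
  expect_false(identical(r1$table, r3$table))
  # ranks are a (tie-averaged) permutation of 1..n-1 and p lies in (0, 1]
  expect_equal(sort(r1$table$observed_rank),
               seq_len(nrow(r1$table)), tolerance = 1e-12)
  expect_true(all(r1$table$pvalue > 0 & r1$table$pvalue <= 1))
})

test_that("gene-set-independent affinities are computed exactly once", {
  sim <- simulate_panel(small_spec())
  calls <- new.env()
  calls$n <- 0L
  real_affinity <- affinity_matrix
  local_mocked_bindings(
    affinity_matrix = function(...) {
      calls$n <- calls$n + 1L
      real_affinity(...)
    },
    .package = "pathdnf")
  n_perm <- 7L
  small_screen(sim, n_perm = n_perm)
  # 3 observed layers + one perturbation affinity per permutation
  expect_identical(calls$n, 3L + n_perm)
})

test_that("an exhausted gene pool forces the degenerate-null sentinel", {
  sim <- simulate_panel(small_spec())
  # shrink the gene universe to exactly the pathway set: every random draw
  # reproduces the observed layer
  prof <- sim$profiles
  prof$perturbation <- prof$perturbation[, sim$truth$pathway_genes]
  prof$gene_ids <- sim$truth$pathway_genes
  res <- suppressMessages(do.call(permutation_screen, c(
    list(profiles = prof, reference = sim$truth$reference,
         gs = sim$truth$pathway, n_perm = 2L, seed = 1),
    small_screen_args)))
  expect_true(all(res$table$degenerate))
  expect_true(all(res$table$zscore == 0))
  expect_true(all(res$table$pvalue == 1))
})

test_that("screen input contracts are enforced", {
  sim <- simulate_panel(small_spec())
  expect_error(small_screen(sim, reference = "nope"), "unknown reference")
  expect_error(small_screen(sim, gs = gene_set("x", c("no1", "no2"))),
               "none of the")
  expect_error(small_screen(sim, n_perm = 0), "n_perm")
})

test_that("hit selection applies both thresholds, z binding under p = Phi(z)", {
  sim <- simulate_panel(small_spec())
  res <- small_screen(sim, n_perm = 19)
  hits <- select_hits(res)
  expect_true(all(hits$pvalue < 0.05 & hits$zscore < -1.8))
  # since p = pnorm(z), the z cutoff alone reproduces the default selection
  z_only <- res$table[res$table$zscore < -1.8, "drug_id"]
  expect_setequal(hits$drug_id, z_only)
  expect_equal(nrow(select_hits(res, z_thresh = -Inf)), 0)
})

test_that("layer contributions decompose reference affinity into percents", {
  mk <- function(val_b, val_c) {
    m <- matrix(c(1, val_b, val_c, val_b, 1, 0, val_c, 0, 1), 3, 3,
                dimnames = list(letters[1:3], letters[1:3]))
    m
  }
  layers <- list(structure = mk(0.8, 0), sensitivity = mk(0.1, 0),
                 perturbation = mk(0.1, 0))
  lc <- layer_contribution(layers, "a")
  b <- lc[lc$drug_id == "b", ]
  expect_equal(c(b$structure_pct, b$sensitivity_pct, b$perturbation_pct),
               c(80, 10, 10))
  # equal layers split evenly; degenerate all-zero rows are flagged uniform
  eq <- layer_contribution(list(s1 = mk(0.4, 0), s2 = mk(0.4, 0),
                                s3 = mk(0.4, 0)), "a")
  expect_equal(unlist(eq[eq$drug_id == "b", 2:4], use.names = FALSE),
               rep(100 / 3, 3))
  cc <- eq[eq$drug_id == "c", ]
  expect_true(cc$degenerate)
  expect_equal(unlist(cc[, 2:4], use.names = FALSE), rep(100 / 3, 3))
  # percentages always sum to 100
  expect_equal(rowSums(lc[, 2:4]), rep(100, nrow(lc)), tolerance = 1e-9)
  expect_error(layer_contribution(layers, "zzz"), "unknown reference")
})

test_that("the hit network is an undirected union keeping the smaller p", {
  sim <- simulate_panel(small_spec())
  mates <- setdiff(sim$truth$cluster, sim$truth$reference)
  edges <- suppressMessages(do.call(build_hit_network, c(
    list(profiles = sim$profiles, reference = sim$truth$reference,
         hits = mates[1:2], gs = sim$truth$pathway, n_perm = 19L, seed = 3),
    small_screen_args)))
  expect_true(is.data.frame(edges))
  if (nrow(edges)) {
    expect_identical(colnames(edges), c("source", "target", "pvalue"))
    # unordered pairs are unique
    key <- paste(pmin(edges$source, edges$target),
                 pmax(edges$source, edges$target))
    expect_false(anyDuplicated(key) > 0)
    expect_true(all(edges$pvalue < 0.05))
  }
})

test_that("reciprocal screens return per-reference hits and symmetric overlaps", {
  sim <- simulate_panel(small_spec())
  refs <- sim$truth$cluster[1:2]
  rec <- suppressMessages(do.call(reciprocal_screen, c(
    list(profiles = sim$profiles, references = refs,
         gs = sim$truth$pathway, n_perm = 19L, seed = 2),
    small_screen_args)))
  expect_named(rec$hits, refs)
  expect_true(isSymmetric(rec$overlap))
  expect_equal(diag(rec$overlap),
               setNames(lengths(rec$hits), refs))
  # identical references give identical hit sets (same derived seed)
  rec2 <- suppressMessages(do.call(reciprocal_screen, c(
    list(profiles = sim$profiles, references = c(refs[1], refs[1]),
         gs = sim$truth$pathway, n_perm = 19L, seed = 2),
    small_screen_args)))
  expect_identical(rec2$hits[[1]], rec2$hits[[2]])
})

test_that("the benchmark reports one timed row per gene-set size", {
  sim <- simulate_panel(small_spec())
  sizes <- c(4L, 8L, 16L)
  bench <- suppressMessages(do.call(benchmark_pipeline, c(
    list(profiles = sim$profiles, gene_sizes = sizes, n_perm = 3L, seed = 1),
    small_screen_args)))
  expect_equal(bench$gene_size, sizes)
  expect_true(all(bench$cpu_seconds > 0))
  expect_true(all(bench$peak_memory_mb > 0))
  expect_error(suppressMessages(do.call(benchmark_pipeline, c(
    list(profiles = sim$profiles, gene_sizes = 10000L, n_perm = 2L),
    small_screen_args))), "universe")
})
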