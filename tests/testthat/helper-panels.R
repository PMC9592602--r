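## Small panels and screen settings shared across test files. Screens on
## these run in well under a second per permutation batch.

small_spec <- function(seed = 42, ...) {
  panel_spec(n_drugs = 16, n_cells = 10, n_genes = 40, pathway_size = 4,
             cluster_size = 4, fingerprint_bits = 128,
             fingerprint_core_bits = 24, seed = seed, ...)
}

small_screen_args <- list(K = 5L, t = 5L, mu = 0.5)

small_screen <- function(sim, reference = NULL, gs = NULL, n_perm = 19,
                         seed = 7, ...) {
  if (is.null(reference)) reference <- sim$truth$reference
  if (is.null(gs)) gs <- sim$truth$pathway
  suppressMessages(do.call(permutation_screen, c(
    list(profiles = sim$profiles, reference = reference, gs = gs,
         n_perm = n_perm, seed = seed, ...),
    small_screen_args)))
}

## hand-built three-drug profile set with fully controlled values
tiny_profiles <- function() {
  fps <- list(
    a = bit_fingerprint(16, c(1, 2, 3)),
    b = bit_fingerprint(16, c(2, 3, 4)),
    c = bit_fingerprint(16, c(10, 11)))
  sens <- matrix(c(1, 2, 3, 4,
                   2, 4, 6, 8,
                   4, 3, 2, 1), 3, 4, byrow = TRUE,
                 dimnames = list(c("a", "b", "c"), paste0("cell", 1:4)))
  pert <- matrix(c(0.1, -0.2, 0.5, 1.0,
                   0.2, -0.1, 0.6, 0.9,
                   -1.0, 0.8, -0.3, 0.2), 3, 4, byrow = TRUE,
                 dimnames = list(c("a", "b", "c"), paste0("g", 1:4)))
  drug_profile_set(fps, sens, pert)
}
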