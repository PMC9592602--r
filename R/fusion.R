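#' Convert a similarity matrix to a distance matrix
#'
#' d(i, j) = 1 - s(i, j): zero diagonal, range `[0, 1]` for Tanimoto input and
#' `[0, 2]` for Pearson input. The bridge between the similarity layers and
#' the local-scaling affinity kernel.
#'
#' @param S square symmetric similarity matrix with unit diagonal.
#' @return A distance matrix of the same dimension and dimnames.
#' @export
similarity_to_distance <- function(S) {
  stopifnot(is.matrix(S), nrow(S) == ncol(S))
  if (max(abs(diag(S) - 1)) > 1e-12) stop("similarity diagonal must be 1")
  D <- 1 - unclass(S)
  diag(D) <- 0
  attr(D, "range") <- NULL
  D
}

#' Locally scaled exponential affinity matrix
#'
#' The scaled exponential kernel of similarity network fusion:
#' eps(i, j) = (mean_K(i) + mean_K(j) + d(i, j)) / 3, where mean_K(i) is the
#' mean distance from i to its K nearest non-self neighbors, and
#' W(i, j) = exp(-d(i, j)^2 / (mu * eps(i, j))). Coincident points
#' (eps = 0) get affinity 1 to avoid 0/0.
#'
#' @param D square symmetric distance matrix, zero diagonal.
#' @param K neighborhood size, `0 < K < n`.
#' @param mu kernel bandwidth factor, positive; typical range 0.3-0.8.
#' @return An `affinity_matrix`: nonnegative symmetric matrix with the
#'   parameters in attributes `K` and `mu`.
#' @export
affinity_matrix <- function(D, K = 20L, mu = 0.5) {
  stopifnot(is.matrix(D), nrow(D) == ncol(D))
  n <- nrow(D)
  K <- as.integer(K)
  if (K <= 0L || K >= n)
    stop("K must satisfy 0 < K < n (n = ", n, ", K = ", K, ")")
  if (!is.numeric(mu) || mu <= 0) stop("mu must be positive")
  ## mean distance to the K nearest non-self neighbors of each point
  mk <- vapply(seq_len(n), function(i) {
    d <- D[i, -i]
    mean(sort(d, method = "radix")[seq_len(K)])
  }, numeric(1L))
  eps <- (outer(mk, mk, "+") + D) / 3
  W <- ifelse(eps > 0, exp(-D^2 / (mu * eps)), 1)
  W <- (W + t(W)) / 2
  dimnames(W) <- dimnames(D)
  structure(W, K = K, mu = mu, class = c("affinity_matrix", "matrix", "array"))
}

## full kernel: P(i,j) = W(i,j) / (2 * sum_{k != i} W(i,k)) off-diagonal,
## P(i,i) = 1/2; rows sum to 1
snf_normalize <- function(W) {
  W <- unclass(W)
  off <- rowSums(W) - diag(W)
  off[off == 0] <- .Machine$double.eps
  P <- W / (2 * off)
  diag(P) <- 0.5
  P
}

## sparse kernel: row-normalized W restricted to each row's K nearest
## non-self neighbors (ties broken by column index), zero elsewhere
snf_sparse_kernel <- function(W, K) {
  W <- unclass(W)
  n <- nrow(W)
  S <- matrix(0, n, n, dimnames = dimnames(W))
  for (i in seq_len(n)) {
    w <- W[i, ]
    w[i] <- -Inf
    nn <- order(w, decreasing = TRUE)[seq_len(K)]
    tot <- sum(W[i, nn])
    if (tot == 0) tot <- .Machine$double.eps
    S[i, nn] <- W[i, nn] / tot
  }
  S
}

#' Fuse affinity matrices by similarity network fusion
#'
#' Iterative cross-diffusion of the per-layer full kernels through each
#' layer's sparse K-nearest-neighbor kernel: at every step and for every
#' layer v, `P_v <- S_v %*% mean(P_u, u != v) %*% t(S_v)`, followed by
#' re-normalization of `P_v` and symmetrization. After `t` iterations the
#' fused network is the element-wise mean of the layer kernels. With a single
#' layer the cross-layer mean degenerates to the layer's own kernel.
#'
#' @param affinities list of [affinity_matrix()] objects over the identical
#'   drug index and order.
#' @param K neighborhood size of the sparse kernel.
#' @param t number of fusion iterations.
#' @return A `fused_network`: the fused matrix with attributes `K`, `t`,
#'   `mu` (per layer), and `layers` (names of the input layers).
#' @export
snf_fuse <- function(affinities, K = 20L, t = 20L) {
  stopifnot(is.list(affinities), length(affinities) >= 1L)
  t <- as.integer(t)
  if (t < 1L) stop("t must be at least 1")
  ids <- rownames(affinities[[1L]])
  for (W in affinities)
    if (!identical(rownames(W), ids) || !identical(colnames(W), ids))
      stop("affinity matrices must share one drug index and order")
  n <- length(ids)
  K <- as.integer(K)
  if (K <= 0L || K >= n) stop("K must satisfy 0 < K < n")
  m <- length(affinities)

  P <- lapply(affinities, snf_normalize)
  S <- lapply(affinities, snf_sparse_kernel, K = K)
  for (step in seq_len(t)) {
    Pnew <- vector("list", m)
    for (v in seq_len(m)) {
      avg <- if (m == 1L) P[[1L]]
             else Reduce(`+`, P[-v]) / (m - 1L)
      Q <- S[[v]] %*% avg %*% t(S[[v]])
      Q <- snf_normalize(Q)
      Pnew[[v]] <- (Q + t(Q)) / 2
    }
    P <- Pnew
  }
  fused <- Reduce(`+`, P) / m
  fused <- (fused + t(fused)) / 2
  dimnames(fused) <- list(ids, ids)
  structure(fused, K = K, t = t,
            mu = vapply(affinities, function(W) {
              m <- attr(W, "mu"); if (is.null(m)) NA_real_ else m
            }, numeric(1L)),
            layers = if (!is.null(names(affinities))) names(affinities)
                     else paste0("layer", seq_len(m)),
            class = c("fused_network", "matrix", "array"))
}

#' @export
print.fused_network <- function(x, ...) {
  cat(sprintf("fused_network: %d drugs, layers [%s], K = %d, t = %d\n",
              nrow(x), paste(attr(x, "layers"), collapse = ", "),
              attr(x, "K"), attr(x, "t")))
  invisible(x)
}
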