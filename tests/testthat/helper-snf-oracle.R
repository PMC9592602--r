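## Independent, deliberately naive implementations of the affinity kernel and
## the fusion update equations, written with explicit element-wise loops.
## These serve as oracles for the vectorized package code and must never call
## into it.

oracle_affinity <- function(D, K, mu) {
  n <- nrow(D)
  mk <- numeric(n)
  for (i in seq_len(n)) {
    d <- sort(D[i, -i])
    mk[i] <- mean(d[1:K])
  }
  W <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    eps <- (mk[i] + mk[j] + D[i, j]) / 3
    W[i, j] <- if (eps > 0) exp(-D[i, j]^2 / (mu * eps)) else 1
  }
  (W + t(W)) / 2
}

oracle_normalize <- function(W) {
  n <- nrow(W)
  P <- matrix(0, n, n)
  for (i in seq_len(n)) {
    s <- sum(W[i, -i])
    if (s == 0) s <- .Machine$double.eps
    for (j in seq_len(n)) P[i, j] <- if (i == j) 0.5 else W[i, j] / (2 * s)
  }
  P
}

oracle_sparse <- function(W, K) {
  n <- nrow(W)
  S <- matrix(0, n, n)
  for (i in seq_len(n)) {
    w <- W[i, ]
    w[i] <- -Inf
    nn <- order(w, decreasing = TRUE)[1:K]
    s <- sum(W[i, nn])
    if (s == 0) s <- .Machine$double.eps
    for (j in nn) S[i, j] <- W[i, j] / s
  }
  S
}

oracle_snf <- function(Ws, K, t) {
  m <- length(Ws)
  n <- nrow(Ws[[1]])
  P <- lapply(Ws, oracle_normalize)
  S <- lapply(Ws, oracle_sparse, K = K)
  for (step in 1:t) {
    Pnew <- vector("list", m)
    for (v in 1:m) {
      if (m == 1) {
        avg <- P[[1]]
      } else {
        avg <- matrix(0, n, n)
        for (u in seq_len(m)[-v]) avg <- avg + P[[u]]
        avg <- avg / (m - 1)
      }
      ## Q = S %*% avg %*% t(S), spelled out
      Q <- matrix(0, n, n)
      for (i in 1:n) for (j in 1:n) {
        acc <- 0
        for (a in 1:n) for (b in 1:n)
          acc <- acc + S[[v]][i, a] * avg[a, b] * S[[v]][j, b]
        Q[i, j] <- acc
      }
      Q <- oracle_normalize(Q)
      Pnew[[v]] <- (Q + t(Q)) / 2
    }
    P <- Pnew
  }
  out <- matrix(0, n, n)
  for (v in 1:m) out <- out + P[[v]]
  out <- out / m
  (out + t(out)) / 2
}

## random symmetric distance matrix on n points, zero diagonal
random_distance <- function(n, seed) {
  set.seed(seed)
  D <- matrix(stats::runif(n * n), n, n)
  D <- (D + t(D)) / 2
  diag(D) <- 0
  dimnames(D) <- list(sprintf("d%02d", 1:n), sprintf("d%02d", 1:n))
  D
}
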