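# internal numerical helpers shared across modules

.set_seed <- function(seed) {
  if (!is.null(seed)) {
    stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
    set.seed(as.integer(seed))
  }
  invisible(NULL)
}

# one Dirichlet draw; alpha > 0
.rdirichlet <- function(alpha) {
  stopifnot(all(alpha > 0))
  g <- rgamma(length(alpha), shape = alpha, rate = 1)
  s <- sum(g)
  if (s == 0) {
    # tiny concentrations can underflow every gamma draw; fall back to a
    # point mass on a category drawn from the mean
    g[sample.int(length(alpha), 1L, prob = alpha)] <- 1
    s <- 1
  }
  g / s
}

# n draws from N(0, Sigma), rows = draws; Cholesky-based
.rmvnorm <- function(n, Sigma) {
  p <- nrow(Sigma)
  L <- chol(Sigma)
  matrix(rnorm(n * p), n, p) %*% L
}

# all permutations of 1..n as a matrix (n! rows); used for exhaustive tests
.all_perms <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- .all_perms(n - 1L)
  out <- vector("list", n)
  for (k in seq_len(n)) {
    rest <- seq_len(n)[-k]
    out[[k]] <- cbind(k, matrix(rest[sub], nrow(sub), n - 1L))
  }
  do.call(rbind, out)
}

# symmetric-matrix trace of H %*% G for symmetric H, G
.tr2 <- function(H, G) sum(H * G)

# hat matrix from a model matrix via QR (rank-revealing)
.hat_matrix <- function(X) {
  qx <- qr(X)
  Q <- qr.Q(qx)[, seq_len(qx$rank), drop = FALSE]
  list(H = tcrossprod(Q), rank = qx$rank)
}

.upper_pairs <- function(n) {
  # row/col indices of the upper triangle (i < j), column-major like dist()
  i <- rep(seq_len(n - 1L), times = (n - 1L):1L)
  j <- unlist(lapply(seq_len(n - 1L), function(a) (a + 1L):n))
  cbind(i = i, j = j)
}
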