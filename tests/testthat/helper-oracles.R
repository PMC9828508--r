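# Independent dense-matrix oracles: literal transcriptions of the model
# formulas using solve()/determinant(), never the package's factorized paths.

oracle_kernel <- function(x, xs, theta, cyclic) {
  s <- 0
  for (d in seq_along(x)) {
    r <- x[d] - xs[d]
    if (cyclic[d]) r <- ((r + pi) %% (2 * pi)) - pi
    s <- s + theta[d] * r^2
  }
  exp(-s)
}

oracle_R <- function(X, theta, cyclic, nugget) {
  n <- nrow(X)
  R <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n))
    R[i, j] <- oracle_kernel(X[i, ], X[j, ], theta, cyclic)
  R + diag(nugget, n)
}

oracle_ll <- function(X, y, theta, cyclic, nugget) {
  R <- oracle_R(X, theta, cyclic, nugget)
  n <- length(y)
  mu <- mean(y)
  res <- y - mu
  -0.5 * drop(t(res) %*% solve(R, res)) -
    0.5 * as.numeric(determinant(R, logarithm = TRUE)$modulus) -
    0.5 * n * log(2 * pi)
}

oracle_predict <- function(X, y, theta, cyclic, nugget, xs) {
  R <- oracle_R(X, theta, cyclic, nugget)
  Rinv <- solve(R)
  n <- length(y)
  mu <- mean(y)
  sigma2 <- drop(t(y - mu) %*% Rinv %*% (y - mu)) / n
  r <- vapply(seq_len(n), function(i) oracle_kernel(xs, X[i, ], theta, cyclic),
              numeric(1L))
  ones <- rep(1, n)
  mean_hat <- mu + drop(t(r) %*% Rinv %*% (y - mu))
  var_hat <- sigma2 * (1 - drop(t(r) %*% Rinv %*% r) +
                         (1 - drop(t(ones) %*% Rinv %*% r))^2 /
                         drop(t(ones) %*% Rinv %*% ones))
  list(mean = mean_hat, variance = var_hat)
}

# Random GP regression instance on the theta box used throughout.
rand_instance <- function(n, d, cyclic_prob = 0.3) {
  X <- matrix(runif(n * d, 0, 3), n, d)
  attr(X, "cyclic") <- runif(d) < cyclic_prob
  list(X = X,
       y = rowSums(sin(X)) + 0.3 * rnorm(n),
       theta = runif(d, 0.1, 2))
}

# As rand_instance, but with a minimum pairwise separation enforced by greedy
# thinning, keeping the covariance matrix well conditioned so that two
# independent solution paths can be compared at tight tolerance.
rand_instance_sep <- function(n, d, sep = 0.4) {
  X <- matrix(runif(n * d * 20, 0, 3), ncol = d)
  keep <- 1L
  for (i in 2:nrow(X)) {
    dm <- min(sqrt(rowSums(
      (X[keep, , drop = FALSE] -
         matrix(X[i, ], length(keep), d, byrow = TRUE))^2)))
    if (dm > sep) keep <- c(keep, i)
    if (length(keep) >= n) break
  }
  Xk <- X[keep, , drop = FALSE]
  attr(Xk, "cyclic") <- runif(d) < 0.3
  list(X = Xk,
       y = rowSums(sin(Xk)) + 0.3 * rnorm(nrow(Xk)),
       theta = runif(d, 0.5, 2))
}

random_rotation <- function() {
  qr_ <- qr(matrix(rnorm(9), 3, 3))
  Q <- qr.Q(qr_)
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}

# Planar zigzag carbon chain with natoms atoms: a generic valid geometry of
# any size for feature-count checks.
chain_config <- function(natoms, bond = 1.54, ang = 112 * pi / 180) {
  delta <- (pi - ang) / 2
  xyz <- matrix(0, natoms, 3L)
  for (k in 2:natoms) {
    phi <- if (k %% 2L == 0L) delta else -delta
    xyz[k, ] <- xyz[k - 1L, ] + bond * c(cos(phi), sin(phi), 0)
  }
  mol_config(rep("C", natoms), xyz)
}
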