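test_that("kernel matches a literal scalar-loop evaluation", {
  mk <- function(v, cyc) structure(v, cyclic = cyc)
  cyc <- c(FALSE, FALSE, TRUE)
  x <- mk(c(0.3, 1.2, 2.9), cyc)
  expect_equal(kernel(x, x, c(1, 1, 1)), 1)
  expect_equal(kernel(x, mk(c(2, 0, -3), cyc), c(0, 0, 0)), 1)
  expect_error(kernel(x, x, c(-1, 0, 0)), "non-negative")
  set.seed(31)
  for (rep in 1:25) {
    a <- mk(runif(3, -3, 3), cyc)
    b <- mk(runif(3, -3, 3), cyc)
    th <- runif(3, 0, 2)
    expect_equal(kernel(a, b, th), oracle_kernel(a, b, th, cyc),
                 tolerance = 1e-12)
  }
})

test_that("covariance factorization solves like a dense inverse", {
  set.seed(37)
  X1 <- matrix(0.5, 1, 2)
  f1 <- covariance_matrix(X1, c(1, 1), nugget = 0)
  expect_equal(as.numeric(f1$U), 1)
  inst <- rand_instance(50, 3)
  fac <- covariance_matrix(inst$X, inst$theta)
  Rd <- oracle_R(inst$X, inst$theta, attr(inst$X, "cyclic"), fac$nugget)
  b <- rnorm(50)
  expect_equal(backsolve(fac$U, forwardsolve(t(fac$U), b)),
               solve(Rd, b), tolerance = 1e-8)
  expect_equal(fac$logdet,
               as.numeric(determinant(Rd, logarithm = TRUE)$modulus),
               tolerance = 1e-8)
})

test_that("duplicated training points need the nugget", {
  X <- rbind(c(1, 2), c(1, 2), c(0, 0))
  attr(X, "cyclic") <- c(FALSE, FALSE)
  Rd <- oracle_R(X, c(1, 1), c(FALSE, FALSE), 0)
  expect_error(chol(Rd))                       # singular without jitter
  fac <- covariance_matrix(X, c(1, 1))         # escalates as needed
  expect_true(fac$nugget >= 1e-10)
  expect_silent(backsolve(fac$U, forwardsolve(t(fac$U), rnorm(3))))
})

test_that("marginal log-likelihood matches the dense formula", {
  # n = 1: quadratic term vanishes (mu = y), leaving the constant
  X1 <- matrix(0, 1, 1)
  ll1 <- log_marginal_likelihood(X1, 5, 1, nugget = 1e-12)
  expect_equal(ll1, -0.5 * log(2 * pi), tolerance = 1e-6)
  # constant outputs: quadratic term exactly zero for any n
  set.seed(41)
  inst <- rand_instance(8, 2)
  llc <- log_marginal_likelihood(inst$X, rep(3.3, 8), inst$theta)
  fac <- covariance_matrix(inst$X, inst$theta)
  expect_equal(llc, -0.5 * fac$logdet - 4 * log(2 * pi), tolerance = 1e-10)
  # random instances against the dense oracle
  for (rep in 1:10) {
    inst <- rand_instance(8, 3)
    got <- log_marginal_likelihood(inst$X, inst$y, inst$theta)
    fac <- covariance_matrix(inst$X, inst$theta)
    want <- oracle_ll(inst$X, inst$y, inst$theta, attr(inst$X, "cyclic"),
                      fac$nugget)
    expect_equal(got, want, tolerance = 1e-8)
  }
})

test_that("likelihood shifts are absorbed by the constant mean", {
  set.seed(43)
  inst <- rand_instance(10, 2)
  ll0 <- log_marginal_likelihood(inst$X, inst$y, inst$theta)
  ll1 <- log_marginal_likelihood(inst$X, inst$y + 77.7, inst$theta)
  expect_equal(ll0, ll1, tolerance = 1e-9)
})

test_that("fitting produces consistent weights and degenerate cases", {
  X1 <- matrix(0.2, 1, 1)
  m1 <- gpr(X1, 4.2, 1)
  expect_equal(m1$weights, 0)
  expect_equal(m1$mu, 4.2)
  set.seed(47)
  inst <- rand_instance(12, 2)
  mc <- gpr(inst$X, rep(2.5, 12), inst$theta)
  expect_equal(mc$weights, rep(0, 12), tolerance = 1e-12)
  m <- gpr(inst$X, inst$y, inst$theta)
  Rd <- oracle_R(inst$X, inst$theta, attr(inst$X, "cyclic"), m$nugget)
  expect_lt(max(abs(Rd %*% m$weights - (inst$y - m$mu))), 1e-8)
})

test_that("prediction interpolates the training data with zero variance", {
  set.seed(53)
  for (rep in 1:5) {
    inst <- rand_instance(15, 3)
    m <- gpr(inst$X, inst$y, inst$theta)
    p <- predict(m, inst$X)
    scale <- max(abs(inst$y - m$mu))
    expect_lt(max(abs(p$mean - inst$y)), 1e-5 * scale)
    expect_true(all(p$variance >= 0))
    expect_lt(max(p$variance), 1e-5 * m$sigma2 + 1e-10)
  }
  # n = 1 degenerate interpolation
  m1 <- gpr(matrix(1, 1, 1), 9.9, 0.5)
  expect_equal(predict(m1, matrix(1, 1, 1))$mean, 9.9)
})

test_that("predictive mean and variance match the dense-matrix oracle", {
  set.seed(59)
  for (rep in 1:10) {
    inst <- rand_instance_sep(sample(5:50, 1), sample(3:4, 1))
    m <- gpr(inst$X, inst$y, inst$theta)
    xs <- runif(ncol(inst$X), 0, 3)
    got <- predict(m, matrix(xs, 1))
    want <- oracle_predict(inst$X, inst$y, inst$theta,
                           attr(inst$X, "cyclic"), m$nugget, xs)
    expect_equal(got$mean, want$mean, tolerance = 1e-8)
    expect_equal(got$variance, max(want$variance, 0), tolerance = 1e-8)
  }
})

test_that("variance far from the data approaches the ordinary kriging limit", {
  set.seed(61)
  X <- matrix(runif(20, 0, 3), 10, 2)
  attr(X, "cyclic") <- c(FALSE, FALSE)
  y <- rnorm(10)
  theta <- c(500, 500)               # near-diagonal R
  m <- gpr(X, y, theta)
  far <- matrix(c(1e3, 1e3), 1)
  v <- predict(m, far)$variance
  limit <- m$sigma2 * (1 + 1 / m$one_rinv_one)
  expect_equal(v, limit, tolerance = 1e-6)
  expect_equal(limit, m$sigma2 * (1 + 1 / 10), tolerance = 1e-3)
})

test_that("model JSON round-trips to bit-comparable predictions", {
  set.seed(67)
  inst <- rand_instance(10, 3)
  m <- gpr(inst$X, inst$y, inst$theta)
  path <- withr::local_tempfile(fileext = ".json")
  write_gpr_json(m, path, atom_label = "O1", alf_triple = c(1, 2, 3))
  back <- read_gpr_json(path)
  xs <- matrix(runif(9, 0, 3), 3)
  expect_identical(predict(back, xs)$mean, predict(m, xs)$mean)
  expect_equal(predict(back, xs)$variance, predict(m, xs)$variance,
               tolerance = 1e-12)
})

test_that("query dimension mismatches are contract errors", {
  m <- gpr(matrix(runif(10), 5, 2), rnorm(5), c(1, 1))
  expect_error(predict(m, matrix(1, 1, 3)), "dimension")
})
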