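#' @title Gaussian process regression with a cyclic RBF kernel
#' @description Ordinary kriging with a constant mean mu = mean(y) and the
#'   squared-exponential kernel k(x, x*) = exp(-sum_d theta_d r_d^2), where
#'   r_d is the plain difference on linear feature dimensions and the wrapped
#'   difference on cyclic (angular) dimensions. Predictions carry the ordinary
#'   kriging variance, which accounts for the estimated constant mean.
#' @name gpr-core
NULL

#' Cyclic RBF kernel between two feature vectors
#'
#' @param x,x_star feature vectors with matching `cyclic` attributes.
#' @param theta non-negative length-scale parameters, one per dimension.
#' @return Covariance in (0, 1].
#' @export
kernel <- function(x, x_star, theta) {
  if (any(theta < 0)) stop("theta must be non-negative", call. = FALSE)
  d <- feature_difference(x, x_star)
  exp(-sum(theta * d^2))
}

# Pairwise scaled squared distance matrix sum_d theta_d r_d^2 between the rows
# of X (n x d) and Y (m x d).
scaled_sqdist <- function(X, Y, theta, cyclic) {
  n <- nrow(X); m <- nrow(Y)
  D <- matrix(0, n, m)
  for (d in seq_len(ncol(X))) {
    if (theta[d] == 0) next
    dif <- outer(X[, d], Y[, d], `-`)
    if (cyclic[d]) dif <- wrap_angle(dif)
    D <- D + theta[d] * dif^2
  }
  D
}

kernel_matrix <- function(X, Y, theta, cyclic) exp(-scaled_sqdist(X, Y, theta, cyclic))

# Cholesky factorization of R + nugget*I with x10 nugget escalation up to a
# ceiling; the paper's GP is noise-free, so the nugget is numerical only.
cov_factor <- function(R, nugget = 1e-10, nugget_max = 1e-4) {
  n <- nrow(R)
  ng <- nugget
  repeat {
    U <- tryCatch(chol(R + diag(ng, n)), error = function(e) NULL)
    if (!is.null(U)) return(list(U = U, nugget = ng,
                                 logdet = 2 * sum(log(diag(U)))))
    if (ng >= nugget_max)
      stop("ill-conditioned covariance matrix: factorization failed at nugget ",
           ng, call. = FALSE)
    ng <- ng * 10
  }
}

chol_solve <- function(U, b) backsolve(U, forwardsolve(t(U), b))

#' Covariance matrix factorization for a training set
#'
#' Builds R_ij = k(x_i, x_j) (unit diagonal before the nugget) and returns a
#' Cholesky factorization of R + nugget*I supporting solves and the
#' log-determinant. On factorization failure the nugget escalates tenfold up
#' to 1e-4 before an ill-conditioned-model error is raised.
#'
#' @param X ntrain x ndim feature matrix (with a `cyclic` attribute).
#' @param theta non-negative hyperparameter vector.
#' @param nugget initial diagonal jitter.
#' @param cyclic logical cyclic mask (defaults to `attr(X, "cyclic")`).
#' @return List with the upper Cholesky factor `U`, the `nugget` actually
#'   used, and `logdet` of R + nugget*I.
#' @export
covariance_matrix <- function(X, theta, nugget = 1e-10,
                              cyclic = attr(X, "cyclic")) {
  X <- as_feature_matrix(X, cyclic)
  if (any(theta < 0)) stop("theta must be non-negative", call. = FALSE)
  R <- kernel_matrix(X, X, theta, attr(X, "cyclic"))
  cov_factor(R, nugget)
}

as_feature_matrix <- function(X, cyclic = NULL) {
  if (!is.matrix(X)) X <- matrix(X, nrow = 1L)
  if (is.null(cyclic)) cyclic <- attr(X, "cyclic")
  if (is.null(cyclic)) cyclic <- rep(FALSE, ncol(X))
  stopifnot(length(cyclic) == ncol(X))
  structure(X, cyclic = as.logical(cyclic))
}

#' Marginal log-likelihood of a constant-mean GP
#'
#' `LL = -1/2 (y-mu)' R^-1 (y-mu) - 1/2 log|R| - n/2 log(2*pi)` with
#' `mu = mean(y)`.
#'
#' @inheritParams covariance_matrix
#' @param y training outputs.
#' @return Scalar log-likelihood.
#' @export
log_marginal_likelihood <- function(X, y, theta, nugget = 1e-10,
                                    cyclic = attr(X, "cyclic")) {
  X <- as_feature_matrix(X, cyclic)
  n <- nrow(X)
  stopifnot(length(y) == n)
  fac <- covariance_matrix(X, theta, nugget)
  resid <- y - mean(y)
  alpha <- chol_solve(fac$U, resid)
  -0.5 * sum(resid * alpha) - 0.5 * fac$logdet - 0.5 * n * log(2 * pi)
}

#' Fit a Gaussian process regression (kriging) model
#'
#' Stores the constant mean `mu = mean(y)`, the Cholesky factorization of
#' R + nugget*I, the GPR weights `alpha = R^-1 (y - mu)`, and the plug-in
#' process variance `sigma2 = (y-mu)' R^-1 (y-mu) / n` used by the ordinary
#' kriging predictive variance.
#'
#' @param X ntrain x ndim feature matrix; a `cyclic` attribute (logical mask)
#'   marks angular dimensions, as produced by [featurize_trajectory].
#' @param y numeric training outputs (kJ/mol).
#' @param theta non-negative hyperparameter vector, one per feature dimension.
#' @param nugget initial diagonal jitter (escalated on factorization failure).
#' @param cyclic optional explicit cyclic mask.
#' @return An object of class `gpr`.
#' @seealso [predict.gpr], [pso_optimize], [gpr_loo_cv]
#' @export
gpr <- function(X, y, theta, nugget = 1e-10, cyclic = attr(X, "cyclic")) {
  X <- as_feature_matrix(X, cyclic)
  n <- nrow(X)
  y <- as.numeric(y)
  stopifnot(length(y) == n, length(theta) == ncol(X))
  fac <- covariance_matrix(X, theta, nugget)
  mu <- mean(y)
  resid <- y - mu
  weights <- chol_solve(fac$U, resid)
  sigma2 <- sum(resid * weights) / n
  rinv_one <- chol_solve(fac$U, rep(1, n))
  structure(
    list(X = X, y = y, mu = mu, theta = as.numeric(theta),
         cyclic = attr(X, "cyclic"), nugget = fac$nugget,
         U = fac$U, logdet = fac$logdet, weights = as.numeric(weights),
         sigma2 = max(sigma2, 0), rinv_one = as.numeric(rinv_one),
         one_rinv_one = sum(rinv_one)),
    class = "gpr")
}

#' Predict mean and ordinary kriging variance at new points
#'
#' Mean: `mu + r' alpha` (linear in ntrain; the stored factorization is
#' reused, never recomputed). Variance:
#' `sigma2 * (1 - r' R^-1 r + (1 - 1' R^-1 r)^2 / (1' R^-1 1))`, clamped at 0
#' against floating-point round-off.
#'
#' @param object a fitted `gpr` model.
#' @param newdata feature vector or m x ndim matrix of query points.
#' @param ... unused.
#' @return data.frame with columns `mean` and `variance` (one row per query).
#' @export
predict.gpr <- function(object, newdata, ...) {
  nd <- if (is.matrix(newdata)) ncol(newdata) else length(newdata)
  if (nd != ncol(object$X))
    stop("query dimension does not match the model", call. = FALSE)
  Xs <- as_feature_matrix(newdata, object$cyclic)
  K <- kernel_matrix(object$X, Xs, object$theta, object$cyclic)  # n x m
  mean_hat <- object$mu + drop(crossprod(K, object$weights))
  rinv_r <- chol_solve(object$U, K)
  quad <- colSums(K * rinv_r)
  u <- drop(crossprod(K, object$rinv_one))   # 1' R^-1 r
  var_hat <- object$sigma2 * (1 - quad + (1 - u)^2 / object$one_rinv_one)
  data.frame(mean = mean_hat, variance = pmax(var_hat, 0))
}

#' @export
print.gpr <- function(x, ...) {
  cat(sprintf("<gpr> %d training points, %d features (%d cyclic)\n",
              nrow(x$X), ncol(x$X), sum(x$cyclic)))
  cat(sprintf("  mu = %.6g kJ/mol, sigma2 = %.6g, nugget = %.1e\n",
              x$mu, x$sigma2, x$nugget))
  cat("  theta:", format(signif(x$theta, 4)), "\n")
  invisible(x)
}

#' @export
summary.gpr <- function(object, ...) {
  res <- stats::residuals(object)
  out <- list(ntrain = nrow(object$X), ndim = ncol(object$X),
              mu = object$mu, sigma2 = object$sigma2,
              nugget = object$nugget, theta = object$theta,
              log_marginal_likelihood =
                -0.5 * sum((object$y - object$mu) * object$weights) -
                0.5 * object$logdet - 0.5 * nrow(object$X) * log(2 * pi),
              max_abs_train_residual = max(abs(res)))
  class(out) <- "summary.gpr"
  out
}

#' @export
print.summary.gpr <- function(x, ...) {
  cat(sprintf("Gaussian process regression: %d points, %d features\n",
              x$ntrain, x$ndim))
  cat(sprintf("  constant mean       %.6g kJ/mol\n", x$mu))
  cat(sprintf("  process variance    %.6g\n", x$sigma2))
  cat(sprintf("  nugget              %.1e\n", x$nugget))
  cat(sprintf("  log marg. likelihood %.4f\n", x$log_marginal_likelihood))
  cat(sprintf("  max |train residual| %.3e kJ/mol\n", x$max_abs_train_residual))
  cat("  theta:", format(signif(x$theta, 4)), "\n")
  invisible(x)
}

#' @export
coef.gpr <- function(object, ...) {
  c(mu = object$mu, stats::setNames(object$theta,
                                    paste0("theta", seq_along(object$theta))))
}

#' @export
fitted.gpr <- function(object, ...) predict(object, object$X)$mean

#' @export
residuals.gpr <- function(object, ...) object$y - stats::fitted(object)

#' Save a fitted per-atom model to JSON
#'
#' The document holds everything needed to reload and predict bit-comparably:
#' atom label, ALF triple, cyclic mask, theta, nugget, mu, sigma2, training
#' features (row-major), outputs, and weights.
#'
#' @param model a `gpr` object.
#' @param path output JSON path.
#' @param atom_label optional atom label (e.g. "O1").
#' @param alf_triple optional integer ALF triple for the atom.
#' @return Invisibly, `path`.
#' @export
write_gpr_json <- function(model, path, atom_label = NULL, alf_triple = NULL) {
  obj <- list(atom_label = atom_label,
              alf = if (!is.null(alf_triple)) as.integer(alf_triple),
              ndim = ncol(model$X), ntrain = nrow(model$X),
              cyclic = as.logical(model$cyclic),
              theta = model$theta, nugget = model$nugget,
              mu = model$mu, sigma2 = model$sigma2,
              X = as.numeric(t(model$X)),    # row-major
              y = model$y, weights = model$weights)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

#' Reload a per-atom model saved by [write_gpr_json]
#'
#' @param path JSON path.
#' @return A `gpr` object (stored weights preserved; the covariance
#'   factorization is rebuilt from the stored inputs).
#' @export
read_gpr_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  X <- matrix(obj$X, nrow = obj$ntrain, ncol = obj$ndim, byrow = TRUE)
  attr(X, "cyclic") <- as.logical(obj$cyclic)
  model <- gpr(X, obj$y, obj$theta, nugget = obj$nugget)
  model$weights <- as.numeric(obj$weights)
  model$mu <- obj$mu
  model$sigma2 <- obj$sigma2
  model
}
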