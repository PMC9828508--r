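#' @title MEPE active learning
#' @description Maximum expected prediction error (MEPE) acquisition: each
#'   sample point is scored by EPE = alpha * PE_CV^2 + (1 - alpha) * s^2,
#'   where PE_CV^2 is a leave-one-out cross-validation error propagated from
#'   the nearest training point (Voronoi assignment), s^2 is the ordinary
#'   kriging variance, and the balance factor alpha adapts each iteration
#'   from the realized prediction error of the previously added point(s).
#'   Acquisition runs per atom (independent training sets) or per system
#'   (shared training set, atom-summed errors), adding one or several points
#'   per iteration.
#' @name mepe-al
NULL

#' Initialize a training set from per-dimension extremes and means
#'
#' For every feature dimension the frames attaining the minimum and the
#' maximum, and the frame closest to the dimension mean, are selected; the
#' union (duplicates removed, first occurrence kept) forms the initial
#' training set, so its size is at most three times the number of dimensions.
#'
#' @param features nframes x ndim feature matrix.
#' @return Integer vector of frame indices (1-based).
#' @export
init_training_set <- function(features) {
  features <- as.matrix(features)
  if (!nrow(features)) stop("empty trajectory", call. = FALSE)
  idx <- integer(0)
  for (d in seq_len(ncol(features))) {
    v <- features[, d]
    idx <- c(idx, which.min(v), which.max(v), which.min(abs(v - mean(v))))
  }
  unique(idx)
}

#' Partition non-training frames into sample and validation sets
#'
#' Defaults mirror the study setup (10,000 sample points, 500 validation
#' points). When fewer frames remain, both sets shrink proportionally (with a
#' warning) and together take all remaining frames.
#'
#' @param trajectory_size total number of frames.
#' @param train_idx indices already in the training set.
#' @param sample_size,valid_size requested sizes.
#' @param seed integer seed (private RNG stream).
#' @return List with integer vectors `sample_idx` and `valid_idx`, disjoint
#'   from each other and from `train_idx`.
#' @export
partition_sets <- function(trajectory_size, train_idx, sample_size = 10000L,
                           valid_size = 500L, seed = 1L) {
  remaining <- setdiff(seq_len(trajectory_size), train_idx)
  m <- length(remaining)
  if (m < 2L) stop("cannot partition: fewer than 2 non-training frames",
                   call. = FALSE)
  if (m < sample_size + valid_size) {
    vs <- max(1L, round(m * valid_size / (sample_size + valid_size)))
    ss <- m - vs
    warning(sprintf(
      "only %d frames remain; shrinking sample/validation sets to %d/%d",
      m, ss, vs))
    sample_size <- ss; valid_size <- vs
  }
  with_local_seed(as.integer(seed), {
    samp <- sort(sample(remaining, sample_size))
    rest <- setdiff(remaining, samp)
    val <- sort(sample(rest, valid_size))
    list(sample_idx = samp, valid_idx = val)
  })
}

#' Exact leave-one-out CV error of one training point
#'
#' Refits the GP without row `i` (same theta, same nugget) and returns the
#' squared prediction error at the held-out point. Slow but exact; serves as
#' the reference for the closed-form approximation [gpr_loo_cv].
#'
#' @param X,y,theta,nugget model inputs as for [gpr].
#' @param i index of the held-out training point.
#' @param cyclic optional cyclic mask.
#' @return Scalar squared CV error.
#' @export
gpr_loo_cv_exact <- function(X, y, theta, i, nugget = 1e-10,
                             cyclic = attr(X, "cyclic")) {
  X <- as_feature_matrix(X, cyclic)
  n <- nrow(X)
  if (n < 2L) stop("LOO-CV requires at least 2 training points", call. = FALSE)
  sub <- gpr(X[-i, , drop = FALSE], y[-i], theta, nugget = nugget,
             cyclic = attr(X, "cyclic"))
  (y[i] - predict(sub, X[i, , drop = FALSE])$mean)^2
}

#' Closed-form leave-one-out CV errors of all training points
#'
#' Fast closed form built from the inverse covariance matrix: with `F` the
#' all-ones column (constant basis), its hat matrix is `H = J/n`, so the
#' held-out error of point `i` is
#' `e_i = [R^-1 (d + H[,i] d_i / (1 - H_ii))]_i / (R^-1)_ii`, returned
#' squared.
#'
#' The residual `d` can be formed with either constant: the model's own mean
#' `mu = mean(y)` (default), or the generalized-least-squares constant
#' `beta = (1' R^-1 1)^-1 1' R^-1 y` of universal kriging. With
#' `residual = "constant"` the formula is algebraically identical to the
#' exact leave-one-out refit of the constant-mean GP: dropping point `i`
#' shifts the mean by `(y_i - mean(y)) / (n - 1)`, which is exactly the
#' `H[,i] d_i / (1 - H_ii)` correction — so agreement with
#' [gpr_loo_cv_exact] is limited only by floating-point conditioning. The
#' GLS variant is a close approximation whose deviation grows with the
#' correlation in R. Points whose `(R^-1)_ii` is non-positive numerically
#' fall back to the exact refit.
#'
#' @param model a fitted [gpr] model with at least 2 training points.
#' @param residual `"constant"` (model mean, exact) or `"gls"` (universal
#'   kriging constant).
#' @return Numeric vector of squared CV errors, one per training point.
#' @export
gpr_loo_cv <- function(model, residual = c("constant", "gls")) {
  residual <- match.arg(residual)
  n <- nrow(model$X)
  if (n < 2L) stop("LOO-CV requires at least 2 training points", call. = FALSE)
  Rinv <- chol2inv(model$U)
  rs <- rowSums(Rinv)                    # R^-1 1
  const <- if (residual == "gls") sum(Rinv %*% model$y) / sum(rs) else
    mean(model$y)
  d <- model$y - const
  rd <- drop(Rinv %*% d)
  dg <- diag(Rinv)
  e <- (rd + d / (n - 1) * rs) / dg      # H[,i] d_i / (1 - 1/n) = d_i/(n-1) * 1
  bad <- which(dg <= 0)
  for (i in bad)
    e[i] <- sqrt(gpr_loo_cv_exact(model$X, model$y, model$theta, i,
                                  nugget = model$nugget))
  e^2
}

#' Propagate training CV errors to sample points by Voronoi assignment
#'
#' Each sample point inherits the squared CV error of its nearest training
#' point, nearness measured by unweighted Euclidean distance in feature space
#' with the cyclic wrap applied on angular dimensions (ties: lowest training
#' index).
#'
#' @param sample_features m x ndim matrix of sample-point features.
#' @param train_features n x ndim matrix of training features.
#' @param train_cv2 length-n vector of squared CV errors.
#' @param cyclic optional cyclic mask.
#' @return Length-m vector of inherited squared CV errors.
#' @export
assign_voronoi <- function(sample_features, train_features, train_cv2,
                           cyclic = attr(train_features, "cyclic")) {
  S <- as_feature_matrix(sample_features, cyclic)
  Tr <- as_feature_matrix(train_features, cyclic)
  stopifnot(nrow(Tr) >= 1L, length(train_cv2) == nrow(Tr))
  D <- scaled_sqdist(S, Tr, rep(1, ncol(Tr)), attr(Tr, "cyclic"))
  train_cv2[max.col(-D, ties.method = "first")]
}

#' Exploration/exploitation balance factor
#'
#' `alpha = 0.5` on the first iteration; afterwards
#' `alpha = 0.99 * min(0.5 * PE_true^2 / PE_CV^2, 1)`, comparing the realized
#' squared prediction error of the point added on the previous iteration with
#' its CV estimate at selection time, so alpha always lies in \[0, 0.99\].
#' A zero CV estimate with q > 1 yields the cap 0.99 (ratio treated as
#' infinite).
#'
#' @param pe_true2_prev realized squared prediction error of the previous
#'   point.
#' @param pe_cv2_prev its squared CV error estimate at selection time.
#' @param q iteration counter (>= 1).
#' @return Scalar alpha in \[0, 0.99\].
#' @export
balance_factor <- function(pe_true2_prev, pe_cv2_prev, q) {
  stopifnot(q >= 1L)
  if (q == 1L) return(0.5)
  if (pe_true2_prev < 0 || pe_cv2_prev < 0)
    stop("squared errors must be non-negative", call. = FALSE)
  if (pe_cv2_prev == 0) return(0.99)
  0.99 * min(0.5 * pe_true2_prev / pe_cv2_prev, 1)
}

#' Batch balance factor for multi-point iterations
#'
#' The arithmetic mean of the per-point balance factors of the previous
#' batch, used directly in the EPE of the next iteration.
#'
#' @param alphas per-point balance factors (length >= 1).
#' @return Scalar mean alpha.
#' @export
batch_balance_factor <- function(alphas) {
  if (!length(alphas)) stop("empty balance-factor vector", call. = FALSE)
  mean(alphas)
}

#' Expected prediction error
#'
#' `EPE = alpha * PE_CV^2 + (1 - alpha) * s^2` (vectorized).
#'
#' @param cv2 squared CV errors (>= 0).
#' @param s2 kriging variances (>= 0).
#' @param alpha balance factor in \[0, 0.99\].
#' @return EPE values.
#' @export
expected_prediction_error <- function(cv2, s2, alpha) {
  alpha * cv2 + (1 - alpha) * s2
}

#' Sum per-atom acquisition quantities into per-system ones
#'
#' Per-system acquisition sums CV errors, variances, and realized prediction
#' errors over the atoms of the system; the per-system balance factor then
#' mirrors the per-atom formula with the summed inputs.
#'
#' @param per_atom_cv2,per_atom_s2 numeric vectors (one value per atom for a
#'   single sample point) or matrices (sample points in rows, atoms in
#'   columns).
#' @param per_atom_pe_true2 optional, same shape.
#' @return List with `cv2_sys`, `s2_sys`, and (when supplied) `pe_true2_sys`.
#' @export
aggregate_per_system <- function(per_atom_cv2, per_atom_s2,
                                 per_atom_pe_true2 = NULL) {
  sum_atoms <- function(x) if (is.matrix(x)) rowSums(x) else sum(x)
  if (is.matrix(per_atom_cv2)) {
    if (!identical(dim(per_atom_cv2), dim(per_atom_s2)))
      stop("per-atom matrices differ in shape", call. = FALSE)
  } else if (length(per_atom_cv2) != length(per_atom_s2)) {
    stop("per-atom vectors differ in length", call. = FALSE)
  }
  out <- list(cv2_sys = sum_atoms(per_atom_cv2),
              s2_sys = sum_atoms(per_atom_s2))
  if (!is.null(per_atom_pe_true2))
    out$pe_true2_sys <- sum_atoms(per_atom_pe_true2)
  out
}

#' Select the points with the largest EPE
#'
#' Ties are broken by the lower sample index. An empty EPE vector returns an
#' empty selection (the loop's stop signal).
#'
#' @param epe per-sample-point EPE values.
#' @param batch_size number of points to select (capped at the sample size).
#' @return Integer positions into `epe` of the selected points.
#' @export
select_points <- function(epe, batch_size = 1L) {
  if (!length(epe)) return(integer(0))
  stopifnot(batch_size >= 1L)
  k <- min(batch_size, length(epe))
  order(-epe, seq_along(epe))[seq_len(k)]
}

#' Active-learning settings
#'
#' @param mode `"per_atom"` (independent training sets, acquisition per
#'   atomic model) or `"per_system"` (one shared training set, acquisition on
#'   atom-summed errors).
#' @param batch_size points added per iteration.
#' @param sample_size,valid_size requested sample/validation pool sizes
#'   (shrunk proportionally when the trajectory is smaller).
#' @param max_train stop once the training set reaches this size.
#' @param target_rmse optional validation-RMSE stopping target (kJ/mol).
#' @param seed integer seed driving every stochastic choice of the run.
#' @param refit_every refit hyperparameters by PSO every k-th iteration
#'   (weights are always refit when the training set grows).
#' @param acquisition `"mepe"` or `"random"` (uniform baseline at equal
#'   budget).
#' @param pso a [pso_control] for the hyperparameter refits.
#' @return A list of class `al_control`.
#' @export
al_control <- function(mode = c("per_atom", "per_system"), batch_size = 1L,
                       sample_size = 10000L, valid_size = 500L,
                       max_train = 500L, target_rmse = NULL, seed = 1L,
                       refit_every = 1L,
                       acquisition = c("mepe", "random"),
                       pso = pso_control(n_particles = 16L, max_iter = 60L)) {
  structure(list(mode = match.arg(mode), batch_size = as.integer(batch_size),
                 sample_size = as.integer(sample_size),
                 valid_size = as.integer(valid_size),
                 max_train = as.integer(max_train),
                 target_rmse = target_rmse, seed = as.integer(seed),
                 refit_every = as.integer(refit_every),
                 acquisition = match.arg(acquisition), pso = pso),
            class = "al_control")
}

# Derived sub-seed kept below 2^31.
sub_seed <- function(seed, a, q = 0L) {
  as.integer((as.numeric(seed) * 97L + a * 7919 + q * 131) %% 2147483647)
}

#' Run MEPE active learning on a labelled trajectory
#'
#' Per atom (or jointly per system): hyperparameters are trained by particle
#' swarm optimization of the marginal log-likelihood on the current training
#' set; every sample point is scored by EPE (CV error propagated by Voronoi
#' assignment, plus kriging variance); the top `batch_size` points are added
#' to the training set with oracle-computed atomic energies; the balance
#' factor is updated from the realized errors of the previous batch. The loop
#' stops at `max_train` training points, an exhausted sample set, or the
#' `target_rmse`. All randomness derives from `control$seed`, so runs are
#' reproducible and atoms' runs are independent of execution order.
#'
#' @param traj a [trajectory].
#' @param pes a [toy_pes] supplying true per-atom energies on demand (the
#'   oracle; only energies of selected frames/atoms are evaluated).
#' @param control an [al_control].
#' @param atoms atom indices to model (default: all).
#' @return Object of class `mepe_al`: per-atom `models` (fitted [gpr]),
#'   `history` data.frame (atom, iteration, ntrain, alpha, val_rmse, val_max,
#'   selected), per-atom index `sets`, the shared `alf`, and bookkeeping.
#' @export
active_learn <- function(traj, pes, control = al_control(), atoms = NULL) {
  nat <- length(traj$configurations[[1L]]$elements)
  if (is.null(atoms)) atoms <- seq_len(nat)
  nframes <- length(traj$configurations)
  alf <- compute_alf(traj$configurations[[1L]])
  feats <- lapply(seq_len(nat), function(a)
    if (a %in% atoms) featurize_trajectory(traj, alf, a) else NULL)

  # per-atom oracle with caching; failures mark the frame unusable
  truth_cache <- matrix(NA_real_, nframes, nat)
  truth_ok <- rep(TRUE, nframes)
  truth <- function(frame, atom) {
    if (is.na(truth_cache[frame, atom])) {
      en <- tryCatch(atomic_energies(traj$configurations[[frame]], pes),
                     error = function(e) NULL)
      if (is.null(en)) { truth_ok[frame] <<- FALSE; return(NA_real_) }
      truth_cache[frame, ] <<- en$atomic
    }
    truth_cache[frame, atom]
  }

  if (control$mode == "per_system") {
    return(al_run_per_system(traj, atoms, feats, truth, alf, control))
  }

  history <- NULL
  models <- vector("list", nat)
  sets <- vector("list", nat)
  for (a in atoms) {
    res <- al_run_single_atom(a, feats[[a]], truth, control)
    models[[a]] <- res$model
    sets[[a]] <- res$sets
    res$history$atom <- a
    history <- rbind(history, res$history)
  }
  structure(list(models = models, history = history, sets = sets, alf = alf,
                 atoms = atoms, elements = traj$configurations[[1L]]$elements,
                 control = control),
            class = "mepe_al")
}

# One independent per-atom MEPE run. `truth(frame, a)` is the oracle.
al_run_single_atom <- function(a, F, truth, control) {
  train <- init_training_set(F)
  part <- partition_sets(nrow(F), train, control$sample_size,
                         control$valid_size, seed = sub_seed(control$seed, a))
  samp <- part$sample_idx
  valid <- part$valid_idx
  y_train <- vapply(train, truth, numeric(1L), atom = a)
  y_valid <- vapply(valid, truth, numeric(1L), atom = a)
  ok <- !is.na(y_valid); valid <- valid[ok]; y_valid <- y_valid[ok]

  theta <- NULL
  q <- 0L
  last <- NULL   # list(frames, pe_cv2, pred) of the previous batch
  history <- NULL
  model <- NULL
  repeat {
    q <- q + 1L
    if (is.null(theta) || (q - 1L) %% control$refit_every == 0L) {
      psoc <- control$pso
      psoc$seed <- sub_seed(control$seed, a, q)
      obj <- function(th) log_marginal_likelihood(
        F[train, , drop = FALSE], y_train, th, cyclic = attr(F, "cyclic"))
      theta <- pso_optimize(obj, ncol(F), psoc)$theta
    }
    model <- gpr(F[train, , drop = FALSE], y_train, theta,
                 cyclic = attr(F, "cyclic"))
    pv <- predict(model, F[valid, , drop = FALSE])
    val_err <- y_valid - pv$mean
    val_rmse <- sqrt(mean(val_err^2))
    val_max <- max(abs(val_err))

    # balance factor from the previous batch's realized errors
    if (q == 1L || is.null(last)) {
      alpha <- 0.5
    } else {
      tr <- vapply(last$frames, truth, numeric(1L), atom = a)
      pe_true2 <- (tr - last$pred)^2
      alphas <- vapply(seq_along(pe_true2), function(k)
        balance_factor(pe_true2[k], last$pe_cv2[k], q), numeric(1L))
      alpha <- batch_balance_factor(alphas)
    }

    stop_now <- length(train) >= control$max_train || !length(samp) ||
      (!is.null(control$target_rmse) && val_rmse <= control$target_rmse)

    sel <- integer(0)
    if (!stop_now) {
      if (control$acquisition == "random") {
        sel <- with_local_seed(sub_seed(control$seed, a, q + 500000L),
                               sample(length(samp),
                                      min(control$batch_size, length(samp))))
        sel <- sort(sel)
        alpha <- NA_real_
      } else {
        cv2_train <- gpr_loo_cv(model)
        cv2_samp <- assign_voronoi(F[samp, , drop = FALSE],
                                   F[train, , drop = FALSE], cv2_train)
        s2_samp <- predict(model, F[samp, , drop = FALSE])$variance
        epe <- expected_prediction_error(cv2_samp, s2_samp, alpha)
        sel <- select_points(epe, control$batch_size)
      }
    }

    history <- rbind(history, data.frame(
      iteration = q, ntrain = length(train), alpha = alpha,
      val_rmse = val_rmse, val_max = val_max,
      selected = paste(samp[sel], collapse = ";")))

    if (stop_now || !length(sel)) break

    new_frames <- samp[sel]
    new_pred <- predict(model, F[new_frames, , drop = FALSE])$mean
    new_cv2 <- if (control$acquisition == "random") rep(NA_real_, length(sel))
               else cv2_samp[sel]
    new_y <- vapply(new_frames, truth, numeric(1L), atom = a)
    drop_bad <- is.na(new_y)
    if (any(drop_bad)) {
      samp <- setdiff(samp, new_frames[drop_bad])
      new_frames <- new_frames[!drop_bad]
      new_pred <- new_pred[!drop_bad]
      new_cv2 <- new_cv2[!drop_bad]
      new_y <- new_y[!drop_bad]
      if (!length(new_frames)) next
    }
    last <- if (control$acquisition == "random") NULL else
      list(frames = new_frames, pe_cv2 = new_cv2, pred = new_pred)
    train <- c(train, new_frames)
    y_train <- c(y_train, new_y)
    samp <- setdiff(samp, new_frames)
  }
  list(model = model, history = history,
       sets = list(train_idx = train, sample_idx = samp, valid_idx = valid))
}

# Per-system run: one shared training set, acquisition on atom-summed errors.
al_run_per_system <- function(traj, atoms, feats, truth, alf, control) {
  F1 <- feats[[atoms[1L]]]
  a1 <- atoms[1L]   # seed anchor: reduces to the per-atom stream for 1 atom
  train <- sort(unique(unlist(lapply(atoms, function(a)
    init_training_set(feats[[a]])))))
  part <- partition_sets(nrow(F1), train, control$sample_size,
                         control$valid_size, seed = sub_seed(control$seed, a1))
  samp <- part$sample_idx
  valid <- part$valid_idx
  y_train <- lapply(atoms, function(a) vapply(train, truth, numeric(1L), a))
  y_valid <- lapply(atoms, function(a) vapply(valid, truth, numeric(1L), a))
  names(y_train) <- names(y_valid) <- atoms

  theta <- vector("list", length(atoms))
  models <- vector("list", length(atoms))
  q <- 0L
  last <- NULL
  history <- NULL
  repeat {
    q <- q + 1L
    for (k in seq_along(atoms)) {
      a <- atoms[k]
      if (is.null(theta[[k]]) || (q - 1L) %% control$refit_every == 0L) {
        psoc <- control$pso
        psoc$seed <- sub_seed(control$seed, a, q)
        Fk <- feats[[a]]
        yk <- y_train[[k]]
        obj <- function(th) log_marginal_likelihood(
          Fk[train, , drop = FALSE], yk, th, cyclic = attr(Fk, "cyclic"))
        theta[[k]] <- pso_optimize(obj, ncol(Fk), psoc)$theta
      }
      models[[k]] <- gpr(feats[[a]][train, , drop = FALSE], y_train[[k]],
                         theta[[k]], cyclic = attr(feats[[a]], "cyclic"))
    }
    val_err <- vapply(seq_along(atoms), function(k)
      y_valid[[k]] - predict(models[[k]],
                             feats[[atoms[k]]][valid, , drop = FALSE])$mean,
      numeric(length(valid)))
    val_err <- matrix(val_err, nrow = length(valid))
    val_rmse <- sqrt(mean(val_err^2))
    val_max <- max(abs(val_err))

    if (q == 1L || is.null(last)) {
      alpha <- 0.5
    } else {
      pe_true2 <- vapply(seq_along(atoms), function(k) {
        tr <- vapply(last$frames, truth, numeric(1L), atom = atoms[k])
        (tr - last$pred[, k])^2
      }, numeric(length(last$frames)))
      pe_true2_sys <- rowSums(matrix(pe_true2, nrow = length(last$frames)))
      alphas <- vapply(seq_along(last$frames), function(p)
        balance_factor(pe_true2_sys[p], last$pe_cv2_sys[p], q), numeric(1L))
      alpha <- batch_balance_factor(alphas)
    }

    stop_now <- length(train) >= control$max_train || !length(samp) ||
      (!is.null(control$target_rmse) && val_rmse <= control$target_rmse)

    sel <- integer(0)
    if (!stop_now) {
      if (control$acquisition == "random") {
        sel <- with_local_seed(sub_seed(control$seed, a1, q + 500000L),
                               sample(length(samp),
                                      min(control$batch_size, length(samp))))
        sel <- sort(sel)
        alpha <- NA_real_
      } else {
        cv2_mat <- vapply(seq_along(atoms), function(k) {
          cv2_train <- gpr_loo_cv(models[[k]])
          assign_voronoi(feats[[atoms[k]]][samp, , drop = FALSE],
                         feats[[atoms[k]]][train, , drop = FALSE], cv2_train)
        }, numeric(length(samp)))
        s2_mat <- vapply(seq_along(atoms), function(k)
          predict(models[[k]],
                  feats[[atoms[k]]][samp, , drop = FALSE])$variance,
          numeric(length(samp)))
        agg <- aggregate_per_system(matrix(cv2_mat, nrow = length(samp)),
                                    matrix(s2_mat, nrow = length(samp)))
        epe <- expected_prediction_error(agg$cv2_sys, agg$s2_sys, alpha)
        sel <- select_points(epe, control$batch_size)
      }
    }

    history <- rbind(history, data.frame(
      iteration = q, ntrain = length(train), alpha = alpha,
      val_rmse = val_rmse, val_max = val_max,
      selected = paste(samp[sel], collapse = ";")))

    if (stop_now || !length(sel)) break

    new_frames <- samp[sel]
    new_pred <- vapply(seq_along(atoms), function(k)
      predict(models[[k]],
              feats[[atoms[k]]][new_frames, , drop = FALSE])$mean,
      numeric(length(new_frames)))
    new_pred <- matrix(new_pred, nrow = length(new_frames))
    new_cv2_sys <- if (control$acquisition == "random")
      rep(NA_real_, length(sel)) else agg$cv2_sys[sel]
    new_y <- lapply(atoms, function(a)
      vapply(new_frames, truth, numeric(1L), atom = a))
    drop_bad <- Reduce(`|`, lapply(new_y, is.na))
    if (any(drop_bad)) {
      samp <- setdiff(samp, new_frames[drop_bad])
      keep <- !drop_bad
      new_frames <- new_frames[keep]
      new_pred <- new_pred[keep, , drop = FALSE]
      new_cv2_sys <- new_cv2_sys[keep]
      new_y <- lapply(new_y, `[`, keep)
      if (!length(new_frames)) next
    }
    last <- if (control$acquisition == "random") NULL else
      list(frames = new_frames, pe_cv2_sys = new_cv2_sys, pred = new_pred)
    train <- c(train, new_frames)
    for (k in seq_along(atoms)) y_train[[k]] <- c(y_train[[k]], new_y[[k]])
    samp <- setdiff(samp, new_frames)
  }
  history$atom <- NA_integer_
  full_models <- vector("list", length(feats))
  full_sets <- vector("list", length(feats))
  for (k in seq_along(atoms)) {
    full_models[[atoms[k]]] <- models[[k]]
    full_sets[[atoms[k]]] <- list(train_idx = train, sample_idx = samp,
                                  valid_idx = valid)
  }
  structure(list(models = full_models, history = history, sets = full_sets,
                 alf = alf, atoms = atoms,
                 elements = attr(alf, "elements"), control = control),
            class = "mepe_al")
}

#' @export
print.mepe_al <- function(x, ...) {
  nt <- vapply(x$atoms, function(a) nrow(x$models[[a]]$X), 1L)
  cat(sprintf("<mepe_al> %s acquisition, %s mode, %d atom model(s)\n",
              x$control$acquisition, x$control$mode, length(x$atoms)))
  cat(sprintf("  training points per atom: %s\n", paste(nt, collapse = ", ")))
  fin <- x$history[!duplicated(x$history$atom, fromLast = TRUE), , drop = FALSE]
  cat(sprintf("  final validation RMSE: %s kJ/mol\n",
              paste(signif(fin$val_rmse, 4), collapse = ", ")))
  invisible(x)
}

#' @export
summary.mepe_al <- function(object, ...) {
  h <- object$history
  agg <- do.call(rbind, lapply(split(h, h$atom), function(s)
    data.frame(atom = s$atom[1L], iterations = max(s$iteration),
               ntrain = max(s$ntrain),
               first_rmse = s$val_rmse[1L],
               final_rmse = s$val_rmse[nrow(s)],
               final_max = s$val_max[nrow(s)])))
  class(agg) <- c("summary.mepe_al", "data.frame")
  agg
}

#' Write per-atom active-learning history CSVs
#'
#' One CSV per atom with columns iteration, ntrain, alpha, selected frame
#' ids, validation RMSE and max error.
#'
#' @param run a `mepe_al` object.
#' @param dir output directory (created if missing).
#' @return Invisibly, the written paths.
#' @export
write_al_history <- function(run, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character(0)
  for (a in unique(run$history$atom)) {
    sub <- run$history[is.na(run$history$atom) |
                         run$history$atom %in% a, , drop = FALSE]
    tag <- if (is.na(a)) "system" else paste0("atom", a)
    p <- file.path(dir, paste0("history_", tag, ".csv"))
    utils::write.csv(sub, p, row.names = FALSE)
    paths <- c(paths, p)
  }
  invisible(paths)
}
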