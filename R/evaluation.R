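#' @title Model quality reporting
#' @description S-curves (cumulative distributions of per-configuration total
#'   prediction errors, with and without cancellation of signed atomic
#'   errors), learning curves across active-learning iterations,
#'   true-versus-predicted tables, and Kabsch superposition for inspecting
#'   trajectory spread.
#' @name evaluation
NULL

#' Total prediction error of one configuration
#'
#' `"no_cancellation"` sums the absolute per-atom errors (always positive);
#' `"cancellation"` sums the signed errors first and takes the magnitude,
#' which is closer to the physics of a total energy and never exceeds the
#' no-cancellation value.
#'
#' @param atomic_pe signed per-atom prediction errors (kJ/mol).
#' @param mode `"no_cancellation"` or `"cancellation"`.
#' @return Scalar total prediction error.
#' @export
total_prediction_error <- function(atomic_pe,
                                   mode = c("no_cancellation", "cancellation")) {
  stopifnot(length(atomic_pe) >= 1L)
  mode <- match.arg(mode)
  if (mode == "no_cancellation") sum(abs(atomic_pe)) else abs(sum(atomic_pe))
}

#' Build an S-curve from per-configuration errors
#'
#' Errors are sorted ascending; the k-th of m errors is plotted at percentile
#' `100 * k / m` (inclusive-right convention, so reproductions are
#' bit-stable).
#'
#' @param per_config_errors numeric vector of total prediction errors.
#' @param mode label recorded on the object.
#' @return Object of class `s_curve`: data.frame with columns `error` and
#'   `percentile`.
#' @export
s_curve <- function(per_config_errors,
                    mode = c("no_cancellation", "cancellation")) {
  stopifnot(length(per_config_errors) >= 1L)
  m <- length(per_config_errors)
  out <- data.frame(error = sort(per_config_errors),
                    percentile = 100 * seq_len(m) / m)
  attr(out, "mode") <- match.arg(mode)
  class(out) <- c("s_curve", "data.frame")
  out
}

#' @export
plot.s_curve <- function(x, add = FALSE, ...) {
  if (add) graphics::lines(x$error, x$percentile, ...)
  else plot(x$error, x$percentile, type = "l",
            xlab = "prediction error / kJ mol-1",
            ylab = "% of validation set", log = "x", ...)
  invisible(x)
}

#' S-curves of a fitted active-learning run
#'
#' Evaluates every atomic model on the given frames, forms per-configuration
#' total prediction errors, and returns the S-curve.
#'
#' @param run a `mepe_al` object.
#' @param traj the [trajectory] the run was trained on.
#' @param pes the [toy_pes] oracle for the true energies.
#' @param frames frame indices to evaluate (default: the run's validation
#'   set).
#' @param mode error-cancellation mode, see [total_prediction_error].
#' @return An [s_curve].
#' @export
s_curve_from_run <- function(run, traj, pes, frames = NULL,
                             mode = c("no_cancellation", "cancellation")) {
  mode <- match.arg(mode)
  tab <- true_vs_predicted(run, traj, pes, frames)
  pe <- as.matrix(tab[, grep("^pe_atom", names(tab)), drop = FALSE])
  s_curve(apply(pe, 1L, total_prediction_error, mode = mode), mode = mode)
}

#' Kabsch superposition of two configurations
#'
#' Returns the proper rotation (determinant +1) minimizing the RMSD between
#' the two coordinate sets over a subset of atoms after centroid alignment,
#' together with the RMSD achieved over all atoms and the aligned copy of
#' `B`. The default subset is the heavy (non-hydrogen) atoms when elements
#' are available and at least three are heavy, otherwise all atoms.
#'
#' @param A,B natoms x 3 coordinate matrices or [mol_config] objects.
#' @param subset atom indices used to determine the rotation (>= 3,
#'   non-collinear).
#' @return List with `rotation` (3 x 3), `rmsd` (over all atoms), and
#'   `aligned` (B mapped onto A).
#' @export
kabsch_superpose <- function(A, B, subset = NULL) {
  elements <- if (inherits(A, "mol_config")) A$elements
  if (inherits(A, "mol_config")) A <- A$coordinates
  if (inherits(B, "mol_config")) B <- B$coordinates
  A <- as.matrix(A); B <- as.matrix(B)
  stopifnot(identical(dim(A), dim(B)), ncol(A) == 3L)
  if (is.null(subset)) {
    subset <- seq_len(nrow(A))
    if (!is.null(elements) && sum(elements != "H") >= 3L)
      subset <- which(elements != "H")
  }
  if (length(subset) < 3L)
    stop("Kabsch subset must contain at least 3 atoms", call. = FALSE)
  cA <- colMeans(A[subset, , drop = FALSE])
  cB <- colMeans(B[subset, , drop = FALSE])
  P <- sweep(B[subset, , drop = FALSE], 2L, cB)
  Q <- sweep(A[subset, , drop = FALSE], 2L, cA)
  sv_check <- svd(Q)$d
  if (sv_check[2L] < 1e-8 * max(sv_check[1L], 1))
    stop("degenerate (collinear) Kabsch subset", call. = FALSE)
  H <- crossprod(P, Q)                     # 3 x 3
  sv <- svd(H)
  sgn <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, sgn)) %*% t(sv$u)
  aligned <- sweep(sweep(B, 2L, cB) %*% t(R), 2L, cA, `+`)
  rmsd <- sqrt(mean(rowSums((aligned - A)^2)))
  list(rotation = R, rmsd = rmsd, aligned = aligned)
}

#' Superpose every frame of a trajectory onto its first frame
#'
#' @param traj a [trajectory].
#' @param subset Kabsch subset (default heavy atoms).
#' @return The trajectory with all frames rotated/translated onto frame 1,
#'   with per-frame RMSDs in attribute `rmsd`.
#' @export
superpose_trajectory <- function(traj, subset = NULL) {
  ref <- traj$configurations[[1L]]
  rmsds <- numeric(length(traj$configurations))
  for (k in seq_along(traj$configurations)) {
    fit <- kabsch_superpose(ref, traj$configurations[[k]], subset)
    traj$configurations[[k]]$coordinates <- fit$aligned
    rmsds[k] <- fit$rmsd
  }
  attr(traj, "rmsd") <- rmsds
  traj
}

#' True-versus-predicted table for an active-learning run
#'
#' One row per frame: true and predicted total energies (predicted total =
#' sum of atomic predictions), per-atom truths, predictions, and signed
#' errors. Frames whose truth evaluation fails are skipped with a warning.
#'
#' @param run a `mepe_al` object with fitted per-atom models.
#' @param traj the underlying [trajectory].
#' @param pes the [toy_pes] oracle.
#' @param frames frame indices (default: the run's validation set).
#' @return data.frame with columns `frame_id`, `true_total`, `pred_total`,
#'   `true_atom<i>`, `pred_atom<i>`, `pe_atom<i>`.
#' @export
true_vs_predicted <- function(run, traj, pes, frames = NULL) {
  atoms <- run$atoms
  if (is.null(frames)) frames <- run$sets[[atoms[1L]]]$valid_idx
  rows <- list()
  for (f in frames) {
    cfg <- traj$configurations[[f]]
    en <- tryCatch(atomic_energies(cfg, pes), error = function(e) NULL)
    if (is.null(en)) { warning("truth unavailable for frame ", f); next }
    preds <- vapply(atoms, function(a)
      predict(run$models[[a]],
              matrix(featurize(cfg, run$alf, a), nrow = 1L))$mean,
      numeric(1L))
    row <- c(frame_id = f,
             true_total = sum(en$atomic[atoms]), pred_total = sum(preds),
             stats::setNames(en$atomic[atoms], paste0("true_atom", atoms)),
             stats::setNames(preds, paste0("pred_atom", atoms)),
             stats::setNames(preds - en$atomic[atoms],
                             paste0("pe_atom", atoms)))
    rows[[length(rows) + 1L]] <- row
  }
  if (!length(rows)) stop("no frames with available truths", call. = FALSE)
  as.data.frame(do.call(rbind, rows))
}

#' Learning curve of an active-learning run
#'
#' @param run a `mepe_al` object.
#' @return Object of class `learning_curve`: the run history with columns
#'   atom, iteration, ntrain, mean (RMSE) and max validation errors.
#' @export
learning_curve <- function(run) {
  h <- run$history[, c("atom", "iteration", "ntrain", "val_rmse", "val_max")]
  class(h) <- c("learning_curve", "data.frame")
  h
}

#' @export
plot.learning_curve <- function(x, ...) {
  plot(x$ntrain, x$val_rmse, type = "n", log = "y",
       xlab = "training points", ylab = "validation RMSE / kJ mol-1", ...)
  for (a in unique(x$atom)) {
    s <- x[is.na(x$atom) | x$atom %in% a, , drop = FALSE]
    graphics::lines(s$ntrain, s$val_rmse, type = "b", pch = 16,
                    col = if (is.na(a)) 1L else a)
  }
  invisible(x)
}

#' @export
plot.mepe_al <- function(x, ...) plot(learning_curve(x), ...)

#' Write evaluation CSVs for an active-learning run
#'
#' Emits `s_curve.csv` (both cancellation modes), `learning_curve.csv` and
#' `true_vs_pred.csv` into `dir`.
#'
#' @param run a `mepe_al` object.
#' @param traj,pes the trajectory and oracle of the run.
#' @param dir output directory (created if missing).
#' @param frames frame indices to evaluate (default: validation set).
#' @return Invisibly, the written paths.
#' @export
write_evaluation <- function(run, traj, pes, dir, frames = NULL) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  tab <- true_vs_predicted(run, traj, pes, frames)
  pe <- as.matrix(tab[, grep("^pe_atom", names(tab)), drop = FALSE])
  sc <- rbind(
    cbind(as.data.frame(s_curve(apply(pe, 1L, total_prediction_error,
                                      mode = "no_cancellation"))),
          mode = "no_cancellation"),
    cbind(as.data.frame(s_curve(apply(pe, 1L, total_prediction_error,
                                      mode = "cancellation"))),
          mode = "cancellation"))
  paths <- c(file.path(dir, "s_curve.csv"),
             file.path(dir, "learning_curve.csv"),
             file.path(dir, "true_vs_pred.csv"))
  utils::write.csv(sc, paths[1L], row.names = FALSE)
  utils::write.csv(as.data.frame(learning_curve(run)), paths[2L],
                   row.names = FALSE)
  utils::write.csv(tab, paths[3L], row.names = FALSE)
  invisible(paths)
}
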