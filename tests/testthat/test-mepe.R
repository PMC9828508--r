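test_that("training-set initialization picks extremes and mean-closest frames", {
  F1 <- matrix(c(0, 1, 2, 3), ncol = 1)
  expect_identical(init_training_set(F1), c(1L, 4L, 2L))
  # identical frames collapse to one
  expect_identical(init_training_set(matrix(5, 10, 3)), 1L)
  set.seed(73)
  F2 <- matrix(runif(200 * 5), 200, 5)
  idx <- init_training_set(F2)
  expect_lte(length(idx), 15L)
  expect_true(all(idx %in% 1:200))
  expect_identical(idx, unique(idx))
})

test_that("sample/validation partition shrinks proportionally and is disjoint", {
  expect_warning(p <- partition_sets(100, 1:10, 10000, 500, seed = 5),
                 "shrinking")
  expect_length(p$sample_idx, 86L)
  expect_length(p$valid_idx, 4L)
  expect_length(intersect(p$sample_idx, p$valid_idx), 0L)
  expect_length(intersect(p$sample_idx, 1:10), 0L)
  expect_length(intersect(p$valid_idx, 1:10), 0L)
  p2 <- suppressWarnings(partition_sets(100, 1:10, 10000, 500, seed = 5))
  expect_identical(p, p2)
  p3 <- suppressWarnings(partition_sets(100, 1:10, 10000, 500, seed = 6))
  expect_false(identical(p, p3))
  expect_error(partition_sets(11, 1:10, 10, 5), "fewer than 2")
  # no shrink needed when the pool suffices
  p4 <- partition_sets(100, 1:10, 50, 20, seed = 1)
  expect_length(p4$sample_idx, 50L)
  expect_length(p4$valid_idx, 20L)
})

test_that("exact LOO error behaves in closed-form limits", {
  # duplicated information: held-out duplicate is predicted exactly
  X <- matrix(c(0, 0, 1), ncol = 1)
  attr(X, "cyclic") <- FALSE
  y <- c(2, 2, 5)
  expect_lt(gpr_loo_cv_exact(X, y, 1, 1L, nugget = 1e-12), 1e-10)
  # n = 2 with huge theta: the remaining 1-point model predicts its own y
  X2 <- matrix(c(0, 1), ncol = 1)
  attr(X2, "cyclic") <- FALSE
  y2 <- c(1, 4)
  expect_equal(gpr_loo_cv_exact(X2, y2, 1e6, 1L), (4 - 1)^2, tolerance = 1e-6)
  expect_error(gpr_loo_cv_exact(matrix(0, 1, 1), 1, 1, 1L), "at least 2")
})

test_that("closed-form LOO matches the retrain oracle", {
  set.seed(79)
  for (rep in 1:10) {
    inst <- rand_instance(12, 2)
    m <- gpr(inst$X, inst$y, inst$theta)
    fast <- gpr_loo_cv(m)
    exact <- vapply(1:12, function(i)
      gpr_loo_cv_exact(inst$X, inst$y, inst$theta, i), numeric(1L))
    expect_equal(fast, exact, tolerance = 1e-6)
  }
  # duplicated training rows carry near-zero CV error
  Xd <- matrix(c(0, 0, 1, 2), ncol = 1)
  attr(Xd, "cyclic") <- FALSE
  md <- gpr(Xd, c(3, 3, 5, 6), c(1))
  cvd <- gpr_loo_cv(md)
  expect_lt(max(cvd[1:2]), 1e-8)
})

test_that("GLS residual variant stays close to the constant-mean form", {
  set.seed(83)
  inst <- rand_instance(15, 2)
  m <- gpr(inst$X, inst$y, inst$theta)
  a <- gpr_loo_cv(m, residual = "constant")
  b <- gpr_loo_cv(m, residual = "gls")
  expect_lt(median(abs(b - a) / pmax(a, 1e-10)), 0.5)
})

test_that("Voronoi assignment agrees with a brute-force nearest scan", {
  set.seed(89)
  cyc <- c(FALSE, TRUE, FALSE)
  Tr <- matrix(runif(30, -3, 3), 10, 3); attr(Tr, "cyclic") <- cyc
  S <- matrix(runif(120, -3, 3), 40, 3)
  cv2 <- runif(10)
  got <- assign_voronoi(S, Tr, cv2)
  brute <- vapply(1:40, function(i) {
    d2 <- vapply(1:10, function(j) {
      r <- S[i, ] - Tr[j, ]
      r[cyc] <- ((r[cyc] + pi) %% (2 * pi)) - pi
      sum(r^2)
    }, numeric(1L))
    cv2[which.min(d2)]
  }, numeric(1L))
  expect_equal(got, brute, tolerance = 1e-12)
  # sample point on a training point inherits that point's error
  expect_equal(assign_voronoi(Tr[4, , drop = FALSE], Tr, cv2), cv2[4])
  # single training point dominates everything
  expect_equal(assign_voronoi(S, Tr[1, , drop = FALSE], 0.7),
               rep(0.7, 40))
})

test_that("balance factor follows the capped ratio rule", {
  expect_equal(balance_factor(123, 456, 1L), 0.5)
  expect_equal(balance_factor(0.8, 1, 2L), 0.99 * 0.4)
  expect_equal(balance_factor(1e6, 1, 2L), 0.99)
  expect_equal(balance_factor(1, 0, 2L), 0.99)
  expect_equal(balance_factor(0, 1, 2L), 0)
  set.seed(97)
  for (rep in 1:50) {
    a <- balance_factor(runif(1, 0, 100), runif(1, 1e-6, 100),
                        sample(2:10, 1))
    expect_gte(a, 0); expect_lte(a, 0.99)
  }
})

test_that("batch balance factor is the plain mean", {
  expect_equal(batch_balance_factor(c(0.4, 0.6)), 0.5)
  expect_equal(batch_balance_factor(0.37), 0.37)
  expect_error(batch_balance_factor(numeric(0)), "empty")
  set.seed(101)
  v <- runif(7, 0, 0.99)
  expect_equal(batch_balance_factor(v), sum(v) / 7)
})

test_that("EPE combines exploitation and exploration linearly", {
  expect_equal(expected_prediction_error(3, 5, 0), 5)
  expect_equal(expected_prediction_error(2, 2, 0.5), 2)
  set.seed(103)
  cv2 <- runif(20); s2 <- runif(20); a <- runif(1, 0, 0.99)
  expect_equal(expected_prediction_error(cv2, s2, a), a * cv2 + (1 - a) * s2)
})

test_that("per-system aggregation sums over atoms", {
  one <- aggregate_per_system(0.3, 0.7, 0.1)
  expect_equal(one, list(cv2_sys = 0.3, s2_sys = 0.7, pe_true2_sys = 0.1))
  expect_equal(aggregate_per_system(rep(0, 5), rep(0, 5))$cv2_sys, 0)
  set.seed(107)
  cv2 <- matrix(runif(15), 3, 5); s2 <- matrix(runif(15), 3, 5)
  agg <- aggregate_per_system(cv2, s2)
  expect_equal(agg$cv2_sys, rowSums(cv2))
  expect_equal(agg$s2_sys, rowSums(s2))
  expect_error(aggregate_per_system(1:3, 1:4), "length")
})

test_that("point selection takes the largest EPE with index tie-breaks", {
  expect_identical(select_points(c(1, 9, 3), 1L), 2L)
  expect_identical(select_points(rep(2, 6), 3L), 1:3)
  expect_identical(select_points(numeric(0), 1L), integer(0))
  set.seed(109)
  epe <- runif(50)
  expect_identical(select_points(epe, 10L), order(-epe)[1:10])
})

test_that("active learning keeps sets disjoint and grows by the batch size", {
  run <- water_al_run(seed = 1, batch_size = 5L, max_train = 30L, atoms = 1L)
  s <- run$sets[[1L]]
  expect_length(intersect(s$train_idx, s$sample_idx), 0L)
  expect_length(intersect(s$train_idx, s$valid_idx), 0L)
  expect_length(intersect(s$sample_idx, s$valid_idx), 0L)
  h <- run$history
  expect_true(all(diff(h$ntrain) == 5L))
  expect_identical(h$iteration, seq_len(nrow(h)))
  a <- h$alpha[!is.na(h$alpha)]
  expect_true(all(a >= 0 & a <= 0.99))
  expect_equal(h$alpha[1L], 0.5)
})

test_that("runs are deterministic and independent of atom order", {
  r1 <- water_al_run(seed = 3, max_train = 16L, atoms = 1L)
  ctrl <- al_control(max_train = 16L, seed = 3, pso = al_pso())
  traj <- water_trajectory()
  pes <- default_systems("water")$pes
  r1b <- suppressWarnings(active_learn(traj, pes, ctrl, atoms = 1L))
  expect_identical(r1$history, r1b$history)
  expect_identical(r1$models[[1L]]$theta, r1b$models[[1L]]$theta)
  # atom 2's model must not depend on whether atom 3 ran before it
  ctrl2 <- al_control(max_train = 14L, seed = 3, pso = al_pso())
  ra <- suppressWarnings(active_learn(traj, pes, ctrl2, atoms = c(2L, 3L)))
  rb <- suppressWarnings(active_learn(traj, pes, ctrl2, atoms = c(3L, 2L)))
  expect_identical(ra$models[[2L]]$X, rb$models[[2L]]$X)
  expect_identical(ra$models[[2L]]$theta, rb$models[[2L]]$theta)
  expect_identical(ra$models[[3L]]$y, rb$models[[3L]]$y)
})

test_that("per-atom and per-system modes coincide on a 1-atom reduction", {
  pa <- water_al_run(seed = 2, max_train = 16L, atoms = 1L, mode = "per_atom")
  ps <- water_al_run(seed = 2, max_train = 16L, atoms = 1L, mode = "per_system")
  expect_identical(pa$history$selected, ps$history$selected)
  expect_identical(pa$history$ntrain, ps$history$ntrain)
  expect_equal(pa$history$alpha, ps$history$alpha)
  expect_equal(pa$history$val_rmse, ps$history$val_rmse)
  expect_identical(sort(pa$sets[[1L]]$train_idx), sort(ps$sets[[1L]]$train_idx))
})

test_that("per-system mode shares one training set across all atoms", {
  run <- water_al_run(seed = 4, batch_size = 2L, max_train = 35L,
                      mode = "per_system")
  tr1 <- run$sets[[1L]]$train_idx
  for (a in 2:3) expect_identical(run$sets[[a]]$train_idx, tr1)
  expect_gte(length(tr1), 35L)
  h <- run$history
  expect_true(all(is.na(h$atom)))
  expect_true(all(diff(h$ntrain) == 2L))
  expect_equal(h$alpha[1L], 0.5)
  a <- h$alpha[!is.na(h$alpha)]
  expect_true(all(a >= 0 & a <= 0.99))
  # every atomic model is fitted on the shared set
  for (a in 1:3) expect_identical(nrow(run$models[[a]]$X), length(tr1))
})

test_that("history export writes one CSV per atom", {
  run <- water_al_run(seed = 1, batch_size = 5L, max_train = 30L, atoms = 1L)
  dir <- withr::local_tempdir()
  paths <- write_al_history(run, dir)
  expect_true(all(file.exists(paths)))
  back <- read.csv(paths[1L])
  expect_identical(nrow(back), nrow(run$history))
})
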