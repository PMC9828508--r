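make_water <- function() {
  r <- 0.9572; th <- 104.52 * pi / 180
  mol_config(c("O", "H", "H"),
             rbind(c(0, 0, 0), c(r, 0, 0), c(r * cos(th), r * sin(th), 0)))
}

make_methane <- function() {
  # regular tetrahedron around C
  d <- 1.09 / sqrt(3)
  mol_config(c("C", "H", "H", "H", "H"),
             rbind(c(0, 0, 0), d * c(1, 1, 1), d * c(1, -1, -1),
                   d * c(-1, 1, -1), d * c(-1, -1, 1)))
}

test_that("ALF indices are distinct and deterministic", {
  for (sys in list(make_water(), make_methane(),
                   default_systems("ammonia")$geometry,
                   default_systems("chain12")$geometry)) {
    alf <- compute_alf(sys)
    for (tri in alf) expect_length(unique(tri), 3L)
    expect_identical(unclass(alf), unclass(compute_alf(sys)))
  }
})

test_that("water oxygen takes the two hydrogens, tie broken by index", {
  alf <- compute_alf(make_water())
  expect_identical(unname(alf[[1L]]), c(1L, 2L, 3L))
})

test_that("methane carbon picks hydrogens per the priority rule", {
  alf <- compute_alf(make_methane())
  expect_identical(unname(alf[[1L]][1L]), 1L)
  # all four H tie on mass and substituents, so lowest indices win
  expect_identical(unname(alf[[1L]][2:3]), c(2L, 3L))
  # heavier substituent outranks lighter ones: replace one H by Cl
  m <- make_methane()
  m$elements[4L] <- "Cl"
  alf2 <- compute_alf(m)
  expect_identical(unname(alf2[[1L]][2L]), 4L)
})

test_that("recursive priority distinguishes equal-mass neighbours", {
  # linear-ish chain C1-C2-C3-O4: for C2, neighbour C3 (bearing O) outranks C1
  cfg <- mol_config(c("C", "C", "C", "O"),
                    rbind(c(0, 0, 0), c(1.5, 0.2, 0), c(3.0, 0, 0),
                          c(4.3, 0.4, 0)))
  alf <- compute_alf(cfg)
  expect_identical(unname(alf[[2L]][2L]), 3L)
})

test_that("featurize reproduces analytic geometry", {
  cfg <- mol_config(c("O", "H", "H"),
                    rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)))
  alf <- compute_alf(cfg)
  f <- featurize(cfg, alf, 1L)
  expect_equal(as.numeric(f), c(1, 1, pi / 2), tolerance = 1e-12)
})

test_that("features are invariant under rigid motions", {
  set.seed(7)
  for (sys in list(make_water(), make_methane(),
                   default_systems("chain12")$geometry)) {
    alf <- compute_alf(sys)
    n <- length(sys$elements)
    f0 <- lapply(seq_len(n), function(a) featurize(sys, alf, a))
    for (rep in 1:5) {
      Q <- random_rotation()
      t <- runif(3, -10, 10)
      moved <- sys
      moved$coordinates <- sweep(sys$coordinates %*% t(Q), 2L, -t)
      for (a in seq_len(n))
        expect_lt(max(abs(featurize(moved, alf, a) - f0[[a]])), 1e-9)
    }
  }
})

test_that("feature dimensionality is 3N - 6 across system sizes", {
  expect_identical(feature_count(3L), 3L)
  expect_identical(feature_count(12L), 30L)
  expect_identical(feature_count(19L), 51L)
  expect_error(feature_count(2L), "at least 3")
  for (nat in 3:19) {
    cfg <- chain_config(nat)
    alf <- compute_alf(cfg)
    expect_length(featurize(cfg, alf, 1L), feature_count(nat))
  }
})

test_that("cyclic mask marks every third dimension", {
  m <- feature_cyclic_mask(5L)
  expect_identical(which(m), c(3L, 6L, 9L))
})

test_that("feature differences wrap cyclic dimensions", {
  mk <- function(v, cyc) structure(v, cyclic = cyc)
  x <- mk(c(1, 2, 3), c(FALSE, FALSE, TRUE))
  expect_equal(feature_difference(x, x), c(0, 0, 0))
  a <- mk(c(0, 0, 3), c(FALSE, FALSE, TRUE))
  b <- mk(c(0, 0, -3), c(FALSE, FALSE, TRUE))
  expect_equal(abs(feature_difference(a, b)[3L]), 2 * pi - 6, tolerance = 1e-12)
  expect_error(feature_difference(a, mk(1:3, c(TRUE, FALSE, FALSE))),
               "masks differ")
  # wrapped difference equals the brute-force argmin over 2*pi shifts
  set.seed(11)
  for (rep in 1:50) {
    xa <- runif(1, -pi, pi); xb <- runif(1, -pi, pi)
    cand <- xa - xb + 2 * pi * (-1:1)
    best <- cand[which.min(abs(cand))]
    got <- feature_difference(mk(xa, TRUE), mk(xb, TRUE))
    expect_equal(as.numeric(got), best, tolerance = 1e-12)
  }
})

test_that("feature vectors invert back to the original geometry", {
  set.seed(23)
  sys <- default_systems("ammonia")$geometry
  alf <- compute_alf(sys)
  traj <- suppressWarnings(
    sample_configurations(sys, 500, 5, seed = 5))
  for (k in seq_along(traj$configurations)) {
    cfg <- traj$configurations[[k]]
    for (a in seq_along(cfg$elements)) {
      f <- featurize(cfg, alf, a)
      rebuilt <- features_to_config(as.numeric(f), alf, a, cfg$elements)
      expect_lt(max(abs(featurize(rebuilt, alf, a) - f)), 1e-9)
    }
  }
})

test_that("degenerate geometries are rejected", {
  cfg <- mol_config(c("O", "H", "H"),
                    rbind(c(0, 0, 0), c(0, 0, 0), c(0, 1, 0)))
  alf <- list(c(1L, 2L, 3L), c(2L, 1L, 3L), c(3L, 1L, 2L))
  expect_error(featurize(cfg, alf, 1L), "degenerate|coincident")
  collinear <- mol_config(c("O", "H", "H"),
                          rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0)))
  expect_error(featurize(collinear, alf, 1L), "degenerate|zero-length")
})
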