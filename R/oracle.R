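#' @title Synthetic configuration sampler and toy potential energy surface
#' @description Stand-ins for the ab initio stages of the pipeline: a
#'   normal-mode-style sampler producing temperature-controlled distorted
#'   geometries with minimum-distance rejection, and a smooth toy potential
#'   energy surface (harmonic bonds and angles plus Lennard-Jones-like
#'   nonbonded terms) whose per-atom energy partition sums exactly to the
#'   total energy — playing the role the quantum-topological (IQA) partition
#'   plays for real systems.
#' @name synthetic-oracle
NULL

#' Construct a toy potential energy surface
#'
#' Terms: harmonic bonds `0.5*kb*(r - r0)^2`, harmonic angles
#' `0.5*ka*(theta - theta0)^2`, and Lennard-Jones-like pair terms
#' `eps*((rm/r)^12 - 2*(rm/r)^6)` (minimum -eps at r = rm). The per-atom
#' partition assigns half of each pair term to each participating atom and a
#' third of each angle term to each of its three atoms, so the atomic
#' energies sum to the total exactly.
#'
#' @param bonds data.frame(i, j, kb, r0): atom indices, force constant
#'   (kJ/mol/A^2), equilibrium length (Angstrom).
#' @param angles data.frame(i, j, k, ka, theta0): `j` is the apex atom;
#'   force constant kJ/mol/rad^2, equilibrium angle radians.
#' @param pairs data.frame(i, j, eps, rm): nonbonded well depth (kJ/mol) and
#'   minimum position (Angstrom).
#' @return Object of class `toy_pes`.
#' @export
toy_pes <- function(bonds, angles = NULL, pairs = NULL) {
  empty_angles <- data.frame(i = integer(), j = integer(), k = integer(),
                             ka = numeric(), theta0 = numeric())
  empty_pairs <- data.frame(i = integer(), j = integer(),
                            eps = numeric(), rm = numeric())
  structure(list(bonds = bonds,
                 angles = if (is.null(angles)) empty_angles else angles,
                 pairs = if (is.null(pairs)) empty_pairs else pairs),
            class = "toy_pes")
}

#' @export
print.toy_pes <- function(x, ...) {
  cat(sprintf("<toy_pes> %d bonds, %d angles, %d nonbonded pairs\n",
              nrow(x$bonds), nrow(x$angles), nrow(x$pairs)))
  invisible(x)
}

vec_angle <- function(a, b) {
  acos(max(-1, min(1, sum(a * b) / sqrt(sum(a^2) * sum(b^2)))))
}

#' Per-atom energies under a toy PES
#'
#' The total energy is defined as the sum of the per-atom energies, so the
#' partition is conservative to machine precision by construction.
#'
#' @param config a [mol_config].
#' @param pes a [toy_pes] whose indices refer to `config`'s atoms.
#' @return List with `atomic` (length-natoms vector, kJ/mol) and `total`.
#' @export
atomic_energies <- function(config, pes) {
  n <- length(config$elements)
  xyz <- config$coordinates
  e <- numeric(n)
  b <- pes$bonds
  if (nrow(b)) {
    if (max(b$i, b$j) > n) stop("PES bond indices exceed atom count", call. = FALSE)
    for (row in seq_len(nrow(b))) {
      r <- sqrt(sum((xyz[b$i[row], ] - xyz[b$j[row], ])^2))
      eb <- 0.5 * b$kb[row] * (r - b$r0[row])^2
      e[b$i[row]] <- e[b$i[row]] + eb / 2
      e[b$j[row]] <- e[b$j[row]] + eb / 2
    }
  }
  a <- pes$angles
  if (nrow(a)) {
    if (max(a$i, a$j, a$k) > n) stop("PES angle indices exceed atom count",
                                     call. = FALSE)
    for (row in seq_len(nrow(a))) {
      th <- vec_angle(xyz[a$i[row], ] - xyz[a$j[row], ],
                      xyz[a$k[row], ] - xyz[a$j[row], ])
      ea <- 0.5 * a$ka[row] * (th - a$theta0[row])^2
      e[a$i[row]] <- e[a$i[row]] + ea / 3
      e[a$j[row]] <- e[a$j[row]] + ea / 3
      e[a$k[row]] <- e[a$k[row]] + ea / 3
    }
  }
  p <- pes$pairs
  if (nrow(p)) {
    if (max(p$i, p$j) > n) stop("PES pair indices exceed atom count", call. = FALSE)
    for (row in seq_len(nrow(p))) {
      r <- sqrt(sum((xyz[p$i[row], ] - xyz[p$j[row], ])^2))
      s6 <- (p$rm[row] / r)^6
      ep <- p$eps[row] * (s6^2 - 2 * s6)
      e[p$i[row]] <- e[p$i[row]] + ep / 2
      e[p$j[row]] <- e[p$j[row]] + ep / 2
    }
  }
  list(atomic = e, total = sum(e))
}

#' Attach toy-PES energy labels to a trajectory
#'
#' @param traj a [trajectory].
#' @param pes a [toy_pes].
#' @return The trajectory with `atomic_energies` and `total_energy` set on
#'   every frame.
#' @export
label_energies <- function(traj, pes) {
  for (k in seq_along(traj$configurations)) {
    en <- atomic_energies(traj$configurations[[k]], pes)
    traj$configurations[[k]]$atomic_energies <- en$atomic
    traj$configurations[[k]]$total_energy <- en$total
  }
  traj
}

# Derive a toy PES whose minimum is exactly the given geometry: bonds from the
# covalent-radius bonding graph, angles from bonded triples, LJ terms for the
# remaining pairs, with every equilibrium value set to the geometry's own.
pes_from_geometry <- function(config, kb = 2000, ka = 300, eps = 0.5) {
  n <- length(config$elements)
  graph <- bond_graph(config)
  xyz <- config$coordinates
  bonds <- do.call(rbind, lapply(seq_len(n), function(i) {
    j <- graph[[i]][graph[[i]] > i]
    if (!length(j)) return(NULL)
    data.frame(i = i, j = j)
  }))
  bonds$kb <- kb
  bonds$r0 <- apply(bonds, 1L, function(rw)
    sqrt(sum((xyz[rw[["i"]], ] - xyz[rw[["j"]], ])^2)))
  angles <- NULL
  for (j in seq_len(n)) {
    nb <- graph[[j]]
    if (length(nb) >= 2L) {
      cmb <- utils::combn(sort(nb), 2L)
      angles <- rbind(angles, data.frame(i = cmb[1L, ], j = j, k = cmb[2L, ]))
    }
  }
  if (!is.null(angles)) {
    angles$ka <- ka
    angles$theta0 <- apply(angles, 1L, function(rw)
      vec_angle(xyz[rw[["i"]], ] - xyz[rw[["j"]], ],
                xyz[rw[["k"]], ] - xyz[rw[["j"]], ]))
  }
  bonded <- matrix(FALSE, n, n)
  for (i in seq_len(n)) bonded[i, graph[[i]]] <- TRUE
  pairs <- NULL
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    if (!bonded[i, j]) {
      rm_ <- sqrt(sum((xyz[i, ] - xyz[j, ])^2))
      pairs <- rbind(pairs, data.frame(i = i, j = j, eps = eps, rm = rm_))
    }
  }
  toy_pes(bonds, angles, pairs)
}

#' Built-in benchmark systems
#'
#' Idealized single-molecule geometries paired with a [toy_pes] whose minimum
#' is exactly that geometry: `"water"` (3 atoms, 3 features), `"ammonia"`
#' (4 atoms, 6 features), and `"chain12"`, a 12-atom zigzag carbon-chain
#' surrogate (30 features).
#'
#' @param name optional system name; omitted returns the full named list.
#' @return A list with elements `geometry` ([mol_config]) and `pes`
#'   ([toy_pes]), or a named list of such pairs.
#' @export
default_systems <- function(name = NULL) {
  water_geom <- local({
    r <- 0.9572; th <- 104.52 * pi / 180
    mol_config(c("O", "H", "H"),
               rbind(c(0, 0, 0), c(r, 0, 0), c(r * cos(th), r * sin(th), 0)))
  })
  ammonia_geom <- local({
    r <- 1.012; hnh <- 106.7 * pi / 180
    # polar angle beta of each H from the C3 axis: solve
    # cos(hnh) = cos^2(beta) - 0.5 sin^2(beta)
    cb2 <- (cos(hnh) + 0.5) / 1.5
    beta <- acos(sqrt(cb2))
    az <- 2 * pi * (0:2) / 3
    h <- t(vapply(az, function(a)
      r * c(sin(beta) * cos(a), sin(beta) * sin(a), cos(beta)), numeric(3L)))
    mol_config(c("N", "H", "H", "H"), rbind(c(0, 0, 0), h))
  })
  chain_geom <- local({
    # planar zigzag: step headings alternate +/- delta so the backbone angle
    # at every interior atom is pi - 2*delta = 112 degrees
    nb <- 1.54; ang <- 112 * pi / 180
    delta <- (pi - ang) / 2
    xyz <- matrix(0, 12L, 3L)
    for (k in 2:12) {
      phi <- if (k %% 2L == 0L) delta else -delta
      xyz[k, ] <- xyz[k - 1L, ] + nb * c(cos(phi), sin(phi), 0)
    }
    mol_config(rep("C", 12L), xyz)
  })
  systems <- list(
    water = list(geometry = water_geom, pes = pes_from_geometry(water_geom)),
    ammonia = list(geometry = ammonia_geom, pes = pes_from_geometry(ammonia_geom)),
    chain12 = list(geometry = chain_geom,
                   pes = pes_from_geometry(chain_geom, kb = 1500, ka = 250,
                                           eps = 0.3)))
  if (is.null(name)) return(systems)
  if (!name %in% names(systems))
    stop("unknown system '", name, "'; available: ",
         paste(names(systems), collapse = ", "), call. = FALSE)
  systems[[name]]
}

# Orthonormal basis of internal displacement directions: random Gaussian
# directions with net translation and rotation projected out.
internal_mode_basis <- function(xyz) {
  n <- nrow(xyz)
  centered <- sweep(xyz, 2L, colMeans(xyz))
  gen <- matrix(0, 3L * n, 6L)
  for (ax in 1:3) gen[seq(ax, 3L * n, by = 3L), ax] <- 1  # translations
  axes <- diag(3L)
  for (ax in 1:3) {                                        # rotations
    for (i in seq_len(n))
      gen[(3L * (i - 1L) + 1L):(3L * i), 3L + ax] <- cross3(axes[ax, ], centered[i, ])
  }
  gen <- qr.Q(qr(gen))
  nint <- 3L * n - 6L
  raw <- matrix(stats::rnorm(3L * n * nint), 3L * n, nint)
  raw <- raw - gen %*% crossprod(gen, raw)
  qr.Q(qr(raw))[, seq_len(nint), drop = FALSE]
}

#' Sample distorted molecular configurations
#'
#' Emulates normal-mode sampling: displacements along a random orthonormal
#' basis of internal directions (net translation and rotation projected out)
#' with per-mode Gaussian amplitudes of standard deviation
#' `0.002 * sqrt(temperature)` Angstrom — the equipartition amplitude
#' `sqrt(kB*T / k)` for the stiffness scale of the built-in toy surfaces
#' (k ~ 2000 kJ/mol/A^2, kB*T ~ 2.5 kJ/mol at 300). The temperature is a
#' monotone distortion control, not thermodynamic Kelvin. A candidate frame is
#' rejected when its feature-space distance (concatenated per-atom ALF
#' features, cyclic wrap applied) to every accepted frame falls below
#' `min_dist_cutoff`; generation stops when `n_frames` are accepted or an
#' attempt cap (50 per requested frame) is reached, with a warning in the
#' latter case.
#'
#' @param seed_geometry a [mol_config] with at least 3 atoms.
#' @param temperature nominal distortion scale (>= 0).
#' @param n_frames number of frames to generate.
#' @param min_dist_cutoff minimum feature-space distance between accepted
#'   frames (0 disables rejection).
#' @param seed integer RNG seed (private stream).
#' @return A [trajectory]; the first frame is the (possibly undistorted) seed.
#' @export
sample_configurations <- function(seed_geometry, temperature, n_frames,
                                  min_dist_cutoff = 0, seed = 1L) {
  stopifnot(temperature >= 0, min_dist_cutoff >= 0, n_frames >= 1L)
  n <- length(seed_geometry$elements)
  if (n < 3L) stop("sampler requires at least 3 atoms", call. = FALSE)
  alf <- compute_alf(seed_geometry)
  sysfeat <- function(xyz) {
    cfg <- mol_config(seed_geometry$elements, xyz)
    unlist(lapply(seq_len(n), function(a) as.numeric(featurize(cfg, alf, a))))
  }
  mask <- rep(feature_cyclic_mask(n), n)
  feat_dist <- function(f1, f2) {
    d <- f1 - f2
    d[mask] <- wrap_angle(d[mask])
    sqrt(sum(d^2))
  }
  sigma <- 0.002 * sqrt(temperature)
  rads <- .covalent_radius[seed_geometry$elements]
  clash_cut <- 0.4 * outer(rads, rads, `+`)
  diag(clash_cut) <- 0
  with_local_seed(as.integer(seed), {
    V <- internal_mode_basis(seed_geometry$coordinates)
    nint <- ncol(V)
    accepted <- list()
    feats <- list()
    attempts <- 0L
    cap <- 50L * n_frames
    while (length(accepted) < n_frames && attempts < cap) {
      attempts <- attempts + 1L
      disp <- if (sigma > 0) V %*% stats::rnorm(nint, sd = sigma) else
        numeric(3L * n)
      xyz <- seed_geometry$coordinates + matrix(disp, n, 3L, byrow = TRUE)
      # steric clash rejection: physically based samplers never emit
      # geometries with strongly overlapping atoms
      if (any(as.matrix(stats::dist(xyz)) < clash_cut)) next
      f <- tryCatch(sysfeat(xyz), error = function(e) NULL)
      if (is.null(f)) next  # degenerate distorted geometry
      if (min_dist_cutoff > 0 && length(feats)) {
        dists <- vapply(feats, feat_dist, numeric(1L), f2 = f)
        if (any(dists < min_dist_cutoff)) next
      }
      accepted[[length(accepted) + 1L]] <-
        mol_config(seed_geometry$elements, xyz,
                   frame_id = length(accepted) + 1L)
      feats[[length(feats) + 1L]] <- f
    }
    if (length(accepted) < n_frames)
      warning(sprintf("attempt cap reached: %d of %d frames accepted",
                      length(accepted), n_frames))
    trajectory(accepted,
               source_tag = sprintf("synthetic-normal-mode T=%g", temperature))
  })
}

#' Default minimum-distance cutoff heuristic
#'
#' One percent of the median nearest-neighbour feature-space distance of a
#' pilot trajectory.
#'
#' @param traj a pilot [trajectory].
#' @return Scalar cutoff.
#' @export
suggest_min_dist_cutoff <- function(traj) {
  cfg0 <- traj$configurations[[1L]]
  n <- length(cfg0$elements)
  alf <- compute_alf(cfg0)
  F <- do.call(cbind, lapply(seq_len(n), function(a)
    featurize_trajectory(traj, alf, a)))
  mask <- rep(feature_cyclic_mask(n), n)
  m <- nrow(F)
  nn <- numeric(m)
  for (i in seq_len(m)) {
    d <- sweep(F[-i, , drop = FALSE], 2L, F[i, ])
    d[, mask] <- wrap_angle(d[, mask])
    nn[i] <- sqrt(min(rowSums(d^2)))
  }
  0.01 * stats::median(nn)
}

#' Write toy-PES parameters to YAML
#'
#' @param pes a [toy_pes].
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_pes_yaml <- function(pes, path) {
  yaml::write_yaml(list(bonds = as.list(pes$bonds),
                        angles = as.list(pes$angles),
                        pairs = as.list(pes$pairs)), path)
  invisible(path)
}

#' Read toy-PES parameters from YAML
#'
#' @param path YAML written by [write_pes_yaml].
#' @return A [toy_pes].
#' @export
read_pes_yaml <- function(path) {
  obj <- yaml::read_yaml(path)
  toy_pes(as.data.frame(obj$bonds),
          if (length(obj$angles$i)) as.data.frame(obj$angles),
          if (length(obj$pairs$i)) as.data.frame(obj$pairs))
}
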