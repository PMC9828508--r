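#' @title Atomic local frame (ALF) features
#' @description Each atom gets a local coordinate frame defined by three atoms
#'   (origin, x-axis atom, xy-plane atom). Features of an atom are the two ALF
#'   distances, the ALF valence angle, and spherical-polar coordinates
#'   (r, theta, phi) of every remaining atom expressed in that frame — a
#'   translation- and rotation-invariant, invertible description of the
#'   geometry with 3*natoms - 6 dimensions.
#' @name alf
NULL

# Covalent radii (Angstrom) and atomic masses for the elements used by the
# bonding heuristic and the ALF priority rule.
.covalent_radius <- c(H = 0.31, He = 0.28, B = 0.84, C = 0.76, N = 0.71,
                      O = 0.66, F = 0.57, Na = 1.66, Mg = 1.41, Si = 1.11,
                      P = 1.07, S = 1.05, Cl = 1.02, K = 2.03, Ca = 1.76,
                      Br = 1.20, I = 1.39)
.atomic_mass <- c(H = 1.008, He = 4.003, B = 10.81, C = 12.011, N = 14.007,
                  O = 15.999, F = 18.998, Na = 22.99, Mg = 24.305, Si = 28.085,
                  P = 30.974, S = 32.06, Cl = 35.45, K = 39.098, Ca = 40.078,
                  Br = 79.904, I = 126.904)

element_mass <- function(el) {
  m <- .atomic_mass[el]
  if (anyNA(m)) stop("unknown element(s): ",
                     paste(unique(el[is.na(m)]), collapse = ", "), call. = FALSE)
  unname(m)
}

# Bonding graph: pairs closer than 1.2 x sum of covalent radii.
bond_graph <- function(config, scale = 1.2) {
  el <- config$elements
  r <- .covalent_radius[el]
  if (anyNA(r)) stop("no covalent radius for element(s): ",
                     paste(unique(el[is.na(r)]), collapse = ", "), call. = FALSE)
  n <- length(el)
  d <- as.matrix(stats::dist(config$coordinates))
  cut <- outer(r, r, `+`) * scale
  adj <- d < cut & d > 0
  lapply(seq_len(n), function(i) as.integer(which(adj[i, ])))
}

# CIP-like priority comparison of two substituents of `origin`: explore the
# substituent trees breadth-first (never stepping back through the bond just
# traversed), comparing descending-sorted mass lists level by level.
# Returns +1 if a outranks b, -1 if b outranks a, 0 on a full tie.
cip_compare <- function(a, b, origin, graph, masses) {
  n <- length(masses)
  level_a <- list(c(parent = origin, atom = a))
  level_b <- list(c(parent = origin, atom = b))
  for (depth in seq_len(n)) {
    ma <- sort(masses[vapply(level_a, `[[`, 1L, "atom")], decreasing = TRUE)
    mb <- sort(masses[vapply(level_b, `[[`, 1L, "atom")], decreasing = TRUE)
    len <- max(length(ma), length(mb))
    ma <- c(ma, rep(0, len - length(ma)))
    mb <- c(mb, rep(0, len - length(mb)))
    diff <- ma - mb
    nz <- which(abs(diff) > 1e-9)
    if (length(nz)) return(sign(diff[nz[1L]]))
    expand <- function(level) {
      out <- list()
      for (e in level) {
        nb <- setdiff(graph[[e[["atom"]]]], e[["parent"]])
        for (x in nb) out[[length(out) + 1L]] <- c(parent = e[["atom"]], atom = x)
      }
      out
    }
    level_a <- expand(level_a)
    level_b <- expand(level_b)
    if (!length(level_a) && !length(level_b)) return(0)
  }
  0
}

# Rank candidate partners of `origin`: CIP-like priority, final ties broken by
# lowest atom index.
rank_partners <- function(candidates, origin, graph, masses) {
  if (length(candidates) <= 1L) return(candidates)
  ord <- candidates
  cmp <- function(i, j) {
    c1 <- cip_compare(i, j, origin, graph, masses)
    if (c1 != 0) return(c1)
    sign(j - i)  # lower index wins
  }
  # insertion sort by pairwise comparison (tiny vectors)
  for (k in 2:length(ord)) {
    x <- ord[k]; j <- k - 1L
    while (j >= 1L && cmp(x, ord[j]) > 0) { ord[j + 1L] <- ord[j]; j <- j - 1L }
    ord[j + 1L] <- x
  }
  ord
}

#' Construct the atomic local frame definition for a molecule
#'
#' For every atom the x-axis and xy-plane partner atoms are chosen
#' deterministically from the bonding graph of the reference geometry: bonded
#' neighbours are ranked by a Cahn-Ingold-Prelog-like priority (descending
#' atomic mass, ties resolved by recursively comparing substituent masses,
#' final ties by lowest atom index); the top two become the x-axis and
#' xy-plane atoms. Atoms with fewer than two bonded partners fall back to the
#' nearest atoms by distance. The ALF is computed once on a reference frame
#' and reused for every frame of a trajectory.
#'
#' @param reference a [mol_config] (natoms >= 3).
#' @return An object of class `alf`, a list with one integer triple
#'   `c(origin, x_axis, xy_plane)` (1-based atom indices) per atom.
#' @export
compute_alf <- function(reference) {
  n <- length(reference$elements)
  if (n < 3L) stop("ALF requires at least 3 atoms", call. = FALSE)
  graph <- bond_graph(reference)
  masses <- element_mass(reference$elements)
  d <- as.matrix(stats::dist(reference$coordinates))
  alf <- vector("list", n)
  for (i in seq_len(n)) {
    cand <- rank_partners(graph[[i]], i, graph, masses)
    if (length(cand) < 2L) {
      # routine for terminal atoms (one bonded partner); a fully unbonded
      # atom signals a disconnected bonding graph, worth a warning
      if (!length(cand))
        warning(sprintf(
          "atom %d is unbonded; ALF partners chosen by distance only", i))
      extra <- setdiff(order(d[i, ]), c(i, cand))
      cand <- c(cand, extra)[1:2]
    }
    alf[[i]] <- c(origin = i, x_axis = cand[1L], xy_plane = cand[2L])
  }
  structure(alf, class = "alf", elements = reference$elements)
}

#' @export
print.alf <- function(x, ...) {
  cat("<alf> origin / x-axis / xy-plane atom indices:\n")
  for (i in seq_along(x))
    cat(sprintf("  %s%d: (%d, %d, %d)\n", attr(x, "elements")[i], i,
                x[[i]][1L], x[[i]][2L], x[[i]][3L]))
  invisible(x)
}

#' Export an ALF definition to JSON
#'
#' @param alf an `alf` object from [compute_alf].
#' @param path output JSON path.
#' @return Invisibly, `path`.
#' @export
write_alf_json <- function(alf, path) {
  obj <- stats::setNames(lapply(alf, function(t) unname(as.integer(t))),
                         as.character(seq_along(alf)))
  jsonlite::write_json(obj, path, auto_unbox = FALSE)
  invisible(path)
}

#' Number of ALF feature dimensions
#'
#' @param natoms number of atoms (>= 3).
#' @return `3 * natoms - 6`.
#' @export
feature_count <- function(natoms) {
  if (any(natoms < 3L)) stop("ALF features require at least 3 atoms", call. = FALSE)
  3L * as.integer(natoms) - 6L
}

#' Cyclic-dimension mask for ALF features
#'
#' Every third feature (1-based dimension d with d mod 3 == 0) is an angle in
#' (-pi, pi] subject to the cyclic wrap: the ALF valence angle (d = 3) and
#' every azimuthal phi (d = 6, 9, ...).
#'
#' @param natoms number of atoms (>= 3).
#' @return Logical vector of length `feature_count(natoms)`.
#' @export
feature_cyclic_mask <- function(natoms) {
  nd <- feature_count(natoms)
  seq_len(nd) %% 3L == 0L
}

unit <- function(v) {
  nv <- sqrt(sum(v^2))
  if (nv < 1e-12) stop("degenerate geometry: zero-length frame vector",
                       call. = FALSE)
  v / nv
}

cross3 <- function(a, b) {
  c(a[2L] * b[3L] - a[3L] * b[2L],
    a[3L] * b[1L] - a[1L] * b[3L],
    a[1L] * b[2L] - a[2L] * b[1L])
}

#' Compute the ALF feature vector of one atom
#'
#' Features are ordered as `[R(x-axis), R(xy-plane), valence angle]` followed
#' by `(r, theta, phi)` spherical-polar triples for each non-ALF atom in
#' ascending atom-index order. Local axes: x-hat along origin -> x-axis atom;
#' z-hat = x-hat x (origin -> xy-plane atom), normalized; y-hat = z-hat x
#' x-hat. theta in \[0, pi\] is the polar angle from z-hat, phi in (-pi, pi\]
#' the azimuth. Distances in Angstrom, angles in radians. The result is
#' invariant under rigid translation and rotation of the input.
#'
#' @param config a [mol_config].
#' @param alf ALF definition from [compute_alf].
#' @param atom 1-based index of the atom to featurize.
#' @return Numeric vector of length `3 * natoms - 6` with a logical `cyclic`
#'   attribute marking the wrap-around dimensions.
#' @export
featurize <- function(config, alf, atom) {
  n <- length(config$elements)
  if (n < 3L) stop("ALF features require at least 3 atoms", call. = FALSE)
  tri <- alf[[atom]]
  xyz <- config$coordinates
  o <- xyz[tri[1L], ]
  v1 <- xyz[tri[2L], ] - o
  v2 <- xyz[tri[3L], ] - o
  r1 <- sqrt(sum(v1^2)); r2 <- sqrt(sum(v2^2))
  if (r1 < 1e-10 || r2 < 1e-10)
    stop("degenerate geometry: coincident ALF atoms", call. = FALSE)
  xhat <- v1 / r1
  zraw <- cross3(xhat, v2)
  zhat <- unit(zraw)                      # errors if v2 parallel to x-axis
  yhat <- cross3(zhat, xhat)
  ang <- acos(max(-1, min(1, sum(v1 * v2) / (r1 * r2))))
  feats <- c(r1, r2, ang)
  others <- setdiff(seq_len(n), tri)
  others <- sort(others)
  for (j in others) {
    v <- xyz[j, ] - o
    loc <- c(sum(v * xhat), sum(v * yhat), sum(v * zhat))
    r <- sqrt(sum(loc^2))
    if (r < 1e-10)
      stop("degenerate geometry: atom coincident with ALF origin", call. = FALSE)
    theta <- acos(max(-1, min(1, loc[3L] / r)))
    phi <- atan2(loc[2L], loc[1L])
    feats <- c(feats, r, theta, phi)
  }
  structure(feats, cyclic = feature_cyclic_mask(n))
}

#' Feature matrix of one atom over a trajectory
#'
#' @param traj a [trajectory].
#' @param alf ALF definition from [compute_alf].
#' @param atom 1-based atom index.
#' @return nframes x ndim numeric matrix with a `cyclic` attribute.
#' @export
featurize_trajectory <- function(traj, alf, atom) {
  n <- length(traj$configurations)
  f1 <- featurize(traj$configurations[[1L]], alf, atom)
  X <- matrix(NA_real_, n, length(f1))
  X[1L, ] <- f1
  if (n > 1L) for (k in 2:n)
    X[k, ] <- featurize(traj$configurations[[k]], alf, atom)
  structure(X, cyclic = attr(f1, "cyclic"))
}

#' Reconstruct Cartesian coordinates from an ALF feature vector
#'
#' Inverse of [featurize], up to rigid motion: the origin atom is placed at
#' the Cartesian origin, the x-axis atom on the positive x axis, and the
#' xy-plane atom in the upper (y > 0) half of the xy-plane; remaining atoms
#' are placed from their spherical-polar triples. Re-featurizing the result
#' reproduces the input features.
#'
#' @param features numeric feature vector as produced by [featurize].
#' @param alf ALF definition.
#' @param atom atom index the features belong to.
#' @param elements element symbols of the molecule.
#' @return A [mol_config] in the canonical local-frame orientation.
#' @export
features_to_config <- function(features, alf, atom, elements) {
  n <- length(elements)
  stopifnot(length(features) == feature_count(n))
  tri <- alf[[atom]]
  xyz <- matrix(0, n, 3L)
  xyz[tri[1L], ] <- c(0, 0, 0)
  xyz[tri[2L], ] <- c(features[1L], 0, 0)
  xyz[tri[3L], ] <- features[2L] * c(cos(features[3L]), sin(features[3L]), 0)
  others <- sort(setdiff(seq_len(n), tri))
  for (k in seq_along(others)) {
    r <- features[3L * k + 1L]
    th <- features[3L * k + 2L]
    ph <- features[3L * k + 3L]
    xyz[others[k], ] <- r * c(sin(th) * cos(ph), sin(th) * sin(ph), cos(th))
  }
  mol_config(elements, xyz)
}

#' Per-dimension feature difference with cyclic wrap
#'
#' Non-cyclic dimensions return `x - x_star`; cyclic (angular) dimensions
#' return the wrapped difference `((x - x_star + pi) mod 2*pi) - pi`, whose
#' magnitude never exceeds pi.
#'
#' @param x,x_star feature vectors with identical `cyclic` attributes
#'   (matrices are handled row-wise against a vector `x_star`).
#' @return Vector (or matrix) of differences.
#' @export
feature_difference <- function(x, x_star) {
  cx <- attr(x, "cyclic"); cs <- attr(x_star, "cyclic")
  if (is.null(cx) && is.null(cs))
    stop("feature vectors carry no cyclic mask", call. = FALSE)
  if (is.null(cx)) cx <- cs
  if (is.null(cs)) cs <- cx
  if (!identical(unname(cx), unname(cs)))
    stop("cyclic masks differ between feature vectors", call. = FALSE)
  if (is.matrix(x)) {
    d <- sweep(x, 2L, as.numeric(x_star))
    d[, cx] <- wrap_angle(d[, cx])
    return(d)
  }
  if (length(x) != length(x_star)) stop("feature length mismatch", call. = FALSE)
  d <- as.numeric(x) - as.numeric(x_star)
  d[cx] <- wrap_angle(d[cx])
  d
}

wrap_angle <- function(d) ((d + pi) %% (2 * pi)) - pi
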