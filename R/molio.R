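#' Molecular configuration
#'
#' A single molecular frame: element symbols plus Cartesian coordinates in
#' Angstrom, optionally labelled with per-atom energies and/or a total energy
#' (kJ/mol). When both energy fields are present the atomic energies must sum
#' to the total (the per-atom partition is exact).
#'
#' @param elements character vector of element symbols (case-normalized).
#' @param coordinates numeric natoms x 3 matrix of Cartesian positions (Angstrom).
#' @param atomic_energies optional numeric vector, one energy per atom (kJ/mol).
#' @param total_energy optional scalar total energy (kJ/mol).
#' @param frame_id integer frame identifier.
#' @return An object of class `mol_config`.
#' @export
mol_config <- function(elements, coordinates, atomic_energies = NULL,
                       total_energy = NULL, frame_id = 1L) {
  elements <- normalize_element(as.character(elements))
  coordinates <- as.matrix(coordinates)
  storage.mode(coordinates) <- "double"
  if (nrow(coordinates) != length(elements) || ncol(coordinates) != 3L)
    stop("coordinates must be a length(elements) x 3 matrix", call. = FALSE)
  if (!is.null(atomic_energies)) {
    atomic_energies <- as.numeric(atomic_energies)
    if (length(atomic_energies) != length(elements))
      stop("atomic_energies must have one value per atom", call. = FALSE)
  }
  if (!is.null(total_energy)) total_energy <- as.numeric(total_energy)[1L]
  if (!is.null(atomic_energies) && !is.null(total_energy)) {
    s <- sum(atomic_energies)
    if (abs(s - total_energy) > 1e-9 * max(1, abs(total_energy)))
      stop("sum(atomic_energies) does not match total_energy", call. = FALSE)
  }
  structure(
    list(elements = elements, coordinates = coordinates,
         atomic_energies = atomic_energies, total_energy = total_energy,
         frame_id = as.integer(frame_id)),
    class = "mol_config")
}

# First letter upper, rest lower ("CL" -> "Cl")
normalize_element <- function(sym) {
  sym <- trimws(sym)
  paste0(toupper(substr(sym, 1L, 1L)), tolower(substr(sym, 2L, nchar(sym))))
}

#' @export
print.mol_config <- function(x, ...) {
  cat(sprintf("<mol_config> %d atoms (%s), frame %d\n",
              length(x$elements), paste(x$elements, collapse = " "), x$frame_id))
  if (!is.null(x$total_energy))
    cat(sprintf("  total energy: %.6f kJ/mol\n", x$total_energy))
  invisible(x)
}

#' Molecular trajectory
#'
#' An ordered collection of [mol_config] frames sharing one atom list.
#'
#' @param configurations list of `mol_config` frames.
#' @param source_tag free-text provenance tag (sampler name, temperature, ...).
#' @return An object of class `trajectory`.
#' @export
trajectory <- function(configurations, source_tag = "") {
  if (!length(configurations)) stop("trajectory must contain at least one frame",
                                    call. = FALSE)
  ref <- configurations[[1L]]$elements
  for (k in seq_along(configurations)) {
    if (!identical(configurations[[k]]$elements, ref))
      stop("all frames must share one element list and atom ordering",
           call. = FALSE)
  }
  structure(list(configurations = configurations,
                 source_tag = as.character(source_tag)),
            class = "trajectory")
}

#' @export
length.trajectory <- function(x) length(x$configurations)

#' @export
`[[.trajectory` <- function(x, i) x$configurations[[i]]

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("<trajectory> %d frames, %d atoms (%s)%s\n",
              length(x$configurations), length(x$configurations[[1L]]$elements),
              paste(x$configurations[[1L]]$elements, collapse = " "),
              if (nzchar(x$source_tag)) paste0(" [", x$source_tag, "]") else ""))
  invisible(x)
}

#' Read a multi-frame XYZ trajectory
#'
#' Standard XYZ layout: an atom-count line, a comment line, then one
#' `element x y z` line per atom, repeated per frame. A comment-line token
#' `energy=<float>` is parsed into the frame's total energy (kJ/mol).
#'
#' @param path path to an XYZ file.
#' @return A [trajectory].
#' @export
read_xyz <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  # trailing blank lines are tolerated
  while (length(lines) && !nzchar(trimws(lines[length(lines)])))
    lines <- lines[-length(lines)]
  if (!length(lines)) stop("parse error: empty XYZ file", call. = FALSE)

  frames <- list()
  pos <- 1L
  fid <- 1L
  while (pos <= length(lines)) {
    nat <- suppressWarnings(as.integer(trimws(lines[pos])))
    if (is.na(nat) || nat < 1L)
      stop(sprintf("parse error at line %d: malformed atom-count line '%s'",
                   pos, lines[pos]), call. = FALSE)
    if (pos + 1L + nat > length(lines))
      stop(sprintf("parse error at line %d: truncated frame (%d atom lines expected)",
                   pos, nat), call. = FALSE)
    comment <- lines[pos + 1L]
    atom_lines <- lines[(pos + 2L):(pos + 1L + nat)]
    toks <- strsplit(trimws(atom_lines), "[[:space:]]+")
    bad <- which(vapply(toks, length, 1L) < 4L)
    if (length(bad))
      stop(sprintf("parse error at line %d: expected 'element x y z'",
                   pos + 1L + bad[1L]), call. = FALSE)
    el <- vapply(toks, `[[`, "", 1L)
    xyz <- matrix(NA_real_, nat, 3L)
    for (j in 1:3) {
      v <- suppressWarnings(as.numeric(vapply(toks, `[[`, "", j + 1L)))
      if (anyNA(v))
        stop(sprintf("parse error at line %d: non-numeric coordinate",
                     pos + 1L + which(is.na(v))[1L]), call. = FALSE)
      xyz[, j] <- v
    }
    energy <- NULL
    m <- regmatches(comment,
                    regexpr("energy=[-+0-9.eE]+", comment))
    if (length(m) && nzchar(m))
      energy <- as.numeric(sub("energy=", "", m))
    frames[[fid]] <- mol_config(el, xyz, total_energy = energy, frame_id = fid)
    fid <- fid + 1L
    pos <- pos + 2L + nat
  }
  ref <- frames[[1L]]$elements
  for (k in seq_along(frames))
    if (!identical(frames[[k]]$elements, ref))
      stop("format error: inconsistent atom lists across frames", call. = FALSE)
  trajectory(frames, source_tag = basename(path))
}

#' Write a multi-frame XYZ trajectory
#'
#' Inverse of [read_xyz]. Frames with a `total_energy` carry an
#' `energy=<float>` token on the comment line. Coordinates are printed with
#' enough digits to round-trip to better than 1e-8 Angstrom.
#'
#' @param traj a [trajectory].
#' @param path output file path.
#' @return Invisibly, `path`.
#' @export
write_xyz <- function(traj, path) {
  stopifnot(inherits(traj, "trajectory"))
  con <- tryCatch(file(path, "w"), error = function(e)
    stop("cannot open for writing: ", path, call. = FALSE))
  on.exit(close(con))
  for (cfg in traj$configurations) {
    writeLines(as.character(length(cfg$elements)), con)
    comment <- sprintf("frame %d", cfg$frame_id)
    if (!is.null(cfg$total_energy))
      comment <- sprintf("%s energy=%.10g", comment, cfg$total_energy)
    writeLines(comment, con)
    writeLines(sprintf("%-3s %18.10f %18.10f %18.10f", cfg$elements,
                       cfg$coordinates[, 1L], cfg$coordinates[, 2L],
                       cfg$coordinates[, 3L]), con)
  }
  invisible(path)
}

#' Write per-atom energies to a sidecar CSV
#'
#' XYZ has no per-atom scalar convention, so atomic energies are persisted in a
#' CSV with columns frame_id, atom_index, atom_label, energy_kj_mol.
#'
#' @param traj a [trajectory] whose frames carry `atomic_energies`.
#' @param path output CSV path.
#' @return Invisibly, `path`.
#' @export
write_atomic_energies <- function(traj, path) {
  stopifnot(inherits(traj, "trajectory"))
  rows <- lapply(traj$configurations, function(cfg) {
    if (is.null(cfg$atomic_energies)) return(NULL)
    data.frame(frame_id = cfg$frame_id,
               atom_index = seq_along(cfg$elements),
               atom_label = cfg$elements,
               energy_kj_mol = cfg$atomic_energies)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) stop("no atomic energies present in trajectory", call. = FALSE)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Read a per-atom energy sidecar CSV
#'
#' @param traj the [trajectory] the energies belong to.
#' @param path CSV written by [write_atomic_energies].
#' @return The trajectory with `atomic_energies` (and `total_energy`) attached.
#' @export
read_atomic_energies <- function(traj, path) {
  stopifnot(inherits(traj, "trajectory"))
  tab <- utils::read.csv(path)
  for (k in seq_along(traj$configurations)) {
    fid <- traj$configurations[[k]]$frame_id
    sub <- tab[tab$frame_id == fid, , drop = FALSE]
    if (!nrow(sub)) next
    sub <- sub[order(sub$atom_index), , drop = FALSE]
    traj$configurations[[k]]$atomic_energies <- sub$energy_kj_mol
    traj$configurations[[k]]$total_energy <- sum(sub$energy_kj_mol)
  }
  traj
}
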