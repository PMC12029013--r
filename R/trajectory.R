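#' Trajectory container
#'
#' A \code{trajectory} holds an atom table plus a coordinate array of
#' dimension \code{n_atoms x 3 x n_frames} (Angstrom), an orthorhombic box
#' (length-3, Angstrom, or \code{NULL}), and per-frame times (ns). Atom
#' count and ordering are identical across frames by construction.
#'
#' @param atoms data.frame with columns \code{index}, \code{name},
#'   \code{resname}, \code{resid}, \code{segid}, \code{element},
#'   \code{is_hydrogen}, \code{mass}.
#' @param coords numeric array \code{n_atoms x 3 x n_frames}.
#' @param box length-3 numeric (Angstrom) or \code{NULL}.
#' @param times numeric vector of frame times (ns); defaults to
#'   \code{0, dt, 2 dt, ...}.
#' @param dt frame spacing in ns used when \code{times} is missing.
#' @param selections optional [selection_spec()] resolved and cached on the
#'   object.
#' @return object of class \code{trajectory}.
#' @export
trajectory <- function(atoms, coords, box = NULL, times = NULL, dt = 1,
                       selections = NULL) {
  if (length(dim(coords)) == 2L) dim(coords) <- c(dim(coords), 1L)
  stopifnot(length(dim(coords)) == 3L, dim(coords)[2] == 3L)
  if (nrow(atoms) != dim(coords)[1]) {
    stop("atom table (", nrow(atoms), ") and coordinate array (",
         dim(coords)[1], ") disagree on atom count")
  }
  if (!all(is.finite(coords))) stop("coordinates must be finite")
  if (anyDuplicated(atoms$index)) stop("atom indices must be unique")
  n_frames <- dim(coords)[3]
  if (is.null(times)) times <- dt * (seq_len(n_frames) - 1)
  if (length(times) != n_frames) stop("times length must equal frame count")
  if (!is.null(box)) stopifnot(length(box) == 3L, all(box > 0))
  traj <- structure(list(atoms = atoms, coords = coords, box = box,
                         times = as.numeric(times),
                         n_frames = n_frames, n_atoms = nrow(atoms),
                         selections = NULL, sel_idx = NULL),
                    class = "trajectory")
  if (!is.null(selections)) {
    traj$selections <- selections
    traj$sel_idx <- resolve_selections(atoms, selections)
  }
  traj
}

#' @export
print.trajectory <- function(x, ...) {
  cat("trajectory:", x$n_atoms, "atoms,", x$n_frames, "frames\n")
  if (!is.null(x$box)) cat("  box:", paste(signif(x$box, 5), collapse = " x "), "A\n")
  cat("  time:", signif(x$times[1], 4), "..", signif(x$times[x$n_frames], 4), "ns\n")
  segs <- table(x$atoms$segid)
  cat("  segments:", paste(names(segs), segs, sep = ":", collapse = ", "), "\n")
  invisible(x)
}

# Coordinates of one frame as an n x 3 matrix.
frame_coords <- function(traj, frame) {
  stopifnot(frame >= 1, frame <= traj$n_frames)
  traj$coords[, , frame, drop = TRUE]
}

#' Load a trajectory from PDB (or DCD) files
#'
#' Reads a topology PDB and coordinate frames (multi-MODEL PDB, or a DCD
#' file read against the topology). Element symbols are taken from PDB
#' columns 77-78 when present, otherwise inferred from the atom name;
#' hydrogens are flagged by element or by name (leading digits stripped,
#' first letter H). The orthorhombic box is parsed from the CRYST1 record.
#'
#' Lateral (x, y) coordinates are unwrapped by default: frame-to-frame
#' displacements are reduced to their minimum image and re-accumulated, so
#' displacement-based analyses (center-of-mass paths, MSD) see continuous
#' paths. z is never wrapped or unwrapped.
#'
#' @param topology path to a PDB file defining atoms (and box).
#' @param coords path to coordinates: a multi-MODEL PDB or a DCD file.
#'   Defaults to \code{topology}.
#' @param selections optional [selection_spec()]; each selection is resolved
#'   against the topology at load time and an empty mandatory selection is
#'   an error.
#' @param dt frame spacing in ns (PDB/DCD files carry no time axis).
#' @param unwrap logical; unwrap lateral coordinates (default \code{TRUE}).
#' @return a [trajectory()].
#' @export
load_trajectory <- function(topology, coords = topology, selections = NULL,
                            dt = 1, unwrap = TRUE) {
  if (!file.exists(topology)) stop("topology file not found: ", topology)
  if (!file.exists(coords)) stop("coordinate file not found: ", coords)
  pdb <- bio3d::read.pdb(topology, multi = TRUE, verbose = FALSE)
  atoms <- .atom_table(pdb)
  box <- .read_cryst1(topology)

  is_dcd <- grepl("\\.dcd$", coords, ignore.case = TRUE)
  if (is_dcd) {
    xyz <- bio3d::read.dcd(coords, verbose = FALSE)
  } else if (identical(normalizePath(coords), normalizePath(topology))) {
    xyz <- pdb$xyz
  } else {
    xyz <- bio3d::read.pdb(coords, multi = TRUE, verbose = FALSE)$xyz
  }
  if (!is.matrix(xyz)) xyz <- matrix(xyz, nrow = 1)
  if (ncol(xyz) != 3L * nrow(atoms)) {
    stop("atom-count mismatch: topology has ", nrow(atoms),
         " atoms but frames carry ", ncol(xyz) / 3, " atoms")
  }
  n_frames <- nrow(xyz)
  arr <- array(NA_real_, c(nrow(atoms), 3L, n_frames))
  for (f in seq_len(n_frames)) {
    arr[, , f] <- matrix(xyz[f, ], ncol = 3L, byrow = TRUE)
  }
  if (unwrap && !is.null(box) && n_frames > 1L) {
    arr <- unwrap_lateral(arr, box)
  }
  trajectory(atoms, arr, box = box, dt = dt, selections = selections)
}

# Build the package's atom table from a bio3d pdb object.
.atom_table <- function(pdb) {
  a <- pdb$atom
  element <- a$elesy
  missing_el <- is.na(element) | !nzchar(trimws(element))
  element[missing_el] <- infer_element(a$elety[missing_el])
  element <- toupper(trimws(element))
  is_h <- element == "H" | grepl("^H", sub("^[0-9]+", "", a$elety))
  segid <- a$segid
  segid[is.na(segid)] <- ""
  data.frame(index = seq_len(nrow(a)),
             name = a$elety,
             resname = a$resid,
             resid = a$resno,
             segid = segid,
             element = element,
             is_hydrogen = is_h,
             mass = element_mass(element),
             stringsAsFactors = FALSE)
}

# Parse the first CRYST1 record of a PDB file; NULL when absent.
.read_cryst1 <- function(path) {
  con <- file(path, "r"); on.exit(close(con))
  while (length(line <- readLines(con, n = 1L))) {
    if (startsWith(line, "CRYST1")) {
      box <- as.numeric(c(substr(line, 7, 15), substr(line, 16, 24),
                          substr(line, 25, 33)))
      if (anyNA(box) || any(box <= 0)) return(NULL)
      return(box)
    }
    if (startsWith(line, "ATOM") || startsWith(line, "MODEL")) break
  }
  NULL
}

# Accumulate minimum-image lateral increments so each atom's (x, y) path is
# continuous; frame 1 is kept as-is, z untouched.
unwrap_lateral <- function(coords, box) {
  n_frames <- dim(coords)[3]
  for (f in seq_len(n_frames)[-1]) {
    for (k in 1:2) {
      d <- coords[, k, f] - coords[, k, f - 1L]
      d <- d - box[k] * round(d / box[k])
      coords[, k, f] <- coords[, k, f - 1L] + d
    }
  }
  coords
}

#' Write a trajectory as a multi-MODEL PDB
#'
#' Emits one MODEL per frame with a CRYST1 record carrying the box.
#' Coordinates are written at PDB precision (0.001 Angstrom).
#'
#' @param traj a [trajectory()].
#' @param path output file path.
#' @param wrap wrap lateral (x, y) coordinates into the box before
#'   writing, as simulation engines do (default \code{FALSE}: write the
#'   coordinates as stored).
#' @return \code{path}, invisibly.
#' @export
write_trajectory <- function(traj, path, wrap = FALSE) {
  a <- traj$atoms
  coords <- traj$coords
  if (wrap) {
    if (is.null(traj$box)) stop("cannot wrap without a box")
    for (k in 1:2) coords[, k, ] <- coords[, k, ] %% traj$box[k]
  }
  xyz <- matrix(NA_real_, traj$n_frames, 3L * traj$n_atoms)
  for (f in seq_len(traj$n_frames)) {
    xyz[f, ] <- as.vector(t(coords[, , f]))
  }
  chain <- substr(a$segid, 1, 1)
  chain[!nzchar(chain)] <- "A"
  bio3d::write.pdb(file = path, xyz = xyz,
                   eleno = a$index, elety = a$name, resid = a$resname,
                   resno = a$resid, chain = chain, elesy = a$element)
  lines <- readLines(path)
  is_atom <- startsWith(lines, "ATOM") | startsWith(lines, "HETATM")
  if (any(is_atom)) {  # bio3d drops the segid column (73-76); patch it in
    seg <- formatC(substr(a$segid, 1, 4), width = -4)
    idx <- which(is_atom)
    per_frame <- length(idx) / traj$n_frames
    seg_all <- rep(seg, length.out = length(idx))
    al <- lines[idx]
    al <- formatC(al, width = -80)
    substr(al, 73, 76) <- seg_all
    lines[idx] <- al
  }
  if (!is.null(traj$box)) {
    cryst <- sprintf("CRYST1%9.3f%9.3f%9.3f%7.2f%7.2f%7.2f P 1           1",
                     traj$box[1], traj$box[2], traj$box[3], 90, 90, 90)
    lines <- c(cryst, lines)
  }
  writeLines(lines, path)
  invisible(path)
}

#' Mean z of a leaflet reference plane
#'
#' Computes the arithmetic mean z of the selected atoms assigned to one
#' leaflet. Assignment is per frame by the sign of (z - bilayer midplane),
#' the midplane being the mean z of all selected atoms across both
#' leaflets, so the plane tracks membrane drift.
#'
#' @param traj a [trajectory()].
#' @param selection selection expression (e.g. head-group phosphorus atoms).
#' @param leaflet \code{"upper"} or \code{"lower"}.
#' @param frames frame indices (default all).
#' @return numeric vector of plane z per requested frame (Angstrom).
#' @export
leaflet_plane_z <- function(traj, selection, leaflet = c("upper", "lower"),
                            frames = NULL) {
  leaflet <- match.arg(leaflet)
  idx <- select_atoms(traj$atoms, selection)
  if (!length(idx)) stop("selection matches no atoms: ", selection)
  if (is.null(frames)) frames <- seq_len(traj$n_frames)
  vapply(frames, function(f) {
    z <- traj$coords[idx, 3L, f]
    mid <- mean(z)
    keep <- if (leaflet == "upper") z > mid else z < mid
    if (!any(keep)) stop("no selected atoms in the ", leaflet,
                         " leaflet at frame ", f)
    mean(z[keep])
  }, numeric(1))
}

#' Per-frame leaflet reference planes
#'
#' Evaluates the phosphate plane and (when a carbonyl selection is present)
#' the carbonyl plane of the binding leaflet for every frame. For the upper
#' leaflet the phosphate plane is expected at or above the carbonyl plane;
#' violations indicate a distorted frame and raise a warning, not an error.
#'
#' @param traj a [trajectory()] carrying a resolved [selection_spec()], or
#'   \code{spec} given explicitly.
#' @param spec a [selection_spec()]; defaults to the one cached on
#'   \code{traj}.
#' @return list with \code{phosphate_z}, \code{carbonyl_z} (numeric per
#'   frame; carbonyl \code{NULL} if no selection), and \code{leaflet}.
#' @export
leaflet_planes <- function(traj, spec = traj$selections) {
  if (is.null(spec)) stop("no selection_spec available")
  leaflet <- spec$binding_leaflet
  phos <- leaflet_plane_z(traj, spec$headgroup_P, leaflet)
  carb <- NULL
  if (!is.null(spec$carbonyl)) {
    carb <- leaflet_plane_z(traj, spec$carbonyl, leaflet)
    bad <- if (leaflet == "upper") phos < carb else phos > carb
    if (any(bad)) {
      warning(sum(bad), " frame(s) have the phosphate plane on the wrong ",
              "side of the carbonyl plane")
    }
  }
  list(phosphate_z = phos, carbonyl_z = carb, leaflet = leaflet)
}
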