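#' Per-frame membrane insertion depth
#'
#' The insertion depth of a peripheral protein at one frame is defined from
#' the protein heavy atom furthest below the binding-leaflet phosphate
#' plane; if no atom penetrates the plane, the heavy atom closest to it is
#' used instead. The reported depth is the z displacement of the
#' side-chain center of mass of that atom's residue relative to the plane:
#' negative values mean the side chain sits below the phosphate plane
#' (inserted), positive values above it (hovering).
#'
#' "Side chain" means all heavy atoms of the residue except the backbone
#' N, CA, C, O; for glycine (or any residue without side-chain heavy
#' atoms) the whole-residue heavy atoms are used. The center of mass is
#' mass-weighted over heavy atoms only. Ties for the deepest atom are
#' broken by the lower atom index.
#'
#' @param traj a [trajectory()].
#' @param protein selection expression for the protein.
#' @param plane_z phosphate-plane z (Angstrom): scalar or one value per
#'   requested frame (see [leaflet_plane_z()]).
#' @param frames frame indices (default all).
#' @return data.frame of class \code{depth_series} with columns
#'   \code{frame}, \code{time} (ns), \code{depth} (Angstrom),
#'   \code{resid} (residue defining the value), \code{inserted} (any
#'   protein heavy atom below the plane).
#' @export
insertion_depth <- function(traj, protein, plane_z, frames = NULL) {
  pidx <- select_atoms(traj$atoms, protein)
  if (!length(pidx)) stop("protein selection matches no atoms: ", protein)
  pidx <- pidx[!traj$atoms$is_hydrogen[pidx]]
  if (!length(pidx)) stop("protein selection contains no heavy atoms")
  if (is.null(frames)) frames <- seq_len(traj$n_frames)
  plane_z <- rep_len(plane_z, length(frames))

  # Pre-compute, per residue, the heavy side-chain atom indices and masses.
  a <- traj$atoms
  reskey <- paste(a$segid[pidx], a$resid[pidx])
  sidechains <- lapply(split(pidx, reskey), function(ridx) {
    sc <- ridx[!(a$name[ridx] %in% c("N", "CA", "C", "O"))]
    if (!length(sc)) sc <- ridx  # glycine fallback: whole-residue heavy atoms
    list(idx = sc, mass = a$mass[sc])
  })

  n <- length(frames)
  depth <- numeric(n); resid <- integer(n); inserted <- logical(n)
  for (i in seq_len(n)) {
    z <- traj$coords[pidx, 3L, frames[i]]
    j <- which.min(z)            # deepest (or closest) atom; ties -> lower index
    inserted[i] <- z[j] < plane_z[i]
    key <- reskey[j]
    sc <- sidechains[[key]]
    com_z <- sum(traj$coords[sc$idx, 3L, frames[i]] * sc$mass) / sum(sc$mass)
    depth[i] <- com_z - plane_z[i]
    resid[i] <- a$resid[pidx[j]]
  }
  structure(data.frame(frame = frames, time = traj$times[frames],
                       depth = depth, resid = resid, inserted = inserted),
            class = c("depth_series", "data.frame"))
}

#' Insertion-depth series for a trajectory
#'
#' Convenience wrapper: evaluates the per-frame phosphate plane of the
#' binding leaflet and the insertion depth against it.
#'
#' @param traj a [trajectory()] carrying a [selection_spec()], or
#'   \code{spec} given explicitly.
#' @param spec a [selection_spec()].
#' @return a \code{depth_series} (see [insertion_depth()]) with an extra
#'   \code{plane_z} column.
#' @export
depth_series <- function(traj, spec = traj$selections) {
  if (is.null(spec)) stop("no selection_spec available")
  plane <- leaflet_plane_z(traj, spec$headgroup_P, spec$binding_leaflet)
  out <- insertion_depth(traj, spec$protein, plane)
  out$plane_z <- plane
  out
}

#' Depth histogram and mode detection
#'
#' Bins depths into fixed-width bins aligned so that a bin edge falls at
#' 0 Angstrom, optionally smooths the counts with a centered moving
#' average, and reports local maxima (modes) with topographic prominence of
#' at least \code{min_prominence} times the maximum smoothed count. For a
#' skipping peripheral protein the histogram is bimodal: one inserted mode
#' below 0 and one surface-hovering mode above it.
#'
#' @param depths numeric vector of depths, or a \code{depth_series}.
#' @param bin_width bin width in Angstrom (default 0.5).
#' @param smooth_window moving-average window in bins (default 3; 1
#'   disables smoothing).
#' @param min_prominence peak prominence floor as a fraction of the maximum
#'   smoothed count (default 0.05), suppressing noise peaks.
#' @return list of class \code{depth_modes}: \code{bin_width}, \code{mids},
#'   \code{counts}, \code{smoothed}, and \code{peaks} (bin centers of the
#'   modes, by decreasing prominence).
#' @export
depth_histogram <- function(depths, bin_width = 0.5, smooth_window = 3L,
                            min_prominence = 0.05) {
  if (inherits(depths, "depth_series") || is.data.frame(depths)) {
    depths <- depths$depth
  }
  if (length(depths) < 2L) stop("need at least two depth samples")
  if (bin_width <= 0) stop("bin_width must be positive")
  bin <- floor(depths / bin_width)            # edge-aligned at 0
  rng <- range(bin)
  counts <- tabulate(bin - rng[1] + 1L, nbins = rng[2] - rng[1] + 1L)
  mids <- (seq.int(rng[1], rng[2]) + 0.5) * bin_width
  smoothed <- moving_average(counts, smooth_window)
  peaks <- local_maxima(smoothed)
  peaks <- peaks[peaks$prominence >= min_prominence * max(smoothed), , drop = FALSE]
  structure(list(bin_width = bin_width, mids = mids, counts = counts,
                 smoothed = smoothed, peaks = mids[peaks$index],
                 prominence = peaks$prominence),
            class = "depth_modes")
}

#' @export
print.depth_modes <- function(x, ...) {
  cat("depth histogram:", length(x$mids), "bins of", x$bin_width, "A;",
      sum(x$counts), "samples\n")
  cat("  modes (A):", paste(signif(x$peaks, 4), collapse = ", "), "\n")
  invisible(x)
}

#' Two-state bound/hover segmentation of a depth series
#'
#' Formalizes "skipping" diffusion as a two-state sequence: a frame is
#' BOUND when its depth is below \code{threshold} (chosen between the two
#' depth modes) and HOVER otherwise. Runs shorter than \code{min_dwell}
#' frames are merged into the flanking state, scanning left to right so
#' the earlier state wins ties; statistics are computed on the merged
#' sequence.
#'
#' @param depths numeric vector of depths, or a \code{depth_series}.
#' @param threshold depth threshold in Angstrom.
#' @param min_dwell minimum run length in frames (default 1 = no merging).
#' @param dt frame spacing in ns for dwell times (taken from a
#'   \code{depth_series}' time column when available).
#' @return list of class \code{state_segmentation}: \code{states}
#'   (character per frame), \code{threshold}, \code{n_excursions} (number
#'   of HOVER to BOUND transitions), \code{bound_fraction}, and
#'   \code{dwell_times} (ns, split by state).
#' @export
segment_states <- function(depths, threshold, min_dwell = 1L, dt = 1) {
  if (inherits(depths, "depth_series") || is.data.frame(depths)) {
    if (!is.null(depths$time) && nrow(depths) > 1L) {
      dt <- depths$time[2] - depths$time[1]
    }
    depths <- depths$depth
  }
  if (!length(depths)) stop("empty depth series")
  if (min_dwell < 1L) stop("min_dwell must be >= 1")
  states <- ifelse(depths < threshold, "BOUND", "HOVER")

  r <- rle(states)
  while (length(r$lengths) > 1L && any(r$lengths < min_dwell)) {
    i <- which(r$lengths < min_dwell)[1]
    r$values[i] <- if (i > 1L) r$values[i - 1L] else r$values[i + 1L]
    r <- rle(inverse.rle(r))
  }
  states <- inverse.rle(r)

  trans <- sum(r$values[-1] == "BOUND" & r$values[-length(r$values)] == "HOVER")
  dwell <- split(r$lengths * dt, r$values)
  structure(list(states = states, threshold = threshold,
                 n_excursions = trans,
                 bound_fraction = mean(states == "BOUND"),
                 dwell_times = dwell),
            class = "state_segmentation")
}

#' @export
print.state_segmentation <- function(x, ...) {
  cat("two-state segmentation (threshold", x$threshold, "A):",
      length(x$states), "frames\n")
  cat(sprintf("  bound fraction %.3f, %d excursion(s) (HOVER -> BOUND)\n",
              x$bound_fraction, x$n_excursions))
  invisible(x)
}
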