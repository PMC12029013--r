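#' Center-of-mass series of a selection
#'
#' Mass-weighted center of mass per frame, re-expressed relative to the
#' first frame. Requires unwrapped lateral coordinates (the
#' [load_trajectory()] default) for displacement-based analyses.
#'
#' @param traj a [trajectory()].
#' @param protein selection expression (default: the protein selection of
#'   the cached [selection_spec()]).
#' @return matrix \code{n_frames x 3} (Angstrom) with the trajectory's
#'   times as attribute \code{times}.
#' @export
com_series <- function(traj, protein = traj$selections$protein) {
  if (is.null(protein)) stop("no protein selection available")
  idx <- select_atoms(traj$atoms, protein)
  if (!length(idx)) stop("selection matches no atoms: ", protein)
  w <- traj$atoms$mass[idx]
  w <- w / sum(w)
  com <- t(vapply(seq_len(traj$n_frames), function(f) {
    colSums(matrix(traj$coords[idx, , f], ncol = 3L) * w)
  }, numeric(3)))
  com <- sweep(com, 2L, com[1L, ])
  attr(com, "times") <- traj$times
  com
}

#' Mean-square displacement over replicates
#'
#' Fixed-origin MSD: \code{msd(t) = mean over replicates of |r(t) - r(0)|^2}
#' using the lateral components (x, y) for \code{dims = 2} or all three
#' for \code{dims = 3}. No sliding-window time averaging is applied by
#' default, so the curve is the displacement from each replicate's initial
#' position; set \code{windowed = TRUE} to average over all time origins
#' at each lag instead.
#'
#' @param com_list a COM matrix from [com_series()] or a list of them (one
#'   per replicate). Replicates of unequal length are truncated to the
#'   shortest, with a warning.
#' @param dims 2 (lateral, x/y) or 3 (x/y/z).
#' @param times frame times in ns; defaults to the \code{times} attribute
#'   of the first replicate.
#' @param windowed average over multiple time origins (default
#'   \code{FALSE}).
#' @return list of class \code{msd_result}: \code{times}, \code{msd}
#'   (Angstrom^2), \code{per_replicate} (matrix, one column per
#'   replicate), \code{n_replicates}, \code{dims}.
#' @export
compute_msd <- function(com_list, dims = 2L, times = NULL,
                        windowed = FALSE) {
  if (is.matrix(com_list)) com_list <- list(com_list)
  if (!length(com_list)) stop("need at least one replicate")
  if (!dims %in% c(2L, 3L)) stop("dims must be 2 or 3")
  n <- vapply(com_list, nrow, integer(1))
  if (length(unique(n)) > 1L) {
    warning("replicates have unequal frame counts; truncating to ", min(n))
  }
  nf <- min(n)
  if (is.null(times)) times <- attr(com_list[[1]], "times")
  if (is.null(times)) times <- seq_len(nf) - 1
  times <- times[seq_len(nf)]
  per <- vapply(com_list, function(com) {
    com <- com[seq_len(nf), seq_len(dims), drop = FALSE]
    if (windowed) {
      vapply(seq_len(nf) - 1L, function(lag) {
        if (lag == 0L) return(0)
        d <- com[(1L + lag):nf, , drop = FALSE] -
             com[1L:(nf - lag), , drop = FALSE]
        mean(rowSums(d * d))
      }, numeric(1))
    } else {
      d <- sweep(com, 2L, com[1L, ])
      rowSums(d * d)
    }
  }, numeric(nf))
  per <- matrix(per, nrow = nf)
  structure(list(times = times - times[1L], msd = rowMeans(per),
                 per_replicate = per, n_replicates = length(com_list),
                 dims = as.integer(dims)),
            class = "msd_result")
}

#' Fickian fit of an MSD curve
#'
#' Ordinary least-squares fit of \code{msd = slope * t + intercept} over a
#' time range, interpreted through the Fickian relation
#' \code{<x^2> = 2 N D t}: the diffusion coefficient is
#' \code{D = slope / (2 N)} with \code{N} the dimensionality of the MSD
#' (2 for lateral, 3 for full). The intercept is left free so ballistic or
#' landing transients remain visible rather than biasing the slope. Both
#' the regression standard error of the slope and (when several replicates
#' are present) the spread of per-replicate fits are reported.
#'
#' @param msd an \code{msd_result} from [compute_msd()].
#' @param fit_range length-2 numeric, time window in ns (default: the full
#'   curve).
#' @return list of class \code{fickian_fit}: \code{slope},
#'   \code{slope_stderr} (Angstrom^2/ns), \code{intercept}, \code{N},
#'   \code{D}, \code{D_stderr} (Angstrom^2/ns), \code{fit_range},
#'   \code{per_replicate_D}, \code{D_replicate_sd}.
#' @export
fit_fickian <- function(msd, fit_range = NULL) {
  stopifnot(inherits(msd, "msd_result"))
  if (is.null(fit_range)) fit_range <- range(msd$times)
  keep <- msd$times >= fit_range[1] & msd$times <= fit_range[2]
  if (sum(keep) < 2L) stop("fewer than two MSD points in fit range")
  t <- msd$times[keep]
  if (diff(range(t)) == 0) stop("degenerate fit range")
  fit <- stats::lm(y ~ t, data = data.frame(t = t, y = msd$msd[keep]))
  # summary.lm warns on an exactly linear input; the zero stderr is correct
  co <- suppressWarnings(summary(fit)$coefficients)
  slope <- co["t", "Estimate"]
  se <- co["t", "Std. Error"]
  N <- msd$dims
  per_D <- apply(msd$per_replicate[keep, , drop = FALSE], 2L, function(y) {
    stats::coef(stats::lm(y ~ t))[["t"]] / (2 * N)
  })
  structure(list(slope = slope, slope_stderr = se,
                 intercept = co["(Intercept)", "Estimate"],
                 N = N, D = slope / (2 * N), D_stderr = se / (2 * N),
                 fit_range = fit_range,
                 per_replicate_D = per_D,
                 D_replicate_sd = if (length(per_D) > 1L) stats::sd(per_D) else NA_real_),
            class = "fickian_fit")
}

#' Diffusion coefficient from a printed MSD slope
#'
#' Direct application of \code{<x^2> = 2 N D t}: \code{D = slope / (2 N)}.
#' Useful for converting reported slopes (e.g. 3.69 Angstrom^2/ns in 3D
#' gives D = 0.615 Angstrom^2/ns; 3.19 in 2D gives 0.7975).
#'
#' @param slope MSD slope in Angstrom^2/ns.
#' @param dims dimensionality N (2 or 3).
#' @return D in Angstrom^2/ns.
#' @export
fickian_D <- function(slope, dims) {
  if (!dims %in% c(2, 3)) stop("dims must be 2 or 3")
  slope / (2 * dims)
}

#' @export
print.fickian_fit <- function(x, ...) {
  cat(sprintf("Fickian fit (N = %d): slope %.4g +/- %.2g A^2/ns, intercept %.4g A^2\n",
              x$N, x$slope, x$slope_stderr, x$intercept))
  cat(sprintf("  D = %.4g A^2/ns (stderr %.2g", x$D, x$D_stderr))
  if (!is.na(x$D_replicate_sd)) {
    cat(sprintf(", replicate sd %.2g", x$D_replicate_sd))
  }
  cat(")\n")
  invisible(x)
}

#' @export
print.msd_result <- function(x, ...) {
  cat("MSD:", length(x$times), "points,", x$n_replicates, "replicate(s),",
      x$dims, "dimensions\n")
  invisible(x)
}
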