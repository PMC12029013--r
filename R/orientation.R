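#' Best-fit heme plane of one frame
#'
#' Fits a plane to the porphyrin-ring heavy atoms by least squares: the
#' ring normal is the direction of least coordinate variance of the
#' centered atoms (smallest-eigenvalue eigenvector of the covariance),
#' with its sign chosen so the z component is non-negative. The in-plane
#' reference direction is the unit projection onto the plane of the vector
#' from the centroid to the first pyrrole nitrogen (ring nitrogens ordered
#' by atom name, e.g. NA < NB < NC < ND); if the ring selection carries no
#' nitrogen, the first ring atom anchors it instead.
#'
#' @param traj a [trajectory()].
#' @param heme_ring selection expression for the ring heavy atoms.
#' @param frame frame index.
#' @param degenerate_tol the basis is flagged degenerate when the angle
#'   between the normal and z is below this many degrees (the tilt
#'   co-normal is then undefined).
#' @return list of class \code{heme_basis}: \code{centroid},
#'   \code{normal}, \code{in_plane_ref} (unit 3-vectors), and
#'   \code{degenerate}.
#' @export
fit_heme_plane <- function(traj, heme_ring, frame = 1L,
                           degenerate_tol = 1e-4) {
  idx <- select_atoms(traj$atoms, heme_ring)
  idx <- idx[!traj$atoms$is_hydrogen[idx]]
  if (length(idx) < 3L) stop("heme-ring selection needs >= 3 heavy atoms")
  xyz <- traj$coords[idx, , frame, drop = TRUE]
  centroid <- colMeans(xyz)
  centered <- sweep(xyz, 2L, centroid)
  ev <- eigen(crossprod(centered), symmetric = TRUE)
  # eigenvalues descending: collinear atoms leave only one non-zero value
  if (ev$values[2] <= 1e-9 * max(ev$values[1], 1e-12)) {
    stop("heme-ring atoms are collinear; plane undefined")
  }
  normal <- ev$vectors[, 3L]
  if (normal[3] < 0) normal <- -normal
  if (normal[3] == 0 && normal[which(normal != 0)[1]] < 0) normal <- -normal

  nitro <- idx[traj$atoms$element[idx] == "N"]
  anchor <- if (length(nitro)) {
    nitro[order(traj$atoms$name[nitro])][1]
  } else idx[1]
  v <- traj$coords[anchor, , frame] - centroid
  v <- v - sum(v * normal) * normal
  in_plane <- unit(v)

  structure(list(centroid = centroid, normal = normal,
                 in_plane_ref = in_plane,
                 degenerate = rad2deg(safe_acos(abs(normal[3]))) < degenerate_tol),
            class = "heme_basis")
}

#' Tilt angles of a heme basis
#'
#' Computes the three tilt angles characterizing a heme-carrying protein's
#' orientation on a membrane whose normal is the z axis:
#' \describe{
#'   \item{phi_beta}{angle between the membrane normal (z) and the heme
#'     ring normal.}
#'   \item{phi_alpha}{angle between the membrane/heme co-normal and the x
#'     axis.}
#'   \item{phi_gamma}{angle between the co-normal and the in-plane
#'     reference vector of the ring.}
#' }
#' The co-normal is the normalized cross product of z with the ring normal
#' (the line of nodes of the corresponding Euler decomposition); it is
#' undefined when the ring normal is parallel to z, in which case the
#' sample is flagged degenerate and phi_alpha/phi_gamma are NA. All angles
#' are reported in degrees in [0, 180).
#'
#' @param basis a \code{heme_basis} from [fit_heme_plane()].
#' @return one-row data.frame: \code{phi_alpha}, \code{phi_beta},
#'   \code{phi_gamma}, \code{degenerate}.
#' @export
tilt_angles <- function(basis) {
  stopifnot(inherits(basis, "heme_basis"))
  zhat <- c(0, 0, 1)
  n <- basis$normal
  beta <- rad2deg(safe_acos(sum(zhat * n)))
  cn <- c(-n[2], n[1], 0)          # z x n
  s <- sqrt(sum(cn^2))             # = sin(beta)
  if (basis$degenerate || s < 1e-12) {
    return(data.frame(phi_alpha = NA_real_, phi_beta = beta %% 180,
                      phi_gamma = NA_real_, degenerate = TRUE))
  }
  cn <- cn / s
  alpha <- rad2deg(safe_acos(cn[1]))
  gamma <- rad2deg(safe_acos(sum(cn * basis$in_plane_ref)))
  data.frame(phi_alpha = alpha %% 180, phi_beta = beta %% 180,
             phi_gamma = gamma %% 180, degenerate = FALSE)
}

#' Orientation time series
#'
#' Fits the heme plane and evaluates the tilt angles for every frame.
#'
#' @param traj a [trajectory()] carrying a [selection_spec()], or
#'   \code{spec} given explicitly.
#' @param spec a [selection_spec()] with a \code{heme_ring} selection.
#' @return data.frame of class \code{orientation_series}: \code{frame},
#'   \code{time}, \code{phi_alpha}, \code{phi_beta}, \code{phi_gamma},
#'   \code{degenerate}.
#' @export
orientation_series <- function(traj, spec = traj$selections) {
  if (is.null(spec) || is.null(spec$heme_ring)) {
    stop("a selection_spec with a heme_ring selection is required")
  }
  rows <- lapply(seq_len(traj$n_frames), function(f) {
    tilt_angles(fit_heme_plane(traj, spec$heme_ring, f))
  })
  out <- do.call(rbind, rows)
  out <- cbind(frame = seq_len(traj$n_frames), time = traj$times, out)
  class(out) <- c("orientation_series", "data.frame")
  out
}

# Axial circular mean/sd (degrees, period 180): computed on doubled angles
# so that 10 and 170 degrees average to 0, not 90.
axial_mean <- function(theta_deg) {
  t2 <- deg2rad(theta_deg * 2)
  (rad2deg(atan2(mean(sin(t2)), mean(cos(t2)))) / 2) %% 180
}

axial_sd <- function(theta_deg) {
  t2 <- deg2rad(theta_deg * 2)
  R <- sqrt(mean(cos(t2))^2 + mean(sin(t2))^2)
  if (R >= 1) return(0)
  rad2deg(sqrt(-2 * log(R))) / 2
}

#' Circular summary of tilt-angle series
#'
#' Per angle, reports the axial circular mean and standard deviation
#' (computed on doubled angles, since a plane normal's sign is arbitrary
#' and the angles live on a 180-degree period) and the histogram mode.
#' Degenerate samples are dropped.
#'
#' @param series an \code{orientation_series} (or data.frame with
#'   \code{phi_alpha}, \code{phi_beta}, \code{phi_gamma}).
#' @param bin_width histogram bin width in degrees (default 2).
#' @return data.frame with one row per angle: \code{angle}, \code{mean},
#'   \code{sd}, \code{mode} (all degrees), \code{n}.
#' @export
orientation_summary <- function(series, bin_width = 2) {
  ok <- if (!is.null(series$degenerate)) !series$degenerate else
    rep(TRUE, nrow(series))
  if (sum(ok) < 2L) stop("need >= 2 non-degenerate orientation samples")
  breaks <- seq(0, 180, by = bin_width)
  if (breaks[length(breaks)] < 180) breaks <- c(breaks, 180)
  one <- function(theta) {
    theta <- theta[ok & !is.na(theta)]
    h <- hist(theta, breaks = breaks, plot = FALSE)
    data.frame(mean = axial_mean(theta), sd = axial_sd(theta),
               mode = h$mids[which.max(h$counts)], n = length(theta))
  }
  out <- do.call(rbind, lapply(
    c(phi_alpha = "phi_alpha", phi_beta = "phi_beta", phi_gamma = "phi_gamma"),
    function(col) one(series[[col]])))
  cbind(angle = rownames(out), out, row.names = NULL)
}
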