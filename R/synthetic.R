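#' Configuration for the synthetic trajectory generator
#'
#' The generator produces a kinematic mimic of a peripheral heme protein
#' skipping over an anionic bilayer leaflet: a static membrane of typed
#' head-group pseudo-lipids, a rigid protein whose basic face alternates
#' between a membrane-inserted (BOUND) and a surface-hovering (HOVER)
#' state under a two-state Markov chain with exponential dwell times,
#' lateral Brownian motion with state-dependent diffusion coefficients,
#' Gaussian depth fluctuations about state means, and axial wrapped-normal
#' tilt-angle fluctuations of the heme ring about prescribed means. There
#' are no forces or lipid dynamics: every generated observable has exact
#' ground truth.
#'
#' @param box unit-cell dimensions in Angstrom (default 110 x 110 x 120).
#' @param composition named lipid-type fractions summing to 1 (default
#'   14\% CDL, 30\% PE, 46\% PG, 10\% PC, the chromatophore composition).
#' @param n_lipids_per_leaflet lipids per leaflet (default 190, about
#'   64 Angstrom^2 per lipid in the default box).
#' @param dt frame spacing in ns (default 0.1).
#' @param n_frames frames per replicate (default 2000, i.e. 200 ns).
#' @param n_replicates number of independent replicates (default 10).
#' @param seed base RNG seed; replicate r uses \code{seed + r - 1}.
#' @param k_bind,k_unbind Markov rates in 1/ns for HOVER to BOUND and
#'   BOUND to HOVER transitions (defaults 0.25 and 0.05: 4 ns hovers,
#'   20 ns bound stretches, stationary bound fraction 5/6).
#' @param depth_bound_mean,depth_hover_mean mean insertion depth in each
#'   state, Angstrom (defaults -1 and +4, the two modes of a skipping
#'   protein).
#' @param depth_sigma Gaussian depth fluctuation, Angstrom (default 0.8).
#' @param D_bound_2d,D_hover_3d lateral diffusion coefficients in
#'   Angstrom^2/ns for the two states (defaults 0.798 and 0.615).
#' @param angle_means named mean tilt angles in degrees
#'   (phi_alpha = 77.5, phi_beta = 72.2, phi_gamma = 101.1 by default).
#' @param angle_kappa named concentrations of the axial wrapped-normal
#'   fluctuations; the Gaussian on the doubled angle has sd
#'   \code{1/sqrt(kappa)} radians. Defaults (alpha 12, beta 40, gamma 12)
#'   give a visibly tighter phi_beta spread.
#' @param cdl_enrichment factor >= 1 by which CDL placement is enriched
#'   inside a disc under the protein start position (default 1 = uniform).
#' @param enrichment_radius radius of that disc, Angstrom (default 32).
#' @param start_height initial protein center height above the bilayer
#'   midplane, Angstrom (default 40).
#' @param descent logical; reproduce the initial descent from
#'   \code{start_height} (default \code{TRUE}). When \code{FALSE} the
#'   protein starts at its state height (stationary statistics from frame
#'   1, useful for recovery studies).
#' @param descent_tau descent relaxation time in ns (default 12; the
#'   height excess decays as exp(-t/tau), placing arrival on the membrane
#'   around 40 ns).
#' @param uniform_headgroups if \code{TRUE}, every lipid type carries
#'   exactly one phosphorus particle and no nitrogen, so contact
#'   opportunity is exactly proportional to composition (a null membrane
#'   for affinity tests). Default \code{FALSE}: CDL carries two
#'   phosphates, PE/PC a head-group nitrogen.
#' @param membrane_half_thickness phosphate-plane height above the
#'   midplane, Angstrom (default 19).
#' @param carbonyl_offset carbonyl particles sit this far below the
#'   phosphates (towards the midplane), Angstrom (default 3).
#' @param headgroup_jitter sd of head-group position jitter, Angstrom
#'   (default 0.8).
#' @param n_face_residues basic face residues on the protein (default 15;
#'   calibrated so the bound phase shows a mean of about eight
#'   lipid-coordinating residues under the default membrane).
#' @param initial_state \code{"HOVER"} (default) or \code{"BOUND"}.
#' @return list of class \code{generator_config}.
#' @export
generator_config <- function(box = c(110, 110, 120),
                             composition = c(CDL = 0.14, PE = 0.30,
                                             PG = 0.46, PC = 0.10),
                             n_lipids_per_leaflet = 190L,
                             dt = 0.1, n_frames = 2000L, n_replicates = 10L,
                             seed = 1L,
                             k_bind = 0.25, k_unbind = 0.05,
                             depth_bound_mean = -1, depth_hover_mean = 4,
                             depth_sigma = 0.8,
                             D_bound_2d = 0.798, D_hover_3d = 0.615,
                             angle_means = c(phi_alpha = 77.5,
                                             phi_beta = 72.2,
                                             phi_gamma = 101.1),
                             angle_kappa = c(phi_alpha = 12,
                                             phi_beta = 40,
                                             phi_gamma = 12),
                             cdl_enrichment = 1,
                             enrichment_radius = 32,
                             start_height = 40,
                             descent = TRUE, descent_tau = 12,
                             uniform_headgroups = FALSE,
                             membrane_half_thickness = 19,
                             carbonyl_offset = 3,
                             headgroup_jitter = 0.8,
                             n_face_residues = 15L,
                             initial_state = c("HOVER", "BOUND")) {
  if (abs(sum(composition) - 1) > 1e-6) stop("composition must sum to 1")
  if (any(composition < 0)) stop("composition fractions must be >= 0")
  if (k_bind < 0 || k_unbind < 0) stop("Markov rates must be >= 0")
  if (cdl_enrichment < 1) stop("cdl_enrichment must be >= 1")
  if (n_lipids_per_leaflet < 4) stop("need at least 4 lipids per leaflet")
  if (dt <= 0 || n_frames < 1) stop("invalid time grid")
  structure(list(box = box, composition = composition,
                 n_lipids_per_leaflet = as.integer(n_lipids_per_leaflet),
                 dt = dt, n_frames = as.integer(n_frames),
                 n_replicates = as.integer(n_replicates),
                 seed = as.integer(seed),
                 k_bind = k_bind, k_unbind = k_unbind,
                 depth_bound_mean = depth_bound_mean,
                 depth_hover_mean = depth_hover_mean,
                 depth_sigma = depth_sigma,
                 D_bound_2d = D_bound_2d, D_hover_3d = D_hover_3d,
                 angle_means = angle_means, angle_kappa = angle_kappa,
                 cdl_enrichment = cdl_enrichment,
                 enrichment_radius = enrichment_radius,
                 start_height = start_height,
                 descent = descent, descent_tau = descent_tau,
                 uniform_headgroups = uniform_headgroups,
                 membrane_half_thickness = membrane_half_thickness,
                 carbonyl_offset = carbonyl_offset,
                 headgroup_jitter = headgroup_jitter,
                 n_face_residues = as.integer(n_face_residues),
                 initial_state = match.arg(initial_state)),
            class = "generator_config")
}

#' Selection spec matching generated systems
#'
#' Generated trajectories use segment \code{PROA} for the protein (with a
#' \code{HEM} pseudo-heme) and \code{MEMB} for the membrane, with
#' head-group phosphorus atoms \code{P1}/\code{P2}, nitrogens \code{N1}
#' and carbonyl particles \code{C1}/\code{C2}.
#'
#' @return a [selection_spec()].
#' @export
synthetic_selections <- function() {
  selection_spec(
    protein = "segid PROA",
    heme_ring = "segid PROA and resname HEM and name NA NB NC ND",
    headgroup_P = "segid MEMB and name P1 P2",
    headgroup_N = "segid MEMB and name N1",
    carbonyl = "segid MEMB and name C1 C2",
    lipid_type_map = c(CDL = "CDL", PE = "PE", PG = "PG", PC = "PC"),
    binding_leaflet = "upper")
}

#' Generate a static membrane fragment
#'
#' Places typed head-group pseudo-lipids on a jittered lattice in both
#' leaflets. Type counts follow the composition by largest-remainder
#' rounding; CDL placement inside a disc of radius
#' \code{enrichment_radius} under the protein start (the box center) is
#' weighted by \code{cdl_enrichment} in the binding leaflet. Uses the
#' current RNG state.
#'
#' @param config a [generator_config()].
#' @return list: \code{atoms} (atom table rows), \code{coords}
#'   (matrix n x 3), \code{lipids} (data.frame with per-lipid resid, type,
#'   leaflet, site position, in_disc flag).
#' @export
generate_membrane <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  n <- config$n_lipids_per_leaflet
  comp <- config$composition
  box <- config$box
  half <- config$membrane_half_thickness
  jit <- config$headgroup_jitter
  center <- box[1:2] / 2

  nx <- ceiling(sqrt(n)); ny <- ceiling(n / nx)
  sx <- box[1] / nx; sy <- box[2] / ny
  grid <- expand.grid(ix = seq_len(nx) - 0.5, iy = seq_len(ny) - 0.5)
  sites <- cbind(grid$ix * sx, grid$iy * sy)[seq_len(n), , drop = FALSE]

  lipid_rows <- list(); atom_rows <- list(); coord_rows <- list()
  resid0 <- 1000L
  lip_i <- 0L
  for (leaflet in c("upper", "lower")) {
    zsign <- if (leaflet == "upper") 1 else -1
    xy <- sites + matrix(stats::rnorm(2 * n, 0, jit), n, 2)
    counts <- largest_remainder(comp, n)
    in_disc <- sqrt(rowSums(sweep(sites, 2L, center)^2)) <=
      config$enrichment_radius
    types <- rep(NA_character_, n)
    # weighted CDL placement (binding = upper leaflet only), then the
    # remaining types shuffled over the remaining sites
    w <- rep(1, n)
    if (leaflet == "upper" && config$cdl_enrichment > 1) {
      w[in_disc] <- config$cdl_enrichment
    }
    if (!is.na(counts["CDL"]) && counts["CDL"] > 0) {
      cdl_sites <- sample.int(n, counts["CDL"], prob = w)
      types[cdl_sites] <- "CDL"
    }
    rest <- sample(rep(names(counts)[names(counts) != "CDL"],
                       counts[names(counts) != "CDL"]))
    types[is.na(types)] <- rest
    for (i in seq_len(n)) {
      lip_i <- lip_i + 1L
      rid <- resid0 + lip_i
      typ <- types[i]
      zP <- zsign * (half + stats::rnorm(1, 0, jit))
      at <- list(c("P1", "P", xy[i, 1], xy[i, 2], zP))
      if (!config$uniform_headgroups) {
        if (typ == "CDL") {
          ang <- stats::runif(1, 0, 2 * pi)
          zP2 <- zsign * (half + stats::rnorm(1, 0, jit))
          at <- c(at, list(c("P2", "P", xy[i, 1] + 3 * cos(ang),
                             xy[i, 2] + 3 * sin(ang), zP2)))
        }
        if (typ %in% c("PE", "PC")) {
          ang <- stats::runif(1, 0, 2 * pi)
          at <- c(at, list(c("N1", "N", xy[i, 1] + 1.5 * cos(ang),
                             xy[i, 2] + 1.5 * sin(ang),
                             zP + zsign * 0.7)))
        }
      }
      # one carbonyl particle per phosphate, towards the midplane
      nP <- sum(vapply(at, function(x) x[2] == "P", logical(1)))
      for (p in seq_len(nP)) {
        px <- as.numeric(at[[p]][3]); py <- as.numeric(at[[p]][4])
        pz <- as.numeric(at[[p]][5])
        at <- c(at, list(c(paste0("C", p), "C", px, py,
                           pz - zsign * config$carbonyl_offset)))
      }
      for (x in at) {
        atom_rows[[length(atom_rows) + 1L]] <-
          data.frame(name = x[1], resname = typ, resid = rid,
                     segid = "MEMB", element = x[2],
                     stringsAsFactors = FALSE)
        coord_rows[[length(coord_rows) + 1L]] <- as.numeric(x[3:5])
      }
      lipid_rows[[lip_i]] <- data.frame(
        resid = rid, type = typ, leaflet = leaflet,
        x = xy[i, 1], y = xy[i, 2], in_disc = in_disc[i])
    }
  }
  atoms <- do.call(rbind, atom_rows)
  list(atoms = atoms, coords = do.call(rbind, coord_rows),
       lipids = do.call(rbind, lipid_rows))
}

# Rigid protein template in the body frame. The origin is the plane of the
# face-residue side-chain centers of mass, so translating the body to
# z = plane_z + depth realizes that insertion depth exactly. Face residues
# are lysine-like: CA (backbone) plus a splayed side chain (CB, CD, NZ)
# whose mass-weighted z is zero by construction; the NZ ring is the lowest
# part of the protein.
.protein_template <- function(n_face) {
  rows <- list(); xyz <- list()
  z_nz <- -(12.011 * 1.0 + 12.011 * 0.0) / 14.007  # side-chain COM z = 0
  for (i in seq_len(n_face)) {
    th <- 2 * pi * (i - 1) / n_face
    add <- function(nm, el, r, z) {
      rows[[length(rows) + 1L]] <<- data.frame(
        name = nm, resname = "LYS", resid = i, segid = "PROA",
        element = el, stringsAsFactors = FALSE)
      xyz[[length(xyz) + 1L]] <<- c(r * cos(th), r * sin(th), z)
    }
    add("CA", "C", 3.5, 3.0)
    add("CB", "C", 2.5, 1.0)
    add("CD", "C", 4.3, 0.0)
    add("NZ", "N", 5.8, z_nz)
  }
  hem <- n_face + 1L
  rows[[length(rows) + 1L]] <- data.frame(
    name = "FE", resname = "HEM", resid = hem, segid = "PROA",
    element = "FE", stringsAsFactors = FALSE)
  xyz[[length(xyz) + 1L]] <- c(0, 0, 7)  # heme centroid; ring set per frame
  for (nm in c("NA", "NB", "NC", "ND")) {
    rows[[length(rows) + 1L]] <- data.frame(
      name = nm, resname = "HEM", resid = hem, segid = "PROA",
      element = "N", stringsAsFactors = FALSE)
    xyz[[length(xyz) + 1L]] <- c(0, 0, 7)
  }
  list(atoms = do.call(rbind, rows), coords = do.call(rbind, xyz),
       heme_centroid = c(0, 0, 7), heme_radius = 2.0)
}

# Per-replicate RNG seed: drawn from the base-seeded generator so that
# nearby base seeds give disjoint replicate streams (a plain seed + r - 1
# scheme would make base seeds s and s + 1 share all but one replicate).
# Seeds within one family are drawn without replacement, hence distinct.
.replicate_seed <- function(seed, replicate) {
  set.seed(seed)
  sample.int(2147483646L, replicate)[replicate]
}

# Two-state continuous-time Markov chain sampled on the frame grid.
# Exponential dwells with the given rates; a zero rate makes the state
# absorbing. Returns a character vector of length n_frames.
.markov_states <- function(n_frames, dt, k_bind, k_unbind, initial) {
  states <- character(n_frames)
  state <- initial
  t_now <- 0
  t_end <- n_frames * dt
  f <- 1L
  while (f <= n_frames) {
    rate <- if (state == "HOVER") k_bind else k_unbind
    dwell <- if (rate > 0) stats::rexp(1, rate) else Inf
    t_next <- t_now + dwell
    f_hi <- if (is.finite(t_next)) min(n_frames, floor(t_next / dt)) else n_frames
    if (f_hi >= f) states[f:f_hi] <- state
    f <- f_hi + 1L
    t_now <- t_next
    state <- if (state == "HOVER") "BOUND" else "HOVER"
    if (t_now >= t_end) break
  }
  if (f <= n_frames) states[f:n_frames] <- state
  states
}

#' Generate one synthetic replicate with ground truth
#'
#' Builds a membrane, runs the two-state Markov chain, integrates the
#' lateral Brownian path, realizes per-frame depths and heme orientations,
#' and assembles a [trajectory()] (with [synthetic_selections()] attached)
#' plus an exact ground-truth record. Coordinates are kept unwrapped (the
#' lateral path is continuous); use \code{wrap = TRUE} in
#' [write_trajectory()] to emit box-wrapped files as a simulation engine
#' would, which [load_trajectory()] unwraps again.
#'
#' @param config a [generator_config()].
#' @param replicate replicate number; the RNG is seeded with a fixed
#'   mixing function of \code{config$seed} and \code{replicate}, so
#'   identical config and seed give bit-identical output while nearby
#'   base seeds still yield disjoint replicate streams.
#' @return list with elements \code{trajectory} and \code{truth} (list:
#'   per-frame \code{state}, \code{depth}, \code{angles}, \code{com};
#'   scalars \code{plane_z}, \code{carbonyl_z}, expected
#'   \code{bound_fraction}, the generating parameters and \code{seed}).
#' @export
generate_trajectory <- function(config, replicate = 1L) {
  stopifnot(inherits(config, "generator_config"))
  seed <- .replicate_seed(config$seed, as.integer(replicate))
  set.seed(seed)
  nf <- config$n_frames
  dt <- config$dt
  times <- dt * (seq_len(nf) - 1)

  mem <- generate_membrane(config)
  upper_P <- mem$atoms$element == "P" & mem$coords[, 3] > 0
  plane_z <- mean(mem$coords[upper_P, 3])
  upper_C <- mem$atoms$element == "C" & mem$coords[, 3] > 0
  carbonyl_z <- mean(mem$coords[upper_C, 3])

  states <- .markov_states(nf, dt, config$k_bind, config$k_unbind,
                           config$initial_state)
  depth_mean <- ifelse(states == "BOUND", config$depth_bound_mean,
                       config$depth_hover_mean)
  depth <- depth_mean + stats::rnorm(nf, 0, config$depth_sigma)

  extra <- rep(0, nf)
  if (config$descent) {
    e0 <- config$start_height - (plane_z + config$depth_hover_mean)
    if (e0 > 0) {
      extra <- e0 * exp(-times / config$descent_tau)
      force_hover <- extra > 1
      states[force_hover] <- "HOVER"
      depth[force_hover] <- config$depth_hover_mean +
        stats::rnorm(sum(force_hover), 0, config$depth_sigma)
    }
  }

  D <- ifelse(states == "BOUND", config$D_bound_2d, config$D_hover_3d)
  step_sd <- sqrt(2 * D * dt)
  inc <- matrix(stats::rnorm(2 * nf, 0, 1), nf, 2) * c(0, step_sd[-nf])
  com_xy <- matrix(apply(inc, 2L, cumsum), nf, 2)
  com_xy <- sweep(com_xy, 2L, config$box[1:2] / 2, "+")

  ang_sd <- rad2deg(1 / sqrt(config$angle_kappa)) / 2
  ang <- vapply(c("phi_alpha", "phi_beta", "phi_gamma"), function(k) {
    (config$angle_means[[k]] + stats::rnorm(nf, 0, ang_sd[[k]])) %% 180
  }, numeric(nf))
  ang <- matrix(ang, nf, 3, dimnames = list(NULL, c("phi_alpha", "phi_beta",
                                                    "phi_gamma")))

  tmpl <- .protein_template(config$n_face_residues)
  atoms_all <- rbind(tmpl$atoms, mem$atoms)
  n_prot <- nrow(tmpl$atoms)
  n_total <- nrow(atoms_all)
  ring_rows <- (n_prot - 3L):n_prot            # NA NB NC ND (after FE)

  coords <- array(NA_real_, c(n_total, 3L, nf))
  body_z <- plane_z + depth + extra
  shift <- cbind(com_xy, body_z)
  for (k in 1:3) {
    coords[seq_len(n_prot), k, ] <- outer(tmpl$coords[, k], shift[, k], "+")
    coords[n_prot + seq_len(nrow(mem$coords)), k, ] <- mem$coords[, k]
  }
  # heme ring orientation, vectorized over frames (same construction as
  # .heme_ring_coords)
  a <- deg2rad(ang[, 1]); b <- deg2rad(ang[, 2]); g <- deg2rad(ang[, 3])
  cn <- cbind(cos(a), sin(a), 0)
  u <- cbind(cn[, 2], -cn[, 1], 0)
  nrm <- cbind(sin(b) * u[, 1], sin(b) * u[, 2], cos(b))
  vcross <- function(p, q) cbind(p[, 2] * q[, 3] - p[, 3] * q[, 2],
                                 p[, 3] * q[, 1] - p[, 1] * q[, 3],
                                 p[, 1] * q[, 2] - p[, 2] * q[, 1])
  e1 <- cos(g) * cn + sin(g) * vcross(nrm, cn)
  e2 <- vcross(nrm, e1)
  centroid <- shift + matrix(tmpl$heme_centroid, nf, 3L, byrow = TRUE)
  phase <- deg2rad(c(0, 90, 180, 270))
  for (j in 1:4) {
    ringj <- centroid + tmpl$heme_radius *
      (cos(phase[j]) * e1 + sin(phase[j]) * e2)
    for (k in 1:3) coords[ring_rows[j], k, ] <- ringj[, k]
  }

  atoms <- data.frame(index = seq_len(n_total), atoms_all,
                      is_hydrogen = FALSE,
                      mass = element_mass(atoms_all$element),
                      stringsAsFactors = FALSE)
  traj <- trajectory(atoms, coords, box = config$box, times = times,
                     selections = synthetic_selections())

  disc <- mem$lipids[mem$lipids$leaflet == "upper", ]
  truth <- list(
    seed = seed, dt = dt, n_frames = nf,
    state = states, depth = depth + extra, times = times,
    com = cbind(x = com_xy[, 1], y = com_xy[, 2], z = body_z),
    angles = ang,
    plane_z = plane_z, carbonyl_z = carbonyl_z,
    D_bound_2d = config$D_bound_2d, D_hover_3d = config$D_hover_3d,
    depth_bound_mean = config$depth_bound_mean,
    depth_hover_mean = config$depth_hover_mean,
    angle_means = as.list(config$angle_means),
    composition = as.list(config$composition),
    cdl_enrichment = config$cdl_enrichment,
    disc_cdl_fraction = mean(disc$type[disc$in_disc] == "CDL"),
    bound_fraction_expected =
      if (config$k_bind + config$k_unbind > 0)
        config$k_bind / (config$k_bind + config$k_unbind) else NA_real_)
  list(trajectory = traj, truth = truth)
}

#' Generate all replicates of a configuration
#'
#' @param config a [generator_config()].
#' @return list of length \code{config$n_replicates}, each an output of
#'   [generate_trajectory()].
#' @export
generate_replicates <- function(config) {
  lapply(seq_len(config$n_replicates), function(r) {
    generate_trajectory(config, replicate = r)
  })
}

#' Write a synthetic data set to disk
#'
#' Emits one multi-MODEL PDB per replicate, a JSON ground-truth sidecar,
#' and a JSON copy of the matching selection spec.
#'
#' @param config a [generator_config()].
#' @param out_dir output directory (created if needed).
#' @return named list of written paths (\code{trajectories},
#'   \code{ground_truth}, \code{selections}), invisibly.
#' @export
emit_synthetic <- function(config, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(config$n_replicates)
  truths <- vector("list", config$n_replicates)
  for (r in seq_len(config$n_replicates)) {
    g <- generate_trajectory(config, replicate = r)
    paths[r] <- file.path(out_dir, sprintf("replicate_%02d.pdb", r))
    write_trajectory(g$trajectory, paths[r])
    truths[[r]] <- g$truth
  }
  gt_path <- file.path(out_dir, "ground_truth.json")
  jsonlite::write_json(truths, gt_path, auto_unbox = TRUE, digits = NA)
  sel_path <- file.path(out_dir, "selections.json")
  sel <- unclass(synthetic_selections())
  sel$lipid_type_map <- as.list(sel$lipid_type_map)  # keep names in JSON
  jsonlite::write_json(sel, sel_path, auto_unbox = TRUE)
  invisible(list(trajectories = paths, ground_truth = gt_path,
                 selections = sel_path))
}
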