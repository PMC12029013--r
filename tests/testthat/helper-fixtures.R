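# Fixtures are built in code: small atom tables and trajectories, plus
# brute-force oracles kept deliberately independent of the package's
# implementation paths.

# Build an atom table from parallel vectors; elements inferred from names
# unless given.
toy_atoms <- function(name, resname, resid, segid = "A", element = NULL) {
  n <- length(name)
  if (is.null(element)) {
    element <- toupper(substr(sub("^[0-9]+", "", name), 1, 1))
    element[name == "FE"] <- "FE"
  }
  data.frame(index = seq_len(n), name = name, resname = resname,
             resid = resid, segid = rep_len(segid, n),
             element = element,
             is_hydrogen = element == "H",
             mass = peritraj:::element_mass(element),
             stringsAsFactors = FALSE)
}

# Trajectory from an atom table and one coordinate matrix per frame.
toy_traj <- function(atoms, ..., box = NULL, dt = 1) {
  frames <- list(...)
  coords <- array(NA_real_, c(nrow(atoms), 3L, length(frames)))
  for (f in seq_along(frames)) coords[, , f] <- frames[[f]]
  trajectory(atoms, coords, box = box, dt = dt)
}

# O(n^2) brute-force contact oracle: double loop over every protein/head
# atom pair with explicit minimum-image distances; no neighbor search.
brute_force_contacts <- function(traj, spec, cutoff, carbonyl_z = NULL) {
  a <- traj$atoms
  pidx <- select_atoms(a, spec$protein)
  pidx <- pidx[!a$is_hydrogen[pidx]]
  hidx <- c(select_atoms(a, spec$headgroup_P),
            if (!is.null(spec$headgroup_N)) select_atoms(a, spec$headgroup_N))
  p_only <- select_atoms(a, spec$headgroup_P)
  mi_dist <- function(p, q, box) {
    d <- p - q
    if (!is.null(box)) d <- d - box * round(d / box)
    sqrt(sum(d^2))
  }
  rows <- list()
  for (f in seq_len(traj$n_frames)) {
    for (i in pidx) {
      for (j in hidx) {
        dij <- mi_dist(traj$coords[i, , f], traj$coords[j, , f], traj$box)
        if (dij <= cutoff) {
          rows[[length(rows) + 1L]] <- data.frame(
            frame = f, resid = a$resid[i], lipid_resid = a$resid[j],
            lipid_type = peritraj:::lipid_type_of(a$resname[j],
                                                  spec$lipid_type_map),
            mode = "COORDINATION", stringsAsFactors = FALSE)
        }
      }
    }
    if (!is.null(carbonyl_z)) {
      below <- pidx[traj$coords[pidx, 3L, f] < carbonyl_z]
      for (rid in unique(a$resid[below])) {
        batoms <- below[a$resid[below] == rid]
        deepest <- batoms[which.min(traj$coords[batoms, 3L, f])]
        dists <- vapply(p_only, function(j) {
          mi_dist(traj$coords[deepest, , f], traj$coords[j, , f], traj$box)
        }, numeric(1))
        j <- p_only[which.min(dists)]
        rows[[length(rows) + 1L]] <- data.frame(
          frame = f, resid = rid, lipid_resid = a$resid[j],
          lipid_type = peritraj:::lipid_type_of(a$resname[j],
                                                spec$lipid_type_map),
          mode = "INSERTION", stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) return(out)
  unique(out[order(out$frame, out$resid, out$lipid_resid, out$mode), ])
}

# Canonical sort of contact records for set comparison.
sorted_records <- function(rec) {
  rec <- as.data.frame(rec)[c("frame", "resid", "lipid_resid",
                              "lipid_type", "mode")]
  out <- rec[order(rec$frame, rec$resid, rec$lipid_resid, rec$mode), ]
  rownames(out) <- NULL
  out
}

# Rotation-matrix oracle for tilt angles: the reference heme is a square
# in the xy-plane (normal = z, first nitrogen towards (1,1,0)); applying a
# rotation R, the expected angles follow directly from the rotated axes.
rotation_oracle_angles <- function(R) {
  zhat <- c(0, 0, 1); xhat <- c(1, 0, 0)
  n <- as.numeric(R %*% zhat)
  ref <- as.numeric(R %*% (c(1, 1, 0) / sqrt(2)))
  if (n[3] < 0) n <- -n
  beta <- acos(max(-1, min(1, sum(n * zhat)))) * 180 / pi
  cn <- c(-n[2], n[1], 0)
  s <- sqrt(sum(cn^2))
  if (s < 1e-12) return(list(beta = beta %% 180, alpha = NA, gamma = NA))
  cn <- cn / s
  # the fitted in-plane reference is the projection of ref onto the plane
  ref <- ref - sum(ref * n) * n
  ref <- ref / sqrt(sum(ref^2))
  list(beta = beta %% 180,
       alpha = (acos(max(-1, min(1, sum(cn * xhat)))) * 180 / pi) %% 180,
       gamma = (acos(max(-1, min(1, sum(cn * ref)))) * 180 / pi) %% 180)
}

# Random rotation matrix (uniform via QR of Gaussian matrix, det +1).
random_rotation <- function() {
  qr_ <- qr(matrix(rnorm(9), 3))
  Q <- qr.Q(qr_)
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}

# Trajectory holding the reference heme square rotated by R: atoms named
# NA..ND so the plane fit anchors its reference on the first nitrogen.
heme_traj <- function(R, centroid = c(0, 0, 0)) {
  sq <- rbind(c(1, 1, 0), c(-1, 1, 0), c(-1, -1, 0), c(1, -1, 0))
  atoms <- toy_atoms(c("NA", "NB", "NC", "ND"), "HEM", 1L, "PROA",
                     element = rep("N", 4))
  toy_traj(atoms, sweep(sq %*% t(R), 2, centroid, "+"))
}
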