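#' Contact classification criteria
#'
#' @param cutoff coordination distance cutoff in Angstrom (default 2.5): a
#'   protein residue coordinates a lipid when at least one qualifying atom
#'   lies within this distance of a head-group phosphorus or nitrogen atom
#'   of that lipid.
#' @param heavy_atoms_only restrict protein atoms to heavy atoms (default
#'   \code{TRUE}); lipid head-group P/N atoms are heavy by definition.
#' @return list of class \code{contact_criteria}.
#' @export
contact_criteria <- function(cutoff = 2.5, heavy_atoms_only = TRUE) {
  if (cutoff <= 0) stop("cutoff must be positive")
  structure(list(cutoff = cutoff, heavy_atoms_only = heavy_atoms_only),
            class = "contact_criteria")
}

# Cell-list neighbor search: returns a two-column matrix (i, j) of pairs
# with minimum-image distance <= cutoff between rows of `a` (n_a x 3) and
# rows of `b` (n_b x 3) under an orthorhombic box (NULL = no periodicity).
# Cells are at least cutoff-sized; atoms in one a-cell are tested only
# against b-atoms in the 27 neighboring cells, looked up by binary search
# over sorted integer cell keys.
neighbor_pairs <- function(a, b, cutoff, box = NULL) {
  na_ <- nrow(a); nb <- nrow(b)
  if (!na_ || !nb) return(cbind(i = integer(), j = integer()))
  if (is.null(box)) {
    origin <- pmin(apply(a, 2, min), apply(b, 2, min))
    span <- pmax(apply(a, 2, max), apply(b, 2, max)) - origin + cutoff
    wrap <- FALSE
  } else {
    origin <- c(0, 0, 0); span <- box; wrap <- TRUE
  }
  nc <- pmax(1L, floor(span / cutoff))
  cell_of <- function(x) {
    idx <- sweep(x, 2L, origin)
    if (wrap) idx <- idx %% matrix(box, nrow(x), 3L, byrow = TRUE)
    ci <- floor(sweep(idx, 2L, span / nc, "/"))
    pmin(pmax(ci, 0L), matrix(nc - 1L, nrow(x), 3L, byrow = TRUE))
  }
  key_of <- function(ci) ci[, 1L] + nc[1L] * (ci[, 2L] + nc[2L] * ci[, 3L])

  bkey <- key_of(cell_of(b))
  bord <- order(bkey)
  bkey_sorted <- bkey[bord]
  ca <- cell_of(a)
  akey <- key_of(ca)
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  cut2 <- cutoff^2
  out_i <- list(); out_j <- list(); nout <- 0L
  for (grp in split(seq_len(na_), akey)) {
    neigh <- sweep(offs, 2L, ca[grp[1L], ], "+")
    if (wrap) {
      neigh <- neigh %% matrix(nc, nrow(neigh), 3L, byrow = TRUE)
    } else {
      ok <- neigh[, 1L] >= 0 & neigh[, 1L] < nc[1L] &
            neigh[, 2L] >= 0 & neigh[, 2L] < nc[2L] &
            neigh[, 3L] >= 0 & neigh[, 3L] < nc[3L]
      neigh <- neigh[ok, , drop = FALSE]
    }
    keys <- unique(key_of(neigh))
    lo <- findInterval(keys - 0.5, bkey_sorted)
    hi <- findInterval(keys + 0.5, bkey_sorted)
    run <- hi - lo
    cand <- bord[sequence(run[run > 0L], from = lo[run > 0L] + 1L)]
    if (!length(cand)) next
    d2 <- 0
    for (k in 1:3) {
      dk <- outer(b[cand, k], a[grp, k], "-")
      if (!is.null(box)) dk <- dk - box[k] * round(dk / box[k])
      d2 <- d2 + dk * dk
    }
    hit <- which(d2 <= cut2, arr.ind = TRUE)
    if (nrow(hit)) {
      nout <- nout + 1L
      out_i[[nout]] <- grp[hit[, 2L]]
      out_j[[nout]] <- cand[hit[, 1L]]
    }
  }
  cbind(i = unlist(out_i, use.names = FALSE) %||% integer(),
        j = unlist(out_j, use.names = FALSE) %||% integer())
}

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Classify protein-lipid contacts
#'
#' Produces one record per (frame, protein residue, lipid molecule, mode):
#' \describe{
#'   \item{COORDINATION}{some qualifying protein atom of the residue lies
#'     within \code{cutoff} of a head-group phosphorus or nitrogen atom of
#'     the lipid. Either phosphate of a cardiolipin can trigger the
#'     contact, but the lipid still counts as one molecule.}
#'   \item{INSERTION}{some qualifying protein atom of the residue lies
#'     below the carbonyl plane of the binding leaflet (hydrophobic
#'     insertion); the record is attributed to the lipid whose head-group
#'     phosphorus is nearest to the deepest such atom.}
#' }
#' All distances are minimum-image under the trajectory's periodic box.
#'
#' @param traj a [trajectory()].
#' @param spec a [selection_spec()]; defaults to the one cached on
#'   \code{traj}.
#' @param criteria a [contact_criteria()].
#' @param carbonyl_z carbonyl-plane z per frame (Angstrom); computed from
#'   \code{spec$carbonyl} when \code{NULL}. Set \code{insertion = FALSE}
#'   to skip insertion analysis when no carbonyl plane exists.
#' @param frames frame indices (default all).
#' @param insertion logical; also classify hydrophobic insertions
#'   (default \code{TRUE}).
#' @return data.frame of class \code{contact_records}: \code{frame},
#'   \code{resid}, \code{lipid_resid}, \code{lipid_type}, \code{mode},
#'   with attribute \code{n_frames}.
#' @export
classify_contacts <- function(traj, spec = traj$selections,
                              criteria = contact_criteria(),
                              carbonyl_z = NULL, frames = NULL,
                              insertion = TRUE) {
  if (is.null(spec)) stop("no selection_spec available")
  sel <- if (!is.null(traj$sel_idx) && identical(spec, traj$selections)) {
    traj$sel_idx
  } else {
    resolve_selections(traj$atoms, spec)
  }
  a <- traj$atoms
  pidx <- sel$protein
  if (criteria$heavy_atoms_only) pidx <- pidx[!a$is_hydrogen[pidx]]
  if (!length(pidx)) stop("protein selection contains no qualifying atoms")
  hidx <- c(sel$headgroup_P, sel$headgroup_N)
  if (!length(hidx)) stop("no head-group atoms selected")
  if (is.null(frames)) frames <- seq_len(traj$n_frames)
  if (insertion) {
    if (is.null(carbonyl_z)) {
      if (is.null(spec$carbonyl)) {
        stop("insertion analysis requested but spec has no carbonyl selection")
      }
      carbonyl_z <- leaflet_plane_z(traj, spec$carbonyl, spec$binding_leaflet,
                                    frames = frames)
    }
    carbonyl_z <- rep_len(carbonyl_z, length(frames))
  }

  lipid_key <- paste(a$segid, a$resid)
  head_lipid <- lipid_key[hidx]
  head_resid <- a$resid[hidx]
  head_type <- lipid_type_of(a$resname[hidx], spec$lipid_type_map)
  pid <- a$resid[pidx]
  p_only <- sel$headgroup_P
  p_lipid_resid <- a$resid[p_only]
  p_lipid_type <- lipid_type_of(a$resname[p_only], spec$lipid_type_map)

  acc <- list(frame = list(), resid = list(), lipid = list(),
              type = list(), mode = list())
  n_acc <- 0L
  push <- function(f, resid, lipid, type, mode) {
    n_acc <<- n_acc + 1L
    acc$frame[[n_acc]] <<- rep.int(f, length(resid))
    acc$resid[[n_acc]] <<- resid
    acc$lipid[[n_acc]] <<- lipid
    acc$type[[n_acc]] <<- type
    acc$mode[[n_acc]] <<- rep.int(mode, length(resid))
  }
  for (k in seq_along(frames)) {
    f <- frames[k]
    pc <- matrix(traj$coords[pidx, , f], ncol = 3L)
    hc <- matrix(traj$coords[hidx, , f], ncol = 3L)
    pairs <- neighbor_pairs(pc, hc, criteria$cutoff, traj$box)
    if (nrow(pairs)) {
      ri <- pid[pairs[, "i"]]
      li <- head_resid[pairs[, "j"]]
      keep <- !duplicated(ri * 1e7 + li)  # one record per (residue, lipid)
      push(f, ri[keep], li[keep], head_type[pairs[, "j"]][keep],
           "COORDINATION")
    }
    if (insertion) {
      below <- which(pc[, 3L] < carbonyl_z[k])
      if (length(below)) {
        pcoords <- matrix(traj$coords[p_only, , f], ncol = 3L)
        for (rid in unique(pid[below])) {
          batoms <- below[pid[below] == rid]
          deepest <- batoms[which.min(pc[batoms, 3L])]
          d <- min_image(sweep(pcoords, 2L, pc[deepest, ]), traj$box)
          nearest <- which.min(rowSums(d * d))
          push(f, rid, p_lipid_resid[nearest], p_lipid_type[nearest],
               "INSERTION")
        }
      }
    }
  }
  out <- data.frame(
    frame = unlist(acc$frame) %||% integer(),
    resid = unlist(acc$resid) %||% integer(),
    lipid_resid = unlist(acc$lipid) %||% integer(),
    lipid_type = unlist(acc$type) %||% character(),
    mode = unlist(acc$mode) %||% character(),
    stringsAsFactors = FALSE)
  structure(out, n_frames = length(frames),
            class = c("contact_records", "data.frame"))
}

#' Per-residue interaction frequency
#'
#' For each protein residue, the fraction of frames in which it has at
#' least one contact record of either mode, and its share of the total
#' number of records.
#'
#' @param records \code{contact_records} from [classify_contacts()].
#' @param n_frames total number of analyzed frames (defaults to the
#'   attribute carried by \code{records}).
#' @param resids optional integer vector of residues to report (residues
#'   without records get frequency 0); defaults to residues present in
#'   \code{records}.
#' @return data.frame: \code{resid}, \code{frequency}, \code{record_share}.
#' @export
residue_interaction_frequency <- function(records,
                                          n_frames = attr(records, "n_frames"),
                                          resids = NULL) {
  if (is.null(n_frames) || n_frames < 1) stop("n_frames must be >= 1")
  if (is.null(resids)) resids <- sort(unique(records$resid))
  n_rec <- nrow(records)
  freq <- vapply(resids, function(r) {
    length(unique(records$frame[records$resid == r])) / n_frames
  }, numeric(1))
  share <- vapply(resids, function(r) {
    if (n_rec == 0) 0 else sum(records$resid == r) / n_rec
  }, numeric(1))
  data.frame(resid = resids, frequency = freq, record_share = share)
}

#' Fractional contribution of each lipid type
#'
#' Frame-based attribution (default): a lipid type contributes in a frame
#' when any lipid of that type contacts any protein residue; the raw
#' fraction is (frames with that type) / (frames with any contact), then
#' fractions are renormalized to sum to 1 across types, since several
#' types can co-occur in one frame. Two alternative attributions are
#' available: \code{"record"} uses each type's share of all contact
#' records (contact opportunity weighted by residence time and by the
#' number of coordinating residues), and \code{"molecule"} uses each
#' type's share of the distinct lipid molecules ever contacted (the
#' fraction of protein-bound lipids), which counts every bound lipid once
#' regardless of how long or by how many residues it was held.
#'
#' @param records \code{contact_records} from [classify_contacts()].
#' @param method \code{"frame"} (default), \code{"record"}, or
#'   \code{"molecule"}.
#' @return named numeric vector of fractions summing to 1 over the types
#'   present.
#' @export
lipid_fractional_contribution <- function(records,
                                          method = c("frame", "record",
                                                     "molecule")) {
  method <- match.arg(method)
  if (!nrow(records)) {
    stop("no contact records; fractional contribution undefined")
  }
  raw <- switch(method,
    frame = {
      contact_frames <- unique(records$frame)
      vapply(split(records$frame, records$lipid_type),
             function(fr) length(unique(fr)) / length(contact_frames),
             numeric(1))
    },
    record = {
      tab <- table(records$lipid_type) / nrow(records)
      stats::setNames(as.numeric(tab), names(tab))
    },
    molecule = {
      mol <- records[!duplicated(records$lipid_resid), ]
      tab <- table(mol$lipid_type) / nrow(mol)
      stats::setNames(as.numeric(tab), names(tab))
    })
  raw / sum(raw)
}

#' Composition-normalized relative lipid affinity
#'
#' Divides each lipid type's fractional contribution to protein-lipid
#' contacts by its membrane composition fraction. A value of 1 means the
#' type is contacted exactly as often as its abundance predicts; values
#' above 1 indicate preferential binding (e.g. the cardiolipin bias of
#' cytochromes on anionic membranes).
#'
#' @param fractions named fractions from [lipid_fractional_contribution()].
#' @param composition named membrane composition fractions (positive,
#'   summing to 1 within 1e-6), e.g.
#'   \code{c(CDL = 0.14, PE = 0.30, PG = 0.46, PC = 0.10)}.
#' @return data.frame of class \code{affinity_table}: \code{lipid_type},
#'   \code{fractional_contribution}, \code{composition_fraction},
#'   \code{relative_affinity}.
#' @export
relative_lipid_affinity <- function(fractions, composition) {
  if (abs(sum(composition) - 1) > 1e-6) {
    stop("composition fractions must sum to 1")
  }
  if (any(composition <= 0)) stop("composition fractions must be positive")
  missing_types <- setdiff(names(fractions), names(composition))
  if (length(missing_types)) {
    stop("lipid type(s) with contacts but no stated composition: ",
         paste(missing_types, collapse = ", "))
  }
  types <- names(composition)
  frac <- stats::setNames(rep(0, length(types)), types)
  frac[names(fractions)] <- fractions
  structure(data.frame(lipid_type = types,
                       fractional_contribution = unname(frac),
                       composition_fraction = unname(composition),
                       relative_affinity = unname(frac / composition)),
            class = c("affinity_table", "data.frame"))
}

#' Per-frame count of interacting residues
#'
#' Number of distinct protein residues with at least one contact record
#' (either mode) in each frame; frames without records count 0.
#'
#' @param records \code{contact_records} from [classify_contacts()].
#' @param n_frames total number of analyzed frames.
#' @param frames frame labels to report (defaults to \code{1:n_frames}).
#' @return data.frame: \code{frame}, \code{n_residues}.
#' @export
contact_count_series <- function(records,
                                 n_frames = attr(records, "n_frames"),
                                 frames = NULL) {
  if (is.null(frames)) frames <- seq_len(n_frames)
  counts <- vapply(frames, function(f) {
    length(unique(records$resid[records$frame == f]))
  }, integer(1))
  data.frame(frame = frames, n_residues = counts)
}

#' Bootstrap confidence intervals for relative lipid affinities
#'
#' Resamples replicate trajectories with replacement and recomputes the
#' mean relative affinity per lipid type, giving confidence intervals
#' that reflect replicate-to-replicate spread. The \code{"percentile"}
#' interval uses the bootstrap quantiles of the resampled mean; the
#' \code{"student"} interval is the studentized (bootstrap-t) interval,
#' which is second-order accurate and holds closer to nominal coverage
#' with a modest number of replicates of a skewed statistic.
#'
#' @param affinities list of \code{affinity_table}s, one per replicate.
#' @param n_boot number of bootstrap resamples (default 1000).
#' @param conf confidence level (default 0.95).
#' @param method \code{"percentile"} (default) or \code{"student"}.
#' @return data.frame: \code{lipid_type}, \code{mean}, \code{lower},
#'   \code{upper}.
#' @export
affinity_bootstrap <- function(affinities, n_boot = 1000L, conf = 0.95,
                               method = c("percentile", "student")) {
  method <- match.arg(method)
  stopifnot(length(affinities) >= 2L)
  types <- affinities[[1]]$lipid_type
  mat <- vapply(affinities, function(a) {
    stats::setNames(a$relative_affinity, a$lipid_type)[types]
  }, numeric(length(types)))
  n_rep <- ncol(mat)
  alpha <- (1 - conf) / 2
  means <- rowMeans(mat)
  if (method == "percentile") {
    boots <- vapply(seq_len(n_boot), function(b) {
      rowMeans(mat[, sample.int(n_rep, n_rep, replace = TRUE), drop = FALSE])
    }, numeric(length(types)))
    lower <- apply(boots, 1L, stats::quantile, probs = alpha)
    upper <- apply(boots, 1L, stats::quantile, probs = 1 - alpha)
  } else {
    se <- apply(mat, 1L, stats::sd) / sqrt(n_rep)
    tstat <- vapply(seq_len(n_boot), function(b) {
      sub <- mat[, sample.int(n_rep, n_rep, replace = TRUE), drop = FALSE]
      se_b <- apply(sub, 1L, stats::sd) / sqrt(n_rep)
      (rowMeans(sub) - means) / pmax(se_b, 1e-12)
    }, numeric(length(types)))
    q_lo <- apply(tstat, 1L, stats::quantile, probs = alpha, na.rm = TRUE)
    q_hi <- apply(tstat, 1L, stats::quantile, probs = 1 - alpha, na.rm = TRUE)
    lower <- means - q_hi * se
    upper <- means - q_lo * se
  }
  data.frame(lipid_type = types, mean = means,
             lower = lower, upper = upper, row.names = NULL)
}
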