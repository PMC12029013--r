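# Minimal membrane-plus-residue system for boundary tests: one PG and one
# PE lipid, one LYS residue with a single side-chain nitrogen.
contact_fixture <- function(nz_pos, box = NULL) {
  atoms <- toy_atoms(
    name    = c("NZ", "P1", "C1", "P1", "N1", "C1", "P1", "C1"),
    resname = c("LYS", "PG", "PG", "PE", "PE", "PE", "PG", "PG"),
    resid   = c(1L, 1001L, 1001L, 1002L, 1002L, 1002L, 1003L, 1003L),
    segid   = c("PROA", rep("MEMB", 7)))
  coords <- rbind(nz_pos,
                  c(0, 0, 20), c(0, 0, 17),      # PG: P1, C1
                  c(30, 0, 20), c(31, 0, 20.5), c(30, 0, 17),
                  c(15, 15, -20), c(15, 15, -17))  # lower-leaflet PG
  spec <- selection_spec(protein = "segid PROA", headgroup_P = "name P1",
                         headgroup_N = "name N1", carbonyl = "name C1")
  list(traj = toy_traj(atoms, coords, box = box), spec = spec)
}

test_that("the 2.5 A coordination cutoff is sharp", {
  hit <- contact_fixture(c(0, 0, 22.4))
  rec <- classify_contacts(hit$traj, hit$spec, insertion = FALSE)
  expect_equal(nrow(rec), 1)
  expect_equal(rec$lipid_type, "PG")
  expect_equal(rec$mode, "COORDINATION")
  miss <- contact_fixture(c(0, 0, 22.6))
  expect_equal(nrow(classify_contacts(miss$traj, miss$spec,
                                      insertion = FALSE)), 0)
})

test_that("an atom below the carbonyl plane far from any head group is INSERTION only", {
  # carbonyl plane (upper) = 17; NZ at z = 13, 8+ A from both P1 atoms
  f <- contact_fixture(c(8, 0, 13))
  rec <- classify_contacts(f$traj, f$spec)
  expect_equal(rec$mode, "INSERTION")
  expect_equal(rec$lipid_resid, 1001L)  # attributed to the nearest phosphate
})

test_that("head-group nitrogens coordinate too", {
  f <- contact_fixture(c(31, 0, 22.2))  # 1.7 A above the PE N1
  rec <- classify_contacts(f$traj, f$spec, insertion = FALSE)
  expect_equal(rec$lipid_type, "PE")
})

test_that("minimum-image distances see lipids across the periodic boundary", {
  f <- contact_fixture(c(49, 0, 20), box = c(50, 50, 60))
  # 1 A from the PG phosphate through the x boundary
  rec <- classify_contacts(f$traj, f$spec, insertion = FALSE)
  expect_equal(rec$lipid_type, "PG")
})

test_that("cell-list classification equals the brute-force all-pairs oracle", {
  set.seed(31)
  for (rep in 1:5) {
    box <- c(24, 24, 40)
    n_prot <- 20; n_lip <- 10
    types <- sample(c("CDL", "PE", "PG", "PC"), n_lip, replace = TRUE)
    atoms <- rbind(
      toy_atoms(rep("CB", n_prot), rep("LYS", n_prot), rep(1:4, 5), "PROA"),
      toy_atoms(rep("P1", n_lip), types, 1000L + 1:n_lip, "MEMB"))
    atoms$index <- seq_len(nrow(atoms))
    coords <- cbind(runif(30, 0, 24), runif(30, 0, 24), runif(30, 10, 25))
    traj <- toy_traj(atoms, coords, box = box)
    spec <- selection_spec(protein = "segid PROA", headgroup_P = "name P1",
                           carbonyl = NULL)
    got <- classify_contacts(traj, spec, contact_criteria(cutoff = 4),
                             insertion = FALSE)
    want <- brute_force_contacts(traj, spec, cutoff = 4)
    expect_equal(sorted_records(got), sorted_records(want))
  }
})

test_that("contacts are invariant under rigid translation and lipid relabeling", {
  set.seed(77)
  cfg <- generator_config(n_frames = 3, n_lipids_per_leaflet = 30,
                          seed = 5, descent = FALSE)
  g <- generate_trajectory(cfg)
  traj <- g$trajectory
  rec0 <- sorted_records(classify_contacts(traj))
  shifted <- traj
  for (k in 1:3) shifted$coords[, k, ] <- shifted$coords[, k, ] +
    c(7.3, -2.1, 0)[k]
  rec1 <- sorted_records(classify_contacts(shifted,
                                           carbonyl_z = leaflet_plane_z(
                                             shifted, "segid MEMB and name C1 C2",
                                             "upper")))
  expect_equal(rec1, rec0)
  # relabeling lipid molecules of one type leaves type-level results intact
  swapped <- traj
  pg <- unique(traj$atoms$resid[traj$atoms$resname == "PG"])[1:2]
  swap <- swapped$atoms$resid
  swap[swapped$atoms$resid == pg[1]] <- -1L
  swap[swapped$atoms$resid == pg[2]] <- pg[1]
  swap[swap == -1L] <- pg[2]
  swapped$atoms$resid <- swap
  rec2 <- classify_contacts(swapped)
  expect_equal(table(rec2$lipid_type), table(classify_contacts(traj)$lipid_type))
})

test_that("residue interaction frequencies and shares follow hand counts", {
  rec <- data.frame(
    frame = c(1, 2, 3, 1:7),
    resid = c(rep(101L, 3), rep(102L, 7)),
    lipid_resid = 1001L, lipid_type = "PG", mode = "COORDINATION")
  freq <- residue_interaction_frequency(rec, n_frames = 10)
  expect_equal(freq$frequency[freq$resid == 101], 0.3)
  expect_equal(freq$frequency[freq$resid == 102], 0.7)
  expect_equal(freq$record_share, c(0.3, 0.7))
  # residues with no records report zero when asked for explicitly
  f2 <- residue_interaction_frequency(rec, n_frames = 10,
                                      resids = c(101L, 103L))
  expect_equal(f2$frequency[f2$resid == 103], 0)
  expect_error(residue_interaction_frequency(rec, n_frames = 0), "n_frames")
})

test_that("fractional contributions follow hand counts and renormalize co-occurrence", {
  one <- function(f, type) data.frame(frame = f, resid = 1L,
                                      lipid_resid = 2000L + f,
                                      lipid_type = type, mode = "COORDINATION")
  rec <- do.call(rbind, c(
    lapply(1:43, one, "CDL"), lapply(44:88, one, "PG"),
    lapply(89:95, one, "PE"), lapply(96:100, one, "PC")))
  fr <- lipid_fractional_contribution(rec)
  expect_equal(fr[["CDL"]], 0.43)
  expect_equal(fr[["PG"]], 0.45)
  expect_equal(fr[["PE"]], 0.07)
  expect_equal(fr[["PC"]], 0.05)

  both <- do.call(rbind, c(lapply(1:20, one, "CDL"), lapply(1:20, one, "PG")))
  fb <- lipid_fractional_contribution(both)
  expect_equal(unname(fb[c("CDL", "PG")]), c(0.5, 0.5))

  only <- do.call(rbind, lapply(1:10, one, "PG"))
  expect_equal(lipid_fractional_contribution(only)[["PG"]], 1)
  expect_error(lipid_fractional_contribution(rec[0, ]), "no contact records")

  # molecule attribution counts each bound lipid once: 2 CDL molecules
  # (one held for 9 frames) and 2 PG molecules give 0.5/0.5
  mol <- data.frame(
    frame = c(1:9, 1, 2, 3),
    resid = 1L,
    lipid_resid = c(rep(2001L, 9), 2002L, 3001L, 3002L),
    lipid_type = c(rep("CDL", 10), "PG", "PG"), mode = "COORDINATION")
  fm <- lipid_fractional_contribution(mol, method = "molecule")
  expect_equal(unname(fm[c("CDL", "PG")]), c(0.5, 0.5))
  # record attribution weights residence: 10 CDL records of 12
  fr2 <- lipid_fractional_contribution(mol, method = "record")
  expect_equal(unname(fr2[["CDL"]]), 10 / 12)
})

test_that("relative affinity is the contribution over the composition", {
  comp <- c(CDL = 0.14, PE = 0.30, PG = 0.46, PC = 0.10)
  fr <- c(CDL = 0.43, PG = 0.45, PE = 0.07, PC = 0.05)
  aff <- relative_lipid_affinity(fr, comp)
  got <- setNames(aff$relative_affinity, aff$lipid_type)
  expect_equal(round(got[["CDL"]], 2), 3.07)
  expect_equal(round(got[["PG"]], 2), 0.98)
  expect_equal(round(got[["PE"]], 2), 0.23)
  expect_equal(round(got[["PC"]], 2), 0.50)
  # null preference: fractions equal to composition give affinity 1
  null <- relative_lipid_affinity(comp, comp)
  expect_equal(null$relative_affinity, rep(1, 4))
  # single-type membrane
  single <- relative_lipid_affinity(c(PG = 1), c(PG = 1))
  expect_equal(single$relative_affinity, 1)
  expect_error(relative_lipid_affinity(fr, comp * 0.9), "sum to 1")
  expect_error(relative_lipid_affinity(c(WAX = 0.2, PG = 0.8),
                                       c(PG = 0.5, PC = 0.5)),
               "no stated composition")
})

test_that("bootstrap intervals track the replicate spread of affinities", {
  set.seed(11)
  mk <- function(cdl) {
    structure(data.frame(
      lipid_type = c("CDL", "PG"),
      fractional_contribution = c(cdl * 0.14, 1 - cdl * 0.14),
      composition_fraction = c(0.14, 0.86),
      relative_affinity = c(cdl, (1 - cdl * 0.14) / 0.86)),
      class = c("affinity_table", "data.frame"))
  }
  affs <- lapply(rnorm(12, mean = 2, sd = 0.2), mk)
  for (m in c("percentile", "student")) {
    ci <- affinity_bootstrap(affs, method = m)
    cdl <- ci[ci$lipid_type == "CDL", ]
    expect_equal(cdl$mean, 2, tolerance = 0.2)
    expect_true(cdl$lower < cdl$mean & cdl$mean < cdl$upper)
    expect_gt(cdl$lower, 1)   # clearly separated from the null
  }
})

test_that("the per-frame interacting-residue count matches hand counts", {
  rec <- data.frame(frame = c(1, 1, 1, 3, 3), resid = c(1L, 1L, 2L, 5L, 6L),
                    lipid_resid = 1001:1005, lipid_type = "PG",
                    mode = "COORDINATION")
  cc <- contact_count_series(rec, n_frames = 4)
  expect_equal(cc$n_residues, c(2L, 0L, 2L, 0L))
  empty <- contact_count_series(rec[0, ], n_frames = 3)
  expect_equal(empty$n_residues, c(0L, 0L, 0L))
})
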