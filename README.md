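# peritraj

Surface-diffusion and lipid-contact analysis for peripheral membrane
proteins.

Soluble electron carriers such as cytochrome c2 travel between the
membrane-anchored complexes of an electron transport chain. On anionic
bioenergetic membranes they often do so by *skipping*: two-dimensional
diffusion on the membrane surface interrupted by brief three-dimensional
excursions, held near the surface by electrostatics — with a marked
preference for cardiolipin (CDL), the doubly phosphorylated anionic
lipid. `peritraj` turns molecular-dynamics trajectories of such systems
into the quantities that characterize this behavior:

* **Insertion depth** — per-frame z displacement of the deepest
  residue's side-chain center of mass relative to the binding-leaflet
  phosphate plane (negative = inserted); histogram mode detection and a
  two-state BOUND/HOVER segmentation with dwell times and excursion
  counts.
* **Orientation** — tilt angles of the heme plane
  (`phi_alpha`, `phi_beta`, `phi_gamma`) from a per-frame least-squares
  plane fit, summarized with axial (period-180°) circular statistics.
* **Protein–lipid contacts** — residue-level coordination (within 2.5 Å
  of a head-group P/N) and hydrophobic insertion (below the carbonyl
  plane), rolled up to per-residue frequencies, per-type fractional
  contributions and composition-normalized relative lipid affinities
  `affinity(type) = fraction(type) / composition(type)`, with bootstrap
  confidence intervals over replicates.
* **Diffusion coefficients** — mean-square displacement of the protein
  center of mass over replicates and the Fickian fit
  `<x²> = 2 N D t`, for lateral (N = 2) and full (N = 3) motion.

A synthetic trajectory generator (`generate_trajectory()`) emulates the
whole system — typed anionic membrane at 14% CDL / 30% PE / 46% PG /
10% PC, rigid protein with a basic face and a heme proxy, two-state
Markov skipping dynamics, prescribed diffusion coefficients, depths and
tilt angles — with an exact ground-truth sidecar, so every analysis
stage is testable without any simulation data. Trajectories are read
and written as multi-MODEL PDB (plus DCD input) via bio3d, with a small
documented selection grammar (`resname`, `name`, `segid`, `resid`,
`protein`, `and`/`or`/`not`).

## Worked example

Generate three synthetic 200 ns replicates and run the full analysis:

```r
library(peritraj)

cfg  <- generator_config(n_frames = 2000, n_replicates = 3, seed = 42,
                         descent = FALSE)
reps <- generate_replicates(cfg)
traj <- reps[[1]]$trajectory
traj
#> trajectory: 1085 atoms, 2000 frames
#>   box: 110 x 110 x 120 A
#>   time: 0 .. 199.9 ns
#>   segments: MEMB:1020, PROA:65

ds <- depth_series(traj)
depth_histogram(ds, bin_width = 0.5)
#> depth histogram: 20 bins of 0.5 A; 2000 samples
#>   modes (A): -0.75, 3.75

segment_states(ds, threshold = 1.5, min_dwell = 3)
#> two-state segmentation (threshold 1.5 A): 2000 frames
#>   bound fraction 0.758, 6 excursion(s) (HOVER -> BOUND)

orientation_summary(orientation_series(traj))
#>       angle   mean    sd mode    n
#> 1 phi_alpha  77.76 8.138   77 2000
#> 2  phi_beta  72.50 4.554   71 2000
#> 3 phi_gamma 101.20 8.189  103 2000

rec <- classify_contacts(traj)
relative_lipid_affinity(lipid_fractional_contribution(rec, "molecule"),
                        cfg$composition)
#>   lipid_type fractional_contribution composition_fraction relative_affinity
#> 1        CDL                  0.1875                 0.14             1.339
#> 2         PE                  0.3125                 0.30             1.042
#> 3         PG                  0.4375                 0.46             0.951
#> 4         PC                  0.0625                 0.10             0.625

msd <- compute_msd(lapply(reps, function(r) com_series(r$trajectory)),
                   dims = 2, windowed = TRUE)
fit_fickian(msd, fit_range = c(0, 10))
#> Fickian fit (N = 2): slope 3.411 +/- 0.0048 A^2/ns, intercept -0.3862 A^2
#>   D = 0.8527 A^2/ns (stderr 0.0012, replicate sd 0.28)
```

Reading the output: the depth histogram is bimodal with an inserted mode
just below the phosphate plane and a hovering mode ~4 Å above it; the
segmentation quantifies the skipping motion (three quarters of the time
bound, six desorption/rebinding events in 200 ns); the heme stays at a
stable tilt (`phi_beta` ≈ 72° with the tightest spread); CDL is
contacted ~1.3× more than its 14% share of the membrane predicts — here
purely from its two-phosphate head group; and the lateral MSD slope of
3.41 Å²/ns corresponds to D = slope/(2·2) ≈ 0.85 Å²/ns, close to the
generator's bound-state setting of 0.798 Å²/ns.

A thin command-line front end (`inst/cli/peritraj`) exposes the same
pipeline as subcommands `depth`, `orient`, `contacts`, `msd` and
`simulate`; see `?peritraj_cli`.

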