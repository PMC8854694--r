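# epiquant

Quantitative analysis of epithelial integrity in the early
post-implantation mouse embryo: daughter-cell movement after apical
divisions, FLIPPER-TR membrane-tension FLIM, apical F-actin intensity
profiles, mesoderm migration metrics, and the statistics that compare
them — together with synthetic-data generators that produce every input
class with known ground truth.

## Who this is for

Developmental biologists and imaging analysts quantifying
pseudostratified epithelia (epiblast, neuroepithelium) from live confocal
tracking and FLIM, who need the full measurement chain — jitter
correction, angle-based movement classification, phasor lifetime
analysis, normalised line profiles — as reviewed, tested code rather than
a collection of spreadsheet steps and vendor macros.

## The measurements

**Daughter-cell kinematics.** After a division at the apical surface,
each daughter's movement is summarised by the distance travelled
*d* = ‖final − mother‖ and the direction angle θ between the reference
vector (mother → embryonic-region centre) and the movement vector
(mother → daughter final position). θ ∈ [0°, 90°) is apical movement
(towards the proamniotic cavity — delamination when it persists),
θ ∈ (90°, 180°] basal (reintegration into the epithelium). Siblings are
labelled apical/basal by their distance to the centre immediately after
division. Division geometry (angle of the daughter–daughter axis to the
apical-basal direction, distance of the division site to the basement
membrane) is computed per event. Stage jitter is removed by expressing
all coordinates relative to the per-frame embryonic-region centre.

**Phasor FLIM.** Per-pixel photon-decay histograms are projected onto
first-harmonic phasor coordinates G = Σc·cos(ωt)/Σc, S = Σc·sin(ωt)/Σc
(ω = 2π·20 MHz), after 5×5 pixel binning and background thresholding;
G and S are median filtered (window 5) and converted to the phase
lifetime τ = S/(ωG). ROI means are taken over the tension-sensitive
window 2.8–7 ns of the FLIPPER-TR probe, whose lifetime increases with
membrane tension.

**Intensity profiles.** Width-3 line profiles across the apical domain,
rescaled to percent distance, normalised by the cell's nuclear mean to
cancel depth attenuation, pooled across cells and summarised by LOWESS
with a bootstrap 95% band.

**Migration.** Movement (total path length, µm), velocity (µm/min) and
directionality (total / straight-line distance, ≥ 1; inverse convention
by flag).

**Statistics.** Two-sided Fisher's exact test (probability-mass
definition) with explicit Bonferroni family size, one-way ANOVA + Tukey
HSD, nested ANOVA (group tested against embryos-within-group), pooled or
Welch t-tests, and box-plot summaries in both whisker conventions.

## Worked example

Simulate the wild-type study design (3 embryos, 28 divisions → 56
daughters, basal probability 51/56), run the kinematics pipeline, and
tabulate movement directions:

```r
library(epiquant)

sim <- generate_embryo_tracks(embryo_sim_config(
  n_embryos = 3, n_divisions_per_embryo = c(10, 9, 9),
  genotype = "wildtype", jitter_sd = 5, seed = 1
))
res <- analyze_divisions(sim$tracks)
res
#> <division_analysis>
#>   28 divisions, 56 daughters (56 classified, 0 exclusion records)
#>   apical 3.6% / basal 96.4%
```

`tidy(res)` returns the per-daughter table (d in µm, θ in degrees,
direction call, sibling label, tie flags); `res$exclusions` lists every
excluded event with its reason. Comparing genotypes:

```r
mut <- generate_embryo_tracks(embryo_sim_config(
  n_embryos = 3, n_divisions_per_embryo = 11,
  genotype = "mutant", seed = 2
))
outcomes <- dplyr::bind_rows(
  dplyr::mutate(tidy(res), genotype = "wildtype"),
  dplyr::mutate(tidy(analyze_divisions(mut$tracks)), genotype = "mutant")
)
ct <- direction_contingency(outcomes, group = "genotype")
fisher_exact_2x2(contingency_matrix(ct, "all"), m = 4)
#> <epiq_stat> two-sided Fisher's exact test (probability-mass)
#>   p = 3.472e-09; adjusted p = 1.389e-08 (bonferroni, m = 4)
```

A FLIM run on a synthetic two-tissue stack (4.83 ns vs 4.50 ns, the
contrast scale seen between epiblast and visceral endoderm):

```r
sim_flim <- generate_flim_stack(flim_sim_config(
  image_shape = c(30, 60),
  regions = list(
    list(polygon = data.frame(x = c(0, 24.6, 24.6, 0),  y = c(0, 0, 29, 29)), tau_ns = 4.83),
    list(polygon = data.frame(x = c(30.4, 59, 59, 30.4), y = c(0, 0, 29, 29)), tau_ns = 4.50)
  ),
  photons_per_pixel_mean = 400, n_time_bins = 256, seed = 2002
))
flim_pipeline(sim_flim$stack,
  rois = list(epiblast = data.frame(x = c(0, 4, 4, 0),  y = c(0, 0, 5, 5)),
              emVE     = data.frame(x = c(7, 11, 11, 7), y = c(0, 0, 5, 5))),
  bin_factor = 5, min_counts = 50)$roi_stats
#> # A tibble: 2 × 6
#>   roi      mean_ns   sd_ns n_pixels n_excluded_window n_excluded_undefined
#>   <chr>      <dbl>   <dbl>    <int>             <int>                <int>
#> 1 epiblast    4.82 0.0241        30                 0                    0
#> 2 emVE        4.52 0.00990       30                 0                    0
```

The per-pixel means recover the configured lifetimes; their difference
(~0.33 ns) is the tissue tension contrast the probe reads out.

`autoplot()` methods exist for lifetime images, phasor clouds, profile
fits and division analyses; a thin command-line wrapper
(`inst/scripts/epiquant`, subcommands `simulate`, `kinematics`, `flim`,
`migrate`, `stats`) writes CSV/JSON outputs plus a run report that makes
every run reproducible from its configuration echo and seed.

Conventions: coordinates in µm (CSV headers carry units; pixel inputs
need an explicit pixel size); images use 0-based pixel indexing, origin
top-left, y increasing downward.

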