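---
title: "Quantifying epiblast integrity: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying epiblast integrity: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epiquant)
```

# The biological problem

The epiblast of the early post-implantation mouse embryo is a
pseudostratified epithelium: a single cell layer whose nuclei sit at
different apical–basal heights. Nuclei migrate apically ahead of mitosis
(interkinetic nuclear migration), cells divide at the apical surface
facing the proamniotic cavity, and both daughters must then reintegrate
basally into the epithelium. Failure of the more apical daughter to
reintegrate — apical delamination into the cavity — destroys the
architecture of the tissue.

`epiquant` implements the quantitative measurements used to characterise
this process from live and fixed imaging:

1. **Track kinematics** — classification of daughter-cell movement after
   apical divisions from manually tracked positions;
2. **Phasor FLIM** — fluorescence-lifetime analysis of the FLIPPER-TR
   membrane tension probe, whose lifetime increases with membrane tension;
3. **Intensity profiles** — apical F-actin line profiles normalised to the
   nuclear signal, with LOWESS summaries and bootstrap confidence bands;
4. **Migration metrics** — movement, velocity and directionality of
   explant-derived mesoderm cells;
5. **Group statistics** — the tests used to compare the resulting
   quantities (Fisher's exact test with Bonferroni adjustment, one-way and
   nested ANOVA, Tukey's HSD, t-tests, box-plot summaries);
6. **Synthetic data** — generators for every input class with known ground
   truth, so that the entire pipeline is testable without microscope data.

# Track kinematics

## The measurement model

All geometry is 2D. The imaging underlying this analysis acquired a
handful of z-sections around the midsagittal plane and the quantification
was done in that plane; an optional z column in track tables is carried
but ignored by angle computations.

Each division event consists of a mother track ending at the apical
surface and two daughter tracks. For every daughter:

* the **reference vector** runs from the mother's position immediately
  prior to the division to the centre of the embryonic region;
* the **movement vector** runs from the same mother position to the
  daughter's final tracked position;
* the **distance travelled** *d* is the Euclidean norm of the movement
  vector, and the **direction angle** θ ∈ [0°, 180°] is the angle between
  the two vectors. θ < 90° means net movement towards the centre
  (**apical**); θ > 90° means movement away from it into the epithelium
  (**basal**).

θ = 90° exactly is a measure-zero boundary; it is assigned to basal and
flagged (`boundary_tie`) so that downstream counts remain exhaustive and
transparent. Sibling identity is assigned at the first post-division
frame: the daughter nearer the centre is the `apical_daughter`. Exact
ties are broken towards the lower track id, again with a flag.

The division angle is the angle between the daughter-to-daughter axis and
the vector from the midpoint between daughters to the centre, folded to
[0°, 90°]. Orientation bins default to parallel < 30°, oblique 30–60°,
orthogonal > 60°; the underlying workflow binned orientations without
publishing its edges, so the edges here are explicit configuration echoed
into every run report.

"Immediately prior" and "immediately after" are frame offsets
(`prior_offset`, `after_offset`) around the division frame, which is
defined as the first frame at which the daughters are tracked. The
follow-up horizon is configurable (`horizon_frames`); by default a
daughter is followed to its last tracked frame, matching a bounded
follow-up of roughly 80 minutes in the reference experiment.

## Jitter correction and numerical exactness

Cultured embryos drift during imaging. The correction re-expresses every
coordinate relative to the per-frame embryonic-region centre, which must
be supplied per frame: the centre's construction was a manual annotation
choice in the original workflow, so no automatic estimator is baked into
the measurement path.

Because the correction is a subtraction, rigid per-frame jitter cancels.
To make this cancellation *bit-exact* in the synthetic-data path — so
that invariance tests can assert identity rather than closeness — the
generator quantizes all coordinates and all injected jitter onto a dyadic
grid (multiples of 2⁻¹⁶ µm ≈ 15 pm, far below any measurement precision).
Sums and differences of such values of laboratory magnitude are exact in
double precision.

```{r kinematics-demo}
sim <- generate_embryo_tracks(embryo_sim_config(
  n_embryos = 3, n_divisions_per_embryo = c(10, 9, 9),
  genotype = "wildtype", jitter_sd = 5, seed = 1
))
res <- analyze_divisions(sim$tracks)
glance(res)
```

## The synthetic track generator

The generator emulates the study conditions as its defaults: three
embryos per genotype; 7.5-minute frame intervals; mothers completing
interkinetic migration to an apical surface of radius 35 µm inside a
basement membrane at 60 µm; wild-type daughters basal with probability
51/56; mutant daughters apical with marginal probability 0.5. The radii
are not printed in the source material and were chosen as typical
egg-cylinder dimensions at this stage; they only set the geometric scale
and do not enter any proportion.

Daughter fates are sampled per **division**, not independently per
daughter: delamination affects one daughter of a division at a time, so a
division carries exactly one apical mover with probability
2·min(p, 1−p) and two with probability max(0, 2p−1). This matters: the
observed pattern — 33 apical movers across 33 mutant divisions, 29 of
them the apical sibling (87.9%) — is unreachable under independent
per-daughter draws, which cap the expected apical-sibling share near 69%
when half of all daughters move apically. With per-division sampling the
marginal apical probability is still exactly `p_apical_mut`, and the
`sibling_apical_share` parameter (default 29/33) reproduces the sibling
asymmetry.

True direction angles are drawn strictly inside (5°, 85°) for apical and
(95°, 175°) for basal fates, so noise-free classification recovers the
ground truth exactly and boundary effects are excluded by construction.
What the generator does **not** model: mechanical interactions between
cells (fates are sampled, not emergent), rotational stage drift (jitter
is a rigid translation), out-of-plane movement, and tracking errors such
as identity swaps. Passing tests therefore validate the measurement
pipeline, not any biological mechanism.

# Phasor FLIM

## Model

Each pixel of a FLIM stack holds a photon-arrival histogram over one
excitation period (repetition rate 20 MHz by default, period 50 ns). The
phasor transform projects the histogram onto first-harmonic Fourier
coordinates

$$G = \frac{\sum_k c_k \cos(\omega t_k)}{\sum_k c_k},\qquad
  S = \frac{\sum_k c_k \sin(\omega t_k)}{\sum_k c_k},\qquad
  \omega = 2\pi f,$$

with bin centres $t_k$. Mono-exponential decays of lifetime τ lie on the
universal semicircle at $G = 1/(1+(\omega\tau)^2)$,
$S = \omega\tau/(1+(\omega\tau)^2)$; mixtures lie inside it on chords.
The per-pixel lifetime estimator is the **phase lifetime**
$\tau = S/(\omega G)$ — the standard phasor choice; the vendor pipeline
this replaces does not document its estimator, so the modulation lifetime
$\tau_m = \sqrt{1/(G^2+S^2)-1}/\omega$ is available as a sensitivity
check.

The processing order follows the published workflow: 5×5 pixel binning
(block sums; 135 → 675 nm/px), background thresholding on total counts
*after* binning (the threshold is labelling-dependent, 25–50 counts in
the reference data, and is a required parameter), phasor transform,
independent 5×5 median filtering of G and S restricted to defined pixels,
lifetime mapping, and unweighted ROI means over the tension-sensitive
window 2.8–7 ns (an intensity-weighted flag exists). Rainbow rendering
over 3.75–4.75 ns, clipped at both ends, is display-only.

## Numerical choices

* **Time bins.** The generator defaults to 512 bins per period. The phase
  lifetime of a bin-sampled decay carries a discretization bias that
  scales as the inverse square of the bin count and is worst for short
  lifetimes; at 256 bins the bias at τ = 0.5 ns is ~1.3%, at 512 bins
  ~0.3%, below the 0.5% round-trip tolerance the test suite enforces
  across 0.5–7 ns. Single-reference calibration cannot remove this bias
  (the aliased harmonics that cause it are lifetime-dependent), so the
  bin count is the honest knob.
* **Calibration.** No instrument response is deconvolved by default. An
  optional single-reference calibration multiplies all phasors by the
  complex factor mapping a measured known-lifetime standard onto its
  theoretical semicircle position; the test suite demonstrates it
  correcting a synthetic timing offset exactly.
* **Aliasing.** Lifetimes at or beyond period/(2π) (≈ 7.96 ns at 20 MHz)
  are generated with a warning, never silently.
* **Partial blocks** at image edges are dropped during binning (padding
  with zero counts is available by flag), so every analysed pixel
  aggregates a full 5×5 block.
* **Undefined pixels** (below threshold, or G ≤ 0) are `NA` throughout
  and are excluded from medians, ROI means and counts; they can never
  re-enter through filtering.

```{r flim-demo}
sim_flim <- generate_flim_stack(flim_sim_config(
  image_shape = c(20, 20),
  regions = list(list(
    polygon = data.frame(x = c(0, 19, 19, 0), y = c(0, 0, 19, 19)),
    tau_ns = 4.83
  )),
  photons_per_pixel_mean = 2500, n_time_bins = 256, seed = 2
))
pipe <- flim_pipeline(
  sim_flim$stack,
  rois = list(all = data.frame(x = c(0, 9, 9, 0), y = c(0, 0, 9, 9))),
  bin_factor = 2, min_counts = 50
)
pipe$roi_stats
```

The simulated photon budgets are chosen so that the test suite and the
acceptance script finish in minutes on a single core: ROI comparisons use
10⁴ photons per analysed (binned) pixel over ~30-pixel ROIs, and the
noise-scaling law (SD of the lifetime estimate ∝ photons^−1/2) is checked
over 10³–10⁵ photons with a few hundred pixels per level.

# Intensity profiles

Apical F-actin organisation is quantified by sampling intensity along a
freehand path across a cell's apical domain with a width of 3: at each
arc-length step the reported value is the mean of three bilinear samples
spaced one pixel apart along the local normal. Because apical domains
differ in size between cells, positions are rescaled to percent of path
length (0% and 100% are the bounding apical junctions, which are supplied
as annotations, not detected). To cancel depth-dependent attenuation,
profiles are divided by the mean intensity over the same cell's nucleus,
which makes them exactly invariant to global illumination scaling.

Pooled profiles (reference design: 3 embryos × 5 cells per genotype) are
summarised by LOWESS. The smoother span is 0.3 by default — the source
workflow names the method but not the span — and is echoed in the output.
The 95% band is a percentile bootstrap over **cells** (resampled with
replacement within each embryo), 1000 resamples by default with a fixed
seed: the reference figures show a band without documenting its
construction, and a cell-level bootstrap is the weakest assumption
consistent with the design's clustering. Apical–basal junction profiles
across several junctions are aggregated as pointwise mean ± sample SD
after resampling onto a common percent grid.

```{r profile-demo}
simj <- generate_profile_image(profile_sim_config(mode = "junctional",
                                                  noise_sd = 2, seed = 3))
pr <- sample_profile(simj$image, simj$path, width = 3) |>
  normalize_profile(simj$image, simj$nucleus)
head(pr, 3)
```

The profile-image generator places Gaussian junctional spots or an
equal-integral uniform band along the apical path, plus a nucleus of
known mean; its `truth` element carries the expected noise-free profile.
The uniform band's level is derived from the discrete pixel count of the
band so that junctional and uniform images carry the same summed signal
exactly, making "same amount, different arrangement" comparisons fair.

# Migration metrics

For each tracked mesoderm cell: **movement** is the summed segment length
(µm); **velocity** is movement over elapsed time (µm/min);
**directionality** is movement divided by the straight start-to-end
distance. This ratio is ≥ 1 and *inverts* the convention common
elsewhere (straight/total ∈ (0, 1]); it is implemented verbatim as
defined in the source workflow, with an explicit `inverse` flag rather
than a silent correction. Cells that end exactly where they started have
undefined directionality and are reported with a note. The synthetic
generator produces correlated random walks with von Mises turning angles;
infinite concentration gives exactly straight paths (directionality 1),
and decreasing concentration increases the ratio monotonically.

# Group statistics

* **Fisher's exact test** (2×2, two-sided) uses the probability-mass
  definition: the total hypergeometric probability, margins fixed, of all
  tables no more probable than the observed one (with the customary
  1 + 10⁻⁷ relative tolerance for floating-point ties). Alternative
  two-sided definitions (e.g. doubling the one-sided p) exist; the
  probability-mass form is the common default and matches exhaustive
  enumeration, which the test suite verifies for every table with total
  ≤ 60. Bonferroni adjustment is explicit: the family size *m* is a
  parameter (the direction-proportion family in the reference figure has
  m = 4) and is always reported alongside the raw p. Computed on the
  printed direction counts, the raw p equals the first printed value at
  printed precision, which identifies the published values as raw
  (pre-adjustment) p's; both are emitted.
* **Nested ANOVA** tests a group effect against the among-unit
  (embryo-within-genotype) mean square, never the residual:
  F = MS_group / MS_unit(group) with df (g−1, Σunits−g). With several
  measurements per embryo this is the stratum that controls
  pseudo-replication; the suite verifies the nominal 5% type-I error
  under a null with strong embryo effects, and the algebraic equivalence
  to a one-way ANOVA on unit means in balanced designs. Unbalanced
  designs use sequential sums of squares from the same stratum.
* **One-way ANOVA + Tukey HSD** for multi-tissue comparisons; degenerate
  all-equal data is reported as undefined rather than p = 1.
* **t-tests** default to the pooled-variance Student form (as the figure
  legends name it) with a Welch flag; two constant groups with equal
  means give p = 1 by convention, flagged.
* **Box summaries** follow the min-to-max whisker convention used in the
  tissue box plots; a 1.5·IQR variant with outlier listing is selectable
  for figures drawn with outlier dots.

# Reproducibility

Every generator and every stochastic procedure takes an explicit integer
seed; fixed seeds give bit-identical outputs. The command-line layer
writes a JSON run report (package version, full configuration echo, seed,
exclusion log) next to every output, and all file writes are atomic
(write-then-rename). Internally coordinates are micrometres, CSV headers
carry units, and pixel-unit inputs require an explicit pixel size. Images
use 0-based pixel indexing with the origin at the top-left and y
increasing downward.

# Known limitations

* Geometry is 2D; movements with a strong out-of-plane component are
  projected.
* The embryonic-region centre is an input; its annotation error
  propagates directly into θ near the centre.
* The FLIM model is mono-exponential per region with Poisson noise; no
  instrument response function, detector afterpulsing, or multi-component
  decays are simulated, and no multi-exponential unmixing is offered.
* The LOWESS band is a bootstrap construction chosen here; other band
  definitions would differ in width, though not in the fitted curve.
* Statistical routines implement exactly the tests named in the reference
  workflow; no mixed-model likelihood machinery is provided beyond the
  nested-ANOVA F construction.
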