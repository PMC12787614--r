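---
title: "Modelling floral colour signals for bee vision: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling floral colour signals for bee vision: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(beesignal)
```

`beesignal` analyses how flowers with different pollinator rewards differ in
their visual displays, as seen by a trichromatic bee. This vignette explains
the models the package implements, the assumptions behind them, the parameters
that matter, and the design decisions taken where the methodology was
genuinely open. It states no empirical result that the package's tests and
acceptance script do not themselves compute.

## 1. The visual model

### Receptor sensitivities

The bee is modelled as a UV/blue/green trichromat. Full sensitivity curves are
rarely published, so `receptor_template()` reconstructs them from peak
wavelengths with the Govardovskii A1 visual-pigment nomogram (alpha band plus
the short-wavelength beta band), normalized to a maximum of 1. The default
peaks are 328, 428 and 536 nm (*Bombus terrestris*), a widely used stand-in
for bee visual systems, which are phylogenetically conservative. One numerical
consequence worth knowing: for the UV receptor the beta band (peaking near
292 nm) overlaps the alpha band, so the realized maximum of the combined curve
sits a few nanometres below the nominal 328 nm. Measured sensitivities can be
supplied via `bee_sensitivities(curves = ...)` or a CSV path, replacing the
template entirely.

### Quantum catch and adaptation

`quantum_catch()` integrates stimulus reflectance x sensitivity x illuminant
by the trapezoid rule on a 1-nm grid over 300–700 nm (the grid is a package
convention; all inputs are resampled onto it by linear interpolation, with
constant-edge extrapolation flagged by a warning and inputs covering less than
half the range rejected). Catches are von Kries-adapted to the background:
the leaf background itself scores P = 1 in every channel, and all downstream
quantities are therefore invariant to rescaling the illuminant — an exact
property the test suite asserts. No photon-flux reweighting is applied beyond
the supplied illuminant; if a quantal irradiance is wanted, supply it as the
illuminant.

The packaged defaults — a forest-shade-like irradiance and a green-leaf
background — are smooth analytic approximations shipped as plain CSV files
(`inst/extdata/*_synthetic.csv`, labelled synthetic). They stand in for
measured curves and should be replaced via
`viewing_context(illuminant = ..., background = ...)` whenever measured
spectra are available. Because of the adaptation step, moderate changes to the
illuminant shape move all loci coherently rather than catastrophically.

### Hexagon coordinates, contrasts

Excitations E = P/(P+1) map to hexagon coordinates
x = (sqrt(3)/2)(E_G − E_UV), y = E_B − (E_UV + E_G)/2 — the fixed coordinate
convention of the package. Chromatic contrast dS is the Euclidean distance in
(x, y) ("hexagon units"); the achromatic channel uses the green receptor only:
`lum = E_G` for a patch against the background (0.5 = background) and
`dL = |ΔE_G|` between two patches. The contrast table covers the ten pairs per
species: leaf against each of the four modules, plus the six intrafloral
pairs. The adapting background serves as the "leaf" term, so leaf–module dS
equals the module's radial distance; this matches the use of a standard leaf
background rather than per-species leaves.

### Spectral purity

`monochromatic_locus()` sweeps narrow-band stimuli (top-hat reflectance,
default bandwidth 10 nm — the bandwidth is a free parameter; anything from the
grid step up to ~20 nm changes little) across 300–700 nm and projects them
like any other stimulus. Purity of a flower locus is its radial distance
divided by the radial distance of a reference boundary point, clamped to
[0, 1].

Two candidate definitions exist for "the corresponding boundary point", and
the choice matters. Under von Kries adaptation against a green leaf the
monochromatic locus is strongly non-convex: it collapses toward the achromatic
centre at the long-wavelength end (the trichromat is nearly red-blind), and
its radius dips where narrow-band stimuli resemble the leaf. The
nearest-Euclidean reference can therefore sit on a different branch of the
curve than the locus's own hue, which inflates the ratio for weakly saturated
colours: a point constructed at exactly half the radius of a boundary point
can score far above 0.5. The package therefore uses the *same-hue ray*
reference by default (`mode = "ray"`): the boundary point closest in hue
angle, which makes purity scale linearly with radial distance (0.5 at half
radius, exactly), with `mode = "nearest"` available for comparison. Boundary
points with radius below 10% of the maximum are excluded as degenerate
references. Loci at the exact centre get purity 0 with an undefined reference
wavelength. One caveat either way: broadband UV+red "purples" fall in the gap
the monochromatic locus does not span, so their ratio can exceed 1 before
clamping; the tests check that this affects only a small fraction of random
smooth spectra.

## 2. Colour categories

Band means are arithmetic means of percent reflectance over the inclusive
windows 301–400 (UV), 401–500 (blue), 501–600 (green) and 601–700 nm (red).
A band is "reflecting" (+) at or above its threshold — 10/30/40/60 % by
default (`default_thresholds()`, configurable). Threshold comparisons are
inclusive; the data source for these cut-offs gave no strictness rule, and
ties at the threshold are vanishingly rare in practice. A green band that
passes its threshold is reclassified as absorbing when it is at least 50%
lower than the larger of the blue and red means (relative reading; an
absolute-difference reading — a 50-point gap — is available via
`green_rule = "absolute"`). The (blue, green, red) states map to 8 hues
(White, Yellow, Green, Red, Blue, Cyan, Pink, Black), prefixed by the UV
state, e.g. `UV+Yellow`. The hue table is the package's completion of the
categories observed in bee-pollinated floras; it is total and deterministic
over band means, so categorization is reproducible by construction.

## 3. Ordination

All PCAs are correlation-matrix PCAs (z-scored input, sd with denominator
n−1); constant columns are an error, missing values are not imputed. Signs
are fixed so each component's largest-magnitude loading is positive, making
output deterministic across platforms. The colour inventory is 34 variables:
per module, dS against leaf, `lum`, purity and the four band means (28), plus
the six intrafloral dS values. Intrafloral dL is deliberately excluded from
ordination input (it could not be normalized in the motivating analyses and
is used only in the mixed models). The nesting — PCA_color, PCA_size, then a
final PCA on `PC1_color, PC2_color, PC1_size, PC2_size` — prevents the 34
colour variables from outweighing the 9 size variables by count alone. A
global PCA on all 43 variables is computed for reference. The size PCA uses
every species with complete sizes; the colour and final PCAs use the subset
with all four modules measured. "Flower radius" is defined as sqrt(area/pi)
from the frontal area when not supplied — the source variable list names a
radius without defining it, and the disc-equivalent radius is the only
definition consistent with a single frontal area measure.

## 4. Statistical tests

* **PERMANOVA** (`permanova()`) is implemented directly for the one-factor
  Euclidean case: sums of squares computed from coordinates (equivalent to
  the distance partitioning), pseudo-F, R², and p = (#{F* ≥ F} + 1)/(n_perm
  + 1) under free label permutation — there are no strata in these designs.
  The implementation is cross-checked against `vegan::adonis2` and against
  exhaustive enumeration at n = 6 in the tests. Pairwise PERMANOVAs report
  raw p-values (matching how such tables are conventionally reported; apply
  `p.adjust` if desired).
* **PERMDISP** wraps `vegan::betadisper` (spatial-median centres, the
  reference default) with `permutest` and Tukey HSD on dispersions.
* **Chi-square** uses `stats::chisq.test(simulate.p.value = TRUE)` (Patefield
  fixed-margin tables; B defaults to 1e6, reduced in quick runs) and reports
  adjusted standardized residuals (`stdres`); plain Pearson residuals sit
  behind `residuals = "pearson"`.
* **Blomberg's K** (`blomberg_k()`) follows the ratio definition with the
  phylogenetic GLS mean and the Brownian expectation term; the randomization
  p shuffles tip values (default 1000 draws). K is invariant to affine trait
  transforms and to rescaling all branch lengths — both asserted exactly in
  tests — and is cross-checked against `phytools::phylosig`.
* **Phylogenetic ANOVA** (`phyl_anova()`) simulates the Brownian null of the
  one-way F on the tree (Cholesky of the phylogenetic covariance; the REML
  rate is reported but cancels from F, which is scale-invariant). Post-hoc
  pairwise t statistics use the same simulated null with Holm adjustment.
  Default 5000 simulations; the calibration tests use fewer per replicate.
* **OLS integration** models are plain `lm` fits with slope inference,
  Shapiro–Wilk and Breusch–Pagan diagnostics; the four colour~size models
  plus each axis against pollinator ITS on the ITS subset.
* **Modularity LMMs** fit `contrast ~ pair + reward + PC1_size + PC2_size +
  (1|sp)` by REML via `lmerTest` (Satterthwaite denominator df; Kenward–Roger
  not implemented). The achromatic response stacks `|lum − 0.5|` for
  extrafloral rows with dL for intrafloral rows, `pair` distinguishing them.
  Marginal/conditional R² follow the Nakagawa–Schielzeth partition
  (fixed / fixed+random / total). Pairwise module-pair comparisons are
  estimated marginal means with Tukey adjustment — the adjustment was not
  named in the motivating analyses; Tukey is the standard choice for
  all-pairs EMM contrasts. Singular fits (species variance estimated at the
  boundary) are flagged, not refit: with a balanced design the fixed effects
  then coincide with OLS, which the tests assert to 1e-6.

All permutation/simulation routines take explicit seeds, which are stored in
their result objects; `run_study()` derives per-stage seeds from one master
seed through a fixed splitting scheme, so a study is reproducible from a
single integer.

## 5. The synthetic community generator

`make_community()` emulates a tropical bee-pollinated orchid study: 95
species in reward groups of 47 unknown / 19 food-deceptive / 8 nectar /
10 oil / 11 fragrance, three replicate spectra per module, 21 species with at
least one missing flower module (so 74 are complete), and 35 species with
pollinator intertegular spans. These defaults mirror the study conditions the
pipeline was built for; all are configurable via `scenario_config()`.

Spectra are logistic-step curves through per-band plateau targets placed at
least 5 percentage points inside each category's threshold region, with
Gaussian noise (default sd 2% reflectance — typical of field spectrometry
after white-standard calibration). Categories are drawn from reward-specific
palettes with disjoint modes (deceptive species tend to UV+White tepals, oil
species to UV+Yellow lip tips, fragrance species to UV-Black lip bases and
UV-Green lip tips, nectar species to UV-Yellow lip tips); the "unknown" group
draws from a broad mixture. Two species-level latents add continuous
within-category variation: a brightness latent scaling the mean plateau level
and a saturation latent scaling the contrast among bands, both clipped into
category-safe boxes so the realized category never flips. These latents give
the colour PCA genuine continuous axes (achromatic and chromatic) on top of
the discrete palette, which is what real communities look like.

Size variables derive from two latent factors — flower size (loading the six
floral measures) and display size (loading the three inflorescence measures),
on log-normal scales with realistic means (e.g. petals ~25 mm, areas
~600 mm²). The flower-size latent is coupled to the species' realized mean
chromatic contrast at correlation `rho_c` (default 0.5) and the display-size
latent to the realized mean green signal at `rho_a` (default −0.3), with the
residual part orthogonalized in-sample so the configured couplings are exact —
"controlled covariance" in the strict sense, asserted by tests. The residual
latents carry a 30% Brownian variance share on a unit-height pure-birth tree
(`make_tree()`), so phylogenetic signal is present but weak, as is typical for
floral colour. Pollinator ITS is log-normal around 3 mm, positively tied to
the achromatic metric. The achromatic coupling metric is the mean green
excitation `lum` itself rather than |lum − 0.5|: most flowers are brighter
than leaves, and the unfolded metric is monotone, giving a clean latent axis.

What the generator does **not** emulate: pigment biophysics (spectra are
steps, not flavonoid/carotenoid curves), within-species among-individual
variation beyond replicate noise, correlated module colours within a flower
beyond the shared latents, scent, and reward quantity. Passing tests
therefore demonstrate that the pipeline recovers known structure of this
form; they do not validate instrument calibration or sampling design on real
data.

## 6. Problem sizes used by the tests and acceptance script

The test suite runs the property batteries at sizes chosen to balance
statistical resolution against runtime on a single CPU: 1000-spectrum random
suites for the hexagon and purity invariants; 1000 noisy draws over the 16
categories for the round-trip; 500 null simulations at 199 permutations for
the PERMANOVA and phylogenetic-ANOVA size checks (the binomial ±2 SE band at
500 replicates is roughly ±0.02 around 0.05); 500 Brownian simulations on a
50-tip tree for the K calibration; 100 seeds of the full 95-species community
for the integration recovery; and 200 replicates of a balanced 40-species,
10-pair design for the LMM recovery. The acceptance script runs one full
paper-like study with 999 permutations, B = 1e5 chi-square replicates, 999 K
randomizations and 1000 Brownian simulations.

## 7. Known limitations

* The hexagon is the only opponent model implemented; receptor-noise (JND)
  models and tetrachromacy are out of scope.
* Purity depends on the monochromatic boundary, which in turn depends on the
  background/illuminant; comparisons across viewing contexts should recompute
  the boundary (as `color_variables()` does).
* PERMANOVA is one-factor Euclidean by design; no strata, no other metrics.
* The LMMs assume a single random intercept per species; phylogenetic mixed
  models are not implemented.
* Tree construction is out of scope: the package consumes a user Newick and
  assumes tips match species ids after simple name normalization.
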