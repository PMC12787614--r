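# beesignal

Bee-vision colour modelling and reward–signal analysis for complex floral
displays.

Bee-pollinated orchids advertise very different things — nectar, floral oils,
perfumes, or nothing at all — and the visual signals of those reward systems
need not converge on a single "bee syndrome". `beesignal` implements the full
analysis chain a visual ecologist needs to ask whether flowers *signal their
reward type*: reflectance spectra of the separate flower colour modules
(sepals, petals, lip tip, lip base) are modelled into the perceptual colour
space of a trichromatic bee, reduced together with morphometric display traits,
and tested for association with reward strategy, phylogenetic signal,
colour–size integration and intrafloral modularity.

## The model

For a stimulus with reflectance R(λ) under illuminant I(λ), the quantum catch
of receptor *i* (sensitivities S_i rebuilt from the Govardovskii A1 template at
peaks 328, 428, 536 nm — the *Bombus terrestris* trichromat) is

    P_i = R_i ∫ R(λ) S_i(λ) I(λ) dλ,      R_i = 1 / ∫ R_b(λ) S_i(λ) I(λ) dλ,

where R_b is the adapting green-leaf background (von Kries adaptation: the
background itself gives P_i = 1). Receptor excitations E_i = P_i/(P_i + 1) map
to Chittka's colour hexagon

    x = (√3/2)(E_G − E_UV),   y = E_B − (E_UV + E_G)/2 ,

where the background sits at the achromatic centre. From the hexagon the
pipeline computes, per species and module:

* **chromatic contrast** dS — Euclidean hexagon distance, against the leaf
  background and between the six intrafloral module pairs;
* **achromatic signal** — green-receptor excitation `lum` against the
  background (0.5 = background), `dL = |ΔE_G|` within flowers;
* **spectral purity** — radial distance relative to the monochromatic locus
  (narrow-band stimuli swept over 300–700 nm), 0 at the centre, 1 on the
  boundary;
* **colour categories** — band means over UV/blue/green/red windows
  (301–400/401–500/501–600/601–700 nm) thresholded at 10/30/40/60 %
  reflectance (green override at a ≥50 % deficit), giving labels such as
  `UV+White` or `UV-Black`.

Colour (34 variables) and size (9 variables) are summarized by a nested PCA
hierarchy — PCA_color, PCA_size, then a final PCA on their first two
components each, so the uneven variable counts do not weight colour over size.
Reward–signal association is tested by PERMANOVA/PERMDISP on the ordination
and hexagon spaces, and by Monte-Carlo chi-square with standardized residuals
on category tables; phylogenetic signal by Blomberg's K with randomization;
signal intensity by simulation-based phylogenetic ANOVA; colour–size
integration by OLS; and intrafloral modularity by linear mixed models
`contrast ~ pair + reward + PC1_size + PC2_size + (1|sp)` with Satterthwaite
F-tests and Nakagawa–Schielzeth R².

A synthetic community generator (`make_community()`) produces spectra, traits,
trees and pollinator body sizes with known ground truth — reward-specific
colour palettes, latent saturation/brightness axes, configurable
chromatic-contrast/flower-size and achromatic/display-size couplings, and a
Brownian component on a pure-birth phylogeny — so every stage of the pipeline
is testable without field data.

## Worked example

```r
library(beesignal)

community <- make_community(scenario_config(), seed = 42)  # paper-like study
study <- run_study(community$spectra, community$traits, community$tree,
                   config = list(n_perm = 999, chisq_B = 1e4,
                                 k_rand = 499, phylo_sims = 500),
                   seed = 42)
print(study)
```

```
== Reward-signal study ==
<analysis_subsets> size: 95 | color (all 4 modules): 74 | its: 35 species
<nested_pca>
  colour PCA (34 vars): first two PCs 43.4% (24.6 + 18.8)
  size PCA   (9 vars): first two PCs 87.0% (62.1 + 24.8)
  final PCA  (4 scores): PC1 38.4%, PC2 30.3%
  global PCA (43 vars): first two PCs 40.4%

PERMANOVA by reward (final PCA space):
  final_presence   F =  4.17  R2 = 0.11  p = 0.005
  final_type       F =  2.63  R2 = 0.13  p = 0.012

Chi-square (reward type x colour category):
  sepal     X2 =  95.58  p = <0.001
  petal     X2 =  92.08  p = <0.001
  lip_tip   X2 =  89.96  p = <0.001
  lip_base  X2 = 142.89  p = <0.001

Blomberg's K:
  PC1_final  K = 0.04  p = 0.710
  ...
Colour-size integration (OLS):
  PC1_color ~ PC1_size: R2 = 0.26, F = 25.88, p = <0.001
  ...
```

Reading this: the 95 synthetic species partition into the three analysis
subsets (95 with sizes, 74 with all four colour modules, 35 with pollinator
data). Species cluster by reward presence in the joint colour–size space
(PERMANOVA R² = 0.11, p = 0.005) and every module's colour category is
associated with reward type (chi-square p < 0.001) — the generator built those
associations in, and the pipeline recovers them. Blomberg's K near zero says
the PC scores carry little phylogenetic signal at the generator's 30 %
Brownian share, and the significant colour~size OLS reflects the configured
coupling of 0.5 between chromatic contrast and flower size (here expressed on
PC1_color, the axis that captured the chromatic latent in this draw).

Individual stages are exposed directly: `read_spectra()`, `viewing_context()`,
`quantum_catch()`, `hexagon_locus()`, `spectral_purity()`, `category_table()`,
`nested_pca()`, `permanova()`, `blomberg_k()`, `phyl_anova()`,
`integration_suite()`, `lmm_modularity()`.

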