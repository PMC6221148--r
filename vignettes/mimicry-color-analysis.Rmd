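---
title: "Receptor-noise modeling of mimetic wing colors: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Receptor-noise modeling of mimetic wing colors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mimicolor)
```

## The question

Müllerian comimics such as *Heliconius erato* and *H. melpomene* converge on
near-identical warning patterns. Whether their colors are *perceptually*
identical depends on the eye doing the looking: an ultraviolet-sensitive
(UVS) bird, a violet-sensitive (VS) bird, and a butterfly with duplicated UV
opsins each sample the same reflectance spectrum differently. mimicolor
implements the full chain needed to ask this question quantitatively —
spectra to quantum catches to noise-limited discrimination distances to
population statistics — plus the two satellite analyses that frame it:
typing predator visual systems from SWS1 opsin sequence, and testing with a
binomial GLM whether UV reflectance matters for mate choice.

## Receptor model

A receptor's stimulus estimate for a patch with reflectance $R(\lambda)$
under illuminant $I(\lambda)$ is the quantum catch

$$Q_i = \int R(\lambda)\, I(\lambda)\, S_i(\lambda)\, d\lambda,$$

integrated by the trapezoid rule on a 300–700 nm grid at 1 nm (dense and
uniform, so the rule is exact for piecewise-linear integrands; the range
covers both camera passbands, 320–380 nm and 400–680 nm, with margin).
Sensitivities $S_i$ are reconstructed from peak wavelengths with the
standard A1 visual-pigment nomogram (alpha plus beta band), peak-normalized;
the constants live in an injectable parameter set so other templates can be
substituted. Ocular media and oil droplets are not modeled: the red-shifted
*Heliconius* LW receptor is represented directly by its effective 600 nm
peak (vs 555 nm unfiltered), which is how the filtering pigments' effect is
conventionally summarized.

Catches are normalized von-Kries style, channel by channel, to the catch of
a flat 40% gray standard under the scene illuminant — mirroring the gray
standard photographed with every specimen — which makes the normalized
catches $q_i$ invariant to illuminant intensity. Receptor signals are
log-transformed, $f_i = \ln q_i$, the bright-light (Weber–Fechner) regime
appropriate for reflective targets in daylight.

## Discrimination distances

Chromatic distance uses the receptor-noise-limited model. Channel noise
scales with cone abundance, $e_i = \omega\sqrt{\eta_{\max}/\eta_i}$ with
Weber fraction $\omega = 0.05$ on the most abundant type, and

$$\Delta S^2 = \frac{\sum_{i<j}\big(\prod_{k \neq i,j} e_k\big)^2
  (\Delta f_i - \Delta f_j)^2}{\sum_i \big(\prod_{k \neq i} e_k\big)^2},$$

the general $n$-receptor quadratic form. The tests verify it reduces to the
familiar dichromat/trichromat/tetrachromat closed forms to $10^{-12}$ and
equals an independently coded matrix oracle (Mahalanobis distance under the
diagonal noise covariance, projected off the achromatic axis). Achromatic
contrast is the double-cone channel alone,
$\Delta S = |\Delta f_D|/e_D$ with $e_D = 0.05$ by default; butterfly
presets carry no double cone and achromatic operations reject them rather
than invent one. Distances above 3.00 JND (strictly greater; the boundary
itself is "not discriminable") are treated as distinguishable in natural
light.

Whether signals should be log or linear in the original toolbox run is not
decidable from the published description; log signals are used throughout
and flagged here.

## Visual-system presets

Cone proportions are the published values (blue tit LW 1, MW 0.99, SW 0.71,
UV 0.37; peafowl LW 0.95, MW 1, SW 0.86, V 0.45; *H. erato* female LW 1,
B 0.17, UV2 0.076, UV1 0.086; male LW 1, B 0.2, UV2 0.13), and the erato
peaks 355/398 nm (UV1/UV2) and 555/600 nm (green/red LW) are likewise
published. The remaining peak wavelengths (blue tit UV 371, SW 448, MW 503,
LW 563; peafowl V 432, SW 477, MW 537, LW 605; erato B 470) are package
defaults taken from the standard microspectrophotometric literature for
these species, stored in a human-editable CSV (`visual_presets.csv`) —
they are defaults, not claims, and any row can be overridden.

## Calibrated photography

The camera module simulates the UV-photography workflow: four sensor
channels (a UV channel confined to the 320–380 nm pass filter and broad
blue/green/red channels confined to 400–680 nm), a gamma response,
linearization, and normalization anchored so the gray standard reads
exactly its reflectance. The camera-to-cone-catch mapping is ordinary least
squares from normalized channel responses to gray-normalized catches over a
training library; the default design is linear with intercept (pairwise
products optional — on the wing-patch library the products improve bird
systems but slightly overfit the butterfly UV channels, so the simpler
model is the default). The training library (200 spectra) spans the four
patch color classes with broadened variation (amplitude CV 0.1, inflection
jitter 10 nm). One limitation is physical, not statistical: neither filter
transmits 380–400 nm, so receptors peaking there (erato UV2, 398 nm) are
poorly constrained and carry the largest per-channel errors, while the
pooled median held-out error stays within a few percent.

## Synthetic wing patches

The generator produces smooth reflectances: a sigmoid long-pass edge
(position, slope, plateau per color class) plus an optional UV Gaussian
lobe — yellow carries one by default, emulating UV-reflecting yellow
pigment. Individual variation has two components: a multiplicative
lognormal amplitude factor (CV 0.05 by default) and Gaussian jitter of the
edge position. The split matters: a pure amplitude change shifts all
log-signals equally and is invisible to the chromatic distance, so the
chromatic variability between conspecifics is carried by the edge jitter.
Red patches get larger edge jitter (8 nm vs 2–4 nm) to emulate the strong
age-related fading of red pigment. Between-species divergence is a
controllable shift of the edge position (and optionally UV lobe amplitude)
applied to one species.

Two scenario parameters are set by bisection against the model itself
(`calibrate_ring_scenario()`): the conspecific jitter to hit a mean
conspecific distance of ~1 JND and the species shift to hit a mean comimic
distance of ~6 JND under the UVS bird model (achieved: 0.97 and 6.02 at
jitter 2.20 nm, shift 15.2 nm). Sample sizes default to 10 individuals per
species, matching the smaller specimen series of the study system. What
the generator does *not* emulate: iridescence, spatial pattern, pixel-level
texture, specular effects, and fluorescence — conclusions from passing
tests are about the modeling chain, not about real wings.

## Statistics

Pairwise chromatic distances are computed for every cross-species
("comimic") and within-species ("conspecific") pair in each patch-color ×
wing-side stratum, averaged per individual and pair type, square-root
transformed (after averaging), and compared with the balanced two-level
within-individual ANOVA: $F = \mathrm{MS}(\text{pair type}) /
\mathrm{MS}(\text{pair type} \times \text{individual})$ with df $(1, n-1)$,
which in this design equals the squared paired $t$ statistic. Strata are
tested independently with no multiplicity correction (none is applied in
the source analysis — bear this in mind when reading many strata at once).
For the butterfly visual systems, conspecific pairs are restricted to the
erato-like species, since the visual data come from that clade.

A caveat this package's own simulations expose: the design's unit of
replication is compromised. Each individual's comimic mean shares
comparison partners with every other individual's, and chance divergence
between the two species' *samples* inflates all comimic distances
simultaneously — distances are nonnegative, so the effect cannot average
out. On simulated true nulls the nominal 5% test rejects at roughly 12–18%,
a rate that does not shrink with more individuals, and an abstract
reduction (absolute differences of two identical Gaussian samples) shows
the same inflation with no color modeling involved. The F engine itself is
exactly calibrated on independent paired tables; the anticonservatism is a
property of distance-based comimic designs generally, and p-values near the
threshold should be read accordingly. A within-individual permutation test
is provided as a companion but shares the limitation.

The mate-choice analysis aggregates each male's events per treatment
(successes = events toward the comimic female model), then fits a binomial
GLM with logit link by iteratively reweighted least squares, weighted by
each male's event total; convergence at coefficient change $< 10^{-10}$ or
50 iterations, Wald $z$ with two-sided normal $p$. Designs are explicit:
intercept-only, treatment, or treatment × behavior on the stacked
approach/courtship table (the exact published model formula is not printed;
per-behavior treatment fits are the default here). Separation is flagged,
not hidden. The published per-male counts are unavailable, so the default
simulated scenario reproduces the experiment's scale (41 males, ~709
approaches, ~62 courtships) for smoke testing, not its test statistics.

## Opsin classification

The SWS1 window is the 11 residues at bovine-rhodopsin positions 84–94.
The call is UVS iff site 90 is cysteine or site 86 is phenylalanine,
otherwise VS — the minimal rule consistent with all eight packaged
reference windows and the spectral-tuning mutagenesis literature; site 93
is carried in the data model but unused by the default rule. Nucleotide
input is translated with the standard code (frame chosen automatically as
the first without internal stops); window location uses an explicit offset
(fragments) with the 11-mer directly addressable.

## Numerical and degenerate-input choices

* Resampling is linear interpolation; outside the source support the
  policies are explicit (`error`, `zero`, `hold`), never silent.
* The nomogram argmax is guaranteed only to within one grid step of the
  nominal peak (at 355 nm the beta band pulls the discrete argmax to
  354 nm on a 1 nm grid).
* Zero catches for the gray standard, nonpositive normalized catches under
  a log, missing achromatic channels, rank-deficient camera designs, and
  GLM separation all produce typed errors or flagged results rather than
  NaN propagation.
* Predicted catches from the camera mapping that come out nonpositive are
  clamped to $10^{-6}$ with a warning, since downstream takes logs.
* All generators are pure functions of an explicit seed and restore the
  caller's RNG state.

## Problem sizes

The shipped analyses and tests run at desk scale: rings of 10 + 10
individuals over up to four strata, 200-spectrum training libraries,
200-replicate power/size runs, 500-replicate GLM recovery runs, and
2000-replicate engine calibration runs. These sizes were chosen so each
property being estimated (a rejection rate, a coverage, a median error)
has Monte-Carlo noise comfortably below the bands asserted on it.
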