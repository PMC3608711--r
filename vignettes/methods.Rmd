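---
title: "Dark-field emphysema analysis: models, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dark-field emphysema analysis: models, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(darklung)
```

## The imaging model

A Talbot grating interferometer converts refraction and small-angle
scattering in the object into measurable changes of a per-pixel sinusoid.
Stepping one grating across one period while recording frames yields, per
pixel, a stepping curve

$$I_k = a_0\,\bigl(1 + v\,\cos(2\pi f_k + \varphi)\bigr),$$

whose mean $a_0$, relative modulation $v$ (the *visibility*) and phase
$\varphi$ are estimated by discrete Fourier analysis: $a_0$ is the curve
mean, $a_1 = |(2/N)\sum_k I_k e^{-2\pi i f_k}|$ the first-harmonic
amplitude, $v = a_1/a_0$. Comparing a sample scan against a sample-free
reference scan gives three contrast channels:

* transmission $T = a_0^s/a_0^r$ — the conventional radiograph;
* dark-field $V = (a_1^s/a_0^s)/(a_1^r/a_0^r)$ — the relative loss of
  visibility, driven by small-angle scattering from structures below the
  system resolution (alveoli, at ~10–100 µm, are far below the 127 µm
  pixels);
* differential phase $\Delta\varphi = \varphi^s - \varphi^r$, carried
  through retrieval but not analyzed further (mirroring practice for this
  application, where the phase channel adds nothing for parenchyma
  assessment).

For uniformly spaced steps over exactly one period the DFT estimator is
*exact* on noiseless single-harmonic curves, which is why it is the
estimator of choice over iterative sinusoid fitting; the test suite keeps
a direct least-squares fit as an independent oracle and checks agreement
to at least six digits.

Both channels are normalized against a water bath (dividing by the median
over a water ROI), so water reads $T = V = 1$.

## The normalized-scatter statistic

Emphysema destroys alveolar walls: fewer air–tissue interfaces per unit
thickness means *less* scattering, but also *more* transmission (less
tissue). Each single channel confounds tissue property with path length,
because both $\ln T$ and $\ln V$ scale linearly with the thickness of
traversed lung. Their ratio does not. With a background correction $c$
for the specimen container,

$$S = \frac{-\ln V}{\ln T - c}$$

is independent of sample thickness and measures scattering strength per
unit of (background-corrected) attenuation. $c$ is estimated as
$\ln(\bar T_{\mathrm{formalin}}/\bar T_{\mathrm{water}})$ from ROIs in
the formalin background inside the container and in the surrounding water
bath — the container's plastic wall makes the formalin background
transmit slightly more than open water. Estimates from all projections of
a specimen are averaged.

Numerical guards: $S$ is only evaluated where $\ln T - c > \varepsilon$
(default $\varepsilon = 10^{-4}$); pixels failing the floor are counted
and excluded rather than allowed to produce exploding or negative values.
The interpretation of "ROI values were averaged" is the arithmetic mean
of $T$ within each ROI followed by one log-ratio; the alternative
(mean of logs) differs at order of the ROI variance, which is negligible
here.

## The synthetic cohort

No raw data from the original ex-vivo experiment is public, so the
package ships a calibrated simulator. The default cohort reproduces the
study layout: 3 emphysema + 3 control specimens, 11 projections each, 16
phase steps, with a two-lobed elliptical lung inside a formalin-filled
container in a water bath, imaged at 128×128 pixels (a working size that
keeps a full cohort in seconds of runtime and tens of megabytes; the
native detector frame is not needed to exercise any part of the method).

Per lung pixel the generator draws two independent fields:

* $u = \ln T - c$, the log-transmission excess, calibrated so that the
  quartiles of $e^{u+c}$ equal the printed per-pixel transmission
  quartiles of each group (emphysema 1.07/1.11/1.17, control
  1.04/1.06/1.10);
* $s$, the true normalized scatter, calibrated to the printed scatter
  quartiles (4.1/4.9/5.8 vs 7.5/10.8/14.7).

The true dark-field is then $V = e^{-s u}$. The dark-field medians are
deliberately *not* a free parameter: with independent $u$ and $s$,
medians multiply on the log scale, and both groups land at
$V \approx 0.66$ — exactly the "no difference in dark-field medians"
observation, which falls out of the calibration as a consistency check.

Two design choices deserve explanation:

* **Two-piece log-normal marginals.** A plain log-normal has two
  parameters and cannot match three quartiles; the printed triples are
  clearly asymmetric (e.g. control $u$ quartiles 0.019/0.038/0.075). Each
  marginal is therefore a split log-normal — $\ln X$ Gaussian with
  separate scales below and above the median — which matches all three
  quartiles exactly and stays positive.
* **Gaussian-copula textures.** Spatial correlation (Gaussian low-pass,
  $\sigma = 3$ px) makes the maps look anatomical rather than like salt
  noise. Smoothing is applied to a latent Gaussian field whose *ranks*
  are then pushed through the split-log-normal quantile function, so the
  marginal distribution is imposed exactly per projection. Simple
  variance re-standardization after smoothing would leave the marginal
  quartiles fluctuating by several percent at realistic pixel counts,
  because a $\sigma = 3$ correlation length reduces $10^5$ pixels to
  under $10^3$ effective samples; the copula construction removes that
  failure mode entirely.

The forward model builds reference curves
$I_k = I_0(1 + V_0 \cos 2\pi f_k)$ (flux $I_0 = 1000$ counts/pixel/frame,
reference visibility $V_0 = 0.3$) and sample curves attenuated by
$T = e^{u + c}$ and de-modulated by $V$ per pixel, with $c = 0.02$ inside
the container; per-frame Poisson noise is the default. The flux default
is a choice, not a printed value: it puts the per-pixel transmission
noise ($\sigma_T \approx T\sqrt{2/(N I_0)} \approx 0.011$) well below the
0.05 group separation in $T$. Every stochastic stage draws from a
substream seeded by hashing (master seed, stage, specimen, projection),
so any phantom is reproducible in isolation and cohorts are bit-identical
across runs.

What the phantom does **not** emulate: ribs, fur, breathing motion,
detector point-spread, beam polychromaticity, or the true joint spatial
distribution of real parenchyma. Passing tests demonstrate that the
*pipeline machinery* is correct and that the statistic behaves as
designed under the printed marginal distributions — they say nothing
about real-data discrimination levels, which depend on joint
distributions the publication does not report (its real-data AUCs and
sensitivities are therefore not reproduction targets; only orderings and
qualitative structure are checked).

## Segmentation

Lung tissue is isolated on the dark-field channel, where it contrasts
most strongly with the background ($V \approx 1$ for water and formalin):
the mask is $V < t$ with $t$ at the histogram valley between the
background mode and the lung signal — the algorithmic counterpart of the
original visually chosen threshold. The estimator histograms valid $V$
values (256 bins), smooths with a 5-bin moving average, and takes the
minimum between the primary mode and the highest sufficiently distant
secondary mode. Three guards make this robust: a minimum mode separation
(32 bins), a minimum mass fraction on the secondary side (2%), and a
maximum valley height relative to the primary peak (40%) — without them,
noise wiggles or tail spikes on a *unimodal* histogram masquerade as
second modes. If no acceptable valley exists the estimator falls back to
Otsu's criterion with a warning (or errors if the fallback is disabled);
a `manual` override exists for external data. Components smaller than 20
pixels are removed, which also strips most of the trachea and main
bronchi. One mask indexes all channels, keeping per-pixel $T$, $V$, $S$
vectors aligned.

A consequence worth understanding: under the calibrated marginals the
control group's dark-field distribution (printed IQR 0.48–0.85) overlaps
the background band, so a threshold that excludes background necessarily
truncates part of the control lung. Statistics pooled over *segmented*
pixels therefore shift relative to the calibrated marginals (kept $V$
medians move down, kept $T$ and $S$ medians move up). The report carries
two tables: `summary_per_pixel` (segmented pixels — what an analyst of
real data would report) and `recovery` (medians over the phantoms' true
lung masks — the segmentation-independent parameter-recovery check that
the acceptance script uses). At the default flux the recovery medians hit
their calibration targets within about a percent, with one exception the
test suite documents: the control group's $S$ median sits a few percent
low, because the denominator noise $\sigma_{\ln T} \approx 0.011$ is a
third of that group's median $u = 0.038$ and the $\varepsilon$-floor
skews which pixels survive. This is a property of per-pixel ratio
statistics at this flux and group contrast, not an implementation defect;
it disappears when noise is disabled.

## ROC analysis and cutoffs

Discrimination between emphysematous and healthy tissue is quantified by
empirical ROC curves per parameter, per-pixel (units = segmented pixels,
pooled over all projections — pixels are treated as independent, an
assumption the report flags since overlapping anatomy is counted
repeatedly) and per-individual (units = specimen medians; with 3 vs 3
specimens the AUC lives on a grid of ninths, which the report also
warns about). Orientations: higher $T$ indicates disease (less tissue),
lower $S$ indicates disease (less scatter per unit thickness); $V$ is
included with a configurable `greater_is_diseased` default even though
its discrimination is near chance by construction.

The AUC is the trapezoidal area, identical (to $10^{-12}$, tested) to
the tie-corrected rescaled Mann-Whitney statistic. Paired AUCs are
compared with DeLong's asymptotic variance of the structural components,
computed with midranks so the per-pixel analysis stays
$O(n\log n)$; a stratified bootstrap serves as the variance oracle in
tests, and `pROC` as an independent implementation cross-check.
"Optimal" cutoffs are operationalized as the Youden point (maximum
sensitivity + specificity − 1; an AUC cannot itself select a threshold),
with ties broken toward higher specificity and the returned cutoff
placed at the midpoint of the score gap. The published per-pixel cutoffs
(T 1.087, V 0.715, S 7.00) and control IQRs (0.06, 0.37, 7.2) are
available as presets for mapping external data; the published table also
prints AUC values that disagree with the same publication's text, so
those numbers are exposed as presets only and never asserted.

## Parametric emphysema maps

For each parameter, the signed deviation of each segmented pixel from
the cutoff *toward the emphysematous direction* is divided by the
control-group IQR of that parameter and clipped to $[0, 1]$ — zero to
one "control IQRs of abnormality". Healthy-direction deviations render
as 0, so only disease-like tissue is color-coded. The overlay draws a
1st–99th-percentile windowed grayscale transmission background and
alpha-blends a yellow-to-red ramp, with blend weight proportional to the
deviation (floor 0.35 so faint abnormality remains visible); colormap,
floor and windowing are conventions chosen for determinism and
visibility, all configurable. By default the control IQR comes from the
current run's pooled control pixels (a global pool, not per specimen)
and cutoffs from the run's own ROC stage.

## Problem sizes and determinism

The default cohort (6 specimens × 11 projections × 128² × 16 steps,
Poisson noise) runs the full pipeline in well under a minute on one core;
the test suite runs it once and shares the result across acceptance
checks. Marginal-calibration tests pool more than $10^5$ lung pixels at
512² resolution. Everything is deterministic given the config seed:
reports are byte-stable, file manifests carry md5 checksums, and the
suite verifies two runs produce identical output files.

## Known limitations

* Per-pixel significance tests and DeLong comparisons treat pixels as
  independent; spatial correlation within specimens makes the reported
  p-values optimistic. A clustered bootstrap would be the fix and is out
  of scope.
* The dark-field segmentation cannot recover lung pixels whose true $V$
  lies in the background band; with the printed control-group marginals
  that is a two-digit percentage of control lung area (the test suite
  measures the consequences; see the segmentation section).
* $S$ may be influenced by lung volume (inflation state); the simulator
  holds volume fixed and the pipeline makes no correction.
* The simulator's independence of $u$ and $s$ within a group is an
  assumption of convenience; only marginals are calibrated.
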