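---
title: "Methods: mapping chemogenetically evoked BOLD responses with chemomap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: mapping chemogenetically evoked BOLD responses with chemomap}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The experimental design this package analyzes

chemomap analyzes pharmacological fMRI (phMRI) experiments in which the
stimulus is a drug injection rather than a timed task. The motivating
design is chemogenetic: rats express an engineered excitatory receptor
(hM3Dq, a DREADD) in a genetically defined neuron population of the
ventral tegmental area (VTA); mid-scan, the designer ligand clozapine
N-oxide (CNO) is injected intraperitoneally and activates exactly those
neurons, and the evoked blood-oxygenation-level-dependent (BOLD)
response is mapped brain-wide. Control runs receive saline instead.

The default timeline mirrors that protocol: 65 volumes per run, 25
pre-injection volumes of which scans 5–25 form the baseline window
(the first scans are discarded as unsteady), injection after volume 25,
and 40 post-injection volumes. Because the drug response develops
slowly — rising from roughly scan 35 and plateauing near scan 40 — the
late window of volumes 45–65 is treated as the activation phase. All
window configuration uses 1-based inclusive scan indices, the
convention in which such protocols are reported; conversion to R's
internal indexing happens in exactly one place (`window_indices()`).

## Pipeline stages

**Normalization.** Each voxel's series is expressed relative to its
baseline-window mean $B$: percent change $100\,(S - B)/B$, or the
ratio scale $S/B$. The two are related by the exact identity
$\mathrm{ratio} = 1 + \mathrm{percent}/100$, and `convert_scale()`
moves between them at machine precision. A voxel with non-positive
baseline inside the brain mask is a hard error (it indicates a masking
or acquisition problem), never a silent `NaN`.

**Smoothing.** Spatial smoothing uses a separable Gaussian kernel with
full width at half maximum equal to twice the voxel size per axis by
default, truncated at $4\sigma$. It is *mask-aware*: the smoothed
image is $\mathrm{smooth}(f \cdot m) / \mathrm{smooth}(m)$ for brain
mask $m$ (normalized convolution), so constant fields are preserved
exactly at mask edges and no out-of-brain zeros bleed into cortex.
This renormalization necessarily trades away exact conservation of the
in-mask volume mean at edges — the two properties are mutually
exclusive on a bounded domain — and we follow the neuroimaging
convention of preserving constants. Mass is conserved exactly wherever
the signal sits at least two kernel radii from the mask boundary, and
the test suite checks precisely that.

**Voxel-wise statistic.** The per-run statistic is the area under the
percent-change curve over the activation phase, by the trapezoid rule
at unit scan spacing (21 samples, 20 intervals; a plain-sum rule is
available — for a fixed window the two are monotone transforms of each
other, and "area" reads as trapezoid). CNO and saline AUC maps are
then compared voxel-wise with a two-sample t-test. The default is the
classical unpaired pooled-variance test with $df = n_A + n_B - 2$ —
the plain reading of a two-group voxel comparison — with Welch and
paired designs available by flag; the acceptance simulations use the
unpaired default. Zero-variance voxels yield `NA` statistics with a
reported count rather than an error, since a phantom background can be
exactly constant.

**Thresholding.** Two map thresholds are produced, matching how such
results are reported: Benjamini–Hochberg FDR at $q \le 0.05$
(`threshold_fdr()`), and an uncorrected $p < 0.001$ map
(`threshold_uncorrected()`, strict inequality) used to limit false
negatives when the corrected map is too conservative. Both default to
positive responses only ($t > 0$), because activation maps report
signal increases; signed variants are a flag away. The BH step-up
itself is delegated to `stats::p.adjust(method = "BH")` behind the
`bh_fdr()` surface and cross-checked in the tests against an
independent rank-enumeration oracle. `NA` p-values (out-of-mask,
zero-variance) are excluded from the family, not counted in $m$.

**ROI response curves.** For each significant region the mean time
course is extracted and fitted by nonlinear least squares
(Levenberg–Marquardt via minpack.lm) to the sigmoid

$$f(x) = d + \frac{a}{1 + e^{\,b\,(c - x)}}$$

over all 65 volumes — the pre-injection plateau is what anchors the
offset. On the ratio scale the offset is fixed at $d = 1$, so the
model's lower asymptote is exactly the unit baseline and the fitted
plateau is $1 + a$; on the percent scale $d = 0$ and the increase
value scales as $a_{\%} = 100\,a_{\mathrm{ratio}}$. We fix $d$ rather
than fit it (a free-offset variant exists) because the model is
defined with a unit baseline, and we constrain $b > 0$ so that the
response sign is carried by $a$ alone — otherwise simultaneous sign
flips of $(a, b)$ are unidentifiable. Starting values are
$a_0 = \overline{y}_{\mathrm{act}} - \overline{y}_{\mathrm{base}}$,
$b_0 = 1$, and $c_0$ at the first post-injection crossing of the
half-rise level (falling back to the midpoint between injection and
the activation window); if the initial Jacobian is singular the fit
retries from coarser starts before reporting `converged = FALSE`.
Exactly flat series short-circuit to $a = 0$. Fits are per subject —
group testing of increase values needs per-subject estimates to have
degrees of freedom — and saline runs, while fittable, are unused by
the default report.

**Comparison matrices and conjunction.** Increase values are compared
pairwise across regions with two-sided pooled t-tests (stars at
$p < 0.05$ and $p < 0.01$; no multiplicity correction by default, as
such matrices are conventionally reported raw — a BH option exists),
and across the two stimulation experiments region by region. The
conjunction map classifies each voxel as responding in neither, one,
or both experiments; it is a mask intersection/union, deliberately not
a minimum-statistic conjunction test, because the question it answers
is "which significant voxels coincide". It defaults to the
uncorrected masks: in the motivating data the multi-region map of the
dopaminergic experiment only appears without correction, so a
conjunction meant to reproduce the reported overlap must use that
rule. The region overlap report distinguishes voxel-level overlap
(`any_both`) from region-level co-activation (`coactive`) — a region
can respond in both experiments without sharing a single voxel, and
the two notions are surfaced separately for that reason.

## The synthetic phantom

Because the motivating datasets are available only on request, the
package ships a deterministic phantom generator that emulates the
acquisition rather than any particular dataset. A 32×32×16 grid at
0.354×0.354×0.8 mm (the stated in-plane resolution and slice
thickness) holds ten disjoint box regions named for the reported
responsive areas, inside an ellipsoidal brain mask of non-responsive
tissue. Every voxel carries a constant baseline intensity
$B_0 = 1000$ arbitrary units; under CNO, voxels of responsive regions
are multiplied by the sigmoid response; optional linear drift and
Gaussian noise (SD = `sigma_frac`·$B_0$, optionally AR(1)-filtered)
are added on top.

Defaults, chosen once to match the qualitative description of the
motivating experiment and held fixed: rate $b = 0.8$/scan and
midpoint $c = 38$, which places the rise onset near scan 35 and the
plateau near scan 40; amplitudes $a \in [0.01, 0.05]$ (1–5% BOLD-scale
responses), with the dopaminergic-like cohort (n = 5) planting
VTA 0.05 > Cg 0.03 > mPFC = Septum 0.02 and the CamKII-like cohort
(n = 4) planting ten regions with VTA and Cg at 0.05, mPFC and Septum
at 0.04, and the rest at 0.03 — encoding the reported orderings (VTA
strongest under dopaminergic stimulation; the shared regions except
VTA stronger under CamKII stimulation; planted overlap {VTA, mPFC,
Cg, Septum}). Noise defaults to `sigma_frac = 0.01` with no drift and
white temporal noise, a conservative stand-in since no noise model is
reported. Per-run seeds are derived by hashing (genotype, subject,
condition) into the base seed, so adding subjects or cohorts never
reshuffles existing runs, and CNO/saline runs of a subject are paired
by subject index while drawing independent noise streams.

What the phantom deliberately does *not* model: hemodynamic
convolution, physiological (cardiac/respiratory) confounds, motion,
inter-subject amplitude variability, and spatial noise correlation.
Passing tests therefore demonstrate that the statistics are correctly
computed and calibrated under the stated noise model — not that the
pipeline is robust to artifacts real rat data would add. Registration
is likewise out of scope: inputs are assumed spatially aligned (true
by construction for phantoms), and real-data users should slot their
own realignment upstream.

## Numerical choices and problem sizes

Arithmetic is double precision throughout. The sigmoid evaluation
saturates at its asymptotes for extreme exponents instead of
overflowing. Undefined values are `NA`/NaN in images and empty cells
in TSV. NIfTI I/O (via RNifti) writes 64-bit floats, so
write-then-read round-trips are bitwise exact; TSV numerics are
written at 17 significant digits for the same reason.

The test and calibration problem sizes were chosen to exercise every
code path at desk scale: the null-calibration simulation uses 500
replicates of two n = 5 groups over 10,000 voxels (under the global
null the family-wise BH rejection rate equals the nominal level by
Simes' identity, so the check allows three binomial standard errors of
Monte-Carlo slack); parameter recovery uses 200 replicates at
0.2%-of-baseline noise plus a 12-point (a, b, c) grid; the end-to-end
check runs both default cohorts — 18 four-dimensional runs — through
the complete pipeline.

## Known limitations

Increase values estimated from smoothed images are attenuated relative
to the planted amplitudes (smoothing mixes region voxels with
surrounding tissue), uniformly enough that orderings and group
contrasts survive; fits on unsmoothed data recover the amplitudes to
solver precision. Pairwise comparison matrices on phantom cohorts
yield extremely small p-values because the phantom has no
inter-subject amplitude variability. The conjunction's uncorrected
default means isolated false-positive voxels (at rate
$p_{\mathrm{unc}}/2$ per null voxel) can in principle land inside a
region active in only one experiment; at the default thresholds and
grid this is rare but not impossible.
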