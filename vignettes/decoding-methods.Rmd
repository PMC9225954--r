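---
title: "Cross-decoding, temporal generalization and EEG-fMRI fusion: methods"
author: "mvpaFuse"
output: rmarkdown::html_document
vignette: >
  %\VignetteIndexEntry{Cross-decoding, temporal generalization and EEG-fMRI fusion: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(mvpaFuse)
```

## The scientific problem

When an object appears in a visual scene, the brain must represent not
only *what* it is but *where* it is. On a blank background, object
location maps retinotopically onto early visual cortex and can be read
out directly; in a cluttered scene, large parts of early visual cortex
respond to the background as well, and a location signal that is
*tolerant* to object identity and clutter has to be constructed.
`mvpaFuse` implements the multivariate analysis pipeline used to ask
where (fMRI), when (EEG) and along which processing hierarchy (layered
feature models) such tolerant representations emerge: cross-decoding of
one stimulus factor across another, time-resolved and temporally
generalized classification, voxel- and sensor-space searchlights,
representational-similarity fusion of EEG and fMRI, and the group-level
inference around them. A synthetic-data generator with planted,
configurable signals makes every stage testable end to end with known
ground truth.

## The experimental design

The pipeline assumes a fully crossed design with factors of object
category (default: animals, cars, faces, chairs; three exemplars each),
object location (four screen quadrants, object centres 3 degrees visual
angle from each central midline, i.e. 4.2 degrees eccentricity) and
background clutter (none / low / high). This yields 48 category-level
and 144 exemplar-level conditions. `designSpec()` encodes the design;
`enumerateConditions()` expands it in a fixed canonical order (clutter
slowest, then location, then category) that every condition axis in the
package shares — this shared ordering is what makes representational
dissimilarity vectors comparable across modalities.

## Cross-decoding

The central statistic is pairwise cross-classification accuracy. To
decode location tolerant to category, a binary linear classifier is
trained to discriminate a pair of locations using data from one
category only and tested on data from a *different* category; accuracy
above the 50% chance level then reflects a location code that
transfers across categories. With four locations and four categories
the scheme has 6 location pairs times 12 ordered (train, test) category
pairs = 72 cells (`buildPairScheme()`, `schemeCellCount()`); reported
accuracies are means over all cells.

All classification uses binary C-support-vector machines with a linear
kernel (libsvm via `e1071`), regularization constant `C = 1`, no
feature scaling, and deterministic behavior given the training data.
The package applies the fitted weight vector directly to test patterns;
this is algebraically identical to `predict()` on the model (asserted
in the test suite) and avoids per-call overhead in the innermost loop.

Signal-to-noise is raised before classification by averaging raw trials
into *pseudo-trials* (`binPseudoTrials()`): EEG trials of each
condition are randomly assigned to 4 bins (60 trials to 4 bins of 15
under the default design) and averaged; training uses 3 pseudo-trials
per class, testing the remaining one; the random assignment is repeated
(100 iterations by default), giving 7,200 averaged accuracies per time
point. fMRI runs are binned analogously into 5 pseudo-runs of 2 runs,
followed by five-fold leave-one-pseudo-run-out cross-validation (6 x 12
x 5 = 360 accuracies per ROI). Train/test separation is structural: the
tested pseudo-trial's bin never contributes raw trials (or runs) to the
training side.

`crossDecodeTimecourse()` applies the scheme per EEG time point,
`crossDecodeROI()` per voxel set, `crossDecodeFeatures()` per layer of
a feature hierarchy; `target = "category"` swaps the factor roles to
decode category tolerant to location.

## Multivariate noise normalization

EEG channels are whitened with the inverse square root of the channel
covariance of within-condition residuals, pooled over time points and
conditions (`noiseNormalize()`). The covariance is shrunk analytically
toward a scaled identity with a Ledoit-Wolf-style intensity estimated
from the same residuals, so the estimate is invertible even with few
trials. Whitening downweights directions dominated by spatially
correlated noise; on synthetic data with correlated noise it restores a
near-identity residual covariance and does not hurt decoding.

## Searchlights

`searchlightVolume()` repeats the ROI analysis inside a sphere of
radius 4 voxels (257 lattice points; radius in voxel units on grid
coordinates) centred on every voxel, storing the accuracy at the
centre. `searchlightChannels()` is the sensor-space analogue: the time-
resolved analysis restricted to the `k = 5` channels closest to each
channel, after down-sampling the time axis to 10 ms bins. Reading the
neighborhood definition strictly ("the closest channels surrounding a
channel"), the centre channel itself is excluded by default; an
`includeCenter` flag preserves the alternative since either reading is
defensible. Voxel selection for ROI definitions (the "most activated"
localizer voxels) is provided by `selectTopKVoxels()` with a
deterministic tie-break by ascending grid coordinate.

## Temporal generalization and peak statistics

`temporalGeneralization()` trains the scheme at every time point of one
condition (no clutter, by default reading) and tests at every time
point of another (high clutter) on a uniform grid (10 ms steps over
-100...600 ms; 71 x 71 entries). The grid points are the native samples
nearest the requested grid; down-sampling elsewhere
(`downsampleTime()`) uses non-overlapping bin means labelled by bin
centers, which is more noise-robust than decimation.

The signed peak-to-diagonal statistic (`peakToDiagonal()`) locates the
post-stimulus maximum at coordinates (pX, pY) (test and train time),
takes the nearest diagonal point bX = (pX + pY)/2, and reports
d = sqrt((pX - bX)^2 + (pY - bX)^2), multiplied by -1 when pX < pY.
Positive d means the training-condition code generalizes to *later*
test times — the signature of a delayed but shared processing stage.
The peak search window defaults to the post-stimulus range (0-600 ms)
because pre-stimulus maxima are necessarily noise; exact ties are
broken to the entry closest to the diagonal (conservative for the
below-diagonal claim), then to the earliest train time, and flagged.
`diagonalDifference()` gives the time-resolved counterpart: each entry
minus its mirror across the diagonal, an exactly antisymmetric matrix.

## EEG-fMRI fusion

For fusion, the 72 cell accuracies are kept unaveraged as a
representational dissimilarity vector (RDV; `buildRDV()`): accuracies
are used directly as dissimilarities, on the assumption that two
conditions classify more easily the more dissimilar their
representations are. The canonical entry order — location pairs in
design order, then unordered category pairs, each in both train/test
directions — is an artifact convention (the enumeration of the 72 cells
is not uniquely dictated by the 6 x 12 and 6 x 6 x 2 descriptions,
which coincide numerically); what matters is that both modalities use
the identical order, which the package guarantees by constructing both
from the same scheme object. EEG RDVs are averaged over the time points
inside the bootstrap confidence interval of the group peak latency and
then over subjects (`eegPeakRDV()`); fusion is the Spearman rank
correlation with subject-specific fMRI ROI RDVs (`fuseRDVs()`), one
value per subject, ROI and clutter level.

## Group inference

Group tests are non-parametric: two-tailed Wilcoxon signed-rank tests
against chance (50% accuracy, zero correlation or distance), with the
`stats::wilcox.test` conventions — exact null distribution for small
samples without ties, continuity-corrected normal approximation
otherwise, zero differences dropped. Multiple comparisons are
controlled with Benjamini-Hochberg FDR at q = 0.05 (`fdrCorrect()`);
the plain step-up procedure is used, not the Benjamini-Yekutieli
variant. Effect sizes follow the standard formulas: partial eta squared
= SS_effect / (SS_effect + SS_residual) for ANOVA effects (ANOVA
fitting itself is left to base R's `aov` and friends and is out of the
package's scope) and r = Z / sqrt(N) for signed-rank tests.

Bootstraps resample subjects with replacement, 10,000 times by default:
percentile (not BCa) 95% confidence intervals for peak latencies
(`bootstrapPeakCI()`), paired resampling for latency differences with a
one-tailed p as the proportion of resampled differences at or below
zero (`bootstrapDifference()`), and a label-shuffle null for the
distance between group searchlight peaks
(`bootstrapSearchlightPeakDistance()`), implemented as per-subject
random swaps of the two condition maps with the group peak taken from
the subject-mean accuracy map. A caveat discovered while validating
this last statistic on planted data: because per-subject swaps produce
complementary mixtures of the two condition maps, the shuffled group
maps still peak at the two planted bump sites, so when the true peaks
genuinely differ the null distance distribution concentrates near the
observed distance itself and the test is extremely conservative. The
implementation follows the swap-null definition faithfully and the test
suite asserts its exchange properties and its behavior under the null,
rather than a power claim the statistic cannot deliver.

## The synthetic-data generator

`generateEEG()`, `generateFMRI()` and `generateFeatures()` produce data
with planted ground truth under a shared model: every signal component
is a spatial pattern times (for EEG) a Gaussian temporal bump, with
latency (the bump mean), width (full width at half maximum), amplitude,
and an *invariant fraction* — the proportion of a location pattern
shared across categories (and vice versa). The invariant fraction is
the construct cross-decoding measures: setting it to zero abolishes
cross-decoding while leaving within-category decoding intact, and the
test suite verifies exactly this separation.

Defaults encode the qualitative structure of the motivating findings as
study conditions: EEG location signals peak at 140 / 133 / 317 ms for
no / low / high clutter (63 channels, 1 kHz, epochs -100...999 ms; 20
runs of the 144 exemplar-level conditions, hence 60 trials per
category-level condition); the fMRI map (10 runs, 48 condition-wise
t-value patterns, two 325-voxel ROIs) plants location SNR of 3 / 1.5 /
0 in the early-visual-like ROI and a clutter-tolerant 2 in the
object-selective ROI, values calibrated once so group-mean ROI
accuracies land in the 55-70% range typical of such experiments; the
four-layer feature generator plants high-clutter location separability
increasing along the hierarchy (0.1, 0.5, 1, 2) and uniformly high
separability without clutter. Noise is spatially correlated across
channels (exponential decay on the cap layout, neighbor correlation
0.3) and temporally smoothed (10 ms moving average), giving noise
normalization something real to remove. Simulated subjects are
independent seeds derived from a root seed; all generation is
bit-reproducible given the configuration and seed.

What the generator does *not* emulate: forward-modelled EEG (lead
fields, reference montages), haemodynamic convolution or GLM fitting
(t-value patterns are simulated directly, since the decoding consumes
t-maps), eye movements and artifacts, inter-subject anatomical
variability, or unbalanced trial counts after artifact rejection.
Passing tests therefore demonstrate that the *pipeline* recovers
planted effects of realistic size and structure — not that any
particular real dataset contains them.

## Numerical and design choices

- **Seeds.** Every stochastic function takes an explicit seed and
  restores the caller's RNG state (`withSeed()`); stage seeds derive
  deterministically from a root seed (`deriveSeed()`), so pipeline
  reruns are byte-identical.
- **Binning.** Random near-equal bins within condition; pseudo-run
  binning is fixed once per subject and seed and shared across
  searchlight spheres (re-randomizing per sphere would only inflate
  variance).
- **Unbalanced data.** Real datasets lose trials to artifact
  rejection; the decoders require at least as many trials as bins per
  condition and balanced designs are recommended, since balance
  protects the 50% chance level.
- **Degenerate inputs.** One-class training sets, constant RDVs
  (undefined rank correlation), empty peak windows, infeasible binning
  and top-k selections beyond the mask raise informative errors rather
  than returning silently biased values.
- **Tie-breaks.** Peak latency ties go to the earliest time point;
  matrix-maximum ties to the entry nearest the diagonal, then earliest
  train time (flagged); voxel-statistic ties to ascending coordinate.
- **Problem sizes.** The test suite and the acceptance script run the
  full algorithms at reduced scale — typically 8-16 channels sampled at
  50-100 Hz, 4-6 runs, ROIs of tens of voxels, 1-7 binning iterations,
  and groups of up to 20 simulated subjects — chosen so parameter
  recovery is well-powered while the whole suite completes in minutes
  on one core. The statistics of interest (counts, chance levels,
  planted latencies and orderings) are scale-invariant; the defaults
  above remain the full-size study conditions.

## Known limitations

- The channel searchlight assumes a meaningful 2-D layout; with the
  synthetic concentric-ring cap, "closest channels" is geometrically
  sensible but not a realistic montage.
- The temporal-generalization grid picks nearest native samples, so
  requesting a step finer than the sampling interval is an error rather
  than an interpolation.
- The swap-null peak-distance test is conservative by construction (see
  above); group peak *locations* are recovered well, but the
  significance machinery for their distance should be interpreted with
  care.
- ANOVA model fitting, sphericity corrections and post-hoc tests are
  deliberately out of scope; only the printed effect-size formulas are
  implemented.
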