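---
title: "Methods: time-resolved decoding, RSA fusion, and nonparametric inference"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: time-resolved decoding, RSA fusion, and nonparametric inference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette is the package's own account of the science it implements:
the models and procedures, the assumptions behind them, the parameters that
matter, and the numerical and design choices made where the methodology
leaves room. It states no empirical result beyond what the test suite and
the acceptance script themselves compute.

## The measurement model

The unit of analysis is an epoched multichannel recording
(`meg_epochs`): `trials × channels × time`, with one condition label per
trial and a time axis in milliseconds relative to stimulus onset. The
synthetic generator (`generate_meg_subjects()`) produces each trial as

```
x(trial of condition c, channel, t) =
    e_id(t) * p_c(channel) + e_cat(t) * q_k(channel) + noise
```

where `p_c` is a condition-specific spatial pattern, `q_k` a pattern shared
by all conditions of category `k` (e.g. faces vs objects), `e_id` and
`e_cat` are temporal envelopes, and the noise is i.i.d. Gaussian per sample
and channel. Patterns are drawn once per subject from a standard Gaussian
and unit-normalized, so `amplitude / noise_sd` has the same meaning
regardless of channel count. Envelopes are Gaussian bumps parameterized by
(onset, peak, fwhm, amplitude), truncated to zero before the onset —
a smooth ramp-then-decay matching the shape of stimulus-evoked decodable
information. The generator returns ground truth (realized patterns, the
noiseless condition × condition × time Euclidean dissimilarity geometry,
and the true envelope latencies) for parameter-recovery testing.

What the generator deliberately does *not* emulate: forward-model MEG
physics, 1/f or spatially correlated sensor noise, trial-to-trial latency
jitter, and cross-subject pattern correspondence. Passing tests therefore
demonstrate that the *analysis chain* recovers structure it is designed to
detect under its stated noise model — not that it is robust to every
property of real recordings.

## Preprocessing

`preprocess_epochs()` applies, in order: baseline correction (subtract each
trial/channel's mean over the baseline window), peak-to-peak rejection
(remove a trial iff max−min on *any* channel strictly exceeds the
threshold; default 6000 fT, the standard MEG artifact criterion), and
zero-phase low-pass filtering (forward–backward 4th-order Butterworth,
default 20 Hz). Choices worth making explicit:

- **Boundary rule.** A trial spanning exactly the threshold is kept; the
  strict inequality makes the rule deterministic at the boundary.
- **Zero phase.** Latencies are the scientific output downstream, so the
  filter must not shift peaks; forward–backward filtering guarantees this
  for symmetric transients (tested).
- **Edge handling.** Odd-reflection padding of six filter settling lengths
  before `filtfilt`, so epoch edges carry no startup transients (DC passes
  through to < 1e-6 relative error).
- **Order.** The filter is applied after rejection (artifact spans should
  be judged on raw amplitudes) and baseline correction first; the order is
  recorded in the output's processing log. On data whose baseline window is
  silent, filtering and baseline correction commute to ~1e-12, so the
  choice is immaterial there.

## Time-resolved pairwise decoding

For every pair of conditions and time point, `pairwise_decoding_timecourse()`
classifies channel pattern vectors with a linear support-vector machine at
fixed cost `C = 1`:

1. Trials of each condition are randomly partitioned into groups of
   `group_size` (default 3) and averaged into `M = floor(n / group_size)`
   pseudo-trials. Remainder trials are dropped for that draw; fresh random
   grouping across `n_repetitions` (default 100) recycles all trials.
2. Cross-validation holds out one pseudo-trial *per class* per fold (two
   test vectors), training on the remaining `2(M−1)`; there are `M` folds.
   The alternative reading — a single held-out vector per fold — would
   train on class-imbalanced sets; the balanced scheme is the standard in
   this literature and is the documented interpretation here.
3. Fold accuracies are averaged within a repetition, then across
   repetitions (when `M` varies, this weights repetitions equally, the
   natural convention). Both matrix triangles are filled; the diagonal is
   undefined (`NA`).

Numerical choices: no feature normalization is applied before
classification (raw patterns keep the single-channel oracle test exact);
when the two conditions have unequal pseudo-trial counts the pair uses the
smaller count so folds stay balanced; and a test vector landing exactly on
the decision boundary counts as *incorrect* — conservative and
deterministic. The time loop runs at the epoch's native resolution with an
optional decimation `stride` for desk-scale work.

The SVM itself is solved in compiled code (SMO on the C-SVC dual with a
bias term, linear kernel; the bias is recomputed from the final dual
variables via the KKT conditions, as the mean over free support vectors or
the feasible-interval midpoint when none are free). The test suite verifies
fold-by-fold agreement with the libsvm reference implementation (e1071) and
against an exhaustive hand-enumerated oracle for `M = 2` single-channel
problems, where a hard-margin boundary is the training-pair midpoint.

`temporal_generalization()` trains at `t` and tests at every `t'` using the
same pseudo-trials and folds, so with equal seeds its diagonal reproduces
the time-resolved decoding exactly (tested). `direct_category_decoding()`
trains face-vs-object classifiers with leave-one-exemplar-per-category-out
folds, so test exemplars never contribute training data.

## Partitions and the categorical division

`pair_partition()` splits the `C(C−1)/2` unordered pairs into within-A,
within-B and between sets (disjoint, exhaustive — tested). Partition means
are unweighted over pairs. The categorical division is

```
division(t) = mean(between, t) − mean(within_A ∪ within_B, t)
```

with the two within sets pooled at equal pair weight. Under exchangeable
conditions (no category structure) it is centered on zero; positive values
indicate category clustering of the decoding geometry.

## fMRI RDMs, searchlight, fusion, and MDS

`correlation_rdm()` computes `1 − Pearson` between condition pattern
vectors (range 0–2, zero diagonal); a zero-variance pattern is an error
naming the condition. `searchlight_rdms()` repeats this within spheres of
radius 4 voxels (center-to-center Euclidean distance, boundary inclusive),
truncated at the mask edge; centers with fewer than two in-mask neighbors
are skipped with a warning. Neighborhood sizes are verified against
brute-force lattice enumeration (7, 33, 123, 257 for radii 1–4).

`fusion_timecourse()` vectorizes the strictly-lower triangle of both RDMs
in one fixed order (row-major, `i > j`, shared by all RDM consumers so that
serialization is bit-stable) and computes Spearman's rho per time point,
one series per fMRI subject. Decoding-accuracy slices are used directly as
dissimilarities — higher accuracy means more distinct patterns — with no
rescaling, since a rank correlation only sees order. Ties get average
ranks; a constant vector yields a missing value rather than an error.

The synthetic fMRI generator inverts this pipeline: given a target
geometry on the 1 − Pearson scale, it factorizes the implied correlation
matrix `C = 1 − G` by eigendecomposition (clipping negative eigenvalues
with a warning when `G` is not exactly embeddable) and applies the loadings
to an exactly orthonormal, zero-mean voxel basis, so the sample correlation
RDM of the generated patterns equals `G` *exactly* at `noise_sd = 0`. This
is what makes the end-to-end fusion recovery test sharp: fMRI patterns
embedded from the MEG ground-truth geometry at time `t*` must make the
fusion series peak near `t*`.

`mds_embed()` performs metric multidimensional scaling by stress
majorization (Guttman transforms) from a deterministic classical-scaling
start, centered at the origin with each dimension's sign fixed so its
largest-magnitude coordinate is positive. Degenerate inputs (all-equal
dissimilarities) embed as a simplex without error.

## Nonparametric inference

- **d′** = `z(hit rate) − z(false-alarm rate)` under the equal-variance
  Gaussian model; rates of 0 and 1 are replaced by `1/(2N)` and
  `1 − 1/(2N)` before the probit — the standard correction where the
  methodology is otherwise silent.
- **Signed-rank test**: two-sided Wilcoxon, zero differences dropped, exact
  null for ≤ 25 nonzero differences without ties, tie-corrected normal
  approximation otherwise.
- **Bootstrap latencies**: subjects are resampled with replacement 1000
  times (default); the latency of each resampled subject-average is
  extracted and the 95% CI is the 2.5/97.5 percentile of that empirical
  distribution (simple percentile, not BCa — matching the "empirical
  distribution" convention). The CI may exclude the plug-in point estimate.
  Latency *differences* are tested by the fraction of bootstrap differences
  crossing zero, `p = 2·min(P(d ≤ 0), P(d ≥ 0))`, floored at `1/n_boot`;
  cross-cohort comparisons resample the cohorts independently (unpaired)
  unless `paired = TRUE`.
- **Onset latency** has no universal definition. The point estimate is the
  first time point of the earliest significant cluster from the
  sign-permutation test; inside bootstrap replicates — where a nested
  1000 × 1000 permutation is infeasible — onset is the first run of at
  least `min_consec_ms` (default 5 ms) exceeding the point-wise
  cluster-defining threshold computed once on the original data. Both
  halves of this rule are interpretive and documented as such; replicates
  with no supra-threshold run are excluded and counted.
- **FDR**: Benjamini–Hochberg step-up at `q = 0.05`, property-tested
  against the exhaustive definition.
- **Cluster-size inference**: under the null, each subject's effect
  (accuracy − 50, or rho − 0) is symmetric about zero, so the permutation
  distribution multiplies whole subjects by ±1 (1000 permutations). The
  point-wise cluster-defining threshold is the per-cell `1 − cdt`
  permutation quantile (default 0.05, one-sided); whether a
  permutation-based or t-based threshold was intended is ambiguous in the
  methodology this follows, and the permutation quantile was chosen as the
  fully nonparametric option. Clusters are connected supra-threshold cells
  (adjacency in 1-D, 4-connectivity for train × test maps), the statistic
  is cluster *size*, and the corrected p is the fraction of permutations
  whose maximum cluster size reaches the observed one, with the observed
  included (`+1/+1`), so `p ≥ 1/(n_perm + 1)`.

Two structural consequences deserve a note. First, with `S` subjects the
smallest attainable point-wise one-sided level is `2^-S`; below about six
subjects a 0.05 CDT is unreachable and no cluster can form — a property of
the method, not a bug. Second, when a strong effect is perfectly
homogeneous across subjects, sign patterns that leave most subjects
positive reproduce the observed cluster extent, so the corrected p sits at
or slightly above its floor rather than exactly at it; the family-wise
error calibration (tested at 200 null simulations) is unaffected.

## The presentation-rate presets

`rsvp_rate_settings()` provides three envelope presets emulating
progressively faster rapid serial visual presentation. Faster presentation
disrupts the feedforward sweep and delays category-selective processing;
the generator renders this as a narrower, weaker identity envelope and a
later, weaker category envelope. Narrowing alone lowers the *measured* peak
(the 20 Hz filter attenuates narrow transients) and delays the *measured*
onset (a narrower bump crosses the detection threshold later), but a later
categorical-division peak must come from the category envelope itself —
an analysis cannot conjure a latency the data do not contain. The
acceptance test verifies that the full chain *recovers* the monotone
ordering (lower peak, later onset, later categorical peak) across the three
presets; it is a parameter-recovery check of ordinal structure, not a
derivation of the phenomenon.

## Default parameters at a glance

| parameter | default | unit | rationale |
|---|---|---|---|
| rejection threshold | 6000 | fT peak-to-peak | standard MEG artifact criterion |
| low-pass cutoff | 20 | Hz | evoked-response smoothing before decoding |
| `group_size` | 3 | trials | pseudo-trial SNR vs fold count |
| `n_repetitions` | 100 | — | averages out grouping randomness |
| `svm_cost` | 1 | — | fixed regularization, field convention |
| searchlight radius | 4 | voxels | standard sphere size |
| `n_boot` | 1000 | — | stable 95% percentile CIs |
| `n_perm` | 1000 | — | p resolution 1/1001 |
| `cdt`, `alpha`, `q` | 0.05 | — | conventional levels |
| generator: conditions | 24 (12+12) | — | face/object study design |
| generator: trials | 30 | per condition | typical session yield |
| generator: channels | 306 | — | whole-head MEG sensor count |
| generator: epoch | −300…900, 1 ms | ms | peri-stimulus window |
| generator: `noise_sd` | 1 | a.u. | with unit-norm patterns and amplitudes ~1–2, yields mid-range (70–90%) peak decoding |

## Problem sizes used by the tests

The test and acceptance suites run the full algorithms at reduced scale,
chosen so each check is statistically sharp yet completes quickly: chance
calibration at 2 subjects × 8 conditions × 100 time points × 10
repetitions; parameter recovery at 100 cohorts of 10 subjects (4
conditions, 10 ms stride, 3 repetitions, identity/category amplitudes
1.2/1.5 at noise 1 — amplitudes set so within-category decoding peaks
around 80%, keeping the accuracy nonlinearity away from ceiling and the
peak estimators unbiased); fusion recovery at 12 conditions with 100
noisy fMRI replicates; family-wise error at 200 null simulations of 12
subjects × 60 time points with 500 permutations; and the ordinal
presentation-rate check at 3 settings × 20 replicates of 6-subject
cohorts. Production-scale defaults (100 repetitions, 1000
bootstraps/permutations, 1 ms stride) remain the package defaults.

## Known limitations

- The noise model is white in time and space; autocorrelated noise would
  widen decoding peaks and is not emulated.
- Onset estimation inside bootstrap replicates reuses the original data's
  point-wise threshold; this ignores threshold uncertainty and makes onset
  CIs slightly anticonservative.
- The fusion stage maps the ground-truth Euclidean geometry onto the
  1 − Pearson scale by linear rescaling; only the rank structure matters
  for Spearman fusion, but absolute fMRI dissimilarity magnitudes are not
  calibrated.
- Searchlight fusion maps (fusing every searchlight RDM with MEG) are out
  of scope; fusion here is ROI-based, and whole-brain cluster statistics on
  searchlight outputs are not provided.
- Multiclass decoding, classifier weight-map interpretation, and
  threshold-free cluster enhancement are deliberately not implemented.
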