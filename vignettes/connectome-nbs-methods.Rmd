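---
title: "Methods: group comparison of resting-state functional connectomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: group comparison of resting-state functional connectomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The analysis

`fcnbs` implements a complete group-comparison pipeline for resting-state
functional connectomes, of the kind used to contrast a patient cohort (the
motivating application is early type-2 diabetes without cerebral small-vessel
disease) against matched healthy controls:

1. **Connectivity.** Per subject, ROI time series (116 anatomical regions,
   frames at TR = 2 s) are band-pass filtered, nuisance-regressed, and
   pairwise Pearson-correlated; correlations are mapped to Fisher z,
   $z = \operatorname{atanh}(r)$, giving a symmetric $116 \times 116$
   matrix per subject with a zero diagonal.
2. **Edge-level inference (NBS).** Network-based statistics: a sign-test
   connection mask, pooled-variance two-sample *t* per masked edge, a primary
   threshold (reference configuration $t = 3$), connected components of the
   suprathreshold graph, and a permutation null of the maximal component size
   to assign each observed component a familywise-error corrected p-value.
3. **Edge patterns.** Each significant edge is classified from its two signed
   group means: *pathological positive* (negative in controls, positive in
   patients), *hyperconnectivity* (positive and increased), *hypoconnectivity*
   (negative in both groups), or *indeterminate*.
4. **Network level.** Within-network strengths
   $W_X = \binom{n_X}{2}^{-1} \sum_{i<j \in X} z_{ij}$ and between-network
   strengths $W_{X,Y} = (n_X n_Y)^{-1} \sum_{i \in X, j \in Y} z_{ij}$ over a
   7-network partition, compared across groups with two-sided pooled *t* tests
   and Benjamini–Hochberg FDR over the 28-measure family.
5. **Clinical statistics.** Group comparisons reproducible from printed
   summary statistics (pooled *t* from mean/sd/n; Pearson $\chi^2$ for sex),
   and covariate-adjusted association models
   `edge ~ variable + age + sex + education` in the patient group.

Every stage is driven by the numbered scripts under `analysis/`; the
computation itself lives in the package so the tests and
`scripts/acceptance.R` exercise the same code.

# Preprocessing choices

**Filter design.** The band (0.01–0.08 Hz) and the filter family (Chebyshev)
are fixed by the analysis the package reproduces, but type, order and ripple
are free choices: we use a type-I band-pass of order 4 with 0.5 dB pass-band
ripple, applied forward–backward (`signal::filtfilt`) so the net phase shift
is zero and frames stay aligned across regions. At this design, in-band
sinusoids retain ≥ 90% amplitude and out-of-band sinusoids are attenuated
below 10% (verified in the test suite at TR = 2 s, 512 frames). Order and
ripple are exposed as arguments.

**Order of operations.** Filtering precedes nuisance regression by default
(`filter_first = TRUE`), matching the workflow this pipeline mirrors;
regressing filtered confounds from filtered data is the common alternative
and is available via the switch.

**Confounds.** The conventional nine regressors (white matter, CSF, global
mean, six motion parameters) plus first-order derivatives, padded with a
leading zero to preserve frame count. Collinear columns are pruned with a
warning rather than failing, because derivative sets are frequently
rank-deficient on short series.

**Degenerate values.** Correlations are clipped to $\pm(1 - 10^{-7})$ before
`atanh`, so duplicated series produce a large finite z rather than infinity.
Zero-variance regions get a zeroed row/column, a warning, and a flag; the
diagonal is zero everywhere and excluded from all statistics.

# The NBS permutation null

Permutations exchange whole subjects between groups; the pooled-*t* edge
statistics, the primary threshold, and the component search are recomputed
per permutation, and the maximal component size (edge count) forms the null
distribution. The corrected p-value uses the +1 estimator,
$p = (1 + \#\{\text{null max} \ge \text{observed}\}) / (1 + n_\text{perm})$,
which never returns zero. Ties count against the observed component.

One design point deserves emphasis: **the sign-test connection mask is
re-derived inside every permutation.** The mask admits an edge when an exact
binomial sign test (zeros dropped, one-tailed toward the observed majority
sign) rejects a zero median in either group at $\alpha = 0.05$. Because the
mask is computed from the same labels being tested, holding it fixed across
permutations selects null edges for sign consistency with the observed
grouping and inflates observed statistics relative to permuted ones — in our
null simulations a fixed mask yields a familywise false-positive rate near
0.30 at a nominal 0.05. Re-deriving the mask per permutation restores the
exchangeability argument, and the calibration experiment
(`fwe_calibration()`) confirms control: the measured familywise rate over
synthetic null studies stays within the binomial envelope of 0.05. A fixed
mask remains available through the `mask` argument for sensitivity analyses.

The primary threshold accepts either form (`t_threshold` or `p_threshold`);
the reference configuration is $t = 3$, the value tied to the component
search being reproduced. One-tailed tests are run as separate passes per
direction (`tails = "both"` reports both); each pass controls its own FWE at
$\alpha$, so the union's familywise rate is bounded by $2\alpha$.

# The synthetic-study generator

`generate_study()` draws, per subject, multivariate Gaussian frames with a
group-specific target correlation matrix and computes connectivity exactly as
the pipeline would. Defaults encode the study conditions the pipeline
targets: 33 patients vs 24 controls, 116 regions, 243 retained frames
(mirroring 253 acquired minus 10 discarded) at TR = 2 s.

* **Baseline structure.** Within-network mean r = 0.3; the sensory-motor ↔
  auditory between-network baseline is r = −0.15 in both groups, mimicking
  the normally anticorrelated relation whose sign flip the pattern
  classification targets. These magnitudes are generator defaults chosen to
  sit in the range of the bundled edge table (|z| ≈ 0–0.34), not measured
  parameters.
* **Planted effects.** `planted_component()` builds a connected bipartite set
  of 30 between-network edges (6 sensory-motor × 5 auditory hubs). For a
  per-edge effect size d, the Fisher-z group gap is
  $d / \sqrt{T - 3}$ (`planted_z_offset()`), since a subject-level z from
  $T$ approximately independent frames has standard deviation
  $\approx 1/\sqrt{T-3}$. Planting is symmetric around zero, giving
  controls a negative and patients a positive target.
* **Covariance repair.** Arbitrary per-edge overrides can break positive
  semi-definiteness; targets are repaired by eigenvalue flooring at $10^{-6}$
  and rescaling to unit diagonal.
* **Clinical coupling.** Covariates are drawn around means and spreads
  typical of an early type-2-diabetes cohort; `clinical_effect` shifts each
  patient's planted-edge target (z scale) by the standardised covariate, so
  association models have a recoverable planted slope.
* **What the generator does not emulate.** Haemodynamic filtering,
  autocorrelated noise, motion artefacts, site effects, and real
  between-subject variability in network topology. Consequently the
  generator's frames are white within band, and `generate_study()` computes
  connectivity directly from them without the band-pass/regression steps —
  filtering white noise would only reduce the effective frame count and
  distort the calibrated effect sizes. The preprocessing operations are
  validated separately on constructed signals. Passing calibration and power
  tests on these studies demonstrates the *procedure's* statistical
  properties, not robustness to real acquisition artefacts.

# Simulation scales and checks

The test suite and the acceptance report run, at fixed seeds:

* FWE calibration: 100–200 null studies at 500 permutations each; the
  familywise false-positive rate is compared with the 95% upper binomial
  bound for 0.05.
* Planted-component power: 50–100 studies at per-edge d = 1, 500–1000
  permutations; detection means a component with $p_\text{fwe} < 0.05$ whose
  edges are mostly planted. Measured power is ≈ 0.95–1.0, and ≥ 99% of
  recovered planted edges classify as pathological-positive.
* Network-level power: the d = 1.2 block-shift example is checked against an
  analytic oracle rather than a fixed round number: with $n = 33/24$,
  noncentrality $d / \sqrt{1/n_1 + 1/n_2} \approx 4.47$ at 55 df, the
  noncentral-*t* power lies between 0.87 (at the most stringent BH threshold
  $q/28$) and 0.99 (at $q$); realized BH power sits near the lower end
  (≈ 0.90 measured), so the test asserts agreement with the analytic band.
* Slope recovery: 1000 patient cohorts of n = 33; 95% CI coverage of the
  planted slope and the type-I rate at 0.05 are checked against binomial
  envelopes.

These sizes were chosen so that statistical assertions have meaningful
resolution while the default suite stays comfortably re-runnable.

# The network partition

The 116-region table bundled as `inst/extdata/partition_aal116.tsv` assigns
the 90 cerebral regions to six networks (default mode, attention, visual,
auditory, sensory-motor, subcortical) and all 26 cerebellar regions to a
cerebellum network. It is a **reconstruction** of a conventional AAL-based
grouping, not a published table: the analysis is partition-parametric, and
faithful re-runs of any specific study should supply that study's own table
via `read_partition()`. One structural fact anchors the reconstruction: the
bundled 33-edge table is described by its source as entirely between-network,
which places the rolandic operculum (ROL) outside the sensory-motor network;
we assign it to the auditory network, to which it is anatomically adjacent.
Network-level *numeric* results therefore reproduce in structure, not value.

# Degenerate inputs and tie-breaking

* Edges with zero pooled variance are excluded from the edge map (warning);
  measures with zero pooled variance are excluded from the FDR family
  (warning).
* A sign test on all-zero values returns p = 1 (never significant).
* Components of equal size tie against the observed component in the
  permutation count ("≥ observed").
* `suprathreshold_components()` with no passing edges returns an empty list.
* The duplicated row in the bundled edge table (the same region pair printed
  twice) is preserved verbatim; region counting de-duplicates by label, so
  the table still yields 33 edges over 22 distinct regions.
* `"C45. L"` in the printed table is not a standard atlas label; it is
  normalised to cerebellum lobule IV–V left (`CB4_5.L`), and the printed
  string is kept in the fixture.

# Known limitations

* The pipeline starts from ROI series; image-space preprocessing of real
  scans (slice timing, realignment, spatial normalisation, smoothing) is out
  of scope.
* White-noise simulations make per-edge effect sizes exact but optimistic;
  real data's temporal autocorrelation reduces effective degrees of freedom.
* The printed sex chi-square p (0.970) and MoCA p (0.058) of the bundled
  demographics table are not reproducible from its printed summaries by the
  stated tests; the fixture carries the printed values for reference, and no
  test asserts them.
* Pooled-variance (Student) *t* is used throughout because it reproduces the
  bundled demographics p-values exactly; Welch would not. For strongly
  unequal variances the pooled test is approximate.
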