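---
title: "Temporal variability of dynamic functional connectivity: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Temporal variability of dynamic functional connectivity: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tvfc)
```

## The statistic

Resting-state functional connectivity (FC) is usually summarised by a single
whole-scan correlation matrix, which hides how the connectivity pattern
reconfigures over the scan. `tvfc` quantifies that reconfiguration. The
parcellated BOLD series (T volumes x R regions of interest) is cut into
non-overlapping windows of length $l$; within each window a full $R \times R$
Pearson correlation matrix is computed. For a given sequence of windowed FC
matrices $F_1, \dots, F_{num}$, three levels of temporal variability are
defined, all of the form "one minus the mean between-window similarity of a
vectorised FC pattern":

* **Regional**, per ROI $k$:
  $V_k = 1 - \overline{\mathrm{corr}\!\left(F(i,k),\, F(j,k)\right)}$, where
  $F(i,k)$ is row $k$ of window $i$'s FC matrix with the self-correlation
  entry removed (length $R-1$), and the average runs over all unordered
  window pairs $i < j$.
* **Intra-network**, per network $m$: the pattern vector is the strict upper
  triangle of the members-by-members FC block, in a fixed row-major order.
* **Inter-network**, per unordered network pair $(m, n)$: the pattern vector
  is the vectorised full $|m| \times |n|$ cross-block. Transposing the block
  reorders both vectors consistently, so the value is symmetric in $(m, n)$.

Because each between-window similarity is a Pearson correlation in
$[-1, 1]$, every variability value lies in $[0, 2]$: 0 when the pattern is
perfectly stable across windows, 2 when patterns in different windows are
perfectly anticorrelated. Pure white noise sits in between, not at any
boundary, because finite windows always produce sampling fluctuation in FC.

## Multi-scale averaging

A single window length is arbitrary, so the statistic is averaged over a
grid: window lengths $l = 21, \dots, 30$ volumes (42-60 s at TR = 2 s, the
range conventionally considered stable for windowed FC), and for each $l$
every start offset $s = 1, \dots, l-1$, giving $l - 1$ distinct
segmentations per length. Leading volumes before $s$ and the trailing
partial window are discarded; a segmentation contributes only if it yields
at least `minWindows` (default 2) full windows. All per-$(l, s)$ values are
averaged with equal weight, regardless of how many windows each
segmentation produced — the grid is treated as a set of equally valid
measurements, not weighted by window count. With 240 analysed volumes and
the default grid, $\sum_{l=21}^{30}(l-1) = 245$ segmentations enter the
average (`nSegmentationsUsed` records the actual count).

Two deliberate conventions, both configurable:

* The regional pattern vector excludes the diagonal self-correlation. A
  constant 1 in every window would only shrink the between-window variance
  and dilute the statistic.
* The between-window comparison operates on raw correlations, not Fisher-z
  transformed values; `fisherZ = TRUE` provides the transformed variant for
  sensitivity analysis.

## Degenerate inputs and undefined values

A ROI that is constant within a window has no defined correlation: its row
and column of that window's FC matrix are set to `NA`. Between-window
pattern correlations involving constant or all-`NA` vectors are skipped; if
more than half of a segmentation's window pairs are skipped for a
statistic, that segmentation is dropped from that statistic's average. A
network needs at least 3 ROIs for an intra-network value — a 2-ROI block
vectorises to a single number, which has no correlatable pattern (with the
default parcellation this affects the 2-ROI thalamus network, whose
intra-network value is reported as `NA`). Undefined values propagate as
explicit `NA` through the feature tables and statistics — never as imputed
zeros — and the per-feature N is reported downstream.

## Preprocessing

The package starts from extracted ROI signals; image-space preprocessing
(slice timing, realignment, normalisation) is assumed done upstream. The
per-subject chain is fixed as **discard → nuisance regression → band-pass**:

1. **Discard** the first `nDiscard = 10` volumes (magnetisation
   equilibration), so a 250-volume acquisition yields 240 analysed volumes.
2. **Nuisance regression**: OLS residualisation on an intercept plus the
   Friston-24 motion expansion $[p(t), p(t-1), p(t)^2, p(t-1)^2]$ (lagged
   terms zero-padded at the first frame), optional extra confound columns
   (e.g. white-matter/CSF signals), and — only when `gsr = TRUE` — the
   global ROI-mean signal. Global signal regression is off by default, as
   its use remains contested; the flag implements the sensitivity re-run.
3. **Band-pass** 0.01-0.10 Hz via an ideal boxcar in the discrete Fourier
   domain: coefficients outside the band, including the DC term, are
   zeroed. The boxcar was chosen over an IIR design because it has no
   filter-order or ripple parameters and is exactly reproducible; a
   Butterworth alternative would change values only marginally inside the
   band. The passband test is inclusive, and frequencies are the two-sided
   DFT bin frequencies, so a sinusoid on an exact in-band bin passes with
   amplitude preserved.

The ordering question (regress before or after filtering) has no single
community standard; the package fixes regression first and records the
order in the run log. Head-motion quality control uses Power-style
framewise displacement — the sum of absolute backward differences of the
three translations plus the three rotations converted to arc length on a
50 mm sphere — and excludes a subject when mean FD is **strictly greater**
than 0.2 mm.

## The synthetic cohort generator

There is no public reference dataset for this analysis, so the package
ships a generator that produces cohorts with exactly the structure the
pipeline assumes: per-subject series and motion TSVs, a manifest with
group, age, sex, education and clinical scores, and a ground-truth table.
The generator is first-class, tested code: every validation claim in the
package is made against data whose dynamics are known by construction.

Each subject's series is zero-mean Gaussian with a covariance that
alternates between two regimes. Two random correlation matrices
$\Sigma_A, \Sigma_B$ (mean off-diagonal `baseCor = 0.2`, a typical
resting-FC level) are fixed per cohort. With per-ROI weight
$\lambda_k(t) = w(t)\,a$ on the modulated ROI set (0 elsewhere), where
$w(t)$ is a square wave and $a \in [0,1]$ the group's modulation
amplitude, the series is built as
$x_k = \sqrt{1-\lambda_k}\,u_k + \sqrt{\lambda_k}\,v_k$ with independent
$u \sim N(0, \Sigma_A)$, $v \sim N(0, \Sigma_B)$, plus white noise
(`noiseSd = 0.2`). This construction was chosen over blending covariance
*entries* directly because it is the covariance of an explicitly
constructed random vector, hence positive definite for every $a$ by
construction — a naive entrywise blend restricted to a sub-block can lose
definiteness. On the modulated block it still realises the intended regime
mixture $(1-wa)\Sigma_A + wa\,\Sigma_B$. The square wave (period 40
volumes, deliberately incommensurate with the 21-30 volume window grid so
aligned segmentation cannot null the dynamics) makes "how much dynamics
was planted" analytically transparent; a raised-cosine mode
(`sinusoidal = TRUE`) is available.

Motion traces are seeded 6-parameter random walks rescaled to a per-subject
target mean FD drawn from a lognormal (median 0.08 mm) — so QC decisions
are deterministic given the targets, and specific subjects can be forced
above threshold. Group sizes default to 66/53/66 at 250 volumes, TR 2 s,
116 ROIs, matching a typical three-group clinical resting-state study; the
default group amplitudes (0.6 / 0.3 / 0) plant a graded patient effect. One
clinical score is generated as a monotone function of the subject's true
amplitude plus calibrated Gaussian noise (using the Gaussian-copula
relation $\rho_{Pearson} = 2\sin(\pi\rho_S/6)$) so its Spearman
correlation with the planted amplitude approximates `clinicalScoreRho`;
remaining scores are plausible group-dependent fillers.

What the generator does **not** emulate: hemodynamic autocorrelation and
convolution, scanner drift and physiological noise spectra, spatial
structure within parcels, and site effects. Passing tests therefore
demonstrate that the statistic recovers planted covariance dynamics under
Gaussian assumptions — not that it is robust to every property of real
BOLD data.

## Group statistics

Each variability feature is tested for a group main effect by ANCOVA:
the extra-sum-of-squares F comparing [intercept + age + sex + education +
mean FD + group] against the covariates-only model, with listwise deletion
and per-feature N reported. No correction is applied across
ROIs/networks at this stage (an optional Benjamini-Hochberg flag exists but
is off by default). Features passing the gate (main-effect p < 0.05) get
post-hoc pairwise contrasts: the covariate-adjusted two-group linear model
per pair, t-test on the group coefficient, Bonferroni-corrected by the
number of pairs (3), significance at corrected p < 0.05. The exact
post-hoc statistic is a design choice (adjusted two-group contrast rather
than pooled-variance estimated marginal means); it is recorded in the
output metadata. Clinical associations use Spearman's rank correlation
(average ranks for ties, two-sided t-approximation p), per group and
pooled, uncorrected.

Calibration is verified by simulation: the null rejection rate of the
ANCOVA at $\alpha = 0.05$ over 2,000 synthetic null cohorts (N = 90, three
groups) must lie in [0.035, 0.065], and the family-wise error of the gated
Bonferroni post-hoc chain stays at or below the nominal level plus
simulation margin.

## Problem sizes used by the test suite

The validation suite runs at desk scale, chosen as the smallest sizes at
which each property is meaningfully exercised: oracle-equivalence checks
compare against a naive double-loop reference on 100 instances with
R ≤ 8, T ≤ 60; the bounds stress suite uses 50 seeded series with
R ≤ 20, T ≤ 300 under the full default window grid; planted-effect
recovery uses 50 replicates per amplitude at R = 12, T = 250 (4 modulated
ROIs); end-to-end pipeline tests use 9-subject cohorts with a trimmed
window grid. Full-scale runs (116 ROIs, 185 subjects) use identical code
paths and differ only in wall time (roughly a second per subject per
hundred segmentations).

## Known limitations

* The packaged AAL-116 → 11-network table is a best-effort construction
  for default use; network-level results depend on the assignment, and
  studies should supply their own table (`loadParcellation()` reads any
  two-column TSV or JSON mapping). Whether cerebellar vermis parcels
  belong in "cerebellum" is a judgement call; here they are included.
* The variability statistic compares FC *patterns*; it does not localise
  which connections drive a change, and it is blind to pattern changes
  that preserve correlation up to an affine map.
* Windowed Pearson FC at 21-30 volumes is noisy; the multi-scale average
  reduces but does not remove the dependence of absolute values on T, so
  variability values should only be compared across subjects with equal
  scan length and TR.
* ANCOVA assumes homogeneous covariate slopes across groups; no
  permutation or mixed-model inference is provided.
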