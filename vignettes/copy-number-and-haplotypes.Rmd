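---
title: "Copy-number calling and haplotype inference for multi-copy gene families"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Copy-number calling and haplotype inference for multi-copy gene families}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kircn)
```

## The measurement model

Real-time PCR reports, per well and fluorophore, the cycle of
quantification Cq, which decreases linearly with the log2 of starting
template. In a multiplex well, the target and the reference assay (STAT6,
two copies in essentially every diploid genome) share the same DNA input,
so the within-well difference

$$\Delta C_q = C_q^{target} - C_q^{reference}$$

depends only on the target's copy number, the two assays' baselines, and
noise. Comparing with a calibrator sample of known copy number
$n_{cal}$ gives the comparative-Cq estimate

$$\widehat{CN} = n_{cal}\,2^{-\Delta\Delta C_q},\qquad
\Delta\Delta C_q = \overline{\Delta C_q}^{sample} - \overline{\Delta C_q}^{cal}.$$

Assumptions: near-perfect amplification efficiency for target and
reference (the uncorrected form is the default; see below), a reference
locus that really is at two copies, and DNA input inside the range where
Cq is linear in log template. Copy-number changes are small on this scale
— 1 cycle between 1 and 2 copies, $\log_2 1.5 \approx 0.585$ between 2
and 3 — which is what makes replicate QC and dispersion monitoring
essential.

## Replicate quality control

Each sample × reaction is run in quadruplicate (`Panel$replicates`,
default 4). `qc_filter()` applies, in order:

1. **Reference failure / late reference.** Replicates whose reference did
   not amplify, or amplified later than `ref_cq_max = 32` cycles, are
   discarded (`REF_FAIL`, `REF_CQ_HIGH`): a weak reference means the well's
   normalisation cannot be trusted.
2. **Zero-copy detection.** A target with Cq above `zero_target_min = 35`
   (or no amplification) while its reference is sound indicates the locus
   is absent. If the majority of surviving replicates say so, the marker
   is a `ZERO_CALL` and the copy number is 0 outright — the
   $2^{-\Delta\Delta C_q}$ arithmetic is bypassed entirely, since there is
   no meaningful ΔCq for a locus with no template.
3. **ΔCq outliers.** A surviving replicate whose ΔCq deviates more than
   `outlier_k = 4` standard deviations from the rest is removed
   (`OUTLIER_REMOVED`). The deviation is evaluated **leave-one-out**: in a
   set of four, an extreme point inflates the inclusive SD so much that it
   can never exceed about 1.7 inclusive SDs, so an inclusive 4-SD rule
   would be a no-op. The inclusive variant remains available
   (`leave_one_out = FALSE`) for comparison. Removal iterates worst-first
   and stops when fewer than three replicates remain.

If nothing survives, the call is abandoned (`TOO_FEW_REPLICATES`).

## Calibration

Two calibration sources are supported, mirroring lab practice:

* **Control samples** of known copy number plated on every run. Several
  controls can be given; each marker is calibrated from the first control
  carrying at least one copy there, because no single KIR genotype carries
  every gene. `control_samples()` builds such a covering set from a
  haplotype library, and the end-to-end simulation uses it by default.
* **Cohort mode** (`cohort_calibrate()`), for runs without a calibrator:
  per-sample mean ΔCq values are clustered onto the integer-copy lattice
  (spacing $\log_2$ of the copy ratio) by a k-means-style alternation
  initialised at the kernel-density peak, and the largest cluster is
  assigned the copy number expected to be most frequent
  (`expected_modal_cn()` derives this from the library). Ties are broken
  toward the lower-ΔCq, i.e. higher-copy, cluster and flagged
  `AMBIGUOUS_MODE`; below 10 samples a warning is issued.

Cohort mode carries an inherent risk the user should understand: if the
cohort's realized modal copy number differs from the expected one — easy
for a marker whose carrier distribution is nearly balanced, such as a
locus riding on one common haplotype — every call at that marker shifts by
a factor of two. Controls are therefore preferred whenever available.

## Rounding, confidence and dispersion

Calculated copy numbers are rounded to the **nearest** integer, ties away
from zero (2.5 → 3). A ceiling rule would systematically inflate calls by
half a copy and break agreement with integer truth, so it is deliberately
not offered.

The per-call metrics are computed from the cohort's clusters
(`cluster_stats()`: mean, $n-1$ SD and size per marker × assigned copy
number, on the calculated-copy-number scale):

* **z-score** — $|x - \bar{x}_{cluster}| / s_{cluster}$; flagged when the
  cluster is degenerate ($s = 0$, `SD_ZERO`) or too small to estimate
  (`CLUSTER_TOO_SMALL`).
* **confidence** — the posterior probability of the assigned integer under
  an equal-prior Gaussian mixture with components at integer copy numbers
  and the marker's pooled cluster SD. A sample midway between two
  well-separated clusters scores ≈ 0.5. This is this package's own
  definition; commercial packages report a similarly named metric whose
  formula is not public, so values are comparable in spirit, not digit by
  digit.

`discrimination_threshold(cn_low, k)` expresses the dispersion a usable
assay needs: with at least $k = 6$ cluster SDs inside the
$\log_2((n+1)/n)$ separation, adjacent copy numbers separate in more than
99.6 % of samples (SD < 0.167 cycles for 1 vs 2 copies); $k = 4$ gives the
> 95 % tier (0.25 cycles). Thresholds shrink as copy number grows, which
is why discrimination beyond 4–5 copies degrades.

## Cross-assay consistency

Two independent defences against assay artefacts:

* **Paired assays** (`paired_assays`): genes assayed at two regions (3DL1
  exon 4 / exon 9; 3DL2 twice) must agree; disagreement
  (`PAIR_DISCORDANT`) is the signature of allele dropout — a rare
  polymorphism under one primer/probe silencing one chromosome's copy for
  that assay only.
* **Sum rules** (`sum_rules`): a whole-gene assay must equal the sum of
  its variant assays (2DS4 = full-length + deletion variant), else
  `RULE_VIOLATION`.

`haplotype_rules_check()` adds genotype-level screening: framework genes
(3DL3, 3DP1, 2DL4, 3DL2) are expected at two copies, except when a
co-duplication group (3DP1, 2DL4 and the combined 3DL1/S1 locus) deviates
*consistently* — the signature of a genuine expanded or contracted
haplotype rather than a miscall. The rules ship as an editable YAML file.

## The haplotype identifier

Per sample, the genotype string (markersig) is expanded into a regular
expression enumerating every per-locus haplotype value, matched against
the library's signature strings, and each match is subtracted from the
genotype. A pair is emitted only when the residual itself is in the
library; residuals outside it are reported as unexplained in the
unresolved log rather than invented. Pairs are unordered, may pair a
haplotype with itself, and are ranked by the plain frequency product
$f_1 f_2$ — a ranking score, not a genotype probability (no
Hardy–Weinberg factor of 2 for heterozygous pairs). All pairs tied at the
maximum appear in the best-pairs file. The digit-string form requires all
copy numbers ≤ 9; internally a delimiter-joined canonical form covers the
general case, and matching falls back to the equivalent element-wise
comparison. Calls are projected onto the library loci by consensus over a
gene's region assays; a discordant pair blocks haplotype inference for
that sample rather than guessing.

`pedigree_filter()` offers a deliberately simple trio screen — a child
pair survives only if one haplotype occurs in some paternal pair and the
other in some maternal pair. Full pedigree segregation is out of scope.

## The synthetic generator

`simulate_cohort()` draws two haplotypes per sample i.i.d. by library
frequency; `simulate_plate()` lays out quadruplicate 384-well plates
(row-major, replicates contiguous) and generates
$C_q = base_m - conc_s - \log_{1+E}(cn / 2) + \varepsilon$, with
per-channel noise $\varepsilon \sim N(0, \sigma_{\Delta C_q}/\sqrt{2})$ so
the within-well ΔCq has SD $\sigma_{\Delta C_q}$, and a per-sample
concentration offset $conc_s \sim N(0, \sigma_{conc})$ that cancels in
ΔCq. Defaults: $\sigma_{\Delta C_q} = 0.15$ cycles (inside the tightest
discrimination tier, matching a validated assay), $\sigma_{conc} = 0.5$
cycles (± ~40 % DNA input), baselines 24/23 cycles, $E = 1$. Zero copies
yield no amplification, or a late Cq (38–42) under `leaky_zero` to
exercise the 35/32 zero-call rule. Dropout events make the affected assay
see one copy fewer — when the last copy is lost this is a shift beyond 10
cycles (no amplification) — reproducing the one-copy-lower discordance an
allele dropout causes in the paired assay.

What the generator does **not** emulate: efficiency drift within a run,
pipetting or inhibitor artefacts beyond the Gaussian model, fluorescence
crosstalk, or plate-position effects. Passing tests therefore demonstrate
the *algorithmic* correctness of QC, calling and haplotype resolution
under the stated noise model, not instrument-level robustness; the
bundled library's frequencies are placeholders, so simulated cohorts
reflect its structure, not a real population's.

## Numerical choices and problem sizes

Degenerate inputs are handled explicitly: empty replicate sets abandon the
call; zero-SD clusters give confidence 1/0 by nearest integer and an
infinite flagged z-score; empty libraries resolve nothing; frequencies
are never silently normalised (a warning is issued when they do not sum
to 1). When every efficiency equals 1 the corrected and uncorrected code
paths are the same code path, so results are bit-identical by
construction.

The test suite runs at desk scale, chosen to finish in well under a
minute of simulation per property: noise-free round trips over cohorts of
30, replicate-dispersion convergence over 10 000 wells, a 2000-sample
1-vs-2-copy miscall measurement at $\sigma_{\Delta C_q} = 0.15$ and 0.30
(≤ 1 % at the tight setting, visibly worse at the loose one), 1000
random brute-force cross-checks of pair enumeration, and ~70 dropout
injections on the full 20-marker panel.

## Known limitations

* The bundled panel's grouping of targets into reactions is a fixed
  convention of this package; real assay designs should load their own
  panel file.
* Cohort-mode calibration depends on the expected-mode assumption (see
  above).
* The confidence metric is mixture-based and assumes roughly Gaussian,
  equally dispersed clusters; heavy asymmetry will distort it.
* Haplotype resolution is only as good as the library: pairs involving
  haplotypes absent from it are reported as unresolved, and the ranking
  frequencies are user-supplied weights.
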