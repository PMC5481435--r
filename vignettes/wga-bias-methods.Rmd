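---
title: "Measuring WGA bias in amplicon sequencing: models and choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring WGA bias in amplicon sequencing: models and choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wgabias)
```

## The problem

Targeted amplicon panels sequenced from FFPE tissue often start from too
little DNA, and whole-genome amplification (WGA) is used to stretch the
input. The two common chemistries behave differently: hybrid
fragmentation/PCR kits ("kitA") and phi29 multiple displacement
amplification ("kitB"). `wgabias` quantifies what each does to the data at
two levels — per-amplicon gene copy number (GCN) and per-variant allele
frequency (VAF) — always against the matched *non-amplified* FFPE sample
from the same patient, tissue, panel and library-prep replicate, so that
fixation effects and amplification effects are separated.

## GCN normalization

The dosage model is the MLPA dosage-quotient idea transplanted to
sequencing depth. For one sample with positive depths $d_1,\dots,d_n$ over
$n \ge 2$ amplicons,

$$\mathrm{AVRT}_i = \frac{1}{n-1}\sum_{j\neq i}\frac{d_i}{d_j},$$

the column mean of the $n\times n$ depth-ratio matrix with the diagonal
excluded (computed in closed form as $(d_i\sum_j 1/d_j - 1)/(n-1)$, which
is algebraically identical and avoids the quadratic loop; tests verify the
equivalence against the explicit double loop to $10^{-12}$). The
inter-sample step is $\mathrm{GCN}_i = \mathrm{AVRT}_i^{test} /
\mathrm{AVRT}_i^{ref}$. Two properties matter:

* **Scale invariance**: multiplying either profile by a constant changes
  nothing, so library size never needs explicit normalization.
* **Compositional coupling**: a genuine gain at one amplicon slightly
  depresses every other amplicon's GCN (ratios are relative). With one
  amplicon doubled among $n = 4$ equal depths the others land at $5/6$,
  not 1. Interpretation of near-band values should keep this in mind.

The arithmetic mean of ratios is used, not the geometric mean, although
the geometric mean would be more symmetric under inversion: the dosage
bands below are calibrated to the arithmetic convention, and changing the
mean would silently shift them.

**Dosage calls.** Normal is the closed interval $1 \pm 0.25$ (band edges
inclusive — "±" reads naturally as a closed interval); below is loss,
above is gain. A heterozygous deletion sits at 0.5, a single-copy gain at
1.5, a doubling at 2.

**Zero depths.** A zero-depth amplicon makes every ratio against it
undefined. This is a hard error by default, with an explicit, logged
`impute_floor()` (zero → 1 read) for callers who prefer to keep the
sample. Silent imputation inside `avrt()` would bias AVRT invisibly.

**Reference choice.** The reference for a WGA sample is the non-WGA FFPE
sample of the *same tissue*, so true copy-number events cancel and GCN
deviations isolate amplification bias. FFPE-vs-frozen contrasts use the
frozen sample as reference. Tumor-vs-normal GCN (where planted or real
CNVs do appear) is available by calling `normalize_gcn()` with that pair
directly.

**Coverage uniformity** is defined here on per-amplicon mean depths: the
percentage of amplicons at or above 0.2× the profile mean. Instrument
pipelines compute a similar metric per base from raw reads; the two are
correlated but not identical, and no per-base claim is made.

## Variant filtering

Retention requires DP4 strand counts present, depth ≥ 50 (inclusive —
"at least") and VAF > 0.04 (strict — "greater than"); checks run in the
order dp4, depth, vaf and each rejected call reports its first failing
reason. Panel intersection is 1-based inclusive on both sides after the
BED half-open coordinates are shifted at parse time. Multi-allelic VCF
records are split per alternate (the primary alternate keeps the
DP4-derived VAF; secondary alternates use their `AF` or are dropped with a
message) and indels are excluded throughout — every downstream analysis is
phrased in base substitutions. Manual alignment review is not
reproducible in code; a deterministic homopolymer-adjacency flag
(`flag_homopolymer()`) is offered as an annotation-only surrogate, off by
default.

## Delta-VAF and variant classes

Classes per sample set: **germline** = present in the non-WGA FFPE normal
reference; **somatic** = present in the non-WGA FFPE tumor reference and
not the normal; **WGA-created** = present only in a WGA sample. Germline
status is *not* additionally conditioned on presence in the tumor
reference (a germline variant may drop out of one library); the classes
still partition keys. WGA-created variants are counted once per sample
and replicate, matching per-replicate averaging of the counts.

$\Delta\mathrm{VAF} = \mathrm{VAF}_{WGA} - \mathrm{VAF}_{ref}$ on shared
keys; biased means $|\Delta\mathrm{VAF}| > 0.05$. The 0.05 default is
anchored in the replicate noise estimate: across triplicate non-WGA FFPE
preps, the mean per-variant VAF SD comes out around 0.02–0.03
(`replicate_vaf_noise()`, sample SD with $n-1$), and 0.05 is the
conservative round-up. A stricter 0.10 is available via the `threshold`
argument; both conventions exist in practice and the package takes 0.05
as the default because that is the value the bias definitions above are
calibrated to. Note the estimator averages over homozygous variants too,
whose clamped VAFs have near-zero SD, so the mean SD is expected to sit
below the raw per-replicate noise of heterozygous sites.

WGA-created variants have no reference VAF: they are biased by
definition with direction "positive". Known-class variants missing from
the matched reference get `NA` deltas and stay out of biased counts
rather than being guessed.

## Statistics

* **Mann–Whitney (two-tailed)** for unpaired group comparisons
  (per-sample biased counts, $|\Delta\mathrm{VAF}|$ by direction). For
  small groups the exact null distribution is computed by full
  enumeration of all $\binom{n_1+n_2}{n_1}$ labelings using mid-ranks, so
  ties are handled exactly: two non-overlapping groups of five give
  $p = 2/\binom{10}{5} = 0.0079$, the smallest attainable two-tailed
  value at that size. Enumeration is used up to $2\times10^5$ labelings;
  beyond that, the mid-rank normal approximation with tie and continuity
  correction (`stats::wilcox.test`). The exact path is cross-checked
  against `wilcox.test(exact = TRUE)` in tie-free cases.
* **Wilcoxon matched-pairs signed-rank (two-tailed)** for
  amplicon-matched GCN contrasts; zero differences are dropped, the exact
  distribution is used up to 25 untied pairs, and an all-zero difference
  vector returns $p = 1$ with a degenerate flag.
* **Two-count z-test** for substitution counts:
  $z = (a-b)/\sqrt{a+b}$, the normal comparison of two Poisson counts,
  two-tailed, no continuity correction. By long-standing convention z
  statistics are reported to two decimals and the tail probability is
  read off at that precision (the table / web-calculator workflow);
  `count_z_test()` follows it, converting via z rounded to two decimals
  ($z_{7,1} = 2.12 \Rightarrow p = 0.0340$). `z_digits = NULL` gives the
  full-precision conversion ($p = 0.0339$ for the same pair); the
  difference only shows in the fourth decimal. The returned `z` is always
  full precision.
* **OLS concordance** (`vaf_concordance()`): slope/intercept of VAF on
  VAF over shared keys, $R^2$ as squared Pearson correlation.
* Raw p-values are reported throughout — the panels of contrasts are
  read individually, as is conventional for this kind of study —
  with an opt-in Benjamini–Hochberg column in `compare_conditions()`.

## The synthetic study generator

`simulate_study()` reproduces the design the analyses assume: sets LC1
(triplicate preps), LC2 and EC1; EC1 run on both a 97-amplicon and a
74-amplicon panel; per set/panel, frozen and FFPE normal/tumor non-WGA
samples plus kitA/kitB WGA products of the FFPE DNA. Ground truth (true
variants, planted copy-number events, realized created variants per
sample) is emitted alongside so parameter-recovery tests can close the
loop.

Generator model and defaults, chosen as plausible values for this assay
class:

* **Depths**: $d_i = \bar d \cdot c_i \cdot e^{\varepsilon}$,
  $\varepsilon \sim N(0, \sigma^2)$ — amplicon PCR efficiency is
  multiplicative, hence lognormal noise. $\bar d = 1500$ reads;
  $\sigma = 0.05$ (non-WGA), $0.25$ (kitA), $0.60$ (kitB), so kitB's GCN
  spread visibly exceeds kitA's; these are presets, not fitted values.
  Copy-number factors $c_i$ (default: one gain ×2, one loss ×0.5) apply
  to tumor samples only.
* **Variants**: 14 germline (heterozygous with probability 0.6, else
  homozygous) and 11 somatic (true VAF uniform on 0.10–0.60, a typical
  FFPE tumor-purity range) per set. Observed VAF = true VAF +
  library-prep noise $N(0, 0.025^2)$ (+ kit shift $N(0, 0.04^2)$ for
  kitA, $N(0, 0.09^2)$ for kitB), truncated to $[0,1]$, then *realized as
  binomial read counts* at a lognormally drawn depth with a Binomial(0.5)
  forward/reverse split — so DP4, depth and VAF are mutually consistent,
  which the readers validate. A consequence: even with all noise
  parameters at zero, realized VAFs match the truth only up to binomial
  sampling at the drawn depth.
* **Created variants**: Poisson per sample, mean 0.2 (kitA) and 28
  (kitB), placed at unused panel positions; substitution type drawn from
  a deamination-dominated spectrum (G>A 0.55, C>T 0.37, C>A 0.06, the
  remaining 2% uniform — pooled C:G>T:A share 0.92); true VAF uniform on
  0.05–0.25, high enough to survive the 0.04 filter, low enough to look
  artifactual. The Poisson assumption is a modelling choice; only means
  are published for the real data.
* **FFPE vs frozen**: no extra effect by default (fixation alone showed
  none or minimal bias in this design); `ffpe_extra_fp_rate` exists to
  stress-test the classifier.

Determinism: every generator call runs under a named seed with the
caller's RNG state saved and restored; the same configuration yields
byte-identical studies, files and reports.

What the generator does **not** emulate: read-level errors and alignment
artifacts, homopolymer miscalls, GC-dependent depth trends, tumor
subclonal structure, and position-specific WGA failure. Tests passing on
synthetic data therefore demonstrate correctness of the estimators and
the pipeline's contracts under the stated noise model — not performance
on any particular real dataset.

## Problem sizes in the shipped tests

Unit tests run on scaled-down configurations (24/16 amplicons, reduced
created-variant rates) chosen to exercise every code path quickly; the
acceptance suite runs the full default configuration (97/74 amplicons,
triplicates, kitB rate 28) across 20 independent seeds for the
parameter-recovery checks, and 200 random instances (n ≤ 20) for the
GCN oracle-equivalence check.

## Known limitations

* The GCN method is single-amplicon: no segmentation, no multi-amplicon
  event calling, no GC correction.
* Biased-variant classification is presence/absence-based and inherits
  the callers' detection limits; a variant filtered out of a reference
  library shifts classes.
* Coverage uniformity here is not the per-base instrument metric.
* Intratumoral heterogeneity and purity are not modelled; VAF shifts are
  attributed wholly to preparation and amplification.
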