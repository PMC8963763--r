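---
title: "methcascade: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{methcascade: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methcascade)
```

This vignette is the package's account of its own methods: the statistical
model behind each stage, the tunable parameters with their defaults and the
reasoning behind them, what the synthetic-data generators do and do not
emulate, and the numerical conventions adopted where the underlying
procedure left genuine freedom.

## The bi-weight statistic

Two-channel CpG-island arrays hybridise a sample's methylated DNA fraction
(labelled Cy5) competitively against its unmethylated fraction (Cy3). The
per-probe summary implemented here is the bi-weight ratio

$$\mathrm{BW} = \frac{\log_2(\mathrm{Cy3})}{\log_2(\mathrm{Cy5})},$$

a quotient of channel log-intensities: equal channels give exactly 1, and
*more* methylated-fraction signal *lowers* BW. This quotient-of-logs form is
unusual — the conventional two-channel summary is the log-ratio
$\log_2(\mathrm{Cy5}/\mathrm{Cy3})$ — and it is not resolvable from the
method's printed definition whether the quotient was meant literally.
`compute_bw_matrix()` therefore implements the quotient literally as the
default (`formula = "literal_quotient"`) and offers the conventional
log-ratio as an explicit alternative (`"log_ratio"`). Two consequences of
the literal form are handled once, centrally:

* **Domain.** $\log_2(\mathrm{Cy5})$ vanishes at one fluorescence unit, so
  the statistic is singular there. All intensities are required to be
  $\ge 2$ (so both logs are $\ge 1$) — enforced at read time with errors
  naming the offending probe and sample, and guaranteed by the simulator.
* **Direction.** Under the literal quotient, hypermethylation in the TR
  group means a *lower* TR mean BW; under the log-ratio, a higher one. The
  direction labels `hyper`/`hypo` always refer to *methylation*, never to
  the sign of the BW difference: `call_dmrs()` reads the formula recorded
  on the BW table and orients accordingly, so the convention lives in one
  place.

One structural asymmetry of the literal quotient is worth knowing: since
$\mathrm{BW} = b/(b+\delta)$ for a methylated-channel log-shift $\delta$
about baseline $b$, hypermethylation can at most drive BW towards 0
(a median difference below 1), whereas hypomethylation can push BW far
above 1. Gene-level median differences exceeding the 1.4 cutoff are
therefore only reachable for hypomethylated genes under the literal
formula; under the log-ratio the scale is symmetric. The demonstration
configuration plants hypomethylated markers for this reason.

## Differential calling

`call_dmrs()` runs one two-sided two-sample t-test per probe. The default
is the pooled-variance Student test (the variance homogeneity assumption is
exactly satisfied by the simulator's equal-noise groups); Welch is
available via `variant = "welch"`. The per-probe statistics are computed
vectorised from the pooled/Welch formulas — the standard approach at array
scale — and the test suite cross-checks them against `stats::t.test` on
random fixtures to $10^{-10}$.

* **α defaults to 0.01**, the stricter of the two thresholds the original
  methods describe (its results section reports p < 0.05 in one place; the
  inconsistency is unresolvable, so α is a parameter).
* **No multiple-testing correction by default**, matching the original
  procedure; Benjamini–Hochberg filtering is available behind
  `adjust = "BH"` for principled use.
* The statistic returned by `t_test_probe(values_cr, values_tr)` is
  oriented first-group-minus-second-group, while the reported `mean_diff`
  is TR minus CR in BW units — the quantity the ranking sorts on
  (descending, ties broken by probe id for determinism).

`summarize_dmrs()` collapses significant probes to unique regions: a
region is `hyper` when all its significant probes are hyper, `hypo` when
all are hypo, `both` otherwise. The partition identities
(`hyper + hypo = significant` probes; `hyper + hypo + both = unique`
regions) are property-tested on random fixtures.

Sample clustering uses Euclidean distance on per-probe Z-scores (sample
SD, $n-1$; constant probes map to all-zero rows) with average linkage by
default — the original description names only the distance, not the
linkage, so the least aggressive common choice is the default and
complete/Ward are options. Cutting at two clusters yields a partition
whose Rand index against the CR/TR labels is reported.

## The marker cascade

The cascade reproduces a four-step prioritisation:

1. **Direction consistency** — keep genes whose significant probes agree
   in direction.
2. **Gene-level medians** — per sample, a gene's value is the median of
   its probes' BW values; per group, the median across samples. The
   within-gene collapse is not specified in the original description;
   median-then-median is used for consistency with the "median bi-weight"
   language and for robustness.
3. **MD cutoff** — $\mathrm{MD} = |\tilde m_{TR} - \tilde m_{CR}|$ with a
   *strict* `MD > 1.4`. MD is treated as absolute because the original
   ranking mixes genes of both directions without sign; strictness is
   supported by the smallest retained reference value (1.4315) exceeding
   the cutoff.
4. **CpG density** — candidates above a strict 60% promoter CpG density
   gate, ranked by density (ties by MD, then gene name), truncated to
   `k = 3`. Applying the gate *and* the top-k rule reproduces the reported
   panel ordering when fed the published densities (90/88/63).

The cascade is monotone in its thresholds (raising the MD cutoff or the
density gate never adds a gene), which is property-tested.

## CpG islands and density

A CpG island here is a segment of length ≥ 500 bp with GC fraction ≥ 0.5
and observed/expected CpG ratio
$\mathrm{O/E} = \#\mathrm{CpG} \cdot L / (\#C \cdot \#G) \ge 0.6$. The
length-500/GC-50% part follows the island definition the original work
cites; the O/E criterion is the standard additional filter, added because
"50% or more of CG dinucleotides" conflates GC content with CpG frequency
— a GC-rich but CpG-free sequence should not be an island. All three
thresholds are parameters.

The detector tests every window of exactly `min_length` bases (prefix-sum
counts), merges overlapping or adjacent qualifying windows into candidate
segments, and re-checks each merged segment against all three thresholds.
A merged segment that fails the re-check is split recursively: its longest
qualifying sub-segment (leftmost on ties) is emitted and the flanks are
processed the same way. Emitted islands are therefore pairwise disjoint
and each satisfies all three thresholds — an invariant asserted per call.
Numerical conventions: coordinates are 0-based half-open throughout; `N`
bases count toward segment length but never toward GC or CpG; when
$\#C \cdot \#G = 0$ the O/E ratio is defined as 0.

Two properties of this algorithm family deserve honesty. First, total
island coverage is *not* strictly monotone in the thresholds: loosening
the GC threshold can merge two qualifying islands into one candidate whose
re-check forces re-segmentation and legitimately loses edge coverage, and
changing `min_length` changes the whole seed-window family. What does hold
— and is property-tested — is that every strictly qualifying seed window
retains island coverage when the GC or O/E threshold is loosened. Second,
the detector's exact output depends on this split rule; the test suite
pins it by comparing against an exhaustive per-substring oracle (no prefix
sums, manual merging) on 100 random 2 kb sequences.

**CpG density** is the percentage of the 2 kb promoter window covered by
the union of detected islands. The original work reports densities from an
external web tool whose parameters and exact promoter coordinates are not
recoverable, so the reported densities (88/63/90%) are treated as *inputs*
(shipped in `inst/extdata/`), never as values the detector is expected to
reproduce.

Promoter windows are `[TSS − 1000, TSS + 1000)` in transcript orientation
(minus-strand windows are reverse-complemented so upstream is always
left); the original "1,000 bp downstream; TSS; 1,000 bp upstream" phrasing
is ambiguous about ordering, and fixing transcript orientation makes the
window strand-covariant.

## MSP logic and clinical statistics

In-silico bisulfite conversion maps every cytosine to thymine except —
when the template is methylated — cytosines in CpG context, which
methylation protects. The three-state MSP call is: band only in the
methylated-primer reaction → `M`; only unmethylated → `U`; both → `HM`;
neither is an indeterminate assay result (error by default, droppable with
a logged count).

Associations use Pearson's chi-square without continuity correction.
All-zero rows/columns are dropped before computing expected counts and
degrees of freedom — necessary because a status can be entirely absent for
a gene (the reference tables contain an all-zero methylated column), which
otherwise yields undefined expected counts. Because several reference
cells have expected counts below 5, a Monte-Carlo p-value (resampling
tables with fixed margins, seeded) is available for every table; the
asymptotic and Monte-Carlo p-values are compared within Monte-Carlo error
in the test suite. The printed p-values of the original association tables
are *not* reproduced by Pearson recomputation (the reference stage table
for BRD9 gives $\chi^2 = 22.63$, p ≈ 1.2 × 10⁻⁵, against a printed
0.00012; two tables' rows do not sum to the cohort size); the package
asserts its own recomputed arithmetic and documents the discrepancy.

Survival uses the Kaplan–Meier product-limit estimator and the two-group
Mantel–Haenszel log-rank test via the survival package. The reported
median is the smallest observed time with $\hat S(t) \le 0.5$ (`NA` when
never reached). Per gene, the comparison is run between the two most
frequent status groups (ties resolved in M, HM, U order) — matching the
two-curve-per-gene design of the original survival analysis — with the
grouping overridable.

## What the simulators emulate — and what they do not

**Array generator** (`simulate_methylation_array()`): per cell, each
channel's log2 intensity is `baseline + noise`; planted regions shift the
methylated channel's log2 intensity in TR samples by `effect_size` (up for
hyper, down for hypo). `effect_size` is therefore exactly the planted
group difference on the log-ratio scale, and `noise_sd` is the standard
deviation of the per-cell log-ratio signal (each channel receives
`noise_sd`/√2). Defaults: 12 CR vs 10 TR (the discovery-cohort layout),
two probes per region (so probe- and region-level counts can differ),
baseline 10 log2 units, `noise_sd` 0.5 and `effect_size` 1.0 — a
standardised per-probe effect of 2.0, a realistic magnitude for a
methylation difference worth validating; the array noise of the original
instrument is unpublished, so these are modelling choices, not
calibrations, and they are deliberately not revisited per test. The
generator does **not** model scanner artifacts, dye bias, spatial or batch
structure, probe-specific affinities, or correlated probes within a
region — so passing recovery tests demonstrate the pipeline's statistical
machinery, not robustness to real-array artifacts.

**Promoter generator** (`simulate_promoters()`): a central island built
from CG/AT dinucleotide slots (exact GC count, shuffled positions — CpG
O/E ≈ 2/GC, hence detectable whenever island GC ≥ 0.5) inside iid flanks
of requested GC. Real promoters have graded island boundaries and repeat
structure; planted boundaries are sharp, which is why recovery tests use
reciprocal-overlap ≥ 0.8 rather than exact coordinates (windows straddling
a sharp boundary can qualify and extend the detected island slightly
beyond the planted one).

**Cohort generator** (`simulate_msp_cohort()`): per-gene M/HM/U statuses
drawn from group-specific distributions whose defaults mirror the observed
validation-cohort frequencies; stage and tumour-size groups drawn per
response group with defaults approximating the published cohort
composition. Survival is exponential: the status of one designated driver
gene (default the first gene) sets the PFS hazard (defaults M = 0.01,
HM = 0.30, U = 0.20 events/month — median PFS of ~2–3 months in the
high-risk statuses, in the reported range), and OS adds an exponential
post-progression time. Censoring is administrative at a fixed horizon
(60 months) rather than random, so the censoring fraction is reproducible.
Real cohorts have covariate-dependent, non-exponential hazards and
heterogeneous follow-up; none of that is modelled.

All generators split a single seed into per-generator substreams (fixed
offsets), so adding one generator to a pipeline never perturbs another's
draws, and identical configurations are byte-identical on disk.

## Orchestration

`run_discovery()` and `run_validation()` chain the stages above from a
single `run_config()` (also loadable from YAML via `read_run_config()`).
The orchestrators compute nothing themselves: every report field traces to
exactly one module function. Reports carry a configuration hash, the seed
and the package version, contain no timestamps, and are therefore
byte-identical across reruns; per-stage record counts go to the message
stream so the probe → region → gene → panel funnel is inspectable.
Configuration errors (α outside (0,1), missing files) are raised before
any computation.

## Problem sizes used by the test suite

The suite exercises the pipeline at the study's own scale where that is
what is being claimed, and smaller where only correctness of arithmetic is
at stake: null calibration on 5,000 regions (10,000 probes), planted
recovery on 2,000 regions with 10% planted at effect 1.0 / noise 0.5 and
the 12-vs-10 design, the end-to-end cascade on the bundled 2,000-region
demonstration, island-detector equivalence on 100 random 2 kb sequences,
Monte-Carlo chi-square at 10⁵ replicates, and log-rank calibration over
500 replicates of 35-per-group cohorts. Sensitivity in the recovery test
is region-level (a planted region counts as recovered when at least one of
its probes is significant, the natural region-level reading); the
false-discovery proportion is probe-level (the fraction of significant
probes originating from unplanted regions, the natural companion of
probe-wise testing).

## Known limitations

* The literal BW quotient caps hypermethylation effects (median
  differences above 1 are unreachable in that direction); use
  `formula = "log_ratio"` for a symmetric scale.
* The island detector's output is pinned to one deterministic
  seed-merge-recheck-split definition; other standard tools use different
  extension rules and will disagree near island boundaries.
* Reported densities, the original screen's probe counts and the printed
  association p-values are treated as fixed reference inputs, not
  reproduction targets — the raw arrays have no public accession.
* Survival simulation ties hazards to a single driver gene's status;
  multi-gene hazard structure is out of scope, as are Cox models and
  multivariable adjustment.
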