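---
title: "Validating RT-qPCR reference genes for two-group designs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Validating RT-qPCR reference genes for two-group designs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(refstab)
```

## The problem

RT-qPCR quantifies a transcript of interest relative to one or more
reference ("housekeeping") genes assumed equally abundant across
samples. When the two sample types being compared are as different as
whole sea urchin eggs and their isolated cortices — a thin peripheral
layer of membrane and cytoplasm stripped of most of the cell content —
that assumption is exactly what must be established first. A gene whose
transcript is itself depleted or enriched in the cortex fraction will
silently bias every fold change normalized to it: ribosomal 28S, for
example, largely reflects the degree of poly(A) purification rather than
biology, and normalizing a cortex-enriched transcript to it can inflate
its apparent enrichment several-fold.

`refstab` implements the full validation workflow for such a two-group
design: Ct-table QC, amplification-efficiency calibration, five
expression-stability estimators with a consensus ranking, the geNorm
criterion for how many reference genes to use, 2^-ddCt relative
quantification with a group comparison, FPKM-based candidate screening,
and seeded simulators that generate data with the exact statistical
structure the estimators assume.

## Data model

The central object is a Ct table: genes x samples x technical
replicates, each sample labeled with a group (`egg`/`cortex` by default;
any two labels work) and a template kind (`total` RNA or `polyA`
mRNA). Analyses operate on one template kind at a time, because total
RNA and poly(A) preparations are different experiments with disjoint
sample sets and, as the egg/cortex case shows, can rank genes
differently.

Technical replicates are collapsed by arithmetic mean on the Ct scale;
all estimators consume per-sample mean Ct. The QC report flags cells
whose replicate spread (max - min) reaches `max_spread` (default 0.5
cycles, the conventional concordance bound for triplicates); flagged
cells are retained, never dropped, since dropping would silently change
the design. Missing gene x sample cells are an error rather than an
imputation target — every estimator below assumes a complete matrix.

Relative quantities are `Q = B^(Ct_min - Ct)` per gene, with base `B = 2`
(perfect doubling) by default or `1 + E/100` when per-gene efficiencies
are supplied. Efficiency correction is off by default throughout: the
standard formulation of each estimator is base-2, and the correction is
exposed as an option rather than a silent default.

## The five stability estimators

**BestKeeper-style dispersion** (`bestkeeper()`): the sample SD (n-1
denominator) of a gene's Ct across samples; genes with SD <= 1 cycle are
flagged acceptable. The original spreadsheet's mean absolute deviation
around the geometric mean Ct is available via
`dispersion = "mad_geomean"`; which variant a given published analysis
used is rarely stated, so both are kept. The CV% reported alongside
(100 SD / mean Ct) is the only quantity in the package that is not
invariant to adding a constant to a gene's Ct — by construction, since
it divides by the absolute Ct level.

**Expression CV** (`cv_method()`): the percent coefficient of variation
of the relative quantities `Q`. Because `Q` is exponential in `-Ct`,
this penalizes Ct dispersion on the abundance scale.

**Comparative delta-Ct** (`delta_ct_method()`): for every gene pair, the
SD across samples of the per-sample Ct difference; a gene's score is the
mean over all pairs containing it. Genes that co-vary tightly with the
rest of the panel score low even if their absolute level drifts.

**geNorm** (`genorm()`): a gene's M value is the mean SD of its pairwise
log2 expression ratios with all other candidates; the highest-M gene is
removed and M recomputed until two genes remain — the best pair, which
shares its mutual pairwise variation as M. Ties at the maximum are
broken by removing the lexicographically later gene id, which makes the
elimination deterministic and documented. M <= 0.5 is the conventional
bound for a usable reference gene. `genorm_pairwise_variation()`
computes V(n/n+1), the SD of log2 ratios of normalization factors built
from the top n versus n+1 genes; the recommended panel size is the
smallest n with V below 0.15, or the full panel if no V passes — so a
clean panel yields the minimal answer, two reference genes.

**NormFinder-style variance decomposition** (`normfinder()`): on the
log2 quantity scale, a two-group mixed model separates each gene's
intergroup difference d (the gene x group interaction of the group
means, summing to zero over genes within each group and over groups
within each gene) from its intragroup variance sigma^2 (two-way
residuals within each group, bias-corrected as
`(S_i - mean(S)/(k-1)) * k/(k-2)` and truncated at zero). The
differences are shrunk by an empirical-Bayes factor
`gamma2 / (gamma2 + sigma2/n)`, where gamma2 is a moment estimate of the
variance of the true intergroup differences on (k-1)(G-1) degrees of
freedom, and the stability value is `|shrunk d| + posterior SD of d`,
averaged over the two groups. Two degenerate regimes are handled
explicitly: when gamma2 truncates to zero (no detectable intergroup
variation) genes are ranked by the sampling SD of their group means —
the intragroup-only mode — and perfectly constant data yield identical
minimal scores. The best two-gene combination minimizes the same
criterion applied to the average of the two genes' log expression;
genes with opposite-signed d combine well, which is why the best pair is
usually not the two top-ranked singles.

All five estimators are invariant to per-gene Ct shifts and to
reordering genes or samples, and each is verified in the test suite
against an independent naive loop-based implementation of the same
definitions to 1e-9.

The consensus in `aggregate_rankings()` — geometric mean of per-method
ranks, with geNorm's pair members taking rank 1.5 — is this package's
explicit formalization of an overall "most suitable" call; published
analyses typically make that call qualitatively, so the output labels
the consensus as the package's own construction.

## Efficiency calibration and relative quantification

`fit_standard_curve()` regresses mean Ct on log10 relative input; the
slope gives `E = (10^(-1/slope) - 1) * 100`, with R^2 from the same fit
and a closed acceptance interval of 90-110% (a slope of -3.32 is
perfect doubling). Replicates are averaged within dilution points before
the fit, matching common instrument software; fitting on raw replicates
is a flag. At least three distinct dilution points are required, and a
non-negative slope is an error, not a warning.

`ddct()` implements 2^-ddCt: per sample, dCt is the gene of interest's
Ct minus the arithmetic mean of the normalizers' Ct (equivalently the
geometric mean of their quantities — the geNorm convention for
multi-gene normalization factors); ddCt subtracts the calibrator group's
mean dCt, so the calibrator's geometric-mean fold is exactly 1. The
group-level fold is `2^-(mean ddCt)`, a geometric-style mean, with
per-sample folds reported for dispersion. The egg-vs-cortex comparison
is a two-tailed unpaired t-test on the per-sample dCt values — the log
scale, where the Gaussian error model lives — pooled-variance by
default with Welch behind a flag; testing the folds directly is exposed
as an option but not the default, since fold distributions are
log-normal. With per-gene efficiencies the same arithmetic runs on the
efficiency-corrected log2-quantity scale (a Pfaffl-style ratio).

Useful identities, all enforced in the test suite: sample-loading
shifts (a constant added to all genes of a sample) cancel exactly;
swapping the calibrator group inverts every fold; k identical
normalizers behave like any single one.

## Candidate screening

`screen_reference_candidates()` and `screen_goi_candidates()` filter an
FPKM table from an egg/cortex RNA-seq comparison. Published screens of
this kind rest on a replicate-level differential-expression call whose
inputs are usually not available downstream; the package substitutes
explicit fold-change thresholds and says so in the documentation.
Defaults: reference candidates need FPKM >= 1000 in both conditions and
a between-condition fold <= 1.5 (abundant and balanced); gene-of-interest
candidates need FPKM > 0.5 in both conditions and cortex/egg fold >= 2.
These are declared proxies, deliberately configurable.

## What the simulators emulate — and what they do not

`simulate_ct_experiment()` draws
`Ct = mu_g + delta_g [cortex] + L_s + b_gs + tau_gsr`, with a shared
per-sample loading shift L, per-gene biological noise b, and technical
noise tau, all Gaussian on the Ct (log-quantity) scale — the standard
qPCR error model. `delta = -log2(fold)` encodes a designed fold at base
2. The simulators reproduce the features the estimators rely on (shared
loading shifts, group effects, replicate structure, seeded
reproducibility) but not features of real data such as inhibitor-driven
efficiency differences between samples, non-Gaussian outliers, or
between-gene correlation beyond the loading shift — so passing
recovery tests demonstrates correctness of the estimators under their
own model, not robustness to assay pathology.

### The "sea-urchin-7gene" preset as a designed benchmark

`preset_sea_urchin()` emulates the shape of a real panel: seven
candidate genes spanning baseline Ct 15.6 (ribosomal 28S) to 28
(GAPDH), three egg and three cortex samples, technical triplicates, and
a cortex-enriched gene of interest (Daglb-2) at a designed fold of 2.

Its noise/shift pattern is a deliberately constructed rank-recovery
benchmark, and it is worth being explicit about why. With three samples
per group, every dispersion estimate carries five (or, within groups,
two) degrees of freedom, so sample SDs fluctuate by tens of percent. A
panel in which candidates differ only moderately — the realistic
situation — does not admit a gene that all five estimators rank first
95% of the time; under such regimes the recovery rate of the designed
winner can drop below 50% for NormFinder and geNorm, not because the
implementations err but because the data carry too little information.
geNorm is the sharpest constraint: its stepwise elimination rewards
co-varying pairs, so some pair of unstable genes will, by sampling luck,
occasionally look tighter than the stable gene's best pairing. The
preset therefore (i) gives the designed winner, Ubb, near-zero noise and
no group effect; (ii) provides one moderately stable partner, Smtnl1
(low noise, small opposite group shift), whose cheap mutual variation
with Ubb anchors both genes through geNorm's elimination rounds; and
(iii) makes the other five candidates both noisy (SD around 1 cycle)
and strongly, distinctly group-shifted (1.5 to 4.25 cycles, mixed
signs, shift sums kept near zero so the sum-to-zero constraint of the
NormFinder decomposition does not leak a spurious intergroup difference
into the stable genes). 28S is shifted up in cortices, mirroring rRNA
depletion in the cortex fraction. Under this design each estimator
recovers Ubb first in roughly 96-100% of simulated experiments, which
is the practical ceiling we observed for a joint five-method benchmark
at n = 3 + 3; with six samples there is no design in this model family
that makes all five methods essentially infallible. The preset's
parameters are fixed; they are a benchmark specification, not a claim
about the biological magnitude of instability in any real panel.

`simulate_dilution_series()` inverts the standard-curve model exactly,
so noise-free series recover the generating efficiency to floating-point
precision, and `simulate_fpkm_table()` draws log-normal abundances with
a designated enriched fraction for screen-recovery tests.

## Numerical choices and edge cases

- Sample SD uses the n-1 denominator everywhere, matching the cited
  method tools.
- geNorm ties at the maximal M remove the lexicographically later id.
- NormFinder variance estimates truncated at zero; gamma2 = 0 falls back
  to intragroup-only ranking as described above.
- A t-test on groups with zero within-group variance (possible only in
  noise-free simulation) returns t = 0, p = 1 for equal means and
  p = 0 otherwise, rather than erroring.
- Consensus ties sort alphabetically; all orderings in the package are
  deterministic under a fixed seed.
- The long-CSV writer prints Ct with 17 significant digits so write/read
  round trips are value-exact.

## Problem sizes

The test suite and the acceptance script use the study-scale design
throughout: 7-8 genes x 6 samples x 3 replicates, 200 simulated
experiments for recovery rates, 100 for efficiency recovery, and
3-7 gene x 4-12 sample matrices for the oracle-equivalence properties.
The full suite runs in well under a minute on a laptop.

## Limitations

- Two groups only: the NormFinder pair criterion and the egg/cortex
  design are two-group; multi-group generalizations are out of scope.
- No fluorescence-level processing: Ct values are the input; baseline
  correction, melting curves, and single-curve efficiency estimation
  belong upstream.
- The published experiment this workflow mirrors deposits its raw Ct
  values as a spreadsheet supplement; those values are not
  redistributable here, so the reproduction test in the suite documents
  the expected printed values and runs only when the user supplies the
  exported CSVs (see `tests/testthat/test-acceptance.R` for the paths).
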