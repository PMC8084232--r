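---
title: "Methods: windowed F_ST / diversity selection scans with sweepscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: windowed F_ST / diversity selection scans with sweepscan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem and the design

`sweepscan` looks for candidate selective sweeps in multi-population SNP
panels — the setting of reduced-representation (RAD-type) livestock surveys
with a handful of populations of five to seven diploid individuals each. A
sweep leaves two fingerprints in such data: the selected population's allele
frequencies drift away from everyone else's (elevated differentiation), and
linked variation is dragged along with the favoured allele (depressed local
diversity). The pipeline quantifies both in sliding windows and calls a
window a candidate only when it is an outlier for *both* statistics.

The contrast design is one-vs-rest: each target population is compared with
the pool of all remaining populations, and the pool is recomputed for every
target. Pooling the remainder gives the reference enough chromosomes for
stable allele-frequency estimates when any single population would be too
small, at the cost of diluting any sharing between the target and its
closest relative.

## Statistics

**Nucleotide diversity.** At a biallelic site with `k` alternate alleles
among `n` called alleles, Nei's unbiased pairwise estimator is
`pi = 2k(n - k) / (n(n - 1))` — the fraction of allele pairs that differ.
Window diversity is the sum of per-site values divided by the *window span
in bp* (not the number of variant sites), so unobserved and monomorphic
positions count as zero differences. This is the convention of VCFtools'
windowed-pi output and of the in-house scripts such scans are usually run
with; dividing by segregating sites instead would conflate diversity with
SNP density.

**Low-diversity score.** The lower tail of the diversity distribution is
selected through `-log10(pi + epsilon)`, so a *high* score marks a *low*
diversity window and the same top-quantile machinery serves both
statistics. `epsilon = 1e-8` keeps `pi = 0` windows finite; it is two to
three orders of magnitude below any attainable nonzero per-bp window
diversity at these sample sizes (one singleton in a 50-kb window at
`n = 14` already gives about `3e-6`), so it never reorders nonzero windows.

**F_ST.** No single canonical F_ST exists; we use the Weir & Cockerham
(1984) variance-components estimator — the de-facto standard of
VCFtools-era selection scans — with the target and the pooled reference as
the two populations. Per site we compute the among-population (`a`),
between-individual (`b`) and within-individual (`c`) components from sample
sizes, allele frequencies and observed heterozygosities (missing calls
excluded per site); a window's F_ST is the ratio of sums
`sum(a) / sum(a + b + c)`. Ratio-of-averages windowing is deliberate:
averaging per-site ratios is badly behaved at low-information sites.
Negative window estimates are retained — they are legitimate draws from the
estimator's null distribution and populate the lower tail only. A window
with no usable site or a zero denominator is *undefined* (`NA`) and
excluded from ranking, never silently zero. Hudson's estimator is available
(`scan_config(fst_estimator = "hudson")`) for sensitivity checks.

Note one finite-sample property the test suite pins down: for two
*identical* samples the `a` component is not 0 but a small negative number
(the estimator subtracts its sampling-noise correction from an
among-population variance of exactly zero). The estimator centres on zero
in expectation, which the panmictic-null simulation checks.

## Windows, outliers, candidates

Windows are 50 kb advanced in 25-kb steps (defaults; `scan_config()`),
0-based half-open internally and in BED output, 1-based inclusive in the
human-readable TSVs. A site at 1-based position `p` belongs to `[s, e)` iff
`p - 1` is in the interval; with a half-span step every interior site falls
in exactly two windows.

For each statistic the outlier cutoff is the empirical 95th percentile
(type-7, linear interpolation — R's default; at around a thousand windows
the choice of quantile type moves the cut by at most one window). A window
is an outlier iff its value is **greater than or equal to** the cutoff:
ties at the threshold are always kept rather than silently dropped.
Candidates are the *intersection* of the two outlier sets, and overlapping
or book-ended candidate windows are merged into maximal regions.

Windows with fewer than `min_sites_per_window = 3` SNPs are excluded from
both distributions (and can never be flagged): in sparse RAD data, empty or
near-empty windows would otherwise dominate the low-diversity tail purely
through missingness. Setting the parameter to 1 mimics a naive script.

Two conventions the literature leaves open are settled here and exposed as
configuration rather than hidden:

* The `-log10` transform is applied to the **target** population's window
  diversity — sweeps deplete diversity in the selected population, not the
  pool. Reference diversity and the ratio `pi_ref / pi_target` are computed
  and reported in every window table, so a ratio-based rule can be applied
  downstream without rerunning the scan.
* The MAF/missingness filter is **cohort-wide** (one pass over all samples
  before any contrast, boundaries strict: a site at MAF exactly 0.05 or
  missingness exactly 25% is dropped), matching a single post-calling
  VCFtools pass rather than per-population filtering.

## Gene extraction and enrichment

Genes are read from GFF3 (`gene` features; `ID` attribute). A gene is
selected iff its body overlaps a candidate region by at least 1 bp, strand
ignored, half-open semantics (an abutting gene does not overlap); no
promoter flank is added. Term enrichment is the one-sided hypergeometric
(Fisher exact upper-tail) test per term, BH-adjusted across all tested
terms, significant iff FDR <= 0.05. The background universe is **all genes
in the supplied annotation**, not just genes carrying at least one term —
this choice changes `N` and every p-value, which is why it is an explicit
argument. Term maps are plain TSV (`gene_id, term_id, term_name,
category`), so offline fixtures and real GO/KEGG exports go through the
same door; no ontology graph is bundled or traversed, and the per-category
"classification" view is a flat tally.

Enrichment is reported per target and for the pooled union of all targets'
selected genes. At desk scale a single contrast selects only a handful of
genes and the hypergeometric test has little power there; the study-level
union is the decisive test and is what the acceptance checks use.

## The simulator: what it emulates, and what it does not

`simulate_dataset()` draws a Balding–Nichols cohort: ancestral frequencies
from a Beta(0.8, 0.8) rescaled to [0.01, 0.99] (a U-shaped spectrum that
straddles the 0.05 MAF filter boundary), population frequencies from
`Beta(p(1-F)/F, (1-p)(1-F)/F)`, Hardy–Weinberg genotypes, and i.i.d.
missing calls. Defaults mirror the motivating study design: seven
populations of 7/7/7/5/7/7/7 diploids (47 samples), 5,000 SNPs on two 2-Mb
chromosomes, background `F = 0.05`, 10% missingness.

Sweeps are modelled phenomenologically: at in-sweep sites the target
population's frequency is drawn at `F = sweep_fst` (default 0.4) and then
moved to the root of `q'(1 - q') = pi_scale * q(1 - q)` on the side of the
nearer boundary — an *exact* per-site heterozygosity scaling (default
`pi_scale = 0.1`). The scan only sees diversity and differentiation, so
matching those two targets is sufficient for correctness and power tests;
no sweep dynamics are simulated.

Default sweeps are 250 kb, aligned to the window grid, ten in total with
targets assigned round-robin (the first three populations carry two each).
The length is chosen so each sweep spans nine full windows while the top-5%
quota of a 160-window genome is eight: the outlier tail saturates *inside*
the swept region, the regime a strong sweep produces in real scans. That is
why, on the default fixture, candidate precision against truth is near
100% — edge windows that only half-overlap a sweep cannot outrank
fully-contained ones.

Fidelity limits, stated plainly: no linkage (sites are independent given
the frequencies, whereas real sweeps create long haplotypes — acceptable
because the scan treats sites within windows additively), no
RAD-locus-structured dropout (missingness is i.i.d. per call), no
demography beyond the single `F` parameter, and no allele-frequency
correlation between neighbouring sites. Passing the recovery tests
therefore shows the *machinery* ranks and intersects correctly under known
truth; it does not calibrate real-data false-discovery rates.

The matched null (`remove_sweeps()`) keeps the sweep *intervals* — so the
planted term's gene set is constructed identically — but resets their
effects (`sweep_fst = background`, `pi_scale = 1`). Comparing the two
fixtures isolates what the intersection rule buys: with around `q^2` of
windows expected as joint outliers by chance, null candidate counts
collapse to a few windows genome-wide.

## Determinism and problem sizes

All randomness lives in the simulator and flows from one seed;
filter/scan/annotate/enrich are deterministic, and identical inputs and
configuration give byte-identical output files (checked by checksum in the
tests). The test suite and the acceptance script run the full pipeline on
the default 5,000-SNP, 47-sample fixture — across five seeds for recovery
and twenty paired seeds for the null control — which completes in a couple
of minutes on a single core; Monte-Carlo checks of the estimators use up to
1e5 sites. These sizes were picked so the whole battery is routinely
rerunnable during development while leaving the Monte-Carlo tolerances
honest (binomial/mean errors of a few percent at the stated `n`).

## Known limitations

* The pooled reference mixes heterogeneous populations; strong structure
  among the non-target populations inflates the within-"population"
  components and deflates F_ST relative to pairwise contrasts. A
  fixed-reference contrast can be had by passing a two-population sample
  map.
* Window-level statistics on overlapping windows are strongly
  autocorrelated; candidate *counts* should be read per merged region, not
  per window.
* Empirical top-quantile selection always names 5% of windows outliers per
  statistic, sweep or no sweep; it is the intersection and the merged-region
  structure, not the tail itself, that carries evidential weight — hence the
  null-control comparison in the tests.
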