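---
title: "Width-matched permutation tests for interval colocalization: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Width-matched permutation tests for interval colocalization: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(peakperm)
```

# The problem

A ChIP-seq experiment yields a set of binding sites for a factor — say
a histone methyltransferase such as KMT2D — and public resources supply
genome-wide domains of histone marks (H3K4me1 for enhancers, H3K27ac
for active enhancers, H3K4me3 for promoters). The fraction of binding
sites falling inside a mark track is easy to compute but meaningless on
its own: wide mark domains catch random intervals too. The question is
whether the observed colocalization exceeds what random placement of
equally many, equally wide intervals would produce.

`peakperm` answers that question with a Monte-Carlo permutation test,
and carries the result through the standard downstream steps of such an
analysis: per-site enhancer-state classification, selection of putative
distal enhancer loci relative to a TSS catalog, and ranking of a factor
panel by mark-overlap fraction.

# The model and its assumptions

## Overlap statistic

All coordinates are BED convention: 0-based, half-open. Book-ended
intervals share no base and do not overlap. The subject set is merged
(`merge_intervals`, gap 0) before counting, so a query site spanning
two abutting subject records counts once; query sites are never merged,
because the statistic is a *per-query-site* count. A site overlaps when
it shares at least `min_overlap_bp` bases with the merged subject; the
default of 1 bp is the field's most common rule and is a parameter, not
a constant, because published analyses rarely state their overlap rule.
When the subject is a list of mark sets, a site must clear the
threshold against *every* member — the site-level conjunction reading
of "positive for H3K4me1 and H3K27ac". The alternative reading
(overlap with the base-level intersection of the marks) is available
via `intersect_intervals` and the pipeline's `intersect_marks` flag;
conjunction is the default because the phrase describes sites, not
pre-intersected regions, and because the conjunction is the weaker
(more conservative about calling a site "active") of the two on
typical data.

## The null

Each permutation draws a random interval set preserving the query's
interval count and exact width multiset ("comparable widths" taken in
its strictest reading — exact per-interval width preservation is what
makes the null width-matched without inventing a binning scheme).
Placement is genome-wide: chromosome chosen with probability
proportional to `max(L - w + 1, 0)`, its number of legal start
positions for width `w`, then start uniform among them. This makes
every legal placement of an interval equally likely, which is the
natural formalization of "randomly generated across the genome".

Random intervals may overlap one another: real mark domains play no
role in the statistic's denominator, and mutual exclusion would distort
the null for dense queries (a `allow_self_overlap = FALSE` mode exists
for sensitivity analysis, as does a `same-chromosome` placement mode).
Assembly gaps are not excluded by default — the original analysis style
this emulates places anywhere — but a `genome_model` can carry an
excluded set, honored by rejection sampling with a budget of 1,000
retries per interval.

## The p-value

With `N` permutations and observed count `k_obs`,

```
p_enrich  = (1 + #{k_null >= k_obs}) / (N + 1)
p_deplete = (1 + #{k_null <= k_obs}) / (N + 1)
```

The add-one rule treats the observed arrangement as one more draw from
the null, so an empirical p-value is never 0 and never smaller than
`1/(N + 1)`; at the default `N = 10000` the floor is `1/10001`, i.e.
just under the conventional `p < 0.0001` reporting bound. Ties count
toward the exceedances in both tails, a conservative choice; a
consequence worth knowing is `p_enrich + p_deplete >= 1 + 1/(N + 1)`.
The z-score `(k_obs - mean(null)) / sd(null)` is reported as a
descriptive effect size only; no normality is assumed.

## Determinism

One integer seed fixes the entire analysis. Permutation `k` uses the
substream seed `(seed + 48271 * k) mod (2^31 - 1)`, so any single
permutation can be regenerated in isolation and partial reruns match
full runs. All generator functions restore the caller's RNG state on
exit.

# Annotation conventions

**Enhancer states.** Mark presence is binary peak overlap; the package
takes no position on signal strength because peak lists carry none.
`active_enhancer` = H3K4me1 and H3K27ac; `enhancer` = H3K4me1 without
H3K27ac; `none` otherwise. The three states partition any site set.

**TSS distance.** Measured from the region midpoint,
`floor((start + end) / 2)`, to the TSS base, signed by the gene's
strand: negative upstream, positive downstream. Midpoint-to-anchor was
chosen over edge-to-anchor because it is symmetric under strand and
insensitive to peak width; distances quoted as "5.4 kb upstream" style
figures reproduce under this convention. Nearest = minimal absolute
distance; ties prefer the upstream candidate, then the smaller label.
A region on a chromosome without any TSS gets `NA`, not an error.

**Distal-locus rule.** Putative distal enhancer loci are sites with
H3K4me1, without H3K4me3, strictly more than `upstream_min_bp`
(default 1,000) bp upstream of the nearest TSS. The inequality is
strict: a site at exactly 1 kb is rejected.

**Peak filtering.** `filter_peaks` retains records passing all supplied
thresholds (`score >=`, `fold_enrichment >=`, `fdr <=`). The FDR-like
column is thresholded on its native scale (MACS 1.x prints percent)
rather than a negative-log transform, avoiding a second sign
convention. Exact stringency is the caller's choice; the package does
not hard-code any particular cutoff because published "stringent
criteria" are rarely specified in full.

# The synthetic-data generator

Real inputs for this kind of study are a supplementary peak list and
versioned ENCODE tracks; neither is redistributable here, and neither
is needed to test the machinery. The generator builds:

* a genome (default 3 chromosomes, 5/3/2 Mb — 10 Mb total);
* 300 mark domains with log-normal widths (median 1 kb, sdlog 0.5),
  placed uniformly — about 3–4% genome coverage, comfortably under the
  10% that keeps the null overlap count well away from saturation;
* a query of 1,605 sites with a **planted overlap fraction**
  `f = 0.87`: exactly `round(f * n)` sites are anchored on a uniformly
  chosen mark domain and the rest are rejection-sampled into the
  complement, so `count_overlapping` returns exactly `round(f * n)` —
  the enrichment is planted exactly, not in expectation, which turns
  acceptance checks into integer equalities instead of tolerances;
* a 19-member factor panel with distinct planted fractions (designated
  query factor on top) and a stranded TSS catalog with unique labels.

The counts 1,605 / 300 / 19 and the fraction 0.87 mirror the motivating
study's scale; the 10 Mb genome is a deliberate desk-scale reduction —
placement probabilities and the planted geometry are scale-free, so
nothing in the statistic depends on genome size beyond runtime. What
the generator does **not** emulate: GC and mappability structure,
spatial clustering of chromatin domains, width correlation between
marks and sites, or read-level noise. Passing tests therefore certify
the statistical machinery, not robustness to those real-data artifacts.

# Numerical and testing choices

* Percentages print with half-up rounding (`floor(100 f + 0.5)`), the
  convention under which 1403/1605 is 87% and 1207/1605 is 75%; R's
  banker's rounding would differ at exact halves.
* Overlap counting runs on a per-chromosome stabbing index (sorted
  merged starts/ends plus cumulative covered width; two
  `findInterval` lookups per query), giving O((n + m) log m) per
  permutation with small constants. The test suite checks it against a
  per-base bitmap oracle and against `GenomicRanges::countOverlaps` on
  random instances.
* The full default test — 1,605 sites, 10,000 permutations — runs in
  well under a minute; tests that loop (1,000 brute-force instances,
  1,000 width-preservation draws, 200 calibration replicates of 200
  permutations) use instance sizes chosen so the whole suite stays in
  the low minutes.
* Null calibration is checked on a 1.5 Mb genome with 60 mark domains:
  a geometry where the null count takes many distinct values. On very
  coarse geometries the discrete add-one p-value is strongly
  conservative (ties inflate the exceedance count), which would mask
  the calibration being measured; conservativeness itself is expected
  and harmless for inference.
* Degenerate inputs are defined, not patched around: an empty query is
  an error (the fraction is undefined), an empty subject gives count 0,
  a subject covering the whole genome gives fraction 1 and
  `p_enrich = 1`, and a width larger than every chromosome is a
  placement error.

# Known limitations

* Binary overlap only — no signal-level (bigWig) scoring, no
  super-enhancer stitching, no differential enrichment between two
  query sets.
* The null randomizes location only; GC-, mappability- or
  distance-to-TSS-matched nulls are out of scope.
* Empirical p-values cannot go below `1/(N + 1)`; claims beyond that
  floor require larger `N`, at linear cost.
* Chromosome-name harmonization handles only the `chr` prefix;
  assembly liftover is the caller's job.
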