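# peakperm

Colocalization statistics for genomic interval sets, built around the
question a ChIP-seq study typically asks of a histone-modification
track: *do my binding sites fall inside these mark regions more often
than chance placement would produce?*

The package is aimed at regulatory-genomics analysts working with
BED-format peak lists — for example KMT2D binding sites against
H3K4me1 / H3K27ac / H3K4me3 enhancer marks in a colorectal cancer cell
line — who want the overlap fraction, a permutation p-value, an
enhancer-state call per site, and a ranked comparison across a panel of
transcription factors, all reproducible from a config file and a seed.

## The statistic

For a query set *Q* of *n* sites and a subject set *S* of mark regions
(merged before counting), the observed statistic is the number of query
sites sharing at least `min_overlap_bp` bases (default 1) with *S*:

    k_obs = #{ q in Q : |q ∩ S| ≥ min_overlap_bp },   fraction = k_obs / n

Significance comes from a **width-matched Monte-Carlo null**: for each
of *N* permutations (default 10,000) a random set with exactly the same
number of intervals and the same width multiset as *Q* is placed across
the genome — chromosome chosen with probability proportional to its
number of legal placements, start uniform among them — and the statistic
is recomputed. The one-sided empirical p-value uses the add-one rule

    p_enrich = (1 + #{ k_null ≥ k_obs }) / (N + 1)

so it is never zero and its minimum is 1/(N+1); with N = 10,000 that is
1/10,001 < 0.0001. Ties count against significance. A z-score
(k_obs − mean)/sd of the null and the depletion tail are reported
alongside.

Downstream annotations operationalize the usual enhancer vocabulary:
a site overlapping H3K4me1 only is an `enhancer`, H3K4me1 + H3K27ac an
`active_enhancer`; putative distal enhancer loci are H3K4me1-positive,
H3K4me3-negative sites lying strictly more than 1 kb upstream of the
nearest TSS (signed midpoint-to-TSS distance, strand-aware).

## Worked example

Everything below runs on a synthetic fixture whose geometry mirrors the
motivating study at desk scale: a 10 Mb genome in 3 chromosomes, 300
mark domains (log-normal widths, median 1 kb), and 1,605 query sites of
which exactly `round(0.87 × 1605) = 1396` are planted to overlap the
marks.

```r
library(peakperm)

spec   <- synthetic_spec(seed = 1)          # defaults shown above
genome <- generate_genome(spec)
marks  <- generate_feature_set(genome, spec$n_subject,
                               spec$subject_width_law, seed = 8,
                               label = "marks")
sites  <- plant_enriched_query(marks, genome, spec$n_query,
                               spec$planted_fraction,
                               spec$query_width_law, seed = 9,
                               label = "sites")

count_overlapping(sites, marks)
#> overlap: 1396 / 1605 query intervals (0.8698, 87%) at >= 1 bp

permutation_test(sites, marks, genome, n_permutations = 10000,
                 config = randomization_config(seed = 1))
#> Width-matched permutation test of interval colocalization
#>   query:   sites (n = 1605)
#>   subject: marks
#>   observed overlap: 1396 / 1605 (0.8698, 87%)
#>   null (N = 10000): mean 102.75, sd 9.76, z = 132.49
#>   p(enrich) = 9.999e-05, p(deplete) = 1  [add-one rule, seed 1]
```

Reading the output: 87% of sites overlap the marks, while random
width-matched placement overlaps about 103 of 1,605 (≈ 6%); no null
draw comes close to 1,396, so the p-value sits at its floor 1/10,001 —
reported, rather than rounded to zero, because the empirical rule
cannot resolve anything smaller at N = 10,000.

The same analysis runs from a shell via the thin CLI over a YAML
config:

```sh
Rscript inst/cli/peakperm.R simulate --config run.yaml
Rscript inst/cli/peakperm.R enrich   --config run.yaml --seed 1
Rscript inst/cli/peakperm.R classify --config run.yaml --select-distal
Rscript inst/cli/peakperm.R rank     --config run.yaml
```

Each output directory contains the echoed config, a TSV and a JSON
report with identical fields, and a log of inputs, seed and overlap
rule.

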