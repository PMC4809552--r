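# barscan

Discovery of lineage-accelerated regulatory elements from multiple genome
alignments, at desk scale and fully testable.

Many clade-specific traits are driven by regulatory DNA that was deeply
conserved across a phylogeny and then evolved rapidly on one lineage —
accelerated regions. `barscan` implements the complete discovery chain for
such elements:

1. **Conserved-element detection** with a two-state phylogenetic HMM
   (neutral vs. rate scale ρ < 1), run with the focal clade *masked* so its
   own divergence cannot suppress conservation calls; fragmented elements
   are merged while gap/span ≤ 0.1.
2. **Candidate construction**: base-level union of regulatory peak sets
   (e.g. ChIP-seq), intersection with merged elements > 100 bp, restoration
   of the focal species, reciprocal-best-hit integration of extra
   focal-clade genomes available only as contigs (Smith–Waterman +
   Karlin–Altschul e ≤ 0.01), and missing-data (> 50%), exon-overlap
   (> 25%) and taxa filters.
3. **The acceleration test**: for each candidate, a likelihood ratio test
   for a free rate scale λ ≥ 1 on the focal clade's *stem edge* (its
   ancestral lineage) against the neutral null, with the boundary null
   ½δ₀ + ½χ²₁ for D = 2(lnL₁ − lnL₀), Benjamini–Hochberg FDR, and calls at
   q < 0.05.
4. **Characterization**: marginal ancestral reconstruction of the focal
   MRCA, TFBS gain/loss screening against PWMs with exact null score
   distributions and a conditional-binomial count test, TSS distances,
   gene deserts, clustering and gene-proximity enrichment.

A truth-labeled synthetic genome generator (`generate_synthetic()`)
exercises every stage with no external data, and is how the package
validates FDR control and sensitivity.

Inputs are the field's plain-text formats: MAF alignments, newick trees,
BED intervals, FASTA contigs, JASPAR-style PFMs.

## Worked example

Generate a 200 kb synthetic genome on a 10-leaf tree whose 4-leaf focal
clade carries planted acceleration (λ = 10 on the clade's stem edge, in
10% of the 60 conserved elements), then run the pipeline:

```r
library(barscan)

bundle <- generate_synthetic(synthetic_config(seed = 4))
bundle
#> synthetic_bundle: 200000 bp chromosome, 60 planted elements (7 accelerated), 59 peaks, 105 contigs

run <- run_pipeline(bundle_config(bundle))
run
#> acceleration discovery pipeline run
#>   conserved        61
#>   merged           61
#>   peaks            54
#>   selected         42
#>   rbh_integrated   68
#>   candidates       31
#>   bars             5
#>   tfbs_significant 0

run$results[run$results$is_bar,
            c("id", "start", "end", "lambda_hat", "D", "p", "q")]
#>        id  start    end lambda_hat        D            p            q
#> 4   cand5  14703  15016   2.681077 33.68648 3.237461e-09 3.345376e-08
#> 10 cand16  64441  64747   2.660646 31.04226 1.262357e-08 9.783265e-08
#> 24 cand32 156077 156408   3.008428 46.92019 3.696845e-12 1.146022e-10
#> 27 cand35 169022 169270   2.394882 19.49192 5.051297e-06 3.131804e-05
#> 28 cand38 183534 183774   3.262092 38.98425 2.136192e-10 3.311097e-09
```

The stage counts mirror the accounting a real analysis reports: 61
detected conserved elements intersect 54 unioned peaks to give 42
selected regions, of which 31 survive the missing-data/exon/taxa filters
and 5 are called accelerated at FDR < 5%. The fitted stem-edge scales
λ̂ ≈ 2.4–3.3 are what planted λ = 10 looks like through the candidates'
conserved background (ρ = 0.3 scales the whole element, so the stem runs
at 3× neutral). Scoring the calls against the planted truth:

```r
truth <- bundle$truth
acc <- truth[truth$accelerated & truth$expected_fate == "pass", ]
evaluate_calls(run$bars, acc)
#> $sensitivity [1] 1
#> $fdp         [1] 0
#> $jaccard     [1] 0.9770674
```

All five plantable accelerated elements are recovered with no false
calls and 98% base-level overlap. The same objects expose the TFBS
screen (`run$tfbs_screen`), reconstructed ancestors (`run$ancestors`)
and annotation statistics (`run$annotation`); `run_pipeline(...,
out_dir = )` writes every stage as BED/TSV plus a machine-readable
stage-count log, byte-identically across reruns with the same seed.

A thin CLI over the same functions lives at `inst/cli/barscan.R`
(subcommands `simulate`, `conserve`, `bars`, `run-all`).

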