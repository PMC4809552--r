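---
title: "Methods: detecting lineage-accelerated regulatory elements"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: detecting lineage-accelerated regulatory elements}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Some of the clearest signals of regulatory innovation are *accelerated
regions*: stretches of non-coding DNA that stayed deeply conserved across
most of a phylogeny but accumulated an excess of substitutions on one
lineage — the pattern made famous by human accelerated regions and equally
informative in other clades with striking derived phenotypes (bat wings
being the motivating example for this package). `barscan` implements the
full discovery chain at desk scale: conserved-element detection with the
focal clade masked, candidate construction against regulatory peak
intervals, a branch-specific likelihood ratio test with FDR control, and
post-hoc characterization (binding-site turnover against a reconstructed
ancestor, spatial clustering, gene proximity).

Everything runs on plain-text standard formats (MAF, newick, BED, FASTA,
JASPAR PFM) and is exercised end to end by a truth-labeled synthetic
genome generator, so every stage is testable without external downloads.

# Substitution models and the likelihood engine

Two reversible nucleotide models are supported, JC69 and HKY85
(equilibrium frequencies $\pi$, transition/transversion ratio $\kappa$,
default $\kappa = 4$ with $\pi$ estimated from the reference sequence
when not supplied). The rate matrix $Q$ is normalized to one expected
substitution per site per unit branch length, so branch lengths keep
their usual units. Transition matrices $P(t) = e^{Qt}$ come from a single
cached eigendecomposition of the symmetrized rate matrix; tiny negative
entries from roundoff (magnitude $\sim 10^{-16}$) are clipped to zero.

Column likelihoods use Felsenstein pruning, vectorized across alignment
columns (per-node partials are $4 \times n$ matrices, one 4×4 by 4×n
product per edge). Partials are rescaled per column to dodge underflow.
Gap and `N` characters are missing data — a partial-likelihood vector of
ones — and a species in the tree but absent from an alignment is treated
the same way unless strict mode is requested. This matches the common
convention of phylogenetic HMM packages; the alternative (treating gaps
as a fifth state) changes little at these divergences and is not
implemented.

Marginal ancestral reconstruction combines the pruning ("down") partials
with a root-to-node ("up") pass; posteriors are exact marginals and the
reported base is the per-column MAP, with ties broken in the fixed order
A < C < G < T. Columns with no observed data anywhere below the target
node are reported as `N`. Joint (path-wise) reconstruction is out of
scope; marginal MAP is what ancestral-sequence tools in this area
conventionally report.

# Conserved-element detection

Conservation is modeled with a two-state phylogenetic HMM: a neutral
state emitting columns under the unit-rate model and a conserved state
emitting them with every branch scaled by $\rho < 1$. Transition
probabilities derive from expected element and spacer lengths,
$\mu = 1/L_c$ and $\nu = 1/L_n$. Defaults are $\rho = 0.3$, $L_c = 100$
bp, $L_n = 1000$ bp, chosen once for reproducibility; no EM
re-estimation or coverage autotuning is performed (fixed, exposed
parameters were preferred over opaque coverage autotuning, so a run is
fully specified by its configuration).
Elements are maximal runs of the Viterbi conserved state; each carries
the summed per-column log-odds
$\sum_i \log P(\text{col}_i \mid \text{conserved}) / P(\text{col}_i \mid \text{neutral})$
and its mean forward–backward posterior. Columns where the reference is
gapped inherit the preceding reference position, so elements can never
be zero-length.

Detection runs with the focal clade removed from both the alignment and
the tree, so that focal-lineage divergence cannot suppress a
conservation call — the step that makes the downstream test unbiased
with respect to the lineage being tested.

## Merging

Adjacent elements are merged while
$\text{gap} / \text{span} \le 0.1$, where *span* is the extent of the
would-be merged region (gap included). Taking the denominator to be the
merged span (rather than, say, the shorter member) is a design choice
frozen here and shared by the implementation and its test oracle. The scan is left-to-right, repeated
to a fixed point. Because merging a pair only enlarges the spans of
neighboring pairs (gaps are unchanged), a merge can never disable
another: the system is confluent and the left-to-right fixed point
equals the best-ratio-first fixed point, which the test suite checks on
hundreds of random inputs. Scores of merged members are summed. Length
filtering (elements must exceed 100 bp) is applied downstream, after
merging, so short fragments can still contribute to a long merged
element.

# Candidate construction

Peak sets are unioned at base level. Merged elements strictly longer
than 100 bp that overlap at least one peak by at least one base become
candidates; the focal species are then restored from the unmasked
alignment. Three filters apply as a conjunction; each threshold is a strict
"more than", so boundary values survive:

* drop if any focal alignment species is missing (gap/`N`) in strictly
  more than 50% of candidate columns — a fraction of exactly 0.5 is kept;
* drop if strictly more than 25% of reference bases overlap a coding
  exon — exactly 25% is kept;
* drop if fewer than one focal taxon (alignment species plus integrated
  contig species) is present.

## Extra genomes by reciprocal best hit

Focal genomes available only as contigs are integrated per candidate.
The forward search is Smith–Waterman local alignment (match +1,
mismatch −2, gap open 5 / extend 2) of the candidate's reference
sequence against the species' contigs; the best hit must reach
$e \le 0.01$ under ungapped Karlin–Altschul statistics
($E = K m n e^{-\lambda S}$, with $\lambda$ solved exactly for the score
scheme and $K$ fixed at 0.1 as a documented approximation constant —
the e-value is a thresholding device here, not a calibrated tail
probability). The winning contig is then aligned back to the reference
genome; the hit is reciprocal iff the reverse top alignment overlaps the
original candidate interval by at least one base — the weakest
requirement that still anchors the contig to the query locus. The
reverse search seeds exact 11-mers into a sorted k-mer index of the
genome, picks the best-supported diagonal window, and runs
Smith–Waterman inside it — the seed-and-extend family of heuristics
BLAST itself uses, which keeps the threshold semantics while avoiding
quadratic full-genome alignment. Accepted contig segments are projected onto
reference columns (contig insertions relative to the reference are
dropped) and added as new alignment rows. The reverse hit is best within the
seeded window rather than provably best genome-wide; for the divergences
this pipeline targets the two coincide whenever usable seeds exist.

Integrated species are grafted into the test tree next to their closest
alignment relative. The graft splits the sister's pendant branch at a
configurable fraction (default: at the tip itself) with a configurable
pendant length; both knobs are exposed because no principled default
exists without genome-wide data for the added species.

# The acceleration test

For each candidate, the focal clade's *stem edge* — the branch from its
most recent common ancestor to its parent — receives a free
multiplicative scale $\lambda$. The null model fixes $\lambda = 1$ (the
neutral model; conservation is deliberately not re-fit per element, so
the test asks "faster than neutral on the stem", a conservative question
for conserved input). The alternative frees $\lambda \ge 1$: a one-sided
acceleration test, fitted by bounded scalar search on $\log \lambda$
over $[1, 100]$ with tolerance $10^{-6}$, ties resolved to the bound.
Only the stem edge is scaled — the hypothesis concerns the clade's
ancestral lineage, not its crown branches (whole-clade scaling exists in
the synthetic generator to probe misspecification, not in the test).

Because the null value sits on the boundary of the parameter space, the
statistic $D = 2(\ln L_1 - \ln L_0)$ is referred to the boundary null
$\tfrac12 \delta_0 + \tfrac12 \chi^2_1$: $p = 1$ when $\hat\lambda$ is
at the bound and $p = \tfrac12 P(\chi^2_1 \ge D)$ otherwise. A
parametric bootstrap p-value is available behind a switch for very short
alignments. Multiple testing uses Benjamini–Hochberg by default, with
Benjamini–Yekutieli available behind a flag for dependence-robust
control; regions with $q < 0.05$ (strictly) are called.

# TFBS gain/loss screening

Hits are called by scanning both strands with log-odds scores against
background, discretized to a 1e-3-bit grid. The null score distribution
is computed *exactly* on that grid by column-wise convolution (widths up
to 25), and window scores are built from the same integer increments, so
p-value lookups are exact with respect to the discretization. A
pseudocount of 0.01 is added to PWM columns; background defaults to
uniform. Per sequence, all window-strand p-values are BH-adjusted and
hits are called at $q \le 0.01$; adjustment is per sequence, not
genome-wide, and flagged as such. Overlapping hits on opposite strands
both count.

Count divergence between the reconstructed focal ancestor and the extant
reference uses a conditional exact test: given $K = k_a + k_b$ total
hits, under the null $k_a \sim \mathrm{Binom}(K, n_a/(n_a+n_b))$ where
$n$ are scannable window-strand slots; the two-sided p-value sums all
outcome probabilities not exceeding the observed one. This is a
simplification of the correlated-binomial treatment of overlapping
windows found in dedicated motif-divergence tools; that refinement is a
stated non-goal, and the
simplification is conservative in the pooled regime the pipeline uses
(counts summed over elements, BH across motifs, significance at
$q < 0.05$).

# Annotation statistics

TSS distances treat a TSS as occupying its single base `[p, p+1)`; the
distance from an element is zero if the TSS is inside, otherwise the
number of intervening bases — a convention that is exactly symmetric
under coordinate reflection. Gene deserts require the nearest TSS on
*each* side to be strictly more than 500 kb away.

The clustering statistic defaults
to the median same-chromosome nearest-neighbor midpoint distance
(robust and scale-free); a pairs-within-distance count is available
behind a flag, and the choice is recorded in output headers. The null
resamples called-sized candidate subsets without replacement, preserving
count only (length/chromosome-matched resampling is a flag). Proximity
enrichment classifies candidates as within 1 Mb of a listed TSS, reports
the 2×2 odds ratio with Haldane–Anscombe 0.5 correction when a cell is
zero, and a resampling p-value. All permutation p-values use the add-one
rule and can never be exactly zero.

# The synthetic genome generator

The generator emulates the statistical structure of the real inputs, not
their content: a neutrally evolving chromosome (default 200 kb) on a
10-leaf tree whose 4-leaf clade plays the bats; 60 planted elements of
150–350 bp at conserved scale $\rho = 0.3$ spaced at least 1.2 kb apart;
10% of elements accelerated at $\lambda = 10$ on the focal stem edge
(mirroring the test's alternative); whole-species dropout within
elements at rate 0.1 per focal species (whole-species rather than
per-column, so the missing-data filter sees realistic structure); peaks
over 70% of elements plus background peaks; exons heavily overlapping
10% of elements; 40 TSSs; two extra focal genomes emitted only as
contigs (evolved from their alignment sisters, branch 0.04) so the RBH
stage is genuinely exercised; and a small set of high-information
8-bp motifs. Where the reference analysis pins no value, defaults were
chosen once as field-plausible and are not tuned: element sizes bracket
typical enhancer-core lengths, tree depth matches a mammal-wide
alignment's order of magnitude, and dropout reflects patchy low-coverage
assemblies.

The generator does *not* emulate indel evolution (alignments are
gapless except for dropout), alignment error, GC-content heterogeneity,
or chromatin-signal structure beyond interval placement — so passing
tests demonstrate correctness of the inference machinery under the
stated generative model, not robustness to real-alignment artifacts.
Every planted element carries a truth record (rates, peak/exon status,
dropout, expected filter fate), and calls are scored by reciprocal
overlap ≥ 50%.

# Numerical choices, validation sizes, limitations

* Tolerances: pruning is validated against exhaustive ancestral-state
  enumeration at relative 1e-10 (100 random trees of up to 6 leaves);
  forward–backward posteriors against path enumeration at 1e-10;
  transition matrices satisfy Chapman–Kolmogorov at 1e-10.
* Calibration: 500 neutral replicates (8-leaf tree, 300 columns) keep
  the fraction of $p \le 0.05$ inside [0.02, 0.08]; scale recovery uses
  50 replicates each at $\lambda \in \{2, 5, 10\}$ and 2000 columns
  (median within ±40%); FDR control and ≥ 0.7 sensitivity are checked
  over 20 truth-labeled genomes at generator defaults.
* Degenerate inputs: all-missing columns have likelihood 1; flat
  likelihoods tie the branch scale to its lower bound; $\nu = 0$
  (infinite expected spacer) yields zero conserved elements; an empty
  contig database is a warned no-op; zero-cell enrichment tables are
  corrected.
* Known limitations: no rate variation across sites (Γ), no GTR, no
  joint ancestral reconstruction, the motif screen ignores hit
  correlation between overlapping windows, and the RBH e-value is an
  ungapped approximation applied to a gapped score. These are the
  documented boundaries of the method, not accidents of implementation.
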