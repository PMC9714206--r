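---
title: "lncirc: models, rules and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{lncirc: models, rules and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the science it implements: the
rules and statistics of each stage, the tunable parameters and why their
defaults are what they are, what the synthetic-data generator does and does
not emulate, and the design decisions that were genuinely open.

## Coordinates and formats

All internal coordinates are 0-based half-open intervals; "overlap" always
means at least one shared base under those semantics. GTF input/output is
1-based inclusive and the conversion happens exactly once, inside `read_gtf()`
and `write_gtf()`; the BED-like junction tables are already half-open. The
GTF reader is deliberately strict about structure (malformed lines are
reported with their line number, `end < start` is rejected) and deliberately
permissive about attribute keys (`gene`/`gene_id`, `transcript`/
`transcript_id` are both accepted, since annotation dialects vary); attributes
the package does not model are carried as opaque text so a read/write round
trip is lossless.

## lncRNA identification

Candidates annotated as known mRNAs or as other non-coding classes
(pseudogene, pre-miRNA, tRNA, ...) are removed first. The structure filter
then requires at least `min_exons = 2` exons and a *spliced* length (summed
exon lengths, not the genomic span — the natural length of a processed
transcript) of at least `min_length = 200` bp; a transcript of exactly 200 bp
is kept, because the filter removes transcripts *shorter than* 200 bp.
`coding_consensus()` keeps a candidate only when all four coding-potential
assessors (CNCI, CPC, PFAM, CPAT) call it noncoding; the verdict table is
consumed as data, the assessors themselves are upstream tools.

## Positional classification

The six lncRNA classes are evaluated in a fixed priority order, because a
transcript can satisfy several definitions at once and the definitions alone
do not say which one wins. The order — same-strand exon overlap, same-strand
intron overlap, antisense exon overlap, antisense intron overlap,
bidirectional, intergenic — encodes two principles: exon-level evidence
outranks intron-level evidence, and sense relationships outrank antisense
ones.

Two operationalizations deserve note:

* **Bidirectional** means divergent ("head-to-head") transcription: the
  lncRNA and the coding transcript are on opposite strands, their spans are
  disjoint, the minus-strand partner lies entirely upstream of the
  plus-strand partner (so the transcripts point away from each other), and
  the TSS-to-TSS distance is at most `bidirectional_window = 1000` bp,
  inclusive. Convergent (tail-to-tail) neighbours are *not* bidirectional.
* **Exon/intron overlap for lncRNAs** uses the lncRNA's exons for the
  exon-exon test but its span for the intron tests; a lncRNA whose intron
  merely contains a coding transcript therefore falls through to intergenic,
  which is the only consistent reading of definitions phrased on the lncRNA's
  transcribed parts.

circRNA classes are also a priority partition: *exonic* requires both
back-splice boundary bases to fall within exons of one same-strand coding
transcript; *intronic* requires the span to sit entirely inside a single
intron; any other same-strand overlap is *sense overlapping*; an overlap on
the opposite strand only is *antisense*; otherwise *intergenic*. Junction
records without a known strand are rejected rather than guessed.

Classification runs on GenomicRanges indexes; the test suite holds it equal,
feature for feature, to a brute-force all-pairs scan on randomly placed
landscapes (1,000 lncRNAs, 500 circRNAs, 200 coding genes).

## Expression screening

The presence filter keeps a lncRNA expressed (value > 0) in at least
`min_positive_samples = 3` samples of either group — the strict reading of
"more than 2 samples" for groups of three, exposed as a parameter because the
wording does not generalize on its own. circRNAs count as expressed when some
sample has junction reads >= 2 ("over one" read strictly: one read is not
over one); because so few circRNAs are typically detected, their CPM screen
only asks for a positive value in any sample (`circ_presence = 1`).

Fold changes are `log2((mean_fat + eps) / (mean_lean + eps))` with
`eps = 0.01`, which keeps line-specific features (one group all zero) at a
large *finite* fold change so they appear among the DE features, as they
should. The screen calls `up` at `log2FC >= 1 & p < 0.05`, `down`
symmetrically, on raw p-values — the conventional screen for this design; a
BH column is available (`adjust = TRUE`) but off by default.

The p-value is a documented stand-in for count-model engines (which are out
of scope): a two-sample t test on `log2(x + 1)`. The default pools the group
variances rather than using Welch's approximation. This was measured, not
assumed: on a 10,000-feature null at 3 vs 3 the Welch form rejects at ~0.036
instead of 0.05 (the Welch–Satterthwaite correction is conservative at such
tiny degrees of freedom), while the pooled form — exact under the generator's
homoscedastic log-scale null — rejects at 0.049–0.051. Since abundances are
modeled as log-normal with a common dispersion, pooling is also the
model-consistent choice; `var_equal = FALSE` restores Welch. Degenerate
features follow a fixed convention: both groups constant and equal gives
p = 1 (no signal), both constant but different gives p = 0.

Line specificity is a zero-pattern rule, independent of the test: `fat_only`
means every lean value is exactly zero and at least one fat value is
positive.

## Target prediction and networks

Cis targets are coding gene loci (per-gene union of transcript spans) whose
span-to-span gap to the lncRNA locus is at most `cis_window = 50000` bp,
inclusive at the boundary, strand ignored; overlapping loci have distance 0.
The window is measured locus-to-locus rather than TSS-to-TSS because the rule
is about genomic position, not promoters.

Trans targets use the Pearson correlation of `log2(x + 1)` profiles (the raw
scale is available behind `log_transform = FALSE`), a two-sided p-value from
the exact t transform `t = r * sqrt((n - 2) / (1 - r^2))` with `n - 2`
degrees of freedom (a permutation p is pointless at n = 6: there are too few
distinct permutations), and BH adjustment over *all* tested pairs as one
global family — the conservative and deterministic choice where a per-lncRNA
family would depend on feature order. Pairs pass at `|r| > 0.95` and
`q < 0.05`. Zero-variance features are skipped with a warning since their
correlation is undefined.

The ceRNA screen keeps DE lncRNAs that are line-specific *and* cytoplasmic
(localization labels are consumed as data). Pair tables are filtered at
prediction score >= 70 — `>=` being the conventional reading of a
"threshold score of 70" — and only miRNAs present in both filtered tables
survive; the network is asserted tripartite (lncRNA-miRNA and miRNA-mRNA
edges only) as a hard failure. Hubs are ranked by degree with a
lexicographic tie-break so rankings are reproducible. Ego sub-networks are
the hub, its miRNAs, and those miRNAs' mRNA partners; because hubs share
miRNAs and mRNAs, sub-network edge counts can sum to more than the global
edge count.

## Enrichment

Over-representation is the exact hypergeometric upper tail
`P(X >= k) = sum_{i=k}^{min(K,n)} f(i; N, K, n)`, assembled by explicit
summation of the pmf; the test suite pins it to a combinatorial enumeration
oracle at 1e-12 on small universes. The universe defaults to all genes in the
term map and is overridable. Only over-representation is tested (one-sided),
results carry both raw p (the default significance readout) and BH q, and the
rich factor is `k / K`. Terms with no background genes are skipped, and
query genes outside the universe are a validation error rather than a silent
drop.

## The synthetic-data generator

`simulate_study()` emulates the study's inputs with planted ground truth:

* **Annotation** (`make_annotation()`): features are placed in disjoint
  20-kb slots, each planted lncRNA/circRNA next to its own private
  three-exon coding "anchor", so each feature satisfies exactly its intended
  class under the priority rules and the truth is unambiguous. A separate
  generator (`make_random_landscape()`) scatters features freely to stress
  the classifiers against the brute-force oracle.
* **Expression** (`make_expression()`): null features are i.i.d. log-normal
  (meanlog 3, sdlog 0.15 by default — low-noise biological replicates of
  inbred lines, and the regime in which planted-truth recovery is a sharp
  test); planted features multiply one group's mean by `fold = 4`;
  line-specific features are exactly zero in the other group; "sparse"
  features are positive in too few samples and exercise the presence filter.
  The defaults plant 5 up + 6 down + 14 fat-only + 5 lean-only lncRNAs so the
  screen recovers 19 up and 11 down (line-specific features surface as
  up/down through the pseudocount), and 5/0/9/3 circRNAs recovering 14 up and
  3 down.
* **Networks** (`make_pair_tables()`, `make_sponge_pairs()`): the qualifying
  edge wiring is planted exactly — 28 shared miRNAs each touching both
  sides, every node covered, 75 qualifying edges in total, plus decoy miRNAs
  present in only one table and sub-threshold rows that must never appear —
  and similarly 364 sponge pairs over 17 circRNAs and 314 miRNAs.
* **Enrichment** (`make_term_map()`): one term is loaded with planted target
  genes; the rest are random draws from the universe.

All generators are pure functions of `(seed, parameters)`: they seed the RNG
locally, restore the caller's RNG state, and re-runs are byte-identical.

What the generator does **not** emulate — and therefore what passing tests do
not show about real data: realistic genome structure (features sit in tidy
slots on one chromosome), count-level sampling noise and library-size
normalization (matrices are drawn directly on the FPKM/CPM scale),
heteroscedasticity and outlier samples, and annotation errors. One behaviour
is worth singling out: with strong planted line effects and n = 6, *any* two
group-shifted features correlate almost perfectly, so the co-expression stage
recovers the planted proportional pairs embedded in a denser block of
genuine |r| > 0.95 group-driven correlations. That is a property of
correlation screening at this design size, not of the implementation; the
dedicated trans-target fidelity test therefore uses an i.i.d. null fixture
(20 proportional pairs among 400 independent pairs) where the FDR bound is
meaningful, and both it and the calibration test pass at the spec'd
tolerances.

## Numerical conventions and problem sizes

Ties in hub ranking and in enrichment ordering break lexicographically;
correlations are clamped to [-1, 1] before the t transform; |r| = 1 maps to
p = 0. The test suite runs the classifier-equivalence check at 1,000 lncRNAs
/ 500 circRNAs / 200 coding genes, DE calibration on a 10,000-feature null,
recovery on a 1,000-feature matrix with 49 planted signals, network
exactness on 1,000-row random pair tables, and the end-to-end pipeline at
120 identified lncRNAs — sizes chosen so the whole suite runs in well under
a minute while keeping Monte-Carlo error far below the asserted margins.

## Known limitations

The DE stand-in is not a count model: it will not match dispersion-modeling
engines on real read counts, and its planted-truth recovery says nothing
about their behaviour. Correlation-based trans prediction at n = 6 cannot
separate direct regulation from shared group response (see above).
Localization and miRNA pair tables are consumed as given — no prediction is
performed — so their quality bounds the ceRNA network's meaning. Enrichment
significance defaults to raw p < 0.05 with the BH column always present;
with few tested terms either convention is defensible and both are reported.
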