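---
title: "Methods: quantifying TF co-occupancy at enhancers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying TF co-occupancy at enhancers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cooccupy)
```

## The problem

During germ-layer specification, lineage transcription factors and
signaling effectors converge on shared enhancers.  A typical study asks
whether a Sox-family factor and β-catenin (acting through Tcf/Lef
sites) co-occupy the same cis-regulatory modules and co-regulate the
same genes.  The computational chain behind that claim has five steps,
each implemented here as a small, testable operation: annotate ChIP
peaks to genes, classify summit windows by motif content against a
matched shuffled background, filter knockdown RNA-seq into regulated
gene sets, intersect bound and regulated sets with an exact test, and
categorize targets by the two knockdown directions.

## Coordinates and peak annotation

All intervals are 0-based half-open (the BED convention); abutting
intervals do not overlap.  Each peak carries a summit — the base of
maximal signal — and every downstream unit (motif windows, density
matrices, feature labels) is anchored at the summit, so each peak gets
exactly one label.

`annotate_peaks()` assigns the gene whose TSS minimizes
|summit − TSS| on the peak's chromosome, with ties broken by
lexicographically smaller gene id for determinism.  Distances are
signed in the gene's orientation (negative = upstream).  Features
follow the precedence promoter > exon > intron > intergenic, evaluated
at the summit: a peak is a promoter peak when |distance| ≤ 1000 bp.
The 1 kb margin is symmetric around the TSS; annotation tools often use
an asymmetric window (e.g. −1 kb/+100 bp), but a symmetric margin has
one parameter, is strand-robust, and matches the common "distal =
more than 1 kb from the TSS" convention for enhancers.

## Motif scanning and the relative score

A window of width 150 bp (the scale at which co-binding is
biochemically meaningful — sequential-ChIP resolves co-occupancy only
within ~150 bp) is scanned on both strands at every offset.  A PWM of
length $L$ scores a window $w$ as

$$S(w) = \sum_{j=1}^{L} \log_2 \frac{p_j(w_j)}{b(w_j)}$$

with uniform background $b$ by default.  The relative score rescales
$S$ between the minimum and maximum attainable scores of the PWM,

$$R(w) = \frac{S(w) - S_{\min}}{S_{\max} - S_{\min}} \in [0, 1],$$

and a hit is any window with $R \ge 0.70$.  This min–max convention is
scale-free (invariant to PWM strength), which is why a single threshold
can be shared across motif databases; a consensus match always scores
$R = 1$, so planted consensus sites are detected deterministically.
Windows containing N are excluded rather than imputed.  Probabilities
get a $10^{-3}$ pseudocount at construction so log-odds stay finite.

Sites from multiple PWMs of one TF class that start at the same offset
and strand are counted once; per-window site counts are distinct
(offset, strand) pairs per class.  The four co-occurrence labels
(`sox_and_tcf`, `sox_only`, `tcf_only`, `neither`) follow directly from
the two counts.

## The dinucleotide-preserving shuffle null

Motif enrichment is judged against shuffles of the *same* windows, not
against genomic draws, so base composition, CpG content and window
length are matched exactly.  Shuffles use the Euler-path
(Altschul–Erickson) construction: the dinucleotide multigraph of the
sequence is walked along a random Eulerian path with the original start
and end vertices.  Every shuffle therefore preserves the exact
dinucleotide count vector — hence mononucleotide counts and GC% — and
both endpoints.  Runs of N split the sequence into independently
shuffled segments.  Ten shuffles per window (the conventional depth)
each count as one background observation, so the background is 10× the
real set; pooling keeps the 2×2 table structure that Fisher's exact
test needs, whereas per-window averaging would discard it.

Randomness is seeded per sequence by hashing (window id, master seed),
so results are bit-reproducible and independent of processing order.

Enrichment of a class label uses the one-sided (greater) Fisher exact
test on (real with/without, background with/without).  One-sided is the
appropriate direction for an enrichment claim; the test is conservative,
which the calibration tests verify empirically.

## Expression integration

*Differential filter.* A gene is regulated when any stage shows
|log2FC| > 1 (strictly — "greater than 2-fold" excludes exactly
2-fold) and FDR < 0.05.  Direction and the early/late class come from
the earliest significant stage; with staged knockdown series this is
the least ambiguous single-stage summary, since later stages mix direct
and cascade effects.  Stages order by their numeric component
(NF9 < NF10 < NF10.5 < … ), overridable.

*Spatial enrichment.* A tissue is enriched when expression strictly
exceeds 1.5× the cross-tissue mean of that gene.  The rule is
scale-invariant, so any TPM-like normalized unit works; an all-zero
profile yields no enrichment.

*Set intersection.* Bound∩regulated overlaps are tested with the exact
hypergeometric upper tail $P(X \ge k)$.  The universe defaults to all
genes in the supplied annotation and is configurable — published
analyses rarely state their universe, and the p-value is sensitive to
it, so it is an explicit argument rather than a hidden constant.

*Regulatory categories.* With knockdown (morpholino) data, "down in
the factor's MO" means the factor normally activates the gene.  Two
factors give a 2×2 of directions mapping onto four categories
(activated by both, activated by one and repressed by the other in
both orders, repressed by both); the mapping is total, so the
categories always partition the co-regulated set.

*Pattern tests.* Both a chi-square goodness-of-fit against genome-wide
label proportions and a two-sample KS test on a per-gene ordinal
statistic are provided for comparing expression-pattern distributions;
field practice varies between the two, and they answer subtly different
questions (composition vs. distribution shift), so the choice is left
to the caller.  The KS p-value is asymptotic with the standard
effective-n correction; the D statistic is exact, with ties handled by
evaluating both ECDFs at all pooled points.

*Reporter assays.* Firefly/Renilla ratios are summarized per condition
(mean, n−1 SD) with a classical pooled-variance two-sided t-test
against the reference.  A zero-variance comparison is reported with a
`degenerate` flag (p = 1 when means agree, p = 0 otherwise) instead of
erroring, since technical replicates occasionally tie exactly.

## Coverage profiles

`density_matrix()` computes, for each peak, mean per-base coverage in
50 bp bins across ±2000 bp around the summit (bin size is a free
parameter; 50 bp resolves typical nucleosome-scale structure without
noise).  Windows truncated at chromosome ends average over covered
bases only; peaks on chromosomes missing from the track produce zero
rows and are counted, not dropped.  Rows order by descending total
signal, the heatmap convention.  Two invariants pin the implementation
down: total signal is conserved (sum(matrix) × bin size equals track
coverage within the windows) and the matrix is equivariant under a
joint shift of track and summits.

## The synthetic-data generator

The generator exists so that every stage has a ground truth at desk
scale; its defaults are the study conditions the pipeline is tested
under.

- **Genome**: first-order Markov chain from a 16-entry dinucleotide
  frequency table (uniform by default), started from the stationary
  distribution — the same class of background the shuffle null
  preserves.
- **Planted peaks**: 300 bp peaks, summit-centered; PWM consensus
  sequences are written at recorded offsets inside the 150 bp window
  (non-overlapping by a slotting scheme).  The default class mix is
  50% both / 25% Sox-only / 0% Tcf-only / 25% neither with 3 Sox and
  2 Tcf sites per planted class, echoing the empirical observation
  that co-occupied enhancers carry a Sox-dominant, multi-site grammar.
  Because consensus scores are exactly 1.0, detection at threshold
  0.70 is deterministic; conversely the generator re-shuffles a
  window's background when it happens to contain a spurious
  above-threshold site, so absence is also guaranteed and the truth
  manifest is exact.  The bundled example PWMs are 12-mers whose
  consensi were chosen so no cross-alignment on either strand reaches
  the threshold — with shorter motifs (≤ 8 bp) a 0.70 relative score
  is reachable by chance in almost every 150 bp window, which is worth
  knowing when interpreting real scans too.
- **Expression**: log-normal baseline TPM shared across five
  gastrula-style territories; enriched genes get one assigned tissue
  multiplied by 3 (comfortably above the 1.5× rule at five tissues:
  with factor $f$ and $T$ tissues, recovery at zero noise needs
  $f > 1.5\,(f + T - 1)/T$).  Noise is multiplicative log-normal with
  a chosen CV; the zero-noise default makes recovery exact.
- **DE tables**: replicate log2 abundances with chosen dispersion; the
  effect of a true DE gene appears from a random onset stage onward;
  p-values from the two-sample t, FDR by Benjamini–Hochberg within
  stage.  This is deliberately not a count model: the downstream
  filter consumes only (log2FC, FDR), so negative-binomial machinery
  would add nothing the tests could see.
- **Dataset**: `simulate_cooccupancy_dataset()` arranges genes on a
  regular 6 kb grid and plants each peak 2 kb upstream of a distinct
  TSS, so the bound gene set is known by construction rather than
  inferred; regulated sets are sampled independently per factor.
  Default sizes (150 genes, 60 peaks, 50 regulated per factor) keep
  the full end-to-end run around a minute on one core while leaving
  all overlaps comfortably non-trivial.

What the generator does *not* emulate: mapping artifacts, copy-number
and accessibility biases, correlated replicate structure, peak-width
variation, overlapping genes, and motif self-similarity within a TF
family.  Passing tests therefore demonstrate algorithmic correctness
and calibration under a clean null — not robustness to every artifact
of real ChIP data.

## Numerical choices

- Exact tails (hypergeometric, Fisher) are computed in log-space via
  the standard distribution functions; tests cross-check them against
  direct binomial-coefficient enumeration to 1e-12 on small tables.
- Scanning compares scores with a 1e-12 slack at the threshold so a
  window scoring exactly at threshold is a hit regardless of rounding.
- Nearest-TSS ties break lexicographically; the earliest-stage rule
  breaks multi-stage DE ties; class-count rounding assigns the
  remainder to the largest class fraction.  All three are arbitrary
  but deterministic, which matters more.
- A peak exactly 1 kb from a TSS is a promoter peak (boundary
  inclusive), consistent with "distal" meaning strictly more than
  1 kb.
- Degenerate inputs have defined behavior rather than errors where a
  real pipeline would hit them: empty scan results for short
  sequences, empty enrichment sets for all-zero profiles, degenerate
  t-tests for zero variance.

## Known limitations

- The scanner is exhaustive per window; it is meant for summit windows
  and similar desk-scale inputs, not whole-genome scans.
- KS p-values are asymptotic; for very small samples use the exact
  chi-square route instead.
- The shuffle preserves dinucleotides only; higher-order composition
  (codon-like or repeat structure) is not matched.
- Motif class membership (which PWMs count as "Sox" vs "Tcf") is
  caller-supplied metadata; the package does not attempt family
  assignment from the matrices themselves.

## Worked pipeline

```{r pipeline, eval = FALSE}
ds <- simulate_cooccupancy_dataset(seed = 1)
ann <- annotate_peaks(ds$peaks, ds$genes)
reg <- filter_differential(ds$de_sox17$table)
dt  <- direct_targets(ann, reg, ds$genes$gene_id)
length(dt$genes)      # bound AND regulated genes
dt$test$p_value       # hypergeometric overlap p

hits <- scan_windows(ds$window_seqs, example_pwms(), rel_threshold = 0.70)
cls  <- classify_windows(hits, ds$peaks$peak_id)
table(cls$label)
```
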