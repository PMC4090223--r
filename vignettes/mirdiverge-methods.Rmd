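---
title: "Methods: two-library small RNA profiling with mirdiverge"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two-library small RNA profiling with mirdiverge}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mirdiverge)
```

mirdiverge implements the classic pooled two-library small RNA-seq design:
one sequencing library per tissue or condition, counts compared feature by
feature with an exact model, novel miRNA candidates discovered from hairpin
energetics, and targets predicted by duplex rules. This vignette is the
package's own account of the models and the design decisions behind them —
what each stage assumes, which knobs matter, and what the synthetic tests
do and do not demonstrate about real data.

## Read cleaning and tags

Raw reads are insert + 3′ adapter. `trim_adapter()` removes the longest
read suffix matching an adapter prefix with at most one mismatch and at
least 6 nt of overlap; reads with no detectable overlap are dropped,
because their insert may have run past the read end and its length cannot
be confirmed. This conservative rule, and the definition of "low quality"
(any N base, or more than 20% of bases under Phred 10 when qualities are
present), are our own concrete choices for steps that the underlying
protocol names but does not specify; both are fixed and documented rather
than tuned.

Clean inserts of 18–30 nt are collapsed into unique **tags** carrying one
count per library. Tags are the pipeline's atom: every later stage (class
assignment, hairpin discovery, quantification) consumes tags, and count
conservation (raw = clean + rejected, per reason) is asserted by tests at
every stage.

## Annotation cascade

Tags are mapped to the genome by exact match on both strands. Exact-only
mapping is deliberate: the conserved-miRNA rule is a perfect-match rule, so
a mismatch-tolerant mode would only add ambiguity to the one step that
forbids it. A tag is a **known miRNA** when it occurs verbatim inside a
catalog precursor and overlaps the mature arm; ties across precursors break
by larger mature overlap, then lexicographic id, making assignment
deterministic. All other tags take the highest-priority annotation class
overlapped by any of their genomic hits, in the order rRNA > tRNA > snRNA >
snoRNA > repeat > exon; leftover tags are unannotated. Placing miRNA first
in the cascade is a design decision (miRNA fractions are what the
downstream stages quantify), not a claim about any particular study's
internal order.

Tags with more than 10 genomic hits are flagged rather than silently
dropped, and the novel-discovery stage excludes them explicitly — repeats
masquerade as hairpins otherwise.

## Novel hairpin discovery

Each candidate tag (unannotated, 1–10 hits) is extended by 150 nt of
genomic flank on both sides (clipped at chromosome ends; minus-strand
windows are reverse-complemented so the tag reads forward). The window is
folded and the candidate must satisfy:

* **in stem** — at least 75% of tag bases paired, all partners on one
  opposing arm. The 75% quantification is ours (the qualitative criterion
  "resides in the stem" has no published number); it is exposed as
  `stem_frac`.
* **length** — the tag (the mature candidate, not the window) is 20–22 nt.
* **energy** — the window folds below −20 kcal/mol.

MFEI = AMFE / GC%, with AMFE = (−MFE/length)·100, is computed on the window
and reported with an `mfei_ok` flag (> 0.85) but kept out of the default
verdict: the length/MFE criteria define the candidate set and MFEI is a
posterior quality band; `strict_mfei = TRUE` folds it in. Whether the
energy criterion refers to the window MFE or a mature:star duplex energy is
ambiguous in the underlying protocol; we implement window MFE (the quantity
the folding stage actually produces) and note the alternative here.

One window per tag is evaluated (the first hit in coordinate order);
multi-locus candidates are counted by their loci in the output table but
not refolded per locus.

## The frozen energy model

All folding and hybridization run under one frozen nearest-neighbour
parameter table shipped with the package (`inst/extdata/energy_params_v1.tsv`):
36 stacking energies over the six pair types (AU, UA, CG, GC, GU, UG),
hairpin/bulge/internal loop penalties following a log law in loop size,
a linear multiloop cost (a = 3.4, b = 0.4 per branch, c = 0 per unpaired
base), and a constant duplex initiation of +4.1 kcal/mol. The stack values
are rounded, literature-style magnitudes; the table is **not** a full
Turner parameter set and makes no claim of thermodynamic fidelity. What it
buys instead is bit-reproducibility and checkability: the model is simple
enough that every energy can be recomputed by explicit loop decomposition
(`score_structure()`), and both engines are validated against exhaustive
enumeration — every nested structure for sequences up to 16 nt, every
bounded-gap alignment for duplexes up to 12 nt — with zero tolerance beyond
floating-point noise. Energies are comparable *within* this model (the −20
kcal/mol gate, the 75% MFE ratio) exactly as intended by the criteria.

Numerical choices: minimum hairpin loop 3 nt; interior loops capped at 30
unpaired bases total (larger loops extrapolate by the same log law);
duplex bulges capped at 3 nt per side, matching miRNA:target geometry;
pseudoknots excluded; T and U synonymous on input; DP traceback resolves
ties deterministically by scanning order, so equal-energy structures are
reported identically across runs.

## Differential expression

Normalized expression is NE = count / total clean reads; the fold change is
log2(NE₁/NE₂). Significance uses the exact two-library count model

$$p(y \mid x) = \left(\frac{N_2}{N_1}\right)^{y}
\frac{(x+y)!}{x!\,y!\,\left(1+\frac{N_2}{N_1}\right)^{x+y+1}}$$

computed in log space, with the two-sided p-value as the doubled smaller
tail capped at 1. The model takes raw counts x, y with library totals N1,
N2 — the only reading under which a discrete model is well defined, even
where the surrounding literature loosely calls x and y "normalized
expression levels". Two-sidedness is our choice (the design does not state
a sidedness); the doubled-tail convention is conservative.

One property deserves a note: exact invariance of this p-value under
swapping the libraries is *impossible* for a conditional-on-x model — the
observed point mass moves between tails, so swapped p-values differ by up
to the point probabilities (negligible at real counts, visible at counts
below ~30). The tests assert invariance up to that bound; log2FC is exactly
antisymmetric.

Zero handling: log2FC is ±Inf when exactly one count is zero and undefined
(NA) when both are; both-zero rows get no category and zero-count rows are
excluded from the scatter plot. "Expressed" means strictly more than 10
raw reads in at least one library (`expressed_rule = "both"` switches to
both). A Benjamini–Hochberg column is always provided but no filter is
applied by default, matching the single-library-pair design where the exact
test is customarily reported unadjusted.

## Target rules

Duplexes are scored per miRNA position from the 5′ end: Watson–Crick 0,
G:U wobble 0.5, unpaired 1. The six rules and their boundaries are listed
in `?apply_rules`. For the summed rules (1 and 5) G:U contributes 0.5; for
the presence/adjacency rules (2–4) any positive score counts as "a mismatch
present" — fractional adjacency is not meaningful, and this strict reading
is the default (`gu_strict = FALSE` provides the lenient alternative).
"No more than two adjacent mismatches" is read plainly: runs of consecutive
mismatched positions may be at most 2 long. Scanning slides windows of the
miRNA length ± 3 at step 1 and merges overlapping passing windows keeping
the lowest-MFE site; window enumeration and merging are implementation
choices validated against per-window evaluation.

## The synthetic study

`synthetic_study()` emulates the two-tissue design with known truth: a
random genome (default 50 kb, GC 0.42) carrying embedded known-miRNA
precursors (~30, about a third on the minus strand), spiked novel hairpins,
and disjoint annotation intervals per ncRNA/repeat/exon class; two
libraries (default 10⁵ reads each at acceptance scale, 2×10⁴ in the demo)
drawn multinomially from designed proportions. Known miRNAs get log-normal
base abundances with designed AF/AM ratios (default: 15% up 8-fold, 15%
down 8-fold — 8-fold being the effect size the detection guarantees are
stated for); novel hairpins share a fixed 5% of reads so every spiked locus
clears the 10-read expression floor; the rest is background from annotated
intervals plus intergenic positions, drawn from a small pool of distinct
tags so the unique-tag universe stays compact.

A subtlety: with per-library multinomial normalization, applying ratios to
one library would distort *all* ratios by the normalizing constant. Here
the background share absorbs that constant (scaled jointly when the
designed ratios inflate the miRNA share), so every designed AF/AM
proportion ratio is exact. When `background_fraction = 0` there is nothing
to absorb it and each library is simply renormalized; the truth table then
records the realized ratios. IsomiR jitter trims or extends the 3′ end by
up to 2 nt (uniform over offsets, 5′ end fixed), templated from the
precursor so extended variants still match it exactly. Reads carry the full
3′ adapter and constant dummy qualities; there are no base-call errors by
default, keeping the perfect-match annotation rule crisply testable.

What the synthetic tests therefore show: the pipeline's logic is correct —
designed effects are detected with the stated error control, spiked
hairpins are recovered, truth classes are re-derived. What they do not
show: robustness to sequencing error, 5′ isomiRs, RNA editing, adapter
dimers, or the abundance skew of a real small RNA library (where a handful
of miRNAs can be half the reads). `simulate_utrs()` similarly plants
perfect-complement sites in random UTRs — a synthetic stand-in for real
annotated 3′UTRs, sufficient to verify the scanner, silent about real
seed-match statistics.

## Problem sizes and determinism

The shipped tests fold hundreds of ≤16 nt oracles, one ~10⁵-read study and
a ~45-window discovery pass; the acceptance script runs the same at seed
control in about a minute. All randomness flows from explicit integer
seeds (the study config seed plus fixed offsets per stage), so every
artifact — FASTQ bytes included — is reproducible; `mir_demo(seed)` twice
yields byte-identical report bundles, which is itself an acceptance check.

## Known limitations

* Exact-match mapping only; SNP-bearing or edited tags fall out of their
  true class.
* The energy model is internally consistent but not thermodynamically
  calibrated against Turner 2004; absolute kcal/mol values should not be
  compared across models.
* One library per condition: no dispersion estimation, and the exact test's
  p-values describe sampling noise only, not biological variability.
* Novel discovery evaluates one locus per tag and does not model Dicer
  processing signatures (star reads, cleavage precision) beyond the stem
  placement rule.
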