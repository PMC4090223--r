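# mirdiverge

Comparative small RNA-seq profiling between two pooled sequencing libraries,
as an end-to-end, fully testable R pipeline. The package targets the classic
two-library miRNA study design — one library per tissue or condition, no
replicates — and covers every stage from raw reads to biology:

1. **Preprocessing** — 3′ adapter trimming, length/quality filtering
   (18–30 nt inserts), collapsing identical reads into unique *tags* with
   per-library counts, and library summaries (tag overlap, length
   distribution).
2. **Annotation cascade** — exact-match genome mapping on both strands,
   then one class per tag in priority order
   `known_miRNA > rRNA > tRNA > snRNA > snoRNA > repeat > exon >
   unannotated`. Conserved miRNAs require a perfect match to a catalog
   precursor overlapping the mature arm; isomiRs collapse onto their miRNA.
3. **Novel miRNA discovery** — unannotated tags with ≤ 10 genomic hits are
   extended by 150 nt flanks; each window is folded and a candidate must sit
   in the stem of a stem-loop, be 20–22 nt, and fold below −20 kcal/mol.
   The MFEI quality band (> 0.85) is reported alongside.
4. **Differential expression** — normalized expression
   `NE = count / total clean reads`, `log2FC = log2(NE₁/NE₂)`, and the exact
   two-library test
   `p(y|x) = (N₂/N₁)^y (x+y)! / (x! y! (1+N₂/N₁)^(x+y+1))`
   with a doubled smaller-tail two-sided p-value, plus the three
   linear-ratio categories (up > 2, mid, down ≤ 1/2) and an
   expressed flag (> 10 reads).
5. **Target prediction** — six-rule scoring of miRNA:3′UTR duplexes
   (≤ 4 mismatches with G:U = 0.5; no runs of > 2 mismatches; no adjacent
   mismatches in positions 2–12; none at positions 10–11; ≤ 2.5 mismatches
   in positions 1–12; duplex MFE ≥ 75 % of the perfect-complement MFE).

The RNA energetics behind stages 3–5 are self-contained: a frozen,
simplified nearest-neighbour model (Watson–Crick + G:U stacks, size-indexed
loop penalties, linear multiloops, constant duplex initiation) shipped as a
versioned table, with Zuker-style folding and intermolecular hybridization
in compiled code. Exhaustive-enumeration references (`fold_exhaustive()`,
`duplex_exhaustive()`) validate both engines bit-for-bit on short inputs.

Because real two-library studies are not desk-reproducible, the package
includes a first-class synthetic study generator (`synthetic_study()`):
genome, annotated ncRNA/repeat/exon intervals, a known-miRNA catalog with
designed AF/AM fold changes, spiked novel hairpins and two read libraries
with a 22 nt mode, adapter contamination, isomiR jitter and a complete
truth table — so every downstream claim is tested against known truth.

## Worked example

The one desk-checkable number of the two-library design: a miRNA observed
260,952 times among 14,244,946 clean reads in the first library and 7,158
times among 13,558,164 in the second.

```r
library(mirdiverge)
log2_fold_change(260952, 14244946, 7158, 13558164)
#> [1] 5.116796            # prints 5.12 at two decimals
ac_pvalue(260952, 7158, 14244946, 13558164)
#> [1] 0                   # overwhelming evidence of enrichment
```

Folding a designed hairpin and computing its MFEI:

```r
f <- fold_hairpin(paste0(strrep("G", 10), "AAAAA", strrep("C", 10)))
f
#> GGGGGGGGGGAAAAACCCCCCCCCC
#> ((((((((((.....)))))))))) (-23.41 kcal/mol)
compute_mfei(f$mfe, f$sequence)
#> # A tibble: 1 × 4
#>     mfe  amfe  mfei gc_pct
#>   <dbl> <dbl> <dbl>  <dbl>
#> 1 -23.4  93.6  1.17     80
```

MFEI 1.17 sits above the 0.85 band that separates miRNA precursors from
tRNA (~0.64), rRNA (~0.59) and mRNA (~0.65).

The end-to-end synthetic demo (seed-deterministic):

```r
demo <- mir_demo(seed = 1, quiet = TRUE)
glance(demo$de)
#> # A tibble: 1 × 7
#>   n_features n_expressed  n_up n_mid n_down    n1    n2
#> 1         30          30     5    20      5 20000 20000
sum(demo$novel$verdict)
#> [1] 25                  # passing hairpin windows, all 8 spiked loci hit
```

The five designed 8-fold-up miRNAs land in `up` with p ≈ 0, the five
designed 8-fold-down in `down`, and the rest in `mid` — matching the truth
table of the generator. `autoplot(demo$de)` draws the red/blue/green
fold-change scatter.

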