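---
title: "Seed-and-growth small RNA quantification: methods and design"
author: "seedgrow authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Seed-and-growth small RNA quantification: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(seedgrow)
```

## What the package computes

An antagomir transfection experiment asks three quantitative questions of
small-RNA sequencing data: how many reads correspond to each reference
small RNA in each library (mature miRNA, star strand, antagomir); how
those counts differ between treated and control conditions; and whether
the antagomir has unintended complementarity to other transcripts.
`seedgrow` answers them with, respectively, a seed-and-growth exact
matcher, fold-change/t-test comparison of a reference × sample count
table, and an ungapped sliding-window complementarity scan. A fourth
module implements the Livak 2^−ΔΔCt method so qPCR validation data can be
analysed alongside.

## The seed-and-growth matcher

Reads are matched to references without gaps and without internal
mismatches. Every contiguous 16-mer of a reference is a *seed* (a
reference of length $L$ has $L-15$ of them; a 23-nt small RNA has 8).
Note this is the matcher's anchoring seed, not the canonical miRNA
"seed region" (bases 2–8) of target recognition. A read sharing a seed
with a reference anchors there, and the match is grown one base at a time
at the 5′ end, then the 3′ end, while read and reference agree:

```{r matcher}
refs <- bundled_references()
idx <- build_index(refs, k = 16)
r <- refs$sequence[refs$ref_id == "miR21"]
# a 5'-shifted isomiR with two non-templated leading bases
match_read(paste0("CC", substr(r, 3, 22)), idx)
```

The grown region defines 1-based inclusive coordinates on the reference;
remaining read bases become the 5′/3′ flanks, so every record decomposes
exactly as `flank5 + reference span + flank3` with a matched length of at
least 16. This representation captures isomiR end heterogeneity (shifted
or extended ends surface as shorter spans or flanks) without any isomiR
nomenclature machinery.

Design choices where more than one convention was defensible:

* **Coordinates** are 0-based internally (seed offsets) and 1-based
  inclusive in reported records, matching the "bases 1–16" convention of
  seed naming.
* **Deduplication**: several anchors that grow to the same reference span
  collapse to one record; *distinct* maximal spans within one reference
  (internal repeats) are all reported.
* **Multi-reference hits**: `match_library()` offers `"all"` and
  `"best"` modes. Quantification uses `"best"` (longest match, ties broken
  by reference id, then position) so a read can never inflate two
  references' counts at once.
* **Strands**: anti-sense matching is realised at the sequence level —
  `build_index(add_reverse_complements = TRUE)` indexes each reference's
  reverse complement under `ref_id|rc` — so the matcher itself is
  strand-agnostic.
* **N** never matches anything (a universal mismatch), in seeds, growth,
  adapters and scans alike.

Correctness is established against an independent brute-force oracle that
enumerates *every* (read position, reference position) alignment,
extends each maximally, and keeps runs ≥ 16; the test suite requires
field-for-field equality on over a thousand random read/reference pairs,
plus maximality and flank-growth (monotonicity) properties.

## Adapter trimming and collapsing

The 3′ adapter is removed by leftmost prefix alignment: the cut is the
first read position where an adapter prefix of length ≥ `min_overlap`
(default 6) aligns with at most `floor(length × max_mismatch_rate)`
mismatches (default rate 0.1). The adapter string is a configuration
value, defaulting to the Illumina TruSeq small-RNA 3′ adapter
`TGGAATTCTCGGGTGCCAAGG`. Inserts shorter than `min_insert_length = 16`
are flagged and dropped rather than erroring — the bound is forced by the
16-nt seed: a shorter insert can never match. Identical inserts are then
collapsed to (sequence, occurrences) pairs, ordered by descending count
with lexicographic tie-break, and occurrence counts ride along through
matching into the count table.

## Quantification and comparison

Counts are sums of occurrences per (reference, sample); by default
conditions are compared on raw totals, with counts-per-million
normalization opt-in (`use_cpm = TRUE`; columns then sum to $10^6$).
Comparisons report treated/control fold change, percent change, and a
two-tailed *unpaired, equal-variance* Student's t-test when both
conditions have at least two replicates (Welch's test is available behind
`var_equal = FALSE`). Zero pooled variance is handled explicitly: equal
means give $t = 0, p = 1$; unequal constant groups are flagged degenerate
with $p = 0$. No multiple-testing correction is applied — results are
per-miRNA, and users comparing many references should adjust with
`p.adjust` themselves.

## The 2^−ΔΔCt module

For each condition, ΔCt = mean(Ct target) − mean(Ct internal standard),
replicates averaged at the Ct level; ΔΔCt = ΔCt treated − ΔCt control;
RQ = $2^{-\Delta\Delta Ct}$, percent change = (RQ − 1) × 100. No
amplification-efficiency correction is applied (the pure Livak form). Ct
values must lie in (0, 40) cycles, the qPCR run length. The bundled
`example_ct.tsv` encodes two worked magnitudes: a ΔΔCt of 0.152 is a 10%
reduction and 2.3219 an 80% reduction:

```{r ddct}
ct <- read_ct_tsv(system.file("extdata", "example_ct.tsv",
                              package = "seedgrow"))
ddct_analysis(ct, control = "mock", treated = "antimir21")
```

## The complementarity scan

The full-length query slides over the target without gaps; at each offset
the duplex is scored antiparallel (window base $j$ pairs with query base
$L+1-j$). Watson–Crick pairs score 1; G:U (here G:T) wobble pairs are
credited at `wobble_weight` (default 0.5, switchable off) in complement
mode. An `identity` mode scores plain equality instead, for homology
rather than hybridization questions — both are provided because either
reading of an observed antagomir/pri-miRNA alignment is plausible, and
the default is `complement`. No thermodynamic (ΔG) model is attempted:
this is match counting, and hits near-tied in score may differ in real
hybridization energy. Note the wobble credit is deliberately
strand-asymmetric: a G:T wobble complemented becomes C:A, which pairs
nothing, so only the Watson–Crick part of a score is invariant under
reverse-complementing both strands.

The bundled pri-miR30 hairpin target is **synthetic** — a constructed
stand-in (the mature miR-30a-5p sequence embedded in an artificial
hairpin whose 3′ arm carries an 18-nt stretch complementary to
anti-miR21), since no machine-readable pri-miR30 sequence ships with the
package. It demonstrates the expected qualitative behaviour (the best
hybrid area in the 3′ half of the hairpin) and is labelled synthetic
everywhere it appears.

```{r scan}
pri <- pri_mir30_synthetic()
head(complementarity_scan(anti_mir21(), pri$sequence,
                          query_id = "antimiR21", target_id = pri$ref_id), 3)
```

## The synthetic read simulator

The simulator generates replicated two-condition libraries with known
truth so the full pipeline can be validated without any external data.
Each read is a reference-derived insert plus the 3′ adapter:

* **Abundances**: per-condition true fractions over the references (must
  sum to 1); each library draws `reads_per_library` reads multinomially.
  Truth counts are recorded at the draw, before any corruption.
* **End shifts** model isomiR heterogeneity: independent 5′ and 3′
  offsets in {−2..+2} (default probabilities 0.05/0.10/0.70/0.10/0.05).
  Negative shifts trim reference bases; positive shifts are *templated*
  extensions drawn from a short fixed precursor-like context attached to
  each reference when the configuration is built — mimicking how real
  templated isomiR extensions come from the precursor, and keeping truth
  assignment unambiguous (no non-templated tailing).
* **Errors** are uniform per-base substitutions on the insert (default
  0.005); no indels, since the matcher is gapless. The adapter is written
  error-free and qualities are constant (unused downstream).
* **Determinism**: each library is a pure function of
  (`rng_seed`, condition, replicate); re-running a configuration is
  byte-identical, and simulation restores the caller's RNG state.

The default scenario (`default_simulation_config()`) is the package's
standing study condition: five references (miR21, miR21*, miR30, miR20,
miR28), mock fractions 0.40/0.02/0.28/0.18/0.12, three replicates of
50,000 reads per condition, and a treated condition with miR21 at 0.87×
(a 13% reduction), miR30 at 0.5× (a clear decrease; chosen once as a
realistic mid-range effect), miR20/miR28 untouched, and miR21* absorbing
the remainder (≈10.6×), emulating the flood of antagomir-derived
star-strand reads after transfection. These sizes keep a full end-to-end
run around fifteen seconds while leaving per-reference counts in the
thousands, where binomial sampling error is a fraction of a percent.

What passing tests do and do not show: the simulator emulates abundance
structure, isomiR end shifts, substitution noise and adapter context, but
not sequencer-specific error profiles, ligation or PCR bias, quality-score
structure, or non-templated tailing — so end-to-end recovery demonstrates
the pipeline's correctness and statistical calibration on idealised
libraries, not robustness to every artefact of real data.

A note on absolute counts versus ratios: a substitution landing mid-insert
destroys every 16-nt perfect window, so at error rate $e$ roughly
$1-(1-e)^{w}$ of reads (with $w$ the count of window-killing positions,
about half the insert) are lost to matching. Absolute matched counts
therefore sit a few percent *below* truth at realistic error rates —
systematically, not within binomial noise — while fold changes between
conditions are unaffected, because the loss factor cancels in the ratio.
The tests assert exact count recovery at error rate zero and fold-change
recovery within three binomial standard errors under the default noisy
conditions.

## Numerical and degenerate-input choices

* Tolerances: RQ identities to 1e−12; CPM column sums to 1e−6 relative;
  t-test agreement with the pooled-variance formula to 1e−9.
* Degenerate inputs: empty libraries and unmatched reads produce empty
  results, never errors; zero-total libraries error only at CPM; a zero
  control mean makes fold change undefined and errors explicitly.
* Tie-breaks are deterministic everywhere (collapse: count then sequence;
  matches: length, reference id, position; scan hits: score then offset),
  so identical inputs give byte-identical outputs.

## Limitations

Gapped or mismatch-tolerant alignment, genome-scale mapping, isomiR
nomenclature standards, dispersion-modelling differential expression
(use DESeq2/edgeR on the exported count table for that), qPCR efficiency
correction, and RNA secondary-structure prediction are all out of scope.
The t-test on three replicates of count data is reported because it is
the field's convention for such experiments, not because counts are
Gaussian; treat small-replicate p-values accordingly.
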