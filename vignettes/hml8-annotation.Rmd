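---
title: "Methods: proviral locus annotation, dating and regulatory profiling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: proviral locus annotation, dating and regulatory profiling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ervscape)
```

This vignette is the package's account of its methods: the models and
rules each stage implements, the tunable parameters and why their
defaults are what they are, what the synthetic-data generator emulates
(and deliberately does not), and the numerical and design choices made
where the problem left the design open.

## The proviral model

A provirus is represented by a consensus sequence plus a six-region
layout — 5'LTR, *gag*, *pro*, *pol*, *env*, 3'LTR — in 1-based inclusive
consensus coordinates. The packaged default is the 10485-bp HML-8 layout
(5'LTR 1–1266, *gag* 1422–3530, *pro* 3341–4345, *pol* 4303–7032, *env*
6890–9217, 3'LTR 9220–10485). The ORF junctions overlap, as retroviral
reading frames do; all region arithmetic treats each region
independently, so a junction base counts toward both flanking regions.
This matches how per-region integrity tables are conventionally
reported, region by region, rather than as a partition of the consensus.

## Discovery

`kmer_search()` follows the classical DNA BLAT design: an index of exact
k-mers over the genome (`k = 11`, stepping by 5), every overlapping
consensus k-mer looked up on both strands, hits chained by diagonal, and
chains extended outward. Because the package's divergence model is
substitution-only, a contiguous stretch of a proviral copy stays on a
single diagonal; internal deletions and nested insertions shift the
diagonal and therefore split a locus into several ungapped records,
which `assemble_loci()` re-merges.

Extension is score-based: +1 per match, −2 per mismatch, stop when the
running score falls 30 below its maximum, trim back to the maximum.
Proviral sequence up to roughly 30% divergence scores positive per base,
so extension reaches the copy's true edge; random flanking sequence
scores −1.25 per base on average, so overshoot is a few bases. On the
standard synthetic bundle, recovered boundaries are within 5 bp of the
planted truth.

Defaults and their meaning:

- `min_identity = 0.95`, `min_len = 25` — the classical "95% and
  greater similarity of length 25 bases" operating point. Note that a
  copy at divergence *d* has expected identity 1 − *d*: a search for
  copies up to 8% diverged must lower the floor accordingly, and the
  synthetic-bundle analyses in this package run at `min_identity =
  0.90` because the bundle plants copies up to *d* = 0.08. The floor is
  a statement about the most diverged copy you intend to find, not a
  quality knob.
- `merge_gap = 2000` bp — records merge into one locus when the
  *implied foreign length* between them (genomic gap minus any unaligned
  consensus between the records) is at most `merge_gap`. Measuring the
  gap net of unaligned query matters: a nested insertion of exactly 2 kb
  plus a few divergence-trimmed edge bases would otherwise exceed a raw
  2-kb gap test and split the locus.
- `occ_cap = 64` — genome k-mers occurring more often than this are
  skipped, a minimal guard against low-complexity seeds. This is
  deliberately not a full repeat-masking tile filter.
- Indel flags are structural, not alignment-level: `Deletion` when the
  query-gap fraction `Qgap/(match+mismatch+Qgap)` reaches 0.10,
  `Insertion` when the genomic span exceeds the aligned bases by at
  least 1 kb. Both thresholds are arguments of `assemble_loci()`;
  published locus tables do not state their flagging rule explicitly,
  and these values were chosen so that the flag boundary falls between
  the largest unflagged (9.29%) and smallest flagged (10.68%) query-gap
  fractions in the packaged catalog, with insertions all at kb scale.

Internally all alignment coordinates are 0-based half-open (the PSL
convention); every report is 1-based inclusive. The conversion happens
in exactly one place, the locus builder, which avoids the classic
off-by-one proliferation. Locus names are `chr:start-end` in report
coordinates. Ties in the coverage-descending locus sort break by
(chromosome, start) so output order is deterministic.

## Structure and length summaries

Per-region integrity is the fraction of each reference region covered by
the union of a locus's aligned consensus intervals. "Complete deletion"
means exactly zero aligned bases — no epsilon — because integrity tables
print hard 0.00% entries and any tolerance would silently reclassify
heavily truncated regions.

A solo LTR is called when at least one LTR retains ≥ 50% of its
reference length while all four internal regions are exactly zero. The
50% default reflects that real solo LTRs are often eroded (reported
human HML-8 solo LTRs retain about 75% of the LTR); requiring total
internal absence keeps heavily 3'-biased fragments from being miscalled.

`summarize_lengths()` reports the mean over all locus lengths but takes
the minimum and maximum over loci *not* flagged `Insertion`: a locus
with kb-scale nested foreign DNA has a genomic span that overstates its
proviral extent, and published length statements follow the proviral
extent. The coarse coverage classes (>70%, 40–70%, <40%) are computed on
coverage of the consensus (`match+mismatch` basis), not genomic length —
the two differ exactly when insertions inflate the span.

## Genomic context

Context labels form a decision cascade: no gene overlap → `intergenic`;
overlap without full containment → `genic&intergenic`; contained with no
exon overlap → `intron`; contained within a single exon → `exon`;
otherwise `exonic&intronic`. Overlap with any annotated transcript of a
gene counts, and where isoforms disagree the exonic call wins for the
overlapped base — annotation sources differ in isoform inventory, and
the conservative choice is to call a base exonic if any isoform says so.
Classification is strand-agnostic, matching how provirus catalogs mix
locus strand and context freely. A locus on a chromosome absent from the
annotation is classified `intergenic` with a warning rather than an
error, since scaffolds routinely lack gene models.

## Chromosomal distribution

Expected counts are proportional to nongap chromosome length,
`e = Cl·N/Tl`. Two tests are provided because published claims of
nonrandom integration mix two granularities: a global χ² goodness-of-fit
over all chromosomes (the headline statistic), and per-chromosome 1-df
χ² tests of each chromosome against the pooled remainder, flagging
`enriched`/`depleted` at raw p < 0.05 by default. Raw p-values are the
default because per-chromosome excesses are conventionally reported
unadjusted; a Benjamini–Hochberg option is exposed for users who prefer
family-wise control. The χ² approximation needs expected counts that are
not tiny; with fewer than ~5 expected per chromosome the flags should be
read qualitatively.

## Integration dating

The clock is linear: a region diverging by fraction *D* from the family
consensus dates to `T = (D·100)/0.2` Myr at the neutral rate of
0.2 %/nt/Myr; LTR–LTR divergence dates to half that, because both LTRs
accumulate substitutions independently after integration.

Design choices:

- **Divergence is uncorrected p-distance with pairwise deletion.** The
  clock formula is phrased in "percentage of divergent nucleotides",
  which is the p-distance; a Jukes–Cantor correction is exposed
  (`model = "JC"`) for users who want multiple-hit correction, which
  matters above roughly 15% divergence.
- **The family consensus stands in for the ancestral sequence.**
  Maximum-likelihood ancestral reconstruction is out of scope; for a
  family of copies that diverged independently from one ancestor, the
  per-column majority converges on that ancestor. Ties break by the
  fixed order A < C < G < T, and a majority-gap column is emitted as a
  gap, so the consensus is deterministic.
- **Eligibility**: only regions whose ungapped length exceeds 90% of
  the reference region enter dating. Short fragments give noisy
  divergences and would bias per-element means.
- **Per-element ages** average the available region divergences
  *unrounded* and only then apply the clock — averaging printed
  (rounded) divergences loses precision visibly at the second decimal of
  the age.
- Ages and percentages print at two decimals with half-up rounding
  (`round_half_up()`), matching how such tables are conventionally
  printed; base R's round-half-even would disagree on exact .5 cases.

The LTR–LTR route is implemented and tested synthetically, but the
catalog analyses rely on the internal-region route: in heavily LTR-eroded
families no LTR pair survives above the eligibility threshold.

## Phylogeny

Trees are Saitou–Nei neighbor joining over pairwise-deletion distances
(p, Jukes–Cantor, or Kimura 2-parameter). NJ is exact on additive
matrices — the suite verifies recovery of every labeled 4- and 5-taxon
topology — and is the appropriate desk-scale stand-in for
maximum-likelihood inference, which this package delegates to external
tools through `export_for_ml()`/`import_tree()`. Q-matrix ties break by
the lowest (i, j) index pair and negative branch lengths clamp to zero
with a warning, so output is deterministic and valid.

Bootstrap support resamples alignment columns with replacement,
rebuilds the NJ tree, and scores each original internal split by the
percentage of replicates containing it, using a canonical bipartition
encoding so support is invariant to taxon input order.
`assign_group()` labels a query with the group of the smallest
supported cluster (default ≥ 70%) it shares with panel references of a
single group, and returns `"unassigned"` otherwise — mirroring how
family membership is argued from supported monophyly with a reference
panel.

## Regulatory association and enrichment

Regulatory domains follow the GREAT basal+extension rule: a strand-aware
basal window (5 kb upstream, 1 kb downstream of the TSS) extended up to
1 Mb per side, stopping at the nearest other gene's basal boundary,
clipped at chromosome ends, and never shrinking below the basal window.
When two basal domains already overlap, extension on that side is zero:
basal domains are inviolate, which is the only consistent reading of the
published rule at this granularity. GREAT's proprietary "curated
regulatory domains" cannot be reproduced and are omitted. Loci qualify
for association when their best LTR retains more than 70% of the
reference LTR; the LTR position is the locus midpoint, since published
distance reports give a single absolute TSS distance per association,
binned as <5 kb, 5–50 kb, 50–500 kb, >500 kb.

Enrichment is a hypergeometric upper tail per category (categories
filtered to 5–2000 in-universe members), Benjamini–Hochberg FDR across
tested categories, sorted by FDR then p, top 10 reported. The gene
universe is supplied by the caller (defaulting to all annotated genes in
the pipeline), and category maps are user-supplied GMT files — no GO
database is bundled.

## The synthetic-data generator

`plant_loci()` builds uniform-random background chromosomes (25% each
base; no composition model is claimed for real flanks, and a uniform
background makes the seed-hit statistics analytically checkable) and
splices in proviral copies described by insertion plans: kept consensus
intervals (truncation classes), a per-site substitution probability
(replacement uniform over the three other bases, so planted divergence
*is* the expected p-distance the clock must recover), optional nested
foreign segments, and strand. Micro-indels are deliberately not
simulated: modeling deletions/insertions explicitly through plans keeps
the planted divergence interpretable as the clock's input and makes the
truth table exact. Solo LTRs are planted directly rather than derived by
simulated recombination. Gene models are placed to *realize* each plan's
requested context class (plus background genes away from loci), so
context truth is true by construction rather than re-derived — this is
what keeps the context acceptance test non-circular.

`simulate_study_bundle()` fixes the standard study conditions used by
the test suite and the acceptance script: five 120-kb chromosomes, 20
planted copies (four per chromosome) cycling through divergence levels
{0, 0.02, 0.05, 0.08}, five truncation classes from full-length to solo
LTR (all kept lengths ≥ 500 bp... the shortest is the 1266-bp LTR), both
strands, all five context classes, and two copies with 2-kb nested
insertions. These sizes keep every stage exercised — merging across
nested inserts, solo-LTR calling, minus-strand projection — while the
full suite runs in well under a minute of search time.

What the generator does **not** emulate: real repeat landscapes (no
other repeat families, no tandem repeats), CpG or transition/transversion
mutation bias, micro-indels within copies, orthology between genomes,
and empirical gene density. Passing tests therefore demonstrate
correctness of the algorithms under the stated model, not robustness to
every artifact of real assemblies; on real genomes the PSL import path
exists precisely so a production aligner can replace the built-in
search.

## Numerical choices and degenerate inputs

- All RNG flows through per-call integer seeds; child streams are
  derived arithmetically (and kept below 2^31), so every artifact is
  byte-identical across runs with the same seed and no call disturbs
  the caller's RNG state.
- `chisq_gof()` requires at least two categories (df ≥ 1) and positive
  expected counts; empty locus sets short-circuit the distribution and
  dating stages rather than erroring the pipeline.
- Saturated pairs (p ≥ 0.75 for JC, log-domain violations for K2P) are
  errors naming the offending pair, not NaNs.
- `p_distance()` errors when no comparable site remains after pairwise
  deletion, rather than returning 0 — silent zeros would date
  non-overlapping fragments to the present.
- Sequence containers are plain character vectors at the API; FASTA and
  GFF3 I/O go through Biostrings and rtracklayer.

## Problem sizes

The shipped analyses are desk-scale by design: 600-kb synthetic genomes
with 20 planted copies for discovery properties, 20 copies × 2730 bp ×
three divergence levels for dating recovery, 10,000 simulated null
genomes for test calibration, all 18 labeled 4–5-taxon additive matrices
for NJ exactness, universes ≤ 25 genes for enumeration-exact enrichment
checks, and ≤ 50-gene random sets for the regulatory-domain oracle.
These sizes were chosen as the smallest at which each property is
non-trivially exercised; nothing in the implementation assumes them, but
the built-in search is not tuned for whole-mammal genomes — use the PSL
import for that.

## Known limitations

- The built-in search has no translated (protein-space) mode and only a
  crude high-occurrence k-mer cap, so very repeat-dense regions may
  produce fragmented records.
- Distance-based trees approximate, and cannot replace, ML inference
  with among-site rate variation; the escape hatch exists for that.
- The dating clock has no calibration uncertainty: reported ages are
  point estimates under an assumed constant rate.
- Context classification ignores UTR/promoter subcategories and
  distance weighting.
- Where published per-region integrity asymmetries exist between the
  two LTRs, this implementation profiles both LTRs symmetrically; the
  packaged fixture preserves the printed values as printed.
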