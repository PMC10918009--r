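# ervscape

Annotation, dating and regulatory profiling of endogenous retrovirus (ERV)
proviral loci in a host genome.

Endogenous retroviruses are the fixed germline remnants of ancient
retroviral infections. A provirus canonically carries the layout
5'LTR–*gag*–*pro*–*pol*–*env*–3'LTR; over tens of millions of years most
copies decay into truncated fragments, and homologous recombination
between the two LTRs can leave a *solo LTR*. Cataloging every copy of a
family — where it sits, what survives of it, when it integrated, and what
genes its LTRs might regulate — is the standard first step before any
functional work on the family. `ervscape` packages that catalog workflow
for the ERV-K (HML-8) family and its 10485-bp MER11A–HERVK11–MER11A
consensus model, and is reusable for any LTR retroelement family with a
consensus and a region layout.

## What it computes

Given a genome FASTA, a proviral consensus with its region layout, and
(optionally) gene annotation:

- **Discovery** — a BLAT-style k-mer seed-and-extend search (11-mers
  stepping by 5 over the genome index, both strands), or ingestion of PSL
  alignments from an external aligner; fragmented hits are merged into
  loci with coverage of the consensus, query-gap fraction
  `Qgap/(match+mismatch+Qgap)`, 10%-coverage range bins, and
  insertion/deletion flags.
- **Structure** — per-region integrity (fraction of each of the six
  reference regions aligned), counts of completely deleted regions,
  solo-LTR detection, and length summaries.
- **Context** — each locus classified against gene models as intergenic,
  intron, exon, exonic&intronic, or genic&intergenic.
- **Distribution** — expected per-chromosome counts `e = Cl·N/Tl` from
  nongap chromosome lengths, a global χ² goodness-of-fit test, and
  per-chromosome enrichment/depletion flags.
- **Dating** — divergence `D` of each element's *gag*/*pro*/*pol*/*env*
  region from the family consensus (p-distance with pairwise deletion; a
  Jukes–Cantor option is exposed), converted to an integration age by the
  neutral molecular clock `T = D/0.2` Myr at 0.2 %/nt/Myr, or
  `T = D/0.2/2` for LTR–LTR divergence (the two LTRs were identical at
  integration).
- **Phylogeny** — neighbor-joining trees (p/JC/K2P distances) with
  column-resampling bootstrap support, and supported-cluster assignment
  of query loci to labeled reference panels; alignments can be exported
  for external maximum-likelihood tools.
- **Regulatory association** — GREAT-style basal+extension regulatory
  domains (5 kb upstream / 1 kb downstream of the TSS, extension up to
  1 Mb or the nearest neighbor's basal domain), LTR–gene association with
  TSS-distance bins, and hypergeometric over-representation analysis with
  Benjamini–Hochberg FDR.

A synthetic-data module (`simulate_study_bundle`, `plant_loci`) builds
multi-chromosome genomes with planted, truncated, diverged proviral
copies, gene models realizing every context class, and a truth table, so
the whole pipeline is testable without any downloads. Transcriptions of a
published 76-locus HML-8 catalog (locus table, six-region integrity,
divergence/age table) ship as checksummed fixtures
(`load_fixture("table1")` etc.).

## Worked example

```r
library(ervscape)

sim  <- simulate_study_bundle(out_dir = tempfile("demo"), seed = 1)
ref  <- sim$reference
hits <- kmer_search(sim$bundle$genome, ref, min_identity = 0.90)
loci <- assemble_loci(hits, ref)
head(loci, 5)
#>                name strand length coverage_fraction q_gap_fraction  range_bin indel_flags
#>    chr1:15000-27484      +  12485           100.00%          0.00% [90%-100%)   Insertion
#>  chr1:140455-150939      -  10485           100.00%          0.00% [90%-100%)        <NA>
#>   chr1:99972-110454      +  10483            99.98%          0.00% [90%-100%)        <NA>
#>    chr1:57485-69969      -  12485            99.97%          0.03% [90%-100%)   Insertion
#>    chr2:90592-98389      -   7798            74.37%          0.00%  [70%-80%)        <NA>

summarize_lengths(loci)
#> 20 loci: mean 6326 bp, min 1266 bp, max 10485 bp
#> coverage classes:  >70%: 12, 40-70%: 0, <40%: 8

count_complete_deletions(profile_loci(loci, ref))
#> 5'LTR   gag   pro   pol   env 3'LTR
#>    16     8     8     4     4     4

distribution_test(loci, nongap_lengths(sim$bundle$genome))
#> Global chi-square = 0.195, df = 4, p = 0.996
#> No chromosome significant at the chosen level
```

The 20 planted copies are all recovered: the two loci longer than the
10485-bp consensus carry planted 2-kb nested insertions (hence the
`Insertion` flag), the four 1266-bp loci are the planted solo LTRs, and
the uniform spread over five equal chromosomes is correctly called
non-significant. On the published catalog fixtures the same functions
reproduce the printed summaries, e.g.

```r
summarize_lengths(load_fixture("table1"))
#> 76 loci: mean 4378 bp, min 875 bp, max 9158 bp
#> coverage classes:  >70%: 9, 40-70%: 21, <40%: 46
```

A thin command-line front end with per-stage subcommands (`simulate`,
`discover`, `profile`, `context`, `distribution`, `date`, `phylo`,
`regulate`, `run`, `fixtures`) is installed at
`system.file("cli", "ervscape.R", package = "ervscape")`.

## Method notes

The methods vignette (`vignettes/hml8-annotation.Rmd`) documents the
model assumptions, parameter defaults and their rationale, what the
synthetic genomes do and do not emulate, and known limitations.
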