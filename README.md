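# mitocomp

Comparative analysis of annotated insect mitochondrial genomes, built
for molecular evolution studies that ask how composition, codon usage
and selection differ across a set of species — the kind of question
typically asked of a family-level collection of RefSeq mitogenomes.
The package covers the full desk-side analysis chain downstream of
assembly and annotation:

* **Genome I/O** — parse annotated mitogenomes from GenBank flat files,
  canonicalize the 37-gene nomenclature across RefSeq annotation
  dialects (COI/cox1, ND4L/nad4l, tRNA-Ser copies by anticodon, ...),
  extract coding-sense gene sequences across circular origins, and
  build fixed-order concatenations.
* **Composition** — base counts, AT% and strand asymmetry at four
  levels (whole genome, concatenated PCGs, concatenated rRNAs/tRNAs,
  and per gene), with `AT skew = (A − T)/(A + T)` and
  `GC skew = (G − C)/(G + C)`, plus the Pearson correlation between
  the two skews across genomes.
* **Codon usage** — codon counting under the invertebrate mitochondrial
  code (NCBI table 5), relative synonymous codon usage
  `RSCU(c) = n_c · |F| / Σ_{c′∈F} n_{c′}`, and the codon adaptation
  index `CAI = (∏ w_i)^{1/L}` with relative adaptiveness
  `w(c) = f(c)/max_{c′∈F} f(c′)` from a Kazusa-style reference table,
  evaluated whole-gene and in 300 bp (100-codon) sliding windows.
* **Selection** — pairwise Ka/Ks by the Nei–Gojobori (1986) counting
  method (fractional site counts, equal-weight mutational-pathway
  averaging, Jukes–Cantor correction `d = −¾ ln(1 − 4p/3)`), a
  protein-guided codon aligner for unequal-length pairs, and the
  neutrality plot: OLS of GC12 on GC3 across species, with mutation
  pressure = slope × 100 % and selection = (1 − slope) × 100 %.
* **Gene order** — numerical gene-order signatures (trnI = 1, trnQ = 2,
  ...), comparison against the ancestral insect arrangement, and a
  circular-adjacency breakpoint count.
* **Synthetic data** — a fully seeded generator of annotated
  mitogenomes, reference codon tables and diverged CDS pairs with
  known ground truth, so every stage is testable without downloading a
  single record.

A pipeline driver (`runPipeline()`, with a thin command-line front end
in `inst/scripts/mitocomp`) orchestrates the whole study from a flat
config file and writes versioned TSV/FASTA/JSON outputs.

## Worked example

```r
library(mitocomp)

sim    <- simulateMitogenome(mitogenomeSpec(seed = 1))
genome <- sim$genome
genome
#> Mitogenome: SYN000001 (Synthetica exempli)
#>   15900 bp, circular
#>   features: 38 (13 PCG, 22 tRNA, 2 rRNA, 1 CR)

skewTable(genome, "whole_genome")[, c("at_percent", "at_skew", "gc_skew")]
#>   at_percent   at_skew    gc_skew
#> 1   74.49057 0.0482945 -0.2588757
```

One simulated genome realizes the default study conditions: AT ≈ 74 %,
a mild adenine excess on the heavy strand and a strong cytosine excess
— the familiar insect-mitogenome pattern.

```r
r <- rscu(codonCounts(concatenatePCGs(genome)))
round(sort(r, decreasing = TRUE)[1:4], 2)
#>  TTA  TCA  ACT  CGA
#> 2.68 1.98 1.98 1.98
```

TTA (Leu) is the most over-used codon (RSCU 2.68, i.e. used 2.68× more
than expected under uniform synonymous usage), reflecting the
generator's A/T-third-position bias.

```r
ref <- readCodonTable(text = makeReferenceTable(bias = 2, seed = 99)$text)
w   <- caiWeights(ref)
prof <- slidingWindowCAI(extractGene(genome, "cob"), w, gene = "cob")
c(gene_cai = prof$gene_cai, peak_cai = prof$peak_cai)
#>  gene_cai  peak_cai
#> 0.7092863 0.8034828
```

The cob gene's codon usage sits at CAI 0.71 against this reference,
with a 100-codon window peaking at 0.80 — the sliding profile locates
the stretch closest to the reference's preferred codons.

```r
div <- simulateDivergence(extractGene(genome, "nad4"),
                          omegaTarget = 1.2, divergence = 0.3, seed = 7)
ng86Pairwise(extractGene(genome, "nad4"), div$cds,
             gene = "nad4")[, c("codons_compared", "Sd", "Nd",
                                "Ks", "Ka", "ratio")]
#>   codons_compared Sd  Nd   Ks    Ka ratio
#> 1             445 25 101 0.09 0.104 1.156

compareGeneOrder(geneOrderSignature(genome))
#> RearrangementReport: identical to reference
#>   breakpoints: 0
```

A nad4 copy diverged at a target Ka/Ks of 1.2 is estimated at 1.156
from 25 synonymous and 101 nonsynonymous pathway-averaged differences
(single pairwise estimates scatter around the target; the test suite
shows means over 50 replicates recover it within a few percent). The
simulated genome keeps the ancestral insect gene order: zero
breakpoints against the reference arrangement.

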