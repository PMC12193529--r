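---
title: "Methods: comparative mitogenome analysis with mitocomp"
author: "mitocomp authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: comparative mitogenome analysis with mitocomp}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitocomp)
```

mitocomp implements the analysis chain of a family-level comparative
mitogenome study: composition and strand asymmetry, codon-usage bias,
counting-based selection inference, and gene-order comparison, together
with a seeded synthetic-data generator that makes every stage testable
without network access. This vignette is the package's own account of
the methods, the choices behind them, and what the tests do and do not
demonstrate.

## Data model

The central object is the `Mitogenome`: a circular nucleotide sequence
(`Biostrings::DNAString`) plus a feature table of canonical genes.
Internally all coordinates are 0-based half-open on the forward (heavy)
strand; GenBank's 1-based inclusive coordinates are converted at the
I/O boundary only. A feature spanning the sequence origin keeps
`start > end` with a `wrapsOrigin` flag, and extraction uses modular
indexing — the alternative (doubling the sequence) would silently
distort genome-length-based composition statistics.

Gene names are canonicalized to the 37-gene mitochondrial nomenclature
(13 protein-coding genes, 2 rRNAs, 22 tRNAs, plus `CR` for the control
region). RefSeq annotation dialects vary enormously; the lookup is
case- and separator-insensitive and covers the common synonyms. The
two serine and two leucine tRNA copies are resolved, in order of
preference, by an explicit copy number in the label, by the annotated
anticodon (GCT/TCT → trnS1, TGA → trnS2, TAG → trnL1, TAA → trnL2),
and finally by positional match against the ancestral order; a copy
that cannot be resolved at all is an error rather than a guess.
When the control region is not annotated it is simply absent; it is
reported when present but excluded from gene-order signatures and all
gene-level statistics.

## Composition and skew

Strand asymmetry uses the standard closed forms
AT skew = (A − T)/(A + T) and GC skew = (G − C)/(G + C). Ambiguity
letters (N and the other IUPAC codes) are excluded from numerators and
denominators alike, which keeps both skews inside [−1, 1] and makes
results independent of how a submitter encoded uncertain bases; a zero
denominator yields a missing value, never a zero. Skews are computed
at four levels — whole deposited sequence, the 13 PCGs concatenated in
a fixed order (atp6, atp8, cox1–3, cob, nad1–nad6 with nad4l after
nad4), the two rRNAs, and the 22 tRNAs in ancestral chromosomal order
— always on coding-sense ("plus/plus") oriented gene sequences, so a
light-strand gene contributes its mRNA-sense composition. The
whole-genome level deliberately includes the control region: the CR
exclusion in this kind of study is scoped to gene-order analysis, not
to composition.

## Codon usage: RSCU and CAI

Codon statistics default to NCBI translation table 5 (invertebrate
mitochondrial: TGA = Trp, ATA = Met, AGA/AGG = Ser, stops TAA/TAG,
hence 62 sense codons). The synonymous families are always derived
from the configured table, never hard-coded, and the standard code is
available by configuration. Published descriptions of this analysis
sometimes speak of "60 sense codons", a count satisfiable under
neither table 1 (61) nor table 5 (62); mitocomp reports the configured
code's full sense set and leaves that discrepancy documented rather
than guessing which codons to drop.

Counting fixes the reading frame at zero, drops a trailing 1–2 nt
remainder (the incomplete stop completed by polyadenylation in
mitochondrial mRNAs), excludes codons containing ambiguity letters,
and keeps stop codons in the 64-entry table but outside every sense
statistic. RSCU is the observed count divided by its family-uniform
expectation; families with zero total count are reported as missing.

CAI follows Sharp & Li: within each family the relative adaptiveness
is w(c) = f(c)/max f over the reference frequencies, and a gene's CAI
is the geometric mean of w over its counted sense codons, computed in
log domain for numerical stability. Reference tables are read in the
Kazusa dialect (codon, frequency per thousand, count) or as two-column
codon/count text, with U mapped to T. Zero-frequency reference codons
receive a 0.5 pseudocount **on the count scale** before normalization
— the parsed table carries its raw counts alongside the normalized
frequencies precisely so that the pseudocount is meaningful; applied
to normalized frequencies it would dwarf genuine small frequencies.
With a zero-free reference, weights are exactly scale-invariant.
Sliding windows are 100 codons (300 bp) advanced one codon at a time —
the finest deterministic, parameter-free step — with a gene shorter
than one window contributing a single whole-gene window; the per-gene
peak is the maximum windowed value.

## Selection: NG86 Ka/Ks and the neutrality plot

Ka/Ks uses the Nei–Gojobori (1986) counting method, the documented
default of the software conventionally used for this analysis. Site
counts per codon take, at each position, the fraction of
single-nucleotide changes that are synonymous, with mutations to stop
codons disregarded (removed from the denominator); each codon then
contributes exactly three sites split between the synonymous and
nonsynonymous classes, and the pair's sites are averaged over the two
sequences. Codon pairs differing at k positions are resolved by
equal-weight averaging over the k! minimal mutational pathways,
skipping pathways that pass through a stop codon; in the rare case
where every pathway is blocked, the average falls back to all pathways
with stop-crossing steps scored as nonsynonymous. Proportions receive
the Jukes–Cantor correction d = −¾ ln(1 − 4p/3); p ≥ 3/4 is reported
as saturation (missing rates plus a note) rather than an exception, so
one distant pair cannot abort a study. The ratio is undefined when
Ks = 0. Site and pathway tables are precomputed per genetic code and
cached, so pairwise estimates are table lookups.

Unequal-length pairs go through a protein-guided codon aligner:
translate (terminal stops stripped), align globally under BLOSUM62
(gap open 10, extend 0.5), back-thread the codons, and delete every
column containing a gap, an ambiguous codon or an internal stop. An
aligned protein identity below 20% is treated as "no usable signal"
— far below anything a congeneric mitochondrial gene pair produces.

The neutrality plot regresses GC12 (mean GC of codon positions 1 and
2) on GC3 across species, one point per species per gene; a
sliding-window variant would also be defensible, but per-species
points match the one-point-per-genome structure of the other analyses
and keep n explicit. The slope decomposes the forces on codon usage as
mutation pressure = slope × 100 % and selection = (1 − slope) × 100 %,
the only reading under which the two percentages complement each other
and follow directly from the fitted slope. Genes are retained for this
analysis when their mean Ka/Ks across species reaches 0.9 — a
threshold that keeps near-neutral genes alongside those at or above 1
— and the threshold is configurable.

## Gene order

The gene-order signature lists the genes in chromosomal order starting
from trnI (the circular order is rotated so trnI leads whenever it is
present — deposited sequences start at arbitrary points, and a fixed
anchor makes signatures comparable), each carrying its index in the
ancestral insect arrangement (trnI = 1, trnQ = 2, ...) and its ±1
orientation. Rearrangement against a reference is summarized by the
number of breakpoints: circular *directed* adjacencies of the
signature absent from the reference, so an adjacent swap scores 3.
Orientation enters a separate inversion report rather than the
adjacency count — a pure in-place inversion therefore shows inverted
genes and zero breakpoints, keeping the two rearrangement classes
distinguishable. Missing genes are reported, never fatal.

## The synthetic generator

`simulateMitogenome()` emits a circular genome carrying all 37 genes
plus a control region in a configurable order (ancestral by default),
with defaults emulating a typical tephritid mitogenome: ~15.9 kb,
whole-genome AT 74 % (published family means run ~73–80 %), heavy-
strand AT skew +0.066 and GC skew −0.227, and a codon bias toward
A/T-ending codons. PCGs are generated codon-wise — a start codon, a
body of sense codons, a TAA stop — so no internal stop can occur and
composition targets remain satisfiable; tRNAs, rRNAs, spacers and the
CR are skew-matched random nucleotide fills. Two details matter for
the composition guarantees:

* the codon-sampling distribution is *calibrated* (one-dimensional
  root-find) so that the expected AT of sampled codons equals the
  target despite the A/T-ending bias and the exclusion of stops;
* light-strand genes are generated in coding sense from
  *complemented* base probabilities and then placed
  reverse-complemented, so the deposited strand carries the target
  composition everywhere.

With that, realized whole-genome AT% is unbiased (the start/stop
codons contribute a ≈0.1 % AT excess) and the skews land on target.
Randomness derives from a single seed split into per-gene substreams
by a counter scheme, so adding a gene leaves other genes' sequences
unchanged and the same seed is byte-reproducible.

`simulateDivergence()` produces a diverged copy of a CDS with known
ground truth: uniformly random single-nucleotide proposals, stop
codons always rejected, synonymous and nonsynonymous proposals
accepted with relative rates 1 : ω (probabilities min(1, 1/ω) and
min(1, ω) — expressing the rates as acceptance probabilities keeps
targets above 1 representable), until round(divergence × codons)
substitutions are accepted. `makeReferenceTable()` draws per-family
frequencies from a Dirichlet whose concentration favors A/T-ending
codons in proportion to a bias parameter and serializes them in the
Kazusa dialect.

What the generator does **not** emulate: phylogenetic correlation
between species (replicates are i.i.d.), tRNA/rRNA secondary
structure, strand-specific mutational pressure within PCGs (real
insect PCG data sets show a thymine-biased AT skew that the generator
does not reproduce), or position-specific selection on codons.
The last point has a visible consequence: across simulated genomes
that differ only in composition targets, GC at all three codon
positions co-varies essentially 1:1, so a neutrality fit on purely
synthetic species yields a slope near 1 ("pure mutation pressure").
That is the correct answer for data generated without selective
constraint, and it is why estimator *correctness* is demonstrated
instead on synthetic clouds with a known generating slope, where
recovery is within three standard errors. Passing tests on generator
output therefore demonstrate the statistics and the plumbing, not that
real data will show any particular biology.

## Numerical and experimental choices

* RSCU family sums are checked to equal family size within 1e-9;
  CAI agrees with a direct log-domain oracle to 1e-12; the neutrality
  slope is exact to 1e-12 on collinear input.
* NG86 site and pathway counts are validated against exhaustive
  enumeration oracles over all 62 sense codons and all ordered sense
  codon pairs.
* The ω-recovery experiments run at 300 codons, 50 replicates and a
  divergence of 0.3 substitutions per codon (≈0.1 per site). The
  divergence matters: the Ka/Ks point estimate is a ratio of counts,
  and with only a handful of synonymous events its mean is visibly
  Jensen-inflated even though each count is unbiased; 0.1
  substitutions per site provides enough events for a stable ratio
  while staying far below the p = 3/4 saturation of the Jukes–Cantor
  map. Mean estimates then recover ω ∈ {0.2, 1.0, 1.5} within 20 %
  (within ~5 % for ω ≤ 1).
* Pipeline-scale tests use five-genome study sets and the test suite
  simulates a few hundred small genomes in total; the full suite runs
  in about two minutes on one core.
* The pipeline writes each run into a fresh `run-NNN` subdirectory, so
  re-running on the same output directory versions results instead of
  overwriting them, and a manifest records package version, config,
  seed and exclusions. No multiple-testing correction is applied
  anywhere because the pipeline performs no hypothesis tests.

## Known limitations

Annotation is consumed, never produced: records must carry gene
features (no ORF or tRNA scanning). Only origin-spanning `join()`
locations are supported — multi-exon joins do not occur in animal
mitogenomes. The aligner is pairwise; multiple alignment, alignment
trimming and tree inference are deliberately out of scope, with the
concatenated 13 PCG + 2 rRNA supermatrix as the hand-off point.
Ka/Ks is the NG86 counting estimate: no codon substitution models, no
branch or site models, no positive-selection tests. Taxonomy for group
summaries is an explicit input table, never inferred from organism
names.
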