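---
title: "Models and methods behind shufflekit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind shufflekit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(shufflekit)
library(data.table)
```

## The assay being modelled

A shuffle cassette is a transposon-delivered DNA unit: a site-specific
recombinase site (palindromic loxPsym for Cre, or directional attB/attP for
Bxb1) flanked by two degenerate 20-nt barcodes, a pair of capture/primer
binding sequences (CS2 next to barcode 1, CS1 next to barcode 2), and
convergent T7 promoters. piggyBac integrates cassettes at TTAA
tetranucleotides, duplicating the TTAA on both sides. After a library of
cassettes is integrated at high MOI, recombinase expression joins pairs of
cassettes and thereby engineers deletions, inversions and translocations whose
junctions carry *novel barcode combinations*. Three readouts recover the
information:

* **IVT-seq** — T7 transcription on genomic DNA produces transcripts spanning
  the barcodes and the flanking genome, giving a barcode-to-locus map.
* **Amplicon-seq** — PCR between the capture sequences counts barcode pairs
  (reads and UMIs) in bulk.
* **Single-cell T7 capture** — the same T7 transcripts captured in droplets
  give per-cell barcode-pair counts next to a transcriptome.

shufflekit implements the sequence model, a truth-tracked simulator of all
three readouts, and the full decoding stack.

## The recombination product algebra

Each cassette has two ends: the CS2 end holding barcode 1 and the CS1 end
holding barcode 2. The central result the package encodes is that the barcode
composition of recombination products depends only on how the two sites
synapse:

* **Parallel synapsis** joins the CS2 end of one parent to the CS1 end of the
  other: products `(A.bc1, B.bc2)` and `(B.bc1, A.bc2)`, each flanked by one
  CS2 and one CS1 — heterotypic, hence amplifiable.
* **Antiparallel synapsis** joins like ends: products `(A.bc1, B.bc1)`
  (CS2–CS2) and `(A.bc2, B.bc2)` (CS1–CS1) — homotypic. Templates with the
  same primer site on both ends fail to amplify (suppression PCR) and are
  modelled as undetectable under both the two- and four-primer schemes.

Because loxPsym is palindromic, Cre synapses either way with equal
probability; enumerating relative integration orientation × synapsis mode
gives eight products of which exactly four are homotypic — the 50%
detectability ceiling of the loxPsym design, computed by
`cre_homotypic_percent()`. Bxb1 sites are directional: only attB × attP pairs
recombine (half of all pairs at 1:1 proportions, `bxb1_competent_fraction()`),
always in the parallel sense, so every Bxb1 product is detectable and carries
an attL or attR site inert to further recombination.

The genomic outcome follows from strand geometry: an excision (deletion plus
extrachromosomal circle) arises when same-strand cassettes synapse parallel
or opposite-strand cassettes synapse antiparallel; the complementary cases
invert the intervening segment; different chromosomes give reciprocal
translocations. For a deletion between upstream insertion X and downstream
insertion Y in top-CS2 orientation, the chromosomal scar carries
`(X.bc1, Y.bc2)` and the circle `(Y.bc1, X.bc2)`; bottom-CS1 pairs mirror the
assignment. The test suite verifies the whole algebra against an independent
oracle that literally rebuilds rearranged chromosome strings, cuts them at
the site cores, rejoins them, and reads the products back by extraction.

## Coordinates and the 4-bp paired-cluster rule

Flank alignments use BED-convention coordinates (0-based start, exclusive
end), matching the convention of the short-read tools this pipeline models.
The junction position of a + strand alignment is its end; of a − strand
alignment its start. Since piggyBac duplicates the TTAA, the two transcripts
of one insertion align on opposite strands around the same reference TTAA,
producing a − cluster at `start0 = pos − 1` and a + cluster at
`end0 = pos + 3`: the two clusters of a bona fide insertion sit exactly
4 bp apart. An insertion call additionally requires opposite cassette-strand
labels (the two transcripts read the cassette in opposite orientations) and
per-slot reverse-complementary barcodes across the pair.

## The simulator and what it does (not) emulate

`sim_config()` collects every tunable with defaults chosen as realistic study
conditions:

* **Genome**: random sequence with a TTAA guaranteed per kilobase;
  two haplotypes ("BL6"/"CAST") differing by SNVs at exponential spacing with
  mean 150 bp, emulating a hybrid line with a heterozygous variant every
  ~150 bp. Variants are SNVs only — indels would shift coordinates between
  haplotypes without exercising any additional pipeline logic — and never
  fall inside a TTAA so every integration site exists on both haplotypes.
* **Library**: 20 clones × 30 cassettes (MOI ≈ 30, matching the order of
  magnitude of the reconstructed clonotypes), unique random barcodes, random
  strand and haplotype, attB/attP at equal probability for Bxb1.
* **Recombination**: one event per cell with probability `event_prob`; cis
  pairs weighted `exp(−d / distance_rate_scale)` (the qualitative
  distance-decay of recombination efficiency; the scale is exposed because
  only the decay, not its constant, is established), trans pairs at a flat
  relative rate.
* **Selection**: multiplicative per-generation weights. Cell-level weights
  apply to deletions (with an extra penalty for centromere-spanning ones),
  inversions and balanced translocations; the two fragments of an unbalanced
  translocation are retained per generation with their own acentric/dicentric
  weights so the reciprocal products deplete at distinct geometric rates, as
  fragment loss at mitosis — not cell death alone — drives their dynamics.
* **Reads**: IVT-seq at 20 reads per cassette end with flank lengths uniform
  on 35–70 bp (deep coverage, so clusters accumulate the read counts and
  distinct aligned lengths the support filters require); amplicon reads with
  8-nt UMIs and PCR chimeras injected by barcode re-pairing on fresh UMIs;
  single-cell molecule counts negative binomial with ambient, chimeric-UMI
  and doublet channels; transcriptome counts Poisson with copy number set by
  truth deletions times a log-normal library factor.

The generator does **not** emulate sequencer error profiles beyond uniform
substitutions, library-prep size selection, duplications from sister-chromatid
recombination, or real mammalian repeat structure; passing tests therefore
demonstrate the correctness of the decoding logic under controlled noise, not
performance on real data. Each pipeline stage draws from its own sub-stream
of the master seed, so stages are independently reproducible.

## Decoding pipelines: numerical choices

**Insertion mapping.** The built-in aligner is an exact-seed (k = 31) and
ungapped-extension mapper over the synthetic reference (the BL6 haplotype),
with a multi-mapper filter and the requirement that the implied junction sit
at a TTAA. Reads from the alternate haplotype mismatch the reference at
variant positions, so when no 31-mer window of a read is variant-free the
mapper falls back to shorter seeds (k = 17, then 13) at denser offsets; false
seed hits are harmless because every candidate locus is verified over the
full read (mismatch fraction ≤ 0.1). Alignments are clustered per
(chromosome, position) by single-linkage Levenshtein ≤ 6 on the concatenated
barcode pair — the joint 40-nt barcode, configurable to per-barcode — with
modal representatives (ties broken lexicographically) and the modal allele
ignoring no-variant reads. Replicate 2 acts as the designated anchor
replicate: clusters with fewer than 6 reads *and* fewer than 3 unique aligned
lengths there are discarded. Duplicate barcode sets at one position are
resolved by the higher anchor-replicate unique-length support on the left
cluster.

**SV calling.** Novel pairs require both barcodes in the bona fide parental
list, a non-parental combination and ≥ 2 raw UMIs (the chimera guard; the
threshold is applied before depth normalization). Deletions are
same-chromosome, same-orientation pairs; inversions opposite-orientation;
translocations cross-chromosome. Same-chromosome pairs with discordant
haplotype labels are classified cis but flagged, following the parsimony
argument that inter-homolog events are rare. For translocation
subclassification, the fragment retained with a barcode is the side of the
junction its capture end faces; a barcode is centromere-proximal when that
fragment contains the centromere — both proximal gives dicentric, both
distal acentric, mixed balanced. Weighted size comparisons resample events
with replacement proportional to read counts for 10,000 iterations; the
two-sided p-value comes from the bootstrap distribution of the difference of
medians. Clone-well genotyping uses the population standard deviation
(ddof = 0) for the mean + 1 SD retention rule.

**Single-cell genotyping.** Per cell, UMIs whose reads are split across
combinations are de-chimerised at a 0.2 read-fraction floor, then collapsed
to Hamming-distance ≤ 1 connected components; entries below the reads-per-UMI
floor (15 and 9 for the two sequencing depths the defaults mirror) are
dropped. Clonotype discovery keys pairs by the CS1-side barcode only (so
rearranged cassettes, which swap one side, do not split clones), filters weak
signal (≥ 3 UMI per pair per cell, ≥ 11 UMIs per cell and per pair),
normalizes to relative counts at scale 10⁴, and clusters cells with PCA
(≤ 100 components), an exact k = 10 nearest-neighbour graph and Louvain
communities at resolution 1 — the contract is the downstream clonotype QC,
not the exact partition, and the seeded igraph implementation keeps it
deterministic. Member sets are cut at the rank-ordered detection-fraction
inflection: the fold-change rule (> 2) and the absolute floor (0.075) each
propose a cut, a rule that never fires abstains, and the larger member set is
taken — the source description of this heuristic is ambiguous, so both
thresholds and the combination are configurable. Clonotypes need a top
detection fraction > 0.45 and > 1 members; redundant clonotypes merge at
Jaccard > 0.5; discovery can iterate after removing assignable cells and can
set aside dominant clones whose ambient emission would otherwise contaminate
other clonotypes. Cells are assigned by precision > 0.75 and recall > 0.1,
with second-best recall > 0.1 flagging putative doublets.

**Expression impact.** Library-size normalization (× 10⁴) after masking genes
expressed in < 10 cells; fold change is the ratio of group means of
normalized expression; the one-sided rank-sum test uses exact permutation
enumeration up to a total of 12 observations (midranks, exact under ties) and
the tie-corrected normal approximation without continuity correction above.
Rolling three-gene windows follow chromosome-then-start order and never span
a chromosome boundary; the designated window's z-score is taken against all
windows sharing none of its genes, which keeps partially overlapping windows
out of the null. No multiple-testing correction is applied by default
(nominal p-values are reported); Benjamini–Hochberg is available via
`stats::p.adjust`. Note that library-size normalization slightly damps the
dosage signal: deleting 3 of 60 genes shrinks the denominators of
deletion-bearing cells, so the measured decrease sits a little below the
copy-number expectation of one third.

## Worked example

```{r example, eval = FALSE}
cfg <- sim_config(seed = 1, chrom_lengths = c(chr1 = 1e6, chr2 = 1e6),
                  n_clones = 5, cassettes_per_clone = 12,
                  cells_per_clone = 40, sub_rate = 0)
genome <- simulate_genome(cfg)
clones <- integrate_cassettes(genome, cfg)

# parental map from two IVT replicates
ivt <- lapply(1:2, function(r) emit_ivt_reads(clones, genome, cfg, r))
pmap <- map_insertions(ivt[[1]], ivt[[2]], build_genome_index(genome))$insertions

# induce events, read out amplicons, call SVs
cells <- induce_rearrangements(clones, cfg, genome)
amp <- emit_amplicon_reads(cells, cfg, "two_primer")
tal <- normalize_and_average(tally_amplicons(amp[, .(seq, replicate)]))
novel <- call_novel_pairs(tal, pmap, min_umi = 2)
svs <- classify_all_svs(novel, pmap, genome$centromeres)
table(svs$class)
```

## Problem sizes and limitations

The shipped tests run the full mapping pipeline at 200 cassettes on a
2 × 5 Mb diploid genome, the clonotype pipeline at 20 clones × 50 cells
(MOI 30), and the classification oracle on 1000 simulated events; these sizes
exercise every code path at full statistical strength while keeping the suite
fast to run. Known limitations: the mapper is ungapped (real indel-bearing
reads would need an external aligner; an import path for externally produced
alignment tables exists via the documented per-read table schema), alignment
assumes the synthetic reference, multi-event cells are limited to one event
per cell by default, and the Cre toxicity observed in practice is subsumed
into the selection weights rather than modelled mechanistically.
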