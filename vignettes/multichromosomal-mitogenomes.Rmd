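---
title: "Assembling and analysing multichromosomal plant mitochondrial genomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assembling and analysing multichromosomal plant mitochondrial genomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitomosaic)
```

## The scientific problem

Plant mitochondrial genomes are large, repeat-rich and structurally fluid.
Repeated sequence mediates recombination, so a mitogenome is often drawn as a
single "master circle" from which smaller subgenomic circles arise. Some
species, however, carry their mitogenome as two or more fully independent
circular chromosomes with no master circle at all. Distinguishing the two
situations from sequencing data is subtle: short-read assembly graphs of a
two-chromosome mitogenome contain spurious join points wherever the
chromosomes share a block of sequence longer than nothing but shorter than a
read, and only reads that *span* such a block with unique flanking sequence
on both sides can resolve which arrangement exists.

`mitomosaic` implements that line of reasoning as a reusable pipeline,
modelled on the sugarcane-type mitogenome: two circular chromosomes (about
300 kb and 145 kb in the real system; a tenth of that at the package's
desk scale), a dozen short, often imperfect regions shared between the
chromosomes, one long direct repeat and one inverted repeat on chromosome 1,
plastid-derived segments with a chloroplast-like GC signature, multi-exon
genes with some exons split across chromosomes, abundant C-to-U RNA editing,
and polyadenylation used as a transcript degradation tag.

The package covers seven concerns:

1. **Synthetic data** (`simulation_config()`, `generate_mitogenome()`,
   `simulate_genomic_reads()`, `simulate_transcript_alignments()`) — a
   generator that plants all of the structures above at recorded
   coordinates and exports the ground truth, so every later stage can be
   validated end to end.
2. **Sequence I/O** — FASTA/FASTQ/GFF3/BED/SAM-text readers and writers, a
   concatenated-coordinate map over ordered chromosomes, and a
   seed-and-extend read mapper for circular references.
3. **Bait-and-assemble** (`iterative_bait_assemble()` and its parts) — the
   iterative k-mer baiting + greedy overlap assembly + homology filtering +
   circularity testing loop used to reconstruct organelle genomes from a
   total-DNA read pool.
4. **Chromosome structure** (`find_shared_regions()`,
   `enumerate_join_paths()`, `count_spanning_reads()`,
   `classify_join_candidates()`, `detect_alternative_conformations()`) —
   the master-circle exclusion test and repeat-conformation analysis.
5. **Splice analysis** (`extract_junctions()`, `cluster_hotspots()`,
   `classify_and_summarize()`, `guide_rna_search()`).
6. **Transcript landscape** (`compute_coverage()`, `polya_islands()`,
   `expression_fold()`).
7. **Genome comparison** (`global_diff()`, `classify_editing()`,
   `gc_classify()`).

## The master-circle test

The core inferential step works as follows. `find_shared_regions()`
enumerates maximal near-exact matches between the two chromosomes (both
orientations) by exact k-mer anchoring, diagonal grouping and X-drop
extension. Each shared block admits four local *join paths*: stay on
chromosome A, stay on B, or switch chromosomes through the block in either
direction (`enumerate_join_paths()`). A read supports a path only if it
covers the whole shared block **plus** at least `anchor` (default 20)
matched bases of flank on each side — the block itself is common to all four
paths, so only the flanks are informative, and a read equal to the block
supports nothing. `classify_join_candidates()` then applies the logic of the
read-length argument:

* a block shorter than the read length with zero chimeric support is
  **excluded** — reads of that length could have spanned it and none did;
* a block at least as long as the read length cannot be resolved by those
  reads and stays a **candidate**;
* any chimeric spanning support makes the block **supported**, and the
  verdict becomes "master circle present".

Note the direction of the inequality: *short* blocks are the ones reads can
exclude. Long blocks require longer reads, which is why the package's
positive control (`simulate_genomic_reads(..., master_circle = TRUE)`, which
fuses the two circles through a shared block) is run with long reads.

Anchors are compared at the same identity threshold as the block (default
95%), but separately per anchor rather than pooled over the whole window.
Pooling would let a window-length mismatch budget absorb an entirely wrong
anchor whenever the block is long; per-side anchor checks keep the
false-support probability at zero for error-free and lightly erroneous
reads, which the test suite verifies across 20 independent simulations.

## The bait-and-assemble loop

Each round baits the read pool by canonical k-mer sharing against the
current bait set (k and the minimum shared-k-mer count `n` follow a
per-round schedule, defaulting to k = 32 with n = 50 in round one — the
published tool settings — and k = 27/31 with n = 1 after, since later
rounds are enrichment rounds), assembles the baited reads with a greedy
overlap-layout assembler (minimum overlap 1,000 bases at 75% identity,
mirroring the published CAP3 settings `-o 1000 -p 75`), keeps contigs with
homology to the initial baits, drops contigs whose aligned coverage by a
plastid reference reaches 90% ("almost complete chloroplast coverage"), and
sets circular contigs aside as potentially complete. Homology hits replace a
BLAST e-value cut-off with explicit, brute-force-checkable criteria (hit
length at least 100 bases at 80% identity); an e-value calibration would add
nothing at this scale. Circularity is detected as a suffix–prefix
end-duplication of at least 100 bases at 95% identity; the duplicate copy is
trimmed and the circle reported in canonical rotation (the lexicographically
minimal rotation over both strands) so assemblies of the same molecule
compare equal whatever rotation the assembler happened to produce. A contig
flagged circular is returned unchanged by a second circularity test — the
flag, not a re-detected end repeat, carries that state.

The greedy assembler finds candidate overlaps by indexing short anchor
k-mers from every contig prefix (several offsets, so one sequencing error
cannot hide a true join) and scanning each contig's k-mer list against the
index — linear in total sequence rather than all-pairs quadratic. Ties break
lexicographically so assembly is deterministic under a fixed input order.
Contained reads are absorbed into their container, preserving the invariant
that every input read belongs to exactly one contig.

## The transcript side

Transcript evidence enters as SAM-text alignments over the two chromosomes
*concatenated* into one pseudo-chromosome, because splice events routinely
cross the chromosome boundary. `extract_junctions()` reads every `N` (skip)
CIGAR operation as a junction — donor is the last aligned base before the
skip, acceptor the first after — aggregates identical events into support
counts, lifts coordinates back to per-chromosome space and flags junctions
whose ends lift to different chromosomes as cross-chromosomal. No splice
motif is assumed: organellar group-II splicing does not follow GT–AG
reliably, so the alignment-level definition is the only safe one.
Junctions cluster into hotspots by single linkage (donor positions within a
window *and* acceptor positions within a window; default 1,000 bases — the
observation being modelled is "a few hundred to a few thousand", so the
window is a tunable order-of-magnitude choice, not a fitted constant).

PolyA-selected coverage is piled up per base (`M`/`D` consume reference,
`N` does not), and `polya_islands()` reports maximal runs of depth at or
above 500 and length at least 50. The depth cut mirrors the >500-read
threshold used for degradation islands in the source system; the minimum
length is a package default chosen to suppress single-spike runs, and both
are parameters. Expression is the worked-example statistic: reads counted
by alignment start in a region, normalised by region length, expressed as
fold change over a non-coding background region. The published table this
reproduces mixes rounding conventions between rows — one fold value needs
unrounded normalised counts, the other matches counts rounded as printed —
so `expression_fold()` reports both (`fold` and `fold_rounded`).

## Genome comparison and editing

`global_diff()` is an affine-gap global alignment (Needleman–Wunsch via
Biostrings, match +1, mismatch −1, gap open 10, gap extend 0.5 — a
Stretcher-like scheme) with event-level counting: one contiguous gap is one
insertion or deletion event, which is the convention that makes indel counts
comparable across cultivar-scale tables. Above 20 kb the sequences are first
anchored on unique shared 31-mers, thinned to roughly 2 kb spacing, and
aligned piecewise between anchor midpoints; on the divergence scales this
package targets (well under 1%), anchor chaining reproduces the direct
alignment exactly, and the suite asserts that agreement. `classify_editing()`
reads the substitution list with A as the genomic and B as the
transcript-derived side: C→T columns are C-to-U editing, G→A columns the
rarer second form, and the "corrected" count removes them in the chosen
mode. Strand normalisation is the caller's job — the classifier works on the
forward strand of the sequences it is given, which is why the simulator
plants all genes on the forward strand.

`gc_classify()` carries the compartment signatures: chloroplast 38.4–38.5%,
nuclear 41.4–42.7%, mitochondrial 43.07–43.93% GC. The ranges are disjoint
as printed; the constructor rejects overlapping configurations.

## What the simulator does and does not emulate

The generator plants every structure with exact ground truth: shared
regions are copied between chromosomes with a 2% per-base mismatch rate
(sampled binomially, so individual regions vary around 98% identity, some
inverted); the long direct repeat (1,500 bases) and inverted repeat (400
bases) are exact copies on chromosome 1; the plastid segment is built with
an exact-count base composition, so its GC hits the 38.4% target within
half a base; genes are exon chains on the forward strand, one of them with
exons on both chromosomes; editing sites are genomic `C`s inside coding
exons that all transcript reads carry as `T`; degradation regions are tiled
deterministically (five full cycles of every read start covering the
region) to a flat depth plateau of 600, and the truth records the interval
the resulting ramp holds at or above the 500 threshold, which is what
maximal-run island detection should return.

Defaults are one tenth of the real chromosome scale (30,000 and 15,000
bases) at 20-fold coverage, with 120-base paired short reads (insert
400 ± 40) and long reads of about 2,000 ± 200 bases. At those conditions a
run of the full loop takes about a minute; the 20-seed specificity property
runs at a further-reduced 12 kb + 6 kb scale with 10-fold paired coverage so
the whole suite stays interactive. Coverage 10 of 2-kb long reads on a
30-kb circle is *not* enough to guarantee assembly closure — the expected
largest start-position gap exceeds the 1,000-base minimum overlap — which
is why the recovery property is stated and tested at the default 20-fold.

What the simulator deliberately does not model: indel sequencing errors
(substitutions only, uniform), base-quality structure, strand-specific
transcription, partially processed transcripts, chimeric library artefacts,
and mappability bias from the nuclear genome. Passing tests therefore show
the *logic* of each stage is correct on data whose structure is known, not
that the pipeline is robust to every artefact of real libraries; on real
data the upstream mapper, duplicate marking and mate-consistency filters
carry that weight.

## Numerical choices and degenerate inputs

* Coordinates are 0-based half-open internally, 1-based inclusive in
  human-readable reports; BED exports need no conversion.
* Circularity everywhere is "sample on the doubled sequence, reduce modulo
  length"; reads and flanks may wrap the origin.
* `N` never matches in any identity computation.
* Identity ties in the read mapper break to the lowest (chromosome id,
  position).
* Zero-junction summaries flag their percentages undefined rather than
  dividing by zero; an all-`N` sequence is an error in `gc_classify()`;
  a zero-read background makes the fold change undefined and flagged.
* Shared-region extension uses X-drop (match +1, mismatch −2, drop 8) and
  cuts at the maximum-score extent, so reported blocks end on matching
  bases and chance single-base flank matches extend a block only when the
  extension genuinely scores.

## Known limitations

The greedy assembler is a desk-scale stand-in for a production OLC or de
Bruijn assembler: repeat copies longer than the minimum overlap can in
principle seduce a greedy merge, and no graph cleaning exists to undo one.
The read mapper is ungapped, sufficient for the substitution-only error
model but not for indel-bearing reads. The guide-locus search reports
every pair of half-window hits without scoring their plausibility. These
are the points to replace first if the package were pointed at real
sequencing data.
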