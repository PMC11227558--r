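---
title: "Scanning genomes for stop-codon-introducing base edits: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scanning genomes for stop-codon-introducing base edits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stopscan)
```

# The model

A cytosine base editor (CBE) deaminates cytosines on the single-stranded,
non-target strand exposed by the Cas9:sgRNA R-loop, converting C•G base
pairs to T•A without a double-strand break. Deamination is efficient only
inside an *editing window* of the 20-nt protospacer; positions are
numbered 1–20 with position 1 PAM-distal, and the window used for
genome-wide scanning here is 4–8 (a 5–9 window, matching what is measured
for hAPOBEC3A-based editors, is available as
`editing_window(5, 9)`).

A single C→T edit creates a premature stop codon in exactly these cases:

* **CAA → TAA**, **CAG → TAG**, **CGA → TGA**: the codon's first base is
  the edited C, on the coding strand.
* **TGG → TGA or TAG**: tryptophan's codon has no C, but the template
  strand opposite it reads CCA; editing its first C (paired with codon
  base 3) yields TGA, editing its second (paired with base 2) yields TAG.
  Both Cs are therefore independent targets, each generating its own
  protospacer placements.

These rules are hard-coded as the scanner's rule table, and the test suite
re-derives them independently: the brute-force oracle mutates every C (on
either strand) of every coding sequence and re-translates the affected
codon with the standard genetic code, confirming that exactly the codons
above produce premature stops.

For each target C the scanner enumerates up to `last - first + 1`
placements, one per window offset, putting the C at each allowed spacer
position on the strand that carries it. A placement is emitted iff the
3-mer immediately 3' of the 20-mer matches the PAM specification
(positionwise IUPAC set membership) and the 23-mer contains no N.
Candidate placements are then deduplicated by physical identity
(contig, spacer sequence, PAM, strand, interval).

# Conventions and parameters

* **Coordinates.** Internally 0-based half-open, the convention that makes
  interval arithmetic unambiguous. GenBank and GFF3 (1-based inclusive)
  are converted on read; BED output is 0-based half-open; TSV reports are
  1-based inclusive.
* **PAM** (`pam_spec`): any IUPAC 3-mer. `NGG` models SpCas9, `NGN`
  SpCas9-NG. Because IUPAC matching is positionwise set membership, a
  narrower pattern's hits are always a subset of a broader one's — a
  property the tests assert (NGG ⊆ NGN on every fixture).
* **Editing window** (`editing_window`, default 4–8): the scan emits one
  candidate per window offset, so widening the window can only add
  placements.
* **Codon range.** Codons 2..(n−1) are scanned. Codon 1 cannot yield a
  premature stop for ATG/GTG/TTG starts, and editing the native terminal
  stop is not a premature stop. No 3'-proximity filter is applied by
  default: a stop introduced in the last few codons may truncate too
  little protein to be a knockout, but any such cutoff is arbitrary and is
  left to downstream filtering of the `codon_index` column.
* **Partial features.** Compound (joined) CDS locations, out-of-frame
  lengths and pseudogene-annotated CDSs are kept in the feature table but
  flagged `partial` and excluded from codon scanning — a joined location
  naively concatenated risks silent frame errors, and bacterial CDSs are
  overwhelmingly single-interval anyway.
* **N bases.** Input characters outside {A,C,G,T,N} become N with a
  warning; candidates whose 23-mer contains any N are dropped, since an
  undefined base can neither be guaranteed to match the PAM nor to edit.
* **Topology.** Linear contigs silently skip placements that would run off
  an end; `topology = "circular"` enables wraparound 23-mers. The
  *S. coelicolor* chromosome is linear, so linear is the default.
* **Gene attribution.** A protospacer is attributed to every gene whose
  editable codon generated it; overlapping genes can therefore each claim
  the same physical 23-mer. Per-gene counts answer "how many options do I
  have for this gene" and may double-attribute; the genome-level total
  (`n_protospacers_total`) deduplicates across genes, since "how many
  protospacers exist in this genome" is a property of the sequence.
* **Uniqueness key.** "Unique protospacers per gene" deduplicates by
  physical placement (sequence *and* location), not by sequence alone; a
  20-mer recurring at two loci is two distinct design options with
  different off-target profiles. The alternative convention is computable
  by keying on sequence only.

# Sequence-context classification

Editing efficiency on GC-rich templates is driven by features the
classifier annotates per candidate:

* `gc_percent` — G+C percentage of the 20-mer spacer (the PAM is
  excluded; the protospacer proper is 20 nt). Thresholds used in scope
  categories are as conventionally printed: "≤ 75%" and "> 75%", strict.
* `gc_motif_in_window` — TRUE iff some window position p carries a C whose
  5' neighbour (p−1) is G. Only the C must lie in the window; the G may
  sit at `first − 1`, because the deaminase reads the 5' context of the
  edited C, not the window boundary. The definition is isolated in
  `has_gc_motif()` so the stricter both-in-window reading is a one-line
  change; on GC-rich genomes the two readings differ by only the cases
  where the G sits exactly at position `first − 1`.
* `bystander_c_count` — the number of window Cs other than the target;
  each is a candidate for unwanted co-editing when the goal is a precise
  single conversion.
* `pam_class` — NGA/NGT/NGC/NGG when the PAM's middle base is G, otherwise
  "other"; the four NGx classes are the experimentally characterized ones.

The three scope categories reported genome-wide — no motif & GC ≤ 75%,
GC motif (any GC), GC > 75% (any motif) — deliberately overlap, mirroring
how such distributions are conventionally presented; the exact identity
`fraction(no motif AND ≤75) + fraction(motif OR >75) = 100` is asserted in
tests to 1e-12.

# Amplicon quantification

Editing outcomes are measured from pooled-exconjugant amplicon sequencing.
Reads carry an 8-bp sample barcode at the 5' end; demultiplexing is exact
prefix matching with no mismatch rescue (an 8-mer at Illumina error rates
loses few reads, and determinism is worth more than the rescue).
Counting is *alignment-free by design*: a read contributes iff its mean
Phred score is ≥ 15 (echoing the common read-level QC threshold) and it
matches the two fixed 12-mer flanks around the protospacer exactly — the
left flank must occur exactly once, and the 12-mer after the extracted
20-mer must equal the right flank. CBEs do not cut, so indel-carrying
reads are rare; those few shift the right flank and are counted as
anchor-failed rather than mis-tallied. The accounting identity
`assigned = anchored + anchor_failed + quality_failed` is asserted per
amplicon.

Frequencies are substitution reads over anchored reads, per position, on
the spacer-strand orientation. The cognate-to-bystander ratio
`freq(cognate C→T) / freq(bystander C→T)` summarizes selectivity: 1 means
entirely non-selective editing; the boundary case bystander = 0 with
cognate > 0 reports Inf, and 0/0 reports 1 (equal frequencies).

# Off-target audit

Variant tables (VCF) from treated and untreated samples are compared as
sets keyed by (contig, pos, ref, alt) — a different alt allele at a
control position does not shield a treated SNV. Records must exceed the
depth threshold strictly (default > 10). The deamination signature counts
both C→T and G→A, since an edited C on the opposite strand reads as G→A
on the forward reference. Genomic binning uses half-open 0.1 Mb bins on
positions, so a position at an exact bin multiple falls in the following
bin (a position equal to the genome length stays in the last bin); counts
always sum to the input size. Replicate summaries report mean, standard
deviation and s.e.m. = sd/√n of the deamination-consistent counts (s.e.m.
undefined for a single replicate), plus a union site-by-replicate
frequency matrix with zeros where a site is absent. VCF ingestion splits
multiallelic rows; depth falls back FORMAT DP → INFO DP, frequency
FORMAT AF → FORMAT AD ratio → INFO AF, since callers differ in where they
record these.

# The synthetic-data generator

The generator exists so every stage can be tested against exact truth
without any downloads.

**Genomes.** Background bases are i.i.d. with P(G or C) = `gc_fraction`,
default 0.72 — the regime of *Streptomyces*-like genomes where GC motifs
dominate the candidate pool. Genes (ATG + filler + TAA) are planted at
evenly spaced offsets; filler codons are drawn GC-weighted but exclude the
four editable codons and stops, so each gene's editable codons are exactly
the planted ones. For each planted target, the PAM trinucleotide is
written at the genomic slot that places the target C at the declared
window position. Because that write can land inside the gene body, the
generator re-inspects every gene afterwards by direct string inspection
(independent of the scanner) and retries with a perturbed seed if an
accidental editable codon, internal stop, or damaged start appears. Note
the corollary: a planted PAM whose own trinucleotide *is* a stop codon and
happens to align with the reading frame can never validate; choose PAM
plants accordingly. The truth manifest enumerates, again by direct string
inspection with Biostrings-based IUPAC matching, every placement a scanner
should find for each declared (PAM, window) combination — including
serendipitous matches at non-declared window offsets.

**Reads.** `"exact"` mode edits exactly `round(f · n)` reads per planted
position, so recovered frequencies are exact rationals and tests can
assert equality; `"binomial"` mode edits each read independently, giving
statistical realism checked within 3 binomial standard deviations
(n = 2000 in the tests). Qualities are a constant Phred offset; no
quality-profile realism is attempted.

**SNV tables.** Shared variants appear in both treated and control tables,
private ones only in treated (deamination-consistent by construction),
with optional sub-threshold-depth plants to exercise the depth filter.

What the synthetic data does *not* emulate: codon usage, operons,
overlapping genes, sequencing-quality profiles, alignment artefacts, or
variant-caller noise. Passing tests demonstrate algorithmic correctness on
defined inputs, not robustness to every pathology of real data — for real
genomes the scan is exact string processing and transfers directly, while
amplicon anchoring and VCF field fallbacks are the components most exposed
to real-data messiness.

# Problem sizes and numerical choices

The test suite works at sizes chosen to keep the full run near twenty
seconds while still exercising every code path: random genomes of 2–3 kb
with three genes for oracle equivalence (50 genomes across 3 PAMs × 2
windows in the acceptance suite), 10 kb planted genomes for truth-manifest
recovery, 100–2000-read amplicon pools, and SNV tables on an 8 Mb
coordinate space. The whole-genome reproduction of the published
*S. coelicolor* M145 statistics (8152 ORFs) runs through the identical
code path via `reproduce_reference_scan()` and needs only the NC_003888.3
GenBank flatfile, which is too large to bundle.

Scope fractions are kept at full precision and rounded only at
presentation time (two decimals in printed reports). Ties and degenerate
inputs are handled explicitly: empty protospacer sets yield NA category
fractions; a gene universe with zero genes yields NA editable fraction;
deduplication keeps the first record in emission order (increasing window
offset within a target, targets in codon order), making outputs
byte-stable across runs, which the CLI tests assert.

# Known limitations

* No on-target activity scoring: reachable is not the same as efficient,
  and activity models are outside scope.
* No mismatch-tolerant off-target site prediction; the audit is purely
  observational (sequencing-based).
* Amplicon quantification excludes indel alleles by construction; it
  reports substitution frequencies only.
* Adenine base editing (A→G) rules are not implemented.
* Multi-interval (joined) CDSs are not codon-scanned; for bacterial
  genomes this affects a negligible minority of features.
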