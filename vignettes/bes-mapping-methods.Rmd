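---
title: "Methods: BAC-end sequence mapping, contigs, rearrangements and polymorphisms"
author: "besmap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: BAC-end sequence mapping}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(besmap)
```

# The analysis in one paragraph

A BAC (bacterial artificial chromosome) library carries ~100 kb inserts of
a genome of interest; single-pass Sanger reads off both insert ends (BAC-end
sequences, BESs) can be mapped onto a related reference genome. Each clone
then reports three things at once: a physical-map interval (if its two ends
land uniquely, on one chromosome, facing inward, within a distance cap), a
structural signal (if its ends land uniquely but in an impossible geometry),
and a set of sequence differences (mismatch and gap columns of its
alignments). `besmap` implements this complete comparative analysis —
read filtering, repeat screening, local alignment, paired-end placement,
hypothetical BAC contig construction with euchromatin/heterochromatin
coverage accounting, discordant-pair clustering into candidate inversions
and translocations, and SNP/indel calling with genic classification —
together with a synthetic-data generator that produces genome pairs and
clone libraries with complete machine-readable truth, so that every stage
is testable without any external download.

# The extraction criteria

A read's alignments are *significant* when sequence identity exceeds 90%,
alignment coverage (aligned query length over full read length) exceeds
0.5, and the Karlin–Altschul E-value is below 1e-100 — all three strict
inequalities. An end is *unique* iff exactly one significant hit survives;
two or more significant hits make it *redundant* with no best-hit rescue,
because a clone end with multiple credible genomic homes cannot anchor a
physical map. Reads are screened against a repeat library first (repeat iff
best E < 1e-50, strict), and reads whose mean Phred quality is below 20 are
removed before anything else. Every read therefore lands in exactly one of
six bins — repeat, no-hit, weak, redundant, unique pair end, unique end —
and the bins must sum to the input; this conservation law is asserted in
the tests.

A unique pair is *concordant* when both ends are on one chromosome, on
opposite strands pointing toward each other (the forward-strand end
leftmost), and the outermost extent of the two alignments is under 200 kb.
"Correct direction" is not defined in the sources this design follows; the
inward-facing rule above is the geometry every paired-end protocol
produces, and it is what we implement. Discordant unique pairs are *kept*
as unique pairs — their ends are, after all, uniquely placed — but they are
routed to rearrangement detection and excluded from contig building.

# The aligner

The similarity search is a seed-and-extend local aligner: exact k-mer
seeds (k = 11, the classic BLASTN word size) against a hash index of the
reference, clustered by diagonal, each qualifying cluster extended by a
full affine-gap Smith–Waterman with traceback over a padded subject
window. Scoring defaults are match +1, mismatch −3, gap open 5, gap
extend 2 (a gap of length L costs 5 + 2L, the Biostrings convention), with
Karlin–Altschul parameters λ = 1.28, κ = 0.46 fixed for this scheme and
configurable alongside it. E = κ·m·n·e^(−λS) with m the read length and n
the summed reference length.

Two numerical choices matter:

* **Two-hit seeding.** A cluster must contain two non-overlapping
  same-diagonal seeds within 40 bp before it is extended. In megabase
  subjects a single 11-mer coincidence occurs hundreds of times per read
  and each would otherwise trigger a full window extension; simulation of
  the relevant query classes (200 bp reads at 5% divergence, repeat units
  at 10%) over 200,000 draws found no instance in which the rule discards
  the true alignment. The tests hold the aligner to exact top-hit score
  equality with an independent full Smith–Waterman
  (`Biostrings::pairwiseAlignment`) on randomly mutated instances.
* **Gap cap.** No single alignment gap may exceed 26 bases. Rather than
  silently clipping, extension is terminated at an over-long gap: the
  optimal alignment is split at the offending gap run and each piece is
  re-trimmed to its maximal-scoring stretch, yielding two hits. A grep
  over all emitted aligned strings for a 27-gap is part of the test suite.
  The cap is also why called indels never exceed 26 bp.

Hits read from or written to disk use the 12-column BLAST tabular dialect
(1-based inclusive, minus-strand hits with subject coordinates reversed),
optionally extended with two columns carrying the aligned strings; files
without aligned strings still support placement but not variant calling.

# Coordinates

Internally everything is Bioconductor convention: 1-based, closed
intervals, held in `IRanges`/`GRanges`. This is a deliberate choice — the
interval algebra this package leans on (`reduce`, `intersect`,
`findOverlaps`) is defined on those semantics, and fighting the ecosystem
with an off-by-one layer is how coordinate bugs are made. File formats
keep their own conventions: the chromatin partition table and contig BED
are 0-based half-open, GFF3 and VCF and the tabular hit format 1-based
inclusive, converted at the boundary.

# Physical map and coverage accounting

Hypothetical BAC contigs are the connected components of interval overlap
among concordant clone intervals (touching intervals merge). Coverage is
reported per chromosome and per chromatin partition: covered bases are the
exact intersection of the contig union with the partition intervals, so a
boundary-spanning contig splits its bases between euchromatin and
heterochromatin; contig and clone *counts*, which cannot be split, are
assigned to the partition holding the contig midpoint. Covered plus
uncovered bases equal the partition length in every row, per-chromosome
rows sum to the grand totals, and percent coverage in a totals row is
total covered over total length (not a mean of percentages) — that is the
arithmetic that turns per-chromosome covered bases into partition-wide
averages. Single-end placements contribute neither contigs nor coverage.

# Rearrangement detection

Each discordant unique pair reduces to a signature: its ends ordered by
position, and a category — `ORIENTATION` (same chromosome, within the
distance cap, strands wrong), `ORIENTATION_AND_DISTANCE`, `DISTANCE`, or
`INTERCHROM`. Typing follows the geometry: orientation anomalies are
inversion candidates; orientation-plus-distance are inverted
translocations; interchromosomal pairs are translocations; pure distance
anomalies are reported as distance anomalies.

Signatures of one category on one chromosome (pair) are clustered by
single linkage over their clone spans with a 50 kb window. Spans — rather
than the two end clusters separately — are used deliberately: an inversion
is witnessed by two sub-families of clones, both-plus pairs entering from
the left and both-minus pairs from the right, whose end clusters do not
coincide; their spans all cross the inverted interval, so span linkage
merges them into the single event they jointly support, and the recovery
tests require exactly one event per planted inversion.

Events need at least `min_support = 2` clones; a single discordant clone
is never evidence, since a chimeric clone produces exactly that signal.
(The default is 2 rather than 3 because the real events this machinery is
modeled on were each supported by two clones; the threshold is a
parameter.) Candidate events are then screened, by flagging rather than
deletion: a 5 kb flank of a breakpoint cluster overlapping annotated
repeats sets `flag_repeat`, and any supporting end with a second raw
similarity below E = 1e-50 sets `flag_multicopy` — an automated stand-in
for manual inspection of secondary BLAST hits.

Breakpoint reporting is two-layered. The cluster spans (`bpA`, `bpB`) are
the union of the supporting end alignments on each side — compact,
human-readable, the shape of a per-clone report table. The breakpoint
*regions* extend those spans by `breakpoint_pad` (default 200 kb, the
pair-distance cap and hence an upper bound on a selected clone's insert):
a junction must lie within one insert length of every end that witnesses
it, so the padded regions are conservative intervals guaranteed to contain
the true breakpoints, and the truth-recovery tests assert exactly that
containment. For inversions supported by both sub-families the implied
size range is reported by bracketing the left junction between the
both-plus clusters and the right junction between the both-minus clusters.

# Polymorphism calling

Variant calling walks the aligned strings of every accepted unique hit
column by column, tracking the subject coordinate through gaps: mismatch
columns give SNPs, gap runs in the query string give `INS` (the reference
carries bases the read lacks), gap runs in the subject string give `DEL`
(the read carries bases the reference lacks) — note the reference-relative
orientation convention. A gap run is one polymorphism of its run length.
Indels are anchored at the reference base immediately left of the gap and
left-normalised against the reference (the VCF convention), which is what
makes calls comparable at identical coordinates when a deletion sits in a
homopolymer and the aligner's tie-break could legally place the gap at
either end of the run. Minus-strand hits are aligned subject-forward, so
alleles are already on the reference forward strand. Ambiguous bases make
no call.

Sites observed by several overlapping reads are deduplicated on
(chromosome, position, type, alleles), keeping the merged source read
list; distinct alternate alleles at one site are all kept and flagged as
conflicting. Deduplication is on by default — without the raw electropherograms
there is no way to distinguish repeated observation from independent
evidence, and densities would otherwise depend on local read depth.

SNPs are classed as transitions (A↔G, C↔T) or transversions; genic
annotation takes the highest-priority feature across all overlapping
transcripts, CDS > UTR > splice junction (first or last two bases of an
intron) > intron > intergenic. Densities are reported per chromosome and
partition as covered bases per polymorphism, with covered bases taken from
the physical-map coverage rows, rounded to the nearest integer only at the
reporting layer; percentages likewise round to one decimal only in
reports.

# The synthetic-data generator

The generator is first-class, tested code, and its defaults are the study
conditions the rest of the package is validated under.

* **Reference** (`genome_spec`): uniform-composition chromosomes at GC
  0.36 (a typical plant euchromatin value), with repeat families planted
  as non-overlapping copies point-mutated away from a consensus unit
  (default: a 400 bp family at 5% divergence and a 150 bp family at 10%),
  a chromatin partition of two distal euchromatin blocks flanking one
  central pericentromeric heterochromatin block (fraction 0.4 by default),
  and non-overlapping multi-exon gene models (30 genes/Mb, 2–6 exons of
  150–400 bp, introns 100–800 bp, UTRs inside terminal exons) written as
  GFF3 with CDS phase. The partition is consumed downstream as a generic
  interval table, so externally derived euchromatin/heterochromatin
  boundaries can be substituted for the synthetic ones.
* **Cultivar** (`mutation_spec`): SNPs at 1 per 3 kb and indels at 1 per
  17 kb by default — the density regime of two closely related cultivars
  of a selfing crop — with indel lengths truncated-geometric (p = 0.9,
  cap 26 bp) so single-base events dominate, and 40% of indels oriented
  as reference-relative insertions. Inversions and translocations are
  planted at explicit coordinates; an inverted interval in the cultivar is
  exactly the reverse complement of the reference interval. Small variants
  keep 30 bp from each other and 200 bp from rearrangement segments so
  that every truth record has a single unambiguous reference coordinate.
* **Library** (`library_spec`): insert sizes Normal(101,300 bp, sd
  10,000), resampled to fit the chromosome; two reads per clone facing
  inward on opposite strands, lengths uniform in 500–900 bp (single-pass
  Sanger reads; the real read-length distribution is not published, so
  this range is an explicit assumption held in the spec object);
  substitution errors at a configurable per-base rate; per-base Phred
  qualities drawn around a read-level mean (Normal(40, 8)) that declines
  by 15 along the read with jitter 3, clamped to [2, 60] — so the mean-QV
  < 20 filter removes a realistic sub-percent tail rather than nothing.

What the generator does *not* emulate, and what passing tests therefore do
not show: chromatogram-level error structure (errors are i.i.d.
substitutions, no indel errors or quality-correlated miscalls), vector or
adapter contamination, chimeric clones, cloning-bias along the genome, and
nested or overlapping rearrangements. Recovery results on synthetic data
bound what the method can do when its alignment assumptions hold; they do
not certify performance on degraded traces.

# Recovery metrics and what "covered" means

On an error-free run the pipeline is held to exact standards: SNP and
indel precision 1.0, and recall *equal* (not approximately equal) to the
covered fraction of planted sites. "Covered" is defined operationally: a
planted site counts as covered when its site interval — the position
itself for a SNP, the variant plus one flanking base on each side for an
indel — lies within a single accepted unique alignment footprint. This
definition makes recall-equals-coverage an identity the code must satisfy
rather than a tolerance: a variant at the very edge of a read is either
included by the optimal local alignment (then called, and its site
interval is inside the footprint) or trimmed away with the terminal
columns (then the footprint excludes the interval and the site is not
counted as covered). Both sides of the ledger derive from the same
alignment, so any discrepancy is a genuine bug, and the acceptance tests
treat it as one.

# Problem sizes and determinism

The validation suite runs on two chromosomes of 1 Mb, 400 clones (~800
reads), ~300 planted SNPs and ~60 indels, one 50 kb inversion and one
30 kb inverted translocation — large enough that every flow bin, both
event types and a few hundred variant calls are exercised, small enough
that a full pipeline run takes seconds. The recovery runs use a
repeat-free genome: planted-event recovery should be a property of the
method, not of where random repeat copies happen to fall relative to the
planted breakpoints; repeat screening, redundancy handling and the
repeat-rich negative control (zero events at every window setting) are
exercised separately. All generators are bit-reproducible for a fixed
seed, pipeline outputs are identical across reruns and invariant under
input read order, and a single master seed drives the three generator
streams through fixed arithmetic.

# Known limitations

* The aligner is heuristic below ~150 bp of homology at 10% divergence
  (the two-hit rule's floor); BLAST-grade statistics (edge-effect and
  composition corrections) are deliberately out of scope.
* "Alignment coverage" is defined on the query; a subject-fraction
  definition would behave differently for reads much longer than their
  alignable portion.
* Repeat-masked ends are not rescued by their mate's unique position, so
  coverage near repeat copies is conservative.
* The repeat-flank screen is deliberately conservative: a single
  supporting end within 5 kb of an annotated repeat flags the whole
  event, so in repeat-dense genomes genuine events will often carry the
  `flag_repeat` mark. Flags are advisory — flagged events are reported,
  never dropped — and the flank width is a parameter.
* Interchromosomal discordance is detected and typed but not exercised by
  the default recovery conditions.
* Breakpoint regions are conservative by construction (padded by an
  insert-length bound); split-read refinement of junctions is out of
  scope.
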