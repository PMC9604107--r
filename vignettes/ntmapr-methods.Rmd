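---
title: "Mapping natural transposon insertions with ntmapr: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping natural transposon insertions with ntmapr: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ntmapr)
```

## The problem

Natural transposons (NTs) move, and every insertion leaves a characteristic
signature at the genomic site: the transposon sequence flanked by a short
**target site duplication** (TSD, e.g. 8 bp for P-element and hobo in
*Drosophila melanogaster*), with the element's **terminal inverted repeats**
(TIRs, 31 bp for P-element, 12 bp for hobo) sitting directly at the two
transposon-genome junctions.  Given a newly assembled genome (contigs or long
reads — the *alternative reference genome*, ARG) and a canonical assembly
(the *canonical reference genome*, CRG), the task is to find where an NT of
interest is inserted, at single-nucleotide resolution, and to distinguish
insertions private to the new genome from insertions shared with the
reference.

ntmapr maps insertions from **junction queries** (JQs): sequences that
straddle a transposon-genome junction.  A JQ aligned against two reference
collections — the genome database (GD) and the transposon database (TD) —
decomposes into genome-derived ("blue") and transposon-derived ("red")
partial alignments.  A mixed blue-red composite marks a junction.  The first
blue nucleotide adjacent to a red nucleotide is the **terminal genomic
nucleotide** (TGN): the reported insertion coordinate.  A JQ that aligns
completely blue against the CRG marks an insertion that the reference
carries too.

## The procedure

Two workflows chain into a pipeline:

* **WF1 (`run_wf1`)** scans the ARG contigs (loaded as the only reference
  database) with the NT's two terminal crops: Q5', the first 60 nt of the
  element, and Q3', the last 60 nt.  Sixty nucleotides comfortably contain
  the TIR plus enough internal sequence to tell the 5' from the 3' terminus
  in either insertion orientation.  Hits are kept when they score at least
  40 (for the 60-nt crops) and carry the complete TIR — the TIR portion of
  the crop aligned at ≥ 90% coverage and identity.  Around each surviving
  hit a junction query is extracted: an upstream flank for Q5' and a
  downstream flank for Q3' (3000 nt by default, hence ~3060-nt JQs),
  reverse-complemented for minus-strand hits so every JQ reads in
  transposon-forward orientation.  When only one terminus of a remnant
  survives (the other TIR lost during evolution), the partner JQ is built by
  a three-part join: the surviving crop region, a window as long as the
  transposon, and 2000 further nucleotides.  Remnants too close to a contig
  end yield truncated JQs flagged with an `ALERT` string in the FASTA
  description.
* **WF2 (`run_wf2`)** aligns the JQs against the CRG (GD) plus the NT
  reference (TD), composes the partial alignments, applies the
  insertion-candidate bonus, ranks, and derives one result row per JQ:
  junction rows carry the TGN, orientation (1 = concordant strands,
  2 = discordant), the TSD and gene annotations; completely blue rows are
  classified `genomic` (insertion shared with the CRG).

### Alignment heuristic

Queries are seeded with exact k-mers (the **nucleus size**, default 20 for
contig scans, 30 for JQ mapping; values below 10 are warned about).  Seeds
on one diagonal band (offset difference ≤ 16) are merged and one
representative per cluster is extended by a banded affine-gap local
alignment (Gotoh; compiled code) with match +1, mismatch −1, gap open −2,
gap extension −1 — a perfect 60-nt crop scores 60, which puts the
recommended score ≥ 40 filter at two-thirds of the maximum.  The explored
reference window around a seed is capped at 2× the query length ("short"
interval extension, the default) or 8× ("long").  Both query orientations
are matched against a plus-strand index.  Once a best alignment covers
(nearly all of) the query, shorter alignments properly nested in its query
range are suppressed — this is what makes a shared insertion come out as a
single blue result rather than a concurrent blue-red one.

### Composition rules

Two blue parts merge into one final alignment only if they sit collinearly
on the same reference and strand, do not overlap in genomic coordinates,
and are separated by at most `max_genomic_gap` nucleotides (default 200).
A query interrupted by a genomic deletion larger than that is reported as
two final results.  Pairs involving a red part compose without these
restrictions, which is what permits junction results, transposon
self-insertions, and remnants with large internal deletions (red parts may
even share transposon coordinates).  Composites are ranked by total score;
ties prefer fewer parts, then lexical reference order, then the leftmost
reference start.  With the bonus option on, a junction composite whose red
part abuts the border with an *almost intact* TIR — ≥ 90% identity over
≥ 90% of the annotated TIR interval, a threshold we chose and made
configurable — gains +500, which reliably lifts insertion candidates above
concurrent genomic-only alignments, so a result list of two is usually
enough.  The **picking depth** (default 1) then limits how many
identical-scoring placements of the same query span are reported: with the
default, a query matching two identical loci yields a single placement.

### Junction trimming and why it is needed

Local alignment endpoints *wander*: whenever a few bases beyond the true
junction happen to extend the score (with +1/−1 scoring a net-positive
excursion occurs with probability ≈ 1/3 per boundary), the blue part
overlaps the red part on the query.  ntmapr resolves such overlaps at
composition time by the split point that maximizes the summed trimmed
score; among ties the transposon part keeps its columns, because at a true
junction it is anchored at a terminus of the transposon reference and
cannot wander outward — the transposon terminus therefore defines the
junction and the TGN.  A trimmed part is then re-aligned within its trimmed
query interval (the optimal alignment of a whole query need not contain the
optimal alignment of a prefix), and the genomic distance between blue parts
is measured from mid-part diagonals plus the residual query gap, which is
identical to the endpoint measure for clean alignments but immune to
endpoint junk.  Overlaps spanning most of either part are genuinely
conflicting placements and are never composed.

One limitation follows from the same geometry: at a junction formed by an
*internal truncation* of the transposon (the single-TIR join), neither side
is anchored at a reference terminus, so the boundary — and hence that
call's TGN — can shift by a few bases of chance microhomology.  The
TIR-anchored call of such an insertion is still exact, and the TSD printed
for the truncation-side call should be treated as approximate, which is why
paired 5'/3' TSDs are compared rather than assumed equal.

## Parameters

| parameter | default | units | role |
|---|---|---|---|
| `nucleus_size` | 20 (WF1), 30 (WF2) | nt | exact-match seed length; larger = faster, fewer spurious partials |
| `picking_depth` | 1 | placements | identical-scoring placements kept per query span |
| `number_of_results` | 1000 (WF1), 2 (WF2) | composites | result-list length per query |
| `interval_extension` | short | — | reference window cap: 2× (short) / 8× (long) query length |
| `bonus` | off (WF1), on (WF2) | — | +500 for junction composites with an almost intact border TIR |
| `max_genomic_gap` | 200 | nt | largest genomic distance merged between blue parts |
| `tsd_flank_length` | 8 | bp | TSD / flank window length (P-element and hobo TSD size) |
| `consensus_threshold` | 20 | % | minimum per-position frequency entering the IUPAC symbol (inclusive, "at least") |
| `min_report_score` | 40 | score | WF1 hit filter for 60-nt crops |
| `match/mismatch/gap_open/gap_extend` | +1/−1/−2/−1 | score | a perfect 60-nt query scores 60 |
| `band` | 32 | diagonals | half-width of the banded extension |

Coordinates: reported insertion coordinates (TGN) are 1-based; internal
intervals are 0-based half-open.  The transposon-annotation format alone is
0-based by rule — **the annotation line referring to the first nucleotide
of a sequence starts at coordinate zero**, so a 1-based TIR 1..31 is
entered as `0,31`.

## The consensus module

`compute_consensus` maps, per position, the set of nucleotides whose
frequency among non-N letters is at least the threshold to the IUPAC
ambiguity code (2-fold R/Y/S/W/K/M, 3-fold B/D/H/V, 4-fold N).  At a 100%
threshold the sequences must be identical or an error is raised; below
that, positions where no nucleotide reaches the threshold are reported as N
with a warning.  Frequency comparison is inclusive because the contract is
"at least".  Raising the threshold never increases positional degeneracy
(for positions that keep a non-empty selection set).

## What the synthetic fixtures emulate — and what they do not

`make_case_study` emulates a resequencing project: a CRG of 10 chromosomes
of 50–200 kb, an ARG of matching contigs, and a mixture of events of a
2-kb class II transposon with 12-bp TIRs and 8-bp TSDs: private full
insertions in both orientations, insertions shared with the CRG, a
single-TIR remnant, and one insertion nested inside a remnant of a second,
longer element private to the ARG (whose genome junctions are then the
callable coordinates, with the second element reported as overlapping
landscape).  The TSD is copied from the genomic site, as transposition
does, so 5'/3' concordance is meaningful; each planted copy carries a
distinct small number of point mutations placed in the crop interior
(outside the TIRs, preserving ≥ 30-nt exact runs so seeding still works),
the divergence real remnants accumulate.  Every fixture is byte-reproducible
from its seed.

The simulator does **not** model sequencing or assembly error inside the
alignments (the method maps contigs, not reads), repeat families beyond the
planted elements, low-complexity sequence, or heterozygosity.  Passing
tests therefore demonstrate the correctness of the mapping logic — exact
TGN/TSD recovery, shared/private discrimination, composition and picking
rules — not robustness to noisy assemblies, where junction boundaries
become approximate and manual curation of borderline alignments remains
advisable.

Problem sizes used by the test-suite: the recovery property runs 50
single-insertion fixtures with genomes drawn from 50–200 kb and TSDs of
4–10 bp; mixed case studies in unit tests use 8 contigs of 20–26 kb; the
aligner is checked against an independent Smith–Waterman implementation on
100 instances of ≤ 2 kb; composition is checked against exhaustive subset
enumeration for up to 6 parts.  These sizes were chosen so the whole suite
exercises every rule at full fidelity in minutes on a laptop core.

## A worked mini-example

```{r example}
cs <- make_case_study(seed = 77, n_contigs = 8,
                      contig_len_range = c(20000, 26000))
wf1 <- run_wf1(cs$arg, cs$nt, tir5_len = cs$tir_len,
               params = wf1_params(picking_depth = 10000))
wf2 <- run_wf2(wf1$jqs, cs$crg, cs$td, tir_features = cs$tir_features,
               params = wf2_params(tsd_flank_length = cs$tsd_len),
               features = cs$gene_features)
wf2$results[, c("query_id", "transposon", "reference_id", "tgn_coordinate",
                "orientation", "tsd", "classification")]
```

Junction rows recover the planted coordinates in `cs$truth`; the 5' and 3'
calls of one insertion bracket the same duplicated motif (the 5'-side TGN
and the 3'-side TGN differ by `tsd_len - 1` by construction of the
duplication).  Shared insertions come out `genomic` with no TGN.

## Known limitations

* Truncation-side junction calls (single-TIR joins) are approximate under
  microhomology, as discussed above.
* Insertions inside long repeats may not be resolvable to a unique CRG
  placement; equal-scoring placements are controlled by `picking_depth`,
  and near-tie score lists indicate chromosome-level rather than
  nucleotide-level resolution.
* One transposon species is processed per workflow run; the TD may hold
  several elements (useful for nested landscapes), but ranking weighs plain
  score only.
* The annotation module expects GFF3 or the minimal 0-based TSV; database
  -specific export formats must be adapted by the user.
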