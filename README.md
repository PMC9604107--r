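# ntmapr — junction-based mapping and annotation of natural transposon insertions

ntmapr locates insertions of natural transposons (NTs) in assembled contigs
and long reads at single-nucleotide resolution, and tells insertions private
to a newly sequenced genome apart from insertions shared with the canonical
reference.  It is written for genome annotators tracking one element of
interest — a P-element, hobo, copia or similar — across a resequenced strain,
rather than for genome-wide repeat masking.

## The method

An insertion leaves a junction signature: transposon sequence flanked by a
short **target site duplication** (TSD), with the element's terminal inverted
repeats (TIRs) at the two transposon–genome borders.  ntmapr aligns
**junction queries** (JQs) — a transposon terminal segment plus genomic
flank — against two indexed reference collections, a genome database (GD)
and a transposon database (TD), using an exact k-mer seeded ("nucleus size"
k, default 20–30), banded, affine-gap local aligner (match +1, mismatch −1,
gaps −2/−1).

Partial alignments of genome origin ("blue") and transposon origin ("red")
are composed into final results.  Two blue parts merge only collinearly,
without genomic overlap, and with a genomic distance ≤ 200 nt (default);
pairs involving red parts compose freely, which permits junction,
self-insertion and internally deleted remnant results.  In a blue–red
composite the first blue nucleotide adjacent to a red nucleotide is the
**TGN** (terminal genomic nucleotide) — the reported insertion coordinate —
and the adjacent duplicated motif is the TSD.  An optional **bonus** adds
+500 to junction composites whose border carries an almost intact TIR,
lifting insertion candidates above concurrent genomic-only alignments, and
the **picking depth** (default 1) limits identical-scoring placements per
query span.

Two workflows chain into a pipeline: **WF1** (`run_wf1`) scans ARG contigs
with the NT's 60-nt terminal crops (Q5'/Q3'), filters hits (score ≥ 40,
complete TIR), and extracts ~3060-nt JQs (3000-nt flanks); **WF2**
(`run_wf2`) maps the JQs against the canonical reference plus the NT,
calls TGN/orientation/TSD, annotates hit and flanking genes, and exports a
results table.  JQs of insertions also present in the reference align
completely blue and are classified `genomic`.  The package also computes
IUPAC ambiguity consensus sequences over TSD or flank sets (inclusion
threshold 20% by default), extracts flanks at arbitrary coordinates,
converts FASTA to headerless RAW files, and ships a synthetic
planted-insertion simulator (`make_case_study`) with truth tables.

## Worked example

Simulate a 50-kb genome, plant a 2-kb element with 12-bp TIRs and an 8-bp
TSD at coordinate 20,000, and run the full pipeline:

```r
library(ntmapr)

g  <- generate_genome(50000, seed = 5, id = "chr1")
nt <- generate_transposon(2000, tir_len = 12, seed = 7, id = "hobo_like")
ins <- plant_insertion(g, nt$record, coordinate = 20000, tsd_len = 8,
                       contig_id = "contig_1")

wf1 <- run_wf1(ins$contig, nt$record, tir5_len = 12,
               params = wf1_params(picking_depth = 10000))
wf1$hits
#>     contig side coordinate strand score
#> 1 contig_1   5'      20001      +    60
#> 2 contig_1   3'      21941      +    60

wf2 <- run_wf2(wf1$jqs, g, seq_records(nt$record$id, nt$record$seq),
               tir_features = nt$features)
wf2$results[, c("query_id", "transposon", "reference_id",
                "tgn_coordinate", "orientation", "score", "tsd",
                "classification")]
#>         query_id transposon reference_id tgn_coordinate orientation score
#> 1 contig_1_JQ5_1  hobo_like         chr1          20000           1  3560
#> 2 contig_1_JQ3_1  hobo_like         chr1          19993           1  3560
#>        tsd classification
#> 1 GAACCAAC       junction
#> 2 GAACCAAC       junction
```

Reading the output: both 60-nt crops hit the contig with the full score of
60.  The two junction queries map back as blue–red composites: the 5'-side
call puts the TGN at 20,000 (the last genomic base before the element) and
the 3'-side call at 19,993 (the start of the duplicated motif) — the two
TGNs of one insertion bracket the 8-bp TSD, so they differ by
`tsd_len − 1 = 7`.  Both calls recover the same duplicated motif
`GAACCAAC`, orientation 1 (plus strand), and the score 3560 = 3000-nt flank
+ 60-nt crop + 500 bonus for the intact border TIR.  Planted truth
(`ins$truth`) confirms: coordinate 20000, tsd GAACCAAC, tgn5 20000,
tgn3 19993.

A command-line front end is installed with the package
(`<library>/ntmapr/exec/ntmapr`) with subcommands `scan`, `map`, `flank`,
`tsd`, `consensus`, `convert`, `annotate-te` and `simulate`.

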