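---
title: "Methods: transcript filtering, noncoding RNA discovery and DE unification"
author: "rnaseqtk"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: transcript filtering, noncoding RNA discovery and DE unification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rnaseqtk)
```

This vignette documents the models, rules and numerical choices behind
each stage of the package, in the order data flows through them, and
states what the synthetic fixtures do and do not demonstrate about real
data.

## Data model and coordinates

Every coordinate in the package is GTF-native: 1-based and inclusive at
both ends. Half-open arithmetic, where convenient, is internal to the
interval routines and never crosses a function boundary. A
`TranscriptModel` is an ordered, non-overlapping exon chain on one strand
of one contig; introns (gaps between consecutive exons) must be at least
1 bp, so a junction is fully described by its donor (last base of the
upstream exon) and acceptor (first base of the downstream exon). The GTF
writer serializes attributes as `gene_id`, `transcript_id`, then the
remaining keys alphabetically, and orders records by (chromosome, start,
transcript id); this makes write→read→write a byte-level fixed point,
which the tests rely on. Abundance is read from the Cufflinks-style
`FPKM` attribute; an assembled transcript without one gets 0 with a
warning, since assemblers other than Cufflinks may omit it.

## Merging assemblies across samples

Two multi-exon transcripts are the same structure exactly when their
intron chains match on the same chromosome and strand; terminal exon ends
are allowed to differ (assembly endpoints are coverage-dependent) and are
merged to the union. Single-exon transcripts have no chain, so the rule
degrades to same-strand overlap of at least 1 bp, applied transitively
(`IRanges::reduce`); the merged exon is the union span. Sample presence —
which samples contributed a structure — is the quantity the single-exon
filter consumes, so it is recorded on every merged transcript. Merged
transcripts are regrouped into loci by same-strand span overlap and
renamed `XLOC_nnnnnn` / `TMERGE_nnnnnn` in genomic order, which makes the
merge invariant to sample order (a property the tests check directly).

## Classification against the reference

Five class codes are assigned with fixed precedence: `equal` (identical
intron chain), `novel_isoform` (at least one shared intron), `intronic`
(whole span inside one intron of a same-strand transcript), `antisense`
(exonic overlap only with opposite-strand genes), `intergenic` (no exonic
overlap). Two cases needed decisions the code alphabet itself does not
make:

* *Same-strand exonic overlap without a shared intron* (for example a
  single-exon fragment inside an exon). The five codes must partition all
  inputs, and such a transcript overlaps an annotated same-strand gene,
  so it is assigned `novel_isoform` after the `intronic` check. The
  brute-force oracle used in the property tests restates the same
  completed rule independently.
* *Single-exon `equal`*: empty chains compare equal everywhere, so for
  single-exon transcripts `equal` additionally requires same-strand
  overlap with a single-exon reference transcript.

`matched_gene_id` is the gene with the largest exonic overlap (ties to
the lexicographically smallest id) and is `NA` exactly for `intergenic`.

## Filtering

Anything containing a splice junction is kept unconditionally: a junction
is strong evidence the fragment is a processed transcript. A single-exon
transcript survives only when present in a *strict* majority of samples
(`n_present > majority_fraction × n_samples`, default fraction 0.5):
"majority" is read conservatively, so exactly half fails, and ties are
flagged in the filter report (`single_exon_tie_minority`). Presence is
counted over all samples, not per experimental group; a per-group reading
would require group labels the assembly stage does not carry. Single-exon
transcripts classified `intronic` are removed regardless of presence, as
likely pre-mRNA fragments; multi-exon intronic transcripts are retained
but visible in the classification report.

The coverage filter keeps a locus when its total read count across
samples is at least `min_locus_reads` (default 10, inclusive) and its
maximum per-sample FPKM is at least `min_fpkm` (default 0). Ten total
reads is deliberately permissive — the point is to exclude loci where
dispersion estimation is meaningless, not to call expression — and both
thresholds are configuration, not constants. Both filters are subset
operations and idempotent, which the property suite verifies on 200
random inputs.

## Coding potential and noncoding subtypes

The discovery rule is the classical longest-ORF proxy: a locus with at
least one isoform containing an ATG-initiated, stop-terminated reading
frame of ≥ `min_orf_codons` codons (default 100, ~300 nt, the
conventional lncRNA cutoff) is a `novel_coding_candidate` and is not
called noncoding. Only the three sense-strand frames of the spliced
sequence are scanned — assembled transcripts are stranded, and the
antisense frames belong to a different (hypothetical) transcript. Codons
containing `N` break a reading frame without terminating it: an ORF
interrupted by ambiguity is not credited with a stop, which is the
conservative direction. ORF length is counted from the start codon up to
and excluding the stop; ties break to the smaller start offset, then the
lower frame. A per-transcript plug-in (`coding_calls`) lets an external
sequence-intrinsic classifier override the ORF rule where its output is
available, so the built-in rule is a default, not a ceiling.

Noncoding loci subtype by their class codes: any `antisense` isoform
makes the locus a `novel_antisense`; otherwise it is a `novel_lincRNA`.
Novel loci receive `NOVEL_LOC_%06d` identifiers in (chromosome, start)
order; annotated loci inherit gene id, name and `gene_biotype` from the
matched reference gene (preferring an `equal` match over `novel_isoform`),
with `"unknown"` and a warning when the reference carries no biotype.

## Primer targets

qPCR validation primers should amplify cDNA but not genomic DNA, hence
the preference for a splice junction present in *all* isoforms of the
gene. When several junctions qualify, the one maximizing the minimum
exonic flank available in every isoform is chosen: both primers must sit
in sequence present in every isoform, and only the exons immediately
adjacent to the junction are guaranteed shared, so the flank on each side
is capped by the shortest such exon across isoforms (and by `flank`,
default 150 bp per side — typical qPCR amplicons of 60–200 bp fit
comfortably). Remaining ties go to the genomically first junction. With
no common junction, the fallback is the longest exonic interval common to
all isoforms, required to be ≥ 40 bp so that two ~20-mers fit; below
that, a design failure is reported, not raised. Templates are always in
transcript orientation; `junction_pos` is the 0-based offset of the first
base after the junction.

The primer picker is a small deterministic engine: candidates of 18–24 nt
are screened on GC fraction (0.35–0.65), a consensus melting-temperature
formula (64.9 + 41·(GC − 16.4)/len, accepted range 55–65 °C),
homopolymer runs (≤ 4) and a 3' G/C clamp; pairs are scored on distance
from the 60 °C optimum, Tm balance and distance from a 120 bp product
optimum, under the hard constraint that for junction templates the left
primer ends strictly before `junction_pos` and the right primer starts
strictly after it. All engine parameters are overridable through the
`params` map. Primer thermodynamics beyond this screen, and genome-wide
specificity checking, are intentionally out of scope — in practice those
are validated by melting curves and gels.

## Read preparation

The trimmer implements standard 3'-adapter semantics: the read is
truncated at the leftmost position where the full adapter matches, or
where a prefix of the adapter of at least `min_overlap` bases (default 3)
matches the read's 3' end, allowing a mismatch fraction up to
`max_mismatch_rate` (default 0.1) of the aligned length. With the error
rate at 0 this reduces to naive exact search, which is how the property
suite checks it. The 3-base minimum overlap trades a small rate of
spurious 3-mer trims for sensitivity at read ends, matching common
practice.

Insert-size bookkeeping treats the adapter length as a constant:
`insert_mean = fragment_mean − 2·adapter_len`, with the standard
deviation passed through unchanged (no variance model is justified by the
inputs). Because "insert" is used ambiguously in the field, the mate
inner distance (`insert_mean − 2·read_len`) is emitted alongside; it is
legitimately negative for overlapping mates.

## DE unification and concordance

The three upstream dialects are mapped onto one record shape; adjusted p
values are taken as emitted (q_value / FDR / padj) and never recomputed —
this package formats results, it does not re-test. A missing adjusted p
value becomes 1.0 with an `fdr_imputed` flag, which keeps such genes out
of any FDR cut without silently dropping rows. All three dialects emit
log2 fold changes, which are passed through unchanged. The DE-only locus
set uses `fdr < alpha` with α = 0.05 by default, the conventional choice.

Concordance between two fold-change series is the Pearson correlation
`r`, its square R² (the coefficient of determination), and the fraction
of sign-concordant pairs with zero counted as positive. Infinite fold
changes (zero counts in one condition) are excluded pairwise with a
warning, since Pearson correlation is undefined on them. R² is invariant
under positive affine maps of either series, so it compares shape, not
scale — which is also why the bundled rat liver dataset, whose qRT-PCR
column is on a visibly different fold-change scale than its RNA-seq
columns, still has interpretable sign agreement but is not used for
cross-method R² checks. On the bundled human and mouse sets, the
human/DESeq2 column contains one gene (ID2) whose RNA-seq and qRT-PCR
directions disagree as published; the package reports the sign agreement
it computes (5/6) rather than the idealized 1.0.

## The synthetic fixture

`make_fixture()` emulates the shape of the inputs, not their content:

* a uniform-random genome, with features laid out on a fixed grid of
  4 kb slots so placement can never collide (an infeasible request fails
  fast instead of retrying);
* reference genes of three exons (every second gene with a two-exon
  second isoform, giving primer design a shared junction), with cycling
  biotypes;
* planted intergenic lincRNA loci, antisense loci overlapping reference
  exons on the opposite strand, minority single-exon noise, and one
  coding locus whose ORF is built by sampling non-stop codons so its
  length is exact (default 120 codons);
* every planted noncoding feature totals < 303 spliced bases, so a
  100-codon ORF is impossible in it *by construction* rather than by
  post-hoc checking;
* reads with the adapter appended to a known 30 % of records, flagged in
  the FASTQ headers;
* DE tables in all three dialects, including one `NA` padj row.

Defaults (4 samples, 8 reference genes, 3 lincRNA + 5 antisense planted
loci, noise in 1 of 4 samples) mirror the scale of a small validation
study: a handful of samples per group and single-digit counts of
novel noncoding loci per dataset. One PRNG stream keyed by `seed` governs
everything, so a configuration reproduces byte-identical files.

What passing the end-to-end tests shows: the merge, classification,
filtering and discovery rules compose correctly and recover planted
structures exactly, including under minority noise. What it does not
show: performance on real assemblies — random sequence has no codon
structure, no repeats, no coverage-dependent fragmentation, and planted
exact copies are an easier merge problem than Cufflinks output across
biological replicates. Conclusions about real-data sensitivity or
specificity must come from wet-lab validation, not from these fixtures.

## Problem sizes and runtime

The shipped tests run the property suites at: 200 random filter inputs,
brute-force classification on instances of up to 50 transcripts, 100
random sequences up to 3 kb for the ORF oracle, 150 random reads for the
trimmer oracle, and end-to-end fixtures with the default configuration
(~22 planted features). These sizes were chosen so each suite exercises
the combinatorics (multiple chromosomes, strands, tie cases, N bases)
while the whole suite stays around a minute on one core.

## Known limitations

* The longest-ORF rule is a proxy for coding potential; it has no notion
  of codon usage, conservation or peptide evidence, so counts of novel
  coding candidates on real data depend strongly on the threshold. The
  `coding_calls` plug-in exists precisely to replace it.
* Class codes are a five-letter reduction sufficient for the downstream
  decisions (annotated vs novel, noncoding subtype); they are not a
  re-implementation of the full Cuffcompare alphabet.
* The primer engine screens composition and Tm only; it does not model
  dimers, hairpins or off-target amplification.
* Quality-based trimming and paired-end adapter read-through detection
  are out of scope for the trimmer.
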