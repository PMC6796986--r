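---
title: "Methods: base-editor guide design and quantification for exon skipping"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: base-editor guide design and quantification for exon skipping}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(skipedit)
```

## The biological model

Splicing of an internal (inner) exon requires an intact splice acceptor: the
intron 3' end terminates in a near-invariant AG dinucleotide immediately
upstream of the exon. Point-mutating either base of that AG prevents
recognition by the spliceosome and causes the exon to be skipped from the
mature transcript. Base editors make this mutation without a double-strand
break:

* an **adenine base editor (ABE)** converts the conserved acceptor **A** to
  G when a guide RNA places it inside the editor's active window on the
  transcript sense strand;
* a **cytidine base editor (BE3)** attacks the conserved acceptor **G**
  indirectly, by converting the complementary **C** on the antisense strand
  (C>T on the antisense strand is G>A on the sense strand).

Both editors are SpCas9 fusions and require an NGG PAM immediately 3' of the
20-nt protospacer. We number protospacer positions 1 (PAM-distal) to 20
(PAM-proximal), with the PAM at 21–23; the editing window is a small set of
positions in the PAM-distal half (defaults: 4–9 for ABE, 4–8 for BE3). For
each canonical acceptor, `find_protospacers()` tests every window position
`p`: a candidate guide exists iff the 20-mer placing the target base at `p`
is followed by NGG and contains no `N`. ABE guides are searched only on the
transcript sense strand (where the acceptor adenine reads as `A`); BE3
guides only on the antisense strand (where the conserved guanine reads as
`C`). Non-canonical acceptors (dinucleotide ≠ AG) are flagged by
`check_acceptors()` and excluded from design rather than silently dropped
from the exon table, so they remain auditable.

### Coordinates

All coordinates in the package are 1-based inclusive, the GTF/Bioconductor
convention, so values flow unchanged between `rtracklayer`, `Biostrings`,
`Rsamtools` and our tables. Acceptor positions follow from the exon bounds:
on `+` the conserved G is at `start - 1` and the A at `start - 2`; on `-`
the G is at `end + 1` and the A at `end + 2`, read in transcript
orientation. An exon region counts as *inner* when it is non-terminal in at
least one transcript; regions are deduplicated by
`(contig, start, end, strand)` and the supporting transcripts recorded.

## Predicted editing efficiency

Editing efficiency depends strongly on the window position of the target
base. The package models this as a per-position table of relative
efficiencies scaled by a maximum absolute efficiency (percent);
positions outside the window predict 0. The shipped defaults
(`inst/extdata/efficiency_tables.json`: ABE window 4–9 peaking at 60% for
position 6; BE3 window 4–8 peaking at 50% at position 5) are placeholder
estimates of published editor behaviour, deliberately stored as an editable
JSON config: users with editor- and cell-type-specific calibration data
should substitute their own values. All results that depend on absolute
efficiencies (threshold filtering, ABE-vs-BE3 comparisons) inherit this
caveat.

Filtering semantics are asymmetric on purpose: a guide survives when its
predicted efficiency is **strictly above** the efficiency threshold
(default 30%) and its off-target score is **at most** the off-target cap
(default 10; guides scoring above 10 are removed). The boundary cases —
efficiency exactly 30 excluded, score exactly 10 retained — are fixed
behaviour, covered by tests.

## Off-target model

For each guide, `enumerate_offtargets()` scans both strands of every contig
for 20-mers within 2 mismatches (Hamming distance; no bulges) of the
protospacer that sit next to an NGG PAM (NAG optionally). The candidate
search runs through `Biostrings::matchPattern(max.mismatch = )`; the test
suite cross-checks it against an independent brute-force Hamming scan on
every fixture genome. Mismatches are counted on the 20-nt protospacer only —
the PAM is matched by rule, never counted.

Each hit is scored with the standard position-weighted scheme: a perfect
match scores 100, and a hit with mismatches at positions `p` scores

$$ 100 \prod_p (1 - w_p) \times \frac{1}{((19 - \bar d)/19)\cdot 4 + 1}
   \times \frac{1}{m^2}, $$

where \(w_p\) are the 20 position-specific penalty weights (PAM-proximal
mismatches weigh more), \(\bar d\) the mean pairwise distance between
mismatch positions, and \(m\) the mismatch count; single-mismatch hits take
distance and count terms of 1. The weight vector and constants ship as
editable config (`inst/extdata/offtarget_weights.json`). A guide's
aggregate off-target score is the **sum** of hit scores over all sites other
than the design locus, so lower means more specific: a perfect duplicate of
the protospacer elsewhere contributes 100 by itself and immediately fails
the ≤10 cap, while a guide with no near-matches scores 0. If the design
locus itself is missing from the scan the function errors, since that
indicates a scan/locus inconsistency rather than a clean guide.

## Genome-wide editor comparison

`targetability_records()` condenses scored candidates to one row per inner
exon: the best efficiency among guides passing the off-target cap, the best
(lowest) off-target score among guides passing the efficiency floor, and a
targetable flag for each mode. From these,

* `cumulative_by_efficiency()` counts exons with at least one guide at or
  above each efficiency threshold (non-increasing curve),
* `cumulative_by_offtarget()` counts exons with at least one guide at or
  below each score threshold (non-decreasing curve),
* `overlap_report()` compares the two editors on exons targetable by both:
  how often ABE's best guide has strictly higher predicted efficiency, and
  strictly lower off-target score, than BE3's.

Ties are reported in their own buckets rather than assigned to either
editor, so the three buckets always sum to the both-targetable count;
published analyses of this kind report only the "higher"/"lower" fractions
and do not state how ties were resolved, and we prefer not to inflate either
side. Curves are evaluated on explicit threshold grids (defaults: efficiency
0–100 by 1; off-target 0–20 by 0.5).

## Amplicon editing quantification

The treated-sample workflow mirrors standard amplicon deep sequencing
practice:

1. **Demultiplexing** assigns a read pair to the unique amplicon whose
   forward/reverse primers prefix-match mate 1/mate 2 with at most 1
   mismatch each; ambiguous or unmatched pairs land in an `unassigned` bin.
2. **Trimming** removes 3' bases below Phred 20; any pair with a mate
   trimmed to 50 bp or less is discarded (exactly 50 discards, 51 keeps).
3. **Pileup** tallies per-position allele depths over a 120-bp window
   centered on the protospacer midpoint (`Rsamtools::pileup` on the
   coordinate-sorted alignments; bases below Q20 ignored; deletions and
   reference skips do not count toward depth).
4. **Error background**: the global estimate is the unweighted mean
   alternative-allele fraction across covered window positions *excluding
   the candidate edited positions* — at 50% editing, including the target
   would absorb the signal into the null. A position-dependent estimate is
   taken from an untreated control pileup when one is provided; estimating
   it from the treated sample at the edited position would do the same.
   Without a control, only the global estimate is used.
5. **Calling**: for a target with depth \(n\) and conversion-matched
   alternative depth \(k\) (G over an A reference, C over T), the
   background is \(p_0 = \max(\text{global}, \text{positional})\) and the
   one-sided exact binomial tail \(P(X \ge k)\), \(X \sim
   \mathrm{Bin}(n, p_0)\), is compared to the \(10^{-5}\) cutoff. No normal
   approximation is used; in the small-\(p_0\) regime it is both inaccurate
   and unnecessary. The editing rate \(k/n\) is reported regardless of
   significance; zero-depth targets yield an undefined rate and no call.

Alignment itself is upstream of the package: SAM input is consumed
(converted with `Rsamtools::asBam`), and the fixture generator emits
pre-aligned SAM so no aligner enters the test path.

## Exon-skipping quantification

RNA reads are classified by splice junction against three probe sequences
built from transcript-orientation exon sequence with a 10-bp anchor on each
side (configurable): the exon-skipped junction (upstream exon 3' end joined
to downstream exon 5' start) and the two canonical junctions
(upstream→target, target→downstream). A read containing the skipped probe
in either orientation counts as skipped, a read containing a canonical probe
as canonical, reads containing both are ambiguous and excluded, and reads
containing neither are excluded. Matching is exact substring by default
(field practice does not state a mismatch tolerance for this step;
a `max_mismatches` argument is provided). Mates are treated as independent
single reads, so a pair spanning a junction in both mates contributes two
counts. The skipping rate is `skipped / (skipped + canonical)`; biological
replicates are combined by an unweighted mean, with undefined replicates
(no junction reads) dropped with a warning. Anchors too short to distinguish
the skipped from a canonical probe are a hard error, not a silent
misclassification. From gel densitometry, percent skipping is
`100 * skipped / (wt + skipped)` over background-subtracted band
intensities.

## The synthetic-data generator

`fixture_spec()` / `make_toy_genome()` build deterministic toy genomes whose
background sequence contains **no GG or CC dinucleotide**: scrubbing
homotypic pairs removes every NGG PAM from both strands, so the only PAMs
are the ones planted on purpose, and the planted guide set is provably the
complete candidate set (tests confirm this by brute force). Each gene
(default: 6 genes, alternating strands, 4 exons of 80 bp, introns of 120 bp)
receives a canonical `AG` acceptor before every non-first exon; for inner
exons a PAM is planted so the acceptor target base sits at a requested
window position — an NGG inside the exon for ABE, a CC on the sense strand
in the intron (an NGG on the antisense strand) for BE3 — with guard bases on
both sides so shifted PAM readings cannot create unplanted candidates.
Near-match copies of chosen guides can be planted on a separate decoy contig
for off-target tests.

`simulate_amplicon_reads()` draws fragments of a fixed 201-bp amplicon in
which a fraction `editing_rate` carry the conversion at the target, then
substitutes every emitted base with probability `sequencing_error`,
uniformly over the three alternatives — so the expected conversion-matched
error component is ε/3, giving a closed-form recovery target of
\(e + (1-e)\,\varepsilon/3\). Alignments are emitted directly as
coordinate-sorted SAM at known positions, and the truth table records the
exact per-position base composition, so the pileup can be checked for exact
equality. `simulate_rna_reads()` mixes junction-spanning reads from the
skipped isoform (probability `skip_fraction`) and the canonical isoform,
plus exon-interior background reads that a correct classifier must exclude;
half of all reads are reverse-complemented.

Defaults emulate a focused amplicon experiment: per-base error 0.002,
depth 1000 fragments, read length 150, 2000 junction reads plus 500
background reads. One integer seed drives everything; each generator
function uses its own documented stream (`seed`, `seed + 1`, `seed + 2` for
genome, amplicon and RNA reads) and fixed seeds give byte-identical output
files. The generator does **not** emulate quality-dependent or
context-dependent error profiles, indels, PCR duplicates or expression
variation; passing tests therefore demonstrate correctness of the counting
and testing machinery on idealized reads, not robustness to real-world
artefacts.

## Statistical checks and their design

Most correctness tests are exact: oracle equivalence for guide design and
off-target enumeration, conservation identities, boundary semantics,
byte-identical determinism. Two checks are stochastic, both seeded:

* **Caller calibration.** At background 0.002 and depth 500, the number of
  significant calls among 10^5 simulated null positions is compared with the
  exact binomial-tail expectation (the smallest k crossing the cutoff has
  tail probability just below 10^-5, so about one call is expected); power
  at 5% true editing and depth 500 must reach 99%.
* **Rate recovery.** Over a 10-seed panel and editing rates
  {1, 5, 20, 50}%, each dataset's pipeline estimate is required to lie
  within 3 binomial standard errors of the rate the generator *actually
  planted* in that dataset (recorded in its truth table, error-adjusted),
  which isolates pipeline recovery from the generator's own binomial draw;
  calibration against the nominal \(e + (1-e)\varepsilon/3\) is then
  asserted on the panel mean with the correspondingly tighter
  \(3/\sqrt{40}\) z-bound. A per-dataset comparison against the nominal rate
  would fail a correct pipeline in roughly one panel in ten purely through
  the generator's sampling noise.

Problem sizes were chosen so the whole suite runs in well under a minute per
module on a single CPU: toy genomes of ~5–15 kb with 12–24 inner exons,
amplicon depths of 200–1000 fragments, 2000 junction reads. These are the
scales at which every planted event is still individually verifiable by
brute force.

## Known limitations

* Efficiency tables are placeholders; absolute targetability counts and
  ABE-vs-BE3 fractions move with them. The machinery (thresholding, curves,
  overlap) is exact for whatever table is supplied.
* Off-target search is Hamming-only (no DNA/RNA bulges) and NGG/NAG-only;
  empirical activity models are out of scope.
* Junction classification handles the two-isoform (canonical vs single-exon
  skip) model only; multi-exon skips and alternative acceptors are not
  deconvolved.
* Indel quantification and chromatin- or sequence-context efficiency models
  are deliberately out of scope.
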