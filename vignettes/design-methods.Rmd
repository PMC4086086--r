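---
title: "Methods: target discovery, off-target search and genotyping design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: target discovery, off-target search and genotyping design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cutdesign)
```

This vignette records how `cutdesign` models the biology, which knobs
matter, and the numerical and design choices behind the implementation —
in enough detail that a reader can judge what a passing test suite does
and does not establish.

## Target-site models

**CRISPR/Cas9.** A candidate site is a 23 bp window: a 20 bp protospacer
followed by the protospacer-adjacent motif -NGG (one free base, two
invariant guanines). Both strands are scanned; a site's genomic
coordinate is always the plus-strand start of its 23 bp footprint, and
sequences are reported 5'→3' in site orientation. Protospacer positions
are numbered 1–20 from the 5' end, so position 20 is PAM-adjacent; the
"G20" ranking feature refers to that base. Overlapping candidates are
all reported — suppression is applied only to TALEN pairs, where
near-identical designs are genuinely redundant. Windows containing N are
rejected at discovery: an ambiguous base can be neither targeted nor
synthesized. Optional 5' constraints (`GG`, `GN_or_NG`) restrict the
protospacer's first two bases to what T7 or U6 transcription requires.

**TALEN.** A monomer site is a window of configurable length (default
15 bp, the typical footprint of commercial assembly kits; the range
10–30 bp is accepted) that begins with T on its strand — the anchoring
requirement of the TALE N-terminal domain. A design is a pair: a
plus-strand monomer and a minus-strand monomer whose footprints face
each other across a spacer of 14–20 bp (configurable), the geometry FokI
needs to dimerize and cut. The RVD string encodes positions 2..L of the
monomer; the invariant 5' T is recognized by the protein N-terminus, not
by a repeat, and is therefore not RVD-encoded. Guanine may be encoded as
NN (default) or as the more specific NH, a per-kit choice.

## Off-target search

Every candidate is searched against the *whole* genome, not just the
query region. Three CRISPR mismatch models are provided:

* `all_upstream` (default): up to `max_mm` mismatches anywhere in the
  protospacer. The default `max_mm = 2` matches the 0/1/2-mismatch
  tallies in the results table; the implementation accepts 0–3.
* `seed_exact`: the 11 PAM-proximal positions (10–20) must match
  exactly — a single mismatch there abolishes cleavage — with up to
  `max_mm` mismatches tolerated in positions 1–9 only.
* `perfect_only`: exact protospacer matches, a fast screening mode.

In every mode the PAM must match NGG at the hit locus; NAG-tolerant
matching is deliberately not counted (a configuration hook exists but is
off and untested). TALEN monomers are searched with 0–2 mismatches
(default 2) and every reported locus must itself begin with T on the hit
strand: a copy that has lost the 5' T cannot be bound, so we enforce the
rule at off-target loci as well. Paired TALEN off-targets are all
opposite-strand hit combinations — drawn from the union of both
monomers' hit lists, since FokI does not care which arm binds where —
whose gap lies in the configured spacer range, excluding the on-target
pair. Genomic N never matches anything (N is not a wildcard), and the
candidate's own locus is returned flagged `is_self` and excluded from
all tallies.

**Index.** The search is seed-and-extend over a k-mer position index of
both strands. For a query of length L at mismatch budget m we use m+1
*disjoint* seeds of length k = ⌊L/(m+1)⌋: by pigeonhole, m mismatches
cannot intersect all m+1 seeds, so every true hit is generated by at
least one exact seed lookup, then verified base-by-base under the mode
predicate. This gives k = 6 for 20 bp protospacers at 2 mismatches and
k = 5 for 15 bp monomers; `build_index()` therefore accepts k down to 4.
(Larger k would be faster but unsound at these query lengths: three
disjoint 8-mers do not fit in 20 bp.) The exhaustive sweep
`brute_force_offtargets()` implements the same predicates with no index
and no seeding, as an independent path; the tests assert exact hit-set
equality between the two on random multi-chromosome genomes in all
modes (200 candidates × 3 modes in the widest test).

## Ranking

The ranking key is strictly lexicographic, in the stated priority order,
with no weights — the criteria are ordinal in the source methodology and
invented weights would only manufacture false precision:

1. ascending count of perfect (0-mismatch) off-targets, then 1-mismatch,
   then 2-mismatch counts — a perfect off-target is the worst outcome;
2. (CRISPR) GC content inside the 45–80% window, bounds inclusive,
   treated as a binary flag — the evidence supports a range, not a
   graded curve;
3. (CRISPR) guanine at protospacer position 20;
4. distance from the transcript 5' end (strand-aware when a gene model
   is supplied, else from the region start) — 5' lesions are likelier to
   produce null alleles;
5. deterministic tie-breaks: plus-strand coordinate, then strand.

For TALENs the paired off-target count dominates the summed monomer
tallies (cutting requires a pair). Ranked TALEN pairs are then clustered:
two pairs whose combined footprints reciprocally overlap ≥ 80% are
considered the same design (e.g. differing only in spacer size), the
highest-ranked member represents the cluster in the summary table, and
all members remain in the detail output. The 80% threshold is this
package's operationalization of "equivalent"; the source describes the
behaviour without a number.

## Genotyping aids

**Primers.** Candidate primers are enumerated exhaustively — every
(start × length) placement on each side of an exclusion zone of
`min_dist` (default 50 bp) around the predicted cut site (Cas9 cuts
~3 bp 5' of the PAM; TALENs in the spacer middle), so the amplicon
always spans the cut. Defaults: length 18–25 bp (optimum 22), product
150–290 bp, Tm 57–63 °C (optimum 60 °C). Melting temperatures use the
unified nearest-neighbor parameter set (SantaLucia 1998) with the
entropic salt correction 0.368·(N−1)·ln[Na+] at 50 mM monovalent salt
and 50 nM oligo with the C_T/4 divisor (C_T/1 and the symmetry entropy
term for self-complementary sequences). Pairs are scored by the penalty
|Tm_l−60| + |Tm_r−60| + 0.2·(|len_l−22| + |len_r−22|) and the best
`max_pairs` (default 10) are emitted. Specificity ranking then maps each
primer genome-wide (exact matches, enumeration capped at 10 per primer)
and counts *off-products*: loci other than the target where a left-primer
hit and a right-primer hit converge within 1.5× the maximum product
size — our operationalization of "off-targets producing amplicons of
similar length". Order: off-products, then total hit count, then design
penalty. Hairpin/dimer structure is out of scope.

**Restriction sites.** Recognition sequences are IUPAC-degenerate and
matched on both strands (palindromes reported once, on the plus strand);
enzymes with sites shorter than `min_site_len` (default 4) are dropped.
A site is flagged unique when its enzyme cuts exactly once in the
displayed region. For TALEN pairs, sites fully contained in the spacer
are listed per design — a cut there is destroyed by repair indels. A
built-in table of ~35 common enzymes with supplier tags ships with the
package; users may load their own TSV.

## Synthetic fixtures

`synth_genome()` draws a seeded random background (default uniform base
composition; GC skew configurable) and writes *plants* — sites, decoy
copies with chosen mismatch edits, TALEN pairs, verbatim sequences — at
fixed positions, erroring on overlap. The background is then verified by
brute force to contain no accidental near-match (≤ 2 mismatches, with
the required PAM or 5'-T context) of any planted protospacer or monomer,
resampling if needed, so the truth table is exact rather than merely
probable. This emulates what matters for correctness testing — known
on-/off-target structure on a clean background — and deliberately not
the repeat structure, isochores or karyotype of real genomes; passing
tests demonstrate algorithmic correctness, not calibrated genome-wide
off-target *rates* for any real organism. Test problem sizes (genomes of
8–60 kb, regions of 0.3–4.5 kb, up to 200 candidates per equivalence
sweep, a 50-locus primer battery) were chosen so the exhaustive oracles
stay exact while the full suite runs in well under a minute per file.

## Numerical and interface conventions

Internal coordinates are 0-based half-open everywhere; every printed
coordinate (TSV, GenBank, query strings) is 1-based inclusive. Gene-name
queries with several transcripts use the longest by exonic length, with
a message. Splice-site sub-regions are ±20 bp windows around each
intron/exon boundary (the filter is named in the source without a
width). Raw pasted sequences become a synthetic `query` sequence that is
added to the search universe, so a pasted copy of a genomic locus
correctly reports its genomic twin as a perfect off-target. All pipeline
stages are deterministic — identical configuration and inputs produce
byte-identical reports, which the suite checks at the byte level.

## Known limitations

No gapped/bulged off-target alignment; no learned on-target efficiency
scores; no NAG-PAM accounting by default; no primer secondary-structure
screening; single-genome (no alt-contig awareness); TALEN pairing
assumes a homodimer-compatible FokI (obligate-heterodimer geometry is
not modelled beyond left/right identity).
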