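# cutdesign

Offline design of CRISPR/Cas9 and TALEN genome-editing reagents, with
rigorous off-target enumeration and integrated genotyping aids, against a
locally supplied genome (FASTA) and gene models (refFlat or BED12). No
network access, external aligner or external primer designer is required.

## What it does

Selecting a good editing target means satisfying the nuclease's sequence
requirements while avoiding similar sequences elsewhere in the genome.
`cutdesign` addresses both halves of that problem for the two classical
systems:

* **CRISPR/Cas9.** Candidate sites are 23 bp: a 20 bp protospacer followed
  by the -NGG protospacer-adjacent motif (PAM). The search can be
  restricted to guides synthesizable with a given polymerase (5' GG- for
  T7, 5' GN-/NG- for U6). Off-targets are enumerated genome-wide under
  three mismatch models: up to `max_mm` mismatches anywhere in the
  protospacer (default, `max_mm = 2`); mismatches confined to the
  PAM-distal positions 1–9, because a single mismatch in the 11
  PAM-proximal bases abolishes cleavage (`seed_exact`); or perfect matches
  only. The PAM must match NGG at every reported locus.
* **TALEN.** Candidate designs are pairs of monomer binding sites on
  opposite strands, each beginning with the 5' thymine required by the
  TALE N-terminus, separated by a 14–20 bp spacer across which FokI
  dimerizes and cuts. Each monomer is searched genome-wide with 0–2
  mismatches (default 2), and *paired* off-targets — loci where both
  monomers land at cutting distance — are counted separately, since only
  those can be cleaved. The repeat-variable di-residue (RVD) string to
  synthesize is emitted per monomer (NI=A, HD=C, NG=T, NN or NH=G).

Candidates are ranked lexicographically by the number of perfect
off-targets, then 1- and 2-mismatch off-targets (for TALENs: paired
off-targets first, then monomer tallies), then — for CRISPR — GC content
inside the effective 45–80% window and a guanine at protospacer position
20 (PAM-adjacent), and finally proximity to the transcript 5' end.

The off-target engine is a k-mer seed index with seed-and-extend
verification: a query of length L searched with up to m mismatches uses
m+1 disjoint seeds of length ⌊L/(m+1)⌋, so by pigeonhole no hit can evade
every seed. An exhaustive brute-force sweep (`brute_force_offtargets()`)
is included and the test suite asserts exact hit-set equality between the
two paths.

For genotyping, the package exhaustively enumerates PCR primer pairs
spanning the predicted cut site (defaults: primers 18–25 bp, optimum 22;
product 150–290 bp; Tm 57–63 °C by unified nearest-neighbor
thermodynamics, optimum 60 °C; ≥ 50 bp between primer and cut), maps each
primer genome-wide and ranks pairs by the number of unintended convergent
amplicons. Restriction sites (IUPAC-degenerate recognition) are mapped
and flagged when unique in the region; for TALENs, enzymes cutting inside
the spacer are reported as direct mutation probes.

## Worked example

All fixtures are generated in code — no downloads:

```r
library(cutdesign)

fix    <- synth_genome(plant_spec(15000, seed = 42, plants = list(
            plant_crispr_site(5100, "+", id = "site"))))
models <- synth_gene_table(fix$genome, 2, seed = 42)
paths  <- write_fixture(fix$genome, models, fix$truth, "demo")

run_cli(c("--query", "gene1", "--genome", paths$fasta,
          "--gene-table", paths$gene_table,
          "--mode", "crispr", "--out", "demo/out"))
```

`demo/out/results.tsv` begins:

```
rank  target_seq               chrom  start_1based  strand  exon  gc_percent  mm0  mm1  mm2
1     AACGCACCCCTCTTATAGCGAGG  chrS   166           +       1     55          0    0    0
2     CGCAACCCTCGCTATAAGAGGGG  chrS   172           -       1     55          0    0    0
3     ATCGCAACCCTCGCTATAAGAGG  chrS   174           -       1     50          0    0    0
```

Each row is one 23 bp candidate site (protospacer + PAM, written 5'→3' in
site orientation). Rank 1 has no off-target occurrence at 0, 1 or 2
mismatches (`mm0`–`mm2` all zero), GC content inside the 45–80% window,
and sits in exon 1 near the transcript 5' end — the preferred place for a
frameshift. `demo/out/primers.tsv` holds the specificity-ranked
genotyping primers for that site:

```
rank  left_seq                right_seq              tm_left  tm_right  product_size  off_products
1     CGCTCGTCTCGTATCCCGTCCA  GCCCCCCTGCTGTTGTGATCG  60.18    60.05     210           0
```

a 210 bp amplicon across the predicted cut, both primers within 0.2 °C of
the 60 °C optimum and no unintended convergent amplicon elsewhere
(`off_products = 0`). The directory also contains `offtargets.tsv` (every
off-target hit with its mismatch count and positions), a region GenBank
file annotated with targets/primers/restriction sites, and
`restriction_sites.tsv`. `--mode talen` produces the analogous TALEN
table with RVD strings and spacer enzymes.

The same pipelines are available programmatically via
`crispr_pipeline()` / `talen_pipeline()`, and a shell wrapper is
installed as `exec/cutdesign`.

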