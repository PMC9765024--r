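# siteseer

Functional-residue annotation transfer and visualization for protein
sequences and families.

A protein's function usually hinges on a handful of residues — catalytic
side chains, metal and ligand binding sites, modified positions — yet most
annotation pipelines ignore them. `siteseer` helps a sequence analyst
answer two questions offline:

1. **Which homologs of my protein have experimentally determined
   functional residues, and are those residues conserved in my protein?**
   A database of per-residue annotations is compiled from Swiss-Prot
   feature tables (only features with experimental evidence, ECO:0000269)
   and BioLiP-style structure-derived binding/active-site records,
   deduplicated by exact sequence. A query is compared against it with
   local alignments, and every annotated subject residue is mapped through
   the alignment and labeled `D12 (= D9)` when conserved, `E41 (≠ R38)`
   when substituted, or `(unaligned)`.
2. **How do those residues vary across the family?** Homologs passing the
   usual thresholds (E ≤ 10⁻³, ≥30% identity, ≥70% query coverage) are
   aligned, a neighbor-joining tree is midpoint rooted, known sites are
   transferred onto alignment columns, and the result is drawn as SVG: a
   full view (one glyph per residue, known sites boxed, hover titles) and
   a compact view for hundreds of sequences, where a residue conserved
   across a clade is drawn once and small variant clades show only their
   color (every amino acid has its own color, interpolated within six
   physicochemical group palettes; gaps are gray).

## Methods at a glance

* Local alignment: Smith–Waterman with affine gaps (BLOSUM62, gap open 11,
  extend 1; a gap of length *L* costs 11 + *L*). Bit scores and E-values
  follow Karlin–Altschul statistics, `bits = (λS − ln K)/ln 2`,
  `E = mn·2^(−bits)` with the standard gapped constants λ = 0.267,
  K = 0.041. An importer for BLAST tabular output (`outfmt 6` with
  `qseq`/`sseq`) lets real BLAST hits flow through the same reports.
* Family trees: alignment columns with ≥50% gaps, or with more lowercase
  than uppercase letters (the HMM-aligner convention for non-homologous
  positions), are trimmed before tree inference only; distances are
  Poisson-corrected mismatch fractions `−ln(1 − p)`; classical
  neighbor joining (exact on additive matrices) followed by midpoint
  rooting. Multifurcating trees are supported end to end; uploaded Newick
  trees are used as-is and treated as rooted.
* Pattern search for choosing sites: `NSG`, `CxxC`, `DEA[DH]`-style
  patterns (literal residues, `x` wildcard, bracket classes) across all
  family members, with matches mapped to alignment columns.

## Worked example

Everything below runs offline from generated fixtures:

```r
library(siteseer)
cmd_fixtures(c("--seed", "1", "--n", "6", "--out-dir", "fx"))
cmd_build_db(c("--swissprot", "fx/swissprot.dat",
               "--biolip", "fx/biolip.tsv", "--out", "sites.store"))
cmd_blast_sites(c("--query", "fx/query.faa", "--db", "sites.store",
                  "--format", "text", "--out", "blast.txt"))
```

`blast.txt` then contains:

```
Query: SYN0001 (116 aa)
Hits: 1 (E <= 0.001, max 20)

SYN0001  Synthetic fixture protein 1
  bits=268.5 E=1.28e-76 identity=100.0% q:1-116 s:1-116
  ...
  Sites: G54 (= G54), H92 (= H92), N112 (= N112), Q6 (= Q6), K114 (= K114), ...
```

One hit passed the E ≤ 0.001 cutoff (the query is itself a database
record; the fixture's unrelated proteins score no positive local
alignment). Each `Sites:` entry is one annotated subject residue with its
conservation call — here every site reads `(= …)` because query and
subject are identical. The family view follows the same inputs:

```r
cmd_tree_sites(c("--query", "fx/query.faa", "--db", "sites.store",
                 "--pool", "fx/family.faa", "--out-prefix", "tree"))
```

which writes `tree_full.svg`, `tree_compact.svg` and
`tree_summary.json` (6 family members selected, 9 known-site columns
displayed, anchor-numbered headers from the query).

The same commands are available from a shell via the thin wrapper
installed at `inst/scripts/siteseer`:

```sh
Rscript "$(Rscript -e 'cat(system.file("scripts", "siteseer", package = "siteseer"))')" \
    blast-sites --query fx/query.faa --db sites.store --format text
```

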