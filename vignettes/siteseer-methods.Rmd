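---
title: "siteseer: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{siteseer: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(siteseer)
```

`siteseer` transfers experimentally determined functional residues onto
query proteins and visualizes them across families. This vignette records
the underlying procedures, the parameters that matter, and the design
choices made where more than one defensible option existed.

## The sites database

The database is built from two kinds of records.

**Swiss-Prot feature tables.** Features are admitted by type:
BINDING, CA_BIND, DNA_BIND, METAL and NP_BIND become `binding`; ACT_SITE
becomes `active`; MOTIF, REGION and SITE become `functional_other`;
MUTAGENESIS is kept as its own category (a mutated residue is recorded
whether or not the mutation mattered, so it is weaker evidence than an
active site); CARBOHYD, CHAIN, CONFLICT, CROSSLNK, DISULFID, INIT_MET,
LIPID, MOD_RES, NON_CONS, NON_STD, PEPTIDE, PROPEP, SIGNAL, TRANSIT,
UNSURE, VAR_SEQ and VARIANT become `modified`. Every feature must carry
experimental evidence — an `ECO:0000269` evidence code — or it is
rejected, and `classify_feature()` is total: each input yields either a
category or a machine-readable rejection reason.

VARIANT features whose comment carries no functional information are
excluded. "No functional information" is not a formal grammar, so we
operationalized it: the comment is rejected when it is empty, contains a
dbSNP reference, is a single bare token (a gene or strain name), or is
purely an "in strain …" phrase. A comment that describes a consequence
("L -> P: loss of kinase activity") is kept. This is a deliberately
conservative reading; it can misclassify an unusual comment, and the
parse report counts every rejection so the decision is auditable.

**Ranged features.** Point features keep their single position. DISULFID
and CROSSLNK keep both endpoints — the two bonded residues are the
functional sites, not the span between them. Other spans (REGION, CHAIN,
SIGNAL, …) are expanded residue-by-residue up to 50 positions; longer
spans keep only their endpoints. The cap prevents a single CHAIN feature
from flooding a report with hundreds of uninformative positions; per-residue
sites are the object of interest.

**BioLiP-style records** supply binding residues per (PDB chain, ligand)
plus optional active-site lists, with the chain sequence inline. We index
residues by 1-based position in that sequence. Reconciling PDB author
numbering with sequence numbering is out of scope: rows whose indices
exceed the chain length are rejected with a warning, and a residue letter
that disagrees with the sequence is warned about but the position is
trusted. Nonstandard letters (B, Z, U, O) are mapped to X at parse time.

**Deduplication** is by exact sequence: identical sequences share residue
numbering, so annotations from duplicate records merge onto one surviving
record with positions unchanged. Lookup (`lookup_by_sequence()`)
uppercases and strips gaps first, so an alignment row finds its record.
The store is a single plain-text file holding two tab-separated tables
(proteins, annotations); it is trivially diffable and round-trips exactly.

## Pairwise site transfer

Local alignment is Smith–Waterman with affine gaps under BLOSUM62, gap
open 11 and extend 1 (a gap of length $L$ costs $11 + L$), the standard
protein-search parameterization. The implementation delegates to
`Biostrings::pairwiseAlignment()`; the test suite holds it to exact
agreement with an independently written textbook Gotoh implementation on
hundreds of random pairs. When no positive-scoring local match exists the
hit is empty rather than an error.

Scores become bit scores and E-values through the Karlin–Altschul closed
form, $\mathrm{bits} = (\lambda S - \ln K)/\ln 2$ and
$E = mn\,2^{-\mathrm{bits}}$, with the standard gapped BLOSUM62/11/1
constants $\lambda = 0.267$, $K = 0.041$. Effective-length corrections
are omitted: at the scale this package searches, only the $E \le 0.001$
threshold matters downstream, and the ordering of hits is unaffected.

Reports keep at most one hit per subject (the best by E-value), sort by
ascending E-value with ties broken by descending bit score and then
subject id (a deterministic total order), and truncate to 20 hits by
default. Percent identity counts equal-letter columns over the full
alignment length including gap columns, the convention BLAST reports, so
numbers are comparable with BLAST output. Query coverage is
$(q_{end}-q_{start}+1)/\mathrm{len}(q)$.

Mapping an annotated subject position through the alignment walks to the
column holding that residue: outside the local alignment or opposite a
query gap the site is `unaligned`; otherwise the site is `match` or
`mismatch` by case-insensitive letter equality, with one exception — X
(unknown residue) never matches anything, including another X, because
agreement between two unknowns is not evidence of conservation. Percent
identity, by contrast, uses plain letter equality; it measures alignment
quality, not site conservation. Labels follow the grammar
`D12 (= D9)` / `E41 (≠ R38)` / `K7 (unaligned)`.

## Family analysis

`select_homologs()` pools database records and user sequences, and keeps
candidates with $E \le 0.001$, identity $\ge 30\%$ and query coverage
$\ge 70\%$. The identity floor keeps alignments trustworthy; the coverage
floor avoids domain-only matches acquiring whole-protein site
annotations. The query is always first, duplicates (by exact sequence)
collapse, and the list is capped at `max_seqs = 100` by ascending
E-value — a cap chosen to keep desk-scale alignment and drawing
comfortable; typical interactive use involves a few dozen sequences.

The built-in aligner is progressive: 3-mer shared-fraction distances, a
UPGMA guide tree, and profile–profile global alignment with affine gaps
under BLOSUM62. It is adequate at these identities and scales; for
anything demanding (distant homologs, structure-aware alignment) the
`external-import` backend ingests a user alignment in FASTA, Clustal or
Stockholm format instead, preserving case and both gap characters
(`-`, `.`). Lowercase letters are honored as the aligner convention for
non-homologous (insert-state) positions.

Before tree inference — and only there — columns are trimmed: a column is
dropped when at least half its characters are gaps, or when lowercase
letters outnumber uppercase (a tie keeps the column). Either rule can be
disabled. All display and site mapping use the untrimmed alignment; the
returned column map exists for diagnostics. If trimming empties the
alignment, the error says which toggle to flip.

Distances are Poisson-corrected mismatch fractions, $d = -\ln(1-p)$ over
columns where neither row is gapped; pairs at $p \ge 0.95$ are clamped to
$d = 3.0$ to keep saturated pairs finite (one substitution per site on
average is already beyond the resolution of this correction). A pair with
no shared columns is an error naming the pair. Trees come from classical
neighbor joining (exact on additive matrices; negative branch lengths
clamped to zero) followed by midpoint rooting — the root is placed at the
midpoint of the longest leaf-to-leaf path, which minimizes the maximum
root-to-leaf distance and needs no outgroup. Two-sequence families skip
NJ and get the direct two-leaf tree. Uploaded Newick trees are used
exactly as given and treated as rooted (rerooting is a job for tree
editors); missing branch lengths default to 1.0, and multifurcations are
legal everywhere, including at the root.

Display columns are chosen three ways: `auto` (every column carrying a
known site), explicit anchor positions (numbered in the anchor sequence,
by default the query; `map_anchor_positions()` and its inverse convert
between numbering and columns), or a pattern. Patterns use literal
uppercase residues, lowercase `x` as the any-residue wildcard, and
bracket classes (`DEA[DH]`). Uppercase `X` is deliberately a literal: it
matches only the unknown-residue code, so a stray capital X cannot turn
into a wildcard silently. Matches may overlap and are reported per row
with alignment columns attached.

## Rendering

Every amino acid gets its own color so that variant residues stay visible
in the compact view. Six physicochemical groups — DE, ST, NQKRH, FWY,
GAVLI, PMC — each own a (light, dark) color pair taken from the standard
12-color paired palette, and a group of $k$ residues gets $k$ evenly
spaced interpolations between its endpoints. For the two 5-member groups
the light endpoint is darkened first (the hard-coded constants
`#7EB6D9` and `#E8A95B` replace the palette's light blue and orange);
without that, neighboring colors in a 5-step ramp from a very light
endpoint are hard to tell apart. Gaps are gray; X gets a darker gray.
The scheme is a fixed constant under a snapshot-style test (21 pairwise
distinct colors over the 20 residues plus gap).

The full view draws one glyph per (row, selected column) on its scheme
color, boxes cells carrying known sites, and attaches hover text (SVG
`<title>`) built from the annotation category, ligand and comment.
Per-protein metadata (TSV: `id`, `color`, `description`, `url`) colors
the leaf markers and wraps labels in links. The compact view partitions
each column's leaves into maximal residue-uniform clades, top-down: a
uniform clade is one band, otherwise recursion descends into the
children — so distinct residues are never merged into one band, and a
clade too small for text shows only its color. The residue letter is
drawn once per band when the band is at least 10 drawing units tall
(configurable). Above 30 sequences the compact view drops per-leaf
identifier text. Branches thinner than one drawing unit are drawn at
that minimum so topology stays visible. All output is static SVG 1.1;
interactivity is limited to hover titles and links by design.

## Synthetic study conditions

The fixture generator (`generate_fixture_database()`,
`generate_fixture_family()`) emits a small Swiss-Prot flat file, a
BioLiP-style table and a mutant family, together with the ground-truth
database assembled by its own bookkeeping — so the parse → build pipeline
is checked against an oracle that never runs the parsers. Fixtures
deliberately include: a feature with predicted-only evidence, an excluded
and a retained VARIANT, an unlisted feature type, endpoint and span
ranges, duplicate sequences within and across sources, an out-of-range
BioLiP row, and family members at increasing divergence including one
below the 30% identity floor. Default sizes are 6 Swiss-Prot entries of
60–120 residues with a 6-member family; test oracles run at the scales
they can verify exhaustively (alignments to length 30 against the
textbook aligner, trees to 16 leaves against clade enumeration, 500–1000
randomized cases for site mapping and pattern search).

What the fixtures do **not** emulate: real Swiss-Prot qualifier diversity
(only `/note`, `/ligand`, `/evidence` are generated), PDB author
numbering offsets, alignment ambiguity among near-equal optima in large
families, and database scale. Passing tests therefore demonstrate
correctness of the mechanics — parsing rules, coordinate transfer,
conservation calls, tree operations, rendering counts — not robustness to
every formatting quirk in the wild databases.

## Known limitations

* The built-in aligners are desk-scale; for large or distant families,
  import externally built alignments and trees.
* E-values are comparable within a run but are not BLAST's (no
  composition-based statistics, no effective-length correction).
* BioLiP author-numbering reconciliation is out of scope; fixture and
  store numbering is sequence-based.
* Only the best local alignment per subject is reported; secondary HSPs
  (e.g. internal repeats) are not shown.
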