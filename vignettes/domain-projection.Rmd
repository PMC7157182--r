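---
title: "Projecting protein domains onto the genome: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Projecting protein domains onto the genome: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem and the model

Protein feature tables annotate two kinds of domains in amino-acid
coordinates: *regions* (structured entities with known function,
typically longer than 100 residues — zinc fingers, WD40 repeats,
ion-transport domains) and *sites* (short, often single-residue
annotations — phosphorylation or nitrosylation sites, transmembrane
segments — frequently nested inside regions). Variant data live in
genomic coordinates. `domainmapr` connects the two with a deterministic
three-stage mapping.

**Stage 1 — protein to cDNA.** The `coded_by` qualifier of a protein's
CDS feature names its mRNA and the 1-based cDNA span of the coding
sequence; the span's start is the frame offset we call the *shift*.
Residue $i$ then occupies cDNA positions
$(i-1)\cdot 3 + \mathrm{shift} \;\dots\; i\cdot 3 + \mathrm{shift} - 1$.
This is the only assignment under which residue 1 begins exactly at the
CDS start; the "multiply by three and add the shift" phrasing common in
database documentation is ambiguous about the boundary, and we fix it
this way deliberately (and test it: a feature at residue 1 with shift 203
must land on cDNA 203..205).

**Stage 2 — verification by degenerate reverse translation.** Coordinate
arithmetic alone cannot detect a stale accession pair or an off-by-one
CDS annotation, so every placement is double-checked against the
sequence. Each residue is reverse-translated to a single degenerate
codon: at each codon position, the IUPAC letter whose base set is the
union of that position's bases over the residue's codons (glycine
GGT/GGC/GGA/GGG → `GGN`; leucine → `YTN`; serine → `WSN`). The *mapping
score* is the fraction of cDNA positions compatible with the degenerate
string — 1.0 when placement and sequence agree everywhere. Two
deliberate choices here:

* **Permissiveness is accepted.** The positionwise union admits some
  codons outside the residue's set (`WSN` matches some non-serine
  codons). The score is a verification diagnostic layered on exact
  arithmetic, not a search tool, so the one-sided error (a wrong
  placement can occasionally score high, a right placement never scores
  low) is the correct trade-off.
* **Unknown bases never verify.** An `N` in the cDNA counts as a
  mismatch unless the degenerate letter itself is `N` — unknown sequence
  must not inflate verification scores.

Scores are stored per record (rounded to two decimals in exports) and
never used as a filter; consumers can impose any threshold downstream.

**Stage 3 — exon splitting.** The cDNA interval is projected through the
transcript's genePred exon model. On `+` transcripts cDNA base 1 is the
first base of the leftmost exon; on `-` transcripts it is the last base
of the rightmost exon, so cDNA ascends as the genome descends. Output
segments are maximal runs within single exons, ordered by transcription
(so records read 5'→3'), with the invariant that segment lengths sum to
three times the feature's amino-acid length. Domains spanning junctions
produce one record per exon touched, which is why the record table is
larger than the domain count.

## Coordinate conventions

Each format keeps its native convention at the boundary: amino-acid and
cDNA coordinates are 1-based inclusive (GenBank), genomic exon intervals
0-based half-open internally (genePred), and exported records 1-based
inclusive. Chromosome names are normalized by stripping an optional
`chr` prefix for queries, while exports keep the gene-model file's
dialect.

## Parameters that matter

| Parameter | Where | Default | Why |
|---|---|---|---|
| `yates` | `chi_square_test()` | `FALSE` | the classical uncorrected 2×2 statistic; the corrected variant is exposed because both are standard |
| zero-cell handling | `odds_ratio()` | Haldane–Anscombe +0.5 | keeps the OR finite and flags the correction; chi-square instead errors on a zero marginal because the test is undefined there |
| score rounding | exports | 2 decimals | matches the published record format; internal arithmetic is exact |
| version matching | ingest | exact, then version-stripped | RefSeq versions drift between releases; the fallback is logged |

## Degenerate and edge inputs

`X` reverse-translates to `NNN`; selenocysteine `U` also maps to `NNN`
with a warning, since its UGA recoding is context-dependent and outside
the standard code; a stop `*` inside a feature is an error. `order(...)`
site locations are expanded to one single-residue feature per listed
position — sites are residue-level entities, and an enclosing span would
fabricate unannotated residues. `coded_by` qualifiers in `join`/
`complement` form are refused rather than guessed. Records without
`coded_by`, without a matching cDNA, or whose CDS exceeds the cDNA are
excluded and counted, never repaired. Duplicate genePred transcript rows
keep the last row, logged; multi-placement is out of scope.

## The store and its exports

The record table is held in memory with a `GenomicRanges` interval index
for position queries; CSV, JSON and SQL dumps are derived views over the
fixed twelve-column schema (gene symbol, NP_, NM_, strand, kind, name,
score, chromosome, start, end, note, exon index). The SQL dump is a
plain `CREATE TABLE` plus `INSERT`s executable by any SQL engine. All
three formats round-trip to an identical record set. Because the flat
schema carries no transcript-frame columns, residue back-calculation is
exact for stores built in-session and `NA` after re-import — the
annotation itself (which domains a position hits) is unaffected.

## Residue back-calculation

For a hit at genomic position $g$ inside a record segment, the cDNA
position is recovered from the segment's stored transcription-order
offset (strand-aware), and the residue is
$\lfloor (c - \mathrm{shift})/3 \rfloor + 1$. Each matched record
reports the residue in its own transcript frame, so a variant hitting
two isoforms can correctly report two residue numbers. Only point
positions are supported; a helper expands ranges to per-base queries.

## Enrichment statistics

The 2×2 table crosses (annotated on a domain vs not) with a user-supplied
variant grouping — population frequency below/above 1%, or
pathogenic/likely-pathogenic status vs other. Group labels are inputs,
not recomputed: frequency and clinical-assertion lookups are
external-data concerns. The chi-square statistic uses the closed form
$n(ad-bc)^2 / ((a{+}b)(c{+}d)(a{+}c)(b{+}d))$, which the suite proves
equal to $\sum (O-E)^2/E$ on random tables and equal to the stock
uncorrected `chisq.test`. Cell products are computed in double precision
because $a\cdot d$ overflows 32-bit integers at realistic cohort sizes.

## What the synthetic generator emulates — and what it does not

`generate_fixture()` produces a random gene model (exon lengths
30–600 bp, intron gaps 50–5000 bp — compact-transcript scale), a random
protein packed into it (5' UTR 0–90 nt, CDS with stop codon, 3' UTR from
the remainder), regions of 20–200 aa and sites of 1–3 aa, with at least
one region forced across an exon junction whenever the CDS crosses one.
The cDNA is assembled by sampling a true codon per residue, so all
uncorrupted features score exactly 1.0, and `corrupt_cdna()` plants
mismatches whose expected scores $(L-k)/L$ are known by construction.
Ground truth is computed through the per-base map — an explicit
base-by-base projection, independent of the interval arithmetic it
checks. Random streams are split per component from one master seed, so
fixture kinds can be added without perturbing existing expected outputs.

The generator deliberately does **not** emulate: real codon-usage bias,
pseudo-autosomal or multi-placement transcripts, selenoproteins,
`join`ed CDS annotations, alternative isoform collisions on shared loci,
or the full richness of real flat files (only the fields the ingest
module consumes are emitted). Passing the round-trip suite therefore
demonstrates the correctness of the arithmetic, the projection, the
store and the query path under clean inputs — not robustness to every
malformation found in live database dumps, which the ingest module
handles by skip-and-count rather than repair.

## Problem sizes and numerical choices

The validation suite uses 200 random fixtures (mixed strands, 1–8 exons)
for end-to-end round-trips; exhaustive interval-vs-oracle comparison on
transcripts of ≤ 60 nt (every interval, both strands, 1–5 exons); 1000
random tables for the chi-square identity; 5000 null simulations for
type-I calibration (expected 0.05 ± 0.01); and 10^5 variants per group
for odds-ratio recovery (planted 32% vs 23% annotated, generating
OR ≈ 1.58, recovered within 5%). These sizes make every check exact or
tightly bounded while keeping the full suite fast on a single CPU.

Determinism: all generator randomness derives from explicit seeds;
`.Random.seed` is saved and restored around every seeded block, so
library calls never perturb user RNG state.

## Known limitations

* Genomic placement relies on the genePred model matching the cDNA's
  transcript version; mismatches surface as projection errors (interval
  beyond transcript length), not as silently shifted coordinates.
* No liftover between assemblies, no realignment rescue of low-scoring
  features, no consequence prediction — the tool answers "which domains
  does this position hit, and which residue is that", nothing more.
* The record table keeps every isoform's domains; deduplication across
  isoforms is left to consumers.
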