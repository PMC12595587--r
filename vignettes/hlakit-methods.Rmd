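---
title: "hlakit: methods, design choices and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{hlakit: methods, design choices and limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hlakit)
```

This vignette is the package's own account of what it computes and why it
computes it that way: the data model, the defaults that matter, the
numerical choices, and what the offline tests do and do not demonstrate
about real data.

## The alignment dialect and its table model

The IPD-IMGT/HLA alignment files present each multiple sequence alignment
in blocks of 50–100 positions. Within a block, the first sequence is the
reference; every other row encodes identity to the reference as `-`, an
indel as `.`, unknown or unsequenced residue as `*`, and gene-feature
boundaries as `|` characters embedded in the sequence. `parse_alignment()`
concatenates the blocks, expands identity dashes against the reference,
lifts the boundary markers into metadata, and returns one row per allele
and one column per aligned position.

Several dialect details are nowhere written down and had to be fixed as
package conventions; they are chosen to match the public files and are
locked in by an exact round-trip test (`write_alignment()` then
`parse_alignment()` reproduces the table identically on 100 seeded
fixtures per run):

* **Position labels** are synthesized by walking columns from the anchor
  label of the first block. Protein alignments number the mature protein
  from 1 with negative labels for the leader peptide and no position 0;
  the same zero-skip applies to genomic alignments crossing the
  transcription start. A column where the reference holds `.` is an
  insertion column and gets a fractional label (`62.1`, `62.2`, …) after
  the preceding integer position.
* **Late entrants and early terminators.** An allele first sequenced
  mid-alignment appears only in later blocks; the parser left-pads it with
  `*`. An allele whose line is short in its final block, or absent from
  trailing blocks, is right-padded with `*`. Padding is always `*`, never
  `-`, so identity expansion cannot invent sequence.
* **Codon tables are derived, not parsed.** The upstream `_nuc.txt` file
  carries both the coding-nucleotide and the codon view; `hlakit` derives
  the codon table by grouping nucleotide columns in threes from the first
  column (the Exon-1 start of the spliced cDNA), attaching insertion
  columns to the preceding in-frame codon.

Errors are deliberately loud and specific — a malformed position-label
line names its block, a symbol-count mismatch names the allele and block —
because silently mis-aligned columns would corrupt every downstream count.

## Nomenclature translation

The allele-list history keys every allele name by a stable accession, one
column per quarterly release. Translation is a two-step lookup: name →
accession in the source release, accession → name in the target release.
An accession with no entry in the target column means the allele was
deleted or did not yet exist there — `translate_allele()` returns `NA` for
that, and reserves errors for names that were never valid in the source
release, keeping "deleted" and "wrong" distinguishable.

Three design points were genuinely open:

* **Truncated names.** The history stores full names only, so a two-field
  query is expanded to every full name that truncates to it, each is
  translated and re-truncated, and the unique result is returned; if the
  expansions disagree after truncation the call fails with an ambiguity
  error rather than guessing.
* **Missing leaves in GL Strings.** What a whole-genotype translation
  should do with a deleted allele is a policy question, so it is an
  explicit parameter: `on_missing = "fail"` (default) errors naming the
  leaf, `"keep"` retains the source-release name, `"drop"` removes the
  leaf so an ambiguity collapses to its survivors. The tokenizer preserves
  the delimiter structure exactly; under `"keep"` the delimiter multiset
  is provably conserved (a property test).
* **`HLA-` prefixes** are opaque: whatever was read is re-emitted,
  because mixed datasets exist in the wild and normalizing them would
  change files that users diff.

## Atlases, and feature names for pseudogenes and gene fragments

`build_atlas()` reads the boundary metadata of each alignment and reports,
per boundary, the feature labels on each side, the position labels of the
flanking columns, and — for nucleotide alignments — the codon spanning the
boundary. Codons are numbered on the **mature protein**: when the locus
protein alignment is supplied, its count of negative positions (the leader
peptide length) is subtracted from the raw `ceil(cDNA/3)` codon index.
Without a protein table no leader is known and the raw index is reported.
When a boundary does not fall on a codon multiple, the reported codon is
the one containing the first nucleotide after the boundary.

Expressed genes decompose into 5'UTR, exons, introns and 3'UTR, but
pseudogenes and gene fragments need not. `classify_fragment_features()`
compares a fragment's genomic alignment to an expressed reference gene
(HLA-C for class I fragments, since its gene body is the longest of the
class I genes; DPA1/DPB1 for the DP pseudogenes) through a column pairing,
and labels each fragment feature:

* a feature covering exactly one full reference feature keeps that
  feature's name (`E.3`);
* a proper subset of one feature is a *segment* (`S.n`);
* contiguous aligned sequence crossing one or more reference boundaries
  is a *join* (`J.n`);
* a mix of aligned and unaligned runs is a *hybrid* (`H.n`) — the
  threshold is strict: any unaligned run of one or more columns inside an
  otherwise aligned feature makes it hybrid, because no tolerance is
  defined anywhere and a strict rule is at least reproducible;
* fully unaligned sequence is *novel* (`N.n`).

Non-standard features are numbered by order of appearance 5'→3'. The
classifier consumes only a pairing (fragment column → reference column or
unaligned), so the pairing source is pluggable: shared multiple-alignment
coordinates when the fragment was lifted from the reference's own file,
or any external global aligner otherwise. Annotations are generated from
the run structure ("H.1 is 287 nucleotides of novel sequence followed
by…"); matching a curator's free prose verbatim is not promised.

The gazetteer's 19-category roster is frozen in
`gazetteer_categories()` and asserted in tests. The packaged gene
metadata table replaces a scrape of the registry website with a curated
TSV; the chromosomal map order of the minor class I fragments is an
approximation where published maps disagree, and the DRB3/4/5 and DRB6/7
clusters share one rank (rendered as merged labels) because structural
variation in the DR region makes their internal order genuinely
ambiguous.

## Frequency maps

`select_variant()` reduces a variant specifier to one value per
population:

* **allele** — the allele's recorded frequency, with 0 for populations
  typed at the locus but lacking the allele (absence of a row is evidence
  of absence only within typed populations, which is why populations not
  typed at the locus contribute nothing at all);
* **motif** — the sum of the population's frequencies over all alleles
  carrying the motif. Because frequency tables are typically two-field
  while alignments are four-field, matches are truncated to each table
  allele's own field depth before joining; a table allele matches if any
  full-resolution match truncates to it;
* **haplotype** — the sum over rows whose alleles at the requested loci,
  truncated to the spec's field depth, equal the spec. A population is
  included only if it records all requested loci at at least the
  requested depth; coarsening the spec can therefore only add populations
  and add matching rows, which is the truncation-monotonicity property
  the tests assert.

Populations flagged migrant or admixed are dropped when
`filter_migrant = TRUE`. A variant whose point values are all below
`1e-4` is refused unless `generate_low_freq = TRUE`; the threshold is the
conventional cutoff below which a frequency estimate from typical survey
sizes is mostly noise. Both refusals are typed conditions
(`hk_low_frequency`, `hk_not_observed`) so callers can distinguish "too
rare to map" from "never observed".

### Gridding

The original mapping pipeline in this field drives a full cartographic
toolchain; `hlakit` replaces it with a documented, dependency-light
interpolator whose behaviour is easy to state and test:
inverse-distance weighting with power 2 over haversine (great-circle)
distances, onto a 1° grid of cell centers (WGS84 degrees, longitude in
(−180, 180]), masked to land cells within 2000 km of at least one
observation. All four parameters are arguments. The consequences are
deliberate:

* IDW is exact at each observation's own cell and bounded by the range of
  the observed values — no spline overshoot — so the grid maximum of a
  planted signal equals the planted frequency exactly (tested);
* cells beyond the cutoff are masked rather than extrapolated, so a
  variant with no nearby data leaves white landmass;
* rendered surfaces resemble but will not pixel-match maps produced by
  other gridding engines. Map-level comparisons in this package are by
  point values and mask topology, never by pixels.

The land mask is computed by even-odd ray casting against a coarse,
hand-digitised set of continental outlines shipped as
`synthetic_coastlines.csv` (enclosed seas are separate polygons that
carve holes). It is explicitly synthetic: adequate for masking at 1–2°
resolution, wrong in detail near coasts, islands and enclosed seas. The
cell containing an observation is always unmasked even if the coarse
coastline calls it sea, so no population can be silently dropped by mask
error. Rendering uses blue→red (colour) or white→black (greyscale) ramps
over 0→vmax, with `scale_mode = "unit"` pinning vmax at 1.0 so
complementary variants (for example the two residues of a biallelic
amino-acid site) share one scale.

Genotype-frequency helpers (`genotype_freqs()`) are Hardy-Weinberg
estimates (`f²`, `2fg`) under random mating, not observed genotype
counts, and are documented as such.

## Synthetic data: what it emulates and what it does not

The fixture generators define the test conditions once and are not tuned
per test:

* alignment fixtures default to 8 alleles over ~60 positions with a
  substitution density of 0.08, one insertion column, one late entrant
  and one early terminator — enough to exercise every dialect feature in
  every file;
* frequency fixtures draw allele frequencies Dirichlet(1) per
  (population, locus) over a 6-allele pool across 8 populations placed at
  fixed inland sites, flag 25% of populations as migrant, and can plant
  one allele at a stated frequency to give map tests an analytic
  expectation;
* haplotype fixtures rotate locus sets (A–B–C–DRB1, A–B–C, A–DRB1-style
  subsets) across populations and record a minority of populations at
  three-field resolution, emulating haplotype data pooled from
  heterogeneous sources.

Problem sizes in the test suite (100 round-trip seeds, 8–10 populations,
2° acceptance grids) were chosen so the full suite completes in seconds
while still exercising every code path; nothing in the methods depends on
these sizes. What passing fixture tests shows is that the *machinery* is
correct — parsing is invertible, matching equals brute force, gridding is
exact where it claims to be. What it cannot show is fidelity to upstream
curation quirks (out-of-order blocks across 62 releases, free-text
annotation wording) or to real linkage disequilibrium, which the
haplotype generator deliberately does not simulate. Those properties are
covered instead by the pinned-release acceptance tests, which download
the real files and reproduce published counts, and which require network
access on first run.

## Known limitations

* Only the IMGT dialect is parsed; MSF/FASTA/PIR/XML/EMBL alignment
  formats are out of scope, as are UNIFORMAT and the BIGDAWG/PyPop
  data-analysis format converters (beyond the simple paired-column
  genotype dialect used for whole-dataset translation).
* The fragment classifier reports run structure; curated prose
  annotations may describe the same structure in different words.
* The synthetic coastline makes no claim near shorelines; users who need
  accurate coastal masks can pass their own polygon table to
  `hk_land_mask()`.
* Live scraping of online frequency databases is not attempted; frequency
  tables are file inputs in the two documented layouts.
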