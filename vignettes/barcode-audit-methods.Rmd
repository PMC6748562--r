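---
title: "Methods: auditing barcode identification against growing reference libraries"
author: "barcodeAudit"
output: rmarkdown::html_document
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the models and procedures it
implements, the parameters that matter, and the choices made where the
design was genuinely open. It states no empirical result that the test
suite and `scripts/acceptance.R` do not themselves compute.

## The audit in one paragraph

A set of intercepted specimens carries two identifications: a
morphological one, often truncated at family or subfamily because the
specimens are larvae, and a DNA-based one obtained by matching a COI-5P
barcode against a reference library. The audit asks three questions. How
does identification success change as the library grows year by year, and
how much is lost when only public records may be used? When both
identifications exist, do they agree — and in which of five well-defined
ways? And do the sequence clusters (MOTUs, standing in for BINs) carry
internally consistent taxonomy?

## Taxonomic comparison

Lineages span six ranks (order, superfamily, family, subfamily, genus,
species). Only ranks named on **both** sides are compared; missing
intermediate ranks never create disagreement. Name comparison is
case-insensitive after whitespace normalisation, with no synonym
resolution — the audit compares labels as deposited, because label
quality is part of what it measures. Species names are binomina;
subspecific epithets are truncated on ingest since nothing below species
participates in the audit.

The relation between a morphological lineage and a hit's lineage is one
of: `identical_species`, `descendant` (hit deeper, consistent),
`ancestor` (hit shallower, consistent), `identical_at_rank` (equal depth,
consistent, below species — e.g. the same family on both sides),
`sister_species` (both species-level, same genus, different epithet),
`interim_only` (the hit has only a BIN label), or `disjoint` (some shared
rank disagrees). The `identical_at_rank` value exists because an
equal-depth self-comparison is neither ancestor nor descendant; it maps
to the concordant category downstream, and with it the antisymmetry
property — `relation(a,b) = descendant` exactly when
`relation(b,a) = ancestor` — holds without exception. "Sister" is
operationalised as congeneric: true sister-group topology is never
computed, which matches how a curator reads a congeneric near-miss.

## Library views and snapshots

Two views mirror the standard search libraries of a barcode
identification engine:

* **SLBR** — records identified to species *or* carrying interim (BIN)
  taxonomy, minimum 500 bp. Non-public records are included; this is the
  practitioner's best case.
* **PRBD** — published (public) records, minimum 500 bp, any
  identification rank; this is what an outside user can verify.

A snapshot at year *y* keeps records with `year_added <= y`. Length is
counted over non-gap characters, ambiguity codes included — deposited
record lengths are raw lengths. Snapshots are monotone in year, which
drives every growth property downstream.

## The matcher

Identity is computed from an end-gap-free global alignment: match +1,
mismatch −1, each gap column −2, terminal gaps free. Identity is
matches over aligned columns with terminal-gap columns excluded; the
aligned-column count is the overlap, and comparisons with overlap below
`minOverlap` (default 300 bp, so that 407 bp barcode fragments remain
identifiable while junk overlaps are rejected) yield a no-comparison
signal distinct from a 0% identity. A column matches when the IUPAC code
sets intersect (N matches anything) — conservative toward
identification, as in common practice.

Numerical choices worth knowing:

* **The strict 98% boundary.** A hit requires identity *strictly* above
  the threshold. The comparison is done in integer arithmetic
  (`100 * matches > threshold * columns`), so a pair at exactly 98.000%
  (e.g. 637/650) is excluded without any floating-point ambiguity.
* **Tie-breaks.** Equal-identity hits order by record id ascending.
  Among equal-score alignments the dynamic programme reports the one
  with the most matched columns, then the fewest columns — a choice that
  is deterministic and invariant under swapping the sequences, making
  identity and p-distance exactly symmetric.
* **Banding.** The dynamic programme is banded: alignments may drift up
  to `bandSlack` (default 50) net indel positions beyond the length
  difference of the two sequences. COI barcodes are length-conserved, so
  this is far beyond anything biologically expected; sequences that
  would need more drift are treated as non-homologous.
* **No-sequence vs no-hit.** A specimen that yielded no sequence is a
  separate signal from a sequence with no hit; the two are never
  conflated in any table.

## Concordance classification

Applied to the top hit, in precedence order: (a) no supra-threshold hit —
category 4 (*no match*), unless some comparable sub-threshold record
carries the same Linnaean name at the morphology's lowest named rank, a
category-3 (*interim*) outcome; (b) identical species — category 2;
(c) hit deeper and consistent — category 1; (d) hit equal-or-higher and
consistent — category 2; (e) BIN-only hit — category 3; (f) congeneric
sister — category 3; (g) shared-rank conflict — category 5
(*discordant*).

Two design points. First, classification follows the single top hit —
that is how a top-match identification engine behaves — but when
runners-up above the threshold conflict with the morphology the result
carries a conflict annotation listing them, because that is the evidence
an expert needs when deciding whether a concordant answer can be
trusted. Second, the sub-threshold same-name rule accepts *any*
comparable sub-threshold record with the matching name (reporting the
best one), not just the single closest record: under the
closest-record reading, the arrival of a nearer but differently-named
record could demote a specimen from category 3 back to category 4, and
identification would no longer be monotone under library growth — an
invariant the audit depends on.

The five categories partition the sequenced specimens in every
(year, view) panel; sequencing failures are reported alongside, never
inside, the partition.

## MOTU clustering and the BIN audit

Clusters are single-linkage components of the p-distance graph at a
threshold of 0.022 — the conventional seed threshold for barcode index
numbers. This is deliberately a *surrogate*: the production BIN
algorithm refines single-linkage clusters with a Markov stage that is
out of scope here, so no equivalence with official BIN pages is claimed.
Single linkage is delegated to `stats::hclust(method = "single")` cut at
the threshold; the test suite proves the result equal to brute-force
connected components on desk-scale inputs, along with order-invariance
and nestedness across thresholds. Pairs with insufficient overlap
contribute no edge. Cluster identifiers are the lexicographically
smallest member id, so a clustering is reproducible byte for byte.

A multi-sequence cluster is **discordant** when any rank named by at
least two members carries two or more distinct names; mixing a
family-only record with a congeneric record of the same family is
concordant (the higher-level name is consistent), and interim-only
members impose no constraint. Discordance is evaluated at *every* rank,
not species only — a cluster mixing two families with no species names
at all is still discordant. Singletons are excluded from the concordance
denominator, since a single record cannot disagree with itself. The
"10 or fewer records" summary uses an inclusive bound.

## The synthetic study

The generator emulates the study design end to end, with complete ground
truth per record and per specimen:

* **Taxonomy and sequences.** Families (default 8) pair into
  superfamilies, each family holds genera (default 3) split across two
  subfamilies, each genus holds species (default 4). Sequences evolve
  along this hierarchy under a uniform substitution model (each site
  flips with probability μ to a uniformly chosen different base):
  family ancestors at 4×, genus ancestors at 2×, species ancestors at
  1× the interspecific divergence (default 0.05) from their parent, and
  every observed haplotype at the intraspecific divergence (default
  0.005) from its species ancestor. Two congeners then disagree at a
  site with probability 2μ − (4/3)μ², the closed form the tests check.
  With defaults, conspecific distances (~1%) sit far inside and
  congeneric distances (~9.7%) far outside both the 98% identity rule
  and the 0.022 clustering threshold. Indels are off by default (COI is
  length-conserved); an optional indel rate exists to exercise the
  alignment path.
* **Library growth.** Records accumulate 2009–2019 on a schedule
  totalling 303 records that plateaus after 2015, mirroring a maturing
  library; 40% of records are public each year, so the public view lags
  the species-level view materially. A configurable fraction of species
  (default 80%) can ever enter the library — the remainder drives the
  no-match category. Some records are BIN-only (10%), some are below
  the 500 bp cut (5%), and a small library misidentification rate
  (2%) swaps a record's name with a congener or confamilial species,
  recorded in a truth ledger.
* **Queries.** Specimens (default 241) sample species uniformly,
  fail to sequence at rate 0.166, are truncated to 407 bp fragments at
  rate 0.065, and carry morphological identifications truncated at a
  rank drawn from a distribution massed at family and species
  (species = 0.383, matching the share of interceptions morphology
  identifies to species). A morphological misidentification (default
  rate 0.025) swaps the lineage with a species from a *different
  superfamily* before truncation, so the corruption is visible at
  whatever rank survives truncation — this is what makes the
  category-5 rate recover the injected rate.
* **Separate misidentification channels.** Library-side and
  morphology-side errors have separate rates (`library_misid_rate`,
  `morph_misid_rate`) because the audit's parameter-recovery property —
  category-5 rate ≈ injected morphological rate — requires the two
  injection channels to be independently controllable.

What the generator does **not** emulate, and hence what passing tests do
not show about real data: codon structure and selection on COI,
coalescent genealogies within species, geographic structure,
heterogeneous record lengths beyond the short-record flag, synonymy and
orthographic variation in deposited names, and the refinement stage of
the production BIN algorithm. Results against the real library will
differ for all of those reasons; the synthetic study validates the
*pipeline*, not the biology.

## Problem sizes and determinism

The default study is desk-scale by design: 241 specimens against a
303-record library, with exhaustive alignment (no heuristic screening —
at these sizes the exact contract is affordable and simpler to reason
about). The parameter-recovery scenario uses 1 000 specimens against a
complete library of ~4 records per species (48 species): full coverage
with several records per species is what "complete" means for an
identification engine, and it keeps haplotype-sampling noise at the 98%
boundary from confounding the misidentification signal. All generator
draws derive from a single integer seed, alignments and clustering are
deterministic, and re-running any stage on the same inputs reproduces
its output byte for byte.

## The reporting convention

Percentages print with one decimal, halves rounded away from zero,
computed in integer arithmetic (tenths of a percent) so the half-way
rule is exact. One consequence is accepted deliberately: a count pair
like 2/43 prints as 4.7, even though a report quoting more precision
would write 4.65.

## Known limitations

* The matcher models a generic identification engine, not any specific
  production system; real engines use k-mer screens and profile
  alignments whose identities differ near the threshold.
* Congeneric "sister" is a proxy; no phylogeny is estimated.
* Name comparison has no synonym or fuzzy matching, so an orthographic
  variant in a real library counts as a conflict.
* The MOTU surrogate omits the Markov refinement of the production BIN
  algorithm and will merge clusters that refinement would split.
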