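---
title: "Consensus taxonomic classification by bottom-up voting"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Consensus taxonomic classification by bottom-up voting}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(taxvote)
```

## The problem

Profiling eukaryotic members of a microbial community — fungi above all —
typically relies on 18S rRNA gene or ITS1 amplicon sequencing. Unlike 16S
work, no large curated reference database exists for ITS1, so reads must
be compared against broad, largely uncurated sequence collections. Naive
best-BLAST-hit annotation then fails in characteristic ways: the best hit
may be an environmental clone annotated only as "uncultured soil
basidiomycete"; a short but high-identity local match may outscore the
true source; and reference lineages can jump ranks (a genus hanging
directly off a phylum), leaving intermediate levels undefined.

`taxvote` addresses this by treating each quality-filtered BLAST hit as a
voter and accepting a taxon name at a rank only when a sufficient
majority of informative hits agrees.

## The algorithm

For each query, the hits (one per subject sequence: multiple HSPs are
collapsed to the highest-bitscore one) pass through:

1. **Quality filter.** A hit survives if its *query coverage* —
   `(|qend − qstart| + 1) / qlen`, the aligned query span over query
   length — is at least `min_coverage` (default 0.70), its percent
   identity is at least `identity_other`, and its accession resolves to
   a taxon in the local taxonomy. Queries with no surviving hit are left
   unclassified with an explanatory status.
2. **Generic screen.** If the fraction of surviving hits whose terminal
   annotation matches a generic keyword ("uncultured", "unidentified",
   ...) or whose lineage names no standardized rank at all exceeds
   `generic_fraction_max` (default 0.70), the query is unassigned: the
   database simply has nothing informative to say.
3. **Bottom-up voting.** Voting walks the eight standardized ranks from
   species to domain. At rank *r*, a hit votes for its lineage's name at
   *r* provided (a) its identity meets the rank's threshold
   (`identity_species` at species, `identity_genus` at genus,
   `identity_other` elsewhere), (b) its lineage actually names rank *r*,
   and (c) its terminal annotation is not generic. Hits passing (a) but
   failing (b) or (c) are logged as ignored generic/partial assignments
   at that rank — a kingdom-only database entry is silent at species
   through phylum and casts its vote once the walk reaches kingdom. The
   winning name is accepted when its share of the eligible votes
   *strictly exceeds* the rank's majority (`majority_low` = 0.60 at
   species/genus/family, `majority_high` = 0.90 at order and above).
   Acceptance at rank *r* automatically fills every rank above *r* from
   the winner's lineage; ranks below stay blank.

The per-rank identity defaults are amplicon-specific presets:
95.2% / 83.05% / 80% (species/genus/other) for ITS1 and 99% / 96% / 80%
for the 18S rRNA gene amplicon. Coverage and generic filters are 0.70
for both.

## Parameters that matter

| Parameter | Default | Meaning |
|---|---|---|
| `min_coverage` | 0.70 | minimum aligned fraction of the query |
| `identity_species/genus/other` | preset | percent-identity floor per voting rank |
| `majority_low` | 0.60 | strict majority at species, genus, family |
| `majority_high` | 0.90 | strict majority at order and above |
| `generic_fraction_max` | 0.70 | max tolerated fraction of generic/rank-free hits |
| `max_hits` | 100 | per-query candidate cap after HSP dedup |
| `min_passing_hits` | 1 | survivors required for voting to start |

## Design choices where the design was open

Several behaviours are conventions this package fixes explicitly:

* **"Surpass" is strict.** A winner must exceed the majority threshold,
  not merely reach it; and a tie at a rank produces no winner, so the
  vote proceeds upward rather than picking an arbitrary (e.g.
  alphabetical) name.
* **Majority denominator.** The denominator is the count of hits
  *eligible at that rank*, not all passing hits. Otherwise a database
  dominated by partially annotated environmental sequences could never
  reach 60% at species level even when every informative hit agrees.
* **Generic screen is global, not per rank.** It is evaluated once over
  all filter-passing hits. The per-rank alternative would interact with
  rank gaps in hard-to-explain ways; the global form matches the intent
  of "too many uninformative hits → no call".
* **"Too few passing hits".** The coverage-failure condition is
  operationalized as a count (`min_passing_hits`, default 1) rather
  than a proportion, and exposed as a knob.
* **Rank gaps count as partial.** A hit whose lineage is blank at the
  voted rank but filled lower down (phylum→genus jumps) is logged with
  the generic/partial count at that rank and re-enters voting at its
  next filled ancestor rank, exactly like kingdom-only entries.
* **Identity gating of the global filter.** Only `identity_other` gates
  the initial filter; the stricter species/genus thresholds act at
  voting time. The species vote therefore sees the same hit set as the
  genus vote, minus identity-ineligible voters.
* **Unresolvable accessions** are dropped with a logged reason
  (`unresolved_taxon`), never an error: real mapping files lag real
  databases.

## The taxonomy store

The classifier consults an offline taxonomy in NCBI taxdump dialect
(nodes/names tables, optional merged-taxid table) plus a two-column
accession→taxid map — no SQL server, no network. `"superkingdom"` (and
`"domain"`) rank labels map to the domain slot of the standardized
8-rank ladder; all other labels must match slot names exactly, and
unranked intermediate nodes are preserved in the full-lineage output
but never voted on, since thresholds are defined per standardized rank.
Generic-name matching is case-insensitive substring matching, so one
keyword covers the many spelling variants of environmental-clone
annotations.

## What the simulator emulates — and what it does not

`simulate_reads()` emulates the error structure used to validate the
classifier on an in silico community: per-base substitutions at rate 1%
(replacement uniform over the other three bases), then truncation from
the 3' end by round-to-nearest of an exponential draw with mean 5 bases
(capped at length − 1), 32 reads per organism. Substitutions are applied
before truncation; truncation is taken from the 3' end because that is
where pyrosequencing quality degrades. Rounding, the truncated end, and
the uniform replacement are conventions of this package — the
distributions' rates and means are the stated world.

It deliberately does **not** model homopolymer indels (the dominant 454
artifact), chimeras, or abundance variation. `emulate_hits()` stands in
for blastn: true semi-global alignments against a small reference set,
with controllable injection of short-coverage and generic-redirected
hits. A green end-to-end test therefore establishes that the voting
logic recovers planted truth under the stated noise — not that any
particular biological database is adequate.

## Numerical conventions

* Semi-global alignment (query end-to-end, subject free ends) uses unit
  edit costs. Where co-optimal alignments differ in length, the
  reported alignment takes the smallest subject end-position and a
  traceback preferring substitutions over query-consuming gaps over
  subject-consuming gaps; percent identity is
  `100 · (columns − distance) / columns` under that convention.
* The primer profiler treats "edit distance" as full
  substitution/indel distance in semi-global mode by default, because
  degenerate-primer target sites can be offset by loop indels; a
  `hamming` flag restricts it to mismatch counting over full-length
  windows for a strict "numbers of mismatches" reading. IUPAC
  degeneracy costs nothing when the target base is in the symbol's set.
  Reverse-complement scanning is off by default (rRNA reference sets
  are stranded).
* Vote fractions are exact ratios of integers; comparisons against
  thresholds use `>` with no epsilon.

## Known limitations

* One subject sequence casts one vote; no weighting by bitscore or
  e-value beyond HSP collapse and the `max_hits` cap.
* The classifier trusts the taxonomy: mislabelled reference entries
  that are not caught by the generic keyword list vote like any other
  hit.
* No confidence measure beyond the winner fraction at the accepted
  rank.
* The simulator's substitution-only error model understates indel-rich
  chemistry; identity thresholds tuned on it should be re-examined for
  other platforms.
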