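# taxvote

Consensus taxonomic classification of 18S rRNA / ITS amplicon sequences
by bottom-up voting on BLAST hits — plus the in silico community
simulator and degenerate-primer profiler used to validate it, all
runnable offline.

## Why

Eukaryotic (especially fungal) community profiling has to search broad,
uncurated databases: no large curated reference set exists for ITS1.
Best-hit annotation then breaks on three recurring database defects —
environmental entries annotated only as "uncultured ...", short
high-identity local matches, and lineages that skip ranks (a genus
hanging directly off a phylum). `taxvote` classifies each query by
letting its quality-filtered hits *vote*, rank by rank.

## The algorithm in brief

For one query with hits $h_1, \dots, h_n$ (one per subject, best HSP):

1. keep hits with query coverage $\ge 0.70$, identity $\ge$ the global
   floor, and a resolvable taxon;
2. if more than 70% of the survivors are generic ("uncultured",
   "unidentified", ...) or carry no ranked lineage at all, report the
   query as unassignable;
3. walk species → domain; at rank $r$, each hit whose identity meets the
   rank threshold and whose lineage names $r$ votes for its name at $r$;
   accept the winner $w$ iff

   $$\frac{\mathrm{votes}(w)}{\mathrm{eligible}(r)} > m_r,\qquad
     m_r = \begin{cases}0.60 & r \in \{\text{species, genus, family}\}\\
                        0.90 & r \ge \text{order}\end{cases}$$

   Acceptance at $r$ fills every rank above $r$ from the winner's
   lineage; lower ranks stay blank.

Identity thresholds (species / genus / other) are preset per amplicon:
**ITS1** 95.2 / 83.05 / 80, **18S** 99 / 96 / 80.

The taxonomy is a local NCBI taxdump-style store (nodes/names tables +
accession→taxid map) — no SQL server, no network.

## Worked example

```r
library(taxvote)

# a 19-node toy taxonomy: 2 organisms + a rank-gap genus + an
# "uncultured" leaf; then a simulated community of reads
tax <- make_toy_taxonomy(2, decoys = c("rank_gap", "generic_leaf"))
store <- load_taxdump(tax$nodes, tax$names)
set.seed(1)
orgs <- data.frame(name = tax$organisms$name, taxid = tax$organisms$taxid,
                   sequence = random_dna(2, 400))
sim <- simulate_reads(community_spec(orgs, reads_per_organism = 4L,
                                     seed = 99L))          # 1% errors
refs <- setNames(orgs$sequence, c("ACC001", "ACC002"))
mapping <- setNames(as.integer(orgs$taxid), names(refs))
hits <- emulate_hits(sim$reads, refs, top_k = 2, mapping = mapping)

cfg <- classifier_config("its")
cfg
#> <classifier_config> preset=its identity(sp/gen/other)=95.2/83.05/80
#>   coverage>=0.7 majority(low/high)=0.6/0.9 generic<=0.7 max_hits=100

res <- classify_batch(hits, cfg, store)
res[[1]]
#> <classification> read_0001: species 'Genus01 species01' (confidence 1.00)
#>   Eukaryota; Fungi; Phylum01; Class01; Order01; Family01; Genus01; Genus01 species01
```

Every read lands on its source organism's full 8-rank lineage with
confidence 1.00 — the winner took 100% of the eligible votes at species
level. The three QIIME-compatible report files (standardized taxonomy,
full NCBI-style taxonomy, voting log):

```r
write_reports(res, "out/")
#> out/standard_taxonomy.tsv:
#> #query_id  standardized_taxonomy                                         confidence  note
#> read_0001  Eukaryota;Fungi;Phylum01;Class01;Order01;Family01;Genus01;Genus01 species01  1
```

Primer complementarity profiling (IUPAC-aware semi-global edit
distance, grouped by clade):

```r
profile_clades("ACGTRYN", c(s1 = "GGACGTATAGG", s2 = "TTTTTTTTTTT"),
               c("fungi", "metazoa"))
#> <primer_profile> primer ACGTRYN, 2 sequences in 2 clades
#>      clade distance proportion
#> 1:   fungi        0          1
#> 2: metazoa        4          1
```

The fungal target contains a fully compatible site (distance 0); the
poly-T decoy sits 4 edits away.

## Command line

```sh
Rscript inst/cli/taxvote.R classify --hits hits.tsv --taxdump taxdump/ \
    --acc-map acc_map.tsv --preset its --out reports/
Rscript inst/cli/taxvote.R simulate --spec community.json --out sim/
Rscript inst/cli/taxvote.R primer-scan --primer ACGTRYN --fasta targets.fa \
    --clades clades.tsv --out profile.tsv
```

The hit table is 13-column tabular BLAST output: the standard 12
columns plus query length (`-outfmt "6 std qlen"`); query length is
required to compute coverage.

## Layout

- `R/` — taxonomy store, BLAST table I/O, classifier, report writers,
  simulator, primer scanner, CLI
- `src/` — Rcpp semi-global alignment kernels
- `tests/testthat/` — unit, property and acceptance suites with
  independent brute-force oracles
- `vignettes/consensus-voting.Rmd` — the model, its parameters, and the
  package's design choices
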