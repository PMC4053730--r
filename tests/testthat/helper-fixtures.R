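# Shared fixtures, built in code.

# 20-node toy taxonomy: 2 organisms + rank-gap genus + generic leaf +
# kingdom-only leaf. Built once per test run.
fixture_tax <- local({
  tax <- NULL
  function() {
    if (is.null(tax))
      tax <<- make_toy_taxonomy(
        2, decoys = c("rank_gap", "generic_leaf", "kingdom_only"))
    tax
  }
})

fixture_store <- local({
  store <- NULL
  function() {
    if (is.null(store)) {
      tax <- fixture_tax()
      store <<- load_taxdump(tax$nodes, tax$names)
    }
    store
  }
})

# One synthetic hit row in the parsed 13-column layout (+taxid).
mk_hit <- function(query_id = "q1", acc = "ACC1", identity = 100,
                   taxid = NA_integer_, qstart = 1L, qend = 100L,
                   qlen = 100L, bitscore = 200, evalue = 1e-50,
                   aln_len = NULL) {
  data.table::data.table(
    query_id = query_id, subject_accession = acc,
    percent_identity = identity,
    alignment_length = if (is.null(aln_len))
      abs(qend - qstart) + 1L else as.integer(aln_len),
    mismatches = 0L, gapopen = 0L,
    qstart = as.integer(qstart), qend = as.integer(qend),
    sstart = 1L, send = abs(qend - qstart) + 1L,
    evalue = evalue, bitscore = bitscore, qlen = as.integer(qlen),
    taxid = as.integer(taxid))
}

mk_hits <- function(...) data.table::rbindlist(list(...))

# 3-line taxdump chain used in several parser tests.
chain_nodes <- c("1\t|\t1\t|\tno rank\t|",
                 "2\t|\t1\t|\tsuperkingdom\t|",
                 "3\t|\t2\t|\tkingdom\t|",
                 "4\t|\t3\t|\tphylum\t|",
                 "5\t|\t4\t|\tgenus\t|")
chain_names <- c("1\t|\troot\t|\t\t|\tscientific name\t|",
                 "2\t|\tEukaryota\t|\t\t|\tscientific name\t|",
                 "3\t|\tFungi\t|\t\t|\tscientific name\t|",
                 "4\t|\tBasidiomycota\t|\t\t|\tscientific name\t|",
                 "5\t|\tRhodotorula\t|\t\t|\tscientific name\t|",
                 "5\t|\tRhodotorula synonymica\t|\t\t|\tsynonym\t|")
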