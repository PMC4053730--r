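# Taxids used repeatedly from the 20-node fixture.
fx <- function() {
  tax <- fixture_tax()
  list(tax = tax,
       sp1 = tax$organisms$taxid[1], sp2 = tax$organisms$taxid[2],
       class1 = tax$truth$taxid[tax$truth$name == "Class01"],
       gap_sp = tax$decoys$rank_gap,
       generic = tax$decoys$generic_leaf,
       kingdom_only = tax$decoys$kingdom_only)
}

# Random single-query hit table over the fixture taxonomy's pathologies.
random_hit_table <- function(n = NULL) {
  f <- fx()
  pool_tax <- c(f$sp1, f$sp2, f$gap_sp, f$generic, f$kingdom_only,
                f$class1, NA_integer_)
  if (is.null(n)) n <- sample(0:30, 1)
  if (n == 0) return(mk_hit()[0])
  data.table::rbindlist(lapply(seq_len(n), function(i)
    mk_hit(acc = paste0("ACC", i),
           taxid = sample(pool_tax, 1),
           identity = sample(c(100, 97, 96, 90, 84, 81, 79), 1),
           qend = sample(c(100L, 65L), 1))))
}

test_that("hit filtering partitions by coverage, identity and resolution", {
  cfg <- classifier_config("its")
  f <- fx()
  hits <- mk_hits(
    mk_hit(acc = "ok", taxid = f$sp1),
    mk_hit(acc = "lowcov", taxid = f$sp1, qend = 65),
    mk_hit(acc = "lowid", taxid = f$sp1, identity = 75),
    mk_hit(acc = "orphan", taxid = NA))
  out <- filter_hits(hits, cfg)
  expect_equal(out$passing$subject_accession, "ok")
  expect_equal(
    out$rejected$reason[match(c("lowcov", "lowid", "orphan"),
                              out$rejected$subject_accession)],
    c("low_coverage", "low_identity", "unresolved_taxon"))
  # coverage exactly at the threshold passes (>=), 0.65 does not
  expect_equal(nrow(filter_hits(mk_hit(qend = 70, taxid = f$sp1),
                                cfg)$passing), 1L)
})

test_that("random partitions equal brute-force predicate evaluation", {
  cfg <- classifier_config("its")
  set.seed(31)
  for (rep in 1:10) {
    hits <- random_hit_table(100L)
    out <- filter_hits(hits, cfg)
    manual <- vapply(seq_len(nrow(hits)), function(i) {
      cov <- (abs(hits$qend[i] - hits$qstart[i]) + 1) / hits$qlen[i]
      cov >= cfg$min_coverage &&
        hits$percent_identity[i] >= cfg$identity_other &&
        !is.na(hits$taxid[i])
    }, NA)
    expect_equal(nrow(out$passing), sum(manual))
    expect_equal(out$passing$subject_accession,
                 hits$subject_accession[manual])
  }
})

test_that("rank eligibility enforces identity, named rank and genericity", {
  cfg <- classifier_config("its")
  store <- fixture_store()
  f <- fx()
  # kingdom-only lineage: silent (generic_ignored) at species, votes at
  # kingdom
  ko <- mk_hit(taxid = f$kingdom_only)
  at_sp <- eligible_at_rank(ko, "species", cfg, store)
  expect_equal(length(at_sp$voters), 0L)
  expect_equal(at_sp$generic_ignored, 1L)
  at_kg <- eligible_at_rank(ko, "kingdom", cfg, store)
  expect_equal(at_kg$voters, "Environmentalia")
  # identity 94 with the ITS preset: below 95.2 at species, above 83.05
  # at genus
  mid <- mk_hit(taxid = f$sp1, identity = 94)
  expect_equal(length(eligible_at_rank(mid, "species", cfg,
                                       store)$voters), 0L)
  expect_equal(eligible_at_rank(mid, "species", cfg,
                                store)$identity_excluded, 1L)
  expect_equal(eligible_at_rank(mid, "genus", cfg, store)$voters,
               "Genus01")
  # generic terminal name never votes, at any rank
  gen <- mk_hit(taxid = f$generic)
  expect_equal(length(eligible_at_rank(gen, "class", cfg,
                                       store)$voters), 0L)
  expect_equal(eligible_at_rank(gen, "class", cfg,
                                store)$generic_ignored, 1L)
  # empty input
  empty <- eligible_at_rank(mk_hit()[0], "species", cfg, store)
  expect_equal(length(empty$voters), 0L)
  expect_equal(empty$generic_ignored, 0L)
})

test_that("tallying picks strict pluralities and refuses ties", {
  rv <- tally(c(rep("A", 7), rep("B", 3)), "species")
  expect_equal(rv$winner, "A")
  expect_equal(rv$winner_fraction, 0.7)
  expect_equal(rv$eligible, 10L)
  tie <- tally(c(rep("A", 5), rep("B", 5)), "genus")
  expect_true(is.na(tie$winner))
  empty <- tally(character(0))
  expect_equal(empty$eligible, 0L)
  expect_true(is.na(empty$winner))
})

test_that("random tallies agree with a brute-force max-count scan", {
  set.seed(17)
  for (rep in 1:50) {
    voters <- sample(LETTERS[1:4], sample(1:50, 1), replace = TRUE)
    rv <- tally(voters)
    counts <- vapply(unique(voters), function(v) sum(voters == v), 1L)
    top <- names(counts)[counts == max(counts)]
    if (length(top) == 1) {
      expect_equal(rv$winner, top)
      expect_equal(rv$winner_fraction, max(counts) / length(voters))
    } else {
      expect_true(is.na(rv$winner))
    }
    expect_equal(sum(rv$votes), length(voters))
  }
})

test_that("unanimous species-level hits classify at species", {
  cfg <- classifier_config("its")
  f <- fx()
  hits <- data.table::rbindlist(lapply(1:10, function(i)
    mk_hit(acc = paste0("A", i), taxid = f$sp1)))
  cls <- classify_query(hits, cfg, fixture_store())
  expect_equal(cls$status, "classified")
  expect_equal(cls$accepted_rank, "species")
  expect_equal(cls$confidence, 1.0)
  expect_false(anyNA(cls$standardized))
  expect_equal(cls$standardized[["genus"]], "Genus01")
})

test_that("a species tie falls back to the shared higher rank", {
  cfg <- classifier_config("its")
  f <- fx()
  # two species of different genera under the same kingdom: species
  # through phylum all tie or fail majority; kingdom is unanimous
  hits <- mk_hits(
    mk_hit(acc = "a", taxid = f$sp1), mk_hit(acc = "b", taxid = f$sp1),
    mk_hit(acc = "c", taxid = f$sp2), mk_hit(acc = "d", taxid = f$sp2))
  cls <- classify_query(hits, cfg, fixture_store())
  expect_equal(cls$status, "classified")
  expect_equal(cls$accepted_rank, "kingdom")
  expect_equal(cls$standardized[["kingdom"]], "Fungi")
  expect_true(is.na(cls$standardized[["phylum"]]))
  # the vote log walked species up to kingdom
  expect_equal(vapply(cls$vote_log, `[[`, "", "rank"),
               c("species", "genus", "family", "order", "class",
                 "phylum", "kingdom"))
})

test_that("generic-dominated queries are unassigned; without the generic hits they classify at class", {
  cfg <- classifier_config("its")
  f <- fx()
  generic_hits <- data.table::rbindlist(lapply(1:8, function(i)
    mk_hit(acc = paste0("g", i), taxid = f$generic)))
  real_hits <- mk_hits(mk_hit(acc = "r1", taxid = f$class1),
                       mk_hit(acc = "r2", taxid = f$class1))
  cls <- classify_query(rbind(generic_hits, real_hits), cfg,
                        fixture_store())
  expect_equal(cls$status, "unclassified_too_generic")
  cls2 <- classify_query(real_hits, cfg, fixture_store())
  expect_equal(cls2$status, "classified")
  expect_equal(cls2$accepted_rank, "class")
  expect_equal(cls2$standardized[["class"]], "Class01")
  expect_true(is.na(cls2$standardized[["order"]]))
})

test_that("all-sub-coverage hit sets are unclassified", {
  cfg <- classifier_config("its")
  f <- fx()
  hits <- data.table::rbindlist(lapply(1:12, function(i)
    mk_hit(acc = paste0("s", i), taxid = f$sp1, qend = 60L)))
  cls <- classify_query(hits, cfg, fixture_store())
  expect_equal(cls$status, "unclassified_low_coverage")
})

test_that("rank-gap lineages classify with blank intermediate slots", {
  cfg <- classifier_config("its")
  f <- fx()
  hits <- data.table::rbindlist(lapply(1:5, function(i)
    mk_hit(acc = paste0("g", i), taxid = f$gap_sp)))
  cls <- classify_query(hits, cfg, fixture_store())
  expect_equal(cls$status, "classified")
  expect_equal(cls$accepted_rank, "species")
  expect_equal(unname(is.na(cls$standardized)),
               c(FALSE, FALSE, FALSE, TRUE, TRUE, TRUE, FALSE, FALSE))
})

test_that("queries with no hits report a status, not an error", {
  cls <- classify_query(mk_hit()[0], classifier_config("its"),
                        fixture_store(), query_id = "lonely")
  expect_equal(cls$status, "unclassified_no_hits")
  expect_equal(cls$query_id, "lonely")
  expect_true(nzchar(cls$message))
})

test_that("batch classification preserves query order and composes", {
  cfg <- classifier_config("its")
  f <- fx()
  hits <- rbind(
    mk_hits(mk_hit("qA", "a1", taxid = f$sp1),
            mk_hit("qA", "a2", taxid = f$sp1)),
    mk_hits(mk_hit("qB", "b1", taxid = f$sp2)))
  res <- classify_batch(hits, cfg, fixture_store(),
                        query_ids = c("qA", "ghost", "qB"))
  expect_equal(names(res), c("qA", "ghost", "qB"))
  expect_equal(res$ghost$status, "unclassified_no_hits")
  # row order invariance
  set.seed(5)
  shuffled <- hits[sample(nrow(hits))]
  res2 <- classify_batch(shuffled, cfg, fixture_store(),
                         query_ids = c("qA", "ghost", "qB"))
  expect_identical(res, res2)
  # equals query-by-query classification
  solo <- classify_query(hits[hits$query_id == "qB"], cfg,
                         fixture_store())
  expect_identical(res$qB, solo)
})

test_that("classification is deterministic and internally consistent", {
  cfg <- classifier_config("its")
  store <- fixture_store()
  set.seed(99)
  for (rep in 1:40) {
    hits <- random_hit_table()
    cls <- classify_query(hits, cfg, store, query_id = "q")
    expect_identical(cls, classify_query(hits, cfg, store,
                                         query_id = "q"))
    # status/accepted_rank/standardized linkage
    if (cls$status == "classified") {
      expect_false(is.na(cls$accepted_rank))
      expect_false(is.na(cls$standardized[[cls$accepted_rank]]))
      # winner fraction strictly exceeds the rank's majority threshold
      last <- cls$vote_log[[length(cls$vote_log)]]
      expect_equal(last$rank, cls$accepted_rank)
      expect_gt(last$winner_fraction,
                taxvote:::.majority_at_rank(cfg, cls$accepted_rank))
      # lineage coherence: filled slots match the winning taxon's chain
      expect_identical(cls$standardized,
                       cls$full_lineage$standardized)
    } else {
      expect_true(is.na(cls$accepted_rank))
      expect_true(all(is.na(cls$standardized)))
    }
    # vote conservation at every attempted rank
    n_passing <- nrow(filter_hits(hits, cfg)$passing)
    for (rv in cls$vote_log) {
      expect_equal(sum(rv$votes) + rv$generic_ignored +
                     rv$identity_excluded, n_passing)
      expect_equal(rv$eligible, sum(rv$votes))
    }
  }
})

test_that("lowering majority thresholds never accepts at a higher rank", {
  base <- classifier_config("its")
  lax <- classifier_config("its", majority_low = 0.10,
                           majority_high = 0.10)
  store <- fixture_store()
  rank_depth <- function(r) match(r, rev(standard_ranks())) # 1 = species
  set.seed(123)
  for (rep in 1:40) {
    hits <- random_hit_table()
    a <- classify_query(hits, base, store, query_id = "q")
    b <- classify_query(hits, lax, store, query_id = "q")
    if (a$status == "classified") {
      expect_equal(b$status, "classified")
      expect_lte(rank_depth(b$accepted_rank),
                 rank_depth(a$accepted_rank))
    }
  }
})

test_that("randomized hit tables match the brute-force reference", {
  cfg <- classifier_config("its")
  store <- fixture_store()
  truth <- fixture_tax()$truth
  set.seed(2024)
  for (rep in 1:60) {
    hits <- random_hit_table()
    got <- classify_query(hits, cfg, store, query_id = "q")
    want <- oracle_classify(as.data.frame(hits), cfg, truth)
    expect_equal(got$status, want$status)
    expect_equal(got$accepted_rank, want$accepted_rank)
    if (got$status == "classified")
      expect_equal(unname(got$standardized),
                   unname(want$standardized))
  }
})
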