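# Status messages written to the report files for unclassified queries.
.STATUS_MSG <- c(
  unclassified_no_hits = "No BLAST hits for this query",
  unclassified_low_coverage =
    "Too few hits passed the coverage/identity filters",
  unclassified_too_generic =
    "Generic or rank-free annotations exceed the allowed fraction",
  unclassified_no_consensus = "No rank reached the required majority")

#' Quality-filter a query's hits
#'
#' Partitions hits into those eligible to vote and those rejected. A hit
#' passes when its query coverage is at least `min_coverage`, its percent
#' identity is at least `identity_other` (the global floor; the stricter
#' species/genus thresholds act later, per rank), and its subject
#' accession resolved to a known taxon. Each rejected hit carries one
#' reason, assessed in order: `low_coverage`, `low_identity`,
#' `unresolved_taxon`.
#'
#' @param hits Hit table for a single query (deduplicated and capped).
#' @param cfg A [classifier_config()].
#' @return List with `passing` (hit table) and `rejected` (hit table with
#'   a `reason` column).
#' @export
filter_hits <- function(hits, cfg) {
  hits <- as.data.table(hits)
  cov_ok <- query_coverage(hits) >= cfg$min_coverage
  id_ok <- hits$percent_identity >= cfg$identity_other
  tax_ok <- !is.na(hits$taxid)
  pass <- cov_ok & id_ok & tax_ok
  reason <- rep(NA_character_, nrow(hits))
  reason[!tax_ok] <- "unresolved_taxon"
  reason[!id_ok] <- "low_identity"
  reason[!cov_ok] <- "low_coverage"
  rejected <- hits[!pass]
  rejected$reason <- reason[!pass]
  list(passing = hits[pass], rejected = rejected)
}

# Per-hit taxon annotations needed repeatedly during voting: the
# standardized name at each of the 8 ranks, the terminal scientific name
# (the hit's own node), and whether that name is generic.
.annotate_hits <- function(passing, cfg, store) {
  if (nrow(passing) == 0L) {
    std <- matrix(NA_character_, 0L, 8L,
                  dimnames = list(NULL, .STANDARD_RANKS))
    return(list(std = std, terminal_name = character(0),
                terminal_generic = logical(0), all_blank = logical(0),
                identity = numeric(0)))
  }
  utx <- unique(passing$taxid)
  lins <- lapply(utx, function(tx) lineage_of(store, tx))
  std <- do.call(rbind, lapply(lins, `[[`, "standardized"))
  term <- vapply(lins, function(l) l$nodes$name[nrow(l$nodes)], "")
  idx <- match(passing$taxid, utx)
  list(std = std[idx, , drop = FALSE],
       terminal_name = term[idx],
       terminal_generic = is_generic(term, cfg$generics)[idx],
       all_blank = apply(std, 1L, function(r) all(is.na(r)))[idx],
       identity = passing$percent_identity)
}

#' Determine which hits vote at a rank
#'
#' A hit votes at a rank when (a) its identity meets the rank's threshold
#' (`identity_species` at species, `identity_genus` at genus,
#' `identity_other` elsewhere), (b) its standardized lineage names that
#' rank, and (c) its terminal scientific name is not generic. Hits that
#' clear (a) but fail (b) or (c) — e.g. kingdom-only database entries
#' voted at species, or "uncultured ..." annotations — are counted as
#' ignored generic/partial assignments at this rank; they re-enter voting
#' at higher ranks their lineage does name.
#'
#' @param passing Filter-passing hit table (see [filter_hits()]).
#' @param rank One of the 8 standardized ranks.
#' @param cfg A [classifier_config()].
#' @param store A `taxonomy_store`.
#' @return List with `voters` (character vector: the name at `rank` of
#'   each voting hit), `generic_ignored` and `identity_excluded` counts.
#' @export
eligible_at_rank <- function(passing, rank, cfg, store) {
  stopifnot(rank %in% .STANDARD_RANKS)
  ann <- .annotate_hits(passing, cfg, store)
  .eligible_at_rank_ann(ann, rank, cfg)
}

.eligible_at_rank_ann <- function(ann, rank, cfg) {
  n <- length(ann$terminal_name)
  if (n == 0L)
    return(list(voters = character(0), generic_ignored = 0L,
                identity_excluded = 0L))
  id_ok <- ann$identity >= .identity_at_rank(cfg, rank)
  named <- !is.na(ann$std[, rank])
  informative <- !ann$terminal_generic
  votes_here <- id_ok & named & informative
  list(voters = unname(ann$std[votes_here, rank]),
       generic_ignored = sum(id_ok & !votes_here),
       identity_excluded = sum(!id_ok))
}

#' Tally votes at one rank
#'
#' One vote per voter for its taxon name at the rank. The winner is the
#' unique name with the strictly greatest count; a tie yields no winner
#' (voting then proceeds to the next higher rank). The winner fraction is
#' the winner's votes over the number of eligible voters.
#'
#' @param voters Character vector of names voted for.
#' @param rank Rank label recorded in the result.
#' @param generic_ignored,identity_excluded Counts carried into the vote
#'   record for the log.
#' @return A `rank_vote` object: rank, eligible count, named vote counts,
#'   winner (or `NA`), winner fraction (or `NA`), exclusion counts.
#' @export
tally <- function(voters, rank = NA_character_, generic_ignored = 0L,
                  identity_excluded = 0L) {
  eligible <- length(voters)
  if (eligible == 0L) {
    votes <- integer(0)
    winner <- NA_character_
    frac <- NA_real_
  } else {
    tab <- table(voters)
    votes <- stats::setNames(as.integer(tab), names(tab))
    top <- max(votes)
    leaders <- names(votes)[votes == top]
    if (length(leaders) == 1L) {
      winner <- leaders
      frac <- top / eligible
    } else {
      winner <- NA_character_
      frac <- NA_real_
    }
  }
  structure(list(rank = rank, eligible = eligible, votes = votes,
                 generic_ignored = as.integer(generic_ignored),
                 identity_excluded = as.integer(identity_excluded),
                 winner = winner, winner_fraction = frac),
            class = "rank_vote")
}

#' @export
print.rank_vote <- function(x, ...) {
  cat("<rank_vote> ", x$rank, ": ", x$eligible, " eligible, winner ",
      if (is.na(x$winner)) "none" else
        sprintf("%s (%.2f)", x$winner, x$winner_fraction),
      ", ", x$generic_ignored, " generic ignored\n", sep = "")
  invisible(x)
}

.make_classification <- function(query_id, status, accepted_rank = NA_character_,
                                 standardized = NULL, full_lineage = NULL,
                                 vote_log = list(), confidence = 0) {
  if (is.null(standardized))
    standardized <- stats::setNames(rep(NA_character_, 8L), .STANDARD_RANKS)
  message <- if (status == "classified") "" else .STATUS_MSG[[status]]
  structure(list(query_id = query_id, status = status,
                 accepted_rank = accepted_rank,
                 standardized = standardized, full_lineage = full_lineage,
                 vote_log = vote_log, confidence = confidence,
                 message = message),
            class = "classification")
}

#' @export
print.classification <- function(x, ...) {
  if (x$status == "classified") {
    filled <- x$standardized[!is.na(x$standardized)]
    cat("<classification> ", x$query_id, ": ", x$accepted_rank, " '",
        x$standardized[[x$accepted_rank]], "' (confidence ",
        sprintf("%.2f", x$confidence), ")\n  ",
        paste(filled, collapse = "; "), "\n", sep = "")
  } else {
    cat("<classification> ", x$query_id, ": ", x$status, " — ",
        x$message, "\n", sep = "")
  }
  invisible(x)
}

#' Classify one query by bottom-up consensus voting
#'
#' The full per-query pipeline: (1) no hits at all leaves the query
#' unclassified; (2) hits are coverage/identity filtered
#' ([filter_hits()]); too few survivors leaves it unclassified; (3) if
#' the fraction of surviving hits with generic terminal annotations or
#' entirely rank-free lineages exceeds `generic_fraction_max`, the query
#' is unassigned; (4) otherwise voting starts at species and walks up to
#' domain: at each rank the eligible hits vote and the winning name is
#' accepted if its fraction strictly exceeds the rank's majority
#' threshold (`majority_low` through family, `majority_high` from order
#' up). Acceptance at a rank fills that slot and every one above it from
#' the winner's lineage; lower slots stay blank. (5) If no rank wins,
#' the query is unclassified for lack of consensus.
#'
#' @param hits Hit table for one query (deduplicated and capped; may have
#'   zero rows).
#' @param cfg A [classifier_config()].
#' @param store A `taxonomy_store`.
#' @param query_id Query name; defaults to the table's query_id.
#' @return A `classification` object.
#' @export
classify_query <- function(hits, cfg, store, query_id = NULL) {
  hits <- as.data.table(hits)
  if (is.null(query_id))
    query_id <- if (nrow(hits)) hits$query_id[1L] else "<unknown>"
  if (nrow(hits) == 0L)
    return(.make_classification(query_id, "unclassified_no_hits"))

  flt <- filter_hits(hits, cfg)
  passing <- flt$passing
  if (nrow(passing) < cfg$min_passing_hits)
    return(.make_classification(query_id, "unclassified_low_coverage"))

  ann <- .annotate_hits(passing, cfg, store)
  generic_fraction <- mean(ann$terminal_generic | ann$all_blank)
  if (generic_fraction > cfg$generic_fraction_max)
    return(.make_classification(query_id, "unclassified_too_generic"))

  vote_log <- list()
  for (rank in rev(.STANDARD_RANKS)) {
    el <- .eligible_at_rank_ann(ann, rank, cfg)
    rv <- tally(el$voters, rank, el$generic_ignored, el$identity_excluded)
    vote_log[[length(vote_log) + 1L]] <- rv
    if (!is.na(rv$winner) &&
        rv$winner_fraction > .majority_at_rank(cfg, rank)) {
      # locate the winning taxon: the rank-level node on the lineage of
      # any voter that voted for the winner
      named <- !is.na(ann$std[, rank]) & ann$std[, rank] == rv$winner &
        ann$identity >= .identity_at_rank(cfg, rank) & !ann$terminal_generic
      voter_idx <- which(named)[1L]
      winner_taxid <- lineage_of(store, passing$taxid[voter_idx])$taxids[[rank]]
      full <- lineage_of(store, winner_taxid)
      return(.make_classification(
        query_id, "classified", accepted_rank = rank,
        standardized = full$standardized, full_lineage = full,
        vote_log = vote_log, confidence = rv$winner_fraction))
    }
  }
  .make_classification(query_id, "unclassified_no_consensus",
                       vote_log = vote_log)
}

#' Classify every query in a hit table
#'
#' Splits the table by query, deduplicates HSPs, caps the candidate set
#' at `cfg$max_hits` per query, and classifies each query independently.
#' Queries listed in `query_ids` but absent from the table are reported
#' as unclassified (no hits). Results follow `query_ids` order when
#' given, otherwise first appearance in the table; row order within the
#' table does not affect any result.
#'
#' @param hits Hit table (multiple queries).
#' @param cfg A [classifier_config()].
#' @param store A `taxonomy_store`.
#' @param query_ids Optional character vector fixing the query set/order.
#' @return Named list of `classification` objects.
#' @export
classify_batch <- function(hits, cfg, store, query_ids = NULL) {
  hits <- dedupe_best_hsp(as.data.table(hits))
  hits <- cap_hits(hits, cfg$max_hits)
  ids <- if (is.null(query_ids)) unique(hits$query_id) else query_ids
  out <- lapply(ids, function(qid)
    classify_query(hits[hits$query_id == qid], cfg, store, query_id = qid))
  stats::setNames(out, ids)
}
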