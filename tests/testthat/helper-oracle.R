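# Independent brute-force reference implementations. These re-derive
# every rule from scratch with plain loops over the raw truth table of a
# toy taxonomy (taxid/parent/rank/name rows), deliberately sharing no
# code with the package internals.

ORACLE_RANKS <- c("domain", "kingdom", "phylum", "class", "order",
                  "family", "genus", "species")

# Parent-chain walk on the raw truth table, root-first.
oracle_chain <- function(truth, taxid) {
  chain <- integer(0)
  cur <- taxid
  repeat {
    chain <- c(cur, chain)
    row <- truth[truth$taxid == cur, ]
    if (nrow(row) != 1) stop("oracle: unknown taxid ", cur)
    if (row$parent_taxid == cur) break
    cur <- row$parent_taxid
  }
  chain
}

# Standardized 8-slot names for a taxid, NA = blank.
oracle_std <- function(truth, taxid) {
  out <- rep(NA_character_, 8)
  names(out) <- ORACLE_RANKS
  for (tx in oracle_chain(truth, taxid)) {
    row <- truth[truth$taxid == tx, ]
    r <- row$rank
    if (r == "superkingdom") r <- "domain"
    if (r %in% ORACLE_RANKS) out[r] <- row$name
  }
  out
}

oracle_name <- function(truth, taxid) truth$name[truth$taxid == taxid]

oracle_is_generic <- function(name, keywords) {
  ok <- FALSE
  for (k in keywords)
    if (grepl(tolower(k), tolower(name), fixed = TRUE)) ok <- TRUE
  ok
}

# Full re-derivation of the per-query decision. Returns status,
# accepted_rank, winner name and the standardized lineage.
oracle_classify <- function(hits, cfg, truth) {
  blank <- structure(rep(NA_character_, 8), names = ORACLE_RANKS)
  result <- function(status, rank = NA_character_, std = blank)
    list(status = status, accepted_rank = rank, standardized = std)
  if (nrow(hits) == 0) return(result("unclassified_no_hits"))

  # step 1: coverage / global identity / resolvable taxid
  keep <- logical(nrow(hits))
  for (i in seq_len(nrow(hits))) {
    cov <- (abs(hits$qend[i] - hits$qstart[i]) + 1) / hits$qlen[i]
    keep[i] <- cov >= cfg$min_coverage &&
      hits$percent_identity[i] >= cfg$identity_other &&
      !is.na(hits$taxid[i])
  }
  passing <- hits[keep, ]
  if (nrow(passing) < cfg$min_passing_hits)
    return(result("unclassified_low_coverage"))

  # step 2: global generic fraction
  n_generic <- 0
  for (i in seq_len(nrow(passing))) {
    nm <- oracle_name(truth, passing$taxid[i])
    std <- oracle_std(truth, passing$taxid[i])
    if (oracle_is_generic(nm, cfg$generics) || all(is.na(std)))
      n_generic <- n_generic + 1
  }
  if (n_generic / nrow(passing) > cfg$generic_fraction_max)
    return(result("unclassified_too_generic"))

  # step 3: bottom-up voting
  for (rank in rev(ORACLE_RANKS)) {
    thr <- if (rank == "species") cfg$identity_species
    else if (rank == "genus") cfg$identity_genus
    else cfg$identity_other
    maj <- if (rank %in% c("species", "genus", "family"))
      cfg$majority_low else cfg$majority_high
    ballots <- character(0)
    ballot_taxid <- integer(0)
    for (i in seq_len(nrow(passing))) {
      if (passing$percent_identity[i] < thr) next
      nm <- oracle_name(truth, passing$taxid[i])
      if (oracle_is_generic(nm, cfg$generics)) next
      std <- oracle_std(truth, passing$taxid[i])
      if (is.na(std[rank])) next
      ballots <- c(ballots, std[rank])
      ballot_taxid <- c(ballot_taxid, passing$taxid[i])
    }
    if (!length(ballots)) next
    counts <- table(ballots)
    top <- max(counts)
    leaders <- names(counts)[counts == top]
    if (length(leaders) != 1) next
    if (top / length(ballots) <= maj) next
    # accepted: slots at and above this rank from the winner's lineage
    win_tax <- ballot_taxid[ballots == leaders][1]
    std <- oracle_std(truth, win_tax)
    cut <- match(rank, ORACLE_RANKS)
    if (cut < 8) std[(cut + 1):8] <- NA_character_
    return(result("classified", rank, std))
  }
  result("unclassified_no_consensus")
}

# Brute-force semi-global primer distance: expand every degenerate
# position into concrete bases, enumerate every substring of the target
# (plus the empty one), take the minimum Levenshtein distance via
# utils::adist.
IUPAC_TABLE <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T"))

oracle_expand_primer <- function(primer) {
  sets <- IUPAC_TABLE[strsplit(primer, "")[[1]]]
  apply(do.call(expand.grid, sets), 1, paste, collapse = "")
}

oracle_substrings <- function(target) {
  n <- nchar(target)
  subs <- "" # the empty placement: primer all-inserted
  for (i in seq_len(n))
    for (j in i:n)
      subs <- c(subs, substr(target, i, j))
  subs
}

oracle_primer_distance <- function(primer, target) {
  min(utils::adist(oracle_expand_primer(primer),
                   oracle_substrings(target)))
}

oracle_hamming_distance <- function(primer, target) {
  m <- nchar(primer)
  n <- nchar(target)
  p <- strsplit(primer, "")[[1]]
  best <- m
  for (s in 0:(n - m)) {
    d <- 0
    for (i in seq_len(m)) {
      tb <- substr(target, s + i, s + i)
      if (!(tb %in% IUPAC_TABLE[[p[i]]])) d <- d + 1
    }
    best <- min(best, d)
  }
  best
}

# Plain (non-degenerate) semi-global edit distance for read-vs-reference
# checks: min Levenshtein over all substrings of the reference.
oracle_sg_distance <- function(read, ref) {
  min(utils::adist(read, oracle_substrings(ref)))
}
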