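# Serialize the standardized lineage of one classification: filled slots
# root-first up to the accepted rank, interior blank slots kept as empty
# components so rank positions stay unambiguous; trailing blanks dropped.
.std_lineage_string <- function(cls) {
  std <- cls$standardized
  filled <- which(!is.na(std))
  if (!length(filled)) return("")
  std <- std[seq_len(max(filled))]
  paste(ifelse(is.na(std), "", std), collapse = ";")
}

.full_lineage_string <- function(cls) {
  if (is.null(cls$full_lineage)) return("")
  paste(cls$full_lineage$nodes$name, collapse = ";")
}

.write_taxonomy_rows <- function(classifications, path, lineage_fun,
                                 header) {
  rows <- vapply(classifications, function(cls) {
    if (cls$status == "classified")
      paste(cls$query_id, lineage_fun(cls),
            format(cls$confidence, digits = 6), "", sep = "\t")
    else
      paste(cls$query_id, "Unclassified", "0", cls$message, sep = "\t")
  }, "")
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(c(header, rows), con)
  invisible(path)
}

#' Write the standardized-taxonomy output file
#'
#' One tab-separated row per query: query id, semicolon-joined
#' standardized lineage (root-first; a blank slot between filled slots is
#' kept as an empty component; slots below the accepted rank are
#' omitted), the winner fraction at the accepted rank as confidence, and
#' a note column. Unclassified queries carry the literal token
#' `Unclassified`, confidence 0, and their status message in the note.
#' The layout matches the QIIME taxonomy-assignment convention
#' (query, lineage string, confidence).
#'
#' @param classifications List of `classification` objects
#'   (see [classify_batch()]).
#' @param path Output path.
#' @export
write_standard_taxonomy <- function(classifications, path) {
  .write_taxonomy_rows(
    classifications, path, .std_lineage_string,
    "#query_id\tstandardized_taxonomy\tconfidence\tnote")
}

#' Write the full-taxonomy output file
#'
#' As [write_standard_taxonomy()], but the lineage string joins every
#' node of the winning taxon's full lineage — subtaxa, supertaxa and
#' unranked intermediate levels included.
#'
#' @inheritParams write_standard_taxonomy
#' @export
write_full_taxonomy <- function(classifications, path) {
  .write_taxonomy_rows(
    classifications, path, .full_lineage_string,
    "#query_id\tfull_taxonomy\tconfidence\tnote")
}

#' Write the voting log
#'
#' One tab-separated row per rank attempted for each query: query id,
#' rank, eligible voter count, winner (or `-` on a tie / empty rank),
#' winner votes, winner fraction, hits ignored at the rank for
#' generic/partial annotation, hits excluded by the rank's identity
#' threshold, and whether the rank was accepted. A terminal `FINAL` row
#' per query records the overall status. Queries unclassified before any
#' vote was cast (no hits, filtered out, or too generic) get only their
#' `FINAL` row.
#'
#' @inheritParams write_standard_taxonomy
#' @export
write_vote_log <- function(classifications, path) {
  header <- paste("#query_id", "rank", "eligible", "winner",
                  "winner_votes", "winner_fraction", "generic_ignored",
                  "identity_excluded", "accepted", sep = "\t")
  rows <- unlist(lapply(classifications, function(cls) {
    rank_rows <- vapply(cls$vote_log, function(rv) {
      accepted <- cls$status == "classified" &&
        identical(rv$rank, cls$accepted_rank)
      winner_votes <- if (is.na(rv$winner)) 0L else
        rv$votes[[rv$winner]]
      paste(cls$query_id, rv$rank, rv$eligible,
            if (is.na(rv$winner)) "-" else rv$winner,
            winner_votes,
            if (is.na(rv$winner_fraction)) "0" else
              format(rv$winner_fraction, digits = 6),
            rv$generic_ignored, rv$identity_excluded,
            if (accepted) "yes" else "no", sep = "\t")
    }, "")
    final <- paste(cls$query_id, "FINAL", "-", cls$status, "-", "-", "-",
                   "-", if (cls$status == "classified") "yes" else "no",
                   sep = "\t")
    c(rank_rows, final)
  }), use.names = FALSE)
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(c(header, rows), con)
  invisible(path)
}

#' Write all three report files
#'
#' Convenience wrapper producing `standard_taxonomy.tsv`,
#' `full_taxonomy.tsv` and `voting_log.tsv` in `dir`.
#'
#' @param classifications List of `classification` objects.
#' @param dir Output directory (created if absent).
#' @return Named character vector of the three paths, invisibly.
#' @export
write_reports <- function(classifications, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(
    standard = file.path(dir, "standard_taxonomy.tsv"),
    full = file.path(dir, "full_taxonomy.tsv"),
    votes = file.path(dir, "voting_log.tsv"))
  write_standard_taxonomy(classifications, paths[["standard"]])
  write_full_taxonomy(classifications, paths[["full"]])
  write_vote_log(classifications, paths[["votes"]])
  invisible(paths)
}
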