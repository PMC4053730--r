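# Column layout: standard 12-column tabular BLAST output (-outfmt 6)
# extended with query length as column 13. qlen is required because query
# coverage cannot be computed without it.
.BLAST_COLS <- c("query_id", "subject_accession", "percent_identity",
                 "alignment_length", "mismatches", "gapopen",
                 "qstart", "qend", "sstart", "send",
                 "evalue", "bitscore", "qlen")

#' Parse tabular BLAST output into a hit table
#'
#' Reads 13-column tab-separated alignment output: the standard 12 tabular
#' columns (query id, subject accession, percent identity, alignment
#' length, mismatches, gap opens, qstart, qend, sstart, send, e-value,
#' bit score) plus query length as column 13. Lines starting with `#` are
#' skipped; trailing columns beyond 13 are ignored. Subject accessions
#' are resolved to taxids when a mapping is supplied; unresolved hits get
#' `NA` taxid (dropped later with a logged reason, never an error).
#'
#' @param source Path, connection, or character vector of lines.
#' @param mapping Optional accession-to-taxid map
#'   (see [load_accession_map()]).
#' @return A `data.table` with the 13 columns above plus `taxid`.
#' @export
parse_blast_table <- function(source, mapping = NULL) {
  lines <- .read_source_lines(source)
  keep <- nzchar(lines) & !startsWith(lines, "#")
  lineno <- which(keep)
  lines <- lines[keep]
  if (!length(lines)) return(.empty_hits())
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- vapply(parts, length, 1L)
  if (any(nf < 13L)) {
    i <- which(nf < 13L)[1L]
    if (nf[i] >= 12L)
      stop("line ", lineno[i], ": only ", nf[i], " columns; the 13th ",
           "column (query length, qlen) is required. Expected columns: ",
           paste(.BLAST_COLS, collapse = ", "))
    stop("line ", lineno[i], ": malformed row with ", nf[i],
         " columns; expected 13 (", paste(.BLAST_COLS, collapse = ", "), ")")
  }
  fld <- function(i) vapply(parts, `[[`, "", i)
  num <- function(i, what) {
    v <- suppressWarnings(as.numeric(fld(i)))
    if (anyNA(v))
      stop("line ", lineno[which(is.na(v))[1L]], ": non-numeric ", what)
    v
  }
  hits <- data.table(
    query_id = fld(1L),
    subject_accession = fld(2L),
    percent_identity = num(3L, "percent_identity"),
    alignment_length = as.integer(num(4L, "alignment_length")),
    mismatches = as.integer(num(5L, "mismatches")),
    gapopen = as.integer(num(6L, "gapopen")),
    qstart = as.integer(num(7L, "qstart")),
    qend = as.integer(num(8L, "qend")),
    sstart = as.integer(num(9L, "sstart")),
    send = as.integer(num(10L, "send")),
    evalue = num(11L, "evalue"),
    bitscore = num(12L, "bitscore"),
    qlen = as.integer(num(13L, "qlen")))
  bad <- which(hits$alignment_length < 1L | hits$qlen < 1L |
                 pmin(hits$qstart, hits$qend) < 1L |
                 pmax(hits$qstart, hits$qend) > hits$qlen |
                 hits$percent_identity < 0 | hits$percent_identity > 100)
  if (length(bad))
    stop("line ", lineno[bad[1L]], ": hit violates coordinate/identity ",
         "invariants (1 <= qstart,qend <= qlen; identity in [0,100])")
  hits$taxid <- if (is.null(mapping)) NA_integer_ else
    resolve_accession(hits$subject_accession, mapping)
  hits[]
}

.empty_hits <- function() {
  data.table(query_id = character(), subject_accession = character(),
             percent_identity = numeric(), alignment_length = integer(),
             mismatches = integer(), gapopen = integer(),
             qstart = integer(), qend = integer(),
             sstart = integer(), send = integer(),
             evalue = numeric(), bitscore = numeric(), qlen = integer(),
             taxid = integer())
}

#' Write a hit table in the 13-column tabular dialect
#'
#' Inverse of [parse_blast_table()]; the `taxid` column is not written
#' (it is derived from the accession map on read).
#'
#' @param hits Hit table.
#' @param path Output path.
#' @export
write_blast_table <- function(hits, path) {
  out <- as.data.table(hits)[, .BLAST_COLS, with = FALSE]
  fwrite(out, path, sep = "\t", col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Query coverage of a hit
#'
#' Fraction of the query spanned by the aligned region:
#' `(|qend - qstart| + 1) / qlen`. Measured on the query span rather than
#' the alignment length so subject-side gaps cannot inflate coverage;
#' symmetric in qstart/qend (reversed coordinates give the same value).
#'
#' @param hits Hit table (or any data.frame with qstart, qend, qlen).
#' @return Numeric vector of fractions in \[0, 1\].
#' @export
query_coverage <- function(hits) {
  (abs(hits$qend - hits$qstart) + 1L) / hits$qlen
}

#' Collapse multiple HSPs of one subject to the best one
#'
#' Keeps at most one hit per (query, subject accession): the highest
#' bit score, ties broken by higher percent identity, then first seen.
#' The relative input order of surviving rows is preserved and no field
#' of a surviving row is altered — one subject sequence casts one vote.
#'
#' @param hits Hit table.
#' @return Deduplicated hit table.
#' @export
dedupe_best_hsp <- function(hits) {
  hits <- as.data.table(hits)
  if (nrow(hits) < 2L) return(hits)
  ord <- order(hits$query_id, hits$subject_accession,
               -hits$bitscore, -hits$percent_identity,
               seq_len(nrow(hits)))
  first <- ord[!duplicated(hits[ord, .(query_id, subject_accession)])]
  hits[sort(first)]
}

#' Cap the per-query candidate set
#'
#' After HSP deduplication, keeps at most `max_hits` hits per query,
#' preferring higher bit scores (ties: higher identity, then first seen);
#' input order of survivors is preserved.
#'
#' @param hits Hit table.
#' @param max_hits Per-query cap (default 100).
#' @return Capped hit table.
#' @export
cap_hits <- function(hits, max_hits = 100L) {
  hits <- as.data.table(hits)
  if (nrow(hits) == 0L) return(hits)
  ord <- order(-hits$bitscore, -hits$percent_identity, seq_len(nrow(hits)))
  split_idx <- split(ord, hits$query_id[ord])
  keep <- unlist(lapply(split_idx, function(ix) ix[seq_len(min(length(ix),
                                                               max_hits))]),
                 use.names = FALSE)
  hits[sort(keep)]
}
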