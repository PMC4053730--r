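# IUPAC nucleotide alphabet: each symbol names a set of concrete bases.
.IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T"))

#' IUPAC symbol / base compatibility
#'
#' TRUE iff the target base belongs to the primer symbol's base set
#' (e.g. `R` matches `A` and `G`; `N` matches everything).
#'
#' @param primer_symbol One-character IUPAC nucleotide code.
#' @param target_base One of `A`, `C`, `G`, `T`.
#' @return Logical scalar.
#' @export
iupac_compatible <- function(primer_symbol, target_base) {
  set <- .IUPAC_SETS[[toupper(primer_symbol)]]
  if (is.null(set))
    stop("unknown IUPAC symbol: '", primer_symbol, "'")
  if (!target_base %in% c("A", "C", "G", "T"))
    stop("target base must be one of A, C, G, T; got '", target_base, "'")
  toupper(target_base) %in% set
}

.revcomp <- function(seq) {
  chartr("ACGTRYSWKMBDHVN", "TGCAYRSWMKVHDBN",
         paste(rev(strsplit(seq, "")[[1L]]), collapse = ""))
}

#' Best edit distance of a degenerate primer to a target
#'
#' Minimum over all target placements of the semi-global edit distance:
#' the primer is aligned end-to-end, the target locally; substitutions
#' cost 0 when the target base is compatible with the primer's IUPAC
#' symbol and 1 otherwise; insertions and deletions cost 1. With
#' `hamming = TRUE`, indels are disallowed and the minimum mismatch
#' count over full-length target windows is returned (a strict
#' "number of mismatches" reading). With `revcomp = TRUE` the reverse
#' complement of the target is also scanned and the smaller distance
#' returned.
#'
#' @param primer Non-empty IUPAC primer sequence.
#' @param target ACGT target sequence.
#' @param hamming Disallow indels (default FALSE).
#' @param revcomp Also scan the reverse-complement strand
#'   (default FALSE; rRNA reference sets are stranded).
#' @return Integer distance, at most `nchar(primer)`.
#' @export
best_edit_distance <- function(primer, target, hamming = FALSE,
                               revcomp = FALSE) {
  primer <- toupper(primer)
  target <- toupper(target)
  d <- cpp_primer_distance(primer, target, hamming)
  if (revcomp)
    d <- min(d, cpp_primer_distance(primer, .revcomp(target), hamming))
  min(d, nchar(primer))
}

#' Edit-distance profile of a primer across clades
#'
#' Computes the best edit distance of the primer to every target
#' sequence, then, within each clade, the proportion of sequences at
#' each distance — the data behind a primer-complementarity heat map
#' (rows: clades; columns: edit distance; cell: proportion of the
#' clade's taxa at that distance).
#'
#' @param primer IUPAC primer sequence.
#' @param sequences Named character vector of target sequences.
#' @param clades Character vector (same length/names) assigning each
#'   sequence to a clade.
#' @inheritParams best_edit_distance
#' @return A `primer_profile`: `$primer`, `$per_sequence` (data.table:
#'   id, clade, distance), `$per_clade` (data.table: clade, distance,
#'   proportion; proportions sum to 1 within each clade).
#' @export
profile_clades <- function(primer, sequences, clades, hamming = FALSE,
                           revcomp = FALSE) {
  stopifnot(length(sequences) == length(clades), length(sequences) >= 1L)
  dist <- vapply(sequences, best_edit_distance, 0L, primer = primer,
                 hamming = hamming, revcomp = revcomp, USE.NAMES = FALSE)
  per_sequence <- data.table(
    id = names(sequences) %||% as.character(seq_along(sequences)),
    clade = as.character(clades), distance = dist)
  per_clade <- per_sequence[, .(n = .N), by = .(clade, distance)]
  per_clade[, proportion := n / sum(n), by = clade]
  per_clade[, n := NULL]
  setorder(per_clade, clade, distance)
  structure(list(primer = toupper(primer), per_sequence = per_sequence,
                 per_clade = per_clade[]),
            class = "primer_profile")
}

#' @export
print.primer_profile <- function(x, ...) {
  cat("<primer_profile> primer ", x$primer, ", ",
      nrow(x$per_sequence), " sequences in ",
      length(unique(x$per_sequence$clade)), " clades\n", sep = "")
  print(x$per_clade)
  invisible(x)
}

#' Load a sequence-to-clade table
#'
#' Two tab-separated columns (sequence id, clade label); `#` comment
#' lines ignored.
#'
#' @param source Path, connection, or character vector of lines.
#' @return Named character vector (id -> clade).
#' @export
load_clade_table <- function(source) {
  lines <- .read_source_lines(source)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  if (any(vapply(parts, length, 1L) < 2L))
    stop("clade table requires 2 tab-separated columns (id, clade)")
  stats::setNames(vapply(parts, `[[`, "", 2L),
                  vapply(parts, `[[`, "", 1L))
}
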