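#' @useDynLib taxvote, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @import data.table
NULL

# Canonical 8-rank ladder used for voting and standardized reporting,
# ordered root-first. "superkingdom" in NCBI dumps maps onto the domain slot.
.STANDARD_RANKS <- c("domain", "kingdom", "phylum", "class", "order",
                     "family", "genus", "species")

#' Standardized taxonomic ranks
#'
#' The fixed eight-rank ladder (domain, kingdom, phylum, class, order,
#' family, genus, species) used for consensus voting and for the
#' standardized lineage output.
#'
#' @return Character vector of length 8, root-first.
#' @export
standard_ranks <- function() .STANDARD_RANKS

# Split NCBI taxdump dialect lines: fields delimited by "\t|\t",
# records terminated by "\t|". Returns a list of character vectors.
.parse_dmp_lines <- function(lines) {
  lines <- lines[nzchar(lines)]
  lines <- sub("\t\\|$", "", lines)
  strsplit(lines, "\t\\|\t")
}

.read_source_lines <- function(source) {
  if (inherits(source, "connection")) return(readLines(source))
  if (is.character(source) && length(source) == 1L && file.exists(source))
    return(readLines(source))
  # already a character vector of lines
  as.character(source)
}

#' Load a local taxonomy from NCBI taxdump-style tables
#'
#' Builds an offline taxonomy store from `nodes` and `names` tables in the
#' NCBI taxdump dialect (fields separated by tab-pipe-tab, records
#' terminated by tab-pipe). The root is detected as the node that is its
#' own parent. Name rows of class `"scientific name"` become the node
#' name; `"synonym"` (and `"equivalent name"`) rows are attached as
#' synonyms. An optional `merged` table (old taxid, new taxid) lets
#' superseded identifiers resolve to their replacement.
#'
#' @param nodes Path, connection, or character vector of lines for the
#'   nodes table (taxid, parent taxid, rank in the first three fields).
#' @param names Path, connection, or character vector of lines for the
#'   names table (taxid, name, unique name, name class).
#' @param merged Optional path/connection/lines for a merged-taxid table.
#' @return An object of class `taxonomy_store`.
#' @examples
#' nodes <- c("1\t|\t1\t|\tno rank\t|",
#'            "2\t|\t1\t|\tkingdom\t|",
#'            "3\t|\t2\t|\tgenus\t|")
#' nms <- c("1\t|\troot\t|\t\t|\tscientific name\t|",
#'          "2\t|\tFungi\t|\t\t|\tscientific name\t|",
#'          "3\t|\tRhodotorula\t|\t\t|\tscientific name\t|")
#' store <- load_taxdump(nodes, nms)
#' lineage_of(store, 3)
#' @export
load_taxdump <- function(nodes, names, merged = NULL) {
  nf <- .parse_dmp_lines(.read_source_lines(nodes))
  if (length(nf) == 0L) stop("nodes table is empty")
  bad <- which(vapply(nf, length, 1L) < 3L)
  if (length(bad))
    stop("nodes table row ", bad[1L], " has fewer than 3 fields")
  taxid  <- as.integer(vapply(nf, `[[`, "", 1L))
  parent <- as.integer(vapply(nf, `[[`, "", 2L))
  rank   <- vapply(nf, `[[`, "", 3L)
  if (anyNA(taxid) || anyNA(parent))
    stop("non-integer taxid or parent taxid in nodes table")
  if (anyDuplicated(taxid))
    stop("duplicate taxid in nodes table: ", taxid[duplicated(taxid)][1L])

  missing_parent <- setdiff(parent, taxid)
  if (length(missing_parent))
    stop("node references missing parent taxid: ", missing_parent[1L])
  root <- taxid[taxid == parent]
  if (length(root) != 1L)
    stop("expected exactly one root (self-parent) node, found ", length(root))

  mf <- .parse_dmp_lines(.read_source_lines(names))
  ntax <- as.integer(vapply(mf, `[[`, "", 1L))
  ntxt <- vapply(mf, `[[`, "", 2L)
  ncls <- vapply(mf, function(x) if (length(x) >= 4L) x[[4L]] else "", "")

  sci <- ncls == "scientific name"
  sci_name <- ntxt[sci][match(taxid, ntax[sci])]
  if (anyNA(sci_name) || any(!nzchar(sci_name)))
    stop("taxid with no scientific name: ",
         taxid[which(is.na(sci_name) | !nzchar(sci_name))][1L])

  syn_sel <- ncls %in% c("synonym", "equivalent name")
  synonyms <- split(ntxt[syn_sel], ntax[syn_sel])

  nodes_dt <- data.table(taxid = taxid, parent_taxid = parent,
                         rank = rank, scientific_name = sci_name,
                         key = "taxid")

  merged_map <- integer(0)
  if (!is.null(merged)) {
    gf <- .parse_dmp_lines(.read_source_lines(merged))
    if (length(gf)) {
      old <- as.integer(vapply(gf, `[[`, "", 1L))
      new <- as.integer(vapply(gf, `[[`, "", 2L))
      merged_map <- stats::setNames(new, old)
    }
  }

  store <- structure(
    list(nodes = nodes_dt, synonyms = synonyms, root = root,
         merged = merged_map, .lineage_cache = new.env(parent = emptyenv())),
    class = "taxonomy_store")
  # eager cycle check: every parent chain must reach the root
  for (tx in taxid) .walk_to_root(store, tx)
  store
}

#' @export
print.taxonomy_store <- function(x, ...) {
  cat("<taxonomy_store> ", nrow(x$nodes), " nodes, root taxid ", x$root,
      ", ", length(x$synonyms), " taxa with synonyms\n", sep = "")
  invisible(x)
}

# Parent-chain walk, leaf-last; errors on unknown taxid or cycle.
.walk_to_root <- function(store, taxid) {
  n <- nrow(store$nodes)
  chain <- integer(0)
  cur <- as.integer(taxid)
  for (i in seq_len(n + 1L)) {
    row <- store$nodes[list(cur)]
    if (is.na(row$parent_taxid))
      stop("unknown taxid: ", cur)
    chain <- c(cur, chain)
    if (cur == row$parent_taxid) return(chain)
    cur <- row$parent_taxid
  }
  stop("cycle detected in taxonomy at taxid ", taxid)
}

#' Synonyms recorded for a taxon
#' @param store A `taxonomy_store`.
#' @param taxid Integer taxon id.
#' @return Character vector (possibly empty).
#' @export
taxon_synonyms <- function(store, taxid) {
  s <- store$synonyms[[as.character(taxid)]]
  if (is.null(s)) character(0) else s
}

#' Load an accession-to-taxid mapping table
#'
#' Two-column tab-separated text (accession, taxid); lines starting with
#' `#` are ignored. If the store carries a merged-taxid table, mappings to
#' superseded taxids are followed to their replacement.
#'
#' @param source Path, connection, or character vector of lines.
#' @param store Optional `taxonomy_store` whose merged table is applied.
#' @return Named integer vector (accession -> taxid).
#' @export
load_accession_map <- function(source, store = NULL) {
  lines <- .read_source_lines(source)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (!length(lines)) return(stats::setNames(integer(0), character(0)))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  if (any(vapply(parts, length, 1L) < 2L))
    stop("accession map requires 2 tab-separated columns (accession, taxid)")
  acc <- vapply(parts, `[[`, "", 1L)
  tax <- as.integer(vapply(parts, `[[`, "", 2L))
  if (!is.null(store) && length(store$merged)) {
    hit <- match(as.character(tax), names(store$merged))
    tax[!is.na(hit)] <- unname(store$merged[hit[!is.na(hit)]])
  }
  stats::setNames(tax, acc)
}

#' Resolve a sequence accession to a taxon id
#'
#' Version-suffixed accessions (`"ABC123.1"`) fall back to the unversioned
#' key when the exact accession is absent. Unmapped accessions return
#' `NA_integer_` (the "unresolved" sentinel): downstream the classifier
#' drops such hits and logs them rather than failing.
#'
#' @param accession Character vector of accessions.
#' @param mapping Named integer vector from [load_accession_map()].
#' @return Integer vector of taxids, `NA` where unresolved.
#' @export
resolve_accession <- function(accession, mapping) {
  out <- unname(mapping[accession])
  miss <- is.na(out)
  if (any(miss)) {
    bare <- sub("\\.[0-9]+$", "", accession[miss])
    out[miss] <- unname(mapping[bare])
  }
  as.integer(out)
}

# Map a raw rank label to its standardized slot index, or NA.
.rank_slot <- function(rank) {
  rank <- ifelse(rank == "superkingdom", "domain", rank)
  match(rank, .STANDARD_RANKS)
}

# Compute the 8-slot standardized view from a root-first node table.
# Slots are filled only from nodes whose rank label equals the slot rank
# ("superkingdom" counts as domain); deeper nodes win if a rank repeats.
.standardize_nodes <- function(nodes_df) {
  name8 <- stats::setNames(rep(NA_character_, 8L), .STANDARD_RANKS)
  tax8 <- stats::setNames(rep(NA_integer_, 8L), .STANDARD_RANKS)
  slot <- .rank_slot(nodes_df$rank)
  for (i in seq_along(slot)) {
    if (!is.na(slot[i])) {
      name8[slot[i]] <- nodes_df$name[i]
      tax8[slot[i]] <- nodes_df$taxid[i]
    }
  }
  list(names = name8, taxids = tax8)
}

#' Full and standardized lineage of a taxon
#'
#' Walks the parent chain root-first, keeping unranked ("no rank")
#' intermediate nodes, and derives the standardized 8-slot view. A slot is
#' filled only by a node whose rank label equals the slot rank
#' ("superkingdom" fills the domain slot); gaps between filled slots are
#' allowed, mirroring rank jumps in the source taxonomy.
#'
#' @param store A `taxonomy_store`.
#' @param taxid Taxon id present in the store.
#' @return A `lineage` object: `$nodes` (data.frame taxid/rank/name,
#'   root-first), `$standardized` (named character(8), `NA` = blank slot),
#'   `$taxids` (named integer(8)).
#' @export
lineage_of <- function(store, taxid) {
  key <- as.character(taxid)
  cached <- store$.lineage_cache[[key]]
  if (!is.null(cached)) return(cached)
  chain <- .walk_to_root(store, taxid)
  rows <- store$nodes[list(chain)]
  nodes_df <- data.frame(taxid = rows$taxid, rank = rows$rank,
                         name = rows$scientific_name,
                         stringsAsFactors = FALSE)
  std <- .standardize_nodes(nodes_df)
  lin <- structure(list(nodes = nodes_df, standardized = std$names,
                        taxids = std$taxids),
                   class = "lineage")
  store$.lineage_cache[[key]] <- lin
  lin
}

#' @export
print.lineage <- function(x, ...) {
  full <- paste(x$nodes$name, collapse = "; ")
  std <- ifelse(is.na(x$standardized), "", x$standardized)
  cat("<lineage> ", full, "\n  standardized: ",
      paste(std, collapse = ";"), "\n", sep = "")
  invisible(x)
}

#' Most specific filled standardized rank
#'
#' @param lineage A `lineage` object.
#' @return The lowest (most specific) of the 8 standardized ranks that is
#'   filled, or `NA_character_` if all slots are blank (e.g. the root).
#' @export
terminal_rank <- function(lineage) {
  filled <- which(!is.na(lineage$standardized))
  if (!length(filled)) return(NA_character_)
  .STANDARD_RANKS[max(filled)]
}

#' Is a database annotation generic/uninformative?
#'
#' Case-insensitive substring match against a user-modifiable keyword list
#' (e.g. "uncultured", "unidentified", "environmental sample"). An empty
#' keyword list marks nothing as generic.
#'
#' @param name Character vector of scientific names.
#' @param keywords Character vector of patterns (fixed strings).
#' @return Logical vector.
#' @examples
#' is_generic("Uncultured soil basidiomycete", c("uncultured"))
#' @export
is_generic <- function(name, keywords) {
  if (!length(keywords)) return(rep(FALSE, length(name)))
  lname <- tolower(name)
  lkey <- tolower(keywords)
  vapply(lname, function(nm) any(vapply(lkey, grepl, NA, x = nm,
                                        fixed = TRUE)),
         NA, USE.NAMES = FALSE)
}

#' Default generic-annotation keyword list
#'
#' Keywords flagging database entries that carry no usable low-rank
#' information. "uncultured soil basidiomycete" entries, for instance,
#' otherwise swamp voting for closely related cultured taxa.
#'
#' @return Character vector.
#' @export
default_generics <- function() {
  c("uncultured", "unidentified", "environmental sample",
    "unclassified", "fungal sp", "fungal endophyte",
    "vouchered mycorrhizae", "soil basidiomycete")
}
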