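#' Random reference sequences
#'
#' Uniform i.i.d. ACGT sequences drawn from the current RNG state; used
#' to build mutually unrelated mock reference databases.
#'
#' @param n Number of sequences.
#' @param length Length of each sequence in bases.
#' @return Character vector of uppercase sequences.
#' @export
random_dna <- function(n, length) {
  vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "T"), length, replace = TRUE),
          collapse = ""),
    "")
}

#' Write/read FASTA
#'
#' Thin wrappers over Biostrings sequence I/O working on plain named
#' character vectors. On read, sequence names are the header up to the
#' first whitespace.
#'
#' @param seqs Named character vector of sequences.
#' @param path File path.
#' @param comments Optional character vector appended to headers (e.g.
#'   the simulator records its seed here).
#' @return `read_fasta` returns a named character vector.
#' @export
write_fasta <- function(seqs, path, comments = NULL) {
  x <- Biostrings::BStringSet(unname(seqs))
  names(x) <- if (is.null(comments)) names(seqs) else
    paste(names(seqs), comments)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' @rdname write_fasta
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(x))
  stats::setNames(toupper(as.character(x)), ids)
}

#' Describe an in silico amplicon community
#'
#' The stated world of the read simulator: a set of organisms with known
#' reference amplicon sequences, a per-organism read count, a per-base
#' substitution error rate, and exponential 3' truncation. Defaults
#' emulate pyrosequencing amplicon data: 32 reads per organism, 1%
#' substitution errors, truncation lengths drawn from an exponential
#' distribution with mean 5 bases.
#'
#' @param organisms data.frame with columns `name`, `taxid`, `sequence`
#'   (uppercase ACGT references).
#' @param reads_per_organism Reads generated per organism (default 32).
#' @param error_rate Per-base substitution probability in \[0,1)
#'   (default 0.01).
#' @param trunc_mean Mean of the exponential truncation-length
#'   distribution, in bases (default 5; 0 disables truncation).
#' @param seed Integer seed governing all draws.
#' @return A `community_spec` object.
#' @export
community_spec <- function(organisms, reads_per_organism = 32L,
                           error_rate = 0.01, trunc_mean = 5,
                           seed = 1L) {
  organisms <- as.data.frame(organisms)
  stopifnot(all(c("name", "taxid", "sequence") %in% names(organisms)),
            nrow(organisms) >= 1L)
  if (any(!nzchar(organisms$sequence)))
    stop("empty reference sequence for organism ",
         organisms$name[!nzchar(organisms$sequence)][1L])
  if (any(grepl("[^ACGT]", organisms$sequence)))
    stop("reference sequences must be uppercase ACGT")
  if (error_rate < 0 || error_rate >= 1)
    stop("error_rate must lie in [0, 1)")
  if (trunc_mean < 0) stop("trunc_mean must be >= 0")
  structure(list(organisms = organisms,
                 reads_per_organism = as.integer(reads_per_organism),
                 error_rate = error_rate, trunc_mean = trunc_mean,
                 seed = as.integer(seed)),
            class = "community_spec")
}

#' Read a community description from JSON
#'
#' Keys mirror the [community_spec()] arguments; `organisms` is an array
#' of objects with `name`, `taxid` and `sequence`.
#'
#' @param path JSON file path.
#' @return A `community_spec`.
#' @export
read_community_spec <- function(path) {
  vals <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  do.call(community_spec, vals)
}

.OTHER_BASE <- list(A = c("C", "G", "T"), C = c("A", "G", "T"),
                    G = c("A", "C", "T"), T = c("A", "C", "G"))

#' Simulate error-bearing truncated amplicon reads
#'
#' For each organism, `reads_per_organism` reads are produced from its
#' reference: each base is substituted independently with probability
#' `error_rate` (the replacement drawn uniformly from the three other
#' bases), then the read is truncated from the 3' end by
#' round-to-nearest of an exponential draw with mean `trunc_mean`,
#' capped at length − 1 so at least one base remains. Deterministic
#' given the spec's seed.
#'
#' @param spec A [community_spec()].
#' @return List with `reads` (named character vector) and `truth`
#'   (data.table: read_id, organism, taxid, substitutions applied,
#'   bases truncated, read length).
#' @export
simulate_reads <- function(spec) {
  stopifnot(inherits(spec, "community_spec"))
  set.seed(spec$seed)
  ids <- character(0); seqs <- character(0)
  truth <- vector("list", nrow(spec$organisms) * spec$reads_per_organism)
  k <- 0L
  for (o in seq_len(nrow(spec$organisms))) {
    ref <- strsplit(spec$organisms$sequence[o], "")[[1L]]
    L <- length(ref)
    for (r in seq_len(spec$reads_per_organism)) {
      bases <- ref
      sub_idx <- which(stats::runif(L) < spec$error_rate)
      for (i in sub_idx)
        bases[i] <- sample(.OTHER_BASE[[ref[i]]], 1L)
      trunc <- if (spec$trunc_mean > 0)
        min(round(stats::rexp(1L, 1 / spec$trunc_mean)), L - 1L)
      else 0L
      if (trunc > 0L) bases <- bases[seq_len(L - trunc)]
      k <- k + 1L
      id <- sprintf("read_%04d", k)
      ids[k] <- id
      seqs[k] <- paste(bases, collapse = "")
      truth[[k]] <- data.table(
        read_id = id, organism = spec$organisms$name[o],
        taxid = as.integer(spec$organisms$taxid[o]),
        substitutions = length(sub_idx), truncated = as.integer(trunc),
        length = L - as.integer(trunc))
    }
  }
  list(reads = stats::setNames(seqs, ids),
       truth = rbindlist(truth),
       seed = spec$seed)
}

#' Build a miniature taxdump-style taxonomy
#'
#' Generates a connected 8-rank toy taxonomy: a shared
#' root/domain/kingdom spine (Eukaryota, Fungi) with one full
#' phylum-to-species path per organism, plus optional pathological
#' decoys mirroring real-database defects:
#' * `"rank_gap"` — a genus whose parent is a phylum (the taxonomy jumps
#'   from phylum to genus, so class/order/family slots stay blank);
#' * `"generic_leaf"` — a species named "Uncultured soil basidiomycete"
#'   attached under the first organism's class;
#' * `"kingdom_only"` — a leaf whose lineage terminates at kingdom rank.
#'
#' @param n_organisms Number of organisms (>= 1).
#' @param decoys Character subset of
#'   `c("rank_gap", "generic_leaf", "kingdom_only")`.
#' @param dir Optional directory; when given, `nodes.dmp` and
#'   `names.dmp` are written there.
#' @return List with `nodes`/`names` (taxdump dialect lines), `truth`
#'   (data.table: taxid, rank, name, parent_taxid), `organisms`
#'   (data.table: name, taxid (species), genus), `decoys` (named list of
#'   decoy taxids), and file paths when `dir` was given.
#' @export
make_toy_taxonomy <- function(n_organisms, decoys = character(),
                              dir = NULL) {
  stopifnot(n_organisms >= 1L)
  bad <- setdiff(decoys, c("rank_gap", "generic_leaf", "kingdom_only"))
  if (length(bad)) stop("unknown decoys: ", paste(bad, collapse = ", "))

  rows <- list()
  add <- function(taxid, parent, rank, name) {
    rows[[length(rows) + 1L]] <<- data.table(
      taxid = taxid, parent_taxid = parent, rank = rank, name = name)
    taxid
  }
  nid <- 0L
  new_id <- function() { nid <<- nid + 1L; nid }

  root <- add(new_id(), 1L, "no rank", "root")
  domain <- add(new_id(), root, "superkingdom", "Eukaryota")
  kingdom <- add(new_id(), domain, "kingdom", "Fungi")

  organisms <- vector("list", n_organisms)
  classes <- integer(n_organisms)
  for (k in seq_len(n_organisms)) {
    phy <- add(new_id(), kingdom, "phylum", sprintf("Phylum%02d", k))
    cls <- add(new_id(), phy, "class", sprintf("Class%02d", k))
    ord <- add(new_id(), cls, "order", sprintf("Order%02d", k))
    fam <- add(new_id(), ord, "family", sprintf("Family%02d", k))
    gen <- add(new_id(), fam, "genus", sprintf("Genus%02d", k))
    sp <- add(new_id(), gen, "species",
              sprintf("Genus%02d species%02d", k, k))
    classes[k] <- cls
    organisms[[k]] <- data.table(
      name = sprintf("Organism%02d", k), taxid = sp,
      genus = sprintf("Genus%02d", k))
  }

  decoy_ids <- list()
  if ("rank_gap" %in% decoys) {
    gap_phy <- add(new_id(), kingdom, "phylum", "GapPhylum")
    gap_gen <- add(new_id(), gap_phy, "genus", "Gapgenus")
    gap_sp <- add(new_id(), gap_gen, "species", "Gapgenus gapspecies")
    decoy_ids$rank_gap <- gap_sp
  }
  if ("generic_leaf" %in% decoys) {
    decoy_ids$generic_leaf <-
      add(new_id(), classes[1L], "species",
          "Uncultured soil basidiomycete")
  }
  if ("kingdom_only" %in% decoys) {
    decoy_ids$kingdom_only <-
      add(new_id(), domain, "kingdom", "Environmentalia")
  }

  truth <- rbindlist(rows)
  nodes_lines <- sprintf("%d\t|\t%d\t|\t%s\t|", truth$taxid,
                         truth$parent_taxid, truth$rank)
  names_lines <- sprintf("%d\t|\t%s\t|\t\t|\tscientific name\t|",
                         truth$taxid, truth$name)
  out <- list(nodes = nodes_lines, names = names_lines, truth = truth,
              organisms = rbindlist(organisms), decoys = decoy_ids)
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    out$nodes_path <- file.path(dir, "nodes.dmp")
    out$names_path <- file.path(dir, "names.dmp")
    writeLines(nodes_lines, out$nodes_path)
    writeLines(names_lines, out$names_path)
  }
  out
}

#' Emulate a BLAST search against a small reference database
#'
#' Offline stand-in for blastn: each read is aligned semi-globally (read
#' end-to-end, reference locally) against every reference; the `top_k`
#' references by identity become hits. Percent identity is
#' `100 * (alignment columns - edit distance) / alignment columns`.
#' Coordinates reflect the aligned query span (the full read, since the
#' read aligns end-to-end). Noise options inject the database
#' pathologies the classifier must survive:
#' * `short_fraction` / `short_span` — this fraction of hits is rewritten
#'   as short matches covering only `short_span` of the query;
#' * `generic_fraction` / `generic_accession` — this fraction of hits is
#'   redirected to a generic database entry (e.g. an "uncultured" leaf).
#'
#' @param reads Named character vector of read sequences (or FASTA path).
#' @param references Named character vector of reference sequences, names
#'   are accessions (or FASTA path).
#' @param top_k Hits retained per read (default 5).
#' @param mapping Optional accession-to-taxid map used to fill `taxid`.
#' @param noise List with any of `short_fraction`, `short_span`,
#'   `generic_fraction`, `generic_accession` (see above).
#' @param seed Optional seed for the noise draws.
#' @return Hit table in the 13-column tabular layout
#'   (see [parse_blast_table()]).
#' @export
emulate_hits <- function(reads, references, top_k = 5L, mapping = NULL,
                         noise = list(), seed = NULL) {
  if (is.character(reads) && length(reads) == 1L && file.exists(reads))
    reads <- read_fasta(reads)
  if (is.character(references) && length(references) == 1L &&
      file.exists(references))
    references <- read_fasta(references)
  stopifnot(length(references) >= 1L, length(reads) >= 1L)
  if (!is.null(seed)) set.seed(seed)
  short_fraction <- noise$short_fraction %||% 0
  short_span <- noise$short_span %||% 0.5
  generic_fraction <- noise$generic_fraction %||% 0
  generic_accession <- noise$generic_accession

  rows <- vector("list", length(reads))
  accs <- names(references)
  for (ri in seq_along(reads)) {
    read <- reads[[ri]]
    qlen <- nchar(read)
    stats <- vapply(references, function(ref)
      cpp_semiglobal_align(read, ref), integer(4))
    dist <- stats[1L, ]; cols <- stats[2L, ]
    sstart <- stats[3L, ]; send <- stats[4L, ]
    identity <- 100 * (cols - dist) / cols
    keep <- order(-identity, seq_along(accs))[seq_len(min(top_k,
                                                          length(accs)))]
    n <- length(keep)
    hit <- data.table(
      query_id = names(reads)[ri],
      subject_accession = accs[keep],
      percent_identity = round(identity[keep], 2),
      alignment_length = cols[keep],
      mismatches = dist[keep],
      gapopen = 0L,
      qstart = 1L, qend = qlen,
      sstart = sstart[keep], send = send[keep],
      evalue = 0, bitscore = round(2 * (cols[keep] - dist[keep]), 1),
      qlen = qlen)
    if (short_fraction > 0) {
      shorten <- stats::runif(n) < short_fraction
      hit$qend[shorten] <- pmax(1L,
                                as.integer(floor(short_span * qlen)))
      hit$alignment_length[shorten] <- hit$qend[shorten]
    }
    if (generic_fraction > 0 && !is.null(generic_accession)) {
      redirect <- stats::runif(n) < generic_fraction
      hit$subject_accession[redirect] <- generic_accession
    }
    rows[[ri]] <- hit
  }
  hits <- rbindlist(rows)
  hits$taxid <- if (is.null(mapping)) NA_integer_ else
    resolve_accession(hits$subject_accession, mapping)
  hits[]
}

`%||%` <- function(a, b) if (is.null(a)) b else a
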