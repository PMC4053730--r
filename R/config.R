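# Identity-threshold presets (percent): species, genus, all other ranks.
# ITS values follow the published ITS1 calibration; 18S values were chosen
# for the longer, more conserved 18S amplicon.
.PRESETS <- list(
  its = c(identity_species = 95.2, identity_genus = 83.05,
          identity_other = 80),
  `18s` = c(identity_species = 99, identity_genus = 96,
            identity_other = 80))

#' Classifier configuration
#'
#' Bundles every threshold the consensus voter uses. The `"its"` preset
#' fixes species/genus/other identity thresholds at 95.2/83.05/80 percent
#' and the `"18s"` preset at 99/96/80; `"custom"` requires all three
#' identity values explicitly. Remaining defaults apply to all amplicons:
#' minimum query coverage 0.70, generic-annotation fraction cap 0.70,
#' 0.60 majority for species-through-family votes and 0.90 for order and
#' above.
#'
#' @param preset One of `"its"`, `"18s"`, `"custom"`.
#' @param identity_species,identity_genus,identity_other Percent identity
#'   thresholds; mandatory when `preset = "custom"`, forbidden otherwise.
#' @param min_coverage Minimum query coverage fraction (default 0.70).
#' @param majority_low Majority fraction required at species, genus and
#'   family (default 0.60). A winner must strictly exceed it.
#' @param majority_high Majority fraction required at order and above
#'   (default 0.90).
#' @param generic_fraction_max If more than this fraction of
#'   filter-passing hits carry generic or rank-free annotations, the
#'   query is left unassigned (default 0.70).
#' @param generics Character vector of generic-name keywords
#'   (default [default_generics()]).
#' @param max_hits Per-query candidate cap after HSP dedup (default 100).
#' @param min_passing_hits Minimum hits surviving coverage/identity
#'   filtering for classification to proceed (default 1).
#' @return An object of class `classifier_config`.
#' @examples
#' classifier_config("its")
#' classifier_config("custom", identity_species = 97,
#'                   identity_genus = 90, identity_other = 80)
#' @export
classifier_config <- function(preset = c("its", "18s", "custom"),
                              identity_species = NULL,
                              identity_genus = NULL,
                              identity_other = NULL,
                              min_coverage = 0.70,
                              majority_low = 0.60,
                              majority_high = 0.90,
                              generic_fraction_max = 0.70,
                              generics = default_generics(),
                              max_hits = 100L,
                              min_passing_hits = 1L) {
  preset <- match.arg(preset)
  ids <- c(identity_species = identity_species,
           identity_genus = identity_genus,
           identity_other = identity_other)
  if (preset == "custom") {
    if (length(ids) != 3L)
      stop("preset 'custom' requires identity_species, identity_genus ",
           "and identity_other")
  } else {
    if (length(ids))
      stop("identity thresholds are fixed by preset '", preset,
           "'; use preset = 'custom' to override")
    ids <- .PRESETS[[preset]]
  }
  fracs <- c(min_coverage = min_coverage, majority_low = majority_low,
             majority_high = majority_high,
             generic_fraction_max = generic_fraction_max)
  if (any(fracs <= 0 | fracs > 1))
    stop("fractions must lie in (0, 1]: ",
         paste(names(fracs)[fracs <= 0 | fracs > 1], collapse = ", "))
  if (any(ids < 0 | ids > 100))
    stop("identity thresholds are percentages in [0, 100]")
  structure(list(
    preset = preset,
    identity_species = unname(ids[["identity_species"]]),
    identity_genus = unname(ids[["identity_genus"]]),
    identity_other = unname(ids[["identity_other"]]),
    min_coverage = min_coverage,
    majority_low = majority_low,
    majority_high = majority_high,
    generic_fraction_max = generic_fraction_max,
    generics = as.character(generics),
    max_hits = as.integer(max_hits),
    min_passing_hits = as.integer(min_passing_hits)),
    class = "classifier_config")
}

#' @export
print.classifier_config <- function(x, ...) {
  cat("<classifier_config> preset=", x$preset,
      " identity(sp/gen/other)=", x$identity_species, "/",
      x$identity_genus, "/", x$identity_other,
      " coverage>=", x$min_coverage,
      " majority(low/high)=", x$majority_low, "/", x$majority_high,
      " generic<=", x$generic_fraction_max,
      " max_hits=", x$max_hits, "\n", sep = "")
  invisible(x)
}

#' Read a classifier configuration from JSON
#'
#' Keys are named exactly as the [classifier_config()] arguments; absent
#' keys take their defaults. `overrides` (a named list, e.g. from CLI
#' flags) take precedence over file values.
#'
#' @param path JSON file path.
#' @param overrides Named list overriding file values.
#' @return A `classifier_config`.
#' @export
read_classifier_config <- function(path, overrides = list()) {
  vals <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  vals[names(overrides)] <- overrides
  known <- names(formals(classifier_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown))
    stop("unknown configuration keys: ", paste(unknown, collapse = ", "))
  do.call(classifier_config, vals)
}

# Identity threshold that applies at a given standardized rank.
.identity_at_rank <- function(cfg, rank) {
  switch(rank,
         species = cfg$identity_species,
         genus = cfg$identity_genus,
         cfg$identity_other)
}

# Majority threshold at a given rank: species-family use majority_low,
# order and above use majority_high.
.majority_at_rank <- function(cfg, rank) {
  if (rank %in% c("species", "genus", "family")) cfg$majority_low
  else cfg$majority_high
}
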