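#' Construct a taxonomic lineage
#'
#' Builds a validated [TaxonLineage-class]. Names are trimmed and internal
#' whitespace collapsed; comparisons elsewhere are case-insensitive, so case
#' is preserved here for display only. Species names are expected as binomina
#' ("Archips packardiana"); anything beyond two tokens (subspecific epithets)
#' is truncated to the binomen, matching the order-to-species rank span of
#' interception reporting.
#'
#' @param order,superfamily,family,subfamily,genus,species Rank names
#'   (character(1) or NA).
#' @param interim Optional interim MOTU/BIN label (e.g. "BOLD:AAP2599").
#' @return A [TaxonLineage-class] object.
#' @examples
#' taxonLineage(family = "Tortricidae", genus = "Archips",
#'              species = "Archips packardiana")
#' taxonLineage(interim = "BOLD:AAP2599")
#' @export
taxonLineage <- function(order = NA, superfamily = NA, family = NA,
                         subfamily = NA, genus = NA, species = NA,
                         interim = NA) {
  vals <- c(order = order, superfamily = superfamily, family = family,
            subfamily = subfamily, genus = genus, species = species)
  vals <- vapply(vals, as.character, character(1))
  vals <- .squish(vals)
  vals <- vals[!is.na(vals) & nzchar(vals)]
  if ("species" %in% names(vals))
    vals[["species"]] <- .truncateBinomen(vals[["species"]])
  interim <- .squish(as.character(interim))
  interim <- interim[!is.na(interim) & nzchar(interim)]
  new("TaxonLineage", ranks = vals, interim = interim)
}

# collapse runs of whitespace and trim ends; NA passes through
.squish <- function(x) {
  out <- gsub("[[:space:]]+", " ", trimws(x))
  out[is.na(x)] <- NA_character_
  out
}

# keep the first two tokens of a species name (drop subspecific epithets)
.truncateBinomen <- function(x) {
  parts <- strsplit(x, " ", fixed = TRUE)[[1]]
  paste(parts[seq_len(min(2L, length(parts)))], collapse = " ")
}

.rankDepth <- function(rank) match(rank, TAXON_RANKS) - 1L

#' Lowest (deepest) named rank of a lineage
#'
#' @param lineage A [TaxonLineage-class].
#' @return One of [TAXON_RANKS], or "interim" when the lineage carries only
#'   an interim label.
#' @examples
#' lowestNamedRank(taxonLineage(family = "Tortricidae"))   # "family"
#' lowestNamedRank(taxonLineage(interim = "BOLD:AAP2599")) # "interim"
#' @export
lowestNamedRank <- function(lineage) {
  stopifnot(is(lineage, "TaxonLineage"))
  validObject(lineage)
  present <- TAXON_RANKS[TAXON_RANKS %in% names(lineage@ranks)]
  if (!length(present)) return("interim")
  present[length(present)]
}

#' Relation between a morphological and a DNA-hit lineage
#'
#' Decides how the taxonomic name attached to a library hit relates to a
#' morphological identification. Only ranks named on both sides are
#' compared; missing intermediate ranks never create disagreement. Name
#' comparison is case-insensitive after whitespace normalisation, with no
#' synonym resolution.
#'
#' Possible values:
#' \describe{
#'   \item{identical_species}{both are species-level and the binomina agree}
#'   \item{descendant}{the hit's lowest named rank is deeper than the
#'     morphology's and every shared rank agrees}
#'   \item{ancestor}{the mirror case: the hit is shallower but consistent}
#'   \item{identical_at_rank}{equal depth, all shared ranks agree, not both
#'     species-level (e.g. family-only vs the same family)}
#'   \item{sister_species}{both species-level, same genus, different species
#'     (congeneric proxy for sisterhood)}
#'   \item{interim_only}{the hit carries only an interim (BIN) label}
#'   \item{disjoint}{some rank named on both sides disagrees}
#' }
#'
#' @param morph,hit [TaxonLineage-class] objects; `morph` must name at least
#'   one rank.
#' @return A single relation string.
#' @examples
#' relation <- lineageRelation(
#'   taxonLineage(family = "Tortricidae"),
#'   taxonLineage(family = "Tortricidae", genus = "Archips",
#'                species = "Archips packardiana"))
#' stopifnot(relation == "descendant")
#' @export
lineageRelation <- function(morph, hit) {
  stopifnot(is(morph, "TaxonLineage"), is(hit, "TaxonLineage"))
  validObject(morph); validObject(hit)
  if (!length(hit@ranks)) return("interim_only")
  if (!length(morph@ranks))
    stop("morphological lineage must name at least one rank")

  shared <- intersect(names(morph@ranks), names(hit@ranks))
  disagree <- shared[tolower(morph@ranks[shared]) != tolower(hit@ranks[shared])]

  bothSpecies <- "species" %in% names(morph@ranks) &&
    "species" %in% names(hit@ranks)
  if (bothSpecies && identical(disagree, "species") &&
      "genus" %in% shared)  # genus agrees, only the binomen differs
    return("sister_species")
  if (length(disagree)) return("disjoint")

  dm <- .rankDepth(lowestNamedRank(morph))
  dh <- .rankDepth(lowestNamedRank(hit))
  if (dh > dm) return("descendant")
  if (dh < dm) return("ancestor")
  if (bothSpecies) return("identical_species")
  "identical_at_rank"
}

#' @describeIn taxonLineage Number of named ranks.
#' @param x,object A [TaxonLineage-class].
#' @export
setMethod("length", "TaxonLineage", function(x) length(x@ranks))

setMethod("show", "TaxonLineage", function(object) {
  if (length(object@ranks)) {
    cat("TaxonLineage:",
        paste(sprintf("%s=%s", names(object@ranks), object@ranks),
              collapse = "; "), "\n")
  } else {
    cat("TaxonLineage: <unnamed>\n")
  }
  if (length(object@interim))
    cat("  interim label:", object@interim, "\n")
})

# lineage from a metadata row (list or 1-row data.frame-like) that carries
# the six rank columns and optionally bin_label
.lineageFromRow <- function(row) {
  args <- lapply(TAXON_RANKS, function(r) {
    v <- row[[r]]
    if (is.null(v) || length(v) != 1 || is.na(v)) NA_character_ else
      as.character(v)
  })
  names(args) <- TAXON_RANKS
  interim <- row[["bin_label"]]
  if (is.null(interim) || length(interim) != 1 || is.na(interim))
    interim <- NA_character_
  do.call(taxonLineage, c(args, list(interim = interim)))
}
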