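#' @import methods
#' @importFrom S4Vectors DataFrame
#' @importClassesFrom S4Vectors DataFrame
#' @importClassesFrom Biostrings DNAStringSet
NULL

#' Taxonomic ranks used throughout the package
#'
#' The six Linnaean ranks spanned by border-interception identifications,
#' ordered from shallowest to deepest. Rank depth is the 0-based position in
#' this vector (order = 0 ... species = 5).
#'
#' @format Character vector of length 6.
#' @export
TAXON_RANKS <- c("order", "superfamily", "family", "subfamily",
                 "genus", "species")

#' Life stages recorded for intercepted specimens
#' @format Character vector of length 4.
#' @export
LIFE_STAGES <- c("larva", "pupa", "adult", "unknown")

#' Concordance categories for a morphology-versus-DNA comparison
#'
#' Category 1: the DNA match carries a lower-level (deeper) taxonomic name
#' than the morphological identification. Category 2: concordant (identical
#' species name, or a higher-level name consistent with the morphology).
#' Category 3: interim identification (match to an interim/BIN-only record,
#' a sub-threshold match with the same Linnaean name, or a congeneric sister
#' species). Category 4: no match available. Category 5: discordant.
#'
#' @format Character vector of length 5.
#' @export
CONCORDANCE_CATEGORIES <- c("1_dna_lower", "2_concordant", "3_interim",
                            "4_no_match", "5_discordant")

#' A Linnaean lineage with an optional interim (BIN/MOTU) label
#'
#' Holds names for any subset of the six ranks in [TAXON_RANKS] plus an
#' optional interim cluster label (e.g. a BIN identifier) standing in for
#' formal taxonomy. A valid lineage names at least one rank or carries an
#' interim label, and a species name implies a genus name (a binomen names
#' its genus).
#'
#' @slot ranks Named character vector; names are a subset of [TAXON_RANKS].
#' @slot interim Character vector of length 0 or 1; interim cluster label.
#' @export
setClass("TaxonLineage",
         representation(ranks = "character", interim = "character"))

setValidity("TaxonLineage", function(object) {
  msgs <- character()
  rk <- object@ranks
  if (length(rk)) {
    if (is.null(names(rk)) || !all(names(rk) %in% TAXON_RANKS))
      msgs <- c(msgs, "rank names must be a subset of TAXON_RANKS")
    if (anyDuplicated(names(rk)))
      msgs <- c(msgs, "duplicated rank names")
    if (any(is.na(rk)) || any(!nzchar(trimws(rk))))
      msgs <- c(msgs, "rank values must be non-empty text")
  }
  if (length(object@interim) > 1)
    msgs <- c(msgs, "interim label must have length 0 or 1")
  if (length(object@interim) == 1 &&
      (is.na(object@interim) || !nzchar(trimws(object@interim))))
    msgs <- c(msgs, "interim label must be non-empty text")
  if (!length(rk) && !length(object@interim))
    msgs <- c(msgs, "lineage must name at least one rank or an interim label")
  if ("species" %in% names(rk) && !("genus" %in% names(rk)))
    msgs <- c(msgs, "a species name requires a genus name")
  if (length(msgs)) msgs else TRUE
})

#' A year-stamped, access-controlled reference library
#'
#' Couples a [Biostrings::DNAStringSet] of COI barcode sequences with a
#' per-record metadata table (taxonomic lineage, BIN label, public flag,
#' deposit year, provenance countries, quarantine-capture flag). Record
#' identifiers are shared between the two slots and are unique.
#'
#' @slot sequences [Biostrings::DNAStringSet], names are record identifiers.
#' @slot meta [S4Vectors::DataFrame] with one row per record.
#' @export
setClass("ReferenceLibrary",
         representation(sequences = "DNAStringSet", meta = "DataFrame"))

.LIBRARY_COLUMNS <- c("record_id", TAXON_RANKS, "bin_label", "is_public",
                      "year_added", "country_of_origin",
                      "country_of_interception", "capture_exception")

.QUERY_COLUMNS <- c("specimen_id", TAXON_RANKS, "life_stage",
                    "country_of_origin", "country_of_interception")

.validSeqAlphabet <- function(seqs) {
  # DNAStringSet already restricts to IUPAC codes plus "-", "+" and ".";
  # "+" has no reading here and is rejected.
  af <- Biostrings::alphabetFrequency(seqs, collapse = TRUE)
  bad <- af[["+"]]
  if (!is.na(bad) && bad > 0) "sequences contain the unsupported '+' code"
  else NULL
}

setValidity("ReferenceLibrary", function(object) {
  msgs <- character()
  m <- object@meta
  if (!all(.LIBRARY_COLUMNS %in% colnames(m)))
    msgs <- c(msgs, paste("metadata lacks columns:",
                          paste(setdiff(.LIBRARY_COLUMNS, colnames(m)),
                                collapse = ", ")))
  else {
    if (anyDuplicated(m$record_id))
      msgs <- c(msgs, "duplicated record_id")
    seqIds <- as.character(names(object@sequences))
    if (length(object@sequences) != nrow(m) ||
        (nrow(m) > 0 && !identical(seqIds, as.character(m$record_id))))
      msgs <- c(msgs, "sequence names must equal meta$record_id, in order")
    if (any(!is.na(m$year_added) & m$year_added < 1990))
      msgs <- c(msgs, "year_added must be >= 1990")
    badsp <- !is.na(m$species) & is.na(m$genus)
    if (any(badsp))
      msgs <- c(msgs, paste("species name without genus for:",
                            paste(m$record_id[badsp], collapse = ", ")))
    named <- Reduce(`|`, lapply(TAXON_RANKS, function(r) !is.na(m[[r]])))
    orphan <- !named & is.na(m$bin_label)
    if (any(orphan))
      msgs <- c(msgs, paste("records with neither a named rank nor a BIN:",
                            paste(m$record_id[orphan], collapse = ", ")))
  }
  msgs <- c(msgs, .validSeqAlphabet(object@sequences))
  if (length(msgs)) msgs else TRUE
})

#' A set of intercepted query specimens
#'
#' Specimen metadata (morphological lineage, life stage, provenance) for all
#' specimens, plus sequences for the subset that yielded barcode data; a
#' specimen absent from the sequence slot represents a sequencing failure.
#'
#' @slot sequences [Biostrings::DNAStringSet]; names are specimen identifiers
#'   of the sequenced subset.
#' @slot meta [S4Vectors::DataFrame] with one row per specimen.
#' @export
setClass("QuerySet",
         representation(sequences = "DNAStringSet", meta = "DataFrame"))

setValidity("QuerySet", function(object) {
  msgs <- character()
  m <- object@meta
  if (!all(.QUERY_COLUMNS %in% colnames(m)))
    msgs <- c(msgs, paste("metadata lacks columns:",
                          paste(setdiff(.QUERY_COLUMNS, colnames(m)),
                                collapse = ", ")))
  else {
    if (anyDuplicated(m$specimen_id))
      msgs <- c(msgs, "duplicated specimen_id")
    if (!all(names(object@sequences) %in% m$specimen_id))
      msgs <- c(msgs, "sequences present for unknown specimen_ids")
    if (anyDuplicated(names(object@sequences)))
      msgs <- c(msgs, "duplicated sequence names")
    if (!all(is.na(m$life_stage) | m$life_stage %in% LIFE_STAGES))
      msgs <- c(msgs, "life_stage outside {larva, pupa, adult, unknown}")
    badsp <- !is.na(m$species) & is.na(m$genus)
    if (any(badsp))
      msgs <- c(msgs, paste("species name without genus for:",
                            paste(m$specimen_id[badsp], collapse = ", ")))
  }
  msgs <- c(msgs, .validSeqAlphabet(object@sequences))
  if (length(msgs)) msgs else TRUE
})

#' Result of matching one query against a reference library
#'
#' @slot queryId Specimen identifier.
#' @slot hits data.frame of supra-threshold hits (record_id, identity_pct,
#'   overlap_bp), sorted by identity descending, ties by record_id ascending.
#' @slot subHits data.frame of the comparable hits at or below the
#'   threshold, same ordering; feeds the sub-threshold same-name rule of
#'   the concordance classifier.
#' @slot thresholdPct Identity threshold (percent) that a hit must exceed.
#' @slot minOverlapBp Minimum aligned overlap for a comparison to count.
#' @slot noSequence TRUE when the query had no sequence (distinct from
#'   "no hit").
#' @export
setClass("MatchResult",
         representation(queryId = "character", hits = "data.frame",
                        subHits = "data.frame", thresholdPct = "numeric",
                        minOverlapBp = "numeric", noSequence = "logical"))

#' One specimen's concordance classification
#'
#' @slot specimenId Specimen identifier.
#' @slot category One of [CONCORDANCE_CATEGORIES].
#' @slot rationale Machine-readable sub-rule that fired.
#' @slot bestRecordId Record behind the decision (NA for category 4).
#' @slot bestIdentityPct Identity of that record (NA for category 4).
#' @slot conflicts Character vector describing supra-threshold hits whose
#'   lineage conflicts with the morphology when the top hit did not.
#' @export
setClass("ConcordanceResult",
         representation(specimenId = "character", category = "character",
                        rationale = "character", bestRecordId = "character",
                        bestIdentityPct = "numeric", conflicts = "character"))

setValidity("ConcordanceResult", function(object) {
  if (!object@category %in% CONCORDANCE_CATEGORIES)
    return("category outside the five concordance categories")
  TRUE
})

#' A BIN-surrogate MOTU cluster
#'
#' @slot clusterId Deterministic identifier (lexicographically smallest
#'   member id).
#' @slot members Character vector of member record/specimen ids.
#' @slot status "singleton", "concordant", "discordant", or NA before audit.
#' @slot namesPerRank Named list: for each rank named by at least one member,
#'   the distinct names observed.
#' @export
setClass("MotuCluster",
         representation(clusterId = "character", members = "character",
                        status = "character", namesPerRank = "list"))

setValidity("MotuCluster", function(object) {
  msgs <- character()
  if (!length(object@members))
    msgs <- c(msgs, "cluster must have at least one member")
  st <- object@status
  if (!is.na(st) && !st %in% c("singleton", "concordant", "discordant"))
    msgs <- c(msgs, "unknown status")
  if (!is.na(st) && st == "singleton" && length(object@members) != 1)
    msgs <- c(msgs, "singleton status on a multi-member cluster")
  if (!is.na(st) && st != "singleton" && length(object@members) == 1)
    msgs <- c(msgs, "one-member cluster must have singleton status")
  if (length(msgs)) msgs else TRUE
})
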