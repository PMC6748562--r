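#' Classify one identification into the five concordance categories
#'
#' Applies the decision procedure to the top hit of a [MatchResult-class],
#' in this precedence order: (a) no sequence, or no supra-threshold hit —
#' category 4, unless the best comparable sub-threshold hit carries the
#' same Linnaean name at the morphology's lowest named rank, which is a
#' category-3 "interim" outcome; (b) identical species name — category 2;
#' (c) the hit names a deeper rank, consistent at all shared ranks —
#' category 1; (d) the hit names an equal or higher rank, consistent —
#' category 2; (e) the hit carries only an interim (BIN) label —
#' category 3; (f) congeneric sister species — category 3; (g) some shared
#' rank disagrees — category 5.
#'
#' When the top hit is concordant but other supra-threshold hits conflict
#' with the morphology, the result carries a conflict annotation listing
#' those hits — the evidence an expert reviewer needs, without changing the
#' top-hit-based category.
#'
#' @param morph The morphological identification ([TaxonLineage-class]).
#' @param match A [MatchResult-class] produced under the same threshold.
#' @param lookup Either a function `record_id -> TaxonLineage` or a
#'   [ReferenceLibrary-class] (see [lineageLookup]).
#' @return A [ConcordanceResult-class].
#' @export
classify <- function(morph, match, lookup) {
  stopifnot(is(morph, "TaxonLineage"), is(match, "MatchResult"))
  lookup <- .asLookup(lookup)
  res <- .classifyCore(morph, match@hits, match@subHits, match@noSequence,
                       lookup)
  new("ConcordanceResult", specimenId = match@queryId,
      category = res$category, rationale = res$rationale,
      bestRecordId = res$best_record_id,
      bestIdentityPct = res$best_identity_pct, conflicts = res$conflicts)
}

.asLookup <- function(lookup) {
  if (is.function(lookup)) return(lookup)
  if (is(lookup, "ReferenceLibrary") || is(lookup, "QuerySet"))
    return(lineageLookup(lookup))
  stop("lookup must be a function or a ReferenceLibrary/QuerySet")
}

.RELATION_MAP <- list(
  identical_species = c("2_concordant", "identical_species"),
  descendant        = c("1_dna_lower", "hit_lower_consistent"),
  ancestor          = c("2_concordant", "hit_higher_consistent"),
  identical_at_rank = c("2_concordant", "identical_at_rank"),
  interim_only      = c("3_interim", "bin_only"),
  sister_species    = c("3_interim", "sister_species"),
  disjoint          = c("5_discordant", "disjoint"))

# rankNameOf(ids, rank): lowercase name of `rank` for each record id (NA
# when unnamed); the default derives it from the lineage lookup, table
# classification supplies a vectorised accessor
.classifyCore <- function(morph, hits, subs, noSequence, lookup,
                          rankNameOf = NULL) {
  if (is.null(rankNameOf))
    rankNameOf <- function(ids, rank) vapply(ids, function(id) {
      nm <- lookup(id)@ranks[rank]
      if (is.na(nm)) NA_character_ else tolower(nm)
    }, character(1), USE.NAMES = FALSE)
  out <- list(category = "4_no_match", rationale = "no_hit",
              best_record_id = NA_character_,
              best_identity_pct = NA_real_, conflicts = character())
  if (noSequence) {
    out$rationale <- "no_sequence"
    return(out)
  }
  if (!nrow(hits)) {
    # sub-threshold rescue: a match below the threshold to a record with
    # the same Linnaean name at the morphology's lowest named rank (the
    # best such record is reported)
    if (nrow(subs)) {
      lr <- lowestNamedRank(morph)
      if (lr != "interim") {
        same <- which(rankNameOf(subs$record_id, lr) ==
                        tolower(morph@ranks[[lr]]))
        if (length(same)) {
          k <- same[1]
          out$category <- "3_interim"
          out$rationale <- "sub_threshold_same_name"
          out$best_record_id <- subs$record_id[k]
          out$best_identity_pct <- subs$identity_pct[k]
        }
      }
    }
    return(out)
  }
  topLineage <- lookup(hits$record_id[1])
  rel <- lineageRelation(morph, topLineage)
  mapped <- .RELATION_MAP[[rel]]
  out$category <- mapped[1]
  out$rationale <- mapped[2]
  out$best_record_id <- hits$record_id[1]
  out$best_identity_pct <- hits$identity_pct[1]
  if (out$category != "5_discordant" && nrow(hits) > 1) {
    others <- hits$record_id[-1]
    rels <- vapply(others,
                   function(id) lineageRelation(morph, lookup(id)),
                   character(1))
    conf <- others[rels == "disjoint"]
    if (length(conf))
      out$conflicts <- sprintf("%s (%.2f%%)", conf,
                               hits$identity_pct[match(conf,
                                                       hits$record_id)])
  }
  out
}

setMethod("show", "ConcordanceResult", function(object) {
  cat(sprintf("ConcordanceResult %s: category %s (%s)\n",
              object@specimenId, object@category, object@rationale))
  if (!is.na(object@bestRecordId))
    cat(sprintf("  best hit %s at %.2f%%\n", object@bestRecordId,
                object@bestIdentityPct))
  if (length(object@conflicts))
    cat("  conflicting hits:", paste(object@conflicts, collapse = ", "),
        "\n")
})

# classify all sequenced queries against one snapshot mask of the library.
# stats: output of matchStats() against the FULL library.
.classifySnapshot <- function(queries, library, mask, stats, threshold,
                              minOverlap) {
  lookup <- .cachedLookup(library)
  morphOf <- .cachedLookup(queries)
  ids <- recordIds(library)[mask]
  allIds <- recordIds(library)
  metaLow <- lapply(TAXON_RANKS, function(r)
    tolower(as.character(library@meta[[r]])))
  names(metaLow) <- TAXON_RANKS
  rankNameOf <- function(rids, rank) metaLow[[rank]][match(rids, allIds)]
  qids <- rownames(stats$matches)
  if (!length(qids))
    return(data.frame(specimen_id = character(), category = character(),
                      rationale = character(),
                      best_record_id = character(),
                      best_identity_pct = numeric(),
                      n_conflicting_hits = integer(),
                      stringsAsFactors = FALSE))
  rows <- lapply(qids, function(q) {
    m <- stats$matches[q, mask]
    k <- stats$columns[q, mask]
    ht <- .hitTable(m, k, ids, threshold, minOverlap)
    morph <- morphOf(q)
    res <- .classifyCore(morph, ht$hits, ht$sub, FALSE, lookup, rankNameOf)
    data.frame(specimen_id = q, category = res$category,
               rationale = res$rationale,
               best_record_id = res$best_record_id,
               best_identity_pct = res$best_identity_pct,
               n_conflicting_hits = length(res$conflicts),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Per-specimen concordance classification against one library snapshot
#'
#' Classifies every sequenced query specimen against the (year, view)
#' snapshot of the reference library. Specimens without sequence data are
#' excluded (the sequencing-failure bucket is reported separately by the
#' aggregation functions).
#'
#' @param queries A [QuerySet-class].
#' @param library A [ReferenceLibrary-class] (full library; the snapshot is
#'   taken internally).
#' @param year Snapshot year.
#' @param view "SLBR" or "PRBD".
#' @param threshold Identity threshold in percent (strictly greater-than).
#' @param minOverlap Minimum aligned overlap (bp).
#' @param minLength Minimum library record length (bp).
#' @param stats Optional precomputed [matchStats] cache.
#' @return data.frame with one row per sequenced specimen: category,
#'   rationale, best hit and identity.
#' @export
classifyQueries <- function(queries, library, year, view = c("SLBR", "PRBD"),
                            threshold = 98, minOverlap = 300,
                            minLength = 500, stats = NULL) {
  stopifnot(is(queries, "QuerySet"), is(library, "ReferenceLibrary"))
  view <- match.arg(view)
  if (is.null(stats)) stats <- matchStats(queries, library)
  mask <- .snapshotMask(library@meta, year, view, minLength)
  df <- .classifySnapshot(queries, library, mask, stats, threshold,
                          minOverlap)
  df$year <- year
  df$view <- view
  df[, c("specimen_id", "year", "view", "category", "rationale",
         "best_record_id", "best_identity_pct", "n_conflicting_hits")]
}

#' Concordance category counts per (year, view) snapshot
#'
#' For each requested snapshot, counts and percentages of the five
#' categories over the sequenced queries. Counts within a snapshot sum to
#' the number of queries with sequence data; the sequencing-failure count
#' is carried in the `n_sequenced`/`n_total` columns.
#'
#' @inheritParams classifyQueries
#' @param years Integer vector of snapshot years.
#' @param views Character vector among "SLBR", "PRBD".
#' @return data.frame with columns year, view, category, n, pct,
#'   n_sequenced, n_total.
#' @export
concordanceTable <- function(queries, library, years,
                             views = c("SLBR", "PRBD"), threshold = 98,
                             minOverlap = 300, minLength = 500,
                             stats = NULL) {
  stopifnot(is(queries, "QuerySet"), is(library, "ReferenceLibrary"))
  views <- match.arg(views, several.ok = TRUE)
  if (is.null(stats)) stats <- matchStats(queries, library)
  nSeq <- nrow(stats$matches)
  nTot <- length(queries)
  out <- list()
  for (view in views) {
    for (year in years) {
      df <- classifyQueries(queries, library, year, view,
                            threshold = threshold, minOverlap = minOverlap,
                            minLength = minLength, stats = stats)
      n <- vapply(CONCORDANCE_CATEGORIES,
                  function(cc) sum(df$category == cc), integer(1))
      out[[length(out) + 1]] <- data.frame(
        year = year, view = view, category = CONCORDANCE_CATEGORIES,
        n = as.integer(n),
        pct = vapply(n, function(k)
          if (nSeq > 0) pct(k, nSeq) else NA_real_, numeric(1)),
        n_sequenced = nSeq, n_total = nTot,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Species-level morphology-versus-DNA comparison
#'
#' Reproduces the species-level arithmetic of the audit: how many sequenced
#' specimens were identified to species by morphology, how many received a
#' species-level DNA identification (a supra-threshold top hit whose record
#' is species-named or interim/BIN-only), how many by both, and — within
#' the both set — the concordant / interim / discordant split (categories
#' 1+2, 3 and 5 respectively).
#'
#' @inheritParams classifyQueries
#' @return A list of counts: `n_total_sequenced`, `n_morph_species`,
#'   `n_dna_species`, `n_both`, `n_both_concordant`, `n_both_interim`,
#'   `n_both_discordant`, plus the matching `pct_*` percentages computed
#'   with [pct].
#' @export
speciesLevelComparison <- function(queries, library, year,
                                   view = c("SLBR", "PRBD"), threshold = 98,
                                   minOverlap = 300, minLength = 500,
                                   stats = NULL) {
  stopifnot(is(queries, "QuerySet"), is(library, "ReferenceLibrary"))
  view <- match.arg(view)
  if (is.null(stats)) stats <- matchStats(queries, library)
  df <- classifyQueries(queries, library, year, view, threshold = threshold,
                        minOverlap = minOverlap, minLength = minLength,
                        stats = stats)
  meta <- queries@meta
  morphSpecies <- !is.na(meta$species)
  names(morphSpecies) <- meta$specimen_id
  morphSp <- morphSpecies[df$specimen_id]

  # species-level DNA identification: supra-threshold top hit whose record
  # carries a species name, or an interim (BIN-only) record standing in
  # for one
  recSpecies <- !is.na(recordMeta(library)$species)
  names(recSpecies) <- recordIds(library)
  recInterim <- is.na(recordMeta(library)$species) &
    !is.na(recordMeta(library)$bin_label) &
    is.na(recordMeta(library)$genus) & is.na(recordMeta(library)$family)
  names(recInterim) <- recordIds(library)
  supra <- !df$category %in% c("4_no_match") &
    df$rationale != "sub_threshold_same_name"
  dnaSp <- supra & !is.na(df$best_record_id) &
    (recSpecies[df$best_record_id] | recInterim[df$best_record_id])

  both <- morphSp & dnaSp
  res <- list(
    n_total_sequenced = nrow(df),
    n_morph_species = sum(morphSp),
    n_dna_species = sum(dnaSp),
    n_both = sum(both),
    n_both_concordant = sum(both &
                              df$category %in% c("1_dna_lower",
                                                 "2_concordant")),
    n_both_interim = sum(both & df$category == "3_interim"),
    n_both_discordant = sum(both & df$category == "5_discordant"))
  res$pct_morph_species <- if (res$n_total_sequenced)
    pct(res$n_morph_species, res$n_total_sequenced) else NA_real_
  res$pct_dna_species <- if (res$n_total_sequenced)
    pct(res$n_dna_species, res$n_total_sequenced) else NA_real_
  res$pct_both_of_morph <- if (res$n_morph_species)
    pct(res$n_both, res$n_morph_species) else NA_real_
  res$pct_both_concordant <- if (res$n_both)
    pct(res$n_both_concordant, res$n_both) else NA_real_
  res$pct_both_interim <- if (res$n_both)
    pct(res$n_both_interim, res$n_both) else NA_real_
  res$pct_both_discordant <- if (res$n_both)
    pct(res$n_both_discordant, res$n_both) else NA_real_
  res
}
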