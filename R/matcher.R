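#' Pairwise sequence identity under the barcode-identification contract
#'
#' Aligns two IUPAC DNA sequences with an end-gap-free global alignment
#' (match +1, mismatch -1, gap -2 per gap column, terminal gaps free) and
#' reports percent identity over the aligned columns, terminal-gap columns
#' excluded. A position where the two IUPAC code sets intersect counts as a
#' match (so N matches anything, R matches A or G, ...). Gap characters in
#' the input are stripped before alignment. The dynamic programme is banded:
#' alignments may drift up to `bandSlack` net indel positions beyond the
#' length difference of the two sequences — far more than length-conserved
#' COI barcodes require.
#'
#' @param a,b DNA sequences (character(1), [Biostrings::DNAString] or
#'   length-1 [Biostrings::DNAStringSet]).
#' @param minOverlap Minimum aligned columns for a comparison to be
#'   meaningful (default 300); below it the identity is NA ("no comparison",
#'   treated downstream as no hit).
#' @param bandSlack Band half-width beyond the length difference.
#' @return List with `identity_pct` (NA when not comparable), `overlap_bp`
#'   (aligned columns), `matches`, and `comparable`.
#' @examples
#' s <- paste(rep("ACGT", 100), collapse = "")
#' pairwiseIdentity(s, s)$identity_pct  # 100
#' @export
pairwiseIdentity <- function(a, b, minOverlap = 300, bandSlack = 50) {
  st <- .cppAlignStats(.asSeqChar(a), .asSeqChar(b), bandSlack)
  comparable <- st[["columns"]] >= minOverlap
  list(identity_pct = if (comparable)
         100 * st[["matches"]] / st[["columns"]] else NA_real_,
       overlap_bp = st[["columns"]],
       matches = st[["matches"]],
       comparable = comparable)
}

#' Uncorrected p-distance between two sequences
#'
#' `1 - identity/100` over the same alignment contract as
#' [pairwiseIdentity]; symmetric, and 0 for identical sequences.
#'
#' @inheritParams pairwiseIdentity
#' @return Proportion in \[0, 1\], or NA when the aligned overlap is below
#'   `minOverlap`.
#' @export
pDistance <- function(a, b, minOverlap = 300, bandSlack = 50) {
  pi <- pairwiseIdentity(a, b, minOverlap = minOverlap,
                         bandSlack = bandSlack)
  if (!pi$comparable) return(NA_real_)
  1 - pi$matches / pi$overlap_bp
}

.asSeqChar <- function(x) {
  if (is(x, "DNAStringSet")) {
    stopifnot(length(x) == 1)
    return(as.character(x[[1]]))
  }
  if (is(x, "DNAString")) return(as.character(x))
  stopifnot(is.character(x), length(x) == 1)
  x
}

# match/column count matrices for a set of queries against a set of
# references; rows = queries, cols = references
.matchStats <- function(querySeqs, refSeqs, bandSlack = 50) {
  .cppIdentityMatrix(unname(querySeqs), unname(refSeqs), bandSlack)
}

#' Precompute query-versus-library alignment statistics
#'
#' Exhaustively aligns every sequenced query against every library record
#' once; the result can be fed to [topHit], [concordanceTable] and friends
#' so that year/view snapshots (which only subset the library) do not
#' trigger re-alignment.
#'
#' @param queries A [QuerySet-class].
#' @param library A [ReferenceLibrary-class].
#' @param bandSlack Band half-width (see [pairwiseIdentity]).
#' @return A list with integer matrices `matches` and `columns`
#'   (sequenced queries x records, dimnames set) — the package's internal
#'   alignment cache.
#' @export
matchStats <- function(queries, library, bandSlack = 50) {
  stopifnot(is(queries, "QuerySet"), is(library, "ReferenceLibrary"))
  qseq <- as.character(queries@sequences)
  rseq <- as.character(library@sequences)
  st <- .matchStats(qseq, rseq, bandSlack)
  dimnames(st$matches) <- dimnames(st$columns) <-
    list(names(qseq), recordIds(library))
  st
}

# hit tables for one query given its match/column count vectors against a
# set of record ids; exact ">threshold" via integer cross-multiplication
.hitTable <- function(matches, columns, ids, threshold, minOverlap) {
  comparable <- columns >= minOverlap & columns > 0
  identity <- ifelse(comparable, 100 * matches / columns, NA_real_)
  supra <- comparable & (100 * matches > threshold * columns)
  mkTab <- function(sel) {
    tab <- data.frame(record_id = ids[sel],
                      identity_pct = identity[sel],
                      overlap_bp = columns[sel],
                      stringsAsFactors = FALSE)
    tab <- tab[order(-tab$identity_pct, tab$record_id), , drop = FALSE]
    rownames(tab) <- NULL
    tab
  }
  list(hits = mkTab(supra), sub = mkTab(comparable & !supra))
}

#' Best library hit(s) for one query
#'
#' The local stand-in for submitting a sequence to an online identification
#' engine: the query is compared exhaustively against the library, hits with
#' identity strictly greater than `threshold` are returned sorted by
#' identity (descending, ties broken by record id ascending), and the
#' comparable hits at or below the threshold are retained for the
#' sub-threshold same-name rule of the concordance classifier. A query
#' without a sequence yields a result flagged `noSequence` — deliberately
#' distinct from "no hit".
#'
#' @param query A length-1 [QuerySet-class], or a named character(1) /
#'   [Biostrings::DNAStringSet] of length 1 holding the query sequence.
#' @param library A [ReferenceLibrary-class] (possibly empty).
#' @param threshold Identity threshold in percent (default 98; the match
#'   must be strictly greater).
#' @param minOverlap Minimum aligned overlap in bp (default 300).
#' @param bandSlack Band half-width (see [pairwiseIdentity]).
#' @return A [MatchResult-class].
#' @export
topHit <- function(query, library, threshold = 98, minOverlap = 300,
                   bandSlack = 50) {
  stopifnot(is(library, "ReferenceLibrary"))
  if (is(query, "QuerySet")) {
    stopifnot(length(query) == 1)
    qid <- specimenIds(query)
    if (!hasSequence(query)[[1]])
      return(new("MatchResult", queryId = qid, hits = .emptyHits(),
                 subHits = .emptyHits(), thresholdPct = threshold,
                 minOverlapBp = minOverlap, noSequence = TRUE))
    qseq <- as.character(query@sequences[[qid]])
  } else {
    qseq <- .asSeqChar(query)
    qid <- if (!is.null(names(query))) names(query)[1] else "query"
  }
  ids <- recordIds(library)
  if (!length(ids))
    return(new("MatchResult", queryId = qid, hits = .emptyHits(),
               subHits = .emptyHits(), thresholdPct = threshold,
               minOverlapBp = minOverlap, noSequence = FALSE))
  st <- .cppIdentityBatch(qseq, as.character(library@sequences), bandSlack)
  ht <- .hitTable(st[, "matches"], st[, "columns"], ids, threshold,
                  minOverlap)
  new("MatchResult", queryId = qid, hits = ht$hits, subHits = ht$sub,
      thresholdPct = threshold, minOverlapBp = minOverlap,
      noSequence = FALSE)
}

.emptyHits <- function() {
  data.frame(record_id = character(), identity_pct = numeric(),
             overlap_bp = numeric(), stringsAsFactors = FALSE)
}

#' @rdname MatchResult-class
#' @param x,object A [MatchResult-class].
#' @export
setGeneric("bestRecordId", function(x) standardGeneric("bestRecordId"))

#' @rdname MatchResult-class
#' @export
setMethod("bestRecordId", "MatchResult", function(x) {
  if (nrow(x@hits)) x@hits$record_id[1] else NA_character_
})

#' @rdname MatchResult-class
#' @export
setGeneric("bestIdentityPct", function(x) standardGeneric("bestIdentityPct"))

#' @rdname MatchResult-class
#' @export
setMethod("bestIdentityPct", "MatchResult", function(x) {
  if (nrow(x@hits)) x@hits$identity_pct[1] else NA_real_
})

#' @rdname MatchResult-class
#' @export
setGeneric("hitsAboveThreshold",
           function(x) standardGeneric("hitsAboveThreshold"))

#' @rdname MatchResult-class
#' @export
setMethod("hitsAboveThreshold", "MatchResult", function(x) x@hits)

setMethod("show", "MatchResult", function(object) {
  cat("MatchResult for", object@queryId, "\n")
  if (object@noSequence) {
    cat("  no sequence data\n")
  } else if (!nrow(object@hits)) {
    cat("  no hits >", object@thresholdPct, "%")
    if (nrow(object@subHits))
      cat("; best overall:", object@subHits$record_id[1],
          sprintf("(%.2f%%)", object@subHits$identity_pct[1]))
    cat("\n")
  } else {
    cat(sprintf("  %d hit(s) > %g%%; best: %s (%.2f%%)\n",
                nrow(object@hits), object@thresholdPct,
                object@hits$record_id[1], object@hits$identity_pct[1]))
  }
})
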