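#' @include AllClasses.R
NULL

#' Accessors for library and query containers
#'
#' @param x,object A [ReferenceLibrary-class] or [QuerySet-class].
#' @param i Index, logical mask or character ids for subsetting.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("recordIds", function(x) standardGeneric("recordIds"))

#' @rdname accessors
#' @export
setMethod("recordIds", "ReferenceLibrary",
          function(x) as.character(x@meta$record_id))

#' @rdname accessors
#' @export
setGeneric("specimenIds", function(x) standardGeneric("specimenIds"))

#' @rdname accessors
#' @export
setMethod("specimenIds", "QuerySet",
          function(x) as.character(x@meta$specimen_id))

#' @rdname accessors
#' @export
setGeneric("recordMeta", function(x) standardGeneric("recordMeta"))

#' @rdname accessors
#' @export
setMethod("recordMeta", "ReferenceLibrary", function(x) x@meta)

#' @rdname accessors
#' @export
setMethod("recordMeta", "QuerySet", function(x) x@meta)

#' @rdname accessors
#' @export
setGeneric("dnaSequences", function(x) standardGeneric("dnaSequences"))

#' @rdname accessors
#' @export
setMethod("dnaSequences", "ReferenceLibrary", function(x) x@sequences)

#' @rdname accessors
#' @export
setMethod("dnaSequences", "QuerySet", function(x) x@sequences)

#' @rdname accessors
#' @export
setGeneric("hasSequence", function(x) standardGeneric("hasSequence"))

#' @rdname accessors
#' @export
setMethod("hasSequence", "QuerySet", function(x) {
  out <- specimenIds(x) %in% names(x@sequences)
  names(out) <- specimenIds(x)
  out
})

#' @rdname accessors
#' @export
setMethod("length", "ReferenceLibrary", function(x) nrow(x@meta))

#' @rdname accessors
#' @export
setMethod("length", "QuerySet", function(x) nrow(x@meta))

#' @rdname accessors
#' @export
setMethod("[", "ReferenceLibrary", function(x, i) {
  if (is.character(i)) i <- match(i, recordIds(x))
  meta <- x@meta[i, , drop = FALSE]
  new("ReferenceLibrary",
      sequences = x@sequences[match(meta$record_id, names(x@sequences))],
      meta = meta)
})

#' @rdname accessors
#' @export
setMethod("[", "QuerySet", function(x, i) {
  if (is.character(i)) i <- match(i, specimenIds(x))
  meta <- x@meta[i, , drop = FALSE]
  keep <- names(x@sequences) %in% meta$specimen_id
  new("QuerySet", sequences = x@sequences[keep], meta = meta)
})

setMethod("show", "ReferenceLibrary", function(object) {
  m <- object@meta
  cat("ReferenceLibrary with", nrow(m), "records\n")
  if (nrow(m)) {
    cat("  years:", paste(range(m$year_added, na.rm = TRUE), collapse = "-"),
        "| public:", sum(m$is_public),
        "| species-named:", sum(!is.na(m$species)),
        "| interim-only:",
        sum(is.na(m$species) & is.na(m$genus) & is.na(m$family) &
              !is.na(m$bin_label)), "\n")
    cat("  sequence length:", paste(range(m$seq_length), collapse = "-"),
        "bp\n")
  }
})

setMethod("show", "QuerySet", function(object) {
  m <- object@meta
  cat("QuerySet with", nrow(m), "specimens,",
      length(object@sequences), "sequenced\n")
  if (nrow(m))
    cat("  morphology to species level:", sum(!is.na(m$species)), "\n")
})

#' Lineage attached to a library record or query specimen
#'
#' @param x A [ReferenceLibrary-class] or [QuerySet-class].
#' @param id A record/specimen identifier.
#' @return A [TaxonLineage-class] (for queries, the morphological
#'   identification; the interim slot is never set from query metadata).
#' @export
setGeneric("lineageOf", function(x, id) standardGeneric("lineageOf"))

#' @rdname lineageOf
#' @export
setMethod("lineageOf", "ReferenceLibrary", function(x, id) {
  j <- match(id, recordIds(x))
  if (is.na(j)) stop("unknown record id: ", id)
  .lineageFromRow(as.list(x@meta[j, , drop = FALSE]))
})

#' @rdname lineageOf
#' @export
setMethod("lineageOf", "QuerySet", function(x, id) {
  j <- match(id, specimenIds(x))
  if (is.na(j)) stop("unknown specimen id: ", id)
  .lineageFromRow(as.list(x@meta[j, , drop = FALSE]))
})

#' Build a lineage-lookup function over one or more containers
#'
#' Several operations (concordance classification, MOTU audits) resolve a
#' record or specimen identifier to its lineage. This helper combines any
#' mix of [ReferenceLibrary-class] and [QuerySet-class] objects into one
#' lookup closure; earlier arguments win on identifier clashes.
#'
#' @param ... Containers to search, in priority order.
#' @return A function `id -> TaxonLineage` (error on unknown ids).
#' @export
lineageLookup <- function(...) {
  sources <- lapply(list(...), .cachedLookup)
  stopifnot(length(sources) > 0)
  function(id) {
    for (s in sources) {
      l <- s(id, missing_ok = TRUE)
      if (!is.null(l)) return(l)
    }
    stop("identifier not found in any source: ", id)
  }
}

# memoising lineage lookup over a container; row access goes through a
# plain data.frame (DataFrame row extraction is far too slow for the
# classifier's inner loop)
.cachedLookup <- function(container) {
  meta <- as.data.frame(recordMeta(container))
  ids <- if (is(container, "ReferenceLibrary")) meta$record_id else
    meta$specimen_id
  cache <- new.env(parent = emptyenv())
  function(id, missing_ok = FALSE) {
    hit <- get0(id, envir = cache, inherits = FALSE)
    if (!is.null(hit)) return(hit)
    j <- match(id, ids)
    if (is.na(j)) {
      if (missing_ok) return(NULL)
      stop("unknown identifier: ", id)
    }
    l <- .lineageFromRow(as.list(meta[j, , drop = FALSE]))
    assign(id, l, envir = cache)
    l
  }
}
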