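#' Read a reference library from FASTA + TSV metadata
#'
#' The FASTA holds the COI sequences (record id = first whitespace-delimited
#' token of the header); the UTF-8, tab-separated metadata table has a header
#' row with the fixed columns `record_id`, the six ranks of [TAXON_RANKS],
#' `bin_label`, `is_public`, `year_added`, `country_of_origin`,
#' `country_of_interception` and `capture_exception`. Empty fields are
#' missing values. The two files must describe the same record set; any
#' identifier present in only one of them is a hard error naming the
#' offending ids, as is a sequence containing non-IUPAC characters or a
#' species name lacking a genus.
#'
#' @param fastaPath Path to the sequence FASTA.
#' @param metadataPath Path to the tab-separated metadata.
#' @return A validated [ReferenceLibrary-class].
#' @export
readLibrary <- function(fastaPath, metadataPath) {
  seqs <- .readFasta(fastaPath)
  meta <- .readTsv(metadataPath, .LIBRARY_COLUMNS)
  .checkIdMatch(names(seqs), meta$record_id, "record")
  seqs <- seqs[match(meta$record_id, names(seqs))]
  meta$is_public <- .asLogical(meta$is_public, "is_public")
  meta$capture_exception <- .asLogical(meta$capture_exception,
                                       "capture_exception")
  meta$year_added <- .asInteger(meta$year_added, "year_added")
  meta$species <- .normalizeSpeciesColumn(meta$species)
  meta$seq_length <- .ungappedLength(seqs)
  lib <- new("ReferenceLibrary", sequences = seqs,
             meta = S4Vectors::DataFrame(meta, check.names = FALSE))
  validObject(lib)
  lib
}

#' Read a query specimen set from FASTA + TSV metadata
#'
#' Metadata columns: `specimen_id`, the six rank columns (the morphological
#' identification, truncated at whatever rank the identifier reached),
#' `life_stage`, `country_of_origin`, `country_of_interception`. Specimens
#' absent from the FASTA are sequencing failures and remain in the set
#' without sequence; FASTA entries lacking a metadata row are an error.
#'
#' @param fastaPath Path to the sequence FASTA (may cover a subset of
#'   specimens).
#' @param metadataPath Path to the tab-separated specimen metadata.
#' @return A validated [QuerySet-class].
#' @export
readQueries <- function(fastaPath, metadataPath) {
  seqs <- .readFasta(fastaPath)
  meta <- .readTsv(metadataPath, .QUERY_COLUMNS)
  orphan <- setdiff(names(seqs), meta$specimen_id)
  if (length(orphan))
    stop("sequences without a metadata row: ", paste(orphan, collapse = ", "))
  meta$life_stage <- ifelse(is.na(meta$life_stage), "unknown",
                            tolower(meta$life_stage))
  bad <- !meta$life_stage %in% LIFE_STAGES
  if (any(bad))
    stop("invalid life_stage for: ",
         paste(meta$specimen_id[bad], collapse = ", "))
  meta$species <- .normalizeSpeciesColumn(meta$species)
  qs <- new("QuerySet",
            sequences = seqs[order(match(names(seqs), meta$specimen_id))],
            meta = S4Vectors::DataFrame(meta, check.names = FALSE))
  validObject(qs)
  qs
}

.readFasta <- function(path) {
  if (!file.exists(path)) stop("no such FASTA file: ", path)
  # readDNAStringSet drops invalid letters with a warning; the contract
  # wants a hard error instead
  seqs <- withCallingHandlers(
    Biostrings::readDNAStringSet(path),
    warning = function(w) {
      if (grepl("invalid one-letter sequence code",
                conditionMessage(w)))
        stop("sequences contain characters outside the IUPAC alphabet: ",
             path, call. = FALSE)
      invokeRestart("muffleWarning")
    })
  names(seqs) <- sub("[[:space:]].*$", "", names(seqs))
  if (anyDuplicated(names(seqs)))
    stop("duplicated FASTA ids: ",
         paste(unique(names(seqs)[duplicated(names(seqs))]), collapse = ", "))
  bad <- .validSeqAlphabet(seqs)
  if (!is.null(bad)) stop(bad)
  seqs
}

.readTsv <- function(path, required) {
  if (!file.exists(path)) stop("no such metadata file: ", path)
  tab <- utils::read.delim(path, sep = "\t", header = TRUE,
                           colClasses = "character", na.strings = c("", "NA"),
                           check.names = FALSE, quote = "",
                           fileEncoding = "UTF-8")
  missing <- setdiff(required, colnames(tab))
  if (length(missing))
    stop("metadata lacks required column(s): ",
         paste(missing, collapse = ", "))
  for (col in colnames(tab)) tab[[col]] <- .squish(tab[[col]])
  idcol <- required[1]
  if (any(is.na(tab[[idcol]])))
    stop("empty ", idcol, " in metadata row(s): ",
         paste(which(is.na(tab[[idcol]])), collapse = ", "))
  tab
}

.checkIdMatch <- function(fastaIds, metaIds, what) {
  onlyFasta <- setdiff(fastaIds, metaIds)
  onlyMeta <- setdiff(metaIds, fastaIds)
  if (length(onlyFasta) || length(onlyMeta))
    stop("FASTA/metadata ", what, " id mismatch",
         if (length(onlyFasta))
           paste0("; only in FASTA: ", paste(onlyFasta, collapse = ", ")),
         if (length(onlyMeta))
           paste0("; only in metadata: ", paste(onlyMeta, collapse = ", ")))
  invisible(TRUE)
}

.asLogical <- function(x, col) {
  out <- rep(NA, length(x))
  out[tolower(x) %in% c("true", "t", "1", "yes")] <- TRUE
  out[tolower(x) %in% c("false", "f", "0", "no")] <- FALSE
  bad <- !is.na(x) & is.na(out)
  if (any(bad)) stop("non-boolean value in column ", col, ": ",
                     paste(unique(x[bad]), collapse = ", "))
  out[is.na(out)] <- FALSE
  out
}

.asInteger <- function(x, col) {
  out <- suppressWarnings(as.integer(x))
  bad <- !is.na(x) & is.na(out)
  if (any(bad)) stop("non-integer value in column ", col, ": ",
                     paste(unique(x[bad]), collapse = ", "))
  out
}

.normalizeSpeciesColumn <- function(x) {
  ifelse(is.na(x), NA_character_,
         vapply(x, .truncateBinomen, character(1), USE.NAMES = FALSE))
}

.ungappedLength <- function(seqs) {
  if (!length(seqs)) return(integer())
  af <- Biostrings::alphabetFrequency(seqs)
  as.integer(Biostrings::width(seqs) - af[, "-", drop = TRUE] -
               af[, ".", drop = TRUE])
}

#' Write a reference library in the package's FASTA/TSV dialect
#'
#' Round-trips everything [readLibrary] reads, including the
#' origin-versus-interception country pair.
#'
#' @param library A [ReferenceLibrary-class].
#' @param fastaPath,metadataPath Output paths.
#' @return Invisibly, the two paths.
#' @export
writeLibrary <- function(library, fastaPath, metadataPath) {
  stopifnot(is(library, "ReferenceLibrary"))
  Biostrings::writeXStringSet(library@sequences, fastaPath)
  out <- as.data.frame(library@meta[, .LIBRARY_COLUMNS])
  out$is_public <- tolower(as.character(out$is_public))
  out$capture_exception <- tolower(as.character(out$capture_exception))
  .writeTsv(out, metadataPath)
  invisible(c(fastaPath, metadataPath))
}

#' Write a query set in the package's FASTA/TSV dialect
#' @param queries A [QuerySet-class].
#' @param fastaPath,metadataPath Output paths.
#' @return Invisibly, the two paths.
#' @export
writeQueries <- function(queries, fastaPath, metadataPath) {
  stopifnot(is(queries, "QuerySet"))
  Biostrings::writeXStringSet(queries@sequences, fastaPath)
  .writeTsv(as.data.frame(queries@meta[, .QUERY_COLUMNS]), metadataPath)
  invisible(c(fastaPath, metadataPath))
}

.writeTsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, na = "",
                     row.names = FALSE, fileEncoding = "UTF-8")
}

#' Materialise a calendar-year snapshot of a library view
#'
#' Reproduces the two access-controlled search libraries of the BOLD
#' identification engine as they stood at the end of a given year:
#' \describe{
#'   \item{SLBR}{"species level barcode records": records identified to
#'     species \emph{or} carrying interim taxonomy (a BIN label), at least
#'     `minLength` bp — non-public records included.}
#'   \item{PRBD}{"public record barcode database": published (public)
#'     records of at least `minLength` bp, any identification rank.}
#' }
#' Snapshots are monotone: `snapshot(y1)` is a subset of `snapshot(y2)`
#' whenever `y1 <= y2` under the same view.
#'
#' @param library A [ReferenceLibrary-class].
#' @param year Calendar year; records with `year_added` after it are
#'   excluded.
#' @param view "SLBR" or "PRBD".
#' @param minLength Minimum ungapped sequence length in bp (default 500).
#' @return A [ReferenceLibrary-class] restricted to the snapshot.
#' @export
librarySnapshot <- function(library, year, view = c("SLBR", "PRBD"),
                            minLength = 500) {
  stopifnot(is(library, "ReferenceLibrary"), minLength > 0)
  view <- match.arg(view)
  keep <- .snapshotMask(library@meta, year, view, minLength)
  library[keep]
}

.snapshotMask <- function(meta, year, view, minLength) {
  keep <- !is.na(meta$year_added) & meta$year_added <= year &
    meta$seq_length >= minLength
  if (view == "SLBR") {
    keep & (!is.na(meta$species) | !is.na(meta$bin_label))
  } else {
    keep & meta$is_public
  }
}
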