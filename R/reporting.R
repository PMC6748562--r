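#' One-decimal percentage with round-half-away-from-zero
#'
#' The reporting convention used throughout the audit: `100 * n / d`,
#' rounded to one decimal with halves rounded away from zero — "42.3%
#' (85/201)" style. Computed in integer arithmetic (tenths of a percent),
#' so the half-way rule is exact and immune to floating-point
#' representation of the quotient.
#'
#' @param numerator Non-negative integer(s), at most `denominator`.
#' @param denominator Positive integer(s).
#' @return Numeric percentage(s) with one decimal, in \[0, 100\].
#' @examples
#' pct(85, 201)  # 42.3
#' pct(47, 55)   # 85.5
#' @export
pct <- function(numerator, denominator) {
  if (any(denominator <= 0)) stop("denominator must be positive")
  if (any(numerator < 0) || any(numerator > denominator))
    stop("numerator must lie in [0, denominator]")
  if (any(numerator != round(numerator)) ||
      any(denominator != round(denominator)))
    stop("pct expects integer counts")
  tenths <- (1000 * numerator) %/% denominator +
    as.integer(2 * ((1000 * numerator) %% denominator) >= denominator)
  tenths / 10
}

#' Identified-percent time series per (year, view)
#'
#' For each snapshot, the percentage of sequenced queries that received any
#' identification (every category except "no match"). Under library growth
#' the series is non-decreasing per view, and the SLBR row is at least the
#' PRBD row whenever the public snapshot is a subset of the species-level
#' one.
#'
#' @inheritParams concordanceTable
#' @return data.frame: year, view, n_sequenced, n_identified,
#'   pct_identified.
#' @export
identificationTimeseries <- function(queries, library, years,
                                     views = c("SLBR", "PRBD"),
                                     threshold = 98, minOverlap = 300,
                                     minLength = 500, stats = NULL) {
  stopifnot(is(queries, "QuerySet"), is(library, "ReferenceLibrary"))
  views <- match.arg(views, several.ok = TRUE)
  if (is.null(stats)) stats <- matchStats(queries, library)
  tab <- concordanceTable(queries, library, years, views,
                          threshold = threshold, minOverlap = minOverlap,
                          minLength = minLength, stats = stats)
  out <- list()
  for (view in views) {
    for (year in years) {
      sub <- tab[tab$year == year & tab$view == view, ]
      nSeq <- sub$n_sequenced[1]
      nId <- sum(sub$n[sub$category != "4_no_match"])
      out[[length(out) + 1]] <- data.frame(
        year = year, view = view, n_sequenced = nSeq,
        n_identified = nId,
        pct_identified = if (nSeq > 0) pct(nId, nSeq) else NA_real_,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Structured run log
#'
#' Auditability is the point of the exercise: every CLI run writes a small
#' plain-text log with the seed, parameter values and snapshot sizes used.
#'
#' @param path Log file path.
#' @param ... Named values to record.
#' @return Invisibly, `path`.
#' @keywords internal
.writeRunLog <- function(path, ...) {
  vals <- list(...)
  lines <- c(sprintf("timestamp: %s", format(Sys.time(), "%Y-%m-%dT%H:%M:%S")),
             vapply(names(vals), function(nm)
               sprintf("%s: %s", nm,
                       paste(format(vals[[nm]]), collapse = ", ")),
               character(1)))
  writeLines(lines, path)
  invisible(path)
}
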