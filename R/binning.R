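#' Cluster sequences into BIN-surrogate MOTUs
#'
#' Single-linkage clustering on uncorrected p-distance: two sequences end
#' up in the same cluster if and only if they are connected by a chain of
#' pairs each within `threshold`. This is the seed stage of the BIN
#' framework; the Markov refinement applied by the production RESL
#' algorithm is deliberately not emulated, so no equivalence with official
#' BIN pages is claimed. Clustering is performed with
#' [stats::hclust]`(method = "single")` cut at the threshold; pairs whose
#' aligned overlap is below `minOverlap` contribute no edge.
#'
#' Cluster identifiers are deterministic: the lexicographically smallest
#' member id. One-member clusters get status "singleton" immediately;
#' multi-member clusters are unaudited (status NA) until [auditCluster].
#'
#' @param x Sequences to cluster: a [ReferenceLibrary-class],
#'   [QuerySet-class] (sequenced specimens only), named character vector or
#'   named [Biostrings::DNAStringSet].
#' @param threshold Maximum p-distance for an edge (default 0.022, the
#'   conventional BIN seed threshold).
#' @param minOverlap Minimum aligned overlap in bp (default 300).
#' @param bandSlack Band half-width (see [pairwiseIdentity]).
#' @return List of [MotuCluster-class], ordered by cluster id.
#' @export
clusterSequences <- function(x, threshold = 0.022, minOverlap = 300,
                             bandSlack = 50) {
  seqs <- .asNamedSeqs(x)
  n <- length(seqs)
  if (n == 0) return(list())
  ids <- names(seqs)
  if (n == 1)
    return(list(new("MotuCluster", clusterId = ids, members = ids,
                    status = "singleton", namesPerRank = list())))
  st <- .cppPairwiseStats(unname(seqs), bandSlack)
  d <- 1 - st$matches / st$columns
  d[st$columns < minOverlap] <- 1.5  # no edge: beyond any valid threshold
  diag(d) <- 0
  dimnames(d) <- list(ids, ids)
  hc <- stats::hclust(stats::as.dist(d), method = "single")
  grp <- stats::cutree(hc, h = threshold)
  .clustersFromGroups(ids, grp)
}

.clustersFromGroups <- function(ids, grp) {
  cl <- lapply(split(ids, grp), function(members) {
    members <- sort(members)
    new("MotuCluster", clusterId = members[1], members = members,
        status = if (length(members) == 1) "singleton" else NA_character_,
        namesPerRank = list())
  })
  cl[order(vapply(cl, function(x) x@clusterId, character(1)))]
}

.asNamedSeqs <- function(x) {
  if (is(x, "ReferenceLibrary") || is(x, "QuerySet"))
    return(as.character(x@sequences))
  if (is(x, "DNAStringSet")) {
    out <- as.character(x)
    if (is.null(names(out))) stop("sequences must be named")
    return(out)
  }
  stopifnot(is.character(x), !is.null(names(x)))
  x
}

#' Audit the taxonomic concordance of a MOTU cluster
#'
#' A multi-member cluster is \emph{discordant} when some rank named by at
#' least two members carries two or more distinct names (case-insensitive),
#' and \emph{concordant} otherwise — so a cluster mixing a family-only
#' record with a congeneric record of that family is concordant (the
#' higher-level name is consistent with the lower-level one), while a
#' cluster mixing two families, or two congeneric species names, is
#' discordant at that rank. Interim-only members impose no naming
#' constraint. Single-member clusters are singletons and are excluded from
#' the concordance denominator.
#'
#' @param cluster A [MotuCluster-class].
#' @param lookup A function `id -> TaxonLineage`, or a
#'   [ReferenceLibrary-class]/[QuerySet-class] (see [lineageLookup]).
#' @return The cluster with `status` set and `namesPerRank` filled with the
#'   distinct names observed at each named rank.
#' @export
auditCluster <- function(cluster, lookup) {
  stopifnot(is(cluster, "MotuCluster"))
  lookup <- .asLookup(lookup)
  lineages <- lapply(cluster@members, lookup)
  perRank <- list()
  for (r in TAXON_RANKS) {
    nm <- unlist(lapply(lineages, function(l) unname(l@ranks[r])))
    nm <- nm[!is.na(nm)]
    if (length(nm)) perRank[[r]] <- unique(nm)
  }
  cluster@namesPerRank <- perRank
  if (length(cluster@members) == 1) {
    cluster@status <- "singleton"
  } else {
    discord <- any(vapply(perRank,
                          function(nm) length(unique(tolower(nm))) > 1,
                          logical(1)))
    cluster@status <- if (discord) "discordant" else "concordant"
  }
  validObject(cluster)
  cluster
}

#' @rdname auditCluster
#' @param clusters List of [MotuCluster-class].
#' @export
auditClusters <- function(clusters, lookup) {
  lookup <- .asLookup(lookup)
  lapply(clusters, auditCluster, lookup = lookup)
}

#' Size and concordance summary over a clustering
#'
#' @param clusters List of [MotuCluster-class] (audited or not; concordance
#'   fractions need an audit first).
#' @return List of counts and one-decimal percentages: total clusters,
#'   singletons, multi-member clusters, concordant/discordant among the
#'   multi-member ones, and clusters built from 10 or fewer records.
#' @export
binSizeSummary <- function(clusters) {
  sizes <- vapply(clusters, function(x) length(x@members), integer(1))
  status <- vapply(clusters, function(x) x@status, character(1))
  n <- length(clusters)
  nSingle <- sum(sizes == 1)
  nMulti <- n - nSingle
  nLe10 <- sum(sizes <= 10)
  res <- list(n_clusters = n, n_singleton = nSingle, n_multi = nMulti,
              n_concordant = sum(!is.na(status) & status == "concordant"),
              n_discordant = sum(!is.na(status) & status == "discordant"),
              n_le_10_members = nLe10)
  res$pct_singleton <- if (n) pct(nSingle, n) else NA_real_
  res$pct_multi <- if (n) pct(nMulti, n) else NA_real_
  res$pct_le_10_members <- if (n) pct(nLe10, n) else NA_real_
  res$pct_concordant <- if (nMulti) pct(res$n_concordant, nMulti) else
    NA_real_
  res$pct_discordant <- if (nMulti) pct(res$n_discordant, nMulti) else
    NA_real_
  res
}

setMethod("show", "MotuCluster", function(object) {
  cat(sprintf("MotuCluster %s: %d member(s), status %s\n", object@clusterId,
              length(object@members), object@status))
  for (r in names(object@namesPerRank))
    cat(sprintf("  %s: %s\n", r,
                paste(object@namesPerRank[[r]], collapse = " | ")))
})

#' Write cluster membership and audit reports
#'
#' `writeMotuTable` emits a TSV (record_id, cluster_id, status);
#' `writeMotuAudit` a JSON report listing the distinct names per rank for
#' every discordant cluster.
#'
#' @param clusters List of audited [MotuCluster-class].
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
writeMotuTable <- function(clusters, path) {
  rows <- lapply(clusters, function(x)
    data.frame(record_id = x@members, cluster_id = x@clusterId,
               status = x@status, stringsAsFactors = FALSE))
  .writeTsv(do.call(rbind, rows), path)
  invisible(path)
}

#' @rdname writeMotuTable
#' @export
writeMotuAudit <- function(clusters, path) {
  disc <- Filter(function(x) !is.na(x@status) && x@status == "discordant",
                 clusters)
  report <- list(
    summary = binSizeSummary(clusters),
    discordant = lapply(disc, function(x)
      list(cluster_id = x@clusterId, n_members = length(x@members),
           members = x@members, distinct_names_per_rank = x@namesPerRank)))
  jsonlite::write_json(report, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}
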