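#' Configuration for the synthetic interception study generator
#'
#' Bundles every tunable of the synthetic-data generator with defaults that
#' emulate a desk-scale border-interception barcoding study: a
#' Lepidoptera-like multi-rank taxonomy, COI-length sequences evolved under
#' a uniform (Jukes-Cantor-like) substitution model with intraspecific
#' divergence well inside and interspecific divergence well outside the
#' MOTU threshold, calendar-year library growth 2009-2019 with a plateau in
#' the final years, a public/non-public record split, morphological
#' identifications truncated at varying ranks with occasional
#' misidentification, a 16.6% sequencing-failure rate and a 6.5% rate of
#' short (407 bp) barcode fragments.
#'
#' @param seed Integer seed; every generator draw derives from it.
#' @param n_families,genera_per_family,species_per_genus Taxonomy shape
#'   (families are paired into superfamilies, genera alternate between two
#'   subfamilies per family).
#' @param seq_length_bp Barcode length (default 658, full-length COI-5P).
#' @param intraspecific_divergence Expected per-site substitutions from the
#'   species ancestor to each haplotype (default 0.005).
#' @param interspecific_divergence Expected per-site substitutions from a
#'   genus ancestor to each species ancestor (default 0.05); must exceed
#'   the intraspecific rate.
#' @param years Calendar years over which the library grows.
#' @param records_per_year Integer schedule, same length as `years`.
#' @param public_fraction_by_year Probability a record deposited that year
#'   is public; same length as `years`.
#' @param morph_rank_distribution Named probabilities (summing to 1) over
#'   [TAXON_RANKS] for the rank at which morphology identifies a specimen.
#' @param morph_misid_rate Probability a query's morphological lineage is
#'   swapped with that of a species from a different superfamily.
#' @param library_misid_rate Probability a reference record's name is
#'   swapped with a congener (or, failing that, a confamilial species);
#'   recorded in the truth ledger.
#' @param sequencing_failure_rate Probability a query yields no sequence
#'   (default 0.166).
#' @param fragment_rate,fragment_length_bp Probability and length of short
#'   barcode fragments among sequenced queries (defaults 0.065 and 407).
#' @param bin_only_rate Probability a reference record carries interim
#'   taxonomy only (a BIN label, no Linnaean names).
#' @param short_record_rate Probability a reference record is shorter than
#'   500 bp and therefore excluded from both library views.
#' @param library_species_coverage Fraction of the true species pool that
#'   can ever enter the reference library (uncovered species drive the
#'   no-match category).
#' @param seed_full_coverage When TRUE the first records of the first year
#'   cover every library-pool species once before random accumulation
#'   starts.
#' @param indel_rate Optional per-site indel probability for haplotypes
#'   (default 0; barcodes are length-conserved).
#' @return A validated list of class "SimulationConfig".
#' @export
simulationConfig <- function(seed = 1L,
                             n_families = 8L,
                             genera_per_family = 3L,
                             species_per_genus = 4L,
                             seq_length_bp = 658L,
                             intraspecific_divergence = 0.005,
                             interspecific_divergence = 0.05,
                             years = 2009:2019,
                             records_per_year = c(40L, 45L, 50L, 45L, 40L,
                                                  35L, 30L, 6L, 5L, 4L, 3L),
                             public_fraction_by_year = rep(0.4, 11),
                             morph_rank_distribution = c(
                               order = 0, superfamily = 0.05, family = 0.40,
                               subfamily = 0.067, genus = 0.10,
                               species = 0.383),
                             morph_misid_rate = 0.025,
                             library_misid_rate = 0.02,
                             sequencing_failure_rate = 0.166,
                             fragment_rate = 0.065,
                             fragment_length_bp = 407L,
                             bin_only_rate = 0.10,
                             short_record_rate = 0.05,
                             library_species_coverage = 0.80,
                             seed_full_coverage = FALSE,
                             indel_rate = 0) {
  cfg <- list(seed = as.integer(seed), n_families = as.integer(n_families),
              genera_per_family = as.integer(genera_per_family),
              species_per_genus = as.integer(species_per_genus),
              seq_length_bp = as.integer(seq_length_bp),
              intraspecific_divergence = intraspecific_divergence,
              interspecific_divergence = interspecific_divergence,
              years = as.integer(years),
              records_per_year = as.integer(records_per_year),
              public_fraction_by_year = public_fraction_by_year,
              morph_rank_distribution = morph_rank_distribution,
              morph_misid_rate = morph_misid_rate,
              library_misid_rate = library_misid_rate,
              sequencing_failure_rate = sequencing_failure_rate,
              fragment_rate = fragment_rate,
              fragment_length_bp = as.integer(fragment_length_bp),
              bin_only_rate = bin_only_rate,
              short_record_rate = short_record_rate,
              library_species_coverage = library_species_coverage,
              seed_full_coverage = isTRUE(seed_full_coverage),
              indel_rate = indel_rate)
  .validateConfig(cfg)
  class(cfg) <- "SimulationConfig"
  cfg
}

.validateConfig <- function(cfg) {
  with(cfg, {
    if (n_families < 1 || genera_per_family < 1 || species_per_genus < 1)
      stop("degenerate taxonomy: need at least one species")
    if (seq_length_bp < 1) stop("seq_length_bp must be positive")
    probs <- c(intraspecific_divergence, interspecific_divergence,
               morph_misid_rate, library_misid_rate,
               sequencing_failure_rate, fragment_rate, bin_only_rate,
               short_record_rate, library_species_coverage, indel_rate,
               public_fraction_by_year, morph_rank_distribution)
    if (any(probs < 0 | probs > 1))
      stop("probabilities must lie in [0, 1]")
    if (interspecific_divergence <= intraspecific_divergence)
      stop("interspecific divergence must exceed intraspecific divergence")
    if (length(records_per_year) != length(years) ||
        length(public_fraction_by_year) != length(years))
      stop("schedules must have the same length as years")
    if (!setequal(names(morph_rank_distribution), TAXON_RANKS))
      stop("morph_rank_distribution must be named by all six ranks")
    if (abs(sum(morph_rank_distribution) - 1) > 1e-8)
      stop("morph_rank_distribution must sum to 1")
    if (fragment_length_bp < 1 || fragment_length_bp > seq_length_bp)
      stop("fragment_length_bp must lie in [1, seq_length_bp]")
  })
  invisible(TRUE)
}

.BASES <- c("A", "C", "G", "T")

# uniform substitution: each site flips with probability mu to one of the
# three other bases, chosen uniformly. Sequences are integer vectors 1..4.
.mutateSeq <- function(seq, mu) {
  if (mu <= 0) return(seq)
  hit <- which(stats::runif(length(seq)) < mu)
  if (length(hit)) {
    shift <- sample.int(3L, length(hit), replace = TRUE)
    seq[hit] <- ((seq[hit] - 1L + shift) %% 4L) + 1L
  }
  seq
}

.applyIndels <- function(seq, rate) {
  if (rate <= 0) return(seq)
  k <- stats::rbinom(1L, length(seq), rate)
  while (k > 0) {
    if (stats::runif(1) < 0.5 && length(seq) > 1) {
      seq <- seq[-sample.int(length(seq), 1L)]
    } else {
      pos <- sample.int(length(seq) + 1L, 1L)
      seq <- append(seq, sample.int(4L, 1L), after = pos - 1L)
    }
    k <- k - 1L
  }
  seq
}

.intsToDNA <- function(seq) paste(.BASES[seq], collapse = "")

#' Generate the true taxonomy and ancestral barcode sequences
#'
#' Builds a fully known ground truth: a six-rank taxonomy (one order,
#' families paired into superfamilies, two subfamilies per family, genera
#' and species below), and per-species ancestral sequences evolved along
#' that hierarchy under the uniform substitution model — family ancestors
#' at four times, genus ancestors at two times, and species ancestors at
#' one times the interspecific divergence from their parent. Every species
#' also receives a synthetic interim label (its "true BIN"). Deterministic
#' under the config seed.
#'
#' @param config A [simulationConfig] object.
#' @return List of class "BarcodeTruth": `taxonomy` (data.frame with
#'   species_id, the six rank columns and bin), `ancestors` (named list of
#'   integer sequences) and the config.
#' @export
generateTruth <- function(config) {
  stopifnot(inherits(config, "SimulationConfig"))
  set.seed(config$seed)
  root <- sample.int(4L, config$seq_length_bp, replace = TRUE)
  mu <- config$interspecific_divergence
  rows <- list()
  ancestors <- list()
  sp <- 0L
  for (f in seq_len(config$n_families)) {
    famAnc <- .mutateSeq(root, 4 * mu)
    famName <- sprintf("Simfamidae%02d", f)
    superName <- sprintf("Simfamoidea%02d", (f + 1L) %/% 2L)
    for (g in seq_len(config$genera_per_family)) {
      genAnc <- .mutateSeq(famAnc, 2 * mu)
      genName <- sprintf("Simgenus%02d%02d", f, g)
      subName <- sprintf("Simfaminae%02d%s", f,
                         if (g %% 2L) "a" else "b")
      for (s in seq_len(config$species_per_genus)) {
        sp <- sp + 1L
        spAnc <- .mutateSeq(genAnc, mu)
        spId <- sprintf("sp%04d", sp)
        rows[[sp]] <- data.frame(
          species_id = spId, order = "Simlepidoptera",
          superfamily = superName, family = famName, subfamily = subName,
          genus = genName,
          species = sprintf("%s simspec%02d", genName, s),
          bin = sprintf("SIM:%04d", sp), stringsAsFactors = FALSE)
        ancestors[[spId]] <- spAnc
      }
    }
  }
  structure(list(taxonomy = do.call(rbind, rows), ancestors = ancestors,
                 config = config),
            class = "BarcodeTruth")
}

#' Generate a growing reference library with known truth
#'
#' Draws records year by year following the growth schedule: each record is
#' a haplotype mutated from its species ancestor at the intraspecific
#' divergence, stamped with its deposit year, a public flag sampled from
#' that year's public fraction, and either its species' full lineage, an
#' interim-only (BIN) identification, or — with the library
#' misidentification rate — the lineage of a congener or confamilial
#' species. Species are drawn from the covered fraction of the pool; when
#' `seed_full_coverage` is set the first year opens with one record per
#' covered species. A small fraction of records is shorter than the
#' 500 bp view cut-off.
#'
#' @param truth Output of [generateTruth].
#' @param config The same [simulationConfig].
#' @return List: `library` (a [ReferenceLibrary-class]) and `ledger`
#'   (data.frame with record_id, true/labelled species ids and flags).
#' @export
generateLibrary <- function(truth, config = truth$config) {
  stopifnot(inherits(truth, "BarcodeTruth"))
  set.seed(config$seed + 1L)
  tax <- truth$taxonomy
  nSp <- nrow(tax)
  nPool <- max(1L, round(config$library_species_coverage * nSp))
  pool <- sort(sample.int(nSp, nPool))

  speciesDraw <- integer(0)
  for (i in seq_along(config$years)) {
    n <- config$records_per_year[i]
    if (n == 0) next
    drawn <- if (i == 1L && config$seed_full_coverage) {
      first <- pool[seq_len(min(nPool, n))]
      extra <- if (n > nPool)
        pool[sample.int(nPool, n - nPool, replace = TRUE)] else integer(0)
      c(first, extra)
    } else {
      pool[sample.int(nPool, n, replace = TRUE)]
    }
    speciesDraw <- c(speciesDraw, drawn)
    names(speciesDraw) <- NULL
  }
  total <- length(speciesDraw)
  yearOf <- rep(config$years, config$records_per_year)
  pubFrac <- rep(config$public_fraction_by_year, config$records_per_year)

  countries <- c("Costa Rica", "Ecuador", "Ghana", "Thailand", "Mexico",
                 "Colombia", "Italy", "Australia")
  ids <- sprintf("LIB%05d", seq_len(total))
  seqs <- character(total)
  labIdxs <- integer(total)
  binOnlys <- logical(total)
  misids <- logical(total)
  isPubs <- logical(total)
  excs <- logical(total)
  origins <- character(total)
  for (k in seq_len(total)) {
    spIdx <- speciesDraw[k]
    hap <- .mutateSeq(truth$ancestors[[spIdx]],
                      config$intraspecific_divergence)
    hap <- .applyIndels(hap, config$indel_rate)
    short <- stats::runif(1) < config$short_record_rate
    if (short) hap <- hap[seq_len(sample(350:499, 1L))]
    seqs[k] <- .intsToDNA(hap)
    binOnlys[k] <- stats::runif(1) < config$bin_only_rate
    misids[k] <- !binOnlys[k] &&
      stats::runif(1) < config$library_misid_rate
    labIdxs[k] <- if (misids[k]) .swapRelative(tax, spIdx) else spIdx
    isPubs[k] <- stats::runif(1) < pubFrac[k]
    excs[k] <- stats::runif(1) < 0.05
    origins[k] <- sample(countries, 1L)
  }
  rankCol <- function(col) ifelse(binOnlys, NA_character_,
                                  tax[[col]][labIdxs])
  meta <- data.frame(
    record_id = ids, order = rankCol("order"),
    superfamily = rankCol("superfamily"), family = rankCol("family"),
    subfamily = rankCol("subfamily"), genus = rankCol("genus"),
    species = rankCol("species"),
    bin_label = tax$bin[speciesDraw],  # the BIN follows the sequence
    is_public = isPubs, year_added = yearOf,
    country_of_origin = origins,
    country_of_interception = ifelse(excs, "USA", NA_character_),
    capture_exception = excs, seq_length = nchar(seqs),
    stringsAsFactors = FALSE)
  ledger <- data.frame(
    record_id = ids, true_species_id = tax$species_id[speciesDraw],
    labeled_species_id = ifelse(binOnlys, NA_character_,
                                tax$species_id[labIdxs]),
    misidentified = misids, bin_only = binOnlys,
    stringsAsFactors = FALSE)
  lib <- new("ReferenceLibrary",
             sequences = Biostrings::DNAStringSet(structure(seqs,
                                                            names = ids)),
             meta = S4Vectors::DataFrame(meta, check.names = FALSE))
  validObject(lib)
  list(library = lib, ledger = ledger)
}

# a congener if one exists, otherwise a confamilial species from another
# genus (library misidentifications are near misses)
.swapRelative <- function(tax, spIdx) {
  congeners <- which(tax$genus == tax$genus[spIdx] &
                       seq_len(nrow(tax)) != spIdx)
  if (length(congeners)) return(.sampleOne(congeners))
  confam <- which(tax$family == tax$family[spIdx] &
                    seq_len(nrow(tax)) != spIdx)
  if (length(confam)) return(.sampleOne(confam))
  .sampleOne(setdiff(seq_len(nrow(tax)), spIdx))
}

# cross-superfamily swap: a morphological misidentification that conflicts
# at every rank the truncated lineage can retain below order
.swapForeign <- function(tax, spIdx) {
  foreign <- which(tax$superfamily != tax$superfamily[spIdx])
  if (!length(foreign)) foreign <- setdiff(seq_len(nrow(tax)), spIdx)
  .sampleOne(foreign)
}

.sampleOne <- function(x) x[sample.int(length(x), 1L)]

#' Generate intercepted query specimens with known ground truth
#'
#' Samples `n` specimens uniformly from the true species (covered by the
#' library or not), evolves each barcode from its species ancestor at the
#' intraspecific divergence, drops sequences at the sequencing-failure
#' rate, truncates a fraction to short fragments, and attaches a
#' morphological identification truncated at a rank drawn from the
#' configured distribution — swapped, at the morphological
#' misidentification rate, with the lineage of a species from a different
#' superfamily before truncation.
#'
#' @param truth Output of [generateTruth].
#' @param config The same [simulationConfig].
#' @param n Number of specimens (default 241).
#' @return List: `queries` (a [QuerySet-class]) and `ledger` (data.frame
#'   with specimen_id, true/labelled species ids, morph rank and flags).
#' @export
generateQueries <- function(truth, config = truth$config, n = 241L) {
  stopifnot(inherits(truth, "BarcodeTruth"), n >= 1)
  set.seed(config$seed + 2L)
  tax <- truth$taxonomy
  nSp <- nrow(tax)
  countries <- c("Costa Rica", "Ecuador", "Ghana", "Thailand", "Mexico",
                 "Colombia", "Italy", "Australia")
  ports <- c("Miami FL", "Los Angeles CA", "New York NY", "Houston TX",
             "San Juan PR")
  stages <- c("larva", "pupa", "adult", "unknown")
  stageP <- c(0.70, 0.10, 0.15, 0.05)

  ids <- sprintf("Q%04d", seq_len(n))
  seqs <- character(n)
  hasSeq <- logical(n)
  frags <- logical(n)
  misids <- logical(n)
  spIdxs <- integer(n)
  labIdxs <- integer(n)
  depths <- integer(n)
  ranks <- character(n)
  stage <- character(n)
  origin <- character(n)
  port <- character(n)
  for (k in seq_len(n)) {
    spIdxs[k] <- sample.int(nSp, 1L)
    fail <- stats::runif(1) < config$sequencing_failure_rate
    if (!fail) {
      hap <- .mutateSeq(truth$ancestors[[spIdxs[k]]],
                        config$intraspecific_divergence)
      hap <- .applyIndels(hap, config$indel_rate)
      frags[k] <- stats::runif(1) < config$fragment_rate
      if (frags[k] && length(hap) > config$fragment_length_bp) {
        start <- sample.int(length(hap) - config$fragment_length_bp + 1L,
                            1L)
        hap <- hap[start:(start + config$fragment_length_bp - 1L)]
      }
      seqs[k] <- .intsToDNA(hap)
      hasSeq[k] <- TRUE
    }
    misids[k] <- stats::runif(1) < config$morph_misid_rate
    labIdxs[k] <- if (misids[k]) .swapForeign(tax, spIdxs[k]) else
      spIdxs[k]
    ranks[k] <- sample(names(config$morph_rank_distribution), 1L,
                       prob = config$morph_rank_distribution)
    depths[k] <- .rankDepth(ranks[k])
    stage[k] <- sample(stages, 1L, prob = stageP)
    origin[k] <- sample(countries, 1L)
    port[k] <- sample(ports, 1L)
  }
  rankCol <- function(col, minDepth)
    ifelse(depths >= minDepth, tax[[col]][labIdxs], NA_character_)
  meta <- data.frame(
    specimen_id = ids, order = rankCol("order", 0L),
    superfamily = rankCol("superfamily", 1L),
    family = rankCol("family", 2L), subfamily = rankCol("subfamily", 3L),
    genus = rankCol("genus", 4L), species = rankCol("species", 5L),
    life_stage = stage, country_of_origin = origin,
    country_of_interception = port, stringsAsFactors = FALSE)
  ledger <- data.frame(
    specimen_id = ids, true_species_id = tax$species_id[spIdxs],
    labeled_species_id = tax$species_id[labIdxs], misidentified = misids,
    morph_rank = ranks, has_sequence = hasSeq, fragment = frags,
    stringsAsFactors = FALSE)
  seqSet <- Biostrings::DNAStringSet(structure(seqs[hasSeq],
                                               names = ids[hasSeq]))
  qs <- new("QuerySet", sequences = seqSet,
            meta = S4Vectors::DataFrame(meta, check.names = FALSE))
  validObject(qs)
  list(queries = qs, ledger = ledger)
}

#' Run the full generator and optionally write its files
#'
#' Convenience wrapper: truth, library and queries in one call; when `dir`
#' is given the library and query FASTA/TSV pairs, the two truth ledgers
#' and the config (as YAML) are written there in the package's I/O dialect.
#'
#' @param config A [simulationConfig].
#' @param nQueries Number of query specimens.
#' @param dir Optional output directory (created if missing).
#' @return List with `truth`, `library`, `libraryLedger`, `queries`,
#'   `queryLedger`, `config`.
#' @export
runSimulation <- function(config = simulationConfig(), nQueries = 241L,
                          dir = NULL) {
  truth <- generateTruth(config)
  lib <- generateLibrary(truth, config)
  qry <- generateQueries(truth, config, nQueries)
  out <- list(truth = truth, library = lib$library,
              libraryLedger = lib$ledger, queries = qry$queries,
              queryLedger = qry$ledger, config = config)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    writeLibrary(lib$library, file.path(dir, "library.fasta"),
                 file.path(dir, "library.tsv"))
    writeQueries(qry$queries, file.path(dir, "queries.fasta"),
                 file.path(dir, "queries.tsv"))
    .writeTsv(lib$ledger, file.path(dir, "truth_library.tsv"))
    .writeTsv(qry$ledger, file.path(dir, "truth_queries.tsv"))
    cfg <- config
    class(cfg) <- NULL
    cfg$morph_rank_distribution <- as.list(cfg$morph_rank_distribution)
    yaml::write_yaml(cfg, file.path(dir, "config.yaml"))
  }
  out
}

#' Read a generator config back from YAML
#' @param path Path to a YAML file written by [runSimulation].
#' @return A [simulationConfig].
#' @export
readSimulationConfig <- function(path) {
  raw <- yaml::read_yaml(path)
  raw$morph_rank_distribution <- unlist(raw$morph_rank_distribution)
  do.call(simulationConfig, raw)
}
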