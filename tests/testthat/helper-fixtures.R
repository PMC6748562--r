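# Fixture builders and independent oracles shared across the suite.

BASES <- c("A", "C", "G", "T")

randomSeq <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(BASES, n, replace = TRUE), collapse = "")
}

# substitute fixed positions with a deterministic different base
mutateAt <- function(seq, positions) {
  v <- strsplit(seq, "")[[1]]
  for (p in positions) v[p] <- setdiff(BASES, v[p])[1]
  paste(v, collapse = "")
}

# mutate k random positions (all real differences)
mutateRandom <- function(seq, k) {
  mutateAt(seq, sample.int(nchar(seq), k))
}

IUPAC_SETS <- list(A = "A", C = "C", G = "G", T = "T",
                   R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"),
                   W = c("A", "T"), K = c("G", "T"), M = c("A", "C"),
                   B = c("C", "G", "T"), D = c("A", "G", "T"),
                   H = c("A", "C", "T"), V = c("A", "C", "G"),
                   N = c("A", "C", "G", "T"))

# oracle: character-by-character identity for equal-length, gap-free pairs
bfIdentityGapFree <- function(a, b) {
  va <- strsplit(toupper(a), "")[[1]]
  vb <- strsplit(toupper(b), "")[[1]]
  stopifnot(length(va) == length(vb))
  m <- mapply(function(x, y)
    length(intersect(IUPAC_SETS[[x]], IUPAC_SETS[[y]])) > 0, va, vb)
  list(matches = sum(m), columns = length(va),
       identity_pct = 100 * sum(m) / length(va))
}

# oracle: connected components of the thresholded p-distance graph by BFS
bfComponents <- function(d, threshold) {
  n <- nrow(d)
  comp <- rep(NA_integer_, n)
  cid <- 0L
  for (s in seq_len(n)) {
    if (!is.na(comp[s])) next
    cid <- cid + 1L
    queue <- s
    comp[s] <- cid
    while (length(queue)) {
      v <- queue[1]
      queue <- queue[-1]
      nbr <- which(!is.na(d[v, ]) & d[v, ] <= threshold & is.na(comp))
      comp[nbr] <- cid
      queue <- c(queue, nbr)
    }
  }
  comp
}

# build a ReferenceLibrary directly from sequences and metadata overrides
makeLibrary <- function(seqs, ...) {
  ids <- names(seqs)
  stopifnot(!is.null(ids))
  n <- length(seqs)
  defaults <- list(order = NA_character_, superfamily = NA_character_,
                   family = NA_character_, subfamily = NA_character_,
                   genus = NA_character_, species = NA_character_,
                   bin_label = NA_character_, is_public = TRUE,
                   year_added = 2009L, country_of_origin = NA_character_,
                   country_of_interception = NA_character_,
                   capture_exception = FALSE)
  over <- list(...)
  meta <- data.frame(record_id = ids, stringsAsFactors = FALSE)
  for (col in names(defaults))
    meta[[col]] <- rep(defaults[[col]], length.out = n)
  for (col in names(over))
    meta[[col]] <- rep(over[[col]], length.out = n)
  meta$seq_length <- nchar(gsub("[-.]", "", seqs))
  new("ReferenceLibrary",
      sequences = Biostrings::DNAStringSet(seqs),
      meta = S4Vectors::DataFrame(meta, check.names = FALSE))
}

# build a QuerySet; seqs may cover a subset of the ids in `ids`
makeQueries <- function(ids, seqs = character(), ...) {
  n <- length(ids)
  defaults <- list(order = NA_character_, superfamily = NA_character_,
                   family = NA_character_, subfamily = NA_character_,
                   genus = NA_character_, species = NA_character_,
                   life_stage = "larva", country_of_origin = NA_character_,
                   country_of_interception = NA_character_)
  over <- list(...)
  meta <- data.frame(specimen_id = ids, stringsAsFactors = FALSE)
  for (col in names(defaults))
    meta[[col]] <- rep(defaults[[col]], length.out = n)
  for (col in names(over))
    meta[[col]] <- rep(over[[col]], length.out = n)
  new("QuerySet", sequences = Biostrings::DNAStringSet(seqs),
      meta = S4Vectors::DataFrame(meta, check.names = FALSE))
}

# random lineage drawn from a tiny fixed taxonomy, for property tests
randomLineage <- function() {
  fam <- sample(c("Tortricidae", "Gelechiidae"), 1)
  gen <- if (fam == "Tortricidae") sample(c("Archips", "Acleris"), 1) else
    "Sitotroga"
  spp <- paste(gen, sample(c("alpha", "beta"), 1))
  depth <- sample(0:5, 1)
  args <- list(order = "Lepidoptera",
               superfamily = if (fam == "Tortricidae") "Tortricoidea" else
                 "Gelechioidea",
               family = fam, subfamily = NA, genus = gen, species = spp)
  keepTo <- c("order", "superfamily", "family", "subfamily", "genus",
              "species")[seq_len(depth + 1)]
  args[setdiff(names(args), keepTo)] <- NA
  # drop some intermediates (never genus when species is kept)
  droppable <- intersect(keepTo, c("superfamily", "subfamily"))
  for (r in droppable) if (stats::runif(1) < 0.3) args[[r]] <- NA
  if (all(vapply(args, is.na, logical(1))))
    args$family <- fam
  do.call(taxonLineage, args)
}
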