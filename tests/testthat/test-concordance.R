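# A hand-built scenario exercising every classification branch. The base
# barcode evolves small variants so that supra-threshold (>98%) and
# sub-threshold (<98%) hits are constructed exactly.
fiveCategoryFixture <- function() {
  base <- randomSeq(658, 101)
  far <- randomSeq(658, 102)    # unrelated: never a hit
  lib <- makeLibrary(
    c(L1 = mutateAt(base, 1:5),          # 99.2%: species-level record
      L2 = randomSeq(658, 103),          # unrelated species record
      L3 = mutateAt(far, 1:5),           # 99.2% to q5's sequence
      L4 = mutateAt(base, seq(20, 640, length.out = 20))),  # ~97% to base
    family = c("Tortricidae", "Tineidae", "Blastobasidae", "Tortricidae"),
    genus = c("Archips", "Tinea", NA, "Archips"),
    species = c("Archips packardiana", "Tinea beta", NA,
                "Archips packardiana"),
    bin_label = c(NA, NA, "BOLD:AAA0001", NA),
    year_added = 2010L, is_public = TRUE)
  # L3 is interim-only (clear its names)
  m <- recordMeta(lib)
  m[m$record_id == "L3", c("family", "genus", "species")] <- NA
  lib@meta <- m

  qs <- makeQueries(
    c("q1", "q2", "q3sub", "q3bin", "q4", "q5", "qfail"),
    seqs = c(q1 = base,                       # hits L1 (deeper than morph)
             q2 = base,                       # hits L1 (same species)
             q3sub = mutateAt(base, seq(30, 650, length.out = 18)),
             q3bin = mutateAt(far, 1:3),      # hits interim-only L3
             q4 = randomSeq(658, 104),        # hits nothing
             q5 = base),                      # hits L1 but morph conflicts
    family = c("Tortricidae", "Tortricidae", "Tortricidae", "Gelechiidae",
               "Plutellidae", "Gelechiidae", "Tortricidae"),
    genus = c(NA, "Archips", "Archips", NA, NA, "Sitotroga", NA),
    species = c(NA, "Archips packardiana", "Archips packardiana", NA, NA,
                "Sitotroga cerealella", NA))
  list(lib = lib, qs = qs)
}

test_that("each classification branch fires on its engineered case", {
  fx <- fiveCategoryFixture()
  df <- classifyQueries(fx$qs, fx$lib, 2019, "SLBR")
  got <- setNames(df$category, df$specimen_id)
  expect_equal(got[["q1"]], "1_dna_lower")      # family morph, species hit
  expect_equal(got[["q2"]], "2_concordant")     # identical species
  expect_equal(got[["q3sub"]], "3_interim")     # <98% with same name
  expect_equal(got[["q3bin"]], "3_interim")     # BIN-only hit
  expect_equal(got[["q4"]], "4_no_match")
  expect_equal(got[["q5"]], "5_discordant")
  rat <- setNames(df$rationale, df$specimen_id)
  expect_equal(rat[["q3sub"]], "sub_threshold_same_name")
  expect_equal(rat[["q3bin"]], "bin_only")
  expect_equal(rat[["q5"]], "disjoint")
  # the sequencing failure is excluded from the classified set
  expect_false("qfail" %in% df$specimen_id)
  expect_equal(nrow(df), 6)
})

test_that("classify() on single specimens mirrors the table", {
  fx <- fiveCategoryFixture()
  lookup <- lineageLookup(fx$lib)
  mr <- topHit(fx$qs["q1"], fx$lib)
  res <- classify(lineageOf(fx$qs, "q1"), mr, fx$lib)
  expect_s4_class(res, "ConcordanceResult")
  expect_equal(res@category, "1_dna_lower")
  expect_equal(res@rationale, "hit_lower_consistent")
  expect_equal(res@bestRecordId, "L1")

  # no sequence: category 4 with its own rationale
  mrn <- topHit(fx$qs["qfail"], fx$lib)
  resn <- classify(lineageOf(fx$qs, "qfail"), mrn, lookup)
  expect_equal(resn@category, "4_no_match")
  expect_equal(resn@rationale, "no_sequence")
})

test_that("sister species and hit-higher cases classify as specified", {
  base <- randomSeq(658, 111)
  lib <- makeLibrary(
    c(S1 = mutateAt(base, 1:4), H1 = mutateAt(base, 5:8)),
    family = "Tortricidae", genus = "Archips",
    species = c("Archips alberta", NA))
  # morph species vs congeneric species record: category 3, sister
  qs <- makeQueries(c("qa", "qb"), seqs = c(qa = base, qb = base),
                    family = "Tortricidae", genus = "Archips",
                    species = c("Archips packardiana",
                                "Archips packardiana"))
  dfa <- classifyQueries(qs["qa"], lib["S1"], 2019, "SLBR")
  expect_equal(dfa$category, "3_interim")
  expect_equal(dfa$rationale, "sister_species")
  # morph species vs genus-only record: category 2, higher consistent
  dfb <- classifyQueries(qs["qb"], lib["H1"], 2019, "PRBD")
  expect_equal(dfb$category, "2_concordant")
  expect_equal(dfb$rationale, "hit_higher_consistent")
})

test_that("classification against an empty library is category 4", {
  qs <- makeQueries("q1", seqs = c(q1 = randomSeq(658, 121)),
                    family = "Tortricidae")
  empty <- makeLibrary(structure(character(), names = character()))
  df <- classifyQueries(qs, empty, 2019, "SLBR")
  expect_equal(df$category, "4_no_match")
  tab <- concordanceTable(qs, empty, 2019, "SLBR")
  expect_equal(tab$n[tab$category == "4_no_match"], 1L)
  expect_equal(sum(tab$n), 1L)
})

test_that("category counts partition the sequenced queries", {
  fx <- fiveCategoryFixture()
  tab <- concordanceTable(fx$qs, fx$lib, c(2009, 2019))
  for (y in unique(tab$year)) for (v in unique(tab$view)) {
    sub <- tab[tab$year == y & tab$view == v, ]
    expect_equal(sum(sub$n), sub$n_sequenced[1])
    expect_equal(sub$n_sequenced[1], 6L)
    expect_equal(sub$n_total[1], 7L)
  }
  # determinism: the same inputs classify identically on re-run
  df1 <- classifyQueries(fx$qs, fx$lib, 2019, "SLBR")
  df2 <- classifyQueries(fx$qs, fx$lib, 2019, "SLBR")
  expect_identical(df1, df2)
})

test_that("the no-match count never increases as the library grows", {
  set.seed(131)
  cfg <- simulationConfig(seed = 99, n_families = 4,
                          genera_per_family = 2, species_per_genus = 3,
                          years = 2009:2013,
                          records_per_year = c(5L, 8L, 10L, 12L, 15L),
                          public_fraction_by_year = rep(0.5, 5))
  sim <- runSimulation(cfg, nQueries = 40)
  st <- matchStats(sim$queries, sim$library)
  tab <- concordanceTable(sim$queries, sim$library, 2009:2013,
                          stats = st)
  for (v in c("SLBR", "PRBD")) {
    n4 <- tab$n[tab$category == "4_no_match" & tab$view == v]
    expect_true(all(diff(n4) <= 0))
  }
})

test_that("a concordant top hit with conflicting runners-up is annotated", {
  base <- randomSeq(658, 141)
  lib <- makeLibrary(
    c(good = mutateAt(base, 1:3), odd = mutateAt(base, 1:6)),
    family = c("Tortricidae", "Tineidae"),
    genus = c("Archips", "Tinea"),
    species = c("Archips packardiana", "Tinea beta"))
  qs <- makeQueries("q", seqs = c(q = base), family = "Tortricidae",
                    genus = "Archips", species = "Archips packardiana")
  df <- classifyQueries(qs, lib, 2019, "SLBR")
  expect_equal(df$category, "2_concordant")
  expect_equal(df$n_conflicting_hits, 1L)
})

test_that("species-level comparison counts morphology and DNA outcomes", {
  base1 <- randomSeq(658, 151)
  base2 <- randomSeq(658, 152)
  lib <- makeLibrary(
    c(r1 = mutateAt(base1, 1:4), r2 = mutateAt(base2, 1:4)),
    family = c("Tortricidae", "Tineidae"),
    genus = c("Archips", "Tinea"),
    species = c("Archips alpha", "Tinea beta"))
  # q1 verbatim concordant; q2 morph species-level but its sequence hits a
  # record named in a different family -> discordant
  qs <- makeQueries(c("q1", "q2", "q3"),
                    seqs = c(q1 = base1, q2 = base2, q3 = base1),
                    family = "Tortricidae", genus = "Archips",
                    species = c("Archips alpha", "Archips gamma", NA))
  res <- speciesLevelComparison(qs, lib, 2019, "SLBR")
  expect_equal(res$n_total_sequenced, 3L)
  expect_equal(res$n_morph_species, 2L)
  expect_equal(res$n_dna_species, 3L)
  expect_equal(res$n_both, 2L)
  expect_equal(res$n_both_concordant, 1L)
  expect_equal(res$n_both_discordant, 1L)
  expect_equal(res$pct_morph_species, pct(2, 3))

  # empty library: no DNA identifications at all
  empty <- makeLibrary(structure(character(), names = character()))
  res0 <- speciesLevelComparison(qs, empty, 2019, "SLBR")
  expect_equal(res0$n_dna_species, 0L)
  expect_equal(res0$n_both, 0L)
})
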