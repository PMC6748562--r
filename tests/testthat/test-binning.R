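test_that("identical sequences collapse into one cluster", {
  s <- randomSeq(658, 201)
  cl <- clusterSequences(c(a = s, b = s, c = s))
  expect_length(cl, 1)
  expect_equal(cl[[1]]@clusterId, "a")
  expect_equal(cl[[1]]@members, c("a", "b", "c"))
})

test_that("well-separated groups form separate clusters", {
  base1 <- randomSeq(658, 211)
  base2 <- mutateAt(base1, seq(5, 655, length.out = 66))  # ~10% apart
  seqs <- c(a1 = base1, a2 = mutateAt(base1, 10:12),
            b1 = base2, b2 = mutateAt(base2, 100:103))
  cl <- clusterSequences(seqs)
  expect_length(cl, 2)
  sizes <- sort(unname(vapply(cl, function(x) length(x@members),
                              integer(1))))
  expect_equal(sizes, c(2L, 2L))
})

test_that("single linkage chains through intermediate sequences", {
  # A-B 2.0%, B-C 2.0%, A-C 4.0%: one cluster at threshold 2.2%
  a <- randomSeq(650, 221)
  b <- mutateAt(a, seq(2, 638, length.out = 13))
  c <- mutateAt(b, seq(3, 639, length.out = 13))
  expect_equal(pDistance(a, b), 0.02)
  expect_equal(pDistance(b, c), 0.02)
  expect_equal(pDistance(a, c), 0.04)
  cl <- clusterSequences(c(A = a, B = b, C = c), threshold = 0.022)
  expect_length(cl, 1)
  expect_equal(cl[[1]]@members, c("A", "B", "C"))
  # at a threshold below the links, all singletons
  cl2 <- clusterSequences(c(A = a, B = b, C = c), threshold = 0.01)
  expect_length(cl2, 3)
})

test_that("clustering equals the brute-force connected-components oracle", {
  set.seed(231)
  # 50 sequences from a handful of diffuse centres
  centres <- replicate(6, randomSeq(600))
  seqs <- vapply(1:50, function(i) {
    mutateRandom(centres[[sample.int(6, 1)]], sample(0:25, 1))
  }, character(1))
  names(seqs) <- sprintf("s%02d", 1:50)
  for (thr in c(0.01, 0.022, 0.05)) {
    cl <- clusterSequences(seqs, threshold = thr)
    # oracle distances
    d <- outer(seq_along(seqs), seq_along(seqs),
               Vectorize(function(i, j) pDistance(seqs[i], seqs[j])))
    comp <- bfComponents(d, thr)
    oracle <- split(names(seqs), comp)
    oracleSet <- sort(vapply(oracle, function(m)
      paste(sort(m), collapse = ","), character(1)))
    mineSet <- sort(vapply(cl, function(x)
      paste(sort(x@members), collapse = ","), character(1)))
    expect_equal(unname(mineSet), unname(oracleSet),
                 info = sprintf("threshold %g", thr))
  }
})

test_that("clustering is order-invariant and nested across thresholds", {
  set.seed(241)
  base <- randomSeq(658)
  seqs <- structure(vapply(1:20, function(i)
    mutateRandom(base, sample(0:30, 1)), character(1)),
    names = sprintf("s%02d", 1:20))
  cl1 <- clusterSequences(seqs)
  cl2 <- clusterSequences(rev(seqs))
  key <- function(cl) sort(vapply(cl, function(x)
    paste(sort(x@members), collapse = ","), character(1)))
  expect_equal(unname(key(cl1)), unname(key(cl2)))

  # refinement: every cluster at t1 <= t2 sits inside one t2 cluster
  clA <- clusterSequences(seqs, threshold = 0.01)
  clB <- clusterSequences(seqs, threshold = 0.03)
  for (a in clA) {
    container <- vapply(clB, function(b) all(a@members %in% b@members),
                        logical(1))
    expect_equal(sum(container), 1L)
  }
})

test_that("pairs with insufficient overlap contribute no edge", {
  s <- randomSeq(658, 251)
  frag <- substr(s, 1, 120)  # overlaps everything by < 300 bp
  cl <- clusterSequences(c(full = s, tiny = frag), minOverlap = 300)
  expect_length(cl, 2)
})

test_that("cluster audits follow the per-rank naming rules", {
  lk <- function(id) switch(id,
    m1 = taxonLineage(family = "Blastobasidae", genus = "Calosima",
                      species = "Calosima albapenella"),
    m2 = taxonLineage(family = "Gelechiidae"),
    m3 = taxonLineage(family = "Oecophoridae"),
    p1 = taxonLineage(genus = "Archips", species = "Archips packardiana"),
    p2 = taxonLineage(genus = "Archips", species = "Archips alberta"),
    p3 = taxonLineage(genus = "Archips", species = "Archips tsuganus"),
    h1 = taxonLineage(family = "Tortricidae"),
    h2 = taxonLineage(family = "Tortricidae", genus = "Archips"),
    i1 = taxonLineage(interim = "BOLD:XYZ0001"),
    stop("unknown id ", id))

  # three families in one cluster: discordant
  fam <- auditCluster(new("MotuCluster", clusterId = "m1",
                          members = c("m1", "m2", "m3"),
                          status = NA_character_, namesPerRank = list()),
                      lk)
  expect_equal(fam@status, "discordant")
  expect_setequal(fam@namesPerRank$family,
                  c("Blastobasidae", "Gelechiidae", "Oecophoridae"))

  # three congeneric species: discordant at species, genus agrees
  trio <- auditCluster(new("MotuCluster", clusterId = "p1",
                           members = c("p1", "p2", "p3"),
                           status = NA_character_, namesPerRank = list()),
                       lk)
  expect_equal(trio@status, "discordant")
  expect_equal(trio@namesPerRank$genus, "Archips")
  expect_length(trio@namesPerRank$species, 3)

  # higher-level name consistent with a lower-level one: concordant
  cons <- auditCluster(new("MotuCluster", clusterId = "h1",
                           members = c("h1", "h2"),
                           status = NA_character_, namesPerRank = list()),
                       lk)
  expect_equal(cons@status, "concordant")

  # interim-only members impose no constraint
  mix <- auditCluster(new("MotuCluster", clusterId = "h1",
                          members = c("h1", "i1"),
                          status = NA_character_, namesPerRank = list()),
                      lk)
  expect_equal(mix@status, "concordant")

  # singletons stay singletons and are excluded from the denominator
  single <- auditCluster(new("MotuCluster", clusterId = "m1",
                             members = "m1", status = NA_character_,
                             namesPerRank = list()), lk)
  expect_equal(single@status, "singleton")
})

test_that("bin size summaries count singletons and small clusters", {
  mk <- function(id, n, status) new("MotuCluster", clusterId = id,
                                    members = paste0(id, seq_len(n)),
                                    status = status, namesPerRank = list())
  # 92 clusters, 37 singletons (the audited study's shape)
  clusters <- c(lapply(1:37, function(i) mk(sprintf("s%02d", i), 1,
                                            "singleton")),
                lapply(1:47, function(i) mk(sprintf("c%02d", i), 2,
                                            "concordant")),
                lapply(1:8, function(i) mk(sprintf("d%02d", i), 3,
                                           "discordant")))
  s <- binSizeSummary(clusters)
  expect_equal(s$n_clusters, 92L)
  expect_equal(s$pct_singleton, 40.2)
  expect_equal(s$pct_multi, 59.8)
  expect_equal(s$n_multi, 55L)
  expect_equal(s$pct_concordant, 85.5)
  expect_equal(s$pct_discordant, 14.5)
  expect_equal(s$n_concordant + s$n_discordant, s$n_multi)

  # boundary of the <=10 rule
  two <- list(mk("a", 11, "concordant"), mk("b", 10, "concordant"))
  expect_equal(binSizeSummary(two)$n_le_10_members, 1L)
  # all singletons: no multi-member clusters
  alls <- lapply(1:5, function(i) mk(paste0("x", i), 1, "singleton"))
  expect_equal(binSizeSummary(alls)$n_multi, 0L)
  expect_true(is.na(binSizeSummary(alls)$pct_concordant))
})

test_that("membership tables and audit reports are written", {
  dir <- withr::local_tempdir()
  s <- randomSeq(658, 261)
  seqs <- c(a = s, b = mutateAt(s, 1:3), c = randomSeq(658, 262))
  lk <- function(id) switch(id,
    a = taxonLineage(family = "Tortricidae"),
    b = taxonLineage(family = "Tineidae"),
    c = taxonLineage(family = "Plutellidae"))
  clusters <- auditClusters(clusterSequences(seqs), lk)
  tsv <- file.path(dir, "motu.tsv")
  js <- file.path(dir, "audit.json")
  writeMotuTable(clusters, tsv)
  writeMotuAudit(clusters, js)
  tab <- utils::read.delim(tsv)
  expect_equal(sort(tab$record_id), c("a", "b", "c"))
  rep <- jsonlite::read_json(js)
  expect_equal(rep$summary$n_clusters, 2L)
  expect_equal(length(rep$discordant), 1L)
  expect_equal(rep$discordant[[1]]$cluster_id, "a")
})
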