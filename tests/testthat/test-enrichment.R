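test_that("GMT reading loads, deduplicates and validates", {
  path <- withr::local_tempfile(fileext = ".gmt")
  writeLines(c("S1\tfirst set\tg1\tg1\tg2",
               "S2\tsecond set\tg3\tg4\tg5"), path)
  coll <- readGMT(path)
  expect_length(coll@sets, 2)
  expect_setequal(coll@sets$S1, c("g1", "g2"))   # within-set dedup
  expect_equal(unname(coll@descriptions["S2"]), "second set")

  writeLines("S1\tonly-two-fields", path)
  expect_error(readGMT(path), "line 1")
  writeLines(character(0), path)
  expect_warning(empty <- readGMT(path), "empty")
  expect_length(empty@sets, 0)
})

test_that("upper-tail probability matches enumeration and choose-sum oracles", {
  # all C(10,3) draws: 4 of them take all 3 from the 4 set members
  expect_equal(hypergeomUpperTail(10, 4, 3, 3), 4 / 120)
  expect_equal(hypergeomUpperTail(37, 12, 9, 0), 1)
  expect_equal(hypergeomUpperTail(8, 8, 5, 5), 1)
  for (N in c(6, 9, 12)) {
    for (K in c(0, 3, N)) {
      for (n in c(1, 4, N)) {
        if (n > N) next
        for (k in unique(c(0, 1, min(n, K)))) {
          expect_equal(hypergeomUpperTail(N, K, n, k),
                       enumUpperTail(N, K, n, k), tolerance = 1e-12)
          expect_equal(hypergeomUpperTail(N, K, n, k),
                       chooseTail(N, K, n, k), tolerance = 1e-12)
        }
      }
    }
  }
  expect_error(hypergeomUpperTail(10, 11, 3, 1), "K <= N")
})

test_that("weighted counts use round-half-up and clamp the overlap", {
  bg <- paste0("g", 1:20)
  w <- c(g1 = 0.6, g2 = 0.6)
  expect_equal(weightedCounts(w, c("g1", "g2"), bg),
               c(nW = 1L, kW = 1L))                  # floor(0.5 + 1.2)
  w1 <- setNames(rep(1, 5), paste0("g", 1:5))
  expect_equal(weightedCounts(w1, paste0("g", 3:8), bg),
               c(nW = 5L, kW = 3L))                  # reduces to raw counts
  expect_equal(weightedCounts(c(g1 = 0.49), "g1", bg),
               c(nW = 0L, kW = 0L))
  # exact .5 rounds up, never banker's
  expect_equal(weightedCounts(c(g1 = 0.5), "g1", bg), c(nW = 1L, kW = 1L))
  expect_equal(weightedCounts(c(g1 = 1.5, g2 = 1), "g1", bg)[["nW"]], 3L)
  expect_error(weightedCounts(c(zz = 1), "zz", bg), "outside background")
})

test_that("weighted ORA recovers a planted gene neighborhood set", {
  m <- generateGEM(nMetabolites = 30, nReactions = 40, nGenes = 12, seed = 11)
  ps <- plantSignature(m, "G0003", coverage = 1, noise = 1, seed = 2)
  res <- mapToGenes(resolveSignature(ps$signature, m), m)
  mg <- mappedGenes(res)
  planted <- mg$geneId[1:min(3, nrow(mg))]
  rand <- lapply(1:6, function(i) {
    set.seed(200 + i)
    sample(gemGeneIds(m), 4)
  })
  names(rand) <- sprintf("RAND%d", 1:6)
  sets <- c(list(PLANTED = planted), rand)
  coll <- new("GeneSetCollection", name = "toy",
              sets = sets, descriptions = setNames(rep("", 7), names(sets)))
  rep <- runORA(res, coll)
  rows <- oraRows(rep)
  expect_equal(rows$setName[1], "PLANTED")
  expect_equal(min(rows$p), rows$p[rows$setName == "PLANTED"])
})

test_that("with unit weights the weighted test reduces to classical ORA", {
  set.seed(7)
  bg <- paste0("g", 1:60)
  for (i in 1:20) {
    mapped <- sample(bg, sample(3:20, 1))
    members <- sample(bg, sample(3:30, 1))
    w <- setNames(rep(1, length(mapped)), mapped)
    wc <- weightedCounts(w, members, bg)
    k <- length(intersect(mapped, members))
    expect_identical(wc, c(nW = length(mapped), kW = k))
    p <- hypergeomUpperTail(60, length(members), wc["nW"], wc["kW"])
    expect_equal(unname(p), chooseTail(60, length(members),
                                       length(mapped), k),
                 tolerance = 1e-12)
    # same one-sided alternative as Fisher's exact test "greater"
    if (i <= 5) {
      tab <- matrix(c(k, length(mapped) - k,
                      length(members) - k,
                      60 - length(mapped) - length(members) + k), 2)
      expect_equal(unname(p),
                   fisher.test(tab, alternative = "greater")$p.value,
                   tolerance = 1e-10)
    }
  }
})

test_that("BH adjustment matches the step-up oracle and keeps monotonicity", {
  m <- generateGEM(nMetabolites = 25, nReactions = 35, nGenes = 15, seed = 3)
  ps <- plantSignature(m, "G0001", coverage = 1, noise = 2, seed = 4)
  res <- mapToGenes(resolveSignature(ps$signature, m), m)
  set.seed(31)
  sets <- lapply(1:12, function(i) sample(gemGeneIds(m), sample(3:8, 1)))
  names(sets) <- sprintf("SET%02d", 1:12)
  coll <- new("GeneSetCollection", name = "rand", sets = sets,
              descriptions = setNames(rep("", 12), names(sets)))
  rows <- oraRows(runORA(res, coll))
  expect_equal(rows$pAdj, bhOracle(rows$p))
  expect_true(all(diff(rows$pAdj) >= -1e-12))
})

test_that("down-weighting a gene never lowers the weighted overlap", {
  bg <- paste0("g", 1:30)
  set.seed(9)
  for (i in 1:20) {
    mapped <- sample(bg, 8)
    members <- sample(bg, 10)
    w <- setNames(runif(8, 0.2, 1), mapped)
    base <- weightedCounts(w, members, bg)
    gene <- sample(mapped, 1)
    w2 <- w; w2[gene] <- w2[gene] * runif(1)
    lower <- weightedCounts(w2, members, bg)
    expect_lte(lower[["kW"]], base[["kW"]])
    expect_lte(lower[["nW"]], base[["nW"]])
  }
})

test_that("degenerate rows are reported with p = 1, not dropped", {
  m <- toyModel()
  res <- mapToGenes(resolveSignature(MetaboliteSignature(c("D", "E")), m), m)
  coll <- new("GeneSetCollection", name = "deg",
              sets = list(EMPTYBG = c("nogene1", "nogene2"),
                          REAL = c("g1", "g3")),
              descriptions = c(EMPTYBG = "", REAL = ""))
  rows <- oraRows(runORA(res, coll))
  expect_equal(nrow(rows), 2)
  expect_equal(rows$p[rows$setName == "EMPTYBG"], 1)
  expect_equal(rows$K[rows$setName == "EMPTYBG"], 0L)
  # single-set collection: pAdj equals p
  one <- new("GeneSetCollection", name = "one",
             sets = list(REAL = c("g1", "g3")),
             descriptions = c(REAL = ""))
  r1 <- oraRows(runORA(res, one))
  expect_equal(r1$pAdj, r1$p)
})
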