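test_that("resolution collapses compartments and reports unresolved names", {
  m <- compartmentModel()
  sig <- MetaboliteSignature(c("ATP", "Nonexistent-X"), label = "demo")
  expect_warning(rsig <- resolveSignature(sig, m), "not found")
  expect_equal(rsig@S, 1L)
  expect_setequal(rsig@resolved[["ATP"]], c("atp_c", "atp_e"))
  expect_equal(rsig@unresolved, "Nonexistent-X")
})

test_that("name matching is case- and whitespace-insensitive", {
  m <- compartmentModel()
  sig <- MetaboliteSignature(c("  glucose ", "PYRUVATE"))
  rsig <- resolveSignature(sig, m)
  expect_equal(rsig@S, 2L)
  # synonym table redirects an otherwise unresolved name
  sig2 <- MetaboliteSignature("dextrose")
  rsig2 <- resolveSignature(sig2, m, synonyms = c(dextrose = "Glucose"))
  expect_equal(rsig2@S, 1L)
})

test_that("directional rule keeps products and reversible reactions only", {
  m <- toyModel()
  # A is only a reactant of irreversible r1
  rsA <- resolveSignature(MetaboliteSignature("A"), m)
  nd <- mapToGenes(rsA, m, rule = "non-directional")
  d <- mapToGenes(rsA, m, rule = "directional")
  expect_equal(mappedGenes(nd)$geneId, "g1")
  expect_equal(nrow(mappedGenes(d)), 0L)
  # C sits in reversible r2: mapped under the directional rule too
  rsC <- resolveSignature(MetaboliteSignature("C"), m)
  dC <- mapToGenes(rsC, m, rule = "directional")
  expect_true("g2" %in% mappedGenes(dC)$geneId)
})

test_that("fully unresolved signature yields an empty flagged mapping", {
  m <- toyModel()
  suppressWarnings(rsig <- resolveSignature(MetaboliteSignature("nope"), m))
  expect_warning(res <- mapToGenes(rsig, m), "empty mapping")
  expect_equal(nrow(mappedGenes(res)), 0L)
  expect_error(MetaboliteSignature(character(0)), "at least one")
})

test_that("mapped-gene records carry evidence, scores and deterministic ranks", {
  m <- toyModel()
  rsig <- resolveSignature(MetaboliteSignature(c("D", "E", "F")), m)
  res <- mapToGenes(rsig, m)
  mg <- mappedGenes(res)
  # g3 catalyzes only r3 = {D, E, F}: perfect overlap, most specific
  expect_equal(mg$geneId[1], "g3")
  expect_equal(mg$Ai[mg$geneId == "g3"], 3L)
  expect_equal(mg$ai[mg$geneId == "g3"], 3L)
  expect_equal(mg$metabolites[mg$geneId == "g3"], "D;E;F")
  expect_equal(mg$rank, seq_len(nrow(mg)))
  expect_true(all(diff(mg$si) >= 0))
  expect_equal(mg$si[1], specificityScore(6, 3, 3, 3))
  # weights consistent with scores
  expect_equal(mg$wi, sigmoidWeight(mg$si))
})

test_that("batch mapping returns one independent result per signature", {
  m <- toyModel()
  sigs <- list(MetaboliteSignature("A", label = "up", direction = "up"),
               MetaboliteSignature("F", label = "down", direction = "down"))
  out <- signatureToGenes(sigs, m)
  expect_named(out, c("up", "down"))
  expect_s4_class(out$up, "MappingResult")
  # a failing signature doesn't abort the batch
  sigs2 <- c(sigs, list(MetaboliteSignature("zzz", label = "bad")))
  suppressWarnings(out2 <- signatureToGenes(sigs2, m))
  expect_equal(nrow(mappedGenes(out2$bad)), 0L)
  expect_equal(mappedGenes(out2$up), mappedGenes(out$up))
})

test_that("directional mapping is contained in non-directional across random models", {
  set.seed(101)
  for (seed in 1:10) {
    m <- generateGEM(nMetabolites = 25, nReactions = 30, nGenes = 10,
                     seed = seed)
    nm <- gemMetabolites(m)$name
    sig <- MetaboliteSignature(sample(nm, 8), label = "rand")
    rsig <- resolveSignature(sig, m)
    gnd <- mappedGenes(mapToGenes(rsig, m, "non-directional"))$geneId
    gd <- mappedGenes(mapToGenes(rsig, m, "directional"))$geneId
    expect_true(all(gd %in% gnd))
  }
})

test_that("growing a signature never removes mapped genes", {
  set.seed(102)
  m <- generateGEM(nMetabolites = 25, nReactions = 30, nGenes = 10, seed = 42)
  nm <- sample(gemMetabolites(m)$name, 10)
  for (rule in c("non-directional", "directional")) {
    prev <- character(0)
    for (k in c(3, 6, 10)) {
      rsig <- resolveSignature(MetaboliteSignature(nm[1:k]), m)
      cur <- mappedGenes(mapToGenes(rsig, m, rule))$geneId
      expect_true(all(prev %in% cur))
      prev <- cur
    }
  }
})

test_that("mapped sets are independent of input metabolite order", {
  set.seed(103)
  m <- generateGEM(nMetabolites = 20, nReactions = 25, nGenes = 8, seed = 5)
  nm <- sample(gemMetabolites(m)$name, 7)
  r1 <- mapToGenes(resolveSignature(MetaboliteSignature(nm), m), m)
  r2 <- mapToGenes(resolveSignature(MetaboliteSignature(rev(nm)), m), m)
  expect_equal(mappedGenes(r1)[, c("geneId", "Ai", "ai", "si", "rank")],
               mappedGenes(r2)[, c("geneId", "Ai", "ai", "si", "rank")])
})

test_that("genes attached only to exchange reactions are never mapped", {
  # force a pathological model: gx catalyzes only a boundary exchange
  mets <- data.frame(id = c("A", "B"), name = c("A", "B"),
                     compartment = "c", boundary = c(FALSE, TRUE))
  rxns <- list(
    list(id = "r1", stoich = c(A = -1, B = 1), reversible = FALSE,
         genes = "g1"),
    list(id = "ex", stoich = c(B = -1), reversible = TRUE, genes = "gx"))
  m <- GEMModel(mets, rxns, c("g1", "gx"))
  expect_equal(gemReactions(m)$ex$kind, "exchange")
  rsig <- resolveSignature(MetaboliteSignature(c("A", "B")), m)
  for (rule in c("non-directional", "directional"))
    expect_false("gx" %in% mappedGenes(mapToGenes(rsig, m, rule))$geneId)
})

test_that("mapping TSV export round-trips the ranked table", {
  m <- toyModel()
  res <- mapToGenes(resolveSignature(MetaboliteSignature(c("C", "D")), m), m)
  path <- withr::local_tempfile(fileext = ".tsv")
  writeMappingTSV(res, path)
  tab <- read.delim(path)
  expect_equal(tab$gene_id, mappedGenes(res)$geneId)
  expect_equal(tab$rank, mappedGenes(res)$rank)
})
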