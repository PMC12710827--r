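test_that("hand-built toy model is indexed, classified and counted correctly", {
  m <- toyModel()
  st <- modelStats(m)
  expect_equal(unname(st), c(6L, 4L, 3L, 3L))
  expect_setequal(mappingEligible(m), c("r1", "r2", "r3"))

  rxns <- gemReactions(m)
  expect_equal(rxns$r4$kind, "exchange")   # single-sided
  expect_equal(rxns$r1$kind, "enzymatic")
  expect_equal(rxns$r2$kind, "enzymatic")

  # index consistency both ways
  for (r in rxns) {
    for (mid in names(r$stoich))
      expect_true(r$id %in% m@metIndex[[mid]])
    for (g in r$genes)
      expect_true(r$id %in% m@geneIndex[[g]])
  }
  expect_setequal(m@geneIndex$g1, c("r1", "r3"))
  expect_setequal(m@metIndex$C, c("r1", "r2"))
})

test_that("integrity violations are rejected naming the offending reaction", {
  mets <- data.frame(id = "A", name = "A", compartment = "c",
                     boundary = FALSE)
  expect_error(
    GEMModel(mets, list(list(id = "rbad", stoich = c(A = -1, ZZZ = 1),
                             reversible = FALSE, genes = character(0))),
             character(0)),
    "rbad.*ZZZ")
  expect_error(
    GEMModel(mets, list(list(id = "rg", stoich = c(A = -1),
                             reversible = FALSE, genes = "ghost")),
             character(0)),
    "rg.*ghost")
})

test_that("empty model yields all-zero stats", {
  m <- GEMModel(data.frame(id = character(0)), list(), character(0))
  expect_equal(unname(modelStats(m)), c(0L, 0L, 0L, 0L))
})

test_that("transport classification compares compartment-stripped names", {
  m <- compartmentModel()
  rxns <- gemReactions(m)
  expect_equal(rxns$t1$kind, "transport")
  expect_equal(rxns$ex1$kind, "exchange")
  expect_equal(rxns$r1$kind, "enzymatic")
  # gene-carrying transporter stays mapping-eligible
  expect_true("t1" %in% mappingEligible(m))
})

test_that("classification is invariant under reaction reordering and relabeling", {
  m <- toyModel()
  kinds <- vapply(gemReactions(m), `[[`, "", "kind")
  # rebuild with reactions reversed and metabolite ids renamed (names kept)
  ren <- setNames(paste0("m_", c("A", "B", "C", "D", "E", "F")),
                  c("A", "B", "C", "D", "E", "F"))
  mets <- gemMetabolites(m)
  mets$id <- unname(ren[mets$id])
  rxns <- rev(lapply(gemReactions(m), function(r) {
    names(r$stoich) <- unname(ren[names(r$stoich)])
    r[c("id", "stoich", "reversible", "genes")]
  }))
  m2 <- GEMModel(mets, rxns, gemGenes(m))
  kinds2 <- vapply(gemReactions(m2), `[[`, "", "kind")
  expect_equal(kinds2[names(kinds)], kinds)
})

test_that("toy-json round trip preserves stats and indexes", {
  m <- toyModel()
  path <- withr::local_tempfile(fileext = ".json")
  writeToyJSON(m, path)
  m2 <- loadGEM(path, format = "toy-json")
  expect_equal(modelStats(m2), modelStats(m))
  expect_equal(m2@metIndex, m@metIndex)
  expect_equal(m2@geneIndex, m@geneIndex)
  expect_equal(vapply(gemReactions(m2), `[[`, "", "kind"),
               vapply(gemReactions(m), `[[`, "", "kind"))
})

test_that("toy-tsv loader infers metabolites, genes and compartments", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("id\tstoich\treversible\tgenes",
               "r1\tglc[c]:-1;pyr[c]:1\tFALSE\tg1;g2",
               "t1\tglc[c]:-1;glc[e]:1\tFALSE\t",
               "r2\tpyr[c]:-1;acc[c]:1\tTRUE\tg2"), path)
  m <- loadGEM(path)
  expect_equal(unname(modelStats(m)), c(4L, 3L, 2L, 2L))
  met <- gemMetabolites(m)
  expect_equal(met$compartment[met$id == "glc[e]"], "e")
  # uncatalyzed transporter: classified transport, never mapping-eligible
  expect_equal(gemReactions(m)$t1$kind, "transport")
  expect_false("t1" %in% mappingEligible(m))
  expect_true(gemReactions(m)$r2$reversible)
  expect_error(loadGEM(path, format = "toy-json"), "parse")
})

test_that("SBML fbc loader flattens GPRs and derives reversibility from bounds", {
  path <- withr::local_tempfile(fileext = ".xml")
  writeTinySBML(path)
  m <- loadGEM(path)   # format guessed from extension
  expect_equal(unname(modelStats(m)), c(3L, 2L, 2L, 1L))
  # nested or/and GPR flattened to the full gene set
  expect_setequal(gemReactions(m)$R_r1$genes, c("G_e1", "G_e2"))
  expect_false(gemReactions(m)$R_r1$reversible)
  expect_true(gemReactions(m)$R_r2$reversible)
  # boundary species makes R_r2 an exchange despite two-sided stoichiometry
  expect_equal(gemReactions(m)$R_r2$kind, "exchange")
  expect_equal(gemMetabolites(m)$name[gemMetabolites(m)$id == "M_a"],
               "Alpha")
  expect_equal(gemGenes(m)$symbol[gemGenes(m)$id == "G_e1"], "ENZ1")
})
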