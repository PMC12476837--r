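# Ablation and cold-start protocol fidelity, end-to-end pipeline.

smallGen <- function() {
  cfg <- syntheticConfig(nProteins = 24, nTerms = 13, nModules = 2, seed = 7)
  generateProteome(cfg)
}
fastParams <- factorParams(maxIter = 300)

test_that("ablation modes force the fusion weight to its boundary", {
  ds <- smallGen()$dataset
  plan <- makeFolds(ds, "kfold", k = 3, seed = 2)
  # no_domain is exactly full with gamma = 1; no_sequence with gamma = 0
  a <- runProtocol(ds, plan, fastParams, mode = "no_domain")
  b <- runProtocol(ds, plan, fastParams, mode = "full", gamma = 1)
  expect_identical(a@fmax, b@fmax)
  expect_identical(a@auc, b@auc)
  expect_identical(a@perFold$aupr, b@perFold$aupr)

  a <- runProtocol(ds, plan, fastParams, mode = "no_sequence")
  b <- runProtocol(ds, plan, fastParams, mode = "full", gamma = 0)
  expect_identical(a@auc, b@auc)
  # and the forcing wins over an explicit conflicting gamma
  c2 <- runProtocol(ds, plan, fastParams, mode = "no_sequence", gamma = 0.9)
  expect_identical(a@auc, c2@auc)
})

test_that("cold-start edits touch only the fold's test proteins", {
  gen <- smallGen()
  ds <- gen$dataset
  test <- evaluableProteins(ds)[1:4]
  plan <- new("FoldPlan", folds = list(test), scheme = "kfold", seed = 1,
              identityThreshold = NA_real_)

  # manually empty the test proteins' domains and run the standard protocol:
  # must equal domain_coldstart on the untouched dataset
  dsEdit <- ds
  dsEdit@domains[test] <- replicate(length(test), character(0),
                                    simplify = FALSE)
  a <- runProtocol(ds, plan, fastParams, mode = "domain_coldstart")
  b <- runProtocol(dsEdit, plan, fastParams, mode = "full")
  expect_identical(a@auc, b@auc)
  expect_identical(a@fmax, b@fmax)

  dsEdit2 <- ds
  dsEdit2@sequences[test] <- NA_character_
  a2 <- runProtocol(ds, plan, fastParams, mode = "sequence_coldstart")
  b2 <- runProtocol(dsEdit2, plan, fastParams, mode = "full")
  expect_identical(a2@auc, b2@auc)
})

test_that("cold-start modes demand the modality they remove", {
  gen <- smallGen()
  ds <- gen$dataset
  ds@sequences[] <- NA_character_
  plan <- makeFolds(ds, "kfold", k = 3, seed = 2)
  expect_error(runProtocol(ds, plan, fastParams, mode = "sequence_coldstart"),
               "sequence_coldstart")
  ds2 <- gen$dataset
  ds2@domains <- replicate(length(ds2@domains), character(0),
                           simplify = FALSE)
  expect_error(runProtocol(ds2, plan, fastParams, mode = "domain_coldstart"),
               "domain_coldstart")
})

test_that("ablating graph learning falls back to neighbour voting", {
  ds <- smallGen()$dataset
  plan <- makeFolds(ds, "kfold", k = 3, seed = 2)
  rep1 <- runProtocol(ds, plan, fastParams, mode = "no_graph_learning")
  # recompute by hand from the scorer
  y <- as.matrix(buildEpg(ds))
  truth <- scores <- NULL
  for (f in foldSets(plan)) {
    s <- neighborVoteScores(ds, f)
    truth <- rbind(truth, y[f, , drop = FALSE])
    scores <- rbind(scores, s[f, , drop = FALSE])
  }
  expect_equal(rep1@auc, aucAupr(truth, scores)$auc)
  expect_equal(rep1@fmax, fmaxScore(truth, scores)$fmax)
})

test_that("per-fold metrics accompany the pooled report", {
  ds <- smallGen()$dataset
  plan <- makeFolds(ds, "kfold", k = 3, seed = 2)
  rep1 <- runProtocol(ds, plan, fastParams)
  expect_identical(nrow(rep1@perFold), 3L)
  expect_true(all(is.finite(rep1@perFold$fmax)))
  expect_identical(sum(rep1@perFold$nTest), rep1@nTestProteins)
  expect_true(rep1@fmax >= 0 && rep1@fmax <= 1)
})

test_that("end-to-end pipeline runs from fixture files and is reproducible", {
  cfg <- syntheticConfig(nProteins = 24, nTerms = 13, nModules = 2, seed = 7)
  ds <- generateProteome(cfg)$dataset
  dir <- file.path(tempdir(), "e2e")
  writeFixture(ds, dir)
  out1 <- file.path(tempdir(), "e2e_out1")
  out2 <- file.path(tempdir(), "e2e_out2")
  r1 <- runEndToEnd(fixtureDir = dir, termMin = 3, termMax = 200,
                    scheme = "kfold", k = 3, params = fastParams,
                    seed = 5, outDir = out1)
  r2 <- runEndToEnd(fixtureDir = dir, termMin = 3, termMax = 200,
                    scheme = "kfold", k = 3, params = fastParams,
                    seed = 5, outDir = out2)
  expect_true(r1$report@fmax >= 0 && r1$report@fmax <= 1)
  expect_identical(r1$report@auc, r2$report@auc)
  expect_true(file.exists(file.path(out1, "report.json")))
  expect_true(file.exists(file.path(out1, "dataset.json")))
  expect_identical(unname(tools::md5sum(file.path(out1, "report.json"))),
                   unname(tools::md5sum(file.path(out2, "report.json"))))
  # stage artifact reloads to the same dataset
  back <- loadDataset(file.path(out1, "dataset.json"))
  expect_identical(proteinIds(back), proteinIds(r1$dataset))

  # homology-aware scheme runs through the same entry point
  r3 <- runEndToEnd(fixtureDir = dir, termMin = 3, termMax = 200,
                    scheme = "homology_kfold", k = 3, params = fastParams,
                    seed = 5)
  expect_true(is.finite(r3$report@auc))
  expect_identical(r3$plan@scheme, "homology_kfold")
})
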