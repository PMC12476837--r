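# CAFA-style metrics, fold planners, homology clustering, neighbour vote.

test_that("Fmax: perfect, empty-prediction, and tie-break behaviour", {
  truth <- matrix(c(1, 0, 0, 1, 1, 0), 2, 3)
  got <- fmaxScore(truth, truth, thresholds = 0.5)
  expect_equal(got$fmax, 1)

  # all-zero scores with a high threshold: no predictions, harmonic mean 0
  got <- fmaxScore(truth, truth * 0, thresholds = 0.5)
  expect_equal(got$fmax, 0)

  # harmonic-mean consistency at the reported threshold
  set.seed(13)
  truth <- matrix(rbinom(24, 1, 0.4), 4, 6)
  truth[1, ] <- c(1, rep(0, 5))
  scores <- matrix(runif(24), 4, 6)
  got <- fmaxScore(truth, scores)
  expect_equal(got$fmax,
               2 * got$precision * got$recall /
                 (got$precision + got$recall))
  expect_error(fmaxScore(truth * 2, scores), "binary")
})

test_that("Fmax equals the brute-force threshold sweep on random instances", {
  set.seed(17)
  for (case in 1:100) {
    n <- sample(2:6, 1); m <- sample(2:8, 1)
    truth <- matrix(rbinom(n * m, 1, 0.35), n, m)
    if (all(truth == 0)) truth[sample(n, 1), sample(m, 1)] <- 1
    scores <- matrix(round(runif(n * m), 2), n, m)
    got <- fmaxScore(truth, scores)
    want <- fmaxOracle(truth, scores)
    expect_equal(got$fmax, want$fmax)
  }
})

test_that("AUC matches Mann-Whitney pair counting; AUPR sane", {
  # hand case: 3 positives, 3 negatives, one inversion -> 8/9
  truth <- c(1, 1, 1, 0, 0, 0)
  scores <- c(0.9, 0.8, 0.4, 0.5, 0.2, 0.1)
  got <- aucAupr(truth, scores)
  expect_equal(got$auc, 8 / 9)

  expect_equal(aucAupr(c(1, 0), c(0.9, 0.1))$auc, 1)
  expect_equal(aucAupr(c(1, 0, 1, 0), rep(0.5, 4))$auc, 0.5)
  expect_error(aucAupr(c(1, 1), c(0.4, 0.2)), "degenerate")
  expect_error(aucAupr(c(0, 0), c(0.4, 0.2)), "degenerate")

  set.seed(19)
  for (case in 1:100) {
    n <- sample(2:6, 1); m <- sample(2:8, 1)
    truth <- matrix(rbinom(n * m, 1, 0.4), n, m)
    if (all(truth == 0)) truth[1, 1] <- 1
    if (all(truth == 1)) truth[1, 1] <- 0
    scores <- matrix(round(runif(n * m), 1), n, m)   # ties likely
    got <- aucAupr(truth, scores)
    expect_lt(abs(got$auc - aucOracle(truth, scores)), 1e-12)
    expect_true(got$aupr >= 0 && got$aupr <= 1)
  }
})

test_that("metrics are invariant to a joint protein permutation", {
  set.seed(23)
  truth <- matrix(rbinom(40, 1, 0.3), 5, 8)
  truth[1, 1] <- 1; truth[2, 2] <- 0
  scores <- matrix(runif(40), 5, 8)
  perm <- sample(5)
  expect_equal(fmaxScore(truth, scores)$fmax,
               fmaxScore(truth[perm, ], scores[perm, ])$fmax)
  expect_equal(aucAupr(truth, scores)$auc,
               aucAupr(truth[perm, ], scores[perm, ])$auc)
})

test_that("fold plans partition the evaluable proteins", {
  cfg <- syntheticConfig(nProteins = 25, nTerms = 12, nModules = 2, seed = 3)
  ds <- generateProteome(cfg)$dataset
  ev <- evaluableProteins(ds)

  plan <- makeFolds(ds, "loocv")
  expect_length(foldSets(plan), length(ev))
  expect_true(all(lengths(foldSets(plan)) == 1L))
  expect_identical(sort(unlist(foldSets(plan))), ev)

  plan <- makeFolds(ds, "kfold", k = 10, seed = 7)
  expect_length(foldSets(plan), 10L)
  expect_identical(sort(unlist(foldSets(plan))), ev)
  sizes <- sort(lengths(foldSets(plan)), decreasing = TRUE)
  expect_lte(max(sizes) - min(sizes), 1L)      # balanced round-robin

  plan2 <- makeFolds(ds, "kfold", k = 10, seed = 7)
  expect_identical(foldSets(plan), foldSets(plan2))
  plan3 <- makeFolds(ds, "kfold", k = 10, seed = 8)
  expect_false(identical(foldSets(plan), foldSets(plan3)))

  expect_error(makeFolds(ds, "kfold", k = length(ev) + 1), "exceeds")
})

test_that("balanced kfold sizes on 25 proteins follow the 3/2 pattern", {
  cfg <- syntheticConfig(nProteins = 26, nTerms = 12, nModules = 2,
                         annotationFlipP = 0, seed = 3)
  ds <- generateProteome(cfg)$dataset
  ev <- evaluableProteins(ds)
  # with zero flip noise every protein is annotated
  expect_length(ev, 26)
  plan <- makeFolds(ds, "kfold", k = 10, seed = 1)
  # 26 = 6 folds of 3 + 4 folds of 2
  expect_identical(sort(lengths(foldSets(plan)), decreasing = TRUE),
                   c(rep(3L, 6), rep(2L, 4)))
})

test_that("homology folds keep linked clusters together", {
  dag <- new("GoDag", terms = "GO:0000001",
             edges = data.frame(child = character(0), parent = character(0),
                                relation = character(0)),
             namespace = "biological_process", names = "r")
  mk <- function(n) paste(rep("A", n), collapse = "")
  # A and C dissimilar; B bridges them (single-linkage chain)
  seqs <- c(PA = strrep("A", 40),
            PB = paste0(strrep("A", 20), strrep("C", 20)),
            PC = strrep("C", 40),
            PD = strrep("W", 40), PE = strrep("Y", 40),
            PF = strrep("G", 40), PG = strrep("H", 40))
  prot <- names(seqs)
  ppi <- data.frame(from = prot[1:6], to = prot[c(2:7)], nMethods = 3L)
  ann <- data.frame(protein = prot, term = "GO:0000001")
  ds <- assembleDataset(seqs, ppi, dag, ann, list())
  feats <- sapply(seqs, pseaacVector)
  cos <- function(a, b) sum(a * b) / sqrt(sum(a^2) * sum(b^2))
  cutoff <- 0.4
  # premise of the chain case
  expect_gte(cos(feats[, "PA"], feats[, "PB"]), cutoff)
  expect_gte(cos(feats[, "PB"], feats[, "PC"]), cutoff)
  expect_lt(cos(feats[, "PA"], feats[, "PC"]), cutoff)

  plan <- makeHomologyFolds(ds, k = 3, similarityCutoff = cutoff, seed = 1)
  foldOf <- function(p) which(sapply(foldSets(plan), function(f)
    match(p, proteinIds(ds)) %in% f))
  expect_identical(foldOf("PA"), foldOf("PB"))
  expect_identical(foldOf("PB"), foldOf("PC"))

  # post-hoc constraint: cross-fold pairs never exceed the cutoff
  idx <- foldSets(plan)
  for (a in seq_along(idx)) for (b in seq_along(idx)) {
    if (a >= b) next
    for (i in idx[[a]]) for (j in idx[[b]]) {
      si <- proteinSequences(ds)[i]; sj <- proteinSequences(ds)[j]
      expect_lte(cos(pseaacVector(si), pseaacVector(sj)), cutoff)
    }
  }
  expect_error(makeHomologyFolds(ds, k = 3, similarityCutoff = 2), "Cutoff|cutoff")
})

test_that("identical sequences always share a fold", {
  dag <- new("GoDag", terms = "GO:0000001",
             edges = data.frame(child = character(0), parent = character(0),
                                relation = character(0)),
             namespace = "biological_process", names = "r")
  seqs <- stats::setNames(
    c(rep(strrep("AC", 20), 2), strrep("W", 30), strrep("Y", 30),
      strrep("G", 30), strrep("H", 30)),
    sprintf("P%d", 1:6))
  prot <- names(seqs)
  ppi <- data.frame(from = prot[1:5], to = prot[2:6], nMethods = 3L)
  ann <- data.frame(protein = prot, term = "GO:0000001")
  ds <- assembleDataset(seqs, ppi, dag, ann, list())
  for (seed in 1:5) {
    plan <- makeHomologyFolds(ds, k = 3, similarityCutoff = 0.9, seed = seed)
    together <- sapply(foldSets(plan), function(f) all(c(1L, 2L) %in% f) ||
                         !any(c(1L, 2L) %in% f))
    expect_true(all(together))
  }
})

test_that("neighbour vote scores are neighbourhood annotation fractions", {
  ds <- tinyDataset()        # path P1-P2-P3-P4
  s <- neighborVoteScores(ds)
  rownames(s) <- proteinIds(ds); colnames(s) <- termIds(ds)
  # P2's neighbours are P1 and P3; both annotated with GO:0000003
  expect_equal(s["P2", "GO:0000003"], 1)
  # only P1 of the two carries GO:0000002
  expect_equal(s["P2", "GO:0000002"], 0.5)
  # P4's single neighbour P3 has GO:0000003 only
  expect_equal(s["P4", "GO:0000003"], 1)
  expect_equal(s["P4", "GO:0000002"], 0)
  # masking removes the held-out protein's votes
  s2 <- neighborVoteScores(ds, match("P3", proteinIds(ds)))
  expect_equal(s2["P2", "GO:0000003"], 0.5)
})
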