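# Masking, SVD initialization, objective, gradients, descent, prediction.

test_that("test-row masking zeroes exactly the requested rows", {
  y <- matrix(1, 4, 3)
  expect_identical(maskTestRows(y, integer(0)), y)
  expect_true(all(maskTestRows(y, 1:4) == 0))
  ym <- maskTestRows(y, 2)
  expect_true(all(ym[2, ] == 0))
  expect_identical(ym[-2, ], y[-2, ])
  expect_identical(y[2, 1], 1)                 # original untouched
  expect_error(maskTestRows(y, 9), "out of range")
})

test_that("SVD init reconstructs in literal mode and is deterministic", {
  u <- c(1, 2, 3); v <- c(2, 1)
  y <- u %*% t(v)                              # rank 1
  init <- svdInit(y, 1, scheme = "literal")
  rec <- init$u0 %*% diag(init$d, 1) %*% t(init$v0)
  expect_lt(max(abs(rec - y)), 1e-8)

  set.seed(2)
  y <- matrix(rbinom(30, 1, 0.4), 6, 5)
  init <- svdInit(y, 5, scheme = "literal")
  rec <- init$u0 %*% diag(init$d) %*% t(init$v0)
  expect_lt(max(abs(rec - y)), 1e-8)           # full rank reconstructs

  i1 <- svdInit(y, 3); i2 <- svdInit(y, 3)
  expect_identical(i1, i2)
  init <- svdInit(y, 3, scheme = "balanced")
  expect_true(all(init$u0 >= 0) && all(init$v0 >= 0))
  expect_error(svdInit(y, 9), "k must")
})

test_that("objective decomposes into its four non-negative components", {
  for (seed in 1:25) {
    inst <- randomFactorInstance(seed)
    lambda <- runif(1, 0, 0.2); mu <- runif(1, 0, 0.5)
    got <- factorObjective(inst$y, inst$u, inst$v, inst$lp, inst$lg,
                           lambda, mu)
    expect_lt(abs(got$total -
                    (got$recon + got$l2 + got$proteinGraph + got$termGraph)),
              1e-10)
    expect_true(all(c(got$recon, got$l2, got$proteinGraph,
                      got$termGraph) >= -1e-12))
    # independent term-by-term recomputation
    want <- objectiveOracle(inst$y, inst$u, inst$v, inst$lp, inst$lg,
                            lambda, mu)
    expect_lt(abs(got$total - want$total), 1e-12)
    expect_lt(abs(got$recon - want$recon), 1e-12)
    expect_lt(abs(got$proteinGraph - want$proteinGraph), 1e-12)
    expect_lt(abs(got$termGraph - want$termGraph), 1e-12)
  }
})

test_that("objective boundary cases", {
  inst <- randomFactorInstance(99)
  z <- inst$u * 0; zv <- inst$v * 0
  got <- factorObjective(inst$y, z, zv, inst$lp, inst$lg, 0.5, 0.5)
  expect_equal(got$total, sum(inst$y^2) / prod(dim(inst$y)))
  # exact factorization with no regularization scores zero
  y <- inst$u %*% t(inst$v)
  got <- factorObjective(y, inst$u, inst$v, inst$lp, inst$lg, 0, 0)
  expect_equal(got$total, 0)
  expect_error(factorObjective(inst$y, inst$u[-1, , drop = FALSE], inst$v,
                               inst$lp, inst$lg, 0, 0),
               "shapes")
})

test_that("analytic gradients match central finite differences", {
  for (seed in 1:15) {
    inst <- randomFactorInstance(seed)
    lambda <- runif(1, 0, 0.1); mu <- runif(1, 0, 0.3)
    g <- factorGradients(inst$y, inst$u, inst$v, inst$lp, inst$lg,
                         lambda, mu)
    num <- numericalGradients(inst$y, inst$u, inst$v, inst$lp, inst$lg,
                              lambda, mu)
    relU <- max(abs(g$du - num$du)) / max(1e-12, max(abs(num$du)))
    relV <- max(abs(g$dv - num$dv)) / max(1e-12, max(abs(num$dv)))
    expect_lt(relU, 1e-5)
    expect_lt(relV, 1e-5)
  }
})

test_that("gradients vanish at an exact unregularized factorization", {
  inst <- randomFactorInstance(4)
  y <- inst$u %*% t(inst$v)
  g <- factorGradients(y, inst$u, inst$v, inst$lp, inst$lg, 0, 0)
  expect_lt(max(abs(g$du)), 1e-12)
  expect_lt(max(abs(g$dv)), 1e-12)
})

makeGraph <- function(y, wp = NULL, wg = NULL) {
  n <- nrow(y); m <- ncol(y)
  if (is.null(wp)) wp <- matrix(0, n, n)
  if (is.null(wg)) wg <- matrix(0, m, m)
  new("HeterogeneousGraph",
      epp = Matrix::Matrix(wp, sparse = TRUE),
      epg = Matrix::Matrix(y, sparse = TRUE),
      egg = Matrix::Matrix(wg, sparse = TRUE),
      gamma = 0.5, wIsa = 0.4, wPartof = 0.3)
}

test_that("descent recovers a planted noiseless rank-2 factorization", {
  # two disjoint blocks: binary, exactly rank 2
  us <- cbind(rep(c(1, 0), c(4, 4)), rep(c(0, 1), c(4, 4)))
  vs <- cbind(rep(c(1, 0), c(3, 3)), rep(c(0, 1), c(3, 3)))
  y <- us %*% t(vs)                            # exact planted product
  g <- makeGraph(y)
  hp <- factorParams(k = 2, lambda = 0, mu = 0, eta = 1e-3,
                     maxIter = 5000, nonneg = TRUE)
  model <- fitFactorization(g, integer(0), hp)
  recon <- factorObjective(y, model@u, model@v,
                           matrix(0, 8, 8), matrix(0, 6, 6), 0, 0)$recon
  expect_lt(recon, 1e-3 * sum(y^2) / prod(dim(y)))
  # predictions approximate Y on training entries (entries lie in [0, 1])
  s <- predictScores(model)
  expect_lt(max(abs(s - y)), 0.05)

  # the literal variant starts from the unscaled singular vectors and must
  # still drive the reconstruction error down monotonically to tolerance
  hpL <- factorParams(k = 2, lambda = 0, mu = 0, eta = 1e-3,
                      maxIter = 20000, nonneg = FALSE)
  mL <- fitFactorization(g, integer(0), hpL)
  expect_true(mL@converged)
  expect_true(all(diff(mL@trace) <= 1e-9))
  expect_lt(utils::tail(mL@trace, 1), 0.05 * mL@trace[1])
})

test_that("termination contract: infinite tolerance stops after one update", {
  inst <- randomFactorInstance(21)
  g <- makeGraph(inst$y, inst$wp, inst$wg)
  model <- fitFactorization(g, integer(0), factorParams(k = 2, tol = Inf))
  expect_identical(model@iterations, 1L)
  expect_true(model@converged)
  expect_length(model@trace, 2)
})

test_that("fitting is deterministic", {
  inst <- randomFactorInstance(22)
  g <- makeGraph(inst$y, inst$wp, inst$wg)
  hp <- factorParams(k = 2, maxIter = 50)
  m1 <- fitFactorization(g, 1L, hp)
  m2 <- fitFactorization(g, 1L, hp)
  expect_identical(m1@trace, m2@trace)
  expect_identical(m1@u, m2@u)
  expect_identical(m1@v, m2@v)
})

test_that("a too-large step size raises the divergence error", {
  inst <- randomFactorInstance(23)
  g <- makeGraph(inst$y, inst$wp, inst$wg)
  expect_error(
    fitFactorization(g, integer(0),
                     factorParams(k = 2, eta = 50, maxIter = 500)),
    "learning rate")
})

test_that("objective trace is non-increasing at the reference step size", {
  for (seed in c(31, 32, 33)) {
    inst <- randomFactorInstance(seed)
    g <- makeGraph(inst$y, inst$wp, inst$wg)
    for (nn in c(TRUE, FALSE)) {
      model <- fitFactorization(
        g, integer(0),
        factorParams(k = 2, eta = 1e-3, maxIter = 400, nonneg = nn))
      expect_true(all(diff(model@trace) <= 1e-9))
    }
  }
})

test_that("non-negative mode keeps factors and raw scores non-negative", {
  inst <- randomFactorInstance(41)
  g <- makeGraph(inst$y, inst$wp, inst$wg)
  model <- fitFactorization(g, integer(0),
                            factorParams(k = 2, maxIter = 200, nonneg = TRUE))
  expect_true(all(model@u >= 0))
  expect_true(all(model@v >= 0))
  expect_true(all(predictScores(model, clip = FALSE) >= 0))
})

test_that("score clipping is idempotent and bounded", {
  inst <- randomFactorInstance(42)
  g <- makeGraph(inst$y, inst$wp, inst$wg)
  model <- fitFactorization(g, integer(0), factorParams(k = 2, maxIter = 100))
  s <- predictScores(model)
  expect_true(all(s >= 0 & s <= 1))
  expect_identical(pmin(pmax(s, 0), 1), s)
})

test_that("held-out predictions never see the held-out annotations", {
  set.seed(55)
  cfg <- syntheticConfig(nProteins = 24, nTerms = 12, nModules = 2, seed = 5)
  ds <- generateProteome(cfg)$dataset
  g <- buildHeterogeneousGraph(ds)
  hp <- factorParams(maxIter = 300)
  test <- c(2L, 7L)
  m1 <- fitFactorization(g, test, hp)
  # permute the held-out rows' annotations; prediction must not move
  y2 <- as.matrix(g@epg)
  for (i in test) y2[i, ] <- sample(y2[i, ])
  g2 <- new("HeterogeneousGraph", epp = g@epp,
            epg = Matrix::Matrix(y2, sparse = TRUE), egg = g@egg,
            gamma = g@gamma, wIsa = g@wIsa, wPartof = g@wPartof)
  m2 <- fitFactorization(g2, test, hp)
  expect_identical(predictScores(m1), predictScores(m2))
})

test_that("stronger graph regularization smooths protein embeddings", {
  cfg <- syntheticConfig(nProteins = 20, nTerms = 10, nModules = 2, seed = 9)
  ds <- generateProteome(cfg)$dataset
  g <- buildHeterogeneousGraph(ds)
  epp <- as.matrix(g@epp)
  smoothness <- sapply(c(0, 0.1, 1), function(mu) {
    m <- fitFactorization(g, integer(0),
                          factorParams(mu = mu, maxIter = 2000))
    u <- m@u
    tot <- 0
    for (i in seq_len(nrow(u))) for (j in seq_len(nrow(u)))
      tot <- tot + epp[i, j] * sum((u[i, ] - u[j, ])^2)
    tot
  })
  expect_true(all(diff(smoothness) <= 1e-9))
})

test_that("held-out entries of two planted communities are recovered", {
  cfg <- syntheticConfig(nModules = 2)
  ds <- generateProteome(cfg)$dataset
  g <- buildHeterogeneousGraph(ds)
  y <- as.matrix(g@epg)
  test <- seq(1, 60, by = 6)
  model <- fitFactorization(g, test, factorParams())
  s <- predictScores(model)
  expect_gt(aucAupr(y[test, ], s[test, ])$auc, 0.9)
})
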