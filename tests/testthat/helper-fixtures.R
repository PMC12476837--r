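# In-code fixture builders shared across test files. Everything is generated
# programmatically; no binary data on disk.

# a tiny hand-wired dataset: 4 proteins on a path PPI graph, 3-term DAG
tinyDataset <- function() {
  dag <- new("GoDag",
    terms = c("GO:0000001", "GO:0000002", "GO:0000003"),
    edges = data.frame(
      child = c("GO:0000002", "GO:0000003"),
      parent = c("GO:0000001", "GO:0000002"),
      relation = c("is_a", "part_of")),
    namespace = "biological_process", names = c("root", "mid", "leaf"))
  ppi <- data.frame(from = c("P1", "P2", "P3"),
                    to = c("P2", "P3", "P4"),
                    nMethods = c(3L, 3L, 4L))
  ann <- data.frame(protein = c("P1", "P1", "P2", "P2", "P3"),
                    term = c("GO:0000002", "GO:0000003",
                             "GO:0000001", "GO:0000002", "GO:0000003"),
                    evidence = "IDA")
  seqs <- c(P1 = "ACDEFGHIKL", P2 = "ACDEFGHIKV", P3 = "MKVLYPWTSG",
            P4 = "MKVLYPWTSA")
  doms <- list(P1 = c("PF00001", "PF00002"), P2 = c("PF00001"),
               P3 = c("PF00003"), P4 = c("PF00003", "PF00004"))
  assembleDataset(seqs, ppi, dag, ann, doms)
}

# random toy dataset for the brute-force domain-similarity oracle:
# <= 10 proteins, <= 6 domains, arbitrary PPI topology
randomToyDataset <- function(seed) {
  set.seed(seed)
  n <- sample(3:10, 1)
  prot <- sprintf("P%02d", seq_len(n))
  pairs <- t(combn(n, 2))
  keep <- runif(nrow(pairs)) < 0.45
  if (!any(keep)) keep[sample(nrow(pairs), 2)] <- TRUE
  ppi <- data.frame(from = prot[pairs[keep, 1]], to = prot[pairs[keep, 2]],
                    nMethods = 3L)
  inNet <- sort(unique(c(ppi$from, ppi$to)), method = "radix")
  nd <- sample(2:6, 1)
  domPool <- sprintf("PF%05d", seq_len(nd))
  doms <- lapply(prot, function(p)
    sort(sample(domPool, sample(0:min(3, nd), 1))))
  names(doms) <- prot
  dag <- new("GoDag", terms = "GO:0000001",
             edges = data.frame(child = character(0), parent = character(0),
                                relation = character(0)),
             namespace = "biological_process", names = "root")
  ann <- data.frame(protein = inNet[1], term = "GO:0000001",
                    evidence = "IDA")
  seqs <- stats::setNames(rep(NA_character_, n), prot)
  suppressWarnings(assembleDataset(seqs, ppi, dag, ann, doms))
}

# random factorization instance: Y, factors, and valid Laplacians built from
# random symmetric non-negative weight matrices
randomFactorInstance <- function(seed, nMax = 8, mMax = 8, kMax = 3) {
  set.seed(seed)
  n <- sample(2:nMax, 1); m <- sample(2:mMax, 1)
  k <- sample(1:min(kMax, n, m), 1)
  y <- matrix(rbinom(n * m, 1, 0.4), n, m)
  u <- matrix(runif(n * k), n, k)
  v <- matrix(runif(m * k), m, k)
  wp <- matrix(runif(n * n), n, n) * (matrix(runif(n * n), n, n) < 0.5)
  wp <- (wp + t(wp)) / 2; diag(wp) <- 0
  wg <- matrix(runif(m * m), m, m) * (matrix(runif(m * m), m, m) < 0.5)
  wg <- (wg + t(wg)) / 2; diag(wg) <- 0
  list(y = y, u = u, v = v, k = k,
       wp = wp, wg = wg,
       lp = diag(rowSums(wp)) - wp, lg = diag(rowSums(wg)) - wg)
}

# independent term-by-term objective recomputation (explicit loops)
objectiveOracle <- function(y, u, v, lp, lg, lambda, mu) {
  n <- nrow(y); m <- ncol(y)
  recon <- 0
  pred <- u %*% t(v)
  for (i in seq_len(n)) for (j in seq_len(m))
    recon <- recon + (y[i, j] - pred[i, j])^2
  recon <- recon / (n * m)
  l2 <- lambda * (sum(u * u) + sum(v * v))
  pg <- 0
  for (a in seq_len(ncol(u))) pg <- pg + drop(t(u[, a]) %*% lp %*% u[, a])
  pg <- mu * pg
  tg <- 0
  for (a in seq_len(ncol(v))) tg <- tg + drop(t(v[, a]) %*% lg %*% v[, a])
  tg <- mu * tg
  list(total = recon + l2 + pg + tg, recon = recon, l2 = l2,
       proteinGraph = pg, termGraph = tg)
}

# central finite differences of the total objective
numericalGradients <- function(y, u, v, lp, lg, lambda, mu, h = 1e-6) {
  f <- function(uu, vv)
    factorObjective(y, uu, vv, lp, lg, lambda, mu)$total
  du <- u * 0; dv <- v * 0
  for (i in seq_along(u)) {
    up <- u; up[i] <- up[i] + h
    um <- u; um[i] <- um[i] - h
    du[i] <- (f(up, v) - f(um, v)) / (2 * h)
  }
  for (i in seq_along(v)) {
    vp <- v; vp[i] <- vp[i] + h
    vm <- v; vm[i] <- vm[i] - h
    dv[i] <- (f(u, vp) - f(u, vm)) / (2 * h)
  }
  list(du = du, dv = dv)
}

# brute-force protein-centric Fmax: explicit per-protein loops over the
# distinct score values as thresholds
fmaxOracle <- function(truth, scores) {
  ts <- sort(unique(as.vector(scores)))
  best <- 0; bestT <- ts[1]
  for (t in ts) {
    precs <- c(); recs <- c()
    for (i in seq_len(nrow(truth))) {
      pred <- which(scores[i, ] >= t)
      tp <- length(intersect(pred, which(truth[i, ] == 1)))
      if (length(pred) > 0) precs <- c(precs, tp / length(pred))
      if (sum(truth[i, ]) > 0) recs <- c(recs, tp / sum(truth[i, ]))
    }
    pr <- if (length(precs)) mean(precs) else 0
    rc <- if (length(recs)) mean(recs) else 0
    f <- if (pr + rc > 0) 2 * pr * rc / (pr + rc) else 0
    if (f > best) { best <- f; bestT <- t }
  }
  list(fmax = best, threshold = bestT)
}

# Mann-Whitney pair-counting AUC oracle
aucOracle <- function(truth, scores) {
  y <- as.vector(truth); s <- as.vector(scores)
  pos <- s[y == 1]; neg <- s[y == 0]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + if (p > q) 1 else if (p == q) 0.5 else 0
  tot / (length(pos) * length(neg))
}
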