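## CAFA-style metrics, cross-validation planners, and the robustness
## protocols (ablations and cold-start).

#' Protein-centric Fmax
#'
#' For each threshold t, a term is predicted when its score is >= t.
#' Precision(t) is averaged over the test proteins with at least one
#' prediction at t; recall(t) over the test proteins with at least one true
#' term (the protein-centric convention of the CAFA challenges). Fmax is
#' the maximum over thresholds of the harmonic mean, with 0/0 defined as 0;
#' threshold ties break toward the smallest t.
#'
#' @param truth binary matrix, test proteins x terms.
#' @param scores real matrix of the same shape.
#' @param thresholds sorted thresholds; default = 0.01 steps over [0, 1]
#'   plus every distinct score value.
#' @return List with \code{fmax}, \code{threshold}, and the
#'   \code{precision} / \code{recall} pair attaining it.
#' @export
fmaxScore <- function(truth, scores, thresholds = NULL) {
  truth <- as.matrix(truth); scores <- as.matrix(scores)
  if (!all(truth %in% c(0, 1))) stop("truth must be binary")
  if (!identical(dim(truth), dim(scores))) stop("shape mismatch")
  if (is.null(thresholds))
    thresholds <- sort(unique(c(seq(0, 1, by = 0.01), as.vector(scores))))
  annotated <- rowSums(truth) > 0
  if (!any(annotated)) stop("no annotated test proteins")
  nAnn <- sum(annotated)
  f <- pr <- rc <- numeric(length(thresholds))
  for (s in seq_along(thresholds)) {
    pred <- scores >= thresholds[s]
    npred <- rowSums(pred)
    tp <- rowSums(pred & (truth == 1))
    covered <- npred > 0
    pr[s] <- if (any(covered)) mean(tp[covered] / npred[covered]) else 0
    rc[s] <- sum(tp[annotated] / rowSums(truth)[annotated]) / nAnn
    f[s] <- if (pr[s] + rc[s] > 0) 2 * pr[s] * rc[s] / (pr[s] + rc[s]) else 0
  }
  best <- which.max(f)     # first max = smallest threshold on ties
  list(fmax = f[best], threshold = thresholds[best],
       precision = pr[best], recall = rc[best])
}

#' Micro-averaged AUC and AUPR
#'
#' All masked (protein, term) pairs are flattened into one binary
#' classification problem. AUC is the trapezoidal area under the ROC curve
#' (tied scores form diagonal segments); AUPR is the step-wise area under
#' the precision-recall curve, \code{sum (R_i - R_{i-1}) P_i} over distinct
#' thresholds in decreasing score order.
#'
#' @param truth binary matrix or vector.
#' @param scores real matrix or vector of the same shape.
#' @return List with \code{auc} and \code{aupr}.
#' @export
aucAupr <- function(truth, scores) {
  y <- as.vector(as.matrix(truth)); s <- as.vector(as.matrix(scores))
  if (length(y) != length(s)) stop("shape mismatch")
  if (!all(y %in% c(0, 1))) stop("truth must be binary")
  P <- sum(y == 1); N <- sum(y == 0)
  if (P == 0L) stop("degenerate truth: no positive entries")
  if (N == 0L) stop("degenerate truth: no negative entries")
  o <- order(s, decreasing = TRUE)
  ys <- y[o]; ss <- s[o]
  last <- cumsum(rle(ss)$lengths)           # last index of each tie group
  tp <- cumsum(ys)[last]
  fp <- last - tp
  tpr <- c(0, tp / P); fpr <- c(0, fp / N)
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  prec <- tp / (tp + fp)
  rec <- tp / P
  aupr <- sum(diff(c(0, rec)) * prec)
  list(auc = auc, aupr = aupr)
}

#' Evaluable proteins of a dataset
#'
#' Proteins carrying at least one annotation in the chosen namespace; only
#' these enter cross-validation folds and metric denominators (unannotated
#' proteins can still be scored).
#'
#' @param dataset a \linkS4class{ProteomeDataset}.
#' @return Integer indices into \code{proteinIds(dataset)}.
#' @export
evaluableProteins <- function(dataset) {
  which(dataset@proteins %in% unique(dataset@annotations$protein))
}

#' Cross-validation fold plans
#'
#' \code{"loocv"} produces one singleton fold per evaluable protein (in
#' axis order); \code{"kfold"} shuffles the evaluable proteins with the
#' seed and deals them round-robin into k folds (sizes differ by at most
#' one).
#'
#' @param dataset a \linkS4class{ProteomeDataset}.
#' @param scheme \code{"loocv"} or \code{"kfold"}.
#' @param k number of folds (kfold only, >= 2).
#' @param seed partition seed.
#' @return A \linkS4class{FoldPlan}.
#' @export
makeFolds <- function(dataset, scheme = c("kfold", "loocv"), k = 10,
                      seed = 1) {
  scheme <- match.arg(scheme)
  ev <- evaluableProteins(dataset)
  if (scheme == "loocv") {
    folds <- lapply(ev, identity)
  } else {
    if (k < 2) stop("k must be >= 2 for kfold")
    if (k > length(ev))
      stop("k exceeds the number of evaluable proteins (", length(ev), ")")
    set.seed(seed)
    perm <- sample(ev)
    folds <- lapply(seq_len(k), function(i) {
      sort(perm[seq(i, length(perm), by = k)])
    })
  }
  new("FoldPlan", folds = folds, scheme = scheme, seed = seed,
      identityThreshold = NA_real_)
}

#' Homology-aware fold plan
#'
#' Clusters evaluable proteins by single-linkage on PseAAC cosine
#' similarity, linking any pair at or above \code{similarityCutoff}, so
#' that sequence-similar proteins (putative homologs) always share a fold.
#' Whole clusters are then assigned greedily, largest first, to the
#' currently smallest fold. Proteins without sequences form singleton
#' clusters. The identity notion here is the PseAAC cosine itself (the
#' clustering feature), with the cutoff as a free parameter defaulting to
#' 0.3.
#'
#' @param dataset a \linkS4class{ProteomeDataset}.
#' @param k number of folds.
#' @param similarityCutoff linking threshold in [0, 1].
#' @param seed used to break assignment ties reproducibly.
#' @param lag,weight PseAAC parameters.
#' @return A \linkS4class{FoldPlan} with scheme \code{"homology_kfold"}.
#' @export
makeHomologyFolds <- function(dataset, k = 10, similarityCutoff = 0.3,
                              seed = 1, lag = 20, weight = 0.05) {
  if (similarityCutoff < 0 || similarityCutoff > 1)
    stop("similarityCutoff must lie in [0, 1]")
  ev <- evaluableProteins(dataset)
  if (k < 2) stop("k must be >= 2")
  hasSeq <- !is.na(dataset@sequences[ev])
  clustered <- ev[hasSeq]
  member <- integer(length(ev))          # cluster id per evaluable protein
  nextId <- 0L
  if (length(clustered) >= 2L) {
    feats <- t(vapply(dataset@sequences[clustered],
                      function(s) pseaacVector(s, lag = lag, weight = weight),
                      numeric(20 + lag)))
    sim <- .cosineMatrix(feats)
    hc <- stats::hclust(stats::as.dist(1 - sim), method = "single")
    cl <- stats::cutree(hc, h = 1 - similarityCutoff)
    member[hasSeq] <- cl
    nextId <- max(cl)
  } else if (length(clustered) == 1L) {
    member[hasSeq] <- 1L
    nextId <- 1L
  }
  member[!hasSeq] <- nextId + seq_len(sum(!hasSeq))
  clusters <- split(ev, member)
  ## largest clusters first; ties broken by seeded shuffle for balance
  set.seed(seed)
  ord <- order(-lengths(clusters), sample(length(clusters)))
  folds <- vector("list", k)
  sizes <- integer(k)
  for (ci in ord) {
    tgt <- which.min(sizes)
    folds[[tgt]] <- c(folds[[tgt]], clusters[[ci]])
    sizes[tgt] <- sizes[tgt] + length(clusters[[ci]])
  }
  folds <- lapply(folds, sort)
  folds <- folds[lengths(folds) > 0L]
  new("FoldPlan", folds = folds, scheme = "homology_kfold", seed = seed,
      identityThreshold = similarityCutoff)
}

.cosineMatrix <- function(feats) {
  nrm <- sqrt(rowSums(feats^2))
  nrm[nrm == 0] <- 1
  x <- feats / nrm
  x %*% t(x)
}

#' Neighbour-vote baseline scorer
#'
#' The simple guilt-by-association scorer used when heterogeneous graph
#' learning is ablated: \code{score(i, t)} is the fraction of protein i's
#' direct PPI neighbours annotated with term t in the (test-masked)
#' annotation matrix. Isolated proteins score 0 everywhere.
#'
#' @param dataset a \linkS4class{ProteomeDataset}.
#' @param testProteins integer indices whose annotation rows are masked
#'   before voting.
#' @return n x m numeric score matrix.
#' @export
neighborVoteScores <- function(dataset, testProteins = integer(0)) {
  p <- dataset@proteins
  n <- length(p)
  y <- as.matrix(maskTestRows(buildEpg(dataset), testProteins))
  a <- matrix(0, n, n)
  ii <- match(dataset@ppi$from, p); jj <- match(dataset@ppi$to, p)
  for (r in seq_along(ii)) { a[ii[r], jj[r]] <- 1; a[jj[r], ii[r]] <- 1 }
  deg <- pmax(rowSums(a), 1)
  out <- (a %*% y) / deg
  dimnames(out) <- list(p, dataset@termIndex)
  out
}

#' Run an evaluation protocol over a fold plan
#'
#' For each fold, rebuilds the similarity layers according to \code{mode},
#' fits the factorization with the fold's proteins masked (or applies the
#' neighbour-vote scorer when graph learning is ablated), and scores the
#' masked rows. Metrics are computed on the pooled test entries and per
#' fold.
#'
#' Modes: \code{"full"} (namespace-default gamma), \code{"no_sequence"}
#' (gamma forced to 0, domain-only graph), \code{"no_domain"} (gamma forced
#' to 1, sequence-only graph), \code{"no_graph_learning"} (neighbour-vote
#' scorer instead of the factorization), \code{"domain_coldstart"} (test
#' proteins' domain sets emptied before the TF-IDF steps),
#' \code{"sequence_coldstart"} (test proteins' sequences removed before
#' featurization). Cold-start edits touch only the fold's test proteins;
#' training proteins keep their inputs.
#'
#' @param dataset a \linkS4class{ProteomeDataset}.
#' @param plan a \linkS4class{FoldPlan}.
#' @param params a \linkS4class{FactorizationParams}.
#' @param mode protocol mode (see Details).
#' @param gamma fusion weight; NULL = namespace default. Ablation modes
#'   override it.
#' @param beta,wIsa,wPartof,lag,weight graph construction parameters.
#' @param eggPolicy GO-layer policy.
#' @param thresholds Fmax threshold grid (NULL = default).
#' @return An \linkS4class{EvaluationReport}.
#' @export
runProtocol <- function(dataset, plan, params = factorParams(),
                        mode = c("full", "no_sequence", "no_domain",
                                 "no_graph_learning", "domain_coldstart",
                                 "sequence_coldstart"),
                        gamma = NULL, beta = 0.1, wIsa = 0.4, wPartof = 0.3,
                        lag = 20, weight = 0.05, eggPolicy = "direct",
                        thresholds = NULL) {
  mode <- match.arg(mode)
  if (is.null(gamma)) gamma <- defaultGamma(dataset@dag@namespace)
  if (mode == "no_sequence") gamma <- 0
  if (mode == "no_domain") gamma <- 1
  if (mode == "sequence_coldstart" && all(is.na(dataset@sequences)))
    stop("sequence_coldstart requires at least one sequence in the dataset")
  if (mode == "domain_coldstart" && all(lengths(dataset@domains) == 0L))
    stop("domain_coldstart requires at least one domain assignment")
  y <- as.matrix(buildEpg(dataset))
  egg <- buildEgg(dataset@dag, dataset@termIndex, wIsa = wIsa,
                  wPartof = wPartof, policy = eggPolicy)
  testIdx <- integer(0)
  truthRows <- scoreRows <- list()
  perFold <- data.frame(fold = integer(0), fmax = numeric(0),
                        auc = numeric(0), aupr = numeric(0),
                        nTest = integer(0))
  for (f in seq_along(plan@folds)) {
    test <- plan@folds[[f]]
    dsf <- dataset
    if (mode == "domain_coldstart")
      dsf@domains[test] <- replicate(length(test), character(0),
                                     simplify = FALSE)
    if (mode == "sequence_coldstart")
      dsf@sequences[test] <- NA_character_
    if (mode == "no_graph_learning") {
      scores <- neighborVoteScores(dsf, test)
    } else {
      seqS <- sequenceSimilarityEdges(dsf, lag = lag, weight = weight)
      domS <- domainSimilarityEdges(dsf, beta = beta)
      graph <- new("HeterogeneousGraph",
                   epp = buildEpp(seqS, domS, gamma),
                   epg = buildEpg(dsf), egg = egg,
                   gamma = gamma, wIsa = wIsa, wPartof = wPartof)
      model <- fitFactorization(graph, test, params)
      scores <- predictScores(model)
    }
    tr <- y[test, , drop = FALSE]
    sc <- scores[test, , drop = FALSE]
    testIdx <- c(testIdx, test)
    truthRows[[f]] <- tr
    scoreRows[[f]] <- sc
    fm <- tryCatch(fmaxScore(tr, sc, thresholds)$fmax,
                   error = function(e) NA_real_)
    au <- tryCatch(aucAupr(tr, sc), error = function(e)
      list(auc = NA_real_, aupr = NA_real_))
    perFold <- rbind(perFold, data.frame(
      fold = f, fmax = fm, auc = au$auc, aupr = au$aupr,
      nTest = length(test)))
  }
  truth <- do.call(rbind, truthRows)
  scores <- do.call(rbind, scoreRows)
  fm <- fmaxScore(truth, scores, thresholds)
  au <- aucAupr(truth, scores)
  new("EvaluationReport", fmax = fm$fmax,
      optimalThreshold = fm$threshold, auc = au$auc, aupr = au$aupr,
      perFold = perFold, nTestProteins = length(testIdx),
      nTerms = length(dataset@termIndex), mode = mode,
      scheme = plan@scheme)
}
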