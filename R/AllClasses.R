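#' @import methods
#' @import Matrix
NULL

## Fixed residue order used by every sequence feature in the package.
.AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

#' The 20-letter amino-acid alphabet
#'
#' Returns the fixed residue ordering used for amino-acid composition (AAC)
#' and PseAAC vectors throughout the package. Every 20-component feature
#' block is indexed in this order.
#'
#' @return Character vector of the 20 standard residues, in the order
#'   \code{ACDEFGHIKLMNPQRSTVWY}.
#' @export
#' @examples
#' aaAlphabet()
aaAlphabet <- function() .AA20

## locale-independent deterministic ordering for all id axes
.sortIds <- function(x) sort(unique(as.character(x)), method = "radix")

.NAMESPACE_MAP <- c(
  BP = "biological_process", MF = "molecular_function", CC = "cellular_component",
  biological_process = "biological_process",
  molecular_function = "molecular_function",
  cellular_component = "cellular_component"
)

.normalizeNamespace <- function(namespace) {
  ns <- .NAMESPACE_MAP[namespace]
  if (is.na(ns)) {
    stop("unknown GO namespace '", namespace,
         "'; use BP, MF, CC or the long OBO names")
  }
  unname(ns)
}

#' GoDag: a single-namespace Gene Ontology DAG
#'
#' Holds the terms of one GO namespace together with the directed
#' child-to-parent \code{is_a} and \code{part_of} links. Acyclicity is part of
#' the class validity.
#'
#' @slot terms character vector of GO term accessions.
#' @slot edges data.frame with columns \code{child}, \code{parent},
#'   \code{relation} (one of \code{"is_a"}, \code{"part_of"}); edges point
#'   child -> parent.
#' @slot namespace character, the single OBO namespace the DAG is restricted
#'   to (\code{"biological_process"}, \code{"molecular_function"} or
#'   \code{"cellular_component"}).
#' @slot names named character vector of human-readable term names (may be
#'   empty strings).
#' @exportClass GoDag
setClass("GoDag",
  slots = c(terms = "character", edges = "data.frame",
            namespace = "character", names = "character"))

setValidity("GoDag", function(object) {
  msg <- character(0)
  if (anyDuplicated(object@terms)) msg <- c(msg, "duplicated term ids")
  ed <- object@edges
  if (!all(c("child", "parent", "relation") %in% colnames(ed)))
    msg <- c(msg, "edges must have columns child, parent, relation")
  else {
    if (!all(ed$relation %in% c("is_a", "part_of")))
      msg <- c(msg, "edge relations must be is_a or part_of")
    if (!all(c(ed$child, ed$parent) %in% object@terms))
      msg <- c(msg, "edge endpoints must be listed terms")
    if (nrow(ed) > 0L) {
      g <- igraph::graph_from_data_frame(ed[, c("child", "parent")],
                                         directed = TRUE)
      if (!igraph::is_dag(g)) msg <- c(msg, "DAG contains a cycle")
    }
  }
  if (length(object@namespace) != 1L)
    msg <- c(msg, "namespace must be a single string")
  if (length(msg)) msg else TRUE
})

#' ProteomeDataset: aligned registry of proteins, annotations and ontology
#'
#' The central container tying together the protein universe (the PPI node
#' set), their sequences and domain assignments, the filtered annotation
#' table, and the GO DAG of one namespace. Protein and term axes are fixed,
#' lexicographically ordered, and used by every downstream matrix.
#'
#' @slot proteins character vector of protein ids, sorted (radix order),
#'   defining row index 1..n of all protein-axis matrices.
#' @slot sequences character vector aligned with \code{proteins};
#'   \code{NA} where no (usable) sequence is available.
#' @slot domains list of character vectors aligned with \code{proteins};
#'   \code{character(0)} where no domains are assigned.
#' @slot ppi data.frame with columns \code{from}, \code{to},
#'   \code{nMethods}; unordered edges stored with \code{from < to}.
#' @slot dag a \linkS4class{GoDag}.
#' @slot annotations data.frame with columns \code{protein}, \code{term},
#'   \code{evidence}.
#' @slot termIndex character vector of retained GO terms, sorted, defining
#'   column index 1..m.
#' @exportClass ProteomeDataset
setClass("ProteomeDataset",
  slots = c(proteins = "character", sequences = "character",
            domains = "list", ppi = "data.frame", dag = "GoDag",
            annotations = "data.frame", termIndex = "character"))

setValidity("ProteomeDataset", function(object) {
  msg <- character(0)
  p <- object@proteins
  if (length(p) < 1L) msg <- c(msg, "at least one protein required")
  if (anyDuplicated(p)) msg <- c(msg, "protein ids must be unique")
  if (!identical(p, sort(p, method = "radix")))
    msg <- c(msg, "proteins must be in radix-sorted order")
  if (length(object@sequences) != length(p))
    msg <- c(msg, "sequences must align with proteins")
  if (length(object@domains) != length(p))
    msg <- c(msg, "domains must align with proteins")
  ed <- object@ppi
  if (!all(c("from", "to", "nMethods") %in% colnames(ed)))
    msg <- c(msg, "ppi must have columns from, to, nMethods")
  else if (nrow(ed) > 0L) {
    if (any(ed$from >= ed$to)) msg <- c(msg, "ppi edges must satisfy from < to")
    if (!all(c(ed$from, ed$to) %in% p))
      msg <- c(msg, "ppi endpoints must be dataset proteins")
  }
  ti <- object@termIndex
  if (length(ti) < 1L) msg <- c(msg, "at least one GO term required")
  if (!identical(ti, sort(unique(ti), method = "radix")))
    msg <- c(msg, "termIndex must be sorted and unique")
  if (!all(ti %in% object@dag@terms))
    msg <- c(msg, "termIndex must be a subset of DAG terms")
  an <- object@annotations
  if (!all(c("protein", "term") %in% colnames(an)))
    msg <- c(msg, "annotations must have columns protein, term")
  else if (nrow(an) > 0L) {
    if (!all(an$protein %in% p))
      msg <- c(msg, "annotation proteins must be dataset proteins")
    if (!all(an$term %in% ti))
      msg <- c(msg, "annotation terms must be indexed terms")
    if (anyDuplicated(paste(an$protein, an$term)))
      msg <- c(msg, "duplicate annotation pairs")
  }
  if (length(msg)) msg else TRUE
})

#' HeterogeneousGraph: the three-layer protein / GO graph
#'
#' Weighted adjacency of the heterogeneous graph: the fused protein-protein
#' similarity layer \code{epp} (gamma-weighted combination of sequence and
#' domain similarity on PPI edges), the binary protein-term annotation layer
#' \code{epg} (the matrix Y that is factorized), and the GO-GO semantic layer
#' \code{egg} (weighted is_a / part_of links).
#'
#' @slot epp n x n symmetric non-negative sparse matrix, zero diagonal.
#' @slot epg n x m binary sparse matrix Y.
#' @slot egg m x m symmetric non-negative sparse matrix, zero diagonal.
#' @slot gamma numeric in [0,1], sequence-vs-domain fusion weight.
#' @slot wIsa numeric, semantic weight of a direct is_a link.
#' @slot wPartof numeric, semantic weight of a direct part_of link.
#' @exportClass HeterogeneousGraph
setClass("HeterogeneousGraph",
  slots = c(epp = "Matrix", epg = "Matrix", egg = "Matrix",
            gamma = "numeric", wIsa = "numeric", wPartof = "numeric"))

setValidity("HeterogeneousGraph", function(object) {
  msg <- character(0)
  epp <- object@epp; egg <- object@egg; epg <- object@epg
  if (nrow(epp) != ncol(epp)) msg <- c(msg, "epp must be square")
  if (nrow(egg) != ncol(egg)) msg <- c(msg, "egg must be square")
  if (nrow(epg) != nrow(epp) || ncol(epg) != nrow(egg))
    msg <- c(msg, "epg must be n x m with n = nrow(epp), m = nrow(egg)")
  if (!isSymmetric(as.matrix(epp), tol = 1e-12) && nrow(epp) > 1)
    msg <- c(msg, "epp must be symmetric")
  if (!isSymmetric(as.matrix(egg), tol = 1e-12) && nrow(egg) > 1)
    msg <- c(msg, "egg must be symmetric")
  if (any(Matrix::diag(epp) != 0)) msg <- c(msg, "epp must have zero diagonal")
  if (any(Matrix::diag(egg) != 0)) msg <- c(msg, "egg must have zero diagonal")
  if (min(epp) < 0 || min(egg) < 0) msg <- c(msg, "graph weights must be >= 0")
  v <- unique(as.vector(as.matrix(epg)))
  if (!all(v %in% c(0, 1))) msg <- c(msg, "epg entries must be 0/1")
  if (object@gamma < 0 || object@gamma > 1)
    msg <- c(msg, "gamma must lie in [0,1]")
  if (length(msg)) msg else TRUE
})

#' FactorizationParams: hyperparameters of the graph-regularized NMF
#'
#' @slot k latent rank (capped at min(n, m) at fit time).
#' @slot lambda L2 regularization coefficient.
#' @slot mu shared graph-regularization weight for the protein and term
#'   Laplacian terms.
#' @slot eta gradient-descent learning rate.
#' @slot tol convergence tolerance on the absolute change of the objective.
#' @slot maxIter iteration cap.
#' @slot nonneg logical; if FALSE (default) the optimization is plain
#'   unconstrained gradient descent from the raw truncated singular
#'   vectors, the algorithm as printed; if TRUE the factors start from the
#'   magnitude-balanced non-negative SVD transform and are projected to be
#'   non-negative after every step (strict NMF variant).
#' @slot seed integer seed for any stochastic fallback.
#' @exportClass FactorizationParams
setClass("FactorizationParams",
  slots = c(k = "numeric", lambda = "numeric", mu = "numeric",
            eta = "numeric", tol = "numeric", maxIter = "numeric",
            nonneg = "logical", seed = "numeric"),
  prototype = list(k = 50, lambda = 0.01, mu = 0.1, eta = 0.001,
                   tol = 1e-6, maxIter = 5000, nonneg = FALSE, seed = 1))

setValidity("FactorizationParams", function(object) {
  msg <- character(0)
  if (object@k < 1) msg <- c(msg, "k must be >= 1")
  if (object@eta <= 0) msg <- c(msg, "eta must be > 0")
  if (object@tol <= 0) msg <- c(msg, "tol must be > 0")
  if (object@mu < 0) msg <- c(msg, "mu must be >= 0")
  if (object@lambda < 0) msg <- c(msg, "lambda must be >= 0")
  if (object@maxIter < 1) msg <- c(msg, "maxIter must be >= 1")
  if (length(msg)) msg else TRUE
})

#' Construct factorization hyperparameters
#'
#' Defaults follow the model's stated operating point: graph weight
#' \code{mu = 0.1}, learning rate \code{eta = 0.001}, convergence tolerance
#' \code{tol = 1e-6}; the remaining values (\code{lambda = 0.01},
#' \code{k = 50} capped at \code{min(n, m)}, \code{maxIter = 5000}) are
#' package defaults, all overridable.
#'
#' @param k latent rank.
#' @param lambda L2 coefficient.
#' @param mu graph-regularization weight.
#' @param eta learning rate.
#' @param tol convergence tolerance.
#' @param maxIter iteration cap.
#' @param nonneg enforce non-negative factors (projected gradient);
#'   FALSE (default) runs the unconstrained printed algorithm.
#' @param seed integer seed.
#' @return A \linkS4class{FactorizationParams} object.
#' @export
#' @examples
#' factorParams(k = 10, mu = 0.1)
factorParams <- function(k = 50, lambda = 0.01, mu = 0.1, eta = 0.001,
                         tol = 1e-6, maxIter = 5000, nonneg = FALSE,
                         seed = 1) {
  new("FactorizationParams", k = k, lambda = lambda, mu = mu, eta = eta,
      tol = tol, maxIter = maxIter, nonneg = nonneg, seed = seed)
}

#' FactorizationModel: fitted latent factors and optimization trace
#'
#' @slot u n x k protein embedding matrix.
#' @slot v m x k term embedding matrix.
#' @slot trace numeric vector of objective values; element 1 is the value at
#'   initialization, element t+1 after update t.
#' @slot converged logical, TRUE if the tolerance rule triggered before the
#'   iteration cap.
#' @slot iterations number of gradient updates performed.
#' @slot params the \linkS4class{FactorizationParams} used.
#' @exportClass FactorizationModel
setClass("FactorizationModel",
  slots = c(u = "matrix", v = "matrix", trace = "numeric",
            converged = "logical", iterations = "numeric",
            params = "FactorizationParams"))

#' FoldPlan: train/test partitions for cross-validation
#'
#' @slot folds list of integer vectors of test-protein indices; pairwise
#'   disjoint, union = the evaluable protein set.
#' @slot scheme one of \code{"loocv"}, \code{"kfold"},
#'   \code{"homology_kfold"}.
#' @slot seed partition seed.
#' @slot identityThreshold similarity cutoff used for homology clustering
#'   (NA for the other schemes).
#' @exportClass FoldPlan
setClass("FoldPlan",
  slots = c(folds = "list", scheme = "character", seed = "numeric",
            identityThreshold = "numeric"))

setValidity("FoldPlan", function(object) {
  msg <- character(0)
  idx <- unlist(object@folds)
  if (anyDuplicated(idx)) msg <- c(msg, "folds must be pairwise disjoint")
  if (!object@scheme %in% c("loocv", "kfold", "homology_kfold"))
    msg <- c(msg, "unknown scheme")
  if (length(msg)) msg else TRUE
})

#' EvaluationReport: pooled and per-fold CAFA-style metrics
#'
#' @slot fmax protein-centric Fmax over the pooled test entries.
#' @slot optimalThreshold threshold attaining fmax (smallest on ties).
#' @slot auc micro-averaged ROC area over pooled masked entries.
#' @slot aupr micro-averaged step-wise precision-recall area.
#' @slot perFold data.frame with per-fold fmax/auc/aupr and test counts.
#' @slot nTestProteins,nTerms evaluation dimensions.
#' @slot mode,scheme protocol labels.
#' @exportClass EvaluationReport
setClass("EvaluationReport",
  slots = c(fmax = "numeric", optimalThreshold = "numeric", auc = "numeric",
            aupr = "numeric", perFold = "data.frame",
            nTestProteins = "numeric", nTerms = "numeric",
            mode = "character", scheme = "character"))
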