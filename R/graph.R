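## Assembly of the three-layer heterogeneous graph and its Laplacians.

#' Default sequence/domain fusion weight per GO namespace
#'
#' Per-category balance of sequence vs domain similarity: 0.5 for
#' biological process, 0.3 for molecular function (domain-driven
#' specificity), 0.6 for cellular component (sequence-borne localization
#' signals).
#'
#' @param namespace \code{"BP"}, \code{"MF"}, \code{"CC"} or long names.
#' @return Numeric gamma in [0, 1].
#' @export
#' @examples
#' defaultGamma("MF")
defaultGamma <- function(namespace) {
  ns <- .normalizeNamespace(namespace)
  c(biological_process = 0.5, molecular_function = 0.3,
    cellular_component = 0.6)[[ns]]
}

#' Fused protein-protein similarity layer
#'
#' Convex per-edge combination \code{gamma * seq + (1 - gamma) * domain} of
#' the two similarity maps, both defined on the same PPI edge set.
#' \code{gamma = 1} is the sequence-only (domain-ablated) graph,
#' \code{gamma = 0} the domain-only (sequence-ablated) graph.
#'
#' @param seqEdges,domEdges sparse symmetric similarity matrices from
#'   \code{\link{sequenceSimilarityEdges}} /
#'   \code{\link{domainSimilarityEdges}}.
#' @param gamma fusion weight in [0, 1].
#' @return Sparse symmetric n x n matrix.
#' @export
buildEpp <- function(seqEdges, domEdges, gamma) {
  if (gamma < 0 || gamma > 1) stop("gamma must lie in [0, 1]")
  if (!identical(dim(seqEdges), dim(domEdges)))
    stop("similarity maps must share dimensions")
  methods::as(gamma * seqEdges + (1 - gamma) * domEdges, "generalMatrix")
}

#' Binary protein-GO annotation matrix Y
#'
#' \code{Y[i, j] = 1} iff protein i is annotated with term j; rows of
#' unannotated proteins are all-zero (the missing entries the factorization
#' imputes).
#'
#' @param dataset a \linkS4class{ProteomeDataset}.
#' @return Sparse n x m 0/1 matrix with protein / term dimnames.
#' @export
buildEpg <- function(dataset) {
  i <- match(dataset@annotations$protein, dataset@proteins)
  j <- match(dataset@annotations$term, dataset@termIndex)
  Matrix::sparseMatrix(i = i, j = j, x = 1,
                       dims = c(length(dataset@proteins),
                                length(dataset@termIndex)),
                       dimnames = list(dataset@proteins,
                                       dataset@termIndex))
}

#' GO-GO semantic similarity layer
#'
#' Under the default \code{"direct"} policy only immediate parent-child
#' pairs carry weight: \code{wIsa} (default 0.4) for an is_a link,
#' \code{wPartof} (default 0.3) for a part_of link; restricting to direct
#' semantic neighbours avoids inflating similarity along long paths. The
#' alternative \code{"pathsum"} policy sums edge weights along the
#' undirected shortest path (fewest edges; ties broken toward the
#' lexicographically smallest node-id sequence) between every connected
#' term pair.
#'
#' @param dag a \linkS4class{GoDag}.
#' @param termIndex terms defining the matrix axes (all must exist in the
#'   DAG).
#' @param wIsa,wPartof edge weights for the two relations.
#' @param policy \code{"direct"} (default) or \code{"pathsum"}.
#' @return Sparse symmetric m x m matrix with zero diagonal.
#' @export
buildEgg <- function(dag, termIndex, wIsa = 0.4, wPartof = 0.3,
                     policy = c("direct", "pathsum")) {
  policy <- match.arg(policy)
  missing <- setdiff(termIndex, dag@terms)
  if (length(missing))
    stop("terms not in the DAG: ", paste(missing, collapse = ", "))
  m <- length(termIndex)
  ed <- dag@edges
  keep <- ed$child %in% termIndex & ed$parent %in% termIndex
  ed <- ed[keep, , drop = FALSE]
  w <- ifelse(ed$relation == "is_a", wIsa, wPartof)
  if (policy == "direct") {
    i <- match(ed$child, termIndex); j <- match(ed$parent, termIndex)
    return(.edgeWeightMatrix(i, j, w, termIndex))
  }
  ## pathsum: shortest undirected path between every connected pair,
  ## summing the relation weights along the chosen path
  if (nrow(ed) == 0L) return(.edgeWeightMatrix(integer(0), integer(0),
                                               numeric(0), termIndex))
  g <- igraph::graph_from_data_frame(
    data.frame(from = ed$child, to = ed$parent),
    directed = FALSE, vertices = termIndex)
  ew <- stats::setNames(w, paste(pmin(ed$child, ed$parent),
                                 pmax(ed$child, ed$parent)))
  ii <- integer(0); jj <- integer(0); ww <- numeric(0)
  for (a in seq_len(m - 1L)) {
    asp <- suppressWarnings(
      igraph::all_shortest_paths(g, from = termIndex[a],
                                 to = termIndex[(a + 1L):m]))
    paths <- if (!is.null(asp$vpaths)) asp$vpaths else asp$res
    if (!length(paths)) next
    ends <- vapply(paths, function(p) igraph::as_ids(p)[length(p)],
                   character(1))
    for (b in unique(ends)) {
      cand <- paths[ends == b]
      seqs <- lapply(cand, igraph::as_ids)
      pick <- seqs[[order(vapply(seqs, paste, character(1),
                                 collapse = "\r"),
                          method = "radix")[1]]]
      s <- 0
      for (t in seq_len(length(pick) - 1L)) {
        key <- paste(min(pick[t], pick[t + 1L]),
                     max(pick[t], pick[t + 1L]))
        s <- s + ew[[key]]
      }
      ii <- c(ii, a); jj <- c(jj, match(b, termIndex)); ww <- c(ww, s)
    }
  }
  .edgeWeightMatrix(ii, jj, ww, termIndex)
}

#' Graph Laplacians of the protein and term layers
#'
#' \code{L = D - W} with \code{D[i, i] = sum_j W[i, j]}; rows sum to zero
#' and both Laplacians are symmetric positive semidefinite, which is what
#' makes the embedding-smoothness penalties
#' \code{tr(U' L_P U)} and \code{tr(V' L_G V)} well defined.
#'
#' @param graph a \linkS4class{HeterogeneousGraph}.
#' @return List with sparse matrices \code{lp} (n x n) and \code{lg}
#'   (m x m).
#' @export
buildLaplacians <- function(graph) {
  list(lp = .laplacian(graph@epp), lg = .laplacian(graph@egg))
}

.laplacian <- function(w) {
  if (!isSymmetric(as.matrix(w), tol = 1e-12) && nrow(w) > 1)
    stop("Laplacian requires a symmetric weight matrix")
  Matrix::Diagonal(x = Matrix::rowSums(w)) - w
}

#' Assemble a HeterogeneousGraph
#'
#' Convenience constructor running the three layer builders with the
#' package defaults; \code{gamma = NULL} resolves the per-namespace
#' default via \code{\link{defaultGamma}}.
#'
#' @param dataset a \linkS4class{ProteomeDataset}.
#' @param gamma fusion weight (NULL = namespace default).
#' @param beta domain-similarity hybrid weight.
#' @param wIsa,wPartof GO edge weights.
#' @param lag,weight PseAAC parameters.
#' @param eggPolicy \code{"direct"} or \code{"pathsum"}.
#' @return A \linkS4class{HeterogeneousGraph}.
#' @export
buildHeterogeneousGraph <- function(dataset, gamma = NULL, beta = 0.1,
                                    wIsa = 0.4, wPartof = 0.3,
                                    lag = 20, weight = 0.05,
                                    eggPolicy = "direct") {
  if (is.null(gamma)) gamma <- defaultGamma(dataset@dag@namespace)
  seqS <- sequenceSimilarityEdges(dataset, lag = lag, weight = weight)
  domS <- domainSimilarityEdges(dataset, beta = beta)
  new("HeterogeneousGraph",
      epp = buildEpp(seqS, domS, gamma),
      epg = buildEpg(dataset),
      egg = buildEgg(dataset@dag, dataset@termIndex, wIsa = wIsa,
                     wPartof = wPartof, policy = eggPolicy),
      gamma = gamma, wIsa = wIsa, wPartof = wPartof)
}
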