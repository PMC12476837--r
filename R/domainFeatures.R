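## Hybrid TF-IDF domain-architecture similarity with PPI-neighbour
## augmentation. Term frequency is binary; document frequencies are counted
## over native domain sets only (the augmented view re-uses them so idf keeps
## a stable meaning across the two views).

#' Build the domain vocabulary of a dataset
#'
#' Orders all domain accessions observed in native domain sets and counts,
#' per domain, the number of proteins carrying it (document frequency).
#'
#' @param dataset a \linkS4class{ProteomeDataset}.
#' @return List with \code{domains} (sorted accessions),
#'   \code{documentFrequency} (named integer), and \code{total} (N, number
#'   of proteins in the dataset).
#' @export
buildDomainVocabulary <- function(dataset) {
  doms <- dataset@domains
  all <- .sortIds(unlist(doms))
  df <- stats::setNames(integer(length(all)), all)
  for (d in doms) df[unique(d)] <- df[unique(d)] + 1L
  list(domains = all, documentFrequency = df, total = length(doms))
}

#' TF-IDF weights of a domain set
#'
#' Binary term frequency times \code{log(N / (n_d + 1))} (natural log).
#' A domain present in (almost) every protein can make the idf negative;
#' such weights are clamped to 0 so profiles stay non-negative and the
#' cosine interpretation downstream holds. Domains absent from the
#' vocabulary weigh 0.
#'
#' @param domains character vector, the (native or augmented) domain set of
#'   one protein.
#' @param vocab vocabulary from \code{\link{buildDomainVocabulary}}.
#' @return Named numeric vector over \code{vocab$domains} (the shared
#'   vocabulary axis; absent domains are explicit zeros).
#' @export
#' @examples
#' vocab <- list(domains = "d1",
#'               documentFrequency = c(d1 = 4L), total = 10L)
#' tfidfWeights("d1", vocab)  # log(10/5) = log 2
tfidfWeights <- function(domains, vocab) {
  w <- stats::setNames(numeric(length(vocab$domains)), vocab$domains)
  hit <- intersect(unique(domains), vocab$domains)
  if (length(hit)) {
    idf <- log(vocab$total / (vocab$documentFrequency[hit] + 1))
    w[hit] <- pmax(idf, 0)
  }
  w
}

#' Neighbour-augmented domain sets
#'
#' For each protein, the union of its own domains with the domains of its
#' direct PPI neighbours. Isolated proteins keep their native set.
#'
#' @param dataset a \linkS4class{ProteomeDataset}.
#' @return List of character vectors aligned with \code{proteinIds}.
#' @export
augmentDomains <- function(dataset) {
  p <- dataset@proteins
  n <- length(p)
  adj <- vector("list", n)
  ii <- match(dataset@ppi$from, p); jj <- match(dataset@ppi$to, p)
  for (r in seq_along(ii)) {
    adj[[ii[r]]] <- c(adj[[ii[r]]], jj[r])
    adj[[jj[r]]] <- c(adj[[jj[r]]], ii[r])
  }
  lapply(seq_len(n), function(i) {
    .sortIds(c(dataset@domains[[i]],
               unlist(dataset@domains[adj[[i]]], use.names = FALSE)))
  })
}

#' Domain-architecture similarity on PPI edges
#'
#' The weighted hybrid of native and neighbour-augmented TF-IDF profiles:
#' \code{beta * cos(native_i, native_j) + (1 - beta) * cos(aug_i, aug_j)},
#' with cosines over the shared vocabulary axis. \code{beta = 0.1}
#' (default) prioritizes the augmented context. A protein with empty
#' support contributes cosine 0 for that term. Defined on PPI edges only.
#'
#' @param dataset a \linkS4class{ProteomeDataset}.
#' @param beta weight of the native-profile cosine, in [0, 1].
#' @return Sparse symmetric n x n matrix with zero diagonal.
#' @export
domainSimilarityEdges <- function(dataset, beta = 0.1) {
  if (beta < 0 || beta > 1) stop("beta must lie in [0, 1]")
  p <- dataset@proteins
  vocab <- buildDomainVocabulary(dataset)
  aug <- augmentDomains(dataset)
  wNat <- lapply(dataset@domains, tfidfWeights, vocab = vocab)
  wAug <- lapply(aug, tfidfWeights, vocab = vocab)
  ed <- dataset@ppi
  ii <- match(ed$from, p); jj <- match(ed$to, p)
  w <- numeric(nrow(ed))
  for (r in seq_len(nrow(ed))) {
    w[r] <- beta * cosineSimilarity(wNat[[ii[r]]], wNat[[jj[r]]]) +
      (1 - beta) * cosineSimilarity(wAug[[ii[r]]], wAug[[jj[r]]])
  }
  .edgeWeightMatrix(ii, jj, w, p)
}
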