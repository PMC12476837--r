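## Alignment-free sequence features: amino-acid composition (AAC), its
## order-aware PseAAC extension, and cosine similarity weights restricted to
## PPI-linked pairs.

#' Amino-acid composition vector
#'
#' Component i is the frequency of the i-th residue of
#' \code{\link{aaAlphabet}} in the sequence; components are non-negative and
#' sum to 1 for any non-empty sequence.
#'
#' @param sequence non-empty sanitized residue string.
#' @return Named numeric vector of length 20.
#' @export
#' @examples
#' aacVector("ACDA")
aacVector <- function(sequence) {
  if (is.na(sequence) || !nzchar(sequence))
    stop("aacVector requires a non-empty sequence")
  chars <- strsplit(sequence, "")[[1]]
  bad <- setdiff(chars, .AA20)
  if (length(bad))
    stop("non-standard residues in sequence: ", paste(bad, collapse = ""),
         " (sanitize first)")
  tab <- table(factor(chars, levels = .AA20))
  stats::setNames(as.numeric(tab) / length(chars), .AA20)
}

#' Sequence autocorrelation at a given lag
#'
#' Over the positions i = 1 .. |s| - l, scores +1 when residues at i and
#' i + l match and -1 otherwise, averaged. Lags at or beyond the sequence
#' length are defined as 0 so that short sequences still featurize.
#'
#' @param sequence residue string.
#' @param l positive integer lag.
#' @return Numeric in [-1, 1].
#' @export
#' @examples
#' seqAutocorrelation("ACAC", 1)  # -1: every pair mismatches
#' seqAutocorrelation("ACAC", 2)  #  1: every pair matches
seqAutocorrelation <- function(sequence, l) {
  if (l < 1) stop("lag must be >= 1")
  n <- nchar(sequence)
  if (l >= n) return(0)
  chars <- strsplit(sequence, "")[[1]]
  same <- chars[seq_len(n - l)] == chars[seq_len(n - l) + l]
  sum(ifelse(same, 1, -1)) / (n - l)
}

#' Pseudo amino-acid composition (PseAAC) vector
#'
#' The 20 AAC components followed by \code{weight *
#' seqAutocorrelation(sequence, l)} for l = 1 .. \code{lag}. Defaults:
#' maximum lag 20 and weighting factor 0.05. Lags >= sequence length
#' contribute 0.
#'
#' @param sequence non-empty sanitized residue string.
#' @param lag maximum lag (>= 1).
#' @param weight weighting factor for the autocorrelation block.
#' @return Numeric vector of length 20 + lag.
#' @export
#' @examples
#' pseaacVector("ACAC", lag = 2)[21:22]  # c(-0.05, 0.05)
pseaacVector <- function(sequence, lag = 20, weight = 0.05) {
  if (lag < 1) stop("lag must be >= 1")
  aac <- aacVector(sequence)
  corr <- vapply(seq_len(lag),
                 function(l) seqAutocorrelation(sequence, l), numeric(1))
  c(aac, stats::setNames(weight * corr, paste0("lag", seq_len(lag))))
}

#' Cosine similarity of two vectors
#'
#' @param u,v numeric vectors of equal length.
#' @return \code{u . v / (|u| |v|)}; defined as 0 when either norm is 0.
#' @export
#' @examples
#' cosineSimilarity(c(1, 1, 0), c(1, 0, 0))  # 1/sqrt(2)
cosineSimilarity <- function(u, v) {
  if (length(u) != length(v)) stop("vectors must have equal length")
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0) return(0)
  sum(u * v) / (nu * nv)
}

#' Sequence-similarity weights on PPI edges
#'
#' Computes PseAAC (or plain AAC) vectors for every protein with a usable
#' sequence and assigns each PPI edge the cosine similarity of its endpoint
#' vectors. Similarity is defined only on PPI edges -- non-interacting
#' pairs carry no weight, which keeps noise from unrelated proteins out of
#' the graph. An edge with a missing sequence on either side gets weight 0
#' (the domain layer then carries that edge).
#'
#' @param dataset a \linkS4class{ProteomeDataset}.
#' @param lag,weight PseAAC parameters.
#' @param method \code{"pseaac"} (default) or \code{"aac"}.
#' @return Sparse symmetric n x n \code{dgCMatrix} with zero diagonal,
#'   dimnames = protein ids.
#' @export
sequenceSimilarityEdges <- function(dataset, lag = 20, weight = 0.05,
                                    method = c("pseaac", "aac")) {
  method <- match.arg(method)
  p <- dataset@proteins
  n <- length(p)
  hasSeq <- !is.na(dataset@sequences)
  feat <- vector("list", n)
  for (i in which(hasSeq)) {
    feat[[i]] <- if (method == "pseaac")
      pseaacVector(dataset@sequences[i], lag = lag, weight = weight)
    else aacVector(dataset@sequences[i])
  }
  ed <- dataset@ppi
  ii <- match(ed$from, p); jj <- match(ed$to, p)
  w <- numeric(nrow(ed))
  for (r in seq_len(nrow(ed))) {
    a <- feat[[ii[r]]]; b <- feat[[jj[r]]]
    w[r] <- if (is.null(a) || is.null(b)) 0 else cosineSimilarity(a, b)
  }
  .edgeWeightMatrix(ii, jj, w, p)
}

## build a symmetric sparse matrix from (i, j, weight) triplets; negative
## weights (possible only from the bounded PseAAC correlation tail) are kept
.edgeWeightMatrix <- function(i, j, w, ids) {
  n <- length(ids)
  keep <- w != 0
  m <- Matrix::sparseMatrix(i = c(i[keep], j[keep]),
                            j = c(j[keep], i[keep]),
                            x = c(w[keep], w[keep]),
                            dims = c(n, n), dimnames = list(ids, ids))
  methods::as(m, "generalMatrix")
}
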