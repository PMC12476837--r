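## The learning core: leakage-safe masking, truncated-SVD initialization,
## the four-term objective, its gradients, projected gradient descent, and
## score prediction.

#' Mask test-protein rows of the annotation matrix
#'
#' Returns a copy of Y with the listed rows zeroed, so the annotations of
#' held-out proteins never enter training (neither the SVD initialization
#' nor the reconstruction term).
#'
#' @param y n x m matrix (base or Matrix).
#' @param testProteins integer row indices to zero (may be empty).
#' @return Matrix of the same class with the rows zeroed.
#' @export
maskTestRows <- function(y, testProteins) {
  testProteins <- as.integer(testProteins)
  if (length(testProteins) &&
      (min(testProteins) < 1L || max(testProteins) > nrow(y)))
    stop("test-protein index out of range")
  out <- y
  if (length(testProteins)) out[testProteins, ] <- 0
  out
}

#' Truncated-SVD initialization of the latent factors
#'
#' Computes the rank-k truncated SVD of the masked annotation matrix with a
#' deterministic sign convention (the largest-magnitude entry of each left
#' singular vector is forced non-negative). Under the default
#' \code{"balanced"} scheme the square root of each singular value is
#' distributed into both factors and magnitudes are taken, so
#' \code{U0 V0'} approximates Y with non-negative starting factors. The
#' \code{"literal"} scheme returns the raw singular vector matrices
#' unmodified (unconstrained start).
#'
#' @param yMasked n x m matrix (test rows already zeroed).
#' @param k rank, 1 <= k <= min(n, m).
#' @param scheme \code{"balanced"} or \code{"literal"}.
#' @return List with \code{u0} (n x k), \code{v0} (m x k) and \code{d}
#'   (the k singular values).
#' @export
svdInit <- function(yMasked, k, scheme = c("balanced", "literal")) {
  scheme <- match.arg(scheme)
  y <- as.matrix(yMasked)
  if (k < 1 || k > min(dim(y)))
    stop("k must satisfy 1 <= k <= min(n, m)")
  sv <- svd(y, nu = k, nv = k)
  u <- sv$u; v <- sv$v
  for (j in seq_len(k)) {            # deterministic sign convention
    i <- which.max(abs(u[, j]))
    if (u[i, j] < 0) { u[, j] <- -u[, j]; v[, j] <- -v[, j] }
  }
  if (scheme == "balanced") {
    s <- sqrt(sv$d[seq_len(k)])
    u0 <- abs(sweep(u, 2, s, `*`))
    v0 <- abs(sweep(v, 2, s, `*`))
  } else {
    u0 <- u; v0 <- v
  }
  list(u0 = u0, v0 = v0, d = sv$d[seq_len(k)])
}

#' Objective of the dual-Laplacian regularized factorization
#'
#' Four components: scale-invariant reconstruction error
#' \code{|Y - UV'|_F^2 / (n m)}; L2 penalty
#' \code{lambda (|U|_F^2 + |V|_F^2)}; protein-graph smoothness
#' \code{mu tr(U' L_P U)}; term-graph smoothness \code{mu tr(V' L_G V)}.
#' The total is their sum; every component is non-negative.
#'
#' @param y n x m matrix.
#' @param u,v latent factors (n x k, m x k).
#' @param lp,lg graph Laplacians (n x n, m x m).
#' @param lambda,mu regularization weights.
#' @return List with \code{total}, \code{recon}, \code{l2},
#'   \code{proteinGraph}, \code{termGraph}.
#' @export
factorObjective <- function(y, u, v, lp, lg, lambda, mu) {
  .checkShapes(y, u, v, lp, lg)
  r <- y - u %*% t(v)
  recon <- sum(r^2) / (nrow(y) * ncol(y))
  l2 <- lambda * (sum(u^2) + sum(v^2))
  pg <- mu * sum(u * as.matrix(lp %*% u))
  tg <- mu * sum(v * as.matrix(lg %*% v))
  list(total = recon + l2 + pg + tg, recon = recon, l2 = l2,
       proteinGraph = pg, termGraph = tg)
}

#' Gradients of the factorization objective
#'
#' \code{dU = -(2/(n m)) (Y - UV')V + 2 lambda U + 2 mu L_P U} and
#' \code{dV = -(2/(n m)) (Y - UV')' U + 2 lambda V + 2 mu L_G V}; these are
#' the exact partial derivatives of \code{\link{factorObjective}} and are
#' validated against central finite differences in the test suite.
#'
#' @inheritParams factorObjective
#' @return List with matrices \code{du} (n x k) and \code{dv} (m x k).
#' @export
factorGradients <- function(y, u, v, lp, lg, lambda, mu) {
  .checkShapes(y, u, v, lp, lg)
  r <- as.matrix(y - u %*% t(v))
  scale <- 2 / (nrow(y) * ncol(y))
  du <- -scale * (r %*% v) + 2 * lambda * u + 2 * mu * as.matrix(lp %*% u)
  dv <- -scale * (t(r) %*% u) + 2 * lambda * v + 2 * mu * as.matrix(lg %*% v)
  list(du = du, dv = dv)
}

.checkShapes <- function(y, u, v, lp, lg) {
  if (nrow(u) != nrow(y) || nrow(v) != ncol(y) || ncol(u) != ncol(v))
    stop("factor shapes inconsistent with Y")
  if (nrow(lp) != nrow(y) || ncol(lp) != nrow(y))
    stop("protein Laplacian must be n x n")
  if (nrow(lg) != ncol(y) || ncol(lg) != ncol(y))
    stop("term Laplacian must be m x m")
}

#' Fit the graph-regularized factorization
#'
#' Masks the test rows of Y, initializes U and V from the truncated SVD of
#' the masked matrix, and runs (projected) gradient descent with learning
#' rate \code{eta}: \code{U <- U - eta dU}, \code{V <- V - eta dV}, with
#' clipping at zero after each step when \code{nonneg} is on. Iteration
#' stops when the absolute change of the objective falls below \code{tol}
#' or the cap is reached; ten consecutive objective increases abort with a
#' step-size error.
#'
#' @param graph a \linkS4class{HeterogeneousGraph}.
#' @param testProteins integer indices of held-out proteins (rows masked
#'   before any computation).
#' @param params a \linkS4class{FactorizationParams}.
#' @return A \linkS4class{FactorizationModel}.
#' @export
fitFactorization <- function(graph, testProteins = integer(0),
                             params = factorParams()) {
  validObject(params)
  y <- as.matrix(graph@epg)
  ym <- maskTestRows(y, testProteins)
  k <- min(params@k, dim(ym))
  init <- svdInit(ym, k,
                  scheme = if (params@nonneg) "balanced" else "literal")
  u <- init$u0; v <- init$v0
  lap <- buildLaplacians(graph)
  lp <- as.matrix(lap$lp); lg <- as.matrix(lap$lg)
  lambda <- params@lambda; mu <- params@mu; eta <- params@eta
  trace <- numeric(params@maxIter + 1L)
  trace[1] <- factorObjective(ym, u, v, lp, lg, lambda, mu)$total
  converged <- FALSE
  nInc <- 0L
  iter <- 0L
  for (t in seq_len(params@maxIter)) {
    g <- factorGradients(ym, u, v, lp, lg, lambda, mu)
    u <- u - eta * g$du
    v <- v - eta * g$dv
    if (params@nonneg) { u[u < 0] <- 0; v[v < 0] <- 0 }
    iter <- t
    trace[t + 1L] <- factorObjective(ym, u, v, lp, lg, lambda, mu)$total
    if (!is.finite(trace[t + 1L]))
      stop("objective diverged to a non-finite value; ",
           "reduce the learning rate eta")
    if (trace[t + 1L] > trace[t]) nInc <- nInc + 1L else nInc <- 0L
    if (nInc >= 10L)
      stop("objective increased for 10 consecutive iterations; ",
           "reduce the learning rate eta")
    if (abs(trace[t + 1L] - trace[t]) < params@tol) {
      converged <- TRUE
      break
    }
  }
  rownames(u) <- rownames(y); rownames(v) <- colnames(y)
  new("FactorizationModel", u = u, v = v,
      trace = trace[seq_len(iter + 1L)], converged = converged,
      iterations = iter, params = params)
}

#' Predicted annotation scores
#'
#' \code{U V'}; with \code{clip = TRUE} (default) scores are clipped to
#' [0, 1] so they behave as probabilistic annotations under threshold
#' sweeps. Rows of held-out proteins are genuine predictions since their Y
#' rows were masked during fitting.
#'
#' @param model a \linkS4class{FactorizationModel}.
#' @param clip clip scores to [0, 1].
#' @return n x m numeric score matrix.
#' @export
predictScores <- function(model, clip = TRUE) {
  s <- model@u %*% t(model@v)
  if (clip) s <- pmin(pmax(s, 0), 1)
  s
}
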