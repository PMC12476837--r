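#' Accessors for the package's S4 containers
#'
#' Small accessor generics so downstream code never touches slots directly:
#' \code{proteinIds}/\code{termIds} return the fixed axis orderings,
#' \code{proteinSequences}/\code{proteinDomains} the per-protein inputs,
#' \code{ppiEdges}/\code{annotationPairs}/\code{goDag} the relational parts,
#' \code{eppMatrix}/\code{epgMatrix}/\code{eggMatrix} the three graph layers,
#' \code{latentU}/\code{latentV}/\code{objectiveTrace} the fitted model, and
#' \code{foldSets} the test partitions of a plan.
#'
#' @param x a ProteomeDataset, HeterogeneousGraph, FactorizationModel or
#'   FoldPlan as appropriate.
#' @return The corresponding component (see the class documentation for
#'   types).
#' @name accessors
#' @examples
#' cfg <- syntheticConfig(nProteins = 12, nTerms = 8, nModules = 2, seed = 1)
#' ds <- generateProteome(cfg)$dataset
#' head(proteinIds(ds))
#' head(termIds(ds))
NULL

#' @rdname accessors
#' @export
setGeneric("proteinIds", function(x) standardGeneric("proteinIds"))
#' @rdname accessors
#' @export
setGeneric("termIds", function(x) standardGeneric("termIds"))
#' @rdname accessors
#' @export
setGeneric("proteinSequences", function(x) standardGeneric("proteinSequences"))
#' @rdname accessors
#' @export
setGeneric("proteinDomains", function(x) standardGeneric("proteinDomains"))
#' @rdname accessors
#' @export
setGeneric("ppiEdges", function(x) standardGeneric("ppiEdges"))
#' @rdname accessors
#' @export
setGeneric("annotationPairs", function(x) standardGeneric("annotationPairs"))
#' @rdname accessors
#' @export
setGeneric("goDag", function(x) standardGeneric("goDag"))
#' @rdname accessors
#' @export
setGeneric("datasetNamespace", function(x) standardGeneric("datasetNamespace"))
#' @rdname accessors
#' @export
setGeneric("eppMatrix", function(x) standardGeneric("eppMatrix"))
#' @rdname accessors
#' @export
setGeneric("epgMatrix", function(x) standardGeneric("epgMatrix"))
#' @rdname accessors
#' @export
setGeneric("eggMatrix", function(x) standardGeneric("eggMatrix"))
#' @rdname accessors
#' @export
setGeneric("latentU", function(x) standardGeneric("latentU"))
#' @rdname accessors
#' @export
setGeneric("latentV", function(x) standardGeneric("latentV"))
#' @rdname accessors
#' @export
setGeneric("objectiveTrace", function(x) standardGeneric("objectiveTrace"))
#' @rdname accessors
#' @export
setGeneric("foldSets", function(x) standardGeneric("foldSets"))

#' @rdname accessors
setMethod("proteinIds", "ProteomeDataset", function(x) x@proteins)
#' @rdname accessors
setMethod("termIds", "ProteomeDataset", function(x) x@termIndex)
#' @rdname accessors
setMethod("proteinSequences", "ProteomeDataset",
          function(x) stats::setNames(x@sequences, x@proteins))
#' @rdname accessors
setMethod("proteinDomains", "ProteomeDataset",
          function(x) stats::setNames(x@domains, x@proteins))
#' @rdname accessors
setMethod("ppiEdges", "ProteomeDataset", function(x) x@ppi)
#' @rdname accessors
setMethod("annotationPairs", "ProteomeDataset", function(x) x@annotations)
#' @rdname accessors
setMethod("goDag", "ProteomeDataset", function(x) x@dag)
#' @rdname accessors
setMethod("datasetNamespace", "ProteomeDataset",
          function(x) x@dag@namespace)
#' @rdname accessors
setMethod("eppMatrix", "HeterogeneousGraph", function(x) x@epp)
#' @rdname accessors
setMethod("epgMatrix", "HeterogeneousGraph", function(x) x@epg)
#' @rdname accessors
setMethod("eggMatrix", "HeterogeneousGraph", function(x) x@egg)
#' @rdname accessors
setMethod("latentU", "FactorizationModel", function(x) x@u)
#' @rdname accessors
setMethod("latentV", "FactorizationModel", function(x) x@v)
#' @rdname accessors
setMethod("objectiveTrace", "FactorizationModel", function(x) x@trace)
#' @rdname accessors
setMethod("foldSets", "FoldPlan", function(x) x@folds)

setMethod("show", "ProteomeDataset", function(object) {
  nseq <- sum(!is.na(object@sequences))
  ndom <- sum(lengths(object@domains) > 0L)
  cat("ProteomeDataset:", length(object@proteins), "proteins x",
      length(object@termIndex), "GO terms (",
      object@dag@namespace, ")\n", sep = " ")
  cat("  sequences:", nseq, " with domains:", ndom,
      " PPI edges:", nrow(object@ppi),
      " annotations:", nrow(object@annotations), "\n")
})

setMethod("show", "HeterogeneousGraph", function(object) {
  cat("HeterogeneousGraph: n =", nrow(object@epp), "proteins, m =",
      nrow(object@egg), "terms\n")
  cat("  epp nnz:", Matrix::nnzero(object@epp),
      " epg ones:", Matrix::nnzero(object@epg),
      " egg nnz:", Matrix::nnzero(object@egg),
      " gamma:", object@gamma, "\n")
})

setMethod("show", "FactorizationModel", function(object) {
  cat("FactorizationModel: U", paste(dim(object@u), collapse = " x "),
      ", V", paste(dim(object@v), collapse = " x "), "\n")
  cat("  iterations:", object@iterations,
      " converged:", object@converged,
      " final objective:", utils::tail(object@trace, 1), "\n")
})

setMethod("show", "FoldPlan", function(object) {
  cat("FoldPlan (", object@scheme, "): ", length(object@folds),
      " folds over ", length(unlist(object@folds)), " proteins\n", sep = "")
})

setMethod("show", "EvaluationReport", function(object) {
  cat("EvaluationReport [", object@scheme, "/", object@mode, "]\n", sep = "")
  cat(sprintf("  Fmax = %.4f (t* = %.3f)  AUC = %.4f  AUPR = %.4f\n",
              object@fmax, object@optimalThreshold, object@auc, object@aupr))
  cat("  test proteins:", object@nTestProteins,
      " terms:", object@nTerms, "\n")
})
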