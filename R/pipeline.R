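## End-to-end orchestration: files -> dataset -> graph -> folds -> fit ->
## report, with every stage artifact written and reloadable.

#' Run the full prediction pipeline end to end
#'
#' Reads the five inputs (either from \code{fixtureDir} using the standard
#' fixture filenames or from explicit paths), applies the experimental
#' filters (distinct-method PPI support, evidence codes, annotation-count
#' bounds), assembles the dataset, builds the heterogeneous graph per fold,
#' fits the factorization and evaluates under the requested protocol. When
#' \code{outDir} is given, the resolved configuration, the assembled
#' dataset and the report are written there as JSON for exact reruns.
#'
#' @param fixtureDir directory containing \code{sequences.fasta},
#'   \code{ontology.obo}, \code{annotations.gaf}, \code{ppi.tsv},
#'   \code{domains.tsv} (as emitted by \code{\link{writeFixture}}).
#' @param fasta,obo,gaf,ppi,domains explicit input paths (ignored when
#'   \code{fixtureDir} is set).
#' @param namespace GO namespace to analyse.
#' @param minMethods PPI distinct-method threshold.
#' @param evidenceCodes retained GAF evidence codes.
#' @param termMin,termMax annotation-count bounds for retained terms.
#' @param scheme \code{"kfold"}, \code{"loocv"} or
#'   \code{"homology_kfold"}.
#' @param k fold count.
#' @param mode protocol mode (see \code{\link{runProtocol}}).
#' @param gamma fusion weight (NULL = namespace default).
#' @param beta,wIsa,wPartof,lag,weight,eggPolicy graph parameters.
#' @param similarityCutoff homology-fold linking threshold.
#' @param params a \linkS4class{FactorizationParams}.
#' @param seed partition seed.
#' @param outDir optional artifact directory.
#' @return List with \code{dataset}, \code{plan} and \code{report}.
#' @export
runEndToEnd <- function(fixtureDir = NULL, fasta = NULL, obo = NULL,
                        gaf = NULL, ppi = NULL, domains = NULL,
                        namespace = "BP", minMethods = 3,
                        evidenceCodes = c("EXP", "IDA", "IMP", "IGI",
                                          "IEP", "TAS", "IC"),
                        termMin = 10, termMax = 200,
                        scheme = c("kfold", "loocv", "homology_kfold"),
                        k = 10, mode = "full", gamma = NULL, beta = 0.1,
                        wIsa = 0.4, wPartof = 0.3, lag = 20, weight = 0.05,
                        eggPolicy = "direct", similarityCutoff = 0.3,
                        params = factorParams(), seed = 1, outDir = NULL) {
  scheme <- match.arg(scheme)
  if (!is.null(fixtureDir)) {
    fasta <- file.path(fixtureDir, "sequences.fasta")
    obo <- file.path(fixtureDir, "ontology.obo")
    gaf <- file.path(fixtureDir, "annotations.gaf")
    ppi <- file.path(fixtureDir, "ppi.tsv")
    domains <- file.path(fixtureDir, "domains.tsv")
  }
  seqs <- readFasta(fasta)
  dag <- readObo(obo, namespace)
  ann <- readGaf(gaf, evidenceCodes)
  net <- readPpiTable(ppi, minMethods)
  dom <- readDomainTable(domains)
  ## count-filter terms on the evaluated universe: PPI proteins, DAG terms
  ann <- ann[ann$protein %in% unique(c(net$from, net$to)) &
               ann$term %in% dag@terms, , drop = FALSE]
  ann <- filterGoTerms(ann, termMin, termMax)
  dataset <- assembleDataset(seqs, net, dag, ann, dom)
  plan <- if (scheme == "homology_kfold")
    makeHomologyFolds(dataset, k = k, similarityCutoff = similarityCutoff,
                      seed = seed, lag = lag, weight = weight)
  else makeFolds(dataset, scheme, k = k, seed = seed)
  report <- runProtocol(dataset, plan, params = params, mode = mode,
                        gamma = gamma, beta = beta, wIsa = wIsa,
                        wPartof = wPartof, lag = lag, weight = weight,
                        eggPolicy = eggPolicy)
  if (!is.null(outDir)) {
    if (!dir.exists(outDir)) dir.create(outDir, recursive = TRUE)
    saveDataset(dataset, file.path(outDir, "dataset.json"))
    cfg <- list(namespace = namespace, minMethods = minMethods,
                evidenceCodes = evidenceCodes, termMin = termMin,
                termMax = termMax, scheme = scheme, k = k, mode = mode,
                gamma = if (is.null(gamma))
                  defaultGamma(namespace) else gamma,
                beta = beta, wIsa = wIsa, wPartof = wPartof, lag = lag,
                weight = weight, eggPolicy = eggPolicy, seed = seed,
                params = list(k = params@k, lambda = params@lambda,
                              mu = params@mu, eta = params@eta,
                              tol = params@tol, maxIter = params@maxIter,
                              nonneg = params@nonneg))
    jsonlite::write_json(cfg, file.path(outDir, "config.json"),
                         auto_unbox = TRUE, digits = NA)
    jsonlite::write_json(reportAsList(report),
                         file.path(outDir, "report.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  list(dataset = dataset, plan = plan, report = report)
}

#' Flatten an EvaluationReport to a plain list
#'
#' Convenience for JSON export of pooled and per-fold metrics.
#'
#' @param report an \linkS4class{EvaluationReport}.
#' @return Nested list mirroring the report slots.
#' @export
reportAsList <- function(report) {
  list(fmax = report@fmax, optimalThreshold = report@optimalThreshold,
       auc = report@auc, aupr = report@aupr,
       nTestProteins = report@nTestProteins, nTerms = report@nTerms,
       mode = report@mode, scheme = report@scheme,
       perFold = report@perFold)
}

#' Fmax of a label-permutation null
#'
#' Permutes the protein rows of the truth matrix relative to the scores
#' \code{nPerm} times and recomputes Fmax each time, giving the null
#' distribution against which an observed Fmax is judged.
#'
#' @param truth binary matrix.
#' @param scores score matrix.
#' @param nPerm number of permutations.
#' @param seed RNG seed.
#' @param thresholds forwarded to \code{\link{fmaxScore}}.
#' @return Numeric vector of \code{nPerm} null Fmax values.
#' @export
permutationNullFmax <- function(truth, scores, nPerm = 20, seed = 1,
                                thresholds = NULL) {
  truth <- as.matrix(truth)
  set.seed(seed)
  vapply(seq_len(nPerm), function(i) {
    fmaxScore(truth[sample(nrow(truth)), , drop = FALSE], scores,
              thresholds)$fmax
  }, numeric(1))
}
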