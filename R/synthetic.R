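## Synthetic proteome generator with planted functional modules. The
## generator emulates the structure the model exploits: proteins fall into
## functional modules that share a residue-usage bias (so PseAAC similarity
## carries module signal), a domain repertoire (so TF-IDF similarity does
## too), dense within-module PPI connectivity, and a coherent GO-term block
## with flip noise on the annotations.

#' SyntheticConfig: parameters of the planted-module generator
#'
#' @slot nProteins,nTerms,nDomains,nModules counts.
#' @slot seqLengthRange integer min/max sequence length.
#' @slot ppiWithinP,ppiBetweenP edge probabilities inside / between
#'   modules.
#' @slot annotationFlipP per-cell label flip probability.
#' @slot dagBranching probability that a term receives a second parent.
#' @slot seed master seed; a fixed seed makes every emitted artifact
#'   byte-identical.
#' @exportClass SyntheticConfig
setClass("SyntheticConfig",
  slots = c(nProteins = "numeric", nTerms = "numeric", nDomains = "numeric",
            nModules = "numeric", seqLengthRange = "numeric",
            ppiWithinP = "numeric", ppiBetweenP = "numeric",
            annotationFlipP = "numeric", dagBranching = "numeric",
            seed = "numeric"))

setValidity("SyntheticConfig", function(object) {
  msg <- character(0)
  probs <- c(object@ppiWithinP, object@ppiBetweenP, object@annotationFlipP)
  if (any(probs < 0 | probs > 1)) msg <- c(msg, "probabilities must be in [0,1]")
  if (object@nProteins < 1 || object@nTerms < 1 || object@nModules < 1 ||
      object@nDomains < 1) msg <- c(msg, "counts must be >= 1")
  if (length(object@seqLengthRange) != 2L ||
      object@seqLengthRange[1] > object@seqLengthRange[2])
    msg <- c(msg, "seqLengthRange must be c(min, max)")
  if (length(msg)) msg else TRUE
})

#' Build a synthetic-data configuration
#'
#' Defaults define the package's reference study condition: 60 proteins in
#' 4 modules, 30 GO terms, 20 domains, 5\% annotation flip noise, PPI edge
#' probability 0.5 within / 0.02 between modules, sequence lengths 80-150,
#' seed 1.
#'
#' @param nProteins,nTerms,nDomains,nModules counts.
#' @param seqLengthRange min/max sequence length.
#' @param ppiWithinP,ppiBetweenP PPI edge probabilities.
#' @param annotationFlipP label noise rate.
#' @param dagBranching probability of a second DAG parent.
#' @param seed master seed.
#' @return A \linkS4class{SyntheticConfig}.
#' @export
syntheticConfig <- function(nProteins = 60, nTerms = 30, nDomains = 20,
                            nModules = 4, seqLengthRange = c(80, 150),
                            ppiWithinP = 0.5, ppiBetweenP = 0.02,
                            annotationFlipP = 0.05, dagBranching = 0.3,
                            seed = 1) {
  new("SyntheticConfig", nProteins = nProteins, nTerms = nTerms,
      nDomains = nDomains, nModules = nModules,
      seqLengthRange = seqLengthRange, ppiWithinP = ppiWithinP,
      ppiBetweenP = ppiBetweenP, annotationFlipP = annotationFlipP,
      dagBranching = dagBranching, seed = seed)
}

.termId <- function(i) sprintf("GO:%07d", i)
.proteinId <- function(i) sprintf("P%04d", i)
.domainId <- function(i) sprintf("PF%05d", i)

## block id of non-root term i (i >= 2): the same round-robin split used by
## generateProteome, so each module's term block forms a DAG-coherent branch
.termBlock <- function(i, nModules) ((i - 2L) %% nModules) + 1L

#' Generate a synthetic GO DAG with module-coherent branches
#'
#' A rooted DAG over \code{nTerms}: term 1 is the root and the non-root
#' terms are split round-robin into \code{nModules} blocks (the same split
#' \code{\link{generateProteome}} uses for its annotation blocks). Each
#' term links to one uniformly chosen earlier term of its own block (the
#' root when none exists yet), plus a second same-block parent with
#' probability \code{dagBranching}; blocks therefore form branches under
#' the root, mirroring how functionally related GO terms cluster in a
#' subgraph of the ontology. Parents always precede children in
#' construction order, so the graph is acyclic by construction. Relations
#' are is_a with probability 0.7 and part_of otherwise.
#'
#' @param cfg a \linkS4class{SyntheticConfig}.
#' @return A \linkS4class{GoDag} (namespace biological_process).
#' @export
generateDag <- function(cfg) {
  validObject(cfg)
  set.seed(cfg@seed)
  nT <- as.integer(cfg@nTerms)
  nM <- as.integer(cfg@nModules)
  terms <- .termId(seq_len(nT))
  child <- parent <- rel <- character(0)
  if (nT > 1L) {
    for (i in 2:nT) {
      sameBlock <- which(.termBlock(2:(i - 1L) + 0L, nM) ==
                           .termBlock(i, nM)) + 1L
      if (i == 2L) sameBlock <- integer(0)
      pool <- if (length(sameBlock)) sameBlock else 1L
      np <- 1L + stats::rbinom(1L, 1L, cfg@dagBranching)
      np <- min(np, length(pool))
      pars <- if (length(pool) == 1L) pool else sample(pool, np)
      for (p in pars) {
        child <- c(child, terms[i]); parent <- c(parent, terms[p])
        rel <- c(rel, if (stats::runif(1) < 0.7) "is_a" else "part_of")
      }
    }
  }
  new("GoDag", terms = terms,
      edges = data.frame(child = child, parent = parent, relation = rel),
      namespace = "biological_process",
      names = paste("synthetic term", seq_len(nT)))
}

#' Generate a synthetic proteome with planted functional modules
#'
#' Proteins are partitioned into modules round-robin. Each module draws a
#' residue distribution from a flat Dirichlet (sequences sampled i.i.d.
#' from it, so composition features correlate with module membership), owns
#' a disjoint domain repertoire (each protein carries 1-3 of its module's
#' domains), and owns a contiguous block of non-root GO terms. PPI edges
#' are sampled with the within/between probabilities (a protein left
#' isolated is connected to one random module-mate so the PPI universe
#' covers all proteins). Annotations start as the module's term block and
#' every (protein, non-root term) cell then flips with probability
#' \code{annotationFlipP}. Per-edge method support is drawn from 3-5 so
#' the standard distinct-method filter keeps all edges.
#'
#' @param cfg a \linkS4class{SyntheticConfig}.
#' @return List with \code{dataset} (a \linkS4class{ProteomeDataset}),
#'   \code{modules} (named integer vector of ground-truth module labels,
#'   kept outside the dataset so leakage checks stay honest), and
#'   \code{termBlocks} (list of term ids per module).
#' @export
generateProteome <- function(cfg) {
  validObject(cfg)
  dag <- generateDag(cfg)
  set.seed(cfg@seed + 1L)
  n <- as.integer(cfg@nProteins)
  nT <- as.integer(cfg@nTerms)
  nM <- as.integer(cfg@nModules)
  nD <- as.integer(cfg@nDomains)
  prot <- .proteinId(seq_len(n))
  module <- rep(seq_len(nM), length.out = n)

  ## module residue distributions: flat Dirichlet over the 20 residues
  resDist <- lapply(seq_len(nM), function(m) {
    g <- stats::rgamma(20, shape = 1)
    g / sum(g)
  })
  lens <- sample(cfg@seqLengthRange[1]:cfg@seqLengthRange[2], n,
                 replace = TRUE)
  seqs <- vapply(seq_len(n), function(i) {
    paste(sample(.AA20, lens[i], replace = TRUE,
                 prob = resDist[[module[i]]]), collapse = "")
  }, character(1))

  ## module domain repertoires (disjoint split of the domain pool)
  repertoire <- split(.domainId(seq_len(nD)),
                      rep(seq_len(nM), length.out = nD))
  domains <- lapply(seq_len(n), function(i) {
    r <- repertoire[[module[i]]]
    sort(sample(r, min(length(r), sample(1:3, 1))))
  })

  ## PPI edges with planted community structure
  from <- to <- character(0)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      p <- if (module[i] == module[j]) cfg@ppiWithinP else cfg@ppiBetweenP
      if (stats::runif(1) < p) { from <- c(from, prot[i]); to <- c(to, prot[j]) }
    }
  }
  deg <- table(factor(c(from, to), levels = prot))
  for (i in which(deg == 0L)) {           # keep every protein in the universe
    mates <- setdiff(which(module == module[i]), i)
    if (!length(mates)) mates <- setdiff(seq_len(n), i)
    j <- sample(mates, 1L)
    from <- c(from, prot[min(i, j)]); to <- c(to, prot[max(i, j)])
  }
  ppi <- data.frame(from = pmin(from, to), to = pmax(from, to))
  ppi <- unique(ppi)
  ppi$nMethods <- sample(3:5, nrow(ppi), replace = TRUE)

  ## coherent GO-term blocks: the same round-robin split of non-root terms
  ## that generateDag used to shape its branches
  nonRoot <- dag@terms[-1L]
  blocks <- split(nonRoot, rep(seq_len(nM), length.out = length(nonRoot)))
  yTrue <- matrix(0L, n, length(nonRoot),
                  dimnames = list(prot, nonRoot))
  for (i in seq_len(n)) yTrue[i, blocks[[module[i]]]] <- 1L
  flips <- matrix(stats::rbinom(length(yTrue), 1L, cfg@annotationFlipP),
                  nrow = n)
  yObs <- (yTrue + flips) %% 2L
  idx <- which(yObs == 1L, arr.ind = TRUE)
  annotations <- data.frame(protein = prot[idx[, 1]],
                            term = nonRoot[idx[, 2]],
                            evidence = "IDA")

  ds <- suppressWarnings(assembleDataset(
    stats::setNames(seqs, prot), ppi, dag, annotations,
    stats::setNames(domains, prot)))
  list(dataset = ds,
       modules = stats::setNames(module, prot),
       termBlocks = blocks)
}

#' Write a dataset to the five on-disk input formats
#'
#' Emits \code{sequences.fasta}, \code{ontology.obo},
#' \code{annotations.gaf}, \code{ppi.tsv} (one row per edge-method pair,
#' methods named m1..mk) and \code{domains.tsv} into \code{dir}, such that
#' reading them back through the io layer reproduces the dataset. Output
#' bytes are a pure function of the dataset.
#'
#' @param dataset a \linkS4class{ProteomeDataset}.
#' @param dir output directory (created if needed).
#' @return Invisibly, the named vector of file paths.
#' @export
writeFixture <- function(dataset, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(fasta = file.path(dir, "sequences.fasta"),
             obo = file.path(dir, "ontology.obo"),
             gaf = file.path(dir, "annotations.gaf"),
             ppi = file.path(dir, "ppi.tsv"),
             domains = file.path(dir, "domains.tsv"))
  hasSeq <- !is.na(dataset@sequences)
  seqset <- Biostrings::BStringSet(dataset@sequences[hasSeq])
  names(seqset) <- dataset@proteins[hasSeq]
  Biostrings::writeXStringSet(seqset, paths["fasta"], width = 60L)

  dag <- dataset@dag
  lines <- c("format-version: 1.2", "")
  for (i in seq_along(dag@terms)) {
    t <- dag@terms[i]
    ed <- dag@edges[dag@edges$child == t, , drop = FALSE]
    lines <- c(lines, "[Term]", paste0("id: ", t),
               paste0("name: ", dag@names[i]),
               paste0("namespace: ", dag@namespace))
    for (r in seq_len(nrow(ed))) {
      lines <- c(lines, if (ed$relation[r] == "is_a")
        paste0("is_a: ", ed$parent[r])
        else paste0("relationship: part_of ", ed$parent[r]))
    }
    lines <- c(lines, "")
  }
  writeLines(lines, paths["obo"])

  writeGaf(dataset@annotations, paths["gaf"])

  ed <- dataset@ppi
  rows <- character(0)
  for (r in seq_len(nrow(ed))) {
    rows <- c(rows, paste(ed$from[r], ed$to[r],
                          paste0("m", seq_len(ed$nMethods[r])), sep = "\t"))
  }
  writeLines(rows, paths["ppi"])

  dl <- character(0)
  for (i in seq_along(dataset@proteins)) {
    d <- dataset@domains[[i]]
    if (length(d))
      dl <- c(dl, paste(dataset@proteins[i], d, sep = "\t"))
  }
  writeLines(dl, paths["domains"])
  invisible(paths)
}
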