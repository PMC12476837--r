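## Readers for the five input formats, the experimental filters, and dataset
## assembly. All axes downstream use the deterministic radix-sorted orderings
## fixed here.

#' Read protein sequences from FASTA
#'
#' Header token up to the first whitespace is taken as the protein id;
#' sequences are uppercased. Residue sanitization (dropping non-standard
#' letters) happens later, at assembly.
#'
#' @param path FASTA file.
#' @return Named character vector, protein id -> sequence.
#' @export
#' @examples
#' f <- tempfile(fileext = ".fasta")
#' writeLines(c(">P1 some description", "acde", ">P2", "MKV"), f)
#' readFasta(f)
readFasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("empty FASTA file: ", path)
  ids <- vapply(strsplit(names(set), "\\s+"), `[`, character(1), 1L)
  dup <- ids[duplicated(ids)]
  if (length(dup))
    stop("duplicate FASTA ids: ", paste(unique(dup), collapse = ", "))
  stats::setNames(toupper(as.character(set)), ids)
}

#' Sanitize an amino-acid sequence
#'
#' Drops every character outside the 20-letter standard alphabet (so the
#' ambiguity codes B, J, O, U, X, Z and \code{*} disappear). A sequence
#' reduced to length zero is reported as \code{NA} (treated as absent).
#'
#' @param sequence character vector of sequences (uppercase).
#' @return Character vector of cleaned sequences, \code{NA} where empty.
#' @export
#' @examples
#' sanitizeSequence(c("ACXDE*", "XXB"))
sanitizeSequence <- function(sequence) {
  out <- gsub("[^ACDEFGHIKLMNPQRSTVWY]", "", toupper(sequence))
  out[!nzchar(out) | is.na(sequence)] <- NA_character_
  out
}

## split a headerless TSV into fields, erroring with the 1-based line number
.readTsv <- function(path, minCols, what) {
  if (!file.exists(path)) stop(what, " file not found: ", path)
  lines <- readLines(path)
  keep <- which(nzchar(lines) & !startsWith(lines, "#"))
  if (!length(keep)) stop("empty ", what, " file: ", path)
  fields <- strsplit(lines[keep], "\t", fixed = TRUE)
  bad <- which(lengths(fields) < minCols)
  if (length(bad))
    stop("malformed ", what, " row at line ", keep[bad[1]],
         ": expected at least ", minCols, " tab-separated columns")
  list(fields = fields, lineNo = keep)
}

#' Read a PPI edge table with a distinct-method support filter
#'
#' Expects a headerless TSV with columns (protein id, protein id, method
#' label). An unordered pair is retained only when it is supported by at
#' least \code{minMethods} \emph{distinct} experimental method labels;
#' repeated listings with the same method count once. Self-loops are
#' dropped.
#'
#' @param path TSV file.
#' @param minMethods minimum number of distinct methods per edge
#'   (default 3, the standard high-confidence filter).
#' @return data.frame with columns \code{from}, \code{to} (with
#'   \code{from < to}) and \code{nMethods}.
#' @export
#' @examples
#' f <- tempfile(fileext = ".tsv")
#' writeLines(c("A\tB\tm1", "B\tA\tm2", "A\tB\tm3", "A\tA\tm1"), f)
#' readPpiTable(f, minMethods = 3)
readPpiTable <- function(path, minMethods = 3) {
  if (minMethods < 1) stop("minMethods must be >= 1")
  tsv <- .readTsv(path, 3L, "PPI")
  a <- vapply(tsv$fields, `[`, character(1), 1L)
  b <- vapply(tsv$fields, `[`, character(1), 2L)
  m <- vapply(tsv$fields, `[`, character(1), 3L)
  ok <- a != b                                  # drop self-loops
  a <- a[ok]; b <- b[ok]; m <- m[ok]
  if (!length(a)) return(data.frame(from = character(0), to = character(0),
                                    nMethods = integer(0)))
  from <- pmin(a, b); to <- pmax(a, b)
  key <- paste(from, to, sep = "\r")
  nm <- vapply(split(m, key), function(x) length(unique(x)), integer(1))
  keep <- names(nm)[nm >= minMethods]
  parts <- strsplit(keep, "\r", fixed = TRUE)
  out <- data.frame(
    from = vapply(parts, `[`, character(1), 1L),
    to = vapply(parts, `[`, character(1), 2L),
    nMethods = unname(nm[keep]))
  out <- out[order(out$from, out$to, method = "radix"), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read a GO ontology from OBO 1.2, restricted to one namespace
#'
#' Parses \code{[Term]} stanzas keeping \code{id}, \code{name},
#' \code{namespace}, \code{is_a} and \code{relationship: part_of} lines.
#' Obsolete terms are excluded; relation types other than is_a / part_of are
#' ignored; edges crossing into another namespace are dropped with a
#' warning. Acyclicity is verified and a detected cycle is reported.
#'
#' @param path OBO 1.2 file.
#' @param namespace \code{"BP"}, \code{"MF"}, \code{"CC"} or the long OBO
#'   namespace names.
#' @return A \linkS4class{GoDag}.
#' @export
readObo <- function(path, namespace = "BP") {
  ns <- .normalizeNamespace(namespace)
  if (!file.exists(path)) stop("OBO file not found: ", path)
  lines <- readLines(path)
  starts <- which(lines == "[Term]")
  if (!length(starts)) stop("no [Term] stanzas found in ", path)
  bounds <- c(which(startsWith(lines, "[")), length(lines) + 1L)
  ids <- names <- nss <- character(0)
  obsolete <- logical(0)
  echild <- eparent <- erel <- character(0)
  childNs <- character(0)
  for (s in starts) {
    e <- min(bounds[bounds > s]) - 1L
    block <- lines[(s + 1L):e]
    val <- function(tag) {
      hits <- block[startsWith(block, paste0(tag, ": "))]
      sub("\\s*!.*$", "", substring(hits, nchar(tag) + 3L))
    }
    id <- val("id")[1]
    if (is.na(id)) next
    ids <- c(ids, id)
    nm <- val("name")[1]; names <- c(names, if (is.na(nm)) "" else nm)
    tns <- val("namespace")[1]
    nss <- c(nss, if (is.na(tns)) "" else tns)
    obsolete <- c(obsolete, identical(val("is_obsolete")[1], "true"))
    isa <- trimws(val("is_a"))
    for (p in isa) {
      echild <- c(echild, id); eparent <- c(eparent, p)
      erel <- c(erel, "is_a"); childNs <- c(childNs, tns)
    }
    rel <- trimws(val("relationship"))
    po <- rel[startsWith(rel, "part_of ")]
    for (p in sub("^part_of\\s+", "", po)) {
      echild <- c(echild, id); eparent <- c(eparent, p)
      erel <- c(erel, "part_of"); childNs <- c(childNs, tns)
    }
  }
  keep <- !obsolete & nss == ns
  terms <- ids[keep]
  termNames <- stats::setNames(names[keep], terms)
  inSet <- echild %in% terms
  crossNs <- inSet & !(eparent %in% terms)
  if (any(crossNs))
    warning(sum(crossNs), " edge(s) leaving namespace '", ns, "' dropped")
  ek <- inSet & (eparent %in% terms)
  edges <- data.frame(child = echild[ek], parent = eparent[ek],
                      relation = erel[ek])
  edges <- unique(edges)
  rownames(edges) <- NULL
  if (nrow(edges) > 0L) {
    g <- igraph::graph_from_data_frame(edges[, c("child", "parent")],
                                       directed = TRUE)
    if (!igraph::is_dag(g)) {
      cyc <- .findCycle(edges)
      stop("ontology contains a cycle: ", paste(cyc, collapse = " -> "))
    }
  }
  new("GoDag", terms = terms, edges = edges, namespace = ns,
      names = unname(termNames))
}

## DFS cycle finder over child -> parent edges (small graphs)
.findCycle <- function(edges) {
  adj <- split(edges$parent, edges$child)
  state <- new.env(parent = emptyenv())
  path <- character(0)
  found <- NULL
  visit <- function(v) {
    if (!is.null(found)) return()
    st <- mget(v, envir = state, ifnotfound = 0L)[[1]]
    if (st == 1L) { found <<- c(path[which(path == v)[1]:length(path)], v); return() }
    if (st == 2L) return()
    assign(v, 1L, envir = state)
    path <<- c(path, v)
    for (w in adj[[v]]) visit(w)
    path <<- path[-length(path)]
    assign(v, 2L, envir = state)
  }
  for (v in unique(edges$child)) { visit(v); if (!is.null(found)) break }
  found
}

#' Read protein-GO annotations from a GAF 2.x file
#'
#' Keeps rows whose evidence code is in \code{evidenceCodes}; rows whose
#' qualifier contains \code{NOT} are dropped; duplicate (protein, term)
#' pairs collapse to one (first evidence code wins). Lines starting with
#' \code{!} are comments.
#'
#' @param path GAF 2.x tab-separated file (>= 15 columns).
#' @param evidenceCodes retained evidence codes; default is the
#'   experimental/curated set EXP, IDA, IMP, IGI, IEP, TAS, IC.
#' @return data.frame with columns \code{protein}, \code{term},
#'   \code{evidence}.
#' @export
readGaf <- function(path,
                    evidenceCodes = c("EXP", "IDA", "IMP", "IGI",
                                      "IEP", "TAS", "IC")) {
  if (!file.exists(path)) stop("GAF file not found: ", path)
  lines <- readLines(path)
  keep <- which(nzchar(lines) & !startsWith(lines, "!"))
  if (!length(keep)) stop("no annotation rows in ", path)
  fields <- strsplit(lines[keep], "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 15L)
  if (length(bad))
    stop("malformed GAF row at line ", keep[bad[1]],
         ": expected >= 15 tab-separated columns, got ",
         lengths(fields)[bad[1]])
  protein <- vapply(fields, `[`, character(1), 2L)
  qualifier <- vapply(fields, `[`, character(1), 4L)
  term <- vapply(fields, `[`, character(1), 5L)
  evidence <- vapply(fields, `[`, character(1), 7L)
  ok <- evidence %in% evidenceCodes &
    !grepl("(^|\\|)NOT($|\\|)", qualifier)
  out <- data.frame(protein = protein[ok], term = term[ok],
                    evidence = evidence[ok])
  out <- out[!duplicated(paste(out$protein, out$term)), , drop = FALSE]
  out <- out[order(out$protein, out$term, method = "radix"), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write an annotation table back to GAF 2.2
#'
#' Inverse of \code{\link{readGaf}} up to column padding; used for
#' round-trip checks and fixture emission.
#'
#' @param annotations data.frame with columns \code{protein}, \code{term}
#'   and optionally \code{evidence} (default \code{"IDA"}).
#' @param path output file.
#' @param db database label for column 1.
#' @return Invisibly, \code{path}.
#' @export
writeGaf <- function(annotations, path, db = "SYNTH") {
  ev <- if ("evidence" %in% colnames(annotations)) annotations$evidence
        else rep("IDA", nrow(annotations))
  rows <- paste(db, annotations$protein, annotations$protein, "",
                annotations$term, "PMID:0000000", ev, "",
                "P", "", "", "protein", "taxon:0000", "20260101", db,
                "", "", sep = "\t")
  writeLines(c("!gaf-version: 2.2", rows), path)
  invisible(path)
}

#' Read protein-domain assignments
#'
#' Headerless TSV: column 1 protein id, column 2 domain accession.
#'
#' @param path TSV file.
#' @return Named list, protein id -> character vector of distinct domain
#'   accessions.
#' @export
readDomainTable <- function(path) {
  tsv <- .readTsv(path, 2L, "domain")
  p <- vapply(tsv$fields, `[`, character(1), 1L)
  d <- vapply(tsv$fields, `[`, character(1), 2L)
  lapply(split(d, p), function(x) .sortIds(x))
}

#' Filter GO terms by annotation count
#'
#' Retains exactly the terms annotating between \code{minCount} and
#' \code{maxCount} distinct proteins inclusive, removing both overly
#' specific and overly general terms. The protein set is unchanged.
#'
#' @param annotations data.frame with columns \code{protein}, \code{term}.
#' @param minCount,maxCount inclusive bounds (defaults 10 and 200).
#' @return The filtered annotation data.frame.
#' @export
filterGoTerms <- function(annotations, minCount = 10, maxCount = 200) {
  if (minCount > maxCount) stop("minCount must be <= maxCount")
  cnt <- vapply(split(annotations$protein, annotations$term),
                function(x) length(unique(x)), integer(1))
  keep <- names(cnt)[cnt >= minCount & cnt <= maxCount]
  out <- annotations[annotations$term %in% keep, , drop = FALSE]
  if (nrow(out) == 0L)
    message("filterGoTerms: no terms satisfy the [", minCount, ", ",
            maxCount, "] bound")
  rownames(out) <- NULL
  out
}

#' Assemble a consistent ProteomeDataset
#'
#' The protein universe is the PPI node set (similarity layers are defined
#' over experimentally validated interaction pairs); proteins without a
#' usable sequence or without domain assignments are retained with empty
#' fields. The term universe is the set of annotated terms present in the
#' DAG. Both axes are radix-sorted so repeated assembly of the same inputs
#' is byte-identical.
#'
#' @param sequences named character vector from \code{\link{readFasta}}
#'   (may cover only part of the proteins).
#' @param ppi edge data.frame from \code{\link{readPpiTable}}.
#' @param dag a \linkS4class{GoDag}.
#' @param annotations evidence-filtered (and typically count-filtered)
#'   annotation data.frame.
#' @param domainMap named list from \code{\link{readDomainTable}}.
#' @return A \linkS4class{ProteomeDataset}.
#' @export
assembleDataset <- function(sequences, ppi, dag, annotations,
                            domainMap = list()) {
  proteins <- .sortIds(c(ppi$from, ppi$to))
  if (length(proteins) == 0L) stop("empty protein universe (no PPI edges)")
  seqs <- sanitizeSequence(sequences[proteins])
  names(seqs) <- NULL
  doms <- lapply(proteins, function(p) {
    d <- domainMap[[p]]
    if (is.null(d)) character(0) else .sortIds(d)
  })
  an <- annotations
  unknownP <- !(an$protein %in% proteins)
  if (any(unknownP))
    warning(sum(unknownP), " annotation(s) referencing proteins outside ",
            "the PPI universe dropped")
  unknownT <- !(an$term %in% dag@terms)
  if (any(unknownT))
    warning(sum(unknownT), " annotation(s) referencing terms absent from ",
            "the DAG dropped")
  an <- an[!unknownP & !unknownT, , drop = FALSE]
  if (!"evidence" %in% colnames(an)) an$evidence <- rep("IDA", nrow(an))
  an <- an[!duplicated(paste(an$protein, an$term)), , drop = FALSE]
  an <- an[order(an$protein, an$term, method = "radix"), , drop = FALSE]
  rownames(an) <- NULL
  termIndex <- .sortIds(an$term)
  if (length(termIndex) == 0L) stop("empty term universe after assembly")
  ppi <- ppi[order(ppi$from, ppi$to, method = "radix"), , drop = FALSE]
  rownames(ppi) <- NULL
  new("ProteomeDataset", proteins = proteins, sequences = seqs,
      domains = doms, ppi = ppi, dag = dag, annotations = an,
      termIndex = termIndex)
}

#' Serialize / restore a ProteomeDataset as JSON
#'
#' Plain-text serialization carrying the id lists so that matrix indices are
#' reproducible across sessions; used by the command-line pipeline.
#'
#' @param dataset a \linkS4class{ProteomeDataset}.
#' @param path JSON file.
#' @return \code{saveDataset}: invisibly the path; \code{loadDataset}: the
#'   restored dataset.
#' @export
saveDataset <- function(dataset, path) {
  obj <- list(
    proteins = dataset@proteins,
    sequences = dataset@sequences,
    domains = stats::setNames(dataset@domains, dataset@proteins),
    ppi = dataset@ppi,
    dag = list(terms = dataset@dag@terms, edges = dataset@dag@edges,
               namespace = dataset@dag@namespace, names = dataset@dag@names),
    annotations = dataset@annotations,
    termIndex = dataset@termIndex)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null")
  invisible(path)
}

#' @rdname saveDataset
#' @export
loadDataset <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  ed <- as.data.frame(obj$dag$edges)
  if (nrow(ed) == 0L)
    ed <- data.frame(child = character(0), parent = character(0),
                     relation = character(0))
  dag <- new("GoDag", terms = as.character(obj$dag$terms), edges = ed,
             namespace = obj$dag$namespace,
             names = as.character(obj$dag$names))
  doms <- lapply(obj$domains, function(d) as.character(unlist(d)))
  new("ProteomeDataset",
      proteins = as.character(obj$proteins),
      sequences = as.character(obj$sequences),
      domains = unname(doms[obj$proteins]),
      ppi = as.data.frame(obj$ppi),
      dag = dag,
      annotations = as.data.frame(obj$annotations),
      termIndex = as.character(obj$termIndex))
}
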