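#' @import methods
NULL

#' FunCatAnnotation: protein-to-term annotation map
#'
#' Maps protein identifiers to non-empty sets of hierarchical FunCat terms
#' (dot-separated numeric fields such as `"01.01.03.01.01"`; deeper means
#' more specific). Proteins without any valid annotation are absent from the
#' map; the number of malformed or empty records dropped while parsing is
#' kept in `skipped`.
#'
#' @slot annotations named list; one character vector of terms per protein,
#'   each non-empty and duplicate-free.
#' @slot skipped integer count of input records skipped during parsing.
#'
#' @seealso [readAnnotations()], [groupProteins()]
#' @export
setClass("FunCatAnnotation",
  slots = c(annotations = "list", skipped = "integer"),
  prototype = prototype(annotations = structure(list(), names = character(0)),
                        skipped = 0L))

setValidity("FunCatAnnotation", function(object) {
  ann <- object@annotations
  if (length(ann) > 0 && (is.null(names(ann)) || any(!nzchar(names(ann)))))
    return("all annotation entries must be named by a protein ID")
  if (anyDuplicated(names(ann)))
    return("duplicated protein IDs in annotation map")
  ok <- vapply(ann, function(x) is.character(x) && length(x) >= 1 &&
                 all(nzchar(x)) && !anyDuplicated(x), logical(1))
  if (length(ok) && !all(ok))
    return("every protein must map to a non-empty, duplicate-free set of terms")
  TRUE
})

#' PPINetwork: an undirected protein-protein interaction network
#'
#' Nodes are opaque, case-sensitive protein identifiers; edges are unordered
#' protein pairs with an optional real-valued confidence score. Self-loops
#' are never stored (the count dropped at parse time is retained). Edges are
#' held in canonical form (`protein1 < protein2` in C-locale order) and
#' deduplicated, so `(a,b)` and `(b,a)` are one edge. `nodes` may contain
#' proteins with no incident edge (isolated nodes of an induced subnetwork).
#'
#' @slot interactions data.frame with columns `protein1`, `protein2`,
#'   `score` (numeric, `NA` when the input had no score column).
#' @slot nodes character vector of protein IDs (superset of edge endpoints).
#' @slot selfLoops integer count of self-interactions dropped on input.
#'
#' @seealso [readEdgeList()], [inducedSubnetwork()]
#' @export
setClass("PPINetwork",
  slots = c(interactions = "data.frame", nodes = "character",
            selfLoops = "integer"),
  prototype = prototype(
    interactions = data.frame(protein1 = character(0),
                              protein2 = character(0),
                              score = numeric(0),
                              stringsAsFactors = FALSE),
    nodes = character(0), selfLoops = 0L))

setValidity("PPINetwork", function(object) {
  e <- object@interactions
  if (!all(c("protein1", "protein2", "score") %in% names(e)))
    return("interactions must have columns protein1, protein2, score")
  if (nrow(e) > 0) {
    if (any(e$protein1 == e$protein2))
      return("self-loop edges are not allowed")
    if (any(e$protein1 > e$protein2))
      return("edges must be stored in canonical order (protein1 < protein2)")
    if (anyDuplicated(paste(e$protein1, e$protein2, sep = "\r")))
      return("duplicate edges")
    if (!all(c(e$protein1, e$protein2) %in% object@nodes))
      return("edge endpoints missing from the node set")
  }
  if (anyDuplicated(object@nodes))
    return("duplicated node IDs")
  TRUE
})

#' ComplexSet: a catalogue of protein complexes
#'
#' A list of protein-ID sets of size >= 2 each, labelled by origin
#' (`"predicted"`, a benchmark name such as `"CYC2008"`, ...). Preliminary
#' clusters, merged predictions and benchmark catalogues all share this
#' shape.
#'
#' @slot members list of character vectors, each of length >= 2 with no
#'   duplicate IDs.
#' @slot label single character string naming the catalogue.
#'
#' @seealso [readComplexes()], [evaluateComplexes()]
#' @export
setClass("ComplexSet",
  slots = c(members = "list", label = "character"),
  prototype = prototype(members = list(), label = "unnamed"))

setValidity("ComplexSet", function(object) {
  if (length(object@label) != 1 || !nzchar(object@label))
    return("label must be a single non-empty string")
  ok <- vapply(object@members, function(x) is.character(x) &&
                 length(x) >= 2 && !anyDuplicated(x), logical(1))
  if (length(ok) && !all(ok))
    return("every complex must be a duplicate-free character vector of size >= 2")
  TRUE
})

#' MCLParams: Markov clustering parameters
#'
#' Controls the expansion/inflation iteration of [runMCL()]. Defaults are
#' the canonical MCL settings (expansion 2, inflation 2.0) with light
#' numerical pruning.
#'
#' @slot expansion integer >= 2; matrix power used at the expansion step.
#' @slot inflation numeric > 1; elementwise (Hadamard) power at the
#'   inflation step.
#' @slot pruneThreshold non-negative numeric; entries below it are zeroed
#'   after inflation, before column renormalization.
#' @slot maxIterations positive integer cap on expansion/inflation rounds.
#' @slot convergenceTol positive numeric; iteration stops when the largest
#'   elementwise change between successive post-inflation matrices falls
#'   below it.
#'
#' @export
setClass("MCLParams",
  slots = c(expansion = "integer", inflation = "numeric",
            pruneThreshold = "numeric", maxIterations = "integer",
            convergenceTol = "numeric"))

setValidity("MCLParams", function(object) {
  if (object@expansion < 2L) return("expansion must be an integer >= 2")
  if (object@inflation <= 1) return("inflation must be > 1")
  if (object@pruneThreshold < 0) return("pruneThreshold must be >= 0")
  if (object@maxIterations < 1L) return("maxIterations must be >= 1")
  if (object@convergenceTol <= 0) return("convergenceTol must be > 0")
  TRUE
})

#' @describeIn MCLParams-class Constructor with canonical MCL defaults.
#' @param expansion,inflation,pruneThreshold,maxIterations,convergenceTol
#'   see the corresponding slots.
#' @return An `MCLParams` object.
#' @examples
#' MCLParams()
#' MCLParams(inflation = 1.8)
#' @export
MCLParams <- function(expansion = 2L, inflation = 2.0,
                      pruneThreshold = 1e-5, maxIterations = 100L,
                      convergenceTol = 1e-6) {
  new("MCLParams", expansion = as.integer(expansion),
      inflation = as.numeric(inflation),
      pruneThreshold = as.numeric(pruneThreshold),
      maxIterations = as.integer(maxIterations),
      convergenceTol = as.numeric(convergenceTol))
}

#' @describeIn ComplexSet-class Constructor; canonicalizes member order.
#' @param members list of character vectors (protein IDs), each size >= 2.
#' @param label catalogue label.
#' @return A `ComplexSet`.
#' @export
ComplexSet <- function(members, label = "unnamed") {
  members <- lapply(members, function(x) sortIds(unique(as.character(x))))
  new("ComplexSet", members = unname(members), label = label)
}

#' @describeIn FunCatAnnotation-class Constructor.
#' @param annotations named list of character term vectors.
#' @param skipped count of records dropped during parsing.
#' @return A `FunCatAnnotation`.
#' @export
FunCatAnnotation <- function(annotations, skipped = 0L) {
  annotations <- lapply(annotations, function(x) sortIds(unique(as.character(x))))
  new("FunCatAnnotation", annotations = annotations,
      skipped = as.integer(skipped))
}

#' @describeIn PPINetwork-class Constructor; canonicalizes and deduplicates
#'   edges, drops self-loops (counted), and completes the node set.
#' @param protein1,protein2 character vectors of edge endpoints.
#' @param score numeric edge confidences (`NA` if absent).
#' @param nodes optional extra node IDs to keep even when isolated.
#' @param selfLoops count of self-interactions already dropped upstream.
#' @return A `PPINetwork`.
#' @export
PPINetwork <- function(protein1 = character(0), protein2 = character(0),
                       score = NA_real_, nodes = character(0),
                       selfLoops = 0L) {
  protein1 <- as.character(protein1)
  protein2 <- as.character(protein2)
  score <- rep_len(as.numeric(score), length(protein1))
  loop <- protein1 == protein2
  selfLoops <- as.integer(selfLoops) + sum(loop)
  protein1 <- protein1[!loop]; protein2 <- protein2[!loop]
  score <- score[!loop]
  a <- pmin(protein1, protein2)
  b <- pmax(protein1, protein2)
  key <- paste(a, b, sep = "\r")
  keep <- !duplicated(key)
  e <- data.frame(protein1 = a[keep], protein2 = b[keep],
                  score = score[keep], stringsAsFactors = FALSE)
  ord <- order(e$protein1, e$protein2, method = "radix")
  e <- e[ord, , drop = FALSE]
  rownames(e) <- NULL
  allNodes <- sortIds(unique(c(e$protein1, e$protein2, as.character(nodes))))
  new("PPINetwork", interactions = e, nodes = allNodes,
      selfLoops = selfLoops)
}

# C-locale sort so output order never depends on the session locale
sortIds <- function(x) sort(x, method = "radix")
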