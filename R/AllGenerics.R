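#' Protein identifiers carried by an object
#'
#' @param x a [FunCatAnnotation-class], [PPINetwork-class] or
#'   [ComplexSet-class] object.
#' @return Character vector of protein IDs, C-locale sorted.
#' @export
setGeneric("proteins", function(x) standardGeneric("proteins"))

#' Edge table of a PPI network
#'
#' @param x a [PPINetwork-class].
#' @return data.frame with columns `protein1`, `protein2`, `score`.
#' @export
setGeneric("interactions", function(x) standardGeneric("interactions"))

#' Number of edges in a PPI network
#' @param x a [PPINetwork-class].
#' @return Integer edge count.
#' @export
setGeneric("numInteractions", function(x) standardGeneric("numInteractions"))

#' Annotation terms of one protein or all proteins
#'
#' @param x a [FunCatAnnotation-class].
#' @param protein optional single protein ID; when missing, the full named
#'   list is returned.
#' @return Character vector of terms, or the full named list.
#' @export
setGeneric("funcatTerms", function(x, protein) standardGeneric("funcatTerms"))

#' Member lists of a complex catalogue
#' @param x a [ComplexSet-class].
#' @return List of character vectors.
#' @export
setGeneric("complexes", function(x) standardGeneric("complexes"))

#' Catalogue label
#' @param x a [ComplexSet-class].
#' @return Single character string.
#' @export
setGeneric("catalogueLabel", function(x) standardGeneric("catalogueLabel"))

#' Complex sizes
#' @param x a [ComplexSet-class].
#' @return Integer vector of member counts.
#' @export
setGeneric("complexSizes", function(x) standardGeneric("complexSizes"))

#' @rdname proteins
#' @export
setMethod("proteins", "FunCatAnnotation",
          function(x) sortIds(names(x@annotations)))

#' @rdname proteins
#' @export
setMethod("proteins", "PPINetwork", function(x) x@nodes)

#' @rdname proteins
#' @export
setMethod("proteins", "ComplexSet",
          function(x) sortIds(unique(unlist(x@members, use.names = FALSE))))

#' @rdname interactions
#' @export
setMethod("interactions", "PPINetwork", function(x) x@interactions)

#' @rdname numInteractions
#' @export
setMethod("numInteractions", "PPINetwork", function(x) nrow(x@interactions))

#' @rdname funcatTerms
#' @export
setMethod("funcatTerms", "FunCatAnnotation", function(x, protein) {
  if (missing(protein)) return(x@annotations)
  stopifnot(length(protein) == 1)
  terms <- x@annotations[[protein]]
  if (is.null(terms))
    stop("protein '", protein, "' has no annotation", call. = FALSE)
  terms
})

#' @rdname complexes
#' @export
setMethod("complexes", "ComplexSet", function(x) x@members)

#' @rdname catalogueLabel
#' @export
setMethod("catalogueLabel", "ComplexSet", function(x) x@label)

#' @rdname complexSizes
#' @export
setMethod("complexSizes", "ComplexSet",
          function(x) vapply(x@members, length, integer(1)))

#' @describeIn FunCatAnnotation-class Number of annotated proteins.
#' @param x object.
#' @export
setMethod("length", "FunCatAnnotation", function(x) length(x@annotations))

#' @describeIn ComplexSet-class Number of complexes.
#' @export
setMethod("length", "ComplexSet", function(x) length(x@members))

#' @describeIn ComplexSet-class Extract one complex's member IDs.
#' @param i index.
#' @export
setMethod("[[", "ComplexSet", function(x, i) x@members[[i]])

setMethod("show", "FunCatAnnotation", function(object) {
  nterm <- sum(lengths(object@annotations))
  cat("FunCatAnnotation with", length(object@annotations),
      "proteins and", nterm, "protein-term assignments\n")
  if (object@skipped > 0)
    cat("  (", object@skipped, " malformed record(s) skipped on input)\n",
        sep = "")
})

setMethod("show", "PPINetwork", function(object) {
  cat("PPINetwork with", length(object@nodes), "proteins and",
      nrow(object@interactions), "interactions\n")
  if (nrow(object@interactions) > 0 &&
      !all(is.na(object@interactions$score)))
    cat("  edge confidence scores present\n")
  if (object@selfLoops > 0)
    cat("  (", object@selfLoops, " self-interaction(s) dropped)\n", sep = "")
})

setMethod("show", "ComplexSet", function(object) {
  sz <- vapply(object@members, length, integer(1))
  cat("ComplexSet '", object@label, "': ", length(sz), " complexes",
      sep = "")
  if (length(sz) > 0)
    cat(" (", sum(sz <= 3), " small [2-3], ", sum(sz >= 4),
        " large [>=4])", sep = "")
  cat("\n")
})

setMethod("show", "MCLParams", function(object) {
  cat("MCLParams: expansion=", object@expansion,
      ", inflation=", object@inflation,
      ", prune=", object@pruneThreshold,
      ", maxIter=", object@maxIterations,
      ", tol=", object@convergenceTol, "\n", sep = "")
})
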