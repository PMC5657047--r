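#' Detect preliminary clusters across all protein groups
#'
#' For every annotation-derived protein group, builds the induced PPI
#' subnetwork, runs Markov clustering on it, discards singleton clusters
#' (a one-protein cluster is not a complex), and pools the survivors.
#' Identical clusters arising from different groups are kept once.
#'
#' Groups with fewer than two members present in the network are skipped
#' without running MCL — they cannot yield a cluster of size two, so the
#' result is unchanged.
#'
#' @param net a [PPINetwork-class] (the full interactome).
#' @param groups named list of protein-ID vectors, as returned by
#'   [groupProteins()].
#' @param params an [MCLParams-class].
#' @return List of clusters (character vectors, size >= 2 each),
#'   deduplicated, in deterministic C-locale order.
#' @examples
#' net <- PPINetwork(c("A", "B", "C"), c("B", "C", "A"))
#' detectPreliminaryClusters(net, list(`01` = c("A", "B", "C")))
#' @export
detectPreliminaryClusters <- function(net, groups, params = MCLParams()) {
  stopifnot(is(net, "PPINetwork"), is.list(groups))
  pooled <- list()
  if (!is.null(names(groups))) groups <- groups[sortIds(names(groups))]
  for (g in groups) {
    sub <- inducedSubnetwork(net, g)
    if (length(proteins(sub)) < 2) next
    cl <- runMCL(sub, params)
    cl <- cl[lengths(cl) >= 2]
    pooled <- c(pooled, cl)
  }
  if (length(pooled) == 0)
    stop("no preliminary clusters were found; check that annotation and ",
         "PPI files use the same protein identifiers", call. = FALSE)
  keys <- vapply(pooled, paste, character(1), collapse = "\r")
  pooled <- pooled[!duplicated(keys)]
  pooled[order(vapply(pooled, paste, character(1), collapse = "\r"),
               method = "radix")]
}
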