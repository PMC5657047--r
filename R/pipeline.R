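#' Predict protein complexes from a PPI network and annotations
#'
#' The full three-step pipeline: (1) group proteins by functional
#' annotation truncated to `level` ([groupProteins()]); (2) run Markov
#' clustering on each group's induced subnetwork and pool the non-singleton
#' clusters ([detectPreliminaryClusters()]); (3) merge clusters that
#' overlap above `overlapThreshold` through cliques of the overlap graph
#' ([mergeClusters()]). A complex must therefore consist of proteins that
#' first share function and then interact densely — which is how the
#' framework captures size-2 and size-3 complexes that plain graph
#' clustering on the whole interactome misses, while still recovering
#' large ones.
#'
#' Proteins without annotations can never be predicted; their count is
#' reported via a message.
#'
#' @param net a [PPINetwork-class].
#' @param ann a [FunCatAnnotation-class].
#' @param level annotation truncation level (default 6, the most specific
#'   FunCat level).
#' @param params an [MCLParams-class].
#' @param overlapThreshold overlap-rate threshold for merging (default 0.8).
#' @return A [ComplexSet-class] labelled `"predicted"`.
#' @examples
#' sim <- simulateComplexData(nComplexes = 5, seed = 7)
#' pred <- predictComplexes(sim$network, sim$annotations)
#' evaluateComplexes(pred, sim$catalogue)
#' @export
predictComplexes <- function(net, ann, level = 6, params = MCLParams(),
                             overlapThreshold = 0.8) {
  stopifnot(is(net, "PPINetwork"), is(ann, "FunCatAnnotation"))
  unannotated <- setdiff(proteins(net), proteins(ann))
  if (length(unannotated) > 0)
    message(length(unannotated),
            " network protein(s) carry no annotation and cannot be predicted")
  groups <- groupProteins(ann, level = level)
  prelim <- detectPreliminaryClusters(net, groups, params)
  merged <- mergeClusters(prelim, threshold = overlapThreshold)
  ComplexSet(merged, label = "predicted")
}
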