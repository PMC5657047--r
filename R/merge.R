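#' Overlap rate between two clusters
#'
#' `olr(C1, C2) = |C1 n C2|^2 / (|C1| |C2|)`: the squared intersection size
#' normalized by both cluster sizes. Symmetric, bounded in `[0, 1]`, and 1
#' exactly when the two sets are identical.
#'
#' @param c1,c2 non-empty character vectors of protein IDs.
#' @return Numeric in `[0, 1]`.
#' @examples
#' overlapRate(c("a", "b", "c", "d"), c("c", "d"))  # 4 / 8 = 0.5
#' @export
overlapRate <- function(c1, c2) {
  c1 <- unique(as.character(c1)); c2 <- unique(as.character(c2))
  if (length(c1) == 0 || length(c2) == 0)
    stop("overlapRate is undefined for empty clusters", call. = FALSE)
  length(intersect(c1, c2))^2 / (length(c1) * length(c2))
}

#' Build the cluster overlap graph
#'
#' Nodes are the input clusters; two clusters are linked when their
#' [overlapRate()] strictly exceeds `threshold` ("exceeds", so a pair at
#' exactly the threshold is not linked).
#'
#' @param clusters list of clusters (deduplicated character vectors).
#' @param threshold numeric overlap-rate threshold (default 0.8).
#' @return An `igraph` undirected graph whose vertices `1..length(clusters)`
#'   index the input list.
#' @export
buildOverlapGraph <- function(clusters, threshold = 0.8) {
  n <- length(clusters)
  if (n > 5000)
    warning("overlap graph has ", n, " nodes; clique enumeration may be slow",
            call. = FALSE)
  edges <- integer(0)
  if (n >= 2) {
    sets <- lapply(clusters, unique)
    for (i in seq_len(n - 1)) {
      for (j in seq((i + 1), n)) {
        if (overlapRate(sets[[i]], sets[[j]]) > threshold)
          edges <- c(edges, i, j)
      }
    }
  }
  igraph::make_graph(edges = edges, n = n, directed = FALSE)
}

#' Merge highly overlapping clusters into predicted complexes
#'
#' Builds the overlap graph at `threshold` and enumerates its maximal
#' cliques (Bron-Kerbosch, via igraph); each clique is a set of clusters
#' that pairwise overlap strongly and is collapsed to the union of its
#' members' proteins. Cliques are processed in decreasing size, ties broken
#' lexicographically on the sorted member-cluster identities; each cluster
#' is consumed by the first processed clique containing it, so a cluster
#' sitting in several maximal cliques is merged exactly once. A clique
#' retaining fewer than two unconsumed clusters merges nothing; clusters
#' never consumed pass through unchanged. Merging is a single pass: the
#' merged complexes are not re-tested against each other.
#'
#' When no pair of clusters exceeds the threshold the function is the
#' identity (up to canonical ordering), and in all cases the union of
#' proteins over the output equals the union over the input.
#'
#' @param clusters list of preliminary clusters (character vectors).
#' @param threshold overlap-rate threshold (default 0.8).
#' @param detail logical; when `TRUE`, also return the provenance mapping.
#' @return List of predicted complexes (deduplicated, deterministic
#'   order); with `detail = TRUE`, a list with elements `complexes` and
#'   `assignment` (for each input cluster, the index of the output complex
#'   that absorbed it).
#' @examples
#' cl <- list(c("a", "b", "c", "d", "e"), c("a", "b", "c", "d", "f"),
#'            c("x", "y"))
#' mergeClusters(cl)  # olr = 16/25: below 0.8, nothing merges
#' @export
mergeClusters <- function(clusters, threshold = 0.8, detail = FALSE) {
  clusters <- lapply(clusters, function(x) sortIds(unique(as.character(x))))
  keys <- vapply(clusters, paste, character(1), collapse = "\r")
  if (anyDuplicated(keys)) {
    clusters <- clusters[!duplicated(keys)]
    keys <- keys[!duplicated(keys)]
  }
  n <- length(clusters)
  g <- buildOverlapGraph(clusters, threshold)
  cliques <- igraph::max_cliques(g, min = 2)
  cliques <- lapply(cliques, function(q) sort(as.integer(q)))
  if (length(cliques) > 1) {
    cliqueKey <- vapply(cliques, function(q)
      paste(sortIds(keys[q]), collapse = "\n"), character(1))
    ord <- order(-lengths(cliques), cliqueKey, method = "radix")
    cliques <- cliques[ord]
  }
  consumed <- rep(FALSE, n)
  assignment <- integer(n)
  out <- list()
  for (q in cliques) {
    remaining <- q[!consumed[q]]
    if (length(remaining) < 2) next
    merged <- sortIds(unique(unlist(clusters[remaining], use.names = FALSE)))
    out[[length(out) + 1L]] <- merged
    consumed[remaining] <- TRUE
    assignment[remaining] <- length(out)
  }
  for (i in which(!consumed)) {
    out[[length(out) + 1L]] <- clusters[[i]]
    assignment[i] <- length(out)
  }
  outKeys <- vapply(out, paste, character(1), collapse = "\r")
  dedupMap <- match(outKeys, outKeys[!duplicated(outKeys)])
  out <- out[!duplicated(outKeys)]
  ord <- order(vapply(out, paste, character(1), collapse = "\r"),
               method = "radix")
  out <- out[ord]
  finalPos <- order(ord)            # old dedup index -> final position
  assignment <- finalPos[dedupMap[assignment]]
  if (detail) list(complexes = out, assignment = assignment) else out
}
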