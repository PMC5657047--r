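#' Read a scored PPI edge list
#'
#' Reads a tab-separated edge list (`protein_A<TAB>protein_B[<TAB>score]`,
#' `#` comment lines ignored) into an undirected, deduplicated
#' [PPINetwork-class]. Self-interactions are dropped with a warning count.
#'
#' When `minScore` is given, an edge is kept only if its score is
#' strictly greater than `minScore` — the convention of confidence-scored
#' interactomes such as the socio-affinity-scored Gavin data, which are
#' used "above" a cutoff. Edge records lacking a score while `minScore` is
#' set are a fatal input error. Leave `minScore = NULL` for pre-filtered
#' inputs (Krogan core, Collins high-confidence).
#'
#' @param path path to the edge-list file.
#' @param minScore optional numeric; keep edges with `score > minScore`.
#' @return A [PPINetwork-class].
#' @examples
#' tf <- tempfile()
#' writeLines(c("A\tB\t6.1", "B\tA\t6.1", "A\tC\t4.0"), tf)
#' readEdgeList(tf, minScore = 5)  # one edge A-B
#' @export
readEdgeList <- function(path, minScore = NULL) {
  lines <- tryCatch(suppressWarnings(readLines(path, warn = FALSE)),
                    error = function(e) stop("cannot read edge list '", path,
                                             "': ", conditionMessage(e),
                                             call. = FALSE))
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  if (length(lines) == 0)
    stop("edge list '", path, "' contains no records", call. = FALSE)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  ncol <- lengths(parts)
  if (any(ncol < 2))
    stop("edge list '", path, "' has lines with fewer than 2 fields",
         call. = FALSE)
  a <- trimws(vapply(parts, `[[`, character(1), 1))
  b <- trimws(vapply(parts, `[[`, character(1), 2))
  s <- rep(NA_real_, length(parts))
  has3 <- ncol >= 3
  if (any(has3))
    s[has3] <- suppressWarnings(
      as.numeric(vapply(parts[has3], `[[`, character(1), 3)))
  if (any(!nzchar(a) | !nzchar(b)))
    stop("edge list '", path, "' has empty protein IDs", call. = FALSE)
  loops <- sum(a == b)
  if (!is.null(minScore)) {
    stopifnot(is.numeric(minScore), length(minScore) == 1)
    if (any(is.na(s[a != b])))
      stop("minScore filtering requested but some edges carry no score",
           call. = FALSE)
    keep <- a == b | s > minScore   # loops handled (and counted) below
    a <- a[keep]; b <- b[keep]; s <- s[keep]
  }
  net <- PPINetwork(protein1 = a, protein2 = b, score = s)
  if (numInteractions(net) == 0)
    stop("no edges remain after filtering '", path, "'", call. = FALSE)
  if (loops > 0)
    warning(loops, " self-interaction(s) dropped", call. = FALSE)
  net
}

#' Induced subnetwork on a protein group
#'
#' Restricts a PPI network to one protein group: the node set is the
#' intersection of the group with the network's proteins, the edge set is
#' every network edge with both endpoints inside it. Group members absent
#' from the network are dropped; members present but unconnected stay as
#' isolated nodes. An empty result is valid (the caller skips it).
#'
#' @param net a [PPINetwork-class].
#' @param members character vector of protein IDs (one group).
#' @return A [PPINetwork-class] on `intersect(members, proteins(net))`.
#' @examples
#' net <- PPINetwork(c("A", "B"), c("B", "D"))
#' inducedSubnetwork(net, c("A", "B", "C"))  # nodes {A,B}, edge A-B
#' @export
inducedSubnetwork <- function(net, members) {
  stopifnot(is(net, "PPINetwork"))
  members <- unique(as.character(members))
  keepNodes <- intersect(members, net@nodes)
  e <- net@interactions
  keep <- e$protein1 %in% keepNodes & e$protein2 %in% keepNodes
  PPINetwork(protein1 = e$protein1[keep], protein2 = e$protein2[keep],
             score = e$score[keep], nodes = keepNodes)
}

#' Write a PPI network as a tab-separated edge list
#'
#' Inverse of [readEdgeList()]: writes `protein1<TAB>protein2` lines, with
#' a third score column when any edge carries a score. Isolated nodes are
#' not representable in the edge-list dialect and are not written.
#'
#' @param net a [PPINetwork-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeEdgeList <- function(net, path) {
  stopifnot(is(net, "PPINetwork"))
  e <- net@interactions
  if (all(is.na(e$score))) {
    lines <- paste(e$protein1, e$protein2, sep = "\t")
  } else {
    lines <- paste(e$protein1, e$protein2, e$score, sep = "\t")
  }
  writeLines(lines, path)
  invisible(path)
}
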