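#' Build the column-stochastic transition matrix of a network
#'
#' Binary adjacency (edge present / absent — edge confidences are not used
#' as weights) plus unit self-loops on the diagonal, then column
#' normalization. Self-loops damp the odd/even oscillations of the pure
#' random walk and guarantee strictly positive column sums.
#'
#' @param net a non-empty [PPINetwork-class].
#' @return A sparse column-stochastic `Matrix` (class `dgCMatrix`) with the
#'   node IDs as dimnames; every column sums to 1 within 1e-9.
#' @examples
#' buildTransitionMatrix(PPINetwork("A", "B"))  # 2x2, all entries 0.5
#' @export
buildTransitionMatrix <- function(net) {
  stopifnot(is(net, "PPINetwork"))
  ids <- net@nodes
  n <- length(ids)
  if (n == 0) stop("cannot build a transition matrix on an empty network",
                   call. = FALSE)
  e <- net@interactions
  i <- match(e$protein1, ids)
  j <- match(e$protein2, ids)
  a <- Matrix::sparseMatrix(i = c(i, j, seq_len(n)),
                            j = c(j, i, seq_len(n)),
                            x = 1, dims = c(n, n),
                            dimnames = list(ids, ids))
  .normalizeColumns(a)
}

.normalizeColumns <- function(m) {
  cs <- Matrix::colSums(m)
  out <- m %*% Matrix::Diagonal(x = 1 / cs)
  dimnames(out) <- dimnames(m)   # %*% drops the column names
  out
}

#' MCL expansion step
#'
#' Raises a column-stochastic matrix to an integer power under ordinary
#' matrix multiplication; the product of column-stochastic matrices is
#' column-stochastic, so the property is preserved.
#'
#' @param m column-stochastic sparse or dense `Matrix`.
#' @param power integer >= 2.
#' @return The expanded matrix.
#' @export
mclExpand <- function(m, power = 2L) {
  power <- as.integer(power)
  stopifnot(power >= 1L)
  out <- m
  for (k in seq_len(power - 1L)) out <- out %*% m
  out
}

#' MCL inflation step
#'
#' Each entry is raised elementwise (Hadamard power) to `inflation`,
#' entries below `prune` are zeroed, and columns are renormalized.
#' Inflation sharpens the walk: strong within-cluster transitions are
#' boosted at the expense of weak between-cluster ones. A column emptied
#' by pruning gets its self-loop restored at the diagonal before
#' renormalization, so the result is always column-stochastic.
#'
#' @param m column-stochastic `Matrix`.
#' @param inflation numeric > 1.
#' @param prune non-negative numeric; entries `< prune` are dropped.
#' @return The inflated, pruned, renormalized matrix.
#' @examples
#' m <- Matrix::Matrix(c(0.8, 0.2, 0.2, 0.8), 2, sparse = TRUE)
#' mclInflate(m, 2)  # columns become (0.9411765, 0.0588235) up to symmetry
#' @export
mclInflate <- function(m, inflation = 2.0, prune = 1e-5) {
  stopifnot(inflation > 1, prune >= 0)
  dn <- dimnames(m)
  m <- as(as(m, "generalMatrix"), "CsparseMatrix")
  m@x <- m@x ^ inflation
  m@x[m@x < prune] <- 0
  m <- Matrix::drop0(m)
  cs <- Matrix::colSums(m)
  dead <- which(cs == 0)
  if (length(dead) > 0) {
    m[cbind(dead, dead)] <- 1
  }
  dimnames(m) <- dn
  .normalizeColumns(m)
}

#' Run Markov clustering on a network
#'
#' Alternates expansion ([mclExpand()]) and inflation ([mclInflate()]) on
#' the network's transition matrix until the largest elementwise change
#' between successive post-inflation matrices drops below
#' `convergenceTol`, or `maxIterations` is reached (a warning, not an
#' error: extraction proceeds on the last matrix).
#'
#' Clusters are read off the attractor structure of the converged matrix:
#' attractors are the rows with a positive diagonal entry; attractors that
#' give each other positive mass form one attractor system (connected
#' components of the attractor-attractor support); every node joins the
#' cluster of each system containing an attractor whose row gives it
#' positive mass. Nodes may therefore sit in several clusters when they
#' are attracted by several systems; identical clusters are deduplicated.
#' A node left unattracted (possible only without convergence) becomes a
#' singleton cluster so that every input node is covered.
#'
#' Because the transition matrix of a disconnected network is block
#' diagonal and stays so under expansion and inflation, no cluster ever
#' spans two connected components.
#'
#' @param net a non-empty [PPINetwork-class].
#' @param params an [MCLParams-class].
#' @return List of clusters (character vectors of protein IDs), each
#'   member-sorted, the list itself in deterministic C-locale order.
#' @examples
#' net <- PPINetwork(c("A", "B", "C"), c("B", "C", "A"))  # triangle
#' runMCL(net)
#' @export
runMCL <- function(net, params = MCLParams()) {
  stopifnot(is(net, "PPINetwork"), is(params, "MCLParams"))
  m <- buildTransitionMatrix(net)
  converged <- FALSE
  for (iter in seq_len(params@maxIterations)) {
    m2 <- mclInflate(mclExpand(m, params@expansion),
                     params@inflation, params@pruneThreshold)
    delta <- max(abs(m2 - m))
    m <- m2
    if (delta < params@convergenceTol) { converged <- TRUE; break }
  }
  if (!converged)
    warning("MCL did not converge within ", params@maxIterations,
            " iterations; extracting clusters from the last matrix",
            call. = FALSE)
  .extractClusters(m)
}

# Attractor-based cluster extraction from a (near-)converged MCL matrix.
.extractClusters <- function(m) {
  ids <- rownames(m)
  n <- nrow(m)
  d <- Matrix::diag(m)
  att <- which(d > 0)
  clusters <- list()
  assigned <- rep(FALSE, n)
  if (length(att) > 0) {
    sub <- m[att, att, drop = FALSE]
    supp <- as(( sub > 0) | Matrix::t(sub > 0), "matrix")
    mode(supp) <- "numeric"
    g <- igraph::graph_from_adjacency_matrix(supp, mode = "undirected",
                                             diag = FALSE)
    sys <- igraph::components(g)$membership
    hits <- as(as(m[att, , drop = FALSE], "generalMatrix"), "TsparseMatrix")
    pos <- hits@x > 0
    node <- hits@j[pos] + 1L
    system <- sys[hits@i[pos] + 1L]
    assigned[unique(node)] <- TRUE
    clusters <- lapply(split(node, system),
                       function(ix) sortIds(ids[unique(ix)]))
  }
  if (any(!assigned))
    clusters <- c(clusters, lapply(which(!assigned), function(i) ids[i]))
  clusters <- unname(clusters)
  keys <- vapply(clusters, paste, character(1), collapse = "\r")
  clusters <- clusters[!duplicated(keys)]
  clusters[order(vapply(clusters, paste, character(1), collapse = "\r"),
                 method = "radix")]
}
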