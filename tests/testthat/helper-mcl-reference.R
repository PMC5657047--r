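# Independent reference Markov clustering, used as the oracle for the
# package's sparse implementation. Deliberately a separate code path:
# dense base-R matrices, sweep() normalization, and a hand-rolled BFS for
# attractor systems (no Matrix, no igraph).

referenceMCL <- function(net, expansion = 2, inflation = 2,
                         prune = 1e-5, maxIter = 100, tol = 1e-6) {
  ids <- proteins(net)
  n <- length(ids)
  A <- matrix(0, n, n, dimnames = list(ids, ids))
  e <- interactions(net)
  for (r in seq_len(nrow(e))) {
    i <- match(e$protein1[r], ids)
    j <- match(e$protein2[r], ids)
    A[i, j] <- 1
    A[j, i] <- 1
  }
  diag(A) <- 1
  M <- sweep(A, 2, colSums(A), "/")
  for (it in seq_len(maxIter)) {
    E <- M
    for (k in seq_len(expansion - 1)) E <- E %*% M
    Infl <- E ^ inflation
    Infl[Infl < prune] <- 0
    cs <- colSums(Infl)
    dead <- which(cs == 0)
    if (length(dead) > 0) {
      Infl[cbind(dead, dead)] <- 1
      cs <- colSums(Infl)
    }
    M2 <- sweep(Infl, 2, cs, "/")
    delta <- max(abs(M2 - M))
    M <- M2
    if (delta < tol) break
  }
  referenceExtract(M, ids)
}

referenceExtract <- function(M, ids) {
  n <- nrow(M)
  att <- which(diag(M) > 0)
  clusters <- list()
  assigned <- rep(FALSE, n)
  if (length(att) > 0) {
    sub <- M[att, att, drop = FALSE]
    adj <- (sub > 0) | t(sub > 0)
    comp <- rep(0L, length(att))
    cur <- 0L
    for (s in seq_along(att)) {
      if (comp[s] > 0) next
      cur <- cur + 1L
      queue <- s
      comp[s] <- cur
      while (length(queue) > 0) {
        v <- queue[[1]]; queue <- queue[-1]
        nb <- which(adj[v, ] & comp == 0L)
        comp[nb] <- cur
        queue <- c(queue, nb)
      }
    }
    for (sys in seq_len(cur)) {
      rows <- att[comp == sys]
      memb <- which(colSums(M[rows, , drop = FALSE] > 0) > 0)
      assigned[memb] <- TRUE
      clusters[[length(clusters) + 1L]] <- sort(ids[memb], method = "radix")
    }
  }
  for (i in which(!assigned)) clusters[[length(clusters) + 1L]] <- ids[i]
  keys <- vapply(clusters, paste, character(1), collapse = "\r")
  clusters <- clusters[!duplicated(keys)]
  clusters[order(vapply(clusters, paste, character(1), collapse = "\r"),
                 method = "radix")]
}
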