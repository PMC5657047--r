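# Small builders used across the suite. Everything is generated in code;
# no fixture files.

# Network from two endpoint vectors.
makeNet <- function(a, b, score = NA_real_, nodes = character(0)) {
  PPINetwork(a, b, score = score, nodes = nodes)
}

# Erdos-Renyi-style random graph on n labelled nodes; optionally forced
# connected by overlaying a random spanning tree.
randomGraph <- function(n, p, connected = FALSE) {
  ids <- sprintf("n%02d", seq_len(n))
  pairs <- t(combn(n, 2))
  hit <- runif(nrow(pairs)) < p
  a <- ids[pairs[hit, 1]]
  b <- ids[pairs[hit, 2]]
  if (connected && n >= 2) {
    perm <- sample(ids)
    parent <- vapply(2:n, function(k) perm[sample.int(k - 1, 1)],
                     character(1))
    a <- c(a, parent)
    b <- c(b, perm[2:n])
  }
  makeNet(a, b, nodes = ids)
}

# Random cluster collection over a shared protein universe, with a few
# perturbed near-duplicates so that overlap-graph edges actually occur.
randomClusterSet <- function(nClusters = 10, universe = 30) {
  ids <- sprintf("p%03d", seq_len(universe))
  base <- lapply(seq_len(nClusters), function(i)
    sample(ids, sample(2:8, 1)))
  extra <- lapply(sample(seq_len(nClusters), ceiling(nClusters / 3)),
                  function(i) {
      cl <- base[[i]]
      if (length(cl) >= 5 && runif(1) < 0.8) {
        # drop one member: olr = (s-1)^2 / (s(s-1)) = (s-1)/s > 0.8 for s >= 5
        sample(cl, length(cl) - 1)
      } else {
        unique(c(cl, sample(ids, 1)))
      }
    })
  cl <- c(base, extra)
  keys <- vapply(lapply(cl, sort), paste, character(1), collapse = "\r")
  cl[!duplicated(keys)]
}

canonical <- function(clusters) {
  clusters <- lapply(clusters, function(x) sort(unique(x), method = "radix"))
  keys <- vapply(clusters, paste, character(1), collapse = "\r")
  sort(keys, method = "radix")
}

# graph connectivity check done with plain BFS (no igraph), for properties
# about components.
componentsOf <- function(net) {
  ids <- proteins(net)
  e <- interactions(net)
  adj <- lapply(setNames(vector("list", length(ids)), ids), function(x) character(0))
  for (r in seq_len(nrow(e))) {
    adj[[e$protein1[r]]] <- c(adj[[e$protein1[r]]], e$protein2[r])
    adj[[e$protein2[r]]] <- c(adj[[e$protein2[r]]], e$protein1[r])
  }
  comp <- setNames(rep(NA_integer_, length(ids)), ids)
  cur <- 0L
  for (s in ids) {
    if (!is.na(comp[[s]])) next
    cur <- cur + 1L
    queue <- s
    comp[[s]] <- cur
    while (length(queue) > 0) {
      v <- queue[[1]]; queue <- queue[-1]
      for (w in adj[[v]]) if (is.na(comp[[w]])) { comp[[w]] <- cur; queue <- c(queue, w) }
    }
  }
  comp
}
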