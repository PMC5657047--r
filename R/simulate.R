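#' Simulate a PPI network with planted complexes and annotations
#'
#' Generates the three inputs the pipeline consumes — a PPI edge list, a
#' hierarchical annotation map, and the ground-truth complex catalogue —
#' with the statistical structure the method assumes: complexes are dense
#' connected subgraphs whose members share one specific (depth-6)
#' functional term.
#'
#' Each planted complex gets a unique depth-6 term of two-digit fields.
#' The first `sharedPrefixDepth` fields are identical across all
#' complexes, so complexes become distinguishable by annotation only at
#' level `sharedPrefixDepth + 1`; with the default 0 every complex is
#' separable from level 1 on. Members receive their complex's term unless
#' dropped at `annotationDropout`, plus one extra random term with
#' probability `multiAnnotationRate` (proteins are multifunctional).
#' Within-complex edges are sampled independently at `pIn` and a uniform
#' random spanning tree is overlaid, so every planted complex is connected
#' (a disconnected planted complex would be unrecoverable by any graph
#' clustering and only make recovery tests flaky); size-2 complexes always
#' get their single edge. Background noise edges are drawn uniformly
#' without replacement from the protein pairs not sharing a complex.
#' Bystander proteins (annotated, in no complex) receive one random term
#' each and may be touched by noise edges.
#'
#' The default size distribution imitates the small/large composition of
#' the CYC2008 catalogue: mass proportional to 156 (size 2), 66 (size 3)
#' and 127 spread evenly over sizes 4-10, i.e. about 64% small complexes.
#'
#' Identical parameters and seed give identical output. The caller's RNG
#' state is restored on exit.
#'
#' @param nComplexes number of planted complexes (>= 1).
#' @param sizeWeights positive weights over complex sizes 2..10.
#' @param pIn within-complex edge probability (default 0.9).
#' @param nNoiseEdges background edge count (default: twice the number of
#'   planted proteins).
#' @param bystanderFraction annotated complex-free proteins, as a fraction
#'   of planted proteins (default 0.2).
#' @param multiAnnotationRate probability a member carries one extra
#'   random term (default 0.1).
#' @param annotationDropout probability a member lacks its complex's term
#'   (default 0).
#' @param sharedPrefixDepth number of leading term fields shared by all
#'   complexes (default 0).
#' @param seed required integer RNG seed.
#' @return List with elements `network` ([PPINetwork-class], nodes include
#'   isolated proteins), `annotations` ([FunCatAnnotation-class]) and
#'   `catalogue` ([ComplexSet-class] labelled `"planted"`).
#' @examples
#' sim <- simulateComplexData(nComplexes = 3, seed = 1)
#' sim$catalogue
#' @export
simulateComplexData <- function(nComplexes,
                                sizeWeights = c(156, 66, rep(127 / 7, 7)),
                                pIn = 0.9,
                                nNoiseEdges = NULL,
                                bystanderFraction = 0.2,
                                multiAnnotationRate = 0.1,
                                annotationDropout = 0,
                                sharedPrefixDepth = 0,
                                seed) {
  stopifnot(nComplexes >= 1, length(sizeWeights) == 9, all(sizeWeights >= 0),
            pIn >= 0, pIn <= 1,
            bystanderFraction >= 0,
            multiAnnotationRate >= 0, multiAnnotationRate <= 1,
            annotationDropout >= 0, annotationDropout <= 1,
            sharedPrefixDepth >= 0, sharedPrefixDepth <= 5)
  if (missing(seed)) stop("a seed is required for reproducibility",
                          call. = FALSE)
  if (nComplexes > 100^(6 - sharedPrefixDepth))
    stop("too many complexes for unique terms at this sharedPrefixDepth",
         call. = FALSE)
  if (exists(".Random.seed", envir = globalenv())) {
    oldSeed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", oldSeed, envir = globalenv()))
  }
  set.seed(seed)

  sizes <- sample(2:10, nComplexes, replace = TRUE, prob = sizeWeights)
  complexMembers <- lapply(seq_len(nComplexes), function(i)
    sprintf("CPX%04d_P%02d", i, seq_len(sizes[i])))
  terms <- vapply(seq_len(nComplexes) - 1L, .complexTerm, character(1),
                  sharedPrefixDepth)
  planted <- unlist(complexMembers, use.names = FALSE)

  # within-complex edges: Bernoulli(pIn) over pairs + random spanning tree
  edgeA <- character(0); edgeB <- character(0)
  for (m in complexMembers) {
    s <- length(m)
    pairs <- which(upper.tri(matrix(0, s, s)), arr.ind = TRUE)
    hit <- stats::runif(nrow(pairs)) < pIn
    a <- m[pairs[hit, 1]]; b <- m[pairs[hit, 2]]
    perm <- sample(m)
    if (s >= 2) {
      parent <- vapply(2:s, function(k)
        perm[sample.int(k - 1, 1)], character(1))
      a <- c(a, parent); b <- c(b, perm[2:s])
    }
    edgeA <- c(edgeA, a); edgeB <- c(edgeB, b)
  }

  nBystanders <- round(bystanderFraction * length(planted))
  bystanders <- if (nBystanders > 0) sprintf("BYS%04d", seq_len(nBystanders))
                else character(0)
  allProteins <- c(planted, bystanders)

  if (is.null(nNoiseEdges)) nNoiseEdges <- 2L * length(planted)
  if (nNoiseEdges > 0) {
    np <- length(allProteins)
    pairIdx <- utils::combn(np, 2)
    complexOf <- c(rep(seq_len(nComplexes), sizes),
                   rep(NA_integer_, nBystanders))
    sameComplex <- !is.na(complexOf[pairIdx[1, ]]) &
      complexOf[pairIdx[1, ]] == complexOf[pairIdx[2, ]]
    sameComplex[is.na(sameComplex)] <- FALSE
    candidates <- which(!sameComplex)
    if (nNoiseEdges > length(candidates))
      stop("nNoiseEdges exceeds the number of available non-complex pairs",
           call. = FALSE)
    pick <- sample(candidates, nNoiseEdges)
    edgeA <- c(edgeA, allProteins[pairIdx[1, pick]])
    edgeB <- c(edgeB, allProteins[pairIdx[2, pick]])
  }

  ann <- vector("list", length(allProteins))
  names(ann) <- allProteins
  k <- 0L
  for (i in seq_len(nComplexes)) {
    for (p in complexMembers[[i]]) {
      k <- k + 1L
      t <- character(0)
      if (annotationDropout == 0 || stats::runif(1) >= annotationDropout)
        t <- terms[i]
      if (stats::runif(1) < multiAnnotationRate)
        t <- c(t, .randomTerm())
      ann[[k]] <- t
    }
  }
  for (p in bystanders) {
    k <- k + 1L
    ann[[k]] <- .randomTerm()
  }
  ann <- ann[lengths(ann) > 0]

  list(network = PPINetwork(edgeA, edgeB, nodes = allProteins),
       annotations = FunCatAnnotation(ann),
       catalogue = ComplexSet(complexMembers, label = "planted"))
}

# Unique depth-6 term for planted complex `idx` (0-based): the first
# `prefixDepth` fields are the shared "01" prefix; the remaining fields
# carry the base-100 digits of idx, least significant first, so complexes
# differ already at field prefixDepth + 1.
.complexTerm <- function(idx, prefixDepth = 0) {
  nEnc <- 6 - prefixDepth
  digits <- integer(nEnc)
  for (k in seq_len(nEnc)) {
    digits[k] <- idx %% 100L
    idx <- idx %/% 100L
  }
  paste(c(rep("01", prefixDepth), sprintf("%02d", digits)), collapse = ".")
}

# Random depth-6 term; fields 1..27 mimic FunCat's main categories and can
# never collide with a planted-complex term (those always contain a "00"
# field at realistic complex counts).
.randomTerm <- function() {
  paste(sprintf("%02d", sample.int(27, 6, replace = TRUE)), collapse = ".")
}

#' Write the three simulated inputs to a directory
#'
#' Writes `ppi.tsv`, `annotations.tsv` and `complexes.tsv` in the dialects
#' read by [readEdgeList()], [readAnnotations()] and [readComplexes()].
#'
#' @param sim result of [simulateComplexData()].
#' @param dir output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
writeSimulatedData <- function(sim, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  writeEdgeList(sim$network, file.path(dir, "ppi.tsv"))
  ann <- sim$annotations@annotations
  writeLines(paste(names(ann),
                   vapply(ann, paste, character(1), collapse = ","),
                   sep = "\t"),
             file.path(dir, "annotations.tsv"))
  writeComplexes(sim$catalogue, file.path(dir, "complexes.tsv"))
  invisible(dir)
}
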