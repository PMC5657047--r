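test_that("transition matrix is binary adjacency + self-loops, column-normalized", {
  m <- buildTransitionMatrix(makeNet("A", "B"))
  expect_equal(as.matrix(m), matrix(0.5, 2, 2, dimnames = list(c("A", "B"),
                                                               c("A", "B"))))
  # isolated node
  m1 <- buildTransitionMatrix(PPINetwork(nodes = "X"))
  expect_equal(as.matrix(m1), matrix(1, 1, 1, dimnames = list("X", "X")))
  # triangle: every column is (1/3, 1/3, 1/3)
  tri <- buildTransitionMatrix(makeNet(c("A", "B", "C"), c("B", "C", "A")))
  expect_equal(unname(as.matrix(tri)), matrix(1 / 3, 3, 3))
  # scores must not be used as weights
  w <- buildTransitionMatrix(makeNet(c("A", "A"), c("B", "C"),
                                     score = c(100, 0.1)))
  expect_equal(Matrix::colSums(w), c(A = 1, B = 1, C = 1))
  expect_equal(w["B", "A"], w["C", "A"])
  expect_error(buildTransitionMatrix(PPINetwork()), "empty network")
})

test_that("expansion is the ordinary matrix power and keeps columns stochastic", {
  id <- Matrix::Diagonal(3)
  expect_equal(as.matrix(mclExpand(id, 2)), diag(3))
  half <- Matrix::Matrix(0.5, 2, 2, sparse = TRUE)
  expect_equal(as.matrix(mclExpand(half, 2)), matrix(0.5, 2, 2))
  set.seed(5)
  raw <- matrix(runif(25), 5, 5)
  m <- Matrix::Matrix(sweep(raw, 2, colSums(raw), "/"), sparse = TRUE)
  e3 <- mclExpand(m, 3)
  # dense brute-force product oracle
  dense <- as.matrix(m)
  expect_equal(as.matrix(e3), dense %*% dense %*% dense, tolerance = 1e-12)
  expect_equal(Matrix::colSums(e3), rep(1, 5), tolerance = 1e-9)
})

test_that("inflation renormalizes the Hadamard power and handles edge cases", {
  col <- function(x) Matrix::Matrix(matrix(x, ncol = 1), sparse = TRUE)
  expect_equal(as.numeric(mclInflate(col(c(0.5, 0.5)), 2)), c(0.5, 0.5))
  # 0.8^2/(0.8^2+0.2^2) = 0.64/0.68, 0.04/0.68
  expect_equal(as.numeric(mclInflate(col(c(0.8, 0.2)), 2)),
               c(0.64, 0.04) / 0.68, tolerance = 1e-12)
  expect_equal(as.numeric(mclInflate(col(c(1, 0)), 7.5)), c(1, 0))
  # pruning can empty a column; the self-loop is restored at the diagonal
  m <- Matrix::Matrix(c(0.3, 0.7, 0.6, 0.4), 2, sparse = TRUE)
  out <- mclInflate(m, 2, prune = 0.95)   # all inflated entries pruned away
  expect_equal(unname(as.matrix(out)), diag(2))
  expect_equal(Matrix::colSums(out), c(1, 1))
  expect_error(mclInflate(col(c(0.5, 0.5)), 1), "inflation > 1")
})

test_that("MCL resolves canonical small graphs", {
  # a single edge is already a fixed point with both diagonals positive
  expect_identical(runMCL(makeNet("A", "B")), list(c("A", "B")))
  # two disjoint triangles -> exactly the two triangles
  net <- makeNet(c("A", "B", "C", "X", "Y", "Z"),
                 c("B", "C", "A", "Y", "Z", "X"))
  expect_identical(runMCL(net),
                   list(c("A", "B", "C"), c("X", "Y", "Z")))
  # barbell: two 4-cliques joined by one edge split back into the cliques
  k1 <- c("a1", "a2", "a3", "a4")
  k2 <- c("b1", "b2", "b3", "b4")
  cl <- function(v) {
    p <- t(combn(v, 2))
    list(a = p[, 1], b = p[, 2])
  }
  e1 <- cl(k1); e2 <- cl(k2)
  barbell <- makeNet(c(e1$a, e2$a, "a1"), c(e1$b, e2$b, "b1"))
  got <- runMCL(barbell)
  expect_identical(got, referenceMCL(barbell))
  expect_identical(canonical(got), canonical(list(k1, k2)))
})

test_that("MCL matches the dense reference on random connected graphs", {
  set.seed(41)
  for (rep in 1:15) {
    net <- randomGraph(sample(4:15, 1), runif(1, 0.2, 0.6), connected = TRUE)
    p <- MCLParams(inflation = sample(c(1.6, 2, 2.5), 1))
    got <- runMCL(net, p)
    ref <- referenceMCL(net, inflation = p@inflation)
    expect_identical(canonical(got), canonical(ref))
  }
})

test_that("clusters never span components and cover every node", {
  set.seed(43)
  for (rep in 1:30) {
    net <- randomGraph(sample(3:18, 1), runif(1, 0.05, 0.5))
    comp <- componentsOf(net)
    cl <- runMCL(net)
    for (c in cl) expect_length(unique(comp[c]), 1)
    expect_setequal(unique(unlist(cl)), proteins(net))
  }
})

test_that("non-convergence warns but still extracts clusters", {
  # a path graph is far from its MCL fixed point after a single round
  net <- makeNet(c("A", "B", "C", "D"), c("B", "C", "D", "E"))
  expect_warning(cl <- runMCL(net, MCLParams(maxIterations = 1L,
                                             convergenceTol = 1e-15)),
                 "did not converge")
  expect_true(length(cl) >= 1)
  expect_setequal(unique(unlist(cl)), proteins(net))
})
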