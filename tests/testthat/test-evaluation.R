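test_that("complex catalogues parse whitespace dialects and drop undersized entries", {
  tf <- withr::local_tempfile()
  writeLines(c("# benchmark",
               "A\tB\tC",
               "D E",
               "LONE",           # size 1: dropped on load
               "F\tF\tG"), tf)   # duplicate member collapses to size 2
  cat <- readComplexes(tf, label = "bench")
  expect_identical(length(cat), 3L)
  expect_identical(catalogueLabel(cat), "bench")
  expect_identical(sort(complexSizes(cat)), c(2L, 2L, 3L))
  tf2 <- withr::local_tempfile()
  writeComplexes(cat, tf2)
  expect_identical(complexes(readComplexes(tf2)), complexes(cat))
})

test_that("overlap degree supports both the affinity and jaccard forms", {
  expect_identical(overlapDegree(c("a", "b"), c("a", "b")), 1)
  expect_equal(overlapDegree(c("a", "b", "c"), c("b", "c", "d", "e")), 4 / 12)
  expect_identical(overlapDegree(c("a", "b"), c("x", "y")), 0)
  expect_equal(overlapDegree(c("a", "b", "c"), c("b", "c", "d", "e"),
                             method = "jaccard"), 2 / 5)
  expect_error(overlapDegree(character(0), "a"), "empty")
})

test_that("perfect and disjoint catalogues give the boundary metrics", {
  pc <- ComplexSet(list(c("a", "b"), c("c", "d", "e")), "predicted")
  perfect <- matchAndScore(pc, pc)
  expect_equal(perfect$recall, 1)
  expect_equal(perfect$precision, 1)
  expect_equal(perfect$fMeasure, 1)
  bc <- ComplexSet(list(c("x", "y"), c("z", "w")), "bench")
  zero <- matchAndScore(pc, bc)
  expect_equal(zero[, c("recall", "precision", "fMeasure")],
               data.frame(recall = 0, precision = 0, fMeasure = 0))
})

test_that("matching at the threshold is inclusive (w >= 0.2 counts)", {
  # |pc n bc| = 2, |pc| = 4, |bc| = 5 -> w = 4/20 = 0.2 exactly
  pc <- ComplexSet(list(c("a", "b", "x", "y")), "predicted")
  bc <- ComplexSet(list(c("a", "b", "p", "q", "r")), "bench")
  expect_equal(overlapDegree(pc[[1]], bc[[1]]), 0.2)
  r <- matchAndScore(pc, bc, wThreshold = 0.2)
  expect_identical(r$mBC, 1L)
  expect_identical(r$mPC, 1L)
})

test_that("size partition splits at the 3/4 boundary, exactly and disjointly", {
  cat <- ComplexSet(list(c("a", "b"), c("a", "b", "c"),
                         c("a", "b", "c", "d"),
                         sprintf("q%d", 1:7)), "demo")
  parts <- sizePartition(cat)
  expect_identical(length(parts$small), 2L)
  expect_identical(length(parts$large), 2L)
  expect_identical(length(parts$small) + length(parts$large), length(cat))
  sm <- complexSizes(parts$small); lg <- complexSizes(parts$large)
  expect_true(all(sm <= 3) && all(lg >= 4))
})

test_that("stratified report flags empty strata instead of zeroing them", {
  pc <- ComplexSet(list(c("a", "b")), "predicted")           # small only
  bc <- ComplexSet(list(c("a", "b"), c("p", "q", "r", "s")), "bench")
  rep <- evaluateComplexes(pc, bc)
  expect_identical(rep$stratum, c("small", "large", "total"))
  large <- rep[rep$stratum == "large", ]
  expect_false(large$defined)
  expect_true(is.na(large$recall))
  small <- rep[rep$stratum == "small", ]
  expect_true(small$defined)
  expect_equal(small$recall, 1)
  # total uses unrestricted sets: 1 of 2 benchmarks matched
  expect_equal(rep[rep$stratum == "total", "recall"], 0.5)
})

test_that("stratification restricts both sides of the match", {
  # a large prediction overlapping a small benchmark must not count in
  # the small column
  pc <- ComplexSet(list(c("a", "b", "c", "d", "e")), "predicted")
  bc <- ComplexSet(list(c("a", "b")), "bench")
  rep <- evaluateComplexes(pc, bc)
  expect_false(rep[rep$stratum == "small", "defined"])    # no small PCs
  expect_false(rep[rep$stratum == "large", "defined"])    # no large BCs
  # but the total row sees the match: w = 4/10 = 0.4 >= 0.2
  expect_equal(rep[rep$stratum == "total", "recall"], 1)
})

test_that("reported metrics agree with brute-force matching on random catalogues", {
  set.seed(71)
  ids <- sprintf("y%03d", 1:40)
  for (rep in 1:30) {
    pc <- ComplexSet(lapply(1:sample(3:6, 1), function(i)
      sample(ids, sample(2:8, 1))), "predicted")
    bc <- ComplexSet(lapply(1:sample(3:6, 1), function(i)
      sample(ids, sample(2:8, 1))), "bench")
    got <- matchAndScore(pc, bc)
    # independent set arithmetic
    w <- outer(seq_len(length(pc)), seq_len(length(bc)),
               Vectorize(function(i, j) {
                 ov <- sum(pc[[i]] %in% bc[[j]])
                 ov^2 / (length(pc[[i]]) * length(bc[[j]]))
               }))
    expect_identical(got$mPC, sum(apply(w >= 0.2, 1, any)))
    expect_identical(got$mBC, sum(apply(w >= 0.2, 2, any)))
    r <- got$mBC / length(bc); p <- got$mPC / length(pc)
    expect_equal(got$recall, r)
    expect_equal(got$precision, p)
    f <- if (r + p == 0) 0 else 2 * r * p / (r + p)
    expect_equal(got$fMeasure, f)
    expect_true(got$fMeasure <= max(r, p) + 1e-12)
  }
})
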