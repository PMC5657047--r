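#' Read a complex catalogue file
#'
#' One complex per line, members separated by tabs or whitespace (the
#' MIPS / CYC2008 file convention); `#` comment lines ignored. Complexes
#' with fewer than two distinct members are dropped on load, per catalogue
#' convention.
#'
#' @param path path to the catalogue file.
#' @param label catalogue label (defaults to the file name).
#' @return A [ComplexSet-class].
#' @export
readComplexes <- function(path, label = basename(path)) {
  lines <- tryCatch(suppressWarnings(readLines(path, warn = FALSE)),
                    error = function(e) stop("cannot read complex file '",
                                             path, "': ", conditionMessage(e),
                                             call. = FALSE))
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  members <- lapply(strsplit(lines, "[\t[:space:]]+"),
                    function(x) unique(x[nzchar(x)]))
  members <- members[lengths(members) >= 2]
  if (length(members) == 0)
    stop("no complexes of size >= 2 in '", path, "'", call. = FALSE)
  ComplexSet(members, label = label)
}

#' Write a complex catalogue
#'
#' One complex per line, tab-separated member IDs — the same dialect
#' [readComplexes()] accepts, so catalogues round-trip.
#'
#' @param x a [ComplexSet-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeComplexes <- function(x, path) {
  stopifnot(is(x, "ComplexSet"))
  writeLines(vapply(x@members, paste, character(1), collapse = "\t"), path)
  invisible(path)
}

#' Overlap degree between a predicted and a benchmark complex
#'
#' The match score `w` used to declare that a prediction hits a benchmark
#' complex. The default (`"affinity"`) is the neighborhood-affinity form
#' `|pc n bc|^2 / (|pc| |bc|)` — the score conventionally paired with the
#' 0.2 match threshold in the complex-prediction literature, and the same
#' functional form as [overlapRate()]. `"jaccard"` is provided as an
#' alternative reading: `|pc n bc| / |pc u bc|`.
#'
#' @param pc,bc non-empty character vectors of protein IDs.
#' @param method `"affinity"` (default) or `"jaccard"`.
#' @return Numeric in `[0, 1]`.
#' @examples
#' overlapDegree(c("a", "b", "c"), c("b", "c", "d", "e"))  # 4/12
#' @export
overlapDegree <- function(pc, bc, method = c("affinity", "jaccard")) {
  method <- match.arg(method)
  pc <- unique(as.character(pc)); bc <- unique(as.character(bc))
  if (length(pc) == 0 || length(bc) == 0)
    stop("overlapDegree is undefined for empty complexes", call. = FALSE)
  ov <- length(intersect(pc, bc))
  if (method == "affinity") ov^2 / (length(pc) * length(bc))
  else ov / length(union(pc, bc))
}

#' Match predictions to a benchmark and score recall / precision / F
#'
#' A benchmark complex counts as matched when at least one prediction
#' reaches overlap degree `w >= wThreshold` against it (inclusive), and
#' symmetrically for predictions. Then
#' `recall = M_bc / |BC|`, `precision = M_pc / |PC|` and the F-measure is
#' their harmonic mean, `2 r p / (r + p)` (0 when both are 0).
#'
#' @param predicted,benchmark [ComplexSet-class] objects.
#' @param wThreshold numeric match threshold (default 0.2).
#' @param method overlap-degree form; see [overlapDegree()].
#' @return One-row data.frame with columns `nPredicted`, `nBenchmark`,
#'   `mPC`, `mBC`, `recall`, `precision`, `fMeasure`.
#' @examples
#' pc <- ComplexSet(list(c("a", "b"), c("c", "d", "e")), "predicted")
#' matchAndScore(pc, pc)  # perfect: all three metrics are 1
#' @export
matchAndScore <- function(predicted, benchmark, wThreshold = 0.2,
                          method = c("affinity", "jaccard")) {
  method <- match.arg(method)
  stopifnot(is(predicted, "ComplexSet"), is(benchmark, "ComplexSet"),
            is.numeric(wThreshold), length(wThreshold) == 1)
  pc <- predicted@members
  bc <- benchmark@members
  if (length(pc) == 0 || length(bc) == 0)
    stop("matchAndScore requires non-empty catalogues; use ",
         "evaluateComplexes() for stratified reports with empty strata",
         call. = FALSE)
  w <- matrix(0, nrow = length(pc), ncol = length(bc))
  for (i in seq_along(pc))
    for (j in seq_along(bc))
      w[i, j] <- overlapDegree(pc[[i]], bc[[j]], method)
  hit <- w >= wThreshold
  mPC <- sum(rowSums(hit) > 0)
  mBC <- sum(colSums(hit) > 0)
  recall <- mBC / length(bc)
  precision <- mPC / length(pc)
  f <- fMeasure(recall, precision)
  data.frame(nPredicted = length(pc), nBenchmark = length(bc),
             mPC = mPC, mBC = mBC, recall = recall, precision = precision,
             fMeasure = f)
}

#' F-measure: harmonic mean of recall and precision
#'
#' `2 r p / (r + p)`, defined as 0 when both arguments are 0.
#'
#' @param recall,precision numerics in `[0, 1]` (vectorized).
#' @return Numeric vector of F-measures.
#' @examples
#' fMeasure(0.5, 0.5)  # 0.5
#' @export
fMeasure <- function(recall, precision) {
  stopifnot(length(recall) == length(precision))
  ifelse(recall + precision == 0, 0,
         2 * recall * precision / (recall + precision))
}

#' Split a catalogue into small and large complexes
#'
#' Small complexes have two or three members; large complexes have at
#' least four. The split is exact and disjoint.
#'
#' @param x a [ComplexSet-class].
#' @return List with [ComplexSet-class] elements `small` and `large`
#'   (labels suffixed accordingly); either may be empty.
#' @examples
#' sizePartition(ComplexSet(list(c("a","b"), c("a","b","c","d")), "demo"))
#' @export
sizePartition <- function(x) {
  stopifnot(is(x, "ComplexSet"))
  sz <- vapply(x@members, length, integer(1))
  list(small = new("ComplexSet", members = x@members[sz <= 3],
                   label = paste0(x@label, ".small")),
       large = new("ComplexSet", members = x@members[sz >= 4],
                   label = paste0(x@label, ".large")))
}

#' Size-stratified evaluation report
#'
#' Computes [matchAndScore()] three times: on the full catalogues
#' (`total`), and on the small (size 2-3) and large (size >= 4) strata.
#' Stratification restricts *both* sides — a large prediction cannot match
#' a small benchmark complex in the small column — which is the symmetric
#' reading of size-wise reporting. A stratum empty on either side yields
#' `NA` metrics with `defined = FALSE`, never a silent zero.
#'
#' @param predicted,benchmark [ComplexSet-class] objects.
#' @param wThreshold match threshold on the overlap degree (default 0.2).
#' @param method overlap-degree form; see [overlapDegree()].
#' @return data.frame with one row per stratum (`small`, `large`,
#'   `total`) and columns `stratum`, `defined`, `nPredicted`,
#'   `nBenchmark`, `mPC`, `mBC`, `recall`, `precision`, `fMeasure`.
#' @export
evaluateComplexes <- function(predicted, benchmark, wThreshold = 0.2,
                              method = c("affinity", "jaccard")) {
  method <- match.arg(method)
  ps <- sizePartition(predicted)
  bs <- sizePartition(benchmark)
  strata <- list(small = list(ps$small, bs$small),
                 large = list(ps$large, bs$large),
                 total = list(predicted, benchmark))
  rows <- lapply(names(strata), function(nm) {
    p <- strata[[nm]][[1]]; b <- strata[[nm]][[2]]
    if (length(p) == 0 || length(b) == 0) {
      data.frame(stratum = nm, defined = FALSE,
                 nPredicted = length(p@members),
                 nBenchmark = length(b@members),
                 mPC = NA_integer_, mBC = NA_integer_,
                 recall = NA_real_, precision = NA_real_,
                 fMeasure = NA_real_)
    } else {
      cbind(data.frame(stratum = nm, defined = TRUE),
            matchAndScore(p, b, wThreshold, method))
    }
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
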