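#' Read a FunCat-style annotation file
#'
#' Parses a plain-text annotation map, one protein per line:
#' `protein_id <TAB> term` or `protein_id <TAB> term,term,...` (both
#' dialects occur in MIPS/CYGD exports and both are accepted, mixed
#' freely). Lines starting with `#` and blank lines are ignored. Records
#' with a missing ID, a missing term field or an empty term are skipped and
#' counted; duplicate (protein, term) pairs are collapsed. A protein listed
#' on several lines accumulates the union of its terms.
#'
#' Term fields are kept as exact strings: `"01"` and `"1"` are different
#' terms, because FunCat uses fixed two-digit fields and numeric
#' normalization could silently merge distinct catalogues.
#'
#' @param path path to the annotation file.
#' @return A [FunCatAnnotation-class]. The number of skipped records is
#'   available via the `skipped` slot and reported with a warning.
#' @examples
#' tf <- tempfile()
#' writeLines(c("YAL007C\t14.04,20.09.07.03", "YBR009C\t10.01.03"), tf)
#' ann <- readAnnotations(tf)
#' funcatTerms(ann, "YAL007C")
#' @export
readAnnotations <- function(path) {
  lines <- tryCatch(suppressWarnings(readLines(path, warn = FALSE)),
                    error = function(e) stop("cannot read annotation file '",
                                             path, "': ", conditionMessage(e),
                                             call. = FALSE))
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  skipped <- 0L
  acc <- new.env(parent = emptyenv())
  for (ln in lines) {
    parts <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(parts) < 2) { skipped <- skipped + 1L; next }
    id <- trimws(parts[[1]])
    terms <- trimws(strsplit(parts[[2]], ",", fixed = TRUE)[[1]])
    terms <- terms[nzchar(terms)]
    if (!nzchar(id) || length(terms) == 0) { skipped <- skipped + 1L; next }
    acc[[id]] <- union(get0(id, envir = acc, ifnotfound = character(0)),
                       terms)
  }
  ids <- ls(acc, sorted = FALSE)
  if (length(ids) == 0)
    stop("no valid annotation records in '", path, "'", call. = FALSE)
  ann <- mget(ids, envir = acc)
  names(ann) <- ids
  ann <- ann[sortIds(ids)]
  if (skipped > 0)
    warning(skipped, " malformed annotation record(s) skipped",
            call. = FALSE)
  FunCatAnnotation(ann, skipped = skipped)
}

#' Truncate hierarchical terms to their first n levels
#'
#' A FunCat term is a chain of dot-separated fields, each field one level
#' of the functional hierarchy; cutting the hierarchy at level `n` keeps
#' only the first `n` fields. Terms shallower than `n` are returned
#' unchanged, so truncation is a projection: `truncateTerm(truncateTerm(t,
#' m), n)` equals `truncateTerm(t, n)` whenever `n <= m`.
#'
#' @param term character vector of dot-separated terms.
#' @param n positive integer level at which to cut.
#' @return Character vector of truncated terms, same length as `term`.
#' @examples
#' truncateTerm("1.1.1", 2)            # "1.1"
#' truncateTerm("01.01.03.01.01", 2)   # "01.01"
#' truncateTerm("14.04", 6)            # unchanged: n exceeds the depth
#' @export
truncateTerm <- function(term, n) {
  if (length(n) != 1 || is.na(n) || n < 1 || n != as.integer(n))
    stop("n must be a single positive integer", call. = FALSE)
  vapply(strsplit(as.character(term), ".", fixed = TRUE),
         function(f) paste(f[seq_len(min(n, length(f)))], collapse = "."),
         character(1))
}

#' Term depth (number of hierarchy levels)
#' @param term character vector of dot-separated terms.
#' @return Integer vector of field counts.
#' @examples
#' termDepth("01.01.03.01.01")  # 5
#' @export
termDepth <- function(term) {
  lengths(strsplit(as.character(term), ".", fixed = TRUE))
}

#' Group proteins by truncated functional annotation
#'
#' Cuts the annotation hierarchy at level `level` and places proteins with
#' an identical truncated term into one group. A protein whose annotations
#' truncate to k distinct terms belongs to k groups, so groups overlap.
#' Size-1 groups are retained here: the downstream clustering discards the
#' singleton clusters they can at most produce.
#'
#' Grouping compares truncated terms by exact string equality, so a term
#' that only exists above the cut (e.g. `"01"` with `level = 2`) forms its
#' own group and does not join deeper siblings such as `"01.01"`.
#'
#' @param ann a [FunCatAnnotation-class].
#' @param level positive integer annotation level (default 6, the most
#'   specific FunCat level).
#' @return Named list of protein-ID character vectors; names are the
#'   truncated terms, C-locale sorted for deterministic order.
#' @examples
#' ann <- FunCatAnnotation(list(A = "1.1.1", B = "1.1.2"))
#' groupProteins(ann, level = 2)  # one group "1.1" = {A, B}
#' groupProteins(ann, level = 3)  # two singleton groups
#' @export
groupProteins <- function(ann, level = 6) {
  stopifnot(is(ann, "FunCatAnnotation"))
  if (length(ann) == 0)
    stop("annotation map is empty", call. = FALSE)
  terms <- ann@annotations
  prot <- rep(names(terms), lengths(terms))
  cut <- truncateTerm(unlist(terms, use.names = FALSE), level)
  pairs <- unique(data.frame(prot = prot, cut = cut,
                             stringsAsFactors = FALSE))
  groups <- split(pairs$prot, pairs$cut)
  groups <- lapply(groups, sortIds)
  groups[sortIds(names(groups))]
}
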