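#' Read a gene-set annotation in GMT format
#'
#' GMT is the standard tab-separated gene-set exchange format: one line
#' per term with `term_id`, description, then member gene ids. Duplicate
#' members within a term are collapsed.
#'
#' @param path Path to a GMT file.
#' @return An `AnnotationDB`: list with `sets` (named list of character
#'   vectors) and `description` (named character vector).
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(parts) < 3)
  if (length(short))
    stop("GMT line(s) with fewer than 3 fields: line ",
         paste(short, collapse = ", "))
  ids <- vapply(parts, `[`, character(1), 1L)
  if (anyDuplicated(ids)) stop("duplicate term id in GMT")
  sets <- stats::setNames(lapply(parts, function(p) unique(p[-(1:2)])), ids)
  if (any(lengths(sets) == 0)) stop("empty member set in GMT")
  desc <- stats::setNames(vapply(parts, `[`, character(1), 2L), ids)
  structure(list(sets = sets, description = desc), class = "AnnotationDB")
}

#' Write an annotation database in GMT format
#' @param db An `AnnotationDB`.
#' @param path Output path.
#' @export
write_gmt <- function(db, path) {
  stopifnot(inherits(db, "AnnotationDB"))
  lines <- vapply(names(db$sets), function(id) {
    paste(c(id, db$description[[id]], db$sets[[id]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @export
print.AnnotationDB <- function(x, ...) {
  cat(sprintf("AnnotationDB: %d terms, member sets of size %d-%d\n",
              length(x$sets), min(lengths(x$sets)), max(lengths(x$sets))))
  invisible(x)
}

#' Over/under-representation analysis of a gene list
#'
#' Hypergeometric enrichment of a query gene set against an annotation,
#' restricted to a background universe. Term member sets are intersected
#' with the universe first; then terms failing the size filters -- more
#' than `term_size_max` members or fewer than `intersection_min` genes
#' overlapping the query -- are excluded BEFORE testing. Over-
#' representation uses the upper hypergeometric tail (P(overlap >=
#' observed)), under-representation the lower tail (P(overlap <=
#' observed)); Benjamini-Hochberg correction is applied within each
#' direction across the surviving terms.
#'
#' @param query Character vector of gene ids, a subset of `universe`.
#' @param db An `AnnotationDB`.
#' @param universe Background gene ids.
#' @param term_size_max Maximum term size after universe intersection
#'   (default 250).
#' @param intersection_min Minimum query-term overlap for a term to be
#'   tested (default 10); set to 0 to disable.
#' @return An `EnrichmentResult` data.frame: `term_id`, `term_name`,
#'   `direction` (`over`/`under`), `overlap`, `term_size`, `query_size`,
#'   `universe_size`, `p`, `fdr`, ordered by direction then p.
#' @export
enrich <- function(query, db, universe, term_size_max = 250,
                   intersection_min = 10) {
  stopifnot(inherits(db, "AnnotationDB"))
  query <- unique(query)
  universe <- unique(universe)
  if (!length(query) || !length(universe)) stop("empty query or universe")
  extra <- setdiff(query, universe)
  if (length(extra))
    stop("query gene(s) outside universe: ",
         paste(utils::head(extra, 5), collapse = ", "))
  N <- length(universe)
  q <- length(query)
  rows <- lapply(names(db$sets), function(id) {
    members <- intersect(db$sets[[id]], universe)
    m <- length(members)
    ov <- length(intersect(members, query))
    if (m == 0 || m > term_size_max || ov < intersection_min) return(NULL)
    data.frame(term_id = id, term_name = unname(db$description[[id]]),
               overlap = ov, term_size = m, query_size = q,
               universe_size = N, stringsAsFactors = FALSE)
  })
  rows <- do.call(rbind, rows)
  if (is.null(rows)) {
    out <- data.frame(term_id = character(), term_name = character(),
                      direction = character(), overlap = integer(),
                      term_size = integer(), query_size = integer(),
                      universe_size = integer(), p = numeric(),
                      fdr = numeric(), stringsAsFactors = FALSE)
    class(out) <- c("EnrichmentResult", "data.frame")
    return(out)
  }
  over <- rows
  over$direction <- "over"
  over$p <- stats::phyper(over$overlap - 1, over$term_size,
                          N - over$term_size, q, lower.tail = FALSE)
  under <- rows
  under$direction <- "under"
  under$p <- stats::phyper(under$overlap, under$term_size,
                           N - under$term_size, q, lower.tail = TRUE)
  over$fdr <- bh_adjust(over$p, over$term_id)
  under$fdr <- bh_adjust(under$p, under$term_id)
  out <- rbind(over, under)
  out <- out[order(out$direction, out$p, out$term_id),
             c("term_id", "term_name", "direction", "overlap", "term_size",
               "query_size", "universe_size", "p", "fdr")]
  rownames(out) <- NULL
  class(out) <- c("EnrichmentResult", "data.frame")
  out
}
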