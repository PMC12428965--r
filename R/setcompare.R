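#' Exclusive intersection decomposition (UpSet regions)
#'
#' For a named collection of gene sets, counts the elements belonging to
#' exactly each non-empty combination of sets (the regions of an UpSet
#' plot). Region sizes partition the union of all sets.
#'
#' @param sets Named list of character vectors.
#' @return data.frame with one row per occupied combination: `combination`
#'   (set names joined by `&`), `degree`, `size`, plus one logical column
#'   per set.
#' @export
upset_intersections <- function(sets) {
  if (!length(sets)) stop("need at least one set")
  if (is.null(names(sets)) || anyDuplicated(names(sets)))
    stop("sets must be uniquely named")
  sets <- lapply(sets, unique)
  universe <- unique(unlist(sets, use.names = FALSE))
  memb <- vapply(sets, function(s) universe %in% s, logical(length(universe)))
  if (length(universe) == 1L) memb <- matrix(memb, nrow = 1,
                                             dimnames = list(NULL, names(sets)))
  key <- apply(memb, 1, function(r) paste(names(sets)[r], collapse = "&"))
  tab <- table(key)
  out <- data.frame(combination = names(tab),
                    degree = lengths(strsplit(names(tab), "&", fixed = TRUE)),
                    size = as.integer(tab), stringsAsFactors = FALSE)
  for (nm in names(sets))
    out[[nm]] <- vapply(strsplit(out$combination, "&", fixed = TRUE),
                        function(v) nm %in% v, logical(1))
  out[order(-out$size, out$combination), , drop = FALSE]
}

#' Jaccard similarity matrix of a gene-set collection
#'
#' `J(A, B) = |A intersect B| / |A union B|`; the Jaccard index offsets the
#' impact of unequal set sizes when comparing differential-gene lists. The
#' Jaccard of two empty sets is defined as 0 (with a warning).
#'
#' @param sets Named list of character vectors (>= 2 sets).
#' @return Symmetric matrix in \[0, 1\] with unit diagonal for non-empty
#'   sets.
#' @export
jaccard_matrix <- function(sets) {
  if (length(sets) < 2) stop("need at least two sets")
  if (is.null(names(sets)) || anyDuplicated(names(sets)))
    stop("sets must be uniquely named")
  sets <- lapply(sets, unique)
  n <- length(sets)
  J <- matrix(0, n, n, dimnames = list(names(sets), names(sets)))
  warned <- FALSE
  for (i in seq_len(n)) for (j in i:n) {
    u <- length(union(sets[[i]], sets[[j]]))
    if (u == 0) {
      if (!warned && i != j) {
        warning("Jaccard of two empty sets defined as 0")
        warned <- TRUE
      }
      J[i, j] <- J[j, i] <- 0
    } else {
      J[i, j] <- J[j, i] <- length(intersect(sets[[i]], sets[[j]])) / u
    }
  }
  J
}

#' Stable-core extraction
#'
#' The intersection of the Stable gene sets across all comparisons: genes
#' whose expression (or translation) level stays within the stable band in
#' every comparison, a candidate core of constitutive activity.
#'
#' @param stable_sets List (>= 2) of character vectors, one Stable set per
#'   comparison.
#' @return Character vector of core gene ids.
#' @export
stable_core <- function(stable_sets) {
  if (length(stable_sets) < 2) stop("need at least two comparisons")
  Reduce(intersect, stable_sets)
}
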