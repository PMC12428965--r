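#' Cross-level module overlap
#'
#' Compares two module partitions (typically one from transcriptional and
#' one from translational expression) on their common gene universe. For
#' every pair of non-grey modules it reports the Jaccard index, the
#' overlap count, a one-sided hypergeometric p-value for overlap at least
#' as large as observed given the module sizes and the universe, and the
#' Benjamini-Hochberg FDR across all pairs. A pair is flagged `related`
#' when its Jaccard index reaches `threshold` (default 5%) AND its FDR is
#' below `alpha`.
#'
#' Grey (unassigned) genes form a residual class, not a module, and are
#' excluded from pairing; they still count toward the universe.
#'
#' @param ma_a,ma_b `ModuleAssignment` objects for the two levels.
#' @param threshold Jaccard threshold (default 0.05).
#' @param alpha FDR threshold (default 0.05).
#' @return A `CrossLevelOverlap` data.frame: `module_a`, `module_b`,
#'   `size_a`, `size_b`, `overlap`, `universe`, `jaccard`, `p`, `fdr`,
#'   `related`.
#' @export
module_overlap <- function(ma_a, ma_b, threshold = 0.05, alpha = 0.05) {
  stopifnot(inherits(ma_a, "ModuleAssignment"),
            inherits(ma_b, "ModuleAssignment"))
  universe <- intersect(names(ma_a$labels), names(ma_b$labels))
  if (!length(universe)) stop("empty common gene universe")
  la <- ma_a$labels[universe]
  lb <- ma_b$labels[universe]
  mods_a <- setdiff(unique(la), "grey")
  mods_b <- setdiff(unique(lb), "grey")
  if (!length(mods_a) || !length(mods_b))
    stop("no non-grey modules to compare")
  N <- length(universe)
  rows <- expand.grid(module_a = mods_a, module_b = mods_b,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  rows$size_a <- vapply(rows$module_a, function(m) sum(la == m), integer(1))
  rows$size_b <- vapply(rows$module_b, function(m) sum(lb == m), integer(1))
  rows$overlap <- mapply(function(a, b) sum(la == a & lb == b),
                         rows$module_a, rows$module_b)
  rows$universe <- N
  rows$jaccard <- rows$overlap /
    (rows$size_a + rows$size_b - rows$overlap)
  rows$p <- stats::phyper(rows$overlap - 1, rows$size_a, N - rows$size_a,
                          rows$size_b, lower.tail = FALSE)
  rows$fdr <- bh_adjust(rows$p, paste(rows$module_a, rows$module_b))
  rows$related <- rows$jaccard >= threshold & rows$fdr < alpha
  class(rows) <- c("CrossLevelOverlap", "data.frame")
  rows
}
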