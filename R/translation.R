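#' Translational ratio
#'
#' The per-gene translational ratio `I = log2(poly / total)` compares the
#' abundance of a transcript in the polysome-bound fraction with its
#' abundance in total RNA: how effectively molecules of a transcript enter
#' translation. By default the ratio is computed per condition from mean
#' CPM across that condition's replicates; `per = "replicate"` instead
#' pairs total and polysome libraries by biological replicate.
#'
#' @param total_nm,poly_nm `NormalizedMatrix` objects on the CPM scale for
#'   the total-RNA and polysome fractions, same gene universe.
#' @param ss Sample sheet covering the columns of both matrices (one row
#'   per collapsed biological sample).
#' @param pseudocount Added to both numerator and denominator CPM before
#'   the log (default 0.5) so the ratio stays finite at zero.
#' @param per `"condition"` (default) or `"replicate"`.
#' @return A `TRMatrix`: list with `values` (genes x units), `mode`
#'   (`"ratio"`), and `pseudocount`.
#' @export
translational_ratio <- function(total_nm, poly_nm, ss, pseudocount = 0.5,
                                per = c("condition", "replicate")) {
  per <- match.arg(per)
  stopifnot(inherits(total_nm, "NormalizedMatrix"),
            inherits(poly_nm, "NormalizedMatrix"))
  if (total_nm$scale_tag != "cpm" || poly_nm$scale_tag != "cpm")
    stop("translational_ratio expects linear-scale (cpm) input")
  if (!identical(rownames(total_nm$values), rownames(poly_nm$values)))
    stop("total and polysome matrices must share the same gene universe")
  ss <- as.data.frame(ss)
  ann <- function(m, frac) {
    i <- match(colnames(m), ss$sample_id)
    if (anyNA(i)) stop("sample(s) missing from sheet: ",
                       paste(colnames(m)[is.na(i)], collapse = ", "))
    if (!all(ss$fraction[i] == frac))
      stop("fraction mismatch for ", frac, " matrix")
    ss[i, ]
  }
  at <- ann(total_nm$values, "total")
  ap <- ann(poly_nm$values, "polysome")
  if (per == "condition") {
    units <- sort(unique(c(at$condition, ap$condition)))
    miss_t <- setdiff(units, at$condition)
    miss_p <- setdiff(units, ap$condition)
    if (length(miss_t) || length(miss_p))
      stop("unpairable condition(s): ",
           paste(unique(c(miss_t, miss_p)), collapse = ", "))
    tr <- vapply(units, function(u) {
      mt <- rowMeans(total_nm$values[, at$condition == u, drop = FALSE])
      mp <- rowMeans(poly_nm$values[, ap$condition == u, drop = FALSE])
      log2((mp + pseudocount) / (mt + pseudocount))
    }, numeric(nrow(total_nm$values)))
  } else {
    keyt <- paste(at$condition, at$biological_replicate, sep = "_")
    keyp <- paste(ap$condition, ap$biological_replicate, sep = "_")
    units <- sort(unique(c(keyt, keyp)))
    orphans <- c(setdiff(units, keyt), setdiff(units, keyp))
    if (length(orphans))
      stop("unpairable replicate(s): ", paste(unique(orphans), collapse = ", "))
    tr <- vapply(units, function(u) {
      mt <- total_nm$values[, which(keyt == u)[1]]
      mp <- poly_nm$values[, which(keyp == u)[1]]
      log2((mp + pseudocount) / (mt + pseudocount))
    }, numeric(nrow(total_nm$values)))
  }
  rownames(tr) <- rownames(total_nm$values)
  structure(list(values = tr, mode = "ratio", pseudocount = pseudocount),
            class = "TRMatrix")
}

#' @export
print.TRMatrix <- function(x, ...) {
  cat(sprintf("TRMatrix (%s): %d genes x %d units\n",
              x$mode, nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' Difference of translational ratios between two units
#'
#' `dTR = I_i - I_j`, the plug-in differential-translation statistic;
#' antisymmetric in its two units.
#'
#' @param tr A `TRMatrix`.
#' @param unit_i,unit_j Unit (condition or replicate) names in `tr`.
#' @return A `DeltaTRResult` data.frame: `gene_id`, `deltaTR`, `class`
#'   (`NA` until classified).
#' @export
delta_tr <- function(tr, unit_i, unit_j) {
  stopifnot(inherits(tr, "TRMatrix"))
  for (u in c(unit_i, unit_j))
    if (!u %in% colnames(tr$values)) stop("unknown unit: ", u)
  d <- tr$values[, unit_i] - tr$values[, unit_j]
  res <- data.frame(gene_id = rownames(tr$values), deltaTR = unname(d),
                    class = NA_character_, stringsAsFactors = FALSE)
  class(res) <- c("DeltaTRResult", "data.frame")
  res
}

#' Interaction test for differential translation
#'
#' Fits, per gene, a negative-binomial GLM with mean structure
#' `fraction + condition + fraction:condition` and library-size offsets to
#' the combined total/polysome counts of two conditions. The interaction
#' coefficient estimates the change in translational ratio (dTR, on the
#' log2 scale after conversion from the natural-log link) between
#' `condition_b` and `condition_a`; its likelihood-ratio p-value tests for
#' differential translation over and above any transcriptional change.
#' Classification follows [classify_genes()] applied to the dTR estimate.
#'
#' @param total_cm,poly_cm [count_matrix()] objects (technical replicates
#'   collapsed), sharing the gene universe.
#' @param ss Sample sheet covering all columns of both matrices.
#' @param condition_a,condition_b The two conditions to compare; positive
#'   `deltaTR` means translation is up in `condition_b` relative to
#'   `condition_a`.
#' @param dispersions Optional `DispersionEstimates` computed on the
#'   combined matrix with one group per condition-fraction cell; estimated
#'   internally when `NULL`.
#' @param lfc_threshold,alpha Classification thresholds, as in
#'   [classify_genes()].
#' @return A `DeltaTRResult` data.frame: `gene_id`, `deltaTR` (interaction
#'   estimate, log2), `PValue`, `FDR`, `class`.
#' @export
test_differential_translation <- function(total_cm, poly_cm, ss,
                                          condition_a, condition_b,
                                          dispersions = NULL,
                                          lfc_threshold = 1, alpha = 0.05) {
  stopifnot(inherits(total_cm, "CountMatrix"), inherits(poly_cm, "CountMatrix"))
  if (!identical(rownames(total_cm$counts), rownames(poly_cm$counts)))
    stop("total and polysome matrices must share the same gene universe")
  ss <- as.data.frame(ss)
  pick <- function(cm, frac, cond) {
    i <- match(colnames(cm$counts), ss$sample_id)
    if (anyNA(i)) stop("sample(s) missing from sheet")
    sel <- which(ss$condition[i] %in% cond & ss$fraction[i] == frac)
    cm$counts[, sel, drop = FALSE]
  }
  blocks <- list(
    ta = pick(total_cm, "total", condition_a),
    tb = pick(total_cm, "total", condition_b),
    pa = pick(poly_cm, "polysome", condition_a),
    pb = pick(poly_cm, "polysome", condition_b)
  )
  nblk <- vapply(blocks, ncol, integer(1))
  if (any(nblk == 0))
    stop("missing fraction for a condition: ",
         paste(names(blocks)[nblk == 0], collapse = ", "))
  counts <- do.call(cbind, blocks)
  frac <- rep(c(0, 0, 1, 1), nblk)   # 1 = polysome
  cond <- rep(c(0, 1, 0, 1), nblk)   # 1 = condition_b
  cells <- paste(frac, cond)
  if (is.null(dispersions)) {
    sub <- count_matrix(counts, "mixed")
    dispersions <- estimate_dispersions(sub, cells)
  }
  phi <- dispersions$phi
  if (length(phi) != nrow(counts)) stop("dispersions do not match gene set")
  libs <- colSums(counts)
  off <- log(libs / mean(libs))
  X1 <- cbind(intercept = 1, fraction = frac, condition = cond,
              interaction = frac * cond)
  X0 <- X1[, 1:3]
  fit <- nb_lrt(counts, X1, X0, off, phi)
  dtr <- fit$beta[, 4] / log(2)
  dtr[fit$all_zero] <- 0
  res <- data.frame(
    gene_id = rownames(counts),
    deltaTR = dtr,
    PValue = fit$p_value,
    FDR = bh_adjust(fit$p_value, rownames(counts)),
    class = NA_character_,
    all_zero = fit$all_zero,
    stringsAsFactors = FALSE
  )
  res <- classify_genes(res, lfc_threshold, alpha)
  class(res) <- c("DeltaTRResult", "data.frame")
  res
}

#' Renormalise translational ratios to one million per unit
#'
#' Maps log2 ratios back to the linear scale (`2^TR`) and scales each
#' column to sum to 1,000,000, producing a CPM-like matrix suitable as
#' input to co-expression analysis at the translational level. The
#' renormalisation is done on the linear ratio scale because log-scale
#' values can be negative and cannot meaningfully sum to a fixed total.
#'
#' @param tr A `TRMatrix` in ratio mode.
#' @return A `NormalizedMatrix` with `scale_tag = "cpm"`.
#' @export
tr_normalize_million <- function(tr) {
  stopifnot(inherits(tr, "TRMatrix"))
  if (tr$mode != "ratio") stop("tr must be in ratio mode")
  lin <- 2^tr$values
  tot <- colSums(lin)
  if (any(tot <= 0)) stop("non-positive column total")
  normalized_matrix(sweep(lin, 2, 1e6 / tot, "*"), "cpm")
}
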