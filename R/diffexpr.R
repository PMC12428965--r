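#' Estimate negative-binomial dispersions
#'
#' Per-gene dispersions are estimated by the method of moments on the
#' library-size-corrected scale, `phi = max(0, (s^2 - m) / m^2)` pooled
#' across groups, and shrunk toward a common dispersion estimated by
#' Cox-Reid adjusted profile likelihood. Shrinkage weight:
#' `phi_shrunk = (d * phi_gene + w * phi_common) / (d + w)` with `d` the
#' pooled residual degrees of freedom and `w = prior_weight`.
#'
#' @param cm A [count_matrix()].
#' @param groups Factor or character vector, one entry per sample, defining
#'   the experimental groups within which variability is assessed.
#' @param prior_weight Weight of the common dispersion in the shrinkage
#'   (default 20, chosen for small-replicate designs where the per-gene
#'   moment estimate is noisy).
#' @return An object of class `DispersionEstimates`: list with `gene_ids`,
#'   `phi_gene` (raw moment estimates), `phi_common`, `phi` (shrunk values
#'   used by the tests), `prior_weight`, and `single_replicate` flag set
#'   when every group has fewer than 2 samples.
#' @export
estimate_dispersions <- function(cm, groups, prior_weight = 20) {
  stopifnot(inherits(cm, "CountMatrix"), prior_weight >= 0)
  counts <- cm$counts
  if (length(groups) != ncol(counts))
    stop("groups must have one entry per sample")
  libs <- colSums(counts)
  s <- libs / mean(libs)
  yn <- sweep(counts, 2, s, "/")
  gl <- split(seq_along(groups), groups)
  num <- rep(0, nrow(counts)); den <- 0
  for (ii in gl) {
    if (length(ii) < 2) next
    m <- rowMeans(yn[, ii, drop = FALSE])
    v <- row_vars(yn[, ii, drop = FALSE])
    w <- length(ii) - 1
    num <- num + w * ifelse(m > 0, (v - m) / m^2, 0)
    den <- den + w
  }
  single <- den == 0
  phi_common <- nb_common_dispersion(counts, groups, s)
  if (single) {
    phi_gene <- rep(phi_common, nrow(counts))
    phi <- phi_gene
    warning("all groups have a single sample; using common dispersion only")
  } else {
    phi_gene <- pmax(0, num / den)
    phi <- (den * phi_gene + prior_weight * phi_common) / (den + prior_weight)
  }
  names(phi_gene) <- names(phi) <- rownames(counts)
  structure(list(gene_ids = rownames(counts), phi_gene = phi_gene,
                 phi_common = phi_common, phi = phi,
                 prior_weight = prior_weight, single_replicate = single),
            class = "DispersionEstimates")
}

#' Negative-binomial differential expression test
#'
#' Per-gene likelihood-ratio test of equal group means under a
#' negative-binomial model with log link and library-size offsets (raw
#' column totals). The log2 fold change is computed from offset-corrected
#' group means with a 0.5 pseudo-count per group mean so that fold changes
#' stay finite at zero counts. Genes with all-zero counts get `p = 1`,
#' `logFC = 0`, and are flagged.
#'
#' @param cm A [count_matrix()] (technical replicates already collapsed).
#' @param group_a,group_b Sample ids (or column indices) of the two groups;
#'   `logFC` is log2 of group B over group A.
#' @param dispersions A `DispersionEstimates` object; computed from the two
#'   groups when `NULL`.
#' @return A `DEResult` data.frame: `gene_id`, `logFC`, `PValue`, `FDR`
#'   (Benjamini-Hochberg), `class` (`NA` until [classify_genes()]), and
#'   `all_zero` flag.
#' @export
test_differential <- function(cm, group_a, group_b, dispersions = NULL) {
  stopifnot(inherits(cm, "CountMatrix"))
  ia <- resolve_samples(cm, group_a)
  ib <- resolve_samples(cm, group_b)
  if (!length(ia) || !length(ib)) stop("both groups must be non-empty")
  if (length(intersect(ia, ib))) stop("groups overlap")
  idx <- c(ia, ib)
  counts <- cm$counts[, idx, drop = FALSE]
  if (is.null(dispersions)) {
    sub <- count_matrix(counts, cm$fraction)
    dispersions <- estimate_dispersions(
      sub, rep(c("A", "B"), c(length(ia), length(ib))))
  }
  phi <- dispersions$phi
  if (length(phi) != nrow(counts)) stop("dispersions do not match gene set")
  libs <- colSums(counts)
  off <- log(libs / mean(libs))
  X1 <- cbind(intercept = 1, group = rep(c(0, 1), c(length(ia), length(ib))))
  X0 <- X1[, 1, drop = FALSE]
  fit <- nb_lrt(counts, X1, X0, off, phi)
  sA <- sum(exp(off[seq_along(ia)]))
  sB <- sum(exp(off[length(ia) + seq_along(ib)]))
  mA <- rowSums(counts[, seq_along(ia), drop = FALSE]) / sA
  mB <- rowSums(counts[, length(ia) + seq_along(ib), drop = FALSE]) / sB
  lfc <- log2((mB + 0.5) / (mA + 0.5))
  lfc[fit$all_zero] <- 0
  res <- data.frame(
    gene_id = rownames(counts),
    logFC = lfc,
    PValue = fit$p_value,
    FDR = bh_adjust(fit$p_value, rownames(counts)),
    class = NA_character_,
    all_zero = fit$all_zero,
    stringsAsFactors = FALSE
  )
  class(res) <- c("DEResult", "data.frame")
  res
}

# BH step-up with deterministic tie-breaking by (p, gene_id).
bh_adjust <- function(p, ids) {
  ord <- order(p, ids)
  n <- length(p)
  adj <- p[ord] * n / seq_len(n)
  adj <- rev(cummin(rev(adj)))
  out <- numeric(n)
  out[ord] <- pmin(adj, 1)
  out
}

resolve_samples <- function(cm, sel) {
  if (is.character(sel)) {
    miss <- setdiff(sel, colnames(cm$counts))
    if (length(miss)) stop("unknown sample(s): ", paste(miss, collapse = ", "))
    match(sel, colnames(cm$counts))
  } else if (is.logical(sel)) which(sel) else as.integer(sel)
}

#' Classify genes into Up / Down / Stable
#'
#' Applies the three-way rule used throughout the analysis: `Up` when
#' `logFC > lfc_threshold` and `PValue < alpha`; `Down` when
#' `logFC < -lfc_threshold` and `PValue < alpha`; `Stable` when
#' `-lfc_threshold <= logFC <= lfc_threshold`. Genes whose fold change
#' exceeds the threshold without reaching significance fall in neither
#' group and are labelled `Unclassified`. Raw p-values (not FDR) drive the
#' classification; FDR is reported alongside.
#'
#' @param de A `DEResult` (or any data.frame with `logFC` and `PValue`;
#'   a `deltaTR` column is used in place of `logFC` if present).
#' @param lfc_threshold Absolute log2 fold-change threshold (default 1).
#' @param alpha Raw p-value cutoff (default 0.05).
#' @return The input with its `class` column filled in.
#' @export
classify_genes <- function(de, lfc_threshold = 1, alpha = 0.05) {
  eff <- if ("logFC" %in% colnames(de)) de$logFC else de$deltaTR
  if (is.null(eff)) stop("no logFC or deltaTR column to classify on")
  p <- de$PValue
  cls <- rep("Unclassified", length(eff))
  cls[eff > lfc_threshold & p < alpha] <- "Up"
  cls[eff < -lfc_threshold & p < alpha] <- "Down"
  cls[eff >= -lfc_threshold & eff <= lfc_threshold] <- "Stable"
  de$class <- cls
  de
}

#' Write a differential expression result to TSV
#' @param de A `DEResult`.
#' @param path Output path.
#' @export
write_de_result <- function(de, path) {
  cols <- intersect(c("gene_id", "logFC", "deltaTR", "PValue", "FDR", "class"),
                    colnames(de))
  utils::write.table(as.data.frame(de)[, cols], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
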