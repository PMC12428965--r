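# Figure helpers. Heatmaps go through pheatmap when available; the other
# figures use base graphics. All helpers accept an optional path and write
# PNG when one is given.

with_png <- function(path, width, height, expr) {
  if (!is.null(path)) {
    grDevices::png(path, width = width, height = height, res = 110)
    on.exit(grDevices::dev.off())
  }
  force(expr)
  invisible(path)
}

#' Plot sample coordinates from a PCA overview
#' @param pca Result of [pca_overview()].
#' @param groups Optional factor colouring the samples.
#' @param path Optional PNG output path.
#' @export
plot_pca <- function(pca, groups = NULL, path = NULL) {
  with_png(path, 700, 600, {
    xy <- pca$coordinates
    col <- if (is.null(groups)) "grey30" else as.integer(factor(groups)) + 1
    graphics::plot(xy[, 1], xy[, 2], col = col, pch = 19,
                   xlab = sprintf("PC1 (%.1f%%)", 100 * pca$explained_variance[1]),
                   ylab = sprintf("PC2 (%.1f%%)", 100 * pca$explained_variance[2]))
    if (!is.null(groups))
      graphics::legend("topright", legend = levels(factor(groups)),
                       col = seq_along(levels(factor(groups))) + 1, pch = 19,
                       cex = 0.8)
  })
}

#' Bar plot of exclusive intersection sizes
#' @param regions Result of [upset_intersections()].
#' @param max_bars Show at most this many regions (largest first).
#' @param path Optional PNG output path.
#' @export
plot_upset <- function(regions, max_bars = 20, path = NULL) {
  with_png(path, 900, 600, {
    r <- utils::head(regions[order(-regions$size), ], max_bars)
    op <- graphics::par(mar = c(12, 4, 2, 1))
    graphics::barplot(r$size, names.arg = r$combination, las = 2,
                      cex.names = 0.6, ylab = "exclusive region size")
    graphics::par(op)
  })
}

#' Jaccard heatmap of a gene-set collection
#' @param J Matrix from [jaccard_matrix()].
#' @param path Optional PNG output path.
#' @export
plot_jaccard_heatmap <- function(J, path = NULL) {
  if (requireNamespace("pheatmap", quietly = TRUE)) {
    ph <- pheatmap::pheatmap(J, display_numbers = TRUE, number_format = "%.2f",
                             silent = TRUE)
    with_png(path, 750, 650, grid::grid.draw(ph$gtable))
  } else {
    with_png(path, 750, 650, {
      graphics::image(seq_len(nrow(J)), seq_len(ncol(J)), J,
                      axes = FALSE, xlab = "", ylab = "")
      graphics::axis(1, seq_len(nrow(J)), rownames(J), las = 2, cex.axis = 0.7)
      graphics::axis(2, seq_len(ncol(J)), colnames(J), las = 2, cex.axis = 0.7)
    })
  }
}

#' Module-trait heatmap with p-values in brackets
#' @param mt data.frame from [module_trait_correlation()].
#' @param path Optional PNG output path.
#' @export
plot_module_trait_heatmap <- function(mt, path = NULL) {
  mods <- unique(mt$module)
  trts <- unique(mt$trait)
  R <- matrix(NA_real_, length(mods), length(trts),
              dimnames = list(mods, trts))
  lab <- R
  for (i in seq_len(nrow(mt))) {
    R[mt$module[i], mt$trait[i]] <- mt$r[i]
    lab[mt$module[i], mt$trait[i]] <-
      sprintf("%.2f\n(%.3f)", mt$r[i], mt$p[i])
  }
  if (requireNamespace("pheatmap", quietly = TRUE)) {
    ph <- pheatmap::pheatmap(R, display_numbers = lab, cluster_rows = FALSE,
                             cluster_cols = FALSE,
                             breaks = seq(-1, 1, length.out = 101),
                             silent = TRUE)
    with_png(path, 700, 100 + 60 * length(mods), grid::grid.draw(ph$gtable))
  } else {
    with_png(path, 700, 600, {
      graphics::image(seq_along(trts), seq_along(mods), t(R),
                      zlim = c(-1, 1), axes = FALSE, xlab = "", ylab = "")
      graphics::axis(1, seq_along(trts), trts, las = 2)
      graphics::axis(2, seq_along(mods), mods, las = 2)
    })
  }
}

# Writes the standard figure set for a pipeline run; returns the paths.
write_pipeline_figures <- function(res, cfg) {
  figs <- character()
  fdir <- file.path(cfg$outdir, "figures")
  dir.create(fdir, showWarnings = FALSE)
  ids <- rownames(res$pca$coordinates)
  frac <- ifelse(ids %in% colnames(res$total$counts), "total", "polysome")
  figs <- c(figs, plot_pca(res$pca, frac, file.path(fdir, "pca.png")))
  for (tag in names(res$sets)) {
    J <- jaccard_matrix(res$sets[[tag]])
    figs <- c(figs, plot_jaccard_heatmap(
      J, file.path(fdir, paste0("jaccard_", tag, ".png"))))
  }
  for (lev in names(res$wgcna)) {
    mt <- res$wgcna[[lev]]$module_trait
    if (!is.null(mt) && nrow(mt))
      figs <- c(figs, plot_module_trait_heatmap(
        mt, file.path(fdir, paste0("module_trait_", lev, ".png"))))
  }
  if (!is.null(res$crosslevel)) {
    ma_t <- res$wgcna$transcription$modules
    ma_p <- res$wgcna$translation$modules
    common <- intersect(names(ma_t$labels), names(ma_p$labels))
    sets <- c(
      stats::setNames(
        lapply(setdiff(names(ma_t$sizes), "grey"),
               function(m) common[ma_t$labels[common] == m]),
        paste0("T_", setdiff(names(ma_t$sizes), "grey"))),
      stats::setNames(
        lapply(setdiff(names(ma_p$sizes), "grey"),
               function(m) common[ma_p$labels[common] == m]),
        paste0("P_", setdiff(names(ma_p$sizes), "grey"))))
    figs <- c(figs, plot_jaccard_heatmap(
      jaccard_matrix(sets), file.path(fdir, "crosslevel_jaccard.png")))
  }
  figs
}
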