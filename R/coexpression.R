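# Self-contained weighted co-expression network analysis: correlation
# adjacency raised to a soft power, topological overlap, average-linkage
# module detection with a static tree cut, eigengenes, module-trait
# correlation and hub genes.

expr_values <- function(x) {
  if (inherits(x, "NormalizedMatrix")) x$values else as.matrix(x)
}

# Fixed module colour vocabulary; "grey" is reserved for unassigned genes.
module_colour_list <- function() {
  head_cols <- c("peachpuff", "lightgrey", "darksalmon", "gainsboro",
                 "darkgrey", "coral", "brown", "saddlebrown", "turquoise",
                 "blue", "yellow", "green", "red", "black", "pink",
                 "magenta", "purple", "greenyellow", "tan", "cyan",
                 "salmon", "midnightblue", "lightcyan", "royalblue",
                 "darkred", "darkgreen", "darkturquoise", "orange")
  extra <- setdiff(grDevices::colours(distinct = TRUE), c(head_cols, "grey", "gray"))
  c(head_cols, extra)
}

#' Scale-free topology fit and soft-threshold selection
#'
#' For each candidate power, builds the correlation adjacency, computes the
#' connectivity `k_i = sum_j a_ij`, bins `k` into `n_bins` equal-width bins
#' and regresses `log10` mean bin frequency on `log10` mean bin
#' connectivity. The signed fit is `-sign(slope) * R^2`, so only networks
#' whose degree distribution decays (negative slope) can score high.
#'
#' Powers under which the network loses essentially all connectivity
#' (`mean_k < min_mean_k`) are reported in the fit table but ineligible for
#' selection: near zero connectivity the binned log-log fit of any data,
#' including pure noise, drifts toward spuriously high R-squared values, so
#' a fit there says nothing about scale-free structure. The returned power
#' is the smallest eligible one reaching `target_r2`; if none does, the
#' maximum-fit eligible power is returned with `low_fit = TRUE`.
#'
#' @param nm `NormalizedMatrix` or plain matrix, genes x samples; constant
#'   genes are dropped with a warning.
#' @param powers Candidate soft powers (default 1:20).
#' @param target_r2 Scale-free fit target (default 0.8).
#' @param min_mean_k Minimum mean connectivity for a power to be eligible
#'   (default 1).
#' @param mode `"unsigned"` or `"signed"` adjacency.
#' @param n_bins Histogram bins for the fit (default 10).
#' @return List with `beta` (selected power), `low_fit` flag, and
#'   `fit_table` (power, fit, slope, mean_k, max_k, eligible).
#' @export
pick_soft_threshold <- function(nm, powers = 1:20, target_r2 = 0.8,
                                min_mean_k = 1, mode = c("unsigned", "signed"),
                                n_bins = 10) {
  mode <- match.arg(mode)
  x <- expr_values(nm)
  if (ncol(x) < 4) stop("need at least 4 samples")
  v <- row_vars(x)
  if (any(v == 0)) {
    warning(sum(v == 0), " constant gene(s) dropped before correlation")
    x <- x[v > 0, , drop = FALSE]
  }
  cc <- stats::cor(t(x))
  base <- if (mode == "unsigned") abs(cc) else (1 + cc) / 2
  diag(base) <- 0
  tab <- do.call(rbind, lapply(powers, function(p) {
    a <- base^p
    k <- rowSums(a)
    f <- scale_free_fit(k, n_bins)
    data.frame(power = p, fit = f$fit, slope = f$slope,
               mean_k = mean(k), max_k = max(k))
  }))
  tab$eligible <- tab$mean_k >= min_mean_k
  elig <- tab[tab$eligible, , drop = FALSE]
  if (!nrow(elig)) elig <- tab
  hit <- elig$power[elig$fit >= target_r2]
  if (length(hit)) {
    beta <- min(hit)
    low_fit <- FALSE
  } else {
    beta <- elig$power[which.max(elig$fit)]
    low_fit <- TRUE
    warning("no candidate power reaches the scale-free fit target; ",
            "returning the maximum-fit power ", beta)
  }
  list(beta = beta, low_fit = low_fit, fit_table = tab)
}

scale_free_fit <- function(k, n_bins = 10) {
  if (max(k) == min(k)) return(list(fit = 0, slope = NA_real_))
  bin <- cut(k, seq(min(k), max(k), length.out = n_bins + 1),
             include.lowest = TRUE)
  km <- tapply(k, bin, mean)
  fr <- tapply(k, bin, length) / length(k)
  ok <- !is.na(km) & km > 0 & !is.na(fr) & fr > 0
  if (sum(ok) < 3) return(list(fit = 0, slope = NA_real_))
  fit <- stats::lm.fit(cbind(1, log10(km[ok])), log10(fr[ok]))
  slope <- fit$coefficients[2]
  r2 <- 1 - sum(fit$residuals^2) /
    sum((log10(fr[ok]) - mean(log10(fr[ok])))^2)
  list(fit = unname(-sign(slope) * r2), slope = unname(slope))
}

#' Weighted co-expression adjacency
#'
#' Unsigned: `a_ij = |cor(x_i, x_j)|^beta`; signed:
#' `a_ij = ((1 + cor) / 2)^beta`; diagonal set to 1.
#'
#' @param nm `NormalizedMatrix` or matrix, genes x samples.
#' @param beta Soft power (>= 1).
#' @param mode `"unsigned"` or `"signed"`.
#' @return A `Network`: list with `adjacency`, `beta`, `mode`.
#' @export
adjacency <- function(nm, beta = 6, mode = c("unsigned", "signed")) {
  mode <- match.arg(mode)
  if (beta < 1) stop("beta must be >= 1")
  x <- expr_values(nm)
  v <- row_vars(x)
  if (any(v == 0))
    stop("zero-variance gene(s): ",
         paste(utils::head(rownames(x)[v == 0], 5), collapse = ", "),
         " (filter before network construction)")
  cc <- stats::cor(t(x))
  a <- if (mode == "unsigned") abs(cc)^beta else ((1 + cc) / 2)^beta
  diag(a) <- 1
  structure(list(adjacency = a, beta = beta, mode = mode), class = "Network")
}

#' Topological overlap matrix
#'
#' `TOM_ij = (l_ij + a_ij) / (min(k_i, k_j) + 1 - a_ij)` with
#' `l_ij = sum_u a_iu a_uj` over `u != i, j` and `k_i = sum_u a_iu` over
#' `u != i`; `TOM_ii = 1`. Genes score as similar when they are both
#' directly connected and share neighbours.
#'
#' @param net A `Network` from [adjacency()].
#' @return Symmetric matrix in \[0, 1\] with unit diagonal.
#' @export
topological_overlap <- function(net) {
  stopifnot(inherits(net, "Network"))
  a <- net$adjacency
  diag(a) <- 0
  k <- rowSums(a)
  l <- a %*% a  # since diag(a) = 0, l_ij = sum_{u != i,j} a_iu a_uj + 0
  tom <- (l + a) / (outer(k, k, pmin) + 1 - a)
  diag(tom) <- 1
  tom[tom > 1] <- 1
  tom[tom < 0] <- 0
  tom
}

#' Detect co-expression modules by static tree cut
#'
#' Average-linkage hierarchical clustering of the dissimilarity `1 - TOM`,
#' cut at `cut_height` times the maximum merge height. Clusters smaller
#' than `min_module_size` are assigned to `"grey"` (unassigned); remaining
#' clusters are named from a fixed colour list in order of decreasing
#' size. Fully deterministic given its input.
#'
#' @param tom TOM (or any symmetric similarity) matrix with gene dimnames.
#' @param min_module_size Minimum genes per module (default 30).
#' @param cut_height Fraction of the maximum merge height at which the
#'   tree is cut (default 0.99).
#' @return A `ModuleAssignment`: list with `labels` (named character
#'   vector gene -> module colour) and `sizes` (named integer vector,
#'   decreasing, `grey` last).
#' @export
detect_modules <- function(tom, min_module_size = 30, cut_height = 0.99) {
  if (is.null(rownames(tom))) stop("tom needs gene dimnames")
  genes <- rownames(tom)
  if (length(genes) < min_module_size) {
    warning("fewer genes than min_module_size; all genes unassigned")
    labels <- stats::setNames(rep("grey", length(genes)), genes)
    return(structure(list(labels = labels,
                          sizes = c(grey = length(genes))),
                     class = "ModuleAssignment"))
  }
  h <- stats::hclust(stats::as.dist(1 - tom), method = "average")
  cl <- stats::cutree(h, h = cut_height * max(h$height))
  sizes <- table(cl)
  big <- names(sizes)[sizes >= min_module_size]
  # deterministic colour order: decreasing size, ties by first gene index
  first_idx <- vapply(big, function(b) min(which(cl == as.integer(b))), integer(1))
  big <- big[order(-sizes[big], first_idx)]
  cols <- module_colour_list()
  if (length(big) > length(cols)) big <- big[seq_along(cols)]
  labels <- rep("grey", length(genes))
  for (i in seq_along(big)) labels[cl == as.integer(big[i])] <- cols[i]
  names(labels) <- genes
  sz <- sort(table(labels[labels != "grey"]), decreasing = TRUE)
  sizes_out <- c(stats::setNames(as.integer(sz), names(sz)),
                 grey = sum(labels == "grey"))
  structure(list(labels = labels, sizes = sizes_out),
            class = "ModuleAssignment")
}

#' @export
print.ModuleAssignment <- function(x, ...) {
  cat("ModuleAssignment:", length(x$sizes) - 1, "modules over",
      length(x$labels), "genes\n")
  print(x$sizes)
  invisible(x)
}

#' Module eigengenes
#'
#' The eigengene of a module is the first principal component of the
#' standardized expression of its genes: the unit-norm sample profile
#' capturing the largest share of the module's variance. Its sign is fixed
#' so that its correlation with the module's mean standardized profile is
#' nonnegative. Grey (unassigned) genes are skipped.
#'
#' @param nm `NormalizedMatrix` or matrix, genes x samples.
#' @param ma A `ModuleAssignment`.
#' @return Matrix, modules x samples, unit-norm rows.
#' @export
module_eigengene <- function(nm, ma) {
  stopifnot(inherits(ma, "ModuleAssignment"))
  x <- expr_values(nm)
  mods <- setdiff(names(ma$sizes), "grey")
  eg <- matrix(NA_real_, length(mods), ncol(x),
               dimnames = list(mods, colnames(x)))
  for (m in mods) {
    genes <- names(ma$labels)[ma$labels == m]
    sub <- x[genes, , drop = FALSE]
    sub <- t(scale(t(sub)))  # standardize each gene across samples
    sub[!is.finite(sub)] <- 0
    sv <- svd(sub, nu = 0, nv = 1)
    v <- sv$v[, 1]
    ref <- colMeans(sub)
    if (sum(v * ref) < 0) v <- -v
    eg[m, ] <- v
  }
  eg
}

#' Two-sided p-value for a Pearson correlation
#'
#' `t = r * sqrt(n - 2) / sqrt(1 - r^2)` referred to a t distribution with
#' `n - 2` degrees of freedom; `|r| = 1` gives `p = 0`.
#'
#' @param r Correlation coefficient(s).
#' @param n Number of observations.
#' @return Two-sided p-value(s).
#' @export
correlation_pvalue <- function(r, n) {
  if (n < 3) stop("need n >= 3")
  p <- rep(NA_real_, length(r))
  one <- !is.na(r) & abs(r) >= 1
  p[one] <- 0
  ok <- !is.na(r) & abs(r) < 1
  t <- r[ok] * sqrt(n - 2) / sqrt(1 - r[ok]^2)
  p[ok] <- 2 * stats::pt(-abs(t), df = n - 2)
  p
}

#' Module-trait correlation table
#'
#' Pearson correlation of each module eigengene with each trait column
#' (typically one-hot condition indicators at sample level), with the
#' closed-form two-sided t-transform p-value. Constant traits give `NA`
#' correlations.
#'
#' @param eigengenes Matrix, modules x samples ([module_eigengene()]).
#' @param traits data.frame or matrix, samples x traits, numeric.
#' @return data.frame: `module`, `trait`, `r`, `p`, `n`.
#' @export
module_trait_correlation <- function(eigengenes, traits) {
  traits <- as.matrix(traits)
  if (ncol(eigengenes) != nrow(traits))
    stop("eigengenes and traits must cover the same samples")
  n <- nrow(traits)
  if (n < 3) stop("need at least 3 samples")
  out <- expand.grid(module = rownames(eigengenes), trait = colnames(traits),
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  out$r <- NA_real_
  out$p <- NA_real_
  out$n <- n
  for (i in seq_len(nrow(out))) {
    tv <- traits[, out$trait[i]]
    if (stats::sd(tv) == 0) next  # constant trait: correlation undefined
    r <- stats::cor(eigengenes[out$module[i], ], tv)
    out$r[i] <- r
    out$p[i] <- correlation_pvalue(r, n)
  }
  out
}

#' Hub genes by module membership (kME)
#'
#' Ranks the genes of each module by kME, the correlation of the gene's
#' expression profile with its module eigengene, and returns the top
#' `top_n` per module (whole module when smaller). Ties break by gene id.
#'
#' @param nm `NormalizedMatrix` or matrix, genes x samples.
#' @param ma A `ModuleAssignment`.
#' @param eigengenes Matrix from [module_eigengene()].
#' @param top_n Genes per module (default 10).
#' @return data.frame: `module`, `gene_id`, `kME`, `rank`.
#' @export
hub_genes <- function(nm, ma, eigengenes, top_n = 10) {
  stopifnot(inherits(ma, "ModuleAssignment"))
  x <- expr_values(nm)
  res <- list()
  for (m in rownames(eigengenes)) {
    genes <- names(ma$labels)[ma$labels == m]
    kme <- vapply(genes, function(g) stats::cor(x[g, ], eigengenes[m, ]),
                  numeric(1))
    ord <- order(-kme, genes)
    take <- utils::head(ord, top_n)
    res[[m]] <- data.frame(module = m, gene_id = genes[take],
                           kME = unname(kme[take]),
                           rank = seq_along(take),
                           stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
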