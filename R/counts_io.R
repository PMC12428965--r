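#' Construct a count matrix object
#'
#' A `CountMatrix` holds a gene-by-sample table of nonnegative integer read
#' counts for one sequencing fraction (total RNA or the polysome-bound
#' fraction), plus a fraction tag. Row names are gene identifiers, column
#' names are sample identifiers; both must be unique.
#'
#' @param counts Integer matrix (genes x samples) with unique row and column
#'   names and no negative entries.
#' @param fraction One of `"total"`, `"polysome"`, `"mixed"`.
#' @return An object of class `CountMatrix`: a list with elements `counts`
#'   and `fraction`.
#' @export
count_matrix <- function(counts, fraction = c("total", "polysome", "mixed")) {
  fraction <- match.arg(fraction)
  counts <- as.matrix(counts)
  if (nrow(counts) > 0 && is.null(rownames(counts)))
    stop("counts must have gene row names")
  if (ncol(counts) > 0 && is.null(colnames(counts)))
    stop("counts must have sample column names")
  if (is.null(rownames(counts))) rownames(counts) <- character(0)
  if (is.null(colnames(counts))) colnames(counts) <- character(0)
  if (anyDuplicated(rownames(counts)))
    stop("duplicate gene id: ",
         paste(unique(rownames(counts)[duplicated(rownames(counts))]), collapse = ", "))
  if (anyDuplicated(colnames(counts)))
    stop("duplicate sample id: ",
         paste(unique(colnames(counts)[duplicated(colnames(counts))]), collapse = ", "))
  if (any(!is.finite(counts)) || any(counts < 0))
    stop("counts must be finite and nonnegative")
  if (any(counts != round(counts)))
    stop("counts must be integers")
  storage.mode(counts) <- "double"  # counts can exceed .Machine$integer.max in sums
  structure(list(counts = counts, fraction = fraction), class = "CountMatrix")
}

#' @export
print.CountMatrix <- function(x, ...) {
  cat(sprintf("CountMatrix: %d genes x %d samples (fraction: %s)\n",
              nrow(x$counts), ncol(x$counts), x$fraction))
  invisible(x)
}

#' @export
dim.CountMatrix <- function(x) dim(x$counts)

#' Read a count matrix from a TSV file
#'
#' Expects a tab-separated file whose first column (`gene_id`) holds gene
#' identifiers and whose remaining columns hold integer counts, one column
#' per sample, with a header row of sample identifiers.
#'
#' @param path Path to the TSV file.
#' @param fraction Fraction tag recorded on the returned object.
#' @return A [count_matrix()] with row and column order as in the file.
#' @export
read_counts <- function(path, fraction = c("total", "polysome", "mixed")) {
  fraction <- match.arg(fraction)
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2)
    stop("malformed count file (need a gene_id column plus >= 1 sample column): ", path)
  gene_ids <- as.character(df[[1]])
  if (anyDuplicated(gene_ids))
    stop("duplicate gene id in ", path, ": ",
         paste(unique(gene_ids[duplicated(gene_ids)]), collapse = ", "))
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m)) {
    bad <- which(!vapply(df[-1], is.numeric, logical(1)))
    stop("non-integer cells in column(s): ",
         paste(colnames(df)[-1][bad], collapse = ", "))
  }
  if (any(m != round(m))) {
    idx <- which(m != round(m), arr.ind = TRUE)[1, ]
    stop(sprintf("non-integer cell at gene '%s', sample '%s'",
                 gene_ids[idx[1]], colnames(m)[idx[2]]))
  }
  rownames(m) <- gene_ids
  count_matrix(m, fraction)
}

#' Write a count matrix to a TSV file
#'
#' @param cm A [count_matrix()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_counts <- function(cm, path) {
  stopifnot(inherits(cm, "CountMatrix"))
  df <- data.frame(gene_id = rownames(cm$counts), cm$counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read and validate a sample sheet
#'
#' The sample sheet annotates every sequencing library with its condition,
#' fraction, and biological/technical replicate indices. It is the pairing
#' key between the total-RNA and polysome-fraction matrices.
#'
#' @param path TSV with columns `sample_id`, `condition`, `fraction`,
#'   `biological_replicate`, `technical_replicate`.
#' @return A validated data.frame of class `SampleSheet`.
#' @export
read_sample_sheet <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  validate_sample_sheet(df)
}

#' @rdname read_sample_sheet
#' @param ss A sample-sheet data.frame to validate.
#' @export
validate_sample_sheet <- function(ss) {
  need <- c("sample_id", "condition", "fraction",
            "biological_replicate", "technical_replicate")
  miss <- setdiff(need, colnames(ss))
  if (length(miss)) stop("sample sheet missing column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(ss$sample_id))
    stop("duplicate sample_id in sample sheet")
  if (!all(ss$fraction %in% c("total", "polysome")))
    stop("fraction must be 'total' or 'polysome'")
  key <- paste(ss$condition, ss$fraction, ss$biological_replicate, ss$technical_replicate)
  if (anyDuplicated(key))
    stop("(condition, fraction, biological_replicate, technical_replicate) not unique")
  if (any(ss$biological_replicate < 1) || any(ss$technical_replicate < 1))
    stop("replicate indices must be >= 1")
  class(ss) <- c("SampleSheet", "data.frame")
  ss
}

#' Write a sample sheet to a TSV file
#' @param ss Sample sheet data.frame.
#' @param path Output path.
#' @export
write_sample_sheet <- function(ss, path) {
  utils::write.table(as.data.frame(ss), path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Collapse technical replicates by summation
#'
#' Technical repeats are resequencings of one library, so their counts are
#' summed into a single column per (condition, fraction, biological
#' replicate); summing rather than averaging keeps the counts integer and
#' avoids pseudo-replication in downstream dispersion estimation.
#'
#' @param cm A [count_matrix()].
#' @param ss Sample sheet annotating every column of `cm`.
#' @return A [count_matrix()] with one column per biological sample, named
#'   `<condition>_<fraction>_<biological_replicate>`, carrying the collapsed
#'   sample sheet in attribute `"sample_sheet"`.
#' @export
collapse_technical_replicates <- function(cm, ss) {
  stopifnot(inherits(cm, "CountMatrix"))
  ss <- validate_sample_sheet(as.data.frame(ss))
  ids <- colnames(cm$counts)
  unknown <- setdiff(ids, ss$sample_id)
  if (length(unknown))
    stop("unannotated sample(s): ", paste(unknown, collapse = ", "))
  ann <- ss[match(ids, ss$sample_id), ]
  key <- paste(ann$condition, ann$fraction, ann$biological_replicate, sep = "_")
  groups <- split(seq_along(ids), factor(key, levels = unique(key)))
  out <- vapply(groups, function(j) rowSums(cm$counts[, j, drop = FALSE]),
                numeric(nrow(cm$counts)))
  rownames(out) <- rownames(cm$counts)
  res <- count_matrix(out, cm$fraction)
  first <- vapply(groups, `[`, integer(1), 1L)
  attr(res, "sample_sheet") <- data.frame(
    sample_id = names(groups),
    condition = ann$condition[first],
    fraction = ann$fraction[first],
    biological_replicate = ann$biological_replicate[first],
    stringsAsFactors = FALSE
  )
  res
}

#' Counts-per-million normalisation
#'
#' Scales every column to one million, optionally followed by a log2
#' transform with a pseudocount. CPM substitutes for TPM when transcript
#' lengths are unavailable; the `scale_tag` attribute records which scale
#' the values are on.
#'
#' @param cm A [count_matrix()].
#' @param log If `TRUE`, return `log2(cpm + pseudocount)`.
#' @param pseudocount Pseudocount added before the log transform.
#' @return A `NormalizedMatrix`: list with `values` (real matrix) and
#'   `scale_tag` (`"cpm"` or `"log2cpm"`).
#' @export
cpm_normalize <- function(cm, log = FALSE, pseudocount = 1) {
  stopifnot(inherits(cm, "CountMatrix"))
  tot <- colSums(cm$counts)
  if (any(tot == 0))
    stop("all-zero column(s): ", paste(colnames(cm$counts)[tot == 0], collapse = ", "))
  v <- sweep(cm$counts, 2, 1e6 / tot, "*")
  tag <- "cpm"
  if (log) {
    v <- log2(v + pseudocount)
    tag <- "log2cpm"
  }
  normalized_matrix(v, tag, pseudocount = if (log) pseudocount else NA_real_)
}

#' @rdname cpm_normalize
#' @param values Real matrix of normalised values (genes x samples).
#' @param scale_tag One of `"cpm"`, `"log2cpm"`, `"tpm"`.
#' @export
normalized_matrix <- function(values, scale_tag = c("cpm", "log2cpm", "tpm"),
                              pseudocount = NA_real_) {
  scale_tag <- match.arg(scale_tag)
  values <- as.matrix(values)
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("values must have gene row names and sample column names")
  structure(list(values = values, scale_tag = scale_tag, pseudocount = pseudocount),
            class = "NormalizedMatrix")
}

#' @export
print.NormalizedMatrix <- function(x, ...) {
  cat(sprintf("NormalizedMatrix: %d genes x %d samples (%s)\n",
              nrow(x$values), ncol(x$values), x$scale_tag))
  invisible(x)
}

#' Filter genes with low counts
#'
#' Keeps genes with at least `min_count` counts in at least `min_samples`
#' samples; row order is preserved.
#'
#' @param cm A [count_matrix()].
#' @param min_count Minimum count per sample (default 10).
#' @param min_samples Minimum number of samples reaching `min_count`
#'   (default 2).
#' @return Filtered [count_matrix()].
#' @export
filter_low_expression <- function(cm, min_count = 10, min_samples = 2) {
  stopifnot(inherits(cm, "CountMatrix"), min_count >= 0, min_samples >= 0)
  keep <- rowSums(cm$counts >= min_count) >= min_samples
  count_matrix(cm$counts[keep, , drop = FALSE], cm$fraction)
}

#' Sample-level PCA overview
#'
#' Principal components of the gene-centred expression matrix (samples as
#' observations), the standard first look at an RNA-seq experiment. Input
#' should be on a log scale (see [cpm_normalize()] with `log = TRUE`); genes
#' are centred but not scaled.
#'
#' @param nm A `NormalizedMatrix` on log scale.
#' @param n_components Number of components to return.
#' @return List with `coordinates` (data.frame sample x PC) and
#'   `explained_variance` (fractions, non-increasing).
#' @export
pca_overview <- function(nm, n_components = 2) {
  stopifnot(inherits(nm, "NormalizedMatrix"))
  x <- t(nm$values)  # samples x genes
  if (nrow(x) < 2) stop("PCA needs at least 2 samples")
  if (n_components > nrow(x))
    stop("n_components exceeds the number of samples")
  xc <- scale(x, center = TRUE, scale = FALSE)
  sv <- svd(xc)
  ev <- sv$d^2 / sum(sv$d^2)
  coords <- sv$u %*% diag(sv$d, nrow = length(sv$d))
  k <- min(n_components, ncol(coords))
  coords <- coords[, seq_len(k), drop = FALSE]
  dimnames(coords) <- list(rownames(x), paste0("PC", seq_len(k)))
  list(coordinates = as.data.frame(coords),
       explained_variance = ev[seq_len(k)])
}
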