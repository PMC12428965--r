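# Shared helpers: small random objects built in code, plus the shipped
# synthetic fixture location.

fixture_dir <- function() {
  system.file("extdata", "synthetic_fixture", package = "translevel")
}

random_count_matrix <- function(n_genes, n_samples, seed, lambda = 50,
                                fraction = "total") {
  set.seed(seed)
  m <- matrix(rpois(n_genes * n_samples, lambda), n_genes, n_samples,
              dimnames = list(sprintf("g%03d", seq_len(n_genes)),
                              sprintf("s%02d", seq_len(n_samples))))
  count_matrix(m, fraction)
}

# sample sheet for one fraction: n_bio biological x n_tech technical reps
# in a single condition
simple_sheet <- function(sample_ids, conditions, fraction = "total",
                         bio = NULL, tech = NULL) {
  n <- length(sample_ids)
  validate_sample_sheet(data.frame(
    sample_id = sample_ids,
    condition = rep_len(conditions, n),
    fraction = rep_len(fraction, n),
    biological_replicate = if (is.null(bio)) seq_len(n) else bio,
    technical_replicate = if (is.null(tech)) rep(1L, n) else tech,
    stringsAsFactors = FALSE))
}

random_sets <- function(n_sets, universe, seed, min_size = 5, max_size = 40) {
  set.seed(seed)
  sets <- lapply(seq_len(n_sets), function(i)
    sample(universe, sample(min_size:max_size, 1)))
  names(sets) <- paste0("set", seq_len(n_sets))
  sets
}

# adjusted Rand index between two label vectors (mclust is the oracle)
ari <- function(a, b) mclust::adjustedRandIndex(a, b)

# expression matrix with planted correlated blocks: each block shares a
# latent sample factor with loading sqrt(rho)
planted_blocks <- function(block_sizes, n_samples, rho, seed,
                           n_noise = 0) {
  set.seed(seed)
  rows <- list()
  for (b in seq_along(block_sizes)) {
    f <- rnorm(n_samples)
    rows[[b]] <- t(sapply(seq_len(block_sizes[b]), function(i)
      sqrt(rho) * f + sqrt(1 - rho) * rnorm(n_samples)))
  }
  if (n_noise > 0)
    rows[[length(rows) + 1L]] <- matrix(rnorm(n_noise * n_samples),
                                        n_noise, n_samples)
  x <- do.call(rbind, rows)
  dimnames(x) <- list(sprintf("g%04d", seq_len(nrow(x))),
                      sprintf("s%02d", seq_len(n_samples)))
  x
}

# NB two-group count simulation used by the calibration/power checks
nb_two_group <- function(n_genes, n_per_group, base_log2_mean = 6,
                         base_log2_sd = 2, phi = 0.1, seed,
                         spiked = integer(), fold = 1, spike_floor = 0) {
  set.seed(seed)
  base <- 2^rnorm(n_genes, base_log2_mean, base_log2_sd)
  if (length(spiked)) base[spiked] <- pmax(base[spiked], spike_floor)
  mu_a <- base
  mu_b <- base
  mu_b[spiked] <- mu_b[spiked] * fold
  n <- 2 * n_per_group
  counts <- cbind(
    matrix(rnbinom(n_genes * n_per_group, mu = rep(mu_a, n_per_group),
                   size = 1 / phi), n_genes),
    matrix(rnbinom(n_genes * n_per_group, mu = rep(mu_b, n_per_group),
                   size = 1 / phi), n_genes))
  dimnames(counts) <- list(sprintf("g%04d", seq_len(n_genes)),
                           sprintf("s%02d", seq_len(n)))
  count_matrix(counts, "total")
}

# paired total/polysome simulation with translation-only and/or
# transcription-only regulated genes across two conditions
nb_two_level <- function(n_genes, n_rep, phi = 0.1, seed,
                         transl_genes = integer(), transl_fold = 1,
                         trans_genes = integer(), trans_fold = 1,
                         base_log2_mean = 6, base_log2_sd = 2,
                         reg_floor = 50) {
  set.seed(seed)
  base <- 2^rnorm(n_genes, base_log2_mean, base_log2_sd)
  base[c(transl_genes, trans_genes)] <-
    pmax(base[c(transl_genes, trans_genes)], reg_floor)
  te <- 2^rnorm(n_genes, 0, 0.5)
  cond <- rep(c("A", "B"), each = 2 * n_rep)
  frac <- rep(rep(c("total", "polysome"), each = n_rep), 2)
  mu <- outer(base, rep(1, 4 * n_rep))
  mu[, frac == "polysome"] <- mu[, frac == "polysome"] * te
  mu[transl_genes, frac == "polysome" & cond == "B"] <-
    mu[transl_genes, frac == "polysome" & cond == "B"] * transl_fold
  mu[trans_genes, cond == "B"] <- mu[trans_genes, cond == "B"] * trans_fold
  counts <- matrix(rnbinom(length(mu), mu = mu, size = 1 / phi),
                   nrow = n_genes)
  ids <- paste0(cond, "_", frac, "_b", rep(rep(seq_len(n_rep), 2), 2))
  dimnames(counts) <- list(sprintf("g%04d", seq_len(n_genes)), ids)
  ss <- data.frame(sample_id = ids, condition = cond, fraction = frac,
                   biological_replicate = rep(rep(seq_len(n_rep), 2), 2),
                   technical_replicate = 1L, stringsAsFactors = FALSE)
  list(total = count_matrix(counts[, frac == "total"], "total"),
       polysome = count_matrix(counts[, frac == "polysome"], "polysome"),
       sheet = validate_sample_sheet(ss))
}
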