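test_that("the generator is deterministic given its seed", {
  cfg <- simulation_config(n_genes = 120, n_stable_core = 20,
                           n_transcription_up = c(Hardening = 10),
                           n_transcription_down = c(Hardening = 10),
                           n_translation_up = c(Stress = 10),
                           n_translation_down = c(Stress = 10),
                           n_modules = 0, library_size_mean = 1e5, seed = 99)
  a <- simulate_experiment(cfg)
  b <- simulate_experiment(cfg)
  expect_identical(a$total$counts, b$total$counts)
  expect_identical(a$polysome$counts, b$polysome$counts)
  expect_identical(a$truth, b$truth)
})

test_that("null simulation concentrates around its baselines", {
  cfg <- simulation_config(n_genes = 800, n_stable_core = 0,
                           n_transcription_up = c(Hardening = 0),
                           n_transcription_down = c(Hardening = 0),
                           n_translation_up = c(Stress = 0),
                           n_translation_down = c(Stress = 0),
                           n_modules = 0, seed = 41)
  sim <- simulate_experiment(cfg)
  cpm <- cpm_normalize(collapse_technical_replicates(sim$total,
                                                     sim$sample_sheet))
  expected <- 2^sim$truth$baseline_log2
  expected <- expected / sum(expected) * 1e6
  ratio <- rowMeans(cpm$values) / expected
  hi <- expected >= 50
  expect_gte(mean(ratio[hi] >= 0.8 & ratio[hi] <= 1.25), 0.98)
  expect_equal(median(ratio[hi]), 1, tolerance = 0.05)
})

test_that("planted translational effects shift the poly/total ratio", {
  cfg <- simulation_config(n_genes = 2000, n_stable_core = 50,
                           n_transcription_up = c(Hardening = 0),
                           n_transcription_down = c(Hardening = 0),
                           n_translation_up = c(Stress = 60),
                           n_translation_down = c(Stress = 0),
                           n_modules = 0, seed = 42)
  sim <- simulate_experiment(cfg)
  tot <- collapse_technical_replicates(sim$total, sim$sample_sheet)
  pol <- collapse_technical_replicates(sim$polysome, sim$sample_sheet)
  sheet <- rbind(attr(tot, "sample_sheet"), attr(pol, "sample_sheet"))
  sheet$technical_replicate <- 1L
  tr <- translational_ratio(cpm_normalize(tot), cpm_normalize(pol), sheet)
  up <- sim$truth$transl_Stress > 0
  shift <- tr$values[, "Stress"] - tr$values[, "Control"]
  expect_equal(median(shift[up]), 2, tolerance = 0.25)
  # unregulated genes: no systematic shift (signed median isolates bias
  # from the per-gene sampling noise of the plug-in ratio)
  expect_lte(abs(median(shift[!up])), 0.25)
})

test_that("simulated counts match negative-binomial moments", {
  # flat baselines: one column's counts are iid NB after binomial thinning,
  # which preserves the dispersion phi
  cfg <- simulation_config(n_genes = 10000, n_stable_core = 0,
                           baseline_log2_sd = 0,
                           n_transcription_up = c(Hardening = 0),
                           n_transcription_down = c(Hardening = 0),
                           n_translation_up = c(Stress = 0),
                           n_translation_down = c(Stress = 0),
                           base_te_log2_sd = 0,
                           n_modules = 0, phi = 0.1, seed = 7)
  sim <- simulate_experiment(cfg)
  y <- sim$total$counts[, 1]
  m <- mean(y); v <- var(y)
  expect_equal(v / (m + 0.1 * m^2), 1, tolerance = 0.1)
})

test_that("fixtures round-trip through files and the shipped copy matches", {
  cfg <- fixture_config()
  sim <- simulate_experiment(cfg)
  ann <- simulate_annotation(sim$truth, n_terms = 25,
                             term_size_range = c(8, 25), seed = 20260901)
  d <- withr::local_tempdir()
  write_fixture(sim, d, annotation = ann)
  back <- read_counts(file.path(d, "counts_total.tsv"), "total")
  expect_equal(back$counts, sim$total$counts)
  expect_equal(as.data.frame(read_sample_sheet(file.path(d, "sample_sheet.tsv"))),
               as.data.frame(sim$sample_sheet))
  expect_equal(read_gmt(file.path(d, "annotation.gmt"))$sets, ann$sets)

  # shipped fixture: the documented config reproduces it exactly
  fd <- fixture_dir()
  shipped_total <- read_counts(file.path(fd, "counts_total.tsv"), "total")
  shipped_poly <- read_counts(file.path(fd, "counts_polysome.tsv"), "polysome")
  expect_equal(shipped_total$counts, sim$total$counts)
  expect_equal(shipped_poly$counts, sim$polysome$counts)
  expect_equal(ncol(shipped_total$counts) + ncol(shipped_poly$counts), 48L)
  truth <- utils::read.delim(file.path(fd, "truth.tsv"))
  expect_equal(nrow(truth), cfg$n_genes)
})
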