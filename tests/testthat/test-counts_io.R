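test_that("count matrices read back exactly what was written", {
  p <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene_id\ts1\ts2", "gA\t5\t0", "gB\t3\t7"), p)
  cm <- read_counts(p)
  expect_equal(unname(cm$counts), matrix(c(5, 3, 0, 7), 2))
  expect_equal(rownames(cm$counts), c("gA", "gB"))

  cm2 <- random_count_matrix(50, 8, seed = 7)
  p2 <- withr::local_tempfile(fileext = ".tsv")
  write_counts(cm2, p2)
  expect_equal(read_counts(p2)$counts, cm2$counts)
})

test_that("malformed count files are rejected with the offending location", {
  p <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene_id\ts1", "gA\t1", "gA\t2"), p)
  expect_error(read_counts(p), "gA")
  writeLines(c("gene_id\ts1", "gA\t1.5"), p)
  expect_error(read_counts(p), "non-integer")
  expect_error(count_matrix(matrix(-1, 1, 1, dimnames = list("g", "s"))),
               "nonnegative")
})

test_that("technical replicates collapse by summation and conserve totals", {
  m <- matrix(c(3, 10, 4, 20), 2, 2,
              dimnames = list(c("g1", "g2"), c("a_t1", "a_t2")))
  cm <- count_matrix(m)
  ss <- simple_sheet(c("a_t1", "a_t2"), "Control", bio = c(1, 1),
                     tech = c(1, 2))
  out <- collapse_technical_replicates(cm, ss)
  expect_equal(ncol(out$counts), 1L)
  expect_equal(unname(out$counts[, 1]), c(7, 30))

  # a single technical repeat passes through unchanged
  one <- collapse_technical_replicates(
    count_matrix(m[, 1, drop = FALSE]),
    simple_sheet("a_t1", "Control", bio = 1, tech = 1))
  expect_equal(unname(one$counts[, 1]), unname(m[, 1]))

  # grand total conserved on a random 4-pair design
  cm2 <- random_count_matrix(20, 8, seed = 3)
  ss2 <- simple_sheet(colnames(cm2$counts), "Control",
                      bio = rep(1:4, each = 2), tech = rep(1:2, 4))
  out2 <- collapse_technical_replicates(cm2, ss2)
  expect_equal(ncol(out2$counts), 4L)
  expect_equal(sum(out2$counts), sum(cm2$counts))

  expect_error(
    collapse_technical_replicates(cm2, ss2[-1, ]), "unannotated")
})

test_that("cpm normalisation scales columns to one million", {
  m <- matrix(c(1, 1, 2), 3, 1, dimnames = list(paste0("g", 1:3), "s1"))
  nm <- cpm_normalize(count_matrix(m))
  expect_equal(unname(nm$values[, 1]), c(250000, 250000, 500000))

  cm <- random_count_matrix(100, 6, seed = 11)
  nm2 <- cpm_normalize(cm)
  expect_equal(unname(colSums(nm2$values)), rep(1e6, 6), tolerance = 1e-6)
  # within-column proportions conserved
  expect_equal(nm2$values[1, 1] / nm2$values[2, 1],
               cm$counts[1, 1] / cm$counts[2, 1])

  # log transform is monotone in the raw counts within each column
  lg <- cpm_normalize(cm, log = TRUE, pseudocount = 1)
  for (j in 1:6)
    expect_equal(order(lg$values[, j], rownames(lg$values)),
                 order(cm$counts[, j], rownames(cm$counts)))

  z <- count_matrix(matrix(c(1, 2, 0, 0), 2, 2,
                           dimnames = list(c("g1", "g2"), c("ok", "bad"))))
  expect_error(cpm_normalize(z), "bad")
})

test_that("low-expression filter matches a brute-force row scan", {
  m <- matrix(c(0, 0, 1), 1, 3, dimnames = list("g1", paste0("s", 1:3)))
  expect_equal(nrow(filter_low_expression(count_matrix(m), 5, 2)$counts), 0L)
  cm <- random_count_matrix(200, 6, seed = 5, lambda = 12)
  expect_equal(filter_low_expression(cm, 0, 0)$counts, cm$counts)
  f <- filter_low_expression(cm, 10, 3)
  brute <- rownames(cm$counts)[apply(cm$counts, 1,
                                     function(r) sum(r >= 10) >= 3)]
  expect_equal(rownames(f$counts), brute)
})

test_that("pca overview separates constructed groups and orders variance", {
  set.seed(2)
  ns <- 10
  shift <- rep(c(0, 5), each = ns / 2)
  x <- t(sapply(1:60, function(i) shift + rnorm(ns, sd = 0.5)))
  dimnames(x) <- list(sprintf("g%02d", 1:60), sprintf("s%02d", 1:ns))
  p <- pca_overview(normalized_matrix(x, "log2cpm"), 3)
  pc1 <- p$coordinates[, 1]
  g1 <- pc1[1:(ns / 2)]; g2 <- pc1[(ns / 2 + 1):ns]
  expect_true(max(range(g1)) < min(range(g2)) ||
                min(range(g1)) > max(range(g2)))
  expect_true(all(diff(p$explained_variance) <= 1e-12))
  expect_lte(sum(p$explained_variance), 1 + 1e-12)

  # duplicated samples land on identical coordinates
  x2 <- cbind(x, dup = x[, 1])
  colnames(x2)[ncol(x2)] <- "dup"
  p2 <- pca_overview(normalized_matrix(x2, "log2cpm"), 2)
  expect_equal(unname(unlist(p2$coordinates["s01", ])),
               unname(unlist(p2$coordinates["dup", ])))

  expect_error(pca_overview(normalized_matrix(x, "log2cpm"), 99),
               "n_components")
})

test_that("sample sheets validate their key invariants", {
  ss <- simple_sheet(c("a", "b"), "Control")
  expect_s3_class(ss, "SampleSheet")
  bad <- as.data.frame(ss)
  bad$sample_id <- c("a", "a")
  bad$biological_replicate <- c(1, 1)
  expect_error(validate_sample_sheet(bad), "duplicate")
  p <- withr::local_tempfile(fileext = ".tsv")
  write_sample_sheet(ss, p)
  expect_equal(as.data.frame(read_sample_sheet(p)), as.data.frame(ss))
})
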