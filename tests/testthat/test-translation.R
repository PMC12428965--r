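make_paired_nm <- function(total_vals, poly_vals, conds) {
  ids_t <- paste0(conds, "_total_b", seq_along(conds))
  ids_p <- paste0(conds, "_polysome_b", seq_along(conds))
  colnames(total_vals) <- ids_t
  colnames(poly_vals) <- ids_p
  ss <- validate_sample_sheet(data.frame(
    sample_id = c(ids_t, ids_p),
    condition = rep(conds, 2),
    fraction = rep(c("total", "polysome"), each = length(conds)),
    biological_replicate = rep(seq_along(conds), 2),
    technical_replicate = 1L, stringsAsFactors = FALSE))
  list(total = normalized_matrix(total_vals, "cpm"),
       poly = normalized_matrix(poly_vals, "cpm"), ss = ss)
}

test_that("translational ratio follows log2(poly/total) with pseudocount", {
  tot <- matrix(c(100, 100, 0), 3, 1, dimnames = list(paste0("g", 1:3), NULL))
  pol <- matrix(c(400, 100, 7), 3, 1, dimnames = list(paste0("g", 1:3), NULL))
  x <- make_paired_nm(tot, pol, "Control")
  tr0 <- translational_ratio(x$total, x$poly, x$ss, pseudocount = 0)
  expect_equal(unname(tr0$values[1:2, 1]), c(2, 0))
  tr <- translational_ratio(x$total, x$poly, x$ss, pseudocount = 0.5)
  expect_equal(unname(tr$values[3, 1]), log2(7.5 / 0.5), tolerance = 1e-4)

  # swapping the fractions negates every value
  sw <- make_paired_nm(pol, tot, "Control")
  sw$ss$fraction <- rev(sw$ss$fraction)  # poly columns now named as total
  tr_fwd <- translational_ratio(x$total, x$poly, x$ss)
  x_sw <- make_paired_nm(pol, tot, "Control")
  tr_rev <- translational_ratio(x_sw$total, x_sw$poly, x_sw$ss)
  expect_equal(tr_rev$values, -tr_fwd$values)
})

test_that("delta TR is the antisymmetric difference of units", {
  v <- matrix(c(2, -1, 0.5, -1, 3, 0), 3, 2,
              dimnames = list(paste0("g", 1:3), c("A", "B")))
  tr <- structure(list(values = v, mode = "ratio", pseudocount = 0.5),
                  class = "TRMatrix")
  d <- delta_tr(tr, "A", "B")
  expect_equal(d$deltaTR[1], 2 - (-1))
  expect_equal(delta_tr(tr, "A", "A")$deltaTR, rep(0, 3))

  set.seed(9)
  v2 <- matrix(rnorm(40), 10, 4,
               dimnames = list(paste0("g", 1:10), LETTERS[1:4]))
  tr2 <- structure(list(values = v2, mode = "ratio", pseudocount = 0.5),
                   class = "TRMatrix")
  expect_equal(delta_tr(tr2, "B", "C")$deltaTR,
               -delta_tr(tr2, "C", "B")$deltaTR)
  expect_error(delta_tr(tr2, "A", "Z"), "unknown unit")
})

test_that("renormalisation to one million preserves within-column ranks", {
  set.seed(4)
  v <- matrix(rnorm(60), 20, 3,
              dimnames = list(sprintf("g%02d", 1:20), c("A", "B", "C")))
  tr <- structure(list(values = v, mode = "ratio", pseudocount = 0.5),
                  class = "TRMatrix")
  nm <- tr_normalize_million(tr)
  expect_equal(unname(colSums(nm$values)), rep(1e6, 3), tolerance = 1e-6)
  for (j in 1:3)
    expect_equal(order(nm$values[, j]), order(2^v[, j]))
  # constant column: equal shares
  trc <- structure(list(values = matrix(1.3, 5, 1,
                                        dimnames = list(paste0("g", 1:5), "A")),
                        mode = "ratio", pseudocount = 0.5),
                   class = "TRMatrix")
  expect_equal(unname(tr_normalize_million(trc)$values[, 1]),
               rep(1e6 / 5, 5))
})

test_that("interaction estimate agrees with the plug-in delta TR", {
  sim <- nb_two_level(400, 3, seed = 31, transl_genes = 1:60,
                      transl_fold = 4, reg_floor = 50)
  dt <- test_differential_translation(sim$total, sim$polysome, sim$sheet,
                                      "A", "B")
  tot_nm <- cpm_normalize(sim$total)
  pol_nm <- cpm_normalize(sim$polysome)
  tr <- translational_ratio(tot_nm, pol_nm, sim$sheet)
  plug <- delta_tr(tr, "B", "A")
  mean_cpm <- rowMeans(tot_nm$values)
  keep <- mean_cpm >= 50
  expect_lte(median(abs(dt$deltaTR[keep] - plug$deltaTR[keep])), 0.2)
})

test_that("unpairable samples are rejected with the orphans listed", {
  x <- make_paired_nm(matrix(1:4, 2, 2, dimnames = list(c("g1", "g2"), NULL)),
                      matrix(1:4, 2, 2, dimnames = list(c("g1", "g2"), NULL)),
                      c("Control", "Stress"))
  ss <- x$ss[x$ss$condition != "Stress" | x$ss$fraction != "polysome", ]
  vals <- x$poly$values[, 1, drop = FALSE]
  expect_error(
    translational_ratio(x$total, normalized_matrix(vals, "cpm"), ss),
    "unpairable|missing")
})
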