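# hub-and-spoke latent expression whose connectivity spans a wide range,
# giving an approximately scale-free weighted network
hub_spoke_expression <- function(n_genes, n_samples, seed) {
  set.seed(seed)
  n_hub <- 5
  fac <- matrix(rnorm(n_hub * n_samples), n_hub, n_samples)
  memb <- sample(n_hub, n_genes, replace = TRUE, prob = (1:n_hub)^-1)
  w <- runif(n_genes, 0.2, 0.95)^2
  x <- t(sapply(seq_len(n_genes), function(i)
    sqrt(w[i]) * fac[memb[i], ] + sqrt(1 - w[i]) * rnorm(n_samples)))
  dimnames(x) <- list(sprintf("g%04d", seq_len(n_genes)),
                      sprintf("s%02d", seq_len(n_samples)))
  x
}

test_that("soft-threshold selection finds scale-free structure and flags noise", {
  x <- hub_spoke_expression(200, 20, seed = 17)
  st <- pick_soft_threshold(x)
  expect_false(st$low_fit)
  expect_equal(nrow(st$fit_table), 20L)
  sel <- st$fit_table[st$fit_table$power == st$beta, ]
  expect_gte(sel$fit, 0.8)
  expect_true(sel$eligible)
  # smallest qualifying power is returned
  earlier <- st$fit_table[st$fit_table$power < st$beta &
                            st$fit_table$eligible, ]
  expect_true(all(earlier$fit < 0.8))

  set.seed(18)
  noise <- matrix(rnorm(200 * 20), 200, 20,
                  dimnames = dimnames(x))
  expect_warning(stn <- pick_soft_threshold(noise), "maximum-fit")
  expect_true(stn$low_fit)
  elig <- stn$fit_table[stn$fit_table$eligible, ]
  expect_true(all(elig$fit < 0.8))
})

test_that("adjacency matches its elementwise definition", {
  x <- rbind(g1 = c(1, 2, 3, 4), g2 = c(2, 4, 6, 8), g3 = c(4, 3, 2, 1))
  colnames(x) <- paste0("s", 1:4)
  a_u <- adjacency(x, beta = 5, mode = "unsigned")$adjacency
  expect_equal(a_u["g1", "g2"], 1)   # perfectly correlated pair
  a_s <- adjacency(x, beta = 2, mode = "signed")$adjacency
  expect_equal(a_s["g1", "g3"], 0)   # perfectly anti-correlated pair

  set.seed(20)
  y <- matrix(rnorm(300), 30, 10,
              dimnames = list(sprintf("g%02d", 1:30), sprintf("s%02d", 1:10)))
  a <- adjacency(y, beta = 6)$adjacency
  cc <- cor(t(y))
  for (i in c(1, 7, 30)) for (j in c(2, 15))
    expect_equal(a[i, j], abs(cc[i, j])^6, tolerance = 1e-12)
  expect_equal(unname(diag(a)), rep(1, 30))

  y[1, ] <- 5
  expect_error(adjacency(y, 6), "zero-variance")
})

test_that("topological overlap equals the triple-loop brute force", {
  ones <- matrix(1, 3, 3, dimnames = list(paste0("g", 1:3), paste0("g", 1:3)))
  net <- structure(list(adjacency = ones, beta = 1, mode = "unsigned"),
                   class = "Network")
  tom <- topological_overlap(net)
  expect_equal(tom["g1", "g2"], 1)  # (1 + 1) / (2 + 1 - 1)

  eye <- diag(3)
  dimnames(eye) <- dimnames(ones)
  net0 <- structure(list(adjacency = eye, beta = 1, mode = "unsigned"),
                    class = "Network")
  expect_equal(sum(topological_overlap(net0)) - 3, 0)

  set.seed(23)
  x <- matrix(rnorm(100), 10, 10,
              dimnames = list(sprintf("g%02d", 1:10), sprintf("s%02d", 1:10)))
  net1 <- adjacency(x, beta = 4)
  tom1 <- topological_overlap(net1)
  a <- net1$adjacency
  diag(a) <- 0
  brute <- diag(10)
  for (i in 1:10) for (j in 1:10) {
    if (i == j) next
    l <- sum(sapply(setdiff(1:10, c(i, j)), function(u) a[i, u] * a[u, j]))
    ki <- sum(a[i, -i]); kj <- sum(a[j, -j])
    brute[i, j] <- (l + a[i, j]) / (min(ki, kj) + 1 - a[i, j])
  }
  expect_equal(unname(tom1), brute, tolerance = 1e-12)
})

test_that("planted blocks are recovered and noise stays grey", {
  x <- planted_blocks(c(50, 50), 16, rho = 0.8, seed = 25)
  tom <- topological_overlap(adjacency(x, beta = 6))
  ma <- detect_modules(tom, min_module_size = 30)
  expect_equal(length(setdiff(names(ma$sizes), "grey")), 2L)
  truth <- rep(1:2, each = 50)
  expect_gte(ari(ma$labels, truth), 0.8)

  set.seed(26)
  noise <- matrix(rnorm(100 * 16), 100, 16,
                  dimnames = list(sprintf("g%04d", 1:100),
                                  sprintf("s%02d", 1:16)))
  man <- detect_modules(topological_overlap(adjacency(noise, beta = 6)),
                        min_module_size = 30)
  expect_gte(mean(man$labels == "grey"), 0.6)

  # permuting gene order changes labels at most, not the partition
  perm <- sample(nrow(x))
  ma_p <- detect_modules(topological_overlap(adjacency(x[perm, ], beta = 6)),
                         min_module_size = 30)
  expect_equal(ari(ma_p$labels[rownames(x)], ma$labels), 1)
})

test_that("module eigengenes are optimal unit-norm summaries", {
  prof <- c(1, -1, 2, 0.5, -2, 1.5)
  x <- matrix(rep(prof, each = 4), 4, 6,
              dimnames = list(paste0("g", 1:4), paste0("s", 1:6)))
  ma <- structure(list(labels = setNames(rep("peachpuff", 4), rownames(x)),
                       sizes = c(peachpuff = 4L, grey = 0L)),
                  class = "ModuleAssignment")
  eg <- module_eigengene(x, ma)
  std <- as.numeric(scale(prof))
  expect_equal(abs(cor(eg["peachpuff", ], std)), 1)
  expect_gte(cor(eg["peachpuff", ], std), 0)  # sign convention
  expect_equal(sum(eg["peachpuff", ]^2), 1)

  # flipping all genes flips the eigengene
  eg_f <- module_eigengene(-x, ma)
  expect_equal(eg_f["peachpuff", ], -eg["peachpuff", ])

  # optimality: no other unit vector explains more variance (seed 27)
  set.seed(27)
  y <- matrix(rnorm(20 * 8), 20, 8,
              dimnames = list(sprintf("g%02d", 1:20), sprintf("s%02d", 1:8)))
  ma2 <- structure(list(labels = setNames(rep("coral", 20), rownames(y)),
                        sizes = c(coral = 20L, grey = 0L)),
                   class = "ModuleAssignment")
  eg2 <- module_eigengene(y, ma2)
  ystd <- t(scale(t(y)))
  var_of <- function(v) sum((ystd %*% v)^2)
  v1 <- eg2["coral", ]
  for (i in 1:25) {
    r <- rnorm(8); r <- r / sqrt(sum(r^2))
    expect_gte(var_of(v1) + 1e-9, var_of(r))
  }
  sv <- svd(ystd)
  expect_equal(var_of(v1), sv$d[1]^2, tolerance = 1e-9)
})

test_that("module-trait p-values follow the closed-form t-transform", {
  expect_equal(round(correlation_pvalue(-0.98, 4), 2), 0.02)
  expect_equal(round(correlation_pvalue(-0.97, 4), 3), 0.030)
  expect_equal(correlation_pvalue(1, 10), 0)
  expect_equal(correlation_pvalue(0.5, 20),
               2 * pt(-0.5 * sqrt(18) / sqrt(0.75), 18),
               tolerance = 1e-12)

  eg <- matrix(c(1, 2, 3, 4), 1, 4,
               dimnames = list("peachpuff", paste0("s", 1:4)))
  traits <- data.frame(Control = c(1, 2, 3, 4), flat = rep(1, 4),
                       row.names = paste0("s", 1:4))
  mt <- module_trait_correlation(eg, traits)
  expect_equal(mt$r[mt$trait == "Control"], 1)
  expect_equal(mt$p[mt$trait == "Control"], 0)
  expect_true(is.na(mt$r[mt$trait == "flat"]))
  expect_equal(unique(mt$n), 4L)
})

test_that("hub genes rank by eigengene membership", {
  set.seed(29)
  ns <- 12
  f <- rnorm(ns)
  load <- c(0.95, rep(0.5, 9))
  x <- t(sapply(seq_along(load), function(i)
    load[i] * f + sqrt(1 - load[i]^2) * rnorm(ns)))
  dimnames(x) <- list(sprintf("g%02d", seq_along(load)),
                      sprintf("s%02d", 1:ns))
  ma <- structure(list(labels = setNames(rep("brown", 10), rownames(x)),
                       sizes = c(brown = 10L, grey = 0L)),
                  class = "ModuleAssignment")
  eg <- module_eigengene(x, ma)
  h <- hub_genes(x, ma, eg, top_n = 5)
  expect_equal(h$gene_id[h$rank == 1], "g01")
  expect_true(all(diff(h$kME) <= 1e-12))
  h_all <- hub_genes(x, ma, eg, top_n = 50)
  expect_equal(nrow(h_all), 10L)

  # a module whose eigengene is one gene's profile puts that gene first
  solo <- x[1, , drop = FALSE]
  ma1 <- structure(list(labels = setNames("coral", "g01"),
                        sizes = c(coral = 1L, grey = 0L)),
                   class = "ModuleAssignment")
  eg1 <- module_eigengene(solo, ma1)
  h1 <- hub_genes(solo, ma1, eg1)
  expect_equal(h1$kME, 1)
})
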