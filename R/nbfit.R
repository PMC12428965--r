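# Internal negative-binomial GLM machinery shared by the differential
# expression and differential translation tests. Log link, fixed dispersion
# phi (var = mu + phi * mu^2); phi = 0 falls back to Poisson.

nb_loglik <- function(y, mu, phi) {
  mu <- pmax(mu, 1e-10)
  if (phi <= 0) sum(stats::dpois(y, mu, log = TRUE))
  else sum(stats::dnbinom(y, size = 1 / phi, mu = mu, log = TRUE))
}

# IRLS fit of a NB GLM with offsets and fixed dispersion.
nb_glm_fit <- function(y, X, offset, phi, maxit = 50L, tol = 1e-8) {
  beta <- qr.solve(X, log(y + 0.5) - offset)
  ll_old <- -Inf
  ll <- NA_real_
  for (it in seq_len(maxit)) {
    eta <- pmin(pmax(drop(X %*% beta) + offset, -30), 30)
    mu <- exp(eta)
    W <- mu^2 / (mu + phi * mu^2)
    z <- (eta - offset) + (y - mu) / mu
    XtW <- t(X * W)
    beta <- tryCatch(drop(solve(XtW %*% X, XtW %*% z)),
                     error = function(e) beta)
    mu <- exp(pmin(pmax(drop(X %*% beta) + offset, -30), 30))
    ll <- nb_loglik(y, mu, phi)
    if (is.finite(ll) && is.finite(ll_old) && abs(ll - ll_old) < tol) break
    ll_old <- ll
  }
  list(beta = beta, loglik = ll)
}

# Per-gene likelihood-ratio test of nested NB GLMs; returns the chi-square
# p-value for the dropped coefficient(s) and the full-model coefficients.
nb_lrt <- function(counts, X1, X0, offset, phi) {
  n <- nrow(counts)
  p <- numeric(n)
  beta <- matrix(NA_real_, n, ncol(X1))
  df <- ncol(X1) - ncol(X0)
  allzero <- rowSums(counts) == 0
  for (g in seq_len(n)) {
    if (allzero[g]) {
      p[g] <- 1
      beta[g, ] <- 0
      next
    }
    y <- counts[g, ]
    f1 <- nb_glm_fit(y, X1, offset, phi[g])
    f0 <- nb_glm_fit(y, X0, offset, phi[g])
    stat <- max(0, 2 * (f1$loglik - f0$loglik))
    p[g] <- stats::pchisq(stat, df = df, lower.tail = FALSE)
    beta[g, ] <- f1$beta
  }
  list(p_value = p, beta = beta, all_zero = allzero)
}

# Common dispersion by Cox-Reid adjusted profile likelihood under a
# group-means model. The unadjusted profile MLE is biased low at small
# replicate numbers because the fitted group means consume degrees of
# freedom; the CR term (0.5 * log det of the Fisher information of the mean
# parameters) removes most of that bias.
nb_common_dispersion <- function(counts, groups, size_factors, n_subset = 300L,
                                 min_mean = 5) {
  keep <- which(rowMeans(counts) > min_mean)
  if (!length(keep)) keep <- seq_len(nrow(counts))
  idx <- keep[unique(round(seq(1, length(keep),
                               length.out = min(n_subset, length(keep)))))]
  gl <- split(seq_along(groups), groups)
  ys <- lapply(gl, function(ii) counts[idx, ii, drop = FALSE])
  mus <- lapply(gl, function(ii) {
    m <- rowMeans(sweep(counts[idx, ii, drop = FALSE], 2, size_factors[ii], "/"))
    pmax(outer(m, size_factors[ii]), 1e-8)
  })
  negll <- function(lphi) {
    phi <- exp(lphi)
    tot <- 0
    for (k in seq_along(gl)) {
      mu <- mus[[k]]
      W <- mu / (1 + phi * mu)
      tot <- tot -
        sum(stats::dnbinom(ys[[k]], size = 1 / phi, mu = mu, log = TRUE)) +
        0.5 * sum(log(pmax(rowSums(W), 1e-12)))
    }
    tot
  }
  exp(stats::optimize(negll, c(log(1e-4), log(5)))$minimum)
}

row_vars <- function(m) {
  n <- ncol(m)
  if (n < 2) return(rep(NA_real_, nrow(m)))
  mu <- rowMeans(m)
  rowSums((m - mu)^2) / (n - 1)
}
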