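# Independent oracles used across the suite. These deliberately avoid the
# package's own computational paths.

# union-find connectivity oracle over the treatment graph
uf_connected <- function(treatments, study_treatments) {
  parent <- stats::setNames(treatments, treatments)
  find <- function(x) {
    while (parent[[x]] != x) x <- parent[[x]]
    x
  }
  for (trts in study_treatments) {
    if (length(trts) < 2) next
    for (b in trts[-1]) {
      ra <- find(trts[1]); rb <- find(b)
      if (ra != rb) parent[[ra]] <- rb
    }
  }
  length(unique(vapply(treatments, find, ""))) == 1L
}

# plain-R ordered probit/logit category probabilities
r_cat_probs <- function(eta, cuts, link = "probit") {
  F <- if (link == "probit") pnorm else plogis
  q <- sapply(cuts, function(a) F(eta - a))
  q <- matrix(q, nrow = length(eta))
  cbind(1 - q[, 1],
        if (ncol(q) > 1) q[, -ncol(q), drop = FALSE] - q[, -1, drop = FALSE],
        q[, ncol(q)])
}

# directly-coded ordinal NMA log-likelihood for a no-covariate network:
# individual rows (study, trt, y) and arm rows (study, trt, counts)
r_ordinal_nma_loglik <- function(ipd_df, agd_arms, mu, gamma, cuts,
                                 link = "probit") {
  ll <- 0
  if (!is.null(ipd_df) && nrow(ipd_df)) {
    for (i in seq_len(nrow(ipd_df))) {
      eta <- mu[[ipd_df$study[i]]] + gamma[[ipd_df$trt[i]]]
      p <- r_cat_probs(eta, cuts, link)[1, ]
      ll <- ll + log(p[ipd_df$y[i]])
    }
  }
  if (!is.null(agd_arms)) {
    for (a in seq_along(agd_arms)) {
      arm <- agd_arms[[a]]
      eta <- mu[[arm$study]] + gamma[[arm$trt]]
      p <- r_cat_probs(eta, cuts, link)[1, ]
      ll <- ll + sum(arm$counts * log(p))
    }
  }
  ll
}

# explicit multivariate normal log density (solve/determinant route)
r_mvn_logdens <- function(x, mean, Sigma) {
  m <- length(x)
  d <- x - mean
  -0.5 * (m * log(2 * pi) + determinant(Sigma, logarithm = TRUE)$modulus[1] +
            as.numeric(t(d) %*% solve(Sigma, d)))
}

# Monte Carlo oracle for grid-averaged category probabilities: draws
# covariates from the same marginals + Gaussian copula by plain MC
r_mc_avg_probs <- function(marginals, correlation, n_mc, mu, coefs, eff, cuts,
                           centers, scales, link = "probit") {
  d <- length(marginals)
  L <- chol(correlation + diag(1e-10, d))
  Z <- matrix(rnorm(n_mc * d), n_mc, d) %*% L
  X <- matrix(0, n_mc, d)
  for (j in seq_len(d)) {
    mj <- marginals[[j]]
    u <- pnorm(Z[, j])
    X[, j] <- switch(mj$family,
      gamma = qgamma(u, shape = mj$shape, rate = mj$rate),
      scaled_logit_normal = mj$lower + (mj$upper - mj$lower) *
        plogis(qnorm(u, mj$mu, mj$sigma)),
      bernoulli = as.numeric(u > 1 - mj$prob))
  }
  Xt <- sweep(sweep(X, 2, centers), 2, scales, "/")
  eta <- mu + as.numeric(Xt %*% coefs) + eff
  P <- r_cat_probs(eta, cuts, link)
  list(mean = colMeans(P), se = apply(P, 2, sd) / sqrt(n_mc))
}

# fine-grid bisection oracle for the baseline-anchoring intercept
r_bisect_mustar <- function(f, target, lo = -40, hi = 40, tol = 1e-10) {
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (f(mid) < target) lo <- mid else hi <- mid
    if (hi - lo < tol) break
  }
  (lo + hi) / 2
}
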