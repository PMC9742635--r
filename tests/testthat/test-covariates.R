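test_that("gamma moment matching is exact in closed form and by quadrature", {
  expect_equal(gamma_from_moments(2, 1), list(shape = 4, rate = 2))
  # mean = sd gives the exponential
  expect_equal(gamma_from_moments(3, 3)$shape, 1)
  expect_error(gamma_from_moments(-1, 1), "positive")
  expect_error(gamma_from_moments(1, 0), "positive")

  # duration-like summaries: numerically integrated moments match to 1e-8
  gp <- gamma_from_moments(18.2, 12.0)
  m1 <- integrate(function(x) x * dgamma(x, gp$shape, gp$rate), 0, Inf,
                  rel.tol = 1e-12)$value
  m2 <- integrate(function(x) x^2 * dgamma(x, gp$shape, gp$rate), 0, Inf,
                  rel.tol = 1e-12)$value
  expect_equal(m1, 18.2, tolerance = 1e-8)
  expect_equal(sqrt(m2 - m1^2), 12.0, tolerance = 1e-8)
})

test_that("scaled logit-normal solver matches quadrature moments", {
  # symmetric case: mean at the midpoint gives mu = 0
  fit <- logitnormal_from_moments(50, 10, 0, 100)
  expect_equal(fit$mu, 0, tolerance = 1e-6)

  # BSA-like summaries
  fit <- logitnormal_from_moments(29.8, 15, 0, 100)
  mom <- mlnmr:::logitnormal_moments(fit$mu, fit$sigma, 0, 100)
  expect_equal(unname(mom["mean"]), 29.8, tolerance = 1e-6)
  expect_equal(unname(mom["sd"]), 15, tolerance = 1e-4)

  # degenerate limit: sd -> 0 collapses to the logit of the scaled mean
  fit0 <- logitnormal_from_moments(29.8, 0, 0, 100)
  expect_equal(fit0$sigma, 0)
  expect_equal(fit0$mu, qlogis(0.298))

  # infeasible sd (exceeds the Bernoulli bound on the support)
  expect_error(logitnormal_from_moments(50, 51, 0, 100), "infeasible")
})

test_that("moment-matching solvers are idempotent", {
  gp <- gamma_from_moments(89.3, 20)
  m <- gp$shape / gp$rate; s <- sqrt(gp$shape) / gp$rate
  gp2 <- gamma_from_moments(m, s)
  expect_equal(gp2, gp, tolerance = 1e-12)

  ln <- logitnormal_from_moments(29.8, 15, 0, 100)
  mom <- mlnmr:::logitnormal_moments(ln$mu, ln$sigma, 0, 100)
  ln2 <- logitnormal_from_moments(mom[["mean"]], mom[["sd"]], 0, 100)
  expect_equal(ln2$mu, ln$mu, tolerance = 1e-4)
  expect_equal(ln2$sigma, ln$sigma, tolerance = 1e-4)
})

test_that("pooled correlation is the weighted elementwise average", {
  set.seed(9)
  mk <- function(study, n) {
    X <- matrix(rnorm(n * 3), n, 3)
    X[, 2] <- X[, 2] + 0.5 * X[, 1]
    df <- data.frame(trt = rep(c("PBO", "A"), length.out = n),
                     a = X[, 1], b = X[, 2], c = X[, 3],
                     y = sample(1:2, n, TRUE))
    structure(list(study = study, treatments = c("PBO", "A"), data = df,
                   covariates = c("a", "b", "c"), n = n),
              class = "mlnmr_ipd")
  }
  s1 <- mk("s1", 100); s2 <- mk("s2", 300)
  R1 <- cor(s1$data[, c("a", "b", "c")])
  R2 <- cor(s2$data[, c("a", "b", "c")])
  pooled <- pooled_correlation(list(s1, s2))
  expect_equal(unname(pooled), unname(0.25 * R1 + 0.75 * R2), tolerance = 1e-10)
  # single study returns its own matrix
  expect_equal(unname(pooled_correlation(list(s1))), unname(R1),
               tolerance = 1e-10)
  # constant covariate in every study is an error
  s1c <- s1; s1c$data$a <- 1; s2c <- s2; s2c$data$a <- 2
  expect_error(pooled_correlation(list(s1c, s2c)), "constant")
})

test_that("integration grids hit marginal moments and the target copula", {
  marg <- list(x = list(family = "gamma", shape = 4, rate = 2))
  g <- build_integration_grid(marg, n_points = 1024, seed = 2)
  expect_equal(mean(g$points[, "x"]), 2, tolerance = 0.01)

  # default point count is 1000
  g1000 <- build_integration_grid(marg, seed = 2)
  expect_equal(nrow(g1000$points), 1000)

  # two correlated gammas: latent correlation 0.5 passes through the copula
  marg2 <- list(x = list(family = "gamma", shape = 4, rate = 2),
                y = list(family = "gamma", shape = 9, rate = 3))
  R <- matrix(c(1, .5, .5, 1), 2)
  g2 <- build_integration_grid(marg2, R, n_points = 4096, seed = 3)
  # oracle: large plain-MC draw through the same copula
  set.seed(99)
  Z <- matrix(rnorm(2e5 * 2), ncol = 2) %*% chol(R)
  xo <- qgamma(pnorm(Z[, 1]), 4, rate = 2)
  yo <- qgamma(pnorm(Z[, 2]), 9, rate = 3)
  expect_equal(cor(g2$points)[1, 2], cor(xo, yo), tolerance = 0.05)

  # binary covariates reproduce the proportion by latent thresholding
  marg3 <- list(b = list(family = "bernoulli", prob = 0.4))
  g3 <- build_integration_grid(marg3, n_points = 2048, seed = 4)
  expect_true(all(g3$points[, "b"] %in% c(0, 1)))
  expect_equal(mean(g3$points[, "b"]), 0.4, tolerance = 0.02)

  expect_error(build_integration_grid(marg, n_points = 1), "at least 2")
})

test_that("QMC averages converge to plain Monte Carlo estimates", {
  marg <- list(x = list(family = "gamma", shape = 4, rate = 2),
               b = list(family = "bernoulli", prob = 0.3))
  R <- diag(2)
  f <- function(M) mean(pnorm(0.3 * M[, 1] - 0.8 * M[, 2] - 0.5))
  set.seed(5)
  Z <- matrix(rnorm(1e6 * 2), ncol = 2)
  Xo <- cbind(qgamma(pnorm(Z[, 1]), 4, rate = 2), as.numeric(pnorm(Z[, 2]) > 0.7))
  target <- f(Xo)
  errs <- sapply(c(64, 256, 1024, 4096), function(n) {
    g <- build_integration_grid(marg, R, n_points = n, seed = 6)
    abs(f(g$points) - target)
  })
  expect_lt(errs[4], 2e-3)
  expect_lt(errs[4], errs[1] + 1e-4)   # error shrinks with n_points
})

test_that("AgD grids reproduce each study's reported summaries", {
  sim <- small_mixed_network(seed = 21, n_ipd = 200, n_agd = 300,
                             n_points = 1024)
  net <- sim$network
  for (s in names(net$agd)) {
    summ <- mlnmr:::study_marginal_summaries(net$agd[[s]])
    G <- net$grids[[s]]$points
    expect_equal(mean(G[, "xc"]), summ$xc$mean, tolerance = 0.02 * summ$xc$mean)
    expect_equal(sd(G[, "xc"]), summ$xc$sd, tolerance = 0.05 * summ$xc$sd)
    expect_equal(mean(G[, "xb"]), summ$xb$prop, tolerance = 0.03)
  }
})

test_that("PSD repair fixes indefinite averages and keeps unit diagonal", {
  R <- matrix(c(1, 0.9, -0.9, 0.9, 1, 0.9, -0.9, 0.9, 1), 3)  # indefinite
  Rr <- mlnmr:::repair_correlation(R)
  expect_true(min(eigen(Rr, symmetric = TRUE)$values) >= 0)
  expect_equal(diag(Rr), rep(1, 3))
})
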