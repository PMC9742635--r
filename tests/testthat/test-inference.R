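test_that("half-normal prior calibration: 95% mass below twice the scale x2", {
  expect_equal(tau_prior_prob(prior_spec(tau_scale = 2.5), 5),
               2 * pnorm(2) - 1, tolerance = 1e-8)
  # Monte Carlo cross-check of the same quantile
  set.seed(1)
  tt <- abs(rnorm(2e5, 0, 2.5))
  expect_equal(quantile(tt, 0.95)[[1]], 4.9, tolerance = 0.08)
  expect_error(prior_spec(effect_sd = 0), "positive")
})

test_that("split R-hat and ESS behave on known chains", {
  set.seed(2)
  good <- matrix(rnorm(4000), 1000, 4)
  expect_lt(split_rhat(good), 1.01)
  bad <- good; bad[, 1] <- bad[, 1] + 3
  expect_gt(split_rhat(bad), 1.5)
  # ESS near the draw count for iid draws, far below it for a sticky AR(1)
  expect_gt(ess_basic(good), 2500)
  ar <- matrix(0, 1000, 2)
  for (i in 2:1000) ar[i, ] <- 0.95 * ar[i - 1, ] + rnorm(2, 0, 0.1)
  expect_lt(ess_basic(ar), 500)
})

test_that("a small mixed fit runs, is seed-reproducible and well calibrated", {
  sim <- small_mixed_network(seed = 10, n_ipd = 100, n_agd = 120, n_points = 32)
  fit <- fit_quick(sim$network, seed = 5)
  expect_s3_class(fit, "mlnmr_fit")
  expect_equal(fit$n_divergent, 0L)
  expect_true(all(unlist(fit$accept) > 0.05))
  # same seed reproduces the draws bit-identically
  fit2 <- fit_quick(sim$network, seed = 5)
  expect_identical(fit$draws, fit2$draws)
  # different seed gives different draws
  fit3 <- fit_quick(sim$network, seed = 6)
  expect_false(identical(fit$draws, fit3$draws))
  # summaries and methods work
  s <- summary(fit)
  expect_true(all(c("mean", "sd", "rhat", "ess") %in% names(s)))
  expect_named(coef(fit), c("A1", "A2", "B1"))
  expect_equal(ncol(as.matrix(fit)), length(fit$parnames))
})

test_that("the convergence gate triggers on hopelessly short chains", {
  sim <- small_mixed_network(seed = 11, n_ipd = 60, n_agd = 60, n_points = 16)
  expect_error(
    mlnmr(sim$network, chains = 2, iter_warmup = 30, iter_sampling = 40,
          seed = 1),
    "convergence gate")
  expect_warning(
    mlnmr(sim$network, chains = 2, iter_warmup = 30, iter_sampling = 40,
          seed = 1, on_nonconvergence = "warn"),
    "convergence gate")
})

test_that("residual deviance identities hold", {
  net <- local({
    agd <- data.frame(study = "g", trt = c("PBO", "A"), n = c(10, 10),
                      cat1 = c(5, 2), cat2 = c(5, 3), cat3 = c(0, 3),
                      cat4 = c(0, 2))
    ipd <- tiny_ipd_df(n = 20, study = "s")
    assemble_network(load_ipd(ipd, c("age", "male"), pasi4),
                     load_agd(cbind(agd, age_mean = 45, age_sd = 8,
                                    male_prop = 0.5),
                              c("age", "male"), pasi4),
                     c(PBO = "p", A = "a"), pasi4, "PBO")
  })
  net <- add_integration(net, n_points = 8, seed = 1,
                         correlation = diag(2))
  design <- mlnmr:::build_design(net, mlnmr:::resolve_spec(net, model_spec()))
  meta <- mlnmr:::point_metadata(design)
  agd_rows <- which(meta$type == "agd")
  # fitted probabilities equal to observed proportions -> zero contribution
  P <- matrix(0.25, nrow(meta), 4)
  P[agd_rows[1], ] <- c(0.5, 0.5, 0, 0)
  dev <- mlnmr:::point_deviance(P, meta, design)
  expect_equal(dev[agd_rows[1]], 0)
  # hand-computed arm deviance: counts (5,5,0,0), p-hat (0.25,0.75,0,0)
  P[agd_rows[1], ] <- c(0.25, 0.75, 0, 0)
  dev <- mlnmr:::point_deviance(P, meta, design)
  expect_equal(dev[agd_rows[1]], 2 * (5 * log(2) + 5 * log(2 / 3)))
  # AgD contributions are non-negative against the saturated model
  set.seed(4)
  Pr <- t(apply(matrix(rexp(nrow(meta) * 4), ncol = 4), 1, function(z) z / sum(z)))
  devr <- mlnmr:::point_deviance(Pr, meta, design)
  expect_true(all(devr[agd_rows] >= -1e-10))
})

test_that("degenerate posteriors give pD = 0 and contributions sum to totals", {
  sim <- small_mixed_network(seed = 12, n_ipd = 50, n_agd = 60, n_points = 16)
  fit <- fit_quick(sim$network, seed = 2, iter_warmup = 200, iter_sampling = 150)
  # freeze the posterior at a single draw: plug-in equals the mean deviance
  frozen <- fit
  one <- fit$draws[[1]][1, , drop = FALSE]
  frozen$draws <- list(one[rep(1, 50), ])
  fs <- dic(frozen)
  expect_equal(fs$pD, 0, tolerance = 1e-9)
  expect_equal(fs$DIC, fs$resdev, tolerance = 1e-9)
  # per-point contributions sum to the reported total
  rd <- residual_deviance(fit, ndraws = 50)
  expect_equal(sum(rd$pointwise$dev), rd$total)
  expect_equal(rd$n_points,
               sum(vapply(sim$network$ipd, `[[`, 0, "n")) +
                 sum(vapply(sim$network$agd, function(s) nrow(s$arms), 0)))
  # pD positive on the non-degenerate fit
  expect_gt(dic(fit, ndraws = 100)$pD, 0)
})

test_that("pD approximates the conjugate effective parameter count", {
  # one AgD arm, binomial-like 2-category outcome, known intercept-only model:
  # a single free location parameter should give pD near 1
  out2 <- outcome_spec(c("fail", "success"))
  agd <- data.frame(study = "g", trt = c("PBO", "A"), n = c(200, 200),
                    cat1 = c(120, 60), cat2 = c(80, 140))
  net <- assemble_network(list(), load_agd(agd, character(0), out2),
                          c(PBO = "p", A = "a"), out2, "PBO")
  net <- add_integration(net, n_points = 2, seed = 1)
  fit <- mlnmr(net, model_spec(), chains = 2, iter_warmup = 600,
               iter_sampling = 1500, seed = 3, on_nonconvergence = "none")
  fs <- dic(fit)
  # two free parameters (mu, gamma) informing two arms
  expect_equal(fs$pD, 2, tolerance = 0.5)
})

test_that("posterior predictive simulation returns valid AgD count tables", {
  sim <- small_mixed_network(seed = 14, n_ipd = 40, n_agd = 60, n_points = 16)
  fit <- fit_quick(sim$network, seed = 3, iter_warmup = 150, iter_sampling = 150)
  pp <- simulate(fit, nsim = 2, seed = 9)
  expect_length(pp, 2)
  arms <- do.call(rbind, lapply(sim$network$agd, `[[`, "arms"))
  expect_equal(rowSums(pp[[1]][, paste0("cat", 1:4)]), arms$n,
               ignore_attr = TRUE)
})
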