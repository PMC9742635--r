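# one moderately sized consistency fit shared across the prediction tests
pred_fit_env <- new.env()
get_pred_fit <- function() {
  if (is.null(pred_fit_env$fit)) {
    pred_fit_env$sim <- small_mixed_network(seed = 31, n_ipd = 120,
                                            n_agd = 150, n_points = 64)
    pred_fit_env$fit <- fit_quick(pred_fit_env$sim$network, seed = 8,
                                  iter_warmup = 600, iter_sampling = 700)
  }
  list(sim = pred_fit_env$sim, fit = pred_fit_env$fit)
}

test_that("conditional average effects obey their structural identities", {
  pf <- get_pred_fit()
  fit <- pf$fit
  # a degenerate population at the centering values reproduces gamma exactly
  ctr <- fit$spec$centers
  pop0 <- target_population("centered",
                            means = c(xc = unname(ctr["xc"])),
                            sds = c(xc = 0), props = c(xb = 0))
  eff0 <- conditional_average_effects(fit, population = pop0)
  gd <- colMeans(mlnmr:::gamma_draws(fit))
  expect_equal(eff0$mean, unname(gd), tolerance = 1e-10)
  # interval endpoints are ordered
  expect_true(all(eff0[["2.5%"]] <= eff0[["50%"]] &
                    eff0[["50%"]] <= eff0[["97.5%"]]))

  # effects depend only on effect-modifier summaries: in a model where xc has
  # no interaction, moving the population's xc mean changes nothing
  spec_pr <- model_spec(interactions = c(xc = "none", xb = "class"))
  fit_pr <- fit_quick(pf$sim$network, spec_pr, seed = 9,
                      iter_warmup = 300, iter_sampling = 300)
  popA <- target_population("A", means = c(xc = 45), sds = c(xc = 10),
                            props = c(xb = 0.3))
  popB <- target_population("B", means = c(xc = 70), sds = c(xc = 14),
                            props = c(xb = 0.3))
  effA <- conditional_average_effects(fit_pr, population = popA)
  effB <- conditional_average_effects(fit_pr, population = popB)
  expect_equal(effA$mean, effB$mean, tolerance = 1e-10)
})

test_that("in-network average event probabilities are monotone and match MC", {
  pf <- get_pred_fit()
  fit <- pf$fit
  probs <- average_event_probs(fit, "s4")
  expect_s3_class(probs, "mlnmr_estimates")
  # monotone across thresholds for every treatment
  for (tr in unique(probs$treatment)) {
    pp <- probs$mean[probs$treatment == tr]
    expect_true(all(diff(pp) <= 1e-9))
  }
  # brute-force check of the grid averaging for one treatment at the
  # posterior mean parameters
  d <- colMeans(as.matrix(fit))
  st <- mlnmr:::draw_state(fit$design, d)
  G <- mlnmr:::transform_grid(fit, pf$sim$network$grids[["s4"]]$points)
  k <- match("A1", fit$design$trts)
  eta <- st$mu[match("s4", fit$design$studies)] +
    as.numeric(G %*% (st$beta1 + st$B2[, k])) + d["gamma[A1]"]
  oracle <- colMeans(ordered_probs(eta, st$cuts)$inclusive) * 100
  got <- probs$mean[probs$treatment == "A1"]
  # posterior mean of a nonlinear map differs from the map at the posterior
  # mean, so compare loosely
  expect_equal(got, oracle, tolerance = 2)
})

test_that("baseline anchoring solves the intercept to the target probability", {
  pf <- get_pred_fit()
  fit <- pf$fit
  D <- nrow(as.matrix(fit))
  G <- matrix(rnorm(64 * 2, 0, 0.8), 64, 2)
  cd <- mlnmr:::cut_draws(fit)
  B <- mlnmr:::beta1_draws(fit)
  eff <- rep(0.4, D)
  # fixed point: target = attained probability at mu* = 0 returns mu* = 0
  p0 <- mlnmr:::cpp_avg_probs_draws(G, rep(0, D), B, eff, cd, 0L)
  incl1 <- 1 - p0[, 1]
  sol <- mlnmr:::cpp_solve_mustar(G, B, eff, cd, incl1, 1L, 0L, 1e-10)
  expect_equal(sol, rep(0, D), tolerance = 1e-6)
  # agreement with an R bisection oracle on random draws
  set.seed(33)
  idx <- sample(D, 10)
  for (i in idx) {
    f <- function(m) mean(pnorm(m + as.numeric(G %*% B[i, ]) + eff[i] - cd[i, 1]))
    target <- runif(1, 0.2, 0.8)
    oracle <- r_bisect_mustar(f, target)
    got <- mlnmr:::cpp_solve_mustar(G, B[i, , drop = FALSE], eff[i],
                                    cd[i, , drop = FALSE], target, 1L, 0L, 1e-10)
    expect_equal(got, oracle, tolerance = 1e-6)
  }
})

test_that("external populations produce anchored probabilities", {
  pf <- get_pred_fit()
  fit <- pf$fit
  bl <- baseline_ref("A1", 243, 330 - 243)
  expect_equal(bl$shape2, 87)
  pop <- target_population("ext", means = c(xc = 55), sds = c(xc = 12),
                           props = c(xb = 0.4), baseline = bl)
  probs <- average_event_probs_external(fit, pop, n_points = 64, seed = 4)
  expect_true(all(probs$mean >= 0 & probs$mean <= 100))
  # the anchor treatment's first-threshold probability concentrates near the
  # Beta mean (243/330 = 73.6%)
  a1 <- probs[probs$treatment == "A1" & probs$threshold == ">=1", ]
  expect_equal(a1$mean, 100 * 243 / 330, tolerance = 3)
  # reparameterising the Beta as (responders, N - responders) is identical
  pop2 <- pop; pop2$baseline <- baseline_ref("A1", 243, 87)
  probs2 <- average_event_probs_external(fit, pop2, n_points = 64, seed = 4)
  expect_equal(probs$mean, probs2$mean)
  expect_error(average_event_probs_external(fit,
    target_population("nobl", means = c(xc = 55), sds = c(xc = 12),
                      props = c(xb = 0.4))), "baseline")
})

test_that("marginal effects shrink under heterogeneity and equal conditional
           effects for a degenerate population", {
  pf <- get_pred_fit()
  fit <- pf$fit
  # degenerate population: marginal equals conditional (no averaging)
  ctr <- fit$spec$centers
  bl <- baseline_ref("PBO", 50, 150)
  pop0 <- target_population("point", means = c(xc = unname(ctr["xc"])),
                            sds = c(xc = 0), props = c(xb = 0),
                            baseline = bl)
  me <- marginal_effects(fit, population = pop0, threshold = 1)
  ce <- conditional_average_effects(fit, population = pop0)
  expect_equal(me$mean, ce$mean, tolerance = 0.02)
  # a population with prognostic spread attenuates the marginal effect
  popH <- target_population("spread", means = c(xc = unname(ctr["xc"])),
                            sds = c(xc = 25), props = c(xb = 0),
                            baseline = bl)
  meH <- marginal_effects(fit, population = popH, threshold = 1,
                          n_points = 256, seed = 6)
  expect_true(all(abs(meH$mean) < abs(ce$mean)))
})

test_that("predict() dispatches to the population-average estimators", {
  pf <- get_pred_fit()
  fit <- pf$fit
  e1 <- predict(fit, "effects", study = "s1")
  expect_s3_class(e1, "mlnmr_estimates")
  p1 <- predict(fit, "probs", study = "s4")
  expect_true(all(c("treatment", "threshold", "mean") %in% names(p1)))
  # UME fits refuse population-average prediction
  fit_ume <- fit_quick(pf$sim$network, model_spec(contrasts = "ume"),
                       seed = 4, iter_warmup = 200, iter_sampling = 200)
  expect_error(conditional_average_effects(fit_ume, study = "s1"),
               "consistency")
})
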