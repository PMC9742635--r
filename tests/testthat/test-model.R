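# shared toy network: 2 IPD studies + 1 AgD study, 3 treatments, no covariates
toy_nocov_network <- function(seed = 13) {
  set.seed(seed)
  ipd <- data.frame(
    study = rep(c("s1", "s2"), each = 40),
    trt = c(rep(c("PBO", "A"), 20), rep(c("PBO", "B"), 20)),
    out_cat = sample(pasi4$labels, 80, TRUE),
    stringsAsFactors = FALSE)
  agd <- data.frame(study = "s3", trt = c("A", "B"), n = c(50, 50),
                    cat1 = c(20, 10), cat2 = c(15, 15), cat3 = c(10, 15),
                    cat4 = c(5, 10), stringsAsFactors = FALSE)
  assemble_network(load_ipd(ipd, character(0), pasi4),
                   load_agd(agd, character(0), pasi4),
                   c(PBO = "p", A = "a", B = "b"), pasi4, "PBO")
}

toy_params <- function(net) {
  list(mu = c(s1 = -0.4, s2 = -0.9, s3 = -0.6),
       cutpoints = c(0, 0.5, 1.1),
       gamma = c(A = 1.2, B = 0.7))
}

test_that("linear predictor follows the individual-level model structure", {
  sim <- small_mixed_network(seed = 2, n_ipd = 30, n_agd = 40, n_points = 8)
  net <- sim$network
  spec <- model_spec()
  B2 <- matrix(0.1, 2, 4, dimnames = list(c("xc", "xb"), c("PBO", "A1", "A2", "B1")))
  B2[, "PBO"] <- 0
  params <- list(mu = c(s1 = -1, s2 = -1.2, s3 = -1.1, s4 = -1.3, s5 = -1.2),
                 cutpoints = c(0, 0.7, 1.5),
                 beta1 = c(xc = 0.2, xb = 0.2), beta2 = B2,
                 gamma = c(A1 = 2, A2 = 1.6, B1 = 1.2))
  x0 <- c(xc = 0, xb = 0)
  # x = 0 at the reference: eta = mu_j
  expect_equal(linear_predictor(x0, "s1", "PBO", params, net, spec), -1)
  # x = 0 on treatment k: difference to reference is gamma_k
  expect_equal(linear_predictor(x0, "s1", "A1", params, net, spec) -
                 linear_predictor(x0, "s1", "PBO", params, net, spec), 2)
  # hand arithmetic: eta = mu + x'(beta1 + beta2) + gamma
  p2 <- params
  p2$beta1 <- c(xc = 0.2, xb = 0); p2$beta2[] <- 0; p2$beta2["xc", "A1"] <- 0.1
  eta <- linear_predictor(c(xc = 1, xb = 0), "s1", "A1", p2, net, spec)
  expect_equal(eta, -1 + 1 * (0.2 + 0.1) + 2)
  expect_error(linear_predictor(x0, "s1", "nope", params, net, spec),
               "unknown treatment")
  expect_error(linear_predictor(x0, "nope", "A1", params, net, spec),
               "unknown study")
})

test_that("ordered probabilities match the normal-CDF oracle and telescope", {
  op <- ordered_probs(0, c(0, 1, 2))
  expect_equal(as.numeric(op$inclusive), c(0.5, pnorm(-1), pnorm(-2)))
  expect_equal(as.numeric(op$category),
               c(0.5, 0.5 - pnorm(-1), pnorm(-1) - pnorm(-2), pnorm(-2)))
  # eta at a cutpoint gives inclusive probability one half
  op2 <- ordered_probs(1.3, c(0, 1.3, 2))
  expect_equal(op2$inclusive[1, 2], 0.5)
  # probabilities sum to one for arbitrary inputs
  set.seed(3)
  for (i in 1:20) {
    eta <- rnorm(5, 0, 2)
    cuts <- cumsum(c(0, abs(rnorm(2))))
    expect_equal(rowSums(ordered_probs(eta, cuts)$category), rep(1, 5))
    expect_true(all(ordered_probs(eta, cuts)$category >= 0))
  }
  expect_error(ordered_probs(0, c(0, 2, 1)), "non-decreasing")
})

test_that("aggregate probabilities collapse without covariates and stay monotone", {
  sim <- small_mixed_network(seed = 4, n_ipd = 40, n_agd = 60, n_points = 32)
  net <- sim$network
  params <- list(mu = c(s1 = -1, s2 = -1.2, s3 = -1.1, s4 = -1.3, s5 = -1.2),
                 cutpoints = c(0, 0.7, 1.5),
                 beta1 = c(xc = 0, xb = 0),
                 gamma = c(A1 = 2, A2 = 1.6, B1 = 1.2))
  ap <- aggregate_probs(net, "s4", "A1", params)
  direct <- ordered_probs(-1.3 + 2, c(0, 0.7, 1.5))
  expect_equal(ap$category, as.numeric(direct$category), tolerance = 1e-12)

  # with covariate effects the inclusive averages remain monotone
  params$beta1 <- c(xc = 0.4, xb = -0.6)
  params$beta2 <- matrix(0.2, 2, 4,
                         dimnames = list(c("xc", "xb"), net$treatments$id))
  params$beta2[, "PBO"] <- 0
  ap2 <- aggregate_probs(net, "s4", "B1", params)
  expect_true(all(diff(ap2$inclusive) <= 1e-12))
  expect_equal(sum(ap2$category), 1)
})

test_that("IPD and AgD log-likelihoods match hand computation", {
  net <- toy_nocov_network()
  params <- toy_params(net)
  # oracle: direct computation over rows/arms
  mu <- params$mu; gamma <- c(PBO = 0, params$gamma)
  ipd_rows <- do.call(rbind, lapply(net$ipd, function(s)
    data.frame(study = s$study, trt = s$data$trt, y = s$data$y)))
  arms <- list(list(study = "s3", trt = "A", counts = c(20, 15, 10, 5)),
               list(study = "s3", trt = "B", counts = c(10, 15, 15, 10)))
  oracle <- r_ordinal_nma_loglik(ipd_rows, NULL, mu, gamma, params$cutpoints)
  expect_equal(loglik_ipd(net, params), oracle, tolerance = 1e-10)
  oracle_agd <- r_ordinal_nma_loglik(NULL, arms, mu, gamma, params$cutpoints)
  expect_equal(loglik_agd(net, params), oracle_agd, tolerance = 1e-10)

  # single individual with category probability one contributes zero
  df1 <- data.frame(study = "z", trt = c("PBO", "A"), out_cat = c("<PASI75", "<PASI75"))
  net1 <- assemble_network(load_ipd(df1, character(0), pasi4), list(),
                           c(PBO = "p", A = "a"), pasi4, "PBO")
  p1 <- list(mu = c(z = -40), cutpoints = c(0, 1, 2), gamma = c(A = 0))
  expect_equal(loglik_ipd(net1, p1), 0)
  # probability one half gives log(1/2) per individual
  p2 <- list(mu = c(z = 0), cutpoints = c(0, 30, 60), gamma = c(A = 0))
  expect_equal(loglik_ipd(net1, p2), 2 * log(0.5))
})

test_that("AgD kernel is linear in the counts", {
  net <- toy_nocov_network()
  params <- toy_params(net)
  ll1 <- loglik_agd(net, params)
  net2 <- net
  for (cc in paste0("cat", 1:4))
    net2$agd$s3$arms[[cc]] <- 2 * net2$agd$s3$arms[[cc]]
  net2$agd$s3$arms$n <- 2 * net2$agd$s3$arms$n
  expect_equal(loglik_agd(net2, params), 2 * ll1, tolerance = 1e-10)
})

test_that("zero-covariate ML-NMR equals a directly coded ordinal NMA", {
  net <- toy_nocov_network()
  set.seed(77)
  for (i in 1:5) {
    params <- list(mu = c(s1 = rnorm(1), s2 = rnorm(1), s3 = rnorm(1)),
                   cutpoints = cumsum(c(0, abs(rnorm(2)))),
                   gamma = c(A = rnorm(1), B = rnorm(1)))
    ipd_rows <- do.call(rbind, lapply(net$ipd, function(s)
      data.frame(study = s$study, trt = s$data$trt, y = s$data$y)))
    arms <- lapply(1:2, function(a) list(
      study = "s3", trt = net$agd$s3$arms$trt[a],
      counts = as.numeric(net$agd$s3$arms[a, paste0("cat", 1:4)])))
    oracle <- r_ordinal_nma_loglik(ipd_rows, arms, params$mu,
                                   c(PBO = 0, params$gamma), params$cutpoints)
    expect_equal(loglik_ipd(net, params) + loglik_agd(net, params), oracle,
                 tolerance = 1e-10)
  }
})

test_that("grid row order does not change the AgD likelihood", {
  sim <- small_mixed_network(seed = 6, n_ipd = 30, n_agd = 50, n_points = 64)
  net <- sim$network
  params <- list(mu = c(s1 = -1, s2 = -1.2, s3 = -1.1, s4 = -1.3, s5 = -1.2),
                 cutpoints = c(0, 0.7, 1.5),
                 beta1 = c(xc = 0.3, xb = -0.2),
                 gamma = c(A1 = 2, A2 = 1.6, B1 = 1.2))
  ll1 <- loglik_agd(net, params)
  set.seed(8)
  for (s in names(net$grids))
    net$grids[[s]]$points <- net$grids[[s]]$points[sample(nrow(net$grids[[s]]$points)), ]
  expect_equal(loglik_agd(net, params), ll1, tolerance = 1e-12)
})

test_that("interaction structures resolve to the right free coefficient counts", {
  sim <- psoriasis_like_network(seed = 2, n_ipd = 20, n_agd = 20)
  net <- sim$network
  # class-shared everywhere: 3 active classes x 5 covariates
  expect_equal(resolve_interactions(net, model_spec())$n_free, 15)
  # splitting weight only: 4 IL-17 regimens own their weight coefficient,
  # singleton classes keep one each, other 4 covariates stay class-shared
  split_w <- resolve_interactions(net,
    model_spec(interactions = c(weight = "independent")))
  expect_equal(split_w$n_free, 4 * 3 + (2 + 4))
  # fully independent: 6 active treatments x 5 covariates
  expect_equal(resolve_interactions(net,
    model_spec(interactions = "independent"))$n_free, 30)
  expect_error(resolve_interactions(net,
    model_spec(interactions = c(nope = "independent"))), "unknown covariate")
})

test_that("RE prior density matches the multivariate normal oracle", {
  # two-arm study: univariate normal
  expect_equal(re_prior(0.5, 0.3, 0.2), dnorm(0.5, 0.3, 0.2, log = TRUE))
  # three-arm study, tau = 0.2: covariance [[0.04, 0.02], [0.02, 0.04]]
  Sig <- matrix(c(0.04, 0.02, 0.02, 0.04), 2)
  x <- c(0.1, -0.2); m <- c(0.3, 0.1)
  expect_equal(re_prior(x, m, 0.2), r_mvn_logdens(x, m, Sig), tolerance = 1e-10)
  # four-arm check against the explicit oracle
  Sig4 <- 0.3^2 * (diag(3) * 0.5 + 0.5)
  x4 <- c(0.2, 0, -0.1); m4 <- c(0.1, 0.1, 0.1)
  expect_equal(re_prior(x4, m4, 0.3), r_mvn_logdens(x4, m4, Sig4),
               tolerance = 1e-10)
  # tau -> 0 concentrates at the consistency means
  expect_equal(re_prior(c(0.3, 0.1), c(0.3, 0.1), 0), Inf)
  expect_equal(re_prior(c(0.4, 0.1), c(0.3, 0.1), 0), -Inf)
  expect_error(re_prior(0.1, 0.1, -1), "non-negative")
})

test_that("UME design enumerates one contrast per observed design pair", {
  net <- toy_nocov_network()
  design <- mlnmr:::build_design(net, model_spec(contrasts = "ume"))
  # s1: PBO->A, s2: PBO->B, s3 (arm1 A): A->B
  expect_setequal(design$pairs, c("PBO:A", "PBO:B", "A:B"))
  # UME linear predictor: gamma_kk = 0 on the arm-1 treatment
  params <- list(mu = c(s1 = -0.4, s2 = -0.9, s3 = -0.6),
                 cutpoints = c(0, 0.5, 1.1),
                 d = matrix(0.5, 3, 3, dimnames = list(c("PBO", "A", "B"),
                                                       c("PBO", "A", "B"))))
  spec <- model_spec(contrasts = "ume")
  eta_arm1 <- linear_predictor(numeric(0), "s3", "A", params, net, spec)
  expect_equal(eta_arm1, -0.6)   # mu_j(t_j1) only
  eta_b <- linear_predictor(numeric(0), "s3", "B", params, net, spec)
  expect_equal(eta_b - eta_arm1, 0.5)   # the A->B contrast
})

test_that("full-IPD networks need no integration grid", {
  df <- tiny_ipd_df(n = 40)
  net <- assemble_network(load_ipd(df, c("age", "male"), pasi4), list(),
                          c(PBO = "p", A = "a"), pasi4, "PBO")
  params <- list(mu = c(s1 = -0.5), cutpoints = c(0, 0.6, 1.2),
                 beta1 = c(age = 0.1, male = -0.2), gamma = c(A = 1))
  spec <- model_spec(centers = c(age = 45), scales = c(age = 10))
  expect_true(is.finite(loglik_ipd(net, params, spec)))
  expect_equal(loglik_agd(net, params, spec), 0)
})
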