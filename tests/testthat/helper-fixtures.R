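# Small fixtures built in code.

pasi4 <- outcome_spec(c("<PASI75", "PASI75-90", "PASI90-100", "PASI100"))

# minimal 2-arm IPD data frame with one continuous + one binary covariate
tiny_ipd_df <- function(n = 30, study = "s1", seed = 11) {
  set.seed(seed)
  data.frame(study = study,
             trt = rep(c("PBO", "A"), each = n / 2),
             age = round(rnorm(n, 45, 8), 1),
             male = rbinom(n, 1, 0.5),
             out_cat = sample(pasi4$labels, n, replace = TRUE),
             stringsAsFactors = FALSE)
}

# a small mixed IPD + AgD network with 3 treatments and 2 covariates
small_mixed_network <- function(seed = 7, n_ipd = 120, n_agd = 150,
                                tau = 0, inconsistency = NULL,
                                beta2_trt = NULL, n_points = 64) {
  studies <- list(
    list(id = "s1", type = "ipd", treatments = c("PBO", "A1"), n_per_arm = n_ipd),
    list(id = "s2", type = "ipd", treatments = c("PBO", "A2"), n_per_arm = n_ipd),
    list(id = "s3", type = "ipd", treatments = c("PBO", "B1"), n_per_arm = n_ipd),
    list(id = "s4", type = "agd", treatments = c("PBO", "A1", "B1"), n_per_arm = n_agd),
    list(id = "s5", type = "agd", treatments = c("A1", "B1"), n_per_arm = n_agd),
    list(id = "s6", type = "agd", treatments = c("PBO", "A2"), n_per_arm = n_agd))
  covariates <- list(
    xc = list(family = "gamma", mean = 50, sd = 12),
    xb = list(family = "bernoulli", prob = 0.35))
  classes <- c(PBO = "placebo", A1 = "clsA", A2 = "clsA", B1 = "clsB")
  offsets <- list(s1 = c(xc = -6, xb = -0.08), s2 = c(xc = -2, xb = 0),
                  s3 = c(xc = 2, xb = 0.05), s4 = c(xc = 6, xb = 0.1),
                  s5 = c(xc = 0, xb = -0.04), s6 = c(xc = 4, xb = 0.08))
  truth <- list(
    mu = c(s1 = -1.1, s2 = -1.3, s3 = -1.2, s4 = -1.4, s5 = -1.2, s6 = -1.0),
    gamma = c(A1 = 2.0, A2 = 1.6, B1 = 1.2),
    beta1 = c(xc = 0.25, xb = -0.35),
    beta2 = list(clsA = c(xc = 0.20, xb = 0.30),
                 clsB = c(xc = -0.10, xb = 0.20)),
    beta2_trt = beta2_trt,
    cutpoints = c(0, 0.7, 1.5),
    tau = tau,
    inconsistency = inconsistency)
  cfg <- sim_config(studies, covariates, classes, truth, reference = "PBO",
                    outcome = pasi4, study_offsets = offsets, seed = seed)
  sim <- simulate_network(cfg)
  sim$network <- add_integration(sim$network, n_points = n_points,
                                 seed = seed + 1)
  sim
}

# quick MCMC settings for smoke-level fits
quick_mcmc <- list(chains = 2, iter_warmup = 500, iter_sampling = 600,
                   on_nonconvergence = "none")

fit_quick <- function(network, spec = model_spec(), seed = 1, ...) {
  do.call(mlnmr, c(list(network, spec, prior_spec(), seed = seed),
                   utils::modifyList(quick_mcmc, list(...))))
}
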