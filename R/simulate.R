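#' Configure a synthetic evidence network
#'
#' Defines the generative model for a synthetic network with known ground
#' truth: the study roster (which treatments, how many patients per arm,
#' IPD or AgD reporting), per-covariate generative families with optional
#' per-study mean shifts, a latent correlation matrix, and the true model
#' parameters (intercepts, effects, prognostic and interaction coefficients,
#' cutpoints, heterogeneity, optional inconsistency offsets).
#'
#' Treatment assignment within a study is balanced (the emulated trials are
#' RCTs, so covariate distributions are common across arms within a study).
#' True coefficients are expressed on the centered/scaled model scale so a
#' fitted model using the same centering recovers them directly.
#'
#' @param studies List of `list(id, type = "ipd"|"agd", treatments, n_per_arm)`.
#' @param covariates Named list of generative marginals: `list(family =
#'   "gamma", mean, sd)`, `list(family = "scaled_logit_normal", mean, sd,
#'   lower, upper)` or `list(family = "bernoulli", prob)`.
#' @param classes Named character vector mapping treatments to classes.
#' @param truth List with `mu` (named per study), `gamma` (named per active
#'   treatment), `beta1` (named per covariate, scaled units), `beta2` (named
#'   list class -> named vector per covariate), optional `beta2_trt`
#'   (treatment-level overrides), `cutpoints` (first 0), `tau`, and optional
#'   `inconsistency` (named list study -> named vector treatment -> offset).
#' @param reference Reference treatment id.
#' @param outcome An [outcome_spec()].
#' @param correlation Latent covariate correlation matrix (default identity).
#' @param study_offsets Named list study -> named numeric vector of mean (or
#'   probability) shifts, creating covariate imbalance across studies.
#' @param centers,scales Centering values / scaling divisors defining the
#'   scale of the true coefficients.
#' @param seed Integer seed.
#' @return An object of class `mlnmr_simconfig`.
#' @export
sim_config <- function(studies, covariates, classes, truth, reference,
                       outcome, correlation = NULL, study_offsets = list(),
                       centers = NULL, scales = NULL, seed = 1) {
  covs <- names(covariates)
  if (is.null(correlation)) correlation <- diag(length(covs))
  if (is.null(dimnames(correlation)))
    dimnames(correlation) <- list(covs, covs)
  if (is.unsorted(truth$cutpoints))
    stop_mlnmr("true cutpoints must be non-decreasing")
  if (length(truth$cutpoints) != outcome$n_categories - 1)
    stop_mlnmr("need ", outcome$n_categories - 1, " true cutpoints")
  centers <- centers %||% vapply(covariates, function(cv)
    if (cv$family == "bernoulli") 0 else cv$mean, 0)
  scales <- scales %||% vapply(covariates, function(cv)
    if (cv$family == "bernoulli") 1 else 10, 0)
  names(centers) <- names(scales) <- covs
  structure(list(studies = studies, covariates = covariates,
                 classes = classes, truth = truth, reference = reference,
                 outcome = outcome, correlation = correlation,
                 study_offsets = study_offsets,
                 centers = centers, scales = scales, seed = seed),
            class = "mlnmr_simconfig")
}

# true covariate-by-treatment interaction matrix implied by a config
sim_true_B2 <- function(config, covs, trts) {
  B2 <- matrix(0, length(covs), length(trts), dimnames = list(covs, trts))
  for (k in trts) {
    if (k == config$reference) next
    cls <- config$classes[[k]]
    if (!is.null(config$truth$beta2[[cls]]))
      B2[names(config$truth$beta2[[cls]]), k] <- config$truth$beta2[[cls]]
    if (!is.null(config$truth$beta2_trt[[k]]))
      B2[names(config$truth$beta2_trt[[k]]), k] <- config$truth$beta2_trt[[k]]
  }
  B2
}

# draw correlated covariates for one study (original scale)
sim_covariates <- function(config, study_id, n) {
  covs <- names(config$covariates)
  d <- length(covs)
  off <- config$study_offsets[[study_id]] %||% numeric(0)
  L <- chol(repair_correlation(config$correlation) + diag(1e-10, d))
  Z <- matrix(stats::rnorm(n * d), n, d) %*% L
  X <- matrix(0, n, d, dimnames = list(NULL, covs))
  for (j in seq_len(d)) {
    cv <- config$covariates[[j]]
    sh <- if (covs[j] %in% names(off)) off[[covs[j]]] else 0
    m <- switch(cv$family,
      gamma = {
        gp <- gamma_from_moments(cv$mean + sh, cv$sd)
        list(family = "gamma", shape = gp$shape, rate = gp$rate)
      },
      scaled_logit_normal = {
        lp <- logitnormal_from_moments(cv$mean + sh, cv$sd, cv$lower, cv$upper)
        c(list(family = "scaled_logit_normal"), lp)
      },
      bernoulli = list(family = "bernoulli", prob = clamp(cv$prob + sh, 0.01, 0.99)),
      stop_mlnmr("unknown covariate family ", cv$family))
    X[, j] <- marginal_quantile(m, stats::pnorm(Z[, j]))
  }
  X
}

#' Simulate individual patient data for every study in a config
#'
#' Covariates are drawn through the same Gaussian-copula machinery used for
#' integration grids; outcome categories are drawn from the ordered probit
#' model via its latent-variable representation. With `tau > 0`, non-arm-1
#' treatment effects receive multivariate normal random effects with the
#' multi-arm compound-symmetry structure. Reproducible under the config
#' seed.
#'
#' @param config An [sim_config()].
#' @return List with `ipd` (one data frame per study: study, trt, covariates,
#'   `out_cat` label) and `truth` (the generating parameters, including the
#'   expanded interaction matrix).
#' @export
simulate_ipd <- function(config) {
  set.seed(config$seed)
  covs <- names(config$covariates)
  trts <- unique(unlist(lapply(config$studies, `[[`, "treatments")))
  gamma <- stats::setNames(rep(0, length(trts)), trts)
  gamma[names(config$truth$gamma)] <- config$truth$gamma
  gamma[config$reference] <- 0
  B2 <- sim_true_B2(config, covs, trts)
  beta1 <- stats::setNames(rep(0, length(covs)), covs)
  beta1[names(config$truth$beta1)] <- config$truth$beta1
  cuts <- config$truth$cutpoints
  tau <- config$truth$tau %||% 0
  out <- list()
  for (s in config$studies) {
    arms <- s$treatments
    n_arm <- s$n_per_arm
    n <- n_arm * length(arms)
    X <- sim_covariates(config, s$id, n)
    Xt <- sweep(sweep(X, 2, config$centers[covs]), 2, config$scales[covs], "/")
    trt <- rep(arms, each = n_arm)
    # study-specific effects: arm 1 fixed at its consistency value, others
    # N(gamma_k - gamma_a1, CS(tau)) around consistency + inconsistency offset
    a1 <- if (config$reference %in% arms) config$reference else arms[1]
    effs <- gamma[arms]
    inc <- config$truth$inconsistency[[s$id]]
    if (!is.null(inc)) effs[names(inc)] <- effs[names(inc)] + inc
    if (tau > 0 && length(arms) > 1) {
      others <- setdiff(arms, a1)
      m <- length(others)
      Sig <- tau^2 * (0.5 * diag(m) + 0.5)
      z <- as.numeric(chol(Sig) %*% stats::rnorm(m))
      effs[others] <- effs[others] + z
    }
    eta <- config$truth$mu[[s$id]] +
      as.numeric(Xt %*% (beta1 + 0)) +
      rowSums(Xt * t(B2[, trt, drop = FALSE])) +
      effs[trt]
    z <- eta + stats::rnorm(n)
    y <- 1L + rowSums(outer(z, cuts, ">"))
    out[[s$id]] <- data.frame(study = s$id, trt = trt, X,
                              out_cat = config$outcome$labels[y],
                              check.names = FALSE, stringsAsFactors = FALSE)
  }
  list(ipd = out,
       truth = list(mu = config$truth$mu, gamma = gamma[setdiff(trts, config$reference)],
                    beta1 = beta1, B2 = B2, cutpoints = cuts, tau = tau))
}

#' Aggregate a simulated IPD table to AgD summaries
#'
#' Produces the arm-level rows a published report would give: per-arm sample
#' size, outcome category counts, and covariate means/sds (continuous) or
#' proportions (binary). Correlations are withheld, as in real aggregate
#' data.
#'
#' @param df IPD data frame (as from [simulate_ipd()]).
#' @param covariates Covariate names.
#' @param outcome An [outcome_spec()].
#' @return Arm-level data frame in the [load_agd()] format.
#' @export
aggregate_to_agd <- function(df, covariates, outcome) {
  binary <- vapply(covariates, function(cv) is_binary01(df[[cv]]), TRUE)
  y <- match_categories(df$out_cat, outcome)
  rows <- lapply(unique(df$trt), function(tr) {
    sel <- df$trt == tr
    cnt <- tabulate(y[sel], outcome$n_categories)
    row <- data.frame(study = df$study[1], trt = tr, n = sum(sel))
    for (c in seq_along(cnt)) row[[paste0("cat", c)]] <- cnt[c]
    for (cv in covariates) {
      if (binary[cv]) {
        row[[paste0(cv, "_prop")]] <- mean(df[[cv]][sel])
      } else {
        row[[paste0(cv, "_mean")]] <- mean(df[[cv]][sel])
        row[[paste0(cv, "_sd")]] <- stats::sd(df[[cv]][sel])
      }
    }
    row
  })
  do.call(rbind, rows)
}

#' Simulate and assemble a full network from a config
#'
#' Runs [simulate_ipd()], aggregates the studies flagged `"agd"` to
#' arm-level summaries, and assembles the resulting `mlnmr_network`.
#'
#' @param config An [sim_config()].
#' @return List with `network`, `truth` and the raw `ipd` tables.
#' @export
simulate_network <- function(config) {
  sim <- simulate_ipd(config)
  covs <- names(config$covariates)
  ipd_ids <- vapply(Filter(function(s) s$type == "ipd", config$studies),
                    `[[`, "", "id")
  agd_ids <- vapply(Filter(function(s) s$type == "agd", config$studies),
                    `[[`, "", "id")
  ipd_tab <- do.call(rbind, sim$ipd[ipd_ids])
  agd_tab <- do.call(rbind, lapply(sim$ipd[agd_ids], aggregate_to_agd,
                                   covariates = covs,
                                   outcome = config$outcome))
  ipd <- if (length(ipd_ids)) load_ipd(ipd_tab, covs, config$outcome) else list()
  agd <- if (length(agd_ids)) load_agd(agd_tab, covs, config$outcome) else list()
  net <- assemble_network(ipd, agd, config$classes, config$outcome,
                          config$reference)
  list(network = net, truth = sim$truth, ipd = sim$ipd, config = config)
}

pasi_outcome <- function() {
  outcome_spec(c("<PASI75", "PASI75-90", "PASI90-100", "PASI100"))
}

#' A psoriasis-like synthetic evidence network
#'
#' Generates a network mirroring the structure of the moderate-to-severe
#' plaque psoriasis evidence base: 9 studies (4 IPD, 5 AgD), placebo plus 6
#' active treatments (two ixekizumab and two secukinumab regimens sharing
#' the IL-17 class, etanercept, ustekinumab) in 3 active classes, a
#' 4-category ordered PASI outcome, and 5 covariates (Gamma-like duration
#' and weight, bounded-percentage body surface area, binary previous
#' systemic treatment and psoriatic arthritis). True effects are on the
#' scale of the published psoriasis analyses (reference effects roughly
#' 1.5-3 probit units, small interactions); study covariate means are
#' deliberately staggered so effect modification is identifiable.
#'
#' @param seed Integer seed.
#' @param n_ipd,n_agd Patients per arm in IPD / AgD studies.
#' @param tau True between-study heterogeneity sd (default 0).
#' @param inconsistency Optional inconsistency offsets (see [sim_config()]).
#' @return List with `network` (no grids attached), `truth`, `ipd`, `config`.
#' @export
psoriasis_like_network <- function(seed = 1, n_ipd = 200, n_agd = 250,
                                   tau = 0, inconsistency = NULL) {
  studies <- list(
    list(id = "ipd_1", type = "ipd",
         treatments = c("PBO", "IXE_Q2W", "IXE_Q4W"), n_per_arm = n_ipd),
    list(id = "ipd_2", type = "ipd",
         treatments = c("PBO", "IXE_Q2W", "IXE_Q4W", "ETN"), n_per_arm = n_ipd),
    list(id = "ipd_3", type = "ipd",
         treatments = c("PBO", "IXE_Q2W", "IXE_Q4W", "ETN"), n_per_arm = n_ipd),
    list(id = "ipd_4", type = "ipd",
         treatments = c("UST", "IXE_Q2W"), n_per_arm = n_ipd),
    list(id = "agd_1", type = "agd",
         treatments = c("PBO", "ETN", "SEC_150", "SEC_300"), n_per_arm = n_agd),
    list(id = "agd_2", type = "agd",
         treatments = c("PBO", "SEC_150", "SEC_300"), n_per_arm = n_agd),
    list(id = "agd_3", type = "agd",
         treatments = c("PBO", "SEC_150", "SEC_300"), n_per_arm = n_agd),
    list(id = "agd_4", type = "agd",
         treatments = c("PBO", "SEC_150", "SEC_300"), n_per_arm = n_agd),
    list(id = "agd_5", type = "agd",
         treatments = c("SEC_300", "UST"), n_per_arm = n_agd))
  classes <- c(PBO = "placebo", ETN = "TNF",
               IXE_Q2W = "IL17", IXE_Q4W = "IL17",
               SEC_150 = "IL17", SEC_300 = "IL17",
               UST = "IL1223")
  covariates <- list(
    duration = list(family = "gamma", mean = 18.2, sd = 12),
    weight = list(family = "gamma", mean = 89.3, sd = 20),
    bsa = list(family = "scaled_logit_normal", mean = 29.8, sd = 17,
               lower = 0, upper = 100),
    prev_sys = list(family = "bernoulli", prob = 0.65),
    psa = list(family = "bernoulli", prob = 0.20))
  correlation <- diag(5)
  dimnames(correlation) <- list(names(covariates), names(covariates))
  correlation["duration", "weight"] <- correlation["weight", "duration"] <- 0.10
  correlation["duration", "bsa"] <- correlation["bsa", "duration"] <- 0.05
  correlation["weight", "bsa"] <- correlation["bsa", "weight"] <- 0.15
  correlation["duration", "prev_sys"] <- correlation["prev_sys", "duration"] <- 0.20
  sids <- vapply(studies, `[[`, "", "id")
  study_offsets <- stats::setNames(lapply(seq_along(sids), function(i) {
    f <- (i - 5) / 4    # -1 .. +1 across the roster
    c(duration = 3 * f, weight = 6 * f, bsa = 5 * f,
      prev_sys = 0.08 * f, psa = 0.05 * f)
  }), sids)
  truth <- list(
    mu = c(ipd_1 = -1.3, ipd_2 = -1.5, ipd_3 = -1.4, ipd_4 = -1.2,
           agd_1 = -1.6, agd_2 = -1.4, agd_3 = -1.3, agd_4 = -1.5,
           agd_5 = -1.4),
    gamma = c(ETN = 1.6, IXE_Q2W = 2.8, IXE_Q4W = 2.6,
              SEC_150 = 2.2, SEC_300 = 2.6, UST = 2.2),
    beta1 = c(duration = 0.10, weight = -0.15, bsa = -0.10,
              prev_sys = -0.20, psa = -0.10),
    beta2 = list(
      TNF = c(duration = 0.17, weight = -0.09, bsa = 0.04,
              prev_sys = 0.11, psa = 0.01),
      IL17 = c(duration = 0.17, weight = -0.05, bsa = 0.01,
               prev_sys = 0.13, psa = 0.28),
      IL1223 = c(duration = 0.12, weight = -0.04, bsa = 0.05,
                 prev_sys = -0.01, psa = 0.32)),
    cutpoints = c(0, 0.6, 1.4),
    tau = tau,
    inconsistency = inconsistency)
  cfg <- sim_config(studies, covariates, classes, truth,
                    reference = "PBO", outcome = pasi_outcome(),
                    correlation = correlation, study_offsets = study_offsets,
                    seed = seed)
  simulate_network(cfg)
}
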