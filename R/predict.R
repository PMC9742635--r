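#' Define a baseline-risk reference for an external target population
#'
#' External populations carry no study intercept, so average event
#' probabilities are anchored on an observed response rate for one reference
#' treatment: a Beta distribution for the average probability of achieving
#' the reference threshold (e.g. PASI 75) on that treatment, typically
#' `Beta(responders, N - responders)`.
#'
#' @param treatment Treatment id on which the response rate was observed.
#' @param responders,nonresponders Beta parameters; both must be positive.
#' @param threshold Outcome threshold the rate refers to (1 = first
#'   threshold, e.g. PASI 75).
#' @return An object of class `mlnmr_baseline`.
#' @examples
#' baseline_ref("SEC_300", 243, 330 - 243)
#' @export
baseline_ref <- function(treatment, responders, nonresponders, threshold = 1) {
  if (responders <= 0 || nonresponders <= 0)
    stop_mlnmr("both Beta parameters must be positive")
  structure(list(treatment = treatment, shape1 = responders,
                 shape2 = nonresponders, threshold = as.integer(threshold)),
            class = "mlnmr_baseline")
}

#' Define a target population from covariate summaries
#'
#' A target population for population-average estimates need not be a study
#' in the network: it is described by the same covariate marginal summaries
#' an AgD study would report (mean and sd for continuous covariates,
#' proportion for binary), an optional correlation matrix (defaulting to the
#' pooled IPD correlation), and an optional [baseline_ref()] for anchored
#' event probabilities.
#'
#' @param name Population label.
#' @param means,sds Named numeric vectors for continuous covariates (an sd of
#'   0 gives a degenerate, point-mass covariate).
#' @param props Named numeric vector of binary covariate proportions.
#' @param correlation Optional correlation matrix override.
#' @param baseline Optional [baseline_ref()].
#' @return An object of class `mlnmr_population`.
#' @export
target_population <- function(name, means = numeric(0), sds = numeric(0),
                              props = numeric(0), correlation = NULL,
                              baseline = NULL) {
  if (!identical(sort(names(means)), sort(names(sds))))
    stop_mlnmr("means and sds must cover the same covariates")
  structure(list(name = name, means = means, sds = sds, props = props,
                 correlation = correlation, baseline = baseline),
            class = "mlnmr_population")
}

# integration grid (original covariate scale) for a fitted model in a given
# population: an AgD study's stored grid, an IPD study's empirical rows, or a
# fresh grid built from an external population's summaries
population_grid <- function(fit, study = NULL, population = NULL,
                            n_points = NULL, seed = 101) {
  network <- fit$network
  covs <- fit$design$covs
  if (!is.null(study)) {
    if (study %in% names(network$agd)) {
      if (!length(covs)) return(matrix(0, 1, 0))
      return(network$grids[[study]]$points[, covs, drop = FALSE])
    }
    if (study %in% names(network$ipd))
      return(as.matrix(network$ipd[[study]]$data[, covs, drop = FALSE]))
    stop_mlnmr("unknown study ", sQuote(study))
  }
  stopifnot(inherits(population, "mlnmr_population"))
  if (!length(covs)) return(matrix(0, 1, 0))
  summaries <- list()
  for (cv in covs) {
    ty <- network$covariate_types[cv]
    if (ty == "binary") {
      if (!cv %in% names(population$props))
        stop_mlnmr("population ", population$name, " lacks a proportion for ",
                   sQuote(cv))
      summaries[[cv]] <- list(type = "binary", prop = population$props[[cv]])
    } else {
      if (!cv %in% names(population$means))
        stop_mlnmr("population ", population$name, " lacks mean/sd for ",
                   sQuote(cv))
      summaries[[cv]] <- list(type = "continuous",
                              mean = population$means[[cv]],
                              sd = population$sds[[cv]])
    }
  }
  fam <- fit$network$grid_info$families %||%
    stats::setNames(rep(NA_character_, length(covs)), covs)
  marg <- lapply(summaries, function(s) {
    if (s$type == "continuous" && s$sd == 0)
      list(family = "degenerate", value = s$mean)
    else NULL
  })
  nondeg <- vapply(marg, is.null, TRUE)
  built <- marginals_from_summaries(summaries[nondeg], fam,
                                    fit$network$grid_info$bounds %||% list())
  marg[nondeg] <- built
  names(marg) <- covs
  R <- population$correlation %||% fit$network$grid_info$correlation %||%
    diag(length(covs))
  n_points <- n_points %||% fit$network$grid_info$n_points %||% 1000
  deg <- !nondeg
  if (any(deg)) {
    # build only the stochastic covariates, then bind constants
    if (any(nondeg)) {
      Rsub <- R[covs[nondeg], covs[nondeg], drop = FALSE]
      g <- build_integration_grid(marg[nondeg], Rsub, n_points, seed)$points
    } else g <- matrix(0, n_points, 0)
    out <- matrix(0, nrow(g), length(covs), dimnames = list(NULL, covs))
    out[, covs[nondeg]] <- g
    for (cv in covs[deg]) out[, cv] <- marg[[cv]]$value
    return(out)
  }
  build_integration_grid(marg, R, n_points, seed)$points
}

transform_grid <- function(fit, G) {
  covs <- fit$design$covs
  if (!length(covs)) return(matrix(0, max(nrow(G), 1), 0))
  sweep(sweep(G[, covs, drop = FALSE], 2, fit$spec$centers[covs]),
        2, fit$spec$scales[covs], "/")
}

# draws x p coefficient matrices
beta1_draws <- function(fit) {
  if (!fit$design$p) return(matrix(0, nrow(pooled_draws(fit)), 0))
  pooled_draws(fit, paste0("beta1[", fit$design$covs, "]"))
}

beta2_draws_for <- function(fit, treatment) {
  design <- fit$design
  p <- design$p
  D <- nrow(pooled_draws(fit))
  if (!p) return(matrix(0, D, 0))
  idx <- design$ia$map[, treatment]
  out <- matrix(0, D, p)
  nz <- idx > 0
  if (any(nz))
    out[, nz] <- pooled_draws(fit, paste0("beta2[", design$ia$labels[idx[nz]], "]"))
  out
}

cut_draws <- function(fit) {
  C <- fit$design$C
  D <- nrow(pooled_draws(fit))
  cbind(0, if (C > 2) pooled_draws(fit, paste0("cut[", 2:(C - 1), "]"))
        else matrix(, D, 0))
}

summarise_draws_df <- function(x, by) {
  data.frame(by, mean = colMeans(x), sd = apply(x, 2, stats::sd),
             `2.5%` = apply(x, 2, stats::quantile, 0.025),
             `50%` = apply(x, 2, stats::quantile, 0.5),
             `97.5%` = apply(x, 2, stats::quantile, 0.975),
             check.names = FALSE, row.names = NULL)
}

#' Population-average conditional treatment effects
#'
#' Averages the covariate-conditional treatment effect `gamma_k + x'beta2_k`
#' over a population's covariate distribution, per posterior draw. Under the
#' probit link these are population-average standardised mean differences
#' versus the reference treatment; because the effect is linear in `x`, they
#' depend only on the population's effect-modifier means.
#'
#' @param fit A consistency `mlnmr_fit`.
#' @param study In-network study id whose population to use, or
#' @param population an [target_population()] for an external population.
#' @param n_points,seed Grid settings for external populations.
#' @return Data frame (class `mlnmr_estimates`): treatment, posterior mean,
#'   sd and equal-tailed credible interval of the conditional average effect.
#' @export
conditional_average_effects <- function(fit, study = NULL, population = NULL,
                                        n_points = NULL, seed = 101) {
  G <- population_grid(fit, study, population, n_points, seed)
  Xt <- transform_grid(fit, G)
  xbar <- if (ncol(Xt)) colMeans(Xt) else numeric(0)
  gd <- gamma_draws(fit)
  trts <- fit$design$trts[-1]
  eff <- vapply(seq_along(trts), function(i) {
    b2 <- beta2_draws_for(fit, trts[i])
    gd[, i] + if (ncol(b2)) as.numeric(b2 %*% xbar) else 0
  }, numeric(nrow(gd)))
  colnames(eff) <- trts
  out <- summarise_draws_df(eff, data.frame(treatment = trts,
                                            stringsAsFactors = FALSE))
  attr(out, "population") <- if (!is.null(study)) study else population$name
  attr(out, "estimand") <- "conditional average effect vs reference"
  class(out) <- c("mlnmr_estimates", class(out))
  out
}

# per-draw grid-averaged category probabilities for each treatment;
# mu_draws: vector of intercept draws (study intercept or solved mu*)
avg_prob_draws_all <- function(fit, Xt, mu_draws, subset = NULL) {
  design <- fit$design
  trts <- design$trts
  b1 <- beta1_draws(fit)
  gd <- gamma_draws(fit)
  cd <- cut_draws(fit)
  if (!is.null(subset)) {
    b1 <- b1[subset, , drop = FALSE]; gd <- gd[subset, , drop = FALSE]
    cd <- cd[subset, , drop = FALSE]; mu_draws <- mu_draws[subset]
  }
  out <- vector("list", length(trts))
  names(out) <- trts
  for (k in seq_along(trts)) {
    b2 <- beta2_draws_for(fit, trts[k])
    if (!is.null(subset)) b2 <- b2[subset, , drop = FALSE]
    eff <- if (k == 1) rep(0, length(mu_draws)) else gd[, k - 1]
    out[[k]] <- cpp_avg_probs_draws(Xt, mu_draws, b1 + b2, eff, cd,
                                    design$link)
  }
  out   # list per treatment of draws x C category probability matrices
}

incl_from_cat <- function(P) {
  # inclusive probabilities: P(category > c), c = 1..C-1
  C <- ncol(P)
  t(apply(P, 1, function(p) rev(cumsum(rev(p)))[-1]))
}

#' Population-average event probabilities in a network study
#'
#' For every treatment, the percentage of individuals in the population
#' represented by a network study who would achieve each outcome threshold:
#' the study's own intercept draws are combined with its covariate
#' distribution (the AgD integration grid, or the IPD study's observed
#' covariates).
#'
#' @param fit A consistency `mlnmr_fit`.
#' @param study In-network study id.
#' @return Data frame (class `mlnmr_estimates`): treatment, threshold,
#'   posterior summaries of the inclusive probabilities (as percentages).
#' @export
average_event_probs <- function(fit, study) {
  design <- fit$design
  G <- population_grid(fit, study = study)
  Xt <- transform_grid(fit, G)
  mu_draws <- pooled_draws(fit, paste0("mu[", study, "]"))[, 1]
  probs <- avg_prob_draws_all(fit, Xt, mu_draws)
  thresholds <- paste0(">=", seq_len(design$C - 1))
  tab <- do.call(rbind, lapply(names(probs), function(tr) {
    Q <- incl_from_cat(probs[[tr]]) * 100
    colnames(Q) <- thresholds
    summarise_draws_df(Q, data.frame(treatment = tr, threshold = thresholds,
                                     stringsAsFactors = FALSE))
  }))
  attr(tab, "population") <- study
  attr(tab, "estimand") <- "average inclusive event probability (%)"
  class(tab) <- c("mlnmr_estimates", class(tab))
  tab
}

#' Population-average event probabilities in an external population
#'
#' For a population outside the network the study intercept is unknown, so
#' each posterior draw samples a response probability `p*` from the
#' population's baseline-risk Beta distribution and solves (by monotone
#' bisection) for the intercept `mu*` at which the population-averaged
#' inclusive probability on the baseline treatment at the reference
#' threshold equals `p*`; all treatments' probabilities are then evaluated
#' at `mu*`. Draws whose `p*` is unattainable are dropped and counted.
#'
#' @param fit A consistency `mlnmr_fit`.
#' @param population A [target_population()] with a [baseline_ref()].
#' @param n_points,seed Grid settings.
#' @param tol Bisection tolerance on the probability scale.
#' @return Data frame (class `mlnmr_estimates`) as in
#'   [average_event_probs()], with attributes `n_flagged` (dropped draws) and
#'   `mustar` (the solved intercept draws).
#' @export
average_event_probs_external <- function(fit, population, n_points = NULL,
                                         seed = 101, tol = 1e-8) {
  stopifnot(inherits(population, "mlnmr_population"))
  bl <- population$baseline
  if (is.null(bl)) stop_mlnmr("population has no baseline_ref()")
  design <- fit$design
  G <- population_grid(fit, population = population, n_points = n_points,
                       seed = seed)
  Xt <- transform_grid(fit, G)
  D <- nrow(pooled_draws(fit))
  set.seed(derive_seed(seed, 7))
  pstar <- stats::rbeta(D, bl$shape1, bl$shape2)
  ref_trt <- bl$treatment
  if (!ref_trt %in% design$trts)
    stop_mlnmr("baseline treatment ", sQuote(ref_trt), " not in the network")
  b1 <- beta1_draws(fit)
  b2 <- beta2_draws_for(fit, ref_trt)
  gd <- gamma_draws(fit)
  kref <- match(ref_trt, design$trts)
  eff <- if (kref == 1) rep(0, D) else gd[, kref - 1]
  cd <- cut_draws(fit)
  mustar <- cpp_solve_mustar(Xt, b1 + b2, eff, cd, pstar, bl$threshold,
                             design$link, tol)
  ok <- is.finite(mustar)
  n_flagged <- sum(!ok)
  probs <- avg_prob_draws_all(fit, Xt, mustar, subset = which(ok))
  thresholds <- paste0(">=", seq_len(design$C - 1))
  tab <- do.call(rbind, lapply(names(probs), function(tr) {
    Q <- incl_from_cat(probs[[tr]]) * 100
    colnames(Q) <- thresholds
    summarise_draws_df(Q, data.frame(treatment = tr, threshold = thresholds,
                                     stringsAsFactors = FALSE))
  }))
  attr(tab, "population") <- population$name
  attr(tab, "estimand") <- "average inclusive event probability (%)"
  attr(tab, "n_flagged") <- n_flagged
  attr(tab, "mustar") <- mustar
  class(tab) <- c("mlnmr_estimates", class(tab))
  tab
}

#' Population-average marginal treatment effects
#'
#' The marginal (unadjusted) analogue of the conditional average effect:
#' per posterior draw, the probit (or logit) difference between each
#' treatment's population-average inclusive probability and the reference's
#' at a chosen threshold. Under noncollapsible links marginal effects differ
#' from conditional average effects whenever the population is heterogeneous,
#' and depend on the baseline risk and prognostic covariates as well as the
#' effect modifiers.
#'
#' @param fit A consistency `mlnmr_fit`.
#' @param study,population Where to evaluate (as in
#'   [conditional_average_effects()]); external populations require a
#'   baseline reference.
#' @param threshold Threshold index (1 = first, e.g. PASI 75).
#' @param n_points,seed Grid settings for external populations.
#' @return Data frame (class `mlnmr_estimates`) of marginal effects versus
#'   the reference treatment.
#' @export
marginal_effects <- function(fit, study = NULL, population = NULL,
                             threshold = 1, n_points = NULL, seed = 101) {
  design <- fit$design
  G <- population_grid(fit, study, population, n_points, seed)
  Xt <- transform_grid(fit, G)
  if (!is.null(study)) {
    mu_draws <- pooled_draws(fit, paste0("mu[", study, "]"))[, 1]
    subset <- NULL
  } else {
    bl <- population$baseline
    if (is.null(bl))
      stop_mlnmr("external populations need a baseline_ref() for marginal effects")
    D <- nrow(pooled_draws(fit))
    set.seed(derive_seed(seed, 7))
    pstar <- stats::rbeta(D, bl$shape1, bl$shape2)
    b2 <- beta2_draws_for(fit, bl$treatment)
    gd0 <- gamma_draws(fit)
    kref <- match(bl$treatment, design$trts)
    effr <- if (kref == 1) rep(0, D) else gd0[, kref - 1]
    mu_draws <- cpp_solve_mustar(Xt, beta1_draws(fit) + b2, effr,
                                 cut_draws(fit), pstar, bl$threshold,
                                 design$link, 1e-8)
    subset <- which(is.finite(mu_draws))
  }
  probs <- avg_prob_draws_all(fit, Xt, mu_draws, subset)
  qf <- if (design$link == 0L) stats::qnorm else stats::qlogis
  pref <- incl_from_cat(probs[[1]])[, threshold]
  trts <- design$trts[-1]
  eff <- vapply(trts, function(tr) {
    qf(clamp(incl_from_cat(probs[[tr]])[, threshold], 1e-12, 1 - 1e-12)) -
      qf(clamp(pref, 1e-12, 1 - 1e-12))
  }, numeric(length(pref)))
  out <- summarise_draws_df(eff, data.frame(treatment = trts,
                                            stringsAsFactors = FALSE))
  attr(out, "population") <- if (!is.null(study)) study else population$name
  attr(out, "estimand") <- sprintf("marginal effect vs reference (threshold %d)",
                                   threshold)
  attr(out, "threshold") <- threshold
  class(out) <- c("mlnmr_estimates", class(out))
  out
}

#' @export
print.mlnmr_estimates <- function(x, ...) {
  cat(attr(x, "estimand"), "in population", sQuote(attr(x, "population")), "\n")
  nf <- attr(x, "n_flagged")
  if (!is.null(nf) && nf > 0)
    cat("  (", nf, "draws dropped: baseline risk unattainable )\n")
  df <- x; class(df) <- "data.frame"
  num <- vapply(df, is.numeric, TRUE)
  df[num] <- lapply(df[num], round, 3)
  print(df)
  invisible(x)
}

#' Predict method for ML-NMR fits
#'
#' Thin dispatcher over the population-average estimators: `type =
#' "effects"` gives conditional average effects, `"probs"` average event
#' probabilities (anchored automatically for external populations with a
#' baseline reference), `"marginal"` marginal effects.
#'
#' @param object An `mlnmr_fit`.
#' @param type One of `"effects"`, `"probs"`, `"marginal"`.
#' @param study,population Target population (one of the two).
#' @param ... Passed to the underlying estimator.
#' @return An `mlnmr_estimates` data frame.
#' @export
predict.mlnmr_fit <- function(object, type = c("effects", "probs", "marginal"),
                              study = NULL, population = NULL, ...) {
  type <- match.arg(type)
  switch(type,
    effects = conditional_average_effects(object, study, population, ...),
    probs = if (!is.null(study)) average_event_probs(object, study)
            else average_event_probs_external(object, population, ...),
    marginal = marginal_effects(object, study, population, ...))
}
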