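#' Prior specification
#'
#' Vague `N(0, sd^2)` priors on intercepts, regression coefficients and
#' treatment effects (default sd 10); improper flat priors on the ordered
#' cutpoints (subject to ordering, with the first fixed at 0); a weakly
#' informative half-normal prior on the heterogeneity standard deviation
#' `tau` (default scale 2.5, putting 95% prior probability on `tau` between
#' 0 and 5).
#'
#' @param effect_sd Normal prior sd for `mu`, `beta1`, `beta2`, and treatment
#'   effects.
#' @param tau_scale Half-normal scale for `tau`.
#' @return An object of class `mlnmr_priors`.
#' @export
prior_spec <- function(effect_sd = 10, tau_scale = 2.5) {
  if (effect_sd <= 0 || tau_scale <= 0) stop_mlnmr("prior scales must be positive")
  structure(list(effect_sd = effect_sd, tau_scale = tau_scale),
            class = "mlnmr_priors")
}

#' Prior probability that tau is below a bound
#'
#' Computed by quadrature on the half-normal prior density, e.g. the default
#' half-N(0, 2.5^2) puts approximately 95% prior probability on `tau <= 5`.
#'
#' @param priors A [prior_spec()].
#' @param upper Upper bound for `tau`.
#' @return Probability in (0, 1).
#' @export
tau_prior_prob <- function(priors = prior_spec(), upper = 5) {
  stats::integrate(function(x) 2 * stats::dnorm(x, 0, priors$tau_scale),
                   0, upper, rel.tol = 1e-10)$value
}

#' Fit a multilevel network meta-regression model
#'
#' Estimates the ML-NMR model on an assembled evidence network by MCMC:
#' IPD studies contribute an individual-level ordered categorical likelihood,
#' AgD studies an ordered multinomial likelihood with category probabilities
#' integrated over each study's reconstructed covariate distribution
#' (quasi-Monte Carlo grids attached by [add_integration()]).
#'
#' Convergence is gated on the split potential scale reduction factor: the
#' fit fails (or warns, per `on_nonconvergence`) unless `max R-hat < 1.01`.
#'
#' @param network An `mlnmr_network`, with integration grids attached when it
#'   contains AgD studies and covariates are modelled.
#' @param spec A [model_spec()].
#' @param priors A [prior_spec()].
#' @param chains Number of MCMC chains (default 4).
#' @param iter_warmup,iter_sampling Iterations per chain.
#' @param seed Integer seed; chain seeds are derived deterministically.
#' @param on_nonconvergence `"error"` (default), `"warn"` or `"none"`.
#' @return An object of class `mlnmr_fit`.
#' @export
mlnmr <- function(network, spec = model_spec(), priors = prior_spec(),
                  chains = 4, iter_warmup = 1000, iter_sampling = 1000,
                  seed = 1,
                  on_nonconvergence = c("error", "warn", "none")) {
  on_nonconvergence <- match.arg(on_nonconvergence)
  stopifnot(inherits(network, "mlnmr_network"))
  t0 <- proc.time()[3]
  design <- build_design(network, spec)
  res <- lapply(seq_len(chains), function(ch) {
    run_chain(design, priors, iter_warmup, iter_sampling,
              seed = derive_seed(seed, ch))
  })
  draws <- lapply(res, `[[`, "draws")
  parnames <- colnames(draws[[1]])
  report <- setdiff(parnames, "loglik__")
  rhat <- vapply(report, function(pn)
    split_rhat(sapply(draws, function(d) d[, pn])), 0)
  ess <- vapply(report, function(pn)
    ess_basic(sapply(draws, function(d) d[, pn])), 0)
  maxr <- max(rhat, na.rm = TRUE)
  converged <- is.finite(maxr) && maxr < 1.01
  if (!converged) {
    msg <- sprintf("convergence gate failed: max split R-hat = %.3f (>= 1.01)",
                   maxr)
    if (on_nonconvergence == "error") stop_mlnmr(msg)
    if (on_nonconvergence == "warn") warning(msg, call. = FALSE)
  }
  fit <- structure(
    list(network = network, spec = design$spec, design = design,
         priors = priors, draws = draws, parnames = parnames,
         rhat = rhat, ess = ess,
         n_divergent = 0L,   # random-walk sampler: divergence-free by construction
         accept = lapply(res, `[[`, "accept"),
         chains = chains, iter_warmup = iter_warmup,
         iter_sampling = iter_sampling, seed = seed,
         converged = converged,
         time = proc.time()[3] - t0),
    class = "mlnmr_fit")
  fit
}

# pooled draws matrix (all chains stacked)
pooled_draws <- function(fit, pars = NULL) {
  d <- do.call(rbind, fit$draws)
  if (!is.null(pars)) d <- d[, pars, drop = FALSE]
  d
}

#' @export
as.matrix.mlnmr_fit <- function(x, ...) pooled_draws(x)

#' Split potential scale reduction factor (R-hat)
#'
#' Each chain is split in half and the standard between/within variance ratio
#' computed on the split chains.
#'
#' @param x Iterations-by-chains matrix of draws for one parameter.
#' @return Scalar R-hat (NA for constant draws).
#' @export
split_rhat <- function(x) {
  x <- as.matrix(x)
  n <- nrow(x)
  h <- floor(n / 2)
  sub <- cbind(x[seq_len(h), , drop = FALSE],
               x[(n - h + 1):n, , drop = FALSE])
  m <- ncol(sub)
  means <- colMeans(sub)
  vars <- apply(sub, 2, stats::var)
  W <- mean(vars)
  B <- h * stats::var(means)
  if (!is.finite(W) || W <= 1e-300) return(NA_real_)
  sqrt(((h - 1) / h * W + B / h) / W)
}

#' Effective sample size (initial positive sequence estimator)
#' @param x Iterations-by-chains matrix of draws for one parameter.
#' @return Scalar effective sample size.
#' @export
ess_basic <- function(x) {
  x <- as.matrix(x)
  n <- nrow(x); m <- ncol(x)
  if (stats::var(as.numeric(x)) <= 1e-300) return(NA_real_)
  maxlag <- min(n - 1, 500)
  rho <- rowMeans(vapply(seq_len(m), function(ch) {
    a <- stats::acf(x[, ch], lag.max = maxlag, plot = FALSE,
                    demean = TRUE)$acf[, 1, 1]
    a
  }, numeric(maxlag + 1)))
  # Geyer initial positive sequence on paired sums
  s <- 0; lag <- 1
  while (lag + 1 <= maxlag) {
    pair <- rho[lag + 1] + if (lag + 2 <= maxlag + 1) rho[lag + 2] else 0
    if (!is.finite(pair) || pair < 0) break
    s <- s + pair
    lag <- lag + 2
  }
  n * m / (1 + 2 * s)
}

#' @export
print.mlnmr_fit <- function(x, ...) {
  cat("ML-NMR fit:", x$spec$effects, "effects,", x$spec$contrasts,
      "contrasts,", x$spec$link, "link\n")
  cat(sprintf("  %d chains x %d sampling iterations (%.1f s); max R-hat %.3f%s\n",
              x$chains, x$iter_sampling, x$time, max(x$rhat, na.rm = TRUE),
              if (x$converged) "" else "  ** NOT CONVERGED **"))
  eff <- grep("^(gamma|d)\\[", x$parnames, value = TRUE)
  print(round(summary(x, pars = c(eff, if ("tau" %in% x$parnames) "tau")), 3))
  invisible(x)
}

#' Posterior summaries
#'
#' @param object An `mlnmr_fit`.
#' @param pars Optional parameter names (default: all).
#' @param probs Quantiles to report.
#' @param ... Unused.
#' @return Data frame with mean, sd, quantiles, R-hat and ESS per parameter.
#' @export
summary.mlnmr_fit <- function(object, pars = NULL,
                              probs = c(0.025, 0.5, 0.975), ...) {
  pars <- pars %||% setdiff(object$parnames, "loglik__")
  d <- pooled_draws(object, pars)
  qs <- t(apply(d, 2, stats::quantile, probs = probs))
  out <- data.frame(mean = colMeans(d), sd = apply(d, 2, stats::sd), qs,
                    check.names = FALSE)
  out$rhat <- object$rhat[pars]
  out$ess <- object$ess[pars]
  out
}

#' Posterior mean treatment effects
#'
#' For consistency fits, the individual-level treatment effects `gamma`
#' (standardised mean differences versus the reference under the probit
#' link); for UME fits, the unrelated contrasts.
#'
#' @param object An `mlnmr_fit`.
#' @param ... Unused.
#' @return Named numeric vector of posterior means.
#' @export
coef.mlnmr_fit <- function(object, ...) {
  pars <- grep("^(gamma|d)\\[", object$parnames, value = TRUE)
  cm <- colMeans(pooled_draws(object, pars))
  names(cm) <- sub("^(gamma|d)\\[(.*)\\]$", "\\2", names(cm))
  cm
}

#' Forest-style plot of treatment effects
#' @param x An `mlnmr_fit`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.mlnmr_fit <- function(x, ...) {
  pars <- grep("^(gamma|d)\\[", x$parnames, value = TRUE)
  s <- summary(x, pars = pars)
  k <- nrow(s)
  graphics::plot(s$mean, seq_len(k), xlim = range(s[["2.5%"]], s[["97.5%"]], 0),
                 yaxt = "n", ylab = "", pch = 16,
                 xlab = "Effect vs reference (link scale)", ...)
  graphics::segments(s[["2.5%"]], seq_len(k), s[["97.5%"]], seq_len(k))
  graphics::abline(v = 0, lty = 2)
  graphics::axis(2, at = seq_len(k),
                 labels = sub("^(gamma|d)\\[(.*)\\]$", "\\2", rownames(s)),
                 las = 1)
  invisible(s)
}

# natural state for one posterior draw row
draw_state <- function(design, row) {
  J <- design$J; C <- design$C; p <- design$p
  m2 <- design$ia$n_free
  mu <- as.numeric(row[paste0("mu[", design$studies, "]")])
  cuts <- c(0, if (C > 2) as.numeric(row[paste0("cut[", 2:(C - 1), "]")]))
  beta1 <- if (p) as.numeric(row[paste0("beta1[", design$covs, "]")]) else numeric(0)
  B2 <- expand_B2(design, if (m2) as.numeric(row[paste0("beta2[", design$ia$labels, "]")])
                          else numeric(0))
  random <- design$spec$effects == "random"
  ume <- design$spec$contrasts == "ume"
  eff <- numeric(design$n_units)
  if (random) {
    nd <- which(!design$unit_arm1)
    lab <- paste0("delta[", design$studies[design$unit_study[nd]], ":",
                  design$trts[design$unit_trt[nd]], "]")
    eff[nd] <- as.numeric(row[lab])
  } else if (ume) {
    nd <- !design$unit_arm1
    dvals <- as.numeric(row[paste0("d[", design$pairs, "]")])
    eff[nd] <- dvals[design$unit_pair[nd]]
  } else {
    gam <- c(0, as.numeric(row[paste0("gamma[", design$trts[-1], "]")]))
    eff <- gam[design$unit_trt]
  }
  list(mu = mu, cuts = cuts, beta1 = beta1, B2 = B2, eff = eff)
}

# effect draws for treatment k (consistency fits): matrix draws x treatments
gamma_draws <- function(fit) {
  if (fit$spec$contrasts != "consistency")
    stop_mlnmr("population-average estimates require a consistency fit")
  pooled_draws(fit, paste0("gamma[", fit$design$trts[-1], "]"))
}
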