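#' Gamma parameters from a mean and standard deviation
#'
#' Continuous, right-skewed covariates reported only as mean and SD (e.g.
#' weight in kg, disease duration in years) are modelled as Gamma
#' distributions. Moment matching is closed form: `shape = mean^2/sd^2`,
#' `rate = mean/sd^2`.
#'
#' @param mean,sd Positive reals.
#' @return Named list with `shape` and `rate`.
#' @examples
#' gamma_from_moments(2, 1)   # shape 4, rate 2
#' @export
gamma_from_moments <- function(mean, sd) {
  if (!is.finite(mean) || mean <= 0) stop_mlnmr("mean must be positive")
  if (!is.finite(sd) || sd <= 0) stop_mlnmr("sd must be positive")
  list(shape = mean^2 / sd^2, rate = mean / sd^2)
}

# moments of lower + (upper-lower) * plogis(Z), Z ~ N(mu, sigma^2), by
# adaptive quadrature on the normal scale
logitnormal_moments <- function(mu, sigma, lower, upper) {
  w <- upper - lower
  if (sigma < 1e-12) {
    m <- lower + w * stats::plogis(mu)
    return(c(mean = m, sd = 0))
  }
  f1 <- stats::integrate(function(z) stats::plogis(mu + sigma * z) * stats::dnorm(z),
                         -Inf, Inf, rel.tol = 1e-12)$value
  f2 <- stats::integrate(function(z) stats::plogis(mu + sigma * z)^2 * stats::dnorm(z),
                         -Inf, Inf, rel.tol = 1e-12)$value
  m <- lower + w * f1
  v <- w^2 * max(f2 - f1^2, 0)
  c(mean = m, sd = sqrt(v))
}

#' Scaled logit-Normal parameters from a mean and standard deviation
#'
#' Bounded-percentage covariates (e.g. body surface area on 0-100) are given a
#' scaled logit-Normal distribution: `X = lower + (upper - lower) *
#' plogis(Z)`, `Z ~ N(mu, sigma^2)`. The two parameters are solved numerically
#' so the distribution's first two moments (computed by quadrature) match the
#' reported mean and SD to within `tol`.
#'
#' @param mean,sd Target mean and standard deviation on the original scale.
#' @param lower,upper Finite support bounds, `lower < mean < upper`.
#' @param tol Moment-matching tolerance (default `1e-8`).
#' @return Named list with `mu`, `sigma`, `lower`, `upper`.
#' @export
logitnormal_from_moments <- function(mean, sd, lower = 0, upper = 100,
                                     tol = 1e-8) {
  if (!is.finite(lower) || !is.finite(upper) || lower >= upper)
    stop_mlnmr("bounds must be finite with lower < upper")
  if (mean <= lower || mean >= upper)
    stop_mlnmr("mean must lie strictly inside (lower, upper)")
  if (sd < 0) stop_mlnmr("sd must be non-negative")
  if (sd == 0) return(list(mu = stats::qlogis((mean - lower) / (upper - lower)),
                           sigma = 0, lower = lower, upper = upper))
  sd_max <- sqrt((mean - lower) * (upper - mean))
  if (sd >= sd_max)
    stop_mlnmr("sd = ", sd, " is infeasible on (", lower, ", ", upper,
               ") with mean ", mean, " (limit ", signif(sd_max, 6), ")")
  mu_for <- function(sigma) {
    # mean is strictly increasing in mu at fixed sigma
    stats::uniroot(function(mu) logitnormal_moments(mu, sigma, lower, upper)["mean"] - mean,
                   c(-50, 50), tol = 1e-12)$root
  }
  sd_of <- function(sigma) {
    logitnormal_moments(mu_for(sigma), sigma, lower, upper)["sd"] - sd
  }
  # sd is increasing in sigma once mu is re-solved to hold the mean fixed
  hi <- 1
  while (sd_of(hi) < 0 && hi < 64) hi <- hi * 2
  if (sd_of(hi) < 0) stop_mlnmr("no scaled logit-Normal matches sd = ", sd)
  sigma <- stats::uniroot(sd_of, c(1e-10, hi), tol = tol)$root
  mu <- mu_for(sigma)
  mom <- logitnormal_moments(mu, sigma, lower, upper)
  if (abs(mom["mean"] - mean) > 1e-6 || abs(mom["sd"] - sd) > 1e-4 * max(1, sd))
    stop_mlnmr("moment matching failed to converge")
  list(mu = mu, sigma = sigma, lower = lower, upper = upper)
}

#' Pooled covariate correlation matrix from the IPD studies
#'
#' AgD studies report no correlation information, so the joint covariate
#' distribution in each AgD study (and in external target populations) uses
#' the weighted average of the Pearson correlation matrices observed in the
#' IPD studies, weights defaulting to IPD sample sizes. The average is
#' repaired to the nearest positive semi-definite correlation matrix by
#' eigenvalue clipping if necessary.
#'
#' @param ipd List of `mlnmr_ipd` studies, or an `mlnmr_network`.
#' @param weights Optional numeric weights, one per IPD study.
#' @return Correlation matrix with covariates as dimnames.
#' @export
pooled_correlation <- function(ipd, weights = NULL) {
  if (inherits(ipd, "mlnmr_network")) ipd <- ipd$ipd
  if (!length(ipd)) stop_mlnmr("no IPD studies to pool correlations from")
  covs <- ipd[[1]]$covariates
  if (length(covs) < 2L) stop_mlnmr("need at least 2 covariates")
  weights <- weights %||% vapply(ipd, `[[`, 0, "n")
  weights <- weights / sum(weights)
  p <- length(covs)
  acc <- matrix(0, p, p, dimnames = list(covs, covs))
  wacc <- matrix(0, p, p)
  for (i in seq_along(ipd)) {
    X <- as.matrix(ipd[[i]]$data[, covs, drop = FALSE])
    sds <- apply(X, 2, stats::sd)
    ok <- sds > 0
    if (any(ok)) {
      R <- suppressWarnings(stats::cor(X[, ok, drop = FALSE]))
      acc[ok, ok] <- acc[ok, ok] + weights[i] * R
      wacc[ok, ok] <- wacc[ok, ok] + weights[i]
    }
  }
  if (any(diag(wacc) == 0))
    stop_mlnmr("covariate(s) constant in every IPD study: ",
               paste(covs[diag(wacc) == 0], collapse = ", "))
  R <- acc / wacc
  diag(R) <- 1
  repair_correlation(R)
}

# nearest-PSD repair by eigenvalue clipping, then rescale to unit diagonal
repair_correlation <- function(R, eps = 1e-8) {
  R <- (R + t(R)) / 2
  e <- eigen(R, symmetric = TRUE)
  if (min(e$values) < eps) {
    lam <- pmax(e$values, eps)
    R2 <- e$vectors %*% diag(lam, length(lam)) %*% t(e$vectors)
    d <- sqrt(diag(R2))
    R2 <- R2 / tcrossprod(d)
    dimnames(R2) <- dimnames(R)
    R <- R2
  }
  R
}

# radical-inverse (van der Corput) sequence in the given base
radical_inverse <- function(idx, base) {
  out <- numeric(length(idx))
  f <- 1 / base
  while (any(idx > 0)) {
    out <- out + f * (idx %% base)
    idx <- idx %/% base
    f <- f / base
  }
  out
}

#' Randomised low-discrepancy point set on the unit hypercube
#'
#' Halton sequence with a Cranley-Patterson random shift per dimension; the
#' shift makes the quasi-Monte Carlo integration error estimable while
#' preserving the low-discrepancy structure. Suitable for the moderate
#' dimensions (a handful of covariates) used here.
#'
#' @param n Number of points (at least 2).
#' @param d Dimension.
#' @param seed Integer seed for the random shift.
#' @return `n` by `d` matrix of points in (0, 1).
#' @export
qmc_points <- function(n, d, seed = 1) {
  if (n < 2) stop_mlnmr("n_points must be at least 2")
  primes <- c(2, 3, 5, 7, 11, 13, 17, 19, 23, 29, 31, 37)
  if (d > length(primes)) stop_mlnmr("dimension too large for Halton bases")
  u <- vapply(seq_len(d), function(j) radical_inverse(seq_len(n), primes[j]),
              numeric(n))
  u <- matrix(u, nrow = n)
  shift <- withr_seed_runif(d, seed)
  u <- (u + matrix(shift, n, d, byrow = TRUE)) %% 1
  clamp(u, 1e-12, 1 - 1e-12)
}

# runif under a local seed without disturbing the caller's RNG stream
withr_seed_runif <- function(d, seed) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
          else suppressWarnings(rm(".Random.seed", envir = globalenv())))
  set.seed(seed)
  stats::runif(d)
}

marginal_quantile <- function(marginal, u) {
  switch(marginal$family,
    gamma = stats::qgamma(u, shape = marginal$shape, rate = marginal$rate),
    scaled_logit_normal = marginal$lower + (marginal$upper - marginal$lower) *
      stats::plogis(stats::qnorm(u, marginal$mu, max(marginal$sigma, 0))),
    bernoulli = as.numeric(u > 1 - marginal$prob),
    stop_mlnmr("unknown marginal family ", sQuote(marginal$family)))
}

#' Build a quasi-Monte Carlo integration grid
#'
#' Constructs correlated covariate points for averaging the individual-level
#' model over a covariate joint distribution: randomised low-discrepancy
#' points are mapped to standard-normal scores, correlated through a Gaussian
#' copula (Cholesky factor of the latent correlation), and pushed through each
#' covariate's marginal inverse CDF. Binary covariates are thresholded on the
#' latent normal at the `1 - proportion` quantile, reproducing the reported
#' proportion exactly in expectation.
#'
#' @param marginals Named list of marginal specifications, each a list with a
#'   `family` of `"gamma"` (`shape`, `rate`), `"scaled_logit_normal"` (`mu`,
#'   `sigma`, `lower`, `upper`) or `"bernoulli"` (`prob`).
#' @param correlation Latent correlation matrix (default independence);
#'   repaired to positive semi-definite if necessary.
#' @param n_points Number of integration points (default 1000).
#' @param seed Integer seed for the randomised point set.
#' @return An `mlnmr_grid`: list with `points` (matrix `n_points` by
#'   covariates), `n_points`, `seed`, `marginals`, `correlation`.
#' @export
build_integration_grid <- function(marginals, correlation = NULL,
                                   n_points = 1000, seed = 1) {
  covs <- names(marginals)
  d <- length(covs)
  if (!d) stop_mlnmr("no marginals supplied")
  if (is.null(correlation)) correlation <- diag(d)
  if (!isTRUE(all.equal(dim(correlation), c(d, d))))
    stop_mlnmr("correlation has wrong dimension")
  if (!is.null(dimnames(correlation)) && !is.null(rownames(correlation)))
    correlation <- correlation[covs, covs, drop = FALSE]
  correlation <- repair_correlation(correlation)
  U <- qmc_points(n_points, d, seed)
  Z <- stats::qnorm(U)
  L <- chol(correlation + diag(1e-10, d))      # upper triangular, t(L) %*% L = R
  Zc <- Z %*% L
  X <- matrix(0, n_points, d, dimnames = list(NULL, covs))
  for (j in seq_len(d)) {
    X[, j] <- marginal_quantile(marginals[[j]], stats::pnorm(Zc[, j]))
  }
  structure(list(points = X, n_points = n_points, seed = seed,
                 marginals = marginals, correlation = correlation),
            class = "mlnmr_grid")
}

# pool per-arm AgD covariate summaries into study-level marginal summaries
# (sample-size weighted mean; variance by the law of total variance)
study_marginal_summaries <- function(agd_study) {
  arms <- agd_study$arms
  w <- arms$n / sum(arms$n)
  types <- agd_study$covariate_types
  out <- list()
  for (cv in agd_study$covariates) {
    if (types[cv] == "binary") {
      out[[cv]] <- list(type = "binary",
                        prop = sum(w * arms[[paste0(cv, "_prop")]]))
    } else {
      m <- arms[[paste0(cv, "_mean")]]
      s <- arms[[paste0(cv, "_sd")]]
      mbar <- sum(w * m)
      v <- sum(w * (s^2 + m^2)) - mbar^2
      out[[cv]] <- list(type = "continuous", mean = mbar, sd = sqrt(v))
    }
  }
  out
}

# build a marginal spec list from summary statistics + family assignment
marginals_from_summaries <- function(summaries, families, bounds) {
  out <- list()
  for (cv in names(summaries)) {
    s <- summaries[[cv]]
    if (s$type == "binary") {
      out[[cv]] <- list(family = "bernoulli", prob = s$prop)
    } else {
      fam <- families[cv]
      if (is.na(fam)) fam <- "gamma"
      if (fam == "gamma") {
        gp <- gamma_from_moments(s$mean, s$sd)
        out[[cv]] <- list(family = "gamma", shape = gp$shape, rate = gp$rate)
      } else if (fam == "scaled_logit_normal") {
        b <- bounds[[cv]] %||% c(0, 100)
        lp <- logitnormal_from_moments(s$mean, s$sd, b[1], b[2])
        out[[cv]] <- c(list(family = "scaled_logit_normal"), lp)
      } else stop_mlnmr("unknown marginal family ", sQuote(fam),
                        " for covariate ", sQuote(cv))
    }
  }
  out
}

#' Attach integration grids to a network
#'
#' Reconstructs the covariate joint distribution of every AgD study from its
#' reported marginal summaries (continuous covariates as Gamma or scaled
#' logit-Normal, binary as Bernoulli) and the pooled IPD correlation matrix,
#' then builds one QMC integration grid per AgD study. Must be called before
#' fitting when the network contains AgD studies and covariates.
#'
#' @param network An `mlnmr_network`.
#' @param n_points Integration points per study (default 1000).
#' @param seed Base seed; each study's grid uses a seed derived from it.
#' @param families Named character vector assigning `"gamma"` or
#'   `"scaled_logit_normal"` to continuous covariates (default all Gamma).
#' @param bounds Named list of `c(lower, upper)` for scaled logit-Normal
#'   covariates (default `c(0, 100)`).
#' @param correlation Optional latent correlation matrix overriding the pooled
#'   IPD correlation.
#' @return The network with `grids` (one `mlnmr_grid` per AgD study) and
#'   `grid_info` attached.
#' @export
add_integration <- function(network, n_points = 1000, seed = 1,
                            families = NULL, bounds = list(),
                            correlation = NULL) {
  stopifnot(inherits(network, "mlnmr_network"))
  covs <- network$covariates
  if (!length(covs) || !length(network$agd)) {
    network$grids <- list()
    network$grid_info <- list(n_points = n_points, seed = seed)
    return(network)
  }
  fam <- stats::setNames(rep(NA_character_, length(covs)), covs)
  if (!is.null(families)) fam[names(families)] <- families
  if (is.null(correlation)) {
    correlation <- if (length(network$ipd) && length(covs) >= 2)
      pooled_correlation(network$ipd) else diag(length(covs))
    if (is.null(dimnames(correlation)))
      dimnames(correlation) <- list(covs, covs)
  }
  grids <- list()
  for (s in names(network$agd)) {
    summ <- study_marginal_summaries(network$agd[[s]])
    marg <- marginals_from_summaries(summ, fam, bounds)
    grids[[s]] <- build_integration_grid(
      marg, correlation, n_points,
      seed = derive_seed(seed, match(s, names(network$agd))))
  }
  network$grids <- grids
  network$grid_info <- list(n_points = n_points, seed = seed,
                            families = fam, bounds = bounds,
                            correlation = correlation)
  network
}
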