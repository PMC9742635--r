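#' Specify an ML-NMR model
#'
#' Defines the structural choices of a multilevel network meta-regression
#' model: fixed or random study-specific treatment effects, consistency or
#' unrelated-mean-effects (UME) contrasts, the interaction (effect modifier)
#' structure, covariate centering/scaling, and the link function.
#'
#' Interactions: with `"class"` every treatment in a class shares one
#' interaction coefficient per covariate (the shared effect modifier
#' assumption); with `"independent"` each active treatment gets its own. A
#' named character vector mixes the two per covariate, which is how the
#' shared-effect-modifier assumption is relaxed one covariate at a time.
#'
#' Continuous covariates are centered at reference values and divided by a
#' scaling constant (default 10, so coefficients are per 10 units, e.g.
#' "per 10 kg"); binary covariates are left on 0/1. Defaults for the
#' psoriasis-type covariate names are duration 18.2 y, bsa 29.8%, weight
#' 89.3 kg; otherwise the pooled mean across studies is used.
#'
#' @param effects `"fixed"` or `"random"` study-specific treatment effects.
#' @param contrasts `"consistency"` (effects expressed against the network
#'   reference, consistency equations imposed) or `"ume"` (independent
#'   contrasts per observed design, for inconsistency checking).
#' @param interactions `"class"`, `"independent"`, `"none"`, or a named
#'   character vector per covariate with values `"class"`/`"independent"`.
#' @param covariates Covariates to adjust for (default: all in the network;
#'   `character(0)` gives an unadjusted NMA).
#' @param centers,scales Optional named numeric vectors overriding the
#'   centering values / scaling divisors.
#' @param link `"probit"` (default; effects are standardised mean
#'   differences) or `"logit"`.
#' @return An object of class `mlnmr_spec`.
#' @export
model_spec <- function(effects = c("fixed", "random"),
                       contrasts = c("consistency", "ume"),
                       interactions = "class",
                       covariates = NULL,
                       centers = NULL, scales = NULL,
                       link = c("probit", "logit")) {
  structure(list(effects = match.arg(effects),
                 contrasts = match.arg(contrasts),
                 interactions = interactions,
                 covariates = covariates,
                 centers = centers, scales = scales,
                 link = match.arg(link)),
            class = "mlnmr_spec")
}

default_center <- c(duration = 18.2, bsa = 29.8, weight = 89.3)

# fill in covariates, per-covariate interaction structure, centers and scales
resolve_spec <- function(network, spec) {
  covs <- spec$covariates %||% network$covariates
  if (length(covs)) covs <- intersect(network$covariates, covs)
  types <- network$covariate_types[covs]
  ia <- spec$interactions
  if (identical(ia, "none") || !length(covs)) {
    ia_map <- stats::setNames(rep("none", length(covs)), covs)
  } else if (is.character(ia) && length(ia) == 1L && is.null(names(ia))) {
    ia_map <- stats::setNames(rep(ia, length(covs)), covs)
  } else {
    unknown <- setdiff(names(ia), covs)
    if (length(unknown))
      stop_mlnmr("interaction structure names unknown covariate(s): ",
                 paste(unknown, collapse = ", "))
    ia_map <- stats::setNames(rep("class", length(covs)), covs)
    ia_map[names(ia)] <- ia
  }
  bad <- setdiff(unique(ia_map), c("class", "independent", "none"))
  if (length(bad)) stop_mlnmr("unknown interaction structure: ", bad[1])
  centers <- stats::setNames(rep(0, length(covs)), covs)
  scales <- stats::setNames(rep(1, length(covs)), covs)
  pooled <- pooled_covariate_means(network)
  for (cv in covs) {
    if (types[cv] == "continuous") {
      centers[cv] <- if (cv %in% names(default_center)) default_center[[cv]]
                     else pooled[cv]
      scales[cv] <- 10
    }
  }
  if (!is.null(spec$centers)) centers[names(spec$centers)] <- spec$centers
  if (!is.null(spec$scales)) {
    if (any(spec$scales <= 0)) stop_mlnmr("scaling divisors must be positive")
    scales[names(spec$scales)] <- spec$scales
  }
  spec$covariates <- covs
  spec$interaction_map <- ia_map
  spec$centers <- centers
  spec$scales <- scales
  spec
}

pooled_covariate_means <- function(network) {
  covs <- network$covariates
  if (!length(covs)) return(numeric(0))
  tot <- stats::setNames(rep(0, length(covs)), covs)
  n <- 0
  for (s in network$ipd) {
    tot <- tot + colSums(as.matrix(s$data[, covs, drop = FALSE]))
    n <- n + s$n
  }
  for (s in network$agd) {
    summ <- study_marginal_summaries(s)
    for (cv in covs) {
      m <- if (summ[[cv]]$type == "binary") summ[[cv]]$prop else summ[[cv]]$mean
      tot[cv] <- tot[cv] + m * s$n
    }
    n <- n + s$n
  }
  tot / n
}

#' Resolve the interaction parameter structure
#'
#' Maps each (covariate, active treatment) pair to a free interaction
#' coefficient. Class-shared covariates use one coefficient per treatment
#' class; independent covariates use one per active treatment; the reference
#' treatment has no interactions.
#'
#' @param network An `mlnmr_network`.
#' @param spec An [model_spec()].
#' @return List with `map` (covariate-by-treatment integer matrix of indices
#'   into the free coefficient vector, 0 for structural zeros), `n_free`, and
#'   `labels` for the free coefficients.
#' @export
resolve_interactions <- function(network, spec) {
  spec <- resolve_spec(network, spec)
  covs <- spec$covariates
  trts <- network$treatments$id
  cls <- stats::setNames(network$treatments$class, trts)
  K <- length(trts)
  map <- matrix(0L, length(covs), K, dimnames = list(covs, trts))
  labels <- character(0)
  for (cv in covs) {
    st <- spec$interaction_map[cv]
    if (st == "none") next
    for (k in trts) {
      if (k == network$reference) next
      key <- if (st == "class") paste0(cls[k], ":", cv) else paste0(k, ":", cv)
      idx <- match(key, labels)
      if (is.na(idx)) {
        labels <- c(labels, key)
        idx <- length(labels)
      }
      map[cv, k] <- idx
    }
  }
  list(map = map, n_free = length(labels), labels = labels)
}

arm1_treatment <- function(network, study) {
  s <- network$ipd[[study]] %||% network$agd[[study]]
  if (is.null(s)) stop_mlnmr("unknown study ", sQuote(study))
  if (network$reference %in% s$treatments) network$reference else s$treatments[1]
}

# Build the flattened likelihood design: one unit per study-arm, with
# transformed covariate matrices ready for the C++ core.
build_design <- function(network, spec) {
  spec <- resolve_spec(network, spec)
  covs <- spec$covariates
  p <- length(covs)
  trts <- network$treatments$id
  K <- length(trts)
  studies <- c(names(network$ipd), names(network$agd))
  J <- length(studies)
  transf <- function(M) {
    if (!p) return(matrix(0, nrow = max(nrow(M), 1L), ncol = 0))
    M <- M[, covs, drop = FALSE]
    sweep(sweep(M, 2, spec$centers[covs]), 2, spec$scales[covs], "/")
  }
  units <- list()
  unit_study <- integer(0); unit_trt <- integer(0); unit_arm1 <- logical(0)
  arm1 <- stats::setNames(integer(J), studies)
  for (s in names(network$ipd)) {
    st <- network$ipd[[s]]
    j <- match(s, studies)
    a1 <- arm1_treatment(network, s)
    arm1[s] <- match(a1, trts)
    for (tr in st$treatments) {
      rows <- st$data$trt == tr
      units[[length(units) + 1L]] <- list(
        type = 1L, study = j, trt = match(tr, trts),
        X = transf(as.matrix(st$data[rows, st$covariates, drop = FALSE])),
        y = as.integer(st$data$y[rows]))
      unit_study <- c(unit_study, j)
      unit_trt <- c(unit_trt, match(tr, trts))
      unit_arm1 <- c(unit_arm1, tr == a1)
    }
  }
  C <- network$outcome$n_categories
  for (s in names(network$agd)) {
    st <- network$agd[[s]]
    j <- match(s, studies)
    a1 <- arm1_treatment(network, s)
    arm1[s] <- match(a1, trts)
    G <- if (p) {
      if (is.null(network$grids[[s]]))
        stop_mlnmr("no integration grid for AgD study ", sQuote(s),
                   "; call add_integration() first")
      transf(network$grids[[s]]$points)
    } else matrix(0, 1, 0)
    for (a in seq_len(nrow(st$arms))) {
      tr <- st$arms$trt[a]
      units[[length(units) + 1L]] <- list(
        type = 2L, study = j, trt = match(tr, trts),
        X = G,
        counts = as.numeric(st$arms[a, paste0("cat", seq_len(C))]),
        N = st$arms$n[a])
      unit_study <- c(unit_study, j)
      unit_trt <- c(unit_trt, match(tr, trts))
      unit_arm1 <- c(unit_arm1, tr == a1)
    }
  }
  ia <- resolve_interactions(network, spec)
  # UME contrast table: one free parameter per observed (arm-1 trt, trt) pair
  pair_key <- ifelse(unit_arm1, NA,
                     paste0(trts[arm1[unit_study]], ":", trts[unit_trt]))
  pairs <- unique(stats::na.omit(pair_key))
  unit_pair <- match(pair_key, pairs)
  # point bookkeeping for residual deviance (IPD: individuals, AgD: arms)
  unit_npoints <- vapply(units, function(u)
    if (u$type == 1L) length(u$y) else 1L, 0L)
  list(network = network, spec = spec,
       studies = studies, trts = trts, covs = covs,
       J = J, K = K, p = p, C = C,
       link = if (spec$link == "probit") 0L else 1L,
       units = units, n_units = length(units),
       unit_study = unit_study, unit_trt = unit_trt, unit_arm1 = unit_arm1,
       unit_pair = unit_pair, pairs = pairs,
       arm1 = arm1, ia = ia,
       unit_npoints = unit_npoints,
       ipd_units = which(vapply(units, function(u) u$type == 1L, TRUE)),
       agd_units = which(vapply(units, function(u) u$type == 2L, TRUE)))
}

# expand a natural parameter list to the flat (mu, cuts, beta1, B2, eff)
# representation the C++ core consumes
params_to_state <- function(design, params) {
  J <- design$J; K <- design$K; p <- design$p; C <- design$C
  mu <- params$mu
  if (!is.null(names(mu))) mu <- mu[design$studies]
  if (length(mu) != J) stop_mlnmr("mu must have one entry per study")
  cuts <- params$cutpoints
  if (length(cuts) != C - 1) stop_mlnmr("cutpoints must have length C - 1")
  if (is.unsorted(cuts)) stop_mlnmr("cutpoints must be non-decreasing")
  beta1 <- params$beta1 %||% stats::setNames(rep(0, p), design$covs)
  if (!is.null(names(beta1)) && p) beta1 <- beta1[design$covs]
  B2 <- matrix(0, p, K, dimnames = list(design$covs, design$trts))
  if (!is.null(params$beta2)) {
    b2 <- params$beta2
    if (is.matrix(b2)) {
      B2[rownames(b2) %||% seq_len(nrow(b2)),
         colnames(b2) %||% seq_len(ncol(b2))] <- b2
    } else {
      # free coefficient vector in resolve_interactions() order
      full <- c(0, as.numeric(b2))
      B2 <- matrix(full[design$ia$map + 1L], p, K,
                   dimnames = list(design$covs, design$trts))
    }
  }
  eff <- numeric(design$n_units)
  if (design$spec$effects == "random" && !is.null(params$delta)) {
    for (u in seq_len(design$n_units)) {
      if (design$unit_arm1[u]) next
      s <- design$studies[design$unit_study[u]]
      tr <- design$trts[design$unit_trt[u]]
      eff[u] <- params$delta[[s]][[tr]]
    }
  } else if (design$spec$contrasts == "ume") {
    d <- params$d
    for (u in seq_len(design$n_units)) {
      if (design$unit_arm1[u]) next
      eff[u] <- if (is.matrix(d))
        d[design$trts[design$arm1[design$unit_study[u]]],
          design$trts[design$unit_trt[u]]]
      else d[[design$pairs[design$unit_pair[u]]]]
    }
  } else {
    gam <- stats::setNames(rep(0, K), design$trts)
    if (!is.null(params$gamma)) gam[names(params$gamma)] <- params$gamma
    gam[design$network$reference] <- 0
    eff <- gam[design$unit_trt]
  }
  list(mu = as.numeric(mu), cuts = as.numeric(cuts),
       beta1 = as.numeric(beta1), B2 = B2, eff = as.numeric(eff))
}

#' Ordered category probabilities from a linear predictor
#'
#' Given linear predictor values `eta` and non-decreasing cutpoints
#' `a_1..a_{C-1}` (identification fixes `a_1 = 0`), the inclusive probability
#' of exceeding threshold `c` is `F(eta - a_c)` with `F` the probit (or
#' logit) link's inverse; category probabilities follow by successive
#' differencing and always sum to one.
#'
#' @param eta Numeric vector of linear predictor values.
#' @param cutpoints Non-decreasing numeric vector of length `C - 1`.
#' @param link `"probit"` or `"logit"`.
#' @return List with `category` (length(eta) by C matrix) and `inclusive`
#'   (length(eta) by C-1 matrix) probabilities.
#' @examples
#' ordered_probs(0, c(0, 1, 2))
#' @export
ordered_probs <- function(eta, cutpoints, link = c("probit", "logit")) {
  link <- match.arg(link)
  if (is.unsorted(cutpoints)) stop_mlnmr("cutpoints must be non-decreasing")
  F <- if (link == "probit") stats::pnorm else stats::plogis
  q <- vapply(cutpoints, function(a) F(eta - a), numeric(length(eta)))
  q <- matrix(q, nrow = length(eta))
  cat <- cbind(1 - q[, 1], if (ncol(q) > 1)
    q[, -ncol(q), drop = FALSE] - q[, -1, drop = FALSE], q[, ncol(q)])
  colnames(cat) <- NULL
  list(category = cat, inclusive = q)
}

#' Individual-level linear predictor
#'
#' Computes `eta = mu_j + x'(beta1 + beta2_k) + gamma_k` (consistency) or
#' `eta = mu_j + x'(beta1 + beta2_k) + d_(t_j1,k)` (UME), where `x` is the
#' covariate vector already centered and scaled per the model specification,
#' and the interaction and effect terms vanish at the reference treatment.
#'
#' @param x Named numeric covariate vector on the centered/scaled model scale
#'   (use `numeric(0)` or zeros for a reference individual).
#' @param study Study id (for the intercept `mu_j`).
#' @param treatment Treatment id.
#' @param params Parameter list: `mu` (named per study), `beta1`, `beta2`
#'   (covariate-by-treatment matrix), `gamma` (named, reference 0) or `d`
#'   (arm-1-treatment by treatment matrix for UME), `cutpoints`.
#' @param network An `mlnmr_network`.
#' @param spec An [model_spec()] (for the contrast structure).
#' @return Scalar linear predictor on the link scale.
#' @export
linear_predictor <- function(x, study, treatment, params, network,
                             spec = model_spec()) {
  if (!treatment %in% network$treatments$id)
    stop_mlnmr("unknown treatment ", sQuote(treatment))
  if (!study %in% c(names(network$ipd), names(network$agd)))
    stop_mlnmr("unknown study ", sQuote(study))
  b1 <- params$beta1 %||% numeric(0)
  b2k <- if (!is.null(params$beta2) && length(x))
    params$beta2[names(x), treatment] else rep(0, length(x))
  xb <- if (length(x)) sum(x * (b1[names(x)] + b2k)) else 0
  if (spec$contrasts == "ume") {
    a1 <- arm1_treatment(network, study)
    effk <- if (treatment == a1) 0 else params$d[a1, treatment]
  } else {
    effk <- if (treatment == network$reference) 0 else params$gamma[[treatment]]
  }
  unname(params$mu[[study]] + xb + effk)
}

#' Population-average category probabilities for an AgD study arm
#'
#' Averages the individual-level ordered category probabilities over the
#' study's integration grid (equal weights), giving the aggregate-level
#' multinomial probabilities. With no covariates in the model the average
#' reduces to the probabilities at `eta = mu_j + gamma_k`.
#'
#' @inheritParams linear_predictor
#' @return List with `category` (length C) and `inclusive` (length C-1)
#'   average probabilities.
#' @export
aggregate_probs <- function(network, study, treatment, params,
                            spec = model_spec()) {
  design <- build_design(network, spec)
  if (!study %in% design$studies) stop_mlnmr("unknown study ", sQuote(study))
  if (!treatment %in% design$trts)
    stop_mlnmr("unknown treatment ", sQuote(treatment))
  st <- params_to_state(design, params)
  j <- match(study, design$studies)
  k <- match(treatment, design$trts)
  G <- if (design$p) {
    if (study %in% names(network$agd)) {
      if (is.null(network$grids[[study]]))
        stop_mlnmr("no integration grid for study ", sQuote(study))
      gp <- network$grids[[study]]$points
    } else {
      gp <- as.matrix(network$ipd[[study]]$data[, design$covs, drop = FALSE])
    }
    sweep(sweep(gp[, design$covs, drop = FALSE], 2, design$spec$centers),
          2, design$spec$scales, "/")
  } else matrix(0, 1, 0)
  effk <- if (design$spec$contrasts == "ume") {
    a1 <- design$trts[design$arm1[j]]
    if (treatment == a1) 0 else params$d[a1, treatment]
  } else if (treatment == network$reference) 0 else params$gamma[[treatment]]
  eta <- st$mu[j] + as.numeric(G %*% (st$beta1 + st$B2[, k])) + effk
  op <- ordered_probs(eta, st$cuts, design$spec$link)
  list(category = colMeans(op$category),
       inclusive = colMeans(op$inclusive))
}

#' Log-likelihood of the IPD studies
#'
#' Sum over IPD individuals of the log probability of the observed ordered
#' category under the individual-level model.
#'
#' @inheritParams aggregate_probs
#' @return Scalar log-likelihood.
#' @export
loglik_ipd <- function(network, params, spec = model_spec()) {
  design <- build_design(network, spec)
  if (!length(design$ipd_units)) return(0)
  st <- params_to_state(design, params)
  sum(cpp_unit_loglik(design$units, st$mu, st$cuts, st$beta1, st$B2, st$eff,
                      design$ipd_units, design$link))
}

#' Log-likelihood of the AgD studies (multinomial kernel)
#'
#' Sum over AgD arms of `sum_c y_c log pbar_c`, the ordered multinomial
#' log-likelihood kernel with the grid-averaged category probabilities. The
#' multinomial constant terms do not involve the parameters and are dropped
#' consistently here and in the deviance computations.
#'
#' @inheritParams aggregate_probs
#' @return Scalar log-likelihood kernel.
#' @export
loglik_agd <- function(network, params, spec = model_spec()) {
  design <- build_design(network, spec)
  if (!length(design$agd_units)) return(0)
  st <- params_to_state(design, params)
  sum(cpp_unit_loglik(design$units, st$mu, st$cuts, st$beta1, st$B2, st$eff,
                      design$agd_units, design$link))
}

#' Random-effects prior density for a study's treatment effects
#'
#' Under the random-effects model the study-specific effects of the non-arm-1
#' arms are multivariate normal around the consistency effects, with common
#' heterogeneity variance `tau^2` on the diagonal and `0.5 * tau^2`
#' off-diagonal (the standard multi-arm compound-symmetry structure). Two-arm
#' studies reduce to a univariate normal.
#'
#' @param delta Numeric vector of study-specific effects (non-arm-1 arms).
#' @param mean Numeric vector of consistency means (same length).
#' @param tau Heterogeneity standard deviation, `tau >= 0`.
#' @return Log density.
#' @export
re_prior <- function(delta, mean, tau) {
  if (tau < 0) stop_mlnmr("tau must be non-negative")
  m <- length(delta)
  if (length(mean) != m) stop_mlnmr("delta and mean lengths differ")
  if (tau == 0)
    return(if (all(abs(delta - mean) < 1e-12)) Inf else -Inf)
  x <- delta - mean
  # Sigma = tau^2 (0.5 I + 0.5 J); Sigma^{-1} = (2 I - 2/(m+1) J) / tau^2
  quad <- (2 * sum(x^2) - 2 / (m + 1) * sum(x)^2) / tau^2
  logdet <- 2 * m * log(tau) + m * log(0.5) + log(m + 1)
  -0.5 * (m * log(2 * pi) + logdet + quad)
}
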