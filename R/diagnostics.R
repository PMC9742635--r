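# Per-point fitted probabilities and residual deviance, averaged over
# posterior draws. One data point per IPD individual and one per AgD arm;
# multinomial constants are dropped consistently (deviance is measured
# against the saturated model, so saturated arms contribute exactly 0).

point_metadata <- function(design) {
  rows <- list()
  for (u in seq_len(design$n_units)) {
    un <- design$units[[u]]
    if (un$type == 1L) {
      rows[[u]] <- data.frame(
        unit = u, type = "ipd",
        study = design$studies[design$unit_study[u]],
        trt = design$trts[design$unit_trt[u]],
        y = un$y, stringsAsFactors = FALSE)
    } else {
      rows[[u]] <- data.frame(
        unit = u, type = "agd",
        study = design$studies[design$unit_study[u]],
        trt = design$trts[design$unit_trt[u]],
        y = NA_integer_, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

# deviance contributions for one draw's pointwise probability matrix
point_deviance <- function(P, meta, design) {
  dev <- numeric(nrow(P))
  ipd <- meta$type == "ipd"
  if (any(ipd))
    dev[ipd] <- -2 * log(pmax(P[cbind(which(ipd), meta$y[ipd])], 1e-300))
  for (i in which(!ipd)) {
    un <- design$units[[meta$unit[i]]]
    y <- un$counts
    pos <- y > 0
    dev[i] <- 2 * sum(y[pos] * (log(y[pos]) - log(un$N * pmax(P[i, pos], 1e-300))))
  }
  dev
}

pointwise_fit_stats <- function(fit, ndraws = 1000) {
  design <- fit$design
  meta <- point_metadata(design)
  d <- pooled_draws(fit)
  keep <- unique(round(seq(1, nrow(d), length.out = min(ndraws, nrow(d)))))
  dev_sum <- 0
  prob_sum <- 0
  for (i in keep) {
    st <- draw_state(design, d[i, ])
    P <- cpp_pointwise_probs(design$units, st$mu, st$cuts, st$beta1, st$B2,
                             st$eff, design$link)
    dev_sum <- dev_sum + point_deviance(P, meta, design)
    prob_sum <- prob_sum + P
  }
  nd <- length(keep)
  pbar <- prob_sum / nd
  list(meta = meta,
       dev_mean = dev_sum / nd,
       dev_plugin = point_deviance(pbar, meta, design),
       pbar = pbar, ndraws = nd)
}

#' Residual deviance
#'
#' Posterior-mean residual deviance contributions versus the saturated model,
#' per data point (one per IPD individual, one per AgD arm) and in total.
#'
#' @param fit An `mlnmr_fit`.
#' @param ndraws Maximum posterior draws used (evenly thinned).
#' @return List with `pointwise` (data frame: study, trt, type, dev) and
#'   `total`, `n_points`.
#' @export
residual_deviance <- function(fit, ndraws = 1000) {
  pw <- pointwise_fit_stats(fit, ndraws)
  out <- pw$meta[, c("study", "trt", "type")]
  out$dev <- pw$dev_mean
  list(pointwise = out, total = sum(pw$dev_mean), n_points = nrow(out))
}

#' @export
residuals.mlnmr_fit <- function(object, ndraws = 1000, ...) {
  residual_deviance(object, ndraws)$pointwise$dev
}

#' Model fit statistics: residual deviance, pD and DIC
#'
#' The effective number of parameters is `pD = Dbar - D(pbar)`: the
#' posterior-mean residual deviance minus the plug-in residual deviance at
#' the posterior-mean fitted category probabilities. `DIC = Dbar + pD`.
#'
#' @inheritParams residual_deviance
#' @return An `mlnmr_fitstats` object: `resdev`, `pD`, `DIC`, `n_points`, and
#'   the `tau` posterior summary for random-effects fits.
#' @export
dic <- function(fit, ndraws = 1000) {
  pw <- pointwise_fit_stats(fit, ndraws)
  Dbar <- sum(pw$dev_mean)
  Dplug <- sum(pw$dev_plugin)
  pD <- Dbar - Dplug
  tau <- NULL
  if ("tau" %in% fit$parnames) {
    td <- pooled_draws(fit, "tau")
    tau <- c(median = stats::median(td),
             `2.5%` = unname(stats::quantile(td, 0.025)),
             `97.5%` = unname(stats::quantile(td, 0.975)))
  }
  structure(list(resdev = Dbar, pD = pD, DIC = Dbar + pD,
                 n_points = nrow(pw$meta), tau = tau),
            class = "mlnmr_fitstats")
}

#' @export
print.mlnmr_fitstats <- function(x, ...) {
  cat(sprintf("Residual deviance %.1f on %d data points; pD %.1f; DIC %.1f\n",
              x$resdev, x$n_points, x$pD, x$DIC))
  if (!is.null(x$tau))
    cat(sprintf("tau %.3f (%.3f, %.3f)\n", x$tau["median"], x$tau["2.5%"],
                x$tau["97.5%"]))
  invisible(x)
}

fitstats_row <- function(fs) {
  data.frame(resdev = fs$resdev, pD = fs$pD, DIC = fs$DIC,
             tau = if (is.null(fs$tau)) NA else fs$tau[["median"]],
             tau_lo = if (is.null(fs$tau)) NA else fs$tau[["2.5%"]],
             tau_hi = if (is.null(fs$tau)) NA else fs$tau[["97.5%"]])
}

#' Residual heterogeneity check: fixed versus random effects
#'
#' Fits the model under fixed- and random-effects treatment contrasts and
#' compares residual deviance, pD and DIC, alongside the posterior of the
#' heterogeneity standard deviation `tau`. Similar DIC with a `tau`
#' posterior concentrated near zero indicates no residual heterogeneity and
#' favours the more parsimonious fixed-effect model.
#'
#' @param network An `mlnmr_network` (grids attached).
#' @param spec Base [model_spec()] (its `effects` field is overridden).
#' @param priors A [prior_spec()].
#' @param ... Passed to [mlnmr()] (chains, iterations, seed, ...).
#' @return An `mlnmr_modcomp`: comparison table plus both fits.
#' @export
heterogeneity_check <- function(network, spec = model_spec(),
                                priors = prior_spec(), ...) {
  spec_fe <- spec; spec_fe$effects <- "fixed"
  spec_re <- spec; spec_re$effects <- "random"
  fe <- mlnmr(network, spec_fe, priors, ...)
  re <- mlnmr(network, spec_re, priors, ...)
  tab <- rbind(FE = fitstats_row(dic(fe)), RE = fitstats_row(dic(re)))
  structure(list(table = tab, fits = list(FE = fe, RE = re)),
            class = "mlnmr_modcomp")
}

#' Residual inconsistency check: consistency versus unrelated mean effects
#'
#' Fits the consistency model and the UME inconsistency model and compares
#' overall fit (DIC) together with per-point residual deviance contributions
#' under either model (a dev-dev table for plotting): points fitting clearly
#' better under UME indicate loops with inconsistent evidence.
#'
#' @inheritParams heterogeneity_check
#' @return An `mlnmr_modcomp` with a `devdev` data frame (one row per data
#'   point: consistency vs UME contribution).
#' @export
consistency_check <- function(network, spec = model_spec(),
                              priors = prior_spec(), ...) {
  spec_con <- spec; spec_con$contrasts <- "consistency"
  spec_ume <- spec; spec_ume$contrasts <- "ume"
  con <- mlnmr(network, spec_con, priors, ...)
  ume <- mlnmr(network, spec_ume, priors, ...)
  rd_con <- residual_deviance(con)
  rd_ume <- residual_deviance(ume)
  devdev <- rd_con$pointwise
  names(devdev)[names(devdev) == "dev"] <- "dev_consistency"
  devdev$dev_ume <- rd_ume$pointwise$dev
  tab <- rbind(consistency = fitstats_row(dic(con)),
               UME = fitstats_row(dic(ume)))
  structure(list(table = tab, devdev = devdev,
                 fits = list(consistency = con, UME = ume)),
            class = "mlnmr_modcomp")
}

#' @export
print.mlnmr_modcomp <- function(x, ...) {
  cat("Model comparison:\n")
  print(round(x$table, 2))
  invisible(x)
}

#' @export
plot.mlnmr_modcomp <- function(x, ...) {
  if (is.null(x$devdev)) stop_mlnmr("no dev-dev table to plot")
  lim <- range(0, x$devdev$dev_consistency, x$devdev$dev_ume)
  graphics::plot(x$devdev$dev_consistency, x$devdev$dev_ume, xlim = lim,
                 ylim = lim, xlab = "Residual deviance (consistency)",
                 ylab = "Residual deviance (UME)",
                 col = ifelse(x$devdev$type == "agd", 2, 1), ...)
  graphics::abline(0, 1, lty = 2)
  invisible(x)
}

#' Shared effect modifier check: split class interactions per covariate
#'
#' For each named covariate, refits the model with that covariate's
#' interactions independent per active treatment (the remaining covariates
#' keep their class-shared coefficients) and compares the split posterior
#' estimates with the shared estimate, plus the DIC difference. Split
#' estimates overlapping the shared estimate support the shared effect
#' modifier assumption.
#'
#' @param network An `mlnmr_network`.
#' @param covariates Covariate names to split, one at a time.
#' @inheritParams heterogeneity_check
#' @return An `mlnmr_emcheck`: per-covariate comparison tables and fits.
#' @export
shared_em_check <- function(network, covariates, spec = model_spec(),
                            priors = prior_spec(), ...) {
  base <- mlnmr(network, spec, priors, ...)
  base_dic <- dic(base)
  base_sum <- summary(base)
  out <- list()
  for (cv in covariates) {
    ia <- stats::setNames("independent", cv)
    spec_cv <- spec
    spec_cv$interactions <- if (is.character(spec$interactions) &&
                                length(spec$interactions) == 1L &&
                                spec$interactions == "class") ia
      else c(spec$interactions[setdiff(names(spec$interactions), cv)], ia)
    fit_cv <- mlnmr(network, spec_cv, priors, ...)
    split_pars <- grep(paste0("^beta2\\[.*:", cv, "\\]$"),
                       fit_cv$parnames, value = TRUE)
    shared_pars <- grep(paste0("^beta2\\[.*:", cv, "\\]$"),
                        base$parnames, value = TRUE)
    out[[cv]] <- list(
      split = summary(fit_cv, pars = split_pars),
      shared = base_sum[shared_pars, , drop = FALSE],
      dic_split = dic(fit_cv),
      dic_delta = dic(fit_cv)$DIC - base_dic$DIC,
      fit = fit_cv)
  }
  structure(list(base = base, base_dic = base_dic, covariates = out),
            class = "mlnmr_emcheck")
}

#' @export
print.mlnmr_emcheck <- function(x, ...) {
  cat("Shared effect modifier check (base DIC",
      sprintf("%.1f)\n", x$base_dic$DIC))
  for (cv in names(x$covariates)) {
    o <- x$covariates[[cv]]
    cat("\n--", cv, sprintf("(split DIC %.1f, delta %+0.1f)\n",
                            o$dic_split$DIC, o$dic_delta))
    cat("  shared:\n"); print(round(o$shared[, 1:4], 3))
    cat("  split:\n"); print(round(o$split[, 1:4], 3))
  }
  invisible(x)
}

#' Posterior predictive category counts for AgD arms
#'
#' Draws multinomial category counts for every AgD arm from the fitted
#' aggregate-level probabilities, one set per posterior draw.
#'
#' @param object An `mlnmr_fit`.
#' @param nsim Number of posterior predictive replicates.
#' @param seed Optional seed.
#' @param ... Unused.
#' @return List of `nsim` data frames (study, trt, cat1..catC).
#' @export
simulate.mlnmr_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  design <- object$design
  if (!length(design$agd_units)) stop_mlnmr("no AgD arms in the network")
  d <- pooled_draws(object)
  rows <- sample.int(nrow(d), nsim, replace = nsim > nrow(d))
  meta <- point_metadata(design)
  agd_rows <- which(meta$type == "agd")
  lapply(rows, function(i) {
    st <- draw_state(design, d[i, ])
    P <- cpp_pointwise_probs(design$units, st$mu, st$cuts, st$beta1, st$B2,
                             st$eff, design$link)
    cnt <- t(vapply(agd_rows, function(r) {
      un <- design$units[[meta$unit[r]]]
      as.numeric(stats::rmultinom(1, un$N, P[r, ]))
    }, numeric(design$C)))
    colnames(cnt) <- paste0("cat", seq_len(design$C))
    data.frame(study = meta$study[agd_rows], trt = meta$trt[agd_rows], cnt,
               stringsAsFactors = FALSE)
  })
}
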