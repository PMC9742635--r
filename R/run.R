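#' Run a full ML-NMR workflow from a configuration
#'
#' Drives the complete analysis sequence from a structured-text (YAML)
#' configuration: assemble the network from the referenced tables (or
#' simulate the packaged psoriasis-like network), attach integration grids,
#' fit the model, optionally run the heterogeneity / consistency /
#' shared-effect-modifier checks, and produce population-average estimates.
#' All outputs are delimited text; every seed and the package version are
#' logged, and the config is copied into the run directory so a run is
#' self-describing.
#'
#' @param config Path to a YAML file or an equivalent named list. Main keys:
#'   `data` (`ipd`/`agd` table paths, or `simulate: psoriasis` with
#'   `seed`), `outcome` (labels), `classes`, `reference`, `covariates`,
#'   `families`, `bounds`, `model` (`effects`, `contrasts`, `interactions`,
#'   `link`), `integration` (`n_points`, `seed`), `mcmc` (`chains`,
#'   `iter_warmup`, `iter_sampling`, `seed`), `compare` (`heterogeneity` /
#'   `consistency` flags), `split_em` (covariates), `predict` (`studies`,
#'   `populations`).
#' @param command One of `"all"`, `"simulate"`, `"fit"`, `"compare"`,
#'   `"split-em"`, `"predict"`.
#' @param outdir Output directory (default from config `outdir`, else
#'   `"mlnmr-run"`).
#' @param on_nonconvergence Passed to [mlnmr()].
#' @return Invisibly, a list with the network, fit and any comparison /
#'   prediction objects produced.
#' @export
run_mlnmr <- function(config, command = c("all", "simulate", "fit", "compare",
                                          "split-em", "predict"),
                      outdir = NULL, on_nonconvergence = "error") {
  command <- match.arg(command)
  cfg <- if (is.character(config)) yaml::read_yaml(config) else config
  outdir <- outdir %||% cfg$outdir %||% "mlnmr-run"
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  yaml::write_yaml(cfg, file.path(outdir, "config-used.yaml"))
  logf <- file.path(outdir, "run.log")
  logit <- function(...) cat(format(Sys.time(), "%H:%M:%S"), ...,
                             "\n", file = logf, append = TRUE)
  logit("mlnmr", as.character(utils::packageVersion("mlnmr")),
        "| command:", command)

  # ---- assemble or simulate the network ----------------------------------
  if (!is.null(cfg$data$simulate)) {
    sim_seed <- cfg$data$seed %||% 1
    logit("simulating psoriasis-like network, seed", sim_seed)
    sim <- psoriasis_like_network(seed = sim_seed)
    network <- sim$network
    write_network(network, file.path(outdir, "data"))
    if (command == "simulate")
      return(invisible(list(network = network, truth = sim$truth)))
  } else {
    outc <- outcome_spec(unlist(cfg$outcome))
    covs <- unlist(cfg$covariates) %||% character(0)
    ipd <- if (!is.null(cfg$data$ipd)) load_ipd(cfg$data$ipd, covs, outc)
           else list()
    agd <- if (!is.null(cfg$data$agd)) load_agd(cfg$data$agd, covs, outc)
           else list()
    network <- assemble_network(ipd, agd, unlist(cfg$classes), outc,
                                cfg$reference)
  }
  logit("network:", nrow(network$treatments), "treatments,",
        length(network$ipd), "IPD +", length(network$agd), "AgD studies")

  ig <- cfg$integration %||% list()
  network <- add_integration(network,
                             n_points = ig$n_points %||% 1000,
                             seed = ig$seed %||% 1,
                             families = unlist(cfg$families),
                             bounds = cfg$bounds %||% list())
  logit("integration grids:", ig$n_points %||% 1000, "points, seed",
        ig$seed %||% 1)

  mdl <- cfg$model %||% list()
  spec <- model_spec(effects = mdl$effects %||% "fixed",
                     contrasts = mdl$contrasts %||% "consistency",
                     interactions = if (is.list(mdl$interactions))
                       unlist(mdl$interactions) else mdl$interactions %||% "class",
                     covariates = unlist(mdl$covariates),
                     link = mdl$link %||% "probit")
  mc <- cfg$mcmc %||% list()
  margs <- list(chains = mc$chains %||% 4,
                iter_warmup = mc$iter_warmup %||% 1000,
                iter_sampling = mc$iter_sampling %||% 1000,
                seed = mc$seed %||% 1)
  out <- list(network = network)

  fit_one <- function(sp) do.call(mlnmr, c(list(network, sp, prior_spec(),
    on_nonconvergence = on_nonconvergence), margs))

  if (command %in% c("all", "fit", "predict")) {
    logit("fitting:", spec$effects, spec$contrasts, "| mcmc seed", margs$seed)
    fit <- fit_one(spec)
    out$fit <- fit
    s <- summary(fit)
    utils::write.table(cbind(parameter = rownames(s), round(s, 6)),
                       file.path(outdir, "posterior_summary.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    fs <- dic(fit)
    utils::write.table(round(fitstats_row(fs), 4),
                       file.path(outdir, "fit_stats.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    dr <- pooled_draws(fit)
    utils::write.csv(
      data.frame(chain = rep(seq_len(fit$chains), each = fit$iter_sampling),
                 iteration = rep(seq_len(fit$iter_sampling), fit$chains),
                 dr, check.names = FALSE),
      file.path(outdir, "draws.csv"), row.names = FALSE)
    logit(sprintf("fit done: max R-hat %.4f, DIC %.1f", max(fit$rhat), fs$DIC))
  }

  if (command %in% c("all", "compare") && !is.null(cfg$compare)) {
    comp <- list()
    if (isTRUE(cfg$compare$heterogeneity)) {
      logit("comparing FE vs RE")
      comp$heterogeneity <- do.call(heterogeneity_check,
        c(list(network, spec, prior_spec(),
               on_nonconvergence = on_nonconvergence), margs))
    }
    if (isTRUE(cfg$compare$consistency)) {
      logit("comparing consistency vs UME")
      comp$consistency <- do.call(consistency_check,
        c(list(network, spec, prior_spec(),
               on_nonconvergence = on_nonconvergence), margs))
      utils::write.table(comp$consistency$devdev,
                         file.path(outdir, "devdev.tsv"), sep = "\t",
                         row.names = FALSE, quote = FALSE)
    }
    if (length(comp)) {
      tab <- do.call(rbind, lapply(names(comp), function(nm) {
        t <- comp[[nm]]$table
        cbind(check = nm, model = rownames(t), round(t, 3))
      }))
      utils::write.table(tab, file.path(outdir, "model_comparison.tsv"),
                         sep = "\t", row.names = FALSE, quote = FALSE)
    }
    out$compare <- comp
  }

  if (command %in% c("all", "split-em") && length(cfg$split_em)) {
    logit("shared effect modifier check:", paste(unlist(cfg$split_em),
                                                 collapse = ", "))
    out$split_em <- do.call(shared_em_check,
      c(list(network, unlist(cfg$split_em), spec, prior_spec(),
             on_nonconvergence = on_nonconvergence), margs))
    for (cv in names(out$split_em$covariates)) {
      o <- out$split_em$covariates[[cv]]
      tab <- rbind(cbind(kind = "shared", parameter = rownames(o$shared),
                         round(o$shared[, 1:5], 4)),
                   cbind(kind = "split", parameter = rownames(o$split),
                         round(o$split[, 1:5], 4)))
      utils::write.table(tab,
                         file.path(outdir, paste0("split_em_", cv, ".tsv")),
                         sep = "\t", row.names = FALSE, quote = FALSE)
    }
  }

  if (command %in% c("all", "predict") && !is.null(cfg$predict)) {
    est <- list()
    for (s in unlist(cfg$predict$studies)) {
      est[[paste0("effects_", s)]] <- conditional_average_effects(out$fit, study = s)
      est[[paste0("probs_", s)]] <- average_event_probs(out$fit, s)
    }
    for (pp in cfg$predict$populations) {
      bl <- if (!is.null(pp$baseline))
        baseline_ref(pp$baseline$treatment, pp$baseline$responders,
                     pp$baseline$nonresponders, pp$baseline$threshold %||% 1)
      pop <- target_population(pp$name, unlist(pp$means), unlist(pp$sds),
                               unlist(pp$props), baseline = bl)
      est[[paste0("effects_", pp$name)]] <-
        conditional_average_effects(out$fit, population = pop)
      if (!is.null(bl))
        est[[paste0("probs_", pp$name)]] <-
          average_event_probs_external(out$fit, pop)
    }
    for (nm in names(est)) {
      df <- est[[nm]]; class(df) <- "data.frame"
      num <- vapply(df, is.numeric, TRUE)
      df[num] <- lapply(df[num], round, 6)
      utils::write.table(df, file.path(outdir, paste0(nm, ".tsv")),
                         sep = "\t", row.names = FALSE, quote = FALSE)
    }
    out$estimates <- est
    logit("predictions written:", length(est), "tables")
  }
  logit("done")
  invisible(out)
}
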