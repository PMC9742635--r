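#' Define an ordered categorical outcome
#'
#' Ordered outcomes are coded worst-to-best, e.g. the four PASI response
#' categories `<PASI75`, `PASI75-90`, `PASI90-100`, `PASI100`. Categories are
#' stored as integers `1..C`; the `C - 1` inclusive thresholds (e.g. "achieved
#' PASI 75 or better") sit between successive categories.
#'
#' @param labels Character vector of unique category labels, ordered from the
#'   worst to the best outcome. At least two.
#' @return An object of class `mlnmr_outcome` with elements `labels`,
#'   `n_categories` and `n_thresholds`.
#' @examples
#' outcome_spec(c("<PASI75", "PASI75-90", "PASI90-100", "PASI100"))
#' @export
outcome_spec <- function(labels) {
  labels <- as.character(labels)
  if (length(labels) < 2L)
    stop_mlnmr("an ordered outcome needs at least 2 categories")
  if (anyDuplicated(labels))
    stop_mlnmr("outcome category labels must be unique")
  structure(
    list(labels = labels,
         n_categories = length(labels),
         n_thresholds = length(labels) - 1L),
    class = "mlnmr_outcome")
}

#' @export
print.mlnmr_outcome <- function(x, ...) {
  cat("Ordered outcome with", x$n_categories, "categories (worst to best):\n ",
      paste(x$labels, collapse = " < "), "\n")
  invisible(x)
}

match_categories <- function(values, outcome) {
  if (is.numeric(values)) {
    idx <- as.integer(values)
    bad <- which(is.na(idx) | idx < 1L | idx > outcome$n_categories)
  } else {
    idx <- match(as.character(values), outcome$labels)
    bad <- which(is.na(idx))
  }
  if (length(bad))
    stop_mlnmr("unknown outcome category ", sQuote(values[bad[1]]),
               " at row ", bad[1])
  idx
}

#' Load individual patient data (IPD) studies
#'
#' Reads a long-format table with one row per patient: study id, treatment,
#' covariate columns, and an ordered outcome category (label or integer code).
#' Binary covariates are coerced to 0/1; rows with missing covariate or
#' outcome values are rejected (missingness handling is out of scope).
#'
#' @param x A data frame or path to a delimited text file (TSV or CSV) with a
#'   header.
#' @param covariates Character vector of covariate column names.
#' @param outcome An [outcome_spec()].
#' @param study,trt,category Column names for the study id, treatment id and
#'   outcome category.
#' @return A list of `mlnmr_ipd` objects, one per study, each with elements
#'   `study`, `treatments` and `data` (columns `trt`, the covariates, and the
#'   integer outcome `y`). Row order is preserved.
#' @export
load_ipd <- function(x, covariates, outcome,
                     study = "study", trt = "trt", category = "out_cat") {
  df <- if (is.character(x)) read_table_auto(x) else as.data.frame(x)
  need <- c(study, trt, category, covariates)
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop_mlnmr("IPD table is missing column(s): ", paste(miss, collapse = ", "))
  for (cv in covariates) {
    if (is.logical(df[[cv]])) df[[cv]] <- as.numeric(df[[cv]])
    bad <- which(is.na(df[[cv]]))
    if (length(bad))
      stop_mlnmr("missing value for covariate ", sQuote(cv), " at row ", bad[1])
    if (!is.numeric(df[[cv]]))
      stop_mlnmr("covariate ", sQuote(cv), " is not numeric")
  }
  y <- match_categories(df[[category]], outcome)
  studies <- unique(as.character(df[[study]]))
  out <- lapply(studies, function(s) {
    rows <- df[[study]] == s
    trts <- as.character(df[[trt]][rows])
    if (length(unique(trts)) < 2L)
      stop_mlnmr("IPD study ", sQuote(s), " has fewer than 2 distinct treatments")
    dat <- data.frame(trt = trts, df[rows, covariates, drop = FALSE],
                      y = y[rows], check.names = FALSE,
                      stringsAsFactors = FALSE)
    rownames(dat) <- NULL
    structure(list(study = s, treatments = unique(trts), data = dat,
                   covariates = covariates, n = nrow(dat)),
              class = "mlnmr_ipd")
  })
  names(out) <- studies
  out
}

#' Load aggregate data (AgD) studies
#'
#' Reads an arm-level table: one row per study arm with the arm sample size
#' `n`, per-category outcome counts `cat1..catC` (worst to best), and
#' covariate summaries named `<cov>_mean` + `<cov>_sd` (continuous) or
#' `<cov>_prop` (binary). Category counts must be non-negative and sum to `n`.
#'
#' @inheritParams load_ipd
#' @return A list of `mlnmr_agd` objects, one per study, each with elements
#'   `study`, `treatments`, `arms` (a data frame) and `covariate_types`.
#' @export
load_agd <- function(x, covariates, outcome, study = "study", trt = "trt") {
  df <- if (is.character(x)) read_table_auto(x) else as.data.frame(x)
  C <- outcome$n_categories
  catcols <- paste0("cat", seq_len(C))
  need <- c(study, trt, "n", catcols)
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop_mlnmr("AgD table is missing column(s): ", paste(miss, collapse = ", "))
  types <- character(0)
  for (cv in covariates) {
    if (all(c(paste0(cv, "_mean"), paste0(cv, "_sd")) %in% names(df))) {
      types[cv] <- "continuous"
    } else if (paste0(cv, "_prop") %in% names(df)) {
      types[cv] <- "binary"
    } else {
      stop_mlnmr("no summary columns (", cv, "_mean/", cv, "_sd or ", cv,
                 "_prop) for covariate ", sQuote(cv))
    }
  }
  counts <- as.matrix(df[, catcols, drop = FALSE])
  if (any(counts < 0))
    stop_mlnmr("negative outcome count at row ", which(rowSums(counts < 0) > 0)[1])
  badsum <- which(abs(rowSums(counts) - df$n) > 1e-8)
  if (length(badsum))
    stop_mlnmr("category counts do not sum to n at row ", badsum[1],
               " (study ", sQuote(as.character(df[[study]][badsum[1]])), ")")
  for (cv in names(types)[types == "continuous"]) {
    sdcol <- df[[paste0(cv, "_sd")]]
    if (any(is.na(sdcol)) || any(sdcol <= 0))
      stop_mlnmr("covariate ", sQuote(cv), " has sd <= 0 or missing sd")
    if (any(is.na(df[[paste0(cv, "_mean")]])))
      stop_mlnmr("covariate ", sQuote(cv), " has a missing mean")
  }
  for (cv in names(types)[types == "binary"]) {
    p <- df[[paste0(cv, "_prop")]]
    if (any(is.na(p)) || any(p < 0 | p > 1))
      stop_mlnmr("covariate ", sQuote(cv), " has proportions outside [0, 1]")
  }
  studies <- unique(as.character(df[[study]]))
  out <- lapply(studies, function(s) {
    rows <- df[[study]] == s
    arms <- df[rows, , drop = FALSE]
    arms[[study]] <- NULL
    names(arms)[names(arms) == trt] <- "trt"
    arms$trt <- as.character(arms$trt)
    rownames(arms) <- NULL
    structure(list(study = s, treatments = unique(arms$trt), arms = arms,
                   covariates = covariates, covariate_types = types,
                   n = sum(arms$n)),
              class = "mlnmr_agd")
  })
  names(out) <- studies
  out
}

#' Inclusive threshold counts from category counts
#'
#' Converts per-category counts (worst to best) into inclusive counts of
#' patients at or above each threshold, e.g. PASI counts `(40, 30, 20, 10)`
#' become `(60, 30, 10)` patients achieving at least PASI 75/90/100. Inclusive
#' counts are always non-increasing across thresholds.
#'
#' @param counts Non-negative per-category counts, worst to best.
#' @return Integer-valued vector of length `length(counts) - 1`.
#' @examples
#' inclusive_counts(c(40, 30, 20, 10))
#' @export
inclusive_counts <- function(counts) {
  if (any(counts < 0)) stop_mlnmr("negative category count")
  if (length(counts) < 2L) stop_mlnmr("need at least 2 categories")
  n <- sum(counts)
  out <- n - cumsum(counts)[-length(counts)]
  stats::setNames(out, NULL)
}

# connected components by BFS over the treatment graph implied by studies
treatment_components <- function(treatments, study_treatments) {
  comp <- stats::setNames(seq_along(treatments), treatments)
  adj <- lapply(stats::setNames(treatments, treatments), function(t) character(0))
  for (trts in study_treatments) {
    for (a in trts) adj[[a]] <- union(adj[[a]], setdiff(trts, a))
  }
  seen <- stats::setNames(rep(FALSE, length(treatments)), treatments)
  comps <- list()
  for (t0 in treatments) {
    if (seen[t0]) next
    queue <- t0; members <- character(0)
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      if (seen[v]) next
      seen[v] <- TRUE
      members <- c(members, v)
      queue <- c(queue, adj[[v]][!seen[adj[[v]]]])
    }
    comps[[length(comps) + 1L]] <- members
  }
  comps
}

#' Assemble an evidence network
#'
#' Combines IPD and AgD studies, a treatment-to-class map and an outcome
#' definition into a validated, connected evidence network. Distinct dosing
#' regimens are distinct treatment nodes; classes group regimens for the
#' shared-effect-modifier interaction structure.
#'
#' @param ipd List of `mlnmr_ipd` studies from [load_ipd()] (may be empty).
#' @param agd List of `mlnmr_agd` studies from [load_agd()] (may be empty).
#' @param classes Named character vector mapping every treatment id to a class
#'   id.
#' @param outcome An [outcome_spec()].
#' @param reference Reference treatment id (e.g. `"PBO"`); must appear in at
#'   least one study.
#' @return An object of class `mlnmr_network`.
#' @export
assemble_network <- function(ipd, agd, classes, outcome, reference) {
  ipd <- ipd %||% list(); agd <- agd %||% list()
  if (!length(ipd) && !length(agd)) stop_mlnmr("no studies supplied")
  ids <- c(vapply(ipd, `[[`, "", "study"), vapply(agd, `[[`, "", "study"))
  if (anyDuplicated(ids))
    stop_mlnmr("duplicate study id(s): ",
               paste(unique(ids[duplicated(ids)]), collapse = ", "))
  study_trts <- c(lapply(ipd, `[[`, "treatments"),
                  lapply(agd, `[[`, "treatments"))
  trts <- unique(unlist(study_trts))
  unclassed <- setdiff(trts, names(classes))
  if (length(unclassed))
    stop_mlnmr("treatment(s) without a class: ", paste(unclassed, collapse = ", "))
  if (!reference %in% trts)
    stop_mlnmr("reference treatment ", sQuote(reference),
               " does not appear in any study")
  comps <- treatment_components(trts, study_trts)
  if (length(comps) > 1L)
    stop_mlnmr("treatment network is disconnected; components: ",
               paste(vapply(comps, paste, "", collapse = "+"), collapse = " | "))
  # order: reference first, then remaining treatments in first-seen order
  trts <- c(reference, setdiff(trts, reference))
  cov_ipd <- unique(unlist(lapply(ipd, `[[`, "covariates")))
  cov_agd <- unique(unlist(lapply(agd, `[[`, "covariates")))
  if (length(ipd) && length(agd) && !identical(sort(cov_ipd), sort(cov_agd)))
    stop_mlnmr("IPD and AgD covariate sets differ")
  covs <- cov_ipd %||% cov_agd
  if (is.null(covs)) covs <- character(0)
  # covariate types: from AgD summaries when present, else inferred from IPD
  types <- stats::setNames(rep("continuous", length(covs)), covs)
  if (length(agd)) {
    types[names(agd[[1]]$covariate_types)] <- agd[[1]]$covariate_types
  }
  for (cv in covs) {
    if (length(ipd) && all(vapply(ipd, function(s) is_binary01(s$data[[cv]]), TRUE)))
      types[cv] <- "binary"
  }
  edges <- unique(do.call(rbind, lapply(study_trts, function(tt) {
    if (length(tt) < 2) return(NULL)
    t(utils::combn(sort(tt), 2))
  })))
  structure(
    list(outcome = outcome,
         treatments = data.frame(id = trts,
                                 class = unname(classes[trts]),
                                 stringsAsFactors = FALSE),
         reference = reference,
         ipd = ipd, agd = agd,
         covariates = covs, covariate_types = types,
         edges = edges, grids = NULL, grid_info = NULL),
    class = "mlnmr_network")
}

#' @export
print.mlnmr_network <- function(x, ...) {
  cat("ML-NMR evidence network\n")
  cat("  Treatments:", nrow(x$treatments), "(reference:", x$reference, ")\n")
  cat("  Classes:   ", length(unique(x$treatments$class)), "\n")
  cat("  Studies:   ", length(x$ipd) + length(x$agd),
      sprintf("(%d IPD, %d AgD)\n", length(x$ipd), length(x$agd)))
  cat("  Edges:     ", NROW(x$edges), "\n")
  cat("  Outcome:   ", paste(x$outcome$labels, collapse = " < "), "\n")
  cat("  Covariates:", if (length(x$covariates))
    paste(sprintf("%s (%s)", x$covariates,
                  substr(x$covariate_types[x$covariates], 1, 4)),
          collapse = ", ") else "none", "\n")
  if (!is.null(x$grids))
    cat("  Integration:", x$grid_info$n_points, "points per AgD study\n")
  invisible(x)
}

#' Write a network to plain-text files
#'
#' Serialises a network as `ipd.tsv`, `agd.tsv` and `network.yaml` (outcome
#' labels, class map, reference treatment) in `dir`. [read_network()] restores
#' it field-for-field.
#'
#' @param network An `mlnmr_network`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_network <- function(network, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (length(network$ipd)) {
    ipd_df <- do.call(rbind, lapply(network$ipd, function(s) {
      data.frame(study = s$study, s$data, check.names = FALSE,
                 stringsAsFactors = FALSE)
    }))
    ipd_df$out_cat <- network$outcome$labels[ipd_df$y]
    ipd_df$y <- NULL
    utils::write.table(ipd_df, file.path(dir, "ipd.tsv"), sep = "\t",
                       row.names = FALSE, quote = FALSE)
  }
  if (length(network$agd)) {
    agd_df <- do.call(rbind, lapply(network$agd, function(s) {
      data.frame(study = s$study, s$arms, check.names = FALSE,
                 stringsAsFactors = FALSE)
    }))
    utils::write.table(agd_df, file.path(dir, "agd.tsv"), sep = "\t",
                       row.names = FALSE, quote = FALSE)
  }
  meta <- list(outcome = network$outcome$labels,
               reference = network$reference,
               classes = as.list(stats::setNames(network$treatments$class,
                                                 network$treatments$id)),
               covariates = as.list(network$covariate_types))
  yaml::write_yaml(meta, file.path(dir, "network.yaml"))
  invisible(dir)
}

#' Read a network written by [write_network()]
#' @param dir Directory containing `network.yaml` and the study tables.
#' @return An `mlnmr_network`.
#' @export
read_network <- function(dir) {
  meta <- yaml::read_yaml(file.path(dir, "network.yaml"))
  outc <- outcome_spec(unlist(meta$outcome))
  covs <- names(meta$covariates)
  ipd <- if (file.exists(file.path(dir, "ipd.tsv")))
    load_ipd(file.path(dir, "ipd.tsv"), covs, outc) else list()
  agd <- if (file.exists(file.path(dir, "agd.tsv")))
    load_agd(file.path(dir, "agd.tsv"), covs, outc) else list()
  assemble_network(ipd, agd, unlist(meta$classes), outc, meta$reference)
}
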