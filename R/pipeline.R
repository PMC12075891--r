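#' Run the full heterogeneous-treatment-effect pipeline
#'
#' Executes the seven analysis steps end to end: (1) role validation, (2)
#' train/test split and saturated design with treatment interactions, (3)
#' penalized (elastic-net) outcome fit with cross-validated lambda and
#' stabilized IPT weights, (4) recycled predictions of both potential
#' outcomes on the test split, (5) individual contrasts (CATEs), (6) Ward
#' clustering of the CATE distribution with a Beale-index choice of k and
#' cluster z-score variable importance, and (7) a marginal structural model
#' per discovered modifier reporting subgroup effects on the risk-difference
#' and risk-ratio scales with robust (or bootstrap) inference.
#'
#' @param data a [cohort_table()] or data.frame.
#' @param treatment,outcome column names (ignored if `data` is already a
#'   cohort table).
#' @param confounders,modifiers role declarations (default: the roles
#'   attached to a simulated cohort).
#' @param family outcome-model family: `"gaussian"` (default; for a 0/1
#'   outcome this is a linear-probability model whose contrasts are risk
#'   differences, matching the additive reporting scale) or `"binomial"`.
#' @param interaction_order,include_covariate_covariate see [design_spec()].
#' @param split_fraction training fraction (default 0.7).
#' @param alpha,lambda,n_folds see [penalty_spec()].
#' @param cv_rule cross-validation rule for the outcome fit: `"1se"`
#'   (default) or `"min"`. The pipeline's modifier discovery needs the
#'   sparser 1-SE choice: under the minimum-deviance rule retained noise
#'   interactions create spurious clusters in the fitted CATEs and inflate
#'   the false-modifier rate under a homogeneous-effect truth.
#' @param double_selection also run [post_double_select()] and use its
#'   unpenalized refit as the outcome model (off by default).
#' @param weight_truncation stabilized-weight truncation percentiles.
#' @param threshold variable-importance selection threshold (default 0.2).
#' @param k_max,beale_alpha,beale_method,beale_B see [select_k_beale()].
#' @param jitter_sd relative jitter SD (default 1e-3).
#' @param estimator subgroup estimator, `"iptw"` (default) or `"gcomp"`.
#' @param msm_sample `"all"` (default: step 7 uses the entire cohort) or
#'   `"test"` to restrict subgroup estimation to the held-out split.
#' @param B bootstrap replicates for `estimator = "gcomp"`.
#' @param seed master seed; split, folds, jitter, the Beale null draws and
#'   any bootstrap derive their seeds from it.
#' @return An object of class `hte_result`; see [print.hte_result()].
#' @export
hte_run <- function(data, treatment = "treat", outcome = "event",
                    confounders = NULL, modifiers = NULL,
                    family = c("gaussian", "binomial"),
                    interaction_order = 1L, include_covariate_covariate = FALSE,
                    split_fraction = 0.7, alpha = 1, lambda = "cv",
                    n_folds = 10L, cv_rule = c("1se", "min"),
                    double_selection = FALSE,
                    weight_truncation = c(0.01, 0.99), threshold = 0.2,
                    k_max = 5L, beale_alpha = 0.05,
                    beale_method = c("mc", "ftest"), beale_B = 40L,
                    jitter_sd = 1e-3, estimator = c("iptw", "gcomp"),
                    msm_sample = c("all", "test"), B = 500L, seed = 1L) {
  family <- match.arg(family)
  estimator <- match.arg(estimator)
  msm_sample <- match.arg(msm_sample)
  beale_method <- match.arg(beale_method)
  cv_rule <- match.arg(cv_rule)
  notes <- character()
  note_handler <- function(w) {
    notes <<- c(notes, conditionMessage(w))
    invokeRestart("muffleWarning")
  }
  tab <- if (inherits(data, "cohort_table")) data else {
    cohort_table(data, treatment = treatment, outcome = outcome,
                 id = if ("id" %in% names(data)) "id")
  }
  if (is.null(confounders)) confounders <- attr(tab, "roles")$confounders
  if (is.null(modifiers)) modifiers <- attr(tab, "roles")$candidate_modifiers
  roles <- variable_roles(confounders, modifiers)
  withCallingHandlers(validate_roles(tab, roles), warning = note_handler)

  dspec <- design_spec(interaction_order, include_covariate_covariate,
                       standardize = TRUE, split_fraction = split_fraction,
                       seed = seed)
  parts <- withCallingHandlers(split_sample(tab, split_fraction, seed = seed),
                               warning = note_handler)
  train <- parts$train; test <- parts$test

  w_train <- withCallingHandlers(
    fit_iptw(train, confounders, truncation = weight_truncation),
    warning = note_handler)
  pspec <- penalty_spec(family = family, alpha = alpha, lambda = lambda,
                        n_folds = n_folds, fold_seed = seed + 1L)
  if (double_selection) {
    sel <- withCallingHandlers(
      post_double_select(train, roles, pspec, dspec), warning = note_handler)
    model <- sel$refit
  } else {
    sel <- NULL
    design_tr <- standardize_design(build_design(train, roles, dspec))
    model <- fit_penalized(design_tr, train[[outcome_col(train)]], pspec,
                           weights = w_train$weights, cv_rule = cv_rule)
  }

  po <- predict_potential_outcomes(model, test, roles, dspec)
  y_binary <- all(tab[[outcome_col(tab)]] %in% c(0, 1))
  cate <- compute_cate(po$y1, po$y0, scale = if (y_binary) "RD" else "MD",
                       ids = po$ids,
                       modifiers = as.data.frame(test)[roles$candidate_modifiers])
  cate_summary <- summarize_cate_distribution(cate)

  discovery <- withCallingHandlers(
    discover_modifiers(cate, threshold = threshold, relative_sd = jitter_sd,
                       k_max = k_max, alpha = beale_alpha,
                       method = beale_method, B = beale_B, seed = seed + 2L),
    warning = note_handler)

  msm_tab <- if (msm_sample == "all") tab else test
  w_msm <- if (estimator == "iptw") {
    withCallingHandlers(fit_iptw(msm_tab, confounders, truncation = weight_truncation),
                        warning = note_handler)
  }
  msm_family <- if (y_binary) "binomial" else "gaussian"
  subgroups <- list()
  for (m in discovery$selected) {
    row <- discovery$importance[discovery$importance$modifier == m, ]
    cutoff <- if (row$type == "continuous") row$cutoff else NULL
    grp <- binarize_modifier(msm_tab, m, cutoff = cutoff)
    msm <- withCallingHandlers(
      fit_msm(msm_tab, grp, weights = w_msm, estimator = estimator,
              family = msm_family, confounders = confounders),
      warning = note_handler)
    subgroups[[m]] <- withCallingHandlers(
      subgroup_contrasts(msm, B = B, seed = seed + 3L), warning = note_handler)
  }
  overall <- withCallingHandlers(
    overall_effect(msm_tab, w_msm, estimator, msm_family, confounders,
                   B = B, seed = seed + 3L),
    warning = note_handler)

  structure(
    list(
      roles = roles, n = nrow(tab), n_train = nrow(train), n_test = nrow(test),
      model = model, selection = sel, weights_train = w_train,
      weights_msm = w_msm, cate = cate, cate_summary = cate_summary,
      discovery = discovery, subgroups = subgroups, overall = overall,
      estimator = estimator, family = family, threshold = threshold,
      seed = seed, notes = notes
    ),
    class = "hte_result"
  )
}

outcome_col <- function(table) attr(table, "outcome")

# overall (no-subgroup) effect row using the same estimator/inference as step 7
overall_effect <- function(table, weights, estimator, family, confounders,
                           B = 500L, seed = 1L) {
  msm <- suppressWarnings(
    fit_msm(table, rep(0L, nrow(table)), weights = weights,
            estimator = estimator, family = family, confounders = confounders)
  )
  suppressWarnings(subgroup_contrasts(msm, B = B, seed = seed))
}

#' @export
print.hte_result <- function(x, digits = 3, ...) {
  cat("Generalized HTE pipeline result\n")
  cat(sprintf("  n = %d (train %d / test %d), family = %s, estimator = %s\n",
              x$n, x$n_train, x$n_test, x$family, x$estimator))
  dg <- x$cate_summary$diagnostic
  cat(sprintf("  CATE distribution: %s (valley/peak ratio %s)\n", dg$flag,
              ifelse(is.na(dg$valley_peak_ratio), "-",
                     format(dg$valley_peak_ratio, digits = 2))))
  cat(sprintf("  clusters: k = %d; importance threshold %.2f\n",
              x$discovery$k, x$threshold))
  imp <- x$discovery$importance
  cat("  variable importance:\n")
  for (i in seq_len(nrow(imp))) {
    cat(sprintf("    %-12s %6.3f %s\n", imp$modifier[i], imp$importance[i],
                ifelse(imp$selected[i], "*", "")))
  }
  if (length(x$subgroups) == 0L) {
    cat("  no effect modifiers selected\n")
    print_subgroup_rows(x$overall, digits)
  } else {
    for (m in names(x$subgroups)) print_subgroup_rows(x$subgroups[[m]], digits)
  }
  invisible(x)
}

print_subgroup_rows <- function(tb, digits = 3) {
  for (i in seq_len(nrow(tb))) {
    pi_rd <- if (is.na(tb$p_int_rd[i])) "" else sprintf(" p-int(RD)=%.3g", tb$p_int_rd[i])
    pi_rr <- if (is.na(tb$p_int_rr[i])) "" else sprintf(" p-int(RR)=%.3g", tb$p_int_rr[i])
    cat(sprintf("    %-18s n=%6d (%5.2f%%)  RD %6.3f (%6.3f, %6.3f)  RR %5.2f (%4.2f, %4.2f)%s%s\n",
                tb$label[i], tb$n[i], tb$prop[i],
                tb$rd[i], tb$rd_lo[i], tb$rd_hi[i],
                tb$rr[i], tb$rr_lo[i], tb$rr_hi[i], pi_rd, pi_rr))
  }
}

#' Write a report directory for a pipeline result
#'
#' Writes `importance.csv`, `subgroups.csv` (all modifiers stacked, mirroring
#' the additive/relative subgroup-effect table layout), `cate.csv`,
#' `cate_histogram.csv`, `balance.csv` and `run.json`.
#'
#' @param result an `hte_result`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(result, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(as.data.frame(result$discovery$importance),
                   file.path(dir, "importance.csv"), row.names = FALSE)
  subs <- if (length(result$subgroups)) {
    do.call(rbind, lapply(names(result$subgroups), function(m) {
      cbind(modifier = m, as.data.frame(result$subgroups[[m]]))
    }))
  } else {
    cbind(modifier = "(none selected)", as.data.frame(result$overall))
  }
  utils::write.csv(subs, file.path(dir, "subgroups.csv"), row.names = FALSE)
  write_cate_csv(result$cate, file.path(dir, "cate.csv"))
  h <- result$cate_summary$histogram
  utils::write.csv(data.frame(mid = h$mids, count = h$counts),
                   file.path(dir, "cate_histogram.csv"), row.names = FALSE)
  if (!is.null(result$weights_msm)) {
    utils::write.csv(result$weights_msm$balance, file.path(dir, "balance.csv"),
                     row.names = FALSE)
  }
  jsonlite::write_json(
    list(
      n = result$n, n_train = result$n_train, n_test = result$n_test,
      family = result$family, estimator = result$estimator,
      k = result$discovery$k, threshold = result$threshold,
      selected = as.list(result$discovery$selected),
      lambda = result$model$lambda, alpha = result$model$alpha,
      seed = result$seed, notes = as.list(result$notes)
    ),
    file.path(dir, "run.json"), auto_unbox = TRUE, digits = NA
  )
  invisible(dir)
}

#' Run the pipeline from a configuration file
#'
#' Reads a YAML (or JSON) configuration with keys `treatment`, `outcome`,
#' `confounders`, `modifiers` and any [hte_run()] option (`interaction_order`,
#' `split_fraction`, `family`, `alpha`, `lambda`, `n_folds`,
#' `double_selection`, `weight_truncation`, `threshold`, `estimator`,
#' `seed`, ...), then runs the pipeline on the supplied table.
#'
#' @param config path to a YAML/JSON file, or a named list.
#' @param data a data.frame or path to a CSV/TSV cohort file.
#' @return An `hte_result`.
#' @export
hte_run_config <- function(config, data) {
  cfg <- if (is.character(config)) {
    if (grepl("\\.json$", config)) jsonlite::read_json(config, simplifyVector = TRUE)
    else yaml::read_yaml(config)
  } else config
  if (is.character(data)) {
    sep <- if (grepl("\\.tsv$", data)) "\t" else ","
    data <- utils::read.table(data, header = TRUE, sep = sep,
                              stringsAsFactors = FALSE)
  }
  args <- cfg[intersect(names(cfg), names(formals(hte_run)))]
  args$data <- data
  do.call(hte_run, args)
}
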