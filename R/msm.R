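#' Binarize an effect modifier
#'
#' Continuous modifiers are split at the data-derived cut-off (see
#' [continuous_cutoff()]), with the boundary convention `value >= cutoff` in
#' the upper group. Binary modifiers pass through unchanged.
#'
#' @param table a [cohort_table()].
#' @param modifier modifier column name.
#' @param cutoff numeric cut-off, required iff the modifier is continuous.
#' @return An object of class `modifier_group`: `group` (0/1 integer),
#'   `labels` (length 2, lower group first), `modifier`, `cutoff`, `type`.
#' @export
binarize_modifier <- function(table, modifier, cutoff = NULL) {
  stopifnot(inherits(table, "cohort_table"))
  if (!modifier %in% names(table)) stop("unknown column: ", modifier)
  v <- as.numeric(table[[modifier]])
  if (length(unique(v)) <= 2L) {
    if (!all(v %in% c(0, 1))) stop("binary modifier must be coded 0/1")
    group <- as.integer(v)
    labels <- paste(modifier, "=", 0:1)
    cutoff <- NA_real_
    type <- "binary"
  } else {
    if (is.null(cutoff)) stop("cutoff is required for a continuous modifier")
    if (cutoff <= min(v) || cutoff > max(v)) {
      stop("cutoff outside the observed range (empty subgroup)")
    }
    group <- as.integer(v >= cutoff)
    labels <- c(sprintf("%s < %.4g", modifier, cutoff),
                sprintf("%s >= %.4g", modifier, cutoff))
    type <- "continuous"
  }
  structure(list(group = group, labels = labels, modifier = modifier,
                 cutoff = cutoff, type = type),
            class = "modifier_group")
}

#' Fit the subgroup marginal structural model
#'
#' Model for the potential-outcome means in the treatment-by-subgroup cells,
#' with terms `{1, X, G, X*G}`. Under `estimator = "iptw"` the model is fit
#' with stabilized IPT weights, so the four fitted cell means are weighted
#' cell proportions and both the risk difference and the risk ratio derive
#' from the same standardized risks (a linear-probability fit carries the RD
#' scale; a log-link fit of the same saturated model carries the RR scale -
#' being saturated, both reproduce the weighted cell means exactly). Under
#' `estimator = "gcomp"` an outcome model retaining the confounders is fit
#' unweighted and subgroup effects are obtained by standardization (recycled
#' predictions restricted to each subgroup); inference is then by bootstrap.
#'
#' @param table a [cohort_table()] (the analysis set; the default pipeline
#'   follows the convention of using the entire cohort here).
#' @param group a `modifier_group` from [binarize_modifier()] or a 0/1 vector.
#' @param weights an `hte_weights` (or numeric vector), required for
#'   `estimator = "iptw"`.
#' @param estimator `"iptw"` or `"gcomp"`.
#' @param family `"binomial"` for a 0/1 outcome (risks), `"gaussian"` for a
#'   continuous one (means; the "RR" columns then report mean ratios).
#' @param confounders confounder names, used by the gcomp outcome model.
#' @return An object of class `hte_msm`.
#' @export
fit_msm <- function(table, group, weights = NULL,
                    estimator = c("iptw", "gcomp"),
                    family = c("binomial", "gaussian"),
                    confounders = NULL) {
  estimator <- match.arg(estimator)
  family <- match.arg(family)
  stopifnot(inherits(table, "cohort_table"))
  grp <- if (inherits(group, "modifier_group")) group else {
    structure(list(group = as.integer(group),
                   labels = paste("G =", 0:1),
                   modifier = "G", cutoff = NA_real_, type = "binary"),
              class = "modifier_group")
  }
  g <- grp$group
  if (length(g) != nrow(table)) stop("group length does not match the cohort")
  y <- table[[attr(table, "outcome")]]
  x <- table[[attr(table, "treatment")]]
  degenerate <- length(unique(g)) < 2L
  if (degenerate) {
    warning("subgroup variable is constant; falling back to the overall effect")
  } else if (any(table(x, g) == 0L)) {
    stop("empty treatment-by-subgroup cell (positivity violation)")
  }
  if (estimator == "iptw") {
    if (is.null(weights)) stop("weights are required for the IPTW estimator")
    w <- if (inherits(weights, "hte_weights")) weights$weights else as.numeric(weights)
  } else {
    w <- rep(1, length(y))
  }
  dat <- data.frame(.y = y, .x = x, .g = g)
  fits <- list()
  if (estimator == "iptw") {
    fml_rd <- if (degenerate) .y ~ .x else .y ~ .x * .g
    fits$rd <- stats::lm(fml_rd, data = dat, weights = w)
    fits$rd_overall <- stats::lm(.y ~ .x, data = dat, weights = w)
    # ratio scale needs a non-negative outcome (risks or rates)
    if (all(y >= 0)) {
      fits$rr <- fit_log_link(fml_rd, dat, w)
      fits$rr_overall <- fit_log_link(.y ~ .x, dat, w)
    }
  } else {
    cdf <- as.data.frame(table)[, confounders, drop = FALSE]
    dat2 <- cbind(dat, cdf)
    rhs <- if (degenerate) ".x" else ".x * .g"
    if (length(confounders)) {
      rhs <- paste(rhs, "+", paste(sprintf("`%s`", confounders), collapse = " + "))
    }
    fml <- stats::as.formula(paste(".y ~", rhs))
    fits$outcome <- if (family == "binomial") {
      stats::glm(fml, data = dat2, family = stats::binomial())
    } else {
      stats::lm(fml, data = dat2)
    }
    fits$data <- dat2
  }
  structure(
    list(estimator = estimator, family = family, fits = fits,
         group = grp, degenerate = degenerate,
         n = length(y), n_g = if (degenerate) NULL else as.vector(table(g)),
         confounders = confounders, weights = w,
         cell_means = if (!degenerate) weighted_cell_means(y, x, g, w)),
    class = "hte_msm"
  )
}

weighted_cell_means <- function(y, x, g, w) {
  out <- matrix(NA_real_, 2, 2, dimnames = list(x = 0:1, g = 0:1))
  for (xx in 0:1) for (gg in 0:1) {
    i <- x == xx & g == gg
    out[xx + 1, gg + 1] <- stats::weighted.mean(y[i], w[i])
  }
  out
}

# saturated log-link fit: log-binomial with the weighted cell means as
# starting values, falling back to Poisson (identical fitted values when
# saturated) if log-binomial fails to converge
fit_log_link <- function(fml, dat, w) {
  fit <- tryCatch(
    suppressWarnings(stats::glm(fml, data = dat, weights = w,
                                family = stats::binomial(link = "log"),
                                start = rep(-0.5, length(attr(stats::terms(fml), "term.labels")) + 1))),
    error = function(e) NULL
  )
  if (is.null(fit) || !fit$converged) {
    fit <- suppressWarnings(stats::glm(fml, data = dat, weights = w,
                                       family = stats::poisson(link = "log")))
  }
  fit
}

sandwich_se <- function(fit, contrast) {
  v <- sandwich::vcovHC(fit, type = "HC0")
  cf <- names(stats::coef(fit))
  l <- setNames(rep(0, length(cf)), cf)
  l[names(contrast)] <- contrast
  sqrt(drop(t(l) %*% v %*% l))
}

#' Subgroup treatment effects on additive and relative scales
#'
#' Extracts the subgroup risk differences `RD_g = risk(X=1, G=g) -
#' risk(X=0, G=g)` and risk ratios `RR_g` (the ratio of the same standardized
#' risks), plus the overall row, with 95 percent confidence intervals and a
#' p-for-interaction per scale. Inference follows the estimator: robust
#' sandwich variance for IPTW, percentile bootstrap (resampling rows and
#' refitting) for G-computation.
#'
#' @param msm an `hte_msm` from [fit_msm()].
#' @param conf_level confidence level (default 0.95).
#' @param inference `"auto"` (sandwich for iptw, bootstrap for gcomp),
#'   `"sandwich"`, or `"bootstrap"`.
#' @param B bootstrap replicates (default 500, minimum 100).
#' @param seed integer bootstrap seed.
#' @return An object of class `subgroup_estimates`: data.frame with one row
#'   per subgroup plus the overall row (`label`, `n`, `prop`, `rd`, `rd_lo`,
#'   `rd_hi`, `rr`, `rr_lo`, `rr_hi`, `p_int_rd`, `p_int_rr`, `estimator`,
#'   `inference`).
#' @export
subgroup_contrasts <- function(msm, conf_level = 0.95,
                               inference = c("auto", "sandwich", "bootstrap"),
                               B = 500L, seed = 1L) {
  stopifnot(inherits(msm, "hte_msm"))
  inference <- match.arg(inference)
  if (inference == "auto") {
    inference <- if (msm$estimator == "iptw") "sandwich" else "bootstrap"
  }
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  if (msm$estimator == "iptw") {
    est <- iptw_estimates(msm)
  } else {
    est <- gcomp_estimates(msm)
  }
  if (inference == "sandwich") {
    if (msm$estimator != "iptw") stop("sandwich inference requires the IPTW estimator")
    ci <- iptw_sandwich_cis(msm, z)
  } else {
    if (B < 100L) stop("bootstrap requires B >= 100")
    ci <- msm_bootstrap_cis(msm, conf_level, B, seed)
  }
  labels <- c("Overall", if (!msm$degenerate) msm$group$labels)
  n_g <- c(msm$n, if (!msm$degenerate) msm$n_g)
  out <- data.frame(
    label = labels, n = n_g, prop = 100 * n_g / msm$n,
    rd = est$rd, rd_lo = ci$rd_lo, rd_hi = ci$rd_hi,
    rr = est$rr, rr_lo = ci$rr_lo, rr_hi = ci$rr_hi,
    p_int_rd = NA_real_, p_int_rr = NA_real_,
    estimator = msm$estimator, inference = inference,
    row.names = NULL
  )
  if (!msm$degenerate) {
    out$p_int_rd[2] <- p_interaction(msm, "RD", B = B, seed = seed)
    if (msm$estimator != "iptw" || !is.null(msm$fits$rr)) {
      out$p_int_rr[2] <- p_interaction(msm, "RR", B = B, seed = seed)
    }
  }
  structure(out, class = c("subgroup_estimates", "data.frame"),
            modifier = msm$group$modifier, cutoff = msm$group$cutoff)
}

iptw_estimates <- function(msm) {
  cm <- msm$cell_means
  has_rr <- !is.null(msm$fits$rr_overall)
  rd_overall <- stats::coef(msm$fits$rd_overall)[".x"]
  rr_overall <- if (has_rr) exp(stats::coef(msm$fits$rr_overall)[".x"]) else NA_real_
  if (msm$degenerate) {
    return(list(rd = unname(rd_overall), rr = unname(rr_overall)))
  }
  rd_g <- c(cm[2, 1] - cm[1, 1], cm[2, 2] - cm[1, 2])
  if (has_rr) {
    rr_g <- c(cm[2, 1] / cm[1, 1], cm[2, 2] / cm[1, 2])
    if (any(!is.finite(rr_g))) warning("zero denominator risk; RR undefined in a subgroup")
  } else {
    rr_g <- c(NA_real_, NA_real_)
  }
  list(rd = unname(c(rd_overall, rd_g)), rr = unname(c(rr_overall, rr_g)))
}

iptw_sandwich_cis <- function(msm, z) {
  has_rr <- !is.null(msm$fits$rr_overall)
  se_rd_o <- sandwich_se(msm$fits$rd_overall, c(.x = 1))
  se_lrr_o <- if (has_rr) sandwich_se(msm$fits$rr_overall, c(.x = 1)) else NA_real_
  est <- iptw_estimates(msm)
  if (msm$degenerate) {
    return(list(rd_lo = est$rd - z * se_rd_o, rd_hi = est$rd + z * se_rd_o,
                rr_lo = est$rr * exp(-z * se_lrr_o), rr_hi = est$rr * exp(z * se_lrr_o)))
  }
  se_rd <- c(se_rd_o,
             sandwich_se(msm$fits$rd, c(.x = 1)),
             sandwich_se(msm$fits$rd, c(.x = 1, `.x:.g` = 1)))
  se_lrr <- if (has_rr) {
    c(se_lrr_o,
      sandwich_se(msm$fits$rr, c(.x = 1)),
      sandwich_se(msm$fits$rr, c(.x = 1, `.x:.g` = 1)))
  } else {
    rep(NA_real_, 3)
  }
  list(rd_lo = est$rd - z * se_rd, rd_hi = est$rd + z * se_rd,
       rr_lo = est$rr * exp(-z * se_lrr), rr_hi = est$rr * exp(z * se_lrr))
}

# G-computation: standardize predictions within each subgroup
gcomp_estimates <- function(msm, fit = msm$fits$outcome, dat = msm$fits$data) {
  pred <- function(xval, rows) {
    nd <- dat[rows, , drop = FALSE]
    nd$.x <- xval
    mean(stats::predict(fit, newdata = nd, type = "response"))
  }
  all_rows <- seq_len(nrow(dat))
  r1 <- pred(1, all_rows); r0 <- pred(0, all_rows)
  rd <- r1 - r0; rr <- r1 / r0
  if (!msm$degenerate) {
    for (gg in 0:1) {
      rows <- which(dat$.g == gg)
      r1g <- pred(1, rows); r0g <- pred(0, rows)
      rd <- c(rd, r1g - r0g); rr <- c(rr, r1g / r0g)
    }
  }
  list(rd = rd, rr = rr)
}

refit_outcome <- function(fit, data) {
  fml <- stats::formula(fit)
  if (inherits(fit, "glm")) {
    stats::glm(fml, data = data, family = stats::family(fit))
  } else {
    stats::lm(fml, data = data)
  }
}

msm_bootstrap_cis <- function(msm, conf_level, B, seed) {
  old <- .Random.seed_safe(); on.exit(.restore_seed(old), add = TRUE)
  set.seed(as.integer(seed))
  dat <- msm$fits$data
  n <- nrow(dat)
  k <- if (msm$degenerate) 1L else 3L
  draws_rd <- matrix(NA_real_, B, k)
  draws_rr <- matrix(NA_real_, B, k)
  skipped <- 0L
  for (b in seq_len(B)) {
    i <- sample.int(n, n, replace = TRUE)
    db <- dat[i, , drop = FALSE]
    if (!msm$degenerate && any(table(db$.x, db$.g) == 0L)) { skipped <- skipped + 1L; next }
    fit_b <- tryCatch(suppressWarnings(refit_outcome(msm$fits$outcome, db)),
                      error = function(e) NULL)
    if (is.null(fit_b)) { skipped <- skipped + 1L; next }
    est_b <- gcomp_estimates(msm, fit = fit_b, dat = db)
    draws_rd[b, ] <- est_b$rd
    draws_rr[b, ] <- est_b$rr
  }
  if (skipped > 0.1 * B) stop("more than 10% of bootstrap resamples skipped (empty cells)")
  a <- (1 - conf_level) / 2
  q <- function(m, p) apply(m, 2, stats::quantile, probs = p, na.rm = TRUE)
  list(rd_lo = q(draws_rd, a), rd_hi = q(draws_rd, 1 - a),
       rr_lo = q(draws_rr, a), rr_hi = q(draws_rr, 1 - a),
       draws_rd = draws_rd, draws_rr = draws_rr, skipped = skipped)
}

#' Test for effect-measure modification
#'
#' Wald test of equal subgroup effects: on the additive scale the null is
#' `RD_1 = RD_0` (the treatment-by-subgroup interaction of the
#' linear-probability MSM); on the relative scale `log RR_1 = log RR_0` (the
#' interaction of the log-link MSM). Variance is robust sandwich under IPTW;
#' under G-computation the interaction contrast is bootstrapped and a normal
#' approximation applied to its resampling distribution.
#'
#' @param msm an `hte_msm` with an estimable interaction.
#' @param scale `"RD"` or `"RR"`.
#' @param B,seed bootstrap settings (gcomp estimator only).
#' @return Two-sided p-value.
#' @export
p_interaction <- function(msm, scale = c("RD", "RR"), B = 500L, seed = 1L) {
  scale <- match.arg(scale)
  stopifnot(inherits(msm, "hte_msm"))
  if (msm$degenerate) stop("non-estimable: subgroup variable is constant")
  if (msm$estimator == "iptw") {
    fit <- if (scale == "RD") msm$fits$rd else msm$fits$rr
    b <- stats::coef(fit)[".x:.g"]
    se <- sandwich_se(fit, c(`.x:.g` = 1))
    return(unname(2 * stats::pnorm(-abs(b / se))))
  }
  ci <- msm_bootstrap_cis(msm, 0.95, B, seed)
  if (scale == "RD") {
    diffs <- ci$draws_rd[, 3] - ci$draws_rd[, 2]
    est <- gcomp_estimates(msm)$rd
    d <- est[3] - est[2]
  } else {
    diffs <- log(ci$draws_rr[, 3]) - log(ci$draws_rr[, 2])
    est <- gcomp_estimates(msm)$rr
    d <- log(est[3]) - log(est[2])
  }
  se <- stats::sd(diffs, na.rm = TRUE)
  unname(2 * stats::pnorm(-abs(d / se)))
}

#' Within-subgroup means of individual treatment effects
#'
#' Aggregates test-set ITEs over a grouping: the size-weighted average of the
#' subgroup means reproduces the overall mean CATE exactly.
#'
#' @param cate an `hte_cate` or numeric vector.
#' @param group grouping vector aligned with the CATEs.
#' @return data.frame with `group`, `n`, `mean_cate`.
#' @export
subgroup_cate_means <- function(cate, group) {
  x <- if (inherits(cate, "hte_cate")) cate$cate else as.numeric(cate)
  data.frame(
    group = sort(unique(group)),
    n = as.vector(table(group)),
    mean_cate = as.vector(tapply(x, group, mean))
  )
}
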