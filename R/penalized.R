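#' Penalized-fit specification
#'
#' Holds the elastic-net family and tuning parameters. `alpha = 1` is the
#' LASSO, `alpha -> 0` approaches ridge regression; `lambda` may be a fixed
#' non-negative number or `"cv"` to select it by cross-validation with
#' deterministic folds.
#'
#' @param family `"gaussian"` (identity link; for a 0/1 outcome this is a
#'   linear-probability model whose contrasts are risk differences) or
#'   `"binomial"` (penalized logistic deviance).
#' @param alpha elastic-net mixing in `[0, 1]`.
#' @param lambda `"cv"` or a single number `>= 0`.
#' @param n_folds folds for cross-validation (default 10).
#' @param fold_seed integer seed fixing the fold assignment.
#' @return An object of class `penalty_spec`.
#' @export
penalty_spec <- function(family = c("gaussian", "binomial"), alpha = 1,
                         lambda = "cv", n_folds = 10L, fold_seed = 1L) {
  family <- match.arg(family)
  if (alpha < 0 || alpha > 1) stop("alpha must be in [0, 1]")
  if (is.numeric(lambda) && lambda < 0) stop("lambda must be >= 0")
  if (!is.numeric(lambda) && !identical(lambda, "cv")) stop("lambda must be a number or \"cv\"")
  if (n_folds < 2L) stop("n_folds must be >= 2")
  structure(
    list(family = family, alpha = alpha, lambda = lambda,
         n_folds = as.integer(n_folds), fold_seed = as.integer(fold_seed)),
    class = "penalty_spec"
  )
}

#' Elastic-net penalized loss
#'
#' The objective the penalized outcome model minimizes, written out so it can
#' be inspected and tested directly. For the gaussian family it is the sum of
#' squared errors plus the elastic-net penalty
#' `lambda * ((1 - alpha)/2 * sum(beta^2) + alpha * sum(|beta|))`;
#' at `lambda = 0` it reduces to the ordinary least-squares loss, and at
#' `alpha = 1` the penalty is the plain LASSO L1 term. For the binomial
#' family the squared-error term is replaced by the deviance. The intercept
#' is never penalized.
#'
#' @param y outcome vector.
#' @param design an `hte_design` (or plain numeric matrix).
#' @param beta coefficient vector aligned with the design columns.
#' @param lambda penalty strength `>= 0`.
#' @param alpha elastic-net mixing in `[0, 1]`.
#' @param intercept unpenalized intercept (default 0).
#' @param family `"gaussian"` or `"binomial"`.
#' @return The scalar loss.
#' @export
penalty_loss <- function(y, design, beta, lambda, alpha = 1, intercept = 0,
                         family = c("gaussian", "binomial")) {
  family <- match.arg(family)
  if (lambda < 0) stop("lambda must be >= 0")
  if (alpha < 0 || alpha > 1) stop("alpha must be in [0, 1]")
  m <- if (inherits(design, "hte_design")) design$x else as.matrix(design)
  if (length(beta) != ncol(m)) stop("beta length does not match design columns")
  eta <- intercept + drop(m %*% beta)
  fit_term <- switch(family,
    gaussian = sum((y - eta)^2),
    binomial = {
      p <- stats::plogis(eta)
      -2 * sum(y * log(p) + (1 - y) * log(1 - p))
    }
  )
  fit_term + lambda * ((1 - alpha) / 2 * sum(beta^2) + alpha * sum(abs(beta)))
}

#' Fit the penalized outcome model
#'
#' Elastic-net fit of the outcome on the standardized saturated design. When
#' `lambda = "cv"` the penalty is chosen to minimize the mean cross-validated
#' deviance over a log-spaced grid (about 100 values from the smallest lambda
#' that zeroes every penalized term down to 1e-4 of it), with fold membership
#' fixed by `fold_seed` so the chosen lambda is reproducible. A `"1se"` rule
#' is available but off by default. The intercept and the treatment main
#' effect are never penalized: the treatment effect must not be selected out
#' of its own model. `lambda = 0` dispatches to the exact unpenalized
#' least-squares/GLM fit.
#'
#' @param design standardized training `hte_design`.
#' @param y outcome vector aligned with the design rows.
#' @param spec a [penalty_spec()].
#' @param weights optional observation weights (for example stabilized IPT
#'   weights from [fit_iptw()]).
#' @param cv_rule `"min"` (default) or `"1se"`.
#' @return An object of class `hte_fit`: intercept, named coefficient vector
#'   `beta`, chosen `lambda`/`alpha`, active set, family, and the scaling
#'   parameters carried from the training design.
#' @export
fit_penalized <- function(design, y, spec = penalty_spec(), weights = NULL,
                          cv_rule = c("min", "1se")) {
  stopifnot(inherits(design, "hte_design"), inherits(spec, "penalty_spec"))
  cv_rule <- match.arg(cv_rule)
  m <- design$x
  if (!all(is.finite(m)) || !all(is.finite(y))) stop("non-finite values in design or outcome")
  if (spec$family == "binomial" && !all(y %in% c(0, 1))) {
    stop("binomial family requires a 0/1 outcome")
  }
  if (is.null(weights)) weights <- rep(1, length(y))
  pf <- ifelse(design$provenance$kind == "treatment-main", 0, 1)
  if (identical(spec$lambda, 0)) {
    fit <- unpenalized_fit(m, y, spec$family, weights)
    beta <- list(intercept = fit$intercept, beta = fit$beta)
    lambda <- 0
    cv <- NULL
  } else if (identical(spec$lambda, "cv")) {
    old <- .Random.seed_safe(); on.exit(.restore_seed(old), add = TRUE)
    set.seed(spec$fold_seed)
    foldid <- sample(rep(seq_len(spec$n_folds), length.out = length(y)))
    # degenerate (all-zero) paths make glmnet interpolate over tied lambdas
    # and warn; the result is still exact, so muffle just that warning
    cv <- withCallingHandlers(
      glmnet::cv.glmnet(m, y, family = spec$family, alpha = spec$alpha,
                        weights = weights, foldid = foldid,
                        penalty.factor = pf, standardize = FALSE),
      warning = function(w) {
        if (grepl("collapsing to unique", conditionMessage(w))) {
          invokeRestart("muffleWarning")
        }
      }
    )
    lambda <- if (cv_rule == "min") cv$lambda.min else cv$lambda.1se
    # glmnet interpolates over the lambda path here and warns when the path
    # has numerically tied entries (degenerate fits); the value is exact at a
    # path point, so the warning is noise
    cf <- suppressWarnings(stats::coef(cv, s = lambda))
    beta <- list(intercept = cf[1], beta = setNames(as.numeric(cf[-1]), rownames(cf)[-1]))
  } else {
    # refit with the requested lambda embedded in the path so the extracted
    # coefficients are solved at it exactly (no interpolation)
    fit0 <- glmnet::glmnet(m, y, family = spec$family, alpha = spec$alpha,
                           weights = weights, penalty.factor = pf,
                           standardize = FALSE)
    lams <- sort(unique(c(fit0$lambda, spec$lambda)), decreasing = TRUE)
    fit <- glmnet::glmnet(m, y, family = spec$family, alpha = spec$alpha,
                          weights = weights, penalty.factor = pf,
                          standardize = FALSE, lambda = lams)
    cf <- stats::coef(fit, s = spec$lambda)
    beta <- list(intercept = cf[1], beta = setNames(as.numeric(cf[-1]), rownames(cf)[-1]))
    lambda <- spec$lambda
    cv <- NULL
  }
  b <- beta$beta[colnames(m)]
  structure(
    list(
      intercept = unname(beta$intercept),
      beta = b,
      lambda = lambda,
      alpha = spec$alpha,
      family = spec$family,
      active = names(b)[b != 0],
      provenance = design$provenance,
      binary = design$binary,
      center = design$center,
      scale = design$scale,
      treatment = design$treatment,
      cv = if (!is.null(cv)) list(lambda = cv$lambda, cvm = cv$cvm, chosen = lambda)
    ),
    class = "hte_fit"
  )
}

# exact unpenalized fit used for lambda = 0 (and post-double-selection refits)
unpenalized_fit <- function(m, y, family, weights) {
  df <- data.frame(.y = y, m, check.names = FALSE)
  fml <- stats::as.formula(paste("`.y` ~", paste(sprintf("`%s`", colnames(m)), collapse = " + ")))
  fit <- if (family == "gaussian") {
    stats::lm(fml, data = df, weights = weights)
  } else {
    stats::glm(fml, data = df, family = stats::binomial(), weights = weights)
  }
  cf <- stats::coef(fit)
  cf[is.na(cf)] <- 0
  list(intercept = cf[1], beta = setNames(cf[-1], colnames(m)), fit = fit)
}

#' Serialize a fitted outcome model to JSON
#'
#' @param fit an `hte_fit`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fit_json <- function(fit, path) {
  jsonlite::write_json(
    list(
      family = fit$family, alpha = fit$alpha, lambda = fit$lambda,
      intercept = fit$intercept, coefficients = as.list(fit$beta),
      center = as.list(fit$center), scale = as.list(fit$scale)
    ),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' Post-double selection of model terms
#'
#' Penalized selection alone can drop a confounder that matters for the
#' causal contrast. This step takes the union of (a) terms selected by the
#' penalized outcome regression on the saturated design, (b) confounders
#' selected by a penalized treatment (propensity) regression, and (c)
#' treatment-by-modifier interactions selected by the outcome regression
#' (a subset of (a), kept explicit because interaction selection is what the
#' modifier-discovery step feeds on), then refits the outcome model on that
#' union without penalty. Run on the training split only.
#'
#' Both selection regressions use the parsimonious "1-SE" cross-validation
#' rule by default: selection (unlike prediction) should err on the side of
#' sparsity, and the minimum-deviance rule is known to admit noise terms.
#'
#' @param train training [cohort_table()].
#' @param roles validated [variable_roles()].
#' @param spec a [penalty_spec()] for both selection fits.
#' @param design_spec a [design_spec()].
#' @param cv_rule `"1se"` (default) or `"min"` for the selection fits.
#' @return list with `terms` (the selected union), `outcome_terms`,
#'   `propensity_terms`, and `refit` (an `hte_fit` from the unpenalized refit
#'   on the union).
#' @export
post_double_select <- function(train, roles, spec = penalty_spec(),
                               design_spec = hetefx::design_spec(),
                               cv_rule = c("1se", "min")) {
  cv_rule <- match.arg(cv_rule)
  design <- standardize_design(build_design(train, roles, design_spec))
  y <- train[[attr(train, "outcome")]]
  xname <- attr(train, "treatment")
  out_fit <- fit_penalized(design, y, spec, cv_rule = cv_rule)
  outcome_terms <- setdiff(out_fit$active, xname)
  # propensity branch: penalized logistic of treatment on confounder mains
  conf <- roles$confounders
  prop_terms <- character()
  if (length(conf) >= 2L) {
    mc <- scale(as.matrix(as.data.frame(train)[conf]))
    mc[, apply(mc, 2, function(v) anyNA(v))] <- 0
    old <- .Random.seed_safe(); on.exit(.restore_seed(old), add = TRUE)
    set.seed(spec$fold_seed)
    foldid <- sample(rep(seq_len(spec$n_folds), length.out = nrow(mc)))
    cvp <- glmnet::cv.glmnet(mc, train[[xname]], family = "binomial",
                             alpha = spec$alpha, foldid = foldid, standardize = FALSE)
    cfp <- stats::coef(cvp, s = if (cv_rule == "min") "lambda.min" else "lambda.1se")
    prop_terms <- rownames(cfp)[-1][as.numeric(cfp[-1]) != 0]
  } else if (length(conf) == 1L) {
    prop_terms <- conf # nothing to select among
  }
  terms <- union(outcome_terms, prop_terms)
  if (length(terms) == 0L) {
    warning("post-double selection returned an empty union; falling back to confounder mains")
    terms <- conf
  }
  keep <- c(xname, intersect(design$provenance$column, terms))
  m <- design$x[, keep, drop = FALSE]
  refit <- unpenalized_fit(m, y, spec$family, rep(1, length(y)))
  beta_full <- setNames(rep(0, ncol(design$x)), colnames(design$x))
  beta_full[names(refit$beta)] <- refit$beta
  refit_fit <- structure(
    list(intercept = unname(refit$intercept), beta = beta_full, lambda = 0,
         alpha = spec$alpha, family = spec$family,
         active = names(refit$beta)[refit$beta != 0],
         provenance = design$provenance, binary = design$binary,
         center = design$center, scale = design$scale,
         treatment = xname, cv = NULL),
    class = "hte_fit"
  )
  list(terms = terms, outcome_terms = outcome_terms,
       propensity_terms = prop_terms, refit = refit_fit)
}

#' Stabilized inverse-probability-of-treatment weights
#'
#' Fits a logistic propensity model on confounder main effects and returns
#' stabilized weights `P(X = x) / P(X = x | C)`, truncated at the requested
#' percentiles (1st/99th by default). The mean of stabilized weights should
#' sit near 1; a mean outside 0.9-1.1 triggers a positivity warning. Weighted
#' and unweighted standardized mean differences are returned as balance
#' diagnostics.
#'
#' @param table a [cohort_table()].
#' @param confounders confounder column names.
#' @param truncation length-2 percentile pair in `[0, 1]`, or `NULL` for no
#'   truncation.
#' @return An object of class `hte_weights`: `weights`, `ps` (propensity
#'   scores), `bounds`, and `balance` (SMD table).
#' @export
fit_iptw <- function(table, confounders, truncation = c(0.01, 0.99)) {
  stopifnot(inherits(table, "cohort_table"))
  xname <- attr(table, "treatment")
  x <- table[[xname]]
  if (length(unique(x)) < 2L) stop("both treatment arms must be present")
  df <- as.data.frame(table)[confounders]
  if (!all(vapply(df, is.numeric, TRUE))) stop("confounder columns must be numeric")
  fml <- stats::as.formula(paste("x ~", paste(sprintf("`%s`", confounders), collapse = " + ")))
  fit <- withCallingHandlers(
    stats::glm(fml, data = cbind(x = x, df), family = stats::binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w))) {
        stop("perfect separation in the propensity model", call. = FALSE)
      }
      invokeRestart("muffleWarning")
    }
  )
  ps <- stats::fitted(fit)
  eps <- 1e-10
  if (any(ps <= eps | ps >= 1 - eps)) stop("estimated propensity of 0 or 1 (positivity violation)")
  px <- mean(x)
  w <- ifelse(x == 1, px / ps, (1 - px) / (1 - ps))
  bounds <- c(-Inf, Inf)
  if (!is.null(truncation)) {
    stopifnot(length(truncation) == 2L, truncation[1] < truncation[2])
    bounds <- stats::quantile(w, truncation)
    w <- pmin(pmax(w, bounds[1]), bounds[2])
  }
  mw <- mean(w)
  if (mw < 0.9 || mw > 1.1) {
    warning(sprintf("mean stabilized weight %.3f outside [0.9, 1.1]; check positivity", mw))
  }
  smd <- function(v, wt) {
    m1 <- stats::weighted.mean(v[x == 1], wt[x == 1])
    m0 <- stats::weighted.mean(v[x == 0], wt[x == 0])
    v1 <- stats::weighted.mean((v[x == 1] - m1)^2, wt[x == 1])
    v0 <- stats::weighted.mean((v[x == 0] - m0)^2, wt[x == 0])
    (m1 - m0) / sqrt((v1 + v0) / 2)
  }
  balance <- data.frame(
    confounder = confounders,
    smd_unweighted = vapply(confounders, function(v) smd(df[[v]], rep(1, length(x))), 0),
    smd_weighted = vapply(confounders, function(v) smd(df[[v]], w), 0),
    row.names = NULL
  )
  structure(
    list(weights = w, ps = ps, bounds = bounds, balance = balance,
         treated_prob = px),
    class = "hte_weights"
  )
}
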