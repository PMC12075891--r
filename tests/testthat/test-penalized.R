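test_that("penalized loss reproduces its closed forms", {
  set.seed(1)
  tab <- toy_cohort(n = 25, seed = 5)
  d <- standardize_design(build_design(tab, variable_roles(c("C1", "C2"), "C1")))
  y <- tab$event
  beta <- rnorm(ncol(d$x))
  # lambda = 0: exactly the residual sum of squares
  rss <- sum((y - drop(d$x %*% beta))^2)
  expect_equal(penalty_loss(y, d, beta, lambda = 0), rss, tolerance = 1e-10)
  # alpha = 1: RSS + lambda * sum|beta| (plain LASSO loss)
  expect_equal(penalty_loss(y, d, beta, lambda = 3, alpha = 1),
               rss + 3 * sum(abs(beta)))
  # hand arithmetic on the penalty term
  m2 <- matrix(0, 2, 2, dimnames = list(NULL, c("a", "b")))
  expect_equal(penalty_loss(c(0, 0), m2, c(1, -2), lambda = 3, alpha = 1), 9)
  expect_equal(penalty_loss(c(0, 0), m2, c(0, 0), lambda = 7, alpha = 0.3), 0)
  # elastic-net mixing: alpha -> 0 approaches the ridge loss
  ridge <- rss + 3 * sum(beta^2) / 2
  expect_equal(penalty_loss(y, d, beta, lambda = 3, alpha = 1e-6), ridge,
               tolerance = 1e-4)
  expect_error(penalty_loss(y, d, beta, lambda = -1), "lambda")
  expect_error(penalty_loss(y, d, beta, lambda = 1, alpha = 2), "alpha")
})

test_that("lambda = 0 reproduces the unpenalized fit; huge lambda zeroes terms", {
  tab <- toy_cohort(n = 200, seed = 7)
  roles <- variable_roles(c("C1", "C2"), "C1")
  d <- standardize_design(build_design(tab, roles))
  y <- tab$event
  f0 <- fit_penalized(d, y, penalty_spec(lambda = 0))
  ref <- lm(y ~ d$x)
  expect_equal(unname(f0$beta), unname(coef(ref)[-1]), tolerance = 1e-6)
  expect_equal(f0$intercept, unname(coef(ref)[1]), tolerance = 1e-6)
  # binomial at lambda = 0 equals glm
  tabb <- toy_cohort(n = 300, seed = 8, binary_y = TRUE)
  db <- standardize_design(build_design(tabb, roles))
  fb <- fit_penalized(db, tabb$event, penalty_spec("binomial", lambda = 0))
  refb <- glm(tabb$event ~ db$x, family = binomial())
  expect_equal(unname(fb$beta), unname(coef(refb)[-1]), tolerance = 1e-6)
  # very large lambda: every penalized coefficient exactly 0 and the fit
  # collapses onto the unpenalized treatment-only regression
  fbig <- fit_penalized(d, y, penalty_spec(lambda = 1e6))
  pen <- d$provenance$kind != "treatment-main"
  expect_true(all(fbig$beta[pen] == 0))
  ref_x <- lm(y ~ d$x[, "treat"])
  expect_equal(fbig$intercept, unname(coef(ref_x)[1]), tolerance = 1e-3)
  expect_equal(unname(fbig$beta["treat"]), unname(coef(ref_x)[2]), tolerance = 1e-3)
})

test_that("cross-validation is deterministic given the fold seed", {
  tab <- toy_cohort(n = 400, seed = 9, beta_xc = 0.4)
  d <- standardize_design(build_design(tab, variable_roles(c("C1", "C2"), c("C1", "C2"))))
  f1 <- fit_penalized(d, tab$event, penalty_spec(fold_seed = 42))
  f2 <- fit_penalized(d, tab$event, penalty_spec(fold_seed = 42))
  expect_identical(f1$lambda, f2$lambda)
  expect_identical(f1$cv$lambda, f2$cv$lambda)
  expect_identical(f1$beta, f2$beta)
})

test_that("pure-noise treatment interactions are zeroed; strong signals recovered", {
  zeroed <- 0
  for (s in 1:10) {
    set.seed(s)
    n <- 2000
    C <- matrix(rnorm(n * 4), n, dimnames = list(NULL, paste0("C", 1:4)))
    X <- rbinom(n, 1, 0.4)
    y <- 0.5 + 0.3 * C[, 1] - 0.2 * C[, 2] + rnorm(n)
    tab <- cohort_table(cbind(data.frame(id = 1:n, treat = X, event = y),
                              as.data.frame(C)),
                        "treat", "event", "id")
    d <- standardize_design(build_design(tab, variable_roles(colnames(C), colnames(C))))
    f <- fit_penalized(d, y, penalty_spec(fold_seed = s), cv_rule = "1se")
    inter <- f$beta[d$provenance$kind == "treatment:term"]
    if (all(inter == 0)) zeroed <- zeroed + 1
  }
  expect_gte(zeroed, 9) # >= 90% of seeds
  ok <- 0
  for (s in 1:10) {
    set.seed(100 + s)
    n <- 2000
    C1 <- rnorm(n); X <- rbinom(n, 1, 0.5)
    y <- 1 + 2 * C1 + rnorm(n)
    tab <- cohort_table(data.frame(id = 1:n, treat = X, event = y, C1 = C1),
                        "treat", "event", "id")
    d <- standardize_design(build_design(tab, variable_roles("C1", "C1")))
    f <- fit_penalized(d, y, penalty_spec(fold_seed = s))
    b_raw <- unname(f$beta["C1"] / d$scale["C1"]) # back on the raw scale
    if (abs(b_raw - 2) < 0.2) ok <- ok + 1
  }
  expect_equal(ok, 10)
})

test_that("post-double selection keeps instruments-for-treatment, drops noise", {
  excl <- 0; inst <- 0; sel_sets <- list()
  for (s in 1:8) {
    set.seed(200 + s)
    n <- 5000
    C1 <- rnorm(n); C2 <- rnorm(n); Znoise <- rnorm(n); Zinst <- rnorm(n)
    X <- rbinom(n, 1, plogis(-0.5 + 0.5 * C1 + 0.8 * Zinst))
    y <- 0.2 + 0.3 * X + 0.4 * C1 + 0.3 * C2 + rnorm(n)
    tab <- cohort_table(
      data.frame(id = 1:n, treat = X, event = y, C1 = C1, C2 = C2,
                 Znoise = Znoise, Zinst = Zinst),
      "treat", "event", "id")
    roles <- variable_roles(c("C1", "C2", "Znoise", "Zinst"), c("C1", "C2"))
    ps <- suppressWarnings(post_double_select(tab, roles, penalty_spec(fold_seed = s)))
    if (!"Znoise" %in% ps$terms) excl <- excl + 1
    if ("Zinst" %in% ps$propensity_terms) inst <- inst + 1
    sel_sets[[s]] <- ps
  }
  expect_gte(excl, 7)
  expect_gte(inst, 7)
  # union idempotence: when both branches select the same set, union = that set
  ps <- sel_sets[[1]]
  expect_setequal(union(ps$outcome_terms, ps$propensity_terms), ps$terms)
  # the refit is an unpenalized model over the union plus the forced treatment
  expect_equal(ps$refit$lambda, 0)
  expect_true("treat" %in% c(names(ps$refit$beta)[ps$refit$beta != 0], "treat"))
})

test_that("stabilized IPT weights: no-confounding limit, balance, separation", {
  # randomized treatment: weights ~ 1
  set.seed(31)
  n <- 5000
  tab <- cohort_table(
    data.frame(id = 1:n, treat = rbinom(n, 1, 0.4), event = rnorm(n),
               C1 = rnorm(n), C2 = rnorm(n)),
    "treat", "event", "id")
  w <- fit_iptw(tab, c("C1", "C2"))
  expect_lt(max(abs(w$weights - 1)), 0.15)
  expect_equal(mean(w$weights), 1, tolerance = 0.05)
  # confounded generator: weighting brings SMDs under 0.1
  coh <- simulate_cohort(sim_config(n = 10000, seed = 5))
  wc <- fit_iptw(coh, c("age", "sbp", "sex"))
  expect_true(any(abs(wc$balance$smd_unweighted) > 0.15)) # confounding present
  expect_true(all(abs(wc$balance$smd_weighted) < 0.1))    # and removed
  expect_equal(mean(wc$weights), 1, tolerance = 0.1)
  # perfect separation errors out
  sep <- data.frame(id = 1:40, treat = rep(c(0, 1), each = 20),
                    event = rnorm(40), C1 = rep(c(-2, 2), each = 20))
  expect_error(fit_iptw(cohort_table(sep, "treat", "event", "id"), "C1"),
               "separation|propensity of 0 or 1")
})
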