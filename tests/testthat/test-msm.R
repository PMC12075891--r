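# deterministic 4-cell cohort with chosen risks per (X, G) cell
cell_cohort <- function(n_cell = 50, risks = c(p00 = 0.2, p10 = 0.4, p01 = 0.1, p11 = 0.3),
                        gname = "grp") {
  mk <- function(x, g, p) {
    k <- round(p * n_cell)
    data.frame(treat = x, grp = g, event = rep(c(1, 0), c(k, n_cell - k)))
  }
  df <- rbind(mk(0, 0, risks["p00"]), mk(1, 0, risks["p10"]),
              mk(0, 1, risks["p01"]), mk(1, 1, risks["p11"]))
  df$id <- seq_len(nrow(df))
  cohort_table(df, "treat", "event", "id")
}

test_that("binarize_modifier: boundary convention, passthrough, range errors", {
  tab <- cohort_table(
    data.frame(id = 1:3, treat = c(0, 1, 1), event = c(0, 1, 0),
               egfr = c(60, 73, 80), bin = c(0, 1, 1)),
    "treat", "event", "id")
  g <- binarize_modifier(tab, "egfr", cutoff = 73)
  expect_equal(g$group, c(0L, 1L, 1L)) # >= cutoff goes to the upper group
  expect_match(g$labels[1], "egfr < 73")
  expect_match(g$labels[2], "egfr >= 73")
  gb <- binarize_modifier(tab, "bin")
  expect_equal(gb$group, c(0L, 1L, 1L))
  expect_equal(gb$type, "binary")
  expect_error(binarize_modifier(tab, "egfr", cutoff = 99), "empty subgroup")
  expect_error(binarize_modifier(tab, "egfr"), "cutoff is required")
})

test_that("saturated MSM with unit weights equals crude stratified contrasts", {
  tab <- cell_cohort(50, c(p00 = 0.20, p10 = 0.40, p01 = 0.10, p11 = 0.30))
  msm <- fit_msm(tab, tab$grp, weights = rep(1, nrow(tab)), estimator = "iptw")
  est <- subgroup_contrasts(msm)
  # G = 0 stratum: 0.40 - 0.20; G = 1 stratum: 0.30 - 0.10 (exact)
  expect_equal(est$rd[est$label == "G = 0"], 0.20, tolerance = 1e-12)
  expect_equal(est$rd[est$label == "G = 1"], 0.20, tolerance = 1e-12)
  expect_equal(est$rr[est$label == "G = 0"], 2.0, tolerance = 1e-8)
  expect_equal(est$rr[est$label == "G = 1"], 3.0, tolerance = 1e-8)
  # overall row is the crude pooled contrast
  expect_equal(est$rd[est$label == "Overall"], 0.35 - 0.15, tolerance = 1e-12)
  # proportions over the modifier's levels sum to 100
  expect_equal(sum(est$prop[est$label != "Overall"]), 100)
  expect_equal(sum(est$n[est$label != "Overall"]), nrow(tab))
  # CI bounds bracket the point estimates; RD and RR agree in sign
  sub <- est[est$label != "Overall", ]
  expect_true(all(sub$rd_lo <= sub$rd & sub$rd <= sub$rd_hi))
  expect_true(all(sub$rr_lo <= sub$rr & sub$rr <= sub$rr_hi))
  expect_true(all(sign(est$rd) == sign(est$rr - 1)))
})

test_that("degenerate grouping falls back to the overall effect with warning", {
  tab <- cell_cohort(40)
  expect_warning(
    msm <- fit_msm(tab, rep(0L, nrow(tab)), weights = rep(1, nrow(tab))),
    "constant")
  est <- subgroup_contrasts(msm)
  expect_equal(nrow(est), 1L)
  expect_equal(est$label, "Overall")
  expect_error(p_interaction(msm), "non-estimable")
  # empty treatment-by-subgroup cell errors (positivity)
  bad <- as.data.frame(cell_cohort(30))
  bad <- bad[!(bad$treat == 1 & bad$grp == 1), ]
  tab_bad <- cohort_table(bad, "treat", "event", "id")
  expect_error(fit_msm(tab_bad, tab_bad$grp, weights = rep(1, nrow(tab_bad))),
               "positivity")
})

test_that("p-for-interaction: null uniformity and strong opposite-sign signal", {
  over <- 0
  for (s in 1:40) {
    set.seed(700 + s)
    n <- 400
    g <- rbinom(n, 1, 0.5); x <- rbinom(n, 1, 0.5)
    y <- rbinom(n, 1, 0.2 + 0.15 * x) # same effect in both subgroups
    tab <- cohort_table(data.frame(id = 1:n, treat = x, event = y, grp = g),
                        "treat", "event", "id")
    msm <- fit_msm(tab, tab$grp, weights = rep(1, n), estimator = "iptw")
    if (p_interaction(msm, "RD") > 0.05) over <- over + 1
  }
  expect_gte(over, 36) # > 0.05 in >= 90% of null seeds
  # opposite-sign subgroup effects: overwhelming evidence on both scales
  tab2 <- cell_cohort(600, c(p00 = 0.35, p10 = 0.15, p01 = 0.15, p11 = 0.35))
  msm2 <- fit_msm(tab2, tab2$grp, weights = rep(1, nrow(tab2)), estimator = "iptw")
  expect_lt(p_interaction(msm2, "RD"), 1e-3)
  expect_lt(p_interaction(msm2, "RR"), 1e-3)
})

test_that("sandwich agrees with classical SEs in the homoskedastic iid limit", {
  set.seed(21)
  n <- 4000
  x <- rbinom(n, 1, 0.5); g <- rbinom(n, 1, 0.5)
  y <- 0.3 + 0.2 * x + rnorm(n) # gaussian, homoskedastic, unweighted
  tab <- cohort_table(data.frame(id = 1:n, treat = x, event = y, grp = g),
                      "treat", "event", "id")
  msm <- fit_msm(tab, tab$grp, weights = rep(1, n), estimator = "iptw",
                 family = "gaussian")
  fit <- msm$fits$rd_overall
  se_rob <- sqrt(sandwich::vcovHC(fit, type = "HC0")[2, 2])
  se_cls <- summary(fit)$coefficients[2, 2]
  expect_lt(abs(se_rob - se_cls) / se_cls, 0.1)
})

test_that("gcomp estimator: bootstrap determinism and agreement with iptw", {
  set.seed(22)
  n <- 1500
  c1 <- rnorm(n)
  x <- rbinom(n, 1, plogis(0.4 * c1 - 0.6))
  g <- rbinom(n, 1, 0.5)
  p <- plogis(-1 + 0.5 * c1 + (0.8 - 1.6 * g) * x)
  y <- rbinom(n, 1, p)
  tab <- cohort_table(data.frame(id = 1:n, treat = x, event = y, grp = g, C1 = c1),
                      "treat", "event", "id")
  msm_g <- fit_msm(tab, tab$grp, estimator = "gcomp", confounders = "C1")
  e1 <- subgroup_contrasts(msm_g, B = 150, seed = 9)
  e2 <- subgroup_contrasts(msm_g, B = 150, seed = 9)
  expect_identical(e1$rd_lo, e2$rd_lo)
  expect_identical(e1$rr_hi, e2$rr_hi)
  expect_false(identical(e1$rd_lo, subgroup_contrasts(msm_g, B = 150, seed = 10)$rd_lo))
  expect_error(subgroup_contrasts(msm_g, B = 50), "B >= 100")
  # iptw route on the same data lands near the gcomp point estimates
  w <- fit_iptw(tab, "C1")
  msm_w <- fit_msm(tab, tab$grp, weights = w, estimator = "iptw")
  e_w <- subgroup_contrasts(msm_w)
  expect_equal(e_w$rd, e1$rd, tolerance = 0.06)
  expect_true(all(e1$rd_lo <= e1$rd & e1$rd <= e1$rd_hi))
})

test_that("within-subgroup ITE means aggregate exactly to the overall mean", {
  set.seed(23)
  cate <- compute_cate(runif(400), runif(400))
  grp <- rbinom(400, 1, 0.3)
  agg <- subgroup_cate_means(cate, grp)
  expect_equal(sum(agg$n * agg$mean_cate) / sum(agg$n), mean(cate$cate),
               tolerance = 1e-14)
})
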