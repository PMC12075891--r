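test_that("role validation catches structural problems and flags W not in C", {
  tab <- toy_cohort()
  expect_error(validate_roles(tab, variable_roles("nope", "C1")), "unknown column")
  expect_error(validate_roles(tab, variable_roles(c("C1", "treat"), "C1")),
               "treatment/outcome listed as covariate")
  expect_error(validate_roles(tab, variable_roles("event", "C1")),
               "treatment/outcome")
  # W subset of C: unchanged, silent
  r <- variable_roles(c("C1", "C2"), "C1")
  expect_silent(out <- validate_roles(tab, r))
  expect_identical(out, r)
  # modifier outside C: informational warning naming the column
  expect_warning(validate_roles(tab, variable_roles("C1", "C2")), "C2")
})

test_that("treatment column invariants are enforced at construction", {
  df <- data.frame(id = 1:4, treat = c(0, 1, 2, 1), event = rnorm(4), C1 = rnorm(4))
  expect_error(cohort_table(df, "treat", "event", "id"), "0/1")
  df$treat <- 1
  expect_error(cohort_table(df, "treat", "event", "id"), "empty treatment arm")
  df$treat <- c(0, 1, 0, 1); df$id <- c(1, 1, 2, 3)
  expect_error(cohort_table(df, "treat", "event", "id"), "duplicated ids")
  df$id <- 1:4; df$C1[2] <- NA
  expect_error(cohort_table(df, "treat", "event", "id"), "missing values")
})

test_that("split_sample sizes, disjointness and determinism", {
  tab <- toy_cohort(n = 10, seed = 3)
  sp <- split_sample(tab, 0.7, seed = 11)
  expect_equal(nrow(sp$train), 7)
  expect_equal(nrow(sp$test), 3)
  expect_length(intersect(cohort_ids(sp$train), cohort_ids(sp$test)), 0)
  expect_setequal(c(cohort_ids(sp$train), cohort_ids(sp$test)), cohort_ids(tab))
  sp2 <- split_sample(tab, 0.7, seed = 11)
  expect_identical(cohort_ids(sp$train), cohort_ids(sp2$train))
  sp3 <- split_sample(tab, 0.7, seed = 12)
  expect_false(identical(cohort_ids(sp$train), cohort_ids(sp3$train)))
  # large-n arithmetic: round(0.7 * 10000) = 7000
  big <- simulate_cohort(sim_config(n = 10000, seed = 1))
  expect_equal(nrow(split_sample(big, 0.7, seed = 1)$train), 7000)
  # both arms survive in both splits
  for (s in 1:5) {
    spb <- split_sample(tab, 0.5, seed = s)
    expect_length(unique(spb$train$treat), 2)
    expect_length(unique(spb$test$treat), 2)
  }
})

test_that("design columns match the enumeration oracle and the 2p+1 identity", {
  set.seed(42)
  n <- 30
  for (p in 1:6) {
    covs <- paste0("V", seq_len(p))
    df <- cbind(data.frame(id = 1:n, treat = rep_len(c(0, 1), n), event = rnorm(n)),
                as.data.frame(setNames(replicate(p, rnorm(n), simplify = FALSE), covs)))
    tab <- cohort_table(df, "treat", "event", "id")
    roles <- variable_roles(covs, covs)
    d <- build_design(tab, roles, design_spec(interaction_order = 1))
    expect_identical(colnames(d$x), enumerate_design_columns(covs))
    expect_equal(ncol(d$x), 2 * p + 1)
    expect_equal(sum(d$provenance$kind == "treatment-main"), 1)
    expect_false(anyDuplicated(d$provenance$column) > 0)
  }
  # order-2 with covariate products: the 7-column case
  df <- data.frame(id = 1:n, treat = rep_len(c(0, 1), n), event = rnorm(n),
                   C1 = rnorm(n), C2 = rnorm(n))
  tab <- cohort_table(df, "treat", "event", "id")
  d2 <- build_design(tab, variable_roles(c("C1", "C2"), c("C1", "C2")),
                     design_spec(interaction_order = 2,
                                 include_covariate_covariate = TRUE))
  expect_identical(colnames(d2$x),
                   c("treat", "C1", "C2", "C1:C2", "treat:C1", "treat:C2",
                     "treat:C1:C2"))
  expect_equal(d2$x[, "C1:C2"], d2$x[, "C1"] * d2$x[, "C2"])
  expect_equal(d2$x[, "treat:C1:C2"], d2$x[, "treat"] * d2$x[, "C1"] * d2$x[, "C2"])
  expect_error(build_design(tab, variable_roles(c("C1", "C2"), NULL),
                            design_spec(interaction_order = 3,
                                        include_covariate_covariate = TRUE)),
               "interaction_order")
})

test_that("standardization: hand arithmetic, errors, round trip, reference", {
  df <- data.frame(id = 1:3, treat = c(0, 1, 0), event = c(0, 1, 1),
                   C1 = c(1, 2, 3), C2 = c(1, 1, 1))
  tab <- cohort_table(df, "treat", "event", "id")
  d <- build_design(tab, variable_roles("C1", NULL))
  s <- standardize_design(d)
  expect_equal(unname(s$x[, "C1"]), c(-1, 0, 1))           # center 2, SD 1
  expect_equal(unname(s$x[, "treat"]), c(0, 1, 0))         # treatment untouched
  # constant continuous column errors
  d_const <- build_design(tab, variable_roles("C2", NULL))
  d_const$binary["C2"] <- FALSE # force it to be treated as continuous
  expect_error(standardize_design(d_const), "zero-variance")
  # binary columns are not rescaled
  d_bin <- standardize_design(build_design(tab, variable_roles(c("C1", "C2"), NULL)))
  expect_equal(unname(d_bin$x[, "C2"]), c(1, 1, 1))
  # round trip and idempotence
  rt <- destandardize_design(s)
  expect_equal(rt$x, d$x, tolerance = 1e-10)
  s2 <- standardize_design(structure(modifyList(s, list(standardized = FALSE)),
                                     class = "hte_design"))
  expect_equal(s2$x, s$x, tolerance = 1e-12)
  # reference application: test scaled with train parameters, never its own
  df_test <- df; df_test$C1 <- c(10, 20, 30)
  tab_test <- cohort_table(df_test, "treat", "event", "id")
  d_test <- build_design(tab_test, variable_roles("C1", NULL))
  s_test <- standardize_design(d_test, reference = s)
  expect_equal(unname(s_test$x[, "C1"]), (c(10, 20, 30) - 2) / 1)
  back <- destandardize_design(s_test)
  expect_equal(unname(back$x[, "C1"]), c(10, 20, 30), tolerance = 1e-10)
})
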