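# Small cohorts and independent oracles used across the test files.

# deterministic toy cohort with one binary + one continuous covariate
toy_cohort <- function(n = 40, seed = 1, beta_x = 0.3, beta_c = 0.5,
                       beta_xc = 0, binary_y = FALSE) {
  set.seed(seed)
  C1 <- rnorm(n)
  C2 <- rbinom(n, 1, 0.5)
  X <- rbinom(n, 1, 0.5)
  while (length(unique(X)) < 2) X <- rbinom(n, 1, 0.5)
  eta <- 0.1 + beta_x * X + beta_c * C1 + beta_xc * X * C1
  y <- if (binary_y) rbinom(n, 1, plogis(eta)) else eta + rnorm(n, 0, 0.5)
  cohort_table(
    data.frame(id = seq_len(n), treat = X, event = y, C1 = C1, C2 = C2),
    treatment = "treat", outcome = "event", id = "id"
  )
}

# exhaustive enumeration oracle for the saturated design column set
enumerate_design_columns <- function(covs, order = 1, cc = FALSE, xname = "treat") {
  prods <- character()
  if (order >= 2) {
    for (o in 2:order) {
      prods <- c(prods, combn(sort(covs), o, paste, collapse = ":"))
    }
    prods <- sort(prods)
  }
  c(xname, covs, if (cc) prods,
    paste(xname, covs, sep = ":"), if (length(prods)) paste(xname, prods, sep = ":"))
}

# greedy brute-force Ward oracle: at every step merge the pair of current
# clusters whose fusion minimally increases total within-cluster SS; returns
# the partition (list of index sets) after each merge.
ward_oracle_partitions <- function(x) {
  clusters <- as.list(seq_along(x))
  wss <- function(idx) sum((x[idx] - mean(x[idx]))^2)
  out <- list()
  while (length(clusters) > 1) {
    best <- NULL
    best_inc <- Inf
    for (i in seq_along(clusters)) {
      for (j in seq_len(i - 1)) {
        inc <- wss(c(clusters[[i]], clusters[[j]])) -
          wss(clusters[[i]]) - wss(clusters[[j]])
        if (inc < best_inc) { best_inc <- inc; best <- c(j, i) }
      }
    }
    merged <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters <- c(clusters[-best], list(merged))
    out[[length(out) + 1]] <- clusters
  }
  out
}

# canonical form of a partition: sorted list of sorted index sets
canonical_partition <- function(parts) {
  parts <- lapply(parts, sort)
  parts[order(vapply(parts, min, 0))]
}

partition_from_labels <- function(labels) {
  canonical_partition(unname(split(seq_along(labels), labels)))
}
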