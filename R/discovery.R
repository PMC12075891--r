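#' Jitter a CATE vector
#'
#' Ward (and k-means) clustering needs more distinct values than clusters;
#' fitted CATEs from a sparse linear model can collapse onto a few values.
#' Adding a whisker of seeded Gaussian noise ("jittering") restores distinct
#' values. The jittered copy is used only to build the tree and select the
#' number of clusters; every reported quantity (cluster means, z-scores,
#' cut-offs) is computed on the untouched original.
#'
#' @param cate an `hte_cate` or numeric vector.
#' @param relative_sd noise SD as a fraction of `sd(cate)` (default 1e-3).
#' @param seed integer seed.
#' @return Numeric vector `cate + noise`.
#' @export
jitter_cates <- function(cate, relative_sd = 1e-3, seed = 1L) {
  x <- if (inherits(cate, "hte_cate")) cate$cate else as.numeric(cate)
  if (relative_sd <= 0) stop("relative_sd must be > 0")
  s <- stats::sd(x) * relative_sd
  # noise below double resolution cannot create distinct values; fall back to
  # an absolute floor for (near-)degenerate CATE vectors
  if (!is.finite(s) || s < 1e-8) {
    warning("SD of CATE is (near) 0; using absolute jitter floor 1e-8")
    s <- 1e-8
  }
  old <- .Random.seed_safe(); on.exit(.restore_seed(old), add = TRUE)
  set.seed(as.integer(seed))
  x + stats::rnorm(length(x), 0, s)
}

ward_tree <- function(x) stats::hclust(stats::dist(x), method = "ward.D2")

within_ss <- function(x, labels) {
  sum(tapply(x, labels, function(v) sum((v - mean(v))^2)))
}

# Beale's pseudo-F for comparing k vs k+1 Ward solutions (p = dimension, 1 here)
beale_f <- function(w_k, w_k1, n, k, p = 1) {
  ((w_k - w_k1) / w_k1) / (((n - k) / (n - k - 1)) * 2^(2 / p) - 1)
}

#' Select the number of clusters by the Beale index
#'
#' Walks k = 1, 2, ... over Ward solutions and computes Beale's pseudo-F for
#' the improvement from k to k+1 clusters,
#' `F = ((W_k - W_k+1) / W_k+1) / (((n-k)/(n-k-1)) * 2^(2/p) - 1)` with
#' p = 1. The first k whose improvement is not significant is returned
#' (typically 2 for a genuinely bimodal effect distribution, 1 under
#' homogeneity).
#'
#' Two decision rules are offered. `method = "mc"` (default) calibrates the
#' cut against a parametric-bootstrap null: data are simulated from the
#' Gaussian mixture implied by the current k-cluster solution, the same
#' statistic is recomputed, and the observed F must exceed its (1 - alpha)
#' null quantile. This is used because in one dimension the classical F
#' reference is a poor approximation for Ward within-SS ratios: even an
#' unambiguous two-component mixture can fail the nominal F cut, while a pure
#' Gaussian sits far below it. `method = "ftest"` applies the classical cut
#' `qf(1 - alpha, p, n - k - 1)` instead.
#'
#' @param jittered jittered CATE vector (see [jitter_cates()]).
#' @param k_max maximum number of clusters to consider (default 5).
#' @param alpha significance level (default 0.05).
#' @param method `"mc"` (Monte-Carlo calibrated, default) or `"ftest"`.
#' @param B null replicates for `"mc"` (default 40).
#' @param mc_size subsample cap for the null replicates (default 800); keeps
#'   the O(n^2) null clustering affordable without touching the observed
#'   statistic.
#' @param seed integer seed for the null replicates.
#' @return Integer k with attribute `"trace"`, a data.frame of the statistic
#'   per step.
#' @export
select_k_beale <- function(jittered, k_max = 5L, alpha = 0.05,
                           method = c("mc", "ftest"), B = 40L, mc_size = 800L,
                           seed = 1L) {
  method <- match.arg(method)
  x <- as.numeric(jittered)
  n <- length(x)
  if (k_max < 2L) stop("k_max must be >= 2")
  if (k_max >= n) stop("k_max must be smaller than the number of observations")
  if (length(unique(x)) < k_max + 1L) {
    stop("need more than k_max distinct values; jitter the CATEs first")
  }
  tree <- ward_tree(x)
  wss <- vapply(seq_len(k_max), function(k) within_ss(x, stats::cutree(tree, k)), 0)
  old <- .Random.seed_safe(); on.exit(.restore_seed(old), add = TRUE)
  set.seed(as.integer(seed))
  trace <- data.frame(k = seq_len(k_max - 1L), F = NA_real_, threshold = NA_real_,
                      significant = NA)
  k_hat <- k_max
  for (k in seq_len(k_max - 1L)) {
    f_obs <- beale_f(wss[k], wss[k + 1L], n, k)
    thr <- if (method == "ftest") {
      stats::qf(1 - alpha, 1, n - k - 1)
    } else {
      labels <- stats::cutree(tree, k)
      mu <- tapply(x, labels, mean)
      sdv <- tapply(x, labels, stats::sd)
      sdv[!is.finite(sdv) | sdv == 0] <- 1e-8
      pr <- tabulate(labels, k) / n
      m <- min(n, mc_size)
      f_null <- vapply(seq_len(B), function(b) {
        cl <- sample.int(k, m, replace = TRUE, prob = pr)
        xs <- stats::rnorm(m, mu[cl], sdv[cl])
        t2 <- ward_tree(xs)
        beale_f(within_ss(xs, stats::cutree(t2, k)),
                within_ss(xs, stats::cutree(t2, k + 1L)), m, k)
      }, 0)
      stats::quantile(f_null, 1 - alpha, names = FALSE)
    }
    sig <- f_obs > thr
    trace$F[k] <- f_obs; trace$threshold[k] <- thr; trace$significant[k] <- sig
    if (!sig) { k_hat <- k; break }
  }
  structure(as.integer(k_hat), trace = trace)
}

#' Ward clustering of the CATE distribution
#'
#' Agglomerative clustering in which each merge minimizes the increase in
#' total within-cluster sum of squares (Ward's minimum-variance criterion).
#' Labels are canonicalized so cluster 1 has the smallest mean CATE. All
#' reported means are computed on the un-jittered values and on the raw
#' candidate-modifier columns; the jittered vector only shapes the tree.
#'
#' @param jittered jittered CATE vector used to build the tree.
#' @param k number of clusters (`>= 1`).
#' @param values un-jittered CATE values (defaults to `jittered`).
#' @param modifiers optional data.frame of candidate-modifier values aligned
#'   with the CATEs.
#' @return An object of class `hte_clusters`: `k`, canonical `labels`,
#'   `sizes`, `cate_means`, `modifier_means` (k x modifiers matrix), `wss`.
#' @export
ward_cluster <- function(jittered, k, values = jittered, modifiers = NULL) {
  x <- as.numeric(jittered)
  n <- length(x)
  if (k < 1L) stop("k must be >= 1")
  if (k > n) stop("k exceeds the number of observations")
  if (k > length(unique(x))) stop("k exceeds the number of distinct values")
  if (k == 1L) {
    labels <- rep(1L, n)
  } else {
    labels <- stats::cutree(ward_tree(x), k)
  }
  means <- tapply(as.numeric(values), labels, mean)
  ord <- order(means) # canonical: cluster 1 = smallest mean CATE
  relabel <- match(labels, ord)
  cate_means <- as.numeric(means[ord])
  sizes <- tabulate(relabel, k)
  modifier_means <- NULL
  if (!is.null(modifiers)) {
    modifier_means <- sapply(as.data.frame(modifiers), function(v) {
      tapply(as.numeric(v), relabel, mean)
    })
    modifier_means <- matrix(modifier_means, nrow = k,
                             dimnames = list(NULL, names(as.data.frame(modifiers))))
  }
  structure(
    list(k = as.integer(k), labels = relabel, sizes = sizes,
         cate_means = cate_means, modifier_means = modifier_means,
         wss = within_ss(as.numeric(values), relabel)),
    class = "hte_clusters"
  )
}

#' Cluster z-score variable importance
#'
#' For each candidate modifier m and cluster g the z-score is
#' `(mean of m in g - overall mean of m) / overall SD of m`; binary modifiers
#' use the same formula with proportions (no special-casing). The importance
#' of a modifier is the absolute difference of its z-scores across the two
#' clusters (maximum pairwise difference when k > 2), and modifiers whose
#' importance reaches `threshold` (default 0.2) are flagged as effect
#' modifiers. For a selected continuous modifier the binarization cut-off is
#' the average of its means in the two (extreme, if k > 2) clusters.
#'
#' @param solution an `hte_clusters` with `k >= 2`.
#' @param modifiers data.frame of candidate-modifier values aligned with the
#'   clustered individuals.
#' @param threshold importance threshold (default 0.2).
#' @return An object of class `importance_table`: data.frame with one row per
#'   modifier (`z_1..z_k`, `importance`, `selected`, `type`, `cutoff`),
#'   attribute `threshold`.
#' @export
importance_table <- function(solution, modifiers, threshold = 0.2) {
  stopifnot(inherits(solution, "hte_clusters"))
  if (solution$k < 2L) stop("importance requires at least 2 clusters")
  modifiers <- as.data.frame(modifiers)
  labels <- solution$labels
  rows <- lapply(names(modifiers), function(nm) {
    v <- as.numeric(modifiers[[nm]])
    s <- stats::sd(v)
    cm <- tapply(v, labels, mean)
    if (!is.finite(s) || s == 0) {
      warning("modifier ", nm, " has zero overall SD; importance set to 0")
      z <- rep(0, solution$k)
    } else {
      z <- (cm - mean(v)) / s
    }
    imp <- max(stats::dist(z))
    type <- if (length(unique(v)) <= 2L) "binary" else "continuous"
    sel <- imp >= threshold
    cutoff <- NA_real_
    if (sel && type == "continuous") {
      # midpoint of the modifier means in the extreme-CATE clusters
      cutoff <- continuous_cutoff(cm[1], cm[solution$k])
    }
    c(setNames(as.list(z), paste0("z_", seq_len(solution$k))),
      list(importance = imp, selected = sel, type = type, cutoff = cutoff))
  })
  out <- do.call(rbind, lapply(rows, function(r) as.data.frame(r, stringsAsFactors = FALSE)))
  out <- cbind(modifier = names(modifiers), out)
  rownames(out) <- NULL
  structure(out, class = c("importance_table", "data.frame"), threshold = threshold)
}

#' Cut-off for binarizing a continuous effect modifier
#'
#' The average of the modifier's means across the two identified clusters:
#' individuals above it behave like the high cluster, below it like the low
#' cluster.
#'
#' @param cluster_mean_1,cluster_mean_2 the modifier's mean in each cluster.
#' @return `(cluster_mean_1 + cluster_mean_2) / 2`.
#' @export
continuous_cutoff <- function(cluster_mean_1, cluster_mean_2) {
  stopifnot(is.finite(cluster_mean_1), is.finite(cluster_mean_2))
  (cluster_mean_1 + cluster_mean_2) / 2
}

#' Discover effect modifiers from a CATE vector
#'
#' Convenience wrapper for the discovery step: jitter, select k by the Beale
#' rule, cluster with Ward's method, and score candidate modifiers. When a
#' single cluster is selected (no evidence of heterogeneity) no modifier is
#' flagged and the importance table reports zero importance throughout.
#'
#' @param cate an `hte_cate` carrying modifier columns, or a numeric vector
#'   with `modifiers` supplied.
#' @param modifiers data.frame of candidate-modifier values (defaults to the
#'   ones attached to `cate`).
#' @param threshold importance threshold (default 0.2).
#' @param relative_sd jitter magnitude (default 1e-3).
#' @param k_max,alpha,method,B,mc_size see [select_k_beale()].
#' @param seed integer seed (jitter and null replicates).
#' @return An object of class `hte_discovery`: `k`, `clusters`,
#'   `importance`, `selected` (modifier names), `k_trace`.
#' @export
discover_modifiers <- function(cate, modifiers = NULL, threshold = 0.2,
                               relative_sd = 1e-3, k_max = 5L, alpha = 0.05,
                               method = c("mc", "ftest"), B = 40L,
                               mc_size = 800L, seed = 1L) {
  method <- match.arg(method)
  if (is.null(modifiers) && inherits(cate, "hte_cate")) {
    modifiers <- attr(cate, "modifiers")
  }
  if (is.null(modifiers)) stop("modifier columns are required")
  x <- if (inherits(cate, "hte_cate")) cate$cate else as.numeric(cate)
  jit <- jitter_cates(x, relative_sd = relative_sd, seed = seed)
  k <- select_k_beale(jit, k_max = k_max, alpha = alpha, method = method,
                      B = B, mc_size = mc_size, seed = seed + 1L)
  clusters <- ward_cluster(jit, k, values = x, modifiers = modifiers)
  if (k >= 2L) {
    imp <- importance_table(clusters, modifiers, threshold = threshold)
  } else {
    modifiers <- as.data.frame(modifiers)
    imp <- data.frame(
      modifier = names(modifiers), z_1 = 0, importance = 0, selected = FALSE,
      type = vapply(modifiers, function(v) {
        if (length(unique(as.numeric(v))) <= 2L) "binary" else "continuous"
      }, ""),
      cutoff = NA_real_
    )
    imp <- structure(imp, class = c("importance_table", "data.frame"),
                     threshold = threshold)
  }
  structure(
    list(k = as.integer(k), clusters = clusters, importance = imp,
         selected = imp$modifier[imp$selected], k_trace = attr(k, "trace")),
    class = "hte_discovery"
  )
}
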