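#' Predict both potential outcomes by recycled predictions
#'
#' For every test-set individual, the fitted outcome model is evaluated twice:
#' once with the treatment column (and every treatment-interaction column) set
#' to 1 and once set to 0, holding all covariates fixed - the "recycled
#' predictions" device behind G-computation. The test design is rebuilt from
#' the cohort table and standardized with the training parameters carried
#' inside the model; test data never re-estimate scaling.
#'
#' @param model an `hte_fit` from [fit_penalized()].
#' @param test test-split [cohort_table()].
#' @param roles validated [variable_roles()].
#' @param spec the [design_spec()] used for the training design.
#' @return list with numeric vectors `y1` and `y0` (probabilities for the
#'   binomial family, means for gaussian) and `ids`.
#' @export
predict_potential_outcomes <- function(model, test, roles, spec = design_spec()) {
  stopifnot(inherits(model, "hte_fit"), inherits(test, "cohort_table"))
  predict_counterfactual <- function(xval) {
    t2 <- test
    t2[[model$treatment]] <- xval
    d <- build_design(t2, roles, spec)
    if (!identical(d$provenance$column, model$provenance$column)) {
      stop("test design columns misaligned with model coefficients")
    }
    ref <- structure(
      list(provenance = model$provenance, center = model$center,
           scale = model$scale, standardized = TRUE),
      class = "hte_design"
    )
    d <- standardize_design(d, reference = ref)
    eta <- model$intercept + drop(d$x %*% model$beta)
    if (model$family == "binomial") stats::plogis(eta) else eta
  }
  list(y1 = predict_counterfactual(1), y0 = predict_counterfactual(0),
       ids = cohort_ids(test))
}

#' Individual treatment-effect contrasts
#'
#' Elementwise contrast of the two potential-outcome predictions. On the RD
#' scale (binomial family) this is a per-individual risk difference; on the
#' MD scale (gaussian) a mean difference. The mean of the returned vector is,
#' by construction, the G-computation (standardization) estimate of the
#' average treatment effect on the test set.
#'
#' @param y1,y0 equal-length prediction vectors.
#' @param scale `"RD"` or `"MD"` (labelling only; the contrast is always the
#'   difference).
#' @param ids optional row identifiers.
#' @param modifiers optional data.frame of candidate-modifier values for the
#'   same individuals, carried along for the discovery step.
#' @return An object of class `hte_cate`: data.frame with columns `id`,
#'   `y1hat`, `y0hat`, `cate`, plus attributes `scale` and `modifiers`.
#' @export
compute_cate <- function(y1, y0, scale = c("RD", "MD"), ids = NULL, modifiers = NULL) {
  scale <- match.arg(scale)
  if (length(y1) != length(y0)) stop("prediction vectors have different lengths")
  if (is.null(ids)) ids <- seq_along(y1)
  out <- data.frame(id = ids, y1hat = y1, y0hat = y0, cate = y1 - y0)
  structure(out, class = c("hte_cate", "data.frame"), scale = scale,
            modifiers = modifiers)
}

#' Summarize the CATE distribution
#'
#' Returns the histogram, the rank-ordered CATE sequence (the "effect by rank
#' of effect" curve), and a descriptive bimodality diagnostic: the
#' valley-to-peak ratio of a kernel density estimate (depth of the valley
#' between the two tallest modes relative to the lower of the two peaks).
#' Ratios near 0 indicate well-separated modes; a degenerate (constant)
#' vector is flagged as such. The diagnostic is reported, never used to gate
#' the pipeline.
#'
#' @param cate an `hte_cate` (or numeric vector).
#' @param n_bins number of histogram bins.
#' @return list with `histogram` (counts, breaks, mids), `rank_cate`
#'   (non-decreasing), and `diagnostic` (`flag`, `n_modes`,
#'   `valley_peak_ratio`).
#' @export
summarize_cate_distribution <- function(cate, n_bins = 30L) {
  x <- if (inherits(cate, "hte_cate")) cate$cate else as.numeric(cate)
  if (length(x) == 0L) stop("empty CATE vector")
  if (stats::sd(x) == 0) {
    return(list(
      histogram = list(counts = length(x), breaks = c(x[1] - 0.5, x[1] + 0.5), mids = x[1]),
      rank_cate = sort(x),
      diagnostic = list(flag = "degenerate", n_modes = 1L, valley_peak_ratio = NA_real_)
    ))
  }
  h <- graphics::hist(x, breaks = n_bins, plot = FALSE)
  d <- stats::density(x)
  yd <- d$y
  is_peak <- which(diff(sign(diff(yd))) == -2) + 1L
  peaks <- is_peak[yd[is_peak] >= 0.05 * max(yd)]
  if (length(peaks) < 2L) {
    diag <- list(flag = "unimodal", n_modes = max(1L, length(peaks)),
                 valley_peak_ratio = NA_real_)
  } else {
    top2 <- peaks[order(yd[peaks], decreasing = TRUE)][1:2]
    lo <- min(top2); hi <- max(top2)
    valley <- min(yd[lo:hi])
    ratio <- valley / min(yd[top2])
    diag <- list(flag = if (ratio < 0.8) "bimodal" else "unimodal",
                 n_modes = length(peaks), valley_peak_ratio = ratio)
  }
  list(
    histogram = list(counts = h$counts, breaks = h$breaks, mids = h$mids),
    rank_cate = sort(x),
    diagnostic = diag
  )
}

#' Export individual contrasts as CSV
#'
#' @param cate an `hte_cate`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_cate_csv <- function(cate, path) {
  utils::write.csv(as.data.frame(cate), path, row.names = FALSE)
  invisible(path)
}
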