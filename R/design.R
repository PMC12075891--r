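#' Design-matrix specification
#'
#' Controls how the saturated outcome design is expanded. "Saturated" is
#' operationalised as all treatment-by-term interactions where the
#' non-treatment terms are the covariate main effects plus, optionally,
#' covariate products up to `interaction_order`. The default (order 1,
#' covariate products off) gives the treatment main effect, covariate mains
#' and one treatment interaction per covariate: full n-way saturation is
#' combinatorially explosive, and treatment-covariate interactions are what
#' the CATE step needs; deeper saturation stays available through the knob.
#'
#' @param interaction_order maximum order of covariate products whose
#'   interaction with the treatment is included; must be >= 1.
#' @param include_covariate_covariate also include covariate-by-covariate
#'   product columns (without treatment) up to `interaction_order`.
#' @param standardize standardize continuous columns by training mean/SD.
#' @param split_fraction training fraction used by the pipeline.
#' @param seed integer seed for the split.
#' @return An object of class `design_spec`.
#' @export
design_spec <- function(interaction_order = 1L, include_covariate_covariate = FALSE,
                        standardize = TRUE, split_fraction = 0.7, seed = 1L) {
  if (interaction_order < 1L) stop("interaction_order must be >= 1")
  if (!(split_fraction > 0 && split_fraction < 1)) stop("split_fraction must be in (0, 1)")
  structure(
    list(
      interaction_order = as.integer(interaction_order),
      include_covariate_covariate = isTRUE(include_covariate_covariate),
      standardize = isTRUE(standardize),
      split_fraction = split_fraction,
      seed = as.integer(seed)
    ),
    class = "design_spec"
  )
}

#' Build the saturated design matrix
#'
#' Expands a cohort table into the model matrix used by the penalized outcome
#' fit: one treatment-main column, covariate mains in declared order
#' (confounders first, then modifiers not already listed), covariate products
#' in lexicographic order of their constituents (if enabled), and finally the
#' treatment interacted with every non-treatment term, mirroring that order.
#' Column provenance (kind + constituent variables) is recorded so that
#' counterfactual designs and coefficient tables stay interpretable.
#'
#' @param table a [cohort_table()].
#' @param roles validated [variable_roles()].
#' @param spec a [design_spec()].
#' @return An object of class `hte_design`: list with the numeric matrix `x`,
#'   a `provenance` data.frame, binary-column flags and (once
#'   [standardize_design()] has run) per-column centering/scaling parameters.
#' @export
build_design <- function(table, roles, spec = design_spec()) {
  stopifnot(inherits(table, "cohort_table"))
  covs <- unique(c(roles$confounders, roles$candidate_modifiers))
  if (anyDuplicated(covs)) stop("duplicate covariate names")
  if (spec$include_covariate_covariate && spec$interaction_order > length(covs)) {
    stop("interaction_order exceeds the number of covariates")
  }
  xname <- attr(table, "treatment")
  X <- as.numeric(table[[xname]])
  cols <- list()
  prov <- list()
  add <- function(name, values, kind, vars) {
    cols[[name]] <<- values
    prov[[name]] <<- list(kind = kind, vars = vars)
  }
  add(xname, X, "treatment-main", xname)
  for (v in covs) add(v, as.numeric(table[[v]]), "covariate-main", v)
  prods <- list()
  if (spec$interaction_order >= 2L) {
    for (ord in 2:spec$interaction_order) {
      sets <- utils::combn(sort(covs), ord, simplify = FALSE)
      for (s in sets) prods[[paste(s, collapse = ":")]] <- s
    }
    prods <- prods[order(names(prods))]
  }
  if (spec$include_covariate_covariate) {
    for (nm in names(prods)) {
      s <- prods[[nm]]
      val <- Reduce(`*`, lapply(s, function(v) as.numeric(table[[v]])))
      add(nm, val, "covariate:covariate", s)
    }
  }
  # treatment interactions mirror the non-treatment terms: mains then products
  for (v in covs) add(paste(xname, v, sep = ":"), X * as.numeric(table[[v]]),
                      "treatment:term", c(xname, v))
  for (nm in names(prods)) {
    s <- prods[[nm]]
    val <- X * Reduce(`*`, lapply(s, function(v) as.numeric(table[[v]])))
    add(paste(xname, nm, sep = ":"), val, "treatment:term", c(xname, s))
  }
  m <- do.call(cbind, cols)
  colnames(m) <- names(cols)
  kinds <- vapply(prov, `[[`, "", "kind")
  binary <- apply(m, 2, function(v) length(unique(v)) <= 2L)
  structure(
    list(
      x = m,
      ids = cohort_ids(table),
      provenance = data.frame(
        column = names(cols), kind = kinds,
        vars = vapply(prov, function(p) paste(p$vars, collapse = "*"), ""),
        row.names = NULL
      ),
      binary = binary,
      treatment = xname,
      center = NULL, scale = NULL, standardized = FALSE
    ),
    class = "hte_design"
  )
}

#' Standardize a design matrix
#'
#' Centers and scales continuous columns by mean/SD. Binary columns (exactly
#' two distinct values) and the treatment-main column are left unscaled so
#' their coefficients - and the cluster-profile means computed later - remain
#' on their natural scale. When `reference` is supplied (a design standardized
#' on the training split), its parameters are applied verbatim; test data are
#' never used to estimate scaling.
#'
#' @param design an [build_design()] result.
#' @param reference optional standardized `hte_design` whose parameters are
#'   applied instead of being re-estimated. Column provenance must match.
#' @return The design with standardized `x` and recorded `center`/`scale`.
#' @export
standardize_design <- function(design, reference = NULL) {
  stopifnot(inherits(design, "hte_design"))
  m <- design$x
  if (is.null(reference)) {
    center <- setNames(numeric(ncol(m)), colnames(m))
    scale <- setNames(rep(1, ncol(m)), colnames(m))
    for (j in seq_len(ncol(m))) {
      nm <- colnames(m)[j]
      if (design$binary[j] || design$provenance$kind[j] == "treatment-main") next
      s <- stats::sd(m[, j])
      if (!is.finite(s) || s == 0) stop("zero-variance continuous column: ", nm)
      center[nm] <- mean(m[, j])
      scale[nm] <- s
    }
  } else {
    stopifnot(inherits(reference, "hte_design"), isTRUE(reference$standardized))
    if (!identical(reference$provenance$column, design$provenance$column) ||
        !identical(reference$provenance$kind, design$provenance$kind)) {
      stop("reference design has different column provenance")
    }
    center <- reference$center
    scale <- reference$scale
  }
  design$x <- sweep(sweep(m, 2, center[colnames(m)], `-`), 2, scale[colnames(m)], `/`)
  design$center <- center
  design$scale <- scale
  design$standardized <- TRUE
  design
}

#' Undo standardization
#'
#' Maps a standardized design back to the original column scales using its
#' stored parameters (round-trip helper, mainly for checks and export).
#'
#' @param design a standardized `hte_design`.
#' @return The design on the original scale.
#' @export
destandardize_design <- function(design) {
  stopifnot(inherits(design, "hte_design"), isTRUE(design$standardized))
  m <- design$x
  design$x <- sweep(sweep(m, 2, design$scale[colnames(m)], `*`), 2,
                    design$center[colnames(m)], `+`)
  design$standardized <- FALSE
  design
}

#' Export a design matrix as CSV
#'
#' Writes the matrix with provenance recorded as `#`-prefixed header comments.
#'
#' @param design an `hte_design`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_design_csv <- function(design, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(design$provenance))) {
    writeLines(sprintf("# %s: kind=%s vars=%s",
                       design$provenance$column[i],
                       design$provenance$kind[i],
                       design$provenance$vars[i]), con)
  }
  utils::write.csv(cbind(id = design$ids, as.data.frame(design$x)), con, row.names = FALSE)
  invisible(path)
}
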