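#' Construct a cohort table
#'
#' A cohort table is a rectangular data set with one row per individual, a
#' binary treatment column, an outcome column (binary 0/1 or continuous) and
#' covariate columns. It is the entry point of the pipeline: every downstream
#' step (design matrix, weighting, G-computation, subgroup estimation) takes a
#' cohort table or an object derived from one.
#'
#' Invariants enforced here: the treatment takes only values 0/1 with both
#' arms non-empty, there are no missing values (imputation is upstream of this
#' tool), and row identifiers are unique.
#'
#' @param data data.frame with one row per individual.
#' @param treatment name of the binary treatment column.
#' @param outcome name of the outcome column.
#' @param id name of a unique identifier column, or `NULL` to use row numbers.
#' @return `data` with class `cohort_table` and attributes `treatment`,
#'   `outcome` and `id_col`.
#' @export
cohort_table <- function(data, treatment, outcome, id = NULL) {
  stopifnot(is.data.frame(data))
  if (nrow(data) == 0L) stop("cohort table is empty")
  for (nm in c(treatment, outcome, id)) {
    if (!nm %in% names(data)) stop("unknown column: ", nm)
  }
  x <- data[[treatment]]
  if (!all(x %in% c(0, 1))) stop("treatment column must take only values 0/1")
  if (length(unique(x)) < 2L) stop("empty treatment arm: both arms must be non-empty")
  covs <- setdiff(names(data), c(treatment, outcome, id))
  if (anyNA(data[c(treatment, outcome, covs)])) {
    stop("cohort table contains missing values; impute upstream")
  }
  if (is.null(id)) {
    ids <- seq_len(nrow(data))
  } else {
    ids <- data[[id]]
    if (anyDuplicated(ids)) stop("duplicated ids in cohort table")
  }
  structure(data,
    class = c("cohort_table", "data.frame"),
    treatment = treatment, outcome = outcome,
    id_col = id, row_ids = ids
  )
}

cohort_ids <- function(table) attr(table, "row_ids")

#' Declare variable roles
#'
#' Splits the covariates into the confounder set C (sufficient, per the
#' investigator's causal reasoning, for confounding control) and the set W of
#' candidate effect modifiers. The two sets may overlap: a confounder can be a
#' modifier. Deciding which covariates satisfy the backdoor criterion is the
#' investigator's job; [validate_roles()] only checks structural validity.
#'
#' @param confounders character vector of confounder column names.
#' @param candidate_modifiers character vector of candidate-modifier names.
#' @return An object of class `variable_roles`.
#' @export
variable_roles <- function(confounders = character(), candidate_modifiers = character()) {
  if (length(confounders) + length(candidate_modifiers) == 0L) {
    stop("at least one confounder or candidate modifier must be declared")
  }
  structure(
    list(
      confounders = unique(as.character(confounders)),
      candidate_modifiers = unique(as.character(candidate_modifiers))
    ),
    class = "variable_roles"
  )
}

#' Validate variable roles against a cohort table
#'
#' Checks that every declared column exists, that neither the treatment nor
#' the outcome is listed as a covariate, and that both treatment arms are
#' non-empty. Candidate modifiers that are not also confounders are reported
#' with an informational warning, since a modifier that is also a confounder
#' must sit in both sets for the adjustment to be valid.
#'
#' @param table a [cohort_table()].
#' @param roles a [variable_roles()] object.
#' @return `roles`, unchanged, invisibly validated.
#' @export
validate_roles <- function(table, roles) {
  stopifnot(inherits(table, "cohort_table"), inherits(roles, "variable_roles"))
  if (nrow(table) == 0L) stop("cohort table is empty")
  all_vars <- c(roles$confounders, roles$candidate_modifiers)
  missing <- setdiff(all_vars, names(table))
  if (length(missing)) stop("unknown column: ", paste(missing, collapse = ", "))
  xy <- c(attr(table, "treatment"), attr(table, "outcome"))
  bad <- intersect(all_vars, xy)
  if (length(bad)) stop("treatment/outcome listed as covariate: ", paste(bad, collapse = ", "))
  x <- table[[attr(table, "treatment")]]
  if (length(unique(x)) < 2L) stop("empty treatment arm")
  not_conf <- setdiff(roles$candidate_modifiers, roles$confounders)
  if (length(not_conf)) {
    warning(
      "candidate modifiers not in the confounder set (fine if they do not ",
      "affect treatment): ", paste(not_conf, collapse = ", ")
    )
  }
  roles
}

#' Split a cohort into training and test sets
#'
#' Simple random split: the model is developed on the training fraction and
#' potential outcomes are predicted on the held-out test fraction, which
#' protects the downstream cluster/importance step from overfitting. The
#' split is checked post hoc so that both treatment arms appear in both parts
#' (redrawn with a warning otherwise).
#'
#' @param table a [cohort_table()].
#' @param fraction training fraction in (0, 1); `round(fraction * n)` rows go
#'   to the training set.
#' @param seed integer seed; the same seed reproduces the same partition.
#' @return list with elements `train` and `test`, both cohort tables.
#' @export
split_sample <- function(table, fraction = 0.7, seed = 1L) {
  stopifnot(inherits(table, "cohort_table"))
  if (!(fraction > 0 && fraction < 1)) stop("fraction must be in (0, 1)")
  n <- nrow(table)
  n_train <- round(fraction * n)
  if (n_train < 2L || n - n_train < 2L) stop("sample too small to split")
  x <- table[[attr(table, "treatment")]]
  if (min(table(x)) < 2L) stop("sample too small to leave both arms in both splits")
  old <- .Random.seed_safe()
  on.exit(.restore_seed(old), add = TRUE)
  set.seed(as.integer(seed))
  both_arms <- function(v) length(unique(v)) == 2L
  for (attempt in seq_len(25L)) {
    idx <- sample.int(n, n_train)
    if (both_arms(x[idx]) && both_arms(x[-idx])) {
      if (attempt > 1L) warning("split redrawn ", attempt - 1L, " time(s) to keep both arms in both splits")
      break
    }
    if (attempt == 25L) stop("could not produce a split with both arms in both parts")
  }
  list(
    train = subset_cohort(table, idx),
    test = subset_cohort(table, setdiff(seq_len(n), idx))
  )
}

subset_cohort <- function(table, i) {
  out <- as.data.frame(table)[i, , drop = FALSE]
  structure(out,
    class = c("cohort_table", "data.frame"),
    treatment = attr(table, "treatment"), outcome = attr(table, "outcome"),
    id_col = attr(table, "id_col"), row_ids = attr(table, "row_ids")[i]
  )
}

# save/restore the RNG state so seeded helpers do not disturb the caller's stream
.Random.seed_safe <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
}

.restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}
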