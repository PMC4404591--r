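## Internal helpers shared across modules.

#' @keywords internal
`%||%` <- function(a, b) if (is.null(a)) b else a

## Run code with a temporarily seeded RNG, restoring the caller's stream.
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

## Standardize a numeric vector to mean 0, sd 1; constant vectors map to 0.
standardize <- function(v) {
  s <- stats::sd(v)
  if (!is.finite(s) || s == 0) return(rep(0, length(v)))
  (v - mean(v)) / s
}

## Quantile convention used for every permutation cutoff in the package:
## empirical order statistic with linear interpolation (type 7).
perm_quantile <- function(x, p) stats::quantile(x, p, type = 7, names = FALSE)

stop2 <- function(...) stop(..., call. = FALSE)

assert_expr_design <- function(expr, design) {
  if (!is.matrix(expr) || !is.numeric(expr))
    stop2("expression must be a numeric matrix (genes x libraries)")
  if (is.null(colnames(expr))) stop2("expression matrix must have library column names")
  if (!all(colnames(expr) %in% design$library_id))
    stop2("libraries missing from design: ",
          paste(setdiff(colnames(expr), design$library_id), collapse = ", "))
  design <- design[match(colnames(expr), design$library_id), , drop = FALSE]
  rownames(design) <- NULL
  design
}

## Canonical trait set of the study design, in model order.
TRAIT_COLUMNS <- c(sex = "sex", weight = "weight", length = "length",
                   delivery = "delivery", maternal_age = "maternal_age",
                   bmi = "bmi", alcohol = "alcohol", vegetarian = "vegetarian")

## Coerce a trait column to numeric: quantitative kept as-is, two-level
## factors/characters/logicals coded 0/1 by sorted level.
trait_as_numeric <- function(v, name = "trait") {
  if (is.numeric(v)) return(as.numeric(v))
  if (is.logical(v)) return(as.numeric(v))
  lev <- sort(unique(as.character(v)))
  if (length(lev) > 2)
    stop2("non-numeric trait '", name, "' has more than two levels")
  as.numeric(match(as.character(v), lev) - 1L)
}
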