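# -- variable typing -----------------------------------------------------------
#
# Types partition the variables exhaustively:
#   empty (0 distinct non-missing), constant (1), binary (2),
#   categorical (cat_min..cat_max), check (cat_max+1..cont_min-1, plus any
#   high-cardinality variable that is not numeric-coercible), continuous
#   (>= cont_min distinct AND numeric-coercible).
# Missing values never count as a level.

VALID_TYPES <- c("binary", "categorical", "continuous", "check", "constant",
                 "empty")

#' Thresholds for unique-value type inference
#'
#' @param cat_min,cat_max Distinct-value range classified as categorical
#'   (defaults 3 and 5).
#' @param cont_min Minimum distinct values for continuous (default 15);
#'   counts strictly between `cat_max` and `cont_min` are flagged `check`
#'   for manual review.
#' @return A validated `categorize_thresholds` list.
#' @export
categorize_thresholds <- function(cat_min = 3L, cat_max = 5L, cont_min = 15L) {
  cat_min <- as.integer(cat_min); cat_max <- as.integer(cat_max)
  cont_min <- as.integer(cont_min)
  if (!(2L < cat_min && cat_min <= cat_max && cat_max < cont_min)) {
    stop("thresholds must satisfy 2 < cat_min <= cat_max < cont_min",
         call. = FALSE)
  }
  structure(list(cat_min = cat_min, cat_max = cat_max, cont_min = cont_min),
            class = "categorize_thresholds")
}

distinct_nonmissing <- function(tokens) length(unique(tokens[!is.na(tokens)]))

classify_one <- function(tokens, th) {
  u <- distinct_nonmissing(tokens)
  if (u == 0L) return("empty")
  if (u == 1L) return("constant")
  if (u == 2L) return("binary")
  if (u >= th$cat_min && u <= th$cat_max) return("categorical")
  if (u >= th$cont_min && is_numeric_coercible(tokens)) return("continuous")
  "check"
}

#' Infer variable types from distinct-value counts
#'
#' Classifies every variable of a [raw_dataset()] by its number of distinct
#' non-missing values (see [categorize_thresholds()]). Variables with enough
#' distinct values to be continuous but containing non-numeric tokens are
#' routed to `check` for manual review rather than silently coerced.
#'
#' @param data A `raw_dataset`.
#' @param thresholds A [categorize_thresholds()].
#' @return A `typed_dataset`: the data plus a per-variable type map,
#'   distinct counts and non-missing counts.
#' @export
categorize <- function(data, thresholds = categorize_thresholds()) {
  stopifnot(inherits(data, "raw_dataset"),
            inherits(thresholds, "categorize_thresholds"))
  vars <- variable_names(data)
  types <- vapply(vars, function(v) classify_one(data$values[[v]], thresholds),
                  character(1))
  u <- vapply(vars, function(v) distinct_nonmissing(data$values[[v]]),
              integer(1))
  nn <- vapply(vars, function(v) sum(!is.na(data$values[[v]])), integer(1))
  data <- log_op(data, "categorize",
                 params = c(unclass(thresholds),
                            list(counts = as.list(table(factor(types,
                                                     levels = VALID_TYPES))))),
                 variables_affected = vars, samples_affected = 0L)
  structure(list(data = data, types = types, thresholds = thresholds,
                 distinct_counts = u, n_nonmissing = nn),
            class = "typed_dataset")
}

#' @export
print.typed_dataset <- function(x, ...) {
  cat("typed_dataset: ", n_samples(x), " samples x ", n_variables(x),
      " variables\n", sep = "")
  print(type_counts(x))
  invisible(x)
}

#' Per-type variable counts
#' @param typed A `typed_dataset`.
#' @return Named integer vector over the six types.
#' @export
type_counts <- function(typed) {
  tab <- table(factor(typed$types, levels = VALID_TYPES))
  stats::setNames(as.integer(tab), names(tab))
}

#' The type assigned to each variable
#' @param typed A `typed_dataset`.
#' @return Named character vector, one entry per variable.
#' @export
variable_types <- function(typed) typed$types

refresh_counts <- function(typed) {
  vars <- variable_names(typed$data)
  typed$distinct_counts <- vapply(vars, function(v)
    distinct_nonmissing(typed$data$values[[v]]), integer(1))
  typed$n_nonmissing <- vapply(vars, function(v)
    sum(!is.na(typed$data$values[[v]])), integer(1))
  typed
}

#' Manually re-type a variable
#'
#' Moves a variable (typically one flagged `check`) to an analysis type after
#' manual inspection. Recoding to binary requires exactly two distinct
#' non-missing values; recoding to continuous requires numeric-coercible
#' values.
#'
#' @param typed A `typed_dataset`.
#' @param variable Variable name.
#' @param new_type One of `"binary"`, `"categorical"`, `"continuous"`.
#' @return The updated `typed_dataset`.
#' @export
recode_type <- function(typed, variable,
                        new_type = c("binary", "categorical", "continuous")) {
  new_type <- match.arg(new_type)
  stopifnot(inherits(typed, "typed_dataset"))
  check_vars_exist(typed$data, variable)
  tokens <- typed$data$values[[variable]]
  if (new_type == "binary" && distinct_nonmissing(tokens) != 2L) {
    stop("cannot recode '", variable, "' to binary: ",
         distinct_nonmissing(tokens), " distinct values (need exactly 2)",
         call. = FALSE)
  }
  if (new_type == "continuous" && !is_numeric_coercible(tokens)) {
    stop("cannot recode '", variable,
         "' to continuous: non-numeric values present", call. = FALSE)
  }
  old <- typed$types[[variable]]
  typed$types[[variable]] <- new_type
  typed$data <- log_op(typed$data, "recode_type",
                       params = list(variable = variable, from = old,
                                     to = new_type),
                       variables_affected = variable, samples_affected = 0L)
  typed
}

# Shared removal helper for the column filters.
drop_variables <- function(typed, drop, op, params) {
  keep <- setdiff(variable_names(typed$data), drop)
  typed$data$values <- typed$data$values[, keep, drop = FALSE]
  typed$types <- typed$types[keep]
  typed$distinct_counts <- typed$distinct_counts[keep]
  typed$n_nonmissing <- typed$n_nonmissing[keep]
  typed$data <- log_op(typed$data, op,
                       params = c(params, list(removed = drop)),
                       variables_affected = drop, samples_affected = 0L)
  typed
}

#' Drop variables with too few non-missing values
#'
#' Removes every variable with *fewer than* `min_n` non-missing values
#' (strict: 199 is dropped at the default, 200 kept). Applies to all types.
#'
#' @param typed A `typed_dataset`.
#' @param min_n Minimum non-missing count (default 200).
#' @return The filtered `typed_dataset`.
#' @export
colfilter_min_n <- function(typed, min_n = 200L) {
  stopifnot(inherits(typed, "typed_dataset"), min_n >= 0)
  nn <- vapply(variable_names(typed$data), function(v)
    sum(!is.na(typed$data$values[[v]])), integer(1))
  drop_variables(typed, names(nn)[nn < min_n], "colfilter_min_n",
                 list(min_n = as.integer(min_n)))
}

#' Drop categorical/binary variables with an undersized level
#'
#' Removes a binary or categorical variable if any observed level has fewer
#' than `min_cat_n` occurrences among non-missing values ("at least
#' `min_cat_n` samples for every category"; a level count equal to the
#' threshold keeps the variable). Other types pass untouched.
#'
#' @param typed A `typed_dataset`.
#' @param min_cat_n Minimum per-level count (default 200).
#' @return The filtered `typed_dataset`.
#' @export
colfilter_min_cat_n <- function(typed, min_cat_n = 200L) {
  stopifnot(inherits(typed, "typed_dataset"))
  cand <- names(typed$types)[typed$types %in% c("binary", "categorical")]
  bad <- Filter(function(v) {
    counts <- table(typed$data$values[[v]][!is.na(typed$data$values[[v]])])
    any(counts < min_cat_n)
  }, cand)
  drop_variables(typed, as.character(bad), "colfilter_min_cat_n",
                 list(min_cat_n = as.integer(min_cat_n)))
}

#' Drop continuous variables dominated by zeros
#'
#' Removes a continuous variable when the proportion of zeros among its
#' non-missing values is *strictly greater than* `threshold` (exactly 90%
#' zeros survives the default). Other types pass untouched. The denominator
#' is the non-missing count, so missingness cannot rescue a degenerate
#' variable.
#'
#' @param typed A `typed_dataset`.
#' @param threshold Maximum tolerated zero proportion (default 0.90).
#' @return The filtered `typed_dataset`.
#' @export
colfilter_percent_zero <- function(typed, threshold = 0.90) {
  stopifnot(inherits(typed, "typed_dataset"),
            threshold >= 0, threshold <= 1)
  cand <- names(typed$types)[typed$types == "continuous"]
  bad <- Filter(function(v) {
    x <- variable_values(typed$data, v, as = "numeric", quiet = TRUE)
    x <- x[!is.na(x)]
    length(x) > 0 && mean(x == 0) > threshold
  }, cand)
  drop_variables(typed, as.character(bad), "colfilter_percent_zero",
                 list(threshold = threshold))
}

#' Drop constant and empty variables
#'
#' Variables with zero or one distinct non-missing value carry no analyzable
#' signal; this removes them ahead of the sample-size filters so each filter's
#' removals are attributable to its own rule.
#'
#' @param typed A `typed_dataset`.
#' @return The filtered `typed_dataset`.
#' @export
drop_degenerate <- function(typed) {
  stopifnot(inherits(typed, "typed_dataset"))
  drop_variables(typed,
                 names(typed$types)[typed$types %in% c("constant", "empty")],
                 "drop_degenerate", list())
}

# -- descriptive summaries -----------------------------------------------------

#' Level frequency tables for binary/categorical variables
#'
#' @param typed A `typed_dataset`.
#' @return Data frame with columns `variable`, `level`, `count`; missing is
#'   reported as level `NA`. Counts per variable sum to the sample count.
#' @export
summarize_frequencies <- function(typed) {
  stopifnot(inherits(typed, "typed_dataset"))
  vars <- names(typed$types)[typed$types %in% c("binary", "categorical")]
  rows <- lapply(vars, function(v) {
    x <- typed$data$values[[v]]
    tab <- table(x, useNA = "ifany")
    data.frame(variable = v,
               level = ifelse(is.na(names(tab)) | names(tab) == "",
                              NA_character_, names(tab)),
               count = as.integer(tab),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  if (is.null(out)) {
    out <- data.frame(variable = character(), level = character(),
                      count = integer(), stringsAsFactors = FALSE)
  }
  out
}

#' Pairwise Pearson correlations among continuous variables
#'
#' Correlations use pairwise-complete observations; pairs with fewer than
#' three complete observations are reported missing. Pairs at or above
#' `report_above` in absolute value are flagged.
#'
#' @param typed A `typed_dataset` with at least two continuous variables.
#' @param report_above Flagging threshold on |r| (default 0.75).
#' @return Data frame with columns `var1`, `var2`, `n`, `r`, `flagged`.
#' @export
summarize_correlations <- function(typed, report_above = 0.75) {
  stopifnot(inherits(typed, "typed_dataset"))
  vars <- names(typed$types)[typed$types == "continuous"]
  if (length(vars) < 2) {
    stop("need at least two continuous variables", call. = FALSE)
  }
  mat <- vapply(vars, function(v)
    variable_values(typed$data, v, as = "numeric", quiet = TRUE),
    numeric(n_samples(typed)))
  pairs <- utils::combn(vars, 2)
  rows <- apply(pairs, 2, function(p) {
    x <- mat[, p[1]]; y <- mat[, p[2]]
    ok <- !is.na(x) & !is.na(y)
    r <- if (sum(ok) >= 3) suppressWarnings(stats::cor(x[ok], y[ok])) else NA_real_
    data.frame(var1 = p[1], var2 = p[2], n = sum(ok), r = r,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$flagged <- !is.na(out$r) & abs(out$r) >= report_above
  out
}

#' Summary statistics before and after outlier exclusion
#'
#' For each continuous variable, reports N, mean, SD, min and max before and
#' after excluding values outside mean +/- `k_sd` * SD, where mean and SD come
#' from the full non-missing data. Purely descriptive: the dataset itself is
#' never modified. Variables with SD = 0 are flagged and left identical.
#'
#' @param typed A `typed_dataset`.
#' @param k_sd Exclusion width in standard deviations (default 3).
#' @return Data frame, one row per continuous variable.
#' @export
compare_outlier_removal <- function(typed, k_sd = 3) {
  stopifnot(inherits(typed, "typed_dataset"), k_sd > 0)
  vars <- names(typed$types)[typed$types == "continuous"]
  rows <- lapply(vars, function(v) {
    x <- variable_values(typed$data, v, as = "numeric", quiet = TRUE)
    x <- x[!is.na(x)]
    m <- mean(x); s <- stats::sd(x)
    degenerate <- is.na(s) || s == 0
    keep <- if (degenerate) x else x[abs(x - m) <= k_sd * s]
    data.frame(variable = v,
               n_before = length(x), mean_before = m, sd_before = s,
               min_before = min(x), max_before = max(x),
               n_after = length(keep), mean_after = mean(keep),
               sd_after = stats::sd(keep),
               min_after = min(keep), max_after = max(keep),
               n_excluded = length(x) - length(keep),
               zero_sd = degenerate,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

# -- type sidecar --------------------------------------------------------------

#' Write / read the variable-type sidecar
#'
#' The sidecar (TSV: `variable`, `type`, `distinct_count`, `n_nonmissing`)
#' persists type assignments — including manual recodes — so pipeline steps
#' can resume from files alone.
#'
#' @param typed A `typed_dataset`.
#' @param path Sidecar file path.
#' @export
save_types <- function(typed, path) {
  stopifnot(inherits(typed, "typed_dataset"))
  df <- data.frame(variable = names(typed$types),
                   type = unname(typed$types),
                   distinct_count = unname(typed$distinct_counts),
                   n_nonmissing = unname(typed$n_nonmissing),
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname save_types
#' @param data The `raw_dataset` the sidecar describes.
#' @return `load_types` returns the reconstructed `typed_dataset`.
#' @export
load_types <- function(data, path) {
  stopifnot(inherits(data, "raw_dataset"))
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          colClasses = c("character", "character", "integer",
                                         "integer"),
                          stringsAsFactors = FALSE)
  check_vars_exist(data, df$variable)
  extra <- setdiff(variable_names(data), df$variable)
  if (length(extra)) {
    stop("sidecar missing variable(s): ", paste(extra, collapse = ", "),
         call. = FALSE)
  }
  bad <- setdiff(unique(df$type), VALID_TYPES)
  if (length(bad)) {
    stop("sidecar has unknown type(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  typed <- structure(
    list(data = data,
         types = stats::setNames(df$type, df$variable)[variable_names(data)],
         thresholds = categorize_thresholds(),
         distinct_counts = NULL, n_nonmissing = NULL),
    class = "typed_dataset")
  refresh_counts(typed)
}
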