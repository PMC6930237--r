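# -- raw_dataset ---------------------------------------------------------------
#
# A raw_dataset holds a sample-by-variable table of tokens. Every cell is a
# character token or NA (the single missing state); numeric interpretation is
# deferred to the operations that need it. Sample IDs and variable names are
# unique; every operation returns a modified copy and appends exactly one
# provenance entry.

#' Construct a raw mixed-type dataset
#'
#' Builds the package's central data container from a data frame. One column
#' holds the sample identifier; every other column is stored as a character
#' token vector with `NA` as the single missing state. Numeric columns are
#' converted losslessly (17 significant digits) so values survive a save/load
#' round trip exactly.
#'
#' @param df A data frame; one column must contain unique sample identifiers.
#' @param id_column Name or index of the identifier column (default: first).
#' @param provenance Internal; an existing provenance log to carry forward.
#' @return An object of class `raw_dataset`.
#' @export
raw_dataset <- function(df, id_column = 1L, provenance = list()) {
  stopifnot(is.data.frame(df))
  if (is.numeric(id_column)) id_column <- names(df)[id_column]
  if (!id_column %in% names(df)) {
    stop("id column '", id_column, "' not found", call. = FALSE)
  }
  ids <- as.character(df[[id_column]])
  dup <- unique(ids[duplicated(ids)])
  if (length(dup)) {
    stop("duplicate sample IDs: ", paste(dup, collapse = ", "), call. = FALSE)
  }
  vals <- df[, setdiff(names(df), id_column), drop = FALSE]
  dupv <- unique(names(vals)[duplicated(names(vals))])
  if (length(dupv)) {
    stop("duplicate variable names: ", paste(dupv, collapse = ", "),
         call. = FALSE)
  }
  vals[] <- lapply(vals, tokenize_cells)
  rownames(vals) <- NULL
  structure(
    list(sample_ids = ids, values = vals, provenance = provenance),
    class = "raw_dataset"
  )
}

# Lossless cell representation: doubles keep 17 significant digits.
tokenize_cells <- function(x) {
  if (is.double(x)) {
    out <- rep(NA_character_, length(x))
    ok <- !is.na(x)
    out[ok] <- sprintf("%.17g", x[ok])
    out
  } else {
    out <- as.character(x)
    out[is.na(x)] <- NA_character_
    out
  }
}

#' @export
print.raw_dataset <- function(x, ...) {
  cat("raw_dataset: ", n_samples(x), " samples x ", n_variables(x),
      " variables, ", length(x$provenance), " logged operations\n", sep = "")
  invisible(x)
}

#' Number of samples / variables in a dataset
#' @param x A `raw_dataset` or `typed_dataset`.
#' @return Integer count.
#' @export
n_samples <- function(x) UseMethod("n_samples")
#' @export
n_samples.raw_dataset <- function(x) length(x$sample_ids)
#' @export
n_samples.typed_dataset <- function(x) n_samples(x$data)

#' @rdname n_samples
#' @export
n_variables <- function(x) UseMethod("n_variables")
#' @export
n_variables.raw_dataset <- function(x) ncol(x$values)
#' @export
n_variables.typed_dataset <- function(x) n_variables(x$data)

#' Variable names / sample identifiers
#' @param x A `raw_dataset` or `typed_dataset`.
#' @return Character vector.
#' @export
variable_names <- function(x) UseMethod("variable_names")
#' @export
variable_names.raw_dataset <- function(x) names(x$values)
#' @export
variable_names.typed_dataset <- function(x) variable_names(x$data)

#' @rdname variable_names
#' @export
sample_ids <- function(x) UseMethod("sample_ids")
#' @export
sample_ids.raw_dataset <- function(x) x$sample_ids
#' @export
sample_ids.typed_dataset <- function(x) sample_ids(x$data)

#' Extract one variable's values
#'
#' @param data A `raw_dataset`.
#' @param variable Variable name.
#' @param as `"character"` (tokens) or `"numeric"` (coerced; non-numeric
#'   tokens become `NA` with a warning unless `quiet = TRUE`).
#' @param quiet Suppress the coercion warning.
#' @return A vector aligned with `sample_ids(data)`.
#' @export
variable_values <- function(data, variable, as = c("character", "numeric"),
                            quiet = FALSE) {
  as <- match.arg(as)
  check_vars_exist(data, variable)
  v <- data$values[[variable]]
  if (as == "numeric") {
    num <- suppressWarnings(as.numeric(v))
    bad <- !is.na(v) & is.na(num)
    if (any(bad) && !quiet) {
      warning(sum(bad), " non-numeric tokens in '", variable,
              "' coerced to NA", call. = FALSE)
    }
    num
  } else {
    v
  }
}

check_vars_exist <- function(data, vars) {
  missing <- setdiff(vars, variable_names(data))
  if (length(missing)) {
    stop("unknown variable(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  invisible(TRUE)
}

is_numeric_coercible <- function(tokens) {
  ok <- !is.na(tokens)
  if (!any(ok)) return(TRUE)
  !anyNA(suppressWarnings(as.numeric(tokens[ok])))
}

# Append exactly one provenance entry; returns the updated dataset.
log_op <- function(data, op, params = list(), variables_affected = character(),
                   samples_affected = 0L) {
  entry <- list(
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    op = op,
    params = params,
    variables_affected = as.character(variables_affected),
    samples_affected = as.integer(samples_affected)
  )
  data$provenance <- c(data$provenance, list(entry))
  data
}

#' Retrieve the audit log
#' @param data A `raw_dataset` or `typed_dataset`.
#' @return A list of provenance entries (timestamp, op, params, counts).
#' @export
provenance_log <- function(data) {
  if (inherits(data, "typed_dataset")) data <- data$data
  data$provenance
}

#' Write the audit log as line-delimited JSON
#' @param data A `raw_dataset` or `typed_dataset`.
#' @param path Output file.
#' @param append Append to an existing log file.
#' @export
write_provenance <- function(data, path, append = FALSE) {
  lines <- vapply(provenance_log(data), function(e) {
    jsonlite::toJSON(e, auto_unbox = TRUE)
  }, character(1))
  if (append && file.exists(path)) {
    cat(lines, file = path, sep = "\n", append = TRUE)
  } else {
    writeLines(lines, path)
  }
  invisible(path)
}

# -- IO ------------------------------------------------------------------------

#' Load a delimited sample-by-variable table
#'
#' Reads a header-bearing delimited text file into a [raw_dataset()]. Cells
#' matching one of `na_tokens` (after the file's own empty cells) are parsed
#' as missing. Duplicate sample IDs or column names are an error.
#'
#' @param path File path.
#' @param id_column Name or index of the sample-ID column (default: first).
#' @param delimiter Field separator (default tab).
#' @param na_tokens Tokens treated as missing on input.
#' @return A `raw_dataset` with the load logged.
#' @export
load_table <- function(path, id_column = 1L, delimiter = "\t",
                       na_tokens = c("", "NA", "NaN", "nan")) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.table(path, header = TRUE, sep = delimiter,
                          colClasses = "character", check.names = FALSE,
                          quote = "", comment.char = "", na.strings = NULL,
                          stringsAsFactors = FALSE)
  dupc <- unique(names(df)[duplicated(names(df))])
  if (length(dupc)) {
    stop("duplicate column names: ", paste(dupc, collapse = ", "),
         call. = FALSE)
  }
  df[] <- lapply(df, function(x) {
    x[x %in% na_tokens] <- NA_character_
    x
  })
  ds <- raw_dataset(df, id_column = id_column)
  log_op(ds, "load_table",
         params = list(path = path, id_column = names(df)[1],
                       delimiter = delimiter, na_tokens = na_tokens),
         variables_affected = variable_names(ds),
         samples_affected = n_samples(ds))
}

#' Save a dataset as delimited text
#'
#' Writes the canonical dialect: header row, sample-ID first column, missing
#' cells as the empty string, no quoting. A save/load round trip through this
#' dialect preserves cells, missingness and column order exactly.
#'
#' @param data A `raw_dataset` or `typed_dataset`.
#' @param path Output file.
#' @param delimiter Field separator (default tab).
#' @param id_name Header name for the sample-ID column.
#' @export
save_table <- function(data, path, delimiter = "\t", id_name = "ID") {
  if (inherits(data, "typed_dataset")) data <- data$data
  df <- data$values
  df[] <- lapply(df, function(x) ifelse(is.na(x), "", x))
  out <- cbind(stats::setNames(data.frame(data$sample_ids,
                                          stringsAsFactors = FALSE), id_name),
               df)
  utils::write.table(out, path, sep = delimiter, quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

# -- sentinel standardization --------------------------------------------------

#' Define a sentinel (coded-missing) map
#'
#' @param variable Character vector of variable names (recycled against
#'   `value`); a variable may appear several times with different sentinels.
#' @param value Sentinel tokens (character or numeric).
#' @return A `sentinel_map` data frame with columns `variable`, `value`.
#' @export
sentinel_map <- function(variable, value) {
  m <- data.frame(variable = as.character(variable),
                  value = as.character(value),
                  stringsAsFactors = FALSE)
  class(m) <- c("sentinel_map", class(m))
  m
}

#' Read a sentinel map from a two-column delimited file
#' @param path TSV/CSV with columns `variable`, `value`.
#' @param delimiter Field separator.
#' @return A `sentinel_map`.
#' @export
read_sentinel_map <- function(path, delimiter = "\t") {
  df <- utils::read.table(path, header = TRUE, sep = delimiter,
                          colClasses = "character", check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (!all(c("variable", "value") %in% names(df))) {
    stop("sentinel map needs columns 'variable' and 'value'", call. = FALSE)
  }
  sentinel_map(df$variable, df$value)
}

#' Replace per-variable sentinel codes with missing
#'
#' Every cell of variable `v` equal to one of `v`'s sentinels becomes missing.
#' Equality is tested on the token and, when both sides are numeric, on the
#' numeric value (so sentinel `9` matches cell `9.0`). Map entries naming
#' unknown variables are collected into a warning, never silently dropped.
#'
#' @param data A `raw_dataset`.
#' @param map A [sentinel_map()].
#' @return The dataset with sentinels replaced and the counts logged.
#' @export
standardize_missing <- function(data, map) {
  stopifnot(inherits(data, "raw_dataset"))
  unknown <- setdiff(unique(map$variable), variable_names(data))
  if (length(unknown)) {
    warning("sentinel map names unknown variable(s): ",
            paste(unknown, collapse = ", "), call. = FALSE)
  }
  counts <- integer(0)
  for (v in intersect(unique(map$variable), variable_names(data))) {
    sentinels <- map$value[map$variable == v]
    col <- data$values[[v]]
    hit <- !is.na(col) & col %in% sentinels
    snum <- suppressWarnings(as.numeric(sentinels))
    if (any(!is.na(snum))) {
      cnum <- suppressWarnings(as.numeric(col))
      hit <- hit | (!is.na(cnum) & cnum %in% snum[!is.na(snum)])
    }
    if (any(hit)) {
      col[hit] <- NA_character_
      data$values[[v]] <- col
    }
    counts[v] <- sum(hit)
  }
  log_op(data, "standardize_missing",
         params = list(replacements = as.list(counts),
                       unknown_variables = unknown),
         variables_affected = names(counts)[counts > 0],
         samples_affected = 0L)
}

# -- merges --------------------------------------------------------------------

#' Merge two datasets column-wise (same samples, disjoint variables)
#' @param a,b `raw_dataset`s with identical sample-ID sets.
#' @return The concatenated `raw_dataset`.
#' @export
merge_variables <- function(a, b) {
  stopifnot(inherits(a, "raw_dataset"), inherits(b, "raw_dataset"))
  diff <- c(setdiff(a$sample_ids, b$sample_ids),
            setdiff(b$sample_ids, a$sample_ids))
  if (length(diff)) {
    stop("sample ID sets differ: ", paste(diff, collapse = ", "),
         call. = FALSE)
  }
  clash <- intersect(variable_names(a), variable_names(b))
  if (length(clash)) {
    stop("variable name collision: ", paste(clash, collapse = ", "),
         call. = FALSE)
  }
  bvals <- b$values[match(a$sample_ids, b$sample_ids), , drop = FALSE]
  rownames(bvals) <- NULL
  a$values <- cbind(a$values, bvals)
  log_op(a, "merge_variables",
         params = list(added = variable_names(b)),
         variables_affected = variable_names(b),
         samples_affected = 0L)
}

#' Merge two datasets row-wise (same variables, disjoint samples)
#' @param a,b `raw_dataset`s with identical variable sets.
#' @return The concatenated `raw_dataset`.
#' @export
merge_observations <- function(a, b) {
  stopifnot(inherits(a, "raw_dataset"), inherits(b, "raw_dataset"))
  diff <- c(setdiff(variable_names(a), variable_names(b)),
            setdiff(variable_names(b), variable_names(a)))
  if (length(diff)) {
    stop("variable sets differ: ", paste(diff, collapse = ", "),
         call. = FALSE)
  }
  clash <- intersect(a$sample_ids, b$sample_ids)
  if (length(clash)) {
    stop("sample ID collision: ", paste(clash, collapse = ", "),
         call. = FALSE)
  }
  a$values <- rbind(a$values, b$values[, variable_names(a), drop = FALSE])
  rownames(a$values) <- NULL
  a$sample_ids <- c(a$sample_ids, b$sample_ids)
  log_op(a, "merge_observations",
         params = list(added_samples = length(b$sample_ids)),
         variables_affected = character(),
         samples_affected = length(b$sample_ids))
}

# -- sample filtering ----------------------------------------------------------

#' Drop samples missing any required variable
#'
#' Retains exactly the samples with a non-missing value for every variable in
#' `required` (complete cases on the required set). `required = character(0)`
#' is the identity. Idempotent.
#'
#' @param data A `raw_dataset`.
#' @param required Character vector of variable names.
#' @return The filtered `raw_dataset` with the removal logged.
#' @export
rowfilter_incomplete <- function(data, required) {
  stopifnot(inherits(data, "raw_dataset"))
  check_vars_exist(data, required)
  if (length(required) == 0) {
    keep <- rep(TRUE, n_samples(data))
  } else {
    miss <- vapply(required, function(v) is.na(data$values[[v]]),
                   logical(n_samples(data)))
    keep <- !apply(matrix(miss, nrow = n_samples(data)), 1, any)
  }
  removed <- sum(!keep)
  data$values <- data$values[keep, , drop = FALSE]
  rownames(data$values) <- NULL
  data$sample_ids <- data$sample_ids[keep]
  log_op(data, "rowfilter_incomplete",
         params = list(required = required, removed = removed),
         variables_affected = character(),
         samples_affected = removed)
}

# -- transforms ----------------------------------------------------------------

#' Transform a numeric variable in place
#'
#' @param data A `raw_dataset`.
#' @param variable Variable name (must be numeric-coercible).
#' @param transform One of `"log"`, `"log1p"`, `"sqrt"`, `"identity"`.
#'   `log` requires all non-missing values strictly positive; `sqrt` and
#'   `log1p` require them nonnegative.
#' @return The dataset with the transformed column and the operation logged.
#' @export
transform_variable <- function(data, variable,
                               transform = c("log", "log1p", "sqrt",
                                             "identity")) {
  transform <- match.arg(transform)
  stopifnot(inherits(data, "raw_dataset"))
  check_vars_exist(data, variable)
  x <- variable_values(data, variable, as = "numeric", quiet = TRUE)
  tok <- data$values[[variable]]
  if (any(!is.na(tok) & is.na(x))) {
    stop("variable '", variable, "' is not numeric", call. = FALSE)
  }
  ok <- !is.na(x)
  if (transform == "log" && any(x[ok] <= 0)) {
    stop(sum(x[ok] <= 0), " non-positive value(s) in '", variable,
         "' under log", call. = FALSE)
  }
  if (transform %in% c("log1p", "sqrt") && any(x[ok] < 0)) {
    stop(sum(x[ok] < 0), " negative value(s) in '", variable, "' under ",
         transform, call. = FALSE)
  }
  y <- switch(transform,
              log = log(x), log1p = log1p(x), sqrt = sqrt(x), identity = x)
  data$values[[variable]] <- tokenize_cells(y)
  log_op(data, "transform_variable",
         params = list(variable = variable, transform = transform),
         variables_affected = variable,
         samples_affected = 0L)
}
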