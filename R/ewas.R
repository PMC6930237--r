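# -- EWAS engine ---------------------------------------------------------------
#
# One regression per exposure: Y ~ intercept + X + covariates, fit on the
# complete cases for that exposure's model (outcome, covariates, X, weight),
# after discarding zero-weight rows. Continuous/binary exposures report a
# single beta, SE and two-sided p; categorical exposures report one term
# p-value (LRT of full vs reduced without a design; design-based Wald F of
# the dummy block with a design). Exposures falling under min_n yield a NULL
# row with a skip reason, never an error.

to_numeric_or_factor <- function(typed, v) {
  type <- typed$types[[v]]
  tokens <- typed$data$values[[v]]
  switch(type,
    continuous = variable_values(typed$data, v, as = "numeric", quiet = TRUE),
    binary = factor(tokens, levels = sort(unique(tokens[!is.na(tokens)]))),
    categorical = factor(tokens, levels = sort(unique(tokens[!is.na(tokens)]))),
    stop("variable '", v, "' has non-analysis type '", type, "'",
         call. = FALSE))
}

null_row <- function(variable, type, n, weight_name, reason) {
  data.frame(variable = variable, type = type, n = as.integer(n),
             beta = NA_real_, se = NA_real_, pvalue = NA_real_,
             lrt_pvalue = NA_real_, converged = NA,
             weight_name = weight_name, skip_reason = reason,
             stringsAsFactors = FALSE)
}

#' Run an environment-wide association study
#'
#' Regresses the outcome on each exposure in turn, adjusting for a fixed set
#' of covariates, optionally honoring a complex sampling design (strata,
#' PSUs, per-variable weights) with Taylor-linearization variance. Exposures
#' are all typed variables except the outcome, the covariates, and any
#' columns the design was built from. Per exposure: complete cases are taken
#' over outcome, covariates, the exposure and its weight; zero-weight rows
#' are discarded; if fewer than `min_n` rows remain a NULL row is emitted
#' with a skip reason.
#'
#' @param typed A `typed_dataset` (run [categorize()] / [recode_type()]
#'   first; `check`, `constant` and `empty` variables are skipped).
#' @param outcome Outcome variable name (numeric for gaussian; two-level for
#'   binomial).
#' @param covariates Character vector of adjustment variables.
#' @param design Optional [build_design()] result over the same samples.
#' @param family `"gaussian"` or `"binomial"`.
#' @param min_n Minimum analysis sample size per exposure (default 200).
#' @param exclude Additional variables to leave untested.
#' @param categorical_test `"auto"` (Wald F with a design, LRT without),
#'   `"lrt"`, or `"wald"` (Wald requires a design covariance; without a
#'   design it uses the classical covariance).
#' @return An `ewas_result` data frame, one row per tested exposure in input
#'   order, with columns `variable`, `type`, `n`, `beta`, `se`, `pvalue`,
#'   `lrt_pvalue`, `converged`, `weight_name`, `skip_reason`.
#' @export
ewas <- function(typed, outcome, covariates = character(), design = NULL,
                 family = c("gaussian", "binomial"), min_n = 200L,
                 exclude = character(),
                 categorical_test = c("auto", "lrt", "wald")) {
  family <- match.arg(family)
  categorical_test <- match.arg(categorical_test)
  stopifnot(inherits(typed, "typed_dataset"))
  check_vars_exist(typed$data, c(outcome, covariates, exclude))
  if (outcome %in% covariates) stop("outcome cannot be a covariate",
                                    call. = FALSE)
  if (!is.null(design)) {
    stopifnot(inherits(design, "survey_design"))
    if (!identical(design$sample_ids, sample_ids(typed))) {
      stop("design and dataset sample IDs differ", call. = FALSE)
    }
    exclude <- union(exclude, design$source_columns)
  }
  exposures <- setdiff(variable_names(typed), c(outcome, covariates, exclude))

  y_raw <- if (family == "gaussian") {
    variable_values(typed$data, outcome, as = "numeric", quiet = TRUE)
  } else {
    tok <- typed$data$values[[outcome]]
    lev <- sort(unique(tok[!is.na(tok)]))
    if (length(lev) != 2) stop("binomial outcome needs exactly 2 levels",
                               call. = FALSE)
    ifelse(is.na(tok), NA_real_, as.numeric(tok == lev[2]))
  }
  cov_frame <- lapply(stats::setNames(covariates, covariates),
                      function(v) to_numeric_or_factor(typed, v))

  rows <- lapply(exposures, function(v) {
    type <- typed$types[[v]]
    if (!type %in% c("continuous", "binary", "categorical")) {
      return(null_row(v, type, 0L, NA_character_,
                      paste0("unsupported_type:", type)))
    }
    x <- to_numeric_or_factor(typed, v)
    winfo <- if (is.null(design)) list(name = NA_character_, w = NULL)
             else design_weights(design, v)
    keep <- !is.na(y_raw) & !is.na(x)
    for (cv in cov_frame) keep <- keep & !is.na(cv)
    if (!is.null(winfo$w)) keep <- keep & !is.na(winfo$w) & winfo$w > 0
    n <- sum(keep)
    if (n < min_n) {
      message("skipping '", v, "': ", n, " samples below min_n = ", min_n)
      return(null_row(v, type, n, winfo$name, "min_n"))
    }
    mf <- data.frame(.x = x[keep], stringsAsFactors = FALSE)
    for (cv in covariates) {
      col <- cov_frame[[cv]][keep]
      if (is.factor(col)) col <- droplevels(col)
      degenerate <- if (is.factor(col)) nlevels(col) < 2 else
        stats::var(col) == 0
      if (degenerate) {
        return(null_row(v, type, n, winfo$name,
                        paste0("zero_variance_covariate:", cv)))
      }
      mf[[cv]] <- col
    }
    if (is.factor(mf$.x)) {
      mf$.x <- droplevels(mf$.x)
      if (nlevels(mf$.x) < 2) {
        return(null_row(v, type, n, winfo$name, "single_level"))
      }
    }
    yk <- y_raw[keep]
    wk <- if (is.null(winfo$w)) NULL else winfo$w[keep]
    idx <- which(keep)
    k_levels <- if (is.factor(mf$.x)) nlevels(mf$.x) else 2L
    res <- tryCatch({
      if (!is.factor(mf$.x) || k_levels == 2L) {
        test_quantitative_predictor(yk, mf, family, design, idx, wk)
      } else {
        test_categorical_predictor(yk, mf, family, design, idx, wk,
                                   categorical_test)
      }
    }, error = function(e) list(skip = conditionMessage(e)))
    if (!is.null(res$skip)) {
      reason <- if (grepl("collinear", res$skip)) "collinear" else res$skip
      return(null_row(v, type, n, winfo$name, reason))
    }
    data.frame(variable = v, type = type, n = as.integer(n),
               beta = res$beta, se = res$se, pvalue = res$pvalue,
               lrt_pvalue = res$lrt_pvalue, converged = res$converged,
               weight_name = winfo$name, skip_reason = NA_character_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  structure(out,
            class = c("ewas_result", "data.frame"),
            outcome = outcome, covariates = covariates, family = family,
            min_n = as.integer(min_n),
            design_based = !is.null(design))
}

# Model matrices: intercept, exposure term(s), covariate terms.
build_model_matrices <- function(mf) {
  full <- stats::model.matrix(~ ., data = mf)
  covs <- mf[, setdiff(names(mf), ".x"), drop = FALSE]
  reduced <- if (ncol(covs)) {
    stats::model.matrix(~ ., data = covs)
  } else {
    matrix(1, nrow(mf), 1, dimnames = list(NULL, "(Intercept)"))
  }
  xcols <- grep("^\\.x", colnames(full))
  list(full = full, reduced = reduced, xcols = xcols)
}

#' Single-coefficient test for a continuous or binary exposure
#'
#' Fits `Y ~ intercept + X + covariates` and reports the exposure
#' coefficient, its standard error (classical covariance without a design;
#' linearized covariance with one) and a two-sided p-value from a t
#' reference (residual df without a design; `design_df - (p - 1)`, floored
#' at 1, with one).
#'
#' @param y Response values for the analysis subset.
#' @param mf Data frame with column `.x` (the exposure, numeric or 2-level
#'   factor) and covariate columns.
#' @param family,design As in [ewas()].
#' @param idx Positions of the subset rows within the design.
#' @param weights Subset weights (NULL = unit).
#' @return List with `beta`, `se`, `pvalue`, `lrt_pvalue` (NA), `converged`.
#' @export
test_quantitative_predictor <- function(y, mf, family = "gaussian",
                                        design = NULL, idx = NULL,
                                        weights = NULL) {
  mm <- build_model_matrices(mf)
  fit <- fit_design_glm(y, mm$full, family, design, idx, weights)
  j <- mm$xcols[1]
  beta <- unname(fit$coefficients[j])
  se <- sqrt(fit$vcov[j, j])
  tstat <- beta / se
  pvalue <- 2 * stats::pt(-abs(tstat), df = fit$df_inference)
  list(beta = beta, se = se, pvalue = pvalue, lrt_pvalue = NA_real_,
       converged = fit$converged)
}

#' Term test for a categorical exposure (3+ levels)
#'
#' Without a design: likelihood-ratio test of the full model against the
#' reduced model (covariates only; intercept-only when there are no
#' covariates), both fit on the identical subset; `2(l_full - l_reduced)` is
#' referred to chi-squared with k-1 df. With a design: Wald F test of joint
#' nullity of the k-1 dummy coefficients using the linearized covariance,
#' with numerator df k-1 and denominator df `design_df - (p_full - 1)`
#' (floored at 1) — the pseudo-likelihood ratio is not chi-squared
#' calibrated under weighting.
#'
#' @inheritParams test_quantitative_predictor
#' @param method `"auto"`, `"lrt"`, or `"wald"`.
#' @return List with `lrt_pvalue` (the term p-value), `beta`/`se`/`pvalue`
#'   NA, and `converged`.
#' @export
test_categorical_predictor <- function(y, mf, family = "gaussian",
                                       design = NULL, idx = NULL,
                                       weights = NULL, method = "auto") {
  if (method == "auto") method <- if (is.null(design)) "lrt" else "wald"
  mm <- build_model_matrices(mf)
  k1 <- length(mm$xcols)  # k - 1 dummy columns
  fit_full <- fit_design_glm(y, mm$full, family, design, idx, weights)
  if (method == "lrt") {
    fit_red <- fit_design_glm(y, mm$reduced, family, design, idx, weights)
    lambda <- 2 * (fit_full$loglik - fit_red$loglik)
    p <- stats::pchisq(pmax(lambda, 0), df = k1, lower.tail = FALSE)
    conv <- fit_full$converged && fit_red$converged
  } else {
    b <- fit_full$coefficients[mm$xcols]
    Vg <- fit_full$vcov[mm$xcols, mm$xcols, drop = FALSE]
    Fstat <- drop(t(b) %*% solve(Vg, b)) / k1
    p <- stats::pf(Fstat, k1, fit_full$df_inference, lower.tail = FALSE)
    conv <- fit_full$converged
  }
  list(beta = NA_real_, se = NA_real_, pvalue = NA_real_,
       lrt_pvalue = p, converged = conv)
}

# -- multiple testing ----------------------------------------------------------

#' The raw p-value tested for each result row
#'
#' Continuous/binary rows carry `pvalue`; categorical rows carry
#' `lrt_pvalue`. This returns whichever is populated (NA for NULL rows).
#'
#' @param results An `ewas_result`.
#' @return Numeric vector aligned with the rows.
#' @export
raw_pvalues <- function(results) {
  ifelse(!is.na(results$pvalue), results$pvalue, results$lrt_pvalue)
}

#' Attach Bonferroni and Benjamini-Hochberg corrected p-values
#'
#' By default `m` is the number of tests actually computed in the table
#' (NULL rows are excluded from `m` and receive no corrected values).
#' Bonferroni: `min(1, m * p)`. FDR: Benjamini-Hochberg step-up q-values.
#'
#' @param results An `ewas_result` with at least one computed p-value.
#' @param m Family size for the correction; override the default when the
#'   table holds only a subset of a larger test family (e.g. the top hits
#'   extracted from a full analysis).
#' @return The table with columns `pvalue_bonferroni` and `pvalue_fdr`
#'   appended; the family size is stored in attribute `n_tests`.
#' @export
add_corrected_pvalues <- function(results, m = NULL) {
  p <- raw_pvalues(results)
  ok <- !is.na(p)
  if (!any(ok)) stop("no computed p-values to correct", call. = FALSE)
  if (is.null(m)) m <- sum(ok)
  if (m < sum(ok)) stop("m cannot be smaller than the number of computed ",
                        "p-values", call. = FALSE)
  results$pvalue_bonferroni <- NA_real_
  results$pvalue_fdr <- NA_real_
  results$pvalue_bonferroni[ok] <- stats::p.adjust(p[ok],
                                                   method = "bonferroni",
                                                   n = m)
  results$pvalue_fdr[ok] <- stats::p.adjust(p[ok], method = "BH", n = m)
  attr(results, "n_tests") <- m
  results
}

#' @export
print.ewas_result <- function(x, ...) {
  cat("ewas_result: ", nrow(x), " exposures, outcome '",
      attr(x, "outcome"), "', family ", attr(x, "family"),
      if (isTRUE(attr(x, "design_based"))) ", design-based", "\n", sep = "")
  print.data.frame(utils::head(as.data.frame(x), 10))
  if (nrow(x) > 10) cat("... ", nrow(x) - 10, " more rows\n")
  invisible(x)
}

#' Write / read an EWAS result table as TSV
#' @param results An `ewas_result`.
#' @param path File path.
#' @export
save_results <- function(results, path) {
  utils::write.table(as.data.frame(results), path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' @rdname save_results
#' @return `read_results` returns the table as an `ewas_result`.
#' @export
read_results <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, na.strings = "NA")
  class(df) <- c("ewas_result", "data.frame")
  df
}
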