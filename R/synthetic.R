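# -- synthetic survey-data generator -------------------------------------------
#
# Emulates the structure of a stratified two-stage health survey: mixed-type
# exposures with known linear effects on a continuous outcome, covariates
# (age, sex, race), cluster random intercepts, and informative Poisson
# sampling (inclusion probability tied to the outcome) with inverse-
# probability weights. Every generated dataset carries a truth_record
# sufficient to recompute expected QC and recovery outcomes.

#' Parameters for the synthetic survey generator
#'
#' @param seed Mandatory integer seed; the generator is byte-reproducible.
#' @param n_samples Target (expected) sample size after selection
#'   (default 2000).
#' @param oversample Population-to-sample size ratio (default 3).
#' @param n_strata,clusters_per_stratum Design structure (defaults 15 and 2,
#'   the shape of a national health-survey cycle).
#' @param n_continuous,n_binary,n_categorical Exposure counts (defaults 35,
#'   10, 5; exposures are named `cont01..`, `bin01..`, `cat01..`).
#' @param effects Named numeric vector of true effect sizes. Default: 0.3 on
#'   the first 10 continuous exposures. Categorical effects are expanded to
#'   level offsets summing to zero.
#' @param categorical_levels Levels per categorical exposure (default 3).
#' @param cluster_sd SD of the cluster (PSU) random intercept (default 0.25).
#' @param covariate_effects Outcome effects of age (per year), sex, and the
#'   five race levels.
#' @param intercept,outcome_sd Outcome intercept and residual SD.
#' @param gamma Informative-sampling strength: inclusion log-odds change by
#'   `2 * gamma` per SD of the outcome (0 = noninformative, constant
#'   weights; 1 = strongly informative).
#' @param min_inclusion Lower bound on the inclusion probability (default
#'   0.05), the usual positivity requirement; it bounds the weights and
#'   keeps the inverse-probability estimator's variance finite.
#' @param missing_rate Per-cell missingness rate applied to exposures.
#' @param sentinels Optional named character vector (exposure -> code):
#'   missing cells in those exposures carry the sentinel code instead of
#'   being blank, for [standardize_missing()] exercises.
#' @param zero_inflation Optional named numeric vector (continuous exposure
#'   -> zero fraction).
#' @return A validated `generator_params` list.
#' @export
generator_params <- function(seed,
                             n_samples = 2000L, oversample = 3,
                             n_strata = 15L, clusters_per_stratum = 2L,
                             n_continuous = 35L, n_binary = 10L,
                             n_categorical = 5L,
                             effects = NULL, categorical_levels = 3L,
                             cluster_sd = 0.25,
                             covariate_effects = list(
                               age = 0.01, sex = 0.2,
                               race = c(0, 0.3, 0.5, 0.2, 0.1)),
                             intercept = 2, outcome_sd = 1,
                             gamma = 1, min_inclusion = 0.05,
                             missing_rate = 0,
                             sentinels = NULL, zero_inflation = NULL) {
  if (missing(seed)) stop("seed is mandatory", call. = FALSE)
  if (is.null(effects)) {
    k <- min(10L, n_continuous)
    effects <- stats::setNames(rep(0.3, k), sprintf("cont%02d", seq_len(k)))
  }
  rates <- c(missing_rate, unname(zero_inflation))
  stopifnot(n_samples > 0, oversample >= 1, n_strata >= 1,
            clusters_per_stratum >= 1,
            all(rates >= 0 & rates <= 1), gamma >= 0,
            min_inclusion >= 0, min_inclusion < 1,
            outcome_sd > 0, categorical_levels >= 2)
  p <- list(seed = as.integer(seed), n_samples = as.integer(n_samples),
            oversample = oversample, n_strata = as.integer(n_strata),
            clusters_per_stratum = as.integer(clusters_per_stratum),
            n_continuous = as.integer(n_continuous),
            n_binary = as.integer(n_binary),
            n_categorical = as.integer(n_categorical),
            effects = effects, categorical_levels = as.integer(categorical_levels),
            cluster_sd = cluster_sd, covariate_effects = covariate_effects,
            intercept = intercept, outcome_sd = outcome_sd, gamma = gamma,
            min_inclusion = min_inclusion,
            missing_rate = missing_rate, sentinels = sentinels,
            zero_inflation = zero_inflation)
  exposure_names <- c(sprintf("cont%02d", seq_len(n_continuous)),
                      sprintf("bin%02d", seq_len(n_binary)),
                      sprintf("cat%02d", seq_len(n_categorical)))
  unknown <- setdiff(names(effects), exposure_names)
  if (length(unknown)) {
    stop("effects name unknown exposure(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  structure(p, class = "generator_params")
}

with_generator_seed <- function(seed, code) {
  withr::with_seed(seed, code,
                   .rng_kind = "Mersenne-Twister",
                   .rng_normal_kind = "Inversion",
                   .rng_sample_kind = "Rejection")
}

#' Generate a survey-structured mixed-type dataset with known truth
#'
#' Draws a finite population with stratum/PSU structure, mixed-type
#' exposures, covariates and a linear continuous outcome, then selects a
#' sample by informative Poisson sampling (inclusion probability increasing
#' in the outcome when `gamma > 0`) and attaches inverse-probability weights
#' plus the design labels. The returned `truth` record is the oracle for
#' recovery tests: it echoes the parameters and holds the realized true
#' effects, inclusion probabilities and weights.
#'
#' @param params A [generator_params()].
#' @return List with `data` (a [raw_dataset()] containing exposures,
#'   covariates `age`/`sex`/`race`, `outcome`, and design columns
#'   `stratum`/`psu`/`weight`) and `truth` (a `truth_record`).
#' @export
generate_survey_dataset <- function(params) {
  stopifnot(inherits(params, "generator_params"))
  p <- params
  with_generator_seed(p$seed, {
    N <- round(p$n_samples * p$oversample)
    stratum <- sprintf("S%02d", sample.int(p$n_strata, N, replace = TRUE))
    psu_in <- sample.int(p$clusters_per_stratum, N, replace = TRUE)
    psu <- paste0(stratum, "_C", psu_in)
    psu_levels <- sort(unique(psu))
    re <- stats::setNames(stats::rnorm(length(psu_levels), 0, p$cluster_sd),
                          psu_levels)

    age <- stats::rnorm(N, 45, 15)
    sex <- stats::rbinom(N, 1, 0.5)
    race_levels <- paste0("R", 1:5)
    race <- sample(race_levels, N, replace = TRUE,
                   prob = c(0.47, 0.19, 0.25, 0.05, 0.04))

    cont_names <- sprintf("cont%02d", seq_len(p$n_continuous))
    bin_names <- sprintf("bin%02d", seq_len(p$n_binary))
    cat_names <- sprintf("cat%02d", seq_len(p$n_categorical))
    X <- list()
    for (v in cont_names) X[[v]] <- stats::rnorm(N)
    for (v in bin_names) X[[v]] <- stats::rbinom(N, 1, 0.5)
    k <- p$categorical_levels
    for (v in cat_names) X[[v]] <- paste0("L", sample.int(k, N, replace = TRUE))

    for (v in names(p$zero_inflation)) {
      frac <- p$zero_inflation[[v]]
      X[[v]][stats::runif(N) < frac] <- 0
    }

    lin <- p$intercept + p$covariate_effects$age * (age - 45) +
      p$covariate_effects$sex * sex +
      p$covariate_effects$race[match(race, race_levels)] +
      re[psu]
    cat_offsets <- list()
    for (v in names(p$effects)) {
      b <- p$effects[[v]]
      if (v %in% cat_names) {
        off <- b * (seq_len(k) - (k + 1) / 2)  # sums to zero
        cat_offsets[[v]] <- stats::setNames(off, paste0("L", seq_len(k)))
        lin <- lin + off[match(X[[v]], paste0("L", seq_len(k)))]
      } else {
        lin <- lin + b * X[[v]]
      }
    }
    y <- lin + stats::rnorm(N, 0, p$outcome_sd)

    z <- (y - mean(y)) / stats::sd(y)
    p_rel <- stats::plogis(2 * p$gamma * z)
    pi <- pmin(pmax(p_rel * (p$n_samples / sum(p_rel)), p$min_inclusion),
               0.99)
    sel <- stats::runif(N) < pi
    n <- sum(sel)
    weight <- 1 / pi[sel]

    df <- data.frame(ID = sprintf("P%05d", which(sel)),
                     stringsAsFactors = FALSE)
    for (v in c(cont_names, bin_names, cat_names)) df[[v]] <- X[[v]][sel]
    df$age <- age[sel]; df$sex <- sex[sel]; df$race <- race[sel]
    df$outcome <- y[sel]
    df$stratum <- stratum[sel]; df$psu <- psu[sel]; df$weight <- weight

    # Exposure missingness (never the outcome, covariates or design columns),
    # optionally encoded as a sentinel token.
    if (p$missing_rate > 0) {
      for (v in c(cont_names, bin_names, cat_names)) {
        hit <- stats::runif(n) < p$missing_rate
        if (!is.null(p$sentinels) && v %in% names(p$sentinels)) {
          df[[v]][hit] <- p$sentinels[[v]]
        } else {
          df[[v]][hit] <- NA
        }
      }
    }

    true_beta <- stats::setNames(numeric(length(c(cont_names, bin_names))),
                                 c(cont_names, bin_names))
    known <- intersect(names(p$effects), names(true_beta))
    true_beta[known] <- p$effects[known]

    data <- raw_dataset(df, id_column = "ID")
    data <- log_op(data, "generate_survey_dataset",
                   params = list(seed = p$seed, n = n),
                   variables_affected = variable_names(data),
                   samples_affected = n)
    truth <- structure(
      list(params = unclass(p), n_realized = n,
           true_beta = as.list(true_beta),
           categorical_offsets = lapply(cat_offsets, as.list),
           sample_ids = df$ID,
           inclusion_prob = pi[sel], weights = weight,
           design_columns = c("stratum", "psu", "weight"),
           outcome = "outcome", covariates = c("age", "sex", "race"),
           tripwires = NULL),
      class = "truth_record")
    list(data = data, truth = truth)
  })
}

#' Generate the QC tripwire fixture
#'
#' A dataset in which one variable is engineered to trip each QC rule, plus
#' boundary survivors and clean variables of every type: a continuous
#' variable with 199 non-missing values (minimum-N victim) and one with
#' exactly 200 (boundary survivor); a binary variable with a 150-count level
#' (per-category victim) and one with an exact 200-count level (survivor); a
#' continuous variable with 95% zeros (percent-zero victim) and one with
#' exactly 90% (survivor); an 8-distinct-value variable (check queue); a
#' constant and an all-missing variable (degenerate). The truth record lists
#' each tripwire and the rule expected to remove it.
#'
#' @param seed Integer seed.
#' @param n_samples Number of samples (default 1000).
#' @return List with `data` (a [raw_dataset()], including an `outcome`
#'   driven by `keep_continuous`) and `truth` (a `truth_record` whose
#'   `tripwires` maps variable -> expected filter).
#' @export
generate_filter_tripwires <- function(seed, n_samples = 1000L) {
  n <- as.integer(n_samples)
  stopifnot(n >= 600)
  with_generator_seed(seed, {
    keep_continuous <- stats::rnorm(n)
    trip_min_n <- stats::rnorm(n)
    trip_min_n[sample.int(n, n - 199L)] <- NA
    keep_min_n_boundary <- stats::rnorm(n)
    keep_min_n_boundary[sample.int(n, n - 200L)] <- NA
    trip_min_cat_n <- sample(rep(c("A", "B"), c(n - 150L, 150L)))
    keep_min_cat_n_boundary <- sample(rep(c("A", "B"), c(200L, n - 200L)))
    trip_percent_zero <- sample(c(rep(0, round(0.95 * n)),
                                  stats::runif(n - round(0.95 * n), 1, 2)))
    keep_percent_zero_boundary <- sample(c(rep(0, round(0.90 * n)),
                                           stats::runif(n - round(0.90 * n),
                                                        1, 2)))
    df <- data.frame(
      ID = sprintf("T%04d", seq_len(n)),
      outcome = 0.5 * keep_continuous + stats::rnorm(n, 0, 1),
      keep_continuous = keep_continuous,
      keep_binary = sample(rep(0:1, c(n %/% 2, n - n %/% 2))),
      keep_categorical = sample(rep(paste0("G", 1:4),
                                    c(rep(n %/% 4, 3), n - 3 * (n %/% 4)))),
      trip_min_n = trip_min_n,
      keep_min_n_boundary = keep_min_n_boundary,
      trip_min_cat_n = trip_min_cat_n,
      keep_min_cat_n_boundary = keep_min_cat_n_boundary,
      trip_percent_zero = trip_percent_zero,
      keep_percent_zero_boundary = keep_percent_zero_boundary,
      trip_check = sample.int(8L, n, replace = TRUE),
      trip_constant = 1,
      trip_empty = NA_character_,
      stringsAsFactors = FALSE)
    data <- raw_dataset(df, id_column = "ID")
    data <- log_op(data, "generate_filter_tripwires",
                   params = list(seed = seed, n = n),
                   variables_affected = variable_names(data),
                   samples_affected = n)
    tripwires <- list(trip_min_n = "min_n",
                      trip_min_cat_n = "min_cat_n",
                      trip_percent_zero = "percent_zero",
                      trip_check = "check",
                      trip_constant = "degenerate",
                      trip_empty = "degenerate")
    expected_types <- list(outcome = "continuous",
                           keep_continuous = "continuous",
                           keep_binary = "binary",
                           keep_categorical = "categorical",
                           trip_min_n = "continuous",
                           keep_min_n_boundary = "continuous",
                           trip_min_cat_n = "binary",
                           keep_min_cat_n_boundary = "binary",
                           trip_percent_zero = "continuous",
                           keep_percent_zero_boundary = "continuous",
                           trip_check = "check",
                           trip_constant = "constant",
                           trip_empty = "empty")
    truth <- structure(
      list(params = list(seed = as.integer(seed), n_samples = n),
           n_realized = n, true_beta = list(keep_continuous = 0.5),
           sample_ids = df$ID, tripwires = tripwires,
           expected_types = expected_types,
           outcome = "outcome"),
      class = "truth_record")
    list(data = data, truth = truth)
  })
}

#' @export
print.truth_record <- function(x, ...) {
  cat("truth_record: n =", x$n_realized, "\n")
  nz <- Filter(function(b) b != 0, x$true_beta)
  cat("  nonzero effects:", length(nz), "\n")
  if (!is.null(x$tripwires)) {
    cat("  tripwires:", paste(names(x$tripwires), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Serialize / restore a truth record as JSON
#' @param truth A `truth_record`.
#' @param path File path.
#' @export
save_truth <- function(truth, path) {
  jsonlite::write_json(unclass(truth), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname save_truth
#' @return `read_truth` returns the `truth_record`.
#' @export
read_truth <- function(path) {
  structure(jsonlite::read_json(path, simplifyVector = TRUE),
            class = "truth_record")
}
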