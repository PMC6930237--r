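# -- survey design -------------------------------------------------------------
#
# Design-based analysis under stratified, clustered, weighted sampling.
# Point estimates come from weighted maximum pseudo-likelihood; covariance
# from Taylor-series linearization in the with-replacement approximation
# (cluster totals of weighted score contributions, no finite-population
# correction). Inference uses a t reference with df = (#PSUs - #strata)
# - (p - 1), floored at 1.

#' Build a complex sampling design from dataset columns
#'
#' @param data A `raw_dataset` whose columns include the design variables.
#' @param strata_var Column holding stratum labels, or `NULL` for a single
#'   stratum.
#' @param cluster_var Column holding PSU (cluster) labels, or `NULL` for one
#'   PSU per sample. A cluster label must appear in exactly one stratum.
#' @param weight_spec `NULL` (unit weights), the name of one weight column,
#'   or a named character vector mapping tested-variable names to weight
#'   columns (heterogeneous subsample weights). Weights must be nonnegative;
#'   a missing weight excludes that sample from any fit using it.
#' @param lonely_psu Policy for strata containing a single PSU:
#'   `"fail"` (default — error), `"adjust"` (center that stratum's score
#'   total at the grand mean of all cluster totals), or `"certainty"`
#'   (the stratum contributes no between-cluster variance).
#' @return A `survey_design` object.
#' @export
build_design <- function(data, strata_var = NULL, cluster_var = NULL,
                         weight_spec = NULL,
                         lonely_psu = c("fail", "adjust", "certainty")) {
  lonely_psu <- match.arg(lonely_psu)
  stopifnot(inherits(data, "raw_dataset"))
  n <- n_samples(data)
  strata <- if (is.null(strata_var)) rep("_stratum_", n) else {
    check_vars_exist(data, strata_var)
    variable_values(data, strata_var)
  }
  clusters <- if (is.null(cluster_var)) sample_ids(data) else {
    check_vars_exist(data, cluster_var)
    variable_values(data, cluster_var)
  }
  if (anyNA(strata) || anyNA(clusters)) {
    stop("missing stratum or cluster label", call. = FALSE)
  }
  span <- tapply(strata, clusters, function(s) length(unique(s)))
  if (any(span > 1)) {
    stop("cluster(s) spanning multiple strata: ",
         paste(names(span)[span > 1], collapse = ", "), call. = FALSE)
  }
  weight_cols <- unique(if (is.null(weight_spec)) character()
                        else unname(weight_spec))
  weights <- lapply(weight_cols, function(wc) {
    check_vars_exist(data, wc)
    w <- variable_values(data, wc, as = "numeric", quiet = TRUE)
    if (any(!is.na(w) & w < 0)) {
      stop("negative weight in column '", wc, "'", call. = FALSE)
    }
    w
  })
  names(weights) <- weight_cols
  weight_map <- if (length(weight_spec) && !is.null(names(weight_spec))) {
    weight_spec
  } else NULL
  default_weight <- if (is.null(weight_map) && length(weight_spec) == 1) {
    unname(weight_spec)
  } else NULL
  structure(
    list(sample_ids = sample_ids(data), strata = strata, clusters = clusters,
         weights = weights, weight_map = weight_map,
         default_weight = default_weight, lonely_psu = lonely_psu,
         source_columns = c(strata_var, cluster_var, weight_cols)),
    class = "survey_design")
}

#' @export
print.survey_design <- function(x, ...) {
  per <- table(tapply(x$clusters, x$strata, function(cl) length(unique(cl))))
  cat("survey_design: ", length(x$sample_ids), " samples, ",
      length(unique(x$strata)), " strata, ",
      length(unique(paste(x$strata, x$clusters))), " PSUs\n", sep = "")
  cat("  clusters per stratum: ",
      paste(names(per), "PSU x", as.integer(per), collapse = ", "), "\n")
  for (wc in names(x$weights)) {
    w <- x$weights[[wc]]
    cat("  weight '", wc, "': range [",
        format(min(w, na.rm = TRUE)), ", ", format(max(w, na.rm = TRUE)),
        "], ", sum(is.na(w)), " missing\n", sep = "")
  }
  cat("  lonely PSU policy:", x$lonely_psu, "\n")
  invisible(x)
}

# Per-sample weights to use when testing `variable` (NULL -> default/unit).
design_weights <- function(design, variable = NULL) {
  if (!is.null(design$weight_map) && !is.null(variable) &&
      variable %in% names(design$weight_map)) {
    wname <- design$weight_map[[variable]]
  } else if (!is.null(design$default_weight)) {
    wname <- design$default_weight
  } else if (!is.null(design$weight_map) && !is.null(variable)) {
    stop("no weight mapped for variable '", variable, "'", call. = FALSE)
  } else {
    return(list(name = NA_character_,
                w = rep(1, length(design$sample_ids))))
  }
  list(name = wname, w = design$weights[[wname]])
}

# Restrict a design to a subset of samples (by position index).
design_subset <- function(design, idx) {
  design$sample_ids <- design$sample_ids[idx]
  design$strata <- design$strata[idx]
  design$clusters <- design$clusters[idx]
  design$weights <- lapply(design$weights, function(w) w[idx])
  design
}

#' Design degrees of freedom
#'
#' The conventional design-based df: number of distinct PSUs minus number of
#' distinct strata over the (sub)design.
#'
#' @param design A `survey_design`.
#' @param idx Optional integer/logical index restricting to a fitted subset.
#' @return Integer df.
#' @export
design_df <- function(design, idx = NULL) {
  stopifnot(inherits(design, "survey_design"))
  if (!is.null(idx)) design <- design_subset(design, idx)
  length(unique(paste(design$strata, design$clusters, sep = "\r"))) -
    length(unique(design$strata))
}

# -- weighted GLM fitting ------------------------------------------------------

# Report which columns break full rank, by QR pivoting.
check_full_rank <- function(X) {
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("model matrix is rank deficient; collinear column(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  invisible(TRUE)
}

wls_solve <- function(X, z, w) {
  sw <- sqrt(w)
  qr.coef(qr(X * sw), z * sw)
}

#' Fit a weighted generalized linear model (maximum pseudo-likelihood)
#'
#' Point estimation for design-based regression: coefficients maximize the
#' weighted log-likelihood `sum_i w_i l_i(beta)`. Gaussian models solve
#' weighted least squares in closed form; binomial (logit) models use
#' iteratively reweighted least squares to a gradient tolerance of 1e-8 with
#' at most 25 iterations (non-convergence is flagged, not raised). Rows must
#' already be complete cases with strictly positive weights.
#'
#' @param y Numeric response (0/1 for binomial).
#' @param X Model matrix with column names, full column rank.
#' @param family `"gaussian"` or `"binomial"`.
#' @param weights Positive per-row weights.
#' @return A `fit_result` with coefficients, pseudo-log-likelihood, fitted
#'   means, convergence flag and the ingredients for [linearized_covariance()].
#' @export
fit_weighted_glm <- function(y, X, family = c("gaussian", "binomial"),
                             weights = rep(1, length(y))) {
  family <- match.arg(family)
  X <- as.matrix(X)
  stopifnot(length(y) == nrow(X), length(weights) == nrow(X),
            all(weights > 0), !anyNA(y), !anyNA(X))
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  check_full_rank(X)
  w <- weights
  if (family == "gaussian") {
    beta <- wls_solve(X, y, w)
    mu <- drop(X %*% beta)
    W <- sum(w)
    sigma2 <- sum(w * (y - mu)^2) / W
    loglik <- -0.5 * (W * log(2 * pi * sigma2) + W)
    converged <- TRUE
    info_w <- w
  } else {
    stopifnot(all(y %in% c(0, 1)))
    beta <- rep(0, ncol(X))
    converged <- FALSE
    for (iter in seq_len(25L)) {
      eta <- drop(X %*% beta)
      p <- stats::plogis(eta)
      score <- drop(crossprod(X, w * (y - p)))
      if (max(abs(score)) < 1e-8) { converged <- TRUE; break }
      v <- pmax(p * (1 - p), 1e-10)
      z <- eta + (y - p) / v
      beta <- wls_solve(X, z, w * v)
    }
    eta <- drop(X %*% beta)
    p <- stats::plogis(eta)
    if (max(abs(drop(crossprod(X, w * (y - p))))) < 1e-8) converged <- TRUE
    mu <- p
    eps <- 1e-12
    loglik <- sum(w * (y * log(pmax(mu, eps)) +
                         (1 - y) * log(pmax(1 - mu, eps))))
    info_w <- w * pmax(mu * (1 - mu), 0)
  }
  structure(
    list(coefficients = stats::setNames(drop(beta), colnames(X)),
         loglik = loglik, family = family, n = length(y),
         converged = converged, fitted = mu, y = y, X = X,
         prior_weights = w, info_weights = info_w),
    class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat("fit_result (", x$family, "): n = ", x$n,
      ", pseudo-logLik = ", format(x$loglik),
      if (!x$converged) " [NOT CONVERGED]", "\n", sep = "")
  print(x$coefficients)
  invisible(x)
}

# -- Taylor linearization ------------------------------------------------------

#' Taylor-series linearization covariance for a weighted GLM fit
#'
#' Computes the design-based sandwich `V = A^{-1} B A^{-1}`, where `A` is the
#' weighted information `X' diag(w v) X` at the estimate and `B` accumulates
#' between-cluster variability of weighted score totals: with `u_i = w_i
#' (y_i - mu_i) x_i`, cluster totals `z_hc = sum_{i in c} u_i`, and `n_h`
#' clusters in stratum `h`,
#' `B = sum_h n_h/(n_h - 1) sum_c (z_hc - zbar_h)(z_hc - zbar_h)'`.
#' This is the with-replacement approximation (no finite-population
#' correction). Strata with a single PSU trigger the `lonely_psu` policy.
#'
#' @param fit A [fit_weighted_glm()] result.
#' @param strata Per-row stratum labels (aligned with the fitted rows).
#' @param clusters Per-row PSU labels.
#' @param lonely_psu `"fail"`, `"adjust"`, or `"certainty"`.
#' @return Symmetric positive semidefinite covariance matrix for the
#'   coefficients.
#' @export
linearized_covariance <- function(fit, strata = NULL, clusters = NULL,
                                  lonely_psu = c("fail", "adjust",
                                                 "certainty")) {
  lonely_psu <- match.arg(lonely_psu)
  stopifnot(inherits(fit, "fit_result"))
  n <- fit$n
  if (is.null(strata)) strata <- rep("_stratum_", n)
  if (is.null(clusters)) clusters <- as.character(seq_len(n))
  stopifnot(length(strata) == n, length(clusters) == n)
  X <- fit$X
  U <- X * (fit$prior_weights * (fit$y - fit$fitted))
  A <- crossprod(X * sqrt(fit$info_weights))
  key <- paste(strata, clusters, sep = "\r")
  Z <- rowsum(U, key, reorder = FALSE)
  z_stratum <- strata[match(rownames(Z), key)]
  p <- ncol(X)
  B <- matrix(0, p, p)
  grand <- colMeans(Z)
  for (h in unique(z_stratum)) {
    rows <- which(z_stratum == h)
    nh <- length(rows)
    if (nh == 1L) {
      if (lonely_psu == "fail") {
        stop("stratum '", h, "' contains a single PSU ",
             "(set lonely_psu to 'adjust' or 'certainty')", call. = FALSE)
      }
      if (lonely_psu == "adjust") {
        d <- Z[rows, ] - grand
        B <- B + tcrossprod(d)
      }
      next
    }
    Zh <- Z[rows, , drop = FALSE]
    D <- sweep(Zh, 2, colMeans(Zh))
    B <- B + (nh / (nh - 1)) * crossprod(D)
  }
  Ainv <- solve(A)
  V <- Ainv %*% B %*% Ainv
  V <- (V + t(V)) / 2
  dimnames(V) <- list(colnames(X), colnames(X))
  V
}

# Full design-based fit: estimate + covariance + inference df.
# idx restricts design rows to the fitted subset (positions in the design).
fit_design_glm <- function(y, X, family, design = NULL, idx = NULL,
                           weights = NULL) {
  if (is.null(design)) {
    fit <- fit_weighted_glm(y, X, family,
                            weights = if (is.null(weights))
                              rep(1, length(y)) else weights)
    fit$vcov <- classical_covariance(fit)
    fit$df_inference <- length(y) - ncol(as.matrix(X))
    fit$design_based <- FALSE
    return(fit)
  }
  sub <- design_subset(design, idx)
  fit <- fit_weighted_glm(y, X, family, weights = weights)
  fit$vcov <- linearized_covariance(fit, sub$strata, sub$clusters,
                                    lonely_psu = sub$lonely_psu)
  ddf <- design_df(sub)
  fit$df_inference <- max(1, ddf - (length(fit$coefficients) - 1))
  fit$design_based <- TRUE
  fit
}

# Classical (model-based) covariance for the no-design path.
classical_covariance <- function(fit) {
  X <- fit$X
  if (fit$family == "gaussian") {
    rdf <- fit$n - ncol(X)
    sigma2 <- sum(fit$prior_weights * (fit$y - fit$fitted)^2) / rdf
    V <- sigma2 * solve(crossprod(X * sqrt(fit$prior_weights)))
  } else {
    V <- solve(crossprod(X * sqrt(fit$info_weights)))
  }
  dimnames(V) <- list(colnames(X), colnames(X))
  V
}
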