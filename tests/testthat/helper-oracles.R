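# Independent oracle implementations used across the suite. These are
# deliberately written with textbook formulas and scalar loops, sharing no
# code with the package's fit/covariance/correction paths.

# Closed-form OLS: beta = (X'X)^-1 X'y, classical SEs, two-sided t p-values.
ols_oracle <- function(y, X) {
  XtXinv <- solve(t(X) %*% X)
  beta <- unname(drop(XtXinv %*% t(X) %*% y))
  e <- drop(y - X %*% beta)
  n <- length(y)
  p <- ncol(X)
  sigma2 <- sum(e^2) / (n - p)
  se <- unname(sqrt(diag(XtXinv) * sigma2))
  tt <- beta / se
  list(beta = beta, se = se, p = 2 * stats::pt(-abs(tt), n - p), df = n - p)
}

# Heteroskedasticity-robust OLS sandwich, scalar accumulation.
# factor = 1 gives HC0; factor = n/(n-1) matches the degenerate-design
# reduction of the stratified-cluster linearization.
robust_ols_oracle <- function(y, X, factor = 1) {
  XtXinv <- solve(t(X) %*% X)
  beta <- unname(drop(XtXinv %*% t(X) %*% y))
  e <- drop(y - X %*% beta)
  meat <- matrix(0, ncol(X), ncol(X))
  for (i in seq_along(y)) meat <- meat + e[i]^2 * (X[i, ] %o% X[i, ])
  V <- XtXinv %*% meat %*% XtXinv * factor
  list(beta = beta, se = unname(sqrt(diag(V))), V = V)
}

# Scalar-loop evaluation of the stratified-cluster linearization formula at
# a given coefficient vector: V = A^-1 B A^-1 with A = sum_i w_i v_i x x',
# u_i = w_i (y_i - mu_i) x_i, z_hc = within-cluster totals of u, and
# B = sum_h n_h/(n_h-1) sum_c (z_hc - zbar_h)(z_hc - zbar_h)'.
sandwich_oracle <- function(y, X, w, strata, clusters, beta,
                            family = "gaussian") {
  n <- length(y)
  p <- ncol(X)
  eta <- drop(X %*% beta)
  mu <- if (family == "gaussian") eta else stats::plogis(eta)
  v <- if (family == "gaussian") rep(1, n) else mu * (1 - mu)
  A <- matrix(0, p, p)
  for (i in seq_len(n)) A <- A + w[i] * v[i] * (X[i, ] %o% X[i, ])
  U <- matrix(0, n, p)
  for (i in seq_len(n)) U[i, ] <- w[i] * (y[i] - mu[i]) * X[i, ]
  B <- matrix(0, p, p)
  for (h in unique(strata)) {
    cl <- unique(clusters[strata == h])
    nh <- length(cl)
    Z <- matrix(0, nh, p)
    for (j in seq_len(nh)) {
      Z[j, ] <- colSums(U[strata == h & clusters == cl[j], , drop = FALSE])
    }
    zbar <- colMeans(Z)
    for (j in seq_len(nh)) {
      d <- Z[j, ] - zbar
      B <- B + (nh / (nh - 1)) * (d %o% d)
    }
  }
  solve(A) %*% B %*% solve(A)
}

# Brute-force Benjamini-Hochberg step-up by its definition:
# q_(i) = min(1, min_{j >= i} m * p_(j) / j), mapped back to input order.
bh_oracle <- function(p, m = length(p)) {
  ord <- order(p)
  sorted <- p[ord]
  k <- length(sorted)
  qs <- numeric(k)
  for (i in seq_len(k)) {
    qs[i] <- min(1, min(m * sorted[i:k] / seq(i, k)))
  }
  out <- numeric(k)
  out[ord] <- qs
  out
}

# Minimal ewas_result carrying given raw p-values (for correction tests).
make_pvalue_result <- function(pvalue, variable = sprintf("v%03d",
                                                          seq_along(pvalue)),
                               type = "continuous") {
  structure(
    data.frame(variable = variable, type = type, n = 1000L,
               beta = NA_real_, se = NA_real_, pvalue = pvalue,
               lrt_pvalue = NA_real_, converged = TRUE,
               weight_name = NA_character_, skip_reason = NA_character_,
               stringsAsFactors = FALSE),
    class = c("ewas_result", "data.frame"))
}

# Write lines to a temp file and return its path.
tiny_file <- function(lines, ext = ".tsv") {
  f <- tempfile(fileext = ext)
  writeLines(lines, f)
  f
}

# raw_dataset from a plain data.frame with generated IDs.
quick_ds <- function(df) {
  df <- cbind(data.frame(ID = sprintf("S%04d", seq_len(nrow(df))),
                         stringsAsFactors = FALSE), df)
  raw_dataset(df, id_column = "ID")
}

# Sample skewness (moment estimator).
skewness <- function(x) {
  x <- x[!is.na(x)]
  mean((x - mean(x))^3) / (sqrt(mean((x - mean(x))^2)))^3
}

# The canonical QC chain used in examples and end-to-end checks.
qc_chain <- function(typed, min_n = 200, min_cat_n = 200, pct = 0.90) {
  colfilter_percent_zero(
    colfilter_min_cat_n(
      colfilter_min_n(drop_degenerate(typed), min_n),
      min_cat_n),
    pct)
}

# The published top-hit table shipped with the package.
published_hits <- function() {
  utils::read.table(system.file("extdata", "nhanes_bmi_top_hits.tsv",
                                package = "ewaspipe"),
                    header = TRUE, sep = "\t", comment.char = "#",
                    stringsAsFactors = FALSE)
}
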