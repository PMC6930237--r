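test_that("build_design validates structure and reports design df", {
  df <- data.frame(x = rnorm(8),
                   st = rep(c("s1", "s2"), each = 4),
                   cl = rep(c("c1", "c2", "c3", "c4"), each = 2),
                   w = rep(1, 8),
                   wneg = c(-1, rep(1, 7)))
  ds <- quick_ds(df)
  des <- build_design(ds, "st", "cl", "w")
  expect_s3_class(des, "survey_design")
  expect_equal(design_df(des), 4 - 2)

  expect_error(build_design(ds, "st", "cl", "wneg"), "negative weight")
  dfbad <- df
  dfbad$cl <- c("c1", "c1", "c2", "c2", "c1", "c1", "c3", "c3")
  expect_error(build_design(quick_ds(dfbad), "st", "cl", "w"), "spanning")

  # df conventions: no design columns declared -> n - 1
  plain <- build_design(quick_ds(data.frame(x = rnorm(50))))
  expect_equal(design_df(plain), 49)
  # 30 clusters in 15 strata -> 15
  big <- data.frame(st = rep(sprintf("s%02d", 1:15), each = 4),
                    cl = rep(sprintf("c%02d", 1:30), each = 2))
  expect_equal(design_df(build_design(quick_ds(big), "st", "cl")), 15)
  # subset-restricted recount equals a direct label count
  idx <- c(1:10, 31:40)
  sub <- big[idx, ]
  expect_equal(design_df(build_design(quick_ds(big), "st", "cl"), idx),
               length(unique(paste(sub$st, sub$cl))) -
                 length(unique(sub$st)))
})

test_that("equal-weight gaussian fit reduces to closed-form OLS", {
  set.seed(131)
  n <- 40
  X <- cbind("(Intercept)" = 1, x1 = rnorm(n), x2 = runif(n))
  y <- drop(X %*% c(1, 0.5, -2)) + rnorm(n)
  fit <- fit_weighted_glm(y, X, "gaussian")
  want <- ols_oracle(y, X)
  expect_equal(unname(fit$coefficients), want$beta, tolerance = 1e-10)

  # positive rescaling of all weights leaves estimates and V unchanged
  w <- runif(n, 0.5, 3)
  f1 <- fit_weighted_glm(y, X, "gaussian", weights = w)
  f7 <- fit_weighted_glm(y, X, "gaussian", weights = 7 * w)
  expect_equal(f1$coefficients, f7$coefficients, tolerance = 1e-12)
  strata <- rep(c("a", "b"), each = n / 2)
  clusters <- rep(sprintf("k%d", 1:8), length.out = n)
  V1 <- linearized_covariance(f1, strata, clusters)
  V7 <- linearized_covariance(f7, strata, clusters)
  expect_equal(V1, V7, tolerance = 1e-10)

  # rank deficiency is reported with the offending column
  Xbad <- cbind(X, dup = X[, "x1"])
  expect_error(fit_weighted_glm(y, Xbad, "gaussian"), "dup")
})

test_that("weighted logistic fit matches the 2x2 cross-product-ratio closed form", {
  set.seed(141)
  n <- 200
  x <- rbinom(n, 1, 0.5)
  y <- rbinom(n, 1, plogis(-0.5 + 1.2 * x))
  w <- runif(n, 0.5, 4)
  X <- cbind("(Intercept)" = 1, x = x)
  fit <- fit_weighted_glm(y, X, "binomial", weights = w)
  expect_true(fit$converged)
  # saturated 2x2: log odds ratio of the weighted table
  S <- function(xx, yy) sum(w[x == xx & y == yy])
  lor <- log((S(1, 1) / S(1, 0)) / (S(0, 1) / S(0, 0)))
  expect_equal(unname(fit$coefficients["x"]), lor, tolerance = 1e-7)
  # weighted Bernoulli pseudo-log-likelihood at the estimate
  p_hat <- fit$fitted
  expect_equal(fit$loglik,
               sum(w * (y * log(p_hat) + (1 - y) * log(1 - p_hat))),
               tolerance = 1e-8)
})

test_that("degenerate design reduces to the HC sandwich with n/(n-1)", {
  set.seed(151)
  n <- 60
  X <- cbind("(Intercept)" = 1, x = rnorm(n))
  y <- drop(X %*% c(2, 1)) + rnorm(n) * (1 + abs(X[, "x"]))
  fit <- fit_weighted_glm(y, X, "gaussian")
  V <- linearized_covariance(fit)  # one stratum, each row its own PSU
  want <- robust_ols_oracle(y, X, factor = n / (n - 1))
  expect_equal(V, want$V, tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("linearized covariance matches a scalar hand evaluation on 6 rows", {
  # 2 strata x 2 clusters, unequal weights, hand-checkable size
  y <- c(1.0, 2.0, 1.5, 3.0, 2.5, 4.0)
  X <- cbind("(Intercept)" = 1, x = c(0.2, -1.0, 0.5, 1.3, -0.4, 0.8))
  w <- c(1.5, 2.0, 1.0, 3.0, 0.5, 2.5)
  strata <- c("s1", "s1", "s1", "s2", "s2", "s2")
  clusters <- c("c1", "c1", "c2", "c3", "c3", "c4")
  fit <- fit_weighted_glm(y, X, "gaussian", weights = w)
  V <- linearized_covariance(fit, strata, clusters)
  Vhand <- sandwich_oracle(y, X, w, strata, clusters, fit$coefficients)
  expect_equal(V, Vhand, tolerance = 1e-10, ignore_attr = TRUE)
  expect_true(isSymmetric(V))

  # same check for a binomial fit
  yb <- c(0, 1, 0, 1, 1, 0)
  fb <- fit_weighted_glm(yb, X, "binomial", weights = w)
  Vb <- linearized_covariance(fb, strata, clusters)
  Vbhand <- sandwich_oracle(yb, X, w, strata, clusters, fb$coefficients,
                            family = "binomial")
  expect_equal(Vb, Vbhand, tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("splitting every observation in two with half weights preserves estimates", {
  set.seed(161)
  n <- 30
  X <- cbind("(Intercept)" = 1, x = rnorm(n))
  y <- drop(X %*% c(1, -0.7)) + rnorm(n)
  w <- runif(n, 0.5, 2)
  f1 <- fit_weighted_glm(y, X, "gaussian", weights = w)
  f2 <- fit_weighted_glm(rep(y, each = 2), X[rep(1:n, each = 2), ],
                         "gaussian", weights = rep(w / 2, each = 2))
  expect_equal(f1$coefficients, f2$coefficients, tolerance = 1e-10)
  # with duplicates kept in the same cluster, the cluster totals -- and the
  # linearized covariance -- are unchanged too
  clusters <- sprintf("c%02d", rep(1:6, each = 5))
  V1 <- linearized_covariance(f1, rep("s", n), clusters)
  V2 <- linearized_covariance(f2, rep("s", 2 * n), rep(clusters, each = 2))
  expect_equal(V1, V2, tolerance = 1e-10)
})

test_that("lonely PSU strata trigger the configured policy", {
  y <- c(1, 2, 3, 4, 5)
  X <- cbind("(Intercept)" = 1, x = c(0.1, -0.2, 0.4, 1.0, -0.5))
  strata <- c("s1", "s1", "s1", "s1", "s2")   # s2 has a single PSU
  clusters <- c("c1", "c1", "c2", "c2", "c3")
  fit <- fit_weighted_glm(y, X, "gaussian")
  expect_error(linearized_covariance(fit, strata, clusters, "fail"),
               "single PSU")
  Vadj <- linearized_covariance(fit, strata, clusters, "adjust")
  Vcert <- linearized_covariance(fit, strata, clusters, "certainty")
  expect_true(all(eigen(Vadj, symmetric = TRUE)$values >= -1e-10))
  # certainty drops the lonely stratum's contribution, so it cannot exceed
  # the adjusted variance on the diagonal
  expect_true(all(diag(Vcert) <= diag(Vadj) + 1e-12))
})

test_that("covariance is symmetric PSD across random designs (property)", {
  set.seed(171)
  for (rep in 1:20) {
    n <- sample(30:80, 1)
    X <- cbind(1, rnorm(n), runif(n))
    colnames(X) <- c("(Intercept)", "a", "b")
    fam <- sample(c("gaussian", "binomial"), 1)
    y <- if (fam == "gaussian") rnorm(n) else rbinom(n, 1, 0.5)
    w <- runif(n, 0.2, 5)
    ns <- sample(2:4, 1)
    strata <- sample(sprintf("s%d", 1:ns), n, replace = TRUE)
    clusters <- paste0(strata, "_", sample(1:3, n, replace = TRUE))
    # ensure no lonely PSU by construction check; adjust policy otherwise
    fit <- fit_weighted_glm(y, X, fam, weights = w)
    V <- linearized_covariance(fit, strata, clusters, lonely_psu = "adjust")
    expect_true(isSymmetric(V))
    expect_true(all(eigen(V, symmetric = TRUE,
                          only.values = TRUE)$values >= -1e-10))
  }
})

test_that("per-variable weight maps reproduce single-weight designs", {
  gen <- generate_survey_dataset(generator_params(
    seed = 181, n_samples = 800, n_continuous = 2, n_binary = 0,
    n_categorical = 0, effects = c(cont01 = 0.4)))
  d <- gen$data
  # second weight column: a genuinely different (perturbed) weight
  wa <- variable_values(d, "weight", as = "numeric")
  d2df <- data.frame(ID = sample_ids(d),
                     WTB = wa * (1 + 0.5 * sin(seq_along(wa))),
                     check.names = FALSE, stringsAsFactors = FALSE)
  d <- merge_variables(d, raw_dataset(d2df, "ID"))
  typed <- categorize(d)
  des_map <- build_design(d, "stratum", "psu",
                          c(cont01 = "weight", cont02 = "WTB"))
  des_a <- build_design(d, "stratum", "psu", "weight")
  des_b <- build_design(d, "stratum", "psu", "WTB")
  r_map <- ewas(typed, "outcome", c("age", "sex", "race"), design = des_map,
                min_n = 100, exclude = c("WTB"))
  r_a <- ewas(typed, "outcome", c("age", "sex", "race"), design = des_a,
              min_n = 100, exclude = c("WTB"))
  r_b <- ewas(typed, "outcome", c("age", "sex", "race"), design = des_b,
              min_n = 100, exclude = c("WTB"))
  for (col in c("beta", "se", "pvalue")) {
    expect_equal(r_map[[col]][r_map$variable == "cont01"],
                 r_a[[col]][r_a$variable == "cont01"], tolerance = 1e-12)
    expect_equal(r_map[[col]][r_map$variable == "cont02"],
                 r_b[[col]][r_b$variable == "cont02"], tolerance = 1e-12)
  }
  expect_equal(r_map$weight_name[r_map$variable == "cont02"], "WTB")
})

test_that("exchangeable design p-values agree with classical robust OLS", {
  set.seed(191)
  n <- 10000
  nexp <- 30
  Xs <- matrix(rnorm(n * nexp), n, nexp)
  y <- rnorm(n)
  dp <- numeric(nexp)
  for (j in seq_len(nexp)) {
    X <- cbind("(Intercept)" = 1, x = Xs[, j])
    fit <- fit_weighted_glm(y, X, "gaussian")
    V <- linearized_covariance(fit)   # 1 stratum, singleton PSUs
    df_inf <- (n - 1) - 1
    p_design <- 2 * pt(-abs(fit$coefficients["x"] / sqrt(V["x", "x"])),
                       df_inf)
    oracle <- robust_ols_oracle(y, X, factor = 1)
    p_robust <- 2 * pt(-abs(oracle$beta[2] / oracle$se[2]), n - 2)
    dp[j] <- abs(p_design - p_robust)
  }
  expect_lt(median(dp), 0.005)
})
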