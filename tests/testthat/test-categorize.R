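test_that("distinct-value counts classify variables per the threshold rules", {
  n <- 60
  df <- data.frame(
    two = rep(0:1, length.out = n),
    four = rep(letters[1:4], length.out = n),
    five = rep(1:5, length.out = n),
    six = rep(1:6, length.out = n),
    eight = rep(1:8, length.out = n),
    fourteen = rep(1:14, length.out = n),
    fifteen = c(1:15, rep(1, n - 15)),
    fifteen_str = c(paste0("s", 1:15), rep("s1", n - 15)),
    one = rep(7, n),
    none = rep(NA_real_, n),
    stringsAsFactors = FALSE)
  typed <- categorize(quick_ds(df))
  ty <- variable_types(typed)
  expect_equal(unname(ty[c("two", "four", "five", "six", "eight",
                           "fourteen", "fifteen", "fifteen_str",
                           "one", "none")]),
               c("binary", "categorical", "categorical", "check", "check",
                 "check", "continuous", "check", "constant", "empty"))
  # exhaustive partition
  expect_equal(sum(type_counts(typed)), n_variables(typed))
  # missing values never count as a level
  dfm <- data.frame(v = c(0, 1, NA, NA))
  expect_equal(unname(variable_types(categorize(quick_ds(dfm)))["v"]),
               "binary")
})

test_that("type counts on a large simulated table match a brute-force classifier", {
  set.seed(61)
  nvar <- 1000
  nsamp <- 40
  cols <- lapply(seq_len(nvar), function(i) {
    u <- sample.int(20, 1)
    as.character(sample.int(u, nsamp, replace = TRUE))
  })
  names(cols) <- sprintf("v%04d", seq_len(nvar))
  df <- as.data.frame(cols, stringsAsFactors = FALSE)
  typed <- categorize(quick_ds(df))
  # independent classification by direct distinct counting
  brute <- vapply(df, function(x) {
    u <- length(unique(x[!is.na(x)]))
    if (u == 0) "empty" else if (u == 1) "constant"
    else if (u == 2) "binary" else if (u >= 3 && u <= 5) "categorical"
    else if (u >= 15) "continuous" else "check"
  }, character(1))
  expect_identical(unname(variable_types(typed)), unname(brute))
})

test_that("threshold validation enforces 2 < cat_min <= cat_max < cont_min", {
  expect_error(categorize_thresholds(2, 5, 15))
  expect_error(categorize_thresholds(3, 2, 15))
  expect_error(categorize_thresholds(3, 15, 15))
  th <- categorize_thresholds(4, 8, 20)
  ty <- variable_types(categorize(quick_ds(
    data.frame(v = rep(1:3, length.out = 30))), th))
  expect_equal(unname(ty["v"]), "check")
})

test_that("recode_type validates compatibility and survives the sidecar", {
  df <- data.frame(eight = rep(1:8, length.out = 40),
                   three = rep(c("a", "b", "c"), length.out = 40),
                   words = rep(paste0("w", 1:8), length.out = 40),
                   stringsAsFactors = FALSE)
  typed <- categorize(quick_ds(df))
  expect_equal(unname(variable_types(typed)["eight"]), "check")
  typed <- recode_type(typed, "eight", "continuous")
  expect_equal(unname(variable_types(typed)["eight"]), "continuous")
  expect_error(recode_type(typed, "three", "binary"), "exactly 2")
  expect_error(recode_type(typed, "words", "continuous"), "non-numeric")

  f <- tempfile(fileext = ".tsv")
  save_types(typed, f)
  typed2 <- load_types(typed$data, f)
  expect_identical(variable_types(typed2), variable_types(typed))
})

test_that("min-n filter drops below 200 and keeps the boundary", {
  n <- 500
  df <- data.frame(v199 = c(rnorm(199), rep(NA, n - 199)),
                   v200 = c(rnorm(200), rep(NA, n - 200)),
                   full = rnorm(n))
  typed <- categorize(quick_ds(df))
  out <- colfilter_min_n(typed)
  expect_false("v199" %in% variable_names(out))
  expect_true(all(c("v200", "full") %in% variable_names(out)))

  # random missingness: survivors equal the brute-force count filter
  set.seed(71)
  raw <- as.data.frame(lapply(1:20, function(i) {
    x <- rnorm(n)
    x[sample.int(n, sample(250:350, 1))] <- NA
    x
  }))
  names(raw) <- sprintf("r%02d", 1:20)
  t2 <- categorize(quick_ds(raw))
  survivors <- variable_names(colfilter_min_n(t2))
  expect_identical(survivors,
                   names(raw)[colSums(!is.na(raw)) >= 200])
})

test_that("per-category filter enforces minimum level counts on cat/binary only", {
  mk <- function(counts, labels = LETTERS[seq_along(counts)]) {
    sample(rep(labels, counts))
  }
  set.seed(81)
  n <- 699
  df <- data.frame(bad_bin = mk(c(500, 199)),
                   ok_bin = mk(c(200, 499)),
                   bad_cat = sample(rep(c("A", "B", "C"), c(400, 250, 49))),
                   cont = rnorm(n),
                   stringsAsFactors = FALSE)
  typed <- categorize(quick_ds(df))
  out <- colfilter_min_cat_n(typed)
  expect_identical(variable_names(out), c("ok_bin", "cont"))
  # brute-force per-level tally agrees
  expect_true(min(table(df$ok_bin)) >= 200)
  expect_true(min(table(df$bad_cat)) < 200)
  # continuous variables pass untouched even with rare values
  expect_true("cont" %in% variable_names(out))
})

test_that("percent-zero filter uses a strict > threshold on non-missing zeros", {
  n <- 1000
  mkzero <- function(frac) {
    k <- round(frac * n)
    sample(c(rep(0, k), runif(n - k, 1, 2)))
  }
  set.seed(91)
  df <- data.frame(z91 = mkzero(0.91), z90 = mkzero(0.90),
                   z50 = mkzero(0.50))
  typed <- categorize(quick_ds(df))
  expect_true(all(variable_types(typed) == "continuous"))
  out <- colfilter_percent_zero(typed)
  expect_identical(variable_names(out), c("z90", "z50"))

  # missingness does not rescue: denominator is the non-missing count
  v <- mkzero(0.89)
  v[sample(which(v != 0), 50)] <- NA   # zeros now 890/950 > 0.9 of non-missing
  t2 <- categorize(quick_ds(data.frame(v = v)))
  expect_equal(unname(variable_types(t2)["v"]), "continuous")
  expect_equal(n_variables(colfilter_percent_zero(t2)), 0)

  # zero-inflated generator fixture vs brute-force proportions
  zi <- c(c1 = 0.95, c2 = 0.5)
  gen <- generate_survey_dataset(generator_params(
    seed = 5, n_samples = 1200, n_continuous = 3, n_binary = 0,
    n_categorical = 0, effects = c(cont01 = 0),
    zero_inflation = c(cont01 = 0.95, cont02 = 0.5)))
  t3 <- categorize(gen$data)
  keep <- variable_names(colfilter_percent_zero(t3))
  for (v in c("cont01", "cont02", "cont03")) {
    x <- variable_values(gen$data, v, as = "numeric", quiet = TRUE)
    frac <- mean(x[!is.na(x)] == 0)
    expect_equal(v %in% keep, frac <= 0.90, info = v)
  }
})

test_that("filters are idempotent, order-stable, and never alter cells", {
  gen <- generate_filter_tripwires(17)
  typed <- drop_degenerate(categorize(gen$data))
  a <- colfilter_min_cat_n(colfilter_min_n(typed))
  b <- colfilter_min_n(colfilter_min_cat_n(typed))
  expect_identical(sort(variable_names(a)), sort(variable_names(b)))
  expect_identical(variable_names(colfilter_min_n(a)), variable_names(a))
  for (v in variable_names(a)) {
    expect_identical(a$data$values[[v]], typed$data$values[[v]])
  }
})

test_that("frequency tables tally levels and missing to the sample count", {
  df <- data.frame(b = c(rep("0", 6), rep("1", 4)),
                   c = c(rep("x", 3), rep("y", 3), rep("z", 1), NA, NA, NA),
                   stringsAsFactors = FALSE)
  freq <- summarize_frequencies(categorize(quick_ds(df)))
  bt <- freq[freq$variable == "b", ]
  expect_equal(bt$count[match(c("0", "1"), bt$level)], c(6, 4))
  ct <- freq[freq$variable == "c", ]
  expect_equal(ct$count[is.na(ct$level)], 3)
  expect_equal(sum(ct$count), 10)
  # brute-force tallies on a random fixture
  set.seed(101)
  d2 <- data.frame(g = sample(c("a", "b", "c", NA), 200, replace = TRUE),
                   stringsAsFactors = FALSE)
  f2 <- summarize_frequencies(categorize(quick_ds(d2)))
  for (lv in c("a", "b", "c")) {
    expect_equal(f2$count[f2$variable == "g" & !is.na(f2$level) &
                            f2$level == lv],
                 sum(d2$g == lv, na.rm = TRUE))
  }
})

test_that("pairwise correlations match the textbook formula and flag strong pairs", {
  n <- 80
  set.seed(111)
  x <- rnorm(n)
  df <- data.frame(x = x, y2 = 2 * x + 1, neg = -x,
                   z = rnorm(n), w = rnorm(n))
  ct <- summarize_correlations(categorize(quick_ds(df)))
  get_r <- function(a, b) {
    ct$r[(ct$var1 == a & ct$var2 == b) | (ct$var1 == b & ct$var2 == a)]
  }
  expect_equal(get_r("x", "y2"), 1.0)
  expect_equal(get_r("x", "neg"), -1.0)
  expect_true(all(abs(ct$r) <= 1))
  expect_true(ct$flagged[ct$var1 == "x" & ct$var2 == "y2"])
  expect_false(ct$flagged[ct$var1 == "z" & ct$var2 == "w"])
  # textbook formula computed independently on pairwise-complete rows
  df$z[1:10] <- NA
  ct2 <- summarize_correlations(categorize(quick_ds(df)))
  ok <- !is.na(df$z) & !is.na(df$w)
  a <- df$z[ok] - mean(df$z[ok]); b <- df$w[ok] - mean(df$w[ok])
  expect_equal(ct2$r[ct2$var1 == "z" & ct2$var2 == "w"],
               sum(a * b) / sqrt(sum(a^2) * sum(b^2)))
  # pairs with <3 complete observations report NA (both variables keep
  # enough distinct values to stay continuous, but overlap on 2 rows only)
  df3 <- data.frame(z = rnorm(n), w = rnorm(n))
  df3$z[1:23] <- NA
  df3$w[26:n] <- NA
  ct3 <- summarize_correlations(categorize(quick_ds(df3)))
  expect_true(is.na(ct3$r[ct3$var1 == "z" & ct3$var2 == "w"]))
  expect_equal(ct3$n[ct3$var1 == "z" & ct3$var2 == "w"], 2)
  expect_error(summarize_correlations(categorize(quick_ds(
    data.frame(only = rnorm(n))))), "two continuous")
})

test_that("outlier comparison summarizes without modifying the data", {
  df <- data.frame(v = c(0:9, 100) + 0.5, flat = rep(5, 11) + 0:10 * 0)
  df$spread <- seq(-20, 20, length.out = 11)
  typed <- categorize(quick_ds(df), categorize_thresholds(3, 5, 10))
  cells_before <- typed$data$values$v
  cmp <- compare_outlier_removal(typed, k_sd = 3)
  vrow <- cmp[cmp$variable == "v", ]
  expect_equal(vrow$n_excluded, 1)
  expect_equal(vrow$max_after, 9.5)
  expect_identical(typed$data$values$v, cells_before)
  # zero-SD variable flagged, untouched (forced continuous by recode)
  dfc <- data.frame(k = rep(3.3, 20), u = rnorm(20))
  t2 <- recode_type(categorize(quick_ds(dfc)), "k", "continuous")
  c2 <- compare_outlier_removal(t2)
  krow <- c2[c2$variable == "k", ]
  expect_true(krow$zero_sd)
  expect_equal(krow$n_after, krow$n_before)
  # Gaussian fixture: excluded count equals the brute-force mask
  set.seed(121)
  x <- rnorm(400)
  t3 <- categorize(quick_ds(data.frame(x = x)))
  c3 <- compare_outlier_removal(t3, k_sd = 2)
  expect_equal(c3$n_excluded, sum(abs(x - mean(x)) > 2 * sd(x)))
})
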