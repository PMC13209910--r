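# Analytic score equations of the Weibull log-likelihood, used as an
# independent stationarity oracle for the fitter.
weibull_score <- function(times, alpha, beta) {
  w <- (times / alpha)^beta
  n <- length(times)
  c(d_alpha = (beta / alpha) * (sum(w) - n),
    d_beta = n / beta - n * log(alpha) + sum(log(times)) -
      sum(w * log(times / alpha)))
}

test_that("the fit recovers exponential truth from a quantile grid", {
  t <- stats::qweibull(((1:500) - 0.5) / 500, shape = 1, scale = 20)
  f <- fit_weibull(t)
  expect_lt(abs(f$alpha - 20) / 20, 0.02)
  expect_lt(abs(f$beta - 1), 0.02)
  expect_true(f$alpha_ci95[1] < f$alpha && f$alpha < f$alpha_ci95[2])
  expect_true(f$beta_ci95[1] < f$beta && f$beta < f$beta_ci95[2])
})

test_that("degenerate and invalid samples are refused", {
  expect_error(fit_weibull(rep(3.5, 50)), "degenerate")
  expect_error(fit_weibull(c(1, 2, 3)), "fit_min_n")
  expect_error(fit_weibull(c(rep(1, 20), 0)), "positive")
  expect_error(fit_weibull(c(rep(1, 20), -2)), "positive")
})

test_that("fitted parameters zero the analytic score equations", {
  set.seed(21)
  for (i in 1:5) {
    t <- rweibull(200, shape = runif(1, 0.5, 2), scale = runif(1, 5, 100))
    f <- fit_weibull(t)
    sc <- weibull_score(t, f$alpha, f$beta)
    expect_lt(max(abs(sc)), 1e-6)
  }
})

test_that("rescaling times by 7 multiplies alpha by 7 and fixes beta", {
  set.seed(22)
  t <- rweibull(150, shape = 0.8, scale = 12)
  f1 <- fit_weibull(t)
  f7 <- fit_weibull(7 * t)
  expect_equal(f7$alpha, 7 * f1$alpha, tolerance = 1e-8)
  expect_equal(f7$beta, f1$beta, tolerance = 1e-8)
})

test_that("bootstrap CIs are seeded, reproducible, and bracket the estimate", {
  set.seed(23)
  t <- rweibull(60, shape = 0.9, scale = 20)
  f1 <- fit_weibull(t, ci = "bootstrap", boot_n = 200, seed = 5)
  f2 <- fit_weibull(t, ci = "bootstrap", boot_n = 200, seed = 5)
  expect_identical(f1$beta_ci95, f2$beta_ci95)
  expect_true(f1$beta_ci95[1] < f1$beta && f1$beta < f1$beta_ci95[2])
})

test_that("the Weibull median formula matches the quantile function", {
  expect_equal(weibull_median(20, 1), 20 * log(2))
  expect_equal(weibull_median(10, 1e6), 10, tolerance = 1e-4)
  expect_equal(weibull_median(13.41, 0.71),
               stats::qweibull(0.5, shape = 0.71, scale = 13.41))
})

test_that("failure patterns follow the CI position against 1", {
  expect_equal(classify_failure(0.71, c(0.65, 0.77)), "early")
  expect_equal(classify_failure(1.35, c(1.03, 1.71)), "wear-out")
  expect_equal(classify_failure(0.77, c(0.48, 1.13)), "random")
  expect_error(classify_failure(2.0, c(0.5, 1.5)), "bracket")
})

test_that("group comparison handles symmetry, ties, and empty groups", {
  same <- compare_groups(list(g1 = c(1.5, 2.5, 3.5), g2 = c(1.5, 2.5, 3.5)))
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)

  expect_error(compare_groups(list(a = 1:3, b = numeric(0))), "b")

  # tie-corrected H against the textbook formula, on the k + 0.5 grid
  g <- list(a = c(1.5, 1.5, 2.5, 3.5, 3.5), b = c(2.5, 3.5, 4.5, 4.5),
            c = c(0.5, 1.5, 2.5))
  got <- compare_groups(g)
  v <- unlist(g); lab <- rep(names(g), lengths(g))
  r <- rank(v); N <- length(v)
  H <- 12 / (N * (N + 1)) * sum(tapply(r, lab, sum)^2 / table(lab)) -
    3 * (N + 1)
  ties <- table(v)
  H <- H / (1 - sum(ties^3 - ties) / (N^3 - N))
  expect_equal(got$statistic, unname(H), tolerance = 1e-12)
  expect_equal(got$df, 2)
  expect_equal(got$p_value, stats::pchisq(H, 2, lower.tail = FALSE),
               tolerance = 1e-12)
})

test_that("exact two-group permutation p matches the rank-sum null", {
  # no ties, so the enumerated p must equal the exact Wilcoxon p
  set.seed(24)
  x <- sort(runif(4)); y <- sort(runif(5)) + 0.2
  got <- compare_groups(list(x = x, y = y), exact = TRUE)
  ref <- stats::wilcox.test(x, y, exact = TRUE)$p.value
  expect_equal(got$p_value, ref, tolerance = 1e-12)

  # complete separation: 2 of the C(6,3) = 20 splits are as extreme
  sep <- compare_groups(list(a = c(1.5, 2.5, 3.5),
                             b = c(101.5, 102.5, 103.5)), exact = TRUE)
  expect_equal(sep$p_value, 2 / 20)
})

test_that("stratified summaries refuse fits below the minimum n", {
  onset <- data.frame(
    report_id = sprintf("r%02d", 1:21),
    drug_name = "vax",
    t_days = c(347.5, stats::rweibull(20, 0.8, 15) + 0.5),
    gender = c("male", rep("female", 20)),
    age_years = c(15, rep(45, 20)),
    stringsAsFactors = FALSE)
  st <- sm(summarize_by_stratum(onset, "gender"))
  male <- st$summary[st$summary$stratum == "male", ]
  expect_equal(male$n, 1)
  expect_equal(male$median_t, 347.5)     # summary emitted ...
  expect_true(is.na(male$alpha))         # ... but the fit is refused
  fem <- st$summary[st$summary$stratum == "female", ]
  expect_false(is.na(fem$beta))
  expect_true(is.finite(st$p_value))

  # age strata cut at 20 years: < 20 vs >= 20
  sa <- sm(summarize_by_stratum(onset, "age"))
  expect_equal(sa$summary$stratum, c("<20 y", ">=20 y"))
  expect_equal(sa$summary$n, c(1L, 20L))

  # a single non-empty stratum yields summaries but no comparison
  onset$gender <- "female"
  expect_warning(st1 <- sm(summarize_by_stratum(onset, "gender")),
                 "comparison omitted")
  expect_true(is.na(st1$p_value))
})

test_that("the comparison p-value is uniform under the null", {
  set.seed(25)   # identical strata: rejection rate must sit near alpha
  reject <- logical(400)
  for (i in seq_along(reject)) {
    g <- list(a = rweibull(100, 0.8, 15), b = rweibull(100, 0.8, 15))
    reject[i] <- compare_groups(g)$p_value < 0.05
  }
  band <- 3 * sqrt(0.05 * 0.95 / length(reject))
  expect_lt(abs(mean(reject) - 0.05), band)
})
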