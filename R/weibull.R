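# Two-parameter Weibull analysis of onset times. The MLE is computed by
# a safeguarded Newton search on the one-dimensional profile equation
# for the shape (globally monotone for this likelihood), with the scale
# in closed form; 95% CIs are Wald intervals on the log parameters, with
# a seeded percentile-bootstrap alternative.

# Profile score for the shape: g(beta) = A(beta) - 1/beta - mean(log t),
# where A(beta) = sum(t^beta log t) / sum(t^beta). g is strictly
# increasing; times are pre-scaled by their maximum for overflow-free
# evaluation at large beta.
weibull_profile_root <- function(times, tol = 1e-10, max_iter = 200L) {
  M <- max(times)
  ls <- log(times / M)
  Lbar <- mean(ls)
  g <- function(beta) {
    w <- exp(beta * ls)            # (t/M)^beta, in (0, 1]
    A <- sum(w * ls) / sum(w)
    B <- sum(w * ls * ls) / sum(w)
    list(g = A - 1 / beta - Lbar, gp = (B - A * A) + 1 / beta^2)
  }
  lo <- 1e-3; hi <- 1e3
  if (g(hi)$g <= 0) {
    stop("Weibull fit is degenerate: shape diverges (are all times equal?)",
         call. = FALSE)
  }
  beta <- 1
  for (iter in seq_len(max_iter)) {
    ev <- g(beta)
    if (ev$g > 0) hi <- beta else lo <- beta
    step <- ev$g / ev$gp
    beta_new <- beta - step
    if (!is.finite(beta_new) || beta_new <= lo || beta_new >= hi) {
      beta_new <- (lo + hi) / 2   # bisection safeguard
    }
    if (abs(beta_new - beta) / beta < tol) {
      return(beta_new)
    }
    beta <- beta_new
  }
  stop(sprintf("Weibull shape search did not converge (last iterate %.6g)",
               beta), call. = FALSE)
}

weibull_loglik <- function(times, alpha, beta) {
  n <- length(times)
  n * log(beta) - n * beta * log(alpha) +
    (beta - 1) * sum(log(times)) - sum((times / alpha)^beta)
}

#' Fit a two-parameter Weibull distribution to onset times
#'
#' Maximum likelihood for F(t) = 1 - exp(-(t/alpha)^beta): the shape
#' solves the profile equation
#' sum(t^b log t)/sum(t^b) - 1/b = mean(log t) by safeguarded Newton
#' (relative tolerance 1e-10, at most 200 iterations), then
#' alpha = (sum(t^b)/n)^(1/b). Onset times on the k + 0.5 grid are
#' treated as exact values (matching the continuity-correction
#' treatment; no interval-censoring likelihood).
#'
#' 95% CIs are Wald intervals on (log alpha, log beta) from the observed
#' information matrix, exponentiated (`ci = "wald"`), or seeded
#' percentile bootstrap (`ci = "bootstrap"`).
#'
#' @param times positive onset times in days.
#' @param fit_min_n smallest sample size the fit accepts (default 10);
#'   smaller samples are refused with an informative error.
#' @param ci `"wald"` (default) or `"bootstrap"`.
#' @param conf_level CI level (default 0.95).
#' @param boot_n bootstrap resamples (default 2000).
#' @param seed RNG seed for the bootstrap.
#' @return Object of class `weibull_fit`: `alpha`, `alpha_ci95`,
#'   `beta`, `beta_ci95`, `n`, `log_likelihood`, `failure_pattern`
#'   (see [classify_failure()]), and the empirical `median_t`, `min_t`,
#'   `max_t`.
#' @export
#' @examples
#' set.seed(1)
#' fit_weibull(rweibull(200, shape = 0.8, scale = 15))
fit_weibull <- function(times, fit_min_n = 10, ci = c("wald", "bootstrap"),
                        conf_level = 0.95, boot_n = 2000, seed = 1) {
  ci <- match.arg(ci)
  times <- as.numeric(times)
  if (any(!is.finite(times)) || any(times <= 0)) {
    stop("all onset times must be positive and finite", call. = FALSE)
  }
  n <- length(times)
  if (n < fit_min_n) {
    stop(sprintf("refusing to fit: n = %d is below fit_min_n = %d",
                 n, fit_min_n), call. = FALSE)
  }

  beta <- weibull_profile_root(times)
  M <- max(times)
  alpha <- M * (mean(exp(beta * log(times / M))))^(1 / beta)

  z <- qnorm(1 - (1 - conf_level) / 2)
  if (ci == "wald") {
    nll <- function(par) -weibull_loglik(times, exp(par[1]), exp(par[2]))
    H <- optimHess(c(log(alpha), log(beta)), nll)
    V <- solve(H)
    se <- sqrt(pmax(diag(V), 0))
    alpha_ci <- exp(log(alpha) + c(-1, 1) * z * se[1])
    beta_ci <- exp(log(beta) + c(-1, 1) * z * se[2])
  } else {
    old_seed <- if (exists(".Random.seed", .GlobalEnv))
      get(".Random.seed", .GlobalEnv) else NULL
    on.exit(if (!is.null(old_seed))
      assign(".Random.seed", old_seed, .GlobalEnv), add = TRUE)
    set.seed(seed)
    est <- matrix(NA_real_, boot_n, 2)
    for (i in seq_len(boot_n)) {
      ts <- sample(times, n, replace = TRUE)
      bb <- tryCatch(weibull_profile_root(ts), error = function(e) NA_real_)
      if (is.na(bb)) next
      Mb <- max(ts)
      est[i, ] <- c(Mb * (mean(exp(bb * log(ts / Mb))))^(1 / bb), bb)
    }
    probs <- c((1 - conf_level) / 2, 1 - (1 - conf_level) / 2)
    alpha_ci <- unname(quantile(est[, 1], probs, na.rm = TRUE))
    beta_ci <- unname(quantile(est[, 2], probs, na.rm = TRUE))
  }

  structure(list(
    alpha = alpha, alpha_ci95 = alpha_ci,
    beta = beta, beta_ci95 = beta_ci,
    n = n, log_likelihood = weibull_loglik(times, alpha, beta),
    failure_pattern = classify_failure(beta, beta_ci),
    median_t = median(times), min_t = min(times), max_t = max(times),
    ci_method = ci, conf_level = conf_level
  ), class = "weibull_fit")
}

#' @export
print.weibull_fit <- function(x, ...) {
  cat(sprintf("Weibull fit (n = %d): alpha = %.2f (%.2f-%.2f) days, beta = %.2f (%.2f-%.2f)\n",
              x$n, x$alpha, x$alpha_ci95[1], x$alpha_ci95[2],
              x$beta, x$beta_ci95[1], x$beta_ci95[2]))
  cat(sprintf("  failure pattern: %s; empirical median %.1f (%.1f-%.1f) days\n",
              x$failure_pattern, x$median_t, x$min_t, x$max_t))
  invisible(x)
}

#' Classify the hazard (failure) pattern from the shape CI
#'
#' The Weibull shape governs the hazard trend: beta < 1 is a decreasing
#' hazard, beta = 1 constant, beta > 1 increasing. Classification uses
#' the 95% CI position relative to 1: `"early"` iff the upper bound is
#' below 1, `"wear-out"` iff the lower bound is above 1, otherwise
#' `"random"` (the CI contains 1).
#'
#' @param beta shape estimate.
#' @param beta_ci95 length-2 CI bracketing `beta`.
#' @return `"early"`, `"random"` or `"wear-out"`.
#' @export
#' @examples
#' classify_failure(0.71, c(0.65, 0.77))  # early
#' classify_failure(1.35, c(1.03, 1.71))  # wear-out
classify_failure <- function(beta, beta_ci95) {
  stopifnot(length(beta_ci95) == 2, beta_ci95[1] <= beta_ci95[2])
  if (beta < beta_ci95[1] || beta > beta_ci95[2]) {
    stop("beta_ci95 must bracket the point estimate", call. = FALSE)
  }
  if (beta_ci95[2] < 1) "early"
  else if (beta_ci95[1] > 1) "wear-out"
  else "random"
}

#' Median of a Weibull distribution
#'
#' alpha * log(2)^(1/beta) days.
#'
#' @param alpha,beta positive scale (days) and shape.
#' @return Median in days.
#' @export
weibull_median <- function(alpha, beta) {
  stopifnot(alpha > 0, beta > 0)
  alpha * log(2)^(1 / beta)
}

#' Compare onset-time distributions across groups
#'
#' Tie-corrected Kruskal-Wallis test with the chi-square approximation
#' (df = number of groups - 1); for two groups this is the squared
#' normal approximation of the Wilcoxon rank-sum test (no continuity
#' correction). With `exact = TRUE` and two groups, the p-value is
#' computed instead by complete enumeration of group assignments of the
#' pooled ranks (feasible for small samples).
#'
#' @param groups named list of numeric vectors, one per group; at least
#'   two, all non-empty.
#' @param exact use the two-group permutation null (default `FALSE`).
#' @return List: `statistic` (H), `df`, `p_value`, `method`, `n` (per
#'   group sizes).
#' @export
compare_groups <- function(groups, exact = FALSE) {
  stopifnot(is.list(groups), length(groups) >= 2)
  if (is.null(names(groups)) || any(!nzchar(names(groups)))) {
    names(groups) <- paste0("group", seq_along(groups))
  }
  sizes <- vapply(groups, length, integer(1))
  if (any(sizes == 0)) {
    stop(sprintf("empty group(s): %s",
                 paste(names(groups)[sizes == 0], collapse = ", ")),
         call. = FALSE)
  }
  values <- unlist(groups, use.names = FALSE)
  labels <- factor(rep(names(groups), sizes), levels = names(groups))

  kw_stat <- function(v, g) {
    r <- rank(v)
    N <- length(v)
    H <- 12 / (N * (N + 1)) *
      sum(tapply(r, g, sum)^2 / tabulate(g)) - 3 * (N + 1)
    ties <- table(v)
    cor <- 1 - sum(ties^3 - ties) / (N^3 - N)
    if (cor == 0) 0 else H / cor
  }

  if (exact) {
    if (length(groups) != 2) {
      stop("exact enumeration is implemented for two groups only",
           call. = FALSE)
    }
    N <- length(values)
    n1 <- sizes[1]
    if (choose(N, n1) > 2e5) {
      stop("too many permutations for exact enumeration", call. = FALSE)
    }
    H_obs <- kw_stat(values, labels)
    sets <- combn(N, n1)
    H_perm <- apply(sets, 2, function(idx) {
      g <- factor(ifelse(seq_len(N) %in% idx, names(groups)[1],
                         names(groups)[2]), levels = names(groups))
      kw_stat(values, g)
    })
    p <- mean(H_perm >= H_obs - 1e-12)
    return(list(statistic = H_obs, df = 1L, p_value = p,
                method = "exact permutation Kruskal-Wallis (2 groups)",
                n = sizes))
  }

  kt <- kruskal.test(values, labels)
  H <- unname(kt$statistic)
  # all-tied data give 0/0 in the tie correction; identical groups give
  # H numerically 0 -- both mean no evidence against equality
  if (!is.finite(H)) H <- 0
  p <- if (abs(H) < 1e-12) 1 else unname(kt$p.value)
  list(statistic = max(H, 0), df = unname(kt$parameter), p_value = p,
       method = "tie-corrected Kruskal-Wallis (chi-square approximation)",
       n = sizes)
}

#' Stratified onset summaries with group comparison
#'
#' Splits an onset table by gender (male vs female; other or missing
#' labels excluded with a logged count) or by age (`< age_cut` vs
#' `>= age_cut` years, default cut at 20; missing ages excluded).
#' Each stratum gets n, median, min and max; a Weibull fit is attempted
#' only where n >= `fit_min_n` (otherwise refused, shown as `NA`).
#' Strata are compared with [compare_groups()] when at least two are
#' non-empty.
#'
#' @param onset an onset table from [build_onset_table()].
#' @param stratum `"gender"` or `"age"`.
#' @param fit_min_n minimum per-stratum n for a Weibull fit.
#' @param age_cut age threshold in years for `stratum = "age"`.
#' @param ci CI method passed to [fit_weibull()].
#' @return List: `summary` (data frame: stratum, n, median_t, min_t,
#'   max_t, alpha, alpha_lo, alpha_hi, beta, beta_lo, beta_hi,
#'   failure_pattern), `fits` (named list of `weibull_fit` or `NULL`),
#'   `p_value` (comparison p, `NA` when fewer than two non-empty
#'   strata), `n_excluded`.
#' @export
summarize_by_stratum <- function(onset, stratum = c("gender", "age"),
                                 fit_min_n = 10, age_cut = 20,
                                 ci = "wald") {
  stratum <- match.arg(stratum)
  stopifnot(is.data.frame(onset), "t_days" %in% names(onset))
  if (stratum == "gender") {
    g <- tolower(trimws(onset$gender))
    keep <- g %in% c("male", "female")
    labels <- factor(g[keep], levels = c("male", "female"))
  } else {
    keep <- !is.na(onset$age_years)
    labels <- factor(ifelse(onset$age_years[keep] < age_cut,
                            sprintf("<%d y", age_cut),
                            sprintf(">=%d y", age_cut)),
                     levels = c(sprintf("<%d y", age_cut),
                                sprintf(">=%d y", age_cut)))
  }
  n_excluded <- sum(!keep)
  if (n_excluded > 0) {
    pv_log("summarize_by_stratum", "excluded %d record(s) with missing %s",
           n_excluded, stratum)
  }
  t <- onset$t_days[keep]
  groups <- split(t, labels)

  fits <- lapply(groups, function(v) {
    if (length(v) < fit_min_n) return(NULL)
    tryCatch(fit_weibull(v, fit_min_n = fit_min_n, ci = ci),
             error = function(e) NULL)
  })
  summary <- data.frame(
    stratum = names(groups),
    n = vapply(groups, length, integer(1)),
    median_t = vapply(groups, function(v)
      if (length(v)) median(v) else NA_real_, numeric(1)),
    min_t = vapply(groups, function(v)
      if (length(v)) min(v) else NA_real_, numeric(1)),
    max_t = vapply(groups, function(v)
      if (length(v)) max(v) else NA_real_, numeric(1)),
    alpha = vapply(fits, function(f)
      if (is.null(f)) NA_real_ else f$alpha, numeric(1)),
    alpha_lo = vapply(fits, function(f)
      if (is.null(f)) NA_real_ else f$alpha_ci95[1], numeric(1)),
    alpha_hi = vapply(fits, function(f)
      if (is.null(f)) NA_real_ else f$alpha_ci95[2], numeric(1)),
    beta = vapply(fits, function(f)
      if (is.null(f)) NA_real_ else f$beta, numeric(1)),
    beta_lo = vapply(fits, function(f)
      if (is.null(f)) NA_real_ else f$beta_ci95[1], numeric(1)),
    beta_hi = vapply(fits, function(f)
      if (is.null(f)) NA_real_ else f$beta_ci95[2], numeric(1)),
    failure_pattern = vapply(fits, function(f)
      if (is.null(f)) NA_character_ else f$failure_pattern, character(1)),
    stringsAsFactors = FALSE
  )
  rownames(summary) <- NULL

  nonempty <- groups[vapply(groups, length, integer(1)) > 0]
  p_value <- NA_real_
  if (length(nonempty) >= 2) {
    p_value <- compare_groups(nonempty)$p_value
  } else {
    warning("fewer than two non-empty strata: comparison omitted",
            call. = FALSE)
  }
  list(summary = summary, fits = fits, p_value = p_value,
       n_excluded = n_excluded)
}
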