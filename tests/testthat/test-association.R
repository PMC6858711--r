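test_that("endpoints derive from dates and responses as defined", {
  raw <- data.frame(
    patient_id = c("A", "B", "C"),
    response = c("PR", "SD", "NE"),
    start_date = as.Date("2020-01-01"),
    progression_date = as.Date(c("2020-09-10", NA, NA)),
    death_date = as.Date(c(NA, NA, "2020-06-01")),
    last_assessment_date = as.Date(c("2020-09-10", "2021-01-01",
                                     "2020-06-01")))
  out <- derive_endpoints(raw)
  expect_equal(out$responder, c(1L, 0L, NA_integer_))
  # A progressed ~8.3 months in
  expect_equal(out$pfs_event, c(1L, 0L, 1L))
  expect_equal(out$pfs_time_months[1], 8.3, tolerance = 0.02)
  # B censored at last assessment
  expect_equal(out$pfs_time_months[2],
               as.numeric(as.Date("2021-01-01") - as.Date("2020-01-01")) / 30.44)
  # C: death drives both endpoints
  expect_equal(out$os_event, c(0L, 0L, 1L))
  expect_error(derive_endpoints(
    data.frame(pfs_time_months = -1, os_time_months = 1)), "negative")
})

test_that("cohort summary reproduces printed-style percentages", {
  resp <- data.frame(response = rep(c("CR", "PR", "SD", "PD"),
                                    c(26, 73, 25, 32)))
  s <- cohort_summary(resp)
  expect_equal(s$pct[s$level == "CR"], 16.7)
  expect_equal(s$pct[s$level == "PR"], 46.8)
  expect_equal(s$n_evaluable[1], 156)
  # single-category column -> 100%
  one <- cohort_summary(data.frame(arm = rep("BRAFi", 10)))
  expect_equal(one$pct, 100)
  expect_error(cohort_summary(data.frame()), "empty")
})

test_that("logistic model is symmetric and directionally correct", {
  # balanced 2x2 with identical response rates -> OR = 1
  df <- data.frame(group = factor(rep(c("1", "3"), each = 100),
                                  levels = c("1", "2", "3")),
                   stage = "M1c", ecog_ps = "0", ldh_elevated = "no",
                   treatment = "BRAFi",
                   response = rep(c("PR", "PD", "PR", "PD"), each = 50))
  m <- fit_response_model(df)
  expect_equal(m$estimate[m$term == "group1"], 1, tolerance = 1e-6)
  expect_equal(m$n, rep(200L, nrow(m)))
  # no responders at all -> error
  expect_error(fit_response_model(transform(df, response = "PD")),
               "responders")
})

test_that("complete separation is reported, not raised", {
  df <- data.frame(group = factor(rep(c("1", "3"), each = 30),
                                  levels = c("1", "2", "3")),
                   stage = "M1c", ecog_ps = "0", ldh_elevated = "no",
                   treatment = "BRAFi",
                   response = rep(c("PR", "PD"), each = 30))
  m <- fit_response_model(df)
  expect_false(m$estimable[m$term == "group1"])
  expect_match(attr(m, "diagnostic"), "separation")
})

test_that("Cox model gives HR 1 for identical groups and handles no events", {
  base <- data.frame(group = factor(rep(c("1", "3"), each = 50),
                                    levels = c("1", "2", "3")),
                     stage = "M1c", ecog_ps = "0", ldh_elevated = "no",
                     treatment = "BRAFi", subsequent_it = "no",
                     os_time_months = rep(c(3, 6, 9, 12, 15), 20),
                     os_event = rep(c(1, 1, 1, 0, 1), 20))
  m <- fit_survival_model(base, "os")
  expect_equal(m$estimate[m$term == "group1"], 1, tolerance = 1e-6)
  none <- transform(base, os_event = 0)
  m0 <- fit_survival_model(none, "os")
  expect_false(any(m0$estimable))
  expect_match(attr(m0, "diagnostic"), "no events")
})

test_that("model estimates are invariant to covariate order and time origin", {
  ch <- generate_cohort(cohort_config(n_patients = 400, seed = 6))
  m1 <- fit_survival_model(ch, "os",
                           covariates = c("stage", "ecog_ps", "ldh_elevated",
                                          "treatment", "subsequent_it"))
  m2 <- fit_survival_model(ch, "os",
                           covariates = c("treatment", "subsequent_it",
                                          "ldh_elevated", "stage", "ecog_ps"))
  expect_equal(sort(m1$estimate), sort(m2$estimate))
  ch2 <- transform(ch, os_time_months = os_time_months + 5)
  m3 <- fit_survival_model(ch2, "os",
                           covariates = c("stage", "ecog_ps", "ldh_elevated",
                                          "treatment", "subsequent_it"))
  expect_equal(m1$estimate[m1$term == "group1"],
               m3$estimate[m3$term == "group1"], tolerance = 1e-8)
})

test_that("Kaplan-Meier estimate follows the product-limit construction", {
  # 10 uncensored times 1..10: S drops in steps of 0.1, median at S(5) = 0.5
  df <- data.frame(os_time_months = 1:10, os_event = 1L)
  km <- km_estimate(df, "os")
  expect_equal(km$curve$survival, seq(0.9, 0, by = -0.1))
  expect_equal(km$quantiles$median, 5)
  expect_equal(km$quantiles$q25, 3)   # first t with S <= 0.75
  expect_equal(km$quantiles$q75, 8)   # first t with S <= 0.25
  # all censored -> median not reached
  cens <- data.frame(os_time_months = 1:10, os_event = 0L)
  expect_true(is.na(km_estimate(cens, "os")$quantiles$median))
  # without censoring the KM curve equals the empirical survival function
  set.seed(3)
  t <- round(rexp(40, 0.1), 2)
  km2 <- km_estimate(data.frame(os_time_months = t, os_event = 1L), "os")
  emp <- vapply(km2$curve$time, function(u) mean(t > u), 0)
  expect_equal(km2$curve$survival, emp)
})

test_that("chi-square test matches the hand-computed statistic", {
  flat <- chi_square_assoc(matrix(c(10, 10, 10, 10), 2))
  expect_equal(flat$statistic, 0)
  expect_equal(flat$p, 1)
  x <- chi_square_assoc(matrix(c(20, 5, 5, 20), 2))
  # all expected cells 12.5: sum (O-E)^2/E = 4 * 7.5^2/12.5 = 18
  expect_equal(x$statistic, 18)
  expect_equal(x$df, 1)
  expect_equal(chi_square_assoc(matrix(1:6, 2))$df, 2)
  tiny <- chi_square_assoc(matrix(c(1, 0, 0, 1), 2))
  expect_match(tiny$warning, "below 1")
})

test_that("Kruskal-Wallis matches brute-force ranks and degenerate cases", {
  v <- c(1, 2, 3, 10, 11, 12, 100, 101, 102)
  g <- rep(1:3, each = 3)
  kw <- kruskal_wallis(v, g)
  # brute-force H = 12/(N(N+1)) * sum n_i (Rbar_i - Rbar)^2, no ties
  r <- rank(v)
  H <- 12 / (9 * 10) * sum(3 * (tapply(r, g, mean) - mean(r))^2)
  expect_equal(kw$statistic, H)
  expect_equal(H, 7.2)
  expect_equal(kw$df, 2)
  same <- kruskal_wallis(rep(5, 9), g)
  expect_equal(same$statistic, 0)
  expect_equal(same$p, 1)
  expect_error(kruskal_wallis(1:3, rep(1, 3)), "2 non-empty groups")
})

test_that("Kruskal-Wallis p-values are calibrated under the null", {
  set.seed(12)
  ps <- replicate(300, kruskal_wallis(rnorm(60), rep(1:3, each = 20))$p)
  expect_gt(suppressWarnings(ks.test(ps, "punif"))$p.value, 0.01)
})
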