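# Mixed models, likelihood-ratio tests, model selection, Welch t-tests.

test_that("welch_t matches the explicit formula and handles equal groups", {
  g <- c(1, 2, 3, 4)
  same <- welch_t(g, g)
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)

  set.seed(51)
  x <- rnorm(12, 0, 1)
  y <- rnorm(7, 1, 3)
  got <- welch_t(x, y)
  se2 <- var(x) / 12 + var(y) / 7
  t_oracle <- (mean(x) - mean(y)) / sqrt(se2)
  df_oracle <- se2^2 / ((var(x) / 12)^2 / 11 + (var(y) / 7)^2 / 6)
  expect_equal(got$statistic, t_oracle, tolerance = 1e-12)
  expect_equal(got$df, df_oracle, tolerance = 1e-12)
  expect_equal(got$p_value, 2 * pt(-abs(t_oracle), df_oracle),
               tolerance = 1e-12)
})

test_that("welch_t holds its nominal size under heterogeneous variances", {
  set.seed(52)
  rej <- mean(replicate(1000, {
    welch_t(rnorm(10, 0, 1), rnorm(25, 0, 4))$p_value < 0.05
  }))
  expect_gt(rej, 0.025)
  expect_lt(rej, 0.075)
})

test_that("lrt of a model against itself is null and non-nesting errors", {
  set.seed(53)
  recs <- make_records(30)
  null_fit <- fit_lme(recs, "mre")
  test <- lrt(null_fit, null_fit)
  expect_equal(test$statistic, 0)
  expect_equal(test$p_value, 1)

  m_img <- fit_lme(recs, "mre", "image")
  m_dev <- fit_lme(recs, "mre", "device")
  expect_error(lrt(m_img, m_dev), "not nested")
  expect_error(lrt(fit_lme(recs, "mre", "image", reml = TRUE), null_fit),
               "REML")
  expect_error(lrt(m_img, fit_lme(recs, "time")), "same response")
})

test_that("noiseless data recovers the generating coefficients exactly", {
  set.seed(54)
  recs <- make_records(40, beta_image = 0.21, beta_gender = -0.24,
                       subject_sd = 0, resid_sd = 0)
  fit <- suppressWarnings(fit_lme(recs, "mre", c("image", "gender")))
  td <- tidy(fit)
  expect_equal(td$estimate[td$term == "imageB"], 0.21, tolerance = 1e-6)
  expect_equal(td$estimate[td$term == "gendermale"], -0.24, tolerance = 1e-6)
  expect_equal(td$estimate[td$term == "(Intercept)"], 2, tolerance = 1e-6)
})

test_that("zero subject variance collapses the fit to least squares", {
  # true subject variance zero: the ML variance estimate sits on the zero
  # boundary (flagged singular) and the fixed effects equal OLS, whose
  # balanced two-group contrast is the group-mean difference
  set.seed(1)
  n <- 200
  recs <- tibble::tibble(
    subject = rep(sprintf("s%03d", 1:n), each = 2),
    device = rep(c("desktop", "tablet"), n),
    image = "A", gender = "female", order = rep(0:1, n),
    mre = rnorm(2 * n, 2, 0.4), time = 15
  )
  fit <- fit_lme(recs, "mre", "device")
  expect_true(fit$singular)
  expect_lt(glance(fit)$subject_sd, 1e-8)
  ols <- lm(mre ~ device, data = recs)
  expect_equal(tidy(fit)$estimate, unname(coef(ols)), tolerance = 1e-6)
  diff_oracle <- mean(recs$mre[recs$device == "tablet"]) -
    mean(recs$mre[recs$device == "desktop"])
  td <- tidy(fit)
  expect_equal(td$estimate[td$term == "devicetablet"], diff_oracle,
               tolerance = 1e-6)
})

test_that("selection keeps real effects and drops pure-noise candidates", {
  set.seed(57)
  recs <- make_records(120, beta_image = 0.35, beta_gender = -0.4,
                       subject_sd = 0.3, resid_sd = 0.4)
  sel <- select_model(recs, "mre")
  expect_setequal(sel$effects, c("image", "gender"))
  hist <- attr(sel, "selection")
  expect_equal(nrow(hist$screen), 4)
  expect_true(all(c("statistic", "p_value") %in% names(hist$screen)))

  # all-noise data mostly selects the intercept-only model
  set.seed(58)
  n_null <- mean(replicate(30, {
    length(select_model(make_records(40), "mre")$effects) == 0
  }))
  expect_gt(n_null, 0.6)
})

test_that("lrt significance is invariant to affine response recoding", {
  set.seed(59)
  recs <- make_records(60, beta_image = 0.3)
  t1 <- lrt(fit_lme(recs, "mre", "image"), fit_lme(recs, "mre"))
  recs$mre <- 5 + 3 * recs$mre
  t2 <- lrt(fit_lme(recs, "mre", "image"), fit_lme(recs, "mre"))
  expect_equal(t1$statistic, t2$statistic, tolerance = 1e-4)
})
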