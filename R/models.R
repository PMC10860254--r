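## Inferential machinery of the device-comparison study: linear mixed-effects
## models with a per-subject random intercept, likelihood-ratio model
## selection, and Welch t-tests for measurement comparisons.

study_factor_levels <- list(
  device = c("desktop", "tablet"),
  image = c("A", "B"),
  gender = c("female", "male"),
  order = c("first", "second")
)

prepare_records <- function(records) {
  records <- tibble::as_tibble(records)
  if (is.numeric(records$order)) {
    records$order <- ifelse(records$order == 0, "first", "second")
  }
  for (nm in names(study_factor_levels)) {
    if (nm %in% names(records)) {
      records[[nm]] <- factor(records[[nm]], levels = study_factor_levels[[nm]])
    }
  }
  records
}

#' Fit a random-intercept mixed model to study records
#'
#' Fits `response ~ fixed effects + (1 | subject)` by maximum likelihood
#' (ML, not REML, so that fits are comparable by likelihood-ratio tests;
#' REML is available for final-model reporting). Reference levels are
#' desktop, image A, female, first order.
#'
#' @param records Study records: a data frame with columns `subject`,
#'   `device`, `image`, `gender`, `order` (0/1 or "first"/"second") and the
#'   response columns `mre` (mm) and/or `time` (minutes).
#' @param response `"mre"` or `"time"` (or any numeric column of `records`).
#' @param fixed Character vector of fixed-effect names, a subset of
#'   `c("device", "image", "gender", "order")`; empty for the intercept-only
#'   null model.
#' @param reml Use REML instead of ML. Never use REML fits in [lrt()].
#' @return An object of class `ceph_lme`; see [tidy.ceph_lme()] and
#'   [glance.ceph_lme()]. A singular fit (e.g. zero subject variance) is
#'   flagged in `$singular`, not an error.
#' @export
fit_lme <- function(records, response = c("mre", "time"), fixed = character(),
                    reml = FALSE) {
  response <- match.arg(response, choices = c("mre", "time", names(records)))
  records <- prepare_records(records)
  stopifnot(length(unique(records$subject)) >= 2)
  rhs <- if (length(fixed)) paste(fixed, collapse = " + ") else "1"
  fml <- as.formula(paste(response, "~", rhs, "+ (1 | subject)"))
  # allow the degenerate one-record-per-subject limit, where the fit
  # collapses to least squares with a zero random-intercept variance
  ctrl <- lme4::lmerControl(check.nobs.vs.nlev = "ignore",
                            check.nobs.vs.nRE = "ignore")
  fit <- suppressMessages(lme4::lmer(fml, data = records, REML = reml,
                                     control = ctrl))
  structure(
    list(
      fit = fit, response = response, effects = sort(fixed),
      reml = reml, singular = lme4::isSingular(fit),
      nobs = nrow(records)
    ),
    class = "ceph_lme"
  )
}

#' @export
print.ceph_lme <- function(x, ...) {
  cat(sprintf("<ceph_lme> %s ~ %s + (1 | subject)  [%s%s]\n",
              x$response,
              if (length(x$effects)) paste(x$effects, collapse = " + ") else "1",
              if (x$reml) "REML" else "ML",
              if (x$singular) ", singular" else ""))
  print(tidy(x))
  invisible(x)
}

#' Tidy and glance methods for mixed-model fits
#'
#' `tidy()` returns the fixed effects with Wald 95% confidence intervals and
#' Wald z p-values; `glance()` returns the variance components and
#' log-likelihood.
#'
#' @param x A `ceph_lme` object from [fit_lme()].
#' @param conf_level Confidence level for the Wald intervals.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.ceph_lme <- function(x, conf_level = 0.95, ...) {
  est <- lme4::fixef(x$fit)
  se <- sqrt(diag(as.matrix(lme4::vcov.merMod(x$fit))))
  z <- qnorm(1 - (1 - conf_level) / 2)
  tibble::tibble(
    term = names(est),
    estimate = unname(est),
    std.error = unname(se),
    statistic = unname(est / se),
    conf.low = unname(est - z * se),
    conf.high = unname(est + z * se),
    p.value = unname(2 * pnorm(-abs(est / se)))
  )
}

#' @rdname tidy.ceph_lme
#' @export
glance.ceph_lme <- function(x, ...) {
  vc <- as.data.frame(lme4::VarCorr(x$fit))
  tibble::tibble(
    response = x$response,
    subject_sd = vc$sdcor[vc$grp == "subject"],
    residual_sd = vc$sdcor[vc$grp == "Residual"],
    logLik = as.numeric(logLik(x$fit)),
    df = attr(logLik(x$fit), "df"),
    nobs = x$nobs,
    singular = x$singular
  )
}

#' Likelihood-ratio test of two nested mixed models
#'
#' `statistic = 2 * (logLik(full) - logLik(null))` referred to a chi-square
#' distribution with the difference in parameter count as degrees of freedom.
#' Both fits must be ML fits of the same response on the same data, with the
#' null model's effects a subset of the full model's.
#'
#' @param full,null `ceph_lme` fits from [fit_lme()].
#' @return A tibble `effect` (the tested term(s)), `statistic`, `df`,
#'   `p_value`.
#' @export
lrt <- function(full, null) {
  if (full$reml || null$reml) {
    stop("likelihood-ratio tests require ML (not REML) fits", call. = FALSE)
  }
  if (full$response != null$response || full$nobs != null$nobs) {
    stop("models must be fits of the same response on the same data",
         call. = FALSE)
  }
  if (!all(null$effects %in% full$effects)) {
    stop("models are not nested", call. = FALSE)
  }
  ll_f <- logLik(full$fit)
  ll_n <- logLik(null$fit)
  df <- attr(ll_f, "df") - attr(ll_n, "df")
  if (df < 1 && !setequal(full$effects, null$effects)) {
    stop("models are not nested", call. = FALSE)
  }
  stat <- max(0, 2 * (as.numeric(ll_f) - as.numeric(ll_n)))
  added <- setdiff(full$effects, null$effects)
  tibble::tibble(
    effect = if (length(added)) paste(added, collapse = "+") else "(none)",
    statistic = stat,
    df = max(df, 0L),
    p_value = if (df >= 1) pchisq(stat, df, lower.tail = FALSE) else 1
  )
}

#' Likelihood-ratio model selection
#'
#' Two-stage selection mirroring the study's procedure. Stage 1 screens each
#' candidate effect singly against the intercept-only null model by LRT.
#' Stage 2 adds the screened-in effects one at a time in ascending order of
#' their stage-1 p-value (ties broken alphabetically), keeping each effect
#' only if the incremental LRT against the current model is significant at
#' `alpha`. The result may be the intercept-only model.
#'
#' @param records Study records (see [fit_lme()]).
#' @param response `"mre"` or `"time"`.
#' @param candidates Candidate fixed effects.
#' @param alpha Significance level for both stages.
#' @return The selected `ceph_lme` fit, with attribute `selection`: a list of
#'   `screen` (stage-1 LRTs) and `steps` (stage-2 incremental LRTs).
#' @export
select_model <- function(records, response = c("mre", "time"),
                         candidates = c("device", "image", "gender", "order"),
                         alpha = 0.05) {
  response <- match.arg(response)
  null_fit <- fit_lme(records, response, character())
  screen <- purrr::map_dfr(candidates, function(eff) {
    lrt(fit_lme(records, response, eff), null_fit)
  })
  sig <- screen[screen$p_value < alpha, ]
  sig <- sig[order(sig$p_value, sig$effect), ]

  current <- null_fit
  steps <- list()
  for (eff in sig$effect) {
    candidate <- fit_lme(records, response, c(current$effects, eff))
    test <- lrt(candidate, current)
    test$kept <- test$p_value < alpha
    steps[[length(steps) + 1]] <- test
    if (test$kept) current <- candidate
  }
  attr(current, "selection") <- list(
    screen = screen,
    steps = if (length(steps)) dplyr::bind_rows(steps) else tibble::tibble()
  )
  current
}

#' Welch two-sample t-test
#'
#' Two-sample t-test assuming heterogeneous variances, with the
#' Welch-Satterthwaite degrees of freedom. Used to compare each cephalometric
#' measurement between student tracings and the expert reference tracings.
#'
#' @param group1,group2 Numeric vectors with at least 2 values each.
#' @return A tibble `estimate` (mean of `group1` minus mean of `group2`),
#'   `statistic`, `df`, `p_value`.
#' @export
welch_t <- function(group1, group2) {
  stopifnot(length(group1) >= 2, length(group2) >= 2)
  ht <- t.test(group1, group2, var.equal = FALSE)
  tibble::tibble(
    estimate = unname(ht$estimate[1] - ht$estimate[2]),
    statistic = unname(ht$statistic),
    df = unname(ht$parameter),
    p_value = ht$p.value
  )
}
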