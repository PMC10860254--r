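## End-to-end study pipeline: ingest -> exclusions -> accuracy ->
## reliability -> mixed models -> measurement comparison.

#' Run the full cephalometric study pipeline
#'
#' Orchestrates the whole analysis on a batch of submissions: parses and
#' excludes invalid tracings, scores landmark accuracy against the reference
#' (per-landmark MRE/SDR table), fits and selects the mixed models for
#' accuracy and tracing time, and — when rater tracings are supplied —
#' computes per-landmark interrater reliability and compares every
#' cephalometric measurement between students and raters by Welch t-tests.
#'
#' @param input A directory of submission JSON files, or a list of
#'   `ceph_submission` objects (e.g. from [simulate_study()]).
#' @param reference Reference coordinates as [reference_landmarks()] (long
#'   tibble with an `image` column). Defaults to the bundled expert
#'   reference.
#' @param mm_per_px Named pixel spacings per image (mm/pixel). Defaults to
#'   the spacing calibrated from the bundled reference for image A and the
#'   generator default for image B.
#' @param rater_landmarks Optional long tibble of rater placements (`rater`,
#'   `image`, `landmark`, `x`, `y`) enabling the reliability table and the
#'   measurement comparison.
#' @param allowed_images Valid cephalogram identifiers.
#' @param min_records Minimum study records required before mixed models are
#'   attempted.
#' @return An object of class `ceph_study_report`: a list with `exclusions`,
#'   `accuracy`, `records`, `model_mre`, `model_time`, `reliability`,
#'   `measurements` and `meta`.
#' @export
run_study <- function(input,
                      reference = reference_landmarks(),
                      mm_per_px = NULL,
                      rater_landmarks = NULL,
                      allowed_images = c("A", "B"),
                      min_records = 20) {
  submissions <- if (is.character(input)) read_submissions(input) else input
  if (is.null(mm_per_px)) {
    mm_per_px <- simulation_config(reference = reference)$mm_per_px
  }
  refs <- split(reference[, c("landmark", "x", "y")], reference$image)

  exclusions <- apply_exclusions(submissions, allowed_images = allowed_images)
  included <- exclusions$included

  empty_report <- function() {
    structure(
      list(
        exclusions = exclusions,
        accuracy = NULL, records = tibble::tibble(),
        model_mre = NULL, model_time = NULL,
        reliability = NULL, measurements = NULL,
        meta = list(
          n_included = 0L, n_landmarks = 0L,
          package_version = as.character(utils::packageVersion("cephmetrics"))
        )
      ),
      class = "ceph_study_report"
    )
  }
  if (!length(included)) {
    warning("no submissions left after exclusions; returning empty report",
            call. = FALSE)
    return(empty_report())
  }

  scored <- score_submissions(included, refs, mm_per_px)
  accuracy <- summarize_accuracy(scored)

  records <- purrr::map_dfr(included, function(s) {
    tibble::tibble(
      subject = s$subject, device = s$device, image = s$image,
      gender = s$gender, order = s$order,
      time = tracing_time(s),
      mre = mre(radial_errors(s, refs[[s$image]],
                              if (length(mm_per_px) > 1) mm_per_px[[s$image]]
                              else mm_per_px))
    )
  })

  model_mre <- NULL
  model_time <- NULL
  if (nrow(records) >= min_records &&
      length(unique(records$subject)) >= 2) {
    model_mre <- select_model(records, "mre")
    model_time <- select_model(records, "time")
  }

  reliability <- NULL
  measurements <- NULL
  if (!is.null(rater_landmarks)) {
    reliability <- landmark_icc(rater_landmarks, mode = "pooled")
    measurements <- compare_measurements(included, rater_landmarks, mm_per_px)
  }

  structure(
    list(
      exclusions = exclusions,
      accuracy = accuracy,
      records = records,
      model_mre = model_mre,
      model_time = model_time,
      reliability = reliability,
      measurements = measurements,
      meta = list(
        n_included = length(included),
        n_landmarks = sum(vapply(included,
                                 function(s) nrow(s$landmarks), integer(1))),
        mm_per_px = mm_per_px,
        package_version = as.character(utils::packageVersion("cephmetrics")),
        input_hash = as.character(openssl::sha256(paste(
          vapply(included, function(s) s$subject, character(1)),
          collapse = ",")))
      )
    ),
    class = "ceph_study_report"
  )
}

#' Compare cephalometric measurements between students and raters
#'
#' Computes the 22-item analysis for every student tracing and every rater
#' tracing and compares each measurement with a Welch t-test (heterogeneous
#' variances), pooling both images.
#'
#' @param submissions List of complete `ceph_submission` objects.
#' @param rater_landmarks Long tibble (`rater`, `image`, `landmark`, `x`,
#'   `y`).
#' @param mm_per_px Named pixel spacings per image.
#' @return A tibble `measurement`, `unit`, `rater_mean`, `rater_sd`,
#'   `student_mean`, `student_sd`, `statistic`, `df`, `p_value`.
#' @export
compare_measurements <- function(submissions, rater_landmarks, mm_per_px) {
  spacing_for <- function(img) {
    if (length(mm_per_px) > 1) mm_per_px[[img]] else mm_per_px
  }
  student_vals <- purrr::map_dfr(submissions, function(s) {
    res <- compute_analysis(s$landmarks, spacing_for(s$image))
    res$who <- "student"
    res
  })
  rater_vals <- rater_landmarks |>
    dplyr::group_by(.data$rater, .data$image) |>
    dplyr::group_map(function(df, key) {
      res <- compute_analysis(df, spacing_for(key$image))
      res$who <- "rater"
      res
    }) |>
    dplyr::bind_rows()
  both <- dplyr::bind_rows(student_vals, rater_vals)
  both |>
    dplyr::group_by(.data$measurement, .data$unit) |>
    dplyr::group_modify(function(df, key) {
      stud <- df$value[df$who == "student"]
      rat <- df$value[df$who == "rater"]
      test <- welch_t(stud, rat)
      tibble::tibble(
        rater_mean = mean(rat), rater_sd = sd(rat),
        student_mean = mean(stud), student_sd = sd(stud),
        statistic = test$statistic, df = test$df, p_value = test$p_value
      )
    }) |>
    dplyr::ungroup()
}

#' @export
print.ceph_study_report <- function(x, ...) {
  cat("== Cephalometric study report ==\n")
  print(x$exclusions)
  if (!is.null(x$accuracy)) {
    ov <- attr(x$accuracy, "overall")
    cat(sprintf("Accuracy: overall MRE %.2f mm, SDR(2 mm) %.1f%% (%d tracings, %d landmarks)\n",
                ov["overall_mre"], ov["overall_sdr_2mm"],
                x$meta$n_included, x$meta$n_landmarks))
  }
  for (nm in c("model_mre", "model_time")) {
    if (!is.null(x[[nm]])) {
      eff <- x[[nm]]$effects
      cat(sprintf("Selected %s model: %s\n",
                  sub("model_", "", nm),
                  if (length(eff)) paste(eff, collapse = " + ")
                  else "intercept only"))
    }
  }
  if (!is.null(x$reliability)) {
    cat(sprintf("Reliability: %d/%d landmarks excellent (ICC > 0.9)\n",
                sum(x$reliability$band == "excellent"),
                nrow(x$reliability)))
  }
  invisible(x)
}
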