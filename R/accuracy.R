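## Landmark localisation accuracy: radial errors, mean radial error (MRE)
## and successful detection rate (SDR).

#' Per-landmark radial errors against a reference
#'
#' The radial error of a landmark is the Euclidean distance between the
#' student's placement and the reference position, converted to mm via the
#' pixel spacing:
#' `d_i = spacing * sqrt((x_stud - x_ref)^2 + (y_stud - y_ref)^2)`.
#'
#' @param student Landmark tibble (columns `landmark`, `x`, `y`) or a
#'   `ceph_submission`.
#' @param reference Reference landmark tibble with the same landmark names.
#' @param mm_per_px Pixel spacing in mm/pixel (> 0).
#' @return A tibble `landmark`, `d_mm`, in the order of the student set.
#' @export
radial_errors <- function(student, reference, mm_per_px) {
  if (inherits(student, "ceph_submission")) student <- student$landmarks
  stopifnot(mm_per_px > 0)
  i <- match(student$landmark, reference$landmark)
  if (anyNA(i)) {
    stop("landmarks absent from reference: ",
         paste(student$landmark[is.na(i)], collapse = ", "), call. = FALSE)
  }
  tibble::tibble(
    landmark = student$landmark,
    d_mm = mm_per_px * sqrt((student$x - reference$x[i])^2 +
                              (student$y - reference$y[i])^2)
  )
}

#' Mean radial error of a tracing
#'
#' Arithmetic mean of the per-landmark radial errors, `MRE = sum(d_i) / l`.
#'
#' @param d Numeric vector of radial errors in mm (or the tibble returned by
#'   [radial_errors()]).
#' @return MRE in mm.
#' @export
mre <- function(d) {
  if (is.data.frame(d)) d <- d$d_mm
  if (length(d) < 1) stop("mre of an empty error vector", call. = FALSE)
  mean(d)
}

#' Successful detection rate
#'
#' Percentage of radial errors falling below each threshold. "Below" is
#' strict (`d < threshold`) by default; ties at the threshold are
#' measure-zero for continuous errors, but the comparison is configurable.
#'
#' @param errors Numeric vector of radial errors in mm.
#' @param thresholds Positive thresholds in mm, default the conventional
#'   1/2/4/8 mm.
#' @param strict Use `<` (default) rather than `<=`.
#' @return A tibble `threshold_mm`, `sdr` (percent in \[0, 100\]).
#' @export
#' @examples
#' sdr(c(0.5, 1.5, 3, 9))
sdr <- function(errors, thresholds = c(1, 2, 4, 8), strict = TRUE) {
  stopifnot(all(thresholds > 0), !is.unsorted(thresholds))
  if (is.data.frame(errors)) errors <- errors$d_mm
  pct <- vapply(thresholds, function(thr) {
    if (strict) 100 * mean(errors < thr) else 100 * mean(errors <= thr)
  }, numeric(1))
  tibble::tibble(threshold_mm = thresholds, sdr = pct)
}

#' Score a batch of submissions against a reference
#'
#' Computes per-landmark radial errors and the per-submission MRE for each
#' submission.
#'
#' @param submissions List of complete `ceph_submission` objects.
#' @param references Named list of reference landmark tibbles, keyed by image
#'   identifier (or a single tibble when all submissions share one image).
#' @param mm_per_px Named numeric vector of spacings keyed by image, or a
#'   single value.
#' @return A tibble with one row per (submission, landmark): `subject`,
#'   `image`, `device`, `landmark`, `d_mm`.
#' @seealso [summarize_accuracy()]
#' @export
score_submissions <- function(submissions, references, mm_per_px) {
  if (is.data.frame(references)) {
    references <- list(references)
    names(references) <- unique(vapply(submissions, function(s) s$image,
                                       character(1)))[1]
  }
  purrr::map_dfr(submissions, function(s) {
    ref <- references[[s$image]]
    if (is.null(ref)) stop("no reference for image ", s$image, call. = FALSE)
    sp <- if (length(mm_per_px) > 1) mm_per_px[[s$image]] else mm_per_px
    d <- radial_errors(s, ref, sp)
    tibble::tibble(subject = s$subject, image = s$image, device = s$device,
                   landmark = d$landmark, d_mm = d$d_mm)
  })
}

#' Per-landmark accuracy summary
#'
#' Summarises scored submissions into the study's accuracy table: per
#' landmark the mean radial error with sample SD and normal-approximation 95%
#' confidence interval (mean +/- 1.96 SD/sqrt(n)), and SDRs at the given
#' thresholds. Overall aggregates (the mean over landmarks of the per-landmark
#' means and SDRs) are attached as attribute `overall`.
#'
#' @param scored Tibble from [score_submissions()] (columns `landmark`,
#'   `d_mm`; any other columns are ignored).
#' @param thresholds SDR thresholds in mm.
#' @return A tibble of class `ceph_accuracy` with columns `landmark`, `n`,
#'   `mre_mean`, `mre_sd`, `ci_lower`, `ci_upper` and one `sdr_<t>mm` column
#'   per threshold; attribute `overall` holds `overall_mre` and the overall
#'   SDRs.
#' @export
summarize_accuracy <- function(scored, thresholds = c(1, 2, 4, 8)) {
  stopifnot(nrow(scored) >= 2)
  tab <- scored |>
    dplyr::group_by(.data$landmark) |>
    dplyr::summarise(
      n = dplyr::n(),
      mre_mean = mean(.data$d_mm),
      mre_sd = sd(.data$d_mm),
      ci_lower = .data$mre_mean - qnorm(0.975) * .data$mre_sd / sqrt(.data$n),
      ci_upper = .data$mre_mean + qnorm(0.975) * .data$mre_sd / sqrt(.data$n),
      .groups = "drop"
    )
  for (thr in thresholds) {
    col <- sprintf("sdr_%gmm", thr)
    sdr_vals <- scored |>
      dplyr::group_by(.data$landmark) |>
      dplyr::summarise(v = 100 * mean(.data$d_mm < thr), .groups = "drop")
    tab[[col]] <- sdr_vals$v[match(tab$landmark, sdr_vals$landmark)]
  }
  ord <- match(landmark_names(), tab$landmark)
  tab <- tab[ord[!is.na(ord)], ]
  overall <- c(
    overall_mre = mean(tab$mre_mean),
    setNames(
      vapply(thresholds,
             function(thr) mean(tab[[sprintf("sdr_%gmm", thr)]]), numeric(1)),
      sprintf("overall_sdr_%gmm", thresholds)
    )
  )
  attr(tab, "overall") <- overall
  class(tab) <- c("ceph_accuracy", class(tab))
  tab
}

#' @export
print.ceph_accuracy <- function(x, ...) {
  NextMethod()
  ov <- attr(x, "overall")
  cat(sprintf("Overall MRE %.2f mm; overall SDR(2 mm) %.1f%%\n",
              ov["overall_mre"], ov["overall_sdr_2mm"]))
  invisible(x)
}
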