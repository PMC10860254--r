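## Interrater reliability: two-way absolute-agreement intraclass correlation
## for averaged ratings of k raters, ICC(A,k) in the McGraw-Wong taxonomy,
## with the Koo-Li interpretation bands.

koo_li_band <- function(icc) {
  if (is.na(icc)) return(NA_character_)
  if (icc < 0.5) "poor"
  else if (icc < 0.75) "moderate"
  else if (icc < 0.9) "good"
  else "excellent"
}

#' ICC(A,k): absolute agreement of k raters' averaged ratings
#'
#' Two-way ANOVA decomposition of an n-targets-by-k-raters matrix into
#' between-target (MSR), between-rater (MSC) and residual (MSE) mean squares,
#' giving `ICC(A,k) = (MSR - MSE) / (MSR + (MSC - MSE) / n)`. The estimate is
#' banded by the Koo-Li cutpoints (poor < 0.5, moderate < 0.75, good < 0.9,
#' excellent above). Negative estimates are reported as such (band "poor");
#' a matrix with zero total variance has no defined ICC and returns `NA`.
#'
#' @param m Numeric matrix, rows = targets (n >= 2), columns = raters
#'   (k >= 2), no missing cells.
#' @return An object of class `ceph_icc` with fields `icc`, `band`, `msr`,
#'   `msc`, `mse`, `n`, `k`. [tidy()] and [glance()] methods are provided.
#' @export
#' @examples
#' m <- cbind(r1 = c(1, 2, 3, 4), r2 = c(1.1, 2, 2.9, 4.2), r3 = c(1, 2.2, 3, 3.9))
#' icc_ak(m)
icc_ak <- function(m) {
  m <- as.matrix(m)
  stopifnot(is.numeric(m), !anyNA(m))
  n <- nrow(m)
  k <- ncol(m)
  if (n < 2 || k < 2) {
    stop("ICC needs at least 2 targets and 2 raters", call. = FALSE)
  }
  grand <- mean(m)
  row_means <- rowMeans(m)
  col_means <- colMeans(m)
  ssr <- k * sum((row_means - grand)^2)
  ssc <- n * sum((col_means - grand)^2)
  sst <- sum((m - grand)^2)
  sse <- sst - ssr - ssc
  msr <- ssr / (n - 1)
  msc <- ssc / (k - 1)
  mse <- sse / ((n - 1) * (k - 1))
  icc <- if (sst < .Machine$double.eps) {
    NA_real_
  } else {
    (msr - mse) / (msr + (msc - mse) / n)
  }
  structure(
    list(icc = icc, band = koo_li_band(icc),
         msr = msr, msc = msc, mse = mse, n = n, k = k),
    class = "ceph_icc"
  )
}

#' @export
print.ceph_icc <- function(x, ...) {
  cat(sprintf("ICC(A,%d) = %s (%s), n = %d targets\n", x$k,
              ifelse(is.na(x$icc), "NA", sprintf("%.3f", x$icc)),
              x$band %||% "NA", x$n))
  invisible(x)
}

#' @rdname icc_ak
#' @param x A `ceph_icc` object.
#' @param ... Unused.
#' @export
tidy.ceph_icc <- function(x, ...) {
  tibble::tibble(estimate = x$icc, band = x$band,
                 msr = x$msr, msc = x$msc, mse = x$mse)
}

#' @rdname icc_ak
#' @export
glance.ceph_icc <- function(x, ...) {
  tibble::tibble(icc = x$icc, band = x$band, n_targets = x$n, n_raters = x$k)
}

#' Per-landmark interrater reliability of coordinate placements
#'
#' For each landmark, assembles a targets-by-raters matrix from the raters'
#' coordinate placements and applies [icc_ak()]. With `mode = "pooled"`
#' (default) the targets are the pooled image-by-axis coordinate values (one
#' row per image and axis, so 2 images give 4 targets); with
#' `mode = "per_axis"` separate matrices are built per axis (targets =
#' images) and one row per landmark and axis is returned.
#'
#' @param rater_landmarks Long tibble with columns `rater`, `image`,
#'   `landmark`, `x`, `y` covering at least 2 raters.
#' @param mode `"pooled"` or `"per_axis"`.
#' @return A tibble with columns `landmark` (and `axis` for `"per_axis"`),
#'   `icc`, `band`.
#' @export
landmark_icc <- function(rater_landmarks, mode = c("pooled", "per_axis")) {
  mode <- match.arg(mode)
  stopifnot(all(c("rater", "image", "landmark", "x", "y") %in%
                  names(rater_landmarks)))
  raters <- sort(unique(rater_landmarks$rater))
  if (length(raters) < 2) stop("need at least 2 raters", call. = FALSE)
  long <- tidyr::pivot_longer(rater_landmarks, c("x", "y"),
                              names_to = "axis", values_to = "value")
  build <- function(df) {
    wide <- tidyr::pivot_wider(df, names_from = "rater",
                               values_from = "value")
    as.matrix(wide[, as.character(raters)])
  }
  if (mode == "pooled") {
    long |>
      dplyr::group_by(.data$landmark) |>
      dplyr::group_modify(function(df, key) {
        fit <- icc_ak(build(df[, c("image", "axis", "rater", "value")]))
        tibble::tibble(icc = fit$icc, band = fit$band)
      }) |>
      dplyr::ungroup()
  } else {
    long |>
      dplyr::group_by(.data$landmark, .data$axis) |>
      dplyr::group_modify(function(df, key) {
        fit <- icc_ak(build(df[, c("image", "rater", "value")]))
        tibble::tibble(icc = fit$icc, band = fit$band)
      }) |>
      dplyr::ungroup()
  }
}
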