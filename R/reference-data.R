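#' The 33 landmark names of the Muenster 22-item analysis
#'
#' Names of the anatomical, radiological and constructed landmarks placed on a
#' lateral cephalogram for the 22-item analysis, in conventional tracing
#' order. `Gnk` (constructed gnathion) and `Xi` (ramus midpoint) can be placed
#' manually or derived geometrically with [derive_constructed()].
#'
#' @return A character vector of length 33.
#' @export
#' @examples
#' landmark_names()
landmark_names <- function() {
  c(
    "S", "N", "P", "Ba", "Or", "Pt", "Spp", "Spa", "A", "Co", "DC",
    "R1", "R2", "R3", "R4", "Xi", "hT", "Me", "Po", "B", "Pm", "Gnk",
    "UpIe", "UpIa", "LoIe", "LoIa", "1UpMdc", "1UpMma",
    "Ap", "Sn", "UpL", "LoL", "Pom"
  )
}

#' Expert consensus reference coordinates
#'
#' Per-landmark reference coordinates for the two study cephalograms ("A" and
#' "B"), established as the mean placement of six experienced orthodontists on
#' a calibrated medical display, together with the interrater reliability
#' (two-way absolute-agreement ICC of the pooled coordinate values) of each
#' landmark. Coordinates are in image pixels, x increasing anteriorly (the
#' patient faces right) and y increasing caudally (downwards).
#'
#' These coordinates are the ground truth against which student placements are
#' scored and the default geometry from which synthetic studies are simulated.
#'
#' @return A tibble with columns `landmark`, `image` ("A"/"B"), `x`, `y`
#'   (pixels) and `icc` (one value per landmark, repeated for both images).
#' @seealso [cohort_accuracy()] for the matching per-landmark accuracy norms.
#' @export
#' @examples
#' reference_landmarks() |> dplyr::filter(image == "A") |> head()
reference_landmarks <- function() {
  lm <- landmark_names()
  # x_A, y_A, x_B, y_B, icc
  v <- c(
    588.88, 152.56, 1360.58, 217.19, 1,
    934.58, 126.09, 1824.02, 179.64, 1,
    468.58, 220.84, 1197.60, 313.30, 0.99,
    453.87, 309.68, 1192.49, 473.38, 1,
    853.62, 256.17, 1703.35, 375.07, 1,
    666.47, 223.62, 1463.15, 328.32, 1,
    685.18, 339.47, 1485.33, 494.78, 0.99,
    925.97, 379.03, 1844.84, 522.46, 1,
    908.00, 389.21, 1796.58, 550.87, 1,
    526.21, 247.91, 1271.20, 342.25, 0.99,
    537.95, 277.44, 1280.59, 432.39, 1,
    681.03, 385.09, 1467.46, 568.39, 0.99,
    542.76, 372.39, 1260.77, 542.93, 1,
    602.15, 311.73, 1374.88, 479.39, 0.99,
    585.33, 494.85, 1350.11, 715.36, 0.98,
    609.52, 404.73, 1361.74, 598.12, 0.98,
    599.22, 502.05, 1344.90, 769.04, 1,
    828.56, 609.04, 1698.74, 868.92, 1,
    860.81, 580.67, 1736.28, 830.39, 1,
    864.70, 527.11, 1727.95, 756.28, 0.99,
    862.51, 556.61, 1734.57, 796.98, 1,
    854.28, 621.05, 1729.89, 877.71, 1,
    914.55, 480.74, 1825.77, 683.21, 1,
    883.65, 376.10, 1756.35, 550.53, 1,
    895.17, 452.82, 1771.70, 638.02, 1,
    834.90, 527.52, 1682.84, 760.65, 1,
    738.83, 413.65, 1542.13, 600.51, 1,
    799.05, 353.53, 1635.35, 515.25, 1,
    1058.36, 337.83, 1993.68, 469.87, 1,
    993.00, 396.88, 1909.98, 550.54, 1,
    979.41, 460.86, 1913.15, 636.74, 1,
    956.21, 497.29, 1870.12, 715.84, 1,
    927.67, 596.93, 1792.92, 847.70, 1
  )
  m <- matrix(v, ncol = 5, byrow = TRUE)
  tibble::tibble(
    landmark = rep(lm, 2),
    image = rep(c("A", "B"), each = length(lm)),
    x = c(m[, 1], m[, 3]),
    y = c(m[, 2], m[, 4]),
    icc = rep(m[, 5], 2)
  )
}

#' Per-landmark accuracy norms from the student cohort
#'
#' Observed landmark localisation accuracy of dental students (277 tracings,
#' 9141 landmarks): per-landmark mean radial error (MRE, mm) with SD and 95%
#' confidence interval, and successful detection rates (SDR, %) at the 1, 2, 4
#' and 8 mm thresholds. The 2 mm threshold is the conventional clinically
#' acceptable limit.
#'
#' These norms parameterise the default synthetic-study generator: the
#' per-landmark Rayleigh scales of [simulate_study()] are chosen so the
#' expected radial errors match the `mre_mean` column.
#'
#' @return A tibble with columns `landmark`, `mre_mean`, `mre_sd`, `ci_lower`,
#'   `ci_upper` (mm) and `sdr_1mm`, `sdr_2mm`, `sdr_4mm`, `sdr_8mm` (%).
#' @seealso [reference_landmarks()], [simulate_study()]
#' @export
cohort_accuracy <- function() {
  v <- c(
    0.79, 1.07, 0.67, 0.92, 81.9, 90.3, 99.6, 99.6,
    0.81, 1.24, 0.66, 0.96, 80.9, 92.4, 96.8, 99.6,
    3.77, 3.04, 3.41, 4.13, 15.9, 31.4, 65.0, 89.5,
    3.76, 3.69, 3.32, 4.20, 14.8, 42.6, 70.0, 85.2,
    1.77, 1.29, 1.62, 1.92, 24.5, 71.1, 94.2, 99.6,
    3.18, 3.42, 2.78, 3.59, 13.4, 47.3, 78.3, 90.6,
    1.39, 3.41, 0.99, 1.80, 64.6, 83.0, 92.8, 99.6,
    2.58, 3.80, 2.13, 3.02, 26.7, 53.4, 85.9, 96.0,
    1.58, 1.63, 1.38, 1.77, 40.4, 74.4, 94.6, 99.6,
    4.92, 3.26, 4.54, 5.31, 11.2, 27.4, 45.8, 72.9,
    2.53, 2.81, 2.20, 2.87, 28.5, 58.8, 84.1, 93.1,
    3.50, 3.96, 3.03, 3.97, 18.4, 48.0, 76.9, 87.4,
    2.76, 2.48, 2.46, 3.05, 26.7, 45.8, 80.5, 94.6,
    3.96, 3.41, 3.56, 4.36, 6.5, 30.7, 69.0, 88.8,
    5.86, 3.30, 5.47, 6.25, 10.1, 18.4, 36.1, 65.0,
    3.19, 2.16, 2.94, 3.45, 13.4, 38.3, 63.5, 98.2,
    2.89, 1.92, 2.66, 3.12, 17.0, 39.0, 74.0, 97.5,
    1.78, 2.81, 1.45, 2.11, 56.3, 78.7, 90.6, 96.0,
    1.29, 0.96, 1.17, 1.40, 46.2, 80.9, 98.2, 100.0,
    1.36, 1.17, 1.22, 1.50, 49.5, 77.6, 96.8, 99.6,
    1.19, 0.98, 1.07, 1.30, 50.9, 84.1, 99.3, 100.0,
    0.81, 0.96, 0.69, 0.92, 79.8, 93.9, 97.1, 100.0,
    0.37, 0.19, 0.35, 0.39, 99.6, 100.0, 100.0, 100.0,
    1.11, 1.08, 0.98, 1.24, 61.7, 88.1, 97.5, 99.6,
    0.28, 0.16, 0.26, 0.30, 99.6, 100.0, 100.0, 100.0,
    1.30, 0.98, 1.19, 1.42, 43.0, 84.5, 97.5, 100.0,
    1.69, 2.52, 1.39, 1.99, 53.4, 77.3, 91.3, 97.5,
    1.60, 2.18, 1.34, 1.86, 40.4, 84.8, 96.0, 96.8,
    0.61, 0.47, 0.55, 0.66, 83.0, 98.9, 100.0, 100.0,
    0.67, 0.58, 0.60, 0.74, 83.8, 97.5, 99.3, 100.0,
    1.31, 1.15, 1.17, 1.44, 54.2, 78.7, 96.8, 100.0,
    0.94, 0.86, 0.84, 1.05, 67.1, 92.8, 99.3, 100.0,
    2.05, 1.37, 1.88, 2.21, 27.8, 54.5, 91.3, 99.6
  )
  m <- matrix(v, ncol = 8, byrow = TRUE)
  tibble::tibble(
    landmark = landmark_names(),
    mre_mean = m[, 1], mre_sd = m[, 2],
    ci_lower = m[, 3], ci_upper = m[, 4],
    sdr_1mm = m[, 5], sdr_2mm = m[, 6], sdr_4mm = m[, 7], sdr_8mm = m[, 8]
  )
}

# reference set for one image as a landmark tibble (landmark, x, y)
reference_set <- function(image = "A") {
  ref <- reference_landmarks()
  ref[ref$image == image, c("landmark", "x", "y")]
}
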