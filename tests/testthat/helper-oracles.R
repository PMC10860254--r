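# Independent oracles and frozen expected values shared across test files.

# Reference measurement means established on cephalogram A by the expert
# raters, as reported with the bundled consensus coordinates.
expected_reference_values <- function() {
  tibble::tribble(
    ~measurement, ~value,
    "Facial axis", 94.41,
    "Facial depth", 86.03,
    "SNB", 75.74,
    "Mandibular plane", 19.76,
    "Inner gonion angle", 150.38,
    "Rel. mand. length", 96.31,
    "Maxillary position", 63.33,
    "SNA", 79.84,
    "Palatal plane", -4.09,
    "Rel. max. length", 83.09,
    "Lower facial height", 35.60,
    "Convexity of point A", 3.25,
    "Rel. max./mand. length", 1.17,
    "Lower incisor position", 0.55,
    "Lower incisor inclination", 25.00,
    "Upper incisor position", 5.76,
    "Upper incisor inclination", 30.30,
    "Inter incisor angle", 124.70,
    "Vertical molar distance", -0.94,
    "Sagittal molar distance", 18.26,
    "Lower lip to E-line", -3.96,
    "Upper lip drape", 83.25
  )
}

# explicit double-loop ANOVA sums of squares, independent of icc_ak()
icc_oracle <- function(m) {
  n <- nrow(m); k <- ncol(m)
  grand <- sum(m) / (n * k)
  ssr <- 0; ssc <- 0; sst <- 0
  for (i in 1:n) ssr <- ssr + k * (mean(m[i, ]) - grand)^2
  for (j in 1:k) ssc <- ssc + n * (mean(m[, j]) - grand)^2
  for (i in 1:n) for (j in 1:k) sst <- sst + (m[i, j] - grand)^2
  msr <- ssr / (n - 1)
  msc <- ssc / (k - 1)
  mse <- (sst - ssr - ssc) / ((n - 1) * (k - 1))
  (msr - mse) / (msr + (msc - mse) / n)
}
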