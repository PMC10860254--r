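# Shared fixtures built in code.

ref_set_a <- function() {
  ref <- reference_landmarks()
  ref[ref$image == "A", c("landmark", "x", "y")]
}

ref_set_b <- function() {
  ref <- reference_landmarks()
  ref[ref$image == "B", c("landmark", "x", "y")]
}

# a complete, well-formed submission built on the bundled reference
example_submission <- function(subject = "007", image = "A",
                               device = "tablet", ...) {
  new_submission(
    subject = subject, image = image, device = device,
    gender = "female", order = 0L,
    t_first = as.POSIXct("2021-03-01 12:00:00", tz = "UTC"),
    t_last = as.POSIXct("2021-03-01 12:11:48", tz = "UTC"),
    landmarks = if (image == "B") ref_set_b() else ref_set_a(),
    ...
  )
}

# rigid motion of a landmark tibble: rotate by `deg` about `center`, then
# translate by `shift`, optionally scale about center
transform_landmarks <- function(lm, deg = 0, shift = c(0, 0),
                                scale = 1, center = c(0, 0)) {
  th <- deg * pi / 180
  x <- lm$x - center[1]
  y <- lm$y - center[2]
  lm$x <- scale * (x * cos(th) - y * sin(th)) + center[1] + shift[1]
  lm$y <- scale * (x * sin(th) + y * cos(th)) + center[2] + shift[2]
  lm
}

rigid_point <- function(p, deg = 0, shift = c(0, 0), scale = 1) {
  th <- deg * pi / 180
  c(scale * (p[1] * cos(th) - p[2] * sin(th)) + shift[1],
    scale * (p[1] * sin(th) + p[2] * cos(th)) + shift[2])
}

random_point <- function() runif(2, -50, 50)

# small study records with known generating coefficients
make_records <- function(n_subjects = 60, beta_image = 0, beta_gender = 0,
                         beta_device = 0, beta_order = 0,
                         subject_sd = 0.3, resid_sd = 0.4, intercept = 2) {
  recs <- list()
  b <- rnorm(n_subjects, 0, subject_sd)
  gender <- sample(c("female", "male"), n_subjects, replace = TRUE)
  for (i in seq_len(n_subjects)) {
    a_first <- i %% 2 == 0
    dev_first <- sample(c("tablet", "desktop"), 1)   # device not aliased
    for (k in 1:2) {                                  # with order
      image <- if ((k == 1) == a_first) "A" else "B"
      device <- if (k == 1) dev_first else setdiff(c("tablet", "desktop"),
                                                   dev_first)
      mu <- intercept + b[i] +
        beta_image * (image == "B") + beta_gender * (gender[i] == "male") +
        beta_device * (device == "tablet") + beta_order * (k == 2)
      recs[[length(recs) + 1]] <- tibble::tibble(
        subject = sprintf("s%03d", i), device = device, image = image,
        gender = gender[i], order = k - 1L,
        mre = mu + rnorm(1, 0, resid_sd),
        time = 20 + b[i] + rnorm(1, 0, 2)
      )
    }
  }
  dplyr::bind_rows(recs)
}
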