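## Synthetic-study generator: emulates student landmark submissions with
## landmark-specific placement error, subject-level heterogeneity, fixed
## image/gender/order effects and tracing times, in the same JSON format the
## ingestion pipeline reads.

# E[radial error] / sigma for bivariate normal noise with axis SDs
# sigma*sqrt(a) and sigma/sqrt(a): sqrt(2/pi) * sigma_major * E(ecc), with E
# the complete elliptic integral of the second kind.
radial_mean_factor <- function(anisotropy = 1) {
  stopifnot(anisotropy >= 1)
  s_major <- sqrt(anisotropy)
  s_minor <- 1 / s_major
  ecc2 <- 1 - (s_minor / s_major)^2
  ell <- stats::integrate(function(th) sqrt(1 - ecc2 * sin(th)^2),
                          0, pi / 2, rel.tol = 1e-10)$value
  sqrt(2 / pi) * s_major * ell
}

#' Configuration of a synthetic cephalometric study
#'
#' Bundles every parameter of the generator. The defaults emulate the study
#' conditions the package's analysis pipeline was built for: 161 students
#' (108 female), 116 of whom trace both cephalograms (277 tracings in all),
#' per-landmark radial error scales calibrated so the expected radial errors
#' match the cohort norms of [cohort_accuracy()], an image-B fixed effect of
#' +0.21 mm and a male fixed effect of -0.24 mm on per-tracing MRE, and a
#' tracing-time model with a 23.79-minute first-analysis mean and a -11.72
#' minute second-analysis (learning) effect.
#'
#' @param n_students Number of students.
#' @param n_both Number of students who trace both cephalograms (the rest
#'   trace one); submissions total `2 * n_both + (n_students - n_both)`.
#' @param p_female Fraction of female students.
#' @param reference Reference coordinates, as [reference_landmarks()].
#' @param mm_per_px Named pixel spacings (mm/pixel) per image.
#' @param landmark_mre Named per-landmark target mean radial errors in mm.
#' @param anisotropy Named per-landmark SD ratios (major/minor axis) of the
#'   placement error ellipse; unnamed landmarks are isotropic. Landmarks on
#'   gradually curved edges (R1, R3, R4, Ba, Co, P) are natural candidates.
#' @param orientation_deg Named major-axis orientations in degrees (y-down
#'   frame) for anisotropic landmarks.
#' @param beta_image_B,beta_male Fixed effects on per-tracing MRE in mm.
#' @param subject_sd,resid_sd Subject random-intercept SD and residual SD of
#'   per-tracing MRE, in mm. Both are on the response scale: averaging the 33
#'   radial errors already contributes sampling noise, and the generator
#'   sizes its explicit residual component so the total matches `resid_sd`.
#' @param time_intercept,time_order Mean first-analysis tracing time and the
#'   second-analysis effect, minutes.
#' @param time_subject_sd,time_resid_sd Subject and residual SD of tracing
#'   time, minutes.
#' @param time_floor Lower bound on simulated tracing times, minutes.
#' @param time_model `"normal"` (floored) or `"lognormal"`.
#' @return A list of class `ceph_simconfig`.
#' @seealso [simulate_study()]
#' @export
simulation_config <- function(n_students = 161,
                              n_both = 116,
                              p_female = 108 / 161,
                              reference = reference_landmarks(),
                              mm_per_px = NULL,
                              landmark_mre = NULL,
                              anisotropy = NULL,
                              orientation_deg = NULL,
                              beta_image_B = 0.21,
                              beta_male = -0.24,
                              subject_sd = 0.3,
                              resid_sd = 0.4,
                              time_intercept = 23.79,
                              time_order = -11.72,
                              time_subject_sd = 3,
                              time_resid_sd = 4,
                              time_floor = 1,
                              time_model = c("normal", "lognormal")) {
  time_model <- match.arg(time_model)
  stopifnot(n_both <= n_students, p_female >= 0, p_female <= 1,
            subject_sd >= 0, resid_sd >= 0,
            time_subject_sd >= 0, time_resid_sd >= 0)
  if (is.null(mm_per_px)) {
    ref_a <- reference[reference$image == "A", ]
    mm_per_px <- c(A = calibrate_spacing(ref_a, "Convexity of point A", 3.25),
                   B = 0.125)
  }
  if (is.null(landmark_mre)) {
    norms <- cohort_accuracy()
    landmark_mre <- setNames(norms$mre_mean, norms$landmark)
  }
  stopifnot(all(landmark_mre >= 0), all(mm_per_px > 0))
  structure(
    list(
      n_students = n_students, n_both = n_both, p_female = p_female,
      reference = reference, mm_per_px = mm_per_px,
      landmark_mre = landmark_mre,
      anisotropy = anisotropy, orientation_deg = orientation_deg,
      beta_image_B = beta_image_B, beta_male = beta_male,
      subject_sd = subject_sd, resid_sd = resid_sd,
      time_intercept = time_intercept, time_order = time_order,
      time_subject_sd = time_subject_sd, time_resid_sd = time_resid_sd,
      time_floor = time_floor, time_model = time_model
    ),
    class = "ceph_simconfig"
  )
}

#' Simulate one landmark placement
#'
#' Draws a placement around a reference point with bivariate normal noise.
#' With `anisotropy = a`, the axis SDs are `scale_mm * sqrt(a)` along the
#' major axis (at `orientation_deg` in the y-down frame) and
#' `scale_mm / sqrt(a)` across it, so the SD ratio is `a` and the variance
#' ratio `a^2`. For isotropic noise the expected radial error is
#' `scale_mm * sqrt(pi / 2)` (the Rayleigh mean); in general it is
#' `sqrt(2 / pi) * scale_mm * sqrt(a) * E(ecc)` with `E` the complete
#' elliptic integral of the second kind.
#'
#' @param ref Reference point `c(x, y)` in pixels.
#' @param scale_mm Noise scale (per-axis SD for isotropic noise) in mm; 0
#'   returns the reference exactly.
#' @param mm_per_px Pixel spacing, mm/pixel.
#' @param anisotropy Major/minor axis SD ratio, >= 1.
#' @param orientation_deg Major-axis orientation in degrees.
#' @param n Number of draws.
#' @return An `n` x 2 matrix of placements in pixels.
#' @export
simulate_placement <- function(ref, scale_mm, mm_per_px = 1,
                               anisotropy = 1, orientation_deg = 0, n = 1) {
  stopifnot(scale_mm >= 0, mm_per_px > 0, anisotropy >= 1)
  ref <- as_point(ref)
  if (scale_mm == 0) {
    return(matrix(rep(ref, each = n), ncol = 2,
                  dimnames = list(NULL, c("x", "y"))))
  }
  s_major <- scale_mm * sqrt(anisotropy)
  s_minor <- scale_mm / sqrt(anisotropy)
  u <- rnorm(n, 0, s_major)
  v <- rnorm(n, 0, s_minor)
  th <- orientation_deg * pi / 180
  dx <- u * cos(th) - v * sin(th)
  dy <- u * sin(th) + v * cos(th)
  cbind(x = ref[1] + dx / mm_per_px, y = ref[2] + dy / mm_per_px)
}

#' Simulate expert rater sets
#'
#' `k` noisy copies of a true landmark set, with isotropic Gaussian noise of
#' `noise_px` pixels per axis; their [build_reference()] mean converges to
#' the truth as the noise shrinks.
#'
#' @param ref_truth Landmark tibble (columns `landmark`, `x`, `y`).
#' @param k Number of raters (>= 2).
#' @param noise_px Per-axis placement SD in pixels.
#' @return A list of `k` landmark tibbles.
#' @export
simulate_raters <- function(ref_truth, k = 6, noise_px = 1) {
  stopifnot(k >= 2, noise_px >= 0)
  lapply(seq_len(k), function(i) {
    out <- ref_truth
    out$x <- out$x + rnorm(nrow(out), 0, noise_px)
    out$y <- out$y + rnorm(nrow(out), 0, noise_px)
    out
  })
}

#' Simulate a complete synthetic study
#'
#' Generates student submissions with the statistical structure the analysis
#' pipeline assumes. Each student receives a gender, a subject random
#' intercept, and a crossover image-device pairing (image A on one device,
#' image B on the other, pairing alternating across students as it was
#' switched semester-wise in the emulated setting). Students trace one or
#' both images; each tracing's per-landmark placements are drawn with
#' [simulate_placement()], with the per-landmark target mean radial errors
#' scaled so that the tracing's expected MRE is shifted additively by the
#' image/gender fixed effects, the subject intercept and a residual draw.
#' Tracing times follow the configured time model, floored at
#' `config$time_floor`.
#'
#' With `include_rejects = TRUE` the raw batch additionally contains tracings
#' that the exclusion rules must catch: 16 of a wrong cephalogram, 5
#' screenshot tracings, 3 with missing landmarks and 2 invalid files.
#'
#' @param config A [simulation_config()].
#' @param seed Integer seed; the same seed reproduces the study byte for
#'   byte, including the JSON files written to `dir`.
#' @param dir Optional directory: submissions are written as JSON files
#'   (invalid ones as truncated files).
#' @param include_rejects Also generate the excludable submissions above.
#' @return A list of class `ceph_synthetic_study` with `submissions` (list of
#'   `ceph_submission` / `ceph_invalid`), `records` (tibble of study records
#'   for the valid tracings: `subject`, `device`, `image`, `gender`, `order`,
#'   `time`, `mre`), and `config` (the generating truth).
#' @export
simulate_study <- function(config = simulation_config(), seed = NULL,
                           dir = NULL, include_rejects = FALSE) {
  if (!is.null(seed)) set.seed(seed)
  cfg <- config
  lm_names <- names(cfg$landmark_mre)
  ref_sets <- split(cfg$reference[, c("landmark", "x", "y")],
                    cfg$reference$image)

  n <- cfg$n_students
  n_female <- round(n * cfg$p_female)
  genders <- sample(rep(c("female", "male"), c(n_female, n - n_female)))
  subjects <- sprintf("%03d", seq_len(n))
  # crossover pairing, switched between (semester) halves of the cohort
  pairing_a_tablet <- sample(rep(c(TRUE, FALSE), length.out = n))
  b_subj <- rnorm(n, 0, cfg$subject_sd)
  b_time <- rnorm(n, 0, cfg$time_subject_sd)
  both <- sample(c(rep(TRUE, cfg$n_both), rep(FALSE, n - cfg$n_both)))

  # centre the per-landmark baseline so the marginal expected MRE equals the
  # configured per-landmark means despite the fixed-effect shifts
  mbar <- mean(cfg$landmark_mre)
  centering <- 0.5 * cfg$beta_image_B + (1 - cfg$p_female) * cfg$beta_male
  base_mre <- if (mbar > 0) {
    cfg$landmark_mre * (1 - centering / mbar)
  } else {
    cfg$landmark_mre
  }
  mbar_base <- mean(base_mre)

  aniso <- setNames(rep(1, length(lm_names)), lm_names)
  orient <- setNames(rep(0, length(lm_names)), lm_names)
  if (!is.null(cfg$anisotropy)) {
    aniso[names(cfg$anisotropy)] <- cfg$anisotropy
  }
  if (!is.null(cfg$orientation_deg)) {
    orient[names(cfg$orientation_deg)] <- cfg$orientation_deg
  }
  factors <- vapply(aniso, radial_mean_factor, numeric(1))

  # resid_sd is the response-scale residual SD of per-tracing MRE; averaging
  # 33 radial draws already contributes sampling noise, so the explicit
  # residual component is the remainder (at baseline scales; the dependence
  # of the placement scales on the per-tracing shift is second order)
  sigma_base <- base_mre / factors
  l <- length(lm_names)
  var_intrinsic <- sum(sigma_base^2 * (aniso + 1 / aniso) - base_mre^2) / l^2
  resid_extra <- sqrt(max(0, cfg$resid_sd^2 - var_intrinsic))

  base_time <- as.POSIXct("2021-03-01 09:00:00", tz = "UTC")

  make_tracing <- function(i, device, order_index) {
    image <- if (pairing_a_tablet[i] == (device == "tablet")) "A" else "B"
    delta <- cfg$beta_image_B * (image == "B") +
      cfg$beta_male * (genders[i] == "male") +
      b_subj[i] + rnorm(1, 0, resid_extra)
    f <- if (mbar_base > 0) max(0.01, 1 + delta / mbar_base) else 1
    scales <- (f * base_mre) / factors
    ref <- ref_sets[[image]]
    ord <- match(lm_names, ref$landmark)
    sp <- cfg$mm_per_px[[image]]
    pts <- t(vapply(seq_along(lm_names), function(j) {
      simulate_placement(c(ref$x[ord[j]], ref$y[ord[j]]), scales[j], sp,
                         aniso[j], orient[j], n = 1)[1, ]
    }, numeric(2)))
    minutes <- if (cfg$time_model == "lognormal") {
      mu <- cfg$time_intercept + b_time[i] +
        cfg$time_order * (order_index == 1)
      exp(rnorm(1, log(max(mu, cfg$time_floor)),
                cfg$time_resid_sd / max(mu, cfg$time_floor)))
    } else {
      cfg$time_intercept + b_time[i] + cfg$time_order * (order_index == 1) +
        rnorm(1, 0, cfg$time_resid_sd)
    }
    minutes <- max(cfg$time_floor, minutes)
    t_first <- base_time + round(runif(1, 0, 3600 * 24 * 200))
    new_submission(
      subject = subjects[i], image = image, device = device,
      gender = genders[i], order = order_index,
      t_first = t_first, t_last = t_first + round(minutes * 60, 3),
      landmarks = tibble::tibble(landmark = lm_names,
                                 x = pts[, 1], y = pts[, 2])
    )
  }

  submissions <- list()
  for (i in seq_len(n)) {
    if (both[i]) {
      first_device <- sample(c("tablet", "desktop"), 1)
      second_device <- setdiff(c("tablet", "desktop"), first_device)
      submissions <- c(submissions, list(
        make_tracing(i, first_device, 0L),
        make_tracing(i, second_device, 1L)
      ))
    } else {
      submissions <- c(submissions, list(
        make_tracing(i, sample(c("tablet", "desktop"), 1), 0L)
      ))
    }
  }

  records <- purrr::map_dfr(submissions, function(s) {
    d <- radial_errors(s, ref_sets[[s$image]], cfg$mm_per_px[[s$image]])
    tibble::tibble(
      subject = s$subject, device = s$device, image = s$image,
      gender = s$gender, order = s$order,
      time = tracing_time(s), mre = mre(d)
    )
  })

  rejects <- list()
  if (include_rejects) {
    spoiled <- function(idx, n_spoil, fun) {
      lapply(seq_len(n_spoil), function(j) fun(j))
    }
    mk <- function(j, image, capture = "dicom", drop = 0) {
      src <- make_tracing(sample(n, 1), sample(c("tablet", "desktop"), 1), 0L)
      src$subject <- sprintf("x%02d", length(rejects) + j)
      src$image <- image
      src$capture <- capture
      if (drop > 0) {
        src$landmarks <- src$landmarks[-sample(nrow(src$landmarks), drop), ]
      }
      src
    }
    rejects <- c(
      lapply(1:16, function(j) mk(j, image = "C")),
      lapply(1:5, function(j) mk(16 + j, image = "A",
                                 capture = "screenshot")),
      lapply(1:3, function(j) mk(21 + j, image = "B", drop = 3)),
      lapply(1:2, function(j) {
        structure(list(source = sprintf("invalid%02d.json", j),
                       message = "not valid JSON"),
                  class = "ceph_invalid")
      })
    )
  }

  all_subs <- c(submissions, rejects)
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    for (i in seq_along(all_subs)) {
      s <- all_subs[[i]]
      path <- file.path(dir, sprintf("submission%03d.json", i))
      if (inherits(s, "ceph_invalid")) {
        writeLines('{"subject": "truncated', path)
      } else {
        write_submission(s, path)
      }
    }
  }

  structure(
    list(submissions = all_subs, records = records, config = cfg),
    class = "ceph_synthetic_study"
  )
}

#' @export
print.ceph_synthetic_study <- function(x, ...) {
  cat(sprintf(
    "<ceph_synthetic_study> %d submissions (%d study records), %d students\n",
    length(x$submissions), nrow(x$records), x$config$n_students))
  invisible(x)
}
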