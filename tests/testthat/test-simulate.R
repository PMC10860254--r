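# The synthetic-study generator.

test_that("simulate_placement reproduces the Rayleigh radial-error mean", {
  expect_equal(simulate_placement(c(10, 20), 0, n = 3),
               cbind(x = rep(10, 3), y = rep(20, 3)))
  set.seed(61)
  sigma <- 1.4
  draws <- simulate_placement(c(0, 0), sigma, mm_per_px = 1, n = 10000)
  r <- sqrt(draws[, 1]^2 + draws[, 2]^2)
  expect_lt(abs(mean(r) / (sigma * sqrt(pi / 2)) - 1), 0.02)
  # spacing converts mm noise into pixels
  draws_px <- simulate_placement(c(0, 0), sigma, mm_per_px = 0.5, n = 10000)
  r_px <- sqrt(draws_px[, 1]^2 + draws_px[, 2]^2)
  expect_lt(abs(mean(r_px) / (2 * sigma * sqrt(pi / 2)) - 1), 0.02)
})

test_that("anisotropic placement has the configured covariance structure", {
  set.seed(62)
  draws <- simulate_placement(c(0, 0), 1, anisotropy = 3,
                              orientation_deg = 0, n = 10000)
  ratio <- var(draws[, 1]) / var(draws[, 2])
  expect_lt(abs(ratio / 9 - 1), 0.1)
  # rotated orientation moves the variance across axes
  rot <- simulate_placement(c(0, 0), 1, anisotropy = 3,
                            orientation_deg = 90, n = 10000)
  expect_lt(abs(var(rot[, 2]) / var(rot[, 1]) / 9 - 1), 0.1)
})

test_that("the radial mean factor matches the isotropic closed form", {
  expect_equal(cephmetrics:::radial_mean_factor(1), sqrt(pi / 2),
               tolerance = 1e-9)
  set.seed(63)
  # and empirically for an anisotropic case
  f3 <- cephmetrics:::radial_mean_factor(3)
  draws <- simulate_placement(c(0, 0), 1, anisotropy = 3, n = 20000)
  expect_lt(abs(mean(sqrt(rowSums(draws^2))) / f3 - 1), 0.02)
})

test_that("simulate_raters converges to the truth through build_reference", {
  ref <- ref_set_a()
  set.seed(64)
  exact <- simulate_raters(ref, k = 3, noise_px = 0)
  expect_equal(exact[[1]]$x, ref$x)
  expect_equal(exact[[2]]$y, ref$y)

  sets <- simulate_raters(ref, k = 6, noise_px = 1)
  rebuilt <- build_reference(sets)
  expect_true(all(abs(rebuilt$x - ref$x) < 1.5))   # ~3.7 sd of sigma/sqrt(6)
  expect_true(all(abs(rebuilt$y - ref$y) < 1.5))
})

test_that("the same seed reproduces byte-identical submission JSON", {
  cfg <- simulation_config(n_students = 8, n_both = 5)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  simulate_study(cfg, seed = 99, dir = d1, include_rejects = TRUE)
  simulate_study(cfg, seed = 99, dir = d2, include_rejects = TRUE)
  f1 <- list.files(d1, full.names = TRUE)
  f2 <- list.files(d2, full.names = TRUE)
  expect_equal(basename(f1), basename(f2))
  for (i in seq_along(f1)) {
    expect_identical(readLines(f1[i], warn = FALSE),
                     readLines(f2[i], warn = FALSE))
  }
})

test_that("zero-noise configuration reproduces the reference exactly", {
  cfg <- simulation_config(n_students = 6, n_both = 4,
                           landmark_mre = setNames(rep(0, 33),
                                                   landmark_names()),
                           beta_image_B = 0, beta_male = 0,
                           subject_sd = 0, resid_sd = 0)
  st <- simulate_study(cfg, seed = 65)
  expect_equal(st$records$mre, rep(0, nrow(st$records)))
  ref_a <- ref_set_a()
  sub_a <- purrr::detect(st$submissions, function(s) s$image == "A")
  expect_equal(sub_a$landmarks$x, ref_a$x[match(sub_a$landmarks$landmark,
                                                ref_a$landmark)])
})

test_that("simulated per-landmark error means average to the configured MRE", {
  cfg <- simulation_config(n_students = 360, n_both = 240)  # 600 tracings
  st <- simulate_study(cfg, seed = 66)
  scored <- score_submissions(
    st$submissions,
    split(cfg$reference[, c("landmark", "x", "y")], cfg$reference$image),
    cfg$mm_per_px
  )
  tab <- summarize_accuracy(scored)
  target <- mean(cfg$landmark_mre)
  got <- attr(tab, "overall")["overall_mre"]
  expect_lt(abs(got - target) / target, 0.02)
})

test_that("study design follows the crossover and cohort structure", {
  cfg <- simulation_config(n_students = 40, n_both = 30)
  st <- simulate_study(cfg, seed = 67)
  recs <- st$records
  expect_equal(nrow(recs), 70)
  expect_equal(length(unique(recs$subject)), 40)
  # students tracing both images use different devices and images
  twice <- recs |> dplyr::count(subject) |> dplyr::filter(n == 2)
  both <- recs[recs$subject %in% twice$subject, ]
  pairs <- both |> dplyr::group_by(subject) |>
    dplyr::summarise(n_img = dplyr::n_distinct(image),
                     n_dev = dplyr::n_distinct(device))
  expect_true(all(pairs$n_img == 2))
  expect_true(all(pairs$n_dev == 2))
  expect_true(all(recs$time >= cfg$time_floor))
})
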