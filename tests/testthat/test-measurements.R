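# The 22-item measurement engine against the bundled expert reference
# (expected values in helper-oracles.R).

test_that("the 22-item analysis reproduces the expert reference values", {
  ref_a <- ref_set_a()
  spacing <- calibrate_spacing(ref_a, "Convexity of point A", 3.25)
  res <- compute_analysis(ref_a, spacing)
  expect_equal(nrow(res), 22)

  joined <- dplyr::left_join(res, expected_reference_values(),
                             by = "measurement")
  angles <- joined[joined$unit == "deg", ]
  expect_true(all(abs(angles$value.x - angles$value.y) < 0.1))
  mms <- joined[joined$unit == "mm", ]
  expect_true(all(abs(mms$value.x - mms$value.y) < 0.15))
  # the ratio rule is a reconstruction; it does not reproduce the printed
  # mean (which may average per-rater ratios) and is flagged as such
  defs <- measurement_definitions()
  expect_equal(defs$status[defs$measurement == "Rel. max./mand. length"],
               "reconstructed")
  ratio <- joined[joined$unit == "ratio", ]
  expect_equal(ratio$value.x, ratio$value.y, tolerance = 0.02)
})

test_that("without spacing the mm items are reported in px and flagged", {
  res <- compute_analysis(ref_set_a())
  expect_true(all(res$unit[!res$calibrated] == "px"))
  expect_equal(sum(!res$calibrated), 8)
  # angle and ratio items do not depend on the spacing at all
  res_sp <- compute_analysis(ref_set_a(), 0.2)
  keep <- res$unit %in% c("deg", "ratio")
  expect_equal(res$value[keep], res_sp$value[keep])
})

test_that("all 22 items are invariant under rigid motion", {
  ref_a <- ref_set_a()
  spacing <- 0.2043
  base <- compute_analysis(ref_a, spacing)
  moved <- transform_landmarks(ref_a, deg = 17, shift = c(120, -35))
  res <- compute_analysis(moved, spacing)
  expect_equal(res$value, base$value, tolerance = 1e-8)
  # uniform scaling with inverse spacing scaling leaves everything unchanged
  scaled <- transform_landmarks(ref_a, scale = 2)
  res2 <- compute_analysis(scaled, spacing / 2)
  expect_equal(res2$value, base$value, tolerance = 1e-8)
})

test_that("spacing calibration anchors agree and scale correctly", {
  ref_a <- ref_set_a()
  sp_conv <- calibrate_spacing(ref_a, "Convexity of point A", 3.25)
  expect_equal(sp_conv, 0.2043, tolerance = 1e-3)
  sp_mand <- calibrate_spacing(ref_a, "Rel. mand. length", 96.31)
  expect_lt(abs(sp_conv - sp_mand) / sp_conv, 0.002)
  doubled <- transform_landmarks(ref_a, scale = 2)
  expect_equal(calibrate_spacing(doubled, "Convexity of point A", 3.25),
               sp_conv / 2, tolerance = 1e-10)
  expect_error(calibrate_spacing(ref_a, "SNA", 80), "mm-valued")
})

test_that("constructed landmarks reproduce the consensus placements", {
  ref_a <- ref_set_a()
  bare <- ref_a[!ref_a$landmark %in% c("Gnk", "Xi"), ]
  filled <- derive_constructed(bare)
  gnk <- filled[filled$landmark == "Gnk", ]
  expect_lt(sqrt((gnk$x - 854.28)^2 + (gnk$y - 621.05)^2), 0.05)
  xi <- filled[filled$landmark == "Xi", ]
  expect_lt(sqrt((xi$x - 609.52)^2 + (xi$y - 404.73)^2), 0.2)

  # manual placements win by default; `constructed` overrides them
  kept <- derive_constructed(ref_a)
  expect_equal(kept[kept$landmark == "Xi", ]$x, 609.52)
  forced <- derive_constructed(ref_a, prefer = "constructed")
  expect_equal(forced[forced$landmark == "Gnk", ]$x, gnk$x)
  report <- attr(kept, "construction_report")
  expect_true(all(report$distance_px < 0.2))

  # the condylar midpoint DC lies on the Ba-N line by definition
  ban <- line_through(c(453.87, 309.68), c(934.58, 126.09))
  dc <- ref_a[ref_a$landmark == "DC", ]
  expect_lt(abs(signed_point_line_distance(c(dc$x, dc$y), ban)), 0.2)
})

test_that("construction is equivariant under rotation of all inputs", {
  ref_a <- ref_set_a()
  bare <- ref_a[!ref_a$landmark %in% c("Gnk", "Xi"), ]
  filled <- derive_constructed(bare)
  rot <- transform_landmarks(bare, deg = 33, shift = c(5, 9))
  filled_rot <- derive_constructed(rot)
  for (nm in c("Gnk", "Xi")) {
    p0 <- c(filled$x[filled$landmark == nm], filled$y[filled$landmark == nm])
    p1 <- c(filled_rot$x[filled_rot$landmark == nm],
            filled_rot$y[filled_rot$landmark == nm])
    expect_equal(p1, rigid_point(p0, 33, c(5, 9)), tolerance = 1e-8)
  }
})
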