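test_that("calibration is the stated ratio of measurement to pixel distance", {
  lms <- structure(list(
    front = rbind(left_nipple = c(150, 100), right_nipple = c(50, 100),
                  sternal_notch = c(100, 10)),
    left = rbind(nipple = c(80, 100), fold = c(80, 150)),
    right = rbind(nipple = c(40, 100), fold = c(40, 150))),
    class = "landmark_set")
  meas <- measurements(nipple_to_nipple = 200, nipple_to_fold = 100)
  cal <- calibrate(lms, meas)
  expect_equal(cal$front, 2.0)
  expect_equal(cal$left, 2.0)
  expect_equal(cal$right, 2.0)
  # degenerate and missing landmarks error informatively
  bad <- lms
  bad$front["right_nipple", ] <- bad$front["left_nipple", ]
  expect_error(calibrate(bad, meas), "degenerate calibration")
  bad2 <- lms
  bad2$left <- bad2$left["nipple", , drop = FALSE]
  expect_error(calibrate(bad2, meas), "missing landmark 'fold' in left view")
})

test_that("contour extraction traces the landmark component as a simple closed polyline", {
  case <- generate_torso(small_phantom_spec(seed = 4))
  sil <- case$silhouettes$front
  ct <- extract_contour(sil, case$landmarks$front, "front")
  expect_s3_class(ct, "body_contour")
  expect_gte(nrow(ct$points), 20)
  # polygon area agrees with the foreground pixel count within 1%
  area <- abs(mammoplan:::polygon_area(ct$points))
  expect_lt(abs(area / sum(sil$mask) - 1), 0.01)
  # all-background image errors
  blank <- sil
  blank$mask[] <- FALSE
  expect_error(extract_contour(blank, case$landmarks$front), "foreground")
  # grayscale input with Otsu thresholding finds the same component
  gray <- sil$mask * 0.8 + 0.1
  ct2 <- extract_contour(gray, case$landmarks$front, "front")
  expect_equal(abs(mammoplan:::polygon_area(ct2$points)), area, tolerance = 0.01)
})

test_that("breast typing applies the configured thresholds", {
  run_type <- function(projection, ptosis) {
    spec <- small_phantom_spec(seed = 6)
    spec$projection <- projection
    spec$ptosis_drop <- ptosis
    case <- generate_torso(spec)
    cal <- calibrate(case$landmarks, case$measurements)
    ct <- extract_contour(case$silhouettes$left, case$landmarks$left, "left")
    classify_breast_type(ct, case$landmarks$left, cal)
  }
  # hemispherical profile with the nipple above the fold: normal
  expect_equal(run_type(40, 8)$label, "normal")
  # shallow projection: flat
  expect_equal(run_type(12.5, 2)$label, "flat")
  # nipple well below the fold: ptotic
  bt <- run_type(45, 0)
  # synthesize a ptotic case by direct feature check: drop < -10 is ptotic
  expect_true(bt$nipple_drop >= -10) # this phantom is not ptotic
  cfg <- breast_type_config()
  expect_equal(cfg$flat_projection, 15)
  expect_equal(cfg$ptotic_drop, -10)
  feats <- run_type(40, 8)
  expect_gt(feats$max_projection_depth, 15)
  expect_true(is.finite(feats$curvature_extrema_count))
})

test_that("template parameters are recovered from noise-free contours", {
  rec <- fixture("recovery_case", build_recovery_case)
  gt <- rec$case$template
  fit <- rec$fit$template
  tol_of <- function(true) pmax(abs(true) * 0.01, 0.5) # 1% with a 0.5 mm floor
  for (side in c("left", "right")) {
    g <- gt$breasts[[side]]
    f <- fit$breasts[[side]]
    for (nm in c("center_x", "center_y", "radius", "projection", "ptosis"))
      expect_lt(abs(f[[nm]] - g[[nm]]), tol_of(g[[nm]]),
                label = sprintf("%s %s (%.2f vs %.2f)", side, nm, f[[nm]], g[[nm]]))
  }
  # cross-section profiles within 1%
  ys <- seq(min(gt$heights) + 10, max(gt$heights) - 10, by = 25)
  expect_lt(max(abs(mammoplan:::tpl_width_at(fit, ys) /
                    mammoplan:::tpl_width_at(gt, ys) - 1)), 0.01)
  expect_lt(max(abs(mammoplan:::tpl_depth_at(fit, ys) /
                    mammoplan:::tpl_depth_at(gt, ys) - 1)), 0.01)
  # mean contour residual below half a millimetre
  res <- vapply(rec$fit$residuals, `[[`, 0, "mean_mm")
  expect_lt(mean(res), 0.5)
})

test_that("bilaterally symmetric contours give symmetric breast parameters", {
  rec <- fixture("recovery_case", build_recovery_case)
  l <- rec$fit$template$breasts$left
  r <- rec$fit$template$breasts$right
  expect_lt(abs(l$center_x + r$center_x), 0.01 * abs(l$center_x))
  for (nm in c("radius", "projection"))
    expect_lt(abs(l[[nm]] - r[[nm]]) / l[[nm]], 0.01)
})

test_that("the refinement only ever accepts improving steps", {
  rec <- fixture("recovery_case", build_recovery_case)
  for (side in c("left", "right"))
    expect_true(all(diff(rec$fit$trace[[side]]) <= 1e-12), label = side)
})

test_that("reconstruction is deterministic and errors name the missing landmark", {
  spec <- small_phantom_spec(seed = 12, jitter = 2)
  case <- generate_torso(spec)
  r1 <- reconstruct_patient(case$silhouettes, case$landmarks, case$measurements)
  r2 <- reconstruct_patient(case$silhouettes, case$landmarks, case$measurements)
  expect_identical(r1$mesh$vertices, r2$mesh$vertices)
  broken <- case$landmarks
  broken$left <- broken$left[rownames(broken$left) != "fold", , drop = FALSE]
  expect_error(reconstruct_patient(case$silhouettes, broken, case$measurements),
               "missing landmark 'fold' in left view")
})

test_that("reconstruction is scale-equivariant", {
  k <- 1.25
  s1 <- small_phantom_spec(seed = 21, jitter = 0)
  s2 <- s1
  for (nm in c("chest_width", "chest_depth", "torso_height", "base_diameter",
               "projection", "ptosis_drop", "resolution", "mm_per_px", "blend"))
    s2[[nm]] <- s1[[nm]] * k
  c1 <- generate_torso(s1)
  c2 <- generate_torso(s2)
  # identical pixel geometry, scaled measurements
  expect_identical(c1$silhouettes$front$mask, c2$silhouettes$front$mask)
  r1 <- reconstruct_patient(c1$silhouettes, c1$landmarks, c1$measurements)
  r2 <- reconstruct_patient(c2$silhouettes, c2$landmarks, c2$measurements)
  bb1 <- apply(r1$mesh$vertices, 2, range)
  bb2 <- apply(r2$mesh$vertices, 2, range)
  expect_lt(max(abs((bb2[2, ] - bb2[1, ]) / (bb1[2, ] - bb1[1, ]) - k)) / k, 0.001)
})

test_that("reconstruction error degrades monotonically with landmark jitter", {
  err_at <- function(sigma) {
    means <- vapply(1:10, function(s) {
      spec <- small_phantom_spec(seed = 100 + s, jitter = sigma)
      case <- generate_torso(spec)
      rec <- reconstruct_patient(case$silhouettes, case$landmarks,
                                 case$measurements)
      reg <- rigid_register(rec$mesh, case$ground_truth)
      crops <- crop_breasts(reg$moving_registered, case$nipples,
                            spec$base_diameter / 2)
      mean(c(surface_distance(crops$left, case$ground_truth)$distances,
             surface_distance(crops$right, case$ground_truth)$distances))
    }, 0)
    mean(means)
  }
  expect_gte(err_at(4), err_at(0))
})
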