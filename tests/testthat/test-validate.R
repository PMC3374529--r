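test_that("ICP recovers known rigid perturbations", {
  mesh <- build_torso_mesh(phantom_template(small_phantom_spec()), 5)
  # identical meshes: identity transform, essentially zero rms
  reg0 <- rigid_register(mesh, mesh)
  expect_lt(reg0$rms, 1e-6)
  expect_lt(max(abs(reg0$transform$rotation - diag(3))), 1e-6)
  # pure translation
  t1 <- rigid_transform(translation = c(10, 5, -3))
  reg1 <- rigid_register(apply_rigid(mesh, t1), mesh, max_iter = 500, tol = 1e-7)
  expect_lt(max(abs(reg1$transform$translation - c(-10, -5, 3))), 0.1)
  # 15 degree rotation about +y
  R <- rotation_about("y", 15)
  reg2 <- rigid_register(apply_rigid(mesh, rigid_transform(R)), mesh, max_iter = 500, tol = 1e-7)
  ang <- acos(pmin(1, (sum(diag(reg2$transform$rotation %*% R)) - 1) / 2)) * 180 / pi
  expect_lt(ang, 0.1)
  # residual is non-increasing across iterations
  expect_true(all(diff(reg2$rms_trace) <= 1e-9))
  # far-apart meshes are flagged, not chased
  far <- apply_rigid(mesh, rigid_transform(translation = c(1000, 0, 0)))
  expect_false(rigid_register(far, mesh)$converged)
})

test_that("breast cropping keeps exactly the stated vertex set", {
  case <- generate_torso(small_phantom_spec(seed = 8))
  mesh <- case$ground_truth
  r <- case$spec$base_diameter / 2
  crops <- crop_breasts(mesh, case$nipples, r)
  expect_lt(nrow(crops$left$vertices), nrow(mesh$vertices))
  for (side in c("left", "right")) {
    nip <- case$nipples[side, ]
    d <- sqrt(colSums((t(crops[[side]]$vertices) - nip)^2))
    expect_lte(max(d), 1.2 * r + 1e-9)
    # the nipple's nearest vertex is retained
    expect_lt(min(d), case$spec$resolution)
  }
  # medial bound: left crop entirely on the patient-left side of the sternum
  expect_gte(min(crops$left$vertices[, 1]), 0)
  expect_lte(max(crops$right$vertices[, 1]), 0)
  expect_error(crop_breasts(mesh, case$nipples + 1e4, r), "empty crop")
})

test_that("directed surface distance matches the exhaustive oracle and records direction", {
  sp <- sphere_mesh(8, 12)
  self <- surface_distance(sp, sp)
  expect_equal(max(self$distances), 0, tolerance = 1e-9)
  expect_match(self$direction, "reconstruction -> reference")
  # parallel planar patches 2 mm apart measure exactly 2 mm
  plane <- tri_mesh(rbind(c(0, 0, 0), c(10, 0, 0), c(10, 10, 0), c(0, 10, 0)),
                    rbind(c(0, 1, 2), c(0, 2, 3)))
  lifted <- plane
  lifted$vertices[, 3] <- 2
  d <- surface_distance(lifted, plane)
  expect_equal(unique(round(d$distances, 9)), 2)
  # exhaustive per-face oracle on a small mesh
  cube <- cube_mesh(7, c(1, 2, 3))
  got <- surface_distance(cube, sp)$distances
  want <- cpp_point_mesh_dist_brute(cube$vertices, sp$vertices, sp$faces)
  expect_lt(max(abs(got - want)), 1e-9)
  # invariant to a common rigid transform of both meshes
  tr <- rigid_transform(rotation_about("z", 33), c(4, -7, 2))
  got2 <- surface_distance(apply_rigid(cube, tr), apply_rigid(sp, tr))$distances
  expect_lt(max(abs(got2 - got)), 1e-9)
  # report invariants
  rep <- surface_distance(cube, sp, side = "left")
  expect_true(rep$q1 <= rep$median && rep$median <= rep$q3 && rep$q3 <= rep$max)
  expect_equal(rep$n_points, length(rep$distances))
})

test_that("box-plot statistics follow the 1.5 IQR rule and a quantile oracle", {
  bs <- boxplot_stats(c(1, 2, 3, 4, 5))
  expect_equal(bs$stats$median, 3)
  expect_equal(bs$stats$q1, 2)
  expect_equal(bs$stats$q3, 4)
  expect_equal(bs$stats$n_outliers, 0)
  # constant vector: zero IQR, no outliers
  bc <- boxplot_stats(rep(2.5, 40))
  expect_equal(bc$stats$q1, bc$stats$q3)
  expect_equal(bc$stats$n_outliers, 0)
  # sort-and-interpolate oracle for the quartiles (linear interpolation)
  q_oracle <- function(x, p) {
    x <- sort(x)
    n <- length(x)
    h <- (n - 1) * p + 1
    lo <- floor(h)
    hi <- ceiling(h)
    x[lo] + (h - lo) * (x[hi] - x[lo])
  }
  set.seed(123)
  for (i in 1:1000) {
    x <- rexp(sample(5:60, 1))
    bs <- boxplot_stats(x)$stats
    expect_equal(bs$q1, q_oracle(x, 0.25))
    expect_equal(bs$median, q_oracle(x, 0.5))
    expect_equal(bs$q3, q_oracle(x, 0.75))
    iqr <- bs$q3 - bs$q1
    expect_true(all(boxplot_stats(x)$outliers < bs$q1 - 1.5 * iqr |
                    boxplot_stats(x)$outliers > bs$q3 + 1.5 * iqr))
  }
  expect_error(boxplot_stats(numeric(0)), "empty")
})

test_that("tidiers and the box plot return well-formed objects", {
  sp <- sphere_mesh(8, 10)
  rep <- surface_distance(cube_mesh(7, c(1, 2, 3)), sp, side = "left")
  td <- tidy(rep)
  expect_s3_class(td, "tbl_df")
  expect_equal(nrow(td), rep$n_points)
  gl <- glance(rep)
  expect_equal(gl$mean_mm, rep$mean)
  p <- autoplot(rep)
  expect_s3_class(p, "ggplot")
  reg <- rigid_register(sp, sp)
  expect_s3_class(glance(reg), "tbl_df")
})
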