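test_that("phantom spec validates its fields", {
  expect_error(torso_phantom_spec(chest_width = -1), "> 0")
  expect_error(torso_phantom_spec(base_diameter = 400), "smaller than chest_width")
  expect_error(torso_phantom_spec(landmark_jitter_sigma = -1), ">= 0")
  expect_error(torso_phantom_spec(resolution = 50), "3 edge lengths")
})

test_that("generated torso is watertight, symmetric and deterministic", {
  spec <- small_phantom_spec(seed = 2)
  mesh <- build_torso_mesh(phantom_template(spec), spec$resolution)
  expect_true(all(edge_share_counts(mesh) == 2))
  expect_lt(mirror_deviation(mesh), 0.1)
  c1 <- generate_torso(spec)
  c2 <- generate_torso(spec)
  expect_identical(c1$ground_truth$vertices, c2$ground_truth$vertices)
  expect_identical(c1$landmarks, c2$landmarks)
})

test_that("breast volume matches the half-ellipsoid closed form and scales with projection", {
  spec <- small_phantom_spec()
  tpl <- phantom_template(spec)
  tpl0 <- tpl
  tpl0$breasts$left$projection <- 0
  tpl0$breasts$right$projection <- 0
  v0 <- mesh_volume(build_torso_mesh(tpl0, 1))
  vol_at <- function(p, res = 1) {
    t2 <- tpl
    t2$breasts$left$projection <- p
    t2$breasts$right$projection <- p
    (mesh_volume(build_torso_mesh(t2, res)) - v0) / 2
  }
  p <- spec$projection
  expect_lt(abs(vol_at(p) / (2 / 3 * pi * (spec$base_diameter / 2)^2 * p) - 1), 0.03)
  # linear scaling in projection (R^2 > 0.99 over three projections)
  ps <- c(25, 35, 45)
  vols <- vapply(ps, vol_at, 0, res = 2)
  expect_gt(summary(lm(vols ~ ps))$r.squared, 0.99)
})

test_that("silhouette rendering obeys projection geometry", {
  spec <- small_phantom_spec()
  mesh <- build_torso_mesh(phantom_template(spec), spec$resolution)
  sil <- render_silhouette(mesh, "front", 1)
  cols <- which(apply(sil$mask, 2, any))
  expect_lt(abs((max(cols) - min(cols) + 1) * sil$mm_per_px - spec$chest_width), 1 + 1e-9)
  # rotating the mesh 90 deg about +y and rendering frontally equals the
  # left-lateral render
  rot <- apply_rigid(mesh, rigid_transform(rotation_about("y", 90)))
  expect_identical(render_silhouette(rot, "front", 1)$mask,
                   render_silhouette(mesh, "left", 1)$mask)
  expect_error(render_silhouette(mesh, "front", -1), "> 0")
})

test_that("annotations are exact at zero jitter and land inside the silhouette", {
  case <- generate_torso(small_phantom_spec(seed = 5, jitter = 0))
  for (view in c("front", "left", "right")) {
    lm <- case$landmarks[[view]]
    mask <- case$silhouettes[[view]]$mask
    idx <- cbind(pmin(pmax(1L, floor(lm[, 2]) + 1L), nrow(mask)),
                 pmin(pmax(1L, floor(lm[, 1]) + 1L), ncol(mask)))
    expect_true(all(mask[idx]), info = view)
  }
  # measurements are the exact ground-truth 3D distances
  n <- case$nipples
  expect_equal(case$measurements$nipple_to_nipple,
               sqrt(sum((n["left", ] - n["right", ])^2)))
  expect_equal(case$measurements$nipple_to_fold,
               sqrt(sum((n["left", ] - case$folds["left", ])^2)))
})

test_that("landmark jitter is Gaussian with the configured sigma (half-normal mean)", {
  case <- generate_torso(small_phantom_spec(seed = 11, jitter = 0))
  exact <- emit_annotations(case, sigma = 0, seed = 1)$landmarks$front
  sigma <- 2
  errs <- unlist(lapply(1:200, function(s) {
    j <- emit_annotations(case, sigma = sigma, seed = s)$landmarks$front
    as.numeric(abs(j - exact))
  }))
  # per-coordinate absolute error is half-normal with mean sigma*sqrt(2/pi)
  expected <- sigma * sqrt(2 / pi)
  n <- length(errs)
  expect_lt(abs(mean(errs) - expected), 4 * sigma / sqrt(n) + 0.05)
})

test_that("silhouettes round-trip through PNG and PGM with their metadata", {
  case <- generate_torso(small_phantom_spec(seed = 3))
  for (ext in c("png", "pgm")) {
    path <- tempfile(fileext = paste0(".", ext))
    write_silhouette(case$silhouettes$front, path)
    back <- read_silhouette(path)
    expect_identical(back$mask, case$silhouettes$front$mask)
    expect_equal(back$mm_per_px, case$silhouettes$front$mm_per_px)
  }
})

test_that("annotations round-trip through JSON", {
  case <- generate_torso(small_phantom_spec(seed = 3, jitter = 2))
  path <- tempfile(fileext = ".json")
  write_annotations(case$landmarks, case$measurements, path)
  back <- read_annotations(path)
  expect_equal(back$landmarks$front, case$landmarks$front)
  expect_equal(back$measurements$nipple_to_nipple,
               case$measurements$nipple_to_nipple)
})
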