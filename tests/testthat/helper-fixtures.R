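# Programmatic fixtures shared across the test files. Everything is built
# in code; nothing is read from disk except the shipped catalogue CSV.

# Axis-aligned cube as an indexed triangle mesh (12 faces, 8 vertices).
cube_mesh <- function(side = 1, center = c(0, 0, 0)) {
  v <- as.matrix(expand.grid(x = c(0, 1), y = c(0, 1), z = c(0, 1)))[, 1:3]
  v <- sweep(v * side, 2, center - side / 2, "+")
  dimnames(v) <- NULL
  f <- rbind(c(0, 1, 3), c(0, 3, 2), c(4, 7, 5), c(4, 6, 7),
             c(0, 5, 1), c(0, 4, 5), c(2, 3, 7), c(2, 7, 6),
             c(0, 2, 6), c(0, 6, 4), c(1, 5, 7), c(1, 7, 3))
  tri_mesh(v, f)
}

# Lat-long sphere mesh.
sphere_mesh <- function(r = 10, n = 32) {
  th <- seq(0, pi, length.out = n)
  ph <- seq(0, 2 * pi, length.out = 2 * n + 1)[-1]
  V <- rbind(c(0, 0, r), c(0, 0, -r))
  rows <- list()
  for (i in 2:(n - 1)) for (j in seq_along(ph))
    rows[[length(rows) + 1]] <- c(r * sin(th[i]) * cos(ph[j]),
                                  r * sin(th[i]) * sin(ph[j]),
                                  r * cos(th[i]))
  V <- rbind(V, do.call(rbind, rows))
  id <- function(i, j) 2 + (i - 2) * length(ph) + ((j - 1) %% length(ph)) + 1
  F <- list()
  for (j in seq_along(ph)) {
    F[[length(F) + 1]] <- c(1, id(2, j), id(2, j + 1))
    F[[length(F) + 1]] <- c(2, id(n - 1, j + 1), id(n - 1, j))
  }
  for (i in 2:(n - 2)) for (j in seq_along(ph)) {
    F[[length(F) + 1]] <- c(id(i, j), id(i + 1, j), id(i + 1, j + 1))
    F[[length(F) + 1]] <- c(id(i, j), id(i + 1, j + 1), id(i, j + 1))
  }
  tri_mesh(V, do.call(rbind, F) - 1L)
}

# A compact torso phantom used by unit tests where the default-size phantom
# would be needlessly slow; the default spec stays untouched for the
# acceptance experiments.
small_phantom_spec <- function(seed = 1, jitter = 0, ...) {
  torso_phantom_spec(chest_width = 220, chest_depth = 150, torso_height = 280,
                     base_diameter = 90, projection = 40, ptosis_drop = 8,
                     resolution = 4, seed = seed,
                     landmark_jitter_sigma = jitter, ...)
}

test_catalogue <- function() {
  # A-series sized for the default phantom (300 mm chest); S-series for the
  # compact unit-test phantom (220 mm chest)
  validate_catalogue(tibble::tibble(
    id = c("A150", "A200", "A250", "S45", "S64", "S87"),
    brand = "synthetic", shape = "round",
    base_diameter_mm = c(100, 110, 115, 58, 64, 70),
    projection_mm = c(38, 42, 48, 26, 30, 34),
    volume_cc = c(150, 200, 250, 45, 64, 87)))
}

bilateral_plan <- function(id, cx = 90, cy = -180,
                           placement = "SUBGLANDULAR") {
  placement_plan(
    left = list(implant_id = id, center = c(cx, cy), placement = placement),
    right = list(implant_id = id, center = c(-cx, cy), placement = placement))
}

# Memoised expensive fixtures (built once per test run).
.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixture_env)) {
    assign(name, builder(), envir = .fixture_env)
  }
  get(name, envir = .fixture_env)
}

# Small phantom with bilateral subglandular pockets (shared builder).
build_pocket_case <- function() {
  spec <- small_phantom_spec()
  mesh <- build_torso_mesh(phantom_template(spec), 4)
  cat_tbl <- test_catalogue()
  imp <- implant_voxels(cat_tbl[cat_tbl$id == "S64", ], spacing = 4)
  grid <- voxelize(mesh, 4, pad = imp$axes[3] + 12)
  plan <- bilateral_plan("S64", cx = 60, cy = -126)
  list(grid = grid,
       pocket = create_pocket(grid, plan, list(left = imp, right = imp)),
       plan = plan, imp = imp, mesh = mesh)
}

# Noise-free fine-scale phantom and its reconstruction (shared builder).
build_recovery_case <- function() {
  spec <- small_phantom_spec(seed = 9, jitter = 0, mm_per_px = 0.5)
  case <- generate_torso(spec)
  list(case = case,
       fit = reconstruct_patient(case$silhouettes, case$landmarks,
                                 case$measurements))
}

# Mirror deviation of a mesh across the sagittal plane (x = 0), mm.
mirror_deviation <- function(mesh) {
  v <- mesh$vertices
  v[, 1] <- -v[, 1]
  max(point_surface_distance(v, mesh))
}

edge_share_counts <- function(mesh) {
  f <- mesh$faces
  e <- rbind(f[, 1:2], f[, 2:3], f[, c(3, 1)])
  table(paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2])))
}
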