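test_that("mesh constructor enforces the invariants", {
  expect_s3_class(cube_mesh(), "tri_mesh")
  v <- matrix(c(0, 0, 0, 1, 0, 0, 0, 1, 0), 3, byrow = TRUE)
  expect_error(tri_mesh(v, rbind(c(0, 1, 3))), "out of range")
  expect_error(tri_mesh(v, rbind(c(0, 1, 1))), "repeated vertex")
  expect_error(tri_mesh(rbind(v, c(0.5, 1e-10, 0)), rbind(c(0, 1, 3))),
               "degenerate")
})

test_that("OBJ, PLY and STL round-trip through read/write", {
  cube <- cube_mesh(1)
  for (fmt in c("obj", "ply", "stl")) {
    path <- tempfile(fileext = paste0(".", fmt))
    write_mesh(cube, path)
    back <- read_mesh(path)
    expect_equal(nrow(back$faces), 12, info = fmt)
    # vertex sets identical within 1e-6 mm (STL may reorder after welding)
    d <- point_surface_distance(back$vertices, cube)
    expect_lt(max(d), 1e-6)
  }
  # OBJ text has one v-record per vertex, 1-based face indices
  path <- tempfile(fileext = ".obj")
  write_mesh(cube, path)
  lines <- readLines(path)
  expect_equal(sum(startsWith(lines, "v ")), 8)
  expect_equal(min(as.integer(unlist(strsplit(sub("^f ", "", lines[startsWith(lines, "f ")]), " ")))), 1)
})

test_that("PLY per-vertex colors survive a round-trip", {
  cube <- cube_mesh(1)
  cube$colors <- matrix(rep(c(1, 0.5, 0), each = 8), 8, 3)
  path <- tempfile(fileext = ".ply")
  write_mesh(cube, path)
  back <- read_mesh(path)
  expect_equal(back$colors, cube$colors, tolerance = 1 / 255)
})

test_that("writing degenerate or missing input errors clearly", {
  expect_error(read_mesh(tempfile(fileext = ".obj")), "not found")
  empty <- structure(list(vertices = matrix(0, 0, 3),
                          faces = matrix(0L, 0, 3), colors = NULL),
                     class = "tri_mesh")
  expect_error(write_mesh(empty, tempfile(fileext = ".obj")), "no vertices")
  bogus <- tempfile(fileext = ".xyz")
  writeLines("not a mesh", bogus)
  expect_error(read_mesh(bogus), "unsupported format")
})

test_that("point-to-surface distance matches an exhaustive per-face oracle", {
  set.seed(42)
  sp <- sphere_mesh(8, 12) # 240 faces
  pts <- matrix(runif(300, -12, 12), ncol = 3)
  brute <- cpp_point_mesh_dist_brute(pts, sp$vertices, sp$faces)
  fast <- point_surface_distance(pts, sp)
  expect_lt(max(abs(brute - fast)), 1e-9)
  # on-surface points are at distance 0; cube centre at half the side
  expect_equal(max(point_surface_distance(sp$vertices, sp)), 0, tolerance = 1e-9)
  expect_equal(point_surface_distance(c(0.5, 0.5, 0.5), cube_mesh(1, c(0.5, 0.5, 0.5))),
               0.5, tolerance = 1e-12)
})

test_that("rigid transforms compose, invert and preserve distances", {
  cube <- cube_mesh(10)
  expect_error(rigid_transform(diag(3) * 1.1), "orthonormal")
  t1 <- rigid_transform(rotation_about("y", 30), c(10, 5, -3))
  t2 <- rigid_transform(rotation_about("z", -45), c(-2, 0, 7))
  a <- apply_rigid(apply_rigid(cube, t1), t2)
  b <- apply_rigid(cube, compose_rigid(t2, t1))
  expect_lt(max(abs(a$vertices - b$vertices)), 1e-9)
  # identity and pure translation behave as stated
  expect_equal(apply_rigid(cube, rigid_transform())$vertices, cube$vertices)
  tr <- apply_rigid(cube, rigid_transform(translation = c(10, 5, -3)))
  expect_equal(unname(colMeans(tr$vertices) - colMeans(cube$vertices)), c(10, 5, -3))
  # pairwise distances are preserved
  d0 <- dist(cube$vertices)
  d1 <- dist(a$vertices)
  expect_lt(max(abs(d0 - d1)), 1e-9)
  # inverse undoes the transform
  back <- apply_rigid(a, invert_rigid(compose_rigid(t2, t1)))
  expect_lt(max(abs(back$vertices - cube$vertices)), 1e-9)
})

test_that("on-mesh measurement: euclidean, metric property and geodesic oracle", {
  sp <- sphere_mesh(1, 40)
  a <- c(0, 0, 1)
  b <- c(0, 0, -1)
  expect_equal(measure_on_mesh(sp, a, a, "euclidean"), 0)
  expect_equal(measure_on_mesh(sp, a, a, "on_surface"), 0)
  # pole-to-pole along edges approximates pi * r
  g <- measure_on_mesh(sp, a, b, "on_surface")
  expect_lt(abs(g - pi) / pi, 0.05)
  # independent oracle: plain Dijkstra over the edge graph
  dijkstra <- function(mesh, src, dst) {
    v <- mesh$vertices
    f <- mesh$faces + 1L
    e <- unique(rbind(cbind(pmin(f[, 1], f[, 2]), pmax(f[, 1], f[, 2])),
                      cbind(pmin(f[, 2], f[, 3]), pmax(f[, 2], f[, 3])),
                      cbind(pmin(f[, 3], f[, 1]), pmax(f[, 3], f[, 1]))))
    w <- sqrt(rowSums((v[e[, 1], ] - v[e[, 2], ])^2))
    n <- nrow(v)
    dist <- rep(Inf, n)
    dist[src] <- 0
    done <- rep(FALSE, n)
    adj <- split(seq_len(nrow(e) * 2),
                 c(e[, 1], e[, 2]))
    eboth <- rbind(e, e[, 2:1])
    wboth <- c(w, w)
    for (it in seq_len(n)) {
      u <- which.min(ifelse(done, Inf, dist))
      if (done[u] || !is.finite(dist[u])) break
      if (u == dst) break
      done[u] <- TRUE
      for (ei in adj[[as.character(u)]]) {
        vtx <- eboth[ei, 2]
        alt <- dist[u] + wboth[ei]
        if (alt < dist[vtx]) dist[vtx] <- alt
      }
    }
    dist[dst]
  }
  sp_small <- sphere_mesh(1, 14)
  src <- which.min(colSums((t(sp_small$vertices) - a)^2))
  dst <- which.min(colSums((t(sp_small$vertices) - b)^2))
  expect_equal(measure_on_mesh(sp_small, a, b, "on_surface"),
               dijkstra(sp_small, src, dst), tolerance = 1e-9)
  # along-edge path can never beat the straight line
  set.seed(7)
  for (i in 1:10) {
    p <- sp$vertices[sample(nrow(sp$vertices), 2), ]
    expect_gte(measure_on_mesh(sp, p[1, ], p[2, ], "on_surface") + 1e-12,
               measure_on_mesh(sp, p[1, ], p[2, ], "euclidean"))
  }
})
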