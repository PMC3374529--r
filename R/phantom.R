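#' Parametric torso template
#'
#' The shared surface parametrization used both by the synthetic phantom
#' generator and by the reconstruction stage: a stack of superellipse
#' cross-sections (one half-width/half-depth pair per control height, a
#' common exponent) with one half-ellipsoid breast patch per side blended
#' smoothly onto the anterior chest wall.
#'
#' @param heights strictly increasing control heights in mm (y, caudal to
#'   cranial; the cranial end is the sternal-notch level, y = 0).
#' @param half_width,half_depth per-height superellipse semi-axes in mm.
#' @param exponent superellipse exponent (2 = ellipse; larger = boxier).
#' @param breasts list with elements `left` and `right`, each a list with
#'   `center_x`, `center_y`, `radius`, `projection`, `ptosis` (mm).
#' @param blend smooth-union blend width in mm; keeps fold curvature finite.
#' @return An object of class `torso_template`.
#' @export
torso_template <- function(heights, half_width, half_depth, exponent = 2.5,
                           breasts, blend = 5) {
  heights <- as.numeric(heights)
  if (any(diff(heights) <= 0)) stop("control heights must be strictly increasing")
  if (any(half_width <= 0) || any(half_depth <= 0)) stop("all radii must be > 0")
  stopifnot(length(half_width) == length(heights), length(half_depth) == length(heights))
  for (side in c("left", "right")) {
    b <- breasts[[side]]
    if (is.null(b)) stop(sprintf("missing %s breast parameters", side))
    if (b$radius <= 0 || b$projection < 0) stop("breast radius must be > 0 and projection >= 0")
  }
  structure(list(heights = heights, half_width = half_width,
                 half_depth = half_depth, exponent = exponent,
                 breasts = breasts, blend = blend),
            class = "torso_template")
}

tpl_width_at <- function(tpl, y) {
  approx(tpl$heights, tpl$half_width, xout = y, rule = 2)$y
}
tpl_depth_at <- function(tpl, y) {
  approx(tpl$heights, tpl$half_depth, xout = y, rule = 2)$y
}

# Anterior chest-wall z at (x, y) on the superellipse stack (no breast).
tpl_chest_z <- function(tpl, x, y) {
  a <- tpl_width_at(tpl, y)
  b <- tpl_depth_at(tpl, y)
  r <- pmin(abs(x) / a, 1)
  b * (1 - r^tpl$exponent)^(1 / tpl$exponent)
}

# Half-ellipsoid breast height field (unitless, 0..1), with a caudal shear of
# the apex by `ptosis` mm applied through a short fixed-point iteration.
breast_height_field <- function(br, x, y) {
  ux <- (x - br$center_x) / br$radius
  h <- sqrt(pmax(0, 1 - ux^2 - ((y - br$center_y) / br$radius)^2))
  if (abs(br$ptosis) > 0) {
    for (i in 1:3)
      h <- sqrt(pmax(0, 1 - ux^2 - ((y + br$ptosis * h - br$center_y) / br$radius)^2))
  }
  h
}

# Smooth union of chest z and chest z + e: the displacement is exactly e
# above the blend width and eases in as a cubic below it, so the fold merges
# tangentially with finite curvature and the breast volume is preserved.
blend_union <- function(z, e, blend) {
  t <- pmin(e / blend, 1)
  z + ifelse(e >= blend, e, blend * (2 * t^2 - t^3))
}

# Total anterior displacement (mm) of surface point (x, y) from both breasts.
tpl_breast_disp <- function(tpl, x, y) {
  e <- breast_height_field(tpl$breasts$left, x, y) * tpl$breasts$left$projection +
       breast_height_field(tpl$breasts$right, x, y) * tpl$breasts$right$projection
  e
}

# Smoothstep taper of the breast displacement as the chest wall turns
# lateral (anterior z -> 0), so the breast base fades out around the side
# of the chest instead of ending in a cliff.
breast_taper <- function(z, tau = 15) {
  w <- pmin(pmax(z / tau, 0), 1)
  w * w * (3 - 2 * w)
}

# Displaced anterior surface: chest z plus the blended, tapered breast field.
apply_breast <- function(z, e, blend) {
  blend_union(z, e * breast_taper(z), blend)
}

# Anterior surface z at (x, y) including breasts (only valid for |x| < a(y)).
tpl_front_z <- function(tpl, x, y) {
  z <- tpl_chest_z(tpl, x, y)
  apply_breast(z, tpl_breast_disp(tpl, x, y), tpl$blend)
}

#' True nipple and fold positions of a template
#'
#' @param tpl a [torso_template()].
#' @return List with `nipples` and `folds`, each a 2 x 3 matrix (rows left,
#'   right) of 3D points in mm.
#' @export
template_nipples <- function(tpl) {
  out_n <- matrix(0, 2, 3, dimnames = list(c("left", "right"), NULL))
  out_f <- out_n
  for (i in 1:2) {
    side <- c("left", "right")[i]
    br <- tpl$breasts[[side]]
    yn <- br$center_y - br$ptosis
    zc <- tpl_chest_z(tpl, br$center_x, yn)
    out_n[i, ] <- c(br$center_x, yn, apply_breast(zc, br$projection, tpl$blend))
    yf <- br$center_y - br$radius
    out_f[i, ] <- c(br$center_x, yf, tpl_chest_z(tpl, br$center_x, yf))
  }
  list(nipples = out_n, folds = out_f)
}

#' Build a watertight triangle mesh from a torso template
#'
#' Sweeps superellipse rings between the caudal and cranial control heights,
#' displaces anterior ring points by the blended breast height fields, and
#' closes both ends with flat fan caps. Fully deterministic.
#'
#' @param tpl a [torso_template()].
#' @param edge_length target mesh edge length in mm.
#' @return A [tri_mesh()].
#' @export
build_torso_mesh <- function(tpl, edge_length = 4) {
  h0 <- min(tpl$heights)
  h1 <- max(tpl$heights)
  n_rows <- max(8L, as.integer(ceiling((h1 - h0) / edge_length)) + 1L)
  ys <- seq(h0, h1, length.out = n_rows)
  a_max <- max(tpl$half_width)
  b_max <- max(tpl$half_depth)
  peri <- 2 * pi * sqrt((a_max^2 + b_max^2) / 2)
  n_theta <- max(16L, 4L * as.integer(ceiling(peri / edge_length / 4)))
  theta <- (seq_len(n_theta) - 1) * 2 * pi / n_theta
  ct <- cos(theta)
  st <- sin(theta)
  # snap the axis crossings exactly so the ring is mirror-symmetric in
  # floating point (sin(pi) is not 0 numerically)
  ct[abs(ct) < 1e-12] <- 0
  st[abs(st) < 1e-12] <- 0
  p <- 2 / tpl$exponent
  ux <- sign(ct) * abs(ct)^p
  uz <- sign(st) * abs(st)^p

  nv <- n_rows * n_theta
  V <- matrix(0, nv + 2L, 3)
  for (r in seq_len(n_rows)) {
    y <- ys[r]
    a <- tpl_width_at(tpl, y)
    b <- tpl_depth_at(tpl, y)
    x <- a * ux
    z <- b * uz
    ant <- z > 0
    if (any(ant)) {
      e <- tpl_breast_disp(tpl, x[ant], rep(y, sum(ant)))
      z[ant] <- apply_breast(z[ant], e, tpl$blend)
    }
    idx <- (r - 1L) * n_theta + seq_len(n_theta)
    V[idx, ] <- cbind(x, rep(y, n_theta), z)
  }
  V[nv + 1L, ] <- c(0, ys[1], 0)        # caudal cap centre
  V[nv + 2L, ] <- c(0, ys[n_rows], 0)   # cranial cap centre

  faces <- vector("list", n_rows - 1L + 2L)
  for (r in seq_len(n_rows - 1L)) {
    i0 <- (r - 1L) * n_theta + seq_len(n_theta) - 1L
    i1 <- i0 + n_theta
    j0 <- c(i0[-1], i0[1])
    j1 <- c(i1[-1], i1[1])
    # split each quad along its shorter diagonal: better-shaped triangles,
    # and the rule is mirror-covariant so a symmetric template yields an
    # exactly mirror-symmetric surface
    d1 <- rowSums((V[i0 + 1L, ] - V[j1 + 1L, ])^2)
    d2 <- rowSums((V[j0 + 1L, ] - V[i1 + 1L, ])^2)
    use1 <- d1 <= d2
    faces[[r]] <- rbind(
      cbind(i0[use1], j0[use1], j1[use1]), cbind(i0[use1], j1[use1], i1[use1]),
      cbind(i0[!use1], j0[!use1], i1[!use1]), cbind(j0[!use1], j1[!use1], i1[!use1]))
  }
  ring_lo <- seq_len(n_theta) - 1L
  ring_hi <- (n_rows - 1L) * n_theta + seq_len(n_theta) - 1L
  faces[[n_rows]] <- cbind(ring_lo, c(ring_lo[-1], ring_lo[1]), nv)
  faces[[n_rows + 1L]] <- cbind(c(ring_hi[-1], ring_hi[1]), ring_hi, nv + 1L)
  Fm <- do.call(rbind, faces)
  dimnames(Fm) <- NULL
  mesh <- tri_mesh(V, Fm)
  if (mesh_volume(mesh) < 0) mesh$faces <- mesh$faces[, c(1, 3, 2)]
  mesh
}

#' Specification of a synthetic torso phantom
#'
#' Defines one synthetic "patient": chest dimensions, per-side breast
#' geometry, annotation noise and the random seed. The phantom stands in for
#' real patient photographs and laser scans, which are not deposited.
#'
#' @param chest_width,chest_depth,torso_height overall torso size, mm.
#' @param base_diameter,projection breast base diameter and anterior
#'   projection, mm.
#' @param ptosis_drop caudal nipple offset, mm.
#' @param asymmetry unitless left/right scale split; 0 = bilateral symmetry.
#' @param resolution target mesh edge length, mm.
#' @param mm_per_px rendering scale of the silhouette images.
#' @param landmark_jitter_sigma Gaussian annotation jitter, px.
#' @param seed integer seed controlling the annotation jitter.
#' @param exponent chest superellipse exponent.
#' @param blend breast/chest smooth-union blend width, mm.
#' @return An object of class `torso_phantom_spec`.
#' @export
torso_phantom_spec <- function(chest_width = 300, chest_depth = 200,
                               torso_height = 400, base_diameter = 120,
                               projection = 50, ptosis_drop = 10,
                               asymmetry = 0, resolution = 4, mm_per_px = 1,
                               landmark_jitter_sigma = 2, seed = 1,
                               exponent = 2.5, blend = 5) {
  lengths <- c(chest_width = chest_width, chest_depth = chest_depth,
               torso_height = torso_height, base_diameter = base_diameter,
               projection = projection, resolution = resolution,
               mm_per_px = mm_per_px)
  if (any(lengths <= 0))
    stop(sprintf("all lengths must be > 0 (%s)",
                 paste(names(lengths)[lengths <= 0], collapse = ", ")))
  if (base_diameter >= chest_width)
    stop("base_diameter must be smaller than chest_width")
  if (landmark_jitter_sigma < 0) stop("landmark jitter sigma must be >= 0")
  if (base_diameter < 3 * resolution || projection < 3 * resolution)
    stop("mesh resolution too coarse for the breast (need >= 3 edge lengths)")
  structure(list(chest_width = chest_width, chest_depth = chest_depth,
                 torso_height = torso_height, base_diameter = base_diameter,
                 projection = projection, ptosis_drop = ptosis_drop,
                 asymmetry = asymmetry, resolution = resolution,
                 mm_per_px = mm_per_px,
                 landmark_jitter_sigma = landmark_jitter_sigma, seed = seed,
                 exponent = exponent, blend = blend),
            class = "torso_phantom_spec")
}

# Fixed smooth torso profile: a mild waist at ~35% height, so that the
# half-width/half-depth control values vary with height like a real build.
phantom_profile <- function(t) 1 - 0.12 * exp(-((t - 0.35) / 0.18)^2)

#' Convert a phantom spec to its generating torso template
#'
#' @param spec a [torso_phantom_spec()].
#' @param n_heights number of control heights.
#' @return A [torso_template()].
#' @export
phantom_template <- function(spec, n_heights = 21) {
  t <- seq(0, 1, length.out = n_heights)
  h <- -spec$torso_height * (1 - t)
  aw <- spec$chest_width / 2 * phantom_profile(t)
  bd <- spec$chest_depth / 2 * (1 - 0.10 * exp(-((t - 0.35) / 0.18)^2))
  sc <- c(left = 1 + spec$asymmetry / 2, right = 1 - spec$asymmetry / 2)
  breasts <- lapply(c(left = "left", right = "right"), function(side) {
    s <- sc[[side]]
    list(center_x = if (side == "left") 0.30 * spec$chest_width else -0.30 * spec$chest_width,
         center_y = -0.45 * spec$torso_height,
         radius = s * spec$base_diameter / 2,
         projection = s * spec$projection,
         ptosis = spec$ptosis_drop)
  })
  torso_template(h, aw, bd, exponent = spec$exponent, breasts = breasts,
                 blend = spec$blend)
}

view_axes <- function(view) {
  # returns function projecting n x 3 points to (u, v) mm; v grows caudally
  switch(view,
         front = function(p) cbind(p[, 1], -p[, 2]),
         left = function(p) cbind(p[, 3], -p[, 2]),
         right = function(p) cbind(-p[, 3], -p[, 2]),
         stop(sprintf("unknown view '%s'", view)))
}

#' Render an orthographic binary silhouette of a mesh
#'
#' Projects along -z (front view) or +/-x (lateral views); a pixel is
#' foreground iff its viewing ray intersects the mesh. The image origin is
#' top-left with rows growing caudally.
#'
#' @param mesh a [tri_mesh()].
#' @param view `"front"`, `"left"` or `"right"`.
#' @param mm_per_px pixel size in mm (> 0).
#' @return An object of class `silhouette`: a logical `mask` plus the pixel
#'   scale and the mm coordinates of the image origin.
#' @export
render_silhouette <- function(mesh, view = c("front", "left", "right"),
                              mm_per_px = 1) {
  view <- match.arg(view)
  if (mm_per_px <= 0) stop("mm_per_px must be > 0")
  if (nrow(mesh$vertices) == 0L || nrow(mesh$faces) == 0L)
    stop("cannot render an empty mesh")
  uv <- view_axes(view)(mesh$vertices)
  margin <- 2.5 * mm_per_px
  u0 <- min(uv[, 1]) - margin
  v0 <- min(uv[, 2]) - margin
  ncol <- as.integer(ceiling((max(uv[, 1]) - u0 + margin) / mm_per_px))
  nrow <- as.integer(ceiling((max(uv[, 2]) - v0 + margin) / mm_per_px))
  U <- cbind((uv[, 1] - u0) / mm_per_px, (uv[, 2] - v0) / mm_per_px)
  mask <- cpp_rasterize(U, mesh$faces, nrow, ncol)
  structure(list(mask = mask, mm_per_px = mm_per_px, view = view,
                 u0 = u0, v0 = v0),
            class = "silhouette")
}

#' @export
print.silhouette <- function(x, ...) {
  cat(sprintf("silhouette (%s view): %d x %d px at %.3g mm/px, %d foreground px\n",
              x$view, nrow(x$mask), ncol(x$mask), x$mm_per_px, sum(x$mask)))
  invisible(x)
}

# Continuous pixel coordinates of 3D points in a silhouette's image frame
# (pixel (r, c) centre is at (c - 0.5, r - 0.5)).
project_to_pixels <- function(points, sil) {
  uv <- view_axes(sil$view)(points)
  cbind((uv[, 1] - sil$u0) / sil$mm_per_px, (uv[, 2] - sil$v0) / sil$mm_per_px)
}

# Snap a continuous pixel coordinate into the mask foreground if its pixel
# is background (annotators click on the visible silhouette).
clamp_to_foreground <- function(px, mask) {
  out <- px
  fg <- which(mask, arr.ind = TRUE)
  for (i in seq_len(nrow(px))) {
    c0 <- pmin(pmax(1L, as.integer(floor(px[i, 1])) + 1L), ncol(mask))
    r0 <- pmin(pmax(1L, as.integer(floor(px[i, 2])) + 1L), nrow(mask))
    if (!mask[r0, c0]) {
      d2 <- (fg[, 2] - 0.5 - px[i, 1])^2 + (fg[, 1] - 0.5 - px[i, 2])^2
      j <- which.min(d2)
      out[i, ] <- c(fg[j, 2] - 0.5, fg[j, 1] - 0.5)
    }
  }
  out
}

phantom_landmark_points <- function(tpl) {
  H <- -min(tpl$heights)
  nf <- template_nipples(tpl)
  y_ax <- -0.06 * H
  y_w <- -0.85 * H
  front <- rbind(
    sternal_notch = c(0, 0, tpl_chest_z(tpl, 0, 0)),
    left_nipple = nf$nipples["left", ],
    right_nipple = nf$nipples["right", ],
    left_fold = nf$folds["left", ],
    right_fold = nf$folds["right", ],
    left_axilla = c(0.98 * tpl_width_at(tpl, y_ax), y_ax, 0),
    right_axilla = c(-0.98 * tpl_width_at(tpl, y_ax), y_ax, 0),
    waist_left = c(0.98 * tpl_width_at(tpl, y_w), y_w, 0),
    waist_right = c(-0.98 * tpl_width_at(tpl, y_w), y_w, 0))
  lat <- function(side) {
    rbind(
      nipple = nf$nipples[side, ],
      fold = nf$folds[side, ],
      sternal_notch = c(0, 0, tpl_chest_z(tpl, 0, 0)),
      back_upper = c(0, -0.15 * H, -0.99 * tpl_depth_at(tpl, -0.15 * H)),
      back_lower = c(0, -0.75 * H, -0.99 * tpl_depth_at(tpl, -0.75 * H)))
  }
  list(front = front, left = lat("left"), right = lat("right"))
}

#' Generate a synthetic torso phantom case
#'
#' Builds the ground-truth mesh from the phantom spec, renders the three
#' orthographic silhouettes, projects the anatomical landmarks into each view
#' (with seeded Gaussian annotation jitter) and emits the two exact
#' anthropometric measurements. Deterministic given the spec (and its seed).
#'
#' @param spec a [torso_phantom_spec()].
#' @return An object of class `phantom_case` with elements `ground_truth`
#'   (mesh), `silhouettes` (front/left/right), `landmarks`, `measurements`,
#'   `nipples`, `folds`, `template` and `spec`.
#' @export
generate_torso <- function(spec) {
  stopifnot(inherits(spec, "torso_phantom_spec"))
  tpl <- phantom_template(spec)
  mesh <- build_torso_mesh(tpl, spec$resolution)
  sils <- lapply(c(front = "front", left = "left", right = "right"),
                 function(v) render_silhouette(mesh, v, spec$mm_per_px))
  nf <- template_nipples(tpl)
  case <- structure(list(ground_truth = mesh, silhouettes = sils,
                         landmarks = NULL, measurements = NULL,
                         nipples = nf$nipples, folds = nf$folds,
                         template = tpl, spec = spec),
                    class = "phantom_case")
  ann <- emit_annotations(case)
  case$landmarks <- ann$landmarks
  case$measurements <- ann$measurements
  case
}

#' @export
print.phantom_case <- function(x, ...) {
  cat(sprintf("phantom_case (seed %d): mesh %d vertices; jitter sigma %.2g px\n",
              x$spec$seed, nrow(x$ground_truth$vertices),
              x$spec$landmark_jitter_sigma))
  invisible(x)
}

#' Emit landmark annotations and measurements for a phantom case
#'
#' Landmarks are the true 3D anatomical points projected into each view plus
#' seeded Gaussian jitter of `landmark_jitter_sigma` px. The two measurements
#' are exact 3D euclidean distances on the ground truth: nipple-to-nipple and
#' (left) nipple-to-submammary-fold.
#'
#' @param case a `phantom_case`.
#' @param sigma jitter standard deviation in px; defaults to the spec value.
#' @param seed jitter seed; defaults to the spec seed.
#' @return List with `landmarks` (class `landmark_set`) and `measurements`.
#' @export
emit_annotations <- function(case, sigma = NULL, seed = NULL) {
  stopifnot(inherits(case, "phantom_case"))
  sigma <- sigma %||% case$spec$landmark_jitter_sigma
  seed <- seed %||% case$spec$seed
  pts <- phantom_landmark_points(case$template)
  lms <- with_seed(seed, {
    out <- list()
    for (view in c("front", "left", "right")) {
      sil <- case$silhouettes[[view]]
      px <- project_to_pixels(pts[[view]], sil)
      px <- clamp_to_foreground(px, sil$mask)
      if (sigma > 0)
        px <- px + matrix(rnorm(length(px), sd = sigma), nrow(px), 2)
      rownames(px) <- rownames(pts[[view]])
      colnames(px) <- c("u", "v")
      out[[view]] <- px
    }
    out
  })
  lm_set <- structure(lms, class = "landmark_set")
  n <- case$nipples
  f <- case$folds
  meas <- measurements(
    nipple_to_nipple = sqrt(sum((n["left", ] - n["right", ])^2)),
    nipple_to_fold = sqrt(sum((n["left", ] - f["left", ])^2)))
  list(landmarks = lm_set, measurements = meas)
}

#' Anthropometric measurements used for image calibration
#'
#' @param nipple_to_nipple,nipple_to_fold distances in mm, both > 0.
#' @return An object of class `measurements`.
#' @export
measurements <- function(nipple_to_nipple, nipple_to_fold) {
  if (nipple_to_nipple <= 0 || nipple_to_fold <= 0)
    stop("measurements must be > 0")
  if (nipple_to_nipple >= 600)
    stop("nipple_to_nipple fails the 600 mm sanity bound")
  structure(list(nipple_to_nipple = nipple_to_nipple,
                 nipple_to_fold = nipple_to_fold),
            class = "measurements")
}

#' Write / read a silhouette as PNG or PGM
#'
#' The binary mask is stored as an 8-bit grayscale image; the pixel scale and
#' image-origin metadata travel in a JSON sidecar (`<path>.json`).
#'
#' @param sil a `silhouette`.
#' @param path output path ending in `.png` or `.pgm`.
#' @return `path`, invisibly.
#' @export
write_silhouette <- function(sil, path) {
  img <- matrix(as.numeric(sil$mask), nrow(sil$mask), ncol(sil$mask))
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    png::writePNG(img, path)
  } else if (ext == "pgm") {
    con <- file(path, "w")
    writeLines(c("P2", sprintf("%d %d", ncol(img), nrow(img)), "255"), con)
    write(t(img) * 255, file = con, ncolumns = ncol(img))
    close(con)
  } else stop("unsupported silhouette format (png or pgm)")
  meta <- list(mm_per_px = sil$mm_per_px, view = sil$view, u0 = sil$u0, v0 = sil$v0)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_silhouette
#' @param mm_per_px,view used if no JSON sidecar is present.
#' @export
read_silhouette <- function(path, mm_per_px = NULL, view = NULL) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    img <- png::readPNG(path)
    if (length(dim(img)) == 3) img <- img[, , 1]
  } else if (ext == "pgm") {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[!grepl("^#", lines)]
    if (lines[1] != "P2") stop("only ASCII (P2) PGM is supported")
    dims <- as.integer(strsplit(trimws(lines[2]), "\\s+")[[1]])
    vals <- as.numeric(strsplit(paste(lines[-(1:3)], collapse = " "), "\\s+")[[1]])
    vals <- vals[!is.na(vals)]
    img <- matrix(vals / as.numeric(lines[3]), nrow = dims[2], ncol = dims[1],
                  byrow = TRUE)
  } else stop("unsupported silhouette format (png or pgm)")
  meta_path <- paste0(path, ".json")
  meta <- if (file.exists(meta_path)) jsonlite::read_json(meta_path) else list()
  structure(list(mask = img >= 0.5,
                 mm_per_px = mm_per_px %||% meta$mm_per_px %||% 1,
                 view = view %||% meta$view %||% "front",
                 u0 = meta$u0 %||% 0, v0 = meta$v0 %||% 0),
            class = "silhouette")
}

#' Write / read landmarks and measurements as JSON
#' @param landmarks a `landmark_set`.
#' @param measurements a `measurements` object.
#' @param path output JSON path.
#' @return `path` (write) or the parsed objects (read).
#' @export
write_annotations <- function(landmarks, measurements, path) {
  payload <- list(
    landmarks = lapply(unclass(landmarks), function(px) {
      stats::setNames(lapply(seq_len(nrow(px)), function(i) as.numeric(px[i, ])),
                      rownames(px))
    }),
    measurements = unclass(measurements))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_annotations
#' @export
read_annotations <- function(path) {
  payload <- jsonlite::read_json(path)
  lms <- lapply(payload$landmarks, function(view) {
    m <- do.call(rbind, lapply(view, function(p) as.numeric(unlist(p))))
    rownames(m) <- names(view)
    colnames(m) <- c("u", "v")
    m
  })
  list(landmarks = structure(lms, class = "landmark_set"),
       measurements = measurements(payload$measurements$nipple_to_nipple,
                                   payload$measurements$nipple_to_fold))
}
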