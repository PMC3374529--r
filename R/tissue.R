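#' Tissue label codes of a voxel grid
#'
#' Integer codes used in [voxelize()] grids: OUTSIDE 0, BONE_CORE 1,
#' MUSCLE 2, FAT_GLAND 3, SKIN 4, IMPLANT 5. The anatomical ordering runs
#' inside-out: torso/bone core, pectoral muscle, fat and gland, skin.
#' @export
tissue_levels <- function() {
  c(OUTSIDE = 0L, BONE_CORE = 1L, MUSCLE = 2L, FAT_GLAND = 3L, SKIN = 4L,
    IMPLANT = 5L)
}

#' Default tissue layer thicknesses
#'
#' Effective consultation-scale layer thicknesses in mm used when peeling
#' the torso volume into shells: skin, then fat/gland, then muscle; whatever
#' lies deeper is the bone/torso core.
#'
#' @param skin,fat_gland,muscle shell thicknesses in mm.
#' @export
layer_thicknesses <- function(skin = 5, fat_gland = 15, muscle = 10) {
  th <- c(skin = skin, fat_gland = fat_gland, muscle = muscle)
  if (any(th <= 0)) stop("layer thicknesses must be > 0")
  as.list(th)
}

#' Labeled voxel grid
#'
#' @param labels integer 3D array of [tissue_levels()] codes.
#' @param origin mm position of the corner of voxel (1,1,1); voxel (i,j,k)
#'   has centre `origin + (c(i,j,k) - 0.5) * spacing`.
#' @param spacing isotropic voxel edge length, mm.
#' @return An object of class `voxel_grid`.
#' @export
voxel_grid <- function(labels, origin, spacing) {
  if (spacing <= 0) stop("spacing must be > 0")
  labels <- as.array(labels)
  storage.mode(labels) <- "integer"
  if (!all(labels %in% tissue_levels()))
    stop("labels must come from tissue_levels()")
  structure(list(labels = labels, origin = as.numeric(origin),
                 spacing = spacing, dims = dim(labels)),
            class = "voxel_grid")
}

#' @export
print.voxel_grid <- function(x, ...) {
  cat(sprintf("voxel_grid: %d x %d x %d at %.3g mm\n", x$dims[1], x$dims[2],
              x$dims[3], x$spacing))
  tab <- table(factor(x$labels, levels = tissue_levels(),
                      labels = names(tissue_levels())))
  print(tab)
  invisible(x)
}

#' Voxel centres of a grid (optionally for one label)
#' @param grid a [voxel_grid()].
#' @param label optional label name or code.
#' @return n x 3 matrix of centres in mm.
#' @export
voxel_centers <- function(grid, label = NULL) {
  idx <- if (is.null(label)) which(grid$labels != 0L) else {
    code <- if (is.character(label)) tissue_levels()[[label]] else as.integer(label)
    which(grid$labels == code)
  }
  ijk <- arrayInd(idx, grid$dims)
  sweep((ijk - 0.5) * grid$spacing, 2, grid$origin, "+")
}

#' Voxelize a watertight mesh into labeled tissue layers
#'
#' Classifies voxel centres inside/outside by ray-casting parity, then peels
#' the interior into concentric shells by euclidean distance to the surface:
#' skin, fat/gland, muscle, and the bone/torso core innermost. Every tissue
#' voxel with an OUTSIDE 6-neighbour is skin by construction.
#'
#' @param mesh a watertight [tri_mesh()].
#' @param spacing isotropic voxel size, mm; must not exceed the smallest
#'   layer thickness.
#' @param thicknesses a [layer_thicknesses()] list.
#' @param pad extra empty margin around the mesh bounding box, mm.
#' @return A [voxel_grid()].
#' @export
voxelize <- function(mesh, spacing = 4, thicknesses = layer_thicknesses(),
                     pad = NULL) {
  stopifnot(inherits(mesh, "tri_mesh"))
  if (spacing <= 0) stop("spacing must be > 0")
  th <- thicknesses
  if (spacing > min(unlist(th)))
    stop("spacing must not exceed the smallest layer thickness")
  pad <- pad %||% (2 * spacing)
  bb <- apply(mesh$vertices, 2, range)
  ext <- bb[2, ] - bb[1, ] + 2 * pad
  dims <- pmax(as.integer(ceiling(ext / spacing)), 3L)
  center <- colMeans(bb)
  origin <- center - dims * spacing / 2
  vi <- cpp_voxel_inside(mesh$vertices, mesh$faces, origin, spacing, dims)
  inside <- array(vi$inside, dims)
  n_cols <- prod(dims[1:2])
  if (vi$ambiguous > 0.001 * n_cols)
    stop(sprintf("mesh appears non-watertight: %d of %d ray columns have odd parity",
                 vi$ambiguous, n_cols))
  d2 <- array(cpp_edt_sq(as.logical(!inside), dims), dims)
  dsurf <- (sqrt(d2) - 0.5) * spacing
  labels <- array(0L, dims)
  lv <- tissue_levels()
  labels[inside] <- lv[["BONE_CORE"]]
  labels[inside & dsurf < th$skin + th$fat_gland + th$muscle] <- lv[["MUSCLE"]]
  labels[inside & dsurf < th$skin + th$fat_gland] <- lv[["FAT_GLAND"]]
  labels[inside & dsurf < th$skin] <- lv[["SKIN"]]
  voxel_grid(labels, origin, spacing)
}

#' Write / read a labeled voxel grid (NRRD-style text format)
#'
#' A small NRRD-like container: a text header (dimension, sizes, spacing,
#' origin) followed by the label codes in ascii, x fastest.
#'
#' @param grid a [voxel_grid()].
#' @param path output path (conventionally `.nrrd`).
#' @export
write_voxel_grid <- function(grid, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("NRRD0004",
               "type: int",
               "dimension: 3",
               sprintf("sizes: %d %d %d", grid$dims[1], grid$dims[2], grid$dims[3]),
               sprintf("spacings: %g %g %g", grid$spacing, grid$spacing, grid$spacing),
               sprintf("axis mins: %g %g %g", grid$origin[1], grid$origin[2], grid$origin[3]),
               "encoding: ascii", ""), con)
  write(as.integer(grid$labels), file = con, ncolumns = grid$dims[1])
  invisible(path)
}

#' @rdname write_voxel_grid
#' @export
read_voxel_grid <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (!startsWith(lines[1], "NRRD")) stop("not an NRRD header")
  blank <- which(lines == "")[1]
  hdr <- lines[seq_len(blank - 1)]
  get <- function(key) {
    ln <- grep(paste0("^", key, ":"), hdr, value = TRUE)[1]
    as.numeric(strsplit(trimws(sub(".*:", "", ln)), "\\s+")[[1]])
  }
  dims <- as.integer(get("sizes"))
  spacing <- get("spacings")[1]
  origin <- get("axis mins")
  vals <- as.integer(strsplit(paste(lines[-seq_len(blank)], collapse = " "),
                              "\\s+")[[1]])
  vals <- vals[!is.na(vals)]
  voxel_grid(array(vals, dims), origin, spacing)
}

#' Read an implant catalogue from CSV
#'
#' Expected header: `id,brand,shape,base_diameter_mm,projection_mm,volume_cc`.
#' Rows are validated (positive dimensions, shape round/anatomical, unique
#' ids).
#'
#' @param path CSV file path.
#' @return A tibble with class `implant_catalogue`.
#' @export
read_implant_catalogue <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("id", "brand", "shape", "base_diameter_mm", "projection_mm", "volume_cc")
  if (!all(need %in% names(df)))
    stop(sprintf("catalogue is missing columns: %s",
                 paste(setdiff(need, names(df)), collapse = ", ")))
  cat <- tibble::as_tibble(df[need])
  validate_catalogue(cat)
}

#' @rdname read_implant_catalogue
#' @param cat a data frame of implant specifications.
#' @export
validate_catalogue <- function(cat) {
  if (nrow(cat) == 0) stop("empty implant catalogue")
  if (anyDuplicated(cat$id)) stop("implant ids must be unique")
  if (!all(cat$shape %in% c("round", "anatomical")))
    stop("implant shape must be 'round' or 'anatomical'")
  if (any(cat$base_diameter_mm <= 0) || any(cat$projection_mm <= 0) ||
      any(cat$volume_cc <= 0))
    stop("implant dimensions and volume must be > 0")
  class(cat) <- c("implant_catalogue", class(cat))
  cat
}

#' Filter an implant catalogue by closed ranges
#'
#' Returns exactly the rows whose diameter, projection and volume fall in
#' all three closed ranges, preserving the input order.
#'
#' @param cat an [read_implant_catalogue()] tibble.
#' @param diameter,projection,volume length-2 `c(min, max)` ranges
#'   (mm, mm, cc); `NULL` leaves that dimension unconstrained.
#' @return The filtered catalogue tibble.
#' @export
filter_catalogue <- function(cat, diameter = NULL, projection = NULL,
                             volume = NULL) {
  if (nrow(cat) == 0) stop("empty implant catalogue")
  chk <- function(rng, nm) {
    if (!is.null(rng) && (length(rng) != 2 || rng[1] > rng[2]))
      stop(sprintf("%s range must be c(min, max) with min <= max", nm))
  }
  chk(diameter, "diameter")
  chk(projection, "projection")
  chk(volume, "volume")
  out <- cat
  if (!is.null(diameter))
    out <- dplyr::filter(out, .data$base_diameter_mm >= diameter[1],
                         .data$base_diameter_mm <= diameter[2])
  if (!is.null(projection))
    out <- dplyr::filter(out, .data$projection_mm >= projection[1],
                         .data$projection_mm <= projection[2])
  if (!is.null(volume))
    out <- dplyr::filter(out, .data$volume_cc >= volume[1],
                         .data$volume_cc <= volume[2])
  out
}

#' Voxelize an implant as a half-ellipsoid
#'
#' Semi-axes `d/2, d/2` (round) or `d/2, 0.85 d/2` (anatomical) and the
#' nominal projection, flat face posterior (z = 0 plane, dome towards +z in
#' the implant frame). The shape is uniformly rescaled so the voxelized
#' volume matches the nominal volume to within 2%.
#'
#' @param spec one catalogue row (or a list with `shape`,
#'   `base_diameter_mm`, `projection_mm`, `volume_cc`).
#' @param pose list with `center` (3, mm) and `rotation` (3 x 3); default
#'   upright at the origin.
#' @param spacing voxel size, mm; must be at most a third of the projection.
#' @return List with `voxels` (n x 3 world-frame centres), `center`, `axes`
#'   (rescaled semi-axes), `rotation`, `volume_cc` (achieved) and
#'   `spacing`.
#' @export
implant_voxels <- function(spec, pose = list(), spacing = 2) {
  spec <- as.list(spec)
  if (spec$projection_mm <= 0) stop("implant projection must be > 0")
  if (spacing > spec$projection_mm / 3)
    stop("spacing must be at most projection/3")
  center <- pose$center %||% c(0, 0, 0)
  rotation <- pose$rotation %||% diag(3)
  a <- spec$base_diameter_mm / 2
  b <- if (identical(spec$shape, "anatomical")) 0.85 * a else a
  cc <- spec$projection_mm
  target <- spec$volume_cc * 1000
  half_ellipsoid_count <- function(s) {
    ax <- s * a
    by <- s * b
    cz <- s * cc
    nx <- ceiling(ax / spacing)
    ny <- ceiling(by / spacing)
    nz <- ceiling(cz / spacing)
    xs <- (seq(-nx, nx - 1) + 0.5) * spacing
    ys <- (seq(-ny, ny - 1) + 0.5) * spacing
    zs <- (seq(0, nz - 1) + 0.5) * spacing
    g <- expand.grid(x = xs, y = ys, z = zs)
    keep <- (g$x / ax)^2 + (g$y / by)^2 + (g$z / cz)^2 <= 1
    g[keep, , drop = FALSE]
  }
  # uniform rescale (bisection) so voxel volume matches the nominal volume
  s_lo <- 0.7
  s_hi <- 1.4
  s <- 1
  for (i in 1:40) {
    s <- (s_lo + s_hi) / 2
    v <- nrow(half_ellipsoid_count(s)) * spacing^3
    if (abs(v / target - 1) < 0.015) break
    if (v < target) s_lo <- s else s_hi <- s
  }
  vox <- half_ellipsoid_count(s)
  achieved <- nrow(vox) * spacing^3
  world <- as.matrix(vox) %*% t(rotation)
  world <- sweep(world, 2, center, "+")
  list(voxels = world, center = center, axes = c(s * a, s * b, s * cc),
       rotation = rotation, volume_cc = achieved / 1000,
       nominal_cc = spec$volume_cc, scale = s, spacing = spacing,
       id = spec$id %||% NA_character_)
}

#' Per-side implant placement plan
#'
#' @param left,right each a list with `implant_id`, `center` (frontal-view
#'   patient coordinates, `c(x, y)` mm) and `placement` (one of
#'   `"SUBGLANDULAR"`, `"SUBMUSCULAR"`, `"DUAL_PLANE"`).
#' @return An object of class `placement_plan`.
#' @export
placement_plan <- function(left = NULL, right = NULL) {
  sides <- list(left = left, right = right)
  sides <- sides[!vapply(sides, is.null, TRUE)]
  if (length(sides) == 0) stop("placement plan needs at least one side")
  for (nm in names(sides)) {
    s <- sides[[nm]]
    if (!s$placement %in% c("SUBGLANDULAR", "SUBMUSCULAR", "DUAL_PLANE"))
      stop("placement must be SUBGLANDULAR, SUBMUSCULAR or DUAL_PLANE")
    if (length(s$center) != 2) stop("plan center must be c(x, y) in mm")
  }
  structure(sides, class = "placement_plan")
}

#' Write / read a placement plan as JSON
#' @param plan a [placement_plan()].
#' @param path JSON path.
#' @export
write_plan <- function(plan, path) {
  jsonlite::write_json(lapply(unclass(plan), function(s)
    list(implant_id = s$implant_id, center = s$center, placement = s$placement)),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_plan
#' @export
read_plan <- function(path) {
  raw <- jsonlite::read_json(path)
  do.call(placement_plan, lapply(raw, function(s)
    list(implant_id = s$implant_id, center = as.numeric(unlist(s$center)),
         placement = s$placement)))
}

#' Insert implants into a voxel grid at the planned pocket depth
#'
#' For each planned side, the implant's flat posterior face is placed at the
#' tissue interface implied by the placement (bone/muscle boundary for
#' submuscular; muscle/fat boundary for subglandular and dual plane),
#' centred on the plan's frontal (x, y). The overlying tissue columns are
#' shifted anteriorly to make space: overlapped tissue is displaced, not
#' deleted, and its particles are resolved by the solver. The pre-insertion
#' labels and the implant ellipsoid geometry are carried as attributes for
#' [build_tem()].
#'
#' @param grid a [voxelize()] grid.
#' @param plan a [placement_plan()].
#' @param implants named list (by side) of [implant_voxels()] results.
#' @return The modified [voxel_grid()] with `pre_pocket` and `implants`
#'   attributes.
#' @export
create_pocket <- function(grid, plan, implants) {
  lv <- tissue_levels()
  labels <- grid$labels
  pre <- labels
  dims <- grid$dims
  meta <- list()
  for (side in names(plan)) {
    p <- plan[[side]]
    imp <- implants[[side]]
    if (is.null(imp)) stop(sprintf("no implant voxels supplied for side '%s'", side))
    ix <- as.integer(floor((p$center[1] - grid$origin[1]) / grid$spacing)) + 1L
    iy <- as.integer(floor((p$center[2] - grid$origin[2]) / grid$spacing)) + 1L
    if (ix < 1 || ix > dims[1] || iy < 1 || iy > dims[2] ||
        !any(labels[ix, iy, ] != lv[["OUTSIDE"]]))
      stop(sprintf("plan center for side '%s' lies outside the torso silhouette", side))
    col <- labels[ix, iy, ]
    target <- if (p$placement == "SUBMUSCULAR") lv[["BONE_CORE"]] else lv[["MUSCLE"]]
    ks <- which(col == target)
    if (length(ks) == 0)
      stop(sprintf("no %s interface under the plan center for side '%s'",
                   if (target == lv[["BONE_CORE"]]) "bone/muscle" else "muscle/fat", side))
    k_int <- max(ks)
    z0 <- grid$origin[3] + k_int * grid$spacing  # boundary plane above voxel k_int
    # implant voxels in world frame, snapped to this grid; ties between
    # neighbouring bins are broken away from the grid centre so mirrored
    # plans snap to mirrored voxels
    world <- sweep(imp$voxels, 2, c(p$center[1], p$center[2], z0) - imp$center, "+")
    gcen <- grid$origin + dims * grid$spacing / 2
    for (d in 1:2)
      world[, d] <- world[, d] + 1e-6 * grid$spacing * sign(world[, d] - gcen[d])
    ijk <- floor(sweep(world, 2, grid$origin, "-") / grid$spacing) + 1L
    in_grid <- ijk[, 1] >= 1 & ijk[, 1] <= dims[1] &
               ijk[, 2] >= 1 & ijk[, 2] <= dims[2] &
               ijk[, 3] >= 1 & ijk[, 3] <= dims[3]
    if (mean(in_grid) < 0.999)
      stop(sprintf("implant footprint exceeds the voxel grid for side '%s'", side))
    ijk <- ijk[in_grid, , drop = FALSE]
    # footprint columns must contain tissue
    cols <- unique(ijk[, 1:2, drop = FALSE])
    has_tissue <- vapply(seq_len(nrow(cols)), function(i)
      any(pre[cols[i, 1], cols[i, 2], ] != lv[["OUTSIDE"]]), TRUE)
    if (mean(has_tissue) < 0.95)
      stop(sprintf("implant footprint exceeds the torso cross-section for side '%s'", side))
    # per column: drape the implant base onto the local interface and shift
    # the overlying tissue anteriorly by the implant thickness there
    for (i in seq_len(nrow(cols))) {
      cx <- cols[i, 1]
      cy <- cols[i, 2]
      h <- sum(ijk[, 1] == cx & ijk[, 2] == cy)
      if (h == 0) next
      colv <- labels[cx, cy, ]
      ks_loc <- which(colv == target)
      if (length(ks_loc) == 0) next
      k_loc <- max(ks_loc)
      nz <- dims[3]
      if (k_loc + h > nz) h <- nz - k_loc
      if (h <= 0) next
      shifted <- colv
      src <- seq(k_loc + 1, nz - h)
      shifted[src + h] <- colv[src]
      shifted[seq(k_loc + 1, k_loc + h)] <- lv[["IMPLANT"]]
      labels[cx, cy, ] <- shifted
    }
    meta[[side]] <- list(center = c(p$center[1], p$center[2], z0),
                         axes = imp$axes, rotation = imp$rotation,
                         placement = p$placement, implant_id = p$implant_id,
                         volume_cc = imp$volume_cc)
  }
  out <- voxel_grid(labels, grid$origin, grid$spacing)
  attr(out, "pre_pocket") <- pre
  attr(out, "implants") <- meta
  out
}
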