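#' Skin elasticity class
#'
#' The four clinical skin elasticity types modulate the skin stiffness used
#' by the tissue solver; multipliers increase strictly with tightness.
#'
#' @param label one of `"loose"`, `"moderate"`, `"tight"`, `"very_tight"`.
#' @param multipliers named multipliers for the four classes.
#' @return An object of class `elasticity_class`.
#' @export
elasticity_class <- function(label = c("loose", "moderate", "tight", "very_tight"),
                             multipliers = c(loose = 0.5, moderate = 0.75,
                                             tight = 1.0, very_tight = 1.3)) {
  label <- match.arg(label)
  if (any(diff(multipliers[c("loose", "moderate", "tight", "very_tight")]) <= 0))
    stop("elasticity multipliers must increase strictly with tightness")
  structure(list(label = label, multiplier = multipliers[[label]],
                 multipliers = multipliers),
            class = "elasticity_class")
}

#' Tissue solver parameters
#'
#' Relative constraint stiffnesses (projection weights) per tissue, plus the
#' implant rigidity factor and the auxiliary constraint weights. The bone
#' core is fixed outright.
#'
#' @param muscle,fat_gland,skin relative stretch stiffness per tissue.
#' @param implant_factor stiffness multiplier making implant particles
#'   near-rigid.
#' @param bend skin bending (shape-memory) weight.
#' @param cell relaxed volume-restoration weight per voxel cell.
#' @param anchor implant anchor weight (holds the inserted pose).
#' @param collide implant-tissue exclusion weight.
#' @export
tissue_params <- function(muscle = 2, fat_gland = 0.6, skin = 1,
                          implant_factor = 100, bend = 0.5, cell = 1,
                          anchor = 50, collide = 10) {
  list(muscle = muscle, fat_gland = fat_gland, skin = skin,
       implant_factor = implant_factor, bend = bend, cell = cell,
       anchor = anchor, collide = collide)
}

#' Solver configuration
#'
#' @param max_iterations iteration cap (>= 1).
#' @param tolerance convergence threshold on the maximum per-iteration
#'   particle displacement, mm (> 0).
#' @param gravity apply a constant caudal force per iteration.
#' @param gravity_step per-iteration gravity displacement, mm.
#' @param omega under-relaxation of the Jacobi constraint projection.
#' @param divergence_window consecutive growing iterations before aborting.
#' @param seed stored for provenance; the solver itself is deterministic.
#' @export
sim_config <- function(max_iterations = 800, tolerance = 0.05,
                       gravity = FALSE, gravity_step = c(0, -0.02, 0),
                       omega = 0.8, divergence_window = 50, seed = 1L) {
  if (max_iterations < 1) stop("max_iterations must be >= 1")
  if (tolerance <= 0) stop("tolerance must be > 0")
  list(max_iterations = as.integer(max_iterations), tolerance = tolerance,
       gravity = gravity, gravity_step = gravity_step, omega = omega,
       divergence_window = as.integer(divergence_window), seed = seed)
}

#' Build the tissue elastic model from a labeled voxel grid
#'
#' One particle per tissue/implant voxel at its centre. Stretch constraints
#' connect 6-neighbours (rest length = spacing) and the 12 edge diagonals
#' (rest length = spacing * sqrt(2)); every voxel cell whose 8 corners are
#' particles carries a relaxed volume-restoration constraint; skin particles
#' with collinear skin neighbours carry bending constraints. Stiffness is
#' the tissue base stiffness (skin additionally scaled by the elasticity
#' multiplier); implant particles are near-rigid (stiffness x implant
#' factor) and anchored to their inserted pose; bone-core particles are
#' fixed. For dual-plane placements the muscle stiffness is halved over the
#' implant's upper half to mimic partial muscle coverage.
#'
#' @param grid a [voxelize()] or [create_pocket()] grid.
#' @param elasticity an [elasticity_class()].
#' @param params a [tissue_params()] list.
#' @return An object of class `tem_state`.
#' @export
build_tem <- function(grid, elasticity = elasticity_class("tight"),
                      params = tissue_params()) {
  lv <- tissue_levels()
  lab <- grid$labels
  idx <- which(lab != lv[["OUTSIDE"]])
  if (length(idx) == 0L) stop("empty tissue: nothing to simulate")
  npart <- length(idx)
  pid <- array(0L, grid$dims)
  pid[idx] <- seq_len(npart)
  ijk <- arrayInd(idx, grid$dims)
  pos <- sweep((ijk - 0.5) * grid$spacing, 2, grid$origin, "+")
  labs <- as.integer(lab[idx])
  invmass <- ifelse(labs == lv[["BONE_CORE"]], 0, 1)

  base <- numeric(6)
  base[lv[["BONE_CORE"]] + 1L] <- params$muscle  # fixed anyway
  base[lv[["MUSCLE"]] + 1L] <- params$muscle
  base[lv[["FAT_GLAND"]] + 1L] <- params$fat_gland
  base[lv[["SKIN"]] + 1L] <- params$skin * elasticity$multiplier
  base[lv[["IMPLANT"]] + 1L] <- params$implant_factor
  stiff <- base[labs + 1L]

  implants <- attr(grid, "implants")
  if (!is.null(implants)) {
    for (side in names(implants)) {
      im <- implants[[side]]
      if (identical(im$placement, "DUAL_PLANE")) {
        rel <- sweep(pos, 2, im$center, "-")
        inside <- (rel[, 1] / (1.2 * im$axes[1]))^2 +
                  (rel[, 2] / (1.2 * im$axes[2]))^2 +
                  (rel[, 3] / (1.2 * im$axes[3]))^2 <= 1
        upper <- rel[, 2] > 0
        sel <- labs == lv[["MUSCLE"]] & inside & upper
        stiff[sel] <- stiff[sel] / 2
      }
    }
  }

  # stretch constraints over 6-neighbours and 12 edge diagonals
  offs <- rbind(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1),
                c(1, 1, 0), c(1, -1, 0), c(1, 0, 1),
                c(1, 0, -1), c(0, 1, 1), c(0, 1, -1))
  e1 <- integer(0); e2 <- integer(0); el <- numeric(0)
  for (o in seq_len(nrow(offs))) {
    off <- offs[o, ]
    nb <- sweep(ijk, 2, off, "+")
    ok <- nb[, 1] >= 1 & nb[, 1] <= grid$dims[1] &
          nb[, 2] >= 1 & nb[, 2] <= grid$dims[2] &
          nb[, 3] >= 1 & nb[, 3] <= grid$dims[3]
    nid <- integer(npart)
    nid[ok] <- pid[nb[ok, , drop = FALSE]]
    keep <- nid > 0L
    e1 <- c(e1, which(keep))
    e2 <- c(e2, nid[keep])
    el <- c(el, rep(grid$spacing * sqrt(sum(off^2)), sum(keep)))
  }
  edge_k <- (stiff[e1] + stiff[e2]) / 2

  # hexahedral cells (corner order: x + 2y + 4z bit pattern)
  corner_offs <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(1, 1, 0),
                       c(0, 0, 1), c(1, 0, 1), c(0, 1, 1), c(1, 1, 1))
  corner_ids <- matrix(0L, npart, 8)
  for (cno in 1:8) {
    nb <- sweep(ijk, 2, corner_offs[cno, ], "+")
    ok <- nb[, 1] <= grid$dims[1] & nb[, 2] <= grid$dims[2] & nb[, 3] <= grid$dims[3]
    cid <- integer(npart)
    cid[ok] <- pid[nb[ok, , drop = FALSE]]
    corner_ids[, cno] <- cid
  }
  full <- rowSums(corner_ids > 0L) == 8L
  cells <- corner_ids[full, , drop = FALSE]
  cell_v0 <- rep(grid$spacing^3, nrow(cells))

  # skin bending triples along each lattice axis
  skin <- labs == lv[["SKIN"]]
  b1 <- integer(0); b2 <- integer(0); b3 <- integer(0)
  for (ax in 1:3) {
    off <- c(0, 0, 0)
    off[ax] <- 1
    nb_p <- sweep(ijk, 2, off, "+")
    nb_m <- sweep(ijk, 2, off, "-")
    okp <- nb_p[, ax] <= grid$dims[ax]
    okm <- nb_m[, ax] >= 1
    idp <- integer(npart); idm <- integer(npart)
    idp[okp] <- pid[nb_p[okp, , drop = FALSE]]
    idm[okm] <- pid[nb_m[okm, , drop = FALSE]]
    keep <- skin & idp > 0L & idm > 0L & skin[pmax(idp, 1L)] & skin[pmax(idm, 1L)]
    b1 <- c(b1, idm[keep]); b2 <- c(b2, which(keep)); b3 <- c(b3, idp[keep])
  }
  bend <- cbind(b1, b2, b3)
  bend_k <- rep(params$bend * elasticity$multiplier, nrow(bend))
  bend_off <- matrix(0, nrow(bend), 3)

  anchor_k <- ifelse(labs == lv[["IMPLANT"]], params$anchor, 0)
  collidable <- invmass > 0 & labs != lv[["IMPLANT"]]
  ell <- matrix(0, 0, 15)
  if (!is.null(implants) && length(implants) > 0) {
    ell <- t(vapply(implants, function(im)
      c(im$center, im$axes, as.numeric(t(im$rotation))), numeric(15)))
  }

  structure(list(pos = pos, rest = pos, invmass = invmass, labels = labs,
                 edges = cbind(e1, e2) - 1L, edge_len0 = el, edge_k = edge_k,
                 cells = cells - 1L, cell_v0 = cell_v0,
                 bend = bend - 1L, bend_off = bend_off, bend_k = bend_k,
                 anchor_k = anchor_k, ellipsoids = ell,
                 collidable = collidable, params = params,
                 elasticity = elasticity, origin = grid$origin,
                 spacing = grid$spacing, dims = grid$dims,
                 solved = FALSE, info = NULL),
            class = "tem_state")
}

#' @export
print.tem_state <- function(x, ...) {
  cat(sprintf("tem_state: %d particles, %d stretch, %d volume, %d bending constraints%s\n",
              nrow(x$pos), nrow(x$edges), nrow(x$cells), nrow(x$bend),
              if (x$solved) sprintf(" (solved: %d iterations, residual %.4g mm)",
                                    x$info$iterations, x$info$residual) else ""))
  invisible(x)
}

#' Solve the tissue elastic model to equilibrium
#'
#' Iterative relaxed constraint projection (Jacobi accumulation with
#' stiffness as projection weight, so the sweep is order-independent,
#' deterministic and mirror-symmetric). Terminates when the maximum
#' per-iteration displacement drops below the tolerance or at the iteration
#' cap; aborts with a diagnostic if the displacement grows for
#' `divergence_window` consecutive iterations. A state with no violated
#' constraints is a fixed point.
#'
#' @param state a [build_tem()] state.
#' @param config a [sim_config()].
#' @return The state with updated particle positions and an `info` list
#'   (`converged`, `iterations`, `residual`).
#' @export
solve_tem <- function(state, config = sim_config()) {
  stopifnot(inherits(state, "tem_state"))
  grav <- if (isTRUE(config$gravity)) config$gravity_step else c(0, 0, 0)
  out <- cpp_tem_solve(state$pos, state$rest, state$invmass,
                       state$edges, state$edge_len0, state$edge_k,
                       state$cells, state$cell_v0, state$params$cell,
                       state$bend, state$bend_off, state$bend_k,
                       state$anchor_k,
                       state$ellipsoids, state$params$collide,
                       state$collidable, grav,
                       config$max_iterations, config$tolerance, config$omega,
                       config$divergence_window)
  if (isTRUE(out$diverged))
    stop(sprintf("tissue solve diverged after %d iterations (residual %.4g mm)",
                 out$iterations, out$residual))
  state$pos <- out$pos
  state$solved <- TRUE
  state$info <- list(converged = out$converged, iterations = out$iterations,
                     residual = out$residual)
  state
}

#' Total cell volume of a TEM state
#' @param state a `tem_state`.
#' @return Summed hexahedral cell volume, mm^3.
#' @export
tem_total_volume <- function(state) {
  sum(cpp_cell_volumes(state$pos, state$cells))
}

#' Extract the outer skin surface of a (solved) TEM state
#'
#' Particles are splatted back onto the voxel lattice as an occupancy mask
#' (with one morphological closing pass to seal stretch gaps), and the
#' surface is taken as the 0.5-occupancy boundary: the zero level set of the
#' occupancy signed-distance field, triangulated by marching tetrahedra.
#' The result is watertight with outward-oriented faces.
#'
#' @param state a `tem_state` (solved or unsolved).
#' @return A [tri_mesh()].
#' @export
extract_skin_surface <- function(state) {
  h <- state$spacing
  dims <- state$dims
  ijk <- round(sweep(state$pos, 2, state$origin, "-") / h + 0.5)
  ijk <- pmin(pmax(ijk, 1), matrix(dims, nrow(ijk), 3, byrow = TRUE))
  mask <- array(FALSE, dims)
  mask[ijk] <- TRUE
  if (!any(mask)) stop("empty occupancy: no particles to extract")
  # closing: dilate then erode by one voxel
  d2 <- array(cpp_edt_sq(as.logical(mask), dims), dims)
  maskd <- d2 <= 1 + 1e-9
  er <- array(cpp_edt_sq(as.logical(!maskd), dims), dims)
  maske <- maskd & er > 1 + 1e-9
  # keep the lattice boundary open so the surface closes inside the grid
  maske[c(1, dims[1]), , ] <- FALSE
  maske[, c(1, dims[2]), ] <- FALSE
  maske[, , c(1, dims[3])] <- FALSE
  if (!any(maske)) stop("empty occupancy after closing")
  din <- sqrt(cpp_edt_sq(as.logical(maske), dims))
  dout <- sqrt(cpp_edt_sq(as.logical(!maske), dims))
  field <- array(din - dout, dims) # negative inside the tissue, positive outside
  field <- smooth_field(smooth_field(field))
  mt <- cpp_march_tets(field, dims, state$origin + h / 2, h, 0)
  tri_mesh(mt$vertices, mt$faces)
}

# separable [1, 2, 1]/4 smoothing of a 3D array along each axis; removes the
# lattice staircase from the occupancy distance field without moving the
# zero crossing appreciably
smooth_field <- function(f) {
  d <- dim(f)
  pad <- function(a, ax, first) {
    idx <- lapply(d, seq_len)
    idx[[ax]] <- if (first) c(1L, seq_len(d[ax] - 1L)) else c(seq_len(d[ax] - 1L) + 1L, d[ax])
    do.call(`[`, c(list(a), idx))
  }
  for (ax in 1:3) f <- (pad(f, ax, TRUE) + 2 * f + pad(f, ax, FALSE)) / 4
  f
}

#' Simulate a breast augmentation end to end
#'
#' Composition of the full simulation pipeline: voxelize the preoperative
#' torso, select the planned implants from the catalogue, create the pockets
#' at the planned interfaces, build and solve the tissue elastic model, and
#' extract the postoperative skin surface. A baseline surface extracted from
#' the implant-free voxelization is returned alongside so volume gain can be
#' measured consistently (both surfaces share the lattice resolution).
#'
#' @param preop preoperative torso [tri_mesh()].
#' @param plan a [placement_plan()].
#' @param catalogue an implant catalogue tibble.
#' @param elasticity an [elasticity_class()].
#' @param config a [sim_config()].
#' @param spacing voxel size, mm.
#' @param thicknesses a [layer_thicknesses()] list.
#' @return An object of class `augmentation_result`: `postop` and
#'   `baseline` meshes, the pocket `grid`, solved `state`, solver `info`,
#'   and the total nominal implant volume (cc).
#' @export
simulate_augmentation <- function(preop, plan, catalogue,
                                  elasticity = elasticity_class("tight"),
                                  config = sim_config(), spacing = 4,
                                  thicknesses = layer_thicknesses()) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("[%s] %s", name, conditionMessage(e)), call. = FALSE))
  }
  imps <- list()
  total_cc <- 0
  for (side in names(plan)) {
    row <- catalogue[catalogue$id == plan[[side]]$implant_id, ]
    if (nrow(row) != 1)
      stop(sprintf("[plan] implant id '%s' not found in the catalogue",
                   plan[[side]]$implant_id))
    imps[[side]] <- stage("implant_voxels",
                          implant_voxels(row, spacing = spacing))
    total_cc <- total_cc + row$volume_cc
  }
  max_proj <- max(vapply(imps, function(i) i$axes[3], 0))
  grid <- stage("voxelize",
                voxelize(preop, spacing, thicknesses,
                         pad = max_proj + 3 * spacing))
  pocket <- stage("create_pocket", create_pocket(grid, plan, imps))
  state <- stage("build_tem", build_tem(pocket, elasticity))
  solved <- stage("solve_tem", solve_tem(state, config))
  post <- stage("extract_skin_surface", extract_skin_surface(solved))
  base_state <- stage("build_tem", build_tem(grid, elasticity))
  baseline <- stage("extract_skin_surface", extract_skin_surface(base_state))
  structure(list(postop = post, baseline = baseline, grid = pocket,
                 state = solved, info = solved$info,
                 implant_volume_cc = total_cc,
                 volume_gain_cc = (mesh_volume(post) - mesh_volume(baseline)) / 1000),
            class = "augmentation_result")
}

#' @export
print.augmentation_result <- function(x, ...) {
  cat(sprintf("augmentation_result: implants %.0f cc total, simulated gain %.0f cc\n",
              x$implant_volume_cc, x$volume_gain_cc))
  cat(sprintf("  solver: %d iterations, residual %.4g mm (%s)\n",
              x$info$iterations, x$info$residual,
              if (x$info$converged) "converged" else "iteration cap"))
  invisible(x)
}
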