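#' Calibrate view scales from landmarks and measurements
#'
#' The frontal scale is nipple-to-nipple distance (mm) over the nipple pixel
#' distance; each lateral scale is nipple-to-fold distance (mm) over the
#' corresponding pixel distance.
#'
#' @param landmarks a `landmark_set` (per-view named pixel points).
#' @param measurements a [measurements()] object.
#' @return An object of class `view_calibration`: mm-per-px for
#'   `front`, `left`, `right`.
#' @export
calibrate <- function(landmarks, measurements) {
  need <- function(view, name) {
    m <- landmarks[[view]]
    if (is.null(m) || !(name %in% rownames(m)))
      stop(sprintf("missing landmark '%s' in %s view", name, view))
    m[name, ]
  }
  pxd <- function(a, b) sqrt(sum((a - b)^2))
  d_front <- pxd(need("front", "left_nipple"), need("front", "right_nipple"))
  if (d_front < 1e-6) stop("degenerate calibration: coincident nipple landmarks")
  scales <- list(front = measurements$nipple_to_nipple / d_front)
  for (view in c("left", "right")) {
    d <- pxd(need(view, "nipple"), need(view, "fold"))
    if (d < 1e-6)
      stop(sprintf("degenerate calibration: coincident nipple/fold landmarks in %s view", view))
    scales[[view]] <- measurements$nipple_to_fold / d
  }
  s <- unlist(scales)
  if (max(s) / min(s) > 3)
    stop("view scales disagree by more than a factor of 3; check landmarks")
  scales$measurements <- measurements
  structure(scales, class = "view_calibration")
}

#' Extract the body contour from a silhouette or grayscale image
#'
#' Thresholds the image (Otsu for grayscale; polarity chosen so the component
#' containing the landmark centroid is foreground), keeps the connected
#' component containing the landmarks, and traces its boundary as a closed
#' sub-pixel polyline (0.5-level contour of the binary mask).
#'
#' @param image a `silhouette` or a numeric matrix (rows = image rows).
#' @param landmarks the landmark pixel matrix for this view (n x 2, (u, v)).
#' @param view view label carried through to the result.
#' @return An object of class `body_contour`: closed polyline `points`
#'   (n x 2, continuous px) plus the view label.
#' @export
extract_contour <- function(image, landmarks, view = "front") {
  img <- if (inherits(image, "silhouette")) image$mask * 1 else as.matrix(image)
  if (length(img) == 0 || all(is.na(img))) stop("empty image")
  if (all(img %in% c(0, 1))) {
    mask <- img > 0.5
  } else {
    thr <- EBImage::otsu(EBImage::Image(t(img)), range = range(img))
    mask <- img > thr
  }
  cen <- colMeans(landmarks)
  ci <- pmin(pmax(1L, as.integer(floor(cen[1])) + 1L), ncol(img))
  ri <- pmin(pmax(1L, as.integer(floor(cen[2])) + 1L), nrow(img))
  if (!mask[ri, ci]) {
    # centroid pixel is background under this polarity; try the other one
    if (!all(img %in% c(0, 1))) {
      thr <- EBImage::otsu(EBImage::Image(t(img)), range = range(img))
      mask2 <- img < thr
      if (mask2[ri, ci]) mask <- mask2
    }
  }
  if (!any(mask)) stop("no foreground component contains the landmarks")
  lab <- EBImage::bwlabel(EBImage::Image(t(mask)))
  lab <- t(EBImage::imageData(lab))
  comp_id <- lab[ri, ci]
  if (comp_id == 0) {
    # fall back to the component nearest any single landmark
    for (i in seq_len(nrow(landmarks))) {
      ci2 <- pmin(pmax(1L, as.integer(floor(landmarks[i, 1])) + 1L), ncol(img))
      ri2 <- pmin(pmax(1L, as.integer(floor(landmarks[i, 2])) + 1L), nrow(img))
      if (lab[ri2, ci2] > 0) { comp_id <- lab[ri2, ci2]; break }
    }
  }
  if (comp_id == 0) stop("no foreground component contains the landmarks")
  comp <- lab == comp_id
  pad <- matrix(0, nrow(comp) + 2, ncol(comp) + 2)
  pad[2:(nrow(comp) + 1), 2:(ncol(comp) + 1)] <- comp
  cl <- grDevices::contourLines(x = seq_len(ncol(pad)) - 1.5,
                                y = seq_len(nrow(pad)) - 1.5,
                                z = t(pad), levels = 0.5)
  if (length(cl) == 0) stop("contour tracing failed")
  areas <- vapply(cl, function(p) abs(polygon_area(cbind(p$x, p$y))), 0)
  p <- cl[[which.max(areas)]]
  pts <- cbind(u = p$x, v = p$y)
  if (sqrt(sum((pts[1, ] - pts[nrow(pts), ])^2)) < 1e-9)
    pts <- pts[-nrow(pts), , drop = FALSE]
  if (nrow(pts) < 20) stop("contour too short (< 20 points)")
  structure(list(points = pts, view = view), class = "body_contour")
}

polygon_area <- function(pts) {
  x <- pts[, 1]
  y <- pts[, 2]
  x2 <- c(x[-1], x[1])
  y2 <- c(y[-1], y[1])
  sum(x * y2 - x2 * y) / 2
}

# Sorted x-crossings of a closed polygon with the horizontal line y = y0.
polygon_scanline <- function(pts, y0) {
  x <- pts[, 1]
  y <- pts[, 2]
  x2 <- c(x[-1], x[1])
  y2 <- c(y[-1], y[1])
  cr <- which((y <= y0 & y2 > y0) | (y2 <= y0 & y > y0))
  if (length(cr) == 0) return(numeric(0))
  sort(x[cr] + (y0 - y[cr]) / (y2[cr] - y[cr]) * (x2[cr] - x[cr]))
}

#' Breast-type thresholds
#'
#' @param flat_projection breasts shallower than this (mm) are typed flat.
#' @param ptotic_drop nipple-below-fold drops beyond this (mm, negative)
#'   are typed ptotic.
#' @export
breast_type_config <- function(flat_projection = 15, ptotic_drop = -10) {
  list(flat_projection = flat_projection, ptotic_drop = ptotic_drop)
}

#' Classify breast type from a lateral profile
#'
#' Samples the contour between the sternal notch and the submammary fold
#' and computes, in mm: the maximum projection depth (anterior bulge beyond
#' the chest wall, with the anterior chest depth taken from the observable
#' posterior half-depth), the signed nipple drop relative to the fold, and
#' the number of curvature extrema along the anterior profile. Thresholds:
#' flat if projection depth < 15 mm, ptotic if nipple drop < -10 mm, else
#' normal.
#'
#' @param lateral_contour a `body_contour` from a lateral view.
#' @param landmarks the lateral view's landmark matrix (needs `nipple`,
#'   `fold`, `sternal_notch`).
#' @param cal a [calibrate()] result.
#' @param thresholds a [breast_type_config()].
#' @return An object of class `breast_type`: `max_projection_depth` (mm),
#'   `nipple_drop` (mm, signed), `curvature_extrema_count`, `label`.
#' @export
classify_breast_type <- function(lateral_contour, landmarks, cal,
                                 thresholds = breast_type_config()) {
  view <- lateral_contour$view
  s <- cal[[view]]
  for (nm in c("nipple", "fold", "sternal_notch"))
    if (!nm %in% rownames(landmarks))
      stop(sprintf("missing landmark '%s' in %s view", nm, view))
  pts <- lateral_contour$points
  notch <- landmarks["sternal_notch", ]
  fold <- landmarks["fold", ]
  nip <- landmarks["nipple", ]
  cen_u <- mean(pts[, 1])
  ant_sign <- sign(nip[1] - cen_u)
  sel <- pts[, 2] >= min(notch[2], fold[2]) & pts[, 2] <= max(notch[2], fold[2]) &
    sign(pts[, 1] - cen_u) == ant_sign
  prof <- pts[sel, , drop = FALSE]
  prof <- prof[order(prof[, 2]), , drop = FALSE]
  if (nrow(prof) < 10) stop("lateral profile shorter than 10 samples")
  # projection depth = anterior bulge over the chest wall, measured as the
  # anterior extent beyond the section centreline minus the posterior
  # half-depth at the same height (the chest section is front/back
  # symmetric away from the breast)
  vs <- seq(min(notch[2], fold[2]) + 1, max(notch[2], fold[2]) - 1,
            length.out = 80)
  top <- seq(min(pts[, 2]) + 1, min(pts[, 2]) + 0.12 * diff(range(pts[, 2])),
             length.out = 7)
  mids <- vapply(top, function(v0) {
    us <- polygon_scanline(pts, v0)
    if (length(us) < 2) NA_real_ else (min(us) + max(us)) / 2
  }, 0)
  uc <- mean(mids, na.rm = TRUE)
  depth <- vapply(vs, function(v0) {
    us <- polygon_scanline(pts, v0)
    if (length(us) < 2) return(NA_real_)
    front <- if (ant_sign > 0) max(us) else min(us)
    back <- if (ant_sign > 0) min(us) else max(us)
    (abs(front - uc) - abs(uc - back)) * s
  }, 0)
  depth <- depth[!is.na(depth)]
  nipple_drop <- (fold[2] - nip[2]) * s
  # curvature extrema along the smoothed profile
  k <- profile_curvature(prof)
  dk <- diff(k)
  extrema <- sum(dk[-length(dk)] * dk[-1] < 0)
  label <- if (max(depth) < thresholds$flat_projection) "flat"
           else if (nipple_drop < thresholds$ptotic_drop) "ptotic"
           else "normal"
  structure(list(max_projection_depth = max(depth), nipple_drop = nipple_drop,
                 curvature_extrema_count = extrema, label = label,
                 thresholds = thresholds),
            class = "breast_type")
}

profile_curvature <- function(prof, window = 7) {
  prof <- prof[!duplicated(round(prof[, 2], 6)), , drop = FALSE]
  u <- stats::filter(prof[, 1], rep(1 / window, window), sides = 2)
  v <- prof[, 2]
  ok <- !is.na(u)
  u <- as.numeric(u[ok])
  v <- v[ok]
  du <- diff(u) / diff(v)
  d2u <- diff(du) / diff(v[-1])
  k <- d2u / (1 + du[-1]^2)^1.5
  k[is.finite(k)]
}

#' @export
print.breast_type <- function(x, ...) {
  cat(sprintf("breast type: %s (projection depth %.1f mm, nipple drop %+.1f mm, %d curvature extrema)\n",
              x$label, x$max_projection_depth, x$nipple_drop,
              x$curvature_extrema_count))
  invisible(x)
}

#' Fitting controls for template reconstruction
#'
#' @param n_heights number of superellipse control heights.
#' @param edge_length output mesh edge length, mm.
#' @param max_iter optimizer iteration cap.
#' @param rel_tol optimizer relative tolerance.
#' @param refine run the contour-distance refinement stage.
#' @param refine_sweeps coordinate-descent sweeps in the refinement.
#' @param exponent chest superellipse exponent assumed by the template.
#' @param blend breast blend width assumed by the template, mm.
#' @param landmark_weight weight of the nipple reprojection term.
#' @export
fit_control <- function(n_heights = 21, edge_length = 4, max_iter = 500,
                        rel_tol = 1e-6, refine = TRUE, refine_sweeps = 4,
                        exponent = 2.5, blend = 5, landmark_weight = 1) {
  list(n_heights = n_heights, edge_length = edge_length, max_iter = max_iter,
       rel_tol = rel_tol, refine = refine, refine_sweeps = refine_sweeps,
       exponent = exponent, blend = blend, landmark_weight = landmark_weight)
}

# Per-view conversion of contour pixels to patient-frame mm.
# front: (x, y); laterals: (z, y) with z not yet centreline-referenced.
# The lateral scales are re-estimated from cross-view consistency of the
# torso silhouette height: the frontal scale rests on the long nipple-to-
# nipple baseline, whereas the nominal lateral scale divides a short,
# doubly-jittered nipple-to-fold segment, so transferring the frontal
# height through the silhouette spans is considerably less noisy.
contours_to_mm <- function(contours, cal, landmarks) {
  out <- list()
  f <- landmarks$front
  mid_u <- mean(c(f["left_nipple", 1], f["right_nipple", 1]))
  notch_v <- f["sternal_notch", 2]
  s <- cal$front
  p <- contours$front$points
  out$front <- cbind(x = (p[, 1] - mid_u) * s, y = -(p[, 2] - notch_v) * s)
  span_front <- diff(range(out$front[, "y"]))
  for (view in c("left", "right")) {
    lv <- landmarks[[view]]
    sgn <- if (view == "left") 1 else -1
    p <- contours[[view]]$points
    span_px <- diff(range(p[, 2]))
    s_eff <- if (span_px > 0) span_front / span_px else cal[[view]]
    z_raw <- sgn * p[, 1] * s_eff
    y <- -(p[, 2] - lv["sternal_notch", 2]) * s_eff
    out[[view]] <- cbind(z = z_raw, y = y)
    attr(out[[view]], "s_eff") <- s_eff
  }
  out
}

# Fused estimate of the residual global scale error of the front-calibrated
# frame, given a provisional template fit. Three redundant observations of
# the same global scale are combined by inverse-variance (pixel-baseline-
# squared) weights: the nipple-to-nipple baseline (defines the frame,
# ratio 1), the fold-to-fold baseline (the folds sit at the same +/- x as
# the nipples), and, per side, the nipple-to-fold measurement divided by the
# fitted template's own 3D nipple-to-fold distance, which rests on the
# jitter-free contours rather than on clicked landmark pairs.
estimate_scale_correction <- function(landmarks, cal, tpl) {
  meas <- cal$measurements
  if (is.null(meas)) return(1)
  f <- landmarks$front
  pxd <- function(a, b) sqrt(sum((a - b)^2))
  d_nn <- pxd(f["left_nipple", ], f["right_nipple", ])
  ratios <- 1
  weights <- d_nn^2
  if (all(c("left_fold", "right_fold") %in% rownames(f))) {
    d_ff <- pxd(f["left_fold", ], f["right_fold", ])
    if (d_ff > 1e-6) {
      ratios <- c(ratios, d_nn / d_ff)
      weights <- c(weights, d_ff^2)
    }
  }
  if (!is.null(tpl)) {
    nf <- template_nipples(tpl)
    for (side in c("left", "right")) {
      view <- side
      d_tpl <- sqrt(sum((nf$nipples[side, ] - nf$folds[side, ])^2))
      if (d_tpl < 10) next
      ratios <- c(ratios, meas$nipple_to_fold / d_tpl)
      weights <- c(weights, (d_tpl / cal[[view]])^2)
    }
  }
  sum(ratios * weights) / sum(weights)
}

# Lateral silhouette front/back curves predicted by a template at heights ys.
# Returns list(back, front) in mm (z relative to the section centreline).
template_lateral_curves <- function(tpl, ys, nx = 61) {
  back <- -tpl_depth_at(tpl, ys)
  a <- tpl_width_at(tpl, ys)
  ts <- seq(-0.999, 0.999, length.out = nx)
  X <- outer(a, ts)
  Y <- matrix(ys, length(ys), nx)
  Z <- matrix(tpl_front_z(tpl, as.vector(X), as.vector(Y)), length(ys), nx)
  front <- do.call(pmax, as.data.frame(Z))
  list(back = back, front = front)
}

# Stage-one fit in a fixed mm frame: per-height superellipse semi-axes read
# from contour scanlines, then per-side breast parameters by bounded
# finite-difference least squares on the dense anterior lateral profile.
fit_stage_a <- function(mm, landmarks, s_front, btype, control) {
  front <- mm$front
  y_top <- max(front[, 2])
  y_bot <- min(front[, 2])
  H <- y_top - y_bot
  if (H <= 0) stop("contour/landmark inconsistency: degenerate torso height")
  hs <- seq(y_bot, y_top, length.out = control$n_heights)

  # superellipse half-widths from front scanlines
  aw <- vapply(hs, function(y) {
    xs <- polygon_scanline(front, y)
    if (length(xs) < 2) return(NA_real_)
    (max(xs) - min(xs)) / 2
  }, 0)
  aw <- fill_ends(aw)

  # lateral centreline + half-depths (average of the two laterals)
  lat <- list()
  for (view in c("left", "right")) {
    p <- mm[[view]]
    top_rows <- seq(y_top - 0.14 * H, y_top - 0.04 * H, length.out = 9)
    mids <- vapply(top_rows, function(y) {
      zs <- polygon_scanline(p, y)
      if (length(zs) < 2) return(NA_real_)
      (min(zs) + max(zs)) / 2
    }, 0)
    zc <- mean(mids, na.rm = TRUE)
    zb <- vapply(hs, function(y) {
      zs <- polygon_scanline(p, y)
      if (length(zs) < 2) return(NA_real_)
      zc - min(zs)
    }, 0)
    lat[[view]] <- list(zc = zc, b = fill_ends(zb),
                        pts = cbind(p[, 1] - zc, p[, 2]))
  }
  bd <- (lat$left$b + lat$right$b) / 2

  # breast centres (x) from the frontal nipple landmarks
  f <- landmarks$front
  mid_u <- mean(c(f["left_nipple", 1], f["right_nipple", 1]))
  cx <- c(left = (f["left_nipple", 1] - mid_u) * s_front,
          right = (f["right_nipple", 1] - mid_u) * s_front)
  nip_y <- c(left = -(f["left_nipple", 2] - f["sternal_notch", 2]) * s_front,
             right = -(f["right_nipple", 2] - f["sternal_notch", 2]) * s_front)

  base_tpl <- torso_template(hs, aw, bd, exponent = control$exponent,
                             breasts = list(
                               left = list(center_x = cx[["left"]], center_y = nip_y[["left"]],
                                           radius = 50, projection = 1e-6, ptosis = 0),
                               right = list(center_x = cx[["right"]], center_y = nip_y[["right"]],
                                            radius = 50, projection = 1e-6, ptosis = 0)),
                             blend = control$blend)

  pt0 <- if (btype$label == "ptotic") 20 else 8
  proj0 <- min(max(btype$max_projection_depth, 8), 120)
  fold_y <- c(left = -(f["left_fold", 2] - f["sternal_notch", 2]) * s_front,
              right = -(f["right_fold", 2] - f["sternal_notch", 2]) * s_front)
  fit_side <- function(side) {
    li <- lat[[side]]
    ygrid <- seq(y_bot + 0.2 * H, y_top - 0.12 * H, length.out = 160)
    obs <- vapply(ygrid, function(y) {
      zs <- polygon_scanline(li$pts, y)
      if (length(zs) < 2) NA_real_ else max(zs)
    }, 0)
    ok <- !is.na(obs)
    ygrid <- ygrid[ok]
    obs <- obs[ok]
    bline <- approx(hs, bd, xout = ygrid, rule = 2)$y
    bulge <- pmax(obs - bline, 0)
    supp <- ygrid[bulge > 2]
    r0 <- if (length(supp) >= 2) max((max(supp) - min(supp)) / 2, 25) else 50
    cy0 <- if (length(supp) >= 2) mean(range(supp)) + pt0 / 2 else nip_y[[side]] + pt0
    par0 <- c(cy = cy0, r = r0, proj = proj0, pt = pt0)
    lower <- c(y_bot + 5, 15, 2, 0)
    upper <- c(y_top - 5, 0.45 * H, 150, 40)
    objective <- function(par) {
      tpl <- base_tpl
      tpl$breasts[[side]] <- list(center_x = cx[[side]], center_y = par[1],
                                  radius = par[2], projection = par[3],
                                  ptosis = par[4])
      other <- setdiff(c("left", "right"), side)
      tpl$breasts[[other]] <- tpl$breasts[[side]]
      tpl$breasts[[other]]$center_x <- cx[[other]]
      pred <- template_lateral_curves(tpl, ygrid)$front
      # weak landmark priors: the frontal nipple and fold heights observe
      # cy - ptosis and cy - radius directly
      prior <- (par[1] - par[4] - nip_y[[side]])^2 +
               (par[1] - par[2] - fold_y[[side]])^2
      mean((pred - obs)^2) + 0.05 * prior
    }
    fit <- nlminb(par0, objective, lower = lower, upper = upper,
                  control = list(iter.max = control$max_iter,
                                 rel.tol = control$rel_tol))
    list(par = fit$par, objective = fit$objective, convergence = fit$convergence)
  }
  side_fits <- lapply(c(left = "left", right = "right"), fit_side)

  tpl <- base_tpl
  for (side in c("left", "right")) {
    p <- side_fits[[side]]$par
    tpl$breasts[[side]] <- list(center_x = cx[[side]], center_y = p[[1]],
                                radius = p[[2]], projection = p[[3]],
                                ptosis = p[[4]])
  }
  list(template = tpl, side_fits = side_fits,
       extracted = list(front = front, left = lat$left$pts, right = lat$right$pts),
       nip_lm = rbind(left = c(cx[["left"]], nip_y[["left"]]),
                      right = c(cx[["right"]], nip_y[["right"]])),
       fold_lm = rbind(left = c(cx[["left"]], fold_y[["left"]]),
                       right = c(cx[["right"]], fold_y[["right"]])))
}

#' Fit the torso template to three extracted contours
#'
#' Deterministic multi-stage fit. Stage one reads the per-height
#' superellipse half-widths and half-depths directly from contour scanlines
#' (front view widths; lateral view depths with the section centreline
#' estimated from the upper chest), then recovers each side's breast
#' parameters (centre height, base radius, projection, ptosis) by bounded
#' finite-difference least squares on the dense anterior lateral profile,
#' initialized from the landmarks and the breast-type features. The global
#' scale is then re-estimated by fusing the two frontal landmark baselines
#' with the per-side nipple-to-fold measurement against the fitted
#' template, the frame is rescaled and stage one repeated. Stage two
#' refines the breast parameters by bounded coordinate descent on the
#' summed squared nearest-point distance between the template's projected
#' silhouette contours and the extracted contours plus a nipple
#' reprojection term; only improving steps are accepted.
#'
#' @param contours named list (`front`, `left`, `right`) of
#'   [extract_contour()] results.
#' @param cal a [calibrate()] result.
#' @param btype a [classify_breast_type()] result (initializes projection
#'   and ptosis).
#' @param landmarks the full `landmark_set`.
#' @param control a [fit_control()].
#' @return An object of class `reconstruction_result`: fitted `template`,
#'   `mesh`, per-view `residuals` (mean contour distance, mm and px),
#'   refinement `trace`, and the inputs used.
#' @export
fit_template <- function(contours, cal, btype, landmarks,
                         control = fit_control()) {
  mm <- contours_to_mm(contours, cal, landmarks)
  stage1 <- fit_stage_a(mm, landmarks, cal$front, btype, control)
  scale_c <- estimate_scale_correction(landmarks, cal, stage1$template)
  if (abs(scale_c - 1) > 1e-4) {
    for (view in c("front", "left", "right")) {
      at <- attr(mm[[view]], "s_eff")
      mm[[view]] <- mm[[view]] * scale_c
      if (!is.null(at)) attr(mm[[view]], "s_eff") <- at * scale_c
    }
    stage1 <- fit_stage_a(mm, landmarks, cal$front * scale_c, btype, control)
  }
  tpl <- stage1$template

  # per-side refinement cost: the opposite breast is mirrored from the side
  # under refinement (keeping its own centre x), because each orthographic
  # lateral silhouette is the union of both breasts and would otherwise
  # leave the smaller side unconstrained
  cost_side <- function(t, side) {
    other <- setdiff(c("left", "right"), side)
    t2 <- t
    t2$breasts[[other]] <- t2$breasts[[side]]
    t2$breasts[[other]]$center_x <- t$breasts[[other]]$center_x
    b <- t$breasts[[side]]
    lm <- (b$center_y - b$ptosis - stage1$nip_lm[side, 2])^2 +
          (b$center_y - b$radius - stage1$fold_lm[side, 2])^2
    contour_term(t2, stage1$extracted) + control$landmark_weight * lm
  }
  trace <- list()
  if (isTRUE(control$refine)) {
    ref <- refine_breasts(tpl, cost_side, sweeps = control$refine_sweeps)
    tpl <- ref$template
    trace <- ref$trace
  }

  res <- contour_residuals(tpl, stage1$extracted, cal)
  mesh <- build_torso_mesh(tpl, control$edge_length)
  structure(list(template = tpl, mesh = mesh, residuals = res,
                 breast_type = btype, calibration = cal, trace = trace,
                 scale_correction = scale_c, side_fits = stage1$side_fits),
            class = "reconstruction_result")
}

fill_ends <- function(x) {
  ok <- which(!is.na(x))
  if (length(ok) == 0) stop("contour scanlines produced no valid samples")
  x[seq_len(min(ok) - 1)] <- x[min(ok)]
  if (max(ok) < length(x)) x[(max(ok) + 1):length(x)] <- x[max(ok)]
  zoo_fill <- which(is.na(x))
  if (length(zoo_fill) > 0)
    x[zoo_fill] <- approx(which(!is.na(x)), x[!is.na(x)], xout = zoo_fill)$y
  x
}

# Template-projected contour points for all three views, in mm.
template_contour_points <- function(tpl, n = 120) {
  hs <- seq(min(tpl$heights), max(tpl$heights), length.out = n)
  a <- tpl_width_at(tpl, hs)
  lc <- template_lateral_curves(tpl, hs)
  list(front = rbind(cbind(a, hs), cbind(-a, hs)),
       left = rbind(cbind(lc$back, hs), cbind(lc$front, hs)),
       right = rbind(cbind(lc$back, hs), cbind(lc$front, hs)))
}

# Mean squared nearest-point distance from the template's projected
# silhouette contours to the extracted contours, over all three views (mm^2).
contour_term <- function(tpl, extracted) {
  proj <- template_contour_points(tpl)
  total <- 0
  npts <- 0
  for (view in c("front", "left", "right")) {
    d <- cpp_nn2d(proj[[view]], extracted[[view]])
    total <- total + sum(d^2)
    npts <- npts + length(d)
  }
  total / npts
}

refine_breasts <- function(tpl, cost_side, sweeps = 4) {
  steps0 <- c(cy = 3, r = 3, proj = 2, pt = 2)
  fields <- c(cy = "center_y", r = "radius", proj = "projection", pt = "ptosis")
  traces <- list()
  for (side in c("left", "right")) {
    steps <- steps0
    cur <- cost_side(tpl, side)
    tr <- cur
    for (sw in seq_len(sweeps)) {
      for (pn in names(fields)) {
        for (dir in c(1, -1)) {
          cand <- tpl
          val <- cand$breasts[[side]][[fields[pn]]] + dir * steps[pn]
          if (fields[pn] %in% c("radius", "projection") && val <= 1) next
          if (fields[pn] == "ptosis" && val < 0) next
          cand$breasts[[side]][[fields[pn]]] <- val
          cc <- cost_side(cand, side)
          if (cc < cur - 1e-9 * (1 + cur)) {
            tpl <- cand
            cur <- cc
            tr <- c(tr, cur)
          }
        }
      }
      steps <- steps / 2
    }
    traces[[side]] <- tr
  }
  list(template = tpl, trace = traces)
}

contour_residuals <- function(tpl, extracted, cal) {
  proj <- template_contour_points(tpl)
  out <- list()
  for (view in c("front", "left", "right")) {
    d <- cpp_nn2d(proj[[view]], extracted[[view]])
    out[[view]] <- c(mean_mm = mean(d), mean_px = mean(d) / cal[[view]])
  }
  out
}

#' @export
print.reconstruction_result <- function(x, ...) {
  r <- vapply(x$residuals, `[[`, 0, "mean_mm")
  cat(sprintf("reconstruction_result: mesh %d vertices; breast type %s\n",
              nrow(x$mesh$vertices), x$breast_type$label))
  cat(sprintf("  mean contour residual mm: front %.2f, left %.2f, right %.2f\n",
              r["front"], r["left"], r["right"]))
  invisible(x)
}

#' Reconstruct a patient torso from three views
#'
#' Full 2D-to-3D composition: [calibrate()], [extract_contour()] per view,
#' [classify_breast_type()] on the left lateral, and [fit_template()].
#' Deterministic: the same inputs give identical meshes. Errors are tagged
#' with the stage that raised them.
#'
#' @param images named list (`front`, `left`, `right`) of silhouettes or
#'   grayscale matrices.
#' @param landmarks a `landmark_set`.
#' @param measurements a [measurements()] object.
#' @param control a [fit_control()].
#' @return A `reconstruction_result` (see [fit_template()]).
#' @export
reconstruct_patient <- function(images, landmarks, measurements,
                                control = fit_control()) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("[%s] %s", name, conditionMessage(e)), call. = FALSE))
  }
  cal <- stage("calibrate", calibrate(landmarks, measurements))
  contours <- list()
  for (view in c("front", "left", "right"))
    contours[[view]] <- stage(paste0("extract_contour:", view),
                              extract_contour(images[[view]], landmarks[[view]], view))
  btype <- stage("classify_breast_type",
                 classify_breast_type(contours$left, landmarks$left, cal))
  stage("fit_template", fit_template(contours, cal, btype, landmarks, control))
}
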