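#' Rigid surface registration by iterative closest point
#'
#' Aligns `moving` onto `fixed` with point-to-surface correspondences and a
#' closed-form (Kabsch) rigid update per iteration. Strictly rigid: no
#' scaling or deformation, so breast shape is preserved and cannot bias a
#' downstream distance comparison. Converges when the rms improvement drops
#' below `tol`; meshes that start further than 200 mm rms apart are flagged
#' as not converged.
#'
#' @param moving,fixed [tri_mesh()] objects.
#' @param max_iter iteration cap.
#' @param tol rms improvement threshold in mm.
#' @return An object of class `registration_result`: `transform`
#'   (a [rigid_transform()] mapping moving into the fixed frame), `rms` (mm),
#'   `iterations`, `converged`, `rms_trace` and the registered mesh
#'   `moving_registered`.
#' @export
rigid_register <- function(moving, fixed, max_iter = 200, tol = 1e-5) {
  stopifnot(inherits(moving, "tri_mesh"), inherits(fixed, "tri_mesh"))
  if (nrow(moving$vertices) == 0L || nrow(fixed$vertices) == 0L)
    stop("cannot register an empty mesh")
  P <- moving$vertices
  total_R <- diag(3)
  total_t <- c(0, 0, 0)
  cp <- cpp_closest_points(P, fixed$vertices, fixed$faces)
  rms <- sqrt(mean(cp$distance^2))
  rms_trace <- rms
  if (rms > 200) {
    return(structure(list(transform = rigid_transform(), rms = rms,
                          iterations = 0L, converged = FALSE,
                          rms_trace = rms_trace, moving_registered = moving),
                     class = "registration_result"))
  }
  it <- 0L
  converged <- FALSE
  while (it < max_iter) {
    Q <- cp$closest
    mp <- colMeans(P)
    mq <- colMeans(Q)
    H <- crossprod(sweep(P, 2, mp), sweep(Q, 2, mq))
    s <- svd(H)
    d <- sign(det(s$v %*% t(s$u)))
    R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
    tv <- as.numeric(mq - R %*% mp)
    P <- P %*% t(R)
    P <- sweep(P, 2, tv, "+")
    total_R <- R %*% total_R
    total_t <- as.numeric(R %*% total_t) + tv
    cp <- cpp_closest_points(P, fixed$vertices, fixed$faces)
    rms_new <- sqrt(mean(cp$distance^2))
    it <- it + 1L
    rms_trace <- c(rms_trace, rms_new)
    if (rms - rms_new < tol) {
      rms <- rms_new
      converged <- TRUE
      break
    }
    rms <- rms_new
  }
  reg <- moving
  reg$vertices <- P
  structure(list(transform = rigid_transform(total_R, total_t), rms = rms,
                 iterations = it, converged = converged,
                 rms_trace = rms_trace, moving_registered = reg),
            class = "registration_result")
}

#' @export
print.registration_result <- function(x, ...) {
  cat(sprintf("registration_result: rms %.4f mm after %d iterations (%s)\n",
              x$rms, x$iterations,
              if (x$converged) "converged" else "not converged"))
  invisible(x)
}

#' Crop the breast regions from a torso mesh
#'
#' Keeps, per side, the vertices within `1.2 * base_radius` of that side's
#' nipple, bounded medially by the sagittal plane through the sternum (the
#' midline between the two nipples). Faces are kept iff all three vertices
#' are kept.
#'
#' @param mesh a [tri_mesh()].
#' @param nipples 2 x 3 matrix of nipple positions in mm (rows left, right;
#'   the patient-left nipple has the larger x).
#' @param base_radius breast base radius in mm.
#' @return List with `left` and `right` [tri_mesh()] submeshes.
#' @export
crop_breasts <- function(mesh, nipples, base_radius) {
  nipples <- as.matrix(nipples)
  stopifnot(nrow(nipples) == 2, ncol(nipples) == 3)
  if (is.null(rownames(nipples)))
    rownames(nipples) <- if (nipples[1, 1] >= nipples[2, 1]) c("left", "right") else c("right", "left")
  x_sternum <- mean(nipples[, 1])
  out <- list()
  for (side in c("left", "right")) {
    nip <- nipples[side, ]
    d <- sqrt(colSums((t(mesh$vertices) - nip)^2))
    medial_ok <- if (nip[1] >= x_sternum) mesh$vertices[, 1] >= x_sternum
                 else mesh$vertices[, 1] <= x_sternum
    keep <- d <= 1.2 * base_radius & medial_ok
    if (!any(keep)) stop(sprintf("empty crop for %s breast", side))
    out[[side]] <- submesh(mesh, keep)
  }
  out
}

submesh <- function(mesh, keep) {
  idx <- which(keep)
  remap <- integer(nrow(mesh$vertices))
  remap[idx] <- seq_along(idx)
  f <- mesh$faces + 1L
  fok <- keep[f[, 1]] & keep[f[, 2]] & keep[f[, 3]]
  f2 <- matrix(remap[f[fok, , drop = FALSE]], ncol = 3) - 1L
  tri_mesh(mesh$vertices[idx, , drop = FALSE], f2,
           colors = if (!is.null(mesh$colors)) mesh$colors[idx, , drop = FALSE])
}

#' Directed surface-to-surface distance
#'
#' For each vertex of the reconstruction, the unsigned distance to the
#' nearest point of the reference surface. The distance is directed
#' (reconstruction to reference) and is not assumed symmetric.
#'
#' @param recon reconstructed (or simulated) [tri_mesh()], already registered
#'   into the reference frame.
#' @param reference reference [tri_mesh()] (e.g. a laser-scan stand-in).
#' @param side optional side label (`"left"`/`"right"`) carried in the report.
#' @return An object of class `distance_report`: per-vertex `distances` (mm),
#'   `n_points`, `mean`, `median`, `q1`, `q3`, `max`, `side`, `direction`.
#' @export
surface_distance <- function(recon, reference, side = NULL) {
  stopifnot(inherits(recon, "tri_mesh"), inherits(reference, "tri_mesh"))
  if (nrow(recon$vertices) == 0L || nrow(reference$faces) == 0L)
    stop("empty mesh in surface_distance")
  d <- cpp_closest_points(recon$vertices, reference$vertices, reference$faces)$distance
  q <- unname(quantile(d, c(0.25, 0.5, 0.75), type = 7))
  structure(list(distances = d, n_points = length(d), mean = mean(d),
                 median = q[2], q1 = q[1], q3 = q[3], max = max(d),
                 side = side, direction = "reconstruction -> reference"),
            class = "distance_report")
}

#' @export
print.distance_report <- function(x, ...) {
  cat(sprintf("distance_report (%s%s): n = %d\n",
              x$direction, if (!is.null(x$side)) paste0(", ", x$side) else "",
              x$n_points))
  cat(sprintf("  mean %.2f | q1 %.2f | median %.2f | q3 %.2f | max %.2f mm\n",
              x$mean, x$q1, x$median, x$q3, x$max))
  invisible(x)
}

#' Box-plot statistics with the 1.5 IQR whisker rule
#'
#' Five-number summary (linear-interpolation quantiles), whiskers at the most
#' extreme points within 1.5 IQR of the quartiles, and the outliers beyond
#' the whiskers.
#'
#' @param report a [surface_distance()] report or a numeric vector (mm).
#' @return An object of class `boxplot_stats`: a one-row `stats` tibble
#'   (`n`, `min`, `whisker_low`, `q1`, `median`, `q3`, `whisker_high`,
#'   `max`, `n_outliers`) and the `outliers` vector.
#' @export
boxplot_stats <- function(report) {
  x <- if (inherits(report, "distance_report")) report$distances else as.numeric(report)
  if (length(x) < 1) stop("empty distance vector")
  q <- unname(quantile(x, c(0.25, 0.5, 0.75), type = 7))
  iqr <- q[3] - q[1]
  lo <- q[1] - 1.5 * iqr
  hi <- q[3] + 1.5 * iqr
  wl <- min(x[x >= lo])
  wh <- max(x[x <= hi])
  outliers <- sort(x[x < wl | x > wh])
  structure(list(
    stats = tibble::tibble(n = length(x), min = min(x), whisker_low = wl,
                           q1 = q[1], median = q[2], q3 = q[3],
                           whisker_high = wh, max = max(x),
                           n_outliers = length(outliers)),
    outliers = outliers), class = "boxplot_stats")
}

#' @export
print.boxplot_stats <- function(x, ...) {
  print(x$stats)
  invisible(x)
}

#' Box plot of a surface-distance report
#'
#' @param object a [surface_distance()] report.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.distance_report <- function(object, ...) {
  df <- tibble::tibble(side = object$side %||% "all",
                       distance = object$distances)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$side, y = .data$distance)) +
    ggplot2::geom_boxplot(outlier.size = 0.6, fill = "grey85") +
    ggplot2::labs(x = NULL, y = "surface distance (mm)",
                  title = "Directed surface-to-surface distance") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 .data
NULL
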