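#' Tidy a surface-distance report into a per-vertex tibble
#' @param x a [surface_distance()] report.
#' @param ... unused.
#' @return Tibble with `vertex`, `distance_mm` and `side`.
#' @export
tidy.distance_report <- function(x, ...) {
  tibble::tibble(vertex = seq_len(x$n_points), distance_mm = x$distances,
                 side = x$side %||% NA_character_)
}

#' One-row summary of a surface-distance report
#' @param x a [surface_distance()] report.
#' @param ... unused.
#' @export
glance.distance_report <- function(x, ...) {
  tibble::tibble(n_points = x$n_points, mean_mm = x$mean, median_mm = x$median,
                 q1_mm = x$q1, q3_mm = x$q3, max_mm = x$max,
                 side = x$side %||% NA_character_, direction = x$direction)
}

#' Tidy fitted template parameters
#' @param x a [fit_template()] / [reconstruct_patient()] result.
#' @param ... unused.
#' @return Tibble with one row per side of fitted breast parameters.
#' @export
tidy.reconstruction_result <- function(x, ...) {
  dplyr::bind_rows(lapply(c("left", "right"), function(side) {
    b <- x$template$breasts[[side]]
    tibble::tibble(side = side, center_x_mm = b$center_x,
                   center_y_mm = b$center_y, radius_mm = b$radius,
                   projection_mm = b$projection, ptosis_mm = b$ptosis)
  }))
}

#' One-row summary of a reconstruction
#' @param x a [fit_template()] / [reconstruct_patient()] result.
#' @param ... unused.
#' @export
glance.reconstruction_result <- function(x, ...) {
  r <- vapply(x$residuals, `[[`, 0, "mean_mm")
  tibble::tibble(breast_type = x$breast_type$label,
                 residual_front_mm = r[["front"]],
                 residual_left_mm = r[["left"]],
                 residual_right_mm = r[["right"]],
                 scale_correction = x$scale_correction %||% 1,
                 n_vertices = nrow(x$mesh$vertices))
}

#' One-row summary of a rigid registration
#' @param x a [rigid_register()] result.
#' @param ... unused.
#' @export
glance.registration_result <- function(x, ...) {
  ang <- acos(pmin(1, pmax(-1, (sum(diag(x$transform$rotation)) - 1) / 2))) * 180 / pi
  tibble::tibble(rms_mm = x$rms, iterations = x$iterations,
                 converged = x$converged, rotation_deg = ang,
                 translation_mm = sqrt(sum(x$transform$translation^2)))
}
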