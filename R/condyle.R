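#' Condylar anterior-posterior translation from a pose and condyle geometry
#'
#' Tracks each femoral condyle as the weighted mean location of its 10 points
#' nearest to a plane on the tibial plateau. Condyle point clouds (given in the
#' femoral component frame) are mapped into the tibial frame by the pose; for
#' each condyle the `n_nearest` points with the smallest signed distance to the
#' plateau plane are selected (penetration counts as nearest), and their
#' anterior-posterior coordinates are averaged with weights proportional to
#' `1 / (|distance| + eps)`, renormalized to sum to one. The result is the A-P
#' coordinate (mm, anterior positive) of that weighted centroid along the
#' plateau's A-P axis.
#'
#' The inverse-distance kernel is a documented package choice: the closest
#' points dominate, the `eps` floor (0.1 mm) keeps weights finite at contact,
#' and equal distances reduce to a plain mean.
#'
#' @param pose 4x4 homogeneous transform (femoral frame -> tibial frame, mm).
#' @param geometry A condyle geometry as returned by [condyle_geometry()].
#' @param n_nearest Number of nearest points per condyle (default 10).
#' @param eps Distance floor in mm for the inverse-distance weights.
#' @return A tibble with columns `medial_ap` and `lateral_ap` (mm).
#' @export
condylar_ap <- function(pose, geometry, n_nearest = 10, eps = 0.1) {
  stopifnot(is.matrix(pose), all(dim(pose) == c(4, 4)))
  check_orthonormal(pose[1:3, 1:3])
  tibble::tibble(
    medial_ap = condyle_ap_one(pose, geometry$medial_points, geometry$tibial_plane,
                               n_nearest, eps),
    lateral_ap = condyle_ap_one(pose, geometry$lateral_points, geometry$tibial_plane,
                                n_nearest, eps)
  )
}

condyle_ap_one <- function(pose, points, plane, n_nearest, eps) {
  if (nrow(points) < n_nearest) {
    stop_synergait(
      sprintf("condyle cloud has %d points; at least %d required", nrow(points), n_nearest),
      "synergait_geometry_error"
    )
  }
  R <- pose[1:3, 1:3]
  t <- pose[1:3, 4]
  tib <- points %*% t(R) + matrix(t, nrow(points), 3, byrow = TRUE)
  rel <- sweep(tib, 2, plane$point)
  d <- drop(rel %*% plane$normal)          # signed distance along the plane normal
  ap <- drop(rel %*% plane$ap_axis)        # A-P coordinate in the plateau frame
  sel <- order(d)[seq_len(n_nearest)]
  w <- 1 / (abs(d[sel]) + eps)
  sum(w * ap[sel]) / sum(w)
}

#' Construct a condyle geometry object
#'
#' Bundles medial and lateral condyle point clouds (femoral component frame,
#' mm) with the tibial plateau plane (a point on the plane, its unit normal,
#' and the unit anterior-posterior axis, all in the tibial component frame).
#'
#' @param medial_points,lateral_points Numeric matrices (n x 3), n >= 10.
#' @param plane_point Point on the plateau plane (length-3, mm).
#' @param plane_normal Plane normal (length-3; normalized internally).
#' @param ap_axis Anterior-posterior axis in the plateau plane (length-3;
#'   normalized internally); must be perpendicular to the normal.
#' @return An object of class `condyle_geometry`.
#' @export
condyle_geometry <- function(medial_points, lateral_points,
                             plane_point = c(0, 0, 0),
                             plane_normal = c(0, 0, 1),
                             ap_axis = c(0, 1, 0)) {
  medial_points <- as_point_matrix(medial_points, "medial_points")
  lateral_points <- as_point_matrix(lateral_points, "lateral_points")
  if (nrow(medial_points) < 10 || nrow(lateral_points) < 10) {
    stop_synergait("each condyle cloud needs at least 10 points",
                   "synergait_geometry_error")
  }
  n <- plane_normal / sqrt(sum(plane_normal^2))
  a <- ap_axis / sqrt(sum(ap_axis^2))
  if (abs(sum(n * a)) > 1e-8) {
    stop_synergait("ap_axis must be perpendicular to the plane normal",
                   "synergait_geometry_error")
  }
  structure(
    list(medial_points = medial_points, lateral_points = lateral_points,
         tibial_plane = list(point = as.numeric(plane_point), normal = n, ap_axis = a)),
    class = "condyle_geometry"
  )
}

as_point_matrix <- function(x, what) {
  if (is.data.frame(x)) x <- as.matrix(x[, c("x", "y", "z")])
  if (!is.matrix(x) || ncol(x) != 3 || !all(is.finite(x))) {
    stop_synergait(sprintf("%s must be a finite n x 3 matrix", what),
                   "synergait_geometry_error")
  }
  unname(x)
}

#' @export
print.condyle_geometry <- function(x, ...) {
  cat(sprintf(
    "<condyle_geometry> medial: %d points, lateral: %d points\n",
    nrow(x$medial_points), nrow(x$lateral_points)
  ))
  invisible(x)
}
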