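#' Tibiofemoral joint angles in the Grood-Suntay joint coordinate system
#'
#' Decomposes the rotation of the femoral component relative to the tibial
#' component into clinically interpretable angles: flexion about the femoral
#' medio-lateral axis (body-fixed), internal/external rotation about the tibial
#' longitudinal axis (body-fixed), and ab/adduction about the mutually
#' perpendicular floating axis. This three-axis (fixed-floating-fixed) joint
#' coordinate system is mathematically equivalent to a Cardan x-y'-z'' sequence
#' of the femoral-to-tibial rotation, which is how it is computed here.
#'
#' Sign convention (fixed and documented): flexion positive, adduction
#' positive, internal rotation positive. Axes of the component frames: x
#' medio-lateral (medial +), y anterior-posterior (anterior +), z longitudinal
#' (proximal +).
#'
#' @param pose A 3x3 rotation matrix or 4x4 homogeneous transform mapping the
#'   femoral component frame into the tibial component frame, or a pose tibble
#'   as returned by [read_pose_tsv()] (columns `r11`..`r33`).
#' @return A tibble with columns `flexion`, `adduction`, `internal_rotation`
#'   in degrees, one row per pose.
#' @seealso [gs_compose()] for the inverse operation.
#' @examples
#' gs_decompose(diag(4))
#' gs_decompose(gs_compose(12, 3, -7))
#' @export
gs_decompose <- function(pose) {
  if (is.data.frame(pose)) {
    rots <- pose_df_rotations(pose)
    return(dplyr::bind_rows(lapply(rots, gs_decompose_one)))
  }
  gs_decompose_one(pose)
}

gs_decompose_one <- function(pose) {
  R <- as_rotation(pose)
  check_orthonormal(R)
  # R = Rx(flex) Ry(add) Rz(int): R[1,3] = sin(add), R[2,3] = -sin(flex)cos(add),
  # R[3,3] = cos(flex)cos(add), R[1,2] = -cos(add)sin(int), R[1,1] = cos(add)cos(int)
  s_add <- max(-1, min(1, R[1, 3]))
  add <- asin(s_add)
  if (abs(cos(add)) < 1e-8) {
    stop_synergait(
      "gimbal proximity: |ab/adduction| is within numerical reach of 90 degrees; flexion and internal rotation are not separable",
      "synergait_gimbal_error"
    )
  }
  flex <- atan2(-R[2, 3], R[3, 3])
  int <- atan2(-R[1, 2], R[1, 1])
  tibble::tibble(
    flexion = flex * 180 / pi,
    adduction = add * 180 / pi,
    internal_rotation = int * 180 / pi
  )
}

#' Compose a femoral-to-tibial rotation from joint angles
#'
#' Inverse of [gs_decompose()]: builds the rotation matrix corresponding to
#' given flexion, adduction and internal-rotation angles (degrees).
#'
#' @param flexion,adduction,internal_rotation Angles in degrees.
#' @return A 3x3 rotation matrix.
#' @export
gs_compose <- function(flexion, adduction, internal_rotation) {
  rot_x(flexion * pi / 180) %*% rot_y(adduction * pi / 180) %*%
    rot_z(internal_rotation * pi / 180)
}

rot_x <- function(a) {
  matrix(c(1, 0, 0, 0, cos(a), sin(a), 0, -sin(a), cos(a)), 3, 3)
}
rot_y <- function(a) {
  matrix(c(cos(a), 0, -sin(a), 0, 1, 0, sin(a), 0, cos(a)), 3, 3)
}
rot_z <- function(a) {
  matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0, 0, 0, 1), 3, 3)
}

as_rotation <- function(pose) {
  if (!is.matrix(pose) || !(all(dim(pose) == c(3, 3)) || all(dim(pose) == c(4, 4)))) {
    stop_synergait("pose must be a 3x3 rotation or 4x4 homogeneous transform",
                   "synergait_pose_error")
  }
  pose[1:3, 1:3]
}

check_orthonormal <- function(R, tol = 1e-6) {
  if (!all(is.finite(R)) || max(abs(crossprod(R) - diag(3))) > tol) {
    stop_synergait("rotation block is not orthonormal", "synergait_pose_error")
  }
  invisible(R)
}

pose_df_rotations <- function(df) {
  cols <- c("r11", "r12", "r13", "r21", "r22", "r23", "r31", "r32", "r33")
  if (!all(cols %in% names(df))) {
    stop_synergait("pose tibble must contain columns r11..r33", "synergait_pose_error")
  }
  lapply(seq_len(nrow(df)), function(i) {
    matrix(as.numeric(df[i, cols]), 3, 3, byrow = TRUE)
  })
}

pose_df_transforms <- function(df) {
  rots <- pose_df_rotations(df)
  if (!all(c("tx", "ty", "tz") %in% names(df))) {
    stop_synergait("pose tibble must contain columns tx, ty, tz", "synergait_pose_error")
  }
  lapply(seq_along(rots), function(i) {
    make_transform(rots[[i]], as.numeric(df[i, c("tx", "ty", "tz")]))
  })
}

make_transform <- function(R, t) {
  T <- diag(4)
  T[1:3, 1:3] <- R
  T[1:3, 4] <- t
  T
}
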