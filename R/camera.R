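# Cameras. Orientation is a unit quaternion; the camera frame is
# right-handed with -z forward and +y up, world is right-handed, pixel
# (0,0) is top-left, and rays go through pixel centers.

.quat <- function(w, x, y, z) c(w, x, y, z)

.quat_mul <- function(a, b) c(
  a[1] * b[1] - a[2] * b[2] - a[3] * b[3] - a[4] * b[4],
  a[1] * b[2] + a[2] * b[1] + a[3] * b[4] - a[4] * b[3],
  a[1] * b[3] - a[2] * b[4] + a[3] * b[1] + a[4] * b[2],
  a[1] * b[4] + a[2] * b[3] - a[3] * b[2] + a[4] * b[1])

.quat_axis_angle <- function(axis, angle_deg) {
  a <- angle_deg * pi / 180
  axis <- axis / sqrt(sum(axis^2))
  c(cos(a / 2), sin(a / 2) * axis)
}

.quat_to_mat <- function(q) {
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
    3, 3, byrow = TRUE)
}

.mat_to_quat <- function(m) {
  tr <- m[1, 1] + m[2, 2] + m[3, 3]
  if (tr > 0) {
    s <- sqrt(tr + 1) * 2
    q <- c(0.25 * s, (m[3, 2] - m[2, 3]) / s, (m[1, 3] - m[3, 1]) / s,
           (m[2, 1] - m[1, 2]) / s)
  } else if (m[1, 1] > m[2, 2] && m[1, 1] > m[3, 3]) {
    s <- sqrt(1 + m[1, 1] - m[2, 2] - m[3, 3]) * 2
    q <- c((m[3, 2] - m[2, 3]) / s, 0.25 * s, (m[1, 2] + m[2, 1]) / s,
           (m[1, 3] + m[3, 1]) / s)
  } else if (m[2, 2] > m[3, 3]) {
    s <- sqrt(1 + m[2, 2] - m[1, 1] - m[3, 3]) * 2
    q <- c((m[1, 3] - m[3, 1]) / s, (m[1, 2] + m[2, 1]) / s, 0.25 * s,
           (m[2, 3] + m[3, 2]) / s)
  } else {
    s <- sqrt(1 + m[3, 3] - m[1, 1] - m[2, 2]) * 2
    q <- c((m[2, 1] - m[1, 2]) / s, (m[1, 3] + m[3, 1]) / s,
           (m[2, 3] + m[3, 2]) / s, 0.25 * s)
  }
  q / sqrt(sum(q^2))
}

.look_at_quat <- function(position, target, up_hint = c(0, 1, 0)) {
  f <- target - position
  f <- f / sqrt(sum(f^2))
  if (abs(sum(f * up_hint)) > 0.999) up_hint <- c(0, 0, 1)
  r <- crossprod3(f, up_hint)        # right = forward x up
  r <- r / sqrt(sum(r^2))
  u <- crossprod3(r, f)
  .mat_to_quat(cbind(r, u, -f))
}

#' Construct a camera
#'
#' @param position camera position (Angstrom)
#' @param target look-at point; required for trackball mode
#' @param fov vertical field of view, degrees, in (0, 180)
#' @param near,far clip distances (0 < near < far), Angstrom
#' @param mode `"trackball"` (orbits `target`) or `"freefly"`
#' @param orientation unit quaternion (w, x, y, z); derived from
#'   `target` when omitted
#' @export
camera <- function(position, target = NULL, fov = 45, near = 0.1, far = 1e4,
                   mode = c("trackball", "freefly"), orientation = NULL) {
  mode <- match.arg(mode)
  stopifnot(fov > 0, fov < 180, near > 0, far > near)
  position <- as.numeric(position)
  if (is.null(orientation)) {
    if (is.null(target)) stop("either target or orientation is required")
    orientation <- .look_at_quat(position, as.numeric(target))
  }
  if (mode == "trackball" && is.null(target))
    stop("trackball camera requires a target")
  structure(list(position = position, orientation = orientation / sqrt(sum(orientation^2)),
                 fov = fov, near = near, far = far, mode = mode,
                 target = if (is.null(target)) NULL else as.numeric(target)),
            class = "molcamera")
}

.cam_basis <- function(cam) {
  m <- .quat_to_mat(cam$orientation)
  list(right = m[, 1], up = m[, 2], forward = -m[, 3], mat = m)
}

#' Per-pixel rays for a camera
#'
#' Perspective projection from the vertical field of view; pixel centers;
#' pixel (0, 0) top-left. Directions are returned in the column-major order
#' of an `height x width` matrix (row index fastest), so buffer matrices
#' index directly.
#'
#' @param cam a `molcamera`
#' @param width,height image dimensions in pixels
#' @return list with `origin` (3-vector) and `dirs` (n_pixels x 3, unit)
#' @export
camera_rays <- function(cam, width, height) {
  stopifnot(width >= 1, height >= 1)
  list(origin = cam$position,
       dirs = .ray_dirs(cam, width, height, seq_len(width * height)))
}

# ray directions for a subset of pixel indices (1-based, column-major of the
# height x width buffer); used internally so large frames never materialize
# all rays at once.
.ray_dirs <- function(cam, width, height, idx) {
  b <- .cam_basis(cam)
  tanv <- tan(cam$fov / 2 * pi / 180)
  i0 <- idx - 1L
  row <- i0 %% height + 1L
  col <- i0 %/% height + 1L
  x <- tanv * (2 * col - 1 - width) / height
  y <- tanv * (height - 2 * row + 1) / height
  d <- cbind(x, y, -1)
  d <- d / sqrt(x * x + y * y + 1)
  unname(d %*% t(b$mat))
}

#' Orbit a trackball camera about its target
#'
#' Yaw about world up, then pitch about the camera's right axis (clamped so
#' the elevation never exceeds +/-89 degrees), then scale the distance to
#' the target by `exp(d_zoom)`; finally re-aim at the target.
#'
#' @param cam a trackball `molcamera`
#' @param d_yaw,d_pitch rotation increments, degrees
#' @param d_zoom log-scale zoom increment (0 = unchanged distance)
#' @export
trackball_update <- function(cam, d_yaw = 0, d_pitch = 0, d_zoom = 0) {
  if (cam$mode != "trackball") stop("not a trackball camera", call. = FALSE)
  off <- cam$position - cam$target
  up <- c(0, 1, 0)
  off <- c(.quat_to_mat(.quat_axis_angle(up, d_yaw)) %*% off)
  # current elevation and clamped pitch
  dist <- sqrt(sum(off^2))
  elev <- asin(max(-1, min(1, sum(off * up) / dist))) * 180 / pi
  d_pitch <- max(-89 - elev, min(89 - elev, d_pitch))
  fwd <- -off / dist
  right <- crossprod3(fwd, up)
  rl <- sqrt(sum(right^2))
  if (rl > 1e-12) {
    right <- right / rl
    off <- c(.quat_to_mat(.quat_axis_angle(right, d_pitch)) %*% off)
  }
  off <- off * exp(d_zoom)
  cam$position <- cam$target + off
  cam$orientation <- .look_at_quat(cam$position, cam$target)
  cam
}

#' Move a free-fly camera
#'
#' Rotates first (yaw about world up, pitch about the camera's right axis),
#' then translates in the rotated camera basis.
#'
#' @param cam a freefly `molcamera`
#' @param move 3-vector (right, up, forward) in Angstrom
#' @param d_yaw,d_pitch rotation increments, degrees
#' @export
freefly_update <- function(cam, move = c(0, 0, 0), d_yaw = 0, d_pitch = 0) {
  if (cam$mode != "freefly") stop("not a freefly camera", call. = FALSE)
  q <- cam$orientation
  q <- .quat_mul(.quat_axis_angle(c(0, 1, 0), d_yaw), q)
  b <- .quat_to_mat(q)
  q <- .quat_mul(.quat_axis_angle(b[, 1], d_pitch), q)
  q <- q / sqrt(sum(q^2))
  b2 <- .quat_to_mat(q)
  cam$orientation <- q
  cam$position <- cam$position + b2[, 1] * move[1] + b2[, 2] * move[2] +
    (-b2[, 3]) * move[3]
  cam
}
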