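# Vectorised quaternion helpers.  Quaternions are Hamilton, scalar-first
# (w, x, y, z), and encode the body-to-earth rotation; the earth frame is
# z-up (ENU-like, with yaw measured about the vertical axis).

#' Rotate vectors by quaternions
#'
#' Applies the body-to-earth rotation encoded by each quaternion row to the
#' corresponding vector row (`inverse = FALSE`), or the earth-to-body
#' rotation (`inverse = TRUE`).
#'
#' @param q numeric matrix with columns `w, x, y, z` (one quaternion per row,
#'   or a single row recycled for all vectors).
#' @param v numeric matrix with 3 columns, one vector per row.
#' @param inverse rotate earth-frame vectors into the body frame instead.
#' @return a numeric matrix of rotated vectors, same shape as `v`.
#' @export
quat_rotate <- function(q, v, inverse = FALSE) {
  q <- matrix(as.numeric(q), ncol = 4)
  v <- matrix(as.numeric(v), ncol = 3)
  if (nrow(q) == 1L && nrow(v) > 1L) q <- q[rep(1L, nrow(v)), , drop = FALSE]
  stopifnot(nrow(q) == nrow(v))
  w <- q[, 1]; x <- q[, 2]; y <- q[, 3]; z <- q[, 4]
  if (inverse) { x <- -x; y <- -y; z <- -z }
  vx <- v[, 1]; vy <- v[, 2]; vz <- v[, 3]
  # t = 2 q_v x v ; v' = v + w t + q_v x t
  tx <- 2 * (y * vz - z * vy)
  ty <- 2 * (z * vx - x * vz)
  tz <- 2 * (x * vy - y * vx)
  cbind(
    vx + w * tx + y * tz - z * ty,
    vy + w * ty + z * tx - x * tz,
    vz + w * tz + x * ty - y * tx
  )
}

#' Euler angles (yaw, pitch, roll) from quaternions
#'
#' Uses the Z-Y-X (yaw-pitch-roll) decomposition with a z-up earth frame.
#' Pitch is the elevation of the body x-axis (the forearm long axis for a
#' wrist-worn sensor) above the horizontal plane, in degrees within
#' \[-90, 90\]; yaw is the heading of the body x-axis in (-180, 180\].
#'
#' @param q numeric matrix with columns `w, x, y, z`.
#' @return a tibble with columns `yaw`, `pitch`, `roll` in degrees.
#' @export
quat_to_euler <- function(q) {
  q <- matrix(as.numeric(q), ncol = 4)
  w <- q[, 1]; x <- q[, 2]; y <- q[, 3]; z <- q[, 4]
  # body->earth rotation matrix elements
  r11 <- 1 - 2 * (y^2 + z^2)
  r21 <- 2 * (x * y + w * z)
  r31 <- 2 * (x * z - w * y)
  r32 <- 2 * (y * z + w * x)
  r33 <- 1 - 2 * (x^2 + y^2)
  deg <- 180 / pi
  tibble::tibble(
    yaw = atan2(r21, r11) * deg,
    pitch = asin(pmin(1, pmax(-1, r31))) * deg,
    roll = atan2(r32, r33) * deg
  )
}

#' Quaternion from yaw and pitch angles
#'
#' Builds the body-to-earth quaternion for a given yaw (heading) and pitch
#' (elevation of the body x-axis), with zero roll.  This is the exact inverse
#' of [quat_to_euler()] for zero-roll attitudes and is used by the synthetic
#' generator to script orientations.
#'
#' @param yaw,pitch angles in degrees (vectors of equal length).
#' @return numeric matrix with columns `w, x, y, z`.
#' @export
euler_to_quat <- function(yaw, pitch) {
  hy <- yaw * pi / 360
  hp <- -pitch * pi / 360  # rotation about +y by -pitch elevates body x
  cy <- cos(hy); sy <- sin(hy); cp <- cos(hp); sp <- sin(hp)
  # qz(yaw) * qy(-pitch)
  cbind(w = cy * cp, x = -sy * sp, y = cy * sp, z = sy * cp)
}

# Tilt-only initial quaternion from a (roughly static) accelerometer sample:
# the rotation taking the measured specific-force direction to earth-up.
tilt_quaternion <- function(a) {
  a <- as.numeric(a)
  nrm <- sqrt(sum(a^2))
  if (!is.finite(nrm) || nrm == 0) return(c(1, 0, 0, 0))
  a <- a / nrm
  e <- c(0, 0, 1)
  d <- sum(a * e)
  if (d > 1 - 1e-12) return(c(1, 0, 0, 0))
  if (d < -1 + 1e-12) return(c(0, 1, 0, 0))  # 180 deg about x
  axis <- c(a[2] * e[3] - a[3] * e[2],
            a[3] * e[1] - a[1] * e[3],
            a[1] * e[2] - a[2] * e[1])
  axis <- axis / sqrt(sum(axis^2))
  half <- acos(d) / 2
  c(cos(half), sin(half) * axis)
}

# Unwrap a series of angles in degrees so successive differences never
# exceed 180 in magnitude (needed before windowed range computations).
unwrap_deg <- function(x) {
  ok <- is.finite(x)
  if (sum(ok) < 2L) return(x)
  xr <- x[ok] * pi / 180
  d <- diff(xr)
  jump <- ((d + pi) %% (2 * pi)) - pi
  jump[d == -pi & jump == -pi] <- pi
  x[ok] <- (xr[1] + c(0, cumsum(jump))) * 180 / pi
  x
}
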