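# Internal quaternion helpers for the synthetic-signal generator.
# Quaternions are length-4 numeric (w, x, y, z), unit norm.

quat_conj <- function(q) c(q[1], -q[2], -q[3], -q[4])

quat_mult <- function(a, b) {
  c(a[1]*b[1] - a[2]*b[2] - a[3]*b[3] - a[4]*b[4],
    a[1]*b[2] + a[2]*b[1] + a[3]*b[4] - a[4]*b[3],
    a[1]*b[3] - a[2]*b[4] + a[3]*b[1] + a[4]*b[2],
    a[1]*b[4] + a[2]*b[3] - a[3]*b[2] + a[4]*b[1])
}

quat_normalize <- function(q) q / sqrt(sum(q^2))

# quaternion for a rotation of `angle` radians about unit `axis`
quat_from_axis_angle <- function(axis, angle) {
  c(cos(angle / 2), sin(angle / 2) * axis)
}

# minimal rotation taking the world up-axis (0,0,1) onto unit vector `g`
quat_minrot_to <- function(g) {
  e3 <- c(0, 0, 1)
  d <- sum(e3 * g)
  if (d > 1 - 1e-12) return(c(1, 0, 0, 0))
  if (d < -1 + 1e-12) return(c(0, 1, 0, 0))  # 180 deg about x
  axis <- c(e3[2]*g[3] - e3[3]*g[2], e3[3]*g[1] - e3[1]*g[3],
            e3[1]*g[2] - e3[2]*g[1])
  axis <- axis / sqrt(sum(axis^2))
  quat_from_axis_angle(axis, acos(d))
}

# 3x3 rotation matrix of q (applies the rotation to column vectors)
quat_to_matrix <- function(q) {
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2*(y^2 + z^2), 2*(x*y + w*z),     2*(x*z - w*y),
           2*(x*y - w*z),     1 - 2*(x^2 + z^2), 2*(y*z + w*x),
           2*(x*z + w*y),     2*(y*z - w*x),     1 - 2*(x^2 + y^2)),
         nrow = 3, byrow = FALSE)
}

# log map: unit quaternion -> rotation vector (axis * angle)
quat_log <- function(q) {
  if (q[1] < 0) q <- -q
  vnorm <- sqrt(sum(q[2:4]^2))
  if (vnorm < 1e-12) return(c(0, 0, 0))
  angle <- 2 * atan2(vnorm, q[1])
  q[2:4] / vnorm * angle
}

quat_exp <- function(v) {
  angle <- sqrt(sum(v^2))
  if (angle < 1e-12) return(c(1, 0, 0, 0))
  c(cos(angle / 2), sin(angle / 2) * v / angle)
}

# slerp between q1 and q2 at fractions s in [0,1]; returns length(s) x 4
quat_slerp <- function(q1, q2, s) {
  if (sum(q1 * q2) < 0) q2 <- -q2
  v <- quat_log(quat_mult(quat_conj(q1), q2))
  out <- matrix(0, length(s), 4)
  for (i in seq_along(s)) {
    out[i, ] <- quat_normalize(quat_mult(q1, quat_exp(s[i] * v)))
  }
  out
}
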