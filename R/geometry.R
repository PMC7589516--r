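#' Volume of a spherocylinder
#'
#' `pi r^2 L + (4/3) pi r^3`: a cylinder of length `seg_length` capped by two
#' hemispheres of radius `radius`. With `seg_length = 0` this is a sphere.
#'
#' @param seg_length Length of the cylindrical section (µm), vectorized.
#' @param radius Cap radius (µm), vectorized.
#' @return Volume(s) in µm³.
#' @examples
#' capsule_volume(0, 0.5)   # sphere limit, 4/3 pi (0.5)^3
#' capsule_volume(2, 0.5)
#' @export
capsule_volume <- function(seg_length, radius) {
  if (any(seg_length < 0) || any(radius <= 0))
    stop("invalid capsule geometry: need seg_length >= 0 and radius > 0")
  pi * radius^2 * seg_length + (4 / 3) * pi * radius^3
}

# inverse of capsule_volume at fixed radius
capsule_seg_length <- function(volume, radius) {
  vs <- (4 / 3) * pi * radius^3
  if (any(volume < vs - 1e-9))
    stop("volume smaller than the spherical minimum for this radius")
  pmax(0, (volume - vs) / (pi * radius^2))
}

# Uniform samples on the 2-D perimeter of capsules (one per input element).
# Returns origins on the surface and outward normal directions. Vectorized;
# consumes runif(n) once, so the draw order is reproducible.
sample_capsule_perimeter <- function(cx, cy, ax, ay, seg, R) {
  n <- length(cx)
  perim <- 2 * seg + 2 * pi * R
  u <- runif(n, 0, perim)
  px <- -ay; py <- ax                    # left-hand perpendicular
  ox <- oy <- dx <- dy <- numeric(n)

  s1 <- u < seg
  s2 <- !s1 & u < 2 * seg
  cap <- !s1 & !s2

  if (any(s1)) {
    tp <- u[s1] - seg[s1] / 2
    ox[s1] <- cx[s1] + ax[s1] * tp + px[s1] * R
    oy[s1] <- cy[s1] + ay[s1] * tp + py[s1] * R
    dx[s1] <- px[s1]; dy[s1] <- py[s1]
  }
  if (any(s2)) {
    tp <- (u[s2] - seg[s2]) - seg[s2] / 2
    ox[s2] <- cx[s2] + ax[s2] * tp - px[s2] * R
    oy[s2] <- cy[s2] + ay[s2] * tp - py[s2] * R
    dx[s2] <- -px[s2]; dy[s2] <- -py[s2]
  }
  if (any(cap)) {
    phi <- (u[cap] - 2 * seg[cap]) / R - pi       # angle in [-pi, pi)
    ca <- cos(phi); sa <- sin(phi)
    ddx <- ca * ax[cap] - sa * ay[cap]
    ddy <- sa * ax[cap] + ca * ay[cap]
    pole <- ifelse(abs(phi) <= pi / 2, 1, -1)
    ox[cap] <- cx[cap] + pole * ax[cap] * seg[cap] / 2 + R * ddx
    oy[cap] <- cy[cap] + pole * ay[cap] * seg[cap] / 2 + R * ddy
    dx[cap] <- ddx; dy[cap] <- ddy
  }
  list(ox = ox, oy = oy, dx = dx, dy = dy)
}
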