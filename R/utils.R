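# Internal angle and small linear-algebra helpers.
#
# Conventions used throughout the package:
#  * maps are numeric matrices indexed [x, y] (x = first index, y = second);
#  * angles are degrees, counterclockwise from the +x axis;
#  * directional angles live in (-180, 180], axial orientations in [0, 180).

deg2rad <- function(d) d * pi / 180
rad2deg <- function(r) r * 180 / pi

#' Wrap directional angles into (-180, 180]
#' @param deg Angles in degrees.
#' @return Wrapped angles.
#' @export
wrap_angle <- function(deg) {
  w <- (deg + 180) %% 360 - 180
  w[w == -180] <- 180
  w
}

#' Wrap axial orientations into [0, 180)
#' @param deg Orientations in degrees (defined modulo 180).
#' @return Wrapped orientations.
#' @export
wrap_axial <- function(deg) deg %% 180

# Smallest absolute difference between two directional angles (deg).
angle_diff <- function(a, b) abs(wrap_angle(a - b))

# Smallest absolute difference between two axial orientations (deg).
axial_diff <- function(a, b) {
  d <- abs(wrap_axial(a) - wrap_axial(b))
  pmin(d, 180 - d)
}

# Unit vector at `deg` degrees CCW from +x.
unit_vec <- function(deg) c(cos(deg2rad(deg)), sin(deg2rad(deg)))

# Rotate points (n x 2 matrix) by `deg` degrees CCW about the origin.
rotate_xy <- function(xy, deg) {
  th <- deg2rad(deg)
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  xy %*% t(R)
}

# Axial orientation (deg in [0, 180)) of the first right-singular vector of
# centred 2D coordinates; also returns the singular values.
principal_axis <- function(xy) {
  xy <- sweep(xy, 2, colMeans(xy))
  sv <- svd(xy)
  list(axis_deg = wrap_axial(rad2deg(atan2(sv$v[2, 1], sv$v[1, 1]))),
       d = sv$d)
}

# Pixel coordinate matrix (n x 2, columns x and y) for TRUE cells of a mask.
mask_coords <- function(mask) {
  idx <- which(mask, arr.ind = TRUE)
  colnames(idx) <- NULL
  idx
}
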