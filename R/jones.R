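# Jones calculus for the circular-input PSOCT polarization model.
#
# Conventions (fixed across the package):
#   * Jones vectors are (E_H, E_V); the instrument's "co" channel is the
#     detector that receives the full return from a mirror (the V detector
#     under circular illumination), "cross" is the other (H).
#   * A linear retarder with retardance phi (degrees) and in-plane axis
#     theta (degrees) is R(theta) diag(e^{+i phi/2}, e^{-i phi/2}) R(-theta).
#     With this sign convention the half-phase-difference orientation
#     estimator is directly equivariant: rotating the sample axis by alpha
#     shifts the estimate by alpha (mod 180).
#   * The illumination QWP is a retarder with phi = 90 at 45 degrees,
#     turning horizontal input into circular polarization on the sample.

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

rotation_matrix <- function(theta_rad) {
  c <- cos(theta_rad); s <- sin(theta_rad)
  matrix(c(c, s, -s, c), 2, 2)
}

#' Jones matrix of a linear retarder
#'
#' @param retardance retardance in degrees.
#' @param axis in-plane fast-axis angle in degrees.
#' @return complex 2x2 unitary matrix.
#' @export
jones_retarder <- function(retardance, axis) {
  phi <- deg2rad(retardance); th <- deg2rad(axis)
  R <- rotation_matrix(th)
  R %*% diag(c(exp(1i * phi / 2), exp(-1i * phi / 2))) %*% rotation_matrix(-th)
}

#' Jones matrix of the illumination quarter-wave plate
#'
#' @param axis plate axis in degrees (default 45, producing circular
#'   polarization from horizontal input).
#' @export
jones_qwp <- function(axis = 45) jones_retarder(90, axis)

# inverse of a unitary Jones matrix
jones_inverse <- function(J) Conj(t(J))

# || J J^H - I ||_max, used by unitarity checks
unitarity_error <- function(J) max(Mod(J %*% Conj(t(J)) - diag(2)))

#' Decompose a unitary Jones matrix into retarder parameters
#'
#' Any 2x2 unitary is, up to a global phase, a linear retarder. Returns the
#' canonical parameters with retardance in `[0, 180]` degrees and axis in
#' `(-90, 90]` degrees.
#'
#' @param J complex 2x2 unitary matrix.
#' @return list with `retardance` and `axis` (degrees) and `phase`
#'   (the removed global phase, radians).
#' @export
jones_to_retarder <- function(J) {
  stopifnot(unitarity_error(J) < 1e-6)
  detJ <- J[1, 1] * J[2, 2] - J[1, 2] * J[2, 1]
  g <- sqrt(detJ)                 # global phase, sign ambiguous
  U <- J / g
  # U = [[cos + i sin cos2t, i sin sin2t], [i sin sin2t, cos - i sin cos2t]]
  cph <- Re(U[1, 1] + U[2, 2]) / 2
  s1 <- Im(U[1, 1] - U[2, 2]) / 2   # sin(phi/2) cos(2 theta)
  s2 <- Im(U[1, 2] + U[2, 1]) / 2   # sin(phi/2) sin(2 theta)
  sph <- sqrt(s1^2 + s2^2)
  if (cph < 0) { cph <- -cph; s1 <- -s1; s2 <- -s2; g <- -g }  # phi <= 180
  phi <- atan2(sph, cph) * 2
  theta <- if (sph > 1e-12) atan2(s2, s1) / 2 else 0
  list(retardance = rad2deg(phi),
       axis = wrap_orientation(rad2deg(theta)),
       phase = Arg(g))
}

# Closed-form double-pass sample response under circular illumination.
# Vectorized over one-way sample retardance delta (degrees) and axis theta
# (degrees); returns list(co, cross) complex amplitudes BEFORE the system
# confound. co/cross naming per detector convention above.
sample_response <- function(delta_deg, theta_deg) {
  Q <- jones_qwp()
  v0 <- Q %*% c(1, 0)             # circular state on the sample
  phi <- deg2rad(2 * delta_deg)   # double pass
  th <- deg2rad(theta_deg)
  cph <- cos(phi / 2); sph <- sin(phi / 2)
  J11 <- cph + 1i * sph * cos(2 * th)
  J22 <- cph - 1i * sph * cos(2 * th)
  J12 <- 1i * sph * sin(2 * th)
  w1 <- J11 * v0[1] + J12 * v0[2]
  w2 <- J12 * v0[1] + J22 * v0[2]
  eH <- Q[1, 1] * w1 + Q[1, 2] * w2
  eV <- Q[2, 1] * w1 + Q[2, 2] * w2
  list(co = eV, cross = eH)
}
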