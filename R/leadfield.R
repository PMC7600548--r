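#' Lead field of a current dipole in a homogeneous sphere
#'
#' Computes the average-referenced electrode potentials produced by a point
#' current dipole inside a homogeneous conducting sphere, using the
#' closed-form solution of the interior Neumann problem.  Writing
#' \eqn{x = b/R} for the dipole eccentricity, \eqn{c = \cos\gamma} for the
#' cosine of the angle between dipole position and electrode, and
#' \eqn{F = \sqrt{1 - 2xc + x^2}}, the surface potential separates into a
#' radial-moment and a tangential-moment kernel obtained by summing the
#' Legendre expansion \eqn{\sum_n \frac{2n+1}{n} x^{n-1} [\,n m_r P_n(c) +
#' m_t \cos\phi\, P_n^1(c)\,]} in closed form via the generating function of
#' the Legendre polynomials.
#'
#' The potential is linear in the moment and is returned re-referenced to
#' the channel average, matching the reference used throughout the analysis
#' chain.
#'
#' @param model a `head_model`.
#' @param location dipole location, 3-vector in mm, strictly inside the
#'   sphere.
#' @param moment dipole moment, 3-vector (arbitrary units; potentials are
#'   proportional).
#' @return numeric vector of average-referenced potentials, one per channel.
#' @examples
#' hm <- make_head_model(16)
#' v <- lead_field(hm, c(0, 0, 50), c(1, 0, 0))
#' max(abs(mean(v)))  # average reference
#' @export
lead_field <- function(model, location, moment) {
  stopifnot(inherits(model, "head_model"))
  location <- as.numeric(location)
  moment <- as.numeric(moment)
  if (length(location) != 3L || any(!is.finite(location))) {
    stop_invalid("`location` must be a finite 3-vector")
  }
  if (length(moment) != 3L || any(!is.finite(moment))) {
    stop_invalid("`moment` must be a finite 3-vector")
  }
  b <- sqrt(sum(location^2))
  if (b >= model$radius) {
    stop_invalid("dipole location (radius %.2f mm) must be strictly inside the sphere (radius %.2f mm)",
                 b, model$radius)
  }
  v <- dipole_potential(model$positions, model$radius, model$sigma,
                        location, moment)
  v - mean(v)
}

# Raw (pre-average-reference) surface potential; elec_unit is n x 3 unit
# vectors on the sphere of radius R.
dipole_potential <- function(elec_unit, R, sigma, location, moment) {
  b <- sqrt(sum(location^2))
  scale <- 1 / (4 * pi * sigma * R^2 * 1e-6)  # mm^2 -> m^2 in the prefactor
  if (b < 1e-9) {
    # central dipole: only the n = 1 term survives, with gain 3
    return(as.numeric(3 * (elec_unit %*% moment)) * scale / 1)
  }
  r0 <- location / b
  x <- b / R
  c_ <- as.numeric(elec_unit %*% r0)
  c_ <- pmin(1, pmax(-1, c_))
  m_r <- sum(moment * r0)
  # tangential projection onto the electrode direction: m_t cos(phi) sin(gamma)
  m_tang <- as.numeric(elec_unit %*% moment) - c_ * m_r

  F_ <- sqrt(pmax(1 - 2 * x * c_ + x^2, 1e-300))
  S_rad <- (2 * x * (c_ - x) / F_^3 + 1 / F_ - 1) / x
  S_tan <- 2 / F_^3 + (F_ + 1) / (F_ * (1 - x * c_ + F_))
  (m_r * S_rad + m_tang * S_tan) * scale
}

#' Lead-field basis for the three Cartesian unit moments
#'
#' @param model a `head_model`.
#' @param location 3-vector in mm.
#' @return channels x 3 matrix; column j is the average-referenced
#'   potential of a unit moment along axis j.
#' @keywords internal
lead_field_basis <- function(model, location) {
  b <- sqrt(sum(location^2))
  elec <- model$positions
  R <- model$radius
  scale <- 1 / (4 * pi * model$sigma * R^2 * 1e-6)
  G <- if (b < 1e-9) {
    3 * elec * scale
  } else {
    # shared geometry for the three unit moments
    r0 <- location / b
    x <- b / R
    c_ <- pmin(1, pmax(-1, as.numeric(elec %*% r0)))
    F_ <- sqrt(pmax(1 - 2 * x * c_ + x^2, 1e-300))
    S_rad <- (2 * x * (c_ - x) / F_^3 + 1 / F_ - 1) / x
    S_tan <- 2 / F_^3 + (F_ + 1) / (F_ * (1 - x * c_ + F_))
    # column j: m = e_j; m_r = r0[j], tangential term = elec[, j] - c_ * r0[j]
    out <- matrix(0, nrow(elec), 3L)
    for (j in 1:3) {
      out[, j] <- (r0[j] * S_rad + (elec[, j] - c_ * r0[j]) * S_tan) * scale
    }
    out
  }
  sweep(G, 2L, colMeans(G), "-")
}
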