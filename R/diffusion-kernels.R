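#' Stokes-Einstein diffusivity
#'
#' \eqn{D = k T / (6 \pi \eta r)} for a spherical solute of hydrodynamic
#' radius `r_mol` in a fluid of viscosity `eta` at temperature `T_K`.
#'
#' @param T_K temperature (K).
#' @param eta dynamic viscosity (Pa s).
#' @param r_mol hydrodynamic radius (m).
#' @return diffusivity (m2/s).
#' @examples
#' stokes_einstein(293, 1e-3, 4e-10)  # ~5.4e-10 m2/s
#' @export
stokes_einstein <- function(T_K, eta, r_mol) {
  if (any(T_K <= 0) || any(eta <= 0) || any(r_mol <= 0))
    stop("stokes_einstein: all inputs must be strictly positive")
  boltzmann_constant * T_K / (6 * pi * eta * r_mol)
}

#' Diffusive length scale
#'
#' \eqn{\sqrt{D t}}: the distance a solute spreads by diffusion in time `t`.
#' Over a 30-minute trial a small molecule travels about a millimetre.
#'
#' @param D diffusivity (m2/s).
#' @param t elapsed time (s), may be a vector; `t = 0` gives 0.
#' @return length (m).
#' @examples
#' diffusion_length(5e-10, 1800) * 1e3  # ~0.95 mm
#' @export
diffusion_length <- function(D, t) {
  if (any(D <= 0)) stop("diffusion_length: D must be positive")
  if (any(t < 0)) stop("diffusion_length: t must be non-negative")
  sqrt(D * t)
}

# Gaussian width of the heat kernel at time t: s = sqrt(4 D t); the kernel is
# exp(-r^2/s^2) / (pi^(3/2) s^3), equivalently dM / (4 pi D t)^(3/2) * exp().
.kernel_width <- function(D, t) sqrt(4 * D * t)

# Error function via the fast C normal CDF.
.erf <- function(x) 2 * stats::pnorm(x * sqrt(2)) - 1

#' Free-space point-source solution (no interface)
#'
#' Concentration at `probe`, time `t`, from `dM` moles released instantly at
#' `source` when the sand/water interface imposes no boundary condition
#' (perfectly still water): the standard free-space heat kernel
#' \deqn{c = \frac{dM}{8(\pi D t)^{3/2}} e^{-r^2/(4Dt)},}
#' with \eqn{r} the source-probe distance.
#'
#' @param dM released moles (mol).
#' @param source,probe points (length-3 vectors or n x 3 matrices /
#'   data.frames with columns x, y, z); `probe` may hold many points.
#' @param D diffusivity (m2/s).
#' @param t time since release (s), strictly positive (the kernel is singular
#'   at t = 0; the initial condition is handled by [capsule_concentration()]).
#' @return concentration (mol/m3), one value per probe row.
#' @export
point_source_free <- function(dM, source, probe, D, t) {
  .check_kernel_args(dM, D, t)
  src <- .as_probe_matrix(source)
  P <- .as_probe_matrix(probe)
  s2 <- 4 * D * t
  r2 <- (P[, 1] - src[1, 1])^2 + (P[, 2] - src[1, 2])^2 +
        (P[, 3] - src[1, 3])^2
  dM / (pi * s2)^1.5 * exp(-r2 / s2)
}

#' Absorbing-interface (Dirichlet) point-source solution
#'
#' Concentration from a point release at `source` (in the sand half-space,
#' z >= 0) when fast water flow above the sand holds the interface at zero
#' concentration. Built by the method of images: the free kernel minus a
#' mirrored negative source at \eqn{-z_s}:
#' \deqn{c = \frac{dM}{8(\pi D t)^{3/2}}
#'       \left(e^{-r^2/(4Dt)} - e^{-\rho^2/(4Dt)}\right),}
#' with \eqn{\rho^2 = (x-x_s)^2 + (y-y_s)^2 + (-z-z_s)^2}. The solution is
#' identically zero on the interface z = 0.
#'
#' @inheritParams point_source_free
#' @return concentration (mol/m3), one value per probe row.
#' @export
point_source_dirichlet <- function(dM, source, probe, D, t) {
  .check_kernel_args(dM, D, t)
  src <- .as_probe_matrix(source)
  if (src[1, 3] < 0)
    stop("point_source_dirichlet: source must lie in sand (z >= 0)")
  P <- .as_probe_matrix(probe)
  s2 <- 4 * D * t
  h2 <- (P[, 1] - src[1, 1])^2 + (P[, 2] - src[1, 2])^2
  dz2 <- (P[, 3] - src[1, 3])^2
  dz2_img <- (P[, 3] + src[1, 3])^2
  dM / (pi * s2)^1.5 * exp(-h2 / s2) * (exp(-dz2 / s2) - exp(-dz2_img / s2))
}

.check_kernel_args <- function(dM, D, t) {
  if (length(t) != 1L || t <= 0)
    stop("point-source kernels require a single t > 0")
  if (dM < 0) stop("dM must be non-negative")
  if (D <= 0) stop("D must be positive")
  invisible(TRUE)
}
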