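#' Physical parameters of the buried-capsule diffusion model
#'
#' Bundles every quantity the diffusion model needs, in strict SI units
#' (lengths m, time s, concentrations mol/m3; note 1 mM = 1 mol/m3).
#' The capsule is a prolate ellipsoid lying flat in the sand with its long
#' axis horizontal; `depth_l` is the depth of the capsule *center* below the
#' sand/water interface (z = 0, z increasing downward into sand).
#'
#' If `D` is omitted it is derived from `T_K`, `eta` and `r_mol` via
#' [stokes_einstein()]; if `r_mol` is omitted it is back-computed from `D` so
#' the stored set is self-consistent. If `V` is omitted it is the geometric
#' ellipsoid volume \eqn{(\pi/6)\,a_{major}a_{minor}^2}. When `V` is supplied
#' it is authoritative for the total moles \eqn{M = c_0 V}; a supplied `V`
#' differing from the geometric volume by more than 1% is accepted (the
#' source density becomes \eqn{M/V_{geom}}) but flagged in `print()`.
#'
#' @param D diffusivity (m2/s), default 1e-9 (small amino-acid-like solutes).
#' @param T_K temperature (K).
#' @param eta dynamic viscosity of water (Pa s).
#' @param r_mol molecular hydrodynamic radius (m); derived from `D` if `NULL`.
#' @param c0 capsule molar concentration (mol/m3); default 100 (= 100 mM).
#' @param V capsule volume (m3) used for total moles; default 1e-6 (= 1 mL).
#' @param a_major,a_minor full ellipsoid axis lengths (m); defaults
#'   16 mm and 6.3 mm.
#' @param depth_l burial depth of the capsule center (m); default 5 mm.
#' @param c_star sensory detection threshold (mol/m3); default 0.01
#'   (= 10 uM, the permissive end of the 10-100 uM range).
#' @param t_max trial duration (s); default 1800 (30 min).
#' @param layer_depth depth of the surface sand layer sampled by the legs
#'   (m); default 0.5 mm.
#' @return an object of class `physical_params` (a validated list).
#' @examples
#' p <- physical_params()
#' p$D
#' @export
physical_params <- function(D = 1e-9, T_K = 293, eta = 1.0e-3, r_mol = NULL,
                            c0 = 100, V = 1e-6,
                            a_major = 16e-3, a_minor = 6.3e-3,
                            depth_l = 5e-3, c_star = 0.01,
                            t_max = 1800, layer_depth = 0.5e-3) {
  if (is.null(D)) {
    if (is.null(r_mol)) stop("supply either `D` or `r_mol`")
    D <- stokes_einstein(T_K, eta, r_mol)
  }
  if (is.null(r_mol)) r_mol <- boltzmann_constant * T_K / (6 * pi * eta * D)
  v_geom <- (pi / 6) * a_major * a_minor^2
  if (is.null(V)) V <- v_geom
  p <- list(D = D, T_K = T_K, eta = eta, r_mol = r_mol, c0 = c0, V = V,
            a_major = a_major, a_minor = a_minor, depth_l = depth_l,
            c_star = c_star, t_max = t_max, layer_depth = layer_depth,
            v_geom = v_geom)
  for (f in c("D", "T_K", "eta", "r_mol", "c0", "V", "a_major", "a_minor",
              "depth_l", "c_star", "t_max", "layer_depth")) {
    if (!is.numeric(p[[f]]) || length(p[[f]]) != 1L || !is.finite(p[[f]]) ||
        p[[f]] <= 0)
      stop("physical_params: field `", f, "` must be a single positive number")
  }
  if (a_minor > a_major)
    stop("physical_params: `a_minor` exceeds `a_major` (prolate ellipsoid)")
  if (depth_l <= a_minor / 2)
    warning("capsule center depth_l <= a_minor/2: the capsule breaks the ",
            "sand surface; free-interface interpretation assumes full burial")
  class(p) <- "physical_params"
  p
}

#' @export
print.physical_params <- function(x, ...) {
  cat("Buried-capsule diffusion parameters (SI)\n")
  cat(sprintf("  D        = %.3g m2/s   (T = %g K, eta = %.3g Pa s, r = %.3g m)\n",
              x$D, x$T_K, x$eta, x$r_mol))
  cat(sprintf("  capsule  : %g x %g mm prolate ellipsoid, center %g mm deep\n",
              x$a_major * 1e3, x$a_minor * 1e3, x$depth_l * 1e3))
  cat(sprintf("  c0 = %g mol/m3, V = %.3g mL (geometric %.3g mL) => M = %.3g mol\n",
              x$c0, x$V * 1e6, x$v_geom * 1e6, x$c0 * x$V))
  if (abs(x$V - x$v_geom) > 0.01 * x$v_geom)
    cat("  note: V differs from geometric volume; source density is M/V_geom\n")
  cat(sprintf("  c* = %g mol/m3, t_max = %g s, surface layer = %g mm\n",
              x$c_star, x$t_max, x$layer_depth * 1e3))
  invisible(x)
}

#' Construct a spatial point (m)
#'
#' Coordinate convention: z = 0 is the sand/water interface, z > 0 is sand
#' (downward), z < 0 is water.
#'
#' @param x,y,z coordinates in m.
#' @return a named numeric vector of length 3.
#' @export
spatial_point <- function(x, y, z) {
  v <- c(x = x, y = y, z = z)
  if (!all(is.finite(v))) stop("spatial_point: coordinates must be finite")
  v
}

# Coerce probe input (vector of length 3, matrix, or data.frame with x,y,z)
# to an n x 3 matrix.
.as_probe_matrix <- function(probe) {
  if (is.data.frame(probe)) probe <- as.matrix(probe[, c("x", "y", "z")])
  if (is.null(dim(probe))) {
    if (length(probe) != 3L) stop("probe must have x, y, z coordinates")
    probe <- matrix(probe, nrow = 1L)
  }
  if (ncol(probe) != 3L) stop("probe matrix must have 3 columns (x, y, z)")
  storage.mode(probe) <- "double"
  probe
}
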