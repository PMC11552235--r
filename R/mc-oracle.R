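# Brute-force Brownian random-walk oracle for the quadrature solution.
# Particles carry equal mole weights; the Dirichlet interface is realized by
# killing particles that step into the water half-space (z < 0). Discrete-dt
# killing under-counts absorption by O(sqrt(D dt)) ~ 0.03 mm at dt = 1 s,
# negligible against the 0.5 mm sampling layer.

#' Initialize a particle ensemble inside the capsule
#'
#' Particles are placed uniformly in the prolate ellipsoid by rejection
#' sampling; each carries `c0 * V / n_particles` moles so the ensemble holds
#' exactly the capsule's total moles.
#'
#' @param params a [physical_params()] object.
#' @param n_particles number of particles (>= 1000).
#' @param seed integer RNG seed (stored with the ensemble).
#' @return a `particle_ensemble`: positions (n x 3, m), per-particle weight
#'   (mol), alive flags, elapsed time and the seed.
#' @export
init_particles <- function(params, n_particles, seed) {
  stopifnot(inherits(params, "physical_params"))
  if (n_particles < 1000)
    stop("init_particles: need at least 1000 particles")
  set.seed(as.integer(seed))
  A <- params$a_major / 2
  B <- params$a_minor / 2
  pos <- matrix(NA_real_, nrow = 0L, ncol = 3L)
  while (nrow(pos) < n_particles) {
    m <- ceiling((n_particles - nrow(pos)) / 0.5)
    u <- matrix(runif(3L * m, -1, 1), ncol = 3L)
    keep <- rowSums(u^2) <= 1
    pos <- rbind(pos, u[keep, , drop = FALSE])
  }
  pos <- pos[seq_len(n_particles), , drop = FALSE]
  pos[, 1] <- A * pos[, 1]
  pos[, 2] <- B * pos[, 2]
  pos[, 3] <- params$depth_l + B * pos[, 3]
  structure(list(positions = pos,
                 weight = params$c0 * params$V / n_particles,
                 alive = rep(TRUE, n_particles),
                 n0 = n_particles, time = 0, seed = as.integer(seed)),
            class = "particle_ensemble")
}

#' Initialize all particles at a single point
#'
#' Point-release ensemble, for checking the oracle against the closed-form
#' point-source kernels.
#'
#' @param source length-3 point (m); must lie in sand (z >= 0) if the
#'   ensemble will be stepped under the Dirichlet scenario.
#' @param dM total released moles.
#' @inheritParams init_particles
#' @return a `particle_ensemble`.
#' @export
init_particles_point <- function(source, dM, n_particles, seed) {
  if (n_particles < 1000)
    stop("init_particles_point: need at least 1000 particles")
  set.seed(as.integer(seed))
  src <- .as_probe_matrix(source)
  structure(list(positions = matrix(rep(src[1, ], each = n_particles),
                                    ncol = 3L),
                 weight = dM / n_particles,
                 alive = rep(TRUE, n_particles),
                 n0 = n_particles, time = 0, seed = as.integer(seed)),
            class = "particle_ensemble")
}

#' Advance an ensemble by one Brownian step
#'
#' Adds independent Gaussian displacements of per-axis variance `2 D dt`.
#' Under `"dirichlet"`, particles ending the step in water (z < 0) are killed
#' (absorbed by the flowing water); under `"free_interface"` the interface
#' has no effect.
#'
#' @param ensemble a `particle_ensemble`.
#' @param D diffusivity (m2/s).
#' @param dt time step (s), > 0.
#' @param scenario boundary scenario.
#' @return the advanced `particle_ensemble`.
#' @export
step_particles <- function(ensemble, D, dt,
                           scenario = c("free_interface", "dirichlet")) {
  scenario <- match.arg(scenario)
  if (dt <= 0) stop("step_particles: dt must be positive")
  idx <- which(ensemble$alive)
  m <- length(idx)
  if (m) {
    ensemble$positions[idx, ] <- ensemble$positions[idx, , drop = FALSE] +
      matrix(rnorm(3L * m, sd = sqrt(2 * D * dt)), ncol = 3L)
    if (scenario == "dirichlet")
      ensemble$alive[idx] <- ensemble$positions[idx, 3] >= 0
  }
  ensemble$time <- ensemble$time + dt
  ensemble
}

#' Run the random walk to given times
#'
#' Steps the ensemble with fixed `dt` and returns snapshots (copies of the
#' ensemble) at each requested time, which must be multiples of `dt`.
#'
#' @inheritParams step_particles
#' @param times increasing snapshot times (s).
#' @param dt time step (s).
#' @return a list of `particle_ensemble` snapshots, one per time.
#' @export
simulate_particles <- function(ensemble, D, times, dt = 1,
                               scenario = c("free_interface", "dirichlet")) {
  scenario <- match.arg(scenario)
  if (is.unsorted(times, strictly = TRUE) || any(times <= ensemble$time))
    stop("simulate_particles: times must be increasing and after `time`")
  if (any(abs(times / dt - round(times / dt)) > 1e-9))
    stop("simulate_particles: times must be multiples of dt")
  out <- vector("list", length(times))
  for (k in seq_along(times)) {
    nstep <- round((times[k] - ensemble$time) / dt)
    for (i in seq_len(nstep))
      ensemble <- step_particles(ensemble, D, dt, scenario)
    out[[k]] <- ensemble
  }
  out
}

#' Binned concentration estimate from an ensemble
#'
#' Counts alive particles in each axis-aligned box and converts to molar
#' concentration; the standard error comes from binomial counting statistics
#' over the initial particle number.
#'
#' @param ensemble a `particle_ensemble`.
#' @param probe_boxes data.frame with columns `xmin, xmax, ymin, ymax, zmin,
#'   zmax` (m); boxes are assumed disjoint.
#' @return data.frame with box centers, counts, concentration `c` (mol/m3)
#'   and its standard error `se`.
#' @export
density_estimate <- function(ensemble, probe_boxes) {
  if (!nrow(probe_boxes)) stop("density_estimate: empty box list")
  pos <- ensemble$positions[ensemble$alive, , drop = FALSE]
  n0 <- ensemble$n0
  out <- probe_boxes
  out$count <- vapply(seq_len(nrow(probe_boxes)), function(i) {
    b <- probe_boxes[i, ]
    sum(pos[, 1] >= b$xmin & pos[, 1] < b$xmax &
        pos[, 2] >= b$ymin & pos[, 2] < b$ymax &
        pos[, 3] >= b$zmin & pos[, 3] < b$zmax)
  }, numeric(1))
  vol <- (probe_boxes$xmax - probe_boxes$xmin) *
         (probe_boxes$ymax - probe_boxes$ymin) *
         (probe_boxes$zmax - probe_boxes$zmin)
  p <- out$count / n0
  out$x <- (probe_boxes$xmin + probe_boxes$xmax) / 2
  out$y <- (probe_boxes$ymin + probe_boxes$ymax) / 2
  out$z <- (probe_boxes$zmin + probe_boxes$zmax) / 2
  out$c <- out$count * ensemble$weight / vol
  out$se <- ensemble$weight * sqrt(n0 * p * (1 - p)) / vol
  out
}

#' Total alive mass of an ensemble
#' @param ensemble a `particle_ensemble`.
#' @return moles (mol).
#' @export
ensemble_mass <- function(ensemble) sum(ensemble$alive) * ensemble$weight

#' @export
print.particle_ensemble <- function(x, ...) {
  cat(sprintf("particle_ensemble: %d/%d alive at t = %g s (seed %d)\n",
              sum(x$alive), x$n0, x$time, x$seed))
  cat(sprintf("  alive mass %.4g mol\n", ensemble_mass(x)))
  invisible(x)
}
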