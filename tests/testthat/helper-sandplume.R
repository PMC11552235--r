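# Shared fixtures, built in code.

# The betaine-capsule experimental conditions (100 mM, 1 mL, 6.3 x 16 mm),
# shallow burial, amino-acid diffusivity, 10 uM threshold.
betaine_params <- function(c0 = 100) {
  physical_params(D = 1e-9, c0 = c0, V = 1e-6, a_major = 16e-3,
                  a_minor = 6.3e-3, depth_l = 5e-3, c_star = 0.01,
                  t_max = 1800, layer_depth = 0.5e-3)
}

# A deterministic envelope-only trace: |signal| follows `shape(t)` exactly.
envelope_trace <- function(shape, duration = 60, fs = 2000, onset = 15,
                           offset = 35, label = "stim") {
  tt <- seq(0, duration - 1 / fs, by = 1 / fs)
  nerve_trace(shape(tt), fs,
              stimuli = data.frame(label = label, onset = onset,
                                   offset = offset))
}

# Independent image-method evaluation used as the oracle for the Dirichlet
# kernel (kept deliberately separate from the package implementation).
oracle_dirichlet <- function(dM, src, probe, D, t) {
  r2 <- sum((probe - src)^2)
  rho2 <- (probe[1] - src[1])^2 + (probe[2] - src[2])^2 +
    (-probe[3] - src[3])^2
  dM / (8 * (pi * D * t)^1.5) * (exp(-r2 / (4 * D * t)) -
                                   exp(-rho2 / (4 * D * t)))
}
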