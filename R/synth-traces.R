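# Seeded generators for synthetic extracellular recordings. Synthesis is
# spike-based (Gaussian baseline noise plus inhomogeneous-Poisson multi-unit
# spikes with biphasic 2 ms waveforms) so the rectify-and-filter
# quantification path is genuinely exercised, not just the integration step.

#' Species sensory profile
#'
#' Detection thresholds and response kinetics per compound for a species'
#' legs. The two default profiles encode the digging / non-digging contrast:
#' the digging species detects L-amino acids at 1e-4 M (0.1 mol/m3), the
#' non-digging species only at 1e-2 M (10 mol/m3) - a 100-fold sensitivity
#' difference - while both respond to betaine; tastants drive fast transient
#' responses and TRP-channel agonists slow sustained ones.
#'
#' @param name species label.
#' @param threshold_map named numeric: compound -> half-activation dose
#'   (mol/m3) of the Hill response gain.
#' @param kinetics_map named character: compound -> `"fast_transient"` or
#'   `"slow_sustained"`.
#' @return a `species_profile` object.
#' @export
species_profile <- function(name, threshold_map, kinetics_map) {
  if (!length(threshold_map) || !length(kinetics_map))
    stop("species_profile: maps must be non-empty")
  if (any(threshold_map <= 0))
    stop("species_profile: thresholds must be positive")
  stopifnot(all(kinetics_map %in% c("fast_transient", "slow_sustained")))
  structure(list(name = name, threshold_map = threshold_map,
                 kinetics_map = kinetics_map),
            class = "species_profile")
}

#' @rdname species_profile
#' @export
digging_profile <- function() {
  species_profile("digging",
    threshold_map = c(l_amino_acids = 0.1, betaine = 0.1, carvacrol = 1),
    kinetics_map = c(l_amino_acids = "fast_transient",
                     betaine = "fast_transient",
                     carvacrol = "slow_sustained"))
}

#' @rdname species_profile
#' @export
nondigging_profile <- function() {
  species_profile("nondigging",
    threshold_map = c(l_amino_acids = 10, betaine = 0.1, carvacrol = 1),
    kinetics_map = c(l_amino_acids = "fast_transient",
                     betaine = "fast_transient",
                     carvacrol = "slow_sustained"))
}

#' @export
print.species_profile <- function(x, ...) {
  cat(sprintf("species_profile '%s'\n", x$name))
  for (cmp in names(x$threshold_map))
    cat(sprintf("  %-15s threshold %g mol/m3, kinetics %s\n", cmp,
                x$threshold_map[[cmp]],
                if (cmp %in% names(x$kinetics_map)) x$kinetics_map[[cmp]]
                else "fast_transient"))
  invisible(x)
}

# Kinetics envelopes (peak-normalized), tau in s relative to stimulus onset.
.kin_envelope <- function(kin, t_rel, offset_rel) {
  if (kin == "fast_transient") {
    # alpha-type: 1 s rise, 3 s decay
    e <- (exp(-t_rel / 3) - exp(-t_rel / 1))
    e[t_rel < 0] <- 0
    e / (exp(-1.648 / 3) - exp(-1.648))   # peak at t* = 1.5 log 3
  } else {
    # sigmoid rise (half-rise 10 s, width 5 s) to a plateau during the
    # stimulus, then a slow (60 s) decay after offset
    e <- 1 / (1 + exp(-(pmin(t_rel, offset_rel) - 10) / 5))
    e <- ifelse(t_rel > offset_rel, e * exp(-(t_rel - offset_rel) / 60), e)
    e[t_rel < 0] <- 0
    e
  }
}

# SD of the filtered rectified envelope of pure Gaussian noise of unit SD.
.envelope_noise_sd <- function(fs, f3db = 25) {
  sig_samp <- sqrt(log(2)) / (2 * pi * f3db) * fs
  K <- ceiling(6 * sig_samp)
  kern <- dnorm(seq(-K, K), sd = sig_samp)
  kern <- kern / sum(kern)
  sqrt(1 - 2 / pi) * sqrt(sum(kern^2))
}

#' Generate a synthetic nerve trace
#'
#' Gaussian baseline noise plus inhomogeneous-Poisson multi-unit spiking.
#' The firing rate is a spontaneous baseline plus a compound-specific term:
#' a saturating Hill dose gain (coefficient 4, half-activation at the
#' profile's threshold for the compound) multiplied by the kinetics envelope
#' (fast transient alpha function or slow sustained sigmoid/plateau). Spikes
#' are biphasic 2 ms waveforms with lognormal amplitude jitter. The peak
#' envelope elevation at full gain is `snr` times the baseline-envelope SD.
#' The expected (ground-truth) envelope area over the quantification window
#' is stored in `meta$truth_area`.
#'
#' @param profile a [species_profile()].
#' @param compound compound label; a compound absent from the profile's
#'   threshold map evokes no response (noise-only trace).
#' @param dose dose (mol/m3), >= 0; 0 gives a blank trace.
#' @param duration trace length (s), >= 60.
#' @param fs sampling rate (Hz), >= 1000.
#' @param snr full-gain peak envelope elevation over baseline-envelope SD.
#' @param seed integer RNG seed.
#' @param onset,offset stimulus window (s).
#' @param tail quantification tail after offset (s), used for the stored
#'   ground-truth area.
#' @return a [nerve_trace()] with generator metadata.
#' @export
gen_trace <- function(profile, compound, dose, duration = 60, fs = 5000,
                      snr = 10, seed = 1L, onset = 15, offset = 35,
                      tail = 20) {
  stopifnot(inherits(profile, "species_profile"))
  if (dose < 0) stop("gen_trace: dose must be non-negative")
  if (fs < 1000) stop("gen_trace: fs must be at least 1000 Hz")
  if (duration < 60) stop("gen_trace: duration must be at least 60 s")
  set.seed(as.integer(seed))
  L <- round(duration * fs)
  sigma_n <- 1e-5                       # 10 uV baseline noise
  sd_env <- sigma_n * .envelope_noise_sd(fs)
  spike_amp <- 5 * sigma_n              # 50 uV biphasic units
  wave <- spike_amp * sin(2 * pi * seq_len(round(0.002 * fs)) /
                            round(0.002 * fs))
  # expected rectified-area elevation per spike: E|noise + w| - E|noise| per
  # waveform sample (rectification is not additive), averaged over the
  # lognormal amplitude jitter with a 5-point Gauss-Hermite rule
  e_abs <- function(mu, s) s * sqrt(2 / pi) * exp(-mu^2 / (2 * s^2)) +
    mu * (1 - 2 * stats::pnorm(-mu / s))
  gh <- pracma::gaussHermite(5)
  l1_spike <- sum(gh$w / sqrt(pi) * vapply(gh$x, function(x) {
    a <- exp(0.2 * sqrt(2) * x)
    sum(e_abs(abs(a * wave), sigma_n) - e_abs(0, sigma_n)) / fs
  }, numeric(1)))
  gain <- 0
  kin <- "fast_transient"
  if (compound %in% names(profile$threshold_map) && dose > 0) {
    K <- profile$threshold_map[[compound]]
    gain <- dose^4 / (dose^4 + K^4)
    if (compound %in% names(profile$kinetics_map))
      kin <- profile$kinetics_map[[compound]]
  }
  r0 <- 10                              # spontaneous multi-unit rate (Hz)
  r_peak <- snr * sd_env / l1_spike     # rate at full gain
  tt <- (seq_len(L) - 1L) / fs
  shape <- .kin_envelope(kin, tt - onset, offset - onset)
  rate <- r0 + r_peak * gain * shape
  x <- rnorm(L, sd = sigma_n)
  spikes <- which(runif(L) < rate / fs)
  if (length(spikes)) {
    amps <- exp(rnorm(length(spikes), sd = 0.2))
    for (j in seq_along(spikes)) {
      i0 <- spikes[j]
      i1 <- min(L, i0 + length(wave) - 1L)
      x[i0:i1] <- x[i0:i1] + amps[j] * wave[seq_len(i1 - i0 + 1L)]
    }
  }
  win <- tt >= onset & tt <= min(offset + tail, duration)
  truth_area <- r_peak * gain * l1_spike * sum(shape[win]) / fs
  nerve_trace(x, fs,
              stimuli = data.frame(label = compound, onset = onset,
                                   offset = offset),
              species = profile$name,
              meta = list(truth_area = truth_area, gain = gain,
                          kinetics = kin, dose = dose, snr = snr,
                          seed = as.integer(seed)))
}

#' Generate a synthetic dose-response series
#'
#' Runs [gen_trace()] plus [quantify_response()] for each replicate at each
#' dose (plus zero-dose blanks) and assembles a [dose_response_series()].
#' The default doses are 7 half-decade steps from 10 uM to 10 mM
#' (0.01-10 mol/m3), a grid that contains both species' nominal L-amino-acid
#' thresholds.
#'
#' @inheritParams gen_trace
#' @param doses ascending doses (mol/m3).
#' @param n_reps replicates per dose (default 4 legs).
#' @param ... further arguments passed to [gen_trace()].
#' @return a [dose_response_series()]; per-replicate ground-truth areas are
#'   kept in `attr(, "truth")`.
#' @export
gen_dose_response <- function(profile, compound = "l_amino_acids",
                              doses = 10^seq(-2, 1, by = 0.5), n_reps = 4,
                              seed = 1L, ...) {
  stopifnot(inherits(profile, "species_profile"))
  if (is.unsorted(doses, strictly = TRUE))
    stop("gen_dose_response: doses must be ascending")
  set.seed(as.integer(seed))
  sub_seeds <- sample.int(.Machine$integer.max - 1L,
                          (length(doses) + 1L) * n_reps)
  k <- 0L
  run_rep <- function(dose) {
    vapply(seq_len(n_reps), function(i) {
      k <<- k + 1L
      tr <- gen_trace(profile, compound, dose, seed = sub_seeds[k], ...)
      quantify_response(tr, compound)$area
    }, numeric(1))
  }
  blanks <- run_rep(0)
  responses <- lapply(doses, run_rep)
  out <- dose_response_series(compound, profile$name, doses, responses,
                              blanks)
  attr(out, "truth") <- list(seed = as.integer(seed), n_reps = n_reps)
  out
}
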