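#' Quantify a stimulus response from a nerve recording
#'
#' Implements the standard extracellular quantification recipe: the rectified
#' signal is low-pass filtered ([envelope()]), the mean envelope over a
#' pre-stimulus window is subtracted as baseline, negative excursions are
#' clipped at zero, and the response amplitude is integrated (trapezoid rule)
#' over the response window (stimulus onset to offset plus a configurable
#' tail that captures slow kinetics). Blank stimuli are measured over the
#' same window length. The decay fraction is the mean clipped envelope over
#' the final stretch of the window (last 5% or 2 s, whichever is longer)
#' divided by the peak, so single-sample noise does not dominate it.
#'
#' @param trace a [nerve_trace()].
#' @param stimulus_label label of the stimulus window to quantify.
#' @param pre_window baseline window length before stimulus onset (s);
#'   at least 5 s of pre-stimulus recording must exist.
#' @param tail response-window extension after stimulus offset (s).
#' @param f3db envelope filter corner (Hz).
#' @return a `response_quant`: stimulus label, baseline level and SD (V),
#'   `area` (V s), `peak` (V), `time_to_peak` (s), `decay_fraction`, and the
#'   kinetics class from [classify_kinetics()].
#' @export
quantify_response <- function(trace, stimulus_label, pre_window = 10,
                              tail = 20, f3db = 25) {
  stopifnot(inherits(trace, "nerve_trace"))
  row <- trace$stimuli[trace$stimuli$label == stimulus_label, , drop = FALSE]
  if (!nrow(row))
    stop("quantify_response: no stimulus labelled '", stimulus_label, "'")
  onset <- row$onset[1L]
  offset <- row$offset[1L]
  if (onset < 5)
    stop("quantify_response: need at least 5 s of pre-stimulus recording")
  pre_window <- min(pre_window, onset)
  fs <- trace$fs
  tt <- (seq_along(trace$samples) - 1L) / fs
  env <- envelope(trace, f3db = f3db)
  pre <- env[tt >= onset - pre_window & tt < onset]
  baseline <- mean(pre)
  baseline_sd <- sd(pre)
  win <- which(tt >= onset & tt <= min(offset + tail, max(tt)))
  resp <- pmax(env[win] - baseline, 0)
  tw <- tt[win]
  area <- pracma::trapz(tw, resp)
  peak <- max(resp)
  # peak location on a 1 s moving average: multi-unit envelopes are shot-noise
  # dominated, so the raw argmax is an unstable estimate of response timing
  half <- max(1L, round(fs / 2))
  n <- length(resp)
  cs <- cumsum(c(0, resp))
  hi <- pmin(n, seq_len(n) + half)
  lo <- pmax(1L, seq_len(n) - half)
  smoothed <- (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
  time_to_peak <- tw[which.max(smoothed)] - onset
  tail_len <- max(2, 0.05 * (max(tw) - min(tw)))
  tail_idx <- tw >= max(tw) - tail_len
  decay_fraction <- if (peak > 0) mean(resp[tail_idx]) / peak else 0
  q <- structure(list(stimulus = stimulus_label, baseline = baseline,
                      baseline_sd = baseline_sd, area = area, peak = peak,
                      time_to_peak = time_to_peak,
                      decay_fraction = decay_fraction,
                      window = c(start = min(tw), end = max(tw)),
                      kinetics_class = NA_character_),
                 class = "response_quant")
  q$kinetics_class <- classify_kinetics(q)
  q
}

#' @export
print.response_quant <- function(x, ...) {
  cat(sprintf("response to '%s': area %.4g V s, peak %.3g V at %.1f s, decay %.2f [%s]\n",
              x$stimulus, x$area, x$peak, x$time_to_peak, x$decay_fraction,
              x$kinetics_class))
  invisible(x)
}

#' Classify response kinetics
#'
#' Distinguishes the fast, transient responses characteristic of tastants
#' from the slow, sustained responses of TRP-channel agonists. A response
#' whose peak does not clear the noise floor (`noise_mult` times the baseline
#' envelope SD) is classed `"none"`. Otherwise it is `"fast_transient"` when
#' the time to peak is at most `tau_fast` *and* the decay fraction is at most
#' `phi_fast`; a late peak (`> tau_fast`) or a sustained tail
#' (`> phi_slow`) makes it `"slow_sustained"`, and the ambiguous middle band
#' of decay fractions is resolved to `"slow_sustained"` as well.
#'
#' @param q a `response_quant`.
#' @param tau_fast time-to-peak bound for fast responses (s).
#' @param phi_fast decay-fraction bound for fast responses.
#' @param phi_slow decay fraction above which a response is sustained.
#' @param noise_mult noise-floor multiple of the baseline SD.
#' @return `"fast_transient"`, `"slow_sustained"` or `"none"`.
#' @export
classify_kinetics <- function(q, tau_fast = 10, phi_fast = 0.3,
                              phi_slow = 0.6, noise_mult = 3) {
  stopifnot(inherits(q, "response_quant"))
  if (!is.finite(q$peak) || q$peak <= noise_mult * q$baseline_sd)
    return("none")
  if (q$time_to_peak <= tau_fast && q$decay_fraction <= phi_fast)
    return("fast_transient")
  "slow_sustained"
}

#' Dose-response series
#'
#' Replicate quantified response areas at ascending doses, with blank
#' (zero-dose) control replicates.
#'
#' @param compound compound label.
#' @param species species label.
#' @param doses ascending doses (mol/m3); at least 2.
#' @param responses list of numeric replicate areas, one element per dose.
#' @param blanks numeric replicate areas at zero dose; at least 1.
#' @return a `dose_response_series` object.
#' @export
dose_response_series <- function(compound, species, doses, responses,
                                 blanks) {
  if (length(doses) < 2L)
    stop("dose_response_series: need at least 2 doses")
  if (length(responses) != length(doses))
    stop("dose_response_series: one replicate vector per dose required")
  if (!length(blanks))
    stop("dose_response_series: need at least 1 blank replicate")
  if (is.unsorted(doses, strictly = TRUE))
    stop("dose_response_series: doses must be strictly ascending")
  structure(list(compound = compound, species = species, doses = doses,
                 responses = responses, blanks = blanks),
            class = "dose_response_series")
}

#' @export
print.dose_response_series <- function(x, ...) {
  cat(sprintf("dose_response_series: %s / %s, %d doses (%g-%g mol/m3), %d blanks\n",
              x$compound, x$species, length(x$doses), min(x$doses),
              max(x$doses), length(x$blanks)))
  invisible(x)
}

#' Detection threshold of a dose-response series
#'
#' A dose is flagged as detected when its mean response area exceeds the
#' blank mean plus three blank standard deviations; the threshold is the
#' lowest detected dose (`NA` if none qualifies). The mean + 3 SD rule is
#' deterministic and scale-free, appropriate for the small replicate numbers
#' (n = 4 legs) of these assays.
#'
#' @param series a [dose_response_series()].
#' @return list with `threshold` (mol/m3 or `NA`), per-dose `detected` flags,
#'   and the detection `criterion` (mol/m3-free area units).
#' @export
estimate_threshold <- function(series) {
  stopifnot(inherits(series, "dose_response_series"))
  if (is.unsorted(series$doses, strictly = TRUE))
    stop("estimate_threshold: doses must be strictly ascending")
  blank_sd <- if (length(series$blanks) > 1L) sd(series$blanks) else 0
  crit <- mean(series$blanks) + 3 * blank_sd
  means <- vapply(series$responses, mean, numeric(1))
  detected <- means > crit
  thr <- if (any(detected)) series$doses[which(detected)[1L]] else NA_real_
  list(threshold = thr, detected = setNames(detected, series$doses),
       criterion = crit, dose_means = setNames(means, series$doses))
}

#' Relative-response heatmap summary
#'
#' Normalizes response areas per leg to that leg's maximal response, then
#' averages across legs, mirroring the way multi-leg chemical screens are
#' summarized: values in [0, 1]. Legs with all-zero areas are excluded with
#' a warning.
#'
#' @param quants data.frame with columns `compound`, `leg`, `area`.
#' @return a `response_heatmap`: `$matrix` (compound x leg, normalized,
#'   `NA` where unmeasured) and `$mean` (per-compound mean across legs).
#' @export
response_heatmap <- function(quants) {
  stopifnot(all(c("compound", "leg", "area") %in% names(quants)))
  if (!nrow(quants)) stop("response_heatmap: empty input")
  legs <- unique(quants$leg)
  zero <- vapply(legs, function(l)
    all(quants$area[quants$leg == l] == 0), logical(1))
  if (any(zero)) {
    warning("response_heatmap: excluding all-zero leg(s): ",
            paste(legs[zero], collapse = ", "))
    quants <- quants[!(quants$leg %in% legs[zero]), , drop = FALSE]
    if (!nrow(quants)) stop("response_heatmap: no non-zero legs left")
  }
  norm <- ave(quants$area, quants$leg, FUN = function(a) a / max(a))
  m <- tapply(norm, list(quants$compound, quants$leg), mean)
  m <- m[unique(quants$compound), , drop = FALSE]
  structure(list(matrix = m, mean = rowMeans(m, na.rm = TRUE)),
            class = "response_heatmap")
}

#' @export
print.response_heatmap <- function(x, ...) {
  cat("response_heatmap (per-leg normalized, mean across legs):\n")
  print(round(x$mean, 3))
  invisible(x)
}
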