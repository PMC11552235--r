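#' Extracellular nerve recording
#'
#' A sampled multi-unit voltage trace with stimulus-window annotations.
#'
#' @param samples signal values (V).
#' @param fs sampling rate (Hz).
#' @param stimuli data.frame with columns `label`, `onset`, `offset` (s);
#'   onsets must be sorted and windows lie within the trace.
#' @param species optional species label.
#' @param meta optional list of metadata (e.g. generator ground truth).
#' @return a `nerve_trace` object.
#' @export
nerve_trace <- function(samples, fs, stimuli = NULL, species = "",
                        meta = list()) {
  if (!is.numeric(fs) || fs <= 0) stop("nerve_trace: fs must be positive")
  samples <- as.numeric(samples)
  dur <- length(samples) / fs
  if (is.null(stimuli))
    stimuli <- data.frame(label = character(), onset = numeric(),
                          offset = numeric())
  stopifnot(all(c("label", "onset", "offset") %in% names(stimuli)))
  if (nrow(stimuli)) {
    if (is.unsorted(stimuli$onset))
      stop("nerve_trace: stimulus onsets must be sorted")
    if (any(stimuli$onset < 0) || any(stimuli$offset > dur) ||
        any(stimuli$offset <= stimuli$onset))
      stop("nerve_trace: stimulus windows must lie within the trace")
  }
  structure(list(samples = samples, fs = fs, stimuli = stimuli,
                 species = species, meta = meta),
            class = "nerve_trace")
}

#' @export
print.nerve_trace <- function(x, ...) {
  cat(sprintf("nerve_trace: %.1f s at %g Hz (%d stimuli)%s\n",
              length(x$samples) / x$fs, x$fs, nrow(x$stimuli),
              if (nzchar(x$species)) paste0(", ", x$species) else ""))
  invisible(x)
}

#' Rectified low-pass envelope of a nerve recording
#'
#' The response-quantification envelope: the absolute value of the signal
#' convolved with a zero-phase Gaussian low-pass filter whose -3 dB frequency
#' is `f3db` (default 25 Hz, giving a time-domain sigma of
#' \eqn{\sqrt{\ln 2}/(2\pi \cdot 25\,\mathrm{Hz}) \approx 5.30} ms). The
#' kernel is normalized to unit sum (unity DC gain) and edges are padded by
#' reflection.
#'
#' @param trace a [nerve_trace()] (or a numeric vector with `fs` supplied).
#' @param f3db -3 dB corner frequency of the Gaussian filter (Hz).
#' @param fs sampling rate (Hz), taken from the trace when omitted.
#' @return numeric envelope, same length as the signal.
#' @export
envelope <- function(trace, f3db = 25, fs = NULL) {
  if (inherits(trace, "nerve_trace")) {
    fs <- trace$fs
    x <- trace$samples
  } else {
    if (is.null(fs)) stop("envelope: supply `fs` for a bare numeric signal")
    x <- as.numeric(trace)
  }
  if (fs < 100) stop("envelope: sampling rate must be at least 100 Hz")
  sigma <- sqrt(log(2)) / (2 * pi * f3db)
  sig_samp <- sigma * fs
  K <- ceiling(6 * sig_samp)
  L <- length(x)
  if (L <= 2L * K)
    stop("envelope: trace shorter than the filter support (6 sigma)")
  kern <- dnorm(seq(-K, K), sd = sig_samp)
  kern <- kern / sum(kern)
  xp <- c(rev(abs(x[seq_len(K)])), abs(x), rev(abs(x[(L - K + 1L):L])))
  n <- length(xp)
  m <- 2L * K + 1L
  N <- nextn(n + m - 1L, 2)
  y <- Re(fft(fft(c(xp, numeric(N - n))) * fft(c(kern, numeric(N - m))),
              inverse = TRUE)) / N
  y[seq_len(L) + 2L * K]
}
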