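# Band-level representation of the speech and masker stimuli: prescription
# gain, long-term speech spectrum, and the spectro-temporally modulated
# speech-shaped-noise masker. Levels are band levels in dB SPL on a
# gammatone-centre grid; no waveform is ever synthesized.

#' Packaged reference tables
#'
#' Small editable tables shipped with the package: `cambridge_intercepts`
#' (frequency-dependent intercepts of the linear prescription-gain rule),
#' `ltass` (long-term average speech spectrum shape, dB re the 1 kHz
#' band), `hl_to_spl` (reference-equivalent threshold sound pressure
#' levels used to convert audiometric dB HL to dB SPL) and
#' `band_importance` (relative band-importance curves for the SPIN and NNS
#' weightings, plus a flat option). Values approximate the standard
#' published tables; results carry the table name used.
#'
#' @param name table name.
#' @return data frame.
#' @export
presbyfit_table <- function(name = c("cambridge_intercepts", "ltass",
                                     "hl_to_spl", "band_importance")) {
  name <- match.arg(name)
  path <- system.file("extdata", paste0(name, ".csv"), package = "presbyfit")
  if (path == "") stop("packaged table not found: ", name)
  utils::read.csv(path)
}

# linear interpolation on a log-frequency axis; errors outside the span
interp_logf <- function(f_tab, v_tab, f_out, what = "table") {
  if (any(f_out < min(f_tab) - 1e-9 | f_out > max(f_tab) + 1e-9))
    stop("frequency outside the span of the ", what,
         " (", min(f_tab), "-", max(f_tab), ")")
  stats::approx(log(f_tab), v_tab, xout = log(f_out), rule = 1)$y
}

# coerce an audiogram (named vector "0.5"=.. in kHz, or data frame with
# freq columns) to a two-column data frame freq_khz / hl_db
as_audiogram <- function(audiogram) {
  if (is.data.frame(audiogram)) {
    stopifnot(all(c("freq_khz", "hl_db") %in% names(audiogram)))
    out <- audiogram[, c("freq_khz", "hl_db")]
  } else {
    out <- data.frame(freq_khz = as.numeric(names(audiogram)),
                      hl_db = as.numeric(audiogram))
  }
  if (anyNA(out$freq_khz)) stop("audiogram frequencies must be numeric (kHz)")
  out[order(out$freq_khz), ]
}

#' Equivalent rectangular bandwidth of the normal auditory filter
#' @param f_hz frequency in Hz.
#' @return ERB_N in Hz (`24.7 * (4.37 f/1000 + 1)`).
#' @export
erb_n <- function(f_hz) 24.7 * (4.37 * f_hz / 1000 + 1)

#' Gammatone channel centre frequencies
#'
#' `n` centres logarithmically spaced over `[lo, hi]` Hz (the masker's
#' spectral-ripple grid uses 32 channels over 80 to 8020 Hz, each 1 ERB_N
#' wide).
#'
#' @param n number of channels.
#' @param lo,hi span in Hz.
#' @return numeric vector of centre frequencies.
#' @export
gammatone_centers <- function(n = 32, lo = 80, hi = 8020) {
  exp(seq(log(lo), log(hi), length.out = n))
}

#' Linear prescription gain from an audiogram
#'
#' The hearing-aid amplification rule used for the speech stimuli:
#' `gain(f) = 0.48 * HL(f) + intercept(f)`, with a frequency-dependent
#' intercept table. Audiogram and intercepts are interpolated linearly in
#' log-frequency onto the requested grid.
#'
#' @param audiogram named numeric vector (names = frequency in kHz) or
#'   data frame with `freq_khz`, `hl_db`.
#' @param frequencies_khz output grid; default the audiogram frequencies.
#' @param intercepts intercept table (`freq_khz`, `intercept_db`).
#' @param slope gain per dB of hearing loss.
#' @return data frame of class `gain_profile`: `freq_khz`, `gain_db`;
#'   attribute `intercept_table` records the table used.
#' @examples
#' cambridge_gain(c("0.5" = 40, "1" = 45, "2" = 50, "4" = 60))
#' @export
cambridge_gain <- function(audiogram, frequencies_khz = NULL,
                           intercepts = presbyfit_table("cambridge_intercepts"),
                           slope = 0.48) {
  ag <- as_audiogram(audiogram)
  if (is.null(frequencies_khz)) frequencies_khz <- ag$freq_khz
  hl <- interp_logf(ag$freq_khz, ag$hl_db, frequencies_khz, "audiogram")
  ic <- interp_logf(intercepts$freq_khz, intercepts$intercept_db,
                    frequencies_khz, "intercept table")
  structure(data.frame(freq_khz = frequencies_khz,
                       gain_db = slope * hl + ic),
            class = c("gain_profile", "data.frame"),
            intercept_table = "cambridge_intercepts")
}

new_band_grid <- function(frequencies_hz, times_s, levels) {
  levels <- matrix(levels, nrow = length(times_s), ncol = length(frequencies_hz))
  if (anyNA(levels)) stop("band levels contain NA")
  structure(list(frequencies_hz = frequencies_hz, times_s = times_s,
                 levels = levels), class = "band_grid")
}

#' @export
print.band_grid <- function(x, ...) {
  cat(sprintf("Band grid: %d frame(s) x %d bands (%.0f-%.0f Hz)\n",
              length(x$times_s), length(x$frequencies_hz),
              min(x$frequencies_hz), max(x$frequencies_hz)))
  invisible(x)
}

#' Long-term speech band levels at presentation level, with optional gain
#'
#' Scales the packaged long-term average speech spectrum shape so that the
#' 1 kHz band sits at `level_db` dB SPL before amplification, then adds
#' the per-band gain.
#'
#' @param frequencies_hz band grid (default 32 gammatone centres).
#' @param gain a [cambridge_gain()] profile, a numeric per-band gain, or
#'   `NULL` for unaided presentation.
#' @param level_db pre-amplification presentation level of the 1 kHz band
#'   (dB SPL).
#' @param ltass speech-spectrum shape table (`freq_hz`, `rel_db`).
#' @return single-frame `band_grid`.
#' @export
speech_band_levels <- function(frequencies_hz = gammatone_centers(),
                               gain = NULL, level_db = 65,
                               ltass = presbyfit_table("ltass")) {
  shape <- interp_logf(ltass$freq_hz, ltass$rel_db, frequencies_hz, "LTASS")
  ref_1k <- interp_logf(ltass$freq_hz, ltass$rel_db, 1000, "LTASS")
  lev <- shape - ref_1k + level_db
  if (!is.null(gain)) {
    g <- if (inherits(gain, "gain_profile"))
      # flat extension beyond the profile's span (audiogram edge values)
      stats::approx(log(gain$freq_khz * 1000), gain$gain_db,
                    xout = log(frequencies_hz), rule = 2)$y
    else rep_len(as.numeric(gain), length(frequencies_hz))
    lev <- lev + g
  }
  new_band_grid(frequencies_hz, 0, matrix(lev, nrow = 1))
}

silence_db <- -100  # level assigned to silenced channels / zero-power frames

#' Spectro-temporally modulated speech-shaped-noise masker
#'
#' Builds the masker band grid: a speech-shaped noise whose band levels
#' follow the speech reference spectrum offset so the broadband
#' signal-to-noise ratio (against the unmodulated masker) equals
#' `snr_db`; an optional sinusoidal amplitude modulation of the envelope
#' (depth 1 means the envelope reaches zero in the dips), with band
#' intensities renormalized to preserve the mean power so the SNR
#' definition is unambiguous; and an optional spectral ripple that
#' silences every other of the 32 gammatone channels (starting parity
#' randomized from the seed, as is the modulation starting phase).
#'
#' @param speech_reference single-frame `band_grid` of the unamplified
#'   speech spectrum (its shape defines the SSN spectrum).
#' @param snr_db broadband signal-to-noise ratio in dB.
#' @param am_rate_hz amplitude-modulation rate (8 Hz in the test).
#' @param am_depth modulation depth in `[0, 1]`.
#' @param ripple_on apply the one-channel-in-two spectral ripple.
#' @param frame_step_s frame step in seconds; must sample the modulation
#'   above its Nyquist rate.
#' @param duration_s grid duration in seconds.
#' @param seed RNG seed for starting phase and ripple parity.
#' @return `band_grid` with attributes `ripple_parity` and `am_phase`.
#' @export
masker_band_grid <- function(speech_reference, snr_db = -4.5,
                             am_rate_hz = 8, am_depth = 1, ripple_on = TRUE,
                             frame_step_s = 0.0094, duration_s = 1,
                             seed = 1) {
  stopifnot(am_depth >= 0, am_depth <= 1, is.finite(snr_db))
  if (am_depth > 0 && frame_step_s >= 1 / (2 * am_rate_hz))
    stop("frame step too coarse to sample the modulation envelope")
  set.seed(seed)
  phase <- stats::runif(1, 0, 2 * pi)
  parity <- sample(0:1, 1)
  f <- speech_reference$frequencies_hz
  base <- as.numeric(speech_reference$levels[1, ]) - snr_db
  times <- seq(0, duration_s - frame_step_s, by = frame_step_s)
  env <- 1 - am_depth / 2 + (am_depth / 2) * sin(2 * pi * am_rate_hz * times + phase)
  ienv <- env^2
  ienv <- ienv / mean(ienv)           # preserve mean power
  lev_t <- ifelse(ienv > 0, 10 * log10(ienv), -Inf)
  levels <- outer(lev_t, base, `+`)
  if (ripple_on) {
    silenced <- (seq_along(f) + parity) %% 2 == 0
    levels[, silenced] <- -Inf
  }
  levels[levels < silence_db] <- silence_db
  g <- new_band_grid(f, times, levels)
  attr(g, "ripple_parity") <- parity
  attr(g, "am_phase") <- phase
  g
}

#' Write / read a band grid as CSV
#'
#' First column is the frame time in seconds, remaining columns the band
#' levels with the band centre frequency (Hz) in the header.
#'
#' @param grid a `band_grid`.
#' @param path file path.
#' @rdname band_grid_io
#' @export
write_band_grid <- function(grid, path) {
  df <- data.frame(time_s = grid$times_s, grid$levels)
  names(df)[-1] <- paste0("band_", round(grid$frequencies_hz, 1))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname band_grid_io
#' @export
read_band_grid <- function(path) {
  df <- utils::read.csv(path)
  f <- as.numeric(sub("^band_", "", names(df)[-1]))
  new_band_grid(f, df$time_s, as.matrix(df[, -1]))
}
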