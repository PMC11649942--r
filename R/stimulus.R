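#' Stimulator sample rate
#'
#' The fixed digital-to-analog sample rate of the constant-current stimulator,
#' 48,828.125 Hz. At this rate one biphasic pulse phase of 2 samples lasts
#' exactly 40.96 microseconds.
#'
#' @return Sample rate in Hz.
#' @export
ci_sample_rate <- function() 48828.125

# hard amplitude ceiling of the stimulator, in microamperes
MAX_AMPLITUDE_UA <- 300

#' Synthesize a charge-balanced biphasic pulse train
#'
#' Builds the per-sample current waveform of an unmodulated rectangular pulse
#' train as delivered to one intracochlear electrode. Each pulse occupies six
#' samples in three 2-sample phases: `+A, +A, 0, 0, -A, -A`, so every pulse is
#' exactly charge balanced (its samples sum to zero) and each phase lasts
#' 40.96 microseconds at the fixed 48,828.125 Hz sample rate.
#'
#' The inter-pulse onset spacing is `round(sample_rate / pulse_rate)` samples,
#' so the realized rate can deviate from the nominal rate by less than half a
#' sample per period; the realized rate is stored in the result. Only whole
#' pulses are emitted: the number of pulses is `floor(pulse_rate * duration)`,
#' which guarantees the train ends charge balanced.
#'
#' @param pulse_rate Pulse rate in pulses per second (pps). Must leave at least
#'   6 samples per pulse period, i.e. `pulse_rate <= sample_rate / 6`.
#' @param duration Train duration in seconds.
#' @param peak_amplitude Peak current per phase in microamperes, at most 300.
#'
#' @return An object of class `pulse_train`: a list with elements
#'   `sample_rate`, `pulse_rate` (nominal), `realized_rate`, `duration`,
#'   `peak_amplitude`, `n_pulses` and `waveform` (numeric vector of per-sample
#'   currents in microamperes).
#' @examples
#' pt <- synthesize_pulse_train(900, 0.01, 100)
#' pt$n_pulses
#' @export
synthesize_pulse_train <- function(pulse_rate, duration, peak_amplitude) {
  fs <- ci_sample_rate()
  if (!is.numeric(pulse_rate) || length(pulse_rate) != 1 || pulse_rate <= 0) {
    abort("`pulse_rate` must be a single positive number (pps).")
  }
  if (pulse_rate > fs / 6) {
    abort(sprintf(
      "Pulse period at %.6g pps is shorter than the 6 samples (122.88 us) one biphasic pulse occupies; pulses would overlap. Maximum admissible rate is %.6g pps.",
      pulse_rate, fs / 6
    ))
  }
  if (!is.numeric(duration) || length(duration) != 1 || duration <= 0) {
    abort("`duration` must be a single positive number of seconds.")
  }
  if (!is.numeric(peak_amplitude) || length(peak_amplitude) != 1 ||
      peak_amplitude <= 0 || peak_amplitude > MAX_AMPLITUDE_UA) {
    abort(sprintf("`peak_amplitude` must be in (0, %d] microamperes.", MAX_AMPLITUDE_UA))
  }

  period <- round(fs / pulse_rate)
  n_pulses <- floor(pulse_rate * duration)
  n_samples <- max(round(duration * fs), if (n_pulses > 0) (n_pulses - 1) * period + 6 else 0)
  waveform <- numeric(n_samples)
  if (n_pulses > 0) {
    onsets <- (seq_len(n_pulses) - 1) * period + 1
    shape <- c(1, 1, 0, 0, -1, -1) * peak_amplitude
    for (off in 0:5) waveform[onsets + off] <- shape[off + 1]
  }
  structure(
    list(
      sample_rate = fs,
      pulse_rate = pulse_rate,
      realized_rate = fs / period,
      duration = duration,
      peak_amplitude = peak_amplitude,
      n_pulses = n_pulses,
      waveform = waveform
    ),
    class = "pulse_train"
  )
}

#' @export
print.pulse_train <- function(x, ...) {
  cat(sprintf(
    "<pulse_train> %g pps (realized %.4f pps), %.4g s, peak %.4g uA, %d pulses, %d samples @ %.3f Hz\n",
    x$pulse_rate, x$realized_rate, x$duration, x$peak_amplitude,
    x$n_pulses, length(x$waveform), x$sample_rate
  ))
  invisible(x)
}

#' Split an average binaural level into per-ear levels
#'
#' Applies an interaural level difference symmetrically around the average
#' binaural level (ABL): the right ear receives `abl + ild/2` and the left ear
#' `abl - ild/2`, so the ABL is held constant across ILDs and
#' `right - left = ild`. Positive ILD means the right ear is louder.
#'
#' @param abl Average binaural level in dB (any finite reference).
#' @param ild Interaural level difference in dB, right minus left.
#' @return A tibble with columns `left_db` and `right_db` (vectorized over the
#'   inputs).
#' @examples
#' apply_ild(10, 6)
#' @export
apply_ild <- function(abl, ild) {
  if (!all(is.finite(abl)) || !all(is.finite(ild))) {
    abort("`abl` and `ild` must be finite.")
  }
  tibble(left_db = abl - ild / 2, right_db = abl + ild / 2)
}

#' Build a binaural pulse-train stimulus with a given ILD
#'
#' Synthesizes sample-aligned (zero interaural time difference) left and right
#' pulse trains whose peak amplitudes differ by the requested ILD in dB of
#' pulse amplitude. Levels in dB are mapped to microamperes against a
#' reference amplitude: `peak = reference_amplitude * 10^(level_db / 20)`
#' (amplitude dB, not power dB).
#'
#' @param pulse_rate Pulse rate in pps.
#' @param duration Duration in seconds.
#' @param abl_db Average binaural level in dB re `reference_amplitude`.
#' @param ild_db ILD in dB (right minus left).
#' @param reference_amplitude Current in microamperes corresponding to 0 dB.
#'   Defaults to 100 uA; in the experiment levels are set per animal relative
#'   to its perception threshold.
#' @return An object of class `binaural_stimulus`: list with `left` and
#'   `right` (`pulse_train` objects), `abl_db`, `ild_db`, `itd_us` (always 0)
#'   and `reference_amplitude`.
#' @examples
#' stim <- make_binaural(900, 0.01, abl_db = 0, ild_db = 6)
#' measure_ild(stim)
#' @export
make_binaural <- function(pulse_rate, duration, abl_db, ild_db,
                          reference_amplitude = 100) {
  levels <- apply_ild(abl_db, ild_db)
  amp <- reference_amplitude * 10^(c(levels$left_db, levels$right_db) / 20)
  if (any(amp > MAX_AMPLITUDE_UA)) {
    abort(sprintf(
      "Requested levels imply peak amplitudes (%.4g, %.4g uA) above the %d uA stimulator ceiling.",
      amp[1], amp[2], MAX_AMPLITUDE_UA
    ))
  }
  structure(
    list(
      left = synthesize_pulse_train(pulse_rate, duration, amp[1]),
      right = synthesize_pulse_train(pulse_rate, duration, amp[2]),
      abl_db = abl_db,
      ild_db = ild_db,
      itd_us = 0,
      reference_amplitude = reference_amplitude
    ),
    class = "binaural_stimulus"
  )
}

#' @export
print.binaural_stimulus <- function(x, ...) {
  cat(sprintf(
    "<binaural_stimulus> %g pps, %.4g s, ABL %.4g dB, ILD %+.4g dB, ITD %g us\n",
    x$left$pulse_rate, x$left$duration, x$abl_db, x$ild_db, x$itd_us
  ))
  invisible(x)
}

#' Measure the ILD of a binaural stimulus from its waveforms
#'
#' Verification oracle for [make_binaural()]: recovers the ILD as
#' `20 * log10(right peak / left peak)` from the per-sample currents alone.
#'
#' @param stimulus A `binaural_stimulus`.
#' @return ILD in dB (right minus left).
#' @export
measure_ild <- function(stimulus) {
  stopifnot(inherits(stimulus, "binaural_stimulus"))
  lp <- max(abs(stimulus$left$waveform))
  rp <- max(abs(stimulus$right$waveform))
  if (lp == 0 || rp == 0) {
    abort("Cannot measure an ILD on a silent channel: level is undefined.")
  }
  20 * log10(rp / lp)
}

#' Convert clinical current-level (CL) units to microamperes
#'
#' The proprietary current-level unit of Cochlear Ltd devices maps to pulse
#' amplitude as `I(uA) = 17.5 * 100^(CL / 255)`, spanning 17.5 uA at CL 0 to
#' 1750 uA at CL 255.
#'
#' @param cl Current level in CL units, in `[0, 255]` (vectorized).
#' @return Current in microamperes.
#' @examples
#' cl_to_microamps(c(0, 127.5, 255))
#' @export
cl_to_microamps <- function(cl) {
  if (!all(is.finite(cl)) || any(cl < 0 | cl > 255)) {
    abort("`cl` must lie in [0, 255].")
  }
  17.5 * 100^(cl / 255)
}

#' Convert a CL-unit level difference to dB of pulse amplitude
#'
#' Because the CL scale is exponential, a difference of `delta_cl` CL units
#' corresponds to an amplitude ratio of `100^(delta_cl / 255)`, i.e.
#' `delta_cl * 20 * log10(100^(1/255)) = delta_cl * 40/255` dB — a fixed
#' factor of about 0.15686 dB per CL unit.
#'
#' @param delta_cl Level difference in CL units (vectorized, any sign).
#' @return Level difference in dB.
#' @examples
#' cl_ild_to_db(5) # ~0.78 dB
#' @export
cl_ild_to_db <- function(delta_cl) {
  if (!all(is.finite(delta_cl))) abort("`delta_cl` must be finite.")
  delta_cl * (40 / 255)
}

#' Export a binaural stimulus as a two-channel float WAV file
#'
#' Writes the left/right per-sample currents as a stereo 32-bit IEEE-float WAV
#' (left = channel 1), with samples scaled by `full_scale` so that
#' `full_scale` microamperes maps to 1.0. The WAV header's sample-rate field
#' only holds integers, so it carries 48828; the exact 48,828.125 Hz rate and
#' the stimulus metadata (pps, ILD, ABL, ITD, reference and full-scale
#' amplitudes) are written to a JSON sidecar at `paste0(path, ".json")`.
#'
#' @param stimulus A `binaural_stimulus`.
#' @param path Output WAV path.
#' @param full_scale Current in microamperes mapped to sample value 1.0.
#' @return Invisibly, a character vector with the WAV and sidecar paths.
#' @export
write_stimulus_wav <- function(stimulus, path, full_scale = MAX_AMPLITUDE_UA) {
  stopifnot(inherits(stimulus, "binaural_stimulus"))
  left <- stimulus$left$waveform / full_scale
  right <- stimulus$right$waveform / full_scale
  n <- max(length(left), length(right))
  length(left) <- n; length(right) <- n
  left[is.na(left)] <- 0; right[is.na(right)] <- 0
  inter <- as.vector(rbind(left, right))

  fs_int <- as.integer(round(stimulus$left$sample_rate))
  n_channels <- 2L; bits <- 32L
  block_align <- n_channels * bits / 8L
  data_bytes <- length(inter) * 4L

  con <- file(path, "wb")
  on.exit(close(con), add = TRUE)
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + data_bytes), con, size = 4, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(3L, con, size = 2, endian = "little")  # format 3 = IEEE float
  writeBin(n_channels, con, size = 2, endian = "little")
  writeBin(fs_int, con, size = 4, endian = "little")
  writeBin(as.integer(fs_int * block_align), con, size = 4, endian = "little")
  writeBin(as.integer(block_align), con, size = 2, endian = "little")
  writeBin(bits, con, size = 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(data_bytes), con, size = 4, endian = "little")
  writeBin(inter, con, size = 4, endian = "little")

  sidecar <- paste0(path, ".json")
  jsonlite::write_json(
    list(
      sample_rate_hz = stimulus$left$sample_rate,
      pulse_rate_pps = stimulus$left$pulse_rate,
      realized_rate_pps = stimulus$left$realized_rate,
      duration_s = stimulus$left$duration,
      abl_db = stimulus$abl_db,
      ild_db = stimulus$ild_db,
      itd_us = stimulus$itd_us,
      reference_amplitude_ua = stimulus$reference_amplitude,
      full_scale_ua = full_scale,
      ild_split = "symmetric about ABL"
    ),
    sidecar, auto_unbox = TRUE, digits = NA
  )
  invisible(c(wav = path, sidecar = sidecar))
}
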