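# Optional audio rendering of trial schedules. Analyses operate on the
# schedules themselves; rendering exists for stimulus verification and export.

#' Render a trial as a two-channel waveform
#'
#' Tones are 50-ms sinusoids with 10-ms linear onset/offset ramps. Noise
#' bursts are 400-ms bandpass (2--3 kHz) noise with 350/50-ms ("approach") or
#' 50/350-ms ("depart") linear ramps; the bandpass is applied as an FFT-domain
#' brick-wall mask, so stopband energy is zero to numerical precision. Triplets
#' and noises are placed on opposite channels.
#'
#' @param trial A `trial_spec`.
#' @param sample_rate_hz Samples per second (default 44100). Must exceed twice
#'   the 3-kHz upper band edge.
#' @param ear_assignment `"tones_left"` or `"tones_right"`.
#' @param seed Optional seed for the noise carriers.
#' @return A numeric matrix with two columns (left, right) and attribute
#'   `sample_rate_hz`. Peak amplitude is 0.9.
#' @export
render_audio <- function(trial, sample_rate_hz = 44100,
                         ear_assignment = c("tones_left", "tones_right"),
                         seed = NULL) {
  stopifnot(inherits(trial, "trial_spec"))
  ear_assignment <- match.arg(ear_assignment)
  assert_that(sample_rate_hz > 6000, "invalid_sample_rate",
              "sample_rate_hz too low for 3 kHz noise content")
  fs <- sample_rate_hz
  n <- ceiling(trial$duration_s * fs)
  tones <- numeric(n)
  tl <- trial$triplets
  add_tone <- function(buf, onset_s, freq) {
    i0 <- round(onset_s * fs)
    len <- round(TONE_DUR_S * fs)
    t <- (seq_len(len) - 1) / fs
    ramp <- pmin(1, t / 0.010, (TONE_DUR_S - t) / 0.010)
    seg <- sin(2 * pi * freq * t) * pmax(ramp, 0)
    idx <- i0 + seq_len(len)
    keep <- idx <= length(buf)
    buf[idx[keep]] <- buf[idx[keep]] + seg[keep]
    buf
  }
  for (k in seq_len(nrow(tl))) {
    tones <- add_tone(tones, tl$onset_s[k], tl$a_freq_hz[k])
    tones <- add_tone(tones, tl$onset_s[k] + tl$b_offset_s[k], tl$b_freq_hz[k])
    tones <- add_tone(tones, tl$onset_s[k] + A2_OFFSET_S, tl$a_freq_hz[k])
  }
  noises <- numeric(n)
  with_seed_or_current(seed, {
    for (k in seq_along(trial$noise_onsets_s)) {
      len <- round(NOISE_DUR_S * fs)
      carrier <- bandpass_brickwall(stats::rnorm(len), fs, 2000, 3000)
      carrier <- carrier / max(abs(carrier))
      t <- (seq_len(len) - 1) / fs
      ramps <- if (trial$noise_tokens[k] == "approach") c(0.350, 0.050)
               else c(0.050, 0.350)
      env <- pmin(1, t / ramps[1], (NOISE_DUR_S - t) / ramps[2])
      i0 <- round(trial$noise_onsets_s[k] * fs)
      idx <- i0 + seq_len(len)
      keep <- idx <= n
      noises[idx[keep]] <- noises[idx[keep]] + (carrier * pmax(env, 0))[keep]
    }
  })
  scale <- 0.9 / max(max(abs(tones)), max(abs(noises)), 1e-12)
  wave <- if (ear_assignment == "tones_left") cbind(left = tones, right = noises)
          else cbind(left = noises, right = tones)
  wave <- wave * scale
  attr(wave, "sample_rate_hz") <- fs
  wave
}

# Brick-wall bandpass via FFT masking: bins outside [lo, hi] Hz are zeroed.
bandpass_brickwall <- function(x, fs, lo, hi) {
  n <- length(x)
  f <- (seq_len(n) - 1) * fs / n
  f <- pmin(f, fs - f) # fold to |frequency|
  mask <- f >= lo & f <= hi
  Re(stats::fft(stats::fft(x) * mask, inverse = TRUE)) / n
}

#' Write a waveform as a 16-bit PCM WAV file
#'
#' @param wave Numeric matrix (samples x channels) in \[-1, 1\], as returned
#'   by [render_audio()].
#' @param path Output file path.
#' @param sample_rate_hz Sample rate; defaults to the matrix attribute.
#' @export
write_wav <- function(wave, path,
                      sample_rate_hz = attr(wave, "sample_rate_hz")) {
  stopifnot(is.matrix(wave), !is.null(sample_rate_hz))
  pcm <- as.integer(round(pmax(pmin(t(wave), 1), -1) * 32767))
  n_ch <- ncol(wave)
  byte_rate <- sample_rate_hz * n_ch * 2L
  data_len <- length(pcm) * 2L
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + data_len), con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")        # PCM
  writeBin(as.integer(n_ch), con, size = 2, endian = "little")
  writeBin(as.integer(sample_rate_hz), con, size = 4, endian = "little")
  writeBin(as.integer(byte_rate), con, size = 4, endian = "little")
  writeBin(as.integer(n_ch * 2L), con, size = 2, endian = "little") # block align
  writeBin(16L, con, size = 2, endian = "little")       # bits per sample
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(data_len), con, size = 4, endian = "little")
  writeBin(pcm, con, size = 2, endian = "little")
  invisible(path)
}
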