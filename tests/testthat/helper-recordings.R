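# fixtures built in code; no files on disk

sineRecording <- function(freqs, fs = 200, duration = 10, amp = 1) {
  t <- (seq_len(round(fs * duration)) - 1) / fs
  data <- t(vapply(freqs, function(f) amp * sin(2 * pi * f * t),
                   numeric(length(t))))
  Recording(data, fs = fs)
}

noiseRecording <- function(nch = 4, n = 2000, fs = 200, seed = 42) {
  set.seed(seed)
  Recording(matrix(rnorm(nch * n, sd = 10), nch, n), fs = fs)
}

# analytic squared-magnitude response of the two-way Butterworth band-pass
butterTwoWayGain <- function(f, fs, low = 1, high = 47, order = 4) {
  bt <- signal::butter(order, c(low, high) / (fs / 2), type = "pass")
  z <- exp(-1i * 2 * pi * f / fs)
  H <- sum(bt$b * z^(0:(length(bt$b) - 1))) /
    sum(bt$a * z^(0:(length(bt$a) - 1)))
  Mod(H)^2
}
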