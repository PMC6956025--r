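# Semi-simulated EEG: artifact-free multichannel background plus vertical
# and horizontal EOG source traces scaled by per-channel propagation
# coefficients,
#   contaminated[i, ] = pure[i, ] + a[i] * veog + b[i] * heog,
# with ground-truth event times. All randomness flows from a single seed
# through named sub-streams, so each piece is reproducible on its own.

subSeed <- function(seed, stream) {
  h <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)))
  as.integer((as.numeric(seed) * 48271 + h * 7919) %% 2147483647)
}

# standard 19-channel 10-20 montage ordered front to back
montage1020 <- c("Fp1", "Fp2", "F7", "F3", "Fz", "F4", "F8",
                 "T3", "C3", "Cz", "C4", "T4",
                 "T5", "P3", "Pz", "P4", "T6", "O1", "O2")

# band-limited 1/f ("pink") noise via spectral shaping, unit RMS
pinkNoise <- function(n, fs, low = 1, high = 47) {
  nf <- floor(n / 2)
  f <- seq_len(nf) * fs / n
  amp <- ifelse(f >= low & f <= high, 1 / sqrt(pmax(f, low)), 0)
  ph <- stats::runif(nf, 0, 2 * pi)
  spec <- complex(modulus = amp, argument = ph)
  full <- complex(n)
  full[2:(nf + 1)] <- spec
  full[n:(n - nf + 2)] <- Conj(spec[seq_len(nf - 1)])
  x <- Re(stats::fft(full, inverse = TRUE)) / n
  x / stats::sd(x)
}

# approximate 2-D scalp positions (x lateral, y front-to-back in [-1, 1])
scalpPositions <- function(nChannels) {
  if (nChannels == 19L)                     # 10-20 layout, front to back
    cbind(x = c(-0.3, 0.3, -0.7, -0.35, 0, 0.35, 0.7,
                -0.9, -0.45, 0, 0.45, 0.9,
                -0.7, -0.35, 0, 0.35, 0.7, -0.3, 0.3),
          y = c(1, 1, 0.72, 0.65, 0.6, 0.65, 0.72,
                0.25, 0.2, 0.15, 0.2, 0.25,
                -0.4, -0.5, -0.55, -0.5, -0.4, -0.85, -0.85))
  else cbind(x = rep_len(c(-0.5, 0.5), nChannels),
             y = seq(1, -1, length.out = nChannels))
}

# normalized front-to-back coordinate (0 forehead, 1 occiput)
scalpCoord <- function(nChannels) {
  (1 - scalpPositions(nChannels)[, "y"]) / 2
}

# bursty band-limited 1/f source: pink noise under a slow random
# amplitude envelope. The envelope makes the marginal super-Gaussian
# (excess kurtosis of several), as real cortical activity is, which is
# what lets an Infomax decomposition actually separate the sources.
burstyPink <- function(n, fs) {
  x <- pinkNoise(n, fs)
  e <- pinkNoise(n, fs, low = 0.1, high = 0.5)
  y <- x * (0.4 + pmax(e, 0))
  y / stats::sd(y)
}

#' Generate artifact-free multichannel EEG
#'
#' Emulates eyes-closed resting EEG: many (more than channels) bursty
#' band-limited 1/f cortical sources with smooth dipolar topographies of
#' comparable strength spread over a 2-D scalp layout, a posterior
#' waxing-and-waning alpha oscillation (8-12 Hz, random frequency and
#' phase), and a small per-electrode noise floor. Source dipoles are
#' placed behind the frontal pole: an artifact-free reference recording
#' contains, by construction, no bursty forehead-dominant activity
#' (that is what ocular artifacts are). Channel RMS follows the
#' eyes-closed front-to-back amplitude gradient, from about 12
#' microvolts at the frontal pole to about 26 microvolts occipitally.
#' Deterministic per seed.
#'
#' @param nChannels number of channels (default 19; labels follow the
#'   10-20 montage when it is exactly 19).
#' @param fs sampling rate in Hz (default 200).
#' @param duration length in seconds (default 120).
#' @param seed integer seed.
#' @return A [Recording-class].
#' @export
genPureEEG <- function(nChannels = 19L, fs = 200, duration = 120,
                       seed = 1L) {
  n <- round(fs * duration)
  pos <- scalpPositions(nChannels)
  withSeed(subSeed(seed, "pure"), {
    nShared <- 60L
    shared <- t(vapply(seq_len(nShared),
                       function(k) burstyPink(n, fs), numeric(n)))
    topo <- vapply(seq_len(nShared), function(k) {
      c1 <- c(stats::runif(1, -1, 1), stats::runif(1, -1, 0.75))
      th <- stats::runif(1, 0, 2 * pi)
      c2 <- c1 + stats::runif(1, 0.3, 0.7) * c(cos(th), sin(th))
      w <- stats::runif(1, 0.4, 0.8)
      v <- exp(-((pos[, 1] - c1[1])^2 + (pos[, 2] - c1[2])^2) / w^2) -
           exp(-((pos[, 1] - c2[1])^2 + (pos[, 2] - c2[2])^2) / w^2)
      v <- v - mean(v)
      v / sqrt(sum(v^2))
    }, numeric(nChannels))                  # equal-norm dipolar patterns
    amps <- stats::runif(nShared, 0.7, 1.3)
    falpha <- stats::runif(1, 8, 12)
    alpha <- sin(2 * pi * falpha * (seq_len(n) - 1) / fs +
                   stats::runif(1, 0, 2 * pi))
    env <- pinkNoise(n, fs, low = 0.1, high = 0.5)
    alpha <- alpha * (0.4 + pmax(env, 0))
    alpha <- alpha / stats::sd(alpha)
    post <- (1 - pos[, 2]) / 2              # 0 forehead, 1 occiput
    aW <- post^2 - mean(post^2)
    aW <- 1.5 * aW / sqrt(sum(aW^2))        # posterior-dominant alpha
    data <- topo %*% (amps * shared) + outer(aW, alpha)
    # eyes-closed amplitude gradient: quiet frontal (~12 uV RMS),
    # alpha-dominated posterior (~26 uV RMS)
    target <- 12 + 14 * post
    data <- data * (target / apply(data, 1L, stats::sd))
    for (i in seq_len(nChannels))           # electrode-noise floor
      data[i, ] <- data[i, ] + 4 * pinkNoise(n, fs)
    labels <- if (nChannels == 19L) montage1020
              else paste0("ch", seq_len(nChannels))
    Recording(data, fs = fs, labels = labels,
              meta = list(generator = "genPureEEG", seed = seed))
  })
}

#' Generate EOG source traces with ground truth
#'
#' Blinks (VEOG) are squared-cosine bumps of 200-400 ms width and
#' 100-400 microvolt amplitude. The HEOG trace models spontaneous gaze
#' shifts: a piecewise-constant eye-position signal jumping to a new
#' level (within +-150 microvolts) at each saccade, with 30 ms
#' raised-cosine edges. Event times follow a jittered renewal process
#' with a refractory gap (1.2 s for blinks, 0.6 s for saccades), so truth
#' events are always separated by more than the detector's 0.5 s spacing
#' rule.
#'
#' @param fs sampling rate in Hz.
#' @param duration length in seconds.
#' @param blinkRate,saccadeRate expected events per minute (defaults 12
#'   and 20; 0 disables a source).
#' @param blinkAmp amplitude range in microvolts (default c(100, 400)).
#' @param seed integer seed.
#' @return List with \code{veog}, \code{heog} (numeric series) and
#'   \code{truth}: \code{blinks} and \code{saccades} event-centre times
#'   in seconds.
#' @export
genEOGSources <- function(fs, duration, blinkRate = 12, saccadeRate = 20,
                          blinkAmp = c(100, 400), seed = 1L) {
  n <- round(fs * duration)
  tgrid <- (seq_len(n) - 1) / fs
  eventTimes <- function(ratePerMin, gap) {
    if (ratePerMin <= 0) return(numeric(0))
    meanIval <- 60 / ratePerMin
    ts <- c(); t <- stats::runif(1, 0.5, meanIval)
    while (t < duration - 0.7) {
      ts <- c(ts, t)
      t <- t + gap + stats::rexp(1, 1 / max(meanIval - gap, 0.1))
    }
    ts
  }
  withSeed(subSeed(seed, "eog"), {
    veog <- numeric(n); heog <- numeric(n)
    blinks <- eventTimes(blinkRate, gap = 1.2)
    for (tc in blinks) {
      wdt <- stats::runif(1, 0.2, 0.4)
      A <- stats::runif(1, blinkAmp[1L], blinkAmp[2L])
      sel <- abs(tgrid - tc) < wdt / 2
      veog[sel] <- veog[sel] + A * cos(pi * (tgrid[sel] - tc) / wdt)^2
    }
    saccades <- eventTimes(saccadeRate, gap = 0.6)
    if (length(saccades)) {
      levels <- c(0, stats::runif(length(saccades), -150, 150))
      heog <- levels[findInterval(tgrid, saccades) + 1L]
      ker <- 0.5 - 0.5 * cos(2 * pi * seq_len(round(0.03 * fs)) /
                               (round(0.03 * fs) + 1))
      ker <- ker / sum(ker)                  # 30 ms raised-cosine edges
      heog <- stats::filter(heog, ker, sides = 2)
      heog[is.na(heog)] <- 0
      heog <- as.numeric(heog) - mean(heog, na.rm = TRUE)
    }
    # snap blink truth to the realized sample grid maximum
    blinks <- vapply(blinks, function(tc) {
      sel <- which(abs(tgrid - tc) <= 2 / fs)
      tgrid[sel[which.max(veog[sel])]]
    }, numeric(1))
    list(veog = veog, heog = heog,
         truth = list(blinks = blinks, saccades = saccades))
  })
}

#' Per-channel EOG propagation profile
#'
#' Exponentially decaying coefficients \code{aMax * exp(-d / tau)} with
#' \code{d} the channel's normalized front-to-back scalp coordinate (0 at
#' the forehead, 1 at the occiput; scalp rows for the 19-channel 10-20
#' montage): frontal channels receive the artifact at full strength,
#' posterior channels almost none, mirroring the frontal-dominant
#' topography of ocular potentials.
#'
#' @param nChannels number of channels.
#' @param aMax coefficient at the most frontal channel.
#' @param tau decay constant on the 0-1 scalp coordinate (default 0.28,
#'   i.e. roughly 3\% residual amplitude at the occiput).
#' @return Nonnegative, non-increasing-by-row numeric vector.
#' @export
propagationProfile <- function(nChannels, aMax = 1, tau = 0.28) {
  aMax * exp(-scalpCoord(nChannels) / tau)
}

#' @rdname propagationProfile
#' @details \code{heogProfile} is the horizontal-EOG variant: the same
#'   front-to-back decay, signed by hemisphere. A horizontal gaze shift
#'   moves one eye's positive pole toward the left electrodes and the
#'   other's negative pole toward the right, so left and right channels
#'   see opposite polarity, strongest at lateral-frontal positions
#'   (F7/F8) and zero on the midline. The anti-symmetry also makes the
#'   VEOG and HEOG propagation vectors (nearly) orthogonal; two
#'   symmetric profiles would be close to collinear and no unmixing
#'   could separate the sources.
#' @export
heogProfile <- function(nChannels, aMax = 1, tau = 0.28) {
  lat <- scalpPositions(nChannels)[, "x"]
  aMax * lat * exp(-scalpCoord(nChannels) / tau)
}

#' Contaminate pure EEG with EOG sources
#'
#' Exact additive mixture
#' \code{contaminated[i, ] = pure[i, ] + a[i] veog + b[i] heog}.
#'
#' @param pure a [Recording-class].
#' @param veog,heog EOG source series (length = nSamples; may be NULL
#'   for none).
#' @param a,b per-channel propagation coefficient vectors (nonnegative,
#'   frontally dominant; see [propagationProfile()] and [heogProfile()]).
#' @return The contaminated [Recording-class].
#' @export
contaminate <- function(pure, veog = NULL, heog = NULL,
                        a = propagationProfile(nChannels(pure)),
                        b = heogProfile(nChannels(pure), 0.5)) {
  data <- pure@data
  if (!is.null(veog)) {
    stopifnot(length(veog) == ncol(data), length(a) == nrow(data))
    data <- data + outer(a, veog)
  }
  if (!is.null(heog)) {
    stopifnot(length(heog) == ncol(data), length(b) == nrow(data))
    data <- data + outer(b, heog)
  }
  Recording(data, fs = pure@fs, labels = pure@labels,
            meta = c(pure@meta, list(contaminated = TRUE)))
}

#' Generate a complete semi-simulated dataset
#'
#' Convenience wrapper producing pure and contaminated recordings, the
#' EOG source traces, the propagation coefficients and the ground-truth
#' event times, all from one seed.
#'
#' @inheritParams genPureEEG
#' @inheritParams genEOGSources
#' @param aMax,bMax frontal propagation coefficients for VEOG and HEOG.
#' @param tau ordinal decay constant of the propagation profile.
#' @return List with \code{pure}, \code{contaminated}
#'   ([Recording-class]), \code{veog}, \code{heog}, \code{a}, \code{b},
#'   \code{truth}, \code{seed}.
#' @examples
#' ds <- simulateDataset(duration = 30, seed = 2)
#' ds$contaminated
#' @export
simulateDataset <- function(nChannels = 19L, fs = 200, duration = 120,
                            blinkRate = 12, saccadeRate = 4,
                            aMax = 1, bMax = 0.5, tau = 0.28, seed = 1L) {
  pure <- genPureEEG(nChannels, fs, duration, seed = seed)
  eog <- genEOGSources(fs, duration, blinkRate, saccadeRate, seed = seed)
  a <- propagationProfile(nChannels, aMax, tau)
  b <- heogProfile(nChannels, bMax, tau)
  contaminated <- contaminate(pure, eog$veog, eog$heog, a, b)
  list(pure = pure, contaminated = contaminated, veog = eog$veog,
       heog = eog$heog, a = a, b = b, truth = eog$truth,
       seed = as.integer(seed))
}

#' Laplacian-source toy problem for ICA validation
#'
#' Independent unit-variance Laplacian sources mixed by a random
#' well-conditioned square matrix (condition number below 10). Laplacian
#' sources are super-Gaussian (excess kurtosis 3), satisfying the
#' non-Gaussianity requirement for separability.
#'
#' @param nSources number of sources.
#' @param nSamples number of samples.
#' @param seed integer seed.
#' @return List with \code{sources} (nSources x nSamples),
#'   \code{mixing} (square) and \code{mixture = mixing \%*\% sources}.
#' @export
genICAToy <- function(nSources, nSamples, seed = 1L) {
  withSeed(subSeed(seed, "icatoy"), {
    rate <- sqrt(2)
    S <- matrix(stats::rexp(nSources * nSamples, rate) -
                  stats::rexp(nSources * nSamples, rate),
                nSources, nSamples)
    repeat {
      A <- matrix(stats::rnorm(nSources^2), nSources, nSources)
      if (kappa(A, exact = TRUE) < 10) break
    }
    list(sources = S, mixing = A, mixture = A %*% S)
  })
}
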