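# Seeded synthetic signal generator: AR(2) resonance + spikes + noise.

ar2Coefficients <- function(centerFrequency, bandwidth, sampleRate) {
    if (centerFrequency >= sampleRate / 2)
        stop(sprintf(
            "centerFrequency %.4g Hz is at or above Nyquist (%.4g Hz)",
            centerFrequency, sampleRate / 2), call. = FALSE)
    rho <- exp(-pi * bandwidth / sampleRate)
    theta <- 2 * pi * centerFrequency / sampleRate
    c(2 * rho * cos(theta), -rho^2)
}

#' Stationary variance of the AR(2) resonance
#'
#' Closed-form variance of the second-order autoregressive process
#' `x_n = a1 x_(n-1) + a2 x_(n-2) + e_n` with unit-variance white driving
#' noise, at the pole placement implied by `centerFrequency` and
#' `bandwidth` (pole radius `exp(-pi * bw / fs)`, pole angle
#' `2 pi f / fs`). Used to calibrate preset gains to target powers and as
#' the analytic oracle for the generator's empirical power.
#'
#' @param centerFrequency resonance frequency, Hz (< Nyquist).
#' @param bandwidth resonance bandwidth, Hz.
#' @param sampleRate sampling rate, Hz.
#' @return stationary variance of the unit-driven resonance.
#' @export
ar2Variance <- function(centerFrequency, bandwidth, sampleRate) {
    a <- ar2Coefficients(centerFrequency, bandwidth, sampleRate)
    a1 <- a[1L]; a2 <- a[2L]
    (1 - a2) / ((1 + a2) * ((1 - a2)^2 - a1^2))
}

# 50 ms raised-cosine bump, unit peak.
spikeShape <- function(sampleRate, widthSec = 0.05) {
    w <- max(3L, round(widthSec * sampleRate))
    0.5 - 0.5 * cos(2 * pi * seq_len(w) / (w + 1))
}

#' Generate one synthetic signal from a class specification
#'
#' Produces `amplitudeScale * AR(2) resonance (unit-variance white
#' drive)` plus Poisson-placed 50 ms raised-cosine spike transients of
#' random polarity plus additive white noise of sd `noiseSd`. The AR
#' recursion is warmed up over a discarded burn-in so windows are drawn
#' from the stationary regime. Output is bit-identical for identical
#' `(spec, nSamples, sampleRate, seed)`.
#'
#' @param spec a [ClassSpec-class].
#' @param nSamples number of samples (>= 1).
#' @param sampleRate sampling rate, Hz; `spec`'s center frequency must be
#'   below Nyquist.
#' @param seed integer seed.
#' @param sourceId provenance string for the resulting signal.
#' @return a labeled [Signal-class].
#' @examples
#' sp <- classSpec("ictal", centerFrequency = 4, bandwidth = 1,
#'                 amplitudeScale = 5, noiseSd = 0.2)
#' sig <- generateSignal(sp, 4096, 173.61, seed = 11)
#' var(samples(sig))
#' @export
generateSignal <- function(spec, nSamples, sampleRate, seed,
                           sourceId = NULL) {
    stopifnot(is(spec, "ClassSpec"), nSamples >= 1)
    a <- ar2Coefficients(spec@centerFrequency, spec@bandwidth, sampleRate)
    set.seed(as.integer(seed))
    burn <- 1000L
    e <- stats::rnorm(nSamples + burn)
    x <- as.numeric(stats::filter(e, a, method = "recursive"))
    x <- x[(burn + 1L):(burn + nSamples)]
    out <- spec@amplitudeScale * x
    if (spec@spikeRate > 0 && spec@spikeAmplitude != 0) {
        shape <- spikeShape(sampleRate)
        nSpikes <- stats::rpois(1L, spec@spikeRate * nSamples / sampleRate)
        if (nSpikes > 0) {
            starts <- sample.int(max(1L, nSamples - length(shape)), nSpikes,
                                 replace = TRUE)
            signs <- sample(c(-1, 1), nSpikes, replace = TRUE)
            for (i in seq_len(nSpikes)) {
                idx <- starts[i] + seq_along(shape) - 1L
                idx <- idx[idx <= nSamples]
                out[idx] <- out[idx] +
                    signs[i] * spec@spikeAmplitude * shape[seq_along(idx)]
            }
        }
    }
    if (spec@noiseSd > 0)
        out <- out + stats::rnorm(nSamples, sd = spec@noiseSd)
    if (is.null(sourceId))
        sourceId <- sprintf("%s-seed%d", spec@classLabel, as.integer(seed))
    Signal(out, sampleRate, classLabel = spec@classLabel,
           sourceId = sourceId)
}

#' Generate a full labeled dataset
#'
#' Generates `nSignalsPerClass` independent signals for every class in
#' the spec. Per-signal seeds are derived from the master seed as
#' `seed + (classIndex - 1) * nSignalsPerClass + (replicate - 1)`, so the
#' master seed fully determines every sample of the dataset.
#'
#' @param spec a [DatasetSpec-class].
#' @return list of labeled [Signal-class] objects, grouped by class.
#' @examples
#' sigs <- generateDataset(freiburgLikePreset(nSignalsPerClass = 2,
#'                                            signalLength = 2048,
#'                                            seed = 7))
#' table(vapply(sigs, classLabel, character(1)))
#' @export
generateDataset <- function(spec) {
    stopifnot(is(spec, "DatasetSpec"))
    out <- list()
    for (ci in seq_along(spec@classes)) {
        cs <- spec@classes[[ci]]
        for (ri in seq_len(spec@nSignalsPerClass)) {
            sd_i <- spec@seed + (ci - 1L) * spec@nSignalsPerClass + (ri - 1L)
            out[[length(out) + 1L]] <- generateSignal(
                cs, spec@signalLength, spec@sampleRate, sd_i,
                sourceId = sprintf("%s-%02d", cs@classLabel, ri))
        }
    }
    out
}

# Gain that brings the AR(2) resonance to a target standard deviation.
gainForTargetSd <- function(targetSd, centerFrequency, bandwidth,
                            sampleRate) {
    targetSd / sqrt(ar2Variance(centerFrequency, bandwidth, sampleRate))
}

#' Five-class short-segment preset
#'
#' A five-class dataset of short single-channel segments sampled at
#' 173.61 Hz, emulating the qualitative structure of the classic
#' five-set short-term recordings: two normal-like low-power classes with
#' alpha-band (~10 Hz) rhythms ("A", "B"), an interictal class recorded
#' away from the epileptogenic zone with mild theta activity and sparse
#' small spikes ("C"), an interictal epileptogenic-zone class with slower
#' rhythm, more frequent spikes and higher power ("D"), and an ictal
#' class with a high-amplitude 3--5 Hz rhythm at five times the baseline
#' gain ("E"). Class powers are ordered E > D > A/B, so energy is highly
#' discriminative for the ictal class.
#'
#' @param nSignalsPerClass signals per class (default 20).
#' @param signalLength samples per signal (default 4096).
#' @param seed master seed (default 1).
#' @return a [DatasetSpec-class].
#' @seealso [freiburgLikePreset()], [generateDataset()]
#' @export
bonnLikePreset <- function(nSignalsPerClass = 20L, signalLength = 4096L,
                           seed = 1L) {
    fs <- 173.61
    g <- function(sd, f, bw) gainForTargetSd(sd, f, bw, fs)
    datasetSpec(
        classes = list(
            classSpec("A", 10.0, 2.0, amplitudeScale = g(1.0, 10.0, 2.0),
                      noiseSd = 0.3),
            classSpec("B", 9.5, 1.5, amplitudeScale = g(1.2, 9.5, 1.5),
                      noiseSd = 0.3),
            classSpec("C", 6.0, 2.0, amplitudeScale = g(1.1, 6.0, 2.0),
                      spikeRate = 0.3, spikeAmplitude = 3, noiseSd = 0.3),
            classSpec("D", 5.0, 1.5, amplitudeScale = g(1.8, 5.0, 1.5),
                      spikeRate = 0.7, spikeAmplitude = 5, noiseSd = 0.3),
            classSpec("E", 4.0, 1.0, amplitudeScale = g(5.0, 4.0, 1.0),
                      spikeRate = 1.0, spikeAmplitude = 8, noiseSd = 0.3)),
        nSignalsPerClass = nSignalsPerClass,
        signalLength = signalLength,
        sampleRate = fs,
        seed = seed)
}

#' Two-class long-record preset
#'
#' A two-class dataset at 256 Hz emulating intracranial long-term
#' recordings in which interictal and ictal activity have nearly equal
#' power but distinct spectral peaks (8 Hz vs 4 Hz, sd 1.0 vs 1.1): a
#' regime where discrimination by signal energy alone fails and the
#' correlation structure captured by the leading PC scores carries the
#' class information. The default data volume (16 signals/class of 32768
#' samples, i.e. 128 s each) is a scaled-down stand-in for hour-long
#' records, sized so the nearest-neighbour classifier is not
#' training-data starved at window lengths of several hundred samples.
#'
#' @param nSignalsPerClass signals per class (default 16).
#' @param signalLength samples per signal (default 32768).
#' @param seed master seed (default 1).
#' @return a [DatasetSpec-class].
#' @export
freiburgLikePreset <- function(nSignalsPerClass = 16L, signalLength = 32768L,
                               seed = 1L) {
    fs <- 256
    g <- function(sd, f, bw) gainForTargetSd(sd, f, bw, fs)
    datasetSpec(
        classes = list(
            classSpec("interictal", 8.0, 1.0,
                      amplitudeScale = g(1.0, 8.0, 1.0), noiseSd = 0.3),
            classSpec("ictal", 4.0, 1.0,
                      amplitudeScale = g(1.1, 4.0, 1.0), noiseSd = 0.3)),
        nSignalsPerClass = nSignalsPerClass,
        signalLength = signalLength,
        sampleRate = fs,
        seed = seed)
}
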