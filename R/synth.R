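# Synthetic replicate EI spectra with the statistical structure the EASI
# model assumes: channel intensities co-vary linearly through a single latent
# per-replicate factor (the effective instrument/ion-source state), plus
# additive measurement noise. Inter-laboratory differences are emulated by
# shifting the latent factor's mean; negatives are either spectrally distinct
# compounds or diastereomer-like compounds sharing every channel but with
# shifted abundance ratios on designated channel pairs.

#' Specification of the synthetic spectrum generator
#'
#' Each replicate draws a latent factor E ~ N(`latent_mean`, `latent_sd`)
#' and sets every channel's raw intensity to `alpha + slope * E` plus
#' N(0, `noise_sd`) measurement noise, floored at 0. Channels with slope 0
#' (the base peak) are constant up to noise. Negatives come in two kinds:
#' `distinct` (own channel set and intensity pattern, uncorrelated with the
#' positives) and `diastereomer` (the positive generative law with the first
#' channel of each designated pair multiplied by a ratio-shift factor).
#'
#' @param channels integer m/z values of the panel.
#' @param alpha mean raw intensity per channel (>= 0), on a scale where the
#'   base peak is 100.
#' @param slope intensity change per latent unit, per channel.
#' @param latent_mean,latent_sd latent factor distribution for this batch
#'   (instrument/lab state).
#' @param noise_sd additive measurement noise sd (raw intensity units; the
#'   base peak is 100, so units are ~% of base peak).
#' @param compound compound label stamped on generated spectra.
#' @param distinct_negative optional list with `channels`, `alpha`, `slope`
#'   and `compound` describing a spectrally distinct negative.
#' @param diastereomer optional list with `pairs` (list of c(mz_a, mz_b)),
#'   `factors` (> 0, multiplies channel `mz_a`'s intensity, shifting the
#'   a/b abundance ratio) and `compound`.
#' @return Object of class `generator_spec`.
#' @seealso [cocaine_like_spec()] for ready-made defaults.
#' @export
generator_spec <- function(channels, alpha, slope,
                           latent_mean = 0, latent_sd = 1, noise_sd = 0.5,
                           compound = "synthetic_positive",
                           distinct_negative = NULL, diastereomer = NULL) {
  channels <- as.integer(channels)
  stopifnot(length(channels) == length(alpha), length(alpha) == length(slope))
  if (anyDuplicated(channels)) stop("channels must be unique", call. = FALSE)
  if (any(alpha < 0)) stop("`alpha` must be >= 0", call. = FALSE)
  if (noise_sd < 0 || latent_sd < 0)
    stop("`noise_sd` and `latent_sd` must be >= 0", call. = FALSE)
  if (!is.null(diastereomer)) {
    stopifnot(is.list(diastereomer$pairs),
              length(diastereomer$factors) == length(diastereomer$pairs))
    if (any(diastereomer$factors <= 0))
      stop("diastereomer ratio-shift factors must be > 0", call. = FALSE)
    for (pr in diastereomer$pairs)
      if (!all(pr %in% channels))
        stop("diastereomer pair channels must belong to the panel", call. = FALSE)
  }
  structure(list(channels = channels, alpha = as.numeric(alpha),
                 slope = as.numeric(slope), latent_mean = latent_mean,
                 latent_sd = latent_sd, noise_sd = noise_sd,
                 compound = compound, distinct_negative = distinct_negative,
                 diastereomer = diastereomer),
            class = "generator_spec")
}

#' Cocaine-like default generator specification
#'
#' A 20-channel panel with m/z values mimicking the major EI fragments of
#' cocaine (82, 182, 94, 96, 105, 152, 155, 198, 272, 303, ...) so that
#' examples read naturally; the intensities and slopes are arbitrary
#' synthetic values, not measured cocaine data. The base peak (m/z 82) is
#' constant (slope 0); the fragments at m/z 77, 94 and 105 anticorrelate
#' with the rest (negative slopes), the others co-vary positively with the
#' latent instrument state. Slope magnitudes are chosen so that pairwise
#' correlations between varying channels typically exceed 0.9 at the default
#' noise level, as observed between normalized fragment pairs in replicate
#' EI spectra. The diastereomer-like negative shifts the 94/96 abundance
#' ratio down (factor 0.55) and the 152/155 ratio up (factor 1.5); the
#' distinct negative has a permuted, uncorrelated intensity pattern.
#'
#' @param noise_sd measurement noise sd (% of base peak), default 0.5.
#' @return A [generator_spec()].
#' @export
cocaine_like_spec <- function(noise_sd = 0.5) {
  channels <- c(82L, 182L, 94L, 83L, 77L, 105L, 42L, 96L, 303L, 272L,
                198L, 97L, 55L, 51L, 152L, 155L, 122L, 166L, 68L, 119L)
  alpha <- c(100, 55, 32, 30, 28, 26, 24, 14, 12, 11,
             10, 9.5, 9, 8.5, 8, 7, 6.5, 6, 5.5, 5)
  slope <- c(0, 6, -3, 2.5, -2.8, -2.6, 2.2, 2, 2.4, 2.2,
             2.1, 2, 2, 2, 2.2, 2, 2, 2, 2, 2)
  generator_spec(
    channels = channels, alpha = alpha, slope = slope,
    latent_mean = 0, latent_sd = 1, noise_sd = noise_sd,
    compound = "synthetic_cocaine",
    distinct_negative = list(
      channels = c(43L, 58L, 82L, 91L, 115L, 146L, 179L, 210L, 241L, 268L),
      alpha = c(100, 70, 45, 40, 30, 22, 15, 10, 8, 5),
      slope = c(0, 3, -2, 2.5, 2, -2.2, 2, 2, 2, 2),
      compound = "synthetic_distinct_negative"),
    diastereomer = list(
      pairs = list(c(94L, 96L), c(152L, 155L)),
      factors = c(0.55, 1.5),
      compound = "synthetic_pseudococaine"))
}

# Draw n replicates from a linear-latent generative law.
draw_replicates <- function(channels, alpha, slope, latent_mean, latent_sd,
                            noise_sd, n, compound, truth, source, id_prefix,
                            ratio_factors = NULL) {
  k <- length(channels)
  lapply(seq_len(n), function(i) {
    E <- rnorm(1, latent_mean, latent_sd)
    intensity <- alpha + slope * E + rnorm(k, 0, noise_sd)
    if (!is.null(ratio_factors)) intensity <- intensity * ratio_factors
    intensity <- pmax(intensity, 0)
    raw_spectrum(mz = channels, intensity = intensity,
                 spectrum_id = sprintf("%s_%04d", id_prefix, i),
                 compound = compound, truth = truth, source = source)
  })
}

#' Simulate replicate spectra of the target compound
#'
#' Draws `n` known-positive replicates under the generator's law for the
#' training laboratory (latent mean as specified). Deterministic under a
#' fixed seed.
#'
#' @param spec a [generator_spec()].
#' @param n number of replicates (>= 1).
#' @param seed integer seed (NULL uses the current RNG stream).
#' @param source source label stamped on the spectra.
#' @param id_prefix prefix for generated spectrum ids.
#' @return List of [raw_spectrum()] objects labeled `known_positive`.
#' @export
simulate_replicates <- function(spec, n, seed = NULL, source = "lab1",
                                id_prefix = "train") {
  stopifnot(inherits(spec, "generator_spec"), n >= 1)
  with_seed(seed, draw_replicates(
    spec$channels, spec$alpha, spec$slope, spec$latent_mean, spec$latent_sd,
    spec$noise_sd, n, spec$compound, "known_positive", source, id_prefix))
}

#' Simulate replicates from a laboratory with a shifted instrument state
#'
#' Identical generative law with the latent factor's mean offset by
#' `delta` (in latent units; the training latent sd is 1 by default, so
#' `delta` reads as training standard deviations). Emulates known-positive
#' spectra collected on different instruments or in different laboratories.
#'
#' @param spec a [generator_spec()].
#' @param delta latent-mean offset.
#' @param n number of replicates.
#' @param seed integer seed.
#' @param source,id_prefix labels for the generated spectra.
#' @return List of [raw_spectrum()] objects labeled `known_positive`.
#' @export
simulate_lab_shift <- function(spec, delta, n, seed = NULL, source = "lab2",
                               id_prefix = "shift") {
  stopifnot(inherits(spec, "generator_spec"), n >= 1)
  with_seed(seed, draw_replicates(
    spec$channels, spec$alpha, spec$slope, spec$latent_mean + delta,
    spec$latent_sd, spec$noise_sd, n, spec$compound, "known_positive",
    source, id_prefix))
}

#' Simulate known-negative spectra
#'
#' `kind = "distinct"` draws from the spec's distinct-negative pattern
#' (different channels/intensities, uncorrelated with the positives).
#' `kind = "diastereomer"` draws from the positive generative law and then
#' multiplies the first channel of each designated pair by its ratio-shift
#' factor, emulating stereoisomers that share every fragment but differ in
#' a few abundance ratios; with all factors at 1 the output is
#' distributionally identical to the positives.
#'
#' @param spec a [generator_spec()] carrying the requested negative spec.
#' @param kind `"distinct"` or `"diastereomer"`.
#' @param n number of spectra.
#' @param seed integer seed.
#' @param source,id_prefix labels for the generated spectra.
#' @return List of [raw_spectrum()] objects labeled `known_negative`.
#' @export
simulate_negatives <- function(spec, kind = c("distinct", "diastereomer"),
                               n, seed = NULL, source = "lab1",
                               id_prefix = NULL) {
  kind <- match.arg(kind)
  stopifnot(inherits(spec, "generator_spec"), n >= 1)
  if (kind == "distinct") {
    dn <- spec$distinct_negative
    if (is.null(dn)) stop("spec has no distinct-negative specification", call. = FALSE)
    id_prefix <- id_prefix %||% "neg"
    with_seed(seed, draw_replicates(
      as.integer(dn$channels), dn$alpha, dn$slope, spec$latent_mean,
      spec$latent_sd, spec$noise_sd, n, dn$compound %||% "distinct_negative",
      "known_negative", source, id_prefix))
  } else {
    dia <- spec$diastereomer
    if (is.null(dia)) stop("spec has no diastereomer specification", call. = FALSE)
    id_prefix <- id_prefix %||% "dia"
    factors <- rep(1, length(spec$channels))
    for (j in seq_along(dia$pairs))
      factors[spec$channels == dia$pairs[[j]][1]] <- dia$factors[j]
    with_seed(seed, draw_replicates(
      spec$channels, spec$alpha, spec$slope, spec$latent_mean, spec$latent_sd,
      spec$noise_sd, n, dia$compound %||% "diastereomer", "known_negative",
      source, id_prefix, ratio_factors = factors))
  }
}
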