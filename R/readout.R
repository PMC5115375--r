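#' Threshold decoding configuration
#'
#' Both fluorescence channels are decoded at the same constant threshold of
#' 0.4 (normalized units). Under the positive logic convention a signal above
#' the threshold reads as bit 1; under the negative convention the assignment
#' is reversed (high signal reads as 0), which is how the digital comparator
#' is obtained from the half-subtractor platform.
#'
#' @param threshold Decision threshold in (0, 1), default 0.4.
#' @param strict Bit is 1 iff intensity is strictly above the threshold
#'   (default `TRUE`). With `strict = FALSE` an intensity exactly at the
#'   threshold still decodes as 1 but is flagged ambiguous.
#' @param convention `"positive"` or `"negative"`.
#' @return A list of class `decode_config`.
#' @export
decode_config <- function(threshold = 0.4, strict = TRUE,
                          convention = c("positive", "negative")) {
  stopifnot(threshold > 0, threshold < 1)
  convention <- match.arg(convention)
  structure(
    list(threshold = threshold, strict = strict, convention = convention),
    class = "decode_config"
  )
}

#' Fluorescence noise configuration
#'
#' Used only when emulating experimental readouts (fixtures): the closed
#' beacon leaks a small residual FAM fraction, and both channels get
#' multiplicative Gaussian noise. Noiseless simulation (the default
#' elsewhere) uses leak 0 and no noise.
#'
#' @param fam_leak Residual closed-beacon FAM fraction (default 0.10); must
#'   stay below the decoding threshold.
#' @param sd Multiplicative noise standard deviation (default 0.05).
#' @param seed Optional integer seed applied when noise is drawn.
#' @return A list of class `noise_config`.
#' @export
noise_config <- function(fam_leak = 0.10, sd = 0.05, seed = NULL) {
  stopifnot(fam_leak >= 0, fam_leak < 0.4, sd >= 0)
  structure(
    list(fam_leak = fam_leak, sd = sd, seed = seed),
    class = "noise_config"
  )
}

#' Dual-channel intensities of a resolved state
#'
#' Structural normalization: the FAM channel reports beacon opening (1 when
#' the beacon is opened by a bound input, otherwise the leak fraction, 0
#' noiseless), and the NMM channel reports G-quadruplex assembly in units of
#' one G-4/NMM equivalent (the integer quadruplex count; 2 when two
#' equivalent complexes coexist). With a [noise_config()], both channels are
#' perturbed multiplicatively and clipped at zero.
#'
#' @param state An `mb_state` from [resolve_state()].
#' @param noise Optional [noise_config()]; `NULL` (default) is noiseless.
#' @return A one-row tibble with `fam_norm` and `nmm_norm`.
#' @export
channel_intensities <- function(state, noise = NULL) {
  leak <- if (is.null(noise)) 0 else noise$fam_leak
  fam <- if (isTRUE(state$beacon_open)) 1 else leak
  nmm <- as.numeric(state$g4_count)
  if (!is.null(noise)) {
    if (!is.null(noise$seed)) set.seed(noise$seed)
    fam <- max(0, fam * (1 + stats::rnorm(1, 0, noise$sd)))
    nmm <- max(0, nmm * (1 + stats::rnorm(1, 0, noise$sd)))
  }
  tibble::tibble(fam_norm = fam, nmm_norm = nmm)
}

#' Decode an intensity into a bit
#'
#' @param intensity Numeric vector of non-negative normalized intensities.
#' @param config A [decode_config()].
#' @return Integer vector of bits, with a logical `ambiguous` attribute
#'   marking intensities exactly at the threshold under `strict = FALSE`.
#' @examples
#' decode_bit(c(0.1, 2), decode_config()) # 0 1
#' @export
decode_bit <- function(intensity, config = decode_config()) {
  stopifnot(all(intensity >= 0))
  at <- intensity == config$threshold
  high <- if (config$strict) {
    intensity > config$threshold
  } else {
    intensity >= config$threshold
  }
  bit <- as.integer(if (config$convention == "positive") high else !high)
  attr(bit, "ambiguous") <- !config$strict & at
  bit
}
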