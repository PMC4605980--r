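#' Default chemical-shift axis
#'
#' Uniform grid from 0.00 to 10.20 ppm with 16,384 points, a desk-scale
#' stand-in for an instrument acquisition grid. Any strictly monotone grid
#' is accepted by the rendering and processing functions.
#'
#' @param n number of points.
#' @param low,high ppm limits.
#' @return numeric vector of ppm values, ascending.
#' @export
default_ppm_axis <- function(n = 16384, low = 0, high = 10.2) {
  seq(low, high, length.out = n)
}

#' Construct a 1D NMR spectrum object
#'
#' @param ppm strictly monotone chemical-shift axis (ppm).
#' @param intensity real intensities, same length as `ppm`.
#' @param acquisition `"noesy"`, `"cpmg"` or `"diffusion-edited"`.
#' @param sample_id identifier string.
#' @return an object of class `nmr_spectrum`.
#' @export
nmr_spectrum <- function(ppm, intensity, acquisition = "noesy",
                         sample_id = "sample") {
  ppm <- as.numeric(ppm)
  intensity <- as.numeric(intensity)
  if (length(ppm) < 2L || length(ppm) != length(intensity)) {
    stop("`ppm` and `intensity` must be equal-length vectors (>= 2 points)",
         call. = FALSE)
  }
  d <- diff(ppm)
  if (!(all(d > 0) || all(d < 0))) {
    stop("`ppm` axis must be strictly monotone", call. = FALSE)
  }
  if (any(!is.finite(intensity))) {
    stop("intensities must be finite", call. = FALSE)
  }
  acquisition <- match.arg(acquisition,
                           c("noesy", "cpmg", "diffusion-edited"))
  structure(list(ppm = ppm, intensity = intensity,
                 acquisition = acquisition,
                 sample_id = as.character(sample_id)),
            class = "nmr_spectrum")
}

#' @export
print.nmr_spectrum <- function(x, ...) {
  cat(sprintf("<nmr_spectrum> %s [%s]: %d points, %.2f..%.2f ppm\n",
              x$sample_id, x$acquisition, length(x$ppm),
              min(x$ppm), max(x$ppm)))
  invisible(x)
}

#' Pulse-sequence component weights
#'
#' The three acquisition schemes are emulated by weighting peak
#' components: NOESY keeps small molecules and macromolecules alike, CPMG
#' attenuates macromolecules (weight 0.2), diffusion editing attenuates
#' small molecules (weight 0.1). Contaminant (Ficoll, water) and drug
#' peaks always carry weight 1 — the polymer's internal dynamics defeat
#' relaxation filtering, so no sequence removes it.
#'
#' @param acquisition `"noesy"`, `"cpmg"` or `"diffusion-edited"`.
#' @return named numeric vector of weights per component class.
#' @export
acquisition_weights <- function(acquisition) {
  acquisition <- match.arg(acquisition,
                           c("noesy", "cpmg", "diffusion-edited"))
  switch(acquisition,
    "noesy" = c("small-molecule" = 1, "macromolecule" = 1,
                "contaminant" = 1, "drug" = 1),
    "cpmg" = c("small-molecule" = 1, "macromolecule" = 0.2,
               "contaminant" = 1, "drug" = 1),
    "diffusion-edited" = c("small-molecule" = 0.1, "macromolecule" = 1,
                           "contaminant" = 1, "drug" = 1))
}

# line-shape evaluation; width is HWHM for both shapes, amplitude the
# height at the centre (lorentzian area = pi * amplitude * width)
eval_peak <- function(x, center, width, amplitude, shape) {
  if (shape == "lorentzian") {
    amplitude * width^2 / ((x - center)^2 + width^2)
  } else {
    amplitude * exp(-log(2) * (x - center)^2 / width^2)
  }
}

#' Render a peak table into a spectrum
#'
#' Sums component-weighted line shapes on the given axis and adds i.i.d.
#' gaussian noise.
#'
#' @param peaks a `peak_table`.
#' @param axis strictly monotone ppm grid.
#' @param acquisition spectrum type driving component weights.
#' @param noise_sd additive gaussian noise scale (>= 0).
#' @param seed RNG seed for the noise draw.
#' @param sample_id identifier recorded on the spectrum.
#' @return an `nmr_spectrum`.
#' @examples
#' sp <- render_spectrum(ficoll_contamination(1), default_ppm_axis(4096))
#' @export
render_spectrum <- function(peaks, axis = default_ppm_axis(),
                            acquisition = "noesy", noise_sd = 0,
                            seed = 1, sample_id = "sample") {
  if (length(axis) == 0L) stop("`axis` must be non-empty", call. = FALSE)
  d <- diff(axis)
  if (length(d) && !(all(d > 0) || all(d < 0))) {
    stop("`axis` must be strictly monotone", call. = FALSE)
  }
  stopifnot_scalar_number(noise_sd, "noise_sd", lower = 0)
  w <- acquisition_weights(acquisition)
  intensity <- numeric(length(axis))
  if (!is.null(peaks) && nrow(peaks) > 0L) {
    for (i in seq_len(nrow(peaks))) {
      amp <- peaks$amplitude[i] * w[[peaks$component[i]]]
      if (amp == 0) next
      intensity <- intensity +
        eval_peak(axis, peaks$center[i], peaks$width[i], amp,
                  peaks$shape[i])
    }
  }
  if (noise_sd > 0) {
    intensity <- intensity +
      with_seed(seed, stats::rnorm(length(axis), 0, noise_sd))
  }
  nmr_spectrum(axis, intensity, acquisition = acquisition,
               sample_id = sample_id)
}

#' Synthesize a free induction decay from a spectrum
#'
#' Inverse discrete Fourier transform of the intensity trace, producing a
#' complex time-domain signal whose forward processing
#' ([process_fid()] with zero line broadening) recovers the input spectrum
#' to numerical precision. With `n_points` larger than the spectrum the
#' FID is zero-filled, so processing returns the spectrum
#' Fourier-interpolated onto a finer grid over the same ppm range.
#'
#' @param spectrum an `nmr_spectrum` on a uniform ppm grid.
#' @param n_points FID length (>= length of the spectrum).
#' @param sf spectrometer frequency in MHz, fixing the Hz/ppm conversion.
#' @return an object of class `nmr_fid` with fields `signal` (complex),
#'   `dwell_time` (s), `spectral_width` (Hz) plus the axis metadata needed
#'   to reconstruct the ppm grid.
#' @export
synthesize_fid <- function(spectrum, n_points = length(spectrum$ppm),
                           sf = 600.13) {
  stopifnot(inherits(spectrum, "nmr_spectrum"))
  n <- length(spectrum$ppm)
  if (!is.numeric(n_points) || length(n_points) != 1L || n_points < n) {
    stop("`n_points` must be >= length of the spectrum", call. = FALSE)
  }
  n_points <- as.integer(n_points)
  step <- diff(spectrum$ppm)
  if (max(abs(step - step[1])) > 1e-9 * abs(step[1])) {
    stop("`spectrum` must sit on a uniform ppm grid", call. = FALSE)
  }
  intensity <- spectrum$intensity
  ppm_min <- min(spectrum$ppm)
  if (step[1] < 0) intensity <- rev(intensity)
  sw_hz <- n * abs(step[1]) * sf
  signal <- stats::fft(as.complex(intensity), inverse = TRUE) / n
  if (n_points > n) signal <- c(signal, complex(real = rep(0, n_points - n)))
  structure(list(signal = signal,
                 dwell_time = 1 / sw_hz,
                 spectral_width = sw_hz,
                 sf = sf,
                 ppm_min = ppm_min,
                 n_native = n,
                 acquisition = spectrum$acquisition,
                 sample_id = spectrum$sample_id),
            class = "nmr_fid")
}

#' @export
print.nmr_fid <- function(x, ...) {
  cat(sprintf("<nmr_fid> %s: %d complex points, sw %.1f Hz\n",
              x$sample_id, length(x$signal), x$spectral_width))
  invisible(x)
}
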