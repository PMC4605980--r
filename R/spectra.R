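#' Process a free induction decay into a spectrum
#'
#' Multiplies the time-domain signal by a decaying exponential equivalent
#' to the requested line-broadening factor, Fourier transforms it, and
#' returns the real part on the ppm axis carried by the FID metadata.
#' The default 1.0 Hz broadening is the conventional choice for 1D plasma
#' profiling; zero broadening makes processing the exact inverse of
#' [synthesize_fid()].
#'
#' @param fid an `nmr_fid`.
#' @param line_broadening exponential line broadening in Hz (>= 0).
#' @return an `nmr_spectrum`.
#' @export
process_fid <- function(fid, line_broadening = 1.0) {
  stopifnot(inherits(fid, "nmr_fid"))
  stopifnot_scalar_number(line_broadening, "line_broadening", lower = 0)
  n <- length(fid$signal)
  t <- (seq_len(n) - 1) * fid$dwell_time
  apod <- exp(-pi * line_broadening * t)
  intensity <- Re(stats::fft(fid$signal * apod))
  step <- fid$spectral_width / (fid$sf * n)
  ppm <- fid$ppm_min + (seq_len(n) - 1) * step
  nmr_spectrum(ppm, intensity, acquisition = fid$acquisition,
               sample_id = fid$sample_id)
}

#' Calibrate the chemical-shift axis on a reference signal
#'
#' Locates the reference feature inside `reference_ppm +/- search_window`
#' and shifts the whole axis so its centre sits at `reference_ppm`. The
#' default target is the glucose anomeric doublet at 5.24 ppm; the
#' locator is doublet-aware, taking the intensity-weighted centroid of
#' the two tallest local maxima in the window (falling back to the single
#' tallest). Intensities are untouched, and the operation is idempotent.
#'
#' @param spectrum an `nmr_spectrum`.
#' @param reference_ppm target chemical shift of the reference feature.
#' @param search_window half-width of the search window, ppm.
#' @return the calibrated `nmr_spectrum`, with the applied shift in
#'   attribute `"shift"`.
#' @export
calibrate <- function(spectrum, reference_ppm = 5.24,
                      search_window = 0.05) {
  stopifnot(inherits(spectrum, "nmr_spectrum"))
  ppm <- spectrum$ppm
  y <- spectrum$intensity
  sel <- which(abs(ppm - reference_ppm) <= search_window)
  if (length(sel) < 3L) {
    stop(errorCondition(
      sprintf("calibration window %.3f +/- %.3f ppm outside spectrum",
              reference_ppm, search_window),
      class = c("calibration_failure", "error", "condition")))
  }
  yw <- y[sel]
  # strict local maxima within the window
  is_max <- which(diff(sign(diff(yw))) == -2) + 1L
  floor_level <- stats::median(yw) + 5 * stats::mad(y)
  is_max <- is_max[yw[is_max] > floor_level]
  if (length(is_max) == 0L) {
    stop(errorCondition(
      sprintf("no reference peak above the noise floor near %.2f ppm",
              reference_ppm),
      class = c("calibration_failure", "error", "condition")))
  }
  ord <- order(yw[is_max], decreasing = TRUE)
  top <- is_max[ord[seq_len(min(2L, length(is_max)))]]
  found <- stats::weighted.mean(ppm[sel][top], yw[top])
  shift <- reference_ppm - found
  out <- nmr_spectrum(ppm + shift, y, acquisition = spectrum$acquisition,
                      sample_id = spectrum$sample_id)
  attr(out, "shift") <- shift
  out
}

# cumulative-trapezoid helper on the grid refined with the given cut
# points; returns the integral between consecutive cuts. Inserting
# linearly interpolated points leaves the trapezoidal integral unchanged,
# so the bin values are exactly additive.
segment_integrals <- function(ppm, intensity, cuts) {
  if (ppm[1] > ppm[length(ppm)]) {
    ppm <- rev(ppm); intensity <- rev(intensity)
  }
  lo <- cuts[1]; hi <- cuts[length(cuts)]
  tol <- 1e-9 * max(abs(lo), abs(hi), 1)
  if (ppm[1] > lo + tol || ppm[length(ppm)] < hi - tol) {
    stop("spectrum does not cover the requested ppm range", call. = FALSE)
  }
  inner <- ppm[ppm > lo & ppm < hi]
  xs <- sort(unique(c(inner, cuts)))
  ys <- stats::approx(ppm, intensity, xout = xs, rule = 2)$y
  n <- length(xs)
  ct <- c(0, cumsum((xs[-1] - xs[-n]) * (ys[-1] + ys[-n]) / 2))
  idx <- match(cuts, xs)
  diff(ct[idx])
}

#' Segment a spectrum into fixed-width chemical-shift bins
#'
#' Divides `[low, high)` into `round((high - low) / width)` left-closed,
#' right-open bins of the given width and integrates the intensity over
#' each by the trapezoidal rule on the native grid (with linear
#' interpolation at bin edges, so the bins sum exactly to the integral
#' over the whole range). The conventional profiling grid — 0.20 to
#' 10.00 ppm at 0.02 ppm — yields 490 bins.
#'
#' @param spectrum an `nmr_spectrum` covering `[low, high]`.
#' @param low,high bucketed range, ppm.
#' @param width bin width, ppm.
#' @return a list of class `bucket_vector`: `values`, `centers`, `width`.
#' @export
bucket <- function(spectrum, low = 0.20, high = 10.00, width = 0.02) {
  stopifnot(inherits(spectrum, "nmr_spectrum"))
  if (!(low < high)) stop("`low` must be < `high`", call. = FALSE)
  stopifnot_scalar_number(width, "width", lower = 0, strict = TRUE)
  n_bins <- round((high - low) / width)
  if (n_bins < 1L) stop("range narrower than one bin", call. = FALSE)
  edges <- low + (0:n_bins) * width
  values <- segment_integrals(spectrum$ppm, spectrum$intensity, edges)
  structure(list(values = values,
                 centers = (edges[-1] + edges[-length(edges)]) / 2,
                 width = width),
            class = "bucket_vector")
}

#' Drop bins inside excluded chemical-shift regions
#'
#' Removes every bin whose centre lies strictly inside any `(low, high)`
#' interval — by default the 3.30-6.00 ppm window holding residual water
#' and the Ficoll contamination envelope. The order of the surviving bins
#' is preserved.
#'
#' @param buckets a `bucket_vector` from [bucket()].
#' @param ranges list of `c(low, high)` ppm intervals.
#' @return a reduced `bucket_vector` with an `excluded_ranges` field.
#' @export
exclude_regions <- function(buckets, ranges = list(c(3.30, 6.00))) {
  stopifnot(inherits(buckets, "bucket_vector"))
  if (length(ranges) && !is.list(ranges)) ranges <- list(ranges)
  for (r in ranges) {
    if (length(r) != 2L || r[1] >= r[2]) {
      stop("each exclusion range must be c(low, high) with low < high",
           call. = FALSE)
    }
  }
  drop <- rep(FALSE, length(buckets$centers))
  for (r in ranges) {
    drop <- drop | (buckets$centers > r[1] & buckets$centers < r[2])
  }
  if (all(drop)) {
    warning("all bins excluded", call. = FALSE)
  }
  structure(list(values = buckets$values[!drop],
                 centers = buckets$centers[!drop],
                 width = buckets$width,
                 excluded_ranges = ranges),
            class = "bucket_vector")
}

#' Total-area normalization
#'
#' Divides a bucket vector by its sum, removing dilution and overall
#' intensity differences between samples; the result sums to 1 and is
#' scale-invariant.
#'
#' @param values numeric bucket values (or a `bucket_vector`).
#' @return the normalized object, same shape as the input.
#' @export
normalize_total_area <- function(values) {
  if (inherits(values, "bucket_vector")) {
    values$values <- normalize_total_area(values$values)
    return(values)
  }
  s <- sum(values)
  if (!is.finite(s) || s <= 0) {
    stop(errorCondition("total area is not positive; cannot normalize",
                        class = c("normalization_failure", "error",
                                  "condition")))
  }
  values / s
}

#' Integrate a spectral region
#'
#' Trapezoidal integral of the intensity over `[low, high]` on the native
#' grid, used to quantify resolved metabolite signals.
#'
#' @param spectrum an `nmr_spectrum`.
#' @param region `c(low, high)` in ppm, inside the spectral window.
#' @return the signal area (scalar).
#' @export
integrate_signal <- function(spectrum, region) {
  stopifnot(inherits(spectrum, "nmr_spectrum"))
  if (length(region) != 2L || region[1] >= region[2]) {
    stop("`region` must be c(low, high) with low < high", call. = FALSE)
  }
  segment_integrals(spectrum$ppm, spectrum$intensity, region)
}

#' Build a samples-by-bins bucket matrix
#'
#' Applies, per spectrum: optional chemical-shift calibration, bucketing
#' over `[low, high)`, exclusion of contaminated regions, and (by
#' default) total-area normalization over the retained bins. All spectra
#' must share one acquisition type; rows keep the input order.
#'
#' @param spectra list of `nmr_spectrum` (same acquisition type).
#' @param low,high,width bucketing parameters, ppm.
#' @param exclude list of `(low, high)` exclusion intervals.
#' @param calibrate_ppm reference shift for calibration, or `NULL` to
#'   skip.
#' @param normalize apply total-area normalization per row.
#' @return an object of class `bucket_matrix`: `values`
#'   (samples x bins matrix), `bin_centers`, `bin_width`,
#'   `excluded_ranges`, `normalized`, `acquisition`, `sample_ids`.
#' @export
build_bucket_matrix <- function(spectra, low = 0.20, high = 10.00,
                                width = 0.02,
                                exclude = list(c(3.30, 6.00)),
                                calibrate_ppm = NULL,
                                normalize = TRUE) {
  if (length(spectra) == 0L) stop("`spectra` is empty", call. = FALSE)
  if (inherits(spectra, "nmr_spectrum")) spectra <- list(spectra)
  acqs <- unique(vapply(spectra, `[[`, character(1), "acquisition"))
  if (length(acqs) != 1L) {
    stop("all spectra must share one acquisition type; got: ",
         paste(acqs, collapse = ", "), call. = FALSE)
  }
  rows <- lapply(spectra, function(sp) {
    if (!is.null(calibrate_ppm)) sp <- calibrate(sp, calibrate_ppm)
    b <- bucket(sp, low = low, high = high, width = width)
    b <- exclude_regions(b, exclude)
    if (normalize) b <- normalize_total_area(b)
    b
  })
  values <- do.call(rbind, lapply(rows, `[[`, "values"))
  ids <- unname(vapply(spectra, `[[`, character(1), "sample_id"))
  rownames(values) <- ids
  colnames(values) <- sprintf("%.2f", rows[[1]]$centers)
  structure(list(values = values, bin_centers = rows[[1]]$centers,
                 bin_width = width, excluded_ranges = exclude,
                 normalized = isTRUE(normalize), acquisition = acqs,
                 sample_ids = ids),
            class = "bucket_matrix")
}

#' @export
print.bucket_matrix <- function(x, ...) {
  cat(sprintf(
    "<bucket_matrix> %d samples x %d bins (%.2f ppm, %s, %snormalized)\n",
    nrow(x$values), ncol(x$values), x$bin_width, x$acquisition,
    if (x$normalized) "" else "not "))
  invisible(x)
}

#' Write a bucket matrix as CSV with a JSON parameter sidecar
#'
#' @param bm a `bucket_matrix`.
#' @param path CSV path; the sidecar is written next to it as
#'   `<path>.json`.
#' @return invisibly, the two paths.
#' @export
write_bucket_matrix <- function(bm, path) {
  stopifnot(inherits(bm, "bucket_matrix"))
  utils::write.csv(data.frame(sample_id = bm$sample_ids, bm$values,
                              check.names = FALSE),
                   path, row.names = FALSE)
  side <- paste0(path, ".json")
  jsonlite::write_json(list(bin_width = bm$bin_width,
                            excluded_ranges = bm$excluded_ranges,
                            normalized = bm$normalized,
                            acquisition = bm$acquisition),
                       side, auto_unbox = TRUE, digits = NA)
  invisible(c(path, side))
}

#' Read one Bruker processed 1D spectrum
#'
#' Adapter for the vendor directory layout holding `1r` (real processed
#' points, 32-bit integers scaled by `2^NC_proc`) and the `procs`
#' parameter file (`OFFSET`, `SW_p`, `SF`, `SI`, `BYTORDP`).
#'
#' @param dir directory containing `1r` and `procs`.
#' @param acquisition acquisition tag to record.
#' @param sample_id identifier; defaults to the directory name.
#' @return an `nmr_spectrum` with ascending ppm axis.
#' @export
read_bruker <- function(dir, acquisition = "noesy",
                        sample_id = basename(dir)) {
  procs <- file.path(dir, "procs")
  onr <- file.path(dir, "1r")
  if (!file.exists(procs) || !file.exists(onr)) {
    stop("not a Bruker processed-spectrum directory: ", dir, call. = FALSE)
  }
  lines <- readLines(procs, warn = FALSE)
  getp <- function(key) {
    ln <- grep(sprintf("^##\\$%s=", key), lines, value = TRUE)
    if (length(ln) == 0L) stop("missing procs parameter: ", key,
                               call. = FALSE)
    as.numeric(sub(sprintf("^##\\$%s=\\s*", key), "", ln[1]))
  }
  si <- as.integer(getp("SI"))
  endian <- if (getp("BYTORDP") == 0) "little" else "big"
  raw <- readBin(onr, what = "integer", n = si, size = 4L,
                 endian = endian)
  intensity <- raw * 2^getp("NC_proc")
  offset <- getp("OFFSET")          # ppm of the first (leftmost) point
  sw_ppm <- getp("SW_p") / getp("SF")
  ppm <- offset - (seq_len(si) - 1) * sw_ppm / si
  nmr_spectrum(rev(ppm), rev(intensity), acquisition = acquisition,
               sample_id = sample_id)
}
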