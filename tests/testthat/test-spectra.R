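test_that("FID synthesis and processing are exact inverses at zero broadening", {
  lib <- make_metabolite_library(20, seed = 1)
  sp <- render_spectrum(lib, default_ppm_axis(4096), noise_sd = 0)
  fid <- synthesize_fid(sp)
  back <- process_fid(fid, line_broadening = 0)
  expect_equal(back$ppm, sp$ppm, tolerance = 1e-12)
  expect_lt(max(abs(back$intensity - sp$intensity)),
            1e-8 * max(abs(sp$intensity)))

  zero <- nmr_spectrum(default_ppm_axis(256), rep(0, 256))
  zfid <- synthesize_fid(zero)
  expect_true(all(Mod(zfid$signal) == 0))
  expect_true(all(process_fid(zfid, 0)$intensity == 0))

  expect_error(synthesize_fid(sp, n_points = 10), ">=")
  expect_error(process_fid(fid, -1), ">=")
})

test_that("exponential apodization broadens lines and conserves the integral", {
  axis <- default_ppm_axis(16384)
  sp <- render_spectrum(peak_table(center = 5.0, width = 0.002,
                                   amplitude = 1), axis)
  fid <- synthesize_fid(sp)
  lb <- process_fid(fid, line_broadening = 1.0)
  # total (periodic-domain) integral conserved to 1e-6 relative
  step <- diff(sp$ppm)[1]
  expect_equal(sum(lb$intensity) * step, sum(sp$intensity) * step,
               tolerance = 1e-6)
  fwhm <- function(s) {  # interpolated half-height crossings
    half <- max(s$intensity) / 2
    above <- which(s$intensity > half)
    i1 <- min(above); i2 <- max(above)
    cross <- function(ia, ib) {
      stats::approx(s$intensity[c(ia, ib)], s$ppm[c(ia, ib)],
                    xout = half)$y
    }
    cross(i2, i2 + 1) - cross(i1 - 1, i1)
  }
  sf <- 600.13
  widen_hz <- (fwhm(lb) - fwhm(sp)) * sf
  expect_equal(widen_hz, 1.0, tolerance = 0.1)
  expect_lt(max(lb$intensity), max(sp$intensity))
})

test_that("calibration shifts the axis onto the reference doublet", {
  axis <- default_ppm_axis(16384)
  doublet <- peak_table(center = c(5.254, 5.266), width = 0.003,
                        amplitude = 2)
  sp <- render_spectrum(doublet, axis)  # centred at 5.26
  cal <- calibrate(sp, reference_ppm = 5.24, search_window = 0.05)
  expect_equal(attr(cal, "shift"), -0.02, tolerance = 1e-3)
  expect_identical(cal$intensity, sp$intensity)

  again <- calibrate(cal, reference_ppm = 5.24, search_window = 0.05)
  expect_equal(attr(again, "shift"), 0, tolerance = 1e-9)
  expect_equal(again$ppm, cal$ppm, tolerance = 1e-9)

  flat <- nmr_spectrum(axis, rep(1, length(axis)))
  expect_error(calibrate(flat), class = "calibration_failure")
})

test_that("bucketing yields the documented grid and conserves area", {
  axis <- default_ppm_axis(8192)
  sp <- render_spectrum(make_metabolite_library(20, 1), axis,
                        noise_sd = 0.01, seed = 3)
  b <- bucket(sp, 0.20, 10.00, 0.02)
  expect_length(b$values, 490L)
  expect_equal(b$centers[1], 0.21)
  # oracle: trapezoid over [0.20, 10.00] with interpolated endpoints
  inside <- axis > 0.2 & axis < 10
  xo <- c(0.2, axis[inside], 10)
  yo <- approx(axis, sp$intensity, xout = xo)$y
  expect_equal(sum(b$values), trapz(xo, yo), tolerance = 1e-9)

  flat <- nmr_spectrum(axis, rep(3, length(axis)))
  bf <- bucket(flat, 0.20, 10.00, 0.02)
  expect_equal(bf$values, rep(3 * 0.02, 490), tolerance = 1e-12)

  narrow <- nmr_spectrum(seq(2, 3, length.out = 100), rep(1, 100))
  expect_error(bucket(narrow, 0.2, 10), "cover")
})

test_that("exclusion by bin centre matches brute-force membership", {
  axis <- default_ppm_axis(8192)
  sp <- render_spectrum(make_metabolite_library(20, 1), axis)
  b <- bucket(sp, 0.20, 10.00, 0.02)
  ex <- exclude_regions(b, list(c(3.30, 6.00)))
  keep <- brute_force_retained(0.20, 10.00, 0.02, list(c(3.30, 6.00)))
  expect_length(ex$values, sum(keep))
  expect_equal(length(b$values) - length(ex$values), 135L)
  expect_equal(ex$values, b$values[keep])
  expect_equal(ex$centers, b$centers[keep])

  # composite ranges agree with brute force too
  rngs <- list(c(0.5, 1.1), c(4.4, 4.5), c(9.0, 9.7))
  keep2 <- brute_force_retained(0.20, 10.00, 0.02, rngs)
  ex2 <- exclude_regions(b, rngs)
  expect_equal(ex2$values, b$values[keep2])

  expect_identical(exclude_regions(b, list())$values, b$values)
  expect_warning(exclude_regions(b, list(c(0.1, 10.1))), "all bins")
  expect_error(exclude_regions(b, list(c(6, 3))), "low < high")
})

test_that("total-area normalization is exact, scale-invariant and idempotent", {
  expect_equal(normalize_total_area(c(1, 3)), c(0.25, 0.75))
  v <- abs(rnorm(50)) + 0.1
  nv <- normalize_total_area(v)
  expect_equal(sum(nv), 1, tolerance = 1e-12)
  expect_equal(normalize_total_area(7 * v), nv)
  expect_equal(normalize_total_area(nv), nv)
  expect_error(normalize_total_area(rep(0, 5)),
               class = "normalization_failure")
})

test_that("signal integration is additive and matches the Lorentzian area", {
  axis <- default_ppm_axis(8192)
  flat <- nmr_spectrum(axis, rep(1, length(axis)))
  expect_equal(integrate_signal(flat, c(2.0, 2.1)), 0.1,
               tolerance = 1e-9)
  expect_equal(integrate_signal(flat, c(2.0, 2.1)) +
                 integrate_signal(flat, c(2.1, 2.3)),
               integrate_signal(flat, c(2.0, 2.3)), tolerance = 1e-12)

  pk <- peak_table(center = 5.0, width = 0.01, amplitude = 2)
  sp <- render_spectrum(pk, axis)
  # full-width integral approaches pi * amplitude * HWHM
  expect_equal(integrate_signal(sp, c(3.0, 7.0)), pi * 2 * 0.01,
               tolerance = 0.01)
  expect_error(integrate_signal(sp, c(3, 2)), "low < high")
})

test_that("bucket matrices assemble with exclusion and normalization metadata", {
  d <- quick_design(n_subjects_per_group = c(4, 3), paired = FALSE,
                    seed = 11, axis_points = 8192)
  coh <- simulate_cohort(d)
  bm <- build_bucket_matrix(coh$spectra, calibrate_ppm = 5.24)
  expect_equal(dim(bm$values), c(7L, 355L))
  expect_true(bm$normalized)
  expect_equal(unname(rowSums(bm$values)), rep(1, 7), tolerance = 1e-9)
  expect_identical(bm$sample_ids, coh$annotation$sample_id)
  expect_false(any(bm$bin_centers > 3.30 & bm$bin_centers < 6.00))

  one <- build_bucket_matrix(coh$spectra[1])
  expect_equal(nrow(one$values), 1L)
  expect_error(build_bucket_matrix(list()), "empty")
  mixed <- coh$spectra[1:2]
  mixed[[2]]$acquisition <- "noesy"
  expect_error(build_bucket_matrix(mixed), "acquisition")
})

test_that("the Bruker adapter reads a processed-spectrum directory", {
  dir <- withr::local_tempdir()
  si <- 1024L
  # synthetic vendor layout: 32-bit integer 1r + procs parameters
  ppm <- seq(10.0, by = -9.8 / si, length.out = si)
  intensity <- 1e4 * exp(-((ppm - 2.5) / 0.05)^2)
  writeBin(as.integer(round(intensity)), file.path(dir, "1r"),
           size = 4L, endian = "little")
  writeLines(c("##$SI= 1024", "##$OFFSET= 10.0", "##$SF= 600.13",
               sprintf("##$SW_p= %.4f", 9.8 * 600.13),
               "##$BYTORDP= 0", "##$NC_proc= -2"),
             file.path(dir, "procs"))
  sp <- read_bruker(dir, acquisition = "cpmg")
  expect_s3_class(sp, "nmr_spectrum")
  expect_length(sp$ppm, si)
  expect_true(all(diff(sp$ppm) > 0))
  expect_equal(sp$ppm[which.max(sp$intensity)], 2.5, tolerance = 0.02)
  expect_equal(max(sp$intensity), max(intensity) * 2^-2,
               tolerance = 1e-3)
  expect_error(read_bruker(withr::local_tempdir()), "Bruker")
})
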