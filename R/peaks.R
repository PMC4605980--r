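#' Construct a table of spectral peaks
#'
#' A peak table is the elementary description of a synthetic 1H-NMR
#' spectrum: each row is one resonance line with a centre (chemical shift),
#' a half-width at half-maximum, an amplitude (the line's maximum height),
#' a line shape and a physical component class. The component class drives
#' pulse-sequence weighting when the spectrum is rendered: small molecules
#' are attenuated in diffusion-edited spectra, macromolecules in CPMG
#' spectra, and contaminant/drug signals are never attenuated.
#'
#' @param center chemical shift of the line maximum, ppm (0 to 10.5).
#' @param width half-width at half-maximum, ppm (> 0).
#' @param amplitude line height, arbitrary units (>= 0).
#' @param shape `"lorentzian"` or `"gaussian"`.
#' @param component `"small-molecule"`, `"macromolecule"`, `"contaminant"`
#'   or `"drug"`.
#' @param metabolite optional label grouping peaks into one signal group.
#' @return a `data.frame` of class `peak_table` with one row per peak.
#' @examples
#' peak_table(center = 1.33, width = 0.005, amplitude = 1)
#' @export
peak_table <- function(center, width, amplitude,
                       shape = "lorentzian",
                       component = "small-molecule",
                       metabolite = NA_character_) {
  n <- max(length(center), length(width), length(amplitude))
  center <- rep_len(as.numeric(center), n)
  width <- rep_len(as.numeric(width), n)
  amplitude <- rep_len(as.numeric(amplitude), n)
  shape <- rep_len(as.character(shape), n)
  component <- rep_len(as.character(component), n)
  metabolite <- rep_len(as.character(metabolite), n)
  if (any(!is.finite(center)) || any(center < 0) || any(center > 10.5)) {
    stop("peak centers must lie in [0, 10.5] ppm", call. = FALSE)
  }
  if (any(!is.finite(width)) || any(width <= 0)) {
    stop("peak widths must be > 0", call. = FALSE)
  }
  if (any(!is.finite(amplitude)) || any(amplitude < 0)) {
    stop("peak amplitudes must be >= 0", call. = FALSE)
  }
  if (!all(shape %in% c("lorentzian", "gaussian"))) {
    stop("shape must be 'lorentzian' or 'gaussian'", call. = FALSE)
  }
  comps <- c("small-molecule", "macromolecule", "contaminant", "drug")
  if (!all(component %in% comps)) {
    stop("component must be one of: ", paste(comps, collapse = ", "),
         call. = FALSE)
  }
  out <- data.frame(metabolite = metabolite, center = center, width = width,
                    amplitude = amplitude, shape = shape,
                    component = component, stringsAsFactors = FALSE)
  class(out) <- c("peak_table", "data.frame")
  out
}

rbind_peaks <- function(...) {
  pieces <- Filter(function(p) !is.null(p) && nrow(p) > 0, list(...))
  if (length(pieces) == 0L) {
    return(peak_table(numeric(0), numeric(0), numeric(0))[0, ])
  }
  out <- do.call(rbind, lapply(pieces, as.data.frame))
  class(out) <- c("peak_table", "data.frame")
  rownames(out) <- NULL
  out
}

# Canonical plasma metabolite signal groups: name, peak positions (ppm),
# relative peak heights within the group, and line HWHM. Positions are the
# familiar resolved plasma resonances; the glucose anomeric doublet
# (2 lines straddling 5.24 ppm) doubles as the chemical-shift reference.
.metabolite_catalog <- function() {
  list(
    list(name = "lactate",           centers = c(1.330, 4.110), rel = c(1.0, 0.45), width = 0.005),
    list(name = "alanine",           centers = c(1.480),        rel = 1.0,          width = 0.005),
    list(name = "valine",            centers = c(0.990, 1.040), rel = c(1.0, 1.0),  width = 0.005),
    list(name = "leucine",           centers = c(0.960),        rel = 1.0,          width = 0.006),
    list(name = "isoleucine",        centers = c(0.940, 1.010), rel = c(1.0, 0.6),  width = 0.005),
    list(name = "glucose",           centers = c(5.234, 5.246), rel = c(1.0, 1.0),  width = 0.004),
    list(name = "glutamine",         centers = c(2.140, 2.450), rel = c(0.8, 1.0),  width = 0.006),
    list(name = "glutamate",         centers = c(2.080, 2.350), rel = c(0.8, 1.0),  width = 0.006),
    list(name = "citrate",           centers = c(2.540, 2.660), rel = c(1.0, 1.0),  width = 0.005),
    list(name = "creatinine",        centers = c(3.040, 4.060), rel = c(1.0, 0.7),  width = 0.004),
    list(name = "acetate",           centers = c(1.920),        rel = 1.0,          width = 0.004),
    list(name = "pyruvate",          centers = c(2.370),        rel = 1.0,          width = 0.004),
    list(name = "3-hydroxybutyrate", centers = c(1.200, 2.310), rel = c(1.0, 0.5),  width = 0.005),
    list(name = "glycine",           centers = c(3.560),        rel = 1.0,          width = 0.004),
    list(name = "histidine",         centers = c(7.050, 7.770), rel = c(1.0, 0.9),  width = 0.005),
    list(name = "tyrosine",          centers = c(6.890, 7.190), rel = c(1.0, 1.0),  width = 0.005),
    list(name = "phenylalanine",     centers = c(7.320, 7.420), rel = c(1.0, 0.8),  width = 0.005),
    list(name = "formate",           centers = c(8.460),        rel = 1.0,          width = 0.004),
    list(name = "threonine",         centers = c(1.320, 4.250), rel = c(0.9, 0.6),  width = 0.005),
    list(name = "proline",           centers = c(2.000, 4.120), rel = c(1.0, 0.6),  width = 0.006)
  )
}

#' Build a reproducible library of metabolite signal groups
#'
#' Returns the peak groups of quantifiable plasma metabolites used by the
#' cohort simulator. The default library holds twenty named small-molecule
#' signal groups at their familiar plasma chemical shifts; most have at
#' least one resolved peak outside the 3.30-6.00 ppm exclusion window, so
#' they survive contamination filtering. The seed applies a small
#' reproducible batch jitter (sd 0.002 ppm) to peak positions, emulating
#' run-to-run referencing variability.
#'
#' Requests beyond twenty metabolites append synthetic signal groups at
#' seed-determined positions.
#'
#' @param n_metabolites number of signal groups (>= 1).
#' @param seed integer seed; the same seed always yields the same library.
#' @return a `peak_table` with a `metabolite` label per row, carrying a
#'   `base_amplitude` attribute-free encoding: amplitudes are the unit
#'   heights used at relative concentration 1.
#' @examples
#' lib <- make_metabolite_library(20, seed = 1)
#' length(unique(lib$metabolite))
#' @export
make_metabolite_library <- function(n_metabolites = 20, seed = 1) {
  if (!is.numeric(n_metabolites) || length(n_metabolites) != 1L ||
      !is.finite(n_metabolites) || n_metabolites < 1) {
    stop("`n_metabolites` must be a positive count", call. = FALSE)
  }
  n_metabolites <- as.integer(n_metabolites)
  catalog <- .metabolite_catalog()
  with_seed(seed, {
    groups <- list()
    # fixed unit heights per group, spread over a realistic dynamic range
    heights <- rep(c(1.2, 0.8, 1.0, 0.6, 1.5, 2.0, 0.7, 0.9, 0.5, 0.8,
                     1.1, 0.6, 0.7, 0.9, 0.4, 0.5, 0.45, 0.35, 0.6, 0.7),
                   length.out = max(n_metabolites, 20L))
    for (i in seq_len(min(n_metabolites, length(catalog)))) {
      g <- catalog[[i]]
      jitter <- stats::rnorm(length(g$centers), 0, 0.002)
      groups[[i]] <- peak_table(
        center = g$centers + jitter,
        width = g$width,
        amplitude = heights[i] * g$rel,
        shape = "lorentzian",
        component = "small-molecule",
        metabolite = g$name
      )
    }
    if (n_metabolites > length(catalog)) {
      for (i in (length(catalog) + 1L):n_metabolites) {
        # synthetic extras placed in the uncrowded aliphatic/aromatic bands
        center <- stats::runif(1, 0, 1) * 2.8 + sample(c(0.3, 6.2), 1)
        groups[[i]] <- peak_table(
          center = center, width = 0.005,
          amplitude = heights[i],
          metabolite = sprintf("synthetic-%02d", i)
        )
      }
    }
    do.call(rbind_peaks, groups)
  })
}

#' Ficoll contamination peak model
#'
#' Plasma separated on a Ficoll density gradient carries polymer signals
#' that no pulse sequence filters out: one broad, intense envelope centred
#' at 3.80 ppm whose support lies within 3.30-4.64 ppm, plus five sharp
#' resonances at 1.81, 1.84, 2.26, 5.42 and 5.58 ppm. All six are tagged
#' `component = "contaminant"` so rendering never attenuates them,
#' whatever the acquisition scheme.
#'
#' @param intensity_scale nonnegative multiplier applied to all amplitudes
#'   (models batch-to-batch contamination variability).
#' @return a `peak_table` with 6 rows.
#' @examples
#' ficoll_contamination(1)
#' @export
ficoll_contamination <- function(intensity_scale = 1) {
  stopifnot_scalar_number(intensity_scale, "intensity_scale", lower = 0)
  envelope <- peak_table(center = 3.80, width = 0.18,
                         amplitude = 4.0 * intensity_scale,
                         shape = "gaussian", component = "contaminant",
                         metabolite = "ficoll-envelope")
  sharp <- peak_table(center = c(1.81, 1.84, 2.26, 5.42, 5.58),
                      width = 0.006,
                      amplitude = 0.6 * intensity_scale,
                      shape = "lorentzian", component = "contaminant",
                      metabolite = "ficoll-sharp")
  rbind_peaks(envelope, sharp)
}

#' Macromolecular plasma baseline peaks
#'
#' Broad lipoprotein/protein humps typical of plasma, tagged
#' `"macromolecule"` so CPMG rendering attenuates them and
#' diffusion-edited rendering retains them.
#'
#' @param intensity_scale nonnegative multiplier.
#' @return a `peak_table`.
#' @export
macromolecule_baseline <- function(intensity_scale = 1) {
  stopifnot_scalar_number(intensity_scale, "intensity_scale", lower = 0)
  peak_table(center = c(0.88, 1.28, 2.02, 2.78, 3.22),
             width = c(0.12, 0.15, 0.18, 0.20, 0.15),
             amplitude = intensity_scale * c(0.9, 1.2, 0.5, 0.35, 0.45),
             shape = "gaussian", component = "macromolecule",
             metabolite = "macromolecule")
}

#' Residual water signal
#'
#' One broad resonance at 4.70 ppm, inside the excluded window; tagged
#' contaminant so it survives every pulse sequence and exercises the
#' exclusion step.
#'
#' @param intensity_scale nonnegative multiplier.
#' @return a `peak_table` with one row.
#' @export
water_peak <- function(intensity_scale = 1) {
  stopifnot_scalar_number(intensity_scale, "intensity_scale", lower = 0)
  peak_table(center = 4.70, width = 0.10,
             amplitude = 3.0 * intensity_scale,
             shape = "gaussian", component = "contaminant",
             metabolite = "water")
}

#' Anesthesia-associated drug peaks
#'
#' Sharp cefuroxime-like resonances appearing only in post-anesthesia
#' samples; two of the three lie outside the exclusion window so the drug
#' signature survives filtering.
#'
#' @param intensity_scale nonnegative multiplier.
#' @return a `peak_table`.
#' @export
drug_peaks <- function(intensity_scale = 1) {
  stopifnot_scalar_number(intensity_scale, "intensity_scale", lower = 0)
  peak_table(center = c(3.46, 6.20, 6.88),
             width = 0.005,
             amplitude = intensity_scale * c(0.5, 0.4, 0.4),
             shape = "lorentzian", component = "drug",
             metabolite = "cefuroxime")
}

#' Default quantification regions of a metabolite library
#'
#' For each metabolite, the integration region around its tallest peak
#' lying outside the given exclusion ranges (metabolites whose every peak
#' falls inside the excluded window, such as glucose, are dropped — they
#' are not quantifiable in Ficoll-contaminated spectra).
#'
#' @param library a `peak_table` from [make_metabolite_library()].
#' @param excluded_ranges list of `c(low, high)` ppm intervals.
#' @param halfwidth integration half-width around the peak centre, ppm.
#' @return a `data.frame` with columns `metabolite`, `low`, `high`.
#' @export
quantification_regions <- function(library,
                                   excluded_ranges = list(c(3.30, 6.00)),
                                   halfwidth = 0.015) {
  stopifnot(inherits(library, "data.frame"))
  keep <- library$component == "small-molecule"
  lib <- library[keep, , drop = FALSE]
  out <- list()
  for (m in unique(lib$metabolite)) {
    pk <- lib[lib$metabolite == m, , drop = FALSE]
    excluded <- vapply(pk$center, function(cc) {
      any(vapply(excluded_ranges,
                 function(r) cc > r[1] && cc < r[2], logical(1)))
    }, logical(1))
    pk <- pk[!excluded, , drop = FALSE]
    if (nrow(pk) == 0L) next
    best <- pk[which.max(pk$amplitude), ]
    out[[m]] <- data.frame(metabolite = m,
                           low = best$center - halfwidth,
                           high = best$center + halfwidth,
                           stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
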