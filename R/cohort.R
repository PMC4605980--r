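#' Describe a synthetic plasma cohort
#'
#' A cohort design captures the statistical structure the downstream
#' analysis assumes: two (or more) disease groups, an optional paired
#' pre/post-anesthesia sampling of every subject, per-metabolite group
#' effects, a general post-anesthesia concentration decrease, drug peaks
#' present only after anesthesia, between-subject log-scale variability,
#' Ficoll contamination with per-subject intensity variability, and
#' additive spectral noise. The seed fully determines the cohort.
#'
#' @param n_subjects_per_group integer count or vector (recycled over
#'   groups); each >= 2. Default 40/30 matches a CRC/LC case mix.
#' @param groups group labels.
#' @param paired if `TRUE`, each subject is sampled pre and post
#'   anesthesia.
#' @param effect_table named list/vector of multiplicative group effects
#'   per metabolite, one sub-entry per non-reference group, e.g.
#'   `list(LC = c(lactate = 2))`. Factors must be > 0; the first group is
#'   the reference.
#' @param anesthesia_decrease multiplicative factor (<= 1 typically)
#'   applied to post-anesthesia concentrations; scalar or named
#'   per-metabolite vector. Default 0.85, a general moderate decrease.
#' @param drug_peak_table `peak_table` added only to post samples
#'   (default [drug_peaks()]); `NULL` for none.
#' @param subject_sd between-subject log-scale sd of concentrations.
#' @param noise_sd additive spectral noise sd.
#' @param ficoll_scale mean contamination intensity; `ficoll_sd` is its
#'   per-subject log-scale sd.
#' @param include_macromolecules,include_water,include_ficoll toggles for
#'   the non-metabolite spectral components.
#' @param acquisition spectrum type(s) to render per sample.
#' @param axis ppm grid for rendering.
#' @param library metabolite library; default
#'   `make_metabolite_library(20, seed)`.
#' @param seed master RNG seed.
#' @return an object of class `cohort_design`.
#' @export
cohort_design <- function(n_subjects_per_group = c(40, 30),
                          groups = c("CRC", "LC"),
                          paired = TRUE,
                          effect_table = NULL,
                          anesthesia_decrease = 0.85,
                          drug_peak_table = drug_peaks(),
                          subject_sd = 0.15,
                          noise_sd = 0.01,
                          ficoll_scale = 1,
                          ficoll_sd = 0.3,
                          include_macromolecules = TRUE,
                          include_water = TRUE,
                          include_ficoll = TRUE,
                          acquisition = "cpmg",
                          axis = default_ppm_axis(),
                          library = NULL,
                          seed = 1) {
  n <- rep_len(as.integer(n_subjects_per_group), length(groups))
  if (any(n < 2L)) stop("need >= 2 subjects per group", call. = FALSE)
  if (any(unlist(effect_table) <= 0)) {
    stop("group effects must be > 0", call. = FALSE)
  }
  if (any(anesthesia_decrease <= 0)) {
    stop("`anesthesia_decrease` must be > 0", call. = FALSE)
  }
  stopifnot_scalar_number(subject_sd, "subject_sd", lower = 0)
  stopifnot_scalar_number(noise_sd, "noise_sd", lower = 0)
  if (is.null(library)) library <- make_metabolite_library(20, seed = seed)
  acquisition <- match.arg(acquisition,
                           c("noesy", "cpmg", "diffusion-edited"),
                           several.ok = TRUE)
  structure(list(n_subjects_per_group = n, groups = as.character(groups),
                 paired = isTRUE(paired), effect_table = effect_table,
                 anesthesia_decrease = anesthesia_decrease,
                 drug_peak_table = drug_peak_table,
                 subject_sd = subject_sd, noise_sd = noise_sd,
                 ficoll_scale = ficoll_scale, ficoll_sd = ficoll_sd,
                 include_macromolecules = isTRUE(include_macromolecules),
                 include_water = isTRUE(include_water),
                 include_ficoll = isTRUE(include_ficoll),
                 acquisition = acquisition, axis = axis,
                 library = library, seed = as.integer(seed)),
            class = "cohort_design")
}

#' @export
print.cohort_design <- function(x, ...) {
  cat(sprintf("<cohort_design> groups %s (n = %s), %s, seed %d\n",
              paste(x$groups, collapse = "/"),
              paste(x$n_subjects_per_group, collapse = "/"),
              if (x$paired) "paired pre/post" else "unpaired", x$seed))
  invisible(x)
}

# expand a scalar-or-named effect over the metabolite set, validating names
expand_factor <- function(value, metabolites, what) {
  out <- stats::setNames(rep(1, length(metabolites)), metabolites)
  if (is.null(value)) return(out)
  if (is.null(names(value)) || all(names(value) == "")) {
    if (length(value) != 1L) {
      stop(sprintf("unnamed `%s` must be a scalar", what), call. = FALSE)
    }
    out[] <- value
    return(out)
  }
  unknown <- setdiff(names(value), metabolites)
  if (length(unknown)) {
    stop(sprintf("%s references unknown metabolite(s): %s", what,
                 paste(unknown, collapse = ", ")), call. = FALSE)
  }
  out[names(value)] <- value
  out
}

#' Simulate a plasma cohort
#'
#' Draws per-subject metabolite concentrations
#' (baseline x group effect x log-normal subject factor, times the
#' anesthesia decrease in post samples), then renders each sample's
#' spectrum: weighted metabolite peaks, macromolecular baseline, residual
#' water, Ficoll contamination at a per-subject intensity, drug peaks in
#' post samples only, and additive gaussian noise. Identical designs
#' (including seed) give bit-identical cohorts.
#'
#' @param design a [cohort_design()].
#' @param render_spectra if `FALSE`, skip spectrum rendering and return
#'   annotations and true concentrations only (fast path for statistical
#'   simulations).
#' @return an object of class `synthetic_cohort`: list with `spectra`
#'   (list of `nmr_spectrum`, or lists of them when several acquisition
#'   types were requested), `annotation` (data.frame: sample_id,
#'   subject_id, group, timepoint, anesthetic, drugs), `truth`
#'   (samples x metabolites matrix of true relative concentrations),
#'   `library`, `regions` and `design`.
#' @examples
#' d <- cohort_design(n_subjects_per_group = 3, paired = FALSE,
#'                    axis = default_ppm_axis(2048), seed = 7)
#' coh <- simulate_cohort(d)
#' nrow(coh$annotation)
#' @export
simulate_cohort <- function(design, render_spectra = TRUE) {
  stopifnot(inherits(design, "cohort_design"))
  lib <- design$library
  metabolites <- unique(lib$metabolite[lib$component == "small-molecule"])
  groups <- design$groups
  effect <- lapply(groups, function(g) {
    expand_factor(design$effect_table[[g]], metabolites,
                  sprintf("effect_table[%s]", g))
  })
  names(effect) <- groups
  anes <- expand_factor(design$anesthesia_decrease, metabolites,
                        "anesthesia_decrease")
  timepoints <- if (design$paired) c("pre", "post") else "pre"

  with_seed(design$seed, {
    subj <- 0L
    ann <- list(); truth <- list(); spectra <- list()
    anesthetics <- c("etomidate", "propofol-2")
    for (gi in seq_along(groups)) {
      for (si in seq_len(design$n_subjects_per_group[gi])) {
        subj <- subj + 1L
        subject_id <- sprintf("S%03d", subj)
        subj_factor <- exp(stats::rnorm(length(metabolites), 0,
                                        design$subject_sd))
        names(subj_factor) <- metabolites
        fic <- design$ficoll_scale *
          exp(stats::rnorm(1, 0, design$ficoll_sd))
        anesthetic <- anesthetics[1L + (subj %% length(anesthetics))]
        for (tp in timepoints) {
          conc <- effect[[gi]] * subj_factor
          if (tp == "post") conc <- conc * anes
          sample_id <- sprintf("%s_%s", subject_id, tp)
          ann[[sample_id]] <- data.frame(
            sample_id = sample_id, subject_id = subject_id,
            group = groups[gi], timepoint = tp,
            anesthetic = if (tp == "post") anesthetic else "none",
            drugs = if (tp == "post" && !is.null(design$drug_peak_table))
              "cefuroxime" else "",
            stringsAsFactors = FALSE)
          truth[[sample_id]] <- conc
          noise_seed <- sample.int(.Machine$integer.max, 1)
          if (render_spectra) {
            pk <- lib[lib$component == "small-molecule", , drop = FALSE]
            pk$amplitude <- pk$amplitude * conc[pk$metabolite]
            pieces <- list(pk)
            if (design$include_macromolecules) {
              pieces <- c(pieces, list(macromolecule_baseline()))
            }
            if (design$include_water) {
              pieces <- c(pieces, list(water_peak()))
            }
            if (design$include_ficoll) {
              pieces <- c(pieces, list(ficoll_contamination(fic)))
            }
            if (tp == "post" && !is.null(design$drug_peak_table)) {
              pieces <- c(pieces, list(design$drug_peak_table))
            }
            peaks <- do.call(rbind_peaks, pieces)
            sp <- lapply(design$acquisition, function(acq) {
              render_spectrum(peaks, axis = design$axis,
                              acquisition = acq,
                              noise_sd = design$noise_sd,
                              seed = noise_seed, sample_id = sample_id)
            })
            spectra[[sample_id]] <-
              if (length(sp) == 1L) sp[[1]] else stats::setNames(
                sp, design$acquisition)
          }
        }
      }
    }
    annotation <- do.call(rbind, ann)
    rownames(annotation) <- NULL
    truth_mat <- do.call(rbind, truth)
    rownames(truth_mat) <- annotation$sample_id
    structure(list(spectra = if (render_spectra) spectra else NULL,
                   annotation = annotation, truth = truth_mat,
                   library = lib,
                   regions = quantification_regions(lib),
                   design = design),
              class = "synthetic_cohort")
  })
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("<synthetic_cohort> %d samples, %d subjects, groups: %s\n",
              nrow(x$annotation), length(unique(x$annotation$subject_id)),
              paste(unique(x$annotation$group), collapse = ", ")))
  invisible(x)
}

#' Write a cohort to plain-text files
#'
#' Writes the spectral matrix (first column ppm, one column per sample,
#' tab-delimited), the annotation table and the true-concentration table
#' as CSV into `dir`.
#'
#' @param cohort a `synthetic_cohort` with rendered spectra.
#' @param dir output directory (created if missing).
#' @return invisibly, the paths written.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  if (is.null(cohort$spectra)) {
    stop("cohort has no rendered spectra", call. = FALSE)
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  first <- cohort$spectra[[1]]
  if (inherits(first, "nmr_spectrum")) {
    specs <- cohort$spectra
  } else {
    specs <- lapply(cohort$spectra, `[[`, 1L)
  }
  mat <- cbind(ppm = specs[[1]]$ppm,
               do.call(cbind, lapply(specs, `[[`, "intensity")))
  colnames(mat) <- c("ppm", names(specs))
  paths <- c(spectra = file.path(dir, "spectra.tsv"),
             annotation = file.path(dir, "annotation.csv"),
             truth = file.path(dir, "truth.csv"))
  utils::write.table(mat, paths[["spectra"]], sep = "\t",
                     row.names = FALSE, quote = FALSE)
  utils::write.csv(cohort$annotation, paths[["annotation"]],
                   row.names = FALSE)
  utils::write.csv(data.frame(sample_id = rownames(cohort$truth),
                              cohort$truth, check.names = FALSE),
                   paths[["truth"]], row.names = FALSE)
  invisible(paths)
}

#' Read a spectral matrix written by [write_cohort()]
#'
#' @param path the `spectra.tsv` file (first column ppm, one column per
#'   sample).
#' @param acquisition acquisition tag to record on each spectrum.
#' @return list of `nmr_spectrum`, one per sample column.
#' @export
read_spectral_matrix <- function(path, acquisition = "cpmg") {
  tab <- utils::read.delim(path, check.names = FALSE)
  if (ncol(tab) < 2L) stop("spectral matrix needs >= 2 columns",
                           call. = FALSE)
  ppm <- tab[[1]]
  lapply(stats::setNames(names(tab)[-1], names(tab)[-1]), function(id) {
    nmr_spectrum(ppm, tab[[id]], acquisition = acquisition, sample_id = id)
  })
}
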