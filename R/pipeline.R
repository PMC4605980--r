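#' Default pipeline configuration
#'
#' One nested list driving [run_pipeline()]: cohort simulation (or input
#' paths), spectral processing, classification and univariate screening.
#' Every random stage derives its stream from the single master seed, so
#' a config plus seed reproduces a run exactly. The config round-trips
#' through YAML unchanged via [read_pipeline_config()] /
#' [write_pipeline_config()].
#'
#' @param seed master seed.
#' @return a list of class `pipeline_config`.
#' @export
default_pipeline_config <- function(seed = 1) {
  structure(list(
    seed = as.integer(seed),
    simulate = list(n_subjects_per_group = c(20L, 20L),
                    groups = c("CRC", "LC"), paired = TRUE,
                    axis_points = 8192L,
                    effect_table = list(LC = list(lactate = 1.6,
                                                  alanine = 0.7)),
                    anesthesia_decrease = 0.85,
                    subject_sd = 0.15, noise_sd = 0.01),
    processing = list(low = 0.20, high = 10.00, width = 0.02,
                      exclude = list(c(3.30, 6.00)),
                      calibrate_ppm = 5.24, normalize = TRUE),
    model = list(kind = "pls-ca", n_iterations = 100L,
                 test_fraction = 0.1, ncomp = 3L),
    contrast = list(type = "group", column = "group",
                    timepoint = "pre"),
    screen = list(alpha = 0.05, timepoint = "pre")),
    class = "pipeline_config")
}

#' Read / write a pipeline configuration as YAML
#'
#' @param path YAML file path.
#' @return for `read_pipeline_config`, a `pipeline_config`; for
#'   `write_pipeline_config`, the path, invisibly.
#' @export
read_pipeline_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  base <- unclass(default_pipeline_config())
  for (nm in names(cfg)) {
    if (is.list(base[[nm]]) && is.list(cfg[[nm]])) {
      base[[nm]][names(cfg[[nm]])] <- cfg[[nm]]
    } else {
      base[[nm]] <- cfg[[nm]]
    }
  }
  base$processing$exclude <- lapply(base$processing$exclude, unlist)
  structure(base, class = "pipeline_config")
}

#' @rdname read_pipeline_config
#' @param config a `pipeline_config`.
#' @export
write_pipeline_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Summarize and check a sample-annotation table
#'
#' Counts samples per group, timepoint and anesthetic, and checks
#' pre/post pairing completeness, warning about subjects that lack a
#' timepoint.
#'
#' @param annotation data.frame with at least `sample_id`, `subject_id`,
#'   `group`; optionally `timepoint`, `anesthetic`.
#' @return a list of class `design_summary`: `n_samples`, `n_subjects`,
#'   `per_group`, `per_timepoint`, `per_anesthetic`,
#'   `pairing_complete`, `unpaired_subjects`.
#' @export
validate_design <- function(annotation) {
  if (!is.data.frame(annotation) || nrow(annotation) == 0L) {
    stop("annotation table is empty", call. = FALSE)
  }
  need <- c("sample_id", "subject_id", "group")
  miss <- setdiff(need, names(annotation))
  if (length(miss)) {
    stop("annotation lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(annotation$sample_id)) {
    stop("duplicate sample_id in annotation", call. = FALSE)
  }
  unpaired <- character(0)
  pairing <- NA
  if ("timepoint" %in% names(annotation) &&
      length(unique(annotation$timepoint)) > 1L) {
    tab <- table(annotation$subject_id, annotation$timepoint)
    ok <- apply(tab, 1, function(r) all(r == 1L))
    unpaired <- rownames(tab)[!ok]
    pairing <- length(unpaired) == 0L
    if (!pairing) {
      warning("subjects missing a timepoint: ",
              paste(unpaired, collapse = ", "), call. = FALSE)
    }
  }
  structure(list(
    n_samples = nrow(annotation),
    n_subjects = length(unique(annotation$subject_id)),
    per_group = table(annotation$group),
    per_timepoint = if ("timepoint" %in% names(annotation))
      table(annotation$timepoint) else NULL,
    per_anesthetic = if ("anesthetic" %in% names(annotation))
      table(annotation$anesthetic) else NULL,
    pairing_complete = pairing,
    unpaired_subjects = unpaired), class = "design_summary")
}

#' @export
print.design_summary <- function(x, ...) {
  cat(sprintf("<design_summary> %d samples, %d subjects\n",
              x$n_samples, x$n_subjects))
  cat("per group: "); print(x$per_group)
  if (!is.null(x$per_timepoint)) {
    cat("per timepoint: "); print(x$per_timepoint)
    cat(sprintf("pairing complete: %s\n", x$pairing_complete))
  }
  invisible(x)
}

pipeline_stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("[stage %s] %s", name, conditionMessage(e)),
         call. = FALSE)
  })
}

#' Run the full simulate-process-classify-screen pipeline
#'
#' Executes the four analysis stages in order on a simulated cohort (or
#' spectra loaded from a spectral-matrix file given in
#' `config$input$spectra` with `config$input$annotation`), failing fast
#' with stage-named errors, and optionally writes a machine-readable
#' report (JSON) plus CSV artifacts to `out_dir`. The report embeds the
#' config and seed that produced it; re-running with them reproduces
#' every number.
#'
#' @param config a `pipeline_config` (or path to one in YAML).
#' @param out_dir output directory, or `NULL` to skip writing.
#' @return a list of class `run_report`: `config`, `design_summary`,
#'   `cv`, `screen`, `stage_counts`, `version`, `timestamp`.
#' @export
run_pipeline <- function(config = default_pipeline_config(),
                         out_dir = NULL) {
  if (is.character(config)) config <- read_pipeline_config(config)
  seed <- config$seed

  # stage 1: obtain spectra + annotation
  if (!is.null(config$input)) {
    cohort <- NULL
    spectra <- pipeline_stage("input",
      read_spectral_matrix(config$input$spectra))
    annotation <- pipeline_stage("input",
      utils::read.csv(config$input$annotation,
                      stringsAsFactors = FALSE))
    regions <- NULL
  } else {
    sim <- config$simulate
    cohort <- pipeline_stage("simulate", {
      eff <- lapply(sim$effect_table, unlist)
      design <- cohort_design(
        n_subjects_per_group = sim$n_subjects_per_group,
        groups = sim$groups, paired = isTRUE(sim$paired),
        effect_table = eff,
        anesthesia_decrease = sim$anesthesia_decrease,
        subject_sd = sim$subject_sd, noise_sd = sim$noise_sd,
        axis = default_ppm_axis(sim$axis_points %||% 8192L),
        seed = seed)
      simulate_cohort(design)
    })
    spectra <- cohort$spectra
    annotation <- cohort$annotation
    regions <- cohort$regions
  }
  summary <- pipeline_stage("validate", validate_design(annotation))

  # stage 2: process into bucket matrix
  pr <- config$processing
  bm <- pipeline_stage("process",
    build_bucket_matrix(spectra, low = pr$low, high = pr$high,
                        width = pr$width, exclude = pr$exclude,
                        calibrate_ppm = pr$calibrate_ppm,
                        normalize = isTRUE(pr$normalize)))

  # stage 3: classify under Monte-Carlo CV
  md <- config$model
  ct <- config$contrast
  cv <- pipeline_stage("classify", {
    if (identical(md$kind, "mpls")) {
      monte_carlo_cv(bm, annotation, model_kind = "mpls",
                     n_iterations = md$n_iterations,
                     test_fraction = md$test_fraction,
                     ncomp = md$ncomp, seed = seed + 1L)
    } else {
      keep <- rep(TRUE, nrow(annotation))
      if (!is.null(ct$timepoint) && "timepoint" %in% names(annotation)) {
        keep <- annotation$timepoint == ct$timepoint
      }
      monte_carlo_cv(bm$values[keep, , drop = FALSE],
                     annotation[[ct$column %||% "group"]][keep],
                     model_kind = "pls-ca",
                     n_iterations = md$n_iterations,
                     test_fraction = md$test_fraction,
                     ncomp = md$ncomp, seed = seed + 1L)
    }
  })

  # stage 4: univariate screen (needs quantification regions)
  screen <- NULL
  if (!is.null(regions)) {
    screen <- pipeline_stage("screen", {
      met <- quantify_metabolites(spectra, regions,
                                  excluded_ranges = pr$exclude,
                                  low = pr$low, high = pr$high)
      contrast <- if (identical(md$kind, "mpls")) {
        list(type = "paired")
      } else {
        list(type = "group", column = ct$column %||% "group",
             timepoint = config$screen$timepoint)
      }
      univariate_screen(met, annotation, contrast,
                        alpha = config$screen$alpha %||% 0.05)
    })
  }

  report <- structure(list(
    config = config,
    design_summary = summary,
    cv = cv,
    screen = screen,
    stage_counts = list(n_spectra = length(spectra),
                        n_samples = nrow(annotation),
                        n_bins = ncol(bm$values)),
    version = as.character(utils::packageVersion("ficollnmr")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
    class = "run_report")

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_bucket_matrix(bm, file.path(out_dir, "buckets.csv"))
    utils::write.csv(annotation, file.path(out_dir, "annotation.csv"),
                     row.names = FALSE)
    if (!is.null(screen)) {
      utils::write.csv(as.data.frame(screen),
                       file.path(out_dir, "screen.csv"),
                       row.names = FALSE)
    }
    jsonlite::write_json(report_to_json(report),
                         file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  report
}

`%||%` <- function(a, b) if (is.null(a)) b else a

report_to_json <- function(report) {
  cv <- report$cv
  list(config = unclass(report$config),
       design = list(n_samples = report$design_summary$n_samples,
                     n_subjects = report$design_summary$n_subjects),
       cv = list(confusion = as.data.frame.matrix(
                   as.data.frame.matrix(cv$confusion)),
                 accuracy = cv$accuracy,
                 sensitivity = cv$sensitivity,
                 specificity = cv$specificity,
                 n_iterations = cv$n_iterations,
                 test_fraction = cv$test_fraction,
                 positive = cv$positive, seed = cv$seed),
       screen = if (!is.null(report$screen))
         as.data.frame(report$screen) else NULL,
       stage_counts = report$stage_counts,
       version = report$version,
       timestamp = report$timestamp)
}

#' @export
print.run_report <- function(x, ...) {
  cat("<run_report>\n")
  print(x$design_summary)
  print(x$cv)
  if (!is.null(x$screen)) {
    cat(sprintf("screen: %d metabolites, %d significant\n",
                nrow(x$screen), sum(x$screen$significant)))
  }
  invisible(x)
}
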