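#' Segment one unmixed field
#'
#' Convenience composition used by [run_pipeline()] and the tests: computes
#' the auto-adaptive thresholds, classifies pixels, forms and classifies
#' gland objects.
#'
#' @param maps an `abundance_maps` object.
#' @param config a [qmif_config()].
#' @return List with `labels` (`pixel_labels`) and `glands` (classified
#'   `gland_set`).
#' @export
segment_field <- function(maps, config = qmif_config()) {
  thr <- segmentation_thresholds(maps, config$channels,
                                 config$threshold_offset)
  labels <- classify_pixels(maps, thr, config$channels,
                            min_basal_area_px = config$min_basal_area_px,
                            min_island_px = config$min_island_px,
                            basal_band_px = config$basal_band_px)
  glands <- form_gland_objects(labels, config$min_gland_area_px,
                               config$basal_dist)
  glands <- classify_glands(glands, config$f_benign, config$f_malignant)
  list(labels = labels, glands = glands)
}

#' Quantify one field end to end
#'
#' Unmixes a multispectral image, segments it, applies the BAFL and
#' saturation exclusions, runs field QC and measures the configured
#' biomarkers in the cancer compartments.
#'
#' @param image an [ms_image()].
#' @param library a [spectral_library()].
#' @param config a [qmif_config()].
#' @return List with `values` (named per-marker means), `qc`
#'   (`field_qc_report`), `labels`, `glands`, `maps`.
#' @export
quantify_field <- function(image, library, config = qmif_config()) {
  maps <- unmix_image(image, library)
  seg <- segment_field(maps, config)
  bafl <- if (any(library$roles == "BAFL"))
    flag_bright_autofluorescence(maps, threshold = config$bafl_threshold)
  else matrix(FALSE, nrow(maps$residual), ncol(maps$residual))
  sat <- flag_saturated(image, config$saturation_ceiling)
  comp <- extract_compartments(seg$labels, seg$glands, exclude = bafl | sat)
  qc <- field_qc(seg$labels, seg$glands,
                 maps$abundance[[config$channels$dapi]],
                 min_cancer_area_px = config$min_cancer_area_px,
                 focus_metric_min = config$focus_metric_min,
                 saturated_frac_max = config$saturated_frac_max,
                 saturated = sat)
  vals <- measure_field(maps, comp, config$markers, config$compartment_map)
  list(values = vals, qc = qc, labels = seg$labels, glands = seg$glands,
       maps = maps)
}

run_stage <- function(stage, code) {
  tryCatch(code, error = function(e)
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

#' Run the full QMIF pipeline
#'
#' Executes unmix -> segment -> quantify -> aggregate -> survival on the
#' inputs named in the configuration and writes every stage output, a log
#' and a manifest into `out_dir`. When `config$stacks` is empty the imaging
#' stages are skipped and the marker columns are taken directly from the
#' cohort CSV.
#'
#' @param config a [qmif_config()]; `cohort` must point to a CSV with
#'   `sample_id`, `time_years`, `event` (and marker columns if no stacks are
#'   given). Stack sidecars must carry `sample_id`, `core_id` and
#'   `field_index` metadata.
#' @param out_dir output directory (created if needed).
#' @return Invisibly, a list with the main tables (`core_measurements`,
#'   `sample_markers`, `univariate`, `bootstrap`) and the manifest.
#' @export
run_pipeline <- function(config, out_dir) {
  run_stage("config", validate_config(config))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_lines <- c(sprintf("qmif %s", as.character(utils::packageVersion("qmif"))),
                 sprintf("started %s", format(Sys.time())),
                 sprintf("root seed %d", as.integer(config$seed)))
  outputs <- character(0)
  emit <- function(df, name) {
    p <- file.path(out_dir, name)
    utils::write.csv(df, p, row.names = FALSE)
    outputs <<- c(outputs, name)
    p
  }

  core_measurements <- NULL
  sample_markers <- NULL

  if (length(config$stacks)) {
    library <- run_stage("library", {
      if (is.null(config$library)) default_spectral_library()
      else read_spectral_library(config$library)
    })
    field_rows <- run_stage("quantify", {
      rows <- lapply(config$stacks, function(path) {
        img <- read_stack(path)
        q <- quantify_field(img, library, config)
        meta <- img$meta
        data.frame(sample_id = as.character(meta$sample_id),
                   core_id = as.character(meta$core_id),
                   field_index = as.integer(meta$field_index),
                   marker = names(q$values),
                   compartment = unname(
                     config$compartment_map[names(q$values)]),
                   value = unname(q$values),
                   qc_pass = q$qc$pass)
      })
      do.call(rbind, rows)
    })
    core_measurements <- run_stage("combine_fields", {
      sp <- split(field_rows,
                  list(field_rows$core_id, field_rows$marker), drop = TRUE)
      do.call(rbind, lapply(sp, function(d) {
        cv <- combine_fields(d$value, d$qc_pass)
        data.frame(sample_id = d$sample_id[1L], core_id = d$core_id[1L],
                   marker = d$marker[1L], compartment = d$compartment[1L],
                   value = cv$value, n_fields_passed = cv$n_fields_passed)
      }))
    })
    emit(core_measurements, "core_measurements.csv")
    sample_markers <- run_stage("aggregate_cores", {
      dirs <- marker_directions(pS6 = config$pS6_direction)
      sp <- split(core_measurements,
                  list(core_measurements$sample_id, core_measurements$marker),
                  drop = TRUE)
      do.call(rbind, lapply(sp, function(d) {
        data.frame(sample_id = d$sample_id[1L], marker = d$marker[1L],
                   value = aggregate_cores(d$value, marker = d$marker[1L],
                                           directions = dirs),
                   direction_used = dirs[[d$marker[1L]]])
      }))
    })
    emit(sample_markers, "sample_markers.csv")
  }

  result <- list(core_measurements = core_measurements,
                 sample_markers = sample_markers)

  if (!is.null(config$cohort)) {
    cohort <- run_stage("cohort", {
      d <- utils::read.csv(config$cohort, check.names = FALSE)
      need <- c("sample_id", "time_years", "event")
      miss <- setdiff(need, names(d))
      if (length(miss)) stop("cohort CSV missing column(s): ",
                             paste(miss, collapse = ", "))
      d
    })
    if (!is.null(sample_markers)) {
      wide <- stats::reshape(sample_markers[, c("sample_id", "marker",
                                                "value")],
                             direction = "wide", idvar = "sample_id",
                             timevar = "marker")
      names(wide) <- sub("^value\\.", "", names(wide))
      cohort <- merge(cohort, wide, by = "sample_id")
    }
    markers <- config$survival_markers
    if (is.null(markers))
      markers <- intersect(names(marker_directions()), names(cohort))
    if (!length(markers)) stop("pipeline stage 'survival' failed: ",
                               "no marker columns available", call. = FALSE)
    std <- run_stage("survival", standardize_markers(cohort, markers))
    uni <- run_stage("survival", {
      do.call(rbind, lapply(markers, function(mk) {
        r <- univariate_marker(std, mk)
        data.frame(marker = mk, cox_coefficient = r$cox_coefficient,
                   hr = r$hr, logrank_chisq = r$logrank_chisq,
                   logrank_p = r$logrank_p,
                   n_high_risk = as.integer(r$n[["high-risk"]]),
                   n_rest = as.integer(r$n[["rest"]]))
      }))
    })
    emit(uni, "univariate.csv")
    boot <- run_stage("survival", {
      bootstrap_evaluate(cohort, markers, B = config$bootstrap_B,
                         seed = config$seed)
    })
    emit(boot$replicates, "bootstrap_metrics.csv")
    emit(boot$summary, "bootstrap_summary.csv")
    km <- run_stage("survival", {
      fit <- fit_cox(as.matrix(std[stats::complete.cases(std[, markers]),
                                   markers, drop = FALSE]),
                     std$time_years[stats::complete.cases(std[, markers])],
                     std$event[stats::complete.cases(std[, markers])])
      grp <- tertile_split(fit$risk, "positive")
      keep <- stats::complete.cases(std[, markers])
      km_logrank_hr(std$time_years[keep], std$event[keep], grp)
    })
    for (gname in names(km$km))
      emit(km$km[[gname]], sprintf("km_%s.csv", gsub("[^A-Za-z0-9]", "_",
                                                     gname)))
    result$univariate <- uni
    result$bootstrap <- boot
    result$km <- km
    log_lines <- c(log_lines,
                   sprintf("survival markers: %s",
                           paste(markers, collapse = ", ")),
                   sprintf("bootstrap B = %d", as.integer(config$bootstrap_B)))
  }

  manifest <- list(package = "qmif",
                   version = as.character(utils::packageVersion("qmif")),
                   seed = as.integer(config$seed),
                   outputs = as.list(outputs))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  writeLines(c(log_lines, sprintf("finished %s", format(Sys.time()))),
             file.path(out_dir, "pipeline.log"))
  result$manifest <- manifest
  invisible(result)
}
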