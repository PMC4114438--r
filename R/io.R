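sidecar_path <- function(path) paste0(sub("\\.[^.]*$", "", path), ".json")

#' Read / write a multispectral stack as multilayer TIFF plus sidecar JSON
#'
#' Planes are stored in band order as 32-bit float TIFF layers, scaled into
#' \[0, 1\] by a factor recorded in the sidecar (TIFF float storage is
#' clipped to that range); the sidecar also carries the band centers and the
#' field metadata, so a write/read round trip restores both array and
#' metadata (to float32 precision).
#'
#' @param image an [ms_image()].
#' @param path TIFF file path; the sidecar is written next to it with a
#'   `.json` extension.
#' @return `write_stack` returns `path` invisibly; `read_stack` returns an
#'   [ms_image()].
#' @export
write_stack <- function(image, path) {
  stopifnot(inherits(image, "ms_image"))
  scale <- max(image$data, 1e-12)
  planes <- lapply(seq_len(dim(image$data)[1L]),
                   function(k) image$data[k, , ] / scale)
  tiff::writeTIFF(planes, path, bits.per.sample = 32L)
  jsonlite::write_json(list(band_centers = image$band_centers,
                            intensity_scale = scale,
                            meta = image$meta),
                       sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_stack
#' @export
read_stack <- function(path) {
  if (!file.exists(path)) stop("stack not found: ", path)
  sc <- sidecar_path(path)
  if (!file.exists(sc))
    stop("missing sidecar metadata file: ", sc)
  meta <- jsonlite::read_json(sc, simplifyVector = TRUE)
  planes <- tiff::readTIFF(path, all = TRUE)
  if (length(planes) != length(meta$band_centers))
    stop("band-count mismatch: stack has ", length(planes),
         " planes, sidecar lists ", length(meta$band_centers), " bands")
  nr <- nrow(planes[[1L]]); nc <- ncol(planes[[1L]])
  arr <- array(0, dim = c(length(planes), nr, nc))
  for (k in seq_along(planes)) arr[k, , ] <- planes[[k]] * meta$intensity_scale
  ms_image(arr, meta$band_centers,
           meta = if (is.null(meta$meta)) list() else as.list(meta$meta))
}

#' Write a pixel label map with its legend
#'
#' The label plane is stored as an 8-bit single-plane TIFF (code/255) next to
#' a JSON legend mapping class names to codes.
#'
#' @param labels a `pixel_labels` object.
#' @param path TIFF file path.
#' @return `path`, invisibly.
#' @export
write_label_map <- function(labels, path) {
  stopifnot(inherits(labels, "pixel_labels"))
  tiff::writeTIFF(labels$labels / 255, path, bits.per.sample = 8L)
  jsonlite::write_json(list(legend = as.list(qmif_labels),
                            thresholds = labels$thresholds),
                       sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Pipeline configuration with validated defaults
#'
#' Central configuration for [run_pipeline()]. Every default is documented in
#' the argument list; `validate_config()` is run on construction and again
#' before any pipeline stage.
#'
#' @param stacks character vector of multispectral TIFF paths (may be empty
#'   when `cohort` already contains marker columns).
#' @param cohort path of the cohort CSV
#'   (`sample_id,time_years,event,gleason_group,age,...`).
#' @param library path of a spectral library CSV, or `NULL` for
#'   [default_spectral_library()].
#' @param markers named character vector biomarker -> endmember carrying it.
#' @param channels segmentation channel mapping (dapi/epithelial/basal/afl).
#' @param threshold_offset auto-adaptive threshold offset factor.
#' @param f_benign,f_malignant basal-adjacency cutoffs of the gland call.
#' @param basal_dist basal adjacency distance, px.
#' @param min_gland_area_px minimum gland object area, px.
#' @param min_basal_area_px minimum retained basal component, px.
#' @param basal_band_px epithelium-adjacent band radius for the basal call,
#'   px.
#' @param min_island_px minimum retained background/stroma island, px.
#' @param min_cancer_area_px field QC: minimum malignant epithelium area, px.
#' @param focus_metric_min field QC: focus floor.
#' @param saturated_frac_max field QC: saturated-pixel fraction cap.
#' @param saturation_ceiling intensity at which a pixel counts as saturated.
#' @param bafl_threshold absolute BAFL abundance above which a pixel is
#'   excluded.
#' @param compartment_map biomarker -> compartment table.
#' @param pS6_direction two-core aggregation direction for pS6.
#' @param survival_markers marker set for the multivariate evaluation.
#' @param bootstrap_B number of bootstrap replicates.
#' @param seed root seed; all pipeline randomness derives from it.
#' @return Validated configuration list of class `qmif_config`.
#' @export
qmif_config <- function(stacks = character(0), cohort = NULL, library = NULL,
                        markers = c(SMAD4 = "Alexa568", SPP1 = "Alexa633"),
                        channels = list(dapi = "DAPI",
                                        epithelial = "Alexa488",
                                        basal = "Alexa555", afl = "AFL"),
                        threshold_offset = 1.0,
                        f_benign = 0.3, f_malignant = 0.05, basal_dist = 2,
                        min_gland_area_px = 50, min_basal_area_px = 5,
                        min_island_px = 25, basal_band_px = 4,
                        min_cancer_area_px = 500,
                        focus_metric_min = 0.5, saturated_frac_max = 0.05,
                        saturation_ceiling = 65535, bafl_threshold = 1.0,
                        compartment_map = marker_compartments(),
                        pS6_direction = "min",
                        survival_markers = NULL,
                        bootstrap_B = 10000, seed = 1) {
  cfg <- structure(list(stacks = stacks, cohort = cohort, library = library,
                        markers = markers, channels = channels,
                        threshold_offset = threshold_offset,
                        f_benign = f_benign, f_malignant = f_malignant,
                        basal_dist = basal_dist,
                        min_gland_area_px = min_gland_area_px,
                        min_basal_area_px = min_basal_area_px,
                        min_island_px = min_island_px,
                        basal_band_px = basal_band_px,
                        min_cancer_area_px = min_cancer_area_px,
                        focus_metric_min = focus_metric_min,
                        saturated_frac_max = saturated_frac_max,
                        saturation_ceiling = saturation_ceiling,
                        bafl_threshold = bafl_threshold,
                        compartment_map = compartment_map,
                        pS6_direction = pS6_direction,
                        survival_markers = survival_markers,
                        bootstrap_B = bootstrap_B, seed = seed),
                   class = "qmif_config")
  validate_config(cfg)
  cfg
}

#' @rdname qmif_config
#' @param config a configuration list.
#' @export
validate_config <- function(config) {
  fail <- function(...) stop("config validation: ", ..., call. = FALSE)
  need <- names(formals(qmif_config))
  miss <- setdiff(need, names(config))
  if (length(miss)) fail("missing field(s): ", paste(miss, collapse = ", "))
  if (!is.numeric(config$seed) || length(config$seed) != 1L ||
      config$seed != round(config$seed)) fail("seed must be a single integer")
  if (!is.numeric(config$bootstrap_B) || config$bootstrap_B < 1)
    fail("bootstrap_B must be >= 1")
  if (!(config$f_malignant >= 0 && config$f_malignant < config$f_benign &&
        config$f_benign <= 1))
    fail("need 0 <= f_malignant < f_benign <= 1")
  for (fld in c("threshold_offset", "basal_dist", "min_gland_area_px",
                "min_basal_area_px", "min_island_px", "basal_band_px",
                "min_cancer_area_px", "saturation_ceiling", "bafl_threshold"))
    if (!is.numeric(config[[fld]]) || config[[fld]] <= 0)
      fail(fld, " must be positive")
  if (length(config$markers)) {
    if (is.null(names(config$markers))) fail("markers must be named")
    unknown <- setdiff(names(config$markers),
                       names(config$compartment_map))
    if (length(unknown))
      fail("unknown marker(s) without a compartment entry: ",
           paste(unknown, collapse = ", "))
    dirs <- marker_directions(pS6 = config$pS6_direction)
    unknown <- setdiff(names(config$markers), names(dirs))
    if (length(unknown))
      fail("unknown marker(s) without an aggregation direction: ",
           paste(unknown, collapse = ", "))
  }
  if (!all(c("dapi", "epithelial", "basal") %in% names(config$channels)))
    fail("channels must name dapi, epithelial and basal")
  invisible(TRUE)
}

#' Read a pipeline configuration from YAML
#'
#' Fields present in the YAML override the defaults of [qmif_config()]; the
#' merged configuration is validated before return.
#'
#' @param path YAML file path.
#' @return A validated `qmif_config`.
#' @export
read_config <- function(path) {
  user <- yaml::read_yaml(path)
  base <- qmif_config()
  for (nm in names(user)) {
    v <- user[[nm]]
    if (nm %in% c("markers", "compartment_map") && is.list(v)) v <- unlist(v)
    if (nm %in% c("stacks", "survival_markers")) v <- as.character(unlist(v))
    base[[nm]] <- v
  }
  validate_config(base)
  base
}
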