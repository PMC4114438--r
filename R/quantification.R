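#' Mean biomarker intensity within a compartment mask
#'
#' Arithmetic mean of the biomarker abundance over the mask pixels. BAFL and
#' saturated pixels are expected to have been removed from the mask upstream
#' ([extract_compartments()]).
#'
#' @param abundance_plane biomarker abundance matrix.
#' @param compartment_mask logical matrix of the same shape.
#' @return Mean intensity; `NA_real_` with a `"reason"` attribute when the
#'   mask is empty. The number of pixels used is attached as attribute
#'   `"n_px"`.
#' @export
measure_biomarker <- function(abundance_plane, compartment_mask) {
  stopifnot(is.matrix(abundance_plane), is.logical(compartment_mask),
            all(dim(abundance_plane) == dim(compartment_mask)))
  n <- sum(compartment_mask)
  if (n == 0L)
    return(structure(NA_real_, reason = "empty compartment mask", n_px = 0L))
  structure(mean(abundance_plane[compartment_mask]), n_px = n)
}

#' Combine per-field values into one core value
#'
#' A core's value is the mean over its fields that passed quality control.
#'
#' @param field_values numeric vector of per-field mean intensities.
#' @param qc_reports list of `field_qc_report`s (or a logical vector of pass
#'   flags), one per field.
#' @return List with `value` (`NA` if no field passed), `n_fields_passed`.
#' @export
combine_fields <- function(field_values, qc_reports) {
  pass <- if (is.logical(qc_reports)) qc_reports
  else vapply(qc_reports, function(r) isTRUE(r$pass), logical(1L))
  if (length(pass) != length(field_values))
    stop("one QC report per field required")
  usable <- pass & !is.na(field_values)
  if (!any(usable))
    return(list(value = NA_real_, n_fields_passed = 0L))
  list(value = mean(field_values[usable]), n_fields_passed = sum(usable))
}

#' Two-core aggregation directions per biomarker
#'
#' Each patient is represented by two TMA cores; the per-sample marker value
#' is the minimum of the two core values for markers negatively correlated
#' with lethal outcome (tumor suppressors) and the maximum for positively
#' correlated markers. The default table: PTEN, SMAD4, pS6 -> min; CCND1,
#' SPP1, p90RSK, pPRAS40, FOXO3 -> max. The pS6 entry is exposed because its
#' published min assignment sits oddly beside its positive univariate hazard
#' ratio; the default keeps the published assignment.
#'
#' @param pS6 `"min"` (default, the published assignment) or `"max"`.
#' @return Named character vector mapping biomarker to `"min"`/`"max"`.
#' @export
marker_directions <- function(pS6 = c("min", "max")) {
  pS6 <- match.arg(pS6)
  c(PTEN = "min", SMAD4 = "min", pS6 = pS6, CCND1 = "max", SPP1 = "max",
    p90RSK = "max", pPRAS40 = "max", FOXO3 = "max")
}

#' Default subcellular compartment per biomarker
#'
#' Canonical localization of each marker's signal: cytoplasmic for PTEN,
#' SPP1 and the phospho-markers; nuclear for the transcription-level markers
#' SMAD4, CCND1 and FOXO3. Override freely — the assay treats this as
#' configuration.
#'
#' @return Named character vector mapping biomarker to
#'   `"cytoplasm"`/`"nucleus"`/`"whole"`.
#' @export
marker_compartments <- function() {
  c(PTEN = "cytoplasm", SPP1 = "cytoplasm", pS6 = "cytoplasm",
    pPRAS40 = "cytoplasm", p90RSK = "cytoplasm",
    SMAD4 = "nucleus", CCND1 = "nucleus", FOXO3 = "nucleus")
}

#' Aggregate two core values into one sample value
#'
#' @param core_values numeric vector of one or two core values (`NA` allowed
#'   for a missing core).
#' @param marker biomarker name, looked up in `directions`; alternatively
#'   pass `direction` directly.
#' @param directions named direction table from [marker_directions()].
#' @param direction `"min"` or `"max"`, bypassing the table.
#' @return The aggregated sample value; `NA_real_` when both cores are
#'   missing.
#' @export
aggregate_cores <- function(core_values, marker = NULL,
                            directions = marker_directions(),
                            direction = NULL) {
  if (is.null(direction)) {
    if (is.null(marker)) stop("give either marker or direction")
    if (!marker %in% names(directions))
      stop("no aggregation direction for biomarker: ", marker)
    direction <- directions[[marker]]
  }
  direction <- match.arg(direction, c("min", "max"))
  if (length(core_values) < 1L || length(core_values) > 2L)
    stop("expected one or two core values")
  v <- core_values[!is.na(core_values)]
  if (!length(v)) return(NA_real_)
  if (direction == "min") min(v) else max(v)
}

#' Grade tissue quality from benign-section QC features
#'
#' FFPE block quality is graded 1 (best) to 4 on three features measured on a
#' benign-containing QC section: mean KRT8/18 epithelial intensity,
#' endothelial pSTAT3 presence, and autofluorescence level. Only grades 1-2
#' enter the study. The rubric is monotone: the base grade comes from KRT8/18
#' cutoffs, absent pSTAT3 caps the grade at 3 or worse, and excessive
#' autofluorescence degrades the grade one step.
#'
#' @param features list with `krt8_18` (mean benign-epithelium intensity,
#'   relative units), `pstat3` (endothelial presence score in \[0, 1\]) and
#'   `afl` (autofluorescence level, relative units).
#' @param cutoffs list of rubric cutoffs; defaults:
#'   `krt_high = 0.75`, `krt_mid = 0.4`, `krt_low = 0.1`, `pstat3_min = 0.5`,
#'   `afl_max = 0.5`.
#' @return List with `grade` (integer 1-4) and `included` (grade <= 2).
#' @export
grade_tissue <- function(features,
                         cutoffs = list(krt_high = 0.75, krt_mid = 0.4,
                                        krt_low = 0.1, pstat3_min = 0.5,
                                        afl_max = 0.5)) {
  need <- c("krt8_18", "pstat3", "afl")
  miss <- setdiff(need, names(features))
  if (length(miss)) stop("missing feature(s): ", paste(miss, collapse = ", "))
  k <- features$krt8_18
  grade <- if (k >= cutoffs$krt_high) 1L else if (k >= cutoffs$krt_mid) 2L
  else if (k >= cutoffs$krt_low) 3L else 4L
  if (features$pstat3 < cutoffs$pstat3_min) grade <- max(grade, 3L)
  if (features$afl > cutoffs$afl_max) grade <- min(grade + 1L, 4L)
  list(grade = grade, included = grade <= 2L)
}

#' Assay dynamic-range check
#'
#' An antibody dilution is acceptable when high-signal control cores exceed
#' low-signal controls by at least three-fold on average.
#'
#' @param low_controls,high_controls positive numeric vectors of control
#'   core values.
#' @param min_ratio required fold change (default 3).
#' @return List with `ratio` (mean(high)/mean(low)) and `pass`.
#' @export
dynamic_range_check <- function(low_controls, high_controls, min_ratio = 3.0) {
  if (!length(low_controls) || !length(high_controls))
    stop("both control lists must be non-empty")
  ml <- mean(low_controls)
  if (ml <= 0) stop("low-control mean must be positive")
  ratio <- mean(high_controls) / ml
  list(ratio = ratio, pass = ratio >= min_ratio)
}

#' Replicate agreement between consecutive TMA sections
#'
#' Compares the same cores measured on two consecutive sections: ordinary
#' least-squares R-squared of section B on section A, plus the maximum
#' relative difference |a - b| / mean(a, b) over pairs.
#'
#' @param values_section_a,values_section_b paired numeric vectors,
#'   length >= 3.
#' @return List with `r_squared` and `max_rel_diff`.
#' @export
replicate_agreement <- function(values_section_a, values_section_b) {
  a <- values_section_a; b <- values_section_b
  if (length(a) != length(b)) stop("sections must have equal length")
  if (length(a) < 3L) stop("need at least 3 paired cores")
  # for simple OLS, R^2 is the squared Pearson correlation
  r2 <- if (stats::sd(a) == 0 || stats::sd(b) == 0) NA_real_
  else stats::cor(a, b)^2
  pm <- (a + b) / 2
  rel <- ifelse(pm > 0, abs(a - b) / pm, 0)
  list(r_squared = r2, max_rel_diff = max(rel))
}

#' Quantify biomarkers for one segmented field
#'
#' Convenience wrapper for one imaged field: measures each biomarker in its
#' configured compartment of the malignant (cancer) gland class.
#'
#' @param maps an `abundance_maps` object.
#' @param compartments a `compartment_masks` object.
#' @param markers named character vector mapping biomarker name to the
#'   library endmember carrying it.
#' @param compartment_map biomarker -> compartment table
#'   ([marker_compartments()]).
#' @param gland_class `"malignant"` (default) or `"benign"`.
#' @return Named numeric vector of per-field mean intensities (may be `NA`).
#' @export
measure_field <- function(maps, compartments, markers,
                          compartment_map = marker_compartments(),
                          gland_class = "malignant") {
  stopifnot(inherits(maps, "abundance_maps"),
            inherits(compartments, "compartment_masks"))
  cls <- compartments[[gland_class]]
  vapply(names(markers), function(mk) {
    comp <- compartment_map[[mk]]
    if (is.null(comp)) stop("no compartment configured for marker ", mk)
    mask <- switch(comp, cytoplasm = cls$cytoplasm, nucleus = cls$nucleus,
                   whole = cls$whole,
                   stop("unknown compartment: ", comp))
    em <- markers[[mk]]
    if (!em %in% names(maps$abundance))
      stop("endmember ", em, " not in abundance maps")
    as.numeric(measure_biomarker(maps$abundance[[em]], mask))
  }, numeric(1L))
}
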