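# Shared small-scene fixtures, generated in code at test time.

test_library <- function() default_spectral_library()

# a compact 160x160 scene that packs reliably
small_scene_params <- function(n_benign = 2, n_malignant = 2) {
  scene_params(size = c(160, 160), n_benign = n_benign,
               n_malignant = n_malignant, radius_range = c(10, 16),
               n_stroma_nuclei = 15, n_bafl_granules = 8)
}

small_config <- function(...) {
  qmif_config(min_gland_area_px = 30, min_cancer_area_px = 150, ...)
}

# noise level used by the robustness checks: 5% of the brightest
# non-artifact channel (DAPI at 8 intensity units)
noise_5pct <- 0.05 * 8

# hand-built abundance_maps object for rule-level tests
fake_maps <- function(planes, lib = test_library(), dims = c(16, 16)) {
  if (length(planes)) dims <- dim(planes[[1L]])
  nr <- dims[1L]; nc <- dims[2L]
  full <- lapply(colnames(lib$profiles), function(nm) {
    if (nm %in% names(planes)) planes[[nm]] else matrix(0, nr, nc)
  })
  names(full) <- colnames(lib$profiles)
  structure(list(abundance = full, residual = matrix(0, nr, nc),
                 library = lib), class = "abundance_maps")
}
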