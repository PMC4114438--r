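test_that("autoadaptive threshold separates bimodal planes and matches the brute-force criterion", {
  pl <- matrix(c(rep(0, 50), rep(100, 50)), 10, 10)
  thr <- autoadaptive_threshold(pl)
  expect_gt(thr, 0); expect_lt(thr, 100)
  expect_true(is.na(autoadaptive_threshold(matrix(3, 5, 5))))
  # 3-level plane with known counts equals exhaustive maximization
  v <- c(rep(0, 40), rep(10, 35), rep(100, 25))
  pl3 <- matrix(v, 10, 10)
  expect_equal(autoadaptive_threshold(pl3), otsu_brute(v))
  # offset factor scales the cutoff
  expect_equal(autoadaptive_threshold(pl3, offset = 1.5),
               otsu_brute(v) * 1.5)
})

test_that("autoadaptive threshold is approximately scale-equivariant", {
  # in the fluorescence regime (intensities >> 1, where log1p ~ log) the
  # Otsu cutoff must track a multiplicative rescaling of the plane
  set.seed(21)
  for (i in 1:20) {
    v <- c(abs(stats::rnorm(80, 30, 4)), abs(stats::rnorm(40, 300, 40)))
    thr1 <- autoadaptive_threshold(matrix(v, 12, 10))
    cc <- stats::runif(1, 0.5, 20)
    thr2 <- autoadaptive_threshold(matrix(cc * v, 12, 10))
    expect_equal(thr2 / thr1, cc, tolerance = 0.05)
  }
})

test_that("pixel classification matches generator ground truth at zero noise", {
  lib <- test_library()
  cfg <- small_config()
  for (sd_ in 1:3) {
    sc <- simulate_scene(small_scene_params(), seed = sd_)
    img <- render_multispectral(sc, lib, noise_sd = 0)
    seg <- segment_field(unmix_image(img, lib), cfg)
    expect_equal(mean(seg$labels$labels == sc$labels), 1)
    expect_equal(seg$labels$nucleus, sc$nucleus)
  }
})

test_that("pixel classification rules: all-background, precedence, missing channel", {
  lib <- test_library()
  zero <- fake_maps(list(), lib)
  thr <- segmentation_thresholds(zero)
  lab <- classify_pixels(zero, thr)
  expect_true(all(lab$labels == qmif_labels[["background"]]))
  # pixel above both basal and epithelial cutoffs is basal
  epi <- matrix(0, 8, 8); epi[4, 4] <- 6
  bas <- matrix(0, 8, 8); bas[4, 4] <- 6
  maps <- fake_maps(list(Alexa488 = epi, Alexa555 = bas), lib)
  lab <- classify_pixels(maps,
                         list(basal = 3, epithelial = 3, nuclear = NA_real_,
                              afl = NA_real_),
                         min_basal_area_px = 1, min_island_px = 1)
  expect_equal(lab$labels[4, 4], unname(qmif_labels[["basal"]]))
  # missing required channel errors
  m2 <- structure(list(abundance = list(DAPI = epi), residual = epi * 0,
                       library = lib), class = "abundance_maps")
  expect_error(classify_pixels(m2, list()), "missing required channel")
})

test_that("gland objects: areas, boundary filter, basal adjacency", {
  lab <- matrix(qmif_labels[["stroma"]], 40, 40)
  lab[5:12, 5:12] <- qmif_labels[["epithelium"]]     # 64 px gland
  lab[25:34, 20:31] <- qmif_labels[["epithelium"]]   # 120 px gland
  px <- structure(list(labels = lab, nucleus = lab > 99,
                       thresholds = list()), class = "pixel_labels")
  gl <- form_gland_objects(px, min_area_px = 50, basal_dist = 2)
  expect_equal(nrow(gl$table), 2L)
  expect_setequal(gl$table$area, c(64L, 120L))
  # fully enclosed by basal ring -> basal adjacency 1
  lab2 <- matrix(qmif_labels[["stroma"]], 20, 20)
  lab2[8:13, 8:13] <- qmif_labels[["epithelium"]]
  ring <- matrix(FALSE, 20, 20); ring[7:14, 7:14] <- TRUE
  ring[8:13, 8:13] <- FALSE
  lab2[ring] <- qmif_labels[["basal"]]
  px2 <- structure(list(labels = lab2, nucleus = lab2 > 99,
                        thresholds = list()), class = "pixel_labels")
  gl2 <- form_gland_objects(px2, min_area_px = 10, basal_dist = 2)
  expect_equal(gl2$table$basal_adjacency_fraction, 1.0)
  # component one pixel below the area cutoff is discarded
  lab3 <- matrix(qmif_labels[["stroma"]], 20, 20)
  lab3[2:8, 2:8] <- qmif_labels[["epithelium"]]      # 49 px
  px3 <- structure(list(labels = lab3, nucleus = lab3 > 99,
                        thresholds = list()), class = "pixel_labels")
  expect_equal(nrow(form_gland_objects(px3, min_area_px = 50)$table), 0L)
  expect_equal(nrow(form_gland_objects(px3, min_area_px = 49)$table), 1L)
})

test_that("components touching only diagonally form one 8-connected object", {
  lab <- matrix(qmif_labels[["stroma"]], 12, 12)
  lab[2:4, 2:4] <- qmif_labels[["epithelium"]]
  lab[5:7, 5:7] <- qmif_labels[["epithelium"]]  # touches at one diagonal
  px <- structure(list(labels = lab, nucleus = lab > 99,
                       thresholds = list()), class = "pixel_labels")
  gl <- form_gland_objects(px, min_area_px = 1)
  expect_equal(nrow(gl$table), 1L)
  expect_equal(gl$table$area, 18L)
})

test_that("gland classification thresholds behave as documented", {
  expect_equal(classify_gland(1.0), "benign")
  expect_equal(classify_gland(0.0), "malignant")
  expect_equal(classify_gland(0.15), "undetermined")
  expect_equal(classify_gland(c(0.3, 0.05)), c("benign", "malignant"))
  expect_error(classify_gland(0.5, f_benign = 0.05, f_malignant = 0.3),
               "f_malignant < f_benign")
  expect_error(classify_gland(1.2), "\\[0, 1\\]")
})

test_that("compartments partition the whole-cell mask", {
  lab <- matrix(qmif_labels[["stroma"]], 30, 30)
  lab[5:14, 5:24] <- qmif_labels[["epithelium"]]   # 200 px gland
  nuc <- matrix(FALSE, 30, 30)
  nuc[5:8, 5:14] <- TRUE                           # 40 px inside the gland
  px <- structure(list(labels = lab, nucleus = nuc, thresholds = list()),
                  class = "pixel_labels")
  gl <- classify_glands(form_gland_objects(px, min_area_px = 10))
  expect_equal(gl$table$class, "malignant")
  cm <- extract_compartments(px, gl)
  expect_equal(sum(cm$malignant$nucleus), 40L)
  expect_equal(sum(cm$malignant$cytoplasm), 160L)
  expect_true(all(cm$malignant$whole ==
                    (cm$malignant$nucleus | cm$malignant$cytoplasm)))
  expect_false(any(cm$malignant$nucleus & cm$malignant$cytoplasm))
  # no nuclei -> cytoplasm is the whole cell; full nuclei -> empty cytoplasm
  px$nucleus <- matrix(FALSE, 30, 30)
  cm2 <- extract_compartments(px, gl)
  expect_equal(cm2$malignant$cytoplasm, cm2$malignant$whole)
  px$nucleus <- matrix(TRUE, 30, 30)
  cm3 <- extract_compartments(px, gl)
  expect_equal(sum(cm3$malignant$cytoplasm), 0L)
  # excluded pixels are removed from every compartment
  excl <- matrix(FALSE, 30, 30); excl[5:14, 5] <- TRUE
  cm4 <- extract_compartments(px, gl, exclude = excl)
  expect_equal(sum(cm4$malignant$whole), 190L)
})

test_that("compartment partition invariant holds on noisy pipeline output", {
  lib <- test_library()
  cfg <- small_config()
  sc <- simulate_scene(small_scene_params(), seed = 9)
  img <- render_multispectral(sc, lib, noise_sd = noise_5pct, seed = 2)
  maps <- unmix_image(img, lib)
  seg <- segment_field(maps, cfg)
  bafl <- flag_bright_autofluorescence(maps, threshold = cfg$bafl_threshold)
  cm <- extract_compartments(seg$labels, seg$glands, exclude = bafl)
  for (cl in c("malignant", "benign")) {
    expect_true(all(cm[[cl]]$whole ==
                      (cm[[cl]]$nucleus | cm[[cl]]$cytoplasm)))
    expect_false(any(cm[[cl]]$nucleus & cm[[cl]]$cytoplasm))
    expect_false(any(cm[[cl]]$whole & bafl))
  }
})

test_that("field QC flags empty, defocused and clean fields correctly", {
  lib <- test_library()
  cfg <- small_config()
  # empty field: no epithelium at all
  empty <- fake_maps(list(), lib)
  thr <- segmentation_thresholds(empty)
  lab <- classify_pixels(empty, thr)
  gl <- classify_glands(form_gland_objects(lab))
  qc <- field_qc(lab, gl, empty$abundance$DAPI,
                 min_cancer_area_px = cfg$min_cancer_area_px)
  expect_false(qc$pass)
  expect_true(qc$flags[["insufficient_epithelium"]])
  # crisp synthetic field passes the focus check; blurred fails
  sc <- simulate_scene(small_scene_params(), seed = 3)
  img <- render_multispectral(sc, lib, noise_sd = 0)
  maps <- unmix_image(img, lib)
  seg <- segment_field(maps, cfg)
  dapi <- maps$abundance$DAPI
  qc1 <- field_qc(seg$labels, seg$glands, dapi,
                  min_cancer_area_px = cfg$min_cancer_area_px,
                  focus_metric_min = cfg$focus_metric_min)
  expect_true(qc1$pass)
  blurred <- as.matrix(EBImage::gblur(dapi, sigma = 4))
  qc2 <- field_qc(seg$labels, seg$glands, blurred,
                  min_cancer_area_px = cfg$min_cancer_area_px,
                  focus_metric_min = cfg$focus_metric_min)
  expect_true(qc2$flags[["out_of_focus"]])
  expect_lt(qc2$focus_metric, qc1$focus_metric)
  # saturation artifact flag
  sat <- matrix(TRUE, nrow(dapi), ncol(dapi))
  qc3 <- field_qc(seg$labels, seg$glands, dapi,
                  min_cancer_area_px = cfg$min_cancer_area_px,
                  saturated = sat)
  expect_true(qc3$flags[["artifact"]])
})

test_that("pixel accuracy stays above 0.98 at 5% noise", {
  lib <- test_library()
  cfg <- small_config()
  sc <- simulate_scene(small_scene_params(), seed = 3)
  img <- render_multispectral(sc, lib, noise_sd = noise_5pct, seed = 11)
  seg <- segment_field(unmix_image(img, lib), cfg)
  expect_gte(mean(seg$labels$labels == sc$labels), 0.98)
})

test_that("benign/malignant calls agree with scene truth under noise", {
  lib <- test_library()
  cfg <- small_config()
  for (sd_ in 1:3) {
    sc <- simulate_scene(small_scene_params(), seed = sd_)
    img <- render_multispectral(sc, lib, noise_sd = noise_5pct,
                                seed = 100 + sd_)
    seg <- segment_field(unmix_image(img, lib), cfg)
    expect_equal(nrow(seg$glands$table), nrow(sc$gland_table))
    for (gid in seg$glands$table$id) {
      tid <- sc$gland_map[seg$glands$gland_map == gid]
      tid <- as.integer(names(which.max(table(tid[tid > 0]))))
      expect_equal(seg$glands$table$class[seg$glands$table$id == gid],
                   sc$gland_table$class[sc$gland_table$id == tid])
    }
  }
})
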