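#' Pixel label codes used by the segmenter
#'
#' Integer codes of the primary pixel classes. Every pixel receives exactly
#' one primary label; the nucleus is a parallel boolean overlay, not a
#' primary class.
#'
#' @format Named integer vector.
#' @export
qmif_labels <- c(background = 0L, stroma = 1L, epithelium = 2L, basal = 3L)

#' Auto-adaptive intensity threshold for one channel
#'
#' Per-field adaptive cutoff: Otsu's criterion (maximum between-class
#' variance) evaluated exhaustively over all cut points of the
#' `log1p`-transformed intensities, mapped back to linear units and scaled by
#' a configurable offset factor. The log transform makes the criterion robust
#' to the heavy right tail of fluorescence intensities. Deterministic for a
#' fixed input.
#'
#' @param plane non-negative numeric matrix (one abundance or intensity
#'   channel).
#' @param offset multiplicative offset applied to the Otsu cutoff
#'   (default 1.0).
#' @return Threshold in linear intensity units, or `NA_real_` (the
#'   "no foreground" sentinel) when the plane is constant.
#' @export
autoadaptive_threshold <- function(plane, offset = 1.0) {
  v <- as.numeric(plane)
  if (any(!is.finite(v)) || any(v < 0))
    stop("plane must be finite and non-negative")
  x <- sort(log1p(v))
  n <- length(x)
  cuts <- which(diff(x) > 0)           # cut between x[i] and x[i+1]
  if (!length(cuts)) return(NA_real_)  # constant plane: no foreground
  cs <- cumsum(x)
  w1 <- cuts / n
  m1 <- cs[cuts] / cuts
  m2 <- (cs[n] - cs[cuts]) / (n - cuts)
  between <- w1 * (1 - w1) * (m1 - m2)^2
  k <- cuts[which.max(between)]
  expm1((x[k] + x[k + 1L]) / 2) * offset
}

#' Compute the per-field segmentation thresholds
#'
#' Applies [autoadaptive_threshold()] to the basal, epithelial, nuclear
#' (DAPI) and diffuse-autofluorescence (AFL) channels. Each channel gets its
#' own cutoff: a pixel counts as tissue when any tissue signal — DAPI or AFL
#' — exceeds its channel's cutoff.
#'
#' @param maps an `abundance_maps` object.
#' @param channels named list mapping roles to endmember names; needs `dapi`,
#'   `epithelial`, `basal` and optionally `afl`.
#' @param offset threshold offset factor passed through.
#' @return Named list with elements `basal`, `epithelial`, `nuclear`, `afl`
#'   (the latter `NA` when the library has no AFL channel).
#' @export
segmentation_thresholds <- function(maps,
                                    channels = list(dapi = "DAPI",
                                                    epithelial = "Alexa488",
                                                    basal = "Alexa555",
                                                    afl = "AFL"),
                                    offset = 1.0) {
  stopifnot(inherits(maps, "abundance_maps"))
  need <- c("dapi", "epithelial", "basal")
  if (!all(need %in% names(channels)))
    stop("channels must name dapi, epithelial and basal endmembers")
  pl <- function(nm) {
    if (!nm %in% names(maps$abundance)) stop("missing channel: ", nm)
    maps$abundance[[nm]]
  }
  list(basal      = autoadaptive_threshold(pl(channels$basal), offset),
       epithelial = autoadaptive_threshold(pl(channels$epithelial), offset),
       nuclear    = autoadaptive_threshold(pl(channels$dapi), offset),
       afl        = if (!is.null(channels$afl) &&
                        channels$afl %in% names(maps$abundance))
         autoadaptive_threshold(pl(channels$afl), offset) else NA_real_)
}

#' Classify pixels into basal / epithelium / stroma / background
#'
#' Fixed precedence basal > epithelium > stroma: a pixel above the basal
#' threshold is basal regardless of the other channels; otherwise epithelium
#' if above the epithelial threshold; otherwise stroma if any tissue signal
#' exceeds its cutoff (DAPI above the nuclear cutoff or AFL above the AFL
#' cutoff); otherwise background. A
#' parallel nucleus overlay marks DAPI above the nuclear threshold. A
#' threshold equal to the `NA` sentinel disables its rule.
#'
#' The basal call is relational: basal cells form the outer layer of glands,
#' so the basal rule is evaluated — and its auto-adaptive threshold computed
#' — only within a band of `basal_band_px` around epithelium-positive
#' pixels. This keeps the sparse basal channel's threshold away from the
#' global background mass, where zero-inflated unmixing noise would
#' otherwise dominate Otsu's criterion. Setting `basal_band_px = NULL` falls
#' back to the global threshold in `thresholds$basal`.
#'
#' Two object-size cleanup passes follow the per-pixel cascade, in the spirit
#' of object-based tissue segmentation: basal and epithelium components
#' smaller than
#' `min_basal_area_px` are demoted (basal layers and glands are contiguous
#' structures, isolated positive pixels are noise), and
#' background/stroma islands smaller than `min_island_px` are absorbed by
#' their surroundings. Real structures — basal rings, gland lumens, the
#' tissue core — exceed these minima by an order of magnitude, so the
#' cleanup is a no-op on clean images.
#'
#' @param maps an `abundance_maps` object.
#' @param thresholds named list as returned by [segmentation_thresholds()].
#' @param channels channel name mapping, as in [segmentation_thresholds()].
#' @param min_basal_area_px minimum pixel count of a retained basal or
#'   epithelium component (default 5).
#' @param min_island_px minimum pixel count of a retained background or
#'   stroma component (default 25; well below any genuine lumen).
#' @param basal_band_px Chebyshev radius of the epithelium-adjacent band in
#'   which basal cells are sought (default 4).
#' @return Object of class `pixel_labels`: list with `labels` (integer matrix
#'   coded by [qmif_labels]), `nucleus` (logical matrix) and `thresholds`.
#' @export
classify_pixels <- function(maps, thresholds,
                            channels = list(dapi = "DAPI",
                                            epithelial = "Alexa488",
                                            basal = "Alexa555",
                                            afl = "AFL"),
                            min_basal_area_px = 5, min_island_px = 25,
                            basal_band_px = 4) {
  stopifnot(inherits(maps, "abundance_maps"))
  need <- c(channels$dapi, channels$epithelial, channels$basal)
  miss <- setdiff(need, names(maps$abundance))
  if (length(miss)) stop("missing required channel(s): ",
                         paste(miss, collapse = ", "))
  dapi <- maps$abundance[[channels$dapi]]
  epi  <- maps$abundance[[channels$epithelial]]
  bas  <- maps$abundance[[channels$basal]]

  gt <- function(plane, thr) if (is.na(thr)) plane > Inf else plane > thr
  tissue <- gt(dapi, thresholds$nuclear)
  if (!is.null(channels$afl) && channels$afl %in% names(maps$abundance) &&
      !is.null(thresholds$afl))
    tissue <- tissue | gt(maps$abundance[[channels$afl]], thresholds$afl)
  lab <- matrix(qmif_labels[["background"]], nrow(dapi), ncol(dapi))
  lab[tissue] <- qmif_labels[["stroma"]]
  epi_pos <- gt(epi, thresholds$epithelial)
  lab[epi_pos] <- qmif_labels[["epithelium"]]
  if (is.null(basal_band_px)) {
    lab[gt(bas, thresholds$basal)] <- qmif_labels[["basal"]]
  } else if (any(epi_pos)) {
    band <- dilate_chebyshev(epi_pos, basal_band_px)
    thr_b <- autoadaptive_threshold(bas[band])
    thresholds$basal <- thr_b
    if (!is.na(thr_b)) lab[band & bas > thr_b] <- qmif_labels[["basal"]]
  }

  drop_small <- function(mask, min_px) {
    comp <- label_components_8(mask)
    sz <- tabulate(comp[comp > 0L])
    small <- which(sz < min_px)
    if (!length(small)) return(mask & FALSE)
    matrix(comp %in% small, nrow(mask), ncol(mask))
  }
  if (min_basal_area_px > 1) {
    demote <- drop_small(lab == qmif_labels[["basal"]], min_basal_area_px)
    if (any(demote)) {
      lab[demote] <- qmif_labels[["background"]]
      lab[demote & epi_pos] <- qmif_labels[["epithelium"]]
      lab[demote & lab == qmif_labels[["background"]] & tissue] <-
        qmif_labels[["stroma"]]
    }
    demote <- drop_small(lab == qmif_labels[["epithelium"]],
                         min_basal_area_px)
    if (any(demote)) {
      lab[demote & tissue] <- qmif_labels[["stroma"]]
      lab[demote & !tissue] <- qmif_labels[["background"]]
    }
  }
  if (min_island_px > 1) {
    isl <- drop_small(lab == qmif_labels[["background"]], min_island_px)
    lab[isl] <- qmif_labels[["stroma"]]
    isl <- drop_small(lab == qmif_labels[["stroma"]], min_island_px)
    lab[isl] <- qmif_labels[["background"]]
  }
  structure(list(labels = lab,
                 nucleus = gt(dapi, thresholds$nuclear),
                 thresholds = thresholds),
            class = "pixel_labels")
}

#' @export
print.pixel_labels <- function(x, ...) {
  tab <- table(factor(x$labels, levels = qmif_labels,
                      labels = names(qmif_labels)))
  cat("pixel_labels:", paste(names(tab), as.integer(tab), sep = "=",
                             collapse = ", "),
      sprintf("; nucleus overlay %d px\n", sum(x$nucleus)))
  invisible(x)
}

# 8-connected component labelling: EBImage::bwlabel is 4-connected, so merge
# labels that touch diagonally with a small union-find pass.
label_components_8 <- function(mask) {
  lbl <- EBImage::bwlabel(mask * 1L)
  nlab <- max(lbl)
  if (nlab < 2L) return(lbl)
  nr <- nrow(lbl); nc <- ncol(lbl)
  a1 <- lbl[-nr, -nc]; b1 <- lbl[-1L, -1L]   # down-right diagonal
  a2 <- lbl[-nr, -1L]; b2 <- lbl[-1L, -nc]   # down-left diagonal
  pa <- c(a1, a2); pb <- c(b1, b2)
  keep <- pa > 0L & pb > 0L & pa != pb
  if (!any(keep)) return(lbl)
  pairs <- unique(cbind(pmin(pa[keep], pb[keep]), pmax(pa[keep], pb[keep])))
  parent <- seq_len(nlab)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (r in seq_len(nrow(pairs))) {
    ra <- find(pairs[r, 1L]); rb <- find(pairs[r, 2L])
    if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
  }
  root <- vapply(seq_len(nlab), find, integer(1L))
  relab <- match(root, sort(unique(root)))
  out <- lbl
  out[lbl > 0L] <- relab[lbl[lbl > 0L]]
  out
}

# 8-neighbourhood binary dilation iterated d times = Chebyshev-distance-d
# coverage.
dilate_chebyshev <- function(mask, d) {
  m <- mask
  nr <- nrow(m); nc <- ncol(m)
  pad <- function(x, dr, dc) {
    out <- matrix(FALSE, nr, nc)
    rs <- seq_len(nr) + dr; cs <- seq_len(nc) + dc
    ok_r <- rs >= 1L & rs <= nr; ok_c <- cs >= 1L & cs <= nc
    out[rs[ok_r], cs[ok_c]] <- x[which(ok_r), which(ok_c)]
    out
  }
  for (i in seq_len(d)) {
    m <- m | pad(m, 1, 0) | pad(m, -1, 0) | pad(m, 0, 1) | pad(m, 0, -1) |
      pad(m, 1, 1) | pad(m, 1, -1) | pad(m, -1, 1) | pad(m, -1, -1)
  }
  m
}

#' Form gland objects from a pixel label map
#'
#' Gland candidates are 8-connected components of epithelium pixels;
#' components below the minimum area are discarded. The gland boundary is the
#' set of epithelium pixels with at least one non-epithelium 4-neighbour
#' (image borders count as non-epithelium). The basal adjacency fraction of a
#' gland is the fraction of its boundary pixels having at least one basal
#' pixel within Chebyshev distance `basal_dist` — the quantitative form of
#' "epithelial structure with an outer layer of basal cells".
#'
#' @param labels a `pixel_labels` object.
#' @param min_area_px minimum component area in pixels (default 50).
#' @param basal_dist Chebyshev adjacency distance in pixels (default 2).
#' @return Object of class `gland_set`: list with `gland_map` (integer matrix,
#'   0 where no gland) and `table` (data frame: id, area,
#'   basal_adjacency_fraction, class — class is `NA` until
#'   [classify_glands()]).
#' @export
form_gland_objects <- function(labels, min_area_px = 50, basal_dist = 2) {
  stopifnot(inherits(labels, "pixel_labels"))
  epi <- labels$labels == qmif_labels[["epithelium"]]
  comp <- label_components_8(epi)
  areas <- tabulate(comp[comp > 0L])
  keep <- which(areas >= min_area_px)
  gland_map <- matrix(0L, nrow(epi), ncol(epi))
  tab <- data.frame(id = integer(0), area = integer(0),
                    basal_adjacency_fraction = numeric(0),
                    class = character(0))
  if (length(keep)) {
    relab <- integer(length(areas))
    relab[keep] <- seq_along(keep)
    inside <- comp > 0L
    gland_map[inside] <- relab[comp[inside]]

    nr <- nrow(epi); nc <- ncol(epi)
    shift_or_border <- function(dr, dc) {
      out <- matrix(TRUE, nr, nc)     # outside the image is non-epithelium
      rs <- seq_len(nr) + dr; cs <- seq_len(nc) + dc
      ok_r <- rs >= 1L & rs <= nr; ok_c <- cs >= 1L & cs <= nc
      out[rs[ok_r], cs[ok_c]] <- !epi[which(ok_r), which(ok_c)]
      out
    }
    boundary <- epi & (shift_or_border(1, 0) | shift_or_border(-1, 0) |
                         shift_or_border(0, 1) | shift_or_border(0, -1))
    near_basal <- dilate_chebyshev(labels$labels == qmif_labels[["basal"]],
                                   basal_dist)
    b_id <- gland_map[boundary]
    n_boundary <- tabulate(b_id[b_id > 0L], nbins = length(keep))
    c_id <- gland_map[boundary & near_basal]
    n_covered <- tabulate(c_id[c_id > 0L], nbins = length(keep))
    tab <- data.frame(id = seq_along(keep),
                      area = areas[keep],
                      basal_adjacency_fraction = ifelse(n_boundary > 0,
                                                        n_covered / n_boundary,
                                                        0),
                      class = NA_character_)
  }
  structure(list(gland_map = gland_map, table = tab,
                 params = list(min_area_px = min_area_px,
                               basal_dist = basal_dist)),
            class = "gland_set")
}

#' @export
print.gland_set <- function(x, ...) {
  cat(sprintf("gland_set: %d glands", nrow(x$table)))
  if (nrow(x$table) && !all(is.na(x$table$class))) {
    tb <- table(x$table$class, useNA = "no")
    cat(" (", paste(names(tb), as.integer(tb), sep = "=", collapse = ", "),
        ")", sep = "")
  }
  cat("\n")
  invisible(x)
}

#' Classify a gland as benign, malignant or undetermined
#'
#' Benign prostate glands retain a basal-cell outer layer; carcinoma glands
#' lack one. A gland is called benign when its basal adjacency fraction is at
#' least `f_benign`, malignant when at most `f_malignant`, and undetermined
#' in between.
#'
#' @param basal_adjacency_fraction numeric in \[0, 1\] (vectorized).
#' @param f_benign lower bound of the benign call (default 0.3).
#' @param f_malignant upper bound of the malignant call (default 0.05);
#'   must satisfy `0 <= f_malignant < f_benign <= 1`.
#' @return Character vector in `c("benign", "malignant", "undetermined")`.
#' @export
classify_gland <- function(basal_adjacency_fraction, f_benign = 0.3,
                           f_malignant = 0.05) {
  if (!(f_malignant >= 0 && f_malignant < f_benign && f_benign <= 1))
    stop("need 0 <= f_malignant < f_benign <= 1")
  if (any(basal_adjacency_fraction < 0 | basal_adjacency_fraction > 1,
          na.rm = TRUE))
    stop("basal adjacency fraction must lie in [0, 1]")
  ifelse(basal_adjacency_fraction >= f_benign, "benign",
         ifelse(basal_adjacency_fraction <= f_malignant, "malignant",
                "undetermined"))
}

#' @rdname classify_gland
#' @param glands a `gland_set`.
#' @return `classify_glands` returns the `gland_set` with the `class` column
#'   filled in.
#' @export
classify_glands <- function(glands, f_benign = 0.3, f_malignant = 0.05) {
  stopifnot(inherits(glands, "gland_set"))
  glands$table$class <- classify_gland(glands$table$basal_adjacency_fraction,
                                       f_benign, f_malignant)
  glands
}

#' Extract per-class cellular compartment masks
#'
#' For each gland class, the whole-cell mask is the union of its glands'
#' pixels minus any excluded pixels (BAFL granules, saturation); the nucleus
#' compartment is its intersection with the nucleus overlay and the cytoplasm
#' is the set difference, so nucleus and cytoplasm partition the whole-cell
#' mask exactly.
#'
#' @param labels a `pixel_labels` object.
#' @param glands a classified `gland_set`.
#' @param exclude optional logical matrix of excluded pixels.
#' @return Object of class `compartment_masks`: per class (`malignant`,
#'   `benign`) a list of logical masks `whole`, `nucleus`, `cytoplasm`.
#' @export
extract_compartments <- function(labels, glands, exclude = NULL) {
  stopifnot(inherits(labels, "pixel_labels"), inherits(glands, "gland_set"))
  if (any(is.na(glands$table$class)))
    stop("glands must be classified first (classify_glands)")
  if (is.null(exclude))
    exclude <- matrix(FALSE, nrow(labels$labels), ncol(labels$labels))
  out <- lapply(c(malignant = "malignant", benign = "benign"), function(cl) {
    ids <- glands$table$id[glands$table$class == cl]
    whole <- matrix(gland_map_in(glands$gland_map, ids),
                    nrow(labels$labels), ncol(labels$labels)) & !exclude
    nucleus <- whole & labels$nucleus
    list(whole = whole, nucleus = nucleus, cytoplasm = whole & !nucleus)
  })
  structure(out, class = "compartment_masks")
}

gland_map_in <- function(gland_map, ids) {
  if (!length(ids)) return(rep(FALSE, length(gland_map)))
  gland_map %in% ids
}

# variance of the 4-neighbour Laplacian of the plane normalized to unit mean;
# scale-invariant sharpness metric
laplacian_focus <- function(plane) {
  m <- mean(plane)
  if (m <= 0) return(0)
  x <- plane / m
  nr <- nrow(x); nc <- ncol(x)
  if (nr < 3L || nc < 3L) return(0)
  ctr <- x[2:(nr - 1), 2:(nc - 1)]
  lap <- 4 * ctr - x[1:(nr - 2), 2:(nc - 1)] - x[3:nr, 2:(nc - 1)] -
    x[2:(nr - 1), 1:(nc - 2)] - x[2:(nr - 1), 3:nc]
  stats::var(as.numeric(lap))
}

#' Field-level quality control
#'
#' A 20X field is excluded from quantification when it has insufficient
#' cancer epithelium, is out of focus (variance of the Laplacian of the
#' mean-normalized DAPI plane below a floor), or shows a staining/saturation
#' artifact (saturated-pixel fraction above a cap).
#'
#' @param labels a `pixel_labels` object.
#' @param glands a classified `gland_set`.
#' @param dapi_plane DAPI abundance matrix used for the focus metric.
#' @param min_cancer_area_px minimum malignant epithelium area (default 500).
#' @param focus_metric_min focus floor (default 0.5; the metric is
#'   scale-invariant).
#' @param saturated_frac_max cap on the saturated-pixel fraction
#'   (default 0.05).
#' @param saturated optional logical matrix of saturated pixels.
#' @return Object of class `field_qc_report`: list with `flags` (named
#'   logical), `cancer_area_px`, `focus_metric`, `saturated_fraction`,
#'   `pass`.
#' @export
field_qc <- function(labels, glands, dapi_plane,
                     min_cancer_area_px = 500,
                     focus_metric_min = 0.5,
                     saturated_frac_max = 0.05,
                     saturated = NULL) {
  stopifnot(inherits(labels, "pixel_labels"), inherits(glands, "gland_set"))
  cls <- glands$table$class
  cancer_area <- if (nrow(glands$table))
    sum(glands$table$area[!is.na(cls) & cls == "malignant"]) else 0L
  focus <- laplacian_focus(dapi_plane)
  sat_frac <- if (is.null(saturated)) 0 else mean(saturated)
  flags <- c(insufficient_epithelium = cancer_area < min_cancer_area_px,
             out_of_focus = focus < focus_metric_min,
             artifact = sat_frac > saturated_frac_max)
  structure(list(flags = flags, cancer_area_px = cancer_area,
                 focus_metric = focus, saturated_fraction = sat_frac,
                 pass = !any(flags)),
            class = "field_qc_report")
}

#' @export
print.field_qc_report <- function(x, ...) {
  cat(sprintf("field_qc: %s (cancer area %d px, focus %.3g, saturated %.3g)\n",
              if (x$pass) "PASS" else
                paste("FAIL:", paste(names(which(x$flags)), collapse = ", ")),
              x$cancer_area_px, x$focus_metric, x$saturated_fraction))
  invisible(x)
}
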