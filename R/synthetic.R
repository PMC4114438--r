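# Evaluate code with a locally scoped RNG seed, restoring the caller's
# random state afterwards.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = .GlobalEnv)
  on.exit({
    if (had) assign(".Random.seed", old, envir = .GlobalEnv)
    else if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE))
      rm(".Random.seed", envir = .GlobalEnv)
  })
  set.seed(seed)
  code
}

#' Scene generation parameters
#'
#' Defaults mimic two 20X fields of a 1 mm prostate TMA core at 0.5 um/px:
#' a 512 x 512 px field with 6-10 glands of 20-60 px radius, a 2-3 px basal
#' ring around benign glands, 3-5 px nuclei, and bright-autofluorescence
#' granules mostly inside benign epithelium.
#'
#' @param size image size in px, length 2 (rows, cols).
#' @param tissue_frac radius of the elliptical tissue (core) region as a
#'   fraction of each half-dimension; outside it lies glass background.
#' @param n_benign,n_malignant gland counts.
#' @param radius_range semi-major axis range, px.
#' @param lumen_frac gland lumen radius as a fraction of the gland radius.
#' @param basal_thickness_range basal ring thickness range, px (benign only).
#' @param nucleus_radius_range nucleus radius range, px.
#' @param nuclei_per_100px nuclei seeded per 100 px of epithelium area.
#' @param n_stroma_nuclei count of scattered stromal nuclei.
#' @param n_bafl_granules count of BAFL granules (radius 1-2 px).
#' @param max_retries placement retries before giving up.
#' @return Named list of parameters for [simulate_scene()].
#' @export
scene_params <- function(size = c(512, 512), tissue_frac = 0.92,
                         n_benign = 4, n_malignant = 4,
                         radius_range = c(20, 60), lumen_frac = 0.45,
                         basal_thickness_range = c(2, 3),
                         nucleus_radius_range = c(3, 5),
                         nuclei_per_100px = 1.2, n_stroma_nuclei = 40,
                         n_bafl_granules = 25, max_retries = 200) {
  list(size = size, tissue_frac = tissue_frac,
       n_benign = n_benign, n_malignant = n_malignant,
       radius_range = radius_range, lumen_frac = lumen_frac,
       basal_thickness_range = basal_thickness_range,
       nucleus_radius_range = nucleus_radius_range,
       nuclei_per_100px = nuclei_per_100px,
       n_stroma_nuclei = n_stroma_nuclei,
       n_bafl_granules = n_bafl_granules, max_retries = max_retries)
}

#' Simulate a ground-truth glandular tissue scene
#'
#' Places non-overlapping elliptical glands on a stromal background inside an
#' elliptical tissue (core) region surrounded by glass background — TMA
#' fields routinely include the core edge. Each
#' gland is a lumen (background class) surrounded by an epithelial ring;
#' benign glands additionally carry a closed basal outer ring, malignant
#' glands carry none — the structural difference the segmenter's
#' benign/malignant call rests on. Disk nuclei are seeded inside epithelium
#' (and sparsely in stroma), and bright-autofluorescence granules are placed
#' mostly in benign epithelium. Deterministic for a fixed seed.
#'
#' @param params parameter list from [scene_params()].
#' @param seed integer seed.
#' @return Object of class `scene_truth`: list with `labels` (integer matrix
#'   coded by [qmif_labels]), `nucleus` (logical matrix), `gland_map`
#'   (integer matrix of gland ids over epithelium), `gland_table` (data
#'   frame: id, class, area, basal_ring), `bafl` (logical matrix), `params`,
#'   `seed`.
#' @export
simulate_scene <- function(params = scene_params(), seed = 1) {
  with_seed(seed, {
    nr <- params$size[1L]; nc <- params$size[2L]
    n_glands <- params$n_benign + params$n_malignant
    classes <- sample(c(rep("benign", params$n_benign),
                        rep("malignant", params$n_malignant)))
    gland_map <- matrix(0L, nr, nc)
    nucleus <- matrix(FALSE, nr, nc)
    bafl <- matrix(FALSE, nr, nc)

    rows <- matrix(seq_len(nr), nr, nc)
    cols <- matrix(seq_len(nc), nr, nc, byrow = TRUE)

    # elliptical tissue core on glass background
    cr0 <- (nr + 1) / 2; cc0 <- (nc + 1) / 2
    ta <- params$tissue_frac * nr / 2; tb <- params$tissue_frac * nc / 2
    core_rho <- sqrt(((rows - cr0) / ta)^2 + ((cols - cc0) / tb)^2)
    labels <- matrix(qmif_labels[["background"]], nr, nc)
    labels[core_rho <= 1] <- qmif_labels[["stroma"]]

    placed <- data.frame(r = numeric(0), c = numeric(0), rad = numeric(0))
    gland_table <- data.frame(id = integer(0), class = character(0),
                              area = integer(0), basal_ring = logical(0))
    gap <- 5  # clearance so one gland's boundary never abuts another's ring
    id <- 0L
    for (g in seq_len(n_glands)) {
      cl <- classes[g]
      bt <- if (cl == "benign")
        stats::runif(1, params$basal_thickness_range[1L],
                     params$basal_thickness_range[2L]) else 0
      ok <- FALSE
      for (try in seq_len(params$max_retries)) {
        a <- stats::runif(1, params$radius_range[1L], params$radius_range[2L])
        b <- stats::runif(1, 0.65 * a, a)
        th <- stats::runif(1, 0, pi)
        margin <- a + bt + 2
        if (2 * margin + 2 > min(nr, nc)) next
        cr <- stats::runif(1, margin + 1, nr - margin)
        cc <- stats::runif(1, margin + 1, nc - margin)
        inside_core <- sqrt(((cr - cr0) / ta)^2 + ((cc - cc0) / tb)^2) <
          1 - (margin + gap) / min(ta, tb)
        if (inside_core &&
            (!nrow(placed) ||
             all(sqrt((placed$r - cr)^2 + (placed$c - cc)^2) >
                 placed$rad + margin + gap))) {
          ok <- TRUE
          break
        }
      }
      if (!ok) stop("could not place gland ", g, " after ",
                    params$max_retries, " retries; reduce counts or radii")
      placed <- rbind(placed, data.frame(r = cr, c = cc, rad = margin))
      id <- id + 1L

      dx <- rows - cr; dy <- cols - cc
      u <- dx * cos(th) + dy * sin(th)
      v <- -dx * sin(th) + dy * cos(th)
      rho <- sqrt((u / a)^2 + (v / b)^2)
      rho_out <- sqrt((u / (a + bt))^2 + (v / (b + bt))^2)
      lumen <- rho <= params$lumen_frac
      epith <- rho > params$lumen_frac & rho <= 1
      labels[lumen] <- qmif_labels[["background"]]
      labels[epith] <- qmif_labels[["epithelium"]]
      gland_map[epith] <- id
      if (cl == "benign") {
        ring <- rho > 1 & rho_out <= 1
        labels[ring] <- qmif_labels[["basal"]]
      }

      # nuclei inside the epithelial ring
      epx <- which(epith)
      n_nuc <- max(2L, round(params$nuclei_per_100px * length(epx) / 100))
      ctr <- sample(epx, min(n_nuc, length(epx)))
      for (p in ctr) {
        rr <- stats::runif(1, params$nucleus_radius_range[1L],
                           params$nucleus_radius_range[2L])
        pr <- (p - 1L) %% nr + 1L; pc <- (p - 1L) %/% nr + 1L
        disk <- (rows - pr)^2 + (cols - pc)^2 <= rr^2
        nucleus <- nucleus | (disk & epith)
      }
      gland_table <- rbind(gland_table,
                           data.frame(id = id, class = cl,
                                      area = sum(epith),
                                      basal_ring = cl == "benign"))
    }

    # scattered stromal nuclei
    stroma_px <- which(labels == qmif_labels[["stroma"]])
    if (params$n_stroma_nuclei > 0 && length(stroma_px)) {
      ctr <- sample(stroma_px, min(params$n_stroma_nuclei, length(stroma_px)))
      for (p in ctr) {
        rr <- stats::runif(1, params$nucleus_radius_range[1L],
                           params$nucleus_radius_range[2L] - 1)
        pr <- (p - 1L) %% nr + 1L; pc <- (p - 1L) %/% nr + 1L
        disk <- (rows - pr)^2 + (cols - pc)^2 <= rr^2
        nucleus <- nucleus | (disk & labels == qmif_labels[["stroma"]])
      }
    }

    # BAFL granules, preferentially in benign epithelium
    benign_ids <- gland_table$id[gland_table$class == "benign"]
    host <- which(gland_map %in% benign_ids)
    if (!length(host)) host <- stroma_px
    if (params$n_bafl_granules > 0 && length(host)) {
      ctr <- sample(host, min(params$n_bafl_granules, length(host)))
      for (p in ctr) {
        rr <- stats::runif(1, 1, 2)
        pr <- (p - 1L) %% nr + 1L; pc <- (p - 1L) %/% nr + 1L
        bafl <- bafl | ((rows - pr)^2 + (cols - pc)^2 <= rr^2)
      }
    }

    structure(list(labels = labels, nucleus = nucleus, gland_map = gland_map,
                   gland_table = gland_table, bafl = bafl, params = params,
                   seed = seed),
              class = "scene_truth")
  })
}

#' @export
print.scene_truth <- function(x, ...) {
  cat(sprintf("scene_truth: %d x %d px, %d glands (%d benign, %d malignant), seed %d\n",
              nrow(x$labels), ncol(x$labels), nrow(x$gland_table),
              sum(x$gland_table$class == "benign"),
              sum(x$gland_table$class == "malignant"), x$seed))
  invisible(x)
}

#' Default endmember weights for rendering a scene
#'
#' Maps scene regions to endmember abundances: DAPI on nuclei, the
#' epithelial channel (Alexa488, KRT8/18) on epithelium, the basal channel
#' (Alexa555, KRT5/TRIM29) on basal rings, diffuse AFL over all tissue, BAFL
#' at the granules, and each biomarker's fluorophore in its configured
#' subcellular compartment of the tumor (and optionally benign) glands.
#'
#' @param markers named character vector: biomarker name -> endmember.
#' @param tumor named numeric: biomarker -> abundance planted in the tumor
#'   compartment.
#' @param benign named numeric: same for benign glands (defaults to
#'   `tumor/2`).
#' @param dapi,epithelial,basal,afl,bafl structural channel abundances.
#' @param compartment_map biomarker -> compartment ([marker_compartments()]).
#' @return Weight specification list for [render_multispectral()]: per
#'   endmember, a named vector of region weights.
#' @export
scene_weights <- function(markers = c(SMAD4 = "Alexa568", SPP1 = "Alexa633"),
                          tumor = c(SMAD4 = 2, SPP1 = 3),
                          benign = tumor / 2,
                          dapi = 8, epithelial = 6, basal = 6,
                          afl = 2, bafl = 15,
                          compartment_map = marker_compartments()) {
  w <- list(DAPI = c(nucleus = dapi),
            Alexa488 = c(epithelium = epithelial),
            Alexa555 = c(basal = basal),
            AFL = c(tissue = afl),
            BAFL = c(bafl = bafl))
  for (mk in names(markers)) {
    comp <- compartment_map[[mk]]
    if (is.null(comp)) stop("no compartment configured for marker ", mk)
    reg <- if (comp == "whole") "" else paste0("_", comp)
    em <- markers[[mk]]
    add <- c(stats::setNames(unname(tumor[mk]), paste0("tumor", reg)),
             stats::setNames(unname(benign[mk]), paste0("benign", reg)))
    w[[em]] <- c(w[[em]], add[!is.na(add)])
  }
  w
}

# logical mask for a named scene region
scene_region_mask <- function(scene, region) {
  lab <- scene$labels
  epi <- lab == qmif_labels[["epithelium"]]
  tumor_ids <- scene$gland_table$id[scene$gland_table$class == "malignant"]
  benign_ids <- scene$gland_table$id[scene$gland_table$class == "benign"]
  switch(region,
         nucleus = scene$nucleus,
         epithelium = epi,
         basal = lab == qmif_labels[["basal"]],
         stroma = lab == qmif_labels[["stroma"]],
         tissue = lab != qmif_labels[["background"]],
         all = lab == lab,
         bafl = scene$bafl,
         tumor = matrix(scene$gland_map %in% tumor_ids, nrow(lab), ncol(lab)),
         benign = matrix(scene$gland_map %in% benign_ids, nrow(lab),
                         ncol(lab)),
         tumor_nucleus = matrix(scene$gland_map %in% tumor_ids, nrow(lab),
                                ncol(lab)) & scene$nucleus,
         tumor_cytoplasm = matrix(scene$gland_map %in% tumor_ids, nrow(lab),
                                  ncol(lab)) & !scene$nucleus,
         benign_nucleus = matrix(scene$gland_map %in% benign_ids, nrow(lab),
                                 ncol(lab)) & scene$nucleus,
         benign_cytoplasm = matrix(scene$gland_map %in% benign_ids, nrow(lab),
                                   ncol(lab)) & !scene$nucleus,
         stop("unknown scene region: ", region))
}

#' Ground-truth abundance planes for a scene
#'
#' Expands a weight specification into per-endmember abundance matrices —
#' the planted truth that [unmix_image()] should recover.
#'
#' @param scene a `scene_truth`.
#' @param library a [spectral_library()].
#' @param weights weight specification from [scene_weights()].
#' @return Named list of abundance matrices, one per library endmember.
#' @export
scene_abundance_truth <- function(scene, library, weights) {
  stopifnot(inherits(scene, "scene_truth"),
            inherits(library, "spectral_library"))
  miss <- setdiff(names(weights), colnames(library$profiles))
  if (length(miss)) stop("library missing endmember(s): ",
                         paste(miss, collapse = ", "))
  nr <- nrow(scene$labels); nc <- ncol(scene$labels)
  planes <- lapply(colnames(library$profiles), function(em) {
    pl <- matrix(0, nr, nc)
    wv <- weights[[em]]
    for (region in names(wv))
      pl[scene_region_mask(scene, region)] <-
        pl[scene_region_mask(scene, region)] + wv[[region]]
    pl
  })
  names(planes) <- colnames(library$profiles)
  planes
}

#' Render a scene through the spectral forward model
#'
#' Builds the planted abundance planes and synthesizes the per-pixel spectra
#' (abundance-weighted sum of library profiles plus Gaussian noise, clipped
#' at zero) into a multispectral image.
#'
#' @param scene a `scene_truth`.
#' @param library a [spectral_library()].
#' @param weights weight specification ([scene_weights()]).
#' @param noise_sd Gaussian noise standard deviation in intensity units.
#' @param seed seed for the noise draw (ignored when `noise_sd = 0`).
#' @param meta metadata list stored on the image.
#' @return An [ms_image()]; the planted truth is attached as attribute
#'   `"truth"`.
#' @export
render_multispectral <- function(scene, library, weights = scene_weights(),
                                 noise_sd = 0, seed = 1, meta = list()) {
  truth <- scene_abundance_truth(scene, library, weights)
  nr <- nrow(scene$labels); nc <- ncol(scene$labels)
  A <- do.call(rbind, lapply(truth, as.numeric))   # endmembers x npix
  S <- library$profiles %*% A
  if (noise_sd > 0)
    S <- with_seed(seed, S + stats::rnorm(length(S), sd = noise_sd))
  S[S < 0] <- 0
  img <- ms_image(array(S, dim = c(nrow(S), nr, nc)),
                  band_centers = library$band_centers, meta = meta)
  attr(img, "truth") <- truth
  img
}

#' Cohort simulation design
#'
#' Markers are multivariate log-normal with exchangeable correlation; the
#' death-of-disease hazard is proportional,
#' `h(t) = h0 * exp(sum beta_k z_k)` with `z` the standardized log markers;
#' censoring is uniform on (0, `censor_max`). Defaults mirror the scale of a
#' prostatectomy TMA cohort: n = 340, about 35 events, about 12 years median
#' follow-up, tumor suppressors (PTEN, SMAD4) with negative log-hazard
#' coefficients and the lethality-associated markers positive. When
#' `baseline_hazard` is omitted it is calibrated numerically so the expected
#' event count matches `target_events`.
#'
#' @param n cohort size.
#' @param beta named log-hazard coefficients per standardized marker.
#' @param meanlog,sdlog log-normal parameters shared by all markers.
#' @param rho exchangeable correlation between markers' latent normals.
#' @param censor_max upper bound of the uniform censoring time (years).
#' @param target_events expected number of events used to calibrate `h0`.
#' @param baseline_hazard `h0`; overrides the calibration when given.
#' @return Named list of class `cohort_design`.
#' @export
cohort_design <- function(n = 340,
                          beta = c(PTEN = -0.4, SMAD4 = -0.4, CCND1 = 0.35,
                                   SPP1 = 0.2, pS6 = 0.4, pPRAS40 = 0.4,
                                   p90RSK = 0.15, FOXO3 = 0.1),
                          meanlog = 1, sdlog = 0.5, rho = 0.2,
                          censor_max = 2 * 11.92, target_events = 35,
                          baseline_hazard = NULL) {
  stopifnot(n > 0, censor_max > 0, rho > -1, rho < 1)
  if (is.null(names(beta))) stop("beta must be a named vector")
  if (is.null(baseline_hazard))
    baseline_hazard <- calibrate_baseline_hazard(beta, rho, censor_max,
                                                 target_events / n)
  structure(list(n = n, beta = beta, meanlog = meanlog, sdlog = sdlog,
                 rho = rho, censor_max = censor_max,
                 target_events = target_events,
                 baseline_hazard = baseline_hazard),
            class = "cohort_design")
}

# With T | lp ~ Exp(h0 e^lp) and C ~ U(0, cmax), P(event | lp) =
# 1 - (1 - exp(-lambda cmax)) / (lambda cmax). lp ~ N(0, v) with
# v = beta' R beta; integrate over lp by Gauss-Legendre on a wide grid and
# root-find h0 for the requested marginal event probability.
calibrate_baseline_hazard <- function(beta, rho, censor_max, p_event) {
  p <- length(beta)
  R <- matrix(rho, p, p); diag(R) <- 1
  v <- drop(t(beta) %*% R %*% beta)
  sd_lp <- sqrt(max(v, 0))
  grid <- seq(-6, 6, length.out = 241)
  wts <- stats::dnorm(grid); wts <- wts / sum(wts)
  pe <- function(h0) {
    lam <- h0 * exp(sd_lp * grid)
    x <- lam * censor_max
    sum(wts * (1 - (1 - exp(-x)) / x)) - p_event
  }
  stats::uniroot(pe, c(1e-8, 10), tol = 1e-12)$root
}

#' Simulate a survival cohort from a design
#'
#' @param design a [cohort_design()].
#' @param seed integer seed; the table is bit-reproducible per seed.
#' @return Data frame of class `cohort_table` with columns `sample_id`,
#'   `time_years`, `event`, `gleason_group`, `age` and one column per
#'   marker; the latent standardized markers are attached as attribute
#'   `"z"`.
#' @export
simulate_cohort <- function(design = cohort_design(), seed = 1) {
  stopifnot(inherits(design, "cohort_design"))
  with_seed(seed, {
    p <- length(design$beta)
    R <- matrix(design$rho, p, p); diag(R) <- 1
    L <- chol(R)
    Z <- matrix(stats::rnorm(design$n * p), design$n, p) %*% L
    colnames(Z) <- names(design$beta)
    markers <- exp(design$meanlog + design$sdlog * Z)
    lp <- drop(Z %*% design$beta)
    Tt <- stats::rexp(design$n) / (design$baseline_hazard * exp(lp))
    C <- stats::runif(design$n, 0, design$censor_max)
    time <- pmax(pmin(Tt, C), 1e-6)
    event <- as.integer(Tt <= C)
    # Gleason group loosely tracks the latent risk, matching the skew of a
    # surgical cohort (about 36/37/26 percent across 2-6 / 7 / 8-10)
    gl_score <- lp + stats::rnorm(design$n, sd = stats::sd(lp) + 0.5)
    br <- stats::quantile(gl_score, c(0, 0.3647, 0.7382, 1))
    gleason <- cut(gl_score, breaks = br, labels = c("2-6", "7", "8-10"),
                   include.lowest = TRUE)
    out <- data.frame(sample_id = sprintf("S%04d", seq_len(design$n)),
                      time_years = time, event = event,
                      gleason_group = as.character(gleason),
                      age = round(stats::rnorm(design$n, 61.9, 6.7), 1))
    out <- cbind(out, as.data.frame(markers))
    attr(out, "z") <- Z
    attr(out, "design") <- design
    attr(out, "seed") <- seed
    class(out) <- c("cohort_table", "data.frame")
    out
  })
}

#' Simulate paired consecutive-section core measurements
#'
#' Two consecutive TMA sections measure the same underlying core biology with
#' small multiplicative technical noise; used to exercise
#' [replicate_agreement()].
#'
#' @param n number of cores.
#' @param cv multiplicative coefficient of variation per section
#'   (default 0.03).
#' @param meanlog,sdlog log-normal parameters of the shared core truth.
#' @param seed integer seed.
#' @return List with vectors `section_a`, `section_b` and the shared `truth`.
#' @export
simulate_section_pair <- function(n = 60, cv = 0.03, meanlog = 1,
                                  sdlog = 0.5, seed = 1) {
  with_seed(seed, {
    truth <- stats::rlnorm(n, meanlog, sdlog)
    list(section_a = truth * (1 + stats::rnorm(n, sd = cv)),
         section_b = truth * (1 + stats::rnorm(n, sd = cv)),
         truth = truth)
  })
}
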