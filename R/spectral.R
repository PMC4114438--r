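#' Build a spectral library of endmember emission profiles
#'
#' A spectral library holds one emission profile per endmember (fluorophores
#' plus the two autofluorescence classes seen in FFPE prostate tissue) sampled
#' on a common grid of wavelength bands. Profiles are rescaled to unit maximum
#' so that unmixed abundances carry the intensity units of the input image.
#'
#' @param profile_table data frame whose first column (named `band_nm` by
#'   convention) gives ascending band center wavelengths in nm and whose
#'   remaining columns give one non-negative emission profile per endmember.
#' @param roles named character vector mapping endmember names to roles; each
#'   role is one of `"fluorophore"`, `"AFL"` (diffuse tissue autofluorescence)
#'   or `"BAFL"` (bright granular autofluorescence). Endmembers not named
#'   default to `"fluorophore"`; columns literally named `AFL`/`BAFL` default
#'   to those roles.
#'
#' @return An object of class `spectral_library`: a list with `band_centers`
#'   (numeric), `profiles` (bands x endmembers matrix, unit-max columns) and
#'   `roles` (named character vector).
#' @export
#' @examples
#' lib <- spectral_library(data.frame(band_nm = c(450, 500, 550),
#'                                    DAPI = c(1, 0.4, 0.1),
#'                                    AFL  = c(0.2, 0.5, 0.4)))
#' lib$roles
spectral_library <- function(profile_table, roles = NULL) {
  stopifnot(is.data.frame(profile_table), ncol(profile_table) >= 2)
  band_centers <- as.numeric(profile_table[[1L]])
  if (nrow(profile_table) < 2L)
    stop("a spectral library needs at least 2 wavelength bands")
  if (is.unsorted(band_centers, strictly = TRUE))
    stop("band centers must be strictly ascending")
  nm <- names(profile_table)[-1L]
  if (anyDuplicated(nm)) stop("duplicate endmember names")
  M <- as.matrix(profile_table[, -1L, drop = FALSE])
  storage.mode(M) <- "double"
  colnames(M) <- nm
  if (any(!is.finite(M)) || any(M < 0))
    stop("emission profiles must be finite and non-negative")
  mx <- apply(M, 2L, max)
  if (any(mx <= 0)) stop("every profile must have a positive maximum")
  M <- sweep(M, 2L, mx, "/")

  r <- rep("fluorophore", length(nm))
  names(r) <- nm
  r[nm == "AFL"] <- "AFL"
  r[nm == "BAFL"] <- "BAFL"
  if (!is.null(roles)) {
    unknown <- setdiff(names(roles), nm)
    if (length(unknown)) stop("roles given for unknown endmembers: ",
                              paste(unknown, collapse = ", "))
    bad <- setdiff(roles, c("fluorophore", "AFL", "BAFL"))
    if (length(bad)) stop("invalid role(s): ", paste(bad, collapse = ", "))
    r[names(roles)] <- roles
  }
  if (!any(r == "fluorophore"))
    stop("library must contain at least one fluorophore endmember")
  structure(list(band_centers = band_centers, profiles = M, roles = r),
            class = "spectral_library")
}

#' @export
print.spectral_library <- function(x, ...) {
  cat(sprintf("spectral_library: %d endmembers over %d bands (%g-%g nm)\n",
              ncol(x$profiles), length(x$band_centers),
              min(x$band_centers), max(x$band_centers)))
  for (nm in colnames(x$profiles)) {
    pk <- x$band_centers[which.max(x$profiles[, nm])]
    cat(sprintf("  %-10s %-11s peak %g nm\n", nm, x$roles[[nm]], pk))
  }
  invisible(x)
}

#' Default synthetic spectral library
#'
#' Gaussian-shaped emission profiles on 20 bands spanning 420-720 nm for the
#' assay's five fluorophores (DAPI plus four Alexa dyes carrying the
#' epithelial, basal and biomarker channels) and the two autofluorescence
#' classes: diffuse AFL and bright granular BAFL. Peak positions follow the
#' dyes' nominal emission maxima; the AFL/BAFL profiles are broad, as
#' autofluorescence is spectrally unstructured.
#'
#' @param n_bands number of wavelength bands (default 20).
#' @param range numeric length-2, wavelength range in nm (default 420-720).
#' @return A [spectral_library()].
#' @export
default_spectral_library <- function(n_bands = 20, range = c(420, 720)) {
  bands <- seq(range[1L], range[2L], length.out = n_bands)
  g <- function(peak, width) exp(-0.5 * ((bands - peak) / width)^2)
  tab <- data.frame(band_nm  = bands,
                    DAPI     = g(461, 25),
                    Alexa488 = g(519, 18),
                    Alexa555 = g(567, 18),
                    Alexa568 = g(603, 20),
                    Alexa633 = g(650, 22),
                    AFL      = g(540, 85),
                    BAFL     = 0.6 * g(500, 40) + g(590, 55))
  spectral_library(tab)
}

#' Read / write a spectral library as CSV
#'
#' The CSV has a first column `band_nm` and one column per endmember. Roles
#' may be given in a YAML config with a top-level `roles:` map
#' (endmember name -> role).
#'
#' @param path CSV file path.
#' @param roles_yaml optional YAML file with a `roles:` mapping.
#' @return A [spectral_library()].
#' @export
read_spectral_library <- function(path, roles_yaml = NULL) {
  tab <- utils::read.csv(path, check.names = FALSE)
  roles <- NULL
  if (!is.null(roles_yaml)) {
    cfg <- yaml::read_yaml(roles_yaml)
    if (!is.null(cfg$roles)) roles <- unlist(cfg$roles)
  }
  spectral_library(tab, roles = roles)
}

#' @rdname read_spectral_library
#' @param library a `spectral_library`.
#' @export
write_spectral_library <- function(library, path) {
  stopifnot(inherits(library, "spectral_library"))
  tab <- data.frame(band_nm = library$band_centers, library$profiles,
                    check.names = FALSE)
  utils::write.csv(tab, path, row.names = FALSE)
  invisible(path)
}

#' Synthesize a single pixel spectrum from endmember abundances
#'
#' Linear forward model: the emitted spectrum is the abundance-weighted sum of
#' the library profiles plus optional Gaussian noise, clipped at zero (photon
#' counts cannot be negative). This is the generative counterpart of
#' [unmix_image()].
#'
#' @param abundances non-negative numeric vector, one weight per endmember
#'   (recycled names are matched to the library if named).
#' @param library a [spectral_library()].
#' @param noise_sd standard deviation of additive Gaussian noise (default 0).
#' @return Numeric vector of per-band intensities.
#' @export
synthesize_pixel <- function(abundances, library, noise_sd = 0) {
  stopifnot(inherits(library, "spectral_library"))
  M <- library$profiles
  if (!is.null(names(abundances))) {
    if (!all(names(abundances) %in% colnames(M)))
      stop("abundance names not in library")
    a <- stats::setNames(numeric(ncol(M)), colnames(M))
    a[names(abundances)] <- abundances
    abundances <- a
  }
  if (length(abundances) != ncol(M))
    stop("need one abundance per endmember (", ncol(M), ")")
  if (any(abundances < 0)) stop("abundances must be non-negative")
  s <- drop(M %*% abundances)
  if (noise_sd > 0) s <- s + stats::rnorm(length(s), sd = noise_sd)
  pmax(s, 0)
}

#' Construct a multispectral image object
#'
#' @param data numeric array of shape (bands, rows, cols), non-negative.
#' @param band_centers wavelength per plane, nm, ascending.
#' @param meta named list of field metadata (core id, field index, exposure
#'   tag, sample id ...).
#' @return Object of class `ms_image`.
#' @export
ms_image <- function(data, band_centers, meta = list()) {
  stopifnot(is.array(data), length(dim(data)) == 3L)
  if (dim(data)[1L] != length(band_centers))
    stop("first array dimension must match the number of band centers")
  if (any(!is.finite(data))) stop("image intensities must be finite")
  if (any(data < 0)) stop("image intensities must be non-negative")
  structure(list(data = data, band_centers = as.numeric(band_centers),
                 meta = meta), class = "ms_image")
}

#' @export
print.ms_image <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("ms_image: %d bands, %d x %d px", d[1L], d[2L], d[3L]))
  if (length(x$meta)) {
    cat(" [", paste(names(x$meta), unlist(lapply(x$meta, format)),
                    sep = "=", collapse = ", "), "]", sep = "")
  }
  cat("\n")
  invisible(x)
}

#' Unmix a multispectral image into endmember abundance maps
#'
#' Per pixel, solves the non-negative least-squares problem
#' `min || s - L a ||_2  s.t.  a >= 0`, where `s` is the pixel spectrum and
#' `L` the bands-by-endmembers library matrix. A vectorized unconstrained
#' least-squares pass handles every pixel whose solution is already
#' non-negative; only the remainder is sent through the active-set solver,
#' grouped by identical spectra so that flat synthetic regions are solved
#' once.
#'
#' @param image an [ms_image()].
#' @param library a [spectral_library()] on the same band grid.
#' @param tol solver tolerance; abundances within `-tol` of zero are snapped
#'   to zero (default 1e-8).
#' @return Object of class `abundance_maps`: list with `abundance` (named list
#'   of rows x cols matrices, one per endmember), `residual` (rows x cols
#'   matrix of per-pixel reconstruction error norms) and `library`.
#' @export
unmix_image <- function(image, library, tol = 1e-8) {
  stopifnot(inherits(image, "ms_image"), inherits(library, "spectral_library"))
  d <- dim(image$data)
  if (d[1L] != length(library$band_centers))
    stop("band count mismatch: image has ", d[1L], ", library has ",
         length(library$band_centers))
  if (any(!is.finite(image$data))) stop("non-finite pixel intensities")
  M <- library$profiles
  p <- ncol(M)
  npix <- d[2L] * d[3L]
  S <- matrix(image$data, nrow = d[1L], ncol = npix)

  # fast path: unconstrained LS, valid wherever it lands in the feasible cone
  MtM <- crossprod(M)
  A <- solve(MtM, crossprod(M, S))          # p x npix
  neg <- .colAnys(A < -tol)
  if (any(neg)) {
    Sb <- S[, neg, drop = FALSE]
    key <- apply(Sb, 2L, function(s) paste(s, collapse = ","))
    first <- !duplicated(key)
    sol <- matrix(0, p, sum(first))
    idx_first <- which(first)
    for (j in seq_along(idx_first)) {
      sol[, j] <- pracma::lsqnonneg(M, Sb[, idx_first[j]])$x
    }
    A[, neg] <- sol[, match(key, key[first])]
  }
  A[A < 0] <- 0
  R <- sqrt(pmax(.colSums((S - M %*% A)^2, d[1L], npix), 0))

  ab <- lapply(seq_len(p), function(k)
    matrix(A[k, ], d[2L], d[3L]))
  names(ab) <- colnames(M)
  structure(list(abundance = ab,
                 residual = matrix(R, d[2L], d[3L]),
                 library = library),
            class = "abundance_maps")
}

.colAnys <- function(m) .colSums(m, nrow(m), ncol(m)) > 0

#' @export
print.abundance_maps <- function(x, ...) {
  d <- dim(x$residual)
  cat(sprintf("abundance_maps: %d planes, %d x %d px; mean residual %.3g\n",
              length(x$abundance), d[1L], d[2L], mean(x$residual)))
  invisible(x)
}

#' Display one abundance plane
#'
#' @param x an `abundance_maps` object.
#' @param endmember which plane to show (name or index; default first).
#' @param ... passed to [graphics::image()].
#' @export
plot.abundance_maps <- function(x, endmember = 1L, ...) {
  pl <- x$abundance[[endmember]]
  nm <- if (is.character(endmember)) endmember else names(x$abundance)[endmember]
  graphics::image(t(pl)[, nrow(pl):1, drop = FALSE], main = nm,
                  useRaster = TRUE, axes = FALSE, ...)
  invisible(x)
}

#' Flag bright-autofluorescence (BAFL) pixels
#'
#' BAFL appears as bright granules, mostly in benign epithelium; it is treated
#' as an artifact class and the flagged pixels are excluded from all
#' downstream biomarker statistics rather than subtracted.
#'
#' @param maps an `abundance_maps` object whose library contains a BAFL-role
#'   endmember.
#' @param threshold absolute BAFL abundance above which a pixel is flagged.
#'   Exactly one of `threshold`/`quantile` must be given.
#' @param quantile alternatively, flag pixels above this quantile of the
#'   positive BAFL abundances.
#' @return Logical rows x cols mask, `TRUE` where excluded.
#' @export
flag_bright_autofluorescence <- function(maps, threshold = NULL,
                                         quantile = NULL) {
  stopifnot(inherits(maps, "abundance_maps"))
  bafl <- names(which(maps$library$roles == "BAFL"))
  if (!length(bafl)) stop("library has no BAFL endmember")
  plane <- maps$abundance[[bafl[1L]]]
  if (is.null(threshold) == is.null(quantile))
    stop("give exactly one of threshold or quantile")
  if (is.null(threshold)) {
    pos <- plane[plane > 0]
    if (!length(pos)) return(plane > Inf)
    threshold <- stats::quantile(pos, quantile, names = FALSE)
  }
  plane > threshold
}

#' Flag saturated pixels
#'
#' Pixels at or above the detector ceiling in any band carry clipped,
#' unusable intensities and are excluded from quantification.
#'
#' @param image an [ms_image()].
#' @param ceiling saturation intensity (e.g. 65535 for uint16 acquisition).
#' @return Logical rows x cols mask, `TRUE` where saturated.
#' @export
flag_saturated <- function(image, ceiling) {
  stopifnot(inherits(image, "ms_image"), is.numeric(ceiling), ceiling > 0)
  d <- dim(image$data)
  sat <- matrix(image$data, d[1L], d[2L] * d[3L]) >= ceiling
  matrix(.colAnys(sat), d[2L], d[3L])
}
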