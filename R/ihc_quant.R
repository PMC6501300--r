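#' Convert an 8-bit RGB image to optical density
#'
#' Beer-Lambert transform `OD = -log10((I + eps) / I0)` per channel, with
#' `eps = 1/255` guarding against zero intensities and negative OD clipped
#' to 0 (intensities above background).
#'
#' @param image H x W x 3 array of intensities in \[0, 255\].
#' @param background_intensity transmitted intensity of blank glass
#'   (default 255).
#' @return H x W x 3 array of non-negative optical densities.
#' @export
rgb_to_optical_density <- function(image, background_intensity = 255) {
  check_that(is.array(image) && length(dim(image)) == 3 && dim(image)[3] == 3,
             "'image' must be an H x W x 3 array")
  check_that(is.numeric(image) && all(image >= 0 & image <= 255),
             "'image' must hold 8-bit intensities in [0, 255]")
  check_that(background_intensity > 0, "'background_intensity' must be > 0")
  eps <- 1 / 255
  od <- -log10((image + eps) / background_intensity)
  od[od < 0] <- 0
  od
}

#' Unmix optical densities into per-stain concentration maps
#'
#' Expresses each pixel's OD vector in the stain basis by a linear solve
#' (color deconvolution). Negative concentrations, which arise from noise,
#' are clipped to 0.
#'
#' @param od H x W x 3 optical-density array.
#' @param stains 3x3 stain matrix, rows = unit stain OD vectors
#'   (see [default_stain_matrix()]).
#' @return a named list of H x W concentration matrices, one per stain row.
#' @export
unmix_stains <- function(od, stains = default_stain_matrix()) {
  check_that(is.array(od) && length(dim(od)) == 3 && dim(od)[3] == 3,
             "'od' must be an H x W x 3 array")
  check_that(all(dim(stains) == c(3, 3)), "'stains' must be 3x3")
  cond <- kappa(stains, exact = TRUE)
  if (!is.finite(cond) || cond > 1e8) {
    stop(sprintf("stain matrix is numerically singular (condition number %.3g)",
                 cond), call. = FALSE)
  }
  h <- dim(od)[1]; w <- dim(od)[2]
  flat <- matrix(od, nrow = h * w, ncol = 3)
  # od_pixel' = conc' %*% stains  =>  conc' = od' %*% stains^-1
  conc <- flat %*% solve(stains)
  conc[conc < 0] <- 0
  out <- lapply(seq_len(3), function(j) matrix(conc[, j], h, w))
  names(out) <- rownames(stains)
  out
}

# 8-connected component labeling by iterative minimum-label propagation.
# Foreground pixels start with unique labels (their linear index) which
# contract to the component minimum; relabeled 1..k on exit.
label_components_8 <- function(bw) {
  h <- nrow(bw); w <- ncol(bw)
  lab <- matrix(seq_len(h * w), h, w)
  lab[!bw] <- 0L
  if (!any(bw)) return(lab)
  shifts <- list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1),
                 c(1, 1), c(1, -1), c(-1, 1), c(-1, -1))
  repeat {
    old <- lab
    for (s in shifts) {
      nb <- matrix(0L, h, w)
      rs <- max(1, 1 + s[1]):min(h, h + s[1])
      cs <- max(1, 1 + s[2]):min(w, w + s[2])
      nb[rs, cs] <- lab[rs - s[1], cs - s[2]]
      upd <- bw & nb > 0 & nb < lab
      lab[upd] <- nb[upd]
    }
    if (identical(lab, old)) break
  }
  ids <- sort(unique(lab[lab > 0]))
  matrix(match(lab, ids, nomatch = 1L) * (lab > 0), h, w)
}

#' Detect marker-positive cells in a concentration map
#'
#' Binarizes the stain-concentration map at `threshold`, labels 8-connected
#' components, and keeps components with pixel area in
#' `[area_min_px, area_max_px]`. Touching cells are not split; the
#' synthetic generator guarantees separation by construction.
#'
#' @param concentration_map H x W stain-concentration matrix.
#' @param threshold binarization threshold in OD units (> 0).
#' @param area_min_px,area_max_px inclusive component-area band in pixels.
#' @return a list of class `cell_detections`: `centroids` (n x 2 matrix of
#'   (row, col)), `count`, `per_object_area_px`.
#' @export
detect_positive_cells <- function(concentration_map, threshold = 0.3,
                                  area_min_px = 20, area_max_px = 2000) {
  check_that(is.matrix(concentration_map), "'concentration_map' must be a matrix")
  check_that(threshold > 0, "'threshold' must be > 0")
  check_that(area_min_px > 0 && area_min_px < area_max_px,
             "need 0 < area_min_px < area_max_px")
  bw <- concentration_map >= threshold
  lab <- label_components_8(bw)
  k <- max(lab)
  if (k == 0) {
    return(structure(list(
      centroids = matrix(numeric(0), ncol = 2,
                         dimnames = list(NULL, c("row", "col"))),
      count = 0L, per_object_area_px = integer(0)), class = "cell_detections"))
  }
  idx <- which(lab > 0, arr.ind = TRUE)
  comp <- lab[lab > 0]
  areas <- tabulate(comp, nbins = k)
  keep <- which(areas >= area_min_px & areas <= area_max_px)
  if (length(keep) == 0) {
    return(structure(list(
      centroids = matrix(numeric(0), ncol = 2,
                         dimnames = list(NULL, c("row", "col"))),
      count = 0L, per_object_area_px = integer(0)), class = "cell_detections"))
  }
  cen_r <- tapply(idx[, 1], comp, mean)[as.character(keep)]
  cen_c <- tapply(idx[, 2], comp, mean)[as.character(keep)]
  centroids <- cbind(row = as.numeric(cen_r), col = as.numeric(cen_c))
  structure(list(centroids = centroids, count = nrow(centroids),
                 per_object_area_px = areas[keep]),
            class = "cell_detections")
}

#' Cell density within an annotated region
#'
#' Counts detections whose centroid (nearest pixel) falls inside the mask
#' and normalizes by the mask area in mm2:
#' `area_mm2 = n_true_pixels * (microns_per_pixel/1000)^2`.
#'
#' @param detections a `cell_detections` object.
#' @param mask H x W logical tumor-region mask.
#' @param microns_per_pixel pixel pitch in micrometres.
#' @return a list: `count` (in-mask), `area_mm2`, `density` (cells/mm2).
#' @export
compute_density <- function(detections, mask, microns_per_pixel) {
  check_that(inherits(detections, "cell_detections"),
             "'detections' must come from detect_positive_cells()")
  check_that(is.matrix(mask) || is.logical(mask), "'mask' must be a matrix")
  mask <- mask > 0
  check_that(any(mask), "mask is empty: region area is zero")
  check_that(microns_per_pixel > 0, "'microns_per_pixel' must be > 0")
  area_mm2 <- sum(mask) * (microns_per_pixel / 1000)^2
  n_in <- 0L
  if (detections$count > 0) {
    r <- pmin(pmax(round(detections$centroids[, 1]), 1), nrow(mask))
    c_ <- pmin(pmax(round(detections$centroids[, 2]), 1), ncol(mask))
    n_in <- sum(mask[cbind(r, c_)])
  }
  list(count = as.integer(n_in), area_mm2 = area_mm2,
       density = n_in / area_mm2)
}

#' Quantify marker-positive cell density from an RGB IHC image
#'
#' End-to-end: OD transform, stain unmixing, detection on the DAB channel,
#' density within the mask.
#'
#' @param image H x W x 3 8-bit RGB array.
#' @param mask H x W logical tumor-region mask.
#' @param microns_per_pixel pixel pitch in micrometres.
#' @param stains 3x3 stain matrix (rows = stains); the stain named by
#'   `stain` is the detection channel.
#' @param stain which unmixed channel carries the marker (default "dab").
#' @param threshold,area_min_px,area_max_px passed to
#'   [detect_positive_cells()].
#' @return a list: `density`, `count`, `area_mm2`, `detections`.
#' @export
quantify_density <- function(image, mask, microns_per_pixel,
                             stains = default_stain_matrix(),
                             stain = "dab",
                             threshold = 0.3,
                             area_min_px = 20, area_max_px = 2000) {
  od <- rgb_to_optical_density(image)
  conc <- unmix_stains(od, stains)
  check_that(stain %in% names(conc),
             sprintf("'%s' is not a row of the stain matrix", stain))
  det <- detect_positive_cells(conc[[stain]], threshold,
                               area_min_px, area_max_px)
  dens <- compute_density(det, mask, microns_per_pixel)
  c(dens, list(detections = det))
}
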