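#' Configuration for a synthetic chromogenic IHC image
#'
#' Describes an image of marker-positive cells rendered as brown (DAB-like)
#' disks on a bluish (hematoxylin-like) counterstained background. The
#' image is composited in optical-density space and converted to 8-bit RGB
#' with additive Gaussian noise, so the Beer-Lambert unmixing used for
#' quantification applies exactly up to noise and quantization.
#'
#' @param width_px,height_px image size in pixels.
#' @param microns_per_pixel pixel pitch in micrometres.
#' @param n_cells number of positive cells to render.
#' @param cell_radius_px disk radius in pixels.
#' @param stain_name marker label, "CD8" or "PD-L1" (metadata only; both
#'   use the DAB chromogen).
#' @param dab_intensity peak DAB optical-density amplitude of a cell.
#' @param hematoxylin_intensity background hematoxylin optical density.
#' @param noise_sd sd of additive Gaussian noise in OD units.
#' @param mask_shape tumor-region mask: "rect" (full frame minus a margin)
#'   or "disk" (centred disk).
#' @param seed integer seed.
#'
#' @return an object of class `image_config`.
#' @export
image_config <- function(width_px = 512, height_px = 512,
                         microns_per_pixel = 0.5,
                         n_cells = 50, cell_radius_px = 6,
                         stain_name = c("CD8", "PD-L1"),
                         dab_intensity = 0.9,
                         hematoxylin_intensity = 0.5,
                         noise_sd = 0.02,
                         mask_shape = c("rect", "disk"),
                         seed = 1L) {
  stain_name <- match.arg(stain_name)
  mask_shape <- match.arg(mask_shape)
  check_scalar_num(width_px, "width_px", lower = 16)
  check_scalar_num(height_px, "height_px", lower = 16)
  check_that(microns_per_pixel > 0, "'microns_per_pixel' must be > 0")
  check_scalar_num(n_cells, "n_cells", lower = 0)
  check_that(cell_radius_px > 0, "'cell_radius_px' must be > 0")
  check_that(cell_radius_px < min(width_px, height_px) / 4,
             "'cell_radius_px' must be < min(width, height)/4")
  check_that(dab_intensity > 0, "'dab_intensity' must be > 0")
  check_that(hematoxylin_intensity > 0, "'hematoxylin_intensity' must be > 0")
  check_scalar_num(noise_sd, "noise_sd", lower = 0)
  check_scalar_num(seed, "seed")

  structure(list(
    width_px = as.integer(width_px), height_px = as.integer(height_px),
    microns_per_pixel = microns_per_pixel,
    n_cells = as.integer(n_cells), cell_radius_px = cell_radius_px,
    stain_name = stain_name,
    dab_intensity = dab_intensity,
    hematoxylin_intensity = hematoxylin_intensity,
    noise_sd = noise_sd, mask_shape = mask_shape,
    seed = as.integer(seed)
  ), class = "image_config")
}

#' Standard hematoxylin / DAB stain vectors
#'
#' Unit-norm optical-density direction vectors (R, G, B order) for
#' hematoxylin and DAB, with the residual direction completing an
#' invertible basis. These are the widely used color-deconvolution
#' defaults; real assays may require calibration from single-stain
#' controls, which can be supplied via a 3x3 CSV (rows = stains).
#'
#' @return a 3x3 numeric matrix with rows `hematoxylin`, `dab`,
#'   `residual`, each a unit vector.
#' @export
default_stain_matrix <- function() {
  h <- c(0.650, 0.704, 0.286)
  d <- c(0.268, 0.570, 0.776)
  h <- h / sqrt(sum(h^2))
  d <- d / sqrt(sum(d^2))
  r <- c(h[2] * d[3] - h[3] * d[2],
         h[3] * d[1] - h[1] * d[3],
         h[1] * d[2] - h[2] * d[1])
  r <- abs(r) / sqrt(sum(r^2))
  m <- rbind(hematoxylin = h, dab = d, residual = r)
  colnames(m) <- c("R", "G", "B")
  m
}

#' Read a stain matrix from a 3x3 CSV
#'
#' Rows are stains (stain1, stain2, residual), columns R, G, B. Rows are
#' renormalized to unit length; the matrix must be invertible.
#'
#' @param path CSV path (no header expected unless present as `R,G,B`).
#' @return a 3x3 unit-row stain matrix.
#' @export
read_stain_matrix <- function(path) {
  m <- as.matrix(utils::read.csv(path, header = FALSE))
  if (!is.numeric(m[1, 1])) m <- as.matrix(utils::read.csv(path))
  storage.mode(m) <- "double"
  check_that(all(dim(m) == c(3, 3)), "stain matrix CSV must be 3x3")
  m <- m / sqrt(rowSums(m^2))
  check_that(all(m >= 0), "stain vectors must be non-negative")
  check_that(is.finite(kappa(m)) && abs(det(m)) > 1e-8,
             "stain matrix is singular")
  m
}

# Place n non-overlapping centers inside the mask, keeping a full radius
# from the mask edge. Bounded rejection sampling.
place_cells <- function(mask, n, radius, max_tries = 20000L) {
  if (n == 0L) return(matrix(numeric(0), ncol = 2,
                             dimnames = list(NULL, c("row", "col"))))
  h <- nrow(mask); w <- ncol(mask)
  eroded <- which(mask, arr.ind = TRUE)
  r <- ceiling(radius) + 1L
  keep <- eroded[, 1] > r & eroded[, 1] <= h - r &
          eroded[, 2] > r & eroded[, 2] <= w - r
  cand <- eroded[keep, , drop = FALSE]
  check_that(nrow(cand) > 0, "mask too small for the requested cell radius")
  centers <- matrix(NA_real_, n, 2)
  placed <- 0L
  min_d2 <- (2 * radius + 2)^2
  for (i in seq_len(max_tries)) {
    pt <- cand[sample.int(nrow(cand), 1L), ]
    if (placed > 0L) {
      d2 <- (centers[seq_len(placed), 1] - pt[1])^2 +
            (centers[seq_len(placed), 2] - pt[2])^2
      if (min(d2) < min_d2) next
    }
    placed <- placed + 1L
    centers[placed, ] <- pt
    if (placed == n) break
  }
  check_that(placed == n,
             sprintf("could not place %d non-overlapping cells after %d tries",
                     n, max_tries))
  colnames(centers) <- c("row", "col")
  centers
}

make_mask <- function(config) {
  h <- config$height_px; w <- config$width_px
  if (config$mask_shape == "rect") {
    mask <- matrix(FALSE, h, w)
    mh <- max(2L, round(0.05 * h)); mw <- max(2L, round(0.05 * w))
    mask[(mh + 1):(h - mh), (mw + 1):(w - mw)] <- TRUE
  } else {
    cc <- c((h + 1) / 2, (w + 1) / 2)
    rad <- 0.45 * min(h, w)
    rows <- matrix(seq_len(h), h, w)
    cols <- matrix(seq_len(w), h, w, byrow = TRUE)
    mask <- (rows - cc[1])^2 + (cols - cc[2])^2 <= rad^2
  }
  mask
}

#' Render a synthetic IHC image with ground truth
#'
#' Renders `n_cells` non-overlapping DAB-stained disks over a uniform
#' hematoxylin background inside the tumor-region mask. The optical-density
#' image is `OD = c_hema * v_hema + c_dab * v_dab + noise`, converted to
#' 8-bit RGB by `I = 255 * 10^-OD`.
#'
#' @param config an [image_config()] object.
#' @return a list with elements
#'   `image` (H x W x 3 array of 8-bit intensities),
#'   `mask` (H x W logical tumor-region mask),
#'   `truth` (list: `centroids` matrix of (row, col), `count`,
#'   `mask_area_mm2`, `true_density` in cells/mm2),
#'   `microns_per_pixel`.
#' @export
generate_ihc_image <- function(config) {
  check_that(inherits(config, "image_config"),
             "'config' must be created by image_config()")
  h <- config$height_px; w <- config$width_px
  stains <- default_stain_matrix()
  mask <- make_mask(config)

  withr::with_seed(config$seed, {
    centers <- place_cells(mask, config$n_cells, config$cell_radius_px)

    dab_conc <- matrix(0, h, w)
    if (nrow(centers) > 0) {
      r <- config$cell_radius_px
      off <- ceiling(r)
      drow <- seq(-off, off)
      local_d2 <- outer(drow^2, drow^2, "+")
      disk <- local_d2 <= r^2
      for (k in seq_len(nrow(centers))) {
        rows <- centers[k, 1] + drow
        cols <- centers[k, 2] + drow
        patch <- dab_conc[rows, cols]
        patch[disk] <- config$dab_intensity
        dab_conc[rows, cols] <- patch
      }
    }
    hema_conc <- matrix(config$hematoxylin_intensity, h, w)

    od <- array(0, dim = c(h, w, 3))
    for (ch in 1:3) {
      od[, , ch] <- hema_conc * stains["hematoxylin", ch] +
                    dab_conc * stains["dab", ch]
      if (config$noise_sd > 0) {
        od[, , ch] <- od[, , ch] + stats::rnorm(h * w, 0, config$noise_sd)
      }
    }
    od[od < 0] <- 0
    img <- round(255 * 10^(-od))
    img[img < 0] <- 0; img[img > 255] <- 255

    area_mm2 <- sum(mask) * (config$microns_per_pixel / 1000)^2
    truth <- list(
      centroids = centers,
      count = nrow(centers),
      mask_area_mm2 = area_mm2,
      true_density = nrow(centers) / area_mm2
    )
    list(image = img, mask = mask, truth = truth,
         microns_per_pixel = config$microns_per_pixel)
  })
}

#' Write a synthetic image set to disk
#'
#' Image as 8-bit RGB PNG, mask as single-channel PNG (0/255), truth as a
#' JSON sidecar.
#'
#' @param sim result of [generate_ihc_image()].
#' @param image_path,mask_path,truth_path output file paths.
#' @return invisibly, the image path.
#' @export
write_ihc_image <- function(sim, image_path, mask_path, truth_path) {
  png::writePNG(sim$image / 255, image_path)
  png::writePNG(matrix(as.numeric(sim$mask), nrow(sim$mask)), mask_path)
  tr <- sim$truth
  jsonlite::write_json(
    list(centroids = unname(tr$centroids), count = tr$count,
         mask_area_mm2 = tr$mask_area_mm2, true_density = tr$true_density,
         microns_per_pixel = sim$microns_per_pixel),
    truth_path, auto_unbox = TRUE, digits = NA)
  invisible(image_path)
}

#' Read an RGB image / binary mask from PNG
#'
#' @param path PNG path.
#' @return `read_rgb_png` returns an H x W x 3 array of 8-bit intensities;
#'   `read_mask_png` a logical matrix.
#' @export
read_rgb_png <- function(path) {
  a <- png::readPNG(path)
  check_that(length(dim(a)) == 3 && dim(a)[3] >= 3,
             "expected an RGB PNG")
  round(a[, , 1:3] * 255)
}

#' @rdname read_rgb_png
#' @export
read_mask_png <- function(path) {
  a <- png::readPNG(path)
  if (length(dim(a)) == 3) a <- a[, , 1]
  a > 0.5
}
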