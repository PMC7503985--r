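# Data model and I/O for HRME-style images, FOV geometry and region masks.
#
# Conventions: images are numeric matrices indexed [row, col] (origin top-left),
# intensities in [0, 1]. Circle membership uses pixel-centre distance <= radius.

#' Construct an HRME image object
#'
#' @param pixels Numeric matrix of intensities in `[0, 1]`.
#' @param fov_mask Logical matrix of the same dimensions, `TRUE` inside the
#'   circular active area of the probe. If `NULL`, detected with [detect_fov()].
#' @param pixel_pitch Physical pixel pitch in micrometres per pixel.
#' @param image_id,biopsy_id Optional identifiers.
#' @param histopath Histopathology label of the imaged site.
#' @return An object of class `"hrme_image"`.
#' @export
hrme_image <- function(pixels, fov_mask = NULL, pixel_pitch = hrme_pixel_pitch(),
                       image_id = NA_character_, biopsy_id = NA_character_,
                       histopath = c("unknown", "neoplastic", "benign")) {
  histopath <- match.arg(histopath)
  if (!is.matrix(pixels) || !is.numeric(pixels))
    stop("`pixels` must be a numeric matrix")
  rng <- range(pixels)
  if (rng[1] < 0 || rng[2] > 1)
    stop("intensities must lie in [0, 1]")
  if (pixel_pitch <= 0) stop("`pixel_pitch` must be positive")
  if (is.null(fov_mask)) {
    fov_mask <- detect_fov(pixels)
  } else {
    if (!identical(dim(fov_mask), dim(pixels)))
      stop("`pixels` and `fov_mask` must have identical dimensions")
    fov_mask <- matrix(as.logical(fov_mask), nrow(pixels))
  }
  structure(
    list(pixels = pixels, fov_mask = fov_mask, pixel_pitch = pixel_pitch,
         image_id = image_id, biopsy_id = biopsy_id, histopath = histopath),
    class = "hrme_image")
}

#' @export
print.hrme_image <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<hrme_image> %dx%d px, pitch %.4f um/px, FOV %d px (%.3f mm^2)\n",
              d[1], d[2], x$pixel_pitch, sum(x$fov_mask),
              mask_area_mm2(x$fov_mask, x$pixel_pitch)))
  if (!is.na(x$image_id)) cat("  image_id:", x$image_id, "\n")
  if (!is.na(x$biopsy_id)) cat("  biopsy_id:", x$biopsy_id, "\n")
  cat("  histopathology:", x$histopath, "\n")
  invisible(x)
}

# --- region masks -----------------------------------------------------------

#' Region-mask label codes
#'
#' Region masks are integer matrices over three pixel classes:
#' 0 = background (outside the FOV), 1 = visible nuclei, 2 = no visible nuclei.
#' @export
REGION_CODES <- c(background = 0L, visible_nuclei = 1L, no_visible_nuclei = 2L)

#' Construct a region mask
#'
#' @param labels Integer matrix with values in `{0, 1, 2}` (see [REGION_CODES]).
#' @return An integer matrix of class `"region_mask"`.
#' @export
region_mask <- function(labels) {
  if (!is.matrix(labels)) stop("`labels` must be a matrix")
  storage.mode(labels) <- "integer"
  if (!all(labels %in% REGION_CODES))
    stop("region mask values must be 0 (background), 1 (visible) or 2 (no visible)")
  structure(labels, class = "region_mask")
}

#' @export
print.region_mask <- function(x, ...) {
  tab <- tabulate(as.integer(x) + 1L, nbins = 3L)
  cat(sprintf("<region_mask> %dx%d px: %d background, %d visible, %d no-visible\n",
              nrow(x), ncol(x), tab[1], tab[2], tab[3]))
  invisible(x)
}

# strip class for matrix arithmetic
rm_labels <- function(m) {
  m <- unclass(m)
  storage.mode(m) <- "integer"
  m
}

#' Area of a pixel mask in square millimetres
#'
#' Counts selected pixels and converts with the physical pixel pitch:
#' `count * (pixel_pitch / 1000)^2`.
#'
#' @param mask Logical matrix, or a [region_mask()] together with `label`.
#' @param pixel_pitch Micrometres per pixel.
#' @param label For region masks, which label to measure
#'   (`"visible_nuclei"`, `"no_visible_nuclei"` or `"background"`).
#' @return Area in mm^2.
#' @export
mask_area_mm2 <- function(mask, pixel_pitch = hrme_pixel_pitch(),
                          label = "visible_nuclei") {
  if (pixel_pitch <= 0) stop("`pixel_pitch` must be positive")
  if (inherits(mask, "region_mask"))
    mask <- rm_labels(mask) == REGION_CODES[[label]]
  sum(mask) * (pixel_pitch / 1000)^2
}

# --- FOV detection ----------------------------------------------------------

# Minimal enclosing circle (Welzl) of a small 2-column point matrix.
# Used on convex-hull vertices only, so n stays small.
min_enclosing_circle <- function(pts) {
  circ2 <- function(p, q) {
    c0 <- (p + q) / 2
    c(c0, sqrt(sum((p - c0)^2)))
  }
  circ3 <- function(p, q, r) {
    ax <- p[1]; ay <- p[2]; bx <- q[1]; by <- q[2]; cx <- r[1]; cy <- r[2]
    d <- 2 * (ax * (by - cy) + bx * (cy - ay) + cx * (ay - by))
    if (abs(d) < 1e-12) return(NULL)
    ux <- ((ax^2 + ay^2) * (by - cy) + (bx^2 + by^2) * (cy - ay) +
             (cx^2 + cy^2) * (ay - by)) / d
    uy <- ((ax^2 + ay^2) * (cx - bx) + (bx^2 + by^2) * (ax - cx) +
             (cx^2 + cy^2) * (bx - ax)) / d
    ctr <- c(ux, uy)
    c(ctr, sqrt(sum((p - ctr)^2)))
  }
  inside <- function(circ, p) sqrt(sum((p - circ[1:2])^2)) <= circ[3] + 1e-9

  n <- nrow(pts)
  if (n == 1) return(c(pts[1, ], 0))
  ord <- sample.int(n)  # randomized order gives expected linear time
  circ <- circ2(pts[ord[1], ], pts[ord[2], ])
  for (i in seq_len(n)[-(1:2)]) {
    pi_ <- pts[ord[i], ]
    if (inside(circ, pi_)) next
    # pi_ on boundary
    circ <- circ2(pts[ord[1], ], pi_)
    for (j in 2:(i - 1)) {
      pj <- pts[ord[j], ]
      if (inside(circ, pj)) next
      circ <- circ2(pi_, pj)
      for (k in 1:(j - 1)) {
        pk <- pts[ord[k], ]
        if (inside(circ, pk)) next
        cc <- circ3(pi_, pj, pk)
        if (!is.null(cc)) circ <- cc
      }
    }
  }
  circ
}

#' Detect the circular field of view of an HRME image
#'
#' Thresholds at 1\% of the maximum intensity, closes small gaps
#' morphologically, takes the largest connected component and fits its minimal
#' enclosing circle. The component must fill more than half of the circle's
#' bounding square (a disc fills ~79\%), otherwise detection fails.
#'
#' @param pixels Numeric intensity matrix (or an `hrme_image`).
#' @param threshold_frac Threshold as a fraction of the maximum intensity.
#' @param min_fill Minimum component area as a fraction of the bounding square.
#' @return Logical matrix, `TRUE` inside the detected disc.
#' @export
detect_fov <- function(pixels, threshold_frac = 0.01, min_fill = 0.5) {
  if (inherits(pixels, "hrme_image")) pixels <- pixels$pixels
  mx <- max(pixels)
  if (mx <= 0) stop("FOV detection failed: image has no non-zero support")
  bw <- (pixels > threshold_frac * mx) * 1
  closed <- EBImage::closing(bw, EBImage::makeBrush(9, shape = "disc"))
  lab <- EBImage::bwlabel(closed)
  lab <- EBImage::imageData(lab)
  if (max(lab) < 1) stop("FOV detection failed: no connected component found")
  counts <- tabulate(lab[lab > 0])
  biggest <- which.max(counts)
  # fit on the thresholded support only: morphological closing can add a thin
  # rim at the disc border which would inflate the enclosing circle
  idx <- which(lab == biggest & bw > 0, arr.ind = TRUE)
  hull <- idx[chull(idx), , drop = FALSE]
  circ <- with_seed(17L, min_enclosing_circle(hull))
  r <- circ[3]
  if (r <= 0 || counts[biggest] <= min_fill * (2 * r)^2)
    stop("FOV detection failed: largest component is not disc-like")
  disc_mask(dim(pixels), center = circ[1:2], radius = r)
}

#' Boolean disc mask
#'
#' @param dims Matrix dimensions `c(nrow, ncol)`.
#' @param center Disc centre `c(row, col)` in pixel coordinates.
#' @param radius Disc radius in pixels; membership is centre distance <= radius.
#' @return Logical matrix.
#' @export
disc_mask <- function(dims, center, radius) {
  dr <- (seq_len(dims[1]) - center[1])^2
  dc <- (seq_len(dims[2]) - center[2])^2
  outer(dr, dc, "+") <= radius^2
}

# --- file I/O ---------------------------------------------------------------

sidecar_mask_path <- function(path) {
  sub("\\.(png|tif|tiff)$", ".mask.png", path, ignore.case = TRUE)
}

#' Read an HRME image from PNG or TIFF
#'
#' 8- or 16-bit grayscale images are rescaled to `[0, 1]` by the bit-depth
#' maximum. If a sidecar region mask `<image>.mask.png` exists it supplies the
#' FOV (non-background pixels); otherwise the FOV is detected from the image.
#'
#' @param path Path to a grayscale PNG or TIFF file.
#' @param pixel_pitch Micrometres per pixel.
#' @param ... Passed to [hrme_image()] (ids, histopathology label).
#' @return An `"hrme_image"`; if a sidecar mask was found it is attached as
#'   attribute `"region_mask"`.
#' @export
read_hrme <- function(path, pixel_pitch = hrme_pixel_pitch(), ...) {
  if (!file.exists(path)) stop("cannot read image: ", path)
  is_tiff <- grepl("\\.tiff?$", path, ignore.case = TRUE)
  px <- if (is_tiff) tiff::readTIFF(path) else png::readPNG(path)
  if (length(dim(px)) == 3) {
    if (dim(px)[3] > 1) stop("unsupported format: multi-channel (RGB) image")
    px <- px[, , 1]
  }
  if (max(px) <= 0) stop("degenerate input: all-zero image")
  mask_path <- sidecar_mask_path(path)
  rmask <- NULL
  fov <- NULL
  if (mask_path != path && file.exists(mask_path)) {
    rmask <- read_region_mask(mask_path)
    if (!identical(dim(rmask), dim(px)))
      stop("sidecar mask dimensions do not match image")
    fov <- rm_labels(rmask) != REGION_CODES[["background"]]
  }
  img <- hrme_image(px, fov_mask = fov, pixel_pitch = pixel_pitch, ...)
  if (!is.null(rmask)) attr(img, "region_mask") <- rmask
  img
}

#' Write an HRME image to PNG (8-bit) or TIFF (8/16-bit)
#'
#' @param image An `"hrme_image"` or a plain intensity matrix in `[0, 1]`.
#' @param path Output path; format chosen by extension.
#' @param bits Bits per sample (8 or 16). 16-bit output requires TIFF; PNG
#'   output is always 8-bit.
#' @export
write_hrme <- function(image, path, bits = 8) {
  px <- if (inherits(image, "hrme_image")) image$pixels else image
  if (grepl("\\.tiff?$", path, ignore.case = TRUE)) {
    tiff::writeTIFF(px, path, bits.per.sample = bits)
  } else {
    if (bits != 8) stop("PNG output is 8-bit; use TIFF for 16-bit")
    png::writePNG(px, path)
  }
  invisible(path)
}

#' Read / write region masks
#'
#' Region masks are stored as single-channel 8-bit PNG with pixel codes
#' 0 = background, 1 = visible nuclei, 2 = no visible nuclei.
#'
#' @param path PNG path.
#' @return [read_region_mask()] returns a `"region_mask"`.
#' @export
read_region_mask <- function(path) {
  px <- png::readPNG(path)
  if (length(dim(px)) == 3) px <- px[, , 1]
  region_mask(matrix(as.integer(round(px * 255)), nrow(px)))
}

#' @rdname read_region_mask
#' @param mask A `"region_mask"`.
#' @export
write_region_mask <- function(mask, path) {
  png::writePNG(rm_labels(mask) / 255, path)
  invisible(path)
}

# FOV radius in pixels implied by a boolean disc mask
fov_radius_px <- function(fov_mask) sqrt(sum(fov_mask) / pi)
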