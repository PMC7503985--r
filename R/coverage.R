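# Coverage-probability validation of the density CI formula: random circular
# ROIs inside full-FOV images of known abnormal density, a CI per ROI at each
# confidence level, and the fraction of intervals containing the truth.

#' Grid of ROI radii
#'
#' Linearly spaced radii from `r_min` up to and including the FOV radius.
#'
#' @param r_fov FOV radius in pixels.
#' @param r_min Smallest ROI radius (default 41 px).
#' @param count Number of radii (default 25).
#' @return Numeric vector of strictly increasing radii.
#' @export
radius_grid <- function(r_fov, r_min = 41, count = 25) {
  if (r_min >= r_fov) stop("`r_min` must be smaller than `r_fov`")
  if (count < 2) stop("`count` must be at least 2")
  seq(r_min, r_fov, length.out = count)
}

#' Sample ROI centres uniformly within the admissible disc
#'
#' An ROI of radius `r_roi` is fully contained in the FOV iff its centre lies
#' within the concentric disc of radius `r_fov - r_roi`. Centres are drawn
#' uniformly by area over that disc (`radius = r_max * sqrt(u)`,
#' `angle = 2*pi*u'`); when `r_roi = r_fov` the centre is the FOV centre.
#'
#' @param r_fov,r_roi FOV and ROI radii in pixels, `r_roi <= r_fov`.
#' @param n Number of centres to draw.
#' @param center FOV centre `c(row, col)`.
#' @return `n x 2` matrix of centres (columns `row`, `col`).
#' @export
sample_roi <- function(r_fov, r_roi, n = 1, center = c(r_fov + 0.5, r_fov + 0.5)) {
  if (r_roi > r_fov) stop("`r_roi` must not exceed `r_fov`")
  r_max <- r_fov - r_roi
  rad <- r_max * sqrt(runif(n))
  ang <- runif(n, 0, 2 * pi)
  cbind(row = center[1] + rad * sin(ang), col = center[2] + rad * cos(ang))
}

#' Build a homogeneous phantom panel for coverage validation
#'
#' Emulates the validation panel of full-FOV images with nuclei visible
#' everywhere and a diverse range of nuclear morphologies: half the images are
#' benign-like (lower nuclear density, small abnormal fraction) and half
#' neoplastic-like (crowded, larger abnormal fraction). Only the ground-truth
#' point process is generated (no rendering), since the experiment operates on
#' nucleus positions and labels.
#'
#' @param n_images Total number of images (split evenly between the two
#'   morphology groups).
#' @param fov_radius_px FOV radius in pixels.
#' @param pixel_pitch Micrometres per pixel.
#' @param seed Integer seed.
#' @return List of `"coverage_image"` entries: `nuclei` (data frame with
#'   `row`, `col`, `abnormal`), `fov_center`, `fov_radius_px`, `pixel_pitch`,
#'   `fov_area_mm2`, `true_density` (abnormal nuclei per mm^2 over the FOV).
#' @export
phantom_panel <- function(n_images = 48, fov_radius_px = 480,
                          pixel_pitch = hrme_pixel_pitch(), seed = 1L) {
  n_lo <- floor(n_images / 2)
  specs <- with_seed(seed, {
    lapply(seq_len(n_images), function(i) {
      lo <- i <= n_lo
      # oral-epithelium HRME shows dense nucleation; benign-like images carry
      # abnormal densities well below the 189/mm^2 boundary, neoplastic-like
      # well above, each group spanning a range of morphologies
      dens <- if (lo) runif(1, 900, 1500) else runif(1, 1400, 2200)
      abn <- if (lo) runif(1, 60, 120) / dens else runif(1, 230, 350) / dens
      phantom_spec(fov_radius_px = fov_radius_px, pixel_pitch = pixel_pitch,
                   nuclear_density = dens, abnormal_fraction = abn,
                   seed = seed * 1000L + i)
    })
  })
  lapply(specs, function(sp) {
    nuc <- sample_nuclei(sp)
    structure(list(
      nuclei = nuc[, c("row", "col", "abnormal")],
      fov_center = attr(nuc, "fov_center"),
      fov_radius_px = attr(nuc, "fov_radius_px"),
      pixel_pitch = attr(nuc, "pixel_pitch"),
      fov_area_mm2 = attr(nuc, "fov_area_mm2"),
      true_density = sum(nuc$abnormal) / attr(nuc, "fov_area_mm2")),
      class = "coverage_image")
  })
}

#' Run the coverage-probability experiment
#'
#' For every image, ROI radius and sampled ROI: restrict nuclei to the ROI
#' (centroid distance <= ROI radius), estimate the abnormal density and its
#' confidence interval at each level, and record whether the interval contains
#' the image's true full-FOV abnormal density. The same ROI draws are shared
#' across confidence levels. ROIs that contain no nuclei yield an invalid
#' interval, which never covers.
#'
#' @param panel List of images from [phantom_panel()] (or any list of entries
#'   with the same fields).
#' @param per_radius ROIs sampled per radius per image (default 200).
#' @param radii ROI radii; defaults to [radius_grid()] of the panel's FOV.
#' @param levels Confidence levels.
#' @param seed Integer seed.
#' @return Data frame of class `"ndci_coverage"` with columns `radius_px`,
#'   `area_fraction`, `level`, `coverage`, `n_rois`.
#' @export
run_coverage <- function(panel, per_radius = 200, radii = NULL,
                         levels = c(0.5, 0.6, 0.7, 0.8, 0.9), seed = 1L) {
  stopifnot(length(panel) >= 1)
  r_fov <- vapply(panel, function(im) im$fov_radius_px, numeric(1))
  if (length(unique(r_fov)) != 1)
    stop("all panel images must share the same FOV radius")
  r_fov <- r_fov[1]
  if (is.null(radii)) radii <- radius_grid(r_fov)
  nl <- length(levels)
  # covered[radius, level] accumulators
  hits <- matrix(0, length(radii), nl)
  tot <- matrix(0, length(radii), nl)
  with_seed(seed, {
    for (im in panel) {
      nuc <- im$nuclei
      ppmm <- (im$pixel_pitch / 1000)^2
      for (ri in seq_along(radii)) {
        r_roi <- radii[ri]
        ctrs <- sample_roi(r_fov, r_roi, n = per_radius, center = im$fov_center)
        # counts per ROI
        d2 <- outer(ctrs[, 1], nuc$row, "-")^2 + outer(ctrs[, 2], nuc$col, "-")^2
        inroi <- d2 <= r_roi^2
        n_hat <- rowSums(inroi)
        k <- as.integer(inroi %*% nuc$abnormal)
        a_hat <- pi * r_roi^2 * ppmm
        rate <- n_hat / a_hat
        pos <- n_hat > 0
        for (li in seq_len(nl)) {
          ci_low <- ci_high <- rep(NA_real_, per_radius)
          if (any(pos)) {
            pb <- clopper_pearson(k[pos], n_hat[pos], levels[li])
            ci_low[pos] <- pb[, "p_low"] * rate[pos]
            ci_high[pos] <- pb[, "p_high"] * rate[pos]
          }
          cov <- pos & ci_low <= im$true_density & im$true_density <= ci_high
          hits[ri, li] <- hits[ri, li] + sum(cov, na.rm = TRUE)
          tot[ri, li] <- tot[ri, li] + per_radius
        }
      }
    }
  })
  out <- data.frame(
    radius_px = rep(radii, times = nl),
    area_fraction = rep((radii / r_fov)^2, times = nl),
    level = rep(levels, each = length(radii)),
    coverage = as.vector(hits) / as.vector(tot),
    n_rois = as.integer(tot))
  class(out) <- c("ndci_coverage", "data.frame")
  attr(out, "r_fov") <- r_fov
  out
}

#' Plot coverage probability against ROI area fraction
#'
#' One curve per confidence level, with the nominal levels as dotted
#' horizontal lines.
#'
#' @param x An `"ndci_coverage"` result.
#' @param ... Passed to [graphics::matplot()].
#' @export
plot.ndci_coverage <- function(x, ...) {
  levels <- sort(unique(x$level))
  af <- sort(unique(x$area_fraction))
  m <- sapply(levels, function(l) {
    xi <- x[x$level == l, ]
    xi$coverage[order(xi$area_fraction)]
  })
  matplot(af, m, type = "l", lty = 1, lwd = 2,
          xlab = "ROI area (fraction of full FOV)",
          ylab = "Coverage probability", ylim = c(min(m, levels) - 0.05, 1), ...)
  abline(h = levels, lty = 3, col = "grey40")
  legend("bottomright", legend = sprintf("%d%%", round(100 * levels)),
         col = seq_along(levels), lty = 1, lwd = 2, bty = "n",
         title = "Nominal level")
  invisible(x)
}
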