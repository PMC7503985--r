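# Nuclear-density (ND) feature extraction: segment nuclei, score each as
# normal/abnormal by size and eccentricity, and compute the number of abnormal
# nuclei per mm^2. The clinically deployed feature relies on
# instrument-specific segmentation internals that are not public; this module
# implements a conventional, fully-documented pipeline (top-hat background
# flattening, Otsu threshold, distance-transform watershed) with every
# threshold exposed in nd_config().

#' Nucleus segmentation and scoring settings
#'
#' @param size_threshold_um2 Area above which a nucleus is abnormal (strict).
#' @param ecc_threshold Eccentricity above which a nucleus is abnormal (strict).
#' @param min_area_um2 Components smaller than this are discarded as debris.
#' @param tophat_radius_factor Top-hat structuring-element radius as a multiple
#'   of the expected mean nuclear radius.
#' @param mean_nucleus_radius_um Expected mean nuclear radius used to size the
#'   top-hat element.
#' @param boundary Decision boundary in abnormal nuclei per mm^2.
#' @return List of class `"nd_config"`.
#' @export
nd_config <- function(size_threshold_um2 = 65, ecc_threshold = 0.65,
                      min_area_um2 = 8, tophat_radius_factor = 3,
                      mean_nucleus_radius_um = 4, boundary = 189) {
  structure(as.list(environment()), class = "nd_config")
}

#' Segment nuclei in an HRME image
#'
#' Pipeline: flatten the background with a white top-hat (structuring element
#' 3x the mean nuclear radius), Otsu-threshold within the analyzed region,
#' split touching nuclei by distance-transform watershed, then drop components
#' below the minimum area or touching the FOV border. If a region mask is
#' supplied, only `visible_nuclei` pixels are analyzed and every returned
#' centroid lies in that region.
#'
#' @param image An [hrme_image()] (or plain intensity matrix in `[0, 1]`).
#' @param mask Optional [region_mask()]; restricts analysis to visible-nuclei
#'   pixels.
#' @param nd An [nd_config()].
#' @param pixel_pitch Micrometres per pixel (taken from `image` when it is an
#'   `hrme_image`).
#' @return Data frame of unlabelled nuclei: `row`, `col` (centroid, pixels),
#'   `area_um2`, `eccentricity`. Empty when nothing is found.
#' @export
segment_nuclei <- function(image, mask = NULL, nd = nd_config(),
                           pixel_pitch = hrme_pixel_pitch()) {
  if (inherits(image, "hrme_image")) {
    px <- image$pixels
    fov <- image$fov_mask
    pixel_pitch <- image$pixel_pitch
  } else {
    px <- image
    fov <- matrix(TRUE, nrow(px), ncol(px))
  }
  analyzed <- fov
  if (!is.null(mask)) {
    stopifnot(identical(dim(mask), dim(px)))
    analyzed <- analyzed & (rm_labels(mask) == REGION_CODES[["visible_nuclei"]])
  }
  empty <- data.frame(row = numeric(0), col = numeric(0),
                      area_um2 = numeric(0), eccentricity = numeric(0))
  if (!any(analyzed)) return(empty)

  r_px <- max(3L, round(nd$tophat_radius_factor * nd$mean_nucleus_radius_um /
                          pixel_pitch))
  brush <- EBImage::makeBrush(2L * r_px + 1L, shape = "disc")
  flat <- as.matrix(EBImage::whiteTopHat(px, brush))
  vals <- flat[analyzed]
  if (max(vals) <= min(vals)) return(empty)
  thr <- otsu_threshold(vals)
  bw <- (flat > thr) & analyzed
  if (!any(bw)) return(empty)

  dmap <- EBImage::distmap(bw * 1)
  labels <- EBImage::watershed(dmap, tolerance = 1, ext = 1)
  labels <- EBImage::imageData(labels)

  # drop components touching the FOV border or the frame edge
  border <- !fov
  border[c(1, nrow(px)), ] <- TRUE
  border[, c(1, ncol(px))] <- TRUE
  border <- border | !erode_mask(fov)
  touching <- unique(labels[labels > 0 & border])
  if (length(touching)) labels[labels %in% touching] <- 0L

  if (max(labels) < 1) return(empty)
  mom <- EBImage::computeFeatures.moment(labels)
  shp <- EBImage::computeFeatures.shape(labels)
  if (is.null(dim(mom))) mom <- matrix(mom, nrow = 1, dimnames = list(NULL, names(mom)))
  if (is.null(dim(shp))) shp <- matrix(shp, nrow = 1, dimnames = list(NULL, names(shp)))
  # EBImage reports centroids as (cx, cy) along (first, second) array index
  out <- data.frame(row = mom[, "m.cx"], col = mom[, "m.cy"],
                    area_um2 = shp[, "s.area"] * pixel_pitch^2,
                    eccentricity = mom[, "m.eccentricity"])
  out <- out[out$area_um2 >= nd$min_area_um2, , drop = FALSE]
  if (nrow(out) == 0) return(empty)
  # a nucleus belongs to a region iff its centroid does
  keep <- analyzed[cbind(pmax(1, pmin(nrow(px), round(out$row))),
                         pmax(1, pmin(ncol(px), round(out$col))))]
  out <- out[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Otsu threshold on a numeric vector (256-bin histogram)
otsu_threshold <- function(v) {
  rng <- range(v)
  h <- hist(v, breaks = seq(rng[1], rng[2], length.out = 257), plot = FALSE)
  w <- h$counts / sum(h$counts)
  mids <- h$mids
  omega <- cumsum(w)
  mu <- cumsum(w * mids)
  mu_t <- mu[length(mu)]
  sigma_b <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  sigma_b[!is.finite(sigma_b)] <- 0
  mids[which.max(sigma_b)]
}

# one-pixel 4-neighbour erosion of a logical mask
erode_mask <- function(m) {
  e <- m
  e[-1, ] <- e[-1, ] & m[-nrow(m), ]
  e[-nrow(m), ] <- e[-nrow(m), ] & m[-1, ]
  e[, -1] <- e[, -1] & m[, -ncol(m)]
  e[, -ncol(m)] <- e[, -ncol(m)] & m[, -1]
  e
}

#' Score nuclei as normal or abnormal
#'
#' A nucleus is abnormal iff its area exceeds `size_threshold_um2` OR its
#' eccentricity exceeds `ecc_threshold`; both comparisons are strict, so a
#' value exactly at a threshold is normal.
#'
#' @param nuclei Data frame from [segment_nuclei()] (or any frame with
#'   `area_um2` and `eccentricity` columns).
#' @param size_threshold_um2,ecc_threshold Strict thresholds.
#' @return The input with a `label` column (`"normal"` / `"abnormal"`).
#' @export
classify_nuclei <- function(nuclei, size_threshold_um2 = 65, ecc_threshold = 0.65) {
  stopifnot(size_threshold_um2 > 0, ecc_threshold > 0)
  abn <- nuclei$area_um2 > size_threshold_um2 | nuclei$eccentricity > ecc_threshold
  nuclei$label <- ifelse(abn, "abnormal", "normal")
  nuclei
}

#' Density estimate of abnormal nuclei
#'
#' @param nuclei Scored nuclei (with a `label` column), or a list with elements
#'   `k` (abnormal count) and `n` (total count).
#' @param area_mm2 Area of the analyzed regions in mm^2 (`A_hat`).
#' @return Object of class `"density_estimate"`: `p_hat` (abnormal
#'   proportion), `n_hat` (nucleus count), `k_abnormal`, `area_mm2`,
#'   `abnormal_density` (abnormal nuclei per mm^2), `degenerate` (`TRUE` when
#'   no nuclei were available).
#' @export
density_estimate <- function(nuclei, area_mm2) {
  if (is.data.frame(nuclei)) {
    n <- nrow(nuclei)
    k <- if (n > 0) sum(nuclei$label == "abnormal") else 0L
  } else {
    k <- nuclei$k; n <- nuclei$n
  }
  if (n > 0 && area_mm2 <= 0) stop("`area_mm2` must be positive")
  structure(list(
    p_hat = if (n > 0) k / n else 0,
    n_hat = as.integer(n),
    k_abnormal = as.integer(k),
    area_mm2 = area_mm2,
    abnormal_density = if (n > 0) k / area_mm2 else 0,
    degenerate = n == 0), class = "density_estimate")
}

#' @rdname density_estimate
#' @export
abnormal_density <- density_estimate

#' @export
print.density_estimate <- function(x, ...) {
  cat(sprintf(
    "<density_estimate> p_hat = %.3f, n_hat = %d, A_hat = %.3f mm^2 -> %.1f abnormal / mm^2%s\n",
    x$p_hat, x$n_hat, x$area_mm2, x$abnormal_density,
    if (x$degenerate) " (degenerate: no nuclei)" else ""))
  invisible(x)
}

#' Original nuclear-density classification (no reject option)
#'
#' Classifies as neoplastic iff the abnormal density strictly exceeds the
#' decision boundary; a density exactly at the boundary is benign.
#'
#' @param x A [density_estimate()] or a numeric density (abnormal nuclei/mm^2).
#' @param boundary Decision boundary (default 189 abnormal nuclei per mm^2).
#' @return `"neoplastic"` or `"benign"`.
#' @export
nd_classify <- function(x, boundary = 189) {
  d <- if (inherits(x, "density_estimate")) x$abnormal_density else x
  ifelse(d > boundary, "neoplastic", "benign")
}
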