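# The reject-option core: exact Clopper-Pearson binomial proportion intervals,
# the abnormal-density confidence interval, and the three-way decision rule.

#' Clopper-Pearson exact binomial proportion confidence interval
#'
#' Two-sided equal-tailed exact interval via beta-distribution quantiles:
#' with `alpha = 1 - level`,
#' `p_low = qbeta(alpha/2, k, n - k + 1)` (0 when `k = 0`) and
#' `p_high = qbeta(1 - alpha/2, k + 1, n - k)` (1 when `k = n`).
#'
#' @param k Number of successes (vectorized).
#' @param n Number of trials, `n >= 1`.
#' @param level Confidence level in `(0, 1)`.
#' @return Matrix with columns `p_low`, `p_high`.
#' @export
clopper_pearson <- function(k, n, level = 0.90) {
  if (any(level <= 0 | level >= 1)) stop("`level` must be in (0, 1)")
  if (any(n < 1)) stop("`n` must be at least 1")
  if (any(k < 0 | k > n)) stop("`k` must satisfy 0 <= k <= n")
  alpha <- 1 - level
  p_low <- ifelse(k == 0, 0, qbeta(alpha / 2, k, n - k + 1))
  p_high <- ifelse(k == n, 1, qbeta(1 - alpha / 2, k + 1, n - k))
  cbind(p_low = p_low, p_high = p_high)
}

#' Confidence interval for the abnormal-nucleus density
#'
#' The density of abnormal nuclei over the full FOV is `p * (n / A)`. Assuming
#' the nuclear density in the analyzed regions equals that of the full FOV
#' (`n / A = n_hat / A_hat`), the only estimated quantity is the abnormal
#' proportion `p`, modelled as binomial. The interval for the density is the
#' Clopper-Pearson interval for `p`, scaled by the observed nuclear density
#' `n_hat / A_hat`.
#'
#' @param estimate A [density_estimate()] (or [abnormal_density()] result).
#' @param level Confidence level, default 0.90.
#' @return Object of class `"density_ci"`: `level`, `p_low`, `p_high`,
#'   `ci_low`, `ci_high`, `valid`. When no nuclei are available the interval is
#'   invalid (`valid = FALSE`, bounds `NA`).
#' @export
density_ci <- function(estimate, level = 0.90) {
  stopifnot(inherits(estimate, "density_estimate"))
  if (estimate$n_hat < 1) {
    return(structure(list(level = level, p_low = NA_real_, p_high = NA_real_,
                          ci_low = NA_real_, ci_high = NA_real_, valid = FALSE),
                     class = "density_ci"))
  }
  pb <- clopper_pearson(estimate$k_abnormal, estimate$n_hat, level)
  p_low <- unname(pb[1, "p_low"])
  p_high <- unname(pb[1, "p_high"])
  rate <- estimate$n_hat / estimate$area_mm2
  structure(list(level = level, p_low = p_low, p_high = p_high,
                 ci_low = p_low * rate, ci_high = p_high * rate,
                 valid = TRUE),
            class = "density_ci")
}

#' @export
print.density_ci <- function(x, ...) {
  if (!x$valid) {
    cat(sprintf("<density_ci> %.0f%% CI: N/A (N/A to N/A)\n", 100 * x$level))
  } else {
    cat(sprintf("<density_ci> %.0f%% CI: %.0f to %.0f abnormal nuclei / mm^2\n",
                100 * x$level, x$ci_low, x$ci_high))
  }
  invisible(x)
}

#' Three-way classification with a reject option
#'
#' Compares the density confidence interval to the decision boundary:
#' neoplastic if the full interval lies above the boundary
#' (`ci_low > boundary`), benign if it lies below (`ci_high < boundary`), and
#' "cannot classify" otherwise — including when the interval spans the
#' boundary, touches it exactly, or is invalid (no nuclei).
#'
#' @param ci A [density_ci()].
#' @param boundary Decision boundary in abnormal nuclei per mm^2 (default 189).
#' @return Object of class `"ndci_decision"`: `category` (one of
#'   `"neoplastic"`, `"benign"`, `"cannot_classify"`), `boundary`, `ci`.
#' @export
ndci_decide <- function(ci, boundary = 189) {
  stopifnot(inherits(ci, "density_ci"))
  category <- if (!ci$valid) "cannot_classify"
    else if (ci$ci_low > boundary) "neoplastic"
    else if (ci$ci_high < boundary) "benign"
    else "cannot_classify"
  structure(list(category = category, boundary = boundary, ci = ci),
            class = "ndci_decision")
}

#' @export
print.ndci_decision <- function(x, ...) {
  lab <- c(neoplastic = "neoplastic", benign = "benign",
           cannot_classify = "cannot classify")[x$category]
  if (x$ci$valid) {
    cat(sprintf("Decision: %s (%.0f%% CI %.0f to %.0f vs boundary %g / mm^2)\n",
                lab, 100 * x$ci$level, x$ci$ci_low, x$ci$ci_high, x$boundary))
  } else {
    cat(sprintf("Decision: %s (no nuclei available)\n", lab))
  }
  invisible(x)
}

#' Classify an HRME image end to end
#'
#' Pipeline: predict the region mask with the segmentation model (or use a
#' supplied mask), segment and score nuclei within the visible-nuclei regions,
#' estimate the abnormal density and its confidence interval, and apply the
#' reject-option decision rule. All intermediates are returned as provenance.
#'
#' @param image An [hrme_image()].
#' @param model A fitted [unet_fit()] model, or `NULL` to use `mask`.
#' @param mask Optional [region_mask()] overriding model prediction; if both
#'   are `NULL` the whole FOV is treated as visible.
#' @param nd Nucleus segmentation/classification settings, see [nd_config()].
#' @param level Confidence level.
#' @param boundary Decision boundary (abnormal nuclei per mm^2).
#' @return Object of class `"ndci_result"`: `decision`, `ci`, `estimate`,
#'   `nuclei`, `region_mask`, `image_id`, `level`, `boundary`.
#' @export
classify_image <- function(image, model = NULL, mask = NULL, nd = nd_config(),
                           level = 0.90, boundary = 189) {
  stopifnot(inherits(image, "hrme_image"))
  if (is.null(mask)) {
    if (!is.null(model)) {
      mask <- predict(model, image)
    } else {
      lab <- matrix(REGION_CODES[["background"]], nrow(image$pixels), ncol(image$pixels))
      lab[image$fov_mask] <- REGION_CODES[["visible_nuclei"]]
      mask <- region_mask(lab)
    }
  }
  nuclei <- segment_nuclei(image, mask, nd = nd)
  nuclei <- classify_nuclei(nuclei, size_threshold_um2 = nd$size_threshold_um2,
                            ecc_threshold = nd$ecc_threshold)
  area <- mask_area_mm2(mask, image$pixel_pitch, "visible_nuclei")
  est <- abnormal_density(nuclei, area)
  ci <- density_ci(est, level = level)
  decision <- ndci_decide(ci, boundary = boundary)
  structure(list(decision = decision, ci = ci, estimate = est, nuclei = nuclei,
                 region_mask = mask, image_id = image$image_id,
                 level = level, boundary = boundary),
            class = "ndci_result")
}

#' @export
print.ndci_result <- function(x, ...) {
  if (!is.na(x$image_id)) cat("Image:", x$image_id, "\n")
  cat(sprintf("Abnormal nuclei / mm^2: %s  (n_hat = %d, A_hat = %.3f mm^2)\n",
              if (x$estimate$n_hat > 0) sprintf("%.0f", x$estimate$abnormal_density)
              else "N/A",
              x$estimate$n_hat, x$estimate$area_mm2))
  print(x$decision)
  invisible(x)
}
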