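# Segmentation metrics, biopsy-level aggregation and algorithm comparison.
# The no-visible-nuclei class is the positive class for sensitivity and
# specificity; background pixels are excluded from every count; metrics over
# sets of images are pooled on a pixel basis.

#' Pixel-level segmentation metrics
#'
#' Accuracy, sensitivity (fraction of no-visible-nuclei pixels correctly
#' classified), specificity (fraction of visible-nuclei pixels correctly
#' classified), per-class intersection-over-union
#' `IoU_c = TP_c / (TP_c + FP_c + FN_c)`, and their mean. Background pixels
#' are excluded. Pass lists of masks to pool pixels across images.
#'
#' @param predicted A [region_mask()] or list of them.
#' @param truth Matching ground-truth mask(s).
#' @return List of class `"pixel_metrics"`: `accuracy`, `sensitivity`,
#'   `specificity`, `iou_visible`, `iou_no_visible`, `mean_iou`, `n_pixels`.
#' @export
pixel_metrics <- function(predicted, truth) {
  if (!is.list(predicted)) { predicted <- list(predicted); truth <- list(truth) }
  stopifnot(length(predicted) == length(truth))
  pred <- integer(0); tru <- integer(0)
  for (i in seq_along(predicted)) {
    p <- rm_labels(predicted[[i]]); t <- rm_labels(truth[[i]])
    if (!identical(dim(p), dim(t))) stop("mask shapes differ")
    if (!identical(p == 0L, t == 0L)) stop("mask backgrounds differ")
    keep <- t != 0L
    pred <- c(pred, p[keep]); tru <- c(tru, t[keep])
  }
  tp_no <- sum(pred == 2L & tru == 2L)
  tp_vis <- sum(pred == 1L & tru == 1L)
  iou <- function(tp, code) {
    denom <- sum(pred == code | tru == code)
    if (denom == 0) NA_real_ else tp / denom
  }
  iou_vis <- iou(tp_vis, 1L)
  iou_no <- iou(tp_no, 2L)
  structure(list(
    accuracy = mean(pred == tru),
    sensitivity = if (any(tru == 2L)) tp_no / sum(tru == 2L) else NA_real_,
    specificity = if (any(tru == 1L)) tp_vis / sum(tru == 1L) else NA_real_,
    iou_visible = iou_vis,
    iou_no_visible = iou_no,
    mean_iou = mean(c(iou_vis, iou_no)),
    n_pixels = length(tru)), class = "pixel_metrics")
}

#' @export
print.pixel_metrics <- function(x, ...) {
  cat(sprintf(paste0("<pixel_metrics> accuracy %.3f, sensitivity %.3f, ",
                     "specificity %.3f, IoU %.3f (visible %.3f / no-visible %.3f)\n"),
              x$accuracy, x$sensitivity, x$specificity, x$mean_iou,
              x$iou_visible, x$iou_no_visible))
  invisible(x)
}

#' Aggregate image-level decisions to a biopsy-level decision
#'
#' The biopsy takes the worst classification that could be made with
#' confidence: neoplastic if any image is neoplastic, otherwise benign if any
#' image is benign, otherwise (all images rejected) cannot-classify.
#'
#' @param decisions Character vector of image-level categories
#'   (`"neoplastic"`, `"benign"`, `"cannot_classify"`) or a list of
#'   `"ndci_decision"` objects.
#' @return A single category string.
#' @export
aggregate_biopsy <- function(decisions) {
  if (is.list(decisions))
    decisions <- vapply(decisions, function(d)
      if (inherits(d, "ndci_decision")) d$category else as.character(d),
      character(1))
  stopifnot(length(decisions) >= 1,
            all(decisions %in% c("neoplastic", "benign", "cannot_classify")))
  if (any(decisions == "neoplastic")) "neoplastic"
  else if (any(decisions == "benign")) "benign"
  else "cannot_classify"
}

#' Confusion table and predictive values at the biopsy level
#'
#' Cross-tabulates algorithm categories against histopathology and computes
#' accuracy, positive predictive value and negative predictive value over the
#' classified biopsies only; rejected (cannot-classify) biopsies are counted
#' separately. Ratios with a zero denominator are reported as `NA`.
#'
#' @param category Character vector of algorithm categories per biopsy
#'   (`"neoplastic"`, `"benign"`, `"cannot_classify"`).
#' @param histopath Character vector of histopathology labels
#'   (`"neoplastic"`, `"benign"`).
#' @return List of class `"biopsy_eval"`: `table` (3 x 2 confusion matrix),
#'   `accuracy`, `ppv`, `npv`, `n_classified`, `n_unclassified`, and the
#'   integer numerators/denominators behind each ratio.
#' @export
confusion_and_predictive_values <- function(category, histopath) {
  stopifnot(length(category) == length(histopath),
            all(category %in% c("neoplastic", "benign", "cannot_classify")),
            all(histopath %in% c("neoplastic", "benign")))
  category <- factor(category, c("neoplastic", "benign", "cannot_classify"))
  histopath <- factor(histopath, c("neoplastic", "benign"))
  tab <- table(algorithm = category, histopath = histopath)
  tp <- tab["neoplastic", "neoplastic"]
  fp <- tab["neoplastic", "benign"]
  fn <- tab["benign", "neoplastic"]
  tn <- tab["benign", "benign"]
  n_classified <- tp + fp + fn + tn
  ratio <- function(num, den) if (den == 0) NA_real_ else num / den
  structure(list(
    table = tab,
    accuracy = ratio(tp + tn, n_classified),
    ppv = ratio(tp, tp + fp),
    npv = ratio(tn, tn + fn),
    n_classified = as.integer(n_classified),
    n_unclassified = as.integer(sum(tab["cannot_classify", ])),
    counts = c(tp = tp, fp = fp, fn = fn, tn = tn)), class = "biopsy_eval")
}

#' @export
print.biopsy_eval <- function(x, ...) {
  print(x$table)
  fmt <- function(v, num, den) if (is.na(v)) "undefined (0 denominator)"
    else sprintf("%.0f%% (%d/%d)", 100 * v, num, den)
  cat(sprintf("accuracy %s, PPV %s, NPV %s; %d biopsies not classified\n",
              fmt(x$accuracy, x$counts["tp"] + x$counts["tn"], x$n_classified),
              fmt(x$ppv, x$counts["tp"], x$counts["tp"] + x$counts["fp"]),
              fmt(x$npv, x$counts["tn"], x$counts["tn"] + x$counts["fn"]),
              x$n_unclassified))
  invisible(x)
}

#' Two-proportion z-test (pooled variance, two-tailed)
#'
#' Used to compare accuracy, PPV or NPV between two algorithms, each expressed
#' as successes over a denominator.
#'
#' @param k1,n1 Successes and denominator for the first proportion.
#' @param k2,n2 Successes and denominator for the second proportion.
#' @return List: `z`, `p_value`, `p1`, `p2`.
#' @export
two_proportion_z <- function(k1, n1, k2, n2) {
  p1 <- k1 / n1; p2 <- k2 / n2
  pool <- (k1 + k2) / (n1 + n2)
  se <- sqrt(pool * (1 - pool) * (1 / n1 + 1 / n2))
  z <- (p1 - p2) / se
  list(z = z, p_value = 2 * pnorm(-abs(z)), p1 = p1, p2 = p2)
}

#' Compare two algorithms' biopsy-level performance
#'
#' Pooled two-proportion z-tests on accuracy, PPV and NPV between two
#' [confusion_and_predictive_values()] results.
#'
#' @param a,b `"biopsy_eval"` objects.
#' @return Data frame with one row per metric: both proportions, z and p.
#' @export
compare_algorithms <- function(a, b) {
  rows <- lapply(c("accuracy", "ppv", "npv"), function(metric) {
    num <- function(e) switch(metric,
      accuracy = unname(e$counts["tp"] + e$counts["tn"]),
      ppv = unname(e$counts["tp"]),
      npv = unname(e$counts["tn"]))
    den <- function(e) switch(metric,
      accuracy = e$n_classified,
      ppv = unname(e$counts["tp"] + e$counts["fp"]),
      npv = unname(e$counts["tn"] + e$counts["fn"]))
    zt <- two_proportion_z(num(a), den(a), num(b), den(b))
    data.frame(metric = metric, p_a = zt$p1, p_b = zt$p2,
               z = zt$z, p_value = zt$p_value)
  })
  do.call(rbind, rows)
}
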