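test_that("Clopper-Pearson endpoints match the tail-sum inversion oracle", {
  # boundary cases of the exact method
  for (n in c(1, 7, 50)) for (lev in c(0.5, 0.9, 0.99)) {
    expect_identical(unname(clopper_pearson(0, n, lev)[, "p_low"]), 0)
    expect_identical(unname(clopper_pearson(n, n, lev)[, "p_high"]), 1)
  }
  # the worked case and a small grid against the independent oracle
  got <- clopper_pearson(5, 50, 0.95)
  orc <- cp_oracle(5, 50, 0.95)
  expect_equal(unname(got[, "p_low"]), unname(orc["p_low"]), tolerance = 1e-8)
  expect_equal(unname(got[, "p_high"]), unname(orc["p_high"]), tolerance = 1e-8)
  for (n in c(3, 20, 120)) for (k in unique(c(0, 1, n %/% 3, n))) {
    orc <- cp_oracle(k, n, 0.90)
    got <- clopper_pearson(k, n, 0.90)
    expect_equal(unname(got[1, ]), unname(orc), tolerance = 1e-7)
  }
  # argument validation
  expect_error(clopper_pearson(5, 4, 0.9), "k")
  expect_error(clopper_pearson(0, 0, 0.9), "n")
  expect_error(clopper_pearson(1, 5, 1.2), "level")
})

test_that("interval families nest across levels and shrink with n", {
  set.seed(1)
  for (i in 1:25) {
    n <- sample(1:300, 1); k <- sample(0:n, 1)
    lo <- clopper_pearson(k, n, 0.50)
    hi <- clopper_pearson(k, n, 0.90)
    expect_gte(lo[, "p_low"], hi[, "p_low"])
    expect_lte(lo[, "p_high"], hi[, "p_high"])
    # point estimate always inside
    expect_gte(k / n, lo[, "p_low"]); expect_lte(k / n, lo[, "p_high"])
  }
  # width -> 0 as n grows at fixed p_hat
  widths <- vapply(10^(2:5), function(n) {
    ci <- clopper_pearson(round(0.3 * n), n, 0.90)
    unname(ci[, "p_high"] - ci[, "p_low"])
  }, numeric(1))
  expect_true(all(diff(widths) < 0))
  expect_lt(widths[length(widths)], 0.01)
})

test_that("empirical coverage never falls below the nominal level (conservatism)", {
  set.seed(7)
  for (n in c(10, 50, 200)) for (p in seq(0.1, 0.9, by = 0.2)) {
    k <- rbinom(10000, n, p)
    ci <- clopper_pearson(k, n, 0.90)
    cov <- mean(ci[, "p_low"] <= p & p <= ci[, "p_high"])
    expect_gte(cov, 0.90 - 0.01)  # Monte-Carlo slack only
  }
})

test_that("density CI scales the proportion interval by the nuclear density", {
  est <- density_estimate(list(k = 25, n = 100), area_mm2 = 0.25)
  ci <- density_ci(est, level = 0.90)
  orc <- cp_oracle(25, 100, 0.90)
  expect_equal(ci$ci_low, unname(orc["p_low"]) * 400, tolerance = 1e-6)
  expect_equal(ci$ci_high, unname(orc["p_high"]) * 400, tolerance = 1e-6)
  expect_true(ci$valid)
  expect_lte(ci$ci_low, ci$ci_high)

  # all abnormal: upper bound is the full nuclear density, exactly
  all_ab <- density_ci(density_estimate(list(k = 40, n = 40), 0.1), 0.90)
  expect_equal(all_ab$ci_high, 400)

  # no nuclei: invalid interval (the N/A (N/A to N/A) case)
  none <- density_ci(density_estimate(list(k = 0, n = 0), 0.05))
  expect_false(none$valid)
  expect_true(is.na(none$ci_low))

  # linear under area rescaling with counts fixed
  ci2 <- density_ci(density_estimate(list(k = 25, n = 100), 0.5), 0.90)
  expect_equal(ci2$ci_low, ci$ci_low / 2)
  expect_equal(ci2$ci_high, ci$ci_high / 2)
})

test_that("the reject-option rule reproduces the worked decisions", {
  make_ci <- function(lo, hi) structure(
    list(level = 0.9, p_low = NA, p_high = NA, ci_low = lo, ci_high = hi,
         valid = TRUE), class = "density_ci")
  expect_identical(ndci_decide(make_ci(233, 325))$category, "neoplastic")
  expect_identical(ndci_decide(make_ci(53, 98))$category, "benign")
  expect_identical(ndci_decide(make_ci(117, 198))$category, "cannot_classify")
  invalid <- structure(list(level = 0.9, p_low = NA, p_high = NA,
                            ci_low = NA_real_, ci_high = NA_real_, valid = FALSE),
                       class = "density_ci")
  expect_identical(ndci_decide(invalid)$category, "cannot_classify")
  # bounds touching the boundary are not confident calls (strict inequalities)
  expect_identical(ndci_decide(make_ci(189, 250))$category, "cannot_classify")
  expect_identical(ndci_decide(make_ci(100, 189))$category, "cannot_classify")

  # trichotomy: exhaustive and mutually exclusive over random intervals
  set.seed(2)
  for (i in 1:200) {
    lo <- runif(1, 0, 400); hi <- lo + runif(1, 0, 200)
    cat3 <- ndci_decide(make_ci(lo, hi), boundary = 189)$category
    expected <- if (lo > 189) "neoplastic" else if (hi < 189) "benign"
      else "cannot_classify"
    expect_identical(cat3, expected)
  }
})

test_that("end-to-end classification integrates masking, counting and the CI", {
  # a fully degraded image cannot be classified
  ph <- generate_phantom(tiny_spec(21, degradations = list(
    degradation("low_contrast", severity = 0.15))))
  res <- classify_image(ph$image, mask = ph$truth$region_mask)
  expect_identical(res$decision$category, "cannot_classify")
  expect_false(res$ci$valid)

  # determinism: identical inputs give identical decisions
  ph2 <- generate_phantom(tiny_spec(22))
  r1 <- classify_image(ph2$image, mask = ph2$truth$region_mask)
  r2 <- classify_image(ph2$image, mask = ph2$truth$region_mask)
  expect_identical(r1$estimate, r2$estimate)
  expect_identical(r1$decision$category, r2$decision$category)

  # dense, high-abnormal-fraction phantoms with half the FOV visible are
  # called neoplastic in nearly all seeds
  calls <- vapply(1:20, function(s) {
    p <- generate_phantom(phantom_spec(
      fov_radius_px = 120, pixel_pitch = 2, nuclear_density = 800,
      abnormal_fraction = 0.5, seed = 3000 + s))
    lab <- ndci:::rm_labels(p$truth$region_mask)
    lab[, 1:120] <- ifelse(lab[, 1:120] == 0L, 0L, 2L)  # hide left half
    classify_image(p$image, mask = region_mask(lab))$decision$category
  }, character(1))
  expect_gte(mean(calls == "neoplastic"), 0.95)
})
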