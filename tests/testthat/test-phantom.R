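test_that("phantom generation is seeded-deterministic and honours edge specs", {
  sp <- tiny_spec(42)
  a <- generate_phantom(sp)
  b <- generate_phantom(sp)
  expect_identical(a$image$pixels, b$image$pixels)
  expect_identical(a$truth$nuclei, b$truth$nuclei)

  # zero density: no nuclei, zero true density
  z <- generate_phantom(tiny_spec(1, nuclear_density = 0))
  expect_identical(nrow(z$truth$nuclei), 0L)
  expect_identical(z$truth$true_abnormal_density, 0)

  # all-abnormal spec: true abnormal density equals the requested density up
  # to count quantization (rounding to a whole number of nuclei)
  f1 <- generate_phantom(tiny_spec(2, abnormal_fraction = 1,
                                   nuclear_density = 500), render = FALSE)
  n <- nrow(f1$truth$nuclei)
  expect_true(all(f1$truth$nuclei$abnormal))
  expect_equal(f1$truth$true_abnormal_density, n / f1$truth$fov_area_mm2)
  expect_lte(abs(f1$truth$true_abnormal_density - 500),
             1 / f1$truth$fov_area_mm2)

  # infeasible density under the hard-core constraint is refused
  expect_error(sample_nuclei(tiny_spec(3, nuclear_density = 2e5)),
               "infeasible")
})

test_that("empirical nuclear density matches the spec in the feasible regime", {
  for (dens in c(200, 600)) {
    got <- vapply(1:4, function(s) {
      nuc <- sample_nuclei(phantom_spec(fov_radius_px = 120, pixel_pitch = 2,
                                        nuclear_density = dens, seed = s))
      nrow(nuc) / attr(nuc, "fov_area_mm2")
    }, numeric(1))
    expect_lt(abs(mean(got) - dens) / dens, 0.10)
  }
})

test_that("abnormal morphology distributions recover the spec means", {
  sets <- lapply(1:50, function(s) sample_nuclei(tiny_spec(s)))
  nuc <- do.call(rbind, sets)
  ab <- nuc[nuc$abnormal, ]
  no <- nuc[!nuc$abnormal, ]
  se <- function(x) sd(x) / sqrt(length(x))
  expect_lt(abs(mean(ab$area_um2) - 90), 2 * se(ab$area_um2) + 2)   # +2: truncation at 5 um^2
  expect_lt(abs(mean(no$area_um2) - 35), 2 * se(no$area_um2) + 1)
  expect_lt(abs(mean(ab$eccentricity) - 0.75), 2 * se(ab$eccentricity) + 0.02)
  # abnormal nuclei are larger and more eccentric on average
  expect_gt(mean(ab$area_um2), mean(no$area_um2))
  expect_gt(mean(ab$eccentricity), mean(no$eccentricity))
})

test_that("degraded regions are rendered distinguishably from visible-nuclei regions", {
  ph <- generate_phantom(tiny_spec(
    9, degradations = list(degradation("saturated"), degradation("dim", 0.15),
                           degradation("keratinized"))))
  px <- ph$image$pixels
  lab <- ndci:::rm_labels(ph$truth$region_mask)
  vis_mean <- mean(px[lab == 1L])
  # reconstruct each degradation's geometry from the truth mask: degraded
  # pixels split by intensity signature
  deg <- lab == 2L
  expect_gt(sum(deg), 0)
  expect_gt(mean(px[deg & px >= 0.99]), vis_mean)          # saturated pixels
  expect_true(any(px[deg] < vis_mean - 0.05))              # dim pixels
  # overall separation of mean intensity between classes
  expect_gt(abs(mean(px[deg]) - vis_mean), 0.05)
  # keratinized bands physically remove their nuclei from the truth
  pk <- generate_phantom(tiny_spec(10, degradations = list(
    degradation("keratinized"))), render = FALSE)
  lk <- ndci:::rm_labels(pk$truth$region_mask)
  if (nrow(pk$truth$nuclei) > 0) {
    hit <- lk[cbind(round(pk$truth$nuclei$row), round(pk$truth$nuclei$col))]
    expect_true(all(hit != 2L))
  }
})

test_that("simulated raters degrade gracefully and majority voting denoises", {
  ph <- generate_phantom(tiny_spec(11, degradations = list(
    degradation("saturated"), degradation("dim", 0.2))), render = FALSE)
  truth <- ph$truth$region_mask

  # zero noise: raters reproduce the truth exactly
  clean <- simulate_raters(truth, flip_rate = 0, boundary_jitter_px = 0, seed = 1)
  expect_identical(clean[[1]], truth)
  expect_identical(clean[[3]], truth)

  # background is never altered
  noisy <- simulate_raters(truth, flip_rate = 0.2, boundary_jitter_px = 3, seed = 2)
  for (r in noisy)
    expect_identical(ndci:::rm_labels(r) == 0L, ndci:::rm_labels(truth) == 0L)

  # majority compositing beats the average single rater (IoU of the
  # no-visible class against truth), Monte-Carlo over seeded phantoms
  iou_no <- function(a, b) {
    A <- ndci:::rm_labels(a) == 2L; B <- ndci:::rm_labels(b) == 2L
    sum(A & B) / sum(A | B)
  }
  comp_iou <- single_iou <- numeric(0)
  for (s in 1:20) {
    p <- generate_phantom(tiny_spec(600 + s, degradations = list(
      degradation("saturated"), degradation("dim", 0.2))), render = FALSE)
    rs <- simulate_raters(p$truth$region_mask, flip_rate = 0.05,
                          boundary_jitter_px = 2, seed = s)
    comp <- composite_ground_truth(rs)
    comp_iou <- c(comp_iou, iou_no(comp, p$truth$region_mask))
    single_iou <- c(single_iou, mean(vapply(rs, iou_no, numeric(1),
                                            b = p$truth$region_mask)))
  }
  expect_gt(mean(comp_iou), mean(single_iou))
})

test_that("datasets split by patient with largest-remainder rounding and no leakage", {
  expect_identical(ndci:::largest_remainder(10, c(0.5, 0.2, 0.3)),
                   c(5L, 2L, 3L))
  expect_identical(sum(ndci:::largest_remainder(169, c(0.5, 0.2, 0.3))), 169L)

  dir1 <- withr::local_tempdir()
  man <- generate_dataset(8, images_per_patient = 2, seed = 5, dir = dir1)
  expect_identical(nrow(man), 16L)
  # every patient appears in exactly one split
  split_of <- tapply(man$split, man$patient_id, function(s) length(unique(s)))
  expect_true(all(split_of == 1))
  expect_setequal(unique(man$split), c("train", "validation", "test"))
  # images of one biopsy stay with one patient
  expect_true(all(tapply(man$patient_id, man$biopsy_id,
                         function(p) length(unique(p))) == 1))

  # same seed reproduces the manifest and the image bytes
  dir2 <- withr::local_tempdir()
  man2 <- generate_dataset(8, images_per_patient = 2, seed = 5, dir = dir2)
  cols <- c("patient_id", "biopsy_id", "split", "label")
  expect_identical(man[cols], man2[cols])
  expect_identical(readBin(man$image_path[1], "raw", 1e6),
                   readBin(man2$image_path[1], "raw", 1e6))

  expect_error(generate_dataset(2, seed = 1, dir = withr::local_tempdir()),
               "non-empty")
})
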