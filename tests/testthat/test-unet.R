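test_that("preprocessing maps [0,1] to [-1,1] and rescales", {
  expect_equal(unet_preprocess(matrix(0.5, 16, 16), 8),
               matrix(0, 8, 8))
  m <- matrix(c(0, 1), 16, 16)
  pm <- unet_preprocess(m, 16)
  expect_equal(range(pm), c(-1, 1))
  # constant image stays constant through the resize
  expect_equal(unet_preprocess(matrix(0.25, 30, 30), 12),
               matrix(-0.5, 12, 12))
  expect_error(unet_preprocess(matrix(2, 4, 4), 4), "\\[0, 1\\]")
})

test_that("majority compositing follows the two-of-three rule", {
  base <- matrix(0L, 6, 6)
  base[2:5, 2:5] <- 1L
  m1 <- base; m2 <- base; m3 <- base
  m1[2, 2] <- 2L; m2[2, 2] <- 2L            # (no, no, yes) -> no visible
  m3[3, 3] <- 2L                            # (yes, yes, no) -> visible
  comp <- composite_ground_truth(list(region_mask(m1), region_mask(m2),
                                      region_mask(m3)))
  expect_identical(comp[2, 2], 2L)
  expect_identical(comp[3, 3], 1L)
  expect_identical(comp[4, 4], 1L)          # unanimous visible
  # idempotence on identical masks
  same <- region_mask(m1)
  expect_identical(unclass(composite_ground_truth(list(same, same, same))),
                   unclass(same))
  # background must agree
  bad <- base; bad[2, 2] <- 0L
  expect_error(composite_ground_truth(list(region_mask(bad), region_mask(m2),
                                           region_mask(m3))), "background")
})

test_that("weighted cross-entropy matches closed forms and hand computation", {
  # confident correct predictions drive the loss to zero
  lab <- c(1L, 2L, 1L, 2L)
  sc <- matrix(-50, 4, 3)
  sc[cbind(1:4, lab)] <- 50
  expect_lt(weighted_cross_entropy(sc, lab)$loss, 1e-10)

  # uniform scores over the two foreground classes: loss = ln 2
  sc2 <- cbind(rep(1, 4), rep(1, 4), rep(-100, 4))
  expect_equal(weighted_cross_entropy(sc2, lab)$loss, log(2), tolerance = 1e-9)

  # 4-pixel toy with a doubled class weight: weighted-mean formula by hand
  sc3 <- cbind(c(2, 0, 1, 0), c(0, 2, 0, 3), rep(0, 4))
  ce <- -log(exp(sc3[cbind(1:4, lab)]) / rowSums(exp(sc3)))
  w <- c(2, 1, 2, 1)  # class 1 weight doubled
  expect_equal(weighted_cross_entropy(sc3, lab, c(2, 1, 0))$loss,
               sum(w * ce) / sum(w), tolerance = 1e-12)

  # background pixels carry no weight; an all-background field errors
  lab_bg <- c(0L, 0L, 1L, 0L)
  expect_equal(weighted_cross_entropy(sc3, lab_bg, c(1, 1, 0))$loss, ce[3])
  expect_error(weighted_cross_entropy(sc3, rep(0L, 4), c(1, 1, 0)),
               "non-background")
})

test_that("architecture shape trace and parameter counts match the layer arithmetic", {
  desk <- unet_config(input_size = 128, base_channels = 8, depth = 5)
  expect_identical(desk$channels, 8 * 2^(0:4))
  expect_identical(unet_count_params(desk), unet_params_closed_form(8, 5))
  expect_identical(unet_count_params(desk), 486307)    # frozen regression value

  full <- unet_config(input_size = 512, base_channels = 32, depth = 5)
  expect_identical(unet_count_params(full), unet_params_closed_form(32, 5))
  expect_identical(unet_count_params(full), 7762051)   # frozen regression value

  # zero-padded convolutions preserve spatial size through the whole network
  params <- ndci:::unet_init(desk, seed = 1)
  x <- array(runif(128 * 128), c(128, 128, 1, 1))
  fw <- unet_forward(params, x, desk)
  expect_identical(dim(fw$scores), c(128L, 128L, 1L, 3L))
  # inference is deterministic
  fw2 <- unet_forward(params, x, desk)
  expect_identical(fw$scores, fw2$scores)
  # indivisible input size is rejected
  expect_error(unet_config(input_size = 100, depth = 5), "divisible")
})

test_that("backward pass agrees with finite differences on a tiny network", {
  cfg <- unet_config(input_size = 16, base_channels = 2, depth = 3)
  params <- ndci:::unet_init(cfg, seed = 5)
  set.seed(3)
  x <- array(runif(16 * 16 * 2), c(16, 16, 2, 1))
  lab <- sample(0:2, 16 * 16 * 2, replace = TRUE)
  cw <- c(1.3, 0.7, 0)
  lossfun <- function(p) {
    fw <- unet_forward(p, x, cfg, training = TRUE)
    weighted_cross_entropy(fw$scores, lab, cw)$loss
  }
  fw <- unet_forward(params, x, cfg, training = TRUE)
  wl <- weighted_cross_entropy(fw$scores, lab, cw)
  grads <- ndci:::unet_backward(wl$grad, fw$caches, params, cfg)
  eps <- 1e-5
  for (nm in c("enc1.conv1.W", "enc3.conv2.W", "up1.W", "dec2.conv1.W",
               "out.W", "out.b", "enc2.bn1.gamma", "dec1.bn2.beta")) {
    i <- sample(length(params[[nm]]), 1)
    pp <- params; pp[[nm]][i] <- pp[[nm]][i] + eps
    pm <- params; pm[[nm]][i] <- pm[[nm]][i] - eps
    num <- (lossfun(pp) - lossfun(pm)) / (2 * eps)
    expect_equal(grads[[nm]][i], num, tolerance = 1e-4)
  }
})

test_that("reflection augmentation transforms image and labels identically", {
  set.seed(9)
  xi <- matrix(runif(64), 8, 8)
  yi <- matrix(sample(0:2, 64, replace = TRUE), 8, 8)
  found_flip <- FALSE
  for (s in 1:20) {
    set.seed(s)
    au <- ndci:::augment_pair(xi, yi, crop_min = 1)  # reflections only
    hflip <- identical(au$x, xi[, 8:1]); vflip <- identical(au$x, xi[8:1, ])
    both <- identical(au$x, xi[8:1, 8:1]); none <- identical(au$x, xi)
    expect_true(hflip || vflip || both || none)
    if (hflip) { expect_identical(au$y, yi[, 8:1]); found_flip <- TRUE }
    if (vflip) expect_identical(au$y, yi[8:1, ])
    if (both) expect_identical(au$y, yi[8:1, 8:1])
  }
  expect_true(found_flip)
})

test_that("postprocessing yields a valid mask with the documented tie-break", {
  fov <- disc_mask(c(40, 40), c(20.5, 20.5), 18)
  # equal scores on both nucleus channels: P(no visible) = 0.5 -> no visible
  sc <- array(0, c(16, 16, 3))
  m <- unet_postprocess(sc, c(40, 40), fov)
  expect_s3_class(m, "region_mask")
  expect_true(all(m[fov] == 2L))
  expect_true(all(m[!fov] == 0L))
  # background exactly complements the FOV (valid RegionMask invariant)
  expect_identical(ndci:::rm_labels(m) == 0L, !fov)
  # all-false FOV forces an all-background mask
  m0 <- unet_postprocess(sc, c(40, 40), matrix(FALSE, 40, 40))
  expect_true(all(m0 == 0L))
  # clear preference for the visible channel wins inside the FOV
  sc[, , 1] <- 5
  mv <- unet_postprocess(sc, c(40, 40), fov)
  expect_true(all(mv[fov] == 1L))
})

test_that("tiny seeded training runs are reproducible and actually learn", {
  dat <- unet_training_phantoms(6, seed = 400)
  cfg <- unet_config(input_size = 32, base_channels = 2, depth = 3)
  ctl <- unet_train_config(epochs = 4, batch_size = 3, augment = TRUE,
                           lr = 1e-3, seed = 11)
  m1 <- unet_fit(dat$x, dat$y, cfg, ctl)
  m2 <- unet_fit(dat$x, dat$y, cfg, ctl)
  expect_identical(m1$history, m2$history)
  expect_identical(m1$params, m2$params)
  # the checkpoint honours the selection contract
  expect_identical(m1$best_epoch, which.max(m1$history$val_iou))
  # loss decreases over the first epochs (learning signal present)
  expect_lt(m1$history$train_loss[4], m1$history$train_loss[1])
  # class weights: inverse prevalence, background zero, mean one
  expect_identical(m1$class_weights[3], 0)
  expect_equal(mean(m1$class_weights[1:2]), 1)
  # prediction produces a valid mask on an hrme_image
  pred <- predict(m1, dat$x[[1]])
  expect_s3_class(pred, "region_mask")
  expect_identical(ndci:::rm_labels(pred) == 0L, !dat$x[[1]]$fov_mask)
})
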