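# Seeded generator of HRME-like phantoms: fields of bright elliptical nuclei on
# a darker cytoplasm background inside a circular FOV, with optional degraded
# regions (saturated / dim / keratinized / low-contrast), ground-truth nuclei
# and region masks, simulated raters, and biopsy-level datasets.

#' Specify a synthetic HRME phantom
#'
#' Defaults emulate oral-epithelium HRME imagery: normal nuclei are small,
#' round and evenly spaced; abnormal nuclei are larger, more eccentric and more
#' variable. Nuclei are placed by a hard-core point process (minimum
#' separation = 0.8 x mean nuclear diameter), so requested densities must be
#' feasible under that packing constraint.
#'
#' @param fov_radius_px FOV radius in pixels (canvas is `2r x 2r`).
#' @param pixel_pitch Micrometres per pixel.
#' @param nuclear_density Total nuclei per mm^2 of FOV.
#' @param abnormal_fraction Probability that a nucleus is abnormal.
#' @param normal_area,abnormal_area `c(mean, sd)` of nuclear area in um^2.
#' @param normal_ecc,abnormal_ecc `c(mean, sd)` of eccentricity in `[0, 1)`.
#' @param degradations List of [degradation()] descriptors.
#' @param noise_sd Additive Gaussian noise SD (intensity units).
#' @param background_level Cytoplasm background intensity.
#' @param nucleus_intensity Nuclear intensity before blur.
#' @param blur_sigma Gaussian blur sigma in pixels (edge softness).
#' @param seed Integer seed; the same spec and seed give bit-identical phantoms.
#' @return A list of class `"phantom_spec"`.
#' @export
phantom_spec <- function(fov_radius_px = 480,
                         pixel_pitch = hrme_pixel_pitch(),
                         nuclear_density = 400,
                         abnormal_fraction = 0.3,
                         normal_area = c(mean = 35, sd = 10),
                         abnormal_area = c(mean = 90, sd = 30),
                         normal_ecc = c(mean = 0.4, sd = 0.15),
                         abnormal_ecc = c(mean = 0.75, sd = 0.1),
                         degradations = list(),
                         noise_sd = 0.02,
                         background_level = 0.15,
                         nucleus_intensity = 0.85,
                         blur_sigma = 1,
                         seed = 1L) {
  stopifnot(fov_radius_px >= 8, pixel_pitch > 0, nuclear_density >= 0,
            abnormal_fraction >= 0, abnormal_fraction <= 1, noise_sd >= 0)
  structure(as.list(environment()), class = "phantom_spec")
}

#' Describe a degraded image region
#'
#' @param kind One of `"saturated"`, `"dim"`, `"keratinized"`, `"low_contrast"`.
#' @param severity For `dim` and `low_contrast`, the multiplicative intensity /
#'   contrast factor in `(0, 1)`; ignored for the other kinds.
#' @param n_blobs Number of discs in the blob union (saturated / dim).
#' @param band_frac Height of the keratinized band as a fraction of the frame.
#' @return A degradation descriptor.
#' @export
degradation <- function(kind = c("saturated", "dim", "keratinized", "low_contrast"),
                        severity = 0.25, n_blobs = 2, band_frac = 0.3) {
  kind <- match.arg(kind)
  list(kind = kind, severity = severity, n_blobs = n_blobs, band_frac = band_frac)
}

# mean nuclear diameter (um) under the spec's normal/abnormal mixture
mean_diameter_um <- function(spec) {
  a <- (1 - spec$abnormal_fraction) * spec$normal_area[["mean"]] +
    spec$abnormal_fraction * spec$abnormal_area[["mean"]]
  2 * sqrt(a / pi)
}

#' Sample ground-truth nuclei for a phantom (hard-core point process)
#'
#' Centres are uniform over the FOV disc subject to a minimum pairwise
#' separation of 0.8 x mean nuclear diameter; morphology is drawn from the
#' spec's normal/abnormal distributions.
#'
#' @param spec A [phantom_spec()].
#' @return Data frame with columns `row`, `col` (pixel coordinates), `area_um2`,
#'   `eccentricity`, `theta` (orientation), `abnormal` (logical). Attributes
#'   `fov_center`, `fov_radius_px`, `pixel_pitch`, `fov_area_mm2`.
#' @export
sample_nuclei <- function(spec) {
  with_seed(spec$seed, sample_nuclei_impl(spec))
}

sample_nuclei_impl <- function(spec) {
  r <- spec$fov_radius_px
  ctr <- c(r + 0.5, r + 0.5)
  area_mm2 <- pi * r^2 * (spec$pixel_pitch / 1000)^2
  n <- round(spec$nuclear_density * area_mm2)
  min_sep <- 0.8 * mean_diameter_um(spec) / spec$pixel_pitch

  rows <- cols <- numeric(n)
  if (n > 0) {
    # grid-accelerated dart throwing
    cell <- max(min_sep, 1e-6)
    ncell <- ceiling(2 * r / cell)
    grid <- vector("list", ncell * ncell)
    cell_of <- function(y, x) {
      gi <- pmin(ncell, pmax(1L, ceiling(y / cell)))
      gj <- pmin(ncell, pmax(1L, ceiling(x / cell)))
      (gj - 1L) * ncell + gi
    }
    placed <- 0L
    attempts <- 0L
    max_attempts <- 400L * n + 1000L
    while (placed < n && attempts < max_attempts) {
      attempts <- attempts + 1L
      rad <- (r - 1) * sqrt(runif(1))
      ang <- runif(1, 0, 2 * pi)
      y <- ctr[1] + rad * sin(ang)
      x <- ctr[2] + rad * cos(ang)
      gi <- ceiling(y / cell); gj <- ceiling(x / cell)
      ok <- TRUE
      for (dj in -1:1) for (di in -1:1) {
        ii <- gi + di; jj <- gj + dj
        if (ii < 1 || jj < 1 || ii > ncell || jj > ncell) next
        for (id in grid[[(jj - 1L) * ncell + ii]]) {
          if ((rows[id] - y)^2 + (cols[id] - x)^2 < min_sep^2) { ok <- FALSE; break }
        }
        if (!ok) break
      }
      if (ok) {
        placed <- placed + 1L
        rows[placed] <- y; cols[placed] <- x
        ci <- cell_of(y, x)
        grid[[ci]] <- c(grid[[ci]], placed)
      }
    }
    if (placed < n)
      stop("infeasible phantom spec: requested density violates the hard-core ",
           "minimum separation (placed ", placed, " of ", n, " nuclei)")
  }

  abnormal <- if (n > 0) runif(n) < spec$abnormal_fraction else logical(0)
  draw <- function(par, k) if (k > 0) rnorm(k, par[["mean"]], par[["sd"]]) else numeric(0)
  area <- ecc <- numeric(n)
  area[!abnormal] <- pmax(5, draw(spec$normal_area, sum(!abnormal)))
  area[abnormal] <- pmax(5, draw(spec$abnormal_area, sum(abnormal)))
  ecc[!abnormal] <- pmin(0.95, pmax(0, draw(spec$normal_ecc, sum(!abnormal))))
  ecc[abnormal] <- pmin(0.95, pmax(0, draw(spec$abnormal_ecc, sum(abnormal))))

  out <- data.frame(row = rows, col = cols, area_um2 = area,
                    eccentricity = ecc,
                    theta = if (n > 0) runif(n, 0, pi) else numeric(0),
                    abnormal = abnormal)
  attr(out, "fov_center") <- ctr
  attr(out, "fov_radius_px") <- r
  attr(out, "pixel_pitch") <- spec$pixel_pitch
  attr(out, "fov_area_mm2") <- area_mm2
  out
}

# realize degradation geometries as logical matrices (within the FOV)
degradation_geometry <- function(deg, dims, ctr, r) {
  fov <- disc_mask(dims, ctr, r)
  g <- switch(deg$kind,
    saturated = ,
    dim = {
      m <- matrix(FALSE, dims[1], dims[2])
      for (i in seq_len(deg$n_blobs)) {
        br <- runif(1, 0.12, 0.3) * r
        brad <- runif(1, 0, 0.8 * r)
        bang <- runif(1, 0, 2 * pi)
        bc <- ctr + brad * c(sin(bang), cos(bang))
        m <- m | disc_mask(dims, bc, br)
      }
      m
    },
    keratinized = {
      h <- deg$band_frac * dims[1]
      c0 <- runif(1, h / 2, dims[1] - h / 2)
      rowsel <- abs(seq_len(dims[1]) - c0) <= h / 2
      matrix(rowsel, dims[1], dims[2])
    },
    low_contrast = matrix(TRUE, dims[1], dims[2]))
  g & fov
}

#' Generate a synthetic HRME phantom
#'
#' Renders the spec's nuclei as bright ellipses with Gaussian edge blur on a
#' darker cytoplasm background, applies degradations, and returns the image
#' together with its ground truth (nuclei table, region mask, true abnormal
#' density over the full FOV). Same spec and seed give bit-identical output.
#'
#' Degradations: `saturated` regions are clipped to intensity 1, `dim` regions
#' are scaled down, `keratinized` bands replace nuclei with a bright texture
#' (those nuclei are removed from the truth), and `low_contrast` compresses
#' contrast over the whole FOV. All degraded pixels are marked
#' `no_visible_nuclei` in the truth region mask.
#'
#' @param spec A [phantom_spec()].
#' @param render If `FALSE`, skip image rendering and return only the truth
#'   (fast path for point-process experiments).
#' @return List of class `"hrme_phantom"` with elements `image`
#'   (an [hrme_image()], `NULL` when `render = FALSE`) and `truth`
#'   (list: `nuclei`, `region_mask`, `true_abnormal_density`, `fov_area_mm2`).
#' @export
generate_phantom <- function(spec, render = TRUE) {
  stopifnot(inherits(spec, "phantom_spec"))
  nuc <- sample_nuclei(spec)
  r <- spec$fov_radius_px
  dims <- c(2 * r, 2 * r)
  ctr <- attr(nuc, "fov_center")
  fov <- disc_mask(dims, ctr, r)

  with_seed(spec$seed + 1003L, {
    geoms <- lapply(spec$degradations, degradation_geometry, dims = dims,
                    ctr = ctr, r = r)

    # keratinized bands physically obliterate nuclei
    kera <- Reduce(`|`, c(list(matrix(FALSE, dims[1], dims[2])),
                          geoms[vapply(spec$degradations, function(d)
                            d$kind == "keratinized", logical(1))]))
    if (nrow(nuc) > 0 && any(kera)) {
      hit <- kera[cbind(pmax(1, pmin(dims[1], round(nuc$row))),
                        pmax(1, pmin(dims[2], round(nuc$col))))]
      nuc <- nuc[!hit, , drop = FALSE]
    }

    degraded <- Reduce(`|`, c(list(matrix(FALSE, dims[1], dims[2])), geoms))
    # low-contrast phantoms below a visibility floor lose the whole FOV
    for (i in seq_along(spec$degradations)) {
      d <- spec$degradations[[i]]
      if (d$kind == "low_contrast" && d$severity < 0.5) degraded <- degraded | fov
    }

    labels <- matrix(REGION_CODES[["background"]], dims[1], dims[2])
    labels[fov] <- REGION_CODES[["visible_nuclei"]]
    labels[degraded & fov] <- REGION_CODES[["no_visible_nuclei"]]

    img <- NULL
    if (render) {
      px <- matrix(spec$background_level, dims[1], dims[2])
      px <- render_ellipses(px, nuc, spec)
      for (i in seq_along(spec$degradations)) {
        d <- spec$degradations[[i]]
        if (d$kind == "keratinized")
          px[geoms[[i]]] <- 0.6 + (runif(sum(geoms[[i]])) - 0.5) * 0.5
      }
      if (spec$blur_sigma > 0)
        px <- as.matrix(EBImage::gblur(px, sigma = spec$blur_sigma))
      for (i in seq_along(spec$degradations)) {
        d <- spec$degradations[[i]]
        if (d$kind == "dim") px[geoms[[i]]] <- px[geoms[[i]]] * d$severity
        if (d$kind == "low_contrast")
          px[geoms[[i]]] <- 0.5 + (px[geoms[[i]]] - 0.5) * d$severity
      }
      if (spec$noise_sd > 0) px <- px + rnorm(length(px), 0, spec$noise_sd)
      px <- pmin(pmax(px, 0), 1)
      for (i in seq_along(spec$degradations)) {
        d <- spec$degradations[[i]]
        if (d$kind == "saturated") px[geoms[[i]]] <- 1
      }
      px[!fov] <- 0
      img <- hrme_image(px, fov_mask = fov, pixel_pitch = spec$pixel_pitch)
    }

    truth <- list(
      nuclei = nuc,
      region_mask = region_mask(labels),
      true_abnormal_density = sum(nuc$abnormal) / attr(nuc, "fov_area_mm2"),
      fov_area_mm2 = attr(nuc, "fov_area_mm2"),
      spec = spec)
    structure(list(image = img, truth = truth), class = "hrme_phantom")
  })
}

# draw hard ellipses into the intensity matrix (blur applied later)
render_ellipses <- function(px, nuc, spec) {
  if (nrow(nuc) == 0) return(px)
  dims <- dim(px)
  pp <- spec$pixel_pitch
  for (i in seq_len(nrow(nuc))) {
    area_px <- nuc$area_um2[i] / pp^2
    ab <- area_px / pi
    e <- nuc$eccentricity[i]
    a <- sqrt(ab / sqrt(1 - e^2))   # semi-major (px)
    b <- ab / a                     # semi-minor
    th <- nuc$theta[i]
    y0 <- nuc$row[i]; x0 <- nuc$col[i]
    ext <- ceiling(a) + 1
    rr <- max(1, floor(y0 - ext)):min(dims[1], ceiling(y0 + ext))
    cc <- max(1, floor(x0 - ext)):min(dims[2], ceiling(x0 + ext))
    dy <- rr - y0
    dx <- cc - x0
    # rotate into ellipse frame; rows vary along dy, cols along dx
    u <- outer(dy, dx, function(Y, X) (X * cos(th) + Y * sin(th)) / a)
    v <- outer(dy, dx, function(Y, X) (-X * sin(th) + Y * cos(th)) / b)
    inside <- u^2 + v^2 <= 1
    sub <- px[rr, cc, drop = FALSE]
    sub[inside] <- pmax(sub[inside], spec$nucleus_intensity)
    px[rr, cc] <- sub
  }
  px
}

#' @export
print.hrme_phantom <- function(x, ...) {
  cat(sprintf("<hrme_phantom> %d nuclei (%d abnormal), true abnormal density %.1f / mm^2\n",
              nrow(x$truth$nuclei), sum(x$truth$nuclei$abnormal),
              x$truth$true_abnormal_density))
  invisible(x)
}

# --- simulated raters -------------------------------------------------------

#' Simulate noisy rater region masks
#'
#' Emulates several human raters labelling the same image: each rater's mask is
#' the truth with morphologically jittered region boundaries plus independent
#' region-level label flips. Background pixels are never altered.
#'
#' @param truth_mask Ground-truth [region_mask()].
#' @param flip_rate Probability in `[0, 0.5)` that a connected region's label
#'   is flipped.
#' @param boundary_jitter_px Maximum dilation/erosion radius applied to the
#'   no-visible-nuclei regions.
#' @param n_raters Number of raters (odd counts make majority voting tie-free).
#' @param seed Integer seed.
#' @return List of `n_raters` region masks.
#' @export
simulate_raters <- function(truth_mask, flip_rate = 0.05, boundary_jitter_px = 2,
                            n_raters = 3, seed = 1L) {
  stopifnot(flip_rate >= 0, flip_rate < 0.5, n_raters >= 1)
  truth <- rm_labels(truth_mask)
  fov <- truth != REGION_CODES[["background"]]
  with_seed(seed, {
    lapply(seq_len(n_raters), function(i) {
      lab <- truth
      if (boundary_jitter_px > 0) {
        no_vis <- (lab == REGION_CODES[["no_visible_nuclei"]]) * 1
        if (any(no_vis > 0) && !all(no_vis[fov] > 0)) {
          jr <- sample.int(boundary_jitter_px, 1)
          kern <- EBImage::makeBrush(2 * jr + 1, shape = "disc")
          no_vis <- if (runif(1) < 0.5) EBImage::dilate(no_vis, kern)
                    else EBImage::erode(no_vis, kern)
          no_vis <- as.matrix(no_vis) > 0
          lab[fov] <- ifelse(no_vis[fov], REGION_CODES[["no_visible_nuclei"]],
                             REGION_CODES[["visible_nuclei"]])
        }
      }
      if (flip_rate > 0) {
        for (code in c(REGION_CODES[["visible_nuclei"]],
                       REGION_CODES[["no_visible_nuclei"]])) {
          comp <- EBImage::bwlabel((lab == code) * 1)
          comp <- EBImage::imageData(comp)
          ncomp <- max(comp)
          if (ncomp > 0) {
            flip <- runif(ncomp) < flip_rate
            if (any(flip)) {
              other <- REGION_CODES[["visible_nuclei"]] +
                REGION_CODES[["no_visible_nuclei"]] - code
              lab[comp > 0 & flip[pmax(comp, 1)] & fov] <- other
            }
          }
        }
      }
      region_mask(lab)
    })
  })
}

# --- datasets ---------------------------------------------------------------

# largest-remainder apportionment of n into fractions
largest_remainder <- function(n, fractions) {
  stopifnot(abs(sum(fractions) - 1) < 1e-8)
  raw <- n * fractions
  base <- floor(raw)
  left <- n - sum(base)
  if (left > 0) {
    ord <- order(raw - base, decreasing = TRUE)
    base[ord[seq_len(left)]] <- base[ord[seq_len(left)]] + 1
  }
  as.integer(base)
}

#' Generate a synthetic patient-level dataset
#'
#' Generates phantoms grouped into biopsies (1-3 images sharing one spec) and
#' patients, writes images and ground-truth masks to `dir`, and partitions
#' patients into train/validation/test splits by largest-remainder rounding of
#' the split fractions. The partition is by patient: all images of a patient
#' share a split, so there is no patient leakage between splits.
#'
#' @param n_patients Number of patients.
#' @param images_per_patient Images acquired per patient.
#' @param split Named or unnamed fractions `c(train, validation, test)`
#'   summing to 1.
#' @param spec_sampler `function(patient_id, biopsy_id)` returning a list with
#'   elements `spec` (a [phantom_spec()]; its `seed` is overridden) and `label`
#'   (`"neoplastic"` or `"benign"`). Defaults to a small desk-scale sampler.
#' @param seed Integer seed.
#' @param dir Output directory (created if needed).
#' @return Manifest data frame (`image_path`, `mask_path`, `patient_id`,
#'   `biopsy_id`, `split`, `label`), also written to `manifest.csv` in `dir`.
#' @export
generate_dataset <- function(n_patients, images_per_patient = 2,
                             split = c(train = 0.5, validation = 0.2, test = 0.3),
                             spec_sampler = NULL, seed = 1L,
                             dir = tempfile("ndci_dataset")) {
  stopifnot(n_patients >= 1, images_per_patient >= 1)
  sizes <- largest_remainder(n_patients, split)
  split_names <- names(split)
  if (is.null(split_names)) split_names <- c("train", "validation", "test")
  if (any(sizes == 0))
    stop("n_patients too small: every split must be non-empty")
  if (is.null(spec_sampler)) {
    spec_sampler <- function(patient_id, biopsy_id) {
      neo <- runif(1) < 0.5
      list(
        spec = phantom_spec(
          fov_radius_px = 48, pixel_pitch = 4,
          nuclear_density = if (neo) 550 else 350,
          abnormal_fraction = if (neo) 0.6 else 0.15),
        label = if (neo) "neoplastic" else "benign")
    }
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  with_seed(seed, {
    assignment <- rep(split_names, times = sizes)[sample.int(n_patients)]
    rows <- list()
    img_counter <- 0L
    for (p in seq_len(n_patients)) {
      pid <- sprintf("P%03d", p)
      n_img <- images_per_patient
      # biopsies of 1-3 images sharing one spec
      biopsy_sizes <- c()
      while (sum(biopsy_sizes) < n_img) {
        biopsy_sizes <- c(biopsy_sizes,
                          min(sample.int(3, 1), n_img - sum(biopsy_sizes)))
      }
      for (b in seq_along(biopsy_sizes)) {
        bid <- sprintf("%s-B%d", pid, b)
        sl <- spec_sampler(pid, bid)
        for (k in seq_len(biopsy_sizes[b])) {
          img_counter <- img_counter + 1L
          sp <- sl$spec
          sp$seed <- seed * 10000L + img_counter
          ph <- generate_phantom(sp)
          ipath <- file.path(dir, sprintf("img%04d.png", img_counter))
          mpath <- sidecar_mask_path(ipath)
          write_hrme(ph$image, ipath)
          write_region_mask(ph$truth$region_mask, mpath)
          rows[[length(rows) + 1L]] <- data.frame(
            image_path = ipath, mask_path = mpath, patient_id = pid,
            biopsy_id = bid, split = assignment[p], label = sl$label)
        }
      }
    }
    manifest <- do.call(rbind, rows)
    write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
    manifest
  })
}
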