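# Independent oracles and shared fixtures for the test suite.

# Clopper-Pearson interval computed by inverting the two binomial tail sums
# with bisection. Deliberately avoids qbeta: the tail probabilities are built
# from log-binomial coefficients so this path is independent of the
# implementation under test.
cp_oracle <- function(k, n, level, tol = 1e-9) {
  alpha <- (1 - level) / 2
  log_pmf <- function(j, p) lchoose(n, j) + j * log(p) + (n - j) * log1p(-p)
  upper_tail <- function(p) sum(exp(log_pmf(k:n, p)))   # P(X >= k)
  lower_tail <- function(p) sum(exp(log_pmf(0:k, p)))   # P(X <= k)
  bisect <- function(f, target, lo, hi) {
    # f assumed increasing in p for upper_tail, decreasing for lower_tail;
    # bisection on f(p) - target with sign handling
    flo <- f(lo) - target
    for (i in 1:200) {
      mid <- (lo + hi) / 2
      fm <- f(mid) - target
      if (sign(fm) == sign(flo)) { lo <- mid; flo <- fm } else hi <- mid
      if (hi - lo < tol) break
    }
    (lo + hi) / 2
  }
  eps <- 1e-12
  p_low <- if (k == 0) 0 else bisect(upper_tail, alpha, eps, 1 - eps)
  p_high <- if (k == n) 1 else bisect(lower_tail, alpha, eps, 1 - eps)
  c(p_low = p_low, p_high = p_high)
}

# closed-form U-Net parameter count derived layer by layer from the stated
# topology; independent of the initializer's bookkeeping
unet_params_closed_form <- function(base, depth, out_channels = 3) {
  cs <- base * 2^(0:(depth - 1))
  group <- function(cin, cout) 9 * cin * cout + 9 * cout^2 + 4 * cout
  total <- 0
  for (i in seq_len(depth))
    total <- total + group(if (i == 1) 1 else cs[i - 1], cs[i])
  for (i in seq_len(depth - 1))
    total <- total + cs[i + 1] * cs[i] * 4 +     # 2x2 transposed conv
      group(2 * cs[i], cs[i])                    # decoder group after concat
  total + cs[1] * out_channels + out_channels    # 1x1 output conv + bias
}

# small phantom used across tests: 128x128 canvas, 2 um/px
tiny_spec <- function(seed = 1L, ...) {
  args <- utils::modifyList(
    list(fov_radius_px = 64, pixel_pitch = 2, nuclear_density = 400,
         abnormal_fraction = 0.3, noise_sd = 0.02, seed = seed),
    list(...))
  do.call(phantom_spec, args)
}

# training set for U-Net runs: phantoms with degraded regions so both
# foreground classes are present
unet_training_phantoms <- function(n = 20, seed = 100L) {
  kinds <- c("saturated", "dim", "keratinized")
  phs <- lapply(seq_len(n), function(i) {
    degs <- ndci:::with_seed(seed + i, {
      lapply(sample(kinds, sample(1:2, 1)), function(k)
        degradation(k, severity = 0.25))
    })
    generate_phantom(phantom_spec(
      fov_radius_px = 64, pixel_pitch = 1.6, nuclear_density = 400,
      abnormal_fraction = 0.3, noise_sd = 0.03, degradations = degs,
      seed = seed + i))
  })
  list(x = lapply(phs, function(p) p$image),
       y = lapply(phs, function(p) p$truth$region_mask))
}

# region mask fixture: dims from a layout matrix of codes
mask_from <- function(m) region_mask(m)
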