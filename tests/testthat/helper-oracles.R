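# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths.

# Binomial-null expected fractions by exhaustive enumeration of all allele
# outcome tuples (2^n states, weighted by their Bernoulli probability).
enum_fractions <- function(p_c, n) {
  states <- as.matrix(expand.grid(rep(list(0:1), n)))
  w <- apply(states, 1, function(s) prod(ifelse(s == 1, p_c, 1 - p_c)))
  k <- rowSums(states)
  vapply(0:n, function(kk) sum(w[k == kk]), numeric(1))
}

# Closed-form probability that an allele's inter-locus distance falls below
# `thr` under the looped/unlooped Rayleigh mixture.
rayleigh_close_prob <- function(p_contact, thr, looped_scale, unlooped_scale) {
  cdf <- function(r, s) 1 - exp(-r^2 / (2 * s^2))
  p_contact * cdf(thr, looped_scale) +
    (1 - p_contact) * cdf(thr, unlooped_scale)
}

# Optimal one-to-one assignment by brute force over permutations
# (instances up to 4x4).
brute_force_matching <- function(xa, ya, xb, yb, max_um) {
  na <- length(xa); nb <- length(xb)
  d <- sqrt(outer(xa, xb, `-`)^2 + outer(ya, yb, `-`)^2)
  k <- min(na, nb)
  best <- list(total = Inf, n = 0L)
  perm_rows <- pracma::perms(seq_len(na))
  for (r in seq_len(nrow(perm_rows))) {
    rows <- perm_rows[r, seq_len(k)]
    cols <- seq_len(k)
    dd <- d[cbind(rows, cols)]
    keep <- dd < max_um
    tot <- sum(dd[keep])
    n <- sum(keep)
    if (n > best$n || (n == best$n && tot < best$total)) {
      best <- list(total = tot, n = n)
    }
  }
  best
}

# Per-cell close-allele counts straight from the generator's truth table
# (bypasses spot pairing).
truth_k_close <- function(truth, thr = 0.27) {
  close <- truth$pair_distance_um < thr
  agg <- stats::aggregate(cbind(k_close = as.integer(close),
                                n_alleles = rep(1L, nrow(truth)))
                          ~ nucleus_id, data = truth, FUN = sum)
  agg$fraction_close <- agg$k_close / agg$n_alleles
  agg
}

# Small rendered field with planted spots on a jittered grid (all
# separations >= min_sep_px), returning ground truth for detector checks.
planted_field <- function(seed, n_spots = 8, size_px = 128, sigma_px = 1.5,
                          noise_sd = 8, amp_range = c(150, 300),
                          min_sep_px = 6 * sigma_px) {
  set.seed(seed)
  psz <- 0.108
  cfg <- synthetic_config(seed = seed, n_cells = 4L, image_size_px = size_px,
                          spot_sigma_px = sigma_px, noise_sd = noise_sd,
                          background_level = 100)
  g <- floor(sqrt(n_spots)) + 1L
  step <- (size_px - 20) / g
  gx <- as.vector(outer(seq_len(g), rep(1, g))) * step + 4
  gy <- as.vector(outer(rep(1, g), seq_len(g))) * step + 4
  pick <- sample(length(gx), n_spots)
  jit <- (step - min_sep_px) / 2.5
  x_px <- gx[pick] + runif(n_spots, -jit, jit)
  y_px <- gy[pick] + runif(n_spots, -jit, jit)
  spots <- data.frame(x_um = (x_px - 0.5) * psz, y_um = (y_px - 0.5) * psz,
                      peak_intensity = runif(n_spots, amp_range[1],
                                             amp_range[2]))
  rendered <- render_fish_image(spots, cfg, noise_seed = seed + 1000L)
  list(truth = spots, image = rendered$image, pixel_size_um = psz,
       sigma_px = sigma_px)
}

# Match detections to planted truth; returns recall, precision and the
# worst centroid error in pixels.
score_detections <- function(det, truth, pixel_size_um, tol_px = 2) {
  if (nrow(det) == 0L) {
    return(list(recall = 0, precision = NA_real_, max_err_px = Inf))
  }
  errs <- vapply(seq_len(nrow(truth)), function(i) {
    min(sqrt((det$x_um - truth$x_um[i])^2 +
             (det$y_um - truth$y_um[i])^2)) / pixel_size_um
  }, numeric(1))
  hits <- sum(errs <= tol_px)
  list(recall = hits / nrow(truth),
       precision = hits / nrow(det),
       max_err_px = max(errs))
}
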