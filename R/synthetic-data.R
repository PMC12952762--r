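#' Generate a synthetic single-allele FISH population
#'
#' Draws a seeded synthetic experiment with the statistical structure the
#' downstream analysis assumes: one nucleus record per cell, two DNA-FISH
#' channels (`dna_a`, `dna_b`) with one spot per allele per channel whose
#' radial separation follows a 2D Rayleigh distribution with the looped or
#' unlooped scale, RNA transcription-site spots within 1 um of the
#' channel-A anchor of active alleles, and a truth table with the latent
#' loop and activity states.
#'
#' Loop states are Bernoulli with condition-dependent baseline probability;
#' `expression_coupling` shifts the per-cell logit by the centred
#' log-expression, and `allele_correlation` mixes a shared per-cell draw
#' with independent per-allele draws. Transcriptional activity is Bernoulli
#' with probability `base_active_prob` for unlooped alleles and odds reduced
#' by `repression_odds_ratio` for looped alleles.
#'
#' Allele anchors sit on a jittered regular polygon at 55-70% of the
#' nucleus radius, so anchors of different alleles are separated by well
#' over the 2 um pairing cap and 2.5 um RNA linkage radius at default
#' nucleus sizes; cross-allele mispairing is excluded by construction.
#'
#' @param config A [synthetic_config()].
#' @return A list with data frames `nuclei`, `spots`, and `truth`.
#'   Coordinates are in um with the image convention (x right, y down,
#'   origin at the field's top-left).
#' @export
generate_population <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed)
  parts <- lapply(seq_along(config$conditions), function(ci) {
    .generate_condition(config, config$conditions[ci], ci)
  })
  nuclei <- do.call(rbind, lapply(parts, `[[`, "nuclei"))
  spots <- do.call(rbind, lapply(parts, `[[`, "spots"))
  truth <- do.call(rbind, lapply(parts, `[[`, "truth"))
  spots$spot_id <- seq_len(nrow(spots))
  rownames(nuclei) <- rownames(spots) <- rownames(truth) <- NULL
  list(nuclei = nuclei, spots = spots, truth = truth)
}

# One light-condition arm; offset keeps nucleus/field ids globally unique.
.generate_condition <- function(cfg, condition, cond_index) {
  n <- cfg$n_cells
  k <- cfg$ploidy
  id_offset <- (cond_index - 1L) * n
  nucleus_id <- id_offset + seq_len(n)

  expression <- stats::rlnorm(n, cfg$expression_mu, cfg$expression_sigma)
  p_base <- if (condition == "light") cfg$p_contact_light else cfg$p_contact_dark
  if (p_base <= 0) {
    p_cell <- rep(0, n)
  } else if (p_base >= 1) {
    p_cell <- rep(1, n)
  } else {
    eta <- stats::qlogis(p_base) +
      cfg$expression_coupling * (log(expression) - cfg$expression_mu)
    p_cell <- stats::plogis(eta)
  }

  # loop states: mixture of a shared per-cell draw and independent draws.
  # Mixing each allele with the shared draw at weight w gives pairwise
  # loop-state correlation w^2, so w = sqrt(allele_correlation) makes the
  # config field the correlation itself.
  z_shared <- stats::rbinom(n, 1L, p_cell)
  cell_of <- rep(seq_len(n), each = k)
  allele_index <- rep(seq_len(k), times = n)
  na <- n * k
  use_shared <- stats::runif(na) < sqrt(cfg$allele_correlation)
  indep <- stats::rbinom(na, 1L, p_cell[cell_of])
  looped <- ifelse(use_shared, z_shared[cell_of], indep)

  # inter-locus separation: 2D Rayleigh with state-dependent scale
  scale_um <- ifelse(looped == 1L, cfg$looped_scale_um, cfg$unlooped_scale_um)
  sep_um <- scale_um * sqrt(-2 * log(stats::runif(na)))
  sep_phi <- stats::runif(na, 0, 2 * pi)

  # transcription: looping divides the odds of being active
  odds_u <- cfg$base_active_prob / (1 - cfg$base_active_prob)
  odds_l <- odds_u / cfg$repression_odds_ratio
  p_active <- ifelse(looped == 1L, odds_l / (1 + odds_l), cfg$base_active_prob)
  active <- stats::rbinom(na, 1L, p_active)

  # nucleus geometry: 4 nuclei per rendered field, one per quadrant
  area <- stats::runif(n, cfg$nucleus_area_range_um2[1],
                       cfg$nucleus_area_range_um2[2])
  radius <- sqrt(area / pi)
  solidity <- stats::runif(n, cfg$solidity_range[1], cfg$solidity_range[2])
  side_um <- cfg$image_size_px * cfg$pixel_size_um
  slot <- (seq_len(n) - 1L) %% 4L
  field_id <- id_offset + (seq_len(n) - 1L) %/% 4L + 1L
  cx <- ifelse(slot %% 2L == 0L, 0.25, 0.75) * side_um
  cy <- ifelse(slot %/% 2L == 0L, 0.25, 0.75) * side_um

  # allele anchors on a jittered regular polygon inside each nucleus
  theta0 <- stats::runif(n, 0, 2 * pi)
  theta <- theta0[cell_of] + 2 * pi * (allele_index - 1L) / k
  rho <- radius[cell_of] * stats::runif(na, cfg$min_allele_radial_frac,
                                        cfg$max_allele_radial_frac)
  ax <- cx[cell_of] + rho * cos(theta)
  ay <- cy[cell_of] + rho * sin(theta)
  bx <- ax + sep_um * cos(sep_phi)
  by <- ay + sep_um * sin(sep_phi)

  # RNA transcription-site spots near active alleles (uniform in 1 um disk)
  act <- which(active == 1L)
  rr <- 1.0 * sqrt(stats::runif(length(act)))
  rang <- stats::runif(length(act), 0, 2 * pi)
  rx <- ax[act] + rr * cos(rang)
  ry <- ay[act] + rr * sin(rang)

  peak_a <- stats::rlnorm(na, log(500), 0.2)
  peak_b <- stats::rlnorm(na, log(500), 0.2)
  peak_r <- stats::rlnorm(length(act), log(300), 0.3)
  gain <- 2 * pi * cfg$spot_sigma_px^2  # integrated/peak for a Gaussian spot

  spots <- data.frame(
    spot_id = NA_integer_,
    nucleus_id = c(nucleus_id[cell_of], nucleus_id[cell_of],
                   nucleus_id[cell_of][act]),
    field_id = c(field_id[cell_of], field_id[cell_of],
                 field_id[cell_of][act]),
    condition = condition,
    channel = c(rep("dna_a", na), rep("dna_b", na),
                rep("rna", length(act))),
    x_um = c(ax, bx, rx),
    y_um = c(ay, by, ry),
    peak_intensity = c(peak_a, peak_b, peak_r),
    integrated_intensity = c(peak_a, peak_b, peak_r) * gain,
    stringsAsFactors = FALSE
  )

  nuclei <- data.frame(
    nucleus_id = nucleus_id, field_id = field_id, condition = condition,
    area_um2 = area, solidity = solidity,
    centroid_x_um = cx, centroid_y_um = cy, radius_um = radius,
    mean_intensity_gfp = expression, mean_intensity_dapi = 1000,
    stringsAsFactors = FALSE
  )

  truth <- data.frame(
    nucleus_id = nucleus_id[cell_of], condition = condition,
    allele_index = allele_index,
    expression = expression[cell_of], p_contact_cell = p_cell[cell_of],
    looped = looped, active = active, pair_distance_um = sep_um,
    stringsAsFactors = FALSE
  )

  list(nuclei = nuclei, spots = spots, truth = truth)
}

#' Simulate a clustering/declustering CV time course
#'
#' Produces a coefficient-of-variation trace of the shape seen after a
#' one-time light activation at t = 0: a linear rise from the baseline to
#' `cv_max` crossing the half-maximal level at `t_c_true`, a peak at
#' `2 * t_c_true`, then a linear decay that re-crosses the same half level
#' at `t_d_true` and settles back at the baseline. Additive Gaussian noise
#' of SD `noise_sd` is applied to every sample.
#'
#' @param t_c_true,t_d_true True half-maximal clustering and declustering
#'   times (s), both measured from activation; requires
#'   `t_d_true > 2 * t_c_true` whenever the trace is non-flat.
#' @param cv_max Peak CV; values at or below `cv_baseline` give a flat
#'   trace.
#' @param frame_interval Sampling interval (s).
#' @param noise_sd Additive noise SD (CV units).
#' @param seed Optional integer seed for the noise.
#' @param cv_baseline Pre-activation CV (default 1, i.e. a relative trace).
#' @param total_time Trace duration (s); defaults to the time the decay
#'   returns to baseline plus four frames.
#' @return A [kinetic_trace()].
#' @export
generate_kinetic_trace <- function(t_c_true, t_d_true, cv_max,
                                   frame_interval = 30, noise_sd = 0,
                                   seed = NULL, cv_baseline = 1,
                                   total_time = NULL) {
  if (t_c_true <= 0 || t_d_true <= 0 || frame_interval <= 0) {
    stop("t_c_true, t_d_true and frame_interval must be positive")
  }
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  flat <- cv_max <= cv_baseline
  if (!flat && t_d_true <= 2 * t_c_true) {
    stop("t_d_true must exceed the peak time 2 * t_c_true")
  }
  if (is.null(total_time)) {
    total_time <- if (flat) 20 * frame_interval else
      2 * (t_d_true - t_c_true) + 4 * frame_interval
  }
  times <- seq(0, total_time, by = frame_interval)
  if (flat) {
    cv <- rep(cv_baseline, length(times))
  } else {
    t_peak <- 2 * t_c_true
    half <- cv_baseline + (cv_max - cv_baseline) / 2
    slope_down <- (cv_max - half) / (t_d_true - t_peak)
    cv <- ifelse(times <= t_peak,
                 cv_baseline + (cv_max - cv_baseline) * times / t_peak,
                 pmax(cv_baseline, cv_max - slope_down * (times - t_peak)))
  }
  if (noise_sd > 0) {
    if (!is.null(seed)) set.seed(seed)
    cv <- cv + stats::rnorm(length(cv), 0, noise_sd)
  }
  kinetic_trace(times, cv)
}

#' Render a synthetic FISH field
#'
#' Draws isotropic Gaussian intensity blobs at the spot centroids over a
#' constant background with optional Gaussian noise, and a matching integer
#' nucleus label mask (disks at the nucleus centroids).
#'
#' @param spots Spot table with `x_um`, `y_um`, `peak_intensity` (a zero-row
#'   table gives a background-only image).
#' @param config A [synthetic_config()] supplying `image_size_px`,
#'   `pixel_size_um`, `spot_sigma_px`, `background_level` and `noise_sd`.
#' @param nuclei Optional nucleus table (`centroid_x_um`, `centroid_y_um`,
#'   `radius_um`, `nucleus_id`) used to build the label mask; without it the
#'   mask is a single full-frame label.
#' @param noise_seed Optional seed for the rendering noise.
#' @return List with `image` (matrix, rows = y), `mask` (integer matrix) and
#'   `labels` (data frame mapping mask label to `nucleus_id`).
#' @export
render_fish_image <- function(spots, config, nuclei = NULL,
                              noise_seed = NULL) {
  stopifnot(inherits(config, "synthetic_config"))
  size <- config$image_size_px
  psz <- config$pixel_size_um
  side_um <- size * psz
  img <- matrix(config$background_level, nrow = size, ncol = size)
  if (nrow(spots) > 0) {
    if (any(spots$x_um < 0 | spots$x_um > side_um |
            spots$y_um < 0 | spots$y_um > side_um)) {
      stop("spot coordinates outside the field")
    }
    sg <- config$spot_sigma_px
    w <- ceiling(4 * sg)
    for (i in seq_len(nrow(spots))) {
      # continuous pixel coordinates: pixel center c sits at (c - 0.5) * psz
      xc <- spots$x_um[i] / psz + 0.5
      yc <- spots$y_um[i] / psz + 0.5
      cols <- max(1L, floor(xc - w)):min(size, ceiling(xc + w))
      rows <- max(1L, floor(yc - w)):min(size, ceiling(yc + w))
      blob <- spots$peak_intensity[i] *
        exp(-(outer((rows - yc)^2, (cols - xc)^2, `+`)) / (2 * sg^2))
      img[rows, cols] <- img[rows, cols] + blob
    }
  }
  if (config$noise_sd > 0) {
    if (!is.null(noise_seed)) set.seed(noise_seed)
    img <- img + matrix(stats::rnorm(size^2, 0, config$noise_sd), size, size)
  }
  mask <- matrix(0L, nrow = size, ncol = size)
  if (is.null(nuclei)) {
    mask[] <- 1L
    labels <- data.frame(label = 1L, nucleus_id = NA_integer_)
  } else {
    xs <- (seq_len(size) - 0.5) * psz
    for (i in seq_len(nrow(nuclei))) {
      r2 <- outer((xs - nuclei$centroid_y_um[i])^2,
                  (xs - nuclei$centroid_x_um[i])^2, `+`)
      mask[r2 <= nuclei$radius_um[i]^2] <- i
    }
    labels <- data.frame(label = seq_len(nrow(nuclei)),
                         nucleus_id = nuclei$nucleus_id)
  }
  list(image = img, mask = mask, labels = labels)
}

#' Build a planted-shift registration fixture
#'
#' Translates an image by an integer pixel offset with edge fill, recording
#' the truth shift. The returned pair satisfies
#' `moving[r, c] == reference[r - dy, c - dx]` inside the frame.
#'
#' @param image Reference image matrix.
#' @param shift_px Integer `c(dy, dx)`; positive dy moves content down,
#'   positive dx right.
#' @param fill Fill value for uncovered edges (default: image median).
#' @return List with `reference`, `moving` and the truth `shift`.
#' @export
make_registration_pair <- function(image, shift_px, fill = NULL) {
  stopifnot(is.matrix(image), length(shift_px) == 2L)
  dy <- as.integer(round(shift_px[1]))
  dx <- as.integer(round(shift_px[2]))
  if (abs(dy) >= nrow(image) || abs(dx) >= ncol(image)) {
    stop("shift exceeds image extent")
  }
  if (is.null(fill)) fill <- stats::median(image)
  moving <- matrix(fill, nrow(image), ncol(image))
  rows <- seq_len(nrow(image))
  cols <- seq_len(ncol(image))
  src_r <- rows - dy
  src_c <- cols - dx
  ok_r <- src_r >= 1L & src_r <= nrow(image)
  ok_c <- src_c >= 1L & src_c <= ncol(image)
  moving[rows[ok_r], cols[ok_c]] <- image[src_r[ok_r], src_c[ok_c]]
  list(reference = image, moving = moving, shift = c(dy = dy, dx = dx))
}
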