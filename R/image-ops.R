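#' Per-nucleus coefficient of variation
#'
#' CV of the pixel intensities inside one labelled nucleus: population
#' standard deviation divided by the mean. Used as a dimensionless proxy for
#' protein clustering; invariant under positive rescaling of intensities.
#'
#' @param image Intensity matrix.
#' @param mask Integer label matrix of the same shape (0 = background).
#' @param label Nucleus label to evaluate.
#' @return Non-negative scalar.
#' @export
compute_cv <- function(image, mask, label) {
  stopifnot(is.matrix(image), all(dim(image) == dim(mask)))
  px <- image[mask == label]
  if (length(px) == 0L) stop("label ", label, " absent from mask")
  m <- mean(px)
  if (!is.finite(m) || m <= .Machine$double.eps * 100) {
    stop("masked mean is zero or near-zero for label ", label)
  }
  sqrt(mean((px - m)^2)) / m
}

#' Normalize a CV trace to its first time point
#'
#' @param trace_values Numeric CV sequence; first value must be positive.
#' @return Sequence of the same length with first element 1.
#' @export
relative_cv <- function(trace_values) {
  stopifnot(length(trace_values) >= 1L)
  if (!is.finite(trace_values[1]) || trace_values[1] <= 0) {
    stop("first CV value must be positive")
  }
  trace_values / trace_values[1]
}

# Discrete Laplacian-of-Gaussian kernel, DC-free so flat background gives a
# zero response.
log_kernel <- function(sigma) {
  rad <- max(2L, ceiling(4 * sigma))
  ax <- -rad:rad
  r2 <- outer(ax^2, ax^2, `+`)
  k <- (r2 - 2 * sigma^2) / sigma^4 * exp(-r2 / (2 * sigma^2)) /
    (2 * pi * sigma^2)
  k - mean(k)
}

#' Detect diffraction-limited spots with a Laplacian-of-Gaussian filter
#'
#' Computes the scale-normalized negative LoG response
#' (`-sigma^2 * (image * LoG)`), finds its local maxima above
#' `min_response`, assigns each detection to the nucleus label at its peak
#' pixel (background detections are discarded when a mask is supplied), and
#' reports an intensity-weighted centroid over the local LoG support. For a
#' rendered Gaussian spot of matched sigma and peak amplitude A over flat
#' background, the response at the center is close to A/2.
#'
#' @param image Intensity matrix.
#' @param mask Optional integer label matrix; detections outside any label
#'   are dropped.
#' @param sigma_px Spot scale in pixels (single scale; FISH spots are
#'   near-constant size).
#' @param min_response Response threshold (a.u., about half the faintest
#'   spot amplitude to keep).
#' @param pixel_size_um Pixel size used to report centroids in um.
#' @return Data frame with one row per detection: `x_um`, `y_um`, `row`,
#'   `col`, `nucleus_label`, `response`, `peak_intensity`,
#'   `integrated_intensity`. Zero rows when nothing is found.
#' @export
detect_spots <- function(image, mask = NULL, sigma_px = 1.5,
                         min_response = 10, pixel_size_um = 0.108) {
  stopifnot(is.matrix(image), sigma_px > 0)
  kern <- log_kernel(sigma_px)
  resp <- EBImage::filter2(image, -sigma_px^2 * kern, boundary = "replicate")
  resp <- matrix(as.numeric(resp), nrow(image), ncol(image))

  nmax <- resp
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0L && dc == 0L) next
    nmax <- pmax(nmax, shift_matrix(resp, dr, dc, fill = -Inf))
  }
  cand <- which(resp >= nmax & resp > min_response, arr.ind = TRUE)
  empty <- data.frame(x_um = numeric(0), y_um = numeric(0),
                      row = integer(0), col = integer(0),
                      nucleus_label = integer(0), response = numeric(0),
                      peak_intensity = numeric(0),
                      integrated_intensity = numeric(0))
  if (nrow(cand) == 0L) return(empty)

  # greedy non-maximum suppression of plateau duplicates
  ord <- order(resp[cand], decreasing = TRUE)
  cand <- cand[ord, , drop = FALSE]
  min_sep2 <- max(2, sigma_px)^2
  keep <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    kept <- which(keep)
    if (length(kept) == 0L ||
        all((cand[kept, 1] - cand[i, 1])^2 +
            (cand[kept, 2] - cand[i, 2])^2 > min_sep2)) {
      keep[i] <- TRUE
    }
  }
  cand <- cand[keep, , drop = FALSE]

  w <- ceiling(2 * sigma_px)
  out <- lapply(seq_len(nrow(cand)), function(i) {
    r0 <- cand[i, 1]; c0 <- cand[i, 2]
    lab <- if (is.null(mask)) NA_integer_ else mask[r0, c0]
    if (!is.null(mask) && lab == 0L) return(NULL)
    rows <- max(1L, r0 - w):min(nrow(image), r0 + w)
    cols <- max(1L, c0 - w):min(ncol(image), c0 + w)
    sub <- image[rows, cols, drop = FALSE]
    wgt <- sub - min(sub)
    tot <- sum(wgt)
    if (tot <= 0) {
      cy <- r0; cx <- c0
    } else {
      cy <- sum(rows * rowSums(wgt)) / tot
      cx <- sum(cols * colSums(wgt)) / tot
    }
    data.frame(x_um = (cx - 0.5) * pixel_size_um,
               y_um = (cy - 0.5) * pixel_size_um,
               row = r0, col = c0,
               nucleus_label = lab, response = resp[r0, c0],
               peak_intensity = image[r0, c0],
               integrated_intensity = tot)
  })
  out <- do.call(rbind, out)
  if (is.null(out)) empty else out
}

shift_matrix <- function(m, dr, dc, fill = 0) {
  out <- matrix(fill, nrow(m), ncol(m))
  rs <- seq_len(nrow(m)) - dr
  cs <- seq_len(ncol(m)) - dc
  okr <- rs >= 1L & rs <= nrow(m)
  okc <- cs >= 1L & cs <= ncol(m)
  out[which(okr), which(okc)] <- m[rs[okr], cs[okc]]
  out
}

#' Translation registration by Fourier phase correlation
#'
#' Estimates the integer-pixel translation between two equally shaped
#' images from the peak of the inverse-transformed normalized cross-power
#' spectrum. The returned shift satisfies
#' `moving[r, c] ~ reference[r - dy, c - dx]`, matching
#' [make_registration_pair()]. The normalized peak height (1 for a perfect
#' cyclic shift, near 0 for unrelated images) gates the `ok` flag.
#'
#' @param reference,moving Image matrices of identical shape.
#' @param min_peak Minimum peak score to accept the shift (default 0.03,
#'   conservatively above the unrelated-noise peak distribution).
#' @return List with `shift` (integer `c(dy, dx)`), `peak_score` and `ok`.
#' @export
register_translation <- function(reference, moving, min_peak = 0.03) {
  if (!all(dim(reference) == dim(moving))) stop("image shapes differ")
  f_ref <- stats::fft(reference - mean(reference))
  f_mov <- stats::fft(moving - mean(moving))
  cp <- Conj(f_ref) * f_mov
  cp <- cp / pmax(Mod(cp), .Machine$double.eps)
  r <- Re(stats::fft(cp, inverse = TRUE)) / length(cp)
  idx <- arrayInd(which.max(r), dim(r))
  peak <- max(r)
  wrap <- function(i, n) { s <- i - 1L; if (s > n %/% 2L) s - n else s }
  shift <- c(dy = wrap(idx[1], nrow(r)), dx = wrap(idx[2], ncol(r)))
  list(shift = shift, peak_score = peak, ok = peak >= min_peak)
}

#' Mean intensity in a circular ROI
#'
#' Averages the pixels whose centers lie within `radius_um` of a point, with
#' the disk clipped at the image borders. At the default 0.108 um pixel
#' size a 1.08 um radius covers a 10-pixel-radius disk.
#'
#' @param image Intensity matrix.
#' @param center_um `c(x, y)` in um.
#' @param radius_um Disk radius in um (> 0).
#' @param pixel_size_um Pixel size (um/px).
#' @return List with `mean` and the pixel count `n_px`.
#' @export
roi_mean <- function(image, center_um, radius_um, pixel_size_um = 0.108) {
  stopifnot(radius_um > 0, length(center_um) == 2L)
  rad_px <- radius_um / pixel_size_um
  xc <- center_um[1] / pixel_size_um + 0.5
  yc <- center_um[2] / pixel_size_um + 0.5
  rows <- max(1L, floor(yc - rad_px)):min(nrow(image), ceiling(yc + rad_px))
  cols <- max(1L, floor(xc - rad_px)):min(ncol(image), ceiling(xc + rad_px))
  if (length(rows) == 0L || length(cols) == 0L || rows[1] > rows[length(rows)]) {
    stop("ROI entirely outside the image")
  }
  d2 <- outer((rows - yc)^2, (cols - xc)^2, `+`)
  inside <- d2 <= rad_px^2
  n_px <- sum(inside)
  if (n_px == 0L) stop("ROI entirely outside the image")
  list(mean = mean(image[rows, cols][inside]), n_px = n_px)
}

#' Per-nucleus region features for quality control
#'
#' Computes, for every label in a mask, the area (pixel count times squared
#' pixel size), the solidity (region pixels divided by the pixels of the
#' filled convex hull of the region's pixel centers), the binary centroid in
#' um, and the mean intensity in each supplied channel image.
#'
#' @param mask Integer label matrix (0 = background).
#' @param images Named list of intensity matrices (may be empty).
#' @param pixel_size_um Pixel size (um/px).
#' @return Data frame with columns `label`, `n_px`, `area_um2`, `solidity`,
#'   `centroid_x_um`, `centroid_y_um` and one `mean_intensity_<name>` per
#'   channel.
#' @export
region_features <- function(mask, images = list(), pixel_size_um = 0.108) {
  labs <- sort(unique(mask[mask > 0L]))
  if (length(labs) == 0L) stop("mask contains no labels")
  rows <- lapply(labs, function(lab) {
    idx <- which(mask == lab, arr.ind = TRUE)
    n_px <- nrow(idx)
    cx <- mean(idx[, 2]); cy <- mean(idx[, 1])
    solidity <- 1
    if (n_px >= 3L) {
      hull <- grDevices::chull(idx[, 2], idx[, 1])
      if (length(hull) >= 3L) {
        hx <- idx[hull, 2]; hy <- idx[hull, 1]
        # bounding-box candidates tested against the hull polygon
        cr <- range(idx[, 2]); rr <- range(idx[, 1])
        grid <- expand.grid(col = cr[1]:cr[2], row = rr[1]:rr[2])
        inhull <- pracma::inpolygon(grid$col, grid$row, hx, hy,
                                    boundary = TRUE)
        hull_px <- sum(inhull)
        solidity <- min(1, n_px / hull_px)
      }
    }
    feat <- data.frame(label = lab, n_px = n_px,
                       area_um2 = n_px * pixel_size_um^2,
                       solidity = solidity,
                       centroid_x_um = (cx - 0.5) * pixel_size_um,
                       centroid_y_um = (cy - 0.5) * pixel_size_um)
    for (ch in names(images)) {
      feat[[paste0("mean_intensity_", ch)]] <- mean(images[[ch]][mask == lab])
    }
    feat
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
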