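#' Link RNA transcription-site spots to DNA alleles
#'
#' Assigns RNA-FISH spots to DNA allele anchors (the channel-A spot of each
#' pair) by greedy one-to-one matching on ascending distance within each
#' nucleus, capped at `rna_link_um`. An allele with an assigned RNA spot is
#' called active; alleles without one are inactive. One-to-one assignment
#' prevents a single transcription site from activating two alleles;
#' `allow_reuse = TRUE` switches to plain nearest-RNA-within-threshold
#' calls.
#'
#' RNA and DNA tables must already be in the same coordinate frame
#' (apply [register_translation()] upstream for sequentially imaged
#' RNA/DNA-FISH fields).
#'
#' @param pairs Allele pair table from [pair_alleles()] (anchor `x_um`,
#'   `y_um` per allele).
#' @param rna_spots Spot table restricted to the RNA channel (`spot_id`,
#'   `nucleus_id`, `x_um`, `y_um`).
#' @param thresholds An [analysis_thresholds()].
#' @param allow_reuse Let one RNA spot activate several alleles.
#' @return `pairs` with added columns `active`, `rna_spot_id`,
#'   `rna_dna_distance_um`.
#' @export
link_rna_to_alleles <- function(pairs, rna_spots, thresholds,
                                allow_reuse = FALSE) {
  stopifnot(inherits(thresholds, "analysis_thresholds"))
  out <- pairs
  out$active <- FALSE
  out$rna_spot_id <- NA_integer_
  out$rna_dna_distance_um <- NA_real_
  if (nrow(pairs) == 0L || nrow(rna_spots) == 0L) return(out)
  nuc_ids <- unique(pairs$nucleus_id)
  ip_by_nuc <- split(seq_len(nrow(pairs)),
                     factor(pairs$nucleus_id, levels = nuc_ids))
  ir_by_nuc <- split(seq_len(nrow(rna_spots)),
                     factor(rna_spots$nucleus_id, levels = nuc_ids))
  for (i in seq_along(nuc_ids)) {
    ip <- ip_by_nuc[[i]]; ir <- ir_by_nuc[[i]]
    if (length(ir) == 0L) next
    d <- sqrt(outer(pairs$x_um[ip], rna_spots$x_um[ir], `-`)^2 +
              outer(pairs$y_um[ip], rna_spots$y_um[ir], `-`)^2)
    if (allow_reuse) {
      j <- apply(d, 1L, which.min)
      dm <- d[cbind(seq_along(ip), j)]
      hit <- dm < thresholds$rna_link_um
      out$active[ip[hit]] <- TRUE
      out$rna_spot_id[ip[hit]] <- rna_spots$spot_id[ir[j[hit]]]
      out$rna_dna_distance_um[ip[hit]] <- dm[hit]
    } else {
      ia <- rep(seq_along(ip), times = length(ir))
      ib <- rep(seq_along(ir), each = length(ip))
      ord <- order(d, pairs$allele_index[ip][ia],
                   rna_spots$spot_id[ir][ib])
      used_p <- logical(length(ip)); used_r <- logical(length(ir))
      for (o in ord) {
        if (d[o] >= thresholds$rna_link_um) break
        pi_ <- ia[o]; ri <- ib[o]
        if (used_p[pi_] || used_r[ri]) next
        used_p[pi_] <- TRUE; used_r[ri] <- TRUE
        row <- ip[pi_]
        out$active[row] <- TRUE
        out$rna_spot_id[row] <- rna_spots$spot_id[ir[ri]]
        out$rna_dna_distance_um[row] <- d[o]
        if (all(used_p) || all(used_r)) break
      }
    }
  }
  out
}

#' Per-cell RNA transcription-site summaries
#'
#' Counts the RNA spots per nucleus and sums their integrated intensities.
#' When a nucleus table is supplied, cells without RNA spots appear with
#' count 0; otherwise only nuclei with spots are reported. Intensities can
#' be normalized to the mean of a stated reference group of cells.
#'
#' @param rna_spots RNA spot table with `nucleus_id` and
#'   `integrated_intensity`.
#' @param nuclei Optional nucleus table supplying the full set of
#'   `nucleus_id`s (and carried-through columns such as `condition`).
#' @param reference Optional logical vector over the output rows (or a
#'   function of the output data frame returning one) marking the
#'   normalization reference group.
#' @return Data frame with `nucleus_id`, `rna_count`, `rna_total_intensity`
#'   and, when a reference is given, `rna_total_intensity_norm`.
#' @export
cell_rna_summary <- function(rna_spots, nuclei = NULL, reference = NULL) {
  if (nrow(rna_spots) > 0L) {
    agg <- stats::aggregate(
      cbind(rna_count = rep(1L, nrow(rna_spots)),
            rna_total_intensity = rna_spots$integrated_intensity)
      ~ nucleus_id, data = rna_spots, FUN = sum)
  } else {
    agg <- data.frame(nucleus_id = integer(0), rna_count = integer(0),
                      rna_total_intensity = numeric(0))
  }
  if (!is.null(nuclei)) {
    out <- merge(nuclei, agg, by = "nucleus_id", all.x = TRUE, sort = TRUE)
    out$rna_count[is.na(out$rna_count)] <- 0L
    out$rna_total_intensity[is.na(out$rna_total_intensity)] <- 0
  } else {
    out <- agg
  }
  if (!is.null(reference)) {
    ref <- if (is.function(reference)) reference(out) else reference
    stopifnot(is.logical(ref), length(ref) == nrow(out))
    ref_mean <- mean(out$rna_total_intensity[ref])
    if (!is.finite(ref_mean) || ref_mean <= 0) {
      stop("reference group mean intensity is zero or undefined")
    }
    out$rna_total_intensity_norm <- out$rna_total_intensity / ref_mean
  }
  out
}

#' Equal-count binning of cells
#'
#' Bins cells on a chosen variable at quantile edges so bins hold similar
#' numbers of cells; tied values are never split across bins (which can
#' merge bins, flagged via `n_bins_effective`). Per bin it reports the cell
#' count, mean RNA site count, mean total (optionally normalized) RNA
#' intensity, and the pooled fraction of close alleles.
#'
#' @param cells Per-cell table carrying the bin variable and, when present,
#'   `rna_count`, `rna_total_intensity`(`_norm`), `k_close`, `n_alleles`.
#' @param variable Column to bin on (e.g. `"fraction_close"` or
#'   `"mean_intensity_gfp"`).
#' @param n_bins Requested number of bins (>= 2).
#' @return List with `summary` (one row per bin), `edges`, `assignment`
#'   (bin index per cell), `n_bins_effective`, `merged`.
#' @export
bin_cells <- function(cells, variable, n_bins = 4L) {
  stopifnot(variable %in% names(cells), n_bins >= 2L)
  x <- cells[[variable]]
  stopifnot(all(is.finite(x)))
  # rank-based equal-count assignment; tied values share a max-rank and so
  # always land in the same bin
  raw <- ceiling(rank(x, ties.method = "max") * n_bins / length(x))
  occupied <- sort(unique(raw))
  assignment <- match(raw, occupied)
  merged <- length(occupied) < n_bins
  groups <- split(seq_len(nrow(cells)), assignment)
  edges <- vapply(groups, function(idx) max(x[idx]), numeric(1))
  summary <- do.call(rbind, lapply(seq_along(groups), function(g) {
    idx <- groups[[g]]
    row <- data.frame(bin = g,
                      upper_edge = edges[g],
                      n_cells = length(idx),
                      mean_bin_variable = mean(x[idx]))
    if ("rna_count" %in% names(cells)) {
      row$mean_rna_count <- mean(cells$rna_count[idx])
    }
    if ("rna_total_intensity" %in% names(cells)) {
      row$mean_rna_total_intensity <- mean(cells$rna_total_intensity[idx])
    }
    if ("rna_total_intensity_norm" %in% names(cells)) {
      row$mean_rna_total_intensity_norm <-
        mean(cells$rna_total_intensity_norm[idx])
    }
    if (all(c("k_close", "n_alleles") %in% names(cells))) {
      row$pooled_fraction_close <-
        sum(cells$k_close[idx]) / sum(cells$n_alleles[idx])
    }
    row
  }))
  rownames(summary) <- NULL
  list(summary = summary, edges = edges, assignment = assignment,
       n_bins_effective = length(groups), merged = merged)
}

#' Proximal fractions of active versus inactive alleles
#'
#' @param activity Allele table from [link_rna_to_alleles()] (columns
#'   `active`, `proximal`).
#' @return List with per-class counts and proximal fractions, their
#'   difference and ratio (inactive / active), and `ok`/`note` flags when a
#'   class is empty.
#' @export
activity_by_proximity <- function(activity) {
  stopifnot(all(c("active", "proximal") %in% names(activity)))
  act <- activity$proximal[activity$active]
  ina <- activity$proximal[!activity$active]
  ok <- length(act) > 0L && length(ina) > 0L
  f_act <- if (length(act) > 0L) mean(act) else NA_real_
  f_ina <- if (length(ina) > 0L) mean(ina) else NA_real_
  list(n_active = length(act), n_inactive = length(ina),
       fraction_proximal_active = f_act,
       fraction_proximal_inactive = f_ina,
       difference = f_ina - f_act,
       ratio = if (ok && f_act > 0) f_ina / f_act else NA_real_,
       ok = ok,
       note = if (ok) NA_character_ else "empty activity class")
}

#' Reporter intensity at each allele and its association with activity
#'
#' Reads the mean reporter (e.g. GFP) intensity in a circular ROI centered
#' on each allele anchor — a proxy for effector recruitment at the locus —
#' and tests whether recruitment differs between active and inactive
#' alleles with a two-sample Welch t-test. The expected control outcome on
#' well-behaved data is a null association.
#'
#' @param activity Allele table with anchor `x_um`, `y_um` and `active`.
#' @param reporter_image Registered reporter intensity matrix.
#' @param thresholds An [analysis_thresholds()] (supplies `roi_radius_um`).
#' @param pixel_size_um Pixel size of the reporter image.
#' @return List with `alleles` (activity table plus `gfp_at_locus`),
#'   `t`, `p_value`, `mean_active`, `mean_inactive`, `significant`,
#'   `ok`, `note`.
#' @export
gfp_control_at_locus <- function(activity, reporter_image, thresholds,
                                 pixel_size_um = 0.108) {
  stopifnot(inherits(thresholds, "analysis_thresholds"))
  gfp <- vapply(seq_len(nrow(activity)), function(i) {
    roi_mean(reporter_image,
             c(activity$x_um[i], activity$y_um[i]),
             thresholds$roi_radius_um, pixel_size_um)$mean
  }, numeric(1))
  out <- activity
  out$gfp_at_locus <- gfp
  ga <- gfp[out$active]; gi <- gfp[!out$active]
  res <- list(alleles = out, t = NA_real_, p_value = NA_real_,
              mean_active = mean(ga), mean_inactive = mean(gi),
              significant = FALSE, ok = FALSE, note = NA_character_)
  if (length(ga) < 2L || length(gi) < 2L) {
    res$note <- "a transcription class has fewer than 2 alleles"
    return(res)
  }
  ht <- tryCatch(stats::t.test(ga, gi), error = function(e) e)
  if (inherits(ht, "error")) {
    res$note <- conditionMessage(ht)  # e.g. constant data on a flat image
    return(res)
  }
  res$t <- unname(ht$statistic)
  res$p_value <- ht$p.value
  res$significant <- ht$p.value < 0.05
  res$ok <- TRUE
  res
}
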