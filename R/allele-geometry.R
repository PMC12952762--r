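#' Analysis thresholds for the FISH pipeline
#'
#' Defaults follow the study conventions: nuclei below the minimum area
#' (50 um^2 for HeLa, 90 um^2 for U2OS) or with solidity below 0.9 are
#' discarded; cross-channel spot pairs further apart than 2 um are not
#' alleles; alleles closer than 0.27 um are proximal (looped); an RNA
#' transcription site within 2.5 um of the channel-A DNA signal marks an
#' active allele; reporter recruitment is read in a 1.08 um-radius ROI.
#'
#' @param min_area_um2 Minimum nucleus area (um^2).
#' @param min_solidity Minimum nucleus solidity.
#' @param pairing_max_um Maximum cross-channel distance for an allele pair.
#' @param proximity_um Proximity (looping) threshold, strict `<`.
#' @param rna_link_um RNA-to-DNA activity linkage radius.
#' @param roi_radius_um Radius of the reporter ROI at each allele.
#' @param ploidy Expected spots per DNA channel per cell (2 for a diploid
#'   U2OS locus pair, 3 for triploid HeLa, 4 for tetraploid U2OS).
#' @return Object of class `analysis_thresholds`.
#' @export
analysis_thresholds <- function(min_area_um2 = 90, min_solidity = 0.9,
                                pairing_max_um = 2.0, proximity_um = 0.27,
                                rna_link_um = 2.5, roi_radius_um = 1.08,
                                ploidy = 2L) {
  th <- list(min_area_um2 = min_area_um2, min_solidity = min_solidity,
             pairing_max_um = pairing_max_um, proximity_um = proximity_um,
             rna_link_um = rna_link_um, roi_radius_um = roi_radius_um,
             ploidy = as.integer(ploidy))
  if (any(unlist(th) <= 0)) stop("all thresholds must be positive")
  if (!(th$proximity_um < th$pairing_max_um)) {
    stop("proximity_um must be below pairing_max_um")
  }
  if (!th$ploidy %in% 2:4) stop("ploidy must be 2, 3 or 4")
  structure(th, class = "analysis_thresholds")
}

#' Quality-control filtering of nucleus and spot tables
#'
#' Removes nuclei that are too small, insufficiently solid, or whose DNA
#' spot count in either channel differs from the expected ploidy, and drops
#' the spots of removed nuclei. Removal counts per rule (applied to the full
#' input, so one nucleus can fail several rules) are reported.
#'
#' @param nuclei Nucleus table with `nucleus_id`, `area_um2`, `solidity`.
#' @param spots Spot table with `nucleus_id`, `channel`.
#' @param thresholds An [analysis_thresholds()].
#' @param dna_channels The two DNA channel labels, must exist in `spots`.
#' @return List with filtered `nuclei`, `spots`, and a `report` data frame.
#' @export
qc_filter <- function(nuclei, spots, thresholds,
                      dna_channels = c("dna_a", "dna_b")) {
  stopifnot(inherits(thresholds, "analysis_thresholds"),
            length(dna_channels) == 2L)
  missing_ch <- setdiff(dna_channels, unique(spots$channel))
  if (length(missing_ch) > 0L) {
    stop("unknown DNA channel label(s): ", paste(missing_ch, collapse = ", "))
  }
  fail_area <- nuclei$area_um2 < thresholds$min_area_um2
  fail_solidity <- nuclei$solidity < thresholds$min_solidity

  count_ch <- function(ch) {
    tab <- table(spots$nucleus_id[spots$channel == ch])
    cnt <- as.integer(tab[as.character(nuclei$nucleus_id)])
    ifelse(is.na(cnt), 0L, cnt)
  }
  n_a <- count_ch(dna_channels[1])
  n_b <- count_ch(dna_channels[2])
  fail_ploidy <- n_a != thresholds$ploidy | n_b != thresholds$ploidy

  keep <- !(fail_area | fail_solidity | fail_ploidy)
  report <- data.frame(
    rule = c("area", "solidity", "spot_count_ploidy", "total_removed",
             "retained"),
    n = c(sum(fail_area), sum(fail_solidity), sum(fail_ploidy),
          sum(!keep), sum(keep))
  )
  kept_ids <- nuclei$nucleus_id[keep]
  list(nuclei = nuclei[keep, , drop = FALSE],
       spots = spots[spots$nucleus_id %in% kept_ids, , drop = FALSE],
       report = report)
}

# Greedy one-to-one matching on ascending cross-channel distance for one
# nucleus. xa/ya etc. are coordinate vectors; ids break exact-distance ties
# lexicographically for determinism.
.greedy_pairs <- function(xa, ya, ida, xb, yb, idb, max_um) {
  na <- length(xa); nb <- length(xb)
  if (na == 0L || nb == 0L) {
    return(matrix(numeric(0), ncol = 5L,
                  dimnames = list(NULL, c("ia", "ib", "d", "ida", "idb"))))
  }
  d <- sqrt(outer(xa, xb, `-`)^2 + outer(ya, yb, `-`)^2)
  ia <- rep(seq_len(na), times = nb)
  ib <- rep(seq_len(nb), each = na)
  ord <- order(d, ida[ia], idb[ib])
  used_a <- logical(na); used_b <- logical(nb)
  out <- matrix(numeric(0), ncol = 5L)
  for (o in ord) {
    if (d[o] >= max_um) break
    i <- ia[o]; j <- ib[o]
    if (used_a[i] || used_b[j]) next
    used_a[i] <- TRUE; used_b[j] <- TRUE
    out <- rbind(out, c(i, j, d[o], ida[i], idb[j]))
    if (all(used_a) || all(used_b)) break
  }
  colnames(out) <- c("ia", "ib", "d", "ida", "idb")
  out
}

#' Pair cross-channel DNA-FISH spots into single alleles
#'
#' Computes all cross-channel distances within each nucleus and greedily
#' matches spots one-to-one on the ascending distance list; pairs at or
#' beyond `pairing_max_um` are discarded and left unpaired. Each pair
#' carries the channel-A (anchor) coordinates used downstream for RNA
#' linkage and reporter ROIs, and a strict-inequality proximity call at
#' `proximity_um`.
#'
#' @param spots Spot table (`spot_id`, `nucleus_id`, `channel`, `x_um`,
#'   `y_um`), typically QC-filtered.
#' @param thresholds An [analysis_thresholds()].
#' @param dna_channels Channel labels, anchor first.
#' @return List with `pairs` (one row per allele: `nucleus_id`,
#'   `allele_index`, `spot_id_a`, `spot_id_b`, anchor `x_um`/`y_um`,
#'   `distance_um`, `proximal`) and `unpaired` (spot ids left unmatched).
#' @export
pair_alleles <- function(spots, thresholds,
                         dna_channels = c("dna_a", "dna_b")) {
  stopifnot(inherits(thresholds, "analysis_thresholds"))
  a <- spots[spots$channel == dna_channels[1], , drop = FALSE]
  b <- spots[spots$channel == dna_channels[2], , drop = FALSE]
  nuc_ids <- sort(unique(c(a$nucleus_id, b$nucleus_id)))
  ia_by_nuc <- split(seq_len(nrow(a)), factor(a$nucleus_id, levels = nuc_ids))
  ib_by_nuc <- split(seq_len(nrow(b)), factor(b$nucleus_id, levels = nuc_ids))

  pair_list <- vector("list", length(nuc_ids))
  unpaired_list <- vector("list", length(nuc_ids))
  for (i in seq_along(nuc_ids)) {
    sa <- ia_by_nuc[[i]]; sb <- ib_by_nuc[[i]]
    m <- .greedy_pairs(a$x_um[sa], a$y_um[sa], a$spot_id[sa],
                       b$x_um[sb], b$y_um[sb], b$spot_id[sb],
                       thresholds$pairing_max_um)
    if (nrow(m) > 0L) {
      ra <- sa[m[, "ia"]]
      pair_list[[i]] <- cbind(nucleus_id = nuc_ids[i],
                              allele_index = seq_len(nrow(m)),
                              spot_id_a = m[, "ida"], spot_id_b = m[, "idb"],
                              x_um = a$x_um[ra], y_um = a$y_um[ra],
                              distance_um = m[, "d"])
    }
    up <- setdiff(c(a$spot_id[sa], b$spot_id[sb]), c(m[, "ida"], m[, "idb"]))
    if (length(up) > 0L) unpaired_list[[i]] <- up
  }
  unpaired <- unlist(unpaired_list)
  if (is.null(unpaired)) unpaired <- integer(0)
  mat <- do.call(rbind, pair_list)
  if (is.null(mat)) {
    pairs <- data.frame(nucleus_id = integer(0), allele_index = integer(0),
                        spot_id_a = integer(0), spot_id_b = integer(0),
                        x_um = numeric(0), y_um = numeric(0),
                        distance_um = numeric(0))
  } else {
    pairs <- as.data.frame(mat)
    pairs$nucleus_id <- as.integer(pairs$nucleus_id)
    pairs$allele_index <- as.integer(pairs$allele_index)
  }
  pairs$proximal <- classify_proximal(pairs$distance_um, thresholds)
  rownames(pairs) <- NULL
  list(pairs = pairs, unpaired = unpaired)
}

#' Proximity call for paired alleles
#'
#' Strict inequality: a pair exactly at the threshold is not proximal.
#'
#' @param distance_um Pair distances (um).
#' @param thresholds An [analysis_thresholds()].
#' @return Logical vector.
#' @export
classify_proximal <- function(distance_um, thresholds) {
  distance_um < thresholds$proximity_um
}

#' Per-cell loop summaries
#'
#' Tallies, per nucleus, the number of paired alleles, the number of
#' proximal ones, and their fraction. When a nucleus lost pairs to the
#' pairing cap, the denominator is the realized pair count by default;
#' `denominator = "ploidy"` divides by the expected allele number instead.
#'
#' @param pairs Pair table from [pair_alleles()].
#' @param nuclei Optional nucleus table; condition columns (`condition`,
#'   `field_id`, ...) are joined onto the output.
#' @param thresholds Required for `denominator = "ploidy"`.
#' @param denominator `"pairs"` (realized) or `"ploidy"` (expected).
#' @return Data frame with `nucleus_id`, `n_alleles`, `k_close`,
#'   `fraction_close`.
#' @export
summarize_cells <- function(pairs, nuclei = NULL, thresholds = NULL,
                            denominator = c("pairs", "ploidy")) {
  denominator <- match.arg(denominator)
  agg <- stats::aggregate(cbind(n_alleles = rep(1L, nrow(pairs)),
                                k_close = as.integer(pairs$proximal))
                          ~ nucleus_id, data = pairs, FUN = sum)
  if (denominator == "ploidy") {
    stopifnot(inherits(thresholds, "analysis_thresholds"))
    agg$n_alleles <- thresholds$ploidy
  }
  agg$fraction_close <- agg$k_close / agg$n_alleles
  if (!is.null(nuclei)) {
    extra <- setdiff(names(nuclei), names(agg))
    agg <- merge(agg, nuclei[, c("nucleus_id", extra), drop = FALSE],
                 by = "nucleus_id", sort = TRUE)
  }
  agg
}

#' Pooled condition-level summaries of allele distances
#'
#' @param pairs Pair table with a grouping column joined on (see `by`).
#' @param by Name of the grouping column in `pairs`.
#' @return One row per group: allele count, proximal count, pooled proximal
#'   fraction, and the median pair distance.
#' @export
summarize_condition <- function(pairs, by = "condition") {
  stopifnot(by %in% names(pairs))
  groups <- split(pairs, pairs[[by]])
  out <- do.call(rbind, lapply(names(groups), function(g) {
    p <- groups[[g]]
    data.frame(group = g, n_alleles = nrow(p), n_proximal = sum(p$proximal),
               fraction_proximal = mean(p$proximal),
               median_distance_um = stats::median(p$distance_um))
  }))
  names(out)[1] <- by
  rownames(out) <- NULL
  out
}
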