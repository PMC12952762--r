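th <- analysis_thresholds()

simple_pairs <- function(x, y, nucleus_id = 1L) {
  n <- length(x)
  data.frame(nucleus_id = nucleus_id, allele_index = seq_len(n),
             spot_id_a = seq_len(n), spot_id_b = seq_len(n) + 100L,
             x_um = x, y_um = y, distance_um = 0.2,
             proximal = TRUE)
}

rna_at <- function(x, y, nucleus_id = 1L, intensity = 1000) {
  data.frame(spot_id = seq_along(x) + 500L, nucleus_id = nucleus_id,
             channel = "rna", x_um = x, y_um = y,
             peak_intensity = 100, integrated_intensity = intensity)
}

test_that("RNA spots activate alleles within the 2.5 um linkage radius", {
  pairs <- simple_pairs(c(0, 10), c(0, 0))
  near <- link_rna_to_alleles(pairs, rna_at(1.0, 0), th)
  expect_equal(near$active, c(TRUE, FALSE))
  expect_equal(near$rna_dna_distance_um[1], 1.0)

  far <- link_rna_to_alleles(pairs, rna_at(0, 3.0), th)
  expect_false(any(far$active))

  # one RNA spot between two alleles activates only the nearer one
  between <- link_rna_to_alleles(simple_pairs(c(0, 3), c(0, 0)),
                                 rna_at(1.0, 0), th)
  expect_equal(between$active, c(TRUE, FALSE))
})

test_that("RNA-to-allele assignment is one-to-one", {
  cfg <- synthetic_config(seed = 151, n_cells = 600, conditions = "light")
  pop <- generate_population(cfg)
  qc <- qc_filter(pop$nuclei, pop$spots, th)
  pairs <- pair_alleles(qc$spots, th)$pairs
  rna <- qc$spots[qc$spots$channel == "rna", ]
  act <- link_rna_to_alleles(pairs, rna, th)
  assigned <- act$rna_spot_id[act$active]
  expect_equal(anyDuplicated(assigned), 0L)
  expect_true(all(!is.na(assigned)))
  expect_true(all(act$rna_dna_distance_um[act$active] < th$rna_link_um))
})

test_that("per-cell RNA summaries count and sum and normalize", {
  rna <- rbind(rna_at(c(0, 1), c(0, 0), nucleus_id = 1L,
                      intensity = c(10, 30)),
               rna_at(2, 2, nucleus_id = 3L, intensity = 20))
  rna$spot_id <- 1:3
  nuclei <- data.frame(nucleus_id = 1:3)
  s <- cell_rna_summary(rna, nuclei)
  expect_equal(s$rna_count, c(2L, 0L, 1L))
  expect_equal(s$rna_total_intensity, c(40, 0, 20))

  # normalization: reference group mean 40 -> cell with 20 reads 0.5
  s2 <- cell_rna_summary(rna, nuclei, reference = c(TRUE, FALSE, FALSE))
  expect_equal(s2$rna_total_intensity_norm, c(1, 0, 0.5))
  expect_error(cell_rna_summary(rna, nuclei,
                                reference = c(FALSE, TRUE, FALSE)),
               "reference group")
})

test_that("equal-count binning keeps ties together", {
  b <- bin_cells(data.frame(fraction_close = 1:9), "fraction_close", 3)
  expect_equal(b$summary$n_cells, c(3L, 3L, 3L))
  expect_false(b$merged)

  tied <- data.frame(fraction_close = c(0, 0, 0, 0.5, 0.5, 1, 1, 1, 1))
  bt <- bin_cells(tied, "fraction_close", 3)
  # tied values never straddle a bin boundary
  for (v in unique(tied$fraction_close)) {
    expect_equal(length(unique(bt$assignment[tied$fraction_close == v])), 1L)
  }
  one <- bin_cells(data.frame(fraction_close = rep(0.5, 6)),
                   "fraction_close", 3)
  expect_true(one$merged)
  expect_equal(one$n_bins_effective, 1L)
})

test_that("binning then pooling conserves the population summaries", {
  set.seed(161)
  cells <- data.frame(fraction_close = stats::runif(40),
                      rna_count = stats::rpois(40, 3),
                      rna_total_intensity = stats::rlnorm(40, 5),
                      k_close = stats::rbinom(40, 2, 0.3), n_alleles = 2L)
  b <- bin_cells(cells, "fraction_close", 4)
  s <- b$summary
  expect_equal(sum(s$n_cells), nrow(cells))
  expect_equal(sum(s$n_cells * s$mean_rna_count) / nrow(cells),
               mean(cells$rna_count))
  expect_equal(sum(s$n_cells * s$mean_rna_total_intensity) / nrow(cells),
               mean(cells$rna_total_intensity))
  expect_equal(sum(s$pooled_fraction_close * s$n_cells * 2) / (nrow(cells) * 2),
               sum(cells$k_close) / (2 * nrow(cells)))
})

test_that("looping represses transcription across fraction-close bins", {
  cfg <- synthetic_config(seed = 171, n_cells = 2500,
                          p_contact_light = 0.35, expression_coupling = 0,
                          repression_odds_ratio = 4, conditions = "light")
  pop <- generate_population(cfg)
  qc <- qc_filter(pop$nuclei, pop$spots, th)
  pairs <- pair_alleles(qc$spots, th)$pairs
  rna <- qc$spots[qc$spots$channel == "rna", ]
  cells <- summarize_cells(pairs)
  cells_rna <- cell_rna_summary(rna, nuclei = cells)
  b <- bin_cells(cells_rna, "fraction_close", 3)
  expect_true(all(diff(b$summary$mean_rna_count) < 0))

  act <- link_rna_to_alleles(pairs, rna, th)
  ap <- activity_by_proximity(act)
  expect_true(ap$ok)
  expect_gt(ap$fraction_proximal_inactive, ap$fraction_proximal_active)
})

test_that("activity-by-proximity flags empty classes and honest nulls", {
  all_active <- data.frame(active = rep(TRUE, 5),
                           proximal = c(TRUE, FALSE, TRUE, TRUE, FALSE))
  r <- activity_by_proximity(all_active)
  expect_false(r$ok)
  expect_true(is.na(r$fraction_proximal_inactive))

  cfg <- synthetic_config(seed = 181, n_cells = 2500,
                          p_contact_light = 0.35, expression_coupling = 0,
                          repression_odds_ratio = 1, conditions = "light")
  pop <- generate_population(cfg)
  qc <- qc_filter(pop$nuclei, pop$spots, th)
  pairs <- pair_alleles(qc$spots, th)$pairs
  act <- link_rna_to_alleles(pairs, qc$spots[qc$spots$channel == "rna", ], th)
  r2 <- activity_by_proximity(act)
  p <- mean(act$proximal)
  se <- sqrt(p * (1 - p) * (1 / r2$n_active + 1 / r2$n_inactive))
  expect_lt(abs(r2$difference), 3 * se)
})

test_that("reporter ROI control reads recruitment and tests association", {
  cfg <- synthetic_config(seed = 191, n_cells = 8, image_size_px = 200,
                          nucleus_area_range_um2 = c(40, 55), noise_sd = 0,
                          conditions = "light")
  pop <- generate_population(cfg)
  f1 <- min(pop$nuclei$field_id)
  nuc <- pop$nuclei[pop$nuclei$field_id == f1, ]
  sp <- pop$spots[pop$spots$field_id == f1, ]
  th_small <- analysis_thresholds(min_area_um2 = 30)
  qc <- qc_filter(nuc, sp, th_small)
  pairs <- pair_alleles(qc$spots, th_small)$pairs
  act <- link_rna_to_alleles(pairs, sp[sp$channel == "rna", ], th_small)

  flat <- gfp_control_at_locus(act, matrix(42, 200, 200), th_small,
                               cfg$pixel_size_um)
  expect_true(all(flat$alleles$gfp_at_locus == 42))
  expect_false(isTRUE(flat$significant))

  # a bright blob planted at each active allele is detected
  img <- matrix(10, 200, 200)
  for (i in which(act$active)) {
    r <- render_fish_image(data.frame(x_um = act$x_um[i], y_um = act$y_um[i],
                                      peak_intensity = 300),
                           synthetic_config(seed = 1, image_size_px = 200,
                                            noise_sd = 0,
                                            background_level = 0,
                                            spot_sigma_px = 4))
    img <- img + r$image
  }
  planted <- gfp_control_at_locus(act, img, th_small, cfg$pixel_size_um)
  expect_true(planted$ok)
  expect_lt(planted$p_value, 0.05)
  expect_gt(planted$mean_active, planted$mean_inactive)
})

test_that("a reporter unrelated to activity shows no association", {
  set.seed(201)
  cfg <- synthetic_config(seed = 201, n_cells = 10, image_size_px = 200,
                          nucleus_area_range_um2 = c(40, 55), noise_sd = 0,
                          conditions = "light")
  pop <- generate_population(cfg)
  f1 <- min(pop$nuclei$field_id)
  th_small <- analysis_thresholds(min_area_um2 = 30)
  qc <- qc_filter(pop$nuclei[pop$nuclei$field_id == f1, ],
                  pop$spots[pop$spots$field_id == f1, ], th_small)
  pairs <- pair_alleles(qc$spots, th_small)$pairs
  act <- link_rna_to_alleles(pairs,
                             qc$spots[qc$spots$channel == "rna", ], th_small)
  n_sig <- sum(replicate(60, {
    img <- matrix(stats::rnorm(200 * 200, 100, 15), 200, 200)
    isTRUE(gfp_control_at_locus(act, img, th_small,
                                cfg$pixel_size_um)$significant)
  }))
  expect_lte(n_sig, 12)  # nominal 5% of 60 is 3; allow wide slack
})
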