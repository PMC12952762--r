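make_nucleus <- function(id, area = 150, solidity = 0.95, cond = "dark") {
  data.frame(nucleus_id = id, field_id = 1L, condition = cond,
             area_um2 = area, solidity = solidity,
             centroid_x_um = 10, centroid_y_um = 10)
}

make_spots <- function(id, xa, ya, xb, yb, first_spot_id = 1L) {
  n <- length(xa) + length(xb)
  data.frame(spot_id = seq(first_spot_id, length.out = n),
             nucleus_id = id,
             channel = c(rep("dna_a", length(xa)), rep("dna_b", length(xb))),
             x_um = c(xa, xb), y_um = c(ya, yb),
             peak_intensity = 100, integrated_intensity = 1000)
}

test_that("threshold validation enforces the documented constraints", {
  th <- analysis_thresholds()
  expect_s3_class(th, "analysis_thresholds")
  expect_error(analysis_thresholds(proximity_um = 3), "below pairing_max_um")
  expect_error(analysis_thresholds(min_area_um2 = -1), "positive")
  expect_error(analysis_thresholds(ploidy = 5), "ploidy")
})

test_that("QC removes small, non-solid and wrong-spot-count nuclei", {
  th <- analysis_thresholds(min_area_um2 = 50, ploidy = 2L)  # HeLa-style area
  nuclei <- rbind(make_nucleus(1, area = 45),
                  make_nucleus(2, solidity = 0.85),
                  make_nucleus(3), make_nucleus(4))
  spots <- rbind(make_spots(1, 1, 1, 2, 2, 1L),
                 make_spots(2, 1, 1, 2, 2, 10L),
                 make_spots(3, c(1, 3, 5), c(1, 3, 5), c(2, 4), c(2, 4), 20L),
                 make_spots(4, c(1, 3), c(1, 3), c(2, 4), c(2, 4), 30L))
  qc <- qc_filter(nuclei, spots, th)
  expect_equal(qc$nuclei$nucleus_id, 4)
  expect_true(all(qc$spots$nucleus_id == 4))
  rep_ <- qc$report
  expect_equal(rep_$n[rep_$rule == "area"], 1)
  expect_equal(rep_$n[rep_$rule == "solidity"], 1)
  expect_equal(rep_$n[rep_$rule == "spot_count_ploidy"], 3)
  expect_equal(rep_$n[rep_$rule == "retained"], 1)
  expect_error(qc_filter(nuclei, spots, th, dna_channels = c("dna_a", "cy5")),
               "unknown DNA channel")
})

test_that("greedy pairing follows the ascending distance list", {
  th <- analysis_thresholds()
  one <- make_spots(1, 0, 0, 0, 0.5)
  p1 <- pair_alleles(one, th)
  expect_equal(nrow(p1$pairs), 1L)
  expect_equal(p1$pairs$distance_um, 0.5)

  # A at (0,0),(0,1.0); B at (0,0.1),(0,0.7): greedy picks 0.1 then 0.3
  sp <- make_spots(1, c(0, 0), c(0, 1.0), c(0, 0), c(0.1, 0.7))
  p <- pair_alleles(sp, th)
  expect_equal(sort(p$pairs$distance_um), c(0.1, 0.3))
  expect_equal(length(p$unpaired), 0L)

  # nearest cross-channel neighbour beyond the 2 um cap: no pair
  far <- make_spots(1, 0, 0, 0, 2.5)
  pf <- pair_alleles(far, th)
  expect_equal(nrow(pf$pairs), 0L)
  expect_setequal(pf$unpaired, far$spot_id)

  # a pair exactly at the cap is rejected (strict "below 2 um")
  edge <- make_spots(1, 0, 0, 0, 2.0)
  expect_equal(nrow(pair_alleles(edge, th)$pairs), 0L)
})

test_that("pairing is symmetric in channel order and bounded by counts", {
  th <- analysis_thresholds()
  set.seed(101)
  for (rep_i in 1:20) {
    na <- sample(1:3, 1); nb <- sample(1:3, 1)
    sp <- make_spots(1, stats::runif(na, 0, 3), stats::runif(na, 0, 3),
                     stats::runif(nb, 0, 3), stats::runif(nb, 0, 3))
    p <- pair_alleles(sp, th)$pairs
    expect_lte(nrow(p), min(na, nb))
    swapped <- sp
    swapped$channel <- ifelse(sp$channel == "dna_a", "dna_b", "dna_a")
    ps <- pair_alleles(swapped, th)$pairs
    expect_equal(sort(ps$distance_um), sort(p$distance_um))
  }
})

test_that("greedy matching tracks the brute-force optimal assignment", {
  th <- analysis_thresholds()
  set.seed(102)
  ratios <- replicate(25, {
    n <- sample(2:4, 1)
    xa <- stats::runif(n, 0, 2); ya <- stats::runif(n, 0, 2)
    xb <- stats::runif(n, 0, 2); yb <- stats::runif(n, 0, 2)
    sp <- make_spots(1, xa, ya, xb, yb)
    greedy <- pair_alleles(sp, th)$pairs
    best <- brute_force_matching(xa, ya, xb, yb, th$pairing_max_um)
    # greedy yields a maximal (not necessarily maximum) matching
    expect_lte(nrow(greedy), best$n)
    if (nrow(greedy) == best$n && best$n > 0) {
      sum(greedy$distance_um) / max(best$total, 1e-12)
    } else NA_real_
  })
  ratios <- ratios[!is.na(ratios)]
  expect_true(all(ratios >= 1 - 1e-9))   # greedy can never beat optimal
  expect_lt(stats::median(ratios), 1.5)  # and is near-optimal here
})

test_that("proximity calls use a strict 0.27 um threshold", {
  th <- analysis_thresholds()
  expect_true(classify_proximal(0.20, th))
  expect_false(classify_proximal(0.27, th))
  expect_false(classify_proximal(1.0, th))
})

test_that("cell and condition summaries tally close alleles", {
  th <- analysis_thresholds()
  pairs <- data.frame(nucleus_id = c(1, 1, 2, 2, 2),
                      allele_index = c(1, 2, 1, 2, 3),
                      spot_id_a = 1:5, spot_id_b = 6:10,
                      x_um = 0, y_um = 0,
                      distance_um = c(0.1, 0.5, 0.1, 0.5, 0.9))
  pairs$proximal <- classify_proximal(pairs$distance_um, th)
  cells <- summarize_cells(pairs)
  expect_equal(cells$k_close[cells$nucleus_id == 1], 1L)
  expect_equal(cells$fraction_close[cells$nucleus_id == 1], 0.5)

  pairs$condition <- "dark"
  cond <- summarize_condition(pairs)
  expect_equal(cond$median_distance_um, 0.5)
  expect_equal(cond$fraction_proximal, 2 / 5)

  # ploidy denominator mode keeps the expected allele count
  cells2 <- summarize_cells(pairs[1:2, ], thresholds = th,
                            denominator = "ploidy")
  expect_equal(cells2$n_alleles, 2L)
})

test_that("pooled proximal fraction matches the Rayleigh mixture oracle", {
  p_contact <- 0.3
  cfg <- synthetic_config(seed = 111, n_cells = 1500,
                          p_contact_light = p_contact,
                          expression_coupling = 0, conditions = "light")
  pop <- generate_population(cfg)
  th <- analysis_thresholds()
  qc <- qc_filter(pop$nuclei, pop$spots, th)
  pairs <- pair_alleles(qc$spots, th)$pairs
  q <- rayleigh_close_prob(p_contact, th$proximity_um,
                           cfg$looped_scale_um, cfg$unlooped_scale_um)
  se <- sqrt(q * (1 - q) / nrow(pairs))
  expect_lt(abs(mean(pairs$proximal) - q), 3 * se)
})
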