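#!/usr/bin/env Rscript
# Cell-to-cell heterogeneity in loop formation: observed distribution of
# cells by number of close alleles against the binomial expectation under
# allele independence, per condition, plus a dose-response of the test
# statistic in the within-cell loop-state correlation.

suppressPackageStartupMessages(library(loopfish))

dir.create("results", showWarnings = FALSE)
pipe_file <- "results/pipeline/cell_summary.csv"
if (!file.exists(pipe_file)) stop("run analysis/03_allele_distances.R first")
cells <- utils::read.csv(pipe_file)

th <- analysis_thresholds()
rows <- do.call(rbind, lapply(split(cells, cells$condition), function(sub) {
  sub <- sub[sub$n_alleles == th$ploidy, ]
  obs <- observed_distribution(sub, th$ploidy)
  tst <- independence_test(obs$counts, obs$p_c, th$ploidy)
  cat(sprintf("\n%s condition (%d cells):\n", sub$condition[1], obs$n_cells))
  print(tst)
  data.frame(condition = sub$condition[1], n_cells = obs$n_cells,
             p_c = obs$p_c, chi2 = tst$chi2, dof = tst$dof,
             p_value = tst$p_value, stars = p_stars(tst$p_value))
}))
write_table_csv(rows, "results/heterogeneity_tests.csv")

# how the departure from independence grows with allele coupling
cat("\nIndependence chi2 vs within-cell loop-state correlation",
    "(2000 cells each):\n")
dose <- do.call(rbind, lapply(c(0, 0.25, 0.5, 0.75, 1), function(rho) {
  cfg <- synthetic_config(seed = 404L + round(100 * rho), n_cells = 2000,
                          p_contact_light = 0.3, expression_coupling = 0,
                          allele_correlation = rho, conditions = "light")
  tr <- generate_population(cfg)$truth
  k <- tapply(tr$pair_distance_um < th$proximity_um, tr$nucleus_id, sum)
  obs <- observed_distribution(data.frame(n_alleles = 2L,
                                          k_close = as.integer(k)), 2)
  tst <- independence_test(obs$counts, obs$p_c, 2)
  data.frame(allele_correlation = rho, chi2 = tst$chi2,
             p_value = tst$p_value)
}))
print(dose, row.names = FALSE)
write_table_csv(dose, "results/heterogeneity_correlation_dose.csv")
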