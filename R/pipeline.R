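#' Run the full FISH looping analysis pipeline
#'
#' Executes, in order: quality control, cross-channel allele pairing with
#' proximity calls, per-cell and per-condition summaries, the
#' allele-independence binomial null with its chi-squared test, the RNA
#' transcription linkage stages (skipped with a note when no RNA channel is
#' present), and the multiple-proportion comparison across conditions.
#' Every intermediate table is written as CSV under `output_dir`, together
#' with a JSON summary and a manifest carrying the run's configuration
#' hash, seed, package version and stage status. The pipeline itself draws
#' no random numbers: identical inputs give byte-identical outputs.
#'
#' @param nuclei Nucleus table (see [read_nucleus_table()] for the schema).
#' @param spots Spot table (see [read_spot_table()]).
#' @param output_dir Output directory, created if missing.
#' @param thresholds An [analysis_thresholds()].
#' @param n_bins Bins for the per-cell RNA summaries.
#' @param seed Recorded in the manifest (the pipeline is deterministic; the
#'   seed documents the upstream generator).
#' @param denominator Per-cell fraction denominator, see [summarize_cells()].
#' @param dna_channels,rna_channel Channel labels.
#' @param reference_condition Condition whose zero-close-allele cells
#'   normalize the RNA intensities (default: first condition).
#' @param condition_col Grouping column in `nuclei`.
#' @return Invisibly, a result bundle: all tables, the summary list, the
#'   manifest, and the output file paths.
#' @export
run_pipeline <- function(nuclei, spots, output_dir,
                         thresholds = analysis_thresholds(),
                         n_bins = 4L, seed = NA_integer_,
                         denominator = c("pairs", "ploidy"),
                         dna_channels = c("dna_a", "dna_b"),
                         rna_channel = "rna",
                         reference_condition = NULL,
                         condition_col = "condition") {
  denominator <- match.arg(denominator)
  stopifnot(inherits(thresholds, "analysis_thresholds"))
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  stages <- character(0)
  log_lines <- c(sprintf("loopfish %s | R %s",
                         as.character(utils::packageVersion("loopfish")),
                         paste(R.version$major, R.version$minor, sep = ".")),
                 sprintf("seed: %s", seed),
                 sprintf("thresholds: %s",
                         paste(names(thresholds), unlist(thresholds),
                               sep = "=", collapse = " ")))
  cfg_hash <- .config_hash(list(thresholds = unclass(thresholds),
                                n_bins = n_bins, denominator = denominator,
                                dna_channels = dna_channels,
                                rna_channel = rna_channel,
                                reference_condition = reference_condition))
  log_lines <- c(log_lines, sprintf("config_hash: %s", cfg_hash))

  emit <- function(df, name) {
    path <- file.path(output_dir, paste0(name, ".csv"))
    df$config_hash <- cfg_hash
    write_table_csv(df, path)
    files <<- c(files, path)
    path
  }
  fail <- function(stage, err) {
    manifest <- list(status = "failed", failed_stage = stage,
                     error = conditionMessage(err),
                     completed_stages = stages, outputs = basename(files),
                     config_hash = cfg_hash, seed = seed)
    jsonlite::write_json(manifest, file.path(output_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
    stop("pipeline failed at stage '", stage, "': ",
         conditionMessage(err), call. = FALSE)
  }
  run_stage <- function(stage, expr) {
    res <- tryCatch(expr, error = function(e) fail(stage, e))
    stages <<- c(stages, stage)
    res
  }
  if (!condition_col %in% names(nuclei)) {
    nuclei[[condition_col]] <- "all"
  }

  qc <- run_stage("qc", qc_filter(nuclei, spots, thresholds, dna_channels))
  emit(qc$report, "qc_report")
  emit(qc$nuclei, "nuclei_qc")

  pairing <- run_stage("pairing",
                       pair_alleles(qc$spots, thresholds, dna_channels))
  pairs <- merge(pairing$pairs,
                 qc$nuclei[, c("nucleus_id", condition_col)],
                 by = "nucleus_id", sort = TRUE)
  emit(pairs, "allele_pairs")

  cells <- run_stage("cell_summary",
                     summarize_cells(pairing$pairs, qc$nuclei, thresholds,
                                     denominator))
  emit(cells, "cell_summary")
  cond_summary <- run_stage("condition_summary",
                            summarize_condition(pairs, by = condition_col))
  emit(cond_summary, "condition_summary")

  het <- run_stage("heterogeneity", {
    conds <- unique(cells[[condition_col]])
    do.call(rbind, lapply(conds, function(cc) {
      sub <- cells[cells[[condition_col]] == cc &
                     cells$n_alleles == thresholds$ploidy, , drop = FALSE]
      if (nrow(sub) == 0L) return(NULL)
      obs <- observed_distribution(sub, thresholds$ploidy)
      tst <- independence_test(obs$counts, obs$p_c, thresholds$ploidy)
      row <- data.frame(condition = cc, n_cells = obs$n_cells,
                        p_c = obs$p_c, chi2 = tst$chi2, dof = tst$dof,
                        p_value = tst$p_value, ok = tst$ok)
      for (k in 0:thresholds$ploidy) {
        row[[paste0("observed_f", k)]] <- obs$counts[k + 1L] / obs$n_cells
        row[[paste0("expected_f", k)]] <- unname(tst$f[k + 1L])
      }
      row
    }))
  })
  if (!is.null(het)) emit(het, "heterogeneity")

  rna <- qc$spots[qc$spots$channel == rna_channel, , drop = FALSE]
  rna_present <- nrow(rna) > 0L
  binned <- NULL; act_prox <- NULL; activity <- NULL
  if (rna_present) {
    activity <- run_stage("rna_linkage",
                          link_rna_to_alleles(pairs, rna, thresholds))
    emit(activity, "allele_activity")
    cells_rna <- run_stage("rna_summary", {
      ref_cond <- if (is.null(reference_condition)) {
        sort(unique(cells[[condition_col]]))[1]
      } else reference_condition
      cell_rna_summary(rna, nuclei = cells, reference = function(d) {
        d[[condition_col]] == ref_cond & d$k_close == 0L
      })
    })
    emit(cells_rna, "cell_rna_summary")
    binned <- run_stage("binning", {
      do.call(rbind, lapply(split(cells_rna, cells_rna[[condition_col]]),
                            function(sub) {
        if (nrow(sub) < n_bins) return(NULL)
        b <- bin_cells(sub, "fraction_close", n_bins)
        b$summary$condition <- sub[[condition_col]][1]
        b$summary
      }))
    })
    if (!is.null(binned)) emit(binned, "rna_binned")
    act_prox <- run_stage("activity_by_proximity", {
      do.call(rbind, lapply(split(activity, activity[[condition_col]]),
                            function(sub) {
        r <- activity_by_proximity(sub)
        data.frame(condition = sub[[condition_col]][1],
                   n_active = r$n_active, n_inactive = r$n_inactive,
                   fraction_proximal_active = r$fraction_proximal_active,
                   fraction_proximal_inactive = r$fraction_proximal_inactive,
                   difference = r$difference, ratio = r$ratio, ok = r$ok)
      }))
    })
    emit(act_prox, "activity_by_proximity")
  }

  stats_tab <- run_stage("statistics", {
    if (nrow(cond_summary) >= 2L) {
      m <- suppressWarnings(
        marascuilo(cond_summary$n_proximal, cond_summary$n_alleles,
                   groups = cond_summary[[condition_col]]))
      m$pairs
    } else NULL
  })
  if (!is.null(stats_tab)) emit(stats_tab, "stats_marascuilo")

  summary <- list(
    config_hash = cfg_hash, seed = seed,
    n_nuclei_in = nrow(nuclei), n_nuclei_qc = nrow(qc$nuclei),
    pooled_proximal_fraction = stats::setNames(
      as.list(cond_summary$fraction_proximal),
      cond_summary[[condition_col]]),
    median_distance_um = stats::setNames(
      as.list(cond_summary$median_distance_um),
      cond_summary[[condition_col]]),
    rna_stages_run = rna_present
  )
  jsonlite::write_json(summary, file.path(output_dir, "summary.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  files <- c(files, file.path(output_dir, "summary.json"))

  manifest <- list(status = "ok", completed_stages = stages,
                   skipped_stages = if (rna_present) character(0) else
                     c("rna_linkage", "rna_summary", "binning",
                       "activity_by_proximity"),
                   outputs = basename(files), config_hash = cfg_hash,
                   seed = seed,
                   package_version =
                     as.character(utils::packageVersion("loopfish")))
  jsonlite::write_json(manifest, file.path(output_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  writeLines(log_lines, file.path(output_dir, "run_log.txt"))

  invisible(list(qc = qc, pairs = pairs, cells = cells,
                 condition_summary = cond_summary, heterogeneity = het,
                 activity = activity, binned = binned,
                 activity_by_proximity = act_prox,
                 marascuilo = stats_tab, summary = summary,
                 manifest = manifest, files = files))
}

# Stable md5 of the run configuration (via a canonical deparse written to a
# temporary file; tools::md5sum is file-based).
.config_hash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(deparse(config), tmp)
  unname(tools::md5sum(tmp))
}

#' Hash the files of a pipeline run
#'
#' Convenience for determinism checks: md5 digests of every regular file in
#' a directory, named by relative path.
#'
#' @param dir Directory.
#' @return Named character vector of md5 sums.
#' @export
hash_outputs <- function(dir) {
  f <- sort(list.files(dir, recursive = TRUE, full.names = TRUE))
  h <- tools::md5sum(f)
  names(h) <- basename(f)
  h
}
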