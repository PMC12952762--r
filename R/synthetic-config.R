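#' Configuration for the synthetic FISH experiment generator
#'
#' Bundles and validates all parameters of the seeded synthetic-data
#' generator. The generator emulates the statistical structure of a
#' high-throughput DNA/RNA-FISH looping experiment: per-cell log-normal
#' reporter expression, ploidy-structured alleles whose loop state follows a
#' (possibly expression-coupled and within-cell correlated) Bernoulli
#' mixture, 2D Rayleigh inter-locus distances for looped and unlooped
#' alleles, transcriptional repression of looped alleles, and Gaussian-spot
#' image rendering at a fixed pixel size.
#'
#' @param seed Integer seed; identical seed and config reproduce identical
#'   tables.
#' @param n_cells Cells generated per condition.
#' @param ploidy Alleles per cell (2 or 3).
#' @param p_contact_dark,p_contact_light Baseline probability that an allele
#'   is in the looped state under each light condition.
#' @param expression_mu,expression_sigma Log-normal parameters of the
#'   per-cell reporter level (a.u., natural-log scale).
#' @param expression_coupling Slope linking per-cell centred log-expression
#'   to the logit of the contact probability (0 = no coupling).
#' @param looped_scale_um,unlooped_scale_um Rayleigh scale (um) of the 2D
#'   radial distance between the two locus signals of a looped / unlooped
#'   allele.
#' @param repression_odds_ratio Odds ratio of an allele being
#'   transcriptionally active given unlooped versus looped (>1 means looping
#'   represses).
#' @param base_active_prob Probability that an unlooped allele is active.
#' @param allele_correlation Within-cell correlation of loop states in
#'   `[0,1]`; 0 = independent alleles, 1 = all alleles share one draw.
#' @param nucleus_area_range_um2,solidity_range Uniform ranges for the
#'   nucleus QC features.
#' @param pixel_size_um Pixel size of rendered images (um/px).
#' @param image_size_px Side length of rendered square fields.
#' @param spot_sigma_px Gaussian sigma of rendered spots (px).
#' @param background_level,noise_sd Image background intensity and additive
#'   Gaussian noise SD (a.u.).
#' @param min_allele_radial_frac,max_allele_radial_frac Radial placement of
#'   allele anchors as a fraction of the nucleus radius; defaults keep
#'   anchors of different alleles further apart than the pairing and RNA
#'   linkage radii.
#' @param conditions Character subset of `c("dark", "light")`; which light
#'   arms to generate.
#'
#' @return An object of class `synthetic_config` (a validated list).
#' @seealso [generate_population()], [render_fish_image()]
#' @export
synthetic_config <- function(seed = 1L,
                             n_cells = 5000L,
                             ploidy = 2L,
                             p_contact_dark = 0.02,
                             p_contact_light = 0.10,
                             expression_mu = log(100),
                             expression_sigma = 0.5,
                             expression_coupling = 0.5,
                             looped_scale_um = 0.12,
                             unlooped_scale_um = 0.45,
                             repression_odds_ratio = 4,
                             base_active_prob = 0.4,
                             allele_correlation = 0,
                             nucleus_area_range_um2 = c(120, 180),
                             solidity_range = c(0.92, 0.99),
                             pixel_size_um = 0.108,
                             image_size_px = 256L,
                             spot_sigma_px = 1.5,
                             background_level = 100,
                             noise_sd = 5,
                             min_allele_radial_frac = 0.55,
                             max_allele_radial_frac = 0.70,
                             conditions = c("dark", "light")) {
  cfg <- list(
    seed = as.integer(seed), n_cells = as.integer(n_cells),
    ploidy = as.integer(ploidy),
    p_contact_dark = p_contact_dark, p_contact_light = p_contact_light,
    expression_mu = expression_mu, expression_sigma = expression_sigma,
    expression_coupling = expression_coupling,
    looped_scale_um = looped_scale_um, unlooped_scale_um = unlooped_scale_um,
    repression_odds_ratio = repression_odds_ratio,
    base_active_prob = base_active_prob,
    allele_correlation = allele_correlation,
    nucleus_area_range_um2 = nucleus_area_range_um2,
    solidity_range = solidity_range,
    pixel_size_um = pixel_size_um, image_size_px = as.integer(image_size_px),
    spot_sigma_px = spot_sigma_px, background_level = background_level,
    noise_sd = noise_sd,
    min_allele_radial_frac = min_allele_radial_frac,
    max_allele_radial_frac = max_allele_radial_frac,
    conditions = match.arg(conditions, c("dark", "light"),
                           several.ok = TRUE)
  )
  validate_synthetic_config(cfg)
}

validate_synthetic_config <- function(cfg) {
  stopifnot(length(cfg$seed) == 1L, is.finite(cfg$seed))
  if (cfg$n_cells <= 0L) stop("n_cells must be positive")
  if (!cfg$ploidy %in% c(2L, 3L)) stop("ploidy must be 2 or 3")
  probs <- c(cfg$p_contact_dark, cfg$p_contact_light,
             cfg$base_active_prob, cfg$allele_correlation)
  if (any(probs < 0 | probs > 1)) {
    stop("probabilities and allele_correlation must lie in [0, 1]")
  }
  scales <- c(cfg$looped_scale_um, cfg$unlooped_scale_um,
              cfg$pixel_size_um, cfg$spot_sigma_px)
  if (any(scales <= 0)) stop("scales must be positive")
  if (cfg$repression_odds_ratio <= 0) stop("repression_odds_ratio must be > 0")
  if (cfg$expression_sigma < 0 || cfg$noise_sd < 0) {
    stop("expression_sigma and noise_sd must be non-negative")
  }
  stopifnot(length(cfg$nucleus_area_range_um2) == 2L,
            diff(cfg$nucleus_area_range_um2) >= 0,
            all(cfg$nucleus_area_range_um2 > 0),
            length(cfg$solidity_range) == 2L,
            all(cfg$solidity_range > 0 & cfg$solidity_range <= 1))
  if (cfg$image_size_px < 16L) stop("image_size_px too small")
  if (cfg$min_allele_radial_frac <= 0 ||
      cfg$max_allele_radial_frac >= 1 ||
      cfg$min_allele_radial_frac > cfg$max_allele_radial_frac) {
    stop("allele radial fractions must satisfy 0 < min <= max < 1")
  }
  structure(cfg, class = "synthetic_config")
}

#' @export
print.synthetic_config <- function(x, ...) {
  cat("synthetic_config:",
      x$n_cells, "cells/condition, ploidy", x$ploidy, "\n")
  cat("  p_contact dark/light:", x$p_contact_dark, "/", x$p_contact_light,
      " allele_correlation:", x$allele_correlation, "\n")
  cat("  Rayleigh scales (um) looped/unlooped:",
      x$looped_scale_um, "/", x$unlooped_scale_um, "\n")
  cat("  repression OR:", x$repression_odds_ratio,
      " base_active_prob:", x$base_active_prob, "\n")
  invisible(x)
}

#' Read or write a generator configuration as YAML
#'
#' @param path File path.
#' @rdname synthetic_config_yaml
#' @return `read_synthetic_config()` returns a validated
#'   `synthetic_config`; `write_synthetic_config()` returns `path`
#'   invisibly.
#' @export
read_synthetic_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(synthetic_config, raw)
}

#' @param config A `synthetic_config`.
#' @rdname synthetic_config_yaml
#' @export
write_synthetic_config <- function(config, path) {
  stopifnot(inherits(config, "synthetic_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}
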