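#' Expected fractions of cells by number of close alleles under
#' independence
#'
#' The allele-independence null: if each of a cell's `n` alleles is close
#' (proximal) with the population frequency `p_c` independently of its
#' siblings, the fraction of cells with exactly `k` close alleles is the
#' binomial mass `choose(n, k) p_c^k (1 - p_c)^(n - k)`.
#'
#' @param p_c Population frequency of close alleles, in `[0, 1]`.
#' @param n Ploidy (2, 3 or 4).
#' @return Numeric vector of length `n + 1`, named `"0"..."n"`, summing
#'   to 1.
#' @export
expected_fractions <- function(p_c, n) {
  if (length(p_c) != 1L || is.na(p_c) || p_c < 0 || p_c > 1) {
    stop("p_c must be a probability in [0, 1]")
  }
  if (!n %in% 2:4) stop("n (ploidy) must be 2, 3 or 4")
  k <- 0:n
  f <- choose(n, k) * p_c^k * (1 - p_c)^(n - k)
  names(f) <- k
  f
}

#' Observed distribution of close-allele counts per cell
#'
#' @param cell_summaries Per-cell table from [summarize_cells()]; every cell
#'   must have `n_alleles == n` (mixed ploidy is an error).
#' @param n Ploidy.
#' @return List with `counts` (cells with k = 0..n close alleles, named),
#'   `n_cells`, and the plug-in estimate `p_c = sum(k_close) / (n * cells)`.
#' @export
observed_distribution <- function(cell_summaries, n) {
  if (!all(cell_summaries$n_alleles == n)) {
    stop("mixed ploidy: all cells must have n_alleles == n")
  }
  n_cells <- nrow(cell_summaries)
  if (n_cells == 0L) stop("no cells")
  counts <- as.integer(table(factor(cell_summaries$k_close, levels = 0:n)))
  names(counts) <- 0:n
  list(counts = counts, n_cells = n_cells,
       p_c = sum(cell_summaries$k_close) / (n * n_cells))
}

#' Chi-squared test of allele independence
#'
#' Pearson goodness-of-fit of the observed close-allele-count distribution
#' against the binomial expectation `n_cells * f(k)` from
#' [expected_fractions()]. Categories with expected count below 1 are
#' pooled into the nearest remaining category before testing. The default
#' degrees of freedom are `categories - 1` (the plain chi-square test);
#' `estimated_p_correction = TRUE` subtracts one further degree of freedom
#' for the plug-in estimate of `p_c`.
#'
#' @param observed_counts Cells per k = 0..n (vector of length n + 1).
#' @param p_c Close-allele frequency used for the expectation.
#' @param n Ploidy.
#' @param min_cells Minimum number of cells for a defined test.
#' @param estimated_p_correction Subtract a dof for the estimated `p_c`.
#' @return Object of class `independence_model`: `p_c`, `n`, `f`
#'   (expected fractions), `observed_counts`, `expected_counts`, pooled
#'   versions, `chi2`, `dof`, `p_value`, `ok`, `note`.
#' @export
independence_test <- function(observed_counts, p_c, n,
                              min_cells = 20L,
                              estimated_p_correction = FALSE) {
  stopifnot(length(observed_counts) == n + 1L, all(observed_counts >= 0))
  n_cells <- sum(observed_counts)
  f <- expected_fractions(p_c, n)
  expected <- n_cells * f
  out <- list(p_c = p_c, n = n, f = f,
              observed_counts = observed_counts,
              expected_counts = expected,
              chi2 = NA_real_, dof = NA_integer_, p_value = NA_real_,
              ok = FALSE, note = NA_character_)
  class(out) <- "independence_model"
  if (n_cells < min_cells) {
    out$note <- sprintf("fewer than %d cells", min_cells)
    return(out)
  }
  # pool categories with expected < 1 into their nearest neighbor
  obs <- as.numeric(observed_counts)
  exp_ <- as.numeric(expected)
  while (length(exp_) > 1L && any(exp_ < 1)) {
    i <- which.min(exp_)
    j <- if (i == 1L) 2L else if (i == length(exp_)) i - 1L else
      if (exp_[i - 1L] <= exp_[i + 1L]) i - 1L else i + 1L
    exp_[j] <- exp_[j] + exp_[i]
    obs[j] <- obs[j] + obs[i]
    exp_ <- exp_[-i]; obs <- obs[-i]
  }
  if (length(exp_) < 2L) {
    out$note <- "all mass in one category; test undefined"
    return(out)
  }
  dof <- length(exp_) - 1L - if (estimated_p_correction) 1L else 0L
  if (dof < 1L) {
    out$note <- "no degrees of freedom left after pooling"
    return(out)
  }
  gof <- pearson_chi2(obs, exp_, dof = dof)
  out$pooled_observed <- obs
  out$pooled_expected <- exp_
  out$chi2 <- gof$chi2
  out$dof <- gof$dof
  out$p_value <- gof$p_value
  out$ok <- TRUE
  out
}

#' @export
print.independence_model <- function(x, ...) {
  cat("Allele-independence binomial null (n =", x$n, ", p_c =",
      signif(x$p_c, 4), ")\n")
  cat("  observed:", paste(x$observed_counts, collapse = " "), "\n")
  cat("  expected:", paste(signif(x$expected_counts, 4), collapse = " "),
      "\n")
  if (x$ok) {
    cat("  chi2 =", signif(x$chi2, 4), "dof =", x$dof,
        "p =", signif(x$p_value, 4), "\n")
  } else {
    cat("  test undefined:", x$note, "\n")
  }
  invisible(x)
}
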