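#' Significance stars
#'
#' Encoding used throughout the outputs: `***` p < 0.001, `**` p < 0.01,
#' `*` p < 0.05, otherwise `ns`.
#'
#' @param p P-values.
#' @return Character vector.
#' @export
p_stars <- function(p) {
  ifelse(is.na(p), NA_character_,
         ifelse(p < 0.001, "***",
                ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", "ns"))))
}

#' Marascuilo's procedure for multiple proportions
#'
#' Simultaneous pairwise comparison of k group proportions. For each pair
#' (i, j) the absolute difference `|p_i - p_j|` is compared with the
#' critical range
#' `sqrt(qchisq(1 - alpha, k - 1)) * sqrt(p_i (1 - p_i) / n_i + p_j (1 - p_j) / n_j)`;
#' the pair is significant when the difference exceeds the range.
#'
#' @param successes,totals Integer vectors per group.
#' @param alpha Family significance level.
#' @param groups Optional group labels.
#' @return Object of class `proportion_comparison` with the per-pair table.
#' @export
marascuilo <- function(successes, totals, alpha = 0.05, groups = NULL) {
  k <- length(successes)
  stopifnot(length(totals) == k, k >= 2L)
  if (any(totals <= 0)) stop("all group totals must be positive")
  if (any(successes < 0 | successes > totals)) {
    stop("successes must lie in [0, totals]")
  }
  if (k == 2L) {
    warning("only 2 groups: Marascuilo reduces to a z-style comparison")
  }
  if (is.null(groups)) groups <- paste0("g", seq_len(k))
  p <- successes / totals
  chi_q <- stats::qchisq(1 - alpha, df = k - 1L)
  ij <- utils::combn(k, 2L)
  pairs <- data.frame(
    group_i = groups[ij[1, ]], group_j = groups[ij[2, ]],
    p_i = p[ij[1, ]], p_j = p[ij[2, ]]
  )
  pairs$difference <- abs(pairs$p_i - pairs$p_j)
  pairs$critical_range <- sqrt(chi_q) *
    sqrt(pairs$p_i * (1 - pairs$p_i) / totals[ij[1, ]] +
         pairs$p_j * (1 - pairs$p_j) / totals[ij[2, ]])
  pairs$significant <- pairs$difference > pairs$critical_range
  structure(list(groups = groups, successes = successes, totals = totals,
                 alpha = alpha, chi2_quantile = chi_q, pairs = pairs),
            class = "proportion_comparison")
}

#' @export
print.proportion_comparison <- function(x, ...) {
  cat("Marascuilo procedure,", length(x$groups), "groups, alpha =",
      x$alpha, "(chi2 quantile", signif(x$chi2_quantile, 4), ")\n")
  print(x$pairs, row.names = FALSE)
  invisible(x)
}

#' Two-way ANOVA with Tukey post-hoc comparisons
#'
#' Fits `values ~ A * B` (the interaction is dropped, with a note, when a
#' design cell is empty), reports type-II sums of squares for unbalanced
#' designs, and runs Tukey HSD over the factor and cell means. Degenerate
#' inputs with zero variance everywhere report F = 0, p = 1.
#'
#' @param values Numeric response.
#' @param factor_a,factor_b Grouping variables, at least 2 levels each.
#' @return List with `anova` (term, sum_sq, df, f, p_value, stars),
#'   `tukey` (list of per-term data frames), `interaction_dropped`, `note`.
#' @export
two_way_anova_tukey <- function(values, factor_a, factor_b) {
  a <- factor(factor_a); b <- factor(factor_b)
  stopifnot(length(values) == length(a), length(values) == length(b))
  if (nlevels(a) < 2L || nlevels(b) < 2L) {
    stop("both factors need at least 2 levels")
  }
  dat <- data.frame(y = values, a = a, b = b)
  cells <- table(a, b)
  interaction_dropped <- any(cells == 0L)
  note <- if (interaction_dropped) "empty design cell: interaction dropped"
          else NA_character_
  form <- if (interaction_dropped) y ~ a + b else y ~ a * b
  fit <- stats::lm(form, data = dat)
  # car's type-II table refuses a zero residual SS (constant response or a
  # noise-free planted effect); fall back to the sequential table then,
  # which coincides for the balanced designs where that happens.
  tab <- tryCatch(car::Anova(fit, type = 2), error = function(e) {
    note <<- paste(c(note[!is.na(note)],
                     "zero residual SS: sequential sums of squares used"),
                   collapse = "; ")
    a1 <- suppressWarnings(stats::anova(fit))
    data.frame(`Sum Sq` = a1$`Sum Sq`, Df = a1$Df, `F value` = a1$`F value`,
               `Pr(>F)` = a1$`Pr(>F)`, row.names = rownames(a1),
               check.names = FALSE)
  })
  terms <- rownames(tab)
  keep <- terms != "Residuals"
  resid_ms <- tab["Residuals", "Sum Sq"] / tab["Residuals", "Df"]
  anova_df <- data.frame(term = terms[keep],
                         sum_sq = tab[keep, "Sum Sq"],
                         df = tab[keep, "Df"],
                         f = tab[keep, "F value"],
                         p_value = tab[keep, "Pr(>F)"])
  # with no residual noise: zero-SS terms are null (F = 0, p = 1),
  # nonzero-SS terms are exact effects (p = 0)
  degenerate <- !is.finite(resid_ms) | resid_ms <= .Machine$double.eps
  zero_ss <- anova_df$sum_sq <=
    .Machine$double.eps * 100 * (1 + abs(mean(values)))
  fix0 <- (degenerate & zero_ss) | (!is.finite(anova_df$f) & zero_ss)
  anova_df$f[fix0] <- 0
  anova_df$p_value[fix0] <- 1
  fix1 <- degenerate & !zero_ss
  anova_df$f[fix1] <- Inf
  anova_df$p_value[fix1] <- 0
  anova_df$stars <- p_stars(anova_df$p_value)

  tukey <- tryCatch({
    aov_fit <- stats::aov(form, data = dat)
    th <- stats::TukeyHSD(aov_fit)
    lapply(th, function(m) {
      d <- as.data.frame(m)
      d$comparison <- rownames(m)
      rownames(d) <- NULL
      names(d) <- c("diff", "lwr", "upr", "p_adj", "comparison")
      d[, c("comparison", "diff", "lwr", "upr", "p_adj")]
    })
  }, error = function(e) {
    note <<- paste(c(note[!is.na(note)], conditionMessage(e)),
                   collapse = "; ")
    NULL
  })
  list(anova = anova_df, tukey = tukey,
       interaction_dropped = interaction_dropped, note = note)
}

#' Paired two-tailed t-test
#'
#' @param values_a,values_b Paired measurements, equal length >= 2.
#' @return List with `t`, `dof`, `p_value`, `mean_difference`, `ok`,
#'   `note`. Identical vectors give t = 0, p = 1; a nonzero constant
#'   difference has zero variance and is flagged rather than tested.
#' @export
paired_t <- function(values_a, values_b) {
  n <- length(values_a)
  stopifnot(length(values_b) == n, n >= 2L)
  d <- values_a - values_b
  if (stats::sd(d) == 0) {
    if (all(d == 0)) {
      return(list(t = 0, dof = n - 1L, p_value = 1, mean_difference = 0,
                  ok = TRUE, note = "no difference anywhere"))
    }
    return(list(t = NA_real_, dof = n - 1L, p_value = NA_real_,
                mean_difference = mean(d), ok = FALSE,
                note = "zero variance of differences"))
  }
  ht <- stats::t.test(values_a, values_b, paired = TRUE,
                      alternative = "two.sided")
  list(t = unname(ht$statistic), dof = unname(ht$parameter),
       p_value = ht$p.value, mean_difference = unname(ht$estimate),
       ok = TRUE, note = NA_character_)
}

#' Pearson chi-squared statistic
#'
#' `sum((O - E)^2 / E)` with caller-stated degrees of freedom (default
#' `length - 1`); p-value from the chi-squared distribution.
#'
#' @param observed,expected Equal-length non-negative vectors; expected
#'   must be positive.
#' @param dof Degrees of freedom.
#' @return List with `chi2`, `dof`, `p_value`.
#' @export
pearson_chi2 <- function(observed, expected, dof = length(observed) - 1L) {
  stopifnot(length(observed) == length(expected), dof >= 1L)
  if (any(observed < 0)) stop("negative observed counts")
  if (any(expected <= 0)) stop("expected counts must be positive")
  chi2 <- sum((observed - expected)^2 / expected)
  list(chi2 = chi2, dof = as.integer(dof),
       p_value = stats::pchisq(chi2, df = dof, lower.tail = FALSE))
}
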