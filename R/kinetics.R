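#' A CV time course
#'
#' Container for a coefficient-of-variation kinetic trace, sampled at
#' strictly increasing times with light activation at `activation_time`
#' (t = 0 by convention).
#'
#' @param times Numeric seconds, strictly increasing, length >= 3 for
#'   half-time estimation.
#' @param cv CV values (raw or relative), same length.
#' @param activation_time Activation time (s).
#' @return Object of class `kinetic_trace`.
#' @export
kinetic_trace <- function(times, cv, activation_time = 0) {
  stopifnot(length(times) == length(cv), length(times) >= 1L,
            all(is.finite(times)), all(diff(times) > 0))
  structure(list(times = as.numeric(times), cv = as.numeric(cv),
                 activation_time = activation_time),
            class = "kinetic_trace")
}

#' @export
as.data.frame.kinetic_trace <- function(x, ...) {
  data.frame(time_s = x$times, cv = x$cv)
}

#' @export
print.kinetic_trace <- function(x, ...) {
  cat("kinetic_trace:", length(x$times), "samples,",
      "t in [", x$times[1], ",", x$times[length(x$times)], "] s\n")
  invisible(x)
}

# Shared machinery: half level relative to (max - initial); first crossings.
.kinetic_core <- function(trace, smooth = FALSE) {
  stopifnot(inherits(trace, "kinetic_trace"))
  if (length(trace$times) < 3L) stop("trace needs at least 3 samples")
  cv <- trace$cv
  if (smooth && length(cv) >= 3L) cv <- stats::runmed(cv, 3L)
  t <- trace$times
  cv0 <- cv[1]
  imax <- which.max(cv)
  cvmax <- cv[imax]
  half <- cv0 + (cvmax - cv0) / 2
  list(t = t, cv = cv, cv0 = cv0, imax = imax, cvmax = cvmax, half = half)
}

.cross_up <- function(t, cv, half, from = 1L) {
  i <- from
  while (i <= length(cv) && cv[i] < half) i <- i + 1L
  if (i > length(cv)) return(NA_real_)
  if (i == 1L || cv[i] == half) return(t[i])
  t[i - 1L] + (half - cv[i - 1L]) / (cv[i] - cv[i - 1L]) * (t[i] - t[i - 1L])
}

# `from` must be the first index after a sample above `half`, so the
# bracketing sample cv[i - 1] > half is always available.
.cross_down <- function(t, cv, half, from) {
  i <- from
  while (i <= length(cv) && cv[i] > half) i <- i + 1L
  if (i > length(cv)) return(NA_real_)
  if (cv[i] == half) return(t[i])
  t[i - 1L] + (cv[i - 1L] - half) / (cv[i - 1L] - cv[i]) * (t[i] - t[i - 1L])
}

#' Estimate clustering and declustering half-times
#'
#' The half level is the initial CV plus half of (maximum CV - initial CV).
#' `t_c` is the first upward crossing of that level, `t_d` the first
#' downward re-crossing after the peak, both linearly interpolated between
#' the bracketing samples. A flat or decreasing trace leaves `t_c`
#' undefined (`NA`, flagged); a trace that never falls back below the half
#' level leaves `t_d` undefined. Both estimates are invariant under affine
#' rescaling of the CV axis.
#'
#' @param trace A [kinetic_trace()].
#' @param smooth Apply a 3-point running median before estimation (off by
#'   default to avoid biasing the half-times).
#' @return A one-row data frame (`t_c`, `t_d`, `cv_initial`, `cv_max`,
#'   `peak_time`, `t_c_defined`, `t_d_defined`).
#' @export
estimate_kinetics <- function(trace, smooth = FALSE) {
  k <- .kinetic_core(trace, smooth)
  rel_tol <- 1e-12 + 1e-9 * abs(k$cv0)
  rising <- k$cvmax > k$cv0 + rel_tol
  t_c <- if (rising) .cross_up(k$t, k$cv, k$half) else NA_real_
  t_d <- if (rising && k$imax < length(k$cv)) {
    .cross_down(k$t, k$cv, k$half, from = k$imax + 1L)
  } else NA_real_
  data.frame(t_c = t_c, t_d = t_d, cv_initial = k$cv0, cv_max = k$cvmax,
             peak_time = k$t[k$imax],
             t_c_defined = !is.na(t_c), t_d_defined = !is.na(t_d))
}

#' @rdname estimate_kinetics
#' @export
estimate_clustering_time <- function(trace, smooth = FALSE) {
  estimate_kinetics(trace, smooth)$t_c
}

#' @rdname estimate_kinetics
#' @export
estimate_declustering_time <- function(trace, smooth = FALSE) {
  estimate_kinetics(trace, smooth)$t_d
}

#' Fit a population summary curve of CV versus reporter expression
#'
#' Least-squares fit of one of three families used to summarize clustering
#' levels across expression: a 4-parameter logistic on log-expression
#' (`cv = d + (a - d) / (1 + exp(-b (log x - m)))`), a decaying exponential
#' (`cv = a exp(-x / b) + c`), or a line (`cv = a x + b`). Nonlinear
#' families are fit with Levenberg-Marquardt; non-convergence or an
#' unidentifiable parameter is flagged rather than raised.
#'
#' @param expression Positive expression values (a.u.), length >= 5.
#' @param cv CV values, same length.
#' @param model One of `"logistic"`, `"exponential"`, `"linear"`.
#' @return List with `model`, `parameters` (named vector), `fitted`,
#'   `residual_sd`, `converged`, and `note` when flagged.
#' @export
fit_cv_vs_expression <- function(expression, cv,
                                 model = c("logistic", "exponential",
                                           "linear")) {
  model <- match.arg(model)
  stopifnot(length(expression) == length(cv), length(cv) >= 5L,
            all(expression > 0))
  x <- expression
  note <- NA_character_
  if (model == "linear") {
    fit <- stats::lm(cv ~ x)
    pars <- c(a = unname(stats::coef(fit)[2]), b = unname(stats::coef(fit)[1]))
    fitted <- unname(stats::fitted(fit))
    rsd <- sqrt(mean(stats::residuals(fit)^2))
    return(list(model = model, parameters = pars, fitted = fitted,
                residual_sd = rsd, converged = TRUE, note = note))
  }
  if (stats::sd(cv) < .Machine$double.eps^0.5 * (1 + abs(mean(cv)))) {
    return(list(model = model,
                parameters = c(a = 0, b = NA_real_, c = mean(cv)),
                fitted = rep(mean(cv), length(cv)), residual_sd = 0,
                converged = FALSE,
                note = "constant response: shape parameter unidentifiable"))
  }
  fit <- tryCatch({
    if (model == "logistic") {
      z <- log(x)
      start <- list(a = max(cv), d = min(cv), m = stats::median(z),
                    b = 2 / max(stats::sd(z), 1e-6))
      minpack.lm::nlsLM(cv ~ d + (a - d) / (1 + exp(-b * (z - m))),
                        start = start,
                        control = minpack.lm::nls.lm.control(maxiter = 200))
    } else {
      rng <- max(x) - min(x)
      start <- list(a = cv[which.min(x)] - cv[which.max(x)],
                    b = max(rng, 1e-6) / 2, c = min(cv))
      minpack.lm::nlsLM(cv ~ a * exp(-x / b) + c, start = start,
                        control = minpack.lm::nls.lm.control(maxiter = 200))
    }
  }, error = function(e) e)
  if (inherits(fit, "error")) {
    return(list(model = model, parameters = NULL, fitted = NULL,
                residual_sd = NA_real_, converged = FALSE,
                note = conditionMessage(fit)))
  }
  list(model = model, parameters = stats::coef(fit),
       fitted = unname(stats::fitted(fit)),
       residual_sd = sqrt(mean(stats::residuals(fit)^2)),
       converged = TRUE, note = note)
}
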