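#' Goodness of fit for retention curves
#'
#' Sum of squared errors on proportions, pooled `R^2` about the grand mean,
#' and the Pearson chi-square statistic
#' `sum n_i (o_i - p_i)^2 / (p_i (1 - p_i))` with `points - n_free` degrees
#' of freedom. The chi-square test grows more severe with the number of
#' observations per point, so it complements `R^2` for high-n data. If a
#' predicted probability is exactly 0 or 1 while the observation disagrees,
#' the chi-square is undefined and returned as `NA` with a warning.
#'
#' @param observed observed proportions.
#' @param predicted model probabilities, same length.
#' @param trials trial counts per point (may be `NA`; chi-square then `NA`).
#' @param n_free number of free parameters used by the fit.
#' @return List with `sse`, `r_squared`, `chisq`, `df`, `chisq_p`.
#' @examples
#' goodness(c(0.6, 0.4), c(0.5, 0.5), trials = c(10, 10))
#' @export
goodness <- function(observed, predicted, trials = NULL, n_free = 0L) {
  if (length(observed) != length(predicted))
    stop("'observed' and 'predicted' must have equal length", call. = FALSE)
  if (any(predicted < 0 | predicted > 1))
    stop("'predicted' must be probabilities", call. = FALSE)
  sse <- sum((observed - predicted)^2)
  sst <- sum((observed - mean(observed))^2)
  r2 <- if (sst > 0) 1 - sse / sst else NA_real_
  chisq <- NA_real_
  df <- length(observed) - n_free
  p <- NA_real_
  if (!is.null(trials) && !anyNA(trials)) {
    degenerate <- (predicted == 0 & observed > 0) |
      (predicted == 1 & observed < 1)
    if (any(degenerate)) {
      warning("predicted probability exactly 0 or 1 with disagreeing ",
              "observation: chi-square undefined", call. = FALSE)
    } else {
      idx <- predicted > 0 & predicted < 1
      chisq <- sum(trials[idx] * (observed[idx] - predicted[idx])^2 /
                     (predicted[idx] * (1 - predicted[idx])))
      p <- if (df > 0) stats::pchisq(chisq, df, lower.tail = FALSE)
           else NA_real_
    }
  }
  list(sse = sse, r_squared = r2, chisq = chisq, df = df, chisq_p = p)
}
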