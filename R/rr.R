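## The relative retrograde (rr) gradient: ratio of lesioned to control trace
## intensity. Because every store intensity is proportional to mu1 and the
## cue term multiplies the chain once, both mu1 and q cancel in the ratio —
## which is what makes the rr-gradient immune to per-time-point item
## difficulty manipulation, unlike a ratio of raw probabilities.

.new_rr_curve <- function(times, rr, source) {
  structure(
    data.frame(time = as.numeric(times), rr = as.numeric(rr),
               source = source, stringsAsFactors = FALSE),
    class = c("rr_curve", "data.frame")
  )
}

#' Relative retrograde gradient from observed probabilities
#'
#' Transforms matched lesioned and control recall probabilities into the
#' rr-gradient: `-log(1 - p_lesioned) / -log(1 - p_control)`, elementwise.
#' Probabilities are first corrected for a declared guessing floor. Observed
#' proportions equal to 1 are clipped to `1 - 1/(2 n)` (continuity
#' correction) when trial counts are supplied, or to just below 1 otherwise;
#' in strict mode they are an error. Points with zero control intensity are
#' dropped with a warning (the ratio is undefined there).
#'
#' @param p_lesioned,p_control probability vectors at matched time points.
#' @param times optional time stamps (defaults to point index).
#' @param trials optional trial counts per point, used for the ceiling
#'   correction.
#' @param g guessing floor shared by both groups.
#' @param strict error instead of clipping probabilities at 1.
#' @return An `"rr_curve"` data frame with columns `time`, `rr`, `source`.
#' @examples
#' rr_transform(p_lesioned = 0.3, p_control = 0.6)  # log(0.7)/log(0.4)
#' @export
rr_transform <- function(p_lesioned, p_control, times = NULL, trials = NULL,
                         g = 0, strict = FALSE) {
  if (length(p_lesioned) != length(p_control))
    stop("lesioned and control points must be matched", call. = FALSE)
  if (is.null(times)) times <- seq_along(p_control)
  if (length(times) != length(p_control))
    stop("'times' must match the probability vectors", call. = FALSE)
  clip <- function(p) {
    hit <- !is.na(p) & p >= 1
    if (any(hit)) {
      if (strict) stop("observed proportion at ceiling (p >= 1)",
                       call. = FALSE)
      ceiling_to <- if (!is.null(trials)) {
        1 - 1 / (2 * as.numeric(trials))
      } else rep(1 - 1e-12, length(p))
      warning(sum(hit), " proportion(s) at ceiling clipped before the log ",
              "transform", call. = FALSE)
      p[hit] <- ceiling_to[hit]
    }
    p
  }
  rl <- intensity_from_probability(clip(p_lesioned), g = g, strict = strict)
  rc <- intensity_from_probability(clip(p_control), g = g, strict = strict)
  bad <- rc <= 0
  if (any(bad)) {
    warning(sum(bad), " point(s) with zero control intensity dropped: ",
            "rr undefined there", call. = FALSE)
  }
  .new_rr_curve(times[!bad], rl[!bad] / rc[!bad], "data")
}

#' Model relative retrograde gradient
#'
#' Ratio of lesioned to control intensity under the generative model. The
#' acquired intensity `mu1` and cue quality `q` cancel, so the curve depends
#' only on the decline/consolidation rates and the lesion. At `t = 0` the
#' analytic limit is returned (see [rr_intercept()]); for a full store-1
#' lesion with no neocortical decline the curve rises from `1 - lambda`
#' toward 1, the closed form being
#' `rr(t) = 1 / (1 + a1 / (mu2 (e^(a1 t) - 1)))`.
#'
#' @inheritParams total_intensity
#' @param lesion a [lesion_profile()].
#' @param times nonnegative times.
#' @return An `"rr_curve"` data frame (`source = "model"`).
#' @examples
#' cp <- chain_params(mu = c(1, 0.1), a = c(0.3, 0))
#' rr_model(cp, lesion_profile(lambda = c(1, 0)), times = c(0, 5, 20))
#' @export
rr_model <- function(params, lesion, times) {
  .check_chain(params)
  times <- .check_times(times)
  rl <- total_intensity(params, times, lesion)
  rc <- total_intensity(params, times, lesion = NULL)
  rr <- ifelse(rc > 0, rl / rc, NA_real_)
  # t = 0 (or fully decayed control) handled by the analytic limit
  at0 <- times == 0 | !is.finite(rr)
  if (any(at0)) rr[at0] <- rr_intercept(lesion)
  .new_rr_curve(times, rr, "model")
}

#' Ordinate intercept of the rr-gradient
#'
#' The limit of the model rr-gradient as memory age approaches 0. Store 1
#' dominates the young-memory intensity, so the intercept is
#' `retrieval * induction_1 * (1 - lambda_1)`: `1 - lambda` for a pure
#' intensity lesion (a 70 percent hippocampal lesion intersects the ordinate
#' at 0.3), and `q_H` for a pure retrieval deficit.
#'
#' @param lesion a [lesion_profile()].
#' @return Scalar in `[0, 1]`.
#' @examples
#' rr_intercept(lesion_profile(lambda = 0.7))           # 0.3
#' rr_intercept(pathology_profile("huntington", q_H = 0.6))  # 0.6
#' @export
rr_intercept <- function(lesion) {
  if (!inherits(lesion, "lesion_profile"))
    stop("'lesion' must be a lesion_profile object", call. = FALSE)
  lam1 <- if (length(lesion$lambda)) lesion$lambda[1L] else 0
  ind1 <- if (length(lesion$induction)) lesion$induction[1L] else 1
  if (anyNA(c(lam1, ind1, lesion$retrieval)))
    stop("lesion profile contains free (NA) parameters", call. = FALSE)
  lesion$retrieval * ind1 * (1 - lam1)
}

#' @export
print.rr_curve <- function(x, ...) {
  cat("Relative retrograde gradient (", x$source[1L], ", ",
      nrow(x), " points)\n", sep = "")
  print.data.frame(x, ...)
  invisible(x)
}

#' @export
plot.rr_curve <- function(x, ylim = c(0, max(1, x$rr)), ...) {
  graphics::plot(x$time, x$rr, ylim = ylim, xlab = "memory age",
                 ylab = "rr (lesioned / control intensity)",
                 pch = if (x$source[1L] == "data") 17 else NA,
                 type = if (x$source[1L] == "data") "p" else "l", ...)
  invisible(x)
}

#' Write an rr curve to CSV
#'
#' @param x an `"rr_curve"`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_rr <- function(x, path) {
  stopifnot(inherits(x, "rr_curve"))
  utils::write.csv(as.data.frame(x), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
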