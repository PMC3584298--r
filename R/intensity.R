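## Core forward model: store intensities of the linear decline/induction
## cascade, their sum, and the link to recall probability.
##
## The exponential cascade
##   dr_1/dt = -a_1 r_1,              r_1(0) = mu_1
##   dr_i/dt = mu_i r_{i-1} - a_i r_i, r_i(0) = 0   (i > 1)
## has the classic sequential-first-order-kinetics solution (sum of
## exponentials) when all decline rates are distinct. Near-equal rates make
## that form cancel catastrophically, in which case we integrate numerically.

# relative closeness below which two decline rates count as confluent
.RATE_TOL <- 1e-9

# r_i(t) for an exponential chain with pairwise-distinct decline rates,
# vectorised over t. Empty product conventions give r_1 = mu_1 e^(-a_1 t).
.bateman_store <- function(mu, a, i, t) {
  ai <- a[seq_len(i)]
  amp <- mu[1L] * prod(mu[seq_len(i)][-1L])
  out <- numeric(length(t))
  for (k in seq_len(i)) {
    ck <- 1 / prod(ai[-k] - ai[k])
    out <- out + ck * exp(-ai[k] * t)
  }
  # tiny negative values can arise from cancellation at t = 0
  pmax(amp * out, 0)
}

.rates_confluent <- function(a, i) {
  ai <- a[seq_len(i)]
  if (i < 2L) return(FALSE)
  d <- abs(outer(ai, ai, "-"))
  mind <- min(d[upper.tri(d)])
  mind < .RATE_TOL * max(ai, 1e-12)
}

# survival function of a single store-1 trace
.survival1 <- function(a1, decline, t) {
  if (decline == "power") (1 + t)^(-a1) else exp(-a1 * t)
}

# intensity matrix r_i(t): rows = times, cols = stores; raw (no q, no lesion)
.intensity_matrix <- function(mu, a, decline, times) {
  n <- length(mu)
  times <- as.numeric(times)
  out <- matrix(0, length(times), n)
  if (decline == "power") {
    out[, 1L] <- mu[1L] * .survival1(a[1L], decline, times)
    if (n >= 2L) {
      # downstream stores by adaptive quadrature of the induction convolution
      prev <- function(s) mu[1L] * (1 + s)^(-a[1L])
      for (i in 2:n) {
        fi <- local({
          pf <- prev; mui <- mu[i]; ai <- a[i]
          function(tt) {
            vapply(tt, function(t1) {
              if (t1 == 0) return(0)
              mui * stats::integrate(
                function(s) pf(s) * exp(-ai * (t1 - s)),
                lower = 0, upper = t1,
                rel.tol = 1e-10, abs.tol = 1e-12
              )$value
            }, numeric(1))
          }
        })
        out[, i] <- fi(times)
        prev <- fi
      }
    }
    return(out)
  }
  if (.rates_confluent(a, n)) {
    # near-equal decline rates: the distinct-rate closed form divides by
    # rate differences; fall back to high-accuracy numeric integration
    return(.ode_intensity_matrix(mu, a, decline, times))
  }
  for (i in seq_len(n)) out[, i] <- .bateman_store(mu, a, i, times)
  out
}

# effective (induction-scaled) rates and lesion weights for a chain + lesion
.effective <- function(params, lesion = NULL) {
  n <- length(params$mu)
  if (is.null(lesion)) {
    return(list(mu = params$mu, a = params$a, w = rep(1, n), retrieval = 1))
  }
  if (!inherits(lesion, "lesion_profile"))
    stop("'lesion' must be a lesion_profile object", call. = FALSE)
  lam <- .pad(lesion$lambda, n, 0)
  ind <- .pad(lesion$induction, n, 1)
  if (anyNA(lam) || anyNA(ind) || is.na(lesion$retrieval))
    stop("lesion profile contains free (NA) parameters; supply values",
         call. = FALSE)
  list(mu = params$mu * ind, a = params$a, w = 1 - lam,
       retrieval = lesion$retrieval)
}

.pad <- function(x, n, fill) {
  x <- as.numeric(x)
  if (length(x) > n)
    stop("lesion profile has more entries than the chain has stores",
         call. = FALSE)
  c(x, rep(fill, n - length(x)))
}

#' Intensity of a single store
#'
#' Expected number of surviving traces in store `store_index` at memory age
#' `t`, before cue quality is applied. Store 1 follows its decline function
#' directly; higher stores follow the induction cascade (closed form for
#' exponential chains with distinct rates, numeric integration otherwise).
#'
#' @param params a [chain_params()] object.
#' @param store_index which store, `1 <= store_index <= n_stores(params)`.
#' @param t nonnegative time(s) since acquisition.
#' @return Numeric vector of intensities, one per element of `t`.
#' @examples
#' cp <- chain_params(mu = c(1.5, 0.00325), a = c(0.103, 0))
#' store_intensity(cp, 1, 3.5)          # MTL trace intensity after 3.5 days
#' store_intensity(cp, 2, c(10, 100))   # neocortical build-up
#' @export
store_intensity <- function(params, store_index, t) {
  .check_chain(params)
  t <- .check_times(t)
  n <- length(params$mu)
  if (!is.numeric(store_index) || length(store_index) != 1L ||
      store_index < 1 || store_index > n || store_index != round(store_index))
    stop("'store_index' must be a store index between 1 and ", n,
         call. = FALSE)
  .intensity_matrix(params$mu, params$a, params$decline, t)[, store_index]
}

#' Total memory intensity
#'
#' Sum of all store intensities multiplied by cue quality `q`:
#' acquisition x decline x cue quality. When a lesion profile is supplied the
#' intensity is the lesioned one: induction rates are scaled per store, each
#' store's surviving intensity is weighted by `1 - lambda_i`, and the
#' retrieval scale multiplies the cue term.
#'
#' @inheritParams store_intensity
#' @param lesion optional [lesion_profile()].
#' @return Numeric vector of total intensities at `t`.
#' @examples
#' cp <- chain_params(mu = c(2, 0.1), a = c(0.3, 0))
#' total_intensity(cp, c(0, 5))
#' @export
total_intensity <- function(params, t, lesion = NULL) {
  .check_chain(params)
  t <- .check_times(t)
  eff <- .effective(params, lesion)
  m <- .intensity_matrix(eff$mu, eff$a, params$decline, t)
  params$q * eff$retrieval * as.numeric(m %*% eff$w)
}

#' Intensity curves for a vector of times
#'
#' Evaluates every store's intensity and their sum on a time grid, optionally
#' under a lesion profile (whose `1 - lambda` weights and induction scalings
#' are then reflected in the per-store columns).
#'
#' @inheritParams total_intensity
#' @param times nonnegative, nondecreasing time grid.
#' @return An object of class `"intensity_curve"`: list with `times`,
#'   `per_store` (matrix, one column per store) and `total` (row sums).
#'   Cue quality is not folded in; see [total_intensity()].
#' @export
intensity_curve <- function(params, times, lesion = NULL) {
  .check_chain(params)
  times <- .check_times(times)
  if (is.unsorted(times)) stop("'times' must be nondecreasing", call. = FALSE)
  eff <- .effective(params, lesion)
  m <- .intensity_matrix(eff$mu, eff$a, params$decline, times)
  m <- sweep(m, 2L, eff$w, "*") * eff$retrieval
  colnames(m) <- paste0("store", seq_along(eff$mu))
  structure(list(times = times, per_store = m, total = rowSums(m)),
            class = "intensity_curve")
}

#' @export
print.intensity_curve <- function(x, ...) {
  cat("Intensity curve over", length(x$times), "times,",
      ncol(x$per_store), "stores\n")
  df <- data.frame(time = x$times, x$per_store, total = x$total)
  print(utils::head(df, 10L))
  if (length(x$times) > 10L) cat("...\n")
  invisible(x)
}

#' @export
as.data.frame.intensity_curve <- function(x, ...) {
  data.frame(time = x$times, x$per_store, total = x$total)
}

#' @export
plot.intensity_curve <- function(x, ...) {
  graphics::matplot(x$times, cbind(x$per_store, x$total), type = "l",
                    lty = c(rep(2, ncol(x$per_store)), 1),
                    xlab = "time since acquisition", ylab = "intensity", ...)
  graphics::legend("topright", bty = "n",
                   legend = c(colnames(x$per_store), "total"),
                   lty = c(rep(2, ncol(x$per_store)), 1),
                   col = seq_len(ncol(x$per_store) + 1L))
  invisible(x)
}

#' Recall probability
#'
#' The retrieval link `p(t) = g + (1 - g) (1 - e^(-r(t)))`, where `r(t)` is
#' the (possibly lesioned) total intensity. With the default guessing floor
#' `g = 0` this is the canonical `p = 1 - e^(-intensity)`.
#'
#' @inheritParams total_intensity
#' @return Probabilities in `[g, 1)`.
#' @examples
#' cp <- chain_params(mu = c(2, 0.1), a = c(0.3, 0))
#' recall_probability(cp, 0)   # 1 - exp(-2)
#' @export
recall_probability <- function(params, t, lesion = NULL) {
  .check_chain(params)
  r <- total_intensity(params, t, lesion)
  recall_from_intensity(r, params$g)
}

#' Map intensity to recall probability
#'
#' @param r nonnegative intensity (expected surviving trace count).
#' @param g guessing floor in `[0, 1)`.
#' @return `g + (1 - g) (1 - e^(-r))`.
#' @export
recall_from_intensity <- function(r, g = 0) {
  if (any(r < 0)) stop("intensity must be nonnegative", call. = FALSE)
  g + (1 - g) * (1 - exp(-r))
}

#' Map recall probability back to intensity
#'
#' Inverse of the retrieval link at guessing floor `g`:
#' `r = -log(1 - (p - g) / (1 - g))`; with `g = 0` simply `-log(1 - p)`.
#' This transform underlies the relative retrograde gradient: probabilities
#' compress trace strength nonlinearly (a memory recalled with p = 0.90 is
#' more than 150 percent stronger than one recalled with p = 0.60, not 50
#' percent).
#'
#' @param p probabilities in `[g, 1)`.
#' @param g guessing floor in `[0, 1)`.
#' @param strict if `TRUE`, values at or above 1 are an error; otherwise they
#'   are clipped just below 1 with a warning.
#' @return Nonnegative intensities.
#' @examples
#' intensity_from_probability(c(0.60, 0.90))
#' @export
intensity_from_probability <- function(p, g = 0, strict = FALSE) {
  if (!is.numeric(p) || anyNA(p)) stop("'p' must be numeric", call. = FALSE)
  if (any(p < 0)) stop("probabilities must be nonnegative", call. = FALSE)
  if (any(p >= 1)) {
    if (strict) stop("probabilities must be below 1", call. = FALSE)
    warning("probabilities at or above 1 clipped below 1", call. = FALSE)
    p <- pmin(p, 1 - 1e-12)
  }
  if (any(p < g)) stop("probabilities below the guessing floor g",
                       call. = FALSE)
  -log1p(-(p - g) / (1 - g))
}
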