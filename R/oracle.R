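## Independent numeric integration of the decline/induction cascade.
## Serves as the package-internal oracle against which the closed forms are
## verified, and as the automatic fallback for confluent decline rates.

# Integrate the cascade for raw (already induction-scaled) rates.
# Returns the times x stores intensity matrix.
.ode_intensity_matrix <- function(mu, a, decline, times) {
  n <- length(mu)
  times <- as.numeric(times)
  grid <- sort(unique(c(0, times)))
  if (max(grid) == 0) {
    # only t = 0 requested: initial state, no integration needed
    out0 <- matrix(0, length(times), n)
    out0[, 1L] <- mu[1L]
    return(out0)
  }
  if (decline == "power") {
    # store 1 is a known forcing term; integrate stores 2..n
    if (n == 1L)
      return(matrix(mu[1L] * (1 + times)^(-a[1L]), ncol = 1L))
    state <- rep(0, n - 1L)
    names(state) <- paste0("r", 2:n)
    deriv <- function(t, y, parms) {
      r_prev <- c(mu[1L] * (1 + t)^(-a[1L]), y[-length(y)])
      list(mu[-1L] * r_prev - a[-1L] * y)
    }
  } else {
    state <- c(mu[1L], rep(0, n - 1L))
    names(state) <- paste0("r", seq_len(n))
    deriv <- function(t, y, parms) {
      d <- -a * y
      if (n > 1L) d[-1L] <- d[-1L] + mu[-1L] * y[-n]
      list(d)
    }
  }
  sol <- deSolve::ode(y = state, times = grid, func = deriv, parms = NULL,
                      method = "lsoda", rtol = 1e-12, atol = 1e-14)
  if (attr(sol, "istate")[1L] < 0)
    stop("numeric integration of the memory cascade did not converge",
         call. = FALSE)
  sol <- as.matrix(sol)
  idx <- match(times, grid)
  out <- sol[idx, -1L, drop = FALSE]
  if (decline == "power")
    out <- cbind(mu[1L] * (1 + times)^(-a[1L]), out)
  unname(pmax(out, 0))
}

#' Numeric oracle for the intensity cascade
#'
#' Integrates the cascade of store intensities numerically (lsoda, tolerances
#' 1e-12) instead of using the closed forms. Intended for verification and
#' for parameter regions where the distinct-rate closed form is ill
#' conditioned. Intensity lesions and retrieval scaling are applied to the
#' integrated curves; induction-rate scalings enter the equations themselves.
#'
#' @inheritParams total_intensity
#' @param times nonnegative, nondecreasing time grid.
#' @return An `"intensity_curve"` object (see [intensity_curve()]).
#' @examples
#' cp <- chain_params(mu = c(2, 0.1), a = c(0.3, 0.02))
#' oc <- ode_oracle(cp, times = c(0, 1, 5, 20))
#' max(abs(oc$total - intensity_curve(cp, c(0, 1, 5, 20))$total))
#' @export
ode_oracle <- function(params, lesion = NULL, times) {
  .check_chain(params)
  times <- .check_times(times)
  if (is.unsorted(times)) stop("'times' must be nondecreasing", call. = FALSE)
  eff <- .effective(params, lesion)
  m <- .ode_intensity_matrix(eff$mu, eff$a, params$decline, times)
  m <- sweep(m, 2L, eff$w, "*") * eff$retrieval
  colnames(m) <- paste0("store", seq_along(eff$mu))
  structure(list(times = times, per_store = m, total = rowSums(m)),
            class = "intensity_curve")
}
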