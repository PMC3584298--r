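#' Fit the model rr-gradient to a relative retrograde curve
#'
#' Least-squares fit of the two-store model rr-gradient to an observed (or
#' simulated) rr curve. Because the acquired intensity `mu1` and cue quality
#' `q` cancel in the intensity ratio, they are structurally absent from the
#' objective: the estimable parameters are the store-1 decline rate `a1`,
#' the consolidation rate `mu2`, the lesion fractions `lambda1` (and
#' optionally `lambda2`), and the retrieval scale. The conventional default
#' frees `a1`, `mu2`, `lambda1` with `a2 = 0`, `lambda2 = 0`,
#' `retrieval = 1` fixed.
#'
#' At least four points are required. If the best-fitting curve is flat, the
#' decline rate is unidentifiable (the Huntington signature: a pure
#' retrieval deficit); the result is flagged accordingly.
#'
#' @param rr_curve an `"rr_curve"` (from [rr_transform()] or [rr_model()]),
#'   or a data frame with columns `time` and `rr`.
#' @param free subset of `c("a1", "mu2", "lambda1", "lambda2", "retrieval")`.
#' @param fixed named numeric vector fixing any of `a1`, `mu2`, `a2`,
#'   `lambda1`, `lambda2`, `retrieval` (defaults fill in `a2 = 0`,
#'   `lambda2 = 0`, `retrieval = 1`).
#' @param start,lower,upper optional named start values / bound overrides.
#' @param multistart,seed as in [fit_memory_chain()].
#' @return An object of class `c("memory_chain_rr_fit", "memory_chain_fit")`
#'   (the shared methods apply where meaningful); element `flat` flags an
#'   unidentifiable decline rate.
#' @examples
#' cp <- chain_params(mu = c(1, 0.001), a = c(0.108, 0))
#' les <- lesion_profile(lambda = c(0.779, 0))
#' rr <- rr_model(cp, les, times = c(1, 5, 10, 20, 40))
#' fit_rr(rr, multistart = 8)$coefficients
#' @export
fit_rr <- function(rr_curve, free = c("a1", "mu2", "lambda1"),
                   fixed = NULL, start = NULL, lower = NULL, upper = NULL,
                   multistart = 32L, seed = 1L) {
  cl <- match.call()
  rr_curve <- as.data.frame(rr_curve)
  if (!all(c("time", "rr") %in% names(rr_curve)))
    stop("'rr_curve' needs 'time' and 'rr' columns", call. = FALSE)
  times <- .check_times(rr_curve$time)
  rrv <- as.numeric(rr_curve$rr)
  if (anyNA(rrv) || any(!is.finite(rrv)))
    stop("rr values must be finite", call. = FALSE)
  if (length(rrv) < 4L)
    stop("at least four rr points are required", call. = FALSE)

  all_pars <- c("a1", "mu2", "a2", "lambda1", "lambda2", "retrieval")
  unknown <- setdiff(c(free, names(fixed)), all_pars)
  if (length(unknown))
    stop("unknown parameter(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  defaults <- c(a2 = 0, lambda2 = 0, retrieval = 1)
  fx <- defaults
  fx[names(fixed)] <- fixed
  fx <- fx[setdiff(names(fx), free)]
  miss <- setdiff(all_pars, c(free, names(fx)))
  if (length(miss))
    stop("parameter(s) neither free nor fixed: ",
         paste(miss, collapse = ", "), call. = FALSE)
  if (length(free) >= length(rrv))
    stop("under-identified: ", length(free), " free parameters for ",
         length(rrv), " points", call. = FALSE)

  kindof <- function(nm) sub("[0-9]+$", "", nm)
  tab <- data.frame(id = free, kind = vapply(free, kindof, ""),
                    store = NA_integer_, groups = NA_character_,
                    stringsAsFactors = FALSE)
  tab$lower <- vapply(tab$kind, function(k) .default_bounds(k)[1], 0)
  tab$upper <- vapply(tab$kind, function(k) .default_bounds(k)[2], 0)
  for (nm in names(lower)) tab$lower[tab$id == nm] <- lower[[nm]]
  for (nm in names(upper)) tab$upper[tab$id == nm] <- upper[[nm]]

  rr_theta <- function(theta) {
    names(theta) <- tab$id
    val <- function(nm) if (nm %in% tab$id) theta[[nm]] else fx[[nm]]
    cp <- chain_params(mu = c(1, val("mu2")),
                       a = c(val("a1"), val("a2")))
    prof <- lesion_profile(lambda = c(val("lambda1"), val("lambda2")),
                           retrieval = max(val("retrieval"), 1e-12))
    rr_model(cp, prof, times)$rr
  }
  objective <- function(theta) {
    m <- tryCatch(rr_theta(theta), error = function(e) NULL)
    if (is.null(m) || anyNA(m)) return(1e10)
    sum((m - rrv)^2)
  }

  best <- .multistart_optim(objective, tab, start, multistart, seed)
  theta <- stats::setNames(best$par, tab$id)
  fitted_rr <- rr_theta(theta)
  sse <- sum((fitted_rr - rrv)^2)
  sst <- sum((rrv - mean(rrv))^2)
  flat <- diff(range(fitted_rr)) < 1e-6
  if (flat && "a1" %in% free)
    warning("fitted rr-gradient is flat: 'a1' is unidentifiable ",
            "(pure retrieval-deficit signature)", call. = FALSE)

  span <- tab$upper - tab$lower
  at_bound <- (theta - tab$lower) < 1e-6 * span |
    (tab$upper - theta) < 1e-6 * span

  val <- function(nm) if (nm %in% tab$id) theta[[nm]] else fx[[nm]]
  structure(list(
    coefficients = theta,
    par_table = cbind(tab, estimate = unname(theta), at_bound = at_bound),
    chain = chain_params(mu = c(1, val("mu2")), a = c(val("a1"), val("a2"))),
    profiles = list(lesioned = lesion_profile(
      lambda = c(val("lambda1"), val("lambda2")),
      retrieval = max(val("retrieval"), 1e-12))),
    data = data.frame(time = times, rr = rrv),
    fitted = fitted_rr,
    sse = sse,
    r_squared = if (sst > 0) 1 - sse / sst else NA_real_,
    intercept = val("retrieval") * (1 - val("lambda1")),
    flat = flat,
    loss = "sse_rr",
    objective = best$objective,
    convergence = best$convergence,
    message = best$message,
    n_free = nrow(tab),
    multistart = multistart,
    seed = seed,
    call = cl
  ), class = c("memory_chain_rr_fit", "memory_chain_fit"))
}

#' @export
print.memory_chain_rr_fit <- function(x, digits = 4, ...) {
  cat("Memory chain rr-gradient fit (", nrow(x$data), " points, ",
      x$n_free, " free parameters)\n", sep = "")
  print(signif(x$coefficients, digits))
  cat("rr intercept (1 - lambda1, retrieval-scaled):",
      format(x$intercept, digits = digits), "\n")
  cat("SSE =", format(x$sse, digits = digits),
      " R^2 =", format(x$r_squared, digits = digits), "\n")
  if (x$flat)
    cat("NOTE: flat rr-gradient; decline rate unidentifiable ",
        "(retrieval-deficit signature)\n", sep = "")
  invisible(x)
}

#' @export
predict.memory_chain_rr_fit <- function(object, newdata = NULL, ...) {
  times <- if (is.null(newdata)) object$data$time else newdata$time
  rr_model(object$chain, object$profiles$lesioned, times)$rr
}

#' @export
plot.memory_chain_rr_fit <- function(x, npoints = 200, ...) {
  tt <- seq(min(x$data$time), max(x$data$time), length.out = npoints)
  graphics::plot(x$data$time, x$data$rr, pch = 17, ylim = c(0, 1),
                 xlab = "memory age", ylab = "rr", ...)
  graphics::lines(tt, predict(x, data.frame(time = tt)))
  invisible(x)
}
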