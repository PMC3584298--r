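#' @export
print.memory_chain_fit <- function(x, digits = 4, ...) {
  cat("Memory chain fit (", x$loss, " loss, ",
      length(unique(x$data$group)), " group(s), ", nrow(x$data),
      " points, ", x$n_free, " free parameters)\n", sep = "")
  cat("Call: ", deparse(x$call), "\n\n")
  print(signif(x$coefficients, digits))
  cat("\nSSE =", format(x$sse, digits = digits),
      " R^2 =", format(x$r_squared, digits = digits), "\n")
  if (x$convergence != 0)
    cat("NOTE: optimiser did not report clean convergence (",
        x$message, ")\n", sep = "")
  if (any(x$par_table$at_bound))
    cat("NOTE: parameter(s) at bound: ",
        paste(x$par_table$id[x$par_table$at_bound], collapse = ", "),
        "\n", sep = "")
  invisible(x)
}

#' @export
coef.memory_chain_fit <- function(object, ...) object$coefficients

#' @export
fitted.memory_chain_fit <- function(object, ...) object$fitted

#' @rdname fit_memory_chain
#' @param object,x a fitted `"memory_chain_fit"`.
#' @param ... passed on to methods.
#' @export
summary.memory_chain_fit <- function(object, ...) {
  gof <- goodness(object$data$proportion, object$fitted,
                  object$data$trials, n_free = object$n_free)
  a1 <- object$chain$a[1L]
  out <- list(fit = object, gof = gof,
              lifetime = if (a1 > 0) 1 / a1 else NA_real_,
              functional_lesion = .functional_lesions(object))
  class(out) <- "summary.memory_chain_fit"
  out
}

# functional lesion sizes 1 - induction_scale for induction-lesioned groups
.functional_lesions <- function(object) {
  rows <- object$par_table[object$par_table$kind == "induction", ,
                           drop = FALSE]
  if (!nrow(rows)) return(NULL)
  stats::setNames(1 - rows$estimate, rows$id)
}

#' @export
print.summary.memory_chain_fit <- function(x, digits = 4, ...) {
  print(x$fit, digits = digits)
  cat("\nGoodness of fit: SSE =", format(x$gof$sse, digits = digits),
      " R^2 =", format(x$gof$r_squared, digits = digits))
  if (is.finite(x$gof$chisq))
    cat("  chi^2(", x$gof$df, ") = ", format(x$gof$chisq, digits = digits),
        ", p = ", format(x$gof$chisq_p, digits = 3), sep = "")
  cat("\n")
  if (is.finite(x$lifetime))
    cat("Expected MTL trace lifetime 1/a1 =",
        formatC(x$lifetime, format = "f", digits = 1), "time units\n")
  if (!is.null(x$functional_lesion)) {
    cat("Functional lesion sizes (1 - induction scale):\n")
    print(round(x$functional_lesion, digits))
  }
  invisible(x)
}

#' @rdname fit_memory_chain
#' @param newdata optional data frame with columns `group` and `time`;
#'   defaults to the fitted points.
#' @param type `"response"` for recall probabilities, `"intensity"` for
#'   total (lesioned) intensities.
#' @export
predict.memory_chain_fit <- function(object, newdata = NULL,
                                     type = c("response", "intensity"),
                                     ...) {
  type <- match.arg(type)
  if (is.null(newdata)) newdata <- object$data
  if (!all(c("group", "time") %in% names(newdata)))
    stop("'newdata' needs 'group' and 'time' columns", call. = FALSE)
  unknown <- setdiff(unique(newdata$group), names(object$profiles))
  if (length(unknown))
    stop("unknown group(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  out <- numeric(nrow(newdata))
  for (gname in unique(newdata$group)) {
    idx <- newdata$group == gname
    prof <- object$profiles[[gname]]
    out[idx] <- if (type == "response") {
      recall_probability(object$chain, newdata$time[idx], prof)
    } else {
      total_intensity(object$chain, newdata$time[idx], prof)
    }
  }
  out
}

#' @export
residuals.memory_chain_fit <- function(object,
                                       type = c("response", "pearson"),
                                       ...) {
  type <- match.arg(type)
  r <- object$data$proportion - object$fitted
  if (type == "pearson") {
    if (anyNA(object$data$trials))
      stop("pearson residuals require trial counts", call. = FALSE)
    r <- r / sqrt(object$fitted * (1 - object$fitted) / object$data$trials)
  }
  r
}

#' @export
simulate.memory_chain_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (anyNA(object$data$trials))
    stop("simulation requires trial counts", call. = FALSE)
  p <- object$fitted
  .with_seed(seed, {
    lapply(seq_len(nsim), function(s) {
      d <- as.data.frame(object$data)
      d$successes <- stats::rbinom(nrow(d), d$trials, p)
      retention_data(d[, c("group", "time", "successes", "trials")])
    })
  })
}

#' @export
plot.memory_chain_fit <- function(x, npoints = 200, ...) {
  d <- x$data
  groups <- unique(d$group)
  cols <- grDevices::hcl.colors(max(3L, length(groups)), "Dark 3")
  tt <- seq(min(d$time), max(d$time), length.out = npoints)
  graphics::plot(NA, xlim = range(d$time), ylim = c(0, 1),
                 xlab = "time since learning", ylab = "recall probability",
                 ...)
  for (i in seq_along(groups)) {
    gi <- d$group == groups[i]
    graphics::points(d$time[gi], d$proportion[gi], col = cols[i], pch = 16)
    pp <- predict(x, data.frame(group = groups[i], time = tt))
    graphics::lines(tt, pp, col = cols[i])
  }
  graphics::legend("topright", legend = groups, col = cols[seq_along(groups)],
                   pch = 16, lty = 1, bty = "n")
  invisible(x)
}
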