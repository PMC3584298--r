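#' Memory chain parameters
#'
#' Constructs the parameter set of a memory chain: an ordered cascade of
#' memory stores in which trace intensity declines at a constant rate while
#' inducing traces in the next store. Store 1 is the first store engaged by
#' the material under study (the hippocampus/MTL in two-store retrograde
#' analyses, working memory in short-delay anterograde analyses); the last
#' store is typically the neocortex.
#'
#' `mu[1]` is the intensity acquired during a single learning episode
#' (expected number of traces laid down in store 1); `mu[i]` for `i > 1` is
#' the induction (consolidation) rate into store `i` per unit of donor
#' intensity per unit time. `a[i]` is the decline rate of store `i` in
#' inverse time units. Time units are whatever the data use (seconds, days,
#' years); the package never converts them.
#'
#' Cue quality `q` scales the total chain intensity once (acquisition x
#' decline x cue quality), and the optional guessing floor `g` maps a task's
#' chance level into the retrieval link, `p = g + (1 - g) (1 - e^-r)`. With
#' the default `g = 0` the link is exactly `p = 1 - e^-r`.
#'
#' @param mu numeric vector of nonnegative acquisition/induction rates, one
#'   per store.
#' @param a numeric vector of nonnegative decline rates, same length as `mu`.
#' @param q cue quality, positive scalar; default 1.
#' @param g chance-guessing floor in `[0, 1)`; default 0.
#' @param decline decline kind of store 1: `"exponential"` (survival
#'   `e^(-a1 t)`) or `"power"` (survival `(1 + t)^(-a1)`, finite at `t = 0`).
#'   Stores beyond the first always decline exponentially.
#' @return An object of class `"chain_params"`.
#' @examples
#' # Two-store chain: hippocampus declining at 0.3/day, slow consolidation
#' cp <- chain_params(mu = c(2, 0.1), a = c(0.3, 0))
#' recall_probability(cp, t = c(0, 5, 30))
#' @seealso [total_intensity()], [recall_probability()], [lesion_profile()]
#' @export
chain_params <- function(mu, a, q = 1, g = 0,
                         decline = c("exponential", "power")) {
  decline <- match.arg(decline)
  mu <- as.numeric(mu)
  a <- as.numeric(a)
  if (length(mu) < 1L) stop("at least one store is required", call. = FALSE)
  if (length(mu) != length(a))
    stop("'mu' and 'a' must have one entry per store", call. = FALSE)
  if (anyNA(mu) || anyNA(a)) stop("store rates must not be NA", call. = FALSE)
  if (any(mu < 0)) stop("'mu' must be nonnegative", call. = FALSE)
  if (any(a < 0)) stop("'a' must be nonnegative", call. = FALSE)
  if (!is.numeric(q) || length(q) != 1L || q <= 0)
    stop("'q' must be a positive scalar", call. = FALSE)
  if (!is.numeric(g) || length(g) != 1L || g < 0 || g >= 1)
    stop("'g' must lie in [0, 1)", call. = FALSE)
  structure(
    list(mu = mu, a = a, q = q, g = g, decline = decline),
    class = "chain_params"
  )
}

#' @export
print.chain_params <- function(x, digits = 4, ...) {
  n <- length(x$mu)
  cat("Memory chain (", n, if (n == 1L) " store" else " stores",
      ", ", x$decline, " decline in store 1)\n", sep = "")
  tab <- rbind(mu = x$mu, a = x$a)
  colnames(tab) <- paste0("store", seq_len(n))
  print(signif(tab, digits))
  cat("cue quality q =", format(x$q, digits = digits),
      " guessing floor g =", format(x$g, digits = digits), "\n")
  invisible(x)
}

#' Number of stores in a chain
#' @param params a [chain_params()] object.
#' @return Integer store count.
#' @export
n_stores <- function(params) {
  stopifnot(inherits(params, "chain_params"))
  length(params$mu)
}

.check_chain <- function(params) {
  if (!inherits(params, "chain_params"))
    stop("'params' must be a chain_params object", call. = FALSE)
  invisible(params)
}

.check_times <- function(t) {
  if (!is.numeric(t) || anyNA(t)) stop("times must be numeric", call. = FALSE)
  if (any(t < 0)) stop("times must be nonnegative", call. = FALSE)
  invisible(as.numeric(t))
}
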