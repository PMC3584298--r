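#' Lesion profile
#'
#' Describes how a pathology or experimental lesion transforms an intact
#' memory chain. Three mechanisms, usable together:
#'
#' * `lambda`: per-store fraction of intensity destroyed at lesion time
#'   (`0` intact, `1` full lesion) — the retrograde mechanism; the store-1
#'   entry is the classic hippocampal lesion parameter.
#' * `induction`: per-store multipliers in `[0, 1]` on the acquisition /
#'   induction rates `mu` — the functional (anterograde) mechanism, e.g. a
#'   reduced working-memory-to-MTL learning rate.
#' * `retrieval`: multiplier in `(0, 1]` on cue quality — a pure retrieval
#'   deficit (the Huntington mechanism).
#'
#' Entries may be `NA` to mark a parameter as free for estimation in
#' [fit_memory_chain()]. Vectors shorter than the chain are padded with the
#' identity (`lambda = 0`, `induction = 1`).
#'
#' @param lambda numeric vector of intensity-lesion fractions in `[0, 1]`
#'   (or `NA`).
#' @param induction numeric vector of induction-rate multipliers in `[0, 1]`
#'   (or `NA`).
#' @param retrieval cue-quality multiplier in `(0, 1]` (or `NA`).
#' @param t_lesion memory age at lesion, or `NULL` for "at test" (the usual
#'   simplification when post-lesion forgetting is negligible).
#' @return An object of class `"lesion_profile"`.
#' @examples
#' lesion_profile()                      # identity: no deficit
#' lesion_profile(lambda = c(1, 0))     # full store-1 (hippocampal) lesion
#' @seealso [pathology_profile()], [ribot_gradient()]
#' @export
lesion_profile <- function(lambda = 0, induction = 1, retrieval = 1,
                           t_lesion = NULL) {
  lambda <- as.numeric(lambda)
  induction <- as.numeric(induction)
  ok01 <- function(x) all(is.na(x) | (x >= 0 & x <= 1))
  if (!ok01(lambda)) stop("'lambda' entries must lie in [0, 1]", call. = FALSE)
  if (!ok01(induction))
    stop("'induction' entries must lie in [0, 1]", call. = FALSE)
  if (length(retrieval) != 1L ||
      (!is.na(retrieval) && (retrieval <= 0 || retrieval > 1)))
    stop("'retrieval' must be a scalar in (0, 1]", call. = FALSE)
  if (!is.null(t_lesion)) {
    if (!is.numeric(t_lesion) || length(t_lesion) != 1L || t_lesion < 0)
      stop("'t_lesion' must be a nonnegative scalar or NULL", call. = FALSE)
  }
  structure(
    list(lambda = lambda, induction = induction,
         retrieval = as.numeric(retrieval), t_lesion = t_lesion),
    class = "lesion_profile"
  )
}

#' @export
print.lesion_profile <- function(x, ...) {
  cat("Lesion profile\n")
  cat("  intensity lesion lambda:", paste(format(x$lambda), collapse = ", "),
      "\n")
  cat("  induction scaling:      ", paste(format(x$induction), collapse = ", "),
      "\n")
  cat("  retrieval scaling:      ", format(x$retrieval), "\n")
  cat("  lesion time:            ",
      if (is.null(x$t_lesion)) "at test" else format(x$t_lesion), "\n")
  invisible(x)
}

.is_identity_lesion <- function(lesion) {
  is.null(lesion) ||
    (all(!is.na(lesion$lambda)) && all(lesion$lambda == 0) &&
       all(!is.na(lesion$induction)) && all(lesion$induction == 1) &&
       !is.na(lesion$retrieval) && lesion$retrieval == 1)
}

#' Named pathology profiles
#'
#' Standard clinical lesion profiles for the two-store
#' (hippocampus/MTL -> neocortex) chain:
#'
#' * `korsakoff`: partial elimination of the hippocampal store,
#'   `lambda = c(lambda, 0)`.
#' * `alzheimer`: hippocampal lesion plus a lowered neocortical intensity,
#'   `lambda = c(lambda, lambda2)`.
#' * `huntington`: intact storage, impaired retrieval — cue quality scaled
#'   by `q_H`, producing a flat relative retrograde gradient at height `q_H`.
#' * `custom`: arguments passed straight to [lesion_profile()].
#'
#' @param name one of `"korsakoff"`, `"alzheimer"`, `"huntington"`,
#'   `"custom"`.
#' @param lambda hippocampal (store 1) lesion fraction.
#' @param lambda2 neocortical (store 2) lesion fraction (Alzheimer).
#' @param q_H reduced retrieval-cue parameter in `(0, 1]` (Huntington).
#' @param ... further arguments for `name = "custom"`.
#' @return A [lesion_profile()].
#' @examples
#' pathology_profile("korsakoff", lambda = 0.94)
#' pathology_profile("huntington", q_H = 0.6)
#' @export
pathology_profile <- function(name = c("korsakoff", "alzheimer",
                                       "huntington", "custom"),
                              lambda = NULL, lambda2 = NULL, q_H = NULL,
                              ...) {
  name <- match.arg(name)
  switch(
    name,
    korsakoff = {
      if (is.null(lambda))
        stop("korsakoff requires 'lambda'", call. = FALSE)
      lesion_profile(lambda = c(lambda, 0))
    },
    alzheimer = {
      if (is.null(lambda) || is.null(lambda2))
        stop("alzheimer requires 'lambda' and 'lambda2'", call. = FALSE)
      lesion_profile(lambda = c(lambda, lambda2))
    },
    huntington = {
      if (is.null(q_H))
        stop("huntington requires 'q_H'", call. = FALSE)
      lesion_profile(retrieval = q_H)
    },
    custom = lesion_profile(...)
  )
}

#' Lesioned total intensity
#'
#' Total chain intensity under a lesion profile,
#' `q * retrieval * sum_i (1 - lambda_i) r_i(t)`, with `r_i` computed from
#' induction-scaled rates. Equivalent to `total_intensity(params, t, lesion)`.
#'
#' @inheritParams total_intensity
#' @param lesion a [lesion_profile()].
#' @return Numeric vector of lesioned intensities.
#' @export
lesioned_intensity <- function(params, lesion, t) {
  total_intensity(params, t, lesion)
}

#' Ribot (retrograde amnesia) gradient
#'
#' Recall probability as a function of memory age at lesion time. With a
#' full store-1 lesion and no neocortical decline this is
#' `1 - exp(-(mu1 mu2 / a1)(1 - e^(-a1 t)))`: older memories survive better
#' (Ribot's Law), because only the consolidated neocortical intensity
#' remains.
#'
#' @inheritParams total_intensity
#' @param lesion a [lesion_profile()].
#' @param times nonnegative memory ages at the time of the lesion.
#' @return Vector of recall probabilities.
#' @examples
#' cp <- chain_params(mu = c(2, 0.1), a = c(0.3, 0))
#' ribot_gradient(cp, lesion_profile(lambda = c(1, 0)), times = c(1, 5, 20))
#' @export
ribot_gradient <- function(params, lesion, times) {
  recall_probability(params, .check_times(times), lesion)
}

#' Post-lesion decay of memory intensity
#'
#' After the lesion no new consolidation occurs; the surviving intensity
#' only declines at the final store's rate:
#' `r_lesioned(t_l) * exp(-a_last * tau)`, where `tau` is the time elapsed
#' since the lesion. With a final-store decline rate of zero the curve is
#' flat in `tau` (post-lesion forgetting negligible).
#'
#' @inheritParams total_intensity
#' @param lesion a [lesion_profile()].
#' @param t_l memory age at the moment of the lesion.
#' @param tau nonnegative time(s) elapsed since the lesion.
#' @return Intensities at `t_l + tau`.
#' @export
post_lesion_decay <- function(params, lesion, t_l, tau) {
  .check_chain(params)
  t_l <- .check_times(t_l)
  tau <- .check_times(tau)
  a_last <- params$a[length(params$a)]
  total_intensity(params, t_l, lesion) * exp(-a_last * tau)
}
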