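## Synthetic-data generators: binomial retention datasets from a generative
## chain (with per-time-point item-difficulty distortion), and an exact
## event-driven trace-level simulator that ties the trace narrative to the
## closed-form intensity/probability curves.

# run expr with a reproducible, locally-scoped RNG state
.with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (has_old) old <- get(".Random.seed", envir = globalenv())
    on.exit({
      if (has_old) assign(".Random.seed", old, envir = globalenv())
      else rm(".Random.seed", envir = globalenv())
    })
    set.seed(seed)
  }
  expr
}

#' Simulate a binomial retention dataset
#'
#' Draws `successes ~ Binomial(n, p(t))` independently per point from the
#' exact model probabilities of each group's (possibly lesioned) chain.
#' Per-time-point difficulty multipliers emulate non-counterbalanced test
#' items: a multiplier `d` on the acquired intensity `mu1` (or on cue
#' quality) scales the whole linear cascade, so the distorted intensity is
#' `d(t) * r(t)`, applied identically to every group — exactly the
#' manipulation the relative retrograde gradient is immune to.
#'
#' @param params generative [chain_params()].
#' @param times retention lags (shared by all groups).
#' @param n trials per point (recycled over `times`).
#' @param lesions named list of [lesion_profile()] objects (or `NULL` for an
#'   intact group), one per group.
#' @param distortion optional positive multipliers on `mu1` per time point
#'   (recycled), the item-difficulty distortion.
#' @param seed mandatory integer seed.
#' @return A [retention_data()] object.
#' @examples
#' cp <- chain_params(mu = c(2, 0.1), a = c(0.3, 0))
#' simulate_retention(cp, times = c(1, 3, 7, 14), n = 30,
#'                    lesions = list(control = NULL,
#'                                   lesion = lesion_profile(lambda = c(1, 0))),
#'                    seed = 42)
#' @export
simulate_retention <- function(params, times, n,
                               lesions = list(control = NULL),
                               distortion = NULL, seed) {
  .check_chain(params)
  times <- .check_times(times)
  if (missing(seed) || is.null(seed))
    stop("'seed' is mandatory for simulation", call. = FALSE)
  if (is.null(names(lesions)) || any(!nzchar(names(lesions))))
    stop("'lesions' must be a named list (one entry per group)",
         call. = FALSE)
  n <- rep_len(as.integer(n), length(times))
  if (any(n < 1L)) stop("'n' must be positive", call. = FALSE)
  d <- if (is.null(distortion)) rep(1, length(times)) else
    rep_len(as.numeric(distortion), length(times))
  if (any(d <= 0)) stop("difficulty multipliers must be positive",
                        call. = FALSE)
  .with_seed(seed, {
    rows <- lapply(names(lesions), function(gname) {
      r <- total_intensity(params, times, lesions[[gname]]) * d
      p <- recall_from_intensity(r, params$g)
      data.frame(group = gname, time = times,
                 successes = stats::rbinom(length(times), n, p),
                 trials = n)
    })
    retention_data(do.call(rbind, rows))
  })
}

#' Event-driven trace-level Monte Carlo
#'
#' Simulates the trace process of a one- or two-store chain directly and
#' returns empirical mean surviving trace counts per store and the recall
#' frequency (recall = at least one surviving trace found by the cue).
#'
#' The default `induction = "poisson"` mechanism realises each store as a
#' Poisson point process: store-1 traces number `Poisson(mu1)` with
#' independent decline (survival `e^(-a1 t)`, or the power law); store-2
#' trace formation is an inhomogeneous Poisson process whose rate tracks the
#' donor intensity, simulated exactly by thinning a homogeneous
#' `mu1 mu2`-rate process against the store-1 survival law, each formed
#' trace then surviving to `t` with probability `e^(-a2 (t - s))`. All event
#' times are drawn exactly (no time stepping), only the primitive rates and
#' survival laws enter, and every store's count is exactly Poisson — the
#' construction under which `P(recall) = 1 - e^(-q r)` holds identically.
#'
#' `induction = "branching"` instead lets each individual store-1 trace
#' spawn store-2 traces at rate `mu2` while it lives. The mean counts are
#' identical, but parent-child clustering overdisperses the store-2 count,
#' so recall frequency falls below `1 - e^(-q r)` when `mu2/a1` is not
#' small; the variant is provided to make that distinction measurable.
#'
#' Intensity lesions remove each surviving store-`i` trace with probability
#' `lambda_i` at test; induction scalings multiply the rates; the retrieval
#' scale and cue quality `q` thin the surviving traces at retrieval.
#'
#' @param params a one- or two-store [chain_params()].
#' @param lesion optional [lesion_profile()].
#' @param t single nonnegative test time.
#' @param replicates number of independent item replicates.
#' @param seed mandatory integer seed.
#' @param induction `"poisson"` (exact Poisson flow, default) or
#'   `"branching"` (per-parent spawning).
#' @return List with `mean_counts` (per store, after lesion, before cue
#'   thinning), `recall_frequency`, `recall_se`, `replicates`.
#' @examples
#' cp <- chain_params(mu = c(2, 0.1), a = c(0.3, 0))
#' sim <- simulate_traces(cp, t = 5, replicates = 2e4, seed = 7)
#' c(sim$recall_frequency, recall_probability(cp, 5))
#' @export
simulate_traces <- function(params, lesion = NULL, t, replicates = 1e5,
                            seed, induction = c("poisson", "branching")) {
  .check_chain(params)
  induction <- match.arg(induction)
  t <- .check_times(t)
  if (length(t) != 1L) stop("'t' must be a single time", call. = FALSE)
  if (missing(seed) || is.null(seed))
    stop("'seed' is mandatory for simulation", call. = FALSE)
  replicates <- as.integer(replicates)
  if (replicates < 1L) stop("'replicates' must be positive", call. = FALSE)
  ns <- length(params$mu)
  if (ns > 2L)
    stop("the trace simulator supports chains of one or two stores",
         call. = FALSE)
  eff <- .effective(params, lesion)
  mu1 <- eff$mu[1L]; a1 <- params$a[1L]
  mu2 <- if (ns == 2L) eff$mu[2L] else 0
  a2 <- if (ns == 2L) params$a[2L] else 0
  keep <- eff$w                      # 1 - lambda per store
  q_eff <- min(1, params$q * eff$retrieval)
  if (params$q * eff$retrieval > 1)
    warning("effective cue quality above 1 truncated to 1 for trace ",
            "thinning", call. = FALSE)

  .with_seed(seed, {
    ## store 1: Poisson initial count, exact survival to t
    n1 <- stats::rpois(replicates, mu1)
    s1t <- .survival1(a1, params$decline, t)
    surv1 <- stats::rbinom(replicates, n1, s1t)

    surv2 <- integer(replicates)
    if (ns == 2L && mu2 > 0 && t > 0) {
      if (induction == "poisson") {
        ## candidate births: homogeneous Poisson(mu1*mu2) on [0, t], thinned
        ## by the store-1 survival law to rate mu1 mu2 S1(s)
        ncand <- stats::rpois(replicates, mu1 * mu2 * t)
        tot <- sum(ncand)
        if (tot > 0) {
          rep_id <- rep.int(seq_len(replicates), ncand)
          s <- stats::runif(tot, 0, t)
          p_keep <- .survival1(a1, params$decline, s) * exp(-a2 * (t - s))
          alive <- stats::runif(tot) < p_keep
          surv2 <- tabulate(rep_id[alive], nbins = replicates)
        }
      } else {
        ## per-parent branching: children at rate mu2 while the parent lives
        tot1 <- sum(n1)
        if (tot1 > 0) {
          rep_id1 <- rep.int(seq_len(replicates), n1)
          life <- if (params$decline == "power") {
            stats::runif(tot1)^(-1 / a1) - 1     # inverse of (1+L)^(-a1)
          } else stats::rexp(tot1, a1)
          active <- pmin(life, t)
          kids <- stats::rpois(tot1, mu2 * active)
          totk <- sum(kids)
          if (totk > 0) {
            par_id <- rep.int(seq_len(tot1), kids)
            birth <- stats::runif(totk) * active[par_id]
            alive <- stats::runif(totk) < exp(-a2 * (t - birth))
            surv2 <- tabulate(rep_id1[par_id[alive]], nbins = replicates)
          }
        }
      }
    }

    ## intensity lesion: independent destruction of surviving traces
    if (keep[1L] < 1) surv1 <- stats::rbinom(replicates, surv1, keep[1L])
    if (ns == 2L && keep[2L] < 1)
      surv2 <- stats::rbinom(replicates, surv2, keep[2L])

    ## retrieval: cue-quality thinning; recall iff >= 1 trace found
    found <- stats::rbinom(replicates, surv1 + surv2, q_eff)
    freq <- mean(found >= 1L)
    list(
      mean_counts = if (ns == 2L) c(store1 = mean(surv1),
                                    store2 = mean(surv2))
           else c(store1 = mean(surv1)),
      recall_frequency = freq,
      recall_se = sqrt(freq * (1 - freq) / replicates),
      replicates = replicates
    )
  })
}
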