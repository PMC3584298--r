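## Simultaneous nonlinear fitting of control + lesioned retention curves.
## Chain parameters (mu_i, a_i) are shared across groups, as in simultaneous
## control/patient fits; per-group lesion parameters are freed by marking
## them NA in that group's lesion profile, optionally shared across groups.

.default_bounds <- function(kind) {
  switch(kind,
         mu = c(0, 100),
         a = c(0, 10),
         lambda = c(0, 1),
         induction = c(0, 1),
         retrieval = c(1e-6, 1),
         stop("unknown parameter kind: ", kind))
}

.kind_scale <- function(kind) {
  # rate-type parameters span decades; multistarts draw them log-uniformly
  if (kind %in% c("mu", "a")) "rate" else "fraction"
}

# build the free-parameter table for fit_memory_chain
.build_par_table <- function(n, free, fixed, lesions, share, lower, upper) {
  chain_names <- c(paste0("mu", seq_len(n)), paste0("a", seq_len(n)))
  unknown <- setdiff(free, chain_names)
  if (length(unknown))
    stop("unknown free parameter(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  unknown <- setdiff(names(fixed), chain_names)
  if (length(unknown))
    stop("unknown fixed parameter(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  both <- intersect(free, names(fixed))
  if (length(both))
    stop("parameter(s) both free and fixed: ", paste(both, collapse = ", "),
         call. = FALSE)
  miss <- setdiff(chain_names, c(free, names(fixed)))
  if (length(miss))
    stop("chain parameter(s) neither free nor fixed: ",
         paste(miss, collapse = ", "), call. = FALSE)

  tab <- data.frame(id = character(), kind = character(), store = integer(),
                    groups = character(), stringsAsFactors = FALSE)
  add <- function(id, kind, store, groups) {
    tab <<- rbind(tab, data.frame(id = id, kind = kind, store = store,
                                  groups = groups, stringsAsFactors = FALSE))
  }
  for (nm in free) {
    kind <- sub("[0-9]+$", "", nm)
    add(nm, kind, as.integer(sub("^[a-z]+", "", nm)), NA_character_)
  }

  # free lesion parameters: NA slots in the profiles
  shared_done <- character()
  for (gname in names(lesions)) {
    prof <- lesions[[gname]]
    if (is.null(prof)) next
    slots <- list(lambda = .pad(prof$lambda, n, 0),
                  induction = .pad(prof$induction, n, 1),
                  retrieval = prof$retrieval)
    for (field in c("lambda", "induction")) {
      for (i in which(is.na(slots[[field]]))) {
        base <- paste0(field, i)
        sh <- share[[base]]
        if (!is.null(sh) && gname %in% sh) {
          id <- paste0(base, ":", paste(sort(sh), collapse = "+"))
          if (id %in% shared_done) next
          shared_done <- c(shared_done, id)
          add(id, field, i, paste(sort(sh), collapse = "+"))
        } else {
          add(paste0(base, ":", gname), field, i, gname)
        }
      }
    }
    if (is.na(slots$retrieval)) {
      sh <- share[["retrieval"]]
      if (!is.null(sh) && gname %in% sh) {
        id <- paste0("retrieval:", paste(sort(sh), collapse = "+"))
        if (!(id %in% shared_done)) {
          shared_done <- c(shared_done, id)
          add(id, "retrieval", NA_integer_, paste(sort(sh), collapse = "+"))
        }
      } else {
        add(paste0("retrieval:", gname), "retrieval", NA_integer_, gname)
      }
    }
  }

  tab$lower <- vapply(tab$kind, function(k) .default_bounds(k)[1], 0)
  tab$upper <- vapply(tab$kind, function(k) .default_bounds(k)[2], 0)
  for (nm in names(lower)) {
    hit <- tab$id == nm | sub(":.*$", "", tab$id) == nm
    tab$lower[hit] <- lower[[nm]]
  }
  for (nm in names(upper)) {
    hit <- tab$id == nm | sub(":.*$", "", tab$id) == nm
    tab$upper[hit] <- upper[[nm]]
  }
  if (any(!is.finite(tab$lower)) || any(!is.finite(tab$upper)))
    stop("every free parameter needs finite bounds", call. = FALSE)
  tab
}

# complete a group's lesion profile from the parameter vector theta
.complete_profile <- function(prof, gname, n, tab, theta) {
  if (is.null(prof)) return(NULL)
  lam <- .pad(prof$lambda, n, 0)
  ind <- .pad(prof$induction, n, 1)
  ret <- prof$retrieval
  pick <- function(field, i) {
    rows <- which(tab$kind == field &
                    (is.na(tab$store) | tab$store == i) &
                    !is.na(tab$groups) &
                    vapply(strsplit(tab$groups, "\\+"),
                           function(gs) gname %in% gs, TRUE))
    if (length(rows) != 1L)
      stop("cannot resolve free ", field, " for group ", gname,
           call. = FALSE)
    theta[[tab$id[rows]]]
  }
  for (i in which(is.na(lam))) lam[i] <- pick("lambda", i)
  for (i in which(is.na(ind))) ind[i] <- pick("induction", i)
  if (is.na(ret)) ret <- pick("retrieval", NA_integer_)
  lesion_profile(lambda = lam, induction = ind,
                 retrieval = max(ret, 1e-12), t_lesion = prof$t_lesion)
}

# bounded multistart minimisation; rate-kind parameters drawn log-uniformly
.multistart_optim <- function(objective, tab, start, multistart, seed) {
  k <- nrow(tab)
  lo <- tab$lower
  hi <- tab$upper
  .with_seed(seed, {
    u <- lhs::randomLHS(max(multistart, 1L), k)
    starts <- matrix(NA_real_, nrow(u), k)
    for (j in seq_len(k)) {
      if (.kind_scale(tab$kind[j]) == "rate") {
        llo <- log(max(lo[j], 1e-4))
        lhi <- log(max(hi[j], 1e-3))
        starts[, j] <- pmin(pmax(exp(llo + u[, j] * (lhi - llo)), lo[j]),
                            hi[j])
      } else {
        starts[, j] <- lo[j] + u[, j] * (hi[j] - lo[j])
      }
    }
    if (!is.null(start)) {
      s0 <- rep(NA_real_, k)
      names(s0) <- tab$id
      for (nm in names(start)) {
        hit <- tab$id == nm | sub(":.*$", "", tab$id) == nm
        s0[hit] <- start[[nm]]
      }
      if (anyNA(s0))
        stop("'start' must supply a value for every free parameter",
             call. = FALSE)
      starts[1L, ] <- pmin(pmax(s0, lo), hi)
    }
    best <- NULL
    for (s in seq_len(nrow(starts))) {
      res <- tryCatch(
        stats::nlminb(starts[s, ], objective, lower = lo, upper = hi,
                      control = list(iter.max = 500, eval.max = 1000)),
        error = function(e) NULL)
      if (is.null(res)) next
      if (is.null(best) || res$objective < best$objective) best <- res
    }
    if (is.null(best))
      stop("optimisation failed from every start", call. = FALSE)
    best
  })
}

#' Fit a memory chain model to retention data
#'
#' Simultaneously fits control and lesioned retention curves by bounded
#' nonlinear least squares on proportions (or binomial maximum likelihood).
#' Chain parameters (`mu1`, `a1`, `mu2`, `a2`, ...) are shared across all
#' groups; each group differs only through its lesion profile, whose `NA`
#' entries are estimated (per group, or shared across a set of groups via
#' `share`). Every chain parameter must be declared either `free` or
#' `fixed`.
#'
#' @param data a [retention_data()] object or a data frame accepted by it.
#' @param lesions named list of [lesion_profile()] objects keyed by group
#'   name (`NULL` entries mean an intact chain). Groups absent from the list
#'   are intact. `NA` entries mark free lesion parameters.
#' @param n_stores number of stores in the chain (default 2).
#' @param free character vector of free chain parameters.
#' @param fixed named numeric vector of fixed chain parameters.
#' @param share named list: for a lesion parameter name (e.g. `"lambda1"`),
#'   a character vector of groups that share one estimated value.
#' @param q,g cue quality and guessing floor (fixed, defaults 1 and 0).
#' @param decline store-1 decline kind, `"exponential"` or `"power"`.
#' @param loss `"sse"` (unweighted least squares on proportions, default) or
#'   `"binomial"` (negative binomial log-likelihood; requires trial counts).
#' @param start optional named start values (used as the first start).
#' @param lower,upper optional named bound overrides.
#' @param multistart number of latin-hypercube starting points (default 32).
#' @param seed integer seed controlling the multistart draw (fits are
#'   deterministic given data, specification and seed).
#' @return An object of class `"memory_chain_fit"` with
#'   print/summary/coef/predict/fitted/residuals/plot/simulate methods.
#'   `R^2` is pooled over all fitted points, `1 - SSE/SST` with `SST` about
#'   the pooled grand mean.
#' @examples
#' cp <- chain_params(mu = c(1.5, 0.00325), a = c(0.103, 0))
#' les <- list(control = NULL, lesion = lesion_profile(lambda = c(1, 0)))
#' dat <- simulate_retention(cp, times = c(3.5, 7, 14, 28), n = 100,
#'                           lesions = les, seed = 1)
#' fit <- fit_memory_chain(dat, lesions = les, multistart = 8)
#' coef(fit)
#' @export
fit_memory_chain <- function(data, lesions = NULL, n_stores = 2L,
                             free = c("mu1", "a1", "mu2"),
                             fixed = c(a2 = 0),
                             share = NULL, q = 1, g = 0,
                             decline = c("exponential", "power"),
                             loss = c("sse", "binomial"),
                             start = NULL, lower = NULL, upper = NULL,
                             multistart = 32L, seed = 1L) {
  cl <- match.call()
  decline <- match.arg(decline)
  loss <- match.arg(loss)
  data <- retention_data(data)
  groups <- unique(data$group)
  if (is.null(lesions)) lesions <- stats::setNames(
    vector("list", length(groups)), groups)
  extra <- setdiff(names(lesions), groups)
  if (length(extra))
    stop("lesion profiles for unknown group(s): ",
         paste(extra, collapse = ", "), call. = FALSE)
  for (gname in setdiff(groups, names(lesions))) lesions[gname] <- list(NULL)
  lesions <- lesions[groups]
  n <- as.integer(n_stores)

  tab <- .build_par_table(n, free, fixed, lesions, share, lower, upper)
  k <- nrow(tab)
  if (k == 0L) stop("no free parameters to estimate", call. = FALSE)
  if (k >= nrow(data))
    stop("under-identified: ", k, " free parameters for ", nrow(data),
         " data points", call. = FALSE)
  if (loss == "binomial" && anyNA(data$trials))
    stop("binomial loss requires trial counts", call. = FALSE)

  g_idx <- split(seq_len(nrow(data)), data$group)[groups]
  obs <- data$proportion

  predict_theta <- function(theta) {
    names(theta) <- tab$id
    mu <- vapply(paste0("mu", seq_len(n)), function(nm)
      if (nm %in% tab$id) theta[[nm]] else fixed[[nm]], 0)
    a <- vapply(paste0("a", seq_len(n)), function(nm)
      if (nm %in% tab$id) theta[[nm]] else fixed[[nm]], 0)
    cp <- chain_params(mu = mu, a = a, q = q, g = g, decline = decline)
    p <- numeric(nrow(data))
    for (gname in groups) {
      prof <- .complete_profile(lesions[[gname]], gname, n, tab, theta)
      idx <- g_idx[[gname]]
      p[idx] <- recall_probability(cp, data$time[idx], prof)
    }
    p
  }

  objective <- if (loss == "sse") {
    function(theta) {
      p <- tryCatch(predict_theta(theta), error = function(e) NULL)
      if (is.null(p) || anyNA(p)) return(1e10)
      sum((p - obs)^2)
    }
  } else {
    function(theta) {
      p <- tryCatch(predict_theta(theta), error = function(e) NULL)
      if (is.null(p) || anyNA(p)) return(1e10)
      p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
      -sum(stats::dbinom(data$successes, data$trials, p, log = TRUE))
    }
  }

  best <- .multistart_optim(objective, tab, start, multistart, seed)
  theta <- stats::setNames(best$par, tab$id)

  fitted_p <- predict_theta(theta)
  sse <- sum((fitted_p - obs)^2)
  sst <- sum((obs - mean(obs))^2)
  r2 <- if (sst > 0) 1 - sse / sst else NA_real_

  span <- tab$upper - tab$lower
  at_bound <- (theta - tab$lower) < 1e-6 * span |
    (tab$upper - theta) < 1e-6 * span
  if (any(at_bound))
    warning("parameter(s) at bound, possibly degenerate: ",
            paste(tab$id[at_bound], collapse = ", "), call. = FALSE)

  mu_hat <- vapply(paste0("mu", seq_len(n)), function(nm)
    if (nm %in% tab$id) theta[[nm]] else fixed[[nm]], 0)
  a_hat <- vapply(paste0("a", seq_len(n)), function(nm)
    if (nm %in% tab$id) theta[[nm]] else fixed[[nm]], 0)
  chain_hat <- chain_params(mu = mu_hat, a = a_hat, q = q, g = g,
                            decline = decline)
  profiles <- stats::setNames(lapply(groups, function(gname)
    .complete_profile(lesions[[gname]], gname, n, tab, theta)), groups)

  structure(list(
    coefficients = theta,
    par_table = cbind(tab, estimate = unname(theta), at_bound = at_bound),
    chain = chain_hat,
    profiles = profiles,
    data = data,
    fitted = fitted_p,
    sse = sse,
    r_squared = r2,
    loss = loss,
    objective = best$objective,
    convergence = best$convergence,
    message = best$message,
    n_free = k,
    multistart = multistart,
    seed = seed,
    call = cl
  ), class = "memory_chain_fit")
}

#' Expected MTL trace lifetime
#'
#' The expected survival time of a single hippocampal/MTL trace is the
#' inverse of the store-1 decline rate, `1 / a1`, in the dataset's time
#' unit. For reporting it is conventionally quoted to one decimal.
#'
#' @param a1 positive decline rate(s), or a `"memory_chain_fit"` from which
#'   `a1` is extracted.
#' @return Lifetime(s) `1 / a1`.
#' @examples
#' mtl_lifetime(0.103)  # about 9.7 days
#' @export
mtl_lifetime <- function(a1) {
  if (inherits(a1, "memory_chain_fit")) a1 <- a1$chain$a[1L]
  if (!is.numeric(a1) || any(a1 <= 0))
    stop("'a1' must be positive", call. = FALSE)
  1 / a1
}
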