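#' Write model configuration to a YAML file
#'
#' Serialises a chain, an optional lesion profile and an optional learning
#' schedule as a flat key/value YAML document. Numbers survive a
#' write/read round trip to at least 12 significant digits.
#'
#' @param path output file.
#' @param params optional [chain_params()].
#' @param lesion optional [lesion_profile()].
#' @param schedule optional [learning_schedule()].
#' @return `path`, invisibly.
#' @examples
#' f <- tempfile(fileext = ".yaml")
#' write_chain_config(f, params = chain_params(mu = c(2, 0.1), a = c(0.3, 0)))
#' read_chain_config(f)$params
#' @export
write_chain_config <- function(path, params = NULL, lesion = NULL,
                               schedule = NULL) {
  doc <- list()
  if (!is.null(params)) {
    .check_chain(params)
    doc$chain <- list(mu = as.list(params$mu), a = as.list(params$a),
                      q = params$q, g = params$g, decline = params$decline)
  }
  if (!is.null(lesion)) {
    stopifnot(inherits(lesion, "lesion_profile"))
    doc$lesion <- list(lambda = as.list(lesion$lambda),
                       induction = as.list(lesion$induction),
                       retrieval = lesion$retrieval,
                       t_lesion = if (is.null(lesion$t_lesion)) "at-test"
                                  else lesion$t_lesion)
  }
  if (!is.null(schedule)) {
    stopifnot(inherits(schedule, "learning_schedule"))
    doc$schedule <- list(trial_times = as.list(schedule$trial_times),
                         trials = as.list(schedule$trials),
                         massed_factor = as.list(schedule$massed_factor))
  }
  writeLines(yaml::as.yaml(doc, precision = 15L), path)
  invisible(path)
}

#' Read model configuration from a YAML file
#'
#' @param path file written by [write_chain_config()] (or hand-authored in
#'   the same dialect).
#' @return List with any of `params`, `lesion`, `schedule`.
#' @export
read_chain_config <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  doc <- yaml::read_yaml(path)
  out <- list()
  if (!is.null(doc$chain)) {
    ch <- doc$chain
    out$params <- chain_params(
      mu = unlist(ch$mu), a = unlist(ch$a),
      q = if (is.null(ch$q)) 1 else ch$q,
      g = if (is.null(ch$g)) 0 else ch$g,
      decline = if (is.null(ch$decline)) "exponential" else ch$decline)
  }
  if (!is.null(doc$lesion)) {
    le <- doc$lesion
    tl <- le$t_lesion
    out$lesion <- lesion_profile(
      lambda = if (is.null(le$lambda)) 0 else unlist(le$lambda),
      induction = if (is.null(le$induction)) 1 else unlist(le$induction),
      retrieval = if (is.null(le$retrieval)) 1 else le$retrieval,
      t_lesion = if (is.null(tl) || identical(tl, "at-test")) NULL else tl)
  }
  if (!is.null(doc$schedule)) {
    sc <- doc$schedule
    out$schedule <- learning_schedule(
      trial_times = unlist(sc$trial_times),
      trials = if (is.null(sc$trials)) 1L else unlist(sc$trials),
      massed_factor = if (is.null(sc$massed_factor)) NULL
                      else unlist(sc$massed_factor))
  }
  out
}
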