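#' Retention dataset
#'
#' A validated table of grouped recall observations: per group, the number
#' of correct responses out of a number of trials at each retention lag.
#' Either `successes` + `trials`, or a `proportion` column (then `trials`
#' may be `NA`, with a warning, in which case the points cannot be weighted
#' or chi-square tested).
#'
#' @param data a data frame with columns `group`, `time`, and either
#'   `successes` and `trials` or `proportion` (plus optional `trials`).
#' @return An object of class `c("retention_data", "data.frame")` with
#'   columns `group`, `time`, `successes`, `trials`, `proportion`.
#' @examples
#' retention_data(data.frame(
#'   group = rep(c("control", "lesion"), each = 2),
#'   time = c(1, 7, 1, 7),
#'   successes = c(18, 12, 6, 9),
#'   trials = 20))
#' @export
retention_data <- function(data) {
  data <- as.data.frame(data)
  need <- c("group", "time")
  missing_cols <- setdiff(need, names(data))
  if (length(missing_cols))
    stop("missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  has_succ <- "successes" %in% names(data)
  has_prop <- "proportion" %in% names(data)
  if (!has_succ && !has_prop)
    stop("need either 'successes' (with 'trials') or 'proportion'",
         call. = FALSE)
  if (!"trials" %in% names(data)) {
    if (has_succ)
      stop("'successes' requires a 'trials' column", call. = FALSE)
    warning("no 'trials' column: points cannot be weighted or ",
            "chi-square tested", call. = FALSE)
    data$trials <- NA_integer_
  }
  if (!has_succ) {
    data$successes <- ifelse(is.na(data$trials), NA_integer_,
                             as.integer(round(data$proportion * data$trials)))
  }
  if (!has_prop) data$proportion <- data$successes / data$trials

  probs <- list()
  bad <- function(cond, msg) {
    rows <- which(cond)
    if (length(rows))
      probs[[length(probs) + 1L]] <<- paste0(msg, " (row ",
                                             paste(rows, collapse = ", "), ")")
  }
  bad(is.na(data$group) | !nzchar(as.character(data$group)),
      "missing group label")
  bad(!is.finite(data$time) | data$time < 0, "time must be nonnegative")
  bad(!is.na(data$trials) & data$trials < 1, "trials must be positive")
  bad(!is.na(data$successes) & (data$successes < 0 |
                                  data$successes != round(data$successes)),
      "successes must be a nonnegative integer")
  bad(!is.na(data$successes) & !is.na(data$trials) &
        data$successes > data$trials, "successes exceed trials")
  bad(!is.finite(data$proportion) | data$proportion < 0 | data$proportion > 1,
      "proportion must lie in [0, 1]")
  bad(duplicated(data[, c("group", "time")]), "duplicate (group, time) point")
  if (length(probs))
    stop("invalid retention data:\n  ",
         paste(unlist(probs), collapse = "\n  "), call. = FALSE)

  data$group <- as.character(data$group)
  data <- data[order(match(data$group, unique(data$group)), data$time), ,
               drop = FALSE]
  rownames(data) <- NULL
  out <- data[, c("group", "time", "successes", "trials", "proportion")]
  class(out) <- c("retention_data", "data.frame")
  out
}

#' @export
print.retention_data <- function(x, ...) {
  gs <- unique(x$group)
  cat("Retention dataset:", nrow(x), "points in", length(gs),
      "group(s):", paste(gs, collapse = ", "), "\n")
  print.data.frame(x, ...)
  invisible(x)
}

#' Read a retention dataset from CSV
#'
#' Expects a header row with columns `group`, `time`, and `successes` +
#' `trials` (or `proportion`). All validation failures are reported at once
#' with their row numbers.
#'
#' @param path CSV file path.
#' @return A [retention_data()] object.
#' @export
read_retention <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  retention_data(df)
}

#' Write a retention dataset to CSV
#'
#' Round-trips losslessly through [read_retention()].
#'
#' @param x a [retention_data()] object.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_retention <- function(x, path) {
  stopifnot(inherits(x, "retention_data"))
  utils::write.csv(as.data.frame(x), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
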