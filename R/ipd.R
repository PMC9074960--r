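#' Individual patient-level right-censored survival data
#'
#' An `ipd` object is a data frame with columns `time` (years, > 0) and
#' `event` (1 = terminal event, 0 = right-censored), the currency between
#' curve reconstruction and parametric fitting.
#'
#' @param time Numeric vector of positive, finite follow-up times in years.
#' @param event Logical or 0/1 vector, `TRUE`/1 meaning the terminal event
#'   occurred at `time`, `FALSE`/0 meaning right censoring.
#' @param arm_label,stratum_label Optional labels carried as attributes
#'   (e.g. `"placebo"`, `"CNS-positive"`).
#' @return A data frame of class `ipd`.
#' @examples
#' ipd(c(1, 2, 3), c(1, 0, 1), arm_label = "placebo")
#' @export
ipd <- function(time, event, arm_label = NA_character_, stratum_label = NA_character_) {
  time <- as.numeric(time)
  event <- as.integer(as.logical(event))
  if (length(time) != length(event)) {
    stop("'time' and 'event' must have the same length", call. = FALSE)
  }
  if (length(time) < 1L) stop("an ipd needs at least one record", call. = FALSE)
  if (any(!is.finite(time)) || any(time <= 0)) {
    stop("all times must be positive and finite", call. = FALSE)
  }
  out <- data.frame(time = time, event = event)
  class(out) <- c("ipd", "data.frame")
  attr(out, "arm_label") <- arm_label
  attr(out, "stratum_label") <- stratum_label
  out
}

#' @export
print.ipd <- function(x, ...) {
  cat(sprintf("<ipd> %d records, %d events, %d censored\n",
              nrow(x), sum(x$event), sum(1 - x$event)))
  if (!is.na(attr(x, "arm_label"))) cat("  arm:", attr(x, "arm_label"), "\n")
  if (!is.na(attr(x, "stratum_label"))) cat("  stratum:", attr(x, "stratum_label"), "\n")
  invisible(x)
}

#' Read or write individual patient data as CSV
#'
#' The on-disk format is a two-column CSV with header `time,event`
#' (`event` in `{0,1}`).
#'
#' @param x An [ipd()] object.
#' @param path File path.
#' @return `read_ipd()` returns an [ipd()]; `write_ipd()` returns `path`
#'   invisibly.
#' @export
write_ipd <- function(x, path) {
  stopifnot(inherits(x, "ipd"))
  utils::write.csv(data.frame(time = x$time, event = x$event), path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_ipd
#' @export
read_ipd <- function(path) {
  df <- utils::read.csv(path)
  if (!all(c("time", "event") %in% names(df))) {
    stop("ipd CSV must have columns 'time' and 'event'", call. = FALSE)
  }
  ipd(df$time, df$event)
}
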