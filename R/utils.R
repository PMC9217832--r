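#' @keywords internal
"_PACKAGE"

#' @importFrom rlang %||% abort warn inform .data
#' @importFrom stats sd qbeta qnorm pnorm qchisq rnorm runif rpois rbinom
#'   setNames complete.cases binomial coef glm glm.control vcov t.test
#'   wilcox.test chisq.test fisher.test shapiro.test predict
#' @importFrom utils read.csv write.csv head tail
NULL

# canonical timestamp format for all CSV interfaces (ISO 8601, minute resolution,
# local clock time -- no time-zone arithmetic anywhere)
.TS_FMT <- "%Y-%m-%d %H:%M"

parse_timestamp <- function(x) {
  as.POSIXct(as.character(x), format = .TS_FMT, tz = "UTC")
}

format_timestamp <- function(x) {
  format(x, .TS_FMT, tz = "UTC")
}

# "HH:MM" -> minutes after local midnight
parse_hm <- function(x) {
  stopifnot(grepl("^\\d{1,2}:\\d{2}$", x))
  parts <- as.integer(strsplit(x, ":", fixed = TRUE)[[1]])
  parts[1] * 60 + parts[2]
}

# minutes after local midnight of a POSIXct clock time
minutes_of_day <- function(t) {
  lt <- as.POSIXlt(t, tz = "UTC")
  lt$hour * 60 + lt$min
}

hours_between <- function(a, b) {
  as.numeric(difftime(b, a, units = "hours"))
}

#' Round half away from zero
#'
#' Report-display rounding used throughout: `round_half_away(78.75, 0)` is 79,
#' unlike banker's rounding. Used when formatting integer-percent cells.
#'
#' @param x numeric vector.
#' @param digits decimal places.
#' @return rounded numeric vector.
#' @export
round_half_away <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' Format a proportion as an integer percentage
#'
#' @param p proportion in \[0, 1\].
#' @return numeric integer percent, rounded half away from zero.
#' @export
as_percent <- function(p) round_half_away(100 * p, 0)

# two significant figures, the convention used for odds-ratio display
signif2 <- function(x) signif(x, 2)

`%theni%` <- function(a, b) if (length(a) == 0 || all(is.na(a))) b else a
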