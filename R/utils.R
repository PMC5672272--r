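#' @importFrom rlang abort warn .data %||%
#' @importFrom tibble tibble as_tibble
#' @import dplyr
NULL

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

# sample SD that returns 0 (not NA) for a single observation; aggregation of a
# single metaphase plate must yield zero spread, not missingness
sd0 <- function(x) {
  if (length(x) < 2L) return(0)
  stats::sd(x)
}

stop_arg <- function(msg) abort(msg, class = "karyometry_argument_error")
stop_validation <- function(msg) abort(msg, class = "karyometry_validation_error")
stop_schema <- function(msg) abort(msg, class = "karyometry_schema_error")

check_number <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop_arg(sprintf("`%s` must be a single finite number", name))
  }
  if (positive && x <= 0) stop_arg(sprintf("`%s` must be > 0", name))
  invisible(x)
}
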