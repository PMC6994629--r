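#' Round half away from zero to a fixed number of decimals
#'
#' Base R's `round()` rounds half to even; printed bookkeeping percentages
#' use the conventional round-half-up instead so that e.g. 0.125 -> 0.13.
#'
#' @param x numeric vector
#' @param digits integer, decimals to keep
#' @return rounded numeric vector
#' @keywords internal
round_half_up <- function(x, digits = 2) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5) / scale
}

#' @keywords internal
`%||%` <- function(a, b) if (is.null(a)) b else a

# fail with a consistent prefix so pipeline stages can be identified in logs
stop2 <- function(...) stop(..., call. = FALSE)

# join a character set into the ";"-separated label form used in locus
# tables and BED name columns (sorted, unique, empty set -> ".")
join_labels <- function(x) {
  x <- sort(unique(x[!is.na(x) & nzchar(x)]))
  if (length(x) == 0L) "." else paste(x, collapse = ";")
}

split_labels <- function(x) {
  out <- strsplit(x, ";", fixed = TRUE)
  lapply(out, function(v) v[v != "." & nzchar(v)])
}

#' Structured log line
#'
#' Emits `[stage] event key=value ...` on stderr. Quiet when the option
#' `twaspleio.quiet` is TRUE (the default inside tests).
#' @keywords internal
log_event <- function(stage, event, ...) {
  if (isTRUE(getOption("twaspleio.quiet", FALSE))) return(invisible(NULL))
  kv <- list(...)
  extra <- if (length(kv)) {
    paste(names(kv), vapply(kv, function(v) paste(format(v), collapse = ","),
                            character(1)), sep = "=", collapse = " ")
  } else ""
  message(sprintf("[%s] %s %s", stage, event, extra))
  invisible(NULL)
}
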