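# Clock-time helpers: times are stored as integer minutes since midnight of
# the record day; occasions crossing midnight carry `next_day = TRUE` on the
# end time and remain attributed to the day on which they started.

#' Parse "HH:MM" clock strings to minutes since midnight
#'
#' @param x Character vector of `"HH:MM"` strings (24-h clock).
#' @return Integer vector of minutes in `[0, 1440)`.
#' @export
#' @examples
#' parse_clock("07:28")  # 448
parse_clock <- function(x) {
  x <- trimws(as.character(x))
  ok <- grepl("^([01]?[0-9]|2[0-3]):[0-5][0-9]$", x)
  if (any(!ok, na.rm = TRUE)) {
    abort(paste0("malformed clock time(s): ",
                 paste(unique(x[!ok]), collapse = ", "),
                 " (expected \"HH:MM\")"))
  }
  hh <- as.integer(sub(":.*", "", x))
  mm <- as.integer(sub(".*:", "", x))
  hh * 60L + mm
}

#' Format minutes since midnight as "HH:MM"
#'
#' @param m Numeric vector of minutes; values >= 1440 wrap around midnight.
#' @return Character vector of `"HH:MM"` strings.
#' @export
format_clock <- function(m) {
  m <- as.integer(round(m)) %% 1440L
  sprintf("%02d:%02d", m %/% 60L, m %% 60L)
}

# effective end minute for interval logic: end + 1440 if it crossed midnight
effective_end <- function(end_time, next_day) {
  end_time + ifelse(isTRUE_vec(next_day), 1440L, 0L)
}

isTRUE_vec <- function(x) {
  if (is.null(x)) return(FALSE)
  !is.na(x) & as.logical(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_if_missing_cols <- function(df, cols, what) {
  miss <- setdiff(cols, names(df))
  if (length(miss)) {
    abort(paste0(what, " is missing required column(s): ",
                 paste(miss, collapse = ", ")))
  }
  invisible(df)
}
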