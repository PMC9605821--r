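#' Parse timestamps into UTC POSIXct instants
#'
#' All timelines in the package are timezone-naive and handled internally as
#' UTC `POSIXct` at minute resolution. Accepted input formats are ISO 8601
#' date-times with either a `T` or a space separator (`2024-03-01T14:30`,
#' `2024-03-01 14:30:00`) or bare dates (midnight assumed).
#'
#' @param x character vector, `POSIXct`, or `Date`.
#' @return `POSIXct` vector in UTC, rounded to whole minutes.
#' @export
parse_instant <- function(x) {
  if (inherits(x, "POSIXct")) {
    return(round_minute(as.POSIXct(as.numeric(x), origin = "1970-01-01", tz = "UTC")))
  }
  if (inherits(x, "Date")) {
    return(as.POSIXct(as.numeric(x) * 86400, origin = "1970-01-01", tz = "UTC"))
  }
  x <- as.character(x)
  out <- rep(as.POSIXct(NA), length(x))
  ok <- !is.na(x) & nzchar(x)
  if (any(ok)) {
    parsed <- as.POSIXct(x[ok],
      tz = "UTC",
      tryFormats = c(
        "%Y-%m-%dT%H:%M:%OS", "%Y-%m-%d %H:%M:%OS",
        "%Y-%m-%dT%H:%M", "%Y-%m-%d %H:%M", "%Y-%m-%d"
      ),
      optional = TRUE
    )
    out[ok] <- parsed
  }
  bad <- ok & is.na(out)
  if (any(bad)) {
    stop(
      "unparseable timestamp(s): ",
      paste(utils::head(x[bad], 5L), collapse = ", "),
      call. = FALSE
    )
  }
  round_minute(out)
}

#' Format instants as ISO 8601 strings
#'
#' @param x `POSIXct` vector.
#' @return character vector like `"2024-03-01T14:30"`.
#' @export
format_instant <- function(x) {
  format(x, "%Y-%m-%dT%H:%M", tz = "UTC")
}

round_minute <- function(x) {
  as.POSIXct(round(as.numeric(x) / 60) * 60, origin = "1970-01-01", tz = "UTC")
}

as_instant_num <- function(x) as.numeric(x)

num_to_instant <- function(x) {
  as.POSIXct(x, origin = "1970-01-01", tz = "UTC")
}

hours_to_secs <- function(h) h * 3600
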