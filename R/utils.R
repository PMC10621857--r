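# Small shared helpers. Times are handled as minutes (numeric); POSIXct
# inputs are converted on the fly so tracklogs can carry either.

#' Convert a time vector to numeric minutes
#'
#' Tracklog times may be numeric (already minutes) or POSIXct; all internal
#' arithmetic works on minutes since an arbitrary origin.
#'
#' @param time numeric or POSIXct vector.
#' @return numeric vector of minutes.
#' @keywords internal
#' @noRd
time_minutes <- function(time) {
  if (inherits(time, "POSIXt")) as.numeric(time) / 60 else as.numeric(time)
}

inv_logit <- function(x) 1 / (1 + exp(-x))

#' z-transform columns of a data frame
#'
#' Centers to mean zero and scales to unit standard deviation, using the
#' table's own mean and sd (computed after any row exclusions). Constant
#' columns raise an error rather than returning NaN.
#'
#' @param data a data frame.
#' @param cols character vector of column names to transform in place.
#' @param suffix optional suffix; if non-`NULL`, transformed values are
#'   written to `paste0(col, suffix)` and the originals kept.
#' @param on_constant `"error"` (default) or `"zero"`: a constant column
#'   either raises an error or maps to all-zero (it carries no
#'   information and is then dropped from model terms downstream).
#' @return `data` with transformed columns, as a tibble.
#' @export
#' @examples
#' z_transform(data.frame(a = 1:5, b = letters[1:5]), "a")
z_transform <- function(data, cols, suffix = NULL,
                        on_constant = c("error", "zero")) {
  on_constant <- match.arg(on_constant)
  data <- tibble::as_tibble(data)
  for (cl in cols) {
    if (!cl %in% names(data)) stop("z_transform: no column '", cl, "'")
    v <- data[[cl]]
    s <- stats::sd(v, na.rm = TRUE)
    if (!is.finite(s) || s == 0) {
      if (on_constant == "error") {
        stop("z_transform: column '", cl, "' is constant")
      }
      out <- rep(0, length(v))
    } else {
      out <- (v - mean(v, na.rm = TRUE)) / s
    }
    data[[if (is.null(suffix)) cl else paste0(cl, suffix)]] <- out
  }
  data
}

# seasonality terms from a date: angle 2*pi*doy/365.25
day_angle <- function(date) {
  doy <- as.numeric(strftime(date, format = "%j"))
  2 * pi * doy / 365.25
}

stop_if_missing_cols <- function(data, cols, what = "input") {
  miss <- setdiff(cols, names(data))
  if (length(miss)) {
    stop(what, " is missing required column(s): ", paste(miss, collapse = ", "))
  }
  invisible(data)
}
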