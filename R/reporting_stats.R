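#' Mean unsigned value of a series
#'
#' The mean of absolute values; applied to deviation series this is the
#' mean unsigned deviation (MUD) / mean unsigned error (MUE) used in the
#' accuracy tables.
#'
#' @param values Non-empty numeric vector.
#' @return Mean of \code{abs(values)}.
#' @export
mean_unsigned <- function(values) {
  if (length(values) == 0 || any(!is.finite(values))) {
    stop("argument error: mean_unsigned() needs a non-empty finite series",
         call. = FALSE)
  }
  mean(abs(values))
}

#' Deviation table against a reference series
#'
#' Per-label deviations of the one-body and two-body series from a
#' reference (e.g. truncated full-system) series, plus their mean unsigned
#' deviations. Values are stored at full precision; rounding is a
#' presentation concern.
#'
#' @param labels Snapshot or system identifiers.
#' @param series_1b,series_2b,series_ref Equal-length numeric series, eV.
#' @return A \code{deviation_table}: data.frame with columns \code{label},
#'   \code{e_1b}, \code{e_2b}, \code{e_ref}, \code{dev1}, \code{dev2} and
#'   attributes \code{mud1}, \code{mud2}.
#' @export
deviation_table <- function(labels, series_1b, series_2b, series_ref) {
  n <- length(labels)
  if (n < 1 || length(series_1b) != n || length(series_2b) != n ||
      length(series_ref) != n) {
    stop("argument error: deviation_table() needs four equal-length series",
         call. = FALSE)
  }
  dev1 <- series_1b - series_ref
  dev2 <- series_2b - series_ref
  out <- data.frame(label = as.character(labels),
                    e_1b = series_1b, e_2b = series_2b, e_ref = series_ref,
                    dev1 = dev1, dev2 = dev2, stringsAsFactors = FALSE)
  attr(out, "mud1") <- mean_unsigned(dev1)
  attr(out, "mud2") <- mean_unsigned(dev2)
  class(out) <- c("deviation_table", "data.frame")
  out
}

#' @export
print.deviation_table <- function(x, digits = 3, ...) {
  df <- as.data.frame(x)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], round, digits = digits)
  print(df, row.names = FALSE)
  cat(sprintf("MUD(1B) = %.*f   MUD(2B) = %.*f\n",
              digits, attr(x, "mud1"), digits, attr(x, "mud2")))
  invisible(x)
}

#' Squared Pearson correlation of two series
#'
#' @param x,y Numeric series of equal length >= 3 with non-zero variance.
#' @return R^2 in [0, 1].
#' @export
r_squared <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3) {
    stop("argument error: r_squared() needs two equal-length series of >= 3",
         call. = FALSE)
  }
  if (stats::var(x) == 0 || stats::var(y) == 0) {
    stop("degenerate-input error: zero variance in a series", call. = FALSE)
  }
  stats::cor(x, y)^2
}
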