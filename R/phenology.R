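#' Accumulate growing degree days
#'
#' Daily heat units above a base temperature, summed over the season. The
#' daily contribution is `max((tmax + tmin) / 2 - t_base, 0)`: days whose mean
#' temperature falls below the base contribute nothing. For pistachio the
#' customary base temperature is 7 degrees C, and the three critical
#' developmental time points fall near 1800, 2100 and 2500 accumulated GDD
#' (kernel-fill completion, hull softening / shell split, commercial harvest).
#' The accumulation start (full bloom) is the caller's responsibility: pass a
#' series that begins on the bloom date.
#'
#' @param temps data frame with numeric columns `tmax` and `tmin` (degrees C),
#'   one row per day, in chronological order. An optional `date` column is
#'   carried through.
#' @param t_base base temperature in degrees C (default 7, pistachio).
#' @return the input as a tibble with two added columns: `daily_gdd` and the
#'   running total `cumulative_gdd` (non-decreasing).
#' @examples
#' gdd_accumulate(data.frame(tmax = c(27, 10, 30), tmin = c(17, 2, 20)))
#' @export
gdd_accumulate <- function(temps, t_base = 7) {
  stopifnot(is.data.frame(temps), nrow(temps) >= 1)
  if (!all(c("tmax", "tmin") %in% names(temps))) {
    stop("`temps` needs columns `tmax` and `tmin`", call. = FALSE)
  }
  bad <- which(temps$tmax < temps$tmin)
  if (length(bad) > 0) {
    day <- if ("date" %in% names(temps)) temps$date[bad[1]] else bad[1]
    stop("tmax < tmin on day ", day, call. = FALSE)
  }
  out <- tibble::as_tibble(temps)
  out$daily_gdd <- pmax((out$tmax + out$tmin) / 2 - t_base, 0)
  out$cumulative_gdd <- cumsum(out$daily_gdd)
  out
}
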