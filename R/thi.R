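#' Temperature-humidity index
#'
#' `THI = (1.8 * T + 32) - (0.55 - 0.55 * RH) * (1.8 * T - 26)` with `T` in
#' degrees Celsius and `RH` a relative-humidity fraction in `[0, 1]`.
#' Values above 1 (up to 100) are interpreted as percentages and divided by
#' 100 with a note; values outside `[0, 100]` are rejected. At `RH = 1`
#' the humidity term vanishes and `THI = 1.8 T + 32`; at `T = 26/1.8`
#' (about 14.44 C) the second factor is zero and `THI = 58` for any
#' humidity. A THI around 72 is the conventional onset of heat stress in
#' dairy cattle; around 84 indicates severe heat load.
#'
#' @param temperature_c air temperature in degrees Celsius.
#' @param relative_humidity relative humidity, fraction in `[0, 1]` (or
#'   percent in `(1, 100]`, auto-scaled).
#' @return numeric THI values.
#' @examples
#' computeTHI(30, 0.6)  # 79.84
#' @export
computeTHI <- function(temperature_c, relative_humidity) {
  rh <- relative_humidity
  if (any(rh < 0 | rh > 100, na.rm = TRUE))
    stop("domain error: relative humidity outside [0, 100]")
  pct <- !is.na(rh) & rh > 1
  if (any(pct)) {
    message("relative_humidity > 1 interpreted as percent and divided by 100")
    rh[pct] <- rh[pct] / 100
  }
  (1.8 * temperature_c + 32) - (0.55 - 0.55 * rh) * (1.8 * temperature_c - 26)
}

#' Append a THI column to a measurement table
#'
#' @param x data.frame with columns `temperature_c` and `relative_humidity`
#'   (any additional columns, e.g. `timestamp` or `group`, are kept).
#' @return `x` with an appended `thi` column.
#' @export
thiTable <- function(x) {
  need <- c("temperature_c", "relative_humidity")
  if (!all(need %in% names(x)))
    stop("need columns ", paste(need, collapse = ", "))
  x$thi <- computeTHI(x$temperature_c, x$relative_humidity)
  x
}

#' Group summary of THI (mean and standard error)
#'
#' @param x data.frame with a `thi` column (see [thiTable()]).
#' @param group name of the grouping column (default `"group"`).
#' @return data.frame with columns `group`, `n`, `mean_thi`, `sem_thi`.
#' @export
thiSummary <- function(x, group = "group") {
  if (!group %in% names(x)) stop("grouping column not found: ", group)
  sp <- split(x$thi, x[[group]])
  data.frame(group = names(sp),
             n = vapply(sp, length, integer(1)),
             mean_thi = vapply(sp, mean, numeric(1)),
             sem_thi = vapply(sp, function(v)
               stats::sd(v) / sqrt(length(v)), numeric(1)),
             stringsAsFactors = FALSE, row.names = NULL)
}
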