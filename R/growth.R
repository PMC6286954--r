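# Crown growth rates from time-stamped CPA series.

#' Growth rate and relative growth rate of crown projection area
#'
#' For each tree and each consecutive pair of observations:
#' `GR = (CPA_t - CPA_{t-dt}) / dt` (m^2/day) and
#' `RGR = (CPA_t - CPA_{t-dt}) / (CPA_{t-dt} * dt)` (1/day), with `dt` the
#' interval in whole calendar days. `RGR = GR / CPA_{t-dt}` identically.
#'
#' @param series Data frame with columns `tree_id`, `date` (Date or ISO-8601
#'   string) and `CPA_m2`. Dates must be strictly increasing within a tree.
#' @return A tibble with one row per tree and interval: `tree_id`,
#'   `date_start`, `date_end`, `dt_days`, `cpa_start`, `cpa_end`,
#'   `gr_m2_day`, `rgr_day`.
#' @export
growth_rates <- function(series) {
  series <- as_tibble(as.data.frame(series))
  for (f in c("tree_id", "date", "CPA_m2"))
    if (!f %in% names(series)) stop("series missing column: ", f)
  series$date <- as.Date(series$date)
  if (any(is.na(series$date))) stop("unparseable dates in series")
  out <- series |>
    dplyr::arrange(.data$tree_id, .data$date) |>
    dplyr::group_by(.data$tree_id) |>
    dplyr::reframe({
      d <- .data$date; cpa <- .data$CPA_m2
      if (length(d) < 2L)
        stop("tree ", .data$tree_id[1], ": need at least two observations")
      dt <- as.numeric(diff(d), units = "days")
      if (any(dt <= 0))
        stop("tree ", .data$tree_id[1], ": dates must be strictly increasing")
      cpa0 <- cpa[-length(cpa)]
      cpa1 <- cpa[-1]
      if (any(cpa0 <= 0))
        stop("tree ", .data$tree_id[1],
             ": non-positive starting CPA; relative growth rate undefined")
      tibble(
        date_start = d[-length(d)], date_end = d[-1], dt_days = dt,
        cpa_start = cpa0, cpa_end = cpa1,
        gr_m2_day = (cpa1 - cpa0) / dt,
        rgr_day = (cpa1 - cpa0) / (cpa0 * dt)
      )
    })
  out
}

#' Plot CPA trajectories and growth rates of a series
#'
#' @param series As in [growth_rates()].
#' @return A ggplot of CPA over time, one line per tree.
#' @export
plot_growth_series <- function(series) {
  series <- as_tibble(as.data.frame(series))
  series$date <- as.Date(series$date)
  ggplot2::ggplot(series, ggplot2::aes(
    x = .data$date, y = .data$CPA_m2,
    group = .data$tree_id, colour = factor(.data$tree_id)
  )) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = NULL, y = expression(CPA ~ (m^2)), colour = "tree") +
    ggplot2::theme_minimal()
}
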