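#' Round half away from zero at a given precision
#'
#' Reporting convention for printed shares and ratios (59.0%, 161%): exact
#' halves round up in magnitude, unlike banker's rounding.
#'
#' @param x numeric
#' @param digits decimal places
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Formatted percentage or ratio of two death totals
#'
#' @param numerator,denominator totals (denominator > 0)
#' @param digits decimal places of the report
#' @param mode `"percent"` (numerator/denominator x 100, suffix `%`) or
#'   `"ratio"` (plain quotient)
#' @return list with `value` (rounded numeric) and `label` (string)
#' @export
summary_ratio <- function(numerator, denominator, digits = 1,
                          mode = c("percent", "ratio")) {
  mode <- match.arg(mode)
  if (denominator <= 0) stop("denominator must be > 0")
  raw <- numerator / denominator * if (mode == "percent") 100 else 1
  val <- round_half_up(raw, digits)
  label <- formatC(val, format = "f", digits = digits)
  if (mode == "percent") label <- paste0(label, "%")
  list(value = val, label = label)
}

#' The standard set of headline summary ratios
#'
#' Given the named death totals of a completed attribution run, computes the
#' report ratios: anthropogenic share of the total and of the within-domain
#' total, extra-regional and residual shares (both bases), and the low/high
#' uncertainty bounds as percentages of the mid estimate.
#'
#' @param totals named list/vector with `J_total`, `J_anthro`, `J_extra`,
#'   and optionally `J_low`, `J_high`
#' @param share_digits decimals for shares (default 1)
#' @param bound_digits decimals for bound ratios (default 0)
#' @return data.frame with `quantity`, `value`, `label`
#' @export
summary_ratios <- function(totals, share_digits = 1, bound_digits = 0) {
  tt <- as.list(totals)
  within <- tt$J_total - tt$J_extra
  resid <- within - tt$J_anthro
  rows <- list(
    c("anthro_share_of_total_pct",
      summary_ratio(tt$J_anthro, tt$J_total, share_digits)),
    c("anthro_share_of_within_domain_pct",
      summary_ratio(tt$J_anthro, within, share_digits)),
    c("extra_regional_share_of_total_pct",
      summary_ratio(tt$J_extra, tt$J_total, share_digits)),
    c("residual_share_of_total_pct",
      summary_ratio(resid, tt$J_total, share_digits)),
    c("residual_share_of_within_domain_pct",
      summary_ratio(resid, within, share_digits))
  )
  if (!is.null(tt$J_low) && !is.null(tt$J_high)) {
    rows <- c(rows, list(
      c("low_bound_pct_of_mid", summary_ratio(tt$J_low, tt$J_total, bound_digits)),
      c("high_bound_pct_of_mid", summary_ratio(tt$J_high, tt$J_total, bound_digits))
    ))
  }
  data.frame(
    quantity = vapply(rows, function(r) r[[1]], ""),
    value = vapply(rows, function(r) r[[2]], numeric(1)),
    label = vapply(rows, function(r) r[[3]], "")
  )
}
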