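#' Extra-regional contribution by boundary perturbation
#'
#' Estimates the deaths contributed by emissions outside the domain from a
#' boundary-inflow perturbation experiment: all boundary concentrations are
#' reduced by a fraction (default 20%, the BC-20 run, with the base run's
#' correction ratios frozen) and the induced difference is multiplied by the
#' inverse fraction (x5) to extrapolate to full removal. In linear mode the
#' extrapolation is exact.
#'
#' @param J_base base `cost_result` (or scalar J)
#' @param J_bc20 perturbed-run `cost_result` (or scalar)
#' @param fraction boundary reduction fraction used in the perturbed run
#' @return list with `total` and (when per-cell data is available) `per_cell`
#' @export
extra_regional_contribution <- function(J_base, J_bc20, fraction = 0.2) {
  jb <- if (inherits(J_base, "cost_result")) J_base$J else J_base
  jp <- if (inherits(J_bc20, "cost_result")) J_bc20$J else J_bc20
  if (jp > jb * (1 + 1e-12)) {
    stop("perturbed J exceeds base J: reduced inflow cannot add deaths in a sane run")
  }
  scale <- 1 / fraction
  out <- list(total = scale * (jb - jp), fraction = fraction)
  if (inherits(J_base, "cost_result") && inherits(J_bc20, "cost_result")) {
    out$per_cell <- scale * (J_base$per_cell - J_bc20$per_cell)
  }
  out
}

#' Split total deaths into extra-regional, domestic anthropogenic, residual
#'
#' The residual (natural sources plus everything the first-order ledger does
#' not capture) is `J_total - J_extra - J_anthro`. Shares are reported on
#' two bases: of the total, and of the within-domain total
#' `J_total - J_extra`.
#'
#' @param J_total,J_extra,J_anthro death totals (deaths/yr)
#' @param tol relative tolerance of the admissibility check
#'   `J_extra + J_anthro <= J_total`; first-order ledgers can overshoot
#'   slightly under nonlinear chemistry, so nonlinear pipelines pass a looser
#'   tolerance and may report a small negative residual
#' @return list of class `regional_split`
#' @export
residual_split <- function(J_total, J_extra, J_anthro, tol = 1e-6) {
  if (J_extra + J_anthro > J_total * (1 + tol)) {
    stop("J_extra + J_anthro exceeds J_total beyond tolerance")
  }
  J_residual <- J_total - J_extra - J_anthro
  within <- J_total - J_extra
  structure(list(
    J_total = J_total, J_extra = J_extra, J_anthro = J_anthro,
    J_residual = J_residual, J_within_domain = within,
    share_of_total = c(extra = J_extra, anthro = J_anthro,
                       residual = J_residual) / J_total,
    share_of_within = c(anthro = J_anthro, residual = J_residual) / within
  ), class = "regional_split")
}

#' @export
print.regional_split <- function(x, ...) {
  cat(sprintf(paste0(
    "regional_split: total %.1f = extra-regional %.1f (%.1f%%) + ",
    "anthropogenic %.1f (%.1f%%) + residual %.1f (%.1f%%)\n"),
    x$J_total, x$J_extra, 100 * x$share_of_total[["extra"]],
    x$J_anthro, 100 * x$share_of_total[["anthro"]],
    x$J_residual, 100 * x$share_of_total[["residual"]]))
  invisible(x)
}

#' Contribution-ratio map: deaths caused versus deaths incurred
#'
#' Per cell, CR = deaths caused anywhere by the cell's emissions divided by
#' deaths occurring in the cell; CR > 1 marks net exporters of health
#' damage, low within-region CR marks over-burdened regions. For the
#' `within_region` variant the caller supplies incurred deaths with the
#' extra-regional share already removed. Cells with zero incurred but
#' positive caused carry an infinite sentinel; cells with neither are
#' masked. Country-level CRs divide country sums.
#'
#' @param caused per-fine-cell deaths caused (source marginal of the ledger)
#' @param incurred per-fine-cell deaths occurring
#' @param mask a `country_mask`
#' @param variant `"vs_total"` or `"within_region"` (label only)
#' @param thresholds named vector: `over` (CR above = over-contributing),
#'   `high` (strongly over-contributing), `burden` (within-region CR below =
#'   over-burdened)
#' @return list of class `contribution_ratio_map`
#' @export
contribution_ratio <- function(caused, incurred, mask,
                               variant = c("vs_total", "within_region"),
                               thresholds = c(over = 1, high = 3, burden = 0.42)) {
  variant <- match.arg(variant)
  caused <- field_values(caused); incurred <- field_values(incurred)
  if (length(caused) != length(incurred)) stop("field lengths differ")
  if (any(caused < 0) || any(incurred < 0)) stop("death fields must be >= 0")
  cr <- rep(NA_real_, length(caused))
  pos <- incurred > 0
  cr[pos] <- caused[pos] / incurred[pos]
  cr[!pos & caused > 0] <- Inf
  key <- c("unassigned", mask$names)[mask$ids + 1L]
  csum <- rowsum(caused, key)
  isum <- rowsum(incurred, key)
  ctab <- data.frame(
    country = rownames(csum), caused = as.numeric(csum),
    incurred = as.numeric(isum)
  )
  ctab$cr <- ifelse(ctab$incurred > 0, ctab$caused / ctab$incurred,
                    ifelse(ctab$caused > 0, Inf, NA_real_))
  ctab$over_contributing <- !is.na(ctab$cr) & ctab$cr > thresholds[["over"]]
  ctab$strongly_over <- !is.na(ctab$cr) & ctab$cr > thresholds[["high"]]
  ctab$over_burdened <- !is.na(ctab$cr) & ctab$cr < thresholds[["burden"]]
  structure(list(
    cr = cr, variant = variant, thresholds = thresholds,
    cell_over = !is.na(cr) & cr > thresholds[["over"]],
    cell_over_burdened = !is.na(cr) & cr < thresholds[["burden"]],
    country = ctab
  ), class = "contribution_ratio_map")
}

#' @export
print.contribution_ratio_map <- function(x, ...) {
  cat(sprintf(
    "contribution_ratio_map (%s): %d over-contributing, %d over-burdened countries\n",
    x$variant, sum(x$country$over_contributing), sum(x$country$over_burdened)))
  invisible(x)
}
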