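#' Causes of death tracked by the health model
#' @export
pm_causes <- function() c("COPD", "IHD", "LRI", "LC", "T2D", "stroke")

#' Cause-specific relative-risk curve set
#'
#' Piecewise-linear relative-risk curves on exposure knots, per cause and per
#' bound (low/mid/high). The first knot is the TMREL with RR = 1; curves are
#' nondecreasing, flat-extrapolated above the last knot, and RR = 1 below the
#' TMREL. `lin_slope` holds the per-cause excess-risk slope used by the
#' linear response mode.
#'
#' @param knots ascending exposure knots (ug/m3), first = TMREL
#' @param rr array `(cause, knot, bound)` with bounds low/mid/high
#' @param tmrel minimum-risk exposure level (ug/m3)
#' @param lin_slope named per-cause slope (excess deaths fraction per ug/m3)
#' @export
rr_curve_set <- function(knots, rr, tmrel = knots[1], lin_slope = NULL) {
  causes <- dimnames(rr)[[1]]
  stopifnot(length(dim(rr)) == 3, dim(rr)[2] == length(knots), dim(rr)[3] == 3)
  if (abs(knots[1] - tmrel) > 1e-9) stop("first knot must equal the TMREL")
  if (any(diff(knots) <= 0)) stop("knots must be ascending")
  if (any(abs(rr[, 1, ] - 1) > 1e-9)) stop("RR at TMREL must be 1")
  if (any(apply(rr, c(1, 3), function(v) any(diff(v) < -1e-12)))) {
    stop("RR curves must be nondecreasing in exposure")
  }
  if (any(rr[, , 1] > rr[, , 2] + 1e-12) || any(rr[, , 2] > rr[, , 3] + 1e-12)) {
    stop("bounds must satisfy low <= mid <= high pointwise")
  }
  dimnames(rr)[[3]] <- c("low", "mid", "high")
  if (is.null(lin_slope)) {
    ref <- max(knots)
    lin_slope <- (rr[, length(knots), "mid"] - 1) / ref
  }
  structure(list(knots = knots, rr = rr, tmrel = tmrel, causes = causes,
                 lin_slope = lin_slope),
            class = "rr_curve_set")
}

#' Default GBD-style curve set
#'
#' Concave power-law mid curves `RR = 1 + a * ((C - TMREL)/10)^0.9`
#' tabulated on fixed knots, steepest at low exposure as in the GBD splines;
#' low/high bounds scale the excess risk by 0.55 and 1.65.
#'
#' @param tmrel minimum-risk exposure (ug/m3)
#' @param exponent concavity of the excess-risk power law
#' @export
default_rr_curves <- function(tmrel = 2.4, exponent = 0.90) {
  causes <- pm_causes()
  a <- c(COPD = 0.18, IHD = 0.25, LRI = 0.15, LC = 0.12, T2D = 0.10,
         stroke = 0.22)[causes]
  knots <- c(tmrel, 5, 10, 15, 20, 30, 45, 60, 80)
  mid <- 1 + outer(a, ((knots - tmrel) / 10)^exponent)
  rr <- array(0, c(length(causes), length(knots), 3),
              dimnames = list(causes, NULL, c("low", "mid", "high")))
  rr[, , "low"] <- 1 + 0.55 * (mid - 1)
  rr[, , "mid"] <- mid
  rr[, , "high"] <- 1 + 1.65 * (mid - 1)
  rr_curve_set(knots, rr, tmrel)
}

#' Relative risk at given exposures
#'
#' Piecewise-linear interpolation on the curve knots; exposure at or below
#' the TMREL gives RR = 1, exposure above the last knot the last RR.
#'
#' @param curves an `rr_curve_set`
#' @param cause one of [pm_causes()]
#' @param C exposure vector (ug/m3), nonnegative
#' @param bound `"low"`, `"mid"` or `"high"`
#' @export
relative_risk <- function(curves, cause, C, bound = "mid") {
  if (!cause %in% curves$causes) stop("unknown cause: ", cause)
  if (any(C < 0)) stop("exposure must be >= 0")
  y <- curves$rr[cause, , bound]
  stats::approx(curves$knots, y, xout = pmin(pmax(C, curves$knots[1]), max(curves$knots)),
                method = "linear", rule = 2)$y
}

# slope dRR/dC of the active segment (0 below TMREL / above last knot)
rr_slope <- function(curves, cause, C, bound = "mid") {
  k <- curves$knots
  y <- curves$rr[cause, , bound]
  seg <- findInterval(C, k)
  slopes <- diff(y) / diff(k)
  out <- numeric(length(C))
  inside <- seg >= 1 & seg < length(k)
  out[inside] <- slopes[seg[inside]]
  out
}

#' Bundle of health-model inputs
#'
#' @param population fine-grid population `field`
#' @param mortality country x cause table with `y0_low/mid/high` per 100k/yr
#' @param curves an `rr_curve_set`
#' @param mask a `country_mask` on the same grid
#' @param pop_bounds multiplicative low/high population factors
#' @param unassigned `"zero"` (unassigned cells contribute no deaths) or
#'   `"mean"` (use the cross-country mean mortality row)
#' @export
health_inputs <- function(population, mortality, curves, mask,
                          pop_bounds = c(low = 1, high = 1),
                          unassigned = c("zero", "mean")) {
  unassigned <- match.arg(unassigned)
  if (any(field_values(population) < 0)) stop("population must be >= 0")
  need <- c("country", "cause", "y0_low", "y0_mid", "y0_high")
  if (!all(need %in% names(mortality))) stop("mortality table missing columns")
  with_pop <- unique(mask$ids[mask$ids > 0 & field_values(population) > 0])
  missing_ctry <- setdiff(mask$names[with_pop], unique(mortality$country))
  if (length(missing_ctry)) {
    stop("mortality rows missing for populated countries: ",
         paste(missing_ctry, collapse = ", "))
  }
  structure(list(population = population, mortality = mortality,
                 curves = curves, mask = mask, pop_bounds = pop_bounds,
                 unassigned = unassigned),
            class = "health_inputs")
}

#' Health inputs of a synthetic world
#' @param world a `synthetic_world`
#' @param ... passed to [health_inputs()]
#' @export
world_health <- function(world, ...) {
  health_inputs(world$population, world$mortality, world$rr, world$mask,
                pop_bounds = c(low = world$pop_bounds[["low"]],
                               high = world$pop_bounds[["high"]]), ...)
}

# per-cell baseline mortality rate (per 100k) for one cause/bound
cell_y0 <- function(health, cause, bound) {
  col <- paste0("y0_", bound)
  tab <- health$mortality[health$mortality$cause == cause, ]
  y0 <- setNames(tab[[col]], tab$country)[health$mask$names]
  y0[is.na(y0)] <- 0
  ids <- health$mask$ids
  out <- numeric(length(ids))
  out[ids > 0] <- y0[ids[ids > 0]]
  if (health$unassigned == "mean") out[ids == 0] <- mean(y0, na.rm = TRUE)
  out
}

#' Attributable premature deaths per cell and cause
#'
#' GBD-style population-attributable-fraction model:
#' `deaths = P * y0/1e5 * (RR(C) - 1)/RR(C)` per cause, with the population
#' and mortality bound matching `bound`. The `"linear"` response replaces the
#' PAF term by `slope * C` (excess deaths linear in exposure through zero),
#' the tangent-model form under which first-order attribution is exact.
#'
#' @param exposure annual-mean fine exposure (`field`, `exposure_field`, or
#'   plain values, ug/m3)
#' @param health a `health_inputs`
#' @param bound `"low"`, `"mid"` or `"high"` (applied to RR, mortality and
#'   population together)
#' @param response `"gbd"` or `"linear"`
#' @return matrix `ncell x n_causes` of deaths/yr
#' @export
attributable_deaths <- function(exposure, health, bound = "mid",
                                response = c("gbd", "linear")) {
  response <- match.arg(response)
  C <- exposure_annual(exposure)
  P <- field_values(health$population)
  pf <- switch(bound, low = health$pop_bounds[["low"]], mid = 1,
               high = health$pop_bounds[["high"]])
  causes <- health$curves$causes
  out <- matrix(0, length(C), length(causes), dimnames = list(NULL, causes))
  for (d in causes) {
    y0 <- cell_y0(health, d, bound)
    base <- P * pf * y0 / 1e5
    if (response == "gbd") {
      rr <- relative_risk(health$curves, d, C, bound)
      out[, d] <- base * (rr - 1) / rr
    } else {
      out[, d] <- base * health$curves$lin_slope[[d]] * C
    }
  }
  out
}

# d(deaths)/dC per cell summed over causes (adjoint seed of the cost chain)
deaths_dC <- function(exposure, health, bound = "mid",
                      response = c("gbd", "linear"), receptor_only = TRUE) {
  response <- match.arg(response)
  C <- exposure_annual(exposure)
  P <- field_values(health$population)
  pf <- switch(bound, low = health$pop_bounds[["low"]], mid = 1,
               high = health$pop_bounds[["high"]])
  g <- numeric(length(C))
  for (d in health$curves$causes) {
    base <- P * pf * cell_y0(health, d, bound) / 1e5
    if (response == "gbd") {
      rr <- relative_risk(health$curves, d, C, bound)
      g <- g + base * rr_slope(health$curves, d, C, bound) / rr^2
    } else {
      g <- g + base * health$curves$lin_slope[[d]]
    }
  }
  if (receptor_only) g[!receptor_cells(health$mask)] <- 0
  g
}

#' The mortality cost function J
#'
#' Total PM2.5-attributable premature deaths over the receptor region,
#' summing [attributable_deaths()] over receptor-flagged cells and the six
#' causes. Also returns per-cell totals (all cells) and per-cause totals with
#' percentage shares.
#'
#' @inheritParams attributable_deaths
#' @return list of class `cost_result` with elements `J`, `per_cell`,
#'   `per_cause`, `bound`, `response`
#' @export
cost_function <- function(exposure, health, bound = "mid",
                          response = c("gbd", "linear")) {
  response <- match.arg(response)
  if (!any(health$mask$receptor)) stop("empty receptor region")
  dm <- attributable_deaths(exposure, health, bound, response)
  rec <- receptor_cells(health$mask)
  per_cause <- colSums(dm[rec, , drop = FALSE])
  J <- sum(per_cause)
  structure(list(
    J = J,
    per_cell = rowSums(dm),
    per_cause = data.frame(cause = names(per_cause),
                           deaths = as.numeric(per_cause),
                           share_pct = if (J > 0) 100 * as.numeric(per_cause) / J else NA_real_),
    bound = bound, response = response
  ), class = "cost_result")
}

#' @export
print.cost_result <- function(x, ...) {
  cat(sprintf("cost_result (%s, %s bound): J = %.1f deaths\n", x$response, x$bound, x$J))
  invisible(x)
}

#' Uncertainty bounds of the cost function
#'
#' Evaluates J with population, mortality and relative risk all at their low
#' and all at their high bounds, and reports the bounds as rounded
#' percentages of the mid estimate.
#'
#' @inheritParams attributable_deaths
#' @param digits rounding precision of the reported percentage ratios
#' @export
uncertainty_bounds <- function(exposure, health, response = "gbd", digits = 0) {
  J <- vapply(c("low", "mid", "high"),
              function(b) cost_function(exposure, health, b, response)$J,
              numeric(1))
  list(
    J_low = J[["low"]], J_mid = J[["mid"]], J_high = J[["high"]],
    low_pct_of_mid = round_half_up(100 * J[["low"]] / J[["mid"]], digits),
    high_pct_of_mid = round_half_up(100 * J[["high"]] / J[["mid"]], digits)
  )
}
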