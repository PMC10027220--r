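#' Emission-driven contribution changes between two inventories
#'
#' Holds the sensitivity field fixed (the base year's adjoint) and computes
#' the entrywise difference ledger `lambda * (E_b - E_a)`, equal to
#' `ledger(E_b) - ledger(E_a)` exactly. Population and mortality stay at
#' their base-year values, so the tables isolate the effect of emission
#' changes alone.
#'
#' @param sens base-year `sensitivity_field`
#' @param inv_a reference-year inventory (e.g. 2005)
#' @param inv_b base-year inventory (e.g. 2015)
#' @param mask optional `country_mask` for country groupings
#' @return list of class `delta_ledger` holding both year ledgers
#' @export
delta_contributions <- function(sens, inv_a, inv_b, mask = NULL) {
  if (!identical(dim(inv_a$mass), dim(inv_b$mass))) {
    stop("inventories have mismatched dimensions")
  }
  if (!identical(inv_a$species, inv_b$species) ||
      !identical(names(inv_a$sector_map), names(inv_b$sector_map))) {
    stop("inventories have mismatched species/sector keys")
  }
  if (abs(inv_a$grid$dlat - inv_b$grid$dlat) > 1e-12 ||
      inv_a$grid$ncell != inv_b$grid$ncell) {
    stop("inventories are on different grids")
  }
  ledger_a <- compute_contributions(sens, inv_a, mask)
  ledger_b <- compute_contributions(sens, inv_b, mask)
  structure(list(
    ledger_a = ledger_a, ledger_b = ledger_b,
    year_a = inv_a$year, year_b = inv_b$year,
    delta_total = ledger_b$total - ledger_a$total
  ), class = "delta_ledger")
}

#' @export
print.delta_ledger <- function(x, ...) {
  cat(sprintf("delta_ledger %s -> %s: net change %.1f deaths\n",
              x$year_a, x$year_b, x$delta_total))
  invisible(x)
}

#' Entrywise delta array (lambda * (E_b - E_a))
#' @param delta a `delta_ledger`
#' @export
delta_array <- function(delta) {
  delta$ledger_b$contrib - delta$ledger_a$contrib
}

#' Avoided/added deaths report by category
#'
#' For every category: contributions in both years, the absolute change, the
#' relative change versus the reference year (undefined when the reference
#' total is zero), an `increase` flag, and the share of the total avoided
#' deaths carried by each decreasing category (shares over decreasing
#' categories sum to 100%).
#'
#' @param delta a `delta_ledger`
#' @param by grouping passed to [aggregate_ledger()]
#' @return data.frame
#' @export
change_report <- function(delta, by = "species") {
  a <- aggregate_ledger(delta$ledger_a, by)
  b <- aggregate_ledger(delta$ledger_b, by)
  keys <- setdiff(intersect(names(a), names(b)),
                  c("value", "share_pct", "rank"))
  m <- merge(a[, c(keys, "value")], b[, c(keys, "value")],
             by = keys, suffixes = c("_a", "_b"))
  m$delta <- m$value_b - m$value_a
  m$rel_change_pct <- ifelse(m$value_a != 0, 100 * m$delta / m$value_a, NA_real_)
  m$increase <- m$delta > 0
  dec <- m$delta < 0
  total_dec <- sum(-m$delta[dec])
  m$share_of_decrease_pct <- ifelse(dec & total_dec > 0,
                                    100 * (-m$delta) / total_dec, NA_real_)
  names(m)[names(m) == "value_a"] <- paste0("deaths_", delta$year_a)
  names(m)[names(m) == "value_b"] <- paste0("deaths_", delta$year_b)
  m[order(m$delta), , drop = FALSE]
}
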