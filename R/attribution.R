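#' Contribution ledger: deaths attributed per emission entry
#'
#' First-order source attribution: the sensitivity field, replicated to the
#' inventory's fine grid, is multiplied entrywise with emission mass,
#' `ledger[s, k, m, i] = lambda[s, m, i] * E[s, k, m, i]`, giving deaths
#' contributed per (species, detailed sector, month, fine cell). Entries with
#' zero emission are exactly zero.
#'
#' @param sens a `sensitivity_field` (coarse; replicated internally)
#' @param inv an `emission_inventory` on the fine grid
#' @param mask a `country_mask` on the fine grid (for country aggregations)
#' @return list of class `contribution_ledger`
#' @export
compute_contributions <- function(sens, inv, mask = NULL) {
  if (!setequal(sens$species, inv$species)) {
    stop("species mismatch between sensitivities and inventory")
  }
  lam_fine <- disaggregate_sensitivity(sens, inv$grid)
  contrib <- inv$mass
  for (s in inv$species) {
    contrib[, , , s] <- contrib[, , , s] * as.vector(lam_fine[, , s])
  }
  structure(list(
    grid = inv$grid, contrib = contrib, sector_map = inv$sector_map,
    species = inv$species, mask = mask, year = inv$year,
    total = sum(contrib)
  ), class = "contribution_ledger")
}

#' @export
print.contribution_ledger <- function(x, ...) {
  cat(sprintf("contribution_ledger (%s): total anthropogenic %.1f deaths\n",
              x$year, x$total))
  invisible(x)
}

# per-fine-cell source totals (deaths caused by each cell's emissions)
ledger_cell_totals <- function(ledger) {
  rowSums(ledger$contrib, dims = 1)
}

#' Aggregate the contribution ledger
#'
#' Group sums with percentage shares of the total anthropogenic
#' contribution, ranked in descending order (ties broken by label).
#'
#' @param ledger a `contribution_ledger`
#' @param by one of `"species"`, `"main_sector"`, `"detailed_sector"`,
#'   `"country"`, `"month"`, `"country_sector"`, `"sector_species"`
#' @return data.frame with `value` (deaths), `share_pct`, `rank` (single-key
#'   groupings)
#' @export
aggregate_ledger <- function(ledger, by = c("species", "main_sector",
                                            "detailed_sector", "country",
                                            "month", "country_sector",
                                            "sector_species")) {
  by <- match.arg(by)
  ct <- ledger$contrib
  total <- ledger$total
  need_mask <- by %in% c("country", "country_sector")
  if (need_mask && is.null(ledger$mask)) stop("country grouping needs a mask")
  finish <- function(df, rank_it = TRUE) {
    df$share_pct <- if (total != 0) 100 * df$value / total else NA_real_
    if (rank_it) {
      ord <- order(-df$value, df[[1]])
      df <- df[ord, , drop = FALSE]
      df$rank <- seq_len(nrow(df))
    }
    rownames(df) <- NULL
    df
  }
  country_of_cells <- function() {
    c("unassigned", ledger$mask$names)[ledger$mask$ids + 1L]
  }
  switch(by,
    species = finish(data.frame(
      species = ledger$species,
      value = vapply(seq_along(ledger$species),
                     function(s) sum(ct[, , , s]), numeric(1))
    )),
    detailed_sector = finish(data.frame(
      sector = names(ledger$sector_map),
      value = vapply(seq_along(ledger$sector_map),
                     function(k) sum(ct[, , k, ]), numeric(1))
    )),
    main_sector = {
      det <- vapply(seq_along(ledger$sector_map),
                    function(k) sum(ct[, , k, ]), numeric(1))
      agg <- rowsum(det, unname(ledger$sector_map))
      finish(data.frame(main_sector = rownames(agg), value = as.numeric(agg)))
    },
    month = finish(data.frame(
      month = 1:12,
      value = vapply(1:12, function(m) sum(ct[, m, , ]), numeric(1))
    ), rank_it = FALSE),
    country = {
      cell <- ledger_cell_totals(ledger)
      agg <- rowsum(cell, country_of_cells())
      finish(data.frame(country = rownames(agg), value = as.numeric(agg)))
    },
    country_sector = {
      cell_sector <- apply(ct, c(1, 3), sum)
      agg <- rowsum(cell_sector, country_of_cells())
      main <- t(rowsum(t(agg), unname(ledger$sector_map)))
      df <- data.frame(
        country = rep(rownames(main), times = ncol(main)),
        main_sector = rep(colnames(main), each = nrow(main)),
        value = as.numeric(main)
      )
      finish(df, rank_it = FALSE)
    },
    sector_species = {
      ks <- apply(ct, c(3, 4), sum)
      df <- data.frame(
        sector = rep(names(ledger$sector_map), times = length(ledger$species)),
        species = rep(ledger$species, each = length(ledger$sector_map)),
        value = as.numeric(ks)
      )
      finish(df, rank_it = FALSE)
    }
  )
}

#' Normalized monthly contribution shares
#'
#' Each month's category contributions divided by the total anthropogenic
#' contribution of that same month, so every month's fractions sum to one.
#' Months with zero total are reported as missing.
#'
#' @param ledger a `contribution_ledger`
#' @param by `"species"`, `"main_sector"` or `"detailed_sector"`
#' @return matrix `category x 12` of fractions
#' @export
monthly_shares <- function(ledger, by = c("species", "main_sector",
                                          "detailed_sector")) {
  by <- match.arg(by)
  ct <- ledger$contrib
  # category x month totals
  catm <- switch(by,
    species = {
      out <- sapply(1:12, function(m) vapply(seq_along(ledger$species),
        function(s) sum(ct[, m, , s]), numeric(1)))
      rownames(out) <- ledger$species
      out
    },
    detailed_sector = {
      out <- sapply(1:12, function(m) vapply(seq_along(ledger$sector_map),
        function(k) sum(ct[, m, k, ]), numeric(1)))
      rownames(out) <- names(ledger$sector_map)
      out
    },
    main_sector = {
      det <- sapply(1:12, function(m) vapply(seq_along(ledger$sector_map),
        function(k) sum(ct[, m, k, ]), numeric(1)))
      rowsum(det, unname(ledger$sector_map))
    }
  )
  tot_m <- colSums(catm)
  shares <- sweep(catm, 2, tot_m, "/")
  shares[, tot_m <= 0] <- NA_real_
  if (any(tot_m <= 0)) {
    warning("month(s) with zero total contribution reported as missing: ",
            paste(which(tot_m <= 0), collapse = ", "))
  }
  colnames(shares) <- month.abb
  shares
}

season_months <- function(season) {
  switch(toupper(season),
    DJF = c(12L, 1L, 2L), MAM = 3:5, JJA = 6:8, SON = 9:11,
    stop("unknown season: ", season)
  )
}

#' Seasonal contribution (or sensitivity) ratio for a category
#'
#' Ratio of summed contributions between two seasons (default winter DJF
#' over summer JJA) for a species and/or sector selection. Also accepts a
#' `sensitivity_field`, in which case mean sensitivities are compared.
#'
#' @param x a `contribution_ledger` or `sensitivity_field`
#' @param species optional species filter
#' @param sector optional detailed- or main-sector filter (ledger only)
#' @param season_a,season_b season codes (DJF, MAM, JJA, SON)
#' @return scalar ratio
#' @export
seasonal_ratio <- function(x, species = NULL, sector = NULL,
                           season_a = "DJF", season_b = "JJA") {
  ma <- season_months(season_a); mb <- season_months(season_b)
  if (inherits(x, "sensitivity_field")) {
    s_idx <- if (is.null(species)) seq_along(x$species) else match(species, x$species)
    if (anyNA(s_idx)) stop("unknown species")
    num <- mean(x$lambda[, ma, s_idx])
    den <- mean(x$lambda[, mb, s_idx])
  } else {
    ct <- x$contrib
    s_idx <- if (is.null(species)) seq_along(x$species) else match(species, x$species)
    if (anyNA(s_idx)) stop("unknown species")
    k_idx <- if (is.null(sector)) {
      seq_along(x$sector_map)
    } else {
      hit <- which(names(x$sector_map) %in% sector | unname(x$sector_map) %in% sector)
      if (!length(hit)) stop("unknown sector: ", sector)
      hit
    }
    num <- sum(ct[, ma, k_idx, s_idx])
    den <- sum(ct[, mb, k_idx, s_idx])
  }
  if (den == 0) stop("zero contribution in season ", season_b)
  num / den
}
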