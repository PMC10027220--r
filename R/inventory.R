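#' Emitted species tracked by the inventory
#' @export
pm_species <- function() c("NOx", "NH3", "SO2", "OC", "BC", "SOAP")

#' Default detailed-sector list and its rollup to the eight main sectors
#'
#' Sixteen detailed sectors, each mapped to one of the eight main sectors
#' (shipping, aviation, energy, industry, ground transport, waste,
#' agricultural, residential). The list is configurable; this default covers
#' every detailed source category the analysis distinguishes.
#'
#' @return named character vector: names are detailed sectors, values main sectors
#' @export
default_sector_map <- function() {
  c(
    "energy-power" = "energy",
    "energy-other" = "energy",
    "industry-combustion" = "industry",
    "industry-process" = "industry",
    "road-transport" = "ground transport",
    "ground-transport-other" = "ground transport",
    "domestic-shipping" = "shipping",
    "international-shipping" = "shipping",
    "aviation-lto" = "aviation",
    "aviation-cruise" = "aviation",
    "residential-heating" = "residential",
    "residential-other" = "residential",
    "waste" = "waste",
    "agriculture-livestock" = "agricultural",
    "agriculture-crops" = "agricultural",
    "agriculture-waste-burning" = "agricultural"
  )
}

#' Monthly gridded emission inventory
#'
#' Emission mass (kg per month) per (fine cell, month, detailed sector,
#' species), stored as an array with dimensions
#' `(ncell, 12, n_sector, n_species)`.
#'
#' @param grid fine `grid_spec`
#' @param mass 4-d array `(ncell, 12, sector, species)`, nonnegative
#' @param sector_map named character vector detailed -> main sector
#' @param species character vector of species labels
#' @param year year label
#' @export
emission_inventory <- function(grid, mass, sector_map = default_sector_map(),
                               species = pm_species(), year = "2015") {
  d <- dim(mass)
  if (length(d) != 4) stop("mass must be a 4-d array (cell, month, sector, species)")
  if (d[1] != grid$ncell) stop("mass cell dimension does not match grid")
  if (d[2] != 12) stop("mass must have 12 months")
  if (d[3] != length(sector_map)) stop("mass sector dimension does not match sector_map")
  if (d[4] != length(species)) stop("mass species dimension does not match species")
  if (anyNA(mass) || any(mass < 0)) stop("emission mass must be finite and >= 0")
  dimnames(mass) <- list(NULL, NULL, names(sector_map), species)
  structure(
    list(grid = grid, mass = mass, sector_map = sector_map,
         species = species, year = as.character(year)),
    class = "emission_inventory"
  )
}

#' @export
print.emission_inventory <- function(x, ...) {
  cat(sprintf(
    "emission_inventory %s: %d cells x 12 months x %d sectors x %d species, total %.4g kg/yr\n",
    x$year, x$grid$ncell, length(x$sector_map), length(x$species), sum(x$mass)
  ))
  invisible(x)
}

#' Annual inventory totals by species and/or sector
#'
#' @param inv an `emission_inventory`
#' @param by one of `"species"`, `"sector"`, `"main_sector"`,
#'   `"species_sector"`, `"species_main_sector"`, `"month"`
#' @return data.frame of kg/yr totals
#' @export
inventory_totals <- function(inv, by = c("species", "sector", "main_sector",
                                         "species_sector", "species_main_sector",
                                         "month")) {
  by <- match.arg(by)
  m <- inv$mass
  sp <- inv$species
  sec <- names(inv$sector_map)
  # collapse cells+months -> (sector, species)
  ks <- apply(m, c(3, 4), sum)
  switch(by,
    species = data.frame(species = sp, total_kg = colSums(ks)),
    sector = data.frame(sector = sec, total_kg = rowSums(ks)),
    main_sector = {
      agg <- rowsum(rowSums(ks), inv$sector_map)
      data.frame(main_sector = rownames(agg), total_kg = as.numeric(agg))
    },
    species_sector = data.frame(
      species = rep(sp, each = length(sec)),
      sector = rep(sec, times = length(sp)),
      total_kg = as.numeric(ks)
    ),
    species_main_sector = {
      agg <- rowsum(ks, inv$sector_map)
      data.frame(
        species = rep(sp, each = nrow(agg)),
        main_sector = rep(rownames(agg), times = length(sp)),
        total_kg = as.numeric(agg)
      )
    },
    month = data.frame(month = 1:12, total_kg = apply(m, 2, sum))
  )
}

#' Scale an inventory by per-(species, sector) factors
#'
#' Multiplies emission mass by nonnegative factors while leaving the spatial
#' and seasonal pattern untouched. Factors may be given as a single number, a
#' named per-species vector, or a full `species x sector` matrix (rownames =
#' species, colnames = detailed sectors). Unknown species/sector names are
#' rejected.
#'
#' @param inv an `emission_inventory`
#' @param factors scalar, named numeric vector (species), or named matrix
#' @param year optional new year label
#' @export
scale_inventory <- function(inv, factors, year = inv$year) {
  sp <- inv$species
  sec <- names(inv$sector_map)
  fm <- matrix(1, length(sp), length(sec), dimnames = list(sp, sec))
  if (is.matrix(factors)) {
    if (is.null(rownames(factors)) || is.null(colnames(factors))) {
      stop("factor matrix needs species rownames and sector colnames")
    }
    bad_sp <- setdiff(rownames(factors), sp)
    bad_sec <- setdiff(colnames(factors), sec)
    if (length(bad_sp)) stop("unknown species: ", paste(bad_sp, collapse = ", "))
    if (length(bad_sec)) stop("unknown sector: ", paste(bad_sec, collapse = ", "))
    fm[rownames(factors), colnames(factors)] <- factors
  } else if (!is.null(names(factors))) {
    bad <- setdiff(names(factors), sp)
    if (length(bad)) stop("unknown species: ", paste(bad, collapse = ", "))
    fm[names(factors), ] <- factors
  } else if (length(factors) == 1) {
    fm[] <- factors
  } else {
    stop("factors must be scalar, a named species vector, or a species x sector matrix")
  }
  if (any(fm < 0)) stop("factors must be >= 0")
  mass <- inv$mass
  for (s in seq_along(sp)) {
    mass[, , , s] <- mass[, , , s] * rep(fm[s, ], each = dim(mass)[1] * 12)
  }
  emission_inventory(inv$grid, mass, inv$sector_map, sp, year)
}

# per-(coarse cell, month, species) emission totals: sum over sectors and
# fine children; used as the forward model source
coarse_emissions <- function(inv, coarse) {
  p <- parent_index(inv$grid, coarse)
  nsp <- length(inv$species)
  out <- array(0, c(coarse$ncell, 12, nsp),
               dimnames = list(NULL, NULL, inv$species))
  for (s in seq_len(nsp)) {
    # sum detailed sectors, then fine cells into parents
    cell_month <- rowSums(inv$mass[, , , s, drop = FALSE], dims = 2)
    out[, , s] <- sum_fine_to_coarse(cell_month, p, coarse$ncell)
  }
  out
}
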