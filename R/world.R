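#' @importFrom stats rnorm runif rlnorm setNames
NULL

# deterministic substream seed: one shared base seed, named substreams per
# component so adding a component never perturbs the others
substream_seed <- function(seed, name) {
  h <- 0
  for (code in utf8ToInt(name)) h <- (h * 131 + code) %% 1999999973
  as.integer((as.numeric(seed) * 1000003 + h) %% 2147483629)
}

with_substream <- function(seed, name, expr) {
  set.seed(substream_seed(seed, name))
  expr
}

# 3x3 box smoothing of a cell vector on a grid (replicated edges)
smooth_grid <- function(v, grid, passes = 1) {
  m <- matrix(v, grid$nlat, grid$nlon)
  for (p in seq_len(passes)) {
    up <- m[c(1, seq_len(grid$nlat - 1)), ]
    dn <- m[c(seq_len(grid$nlat - 1) + 1, grid$nlat), ]
    lf <- m[, c(1, seq_len(grid$nlon - 1))]
    rt <- m[, c(seq_len(grid$nlon - 1) + 1, grid$nlon)]
    m <- (m + up + dn + lf + rt) / 5
  }
  as.vector(m)
}

#' Configuration of the synthetic study world
#'
#' Bundles every tunable of the seeded input generator: grid sizes, country
#' partition, population, emission totals and seasonality, exposure-response
#' and mortality parameters with low/mid/high bounds, satellite noise,
#' meteorology, chemistry and boundary inflow. The seed fully determines all
#' generated inputs. Defaults are fixed at the desk-scale study conditions
#' described in the methods vignette.
#'
#' @param seed integer RNG seed for all substreams
#' @param nlat,nlon,refine grid sizes (see [make_grids()])
#' @param n_countries number of countries tiling the land area
#' @param country_blocks c(lat blocks, lon blocks); product = `n_countries`
#' @param receptor_countries indices of receptor-flagged countries
#' @param ocean_frac fraction of westernmost columns declared ocean
#' @param population_total persons in the domain
#' @param pop_bounds multiplicative low/high population bounds
#' @param n_cities number of urban log-normal clusters
#' @param emission_totals species x main-sector annual totals (kg/yr, 2015)
#' @param emission_changes named per-species relative change 2005 -> 2015
#' @param sector_changes named per-detailed-sector relative change 2005 -> 2015
#' @param satellite_noise_cv coefficient of variation of satellite noise
#' @param satellite_mean domain-mean satellite PM2.5 (ug/m3)
#' @param satellite_background additive floor of the satellite proxy (ug/m3)
#' @param tmrel theoretical minimum-risk exposure level (ug/m3)
#' @param mortality_mean_west,mortality_mean_east six-cause mean baseline
#'   mortality (deaths per 100k/yr) at the west/east edges of the domain
#' @param wind_u0,wind_u_amp,wind_v0,wind_v_amp,wind_noise monthly wind (m/s)
#' @param diffusivity horizontal eddy diffusivity (m2/s)
#' @param mixing_height boundary-layer mixing height (m)
#' @param deposition per-component first-order deposition rate (1/day)
#' @param yields precursor-to-aerosol mass yields per species
#' @param boundary_inflow per-component edge inflow concentration (ug/m3)
#' @param nh3_demand,nh3_yield_free,nh3_sharpness ammonia-limitation params
#' @return a list of class `world_config`
#' @export
world_config <- function(
    seed = 1L,
    nlat = 30, nlon = 40, refine = 4,
    n_countries = 12, country_blocks = c(4, 3),
    receptor_countries = seq_len(n_countries),
    ocean_frac = 0.15,
    population_total = 5.9897e8,
    pop_bounds = c(low = 0.80, high = 1.54),
    n_cities = 25,
    emission_totals = default_emission_totals(),
    emission_changes = c(NOx = -0.193, NH3 = -0.013, SO2 = -0.349,
                         SOAP = -0.268, OC = -0.12, BC = -0.18),
    sector_changes = c("aviation-cruise" = 0.262, "aviation-lto" = 0.05,
                       "agriculture-crops" = 0.053,
                       "agriculture-waste-burning" = 0.051,
                       "residential-heating" = 0.02, "residential-other" = 0.02),
    satellite_noise_cv = 0.15,
    satellite_mean = 12, satellite_background = 4,
    tmrel = 2.4,
    mortality_mean_west = 295, mortality_mean_east = 1025,
    wind_u0 = 3.0, wind_u_amp = 1.2, wind_v0 = 0.4, wind_v_amp = 0.5,
    wind_noise = 0.6,
    diffusivity = 2.5e4,
    mixing_height = 1000,
    deposition = c(sulfate = 0.15, nitrate = 0.18, ammonium = 0.15,
                   OC = 0.20, BC = 0.15, SOA = 0.15, dust = 0.30,
                   NH3avail = 0.25),
    yields = c(NOx = 0.35, NH3 = 0.40, SO2 = 0.55, OC = 1.0, BC = 1.0,
               SOAP = 0.50),
    boundary_inflow = c(sulfate = 0.85, nitrate = 0.43, ammonium = 0.34,
                        OC = 0.60, BC = 0.13, SOA = 0.51, dust = 1.02),
    nh3_demand = 1.2, nh3_yield_free = 1.0, nh3_sharpness = 1.5) {
  if (prod(country_blocks) != n_countries) {
    stop("country_blocks must multiply to n_countries")
  }
  if (length(receptor_countries) < 1) stop("receptor country set must not be empty")
  if (satellite_noise_cv < 0) stop("satellite noise CV must be >= 0")
  if (any(emission_totals < 0)) stop("emission totals must be >= 0")
  if (any(deposition <= 0)) stop("deposition rates must be > 0")
  if (any(yields < 0)) stop("yields must be >= 0")
  cfg <- as.list(environment())
  class(cfg) <- "world_config"
  cfg
}

#' Default 2015 annual emission totals (kg/yr) by species and main sector
#' @export
default_emission_totals <- function() {
  main <- c("shipping", "aviation", "energy", "industry", "ground transport",
            "waste", "agricultural", "residential")
  m <- 1.2 * rbind(
    NOx  = c(8.0e7, 3.5e7, 1.5e8, 1.0e8, 2.5e8, 5e6, 1.0e7, 3.0e7),
    NH3  = c(0,     0,     2e6,   5e6,   8e6,   2e7, 3.0e8, 3.0e7),
    SO2  = c(5.0e7, 5e6,   2.2e8, 1.0e8, 1e7,   5e6, 2e6,   3.0e7),
    OC   = c(5e6,   1e6,   5e6,   1.5e7, 2.5e7, 1e7, 3.0e7, 1.2e8),
    BC   = c(1.0e7, 2e6,   5e6,   1.5e7, 5.0e7, 5e6, 5e6,   4.5e7),
    SOAP = c(5e6,   2e6,   2.0e7, 5.0e7, 6.0e7, 5e6, 5e6,   8.0e7)
  )
  colnames(m) <- main
  m
}

# monthly profile helpers: 12 weights normalized to sum to 12
norm_profile <- function(w) 12 * w / sum(w)

#' Seasonal emission profiles per detailed sector
#'
#' Twelve monthly weights per detailed sector, each summing to 12. The
#' residential sectors peak in winter, the agricultural crop/waste-burning
#' sectors peak in late winter-spring (Feb-Apr), aviation mildly in summer.
#'
#' @param sector_map detailed -> main sector map
#' @return matrix `n_sector x 12`
#' @export
default_seasonal_profiles <- function(sector_map = default_sector_map()) {
  m <- 1:12
  base <- list(
    "shipping" = rep(1, 12),
    "aviation" = 1 + 0.15 * cos(2 * pi * (m - 7) / 12),
    "energy" = 1 + 0.25 * cos(2 * pi * (m - 1) / 12),
    "industry" = 1 + 0.10 * cos(2 * pi * (m - 1) / 12),
    "ground transport" = rep(1, 12),
    "waste" = rep(1, 12),
    "agricultural" = 1 + 0.20 * cos(2 * pi * (m - 4) / 12),
    "residential" = 1 + 0.80 * cos(2 * pi * (m - 1) / 12)
  )
  prof <- t(vapply(names(sector_map), function(s) base[[sector_map[[s]]]], numeric(12)))
  spring <- 1 + 0.80 * cos(2 * pi * (m - 3) / 12) # Feb-Apr peak
  for (s in c("agriculture-crops", "agriculture-waste-burning")) {
    if (s %in% rownames(prof)) prof[s, ] <- spring
  }
  t(apply(prof, 1, norm_profile))
}

# fraction of each main-sector total carried by its detailed sectors
default_sector_split <- function(sector_map = default_sector_map()) {
  split <- c(
    "energy-power" = 0.80, "energy-other" = 0.20,
    "industry-combustion" = 0.60, "industry-process" = 0.40,
    "road-transport" = 0.75, "ground-transport-other" = 0.25,
    "domestic-shipping" = 0.30, "international-shipping" = 0.70,
    "aviation-lto" = 0.30, "aviation-cruise" = 0.70,
    "residential-heating" = 0.70, "residential-other" = 0.30,
    "waste" = 1.00,
    "agriculture-livestock" = 0.55, "agriculture-crops" = 0.35,
    "agriculture-waste-burning" = 0.10
  )
  split[names(sector_map)]
}

# Bresenham-style raster of the straight segment between two (ilat, ilon)
line_cells <- function(grid, a, b) {
  n <- max(abs(b - a)) + 1L
  ilat <- round(seq(a[1], b[1], length.out = n))
  ilon <- round(seq(a[2], b[2], length.out = n))
  unique(cell_index(grid, ilat, ilon))
}

#' Generate the synthetic study world
#'
#' Deterministically builds every input of the analysis from a
#' [world_config()]: a country partition of the land area, log-normal urban
#' population clusters on a rural floor, a monthly multi-species emission
#' inventory assembled from sectoral source archetypes (point sources for
#' energy/industry, population-proportional area sources, transport and
#' shipping corridors, cropland blocks) with seasonal cycles, GBD-style
#' mortality tables and relative-risk curves with bounds, monthly wind
#' fields, boundary inflow, and a noisy satellite-style PM2.5 field. The same
#' seed yields a bit-identical world; each component draws from its own
#' named substream.
#'
#' @param config a [world_config()]
#' @return a list of class `synthetic_world`
#' @export
generate_world <- function(config = world_config()) {
  stopifnot(inherits(config, "world_config"))
  grids <- make_grids(config$nlat, config$nlon, config$refine)
  fine <- grids$fine
  coarse <- grids$coarse
  seed <- config$seed

  ## country mask: westernmost band is ocean, land tiled by contiguous blocks
  n_ocean_cols <- max(1L, round(config$ocean_frac * fine$nlon))
  ilat <- rep(seq_len(fine$nlat), times = fine$nlon)
  ilon <- rep(seq_len(fine$nlon), each = fine$nlat)
  land <- ilon > n_ocean_cols
  bl <- config$country_blocks
  land_cols <- fine$nlon - n_ocean_cols
  blk_lat <- pmin(bl[1], 1L + ((ilat - 1L) * bl[1]) %/% fine$nlat)
  blk_lon <- pmin(bl[2], pmax(1L, 1L + ((ilon - n_ocean_cols - 1L) * bl[2]) %/% land_cols))
  ids <- ifelse(land, (blk_lon - 1L) * bl[1] + blk_lat, 0L)
  cnames <- sprintf("country_%02d", seq_len(config$n_countries))
  receptor <- seq_len(config$n_countries) %in% config$receptor_countries
  if (!any(receptor)) stop("receptor country set must not be empty")
  mask <- country_mask(fine, ids, cnames, receptor)

  ## population: log-normal urban clusters on a rural floor
  pop <- with_substream(seed, "population", {
    land_idx <- which(land)
    n_cities <- min(config$n_cities, length(land_idx))
    cities <- sample(land_idx, n_cities)
    amp <- rlnorm(n_cities, meanlog = 0, sdlog = 0.7)
    sig <- runif(n_cities, 1.5, 4.0)
    dens <- numeric(fine$ncell)
    for (k in seq_len(n_cities)) {
      d2 <- (ilat - ilat[cities[k]])^2 + (ilon - ilon[cities[k]])^2
      dens <- dens + amp[k] * exp(-d2 / (2 * sig[k]^2))
    }
    dens[!land] <- 0
    rural <- as.numeric(land)
    p <- 0.8 * dens / sum(dens) + 0.2 * rural / sum(rural)
    p * config$population_total
  })
  population <- field(fine, pop, "persons")

  ## country x cause baseline mortality with low/mid/high bounds
  cause_shares <- c(IHD = 0.45, stroke = 0.24, COPD = 0.11, LC = 0.08,
                    LRI = 0.06, T2D = 0.06)
  mortality <- with_substream(seed, "mortality", {
    blc <- config$country_blocks[2]
    col_of <- function(id) (id - 1L) %/% config$country_blocks[1] + 1L
    rows <- list()
    for (cid in seq_len(config$n_countries)) {
      frac <- if (blc > 1) (col_of(cid) - 1) / (blc - 1) else 0
      mean6 <- config$mortality_mean_west +
        frac * (config$mortality_mean_east - config$mortality_mean_west)
      mean6 <- mean6 * exp(rnorm(1, 0, 0.08))
      lo_f <- runif(1, 0.85, 0.95)
      hi_f <- runif(1, 1.05, 1.20)
      for (d in names(cause_shares)) {
        mid <- mean6 * cause_shares[[d]]
        rows[[length(rows) + 1L]] <- data.frame(
          country = cnames[cid], cause = d,
          y0_low = lo_f * mid, y0_mid = mid, y0_high = hi_f * mid
        )
      }
    }
    do.call(rbind, rows)
  })

  rr <- default_rr_curves(tmrel = config$tmrel)

  ## emission inventory 2015 from sectoral source archetypes
  smap <- default_sector_map()
  profiles <- default_seasonal_profiles(smap)
  split <- default_sector_split(smap)
  templates <- with_substream(seed, "emissions", {
    land_idx <- which(land)
    ocean_idx <- which(!land)
    point_template <- function(k, sdlog = 1) {
      k <- min(k, length(land_idx))
      cells <- sample(land_idx, k)
      wts <- rlnorm(k, 0, sdlog)
      t <- numeric(fine$ncell); t[cells] <- wts; t / sum(t)
    }
    patch_template <- function(n_patches, wmin = 6, wmax = 16) {
      t <- numeric(fine$ncell)
      for (p in seq_len(n_patches)) {
        c0 <- sample(land_idx, 1)
        hw <- round(runif(2, wmin, wmax) / 2)
        sel <- abs(ilat - ilat[c0]) <= hw[1] & abs(ilon - ilon[c0]) <= hw[2] & land
        t[sel] <- t[sel] + runif(1, 0.5, 1.5)
      }
      if (sum(t) == 0) t[land_idx] <- 1
      t / sum(t)
    }
    pop_template <- pop / sum(pop)
    top_cities <- order(pop, decreasing = TRUE)[seq_len(min(10, length(land_idx)))]
    corridor <- {
      t <- numeric(fine$ncell)
      for (k in seq_len(length(top_cities) - 1)) {
        a <- top_cities[k]; b <- top_cities[k + 1]
        cl <- line_cells(fine, c(ilat[a], ilon[a]), c(ilat[b], ilon[b]))
        t[cl] <- t[cl] + 1
      }
      t[top_cities] <- t[top_cities] + 3
      t[!land] <- 0
      t / sum(t)
    }
    lane <- function(cols) {
      t <- numeric(fine$ncell)
      t[ilon %in% cols] <- 1
      t / sum(t)
    }
    uniform_all <- rep(1 / fine$ncell, fine$ncell)
    lto <- { t <- numeric(fine$ncell)
             t[top_cities[seq_len(min(8, length(top_cities)))]] <- 1
             t / sum(t) }
    list(
      "energy-power" = point_template(10),
      "energy-other" = point_template(15),
      "industry-combustion" = point_template(25),
      "industry-process" = point_template(20),
      "road-transport" = 0.85 * corridor + 0.15 * pop_template,
      "ground-transport-other" = 0.5 * corridor + 0.5 * pop_template,
      "domestic-shipping" = lane(max(1L, n_ocean_cols - 1L):n_ocean_cols),
      "international-shipping" = lane(max(1L, n_ocean_cols %/% 2L)),
      "aviation-lto" = lto,
      "aviation-cruise" = uniform_all,
      "residential-heating" = pop_template,
      "residential-other" = pop_template,
      "waste" = pop_template,
      "agriculture-livestock" = patch_template(8),
      "agriculture-crops" = patch_template(8),
      "agriculture-waste-burning" = patch_template(5)
    )
  })
  sp <- pm_species()
  main_of <- smap
  tot <- config$emission_totals
  mass <- array(0, c(fine$ncell, 12, length(smap), length(sp)))
  for (s in seq_along(sp)) {
    for (k in seq_along(smap)) {
      det <- names(smap)[k]
      total_sk <- tot[sp[s], main_of[[det]]] * split[[det]]
      if (total_sk <= 0) next
      mass[, , k, s] <- outer(templates[[det]] * total_sk, profiles[det, ] / 12)
    }
  }
  inv2015 <- emission_inventory(fine, mass, smap, sp, "2015")

  ## 2005 inventory: invert the printed 2005 -> 2015 changes
  fac <- matrix(1, length(sp), length(smap), dimnames = list(sp, names(smap)))
  for (s in names(config$emission_changes)) {
    fac[s, ] <- 1 / (1 + config$emission_changes[[s]])
  }
  for (k in names(config$sector_changes)) {
    fac[, k] <- fac[, k] / (1 + config$sector_changes[[k]])
  }
  inv2005 <- scale_inventory(inv2015, fac, year = "2005")

  ## meteorology: monthly wind on the coarse grid with smooth spatial texture
  met <- with_substream(seed, "meteorology", {
    m <- 1:12
    u <- outer(rep(1, coarse$ncell), config$wind_u0 +
                 config$wind_u_amp * cos(2 * pi * (m - 1) / 12))
    v <- outer(rep(1, coarse$ncell), config$wind_v0 +
                 config$wind_v_amp * sin(2 * pi * (m - 1) / 12))
    for (i in 1:12) {
      u[, i] <- u[, i] + smooth_grid(rnorm(coarse$ncell, 0, config$wind_noise), coarse, 3)
      v[, i] <- v[, i] + smooth_grid(rnorm(coarse$ncell, 0, config$wind_noise), coarse, 3)
    }
    list(u = u, v = v)
  })

  ## satellite-style annual PM2.5: smoothed emission proxy plus noise
  em_density <- rowSums(mass, dims = 1) / fine$area_w
  proxy <- smooth_grid(em_density, fine, 8)
  bg <- config$satellite_background
  truth <- bg + proxy / mean(proxy) * max(config$satellite_mean - bg, 0)
  satellite_truth <- field(fine, truth, "ug m-3")
  world <- structure(list(
    config = config, grids = grids, mask = mask,
    population = population, pop_bounds = config$pop_bounds,
    mortality = mortality, rr = rr,
    emissions = list("2015" = inv2015, "2005" = inv2005),
    profiles = profiles,
    met = met, boundary_inflow = config$boundary_inflow,
    satellite_truth = satellite_truth
  ), class = "synthetic_world")
  world$satellite <- generate_satellite(world, satellite_truth)
  world
}

#' @export
print.synthetic_world <- function(x, ...) {
  cat(sprintf(
    "synthetic_world (seed %d): %dx%d coarse / %dx%d fine, %d countries, pop %.4g\n",
    x$config$seed, x$grids$coarse$nlat, x$grids$coarse$nlon,
    x$grids$fine$nlat, x$grids$fine$nlon,
    length(x$mask$names), sum(x$population$values)
  ))
  invisible(x)
}

#' Satellite-style observation of an annual PM2.5 truth field
#'
#' Applies seeded multiplicative log-normal noise with mean one and the
#' configured coefficient of variation to a nonnegative truth field.
#'
#' @param world a `synthetic_world` (supplies seed and noise CV)
#' @param truth_annual nonnegative annual-mean `field` on the fine grid
#' @param cv optional CV override
#' @export
generate_satellite <- function(world, truth_annual, cv = world$config$satellite_noise_cv) {
  if (cv < 0) stop("satellite noise CV must be >= 0")
  tv <- field_values(truth_annual)
  if (any(tv < 0)) stop("truth field must be >= 0")
  if (cv == 0) return(field(world$grids$fine, tv, "ug m-3"))
  noise <- with_substream(world$config$seed, "satellite", {
    sdlog <- sqrt(log(1 + cv^2))
    rlnorm(length(tv), meanlog = -sdlog^2 / 2, sdlog = sdlog)
  })
  field(world$grids$fine, tv * noise, "ug m-3")
}
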