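#' Regular latitude-longitude grid specification
#'
#' Cell-centered regular lat-lon grid with half-open cell bounds
#' `[center - step/2, center + step/2)`. Cells are indexed latitude-fastest:
#' `cell = (ilon - 1) * nlat + ilat`, with both axes ascending. Relative cell
#' area weights are proportional to the cosine of the center latitude,
#' normalized to mean 1 over the grid; all fields on a grid share them.
#'
#' @param lat_centers ascending, regularly spaced latitude centers (degrees)
#' @param lon_centers ascending, regularly spaced longitude centers (degrees)
#' @return an object of class `grid_spec`
#' @export
grid_spec <- function(lat_centers, lon_centers) {
  check_regular <- function(x, what) {
    if (length(x) < 2) stop(what, " needs at least 2 centers")
    d <- diff(x)
    if (any(d <= 0)) stop(what, " centers must be ascending")
    if (max(d) - min(d) > 1e-9) stop(what, " step is not uniform")
    mean(d)
  }
  dlat <- check_regular(lat_centers, "lat")
  dlon <- check_regular(lon_centers, "lon")
  nlat <- length(lat_centers)
  nlon <- length(lon_centers)
  area_row <- cos(lat_centers * pi / 180)
  area_row <- area_row / mean(area_row)
  g <- list(
    lat = as.numeric(lat_centers), lon = as.numeric(lon_centers),
    nlat = nlat, nlon = nlon, ncell = nlat * nlon,
    dlat = dlat, dlon = dlon,
    # per-cell relative area weight, lat-fastest ordering
    area_w = rep(area_row, times = nlon)
  )
  class(g) <- "grid_spec"
  g
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf(
    "grid_spec: %d x %d cells, lat [%.3f, %.3f] step %.4f, lon [%.3f, %.3f] step %.4f\n",
    x$nlat, x$nlon, min(x$lat), max(x$lat), x$dlat, min(x$lon), max(x$lon), x$dlon
  ))
  invisible(x)
}

#' Linear cell index from (lat, lon) indices
#' @param grid a `grid_spec`
#' @param ilat,ilon 1-based axis indices
#' @export
cell_index <- function(grid, ilat, ilon) (ilon - 1L) * grid$nlat + ilat

#' Default coarse/fine grid pair for the toy European domain
#'
#' A 30 x 40 coarse grid spanning 32.75-61.25N, -15-40E (standing in for the
#' 0.25 x 0.3125 degree nested domain) with an integer refinement factor
#' giving the fine inventory/exposure grid (default 4, i.e. 120 x 160).
#'
#' @param nlat,nlon coarse grid size
#' @param refine integer refinement factor of the fine grid
#' @param lat0,lat1,lon0,lon1 domain edges (degrees)
#' @return list with elements `coarse` and `fine`
#' @export
make_grids <- function(nlat = 30, nlon = 40, refine = 4,
                       lat0 = 32.75, lat1 = 61.25, lon0 = -15, lon1 = 40) {
  dlat <- (lat1 - lat0) / nlat
  dlon <- (lon1 - lon0) / nlon
  coarse <- grid_spec(
    lat0 + dlat * (seq_len(nlat) - 0.5),
    lon0 + dlon * (seq_len(nlon) - 0.5)
  )
  nlat_f <- nlat * refine
  nlon_f <- nlon * refine
  fine <- grid_spec(
    lat0 + dlat / refine * (seq_len(nlat_f) - 0.5),
    lon0 + dlon / refine * (seq_len(nlon_f) - 0.5)
  )
  list(coarse = coarse, fine = fine)
}

#' Gridded field
#'
#' A field holds values over the cells of a grid: a vector (one slab), a
#' `ncell x 12` matrix (monthly), or any array whose first dimension is the
#' cell dimension. No NaN/NA values are permitted.
#'
#' @param grid a `grid_spec`
#' @param values numeric vector/matrix/array; first (or only) dim = ncell
#' @param units unit label
#' @export
field <- function(grid, values, units = "1") {
  stopifnot(inherits(grid, "grid_spec"))
  v <- if (is.null(dim(values))) as.numeric(values) else values
  n1 <- if (is.null(dim(v))) length(v) else dim(v)[1]
  if (n1 != grid$ncell) stop("values do not match grid: ", n1, " vs ", grid$ncell, " cells")
  if (anyNA(v) || any(!is.finite(v))) stop("field values must be finite (no NA/NaN)")
  structure(list(grid = grid, values = v, units = units), class = "field")
}

#' @export
print.field <- function(x, ...) {
  d <- if (is.null(dim(x$values))) length(x$values) else paste(dim(x$values), collapse = " x ")
  cat(sprintf("field [%s] on %d x %d grid, units '%s'\n", d, x$grid$nlat, x$grid$nlon, x$units))
  invisible(x)
}

field_values <- function(x) if (inherits(x, "field")) x$values else x

#' Integer refinement factor of a nested grid pair
#'
#' Checks that `fine` nests exactly in `coarse`: same extent, uniform steps,
#' and the coarse step an integer multiple of the fine step (within 1e-9
#' degrees). Rejects non-nesting pairs with a diagnostic.
#'
#' @param fine,coarse `grid_spec`s
#' @return the integer refinement factor
#' @export
nesting_factor <- function(fine, coarse) {
  r_lat <- coarse$dlat / fine$dlat
  r_lon <- coarse$dlon / fine$dlon
  r <- round(r_lat)
  if (abs(r_lat - r) > 1e-9 || abs(r_lon - r) > 1e-9 || r < 1) {
    stop("grids do not nest: step ratio lat ", r_lat, ", lon ", r_lon)
  }
  lo_f <- c(min(fine$lat) - fine$dlat / 2, min(fine$lon) - fine$dlon / 2)
  lo_c <- c(min(coarse$lat) - coarse$dlat / 2, min(coarse$lon) - coarse$dlon / 2)
  hi_f <- c(max(fine$lat) + fine$dlat / 2, max(fine$lon) + fine$dlon / 2)
  hi_c <- c(max(coarse$lat) + coarse$dlat / 2, max(coarse$lon) + coarse$dlon / 2)
  if (any(abs(lo_f - lo_c) > 1e-9) || any(abs(hi_f - hi_c) > 1e-9)) {
    stop("grids do not nest: domain extents differ")
  }
  as.integer(r)
}

#' Coarse parent cell index for every fine cell
#' @param fine,coarse nested `grid_spec`s
#' @return integer vector of length `fine$ncell`
#' @export
parent_index <- function(fine, coarse) {
  r <- nesting_factor(fine, coarse)
  ilat_f <- rep(seq_len(fine$nlat), times = fine$nlon)
  ilon_f <- rep(seq_len(fine$nlon), each = fine$nlat)
  ilat_c <- (ilat_f - 1L) %/% r + 1L
  ilon_c <- (ilon_f - 1L) %/% r + 1L
  cell_index(coarse, ilat_c, ilon_c)
}

#' Area-weighted aggregation of an intensive field to the coarse grid
#'
#' Each coarse value is the area-weighted mean of its fine children, so
#' intensive quantities (concentrations, rates) are conserved in the
#' area-mean sense.
#'
#' @param f a `field` (or plain values) on the fine grid
#' @param coarse the target `grid_spec`
#' @param fine fine `grid_spec` (required when `f` is not a `field`)
#' @return a `field` on the coarse grid (or plain values if `f` was plain)
#' @export
aggregate_fine_to_coarse <- function(f, coarse, fine = NULL) {
  is_f <- inherits(f, "field")
  if (is_f) fine <- f$grid
  if (is.null(fine)) stop("fine grid must be supplied for plain values")
  p <- parent_index(fine, coarse)
  w <- fine$area_w
  v <- field_values(f)
  vm <- if (is.null(dim(v))) matrix(v, ncol = 1) else v
  num <- rowsum(vm * w, p, reorder = TRUE)
  den <- rowsum(w, p, reorder = TRUE)
  out <- num / as.vector(den)
  if (is.null(dim(v))) out <- as.vector(out)
  if (is_f) field(coarse, out, f$units) else out
}

# extensive aggregation (mass): coarse value = sum of fine children
sum_fine_to_coarse <- function(values, p_index, ncoarse) {
  vm <- if (is.null(dim(values))) matrix(values, ncol = 1) else values
  out <- matrix(0, ncoarse, ncol(vm))
  agg <- rowsum(vm, p_index, reorder = TRUE)
  out[as.integer(rownames(agg)), ] <- agg
  if (is.null(dim(values))) as.vector(out) else out
}

#' Disaggregate a coarse field onto the fine grid
#'
#' Without a pattern each fine child copies its parent. With a nonnegative
#' pattern field, each child gets `parent * pattern / (area-weighted mean of
#' the pattern over the siblings)`, so the area-weighted child mean always
#' equals the parent value. Parents whose pattern sums to zero fall back to
#' the uniform copy with a warning.
#'
#' @param f coarse `field` or plain values
#' @param fine target `grid_spec`
#' @param pattern optional nonnegative `field`/values on the fine grid
#' @param coarse coarse `grid_spec` (when `f` is plain values)
#' @export
disaggregate_coarse_to_fine <- function(f, fine, pattern = NULL, coarse = NULL) {
  is_f <- inherits(f, "field")
  if (is_f) coarse <- f$grid
  if (is.null(coarse)) stop("coarse grid must be supplied for plain values")
  w <- disaggregation_weights(fine, coarse, pattern)
  v <- field_values(f)
  vm <- if (is.null(dim(v))) matrix(v, ncol = 1) else v
  out <- vm[w$parent, , drop = FALSE] * w$weight
  if (is.null(dim(v))) out <- as.vector(out)
  if (is_f) field(fine, out, f$units) else out
}

# Per-fine-cell multiplicative weights for pattern disaggregation; weight 1
# without pattern or within zero-pattern parents (uniform fallback).
disaggregation_weights <- function(fine, coarse, pattern = NULL) {
  p <- parent_index(fine, coarse)
  if (is.null(pattern)) {
    return(list(parent = p, weight = rep(1, fine$ncell)))
  }
  pv <- field_values(pattern)
  if (!is.null(dim(pv))) stop("pattern must be a single slab on the fine grid")
  if (length(pv) != fine$ncell) stop("pattern does not match the fine grid")
  if (any(pv < 0)) stop("pattern must be nonnegative")
  w <- fine$area_w
  den <- rowsum(pv * w, p, reorder = TRUE) / rowsum(w, p, reorder = TRUE)
  den <- as.vector(den)
  zero <- den <= 0
  if (any(zero)) {
    warning(sum(zero), " parent cell(s) have zero pattern; uniform fallback used")
  }
  weight <- ifelse(zero[p], 1, pv / ifelse(den[p] > 0, den[p], 1))
  list(parent = p, weight = weight)
}

#' Gridded country mask
#'
#' Integer country id per cell (0 = unassigned/ocean) plus a receptor flag
#' per country. The receptor region is the union of receptor-flagged
#' countries.
#'
#' @param grid a `grid_spec`
#' @param ids integer vector (length ncell), 0 for unassigned
#' @param names character vector of country names, one per positive id
#' @param receptor logical vector per country (same length as `names`)
#' @export
country_mask <- function(grid, ids, names, receptor = rep(TRUE, length(names))) {
  ids <- as.integer(ids)
  if (length(ids) != grid$ncell) stop("mask ids do not match grid")
  if (any(ids < 0) || anyNA(ids)) stop("ids must be >= 0")
  if (max(ids) > length(names)) stop("id exceeds country list")
  if (length(receptor) != length(names)) stop("receptor flags must match country list")
  structure(
    list(grid = grid, ids = ids, names = as.character(names), receptor = as.logical(receptor)),
    class = "country_mask"
  )
}

#' @export
print.country_mask <- function(x, ...) {
  cat(sprintf(
    "country_mask: %d countries (%d receptor-flagged), %d/%d unassigned cells\n",
    length(x$names), sum(x$receptor), sum(x$ids == 0L), length(x$ids)
  ))
  invisible(x)
}

#' Logical receptor-cell indicator
#' @param mask a `country_mask`
#' @export
receptor_cells <- function(mask) {
  rec_ids <- which(mask$receptor)
  mask$ids %in% rec_ids
}

#' Aggregate a field over countries
#'
#' Cells with id 0 are reported under `"unassigned"`; for `statistic = "sum"`
#' the country rows plus unassigned always add up to the domain total.
#'
#' @param f a `field` (single slab) or plain values on the mask's grid
#' @param mask a `country_mask`
#' @param statistic one of `"sum"`, `"mean"`, `"popwt"`
#' @param pop population values (required for `statistic = "popwt"`)
#' @return data.frame with columns `country`, `value`
#' @export
country_aggregate <- function(f, mask, statistic = c("sum", "mean", "popwt"), pop = NULL) {
  statistic <- match.arg(statistic)
  v <- field_values(f)
  if (!is.null(dim(v))) stop("country_aggregate expects a single slab")
  if (inherits(f, "field") && f$grid$ncell != mask$grid$ncell) {
    stop("field and mask grids differ")
  }
  if (length(v) != mask$grid$ncell) stop("values do not match mask grid")
  key <- factor(mask$ids, levels = 0:length(mask$names))
  val <- switch(statistic,
    sum = tapply(v, key, sum, default = 0),
    mean = tapply(v, key, mean, default = NA_real_),
    popwt = {
      if (is.null(pop)) stop("popwt statistic needs pop")
      pw <- field_values(pop)
      num <- tapply(v * pw, key, sum, default = 0)
      den <- tapply(pw, key, sum, default = 0)
      ifelse(den > 0, num / den, NA_real_)
    }
  )
  data.frame(
    country = c("unassigned", mask$names),
    value = as.numeric(val),
    row.names = NULL
  )
}
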