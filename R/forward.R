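#' @importFrom Matrix sparseMatrix Diagonal solve t
NULL

M_PER_DEG <- 111320           # meters per degree of latitude
DAYS_IN_MONTH <- c(31, 28, 31, 30, 31, 30, 31, 31, 30, 31, 30, 31)

#' PM2.5 aerosol components
#' @export
pm_components <- function() {
  c("sulfate", "nitrate", "ammonium", "OC", "BC", "SOA", "dust")
}

# which transported precursor field feeds each emitted species, plus the
# emission yield applied at the source
precursor_table <- function(yields) {
  data.frame(
    precursor = c("sulfate", "Np", "N3", "OC", "BC", "SOA"),
    species = c("SO2", "NOx", "NH3", "OC", "BC", "SOAP"),
    yield = c(yields[["SO2"]], yields[["NOx"]], 1.0, yields[["OC"]],
              yields[["BC"]], yields[["SOAP"]]),
    deposition = c("sulfate", "nitrate", "NH3avail", "OC", "BC", "SOA"),
    stringsAsFactors = FALSE
  )
}

# finite-volume transport operator for one month: first-order upwind
# advection plus 5-point diffusion, in flux form so that volume-integrated
# mass is conserved across interior faces. Units: per day. Boundary faces
# are advectively open (inflow carries the boundary concentration, outflow
# removes mass); diffusion is closed at the boundary.
build_transport <- function(grid, u, v, diffusivity, mixing_height) {
  nlat <- grid$nlat; nlon <- grid$nlon; ncell <- grid$ncell
  idx <- matrix(seq_len(ncell), nlat, nlon)
  dy <- grid$dlat * M_PER_DEG
  dx_row <- grid$dlon * M_PER_DEG * cos(grid$lat * pi / 180)
  h <- mixing_height
  vol <- rep(dx_row, times = nlon) * dy * h
  day <- 86400
  D <- diffusivity * day

  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  inflow <- numeric(ncell)
  add <- function(i, j, x) {
    ii <<- c(ii, i); jj <<- c(jj, j); xx <<- c(xx, x)
  }

  ## x-direction interior faces
  if (nlon > 1) {
    L <- as.vector(idx[, 1:(nlon - 1)])
    R <- as.vector(idx[, 2:nlon])
    uf <- 0.5 * (u[L] + u[R]) * day
    A <- dy * h
    up <- uf > 0
    # advection: donor-cell flux uf * A * c_donor
    add(L[up], L[up], -uf[up] * A / vol[L[up]])
    add(R[up], L[up], uf[up] * A / vol[R[up]])
    dn <- !up
    add(R[dn], R[dn], uf[dn] * A / vol[R[dn]])
    add(L[dn], R[dn], -uf[dn] * A / vol[L[dn]])
    # diffusion across the face, gradient distance = local dx
    d <- rep(dx_row, times = nlon - 1)
    g <- D * A / d
    add(L, L, -g / vol[L]); add(L, R, g / vol[L])
    add(R, R, -g / vol[R]); add(R, L, g / vol[R])
  }
  ## y-direction interior faces
  if (nlat > 1) {
    S <- as.vector(idx[1:(nlat - 1), ])
    N <- as.vector(idx[2:nlat, ])
    vf <- 0.5 * (v[S] + v[N]) * day
    dx_face <- rep(0.5 * (dx_row[1:(nlat - 1)] + dx_row[2:nlat]), times = nlon)
    A <- dx_face * h
    up <- vf > 0
    add(S[up], S[up], -vf[up] * A[up] / vol[S[up]])
    add(N[up], S[up], vf[up] * A[up] / vol[N[up]])
    dn <- !up
    add(N[dn], N[dn], vf[dn] * A[dn] / vol[N[dn]])
    add(S[dn], N[dn], -vf[dn] * A[dn] / vol[S[dn]])
    g <- D * A / dy
    add(S, S, -g / vol[S]); add(S, N, g / vol[S])
    add(N, N, -g / vol[N]); add(N, S, g / vol[N])
  }
  ## open advective boundaries
  west <- idx[, 1]; east <- idx[, nlon]
  ub_w <- u[west] * day; ub_e <- u[east] * day
  A_x <- dy * h
  inflow[west] <- inflow[west] + pmax(ub_w, 0) * A_x / vol[west]
  add(east, east, -pmax(ub_e, 0) * A_x / vol[east])
  inflow[east] <- inflow[east] + pmax(-ub_e, 0) * A_x / vol[east]
  add(west, west, -pmax(-ub_w, 0) * A_x / vol[west])
  south <- idx[1, ]; north <- idx[nlat, ]
  vb_s <- v[south] * day; vb_n <- v[north] * day
  A_s <- dx_row[1] * h; A_n <- dx_row[nlat] * h
  inflow[south] <- inflow[south] + pmax(vb_s, 0) * A_s / vol[south]
  add(north, north, -pmax(vb_n, 0) * A_n / vol[north])
  inflow[north] <- inflow[north] + pmax(-vb_n, 0) * A_n / vol[north]
  add(south, south, -pmax(-vb_s, 0) * A_s / vol[south])

  keep <- xx != 0
  T <- sparseMatrix(i = ii[keep], j = jj[keep], x = xx[keep],
                    dims = c(ncell, ncell))
  list(T = T, inflow = inflow, vol = vol)
}

#' Toy chemical-transport model parameters and operators
#'
#' Assembles the monthly transport operators (first-order upwind advection +
#' 5-point diffusion + open advective boundaries, adjoint = exact matrix
#' transpose), per-component deposition rates, precursor-to-aerosol yields,
#' boundary inflow and the ammonia-limitation settings from a synthetic
#' world. Months are independent steady states, solved directly as sparse
#' linear systems.
#'
#' @param world a `synthetic_world`
#' @param nonlinear enable the ammonia-limited nitrate coupling
#' @param boundary optional override of the per-component inflow
#'   concentrations (ug/m3)
#' @return list of class `ctm_params`
#' @export
ctm_params <- function(world, nonlinear = FALSE, boundary = NULL) {
  cfg <- world$config
  coarse <- world$grids$coarse
  ops <- lapply(1:12, function(m) {
    build_transport(coarse, world$met$u[, m], world$met$v[, m],
                    cfg$diffusivity, cfg$mixing_height)
  })
  structure(list(
    grid = coarse, ops = ops, days = DAYS_IN_MONTH,
    deposition = cfg$deposition, yields = cfg$yields,
    boundary = if (is.null(boundary)) cfg$boundary_inflow else boundary,
    nonlinear = isTRUE(nonlinear),
    nh3 = list(demand = cfg$nh3_demand, yield_free = cfg$nh3_yield_free,
               sharpness = cfg$nh3_sharpness),
    mixing_height = cfg$mixing_height,
    yield_nh4 = cfg$yields[["NH3"]],
    prec = precursor_table(cfg$yields)
  ), class = "ctm_params")
}

# stable softplus and smooth-min plus their partial derivatives
softplus <- function(x, beta) {
  ifelse(x > 0, x + log1p(exp(-beta * x)) / beta, log1p(exp(beta * x)) / beta)
}
smooth_min <- function(a, b, beta) {
  pmin(a, b) - log1p(exp(-beta * abs(a - b))) / beta
}

#' Ammonia-limited nitrate formation
#'
#' The toy model's sole chemical nonlinearity: nitrate is the smooth minimum
#' of the transport-limited nitrate potential and the yield times the free
#' ammonia remaining after sulfate neutralization,
#' `smin(Np, yield * softplus(NH3 - demand * sulfate))`. Smooth operators
#' (sharpness `beta`) keep the model differentiable for the adjoint.
#'
#' @param sulfate,nitrate_potential,nh3_available nonnegative fields (ug/m3)
#' @param yield nitrate formed per unit free ammonia
#' @param demand ammonia consumed per unit sulfate
#' @param beta sharpness of the smooth min / softplus (per ug/m3)
#' @export
apply_nh3_limitation <- function(sulfate, nitrate_potential, nh3_available,
                                 yield = 1.0, demand = 1.2, beta = 1.5) {
  if (any(sulfate < 0) || any(nitrate_potential < 0) || any(nh3_available < 0)) {
    stop("inputs must be >= 0")
  }
  free <- softplus(nh3_available - demand * sulfate, beta)
  smooth_min(nitrate_potential, yield * free, beta)
}

# partial derivatives of the limited nitrate w.r.t. (Np, N3, S)
nh3_limitation_grad <- function(sulfate, nitrate_potential, nh3_available,
                                yield, demand, beta) {
  x <- nh3_available - demand * sulfate
  free <- softplus(x, beta)
  a <- nitrate_potential; b <- yield * free
  d_a <- stats::plogis(beta * (b - a))   # d smin / d a
  d_b <- 1 - d_a
  d_free <- stats::plogis(beta * x)
  list(dNp = d_a, dN3 = d_b * yield * d_free, dS = -d_b * yield * d_free * demand)
}

#' Run the forward model for one year
#'
#' For every month and transported precursor the steady-state balance
#' (advection + diffusion + first-order deposition + converted emission
#' source + boundary inflow) is solved directly. In linear mode the output is
#' exactly linear in emissions and boundary inflow; with
#' `params$nonlinear = TRUE` nitrate passes through the ammonia limitation.
#'
#' @param emissions an `emission_inventory` (fine grid) or a pre-aggregated
#'   coarse array `(ncell_coarse, 12, species)`
#' @param params a [ctm_params()]
#' @param boundary_scale scalar multiplier of all boundary inflow (the BC
#'   perturbation knob)
#' @return list of class `concentration_set`: per-component monthly coarse
#'   fields (ug/m3) plus the transported precursor fields
#' @export
run_forward <- function(emissions, params, boundary_scale = 1) {
  grid <- params$grid
  E <- if (inherits(emissions, "emission_inventory")) {
    coarse_emissions(emissions, grid)
  } else emissions
  stopifnot(length(dim(E)) == 3, dim(E)[1] == grid$ncell, dim(E)[2] == 12)
  sp_names <- dimnames(E)[[3]]
  prec <- params$prec
  cb <- params$boundary * boundary_scale
  # boundary ammonium rides the free-ammonia tracer
  cb_prec <- c(sulfate = cb[["sulfate"]], Np = cb[["nitrate"]],
               N3 = cb[["ammonium"]] / params$yield_nh4,
               OC = cb[["OC"]], BC = cb[["BC"]], SOA = cb[["SOA"]])
  fields <- lapply(setNames(nm = prec$precursor), function(p) matrix(0, grid$ncell, 12))
  dust <- matrix(0, grid$ncell, 12)
  for (m in 1:12) {
    op <- params$ops[[m]]
    src_scale <- 1e9 / (op$vol * params$days[m])   # kg/month -> ug m-3 day-1
    for (r in seq_len(nrow(prec))) {
      p <- prec$precursor[r]
      k <- params$deposition[[prec$deposition[r]]]
      s_idx <- match(prec$species[r], sp_names)
      q <- prec$yield[r] * E[, m, s_idx] * src_scale
      rhs <- q + op$inflow * cb_prec[[p]]
      M <- Diagonal(grid$ncell, k) - op$T
      fields[[p]][, m] <- as.numeric(solve(M, rhs))
    }
    Md <- Diagonal(grid$ncell, params$deposition[["dust"]]) - op$T
    dust[, m] <- as.numeric(solve(Md, op$inflow * cb[["dust"]]))
  }
  nh3 <- params$nh3
  nitrate <- if (params$nonlinear) {
    apply_nh3_limitation(fields$sulfate, fields$Np, fields$N3,
                         yield = nh3$yield_free, demand = nh3$demand,
                         beta = nh3$sharpness)
  } else {
    fields$Np
  }
  comp <- list(
    sulfate = fields$sulfate, nitrate = nitrate,
    ammonium = params$yield_nh4 * fields$N3,
    OC = fields$OC, BC = fields$BC, SOA = fields$SOA, dust = dust
  )
  structure(list(grid = grid, components = comp, precursors = fields,
                 nonlinear = params$nonlinear),
            class = "concentration_set")
}

#' @export
print.concentration_set <- function(x, ...) {
  cat(sprintf("concentration_set: %d components, %s chemistry\n",
              length(x$components), if (x$nonlinear) "nonlinear" else "linear"))
  invisible(x)
}

#' Total PM2.5 from a concentration set
#'
#' PM2.5 is the sum of the seven component fields (sulfate, nitrate,
#' ammonium, OC, BC, SOA, dust); the annual field is the unweighted mean of
#' the 12 monthly fields.
#'
#' @param conc a `concentration_set`
#' @return list with `monthly` (ncell x 12) and `annual` (ncell) values
#' @export
compute_pm25 <- function(conc) {
  need <- pm_components()
  missing <- setdiff(need, names(conc$components))
  if (length(missing)) stop("missing component(s): ", paste(missing, collapse = ", "))
  monthly <- Reduce(`+`, conc$components[need])
  list(monthly = monthly, annual = rowMeans(monthly))
}

# steady-state mass budget (ug/day): deposition loss vs source + net
# boundary exchange; closes to machine precision by construction
mass_budget <- function(c_field, op, k, q, cb) {
  vol <- op$vol
  list(
    deposition = sum(vol * k * c_field),
    source = sum(vol * q),
    inflow = sum(vol * op$inflow * cb),
    net_transport = sum(vol * as.numeric(op$T %*% c_field))
  )
}
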