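#' Run the base forward chain: emissions -> exposure -> deaths
#'
#' Executes the full forward pipeline for one inventory: forward transport
#' and chemistry, satellite rescaling (fresh, or frozen to a previous run's
#' ratios), satellite-pattern downscaling, and the mortality cost function.
#' The returned bundle is the linearization point for the adjoint.
#'
#' @param world a `synthetic_world`
#' @param params a [ctm_params()]
#' @param health a `health_inputs`
#' @param inv inventory to run (default the world's 2015 inventory)
#' @param boundary_scale scalar on all boundary inflow
#' @param ratios frozen `rescale_result` (NULL computes fresh ratios)
#' @param response health response mode, `"gbd"` or `"linear"`
#' @param bound health bound
#' @return list of class `base_run`
#' @export
run_base <- function(world, params, health, inv = world$emissions[["2015"]],
                     boundary_scale = 1, ratios = NULL,
                     response = "gbd", bound = "mid") {
  conc <- run_forward(inv, params, boundary_scale)
  pm <- compute_pm25(conc)
  resc <- rescale_to_satellite(pm$monthly, world$satellite,
                               coarse = world$grids$coarse, ratios = ratios)
  expo <- downscale_exposure(resc, world$satellite,
                             fine = world$grids$fine,
                             coarse = world$grids$coarse)
  cost <- cost_function(expo, health, bound = bound, response = response)
  structure(list(world = world, params = params, health = health,
                 conc = conc, pm = pm, rescale = resc, exposure = expo,
                 cost = cost, response = response, bound = bound,
                 boundary_scale = boundary_scale),
            class = "base_run")
}

#' @export
print.base_run <- function(x, ...) {
  cat(sprintf("base_run: J = %.1f deaths (%s response, %s chemistry)\n",
              x$cost$J, x$response,
              if (x$params$nonlinear) "nonlinear" else "linear"))
  invisible(x)
}

# J for a perturbed input, reusing the base run's frozen correction ratios
evaluate_cost <- function(base, inv = NULL, E_coarse = NULL,
                          boundary_scale = base$boundary_scale) {
  emissions <- if (!is.null(E_coarse)) E_coarse else inv
  conc <- run_forward(emissions, base$params, boundary_scale)
  pm <- compute_pm25(conc)
  resc <- rescale_to_satellite(pm$monthly, base$world$satellite,
                               coarse = base$world$grids$coarse,
                               ratios = base$rescale)
  expo <- downscale_exposure(resc, base$world$satellite,
                             fine = base$world$grids$fine,
                             coarse = base$world$grids$coarse)
  cost_function(expo, base$health, bound = base$bound,
                response = base$response)$J
}

#' Chain the annual-exposure adjoint into monthly seeds
#'
#' The annual exposure is the unweighted mean of 12 months, so the exact
#' chain rule gives `dJ/dC_month = dJ/dC_annual / 12` for every month.
#'
#' @param dJ_dC_annual per-cell adjoint of the annual exposure
#' @return `ncell x 12` matrix of monthly adjoints
#' @export
monthly_exposure_chain <- function(dJ_dC_annual) {
  matrix(dJ_dC_annual / 12, length(dJ_dC_annual), 12)
}

#' Adjoint sensitivities of total deaths to emissions
#'
#' One reverse sweep through the discrete forward chain per month: the
#' health-model adjoint seeds the annual fine-exposure adjoint; the exact
#' chain rule through the annual mean, the downscaling weights and the
#' frozen rescaling ratios brings it to the coarse monthly PM2.5 adjoint;
#' the chemistry adjoint (transposed yields, or the ammonia-limitation
#' Jacobian in nonlinear mode) seeds each transported precursor; and the
#' transposed transport solve propagates back to emission space. Sensitivity
#' units are deaths per kg emitted, per (species, month, coarse cell).
#'
#' @param base a [run_base()] result (the linearization point)
#' @return list of class `sensitivity_field` with `lambda`
#'   `(ncell_coarse, 12, species)` and metadata
#' @export
run_adjoint <- function(base) {
  world <- base$world; params <- base$params; health <- base$health
  if (params$nonlinear && is.null(base$conc$precursors)) {
    stop("nonlinear mode needs the stored linearization point")
  }
  coarse <- world$grids$coarse
  g_ann <- deaths_dC(base$exposure, health, bound = base$bound,
                     response = base$response)
  g_month_fine <- monthly_exposure_chain(g_ann)
  # downscaling adjoint: fine = coarse[parent] * weight
  w <- base$exposure$weights
  g_coarse <- rowsum(g_month_fine * w$weight, w$parent, reorder = TRUE)
  # frozen-rescale adjoint (satellite-assigned cells have zero derivative)
  g_resc <- g_coarse * base$rescale$ratios

  prec <- params$prec
  sp <- pm_species()
  lambda <- array(0, c(coarse$ncell, 12, length(sp)),
                  dimnames = list(NULL, NULL, sp))
  nh3 <- params$nh3
  for (m in 1:12) {
    g_pm <- g_resc[, m]
    # PM2.5 sum adjoint: every component receives the same seed
    g_prec <- list(sulfate = g_pm, Np = numeric(coarse$ncell),
                   N3 = params$yield_nh4 * g_pm,
                   OC = g_pm, BC = g_pm, SOA = g_pm)
    if (params$nonlinear) {
      pr <- base$conc$precursors
      gr <- nh3_limitation_grad(pr$sulfate[, m], pr$Np[, m], pr$N3[, m],
                                yield = nh3$yield_free, demand = nh3$demand,
                                beta = nh3$sharpness)
      g_prec$Np <- gr$dNp * g_pm
      g_prec$N3 <- g_prec$N3 + gr$dN3 * g_pm
      g_prec$sulfate <- g_prec$sulfate + gr$dS * g_pm
    } else {
      g_prec$Np <- g_pm
    }
    op <- params$ops[[m]]
    src_scale <- 1e9 / (op$vol * params$days[m])
    for (r in seq_len(nrow(prec))) {
      p <- prec$precursor[r]
      k <- params$deposition[[prec$deposition[r]]]
      M <- Diagonal(coarse$ncell, k) - op$T
      lam_c <- as.numeric(solve(Matrix::t(M), g_prec[[p]]))
      lambda[, m, prec$species[r]] <- lam_c * prec$yield[r] * src_scale
    }
  }
  structure(list(grid = coarse, lambda = lambda, species = sp,
                 response = base$response, bound = base$bound,
                 nonlinear = params$nonlinear,
                 J_at_linearization = base$cost$J),
            class = "sensitivity_field")
}

#' @export
print.sensitivity_field <- function(x, ...) {
  cat(sprintf(
    "sensitivity_field: %d cells x 12 months x %d species, range [%.3g, %.3g] deaths/kg\n",
    dim(x$lambda)[1], dim(x$lambda)[3], min(x$lambda), max(x$lambda)))
  invisible(x)
}

#' Replicate coarse sensitivities onto the fine grid
#'
#' Sensitivity (deaths per kg) is an intensive quantity: every fine child
#' inherits its parent's value unchanged.
#'
#' @param sens a `sensitivity_field`
#' @param fine fine `grid_spec`
#' @return array `(ncell_fine, 12, species)`
#' @export
disaggregate_sensitivity <- function(sens, fine) {
  p <- parent_index(fine, sens$grid)
  out <- sens$lambda[p, , , drop = FALSE]
  dimnames(out) <- list(NULL, NULL, sens$species)
  out
}

#' Finite-difference verification of the adjoint gradient
#'
#' Samples emitting (species, month, fine cell) entries, perturbs each
#' entry's total mass by a symmetric relative step (all sectors scaled
#' together), recomputes J through the frozen-correction chain, and compares
#' the central difference against the adjoint sensitivity.
#'
#' Entries whose predicted cost response `2 h E lambda` falls below
#' `signal_floor` times J are excluded from sampling: there the central
#' difference of the cost sum resolves floating-point roundoff rather than
#' the gradient, so the oracle itself is meaningless at such entries.
#'
#' @param base a [run_base()] result
#' @param sens matching [run_adjoint()] result (computed if NULL)
#' @param inv inventory to perturb (default world 2015)
#' @param n_samples number of sampled entries (>= 1)
#' @param rel_step relative perturbation of the sampled entry
#' @param seed sampling seed
#' @param signal_floor minimum predicted |dJ|/J of a sampled entry
#' @return list with `max_rel_err`, `median_rel_err` and the per-sample table
#' @export
gradient_check <- function(base, sens = NULL, inv = base$world$emissions[["2015"]],
                           n_samples = 30, rel_step = 0.005, seed = 1,
                           signal_floor = 1e-8) {
  stopifnot(n_samples >= 1)
  if (is.null(sens)) sens <- run_adjoint(base)
  world <- base$world
  fine <- world$grids$fine
  lam_fine <- disaggregate_sensitivity(sens, fine)
  totals <- apply(inv$mass, c(1, 2, 4), sum)   # (cell, month, species)
  signal <- 2 * rel_step * totals * abs(lam_fine)
  floor_abs <- signal_floor * abs(base$cost$J)
  pos <- which(totals > 0 & signal > floor_abs, arr.ind = TRUE)
  if (nrow(pos) == 0) pos <- which(totals > 0, arr.ind = TRUE)
  set.seed(substream_seed(seed, "gradient-check"))
  if (nrow(pos) == 0) {
    # degenerate zero-emission base: sample anywhere, one-sided absolute step
    pos <- which(totals >= 0, arr.ind = TRUE)
  }
  take <- pos[sample(nrow(pos), min(n_samples, nrow(pos))), , drop = FALSE]
  res <- data.frame(cell = take[, 1], month = take[, 2],
                    species = inv$species[take[, 3]],
                    adjoint = NA_real_, fd = NA_real_, rel_err = NA_real_)
  for (r in seq_len(nrow(take))) {
    i <- take[r, 1]; m <- take[r, 2]; s <- take[r, 3]
    E0 <- totals[i, m, s]
    if (E0 > 0) {
      dE <- rel_step * E0
      inv_p <- inv; inv_p$mass[i, m, , s] <- inv$mass[i, m, , s] * (1 + rel_step)
      J_plus <- evaluate_cost(base, inv = inv_p)
      inv_p$mass[i, m, , s] <- inv$mass[i, m, , s] * (1 - rel_step)
      J_minus <- evaluate_cost(base, inv = inv_p)
      fd <- (J_plus - J_minus) / (2 * dE)
    } else {
      # one-sided absolute step at a zero-emission entry
      dE <- 1e3
      inv_p <- inv; inv_p$mass[i, m, 1, s] <- dE
      J_plus <- evaluate_cost(base, inv = inv_p)
      fd <- (J_plus - base$cost$J) / dE
    }
    adj <- lam_fine[i, m, s]
    res$adjoint[r] <- adj
    res$fd[r] <- fd
    res$rel_err[r] <- abs(fd - adj) / max(abs(fd), abs(adj), 1e-300)
  }
  list(max_rel_err = max(res$rel_err), median_rel_err = stats::median(res$rel_err),
       n = nrow(res), samples = res)
}

#' Inner-product identities of every linear operator
#'
#' For random forward input u and adjoint seed w, checks
#' `<A u, w> = <u, A' w>` for each linear building block of the chain: the
#' raw transport operator, the steady-state transport solve, fine-to-coarse
#' aggregation, pattern disaggregation, the frozen rescale diagonal, and the
#' annual-mean reduction, for every requested month.
#'
#' @param world a `synthetic_world`
#' @param params a [ctm_params()]
#' @param months months to test
#' @param seed RNG seed
#' @return list with `max_rel_err` and the per-check table
#' @export
adjoint_identity_check <- function(world, params, months = 1:12, seed = 1) {
  set.seed(substream_seed(seed, "adjoint-identity"))
  coarse <- world$grids$coarse
  fine <- world$grids$fine
  rel <- function(a, b) abs(a - b) / max(abs(a), abs(b), 1e-300)
  rows <- list()
  push <- function(op, m, err) {
    rows[[length(rows) + 1L]] <<- data.frame(op = op, month = m, rel_err = err)
  }
  k <- params$deposition[["sulfate"]]
  for (m in months) {
    op <- params$ops[[m]]
    u <- rnorm(coarse$ncell); w <- rnorm(coarse$ncell)
    Tu <- as.numeric(op$T %*% u)
    Ttw <- as.numeric(Matrix::t(op$T) %*% w)
    push("transport_operator", m, rel(sum(Tu * w), sum(u * Ttw)))
    M <- Diagonal(coarse$ncell, k) - op$T
    Au <- as.numeric(solve(M, u))
    Atw <- as.numeric(solve(Matrix::t(M), w))
    push("steady_solve", m, rel(sum(Au * w), sum(u * Atw)))
  }
  # aggregation: coarse = rowsum(w_area * fine) / rowsum(w_area)
  u_f <- rnorm(fine$ncell); w_c <- rnorm(coarse$ncell)
  p <- parent_index(fine, coarse)
  agg <- aggregate_fine_to_coarse(u_f, coarse, fine)
  den <- as.vector(rowsum(fine$area_w, p))
  adj_agg <- (fine$area_w / den[p]) * w_c[p]
  push("aggregate_mean", 0, rel(sum(agg * w_c), sum(u_f * adj_agg)))
  # disaggregation with the satellite pattern
  u_c <- rnorm(coarse$ncell); w_f <- rnorm(fine$ncell)
  dw <- disaggregation_weights(fine, coarse, world$satellite)
  dis <- u_c[dw$parent] * dw$weight
  adj_dis <- as.vector(rowsum(dw$weight * w_f, dw$parent, reorder = TRUE))
  push("disaggregate_pattern", 0, rel(sum(dis * w_f), sum(u_c * adj_dis)))
  # annual mean over months
  u_m <- matrix(rnorm(coarse$ncell * 12), coarse$ncell, 12)
  w_a <- rnorm(coarse$ncell)
  ann <- rowMeans(u_m)
  adj_ann <- matrix(w_a / 12, coarse$ncell, 12)
  push("annual_mean", 0, rel(sum(ann * w_a), sum(u_m * adj_ann)))
  tab <- do.call(rbind, rows)
  list(max_rel_err = max(tab$rel_err), checks = tab)
}
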