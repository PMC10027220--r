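#' Annual values of an exposure-like object
#'
#' Accepts an `exposure_field`, a `field` (vector slab, or monthly matrix
#' whose annual mean is taken), or plain numeric values.
#' @param x exposure object
#' @export
exposure_annual <- function(x) {
  if (inherits(x, "exposure_field")) return(x$fine_annual)
  v <- field_values(x)
  if (is.null(dim(v))) v else rowMeans(v)
}

#' Rescale modeled PM2.5 toward a satellite annual field
#'
#' Per coarse cell, the ratio of the satellite annual mean (aggregated to the
#' coarse grid) to the model annual mean is computed, clamped to
#' `[0.25, 4]`, and applied to every month, correcting the model bias while
#' preserving the monthly cycle. Cells with zero model annual but positive
#' satellite get the satellite annual assigned uniformly across months.
#' Passing previously computed `ratios` freezes the correction (used when
#' evaluating perturbed runs, so the correction does not absorb the
#' perturbation).
#'
#' @param model coarse monthly PM2.5 (`field` or `ncell x 12` matrix)
#' @param satellite fine annual satellite `field`
#' @param coarse coarse `grid_spec` (needed when `model` is a plain matrix)
#' @param ratios optional frozen ratio set from a previous call
#' @param clamp lower/upper ratio bounds
#' @return list of class `rescale_result` with `values` (ncell x 12),
#'   `ratios`, `zero_model` (logical), `clamp`
#' @export
rescale_to_satellite <- function(model, satellite, coarse = NULL,
                                 ratios = NULL, clamp = c(0.25, 4)) {
  if (inherits(model, "field")) coarse <- model$grid
  v <- field_values(model)
  stopifnot(is.matrix(v), ncol(v) == 12)
  sat <- field_values(satellite)
  if (any(sat < 0)) stop("satellite field must be >= 0")
  sat_c <- aggregate_fine_to_coarse(satellite, coarse)$values
  if (!is.null(ratios)) {
    stopifnot(inherits(ratios, "rescale_result"))
    out <- v * ratios$ratios
    out[ratios$zero_model, ] <- ratios$assigned[ratios$zero_model]
    return(structure(list(values = out, ratios = ratios$ratios,
                          zero_model = ratios$zero_model,
                          assigned = ratios$assigned, clamp = ratios$clamp),
                     class = "rescale_result"))
  }
  ann <- rowMeans(v)
  if (all(sat_c == 0)) {
    warning("all-zero satellite field; rescaling is the identity")
    r <- rep(1, length(ann))
    return(structure(list(values = v, ratios = r,
                          zero_model = rep(FALSE, length(ann)),
                          assigned = numeric(length(ann)), clamp = clamp),
                     class = "rescale_result"))
  }
  zero_model <- ann <= 0 & sat_c > 0
  r <- rep(1, length(ann))
  pos <- ann > 0
  r[pos] <- pmin(pmax(sat_c[pos] / ann[pos], clamp[1]), clamp[2])
  r[zero_model] <- 0  # corrected value is satellite-assigned, not model-scaled
  out <- v * r
  out[zero_model, ] <- sat_c[zero_model]
  structure(list(values = out, ratios = r, zero_model = zero_model,
                 assigned = sat_c, clamp = clamp),
            class = "rescale_result")
}

#' Downscale corrected coarse exposure to the fine grid
#'
#' Month-wise pattern disaggregation using the satellite annual field as the
#' fine-scale spatial pattern; the area-weighted mean over each parent cell
#' is conserved every month. Returns an `exposure_field` whose annual field
#' is the mean of the 12 downscaled months.
#'
#' @param corrected a `rescale_result`, coarse monthly `field`, or matrix
#' @param satellite fine annual satellite `field`
#' @param fine,coarse the grid pair (inferred from `field` inputs if given)
#' @export
downscale_exposure <- function(corrected, satellite, fine = NULL, coarse = NULL) {
  v <- if (inherits(corrected, "rescale_result")) corrected$values
       else field_values(corrected)
  if (inherits(corrected, "field")) coarse <- corrected$grid
  if (inherits(satellite, "field")) fine <- satellite$grid
  stopifnot(!is.null(fine), !is.null(coarse), is.matrix(v), ncol(v) == 12)
  w <- disaggregation_weights(fine, coarse, satellite)
  monthly <- v[w$parent, , drop = FALSE] * w$weight
  structure(list(
    fine_monthly = monthly,
    fine_annual = rowMeans(monthly),
    weights = w,
    provenance = "downscaled"
  ), class = "exposure_field")
}

#' @export
print.exposure_field <- function(x, ...) {
  cat(sprintf("exposure_field (%s): %d fine cells, annual mean %.2f ug/m3\n",
              x$provenance, length(x$fine_annual), mean(x$fine_annual)))
  invisible(x)
}

#' Population-weighted mean concentration
#'
#' @param conc fine concentration (`field`, `exposure_field`, or values)
#' @param pop population `field` or values on the same grid
#' @param cells optional logical cell mask
#' @return scalar ug/m3
#' @export
population_weighted_mean <- function(conc, pop, cells = NULL) {
  C <- exposure_annual(conc)
  P <- field_values(pop)
  if (length(C) != length(P)) stop("concentration and population grids differ")
  if (!is.null(cells)) {
    C <- C[cells]; P <- P[cells]
  }
  if (sum(P) <= 0) stop("zero population in the requested region")
  sum(C * P) / sum(P)
}
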