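test_that("rescaling reproduces ratio arithmetic and clamps extremes", {
  gs <- make_grids(nlat = 4, nlon = 5, refine = 2)
  model <- matrix(10, gs$coarse$ncell, 12)
  # satellite equal to the model annual: identity
  sat_eq <- field(gs$fine, rep(10, gs$fine$ncell))
  r1 <- rescale_to_satellite(model, sat_eq, coarse = gs$coarse)
  expect_equal(r1$values, model, tolerance = 1e-12)
  expect_equal(r1$ratios, rep(1, gs$coarse$ncell), tolerance = 1e-12)
  # the printed-bias direction: satellite 14.08/12.77 higher than the model
  sat_hi <- field(gs$fine, rep(10 * 14.08 / 12.77, gs$fine$ncell))
  r2 <- rescale_to_satellite(model, sat_hi, coarse = gs$coarse)
  expect_rel_equal(mean(rowMeans(r2$values)) / 10, 14.08 / 12.77, 1e-9)
  # extreme satellite clamps at 4
  sat_x <- field(gs$fine, rep(100, gs$fine$ncell))
  model1 <- matrix(1, gs$coarse$ncell, 12)
  r3 <- rescale_to_satellite(model1, sat_x, coarse = gs$coarse)
  expect_equal(r3$ratios, rep(4, gs$coarse$ncell))
  # zero model with positive satellite: satellite annual assigned each month
  model0 <- model; model0[3, ] <- 0
  r4 <- rescale_to_satellite(model0, sat_eq, coarse = gs$coarse)
  expect_equal(unname(r4$values[3, ]), rep(10, 12), tolerance = 1e-12)
  # all-zero satellite: identity with a warning
  expect_warning(r5 <- rescale_to_satellite(model, field(gs$fine, rep(0, gs$fine$ncell)),
                                            coarse = gs$coarse), "all-zero")
  expect_equal(r5$values, model)
})

test_that("rescaling is idempotent and frozen ratios are reused verbatim", {
  w <- tiny_world()
  params <- cached("tiny_params", ctm_params(w))
  pm <- compute_pm25(run_forward(w$emissions[["2015"]], params))
  r1 <- rescale_to_satellite(pm$monthly, w$satellite, coarse = w$grids$coarse)
  r2 <- rescale_to_satellite(r1$values, w$satellite, coarse = w$grids$coarse)
  unclamped <- r1$ratios > r1$clamp[1] & r1$ratios < r1$clamp[2]
  expect_lt(max(abs(r2$values[unclamped, ] - r1$values[unclamped, ])),
            1e-9 * max(r1$values))
  # frozen application multiplies by the stored ratios exactly
  r3 <- rescale_to_satellite(2 * pm$monthly, w$satellite,
                             coarse = w$grids$coarse, ratios = r1)
  expect_equal(r3$values, 2 * pm$monthly * r1$ratios, tolerance = 1e-12)
})

test_that("downscaling conserves parents and falls back on zero patterns", {
  gs <- make_grids(nlat = 4, nlon = 5, refine = 3)
  set.seed(12)
  corrected <- matrix(runif(gs$coarse$ncell * 12, 5, 20), ncol = 12)
  sat <- field(gs$fine, runif(gs$fine$ncell, 0.5, 2))
  ex <- downscale_exposure(corrected, sat, fine = gs$fine, coarse = gs$coarse)
  for (m in c(1, 6)) {
    back <- aggregate_fine_to_coarse(ex$fine_monthly[, m], gs$coarse, gs$fine)
    expect_lt(max(abs(back - corrected[, m])), 1e-12 * max(corrected))
  }
  expect_equal(ex$fine_annual, rowMeans(ex$fine_monthly))
  # uniform satellite replicates the coarse values
  ex_u <- downscale_exposure(corrected, field(gs$fine, rep(3, gs$fine$ncell)),
                             fine = gs$fine, coarse = gs$coarse)
  p <- parent_index(gs$fine, gs$coarse)
  expect_equal(ex_u$fine_monthly, corrected[p, ], tolerance = 1e-12)
  # satellite zero within one parent: uniform fallback, logged
  sat0 <- sat$values; sat0[p == 2] <- 0
  expect_warning(
    ex0 <- downscale_exposure(corrected, field(gs$fine, sat0),
                              fine = gs$fine, coarse = gs$coarse),
    "zero pattern")
  expect_equal(ex0$fine_monthly[p == 2, 1], rep(corrected[2, 1], sum(p == 2)))
})

test_that("downscaling preserves area-consistent population-weighted means", {
  gs <- make_grids(nlat = 6, nlon = 5, refine = 2)
  set.seed(13)
  corrected <- matrix(runif(gs$coarse$ncell * 12, 5, 20), ncol = 12)
  sat <- field(gs$fine, runif(gs$fine$ncell, 0.5, 2))
  ex <- downscale_exposure(corrected, sat, fine = gs$fine, coarse = gs$coarse)
  # population proportional to cell area: the domain mean is untouched
  pop_fine <- gs$fine$area_w
  pop_coarse <- gs$coarse$area_w
  before <- sum(rowMeans(corrected) * pop_coarse) / sum(pop_coarse)
  after <- population_weighted_mean(ex, pop_fine)
  expect_rel_equal(after, before, 1e-12)
})

test_that("population-weighted means follow the weighting arithmetic", {
  g <- grid_spec(c(0.1, 0.3), c(10, 20))
  # hand case: (10, 1) and (20, 3) -> 17.5 (remaining cells empty)
  expect_equal(population_weighted_mean(c(10, 20, 0, 0), c(1, 3, 0, 0)), 17.5)
  expect_equal(population_weighted_mean(rep(4.4, 4), runif(4, 1, 2)), 4.4)
  # loop oracle
  set.seed(14)
  C <- runif(50); P <- runif(50)
  expect_rel_equal(population_weighted_mean(C, P), sum(C * P) / sum(P), 1e-12)
  expect_error(population_weighted_mean(C, 0 * P), "zero population")
  # masked variant
  cells <- seq(50) <= 25
  expect_rel_equal(population_weighted_mean(C, P, cells),
                   sum((C * P)[cells]) / sum(P[cells]), 1e-12)
})
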