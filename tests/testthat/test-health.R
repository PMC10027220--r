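test_that("relative risk interpolates piecewise-linearly with flat tails", {
  curves <- default_rr_curves()
  expect_equal(relative_risk(curves, "IHD", curves$tmrel), 1)
  expect_equal(relative_risk(curves, "IHD", 0), 1)
  # above the last knot the curve is flat
  top <- relative_risk(curves, "IHD", max(curves$knots))
  expect_equal(relative_risk(curves, "IHD", 500), top)
  # midpoint of a hand-made segment with RR 1.2 and 1.4 is 1.3
  causes <- pm_causes()
  rr <- array(1, c(6, 3, 3), dimnames = list(causes, NULL, NULL))
  rr["LC", , ] <- matrix(rep(c(1.2, 1.2, 1.4), 3), 3)
  # knots 0, 10, 20: LC rises 1.2 at 0?? keep RR(TMREL)=1 -> use knots 0,10,20
  rr["LC", 1, ] <- 1; rr["LC", 2, ] <- 1.2; rr["LC", 3, ] <- 1.4
  for (d in causes) rr[d, 1, ] <- 1
  cs <- rr_curve_set(c(0, 10, 20), rr, 0)
  expect_equal(relative_risk(cs, "LC", 15), 1.3)
  # loop-based interpolation oracle on 100 random exposures
  set.seed(5)
  C <- runif(100, 0, 90)
  got <- relative_risk(curves, "stroke", C)
  y <- curves$rr["stroke", , "mid"]; k <- curves$knots
  oracle <- vapply(C, function(x) {
    if (x <= k[1]) return(1)
    if (x >= k[length(k)]) return(y[length(k)])
    i <- max(which(k <= x))
    y[i] + (y[i + 1] - y[i]) * (x - k[i]) / (k[i + 1] - k[i])
  }, numeric(1))
  expect_lt(max(abs(got - oracle)), 1e-12)
  expect_error(relative_risk(curves, "asthma", 10), "unknown cause")
})

test_that("curve-set validation enforces the risk-model invariants", {
  causes <- pm_causes()
  rr <- array(1, c(6, 3, 3), dimnames = list(causes, NULL, NULL))
  rr[, 2, ] <- 1.2; rr[, 3, ] <- 1.4
  expect_s3_class(rr_curve_set(c(0, 10, 20), rr, 0), "rr_curve_set")
  bad <- rr; bad[1, 1, ] <- 1.1
  expect_error(rr_curve_set(c(0, 10, 20), bad, 0), "TMREL")
  bad <- rr; bad[2, 3, ] <- 1.0
  expect_error(rr_curve_set(c(0, 10, 20), bad, 0), "nondecreasing")
  bad <- rr; bad[, 2, 1] <- 1.3; bad[, 3, 1] <- 1.5
  expect_error(rr_curve_set(c(0, 10, 20), bad, 0), "low <= mid")
})

test_that("the PAF formula reproduces hand-computed deaths", {
  # one cell carrying P = 1e5 with y0 = 1025 per 100k at flat RR 1.25:
  # deaths = 1e5 * 1025/1e5 * (0.25/1.25) = 205
  g <- grid_spec(c(40, 41), c(5, 6))
  pop <- field(g, c(1e5, 0, 0, 0), "persons")
  mask <- country_mask(g, c(1L, 1L, 1L, 1L), "A")
  mort <- data.frame(country = "A", cause = pm_causes(),
                     y0_low = 0, y0_mid = 0, y0_high = 0)
  mort[mort$cause == "IHD", c("y0_low", "y0_mid", "y0_high")] <- 1025
  h <- health_inputs(pop, mort, flat_rr(1.25, "IHD"), mask)
  dm <- attributable_deaths(rep(10, 4), h)
  expect_equal(sum(dm), 205, tolerance = 1e-9)
  # doubling population doubles deaths
  h2 <- health_inputs(field(g, 2 * pop$values), mort, flat_rr(1.25, "IHD"), mask)
  expect_equal(sum(attributable_deaths(rep(10, 4), h2)), 410, tolerance = 1e-9)
  # PAF stays in [0, 1): deaths never exceed P * y0
  expect_true(all(dm <= 1e5 * 1025 / 1e5))
  # RR = 1 everywhere gives zero deaths
  h1 <- health_inputs(pop, mort, flat_rr(1.0, "IHD"), mask)
  expect_equal(sum(attributable_deaths(rep(10, 4), h1)), 0)
})

test_that("the cost function closes over cells and causes", {
  w <- small_world()
  h <- small_health()
  base <- small_base()
  cost <- base$cost
  dm <- attributable_deaths(base$exposure, h)
  rec <- receptor_cells(w$mask)
  expect_rel_equal(cost$J, sum(dm[rec, ]), 1e-12)
  expect_rel_equal(sum(cost$per_cause$share_pct), 100, 1e-9)
  # with every country receptor-flagged, per-cell totals sum to J
  expect_rel_equal(sum(cost$per_cell[rec]), cost$J, 1e-12)
  # circulatory causes dominate the synthetic configuration
  ranked <- cost$per_cause$cause[order(-cost$per_cause$deaths)]
  expect_setequal(ranked[1:2], c("IHD", "stroke"))
})

test_that("J is nondecreasing in every cell's exposure", {
  h <- small_health()
  w <- small_world()
  base <- small_base()
  C <- base$exposure$fine_annual
  J0 <- cost_function(C, h)$J
  set.seed(31)
  for (i in sample(which(receptor_cells(w$mask)), 8)) {
    C2 <- C; C2[i] <- C2[i] + 1
    expect_gte(cost_function(C2, h)$J, J0)
  }
})

test_that("uncertainty bounds are ordered and reported as printed ratios", {
  w <- small_world()
  h <- small_health()
  base <- small_base()
  ub <- uncertainty_bounds(base$exposure, h)
  expect_lte(ub$J_low, ub$J_mid)
  expect_lte(ub$J_mid, ub$J_high)
  # bounds equal to mid collapse the interval
  h_flat <- h
  h_flat$mortality$y0_low <- h_flat$mortality$y0_mid
  h_flat$mortality$y0_high <- h_flat$mortality$y0_mid
  h_flat$curves$rr[, , "low"] <- h_flat$curves$rr[, , "mid"]
  h_flat$curves$rr[, , "high"] <- h_flat$curves$rr[, , "mid"]
  h_flat$pop_bounds <- c(low = 1, high = 1)
  ub2 <- uncertainty_bounds(base$exposure, h_flat)
  expect_equal(ub2$J_low, ub2$J_mid, tolerance = 1e-12)
  expect_equal(ub2$J_high, ub2$J_mid, tolerance = 1e-12)
})

test_that("mortality rows must exist for every populated country", {
  w <- tiny_world()
  mort <- w$mortality[w$mortality$country != "country_01", ]
  expect_error(health_inputs(w$population, mort, w$rr, w$mask), "country_01")
})
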