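test_that("grid construction validates regularity and computes area weights", {
  g <- grid_spec(seq(40.5, 49.5, 1), seq(0.5, 11.5, 1))
  expect_equal(g$ncell, 120)
  expect_true(all(g$area_w > 0))
  expect_equal(mean(g$area_w), 1, tolerance = 1e-12)
  # weights shared per latitude row, monotone toward the pole
  w_rows <- matrix(g$area_w, g$nlat, g$nlon)
  expect_true(all(apply(w_rows, 1, function(r) diff(range(r)) == 0)))
  expect_true(all(diff(w_rows[, 1]) < 0))
  expect_error(grid_spec(c(1, 2, 4), 1:3), "uniform")
  expect_error(grid_spec(c(3, 2, 1), 1:3), "ascending")
})

test_that("nesting detection accepts exact refinements and rejects others", {
  gs <- make_grids(nlat = 6, nlon = 8, refine = 4)
  expect_identical(nesting_factor(gs$fine, gs$coarse), 4L)
  shifted <- grid_spec(gs$fine$lat + 0.01, gs$fine$lon)
  expect_error(nesting_factor(shifted, gs$coarse), "do not nest")
  odd <- grid_spec(seq(33, 61, length.out = 25), gs$fine$lon)
  expect_error(nesting_factor(odd, gs$coarse), "do not nest")
})

test_that("aggregation is the area-weighted mean of fine children", {
  gs <- make_grids(nlat = 5, nlon = 4, refine = 4)
  # constant field stays constant
  expect_equal(aggregate_fine_to_coarse(rep(7, gs$fine$ncell), gs$coarse, gs$fine),
               rep(7, gs$coarse$ncell))
  # brute-force loop oracle on a random field
  set.seed(42)
  v <- runif(gs$fine$ncell)
  got <- aggregate_fine_to_coarse(v, gs$coarse, gs$fine)
  p <- parent_index(gs$fine, gs$coarse)
  w <- gs$fine$area_w
  oracle <- vapply(seq_len(gs$coarse$ncell), function(cc) {
    kids <- which(p == cc)
    sum(v[kids] * w[kids]) / sum(w[kids])
  }, numeric(1))
  expect_lt(max(abs(got - oracle)), 1e-12)
  # one fine cell = v, rest 0, 4x4 refinement, (near-)equal areas: parent =
  # v/16; use a narrow near-equator band where cos(lat) is effectively flat
  eq <- make_grids(nlat = 4, nlon = 4, refine = 4, lat0 = -0.4, lat1 = 0.4,
                   lon0 = 0, lon1 = 4)
  one <- numeric(eq$fine$ncell); one[77] <- 3.2
  got1 <- aggregate_fine_to_coarse(one, eq$coarse, eq$fine)
  p_eq <- parent_index(eq$fine, eq$coarse)
  expect_equal(got1[p_eq[77]], 3.2 / 16, tolerance = 1e-4)
})

test_that("disaggregation replicates, follows patterns, and conserves parents", {
  gs <- make_grids(nlat = 5, nlon = 4, refine = 3)
  u <- runif(gs$coarse$ncell, 1, 5)
  # plain replication
  rep_out <- disaggregate_coarse_to_fine(u, gs$fine, coarse = gs$coarse)
  p <- parent_index(gs$fine, gs$coarse)
  expect_identical(rep_out, u[p])
  # uniform pattern identical to no pattern
  unif <- disaggregate_coarse_to_fine(u, gs$fine, pattern = rep(2, gs$fine$ncell),
                                      coarse = gs$coarse)
  expect_equal(unif, rep_out, tolerance = 1e-14)
  # conservation: per-parent area-weighted child mean equals parent
  set.seed(1)
  pat <- runif(gs$fine$ncell, 0.1, 3)
  out <- disaggregate_coarse_to_fine(u, gs$fine, pattern = pat, coarse = gs$coarse)
  back <- aggregate_fine_to_coarse(out, gs$coarse, gs$fine)
  expect_lt(max(abs(back - u)), 1e-12)
  # aggregate(disaggregate(x)) identity without pattern
  expect_equal(aggregate_fine_to_coarse(rep_out, gs$coarse, gs$fine), u,
               tolerance = 1e-14)
  # zero pattern within a parent falls back to uniform with a warning
  pat0 <- pat; pat0[p == 1] <- 0
  expect_warning(out0 <- disaggregate_coarse_to_fine(u, gs$fine, pattern = pat0,
                                                     coarse = gs$coarse),
                 "zero pattern")
  expect_equal(out0[p == 1], rep(u[1], sum(p == 1)))
})

test_that("country aggregation partitions the domain total", {
  w <- tiny_world()
  f <- field(w$grids$fine, runif(w$grids$fine$ncell))
  tab <- country_aggregate(f, w$mask, "sum")
  expect_rel_equal(sum(tab$value), sum(f$values), 1e-9)
  # indicator of one country
  ind <- as.numeric(w$mask$ids == 2L)
  tab2 <- country_aggregate(ind, w$mask, "sum")
  expect_equal(tab2$value[tab2$country == "country_02"], sum(w$mask$ids == 2L))
  expect_equal(sum(tab2$value[!tab2$country %in% c("country_02")]), 0)
  # population-weighted mean of a uniform field is that value everywhere
  tab3 <- country_aggregate(rep(4.2, w$grids$fine$ncell), w$mask, "popwt",
                            pop = w$population)
  expect_equal(tab3$value[tab3$country != "unassigned"],
               rep(4.2, length(w$mask$names)), tolerance = 1e-12)
  # grid mismatch is rejected
  other <- field(w$grids$coarse, runif(w$grids$coarse$ncell))
  expect_error(country_aggregate(other, w$mask), "grid")
})

test_that("country sums are additive under mask refinement", {
  w <- tiny_world()
  v <- runif(w$grids$fine$ncell)
  tab <- country_aggregate(v, w$mask, "sum")
  # split country 1 into two ids by alternating cells
  ids2 <- w$mask$ids
  split_cells <- which(ids2 == 1L)
  ids2[split_cells[seq_along(split_cells) %% 2 == 0]] <- 5L
  mask2 <- country_mask(w$grids$fine, ids2, c(w$mask$names, "country_01b"),
                        c(w$mask$receptor, TRUE))
  tab2 <- country_aggregate(v, mask2, "sum")
  pair <- sum(tab2$value[tab2$country %in% c("country_01", "country_01b")])
  expect_rel_equal(pair, tab$value[tab$country == "country_01"], 1e-12)
})
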