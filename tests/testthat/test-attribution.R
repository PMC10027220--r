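# hand-built sensitivity field on a given coarse grid
make_sens <- function(grid, lambda) {
  structure(list(grid = grid, lambda = lambda, species = pm_species(),
                 response = "gbd", bound = "mid", nonlinear = FALSE),
            class = "sensitivity_field")
}

test_that("the ledger is the entrywise product lambda * E", {
  w <- tiny_world()
  coarse <- w$grids$coarse; fine <- w$grids$fine
  # zero inventory: all-zero ledger
  inv0 <- w$emissions[["2015"]]; inv0$mass[] <- 0
  lam <- array(runif(coarse$ncell * 12 * 6), c(coarse$ncell, 12, 6),
               dimnames = list(NULL, NULL, pm_species()))
  led0 <- compute_contributions(make_sens(coarse, lam), inv0, w$mask)
  expect_equal(led0$total, 0)
  expect_true(all(led0$contrib == 0))
  # hand product: one entry, lambda 2e-6 deaths/kg x 5e5 kg = 1 death
  lam1 <- array(0, c(coarse$ncell, 12, 6), dimnames = list(NULL, NULL, pm_species()))
  lam1[5, 3, 2] <- 2e-6
  inv1 <- inv0
  fine_child <- which(parent_index(fine, coarse) == 5)[1]
  inv1$mass[fine_child, 3, 4, 2] <- 5e5
  led1 <- compute_contributions(make_sens(coarse, lam1), inv1, w$mask)
  expect_equal(led1$total, 1.0, tolerance = 1e-12)
  # zero-emission entries are exactly zero even with nonzero lambda
  expect_equal(sum(led1$contrib != 0), 1L)
  # brute-force total oracle on random lambda and E
  set.seed(33)
  invr <- w$emissions[["2015"]]
  lamr <- array(runif(coarse$ncell * 12 * 6, 0, 1e-6),
                c(coarse$ncell, 12, 6), dimnames = list(NULL, NULL, pm_species()))
  ledr <- compute_contributions(make_sens(coarse, lamr), invr, w$mask)
  lam_fine <- disaggregate_sensitivity(make_sens(coarse, lamr), fine)
  oracle <- 0
  for (s in 1:6) for (k in 1:16) {
    oracle <- oracle + sum(lam_fine[, , s] * invr$mass[, , k, s])
  }
  expect_rel_equal(ledr$total, oracle, 1e-10)
  # species mismatch is rejected
  bad <- make_sens(coarse, lamr); bad$species <- c("A", "B")
  expect_error(compute_contributions(bad, invr, w$mask), "species mismatch")
})

test_that("all ledger marginals close on the same total", {
  w <- small_world()
  sens <- cached("small_sens_gbd", run_adjoint(small_base()))
  led <- cached("small_ledger",
                compute_contributions(sens, w$emissions[["2015"]], w$mask))
  for (by in c("species", "main_sector", "detailed_sector", "country",
               "month", "country_sector", "sector_species")) {
    tab <- aggregate_ledger(led, by)
    expect_rel_equal(sum(tab$value), led$total, 1e-9)
  }
  # shares sum to 100 and ranking is value-descending with label tie-breaks
  tab <- aggregate_ledger(led, "species")
  expect_rel_equal(sum(tab$share_pct), 100, 1e-9)
  expect_true(all(diff(tab$value) <= 0))
})

test_that("a single-species inventory takes a 100% share", {
  w <- tiny_world()
  inv <- w$emissions[["2015"]]
  for (s in setdiff(pm_species(), "NOx")) inv$mass[, , , s] <- 0
  coarse <- w$grids$coarse
  lam <- array(1e-6, c(coarse$ncell, 12, 6), dimnames = list(NULL, NULL, pm_species()))
  led <- compute_contributions(make_sens(coarse, lam), inv, w$mask)
  tab <- aggregate_ledger(led, "species")
  expect_equal(tab$share_pct[tab$species == "NOx"], 100, tolerance = 1e-9)
})

test_that("one emitting cell attributes everything to its country", {
  w <- small_world()
  inv <- w$emissions[["2015"]]
  cell <- which(w$mask$ids == 3L & field_values(w$population) > 0)[5]
  mass <- array(0, dim(inv$mass))
  mass[cell, , 5, 1] <- 1e6
  inv1 <- emission_inventory(w$grids$fine, mass, inv$sector_map, inv$species, "2015")
  base <- run_base(w, small_params(), small_health(), inv = inv1)
  sens1 <- run_adjoint(base)
  led <- compute_contributions(sens1, inv1, w$mask)
  tab <- aggregate_ledger(led, "country")
  home <- w$mask$names[3]
  expect_gte(tab$value[tab$country == home] / led$total, 0.999)
})

test_that("monthly shares normalize within each month", {
  w <- small_world()
  led <- cached("small_ledger",
                compute_contributions(cached("small_sens_gbd", run_adjoint(small_base())),
                                      w$emissions[["2015"]], w$mask))
  sh <- monthly_shares(led, "species")
  expect_equal(unname(colSums(sh)), rep(1, 12), tolerance = 1e-12)
  sh_m <- monthly_shares(led, "main_sector")
  expect_equal(unname(colSums(sh_m)), rep(1, 12), tolerance = 1e-12)
  # winter-peaked residential OC: winter share above summer share
  res_w <- mean(sh_m["residential", c(12, 1, 2)])
  res_s <- mean(sh_m["residential", 6:8])
  expect_gt(res_w, res_s)
  # a single-category ledger has fraction 1 every month
  inv1 <- w$emissions[["2015"]]
  for (s in setdiff(pm_species(), "SO2")) inv1$mass[, , , s] <- 0
  lam <- array(1e-6, c(w$grids$coarse$ncell, 12, 6),
               dimnames = list(NULL, NULL, pm_species()))
  led1 <- compute_contributions(make_sens(w$grids$coarse, lam), inv1, w$mask)
  sh1 <- monthly_shares(led1, "species")
  expect_equal(unname(sh1["SO2", ]), rep(1, 12), tolerance = 1e-12)
})

test_that("seasonal ratios follow the DJF/JJA bookkeeping", {
  w <- tiny_world()
  coarse <- w$grids$coarse
  lam <- array(1e-6, c(coarse$ncell, 12, 6), dimnames = list(NULL, NULL, pm_species()))
  inv <- w$emissions[["2015"]]
  # uniform construction: flat sectors have ratio 1
  flat <- inv; flat$mass[] <- 1
  led_flat <- compute_contributions(make_sens(coarse, lam), flat, w$mask)
  expect_equal(seasonal_ratio(led_flat, species = "NOx"), 1, tolerance = 1e-12)
  # doubling DJF contributions doubles the ratio
  dbl <- flat; dbl$mass[, c(12, 1, 2), , ] <- 2
  led_dbl <- compute_contributions(make_sens(coarse, lam), dbl, w$mask)
  expect_equal(seasonal_ratio(led_dbl, species = "NOx"), 2, tolerance = 1e-12)
  # loop oracle on the real ledger
  led <- compute_contributions(make_sens(coarse, lam), inv, w$mask)
  got <- seasonal_ratio(led, species = "OC", sector = "residential")
  k_idx <- which(unname(led$sector_map) == "residential")
  num <- sum(led$contrib[, c(12, 1, 2), k_idx, "OC"])
  den <- sum(led$contrib[, 6:8, k_idx, "OC"])
  expect_rel_equal(got, num / den, 1e-12)
  expect_gt(got, 1)  # winter-peaked residential profile
  # degenerate season is rejected
  zero_summer <- flat; zero_summer$mass[, 6:8, , ] <- 0
  led_z <- compute_contributions(make_sens(coarse, lam), zero_summer, w$mask)
  expect_error(seasonal_ratio(led_z, species = "NOx"), "zero contribution")
})
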