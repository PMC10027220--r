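test_that("the generator is deterministic and honors configured totals", {
  cfg <- tiny_config()
  w1 <- tiny_world()
  w2 <- generate_world(cfg)
  expect_identical(w1$emissions[["2015"]]$mass, w2$emissions[["2015"]]$mass)
  expect_identical(w1$population$values, w2$population$values)
  expect_identical(w1$satellite$values, w2$satellite$values)
  expect_identical(w1$mask$ids, w2$mask$ids)
  # configured population total
  expect_rel_equal(sum(w1$population$values), cfg$population_total, 1e-6)
  # configured emission totals per (species, main sector)
  tot <- inventory_totals(w1$emissions[["2015"]], "species_main_sector")
  for (r in seq_len(nrow(tot))) {
    want <- cfg$emission_totals[tot$species[r], tot$main_sector[r]]
    if (want > 0) expect_rel_equal(tot$total_kg[r], want, 1e-9)
  }
  # everything nonnegative and finite
  expect_true(all(w1$emissions[["2015"]]$mass >= 0))
  expect_true(all(w1$population$values >= 0))
  expect_true(all(is.finite(w1$satellite$values)))
})

test_that("seasonal profiles are reflected in the generated inventory", {
  w <- tiny_world()
  inv <- w$emissions[["2015"]]
  res_oc_dec <- sum(inv$mass[, 12, "residential-heating", "OC"])
  res_oc_jul <- sum(inv$mass[, 7, "residential-heating", "OC"])
  prof <- w$profiles["residential-heating", ]
  expect_rel_equal(res_oc_dec / res_oc_jul, prof[12] / prof[7], 1e-9)
  # winter residential peak and Feb-Apr agricultural-crop peak
  expect_gt(prof[1], prof[7])
  crop <- w$profiles["agriculture-crops", ]
  expect_gt(mean(crop[2:4]), mean(crop[c(8, 9, 10)]))
  # all profiles sum to 12
  expect_equal(unname(rowSums(w$profiles)), rep(12, nrow(w$profiles)),
               tolerance = 1e-9)
})

test_that("satellite noise has unit mean and respects cv = 0", {
  w <- tiny_world()
  truth <- w$satellite_truth
  exact <- generate_satellite(w, truth, cv = 0)
  expect_identical(exact$values, truth$values)
  # larger world for the Monte-Carlo mean check
  wb <- small_world()
  cv <- 0.1
  sat <- generate_satellite(wb, wb$satellite_truth, cv = cv)
  ratio <- sat$values / wb$satellite_truth$values
  n <- length(ratio)
  se <- cv / sqrt(n)
  expect_lt(abs(mean(ratio) - 1), 3 * se + 5e-3)
  # different seeds give different noise on identical truth
  w_alt <- generate_world(tiny_config(seed = 8))
  expect_false(identical(w_alt$satellite$values / w_alt$satellite_truth$values,
                         w$satellite$values / w$satellite_truth$values))
  expect_error(generate_satellite(w, truth, cv = -0.1), ">= 0")
})

test_that("inventory scaling multiplies the selected keys only", {
  w <- tiny_world()
  inv <- w$emissions[["2015"]]
  expect_identical(scale_inventory(inv, 1)$mass, inv$mass)
  z <- scale_inventory(inv, c(NOx = 0))
  expect_equal(sum(z$mass[, , , "NOx"]), 0)
  expect_identical(z$mass[, , , "NH3"], inv$mass[, , , "NH3"])
  fm <- matrix(1.25, 1, 1, dimnames = list("NOx", "road-transport"))
  s <- scale_inventory(inv, fm)
  expect_rel_equal(sum(s$mass[, , "road-transport", "NOx"]),
                   1.25 * sum(inv$mass[, , "road-transport", "NOx"]), 1e-12)
  other <- sum(s$mass) - sum(s$mass[, , "road-transport", "NOx"])
  other0 <- sum(inv$mass) - sum(inv$mass[, , "road-transport", "NOx"])
  expect_rel_equal(other, other0, 1e-12)
  expect_error(scale_inventory(inv, c(CO2 = 1)), "unknown species")
  bad <- matrix(1, 1, 1, dimnames = list("NOx", "mining"))
  expect_error(scale_inventory(inv, bad), "unknown sector")
})

test_that("changing one config field leaves independent components untouched", {
  cfg_a <- tiny_config()
  cfg_b <- tiny_config(emission_totals = default_emission_totals() * 2)
  wa <- tiny_world()
  wb <- generate_world(cfg_b)
  expect_identical(wa$mask$ids, wb$mask$ids)
  expect_identical(wa$population$values, wb$population$values)
  expect_identical(wa$mortality, wb$mortality)
  expect_rel_equal(sum(wb$emissions[["2015"]]$mass),
                   2 * sum(wa$emissions[["2015"]]$mass), 1e-9)
})

test_that("degenerate configurations are rejected", {
  expect_error(tiny_config(receptor_countries = integer(0)), "receptor")
  expect_error(tiny_config(satellite_noise_cv = -1), "CV")
  expect_error(world_config(n_countries = 5, country_blocks = c(2, 2)),
               "country_blocks")
})

test_that("the 2005 inventory embodies the configured species and sector changes", {
  w <- tiny_world()
  cfg <- w$config
  t15 <- inventory_totals(w$emissions[["2015"]], "species")
  t05 <- inventory_totals(w$emissions[["2005"]], "species")
  # SO2 has no sector-level adjustment in any of its dominant sectors, so the
  # species ratio is exactly 1/(1 + change) in sectors without overrides
  s15 <- sum(w$emissions[["2015"]]$mass[, , "energy-power", "SO2"])
  s05 <- sum(w$emissions[["2005"]]$mass[, , "energy-power", "SO2"])
  expect_rel_equal(s15 / s05, 1 + cfg$emission_changes[["SO2"]], 1e-9)
  # aviation-cruise increased 2005 -> 2015 on top of the species change
  a15 <- sum(w$emissions[["2015"]]$mass[, , "aviation-cruise", "NOx"])
  a05 <- sum(w$emissions[["2005"]]$mass[, , "aviation-cruise", "NOx"])
  expect_rel_equal(a15 / a05,
                   (1 + cfg$emission_changes[["NOx"]]) *
                     (1 + cfg$sector_changes[["aviation-cruise"]]), 1e-9)
})
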