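# Shared synthetic fixtures, built once per test run and cached.
.fixtures <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixtures)) {
    assign(key, force(expr), envir = .fixtures)
  }
  get(key, envir = .fixtures)
}

# 6x8 coarse / 12x16 fine: fast unit-test world
tiny_config <- function(seed = 7, ...) {
  world_config(seed = seed, nlat = 6, nlon = 8, refine = 2,
               n_countries = 4, country_blocks = c(2, 2), n_cities = 6,
               population_total = 1e7, ...)
}
tiny_world <- function() cached("tiny_world", generate_world(tiny_config()))

# 8x10 coarse / 16x20 fine: adjoint/attribution test world
small_config <- function(seed = 2, ...) {
  world_config(seed = seed, nlat = 8, nlon = 10, refine = 2,
               n_countries = 6, country_blocks = c(3, 2), n_cities = 8,
               population_total = 2e7, ...)
}
small_world <- function() cached("small_world", generate_world(small_config()))

small_params <- function(nonlinear = FALSE) {
  cached(paste0("small_params_", nonlinear),
         ctm_params(small_world(), nonlinear = nonlinear))
}
small_health <- function() cached("small_health", world_health(small_world()))

small_base <- function(response = "gbd", nonlinear = FALSE, boundary_scale = 1) {
  key <- paste("small_base", response, nonlinear, boundary_scale, sep = "_")
  cached(key, run_base(small_world(), small_params(nonlinear), small_health(),
                       boundary_scale = boundary_scale, response = response))
}

# pipeline smoke-test config: the coarser 8x10 grid dilutes sources, so the
# emission totals and satellite level are raised to keep the world in the
# same exposure regime as the default study configuration
pipeline_config <- function(seed = 2) {
  small_config(seed = seed,
               emission_totals = default_emission_totals() * 3,
               satellite_mean = 20)
}

# closed-box world: no wind, no diffusion, no boundary exchange; every coarse
# cell is an isolated box so steady states have a closed form
closedbox_config <- function(seed = 11) {
  world_config(seed = seed, nlat = 4, nlon = 6, refine = 1,
               n_countries = 2, country_blocks = c(1, 2), n_cities = 4,
               population_total = 5e6,
               wind_u0 = 0, wind_u_amp = 0, wind_v0 = 0, wind_v_amp = 0,
               wind_noise = 0, diffusivity = 0,
               satellite_noise_cv = 0)
}
closedbox_world <- function() cached("closedbox_world", generate_world(closedbox_config()))

# hand-made flat RR curve set: one cause carries all risk at constant RR
flat_rr <- function(rr_value = 1.25, cause = "IHD", tmrel = 0) {
  causes <- pm_causes()
  knots <- c(tmrel, 1, 100)
  rr <- array(1, c(length(causes), 3, 3), dimnames = list(causes, NULL, NULL))
  rr[cause, 2:3, ] <- rr_value
  rr_curve_set(knots, rr, tmrel)
}

expect_rel_equal <- function(actual, expected, tol) {
  expect_lt(abs(actual - expected) / max(abs(expected), 1e-300), tol)
}
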