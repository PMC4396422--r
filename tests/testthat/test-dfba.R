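cfg <- sim_config()

test_that("Michaelis-Menten uptake bound follows the kinetics", {
  env <- make_environment("cooperation")
  expect_equal(uptake_bound(0, env, cfg), 0)
  ## at c = Km the bound is Vmax/2; Km = 10 uM = 0.01 mmol/L
  pool_at_km <- 0.01 * env$volume
  expect_equal(uptake_bound(pool_at_km, env, cfg), 5)
  ## unlimited metabolites saturate at Vmax
  env2 <- make_environment("competition")
  expect_equal(uptake_bound(123, env2, cfg, metabolite_id = "ac_e"), 10)
  ## monotone in the pool amount
  amounts <- c(1e-12, 1e-9, 1e-7, 1e-5)
  bounds <- vapply(amounts, uptake_bound, 0, env = env, config = cfg)
  expect_true(all(diff(bounds) > 0))
  expect_true(all(bounds <= 10))
})

test_that("per-step pool bookkeeping is exact", {
  env <- make_environment("cooperation")
  states <- list(list(model = toy$E, biomass = 3e-7),
                 list(model = toy$S, biomass = 3e-7))
  for (k in 1:25) {
    B <- vapply(states, `[[`, 0, "biomass")
    out <- step_community(states, env, cfg)
    for (met in names(env$pools)) {
      if (met %in% env$unlimited) next
      flux_sum <- sum(vapply(seq_along(states), function(si) {
        exf <- out$exchange[[si]]
        if (met %in% names(exf)) exf[[met]] * B[si] else 0
      }, 0))
      delta <- out$env$pools[[met]] - env$pools[[met]]
      scale_ref <- max(abs(delta), abs(flux_sum * cfg$dt))
      expect_lt(abs(delta - flux_sum * cfg$dt),
                1e-12 * scale_ref + cfg$tolerance)
    }
    states <- out$states
    env <- out$env
    expect_true(all(env$pools >= 0))
    expect_true(all(vapply(states, `[[`, 0, "biomass") >= 0))
  }
})

test_that("a species with zero growth decays at the death rate", {
  ## the auxotroph alone on lactose: maintenance runs but growth never
  ## starts, so biomass follows B0 * (1 - d*dt)^n exactly
  sim <- simulate_community(toy$E, make_environment("cooperation"), cfg)
  n <- length(sim$times) - 1L
  expect_equal(nrow(sim$biomass), 101L)
  expect_true(all(diff(sim$biomass[, 1]) < 0))
  expect_equal(final_biomass(sim), 3e-7 * (1 - 0.01 * 0.1)^n,
               tolerance = 1e-12)
})

test_that("unlimited nutrients reproduce the closed-form geometry", {
  env <- community_env(c(lcts_e = 0, o2_e = 0, ac_e = 0, met_e = 0),
                       unlimited = c("lcts_e", "o2_e", "met_e", "ac_e"))
  sim <- simulate_community(toy$E, env, cfg)
  n <- round(cfg$duration / cfg$dt)
  mu <- 3.8                              # constant at saturation
  expect_equal(final_biomass(sim),
               3e-7 * (1 + (mu - cfg$death_rate) * cfg$dt)^n,
               tolerance = 1e-9)
  expect_true(all(abs(sim$mu[, 1] - mu) < 1e-9))
})

test_that("species order does not change the trajectory", {
  env <- make_environment("cooperation")
  sim_es <- simulate_community(list(toy$E, toy$S), env, cfg)
  sim_se <- simulate_community(list(toy$S, toy$E), env, cfg)
  expect_equal(sim_es$biomass[, "toy_E"], sim_se$biomass[, "toy_E"],
               tolerance = 1e-12)
  expect_equal(sim_es$biomass[, "toy_S"], sim_se$biomass[, "toy_S"],
               tolerance = 1e-12)
  expect_equal(sim_es$pools, sim_se$pools, tolerance = 1e-12)
})

test_that("joint overdraw of a scarce pool is allocated, not violated", {
  ## tiny oxygen pool, both species saturated on carbon: the requested
  ## drawdown far exceeds the pool in one step
  env <- community_env(c(lcts_e = 1e-3, o2_e = 1e-9, ac_e = 1e-3,
                         met_e = 1e-3))
  states <- list(list(model = toy$E, biomass = 1e-4),
                 list(model = toy$S, biomass = 1e-4))
  out <- step_community(states, env, cfg)
  expect_true(all(out$env$pools >= 0))
  drawn <- env$pools[["o2_e"]] - out$env$pools[["o2_e"]]
  expect_lte(drawn, env$pools[["o2_e"]] * (1 + 1e-9))
})

test_that("cooperative biomass gain respects the lactose yield ceiling", {
  env <- make_environment("cooperation")
  sim <- simulate_community(list(toy$E, toy$S), env, cfg)
  gain <- sum(sim$biomass[nrow(sim$biomass), ]) - 2 * 3e-7
  lcts <- 1.2e-5
  ## all lactose aerobic (6 ATP) plus full respiration of the acetate
  ## byproduct (2 * 3 ATP), 10 ATP per gDW
  ceiling <- (6 * lcts + 2 * 3 * lcts) / 10
  expect_gt(gain, 0)
  expect_lt(gain, ceiling)
})

test_that("trajectory serialization is tidy and re-readable", {
  env <- make_environment("cooperation")
  short <- sim_config(duration = 1)
  sim <- simulate_community(list(toy$E, toy$S), env, short)
  tf <- tempfile(fileext = ".csv")
  write_trajectory(sim, tf, provenance = c(run = "test"))
  lines <- readLines(tf)
  expect_true(any(grepl("^# run: test", lines)))
  df <- utils::read.csv(tf, comment.char = "#")
  expect_identical(nrow(df), 2L * 11L)
  expect_identical(sort(unique(df$species_id)), c("toy_E", "toy_S"))
  expect_true(all(c("time_h", "biomass_g", "lcts_e", "o2_e") %in%
                    names(df)))
})

test_that("configuration invariants are enforced", {
  expect_error(sim_config(dt = 0), "dt")
  expect_error(sim_config(duration = 0.25), "multiple of dt")
  expect_error(sim_config(death_rate = -1), ">= 0")
  expect_error(community_env(c(a = -1)), ">= 0")
  expect_error(make_environment("cooperation", scale = 0), "positive")
})
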