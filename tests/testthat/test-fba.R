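## Growth rates below were derived by hand from the toy stoichiometry:
## with lactose/O2/methionine uptake capped at 10 mmol/gDW/h, oxygen
## (2 per lactose) limits aerobic catabolism to flux 5 (30 ATP), the
## remaining 5 lactose ferments (10 ATP), maintenance burns 2, and
## biomass costs 10 ATP/gDW: mu = (30 + 10 - 2)/10 = 3.8. Knocking out
## fermentation removes 10 ATP (mu = 2.8); without oxygen only
## fermentation runs at lactose cap 10 (mu = (20 - 2)/10 = 1.8). The
## S-like model respires acetate at O2-limited flux 5 (15 ATP, minus 1
## maintenance): mu = 1.4, methionine secretion 0.5 * 1.4 = 0.7.

test_that("toy growth rates match the hand-solved linear programs", {
  expect_equal(solve_fba(toy$E, ov_full)$growth_rate, 3.8,
               tolerance = 1e-9)
  expect_equal(solve_fba(apply_knockout(toy$E, "FERM"),
                         ov_full)$growth_rate, 2.8, tolerance = 1e-9)
  ## oxygen exchange knocked out: overrides must not name the disabled
  ## reaction, since an override replaces the stored bounds
  expect_equal(solve_fba(apply_knockout(toy$E, "EX_o2"),
                         ov_full[c("EX_lcts", "EX_met")])$growth_rate,
               1.8, tolerance = 1e-9)
  ## methionine auxotrophy: no uptake, no growth
  no_met <- c(ov_full[c("EX_lcts", "EX_o2")],
              list(EX_met = c(0, 1000)))
  expect_equal(solve_fba(toy$E, no_met)$growth_rate, 0)
  sS <- solve_fba(toy$S, ov_s)
  expect_equal(sS$growth_rate, 1.4, tolerance = 1e-9)
  expect_equal(unname(sS$fluxes["EX_met"]), 0.7, tolerance = 1e-9)
})

test_that("growth-coupled secretion tracks the growth rate exactly", {
  for (cap in c(2, 6, 10)) {
    s <- solve_fba(toy$S, list(EX_ac = c(-cap, 1000),
                               EX_o2 = c(-10, 1000)))
    expect_equal(unname(s$fluxes["EX_met"]), 0.5 * s$growth_rate,
                 tolerance = 1e-9)
  }
})

test_that("flux minimization never changes the growth rate", {
  cases <- list(list(toy$E, ov_full),
                list(toy$S, ov_s),
                list(apply_knockout(toy$E, "AERO"), ov_full),
                list(apply_knockout(toy$E, "EX_met"), ov_full))
  for (cs in cases) {
    mu1 <- solve_fba(cs[[1]], cs[[2]], tie_break = "none")$growth_rate
    mu2 <- solve_fba(cs[[1]], cs[[2]],
                     tie_break = "flux_min")$growth_rate
    expect_lt(abs(mu1 - mu2), 1e-9)
  }
})

test_that("optimal solutions satisfy coupling-augmented mass balance", {
  for (md in list(toy$E, toy$S)) {
    ov <- if (identical(md$species_id, "toy_E")) ov_full else ov_s
    s <- solve_fba(md, ov)
    S <- cofba:::stoich_matrix(md, augmented = TRUE)
    resid <- as.numeric(S %*% s$fluxes[colnames(S)])
    expect_lt(max(abs(resid)), 1e-9)
    ## bounds respected
    bnd <- cofba:::model_bounds(md, ov)
    expect_true(all(s$fluxes >= bnd$lb[names(s$fluxes)] - 1e-9))
    expect_true(all(s$fluxes <= bnd$ub[names(s$fluxes)] + 1e-9))
    ## mu equals the biomass flux
    expect_equal(unname(s$fluxes[md$biomass_reaction_id]),
                 s$growth_rate, tolerance = 1e-12)
  }
})

test_that("infeasible networks report zero growth, not an error", {
  ## maintenance cannot be met without any carbon source
  starved <- list(EX_lcts = c(0, 1000), EX_o2 = c(-10, 1000),
                  EX_met = c(-10, 1000))
  s <- solve_fba(toy$E, starved)
  expect_identical(s$status, "infeasible")
  expect_identical(s$growth_rate, 0)
  expect_length(s$fluxes, 0L)
})

test_that("knocking out the biomass reaction forces zero growth", {
  s <- solve_fba(apply_knockout(toy$E, "BIOMASS"), ov_full)
  expect_equal(s$growth_rate, 0)
  ## the cell still runs maintenance catabolism and secretes acetate
  expect_gt(unname(s$fluxes["EX_ac"]), 0)
})

test_that("knockout of a zero-flux reaction cannot raise growth", {
  ## without methionine the optimum is pure maintenance: fermentation,
  ## methionine transport and biomass all carry zero flux
  no_met <- c(ov_full[c("EX_lcts", "EX_o2")],
              list(EX_met = c(0, 1000)))
  base <- solve_fba(toy$E, no_met)
  zero_flux <- names(base$fluxes)[base$fluxes == 0]
  expect_true(length(zero_flux) >= 3L)
  for (rid in zero_flux) {
    mu <- solve_fba(apply_knockout(toy$E, rid),
                    no_met[setdiff(names(no_met), rid)])$growth_rate
    expect_lte(mu, base$growth_rate + 1e-9)
  }
})

test_that("bound overrides are validated", {
  expect_error(solve_fba(toy$E, list(NOPE = c(0, 1))),
               "unknown reaction")
  expect_error(solve_fba(toy$E, list(FERM = c(2, 1))), "lower > upper")
})
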