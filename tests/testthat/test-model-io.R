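test_that("JSON round trip is the identity on models", {
  tf <- tempfile(fileext = ".json")
  write_model(toy$S, tf)
  back <- read_model(tf)
  expect_identical(back$species_id, toy$S$species_id)
  expect_identical(names(back$reactions), names(toy$S$reactions))
  for (id in names(back$reactions)) {
    a <- back$reactions[[id]]
    b <- toy$S$reactions[[id]]
    expect_equal(a$stoichiometry[sort(names(a$stoichiometry))],
                 b$stoichiometry[sort(names(b$stoichiometry))])
    expect_equal(a$lower_bound, b$lower_bound)
    expect_equal(a$upper_bound, b$upper_bound)
    expect_identical(a$is_exchange, b$is_exchange)
  }
  expect_equal(back$coupled_secretions, toy$S$coupled_secretions)
  expect_identical(model_checksum(back), model_checksum(toy$S))
  ## a second round trip is byte-stable
  tf2 <- tempfile(fileext = ".json")
  write_model(back, tf2)
  expect_identical(readLines(tf), readLines(tf2))
})

test_that("coupled secretion survives serialization", {
  tf <- tempfile(fileext = ".json")
  write_model(toy$S, tf)
  back <- read_model(tf)
  expect_length(back$coupled_secretions, 1L)
  expect_identical(back$coupled_secretions[[1]]$metabolite_id, "met_e")
  expect_equal(back$coupled_secretions[[1]]$rate, 0.5)
})

test_that("validate_model reports specific violations", {
  expect_length(validate_model(toy$E), 0L)
  bad <- toy$E
  bad$reactions$AERO$stoichiometry <-
    c(bad$reactions$AERO$stoichiometry, ghost_c = -1)
  v <- validate_model(bad)
  expect_length(v, 1L)
  expect_match(v, "AERO")
  expect_match(v, "ghost_c")

  bad2 <- toy$E
  bad2$reactions$FERM$lower_bound <- 5
  bad2$reactions$FERM$upper_bound <- 1
  v2 <- validate_model(bad2)
  expect_length(v2, 1L)
  expect_match(v2, "lower_bound > upper_bound")

  bad3 <- toy$E
  bad3$reactions <- list()
  expect_true(any(grepl("no reactions", validate_model(bad3))))
  expect_error(write_model(bad3, tempfile()), "invalid")
})

test_that("knockouts zero bounds on a copy and unknown ids error", {
  mut <- apply_knockout(toy$E, "FERM")
  expect_equal(mut$reactions$FERM$lower_bound, 0)
  expect_equal(mut$reactions$FERM$upper_bound, 0)
  expect_equal(toy$E$reactions$FERM$upper_bound, 1000) # original intact
  expect_error(apply_knockout(toy$E, "NOPE"), "unknown reaction")
})

test_that("enumerate_knockouts lists every reaction in model order", {
  expect_identical(enumerate_knockouts(toy$E), names(toy$E$reactions))
  expect_length(enumerate_knockouts(toy$E), 12L)
  expect_length(enumerate_knockouts(toy$S), 8L)
})

test_that("SBML import reproduces the JSON toy model", {
  sbml <- read_model(system.file("extdata", "toy_e_synthetic.sbml.xml",
                                 package = "cofba"))
  expect_length(sbml$reactions, 12L)
  expect_equal(nrow(sbml$metabolites), 10L)
  expect_identical(sbml$biomass_reaction_id, "BIOMASS")
  ## exchange sign convention is normalized on read
  for (r in sbml$reactions)
    if (isTRUE(r$is_exchange))
      expect_equal(unname(r$stoichiometry[[1]]), -1)
  expect_setequal(
    sbml$metabolites$id[sbml$metabolites$compartment == "extracellular"],
    c("lcts_e", "o2_e", "ac_e", "met_e"))
  ## fbc bounds are honoured (maintenance lower bound)
  expect_equal(sbml$reactions$ATPM$lower_bound, 2)
  ## same growth rate as the generated model
  s <- solve_fba(sbml, ov_full)
  expect_equal(s$growth_rate, solve_fba(toy$E, ov_full)$growth_rate,
               tolerance = 1e-9)
})

test_that("load-time reaction blocking equals an explicit knockout", {
  path <- system.file("extdata", "toy_e_synthetic.sbml.xml",
                      package = "cofba")
  blocked <- read_model(path, blocked_reactions = "FERM")
  expect_equal(blocked$reactions$FERM$upper_bound, 0)
  expect_equal(solve_fba(blocked, ov_full)$growth_rate, 2.8,
               tolerance = 1e-9)
})

test_that("read errors are informative", {
  expect_error(read_model(tempfile()), "not found")
  tf <- tempfile(fileext = ".json")
  writeLines("{not json", tf)
  expect_error(read_model(tf), "parse")
  tf2 <- tempfile(fileext = ".json")
  writeLines('{"species_id": "x", "metabolites": []}', tf2)
  expect_error(read_model(tf2), "lacks element")
})
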