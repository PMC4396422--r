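fake_traj <- function(b0, b1, horizon = 10) {
  structure(list(times = c(0, horizon),
                 biomass = matrix(c(b0, b1), 2, 1)),
            class = "community_sim")
}

test_that("essentiality is a threshold on the biomass-gain ratio", {
  unp <- fake_traj(3e-7, 3e-6)           # gain 2.7e-6
  expect_true(call_essential(fake_traj(3e-7, 3e-7 + 2.7e-8 * 0.5),
                             unp, 0.02)) # ratio 0.005
  expect_false(call_essential(fake_traj(3e-7, 3e-7 + 2.7e-6 * 0.5),
                              unp, 0.02)) # ratio 0.5
  expect_false(call_essential(unp, unp, 0.02)) # ratio 1
  ## non-growing reference: essential iff the mutant also fails to gain
  dead <- fake_traj(3e-7, 2e-7)
  expect_true(call_essential(fake_traj(3e-7, 1e-7), dead, 0.02))
  expect_false(call_essential(fake_traj(3e-7, 4e-7), dead, 0.02))
  expect_error(call_essential(fake_traj(1, 2, horizon = 5), unp, 0.02),
               "horizons")
})

test_that("screen covers every mutant in both conditions", {
  scr <- toy_screen_cached()
  expect_identical(nrow(scr$records), 24L)
  expect_identical(nrow(scr$unperturbed), 2L)
  counts <- table(scr$records$condition)
  expect_identical(as.integer(counts[["cooperation"]]), 12L)
  expect_identical(as.integer(counts[["competition"]]), 12L)
  expect_false(any(duplicated(
    scr$records[c("reaction_id", "condition")])))
  ## metrics in the records are consistent with the metric functions
  for (i in seq_len(nrow(scr$records))) {
    r <- scr$records[i, ]
    u <- scr$unperturbed[scr$unperturbed$condition == r$condition, ]
    expect_equal(r$ECD, ecd(r$E_final, r$S_final, u$E_final, u$S_final),
                 tolerance = 1e-12)
    expect_equal(r$BM_norm,
                 normalized_bm(r$E_final, r$S_final,
                               u$E_final, u$S_final),
                 tolerance = 1e-12)
  }
})

test_that("the unperturbed outcome maps to the metric triple (0, 1, 1)", {
  unp <- toy_screen_cached()$unperturbed
  for (i in seq_len(nrow(unp))) {
    expect_identical(ecd(unp$E_final[i], unp$S_final[i],
                         unp$E_final[i], unp$S_final[i]), 0)
    expect_equal(normalized_percent_e(unp$E_final[i], unp$S_final[i],
                                      unp$E_final[i], unp$S_final[i]), 1)
    expect_equal(normalized_bm(unp$E_final[i], unp$S_final[i],
                               unp$E_final[i], unp$S_final[i]), 1)
  }
})

test_that("biomass-reaction knockout is essential in every context", {
  scr <- toy_screen_cached()
  bio <- scr$records[scr$records$reaction_id == "BIOMASS", ]
  expect_true(all(bio$essential_monoculture))
  expect_true(all(bio$essential_cooperation))
  expect_true(all(bio$essential_competition))
  ## the partner keeps growing on the supplemented competition medium,
  ## but in cooperation it is starved down to a fraction of that
  s_coop <- bio$S_final[bio$condition == "cooperation"]
  s_comp <- bio$S_final[bio$condition == "competition"]
  expect_gt(s_comp, 3e-7)
  expect_lt(s_coop, 0.1 * s_comp)
})

test_that("monoculture and competition essentiality sets coincide", {
  scr <- toy_screen_cached()
  comp <- scr$records[scr$records$condition == "competition", ]
  expect_identical(comp$essential_competition,
                   comp$essential_monoculture)
  ## cooperation adds essentials (the jumpstart class), never removes
  coop <- scr$records[scr$records$condition == "cooperation", ]
  extra <- coop$reaction_id[coop$essential_cooperation &
                              !coop$essential_monoculture]
  expect_true("ATPM" %in% extra)
  expect_true(all(coop$essential_cooperation[coop$essential_monoculture]))
})

test_that("oxygen-loss knockouts shift composition toward the partner", {
  scr <- toy_screen_cached()
  for (rid in c("EX_o2", "T_o2")) {
    r <- scr$records[scr$records$reaction_id == rid, ]
    expect_true(all(r$pctE_norm < 1),
                info = paste(rid, "should reduce the E fraction"))
  }
})

test_that("mutant order does not affect screen records", {
  short <- screen_config(focal_species = "S",
                         conditions = c("cooperation", "competition"),
                         simulation = sim_config(duration = 2))
  scr1 <- run_screen(toy$S, toy$E, short)
  perm <- toy$S
  perm$reactions <- perm$reactions[rev(names(perm$reactions))]
  scr2 <- run_screen(perm, toy$E, short)
  a <- scr1$records[order(scr1$records$reaction_id,
                          scr1$records$condition), ]
  b <- scr2$records[order(scr2$records$reaction_id,
                          scr2$records$condition), ]
  rownames(a) <- rownames(b) <- NULL
  expect_equal(a, b, tolerance = 1e-12)
})

test_that("screen TSV round trip preserves records and provenance", {
  scr <- toy_screen_cached()
  tf <- tempfile(fileext = ".tsv")
  write_screen(scr, tf)
  lines <- readLines(tf)
  expect_true(any(grepl("^# focal_checksum: [0-9a-f]{32}", lines)))
  back <- read_screen(tf)
  expect_equal(back$records$ECD, scr$records$ECD, tolerance = 1e-10)
  expect_equal(back$unperturbed$E_final, scr$unperturbed$E_final,
               tolerance = 1e-10)
  ## writing the same screen twice is byte-identical (determinism of
  ## the serialization itself)
  tf2 <- tempfile(fileext = ".tsv")
  write_screen(scr, tf2)
  expect_identical(readLines(tf), readLines(tf2))
})
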