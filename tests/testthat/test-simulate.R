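test_that("simulate_population draws cycling cells and phases correctly", {
  p <- preset_kinetics("control")
  pop <- simulate_population(1e5, p, seed = 31)
  # cycling fraction within 3 binomial SE of GF
  se <- sqrt(0.11 * 0.89 / 1e5)
  expect_lt(abs(mean(pop$cycling) - 0.11), 3 * se)
  # positions uniform on [0, Tc); phases consistent with position
  pos <- pop$cycle_position[pop$cycling]
  expect_true(all(pos >= 0 & pos < p$tc))
  expect_true(all(pop$phase[!pop$cycling] == "G1"))
  in_s <- !is.na(pop$cycle_position) &
    pop$cycle_position >= p$tg1 & pop$cycle_position < p$tg1 + p$ts
  expect_identical(pop$phase == "S", in_s)
  expect_true(all(pop$s_progress[pop$phase == "S"] >= 0 &
                    pop$s_progress[pop$phase == "S"] < 1))
  # empirical phase fractions match truth within 3 multinomial SE
  truth <- phase_fractions_true(p)
  for (ph in c("G1", "S", "G2M")) {
    tr <- switch(ph, G1 = truth$g1, S = truth$s, G2M = truth$g2m)
    expect_lt(abs(mean(pop$phase == ph) - tr),
              3 * sqrt(tr * (1 - tr) / 1e5))
  }
})

test_that("simulate_population handles edge cases and is reproducible", {
  p <- control_labelling()
  expect_equal(nrow(simulate_population(0, p)), 0L)
  all_cyc <- simulate_population(500, kinetic_params(10.5, 5, 1), seed = 1)
  expect_true(all(all_cyc$cycling))
  a <- simulate_population(1000, p, seed = 99)
  b <- simulate_population(1000, p, seed = 99)
  expect_identical(a, b)
  expect_false(identical(a, simulate_population(1000, p, seed = 100)))
  # caller RNG state untouched
  set.seed(5); x1 <- runif(1)
  set.seed(5); invisible(simulate_population(10, p, seed = 1)); x2 <- runif(1)
  expect_identical(x1, x2)
})

test_that("label_cumulative marks exactly the S-transiting cells", {
  p <- preset_kinetics("control")
  pop <- simulate_population(1e5, p, seed = 32)
  # T = 0: labelled iff currently in S
  l0 <- label_cumulative(pop, p, 0)
  expect_identical(l0$labelled, pop$phase == "S")
  se0 <- sqrt(0.057 * 0.943 / 1e5)
  expect_lt(abs(mean(l0$labelled) - expected_li(p, 0)), 3 * se0)
  # T = 0.5 h: labelled fraction near expected_li
  l1 <- label_cumulative(pop, p, 0.5)
  e1 <- expected_li(p, 0.5)
  expect_lt(abs(mean(l1$labelled) - e1), 3 * sqrt(e1 * (1 - e1) / 1e5))
  # beyond Tc - Ts every cycling cell is labelled, non-cycling never
  lfull <- label_cumulative(pop, p, p$tc - p$ts)
  expect_identical(lfull$labelled, pop$cycling)
  expect_true(!any(lfull$labelled[!lfull$cycling]))
  # labels are monotone in T
  expect_true(all(l1$labelled[l0$labelled]))
})

test_that("simulate_sections samples sections and balances density*area", {
  p <- preset_kinetics("control")
  pop <- label_cumulative(simulate_population(600, p, seed = 33), p, 10.5)
  # noiseless whole-population section reproduces the labelled fraction
  sec <- simulate_sections(list(pop), times = 10.5, cells_per_section = 600,
                           n_retinas = 1, noise_cv = 0, seed = 34)
  total <- round(sec$dapi_density_per_um2 * sec$section_area_um2)
  expect_equal(total, 600)
  expect_equal(sec$brdu_pos / total, mean(pop$labelled))
  # noisy draws still satisfy the rounding constraint
  pops <- lapply(1:3, function(r)
    label_cumulative(simulate_population(2000, p, seed = 40 + r), p, 10.5))
  sec3 <- simulate_sections(list(pops), times = 10.5,
                            cells_per_section = 500, n_retinas = 3,
                            noise_cv = 0.1, seed = 35)
  expect_equal(round(sec3$dapi_density_per_um2 * sec3$section_area_um2),
               rep(500, 3))
  expect_true(all(sec3$brdu_pos <= 500))
  # one-cell sections are 0/1 counts
  sec1 <- simulate_sections(list(pop), times = 10.5, cells_per_section = 1,
                            n_retinas = 1, seed = 36)
  expect_true(sec1$brdu_pos %in% c(0L, 1L))
  expect_error(
    simulate_sections(list(pop), times = 10.5, cells_per_section = 601,
                      n_retinas = 1, seed = 37),
    "exceeds")
})

test_that("a simulated experiment reproduces the plateau LI on average", {
  p <- preset_kinetics("control")
  # 3 retinas x 500 cells at T = 10.5 (plateau): mean LI ~ GF
  lis <- sapply(1:20, function(i) {
    sec <- simulate_experiment(p, times = 10.5, seed = 300 + i)
    suppressWarnings(labelling_index(sec))$li
  })
  se <- sqrt(0.11 * 0.89 / (3 * 500 * 20))
  expect_lt(abs(mean(lis) - 0.11), 3 * se)
})

test_that("simulate_experiment is bit-reproducible under a fixed seed", {
  p <- control_labelling()
  a <- simulate_experiment(p, seed = 77)
  b <- simulate_experiment(p, seed = 77)
  expect_identical(a, b)
  expect_false(identical(a, simulate_experiment(p, seed = 78)))
})

test_that("simulate_dna_content maps phase to nominal 2C/4C content", {
  # gf = 0 gives a pure G1/G0 population: all events exactly 2C at cv = 0
  pure <- simulate_population(2000, kinetic_params(10, 5, 0), seed = 38)
  x <- simulate_dna_content(pure, c2_level = 50, cv = 0, seed = 39)
  expect_true(all(x == 50))

  p <- preset_kinetics("control")
  pop <- simulate_population(2e5, p, seed = 40)
  x0 <- simulate_dna_content(pop, c2_level = 50, cv = 0, seed = 41)
  # S-phase nominal values strictly between 2C and 4C
  expect_true(all(x0[pop$phase == "S"] > 50 & x0[pop$phase == "S"] < 100))
  expect_true(all(x0[pop$phase == "G2M"] == 100))
  # with noise, G1 events average to the 2C level within 0.5%
  x <- simulate_dna_content(pop, c2_level = 50, cv = 0.03, seed = 42)
  expect_lt(abs(mean(x[pop$phase == "G1"]) - 50) / 50, 0.005)
  expect_error(simulate_dna_content(pop, n_events = 3e5), "exceeds")
})

test_that("simulate_morphometry draws Gaussian groups to spec", {
  spec <- data.frame(label = c("control", "morphant"),
                     mean = c(15.3, 28.0), sd = c(4.7, 3.4), n = c(3, 3))
  m <- simulate_morphometry(spec, seed = 43)
  expect_equal(names(m), c("group", "embryo_id", "value"))
  expect_equal(as.vector(table(m$group)[c("control", "morphant")]), c(3, 3))
  # sd = 0 collapses onto the mean
  m0 <- simulate_morphometry(data.frame(label = "a", mean = 7, sd = 0, n = 5),
                             seed = 44)
  expect_true(all(m0$value == 7))
  # large-n convergence of the sample mean
  ml <- simulate_morphometry(data.frame(label = "a", mean = 0, sd = 1,
                                        n = 1e5), seed = 45)
  expect_lt(abs(mean(ml$value)), 0.01)
})
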