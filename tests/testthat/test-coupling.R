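test_that("clock validation enforces ordering and integer multiples", {
  expect_s3_class(clock_config(0.01, 0.1, 10, 100), "clock_config")
  expect_error(clock_config(1, 0.1, 10, 100), "dt_diffusion <= dt_mechanics")
  expect_error(clock_config(0.03, 0.1, 10, 100), "integer multiple")
  expect_error(clock_config(0.1, 0.1, 10, -5), "t_end")
})

test_that("input rules threshold their sources and commute on disjoint nodes", {
  net <- parse_network(
    "TNF { is_input = TRUE; } O2low { is_input = TRUE; }
     A { logic = TNF; rate_up = 1; rate_down = 1; }")
  g <- voxel_grid(c(-50, 50), dx = 20, ndim = 2)
  add_substrate(g, "TNF", D = 100, decay = 0, initial = 0.4)
  p <- cell_population(strain_params("WT"), network = net, ndim = 2, seed = 1)
  add_cells(p, x = c(0, 10), y = 0)
  rules <- list(input_rule("TNF", "substrate", threshold = 0.3, substrate = "TNF"),
                input_rule("O2low", "receptor", threshold = 0.5))
  p$internalised <- c(0.6, 0.1)
  sync_inputs(p, g, rules)
  expect_equal(p$net_states[, 1], c(1L, 1L))   # substrate 0.4 > 0.3
  expect_equal(p$net_states[, 2], c(1L, 0L))   # receptor thresholds per cell
  # below threshold switches back off; other node values untouched
  density_array(g, "TNF")[] <- 0
  p$net_states[, 3] <- 1L
  sync_inputs(p, g, rules)
  expect_equal(p$net_states[, 1], c(0L, 0L))
  expect_equal(p$net_states[, 3], c(1L, 1L))
  # reversed rule order gives the same result (disjoint targets)
  p2 <- cell_population(strain_params("WT"), network = net, ndim = 2, seed = 1)
  add_cells(p2, x = c(0, 10), y = 0)
  p2$internalised <- c(0.6, 0.1)
  sync_inputs(p2, g, rev(rules))
  expect_equal(p2$net_states[, 2], c(1L, 0L))
  # rules must target declared input nodes
  cfgerr <- tryCatch(
    sim_config(strains = strain_params("WT"),
               positions = data.frame(type = "cell", strain = 1L, x = 0, y = 0),
               network = net, ndim = 2,
               input_rules = list(input_rule("A", "receptor", 1))),
    error = conditionMessage)
  expect_match(cfgerr, "not an input node")
})

test_that("output rules latch death fates, gate the cycle and flag secretion", {
  net <- parse_network(
    "Apoptosis { logic = 0; rate_up = 1; rate_down = 1; }
     NonACD { logic = 0; rate_up = 1; rate_down = 1; }
     Survival { logic = 1; rate_up = 1; rate_down = 1; }
     NFkB { logic = 0; rate_up = 1; rate_down = 1; }")
  p <- cell_population(strain_params("WT"), network = net, ndim = 2, seed = 1)
  add_cells(p, x = c(0, 20, 40), y = 0)
  rules <- default_output_rules()
  # all read-outs 0: nothing happens
  apply_outputs(p, rules)
  expect_equal(p$fate, rep(0L, 3))
  expect_false(any(p$secreting))
  # NFkB on: secretion + permanent activated flag
  p$net_states[1, 4] <- 1L
  apply_outputs(p, rules)
  expect_true(p$secreting[1] && p$activated[1])
  p$net_states[1, 4] <- 0L
  apply_outputs(p, rules)
  expect_false(p$secreting[1])
  expect_true(p$activated[1])      # latched
  # Apoptosis node on, later off: fate stays Apoptosis
  p$net_states[2, 1] <- 1L
  apply_outputs(p, rules)
  expect_equal(p$fate[2], 1L)
  p$net_states[2, 1] <- 0L
  apply_outputs(p, rules)
  expect_equal(p$fate[2], 1L)
  # Survival=0 arrests without killing
  p$net_states[3, 3] <- 0L
  apply_outputs(p, rules)
  expect_true(p$arrest[3])
  expect_equal(p$fate[3], 0L)
  p$net_states[3, 3] <- 1L
  apply_outputs(p, rules)
  expect_false(p$arrest[3])
})

test_that("a run with t_end = 0 contains exactly the initial census", {
  cfg <- tiny_monolayer_config(t_end = 0)
  out <- run_simulation(cfg)
  expect_equal(unique(out$population$t), 0)
  expect_equal(sum(out$population$count), 4)
})

test_that("identical config and seed reproduce the outputs bitwise", {
  net <- build_cell_fate_network()
  mk <- function() {
    cfg <- sim_config(
      strains = strain_params("WT", motility_speed = 0.5,
                              cycle_duration = 300,
                              volume_growth_rate = 0.02,
                              tnf_secretion_rate = 0.05),
      positions = data.frame(type = "cell", strain = 1L,
                             x = c(-15, 0, 15), y = c(0, 12, -12)),
      network = net,
      substrates = list(TNF = list(
        D = 1200, decay = 0.0275,
        schedule = injection_schedule("continuous", 0.5))),
      bounds = c(-80, 80), dx = 20, ndim = 2,
      input_rules = list(input_rule("TNF", "receptor", 0.15)),
      receptor = tnf_receptor_params(),
      clock = clock_config(0.1, 0.1, 10, 240, 60), seed = 42,
      record_snapshots = TRUE)
    run_simulation(cfg)
  }
  o1 <- mk(); o2 <- mk()
  expect_identical(o1$population, o2$population)
  expect_identical(o1$snapshots, o2$snapshots)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_simulation_csv(o1, d1); write_simulation_csv(o2, d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  }
})

test_that("fate transitions over a run form the Proliferative -> death DAG", {
  net <- build_cell_fate_network()
  cfg <- sim_config(
    strains = strain_params("WT", cycle_duration = 1e9,
                            tnf_secretion_rate = 0.05),
    positions = data.frame(type = "cell", strain = 1L,
                           x = seq(-40, 40, by = 20), y = 0),
    network = net,
    substrates = list(TNF = list(
      D = 1200, decay = 0.0275,
      schedule = injection_schedule("continuous", 2))),
    bounds = c(-80, 80), dx = 20, ndim = 2,
    input_rules = list(input_rule("TNF", "receptor", 0.15)),
    receptor = tnf_receptor_params(),
    clock = clock_config(0.1, 0.1, 10, 720, 30), seed = 7)
  out <- run_simulation(cfg)
  pop <- out$population
  # cumulative committed counts never decrease
  for (f in c("Apoptosis", "NonACD")) {
    cm <- pop$committed[pop$fate == f]
    expect_true(all(diff(cm) >= 0))
  }
  expect_gt(sum(out$final$committed), 0)   # strong dose kills some cells
})

test_that("without input rules the cells ignore the substrate fields", {
  net <- build_cell_fate_network()
  mk <- function(dose) {
    cfg <- sim_config(
      strains = strain_params("WT", cycle_duration = 400,
                              volume_growth_rate = 0.02),
      positions = data.frame(type = "cell", strain = 1L,
                             x = c(-15, 0, 15), y = 0),
      network = net,
      substrates = list(TNF = list(
        D = 1200, decay = 0.0275,
        schedule = injection_schedule("continuous", dose))),
      bounds = c(-80, 80), dx = 20, ndim = 2,
      input_rules = list(),
      clock = clock_config(0.1, 0.1, 10, 480, 120), seed = 3)
    run_simulation(cfg)
  }
  o_hi <- mk(5); o_lo <- mk(0)
  expect_identical(o_hi$population, o_lo$population)
  # but the fields themselves did evolve
  expect_gt(total_mass(o_hi$grid, "TNF"), total_mass(o_lo$grid, "TNF"))
})

test_that("signalling updates happen about t_end/dt_signalling times per cell", {
  net <- parse_network("TNF { is_input = TRUE; }
                        Ticker { logic = !Ticker; rate_up = 100; rate_down = 100; }")
  cfg <- sim_config(
    strains = strain_params("WT", cycle_duration = 1e9),
    positions = data.frame(type = "cell", strain = 1L, x = c(0, 25), y = 0),
    network = net, substrates = list(),
    clock = clock_config(0.1, 0.1, 10, 200, 100), seed = 1, ndim = 2)
  out <- run_simulation(cfg)
  # staggered phases: each cell got floor(t_end/dt) or one more update;
  # verify via the next_signal bookkeeping
  expect_true(all(out$final$next_signal > 200 - 10 - 1e-6 &
                  out$final$next_signal <= 200 + 10 + 1e-6))
})
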