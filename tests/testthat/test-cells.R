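test_that("volume dynamics: fixed point, death programs, half-life", {
  st <- strain_params("WT")
  p <- cell_population(list(st), ndim = 2, seed = 1)
  add_cells(p, x = 0, y = 0)
  p$arrest[1] <- TRUE     # growth off: reference volume is a fixed point
  v0 <- p$v_fluid + p$v_cyto + p$v_nucl
  update_volume(p, 1)
  expect_equal(p$v_fluid + p$v_cyto + p$v_nucl, v0, tolerance = 1e-9)

  # apoptosis: strictly decreasing until removal below 5% of commit volume
  p2 <- cell_population(list(st), ndim = 2, seed = 1)
  add_cells(p2, x = 0, y = 0)
  set_fate(p2, 1L, "Apoptosis")
  v <- sum(p2$v_fluid, p2$v_cyto, p2$v_nucl)
  steps <- 0
  while (length(p2$id) && steps < 10000) {
    update_volume(p2, 1)
    if (length(p2$id)) {
      vnew <- sum(p2$v_fluid, p2$v_cyto, p2$v_nucl)
      expect_lt(vnew, v)
      v <- vnew
    }
    steps <- steps + 1
  }
  expect_equal(length(p2$id), 0L)
  expect_equal(p2$n_removed, 1L)
  expect_gt(v, 0)

  # exponential relaxation: half-life matches ln 2 / rate within 1%
  p3 <- cell_population(list(st), ndim = 2, seed = 1)
  add_cells(p3, x = 0, y = 0)
  rate <- st$volume_growth_rate
  v0 <- sum(p3$v_fluid, p3$v_cyto, p3$v_nucl)
  target <- 2 * st$volume_total
  gap0 <- target - v0
  t_half <- log(2) / rate
  nstep <- round(t_half / 0.1)
  for (i in seq_len(nstep)) update_volume(p3, 0.1)
  gap <- target - sum(p3$v_fluid, p3$v_cyto, p3$v_nucl)
  expect_lt(abs(gap / gap0 - 0.5 * 2^(-(nstep * 0.1 - t_half) / t_half)), 0.01)
})

test_that("necrotic cells swell toward 1.5x and lyse after 6 h", {
  st <- strain_params("WT")
  p <- cell_population(list(st), ndim = 2, seed = 1)
  add_cells(p, x = 0, y = 0)
  set_fate(p, 1L, "NonACD")
  for (i in 1:359) update_volume(p, 1)
  expect_equal(length(p$id), 1L)
  v <- sum(p$v_fluid, p$v_cyto, p$v_nucl)
  expect_gt(v, st$volume_total)                 # swollen
  expect_lte(v, 1.5 * st$volume_total + 1e-6)   # bounded by the lysis target
  update_volume(p, 1)
  expect_equal(length(p$id), 0L)                # lysed and removed
})

test_that("division conserves volume, copies the network state, renews ids", {
  net <- parse_network(
    "A { logic = 1; rate_up = 0.05; rate_down = 0.05; }
     B { logic = A; rate_up = 0.1; rate_down = 0.1; }")
  st <- strain_params("WT", cycle_duration = 100)
  p <- cell_population(list(st), network = net, ndim = 2, seed = 5)
  add_cells(p, x = 0, y = 0)
  # force readiness: aged timer and doubled volume
  p$age[1] <- 1e5
  p$v_fluid[1] <- 2 * p$v_fluid[1]
  p$v_cyto[1] <- 2 * p$v_cyto[1]
  p$v_nucl[1] <- 2 * p$v_nucl[1]
  p$net_states[1, ] <- c(1L, 0L)
  vtot <- sum(p$v_fluid, p$v_cyto, p$v_nucl)
  mother_id <- p$id[1]
  daughters <- cycle_and_divide(p, dt = 0.1, dt_signalling = 10, t = 0)
  expect_length(daughters, 2L)
  expect_equal(length(p$id), 2L)
  expect_false(mother_id %in% p$id)
  expect_equal(sum(p$v_fluid, p$v_cyto, p$v_nucl), vtot, tolerance = 1e-9)
  expect_equal(p$net_states[1, ], c(1L, 0L))
  expect_equal(p$net_states[2, ], c(1L, 0L))
  # daughters sit at mother position +/- r/2: symmetric about the origin
  expect_equal(p$x[1] + p$x[2], 0, tolerance = 1e-9)
  expect_equal(p$y[1] + p$y[2], 0, tolerance = 1e-9)
})

test_that("division is suppressed for non-proliferative cells", {
  st <- strain_params("WT", cycle_duration = 1)
  p <- cell_population(list(st), ndim = 2, seed = 1)
  add_cells(p, x = 0, y = 0)
  p$age[1] <- 1e6
  p$v_fluid[1] <- 4 * p$v_fluid[1]
  set_fate(p, 1L, "Apoptosis")
  expect_length(cycle_and_divide(p, 0.1), 0L)
  expect_equal(length(p$id), 1L)
})

test_that("fates latch irreversibly and counters never decrease", {
  st <- strain_params("WT")
  p <- cell_population(list(st), ndim = 2, seed = 1)
  add_cells(p, x = c(0, 20), y = c(0, 0))
  set_fate(p, 1L, "Apoptosis")
  set_fate(p, 1L, "Proliferative")
  expect_equal(p$fate[1], 1L)
  set_fate(p, 1L, "NonACD")
  expect_equal(p$fate[1], 1L)        # still Apoptosis
  set_fate(p, 2L, "NonACD")
  set_fate(p, 2L, "NonACD")          # idempotent
  expect_equal(unname(p$committed[1, ]), c(1L, 1L))
})

test_that("oxygen necrosis uses a strict threshold", {
  st <- strain_params("WT", oxygen_necrosis_threshold = 5)
  p <- cell_population(list(st), ndim = 2, seed = 1)
  add_cells(p, x = c(0, 20, 40), y = 0)
  oxygen_death_check(p, c(5 - 1e-9, 5, 38))
  expect_equal(p$fate, c(2L, 0L, 0L))
})

test_that("id bookkeeping accounts for every agent ever created", {
  st <- strain_params("WT", cycle_duration = 120, volume_growth_rate = 0.02)
  p <- cell_population(list(st), ndim = 2, seed = 9)
  add_cells(p, x = c(-30, 0, 30), y = 0)
  add_spheres(p, x = 60, y = 0)
  for (i in 1:1000) {
    update_volume(p, 0.5)
    cycle_and_divide(p, 0.5)
    if (i == 500) set_fate(p, 1L, "Apoptosis")
  }
  expect_gt(p$n_created_cells, 3L)   # divisions happened
  expect_equal(p$n_created_cells + p$n_created_spheres,
               length(p$id) + p$n_removed)
})
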