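test_that("receptor update: identity, steady state, decoupling", {
  rs <- list(bound = 0, internalised = 0, k_on = 0.1, k_int = 0.5,
             k_clear = 0.05)
  out <- receptor_update(rs, local_conc = 0, dt = 1)
  expect_equal(out$rs$bound, 0)
  expect_equal(out$rs$internalised, 0)
  expect_equal(out$uptaken, 0)
  # constant concentration: internalised plateau = k_on c / k_clear
  rs2 <- rs
  for (i in 1:40000) rs2 <- receptor_update(rs2, 2, dt = 0.1)$rs
  expect_equal(rs2$internalised, 0.1 * 2 / 0.05, tolerance = 0.01)
  expect_equal(rs2$bound, 0.1 * 2 / 0.5, tolerance = 0.01)
  # k_int = 0: the internalised pool only decays
  rs3 <- list(bound = 0, internalised = 1, k_on = 0.1, k_int = 0,
              k_clear = 0.05)
  for (i in 1:100) rs3 <- receptor_update(rs3, 5, dt = 0.1)$rs
  expect_equal(rs3$internalised, exp(-0.05 * 10), tolerance = 0.01)
  # the uptaken amount respects the availability cap
  expect_equal(receptor_update(rs, 10, 1, available = 0.3)$uptaken, 0.3)
})

test_that("ligand mass is conserved between grid and receptor pools", {
  g <- voxel_grid(c(-40, 40), dx = 20, ndim = 2)
  add_substrate(g, "TNF", D = 0, decay = 0, initial = 1)
  rec <- tnf_receptor_params(k_on = 0.2, k_int = 0.5, k_clear = 0)
  p <- cell_population(strain_params("WT"), ndim = 2, seed = 1)
  add_cells(p, x = c(-10, -10, 15), y = 0)   # two cells share a voxel
  total0 <- sum(density_array(g, "TNF"))
  for (i in 1:500) {
    boolcell:::receptor_update_population(p, g, rec, dt = 0.1,
                                          rows = which(p$type == 0L))
  }
  total <- sum(density_array(g, "TNF")) + sum(p$bound) + sum(p$internalised)
  expect_lt(abs(total - total0) / total0, 1e-8)
  expect_true(all(density_array(g, "TNF") >= 0))
})

test_that("secretion adds rate*dt to the secreting cell's voxel only", {
  g <- voxel_grid(c(-40, 40), dx = 20, ndim = 2)
  add_substrate(g, "TNF", D = 1200, decay = 0)
  st <- strain_params("WT", tnf_secretion_rate = 0.3)
  p <- cell_population(list(st), ndim = 2, seed = 1)
  add_cells(p, x = c(0, -30), y = 0)
  p$secreting <- c(TRUE, FALSE)
  secretion_update(p, g, "TNF", dt = 2)
  expect_equal(sample_density(g, "TNF", c(0, 0)), 0.6)
  expect_equal(sample_density(g, "TNF", c(-30, 0)), 0)
  # a zero-rate strain disables the autocrine loop regardless of the flag
  st0 <- strain_params("none", tnf_secretion_rate = 0)
  p2 <- cell_population(list(st0), ndim = 2, seed = 1)
  add_cells(p2, x = 0, y = 0)
  p2$secreting <- TRUE
  g2 <- voxel_grid(c(-40, 40), dx = 20, ndim = 2)
  add_substrate(g2, "TNF", D = 1200, decay = 0)
  secretion_update(p2, g2, "TNF", dt = 2)
  expect_equal(max(density_array(g2, "TNF")), 0)
})

test_that("sustained TNF yields heterogeneous fate commitment", {
  net <- build_cell_fate_network()
  fd <- ensemble_fates(net, 1440, 4000, seed = 11, inputs = c(TNF = 1))
  expect_gt(fd$prob[["Apoptosis"]], 0)
  expect_gt(fd$prob[["NonACD"]], 0)
  expect_gt(fd$prob[["Survival"]], 0)
  # without the stimulus essentially nobody dies
  fd0 <- ensemble_fates(net, 1440, 2000, seed = 12, inputs = c(TNF = 0))
  expect_lt(fd0$prob[["Apoptosis"]] + fd0$prob[["NonACD"]], 0.01)
})

test_that("faster transcription favours non-apoptotic death", {
  fd1 <- ensemble_fates(build_cell_fate_network(0.2), 1440, 10000,
                        seed = 21, inputs = c(TNF = 1))
  fd5 <- ensemble_fates(build_cell_fate_network(1.0), 1440, 10000,
                        seed = 22, inputs = c(TNF = 1))
  p1 <- fd1$prob[["NonACD"]]; p5 <- fd5$prob[["NonACD"]]
  se <- sqrt(p1 * (1 - p1) / 10000 + p5 * (1 - p5) / 10000)
  expect_gt(p5 - p1, 3 * se)
})

test_that("apoptosis commits faster than non-apoptotic death", {
  net <- build_cell_fate_network()
  fd <- ensemble_fates(net, 1440, 4000, seed = 31, inputs = c(TNF = 1),
                       track = c("Apoptosis", "NonACD"))
  ft <- fd$first_times
  med_a <- median(ft[is.finite(ft[, 1]), 1])
  med_n <- median(ft[is.finite(ft[, 2]), 2])
  expect_lt(med_a, med_n)
})

test_that("the Survival stable state resists a TNF increase", {
  net <- build_cell_fate_network()
  # survival stable state under sustained TNF: NFkB branch fully on
  on <- c("TNF", "TNFR", "DISC", "RIP1", "RIP1ub", "RIP1K", "IKK", "NFkB",
          "cFLIP", "BCL2", "mROS", "mXIAP", "XIAP", "ATP", "Survival")
  s <- network_state(net, on)
  r <- transition_rates(net, s)
  expect_true(all(r == 0))   # absorbing
  # a 10-fold dose increase keeps the Boolean input at 1: state unchanged
  s2 <- advance(net, s, 1440, bc_rng(5))
  expect_identical(as.integer(s2), as.integer(s))
  expect_equal(s2[["Survival"]], 1L)
})

test_that("activation census is relative to the initial viable count", {
  p <- cell_population(strain_params("WT"), ndim = 2, seed = 1)
  add_cells(p, x = c(0, 20, 40, 60), y = 0)
  expect_equal(activation_census(p, 4), 0)
  p$activated[] <- TRUE
  expect_equal(activation_census(p, 4), 1)
  expect_error(activation_census(p, 0), "> 0")
})
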