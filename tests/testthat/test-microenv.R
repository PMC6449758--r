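test_that("pure decay matches exp(-lambda t) exactly", {
  g <- voxel_grid(c(-50, 50), dx = 10, ndim = 2)
  add_substrate(g, "s", D = 123, decay = 0.1, initial = 1)
  diffuse_decay(g, "s", dt = 1)
  expect_equal(as.numeric(density_array(g, "s")),
               rep(exp(-0.1), 100), tolerance = 1e-12)
  # uniform field with no decay is an exact fixed point of diffusion
  g2 <- voxel_grid(c(-50, 50), dx = 10, ndim = 3)
  add_substrate(g2, "s", D = 1000, decay = 0, initial = 2.5)
  diffuse_decay(g2, "s", dt = 0.5, nsub = 20)
  expect_equal(as.numeric(density_array(g2, "s")),
               rep(2.5, 1000), tolerance = 1e-12)
})

test_that("zero-flux diffusion conserves mass over 1000 steps", {
  g <- voxel_grid(c(-50, 50), dx = 10, ndim = 2)
  add_substrate(g, "s", D = 500, decay = 0)
  density_array(g, "s")[5, 5] <- 7
  m0 <- total_mass(g, "s")
  diffuse_decay(g, "s", dt = 0.1, nsub = 1000)
  expect_lt(abs(total_mass(g, "s") - m0) / m0, 1e-10)
  expect_true(all(density_array(g, "s") >= 0))
})

test_that("a point mass spreads like the heat kernel", {
  dx <- 4; D <- 100
  g <- voxel_grid(c(-100, 100), dx = dx, ndim = 2)
  add_substrate(g, "h", D = D, decay = 0)
  density_array(g, "h")[26, 26] <- 1 / dx^2   # unit mass
  diffuse_decay(g, "h", dt = 0.05, nsub = 10)
  t <- 0.5
  xc <- (seq_len(50) - 0.5) * dx - 100
  cen <- xc[26]
  G <- outer(xc - cen, xc - cen,
             function(a, b) exp(-(a^2 + b^2) / (4 * D * t)) / (4 * pi * D * t))
  num <- density_array(g, "h")
  expect_lt(sqrt(mean((num - G)^2)) / max(G), 0.02)
})

test_that("3D solution of a z-uniform problem matches 2D per slice", {
  dx <- 10; D <- 300
  g2 <- voxel_grid(c(-50, 50), dx = dx, ndim = 2)
  add_substrate(g2, "s", D = D, decay = 0.01)
  density_array(g2, "s")[4, 6] <- 5
  g3 <- voxel_grid(c(-50, 50), dx = dx, ndim = 3)
  add_substrate(g3, "s", D = D, decay = 0.01)
  a3 <- density_array(g3, "s")
  a3[4, 6, ] <- 5
  density_array(g3, "s") <- a3
  diffuse_decay(g2, "s", dt = 0.1, nsub = 50)
  diffuse_decay(g3, "s", dt = 0.1, nsub = 50)
  for (k in c(1, 5, 10)) {
    expect_equal(density_array(g3, "s")[, , k],
                 density_array(g2, "s"), tolerance = 1e-8)
  }
})

test_that("sampling uses the nearest-voxel convention", {
  g <- voxel_grid(c(0, 40), dx = 20, ndim = 2)
  add_substrate(g, "s", D = 1, decay = 0)
  density_array(g, "s")[] <- matrix(c(1, 2, 3, 4), 2)
  expect_equal(sample_density(g, "s", c(5, 5)), 1)
  expect_equal(sample_density(g, "s", c(25, 5)), 2)
  expect_equal(sample_density(g, "s", c(5, 25)), 3)
  expect_error(sample_density(g, "s", c(45, 5)), "outside")
  expect_error(sample_density(g, "s", c(-1, 5)), "outside")
})

test_that("cell sources and sinks are implicit, saturating and positive", {
  g <- voxel_grid(c(-30, 30), dx = 20, ndim = 2)
  add_substrate(g, "o", D = 0, decay = 0, initial = 2)
  # pure sink: implicit update c/(1 + U dt), stays positive
  up <- apply_sources_sinks(g, "o", rbind(c(0, 0)), secretion = 0,
                            uptake = 1, saturation = 0, dt = 1)
  expect_equal(sample_density(g, "o", c(0, 0)), 1)
  expect_equal(up, 1)   # uptake of the post-update density over dt
  # zero rates leave the grid unchanged
  before <- density_array(g, "o")
  apply_sources_sinks(g, "o", rbind(c(0, 0)), 0, 0, 0, dt = 5)
  expect_identical(density_array(g, "o"), before)
  # a saturating source approaches and never exceeds its target
  for (i in 1:50) {
    apply_sources_sinks(g, "o", rbind(c(0, 0)), secretion = 10,
                        uptake = 0, saturation = 5, dt = 10)
    expect_lte(sample_density(g, "o", c(0, 0)), 5)
  }
  expect_equal(sample_density(g, "o", c(0, 0)), 5, tolerance = 1e-3)
  expect_error(apply_sources_sinks(g, "o", rbind(c(999, 0)), 0, 1, 0, 1),
               "outside")
})

test_that("injection schedules gate the Dirichlet rim", {
  cont <- injection_schedule("continuous", 0.5)
  expect_equal(schedule_value(cont, 0), 0.5)
  expect_equal(schedule_value(cont, 1e5), 0.5)
  pulsed <- injection_schedule("pulsed", 0.5, pulse_duration = 10, period = 150)
  expect_equal(schedule_value(pulsed, 0), 0.5)
  expect_equal(schedule_value(pulsed, 9.9), 0.5)
  expect_equal(schedule_value(pulsed, 20), 0)
  expect_equal(schedule_value(pulsed, 155), 0.5)
  stp <- injection_schedule("stop_at", 0.5, switch_time = 600)
  expect_equal(schedule_value(stp, 599), 0.5)
  expect_equal(schedule_value(stp, 601), 0)
  step <- injection_schedule("step_change", 0.5, switch_time = 600,
                             new_concentration = 5)
  expect_equal(schedule_value(step, 599), 0.5)
  expect_equal(schedule_value(step, 601), 5)
  expect_true(is.na(schedule_value(injection_schedule("none"), 3)))
  expect_error(injection_schedule("pulsed", 1, pulse_duration = 20, period = 10),
               "pulse_duration")
  expect_error(injection_schedule("stop_at", 1, switch_time = -5), "switch_time")

  g <- voxel_grid(c(-60, 60), dx = 20, ndim = 2)
  add_substrate(g, "TNF", D = 1200, decay = 0.0275)
  apply_injection(g, "TNF", cont, 0)
  expect_equal(sample_density(g, "TNF", c(-55, 0)), 0.5)
  # rim value persists through diffusion substeps while the schedule is on
  diffuse_decay(g, "TNF", dt = 0.01, nsub = 100)
  expect_equal(sample_density(g, "TNF", c(-55, 0)), 0.5)
  expect_gt(sample_density(g, "TNF", c(0, 0)), 0)
  # off: rim drops to zero and the substrate washes out
  apply_injection(g, "TNF", injection_schedule("stop_at", 0.5,
                                               switch_time = 10), 20)
  expect_equal(sample_density(g, "TNF", c(-55, 0)), 0)
})

test_that("the ECM density never diffuses and clamps to its ceiling", {
  g <- voxel_grid(c(-30, 30), dx = 20, ndim = 2)
  add_substrate(g, "ecm", D = 0, decay = 0, diffusing = FALSE, initial = 1,
                max_density = 1.2)
  before <- density_array(g, "ecm")
  diffuse_decay(g, "ecm", dt = 1, nsub = 100)
  expect_identical(density_array(g, "ecm"), before)
  ecm_modify(g, "ecm", rbind(c(0, 0)), degrade = 0.1, deposit = 0, dt = 1)
  expect_equal(sample_density(g, "ecm", c(0, 0)), 0.9)
  ecm_modify(g, "ecm", rbind(c(0, 0)), degrade = 0, deposit = 100, dt = 1)
  expect_equal(sample_density(g, "ecm", c(0, 0)), 1.2)
  ecm_modify(g, "ecm", rbind(c(0, 0)), degrade = 1e6, deposit = 0, dt = 1)
  expect_equal(sample_density(g, "ecm", c(0, 0)), 0)
  g2 <- voxel_grid(c(-30, 30), dx = 20, ndim = 2)
  add_substrate(g2, "d", D = 10, decay = 0)
  expect_error(ecm_modify(g2, "d", rbind(c(0, 0)), 0.1), "non-diffusing")
})
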