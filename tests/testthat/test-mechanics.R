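strains1 <- list(strain_params("WT"))

test_that("pairwise force: range, boundary and antisymmetry", {
  a <- list(pos = c(0, 0), radius = 8.4)
  b <- list(pos = c(30, 0), radius = 8.4)
  expect_equal(pairwise_force(a, b, strains1), c(0, 0, 0))  # beyond f*R
  # at contact distance d = R the repulsion term is exactly 0: pure adhesion
  b$pos <- c(16.8, 0)
  f <- pairwise_force(a, b, strains1)
  expect_gt(f[1], 0)   # attractive: a is pulled toward b (+x)
  q <- 1 - 16.8 / (1.25 * 16.8)
  expect_equal(f[1], 0.4 * q^2)
  # antisymmetry at random separations
  rng <- bc_rng(4)
  for (i in 1:20) {
    b$pos <- c(rng_unif(rng) * 25, rng_unif(rng) * 25)
    fa <- pairwise_force(a, b, strains1)
    fb <- pairwise_force(b, a, strains1)
    expect_equal(fa, -fb)
  }
  # coincident centres: deterministic +x push, never NaN
  b$pos <- c(0, 0)
  f0 <- pairwise_force(a, b, strains1)
  expect_false(any(is.nan(f0)))
  expect_gt(f0[1], 0)
  expect_equal(f0[2:3], c(0, 0))
})

test_that("two cells relax to the force-law equilibrium spacing", {
  p <- cell_population(strains1, ndim = 2, seed = 1)
  add_cells(p, x = c(0, 12), y = c(0, 0))
  for (i in 1:600) {
    integrate_motion(p, compute_forces(p, "allpairs"), NULL, 0.1)
  }
  d <- abs(p$x[1] - p$x[2])
  R <- sum(p$radius)
  root <- uniroot(function(d) 10 * (1 - d / R)^2 - 0.4 * (1 - d / (1.25 * R))^2,
                  c(0.5 * R, R))$root
  expect_lt(abs(d - root) / root, 0.005)
})

test_that("hash and all-pairs forces agree exactly on 200 cells", {
  p <- cell_population(list(strain_params("A"),
                            strain_params("B", adhesion_homotypic = 1.1,
                                          repulsion = 7)),
                       ndim = 3, seed = 2)
  rng <- bc_rng(5)
  add_cells(p, x = rng_unif(rng, 180) * 200 - 100,
            y = rng_unif(rng, 180) * 200 - 100,
            z = rng_unif(rng, 180) * 200 - 100,
            strain = rep(1:2, 90))
  add_spheres(p, x = rng_unif(rng, 20) * 200 - 100,
              y = rng_unif(rng, 20) * 200 - 100,
              z = rng_unif(rng, 20) * 200 - 100)
  expect_identical(compute_forces(p, "allpairs"), compute_forces(p, "hash"))
})

test_that("motion integration: statics, third law, pinned spheres", {
  p <- cell_population(strains1, ndim = 2, seed = 1)
  add_cells(p, x = c(0, 100), y = c(0, 0))   # out of range: no forces
  x0 <- p$x
  integrate_motion(p, compute_forces(p), NULL, 0.1)
  expect_identical(p$x, x0)
  # equal drags: the centroid of an interacting pair is invariant
  p2 <- cell_population(strains1, ndim = 2, seed = 1)
  add_cells(p2, x = c(0, 12), y = c(0, 0))
  cen0 <- mean(p2$x)
  for (i in 1:100) integrate_motion(p2, compute_forces(p2), NULL, 0.1)
  expect_equal(mean(p2$x), cen0, tolerance = 1e-12)
  # pinned spheres do not move when pushed
  p3 <- cell_population(strains1, ndim = 2, seed = 1)
  add_cells(p3, x = 0, y = 0)
  add_spheres(p3, x = 10, y = 0, pinned = TRUE)
  for (i in 1:50) integrate_motion(p3, compute_forces(p3), NULL, 0.1)
  expect_equal(p3$x[2], 10)
  expect_equal(p3$y[2], 0)
})

test_that("polarity: zero speed, ballistic limit, Fuerth MSD", {
  st <- strain_params("m", motility_speed = 0, persistence_time = 10)
  p <- cell_population(list(st), ndim = 2, seed = 3)
  add_cells(p, x = 0, y = 0)
  expect_equal(update_polarity_motility(p, 0.1), matrix(0, 1, 3))
  # tau = Inf: polarity never changes
  st2 <- strain_params("b", motility_speed = 1, persistence_time = Inf)
  p2 <- cell_population(list(st2), ndim = 2, seed = 3)
  add_cells(p2, x = 0, y = 0)
  pol0 <- c(p2$px, p2$py)
  for (i in 1:100) update_polarity_motility(p2, 0.1)
  expect_identical(c(p2$px, p2$py), pol0)
  # persistent random walk: MSD matches 2 v^2 tau (t - tau(1-exp(-t/tau)))
  v <- 2; tau <- 5; tmax <- 60; dt <- 0.1
  nrep <- 400
  msd <- vapply(seq_len(nrep), function(r) {
    st3 <- strain_params("w", motility_speed = v, persistence_time = tau)
    pp <- cell_population(list(st3), ndim = 2, seed = r)
    add_cells(pp, x = 0, y = 0)
    for (i in seq_len(tmax / dt)) {
      Fm <- update_polarity_motility(pp, dt)
      integrate_motion(pp, matrix(0, 1, 3), Fm, dt)
    }
    pp$x^2 + pp$y^2
  }, 1.0)
  expected <- 2 * v^2 * tau * (tmax - tau * (1 - exp(-tmax / tau)))
  expect_lt(abs(mean(msd) - expected) / expected, 0.10)
})

test_that("passive spheres degrade on contact and leave tracks", {
  st <- strain_params("d", ecm_degrade_rate = 0.1)
  p <- cell_population(list(st), ndim = 2, seed = 1)
  add_cells(p, x = 0, y = 0)
  add_spheres(p, x = c(5, 50), y = c(0, 0), radius = 8)
  degrade_passive_spheres(p, dt = 1)
  expect_equal(p$radius[p$type == 1L], c(7.9, 8))  # no contact: unchanged
  # continued contact removes the sphere
  for (i in 1:100) degrade_passive_spheres(p, dt = 1)
  expect_equal(sum(p$type == 1L), 1L)
  expect_equal(p$n_removed, 1L)
})
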