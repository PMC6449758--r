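test_that("transition rate follows the up/down/at-target rule", {
  net <- parse_network(
    "A { is_input = TRUE; }
     B { logic = A; rate_up = 2; rate_down = 1; }", "")
  expect_equal(transition_rate(net, network_state(net, "A"), "B"), 2)
  expect_equal(transition_rate(net, network_state(net), "B"), 0)
  expect_equal(transition_rate(net, network_state(net, "B"), "B"), 1)
  expect_error(transition_rate(net, network_state(net), "A"), "input")
})

test_that("absorbing states are fixed points of step and advance", {
  net <- one_node_net(u = 3)
  s_on <- network_state(net, "A")   # logic=1, A=1: no transitions
  st <- gillespie_step(net, s_on, bc_rng(1))
  expect_identical(as.integer(st$state), as.integer(s_on))
  expect_identical(st$wait, Inf)
  for (w in c(0, 5, 500)) {
    expect_identical(as.integer(advance(net, s_on, w, bc_rng(2))),
                     as.integer(s_on))
  }
})

test_that("waiting times are exponential with the exit rate", {
  u <- 0.8
  net <- one_node_net(u = u)
  rng <- bc_rng(42)
  waits <- vapply(1:10000, function(i)
    gillespie_step(net, network_state(net), rng)$wait, 1.0)
  se <- sd(waits) / sqrt(length(waits))
  expect_lt(abs(mean(waits) - 1 / u), 3 * se)
})

test_that("competing transitions fire proportionally to their rates", {
  net <- fork_net(a = 2, b = 1)
  rng <- bc_rng(7)
  s0 <- network_state(net, "X")
  first_a <- vapply(1:4000, function(i) {
    st <- gillespie_step(net, s0, rng)
    st$state[["A"]]
  }, 1L)
  phat <- mean(first_a)
  expect_lt(abs(phat - 2 / 3), 3 * sqrt(2 / 9 / 4000))
})

test_that("advance matches the closed-form one-node CTMC", {
  u <- 0.5
  net <- one_node_net(u = u)
  for (t in c(0.5, 2)) {
    on <- vapply(1:4000, function(i)
      advance(net, network_state(net), t, bc_rng(i))[["A"]], 1L)
    p <- 1 - exp(-u * t)
    expect_lt(abs(mean(on) - p), 3 * sqrt(p * (1 - p) / 4000))
  }
  # window 0 is the identity
  expect_identical(as.integer(advance(net, network_state(net), 0, bc_rng(1))),
                   0L)
})

test_that("trajectories are asynchronous and seed-deterministic", {
  net <- feedback_net()
  rng <- bc_rng(9)
  s <- network_state(net)
  for (i in 1:200) {
    st <- gillespie_step(net, s, rng)
    if (!is.finite(st$wait)) break
    expect_equal(sum(abs(as.integer(st$state) - as.integer(s))), 1)
    s <- st$state
  }
  a <- advance(net, network_state(net), 50, bc_rng(123))
  b <- advance(net, network_state(net), 50, bc_rng(123))
  expect_identical(a, b)
  # ensembles too
  f1 <- ensemble_fates(net, 10, 100, seed = 5)
  f2 <- ensemble_fates(net, 10, 100, seed = 5)
  expect_identical(f1$prob, f2$prob)
})

test_that("empirical state distributions match the master equation", {
  n <- 10000
  for (make in list(function() fork_net(2, 1), feedback_net)) {
    net <- make()
    for (t in c(0.8, 2.5)) {
      exact <- master_equation_dist(net, t)
      emp <- empirical_state_dist(net, t, n, seed = 31)
      tol <- 3 * sqrt(exact * (1 - exact) / n) + 1 / n
      expect_true(all(abs(emp - exact) <= tol),
                  label = sprintf("CTMC oracle at t=%g (max dev %.4g)", t,
                                  max(abs(emp - exact) - tol)))
    }
  }
})

test_that("fate classification uses the documented priority and sums to 1", {
  net <- parse_network(
    "Apoptosis { logic = 1; rate_up = 10; rate_down = 0; }
     NonACD { logic = 1; rate_up = 10; rate_down = 0; }
     Survival { logic = 1; rate_up = 10; rate_down = 0; }")
  fd <- ensemble_fates(net, 100, 500, seed = 2)
  # all three active at the horizon: Apoptosis wins the tie-break
  expect_equal(unname(fd$prob[["Apoptosis"]]), 1)
  expect_equal(sum(fd$prob), 1, tolerance = 1e-12)
})

test_that("a single always-on read-out gets probability 1", {
  net <- one_node_net(u = 50)
  fd <- ensemble_fates(net, 10, 300, seed = 3, readouts = "A")
  expect_equal(unname(fd$prob[["A"]]), 1)
  expect_equal(fd$n, 300)
})

test_that("fate tables round-trip to CSV", {
  net <- fork_net()
  fd <- ensemble_fates(net, 50, 200, seed = 1, readouts = c("A", "B"))
  path <- withr::local_tempfile(fileext = ".csv")
  write_fates_csv(fd, path)
  df <- read.csv(path)
  expect_named(df, c("fate", "probability", "n"))
  expect_equal(sum(df$probability), 1, tolerance = 1e-12)
})
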