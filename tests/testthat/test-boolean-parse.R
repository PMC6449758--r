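test_that("minimal model and config parse, rate symbols resolve", {
  net <- parse_network("A { logic = 1; rate_up = $u; rate_down = 0; }",
                       "$u = 0.5;")
  expect_s3_class(net, "boolean_network")
  expect_equal(length(net), 1L)
  expect_equal(net$rate_up, 0.5)
  expect_equal(net$rate_down, 0)
})

test_that("parser validation errors name the offender", {
  expect_error(parse_network("A { logic = Z; rate_up = 1; }"), "Z")
  expect_error(parse_network("A { logic = 1; rate_up = $u; }"), "\\$u")
  expect_error(parse_network("A { logic = 1; } A { logic = 0; }"),
               "duplicate")
  expect_error(parse_network("A { weird = 1; }"), "weird")
  expect_error(parse_network("A { logic = 1; }", "A.istate = 2;"), "istate")
})

test_that("logic operators, keywords and parentheses are equivalent", {
  m1 <- parse_network(
    "A { is_input = TRUE; } B { is_input = TRUE; }
     C { logic = (A & !B) | B; rate_up = 1; rate_down = 1; }")
  m2 <- parse_network(
    "A { is_input = TRUE; } B { is_input = TRUE; }
     C { logic = (A AND NOT B) OR B; rate_up = 1; rate_down = 1; }")
  expect_identical(m1$code, m2$code)
  for (vals in list(c(0, 0), c(0, 1), c(1, 0), c(1, 1))) {
    s <- network_state(m1, c(A = vals[1], B = vals[2]))
    r <- transition_rate(m1, s, "C")
    expect_identical(r, transition_rate(m2, s, "C"))
  }
})

test_that("config flags drive internal/input/istate", {
  net <- parse_network(
    "A { logic = 1; rate_up = 1; } B { logic = A; rate_up = 1; }",
    "A.is_input = TRUE; B.is_internal = TRUE; B.istate = 0.25;")
  expect_true(net$is_input[1])
  expect_true(net$is_internal[2])
  expect_equal(net$istate[2], 0.25)
})

test_that("the bundled cell-fate fixture parses with the three read-outs", {
  net <- build_cell_fate_network()
  readouts <- net$nodes[!net$is_internal & !net$is_input]
  expect_setequal(readouts, c("Survival", "Apoptosis", "NonACD"))
  expect_true(all(c("mXIAP", "mROS") %in% net$nodes))
  expect_equal(net$nodes[net$is_input], "TNF")
  # mRNA rates scale with the transcription multiplier
  net5 <- build_cell_fate_network(1.0)
  i <- net$index[["mXIAP"]]
  expect_equal(net5$rate_up[i] / net$rate_up[i], 5)
})

test_that("rate overrides replace rates, leave logic, compose left-to-right", {
  net <- parse_network(
    "A { logic = 1; rate_up = 1; rate_down = 1; }
     B { logic = A; rate_up = 2; rate_down = 2; }")
  ov <- apply_overrides(net, list(rate_override("B", rate_up = 5),
                                  rate_override("B", rate_down = 7),
                                  rate_override("B", rate_up = 9)))
  expect_equal(ov$rate_up[2], 9)
  expect_equal(ov$rate_down[2], 7)
  expect_identical(ov$code, net$code)
  # identity and error cases
  expect_identical(apply_overrides(net, list()), net)
  expect_error(apply_overrides(net, list(rate_override("Q", 1))), "Q")
  expect_error(rate_override("A"), "at least one")
})

test_that("over-expression pins a node at 1 within a minute, knockout at 0", {
  net <- parse_network(
    "X { is_input = TRUE; }
     A { logic = X; rate_up = 0.1; rate_down = 0.1; }")
  oe <- apply_overrides(net, overexpress("A"))
  # logic says A should be 0 (X = 0), but the huge up-rate wins
  n_on <- 0
  for (i in 1:200) {
    s <- advance(oe, network_state(oe), 1, bc_rng(i))
    n_on <- n_on + s[["A"]]
  }
  expect_gte(n_on, 200 * 0.999)
  ko <- apply_overrides(net, knockout("A"))
  s0 <- network_state(ko, c(X = 1, A = 1))
  n_off <- 0
  for (i in 1:200) {
    s <- advance(ko, s0, 1, bc_rng(i))
    n_off <- n_off + (1 - s[["A"]])
  }
  expect_gte(n_off, 200 * 0.999)
})
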