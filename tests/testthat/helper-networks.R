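# small fixture networks built in code

one_node_net <- function(u = 0.5, down = 0) {
  parse_network(sprintf("A { logic = 1; rate_up = %g; rate_down = %g; }",
                        u, down))
}

# competing activation fork driven by a pinned input
fork_net <- function(a = 2, b = 1) {
  parse_network(sprintf(
    "X { is_input = TRUE; }
     A { logic = X & !B; rate_up = %g; rate_down = 0; }
     B { logic = X & !A; rate_up = %g; rate_down = 0; }", a, b),
    "X.istate = 1;")
}

# 4-node feedback network with asymmetric rates (CTMC oracle fixture)
feedback_net <- function() {
  parse_network(
    "A { logic = !B; rate_up = 0.7; rate_down = 0.3; }
     B { logic = A;  rate_up = 1.2; rate_down = 0.4; }
     C { logic = A & B; rate_up = 0.5; rate_down = 0.9; }
     D { logic = A | C; rate_up = 0.25; rate_down = 0.6; }")
}

empirical_state_dist <- function(net, horizon, n, seed) {
  fd <- ensemble_fates(net, horizon, n, seed)
  k <- length(net$nodes)
  key <- apply(fd$final_states, 1, paste, collapse = "")
  tab <- table(key) / n
  all_keys <- vapply(seq_len(2^k) - 1L, function(q)
    paste(as.integer(bitwAnd(bitwShiftR(q, seq_len(k) - 1L), 1L)),
          collapse = ""), "")
  p <- setNames(numeric(length(all_keys)), all_keys)
  p[names(tab)] <- as.numeric(tab)
  p
}

# small coupled-run config used by several tests
tiny_monolayer_config <- function(seed = 1, t_end = 60, network = NULL,
                                  substrates = list(), ...) {
  positions <- data.frame(type = "cell", strain = 1L,
                          x = c(-20, 0, 20, 0), y = c(0, -20, 0, 20),
                          z = 0, radius = 8.4)
  sim_config(strains = strain_params("WT"), positions = positions,
             network = network, substrates = substrates,
             bounds = c(-100, 100), dx = 20, ndim = 2,
             clock = clock_config(dt_diffusion = 0.1, dt_mechanics = 0.1,
                                  dt_signalling = 10, t_end = t_end,
                                  snapshot_interval = 30),
             seed = seed, ...)
}
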