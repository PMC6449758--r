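# Continuous-time stochastic simulation of Boolean networks (asynchronous
# Gillespie kernel).  The network defines, in every state, one candidate
# transition per non-input node: a node whose logic evaluates to 1 while the
# node is 0 may flip up at rate_up, and symmetrically down at rate_down.
# Waiting times are exponential in the total exit rate; exactly one node
# flips per event.

.bn_check_state <- function(net, state) {
  if (length(state) != length(net$nodes))
    stop("state length (", length(state), ") does not match node count (",
         length(net$nodes), ")", call. = FALSE)
  as.integer(state)
}

#' Transition rate of one node in a state
#'
#' Returns `rate_up` if the node's logic evaluates to 1 while the node is 0,
#' `rate_down` if the logic is 0 while the node is 1, and 0 when the node
#' already sits at its target value.  Input nodes have no transitions (they
#' are pinned by the coupling layer) and asking for their rate is an error.
#'
#' @param net a `boolean_network`.
#' @param state a state vector (see [network_state()]).
#' @param node node name.
#' @return rate in 1/min.
#' @export
transition_rate <- function(net, state, node) {
  i <- net$index[[node]]
  if (is.null(i)) stop("unknown node '", node, "'", call. = FALSE)
  if (net$is_input[i])
    stop("node '", node, "' is an input node: it is pinned by the coupling ",
         "layer and has no transitions", call. = FALSE)
  s <- .bn_check_state(net, state)
  r <- cpp_transition_rates(net$flat$code, net$flat$off, net$flat$len,
                            net$rate_up, net$rate_down,
                            as.integer(net$is_input), s)
  r[i]
}

# all-node transition rates (0 for inputs); internal use and tests
transition_rates <- function(net, state) {
  s <- .bn_check_state(net, state)
  setNames(cpp_transition_rates(net$flat$code, net$flat$off, net$flat$len,
                                net$rate_up, net$rate_down,
                                as.integer(net$is_input), s),
           net$nodes)
}

#' One Gillespie step
#'
#' Draws an exponential waiting time from the total exit rate and flips one
#' node chosen with probability proportional to its rate.  In an absorbing
#' state (zero exit rate) the state is returned unchanged with `wait = Inf`.
#'
#' @inheritParams transition_rate
#' @param rng a [bc_rng()] stream (advanced in place).
#' @return list with `state` (new state, one bit flipped) and `wait` (min).
#' @export
gillespie_step <- function(net, state, rng) {
  s <- .bn_check_state(net, state)
  out <- cpp_gillespie_step(net$flat$code, net$flat$off, net$flat$len,
                            net$rate_up, net$rate_down,
                            as.integer(net$is_input), s, rng$state)
  st <- setNames(out$state, net$nodes)
  class(st) <- "network_state"
  list(state = st, wait = out$wait)
}

#' Advance a network state over a time window
#'
#' Repeatedly applies Gillespie steps until the cumulative waiting time
#' exceeds `window`; returns the state occupied at the window end.
#' Deterministic given the stream.
#'
#' @inheritParams gillespie_step
#' @param window time window in minutes (>= 0).
#' @return the state at `window`.
#' @export
advance <- function(net, state, window, rng) {
  stopifnot(window >= 0)
  s <- .bn_check_state(net, state)
  out <- cpp_advance(net$flat$code, net$flat$off, net$flat$len,
                     net$rate_up, net$rate_down,
                     as.integer(net$is_input), s, window, rng$state)
  st <- setNames(out, net$nodes)
  class(st) <- "network_state"
  st
}

# canonical read-out priority when several read-outs are simultaneously
# active: death read-outs are irreversible, apoptosis commits fastest
.BC_FATE_PRIORITY <- c("Apoptosis", "NonACD", "Survival")

# classify final states into fate labels by read-out priority
classify_fates <- function(net, finals, readouts = NULL) {
  if (is.null(readouts)) {
    readouts <- net$nodes[!net$is_internal & !net$is_input]
    if (!length(readouts)) readouts <- net$nodes[!net$is_input]
  }
  pri <- c(intersect(.BC_FATE_PRIORITY, readouts),
           setdiff(readouts, .BC_FATE_PRIORITY))
  labels <- rep("None", nrow(finals))
  for (r in rev(pri)) {
    labels[finals[, net$index[[r]]] == 1] <- r
  }
  factor(labels, levels = c(pri, "None"))
}

#' Ensemble fate probabilities
#'
#' Runs `n` independent trajectories from the network's initial-state
#' distribution (independent per-node Bernoulli probabilities, overridable)
#' and classifies each trajectory by which read-out node is active at the
#' horizon.  When several read-outs are active at once, classification
#' follows the fixed priority Apoptosis > NonACD > Survival (then any other
#' read-outs in declaration order); trajectories with no active read-out are
#' labelled "None".
#'
#' @inheritParams transition_rate
#' @param horizon simulation horizon in minutes.
#' @param n number of trajectories (>= 1).
#' @param seed integer seed (per-trajectory sub-streams are derived from it,
#'   so results do not depend on scheduling order).
#' @param inputs named vector fixing input-node values (e.g. `c(TNF = 1)`).
#' @param istate named vector of initial activation probabilities overriding
#'   the config's.
#' @param readouts read-out node names (default: all non-internal,
#'   non-input nodes).
#' @param track optional node names whose first-activation times are
#'   recorded per trajectory.
#' @return object of class `fate_distribution`: list with `prob` (named,
#'   sums to 1), `n`, and `first_times` (matrix, Inf where never active)
#'   when `track` is given.
#' @export
ensemble_fates <- function(net, horizon, n, seed, inputs = NULL, istate = NULL,
                           readouts = NULL, track = NULL) {
  stopifnot(inherits(net, "boolean_network"), n >= 1, horizon >= 0)
  p0 <- net$istate
  if (!is.null(istate)) {
    idx <- match(names(istate), net$nodes)
    if (anyNA(idx)) stop("istate names unknown node(s)", call. = FALSE)
    p0[idx] <- as.numeric(istate)
  }
  if (!is.null(inputs)) {
    idx <- match(names(inputs), net$nodes)
    if (anyNA(idx)) stop("inputs name unknown node(s)", call. = FALSE)
    if (!all(net$is_input[idx]))
      stop("'inputs' may only set input nodes", call. = FALSE)
    p0[idx] <- as.numeric(inputs)
  }
  track_idx <- integer(0)
  if (!is.null(track)) {
    track_idx <- match(track, net$nodes)
    if (anyNA(track_idx)) stop("track names unknown node(s)", call. = FALSE)
  }
  out <- cpp_ensemble(net$flat$code, net$flat$off, net$flat$len,
                      net$rate_up, net$rate_down, as.integer(net$is_input),
                      p0, horizon, as.integer(n), as.double(seed),
                      as.integer(track_idx - 1L))
  labels <- classify_fates(net, out$final_states, readouts)
  prob <- table(labels) / n
  ft <- out$first_times
  if (length(track_idx)) colnames(ft) <- track
  res <- list(prob = c(prob), n = n,
              first_times = if (length(track_idx)) ft else NULL,
              final_states = out$final_states,
              nodes = net$nodes)
  class(res) <- "fate_distribution"
  res
}

#' @export
print.fate_distribution <- function(x, ...) {
  cat("Fate distribution over", x$n, "trajectories:\n")
  print(round(x$prob, 4))
  invisible(x)
}

#' @export
as.data.frame.fate_distribution <- function(x, ...) {
  data.frame(fate = names(x$prob), probability = as.numeric(x$prob),
             n = x$n, row.names = NULL)
}

#' Write an ensemble fate table as CSV
#'
#' Columns: fate, probability, n.
#'
#' @param fd a `fate_distribution`.
#' @param path output file.
#' @export
write_fates_csv <- function(fd, path) {
  write.csv(as.data.frame(fd), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Master-equation distribution (matrix-exponential oracle)
#'
#' Builds the 2^k-state master equation of the continuous-time Markov chain
#' defined by the network's transitions and returns the exact state
#' distribution at time `t` via the matrix exponential.  Intended as an
#' independent cross-check of the Gillespie kernel; practical only for small
#' networks (<= ~12 non-input nodes).
#'
#' @inheritParams transition_rate
#' @param t time in minutes.
#' @param init_state optional initial state (default: the network's
#'   initial-state distribution).
#' @return named numeric vector of probabilities over all 2^k states; names
#'   are the state bit-strings in node order.
#' @export
master_equation_dist <- function(net, t, init_state = NULL) {
  if (!requireNamespace("Matrix", quietly = TRUE))
    stop("the Matrix package is required for master_equation_dist")
  k <- length(net$nodes)
  if (k > 14) stop("network too large for the dense master equation")
  nstates <- 2L^k
  # enumerate states: state id q has bit j = node j value
  bits <- function(q) as.integer(bitwAnd(bitwShiftR(q, seq_len(k) - 1L), 1L))
  Q <- matrix(0, nstates, nstates)
  for (q in seq_len(nstates) - 1L) {
    s <- bits(q)
    r <- cpp_transition_rates(net$flat$code, net$flat$off, net$flat$len,
                              net$rate_up, net$rate_down,
                              as.integer(net$is_input), s)
    for (j in seq_len(k)) {
      if (r[j] > 0) {
        q2 <- bitwXor(q, bitwShiftL(1L, j - 1L))
        Q[q + 1L, q2 + 1L] <- r[j]
      }
    }
  }
  diag(Q) <- -rowSums(Q)
  p0 <- numeric(nstates)
  if (is.null(init_state)) {
    # product of independent Bernoulli istate probabilities
    for (q in seq_len(nstates) - 1L) {
      s <- bits(q)
      p0[q + 1L] <- prod(ifelse(s == 1, net$istate, 1 - net$istate))
    }
  } else {
    s <- .bn_check_state(net, init_state)
    q <- sum(bitwShiftL(s, seq_len(k) - 1L))
    p0[q + 1L] <- 1
  }
  pt <- as.numeric(p0 %*% as.matrix(Matrix::expm(Matrix::Matrix(Q * t))))
  names(pt) <- vapply(seq_len(nstates) - 1L,
                      function(q) paste(bits(q), collapse = ""), "")
  pt
}
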