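#' Brute-force oracles for the minimax control problem
#'
#' Independent reference solvers for small instances, used to verify the
#' dynamic program.
#'
#' `game_tree_value()` evaluates the minimax recursion
#' `V(z, t) = C(z)` if `t = M`, else `min_u max_{z' in F(z,u)} V(z', t+1)`
#' by plain memoisation-free recursion over the game tree; it equals the
#' [minimax_dp()] value exactly.
#'
#' `open_loop_bruteforce()` enumerates every fixed control sequence
#' `(u_0, ..., u_{M-1})`, propagates the set of possible states forward,
#' and returns the smallest worst-case terminal cost. Because an open-loop
#' controller cannot react to the realised trajectory, its value is always
#' at least the feedback (DP) value, with equality for deterministic
#' single-constituent networks.
#'
#' @param model A [transition_model()].
#' @param M Horizon.
#' @param z0 Initial state.
#' @param cost Terminal cost (see [minimax_dp()]).
#' @param states State set (defaults to all states).
#' @param max_nodes Guard on the game-tree size.
#' @return A single numeric value.
#' @export
game_tree_value <- function(model, M, z0, cost = "identity", states = NULL,
                            max_nodes = 1e7) {
  stopifnot(inherits(model, "pbn_tm"))
  S <- 2^model$n
  if (is.null(states)) states <- seq_len(S)
  states <- sort(unique(as.integer(states)))
  cvec <- terminal_cost_vector(cost, S)
  U <- 2^model$m
  maxF <- max(vapply(seq_len(U), function(u) {
    max(vapply(states, function(z) length(reachable_set(model, z, u)), integer(1)))
  }, integer(1)))
  if ((U * maxF)^M > max_nodes) {
    stop_too_large("game tree of up to (%d*%d)^%d nodes exceeds the guard", U, maxF, M)
  }
  recurse <- function(z, t) {
    if (t == M) {
      return(cvec[z])
    }
    best <- Inf
    for (u in seq_len(U)) {
      succ <- reachable_set(model, z, u)
      worst <- -Inf
      for (zp in succ) {
        v <- recurse(zp, t + 1)
        if (v > worst) worst <- v
      }
      if (worst < best) best <- worst
    }
    best
  }
  recurse(as.integer(z0), 0L)
}

#' @rdname game_tree_value
#' @export
open_loop_bruteforce <- function(model, M, z0, cost = "identity") {
  stopifnot(inherits(model, "pbn_tm"))
  S <- 2^model$n
  cvec <- terminal_cost_vector(cost, S)
  U <- 2^model$m
  if (model$m * M > 20) {
    stop_too_large("open-loop enumeration limited to m*M <= 20 (got %d)", model$m * M)
  }
  nseq <- U^M
  best <- Inf
  for (s in 0:(nseq - 1)) {
    us <- (s %/% U^(0:(M - 1))) %% U + 1 # u_0 ... u_{M-1}
    reach <- logical(S)
    reach[z0] <- TRUE
    for (t in seq_len(M)) {
      cur <- which(reach)
      reach <- logical(S)
      for (z in cur) {
        reach[reachable_set(model, z, us[t])] <- TRUE
      }
    }
    worst <- max(cvec[reach])
    if (worst < best) best <- worst
  }
  best
}
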