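#' Minimax optimal control by backward dynamic programming
#'
#' Solves the worst-case terminal-cost control problem: starting from `z0`,
#' choose controls `u_0, ..., u_{M-1}` so that the maximum possible terminal
#' cost `C(z_M)` over all trajectories the PBN may follow is minimised. The
#' backward recursion is
#' `J_M(z) = C(z)`,
#' `J_t(z) = min_u max_{z' in F(z, u)} J_{t+1}(z')`,
#' where `F(z, u)` is the one-step reachable set under the unperturbed
#' dynamics. Ties in the minimising control go to the smallest control
#' index; successors are scanned in ascending state order.
#'
#' When `states` is a reduced state set, costs are still indexed by the
#' *original* state labels, and the solver verifies that no reachable set
#' escapes `states` (raising an error that signals an unsound reduction).
#'
#' With a `switch_budget` `H`, the controller may change its control value
#' at most `H` times over the horizon (the first choice is free); the
#' recursion then runs over (state, remaining switches, previous control).
#' `H >= M - 1` reproduces the unconstrained solution.
#'
#' @param model A [transition_model()].
#' @param M Horizon (number of control steps, `>= 1`).
#' @param z0 Initial state.
#' @param cost `"identity"` for `C(z) = z`, or a numeric vector of length
#'   `2^n` giving the terminal cost of each original state.
#' @param states State set to solve on: defaults to all `2^n` states; pass
#'   `reduce_network(...)$kept` to solve on the reduced network.
#' @param switch_budget Optional maximum number of control changes.
#' @return An object of class `minimax_solution`: `value` (the minimax
#'   cost `J_0(z0)`), `J` (value table, states x times `0..M`), `policy`
#'   (states x times `0..M-1`), `states`, `z0`, `M`, and the worst-case
#'   rollout (`trajectory`, `controls`).
#' @examples
#' # gene copies the control bit: any horizon drives the state to 1
#' net <- pbn(list(list(boolean_function(2, c(0, 1)))), m = 1)
#' minimax_dp(transition_model(net), M = 3, z0 = 2)$value # 1
#' @export
minimax_dp <- function(model, M, z0, cost = "identity", states = NULL,
                       switch_budget = NULL) {
  stopifnot(inherits(model, "pbn_tm"))
  if (M < 1) stop_input("horizon `M` must be at least 1")
  S <- 2^model$n
  if (is.null(states)) states <- seq_len(S)
  states <- sort(unique(as.integer(states)))
  if (!(z0 %in% states)) stop_input("z0 = %d is not in the supplied state set", z0)
  cvec <- terminal_cost_vector(cost, S)[states]
  supp <- support_lists(model, states) # errors if reduction is unsound
  U <- 2^model$m
  ns <- length(states)
  if (!is.null(switch_budget)) {
    return(minimax_dp_budget(model, M, z0, cvec, states, supp, switch_budget))
  }
  J <- matrix(NA_real_, nrow = ns, ncol = M + 1)
  policy <- matrix(NA_integer_, nrow = ns, ncol = M)
  J[, M + 1] <- cvec
  for (t in M:1) {
    nxt <- J[, t + 1]
    for (zl in seq_len(ns)) {
      best <- Inf
      bu <- 1L
      for (u in seq_len(U)) {
        w <- max(nxt[supp[[u]][[zl]]])
        if (w < best) {
          best <- w
          bu <- u
        }
      }
      J[zl, t] <- best
      policy[zl, t] <- bu
    }
  }
  sol <- structure(
    list(
      value = J[match(z0, states), 1],
      J = J, policy = policy, states = states, z0 = as.integer(z0),
      M = as.integer(M), cost = cvec, switch_budget = NULL
    ),
    class = "minimax_solution"
  )
  ro <- rollout_worst_case(model, sol)
  sol$trajectory <- ro$trajectory
  sol$controls <- ro$controls
  sol
}

terminal_cost_vector <- function(cost, S) {
  if (identical(cost, "identity")) {
    return(as.numeric(seq_len(S)))
  }
  if (!is.numeric(cost) || length(cost) != S) {
    stop_input("`cost` must be \"identity\" or a numeric vector of length %d", S)
  }
  as.numeric(cost)
}

# Switch-budget variant: value tables indexed by (state, h, previous u).
# previous-control index U+1 means "no control chosen yet".
minimax_dp_budget <- function(model, M, z0, cvec, states, supp, H) {
  H <- as.integer(H)
  if (H < 0) stop_input("`switch_budget` must be nonnegative")
  U <- 2^model$m
  ns <- length(states)
  # J[[t]][zl, h+1, up] for t = 1..M+1
  Jt <- array(rep(cvec, (H + 1) * (U + 1)), dim = c(ns, H + 1, U + 1))
  Pt <- vector("list", M)
  for (t in M:1) {
    Jn <- array(Inf, dim = c(ns, H + 1, U + 1))
    Pn <- array(NA_integer_, dim = c(ns, H + 1, U + 1))
    for (up in seq_len(U + 1)) {
      for (h in 0:H) {
        for (zl in seq_len(ns)) {
          best <- Inf
          bu <- NA_integer_
          for (u in seq_len(U)) {
            switching <- up <= U && u != up
            h2 <- h - as.integer(switching)
            if (h2 < 0) next
            w <- max(Jt[supp[[u]][[zl]], h2 + 1, u])
            if (w < best) {
              best <- w
              bu <- u
            }
          }
          Jn[zl, h + 1, up] <- best
          Pn[zl, h + 1, up] <- bu
        }
      }
    }
    Jt <- Jn
    Pt[[t]] <- Pn
  }
  structure(
    list(
      value = Jt[match(z0, states), H + 1, U + 1],
      J_budget = Jt, policy_budget = Pt, states = states, z0 = as.integer(z0),
      M = as.integer(M), cost = cvec, switch_budget = H
    ),
    class = "minimax_solution"
  )
}

#' @export
print.minimax_solution <- function(x, ...) {
  cat(sprintf(
    "<minimax_solution> value %g over horizon M = %d from z0 = %d (%d states%s)\n",
    x$value, x$M, x$z0, length(x$states),
    if (is.null(x$switch_budget)) "" else sprintf(", switch budget %d", x$switch_budget)
  ))
  invisible(x)
}

#' Worst-case rollout of a minimax policy
#'
#' Follows the computed policy from `z0`, at each step moving to the
#' reachable successor with the largest next-stage value (ascending state
#' order breaks ties). The terminal cost along this trajectory equals the
#' solution's minimax value.
#'
#' @param model A [transition_model()].
#' @param solution A [minimax_dp()] solution (default mode).
#' @return A list with `trajectory` (states `z_0..z_M`), `controls`
#'   (`u_0..u_{M-1}`) and `cost`.
#' @export
rollout_worst_case <- function(model, solution) {
  stopifnot(inherits(solution, "minimax_solution"))
  if (!is.null(solution$switch_budget)) {
    stop_input("rollout is only implemented for the default (unbudgeted) mode")
  }
  states <- solution$states
  z <- solution$z0
  traj <- integer(solution$M + 1)
  ctrl <- integer(solution$M)
  traj[1] <- z
  for (t in seq_len(solution$M)) {
    zl <- match(z, states)
    u <- solution$policy[zl, t]
    succ <- reachable_set(model, z, u)
    nv <- solution$J[match(succ, states), t + 1]
    z <- succ[which.max(nv)]
    ctrl[t] <- u
    traj[t + 1] <- z
  }
  list(trajectory = traj, controls = ctrl, cost = solution$cost[match(z, states)])
}

#' @export
tidy.minimax_solution <- function(x, ...) {
  if (!is.null(x$switch_budget)) {
    stop_input("tidy() is only implemented for the default (unbudgeted) mode")
  }
  purrr::map_dfr(seq_len(x$M), function(step) {
    tibble(
      t = step - 1L, state = x$states,
      control = x$policy[, step], value = x$J[, step]
    )
  })
}

#' @export
glance.minimax_solution <- function(x, ...) {
  tibble(
    value = x$value, M = x$M, z0 = x$z0,
    n_states = length(x$states),
    switch_budget = if (is.null(x$switch_budget)) NA_integer_ else x$switch_budget
  )
}

#' @export
autoplot.minimax_solution <- function(object, ...) {
  if (!is.null(object$switch_budget)) {
    stop_input("autoplot() is only implemented for the default (unbudgeted) mode")
  }
  df <- purrr::map_dfr(seq_len(object$M + 1), function(step) {
    tibble(t = step - 1L, state = object$states, J = object$J[, step])
  })
  ggplot2::ggplot(df, ggplot2::aes(x = .data$t, y = factor(.data$state), fill = .data$J)) +
    ggplot2::geom_tile() +
    ggplot2::labs(
      x = "time step", y = "state", fill = "J(z, t)",
      title = "Minimax value table"
    )
}

#' Compare minimax control on the original and the reduced network
#'
#' Reduces the network (preserving attractors and `z0`), solves the minimax
#' problem on both state spaces, and reports both values. Whenever the
#' reduction is sound (no reachable set escapes the kept states) the two
#' values agree.
#'
#' @param x A [pbn()].
#' @param M Horizon.
#' @param z0 Initial state.
#' @param cost Terminal cost (see [minimax_dp()]).
#' @param xi Optional deletion threshold override.
#' @return A one-row tibble: sizes, values, `equal`, timings (seconds).
#' @export
compare_original_reduced <- function(x, M = 20, z0 = 1, cost = "identity", xi = NULL) {
  stopifnot(inherits(x, "pbn"))
  model <- transition_model(x)
  red <- reduce_network(model, z0 = z0, xi = xi)
  t_o <- system.time(sol_o <- minimax_dp(model, M, z0, cost))[["elapsed"]]
  t_r <- system.time(sol_r <- minimax_dp(model, M, z0, cost, states = red$kept))[["elapsed"]]
  tibble(
    size_original = 2^model$n,
    size_reduced = length(red$kept),
    value_original = sol_o$value,
    value_reduced = sol_r$value,
    equal = isTRUE(all.equal(sol_o$value, sol_r$value)),
    time_original = t_o,
    time_reduced = t_r
  )
}
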