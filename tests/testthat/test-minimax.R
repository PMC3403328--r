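test_that("minimax DP solves the hand-checked toys", {
  ctl <- transition_model(controllable_toy())
  for (M in 1:4) {
    sol <- minimax_dp(ctl, M = M, z0 = 2)
    expect_equal(sol$value, 1)
    expect_equal(unname(sol$policy[, M]), c(1L, 1L))
  }

  unc <- transition_model(uncontrollable_toy())
  expect_equal(minimax_dp(unc, M = 1, z0 = 1)$value, 2)
  expect_equal(minimax_dp(unc, M = 2, z0 = 1)$value, 1)

  # state never moves when every gene copies itself; control is unused
  idm <- transition_model(identity_bn(3, m = 1))
  expect_equal(minimax_dp(idm, M = 5, z0 = 5)$value, 5)

  # value settles once the controllability diameter is passed: gene1 follows
  # the control bit, gene2 follows gene1
  chain <- pbn(list(
    list(boolean_function(3, c(0, 1))),
    list(boolean_function(1, c(0, 1)))
  ), m = 1)
  cm <- transition_model(chain)
  vals <- vapply(2:6, function(M) minimax_dp(cm, M = M, z0 = 4)$value, numeric(1))
  expect_equal(vals, rep(1, 5))
})

test_that("DP value equals the game-tree oracle on random instances", {
  set.seed(31)
  for (rep in 1:60) {
    n <- sample(2:4, 1)
    m <- sample(1:2, 1)
    M <- sample(2:4, 1)
    net <- generate_random_pbn(n, m = m, N = sample(1:3, 1), K = 2)
    model <- transition_model(net)
    z0 <- sample(2^n, 1)
    sol <- minimax_dp(model, M = M, z0 = z0)
    expect_identical(sol$value, game_tree_value(model, M, z0))
  }
})

test_that("open-loop control never beats feedback, and matches it for deterministic BNs", {
  set.seed(32)
  for (rep in 1:20) {
    n <- sample(2:3, 1)
    net <- generate_random_pbn(n, m = 1, N = sample(1:3, 1), K = 2)
    model <- transition_model(net)
    M <- sample(2:4, 1)
    z0 <- sample(2^n, 1)
    fb <- minimax_dp(model, M = M, z0 = z0)$value
    ol <- open_loop_bruteforce(model, M = M, z0 = z0)
    expect_gte(ol, fb)
  }
  for (rep in 1:10) {
    net <- generate_random_pbn(3, m = 1, N = 1, K = 2)
    model <- transition_model(net)
    z0 <- sample(8, 1)
    expect_equal(
      open_loop_bruteforce(model, M = 3, z0 = z0),
      minimax_dp(model, M = 3, z0 = z0)$value
    )
  }
})

test_that("oracles refuse instances beyond their guards", {
  model <- transition_model(generate_random_pbn(3, m = 2, N = 4, K = 2))
  expect_error(open_loop_bruteforce(model, M = 15, z0 = 1), class = "pbnred_too_large")
  expect_error(
    game_tree_value(model, M = 20, z0 = 1, max_nodes = 100),
    class = "pbnred_too_large"
  )
})

test_that("worst-case rollout reproduces the minimax value", {
  set.seed(33)
  for (rep in 1:15) {
    n <- sample(2:4, 1)
    net <- generate_random_pbn(n, m = 1, N = sample(1:4, 1), K = 2)
    model <- transition_model(net)
    sol <- minimax_dp(model, M = 5, z0 = sample(2^n, 1))
    ro <- rollout_worst_case(model, sol)
    expect_equal(ro$cost, sol$value)
    expect_equal(ro$trajectory[length(ro$trajectory)], sol$trajectory[sol$M + 1])
    # value bounds: terminal costs bracket the minimax value
    expect_gte(sol$value, 1)
    expect_lte(sol$value, 2^n)
  }
})

test_that("enlarging the control alphabet never raises the value", {
  set.seed(34)
  for (rep in 1:10) {
    n <- 3
    net1 <- generate_random_pbn(n, m = 1, N = 2, K = 2, seed = rep)
    # same functions, one extra (unused) control node
    net2 <- pbn_explicit(net1$constituents, net1$q, m = 2, p = 0, K = net1$K)
    v1 <- minimax_dp(transition_model(net1), M = 3, z0 = 2)$value
    v2 <- minimax_dp(transition_model(net2), M = 3, z0 = 2)$value
    expect_lte(v2, v1)
  }
})

test_that("switch-budget mode nests the unconstrained solution", {
  set.seed(35)
  for (rep in 1:8) {
    n <- sample(2:3, 1)
    net <- generate_random_pbn(n, m = 1, N = sample(1:3, 1), K = 2)
    model <- transition_model(net)
    M <- 4
    z0 <- sample(2^n, 1)
    free <- minimax_dp(model, M = M, z0 = z0)$value
    vals <- vapply(0:(M - 1), function(H) {
      minimax_dp(model, M = M, z0 = z0, switch_budget = H)$value
    }, numeric(1))
    # more allowed switches can only help, and a full budget is unconstrained
    expect_true(all(diff(vals) <= 0))
    expect_equal(vals[M], free)
    # zero switches = best constant control sequence (open loop, constant u)
    const_best <- min(vapply(1:2, function(u) {
      reach <- z0
      for (t in 1:M) {
        reach <- unique(unlist(lapply(reach, reachable_set, model = model, u = u)))
      }
      max(reach)
    }, numeric(1)))
    expect_equal(vals[1], const_best)
  }
})

test_that("DP on the reduced network matches the original (sound reductions)", {
  set.seed(36)
  for (rep in 1:12) {
    n <- sample(3:5, 1)
    m <- sample(1:2, 1)
    p <- sample(c(0, 0.01), 1)
    net <- generate_random_pbn(n, m = m, N = sample(c(2, 4), 1), K = 2, p = p)
    rep_row <- compare_original_reduced(net, M = 10, z0 = sample(2^n, 1))
    expect_true(rep_row$equal)
    expect_lte(rep_row$size_reduced, rep_row$size_original)
  }
})

test_that("solvers reject states outside the supplied set and unsound sets", {
  model <- transition_model(copy_gene1_bn())
  expect_error(minimax_dp(model, M = 3, z0 = 2, states = c(1, 4)),
    class = "pbnred_invalid_input"
  )
  # state 1 maps to itself, but state 3 maps to 2 which is excluded
  expect_error(minimax_dp(model, M = 3, z0 = 1, states = c(1, 3)),
    class = "pbnred_reduced_model_inconsistency"
  )
})

test_that("solution tidiers expose the policy and value tables", {
  model <- transition_model(controllable_toy())
  sol <- minimax_dp(model, M = 3, z0 = 2)
  td <- tidy(sol)
  expect_named(td, c("t", "state", "control", "value"))
  expect_equal(nrow(td), 2 * 3)
  expect_true(all(td$control %in% 1:2))
  g <- glance(sol)
  expect_equal(g$value, 1)
  expect_s3_class(autoplot(sol), "ggplot")
})
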