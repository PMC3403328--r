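test_that("inflow sums transition mass from the surviving columns", {
  m_id <- transition_model(identity_bn(2))
  for (i in 1:4) expect_equal(inflow(m_id, i), 1)

  m_copy <- transition_model(copy_gene1_bn())
  expect_equal(inflow(m_copy, 2), 0) # no state maps to 01
  expect_equal(inflow(m_copy, 1), 2) # 00 and 01 both map to 00

  # removing a column lowers inflow by exactly that entry
  A <- m_copy$matrices[[1]]
  expect_equal(
    inflow(m_copy, 1, kept = c(1, 3, 4)),
    inflow(m_copy, 1) - A[1, 2]
  )
})

test_that("critical states are the bottom SCCs plus the initial state", {
  expect_equal(critical_states(transition_model(identity_bn(2)), 1), 1:4)
  expect_equal(critical_states(transition_model(copy_gene1_bn()), 2), c(1L, 2L, 4L))
  expect_equal(critical_states(transition_model(copy_gene1_bn())), c(1L, 4L))
  expect_equal(critical_states(transition_model(negation_bn())), c(1L, 2L))
  # attractors are unioned over all control values
  toy <- transition_model(controllable_toy())
  expect_equal(critical_states(toy), c(1L, 2L))
})

test_that("deletable states have inflow at or below xi under every control", {
  expect_length(deletable_states(transition_model(identity_bn(2))), 0)
  m_copy <- transition_model(copy_gene1_bn())
  expect_equal(deletable_states(m_copy, preserve = c(1, 4)), c(2L, 3L))
  # with xi = 0 only exactly-zero inflow qualifies
  del <- deletable_states(m_copy)
  for (i in del) expect_equal(inflow(m_copy, i), 0)
})

test_that("iterative reduction deletes transient states and keeps critical ones", {
  r_id <- reduce_network(transition_model(identity_bn(2)), z0 = 1)
  expect_equal(r_id$kept, 1:4)
  expect_equal(r_id$iterations, 0L)
  expect_equal(reduction_rate(r_id), 0)

  r_copy <- reduce_network(transition_model(copy_gene1_bn()), z0 = 1)
  expect_equal(r_copy$kept, c(1L, 4L))
  expect_equal(reduction_rate(r_copy), 50)
  expect_equal(sort(c(r_copy$kept, r_copy$deleted$state)), 1:4)
  expect_equal(dim(r_copy$matrices[[1]]), c(2L, 2L))

  # chain 3 -> 2 -> 1 (self-loop at 1) needs two rounds: gene1 = AND of the
  # two genes, gene2 = gene1's value
  chain <- pbn(list(
    list(boolean_function(c(1, 2), c(0, 0, 0, 1))),
    list(boolean_function(1, c(0, 1)))
  ))
  r_chain <- reduce_network(transition_model(chain), z0 = 4)
  expect_equal(max(r_chain$deleted$iteration), 2L)
  seq_chain <- reduce_network(transition_model(chain), z0 = 4, order = "sequential")
  expect_equal(sort(seq_chain$kept), sort(r_chain$kept))
})

test_that("deleted states are unreachable: zero inflow at deletion time, never visited", {
  set.seed(21)
  for (rep in 1:8) {
    n <- sample(3:6, 1)
    m <- sample(0:1, 1)
    z0 <- sample(2^n, 1)
    net <- generate_random_pbn(n, m = m, N = sample(1:4, 1), K = 2)
    model <- transition_model(net)
    red <- reduce_network(model, z0 = z0)

    # each deleted state had zero inflow from the then-surviving set, under
    # every control
    if (nrow(red$deleted)) {
      for (it in unique(red$deleted$iteration)) {
        gone_before <- red$deleted$state[red$deleted$iteration < it]
        kept_then <- setdiff(seq_len(2^n), gone_before)
        for (s in red$deleted$state[red$deleted$iteration == it]) {
          expect_equal(max(inflow(model, s, kept_then)), 0)
        }
      }
    }

    # exhaustive forward reachability from z0 over 10 steps avoids them all
    reach <- z0
    visited <- z0
    for (t in 1:10) {
      nxt <- unique(unlist(lapply(reach, function(z) {
        unlist(lapply(seq_len(2^model$m), function(u) reachable_set(model, z, u)))
      })))
      reach <- setdiff(nxt, visited)
      visited <- union(visited, nxt)
      if (!length(reach)) break
    }
    expect_length(intersect(visited, red$deleted$state), 0)
  }
})

test_that("reduction is monotone in xi, idempotent, and preserves critical states", {
  set.seed(22)
  for (rep in 1:6) {
    net <- generate_random_pbn(5, N = 4, K = 2, p = 0.01)
    model <- transition_model(net)
    xi0 <- perturbation_threshold(5, 0.01)
    kept_sets <- lapply(c(0, xi0 / 2, xi0, 3 * xi0), function(xi) {
      reduce_network(model, z0 = 1, xi = xi)$kept
    })
    for (k in 2:length(kept_sets)) {
      expect_true(all(kept_sets[[k]] %in% kept_sets[[k - 1]]))
    }

    red <- reduce_network(model, z0 = 1)
    # fixpoint: nothing further is deletable from the kept set
    expect_length(
      deletable_states(model, kept = red$kept, xi = red$xi, preserve = red$preserve),
      0
    )
    # critical states survive even an absurdly large threshold
    crit <- critical_states(model, 1)
    big <- reduce_network(model, z0 = 1, xi = 0.9)
    expect_true(all(crit %in% big$kept))
  }
})

test_that("mean reduction rate is nondecreasing in p on matched seeds", {
  rates <- vapply(c(0.001, 0.002, 0.005, 0.01), function(p) {
    mean(run_reduction_experiment(6, N = 4, K = 2, p = p, replicates = 4, seed = 99)$rate)
  }, numeric(1))
  expect_true(all(diff(rates) >= 0))
})

test_that("reduction accessors and tidiers report consistent bookkeeping", {
  red <- reduce_network(transition_model(copy_gene1_bn()), z0 = 1)
  g <- glance(red)
  expect_equal(g$n_kept + g$n_deleted, g$n_states)
  expect_equal(g$rate, reduction_rate(red))
  td <- tidy(red)
  expect_named(td, c("state", "iteration"))
  expect_equal(red$index_map[red$kept], seq_along(red$kept))
  expect_true(all(red$index_map[td$state] == 0))
  expect_s3_class(autoplot(red), "ggplot")
})
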