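test_that("threshold function is 1 exactly when activation is >= 0", {
  expect_identical(threshold_function(0), 1L)
  expect_identical(threshold_function(-0.5), 0L)
  expect_identical(threshold_function(0.5), 1L)
  expect_identical(threshold_function(c(-1, -1e-9, 0, 1e-9, 2)),
                   c(0L, 0L, 1L, 1L, 1L))
  expect_error(threshold_function(NaN))
})

test_that("clamping and perturbation are pure threshold overrides", {
  net <- make_fixture("and_gate")
  B <- 1 + sum(abs(net$W))
  th <- effective_thresholds(net, env = "IN1")
  expect_equal(th[["IN1"]], 0)
  expect_equal(th[["IN2"]], B)
  expect_equal(th[["G"]], 1)

  th <- effective_thresholds(net, "IN1", perturbation(inhibited = "G"))
  expect_equal(th[["G"]], B)
  th <- effective_thresholds(net, "IN1", perturbation(activated = "G"))
  expect_equal(th[["G"]], -B)

  expect_error(perturbation(inhibited = "G", activated = "G"),
               "both inhibited and activated")
  expect_error(effective_thresholds(net, "G"), "non-input")
  expect_error(effective_thresholds(net, "IN1",
                                    perturbation(inhibited = "NOPE")),
               "NOPE")
})

test_that("AND and NOT gate semantics follow the weighted threshold rule", {
  andn <- make_fixture("and_gate")
  th <- effective_thresholds(andn, c("IN1", "IN2"))
  s <- stats::setNames(c(1L, 1L, 0L, 0L, 0L), andn$nodes$id)
  expect_equal(bcn_step(andn, s, th)[["G"]], 1L)
  s1 <- stats::setNames(c(1L, 0L, 0L, 0L, 0L), andn$nodes$id)
  expect_equal(bcn_step(andn, s1, effective_thresholds(andn, "IN1"))[["G"]],
               0L)

  notn <- make_fixture("not_gate")
  th <- effective_thresholds(notn, c("ACT", "INH"))
  s <- stats::setNames(c(1L, 1L, 0L, 0L, 0L), notn$nodes$id)
  expect_equal(bcn_step(notn, s, th)[["C"]], 0L)  # thr(1 - 1 - 1) = 0
  th <- effective_thresholds(notn, "ACT")
  s <- stats::setNames(c(1L, 0L, 0L, 0L, 0L), notn$nodes$id)
  expect_equal(bcn_step(notn, s, th)[["C"]], 1L)  # thr(1 - 1) = 1

  # all-inactive state with unit thresholds and nothing clamped is fixed
  chain <- make_fixture("chain")
  z <- integer(n_nodes(chain))
  expect_equal(unname(bcn_step(chain, z, effective_thresholds(chain))),
               z)
  expect_error(bcn_step(chain, z[-1]), "length")
})

test_that("Brent detection recovers a known orbit with transient 1, period 3", {
  # two inner nodes wired so the trajectory visits
  # (0,0) -> (1,0) -> (1,1) -> (0,1) -> (1,0): a 3-cycle entered after
  # one transient step
  net <- new_bcn(
    rbind(node_row("A", "inner", threshold = -1),
          node_row("B", "inner", threshold = 1)),
    rbind(edge_row("A", "A", -1), edge_row("B", "A", -1),
          edge_row("A", "B", 1), edge_row("B", "B", 0.5)))
  a <- find_attractor(net)
  expect_equal(a$period, 3L)
  expect_equal(a$transient, 1L)
  expect_identical(unname(a$cycle),
                   matrix(c(1L, 0L, 1L, 1L, 0L, 1L), 3, 2, byrow = TRUE))
  o <- oracle_attractor(net)
  expect_equal(a$period, o$period)
  expect_equal(a$transient, o$transient)
  expect_identical(unname(a$cycle), unname(o$cycle))
})

test_that("feed-forward networks reach steady states; transient is bounded", {
  for (i in 1:50) {
    net <- generate_random_bcn(synth_config(
      n_in = 1L + i %% 3L, n_inner = 3L + i %% 6L, n_out = 2L,
      cycle_edges = 0L, seed = 2000L + i))
    envs <- enumerate_environments(net)
    env <- envs[[1L + i %% length(envs)]]
    a <- find_attractor(net, env)
    expect_equal(a$period, 1L)
    expect_lte(a$transient, n_nodes(net) + 1L)
    expect_attractor_agrees(net, env)
  }
})

test_that("the ring fixture oscillates with fractional activity", {
  net <- make_fixture("ring_oscillator")
  a <- find_attractor(net, "IN1")
  expect_gt(a$period, 1L)
  act <- a$activity[c("R1", "R2", "R3")]
  expect_true(all(act > 0 & act < 1))
  o <- oracle_attractor(net, "IN1")
  expect_equal(a$period, o$period)
  expect_identical(unname(a$cycle), unname(o$cycle))
})

test_that("detection is deterministic and period-1 means a fixed point", {
  net <- generate_random_bcn(synth_config(2, 6, 2, cycle_edges = 2,
                                          seed = 5))
  for (env in enumerate_environments(net)) {
    a1 <- find_attractor(net, env)
    a2 <- find_attractor(net, env)
    expect_identical(a1, a2)
    th <- effective_thresholds(net, env)
    s <- a1$cycle[1, ]
    same <- identical(unname(bcn_step(net, s, th)), unname(s))
    expect_identical(a1$period == 1L, same)
  }
})

test_that("clamped nodes never deviate inside transient or cycle", {
  for (i in 1:20) {
    net <- small_random_net(i)
    envs <- enumerate_environments(net)
    env <- envs[[1L + i %% length(envs)]]
    target <- node_ids(net, "inner")[1]
    pert <- perturbation(inhibited = target)
    th <- effective_thresholds(net, env, pert)
    s <- integer(n_nodes(net))
    for (t in 1:30) {
      s <- bcn_step(net, s, th)
      expect_equal(unname(s[net$index[target]]), 0L)
      expect_true(all(s[net$index[env]] == 1L))
      off <- setdiff(node_ids(net, "input"), env)
      expect_true(all(s[net$index[off]] == 0L))
    }
    a <- find_attractor(net, env, pert)
    expect_true(all(a$cycle[, target] == 0L))
  }
})

test_that("non-convergence within the step cap raises a contextual error", {
  net <- make_fixture("ring_oscillator")
  expect_error(find_attractor(net, "IN1", max_steps = 2L),
               "no attractor confirmed within 2 steps")
})

test_that("batch evaluation is bit-identical to per-environment Brent", {
  # includes cyclic networks so the limit-cycle fallback path is hit
  for (i in c(3, 7, 11)) {
    net <- small_random_net(i)
    envs <- enumerate_environments(net)
    batch <- batch_attractors(net, envs)
    single <- lapply(envs, function(e) find_attractor(net, e))
    expect_identical(batch, single)
  }
  net <- make_fixture("ring_oscillator")
  expect_identical(batch_attractors(net, list("IN1", character(0))),
                   list(find_attractor(net, "IN1"),
                        find_attractor(net, character(0))))
  expect_identical(batch_attractors(net, list()), list())
})

test_that("attractor TSV serialization carries metadata and activities", {
  net <- make_fixture("ring_oscillator")
  a <- find_attractor(net, "IN1")
  path <- withr::local_tempfile(fileext = ".tsv")
  write_attractor_tsv(a, path, env = "IN1")
  lines <- readLines(path)
  expect_equal(lines[1], sprintf("# period\t%d", a$period))
  expect_equal(lines[2], sprintf("# transient\t%d", a$transient))
  body <- utils::read.delim(path, skip = 4)
  expect_equal(body$node_id, net$nodes$id)
  expect_equal(body$activity_fraction, unname(a$activity))
})
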