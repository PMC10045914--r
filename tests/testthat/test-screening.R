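test_that("environment enumeration counts 2^k - 1 in bitmask order", {
  net9 <- generate_random_bcn(synth_config(9, 4, 2, seed = 1))
  envs <- enumerate_environments(net9)
  expect_length(envs, 511L)
  expect_equal(attr(envs[[1]], "mask"), 1L)
  expect_equal(envs[[1]], structure(node_ids(net9, "input")[1], mask = 1L),
               ignore_attr = TRUE)
  expect_length(envs[[511]], 9L)

  net1 <- make_fixture("two_path_synergy")
  expect_length(enumerate_environments(net1), 1L)
  net2 <- make_fixture("and_gate")
  e2 <- enumerate_environments(net2)
  expect_length(e2, 3L)
  expect_equal(lapply(e2, as.character),
               list("IN1", "IN2", c("IN1", "IN2")))
})

test_that("target eligibility excludes receptors except TLR2 and TLR4", {
  nodes <- rbind(
    node_row("IN1", "input"),
    node_row(c("K1", "K2", "K3"), "inner"),
    node_row("OUT1", "output", "type1"))
  edges <- rbind(edge_row("IN1", "K1", 1), edge_row("K1", "K2", 1),
                 edge_row("K2", "K3", 1), edge_row("K3", "OUT1", 1))
  net <- new_bcn(nodes, edges)
  expect_equal(eligible_targets(net), c("K1", "K2", "K3"))

  nodes$is_receptor[nodes$id == "K2"] <- TRUE
  expect_equal(eligible_targets(new_bcn(nodes, edges)), c("K1", "K3"))

  # a lone receptor inner node yields an empty list
  lone <- new_bcn(rbind(node_row("IN1", "input"),
                        node_row("R", "inner", receptor = TRUE),
                        node_row("OUT1", "output", "type1")),
                  rbind(edge_row("IN1", "R", 1), edge_row("R", "OUT1", 1)))
  expect_length(eligible_targets(lone), 0L)

  # ... unless it is one of the toll-like receptors kept in scope
  tlr <- new_bcn(rbind(node_row("IN1", "input"),
                       node_row("TLR4", "inner", receptor = TRUE),
                       node_row("OUT1", "output", "type1")),
                 rbind(edge_row("IN1", "TLR4", 1),
                       edge_row("TLR4", "OUT1", 1)))
  expect_equal(eligible_targets(tlr), "TLR4")
})

test_that("the synergy index matches its defining ratio", {
  expect_equal(synergy_index(0.57, 0.05, 0, 0.1), 5.7)
  expect_equal(synergy_index(0.4, 0.3, 0.2, 0.1), 0.8)
  expect_equal(synergy_index(0, 0, 0, 0.1), 0)
  expect_equal(synergy_index(-0.3, 0.1, -0.1, 0.1), 1.5)
  expect_error(synergy_index(0.1, 0, 0, tau = 0))
  # identity: capped at |delta_ab| / tau when singles vanish
  for (d in c(0.05, 0.2, 1, 2))
    expect_equal(synergy_index(d, 0, 0, 0.1), d / 0.1)
  # always non-negative over random operands
  set.seed(1)
  d <- matrix(stats::runif(300, -2, 2), ncol = 3)
  expect_true(all(synergy_index(d[, 1], d[, 2], d[, 3], 0.1) >= 0))
})

test_that("record counts follow |T| x |E| and C(|T|,2) x |E|", {
  net <- generate_random_bcn(synth_config(3, 6, 4, seed = 9))
  envs <- enumerate_environments(net)
  targets <- eligible_targets(net)
  r1 <- run_screen(net, screen_config(order = 1))
  expect_equal(nrow(r1), length(targets) * length(envs))
  expect_true(all(is.na(r1$target2)))
  expect_true(all(is.na(r1$synI)))
  r2 <- run_screen(net, screen_config(order = 2))
  expect_equal(nrow(r2), choose(length(targets), 2) * length(envs))
  expect_true(all(!is.na(r2$synI)))

  tp <- make_fixture("two_path_synergy")  # C(2,2)=1 pair x 1 env
  expect_equal(nrow(run_screen(tp, screen_config(order = 2))), 1L)
})

test_that("inhibiting a baseline-inactive node leaves pI unchanged", {
  for (i in 1:10) {
    net <- small_random_net(i)
    envs <- enumerate_environments(net)
    r1 <- run_screen(net, screen_config(order = 1))
    base <- batch_attractors(net, envs)
    env_key <- vapply(envs, paste, character(1), collapse = ",")
    for (k in seq_len(nrow(r1))) {
      a <- base[[match(r1$env_ids[k], env_key)]]
      if (a$activity[[r1$target1[k]]] == 0)
        expect_equal(r1$delta_pI[k], 0)
    }
  }
})

test_that("pair records are symmetric in target order", {
  net <- generate_random_bcn(synth_config(2, 5, 2, cycle_edges = 1,
                                          seed = 21))
  envs <- enumerate_environments(net)
  tg <- eligible_targets(net)[1:2]
  cfg <- screen_config(order = 2)
  ab <- run_screen(net, cfg, targets = tg)
  ba <- run_screen(net, cfg, targets = rev(tg))
  for (col in c("pI_base", "pI_pert", "delta_pI", "period", "flip", "synI"))
    expect_equal(ab[[col]], ba[[col]])
})

test_that("screen quantities agree with the naive unbatched oracle", {
  for (i in c(2, 6)) {
    net <- small_random_net(i)  # <= 10 usable nodes at these sizes
    envs <- enumerate_environments(net)
    targets <- eligible_targets(net)[1:3]
    for (ord in 1:2) {
      cfg <- screen_config(order = ord)
      got <- run_screen(net, cfg, targets = targets)
      want <- oracle_screen(net, cfg, targets, envs)
      # oracle enumerates env-major; sort both to a common order
      key <- function(d) order(d$target1, d$target2, d$env_ids)
      got <- got[key(got), ]
      want <- want[key(want), ]
      for (col in c("pI_base", "pI_pert", "delta_pI", "period", "flip"))
        expect_equal(got[[col]], want[[col]], ignore_attr = TRUE)
      if (ord == 2L) expect_equal(got$synI, want$synI, ignore_attr = TRUE)
    }
  }
})

test_that("summaries tally hand-set records correctly", {
  recs <- data.frame(
    env_bitmask = 1L, env_ids = "IN1",
    target1 = c("A", "B", "C", "D", "E", "F"),
    target2 = c("B", "C", "D", "E", "F", "A"),
    pI_base = c(0.5, -0.5, 0.1, 0.6, -0.3, 0.0),
    pI_pert = c(-0.5, 0.5, 0.8, 0.1, -0.9, 0.45),
    delta_pI = c(-1.0, 1.0, 0.7, -0.5, -0.6, 0.45),
    period = c(1L, 1L, 2L, 1L, 4L, 1L),
    flip = c(1L, 1L, 0L, 0L, 0L, 0L),
    flip_direction = c("tissue_protective", "inflammatory", "none", "none",
                       "none", "none"),
    synI = c(2.0, 1.0, 1 + 1e-12, 0.3, 0.99, 1.2),
    stringsAsFactors = FALSE)
  s <- summarize_screen(recs, screen_config(order = 2))
  expect_equal(s$n_records, 6L)
  expect_equal(unname(s$shift_up["count"]), 3)    # 1.0, 0.7, 0.45
  expect_equal(unname(s$shift_up["pct"]), 50)
  expect_equal(unname(s$shift_down["count"]), 3)  # -1.0, -0.5, -0.6
  expect_equal(s$flips_inflammatory, 1L)
  expect_equal(s$flips_tissue_protective, 1L)
  expect_equal(unname(s$limit_cycles["count"]), 2)
  expect_equal(s$synI_buckets$count, c(2L, 2L, 2L))  # <1, =1 (tolerant), >1
  # buckets are exhaustive and exclusive; rounded pcts sum to ~100
  expect_equal(sum(s$synI_buckets$count), nrow(recs))
  expect_lt(abs(sum(s$synI_buckets$pct) - 100), 0.05)
  # flip involvement covers both flip records
  inv <- s$flip_node_involvement
  expect_equal(sum(inv$n_flips), 4L)  # 2 flips x 2 targets
  expect_equal(inv$fraction[inv$node == "B"], 1)  # B is in both flips
  expect_error(summarize_screen(recs[0, ], screen_config(order = 2)),
               "empty")
})

test_that("screen TSV export preserves the canonical column layout", {
  net <- make_fixture("two_path_synergy")
  recs <- run_screen(net, screen_config(order = 2))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_screen_tsv(recs, path)
  back <- utils::read.delim(path)
  expect_equal(names(back),
               c("env_bitmask", "env_ids", "target1", "target2", "pI_base",
                 "pI_pert", "delta_pI", "period", "flip", "flip_direction",
                 "synI"))
  expect_equal(back$synI, recs$synI)
})
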