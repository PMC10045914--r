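# Independent oracles: brute-force implementations kept deliberately
# separate from the package's algorithms.

# Brute-force attractor detection: step from the all-inactive state
# recording every visited state in a table until one repeats.
oracle_attractor <- function(net, env = character(0), pert = NULL,
                             max_steps = 10000L) {
  theta <- effective_thresholds(net, env, pert)
  s <- stats::setNames(integer(n_nodes(net)), net$nodes$id)
  seen <- new.env(hash = TRUE, parent = emptyenv())
  traj <- list()
  for (t in 0:max_steps) {
    key <- paste(s, collapse = "")
    hit <- seen[[key]]
    if (!is.null(hit)) {
      cycle <- do.call(rbind, traj[(hit + 1L):t])
      return(list(period = t - hit, transient = hit, cycle = cycle,
                  activity = colMeans(cycle)))
    }
    assign(key, t, envir = seen)
    traj[[t + 1L]] <- s
    s <- bcn_step(net, s, theta)
  }
  stop("oracle: no repeat within max_steps")
}

expect_attractor_agrees <- function(net, env = character(0), pert = NULL) {
  a <- find_attractor(net, env, pert)
  o <- oracle_attractor(net, env, pert)
  expect_identical(a$period, o$period)
  expect_identical(a$transient, o$transient)
  expect_identical(unname(a$cycle), unname(o$cycle))
}

# Brandes betweenness on unweighted directed graphs, written against
# the textbook description rather than igraph.
oracle_betweenness <- function(net, normalized = TRUE) {
  ids <- net$nodes$id
  n <- length(ids)
  adj <- lapply(stats::setNames(ids, ids), function(v)
    net$edges$target[net$edges$source == v])
  btw <- stats::setNames(numeric(n), ids)
  for (s in ids) {
    dist <- stats::setNames(rep(Inf, n), ids)
    sigma <- stats::setNames(numeric(n), ids)
    dist[s] <- 0; sigma[s] <- 1
    queue <- s
    visit_order <- character(0)
    while (length(queue) > 0L) {
      v <- queue[1]; queue <- queue[-1]
      visit_order <- c(visit_order, v)
      for (w in adj[[v]]) {
        if (!is.finite(dist[w])) {
          dist[w] <- dist[v] + 1
          queue <- c(queue, w)
        }
        if (dist[w] == dist[v] + 1) sigma[w] <- sigma[w] + sigma[v]
      }
    }
    delta <- stats::setNames(numeric(n), ids)
    for (v in rev(visit_order)) {
      for (w in adj[[v]]) if (dist[w] == dist[v] + 1)
        delta[v] <- delta[v] + sigma[v] / sigma[w] * (1 + delta[w])
      if (v != s) btw[v] <- btw[v] + delta[v]
    }
  }
  if (normalized && n > 2L) btw <- btw / ((n - 1) * (n - 2))
  btw
}

# Naive screen: one unbatched attractor per case, pI computed from
# first principles, no caching.
oracle_pI <- function(net, attractor) {
  nd <- net$nodes
  t1 <- nd$id[nd$class == "output" & nd$polarity == "type1"]
  t2 <- nd$id[nd$class == "output" & nd$polarity == "type2"]
  sum(attractor$activity[t1]) / length(t1) -
    sum(attractor$activity[t2]) / length(t2)
}

oracle_screen <- function(net, config, targets, environments) {
  rows <- list()
  for (e in environments) {
    base <- oracle_attractor(net, e)
    pb <- oracle_pI(net, base)
    sets <- if (config$order == 1L) as.list(targets) else
      utils::combn(targets, 2L, simplify = FALSE)
    for (ts in sets) {
      a <- oracle_attractor(net, e, perturbation(inhibited = ts))
      pp <- oracle_pI(net, a)
      syn <- NA_real_
      if (config$order == 2L) {
        d1 <- vapply(ts, function(x) {
          oracle_pI(net, oracle_attractor(net, e,
                                          perturbation(inhibited = x))) - pb
        }, numeric(1))
        syn <- abs(pp - pb) / max(abs(d1[1]) + abs(d1[2]), config$tau)
      }
      rows[[length(rows) + 1L]] <- data.frame(
        env_ids = paste(e, collapse = ","),
        target1 = ts[1], target2 = if (length(ts) == 2L) ts[2] else NA,
        pI_base = pb, pI_pert = pp, delta_pI = pp - pb,
        period = a$period,
        flip = detect_flip(pb, pp, config$flip_threshold),
        synI = syn, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

# Varied small random networks for property tests.
small_random_net <- function(i) {
  generate_random_bcn(synth_config(
    n_in = 1L + i %% 3L,
    n_inner = 3L + i %% 5L,
    n_out = 2L,
    and_gate_fraction = c(0, 0.25, 0.5)[1L + i %% 3L],
    inhibitory_fraction = c(0.1, 0.3, 0.5)[1L + i %% 3L],
    cycle_edges = i %% 4L,
    seed = 1000L + i))
}
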