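# Deterministic synthetic networks: hand-built fixtures with known
# exact attractors, and a random generator producing the three-layer
# (input -> inner -> output) shape the analysis assumes, with AND/OR
# gate wiring, optional inhibitory veto edges, optional injected
# cycles, and preferential attachment for a heavy-tailed degree
# distribution.

FIXTURE_NAMES <- c("and_gate", "or_gate", "not_gate", "chain",
                   "ring_oscillator", "two_path_synergy")

node_row <- function(id, class, polarity = "none", threshold = NA_real_,
                     receptor = FALSE, technical = FALSE,
                     constitutive = FALSE) {
  data.frame(id = id, name = id, class = class, is_receptor = receptor,
             is_technical = technical, is_constitutive = constitutive,
             polarity = polarity, threshold = threshold,
             stringsAsFactors = FALSE)
}

edge_row <- function(source, target, weight) {
  data.frame(source = source, target = target, weight = weight,
             evidence = "", stringsAsFactors = FALSE)
}

#' Hand-built fixture networks
#'
#' Small networks with documented exact behaviour, used throughout the
#' test suite and as worked examples:
#' \describe{
#'   \item{and_gate}{`IN1`, `IN2` feed inner `G` with weight 0.5 each
#'     (both necessary); `G` activates the type-1 output `OUT1`.}
#'   \item{or_gate}{as above with weight 1 edges (either sufficient).}
#'   \item{not_gate}{activator input `ACT` (+1) and inhibitor input
#'     `INH` (-1) on inner `C`; `INH` vetoes activation.}
#'   \item{chain}{a 3-link feed-forward relay `IN1 -> X1 -> X2 -> X3
#'     -> OUT1`.}
#'   \item{ring_oscillator}{a 3-node inner ring with one inhibitory
#'     edge and a zero threshold on the inhibited member; oscillates
#'     with period 6 from the all-inactive start, every ring node
#'     active in exactly half of the cycle states.}
#'   \item{two_path_synergy}{two parallel inner paths `P1`, `P2`, each
#'     alone sufficient to keep the type-1 output on, so single
#'     inhibitions leave the polarization unchanged and only the pair
#'     inhibition shifts it (synI = |DeltaPI| / tau by construction).}
#' }
#' Each fixture carries one type-1 and one (never-active) type-2
#' output so the polarization index is defined.
#'
#' @param name one of `"and_gate"`, `"or_gate"`, `"not_gate"`,
#'   `"chain"`, `"ring_oscillator"`, `"two_path_synergy"`.
#' @return a `bcn`.
#' @export
make_fixture <- function(name) {
  name <- match.arg(name, FIXTURE_NAMES)
  outs <- rbind(node_row("OUT1", "output", "type1"),
                node_row("OUT2", "output", "type2"))
  switch(name,
    and_gate = new_bcn(
      rbind(node_row("IN1", "input"), node_row("IN2", "input"),
            node_row("G", "inner"), outs),
      rbind(edge_row("IN1", "G", 0.5), edge_row("IN2", "G", 0.5),
            edge_row("G", "OUT1", 1), edge_row("G", "OUT2", -1))),
    or_gate = new_bcn(
      rbind(node_row("IN1", "input"), node_row("IN2", "input"),
            node_row("G", "inner"), outs),
      rbind(edge_row("IN1", "G", 1), edge_row("IN2", "G", 1),
            edge_row("G", "OUT1", 1), edge_row("G", "OUT2", -1))),
    not_gate = new_bcn(
      rbind(node_row("ACT", "input"), node_row("INH", "input"),
            node_row("C", "inner"), outs),
      rbind(edge_row("ACT", "C", 1), edge_row("INH", "C", -1),
            edge_row("C", "OUT1", 1), edge_row("C", "OUT2", -1))),
    chain = new_bcn(
      rbind(node_row("IN1", "input"), node_row("X1", "inner"),
            node_row("X2", "inner"), node_row("X3", "inner"), outs),
      rbind(edge_row("IN1", "X1", 1), edge_row("X1", "X2", 1),
            edge_row("X2", "X3", 1), edge_row("X3", "OUT1", 1),
            edge_row("X3", "OUT2", -1))),
    ring_oscillator = new_bcn(
      rbind(node_row("IN1", "input"),
            node_row("R1", "inner", threshold = 0),
            node_row("R2", "inner"), node_row("R3", "inner"), outs),
      rbind(edge_row("R1", "R2", 1), edge_row("R2", "R3", 1),
            edge_row("R3", "R1", -1),
            edge_row("R1", "OUT1", 1), edge_row("R2", "OUT2", 1))),
    two_path_synergy = new_bcn(
      rbind(node_row("IN1", "input"), node_row("P1", "inner"),
            node_row("P2", "inner"), outs),
      rbind(edge_row("IN1", "P1", 1), edge_row("IN1", "P2", 1),
            edge_row("P1", "OUT1", 1), edge_row("P2", "OUT1", 1),
            edge_row("P1", "OUT2", -1))))
}

#' Configuration for the random network generator
#'
#' @param n_in,n_inner,n_out layer sizes (each >= 1).
#' @param and_gate_fraction probability that a node is wired as an AND
#'   gate (two jointly necessary weight-0.5 activators) rather than an
#'   OR gate (one or two individually sufficient weight-1 activators).
#' @param inhibitory_fraction probability that a node additionally
#'   receives one weight -1 veto edge.
#' @param cycle_edges number of feedback edges injected among inner
#'   nodes (0 keeps the network acyclic, so every attractor is a
#'   steady state).
#' @param seed RNG seed (Mersenne-Twister).
#' @return list of class `bcn_synth_config`.
#' @export
synth_config <- function(n_in, n_inner, n_out, and_gate_fraction = 0.25,
                         inhibitory_fraction = 0.15, cycle_edges = 0L,
                         seed = 1L) {
  stopifnot(n_in >= 1, n_inner >= 1, n_out >= 1,
            and_gate_fraction >= 0, and_gate_fraction <= 1,
            inhibitory_fraction >= 0, inhibitory_fraction <= 1,
            cycle_edges >= 0)
  structure(list(n_in = as.integer(n_in), n_inner = as.integer(n_inner),
                 n_out = as.integer(n_out),
                 and_gate_fraction = and_gate_fraction,
                 inhibitory_fraction = inhibitory_fraction,
                 cycle_edges = as.integer(cycle_edges),
                 seed = as.integer(seed)),
            class = "bcn_synth_config")
}

with_local_seed <- function(seed, expr) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = genv)
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion",
           sample.kind = "Rejection")
  expr
}

#' Generate a random layered Boolean control network
#'
#' Wiring is feed-forward by construction (inputs -> inner, in index
#' order, -> outputs): every inner or output node receives either an
#' AND gate (two weight-0.5 activators) or an OR gate (one or two
#' weight-1 activators), plus, with probability
#' `inhibitory_fraction`, one weight -1 veto edge. Activator sources
#' are drawn preferentially by current out-degree, giving an
#' approximately heavy-tailed degree distribution. `cycle_edges`
#' feedback edges (later inner node -> earlier inner node) are then
#' injected. Output (and input) polarities alternate
#' type1/type2/type1/... so the polarization index is always defined.
#' Identical configuration implies an identical network, byte for byte
#' in its TSV export; the caller's RNG state is left untouched.
#'
#' @param config a [synth_config()].
#' @return a `bcn`; the configuration and RNG identity are attached as
#'   attributes `synth_config` and `rng_kind`.
#' @export
generate_random_bcn <- function(config) {
  stopifnot(inherits(config, "bcn_synth_config"))
  with_local_seed(config$seed, {
    inputs <- sprintf("IN%d", seq_len(config$n_in))
    inner <- sprintf("N%d", seq_len(config$n_inner))
    outputs <- sprintf("OUT%d", seq_len(config$n_out))
    alt <- function(k) rep(c("type1", "type2"), length.out = k)
    nodes <- rbind(
      node_row(inputs, "input", polarity = alt(config$n_in)),
      node_row(inner, "inner"),
      node_row(outputs, "output", polarity = alt(config$n_out)))

    out_deg <- stats::setNames(numeric(length(c(inputs, inner))),
                               c(inputs, inner))
    pick <- function(pool, k) {
      w <- out_deg[pool] + 1
      pool[sample.int(length(pool), k, prob = w)]
    }
    es <- list()
    wire <- function(target, pool) {
      if (stats::runif(1) < config$and_gate_fraction && length(pool) >= 2L) {
        src <- pick(pool, 2L)
        w <- c(0.5, 0.5)
      } else {
        k <- if (length(pool) >= 2L) sample(1:2, 1L) else 1L
        src <- pick(pool, k)
        w <- rep(1, k)
      }
      if (stats::runif(1) < config$inhibitory_fraction &&
          length(setdiff(pool, src)) >= 1L) {
        inh <- pick(setdiff(pool, src), 1L)
        src <- c(src, inh)
        w <- c(w, -1)
      }
      out_deg[src] <<- out_deg[src] + 1
      es[[length(es) + 1L]] <<- edge_row(src, rep(target, length(src)), w)
    }
    for (i in seq_along(inner))
      wire(inner[i], c(inputs, inner[seq_len(i - 1L)]))
    for (o in outputs)
      wire(o, inner)

    edges <- do.call(rbind, es)
    # feedback edges among inner nodes (later -> earlier)
    added <- 0L
    attempts <- 0L
    if (config$cycle_edges > 0L && config$n_inner >= 2L) {
      have <- paste(edges$source, edges$target)
      while (added < config$cycle_edges && attempts < 200L * config$cycle_edges) {
        attempts <- attempts + 1L
        j <- sample(2:config$n_inner, 1L)
        i <- sample.int(j - 1L, 1L)
        s <- inner[j]; t <- inner[i]
        if (paste(s, t) %in% have) next
        w <- if (stats::runif(1) < config$inhibitory_fraction) -1 else 1
        edges <- rbind(edges, edge_row(s, t, w))
        have <- c(have, paste(s, t))
        added <- added + 1L
      }
    }
    net <- new_bcn(nodes, edges)
    attr(net, "synth_config") <- config
    attr(net, "rng_kind") <- "Mersenne-Twister"
    net
  })
}

#' Export a synthetic network with its generation metadata
#'
#' Writes the canonical TSV pair plus a `<prefix>.meta.json` sidecar
#' echoing the generator configuration, seed and RNG algorithm.
#'
#' @param net a `bcn` from [generate_random_bcn()] (other networks get
#'   a sidecar without a config echo).
#' @param prefix output path prefix.
#' @return invisibly, the paths written.
#' @export
export_synth <- function(net, prefix) {
  paths <- export_network(net, prefix, "tsv")
  meta <- list(rng = attr(net, "rng_kind"),
               config = unclass(attr(net, "synth_config")))
  mp <- paste0(prefix, ".meta.json")
  jsonlite::write_json(meta, mp, auto_unbox = TRUE, null = "null")
  invisible(c(paths, meta = mp))
}
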