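# Exhaustive in-silico inhibition screens: every eligible target (or
# unordered target pair) crossed with every non-empty input
# environment; Delta-pI, flips, and the synergy index for pairs.

#' Screen configuration
#'
#' @param tau synergy-index floor parameter (default 0.1): caps synI at
#'   `|DeltaPI(AB)| / tau` when both single effects are negligible.
#' @param flip_threshold commitment threshold for flips (default 0.2).
#' @param shift_threshold DeltaPI magnitude counted as a "considerable
#'   shift" in summaries (default 0.4).
#' @param order 1 (single targets) or 2 (unordered pairs).
#' @return list of class `bcn_screen_config`.
#' @export
screen_config <- function(tau = 0.1, flip_threshold = 0.2,
                          shift_threshold = 0.4, order = 1L) {
  stopifnot(tau > 0, flip_threshold > 0, shift_threshold > 0,
            order %in% c(1L, 2L))
  structure(list(tau = tau, flip_threshold = flip_threshold,
                 shift_threshold = shift_threshold, order = as.integer(order)),
            class = "bcn_screen_config")
}

#' Enumerate all non-empty input environments
#'
#' Binary counting over the node-table input order: environment `m`
#' (1..2^k-1) activates input `j` iff bit `j` (value `2^(j-1)`) of `m`
#' is set, so with k inputs there are `2^k - 1` environments and the
#' all-inactive environment is excluded.
#'
#' @param net a `bcn` with `k >= 1` input nodes.
#' @return list of character vectors of active input ids; the bitmask
#'   is attached as attribute `mask` on each element.
#' @export
enumerate_environments <- function(net) {
  inputs <- node_ids(net, "input")
  k <- length(inputs)
  stopifnot(k >= 1)
  if (k > 24L) stop("too many inputs to enumerate exhaustively: ", k)
  lapply(seq_len(2^k - 1L), function(m) {
    on <- bitwAnd(m, bitwShiftL(1L, seq_len(k) - 1L)) != 0L
    structure(inputs[on], mask = m)
  })
}

#' Eligible inhibition targets
#'
#' Inner nodes only (inputs and outputs are never inhibited directly),
#' excluding receptor-flagged nodes with the exception of TLR2 and
#' TLR4.
#'
#' @param net a `bcn`.
#' @return character vector of node ids, in node-table order.
#' @export
eligible_targets <- function(net) {
  nd <- net$nodes
  keep <- nd$class == "inner" &
    (!nd$is_receptor | nd$id %in% c("TLR2", "TLR4"))
  nd$id[keep]
}

#' Synergy index of a target pair
#'
#' `synI = |DeltaPI(AB)| / max(|DeltaPI(A)| + |DeltaPI(B)|, tau)`.
#' Values above 1 indicate synergy, 1 additive (independent) action,
#' below 1 overlapping pathways; `tau` prevents runaway values when
#' both single effects are negligible.
#'
#' @param delta_ab DeltaPI of the pair inhibition.
#' @param delta_a,delta_b DeltaPI of each single inhibition under the
#'   same environment.
#' @param tau floor parameter (> 0).
#' @return non-negative number.
#' @export
synergy_index <- function(delta_ab, delta_a, delta_b, tau = 0.1) {
  stopifnot(tau > 0)
  abs(delta_ab) / pmax(abs(delta_a) + abs(delta_b), tau)
}

flip_direction <- function(flip, pI_pert) {
  ifelse(flip == 1L, ifelse(pI_pert > 0, "inflammatory", "tissue_protective"),
         "none")
}

#' Run an exhaustive inhibition screen
#'
#' Crosses every eligible target (order 1) or unordered target pair
#' (order 2) with every non-empty environment. Baseline attractors are
#' computed once per environment and shared; for order 2 the
#' single-target DeltaPI values needed by the synergy index are
#' computed (or reused) for the same environments. All runs restart
#' from the all-inactive state.
#'
#' @param net a `bcn` with output polarity assignments.
#' @param config a [screen_config()].
#' @param targets target id vector; defaults to [eligible_targets()].
#' @param environments environment list; defaults to
#'   [enumerate_environments()].
#' @param max_steps per-run step cap.
#' @return data.frame of class `bcn_screen` with one row per
#'   (target-set, environment): columns `env_bitmask`, `env_ids`,
#'   `target1`, `target2` (NA for order 1), `pI_base`, `pI_pert`,
#'   `delta_pI`, `period`, `flip`, `flip_direction`, `synI` (NA for
#'   order 1). The config is attached as attribute `config`.
#' @export
run_screen <- function(net, config = screen_config(),
                       targets = eligible_targets(net),
                       environments = enumerate_environments(net),
                       max_steps = 10000L) {
  stopifnot(inherits(config, "bcn_screen_config"))
  E <- length(environments)
  masks <- vapply(environments, function(e) {
    m <- attr(e, "mask")
    if (is.null(m)) NA_integer_ else as.integer(m)
  }, integer(1))
  env_ids <- vapply(environments, paste, character(1), collapse = ",")

  base_atts <- batch_attractors(net, environments, NULL, max_steps)
  pI_base <- vapply(base_atts, function(a)
    polarization_index(a, net, "output")$pI, numeric(1))

  pert_pass <- function(target_set) {
    atts <- batch_attractors(net, environments,
                             perturbation(inhibited = target_set), max_steps)
    list(pI = vapply(atts, function(a)
           polarization_index(a, net, "output")$pI, numeric(1)),
         period = vapply(atts, function(a) a$period, integer(1)))
  }

  single <- lapply(stats::setNames(targets, targets), pert_pass)
  delta1 <- vapply(single, function(r) r$pI - pI_base, numeric(E))
  delta1 <- matrix(delta1, nrow = E,
                   dimnames = list(NULL, targets))  # E x |targets|

  if (config$order == 1L) {
    recs <- do.call(rbind, lapply(targets, function(tg) {
      r <- single[[tg]]
      data.frame(env_bitmask = masks, env_ids = env_ids,
                 target1 = tg, target2 = NA_character_,
                 pI_base = pI_base, pI_pert = r$pI,
                 delta_pI = r$pI - pI_base, period = r$period,
                 flip = detect_flip(pI_base, r$pI, config$flip_threshold),
                 synI = NA_real_, stringsAsFactors = FALSE)
    }))
  } else {
    if (length(targets) < 2L)
      stop("order-2 screen needs at least two targets")
    pairs <- utils::combn(targets, 2L)
    recs <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(p) {
      a <- pairs[1L, p]; b <- pairs[2L, p]
      r <- pert_pass(c(a, b))
      d <- r$pI - pI_base
      data.frame(env_bitmask = masks, env_ids = env_ids,
                 target1 = a, target2 = b,
                 pI_base = pI_base, pI_pert = r$pI,
                 delta_pI = d, period = r$period,
                 flip = detect_flip(pI_base, r$pI, config$flip_threshold),
                 synI = synergy_index(d, delta1[, a], delta1[, b],
                                      config$tau),
                 stringsAsFactors = FALSE)
    }))
  }
  recs$flip_direction <- flip_direction(recs$flip, recs$pI_pert)
  recs <- recs[, c("env_bitmask", "env_ids", "target1", "target2",
                   "pI_base", "pI_pert", "delta_pI", "period", "flip",
                   "flip_direction", "synI")]
  rownames(recs) <- NULL
  attr(recs, "config") <- config
  class(recs) <- c("bcn_screen", "data.frame")
  recs
}

#' Summarise a screen
#'
#' Counts and percentages (2 decimal places) of considerable shifts
#' (`delta_pI` beyond the shift threshold in either direction), flips
#' by direction, limit-cycle attractors, and, for order-2 screens, the
#' synergy-index buckets (`<1`, `=1` within 1e-9, `>1`) and the
#' fraction of flip records each node participates in.
#'
#' @param records a `bcn_screen` data.frame from [run_screen()].
#' @param config the [screen_config()]; defaults to the one attached
#'   to `records`.
#' @return list of class `bcn_screen_summary`.
#' @export
summarize_screen <- function(records, config = attr(records, "config")) {
  if (is.null(records) || nrow(records) == 0L)
    stop("empty screen record list")
  if (is.null(config)) config <- screen_config()
  n <- nrow(records)
  pct <- function(k) round(100 * k / n, 2)
  up <- sum(records$delta_pI > config$shift_threshold)
  down <- sum(records$delta_pI < -config$shift_threshold)
  fl_inf <- sum(records$flip_direction == "inflammatory")
  fl_tp <- sum(records$flip_direction == "tissue_protective")
  lc <- sum(records$period > 1L)
  out <- list(
    n_records = n,
    order = if (all(is.na(records$target2))) 1L else 2L,
    shift_up = c(count = up, pct = pct(up)),
    shift_down = c(count = down, pct = pct(down)),
    flips_inflammatory = fl_inf,
    flips_tissue_protective = fl_tp,
    limit_cycles = c(count = lc, pct = pct(lc)))
  if (out$order == 2L) {
    s <- records$synI
    b_lt <- sum(s < 1 - 1e-9)
    b_eq <- sum(abs(s - 1) <= 1e-9)
    b_gt <- sum(s > 1 + 1e-9)
    out$synI_buckets <- data.frame(
      bucket = c("<1", "=1", ">1"),
      count = c(b_lt, b_eq, b_gt),
      pct = c(pct(b_lt), pct(b_eq), pct(b_gt)))
    fl <- records[records$flip == 1L, ]
    if (nrow(fl) > 0L) {
      inv <- sort(table(c(fl$target1, fl$target2)), decreasing = TRUE)
      out$flip_node_involvement <- data.frame(
        node = names(inv), n_flips = as.integer(inv),
        fraction = round(as.integer(inv) / nrow(fl), 4))
    } else {
      out$flip_node_involvement <- data.frame(
        node = character(0), n_flips = integer(0), fraction = numeric(0))
    }
  }
  class(out) <- "bcn_screen_summary"
  out
}

#' @export
print.bcn_screen_summary <- function(x, ...) {
  cat(sprintf("screen summary (order %d): %d records\n", x$order,
              x$n_records))
  cat(sprintf("  delta_pI > +shift: %d (%.2f%%); < -shift: %d (%.2f%%)\n",
              x$shift_up[["count"]], x$shift_up[["pct"]],
              x$shift_down[["count"]], x$shift_down[["pct"]]))
  cat(sprintf("  flips: %d inflammatory, %d tissue-protective\n",
              x$flips_inflammatory, x$flips_tissue_protective))
  cat(sprintf("  limit cycles: %d (%.2f%%)\n",
              x$limit_cycles[["count"]], x$limit_cycles[["pct"]]))
  if (!is.null(x$synI_buckets)) {
    cat("  synI buckets:\n")
    for (k in seq_len(nrow(x$synI_buckets)))
      cat(sprintf("    %s: %d (%.2f%%)\n", x$synI_buckets$bucket[k],
                  x$synI_buckets$count[k], x$synI_buckets$pct[k]))
  }
  invisible(x)
}

#' Flatten a screen summary to key/value pairs
#'
#' @param summary a `bcn_screen_summary`.
#' @return data.frame with columns `key`, `value` (machine-checkable).
#' @export
summary_to_kv <- function(summary) {
  kv <- list(
    n_records = summary$n_records,
    order = summary$order,
    shift_up_count = summary$shift_up[["count"]],
    shift_up_pct = summary$shift_up[["pct"]],
    shift_down_count = summary$shift_down[["count"]],
    shift_down_pct = summary$shift_down[["pct"]],
    flips_inflammatory = summary$flips_inflammatory,
    flips_tissue_protective = summary$flips_tissue_protective,
    limit_cycle_count = summary$limit_cycles[["count"]],
    limit_cycle_pct = summary$limit_cycles[["pct"]])
  if (!is.null(summary$synI_buckets)) {
    kv$synI_lt1_count <- summary$synI_buckets$count[1]
    kv$synI_eq1_count <- summary$synI_buckets$count[2]
    kv$synI_gt1_count <- summary$synI_buckets$count[3]
    kv$synI_lt1_pct <- summary$synI_buckets$pct[1]
    kv$synI_eq1_pct <- summary$synI_buckets$pct[2]
    kv$synI_gt1_pct <- summary$synI_buckets$pct[3]
  }
  data.frame(key = names(kv), value = unlist(kv, use.names = FALSE),
             stringsAsFactors = FALSE)
}

#' Write screen records to TSV
#'
#' @param records a `bcn_screen` data.frame.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_screen_tsv <- function(records, path) {
  utils::write.table(records, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}
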