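# Synchronous threshold dynamics:
#   S[t+1] = thr(W %*% S[t] - theta_eff)
# with environment clamping and perturbations realised purely through
# threshold overrides, so the update rule above is the only dynamics.

#' Threshold (Heaviside) function of the update rule
#'
#' `thr(x) = 1` when `x >= 0`, else 0; vectorised.
#'
#' @param x numeric vector of net activation values.
#' @return integer vector of bits.
#' @export
threshold_function <- function(x) {
  stopifnot(is.numeric(x), all(is.finite(x)))
  as.integer(x >= 0)
}

#' Define an environment (clamped input states)
#'
#' @param active_inputs character vector of input-node ids held active;
#'   all other inputs are held inactive.
#' @return character vector with class `bcn_environment`.
#' @export
environment_of <- function(active_inputs = character(0)) {
  structure(unique(as.character(active_inputs)), class = "bcn_environment")
}

#' Define a perturbation (forced node states)
#'
#' Nodes listed in `inhibited` are immutably held inactive and nodes in
#' `activated` immutably active, modelling 100%-efficient constitutive
#' inhibition/activation via threshold overrides.
#'
#' @param inhibited,activated disjoint character vectors of node ids.
#' @return list with class `bcn_perturbation`.
#' @export
perturbation <- function(inhibited = character(0), activated = character(0)) {
  inhibited <- unique(as.character(inhibited))
  activated <- unique(as.character(activated))
  both <- intersect(inhibited, activated)
  if (length(both) > 0L)
    stop("node(s) both inhibited and activated: ",
         paste(both, collapse = ", "))
  structure(list(inhibited = inhibited, activated = activated),
            class = "bcn_perturbation")
}

check_env <- function(net, env) {
  env <- as.character(env)
  inputs <- node_ids(net, "input")
  bad <- setdiff(env, inputs)
  if (length(bad) > 0L)
    stop("environment names non-input node(s): ", paste(bad, collapse = ", "))
  env
}

#' Effective threshold vector under clamping and perturbation
#'
#' Copies the network's threshold vector and overrides it so that
#' active inputs get threshold 0 (always on: inputs have no incoming
#' edges and `thr(0) = 1`), inactive inputs get `+B`, inhibited nodes
#' `+B` and activated nodes `-B`, where `B = 1 + sum(|W|)` is
#' unreachable by any achievable activation sum.
#'
#' @param net a `bcn` object.
#' @param env environment (character vector of active input ids).
#' @param pert a [perturbation()] or `NULL`.
#' @return named numeric threshold vector.
#' @export
effective_thresholds <- function(net, env = character(0), pert = NULL) {
  env <- check_env(net, env)
  theta <- net$theta
  B <- theta_bound(net)
  inputs <- node_ids(net, "input")
  theta[inputs] <- B
  theta[env] <- 0
  if (!is.null(pert)) {
    if (!inherits(pert, "bcn_perturbation")) pert <- do.call(perturbation, pert)
    unknown <- setdiff(c(pert$inhibited, pert$activated), net$nodes$id)
    if (length(unknown) > 0L)
      stop("perturbation names unknown node(s): ",
           paste(unknown, collapse = ", "))
    theta[pert$inhibited] <- B
    theta[pert$activated] <- -B
  }
  theta
}

#' One synchronous update step
#'
#' @param net a `bcn` object.
#' @param state integer 0/1 vector of length `n_nodes(net)`.
#' @param theta_eff effective threshold vector (see
#'   [effective_thresholds()]); defaults to the network's own.
#' @return the next state (integer 0/1 vector, named by node id).
#' @export
bcn_step <- function(net, state, theta_eff = net$theta) {
  if (length(state) != nrow(net$nodes))
    stop("state length ", length(state), " != node count ", nrow(net$nodes))
  if (length(theta_eff) != nrow(net$nodes))
    stop("threshold vector length mismatch")
  s <- as.integer(drop(net$W %*% as.numeric(state)) - theta_eff >= 0)
  names(s) <- net$nodes$id
  s
}

#' Find the attractor reached from the all-inactive start state
#'
#' Iterates the synchronous update from the all-inactive state at step
#' 0 (inputs switch on at step 1 via their clamped thresholds) and
#' detects the attractor with Brent's power-of-two cycle-finding
#' algorithm, then recovers the exact transient length and the minimal
#' cycle by the standard two-pointer replay.
#'
#' @param net a `bcn` object.
#' @param env active input ids.
#' @param pert a [perturbation()] or `NULL`.
#' @param max_steps cap on update-function evaluations; the state space
#'   is finite so detection always terminates below `2^n`, the cap only
#'   guards pathological inputs.
#' @return an object of class `bcn_attractor`: list with `period`,
#'   `transient` (steps before the first cycle state), `cycle`
#'   (period x n matrix of states, rows in cycle order) and `activity`
#'   (per-node fraction of cycle states in which the node is active).
#' @examples
#' net <- make_fixture("and_gate")
#' a <- find_attractor(net, env = c("IN1", "IN2"))
#' a$period
#' a$activity[["OUT1"]]
#' @export
find_attractor <- function(net, env = character(0), pert = NULL,
                           max_steps = 10000L) {
  stopifnot(max_steps >= 1)
  theta <- effective_thresholds(net, env, pert)
  W <- net$W
  n <- nrow(net$nodes)
  used <- 0L
  f_free <- function(s) as.integer(drop(W %*% as.numeric(s)) - theta >= 0)
  f <- function(s) {
    if (used >= max_steps)
      stop(sprintf("no attractor confirmed within %d steps (env: %s)",
                   max_steps, paste(env, collapse = ",")))
    used <<- used + 1L
    f_free(s)
  }
  x0 <- integer(n)

  # Brent: power-of-two teleporting tortoise; lam = minimal period
  power <- 1L; lam <- 1L
  tortoise <- x0
  hare <- f(x0)
  while (!identical(tortoise, hare)) {
    if (power == lam) {
      tortoise <- hare
      power <- power * 2L
      lam <- 0L
    }
    hare <- f(hare)
    lam <- lam + 1L
  }
  # transient length mu: advance one pointer lam steps, then walk together
  # (replay; cycle existence is already confirmed, so no cap applies)
  tortoise <- x0; hare <- x0
  for (i in seq_len(lam)) hare <- f_free(hare)
  mu <- 0L
  while (!identical(tortoise, hare)) {
    tortoise <- f_free(tortoise)
    hare <- f_free(hare)
    mu <- mu + 1L
  }
  cycle <- matrix(0L, lam, n, dimnames = list(NULL, net$nodes$id))
  s <- tortoise
  for (k in seq_len(lam)) {
    cycle[k, ] <- s
    if (k < lam) s <- f_free(s)
  }
  new_attractor(transient = mu, cycle = cycle)
}

new_attractor <- function(transient, cycle) {
  structure(list(period = nrow(cycle), transient = as.integer(transient),
                 cycle = cycle,
                 activity = colMeans(cycle)),
            class = "bcn_attractor")
}

#' @export
print.bcn_attractor <- function(x, ...) {
  cat(sprintf("attractor: period %d, transient %d, %d/%d nodes ever active\n",
              x$period, x$transient, sum(x$activity > 0),
              length(x$activity)))
  invisible(x)
}

#' Attractors for many environments in one vectorised pass
#'
#' Equivalent to `lapply(environments, find_attractor, ...)` but steps
#' all environments simultaneously as one state matrix (a single
#' matrix product per step) with exact fixed-point detection; any
#' environment that has not settled on a steady state within the batch
#' window is finished off with per-environment Brent detection, so the
#' result is bit-identical to the per-environment path.
#'
#' @param net a `bcn` object.
#' @param environments list of active-input character vectors.
#' @param pert a [perturbation()] or `NULL`.
#' @param max_steps per-environment step cap.
#' @return list of `bcn_attractor`, in the order of `environments`.
#' @export
batch_attractors <- function(net, environments, pert = NULL,
                             max_steps = 10000L) {
  E <- length(environments)
  if (E == 0L) return(list())
  n <- nrow(net$nodes)
  Theta <- vapply(environments,
                  function(e) effective_thresholds(net, e, pert),
                  numeric(n))
  W <- net$W
  S <- matrix(0, n, E)
  done <- logical(E)
  transient <- integer(E)
  fixed <- matrix(0L, n, E)
  cap <- min(max_steps, n + 64L)
  for (t in seq_len(cap)) {
    S2 <- (W %*% S - Theta >= 0) + 0
    newly <- !done & colSums(S2 != S) == 0L
    if (any(newly)) {
      transient[newly] <- t - 1L
      fixed[, newly] <- S2[, newly]
      done <- done | newly
    }
    if (all(done)) break
    S <- S2
  }
  out <- vector("list", E)
  for (j in seq_len(E)) {
    if (done[j]) {
      cyc <- matrix(as.integer(fixed[, j]), 1L, n,
                    dimnames = list(NULL, net$nodes$id))
      out[[j]] <- new_attractor(transient = transient[j], cycle = cyc)
    } else {
      out[[j]] <- tryCatch(
        find_attractor(net, environments[[j]], pert, max_steps),
        error = function(e) stop(sprintf("environment %d: %s", j,
                                         conditionMessage(e)), call. = FALSE))
    }
  }
  out
}

#' Write an attractor to TSV
#'
#' One row per node (`node_id`, `activity_fraction`) preceded by
#' `# period`, `# transient`, `# env`, `# pert` metadata lines.
#'
#' @param attractor a `bcn_attractor`.
#' @param path output file path.
#' @param env,pert the run's environment/perturbation, echoed in the
#'   header.
#' @return invisibly, `path`.
#' @export
write_attractor_tsv <- function(attractor, path, env = character(0),
                                pert = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("# period\t%d", attractor$period),
    sprintf("# transient\t%d", attractor$transient),
    sprintf("# env\t%s", paste(env, collapse = ",")),
    sprintf("# pert\t%s",
            if (is.null(pert)) "" else
              paste(c(sprintf("inhibit:%s", pert$inhibited),
                      sprintf("activate:%s", pert$activated)),
                    collapse = ",")),
    "node_id\tactivity_fraction"), con)
  writeLines(sprintf("%s\t%s", names(attractor$activity),
                     format(attractor$activity, digits = 15, trim = TRUE)),
             con)
  invisible(path)
}
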