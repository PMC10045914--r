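# Literature-criteria verification: each criterion states whether a
# transcriptional output should be active when exactly one input is
# supplied; the model is scored by the fraction of criteria it
# reproduces in unperturbed simulation.

#' Read a verification-criteria table
#'
#' TSV columns: `input_id`, `output_id`, `expected`
#' (`active`/`inactive`), `evidence` (optional PubMed ids).
#'
#' @param path file path.
#' @return data.frame of criteria.
#' @export
read_criteria <- function(path) {
  cr <- utils::read.delim(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE,
                          na.strings = c("NA", ""), quote = "")
  req <- c("input_id", "output_id", "expected")
  missing <- setdiff(req, names(cr))
  if (length(missing) > 0L)
    stop("criteria table lacks column(s): ", paste(missing, collapse = ", "))
  if (is.null(cr$evidence)) cr$evidence <- ""
  cr$evidence[is.na(cr$evidence)] <- ""
  bad <- setdiff(unique(cr$expected), c("active", "inactive"))
  if (length(bad) > 0L)
    stop("unknown expectation value(s): ", paste(bad, collapse = ", "))
  cr
}

#' Score the model against single-input criteria
#'
#' For each criterion the network is simulated unperturbed with only
#' the criterion's input active, and the attractor activity of the
#' output node is compared with the expectation. A steady state gives
#' a crisp 0/1 activity; for a limit cycle an activity fraction of at
#' least 0.5 counts as active.
#'
#' @param net a `bcn`.
#' @param criteria data.frame from [read_criteria()] (or equivalent).
#' @return list of class `bcn_verification`: `results` (per-criterion
#'   data.frame with `observed_activity` and `pass`), `n_pass`,
#'   `n_total`, `score` (fraction), `match_pct` (2 decimals).
#' @export
run_verification <- function(net, criteria) {
  criteria <- as.data.frame(criteria, stringsAsFactors = FALSE)
  if (nrow(criteria) == 0L)
    stop("verification score undefined for an empty criteria list")
  ids <- net$nodes$id
  unknown <- setdiff(unique(c(criteria$input_id, criteria$output_id)), ids)
  if (length(unknown) > 0L)
    stop("criteria reference unknown node(s): ",
         paste(unknown, collapse = ", "))
  not_in <- unique(criteria$input_id[
    !criteria$input_id %in% node_ids(net, "input")])
  if (length(not_in) > 0L)
    stop("criteria input(s) not input-class: ", paste(not_in, collapse = ", "))
  not_out <- unique(criteria$output_id[
    !criteria$output_id %in% node_ids(net, "output")])
  if (length(not_out) > 0L)
    stop("criteria output(s) not output-class: ",
         paste(not_out, collapse = ", "))

  # one attractor per distinct single-input stimulus
  stim <- unique(criteria$input_id)
  atts <- batch_attractors(net, as.list(stim))
  names(atts) <- stim
  obs <- vapply(seq_len(nrow(criteria)), function(k) {
    atts[[criteria$input_id[k]]]$activity[[criteria$output_id[k]]]
  }, numeric(1))
  active <- obs >= 0.5
  pass <- active == (criteria$expected == "active")
  res <- cbind(criteria,
               data.frame(observed_activity = obs, pass = pass))
  structure(list(results = res, n_pass = sum(pass),
                 n_total = nrow(criteria),
                 score = sum(pass) / nrow(criteria),
                 match_pct = round(100 * sum(pass) / nrow(criteria), 2)),
            class = "bcn_verification")
}

#' @export
print.bcn_verification <- function(x, ...) {
  cat(sprintf("verification: %d of %d criteria satisfied (%.2f%% match)\n",
              x$n_pass, x$n_total, x$match_pct))
  invisible(x)
}
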