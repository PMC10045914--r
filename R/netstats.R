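# Structural statistics of the directed interaction graph: total-degree
# distribution, log-log power-law fit with optional outlier-degree
# exclusion, and betweenness centrality (topological: edge signs are
# ignored, edges unweighted).

#' Total-degree distribution
#'
#' Total degree = in-degree + out-degree on the directed simple edge
#' set.
#'
#' @param net a `bcn`.
#' @return list of class `bcn_degree_distribution`: `table`
#'   (data.frame `degree`, `count`), `node_degrees` (named integer
#'   vector).
#' @export
degree_distribution <- function(net) {
  deg <- stats::setNames(integer(nrow(net$nodes)), net$nodes$id)
  if (nrow(net$edges) > 0L) {
    t_in <- table(net$edges$target)
    t_out <- table(net$edges$source)
    deg[names(t_in)] <- deg[names(t_in)] + as.integer(t_in)
    deg[names(t_out)] <- deg[names(t_out)] + as.integer(t_out)
  }
  tab <- if (length(deg) > 0L) {
    tt <- table(deg)
    data.frame(degree = as.integer(names(tt)), count = as.integer(tt))
  } else data.frame(degree = integer(0), count = integer(0))
  structure(list(table = tab, node_degrees = deg),
            class = "bcn_degree_distribution")
}

#' Power-law fit to a degree distribution
#'
#' Ordinary least squares of `log(count)` on `log(degree)` over the
#' included degree classes with positive count; the exponent is the
#' negated slope. Degrees listed in `exclude` (e.g. classes inflated by
#' the input/output layering or by technical nodes) are left out of the
#' regression.
#'
#' @param dist a `bcn_degree_distribution`.
#' @param exclude integer vector of degree values to exclude.
#' @return list with `exponent`, `r_squared`, and the `lm` fit.
#' @export
power_law_fit <- function(dist, exclude = integer(0)) {
  tab <- dist$table
  use <- tab$count > 0 & tab$degree > 0 & !tab$degree %in% exclude
  if (sum(use) < 3L)
    stop("power-law fit needs at least 3 usable degree classes, got ",
         sum(use))
  d <- tab[use, ]
  fit <- stats::lm(log(count) ~ log(degree), data = d)
  # suppressWarnings: lm warns on an exactly power-law histogram
  # ("essentially perfect fit"), which is a legitimate input here
  r2 <- suppressWarnings(summary(fit)$r.squared)
  list(exponent = -unname(stats::coef(fit)[2]),
       r_squared = r2,
       fit = fit)
}

#' Betweenness centrality
#'
#' Directed shortest-path betweenness with edges unweighted and
#' inhibitory signs ignored (centrality here is topological, not
#' dynamical). When `normalized`, values are divided by
#' `(n-1)(n-2)`, the number of ordered source/target pairs a node can
#' mediate in a directed graph.
#'
#' @param net a `bcn`.
#' @param normalized divide by `(n-1)(n-2)`? Default TRUE.
#' @return named numeric vector over all nodes.
#' @export
betweenness_centrality <- function(net, normalized = TRUE) {
  g <- as_igraph(net)
  b <- igraph::betweenness(g, directed = TRUE, weights = NA)
  n <- nrow(net$nodes)
  if (normalized && n > 2L) b <- b / ((n - 1) * (n - 2))
  b[net$nodes$id]
}

#' Write structural statistics to TSV files
#'
#' Writes `<prefix>.degree_hist.tsv` (`degree`, `count`) and
#' `<prefix>.centrality.tsv` (`node_id`, `degree`, `betweenness`,
#' descending by betweenness).
#'
#' @param net a `bcn`.
#' @param prefix output path prefix.
#' @param normalized passed to [betweenness_centrality()].
#' @return invisibly, the two paths.
#' @export
write_netstats_tsv <- function(net, prefix, normalized = TRUE) {
  dd <- degree_distribution(net)
  bc <- betweenness_centrality(net, normalized = normalized)
  hp <- paste0(prefix, ".degree_hist.tsv")
  cp <- paste0(prefix, ".centrality.tsv")
  utils::write.table(dd$table, hp, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  ct <- data.frame(node_id = names(bc),
                   degree = unname(dd$node_degrees[names(bc)]),
                   betweenness = unname(bc))
  ct <- ct[order(-ct$betweenness, ct$node_id), ]
  utils::write.table(ct, cp, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(degree_hist = hp, centrality = cp))
}
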