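#' @keywords internal
"_PACKAGE"

NODE_CLASSES <- c("input", "inner", "output")
POLARITIES <- c("type1", "type2", "none")

#' Construct a Boolean control network
#'
#' Builds the static model object from a node table and an edge table:
#' the signed weight matrix `W` (row = target, column = source), the
#' threshold vector `theta`, and an id-to-position index. Most users
#' load networks from files with [load_network()] or create them with
#' [make_fixture()] / [generate_random_bcn()]; this constructor is the
#' common back end.
#'
#' @param nodes data.frame with columns `id`, `name`, `class`
#'   (`input`/`inner`/`output`), `is_receptor`, `is_technical`,
#'   `is_constitutive` (logical), `polarity`
#'   (`type1`/`type2`/`none`) and `threshold` (numeric).
#' @param edges data.frame with columns `source`, `target`, `weight`
#'   (nonzero; negative = inhibition) and `evidence` (character,
#'   semicolon-separated PubMed ids, may be empty).
#' @return An object of class `bcn`: a list with elements `nodes`,
#'   `edges`, `W`, `theta` and `index`.
#' @seealso [load_network()], [validate_network()]
#' @export
new_bcn <- function(nodes, edges) {
  nodes <- as.data.frame(nodes, stringsAsFactors = FALSE)
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  req_n <- c("id", "name", "class", "is_receptor", "is_technical",
             "is_constitutive", "polarity", "threshold")
  missing_n <- setdiff(req_n, names(nodes))
  if (length(missing_n) > 0L)
    stop("node table lacks column(s): ", paste(missing_n, collapse = ", "))
  req_e <- c("source", "target", "weight")
  missing_e <- setdiff(req_e, names(edges))
  if (length(missing_e) > 0L)
    stop("edge table lacks column(s): ", paste(missing_e, collapse = ", "))
  if (is.null(edges$evidence)) edges$evidence <- rep("", nrow(edges))
  edges$evidence[is.na(edges$evidence)] <- ""

  nodes$id <- as.character(nodes$id)
  if (anyDuplicated(nodes$id))
    stop("duplicate node id(s): ",
         paste(unique(nodes$id[duplicated(nodes$id)]), collapse = ", "))
  bad_class <- setdiff(unique(nodes$class), NODE_CLASSES)
  if (length(bad_class) > 0L)
    stop("unknown node class(es): ", paste(bad_class, collapse = ", "))
  for (fl in c("is_receptor", "is_technical", "is_constitutive"))
    nodes[[fl]] <- as.logical(nodes[[fl]])
  nodes$polarity[is.na(nodes$polarity) | nodes$polarity == ""] <- "none"
  bad_pol <- setdiff(unique(nodes$polarity), POLARITIES)
  if (length(bad_pol) > 0L)
    stop("unknown polarity value(s): ", paste(bad_pol, collapse = ", "))
  nodes$threshold <- as.numeric(nodes$threshold)
  # blank/NA thresholds: 1.0 ordinarily, 0.0 for constitutively active nodes
  # (thr(0) = 1, so theta = 0 keeps a source-less node permanently on)
  na_thr <- is.na(nodes$threshold)
  nodes$threshold[na_thr] <- ifelse(nodes$is_constitutive[na_thr], 0, 1)

  n <- nrow(nodes)
  idx <- stats::setNames(seq_len(n), nodes$id)

  edges$source <- as.character(edges$source)
  edges$target <- as.character(edges$target)
  unknown <- setdiff(c(edges$source, edges$target), nodes$id)
  if (length(unknown) > 0L)
    stop("edge endpoint(s) not in node table: ",
         paste(unknown, collapse = ", "))
  key <- paste(edges$source, edges$target, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- unique(key[duplicated(key)])
    stop("duplicate edge(s): ",
         paste(gsub("\r", " -> ", dup), collapse = ", "))
  }
  edges$weight <- as.numeric(edges$weight)
  if (any(!is.finite(edges$weight) | edges$weight == 0))
    stop("edge weights must be finite and nonzero")

  W <- matrix(0, n, n, dimnames = list(nodes$id, nodes$id))
  if (nrow(edges) > 0L)
    W[cbind(idx[edges$target], idx[edges$source])] <- edges$weight

  structure(
    list(nodes = nodes, edges = edges, W = W,
         theta = stats::setNames(nodes$threshold, nodes$id), index = idx),
    class = "bcn")
}

#' @export
print.bcn <- function(x, ...) {
  tab <- table(factor(x$nodes$class, levels = NODE_CLASSES))
  cat(sprintf(
    "Boolean control network: %d nodes (%d input / %d inner / %d output), %d edges\n",
    nrow(x$nodes), tab[["input"]], tab[["inner"]], tab[["output"]],
    nrow(x$edges)))
  n_inh <- sum(x$edges$weight < 0)
  cat(sprintf("  inhibitory edges: %d; AND-gate (|w| < 1) edges: %d\n",
              n_inh, sum(abs(x$edges$weight) < 1)))
  invisible(x)
}

#' Node ids of a network, optionally filtered by class
#' @param net a `bcn` object.
#' @param class `NULL` (all nodes) or a subset of
#'   `c("input", "inner", "output")`.
#' @return character vector of node ids in node-table order.
#' @export
node_ids <- function(net, class = NULL) {
  if (is.null(class)) return(net$nodes$id)
  net$nodes$id[net$nodes$class %in% class]
}

#' Number of nodes in a network
#' @param net a `bcn` object.
#' @return integer node count.
#' @export
n_nodes <- function(net) nrow(net$nodes)

# unreachable bound used for threshold overrides: no achievable input sum
# can cross a threshold shifted by +/- B
theta_bound <- function(net) 1 + sum(abs(net$W))
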