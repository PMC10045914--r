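# Canonical tabular interchange:
#   nodes.tsv: id, name, class, is_receptor, is_technical, is_constitutive,
#              polarity, threshold (blank -> default)
#   edges.tsv: source, target, weight, evidence (";"-separated PubMed ids)

read_table_file <- function(path, sheet = NULL) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("xlsx", "xls")) {
    if (!requireNamespace("readxl", quietly = TRUE))
      stop("reading spreadsheets requires the 'readxl' package")
    as.data.frame(readxl::read_excel(path, sheet = sheet),
                  stringsAsFactors = FALSE)
  } else {
    utils::read.delim(path, sep = "\t", header = TRUE,
                      stringsAsFactors = FALSE, na.strings = c("NA", ""),
                      quote = "", comment.char = "", check.names = TRUE)
  }
}

#' Load a Boolean control network from node and edge tables
#'
#' Reads the canonical tab-separated tables (or spreadsheet sheets named
#' `"nodes"` and `"edges"` when both paths point at the same `.xlsx`
#' file) and assembles a validated [new_bcn()] object. Blank thresholds
#' default to 1.0, or 0.0 for constitutively active nodes.
#'
#' @param nodes_table path to the node table (TSV or xlsx).
#' @param edges_table path to the edge table (TSV or xlsx).
#' @param quiet suppress the per-class count message.
#' @return a `bcn` object.
#' @examples
#' net <- make_fixture("and_gate")
#' paths <- export_network(net, file.path(tempdir(), "andgate"), "tsv")
#' load_network(paths[1], paths[2], quiet = TRUE)
#' @export
load_network <- function(nodes_table, edges_table, quiet = FALSE) {
  is_xlsx <- tolower(tools::file_ext(nodes_table)) %in% c("xlsx", "xls")
  nodes <- read_table_file(nodes_table, sheet = if (is_xlsx) "nodes")
  edges <- read_table_file(edges_table,
                           sheet = if (tolower(tools::file_ext(edges_table))
                                       %in% c("xlsx", "xls")) "edges")
  for (col in c("name", "polarity"))
    if (is.null(nodes[[col]])) nodes[[col]] <- NA_character_
  nodes$name[is.na(nodes$name)] <- nodes$id[is.na(nodes$name)]
  for (col in c("is_receptor", "is_technical", "is_constitutive"))
    if (is.null(nodes[[col]])) nodes[[col]] <- FALSE
  if (is.null(nodes$threshold)) nodes$threshold <- NA_real_
  net <- new_bcn(nodes, edges)
  if (!quiet) {
    tab <- table(factor(net$nodes$class, levels = NODE_CLASSES))
    message(sprintf("loaded %d nodes (%d input, %d inner, %d output), %d edges",
                    nrow(net$nodes), tab[["input"]], tab[["inner"]],
                    tab[["output"]], nrow(net$edges)))
  }
  net
}

#' Validate network invariants
#'
#' Checks the structural rules of the model: unique ids, legal class
#' and polarity values, no zero-weight or duplicate edges, inputs
#' without incoming edges, outputs without outgoing edges (unless
#' flagged technical/constitutive), constitutive nodes without incoming
#' edges, no isolated inner nodes, and consistency between the edge
#' list and the weight matrix. Violations are returned as data, not
#' raised as errors.
#'
#' @param net a `bcn` object.
#' @return data.frame with columns `item` (node/edge id) and `rule`
#'   (human-readable rule name); zero rows when the network is valid.
#' @export
validate_network <- function(net) {
  v <- list()
  add <- function(item, rule) v[[length(v) + 1L]] <<- data.frame(
    item = item, rule = rule, stringsAsFactors = FALSE)

  nd <- net$nodes
  ed <- net$edges
  if (anyDuplicated(nd$id))
    add(paste(unique(nd$id[duplicated(nd$id)]), collapse = ","),
        "duplicate node id")
  bad_class <- nd$id[!nd$class %in% NODE_CLASSES]
  for (id in bad_class) add(id, "unknown class")
  bad_pol <- nd$id[nd$polarity %in% c("type1", "type2") &
                     !nd$class %in% c("input", "output")]
  for (id in bad_pol) add(id, "polarity on non-input/output node")

  if (nrow(ed) > 0L) {
    zero <- ed$weight == 0 | !is.finite(ed$weight)
    for (k in which(zero))
      add(paste(ed$source[k], ed$target[k], sep = "->"), "zero-weight edge")
    key <- paste(ed$source, ed$target)
    for (k in which(duplicated(key)))
      add(paste(ed$source[k], ed$target[k], sep = "->"), "duplicate edge")
  }

  in_deg <- stats::setNames(integer(nrow(nd)), nd$id)
  out_deg <- in_deg
  if (nrow(ed) > 0L) {
    ti <- table(ed$target[ed$target %in% nd$id])
    to <- table(ed$source[ed$source %in% nd$id])
    in_deg[names(ti)] <- as.integer(ti)
    out_deg[names(to)] <- as.integer(to)
  }
  for (id in nd$id[nd$class == "input" & in_deg[nd$id] > 0])
    add(id, "input node with incoming edge")
  for (id in nd$id[nd$class == "output" & out_deg[nd$id] > 0 &
                     !(nd$is_technical | nd$is_constitutive)])
    add(id, "output node with outgoing edge")
  for (id in nd$id[nd$is_constitutive & in_deg[nd$id] > 0])
    add(id, "constitutive node with incoming edge")
  for (id in nd$id[nd$class == "inner" & in_deg[nd$id] == 0 &
                     !nd$is_constitutive])
    add(id, "isolated inner node")

  # W must mirror the edge list exactly
  W2 <- matrix(0, nrow(nd), nrow(nd), dimnames = dimnames(net$W))
  if (nrow(ed) > 0L) {
    ok <- ed$source %in% nd$id & ed$target %in% nd$id
    W2[cbind(ed$target[ok], ed$source[ok])] <- ed$weight[ok]
    for (id in ed$source[!ok]) add(id, "edge endpoint missing from node table")
    for (id in ed$target[!ok]) add(id, "edge endpoint missing from node table")
  }
  if (!isTRUE(all.equal(W2, net$W, check.attributes = FALSE)))
    add("W", "weight matrix inconsistent with edge list")
  if (length(net$theta) != nrow(nd))
    add("theta", "threshold vector length mismatch")

  if (length(v) == 0L)
    data.frame(item = character(0), rule = character(0),
               stringsAsFactors = FALSE)
  else unique(do.call(rbind, v))
}

#' Export a network to TSV, SIF or GraphML
#'
#' The TSV export writes the canonical `<path>.nodes.tsv` and
#' `<path>.edges.tsv` pair and round-trips exactly through
#' [load_network()]. SIF uses `source<TAB>activates|inhibits<TAB>target`
#' and GraphML stores `weight` (double) and `class` (string) node/edge
#' attributes; both are lossy one-way exports.
#'
#' @param net a `bcn` object.
#' @param path output path; for `tsv` a prefix (two files are written),
#'   otherwise the file path itself.
#' @param format one of `"tsv"`, `"sif"`, `"graphml"`.
#' @return invisibly, the path(s) written.
#' @export
export_network <- function(net, path, format = c("tsv", "sif", "graphml")) {
  format <- match.arg(format)
  if (format == "tsv") {
    np <- paste0(path, ".nodes.tsv")
    ep <- paste0(path, ".edges.tsv")
    nd <- net$nodes
    for (fl in c("is_receptor", "is_technical", "is_constitutive"))
      nd[[fl]] <- as.integer(nd[[fl]])
    utils::write.table(nd, np, sep = "\t", quote = FALSE, row.names = FALSE,
                       na = "")
    utils::write.table(net$edges, ep, sep = "\t", quote = FALSE,
                       row.names = FALSE, na = "")
    return(invisible(c(nodes = np, edges = ep)))
  }
  if (format == "sif") {
    rel <- ifelse(net$edges$weight < 0, "inhibits", "activates")
    writeLines(paste(net$edges$source, rel, net$edges$target, sep = "\t"),
               path)
    return(invisible(path))
  }
  g <- as_igraph(net)
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' Convert a network to an igraph object
#'
#' Directed simple graph carrying `class` (vertex) and `weight` (edge)
#' attributes; used by the structural-statistics functions and the
#' GraphML export.
#'
#' @param net a `bcn` object.
#' @return an `igraph` graph.
#' @export
as_igraph <- function(net) {
  igraph::graph_from_data_frame(
    d = data.frame(from = net$edges$source, to = net$edges$target,
                   weight = net$edges$weight, stringsAsFactors = FALSE),
    directed = TRUE,
    vertices = data.frame(name = net$nodes$id, class = net$nodes$class,
                          stringsAsFactors = FALSE))
}
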