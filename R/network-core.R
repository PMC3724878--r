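#' Construct a threshold Boolean network
#'
#' Builds a validated \linkS4class{ThresholdNetwork} from a node table and an
#' edge table, applying the model's defaults: a missing \code{threshold}
#' column (or \code{NA} entries) defaults to 0, a missing \code{is_input}
#' column to \code{FALSE}, and a missing \code{strength} column to magnitude 1
#' with the sign taken from an \code{effect} column (\code{"activation"} /
#' \code{"inhibition"}, or \code{"+"} / \code{"-"}).
#'
#' @param nodes data.frame with at least a \code{name} column.
#' @param edges data.frame with \code{source} and \code{target} columns and
#'   either a \code{strength} or an \code{effect} column.
#' @param metadata optional provenance list.
#' @return a \linkS4class{ThresholdNetwork}.
#' @examples
#' net <- thresholdNetwork(
#'   nodes = data.frame(name = c("A", "B")),
#'   edges = data.frame(source = "A", target = "B", effect = "activation"))
#' thresholds(net)   # both default to 0
#' @export
thresholdNetwork <- function(nodes, edges, metadata = list()) {
  nodes <- as.data.frame(nodes, stringsAsFactors = FALSE)
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  if (!"name" %in% names(nodes))
    stop("node table must have a 'name' column", call. = FALSE)
  nodes$name <- as.character(nodes$name)
  if (!"threshold" %in% names(nodes)) nodes$threshold <- 0L
  nodes$threshold[is.na(nodes$threshold)] <- 0L
  nodes$threshold <- as.integer(nodes$threshold)
  if (!"is_input" %in% names(nodes)) nodes$is_input <- FALSE
  nodes$is_input <- .as_flag(nodes$is_input)
  nodes <- nodes[, c("name", "threshold", "is_input")]

  if (nrow(edges)) {
    if (!all(c("source", "target") %in% names(edges)))
      stop("edge table must have 'source' and 'target' columns", call. = FALSE)
    edges$source <- as.character(edges$source)
    edges$target <- as.character(edges$target)
    if (!"strength" %in% names(edges)) edges$strength <- NA_integer_
    edges$strength <- suppressWarnings(as.integer(edges$strength))
    if (anyNA(edges$strength)) {
      if (!"effect" %in% names(edges))
        stop("edges without explicit strength need an 'effect' column",
             call. = FALSE)
      sgn <- .effect_sign(edges$effect)
      miss <- is.na(edges$strength)
      edges$strength[miss] <- sgn[miss]
    }
    edges <- edges[, c("source", "target", "strength")]
  } else {
    edges <- data.frame(source = character(), target = character(),
                        strength = integer(), stringsAsFactors = FALSE)
  }
  rownames(nodes) <- NULL
  rownames(edges) <- NULL
  new("ThresholdNetwork", nodes = nodes, edges = edges, metadata = metadata)
}

.as_flag <- function(x) {
  if (is.logical(x)) return(ifelse(is.na(x), FALSE, x))
  if (is.numeric(x)) return(!is.na(x) & x != 0)
  x <- tolower(trimws(as.character(x)))
  x %in% c("true", "t", "1", "yes", "y")
}

.effect_sign <- function(effect) {
  e <- tolower(trimws(as.character(effect)))
  sgn <- ifelse(e %in% c("activation", "activates", "activating", "+", "1"), 1L,
         ifelse(e %in% c("inhibition", "inhibits", "inhibiting", "-", "-1"),
                -1L, NA_integer_))
  if (anyNA(sgn))
    stop("unrecognized effect value(s) in edge row(s): ",
         paste(which(is.na(sgn)), collapse = ", "), call. = FALSE)
  sgn
}

#' Read / write a network as TSV tables
#'
#' The node table is a TSV with header \code{name threshold is_input}; the
#' edge table a TSV with header \code{source target strength} (a SIF-like
#' dialect with explicit signed integer weights). \code{readNetwork} and
#' \code{writeNetwork} round-trip all fields.
#'
#' @param nodeFile,edgeFile paths to the TSV tables.
#' @param net a \linkS4class{ThresholdNetwork}.
#' @return \code{readNetwork}: a \linkS4class{ThresholdNetwork};
#'   \code{writeNetwork}: invisibly, the two paths written.
#' @export
readNetwork <- function(nodeFile, edgeFile) {
  nodes <- utils::read.delim(nodeFile, stringsAsFactors = FALSE,
                             comment.char = "#")
  edges <- utils::read.delim(edgeFile, stringsAsFactors = FALSE,
                             comment.char = "#")
  thresholdNetwork(nodes, edges,
                   metadata = list(node_file = nodeFile, edge_file = edgeFile))
}

#' @rdname readNetwork
#' @export
writeNetwork <- function(net, nodeFile, edgeFile) {
  stopifnot(is(net, "ThresholdNetwork"))
  utils::write.table(nodeTable(net), nodeFile, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(edgeTable(net), edgeFile, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(nodeFile, edgeFile))
}

#' Export a network to GraphML for visualization
#'
#' @param net a \linkS4class{ThresholdNetwork}.
#' @param file output path.
#' @export
exportGraphML <- function(net, file) {
  g <- asIgraph(net)
  igraph::write_graph(g, file, format = "graphml")
  invisible(file)
}

#' Convert a threshold network to an igraph object
#'
#' Node attributes \code{threshold} and \code{is_input} and the edge attribute
#' \code{strength} are carried over.
#'
#' @param net a \linkS4class{ThresholdNetwork}.
#' @return a directed \code{igraph} graph.
#' @export
asIgraph <- function(net) {
  igraph::graph_from_data_frame(
    edgeTable(net), directed = TRUE,
    vertices = nodeTable(net)[, c("name", "threshold", "is_input")])
}

## ---- accessors -------------------------------------------------------------

#' Accessors for ThresholdNetwork objects
#'
#' @param x a \linkS4class{ThresholdNetwork}.
#' @name ThresholdNetwork-accessors
#' @aliases nNodes nEdges nodeNames inputNodes thresholds edgeTable nodeTable
NULL

#' @rdname ThresholdNetwork-accessors
#' @export
setMethod("nNodes", "ThresholdNetwork", function(x) nrow(x@nodes))

#' @rdname ThresholdNetwork-accessors
#' @export
setMethod("nEdges", "ThresholdNetwork", function(x) nrow(x@edges))

#' @rdname ThresholdNetwork-accessors
#' @export
setMethod("nodeNames", "ThresholdNetwork", function(x) x@nodes$name)

#' @rdname ThresholdNetwork-accessors
#' @export
setMethod("inputNodes", "ThresholdNetwork",
          function(x) x@nodes$name[x@nodes$is_input])

#' @rdname ThresholdNetwork-accessors
#' @export
setMethod("thresholds", "ThresholdNetwork",
          function(x) setNames(x@nodes$threshold, x@nodes$name))

#' @rdname ThresholdNetwork-accessors
#' @export
setMethod("edgeTable", "ThresholdNetwork", function(x) x@edges)

#' @rdname ThresholdNetwork-accessors
#' @export
setMethod("nodeTable", "ThresholdNetwork", function(x) x@nodes)

setMethod("show", "ThresholdNetwork", function(object) {
  cat(sprintf("ThresholdNetwork: %d nodes, %d edges (%d input nodes)\n",
              nNodes(object), nEdges(object), length(inputNodes(object))))
  if (length(inputNodes(object)))
    cat("  inputs:", paste(inputNodes(object), collapse = ", "), "\n")
  if (!is.null(object@metadata$name))
    cat("  model:", object@metadata$name, "\n")
})

## ---- microenvironments -----------------------------------------------------

#' Microenvironments: binary assignments of the input nodes
#'
#' A microenvironment fixes every input node of the network to 0 or 1. It is
#' written as a binary code over the input nodes in their network order, most
#' significant bit first (for the built-in cancer network: carcinogens, growth
#' factors, nutrients, TNF-alpha, hypoxia — so \code{"00100"} is normoxia with
#' adequate nutrients and no growth signaling).
#'
#' @param net a \linkS4class{ThresholdNetwork}.
#' @param code a binary string such as \code{"00100"}, or a named 0/1 vector
#'   covering exactly the input nodes.
#' @return \code{microenvironment}: a named integer vector over the input
#'   nodes; \code{environmentCode}: the binary string; \code{allEnvironments}:
#'   character vector of all codes.
#' @examples
#' net <- exampleToggleNetwork()
#' @export
microenvironment <- function(net, code) {
  inp <- inputNodes(net)
  if (is.character(code) && length(code) == 1L) {
    bits <- as.integer(strsplit(code, "")[[1]])
    if (length(bits) != length(inp) || anyNA(bits) || !all(bits %in% 0:1))
      stop("environment code must be a ", length(inp),
           "-character binary string", call. = FALSE)
    return(setNames(bits, inp))
  }
  v <- code
  if (is.null(names(v)) || !setequal(names(v), inp))
    stop("microenvironment must cover exactly the input nodes: ",
         paste(inp, collapse = ", "), call. = FALSE)
  if (!all(v %in% 0:1)) stop("microenvironment values must be 0/1", call. = FALSE)
  setNames(as.integer(v[inp]), inp)
}

#' @rdname microenvironment
#' @param env a named microenvironment vector.
#' @export
environmentCode <- function(env) paste(as.integer(env), collapse = "")

#' @rdname microenvironment
#' @export
allEnvironments <- function(net) {
  k <- length(inputNodes(net))
  if (k == 0L) return("")
  apply(as.matrix(expand.grid(rep(list(0:1), k)))[, k:1, drop = FALSE], 1L,
        paste, collapse = "")
}

## ---- toy example -----------------------------------------------------------

#' Two-node mutual-activation toy network
#'
#' Nodes A and B activate each other (+1, thresholds 0); the synchronous
#' dynamics has two fixed points, (0,0) and (1,1), and one period-2 cycle.
#' Used in examples and tests.
#'
#' @return a \linkS4class{ThresholdNetwork}.
#' @export
exampleToggleNetwork <- function() {
  thresholdNetwork(
    nodes = data.frame(name = c("A", "B")),
    edges = data.frame(source = c("A", "B"), target = c("B", "A"),
                       strength = c(1L, 1L)),
    metadata = list(name = "two-node mutual activation"))
}

## ---- compiled form for the dynamics core ----------------------------------

# Flatten a network plus clamp set into the integer arrays the C++ core wants.
# Inputs behave as clamped nodes; `state0` supplies their values when they are
# not explicitly clamped.
.compiled <- function(net, clamps = NULL, state0 = NULL) {
  nm <- nodeNames(net)
  n <- length(nm)
  idx <- setNames(seq_len(n), nm)
  ed <- edgeTable(net)
  ord <- order(match(ed$target, nm))
  ed <- ed[ord, , drop = FALSE]
  cnt <- tabulate(match(ed$target, nm), nbins = n)
  in_ptr <- c(0L, cumsum(cnt))
  clamp_mask <- integer(n)
  clamp_val <- integer(n)
  is_inp <- nodeTable(net)$is_input
  clamp_mask[is_inp] <- 1L
  if (!is.null(state0)) clamp_val[is_inp] <- as.integer(state0[is_inp])
  if (length(clamps)) {
    j <- idx[names(clamps)]
    if (anyNA(j))
      stop("unknown clamped node(s): ",
           paste(names(clamps)[is.na(j)], collapse = ", "), call. = FALSE)
    clamp_mask[j] <- 1L
    clamp_val[j] <- as.integer(clamps)
  }
  list(in_ptr = as.integer(in_ptr),
       in_src = as.integer(idx[ed$source] - 1L),
       in_w = as.integer(ed$strength),
       theta = as.integer(thresholds(net)),
       clamp_mask = clamp_mask, clamp_val = clamp_val,
       names = nm)
}
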