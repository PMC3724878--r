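#' Structural characterization of a network
#'
#' Computes node/edge counts, mean connectivity (edges per node), the
#' characteristic (mean shortest) path length, the average local clustering
#' coefficient, in/out-degree distributions and betweenness centrality.
#'
#' Two clustering conventions are offered. \code{"directed_links"} (default)
#' counts the number of directed edges among a node's neighbours (neighbours
#' taken in the undirected sense) over \code{k (k - 1)} ordered pairs, so a
#' directed Erdős–Rényi graph has expected clustering equal to its directed
#' density \code{m / (n (n - 1))}. \code{"undirected"} is the classic local
#' clustering of the undirected simple projection. Nodes with fewer than two
#' neighbours are excluded from the average. Path length is measured on the
#' undirected projection by default, averaged over connected pairs only, with
#' the number of disconnected pairs reported; betweenness is computed on the
#' directed graph by default (signal flow), unnormalized.
#'
#' @param net a \linkS4class{ThresholdNetwork}.
#' @param clustering \code{"directed_links"} or \code{"undirected"}.
#' @param paths \code{"undirected"} or \code{"directed"}.
#' @param betweenness \code{"directed"} or \code{"undirected"}.
#' @return list with elements \code{n_nodes}, \code{n_edges},
#'   \code{mean_connectivity}, \code{char_path_length},
#'   \code{disconnected_pairs}, \code{clustering}, \code{in_degree_dist},
#'   \code{out_degree_dist} (data.frames \code{k}, \code{p}),
#'   \code{betweenness} (named vector), \code{conventions}.
#' @export
topologyReport <- function(net,
                           clustering = c("directed_links", "undirected"),
                           paths = c("undirected", "directed"),
                           betweenness = c("directed", "undirected")) {
  clustering <- match.arg(clustering)
  paths <- match.arg(paths)
  betweenness <- match.arg(betweenness)
  stopifnot(nNodes(net) > 0)
  g <- asIgraph(net)
  gu <- igraph::as_undirected(g, mode = "collapse")

  deg_in <- igraph::degree(g, mode = "in")
  deg_out <- igraph::degree(g, mode = "out")
  dist_of <- function(d) {
    tb <- table(factor(d, levels = 0:max(d)))
    data.frame(k = as.integer(names(tb)), p = as.numeric(tb) / length(d))
  }

  gp <- if (paths == "undirected") gu else g
  dm <- igraph::distances(gp, mode = "out")
  offdiag <- dm[row(dm) != col(dm)]
  finite <- is.finite(offdiag)
  cpl <- if (any(finite)) mean(offdiag[finite]) else NA_real_

  cc <- if (clustering == "undirected") {
    vals <- igraph::transitivity(gu, type = "local", isolates = "NaN")
    mean(vals, na.rm = TRUE)
  } else {
    .directed_link_clustering(net)
  }

  btw <- igraph::betweenness(if (betweenness == "directed") g else gu,
                             directed = betweenness == "directed")

  list(n_nodes = nNodes(net),
       n_edges = nEdges(net),
       mean_connectivity = nEdges(net) / nNodes(net),
       char_path_length = cpl,
       disconnected_pairs = sum(!finite),
       clustering = cc,
       in_degree_dist = dist_of(deg_in),
       out_degree_dist = dist_of(deg_out),
       betweenness = btw,
       conventions = list(clustering = clustering, paths = paths,
                          betweenness = betweenness))
}

# mean over nodes with >= 2 neighbours of
#   (# directed edges among neighbours) / (k (k - 1))
.directed_link_clustering <- function(net) {
  nm <- nodeNames(net)
  n <- length(nm)
  A <- matrix(0L, n, n, dimnames = list(nm, nm))
  ed <- edgeTable(net)
  ed <- ed[ed$source != ed$target, , drop = FALSE]  # self-loops excluded
  A[cbind(match(ed$source, nm), match(ed$target, nm))] <- 1L
  U <- (A + t(A)) > 0
  vals <- vapply(seq_len(n), function(i) {
    nbr <- which(U[i, ])
    k <- length(nbr)
    if (k < 2) return(NA_real_)
    sum(A[nbr, nbr]) / (k * (k - 1))
  }, numeric(1))
  mean(vals, na.rm = TRUE)
}

#' Topology of a random-network null ensemble
#'
#' Generates \code{nReplicates} random networks matched to the given node and
#' edge counts (see \code{\link{randomNetwork}}), computes a
#' \code{\link{topologyReport}} for each, and returns the ensemble mean and
#' standard deviation of the scalar metrics.
#'
#' @inheritParams randomNetwork
#' @param nReplicates ensemble size (>= 2).
#' @param seed base seed; replicate r uses \code{seed + r}.
#' @param ... conventions passed on to \code{\link{topologyReport}}.
#' @return data.frame with columns \code{metric}, \code{mean}, \code{sd}.
#' @export
nullEnsemble <- function(nNodes, nEdges, nReplicates = 1000L, seed = 1L,
                         inhibitoryFraction = 0.5,
                         model = c("fixed_m", "per_edge"), ...) {
  model <- match.arg(model)
  stopifnot(nReplicates >= 2L)
  metrics <- c("n_edges", "mean_connectivity", "char_path_length",
               "clustering")
  vals <- matrix(NA_real_, nReplicates, length(metrics),
                 dimnames = list(NULL, metrics))
  for (r in seq_len(nReplicates)) {
    net <- randomNetwork(nNodes, nEdges,
                         inhibitoryFraction = inhibitoryFraction,
                         seed = as.integer(seed) + r, model = model)
    rep <- topologyReport(net, ...)
    vals[r, ] <- c(rep$n_edges, rep$mean_connectivity, rep$char_path_length,
                   rep$clustering)
  }
  data.frame(metric = metrics,
             mean = colMeans(vals, na.rm = TRUE),
             sd = apply(vals, 2, stats::sd, na.rm = TRUE),
             row.names = NULL)
}

#' Betweenness/degree profile of selected nodes
#'
#' Reports, for each node in \code{nodes}, its betweenness centrality and
#' total degree together with the network-wide means, for ranking candidate
#' driver nodes against the network average. Group cutoffs are left to the
#' caller.
#'
#' @param net a \linkS4class{ThresholdNetwork}.
#' @param nodes node names (empty vector gives an empty table).
#' @param ... conventions passed to \code{\link{topologyReport}}.
#' @return data.frame: \code{node}, \code{betweenness}, \code{degree},
#'   \code{betweenness_ratio} (to the network mean), \code{degree_ratio};
#'   attributes \code{mean_betweenness}, \code{mean_degree}.
#' @export
centralityProfile <- function(net, nodes = nodeNames(net), ...) {
  bad <- setdiff(nodes, nodeNames(net))
  if (length(bad))
    stop("unknown node(s): ", paste(bad, collapse = ", "), call. = FALSE)
  rep <- topologyReport(net, ...)
  g <- asIgraph(net)
  deg <- igraph::degree(g, mode = "all")
  mb <- mean(rep$betweenness)
  md <- mean(deg)
  out <- data.frame(node = nodes,
                    betweenness = unname(rep$betweenness[nodes]),
                    degree = unname(deg[nodes]),
                    betweenness_ratio = unname(rep$betweenness[nodes]) / mb,
                    degree_ratio = unname(deg[nodes]) / md,
                    row.names = NULL)
  attr(out, "mean_betweenness") <- mb
  attr(out, "mean_degree") <- md
  out[order(-out$betweenness), , drop = FALSE]
}
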