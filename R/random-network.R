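#' Random threshold networks (null ensemble generator)
#'
#' Generates a simple directed random graph (no self-loops, no duplicate
#' ordered pairs) with strengths ±1 and all thresholds 0, used as the null
#' model for topology comparisons and as the test-bed generator. Two sampling
#' models are available: \code{"fixed_m"} draws exactly \code{nEdges} ordered
#' pairs uniformly at random, \code{"per_edge"} includes every ordered pair
#' independently with probability \code{nEdges / (n (n-1))} so the edge count
#' itself fluctuates (binomially, about \code{nEdges ± sqrt(nEdges)}).
#'
#' @param nNodes,nEdges counts; \code{nEdges} must not exceed
#'   \code{nNodes * (nNodes - 1)}.
#' @param inhibitoryFraction probability that an edge is inhibitory (-1).
#' @param seed integer; the same seed reproduces the same network.
#' @param model \code{"fixed_m"} or \code{"per_edge"}.
#' @return a \linkS4class{ThresholdNetwork} with nodes \code{N1..Nn}.
#' @examples
#' net <- randomNetwork(10, 20, seed = 1)
#' nEdges(net)
#' @export
randomNetwork <- function(nNodes, nEdges, inhibitoryFraction = 0.5,
                          seed = 1L, model = c("fixed_m", "per_edge")) {
  model <- match.arg(model)
  stopifnot(nNodes >= 1, nEdges >= 0,
            inhibitoryFraction >= 0, inhibitoryFraction <= 1)
  maxm <- nNodes * (nNodes - 1)
  if (nEdges > maxm)
    stop("infeasible edge count: ", nEdges, " > ", maxm, call. = FALSE)
  set.seed(as.integer(seed))
  if (model == "fixed_m") {
    pick <- sample.int(maxm, nEdges)
  } else {
    pick <- which(stats::runif(maxm) < nEdges / maxm)
  }
  # ordered-pair index -> (source, target), skipping the diagonal
  src <- (pick - 1L) %/% (nNodes - 1L) + 1L
  off <- (pick - 1L) %% (nNodes - 1L) + 1L
  tgt <- ifelse(off >= src, off + 1L, off)
  strength <- ifelse(stats::runif(length(pick)) < inhibitoryFraction, -1L, 1L)
  nm <- paste0("N", seq_len(nNodes))
  thresholdNetwork(
    nodes = data.frame(name = nm, threshold = 0L, is_input = FALSE),
    edges = data.frame(source = nm[src], target = nm[tgt],
                       strength = strength),
    metadata = list(name = sprintf("random %s digraph", model),
                    seed = seed, model = model,
                    requested_edges = nEdges,
                    inhibitory_fraction = inhibitoryFraction))
}
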