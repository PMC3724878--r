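#' @import methods
NULL

#' Threshold Boolean network
#'
#' A directed network of binary nodes with integer activation thresholds and
#' signed integer interaction strengths. A node \eqn{i} updates as
#' \eqn{s_i(t+1) = \sigma(\sum_j a_{ij} s_j(t) - \theta_i)} with
#' \eqn{\sigma(x) = 1} for \eqn{x > 0} and 0 otherwise, all nodes in parallel.
#' Designated input nodes are unregulated and carry the microenvironment.
#'
#' @slot nodes data.frame with columns \code{name} (unique character),
#'   \code{threshold} (integer) and \code{is_input} (logical); row order fixes
#'   the state-vector index.
#' @slot edges data.frame with columns \code{source}, \code{target}
#'   (node names) and \code{strength} (nonzero signed integer); at most one
#'   edge per ordered pair. Self-loops are allowed.
#' @slot metadata free-form provenance list.
#'
#' @examples
#' net <- exampleToggleNetwork()
#' nNodes(net)
#' edgeTable(net)
#' @aliases ThresholdNetwork
#' @exportClass ThresholdNetwork
setClass("ThresholdNetwork",
  representation(nodes = "data.frame", edges = "data.frame",
                 metadata = "list"),
  prototype(
    nodes = data.frame(name = character(), threshold = integer(),
                       is_input = logical(), stringsAsFactors = FALSE),
    edges = data.frame(source = character(), target = character(),
                       strength = integer(), stringsAsFactors = FALSE),
    metadata = list()
  )
)

validThresholdNetwork <- function(object) {
  nd <- object@nodes
  ed <- object@edges
  msg <- character()
  need_nd <- c("name", "threshold", "is_input")
  need_ed <- c("source", "target", "strength")
  if (!all(need_nd %in% names(nd)))
    return("node table must have columns name, threshold, is_input")
  if (!all(need_ed %in% names(ed)))
    return("edge table must have columns source, target, strength")
  if (anyDuplicated(nd$name))
    msg <- c(msg, paste0("duplicate node name(s): ",
                         paste(unique(nd$name[duplicated(nd$name)]),
                               collapse = ", ")))
  if (any(is.na(nd$threshold)))
    msg <- c(msg, "missing threshold")
  bad_src <- setdiff(ed$source, nd$name)
  bad_tgt <- setdiff(ed$target, nd$name)
  if (length(bad_src) || length(bad_tgt))
    msg <- c(msg, paste0("edge endpoint(s) not declared as nodes: ",
                         paste(unique(c(bad_src, bad_tgt)), collapse = ", ")))
  if (nrow(ed)) {
    if (any(ed$strength == 0 | is.na(ed$strength)))
      msg <- c(msg, paste0("zero/missing strength on edge row(s): ",
                           paste(which(ed$strength == 0 | is.na(ed$strength)),
                                 collapse = ", ")))
    pair <- paste(ed$source, ed$target, sep = "\r")
    if (anyDuplicated(pair))
      msg <- c(msg, paste0("duplicate edge(s): ",
                           paste(unique(gsub("\r", " -> ",
                                             pair[duplicated(pair)])),
                                 collapse = ", ")))
    inp <- nd$name[nd$is_input]
    reg_inp <- intersect(unique(ed$target), inp)
    if (length(reg_inp))
      msg <- c(msg, paste0("input node(s) with incoming edges: ",
                           paste(reg_inp, collapse = ", ")))
  }
  if (length(msg)) msg else TRUE
}

setValidity("ThresholdNetwork", validThresholdNetwork)

#' Attractor of a synchronous threshold network
#'
#' A fixed point (period 1) or limit cycle (period > 1), stored as the ordered
#' sequence of its states rotated so the lexicographically smallest state
#' (in the packed encoding used by the dynamics core) comes first, which makes
#' \code{attractorKey} invariant under the transient that discovered it.
#'
#' @slot states integer matrix, one row per cycle state, one column per node
#'   (column names are node names).
#' @slot period integer cycle length.
#' @slot key character canonical identity (hex encoding of the rotated cycle).
#' @slot environment named integer vector of input-node values under which the
#'   attractor was found (may be empty for free runs).
#' @aliases Attractor
#' @exportClass Attractor
setClass("Attractor",
  representation(states = "matrix", period = "integer", key = "character",
                 environment = "integer"))

setValidity("Attractor", function(object) {
  if (nrow(object@states) != object@period)
    return("period must equal the number of stored states")
  if (!all(object@states %in% c(0L, 1L)))
    return("attractor states must be binary")
  TRUE
})

#' A perturbed threshold-network model
#'
#' Couples a base network with the constitutive clamps and strength rescalings
#' produced by mutations and therapeutic interventions, plus the DNA-damage
#' bookkeeping mode: \code{"auto_on"} clamps the DNA-damage node to 1 as soon
#' as one mutation is present (intact integrity sensors), \code{"forced_off"}
#' clamps it to 0 (defective sensors), \code{"free"} leaves it alone.
#'
#' @slot network the (possibly strength-rescaled) \linkS4class{ThresholdNetwork}.
#' @slot clamps named integer vector of constitutively fixed node values.
#' @slot dnaDamageMode one of \code{"auto_on"}, \code{"forced_off"}, \code{"free"}.
#' @slot forcedInputs named integer vector overriding microenvironment bits at
#'   simulation time (e.g. an anti-VEGF intervention).
#' @slot history list describing the perturbations applied, in order.
#' @aliases PerturbedModel
#' @exportClass PerturbedModel
setClass("PerturbedModel",
  representation(network = "ThresholdNetwork", clamps = "integer",
                 dnaDamageMode = "character", forcedInputs = "integer",
                 history = "list"),
  prototype(clamps = setNames(integer(), character()),
            dnaDamageMode = "free",
            forcedInputs = setNames(integer(), character()),
            history = list()))

setValidity("PerturbedModel", function(object) {
  msg <- character()
  nm <- nodeNames(object@network)
  if (length(object@clamps)) {
    if (is.null(names(object@clamps)) || !all(names(object@clamps) %in% nm))
      msg <- c(msg, "clamps must be named after existing nodes")
    if (!all(object@clamps %in% c(0L, 1L)))
      msg <- c(msg, "clamp values must be 0/1")
  }
  if (!object@dnaDamageMode %in% c("auto_on", "forced_off", "free"))
    msg <- c(msg, "dnaDamageMode must be auto_on, forced_off or free")
  if (length(object@forcedInputs) &&
      !all(names(object@forcedInputs) %in% inputNodes(object@network)))
    msg <- c(msg, "forcedInputs must name input nodes")
  if (length(msg)) msg else TRUE
})
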