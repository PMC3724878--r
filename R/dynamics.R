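#' @useDynLib cancerTBN, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats setNames runif sd
NULL

#' Attractor census of one microenvironment
#'
#' Holds the attractors found under a fixed microenvironment together with
#' their (exact or sampled) basin-of-attraction fractions.
#'
#' @slot table data.frame with one row per attractor: \code{key},
#'   \code{kind} (\code{"fixed_point"} or \code{"limit_cycle"}),
#'   \code{period}, \code{fraction}, \code{count}.
#' @slot attractors named list of \linkS4class{Attractor} objects, keyed by
#'   canonical key.
#' @slot environment named integer vector of input values.
#' @slot nSamples total number of initial states behind the fractions.
#' @slot protocol list describing how initial states were generated
#'   (\code{"exhaustive"} or the sampling-protocol parameters).
#' @aliases AttractorCensus
#' @exportClass AttractorCensus
setClass("AttractorCensus",
  representation(table = "data.frame", attractors = "list",
                 environment = "integer", nSamples = "numeric",
                 protocol = "list"))

setValidity("AttractorCensus", function(object) {
  if (nrow(object@table) &&
      abs(sum(object@table$fraction) - 1) > 1e-9)
    return("basin fractions must sum to 1")
  if (!identical(sort(names(object@attractors)),
                 sort(object@table$key)))
    return("attractor list and census table must carry the same keys")
  TRUE
})

setMethod("show", "AttractorCensus", function(object) {
  cat(sprintf("AttractorCensus: environment %s, %d attractor(s), %g initial states\n",
              environmentCode(object@environment), nrow(object@table),
              object@nSamples))
  tb <- object@table
  tb$key <- paste0(substr(tb$key, 1, 10), "...")
  print(tb, row.names = FALSE)
})

#' @rdname AttractorCensus-class
#' @param x an \code{AttractorCensus}.
#' @export
censusTable <- function(x) x@table

#' @rdname AttractorCensus-class
#' @export
censusAttractors <- function(x) x@attractors

## ---- Attractor accessors ----------------------------------------------------

#' Accessors for Attractor objects
#'
#' @param x an \linkS4class{Attractor}.
#' @name Attractor-accessors
NULL

#' @rdname Attractor-accessors
#' @export
setMethod("attractorStates", "Attractor", function(x) x@states)

#' @rdname Attractor-accessors
#' @export
setMethod("attractorKey", "Attractor", function(x) x@key)

#' @rdname Attractor-accessors
#' @export
setMethod("period", "Attractor", function(x) x@period)

#' @rdname Attractor-accessors
#' @export
setMethod("attractorKind", "Attractor", function(x)
  if (x@period == 1L) "fixed_point" else "limit_cycle")

setMethod("show", "Attractor", function(object) {
  cat(sprintf("Attractor: %s (period %d)\n", attractorKind(object),
              object@period))
  on <- colnames(object@states)[colSums(object@states) == object@period]
  cat("  always-on nodes:", if (length(on)) paste(on, collapse = ", ") else "none",
      "\n")
})

## ---- single-step update -----------------------------------------------------

#' One synchronous update step
#'
#' Applies the threshold rule simultaneously to every non-input, non-clamped
#' node: the node becomes active iff the integer sum of its weighted inputs at
#' time t strictly exceeds its activation threshold (ties deactivate). Input
#' nodes and clamped nodes keep their values.
#'
#' @param net a \linkS4class{ThresholdNetwork}.
#' @param state 0/1 vector aligned with \code{nodeNames(net)} (names optional).
#' @param clamps named 0/1 vector of clamped nodes (may include input nodes).
#' @return the successor state, named integer vector.
#' @examples
#' net <- exampleToggleNetwork()
#' stepNetwork(net, c(A = 1, B = 1))   # fixed point
#' @export
stepNetwork <- function(net, state, clamps = NULL) {
  nm <- nodeNames(net)
  n <- length(nm)
  if (length(state) != n)
    stop("state has length ", length(state), ", network has ", n, " nodes",
         call. = FALSE)
  if (!is.null(names(state))) state <- state[nm]
  state <- as.integer(state)
  if (anyNA(state) || !all(state %in% 0:1))
    stop("state must be a 0/1 vector over the network's nodes", call. = FALSE)
  ed <- edgeTable(net)
  acc <- integer(n)
  if (nrow(ed)) {
    contrib <- ed$strength * state[match(ed$source, nm)]
    s <- rowsum(contrib, match(ed$target, nm))
    acc[as.integer(rownames(s))] <- as.integer(s)
  }
  nxt <- ifelse(acc > thresholds(net), 1L, 0L)
  keep <- nodeTable(net)$is_input
  nxt[keep] <- state[keep]
  if (length(clamps)) {
    j <- match(names(clamps), nm)
    if (anyNA(j))
      stop("unknown clamped node(s): ",
           paste(names(clamps)[is.na(j)], collapse = ", "), call. = FALSE)
    nxt[j] <- as.integer(clamps)
  }
  setNames(nxt, nm)
}

## ---- attractor detection ----------------------------------------------------

.attractors_from_core <- function(att, nm, env) {
  out <- list()
  env <- if (is.null(env)) setNames(integer(), character()) else env
  for (a in seq_along(att$period)) {
    st <- att$states[[a]]
    colnames(st) <- nm
    obj <- new("Attractor", states = st, period = att$period[a],
               key = att$key[a], environment = env)
    out[[att$key[a]]] <- obj
  }
  out
}

#' Find the attractor reached from one initial state
#'
#' Iterates the synchronous dynamics, recording every visited state in a hash
#' map; the first revisit closes the cycle. The returned attractor is
#' canonicalized (rotated to start at the lexicographically smallest state) so
#' that the same cycle reached through different transients gets the same key.
#'
#' @inheritParams stepNetwork
#' @param maxSteps maximum number of steps before giving up. The dynamics is
#'   deterministic on a finite state space, so a revisit always exists;
#'   exceeding \code{maxSteps} raises an error signalling the cap is too small.
#' @return list with elements \code{attractor} (\linkS4class{Attractor}) and
#'   \code{transient} (steps before cycle entry).
#' @examples
#' net <- exampleToggleNetwork()
#' findAttractor(net, c(A = 1, B = 1))$attractor
#' @export
findAttractor <- function(net, state, clamps = NULL, maxSteps = 1000L) {
  stopifnot(maxSteps >= 1L)
  nm <- nodeNames(net)
  if (length(state) != length(nm))
    stop("state has length ", length(state), ", network has ", length(nm),
         " nodes", call. = FALSE)
  if (!is.null(names(state))) state <- state[nm]
  state <- as.integer(state)
  cmp <- .compiled(net, clamps = clamps, state0 = state)
  res <- .tbn_find_attractors(cmp$in_ptr, cmp$in_src, cmp$in_w, cmp$theta,
                              cmp$clamp_mask, cmp$clamp_val,
                              matrix(state, nrow = 1L), as.integer(maxSteps))
  if (res$attractor_id[1] < 0)
    stop("no attractor found within ", maxSteps,
         " steps; increase maxSteps", call. = FALSE)
  env <- setNames(state[nodeTable(net)$is_input], inputNodes(net))
  atts <- .attractors_from_core(res$attractors, nm, env)
  list(attractor = atts[[1L]], transient = res$transient[1])
}

.free_nodes <- function(net, clamps) {
  nm <- nodeNames(net)
  free <- !nodeTable(net)$is_input
  if (length(clamps)) free[match(names(clamps), nm)] <- FALSE
  free
}

.make_census <- function(keys, periods, attractors, counts, env, protocol) {
  total <- sum(counts)
  tb <- data.frame(key = keys,
                   kind = ifelse(periods == 1L, "fixed_point", "limit_cycle"),
                   period = periods,
                   fraction = counts / total,
                   count = counts,
                   stringsAsFactors = FALSE)
  tb <- tb[order(-tb$fraction, tb$key), , drop = FALSE]
  rownames(tb) <- NULL
  new("AttractorCensus", table = tb, attractors = attractors,
      environment = env, nSamples = total, protocol = protocol)
}

#' Exhaustive attractor enumeration (exact basins)
#'
#' Runs \code{\link{findAttractor}} from every configuration of the free
#' (non-input, non-clamped) nodes and returns the exact basin fractions. Used
#' as the ground-truth oracle for the Monte Carlo protocol on small networks;
#' limited to 24 free nodes.
#'
#' @inheritParams findAttractor
#' @param environment microenvironment code or named vector
#'   (see \code{\link{microenvironment}}).
#' @return an \linkS4class{AttractorCensus} with exact fractions.
#' @examples
#' net <- thresholdNetwork(data.frame(name = "S"),
#'                         data.frame(source = "S", target = "S", strength = 1))
#' censusTable(enumerateAttractors(net))  # two fixed points, basins 1/2 each
#' @export
enumerateAttractors <- function(net, environment = NULL, clamps = NULL,
                                maxSteps = 1000L) {
  env <- if (is.null(environment)) setNames(integer(), character())
         else microenvironment(net, environment)
  allclamps <- .merge_clamps(env, clamps)
  cmp <- .compiled(net, clamps = allclamps)
  free <- .free_nodes(net, allclamps)
  if (sum(free) > 24)
    stop("too many free nodes for exhaustive enumeration (",
         sum(free), " > 24)", call. = FALSE)
  res <- .tbn_enumerate(cmp$in_ptr, cmp$in_src, cmp$in_w, cmp$theta,
                        cmp$clamp_mask, cmp$clamp_val,
                        as.integer(which(free) - 1L), as.integer(maxSteps))
  atts <- .attractors_from_core(res$attractors, nodeNames(net), env)
  .make_census(res$attractors$key, res$attractors$period, atts, res$count,
               env, list(method = "exhaustive"))
}

.merge_clamps <- function(env, clamps) {
  out <- as.integer(env)
  names(out) <- names(env)
  if (length(clamps)) {
    cl <- setNames(as.integer(clamps), names(clamps))
    out <- c(out[!names(out) %in% names(cl)], cl)
  }
  out
}

#' Monte Carlo basin-of-attraction estimation
#'
#' Implements the stratified initial-state protocol: for each activation
#' probability p in \code{pLevels}, \code{samplesPerLevel} initial
#' configurations of the free nodes are drawn with independent per-node
#' activation probability p, evolved to their attractors, and aggregated by
#' canonical key. Defaults follow the protocol of eleven equally spaced
#' p-levels.
#'
#' @inheritParams enumerateAttractors
#' @param pLevels activation probabilities for the stratified draw.
#' @param samplesPerLevel initial states per p-level.
#' @param seed integer seed; the run is bit-reproducible for a fixed seed.
#' @return an \linkS4class{AttractorCensus} with sampled fractions.
#' @examples
#' net <- exampleToggleNetwork()
#' @export
sampleBasins <- function(net, environment = NULL, clamps = NULL,
                         pLevels = seq(0, 1, by = 0.1),
                         samplesPerLevel = 10000L, seed = 1L,
                         maxSteps = 1000L) {
  stopifnot(all(pLevels >= 0 & pLevels <= 1), samplesPerLevel >= 1L)
  env <- if (is.null(environment)) setNames(integer(), character())
         else microenvironment(net, environment)
  allclamps <- .merge_clamps(env, clamps)
  cmp <- .compiled(net, clamps = allclamps)
  free <- .free_nodes(net, allclamps)
  n <- nNodes(net)
  counts <- numeric()      # named by key
  periods <- integer()
  atts <- list()
  set.seed(as.integer(seed))
  for (p in pLevels) {
    init <- matrix(0L, nrow = samplesPerLevel, ncol = n)
    if (any(free))
      init[, free] <- (matrix(stats::runif(samplesPerLevel * sum(free)),
                              samplesPerLevel) < p) + 0L
    cl_idx <- which(cmp$clamp_mask == 1L)
    init[, cl_idx] <- rep(cmp$clamp_val[cl_idx], each = samplesPerLevel)
    res <- .tbn_find_attractors(cmp$in_ptr, cmp$in_src, cmp$in_w, cmp$theta,
                                cmp$clamp_mask, cmp$clamp_val, init,
                                as.integer(maxSteps))
    if (any(res$attractor_id < 0)) {
      bad <- which(res$attractor_id < 0)[1]
      stop("no attractor within ", maxSteps, " steps for initial state: ",
           paste(init[bad, ], collapse = ""), " (p = ", p, ")", call. = FALSE)
    }
    tab <- table(res$attractor_id)
    keys <- res$attractors$key[as.integer(names(tab))]
    newk <- setdiff(keys, names(counts))
    counts[newk] <- 0
    counts[keys] <- counts[keys] + as.numeric(tab)
    newa <- .attractors_from_core(res$attractors, nodeNames(net), env)
    atts[setdiff(names(newa), names(atts))] <-
      newa[setdiff(names(newa), names(atts))]
    periods[names(newa)] <- res$attractors$period
  }
  .make_census(names(counts), as.integer(periods[names(counts)]),
               atts[names(counts)], as.numeric(counts), env,
               list(method = "sampled", p_levels = pLevels,
                    samples_per_level = samplesPerLevel, seed = seed,
                    max_steps = maxSteps))
}
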