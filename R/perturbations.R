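#' Create a perturbable model from a network
#'
#' Wraps a \linkS4class{ThresholdNetwork} together with an (initially empty)
#' clamp set and the DNA-damage bookkeeping mode. Under \code{"auto_on"}
#' (intact integrity sensors) the DNA-damage node is clamped to 1 as soon as
#' the first mutation is applied, so the Atm/Atr pathway sees the lesion;
#' under \code{"forced_off"} (defective sensors) it is clamped to 0
#' immediately; \code{"free"} leaves it under network control.
#'
#' @param net a \linkS4class{ThresholdNetwork}.
#' @param dnaDamageMode \code{"auto_on"}, \code{"forced_off"} or \code{"free"}.
#' @param dnaDamageNode name of the DNA-damage node (ignored for
#'   \code{"free"}; must exist otherwise).
#' @return a \linkS4class{PerturbedModel}.
#' @export
perturbedModel <- function(net, dnaDamageMode = c("auto_on", "forced_off",
                                                  "free"),
                           dnaDamageNode = "DNA_damage") {
  dnaDamageMode <- match.arg(dnaDamageMode)
  stopifnot(is(net, "ThresholdNetwork"))
  clamps <- setNames(integer(), character())
  if (dnaDamageMode != "free") {
    if (!dnaDamageNode %in% nodeNames(net))
      stop("DNA-damage node '", dnaDamageNode, "' not in the network",
           call. = FALSE)
    if (dnaDamageMode == "forced_off")
      clamps[dnaDamageNode] <- 0L
  }
  m <- new("PerturbedModel", network = net, clamps = clamps,
           dnaDamageMode = dnaDamageMode,
           forcedInputs = setNames(integer(), character()),
           history = list())
  m@history <- list(list(event = "init", dna_damage_mode = dnaDamageMode,
                         dna_damage_node = dnaDamageNode))
  m
}

#' @rdname PerturbedModel
#' @param x a \linkS4class{PerturbedModel}.
#' @export
setMethod("baseNetwork", "PerturbedModel", function(x) x@network)

#' @rdname PerturbedModel
#' @export
setMethod("clamps", "PerturbedModel", function(x) x@clamps)

setMethod("show", "PerturbedModel", function(object) {
  cat(sprintf("PerturbedModel: %d nodes, dnaDamageMode = %s\n",
              nNodes(object@network), object@dnaDamageMode))
  if (length(object@clamps))
    cat("  clamps:", paste(names(object@clamps), "=", object@clamps,
                           collapse = ", "), "\n")
  if (length(object@forcedInputs))
    cat("  forced inputs:", paste(names(object@forcedInputs), "=",
                                  object@forcedInputs, collapse = ", "), "\n")
  nmut <- sum(vapply(object@history, function(h)
    identical(h$event, "mutation"), logical(1)))
  cat("  perturbations applied:", length(object@history) - 1L,
      sprintf("(%d mutation(s))\n", nmut))
})

.dna_damage_node <- function(model) {
  model@history[[1L]]$dna_damage_node
}

.set_clamp <- function(model, node, value, what, override = FALSE) {
  cur <- model@clamps
  if (node %in% names(cur) && cur[[node]] != value && !override)
    stop(what, " of '", node, "' conflicts with existing clamp ", node, " = ",
         cur[[node]], call. = FALSE)
  cur[node] <- as.integer(value)
  model@clamps <- cur
  model
}

.scale_out_strengths <- function(model, node, scale) {
  ed <- model@network@edges
  sel <- ed$source == node
  if (any(sel)) {
    scaled <- as.integer(round(ed$strength[sel] * scale))
    if (any(scaled == 0))
      stop("strength scaling by ", scale, " would zero an edge out of '",
           node, "'", call. = FALSE)
    ed$strength[sel] <- scaled
    model@network@edges <- ed
  }
  model
}

#' Apply a constitutive mutation to a model
#'
#' Mutations are permanent: \code{activation} clamps the node to 1,
#' \code{deletion} clamps it to 0, \code{overexpression} clamps it to 1 and
#' multiplies all its outgoing interaction strengths by \code{scale}, and
#' \code{strength_scaling} rescales the outgoing strengths without clamping.
#' Under \code{dnaDamageMode = "auto_on"} the DNA-damage node is clamped to 1
#' once at least one mutation is present.
#'
#' @param model a \linkS4class{PerturbedModel}.
#' @param node name of the mutated node.
#' @param kind one of \code{"activation"}, \code{"deletion"},
#'   \code{"overexpression"}, \code{"strength_scaling"}.
#' @param scale positive factor for the outgoing strengths (default 2,
#'   the model's canonical doubling); products are rounded to integers.
#' @param override replace a conflicting existing clamp instead of erroring.
#' @return the updated \linkS4class{PerturbedModel}.
#' @export
applyMutation <- function(model, node,
                          kind = c("activation", "deletion", "overexpression",
                                   "strength_scaling"),
                          scale = 2, override = FALSE) {
  kind <- match.arg(kind)
  stopifnot(is(model, "PerturbedModel"), scale > 0)
  if (!node %in% nodeNames(model@network))
    stop("unknown node '", node, "'", call. = FALSE)
  if (kind %in% c("activation", "overexpression"))
    model <- .set_clamp(model, node, 1L, "mutation", override)
  if (kind == "deletion")
    model <- .set_clamp(model, node, 0L, "mutation", override)
  if (kind %in% c("overexpression", "strength_scaling"))
    model <- .scale_out_strengths(model, node, scale)
  if (model@dnaDamageMode == "auto_on")
    model@clamps[.dna_damage_node(model)] <- 1L
  model@history <- c(model@history,
                     list(list(event = "mutation", node = node, kind = kind,
                               scale = scale)))
  validObject(model)
  model
}

#' Apply a therapeutic intervention to a model
#'
#' \code{inhibit} clamps the target to 0 and \code{activate}
#' (wild-type reintroduction) to 1. \code{force_inputs} overrides
#' microenvironment bits at simulation time — e.g. an anti-VEGF agent is
#' modelled as forcing hypoxia on and nutrients off regardless of the scenario
#' environment. Conflicts with existing clamps raise an error unless
#' \code{override} is set, in which case the intervention wins.
#'
#' @param model a \linkS4class{PerturbedModel}.
#' @param node target node (\code{inhibit}/\code{activate} modes).
#' @param mode one of \code{"inhibit"}, \code{"activate"},
#'   \code{"force_inputs"}.
#' @param forcedInputs named 0/1 vector over input nodes
#'   (\code{force_inputs} mode).
#' @param override replace a conflicting clamp instead of erroring.
#' @return the updated \linkS4class{PerturbedModel}.
#' @export
applyIntervention <- function(model, node = NULL,
                              mode = c("inhibit", "activate", "force_inputs"),
                              forcedInputs = NULL, override = FALSE) {
  mode <- match.arg(mode)
  stopifnot(is(model, "PerturbedModel"))
  if (mode == "force_inputs") {
    if (is.null(forcedInputs) || is.null(names(forcedInputs)))
      stop("force_inputs needs a named 0/1 vector of input nodes",
           call. = FALSE)
    bad <- setdiff(names(forcedInputs), inputNodes(model@network))
    if (length(bad))
      stop("force_inputs may only touch input nodes; offending: ",
           paste(bad, collapse = ", "), call. = FALSE)
    fi <- model@forcedInputs
    fi[names(forcedInputs)] <- as.integer(forcedInputs)
    model@forcedInputs <- fi
  } else {
    if (is.null(node) || !node %in% nodeNames(model@network))
      stop("unknown node '", node, "'", call. = FALSE)
    model <- .set_clamp(model, node, if (mode == "inhibit") 0L else 1L,
                        "intervention", override)
  }
  model@history <- c(model@history,
                     list(list(event = "intervention", node = node,
                               mode = mode,
                               forced_inputs = as.list(forcedInputs))))
  validObject(model)
  model
}

#' Effective clamp set of a model under a microenvironment
#'
#' Merges the environment's input values with the model's forced inputs
#' (which win) and constitutive clamps. This is the clamp vector handed to the
#' dynamics engine.
#'
#' @param model a \linkS4class{PerturbedModel}.
#' @param environment code or named vector (see
#'   \code{\link{microenvironment}}).
#' @return named integer 0/1 vector.
#' @export
modelClamps <- function(model, environment) {
  env <- microenvironment(model@network, environment)
  if (length(model@forcedInputs))
    env[names(model@forcedInputs)] <- model@forcedInputs
  cl <- model@clamps
  out <- c(env[!names(env) %in% names(cl)], cl)
  setNames(as.integer(out), names(out))
}

#' Basin sampling / enumeration for a perturbed model
#'
#' Convenience wrappers running the dynamics of the perturbed network under
#' its effective clamps.
#'
#' @inheritParams sampleBasins
#' @param model a \linkS4class{PerturbedModel}.
#' @param environment scenario microenvironment (forced inputs override it).
#' @return an \linkS4class{AttractorCensus}.
#' @export
sampleModelBasins <- function(model, environment,
                              pLevels = seq(0, 1, by = 0.1),
                              samplesPerLevel = 10000L, seed = 1L,
                              maxSteps = 1000L) {
  cl <- modelClamps(model, environment)
  env <- microenvironment(model@network, environment)
  cen <- sampleBasins(model@network, env, clamps = cl, pLevels = pLevels,
                      samplesPerLevel = samplesPerLevel, seed = seed,
                      maxSteps = maxSteps)
  cen
}
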