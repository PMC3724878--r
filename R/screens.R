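#' Genome-wide driver-mutation screen
#'
#' Applies every requested mutation kind to every candidate node in turn (DNA
#' damage bookkeeping per \code{dnaDamageMode}), samples the basins under the
#' given microenvironment and records the efficacy of the target phenotypic
#' transition: under normoxia with nutrients the transition of interest is
#' quiescent-to-proliferative (\code{target = "proliferative"}); under hypoxia
#' it is evading apoptosis, where any non-apoptotic primary counts
#' (\code{target = "non_apoptotic"}). Efficacy is the fraction of all sampled
#' initial states of the environment that land in the target phenotype.
#'
#' Each (node, kind) run derives its own seed (\code{seed + run index}), so
#' results do not depend on execution order.
#'
#' @param net a \linkS4class{ThresholdNetwork}.
#' @param environment microenvironment code or named vector.
#' @param kinds mutation kinds to screen.
#' @param target \code{"proliferative"} or \code{"non_apoptotic"}.
#' @param nodes candidate nodes (default: all non-input nodes).
#' @param dnaDamageMode DNA-damage bookkeeping (see
#'   \code{\link{perturbedModel}}).
#' @param markers a \code{\link{markerConfig}}.
#' @inheritParams sampleBasins
#' @param scale overexpression / strength-scaling factor.
#' @return list with \code{report} (efficacy > 0 rows), \code{raw} (all rows:
#'   node, kind, efficacy, apoptotic, proliferative, quiescent),
#'   \code{baseline} (phenotype fractions without mutation) and
#'   \code{failed} (nodes whose simulation errored, with messages).
#' @export
driverScreen <- function(net, environment,
                         kinds = c("activation", "deletion", "overexpression"),
                         target = c("proliferative", "non_apoptotic"),
                         nodes = NULL, dnaDamageMode = "auto_on",
                         markers = markerConfig(),
                         pLevels = seq(0, 1, by = 0.1),
                         samplesPerLevel = 1000L, seed = 1L,
                         maxSteps = 1000L, scale = 2) {
  target <- match.arg(target)
  env <- microenvironment(net, environment)
  if (is.null(nodes)) nodes <- setdiff(nodeNames(net), inputNodes(net))
  base_cen <- sampleBasins(net, env, pLevels = pLevels,
                           samplesPerLevel = samplesPerLevel, seed = seed,
                           maxSteps = maxSteps)
  baseline <- phenotypeCensus(base_cen, markers)$primary

  grid <- expand.grid(node = nodes, kind = kinds, stringsAsFactors = FALSE)
  rows <- vector("list", nrow(grid))
  failed <- list()
  for (i in seq_len(nrow(grid))) {
    node <- grid$node[i]; kind <- grid$kind[i]
    res <- tryCatch({
      m <- perturbedModel(net, dnaDamageMode = dnaDamageMode)
      m <- applyMutation(m, node, kind, scale = scale)
      cen <- sampleModelBasins(m, env, pLevels = pLevels,
                               samplesPerLevel = samplesPerLevel,
                               seed = as.integer(seed) + i,
                               maxSteps = maxSteps)
      phenotypeCensus(cen, markers)$primary
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failed[[paste(node, kind)]] <- conditionMessage(res)
      next
    }
    eff <- if (target == "proliferative") res[["proliferative"]]
           else 1 - res[["apoptotic"]]
    rows[[i]] <- data.frame(node = node, kind = kind, efficacy = eff,
                            apoptotic = res[["apoptotic"]],
                            proliferative = res[["proliferative"]],
                            quiescent = res[["quiescent"]],
                            stringsAsFactors = FALSE)
  }
  raw <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  rownames(raw) <- NULL
  list(report = raw[raw$efficacy > 0, , drop = FALSE],
       raw = raw, baseline = baseline, failed = failed,
       environment = environmentCode(env), target = target)
}

#' The canonical colorectal mutation sequence
#'
#' Cumulative driver stages: (1) Apc deletion with Tcf interactions
#' strengthened, (2) constitutive Ras activation, (3) Smad4 deletion,
#' (4) Pten deletion with doubled Akt interaction strengths, (5) p53 deletion.
#'
#' @param tcfFactor strengthening factor for the Tcf interactions (default 2).
#' @param aktFactor factor for the Akt interaction strengths (default 2).
#' @return list of stages; each stage is a list of mutation specs
#'   (\code{node}, \code{kind}, \code{scale}).
#' @export
colorectalStages <- function(tcfFactor = 2, aktFactor = 2) {
  list(
    "Apc del + Tcf up" = list(
      list(node = "Apc", kind = "deletion"),
      list(node = "Tcf", kind = "strength_scaling", scale = tcfFactor)),
    "+ Ras act" = list(list(node = "Ras", kind = "activation")),
    "+ Smad4 del" = list(list(node = "Smad4", kind = "deletion")),
    "+ Pten del, Akt x2" = list(
      list(node = "Pten", kind = "deletion"),
      list(node = "Akt", kind = "strength_scaling", scale = aktFactor)),
    "+ p53 del" = list(list(node = "p53", kind = "deletion")))
}

.apply_mutation_list <- function(model, muts) {
  for (m in muts)
    model <- applyMutation(model, m$node, m$kind,
                           scale = if (is.null(m$scale)) 2 else m$scale)
  model
}

#' Sequential mutation-accumulation (carcinogenesis) protocol
#'
#' Accumulates the given mutation stages one by one and, after each stage,
#' computes a full per-environment phenotype census and attractor counts by
#' primary label. Stage 0 (no mutations) is always included as the baseline.
#'
#' @param net a \linkS4class{ThresholdNetwork}.
#' @param stages list of stages as in \code{\link{colorectalStages}}; an empty
#'   list yields the baseline census only.
#' @param environments character vector of environment codes (default: all).
#' @param dnaDamageMode see \code{\link{perturbedModel}}.
#' @inheritParams driverScreen
#' @return list of stage reports; each has \code{stage}, \code{mutations}
#'   (cumulative spec list), \code{census} (data.frame: environment,
#'   apoptotic, proliferative, quiescent) and \code{attractor_counts}
#'   (data.frame: primary, attractors over all environments).
#' @export
carcinogenesisRun <- function(net, stages = colorectalStages(),
                              environments = allEnvironments(net),
                              dnaDamageMode = "auto_on",
                              markers = markerConfig(),
                              pLevels = seq(0, 1, by = 0.1),
                              samplesPerLevel = 1000L, seed = 1L,
                              maxSteps = 1000L) {
  cumulative <- list()
  out <- list()
  for (s in 0:length(stages)) {
    if (s > 0) cumulative <- c(cumulative, stages[[s]])
    label <- if (s == 0) "baseline" else names(stages)[s]
    if (is.null(label) || !nzchar(label)) label <- paste("stage", s)
    model <- perturbedModel(net, dnaDamageMode = dnaDamageMode)
    model <- .apply_mutation_list(model, cumulative)
    census_rows <- vector("list", length(environments))
    att_primary <- character()
    for (j in seq_along(environments)) {
      cen <- sampleModelBasins(model, environments[j], pLevels = pLevels,
                               samplesPerLevel = samplesPerLevel,
                               seed = as.integer(seed) + s * 1000L + j,
                               maxSteps = maxSteps)
      ph <- phenotypeCensus(cen, markers)
      census_rows[[j]] <- data.frame(environment = environments[j],
                                     t(ph$primary))
      att_primary <- c(att_primary, ph$detail$primary)
    }
    census <- do.call(rbind, census_rows)
    rownames(census) <- NULL
    counts <- table(factor(att_primary,
                           levels = c("apoptotic", "proliferative",
                                      "quiescent")))
    out[[label]] <- list(stage = s, mutations = cumulative, census = census,
                         attractor_counts = data.frame(
                           primary = names(counts),
                           attractors = as.integer(counts)))
  }
  out
}

#' Targeted-therapy screen on a perturbed model
#'
#' Evaluates intervention sets (mono- or combination therapies) on a mutant
#' model across microenvironments. Each intervention set is a list of specs
#' \code{list(node =, mode =)} or \code{list(mode = "force_inputs",
#' forcedInputs = c(...))}; an empty set reproduces the untreated census.
#'
#' @param model a \linkS4class{PerturbedModel} (e.g. the quintuple colorectal
#'   mutant).
#' @param interventions named list of intervention sets.
#' @param environments character vector of environment codes.
#' @inheritParams driverScreen
#' @return data.frame with one row per (set, environment): phenotype fractions
#'   and their deltas versus the untreated model.
#' @export
therapyScreen <- function(model, interventions, environments,
                          markers = markerConfig(),
                          pLevels = seq(0, 1, by = 0.1),
                          samplesPerLevel = 1000L, seed = 1L,
                          maxSteps = 1000L) {
  stopifnot(is(model, "PerturbedModel"))
  if (is.null(names(interventions)))
    names(interventions) <- paste("set", seq_along(interventions))
  run_census <- function(mod, env, sd) {
    cen <- sampleModelBasins(mod, env, pLevels = pLevels,
                             samplesPerLevel = samplesPerLevel, seed = sd,
                             maxSteps = maxSteps)
    phenotypeCensus(cen, markers)$primary
  }
  untreated <- lapply(seq_along(environments), function(j)
    run_census(model, environments[j], as.integer(seed) + j))
  names(untreated) <- environments
  rows <- list()
  for (k in seq_along(interventions)) {
    mod <- model
    for (iv in interventions[[k]])
      mod <- applyIntervention(mod, node = iv$node,
                               mode = if (is.null(iv$mode)) "inhibit"
                                      else iv$mode,
                               forcedInputs = iv$forcedInputs,
                               override = isTRUE(iv$override))
    for (j in seq_along(environments)) {
      ph <- run_census(mod, environments[j],
                       as.integer(seed) + k * 1000L + j)
      un <- untreated[[environments[j]]]
      rows[[length(rows) + 1L]] <- data.frame(
        set = names(interventions)[k], environment = environments[j],
        apoptotic = ph[["apoptotic"]], proliferative = ph[["proliferative"]],
        quiescent = ph[["quiescent"]],
        d_apoptotic = ph[["apoptotic"]] - un[["apoptotic"]],
        d_proliferative = ph[["proliferative"]] - un[["proliferative"]],
        d_quiescent = ph[["quiescent"]] - un[["quiescent"]],
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "untreated") <- do.call(rbind, lapply(environments, function(e)
    data.frame(environment = e, t(untreated[[e]]))))
  out
}
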