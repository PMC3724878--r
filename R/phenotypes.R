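#' Marker-node configuration for phenotype calls
#'
#' Phenotypes are read off a small set of marker nodes rather than the full
#' activation pattern: caspases (apoptosis effectors), the four cyclins in
#' their cell-cycle order, Hif1 (glycolytic switch), hTert (immortalization),
#' E-cadherin (loss marks a migratory cell) and Atm/Atr together with the
#' DNA-damage node (silent sensors under damage mark a mutator cell). Defaults
#' name the built-in cancer network's nodes.
#'
#' @param caspases,hif1,htert,ecadherin,atm_atr,dna_damage,hypoxia node names.
#' @param cyclins the four cyclin nodes in expected firing order (D, E, A, B).
#' @return a named list of class \code{marker_config}.
#' @export
markerConfig <- function(caspases = "Caspases",
                         hif1 = "Hif1",
                         htert = "hTert",
                         ecadherin = "E-cadherin",
                         atm_atr = "Atm/Atr",
                         dna_damage = "DNA_damage",
                         hypoxia = "Hypoxia",
                         cyclins = c("CyclinD", "CyclinE", "CyclinA",
                                     "CyclinB")) {
  stopifnot(length(cyclins) == 4L)
  structure(list(caspases = caspases, hif1 = hif1, htert = htert,
                 ecadherin = ecadherin, atm_atr = atm_atr,
                 dna_damage = dna_damage, hypoxia = hypoxia,
                 cyclins = cyclins),
            class = "marker_config")
}

.check_markers <- function(markers, nodeNames) {
  want <- unique(c(markers$caspases, markers$hif1, markers$htert,
                   markers$ecadherin, markers$atm_atr, markers$dna_damage,
                   markers$cyclins))
  miss <- setdiff(want, nodeNames)
  if (length(miss))
    stop("marker node(s) missing from the network: ",
         paste(miss, collapse = ", "), call. = FALSE)
  invisible(TRUE)
}

# Is the cyclic order of first switch-on events D, E, A, B?
# A cyclin active in every cycle state has no switch-on event and is excluded
# from the ordering; a cyclin never active fails the proliferative call.
.cyclin_sequence_ok <- function(states, cyclins) {
  T <- nrow(states)
  if (T < 2L) return(FALSE)   # fixed points never proliferate
  first_on <- rep(NA_integer_, length(cyclins))
  for (k in seq_along(cyclins)) {
    v <- states[, cyclins[k]]
    if (!any(v == 1L)) return(FALSE)
    prev <- v[c(T, seq_len(T - 1L))]
    ev <- which(v == 1L & prev == 0L)
    if (length(ev)) first_on[k] <- min(ev)
  }
  sw <- which(!is.na(first_on))
  if (!length(sw)) return(FALSE)  # all cyclins constant: no ordered firing
  off <- (first_on[sw] - first_on[sw[1L]]) %% T
  all(diff(off) >= 0)
}

.constant_value <- function(states, node) {
  v <- states[, node]
  if (all(v == v[1L])) v[1L] else NA_integer_
}

#' Classify an attractor into a cell phenotype
#'
#' The primary label is \code{"apoptotic"} when the caspases are active,
#' \code{"proliferative"} when a limit cycle activates every cyclin with first
#' switch-on events in the cyclic order D, E, A, B, and \code{"quiescent"}
#' otherwise (cyclins silent or fired in a wrong sequence; fixed points are
#' never proliferative). Trait flags are evaluated for non-apoptotic
#' attractors on marker nodes constant along the cycle: \code{glycolytic}
#' (Hif1 active under normoxia), \code{immortalized} (hTert active),
#' \code{migratory} (E-cadherin inactive) and \code{mutator} (Atm/Atr inactive
#' while DNA damage is present). A trait whose marker oscillates is reported
#' in \code{oscillating} rather than guessed.
#'
#' @param attractor an \linkS4class{Attractor}.
#' @param environment microenvironment under which it was reached (named 0/1
#'   vector; defaults to the attractor's own record).
#' @param markers a \code{\link{markerConfig}}.
#' @param caspaseMode \code{"any"} (default: caspases active in at least one
#'   cycle state mark apoptosis, which is irreversible once triggered) or
#'   \code{"all"} (active in every state).
#' @return list with elements \code{primary}, \code{traits},
#'   \code{oscillating}.
#' @export
classifyAttractor <- function(attractor, environment = NULL,
                              markers = markerConfig(),
                              caspaseMode = c("any", "all")) {
  caspaseMode <- match.arg(caspaseMode)
  st <- attractorStates(attractor)
  .check_markers(markers, colnames(st))
  if (is.null(environment)) environment <- attractor@environment

  casp <- st[, markers$caspases, drop = FALSE]
  casp_on <- apply(casp == 1L, 1L, all)       # all caspase nodes per state
  apoptotic <- if (caspaseMode == "any") any(casp_on) else all(casp_on)

  if (apoptotic)
    return(list(primary = "apoptotic", traits = character(),
                oscillating = character()))

  primary <- if (.cyclin_sequence_ok(st, markers$cyclins)) "proliferative"
             else "quiescent"

  traits <- character()
  oscillating <- character()
  hypoxic <- !is.null(environment) && markers$hypoxia %in% names(environment) &&
    environment[[markers$hypoxia]] == 1L

  chk <- function(node, trait, active_means_trait, gate = TRUE) {
    v <- .constant_value(st, node)
    if (is.na(v)) {
      if (gate) oscillating <<- c(oscillating, trait)
    } else if (gate && ((v == 1L) == active_means_trait)) {
      traits <<- c(traits, trait)
    }
  }
  chk(markers$hif1, "glycolytic", TRUE, gate = !hypoxic)
  chk(markers$htert, "immortalized", TRUE)
  chk(markers$ecadherin, "migratory", FALSE)
  dmg <- .constant_value(st, markers$dna_damage)
  dmg_on <- !is.na(dmg) && dmg == 1L
  chk(markers$atm_atr, "mutator", FALSE, gate = dmg_on)

  list(primary = primary, traits = traits, oscillating = oscillating)
}

#' Phenotype census of one microenvironment
#'
#' Aggregates the basin fractions of an \linkS4class{AttractorCensus} by
#' primary phenotype, with a per-attractor detail table carrying the trait
#' flags. Fractions are conserved: the primary fractions sum to the census
#' total (1).
#'
#' @param census an \linkS4class{AttractorCensus} (one environment).
#' @inheritParams classifyAttractor
#' @return list with \code{primary} (named numeric: apoptotic, proliferative,
#'   quiescent), \code{detail} (data.frame: key, kind, period, fraction,
#'   primary, traits), and \code{environment} (the code).
#' @export
phenotypeCensus <- function(census, markers = markerConfig(),
                            caspaseMode = c("any", "all")) {
  caspaseMode <- match.arg(caspaseMode)
  stopifnot(is(census, "AttractorCensus"))
  tb <- censusTable(census)
  cls <- lapply(censusAttractors(census)[tb$key], classifyAttractor,
                environment = census@environment, markers = markers,
                caspaseMode = caspaseMode)
  primary_per <- vapply(cls, `[[`, character(1), "primary")
  traits_per <- vapply(cls, function(x)
    paste(x$traits, collapse = ","), character(1))
  prim <- c(apoptotic = 0, proliferative = 0, quiescent = 0)
  agg <- tapply(tb$fraction, primary_per, sum)
  prim[names(agg)] <- agg
  detail <- cbind(tb, primary = primary_per, traits = traits_per,
                  stringsAsFactors = FALSE)
  rownames(detail) <- NULL
  list(primary = prim, detail = detail,
       environment = environmentCode(census@environment))
}

#' Pairwise Hamming distances between the attractors of a census
#'
#' Reporting utility for grouping similar attractors: the distance between two
#' attractors is the minimum Hamming distance over all pairs of their states.
#'
#' @param census an \linkS4class{AttractorCensus}.
#' @return symmetric integer matrix keyed by attractor key.
#' @export
attractorDistances <- function(census) {
  at <- censusAttractors(census)
  k <- length(at)
  d <- matrix(0L, k, k, dimnames = list(names(at), names(at)))
  if (k < 2L) return(d)
  for (i in seq_len(k - 1L)) for (j in seq(i + 1L, k)) {
    a <- attractorStates(at[[i]])
    b <- attractorStates(at[[j]])
    best <- min(vapply(seq_len(nrow(a)), function(r)
      min(colSums(abs(t(b) - a[r, ]))), numeric(1)))
    d[i, j] <- d[j, i] <- as.integer(best)
  }
  d
}
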