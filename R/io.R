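#' Read a scenario configuration
#'
#' Scenario files (YAML or JSON) bundle everything needed for a reproducible
#' run: the model source, the microenvironment(s), mutation and intervention
#' lists (applied in listed order), the sampling protocol and the seed.
#'
#' Recognized fields: \code{model} (\code{"builtin"} or a list with
#' \code{nodes}/\code{edges} paths), \code{environment} (one code, a list of
#' codes, or \code{"all"}), \code{mutations} (list of \code{node}/\code{kind}/
#' \code{scale}), \code{interventions} (list of \code{node}/\code{mode} or
#' \code{forced_inputs}), \code{dna_damage_mode}, and \code{protocol}
#' (\code{p_levels}, \code{samples_per_level}, \code{seed}, \code{max_steps}).
#'
#' @param path scenario file path (.yaml/.yml or .json).
#' @return a named list with validated defaults filled in.
#' @export
readScenario <- function(path) {
  sc <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = FALSE)
  else yaml::read_yaml(path)
  if (is.null(sc$model)) sc$model <- "builtin"
  if (is.null(sc$environment)) sc$environment <- "all"
  if (is.null(sc$mutations)) sc$mutations <- list()
  if (is.null(sc$interventions)) sc$interventions <- list()
  if (is.null(sc$dna_damage_mode))
    sc$dna_damage_mode <- if (length(sc$mutations)) "auto_on" else "free"
  pr <- sc$protocol
  if (is.null(pr)) pr <- list()
  if (is.null(pr$p_levels)) pr$p_levels <- seq(0, 1, by = 0.1)
  if (is.null(pr$samples_per_level)) pr$samples_per_level <- 10000L
  if (is.null(pr$seed)) pr$seed <- 20130726L
  if (is.null(pr$max_steps)) pr$max_steps <- 1000L
  pr$p_levels <- as.numeric(unlist(pr$p_levels))
  sc$protocol <- pr
  sc
}

#' Load the model a scenario points at
#'
#' @param model \code{"builtin"} or a list with \code{nodes} and \code{edges}
#'   TSV paths.
#' @return a \linkS4class{ThresholdNetwork}.
#' @export
loadModel <- function(model) {
  if (identical(model, "builtin") || isTRUE(model$builtin))
    return(cancerNetwork())
  if (!is.null(model$nodes) && !is.null(model$edges))
    return(readNetwork(model$nodes, model$edges))
  stop("model must be \"builtin\" or a list with nodes/edges paths",
       call. = FALSE)
}

#' Content hash of a network
#'
#' MD5 over the serialized node and edge tables; used in run manifests so an
#' output can be traced to the exact model that produced it.
#'
#' @param net a \linkS4class{ThresholdNetwork}.
#' @return character MD5 string.
#' @export
networkHash <- function(net) {
  tmp <- tempfile(fileext = ".tsv")
  on.exit(unlink(tmp))
  con <- file(tmp, "w")
  utils::write.table(nodeTable(net), con, sep = "\t", row.names = FALSE)
  utils::write.table(edgeTable(net), con, sep = "\t", row.names = FALSE)
  close(con)
  unname(tools::md5sum(tmp))
}

.tsv_header <- function(con, columns) {
  writeLines(c("# cancerTBN output",
               paste0("# columns: ", paste(columns, collapse = ", "))), con)
}

#' Write an attractor census as TSV and/or JSON
#'
#' The TSV carries one row per attractor (environment code, canonical key,
#' kind, period, basin fraction, sample count); the JSON detail file adds the
#' full attractor state sequences and is the machine-readable source of truth.
#'
#' @param census an \linkS4class{AttractorCensus}.
#' @param tsv,json output paths (either may be \code{NULL}).
#' @export
writeCensus <- function(census, tsv = NULL, json = NULL) {
  tb <- censusTable(census)
  tb <- cbind(environment = environmentCode(census@environment), tb)
  if (!is.null(tsv)) {
    con <- file(tsv, "w")
    .tsv_header(con, names(tb))
    utils::write.table(tb, con, sep = "\t", quote = FALSE, row.names = FALSE)
    close(con)
  }
  if (!is.null(json)) {
    detail <- list(
      environment = environmentCode(census@environment),
      n_samples = census@nSamples,
      protocol = census@protocol,
      attractors = lapply(censusAttractors(census)[tb$key], function(a)
        list(key = attractorKey(a), period = period(a),
             kind = attractorKind(a),
             states = unname(apply(attractorStates(a), 1L, paste,
                                   collapse = "")),
             nodes = colnames(attractorStates(a)))),
      fractions = setNames(as.list(tb$fraction), tb$key))
    jsonlite::write_json(detail, json, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  }
  invisible(c(tsv, json))
}

#' Write a phenotype census table as TSV
#'
#' @param rows data.frame with an \code{environment} column plus phenotype
#'   fraction columns.
#' @param file output path.
#' @export
writePhenotypeTSV <- function(rows, file) {
  con <- file(file, "w")
  .tsv_header(con, names(rows))
  utils::write.table(rows, con, sep = "\t", quote = FALSE, row.names = FALSE)
  close(con)
  invisible(file)
}

#' Write a run manifest
#'
#' Records the configuration echo, seed, model hash and package version, so a
#' run can be reproduced byte-for-byte from the manifest alone.
#'
#' @param config the scenario / parameter list that drove the run.
#' @param net the model used.
#' @param file output path.
#' @param outputs character vector of files the run wrote.
#' @export
writeManifest <- function(config, net, file, outputs = character()) {
  manifest <- list(
    package = "cancerTBN",
    version = as.character(utils::packageVersion("cancerTBN")),
    model_hash = networkHash(net),
    config = config,
    outputs = outputs)
  jsonlite::write_json(manifest, file, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(file)
}
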