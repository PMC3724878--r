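#' The built-in integrated cancer signaling network
#'
#' Loads the packaged pan-pathway cancer model: 96 proteins/complexes and 249
#' signed interactions spanning the PI3K/AKT, MAPK/ERK, WNT/beta-catenin,
#' TGF-beta/Smad, HIF-1, NF-kB/TNF, p53/ATM, apoptosis and cell-cycle
#' modules, with five microenvironment inputs (carcinogens, growth factors,
#' nutrients, TNF-alpha, hypoxia — in that order, defining the 5-bit
#' environment code). Almost all interactions have strength ±1 and almost all
#' activation thresholds are 0; the exceptions (strong interactions such as
#' Ikk→Nf-kB +2 or Rb→E2f −2, and the special thresholds of nodes like Gsk-3,
#' Rb, Hif1, hTert or the binary complexes) are carried by the node and edge
#' tables.
#'
#' The edge list is a curated reconstruction assembled from the published
#' special-value tables, the stated pathway composition and the reported
#' wild-type behaviors; see the provenance notes distributed with the data
#' files (\code{system.file("extdata", "cancer_network", "PROVENANCE.md",
#' package = "cancerTBN")}) for which values are printed sources and which are
#' curation.
#'
#' @return a validated \linkS4class{ThresholdNetwork}.
#' @examples
#' net <- cancerNetwork()
#' nNodes(net)   # 96
#' nEdges(net)   # 249
#' @export
cancerNetwork <- function() {
  dir <- system.file("extdata", "cancer_network", package = "cancerTBN")
  nodes <- file.path(dir, "nodes_reconstructed.tsv")
  edges <- file.path(dir, "edges_reconstructed.tsv")
  if (!file.exists(nodes) || !file.exists(edges))
    stop("packaged cancer-network tables are missing or corrupt", call. = FALSE)
  net <- readNetwork(nodes, edges)
  net@metadata <- list(name = "integrated cancer signaling network",
                       source = "packaged reconstruction",
                       provenance = file.path(dir, "PROVENANCE.md"))
  validObject(net)
  net
}
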