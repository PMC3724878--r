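test_that("defaults are applied when parsing minimal tables", {
  net <- thresholdNetwork(
    nodes = data.frame(name = c("A", "B")),
    edges = data.frame(source = "A", target = "B", effect = "activation"))
  expect_identical(unname(thresholds(net)), c(0L, 0L))
  expect_identical(edgeTable(net)$strength, 1L)
  expect_identical(inputNodes(net), character(0))
  inh <- thresholdNetwork(
    nodes = data.frame(name = c("A", "B")),
    edges = data.frame(source = "A", target = "B", effect = "inhibition"))
  expect_identical(edgeTable(inh)$strength, -1L)
})

test_that("validation errors name the offending entity", {
  expect_error(
    thresholdNetwork(data.frame(name = c("A", "A")),
                     data.frame(source = "A", target = "A", strength = 1)),
    "duplicate node.*A")
  expect_error(
    thresholdNetwork(data.frame(name = c("A", "B")),
                     data.frame(source = "A", target = "X", strength = 1)),
    "X")
  expect_error(
    thresholdNetwork(data.frame(name = c("A", "B")),
                     data.frame(source = "A", target = "B", strength = 0)),
    "strength")
  expect_error(
    thresholdNetwork(
      data.frame(name = c("A", "B"), is_input = c(FALSE, TRUE)),
      data.frame(source = "A", target = "B", strength = 1)),
    "input node.*B")
})

test_that("serialization round-trips random networks losslessly", {
  for (seed in 1:20) {
    net <- randomNetwork(10, 25, inhibitoryFraction = 0.4, seed = seed)
    nf <- tempfile(fileext = ".tsv"); ef <- tempfile(fileext = ".tsv")
    writeNetwork(net, nf, ef)
    back <- readNetwork(nf, ef)
    expect_identical(nodeTable(back), nodeTable(net))
    expect_identical(edgeTable(back), edgeTable(net))
    unlink(c(nf, ef))
  }
})

test_that("the built-in cancer network matches its published shape", {
  net <- cancerNetwork()
  expect_true(validObject(net))
  expect_identical(nNodes(net), 96L)
  expect_identical(nEdges(net), 249L)
  expect_identical(inputNodes(net),
                   c("Carcinogens", "GFs", "Nutrients", "TNFalpha", "Hypoxia"))
  th <- thresholds(net)
  expect_identical(unname(th["Gsk-3"]), -3L)
  expect_identical(unname(th["hTert"]), 4L)
  expect_identical(unname(th["Hif1"]), -2L)
  expect_identical(unname(th["Akt"]), 1L)
  ed <- edgeTable(net)
  strength_of <- function(s, t) ed$strength[ed$source == s & ed$target == t]
  expect_identical(strength_of("Ikk", "Nf-kB"), 2L)
  expect_identical(strength_of("Nf-kB", "Bcl-2"), 2L)
  expect_identical(strength_of("Gsk-3", "CyclinD"), -2L)
  expect_identical(strength_of("Rb", "E2f"), -2L)
  expect_identical(strength_of("Vhl", "Hif1"), -2L)
  # regression-lock the degree sequence
  g <- asIgraph(net)
  expect_identical(sum(igraph::degree(g, mode = "in")), 249)
  expect_identical(mean(igraph::degree(g, mode = "in")), 249 / 96)
})

test_that("random networks are reproducible, simple, and calibrated", {
  a <- randomNetwork(12, 40, seed = 99)
  b <- randomNetwork(12, 40, seed = 99)
  expect_identical(edgeTable(a), edgeTable(b))
  # saturation: max edges for a simple digraph gives the complete digraph
  full <- randomNetwork(5, 20, seed = 1)
  expect_identical(nEdges(full), 20L)
  ed <- edgeTable(full)
  expect_true(all(ed$source != ed$target))
  expect_false(anyDuplicated(paste(ed$source, ed$target)) > 0)
  expect_error(randomNetwork(5, 21, seed = 1), "infeasible")
  # binomial check on the inhibitory share at m = 10^4
  big <- randomNetwork(150, 10000, inhibitoryFraction = 0.5, seed = 3)
  share <- mean(edgeTable(big)$strength < 0)
  expect_lt(abs(share - 0.5), 3 * sqrt(0.25 / 10000))
  # per-edge-probability variant fluctuates around the requested count
  m <- vapply(1:30, function(s)
    nEdges(randomNetwork(96, 249, seed = s, model = "per_edge")), numeric(1))
  expect_lt(abs(mean(m) - 249), 4 * sqrt(249) / sqrt(30))
})

test_that("microenvironment codes map to input assignments and back", {
  net <- cancerNetwork()
  env <- microenvironment(net, "11000")
  expect_identical(unname(env), c(1L, 1L, 0L, 0L, 0L))
  expect_identical(environmentCode(env), "11000")
  expect_length(allEnvironments(net), 32L)
  expect_error(microenvironment(net, "101"), "binary string")
})
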