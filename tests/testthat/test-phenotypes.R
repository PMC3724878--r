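# small synthetic attractors for classifier checks
fake_attractor <- function(states, nodes) {
  m <- matrix(as.integer(t(rbind(states))), ncol = length(nodes), byrow = TRUE,
              dimnames = list(NULL, nodes))
  new("Attractor", states = m, period = nrow(m), key = "synthetic",
      environment = setNames(integer(), character()))
}

marker_nodes <- c("Caspases", "Hif1", "hTert", "E-cadherin", "Atm/Atr",
                  "DNA_damage", "CyclinD", "CyclinE", "CyclinA", "CyclinB")

test_that("caspase activity dominates the primary label", {
  a <- fake_attractor(c(1, 0, 0, 1, 1, 0, 0, 0, 0, 0), marker_nodes)
  env <- c(Hypoxia = 0L)
  cls <- classifyAttractor(a, env)
  expect_identical(cls$primary, "apoptotic")
  expect_length(cls$traits, 0)
})

test_that("quiescent: caspases off and cyclins silent", {
  a <- fake_attractor(c(0, 0, 0, 1, 1, 0, 0, 0, 0, 0), marker_nodes)
  cls <- classifyAttractor(a, c(Hypoxia = 0L))
  expect_identical(cls$primary, "quiescent")
})

test_that("ordered cyclin firing marks proliferation; traits are read off markers", {
  # period 4, cyclins switch on in the order D, E, A, B
  states <- rbind(
    #  Casp Hif1 hTert Ecad Atm Dmg  D  E  A  B
    c(0, 1, 1, 1, 1, 0,  1, 0, 0, 0),
    c(0, 1, 1, 1, 1, 0,  1, 1, 0, 0),
    c(0, 1, 1, 1, 1, 0,  0, 1, 1, 0),
    c(0, 1, 1, 1, 1, 0,  0, 0, 1, 1))
  a <- fake_attractor(states, marker_nodes)
  cls <- classifyAttractor(a, c(Hypoxia = 0L))
  expect_identical(cls$primary, "proliferative")
  expect_setequal(cls$traits, c("glycolytic", "immortalized"))
  # same cycle under hypoxia: the glycolytic flag is not applicable
  cls_h <- classifyAttractor(a, c(Hypoxia = 1L))
  expect_false("glycolytic" %in% cls_h$traits)
  # wrong order (swap the A and B columns) falls back to quiescent
  b <- fake_attractor(states[, c(1:8, 10, 9)], marker_nodes)
  expect_identical(classifyAttractor(b, c(Hypoxia = 0L))$primary, "quiescent")
  # fixed points can never be proliferative
  fp <- fake_attractor(c(0, 0, 0, 1, 1, 0, 1, 1, 1, 1), marker_nodes)
  expect_identical(classifyAttractor(fp, c(Hypoxia = 0L))$primary, "quiescent")
})

test_that("migratory and mutator traits", {
  a <- fake_attractor(c(0, 0, 0, 0, 0, 1, 0, 0, 0, 0), marker_nodes)
  cls <- classifyAttractor(a, c(Hypoxia = 0L))
  expect_true(all(c("migratory", "mutator") %in% cls$traits))
  # sensors intact: no mutator call
  b <- fake_attractor(c(0, 0, 0, 0, 1, 1, 0, 0, 0, 0), marker_nodes)
  expect_false("mutator" %in% classifyAttractor(b, c(Hypoxia = 0L))$traits)
})

test_that("a missing marker node raises an error", {
  a <- fake_attractor(c(0, 0), c("Caspases", "Hif1"))
  expect_error(classifyAttractor(a, c(Hypoxia = 0L)), "missing")
})

test_that("caspase any/all modes agree on the built-in network", {
  net <- cancerNetwork()
  for (e in c("00100", "01100", "00101", "00110")) {
    cen <- sampleBasins(net, e, pLevels = c(0.25, 0.75),
                        samplesPerLevel = 150, seed = 8)
    for (a in censusAttractors(cen)) {
      any_mode <- classifyAttractor(a, markers = builtin_markers(),
                                    caspaseMode = "any")$primary
      all_mode <- classifyAttractor(a, markers = builtin_markers(),
                                    caspaseMode = "all")$primary
      expect_identical(any_mode, all_mode)
    }
  }
})

test_that("phenotype census conserves basin mass", {
  net <- cancerNetwork()
  cen <- sampleBasins(net, "01101", samplesPerLevel = 300, seed = 2)
  ph <- phenotypeCensus(cen)
  expect_equal(sum(ph$primary), 1, tolerance = 1e-12)
  expect_equal(sum(ph$detail$fraction), 1, tolerance = 1e-12)
  expect_identical(nrow(ph$detail), nrow(censusTable(cen)))
  # every attractor receives exactly one primary label
  expect_true(all(ph$detail$primary %in%
                    c("apoptotic", "proliferative", "quiescent")))
})

test_that("attractor Hamming distances are symmetric with zero diagonal", {
  net <- randomNetwork(10, 30, seed = 12)
  cen <- sampleBasins(net, samplesPerLevel = 300, seed = 5)
  d <- attractorDistances(cen)
  expect_identical(d, t(d))
  expect_true(all(diag(d) == 0L))
  if (nrow(d) >= 2) expect_true(all(d[upper.tri(d)] > 0L))
})
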