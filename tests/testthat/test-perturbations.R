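test_that("mutation operators clamp and rescale as specified", {
  net <- cancerNetwork()
  m <- perturbedModel(net)
  # deletion clamps to 0 and leaves every rule untouched
  del <- applyMutation(m, "p53", "deletion")
  expect_identical(unname(clamps(del)["p53"]), 0L)
  expect_identical(edgeTable(baseNetwork(del)), edgeTable(net))
  # strength scaling doubles outgoing strengths without clamping
  sc <- applyMutation(m, "Akt", "strength_scaling", scale = 2)
  expect_false("Akt" %in% setdiff(names(clamps(sc)), "DNA_damage"))
  ed0 <- edgeTable(net); ed1 <- edgeTable(baseNetwork(sc))
  out <- ed0$source == "Akt"
  expect_identical(ed1$strength[out], 2L * ed0$strength[out])
  expect_identical(ed1$strength[!out], ed0$strength[!out])
  # overexpression = clamp 1 + scaling
  oe <- applyMutation(m, "Snail", "overexpression")
  expect_identical(unname(clamps(oe)["Snail"]), 1L)
  expect_identical(edgeTable(baseNetwork(oe))$strength[ed0$source == "Snail"],
                   2L * ed0$strength[ed0$source == "Snail"])
  # overexpression of a node with no outgoing edges behaves like activation
  sink_net <- thresholdNetwork(data.frame(name = c("A", "B")),
                               data.frame(source = "A", target = "B",
                                          strength = 1))
  mo <- applyMutation(perturbedModel(sink_net, "free"), "B", "overexpression")
  ma <- applyMutation(perturbedModel(sink_net, "free"), "B", "activation")
  expect_identical(clamps(mo), clamps(ma))
  expect_identical(edgeTable(baseNetwork(mo)), edgeTable(sink_net))
  expect_error(applyMutation(m, "NoSuchNode", "deletion"), "unknown node")
})

test_that("DNA-damage bookkeeping follows the model mode", {
  net <- cancerNetwork()
  auto <- applyMutation(perturbedModel(net, "auto_on"), "Ras", "activation")
  expect_identical(unname(clamps(auto)["DNA_damage"]), 1L)
  off <- perturbedModel(net, "forced_off")
  expect_identical(unname(clamps(off)["DNA_damage"]), 0L)
  off <- applyMutation(off, "Ras", "activation")
  expect_identical(unname(clamps(off)["DNA_damage"]), 0L)
  free <- applyMutation(perturbedModel(net, "free"), "Ras", "activation")
  expect_false("DNA_damage" %in% names(clamps(free)))
})

test_that("conflicting clamps error unless overridden", {
  net <- cancerNetwork()
  m <- applyIntervention(perturbedModel(net, "free"), "p53", "activate")
  expect_error(applyIntervention(m, "p53", "inhibit"), "conflict")
  ok <- applyIntervention(m, "p53", "inhibit", override = TRUE)
  expect_identical(unname(clamps(ok)["p53"]), 0L)
  expect_error(applyMutation(m, "p53", "deletion"), "conflict")
})

test_that("input forcing overrides the scenario environment", {
  net <- cancerNetwork()
  m <- applyIntervention(perturbedModel(net, "free"),
                         mode = "force_inputs",
                         forcedInputs = c(Hypoxia = 1, Nutrients = 0))
  cl <- modelClamps(m, "01100")
  expect_identical(unname(cl["Hypoxia"]), 1L)
  expect_identical(unname(cl["Nutrients"]), 0L)
  expect_identical(unname(cl["GFs"]), 1L)
  expect_error(applyIntervention(perturbedModel(net, "free"),
                                 mode = "force_inputs",
                                 forcedInputs = c(p53 = 1)),
               "input nodes")
})

test_that("mutations on disjoint nodes commute", {
  net <- cancerNetwork()
  specs <- list(list("p53", "deletion"), list("Akt", "strength_scaling"),
                list("Ras", "activation"), list("Snail", "overexpression"))
  set.seed(1)
  for (k in 1:6) {
    pair <- sample(specs, 2)
    ab <- applyMutation(applyMutation(perturbedModel(net), pair[[1]][[1]],
                                      pair[[1]][[2]]),
                        pair[[2]][[1]], pair[[2]][[2]])
    ba <- applyMutation(applyMutation(perturbedModel(net), pair[[2]][[1]],
                                      pair[[2]][[2]]),
                        pair[[1]][[1]], pair[[1]][[2]])
    expect_identical(edgeTable(baseNetwork(ab)), edgeTable(baseNetwork(ba)))
    expect_identical(clamps(ab)[sort(names(clamps(ab)))],
                     clamps(ba)[sort(names(clamps(ba)))])
  }
})

test_that("clamped nodes are invariant under the dynamics", {
  for (seed in 1:5) {
    net <- randomNetwork(10, 30, seed = seed)
    cl <- setNames(c(1L, 0L), sample(nodeNames(net), 2))
    set.seed(seed)
    st <- setNames(rbinom(10, 1, 0.5), nodeNames(net))
    st[names(cl)] <- cl
    nxt <- stepNetwork(net, st, clamps = cl)
    expect_identical(nxt[names(cl)], cl)
    fa <- findAttractor(net, st, clamps = cl)
    expect_true(all(attractorStates(fa$attractor)[, names(cl)[1]] == cl[1]))
    expect_true(all(attractorStates(fa$attractor)[, names(cl)[2]] == cl[2]))
  }
})
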