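test_that("the threshold step rule follows the strict step function", {
  # only inhibitory inputs, theta = -1: active when inhibitors are silent
  net <- thresholdNetwork(
    nodes = data.frame(name = c("I", "T"), threshold = c(0L, -1L)),
    edges = data.frame(source = "I", target = "T", strength = -1L))
  expect_identical(unname(stepNetwork(net, c(I = 0, T = 0))["T"]), 1L)
  expect_identical(unname(stepNetwork(net, c(I = 1, T = 1))["T"]), 0L)
  # binary complex, theta = +1: both components required (tie deactivates)
  cx <- thresholdNetwork(
    nodes = data.frame(name = c("A", "B", "C"), threshold = c(0L, 0L, 1L)),
    edges = data.frame(source = c("A", "B"), target = c("C", "C"),
                       strength = c(1L, 1L)))
  expect_identical(unname(stepNetwork(cx, c(1, 0, 0))["C"]), 0L)
  expect_identical(unname(stepNetwork(cx, c(1, 1, 0))["C"]), 1L)
  # mutual activation fixed point
  expect_identical(unname(stepNetwork(toggle_net(), c(A = 1, B = 1))),
                   c(1L, 1L))
  expect_error(stepNetwork(toggle_net(), c(1, 1, 1)), "length")
})

test_that("stepNetwork agrees with the brute-force table oracle", {
  for (seed in 1:10) {
    net <- randomNetwork(8, 20, seed = seed)
    state <- setNames(as.integer(intToBits(seed * 7)[1:8]), nodeNames(net))
    expect_identical(stepNetwork(net, state), brute_step(net, state))
  }
})

test_that("findAttractor recovers cycles and transients exactly", {
  # a state already on a fixed point has transient 0
  fa <- findAttractor(toggle_net(), c(A = 1, B = 1))
  expect_identical(attractorKind(fa$attractor), "fixed_point")
  expect_identical(fa$transient, 0L)

  # three-node ring from (1,0,0): freeze the brute-force enumeration
  for (th in c(0L, -1L)) {
    net <- ring_net(th)
    oracle <- brute_attractor(net, c(1L, 0L, 0L))
    fa <- findAttractor(net, c(X = 1, Y = 0, Z = 0))
    expect_identical(period(fa$attractor), length(oracle$cycle))
    expect_identical(fa$transient, oracle$transient)
  }
  # the strict step function sends the theta=0 ring to the all-off point,
  # while theta=-1 sustains a rotating wave
  expect_identical(period(findAttractor(ring_net(0L), c(1, 0, 0))$attractor), 1L)
  expect_identical(period(findAttractor(ring_net(-1L), c(1, 0, 0))$attractor), 6L)

  expect_error(findAttractor(ring_net(-1L), c(1, 0, 0), maxSteps = 2),
               "maxSteps")
})

test_that("exhaustive enumeration gives exact basins", {
  cen <- enumerateAttractors(self_activator())
  tb <- censusTable(cen)
  expect_identical(nrow(tb), 2L)
  expect_identical(tb$fraction, c(0.5, 0.5))
  expect_identical(sum(tb$count), 2)
  expect_true(all(tb$kind == "fixed_point"))
  expect_error(enumerateAttractors(randomNetwork(30, 100, seed = 1)),
               "free nodes")
})

test_that("enumeration agrees with the independent brute-force oracle", {
  for (seed in c(2, 5, 11)) {
    net <- randomNetwork(9, 24, seed = seed)
    oracle <- brute_basins(net)
    cen <- enumerateAttractors(net)
    tb <- censusTable(cen)
    expect_identical(nrow(tb), length(oracle))
    expect_equal(sort(tb$fraction), sort(unname(oracle)), tolerance = 1e-12)
  }
})

test_that("sampled basins converge to exhaustive fractions (oracle equivalence)", {
  n_samp <- 4000L
  for (seed in 1:20) {
    net <- randomNetwork(10, 26, seed = seed)
    exact <- censusTable(enumerateAttractors(net))
    sam <- censusTable(sampleBasins(net, pLevels = 0.5,
                                    samplesPerLevel = n_samp,
                                    seed = 1000 + seed))
    m <- merge(exact, sam, by = "key", all.x = TRUE,
               suffixes = c(".ex", ".sam"))
    m$fraction.sam[is.na(m$fraction.sam)] <- 0
    se <- sqrt(pmax(m$fraction.ex * (1 - m$fraction.ex), 1 / n_samp) / n_samp)
    expect_true(all(abs(m$fraction.ex - m$fraction.sam) < 4 * se),
                info = paste("seed", seed))
  }
})

test_that("attractors are closed under the dynamics and canonically keyed", {
  net <- randomNetwork(12, 35, seed = 4)
  cen <- sampleBasins(net, samplesPerLevel = 500, seed = 9)
  for (a in censusAttractors(cen)) {
    st <- attractorStates(a)
    for (k in seq_len(nrow(st))) {
      nxt <- stepNetwork(net, st[k, ])
      expect_identical(unname(nxt), unname(st[(k %% nrow(st)) + 1L, ]))
    }
    # canonical rotation: first state is the lexicographic minimum
    strs <- apply(st, 1, paste, collapse = "")
    expect_identical(strs[1], min(strs))
  }
  # the same cycle reached from different transients maps to one key
  net2 <- ring_net(-1L)
  k1 <- attractorKey(findAttractor(net2, c(1, 0, 0))$attractor)
  k2 <- attractorKey(findAttractor(net2, c(0, 1, 1))$attractor)
  expect_identical(k1, k2)
})

test_that("basin sampling is deterministic given a seed and conserves mass", {
  net <- randomNetwork(15, 45, seed = 6)
  a <- censusTable(sampleBasins(net, samplesPerLevel = 400, seed = 42))
  b <- censusTable(sampleBasins(net, samplesPerLevel = 400, seed = 42))
  expect_identical(a, b)
  expect_equal(sum(a$fraction), 1, tolerance = 1e-12)
  expect_identical(sum(a$count), 400 * 11)
})

test_that("attractors are never shared between microenvironments", {
  net <- cancerNetwork()
  seen <- list()
  for (e in allEnvironments(net)) {
    cen <- sampleBasins(net, e, pLevels = c(0.2, 0.5, 0.8),
                        samplesPerLevel = 60, seed = 3)
    keys <- censusTable(cen)$key
    for (prev in names(seen))
      expect_length(intersect(keys, seen[[prev]]), 0)
    seen[[e]] <- keys
  }
})
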