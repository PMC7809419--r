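test_that("packaged CCM network has the documented dimensions and valid structure", {
  net <- ccm_net()
  k <- speciesCounts(net)
  expect_identical(unname(k[c("p", "s", "m", "c")]), c(37L, 29L, 41L, 27L))
  expect_true(validObject(net))
  # every constant in range, every matrix entry in {-1, 0, +1}
  expect_true(all(net@interactionMatrix %in% c(-1L, 0L, 1L)))
  expect_true(all(net@stoichMatrix %in% c(-1L, 0L, 1L)))
  for (r in net@geneRules) {
    expect_true(all(c(r@activators, r@enhMet, r@enhInput, r@inhMet,
                      r@inhInput, r@inhSig) >= 0))
    expect_true(all(c(r@activators, r@enhMet, r@enhInput, r@inhMet,
                      r@inhInput, r@inhSig) < 1))
    expect_true(r@basal > 0 && r@basal < 1)
    expect_true(r@decay > 0 && r@decay < 1)
  }
  for (r in net@reactionRules) {
    expect_true(r@K > 0 && r@K <= 1)
    expect_true(r@Km > 0 && r@Km <= 1)
    expect_length(r@catGene, 1L)
  }
})

test_that("stoichiometric and interaction matrix columns match their rules", {
  for (net in list(toy_net(), ccm_net())) {
    mn <- net@metaboliteNames; sn <- net@signalNames
    for (j in seq_along(net@reactionRules)) {
      r <- net@reactionRules[[j]]
      expect_setequal(mn[net@stoichMatrix[, j] == -1], r@substrates)
      expect_setequal(mn[net@stoichMatrix[, j] == 1], r@products)
    }
    for (j in seq_along(net@interactionRules)) {
      r <- net@interactionRules[[j]]
      plus <- sn[net@interactionMatrix[, j] == 1]
      expect_setequal(plus, if (is.na(r@target)) character(0) else r@target)
      expect_setequal(sn[net@interactionMatrix[, j] == -1], r@consumes)
    }
  }
})

test_that("save/load round-trips a network exactly", {
  for (net in list(toy_net(), ccm_net())) {
    path <- withr::local_tempfile(fileext = ".net.json")
    saveNetwork(net, path)
    back <- loadNetwork(path)
    expect_true(isTRUE(networkEquals(net, back)))
  }
})

test_that("the comparator detects a mutated constant after a round trip", {
  net <- toy_net()
  path <- withr::local_tempfile(fileext = ".net.json")
  saveNetwork(net, path)
  back <- loadNetwork(path)
  back@reactionRules[[1]]@K <- back@reactionRules[[1]]@K + 1e-3
  diffs <- networkEquals(net, back)
  expect_false(isTRUE(diffs))
  expect_true(any(grepl("reaction_rules", diffs)))
})

test_that("a degenerate network with no interactions round-trips", {
  net <- pathwayNetwork(
    geneNames = "g1", signalNames = "y1", metaboliteNames = "z1",
    inputNames = "u1",
    geneRules = list(geneRule("g1", 0.1, 0.2,
                              activators = c(y1 = 0.5))),
    interactionRules = list(),
    reactionRules = list(reactionRule("r1", character(0), "z1", "g1",
                                      0.5, 0.5)))
  expect_identical(dim(net@interactionMatrix), c(1L, 0L))
  path <- withr::local_tempfile(fileext = ".net.json")
  saveNetwork(net, path)
  expect_true(isTRUE(networkEquals(net, loadNetwork(path))))
})

test_that("invalid matrix entries are rejected with the matrix named", {
  net <- toy_net()
  path <- withr::local_tempfile(fileext = ".net.json")
  saveNetwork(net, path)
  doc <- jsonlite::fromJSON(path, simplifyVector = TRUE,
                            simplifyDataFrame = FALSE,
                            simplifyMatrix = FALSE)
  doc$stoich_matrix$values[[1]] <- 2
  writeLines(jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA,
                              null = "null"), path)
  expect_error(loadNetwork(path), "stoich_matrix")
})

test_that("rule validity errors name the offending field", {
  expect_error(geneRule("g", basal = 0.1, decay = 0.2,
                        activators = c(y1 = 1.2)),
               "activators")
  expect_error(reactionRule("r", "a", "b", "g", K = 1.5, Km = 0.2),
               "rate constant")
  expect_error(interactionRule("i", target = "y1", rate = 0),
               "rate constant")
})

test_that("toy network generation is seed-deterministic and valid at several sizes", {
  a <- buildToyNetwork(2, 2, 3, 1, seed = 7)
  b <- buildToyNetwork(2, 2, 3, 1, seed = 7)
  expect_true(isTRUE(networkEquals(a, b)))
  expect_false(isTRUE(networkEquals(a, buildToyNetwork(2, 2, 3, 1, seed = 8))))
  for (dims in list(c(1, 1, 1, 1), c(3, 3, 4, 2), c(5, 2, 6, 3))) {
    net <- buildToyNetwork(dims[1], dims[2], dims[3], dims[4], seed = 1)
    expect_true(validObject(net))
    k <- speciesCounts(net)
    expect_true(k[["q"]] >= 1 && k[["n"]] >= 1)
    for (r in net@reactionRules)
      expect_true(r@K > 0 && r@K <= 1 && r@Km > 0 && r@Km <= 1)
    for (r in net@interactionRules)
      expect_true(all(r@activators >= 0 & r@activators < 1))
  }
  expect_error(buildToyNetwork(0, 1, 1, 1), "counts")
})
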