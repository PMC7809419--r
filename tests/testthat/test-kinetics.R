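# Micro-networks wired so each rate-law branch can be checked against
# hand arithmetic.
kin_net <- function() {
  pathwayNetwork(
    geneNames = "g1",
    signalNames = c("y1", "y2"),
    metaboliteNames = c("z1", "z2"),
    inputNames = "u1",
    geneRules = list(
      geneRule("g1", basal = 0.1, decay = 0.05,
               activators = c(y1 = 0.5), enhMet = c(z1 = 0.5))),
    interactionRules = list(
      interactionRule("act_y1", target = "y1", activators = c(y2 = 0.5),
                      rate = 1)),
    reactionRules = list(
      reactionRule("r1", substrates = "z1", products = "z2",
                   catGene = "g1", K = 1, Km = 1)))
}

state_of <- function(x, y, z) c(x, y, z)

test_that("gene rate law reproduces the hand-worked branch values", {
  net <- kin_net()
  rule <- net@geneRules[[1]]
  # cofactor-enhanced expression: (1 + 0.5*0.4) * (0.5*0.8) + 0.1 - 0.05
  st <- state_of(0.5, c(0.8, 0.3), c(0.4, 0.2))
  expect_equal(geneRate(rule, net, st, u = 0.5), 1.2 * 0.4 + 0.1 - 0.05)
  # absent transcription factor: exactly basal - decay
  st0 <- state_of(0.5, c(0, 0.3), c(0.4, 0.2))
  expect_identical(geneRate(rule, net, st0, u = 0.5), 0.1 - 0.05)
  # inhibited form divides expression plus basal production
  inh <- geneRule("g1", basal = 0.1, decay = 0.05,
                  activators = c(y1 = 0.5), inhMet = c(z1 = 0.5))
  st1 <- state_of(0.5, c(0.8, 0.3), c(0.5, 0.2))
  expect_equal(geneRate(inh, net, st1, u = 0.5), (0.4 + 0.1) / 1.25 - 0.05)
  # with no modifiers at all the rate is expression + basal - decay
  plain <- geneRule("g1", basal = 0.1, decay = 0.05,
                    activators = c(y1 = 0.5))
  expect_equal(geneRate(plain, net, st, u = 0.5), 0.4 + 0.1 - 0.05)
})

test_that("signaling rates follow the enhanced and inhibited mass-action forms", {
  base <- function(...) pathwayNetwork(
    geneNames = "g1", signalNames = c("y1", "y2"),
    metaboliteNames = "z1", inputNames = "u1",
    geneRules = list(geneRule("g1", 0.1, 0.05, activators = c(y1 = 0.5))),
    interactionRules = list(interactionRule("i1", target = "y1",
                                            activators = c(y2 = 0.5), ...)),
    reactionRules = list(reactionRule("r1", character(0), "z1", "g1",
                                      0.5, 0.5)))
  st <- state_of(0.5, c(0.2, 0.6), 0.4)
  expect_equal(unname(signalingRates(base(), st, 0.5)[1]), 0.30)
  expect_equal(unname(signalingRates(base(enhMet = c(z1 = 0.5)), st, 0.5)[1]),
               0.30 * 1.2)
  expect_equal(unname(signalingRates(base(inhMet = c(z1 = 0.5)), st, 0.5)[1]),
               0.30 / 1.2)
  # a rate is exactly zero when a required activator is absent
  st0 <- state_of(0.5, c(0.2, 0), 0.4)
  expect_identical(unname(signalingRates(base(), st0, 0.5)[1]), 0)
})

test_that("metabolic fluxes follow modified Michaelis-Menten kinetics", {
  net <- kin_net()
  # half saturation: K=1, E=1, z=1, Km=1 -> 0.5
  st <- state_of(1, c(0.5, 0.5), c(1, 0.4))
  expect_equal(unname(metabolicRates(net, st, 0.5)[1]), 0.5)
  # enhancer multiplies the flux
  enh <- kin_net()
  enh@reactionRules[[1]]@enhMet <- c(z2 = 0.5)
  expect_equal(unname(metabolicRates(enh, st, 0.5)[1]), 0.5 * 1.2)
  # knockout: zero rate constant makes the flux identically zero
  ko <- kin_net()
  ko@reactionRules[[1]]@K <- 0
  for (i in 1:20) {
    stR <- runif(5)
    expect_identical(unname(metabolicRates(ko, stR, runif(1))[1]), 0)
  }
  # absent substrate nullifies the flux
  st0 <- state_of(1, c(0.5, 0.5), c(0, 0.4))
  expect_identical(unname(metabolicRates(net, st0, 0.5)[1]), 0)
})

test_that("the full derivative assembles the timescale-scaled products", {
  # one interaction producing y1 and consuming y2 at rate 0.2
  net <- pathwayNetwork(
    geneNames = "g1", signalNames = c("y1", "y2"), metaboliteNames = "z1",
    inputNames = "u1",
    geneRules = list(geneRule("g1", 0.1, 0.05, activators = c(y1 = 0.5))),
    interactionRules = list(
      interactionRule("i1", target = "y1", activators = c(y2 = 0.5),
                      rate = 0.5, consumes = "y2")),
    reactionRules = list(reactionRule("r1", character(0), "z1", "g1",
                                      0.5, 0.5)))
  st <- state_of(0.5, c(0.3, 0.8), 0.5)
  d <- fullDerivative(net, st, 0.5, omega1 = 1 / 60, omega2 = 1)
  expect_equal(unname(d$ydot), c(12, -12))       # (1/omega1) * N_s %*% 0.2
  # identity scaling at omega = 1
  d1 <- fullDerivative(net, st, 0.5, omega1 = 1, omega2 = 1)
  rs <- signalingRates(net, st, 0.5)
  rm <- metabolicRates(net, st, 0.5)
  expect_equal(unname(d1$ydot),
               unname(as.numeric(net@interactionMatrix %*% rs)))
  expect_equal(unname(d1$zdot),
               unname(as.numeric(net@stoichMatrix %*% rm)))
  # with all activities silenced (no enzyme, no activators) the gene
  # layer falls back to basal - decay and the fast layers are static
  st0 <- state_of(0, c(0, 0), 0)
  d0 <- fullDerivative(net, st0, 0)
  expect_equal(unname(d0$xdot), 0.1 - 0.05)
  expect_equal(unname(d0$ydot), rep(0, 2))
  expect_equal(unname(d0$zdot), 0)
})

test_that("rates are nonnegative and fluxes monotone over random states", {
  net <- toy_net()
  k <- speciesCounts(net)
  nstate <- sum(k[c("p", "s", "m")])
  ptr <- pathMPC:::.compiledModel(net)
  set.seed(31)
  for (i in seq_len(10000)) {
    r <- pathMPC:::.model_rates(ptr, runif(nstate), runif(k[["c"]]))
    if (any(r$rs < 0) || any(r$rm < 0))
      fail(sprintf("negative rate at draw %d", i))
  }
  succeed()
  # monotonicity in substrate and enzyme level; saturation bound
  rx <- net@reactionRules[[2]]            # z1 -> z2, catalyzed chain gene
  gi <- match(rx@catGene, net@geneNames)
  zi <- k[["p"]] + k[["s"]] + match(rx@substrates[1], net@metaboliteNames)
  st <- runif(nstate, 0.3, 0.7); u <- rep(0.5, k[["c"]])
  grid <- seq(0.01, 0.99, length.out = 25)
  fl_sub <- vapply(grid, function(v) {
    s2 <- st; s2[zi] <- v
    unname(metabolicRates(net, s2, u)[rx@id])
  }, numeric(1))
  expect_true(all(diff(fl_sub) >= -1e-12))
  fl_E <- vapply(grid, function(v) {
    s2 <- st; s2[gi] <- v
    unname(metabolicRates(net, s2, u)[rx@id])
  }, numeric(1))
  expect_true(all(diff(fl_E) >= -1e-12))
  # saturates below K * E * (enhancer product); enhancers bounded by 2 per term
  enhBound <- prod(1 + rx@enhMet) * prod(1 + rx@enhInput)
  expect_true(max(fl_sub) <= rx@K * st[gi] * enhBound + 1e-12)
})

test_that("compiled and reference derivative implementations agree", {
  for (net in list(toy_net(), ccm_net())) {
    k <- speciesCounts(net)
    nstate <- sum(k[c("p", "s", "m")])
    ptr <- pathMPC:::.compiledModel(net)
    set.seed(11)
    for (i in 1:25) {
      st <- runif(nstate); u <- runif(k[["c"]])
      ref <- fullDerivative(net, st, u, 1 / 60, 1 / 60)
      cmp <- pathMPC:::.model_rhs(ptr, st, u, 1 / 60, 1 / 60, FALSE,
                                  integer(0), numeric(0))
      expect_equal(unname(c(ref$xdot, ref$ydot, ref$zdot)), as.numeric(cmp),
                   tolerance = 1e-12)
    }
  }
})
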