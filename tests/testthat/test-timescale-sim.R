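# A hand-built linear-ish cascade: input drives y, y drives z. Used for
# fixed-point and mode-equivalence checks where behavior is predictable.
lin_net <- function() {
  pathwayNetwork(
    geneNames = "g1", signalNames = "y1", metaboliteNames = "z1",
    inputNames = "u1",
    geneRules = list(geneRule("g1", 0.1, 0.1, activators = c(y1 = 0.5))),
    interactionRules = list(
      interactionRule("src", target = "y1", rate = 0.4,
                      enhInput = c(u1 = 0.5)),
      interactionRule("dec", activators = c(y1 = 0.8), consumes = "y1")),
    reactionRules = list(
      reactionRule("in", character(0), "z1", "g1", 0.5, 0.5,
                   enhInput = c(u1 = 0.4)),
      reactionRule("out", "z1", character(0), "g1", 0.6, 0.5)))
}

test_that("the integrator relaxes fast layers onto their fixed point", {
  net <- lin_net()
  u <- 0.5
  cfg <- timescaleConfig(omega1 = 1 / 20, omega2 = 1 / 20,
                         tGrid = seq(0, 8, by = 0.5))
  tr <- integrateNetwork(net, c(0.5, 0.1, 0.9), u, cfg)
  S <- stateMatrix(tr)
  # y* = rate * (1 + F u) / k_dec, independent of the start
  ystar <- 0.4 * (1 + 0.5 * 0.5) / 0.8
  expect_equal(unname(S[nrow(S), "y1"]), ystar, tolerance = 1e-4)
  tr2 <- integrateNetwork(net, c(0.5, 0.9, 0.1), u, cfg)
  expect_equal(unname(stateMatrix(tr2)[nrow(S), "y1"]), ystar,
               tolerance = 1e-4)
  # z settles where inflow equals outflow given the enzyme level
  zend <- S[nrow(S), "z1"]
  E <- S[nrow(S), "g1"]
  inflow <- 0.5 * E / (0.5 + 1) * (1 + 0.4 * u)
  outflow <- 0.6 * E * zend / (0.5 + zend)
  expect_equal(unname(inflow), unname(outflow), tolerance = 1e-3)
})

test_that("at unit timescale ratios the solver matches an independent reference", {
  net <- toy_net()
  k <- speciesCounts(net)
  nstate <- sum(k[c("p", "s", "m")])
  set.seed(3)
  init <- runif(nstate, 0.2, 0.8)
  u <- rep(0.5, k[["c"]])
  cfg <- timescaleConfig(omega1 = 1, omega2 = 1, tGrid = seq(0, 4, 0.5),
                         clamp = FALSE, absTol = 1e-10, relTol = 1e-9)
  tr <- integrateNetwork(net, init, u, cfg)
  # oracle: deSolve on the unscaled system through the plain R rate laws
  rhs <- function(t, y, p) {
    # rates are evaluated at box-clamped states, like the solver's kernel
    d <- fullDerivative(net, clamp01(y), u, omega1 = 1, omega2 = 1)
    list(c(d$xdot, d$ydot, d$zdot))
  }
  ref <- deSolve::lsoda(init, cfg$tGrid, rhs, NULL, rtol = 1e-9,
                        atol = 1e-10)
  expect_lt(max(abs(stateMatrix(tr) - ref[, -1])), 1e-6)
})

test_that("direct stiff and nested multirate modes agree on a toy", {
  net <- lin_net()
  init <- c(0.4, 0.3, 0.6); u <- 0.5
  grid <- seq(0, 2, by = 0.25)
  a <- integrateNetwork(net, init, u,
                        timescaleConfig(1 / 8, 1 / 8, grid,
                                        mode = "direct_stiff",
                                        relTol = 1e-8, absTol = 1e-10))
  b <- integrateNetwork(net, init, u,
                        timescaleConfig(1 / 8, 1 / 8, grid,
                                        mode = "nested_multirate"))
  expect_lt(max(abs(stateMatrix(a) - stateMatrix(b))), 1e-2)
})

test_that("box-root solving recovers closed-form equilibria", {
  # y = x (root of x - y)
  s1 <- solveBoxRoot(function(y) 0.25 - y, init = 0.5)
  expect_equal(s1$root, 0.25, tolerance = 1e-9)
  # x*u - y^2 with x = 0.25, u = 1 -> y* = 0.5
  s2 <- solveBoxRoot(function(y) 0.25 * 1 - y^2, init = 0.9)
  expect_equal(s2$root, 0.5, tolerance = 1e-8)
  # Michaelis balance: K E z/(Km + z) = inflow 0.2 with K = E = Km = 1
  # => z/(1+z) = 0.2 => z* = 0.25
  s3 <- solveBoxRoot(function(z) 0.2 - z / (1 + z), init = 0.5)
  expect_equal(s3$root, 0.25, tolerance = 1e-8)
})

test_that("network QSS maps satisfy their defining residuals", {
  # a cascade whose outflow capacity always exceeds the maximal inflow,
  # so an interior metabolite equilibrium exists for every (x, u)
  net <- pathwayNetwork(
    geneNames = "g1", signalNames = "y1", metaboliteNames = "z1",
    inputNames = "u1",
    geneRules = list(geneRule("g1", 0.1, 0.1, activators = c(y1 = 0.5))),
    interactionRules = list(
      interactionRule("src", target = "y1", rate = 0.4,
                      enhInput = c(u1 = 0.5)),
      interactionRule("dec", activators = c(y1 = 0.8), consumes = "y1")),
    reactionRules = list(
      reactionRule("in", character(0), "z1", "g1", 0.3, 0.5,
                   enhInput = c(u1 = 0.4)),
      reactionRule("out", "z1", character(0), "g1", 0.6, 0.5)))
  ptr <- pathMPC:::.compiledModel(net)
  set.seed(17)
  for (i in 1:20) {
    x <- runif(1, 0.2, 0.8); u <- runif(1)
    ystar <- qssFast(net, x, u)
    expect_lt(attr(ystar, "residual"), 1e-8)
    zstar <- attr(ystar, "z")
    r <- pathMPC:::.model_rates(ptr, c(x, as.numeric(ystar),
                                       as.numeric(zstar)), u)
    expect_lt(max(abs(r$gdot)), 1e-8)
    z2 <- qssUltrafast(net, x, as.numeric(ystar), u,
                       zInit = as.numeric(zstar))
    expect_lt(attr(z2, "residual"), 1e-9)
  }
  # the fast-layer map also solves on the random toy fixture
  toy <- toy_net()
  kt <- speciesCounts(toy)
  for (i in 1:5) {
    x <- runif(kt[["p"]], 0.2, 0.8); u <- runif(kt[["c"]])
    ystar <- qssFast(toy, x, u)
    expect_lt(attr(ystar, "residual"), 1e-8)
  }
})

test_that("the reduced slow model approaches the full simulation as the ratios shrink", {
  net <- lin_net()
  init <- c(0.4, 0.3, 0.6); u <- 0.5
  grid <- seq(0, 3, by = 0.5)
  errs <- vapply(c(1 / 4, 1 / 16, 1 / 60), function(w) {
    tr <- integrateNetwork(net, init, u, timescaleConfig(w, w, grid))
    # reduced model: integrate x alone with y, z at their QSS maps
    x <- init[1]; xs <- x
    for (i in seq_len(length(grid) - 1)) {
      h <- grid[i + 1] - grid[i]
      for (sub in 1:4) {
        d <- reducedSlowDerivative(net, x, u)
        x <- clamp01(x + h / 4 * as.numeric(d))
      }
      xs <- c(xs, x)
    }
    max(abs(stateMatrix(tr)[, 1] - xs))
  }, numeric(1))
  expect_lt(errs[3], 0.05)
  expect_true(errs[3] <= errs[1] + 1e-8)
  # after burn-in the metabolites track the ultrafast QSS map
  w <- 1 / 16
  tr <- integrateNetwork(net, init, u, timescaleConfig(w, w, grid))
  S <- stateMatrix(tr)
  last <- nrow(S)
  zq <- qssUltrafast(net, S[last, 1], S[last, 2], u)
  expect_lt(abs(S[last, 3] - as.numeric(zq)), 5 * w)
})

test_that("equilibrium-input solving matches algebra and least squares", {
  # single input entering only the metabolite inflow: residual vanishes
  # when inflow(u) = outflow(z)
  net <- pathwayNetwork(
    geneNames = "g1", signalNames = "y1", metaboliteNames = "z1",
    inputNames = "u1",
    geneRules = list(geneRule("g1", 0.1, 0.1, activators = c(y1 = 0.5))),
    interactionRules = list(
      interactionRule("src", target = "y1", rate = 0.4),
      interactionRule("dec", activators = c(y1 = 0.8), consumes = "y1")),
    reactionRules = list(
      reactionRule("in", character(0), "z1", "g1", 0.5, 0.5,
                   enhInput = c(u1 = 0.4)),
      reactionRule("out", "z1", character(0), "g1", 0.6, 0.5)))
  # the signaling fixed point is input-independent here
  ystar <- 0.4 / 0.8
  E <- 0.55
  # pick z so that some u in (0,1) balances: inflow(u)=0.5E/1.5*(1+0.4u)
  z <- 0.8
  out <- 0.6 * E * z / (0.5 + z)
  # solve (1+0.4u) = out / (0.5E/1.5) -> u
  uTrue <- (out / (0.5 * E / 1.5) - 1) / 0.4
  stopifnot(uTrue > 0, uTrue < 1)
  # gene layer cannot be silenced (constant basal-decay=0), so the
  # minimizer should still land on the u that zeroes the fast layers
  ufit <- solveEquilibriumInput(net, c(E, ystar, z), uInit = 0.2)
  expect_equal(unname(as.numeric(ufit)), uTrue, tolerance = 1e-3)
  # random-restart property: the returned input is at least as good as
  # random draws
  obj <- function(u) {
    r <- pathMPC:::.model_rates(pathMPC:::.compiledModel(net),
                                c(E, ystar, z), u)
    sum(r$xdot^2) + sum(r$gdot^2) + sum(r$hdot^2)
  }
  set.seed(4)
  draws <- vapply(1:100, function(i) obj(runif(1)), numeric(1))
  expect_true(obj(as.numeric(ufit)) <= min(draws) + 1e-10)
})

test_that("trajectories are reproducible and CSV output is faithful", {
  net <- toy_net()
  k <- speciesCounts(net)
  init <- rep(0.4, sum(k[c("p", "s", "m")]))
  u <- rep(0.5, k[["c"]])
  cfg <- timescaleConfig(1 / 8, 1 / 8, seq(0, 2, 0.5))
  a <- integrateNetwork(net, init, u, cfg)
  b <- integrateNetwork(net, init, u, cfg)
  expect_identical(stateMatrix(a), stateMatrix(b))
  path <- withr::local_tempfile(fileext = ".csv")
  writeTrajectoryCSV(a, path)
  df <- utils::read.csv(path, check.names = FALSE)
  expect_identical(names(df), c("time", speciesNames(net, "all")))
  expect_equal(as.matrix(df[, -1]), stateMatrix(a), tolerance = 1e-12,
               ignore_attr = TRUE)
})
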