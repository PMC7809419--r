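test_that("fitness is the reciprocal-L1 cost of the predicted tracking error", {
  nout <- 4; nio <- 6
  exact <- function(V) V[, ncol(V) - nio + seq_len(nout), drop = FALSE]
  vContext <- runif(2 * (nio + nout) + nio)
  ref <- c(0.2, 0.4, 0.6, 0.8)
  # an input whose predicted output equals the reference scores exactly 1
  g1 <- c(ref, 0.5, 0.5)
  expect_equal(unname(gaFitness(g1, exact, vContext, ref)), 1)
  # an L1 prediction error of 1 scores 1/2
  g2 <- c(ref + 0.25, 0.5, 0.5)
  expect_equal(unname(gaFitness(g2, exact, vContext, ref)), 0.5)
  # strictly decreasing in the prediction error
  set.seed(10)
  errs <- sort(runif(20, 0, 3))
  fits <- vapply(errs, function(e)
    gaFitness(c(ref + e / nout, 0.5, 0.5), exact, vContext, ref),
    numeric(1))
  expect_true(all(diff(fits) < 0))
  # per-output weights rescale the cost
  w <- c(10, 1, 1, 1)
  gw <- c(ref + c(0.1, 0, 0, 0), 0.5, 0.5)
  expect_equal(unname(gaFitness(gw, exact, vContext, ref, weights = w)),
               1 / (1 + 10 * 0.1))
})

test_that("evolution keeps genomes in the unit box with monotone best fitness", {
  nout <- 4; nio <- 6
  exact <- function(V) V[, ncol(V) - nio + seq_len(nout), drop = FALSE]
  vContext <- runif(2 * (nio + nout) + nio)
  ref <- rep(0.5, nout)
  cur <- runif(nio)
  for (mode in c("uniform", "single_point")) {
    sol <- gaEvolve(cur, vContext, ref, exact,
                    cfg = gaConfig(crossover = mode, crossoverIndex = 3),
                    seed = 2)
    expect_true(all(sol$input >= 0 & sol$input <= 1))
    expect_true(all(diff(sol$history) >= 0))
  }
  # the locus mutation mode also respects the box and elitism
  sol <- gaEvolve(cur, vContext, ref, exact,
                  cfg = gaConfig(mutation = "locus"), seed = 2)
  expect_true(all(sol$input >= 0 & sol$input <= 1))
  expect_true(all(diff(sol$history) >= 0))
})

test_that("a reachable reference is solved immediately by elitism", {
  nout <- 2; nio <- 3
  exact <- function(V) V[, ncol(V) - nio + seq_len(nout), drop = FALSE]
  vContext <- runif(nio + nout + nio)
  cur <- c(0.3, 0.7, 0.5)
  sol <- gaEvolve(cur, vContext, reference = c(0.3, 0.7), exact,
                  cfg = gaConfig(fitnessThreshold = 0.999), seed = 5)
  expect_identical(sol$generations, 0L)
  expect_equal(unname(sol$input), cur)
})

test_that("the GA locates the preimage of a quadratic response", {
  # single-output surrogate gamma_hat = (first input locus)^2
  quad <- function(V) matrix(V[, ncol(V) - 2 + 1]^2, nrow(V), 1)
  vContext <- runif(8)
  hits <- vapply(1:20, function(sd) {
    sol <- gaEvolve(c(0.9, 0.5), vContext, reference = 0.25, quad,
                    cfg = gaConfig(maxGenerations = 25,
                                   fitnessThreshold = 0.999), seed = sd)
    sol$input[1]
  }, numeric(1))
  expect_true(mean(abs(hits - 0.5) <= 0.05) >= 0.95)
})

test_that("the closed loop converges on an identity plant with an exact surrogate", {
  net <- toy_net()
  pl <- buildPlant(net, initSeed = 2, stepHorizon = 1e-9)
  exact <- identity_surrogate(net, tau = 3)
  hist <- controlHistory(pl, tau = 3)
  conv <- logical(20); iters <- integer(20)
  for (s in 1:20) {
    res <- controlLoop(pl, exact, hist, setpoints = c(z2 = 0.8),
                       l1Threshold = 0.02, maxIter = 30,
                       cfg = gaConfig(), seed = s)
    conv[s] <- res$converged
    iters[s] <- res$iterations
  }
  expect_gte(mean(conv), 0.95)
  expect_lte(max(iters[conv]), 30)
  # the achieved setpoint is tracked on the actual plant output
  res <- controlLoop(pl, exact, hist, setpoints = c(z2 = 0.8),
                     l1Threshold = 0.02, maxIter = 30,
                     cfg = gaConfig(), seed = 1)
  expect_lt(abs(res$output[["z2"]] - 0.8), 0.03)
})

test_that("the loop is seed-deterministic and respects a trivial threshold", {
  net <- toy_net()
  pl <- buildPlant(net, initSeed = 2, stepHorizon = 1e-9)
  exact <- identity_surrogate(net, tau = 3)
  hist <- controlHistory(pl, tau = 3)
  a <- controlLoop(pl, exact, hist, setpoints = c(z2 = 0.8),
                   maxIter = 10, seed = 7)
  b <- controlLoop(pl, exact, hist, setpoints = c(z2 = 0.8),
                   maxIter = 10, seed = 7)
  expect_identical(a$output, b$output)
  expect_identical(a$trace, b$trace)
  # an enormous threshold accepts the very first iteration
  big <- controlLoop(pl, exact, hist, setpoints = c(z2 = 0.8),
                     l1Threshold = sum(speciesCounts(net)[c("p", "s", "m")]),
                     maxIter = 10, seed = 7)
  expect_true(big$converged)
  expect_identical(big$iterations, 1L)
})

test_that("the cached-context GA predictor matches the full kernel expansion", {
  m <- toy_surrogate()
  d <- ncol(m@SV)
  k <- speciesCounts(toy_net())
  nio <- sum(k[c("p", "s", "m", "c")])
  set.seed(9)
  vContext <- runif(d)
  G <- matrix(runif(5 * nio), 5, nio)
  fast <- pathMPC:::.gaPredictor(m, vContext, nio)(G)
  slow <- predictSurrogate(m, pathMPC:::.withCurrentInput(vContext, G))
  attr(slow, "clamped") <- NULL
  expect_equal(unname(fast), unname(slow), tolerance = 1e-10)
})
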