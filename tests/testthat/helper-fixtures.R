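# Shared fixtures. Heavy CCM artifacts are built lazily once per test run
# and cached in this environment so several test files can reuse them.
.fx <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fx[[name]])) .fx[[name]] <- builder()
  .fx[[name]]
}

toy_net <- function() fixture("toy_net", function()
  buildToyNetwork(3, 3, 4, 2, seed = 5))

toy_plant <- function() fixture("toy_plant", function()
  buildPlant(toy_net(), initSeed = 2))

toy_dataset <- function() fixture("toy_dataset", function()
  generateDataset(toy_plant(), phi = 80, tau = 3, seed = 9))

toy_split <- function() fixture("toy_split", function()
  splitDataset(toy_dataset(), 0.65, seed = 1))

toy_surrogate <- function() fixture("toy_surrogate", function()
  fitSurrogate(toy_split()$train))

ccm_net <- function() fixture("ccm_net", function() ccmNetwork())

# scenario runs (trajectory simulations, a few seconds each)
scenario_run <- function(name) fixture(paste0("scen_", name), function() {
  arts <- list(network = ccm_net())
  if (!is.null(.fx$scen_normal) && name != "normal")
    arts$normalTrajectory <- .fx$scen_normal$trajectory
  runScenario(name, artifacts = arts)
})

# the controlled cancer scenario and its surrogate (minutes; shared by the
# scenario and acceptance tests)
cancer_artifacts <- function() fixture("cancer_arts", function() {
  scen <- ccmScenario("cancer")
  plant <- pathMPC:::.scenario_plant(scen, ccm_net())
  surrogate <- cancerSurrogate(plant)
  list(network = ccm_net(), surrogate = surrogate,
       normalTrajectory = scenario_run("normal")$trajectory)
})

cancer_run <- function() fixture("cancer_run", function()
  runScenario("cancer", artifacts = cancer_artifacts()))

# exact surrogate for the identity-plant controller experiments
identity_surrogate <- function(network, tau) {
  k <- speciesCounts(network)
  nout <- sum(k[c("p", "s", "m")]); nio <- nout + k[["c"]]
  f <- function(V) V[, ncol(V) - nio + seq_len(nout), drop = FALSE]
  attr(f, "tau") <- as.integer(tau)
  f
}
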