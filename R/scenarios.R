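#' Packaged central-carbon-metabolism scenarios
#'
#' The shipped experiment matrix on the curated CCM network:
#' \describe{
#'   \item{normal}{baseline micro-environment; asserts the qualitative
#'     normal-behavior checklist (PEP, oxaloacetate and citrate surge
#'     during the growth phase; ribose-5P, NADPH, FFA, G6P and glucose
#'     accumulate as the expression program ramps up).}
#'   \item{warburg}{six knocked-out reactions (pyruvate dehydrogenase,
#'     pyruvate carboxylase, acyl-CoA synthetase, fatty acid synthase,
#'     PEP carboxykinase 1, succinyl-CoA synthetase); asserts lactate,
#'     pyruvate and p53 up and FFA, citrate, succinate, ATP, NADPH and
#'     glucose down versus the seed-matched normal run.}
#'   \item{hypoxia}{hexokinase, aldolase and pyruvate kinase pinned high
#'     with oxygen low; asserts lactate up versus normal.}
#'   \item{insulin_deprivation}{LDH pinned low, GLUT1 pinned high with
#'     insulin withdrawn; asserts lactate down versus normal.}
#'   \item{cancer}{the Warburg-perturbed plant under closed-loop GA
#'     control toward ATP 0.95 and ribose-5P 0.70; asserts the full
#'     cancer-versus-normal direction table (metabolic, signaling and
#'     gene-regulatory rows).}
#' }
#' Drug-target cases are run on top of a converged cancer loop with
#' [runDrugTarget()].
#'
#' @param name scenario name.
#' @return `ccmScenario`: one scenario definition (list);
#'   `ccmScenarioNames`: the registered names.
#' @export
ccmScenario <- function(name) {
  defs <- .scenario_registry()
  if (!name %in% names(defs))
    stop("unknown scenario '", name, "'; registered: ",
         paste(names(defs), collapse = ", "))
  defs[[name]]
}

#' @rdname ccmScenario
#' @export
ccmScenarioNames <- function() names(.scenario_registry())

# Warburg knockout set (reaction ids in the packaged network)
.warburgKnockouts <- c("pdh", "pc", "acsl", "fasn", "pepck1", "scs")

.dir_assert <- function(species, direction, from = NULL, to = c(0.9, 1),
                        comparator = NULL, group = "metabolic",
                        kind = "level")
  list(species = species, direction = direction, from = from, to = to,
       comparator = comparator, group = group, kind = kind)

.scenario_registry <- function() {
  growth <- function(sp) .dir_assert(sp, "up", from = c(0, 0.02),
                                     to = c(0.35, 0.55))
  late <- function(sp) .dir_assert(sp, "up", from = c(0.35, 0.45),
                                   to = c(0.9, 1))
  vsn <- function(sp, dir, group) .dir_assert(sp, dir, comparator = "normal",
                                              group = group)
  t3 <- c(
    lapply(c("atp", "r5p", "lac", "ga3p", "pyr", "g6p"),
           vsn, dir = "up", group = "metabolic"),
    list(vsn("glc", "down", "metabolic"), vsn("pep", "down", "metabolic"),
         vsn("f6p", "down", "metabolic"), vsn("nadh", "down", "metabolic")),
    lapply(c("hif1a", "pi3k", "akt", "mtor", "myc", "erk", "stat3", "nfkb"),
           vsn, dir = "up", group = "signaling"),
    list(vsn("p53", "down", "signaling"), vsn("phd", "down", "signaling")),
    lapply(c("hk", "glut1", "ldh", "pfk1", "pfk2", "gapdh", "g6pd", "pgd",
             "rpi", "tkt", "taldo"),
           vsn, dir = "up", group = "gene"),
    list(.dir_assert("pk", "switch", group = "gene")))
  list(
    normal = list(
      name = "normal", base = "normal", knockouts = character(0),
      signals = numeric(0), inputs = numeric(0), horizon = 16, seed = 42L,
      setpoints = NULL,
      assertions = c(lapply(c("pep", "oaa", "cit"), growth),
                     lapply(c("r5p", "nadph", "ffa", "g6p", "glc"), late))),
    warburg = list(
      name = "warburg", base = "warburg", knockouts = .warburgKnockouts,
      signals = numeric(0), inputs = numeric(0), horizon = 16, seed = 42L,
      setpoints = NULL,
      assertions = c(
        lapply(c("lac", "pyr", "p53"), function(sp)
          .dir_assert(sp, "up", comparator = "normal")),
        lapply(c("ffa", "cit", "succ", "atp", "nadph", "glc"), function(sp)
          .dir_assert(sp, "down", comparator = "normal")))),
    hypoxia = list(
      name = "hypoxia", base = "normal", knockouts = character(0),
      signals = c(hk = 0.95, aldo = 0.95, pk = 0.95),
      inputs = c(o2 = 0.3), horizon = 16, seed = 42L, setpoints = NULL,
      assertions = list(.dir_assert("lac", "up", comparator = "normal"))),
    insulin_deprivation = list(
      name = "insulin_deprivation", base = "normal",
      knockouts = character(0),
      signals = c(ldh = 0.2, glut1 = 0.8),
      inputs = c(insulin = 0.02), horizon = 16, seed = 42L,
      setpoints = NULL,
      assertions = list(.dir_assert("ldh", "down", comparator = "normal",
                                    kind = "flux"))),
    cancer = list(
      name = "cancer", base = "warburg", knockouts = .warburgKnockouts,
      signals = numeric(0), inputs = numeric(0), horizon = 16, seed = 42L,
      setpoints = c(atp = 0.95, r5p = 0.70),
      maxIter = 60, l1Threshold = 0.02, setpointWeight = 25,
      assertions = t3))
}

#' Registered drug-target cases
#'
#' Six rational drug targets evaluated on top of the converged cancer
#' loop: a gene-expression reference level is added to the controller
#' reference mid-run and the direction table of downstream outcomes is
#' checked before versus after the gate.
#'
#' @return named list of case definitions.
#' @export
drugTargetCases <- function() {
  out <- function(species, direction)
    list(species = species, direction = direction)
  list(
    pk_deact = list(
      target = c(pk = 0.02),
      outcomes = list(out("atp", "down"), out("r5p", "high"),
                      out("nadph", "high"), out("g6p", "up"),
                      out("p53", "down"), out("glut1", "flat"))),
    g6pd_deact = list(
      target = c(g6pd = 0.02),
      outcomes = list(out("r5p", "down"), out("nadph", "down"),
                      out("p53", "up"), out("glut1", "down"),
                      out("lac", "high"), out("atp", "high"))),
    tkt_deact = list(
      target = c(tkt = 0.09),
      outcomes = list(out("r5p", "down"), out("nadph", "down"),
                      out("p53", "up"), out("glut1", "down"),
                      out("atp", "down"), out("lac", "down"))),
    rpi_deact = list(
      target = c(rpi = 0.09),
      outcomes = list(out("r5p", "down"), out("nadph", "down"),
                      out("p53", "up"), out("glut1", "down"),
                      out("lac", "down"), out("atp", "flat"))),
    gpi_deact = list(
      target = c(gpi = 0.03),
      outcomes = list(out("r5p", "down"), out("nadph", "down"),
                      out("p53", "up"), out("glut1", "down"),
                      out("lac", "down"), out("atp", "down"))),
    pk_act = list(
      target = c(pk = 0.98),
      outcomes = list(out("r5p", "down"), out("nadph", "down"),
                      out("lac", "down"), out("p53", "up"),
                      out("glut1", "down"), out("atp", "high"))))
}

.scenario_plant <- function(scen, network = ccmNetwork()) {
  plant <- buildPlant(network, initSeed = scen$seed,
                      initRange = c(0.05, 0.35))
  if (length(scen$knockouts) || length(scen$signals))
    plant <- applyPerturbation(plant, knockouts = scen$knockouts,
                               signals = scen$signals)
  plant
}

.scenario_input <- function(scen) {
  u <- ccmBaselineInput()
  if (length(scen$inputs)) u[names(scen$inputs)] <- scen$inputs
  u
}

# window mean over a fraction range of a sample matrix (rows = time)
.frac_mean <- function(M, species, win) {
  n <- nrow(M)
  lo <- max(1L, ceiling(win[1] * (n - 1)) + 1L)
  hi <- max(lo, floor(win[2] * (n - 1)) + 1L)
  mean(M[lo:hi, species])
}

# mean flux of one reaction over a window of recorded states
.flux_mean <- function(M, win, network, u, rid) {
  n <- nrow(M)
  lo <- max(1L, ceiling(win[1] * (n - 1)) + 1L)
  hi <- max(lo, floor(win[2] * (n - 1)) + 1L)
  mean(vapply(lo:hi, function(i)
    unname(metabolicRates(network, M[i, ], u)[rid]), numeric(1)))
}

.eval_assertion <- function(a, M, comparators, fluxCtx = NULL) {
  to <- a$to %||% c(0.9, 1)
  if (identical(a$kind %||% "level", "flux")) {
    obs <- .flux_mean(M, to, fluxCtx$network, fluxCtx$u, a$species)
    ref <- .flux_mean(comparators[[a$comparator]], to,
                      fluxCtx$normalNetwork, fluxCtx$normalU, a$species)
    pass <- switch(a$direction, up = obs > ref, down = obs < ref)
    return(data.frame(species = a$species, direction = a$direction,
                      observed = obs, reference = ref,
                      group = a$group %||% "", pass = pass))
  }
  obs <- .frac_mean(M, a$species, to)
  if (a$direction == "switch") {
    x <- M[, a$species]
    dx <- diff(x)
    pass <- max(abs(dx)) >= 0.02 && any(dx > 0) && any(dx < 0)
    return(data.frame(species = a$species, direction = "switch",
                      observed = max(x) - min(x), reference = NA_real_,
                      group = a$group %||% "", pass = pass))
  }
  ref <- if (!is.null(a$comparator))
    .frac_mean(comparators[[a$comparator]], a$species, to)
  else .frac_mean(M, a$species, a$from)
  pass <- switch(a$direction,
                 up = obs > ref,
                 down = obs < ref,
                 flat = abs(obs - ref) <= 0.1,
                 high = obs >= 0.7 * ref,
                 stop("unknown direction ", a$direction))
  data.frame(species = a$species, direction = a$direction, observed = obs,
             reference = ref, group = a$group %||% "", pass = pass)
}

#' Run a packaged scenario
#'
#' Builds the scenario's plant (applying knockouts, pinned signals and
#' input overrides), simulates it — or, for the controlled cancer
#' scenario, trains/loads the surrogate and runs the closed-loop GA
#' controller — and evaluates every registered directional assertion
#' (comparator assertions are matched to a same-seed normal run).
#'
#' @param name registered scenario name.
#' @param artifacts optional list of precomputed pieces to reuse:
#'   `surrogate` (a [SurrogateModel-class] for the Warburg plant),
#'   `normalTrajectory`, `controlSeed`, `phi`, `segments` (scaled
#'   surrogate training size for auto-building).
#' @param dir optional output directory for trajectory CSVs.
#' @return list with `name`, `trajectory` (state samples), `assertions`
#'   (data.frame with pass/fail per row), `control` (controller result
#'   for controlled scenarios), `plant`, and `normal` (comparator
#'   samples) when used.
#' @export
runScenario <- function(name, artifacts = list(), dir = NULL) {
  scen <- ccmScenario(name)
  net <- artifacts$network %||% ccmNetwork()
  plant <- .scenario_plant(scen, net)
  u <- .scenario_input(scen)
  needNormal <- any(vapply(scen$assertions, function(a)
    !is.null(a$comparator), logical(1)))
  normalM <- NULL
  if (needNormal) {
    normalM <- artifacts$normalTrajectory
    if (is.null(normalM)) {
      nsc <- ccmScenario("normal")
      ntraj <- plantSimulate(.scenario_plant(nsc, net), .scenario_input(nsc),
                             horizon = nsc$horizon)
      normalM <- stateMatrix(ntraj)
    }
  }
  control <- NULL
  if (is.null(scen$setpoints)) {
    traj <- plantSimulate(plant, u, horizon = scen$horizon)
    M <- stateMatrix(traj)
    if (!is.null(dir)) {
      dir.create(dir, showWarnings = FALSE, recursive = TRUE)
      writeTrajectoryCSV(traj, file.path(dir, paste0(name, ".csv")))
    }
  } else {
    surrogate <- artifacts$surrogate %||% cancerSurrogate(
      plant, phi = artifacts$phi %||% 900,
      segments = artifacts$segments %||% 6L,
      seed = artifacts$surrogateSeed %||% 7L)
    hist <- controlHistory(plant, tau = surrogate@meta$tau, uInit = u)
    control <- controlLoop(plant, surrogate, hist,
                           setpoints = scen$setpoints,
                           l1Threshold = scen$l1Threshold %||% 0.02,
                           maxIter = scen$maxIter %||% 60,
                           cfg = artifacts$gaConfig %||% gaConfig(),
                           seed = artifacts$controlSeed %||% 1L,
                           setpointWeight = scen$setpointWeight %||% 1)
    M <- control$history$outputs
    colnames(M) <- speciesNames(plant@network, "all")
    if (!is.null(dir)) {
      dir.create(dir, showWarnings = FALSE, recursive = TRUE)
      utils::write.csv(data.frame(iter = seq_len(nrow(M)), M,
                                  check.names = FALSE),
                       file.path(dir, paste0(name, ".csv")),
                       row.names = FALSE)
      if (!is.null(control$trace))
        utils::write.csv(control$trace,
                         file.path(dir, paste0(name, "_trace.csv")),
                         row.names = FALSE)
    }
  }
  nsc <- ccmScenario("normal")
  fluxCtx <- list(network = plant@network, u = u,
                  normalNetwork = net, normalU = .scenario_input(nsc))
  assertions <- do.call(rbind, lapply(scen$assertions, .eval_assertion,
                                      M = M,
                                      comparators = list(normal = normalM),
                                      fluxCtx = fluxCtx))
  list(name = name, trajectory = M, assertions = assertions,
       control = control, plant = plant, normal = normalM)
}

#' Train the scaled surrogate for the controlled scenarios
#'
#' Generates a segmented sliding-window dataset from the (perturbed)
#' plant, splits it 65:35 and fits the epsilon-SVR ensemble with the
#' standard hyperparameters (radial-basis coefficient 10, C = 100,
#' epsilon = 0.0025).
#'
#' @param plant the (perturbed) [Plant-class].
#' @param phi number of window samples.
#' @param tau window length.
#' @param segments number of random-restart segments.
#' @param seed RNG seed.
#' @param gamma radial-basis kernel coefficient.
#' @param stateJitter state-block excitation amplitude (see
#'   [generateDataset()]); the controller needs a surrogate trained on
#'   state-excited data.
#' @return a [SurrogateModel-class].
#' @export
cancerSurrogate <- function(plant, phi = 900, tau = 19, segments = 6L,
                            seed = 7L, gamma = 1e-4, stateJitter = 0.3) {
  ds <- generateDataset(plant, phi = phi, tau = tau, seed = seed,
                        segments = segments, stateJitter = stateJitter,
                        stateJitterProb = 1)
  sp <- splitDataset(ds, 0.65, seed = seed)
  fitSurrogate(sp$train, gamma = gamma)
}

#' Run a drug-target case on the controlled cancer plant
#'
#' Continues the converged cancer control loop with the case's gene
#' reference expression level added to the controller reference from
#' the gate iteration (mid-run) onward, then evaluates the case's
#' direction table by comparing the post-gate window against the
#' pre-gate (cancer baseline) window.
#'
#' @param case registered case name (see [drugTargetCases()]).
#' @param cancer result of `runScenario("cancer", ...)` to continue
#'   from; when `NULL` a fresh cancer run is executed.
#' @param artifacts artifact list passed through to [runScenario()] and
#'   used for the surrogate.
#' @param iterations total controller iterations for the case run.
#' @return list with `case`, `assertions`, `trace`, `outputs`.
#' @export
runDrugTarget <- function(case, cancer = NULL, artifacts = list(),
                          iterations = 20L) {
  cases <- drugTargetCases()
  if (!case %in% names(cases))
    stop("unknown drug-target case '", case, "'; registered: ",
         paste(names(cases), collapse = ", "))
  def <- cases[[case]]
  if (is.null(cancer)) cancer <- runScenario("cancer", artifacts = artifacts)
  plant <- cancer$plant
  surrogate <- artifacts$surrogate
  if (is.null(surrogate))
    stop("runDrugTarget needs the cancer surrogate in artifacts$surrogate")
  gate <- iterations %/% 2 + 1L
  scen <- ccmScenario("cancer")
  res <- controlLoop(plant, surrogate, cancer$control$history,
                     setpoints = scen$setpoints,
                     l1Threshold = 1e-6,        # run all iterations
                     maxIter = iterations,
                     cfg = artifacts$gaConfig %||% gaConfig(),
                     seed = artifacts$drugSeed %||% 11L,
                     gate = gate, extraSetpoints = def$target,
                     setpointWeight = scen$setpointWeight %||% 1)
  M <- res$history$outputs
  colnames(M) <- speciesNames(plant@network, "all")
  nPrev <- nrow(cancer$control$history$outputs)
  newM <- M[(nPrev + 1):nrow(M), , drop = FALSE]
  # baseline: the converged cancer run's steady window (stabler than the
  # few pre-gate iterations of the continuation run)
  before <- M[max(1, nPrev - 4):nPrev, , drop = FALSE]
  after <- newM[(nrow(newM) - max(2L, nrow(newM) %/% 3L) + 1L):nrow(newM), ,
                drop = FALSE]
  rows <- lapply(def$outcomes, function(o) {
    obs <- mean(after[, o$species]); ref <- mean(before[, o$species])
    pass <- switch(o$direction,
                   up = obs > ref, down = obs < ref,
                   flat = abs(obs - ref) <= 0.1,
                   high = obs >= 0.7 * ref)
    data.frame(species = o$species, direction = o$direction,
               observed = obs, reference = ref, pass = pass)
  })
  list(case = case, target = def$target,
       assertions = do.call(rbind, rows),
       trace = res$trace, outputs = newM,
       targetLevel = mean(after[, names(def$target)]))
}
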