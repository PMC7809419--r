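#' Build a MIMO plant from a network specification
#'
#' Freezes a reproducible simulator around a network: draws the initial
#' state uniformly in (0, 1) from `initSeed`, fixes the timescale ratios
#' and per-step horizon, and optionally verifies a behavior checklist
#' (directional trend assertions on a simulated trajectory, see
#' [tuneParameters()]). The plant exposes [plantStep()] — a pure function
#' from a full input instance `<x, y, z, u>` to the output instance
#' `<x, y, z>` one step-horizon later — which is what the sliding-window
#' dataset generator and the controller consume.
#'
#' @param network a [PathwayNetwork-class].
#' @param initSeed seed for the uniform initial state.
#' @param omega1,omega2 timescale ratios (defaults 1/60).
#' @param stepHorizon slow time integrated per plant step.
#' @param initRange range of the uniform initial draw (sub-interval of
#'   the unit interval).
#' @param checklist optional list of checklist items (see
#'   [checklistItem()]); the plant build fails with a report if any item
#'   fails on the baseline trajectory.
#' @param u baseline external-input vector used for checklist runs.
#' @param relTol,absTol solver tolerances for plant steps.
#' @return a [Plant-class].
#' @export
buildPlant <- function(network, initSeed = 1L, omega1 = 1 / 60,
                       omega2 = 1 / 60, stepHorizon = 1,
                       initRange = c(0, 1), checklist = list(),
                       u = NULL, relTol = 1e-6, absTol = 1e-8) {
  k <- speciesCounts(network)
  nstate <- sum(k[c("p", "s", "m")])
  init <- withSeed(initSeed, runif(nstate, initRange[1], initRange[2]))
  names(init) <- speciesNames(network, "all")
  plant <- new("Plant", network = network, omega1 = omega1,
               omega2 = omega2, stepHorizon = stepHorizon,
               knockouts = integer(0), signalOverrides = numeric(0),
               initState = init,
               config = list(initSeed = initSeed, initRange = initRange,
                             relTol = relTol, absTol = absTol))
  if (length(checklist)) {
    if (is.null(u)) stop("checklist evaluation requires a baseline input u")
    rep <- evaluateChecklist(plant, checklist, u)
    if (!all(rep$pass))
      stop("plant behavior checklist failed: ",
           paste(rep$item[!rep$pass], collapse = ", "))
    plant@config$checklist <- rep
  }
  plant
}

#' Directional checklist items for plant behavior
#'
#' One machine-checkable qualitative assertion on a simulated trajectory:
#' the mean of `species` over the `to` window must be greater (direction
#' `"up"`) or smaller (`"down"`) than over the `from` window, either
#' within one run or against a comparator run (same seed, different
#' perturbation).
#'
#' @param species species id.
#' @param direction `"up"` or `"down"`.
#' @param from,to window fractions of the horizon (length-2 numerics in
#'   `[0, 1]`); `to` defaults to the last 10%.
#' @param comparator optional name of a comparator scenario/run; when
#'   set, the comparison is end-window vs end-window across runs.
#' @return a checklist item (list).
#' @export
checklistItem <- function(species, direction = c("up", "down"),
                          from = c(0, 0.05), to = c(0.9, 1),
                          comparator = NULL) {
  list(species = species, direction = match.arg(direction),
       from = from, to = to, comparator = comparator)
}

.window_mean <- function(traj, species, win) {
  t0 <- min(traj@times); t1 <- max(traj@times)
  lo <- t0 + win[1] * (t1 - t0); hi <- t0 + win[2] * (t1 - t0)
  sel <- traj@times >= lo - 1e-9 & traj@times <= hi + 1e-9
  mean(traj@states[sel, species])
}

#' Evaluate a checklist on plant trajectories
#'
#' @param plant a [Plant-class].
#' @param checklist list of [checklistItem()]s.
#' @param u baseline input vector.
#' @param horizon slow-time length of the evaluation run.
#' @param comparators named list of comparator trajectories (for items
#'   with a `comparator`).
#' @param traj optional precomputed trajectory (skips simulation).
#' @return data.frame with columns `item`, `observed`, `reference`,
#'   `pass`.
#' @export
evaluateChecklist <- function(plant, checklist, u, horizon = 16,
                              comparators = list(), traj = NULL) {
  if (is.null(traj))
    traj <- plantSimulate(plant, u, horizon = horizon)
  rows <- lapply(checklist, function(it) {
    obs <- .window_mean(traj, it$species, it$to)
    ref <- if (is.null(it$comparator)) .window_mean(traj, it$species, it$from)
           else .window_mean(comparators[[it$comparator]], it$species, it$to)
    pass <- if (it$direction == "up") obs > ref else obs < ref
    data.frame(item = paste0(it$species, " ", it$direction,
                             if (!is.null(it$comparator))
                               paste0(" vs ", it$comparator) else ""),
               observed = obs, reference = ref, pass = pass)
  })
  do.call(rbind, rows)
}

#' Simulate a plant over a horizon
#'
#' Runs the three-timescale integrator from the plant's frozen initial
#' state under constant (or policy) inputs, honoring knockouts and
#' pinned species.
#'
#' @param plant a [Plant-class].
#' @param u external-input vector or policy function.
#' @param horizon slow-time length.
#' @param dt sampling interval on the slow grid.
#' @param init optional replacement initial state.
#' @return a [Trajectory-class].
#' @export
plantSimulate <- function(plant, u, horizon = 16, dt = 0.5, init = NULL) {
  cfg <- timescaleConfig(omega1 = plant@omega1, omega2 = plant@omega2,
                         tGrid = seq(0, horizon, by = dt),
                         relTol = plant@config$relTol %||% 1e-6,
                         absTol = plant@config$absTol %||% 1e-8)
  integrateNetwork(plant@network, init %||% plant@initState, u, cfg,
                   overrides = plant@signalOverrides)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Randomly perturb kinetic constants until a checklist passes
#'
#' Hill-climbing calibration in the spirit of trial-and-error parameter
#' tuning: starting from the network's current constants, each iteration
#' perturbs every kinetic/binding constant by a uniform step of at most
#' `stepSize` (clamped to the constant's legal range), re-simulates, and
#' keeps the proposal iff it passes at least as many checklist items as
#' the incumbent. Returns the first network satisfying all items, or the
#' best found with a partial-satisfaction report after `budget`
#' iterations (never an exception).
#'
#' @param plant a [Plant-class].
#' @param checklist list of [checklistItem()]s (may be empty: the input
#'   network is returned unchanged).
#' @param u baseline input for checklist runs.
#' @param budget maximum number of perturbation iterations.
#' @param seed RNG seed.
#' @param stepSize maximum absolute perturbation per constant.
#' @return list with `network`, `report` (checklist data.frame),
#'   `satisfied` (logical), `iterations`.
#' @export
tuneParameters <- function(plant, checklist, u, budget = 100, seed = 1L,
                           stepSize = 0.05) {
  if (!length(checklist))
    return(list(network = plant@network,
                report = data.frame(), satisfied = TRUE, iterations = 0L))
  score <- function(net) {
    p2 <- plant; p2@network <- net
    rep <- evaluateChecklist(p2, checklist, u)
    list(n = sum(rep$pass), rep = rep)
  }
  cur <- plant@network
  sc <- score(cur)
  it <- 0L
  withSeed(seed, {
    while (sc$n < length(checklist) && it < budget) {
      it <- it + 1L
      cand <- .perturb_network(cur, stepSize)
      sc2 <- score(cand)
      if (sc2$n >= sc$n) { cur <- cand; sc <- sc2 }
    }
  })
  list(network = cur, report = sc$rep,
       satisfied = sc$n == length(checklist), iterations = it)
}

# uniform +-step on every kinetic constant, clamped to its legal range
.perturb_network <- function(net, stepSize) {
  jig <- function(x, lo, hi) {
    if (!length(x)) return(x)
    pmin(pmax(x + runif(length(x), -stepSize, stepSize), lo), hi)
  }
  rr <- lapply(net@reactionRules, function(r) {
    if (r@K > 0) r@K <- jig(r@K, 1e-3, 1)   # keep knockouts at exactly 0
    r@Km <- jig(r@Km, 1e-3, 1)
    r@enhMet <- jig(r@enhMet, 0, 1 - 1e-9)
    r@inhMet <- jig(r@inhMet, 0, 1 - 1e-9)
    r
  })
  ir <- lapply(net@interactionRules, function(r) {
    r@rate <- jig(r@rate, 1e-3, 1)
    r@activators <- jig(r@activators, 1e-6, 1 - 1e-9)
    r
  })
  gr <- lapply(net@geneRules, function(r) {
    r@basal <- jig(r@basal, 1e-6, 1 - 1e-6)
    r@decay <- jig(r@decay, 1e-6, 1 - 1e-6)
    r@activators <- jig(r@activators, 1e-6, 1 - 1e-9)
    r
  })
  pathwayNetwork(net@geneNames, net@signalNames, net@metaboliteNames,
                 net@inputNames, gr, ir, rr,
                 displayNames = net@displayNames, meta = net@meta)
}

#' Apply a perturbation to a plant
#'
#' Knockouts set the named reactions' kinetic rate constants to zero
#' (their fluxes are identically zero afterwards); enzyme/protein signals
#' pin the named species to fixed externally imposed levels in (0, 1)
#' during integration (hard overrides, the component's derivative is
#' forced to zero).
#'
#' @param plant a [Plant-class].
#' @param knockouts character vector of reaction ids to knock out.
#' @param signals named numeric of pinned species levels in (0, 1).
#' @return a new [Plant-class] with the perturbation applied.
#' @export
applyPerturbation <- function(plant, knockouts = character(0),
                              signals = numeric(0)) {
  net <- plant@network
  if (length(knockouts)) {
    ids <- vapply(net@reactionRules, function(r) r@id, character(1))
    idx <- match(knockouts, ids)
    if (anyNA(idx))
      stop("unknown reaction(s): ",
           paste(knockouts[is.na(idx)], collapse = ", "))
    rr <- net@reactionRules
    for (i in idx) rr[[i]]@K <- 0
    net <- pathwayNetwork(net@geneNames, net@signalNames,
                          net@metaboliteNames, net@inputNames,
                          net@geneRules, net@interactionRules, rr,
                          displayNames = net@displayNames, meta = net@meta)
    plant@knockouts <- sort(unique(c(plant@knockouts, as.integer(idx))))
  }
  if (length(signals)) {
    all <- speciesNames(plant@network, "all")
    bad <- setdiff(names(signals), all)
    if (length(bad)) stop("unknown species: ", paste(bad, collapse = ", "))
    ov <- plant@signalOverrides
    ov[names(signals)] <- signals
    plant@signalOverrides <- ov
  }
  plant@network <- net
  validObject(plant)
  plant
}

#' One plant step
#'
#' The MIMO plant map: takes a full input instance `<x, y, z, u>` (length
#' `p+s+m+c`), integrates the three-timescale system for one step horizon
#' from that state under constant `u`, and returns the output instance
#' `<x, y, z>` (length `p+s+m`), clamped to the unit box. The map is a
#' pure function of the input instance — repeated calls with the same
#' instance give identical outputs.
#'
#' @param plant a [Plant-class].
#' @param input numeric vector of length `p+s+m+c`.
#' @param ... unused.
#' @return named numeric output instance of length `p+s+m`.
#' @export
setMethod("plantStep", "Plant", function(plant, input, ...) {
  k <- speciesCounts(plant@network)
  nstate <- sum(k[c("p", "s", "m")])
  if (length(input) != nstate + k[["c"]])
    stop(sprintf("input instance must have length p+s+m+c = %d",
                 nstate + k[["c"]]))
  state <- clamp01(as.numeric(input[seq_len(nstate)]))
  u <- clamp01(as.numeric(input[nstate + seq_len(k[["c"]])]))
  cfg <- timescaleConfig(omega1 = plant@omega1, omega2 = plant@omega2,
                         tGrid = c(0, plant@stepHorizon),
                         relTol = plant@config$relTol %||% 1e-6,
                         absTol = plant@config$absTol %||% 1e-8)
  traj <- integrateNetwork(plant@network, state, u, cfg,
                           overrides = plant@signalOverrides)
  out <- traj@states[nrow(traj@states), ]
  stats::setNames(clamp01(out), speciesNames(plant@network, "all"))
})
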