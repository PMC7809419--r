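#' Genetic-algorithm controller configuration
#'
#' Parameters of the GA that the model-predictive controller runs at
#' every closed-loop iteration.
#'
#' @param populationSize chromosomes per generation (>= 2).
#' @param maxGenerations generation cap per optimization call.
#' @param mutationProb mutation probability (uniform redraw in the unit
#'   interval).
#' @param mutation `"chromosome"` (default: each chromosome mutates with
#'   probability `mutationProb` by redrawing one randomly chosen locus)
#'   or `"locus"` (every locus mutates independently with that
#'   probability). The chromosome mode is what lets the search refine a
#'   near-optimal input; the locus mode is pure exploration.
#' @param crossover `"uniform"` (per-locus swap with probability 0.5) or
#'   `"single_point"`.
#' @param crossoverIndex swap point for single-point crossover (applied
#'   within the first `p+s+m` loci; 53 for the packaged CCM sizes, about
#'   half the output-vector length).
#' @param selectionWeight fitness cutoff for selection; `NULL` uses the
#'   population median (with a top-half fallback when the cutoff empties
#'   the pool).
#' @param fitnessThreshold early-stop fitness for the optimization call.
#' @param jitter radius of the uniform initialization around the current
#'   input instance.
#' @return configuration list.
#' @export
gaConfig <- function(populationSize = 60, maxGenerations = 10,
                     mutationProb = 0.7,
                     mutation = c("chromosome", "locus"),
                     crossover = c("uniform", "single_point"),
                     crossoverIndex = 53, selectionWeight = NULL,
                     fitnessThreshold = 0.98, jitter = 0.1) {
  stopifnot(populationSize >= 2, maxGenerations >= 1,
            mutationProb >= 0, mutationProb <= 1, jitter >= 0)
  list(populationSize = as.integer(populationSize),
       maxGenerations = as.integer(maxGenerations),
       mutationProb = mutationProb, mutation = match.arg(mutation),
       crossover = match.arg(crossover),
       crossoverIndex = as.integer(crossoverIndex),
       selectionWeight = selectionWeight,
       fitnessThreshold = fitnessThreshold, jitter = jitter)
}

# insert candidate current-input blocks into a window context
.withCurrentInput <- function(vContext, genomes) {
  nio <- ncol(genomes)
  V <- matrix(vContext, nrow(genomes), length(vContext), byrow = TRUE)
  V[, length(vContext) - nio + seq_len(nio)] <- genomes
  V
}

# Fast batched predictor for GA populations: the squared distance between
# a candidate window and a support vector splits into the (shared) context
# part and the current-input part, so the context distances are computed
# once per optimization call and each generation only pays for the
# current-input block.
.gaPredictor <- function(surrogate, vContext, nio) {
  if (is.function(surrogate))
    return(function(G) surrogate(.withCurrentInput(vContext, G)))
  d <- length(vContext)
  ctxIdx <- seq_len(d - nio)
  SVctx <- surrogate@SV[, ctxIdx, drop = FALSE]
  SVcur <- surrogate@SV[, d - nio + seq_len(nio), drop = FALSE]
  dCtx <- as.numeric(colSums((t(SVctx) - vContext[ctxIdx])^2))
  svn <- rowSums(SVcur^2)
  function(G) {
    d2cur <- outer(rowSums(G^2), svn, `+`) - 2 * tcrossprod(G, SVcur)
    d2cur[d2cur < 0] <- 0
    K <- exp(-surrogate@gamma * sweep(d2cur, 2, dCtx, `+`))
    pred <- sweep(K %*% surrogate@alpha, 2, surrogate@bias, `+`)
    colnames(pred) <- surrogate@outputNames
    clamp01(pred)
  }
}

#' Controller fitness of candidate input instances
#'
#' Fitness of a chromosome (candidate full input instance) given the
#' window context and a reference output:
#' `1 / (1 + ||gamma_hat(v') - reference||_1)` where `v'` is the window
#' vector with its current-input block replaced by the genome and
#' `gamma_hat` is the surrogate prediction. Fitness lies in (0, 1] and
#' equals 1 iff the predicted output matches the reference exactly; it
#' is strictly decreasing in the L1 prediction error.
#'
#' @param genomes one genome (vector) or a matrix with one genome per
#'   row, each of length `p+s+m+c`.
#' @param surrogate a [SurrogateModel-class], or a function mapping a
#'   matrix of window vectors to a matrix of predicted outputs (used for
#'   exact-surrogate experiments on toy plants).
#' @param vContext window vector whose current-input block is replaced.
#' @param reference numeric reference output (length `p+s+m`).
#' @param weights optional per-output weights on the absolute error
#'   (default: unweighted L1). The closed-loop controller up-weights the
#'   setpoint components so the cost concentrates on the tracked
#'   outputs.
#' @return numeric fitness vector.
#' @export
gaFitness <- function(genomes, surrogate, vContext, reference,
                      weights = NULL) {
  G <- if (is.null(dim(genomes))) matrix(genomes, nrow = 1)
       else as.matrix(genomes)
  V <- .withCurrentInput(vContext, G)
  pred <- if (is.function(surrogate)) surrogate(V)
          else predictSurrogate(surrogate, V)
  E <- abs(sweep(pred, 2, as.numeric(reference)))
  if (!is.null(weights)) E <- sweep(E, 2, as.numeric(weights), `*`)
  err <- rowSums(E)
  1 / (1 + err)
}

#' One GA optimization of the controller input
#'
#' Evolves a population of candidate input instances seeded around the
#' current input (uniform jitter, the unmodified current input included,
#' so an already-optimal input survives by elitism): per generation,
#' chromosomes with fitness above the selection cutoff (population
#' median by default; top half as fallback) are recombined by uniform
#' or single-point crossover, each locus mutates with the configured
#' probability by a uniform redraw in the unit interval, and the best
#' chromosome is carried over unchanged. Stops when the best fitness
#' exceeds the threshold or after the generation cap.
#'
#' @param currentInput current full input instance (length `p+s+m+c`).
#' @param vContext window vector supplying the history context.
#' @param reference reference output vector.
#' @param surrogate a [SurrogateModel-class].
#' @param cfg a [gaConfig()] list.
#' @param seed RNG seed.
#' @return list with `input` (best genome), `fitness`, `generations`,
#'   `history` (best fitness per generation).
#' @export
gaEvolve <- function(currentInput, vContext, reference, surrogate,
                     cfg = gaConfig(), seed = 1L, weights = NULL) {
  nloc <- length(currentInput)
  predictor <- .gaPredictor(surrogate, vContext, nloc)
  fitFun <- function(pop) {
    E <- abs(sweep(predictor(pop), 2, as.numeric(reference)))
    if (!is.null(weights)) E <- sweep(E, 2, as.numeric(weights), `*`)
    1 / (1 + rowSums(E))
  }
  withSeed(seed, {
    pop <- matrix(runif(cfg$populationSize * nloc,
                        rep(clamp01(currentInput - cfg$jitter), each = cfg$populationSize),
                        rep(clamp01(currentInput + cfg$jitter), each = cfg$populationSize)),
                  cfg$populationSize, nloc)
    pop[1, ] <- currentInput
    fit <- fitFun(pop)
    best <- list(genome = pop[which.max(fit), ], fitness = max(fit))
    history <- best$fitness
    gen <- 0L
    while (best$fitness <= cfg$fitnessThreshold &&
           gen < cfg$maxGenerations) {
      gen <- gen + 1L
      cutoff <- cfg$selectionWeight %||% stats::median(fit)
      pool <- which(fit > cutoff)
      if (length(pool) < 2)                       # fallback: top half
        pool <- order(fit, decreasing = TRUE)[seq_len(max(2, cfg$populationSize %/% 2))]
      parents <- pop[pool, , drop = FALSE]
      np <- nrow(parents)
      i1 <- sample.int(np, cfg$populationSize, replace = TRUE)
      i2 <- sample.int(np, cfg$populationSize, replace = TRUE)
      child <- parents[i1, , drop = FALSE]
      other <- parents[i2, , drop = FALSE]
      if (cfg$crossover == "uniform") {
        swap <- matrix(runif(cfg$populationSize * nloc) < 0.5,
                       cfg$populationSize, nloc)
      } else {
        cut <- min(cfg$crossoverIndex, nloc)
        swap <- matrix(FALSE, cfg$populationSize, nloc)
        swap[, seq_len(cut)] <- TRUE
      }
      child[swap] <- other[swap]
      if (cfg$mutation == "chromosome") {
        # each chromosome mutates with the configured probability by a
        # uniform redraw of one randomly chosen locus
        hit <- which(runif(cfg$populationSize) < cfg$mutationProb)
        loci <- sample.int(nloc, length(hit), replace = TRUE)
        child[cbind(hit, loci)] <- runif(length(hit))
      } else {
        mut <- matrix(runif(cfg$populationSize * nloc) < cfg$mutationProb,
                      cfg$populationSize, nloc)
        child[mut] <- runif(sum(mut))
      }
      child[1, ] <- best$genome                   # elitism
      pop <- child
      fit <- fitFun(pop)
      if (max(fit) > best$fitness)
        best <- list(genome = pop[which.max(fit), ], fitness = max(fit))
      history <- c(history, best$fitness)
    }
    list(input = stats::setNames(best$genome, names(currentInput)),
         fitness = best$fitness, generations = gen, history = history)
  })
}

#' Closed-loop GA model-predictive control
#'
#' Drives selected plant outputs to reference setpoints: each iteration
#' runs one GA optimization ([gaEvolve()]) of the next input instance
#' against the surrogate, applies the optimized instance to the actual
#' plant, rolls the window history forward, and compares the plant
#' output with the reference. Free (non-setpoint) outputs are referenced
#' at their previously observed values. When an iteration's best fitness
#' falls below the previous iteration's, the GA retries with a fresh
#' seed (up to `retries` times) before accepting. The loop returns on
#' `L1 < l1Threshold` (converged) or after `maxIter` iterations (a
#' structured failure report, not an exception).
#'
#' @param plant a [Plant-class].
#' @param surrogate a [SurrogateModel-class] sharing the plant's network.
#' @param history list with `inputs` and `outputs` matrices of at least
#'   `tau` recorded plant steps (e.g. from [controlHistory()]).
#' @param setpoints named numeric of target output values in (0, 1).
#' @param l1Threshold L1-norm convergence threshold on the full output
#'   vector (default 0.02).
#' @param maxIter iteration cap (default 30).
#' @param cfg a [gaConfig()] list.
#' @param seed master seed for the per-iteration GA streams.
#' @param retries GA retries allowed when fitness regresses.
#' @param setpointWeight weight applied to the setpoint components of
#'   the reference inside the GA cost (free outputs keep weight 1); the
#'   convergence test remains the unweighted L1 norm.
#' @param gate iteration (1-based) from which the setpoints are active;
#'   before it the reference tracks the observed outputs only. Used by
#'   the drug-target scenarios to switch a target on mid-run.
#' @param extraSetpoints named numeric of additional setpoints activated
#'   at `gate` (the base `setpoints` are active from the start).
#' @return list with `converged`, `input` and `output` (the final
#'   solution on convergence, otherwise the best-tracking solution of
#'   the failure report), `bestL1`, `trace` (per-iteration data.frame),
#'   `iterations`, and the full `history`.
#' @export
controlLoop <- function(plant, surrogate, history, setpoints,
                        l1Threshold = 0.02, maxIter = 30,
                        cfg = gaConfig(), seed = 1L, retries = 2,
                        gate = 1L, extraSetpoints = numeric(0),
                        setpointWeight = 1) {
  k <- speciesCounts(plant@network)
  outNames <- speciesNames(plant@network, "all")
  stopifnot(all(names(setpoints) %in% outNames),
            all(names(extraSetpoints) %in% outNames))
  inputs <- history$inputs; outputs <- history$outputs
  tau <- if (is.function(surrogate)) attr(surrogate, "tau")
         else surrogate@meta$tau
  if (nrow(inputs) < tau + 1)
    stop(sprintf("history must contain at least tau+1 = %d steps", tau + 1))
  seeds <- subSeeds(seed, maxIter * (retries + 1))
  sIdx <- 0L
  currentInput <- inputs[nrow(inputs), ]
  lastOutput <- outputs[nrow(outputs), ]
  prevFitness <- -Inf
  trace <- list()
  converged <- FALSE
  bestL1 <- Inf
  bestRow <- NA_integer_
  for (iter in seq_len(maxIter)) {
    ref <- stats::setNames(as.numeric(lastOutput), outNames)
    ref[names(setpoints)] <- setpoints
    if (iter >= gate && length(extraSetpoints))
      ref[names(extraSetpoints)] <- extraSetpoints
    w <- rollWindow(inputs, outputs, theta = nrow(inputs), tau = tau)
    vContext <- w$v
    w <- stats::setNames(rep(1, length(ref)), outNames)
    if (setpointWeight != 1) {
      w[names(setpoints)] <- setpointWeight
      if (iter >= gate) w[names(extraSetpoints)] <- setpointWeight
    }
    attempt <- 0L
    repeat {
      sIdx <- sIdx + 1L
      sol <- gaEvolve(currentInput, vContext, ref, surrogate,
                      cfg = cfg, seed = seeds[sIdx],
                      weights = if (setpointWeight != 1) w else NULL)
      if (sol$fitness >= prevFitness || attempt >= retries) break
      attempt <- attempt + 1L                    # fitness regressed: retry
    }
    accepted <- sol$fitness >= prevFitness
    if (accepted) {
      # advance the loop with the accepted optimal solution
      prevFitness <- sol$fitness
      newInput <- sol$input
      out <- plantStep(plant, newInput)
      l1 <- sum(abs(out - ref))
      inputs <- rbind(inputs, newInput)
      outputs <- rbind(outputs, out)
      currentInput <- newInput
      lastOutput <- out
    } else {
      # still regressed after all retries: keep the same current input
      # (the next iteration tries again from it with fresh GA draws)
      l1 <- sum(abs(lastOutput - ref))
      prevFitness <- prevFitness * 0.9    # relax the bar so the loop cannot jam
    }
    if (accepted && l1 < bestL1) {
      bestL1 <- l1
      bestRow <- nrow(outputs)
    }
    trace[[iter]] <- data.frame(iter = iter, l1 = l1,
                                fitness = sol$fitness,
                                generations = sol$generations,
                                retries = attempt, accepted = accepted)
    if (l1 < l1Threshold) { converged <- TRUE; break }
  }
  # on convergence the final solution is the current one; otherwise the
  # failure report carries the best-tracking solution found
  outRow <- if (converged || is.na(bestRow)) nrow(outputs) else bestRow
  list(converged = converged,
       input = stats::setNames(inputs[outRow, ], names(currentInput)),
       output = stats::setNames(outputs[outRow, ], outNames),
       bestL1 = bestL1,
       trace = do.call(rbind, trace),
       iterations = length(trace),
       history = list(inputs = inputs, outputs = outputs))
}

#' Record an initial control history from a plant
#'
#' Runs the plant open-loop for `tau + 1` steps (equilibrium-consistent
#' inputs, as in dataset generation but without excitation jitter) to
#' provide the window context the controller starts from.
#'
#' @param plant a [Plant-class].
#' @param tau window length of the surrogate.
#' @param uInit optional starting input.
#' @return list with `inputs` and `outputs` matrices.
#' @export
controlHistory <- function(plant, tau, uInit = NULL) {
  k <- speciesCounts(plant@network)
  nio <- sum(k[c("p", "s", "m", "c")])
  state <- as.numeric(plant@initState)
  u <- if (is.null(uInit))
    as.numeric(solveEquilibriumInput(plant@network, state))
  else as.numeric(uInit)
  nstep <- tau + 1
  inputs <- matrix(NA_real_, nstep, nio)
  outputs <- matrix(NA_real_, nstep, nio - k[["c"]])
  for (i in seq_len(nstep)) {
    inputs[i, ] <- c(state, u)
    out <- plantStep(plant, inputs[i, ])
    outputs[i, ] <- out
    state <- as.numeric(out)
    u <- as.numeric(solveEquilibriumInput(plant@network, state, uInit = u))
  }
  list(inputs = inputs, outputs = outputs)
}
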