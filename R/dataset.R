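#' Dimension of the sliding-window regressor
#'
#' Length of the window vector built from `tau` past input/output
#' instance pairs plus the current input instance:
#' `tau * (2*(p+s+m) + c) + (p+s+m+c)`.
#'
#' @param tau number of past input/output pairs.
#' @param p,s,m,c species counts.
#' @return integer dimension `d`.
#' @examples
#' windowDimension(19, 37, 29, 41, 27)  # 4713
#' @export
windowDimension <- function(tau, p, s, m, c) {
  v <- c(tau = tau, p = p, s = s, m = m, c = c)
  if (any(v < 0)) stop("counts must be non-negative")
  as.integer(tau * (2 * (p + s + m) + c) + (p + s + m + c))
}

#' Extract one window sample from recorded plant history
#'
#' Builds the regressor vector for time index `theta` from matrices of
#' recorded input instances (`p+s+m+c` columns) and output instances
#' (`p+s+m` columns): the `tau` past (input, output) pairs ordered from
#' oldest (age `tau`) to most recent (age 1), followed by the current
#' input instance; the supervised target is the current output instance.
#'
#' @param inputs numeric matrix of input instances, one row per time.
#' @param outputs numeric matrix of output instances, row-aligned.
#' @param theta time index (row) of the current instance.
#' @param tau number of past pairs; requires `theta > tau`.
#' @return list with `v` (regressor), `target`, `theta`.
#' @export
rollWindow <- function(inputs, outputs, theta, tau) {
  if (theta <= tau)
    stop(sprintf("insufficient history: theta=%d requires tau=%d past rows",
                 theta, tau))
  past <- if (tau > 0)
    unlist(lapply((theta - tau):(theta - 1), function(i)
      c(inputs[i, ], outputs[i, ])), use.names = FALSE)
  else numeric(0)
  list(v = c(past, unname(inputs[theta, ])),
       target = unname(outputs[theta, ]), theta = theta)
}

# inverse of rollWindow: slice a window vector back into its blocks
.unrollWindow <- function(v, tau, dims) {
  nio <- sum(dims[c("p", "s", "m", "c")]); nout <- nio - dims[["c"]]
  blk <- nio + nout
  inputs <- matrix(NA_real_, tau + 1, nio)
  outputs <- matrix(NA_real_, tau, nout)
  for (a in seq_len(tau)) {
    off <- (a - 1) * blk
    inputs[a, ] <- v[off + seq_len(nio)]
    outputs[a, ] <- v[off + nio + seq_len(nout)]
  }
  inputs[tau + 1, ] <- v[tau * blk + seq_len(nio)]
  list(inputs = inputs, outputs = outputs)
}

#' Generate the sliding-window supervised dataset from a plant
#'
#' Closed-loop data generation: starting from the plant's initial state
#' and its equilibrium-consistent input, each step feeds the current
#' input instance to [plantStep()], derives the next external input from
#' the output by equilibrium solving ([solveEquilibriumInput()]) plus a
#' small seeded uniform excitation jitter (so the regressor matrix has
#' full numerical rank), and forms the next input instance from the
#' output and the new input. Window samples are recorded once `tau`
#' steps of history exist.
#'
#' @param plant a [Plant-class].
#' @param phi number of samples to generate.
#' @param tau past-pair count per window.
#' @param seed RNG seed for the excitation jitter.
#' @param jitter half-width of the uniform input excitation.
#' @param uInit optional starting input (defaults to the equilibrium
#'   input of the initial state).
#' @param stateJitter optional excitation of the state block of the
#'   next input instance: with probability `stateJitterProb` per step the
#'   state components are perturbed by a uniform step of this amplitude
#'   before being applied (the recorded input instance is the perturbed
#'   one, so windows stay self-consistent). Zero (default) reproduces
#'   the plain closed-loop protocol, where the current-input state block
#'   is collinear with the previous output and the one-step response to
#'   state changes is unidentifiable; the controller's surrogate needs
#'   this excitation.
#' @param stateJitterProb per-step probability of a state excitation.
#' @param segments number of independent closed-loop segments. With one
#'   segment (default) the whole dataset is a single run from the
#'   plant's initial state; with more, the loop restarts from fresh
#'   uniform random states in (0, 1), which spreads the samples over the
#'   state space when the sample budget is small (each segment re-warms
#'   its own window history, so windows never straddle a restart).
#' @return a [WindowDataset-class].
#' @export
generateDataset <- function(plant, phi, tau = 19, seed = 1L,
                            jitter = 0.02, uInit = NULL, segments = 1L,
                            stateJitter = 0, stateJitterProb = 0.5) {
  k <- speciesCounts(plant@network)
  nio <- sum(k[c("p", "s", "m", "c")]); nout <- nio - k[["c"]]
  segSizes <- rep(phi %/% segments, segments)
  if (phi %% segments) segSizes[seq_len(phi %% segments)] <-
    segSizes[seq_len(phi %% segments)] + 1L
  d <- windowDimension(tau, k[["p"]], k[["s"]], k[["m"]], k[["c"]])
  V <- matrix(NA_real_, phi, d)
  Y <- matrix(NA_real_, phi, nout)
  row <- 0L
  truncated <- FALSE
  withSeed(seed, {
    for (seg in seq_along(segSizes)) {
      state <- if (seg == 1L) as.numeric(plant@initState)
               else runif(nio - k[["c"]])
      u <- if (seg == 1L && !is.null(uInit)) as.numeric(uInit)
           else as.numeric(solveEquilibriumInput(plant@network, state))
      nstep <- segSizes[seg] + tau
      inputs <- matrix(NA_real_, nstep, nio)
      outputs <- matrix(NA_real_, nstep, nout)
      nrec <- 0L
      for (i in seq_len(nstep)) {
        if (stateJitter > 0 && runif(1) < stateJitterProb)
          state <- clamp01(state + runif(length(state), -stateJitter,
                                         stateJitter))
        inputs[i, ] <- c(state, u)
        out <- tryCatch(plantStep(plant, inputs[i, ]),
                        error = function(e) NULL)
        if (is.null(out)) {
          warning(sprintf(
            "plant step failed at segment %d step %d; dataset truncated",
            seg, i))
          truncated <- TRUE
          break
        }
        outputs[i, ] <- out
        nrec <- i
        state <- as.numeric(out)
        u <- as.numeric(solveEquilibriumInput(plant@network, state,
                                              uInit = u))
        u <- clamp01(u + runif(length(u), -jitter, jitter))
      }
      for (theta in seq_len(nrec)[-seq_len(min(tau, nrec))]) {
        w <- rollWindow(inputs, outputs, theta = theta, tau = tau)
        row <- row + 1L
        V[row, ] <- w$v
        Y[row, ] <- w$target
      }
    }
  })
  V <- V[seq_len(row), , drop = FALSE]
  Y <- Y[seq_len(row), , drop = FALSE]
  colnames(Y) <- speciesNames(plant@network, "all")
  new("WindowDataset", V = V, Y = Y, tau = as.integer(tau),
      dims = stats::setNames(as.integer(k[c("p", "s", "m", "c")]),
                             c("p", "s", "m", "c")),
      meta = list(seed = seed, jitter = jitter, phi = phi,
                  segments = segments, stateJitter = stateJitter,
                  spec = networkHash(plant@network),
                  truncated = truncated || row < phi))
}

#' Split a window dataset into training and test parts
#'
#' Seeded i.i.d. random split (not temporal): `floor(n * fraction)`
#' samples go to training, the rest to test; the two parts partition the
#' dataset.
#'
#' @param dataset a [WindowDataset-class].
#' @param fraction training fraction in (0, 1).
#' @param seed RNG seed.
#' @return list with `train` and `test` [WindowDataset-class] objects.
#' @export
splitDataset <- function(dataset, fraction = 0.65, seed = 1L) {
  stopifnot(fraction > 0, fraction < 1)
  n <- nrow(dataset@V)
  ntr <- floor(n * fraction)
  idx <- withSeed(seed, sample.int(n, ntr))
  take <- function(rows) new("WindowDataset",
    V = dataset@V[rows, , drop = FALSE], Y = dataset@Y[rows, , drop = FALSE],
    tau = dataset@tau, dims = dataset@dims,
    meta = c(dataset@meta, list(split_seed = seed, fraction = fraction)))
  list(train = take(sort(idx)), test = take(setdiff(seq_len(n), idx)))
}

#' Persist and reload a window dataset
#'
#' Two-table columnar archive (CSV regressors and targets) with a JSON
#' manifest recording the window length, species counts and seeds.
#'
#' @param dataset a [WindowDataset-class].
#' @param dir directory to create/fill.
#' @return `saveDataset`: the directory, invisibly; `loadDataset`: the
#'   dataset.
#' @export
saveDataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(as.data.frame(dataset@V),
                   file.path(dir, "regressors.csv"), row.names = FALSE)
  utils::write.csv(as.data.frame(dataset@Y),
                   file.path(dir, "targets.csv"), row.names = FALSE)
  manifest <- list(tau = dataset@tau, dims = as.list(dataset@dims),
                   meta = dataset@meta)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @param dir dataset directory written by `saveDataset`.
#' @rdname saveDataset
#' @export
loadDataset <- function(dir) {
  man <- jsonlite::fromJSON(file.path(dir, "manifest.json"))
  V <- as.matrix(utils::read.csv(file.path(dir, "regressors.csv")))
  Y <- as.matrix(utils::read.csv(file.path(dir, "targets.csv")))
  dimnames(V) <- NULL
  new("WindowDataset", V = V, Y = Y, tau = as.integer(man$tau),
      dims = stats::setNames(as.integer(unlist(man$dims)),
                             names(man$dims)),
      meta = as.list(man$meta))
}
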