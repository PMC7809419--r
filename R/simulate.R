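#' Timescale and solver configuration
#'
#' @param omega1 slow-to-fast timescale ratio (gene regulatory vs
#'   signaling), in (0, 1]. Default 1/60.
#' @param omega2 fast-to-ultrafast ratio (signaling vs metabolic), in
#'   (0, 1]. Default 1/60.
#' @param tGrid strictly increasing slow-timescale sample times.
#' @param mode `"direct_stiff"` (implicit adaptive solver on the full
#'   scaled system; default) or `"nested_multirate"` (hierarchical
#'   explicit sub-stepping of the fast and ultrafast subsystems).
#' @param absTol,relTol solver tolerances.
#' @param clamp clamp states to the unit box after accepted steps.
#' @return configuration list.
#' @export
timescaleConfig <- function(omega1 = 1 / 60, omega2 = 1 / 60,
                            tGrid = seq(0, 10, by = 0.25),
                            mode = c("direct_stiff", "nested_multirate"),
                            absTol = 1e-8, relTol = 1e-6, clamp = TRUE) {
  stopifnot(omega1 > 0, omega1 <= 1, omega2 > 0, omega2 <= 1,
            length(tGrid) >= 2, all(diff(tGrid) > 0))
  list(omega1 = omega1, omega2 = omega2, tGrid = tGrid,
       mode = match.arg(mode), absTol = absTol, relTol = relTol,
       clamp = clamp)
}

.as_u_fun <- function(uPolicy, cn) {
  if (is.function(uPolicy)) return(uPolicy)
  u <- as.numeric(uPolicy)
  if (length(u) != cn)
    stop(sprintf("constant input policy must have length c=%d", cn))
  function(t) u
}

.pins <- function(network, overrides) {
  if (!length(overrides))
    return(list(idx = integer(0), val = numeric(0)))
  all <- speciesNames(network, "all")
  idx <- match(names(overrides), all)
  if (anyNA(idx))
    stop("unknown species in overrides: ",
         paste(names(overrides)[is.na(idx)], collapse = ", "))
  list(idx = as.integer(idx - 1L), val = as.numeric(overrides))
}

#' Integrate the three-timescale pathway system
#'
#' Solves the full stiff coupled system on a slow-timescale grid. The
#' default mode hands the scaled system to an implicit adaptive solver
#' (the `1/(omega1*omega2)` metabolic scaling makes explicit stepping
#' impractical at the default ratios). The nested multirate mode instead
#' sub-steps the metabolic block at `dt*omega1*omega2` and the signaling
#' block at `dt*omega1` resolution with a midpoint rule, mirroring the
#' stretched-timescale construction; both modes agree to solver tolerance.
#' States are clamped to the unit box after each accepted step; the number
#' of clamped entries is reported in the trajectory metadata.
#'
#' @param network a [PathwayNetwork-class].
#' @param init numeric initial state of length `p+s+m` (canonical order).
#' @param uPolicy external-input policy: a constant length-`c` vector or a
#'   function of slow time returning one.
#' @param config a [timescaleConfig()] list.
#' @param overrides named numeric of pinned species levels (hard
#'   overrides, derivative forced to zero).
#' @return a [Trajectory-class].
#' @export
integrateNetwork <- function(network, init, uPolicy,
                             config = timescaleConfig(),
                             overrides = numeric(0)) {
  k <- speciesCounts(network)
  nstate <- sum(k[c("p", "s", "m")])
  if (length(init) != nstate)
    stop(sprintf("init must have length p+s+m = %d", nstate))
  ptr <- .compiledModel(network)
  ufun <- .as_u_fun(uPolicy, k[["c"]])
  pins <- .pins(network, overrides)
  init <- as.numeric(init)
  if (length(pins$idx)) init[pins$idx + 1L] <- pins$val
  tg <- config$tGrid
  clamped <- 0L

  if (config$mode == "direct_stiff") {
    if (!is.function(uPolicy)) {
      # constant inputs: hand the compiled derivative straight to the
      # solver (no per-evaluation R call)
      .model_activate(ptr, as.numeric(uPolicy), config$omega1,
                      config$omega2, config$clamp, pins$idx, pins$val)
      sol <- deSolve::lsoda(y = init, times = tg, func = "pathmpc_deriv",
                            dllname = "pathMPC", initfunc = NULL,
                            parms = NULL, rtol = config$relTol,
                            atol = config$absTol, maxsteps = 50000)
    } else {
      rhs <- function(t, y, parms) {
        list(.model_rhs(ptr, y, ufun(t), config$omega1, config$omega2,
                        config$clamp, pins$idx, pins$val))
      }
      sol <- deSolve::lsoda(y = init, times = tg, func = rhs, parms = NULL,
                            rtol = config$relTol, atol = config$absTol,
                            maxsteps = 50000)
    }
    if (nrow(sol) < length(tg))
      stop(sprintf("integration failed at t=%.4g (last good time)",
                   sol[nrow(sol), 1]))
    states <- unname(sol[, -1, drop = FALSE])
  } else {
    n1 <- max(1L, ceiling(1 / config$omega1 / 4))
    n2 <- max(1L, ceiling(1 / config$omega2 / 4))
    heun <- function(state, t, dt, sel) {
      d1 <- .model_rhs(ptr, state, ufun(t), config$omega1, config$omega2,
                       config$clamp, pins$idx, pins$val)
      mid <- state; mid[sel] <- mid[sel] + dt * d1[sel]
      d2 <- .model_rhs(ptr, mid, ufun(t + dt), config$omega1, config$omega2,
                       config$clamp, pins$idx, pins$val)
      state[sel] <- state[sel] + dt / 2 * (d1[sel] + d2[sel])
      state
    }
    ix <- seq_len(k[["p"]]); iy <- k[["p"]] + seq_len(k[["s"]])
    iz <- k[["p"]] + k[["s"]] + seq_len(k[["m"]])
    states <- matrix(NA_real_, length(tg), nstate)
    state <- init; states[1, ] <- state
    for (g in seq_len(length(tg) - 1L)) {
      h <- tg[g + 1] - tg[g]
      nouter <- max(1L, ceiling(h / 0.05))
      dtx <- h / nouter
      for (o in seq_len(nouter)) {
        t0 <- tg[g] + (o - 1) * dtx
        dty <- dtx / n1; dtz <- dty / n2
        for (j in seq_len(n1)) {
          tj <- t0 + (j - 1) * dty
          for (kk in seq_len(n2))
            state <- heun(state, tj + (kk - 1) * dtz, dtz, iz)
          state <- heun(state, tj, dty, iy)
          if (config$clamp) state <- clamp01(state)
        }
        state <- heun(state, t0, dtx, ix)
        if (config$clamp) state <- clamp01(state)
      }
      states[g + 1, ] <- state
    }
  }
  if (config$clamp) {
    cl <- clamp01(states)
    clamped <- sum(cl != states)
    states <- cl
  }
  colnames(states) <- speciesNames(network, "all")
  inputs <- t(vapply(tg, ufun, numeric(k[["c"]])))
  if (k[["c"]] == 1L) inputs <- matrix(inputs, ncol = 1L)
  colnames(inputs) <- network@inputNames
  new("Trajectory", times = tg, states = states, inputs = inputs,
      meta = list(spec = networkHash(network), config = config,
                  clamped = clamped, counts = k))
}

#' Write a trajectory to CSV
#'
#' One row per sample time with a `time` column followed by one column per
#' state variable in canonical species order (and optionally the external
#' inputs).
#'
#' @param traj a [Trajectory-class].
#' @param path output file.
#' @param inputs also write the external-input columns.
#' @return the path, invisibly.
#' @export
writeTrajectoryCSV <- function(traj, path, inputs = FALSE) {
  df <- data.frame(time = traj@times, traj@states, check.names = FALSE)
  if (inputs) df <- cbind(df, as.data.frame(traj@inputs))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
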