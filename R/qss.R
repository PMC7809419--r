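#' Solve a nonlinear system inside the unit box
#'
#' Damped Newton iteration with a numerically estimated Jacobian and
#' projection onto `[lower, upper]`, falling back to box-constrained
#' quasi-Newton minimization of the squared residual when Newton stalls.
#' Ties (multiple roots) resolve to the root the damped iteration reaches
#' from `init`; the fallback favors the smallest-norm minimizer found.
#'
#' @param fn residual function, length-n numeric to length-n numeric.
#' @param init starting point.
#' @param lower,upper box bounds (scalars or vectors).
#' @param absTol residual sup-norm target.
#' @param maxIter Newton iteration cap.
#' @return list with `root`, `residual` (sup norm), `converged`.
#' @export
solveBoxRoot <- function(fn, init, lower = 0, upper = 1, absTol = 1e-10,
                         maxIter = 100) {
  n <- length(init)
  lo <- rep_len(lower, n); hi <- rep_len(upper, n)
  x <- pmin(pmax(as.numeric(init), lo), hi)
  fx <- fn(x)
  best <- list(x = x, norm = max(abs(fx)))
  for (it in seq_len(maxIter)) {
    if (best$norm <= absTol) break
    J <- matrix(0, n, n)
    h <- pmax(1e-7, 1e-7 * abs(x))
    for (j in seq_len(n)) {
      xp <- x; xp[j] <- min(x[j] + h[j], hi[j])
      xm <- x; xm[j] <- max(x[j] - h[j], lo[j])
      dj <- xp[j] - xm[j]
      J[, j] <- if (dj > 0) (fn(xp) - fn(xm)) / dj else 0
    }
    step <- tryCatch(solve(J, -fx), error = function(e) NULL)
    if (is.null(step))
      step <- tryCatch(-as.numeric(MASS_ginv(J) %*% fx),
                       error = function(e) NULL)
    if (is.null(step)) break
    lam <- 1; improved <- FALSE
    for (half in 1:20) {
      xn <- pmin(pmax(x + lam * step, lo), hi)
      fxn <- fn(xn)
      if (max(abs(fxn)) < best$norm) {
        x <- xn; fx <- fxn
        best <- list(x = x, norm = max(abs(fx)))
        improved <- TRUE
        break
      }
      lam <- lam / 2
    }
    if (!improved) break
  }
  if (best$norm > absTol) {
    obj <- function(v) sum(fn(v)^2)
    opt <- tryCatch(
      stats::optim(best$x, obj, method = "L-BFGS-B", lower = lo, upper = hi,
                   control = list(maxit = 500, factr = 1e4)),
      error = function(e) NULL)
    if (!is.null(opt)) {
      nrm <- max(abs(fn(opt$par)))
      if (nrm < best$norm) best <- list(x = opt$par, norm = nrm)
    }
  }
  list(root = best$x, residual = best$norm, converged = best$norm <= absTol)
}

# Moore-Penrose pseudo-inverse via SVD (small systems only).
MASS_ginv <- function(A, tol = 1e-10) {
  sv <- svd(A)
  keep <- sv$d > tol * max(sv$d)
  if (!any(keep)) return(matrix(0, ncol(A), nrow(A)))
  sv$v[, keep, drop = FALSE] %*% (t(sv$u[, keep, drop = FALSE]) / sv$d[keep])
}

#' Quasi-steady state of the metabolic (ultrafast) subsystem
#'
#' Solves `N_m %*% r_m = 0` for the metabolite vector `z` inside the unit
#' box at frozen gene expression `x`, signaling `y` and inputs `u` -- the
#' ultrafast equilibrium map obtained by letting the fast-to-ultrafast
#' ratio tend to zero.
#'
#' @param network a [PathwayNetwork-class].
#' @param x,y,u gene, signaling and input vectors.
#' @param zInit optional warm start.
#' @param absTol residual tolerance.
#' @return named metabolite vector `z*` with attributes `residual` and
#'   `converged`.
#' @export
qssUltrafast <- function(network, x, y, u, zInit = NULL, absTol = 1e-10) {
  k <- speciesCounts(network)
  ptr <- .compiledModel(network)
  fn <- function(z) as.numeric(
    .model_rates(ptr, c(x, y, z), u)$hdot)
  z0 <- if (is.null(zInit)) rep(0.5, k[["m"]]) else as.numeric(zInit)
  sol <- solveBoxRoot(fn, z0, absTol = absTol)
  if (!sol$converged) {
    alt <- solveBoxRoot(fn, rep(0.25, k[["m"]]), absTol = absTol)
    if (alt$residual < sol$residual) sol <- alt
  }
  out <- stats::setNames(sol$root, network@metaboliteNames)
  attr(out, "residual") <- sol$residual
  attr(out, "converged") <- sol$converged
  out
}

#' Quasi-steady state of the signaling (fast) subsystem
#'
#' Solves the fast subsystem residual `N_s %*% r_s = 0` for `y`, with the
#' metabolites simultaneously held at their own ultrafast equilibrium
#' (`z = H'(x, y, u)` re-solved inside every residual evaluation), i.e.
#' the map `y = G(x, u)` of the slow reduced model.
#'
#' @inheritParams qssUltrafast
#' @param yInit optional warm start.
#' @return named signaling vector `y*` with attributes `residual`,
#'   `converged` and `z` (the consistent metabolite equilibrium).
#' @export
qssFast <- function(network, x, u, yInit = NULL, absTol = 1e-8) {
  k <- speciesCounts(network)
  ptr <- .compiledModel(network)
  zWarm <- rep(0.5, k[["m"]])
  fn <- function(y) {
    z <- qssUltrafast(network, x, y, u, zInit = zWarm, absTol = absTol * 1e-2)
    zWarm <<- as.numeric(z)
    as.numeric(.model_rates(ptr, c(x, y, zWarm), u)$gdot)
  }
  y0 <- if (is.null(yInit)) rep(0.5, k[["s"]]) else as.numeric(yInit)
  sol <- solveBoxRoot(fn, y0, absTol = absTol)
  if (!sol$converged)
    stop(sprintf("no fast-subsystem equilibrium found in the unit box (residual %.3g)",
                 sol$residual))
  out <- stats::setNames(sol$root, network@signalNames)
  attr(out, "residual") <- sol$residual
  attr(out, "converged") <- sol$converged
  attr(out, "z") <- stats::setNames(zWarm, network@metaboliteNames)
  out
}

#' Reduced slow derivative
#'
#' Gene-expression derivative of the singular-perturbation-reduced model:
#' signaling and metabolites are replaced by their quasi-steady-state maps
#' `G(x, u)` and `H(x, u)` before evaluating the gene rate laws.
#'
#' @inheritParams qssFast
#' @return named `xdot` vector with attributes `y` and `z` (the QSS maps).
#' @export
reducedSlowDerivative <- function(network, x, u, yInit = NULL) {
  ystar <- qssFast(network, x, u, yInit = yInit)
  zstar <- attr(ystar, "z")
  ptr <- .compiledModel(network)
  xdot <- as.numeric(.model_rates(ptr, c(x, as.numeric(ystar),
                                         as.numeric(zstar)), u)$xdot)
  out <- stats::setNames(xdot, network@geneNames)
  attr(out, "y") <- ystar
  attr(out, "z") <- zstar
  out
}

#' Equilibrium-consistent external input
#'
#' Finds the external-input vector under which the given state is closest
#' to an equilibrium of the integrated system: minimizes the squared norm
#' of the unscaled subsystem residuals (gene, signaling, metabolic) over
#' `u` in the unit box, returning an exact root when one exists. Used in
#' the sliding-window data-generation loop, so it never hard-fails: on
#' optimizer failure the starting input is returned with a warning flag.
#'
#' @param network a [PathwayNetwork-class].
#' @param state full state vector (length `p+s+m`).
#' @param uInit starting input (defaults to mid-box).
#' @param maxit optimizer iteration cap.
#' @return named input vector with attributes `residual` and `converged`.
#' @export
solveEquilibriumInput <- function(network, state, uInit = NULL, maxit = 40) {
  k <- speciesCounts(network)
  ptr <- .compiledModel(network)
  u0 <- if (is.null(uInit)) rep(0.5, k[["c"]]) else as.numeric(uInit)
  obj <- function(u) {
    r <- .model_rates(ptr, state, u)
    sum(r$xdot^2) + sum(r$gdot^2) + sum(r$hdot^2)
  }
  opt <- tryCatch(
    stats::optim(u0, obj, method = "L-BFGS-B", lower = 0, upper = 1,
                 control = list(maxit = maxit)),
    error = function(e) NULL)
  if (is.null(opt)) {
    out <- stats::setNames(u0, network@inputNames)
    attr(out, "residual") <- sqrt(obj(u0))
    attr(out, "converged") <- FALSE
    return(out)
  }
  out <- stats::setNames(opt$par, network@inputNames)
  attr(out, "residual") <- sqrt(opt$value)
  attr(out, "converged") <- TRUE
  out
}
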