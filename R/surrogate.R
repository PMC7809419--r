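#' Radial-basis kernel matrix between two sample sets
#'
#' `K[i, j] = exp(-gamma * ||a_i - b_j||^2)`, computed via the expanded
#' squared distance so the cross term is a single matrix product.
#'
#' @param A,B numeric matrices with one sample per row (same column
#'   count).
#' @param gamma kernel coefficient.
#' @return `nrow(A) x nrow(B)` kernel matrix.
#' @export
rbfKernel <- function(A, B, gamma) {
  d2 <- outer(rowSums(A^2), rowSums(B^2), `+`) - 2 * tcrossprod(A, B)
  d2[d2 < 0] <- 0
  exp(-gamma * d2)
}

#' Fit the MISO-ensemble epsilon-SVR surrogate
#'
#' Trains one epsilon-insensitive support vector regressor per output
#' component on the window regressors. All outputs share a single
#' precomputed radial-basis kernel matrix; each per-output dual problem
#' (box constraint `C`, tube `epsilon`) is solved by the kernlab SMO
#' solver. The fitted ensemble is stored in dual form — union of support
#' vectors, per-output dual coefficients `alpha_b = zeta_b - zeta_b*`
#' and biases — and predictions are evaluated by this package's own
#' kernel expansion (see [predictSurrogate()]). Outputs with (near-)
#' constant targets degenerate to an empty support set with the bias at
#' the target value.
#'
#' @param train a [WindowDataset-class] (training part).
#' @param gamma radial-basis kernel coefficient (default 10).
#' @param C box constraint (default 100).
#' @param epsilon insensitive-tube half width (default 0.0025).
#' @param tol SMO convergence tolerance.
#' @return a [SurrogateModel-class].
#' @export
fitSurrogate <- function(train, gamma = 10, C = 100, epsilon = 0.0025,
                         tol = 0.001) {
  V <- train@V; Y <- train@Y
  n <- nrow(V)
  if (n < 2) stop("training set must contain at least two samples")
  K <- rbfKernel(V, V, gamma)
  Kk <- kernlab::as.kernelMatrix(K)
  nout <- ncol(Y)
  alphaAll <- matrix(0, n, nout)
  bias <- numeric(nout)
  for (mu in seq_len(nout)) {
    y <- Y[, mu]
    if (max(y) - min(y) <= epsilon) {      # flat target fits inside the tube
      bias[mu] <- mean(range(y))
      next
    }
    fit <- kernlab::ksvm(Kk, y, type = "eps-svr", C = C,
                         epsilon = epsilon, tol = tol)
    alphaAll[kernlab::alphaindex(fit), mu] <- kernlab::coef(fit)
    bias[mu] <- -kernlab::b(fit)
  }
  used <- rowSums(alphaAll != 0) > 0
  new("SurrogateModel",
      SV = V[used, , drop = FALSE],
      alpha = alphaAll[used, , drop = FALSE],
      bias = bias, gamma = gamma, cost = C, epsilon = epsilon,
      outputNames = colnames(Y) %||% character(ncol(Y)),
      meta = list(n_train = n, tau = train@tau, dims = as.list(train@dims),
                  spec = train@meta$spec, sv_rows = which(used)))
}

#' Predict plant outputs with the surrogate
#'
#' Kernel expansion over the stored support vectors:
#' `gamma_hat_mu(v) = sum_b alpha_b[mu] * k(v, v_b) + beta_mu`, evaluated
#' for all outputs at once. Predictions are clamped to the unit box for
#' downstream plant compatibility; the number of clamped entries is
#' attached as an attribute.
#'
#' @param model a [SurrogateModel-class].
#' @param v a single regressor vector or a matrix with one regressor per
#'   row.
#' @param clamp clamp predictions into the unit interval (default TRUE).
#' @param ... unused.
#' @return numeric matrix `n x (p+s+m)` (a named vector for single-row
#'   input) with attribute `clamped`.
#' @export
setMethod("predictSurrogate", "SurrogateModel",
          function(model, v, clamp = TRUE, ...) {
  single <- is.null(dim(v))
  V <- if (single) matrix(v, nrow = 1) else as.matrix(v)
  if (ncol(V) != ncol(model@SV) && nrow(model@SV) > 0)
    stop(sprintf("regressor length %d does not match model dimension %d",
                 ncol(V), ncol(model@SV)))
  raw <- if (nrow(model@SV))
    rbfKernel(V, model@SV, model@gamma) %*% model@alpha
  else matrix(0, nrow(V), length(model@bias))
  pred <- sweep(raw, 2, model@bias, `+`)
  nclamp <- sum(pred < 0 | pred > 1)
  if (clamp) pred <- clamp01(pred)
  colnames(pred) <- model@outputNames
  if (single) {
    out <- stats::setNames(pred[1, ], model@outputNames)
    attr(out, "clamped") <- nclamp
    return(out)
  }
  attr(pred, "clamped") <- nclamp
  pred
})

#' Test accuracy of the surrogate at an MSE threshold
#'
#' Fraction (as a percentage) of test samples whose mean squared error
#' across all output components is below `threshold` (default 0.05).
#'
#' @param model a [SurrogateModel-class].
#' @param test a [WindowDataset-class].
#' @param threshold per-sample MSE threshold.
#' @return percentage in `[0, 100]`, with attribute `mse` (per-sample
#'   MSE vector).
#' @export
surrogateAccuracy <- function(model, test, threshold = 0.05) {
  if (!nrow(test@V)) stop("empty test set: accuracy undefined")
  stopifnot(threshold > 0)
  pred <- predictSurrogate(model, test@V, clamp = FALSE)
  mse <- rowMeans((pred - test@Y)^2)
  out <- 100 * mean(mse < threshold)
  attr(out, "mse") <- mse
  out
}

#' Karush-Kuhn-Tucker diagnostics of the fitted ensemble
#'
#' Recomputes, per output model: the dual equality `|sum_b alpha_b|`,
#' the worst box-constraint violation `max(|alpha| - C)`, and the worst
#' tube excess `max(|residual| - epsilon)` over the non-bound support
#' vectors (where the residual must sit on the tube boundary).
#'
#' @param model a [SurrogateModel-class].
#' @param train the training [WindowDataset-class] used to fit it.
#' @param boundTol relative margin for classifying bound support
#'   vectors.
#' @return data.frame with one row per output.
#' @export
surrogateKKT <- function(model, train, boundTol = 1e-6) {
  pred <- predictSurrogate(model, train@V, clamp = FALSE)
  resid <- train@Y - pred
  svIdx <- as.integer(unlist(model@meta$sv_rows))
  if (!length(svIdx) && nrow(model@SV))
    stop("model does not record its training rows; refit with fitSurrogate")
  rows <- lapply(seq_along(model@bias), function(mu) {
    a <- model@alpha[, mu]
    act <- which(a != 0)
    nonBound <- act[abs(a[act]) < model@cost * (1 - boundTol)]
    trainRows <- svIdx[nonBound]
    data.frame(
      output = model@outputNames[mu],
      n_sv = length(act),
      dual_equality = abs(sum(a)),
      box_violation = if (length(act)) max(0, max(abs(a[act])) - model@cost) else 0,
      tube_excess = if (length(trainRows))
        max(0, max(abs(resid[trainRows, mu])) - model@epsilon) else 0)
  })
  do.call(rbind, rows)
}

#' Persist and reload a fitted surrogate
#'
#' Versioned plain-text archive: support vectors and dual coefficients
#' as CSV, hyperparameters and provenance in a JSON manifest.
#'
#' @param model a [SurrogateModel-class].
#' @param dir directory to create/fill.
#' @return `saveSurrogate`: the directory, invisibly; `loadSurrogate`:
#'   the model.
#' @export
saveSurrogate <- function(model, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(as.data.frame(model@SV),
                   file.path(dir, "support_vectors.csv"), row.names = FALSE)
  utils::write.csv(as.data.frame(model@alpha),
                   file.path(dir, "dual_coefficients.csv"), row.names = FALSE)
  jsonlite::write_json(
    list(format = "surrogate/1", bias = model@bias, gamma = model@gamma,
         C = model@cost, epsilon = model@epsilon,
         output_names = model@outputNames, meta = model@meta),
    file.path(dir, "manifest.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @param dir archive directory written by `saveSurrogate`.
#' @rdname saveSurrogate
#' @export
loadSurrogate <- function(dir) {
  man <- jsonlite::fromJSON(file.path(dir, "manifest.json"))
  SV <- as.matrix(utils::read.csv(file.path(dir, "support_vectors.csv")))
  A <- as.matrix(utils::read.csv(file.path(dir, "dual_coefficients.csv")))
  dimnames(SV) <- NULL; dimnames(A) <- NULL
  new("SurrogateModel", SV = SV, alpha = A, bias = as.numeric(man$bias),
      gamma = man$gamma, cost = man$C, epsilon = man$epsilon,
      outputNames = as.character(man$output_names),
      meta = as.list(man$meta))
}
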