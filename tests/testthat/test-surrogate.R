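test_that("flat targets degenerate to a bias-only model inside the tube", {
  ds <- toy_dataset()
  flat <- new("WindowDataset", V = ds@V[1:30, ],
              Y = matrix(0.4, 30, ncol(ds@Y),
                         dimnames = list(NULL, colnames(ds@Y))),
              tau = ds@tau, dims = ds@dims, meta = ds@meta)
  m <- fitSurrogate(flat)
  expect_identical(nrow(m@SV), 0L)
  pred <- predictSurrogate(m, ds@V[31:40, ])
  expect_true(all(abs(pred - 0.4) <= m@epsilon + 1e-12))
})

test_that("a linear one-dimensional relationship is recovered", {
  set.seed(21)
  V <- matrix(runif(50), 50, 1)
  Y <- matrix(0.5 * V[, 1], 50, 1, dimnames = list(NULL, "out"))
  ds <- new("WindowDataset", V = V, Y = Y, tau = 0L,
            dims = c(p = 1L, s = 0L, m = 0L, c = 0L), meta = list())
  m <- fitSurrogate(ds, gamma = 10, C = 100, epsilon = 0.0025)
  Vt <- matrix(runif(40), 40, 1)
  pred <- predictSurrogate(m, Vt, clamp = FALSE)
  expect_lt(mean((pred - 0.5 * Vt[, 1])^2), 1e-3)
})

test_that("every fitted output satisfies the KKT conditions", {
  m <- toy_surrogate()
  kkt <- surrogateKKT(m, toy_split()$train)
  expect_true(all(kkt$dual_equality <= 1e-6))
  expect_true(all(kkt$box_violation <= 1e-9))
  expect_true(all(kkt$tube_excess <= 1e-3))
  expect_true(all(abs(m@alpha) <= m@cost + 1e-6))
})

test_that("prediction equals a direct dual-expansion oracle", {
  m <- toy_surrogate()
  sp <- toy_split()
  set.seed(14)
  idx <- sample(nrow(sp$test@V), 20)
  V <- sp$test@V[idx, , drop = FALSE]
  # independent re-implementation of the kernel expansion
  manual <- sapply(seq_along(m@bias), function(mu) {
    vapply(seq_len(nrow(V)), function(i) {
      kv <- exp(-m@gamma * colSums((t(m@SV) - V[i, ])^2))
      sum(m@alpha[, mu] * kv) + m@bias[mu]
    }, numeric(1))
  })
  pred <- predictSurrogate(m, V, clamp = FALSE)
  expect_lt(max(abs(manual - pred)), 1e-10)
})

test_that("predictions agree with an independently solved QP", {
  skip_if_not_installed("e1071")
  sp <- toy_split()
  # both solvers tightly converged so the unique QP optimum is compared
  m <- fitSurrogate(sp$train, tol = 1e-8)
  spread <- apply(sp$train@Y, 2, function(y) max(y) - min(y))
  for (mu in order(spread, decreasing = TRUE)[1:3]) {
    ref <- e1071::svm(sp$train@V, sp$train@Y[, mu],
                      type = "eps-regression", kernel = "radial",
                      gamma = m@gamma, cost = m@cost,
                      epsilon = m@epsilon, scale = FALSE,
                      tolerance = 1e-8)
    p_ref <- as.numeric(predict(ref, sp$test@V))
    p_own <- predictSurrogate(m, sp$test@V, clamp = FALSE)[, mu]
    expect_lt(max(abs(p_ref - p_own)), 1e-4)
  }
})

test_that("non-bound support vectors sit on the tube boundary", {
  m <- toy_surrogate()
  tr <- toy_split()$train
  pred <- predictSurrogate(m, tr@V, clamp = FALSE)
  svRows <- m@meta$sv_rows
  for (mu in seq_along(m@bias)) {
    a <- m@alpha[, mu]
    nb <- which(a != 0 & abs(a) < m@cost * (1 - 1e-6))
    if (!length(nb)) next
    resid <- abs(tr@Y[svRows[nb], mu] - pred[svRows[nb], mu])
    expect_true(all(resid <= m@epsilon + 1e-3))
  }
})

test_that("accuracy counts test samples under the per-sample MSE threshold", {
  ds <- toy_dataset()
  m <- toy_surrogate()
  # a perfect model scores 100%
  perfect <- function(D) {
    pred <- D@Y
    100 * mean(rowMeans((pred - D@Y)^2) < 0.05)
  }
  expect_identical(perfect(ds), 100)
  # an all-zero model against constant 0.5 targets has MSE 0.25 > 0.05
  zeroModel <- new("SurrogateModel", SV = matrix(0, 0, ncol(ds@V)),
                   alpha = matrix(0, 0, ncol(ds@Y)),
                   bias = rep(0, ncol(ds@Y)), gamma = 10, cost = 100,
                   epsilon = 0.0025,
                   outputNames = colnames(ds@Y), meta = list())
  half <- new("WindowDataset", V = ds@V, Y = matrix(0.5, nrow(ds@Y),
                                                    ncol(ds@Y)),
              tau = ds@tau, dims = ds@dims, meta = ds@meta)
  expect_identical(as.numeric(surrogateAccuracy(zeroModel, half)), 0)
  # the fitted toy surrogate generalizes on held-out windows
  acc <- surrogateAccuracy(m, toy_split()$test)
  expect_gte(as.numeric(acc), 95)
  expect_error(surrogateAccuracy(m, new("WindowDataset",
                                        V = ds@V[0, , drop = FALSE],
                                        Y = ds@Y[0, , drop = FALSE],
                                        tau = ds@tau, dims = ds@dims,
                                        meta = list())),
               "empty test set")
})

test_that("prediction clamping is applied and reported", {
  m <- toy_surrogate()
  V <- toy_split()$test@V
  raw <- predictSurrogate(m, V, clamp = FALSE)
  cl <- predictSurrogate(m, V, clamp = TRUE)
  expect_true(all(cl >= 0 & cl <= 1))
  expect_identical(attr(cl, "clamped"), sum(raw < 0 | raw > 1))
})

test_that("surrogate archives round-trip", {
  m <- toy_surrogate()
  dir <- withr::local_tempdir()
  saveSurrogate(m, dir)
  back <- loadSurrogate(dir)
  expect_equal(back@SV, m@SV, tolerance = 1e-12)
  expect_equal(back@alpha, m@alpha, tolerance = 1e-12)
  expect_equal(back@bias, m@bias, tolerance = 1e-12)
  V <- toy_split()$test@V[1:5, ]
  expect_equal(predictSurrogate(back, V), predictSurrogate(m, V),
               tolerance = 1e-10)
})
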