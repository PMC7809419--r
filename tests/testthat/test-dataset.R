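test_that("window dimension follows the sliding-window arithmetic", {
  expect_identical(windowDimension(19, 37, 29, 41, 27), 4713L)
  expect_identical(windowDimension(0, 37, 29, 41, 27), 134L)
  expect_identical(windowDimension(1, 37, 29, 41, 27), 375L)
  # property: matches independent arithmetic for arbitrary counts
  set.seed(2)
  for (i in 1:50) {
    v <- sample.int(40, 5)
    tau <- v[1]; p <- v[2]; s <- v[3]; m <- v[4]; cc <- v[5]
    blocks <- tau * (2 * (p + s + m) + cc)      # tau past (in, out) pairs
    expect_identical(windowDimension(tau, p, s, m, cc),
                     as.integer(blocks + p + s + m + cc))
  }
  expect_error(windowDimension(-1, 1, 1, 1, 1), "non-negative")
})

test_that("window extraction orders blocks oldest-to-newest and round-trips", {
  set.seed(6)
  nio <- 9; nout <- 6; tau <- 3
  inputs <- matrix(runif(10 * nio), 10, nio)
  outputs <- matrix(runif(10 * nout), 10, nout)
  w <- rollWindow(inputs, outputs, theta = 7, tau = tau)
  expect_length(w$v, tau * (nio + nout) + nio)
  expect_identical(w$target, unname(outputs[7, ]))
  # explicit layout: ages tau..1 then the current input
  expect_identical(w$v,
                   c(inputs[4, ], outputs[4, ], inputs[5, ], outputs[5, ],
                     inputs[6, ], outputs[6, ], inputs[7, ]),
                   ignore_attr = TRUE)
  # slicing the vector back reproduces the recorded history rows exactly
  parts <- pathMPC:::.unrollWindow(w$v, tau,
                                   c(p = 2L, s = 2L, m = 2L, c = 3L))
  expect_equal(parts$inputs, inputs[4:7, ], ignore_attr = TRUE)
  expect_equal(parts$outputs, outputs[4:6, ], ignore_attr = TRUE)
  # tau = 0: the window is the current input alone
  w0 <- rollWindow(inputs, outputs, theta = 5, tau = 0)
  expect_identical(w0$v, unname(inputs[5, ]))
  expect_error(rollWindow(inputs, outputs, theta = 3, tau = 3),
               "insufficient history")
})

test_that("dataset generation is deterministic and dimensioned", {
  pl <- toy_plant()
  k <- speciesCounts(pl@network)
  a <- generateDataset(pl, phi = 30, tau = 3, seed = 9)
  b <- generateDataset(pl, phi = 30, tau = 3, seed = 9)
  expect_identical(a@V, b@V)
  expect_identical(a@Y, b@Y)
  expect_identical(nrow(a@V), 30L)
  expect_identical(ncol(a@V),
                   windowDimension(3, k[["p"]], k[["s"]], k[["m"]],
                                   k[["c"]]))
  expect_false(isTRUE(all.equal(a@V,
                                generateDataset(pl, 30, 3, seed = 10)@V)))
  expect_true(validObject(a))
  # all recorded values live in the unit box
  expect_true(all(a@V >= 0 & a@V <= 1))
  expect_true(all(a@Y >= 0 & a@Y <= 1))
})

test_that("segmented and state-excited generation keeps windows consistent", {
  pl <- toy_plant()
  ds <- generateDataset(pl, phi = 24, tau = 2, seed = 3, segments = 3,
                        stateJitter = 0.2, stateJitterProb = 1)
  expect_identical(nrow(ds@V), 24L)
  # within each window, the recorded past outputs must reproduce the
  # plant's response to the recorded past inputs (self-consistency)
  parts <- pathMPC:::.unrollWindow(ds@V[5, ], 2L, ds@dims)
  for (a in 1:2) {
    out <- plantStep(pl, parts$inputs[a, ])
    expect_equal(unname(out), parts$outputs[a, ], tolerance = 1e-8,
                 ignore_attr = TRUE)
  }
  expect_equal(unname(plantStep(pl, parts$inputs[3, ])),
               unname(ds@Y[5, ]), tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("the train/test split is a seeded partition with the documented sizes", {
  ds <- toy_dataset()
  sp <- splitDataset(ds, 0.65, seed = 1)
  expect_identical(nrow(sp$train@V), 52L)   # floor(80 * 0.65)
  expect_identical(nrow(sp$test@V), 28L)
  sp2 <- splitDataset(ds, 0.65, seed = 1)
  expect_identical(sp$train@V, sp2$train@V)
  # partition: every sample lands in exactly one part
  key <- function(M) apply(M, 1, function(r) paste(signif(r, 12),
                                                   collapse = ","))
  all_keys <- key(ds@V)
  expect_setequal(c(key(sp$train@V), key(sp$test@V)), all_keys)
  expect_length(intersect(key(sp$train@V), key(sp$test@V)), 0)
  # 90:10 on ten samples
  small <- splitDataset(new("WindowDataset", V = ds@V[1:10, ],
                            Y = ds@Y[1:10, ], tau = ds@tau,
                            dims = ds@dims, meta = ds@meta), 0.9, seed = 2)
  expect_identical(nrow(small$train@V), 9L)
  expect_identical(nrow(small$test@V), 1L)
})

test_that("dataset archives round-trip through the columnar format", {
  ds <- toy_dataset()
  dir <- withr::local_tempdir()
  saveDataset(ds, dir)
  back <- loadDataset(dir)
  expect_equal(back@V, ds@V, tolerance = 1e-12)
  expect_equal(back@Y, ds@Y, tolerance = 1e-12, ignore_attr = TRUE)
  expect_identical(back@tau, ds@tau)
  expect_identical(back@dims, ds@dims)
})
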