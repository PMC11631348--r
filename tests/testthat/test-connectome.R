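test_that("Fisher-z FC matches the atanh closed form", {
  # construct two series with exact correlation 0.5 via Gram-Schmidt
  set.seed(1)
  a <- scale(rnorm(200))[, 1]
  b0 <- scale(residuals(lm(rnorm(200) ~ a)))[, 1]
  b <- 0.5 * a + sqrt(1 - 0.25) * b0
  ts <- rbind(a, b, rnorm(200))
  z <- timeseriesToFC(ts)
  expect_equal(z[1, 2], 0.54931, tolerance = 1e-5)
  expect_equal(z, t(z))
  # orthogonal series: z = 0
  ts0 <- rbind(a, b0, rnorm(200))
  expect_equal(timeseriesToFC(ts0)[1, 2], 0, tolerance = 1e-12)
})

test_that("degenerate correlations are clipped with a warning", {
  a <- rnorm(50)
  ts <- rbind(a, a, rnorm(50))
  expect_warning(z <- timeseriesToFC(ts), "clipped")
  expect_true(is.finite(z[1, 2]))
  expect_equal(z[1, 2], atanh(1 - 1e-7))
  expect_error(timeseriesToFC(rbind(a, rep(1, 50))), "constant")
  expect_error(timeseriesToFC(matrix(rnorm(4), 2)), "3 time points")
})

test_that("the Fisher transform is odd in r", {
  set.seed(2)
  r <- runif(50, -0.99, 0.99)
  expect_equal(atanh(-r), -atanh(r))
})

test_that("phase-run averaging is the elementwise mean on the z scale", {
  m1 <- matrix(0.2, 3, 3); diag(m1) <- 0
  m2 <- matrix(0.6, 3, 3); diag(m2) <- 0
  avg <- averagePhaseRuns(m1, m2)
  expect_equal(avg[1, 2], 0.4)
  expect_equal(averagePhaseRuns(m1, m1), m1)
  # averaging commutes with edge vectorization
  expect_equal(matrixToEdges(avg),
               averagePhaseRuns(matrixToEdges(m1), matrixToEdges(m2)))
  expect_error(averagePhaseRuns(m1, matrix(0, 4, 4)), "identical shape")
})

test_that("latent FC recovers a common factor across states", {
  set.seed(3)
  n <- 2000
  nStates <- 6
  nE <- 25
  common <- matrix(rnorm(nE * n), nE, n)
  arr <- array(NA_real_, c(nE, nStates, n),
               dimnames = list(NULL, paste0("s", 1:6), NULL))
  for (s in 1:nStates)
    arr[, s, ] <- 0.8 * common + sqrt(1 - 0.64) * matrix(rnorm(nE * n),
                                                         nE, n)
  fit <- latentFC(arr, states = paste0("s", 1:6))
  expect_lt(abs(mean(abs(fit$loadings)) - 0.8), 0.05)
  recov <- sapply(seq_len(nE), function(e) cor(fit$scores[e, ], common[e, ]))
  expect_gt(mean(abs(recov)), 0.9)
})

test_that("a pure-noise state gets a near-zero loading", {
  set.seed(4)
  n <- 2000
  nE <- 15
  common <- matrix(rnorm(nE * n), nE, n)
  arr <- array(NA_real_, c(nE, 4, n),
               dimnames = list(NULL, c("a", "b", "c", "noise"), NULL))
  for (s in 1:3) arr[, s, ] <- 0.8 * common +
      0.6 * matrix(rnorm(nE * n), nE, n)
  arr[, 4, ] <- matrix(rnorm(nE * n), nE, n)
  fit <- latentFC(arr, states = c("a", "b", "c", "noise"))
  expect_lt(mean(abs(fit$loadings[, "noise"])), 0.05)
  expect_gt(mean(fit$loadings[, "a"]), 0.7)
})

test_that("latent scores follow a perfect common factor and ignore state order", {
  set.seed(5)
  n <- 120
  nE <- 6
  shared <- matrix(rnorm(nE * n), nE, n)
  arr <- array(NA_real_, c(nE, 3, n),
               dimnames = list(NULL, c("x", "y", "z"), NULL))
  for (s in 1:3) arr[, s, ] <- shared
  fit <- latentFC(arr, states = c("x", "y", "z"))
  for (e in seq_len(nE))
    expect_equal(abs(cor(fit$scores[e, ], shared[e, ])), 1,
                 tolerance = 1e-8)
  # invariance to state relabeling/order
  fit2 <- latentFC(arr[, c(3, 1, 2), , drop = FALSE],
                   states = c("z", "x", "y"))
  expect_equal(fit2$scores, fit$scores, tolerance = 1e-8)
})

test_that("retest ICC matches its variance-components oracle", {
  set.seed(6)
  n <- 1000
  truth <- matrix(rnorm(30 * n), 30, n)
  r1 <- truth + matrix(rnorm(30 * n), 30, n)
  r2 <- truth + matrix(rnorm(30 * n), 30, n)
  icc <- iccRetest(r1, r2)
  expect_lt(abs(mean(icc) - 0.5), 0.05)   # 1:1 variance ratio
  expect_equal(iccRetest(r1, r1), rep(1, 30), tolerance = 1e-10)
  rA <- matrix(rnorm(30 * n), 30, n)
  rB <- matrix(rnorm(30 * n), 30, n)
  expect_lt(abs(mean(iccRetest(rA, rB))), 0.05)  # independent runs
  expect_warning(iccRetest(matrix(1, 1, 10), matrix(1, 1, 10)),
                 "zero between-subject")
})

test_that("latent states can be appended to a ConnectomeSet", {
  cset <- smallStudy(6, nNodes = 10, nSubjects = 80,
                     nRelevant = 5, blockSize = 5,
                     states = c(rest = 0.5, a = 1, b = 1, c = 0.8))
  cset2 <- appendLatentStates(cset)
  expect_true(all(c("latent", "latent_task") %in% states(cset2)))
  expect_identical(nEdges(cset2), nEdges(cset))
})
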