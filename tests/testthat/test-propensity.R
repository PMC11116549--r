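# Multinomial propensity model, IP weighting, balance diagnostics.

test_that("intercept-only fit reproduces the study arm shares exactly", {
  counts <- c(6155, 1446, 3912, 1231)
  A <- rep(0:3, counts)
  mat <- raw_matrix(Y = rep(1, sum(counts)), A = A,
                    L = matrix(1, sum(counts), 1,
                               dimnames = list(NULL, "(Intercept)")))
  fit <- fit_multinomial(mat)
  p <- predict_probs(fit, mat$L)[1, ]
  expect_equal(unname(p), counts / sum(counts), tolerance = 1e-9)
})

test_that("saturated fit recovers within-stratum arm shares", {
  # 40-row toy: binary covariate, known conditional arm counts
  x <- rep(c(0, 1), each = 20)
  A <- c(rep(0:3, c(8, 4, 6, 2)), rep(0:3, c(4, 6, 2, 8)))
  L <- cbind("(Intercept)" = 1, x = x)
  mat <- raw_matrix(Y = rep(1, 40), A = A, L = L)
  fit <- fit_multinomial(mat)
  p <- predict_probs(fit, L)
  expect_equal(unname(p[1, ]), c(8, 4, 6, 2) / 20, tolerance = 1e-7)
  expect_equal(unname(p[40, ]), c(4, 6, 2, 8) / 20, tolerance = 1e-7)
})

test_that("fit matches the reference multinomial implementation", {
  skip_if_not_installed("nnet")
  co <- generate_cohort(benchmark_spec(2000, seed = 21))
  mat <- analysis_matrix(co)
  fit <- fit_multinomial(mat)
  ref <- nnet::multinom(A ~ L - 1, data = list(A = factor(mat$A), L = mat$L),
                        trace = FALSE, reltol = 1e-14, maxit = 500)
  expect_equal(unname(t(coef(ref))), unname(fit$betas), tolerance = 1e-4)
  pref <- predict(ref, type = "probs")
  expect_equal(unname(predict_probs(fit, mat$L)), unname(pref),
               tolerance = 1e-5)
})

test_that("refit on permuted rows returns identical coefficients", {
  co <- generate_cohort(benchmark_spec(1200, seed = 22))
  mat <- analysis_matrix(co)
  fit <- fit_multinomial(mat)
  perm <- sample(nrow(co))
  mat2 <- analysis_matrix(co[perm, ])
  fit2 <- fit_multinomial(mat2)
  expect_equal(fit$betas, fit2$betas, tolerance = 1e-8)
})

test_that("probability predictions are normalized and match hand softmax", {
  L <- matrix(1, 5, 1, dimnames = list(NULL, "(Intercept)"))
  fit <- structure(list(betas = matrix(0, 1, 3,
                                       dimnames = list("(Intercept)",
                                                       c("t1", "t2", "t3")))),
                   class = "propensity_fit")
  expect_equal(unname(predict_probs(fit, L)),
               matrix(0.25, 5, 4), tolerance = 1e-15)
  # intercepts (ln 2, ln 1, ln 1) -> (0.2, 0.4, 0.2, 0.2)
  fit$betas[1, ] <- c(log(2), 0, 0)
  expect_equal(unname(predict_probs(fit, L)[1, ]), c(0.2, 0.4, 0.2, 0.2),
               tolerance = 1e-12)
  # softmax limit: large coefficient sends the row to (0, 1, 0, 0)
  for (b in c(5, 10, 20)) {
    fit$betas[1, ] <- c(b, 0, 0)
    p <- predict_probs(fit, L)[1, ]
    expect_equal(sum(p), 1, tolerance = 1e-12)
  }
  fit$betas[1, ] <- c(500, 0, 0)
  expect_equal(unname(predict_probs(fit, L)[1, ]), c(0, 1, 0, 0),
               tolerance = 1e-12)
  # misaligned columns are an encoding error
  Lbad <- matrix(1, 5, 1, dimnames = list(NULL, "x"))
  expect_error(predict_probs(fit, Lbad), "encoding")
})

test_that("rows of fitted probabilities always sum to one", {
  co <- generate_cohort(benchmark_spec(1500, seed = 23))
  mat <- analysis_matrix(co)
  p <- predict_probs(fit_multinomial(mat), mat$L)
  expect_lt(max(abs(rowSums(p) - 1)), 1e-10)
  expect_true(all(p >= 0))
})

test_that("empty arms and rank deficiency are estimation errors", {
  mat <- raw_matrix(Y = rep(1, 30), A = rep(c(0, 1, 2), 10),
                    L = matrix(1, 30, 1, dimnames = list(NULL, "(Intercept)")))
  expect_error(fit_multinomial(mat), "empty treatment arm")
  L2 <- cbind("(Intercept)" = 1, a = rep(1, 40), b = rep(2, 40))
  mat2 <- raw_matrix(Y = rep(1, 40), A = rep(0:3, 10), L = L2)
  expect_error(fit_multinomial(mat2), "rank deficient")
})

test_that("HT means: randomized design, saturated reduction, zero outcome", {
  # known pi = 0.25 in every arm, Y = 1
  A <- rep(0:3, c(10, 6, 9, 5))
  n <- length(A)
  mat <- raw_matrix(Y = rep(1, n), A = A,
                    L = matrix(1, n, 1, dimnames = list(NULL, "(Intercept)")))
  probs <- matrix(0.25, n, 4)
  expect_equal(unname(ht_means(mat, probs)),
               c(10, 6, 9, 5) / (0.25 * n), tolerance = 1e-12)
  # Y = 0 everywhere -> all means zero
  mat0 <- raw_matrix(Y = rep(0, n), A = A, L = mat$L)
  expect_equal(unname(ht_means(mat0, probs)), rep(0, 4))
  # saturated propensity: HT equals arm-specific sample means (8-row toy)
  x <- rep(c(0, 1), each = 4)
  A8 <- rep(0:3, 2)
  Y8 <- c(1, 0, 1, 1, 0, 1, 1, 0)
  L8 <- cbind("(Intercept)" = 1, x = x)
  mat8 <- raw_matrix(Y8, A8, L8)
  fit8 <- fit_multinomial(mat8)
  p8 <- predict_probs(fit8, L8)
  ht <- suppressWarnings(ht_means(mat8, p8))
  armmean <- vapply(0:3, function(i) mean(Y8[A8 == i]), numeric(1))
  expect_equal(unname(ht), armmean, tolerance = 1e-6)
  # exact zero probability in the received arm is a positivity error
  pbad <- p8
  pbad[1, 1] <- 0
  expect_error(ht_means(mat8, pbad), "positivity|zero fitted")
})

test_that("SMD is zero for identical arms and matches hand arithmetic unweighted", {
  # identical covariate values in every arm
  x <- rep(c(0, 1, 1), 4)
  A <- rep(0:3, each = 3)
  mat <- raw_matrix(Y = rep(1, 12), A = A,
                    L = cbind("(Intercept)" = 1, x = x))
  bal <- smd_balance(mat, weights = rep(1, 12))
  expect_true(all(abs(as.matrix(bal[, -1])) < 1e-12))

  # 6-row confounded toy, unweighted: arms 0 and 1 only
  x6 <- c(1, 1, 0, 1, 0, 0)
  A6 <- c(0, 0, 0, 1, 1, 2)
  # pad arms 2,3 so the pair structure exists
  x6 <- c(x6, 0, 1)
  A6 <- c(A6, 3, 3)
  mat6 <- raw_matrix(Y = rep(1, 8), A = A6,
                     L = cbind("(Intercept)" = 1, x = x6))
  bal6 <- smd_balance(mat6, weights = rep(1, 8))
  m0 <- mean(c(1, 1, 0)); v0 <- mean((c(1, 1, 0) - m0)^2)
  m1 <- mean(c(1, 0)); v1 <- mean((c(1, 0) - m1)^2)
  hand <- (m0 - m1) / sqrt((v0 + v1) / 2)
  expect_equal(bal6[["0_vs_1"]], hand, tolerance = 1e-12)

  # zero pooled SD: equal constant means -> 0
  xc <- rep(1, 8)
  matc <- raw_matrix(Y = rep(1, 8), A = A6,
                     L = cbind("(Intercept)" = 1, x = xc))
  balc <- smd_balance(matc, weights = rep(1, 8))
  expect_true(all(balc[, -1] == 0))
})

test_that("IP weighting balances covariates when assignment is independent of L", {
  spec <- cohort_spec(
    n_patients = 20000,
    factors = list(g = c(a = 0.5, b = 0.3, c = 0.2)),
    flags = c(f = 0.4),
    treatment_coefs = list(t1 = c("(Intercept)" = -1),
                           t2 = c("(Intercept)" = -0.3),
                           t3 = c("(Intercept)" = -1.2)),
    outcome_coefs = list(alpha1 = c("(Intercept)" = 1), alpha2 = c(0, 0.2, 0.4)),
    seed = 31)
  co <- generate_cohort(spec)
  mat <- analysis_matrix(co)
  fit <- fit_multinomial(mat)
  probs <- predict_probs(fit, mat$L)
  ht <- ht_means(mat, probs)
  armmean <- vapply(0:3, function(i) mean(mat$Y[mat$A == i]), numeric(1))
  counts <- tabulate(mat$A + 1L, 4)
  se <- sqrt(armmean * (1 - armmean) / counts)
  expect_true(all(abs(ht - armmean) < 3 * pmax(se, 0.005)))
})
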