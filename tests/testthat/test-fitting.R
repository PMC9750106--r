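test_that("maximum-weight branching matches brute-force enumeration", {
  set.seed(31)
  for (k in 1:20) {
    n <- sample(3:5, 1)
    W <- matrix(rnorm(n * n), n, n)
    par <- max_weight_branching(W, root = 1L)
    oracle <- brute_force_branching(W)
    expect_equal(branching_weight(W, par), oracle$weight, tolerance = 1e-12)
  }
})

test_that("fit_ot recovers generating trees and Bernoulli parameters", {
  # structure recovery from a 2-edge OT
  ot <- ot_two_edge(0.8, 0.5)
  d <- sample_genotypes(untimed_distribution(ot), 1e4, seed = 42)
  f <- fit_ot(d)
  expect_identical(f$model$parents$A, character(0))
  expect_identical(f$model$parents$B, "A")
  expect_equal(unname(coef(f)), c(0.8, 0.5), tolerance = 0.03)

  # single event present in ~30% of rows
  one <- matrix(c(rep(1L, 300), rep(0L, 700)), ncol = 1,
                dimnames = list(NULL, "E"))
  f1 <- fit_ot(one)
  expect_identical(f1$model$parents$E, character(0))
  expect_equal(unname(coef(f1)), 0.3, tolerance = 0.02)

  # perfectly nested events: B under A, not under root
  nested <- cbind(A = rep(c(1L, 1L, 0L), c(30, 30, 40)),
                  B = rep(c(1L, 0L, 0L), c(30, 30, 40)))
  fn <- fit_ot(nested)
  expect_identical(fn$model$parents$B, "A")

  # constant columns are rejected with advice
  bad <- cbind(A = rep(1L, 10), B = rep(c(0L, 1L), 5))
  expect_error(fit_ot(bad), "remove")
})

test_that("fit_ot is idempotent: refitting its own samples returns the tree", {
  ot <- random_dag_model("OT", 4, seed = 51)
  d <- sample_genotypes(untimed_distribution(ot), 1e4, seed = 52)
  f1 <- fit_ot(d)
  d2 <- sample_genotypes(untimed_distribution(f1$model), 1e4, seed = 53)
  f2 <- fit_ot(d2)
  expect_identical(f1$model$parents, f2$model$parents)
})

test_that("fit_mhn solves the one-event closed form and recovers theta = 0", {
  # single event: theta = log(f / (1 - f)) exactly
  one <- matrix(c(rep(1L, 300), rep(0L, 700)), ncol = 1,
                dimnames = list(NULL, "E"))
  f1 <- fit_mhn(one, lambda_penalty = 0)
  expect_equal(unname(coef(f1)[1, 1]), log(0.3 / 0.7), tolerance = 1e-3)

  # n = 3, independent unit rates: off-diagonals shrink below 0.1
  m0 <- mhn_model(matrix(0, 3, 3))
  d <- sample_genotypes(observation_distribution(m0), 1e4, seed = 61)
  f <- fit_mhn(d, lambda_penalty = 0.01)
  th <- coef(f)
  expect_lt(max(abs(th[row(th) != col(th)])), 0.1)
  expect_true(f$diagnostics$converged)

  # penalty limit: a huge L1 penalty zeroes all off-diagonals
  fbig <- fit_mhn(d, lambda_penalty = 1e6)
  thb <- coef(fbig)
  expect_equal(max(abs(thb[row(thb) != col(thb)])), 0)

  # accepted iterates never increase the penalised objective
  expect_true(all(diff(f$diagnostics$objective_trace) <= 1e-12))
})

test_that("the analytic MHN gradient matches finite differences", {
  set.seed(71)
  n <- 3
  th <- matrix(rnorm(n * n, 0, 0.5), n, n)
  counts <- rmultinom(1, 500, rep(1 / 2^n, 2^n))[, 1]
  g <- evoaccum:::.mhn_dp(th, 1, counts = counts, gradient = TRUE)$grad
  num <- matrix(0, n, n)
  ll <- function(t) sum(counts * log(evoaccum:::.mhn_dp(t, 1)$p))
  for (j in 1:n) for (i in 1:n) {
    e <- 1e-6
    tp <- th; tp[j, i] <- tp[j, i] + e
    tm <- th; tm[j, i] <- tm[j, i] - e
    num[j, i] <- (ll(tp) - ll(tm)) / (2 * e)
  }
  expect_equal(g, num, tolerance = 1e-4)
})

test_that("fit_cbn_rates recovers rates and the single-event closed form", {
  # single event with frequency f: lambda = f / (1 - f)
  one <- matrix(c(rep(1L, 400), rep(0L, 600)), ncol = 1,
                dimnames = list(NULL, "E"))
  dag1 <- restriction_dag("CBN", "E", param = c(E = 1))
  fc1 <- fit_cbn_rates(one, dag1, epsilon = 0)
  expect_equal(unname(coef(fc1)), 0.4 / 0.6, tolerance = 1e-4)

  # AND worked example: rates recovered within 15%
  cbn <- cbn_and_example()
  d <- sample_genotypes(observation_distribution(cbn), 1e4, seed = 81)
  fc <- fit_cbn_rates(d, cbn)
  expect_true(all(abs(coef(fc) - 1) < 0.15))
  expect_error(fit_cbn_rates(d[, c(2, 1, 3)], cbn), "match")
})

test_that("empty-DAG CBN and diagonal-only MHN give the same fit", {
  m0 <- mhn_model(diag(c(0.4, -0.7)), c("A", "B"))
  d <- sample_genotypes(observation_distribution(m0), 5e3, seed = 91)
  cbn0 <- restriction_dag("CBN", c("A", "B"), param = c(A = 1, B = 1))
  fc <- fit_cbn_rates(d, cbn0, epsilon = 0)
  fm <- fit_mhn(d, lambda_penalty = 0, diagonal_only = TRUE)
  expect_equal(unname(coef(fc)), unname(exp(diag(coef(fm)))),
               tolerance = 1e-3)
})

test_that("reported log-likelihoods are reproducible through the prediction path", {
  ot <- ot_two_edge()
  d <- sample_genotypes(untimed_distribution(ot), 2e3, seed = 95)
  f <- fit_ot(d)
  expect_equal(f$log_likelihood, model_log_likelihood(f$model, d),
               tolerance = 1e-6)

  m0 <- mhn_model(matrix(0, 2, 2))
  dm <- sample_genotypes(observation_distribution(m0), 2e3, seed = 96)
  fm <- fit_mhn(dm, lambda_penalty = 0.1)
  expect_equal(fm$log_likelihood, model_log_likelihood(fm$model, dm),
               tolerance = 1e-6)

  cbn <- cbn_two_independent(1, 1)
  dc <- sample_genotypes(observation_distribution(cbn), 2e3, seed = 97)
  fcb <- fit_cbn_rates(dc, cbn, epsilon = 0.001)
  expect_equal(fcb$log_likelihood,
               model_log_likelihood(fcb$model, dc, epsilon = 0.001),
               tolerance = 1e-6)
})

test_that("fit objects expose the standard modelling methods", {
  d <- sample_genotypes(untimed_distribution(ot_two_edge()), 500, seed = 99)
  f <- fit_ot(d)
  expect_s3_class(predict(f), "genotype_distribution")
  expect_identical(dim(simulate(f, nsim = 20, seed = 1)), c(20L, 2L))
  ll <- logLik(f)
  expect_s3_class(ll, "logLik")
  expect_identical(attr(ll, "nobs"), 500L)
  expect_output(print(f), "Fitted OT model")
  expect_output(summary(f), "genotype counts")
})
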