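test_that("gain_rate follows the multiplicative-hazard and AND semantics", {
  mhn <- mhn_model(matrix(c(log(2), 0, log(3), 0), 2, 2, byrow = TRUE))
  # rate of event 2 from {1}: exp(theta_22) * exp(theta_21) = 1 * 3
  expect_equal(gain_rate(mhn, "E1", "E2"), 3)
  expect_equal(gain_rate(mhn, character(0), "E1"), 2)

  # all-zero theta: every rate is 1 (empty product)
  z <- mhn_model(matrix(0, 3, 3))
  for (ev in z$events) expect_equal(gain_rate(z, character(0), ev), 1)

  # CBN AND: C has rate 0 until both parents are present
  cbn <- cbn_and_example()
  expect_equal(gain_rate(cbn, "A", "C"), 0)
  expect_equal(gain_rate(cbn, c("A", "B"), "C"), 1)

  # untimed families have no rates
  expect_error(gain_rate(ot_two_edge(), character(0), "A"), "untimed")
  expect_error(gain_rate(cbn, "A", "A"), "already present")
})

test_that("rate_matrix assembles the generator with zero row sums", {
  rm2 <- rate_matrix(cbn_two_independent(2, 1))
  expect_equal(rm2$Q["WT", "E1"], 2)
  expect_equal(rm2$Q["WT", "E2"], 1)
  expect_equal(rm2$Q["WT", "WT"], -3)
  expect_equal(max(abs(rowSums(rm2$Q))), 0, tolerance = 1e-12)

  # MHN all-zero theta, n = 3: WT row has three unit rates
  rm3 <- rate_matrix(mhn_model(matrix(0, 3, 3)))
  expect_equal(unname(sort(rm3$Q["WT", ])[1:5]), c(-3, 0, 0, 0, 0))
  expect_equal(sum(rm3$Q["WT", ] == 1), 3L)

  # transitions add exactly one event
  for (i in seq_along(rm3$masks)) for (j in seq_along(rm3$masks))
    if (i != j && rm3$Q[i, j] != 0) {
      d <- bitwXor(rm3$masks[i], rm3$masks[j])
      expect_true(bitwAnd(rm3$masks[j], d) == d && sum(d == 2^(0:2)) == 1)
    }
})

test_that("jump chain uses competing-risks normalisation with zero absorbing rows", {
  tm <- transition_matrix(rate_matrix(cbn_two_independent(2, 1)))
  expect_equal(tm$P["WT", "E1"], 2 / 3)
  expect_equal(tm$P["WT", "E2"], 1 / 3)
  # one available event -> probability 1
  expect_equal(tm$P["E1", "E1, E2"], 1)
  # full genotype is absorbing: all-zero row
  expect_equal(unname(tm$P["E1, E2", ]), rep(0, 4))
})

test_that("observation_distribution reproduces the closed-form worked examples", {
  d1 <- observation_distribution(cbn_two_independent(1, 1))
  expect_equal(d1$probability, c(1/3, 1/6, 1/6, 1/3), tolerance = 1e-12)

  d2 <- observation_distribution(cbn_two_independent(2, 1))
  expect_equal(d2$probability, c(1/4, 1/4, 1/12, 5/12), tolerance = 1e-12)

  d3 <- observation_distribution(cbn_and_example())
  expect_equal(d3$probability, c(1/3, 1/6, 1/6, 1/6, 1/6), tolerance = 1e-12)
  expect_identical(d3$genotype, c("WT", "A", "B", "A, B", "A, B, C"))
})

test_that("lattice DP and linear-system solution agree on random models", {
  for (k in 1:25) {
    fam <- c("CBN", "HESBCN", "MHN")[(k %% 3) + 1L]
    m <- random_any_model(fam, n = 2L + (k %% 5L), seed = 100 + k)
    s <- c(0.5, 1, 2)[(k %% 3) + 1L]
    a <- observation_distribution(m, s, method = "dp")
    b <- observation_distribution(m, s, method = "linear")
    expect_equal(sum(a$probability), 1, tolerance = 1e-9)
    expect_equal(a$probability, b$probability, tolerance = 1e-9)
  }
})

test_that("rescaling all rates and the sampling rate leaves the distribution unchanged", {
  for (k in 1:5) {
    m <- random_dag_model("CBN", 4, seed = 200 + k)
    c_scale <- exp(runif(1, -2, 2))
    m2 <- m
    m2$param <- m$param * c_scale
    a <- observation_distribution(m, sampling_rate = 1)
    b <- observation_distribution(m2, sampling_rate = c_scale)
    expect_equal(a$probability, b$probability, tolerance = 1e-9)
  }
  mh <- random_mhn(3, seed = 17)
  mh2 <- mh
  c_scale <- 3.7
  mh2$theta <- mh$theta
  diag(mh2$theta) <- diag(mh$theta) + log(c_scale)
  expect_equal(observation_distribution(mh)$probability,
               observation_distribution(mh2, sampling_rate = c_scale)$probability,
               tolerance = 1e-9)
})

test_that("diagonal MHN is distribution-identical to an edgeless CBN", {
  th <- c(-0.5, 0.3, 1.1)
  mhn <- mhn_model(diag(th), c("A", "B", "C"))
  cbn <- restriction_dag("CBN", c("A", "B", "C"),
                         param = setNames(exp(th), c("A", "B", "C")))
  expect_equal(observation_distribution(mhn)$probability,
               observation_distribution(cbn)$probability, tolerance = 1e-9)
})

test_that("untimed families are rejected by the CTMC engine", {
  expect_error(rate_matrix(ot_two_edge()), "untimed")
  expect_error(observation_distribution(oncobn_or_example()), "untimed")
})
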