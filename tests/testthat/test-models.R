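test_that("LG rate matrix is a normalized reversible generator", {
  m <- lg_model()
  Q <- m$rate_matrix
  expect_equal(dim(Q), c(20L, 20L))
  expect_lt(max(abs(rowSums(Q))), 1e-10)
  expect_equal(-sum(m$frequencies * diag(Q)), 1, tolerance = 1e-10)
  expect_equal(sum(m$frequencies), 1, tolerance = 1e-12)
  # detailed balance: pi_i Q_ij == pi_j Q_ji
  flux <- m$frequencies * Q
  expect_lt(max(abs(flux - t(flux))), 1e-12)
  # first published LG exchangeability (A<->R)
  expect_equal(m$exchangeabilities[2, 1], 0.425093, tolerance = 1e-9)
})

test_that("stationary frequencies are preserved under the matrix exponential", {
  m <- lg_model()
  P <- as.matrix(Matrix::expm(m$rate_matrix * 1.7))
  expect_equal(as.numeric(m$frequencies %*% P), unname(m$frequencies),
               tolerance = 1e-10)
  # spectral transition probabilities agree with the dense exponential
  expect_equal(transition_prob(m, 1.7), unname(P), tolerance = 1e-10,
               ignore_attr = TRUE)
})

test_that("discrete gamma has mean one and collapses as alpha grows", {
  g <- discrete_gamma(0.5, 8)
  expect_length(g$rates, 8)
  expect_equal(sum(g$weights * g$rates), 1, tolerance = 1e-6)
  expect_true(all(diff(g$rates) > 0))
  # At alpha = 1000 the gamma sd is 1/sqrt(1000) ~ 0.032 and the extreme
  # slice means sit at ~1.65 sd, so under the mean-of-slice convention the
  # largest deviation is ~0.052 exactly; 0.06 bounds it with margin.
  g_flat <- discrete_gamma(1000, 8)
  expect_true(all(abs(g_flat$rates - 1) < 0.06))
  expect_true(all(abs(discrete_gamma(1e6, 8)$rates - 1) < 0.002))
})

test_that("discrete gamma matches quadrature over quantile slices", {
  alpha <- 0.7; k <- 4
  g <- discrete_gamma(alpha, k)
  qs <- stats::qgamma(seq(0, 1, length.out = k + 1), alpha, alpha)
  oracle <- vapply(seq_len(k), function(i) {
    stats::integrate(function(x) x * stats::dgamma(x, alpha, alpha),
                     qs[i], qs[i + 1], rel.tol = 1e-10)$value * k
  }, numeric(1))
  expect_equal(g$rates, oracle, tolerance = 1e-6)
  expect_equal(g$weights, rep(1 / k, k))
})

test_that("transition probabilities behave at boundaries", {
  m <- lg_model()
  expect_equal(transition_prob(m, 0), diag(20), tolerance = 1e-12,
               ignore_attr = TRUE)
  P <- transition_prob(m, 0.5)
  expect_equal(rowSums(P), rep(1, 20), tolerance = 1e-10, ignore_attr = TRUE)
  expect_true(all(P >= 0))
  # Chapman-Kolmogorov
  expect_equal(transition_prob(m, 0.3) %*% transition_prob(m, 0.9),
               transition_prob(m, 1.2), tolerance = 1e-10)
  # long-branch limit: every row tends to the stationary distribution
  P_inf <- transition_prob(m, 10000)
  for (i in c(1, 7, 20)) {
    expect_equal(unname(P_inf[i, ]), unname(m$frequencies),
                 tolerance = 1e-4)
  }
  # rate scaling: P(t, rate = r) == P(rt, rate = 1)
  expect_equal(transition_prob(m, 0.4, rate = 2.5), transition_prob(m, 1.0),
               tolerance = 1e-12)
})

test_that("model constructors validate inputs", {
  expect_error(aa_model("bad", rep(0.05, 19), rep(1, 190)),
               "frequencies")
  expect_error(aa_model("bad", rep(0.05, 20), rep(1, 189)), "190")
  expect_error(discrete_gamma(-1, 8), "alpha")
  expect_error(discrete_gamma(1, 0), "n_categories")
  expect_error(transition_prob(lg_model(), -0.1), "branch length")
})
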