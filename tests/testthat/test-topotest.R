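model <- lg_model()
g1 <- discrete_gamma(1, 2)

test_that("KH test matches exhaustive enumeration on 4-site toys", {
  cases <- list(
    list(a = c(-1.0, -2.0, -0.5, -1.5), b = c(-2.0, -3.0, -1.5, -2.5)),
    list(a = c(-1.0, -2.2, -0.6, -1.4), b = c(-1.1, -2.0, -0.9, -1.2)),
    list(a = c(-3.0, -0.5, -2.0, -1.0), b = c(-0.5, -3.0, -1.0, -2.0))
  )
  for (cs in cases) {
    exact <- kh_exhaustive_p(cs$a, cs$b)
    # large-resample RELL estimate converges to the enumeration value
    p_hat <- kh_test(cs$a, cs$b, n_resamples = 20000, seed = 61)
    expect_lt(abs(p_hat - exact), 0.02)
  }
  # constant positive difference: reference toy from the enumeration oracle
  p <- kh_test(c(-1, -1, -1, -1), c(-2, -2, -2, -2), n_resamples = 1000,
               seed = 62)
  expect_lt(p, 0.05)
  expect_equal(kh_exhaustive_p(c(-1, -1, -1, -1), c(-2, -2, -2, -2)), 0)
})

test_that("KH boundary conventions", {
  v <- c(-1.3, -0.7, -2.1)
  expect_equal(kh_test(v, v, n_resamples = 500, seed = 63), 1)
  expect_error(kh_test(v, v[1:2]), "equal length")
  expect_error(kh_test(v, v, n_resamples = 10), ">= 100")
  # determinism
  a <- c(-1, -2.5, -0.3, -1.8); b <- c(-1.4, -2.1, -0.9, -1.1)
  expect_identical(kh_test(a, b, 500, seed = 64), kh_test(a, b, 500, seed = 64))
})

test_that("SH test conventions: ML tree maximal, identical candidates p = 1", {
  set.seed(65)
  la <- rnorm(100, -2); lb <- la - 0.05 + rnorm(100, sd = 0.2)
  expect_equal(sh_test(list(la, la), 1, 500, seed = 66), 1)
  p_best <- sh_test(list(la, lb), which.max(c(sum(la), sum(lb))), 500, seed = 66)
  expect_gte(p_best, 0.5)
})

test_that("SH dominates the like-sided KH tail", {
  # With two candidates the SH statistic max(D*, 0) >= |T| reduces to the
  # one-sided tail P(D* >= |T|), while the KH test here is two-sided
  # (P(|D*| >= |T|)), so the correct dominance relation is
  # p_SH >= p_KH / 2 (up to resampling noise); p_SH = 1 when the tested
  # tree is the ML tree.
  worse <- 0
  for (s in 1:50) {
    set.seed(700 + s)
    la <- rnorm(60, -2, 0.7)
    lb <- la - 0.02 + rnorm(60, sd = 0.3)
    p_kh <- kh_test(la, lb, 300, seed = s)
    p_sh <- sh_test(list(la, lb), 2, 300, seed = s)
    if (sum(lb) >= sum(la)) {
      if (p_sh < 1 - 1e-12) worse <- worse + 1
    } else if (p_sh < p_kh / 2 - 0.02) {
      worse <- worse + 1
    }
  }
  expect_equal(worse, 0)
})

test_that("ELW weights sum to one, split ties, and crush dominated trees", {
  set.seed(67)
  la <- rnorm(50, -2)
  elw_tie <- expected_likelihood_weights(list(la, la), 500, seed = 68)
  expect_equal(sum(elw_tie$weights), 1, tolerance = 1e-12)
  expect_equal(elw_tie$weights, c(0.5, 0.5))
  expect_true(all(elw_tie$accepted))
  # candidate worse at every site gets essentially zero weight
  lb <- la - 0.5
  elw_dom <- expected_likelihood_weights(list(la, lb), 1000, seed = 69)
  expect_lte(elw_dom$weights[2], 0.01)
  expect_true(elw_dom$accepted[1])
  expect_false(elw_dom$accepted[2])
})

test_that("classification follows the k-of-3 rule", {
  pass <- list(p_kh = 0.5, p_sh = 0.6, elw_accepted = TRUE, d_ll = 1)
  fail <- list(p_kh = 0.01, p_sh = 0.02, elw_accepted = FALSE, d_ll = 9)
  mixed <- list(p_kh = 0.5, p_sh = 0.01, elw_accepted = TRUE, d_ll = 3)
  expect_equal(classify_pair(pass, pass)$category, "(+,+)")
  expect_equal(classify_pair(pass, fail)$category, "(+,-)")
  expect_equal(classify_pair(fail, pass)$category, "(+,-)")
  expect_equal(classify_pair(fail, fail)$category, "(-,-)")
  expect_equal(classify_pair(mixed, fail)$category, "(-,-)")
  expect_equal(classify_pair(mixed, fail, min_criteria = 2)$category, "(+,-)")
})

test_that("cross-fit of an identical topology yields negligible d_ll", {
  tr <- sample_species_tree(6, 0.25, seed = 71)
  a <- evolve_alignment(tr, model, g1, 300, seed = 72)
  own <- optimize_branch_lengths(tr, a, model, g1)
  other <- tr
  set.seed(73)
  other$edge.length <- tr$edge.length * exp(runif(length(tr$edge.length), -0.5, 0.5))
  cf <- cross_fit(a, own, other, model, g1)
  expect_lte(abs(cf$d_ll), 1e-3)
  tt <- topology_tests(cf, n_resamples = 200, seed = 74)
  expect_gte(tt$p_kh, 0.05)
  expect_gte(tt$p_sh, 0.05)
  expect_true(tt$elw_accepted)
})

test_that("distant topologies are decisively rejected; identical give (+,+)", {
  true_tree <- sample_species_tree(10, 0.25, seed = 75)
  a <- evolve_alignment(true_tree, model, g1, 1200, seed = 76)
  own <- optimize_branch_lengths(true_tree, a, model, g1)
  set.seed(77)
  far <- phangorn::rNNI(true_tree, moves = 5)
  cmp <- compare_topologies(a, a, own, far, model, g1, g1,
                            n_resamples = 200, seed = 78)
  cf <- cross_fit(a, own, far, model, g1)
  expect_gt(cf$d_ll, 0)
  tt <- topology_tests(cf, n_resamples = 200, seed = 79)
  expect_lt(tt$p_kh, 0.05)
  # self-comparison is (+,+) by construction
  self <- compare_topologies(a, a, own, own, model, g1, g1,
                             n_resamples = 200, seed = 80)
  expect_equal(self$category, "(+,+)")
})

test_that("compare_topologies validates leaf sets and is deterministic", {
  tr <- sample_species_tree(5, 0.25, seed = 81)
  a <- evolve_alignment(tr, model, g1, 150, seed = 82)
  tr_bad <- tr; tr_bad$tip.label[1] <- "nope"
  expect_error(cross_fit(a, tr, tr_bad, model, g1))
  c1 <- compare_topologies(a, a, tr, tr, model, g1, g1, 200, seed = 83)
  c2 <- compare_topologies(a, a, tr, tr, model, g1, g1, 200, seed = 83)
  expect_identical(c1$tests_a$p_kh, c2$tests_a$p_kh)
  expect_identical(c1$category, c2$category)
})
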