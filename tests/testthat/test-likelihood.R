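model <- lg_model()
gamma2 <- discrete_gamma(0.8, 2)

test_that("pruning equals brute-force enumeration on toy trees", {
  for (seed in c(41, 42)) {
    tr <- sample_species_tree(4, 0.3, seed = seed)
    a <- evolve_alignment(tr, model, gamma2, 3, seed = seed + 100)
    got <- tree_log_likelihood(tr, a, model, gamma2)
    oracle <- brute_force_loglik(tr, a, model, gamma2)
    expect_equal(got$per_site, oracle, tolerance = 1e-8)
    expect_equal(got$total, sum(oracle), tolerance = 1e-8)
  }
})

test_that("pruning handles gaps; an all-gap column contributes zero", {
  tr <- sample_species_tree(4, 0.3, seed = 43)
  a <- evolve_alignment(tr, model, gamma2, 4, seed = 143)
  m <- unclass(a)
  m[, 2] <- "-"          # all-gap column
  m[1, 3] <- "-"         # partial gap
  a2 <- msa(m)
  got <- tree_log_likelihood(tr, a2, model, gamma2)
  expect_equal(got$per_site[2], 0, tolerance = 1e-12)
  oracle <- brute_force_loglik(tr, a2, model, gamma2)
  expect_equal(got$per_site, oracle, tolerance = 1e-8)
})

test_that("likelihood matches an independent implementation", {
  tr <- sample_species_tree(6, 0.3, seed = 44)
  a <- evolve_alignment(tr, model, discrete_gamma(0.8, 4), 200, seed = 144)
  g4 <- discrete_gamma(0.8, 4)
  got <- tree_log_likelihood(tr, a, model, g4)$total
  pd <- phangorn::phyDat(unclass(a), type = "AA")
  fit <- phangorn::pml(tr, pd, model = "LG", k = 4, shape = 0.8)
  expect_equal(got, as.numeric(fit$logLik), tolerance = 1e-6)
})

test_that("branch optimization is monotone and dominates generating lengths", {
  tr <- sample_species_tree(6, 0.3, seed = 45)
  a <- evolve_alignment(tr, model, gamma2, 400, seed = 145)
  ll_true <- tree_log_likelihood(tr, a, model, gamma2)$total
  perturbed <- tr
  set.seed(46)
  perturbed$edge.length <- tr$edge.length * exp(stats::runif(length(tr$edge.length), -1, 1))
  opt <- optimize_branch_lengths(perturbed, a, model, gamma2)
  ll_opt <- attr(opt, "loglik")
  expect_gte(ll_opt, ll_true - 1e-3)  # ML dominance on the same topology
  expect_gte(ll_opt, tree_log_likelihood(perturbed, a, model, gamma2)$total)
  expect_equal(tree_log_likelihood(opt, a, model, gamma2)$total, ll_opt,
               tolerance = 1e-9)
  # fixed point: re-optimizing an optimum changes nothing material
  opt2 <- optimize_branch_lengths(opt, a, model, gamma2)
  expect_equal(attr(opt2, "loglik"), ll_opt, tolerance = 1e-6)
})

test_that("branch optimization agrees with an independent optimizer", {
  tr <- sample_species_tree(5, 0.3, seed = 47)
  a <- evolve_alignment(tr, model, gamma2, 300, seed = 147)
  opt <- optimize_branch_lengths(tr, a, model, gamma2)
  pd <- phangorn::phyDat(unclass(a), type = "AA")
  fit <- phangorn::pml(tr, pd, model = "LG", k = 2, shape = 0.8)
  fit <- phangorn::optim.pml(fit, optEdge = TRUE, model = "LG",
                             control = phangorn::pml.control(trace = 0))
  expect_equal(attr(opt, "loglik"), as.numeric(fit$logLik), tolerance = 1e-3)
})

test_that("alpha estimation recovers heterogeneity regimes", {
  tr <- sample_species_tree(6, 0.25, seed = 48)
  g_true <- discrete_gamma(0.8, 4)
  a <- evolve_alignment(tr, model, g_true, 1500, seed = 148)
  est <- estimate_alpha(tr, a, model, n_categories = 4)
  expect_gte(as.numeric(est), 0.5)
  expect_lte(as.numeric(est), 1.3)
  # homogeneous-rate data pushes alpha to the upper region
  a_h <- evolve_alignment(tr, model, discrete_gamma(1, 1), 800, seed = 149)
  expect_warning(
    est_h <- estimate_alpha(tr, a_h, model, n_categories = 4),
    "boundary")
  expect_gte(as.numeric(est_h), 5)
})

test_that("nni search leaves an optimal tree unchanged and repairs errors", {
  g1 <- discrete_gamma(1, 2)
  true_tree <- sample_species_tree(6, 0.3, seed = 50)
  a <- evolve_alignment(true_tree, model, g1, 1000, seed = 150)
  start <- optimize_branch_lengths(true_tree, a, model, g1)
  out <- nni_search(start, a, model, g1)
  expect_equal(rf_distance(out, true_tree), 0)
  expect_gte(attr(out, "loglik"), attr(start, "loglik") - 1e-6)
  # start from a topology 2 NNI moves away: search must not end worse
  set.seed(51)
  wrong <- phangorn::rNNI(true_tree, moves = 2)
  wrong <- optimize_branch_lengths(wrong, a, model, g1)
  fixed <- nni_search(wrong, a, model, g1)
  expect_gte(attr(fixed, "loglik"), attr(wrong, "loglik"))
  expect_gte(attr(fixed, "loglik"), attr(wrong, "loglik"))
})
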