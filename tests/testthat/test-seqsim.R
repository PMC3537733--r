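test_that("species tree sampling has the stated shape", {
  tr <- sample_species_tree(3, 0.25, seed = 91)
  expect_equal(length(tr$tip.label), 3L)
  expect_equal(nrow(tr$edge), 3L)      # unrooted 3-leaf: 3 branches
  tr2 <- sample_species_tree(12, 0.25, seed = 92)
  expect_false(ape::is.rooted(tr2))
  expect_true(all(tr2$edge.length > 0))
  expect_equal(tr2$tip.label, sprintf("sp%02d", 1:12))
  # branch lengths are exponential with the requested mean (loose MC check)
  big <- sample_species_tree(300, 0.25, seed = 93)
  expect_equal(mean(big$edge.length), 0.25, tolerance = 0.05)
  expect_error(sample_species_tree(2), "at least 3")
})

test_that("pair-tree derivation honors rho and n_nni", {
  sp <- sample_species_tree(10, 0.25, seed = 94)
  # rho = 1, equal base rates, no NNI: identical trees
  same <- derive_pair_trees(sp, rho = 1, sigma = 0.5, seed = 95)
  expect_equal(same$tree_a$edge.length, same$tree_b$edge.length,
               tolerance = 1e-12)
  expect_equal(rf_distance(same$tree_a, same$tree_b), 0)
  # rho = 0.9 over ~500 branches: sample correlation of log multipliers
  big <- sample_species_tree(252, 0.25, seed = 96)   # 2n-3 = 501 branches
  pt <- derive_pair_trees(big, rho = 0.9, sigma = 0.5, seed = 97)
  r_hat <- cor(pt$log_mult_a, pt$log_mult_b)
  expect_gte(r_hat, 0.85); expect_lte(r_hat, 0.95)
  # multipliers are mean-one on the natural scale (lognormal correction)
  expect_equal(mean(exp(pt$log_mult_a)), 1, tolerance = 0.1)
  # n_nni = 3 changes the topology
  moved <- derive_pair_trees(sp, rho = 0.9, sigma = 0.5, n_nni = 3, seed = 98)
  expect_gt(rf_distance(moved$tree_a, moved$tree_b), 0)
  # base rates scale expected branch lengths
  fast <- derive_pair_trees(sp, rho = 1, sigma = 0, base_rate_b = 2, seed = 99)
  expect_equal(fast$tree_b$edge.length, 2 * fast$tree_a$edge.length,
               tolerance = 1e-12)
})

test_that("sequence evolution hits its boundary behaviors", {
  model <- lg_model(); g <- discrete_gamma(1, 2)
  tr <- sample_species_tree(4, 0.3, seed = 100)
  zero <- tr; zero$edge.length[] <- 0
  a0 <- evolve_alignment(zero, model, g, 50, seed = 101)
  m <- unclass(a0)
  expect_true(all(m == rep(m[1, ], each = nrow(m))))
  # long-branch pair: empirical frequencies approach the stationary ones
  pair <- ape::read.tree(text = "(x:25,y:25);")
  a_inf <- evolve_alignment(pair, model, g, 50000, seed = 102)
  freqs <- table(factor(unclass(a_inf)[2, ], levels = AA_STATES)) / 50000
  expect_true(all(abs(as.numeric(freqs) - model$frequencies) < 0.02))
  # determinism and dimensions
  a1 <- evolve_alignment(tr, model, g, 30, seed = 103)
  a2 <- evolve_alignment(tr, model, g, 30, seed = 103)
  expect_identical(unclass(a1), unclass(a2))
  expect_equal(dim(a1), c(4L, 30L))
  expect_equal(sort(msa_species(a1)), sort(tr$tip.label))
})

test_that("simulate_pair wires the POS/NEG contract", {
  cfg <- sim_config(n_taxa = 6, sites_per_protein = 40, n_nni = 2, seed = 104)
  pos <- simulate_pair(cfg, "pos001", interacting = TRUE)
  neg <- simulate_pair(cfg, "neg001", interacting = FALSE)
  expect_equal(pos$rho, 0.9); expect_equal(pos$n_nni, 0L)
  expect_equal(neg$rho, 0);   expect_equal(neg$n_nni, 2L)
  expect_equal(rf_distance(pos$tree_a, pos$tree_b), 0)
  expect_equal(dim(pos$aln_a), c(6L, 40L))
  expect_equal(pos$label, "interacting")
  # derived streams: same config + id reproduce exactly
  pos2 <- simulate_pair(cfg, "pos001", interacting = TRUE)
  expect_identical(unclass(pos$aln_a), unclass(pos2$aln_a))
  # different ids give different species trees
  other <- simulate_pair(cfg, "pos002", interacting = TRUE)
  expect_false(identical(unclass(pos$aln_a), unclass(other$aln_a)))
})

test_that("generate_dataset writes a consumable file set", {
  cfg <- sim_config(n_taxa = 5, sites_per_protein = 20,
                    n_pos_pairs = 5, n_neg_pairs = 5, seed = 105)
  dir <- tempfile("simds")
  on.exit(unlink(dir, recursive = TRUE))
  ds <- generate_dataset(cfg, dir)
  expect_length(ds$pairs, 10L)
  expect_equal(nrow(ds$manifest), 10L)
  fastas <- list.files(dir, pattern = "\\.fasta$")
  expect_length(fastas, 20L)
  expect_true(file.exists(file.path(dir, "manifest.tsv")))
  truth <- jsonlite::read_json(file.path(dir, "truth.json"))
  expect_length(truth, 10L)
  expect_equal(truth[[1]]$label, "interacting")
  expect_equal(truth[[6]]$label, "non-interacting")
  # round trip: written FASTA matches the in-memory alignment
  back <- read_msa_fasta(file.path(dir, ds$manifest$path_a[1]))
  expect_equal(unclass(back), unclass(ds$pairs[[1]]$aln_a),
               ignore_attr = TRUE)
  # ground-truth newick reparses to the generating tree
  tr <- read_newick(truth[[1]]$tree_a)
  expect_equal(rf_distance(tr, ds$pairs[[1]]$tree_a), 0)
})

test_that("seed derivation separates streams and stays in range", {
  s1 <- derive_seed(1L, "pos001", 1L)
  expect_identical(s1, derive_seed(1L, "pos001", 1L))
  expect_false(s1 == derive_seed(1L, "pos002", 1L))
  expect_false(s1 == derive_seed(1L, "pos001", 2L))
  expect_false(s1 == derive_seed(2L, "pos001", 1L))
  many <- vapply(1:200, function(i) derive_seed(7L, paste0("p", i), 3L),
                 numeric(1))
  expect_true(all(many == floor(many)))
  expect_true(all(many >= 0 & many < 2^31))
  expect_equal(length(unique(many)), 200L)
})
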