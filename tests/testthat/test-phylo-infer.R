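test_that("ML distances are symmetric, zero on identity, positive on divergence", {
  m <- subst_model()
  s1 <- strrep("ACGT", 25)
  expect_equal(ml_distance(s1, s1, m), 0)
  set.seed(51)
  s2 <- paste(sample(c("A", "C", "G", "T"), 100, TRUE), collapse = "")
  expect_equal(ml_distance(s1, s2, m), ml_distance(s2, s1, m),
               tolerance = 1e-9)
  expect_gt(ml_distance(s1, s2, m), 0)
})

test_that("NJ tree on three taxa is the unique topology, rooted with labels", {
  set.seed(52)
  spec <- simulation_spec(n_leaves = 3, n_columns = 60, seed = 1)
  sim <- evolve_codon_alignment(generate_tree(spec), spec)
  tr <- build_nj_tree(sim$alignment, subst_model())
  expect_s3_class(tr, "phylo")
  expect_identical(ape::Ntip(tr), 3L)
  expect_true(ape::is.rooted(tr))
  expect_true(all(tr$edge.length >= 0))
})

test_that("NJ recovers a deep 4-taxon split in most simulations", {
  m <- subst_model()
  hits <- 0L
  for (s in 1:20) {
    spec <- simulation_spec(
      n_leaves = 4, tree_shape = "balanced", total_tree_length = 1.2,
      n_columns = 150, omega_background = 1, seed = 600 + s)
    tr <- generate_tree(spec)
    sim <- evolve_codon_alignment(tr, spec)
    nj <- build_nj_tree(sim$alignment, m)
    # balanced 4-taxon truth pairs t1+t2 against t3+t4
    split_ok <- ape::is.monophyletic(ape::unroot(nj), c("t1", "t2")) ||
      ape::is.monophyletic(ape::unroot(nj), c("t3", "t4"))
    hits <- hits + split_ok
  }
  expect_gte(hits, 18L)
})

test_that("bootstrap supports live in [0,100] and a clean deep split scores high", {
  spec <- simulation_spec(n_leaves = 6, tree_shape = "balanced",
                          total_tree_length = 1.2, n_columns = 150,
                          omega_background = 1, seed = 61)
  tr <- generate_tree(spec)
  sim <- evolve_codon_alignment(tr, spec)
  m <- subst_model()
  one <- bootstrap_support(sim$alignment, m, n_reps = 1, seed = 5)
  expect_true(all(one$support %in% c(0, 100)))
  bs <- bootstrap_support(sim$alignment, m, n_reps = 30, seed = 5)
  expect_true(all(bs$support >= 0 & bs$support <= 100))
  # the deepest split (t1-t3 vs t4-t6) should be strongly supported
  grp <- vapply(bs$tree$node.label, function(nl) {
    node <- ape::Ntip(bs$tree) + which(bs$tree$node.label == nl)
    tips <- ape::extract.clade(bs$tree, node)$tip.label
    setequal(tips, c("t1", "t2", "t3")) || setequal(tips, c("t4", "t5", "t6"))
  }, TRUE)
  expect_gte(max(bs$support[grp]), 90)
})

test_that("model fitting improves the likelihood and roughly recovers JC", {
  set.seed(63)
  devs <- c()
  for (s in 1:5) {
    spec <- simulation_spec(n_leaves = 6, total_tree_length = 1.5,
                            n_columns = 150, omega_background = 1,
                            seed = 700 + s)
    tr <- generate_tree(spec)
    sim <- evolve_codon_alignment(tr, spec)
    gen <- subst_model()   # equal rates: the generating mutation process
    fit <- fit_model(sim$alignment, tr, n_rate_categories = 2L,
                     fit_invariant = FALSE)
    expect_gte(fit$log_likelihood,
               log_likelihood(tr, sim$alignment, gen) - 1e-6)
    r <- fit$model$exchangeabilities
    devs <- c(devs, abs(log(r[1:5] / r[6])))
  }
  # median exchangeability within ~20% of equal across runs
  expect_lte(median(devs), log(1.25))
})
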