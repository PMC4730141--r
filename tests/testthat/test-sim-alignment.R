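test_that("omega zero forbids amino-acid change anywhere on the tree", {
  spec <- simulation_spec(n_leaves = 6, total_tree_length = 3,
                          n_columns = 30, conserved_columns = 1:30,
                          omega_conserved = 0, seed = 71)
  tr <- generate_tree(spec)
  sim <- evolve_codon_alignment(tr, spec)
  root_aa <- translate_cds(sim$ground_truth$root_sequence)
  all_seqs <- c(sim$alignment$seqs,
                sim$ground_truth$true_ancestral_sequences)
  for (s in all_seqs) expect_identical(translate_cds(s), root_aa)
  expect_true(all(sim$ground_truth$event_log$type == "syn"))
})

test_that("zero tree length leaves every sequence at the root state", {
  spec <- simulation_spec(n_leaves = 5, total_tree_length = 0,
                          n_columns = 20, seed = 72)
  tr <- generate_tree(spec)
  sim <- evolve_codon_alignment(tr, spec)
  for (s in sim$alignment$seqs)
    expect_identical(s, sim$ground_truth$root_sequence)
})

test_that("no stop codons appear in any row or recorded ancestor", {
  stops <- genetic_code()$stops
  for (seed in 73:75) {
    spec <- simulation_spec(n_leaves = 6, total_tree_length = 2.5,
                            n_columns = 50, hotspot_columns = 1:10,
                            omega_hotspot = 5, seed = seed)
    tr <- generate_tree(spec)
    sim <- evolve_codon_alignment(tr, spec)
    for (s in c(sim$alignment$seqs,
                sim$ground_truth$true_ancestral_sequences))
      expect_false(any(split_codons(s) %in% stops))
  }
})

test_that("simulation is bit-stable for a fixed seed", {
  spec <- simulation_spec(n_leaves = 5, n_columns = 25, seed = 76)
  tr <- generate_tree(spec)
  a <- evolve_codon_alignment(tr, spec)
  b <- evolve_codon_alignment(tr, spec)
  expect_identical(a$alignment$seqs, b$alignment$seqs)
  expect_identical(a$ground_truth$event_log, b$ground_truth$event_log)
})

test_that("hotspot columns accumulate more nonsynonymous events per site", {
  # event-counting oracle over the recorded simulation log: with omega = 5
  # the nonsynonymous rate per replacement site should exceed the
  # synonymous rate per silent site
  n_syn <- n_nonsyn <- 0
  S_sites <- N_sites <- 0
  for (rep in 1:200) {
    spec <- simulation_spec(n_leaves = 3, total_tree_length = 1.0,
                            n_columns = 2, hotspot_columns = 1:2,
                            omega_hotspot = 5, seed = 900 + rep)
    tr <- generate_tree(spec)
    sim <- evolve_codon_alignment(tr, spec)
    ev <- sim$ground_truth$event_log
    n_syn <- n_syn + sum(ev$type == "syn")
    n_nonsyn <- n_nonsyn + sum(ev$type == "nonsyn")
    for (cod in split_codons(sim$ground_truth$root_sequence)) {
      cs <- count_sites(cod)
      S_sites <- S_sites + cs$S
      N_sites <- N_sites + cs$N
    }
  }
  expect_gt(n_nonsyn / N_sites, n_syn / S_sites)
})
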