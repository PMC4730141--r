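test_that("identical cavity sets pair one-to-one with Jaccard 1", {
  a <- fake_cavity_set(fake_cavity(1:10), fake_cavity(20:25))
  m <- match_cavities(a, a)
  expect_identical(m$id_a, m$id_b)
  expect_equal(m$jaccard, c(1, 1))
})

test_that("disjoint lining sets stay unmatched; matching is symmetric", {
  a <- fake_cavity_set(fake_cavity(1:5), fake_cavity(10:15))
  b <- fake_cavity_set(fake_cavity(30:35), fake_cavity(12:16))
  m <- match_cavities(a, b)
  expect_identical(nrow(m), 1L)
  expect_identical(m$id_a, 2L)
  expect_identical(m$id_b, 2L)
  mt <- match_cavities(b, a)
  expect_identical(mt$id_a, m$id_b)
  expect_identical(mt$id_b, m$id_a)
  expect_equal(mt$jaccard, m$jaccard)
  none <- match_cavities(fake_cavity_set(fake_cavity(1:5)),
                         fake_cavity_set(fake_cavity(50:55)))
  expect_identical(nrow(none), 0L)
})

test_that("cage and its apertured twin share a lineage by construction", {
  gs <- generate_structure(structure_spec("sealed_cage", cage_radius = 6,
                                          n_shell_atoms = 80, seed = 9),
                           oracle_samples = 1e4)
  ga <- generate_structure(structure_spec("aperture_cage", cage_radius = 6,
                                          n_shell_atoms = 80, seed = 9),
                           oracle_samples = 1e4)
  cols <- stats::setNames(seq_len(80), seq_len(80))
  gs$structure$residue_columns <- cols
  ga$structure$residue_columns <- cols[seq_len(nrow(ga$structure$atoms))]
  p <- geometry_params(volume_mc_samples = 1e4, seed = 1)
  ca <- detect_cavities(gs$structure, p)
  cb <- detect_cavities(ga$structure, p)
  m <- match_cavities(ca, cb)
  expect_identical(nrow(m), 1L)
  expect_gte(m$jaccard, 0.3)
})

test_that("lineages are numbered by pre-order appearance with class history", {
  tr <- ensure_node_labels(ape::read.tree(
    text = "((t1:1,t2:1)A:1,(t3:1,t4:1)B:1)R;"))
  sets <- list(
    R = fake_cavity_set(fake_cavity(1:10, "dent", volume = 120)),
    A = fake_cavity_set(fake_cavity(1:10, "crack", volume = 600),
                        fake_cavity(40:45, "dent")),
    B = fake_cavity_set(fake_cavity(60:70, "internal", mouth_count = 0L)),
    t1 = fake_cavity_set(fake_cavity(1:9, "crevice", volume = 1500)))
  lin <- number_by_appearance(tr, sets)
  expect_identical(length(lin$lineages), 3L)
  l1 <- lin$lineages[[1]]
  expect_identical(l1$first_node, "R")
  expect_identical(unname(l1$class_history[c("R", "A", "t1")]),
                   c("dent", "crack", "crevice"))
  firsts <- vapply(lin$lineages, `[[`, "", "first_node")
  expect_identical(firsts, c("R", "A", "B"))
  expect_identical(unname(lin$node_designations["A"]), "1k + 2d")
  expect_identical(unname(lin$node_designations["B"]), "3i")
  # rerunning yields identical ids
  expect_identical(lin$node_designations,
                   number_by_appearance(tr, sets)$node_designations)
})

test_that("a widening dent stays one lineage along a chain", {
  tr <- ensure_node_labels(ape::read.tree(text = "(((t1:1)n3:1)n2:1)n1;"))
  # degenerate chain trees are awkward in ape; use a 2-tip tree instead
  tr <- ensure_node_labels(ape::read.tree(text = "((t1:1)A:1,t2:2)R;"))
  sets <- list(
    A = fake_cavity_set(fake_cavity(5:15, "dent", volume = 300)),
    t1 = fake_cavity_set(fake_cavity(5:16, "crack", volume = 700)))
  lin <- number_by_appearance(tr, sets)
  expect_identical(length(lin$lineages), 1L)
  expect_identical(unname(lin$lineages[[1]]$class_history[c("A", "t1")]),
                   c("dent", "crack"))
})

test_that("cavity score counts structures per column with the counting identity", {
  s1 <- fake_cavity_set(fake_cavity(c(1, 2, 3)), fake_cavity(c(3, 4)))
  s2 <- fake_cavity_set(fake_cavity(c(2, 3)))
  s3 <- fake_cavity_set()
  sp <- cavity_score_profile(list(s1, s2, s3), 6)
  expect_identical(sp$score, c(1L, 2L, 2L, 1L, 0L, 0L))
  expect_true(all(sp$score <= attr(sp, "n_structures")))
  expect_identical(sum(sp$score), 4L + 2L)   # union sizes per structure
})

test_that("overlay summarises positive, lining and conserved-lining columns", {
  prof <- structure(data.frame(
    column = 1:4, deltaN = c(1, 0, 0.2, NA), deltaS = c(0, 1, 0.1, NA),
    deltaN_minus_deltaS = c(1, -1, 0.1, NA),
    n_branches_informative = c(3L, 3L, 3L, 0L),
    Z = NA_real_, p_one_tailed = NA_real_),
    class = c("site_selection_profile", "data.frame"))
  sp <- cavity_score_profile(list(fake_cavity_set(fake_cavity(c(1, 2)))), 4)
  ov <- overlay_report(sp, prof)
  expect_identical(ov$summary$n_positive, 2L)
  expect_identical(ov$summary$n_cavity_lining, 2L)
  expect_identical(ov$summary$n_positive_and_lining, 1L)
  expect_identical(ov$summary$n_lining_conserved, 1L)
  sp2 <- cavity_score_profile(list(), 3)
  expect_error(overlay_report(sp2, prof), "mismatch")
})
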