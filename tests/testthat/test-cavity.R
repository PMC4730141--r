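# alpha-complex cavity detection on constructed fixtures

cage_fixture <- function(kind = "sealed_cage", R = 6, n = 80, seed = 1,
                         mc = 1e4) {
  gs <- generate_structure(structure_spec(kind, cage_radius = R,
                                          n_shell_atoms = n, seed = seed),
                           oracle_samples = mc)
  gs
}

# the reference cage is reused by several blocks below
cage8 <- cage_fixture("sealed_cage", R = 8, n = 200, seed = 4, mc = 1e5)

test_that("a single wide tetrahedron of atoms is all exterior, no cavity", {
  # regular tetrahedron, edge 10: circumradius 6.12 and facet circumradius
  # 5.77 both exceed the alpha threshold 1.8 + 1.4 = 3.2
  e <- 10
  xyz <- rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1)) *
    e / (2 * sqrt(2))
  st <- atom_structure(xyz, radius = 1.8)
  ac <- build_alpha_complex(st, geometry_params())
  expect_identical(sum(ac$in_alpha), 0L)
  expect_identical(sum(ac$exterior), 1L)
  expect_length(find_voids(ac), 0L)
})

test_that("a dense blob triangulates fully into the alpha complex", {
  gs <- cage_fixture("convex_blob", R = 4, n = 20, seed = 3)
  cs <- detect_cavities(gs$structure,
                        geometry_params(volume_mc_samples = 1e4))
  expect_length(cs$cavities, 0L)
})

test_that("sealed cage yields one insulated cavity agreeing with the oracle", {
  gs <- cage8
  cs <- detect_cavities(gs$structure,
                        geometry_params(volume_mc_samples = 3e4, seed = 2))
  expect_length(cs$cavities, 1L)
  cv <- cs$cavities[[1]]
  expect_identical(cv$mouth_count, 0L)
  expect_identical(cv$class_label, "internal")
  ref <- gs$ground_truth$reference_void_volume
  expect_lt(abs(cv$volume - ref) / ref, 0.05)
  # every shell residue lines the single void
  expect_setequal(cv$lining_residues, gs$structure$atoms$residue_index)
})

test_that("aperture cage opens exactly one mouth", {
  gs <- cage_fixture("aperture_cage", R = 8, n = 200, seed = 5)
  cs <- detect_cavities(gs$structure,
                        geometry_params(volume_mc_samples = 2e4, seed = 2))
  expect_length(cs$cavities, 1L)
  expect_gte(cs$cavities[[1]]$mouth_count, 1L)
  expect_true(cs$cavities[[1]]$class_label %in%
                c("dent", "crack", "crevice"))
})

test_that("cavity census is invariant under rigid motion", {
  gs <- cage_fixture("sealed_cage", R = 6, n = 100, seed = 6)
  st <- gs$structure
  th <- 1.1
  R <- rbind(c(cos(th), 0, sin(th)), c(0, 1, 0), c(-sin(th), 0, cos(th)))
  xyz <- sweep(as.matrix(st$atoms[, c("x", "y", "z")]) %*% t(R), 2L,
               c(5, -3, 11), "+")
  st2 <- atom_structure(xyz, radius = st$atoms$radius,
                        residue_index = st$atoms$residue_index)
  p <- geometry_params(volume_mc_samples = 2e4, seed = 3)
  a <- detect_cavities(st, p)
  b <- detect_cavities(st2, p)
  expect_identical(length(a$cavities), length(b$cavities))
  expect_identical(a$table$mouth_count, b$table$mouth_count)
  se <- sqrt(a$table$volume_se^2 + b$table$volume_se^2)
  expect_true(all(abs(a$table$volume - b$table$volume) < 4 * se + 1))
})

test_that("growing the probe never increases the empty tetra count", {
  gs <- cage_fixture("sealed_cage", R = 6, n = 80, seed = 7)
  empties <- vapply(c(0.8, 1.4, 2.2), function(pr) {
    ac <- build_alpha_complex(gs$structure, geometry_params(probe_radius = pr))
    sum(!ac$in_alpha)
  }, 0)
  expect_true(all(diff(empties) <= 0))
})

test_that("classification thresholds are exactly 500 and 1000 with internal override", {
  expect_identical(classify_cavity(499.99, 1), "dent")
  expect_identical(classify_cavity(500.0, 1), "crack")
  expect_identical(classify_cavity(999.999, 3), "crack")
  expect_identical(classify_cavity(1000.0, 2), "crevice")
  expect_identical(classify_cavity(750.0, 0), "internal")
  expect_identical(classify_cavity(0, 0), "internal")
  expect_error(classify_cavity(-1, 1), "negative")
})

test_that("measurement refuses under-sampled requests and reports MC error", {
  ac <- build_alpha_complex(cage8$structure, geometry_params())
  voids <- find_voids(ac)
  main <- voids[[which.max(vapply(voids, function(v)
    length(v$tetrahedra), 0L))]]
  expect_error(measure_cavity(main, ac,
                              geometry_params(volume_mc_samples = 100)),
               "1e4")
  m1 <- measure_cavity(main, ac,
                       geometry_params(volume_mc_samples = 1e4, seed = 4))
  m2 <- measure_cavity(main, ac,
                       geometry_params(volume_mc_samples = 4e4, seed = 4))
  # quadrupling samples should roughly halve the standard error
  expect_lt(m2$volume_se, m1$volume_se * 0.75)
})
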