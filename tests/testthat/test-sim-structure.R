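test_that("structure specs validate geometry and aperture usage", {
  expect_error(structure_spec(cage_radius = 1, atom_radius = 1.8),
               "cage_radius")
  expect_error(structure_spec(n_shell_atoms = 8), "12")
  expect_error(structure_spec("sealed_cage", aperture_solid_angle = 0.5),
               "aperture")
})

test_that("a dense convex blob has zero reference void volume", {
  gs <- generate_structure(structure_spec("convex_blob", cage_radius = 4,
                                          n_shell_atoms = 20, seed = 81),
                           oracle_samples = 1e5)
  expect_equal(gs$ground_truth$reference_void_volume, 0)
  expect_identical(gs$ground_truth$reference_mouth_count, 0L)
})

test_that("sealed cage volume sits inside the closed-form sanity envelope", {
  gs <- generate_structure(structure_spec("sealed_cage", cage_radius = 8,
                                          n_shell_atoms = 200, seed = 82),
                           oracle_samples = 2e5)
  vol <- gs$ground_truth$reference_void_volume
  ball <- 4 / 3 * pi * (8 - 1.8 - 1.4)^3
  expect_lt(abs(vol - ball) / ball, 0.10)
  expect_identical(gs$ground_truth$reference_mouth_count, 0L)
})

test_that("an aperture never increases the insulated reference volume", {
  sealed <- generate_structure(structure_spec("sealed_cage",
                                              cage_radius = 8,
                                              n_shell_atoms = 200,
                                              seed = 83),
                               oracle_samples = 1e5)
  open <- generate_structure(structure_spec("aperture_cage",
                                            cage_radius = 8,
                                            n_shell_atoms = 200,
                                            seed = 83),
                             oracle_samples = 1e5)
  expect_lte(open$ground_truth$reference_void_volume,
             sealed$ground_truth$reference_void_volume)
})

test_that("structure generation is coordinate-deterministic per seed", {
  a <- generate_structure(structure_spec("sealed_cage", seed = 84),
                          oracle_samples = 1e4)
  b <- generate_structure(structure_spec("sealed_cage", seed = 84),
                          oracle_samples = 1e4)
  expect_identical(a$structure$atoms, b$structure$atoms)
  expect_identical(a$ground_truth$reference_void_volume,
                   b$ground_truth$reference_void_volume)
})
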