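# NG86 counting machinery against literal enumeration oracles

test_that("site counts match neighbour-enumeration oracle on all sense codons", {
  code <- genetic_code()
  for (cod in sense_codons(code)) {
    got <- count_sites(cod, code)
    ref <- oracle_count_sites(cod, code)
    expect_equal(got$S, ref$S, tolerance = 1e-12, label = cod)
    expect_equal(got$S + got$N, 3, tolerance = 1e-9, label = cod)
  }
  expect_equal(count_sites("TTT")$S, 1 / 3)
  expect_equal(count_sites("ATG")$S, 0)
  expect_error(count_sites("TAA"), "sense")
})

test_that("pathway-averaged differences match the permutation oracle", {
  code <- genetic_code()
  set.seed(41)
  sc <- sense_codons(code)
  pairs <- cbind(sample(sc, 400, replace = TRUE),
                 sample(sc, 400, replace = TRUE))
  for (i in seq_len(nrow(pairs))) {
    a <- pairs[i, 1L]; b <- pairs[i, 2L]
    got <- count_differences(a, b, code)
    ref <- oracle_count_differences(a, b, code)
    expect_equal(got$Sd, ref$Sd, tolerance = 1e-12,
                 label = paste(a, b))
    expect_equal(got$Nd, ref$Nd, tolerance = 1e-12,
                 label = paste(a, b))
    if (!got$inadmissible) {
      hamming <- sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
      expect_equal(got$Sd + got$Nd, hamming, tolerance = 1e-9)
    }
  }
  # the classic two-pathway case
  d <- count_differences("TTT", "GTA")
  expect_equal(d$Sd, 0.5)
  expect_equal(d$Nd, 1.5)
  expect_identical(d$n_pathways, 2L)
  expect_identical(count_differences("TTT", "TTT")$Sd, 0)
})

test_that("pairwise NG86 is symmetric, zero on identity, exact on a constructed pair", {
  set.seed(7)
  base <- paste(replicate(100, sample(c("GCT", "ACT", "GGA", "CTC"), 1)),
                collapse = "")
  expect_equal(pairwise_ng(base, base, n_boot = 0)$dN, 0)
  expect_equal(pairwise_ng(base, base, n_boot = 0)$dS, 0)

  # plant exactly 3 synonymous third-position changes (GCT -> GCC is 4-fold)
  cods <- split_codons(base)
  idx <- which(cods == "GCT")[1:3]
  cods2 <- cods; cods2[idx] <- "GCC"
  other <- paste(cods2, collapse = "")
  r <- pairwise_ng(base, other, n_boot = 0)
  expect_equal(r$Sd, 3)
  expect_equal(r$pN, 0)

  a <- pairwise_ng(base, other, n_boot = 50, seed = 3)
  b <- pairwise_ng(other, base, n_boot = 50, seed = 3)
  for (f in c("pS", "pN", "dS", "dN"))
    expect_equal(a[[f]], b[[f]], tolerance = 1e-12, label = f)
})

test_that("Z-test arithmetic, tails and degenerate cases", {
  z <- z_test(0.10, 0.02, 0.0008, 0.0008)
  expect_equal(z$Z, 2)
  expect_equal(z$p_one_tailed, pnorm(2, lower.tail = FALSE),
               tolerance = 1e-12)
  expect_equal(z_test(0.3, 0.3, 0.001, 0.002)$Z, 0)
  expect_equal(z_test(0.3, 0.3, 0, 0)$p_one_tailed, 0.5)
  expect_true(z_test(0.2, 0.1, 0, 0)$infinite)
  # antisymmetry under swapping the two rate estimates
  z1 <- z_test(0.4, 0.1, 0.001, 0.003)
  z2 <- z_test(0.1, 0.4, 0.003, 0.001)
  expect_equal(z1$Z, -z2$Z, tolerance = 1e-12)
})
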