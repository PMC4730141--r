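test_that("opal readthrough translates the textbook example", {
  rt <- find_opal_readthrough("ATGTGATTTTAA")
  expect_identical(rt$opal_position, 2L)
  expect_identical(rt$standard_protein, "M")
  expect_identical(rt$extended_protein, "MUF")
  expect_identical(rt$second_stop_position, 4L)
})

test_that("sequences without an opal candidate return NULL", {
  expect_null(find_opal_readthrough("ATGTTTTAA"))          # no TGA at all
  expect_null(find_opal_readthrough("ATGTAATGATTTTAA"))    # TAA first
  expect_error(find_opal_readthrough("TAAATG"), "sense")
})

test_that("a long constructed CDS reads through at the planted opal", {
  set.seed(101)
  sense <- setdiff(sense_codons(), "ATG")
  cods <- c("ATG", sample(sense, 58, replace = TRUE), "TAA")
  cods[40] <- "TGA"
  cods <- ifelse(seq_along(cods) < 60 & cods %in% c("TGA") &
                   seq_along(cods) != 40, "TGC", cods)
  rt <- find_opal_readthrough(paste(cods, collapse = ""))
  expect_identical(rt$opal_position, 40L)
  expect_identical(nchar(rt$extended_protein), 59L)
  expect_identical(substr(rt$extended_protein, 40, 40), "U")
  expect_identical(nchar(rt$standard_protein), 39L)
})

test_that("readthrough never alters residues outside the opal position", {
  set.seed(102)
  for (rep in 1:20) {
    sense <- setdiff(sense_codons(), c("ATG", "TGA"))
    n <- sample(10:30, 1)
    cods <- c("ATG", sample(sense, n, replace = TRUE), "TGA",
              sample(sense, 5, replace = TRUE), "TAG")
    rt <- find_opal_readthrough(paste(cods, collapse = ""))
    std <- strsplit(rt$standard_protein, "")[[1]]
    ext <- strsplit(rt$extended_protein, "")[[1]]
    expect_identical(ext[seq_along(std)], std)
    expect_identical(ext[rt$opal_position], "U")
  }
})

test_that("hairpin scanner matches the literal geometry enumerator", {
  got <- scan_secis("GGGGAAAACCCC", min_stem = 4, min_loop = 3,
                    max_loop = 8)
  expect_identical(got$stem_length, 4L)
  expect_identical(got$loop_length, 4L)
  expect_identical(got$pairing_score, 4L)
  expect_null(scan_secis(strrep("A", 50)))
  set.seed(103)
  for (rep in 1:60) {
    w <- paste(sample(c("A", "C", "G", "T"), 60, TRUE), collapse = "")
    got <- scan_secis(w, min_stem = 4, min_loop = 3, max_loop = 8)
    ref <- oracle_best_hairpin(w, 4L, 3L, 8L)
    if (is.null(ref)) expect_null(got)
    else {
      expect_identical(got$pairing_score, ref$pairing_score)
      expect_identical(got$window_start, ref$window_start)
      expect_identical(got$stem_length, ref$stem_length)
      expect_identical(got$loop_length, ref$loop_length)
    }
  }
})

test_that("planted hairpins outscore their shuffled controls", {
  set.seed(104)
  wins <- 0L
  for (rep in 1:40) {
    stem <- sample(c("A", "C", "G", "T"), 8, TRUE)
    comp <- c(A = "T", C = "G", G = "C", T = "A")[stem]
    hairpin <- c(stem, sample(c("A", "C", "G", "T"), 4, TRUE),
                 rev(unname(comp)))
    pad <- function(k) sample(c("A", "C", "G", "T"), k, TRUE)
    planted <- paste(c(pad(15), hairpin, pad(15)), collapse = "")
    shuffled <- paste(sample(strsplit(planted, "")[[1]]), collapse = "")
    s1 <- scan_secis(planted, min_stem = 5, min_loop = 3, max_loop = 8)
    s0 <- scan_secis(shuffled, min_stem = 5, min_loop = 3, max_loop = 8)
    if (!is.null(s1) &&
        (is.null(s0) || s1$pairing_score > s0$pairing_score))
      wins <- wins + 1L
  }
  expect_gte(wins, 36L)
})

test_that("the readthrough report combines opal and SECIS coordinates", {
  cds <- c(with_opal = "ATGTGAGGGGAAAACCCCTTTTAA",
           plain = "ATGAAATAA")
  rep <- readthrough_report(cds, window_nt = 18, min_stem = 4)
  expect_identical(rep$opal_position, c(2L, NA))
  expect_identical(rep$secis_score[1], 4L)
  expect_true(rep$secis_start[1] >= 7L)
  expect_true(is.na(rep$extended_protein[2]))
})
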