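#' Genetic code tables with optional opal (UGA) readthrough as Sec
#'
#' Builds a codon -> amino-acid lookup over all 64 codons. In
#' \code{"standard"} mode the stop set is \{TAA, TAG, TGA\}. In
#' \code{"opal_as_Sec"} mode the opal codon TGA is decoded as selenocysteine
#' (one-letter code \code{"U"}) and only TAA/TAG terminate, the situation in
#' selenoprotein mRNAs once the Sec-insertion machinery engages.
#'
#' @param mode one of \code{"standard"}, \code{"opal_as_Sec"}.
#' @return an object of class \code{genetic_code}: a list with \code{table}
#'   (named character vector of 64 amino acids, \code{"*"} for stop),
#'   \code{stops} (character vector of stop codons) and \code{mode}.
#' @examples
#' gc <- genetic_code()
#' gc$table[["ATG"]]                 # "M"
#' genetic_code("opal_as_Sec")$table[["TGA"]]  # "U"
#' @export
genetic_code <- function(mode = c("standard", "opal_as_Sec")) {
  mode <- match.arg(mode)
  tab <- .standard_code_table()
  if (mode == "opal_as_Sec") tab[["TGA"]] <- "U"
  stops <- names(tab)[tab == "*"]
  structure(list(table = tab, stops = stops, mode = mode),
            class = "genetic_code")
}

# Standard code laid out in TCAG nesting order (first base slowest).
.standard_code_table <- function() {
  bases <- c("T", "C", "A", "G")
  codons <- as.vector(t(outer(
    as.vector(t(outer(bases, bases, paste0))), bases, paste0)))
  aa <- strsplit(paste0(
    "FFLLSSSSYY**CC*W",
    "LLLLPPPPHHQQRRRR",
    "IIIMTTTTNNKKSSRR",
    "VVVVAAAADDEEGGGG"), "")[[1]]
  stats::setNames(aa, codons)
}

#' @export
print.genetic_code <- function(x, ...) {
  cat("Genetic code (", x$mode, "): ", sum(x$table != "*"),
      " sense codons, stops: ", paste(x$stops, collapse = ", "), "\n",
      sep = "")
  invisible(x)
}

#' Sense codons under a genetic code
#' @param code a \code{genetic_code}.
#' @return character vector of codons that are not stops (61 for standard).
#' @export
sense_codons <- function(code = genetic_code()) {
  setdiff(names(code$table), code$stops)
}

#' Translate an in-frame nucleotide sequence
#'
#' @param cds nucleotide string (length divisible by 3) or character vector of
#'   codons.
#' @param code a \code{genetic_code}.
#' @return character string of one-letter amino acids (\code{"*"} for stop,
#'   \code{"X"} for codons with non-ACGT characters).
#' @export
translate_cds <- function(cds, code = genetic_code()) {
  cod <- if (length(cds) == 1L && nchar(cds) > 3L) split_codons(cds) else cds
  aa <- code$table[toupper(cod)]
  aa[is.na(aa)] <- "X"
  paste(aa, collapse = "")
}

#' Split a nucleotide string into codons
#' @param seq nucleotide string; length must be divisible by 3.
#' @return character vector of 3-letter codons.
#' @export
split_codons <- function(seq) {
  n <- nchar(seq)
  if (n %% 3L != 0L)
    stop("sequence length ", n, " is not divisible by 3")
  substring(seq, seq(1L, n, 3L), seq(3L, n, 3L))
}

.is_acgt_codon <- function(codon) {
  nchar(codon) == 3L & !grepl("[^ACGT]", codon)
}

.is_sense <- function(codon, code) {
  ok <- .is_acgt_codon(codon)
  ok & !(codon %in% code$stops)
}
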