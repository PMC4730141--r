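#' Opal-codon readthrough translation (UGA as selenocysteine)
#'
#' Scans an in-frame CDS for the first TGA that is followed, in frame, by a
#' second stop codon. The standard translation ends before that opal codon;
#' the extended (selenoprotein) translation decodes it as Sec (\code{"U"})
#' and continues to the second stop.
#'
#' @param cds nucleotide string, length divisible by 3, starting with a
#'   sense codon.
#' @return \code{NULL} when there is no opal-readthrough candidate (no
#'   in-frame TGA before the terminal stop, or a TAA/TAG terminates the
#'   frame first); otherwise a list with \code{opal_position} (1-based
#'   codon index), \code{standard_protein}, \code{extended_protein},
#'   \code{second_stop_position} (codon index or NA when the frame ends
#'   without one).
#' @examples
#' find_opal_readthrough("ATGTGATTTTAA")  # "M" -> "MUF", opal at codon 2
#' @export
find_opal_readthrough <- function(cds) {
  cds <- toupper(cds)
  cods <- split_codons(cds)
  std <- genetic_code("standard")
  if (cods[1L] %in% std$stops)
    stop("CDS must start with a sense codon")
  first_stop <- which(cods %in% std$stops)
  if (length(first_stop) == 0L) return(NULL)
  fs <- first_stop[1L]
  if (cods[fs] != "TGA") return(NULL)           # TAA/TAG terminates: no opal
  later_stops <- first_stop[first_stop > fs]
  aa <- genetic_code("opal_as_Sec")$table
  std_prot <- paste(std$table[cods[seq_len(fs - 1L)]], collapse = "")
  if (length(later_stops) == 0L) {
    ext_end <- length(cods)
    second <- NA_integer_
  } else {
    # the first downstream stop under Sec readthrough (TGA decoded as U)
    down <- cods[(fs + 1L):length(cods)]
    hit <- which(aa[down] == "*")
    if (length(hit) == 0L) {
      ext_end <- length(cods)
      second <- NA_integer_
    } else {
      second <- unname(fs + hit[1L])
      ext_end <- second - 1L
    }
  }
  ext <- aa[cods[seq_len(ext_end)]]
  list(opal_position = fs,
       standard_protein = std_prot,
       extended_protein = paste(ext, collapse = ""),
       second_stop_position = second)
}

#' Scan a window for the best SECIS-like hairpin
#'
#' A deliberately minimal stem-loop maximiser, not a thermodynamic folder:
#' it searches all hairpin geometries with a perfectly paired stem
#' (Watson-Crick plus GU wobble, no bulges) and a loop of the given length
#' range, and returns the highest-scoring candidate. The score is the stem
#' length in base pairs.
#'
#' @param window nucleotide string (DNA alphabet; T pairs as U).
#' @param min_stem minimum stem length in base pairs.
#' @param min_loop,max_loop loop length bounds (nucleotides, >= 3).
#' @return \code{NULL} when no geometry reaches \code{min_stem}; otherwise
#'   a list with \code{window_start}, \code{window_end} (1-based inclusive
#'   nucleotide coordinates of the full hairpin), \code{stem_length},
#'   \code{loop_length} and \code{pairing_score}. Ties break by smaller
#'   start, then longer stem.
#' @export
scan_secis <- function(window, min_stem = 6L, min_loop = 3L,
                       max_loop = 8L) {
  window <- toupper(gsub("U", "T", toupper(window)))
  n <- nchar(window)
  if (min_loop < 3L) stop("min_loop must be >= 3")
  if (n < 2L * min_stem + min_loop) return(NULL)
  x <- strsplit(window, "")[[1]]
  best <- NULL
  # parametrise by the loop: loop occupies a..a+loop-1, stem pairs
  # (a-k, a+loop-1+k) nest consistently as the stem grows outward
  for (loop in min_loop:max_loop) {
    for (a in seq_len(n)) {
      if (a + loop - 1L > n) break
      L <- 0L
      while (a - L - 1L >= 1L && a + loop + L <= n &&
             .rna_pair(x[a - L - 1L], x[a + loop + L]))
        L <- L + 1L
      if (L < min_stem) next
      cand <- list(window_start = a - L,
                   window_end = a + loop - 1L + L,
                   stem_length = L, loop_length = loop,
                   pairing_score = L)
      if (is.null(best) ||
          cand$pairing_score > best$pairing_score ||
          (cand$pairing_score == best$pairing_score &&
           (cand$window_start < best$window_start ||
            (cand$window_start == best$window_start &&
             cand$stem_length > best$stem_length))))
        best <- cand
    }
  }
  best
}

.rna_pair <- function(a, b) {
  (a == "A" && b == "T") || (a == "T" && b == "A") ||
    (a == "G" && b == "C") || (a == "C" && b == "G") ||
    (a == "G" && b == "T") || (a == "T" && b == "G")
}

#' Readthrough + SECIS report for a set of coding sequences
#'
#' @param cds_set named character vector of CDS nucleotide strings.
#' @param window_nt length of the window scanned immediately 3' of the
#'   opal codon.
#' @param min_stem,min_loop,max_loop hairpin scan parameters.
#' @return data.frame with one row per sequence: opal position, extended
#'   protein, SECIS window coordinates (relative to the CDS) and score;
#'   NA-filled for sequences without an opal-readthrough candidate.
#' @export
readthrough_report <- function(cds_set, window_nt = 60L, min_stem = 6L,
                               min_loop = 3L, max_loop = 8L) {
  rows <- lapply(names(cds_set), function(nm) {
    rt <- find_opal_readthrough(cds_set[[nm]])
    if (is.null(rt))
      return(data.frame(id = nm, opal_position = NA_integer_,
                        extended_protein = NA_character_,
                        secis_start = NA_integer_, secis_end = NA_integer_,
                        secis_score = NA_integer_))
    w0 <- 3L * rt$opal_position + 1L
    win <- substr(cds_set[[nm]], w0, min(nchar(cds_set[[nm]]),
                                         w0 + window_nt - 1L))
    sc <- if (nchar(win) >= 2L * min_stem + min_loop)
      scan_secis(win, min_stem, min_loop, max_loop) else NULL
    data.frame(id = nm, opal_position = rt$opal_position,
               extended_protein = rt$extended_protein,
               secis_start = if (is.null(sc)) NA_integer_
                             else w0 + sc$window_start - 1L,
               secis_end = if (is.null(sc)) NA_integer_
                           else w0 + sc$window_end - 1L,
               secis_score = if (is.null(sc)) NA_integer_
                             else sc$pairing_score)
  })
  do.call(rbind, rows)
}
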