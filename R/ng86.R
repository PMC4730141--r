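#' Nei-Gojobori (NG86) synonymous / nonsynonymous site counts for one codon
#'
#' For each of the three codon positions, the synonymous fraction is the
#' number of single-nucleotide changes at that position that preserve the
#' encoded amino acid, divided by the number of changes that do not create a
#' stop codon (mutations to stops are excluded and the position renormalised,
#' so S + N = 3 always holds for a sense codon).
#'
#' @param codon 3-letter ACGT codon, sense under \code{code}.
#' @param code a \code{genetic_code}.
#' @return list with \code{S} (synonymous sites), \code{N} (nonsynonymous
#'   sites) and \code{per_position} (synonymous fraction at each position).
#' @examples
#' count_sites("TTT")$S   # 1/3: only TTC is synonymous among non-stop changes
#' count_sites("ATG")$S   # 0: Met has no synonymous neighbour
#' @export
count_sites <- function(codon, code = genetic_code()) {
  codon <- toupper(codon)
  if (!.is_sense(codon, code))
    stop("count_sites() requires a sense codon, got '", codon, "'")
  bases <- c("A", "C", "G", "T")
  aa <- code$table[[codon]]
  nt <- strsplit(codon, "")[[1]]
  frac <- numeric(3L)
  for (pos in 1:3) {
    n_syn <- 0L
    n_ok <- 0L
    for (b in setdiff(bases, nt[pos])) {
      alt <- nt
      alt[pos] <- b
      alt_codon <- paste(alt, collapse = "")
      if (alt_codon %in% code$stops) next
      n_ok <- n_ok + 1L
      if (code$table[[alt_codon]] == aa) n_syn <- n_syn + 1L
    }
    frac[pos] <- if (n_ok > 0L) n_syn / n_ok else 0
  }
  S <- sum(frac)
  list(S = S, N = 3 - S, per_position = frac)
}

#' NG86 pathway-averaged synonymous / nonsynonymous differences
#'
#' Codons differing at d positions are connected by d! single-step mutational
#' pathways. Each step is classified synonymous or nonsynonymous; pathways
#' passing through a stop codon are discarded; step counts are averaged with
#' equal weight over the admissible pathways.
#'
#' @param codon_a,codon_b sense ACGT codons.
#' @param code a \code{genetic_code}.
#' @return list with \code{Sd}, \code{Nd} (pathway-averaged difference
#'   counts; \code{NA} when inadmissible), \code{n_pathways} (admissible
#'   pathway count) and \code{inadmissible} (TRUE when every pathway passes
#'   through a stop).
#' @examples
#' count_differences("TTT", "GTA")  # Sd = 0.5, Nd = 1.5 over two pathways
#' @export
count_differences <- function(codon_a, codon_b, code = genetic_code()) {
  codon_a <- toupper(codon_a); codon_b <- toupper(codon_b)
  if (!.is_sense(codon_a, code) || !.is_sense(codon_b, code))
    stop("count_differences() requires sense codons")
  a <- strsplit(codon_a, "")[[1]]
  b <- strsplit(codon_b, "")[[1]]
  diff_pos <- which(a != b)
  if (length(diff_pos) == 0L)
    return(list(Sd = 0, Nd = 0, n_pathways = 1L, inadmissible = FALSE))

  # depth-first walk over orderings of the differing positions
  acc <- new.env(parent = emptyenv())
  acc$n <- 0L; acc$Sd <- 0; acc$Nd <- 0
  walk <- function(cur, remaining, syn, nonsyn) {
    if (length(remaining) == 0L) {
      acc$n <- acc$n + 1L
      acc$Sd <- acc$Sd + syn
      acc$Nd <- acc$Nd + nonsyn
      return(invisible())
    }
    for (pos in remaining) {
      nxt <- cur
      nxt[pos] <- b[pos]
      nxt_codon <- paste(nxt, collapse = "")
      if (nxt_codon %in% code$stops) next
      step_syn <- code$table[[paste(cur, collapse = "")]] ==
        code$table[[nxt_codon]]
      walk(nxt, setdiff(remaining, pos),
           syn + as.integer(step_syn), nonsyn + as.integer(!step_syn))
    }
  }
  walk(a, diff_pos, 0L, 0L)
  if (acc$n == 0L)
    return(list(Sd = NA_real_, Nd = NA_real_, n_pathways = 0L,
                inadmissible = TRUE))
  list(Sd = acc$Sd / acc$n, Nd = acc$Nd / acc$n,
       n_pathways = acc$n, inadmissible = FALSE)
}

#' Pairwise NG86 comparison of two codon sequences
#'
#' Proportions pS = sum(Sd)/mean-S-sites and pN = sum(Nd)/mean-N-sites with
#' Jukes-Cantor multiple-hit correction d = -(3/4) log(1 - (4/3) p), and
#' bootstrap variances over codon columns.
#'
#' Columns are skipped when either codon is a stop, contains a non-ACGT
#' character (gap or ambiguity), or when every mutational pathway between the
#' two codons is stop-interrupted.
#'
#' @param seq_a,seq_b equal-length nucleotide strings (length divisible by 3).
#' @param code a \code{genetic_code}.
#' @param n_boot bootstrap replicates for the variances (0 disables).
#' @param seed integer seed for the bootstrap resampling.
#' @return list with \code{pS}, \code{pN}, \code{dS}, \code{dN}, \code{varS},
#'   \code{varN}, \code{S_sites}, \code{N_sites}, \code{Sd}, \code{Nd},
#'   \code{n_codons_used} and \code{saturated} (TRUE when p >= 3/4 so the
#'   correction is undefined and the uncorrected p is returned).
#' @export
pairwise_ng <- function(seq_a, seq_b, code = genetic_code(),
                        n_boot = 1000L, seed = 1L) {
  ca <- split_codons(toupper(seq_a))
  cb <- split_codons(toupper(seq_b))
  if (length(ca) != length(cb))
    stop("sequences differ in codon length (", length(ca), " vs ",
         length(cb), ")")
  per <- .ng_per_column(ca, cb, code)
  used <- which(per$usable)
  est <- .ng_estimate(per, used)
  varS <- varN <- 0
  if (n_boot > 0L && length(used) > 0L) {
    rs <- .with_seed(seed, {
      reps <- matrix(NA_real_, n_boot, 2L)
      for (r in seq_len(n_boot)) {
        idx <- sample(used, length(used), replace = TRUE)
        e <- .ng_estimate(per, idx)
        reps[r, ] <- c(e$dS, e$dN)
      }
      reps
    })
    varS <- stats::var(rs[, 1L], na.rm = TRUE)
    varN <- stats::var(rs[, 2L], na.rm = TRUE)
  }
  c(est[c("pS", "pN", "dS", "dN")],
    list(varS = varS, varN = varN,
         S_sites = est$S_sites, N_sites = est$N_sites,
         Sd = est$Sd, Nd = est$Nd,
         n_codons_used = length(used), saturated = est$saturated))
}

# per-column Sd/Nd and averaged site counts for two codon vectors
.ng_per_column <- function(ca, cb, code) {
  n <- length(ca)
  Sd <- Nd <- Sbar <- Nbar <- numeric(n)
  usable <- logical(n)
  for (i in seq_len(n)) {
    if (!.is_sense(ca[i], code) || !.is_sense(cb[i], code)) next
    d <- count_differences(ca[i], cb[i], code)
    if (d$inadmissible) next
    sa <- count_sites(ca[i], code)
    sb <- count_sites(cb[i], code)
    Sd[i] <- d$Sd; Nd[i] <- d$Nd
    Sbar[i] <- (sa$S + sb$S) / 2
    Nbar[i] <- (sa$N + sb$N) / 2
    usable[i] <- TRUE
  }
  list(Sd = Sd, Nd = Nd, Sbar = Sbar, Nbar = Nbar, usable = usable)
}

.jc_correct <- function(p) {
  if (is.na(p) || p >= 0.75) return(list(d = p, saturated = !is.na(p)))
  list(d = -0.75 * log(1 - 4 * p / 3), saturated = FALSE)
}

.ng_estimate <- function(per, idx) {
  S <- sum(per$Sbar[idx]); N <- sum(per$Nbar[idx])
  Sd <- sum(per$Sd[idx]); Nd <- sum(per$Nd[idx])
  pS <- if (S > 0) Sd / S else 0
  pN <- if (N > 0) Nd / N else 0
  cs <- .jc_correct(pS); cn <- .jc_correct(pN)
  list(pS = pS, pN = pN, dS = cs$d, dN = cn$d,
       S_sites = S, N_sites = N, Sd = Sd, Nd = Nd,
       saturated = cs$saturated || cn$saturated)
}

#' Codon-based Z-test for positive selection
#'
#' Z = (dN - dS) / sqrt(varN + varS); the one-tailed p-value is the upper
#' tail of the standard normal (alternative hypothesis: dN > dS, positive
#' selection).
#'
#' @param dN,dS distance estimates per nonsynonymous / synonymous site.
#' @param varN,varS their variances (both >= 0).
#' @return list with \code{Z}, \code{p_one_tailed} and \code{infinite}
#'   (TRUE when the variance is zero but dN != dS).
#' @examples
#' z_test(0.10, 0.02, 0.0008, 0.0008)  # Z = 2, p ~ 0.0228
#' @export
z_test <- function(dN, dS, varN, varS) {
  if (varN < 0 || varS < 0) stop("variances must be nonnegative")
  v <- varN + varS
  if (v == 0) {
    if (dN == dS) return(list(Z = 0, p_one_tailed = 0.5, infinite = FALSE))
    return(list(Z = sign(dN - dS) * Inf,
                p_one_tailed = if (dN > dS) 0 else 1, infinite = TRUE))
  }
  Z <- (dN - dS) / sqrt(v)
  list(Z = Z, p_one_tailed = stats::pnorm(Z, lower.tail = FALSE),
       infinite = FALSE)
}

# evaluate expr under a local RNG seed without disturbing the caller's stream
.with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
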