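#' Per-column deltaN / deltaS selection profile over tree branches
#'
#' For every branch (parent, child) of a rooted tree whose nodes all carry
#' sequences (tips from the alignment, internal nodes from an ancestral
#' reconstruction), accumulates NG86 pathway-averaged synonymous and
#' nonsynonymous differences and averaged site counts per codon column. Per
#' column, deltaS = sum(Sd)/sum(S-sites) (synonymous changes per silent
#' site) and deltaN = sum(Nd)/sum(N-sites) (nonsynonymous changes per
#' replacement site); deltaN - deltaS > 0 marks positions under positive
#' selection pressure. A codon-based Z-test per column uses
#' bootstrap-over-branches variances.
#'
#' @param alignment a \code{codon_alignment} whose names cover the tips.
#' @param tree rooted \code{phylo} with node labels (see
#'   \code{\link{ensure_node_labels}}).
#' @param ancestors named character vector of internal-node nucleotide
#'   sequences (names = node labels), or an \code{ancestral_states} object.
#' @param code a \code{genetic_code}.
#' @param branches \code{"all"} aggregates over every tree branch;
#'   \code{"root_to_tips"} instead compares the root sequence with each
#'   extant tip directly.
#' @param n_boot bootstrap-over-branches replicates for the per-column
#'   Z-test variances (0 disables the test).
#' @param seed integer seed for the bootstrap.
#' @return a \code{site_selection_profile}: data.frame with one row per
#'   codon column (\code{column}, \code{deltaN}, \code{deltaS},
#'   \code{deltaN_minus_deltaS}, \code{n_branches_informative}, \code{Z},
#'   \code{p_one_tailed}). Columns informative on no branch carry NA, never
#'   a fabricated zero.
#' @export
site_profile <- function(alignment, tree, ancestors,
                         code = genetic_code(),
                         branches = c("all", "root_to_tips"),
                         n_boot = 200L, seed = 1L) {
  branches <- match.arg(branches)
  stopifnot(inherits(alignment, "codon_alignment"))
  tree <- ensure_node_labels(tree)
  if (inherits(ancestors, "ancestral_states")) ancestors <- ancestors$sequences
  seqs <- .bind_node_sequences(tree, alignment, ancestors)
  ncol <- alignment$n_columns

  labs <- .node_labels(tree)
  if (branches == "all") {
    pairs <- cbind(labs[tree$edge[, 1L]], labs[tree$edge[, 2L]])
  } else {
    ntip <- length(tree$tip.label)
    root_lab <- labs[ntip + 1L]
    pairs <- cbind(rep(root_lab, ntip), tree$tip.label)
  }
  nb <- nrow(pairs)
  Sd <- Nd <- Sbar <- Nbar <- matrix(0, nb, ncol)
  usable <- matrix(FALSE, nb, ncol)
  for (k in seq_len(nb)) {
    per <- .ng_per_column(split_codons(seqs[[pairs[k, 1L]]]),
                          split_codons(seqs[[pairs[k, 2L]]]), code)
    Sd[k, ] <- per$Sd; Nd[k, ] <- per$Nd
    Sbar[k, ] <- per$Sbar; Nbar[k, ] <- per$Nbar
    usable[k, ] <- per$usable
  }

  prof <- .profile_from_counts(Sd, Nd, Sbar, Nbar, usable)
  Z <- p1 <- rep(NA_real_, ncol)
  if (n_boot > 0L && nb > 1L) {
    boot <- .with_seed(seed, {
      bn <- array(NA_real_, c(n_boot, ncol, 2L))
      for (r in seq_len(n_boot)) {
        idx <- sample.int(nb, nb, replace = TRUE)
        p <- .profile_from_counts(Sd[idx, , drop = FALSE],
                                  Nd[idx, , drop = FALSE],
                                  Sbar[idx, , drop = FALSE],
                                  Nbar[idx, , drop = FALSE],
                                  usable[idx, , drop = FALSE])
        bn[r, , 1L] <- p$deltaS
        bn[r, , 2L] <- p$deltaN
      }
      bn
    })
    for (j in seq_len(ncol)) {
      if (is.na(prof$deltaN[j])) next
      vS <- stats::var(boot[, j, 1L], na.rm = TRUE)
      vN <- stats::var(boot[, j, 2L], na.rm = TRUE)
      if (is.na(vS) || is.na(vN)) next
      zt <- z_test(prof$deltaN[j], prof$deltaS[j], vN, vS)
      Z[j] <- zt$Z; p1[j] <- zt$p_one_tailed
    }
  }

  out <- data.frame(column = seq_len(ncol),
                    deltaN = prof$deltaN, deltaS = prof$deltaS,
                    deltaN_minus_deltaS = prof$deltaN - prof$deltaS,
                    n_branches_informative = prof$n_informative,
                    Z = Z, p_one_tailed = p1)
  class(out) <- c("site_selection_profile", "data.frame")
  attr(out, "branches") <- branches
  attr(out, "n_branch_pairs") <- nb
  out
}

.profile_from_counts <- function(Sd, Nd, Sbar, Nbar, usable) {
  SdU <- Sd * usable; NdU <- Nd * usable
  SbU <- Sbar * usable; NbU <- Nbar * usable
  n_informative <- colSums(usable)
  totS <- colSums(SbU); totN <- colSums(NbU)
  deltaS <- ifelse(totS > 0, colSums(SdU) / totS, NA_real_)
  deltaN <- ifelse(totN > 0, colSums(NdU) / totN, NA_real_)
  deltaS[n_informative == 0L] <- NA_real_
  deltaN[n_informative == 0L] <- NA_real_
  list(deltaS = deltaS, deltaN = deltaN, n_informative = n_informative)
}

# resolve one sequence per tree node; errors name the missing node
.bind_node_sequences <- function(tree, alignment, ancestors) {
  labs <- .node_labels(tree)
  seqs <- vector("list", length(labs))
  names(seqs) <- labs
  for (tip in tree$tip.label) {
    if (!tip %in% names(alignment$seqs))
      stop("tip '", tip, "' has no row in the alignment")
    seqs[[tip]] <- alignment$seqs[[tip]]
  }
  for (lab in tree$node.label) {
    if (!lab %in% names(ancestors))
      stop("internal node '", lab, "' has no reconstructed sequence")
    seqs[[lab]] <- toupper(ancestors[[lab]])
  }
  len <- unique(nchar(unlist(seqs)))
  if (length(len) != 1L)
    stop("node sequences have unequal lengths")
  seqs
}

#' @export
print.site_selection_profile <- function(x, ...) {
  pos <- sum(x$deltaN_minus_deltaS > 0, na.rm = TRUE)
  cat("Site selection profile: ", nrow(x), " codon columns over ",
      attr(x, "n_branch_pairs"), " branch pairs (",
      attr(x, "branches"), ")\n", sep = "")
  cat("  columns with deltaN - deltaS > 0: ", pos, "\n", sep = "")
  invisible(x)
}

#' Count columns under apparent positive selection
#'
#' @param profile a \code{site_selection_profile}.
#' @return list with \code{n_positive} (columns with deltaN - deltaS > 0),
#'   \code{n_total} (all aligned codon columns) and \code{fraction}.
#' @export
summarize_positive_sites <- function(profile) {
  stopifnot(inherits(profile, "site_selection_profile"))
  n_pos <- sum(profile$deltaN_minus_deltaS > 0, na.rm = TRUE)
  n_tot <- nrow(profile)
  list(n_positive = n_pos, n_total = n_tot,
       fraction = if (n_tot > 0) n_pos / n_tot else NA_real_)
}
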