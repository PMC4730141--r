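#' Evolve a codon alignment on a tree with planted selection regimes
#'
#' Simulates codon substitution column by column down the tree. Nucleotide
#' changes are proposed under the spec's GTR mutation process (rate 1 per
#' site); synonymous changes proceed at the full mutation rate, a
#' nonsynonymous change at omega times it (the column's regime), and
#' changes creating a stop codon are rejected (rate zero). True internal-node
#' sequences and the full accepted-event log are recorded as ground truth.
#'
#' @param tree rooted \code{phylo} with branch lengths and node labels
#'   (typically from \code{\link{generate_tree}}).
#' @param spec a \code{simulation_spec}.
#' @param code a \code{genetic_code}.
#' @return list with \code{alignment} (a \code{codon_alignment} over the
#'   tips) and \code{ground_truth}: \code{true_ancestral_sequences} (named
#'   by internal-node label), \code{true_column_regime},
#'   \code{event_log} (data.frame: parent, child, column, position,
#'   from, to, type = syn/nonsyn) and \code{root_sequence}.
#' @export
evolve_codon_alignment <- function(tree, spec, code = genetic_code()) {
  stopifnot(inherits(spec, "simulation_spec"))
  tree <- ensure_node_labels(tree)
  if (length(tree$tip.label) < 3L) stop("tree must have >= 3 leaves")
  regimes <- column_regimes(spec)
  omega <- c(hotspot = spec$omega_hotspot,
             background = spec$omega_background,
             conserved = spec$omega_conserved)[regimes]
  m <- subst_model(spec$exchangeabilities, spec$base_frequencies)
  Q <- m$Q
  bases <- c("A", "C", "G", "T")

  .with_seed(spec$seed + 1L, {
    root_codons <- .sample_sense_codons(spec$n_columns,
                                        spec$base_frequencies, code)
    ntip <- length(tree$tip.label)
    labs <- .node_labels(tree)
    node_seq <- vector("list", ntip + tree$Nnode)
    root_id <- ntip + 1L
    node_seq[[root_id]] <- root_codons

    log_rows <- list()
    edges <- ape::reorder.phylo(tree, "postorder")$edge
    elen <- ape::reorder.phylo(tree, "postorder")$edge.length
    for (e in rev(seq_len(nrow(edges)))) {   # preorder: parent first
      par <- edges[e, 1L]; child <- edges[e, 2L]
      cods <- node_seq[[par]]
      blen <- elen[e]
      for (col in seq_len(spec$n_columns)) {
        sim <- .evolve_codon(cods[col], blen, omega[col], Q, code, bases)
        cods[col] <- sim$codon
        if (nrow(sim$events) > 0L) {
          sim$events$parent <- labs[par]
          sim$events$child <- labs[child]
          sim$events$column <- col
          log_rows[[length(log_rows) + 1L]] <- sim$events
        }
      }
      node_seq[[child]] <- cods
    }

    leaf_seqs <- vapply(seq_len(ntip),
                        function(i) paste(node_seq[[i]], collapse = ""), "")
    names(leaf_seqs) <- tree$tip.label
    anc <- vapply((ntip + 1L):(ntip + tree$Nnode),
                  function(i) paste(node_seq[[i]], collapse = ""), "")
    names(anc) <- tree$node.label
    ev <- if (length(log_rows) > 0L) do.call(rbind, log_rows)
          else data.frame(position = integer(), from = character(),
                          to = character(), type = character(),
                          parent = character(), child = character(),
                          column = integer())
    list(alignment = codon_alignment(leaf_seqs),
         ground_truth = list(
           true_ancestral_sequences = anc,
           true_column_regime = regimes,
           event_log = ev[, c("parent", "child", "column", "position",
                              "from", "to", "type")],
           root_sequence = paste(root_codons, collapse = "")))
  })
}

# Gillespie walk for one codon along one branch. Each of the nine
# single-nucleotide neighbours gets rate = GTR mutation rate x (0 for
# stops, 1 for synonymous, omega for nonsynonymous); equivalent to
# stop-rejection thinning with synonymous acceptance 1 and nonsynonymous
# acceptance omega, and well-defined for omega > 1.
.evolve_codon <- function(codon, blen, omega, Q, code, bases) {
  nt <- match(strsplit(codon, "")[[1]], bases)
  t <- 0
  ev <- list()
  repeat {
    cur_aa <- code$table[[paste(bases[nt], collapse = "")]]
    pos_v <- rep(1:3, each = 3L)
    to_v <- integer(9L); rate <- numeric(9L); syn_v <- logical(9L)
    k <- 0L
    for (pos in 1:3) {
      from <- nt[pos]
      for (to in seq_len(4L)[-from]) {
        k <- k + 1L
        cand <- nt; cand[pos] <- to
        cand_codon <- paste(bases[cand], collapse = "")
        to_v[k] <- to
        if (cand_codon %in% code$stops) { rate[k] <- 0; next }
        syn_v[k] <- code$table[[cand_codon]] == cur_aa
        rate[k] <- Q[from, to] * if (syn_v[k]) 1 else omega
      }
    }
    R <- sum(rate)
    if (R <= 0) break
    t <- t + stats::rexp(1L, R)
    if (t > blen) break
    j <- sample.int(9L, 1L, prob = rate)
    pos <- pos_v[j]
    ev[[length(ev) + 1L]] <- data.frame(
      position = pos, from = bases[nt[pos]], to = bases[to_v[j]],
      type = if (syn_v[j]) "syn" else "nonsyn")
    nt[pos] <- to_v[j]
  }
  list(codon = paste(bases[nt], collapse = ""),
       events = if (length(ev) > 0L) do.call(rbind, ev)
                else data.frame(position = integer(), from = character(),
                                to = character(), type = character()))
}

.sample_sense_codons <- function(n, pi, code) {
  bases <- c("A", "C", "G", "T")
  out <- character(n)
  for (i in seq_len(n)) {
    repeat {
      cod <- paste(sample(bases, 3L, replace = TRUE, prob = pi),
                   collapse = "")
      if (!(cod %in% code$stops)) break
    }
    out[i] <- cod
  }
  out
}
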