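#' Marginal ancestral state reconstruction (maximum a posteriori)
#'
#' For every internal node and alignment column, computes the marginal
#' posterior over the four bases by the standard up-down (outside-inside)
#' pass: posterior proportional to (partial likelihood of the subtree below
#' the node) times (partial likelihood of the rest of the tree), mixed over
#' rate categories by their likelihood contribution. The MAP base is the
#' posterior argmax with ties broken in fixed A < C < G < T order.
#'
#' @inheritParams log_likelihood
#' @return an \code{ancestral_states} object: list with \code{posteriors}
#'   (list per internal node label of 4 x n_sites matrices, rows A,C,G,T,
#'   columns summing to 1), \code{map_sequences} (named character vector of
#'   MAP nucleotide strings), \code{sequences} (MAP sequences with any stop
#'   codon repaired to the best-posterior sense codon; see
#'   \code{\link{assemble_codon_ancestors}}), \code{n_stop_repaired},
#'   \code{log_likelihood} and the tree used (with node labels).
#' @export
marginal_asr <- function(tree, alignment, model, code = genetic_code()) {
  tree <- ensure_node_labels(tree)
  d <- .likelihood_data(tree, alignment)
  K <- length(model$rates)
  ntip <- d$ntip
  n_int <- tree$Nnode
  S <- ncol(d$patterns)
  pi <- model$base_frequencies

  # joint (node state, category) weights per site, unscaled per category
  post <- vector("list", n_int)     # each 4 x S accumulated over categories
  for (i in seq_len(n_int)) post[[i]] <- matrix(0, 4, S)
  site_lik <- numeric(S)

  edges <- d$postorder$edge
  for (k in seq_len(K)) {
    pr <- .prune(tree, d, model, model$rates[k], scale = FALSE)
    up <- vector("list", ntip + n_int)
    up[[d$root]] <- matrix(pi, 4, S)
    # preorder: parents before children
    for (e in rev(seq_len(nrow(edges)))) {
      par <- edges[e, 1L]; child <- edges[e, 2L]
      if (child <= ntip) next
      A <- up[[par]]
      sib_edges <- which(edges[, 1L] == par & edges[, 2L] != child)
      for (se in sib_edges)
        A <- A * (pr$P[[se]] %*% pr$partials[[edges[se, 2L]]])
      up[[child]] <- crossprod(pr$P[[e]], A)
    }
    w <- model$weights[k]
    for (i in seq_len(n_int)) {
      node <- ntip + i
      post[[i]] <- post[[i]] + w * up[[node]] * pr$partials[[node]]
    }
    site_lik <- site_lik + w * colSums(pi * pr$partials[[d$root]])
  }
  logL <- sum(log(site_lik) * d$weights)

  bases <- c("A", "C", "G", "T")
  posteriors <- vector("list", n_int)
  map_seqs <- character(n_int)
  for (i in seq_len(n_int)) {
    p <- sweep(post[[i]], 2L, colSums(post[[i]]), "/")
    full <- p[, d$site_map, drop = FALSE]   # expand patterns to sites
    rownames(full) <- bases
    posteriors[[i]] <- full
    map_seqs[i] <- paste(bases[apply(full, 2L, which.max)], collapse = "")
  }
  names(posteriors) <- tree$node.label
  names(map_seqs) <- tree$node.label

  out <- structure(list(posteriors = posteriors,
                        map_sequences = map_seqs,
                        tree = tree, log_likelihood = logL),
                   class = "ancestral_states")
  rep <- assemble_codon_ancestors(out, code)
  out$sequences <- rep$sequences
  out$n_stop_repaired <- rep$n_repaired
  out
}

#' @export
print.ancestral_states <- function(x, ...) {
  cat("Ancestral states: ", length(x$posteriors), " internal nodes x ",
      nchar(x$map_sequences[[1]]), " sites; logL = ",
      format(x$log_likelihood, digits = 8), "\n", sep = "")
  if (x$n_stop_repaired > 0)
    cat("  stop codons repaired in assembled ancestors: ",
        x$n_stop_repaired, "\n", sep = "")
  invisible(x)
}

#' Assemble codon ancestral sequences from per-base posteriors
#'
#' MAP bases are taken in codon triples; a triple forming a stop codon is
#' replaced by the sense codon with the highest posterior product
#' (deterministic search order: codons ranked by probability, ties by
#' alphabetical codon order).
#'
#' @param states an \code{ancestral_states} object.
#' @param code a \code{genetic_code}.
#' @return list with \code{sequences} (named character vector) and
#'   \code{n_repaired} (count of repaired stop codons over all nodes).
#' @export
assemble_codon_ancestors <- function(states, code = genetic_code()) {
  stopifnot(inherits(states, "ancestral_states"))
  bases <- c("A", "C", "G", "T")
  n_rep <- 0L
  seqs <- states$map_sequences
  for (nm in names(seqs)) {
    s <- seqs[[nm]]
    if (nchar(s) %% 3L != 0L) next    # not a coding alignment; leave as-is
    cods <- split_codons(s)
    bad <- which(cods %in% code$stops)
    if (length(bad) == 0L) next
    p <- states$posteriors[[nm]]
    for (j in bad) {
      cols <- (3L * (j - 1L) + 1L):(3L * j)
      combos <- expand.grid(b3 = 1:4, b2 = 1:4, b1 = 1:4)[, 3:1]
      cand <- apply(combos, 1L, function(ix)
        paste(bases[as.integer(ix)], collapse = ""))
      score <- apply(combos, 1L, function(ix)
        p[ix[[1]], cols[1]] * p[ix[[2]], cols[2]] * p[ix[[3]], cols[3]])
      ord <- order(-score, cand)
      pick <- cand[ord][.is_sense(cand[ord], code)][1L]
      cods[j] <- pick
      n_rep <- n_rep + 1L
    }
    seqs[[nm]] <- paste(cods, collapse = "")
  }
  list(sequences = seqs, n_repaired = n_rep)
}
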