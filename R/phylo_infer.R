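#' Pairwise maximum-likelihood distance under the substitution model
#'
#' Optimises the branch length separating two sequences under the GTR
#' (+Gamma+I) model with stationary start, by one-dimensional likelihood
#' maximisation.
#'
#' @param seq_a,seq_b nucleotide strings of equal length.
#' @param model a \code{subst_model}.
#' @param max_dist upper search bound (expected substitutions/site).
#' @return nonnegative ML distance estimate.
#' @export
ml_distance <- function(seq_a, seq_b, model, max_dist = 10) {
  code <- c(A = 1L, C = 2L, G = 3L, T = 4L)
  a <- code[strsplit(toupper(seq_a), "")[[1]]]
  b <- code[strsplit(toupper(seq_b), "")[[1]]]
  ok <- !is.na(a) & !is.na(b)
  a <- a[ok]; b <- b[ok]
  if (length(a) == 0L) return(0)
  if (all(a == b)) return(0)
  pi <- model$base_frequencies
  nll <- function(t) {
    l <- 0
    for (k in seq_along(model$rates)) {
      P <- prob_matrix(model, t, model$rates[k])
      l <- l + model$weights[k] * pi[a] * P[cbind(a, b)]
    }
    -sum(log(pmax(l, 1e-300)))
  }
  opt <- stats::optimize(nll, c(1e-8, max_dist))
  # accept 0 when the boundary beats the interior optimum
  if (nll(1e-9) <= opt$objective) return(0)
  opt$minimum
}

#' Neighbor-joining tree from model-based ML distances
#'
#' Computes all pairwise ML distances, applies neighbor joining, clamps any
#' negative branch lengths to zero and midpoint-roots the result.
#'
#' @param alignment a \code{codon_alignment} or named character vector.
#' @param model a \code{subst_model}.
#' @return rooted \code{phylo} with stable internal-node labels.
#' @export
build_nj_tree <- function(alignment, model) {
  seqs <- if (inherits(alignment, "codon_alignment")) alignment$seqs
          else toupper(vapply(alignment, as.character, ""))
  n <- length(seqs)
  if (n < 3L) stop("need at least 3 sequences")
  D <- matrix(0, n, n, dimnames = list(names(seqs), names(seqs)))
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    D[i, j] <- D[j, i] <- ml_distance(seqs[[i]], seqs[[j]], model)
  }
  tr <- ape::nj(as.dist(D))
  tr$edge.length[tr$edge.length < 0] <- 0
  tr <- phangorn::midpoint(tr)
  tr$node.label <- NULL                 # drop midpoint's empty labels
  ensure_node_labels(tr)
}

#' Nonparametric bootstrap support for NJ tree splits
#'
#' Resamples alignment columns (nucleotides) with replacement, rebuilds the
#' NJ tree for each replicate, and reports the percentage of replicates
#' containing each internal split of the point-estimate tree (compared as
#' unrooted bipartitions).
#'
#' @param alignment a \code{codon_alignment} or named character vector.
#' @param model a \code{subst_model}.
#' @param n_reps bootstrap replicate count.
#' @param seed integer seed.
#' @return list with \code{tree} (the point-estimate tree), \code{support}
#'   (named numeric vector, percent, by internal-node label) and
#'   \code{n_reps}.
#' @export
bootstrap_support <- function(alignment, model, n_reps = 100L, seed = 1L) {
  stopifnot(n_reps >= 1L)
  seqs <- if (inherits(alignment, "codon_alignment")) alignment$seqs
          else toupper(vapply(alignment, as.character, ""))
  pt <- build_nj_tree(seqs, model)
  chars <- lapply(seqs, function(s) strsplit(s, "")[[1]])
  L <- length(chars[[1]])
  boots <- .with_seed(seed, {
    lapply(seq_len(n_reps), function(r) {
      idx <- sample.int(L, L, replace = TRUE)
      rs <- vapply(chars, function(v) paste(v[idx], collapse = ""), "")
      build_nj_tree(rs, model)
    })
  })
  counts <- ape::prop.clades(pt, boots, rooted = FALSE)
  counts[is.na(counts)] <- 0L
  support <- 100 * counts / n_reps
  names(support) <- pt$node.label
  list(tree = pt, support = support, n_reps = n_reps)
}

#' Fit GTR+Gamma+I parameters on a fixed tree
#'
#' Maximises the pruning log-likelihood over the six exchangeabilities (GT
#' fixed at 1 for identifiability), the gamma shape and the invariant-site
#' proportion, with empirical base frequencies, by bounded quasi-Newton
#' (L-BFGS-B on transformed parameters).
#'
#' @param alignment a \code{codon_alignment} or named character vector.
#' @param tree rooted \code{phylo} with branch lengths.
#' @param n_rate_categories discrete-gamma categories.
#' @param fit_invariant also fit the invariant-site proportion.
#' @return list with \code{model} (fitted \code{subst_model}),
#'   \code{log_likelihood}, and \code{converged} (FALSE flags the
#'   best-so-far result of a non-converged optimiser run).
#' @export
fit_model <- function(alignment, tree, n_rate_categories = 4L,
                      fit_invariant = TRUE) {
  seqs <- if (inherits(alignment, "codon_alignment")) alignment$seqs
          else toupper(vapply(alignment, as.character, ""))
  if (length(seqs) == 0L || nchar(seqs[[1]]) == 0L) stop("empty alignment")
  tab <- table(factor(unlist(strsplit(toupper(unlist(seqs)), "")),
                      levels = c("A", "C", "G", "T")))
  pi <- (as.numeric(tab) + 0.5) / sum(as.numeric(tab) + 0.5)

  mk <- function(par) {
    r <- c(exp(par[1:5]), 1)
    shape <- exp(par[6])
    pinv <- if (fit_invariant) stats::plogis(par[7]) * 0.99 else 0
    subst_model(r, pi, gamma_shape = shape,
                n_rate_categories = n_rate_categories, p_invariant = pinv)
  }
  nll <- function(par) {
    m <- try(mk(par), silent = TRUE)
    if (inherits(m, "try-error")) return(1e10)
    ll <- try(log_likelihood(tree, seqs, m), silent = TRUE)
    if (inherits(ll, "try-error") || !is.finite(ll)) return(1e10)
    -ll
  }
  p0 <- c(rep(0, 5), 0, if (fit_invariant) -2 else NULL)
  opt <- stats::optim(p0, nll, method = "L-BFGS-B",
                      lower = rep(-8, length(p0)),
                      upper = rep(8, length(p0)),
                      control = list(maxit = 200))
  list(model = mk(opt$par), log_likelihood = -opt$value,
       converged = opt$convergence == 0L)
}
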