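#' Felsenstein pruning log-likelihood on a fixed rooted tree
#'
#' Computes the GTR+Gamma(+I) log-likelihood of a nucleotide alignment on a
#' rooted tree with branch lengths, mixing over rate categories per site.
#' Non-ACGT characters (gaps, ambiguities) contribute a partial likelihood
#' of 1 in all states.
#'
#' @param tree rooted \code{phylo}; branch lengths in expected
#'   substitutions/site; tip labels must match alignment names.
#' @param alignment a \code{codon_alignment} or named character vector of
#'   equal-length nucleotide strings.
#' @param model a \code{subst_model}.
#' @return total log-likelihood (natural log).
#' @export
log_likelihood <- function(tree, alignment, model) {
  d <- .likelihood_data(tree, alignment)
  K <- length(model$rates)
  site_log <- matrix(NA_real_, K, ncol(d$patterns))
  for (k in seq_len(K)) {
    pr <- .prune(tree, d, model, model$rates[k])
    root_part <- pr$partials[[d$root]]
    lik <- colSums(model$base_frequencies * root_part)
    site_log[k, ] <- log(lik) + pr$logscale
  }
  w <- log(model$weights)
  persite <- apply(site_log + w, 2L, .logsumexp)
  sum(persite * d$weights)
}

.logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# encode alignment to integer patterns; 0 = missing/ambiguous
.likelihood_data <- function(tree, alignment) {
  stopifnot(inherits(tree, "phylo"))
  if (inherits(alignment, "codon_alignment")) seqs <- alignment$seqs
  else seqs <- toupper(vapply(alignment, as.character, ""))
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")
  if (any(tree$edge.length < 0)) stop("negative branch length")
  miss <- setdiff(tree$tip.label, names(seqs))
  if (length(miss) > 0L)
    stop("tips without alignment rows: ", paste(miss, collapse = ", "))
  ntip <- length(tree$tip.label)
  len <- unique(nchar(seqs[tree$tip.label]))
  if (length(len) != 1L) stop("alignment rows have unequal lengths")
  code <- c(A = 1L, C = 2L, G = 3L, T = 4L)
  X <- matrix(vapply(tree$tip.label, function(nm) {
    v <- code[strsplit(seqs[[nm]], "")[[1]]]
    v[is.na(v)] <- 0L
    v
  }, integer(len)), nrow = len)
  X <- t(X)  # ntip x sites
  # pattern compression
  key <- apply(X, 2L, paste, collapse = ",")
  uk <- unique(key)
  map <- match(key, uk)
  patterns <- X[, match(uk, key), drop = FALSE]
  weights <- tabulate(map, nbins = length(uk))
  po <- ape::reorder.phylo(tree, "postorder")
  list(patterns = patterns, weights = weights, site_map = map,
       n_sites = len, ntip = ntip, root = ntip + 1L, postorder = po)
}

# one pruning pass at a fixed relative rate; per-site scaling at internal nodes
.prune <- function(tree, d, model, rate, scale = TRUE) {
  S <- ncol(d$patterns)
  ntip <- d$ntip
  nnode <- ntip + tree$Nnode
  partials <- vector("list", nnode)
  for (i in seq_len(ntip)) {
    M <- matrix(0, 4, S)
    x <- d$patterns[i, ]
    obs <- x > 0L
    M[cbind(x[obs], which(obs))] <- 1
    M[, !obs] <- 1
    partials[[i]] <- M
  }
  logscale <- numeric(S)
  edges <- d$postorder$edge
  elen <- d$postorder$edge.length
  Plist <- lapply(seq_len(nrow(edges)),
                  function(e) prob_matrix(model, elen[e], rate))
  for (e in seq_len(nrow(edges))) {
    par <- edges[e, 1L]; child <- edges[e, 2L]
    contrib <- Plist[[e]] %*% partials[[child]]
    if (is.null(partials[[par]])) partials[[par]] <- contrib
    else partials[[par]] <- partials[[par]] * contrib
  }
  # rescale root partials only (trees handled here are moderate-sized);
  # guard against total underflow
  mx <- apply(partials[[d$root]], 2L, max)
  # a category may contribute zero at a site (e.g. the invariant class at a
  # variable column): keep the zero, the category mixture absorbs it
  mx[mx == 0] <- 1
  if (scale) {
    partials[[d$root]] <- sweep(partials[[d$root]], 2L, mx, "/")
    logscale <- logscale + log(mx)
  }
  list(partials = partials, logscale = logscale, P = Plist)
}
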