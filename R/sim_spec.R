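#' Specification for a synthetic evolutionary scenario
#'
#' Describes the tree and the planted per-column selection regimes used by
#' \code{\link{generate_tree}} and \code{\link{evolve_codon_alignment}}.
#' Columns not listed as hotspot or conserved evolve at
#' \code{omega_background}.
#'
#' @param n_leaves number of extant taxa (>= 3).
#' @param tree_shape \code{"yule"} (stochastic birth process) or
#'   \code{"balanced"}.
#' @param total_tree_length sum of branch lengths, expected
#'   substitutions/site.
#' @param n_columns codon column count.
#' @param hotspot_columns 1-based column indices under positive selection.
#' @param conserved_columns 1-based column indices under purifying
#'   selection; disjoint from the hotspots.
#' @param omega_hotspot nonsynonymous/synonymous acceptance ratio for
#'   hotspot columns (> 1 plants positive selection).
#' @param omega_background ratio for background columns.
#' @param omega_conserved ratio for conserved columns (>= 0; 0 forbids all
#'   amino-acid change).
#' @param base_frequencies 4 proportions (A, C, G, T).
#' @param exchangeabilities 6 GTR exchangeabilities for the mutation process.
#' @param seed integer seed.
#' @return object of class \code{simulation_spec}.
#' @export
simulation_spec <- function(n_leaves = 8L,
                            tree_shape = c("yule", "balanced"),
                            total_tree_length = 1.5,
                            n_columns = 220L,
                            hotspot_columns = integer(),
                            conserved_columns = integer(),
                            omega_hotspot = 5,
                            omega_background = 0.2,
                            omega_conserved = 0,
                            base_frequencies = rep(0.25, 4),
                            exchangeabilities = rep(1, 6),
                            seed = 1L) {
  tree_shape <- match.arg(tree_shape)
  if (n_leaves < 3L) stop("invalid spec: n_leaves must be >= 3")
  if (total_tree_length < 0) stop("invalid spec: negative tree length")
  if (n_columns < 1L) stop("invalid spec: n_columns must be >= 1")
  hotspot_columns <- as.integer(hotspot_columns)
  conserved_columns <- as.integer(conserved_columns)
  idx <- c(hotspot_columns, conserved_columns)
  if (length(idx) > 0 && (min(idx) < 1L || max(idx) > n_columns))
    stop("invalid spec: column indices must lie in [1, n_columns]")
  if (length(intersect(hotspot_columns, conserved_columns)) > 0L)
    stop("invalid spec: hotspot and conserved column sets must be disjoint")
  if (omega_hotspot <= 0 || omega_background <= 0)
    stop("invalid spec: omega values must be > 0 (omega_conserved may be 0)")
  if (omega_conserved < 0)
    stop("invalid spec: omega_conserved must be >= 0")
  pi <- as.numeric(base_frequencies)
  if (length(pi) != 4L || abs(sum(pi) - 1) > 1e-12 || any(pi <= 0))
    stop("invalid spec: base frequencies must be 4 proportions summing to 1")
  structure(list(n_leaves = as.integer(n_leaves), tree_shape = tree_shape,
                 total_tree_length = total_tree_length,
                 n_columns = as.integer(n_columns),
                 hotspot_columns = hotspot_columns,
                 conserved_columns = conserved_columns,
                 omega_hotspot = omega_hotspot,
                 omega_background = omega_background,
                 omega_conserved = omega_conserved,
                 base_frequencies = pi,
                 exchangeabilities = as.numeric(exchangeabilities),
                 seed = as.integer(seed)),
            class = "simulation_spec")
}

#' @export
print.simulation_spec <- function(x, ...) {
  cat("Simulation spec: ", x$n_leaves, " leaves (", x$tree_shape,
      "), tree length ", x$total_tree_length, ", ", x$n_columns,
      " codon columns\n", sep = "")
  cat("  hotspots: ", length(x$hotspot_columns), " (omega ",
      x$omega_hotspot, "), conserved: ", length(x$conserved_columns),
      " (omega ", x$omega_conserved, "), background omega ",
      x$omega_background, "\n", sep = "")
  invisible(x)
}

#' Column regime labels for a simulation spec
#' @param spec a \code{simulation_spec}.
#' @return character vector of length \code{n_columns} with values
#'   \code{"hotspot"}, \code{"background"}, \code{"conserved"}.
#' @export
column_regimes <- function(spec) {
  reg <- rep("background", spec$n_columns)
  reg[spec$hotspot_columns] <- "hotspot"
  reg[spec$conserved_columns] <- "conserved"
  reg
}

#' Generate a rooted binary tree for a simulation spec
#'
#' Yule trees are grown as a pure-birth process; balanced trees split taxa
#' as evenly as possible with unit branch lengths. Branch lengths are
#' rescaled so their sum equals \code{total_tree_length}.
#'
#' @param spec a \code{simulation_spec}.
#' @return rooted binary \code{phylo} with node labels; tips
#'   \code{t1..tn}.
#' @export
generate_tree <- function(spec) {
  stopifnot(inherits(spec, "simulation_spec"))
  n <- spec$n_leaves
  tr <- .with_seed(spec$seed, {
    if (spec$tree_shape == "yule") {
      t0 <- ape::rphylo(n, birth = 1, death = 0)
    } else {
      t0 <- .balanced_tree(n)
    }
    t0
  })
  tr$tip.label <- paste0("t", seq_len(n))
  tot <- sum(tr$edge.length)
  if (tot > 0) tr$edge.length <- tr$edge.length * spec$total_tree_length / tot
  else tr$edge.length <- rep(spec$total_tree_length / length(tr$edge.length),
                             length(tr$edge.length))
  if (spec$total_tree_length == 0) tr$edge.length[] <- 0
  ensure_node_labels(tr)
}

# balanced topology by recursive halving, unit branch lengths
.balanced_tree <- function(n) {
  newick <- function(k, off) {
    if (k == 1L) return(sprintf("t%d:1", off))
    left <- k %/% 2L
    sprintf("(%s,%s):1", newick(left, off), newick(k - left, off + left))
  }
  s <- sprintf("(%s,%s);", newick(n %/% 2L, 0L),
               newick(n - n %/% 2L, n %/% 2L))
  tr <- ape::read.tree(text = s)
  tr$tip.label <- paste0("t", seq_len(n))
  tr
}
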