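#' Codon alignment container
#'
#' A named set of aligned, in-frame nucleotide sequences addressed by 1-based
#' codon columns.
#'
#' @param seqs named character vector of equal-length nucleotide strings,
#'   each length divisible by 3.
#' @return object of class \code{codon_alignment}.
#' @export
codon_alignment <- function(seqs) {
  if (is.null(names(seqs)) || anyNA(names(seqs)) || any(names(seqs) == ""))
    stop("all sequences must be named")
  if (anyDuplicated(names(seqs)))
    stop("duplicate sequence names")
  seqs <- toupper(vapply(seqs, as.character, ""))
  len <- unique(nchar(seqs))
  if (length(len) != 1L)
    stop("sequences have unequal lengths: ", paste(len, collapse = ", "))
  if (len %% 3L != 0L)
    stop("alignment length ", len, " is not divisible by 3")
  structure(list(seqs = seqs, n_columns = len %/% 3L),
            class = "codon_alignment")
}

#' @export
print.codon_alignment <- function(x, ...) {
  cat("Codon alignment: ", length(x$seqs), " sequences x ",
      x$n_columns, " codon columns\n", sep = "")
  invisible(x)
}

#' Codon matrix view of an alignment
#' @param aln a \code{codon_alignment}.
#' @return character matrix, rows = sequences, columns = codon columns.
#' @export
codon_matrix <- function(aln) {
  stopifnot(inherits(aln, "codon_alignment"))
  m <- t(vapply(aln$seqs, split_codons,
                character(aln$n_columns)))
  if (aln$n_columns == 1L) m <- matrix(m, ncol = 1L,
                                       dimnames = list(names(aln$seqs), NULL))
  m
}

#' Ensure stable internal-node labels on a rooted tree
#'
#' Internal nodes receive labels \code{N1, N2, ...} in postorder (so the root
#' gets the highest number). Existing non-empty labels are kept.
#'
#' @param tree an \code{ape} \code{phylo} object.
#' @return the tree with complete \code{node.label}.
#' @export
ensure_node_labels <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  n_int <- tree$Nnode
  have <- tree$node.label
  if (!is.null(have) && all(!is.na(have)) && all(have != "")) return(tree)
  po <- ape::reorder.phylo(tree, "postorder")
  ntip <- length(tree$tip.label)
  # internal nodes in order of completion during a postorder sweep
  # (a node completes when its last child edge is processed; root is last)
  int_order <- rev(unique(rev(po$edge[, 1L])))
  lab <- character(n_int)
  lab[int_order - ntip] <- paste0("N", seq_len(n_int))
  if (!is.null(have)) {
    keep <- !is.na(have) & have != ""
    lab[keep] <- have[keep]
  }
  tree$node.label <- lab
  tree
}

# named vector node id -> label for all nodes (tips + internal)
.node_labels <- function(tree) {
  ntip <- length(tree$tip.label)
  c(tree$tip.label, tree$node.label)[seq_len(ntip + tree$Nnode)]
}
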