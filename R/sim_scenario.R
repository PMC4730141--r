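#' Wired end-to-end synthetic scenario
#'
#' Builds a complete miniature study in which the planted selection regimes
#' are wired to cavity geometry: a tree, a codon alignment with hotspot and
#' conserved columns, and one cage structure per selected tree node whose
#' shell residues map onto a mix of hotspot, conserved and background
#' columns. Every cavity-lining residue therefore has a known selection
#' regime, so the selection-vs-cavity overlay can be validated against
#' ground truth (hotspot lining columns should surface as positively
#' selected and cavity-forming; conserved lining columns reproduce the
#' conserved-but-cavity-forming signature).
#'
#' @param seed integer master seed.
#' @param n_leaves taxa count.
#' @param n_columns codon columns.
#' @param n_hotspot,n_conserved planted column counts (hotspots are
#'   columns 1..n_hotspot, conserved the following block).
#' @param total_tree_length tree length, expected substitutions/site.
#' @param structure_nodes node labels receiving structures; defaults to the
#'   root, one internal node and one tip.
#' @param cage_radius,n_shell_atoms cage geometry per structure.
#' @return list with \code{spec}, \code{tree}, \code{alignment},
#'   \code{ground_truth}, \code{structures} (named \code{atom_structure}
#'   list) and \code{lined_columns} (the columns wired to shell residues,
#'   split by regime).
#' @export
wired_scenario <- function(seed = 1L, n_leaves = 8L, n_columns = 120L,
                           n_hotspot = 12L, n_conserved = 12L,
                           total_tree_length = 1.5,
                           structure_nodes = NULL,
                           cage_radius = 6, n_shell_atoms = 80L) {
  spec <- simulation_spec(
    n_leaves = n_leaves, total_tree_length = total_tree_length,
    n_columns = n_columns,
    hotspot_columns = seq_len(n_hotspot),
    conserved_columns = n_hotspot + seq_len(n_conserved),
    seed = seed)
  tree <- generate_tree(spec)
  sim <- evolve_codon_alignment(tree, spec)
  if (is.null(structure_nodes)) {
    structure_nodes <- c(tree$node.label[length(tree$node.label)],
                         tree$node.label[1L], tree$tip.label[1L])
  }
  # shell residues map onto all hotspots, all conserved columns, and
  # background columns for the remainder
  n_bg <- n_shell_atoms - n_hotspot - n_conserved
  if (n_bg < 0L) stop("cage too small to host all planted columns")
  bg_cols <- setdiff(seq_len(n_columns),
                     seq_len(n_hotspot + n_conserved))[seq_len(n_bg)]
  wired_cols <- c(seq_len(n_hotspot), n_hotspot + seq_len(n_conserved),
                  bg_cols)
  structures <- list()
  for (i in seq_along(structure_nodes)) {
    ss <- structure_spec("sealed_cage", cage_radius = cage_radius,
                         n_shell_atoms = n_shell_atoms,
                         seed = seed + 100L * i)
    gs <- generate_structure(ss, oracle_samples = 1e4)
    st <- gs$structure
    st$residue_columns <- stats::setNames(wired_cols,
                                          seq_len(n_shell_atoms))
    structures[[structure_nodes[i]]] <- st
  }
  list(spec = spec, tree = tree, alignment = sim$alignment,
       ground_truth = sim$ground_truth, structures = structures,
       lined_columns = list(hotspot = seq_len(n_hotspot),
                            conserved = n_hotspot + seq_len(n_conserved),
                            background = bg_cols))
}
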