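#' Read aligned nucleotide FASTA into a codon alignment
#' @param path FASTA file.
#' @return a \code{codon_alignment}.
#' @export
read_codon_fasta <- function(path) {
  x <- ape::read.FASTA(path)
  seqs <- toupper(vapply(as.character(x), paste, "", collapse = ""))
  codon_alignment(seqs)
}

#' Write named sequences as FASTA
#' @param seqs named character vector (nucleotides) or
#'   \code{codon_alignment}.
#' @param path output file.
#' @export
write_fasta <- function(seqs, path) {
  if (inherits(seqs, "codon_alignment")) seqs <- seqs$seqs
  dna <- ape::as.DNAbin(lapply(seqs, function(s)
    strsplit(tolower(s), "")[[1]]))
  ape::write.FASTA(dna, path)
  invisible(path)
}

#' Write an atom structure as a PDB file
#'
#' ATOM records with occupancy 1.00 and B-factor 0.00; one CA pseudo-atom
#' per atom record, residue name GLY.
#'
#' @param structure an \code{atom_structure}.
#' @param path output file.
#' @export
write_structure_pdb <- function(structure, path) {
  a <- structure$atoms
  lines <- sprintf(
    "ATOM  %5d  CA  GLY %s%4d    %8.3f%8.3f%8.3f  1.00  0.00           %s",
    a$id, substr(a$chain, 1L, 1L), a$residue_index, a$x, a$y, a$z,
    toupper(substr(a$element, 1L, 1L)))
  writeLines(c(lines, "END"), path)
  invisible(path)
}

# van der Waals radii used when a PDB provides element symbols
.element_radii <- c(C = 1.7, N = 1.55, O = 1.52, S = 1.8, SE = 1.9)

#' Read a PDB file into an atom structure
#'
#' Uses bio3d's PDB parser (first alternate location kept). Radii come
#' from a per-element table (C 1.7, N 1.55, O 1.52, S 1.8, Se 1.9) or a
#' uniform value.
#'
#' @param path PDB file.
#' @param uniform_radius single radius overriding the per-element table.
#' @param residue_columns optional named integer vector (residue index ->
#'   alignment column).
#' @return an \code{atom_structure}.
#' @export
read_structure_pdb <- function(path, uniform_radius = NULL,
                               residue_columns = NULL) {
  pdb <- bio3d::read.pdb(path, verbose = FALSE)
  at <- pdb$atom[pdb$atom$type %in% c("ATOM", "HETATM"), , drop = FALSE]
  elem <- toupper(trimws(at$elesy))
  rad <- if (!is.null(uniform_radius)) rep(uniform_radius, nrow(at))
         else ifelse(elem %in% names(.element_radii),
                     .element_radii[elem], 1.8)
  atom_structure(cbind(at$x, at$y, at$z), radius = rad,
                 residue_index = at$resno, element = elem,
                 chain = ifelse(is.na(at$chain), "A", at$chain),
                 residue_columns = residue_columns)
}

#' Write a complete synthetic fixture bundle
#'
#' Writes the alignment (FASTA), the tree (Newick), each structure (PDB),
#' the residue-to-column maps and ground-truth tables (TSV), and a
#' manifest listing every file with its MD5 checksum and the seeds used.
#'
#' @param path output directory (created if needed).
#' @param tree rooted \code{phylo}.
#' @param alignment a \code{codon_alignment}.
#' @param ground_truth the \code{ground_truth} element from
#'   \code{\link{evolve_codon_alignment}}.
#' @param structures optional named list (by tree-node label) of
#'   \code{atom_structure} objects.
#' @param seeds named integer vector of the seeds consumed.
#' @return invisibly, the manifest data.frame (file, md5).
#' @export
write_fixture_bundle <- function(path, tree, alignment, ground_truth,
                                 structures = list(), seeds = integer()) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(path)) stop("cannot create output directory: ", path)
  files <- character(0)
  f <- file.path(path, "alignment.fasta")
  write_fasta(alignment, f); files <- c(files, f)
  f <- file.path(path, "tree.nwk")
  ape::write.tree(tree, f); files <- c(files, f)
  f <- file.path(path, "ancestral_truth.fasta")
  write_fasta(ground_truth$true_ancestral_sequences, f)
  files <- c(files, f)
  f <- file.path(path, "column_regimes.tsv")
  utils::write.table(
    data.frame(column = seq_along(ground_truth$true_column_regime),
               regime = ground_truth$true_column_regime),
    f, sep = "\t", row.names = FALSE, quote = FALSE)
  files <- c(files, f)
  if (length(structures) > 0L) {
    maps <- list()
    for (nm in names(structures)) {
      f <- file.path(path, paste0("structure_", nm, ".pdb"))
      write_structure_pdb(structures[[nm]], f); files <- c(files, f)
      rc <- structures[[nm]]$residue_columns
      if (!is.null(rc))
        maps[[nm]] <- data.frame(structure = nm,
                                 residue_index = as.integer(names(rc)),
                                 column = as.integer(rc))
    }
    if (length(maps) > 0L) {
      f <- file.path(path, "residue_columns.tsv")
      utils::write.table(do.call(rbind, maps), f, sep = "\t",
                         row.names = FALSE, quote = FALSE)
      files <- c(files, f)
    }
  }
  manifest <- data.frame(file = basename(files),
                         md5 = unname(tools::md5sum(files)))
  mf <- file.path(path, "manifest.tsv")
  utils::write.table(manifest, mf, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  if (length(seeds) > 0L) {
    utils::write.table(data.frame(name = names(seeds), seed = seeds),
                       file.path(path, "seeds.tsv"), sep = "\t",
                       row.names = FALSE, quote = FALSE)
  }
  invisible(manifest)
}

#' Read a residue-to-column map TSV
#' @param path TSV with columns structure, residue_index, column.
#' @return named list (by structure) of named integer vectors.
#' @export
read_residue_columns <- function(path) {
  d <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE)
  lapply(split(d, d$structure), function(g)
    stats::setNames(as.integer(g$column), g$residue_index))
}
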