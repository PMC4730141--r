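#' Pipeline configuration
#'
#' Collects paths, model and geometry settings and the seeds for one
#' reproducible end-to-end run (ancestral reconstruction -> selection
#' profile -> cavity detection per structure -> lineage tracking ->
#' overlay). Can be loaded from a YAML file with
#' \code{\link{read_pipeline_config}}.
#'
#' @param alignment path to the codon-aware FASTA alignment.
#' @param tree path to the rooted Newick tree.
#' @param structures named character vector of PDB paths; names must be
#'   tree-node labels (tips or internal).
#' @param residue_columns path to the residue-to-column TSV (structure,
#'   residue_index, column).
#' @param out_dir output directory.
#' @param seed master seed for every stochastic stage.
#' @param gamma_shape,p_invariant,n_rate_categories substitution-model
#'   settings (exchangeabilities and base frequencies are fitted
#'   empirically when \code{fit} is TRUE, else equal/empirical defaults).
#' @param fit refit model parameters on the input tree before ASR.
#' @param n_boot bootstrap replicates for the per-column Z-test.
#' @param probe_radius,uniform_atom_radius,volume_mc_samples cavity
#'   geometry settings.
#' @param jaccard_min lineage-matching threshold.
#' @return object of class \code{pipeline_config}.
#' @export
pipeline_config <- function(alignment, tree, structures = character(),
                            residue_columns = NULL, out_dir = "hyscav_out",
                            seed = 1L, gamma_shape = 1, p_invariant = 0,
                            n_rate_categories = 4L, fit = FALSE,
                            n_boot = 200L, probe_radius = 1.4,
                            uniform_atom_radius = NULL,
                            volume_mc_samples = 1e5, jaccard_min = 0.3) {
  structure(list(alignment = alignment, tree = tree,
                 structures = structures,
                 residue_columns = residue_columns, out_dir = out_dir,
                 seed = as.integer(seed), gamma_shape = gamma_shape,
                 p_invariant = p_invariant,
                 n_rate_categories = as.integer(n_rate_categories),
                 fit = isTRUE(fit), n_boot = as.integer(n_boot),
                 probe_radius = probe_radius,
                 uniform_atom_radius = uniform_atom_radius,
                 volume_mc_samples = volume_mc_samples,
                 jaccard_min = jaccard_min),
            class = "pipeline_config")
}

#' Load a pipeline configuration from YAML
#' @param path YAML file whose keys mirror \code{\link{pipeline_config}}
#'   arguments.
#' @return a \code{pipeline_config}.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$structures)) y$structures <- unlist(y$structures)
  do.call(pipeline_config, y)
}

#' Validate pipeline inputs
#'
#' Checks that files exist and parse, tree tips bind to alignment rows,
#' row lengths are codon-divisible, and mapped residues exist in their
#' structures. Problems are reported, not thrown.
#'
#' @param config a \code{pipeline_config}.
#' @return data.frame with \code{level} ("error"/"warning"),
#'   \code{field} and \code{message}; zero rows when everything checks out.
#' @export
validate_inputs <- function(config) {
  rep <- list()
  note <- function(level, field, msg)
    rep[[length(rep) + 1L]] <<- data.frame(level = level, field = field,
                                           message = msg)
  for (f in c("alignment", "tree")) {
    if (is.null(config[[f]]) || !file.exists(config[[f]]))
      note("error", f, paste0("missing file: ",
                              if (is.null(config[[f]])) "(unset)"
                              else config[[f]]))
  }
  aln <- tr <- NULL
  if (!is.null(config$alignment) && file.exists(config$alignment)) {
    aln <- tryCatch(read_codon_fasta(config$alignment), error = function(e) {
      note("error", "alignment", conditionMessage(e)); NULL })
  }
  if (!is.null(config$tree) && file.exists(config$tree)) {
    tr <- tryCatch(ape::read.tree(config$tree), error = function(e) {
      note("error", "tree", conditionMessage(e)); NULL })
  }
  if (!is.null(aln) && !is.null(tr)) {
    missing_tips <- setdiff(tr$tip.label, names(aln$seqs))
    if (length(missing_tips) > 0L)
      note("error", "tree",
           paste("tips absent from alignment:",
                 paste(missing_tips, collapse = ", ")))
  }
  maps <- NULL
  if (!is.null(config$residue_columns)) {
    if (!file.exists(config$residue_columns))
      note("error", "residue_columns",
           paste("missing file:", config$residue_columns))
    else maps <- read_residue_columns(config$residue_columns)
  }
  for (nm in names(config$structures)) {
    p <- config$structures[[nm]]
    if (!file.exists(p)) { note("error", "structures",
                                paste0(nm, ": missing file ", p)); next }
    st <- tryCatch(read_structure_pdb(p), error = function(e) {
      note("error", "structures", paste0(nm, ": ", conditionMessage(e)))
      NULL })
    if (!is.null(st) && !is.null(maps[[nm]])) {
      absent <- setdiff(as.integer(names(maps[[nm]])),
                        st$atoms$residue_index)
      if (length(absent) > 0L)
        note("warning", "residue_columns",
             paste0(nm, ": mapped residues absent from PDB: ",
                    paste(absent, collapse = ", ")))
    }
  }
  if (length(rep) == 0L)
    return(data.frame(level = character(), field = character(),
                      message = character()))
  do.call(rbind, rep)
}

#' Run the full analysis pipeline
#'
#' Stages: (1) marginal ancestral reconstruction on the given tree, (2)
#' per-column deltaN/deltaS selection profile over all branches, (3)
#' cavity detection per structure, (4) cavity-lineage tracking across the
#' tree, (5) overlay of cavity score and selection profile. All outputs
#' are TSV under \code{out_dir}; a JSON manifest records input checksums,
#' seeds, versions and stage timings.
#'
#' @param config a \code{pipeline_config}.
#' @return invisibly, a list with all stage results and the manifest.
#' @export
run_pipeline <- function(config) {
  rep <- validate_inputs(config)
  if (any(rep$level == "error"))
    stop("input validation failed:\n",
         paste(rep$field, rep$message, sep = ": ", collapse = "\n"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  timings <- c()
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    r <- tryCatch(force(expr), error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e)))
    timings[[name]] <<- round(proc.time()[["elapsed"]] - t0, 3)
    r
  }

  aln <- read_codon_fasta(config$alignment)
  tr <- ensure_node_labels(ape::read.tree(config$tree))
  model <- subst_model(gamma_shape = config$gamma_shape,
                       n_rate_categories = config$n_rate_categories,
                       p_invariant = config$p_invariant)
  if (config$fit)
    model <- stage("fit_model", fit_model(aln, tr,
                                          config$n_rate_categories))$model

  asr <- stage("asr", marginal_asr(tr, aln, model))
  write_fasta(asr$sequences, file.path(config$out_dir, "ancestors.fasta"))

  prof <- stage("selection",
                site_profile(aln, tr, asr, n_boot = config$n_boot,
                             seed = config$seed))
  utils::write.table(as.data.frame(prof),
                     file.path(config$out_dir, "selection_profile.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)

  gp <- geometry_params(probe_radius = config$probe_radius,
                        uniform_atom_radius = config$uniform_atom_radius,
                        volume_mc_samples = config$volume_mc_samples,
                        seed = config$seed)
  maps <- if (!is.null(config$residue_columns))
    read_residue_columns(config$residue_columns) else list()
  cavity_sets <- stage("cavities", {
    out <- list()
    for (nm in names(config$structures)) {
      st <- read_structure_pdb(config$structures[[nm]],
                               uniform_radius = config$uniform_atom_radius,
                               residue_columns = maps[[nm]])
      out[[nm]] <- detect_cavities(st, gp)
    }
    out
  })
  if (length(cavity_sets) > 0L) {
    ctab <- do.call(rbind, lapply(names(cavity_sets), function(nm) {
      t <- cavity_sets[[nm]]$table
      if (nrow(t) > 0L) cbind(node = nm, t) else NULL
    }))
    if (!is.null(ctab))
      utils::write.table(ctab, file.path(config$out_dir, "cavities.tsv"),
                         sep = "\t", row.names = FALSE, quote = FALSE)
  }

  lineages <- overlay <- NULL
  if (length(cavity_sets) > 0L) {
    lineages <- stage("track",
                      number_by_appearance(tr, cavity_sets,
                                           config$jaccard_min))
    ltab <- do.call(rbind, lapply(lineages$lineages, function(l)
      data.frame(lineage = l$lineage_id, node = names(l$members),
                 cavity_id = unname(l$members),
                 class = unname(l$class_history))))
    utils::write.table(ltab, file.path(config$out_dir, "lineages.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    score <- cavity_score_profile(cavity_sets, aln$n_columns)
    overlay <- stage("overlay", overlay_report(score, prof))
    utils::write.table(overlay$table,
                       file.path(config$out_dir, "overlay.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  }

  inputs <- c(config$alignment, config$tree,
              unname(config$structures),
              if (!is.null(config$residue_columns)) config$residue_columns)
  manifest <- list(
    package = "hyscav",
    version = as.character(utils::packageVersion("hyscav")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = config$seed,
    inputs = lapply(stats::setNames(inputs, basename(inputs)),
                    function(p) unname(tools::md5sum(p))),
    settings = config[c("gamma_shape", "p_invariant", "n_rate_categories",
                        "n_boot", "probe_radius", "volume_mc_samples",
                        "jaccard_min")],
    timings_sec = as.list(timings),
    overlay_summary = if (!is.null(overlay)) overlay$summary else NULL)
  jsonlite::write_json(manifest,
                       file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(asr = asr, selection = prof, cavities = cavity_sets,
                 lineages = lineages, overlay = overlay,
                 manifest = manifest))
}
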