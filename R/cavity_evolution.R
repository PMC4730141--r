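#' Match cavities between two structures by lining-column overlap
#'
#' Greedy maximum-Jaccard matching on the sets of alignment columns lined
#' by each cavity. Pairs below \code{jaccard_min} stay unmatched. Ties are
#' broken deterministically by lower cavity id in the first structure, then
#' in the second.
#'
#' @param cavities_a,cavities_b \code{cavity_set} objects whose cavities
#'   carry \code{lining_columns} (structures mapped onto one alignment).
#' @param jaccard_min minimum Jaccard index to accept a pair.
#' @return data.frame with \code{id_a}, \code{id_b}, \code{jaccard}.
#' @export
match_cavities <- function(cavities_a, cavities_b, jaccard_min = 0.3) {
  la <- .lining_column_sets(cavities_a)
  lb <- .lining_column_sets(cavities_b)
  out <- data.frame(id_a = integer(), id_b = integer(), jaccard = numeric())
  if (length(la) == 0L || length(lb) == 0L) return(out)
  J <- matrix(0, length(la), length(lb))
  for (i in seq_along(la)) for (j in seq_along(lb)) {
    u <- length(union(la[[i]], lb[[j]]))
    J[i, j] <- if (u == 0L) 0 else length(intersect(la[[i]], lb[[j]])) / u
  }
  repeat {
    best <- max(J)
    if (best < jaccard_min) break
    hit <- which(J == best, arr.ind = TRUE)
    hit <- hit[order(hit[, 1L], hit[, 2L]), , drop = FALSE][1L, ]
    out <- rbind(out, data.frame(id_a = hit[[1L]], id_b = hit[[2L]],
                                 jaccard = best))
    J[hit[1L], ] <- -1
    J[, hit[2L]] <- -1
  }
  out[order(out$id_a), , drop = FALSE]
}

.lining_column_sets <- function(cs) {
  stopifnot(inherits(cs, "cavity_set"))
  lapply(cs$cavities, function(cv) {
    if (is.null(cv$lining_columns))
      stop("cavity ", cv$id, " has no lining_columns: structure lacks a ",
           "residue-to-column map")
    cv$lining_columns
  })
}

#' Number cavity lineages by order of appearance on the tree
#'
#' Pre-order traversal from the root: each structure-bearing node is
#' matched against its nearest structure-bearing ancestor; a cavity with no
#' ancestral match starts a new lineage and receives the next integer id,
#' matched cavities inherit the ancestral lineage. The per-node class
#' labels are recorded as the lineage's class history (the basis for
#' composite designations like "5d + 5i").
#'
#' @param tree rooted \code{phylo} with node labels.
#' @param cavity_sets named list (by node label) of \code{cavity_set}
#'   objects for the nodes carrying structures.
#' @param jaccard_min passed to \code{\link{match_cavities}} along each
#'   tree edge between structure-bearing nodes.
#' @return list of \code{cavity_lineage} records: \code{lineage_id},
#'   \code{first_node}, \code{members} (node -> cavity id) and
#'   \code{class_history} (node -> class label); plus a per-node composite
#'   string in \code{node_designations}.
#' @export
number_by_appearance <- function(tree, cavity_sets, jaccard_min = 0.3) {
  tree <- ensure_node_labels(tree)
  labs <- .node_labels(tree)
  edges <- ape::reorder.phylo(tree, "cladewise")$edge   # natural pre-order
  order_pre <- seq_len(nrow(edges))
  # lineage id per (node label, cavity id)
  assign_l <- list()
  lineages <- list()
  next_id <- 0L
  new_lineage <- function(node, cav_id, class_label) {
    next_id <<- next_id + 1L
    lineages[[next_id]] <<- list(lineage_id = next_id, first_node = node,
                                 members = stats::setNames(cav_id, node),
                                 class_history =
                                   stats::setNames(class_label, node))
    next_id
  }
  root_lab <- labs[length(tree$tip.label) + 1L]
  # parent lookup by node label; ancestors without structures are skipped
  parent_of <- stats::setNames(labs[edges[, 1L]], labs[edges[, 2L]])
  nearest_structured_ancestor <- function(lab) {
    while (lab %in% names(parent_of)) {
      lab <- parent_of[[lab]]
      if (!is.null(cavity_sets[[lab]])) return(lab)
    }
    NULL
  }
  visit_node <- function(lab, parent_lab) {
    cs <- cavity_sets[[lab]]
    if (is.null(cs)) return(invisible())
    matched <- integer(0)
    if (!is.null(parent_lab) && !is.null(cavity_sets[[parent_lab]])) {
      pm <- match_cavities(cavity_sets[[parent_lab]], cs, jaccard_min)
      if (anyDuplicated(pm$id_b) > 0L)
        stop("constraint violation: child cavity matched to two parents")
      for (r in seq_len(nrow(pm))) {
        lid <- assign_l[[parent_lab]][[as.character(pm$id_a[r])]]
        cid <- pm$id_b[r]
        cls <- cs$cavities[[cid]]$class_label
        lineages[[lid]]$members[[lab]] <<- cid
        lineages[[lid]]$class_history[[lab]] <<- cls
        assign_l[[lab]][[as.character(cid)]] <<- lid
        matched <- c(matched, cid)
      }
    }
    for (cv in cs$cavities) {
      if (cv$id %in% matched) next
      lid <- new_lineage(lab, cv$id, cv$class_label)
      assign_l[[lab]][[as.character(cv$id)]] <<- lid
    }
    invisible()
  }
  visit_node(root_lab, NULL)
  for (e in order_pre) {
    lab <- labs[edges[e, 2L]]
    if (lab == root_lab) next
    visit_node(lab, nearest_structured_ancestor(lab))
  }
  desigs <- vapply(names(cavity_sets), function(lab) {
    ids <- assign_l[[lab]]
    if (is.null(ids) || length(ids) == 0L) return("")
    letter <- c(dent = "d", crack = "k", crevice = "v", internal = "i")
    parts <- vapply(names(ids), function(cid) {
      lid <- ids[[cid]]
      cls <- lineages[[lid]]$class_history[[lab]]
      paste0(lid, letter[[cls]])
    }, "")
    paste(sort(parts), collapse = " + ")
  }, "")
  structure(list(lineages = lineages, node_designations = desigs),
            class = "cavity_lineages")
}

#' @export
print.cavity_lineages <- function(x, ...) {
  cat("Cavity lineages: ", length(x$lineages), "\n", sep = "")
  for (l in x$lineages) {
    cat("  #", l$lineage_id, " first at ", l$first_node, ": ",
        paste(names(l$class_history), unname(l$class_history),
              sep = "=", collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

#' Per-column cavity score over a set of structures
#'
#' The score of an alignment column is the number of structures in which
#' the residue at that column lines any detected cavity.
#'
#' @param cavity_sets list of \code{cavity_set} objects (all mapped onto
#'   the same alignment).
#' @param n_columns total alignment codon columns.
#' @return object of class \code{cavity_score_profile}: data.frame with
#'   \code{column} and \code{score}; attribute \code{n_structures}.
#' @export
cavity_score_profile <- function(cavity_sets, n_columns) {
  score <- integer(n_columns)
  for (cs in cavity_sets) {
    cols <- unique(unlist(.lining_column_sets(cs)))
    cols <- cols[cols >= 1L & cols <= n_columns]
    score[cols] <- score[cols] + 1L
  }
  out <- data.frame(column = seq_len(n_columns), score = score)
  class(out) <- c("cavity_score_profile", "data.frame")
  attr(out, "n_structures") <- length(cavity_sets)
  out
}

#' Overlay the cavity score with the selection profile
#'
#' Joins the per-column cavity score with the per-column deltaN/deltaS
#' profile and summarises the key contrasts: columns under apparent
#' positive selection, cavity-lining columns, their intersection, and the
#' cavity-forming-but-conserved count (lining columns with
#' deltaN - deltaS < 0), the signature of conserved residues that
#' nevertheless shape the cavities.
#'
#' @param score_profile a \code{cavity_score_profile}.
#' @param selection_profile a \code{site_selection_profile} over the same
#'   columns.
#' @return list with \code{table} (per-column data.frame) and
#'   \code{summary} (named counts).
#' @export
overlay_report <- function(score_profile, selection_profile) {
  stopifnot(inherits(score_profile, "cavity_score_profile"),
            inherits(selection_profile, "site_selection_profile"))
  if (nrow(score_profile) != nrow(selection_profile))
    stop("column count mismatch: ", nrow(score_profile), " vs ",
         nrow(selection_profile))
  tab <- data.frame(column = selection_profile$column,
                    deltaN = selection_profile$deltaN,
                    deltaS = selection_profile$deltaS,
                    deltaN_minus_deltaS =
                      selection_profile$deltaN_minus_deltaS,
                    Z = selection_profile$Z,
                    p_one_tailed = selection_profile$p_one_tailed,
                    cavity_score = score_profile$score)
  dd <- tab$deltaN_minus_deltaS
  pos <- !is.na(dd) & dd > 0
  lined <- tab$cavity_score > 0
  summary <- list(
    n_columns = nrow(tab),
    n_positive = sum(pos),
    n_cavity_lining = sum(lined),
    n_positive_and_lining = sum(pos & lined),
    n_lining_conserved = sum(lined & !is.na(dd) & dd < 0))
  list(table = tab, summary = summary)
}
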