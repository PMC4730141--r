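# Independent oracles used across the suite. These deliberately use the
# most literal/brute-force formulation of each quantity and share no code
# with the implementation paths they check.

# --- NG86 oracles -----------------------------------------------------------

# all single-nucleotide neighbours of a codon
oracle_neighbours <- function(codon) {
  bases <- c("A", "C", "G", "T")
  nt <- strsplit(codon, "")[[1]]
  out <- character(0)
  for (pos in 1:3) for (b in setdiff(bases, nt[pos])) {
    alt <- nt; alt[pos] <- b
    out <- c(out, paste(alt, collapse = ""))
  }
  out
}

# site counts by literal neighbour enumeration
oracle_count_sites <- function(codon, code = genetic_code()) {
  nt <- strsplit(codon, "")[[1]]
  bases <- c("A", "C", "G", "T")
  S <- 0
  for (pos in 1:3) {
    syn <- 0; ok <- 0
    for (b in setdiff(bases, nt[pos])) {
      alt <- nt; alt[pos] <- b
      ac <- paste(alt, collapse = "")
      if (ac %in% code$stops) next
      ok <- ok + 1
      if (code$table[[ac]] == code$table[[codon]]) syn <- syn + 1
    }
    if (ok > 0) S <- S + syn / ok
  }
  list(S = S, N = 3 - S)
}

# pathway counts by literal permutation enumeration
oracle_count_differences <- function(a, b, code = genetic_code()) {
  va <- strsplit(a, "")[[1]]; vb <- strsplit(b, "")[[1]]
  diff <- which(va != vb)
  if (length(diff) == 0L) return(list(Sd = 0, Nd = 0))
  perms <- if (length(diff) == 1L) list(diff) else {
    p <- combinat_perms(length(diff))
    lapply(seq_len(nrow(p)), function(i) diff[p[i, ]])
  }
  tot_s <- tot_n <- 0; n_ok <- 0L
  for (ord in perms) {
    cur <- va; s <- n <- 0; ok <- TRUE
    for (pos in ord) {
      nxt <- cur; nxt[pos] <- vb[pos]
      cc <- paste(nxt, collapse = "")
      if (cc %in% code$stops) { ok <- FALSE; break }
      if (code$table[[paste(cur, collapse = "")]] == code$table[[cc]])
        s <- s + 1 else n <- n + 1
      cur <- nxt
    }
    if (ok) { tot_s <- tot_s + s; tot_n <- tot_n + n; n_ok <- n_ok + 1L }
  }
  if (n_ok == 0L) return(list(Sd = NA_real_, Nd = NA_real_))
  list(Sd = tot_s / n_ok, Nd = tot_n / n_ok)
}

# all permutations of 1..n as a matrix (n <= 3 needed here)
combinat_perms <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- combinat_perms(n - 1L)
  out <- NULL
  for (k in seq_len(n)) {
    rest <- setdiff(seq_len(n), k)
    out <- rbind(out, cbind(k, matrix(rest[sub], nrow(sub))))
  }
  unname(out)
}

# --- likelihood oracle ------------------------------------------------------

# brute-force likelihood: sum over all ancestral state assignments
oracle_log_likelihood <- function(tree, seqs, model) {
  ntip <- length(tree$tip.label)
  nnode <- tree$Nnode
  edges <- tree$edge
  bases <- c("A", "C", "G", "T")
  X <- t(vapply(tree$tip.label, function(nm)
    match(strsplit(seqs[[nm]], "")[[1]], bases), integer(nchar(seqs[[1]]))))
  nsite <- ncol(X)
  total <- 0
  for (s in seq_len(nsite)) {
    site_lik <- 0
    for (k in seq_along(model$rates)) {
      P <- lapply(seq_len(nrow(edges)), function(e)
        prob_matrix(model, tree$edge.length[e], model$rates[k]))
      grid <- as.matrix(expand.grid(rep(list(1:4), nnode)))
      lik_k <- 0
      for (g in seq_len(nrow(grid))) {
        state <- c(X[, s], grid[g, ])
        l <- model$base_frequencies[state[ntip + 1L]]
        for (e in seq_len(nrow(edges)))
          l <- l * P[[e]][state[edges[e, 1L]], state[edges[e, 2L]]]
        lik_k <- lik_k + l
      }
      site_lik <- site_lik + model$weights[k] * lik_k
    }
    total <- total + log(site_lik)
  }
  total
}

# --- hairpin oracle ---------------------------------------------------------

oracle_pairs <- function(a, b) {
  paste0(a, b) %in% c("AT", "TA", "GC", "CG", "GT", "TG")
}

# literal enumeration over all (start, stem, loop) hairpin geometries
oracle_best_hairpin <- function(window, min_stem, min_loop, max_loop) {
  x <- strsplit(gsub("U", "T", toupper(window)), "")[[1]]
  n <- length(x)
  best <- NULL
  for (start in seq_len(n)) for (L in min_stem:floor((n - min_loop) / 2)) {
    for (loop in min_loop:max_loop) {
      end <- start + 2L * L + loop - 1L
      if (end > n) next
      ps <- start + seq_len(L) - 1L
      qs <- start + 2L * L + loop - seq_len(L)
      if (!all(oracle_pairs(x[ps], x[qs]))) next
      cand <- list(window_start = start, window_end = end,
                   stem_length = L, loop_length = loop, pairing_score = L)
      if (is.null(best) || cand$pairing_score > best$pairing_score ||
          (cand$pairing_score == best$pairing_score &&
           (cand$window_start < best$window_start ||
            (cand$window_start == best$window_start &&
             cand$stem_length > best$stem_length))))
        best <- cand
    }
  }
  best
}

# --- misc fixture helpers ---------------------------------------------------

random_tree <- function(n_tips, max_nodes = 5L) {
  tr <- ape::rtree(n_tips)
  tr$edge.length <- runif(nrow(tr$edge), 0.02, 0.8)
  hyscav::ensure_node_labels(tr)
}

random_seqs <- function(tree, n_sites) {
  seqs <- vapply(tree$tip.label, function(nm)
    paste(sample(c("A", "C", "G", "T"), n_sites, replace = TRUE),
          collapse = ""), "")
  seqs
}

random_model <- function() {
  subst_model(exchangeabilities = runif(6, 0.3, 3),
              base_frequencies = { p <- runif(4, 0.5, 2); p / sum(p) },
              gamma_shape = if (runif(1) < 0.5) Inf else runif(1, 0.3, 3),
              n_rate_categories = 2L,
              p_invariant = if (runif(1) < 0.5) 0 else runif(1, 0.05, 0.3))
}

# minimal hand-built cavity_set for lineage/matching tests
fake_cavity_set <- function(...) {
  cavs <- list(...)
  for (i in seq_along(cavs)) cavs[[i]]$id <- i
  tab <- data.frame(id = seq_along(cavs),
                    class = vapply(cavs, `[[`, "", "class_label"))
  structure(list(cavities = cavs, table = tab, params = NULL,
                 n_atoms = 0L), class = "cavity_set")
}

fake_cavity <- function(lining_columns, class_label = "dent",
                        volume = 100, mouth_count = 1L) {
  list(lining_columns = lining_columns, class_label = class_label,
       volume = volume, mouth_count = mouth_count)
}
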