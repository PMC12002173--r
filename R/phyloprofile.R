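#' Phi coefficient between two binary profiles
#'
#' The phi coefficient (Pearson correlation specialized to binary data)
#' computed from the 2x2 contingency table of two presence/absence vectors:
#' `phi = (n11*n00 - n10*n01) / sqrt(r1*r0*c1*c0)` where r/c are row/column
#' margins. Missing entries are pairwise-deleted. Undefined (returns `NA`)
#' when any margin is zero, i.e. when either vector is constant over the
#' shared taxa.
#'
#' @param a,b Binary vectors of equal length (0/1, `NA` allowed).
#' @return Numeric in `[-1, 1]`, or `NA` when undefined.
#' @export
phi_correlation <- function(a, b) {
  if (length(a) != length(b)) stop_invalid("vectors must have equal length")
  if (length(a) < 2L) stop_invalid("vectors must have length >= 2")
  keep <- !is.na(a) & !is.na(b)
  a <- as.integer(a[keep]); b <- as.integer(b[keep])
  if (length(a) < 2L) return(NA_real_)
  n11 <- sum(a == 1 & b == 1); n10 <- sum(a == 1 & b == 0)
  n01 <- sum(a == 0 & b == 1); n00 <- sum(a == 0 & b == 0)
  r1 <- n11 + n10; r0 <- n01 + n00; c1 <- n11 + n01; c0 <- n10 + n00
  if (r1 == 0 || r0 == 0 || c1 == 0 || c0 == 0) return(NA_real_)
  (n11 * n00 - n10 * n01) / sqrt(as.numeric(r1) * r0 * c1 * c0)
}

# Precompute the permutation machinery for one gene on a tree: eligible loss
# edges (strictly inside the gain clade), their descendant-tip membership, and
# the ancestor/descendant relation among them.
dollo_null_setup <- function(tree, gene_states) {
  rec <- infer_dollo(tree, gene_states)
  if (is.na(rec$gain_edge)) stop_invalid("gene is never gained; no Dollo null exists")
  clade <- subtree_labels(tree, rec$gain_edge)
  eligible <- setdiff(clade, rec$gain_edge)
  tipset <- lapply(tree$desc_tips[eligible], function(t) tree$tips %in% t)
  base <- tree$tips %in% tree$desc_tips[[rec$gain_edge]]
  # related[i,j]: edges i and j are nested (one contains the other)
  ne <- length(eligible)
  related <- matrix(FALSE, ne, ne)
  if (ne > 0) {
    for (i in seq_len(ne)) {
      for (j in seq_len(ne)) {
        related[i, j] <- all(tipset[[j]] <= tipset[[i]]) || all(tipset[[i]] <= tipset[[j]])
      }
    }
  }
  list(rec = rec, eligible = eligible, tipset = tipset, base = base,
       related = related, n_loss = length(rec$loss_edges))
}

# Draw one non-nested set of k loss edges uniformly-sequentially and return
# the resulting 0/1 tip-state vector (ordered as tree$tips).
dollo_null_draw <- function(setup, k) {
  states <- setup$base
  if (k == 0L || length(setup$eligible) == 0L) return(as.integer(states))
  repeat {
    avail <- rep(TRUE, length(setup$eligible))
    chosen <- integer(0)
    ok <- TRUE
    for (i in seq_len(k)) {
      idx <- which(avail)
      if (length(idx) == 0L) { ok <- FALSE; break }
      e <- if (length(idx) == 1L) idx else sample(idx, 1L)
      chosen <- c(chosen, e)
      avail <- avail & !setup$related[e, ]
    }
    if (ok) break
  }
  for (e in chosen) states <- states & !setup$tipset[[e]]
  as.integer(states)
}

#' Dollo-aware permutation p-value for profile correlation
#'
#' Tests the association between a query gene's presence/absence profile and
#' another gene's, against a null that respects the tree: the gene's Dollo
#' gain edge is kept fixed and its observed number of losses is re-placed
#' uniformly at random on eligible edges (non-nested, strictly within the
#' gain clade), regenerating the tip profile and recomputing phi each time.
#' This preserves phylogenetic autocorrelation that an i.i.d. tip shuffle
#' would destroy. One-sided: large phi is evidence of co-evolution.
#'
#' @param tree A `phylo_index` or `ape` `phylo`.
#' @param query_states,gene_states Named binary tip-state vectors.
#' @param n_perm Number of permutations (>= 99).
#' @param seed Integer seed.
#' @return List with `phi` (observed), `p` (`(1 + exceedances)/(1 + n_perm)`),
#'   `n_loss` (losses re-placed under the null) and `n_perm`.
#' @export
dollo_permutation_pvalue <- function(tree, query_states, gene_states,
                                     n_perm = 999L, seed = 1L) {
  tree <- index_tree(tree)
  if (n_perm < 99L) stop_invalid("n_perm must be >= 99")
  setup <- dollo_null_setup(tree, gene_states)
  q <- normalize_tip_states(tree, query_states)[tree$tips]
  g <- normalize_tip_states(tree, gene_states)[tree$tips]
  obs <- phi_correlation(q, g)
  if (is.na(obs)) {
    return(list(phi = NA_real_, p = NA_real_, n_loss = setup$n_loss, n_perm = n_perm))
  }
  exceed <- with_seed(seed, {
    hits <- 0L
    for (i in seq_len(n_perm)) {
      perm <- dollo_null_draw(setup, setup$n_loss)
      ph <- phi_correlation(q, perm)
      if (!is.na(ph) && ph >= obs - 1e-12) hits <- hits + 1L
    }
    hits
  })
  list(phi = obs, p = (1 + exceed) / (1 + n_perm), n_loss = setup$n_loss,
       n_perm = n_perm)
}

#' Rank genes by profile correlation with a query gene
#'
#' For every non-query gene in a presence/absence matrix, computes phi with
#' the query profile, a Dollo-aware permutation p-value, and a
#' Benjamini-Hochberg q-value; genes are ranked by descending phi (ties
#' broken lexicographically by gene id), with undefined-phi genes last.
#'
#' @param tree A `phylo_index` or `ape` `phylo`.
#' @param matrix Taxa-by-genes matrix/data frame of 0/1/NA states (row names
#'   = taxa).
#' @param query Column name of the query gene.
#' @param n_perm Permutations per gene.
#' @param seed Integer seed (per-gene seeds are derived deterministically).
#' @return Data frame: `gene`, `phi`, `p`, `q`, `rank`.
#' @export
rank_coevolving <- function(tree, matrix, query, n_perm = 999L, seed = 1L) {
  tree <- index_tree(tree)
  matrix <- as.matrix(matrix)
  if (!query %in% colnames(matrix)) stop_invalid("query gene '%s' not in matrix", query)
  genes <- setdiff(colnames(matrix), query)
  if (length(genes) == 0L) stop_invalid("matrix must contain at least one non-query gene")
  qstates <- stats::setNames(matrix[, query], rownames(matrix))

  res <- data.frame(gene = genes, phi = NA_real_, p = NA_real_,
                    stringsAsFactors = FALSE)
  for (i in seq_along(genes)) {
    gstates <- stats::setNames(matrix[, genes[i]], rownames(matrix))
    ph <- phi_correlation(qstates[tree$tips], normalize_tip_states(tree, gstates)[tree$tips])
    res$phi[i] <- ph
    if (!is.na(ph) && any(gstates == 1, na.rm = TRUE)) {
      res$p[i] <- dollo_permutation_pvalue(tree, qstates, gstates, n_perm = n_perm,
                                           seed = derive_seed(seed, i))$p
    }
  }
  res$q <- NA_real_
  def <- !is.na(res$p)
  res$q[def] <- stats::p.adjust(res$p[def], method = "BH")
  ord <- order(is.na(res$phi), -ifelse(is.na(res$phi), -Inf, res$phi), res$gene)
  res <- res[ord, , drop = FALSE]
  res$rank <- seq_len(nrow(res))
  rownames(res) <- NULL
  res
}
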