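#' Simulate a rooted binary phylogeny
#'
#' Draws a pure-birth (Yule) tree with `n_tips` tips, relabels tips
#' `t1..tn` and internal nodes `n1..` by deterministic preorder, and returns
#' the indexed tree. Bit-identical for identical `(n_tips, seed)`; the
#' caller's RNG stream is untouched.
#'
#' @param n_tips Number of tips (>= 2).
#' @param seed Integer seed.
#' @param birth Speciation rate of the pure-birth process (default 1).
#' @return A `phylo_index`.
#' @export
sim_tree <- function(n_tips, seed, birth = 1) {
  if (n_tips < 2L) stop_invalid("n_tips must be >= 2")
  phy <- with_seed(seed, ape::rphylo(n_tips, birth = birth, death = 0))
  phy$tip.label <- paste0("t", seq_len(n_tips))
  phy$node.label <- NULL  # internal labels assigned by index_tree preorder
  index_tree(phy)
}

#' Simulate a single-gain/multiple-loss (Dollo) binary character
#'
#' The generative model Dollo parsimony assumes: the character appears once,
#' on `gain_edge`, and propagates to all descendants; on every edge within
#' the gain clade an active lineage loses the character independently with
#' probability `loss_rate`, and once lost it stays lost. Tips outside the
#' gain clade are 0.
#'
#' @param tree A `phylo_index` or `ape` `phylo`.
#' @param gain_edge Edge id (child-node label); the root label means the
#'   character is ancestrally present.
#' @param loss_rate Per-branch loss probability in `[0, 1)`.
#' @param seed Integer seed.
#' @param missing_fraction Probability that a tip's state is masked to `NA`
#'   (default 0, so ground truth stays unambiguous).
#' @return List: `tip_states` (named 0/1/NA over tips) and `events`
#'   (`gain_edge`, `loss_edges` actually realized -- losses on already-lost
#'   lineages do not occur and are not recorded).
#' @export
sim_dollo_character <- function(tree, gain_edge, loss_rate, seed,
                                missing_fraction = 0) {
  tree <- index_tree(tree)
  if (!gain_edge %in% tree$labels) stop_invalid("edge '%s' not found in tree", gain_edge)
  if (loss_rate < 0 || loss_rate >= 1) stop_invalid("loss_rate must be in [0, 1)")
  clade <- subtree_labels(tree, gain_edge)
  with_seed(seed, {
    state <- stats::setNames(rep(0L, length(tree$labels)), tree$labels)
    state[gain_edge] <- 1L
    losses <- character(0)
    for (v in clade) {
      if (v == gain_edge) next
      p <- tree$parent[[v]]
      if (state[[p]] == 1L) {
        if (stats::runif(1) < loss_rate) {
          state[v] <- 0L
          losses <- c(losses, v)
        } else {
          state[v] <- 1L
        }
      } else {
        state[v] <- 0L
      }
    }
    tips <- state[tree$tips]
    if (missing_fraction > 0) {
      mask <- stats::runif(length(tips)) < missing_fraction
      tips[mask] <- NA_integer_
    }
    list(tip_states = tips,
         events = list(gain_edge = gain_edge, loss_edges = losses))
  })
}

#' Simulate a presence/absence profile matrix with planted co-evolving genes
#'
#' Generates a query character (gained at the root, lost at `loss_rate` per
#' branch) plus `n_genes` gene characters: `n_coevolving` of them copy the
#' query's realized loss events and then flip each tip state independently
#' with probability `flip_noise`; the remaining background genes are
#' independent Dollo characters at the same loss rate. With `flip_noise = 0`
#' every planted gene's profile is identical to the query's.
#'
#' @param tree A `phylo_index` or `ape` `phylo`.
#' @param n_genes Number of gene characters (in addition to the query).
#' @param n_coevolving Number of planted co-evolving genes (<= `n_genes`).
#' @param flip_noise Per-tip flip probability for planted genes.
#' @param seed Integer seed.
#' @param loss_rate Per-branch loss probability (default 0.05, so a tree of
#'   a few dozen taxa typically shows a handful of independent losses).
#' @return List: `matrix` (tips x (1 + n_genes) integer matrix; first column
#'   `query`) and `truth` (`coevolving_gene_ids`, `query_events`).
#' @export
sim_profile_matrix <- function(tree, n_genes, n_coevolving, flip_noise, seed,
                               loss_rate = 0.05) {
  tree <- index_tree(tree)
  if (n_coevolving > n_genes) stop_invalid("n_coevolving must be <= n_genes")
  if (flip_noise < 0 || flip_noise > 1) stop_invalid("flip_noise must be in [0, 1]")
  query <- sim_dollo_character(tree, tree$root, loss_rate, derive_seed(seed, 0))
  with_seed(seed, {
    gene_ids <- sprintf("g%03d", seq_len(n_genes))
    coev <- if (n_coevolving > 0) sort(sample(gene_ids, n_coevolving)) else character(0)
    m <- matrix(NA_integer_, nrow = length(tree$tips), ncol = n_genes + 1L,
                dimnames = list(tree$tips, c("query", gene_ids)))
    m[, "query"] <- query$tip_states
    for (j in seq_along(gene_ids)) {
      g <- gene_ids[j]
      if (g %in% coev) {
        s <- query$tip_states
        if (flip_noise > 0) {
          flip <- stats::runif(length(s)) < flip_noise
          s[flip] <- 1L - s[flip]
        }
        m[, g] <- s
      } else {
        bg <- sim_dollo_character(tree, tree$root, loss_rate,
                                  derive_seed(seed, j))
        m[, g] <- bg$tip_states
      }
    }
    list(matrix = m,
         truth = list(coevolving_gene_ids = coev, query_events = query$events))
  })
}

#' Simulate an alignment with clade-restricted active-site degradation
#'
#' One aligned sequence per tip plus the model's reference row. Tips inside
#' the `pseudo_clade` subtree carry at least one disallowed residue at a
#' required M1 or M2 position of the site model (mimicking active-site
#' degeneration in one clade, e.g. the metazoan loss); all other tips carry
#' allowed residues at every model position. Non-site columns are random.
#'
#' @param tree A `phylo_index` or `ape` `phylo`.
#' @param model A `catalytic_site_model`; must have at least one required
#'   position.
#' @param pseudo_clade Node label (internal node or tip) whose subtree is
#'   degraded.
#' @param seed Integer seed.
#' @param extra_columns Random columns appended after the last site position
#'   (default 20).
#' @param palette Substitution palette for degraded positions; disallowed
#'   residues are drawn from it (default includes C, so a cysteine can
#'   appear at an M2 aspartate position, the zinc-site signature).
#' @return List: `alignment` (named character vector, reference row included,
#'   ungapped) and `truth` (`sequence_classes`: tip -> active/pseudo,
#'   `pseudo_clade`).
#' @export
sim_catalytic_msa <- function(tree, model, pseudo_clade, seed,
                              extra_columns = 20L,
                              palette = c("C", "A", "G", "S", "N", "K")) {
  tree <- index_tree(tree)
  stopifnot(inherits(model, "catalytic_site_model"))
  if (!any(model$required)) stop_invalid("site model has zero required positions")
  if (!pseudo_clade %in% tree$labels) stop_invalid("node '%s' not found in tree", pseudo_clade)
  pseudo_tips <- intersect(tree$desc_tips[[pseudo_clade]], tree$tips)
  width <- max(model$position) + extra_columns
  allowed_sets <- strsplit(model$allowed, "")
  req_m12 <- which(model$required & model$role %in% c("M1", "M2"))

  with_seed(seed, {
    draw_backbone <- function() sample(AA_ALPHABET20, width, replace = TRUE)
    set_allowed <- function(s) {
      for (k in seq_len(nrow(model))) {
        s[model$position[k]] <- sample(allowed_sets[[k]], 1)
      }
      s
    }
    ref <- set_allowed(draw_backbone())
    aln <- stats::setNames(vector("character", length(tree$tips) + 1L),
                           c(attr(model, "reference_id"), tree$tips))
    aln[[attr(model, "reference_id")]] <- paste(ref, collapse = "")
    for (t in tree$tips) {
      s <- set_allowed(draw_backbone())
      if (t %in% pseudo_tips) {
        n_corrupt <- sample.int(length(req_m12), 1)
        for (k in req_m12[sample.int(length(req_m12), n_corrupt)]) {
          bad <- setdiff(palette, allowed_sets[[k]])
          s[model$position[k]] <- sample(bad, 1)
        }
      }
      aln[[t]] <- paste(s, collapse = "")
    }
    classes <- stats::setNames(
      ifelse(tree$tips %in% pseudo_tips, "pseudo", "active"), tree$tips
    )
    list(alignment = aln,
         truth = list(sequence_classes = classes, pseudo_clade = pseudo_clade))
  })
}
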