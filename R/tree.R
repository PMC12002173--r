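#' Read a rooted phylogeny from Newick text
#'
#' Parses a Newick string (or a file containing one) into an indexed rooted
#' phylogeny. Tip labels must be present and unique; internal nodes without
#' labels are auto-named deterministically by their preorder index
#' (`n1`, `n2`, ... starting at the root), so that edges -- addressed by the
#' label of their child node -- are stable across runs.
#'
#' @param text A Newick string, or the path to a file whose first line is one.
#' @return An object of class `phylo_index`; see [index_tree()].
#' @examples
#' tr <- read_newick("((A,B),(C,D));")
#' tr$tips
#' @export
read_newick <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  if (!grepl(";", text, fixed = TRUE) && file.exists(text)) {
    text <- paste(readLines(text, warn = FALSE), collapse = "")
  }
  phy <- tryCatch(
    ape::read.tree(text = text),
    error = function(e) NULL
  )
  if (is.null(phy)) {
    # locate the first structurally offending character for the error message
    off <- newick_offset(text)
    stop_invalid("malformed Newick string (near character %d)", off)
  }
  index_tree(phy)
}

# Best-effort character offset of the first parenthesis imbalance.
newick_offset <- function(text) {
  depth <- 0L
  chars <- strsplit(text, "")[[1]]
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    if (chars[i] == ")") depth <- depth - 1L
    if (depth < 0L) return(i)
  }
  nchar(text)
}

#' Index a phylogeny for edge-addressed traversal
#'
#' Converts an `ape` `phylo` object into the indexed representation used
#' throughout the package: parent and children maps keyed by node label, a
#' deterministic preorder, and per-node descendant-tip sets. Every edge is
#' addressed by the label of its child node; the root label doubles as the id
#' of a virtual root edge (the branch subtending the whole tree).
#'
#' @param phy An `ape` `phylo` object (rooted), or an existing `phylo_index`
#'   (returned unchanged).
#' @return A list of class `phylo_index` with elements `phy` (the relabeled
#'   `phylo`), `root`, `tips`, `labels` (all node labels, preorder),
#'   `parent` (named character, `NA` for the root), `children` (named list),
#'   `brlen` (named by child label) and `desc_tips` (named list of tip-label
#'   vectors per node).
#' @export
index_tree <- function(phy) {
  if (inherits(phy, "phylo_index")) return(phy)
  stopifnot(inherits(phy, "phylo"))
  if (!ape::is.rooted(phy)) stop_invalid("tree must be rooted")
  ntip <- length(phy$tip.label)
  if (anyDuplicated(phy$tip.label)) stop_invalid("tip labels must be unique")
  nnode <- phy$Nnode
  n_all <- ntip + nnode
  root <- ntip + 1L

  kids <- vector("list", n_all)
  par <- rep(NA_integer_, n_all)
  for (i in seq_len(nrow(phy$edge))) {
    u <- phy$edge[i, 1]; v <- phy$edge[i, 2]
    kids[[u]] <- c(kids[[u]], v)
    par[v] <- u
  }
  # deterministic preorder (children in edge-matrix order)
  pre <- integer(n_all)
  stack <- root; k <- 0L
  while (length(stack)) {
    v <- stack[1]; stack <- stack[-1]
    k <- k + 1L; pre[k] <- v
    stack <- c(kids[[v]], stack)
  }

  # auto-name unlabeled internal nodes by preorder index among internals
  ilab <- phy$node.label
  if (is.null(ilab)) ilab <- rep("", nnode)
  ilab[is.na(ilab)] <- ""
  internal_pre <- pre[pre > ntip]
  auto <- paste0("n", seq_len(nnode))
  for (j in seq_len(nnode)) {
    v <- internal_pre[j]
    if (ilab[v - ntip] == "") ilab[v - ntip] <- auto[j]
  }
  phy$node.label <- ilab
  labels <- c(phy$tip.label, ilab)
  if (anyDuplicated(labels)) stop_invalid("node labels must be unique")

  brlen <- rep(NA_real_, n_all)
  if (!is.null(phy$edge.length)) brlen[phy$edge[, 2]] <- phy$edge.length

  desc <- vector("list", n_all)
  for (v in rev(pre)) {
    if (v <= ntip) desc[[v]] <- labels[v]
    else desc[[v]] <- unlist(lapply(kids[[v]], function(w) desc[[w]]), use.names = FALSE)
  }

  out <- list(
    phy = phy,
    root = labels[root],
    tips = phy$tip.label,
    labels = labels[pre],
    parent = stats::setNames(ifelse(is.na(par), NA_character_, labels[par]), labels)[labels[pre]],
    children = stats::setNames(lapply(seq_len(n_all), function(v) labels[kids[[v]]]), labels)[labels[pre]],
    brlen = stats::setNames(brlen, labels)[labels[pre]],
    desc_tips = stats::setNames(desc, labels)[labels[pre]]
  )
  class(out) <- "phylo_index"
  out
}

#' @export
print.phylo_index <- function(x, ...) {
  cat(sprintf(
    "Indexed rooted phylogeny: %d tips, %d internal nodes (root '%s')\n",
    length(x$tips), length(x$labels) - length(x$tips), x$root
  ))
  invisible(x)
}

#' Write a phylogeny to Newick
#'
#' @param tree A `phylo_index` or `ape` `phylo` object.
#' @param file Optional path; if `NULL` the Newick string is returned.
#' @return The Newick string, invisibly when writing to a file.
#' @export
write_newick <- function(tree, file = NULL) {
  tree <- index_tree(tree)
  s <- ape::write.tree(tree$phy)
  if (!is.null(file)) {
    writeLines(s, file)
    return(invisible(s))
  }
  s
}

# All node labels in the subtree rooted at `node` (inclusive), preorder.
subtree_labels <- function(tree, node) {
  if (!node %in% tree$labels) stop_invalid("node '%s' not found in tree", node)
  out <- character(0)
  stack <- node
  while (length(stack)) {
    v <- stack[1]; stack <- stack[-1]
    out <- c(out, v)
    stack <- c(tree$children[[v]], stack)
  }
  out
}

# MRCA of a set of tip labels (label of the shallowest common ancestor).
mrca_label <- function(tree, tips) {
  stopifnot(length(tips) >= 1L)
  if (!all(tips %in% tree$tips)) {
    stop_invalid("tip(s) not found in tree: %s",
                 paste(setdiff(tips, tree$tips), collapse = ", "))
  }
  if (length(tips) == 1L) return(tips)
  path_up <- function(t) {
    p <- t
    while (!is.na(tree$parent[[p]])) {
      p <- tree$parent[[p]]
      t <- c(t, p)
    }
    t
  }
  common <- Reduce(intersect, lapply(tips, path_up))
  common[1]  # paths are ordered leaf -> root, so first common is deepest
}
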