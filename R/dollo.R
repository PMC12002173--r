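#' Dollo-parsimony reconstruction of a binary character
#'
#' Reconstructs the unique minimum-loss single-gain history of a binary
#' (presence/absence) character on a rooted phylogeny under Dollo parsimony:
#' the character is gained exactly once -- on the edge subtending the most
#' recent common ancestor (MRCA) of all taxa that carry it -- and can only be
#' lost thereafter. Losses are placed on the maximal subtrees inside the gain
#' clade that contain no observed presence. Missing tips are excluded from the
#' MRCA computation and afterwards imputed to the state of their parent node,
#' so unsampled genomes never create spurious losses.
#'
#' @param tree A `phylo_index` (see [read_newick()]) or `ape` `phylo`.
#' @param tip_states Named vector of tip states in `{0, 1, NA}`; `NA` means
#'   missing. Tips of the tree absent from the vector are treated as missing.
#' @param character_id Optional label stored on the result.
#' @return An object of class `dollo_reconstruction` with elements
#'   `character`, `gain_edge` (child-node label of the gain edge, or `NA` if
#'   the character is absent everywhere; the root label denotes a virtual root
#'   edge), `loss_edges` (character vector of child-node labels), and
#'   `node_states` (named 0/1 vector over all nodes).
#' @examples
#' tr <- read_newick("((A,B),(C,D));")
#' rec <- infer_dollo(tr, c(A = 1, B = 1, C = 0, D = 0))
#' rec$gain_edge
#' count_independent_losses(rec)
#' @seealso [map_characters()] to reconstruct a whole matrix of characters.
#' @export
infer_dollo <- function(tree, tip_states, character_id = NA_character_) {
  tree <- index_tree(tree)
  states <- normalize_tip_states(tree, tip_states)
  obs <- states[!is.na(states)]
  if (length(obs) == 0L) stop_invalid("all tips are missing; nothing to reconstruct")

  present <- names(obs)[obs == 1]
  node_states <- stats::setNames(rep(0L, length(tree$labels)), tree$labels)

  if (length(present) == 0L) {
    out <- list(character = character_id, gain_edge = NA_character_,
                loss_edges = character(0), node_states = node_states)
    class(out) <- "dollo_reconstruction"
    return(out)
  }

  gain <- mrca_label(tree, present)
  clade <- subtree_labels(tree, gain)

  # per node: does its subtree contain an observed presence / absence?
  obs1 <- vapply(tree$desc_tips[clade],
                 function(t) any(obs[intersect(t, names(obs))] == 1), logical(1))
  obs0 <- vapply(tree$desc_tips[clade],
                 function(t) any(obs[intersect(t, names(obs))] == 0), logical(1))

  loss <- character(0)
  for (v in clade) {
    if (v == gain) next
    p <- tree$parent[[v]]
    if (!obs1[[v]] && obs0[[v]] && obs1[[p]]) loss <- c(loss, v)
  }

  # propagate 1 down from the gain node, zeroing at loss edges
  node_states[gain] <- 1L
  for (v in clade) {
    if (v == gain) next
    p <- tree$parent[[v]]
    node_states[v] <- if (v %in% loss) 0L else node_states[[p]]
  }

  out <- list(character = character_id, gain_edge = gain,
              loss_edges = sort(loss), node_states = node_states)
  class(out) <- "dollo_reconstruction"
  out
}

normalize_tip_states <- function(tree, tip_states) {
  if (is.null(names(tip_states)) || any(names(tip_states) == "")) {
    stop_invalid("tip_states must be a named vector")
  }
  unknown <- setdiff(names(tip_states), tree$tips)
  if (length(unknown)) {
    stop_invalid("tip(s) not found in tree: %s", paste(unknown, collapse = ", "))
  }
  vals <- suppressWarnings(as.integer(tip_states))
  bad <- !is.na(vals) & !vals %in% c(0L, 1L)
  if (any(bad)) stop_invalid("tip states must be 0, 1 or NA")
  states <- stats::setNames(rep(NA_integer_, length(tree$tips)), tree$tips)
  states[names(tip_states)] <- vals
  states
}

#' Count independent loss events in a Dollo reconstruction
#'
#' @param recon A `dollo_reconstruction` from [infer_dollo()].
#' @return The number of loss edges (independent loss events).
#' @export
count_independent_losses <- function(recon) {
  stopifnot(inherits(recon, "dollo_reconstruction"))
  length(recon$loss_edges)
}

#' @export
print.dollo_reconstruction <- function(x, ...) {
  cat(sprintf(
    "Dollo reconstruction%s: gain edge %s, %d independent loss%s%s\n",
    if (is.na(x$character)) "" else sprintf(" of '%s'", x$character),
    if (is.na(x$gain_edge)) "none (character absent)" else sprintf("'%s'", x$gain_edge),
    length(x$loss_edges),
    if (length(x$loss_edges) == 1) "" else "es",
    if (length(x$loss_edges)) sprintf(" (%s)", paste(x$loss_edges, collapse = ", ")) else ""
  ))
  invisible(x)
}

#' Map a matrix of binary characters onto a tree by Dollo parsimony
#'
#' Runs [infer_dollo()] for every character of a presence/absence matrix and
#' collects the gain and loss events per edge, the way gene, domain and
#' active-site gains/losses are annotated on a family phylogeny
#' (`+X` for a gain of character X on an edge, `-X` for a loss).
#'
#' @param tree A `phylo_index` or `ape` `phylo`.
#' @param matrix Taxa-by-characters matrix or data frame of states in
#'   `{0, 1, NA}`, with taxa as row names and characters as column names.
#'   Taxa must be a subset of the tree's tips.
#' @return A list of class `dollo_map` with `reconstructions` (named list of
#'   `dollo_reconstruction`), `events` (data frame: character, event
#'   (gain/loss), edge), and `edge_annotations` (named list: per edge, the
#'   `+X`/`-X` labels).
#' @export
map_characters <- function(tree, matrix) {
  tree <- index_tree(tree)
  matrix <- as.matrix(matrix)
  if (length(matrix) == 0L || ncol(matrix) == 0L) stop_invalid("character matrix is empty")
  if (is.null(rownames(matrix)) || is.null(colnames(matrix))) {
    stop_invalid("matrix must have taxa as row names and characters as column names")
  }
  recs <- lapply(colnames(matrix), function(ch) {
    infer_dollo(tree, stats::setNames(matrix[, ch], rownames(matrix)), character_id = ch)
  })
  names(recs) <- colnames(matrix)

  ev <- do.call(rbind, lapply(recs, function(r) {
    rows <- NULL
    if (!is.na(r$gain_edge)) {
      rows <- data.frame(character = r$character, event = "gain",
                         edge = r$gain_edge, stringsAsFactors = FALSE)
    }
    if (length(r$loss_edges)) {
      rows <- rbind(rows, data.frame(character = r$character, event = "loss",
                                     edge = r$loss_edges, stringsAsFactors = FALSE))
    }
    rows
  }))
  if (is.null(ev)) {
    ev <- data.frame(character = character(0), event = character(0),
                     edge = character(0), stringsAsFactors = FALSE)
  }
  rownames(ev) <- NULL

  ann <- stats::setNames(vector("list", length(tree$labels)), tree$labels)
  for (i in seq_len(nrow(ev))) {
    tag <- paste0(if (ev$event[i] == "gain") "+" else "-", ev$character[i])
    ann[[ev$edge[i]]] <- c(ann[[ev$edge[i]]], tag)
  }
  out <- list(tree = tree, reconstructions = recs, events = ev,
              edge_annotations = ann[!vapply(ann, is.null, logical(1))])
  class(out) <- "dollo_map"
  out
}

#' @export
print.dollo_map <- function(x, ...) {
  cat(sprintf("Dollo map: %d characters, %d events on %d edges\n",
              length(x$reconstructions), nrow(x$events),
              length(x$edge_annotations)))
  invisible(x)
}

#' Write an event-annotated Newick string
#'
#' Emits the tree in Newick form with per-edge comment tags
#' `[&gain=...,loss=...]` listing the characters gained and lost on each edge
#' (root-edge events are attached to the root node). `ape` cannot emit such
#' comments, so the string is assembled directly from the indexed tree.
#'
#' @param map A `dollo_map` from [map_characters()].
#' @param file Optional output path.
#' @return The annotated Newick string (invisibly when `file` is given).
#' @export
write_annotated_newick <- function(map, file = NULL) {
  stopifnot(inherits(map, "dollo_map"))
  tree <- map$tree
  tag_for <- function(v) {
    gains <- map$events$character[map$events$edge == v & map$events$event == "gain"]
    losses <- map$events$character[map$events$edge == v & map$events$event == "loss"]
    if (!length(gains) && !length(losses)) return("")
    parts <- c(
      if (length(gains)) paste0("gain=", paste(gains, collapse = "|")),
      if (length(losses)) paste0("loss=", paste(losses, collapse = "|"))
    )
    paste0("[&", paste(parts, collapse = ","), "]")
  }
  emit <- function(v) {
    kids <- tree$children[[v]]
    core <- if (length(kids)) {
      paste0("(", paste(vapply(kids, emit, character(1)), collapse = ","), ")", v)
    } else {
      v
    }
    bl <- tree$brlen[[v]]
    paste0(core, tag_for(v), if (!is.na(bl)) paste0(":", format(bl, digits = 10)) else "")
  }
  s <- paste0(emit(tree$root), ";")
  if (!is.null(file)) {
    writeLines(s, file)
    return(invisible(s))
  }
  s
}

#' Write a Dollo event table as TSV
#'
#' @param map A `dollo_map`.
#' @param file Output path.
#' @return The events data frame, invisibly.
#' @export
write_event_table <- function(map, file) {
  stopifnot(inherits(map, "dollo_map"))
  utils::write.table(map$events, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(map$events)
}
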