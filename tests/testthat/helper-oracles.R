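# Independent oracles used to cross-check the implementation. These stay
# deliberately naive: exhaustive enumeration and direct scans, no sharing of
# code paths with the package internals.

# Minimum number of 1->0 transitions over all full node-state assignments
# with at most one gain (a 0->1 transition, counting state 1 at the root as
# a gain on the virtual root edge), with observed tip states fixed and
# missing tips free. Exhaustive over 2^(free nodes).
brute_force_dollo_losses <- function(tree, tip_states) {
  tree <- index_tree(tree)
  labels <- tree$labels
  fixed <- stats::setNames(rep(NA_integer_, length(labels)), labels)
  obs <- tip_states[!is.na(tip_states)]
  fixed[names(obs)] <- as.integer(obs)
  free <- labels[is.na(fixed)]
  nf <- length(free)
  stopifnot(nf <= 22)  # enumeration guard
  best <- Inf
  for (mask in 0:(2^nf - 1)) {
    st <- fixed
    if (nf > 0) st[free] <- as.integer(bitwAnd(bitwShiftR(mask, seq_len(nf) - 1L), 1L))
    gains <- st[[tree$root]]
    losses <- 0L
    for (v in labels) {
      p <- tree$parent[[v]]
      if (is.na(p)) next
      if (st[[p]] == 0L && st[[v]] == 1L) gains <- gains + 1L
      if (st[[p]] == 1L && st[[v]] == 0L) losses <- losses + 1L
    }
    if (gains <= 1L && losses < best) best <- losses
  }
  best
}

# Second, independent implementation of the Dollo propagation rule used by
# sim_dollo_character: recursive descent, same preorder and same RNG
# consumption discipline (one uniform draw per active edge).
replay_dollo_sim <- function(tree, gain_edge, loss_rate, seed) {
  tree <- index_tree(tree)
  set.seed(as.integer(seed))
  losses <- character(0)
  states <- stats::setNames(rep(0L, length(tree$labels)), tree$labels)
  descend <- function(v, active) {
    if (v != gain_edge) {
      if (active) {
        if (stats::runif(1) < loss_rate) {
          active <- FALSE
          losses <<- c(losses, v)
        }
      }
    }
    states[v] <<- as.integer(active)
    for (w in tree$children[[v]]) descend(w, active)
  }
  descend(gain_edge, TRUE)
  list(tip_states = states[tree$tips],
       loss_edges = losses)
}

# Naive per-character scan mapping reference positions to columns.
naive_refpos_scan <- function(ref_row, positions) {
  chars <- strsplit(ref_row, "")[[1]]
  out <- integer(length(positions))
  for (i in seq_along(positions)) {
    seen <- 0L
    for (j in seq_along(chars)) {
      if (chars[j] != "-" && chars[j] != ".") seen <- seen + 1L
      if (seen == positions[i]) { out[i] <- j; break }
    }
  }
  out
}

# Binomial upper-tail by direct summation (hotspot p-value oracle).
binom_tail_sum <- function(k, m, prob) {
  sum(vapply(k:m, function(j) choose(m, j) * prob^j * (1 - prob)^(m - j), numeric(1)))
}

# Random rooted tree + random tip states for oracle comparisons.
random_tree_states <- function(n_tips, seed, p_present = 0.5, p_missing = 0) {
  tr <- sim_tree(n_tips, seed)
  set.seed(seed + 31L)
  st <- stats::setNames(
    ifelse(stats::runif(n_tips) < p_missing, NA_integer_,
           as.integer(stats::runif(n_tips) < p_present)),
    tr$tips
  )
  if (all(is.na(st))) st[1] <- 1L
  list(tree = tr, states = st)
}

# 20-letter amino-acid alphabet for alignment fixtures.
AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
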