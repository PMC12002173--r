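#' Worked example: PHLPP2 presence/absence across jawed vertebrates
#'
#' Builds a small gnathostome (jawed-vertebrate) species tree from named
#' lineages and the PHLPP2 presence/absence pattern across them: the gene is
#' retained everywhere except in caecilians, in squamates (snakes and
#' lizards, while the tuatara retains it), and in two non-sister turtle
#' subclades separated by a retaining subclade -- so Dollo parsimony must
#' place two independent losses within turtles, four independent losses in
#' total. The AKT and PKC characters are retained in every lineage, so their
#' reconstructions show zero losses.
#'
#' @return List: `tree` (`phylo_index`), `states` (named PHLPP2 0/1 vector
#'   over tips), and `matrix` (tips x {PHLPP2, AKT, PKC}).
#' @examples
#' ex <- gnathostome_phlpp2_example()
#' rec <- infer_dollo(ex$tree, ex$states, "PHLPP2")
#' count_independent_losses(rec)
#' @export
gnathostome_phlpp2_example <- function() {
  nwk <- paste0(
    "((shark,ray)chondrichthyes,",
    "((zebrafish,medaka)actinopterygii,",
    "(coelacanth,(lungfish,",
    "((caecilian,(frog,salamander)batrachia)amphibia,",
    "((mammal_human,mammal_mouse)mammalia,",
    "((tuatara,(snake,lizard)squamata)lepidosauria,",
    "((pleurodire,(softshell,cryptodire)durocryptodira)testudines,",
    "(crocodile,bird)archosauria)archelosauria)sauropsida",
    ")amniota)tetrapoda)dipnomorpha)sarcopterygii",
    ")osteichthyes)gnathostomata;"
  )
  tree <- read_newick(nwk)
  absent <- c("caecilian", "snake", "lizard", "pleurodire", "cryptodire")
  phlpp2 <- stats::setNames(as.integer(!tree$tips %in% absent), tree$tips)
  always <- stats::setNames(rep(1L, length(tree$tips)), tree$tips)
  m <- cbind(PHLPP2 = phlpp2, AKT = always, PKC = always)
  list(tree = tree, states = phlpp2, matrix = m)
}
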