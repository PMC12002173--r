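# pseudolock

Comparative-evolution and genomics toolkit for asking whether a putative
enzyme is actually a **pseudoenzyme** — a protein that keeps the catalytic
fold but has lost the chemistry. The package grew out of the case of the
PHLPP phosphatases (PPM/PP2C-family "Akt phosphatases" whose activity has
been called into question) and implements the five computational lines of
evidence such a case rests on, each usable on its own:

1. **Dollo-parsimony mapping** (`infer_dollo`, `map_characters`) — reconstructs
   single-gain/multiple-loss histories of binary characters (genes, domains,
   active sites) on rooted phylogenies. Under Dollo parsimony a character is
   gained once, on the edge above the MRCA of the taxa that carry it, and the
   minimal history places one loss on each maximal subtree with no surviving
   presence. The loss count is provably minimal (checked in the tests against
   exhaustive enumeration).
2. **Active-site integrity calling** (`call_active_site`) — classifies
   PPM-family sequences as catalytically intact or pseudo from conservation of
   the M1/M2/M3 metal-coordination constellation, in reference (PPM1A)
   numbering: `active` iff every required M1 and M2 position carries an
   allowed residue. A cysteine appearing at an M2 position is flagged as the
   signature of a degenerate site converted into a structural zinc site.
   Sequence-logo matrices and per-column information content
   (`log2 20 − H`, bits) come from `conservation_profile`.
3. **Phylogenomic profiling** (`rank_coevolving`) — ranks genes by the phi
   coefficient (Pearson on 0/1 profiles) between their presence/absence
   pattern and a query gene's, with a Dollo-aware permutation null: the
   gene's gain edge and loss count are held fixed and the losses re-placed
   uniformly on eligible edges, preserving phylogenetic autocorrelation that
   an i.i.d. tip shuffle would destroy.
4. **Mutation-burden comparison** (`burden_report`) — COSMIC-style per-gene
   synonymous/nonsynonymous rates per 1,000 aa, binomial positional hotspot
   tests with Benjamini–Hochberg control, copy-number gain/loss skew, and a
   TSG-like / oncogene-like / neutral-like class call.
5. **Assay scoring** (`fit_calibration`, `endpoint_rate`, `timecourse_rate`,
   `oa_attribution`, `alkylation_accessibility`) — converts malachite-green /
   pNPP readouts into mol product/min, applies a 3-sigma detectability rule,
   attributes inhibitor-sensitive activity to a contaminating phosphatase
   when a sub-stoichiometric okadaic-acid dose abolishes it, and turns
   MMTS:IAA differential-alkylation ratios into buried/exposed calls.

A synthetic-data module (`sim_tree`, `sim_dollo_character`,
`sim_profile_matrix`, `sim_catalytic_msa`, `sim_mutation_catalog`,
`sim_alkylation_table`, `sim_assay`) generates every input with known ground
truth, so the whole pipeline runs and calibrates without downloads. All
generators are pure functions of their arguments including the seed.

## Worked example

PHLPP2 presence/absence across a jawed-vertebrate species tree. The gene is
retained everywhere except in caecilians, squamates, and two non-sister
turtle subclades separated by a retaining lineage — so the most parsimonious
single-gain history needs two *independent* turtle losses:

```r
library(pseudolock)

ex  <- gnathostome_phlpp2_example()
rec <- infer_dollo(ex$tree, ex$states, "PHLPP2")
rec
#> Dollo reconstruction of 'PHLPP2': gain edge 'gnathostomata',
#>   4 independent losses (caecilian, cryptodire, pleurodire, squamata)
count_independent_losses(rec)
#> [1] 4
```

Four independent losses: the caecilian stem, the squamate stem, and the two
turtle edges. Mapping the AKT and PKC characters alongside shows they are
never lost, which is exactly the tension that motivates profiling for
*other* co-evolving genes:

```r
map <- map_characters(ex$tree, ex$matrix)
head(map$events)
#>   character event          edge
#> 1    PHLPP2  gain gnathostomata
#> 2    PHLPP2  loss     caecilian
#> 3    PHLPP2  loss    cryptodire
#> 4    PHLPP2  loss    pleurodire
#> 5    PHLPP2  loss      squamata
#> 6       AKT  gain gnathostomata

tr  <- sim_tree(40, 123)
sim <- sim_profile_matrix(tr, n_genes = 30, n_coevolving = 3,
                          flip_noise = 0.02, seed = 321)
head(rank_coevolving(tr, sim$matrix, "query", n_perm = 199, seed = 11), 5)
#>   gene       phi     p          q rank
#> 1 g013 1.0000000 0.005 0.04833333    1
#> 2 g022 1.0000000 0.005 0.04833333    2
#> 3 g018 0.8547747 0.005 0.04833333    3
#> 4 g010 0.4276686 0.075 0.54375000    4
#> 5 g005 0.3684551 0.120 0.58000000    5
```

The three planted co-evolving genes (`g013`, `g022`, `g018`) occupy the top
ranks with permutation q-values below 0.05; background genes fall away.

An end-to-end run (simulation → reconstruction → classification → profiling
→ burden → assay scoring) is one call:

```r
rep <- run_pipeline(list(seed = 42, out_dir = "out",
                         stages = list(dollo = TRUE, profile = TRUE,
                                       burden = TRUE, assay = TRUE)))
```

which writes TSV/Newick/JSON outputs plus the fully resolved config under
`out/`. A thin shell wrapper lives at `inst/scripts/pseudolock.R`.

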