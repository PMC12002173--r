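---
title: "Methods: comparative-evolution evidence for pseudoenzymes"
author: "pseudolock authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: comparative-evolution evidence for pseudoenzymes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pseudolock)
```

This vignette is the package's own account of the statistics and procedures
it implements, the assumptions behind them, and the design choices made
where the design was genuinely open. The running scientific example is the
question of whether a protein with a metal-dependent phosphatase fold — such
as PHLPP2, a PPM/PP2C-family protein long described as an Akt phosphatase —
is in fact a pseudophosphatase. Several independent lines of computational
evidence bear on that question, and the package implements each as a
separately testable module.

## Dollo parsimony on binary characters

### Model and assumptions

A binary character (gene present/absent, domain present/absent, active site
intact/degenerate) evolves under the Dollo assumption: it is gained exactly
once and, once lost, never re-gained. This is appropriate for complex
characters whose re-invention is essentially impossible — a multi-domain
gene or a catalytic residue constellation — and it is the assumption under
which "lost independently in k lineages" is a meaningful count.

Given a rooted tree and tip states, `infer_dollo()` places the gain on the
edge above the MRCA of all presence tips (a virtual root edge when the MRCA
is the root, so the gain is always representable) and one loss on each
*maximal* subtree inside the gain clade that contains an observed absence
but no observed presence. Two properties matter:

* **Minimality.** Among all histories with at most one gain consistent with
  the tip states, this one has the fewest losses. The test suite checks this
  against exhaustive enumeration of all internal-state assignments on 200
  random trees of up to 10 tips; on larger trees minimality follows from the
  same maximal-absent-subtree argument. The reconstruction is also unique:
  moving the gain deeper than the MRCA is inconsistent with presence tips,
  moving it shallower can only add losses, and each maximal absent subtree
  must be covered by exactly one loss on its stem.
* **A lower bound on truth.** Parsimony can merge adjacent simulated losses
  but never invent extra ones, so the inferred count is a lower bound on the
  number of losses that actually occurred. The suite checks the bound over
  500 simulated characters, and the package's language follows it:
  "lost in *at least* k lineages".

### Missing data

Unsampled or unassembled genomes are a fact of presence/absence matrices.
Missing tips are excluded from the MRCA computation and afterwards imputed
to the state of their parent node. The consequence — deliberate — is that a
subtree consisting only of missing tips never creates a loss; absence of
evidence is not evidence of loss. How published analyses handle this case is
usually unstated, so this convention is this package's own and is documented
here rather than buried in code.

### Polytomies and edge identity

Polytomies are accepted; the maximal-absent-subtree rule generalizes
unchanged. Edges are addressed by the label of their child node, with
unlabeled internal nodes auto-named `n1, n2, ...` in deterministic preorder,
so event tables are stable across runs and across programs.

## Active-site integrity calling

PPM-family phosphatases need at least two divalent metal ions, M1 and M2,
for catalysis; M3 is dispensable. The caller therefore classifies a sequence
as `active` iff *every* required M1 and M2 position (mapped from reference
numbering through the alignment) carries an allowed residue; M3 positions
are reported but never affect the class. Three deliberate choices:

* **Strict allowed sets.** Aspartate-coordinating positions allow only D by
  default, with a `conservative` mode adding E. Residue identity at
  coordinating positions is the criterion; strictness is the conservative
  default for calling something a *pseudo*enzyme, because a D→E call of
  "still active" is cheap to relax but a false "pseudo" is not.
* **Gaps are mismatches.** A gap in a non-reference row at a required
  position counts as a mismatch, not as missing data: a deleted coordinating
  residue cannot bind metal. (The `ambiguous` class exists in the vocabulary
  for reference-gap corner cases, but the column map is built from the
  reference row's non-gap characters, so it cannot arise from a valid map.)
* **The M2 cysteine flag.** `m2_zinc_flag` marks sequences carrying C at any
  M2-role column. In PHLPP2 the M2 constellation (C799/D820/D822/D1024 in
  human numbering) coordinates a single structural zinc ion; a cysteine
  where an aspartate should be is the signature of that conversion, and the
  flag surfaces it without changing the activity call.

The shipped reference model (`inst/extdata/ppm1a_sites.json`,
`default_site_model()`) uses PPM1A numbering — E37/D38/D60 at M1,
D60/D239/D282 at M2 (the bridging D60 listed once), D146 at M3 — transcribed
from the standard structural literature on the PPM1A binuclear site. The
engine does not depend on this numbering; models are plain JSON/TSV and the
reference id is a parameter, because different studies number from different
reference sequences.

Conservation profiles report per-column residue frequencies over non-gap
characters and information content `log2(20) − H` in bits, the quantity a
sequence logo draws. Gap characters are excluded from the distribution (an
all-gap column is reported as undefined, not an error); whether published
logos include gaps varies and is rarely stated, so the package picks the
convention that keeps the `[0, log2 20]` bound exact.

## Phylogenomic profiling

The association statistic is the phi coefficient — Pearson correlation
specialized to binary vectors, computed from the 2×2 contingency table, and
undefined when a margin is zero (a gene present or absent everywhere carries
no signal). Phi was chosen as the simplest symmetric measure of binary
co-distribution; missing states are pairwise-deleted per gene pair, which
uses every available taxon without imputation.

Shared phylogenetic history makes i.i.d. shuffling of tip states a broken
null: sister taxa are correlated, so tip-shuffled phi values are too small
in magnitude and significance is inflated. The permutation null used here
preserves the tree and the gene's reconstructed history shape: the gain edge
stays fixed, and the gene's number of losses is re-placed uniformly at
random on eligible edges (strictly inside the gain clade, non-nested),
regenerating tip profiles and recomputing phi each time. The p-value is
`(1 + exceedances) / (1 + n_perm)`, one-sided for positive association,
hence never zero; Benjamini–Hochberg q-values are reported across genes.
One boundary case follows from the construction: a gene whose reconstruction
has zero losses has a single-atom null, so its p-value is 1 — a gene that
never diverged from its clade pattern cannot be evidence of co-evolution
under this test. The test's empirical type-I error at α = 0.05, measured in
the acceptance suite over 1,000 independently simulated character pairs on a
40-taxon tree, is required to lie in [0.03, 0.07]; the test is mildly
conservative because the permutation p-values are discrete at
`n_perm = 199`.

## Mutation-burden comparison

Burden rates are per-gene totals normalized by protein length only —
substitutions per 1,000 amino acids, matching how aggregated somatic-mutation
catalogs are usually plotted — with nonsynonymous = missense + nonsense +
frameshift. Frameshifts count as truncating, consistent with loss-of-function
logic for tumor suppressors.

Hotspots are formalized as a test (public catalogs typically mark them from
curation instead, but a planted-truth simulation needs a rule): for a codon
carrying k of the gene's m nonsynonymous records over L codons, the p-value
is the binomial tail `P[Bin(m, 1/L) ≥ k]` against positional uniformity, BH-
adjusted across the gene's mutated codons, with a hard recurrence floor
k ≥ 3 so that an isolated doubleton can never be a hotspot. The uniform null
ignores real positional mutability (CpG, trinucleotide context), which is
out of scope; the k ≥ 3 floor absorbs most of what that simplification would
otherwise miscall at the catalog sizes the generator produces.

The class call is a two-rule decision with explicit thresholds:
`tsg_like` iff truncating fraction ≥ 0.2 *and* CNV skew ≤ −0.3;
`oncogene_like` iff ≥ 1 hotspot *and* skew ≥ +0.3; otherwise
`neutral_like`. When both fire, the oncogene rule wins and the conflict is
flagged rather than hidden. Requiring the mutational and copy-number
signatures *jointly* is what keeps neutral genes from drifting into a driver
class on one noisy axis.

## Assay scoring

* **Calibration.** Ordinary least squares of absorbance on phosphate amount;
  the fit refuses (without `force = TRUE`) when r² < 0.98, because every
  downstream rate divides by this slope.
* **Endpoint rates.** `rate = max(0, (A − blank_mean − intercept)/slope) /
  incubation_time`, in mol product/min. Detectability uses the standard
  limit-of-detection convention, blank mean + 3 blank SDs. The three-sigma
  rule only holds its nominal error rate when the blank SD is estimated from
  enough replicates; the generator provides 16 blank wells (a full plate
  column) for exactly this reason.
* **Time courses.** The initial rate is the slope of the longest *prefix* of
  the course (≥ 5 points) whose linear fit reaches r² ≥ 0.99 — published
  linear-phase rates rarely state a window rule, so the package fixes one
  that excludes substrate-depletion plateaus deterministically. A perfectly
  flat course is treated as perfectly linear with rate 0 (r² is undefined at
  zero variance); if no prefix qualifies, the full-course fit is returned
  with a low-linearity flag instead of an error.
* **Contaminant attribution.** The okadaic-acid logic: with inhibited
  fraction `f = clip(1 − rate_treated/rate_untreated, 0, 1)` (f = 0 when the
  untreated rate is below detection), activity is contaminant-attributed iff
  f ≥ 0.9 *and* the purified enzyme is in molar excess over the inhibitor —
  a sub-stoichiometric dose cannot have silenced the target itself. "Entirely
  lost" is operationalized at 0.9 and configurable; the molar-excess check
  compares total concentrations with no binding model, mirroring the
  stoichiometric argument it encodes.
* **Alkylation accessibility.** `log2((I_MMTS + c)/(I_IAA + c))` per
  cysteine, with calls buried (≥ +2), exposed (≤ −1), else intermediate.
  Within-row ratios cancel peptide ionization efficiency, which is why no
  cross-peptide normalization is attempted. The asymmetric thresholds
  reflect that MMTS-dominance requires protection from the *first* (native)
  labeling step, a stronger claim than mere exposure.

## What the generators emulate — and what they do not

Every module's inputs can be simulated with known truth. The defaults *are*
the study conditions the tests and the acceptance script run under, chosen
once as realistic for the kind of data each module consumes:

* `sim_tree`: pure-birth trees; `sim_dollo_character`: per-branch loss
  probability (default 0.05 in profiling contexts) chosen so a tree of a few
  dozen taxa shows a handful of independent losses — the regime in which
  "lost in at least four lineages" is an interesting statement. Losses are
  per-edge, ignoring branch lengths: a simplification that matches the
  parsimony method's own blindness to time.
* `sim_profile_matrix`: planted co-evolving genes copy the query's realized
  losses, then flip tips at `flip_noise`; background genes are independent
  Dollo characters. Real matrices also contain ortholog-calling error that
  is *correlated* across genes (assembly quality), which this does not
  emulate — perfect recovery of planted genes shows the statistics work, not
  that ortholog calling is solved.
* `sim_catalytic_msa`: degradations are confined to the designated pseudo
  clade and guaranteed to hit a required M1/M2 position, with cysteine in
  the substitution palette so the zinc-site signature occurs. Non-site
  columns are i.i.d. random; there is no substitution model, no indels, no
  rate heterogeneity — by design, since the caller's job is position lookup
  and set membership, not homology inference.
* `sim_mutation_catalog`: background rates default to 15 synonymous and 45
  nonsynonymous events per 1,000 aa aggregated over a 200-sample cohort,
  with a 5% truncating admixture among background nonsynonymous events
  (nonsense/frameshift arising without selection); driver classes multiply
  the nonsynonymous rate by 4, TSGs draw 40% truncating and skew CNV toward
  loss (0.30 vs 0.03 per sample), oncogenes place half their missense events
  on 2 hotspot codons and skew toward gain. These sizes put the neutral
  class's truncating fraction and skew well inside the neutral thresholds
  while keeping the hotspot test's false-call rate under its FDR bound —
  both properties are measured, not assumed, in the acceptance suite.
  Mutations are codon-indexed on the protein; nucleotide-level processes and
  signature context are not simulated.
* `sim_assay` / `sim_alkylation_table`: linear chemistry with Gaussian
  absorbance noise (default calibration slope 3 × 10⁸ absorbance/mol,
  measurement SD 0.002) and log-normal intensity noise (SD 0.25 on the log2
  ratio, class centers `separation` apart, symmetric about the midpoint of
  the call thresholds). Real assays add drift, plate effects and saturation;
  the time-course window rule is exercised against a synthetic kink instead.

All generators take an explicit seed, restore the caller's RNG state, and
are bit-identical on reruns; the pipeline fans a single config seed out to
per-stage seeds deterministically.

## Problem sizes

The test and acceptance workloads use: 200 random trees of ≤ 10 tips for the
exhaustive-oracle comparison (enumeration over all internal-state
assignments), 500 simulated characters on a 20-tip tree for the parsimony
bound, a 40-taxon tree with 30 genes (3 planted) and 199 permutations for
profiling, 1,000 simulated null character pairs for type-I calibration,
30 genes per class over 200 samples for classifier recall plus 1,000 neutral
genes for the hotspot false-call rate, and 50/20 seeded assay replicates for
rate recovery and attribution. These sizes make every stochastic check a
measurement with a usable Monte-Carlo margin while keeping a full run in the
low minutes on one core.

## Known limitations

* Dollo is an assumption, not an inference: for characters that plausibly
  re-evolve (short motifs, single residues) the single-gain constraint is
  wrong and the loss count misleading. No multiple-gain relaxation is
  offered.
* The profiling null conditions on the *reconstructed* (minimal) loss count,
  which underestimates the true number of loss events; the measured effect
  at the default conditions is mild conservatism.
* The hotspot test's uniform positional null and the two-threshold class
  rule are formalizations built for planted-truth calibration, not clinical
  driver calling.
* Tree inference, ortholog detection, alignment construction and raw
  mass-spectrometry processing are all upstream of this package and out of
  scope; every module starts from their outputs.
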