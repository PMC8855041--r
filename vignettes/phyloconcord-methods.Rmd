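---
title: "Methods and design of the phyloconcord pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design of the phyloconcord pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(phyloconcord)
```

`phyloconcord` reimplements, as one seeded and tested pipeline, a protocol
for comparing species trees estimated from multi-locus target-capture data:
locus quality control, species-tree inference under concatenation and the
multispecies coalescent (MSC), tree-landscape ordination, RELL-based
topology tests, and gene/site concordance factors. This vignette records
the models, the tunable parameters, and the design decisions, so that every
number the package produces can be traced to an explicit choice.

## The synthetic data generator

Real target-capture datasets cannot be regenerated at desk scale, so the
package ships a generator that emulates their statistical structure and
returns the generating truth for parameter-recovery work.

**Species tree.** `sim_species_tree()` draws a Yule (pure-birth) tree:
waiting times between speciation events are exponential with rate
(birth rate × current lineage count), tips are ultrametric, and branch
lengths are read as coalescent units. Internal branches are then multiplied
by `ils_scale` — the single knob controlling incomplete lineage sorting
(ILS): internals ≪ 1 coalescent unit produce strong gene-tree discordance,
internals ≫ 1 almost none.

**Gene trees.** `sim_gene_trees_msc()` implements the standard MSC: one
lineage per species; within a species-tree branch of duration *t*, each
pair of gene lineages coalesces at rate 1 (so *k* lineages coalesce at rate
k(k−1)/2) with exponential waiting times; survivors enter the parent
branch, and everything coalesces above the root. The implementation is
validated against the closed-form triplet law: a rooted triplet with
internal branch *t* matches the species tree with probability
1 − (2/3)·e^(−t) (checked at three *t* values within three Monte-Carlo
standard errors). With `linked = TRUE` a single genealogy is drawn and
shared by every locus, emulating the uniparentally inherited,
non-recombining plastid genome.

**Sequences.** `sim_alignment()` evolves i.i.d. sites root-to-tips under
JC69 or HKY85 (transition probabilities from the spectral decomposition of
the normalised rate matrix; branch length × `rate` = expected
substitutions/site). The two-sequence mismatch fraction matches the JC
expectation p = (3/4)(1 − e^(−4d/3)) in simulation. Missing data is
injected in two stages — whole-taxon dropout first (emulating failed locus
capture, the dominant mode in real capture data), then random cells — until
the realised missing fraction is within 2 percentage points of target.

**Locus classes.** `sim_config()` defines three classes whose defaults
emulate published summary structure for exon ("CDS": many short loci,
moderate signal, ~16% missing), intron flank ("INT": longer, high signal,
~35% missing) and off-target plastid loci ("PL": few, low signal, ~78%
missing, linked genealogy). Locus lengths are lognormal (σ_log = 0.55)
matched to the class mean and truncated to the class range; the class rate
multipliers (0.02, 0.068, 0.016 substitutions/site per coalescent unit)
were calibrated once so that the realised proportions of
parsimony-informative sites land near the emulation targets (≈12%, ≈27%,
≈1%) on a 12-taxon desk-scale dataset, and are not adjusted thereafter.
Full scale is 306/239/44 loci; desk scale (the default, used throughout the
tests) is 30/24/8 with the same length and missingness structure. What the
generator does *not* emulate: alignment error, indels, paralogy,
introgression, rate heterogeneity across sites (Γ is deliberately off —
no validated property needs it), or base-compositional heterogeneity.
Passing tests therefore demonstrate correctness of the machinery under a
clean MSC + JC world, not robustness to every pathology of real data.

## Locus QC

`trim_gapped_columns(gt = 0.2)` keeps exactly the columns whose non-gap
fraction is ≥ `gt` (the classic gap-threshold rule; only `-` counts as a
gap, while `N` is missing for statistics but a residue for trimming).
Trimming is idempotent.

`bowker_symmetry_test()` is the matched-pairs test of symmetry on the 4×4
joint state counts of two aligned sequences; `filter_loci_symtest()`
aggregates pairwise tests to a locus decision using the *max-pair rule*:
the locus p-value is that of the pair with the largest statistic (pairs
need ≥ 50 shared called sites), and the locus is removed when p < α
(default 0.05). No multiplicity correction is applied — deliberately, to
mirror the screening behaviour of the alignment-filtering tools this
reproduces. Consequence worth knowing: with many taxa the locus-level
test is anticonservative on perfectly symmetric data (with ~66 testable
pairs, roughly half of null loci are removed). The per-pair test itself is
calibrated (type-I error ≈ α, verified by simulation); the aggregation is
a screening heuristic, not a calibrated test, and `alpha` is exposed.

`count_pis()` counts columns with ≥ 2 called states each in ≥ 2 sequences;
`summarize_dataset()` reproduces the usual per-dataset table (total length,
PIS count/%, AT/GC% over called bases, length range, missing %).

## Likelihood engine

`site_loglik()` is Felsenstein pruning over compressed site patterns; gaps
and `N` contribute partial likelihood 1 over all states; stationary
frequencies sit at the root, which is irrelevant to the total under
reversibility (re-rooting invariance is tested at 1e-8). The
implementation is checked against an exhaustive sum over internal-state
assignments on ≤ 5-leaf trees and against an independent likelihood
implementation.

`optimize_branch_lengths()` fits branch lengths on a fixed topology by
sweeps of edge-wise optimisation: per sweep, tip-ward and root-ward partial
likelihoods are computed once, and each branch is optimised by a bounded
scalar search on [0, 10] substitutions/site using only its incident
partials. Because the independent per-edge optima can jointly overshoot
when lengths are strongly correlated (heavy missing data does this), the
joint step is damped (step-halving) and, failing that, reduced to the best
single-edge update; sweeping stops when the total log-likelihood improves
by < 1e-6 or after 20 sweeps (the cap raises a warning and returns the
best tree found — on large supermatrices the final sweeps chase
sub-1e-3 improvements and the cap is routinely the active stop). The
bounds and tolerance are conventional choices, exposed as arguments.

Gene trees are inferred by neighbor joining on ML (JC/HKY) pairwise
distances rather than full ML tree search — a deliberate scope decision:
NJ preserves the discordance structure the downstream congruence machinery
must detect, runs at desk scale, and externally supplied Newick gene trees
can bypass this stage entirely. Saturated pairs (p ≥ 0.75 under JC) are
imputed as the largest finite distance + 1 and flagged.

## Species-tree grid

`msc_tree()` maximises the quartet score (number of gene-tree quartets
concordant with the candidate), the objective that makes quartet methods
statistically consistent under the MSC. For n ≤ 8 taxa the maximiser is
found by exhaustive enumeration of all (2n−5)!! unrooted topologies (ties
broken by smallest Newick string); above that, NNI hill-climbing from an
NJ start on average topological gene-tree distances, which by construction
never scores below its start. Internal branches are annotated with
*normalised quartet support* — the share of the dominant resolution among
the three, over resolved gene-tree quartets spanning the branch. This is
intentionally **not** ASTRAL's local posterior probability (whose formula
this package does not reimplement); mixing the two semantics silently
would mislead, so the label differs. No automatic polytomy collapse is
performed; users can collapse low-support branches themselves.

`concatenated_tree()` builds the supermatrix, infers topology by NJ on
supermatrix distances, re-optimises branch lengths by ML, and (for the
partitioned variant) gives each locus a rate scalar multiplying the shared
branch lengths, optimised jointly with an identifiability constraint (mean
log-rate 0). Support is a site-resampling bootstrap that resamples within
loci, preserving partition sizes.

`msc_bootstrap()` provides the two bootstrap flavours of the grid: the
two-level gene+site bootstrap (resample loci, then sites within each
sampled locus, rebuild gene trees, re-estimate; the classic 100-replicate
design) and a site-only fast analog standing in for ultrafast-bootstrap
style supports (replicate counts 100 and 200 by default at desk scale;
1,000 replicates reproduce the full design when time allows). The analog
reproduces the *comparison structure* — one more support flavour per
dataset — not the internals of any particular fast-bootstrap algorithm,
and it is labelled as such. A greedy majority-rule-extended consensus of
the replicates is attached.

`run_protocol()` assembles the 4 × 5 grid: datasets {ncCDS, ncINT, ncGD
(= CDS ∪ INT loci and gene trees), plCDS} × methods {As, Abs, AUFbs, Cpa,
Cun}, then harmonizes all 20 trees (explicit drop list, rerooting on a
named outgroup taxon — the drop list is explicit because no principled
selection rule exists for which tips to discard before landscape
analysis).

## Tree landscape

`rf_distance()` is the symmetric difference of non-trivial bipartition
sets on *unrooted* trees; `kc_distance()` the Euclidean distance between
Kendall-Colijn vectors of *rooted* trees (root-to-MRCA edge counts and/or
path lengths per tip pair, mixed by λ). λ defaults to 0 (pure topology) —
the conventional default where no value is stated — and is configurable.
RF is reported unnormalised, with a normalised option (÷ 2(n−3)).
The rooted/unrooted assignment (RF unrooted, KC rooted) follows the
methods convention of the protocol being reproduced; its figure captions
swap the two labels, and this package follows the methods text.
`pcoa()` is classical scaling (negative eigenvalues dropped and counted);
`find_groves()` cuts a Ward-linkage dendrogram on the first 3 axes (3
mirroring the "most informative axes" convention) into a requested number
of groves.

## Topology tests

`rell_resample()` draws round(scale × n) sites with replacement and sums
per-site log-likelihoods — implemented as a multinomial draw over collapsed
identical columns, which is distributionally identical and much faster.
`sh_test()` is the classic SH construction (centring per tree, null gap =
max-tree replicate minus own replicate); the best tree gets p = 1 by
construction. `au_test()` is the canonical multiscale construction:
bootstrap proportions at scales 0.5–1.4, normal quantiles fitted by
weighted least squares to d·√r + c/√r, p = 1 − Φ(d − c); BP values are
clipped to [1/(2B), 1 − 1/(2B)], replicate-maximum ties are split equally
(duplicated topologies occur in real tree sets), and fully degenerate
trees short-circuit to p ∈ {0, 1} with a flag. `compare_to_fixed()`
re-optimises branch lengths of the fixed tree and every candidate on the
evaluation supermatrix before testing — RELL requires per-site
log-likelihoods under a common alignment, so re-optimisation is the only
coherent choice — and caches one optimisation per distinct topology.
Defaults: B = 10,000 replicates, α = 0.05. Calibration is verified by
simulation: AU type-I error near nominal on the three tied resolutions of
a star tree, SH never rejecting the ML tree.

## Concordance factors

`gcf()`: a gene tree is decisive for branch A|B when it has ≥ 2 taxa on
each restricted side (the standard convention, stated explicitly so the
test oracle can mirror it), concordant when it contains the restricted
bipartition; gCF = 100·concordant/decisive, `NA` (never 0) when nothing is
decisive. `scf()` samples, per branch, `q = 100` quartets (one taxon
uniform from each of the four adjacent subtrees, with replacement across
quartets, seed recorded); a site is decisive for a quartet when all four
taxa are called and the pattern cleanly supports exactly one pairing; when
fewer than `q` distinct quartets exist, all are enumerated, making the
statistic deterministic. Under pure noise sCF sits at the 1/3 floor —
verified on i.i.d. uniform alignments. `classify_scores()` applies the
reporting bands (gCF: <30 low, ≥80 high; posterior probability: <0.75 low,
≥0.9 high; bootstrap: <75 low, ≥90 high). `clade_recovery()` distinguishes
"contradicted" (the clade's split is incompatible with a split the tree
contains) from "unresolved" (compatible but absent → `NA`).
`cf_heatmap_table()` composes these into the long clade × tree table that
feeds per-dataset heatmaps, scoring each dataset's trees against that
dataset's own gene trees and supermatrix.

## Problem sizes and determinism

Desk scale throughout: 12 taxa, 30/24/8 loci at full published length
distributions; the unit-test mini-protocol is smaller still (9 taxa,
8/6/4 shortened loci, 5–10 bootstrap replicates). Exact-mode MSC is used
up to 8 taxa; the 12-taxon protocol uses the NNI heuristic with
warm-started bootstrap replicates. Every stochastic stage takes a seed,
and a protocol run is reproducible byte-for-byte from (config, seed).

## Known limitations

* Gene trees come from NJ on pairwise distances; very short or very gappy
  loci yield noisy gene trees, which depresses gCF relative to full ML
  gene trees.
* The locus-level symmetry filter inherits the max-pair heuristic's
  anticonservatism at large taxon counts (see above).
* Normalised quartet support is not a posterior probability; its bands are
  those of bootstrap-style supports.
* The AU fit can fail on pathological BP curves; it then substitutes the
  SH p-value with a warning rather than failing the run.
* HKY85 pairwise distances use numeric MLE and are considerably slower
  than the closed-form JC path; the JC default is appropriate for the
  simulated data the pipeline validates against.
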