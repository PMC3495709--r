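---
title: "Graph-based progressive alignment with phylogeny-aware gap placement: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Graph-based progressive alignment: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(graphmsa)
```

## The problem

Progressive multiple sequence alignment merges sequences pairwise along a
guide tree. Two classical weaknesses motivate this package's design: a
plain profile merge penalizes a single insertion event again at every later
merge, and an error made at an early merge (because of a wrong guide tree,
or an alternative splicing that is genuinely inconsistent with the species
tree) can never be revised. `graphmsa` addresses both by representing the
ancestral sequence at every internal guide-tree node as a **partial-order
sequence graph** rather than a linear profile: a DAG with explicit start
and end sentinels in which every path is a candidate ancestral sequence,
and whose edges carry the full indel history of the sub-tree.

## Sequence graphs and phylogeny-aware gap placement

Leaves are linear chains, one node per residue. At each internal node the
two child graphs are aligned and merged: matched nodes fuse (their columns
are united), and every node and edge of both children is retained — the
indel history is never deleted, which is what prevents an insertion from
being penalized repeatedly as it travels towards the root.

A new gap found during an alignment is **not** immediately classified as an
insertion or a deletion. Both alternatives are kept in the merged graph — a
character path and a skip edge around it — and the decision is postponed to
the alignment at the next guide-tree node towards the root, the closest
outgroup: if any node of the character path is matched there, the
characters were ancestral and the gap is a deletion; otherwise it is an
insertion. At the root, where no outgroup exists, remaining undecided
indels default to insertions.

Edges off the current ancestral path remain usable in later alignments but
are penalized in natural-log space by

$$E = -\frac{\Delta d}{l},$$

where $\Delta d$ is the evolutionary distance (cumulative branch length)
between the current node and the edge's last use, and $l$ (option
`lifetime`, CLI `-l`) is the e-folding distance of the reuse probability.
$l = 0$ forbids reuse entirely — insertions, once inferred, are kept
forever — and $l = \infty$ makes all historical paths free. The default is
$l = 1$ expected substitution per site; the functional form (exponentially
declining reuse probability) is fixed, the constant is exposed because no
canonical value exists. Undecided (pending) alternatives carry no penalty,
since no decision against them has been made yet. "Height" of a tree node
is defined as the maximum cumulative branch length to any descendant leaf,
which is monotone along every root-ward path even for non-ultrametric
trees — a property the penalty requires.

One design question is genuinely open: after an indel decision, should the
losing alternative be discarded? This implementation keeps both paths
indefinitely, with the losing one penalized, because revocation of earlier
decisions is exactly what makes the method robust to guide-tree error and
alternative splicing. A consequence (shared with the published behaviour of
this family of aligners) is that one true event can resurface as several
inferred events in the indel statistics.

## Scoring: a distance-dependent pair-HMM on probabilistic ancestral sequences

Graphs are aligned by Viterbi dynamic programming over node pairs with four
layers — match $M$, gaps $X$ and $Y$, and the silent running maximum $H$ —
where the match layer maximizes over all pairs of predecessor nodes and the
gap layers over one graph's predecessors. The transition scores derive from
a pair-HMM with gap-opening probability $\delta$, gap extension
$\varepsilon$, and termination $\omega$:

* `match_init` $= \log(1 - 2\delta(d) - \omega)$,
* `gap_init` $= \log \delta(d)$, `gap_ext` $= \log \varepsilon$,

with the opening probability growing with the combined branch distance $d$
separating the graphs, $\delta(d) = \delta\,(1-e^{-gd})/(1-e^{-g})$, so
that $\delta(1)$ equals the base parameter. The defaults
($\delta = 0.03$, $\varepsilon = 0.6$, $\omega = 0.005$, $g = 1$) are
configuration values: gap parameters of this kind are fitted to curated
benchmark alignments and no canonical printed set exists, so they are
exposed in `msa_options()` rather than hard-coded. $\delta(d)$ is capped at
0.45 to keep `match_init` defined, and degenerate probabilities are floored
at $\log 10^{-6}$; $-\infty$ is reserved for structurally forbidden moves.

Terminal gaps are treated specially because indels are empirically more
frequent at protein ends (and sequence boundaries are often artefacts of
domain annotation): a separate probability $\alpha$ (option
`end_indel_prob`, default 0.1, `-1` to disable) replaces $\delta(d)$ for
gap runs opened from the start pair or held at a predecessor of the end
sentinel. For linear sequences this is exactly the first/last row and
column of the DP matrix. The transition into the final cell costs
$\log\omega$ from the match history. Optionally, when both graphs' initial
character nodes are all methionine, matching them receives a bonus
(`force_align_m`), reflecting that mature proteins nearly always retain the
initiator M.

Emissions come from **probabilistic ancestral sequences**: each node stores
the conditional likelihood $\mathcal{L}(t, \mathrm{root}=x; C)$ of its
column under each ancestral amino acid $x$, computed by Felsenstein's
pruning recursion with the WAG (default) or GONNET substitution model,
optionally with equilibrium frequencies re-estimated from the input
(`estimate_aafreqs`, one pseudocount per amino acid). The match score of
nodes $i, j$ at branch distances $d_L, d_R$ is the log-odds of common
ancestry against independence,

$$S(i,j) = \log \mathcal{L}_{\mathrm{joint}}(i,j) - \log \mathcal{L}(i) -
\log \mathcal{L}(j),$$

where the joint likelihood applies one further pruning step and sums over
the root state under the equilibrium distribution. The log-odds form makes
background (uninformative) columns score zero, so all gap cost lives in the
gap scores — the standard pair-HMM decomposition. Likelihood vectors are
stored scaled to maximum entry 1 with the log-scale accumulated separately;
because $S$ is a ratio, the scale factors cancel exactly.

Ties in the DP are broken deterministically (M over X over Y, then the
smallest predecessor pair in topological order), and the topological order
itself is Kahn's algorithm with a smallest-id tie-break, so the aligner is
fully deterministic — there is no random number generator anywhere in the
alignment path.

Numerical notes: the 20-state generators are built from symmetric
exchangeabilities and equilibrium frequencies, scaled to one expected
substitution per unit distance; transition matrices use the symmetric
similarity transform $\mathrm{diag}(\sqrt\pi)\,Q\,\mathrm{diag}(1/\sqrt\pi)$,
whose real spectrum (guaranteed by reversibility) gives a stable matrix
exponential. The GONNET generator is derived from the published 1992
log-odds table: the implied equilibrium frequencies solve the linear
marginal-consistency system, the conditional matrix at the table's PAM
scale is log-transformed through the same symmetrization, spurious negative
off-diagonal rates are clamped, and the result is re-symmetrized and
rescaled.

## Context-specific profiles

Substitution patterns depend on sequence context. Instead of adding HMM
states, each leaf position $i$ is matched against a library of context
profiles (width 13 by default): the posterior weight of profile $k$ for the
window $X_i$ is

$$P(p_k \mid X_i) \propto P(p_k) \prod_j p_k(j, x_{i+j})^{w_j}, \qquad
w_j = 1.3 \cdot 0.9^{|j|},$$

computed in log space, with out-of-range window positions contributing a
factor of one (no invented boundary letters). The position-specific
substitution distribution is the posterior mixture of the profiles' centre
columns. The expected divergence encoded in such a profile is adjusted to
the leaf's terminal branch length by the interpolation

$$P'(y \mid X_i) = (1-\tau)\,\delta_{x_i,y} + \tau\,P(y \mid X_i), \qquad
\tau = \min\!\left(1, \frac{\hat\delta(d)}{1-\bar c}\right),$$

where $\hat\delta(d)$ inverts Kimura's distance formula
($d = -\log(1-\delta-0.2\delta^2)$) and $\bar c$ is the library's expected
conservation. $\bar c$ is computed by the width-one matching procedure —
posterior over profiles given a single centre residue, centre-column
mixture, conservation averaged over equilibrium frequencies. (The compact
published double-sum formula for this quantity omits the two normalization
steps of the matching equations; the normalized computation is used here
because it, and not the raw double sum, has the expected limits: a single
delta profile and a uniform library both give $1/20$ under uniform
frequencies.) $\tau$ is capped at 1 for branches whose expected divergence
exceeds $1 - \bar c$.

Adjusted profiles convert to probabilistic leaves by Bayes' theorem,
$\mathcal{L}(\mathrm{root} = y; x_i) \propto P(y \mid X_i)/\Pi_y$; terminal
branch lengths are then set to zero in the substitution model, because the
expected terminal-branch evolution is already encoded in the leaf vectors.
The gap model keeps the true branch lengths. A deterministic synthetic
library generator (`generate_test_library`) provides a valid library with
delta-like, uniform, and random profiles so that all profile code paths are
exercised without any external download; real CS-BLAST-style libraries load
through a tolerant parser that reports its decoding interpretation
(plain probabilities, or $2^{-v/1000}$ scaled negative log2 values).

## Guide trees

The initial guide tree is built without any alignment: sequences are
compressed to the six Dayhoff classes, distinct 6-mers are collected, and
the shared fraction $F = |A \cap B| / \min(|A|,|B|)$ is corrected for the
random background share and log-transformed,
$d = -\log\frac{F - F_\mathrm{rand}}{1 - F_\mathrm{rand}}$, clipped to
$[10^{-5}, 2.2]$. The variance proxy for these distances is $V = d$. The
compression, word length, and clip constants are exposed configuration; the
2.2 cap reflects that pairwise distances beyond about two expected
substitutions per site are effectively unresolvable for these estimators.

The tree is built by **BioNJ**: neighbour joining whose reduction step
weights the two merged rows by $\lambda$ chosen to minimize the variance of
the reduced distances given the variance matrix, clamped to $[0,1]$. The
implementation takes an explicit variance matrix because subsequent
iterations re-estimate distances by maximum likelihood from the alignment's
induced pairwise rows (`ml_pairwise_distance`: bounded scalar optimization
of the independent-sites likelihood on $[10^{-5}, 10]$, variance from the
numerical curvature at the optimum; or p-distances via the Kimura transform
with `--pdist`). With $V = D$ the procedure reduces to the classical BioNJ,
and with constant variances to classical NJ — both checked against the
independent implementations in ape. The unrooted result is rooted at the
midpoint of the longest leaf-to-leaf path (a deterministic choice that
fixes the progressive order; no rooting rule is canonical here), and
estimation–alignment rounds iterate until the tree topology repeats
(Robinson–Foulds distance 0) or the iteration cap (default 2 passes) is
reached.

## The simulator

`simulate_msa()` generates ground-truth data under the same evolutionary
scenario the aligner targets: a root sequence of gamma-distributed length
(shape 2, scale set for mean 300 — only the mean is canonical, the shape is
a configurable choice), residues and substitutions under WAG with
discrete-gamma rate variation among sites (4 equal-probability categories,
shape 1 by default, category means computed from the incomplete-gamma
formula), and insertions and deletions each as independent Poisson
processes at 0.005 events per expected substitution, with truncated-Zipf
lengths (exponent solved by bisection so the truncated mean is 3.5 with
maximum 50 — the exponent itself is not a published constant). Evolution
along each branch is an exact Gillespie simulation: substitution jumps at
rate $r_i \cdot (-Q_{x_i x_i})$ per site, the indel clocks at
$0.005 \sum_i r_i$ (the expected-substitution rate scale), insertion
positions uniform, inserted residues from the equilibrium distribution and
rates from the category distribution, deletions truncated at the sequence
end. Every residue ever created carries a unique site id placed into a
global column registry, so the true alignment records all homologies
including nested insertions; the event ledger (every substitution,
insertion, deletion per branch) replays to the exact leaf sequences, which
is asserted in the tests.

What the simulator does **not** emulate: domain-level events (duplications,
rearrangements), compositional heterogeneity across lineages,
context-dependent substitution, and indel hotspots. Passing the simulation
suite therefore demonstrates correctness of the algorithms under the
homogeneous-model scenario, not alignment accuracy on real proteins.

## Quality metrics

`developer_modeler_scores` counts homologous residue pairs (fD divides the
shared pairs by the reference's pairs, fM by the test's), `column_score`
counts reference columns whose residue set is reproduced exactly, and
`relative_length` compares column counts. `indel_event_stats` diffs each
branch's parent/child ancestral presence rows in the reconstructed
alignment; an event is correct if it starts at the correct column, has the
right length, and lies on the correct branch, with columns matched between
test and reference through the residues they contain, never through column
indices. `robinson_foulds` wraps the standard bipartition symmetric
difference, normalized by $2(n-3)$.

Ancestral presence is tracked with one-level resolution: a pending indel
created at node $m$ is decided at $m$'s parent, and reuse of an old path at
a higher node does not retroactively edit lower nodes' ancestral sets. This
is a deliberate simplification; its visible consequence is that a revoked
inference appears as extra events rather than as a corrected history.

## Validation design and problem sizes

The test suite checks every computational core against an independent
oracle: the graph Viterbi DP against exhaustive enumeration of all affine
alignments (200 random pairs of length at most 6 — small enough for
complete enumeration, large enough to cover every transition type); the
pruning recursion against brute-force summation over ancestral state
assignments (1000 random trees with up to 4 leaves, relative error below
$10^{-10}$); the likelihood of a 4-taxon alignment against phangorn's
independent implementation; BioNJ against exact recovery of additive 4- and
6-taxon matrices and against ape's bionj/nj; the Kimura transform against
its algebraic inverse on a grid; and the simulator's calibrated laws
(indel-length mean 3.5, maximum 50; root-length mean 300; insertion rate
0.005 per expected substitution) by direct Monte-Carlo estimation at
$10^4$–$10^5$ draws.

Two system-level properties are checked on simulated data at the generator
defaults (8 taxa, maximum pairwise distance 2). First, gap-pattern
consistency: an insertion should appear as gaps in exactly the
non-descendant rows. This is evaluated on *clean, conserved-flank*
insertion events — contiguous in the true alignment, not overlapping any
other indel, flanking columns present in every leaf and conserved within
the clade where the indel decision is made (the event's descendants plus
their sibling clade), and with boundary residues differing from the flanks.
The last condition excludes events whose left/right placement against an
identical neighbouring residue is score-equivalent, where no aligner can
recover the registry's arbitrary choice; residual failures are dominated by
substitution homoplasy (an inserted residue mutating to match a flank).
Under these conditions the consistency rate is around 94% across several
independent seed sets. Second, robustness to guide-tree error: aligning
with one swapped leaf pair under path reuse ($l=1$) versus frozen indels
($l=0$). The reuse machinery demonstrably operates (demoted edges are
re-traversed, and the alternative-splicing test shows that shared exons
align to common columns only when reuse is allowed), but the net effect of
the leaf swap on the developer score is a statistical tie in this
implementation: per-replicate differences are below 0.01 with signs split
roughly evenly (paired means between $-0.002$ and $+0.0002$ across
independent 20–100 replicate batches), so the directional claim is at the
mercy of sampling noise; see the acceptance suite for the fixed-seed
measurement.

Problem sizes throughout (sequence length ~300, 5–10 taxa, 30-replicate
property batches) were chosen as the smallest sizes at which each check is
statistically meaningful.

## Limitations

Protein sequences only (no DNA/codon models); Viterbi alignment only (no
posterior decoding); no iterative refinement of the final alignment; guide
trees of at most a few hundred taxa are practical since distance estimation
is quadratic; the DP is quadratic in sequence length with a predecessor
factor, and graphs beyond roughly 2000 nodes per side are refused.
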