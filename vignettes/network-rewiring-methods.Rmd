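---
title: "Methods: quantifying rewiring in domain-peptide interaction networks"
author: "NetRewire"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying rewiring in domain-peptide interaction networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(NetRewire)
```

# The problem

Peptide recognition modules such as SH3 domains, and kinase catalytic
domains, bind short linear motifs (roughly 5-9 residues) on their partner
proteins. Because a domain's binding preference can be summarized as a
position weight matrix (PWM), interaction networks can be *predicted* in
any species with a sequenced proteome, rather than mapped by homology from
a model organism. That makes domain-peptide networks an unusually good
setting for measuring how fast protein interaction networks rewire: the
same specificity model applied to many proteomes yields directly comparable
per-species networks, and differences between them can be attributed either
to **interaction rewiring** (a binding site gained or lost while both genes
survive) or to **protein change** (gain or loss of a partner gene).

NetRewire implements that full analysis stack: PWM scanning with
disorder/accessibility gating, per-species network assembly, orthology-
constrained network comparison, normalized change-rate estimation with
saturation and randomization analyses, interaction-profile phylogenies,
binding-site clustering and a divergence-weighted binding-site conservation
metric — plus a forward simulator of network evolution that provides ground
truth for every stage.

# Site scoring and network assembly

A specificity class `c` is a count matrix over motif positions. Counts are
converted to a strictly positive profile with Henikoff position-based
pseudocounts,

$$m(p, aa) = \frac{n(p,aa) + B_p\, b_{aa}}{N_p + B_p}, \qquad
B_p = 5 R_p,\; b_{aa} = 1/20,$$

where $R_p$ is the number of distinct residues observed at position $p$.
A candidate peptide is scored additively and normalized by the optimal
score,

$$\mathrm{score} = \frac{\sum_p m(p, aa_p)}{S_{opt}}, \qquad
S_{opt} = \sum_p \max_{aa} m(p, aa),$$

so scores lie in $(0, 1]$ and the consensus peptide scores exactly 1. The
additive, $S_{opt}$-normalized form is this package's declared reading of
the scanning score: it uses exactly the two named ingredients (per-position
adjusted counts, optimal binding score) and gives the score scale a fixed
interpretation. Scanning scores every window of a protein and attaches the
mean per-residue disorder and surface-accessibility values over the window;
per-protein best-score backgrounds can be converted to upper-tail p-values
under a fitted location/scale Student t (df = n - 1, location and scale the
sample mean and sd).

Networks are assembled with the selection rule used for the yeast SH3
networks: sites must pass strict feature gates
(`accessibility > minAccessibility`, `disorder > minDisorder`; SH3-style
defaults 3 and 0), then the top `topN` surviving sites per class are kept
(default 30). The ranking is made total (score desc, accessibility desc,
target id, start) so assembly is deterministic and independent of input
order. Note one subtlety: with a *binding* top-N cap, tightening a feature
gate can admit previously excluded sites into the freed slots, so edge
monotonicity in the gates is only guaranteed when the cap does not bind.

# Orthology and window mapping

Cross-species comparisons run through orthogroups with reconstructed gene
trees. For rate estimation the mapping is constrained to one-to-one /
many-to-one with respect to the reference species: for each reference
protein and species, the orthogroup member with the smallest gene-tree
patristic distance is chosen, ties broken lexicographically. "Global"
comparisons (conservation fractions, profile matrices) instead accept any
orthogroup member as a target ortholog (one-to-many). Reference proteins
missing from their gene tree are excluded with a warning.

Binding-site positions are compared through per-family alignments (one row
per species). A site window is the site plus 10 flanking residues on each
side, clipped at the sequence ends, converted to alignment columns and read
back as residue coordinates in each species. The "local" conservation
criterion asks for a same-class site on the mapped ortholog whose start
falls inside that window; window membership is start-based, which is stable
under end clipping. The local criterion is strictly stronger than the
global one on the same constrained mapping.

# Rates, saturation and nulls

Change counts are normalized as

$$\mathrm{rate} = \frac{intChanges}
{orthDomainProteins \times orthProteins \times divergenceTime},$$

interaction changes per protein pair per million years: the fraction of
observed changes over all possible interactions among proteins with
orthologs, per My. Gains are counted over the other species' edges whose
endpoints have reference orthologs, keeping the numerator consistent with
the denominator's "proteins with orthologs" universe; reference edges with
no orthologous endpoints belong to the protein-change mechanism and are
excluded from rewiring counts (reported as `skipped`).

Because an interaction lost and later regained is observed as conserved,
observed change counts saturate with divergence time. Under the two-state
edge process with gain hazard $\lambda_g$ and loss hazard $\lambda_l$ the
expected observed count is

$$E[\Delta](t) = n_{edges}\,\pi_{off}(1 - e^{-(\lambda_g+\lambda_l)t})
 + (n_{pot} - n_{edges})\,\pi_{on}(1 - e^{-(\lambda_g+\lambda_l)t}),$$

which `expectedObservedChanges()` evaluates and the simulator reproduces
empirically. Two practical consequences are built into the test suite: the
estimated rate falls with reference distance (so distant references
underestimate the true rate), and rates should be quoted against the
closest available relative.

Significance of slow rewiring is assessed against degree-preserving
randomizations: double-edge swaps on the bipartite (domain, class) to
target graph, rejecting swaps that would create duplicate edges (default
100 x |E| attempts), with the add-one empirical p-value
$p = (1 + \#\{null \le observed\})/(1 + n_{reps})$, which never returns 0
at finite replicates. The error bound on a rate is
`2 (FP + FN) / denominator` — each wrong prediction can contribute at most
two spurious changes.

# Profiles, clusters and the conservation metric

Treating each orthology-mapped interaction as a binary character (1 =
present) gives a species-by-interaction profile matrix; normalized Hamming
distances between rows feed neighbor joining (`ape::nj`). NJ stands in for
a minimum-evolution tree search: both are consistent on additive matrices,
and NJ is fully specified, which the test oracles exploit (3-taxon closed
form, exact recovery of additive matrices). Species lacking an orthologous
pair are coded 0, consistent with the "present = 1, else 0" character
definition.

Binding-site clusters on a target are maximal greedy groups in which every
pair of sites overlaps by more than 50% of the shorter site's length. The
greedy pass is order-deterministic (start asc, length desc, class lex); a
site that fails the all-pairs predicate closes the active cluster and
seeds the next. The output is always a partition of the input, and every
emitted cluster satisfies the predicate for all pairs — both properties are
oracle-checked on random instances.

The divergence-weighted conservation metric scores how much a reference
binding site has evolved in each ortholog: the best PWM score inside the
mapped ±10-residue window, minus the reference site's score
($\delta_o = s_o - s_{ref}$), averaged with weights $w_o = 1/d_o$
(reciprocal gene-tree distances). Values near zero mean the site is intact
everywhere; negative values flag diverging sites. Two numerical choices:
$\delta$ below $-\tau$, with $\tau$ twice the worst accepted score in the
reference network, is floored at $-\tau$ (saturating "site absent" signals
without discarding the species — one reading of the published threshold,
flagged as such), and zero gene-tree distances are floored at $10^{-6}$
before taking reciprocals. Sites with no scorable ortholog return `NA`
rather than 0. Column-level sequence conservation is the normalized inverse
entropy of the non-gap residues times a gap weight
$\max(0, 1 - gaps/nongaps)$ — an emulation of unweighted-frequency
alignment conservation scoring with gap down-weighting, not a
reimplementation of any external tool.

# The simulator

The simulator is an explicit modeling choice, not a reconstruction of any
published evolutionary process: it generates the *kind* of data the
analysis consumes, with known ground truth.

* **Species tree**: rooted binary newick, branch lengths in My. One global
  RNG stream is seeded from the config; branches are processed in preorder,
  so a seed fully determines the output (byte-identical fixture sets).
* **Gene content**: every gene founds an orthogroup; duplication and loss
  are per-gene Poisson processes (defaults 0). Gene trees mirror the
  species tree with duplication bifurcations at their event times; with
  both rates zero every species keeps exactly one copy and orthology is the
  identity. Duplicate copies start without interactions.
* **Direct mode**: the potential edge set is all domain proteins x all
  target proteins (matching the rate equation's denominator semantics). The
  ancestral network is drawn at `edgeDensity` (default 0.25; ~a quarter of
  scannable targets per class is in the range the yeast SH3 networks
  occupy, ~800 edges over 30 classes x ~400 proteins). Each potential edge
  then follows an independent two-state jump process; every toggle is
  logged, and replaying the log reproduces each leaf network exactly. With
  `degreeCoupling = TRUE` an edge's loss hazard is divided by its target's
  ancestral in-degree, creating hub-coupled retention.
* **Mechanistic mode**: each class gets a random consensus and a sharply
  peaked count matrix; true sites are the consensus planted at recorded,
  non-overlapping positions in disordered, accessible stretches. Sequences
  accumulate uniform substitutions (choosing among the 19 other residues);
  no networks are emitted — they must re-emerge by scanning the evolved
  proteomes. Tracks are drawn once from the ancestral site map and
  inherited unchanged, so site turnover is purely sequence-driven. Indels
  are off, so family alignments are exact by construction.

What the simulator does *not* emulate: realistic amino-acid substitution
matrices, indels, codon structure, track evolution, or binding-energy
models. Passing tests therefore demonstrate the correctness and the
qualitative phenomenology of the pipeline (saturation, reference bias,
hub-coupled retention), not quantitative agreement with any real proteome.

# Study sizes used by the packaged analyses

The packaged test suite and `scripts/acceptance.R` run the following
desk-scale studies, chosen once as the package's standard conditions:

* **Saturation / reference bias**: 10 classes x 120 targets (1200
  potential edges), $\lambda_g = \lambda_l = 0.01$/My at stationary density
  0.5, on a divergence ladder with leaf-to-leaf paths 2-370 My and a close
  (80 My) sister for the most distant clade, so the same run exhibits both
  the saturation curve and the near-vs-far reference comparison. Observed
  counts are compared with the closed form at 3 SD (per-edge flip
  probabilities are uniform when the two hazards are equal).
* **Null model**: mechanistic run, 6 classes x 40 targets, 2 My branches at
  substitution rate 5e-4 (sites conserved), 200 degree-preserving
  randomizations.
* **Tree recovery**: 10 classes x 150 targets on a 6-species tree,
  $\lambda = 0.004$/My — enough toggles per branch for additive-like
  distances; profile-tree topology must match the generating tree (RF 0).
* **In-degree coupling**: 15 classes x 80 targets, degree-coupled loss
  ($\lambda_l = 0.025$/My), reference 1 My from the root with compared
  species at 60-80 My paths. The reference sits next to the root because
  the coupling acts on *ancestral* in-degree: a reference that has itself
  drifted for tens of My measures hub structure the coupling no longer
  reflects, which empirically halves the observable correlation.
* **Conservation metric**: mechanistic runs with zero substitution (metric
  must be exactly 0 at every planted site) and a 250 My branch at 0.002
  substitutions/residue/My (metric strictly negative where anchors
  mutated).

# Known limitations

* The published yeast rates are reproduced from their printed count and
  ortholog inputs; re-deriving those inputs requires the original PWM sets
  and 23 proteomes, which are not redistributable here.
* One published protein-change value (the S. mikatae row) is inconsistent
  with its own printed inputs by a factor of ten and is excluded from the
  reproduction set.
* `conservedLocal` counts gains by reverse-mapping other-species sites
  through the same family alignments; pairs whose family alignment is
  missing are skipped and counted, not imputed.
* The profile-tree stage assumes networks mapped to a common reference;
  characters unmappable to the reference frame are dropped.
* Scanning is dense (every window scored); for proteome-scale inputs
  memory grows with L x classes, and callers should filter by the feature
  gates early.
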