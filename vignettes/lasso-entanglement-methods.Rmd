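---
title: "Methods: detecting non-covalent lasso entanglements and their role in misfolding"
author: "lassotop"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: detecting non-covalent lasso entanglements and their role in misfolding}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lassotop)
```

## The geometry being detected

A non-covalent lasso entanglement (NCLE) has three parts: a backbone **loop**
closed by a non-covalent residue-residue contact, a **thread** — a stretch of
the N- or C-terminal tail that passes through the loop — and the **crossing
residue(s)** where the thread pierces the loop surface, each carrying a
chirality sign. Unlike knots or covalent (disulfide-closed) lassos, the loop
here is held shut only by a contact, which makes NCLEs both very common in
native folds and easy to gain or lose during folding; both failure to form a
native NCLE and gain of a non-native one produce long-lived, kinetically
trapped misfolded states.

`lassotop` implements the full analysis stack around this geometry: detection
in single structures, degeneracy clustering, trajectory order parameters,
Markov-state decomposition, consistency testing against limited-proteolysis
(LiP) and crosslinking (XL) mass-spectrometry signals, and proteome-scale
association statistics with Monte Carlo candidate selection.

## Partial linking values and the rounding rule

For a loop closed by residues $(i, j)$ and a tail segment $m..k$, the partial
Gauss linking value $g(i,j,m,k)$ is the discrete double sum over segment
pairs,

$$
g = \frac{1}{4\pi}\sum_a \sum_b
\frac{R_a - R_b}{\lVert R_a - R_b\rVert^{3}}\cdot(dR_a \times dR_b),
$$

where each curve is the C$\alpha$ polyline, $R$ are bond midpoints and $dR$
bond vectors, and the loop is closed by the virtual segment from residue $j$
back to residue $i$. The value is invariant under rigid motion and flips sign
exactly under reflection (the implementation preserves this to floating-point
exactness, which the tests assert at $10^{-12}$).

Because the thread is an *open* curve, $g$ is not integer-valued and
spuriously large fractional values occur near the ends. Two guards control
false positives:

* **Exclusion buffers.** The first and last 5 residues of the chain and the
  4 residues flanking each loop-closing residue are excluded, so the N tail
  of a contact $(i,j)$ is $[6,\, i-5]$ and the C tail $[j+5,\, N-5]$.
* **The 0.6 rule.** Presence requires $|g| \ge 0.6$, and the rounded linking
  number GLN uses the same threshold on the fractional remainder (0.59
  rounds to 0, 0.61 to 1, 1.55 to 1, 1.65 to 2). A remainder of exactly 0.6
  rounds away from zero, consistent with the $\ge$ in the presence
  criterion.

Contacts can be defined at 8 Å between C$\alpha$ atoms or 4.5 Å between any
heavy atoms (preferred for high-resolution structures); linking geometry is
always computed on the C$\alpha$ trace. Entanglement loops use a minimum
sequence separation of 10 residues — shorter loops cannot physically be
pierced by a chain of C$\alpha$ thickness — while Q-style native contacts use
separation 3.

## Crossing localisation

Two methods localise the pierce:

* **surface** (default): the loop polygon is fan-triangulated about its
  vertex centroid and every tail bond is intersected with every triangle
  (Möller–Trumbore); a bond whose signed hits do not cancel is a crossing,
  with chirality from the bond direction against the oriented surface
  normal. Degenerate triangles are retried once after a $10^{-3}$ Å
  perturbation.
* **sliding**: $|g|$ over a 15-residue window slid along the tail; local
  maxima above 0.6 mark crossings, with chirality from the window's sign.
  Faster, resolution of a few residues; retained for large batch scans.

Accepted crossings must be at least `min_cross_sep = 10` residues from the
loop-closing residues and from each other; nearer same-sign crossings merge,
nearer opposite-sign pairs cancel (they indicate a local back-and-forth, not
net linking). On clean fixtures the signed crossing sum equals the rounded
GLN, which the tests assert.

## Degeneracy clustering and quality filters

A single structure yields many near-duplicate records (neighbouring contacts
close the same loop). Records join a cluster when they share the entangled
tail and ordered chirality signature and all matched crossings are within 20
residues *and* 10 Å; clusters are connected components of that relation and
the representative is the minimal loop (ties to the smaller start). Both
proximity criteria are required — sequence proximity alone would merge
spatially remote repeats, spatial alone would merge different topologies.

Quality filters drop slipknot-like records (a tail whose crossings sum to
zero pierces and backs out — not a lasso) in all modes, and, for predicted
models, records whose loop-closure or crossing residues have pLDDT below 70;
only those residues define the topology, so the filter is deliberately not
applied to the whole loop.

## Trajectory order parameters

Against a reference (usually native) structure with secondary-structure
elements:

* **Q** — fraction of native contacts formed. Native contacts are C$\alpha$
  pairs $\le$ 8 Å with both residues in secondary structure and separation
  $\ge 3$; a contact is formed in a frame within 1.2× its native distance.
  The 1.2 factor and the secondary-structure restriction are configurable,
  as conventions for Q vary.
* **G** — fraction of native contacts whose entanglement status changed. The
  status of a contact is the rounded pair $(\mathrm{gln}_N,
  \mathrm{gln}_C)$ computed with identical buffers in reference and frame; a
  contact counts as changed only when it is *formed* in the frame and its
  status differs. This normalisation makes $G = 0$ both for the reference
  and for a fully extended chain, where no native contact exists to carry a
  changed status.
* **K** — fraction of native packing chirality retained. For each pair of
  secondary-structure elements sharing a native contact, the chirality is
  the sign of $(\mathbf a \times \mathbf b)\cdot \mathbf d$ with $\mathbf
  a,\mathbf b$ the elements' end-to-end axes and $\mathbf d$ the
  midpoint connector; K is the fraction of pairs matching the reference
  sign. Pairs whose reference sign is zero (coplanar or parallel axes) carry
  no handedness and are dropped; if none remain K is reported as NA.

A trajectory with window averages $\langle Q\rangle > 0.2$ and $\langle
K\rangle < 0.6$ is flagged as a mirror-image artifact: reflection preserves
all distances (so Q stays native-like) while reversing every packing
chirality. Such artifacts arise in coarse-grained models with symmetric
potentials and must be removed before entanglement analysis because they
inflate G.

## Change typing and permutation-stabilised clustering

Each changed contact is typed on the $\{L+, L-, L\#\}\times\{C\#, C*\}$
grid: gain/loss/no change of $|\mathrm{gln}|$ crossed with whether any
persistent crossing (or the sign of the linking number itself) flipped
chirality; a pure sign flip at constant magnitude is `L#C*`. Records are
clustered within type by greedy agglomeration (loop Jaccard $\ge 0.5$,
matched crossings within 20 residues, and a contamination bar: no merge when
one record's crossings fall inside the other's loop). Because greedy
agglomeration depends on input order, the pass is repeated over 100 shuffled
orders and the final clusters are components of pairs co-clustered in more
than half of them; the result is order-independent by construction and by
test.

## Markov-state decomposition of (Q, G)

Frames are clustered into microstates by k-means on standardised $(Q, G)$
(default $k = 400$, kmeans++-style seeding, multi-start, fixed seed — the
seed is exposed because microstate identity otherwise varies between runs).
Transition counts at lag 1 frame, within trajectories only, give a
row-stochastic matrix; no Markovianity validation is attempted, which is
acceptable for a rough decomposition into visual regions but not for
kinetics. The largest connected component is lumped by spectral clustering
of the symmetrised transition matrix; the number of metastable states is
chosen by the largest spectral gap among the leading eigenvalues, capped at
`n_large_states`, so wells are never split merely because the cap allows
more states and the final count may be below the cap. Smaller components
become one state each.

Folding pathways are run-length-collapsed metastable sequences aggregated
into a directed graph with per-edge probabilities; ensemble divergence
between two conditions is the Jensen–Shannon divergence (natural log, upper
bound $\ln 2$) between their state distributions. A state's representative
frame is drawn from its microstates proportionally to their weight, then the
frame nearest that microstate's centre is returned.

## Consistency with LiP-/XL-MS signals

The tests connect simulated ensembles to mass-spectrometry observables:

* **LiP**: the per-frame feature of a cut-site is the summed solvent
  accessibility over the site ±5 residues (truncated at chain ends),
  computed by a Shrake–Rupley implementation (probe 1.4 Å, ≥ 500
  deterministic golden-spiral points per atom, Bondi radii; heavy atoms when
  present, C$\alpha$ spheres otherwise).
* **XL**: the feature is a crosslinking propensity
  $XP = 1/(1+\exp((\mathrm{SASD} - d_0)/s))$ with $d_0 = 33$ Å and $s = 3$ Å
  for the DSBU linker, where SASD is the solvent-accessible surface distance:
  the shortest path between crosslinkable atoms (Lys NZ, else C$\beta$, else
  C$\alpha$) through a 2 Å grid of solvent voxels with 26-neighbour
  connectivity and Euclidean edge weights. Buried or unreachable residues
  return an infinite-distance sentinel, which maps to $XP = 0$. The exact
  published scoring form for DSBU is not available, so the two-parameter
  logistic is the package's default and both parameters are exposed.

Per signal, the statistic is the state-minus-native mean difference; the
two-tailed p-value comes from label permutation with the add-one convention
$p = (1 + \#\{|T^{\pi}| \ge |T|\})/(1 + n_{\mathrm{perm}})$ (so $p$ is never
zero and the test is valid for finite permutations), followed by
Benjamini–Hochberg correction across signals at $\alpha = 0.05$. Frames
should be decorrelated by striding before testing; the test treats frames as
exchangeable. Representative structures are grouped by (entanglement-change
cluster ids, signals outside the native 2.5–97.5 percentile band) and the
highest-microstate-probability frame represents each group.

## Proteome-scale association and candidate selection

Proteins need $\ge 50\%$ of the canonical sequence detected in the untreated
condition to enter the analysis; the sum of peptide abundances (median
across replicates, summed over detected peptides) is carried as an abundance
proxy. Per protein, a residue table marks response (significant
conformational-change site), region (inside a representative NCLE loop or
within ±5 of a crossing) and confounders. Logistic regression (IRLS via
`glm`) gives the log-odds of a significant change as a function of region
and confounders; odds ratios are exponentiated coefficients, complete
separation is flagged with an infinite-OR sentinel, and when several
condition sets are fit the region p-values are BH-corrected.

Because single-protein power is poor, candidates are selected by Metropolis
Monte Carlo over balanced groups (default $n = 4$; at least 3): a step swaps
one protein between two groups, refits the affected groups' region
coefficients (pooled rows with per-protein intercepts, so between-protein
base-rate differences cannot masquerade as region effects), recomputes the
energy and accepts with probability $\min(1, e^{-\Delta E/T})$ under a
geometric schedule $T(t) = T_0\,\gamma^t$.

**Choice of the energy.** The published energy form is not printed, so the
objective is pluggable. Two forms are provided. The linear rank-weighted
form $E = -\sum_g g\,\beta_{(g)}$ looks natural but its minima provably
prefer *spreading* strong proteins across the upper ranks while pooling
negative-coefficient proteins at the bottom — on planted-subpopulation data
its optimum keeps a large fraction of the high-bias proteins out of the top
group, so it ranks groups but cannot concentrate candidates. The default is
therefore $E = -n\,e^{\beta_{(n)}}$, the top-ranked group's pooled odds
ratio: its minima are exactly the assignments that concentrate the strongest
positive misfolding bias in one group, while swaps among lower ranks are
energy-neutral and keep the chain mixing. After the trace reaches steady
state, groups are ranked by their mean odds ratio over the last 100 steps;
across multiple independent runs, consensus candidates are proteins in the
top group in more than 70% of runs.

## The synthetic generators, and what passing tests do not show

All fixtures are generated in code, seed-deterministically, with the ground
truth returned alongside:

* `make_lasso` builds a protein-like curve (3.8 Å C$\alpha$ spacing): a
  planar ring closed by its ends, a short leader, and a thread piercing the
  ring plane 1 or 2 times with chosen chirality and radial offset; the
  analytic linking number is chirality × pierces.
* `make_helix_bundle` builds an idealised four-helix bundle (radius 2.3 Å,
  rise 1.5 Å/residue, 100°/residue, axes tilted ±12° so packing chirality is
  well defined) with its secondary-structure table.
* `make_trajectory` linearly interpolates two conformations with Gaussian
  noise.
* `make_ms_tables` draws log-normal peptide abundances with planted effects
  (q-values from Welch tests + BH) and realises the accessibility change
  geometrically: a tightly wound coil in which the ±5 window around a
  planted cut-site is displaced outward by 5 Å, which shifts the windowed
  SASA feature by about 3 pooled standard deviations under the default
  frame noise — the effect size at which the consistency test is expected
  to reach power above 0.9 at 50 frames per ensemble.
* `make_proteome` draws Bernoulli residue tables with
  $\mathrm{logit}\,p = \beta_0 + \beta_{\mathrm{region}}\cdot\mathrm{region}$,
  baseline $\beta_0 = -2.5$ (about 8% of residues are significant sites) and
  lengths 300–600 residues — realistic for well-covered proteins in
  proteome LiP-MS (phosphoglycerate kinase, the archetypal substrate for
  this analysis, has 387 residues). Protein length controls the sampling
  noise of per-protein coefficients; at substantially shorter lengths the
  weakest planted proteins become statistically indistinguishable from the
  best null proteins and no selection procedure can recover them.

These generators emulate topology, order-parameter behaviour and the
statistical structure of the signals. They do **not** emulate real side-chain
packing, force-field dynamics, peptide-level quantification noise,
autocorrelated frames, or structures with missing residues; a passing suite
shows the algorithms are correct on their contracts, not that any particular
biological dataset will behave as cleanly.

## Numerical choices and degenerate inputs

* Rounding ties at remainder exactly 0.6 go away from zero.
* Altlocs collapse to the highest occupancy, ties by first alphabetical ID;
  residues without a C$\alpha$ are hard errors naming the residue; numbering
  gaps are errors unless explicitly renumbered over.
* Chains shorter than 12 residues admit no tail and return no records.
* Zero-length bonds in the linking sum are errors (degenerate geometry).
* k-means with as many clusters as distinct points degenerates to one
  microstate per point without calling the solver.
* Transition-matrix rows with no observed outgoing counts are zero rows
  isolated into their own components.
* Permutation p-values use the add-one convention; BH is `p.adjust`.
* Unfittable Monte Carlo proposals (a swap that leaves a group without both
  response values) are rejected and logged in the trace.

## Problem sizes used by the test-suite studies

The packaged studies run at desk scale, chosen to estimate each quantity
stably: 50 lasso fixtures against a 10×-denser discretisation oracle; 10^4
random frames for order-parameter bounds; 500 null replicates (999
permutations each) for test calibration and 25 replicates at 50 frames per
ensemble for power; 200 replicates of 5,000-residue tables for regression
recovery; 40 proteins and 2,000 Monte Carlo steps (scaled down from the
recommended 200,000 production steps) for candidate selection; 2×10^4-step
chains for Markov-state recovery.

## Known limitations

* Interchain (multi-chain) linking, knot/slipknot classification and
  covalent lassos are out of scope.
* DCD plus PDB/PSF topologies are the supported trajectory dialect; XTC and
  CHARMM `.cor` files are not read.
* The SASD grid path overestimates true geodesics by up to ~13% (26-neighbour
  lattice metric); the default 2 Å grid trades accuracy for speed.
* The Q-definition (1.2× native distance, secondary-structure-restricted
  contacts) and the K sign convention follow common practice but published
  variants differ; both are configurable.
* Lag-1 Markov models are a decomposition device, not a kinetic model.
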