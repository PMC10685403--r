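---
title: "Graph-coupled model quality assessment: models, features and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Graph-coupled model quality assessment: models, features and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Single-model quality assessment (MQA/EMA) asks: given one predicted protein
structure and no native, how good is each residue? The field's standard
per-residue target is the local Distance Difference Test (lDDT): for residue
$i$, the fraction of reference inter-residue distances within a 15 Å
inclusion radius that the model reproduces within thresholds
$s \in \{0.5, 1, 2, 4\}$ Å,

$$\mathrm{lDDT}_i \;=\; \frac{1}{|T|}\sum_{s\in T}\;
\frac{\#\{j \ne i:\; d^{\mathrm{ref}}_{ij} < 15,\;
|d^{\mathrm{mod}}_{ij}-d^{\mathrm{ref}}_{ij}| < s\}}
{\#\{j \ne i:\; d^{\mathrm{ref}}_{ij} < 15\}},$$

and the global score is the mean over residues. `graphmqa` implements a
graph-coupled encoder–decoder network that predicts this quantity from a
single model structure plus (mock or plug-in) protein language-model
embeddings, together with everything needed to train and evaluate it at desk
scale: ground-truth labelling, designed topological descriptors, a synthetic
decoy generator, and a composite training loss.

`compute_lddt()` works on Cα atoms only. Residue-level assessment is the
package's target, a Cα definition keeps the independent brute-force oracle
trivial to state, and full-atom lDDT would require side chains the backbone
container deliberately omits. The 15 Å inclusion set is defined on the
*reference* structure (the standard lDDT convention). No sequence-separation
exclusion is applied beyond $j \ne i$. Residues with no in-radius partner
are reported as 1 and flagged. Distance-error classes for the decoder's
categorical head bin $|d^{\mathrm{mod}}-d^{\mathrm{ref}}|$ into
$[0,0.5), [0.5,1), [1,2), [2,4), [4,\infty)$; edges are half-open so an
error of exactly 0.5 Å falls deterministically into the second class.

## Designed topological descriptors

Two descriptor families tie each residue's local environment to the global
topology.

**Triangular location.** For residue $i$, $P_1$ is its Cα, $P_2$ the
farthest Cα from $P_1$, and $P_3$ the farthest Cα from $P_2$ excluding
$P_1$ (ties broken by lowest residue index, for determinism). The feature
is the triangle's three side lengths, the mean distance of *all* residues
to each vertex (the text of the defining description says all residues, and
we follow it literally), and the Euler angles of the frame built from the
triangle edges: $e_x \propto P_3-P_1$, $e_y$ the component of $P_2-P_1$
orthogonal to $e_x$, $e_z = e_x \times e_y$. The Euler convention is fixed
to intrinsic Z–Y–X; no convention is canonical, so one had to be chosen and
recorded. Angles are emitted to the network as sin/cos pairs (12 values in
total with the six distances) to avoid the wrap-around discontinuity at
$\pm\pi$. The distances are exactly rigid-invariant; the Euler angles rotate
with the global pose, which the symmetry tests document rather than hide.
A collinear triangle (degenerate $e_y$) falls back to an arbitrary unit
vector orthogonal to $e_x$ and sets a `degenerate` flag.

**Residue-level contact order.** The node descriptor averages the sequence
separation of spatial neighbours, $O_i = \sum_{j: d_{ij}\le 15, j\ne i}
|i-j| / (R_i N)$ with $R_i$ the neighbour count; the summation range is
restricted to the same 15 Å shell that defines $R_i$ (an unrestricted sum
would make the radius meaningless). $R_i = 0$ gives $O_i = 0$. The pair
descriptor is $O_{ij} = |i-j|/d_{ij}$, with coincident-atom pairs skipped
(set to 0) under a warning.

**Invariant voxelization.** Each residue's environment is binned into an
$8^3$ occupancy grid over a 16 Å cube expressed in the residue's backbone
frame (Gram–Schmidt on N, Cα, C), which makes the counts independent of the
global pose. Only the five stored backbone atoms are binned, and an imputed
Cβ (glycine) is excluded.

## Graph features

Residue graphs use $K$ nearest neighbours by Cα distance ($K = 30$ by
default; the choice follows common residue-graph practice and keeps small
graphs connected). Distances are rounded to $10^{-6}$ Å before the ordering
so exact geometric ties — common in idealized helices — break by residue
index, stably under the floating-point jitter a rigid transform introduces.

Node channels: sinusoidal position encoding (width 16, offsets clipped to
±32), Meiler's 7 physico-chemical descriptors, the residue's BLOSUM62 row
(scaled by 1/10), a 3-state secondary-structure one-hot, φ/ψ/ω sin/cos,
triangular location, node contact order, and the flattened voxel grid.
Secondary structure comes from a self-contained φ/ψ-box rule (helix:
φ∈[−100,−30], ψ∈[−80,−5]; strand: φ∈[−180,−80] with ψ∈[80,180] or
ψ∈[−180,−170]; else coil) rather than a hydrogen-bond DSSP — the package
must run without external binaries, and the interface accepts a plug-in
assignment where a real DSSP is available.

Edge channels: Gaussian radial-basis expansions (16 centres uniform on
[0, 20] Å, σ equal to the centre spacing; no canonical values exist, these
cover the distance range the 15 Å radius makes relevant) of the N–N, Cα–Cα,
C–C, O–O and Cβ–Cβ distances; the frame-relative displacement
$s_{ij} = R_i^{\top}(x_j - x_i)$; the quaternion of $R_i^{\top}R_j$
(sign-fixed to non-negative scalar part, removing the double-cover
ambiguity); pair contact order; a relative-index position encoding; and a
zero-filled inter-residue energy slot. The energy slot is a provider hook:
physics-based pairwise energies require an external licensed tool, so the
schema keeps the channel and ships zeros. The Cβ distance map stands in for
a tip-atom map by default for the same reason (the tip-atom lookup is an
optional extension). The feature layout (channel names, widths, K, RBF
parameters) is serialized as JSON next to every feature container, and a
31-bit hash of it binds checkpoints to the layout they were trained on.

## Embeddings

The embedding interface reproduces the dimensionalities a language-model
provider would return — per-residue 1280 (single-sequence mode) or 768 plus
an N×N×144 pair-attention tensor (MSA mode), and a 512-dim structural
embedding — and the long-sequence rule: inputs up to 1022 residues pass
through unchanged; lengths in (1022, 2044) are cut into two halves at
⌊L/2⌋ and re-assembled in order; lengths ≥ 2044 are refused explicitly
(the behaviour in that regime is unspecified upstream, and a loud error
beats a silent guess). The shipped provider is a deterministic mock: a pure
function of (sequence, seed), with the structural embedding additionally
modulated by smooth pose-invariant summaries of the Cα geometry (radial
position, mean pairwise distance, 10 Å neighbour count) so that decoys of
one sequence receive distinct, structure-sensitive embeddings. Real
providers plug in behind the same interface and are never needed by tests.
What passing tests show is therefore that the *pipeline* learns from
structure-sensitive embeddings plus geometry — not that mock embeddings
carry evolutionary signal; they do not.

## The network

The encoder couples three stages, all written against the package's
internal reverse-mode autodiff engine so the same code path serves plain
inference and training.

**Graph-transformer layers** (default 3, width 128, 8 heads of dimension
16). Each residue attends over all residues with scaled dot-product
attention; projections of the KNN edge features enter both the logits
(as $\langle q_i, m_{ij}\rangle$ bias) and the values (added to $W h_j$
inside the attention sum); off-graph pairs carry zero bias. Head outputs
are concatenated and projected, then mixed with the input through a learned
sigmoid gate $C^1 = \sigma(\Phi_s[h-\bar h, h, \bar h])$ applied as
$C^1 h + (1-C^1)\bar h$. The gate contrasts the *updated* embedding with
the original — where the defining equation's index is ambiguous, the
surrounding prose ("weighs the updated embedding with the original by
gating") fixes that reading. The edge bias is head-specific; making it
shared would save parameters but the per-head form is the natural reading
of a per-head value term.

**Invariant point attention** (default 2 blocks, 4 heads, 4 points).
Scalar queries/keys are combined with learned 3D points lifted into the
global frame through each residue's backbone frame, an edge bias, and a
squared point-distance penalty with a per-head learned weight
(softplus-positive). Because points transform with the frames, all scalar
outputs are invariant under a global rigid motion; attended value points
are mapped back into each residue's local frame (with their norms) before
re-projection. After the blocks a per-residue translation predicted in the
local frame updates the Cα coordinates equivariantly; these refined
coordinates feed the geometric loss.

**EGNN layers** (default 2) on the KNN graph. Messages are built from both
node states, Fourier (sin/cos at geometric frequencies) features of the
inter-node distance, and the edge state; coordinates update along
difference vectors weighted by a learned scalar with the $1/(N-1)$
normalisation, so the coordinate channel is exactly E(3)-equivariant and
the feature channel invariant — both properties are asserted under random
rigid transforms in the test suite rather than assumed.

**Decoder.** Encoder node states (row-tiled), fresh projections of the raw
node and edge features under separate parameters, and the dense-scattered
edge states are concatenated into an N×N pair map. A residual trunk of
dilated 3×3 convolution blocks (dilations cycling 1, 4, 9, 16; each block
LN → GELU → conv → GELU → conv → GELU → 1×1, with the inner convolutions
widened — the inverted-bottleneck pattern) feeds two branch blocks: a
5-class softmax over distance-error bins and a sigmoid 15 Å contact head.
Both heads are symmetrised by averaging logits over $(i,j)$ and $(j,i)$.

**Scoring.** Per pair and threshold $s$, the probability that the error is
below $s$ is the cumulative mass of the bins below $s$; weighting by the
contact probability and normalising gives

$$\widehat{\mathrm{lDDT}}_i \;=\;
\frac{\sum_j t_{ij} \sum_{s\in T} \big(\textstyle\sum_{b < b(s)} e_{ijb}\big)}
{|T| \cdot \sum_j t_{ij}},$$

clipped to [0, 1]; the global score is the mean. The $1/|T|$ factor is a
deliberate normalisation choice: without it a perfect prediction would
score 4, not 1, and the identity "exact one-hot labels reproduce the true
lDDT to numerical precision" — which the tests assert — could not hold.
Residues whose contact mass is zero score 0 and are flagged.

## Training

The loss is a weighted sum of four terms, all weights defaulting to 1
(no canonical weighting exists; the weights are exposed in the config):

* geometric — MSE between the encoder's refined Cα coordinates (after
  optimal rigid superposition by the Kabsch algorithm, with the alignment
  treated as a constant so the global pose carries no gradient) and the
  reference, plus mean L1 error between predicted and reference pairwise
  distances;
* categorical cross-entropy of the 5 error bins, masked to reference pairs
  within 15 Å;
* binary cross-entropy of the contact head over off-diagonal pairs;
* MSE between predicted and true per-residue lDDT.

Optimisation is AdamW at learning rate $10^{-3}$ with a multiplicative
0.99 per-epoch decay (the natural reading of "decays at a rate of 1%"),
decoupled weight decay 0.01 (biases, layer norms and the IPA point weights
exempt), batch size one model, 4% of models held out for validation.
Per-residue validation Pearson is tracked each epoch; the five best
parameter snapshots are retained and the best is returned.

## Synthetic decoys

`perturb_dihedrals()` measures the full internal coordinates of a
reference (bond lengths, bond angles, torsions — including carbonyl and Cβ
placement), adds zero-mean Gaussian noise of sd σ degrees to the φ/ψ
torsions of a random 30% subset of residues, and rebuilds the chain. Because
bonds and angles are preserved, σ = 0 reproduces the reference exactly and
labels are exactly 1. No relaxation follows the perturbation: the physical
pipeline this emulates relaxes each adjusted structure with an external
force field, which is out of reach here; for labelling purposes small
clashes are tolerable, but users should know the decoys are not
physically relaxed ensembles. On the 30-residue built-in toy protein the
generator yields global lDDT from ~1.0 down to ~0.75 across σ = 1–40°,
strictly decreasing in σ — a narrower spread than a paper-scale decoy
factory produces, because Cα-only lDDT on a short chain is forgiving.
The similarity filter is a greedy pass keeping a decoy only if its global
lDDT against every kept decoy is at most $1 - \text{gap}$ (the upstream
filter criterion is unspecified; an lDDT-gap filter is the natural stand-in
given the labels already exist).

## Problem sizes and numerical choices

The demonstration and acceptance runs use a reduced architecture,
`toy_network_config()` — 1 graph-transformer layer (2 heads of width 4),
1 IPA block (2 heads, 2 points), 1 EGNN layer, a 2-block trunk at 8
channels with 2× expansion, K = 10 — on a 30-residue toy protein with 200
decoys and 40 epochs. These sizes were chosen once, as the package's
desk-scale working point, so the full train-and-evaluate cycle completes in
minutes on a single CPU; the constructor defaults remain the full-scale
architecture. The training demonstration (see `tests/testthat/
test-acceptance.R` and `scripts/acceptance.R`) asserts that training loss
decreases strictly over the first ten epochs, that held-out per-residue
Pearson exceeds 0.5, and that a control trained on labels whose
model-and-residue assignment has been destroyed stays below 0.2. The
control permutes label sets across decoys *and* residues within each,
because a residue-only shuffle preserves each decoy's mean quality and a
network that has learned global quality alone would still correlate with
it — the stricter shuffle is the one that actually tests for leakage.

Numerical conventions worth recording: torsion signs follow the IUPAC
convention and the sequential builder is its exact inverse (round-trip
errors at machine precision); quaternions are sign-fixed to $w \ge 0$;
Euler extraction folds the gimbal-locked case into the first angle; the
softmax subtracts row maxima; GELU uses the tanh-form approximation;
division by attention or contact mass is guarded with small epsilons
(10⁻⁸–10⁻⁹); exponentials in softmax/sigmoid paths are clamped and
vanishing AdamW moments flushed to zero, so saturated heads late in
training cannot push arithmetic into the denormal range (which stalls
long runs); gradient correctness of every parameter tensor is checked
against central finite differences at tolerance 10⁻³ relative in the test
suite (observed agreement is 10⁻⁷–10⁻⁵).

## Limitations

* Mock embeddings are structure-sensitive noise, not evolutionary signal;
  results with real language-model providers will differ and the package
  makes no claim about them.
* lDDT is Cα-only; stereochemistry-aware and symmetry-corrected interface
  variants are out of scope.
* Decoys come from dihedral perturbation only; template-based and
  deep-learning-guided decoy generation belong to external tools.
* Multimers are accepted (chains concatenate into one graph) but no
  interface-residue selection protocol is provided.
* The toy-scale learning demonstration shows the gradient path and feature
  stack function end to end; it says nothing about accuracy on real
  community-benchmark-scale model sets.
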