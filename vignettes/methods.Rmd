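---
title: "Model and methods: graph-convolutional HLA-peptide affinity prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model and methods: graph-convolutional HLA-peptide affinity prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pepGCN)
```

## The problem and the model

HLA (human leukocyte antigen) molecules present short peptides on the cell
surface; whether a peptide binds a given HLA allele — usually summarized by
an IC50 from a competition assay — determines whether it can be seen by
T cells. pepGCN regresses that binding affinity from a structural
representation of the pair. The two molecules are of very different size
(an HLA heavy chain is hundreds of residues; a class I ligand is ~8–12),
so the two sides are encoded at different granularity:

* the **HLA** is a residue-level graph built from its 3D structure: one
  node per residue carrying a 43-dimensional feature vector (a scaled
  BLOSUM62 substitution row with an unknown channel, an 8-state
  secondary-structure one-hot, the raw alpha-carbon coordinates in
  angstrom, a hydrogen-donor/acceptor class one-hot, and seven
  physicochemical descriptors), with four typed edge classes — backbone
  peptide bonds, hydrogen bonds, ionic bonds, disulfide bridges — detected
  from interatomic distances;
* the **peptide** is an atom-level molecular graph obtained by
  assembling a SMILES string residue by residue (condensation of
  `N-CA(-R)-C(=O)` units) and parsing it with a cheminformatics kernel:
  one node per heavy atom with a 22-dimensional feature vector (element
  one-hot, atomic number, donor/acceptor/aromatic flags, hybridization,
  hydrogen counts, formal charge, valences, radicals), edges carrying
  integer bond orders after kekulization.

Each branch is processed by a stack of graph convolutions

$$H^{(l+1)} = \mathrm{ReLU}\!\left(\hat{D}^{-1/2}\hat{A}\hat{D}^{-1/2}
H^{(l)} W^{(l+1)}\right),$$

with $\hat{A} = A + I$ the self-loop-augmented adjacency and $\hat{D}$ its
degree matrix. Node embeddings are pooled (mean by default), the two
pooled vectors are concatenated, and a three-hidden-layer perceptron
(ReLU, dropout 0.1 after each hidden layer) emits the affinity score.
Training minimizes the mean squared error against the log50k-transformed
IC50,

$$y = 1 - \frac{\log \mathrm{IC50\,(nM)}}{\log 50000} \in [0, 1],$$

under which 500 nM — the conventional binder threshold — maps to a score
of about 0.426; scores strictly above that cutoff classify as binders.

### Assumptions worth stating

* Self-loops are added before normalization; without them isolated nodes
  would break the $\hat D^{-1/2}$ scaling.
* The propagation rule uses the adjacency only. Edge attributes (bond
  type, distance) annotate the graph but do not enter the convolution; an
  optional `distance_inverse` mode weights adjacency entries by inverse
  distance for users who want geometry in the operator.
* Losses are computed on the raw network output; the output is clamped to
  $[0,1]$ only at prediction time. The target scale itself is bounded, so
  clamping during training would zero gradients at the rails.
* Alpha-carbon coordinates enter the features raw (no centering) by
  default, which makes predictions translation-sensitive; a
  `center_coords` flag subtracts the centroid. Feature standardization
  (per channel, training-set statistics, stored in the model) is on by
  default and removes most of that sensitivity in practice.

## Node attribution (gradient-weighted activation mapping)

To say *which* residues or atoms drive a prediction, the package computes
a gradient-weighted activation map over the last GCN layer of either
branch. Let $T$ be that layer's node-by-channel activations and $P$ the
raw prediction. Channel weights combine rectified first partials with
coefficients

$$\alpha_{ic} = \frac{\partial P/\partial T_{ic}}
{\partial P/\partial T_{ic} + T_{ic}\,\partial^2 P/\partial T_{ic}^2},
\qquad
w_c = \sum_i \alpha_{ic}\,\mathrm{ReLU}\!\left(\frac{\partial P}
{\partial T_{ic}}\right),$$

and each node's raw score is $s_i = \mathrm{ReLU}(\sum_c w_c T_{ic})$,
min-max normalized per graph for the blue-to-red display scale. The
scalar $\omega = \sum_c w_c$ is reported as a diagnostic but not folded
into the scores.

Numerical choices:

* First partials are computed analytically by reverse-mode chain rule
  through the readout and MLP; the test suite checks them against central
  finite differences of the same forward map.
* The head downstream of $T$ (pooling, linear maps, ReLU) is piecewise
  linear, so the exact diagonal second partials vanish almost everywhere
  and the $\alpha$ coefficients reduce to 1 wherever the first partial is
  nonzero. The $\alpha$ formula is kept in full generality for heads with
  curvature.
* The denominator of $\alpha$ carries an $\varepsilon$-guard
  ($10^{-12}$): degenerate entries (including 0/0) are set to
  $\alpha = 1$, so the method degrades to plain rectified-gradient
  weighting instead of emitting non-finite values.
* If every node scores identically, min-max normalization is undefined;
  the normalized vector is defined as all zeros and a warning is raised.

### The occlusion oracle, and what it can disagree about

`occlusion_scores()` is an independent check on the attribution: zero one
node's feature row, re-predict, record the drop. By default it occludes
rows of the *same feature map* $T$ the attribution scores, so oracle and
method measure importance at the same interface. The `level = "input"`
variant zeroes the node's standardized input features instead and re-runs
the whole branch; that answers a broader question, because zeroing an
input also perturbs the embeddings of its graph neighbours through the
convolution, and it weighs negative-gradient channels that the rectified
attribution deliberately ignores. On well-trained models the two variants
can rank mid-importance nodes quite differently; both are exposed so
users can ask either question deliberately.

## Tunable parameters

| Parameter | Default | Units / range | Why |
|---|---|---|---|
| `hla_layer_dims` | 32, 32 | channels | two hops cover local residue neighbourhoods |
| `pep_layer_dims` | 48, 48, 48 | channels | three bond hops let an atom embedding see nearby functional context (e.g. a side chain *and* the adjacent backbone terminus) |
| `readout` | mean | mean/sum/max | size-invariant pooling across unequal graphs |
| `mlp_dims` | 64, 32, 16 | units | three hidden layers, tapering |
| `dropout` | 0.1 | fraction | regularization of the head |
| `learning_rate` | 0.005 | — | Adam step size; converges on the fixture within the default epochs |
| `n_epochs` | 200 | — | training length at desk scale |
| `batch_size` | 16 | pairs | minibatch SGD |
| `edge_weight_mode` | binary | binary / distance_inverse | faithful default; geometry optional |
| edge cutoffs | 1.8 / 2.5 / 4.0 / 3.5 | angstrom | peptide C–N, disulfide SG–SG, ionic N–O, hydrogen-bond heavy-atom conventions |
| `blosum_scale` | 0.1 | — | keeps the integer substitution scores on the same magnitude as the other blocks |

All geometric cutoffs follow common structural-biology conventions and
are exposed as configuration; they are frozen defaults rather than
empirically fitted values.

## The synthetic study system

Every statistical claim in the test suite is made on synthetic data
generated by the package itself, so the whole pipeline runs from a clean
checkout with no downloads.

* `gen_helix_structure()` builds an ideal alpha-helical trace (radius
  2.3 A, rise 1.5 A per residue, 100 degrees per residue; consecutive
  alpha-carbons land 3.83 A apart) with backbone N, C, O placed on the
  same helix so the peptide-bond detector fires between all consecutive
  residues, plus CB pseudo-atoms, and — on request — cysteine SG pairs in
  disulfide range or lysine/glutamate NZ/OE1 pairs in salt-bridge range.
* `gen_affinity_dataset()` plants a recoverable rule: peptides drawn
  uniformly over the 20 residues receive a transformed score of
  0.3, plus 0.4 if the **anchor position carries a favored residue**,
  plus Gaussian noise (sd 0.05), clamped; IC50 values are the exact
  inverse transform. The default rule anchors at position 1 with the
  large hydrophobic set F, W, Y, L, I, V — mirroring the P1-pocket
  preference of class II grooves — and position 1 is deliberate for a
  second reason: in a heavy-atom graph the only feature that
  distinguishes *position* along the chain is proximity to the free
  N-terminal amine (two hydrogens instead of one), which a three-hop
  convolution can see from the anchor side chain. A planted rule at a
  mid-chain position would require a much deeper receptive field and
  would not be reliably learnable at this problem size.

The study conditions used by the acceptance checks are 200 pairs of
9-mers against a 30-residue helix, trained with the package defaults;
held-out correlation, anchor recovery over 20 seeded training runs, and
the occlusion/attribution agreement are all computed by the test suite at
those sizes.

What the fixture does *not* emulate: real HLA groove geometry, contact
between the peptide and the structure (the planted rule is carried
entirely by the peptide branch; a structure-side variant is provided via
`planted_rule(mode = "structure_pocket")` for users who want signal on the
HLA branch), assay noise structure, or allele diversity. Passing the
planted-signal tests demonstrates that the architecture, gradients and
attribution machinery work end to end — not that the defaults would reach
published benchmark accuracy on real binding corpora, which require
datasets and training budgets far beyond a test suite.

## Numerical and design notes

* **MCC.** The Matthews correlation coefficient is implemented in its
  standard form with the square root over the denominator product;
  without the root the statistic is not bounded by $[-1, 1]$. Metrics
  with zero denominators return `NA` ("undefined") rather than 0, so
  averaging across folds cannot silently inflate.
* **AUC** uses midranks for ties and is verified against a brute-force
  pairwise oracle and against `pROC`.
* **Determinism.** Every stochastic step (weight init, shuffling,
  dropout, fixture generation, fold assignment) is driven by an explicit
  integer seed; identical seeds give byte-identical datasets, training
  histories and evaluation reports. Altloc ties in PDB parsing resolve to
  the first record; max-pool gradient ties route to the first argmax.
* **Secondary structure.** An external DSSP-style annotation is used
  verbatim when supplied. The built-in fallback is a deliberately modest
  three-state geometric assigner (helix from runs of CA(i)–CA(i+3)
  distances in [4.5, 6.5] A; strand from locally extended CA spans
  > 6.0 A; otherwise coil); it never emits the other five states, whose
  one-hot slots simply stay zero. A full hydrogen-bond-energy assigner
  was judged out of proportion for the feature's role.
* **Chain policy.** Class II molecules bring two chains; the default
  merges all chains into one graph (one graph per molecule), with
  `single:<id>` available.
* **Windows in the mutation scan.** A substitution is covered by up to
  nine 9-mer windows; per HLA the window scores are combined by maximum
  (the usual epitope-scan convention; mean available) before the paired
  t-test across the panel. A panel smaller than two, or identical
  wild-type and mutant scores, yields a flagged undefined test rather
  than a fabricated p-value.
* **Peptide lengths** outside 8–25 are accepted with a warning — the
  biological range is context, not a validation rule.

## Known limitations

* No mmCIF input; no structure validation or prediction.
* The convolution ignores edge attributes by design fidelity; message
  passing over typed edges is out of scope.
* Attribution is defined over the last GCN layer only; MLP-input or
  counterfactual explanations are not provided.
* Training is plain R at desk scale; the implementation is not intended
  for corpus-scale training runs.
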