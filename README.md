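# pepGCN — graph-convolutional HLA–peptide binding affinity prediction

pepGCN predicts how strongly a peptide binds an HLA (human leukocyte
antigen) molecule, and — just as importantly — *why*: which residues of the
HLA and which atoms of the peptide drive the prediction. It is aimed at
computational immunologists who want a structure-aware, fully inspectable
affinity model at laptop scale: epitope screening on synthetic or curated
structures, neoepitope delta-affinity scans, and method development around
graph-network attribution.

## The model

The two molecules differ in size by an order of magnitude, so they are
encoded at different granularity and processed by twin graph-convolution
branches:

* **HLA branch** — the structure becomes a residue-level graph: one node
  per residue with a 43-dimensional feature vector (scaled BLOSUM62 row
  + unknown channel [21], secondary-structure one-hot [8], alpha-carbon
  coordinates [3], donor/acceptor class [4], seven physicochemical
  descriptors [7]); typed edges for peptide bonds, hydrogen bonds, ionic
  bonds and disulfide bridges, detected from interatomic distances.
* **Peptide branch** — the sequence is assembled into a SMILES string and
  parsed into an atom-level graph: one node per heavy atom with a
  22-dimensional feature vector (element one-hot [9], atomic number,
  donor/acceptor/aromatic flags, hybridization [3], hydrogen counts,
  formal charge, valences, radicals); bonds carry integer orders after
  kekulization.

Each branch stacks graph convolutions
`H' = ReLU(D̂^(-1/2)(A+I)D̂^(-1/2) H W)`; node embeddings are mean-pooled,
concatenated, and passed through a three-hidden-layer MLP (ReLU, dropout
0.1) onto the log50k affinity scale
`y = 1 − log(IC50 nM)/log(50000)`, where the conventional 500 nM binder
threshold sits at y ≈ 0.426 (scores strictly above classify as binders).
Training minimizes mean squared error with Adam; every random step is
seed-controlled.

For interpretation, the package computes a gradient-weighted activation
map over the last GCN layer of either branch: channel weights
`w_c = Σ_i α_ic · ReLU(∂P/∂T_ic)` (with `α` the curvature-corrected
coefficients, identically 1 for the piecewise-linear head) score each
node as `s_i = ReLU(Σ_c w_c T_ic)`, min-max normalized for blue-to-red
structure coloring. An occlusion oracle provides an independent check,
and an annotated-PDB writer puts the scores in the B-factor column for
any molecular viewer.

## Worked example

The package ships a seed-deterministic synthetic study system: an ideal
helical HLA stand-in and an affinity dataset with a *planted* binding
rule (peptides with a large hydrophobic residue — F, W, Y, L, I or V — at
anchor position 1 gain 0.4 on the transformed scale over a 0.3 baseline,
noise sd 0.05).

```r
library(pepGCN)

hla_structure <- assign_secondary_structure(gen_helix_structure(30, seed = 1))
hla <- build_residue_graph(hla_structure)
hla
#> <residue_graph> 30 nodes x 43 features, 29 edges (PEPTIDE=29)

sim <- gen_affinity_dataset(200, planted_rule(seed = 101))
training_set <- build_training_set(sim$records, list(HLAFIX01 = hla))
model <- train_affinity_model(training_set, gcn_config(seed = 1))
tail(model$training_history, 1)
#> 0.00373

pep <- build_peptide_graph("FAGKSHWTV")   # F at the anchor position
score <- predict_affinity(model, hla, pep)
c(score, score_to_ic50(score), classify_binder(score))
#> score 0.681   IC50 31.4 nM   "binder"

pep2 <- build_peptide_graph("SAGKSHWTV")  # anchor mutated F -> S
score2 <- predict_affinity(model, hla, pep2)
c(score2, score_to_ic50(score2), classify_binder(score2))
#> score 0.307   IC50 1810.4 nM   "nonbinder"
```

The model has learned the planted rule: substituting only the anchor
drops the score from well above the 0.426 binder cutoff back to the 0.3
baseline. Attribution agrees — aggregated to residues, the peptide-branch
scores single out position 1, and notably *not* the tryptophan at
position 7, which is a favored residue type at the wrong position:

```r
attr <- gradwam_scores(model, hla, pep, "peptide")
attribution_by_residue(attr, pep)
#>   position code      raw normalized
#> 1        1    F 0.731797   1.000000
#> 2        2    A 0.000000   0.000000
#> 3        3    G 0.000000   0.000000
#> 4        4    K 0.312486   0.427012
#> 5        5    S 0.011798   0.016122
#> 6        6    H 0.006798   0.009290
#> 7        7    W 0.000658   0.000899
#> 8        8    T 0.010189   0.013923
#> 9        9    V 0.007287   0.009958
```

`annotate_structure()` writes the equivalent HLA-branch scores into a
PDB B-factor column for viewer coloring, and `delta_affinity()` runs the
wild-type-versus-mutant 9-mer scan with a paired t-test across an HLA
panel. See the methods vignette (`vignettes/methods.Rmd`) for the model,
its assumptions, and every tunable parameter.

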