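# mdhgi

Prediction of candidate miRNA–disease associations by **m**atrix
**d**ecomposition and **h**eterogeneous **g**raph **i**nference.

Experimentally validating that a miRNA is involved in a disease is slow and
expensive, so curated catalogs of known associations (such as HMDD) cover
only a small corner of the true association matrix. `mdhgi` is aimed at
computational biologists who want to rank the *unknown* miRNA–disease pairs
of such a catalog by their probability of being genuine, so that wet-lab
validation effort can be spent on the most promising candidates.

## The model

Let `A` be the binary `m × n` miRNA × disease association matrix. Two ideas
are combined:

1. **Denoising by a self-expressive low-rank decomposition.** Curated
   catalogs contain both redundant and missing entries. `A` is decomposed as
   `A = AX + E`, with

   ```
   min ‖X‖* + α ‖E‖₂,₁   s.t.  A = AX + E         (α = 0.1)
   ```

   where `‖·‖*` is the nuclear norm (a convex surrogate for rank) and
   `‖·‖₂,₁` the sum of column norms (column-sparse noise). The problem is
   solved by inexact augmented Lagrange multipliers (alternating singular
   value thresholding, a linear system, and column-wise shrinkage). The
   denoised matrix is `A* = AX*`; with the left factor replaced by the
   identity the model degenerates to robust PCA.

2. **Propagation over a heterogeneous similarity graph.** Disease
   similarity `SD` integrates ontology-DAG semantic similarity (two
   contribution models — geometric decay with factor Δ = 0.5, and
   −log DAG-frequency — averaged) with a Gaussian interaction-profile
   kernel; miRNA similarity `SR` integrates a functional similarity matrix
   with the analogous kernel. After symmetric degree normalization of both,
   scores are the fixed point of

   ```
   P ← a · SR · P · SD + (1 − a) · A*            (a = 0.4, L1 cutoff 1e-6)
   ```

   which sums the weights of all length-three paths miRNA′–miRNA–disease′–
   disease, iterated to convergence.

Evaluation harnesses (global/local leave-one-out and repeated 5-fold
cross-validation with ROC/AUC) recompute every association-dependent
quantity — kernels, decomposition, propagation — inside each fold, so the
held-out label cannot leak through the similarity matrices.

## Worked example

```r
library(mdhgi)

ds  <- generate_synthetic(synth_config(seed = 1))
ds
#> Synthetic miRNA-disease dataset: 40 miRNAs x 30 diseases, 148 observed
#> associations, 24 hidden true pairs, rank 3 truth

fit <- mdhgi(ds$observed, ds$ontology, ds$ms)
fit
#> MDHGI association model
#>   40 miRNAs x 30 diseases, 148 known associations
#>   decomposition: average
#>   propagation: 13 iterations, final L1 change 6.22929e-07

predict(fit, disease = "disease-002", n = 5)
#>     mirna     score rank
#> 1 mir-005 0.1965600    1
#> 2 mir-008 0.1852587    2
#> 3 mir-002 0.1823853    3
#> 4 mir-012 0.1650227    4
#> 5 mir-014 0.1644287    5

recovery_score(ds, fit$scores)$auc
#> [1] 0.9215902
```

The synthetic generator plants a rank-3 association pattern, hides 20 % of
the true pairs and flips 5 % of entries as noise; the recovery AUC of 0.92
says the fitted model ranks the hidden true pairs far above never-true
pairs. `predict()` lists, for one disease, the candidate miRNAs (those with
no known association) in decreasing score order — the list a bench
scientist would walk down.

Real data goes through the same interface: `read_associations()` (two-column
TSV), `read_ontology()` (per-disease `child<TAB>parent` ancestor blocks) and
`read_similarity()` (TSV matrix with name headers). A thin command-line
front end with `simulate` / `predict` / `evaluate` subcommands is installed
at `inst/cli/mdhgi`.

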