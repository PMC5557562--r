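---
title: "Predicting arginine methylation sites from sequence windows"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting arginine methylation sites from sequence windows}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Arginine methylation is a widespread post-translational modification with
roles in transcription, RNA processing and signalling. Experimentally
mapping methylated arginines is slow and expensive, so sequence-based
classifiers are used to triage candidate sites. The biological premise is
that the local context flanking an arginine — many known substrates sit in
glycine/arginine-rich (GAR) or proline/serine-rich stretches — carries
enough signal to separate methylated from non-methylated sites.

`metharg` implements that idea as a complete, reproducible pipeline:
arginine-centered peptide windows, physicochemical feature encoding,
information-gain feature selection, and an RBF-kernel soft-margin support
vector classifier tuned by cross-validated grid search.

## Dataset construction

Every arginine in an annotated protein yields one window of odd length
$L$ (position $0$ is the arginine; protein termini are padded with `X`).
Annotated positions become positives; all other arginines start as
*unlabeled*, because absence of a report is not evidence of absence.

Three identity-based filters follow, all using ungapped positional
identity on equal-length windows with `X` matching nothing (so padding
cannot create spurious similarity):

1. positives are redundancy-reduced greedily at a 40% identity cut-off;
2. unlabeled windows are likewise reduced;
3. unlabeled windows within 40% identity of *any* positive are discarded,
   and the survivors become pseudo-negatives.

Greedy first-come selection in input order is deterministic and, for
equal-length peptides, a faithful desk-scale stand-in for short-word
clustering tools. The positive set is then split 4:1 (test size
$\mathrm{round}(n/5)$), an equal-sized negative test set is drawn, and
class imbalance in training is handled by undersampling: $k$ balanced
negative subsets (default $k = 5$), each the size of the positive
training set.

## Feature encoding

Each window of length $L$ maps to $10L + 4$ named features — for
$L = 19, 23, 27, 31, 35$ that is $194, 234, 274, 314, 354$. Per position:

* five Atchley factors (a five-dimensional summary of amino-acid
  physicochemical space: polarity/accessibility, secondary structure,
  size, codon composition, charge);
* the positional amino-acid frequency, read from a $21 \times L$ table
  (20 residues + `X`, columns normalized to 1) fitted **only on positive
  training windows** to avoid test-set leakage;
* predicted solvent accessibility and intrinsic disorder, from a
  pluggable provider (below);
* Kyte–Doolittle hydropathy and van der Waals volume (Darby–Creighton
  values).

Whole-peptide features: mean van der Waals volume, GRAVY (both averaged
over non-`X` residues only, so terminal padding does not dilute
short-context peptides), net charge at pH 7, and isoelectric point.

Charge and pI use a Henderson–Hasselbalch sum over free termini and the
C/D/E/H/K/R/Y side chains with a simplified Bjellqvist-style pKa set
(constant termini, `inst/extdata/scales/pka.tsv`); pI is the unique root
of the strictly decreasing charge curve, found by bisection on
$[0, 14]$. The padding residue `X` encodes as 0 in every per-residue
scale: padding must carry no physicochemical signal.

### The property provider

External structure predictors for accessibility and disorder are
deliberately abstracted behind a contract: `predict(peptide)` returns two
vectors in $[0,1]$ of the peptide's length. The built-in default is an
explicit stand-in, not a re-implementation of any published predictor: it
maps residues to embedded propensity scales (theoretical maximum
accessible surface area; TOP-IDP disorder propensity), min–max scales
them to $[0,1]$, sets `X` to 0.5, and smooths with a symmetric sliding
mean of half-width 3. It is deterministic, order-symmetric, and
replaceable by a real predictor without touching the rest of the
pipeline.

## Feature selection

Feature relevance is scored by information gain in bits,
$H(Y) - H(Y \mid \mathrm{bin}(X))$, which for two classes lies in
$[0, 1]$. Continuous features are discretized by recursive Fayyad–Irani
MDL splitting; when MDL accepts no cut the gain is exactly 0 and the
feature is pruned as irrelevant. Features with at most two distinct
values are already discrete and are used as their own bins — without this
rule a genuinely label-aligned binary feature at small $n$ would be
rejected by the MDL penalty, which is calibrated for continuous cut
selection. On any arginine-centered dataset the residue-lookup features
at position 0 are constant (the center is always `R`) and are always
pruned, a useful sanity check on the scoring.

Scores are ranked descending with ties broken by the canonical
family-major, position-minor feature order, so rankings are fully
reproducible. The selection sweep evaluates nested prefixes of the
ranking (default step 50, final partial prefix included). Ranking is
computed per balanced training set (positive training windows plus one
negative subset), since relevance is assessed on the data the classifier
will actually see.

## Classifier

The classifier is a two-class soft-margin C-SVC with RBF kernel
$K(x_i, x_j) = \exp(-\gamma \lVert x_i - x_j \rVert^2)$. No SVM library
is a dependency: the dual problem is solved by a deterministic SMO with
maximal-violating-pair working-set selection (stopping tolerance $10^{-3}$
on the KKT violation), authored in C++ inside the package and verified in
the test suite against a brute-force pairwise dual-ascent solve on small
instances. Features are min–max scaled to $[0,1]$ with training-set
bounds that are stored in the model and re-applied at prediction time.
The decision threshold is 0 on the raw decision value; ROC analysis uses
the raw scores, and no probability calibration is attempted.

$(C, \gamma)$ are chosen by exhaustive grid search under stratified
10-fold cross-validated ROC AUC (per-fold AUC averaged; folds fixed
across the grid and seeded). Ties prefer the smaller $C$, then the
smaller $\gamma$. The low-level default grid is the canonical coarse one,
$C \in 2^{\{-5,-3,\dots,15\}}$, $\gamma \in 2^{\{-15,\dots,3\}}$; the
pipeline front end `metharg()` defaults to a condensed grid
($C \in 2^{\{-3..7\}}$, $\gamma \in 2^{\{-11..-3\}}$) because the full
grid costs ~20x more CV fits and, on the synthetic world, selects the
same region. Pass `svm_config()` explicitly to sweep the full grid.

With $k$ negative subsets and several feature-subset sizes there are many
candidate models; the pipeline retains the one with the highest CV AUC
and reports the whole sweep table, so the per-subset spread stays
visible. Cross-validated metrics are pooled over concatenated
out-of-fold predictions (not averaged per fold), keeping the count-based
formulas exact. MCC with a zero denominator factor is defined as 0.

## The synthetic world

Because curated methylation-site compendia are not bundled, the package
generates its own: proteins drawn i.i.d. from a background composition
(uniform over 20 residues with arginine boosted to 0.08 so each protein
carries several candidate sites), arginines methylated at rate 0.25, and
a GAR-like motif planted around methylated sites — glycine at offsets
$\pm 1, \pm 2$ with probability 0.8 each. Defaults (300 proteins of
80–200 aa) give roughly 700 positive and 2300 negative windows after
filtering, i.e. more than 500 per class.

What a green end-to-end test establishes: the pipeline recovers planted
positional signal (motif-offset features occupy the top information-gain
ranks) and discriminates held-out windows (AUC > 0.9), while a motif-free
null world stays at chance (AUC $0.5 \pm 0.05$). What it does *not*
establish: performance on real proteomes — the generator has i.i.d.
background composition, a single hard-coded motif geometry, no homology
structure between proteins and no real PRMT substrate specificity, so
real-data difficulty (correlated windows, weak and heterogeneous motifs,
annotation noise) is absent by construction.

## Numerical choices and edge cases

* Identity values are multiples of $1/L$; the threshold comparison is
  strict (`< t` retains).
* The 4:1 split uses `round(n/5)` for the test share, remainder to
  training; negative subsets sample without replacement within a subset
  and independently across subsets. A pool exactly equal to the subset
  size degenerates to identical subsets, with a message.
* Windows containing nonstandard residues (B, Z, U, O, J) are dropped
  with a warning; proteins shorter than 30 aa are rejected at load.
* `uniroot` tolerance for pI is $10^{-9}$ in pH; SMO kernel matrices are
  held densely (desk-scale $n$); models serialize to JSON at full double
  precision and restored models reproduce scores to $10^{-12}$.
* If every feature is pruned (possible on null data), the pipeline falls
  back to the full canonical feature list so a model can still be fit —
  and honestly sit at chance.

## Known limitations

The identity filter approximates clustering-tool behaviour rather than
wrapping the real binary; the default accessibility/disorder provider is
a propensity smoother, not a structure predictor; and the headline
performance of the original curated-data study is out of reach by design,
since that dataset is not deposited — the synthetic world tests the
machinery, not the biology.
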