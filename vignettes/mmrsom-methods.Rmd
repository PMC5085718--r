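---
title: "Bond-level CYP metabolism models: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bond-level CYP metabolism models: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The modeling problem

CYP3A4, CYP2D6 and CYP2C9 together clear the majority of marketed drugs.
For a candidate molecule the practical questions are *which bond* is
attacked, *by which biotransformation*, and *under which isozyme*.
`mmrsom` treats every candidate bond, paired with an isozyme, as one
classification instance — a *microsomal metabolic reaction system*
(MMRS) — and builds one binary classifier per biotransformation:

| type | biotransformation            | candidate bond pattern                                  |
|------|------------------------------|---------------------------------------------------------|
| I    | aliphatic C-hydroxylation    | H on a non-aromatic carbon                              |
| II   | aromatic C-hydroxylation     | H on an aromatic carbon                                 |
| III  | N-dealkylation               | single C–N bond, sp3 carbon bearing ≥ 1 H               |
| IV   | O-dealkylation               | single C–O bond, sp3 carbon bearing ≥ 1 H, ether-type O |

Patterns I and II are disjoint by the aromatic flag.  The oriented pair
(A, B) always places the reacting carbon in A; B is the hydrogen (I, II),
nitrogen (III) or oxygen (IV).  This orientation is fixed once and shared
between training and prediction, because half of the 56 descriptors are
side-specific.

Reactions with too few observed sites to support a model (S-/N-oxidation,
desulfurization) are outside the scope by design; the package models the
four patterns above only.

## Pattern decisions where the definitions are pictorial

Bond-pattern definitions in the field are usually drawn, not written, so
three edges needed a decision:

* **Amide nitrogens.** Pattern III includes sp3-C–N bonds whose nitrogen
  is an amide nitrogen by default; the stricter reading is available as
  `exclude_amide_n = TRUE`.  N-dealkylation of amides is chemically
  real (if slower), so inclusion is the safer default.
* **Aromatic C–N bonds** are excluded from pattern III: with no alpha
  hydrogen available on the aryl carbon there is nothing to dealkylate.
* **Hydroxyl C–O bonds** are excluded from pattern IV: O-dealkylation by
  definition releases an alcohol from an ether, so the oxygen must carry
  a second heavy neighbor.

## Symmetry

Counting the three C–H bonds of a methyl group as three instances would
triple-count one chemical site and inflate the unlabeled pool, so
candidates are collapsed to one representative per automorphism orbit:
two bonds are equivalent when a graph automorphism respecting element,
formal charge and bond kind (single/double/triple/aromatic) maps one
oriented pair onto the other.  Orbits are computed from vertex-colored
BLISS automorphism generators (`igraph`); bond kinds are encoded by
colored subdivision vertices because the backend colors vertices only.
The test suite validates the orbit partition against a brute-force
backtracking enumeration of automorphisms for every fixture molecule
with at most 12 heavy atoms.

An annotation may name any member of an orbit (for C–H sites, either the
carbon with `atom_b = 0` or one specific hydrogen); the whole orbit
becomes positive.

## Descriptors

Each MMRS is described by 56 bond descriptors (29 physicochemical, 27
topological) plus three enzyme indicator columns.  Conventions that
matter:

* Neighbor statistics of A exclude B and vice versa (descriptors 17–24,
  30–43).  A max/min over an empty neighbor set (e.g. the B-side of a
  C–H bond) is reported as a 0 sentinel to keep vectors dense and
  fixed-length.
* The carbon-hybridization neighbor counts (50–55) count all carbon
  neighbors including the partner, following their plain definition.
* Aromatic bonds carry bond order 1.5; Kekulé structures are never used
  for descriptors.
* The enzyme is encoded as three 0/1 indicators rather than one
  categorical column, so that distance-based classifiers see a metric
  difference of the same magnitude between any two isozymes.

### Partial charges

Sigma charges are computed by the classical damped PEOE iteration
(quadratic electronegativity in the charge, transfer across each bond
scaled by the donor's cation electronegativity, damping (1/2)^k, 8
iterations), with the published sigma parameters per element and
hybridization; phosphorus uses the parameter triple of the common
open-source extension of the original table.  The iteration conserves
total charge exactly (pairwise transfers), which the tests assert to
1e-6 on every fixture.

Pi charges use the same damped equalization restricted to the conjugated
subsystem — atoms in multiple/aromatic bonds plus lone-pair donor N/O/S
attached to them — with an *approximate* pi parameter table chosen to
reproduce the qualitative mesomeric directions (donors acquire positive,
acceptor neighborhoods negative pi charge).  Atoms outside any
conjugated system have pi charge exactly 0.  Polarizabilities come from
atomic-hybrid contribution tables; charge densities are charge per van
der Waals sphere surface, q / (4 pi r²), with Bondi radii.  The original
study computed these quantities with a proprietary engine whose exact
definitions are unpublished; the package's contract is therefore
*internal consistency* — determinism, renumbering invariance, charge
conservation, neighborhood-exclusion semantics — rather than numerical
equality with any external tool, and absolute descriptor values should
not be compared across charge engines.

### pH 7.4 microspecies

Descriptors are computed on the major microspecies at physiological pH,
obtained from a fixed rule table rather than a pKa engine: carboxylic,
sulfonic and P–OH acids and tetrazole N–H are deprotonated; aliphatic
amines (sp3 N, neutral, all heavy neighbors sp3 carbons) and
amidine/guanidine imino nitrogens are protonated; anilines, amides,
alcohols, phenols and pyridines stay neutral.  Groups with pKa close to
7.4 (imidazole, phenol) deliberately stay neutral — a rule table should
only encode clear-cut cases.

## Positive/unlabeled screening

Metabolism data cannot contain trustworthy negatives: a bond never
reported as a site of metabolism may simply never have been probed.
Unlabeled MMRS are therefore promoted to *reliable negatives* by an
ensemble vote: the eight roster classifiers are trained
positive-vs-unlabeled under stratified 10-fold cross-validation, and an
unlabeled record receives one vote from each classifier whose
out-of-fold prediction calls it unlabeled.  Records with **more than 5
of 8 votes** become negatives; the rest of the unlabeled pool is
discarded before modeling.  Out-of-fold verdicts (rather than in-sample
predictions) are used so that no record is judged by a model that was
trained on it; the vote threshold is exposed (`vote_threshold`) for
sensitivity analysis.  A classifier that fails to fit abstains with a
warning; more than two abstentions abort the screening.

The retained positives and negatives are split 4:1 into training and
test parts, stratified by label, under a caller-supplied seed.

## Model search

Per reaction type, four feature-selection arms (chi-squared, information
gain, gain ratio — all on Fayyad–Irani MDL bins — and ReliefF with k =
10 over all instances) are scored on the training part of each of 10 CV
folds and averaged.  Zero-scored features are removed (ReliefF: ≤ 0,
since its weights may be legitimately negative).  Backward elimination
then evaluates all eight classifiers at every subset size m, m−1, …, 1,
dropping the lowest-ranked feature each step without re-scoring.  A
fifth "none" arm evaluates the full 56-descriptor set.  The winner is
the grid cell with the highest pooled CV accuracy among cells with AUC
> 0.9; ties go to fewer features, then higher AUC, then roster order.
The enzyme indicators are exempt from elimination by default — they
carry the MMRS enzyme identity, which is the framework's central
concept — and the exemption is configurable.

The roster approximates the classical WEKA line-up with the engines
available in a scientific R stack: Gaussian naive Bayes (BN),
1-nearest-neighbour (IBK), an entropy-split `rpart` tree (J48), a
100-tree `ranger` probability forest (RF), an RBF `e1071` SVM (C = 1,
gamma = 1/d, decision values mapped through a logistic link), AdaBoostM1
(50 rounds on decision stumps — the classical WEKA base for this
booster — with the standard early stop at zero or ≥ 0.5 weighted
error), Bagging (10 bootstrap bags of 1-NN), and KStar
as an instance-based learner with an exponential distance kernel whose
scale is 20% of the mean training distance (a declared simplification of
the entropic distance; the manifest records every hyperparameter).
Hyperparameters are fixed — the grid searches over feature subsets and
classifier families, never over tuning constants.

Two implementation notes worth knowing when reading timings: inside
backward elimination the distance-based members and naive Bayes are
evaluated incrementally across subset sizes (the squared-distance or
log-likelihood contribution of an eliminated feature is subtracted),
while trees, forests, boosting and the SVM are refit per size; and CV
metrics are pooled over out-of-fold predictions rather than averaged
over folds, so a single record count underlies ACC and AUC.

## Evaluation

SE = TP/(TP+FN), SP = TN/(TN+FP), ACC = (TP+TN)/n, BACC = (SE+SP)/2, and
AUC by the Mann–Whitney rank statistic (equal to trapezoidal ROC
integration, which the tests assert to 1e-12).  Reports carry a
`training` row (seeded 10-fold CV — the package always labels the row
explicitly, since resubstitution and CV "training" figures are not
comparable) and a `test` row (single evaluation of the final model on
the held-out split).  Scores convert to calls at probability 0.5 by
default; the threshold is an argument, not a constant.

## The synthetic library: what it emulates, what it does not

`make_toy_library()` defines the package's reference study conditions:
**200 molecules, seed 0**, 85% benzene-core molecules with 1–3
substituents drawn from a fixed fragment grammar (methyl/ethyl/propyl,
aryl and alkyl ethers, tertiary/secondary amines, halogens), 15% small
acyclic amines/ethers/alkanes, at most ~15 heavy atoms per molecule (so
the brute-force automorphism oracle stays tractable), and 1–3 isozymes
per molecule assigned uniformly.  At these settings every reaction type
exceeds the 60-positive floor below which a dataset is considered too
small to model.

Planted positives are deterministic, automorphism-invariant structural
rules: benzylic C–H (I), ring C–H *ortho* to an O substituent (II),
N-methyl on a nitrogen with ≥ 2 carbon neighbors (III), aryl-methyl
ether (IV).  The ortho rule was chosen over a para rule deliberately:
ortho membership is visible to the descriptor set through the
neighbor-charge channel (the ipso carbon attached to O is strongly
positive under PEOE and appears in `maxqtot_A`), whereas a para
relationship is invisible to every first/second-shell channel the
framework computes — a planted rule must be *descriptor-separable* for
ceiling accuracy 1 to exist.  Because unlabeled candidates are true
negatives by construction, the screening stage has exact ground truth,
and the paper-style selection gate (CV ACC ≥ 0.95, AUC > 0.9) is
attainable by an honest model.

What the toy library does **not** emulate: real CYP substrate chemistry
(no steric or electronic subtlety beyond the planted rules, no
enzyme-specific regioselectivity — planted sites are positive for every
isozyme assigned to the molecule, so the enzyme indicators carry no
signal in the synthetic setting), no fused heterocycles, no
stereochemistry, no false negatives unless explicitly injected.
Passing the synthetic gates therefore demonstrates that the machinery —
extraction, descriptors, screening, search, prediction — is correct and
self-consistent, not that real-data accuracies would reach the same
level.

The abstract benchmark (`make_feature_table()`) complements the
molecular one: 500 rows, 5 informative of 56 descriptor columns.  For
feature-*ranking* properties the generator's strong default (separation
3 within-class standard deviations) is appropriate — every scorer should
put the planted columns on top.  The feature-*recovery* benchmark (does
the winning subset retain the planted columns?) instead runs at
separation 1.5, and the distinction matters: recovery is only a
well-posed property when the optimal subset needs all informative
columns.  At separation 1.5 the expected accuracy still climbs from
Φ(1.5) ≈ 0.93 with four features to Φ(1.68) ≈ 0.95 with five, so the
highest-accuracy cell must keep them; at separation 3 three columns
already classify perfectly and the fewer-features tie rule then
*correctly* discards planted columns — a smaller perfect model is the
right answer there, not a recovery failure.  At the 1.5 setting the
winning subset is expected to recover at least 80% of the planted
columns.

## Numerical choices and degenerate inputs

* PEOE: 8 damped iterations; H cation electronegativity 20.02.
* Naive Bayes standard deviations are floored at 1e-6; feature scaling
  treats near-constant columns (sd < 1e-9) as unit-scale.
* 1-NN breaks distance ties by the lower training-row index.
* Feature-score ties rank by lower feature id; elimination drops the
  tail of the ranking deterministically.
* Stratified folds are reduced (with a message) when the minority class
  has fewer members than folds.
* Empty candidate sets, molecules without annotations, and reactions
  missing from a prediction bundle set all yield empty results, not
  errors; genuinely contradictory inputs (annotation not matching any
  enumerated candidate, unknown enzyme, malformed scheme string) raise
  errors naming the offending record.
* All randomness (folds, bags, forests, boosting, splits, generators)
  derives from caller-supplied integer seeds; derived seeds stay far
  below 2^31.

## Known limitations

* Partial charges and electronegativities are open re-implementations;
  absolute values differ from proprietary engines, so models trained on
  descriptors from one engine must never be applied to descriptors from
  another.
* The pi-charge model is a declared approximation; its parameters encode
  qualitative mesomeric behavior, not fitted reference data.
* The pH rule table ignores borderline pKa groups.
* KStar uses an exponential-kernel simplification of the entropic
  distance.
* Aromaticity perception is ring-local Hückel counting; exotic fused or
  charged aromatic systems may be mis-flagged.
* The synthetic generator covers the four modeled patterns only and
  makes no attempt to mimic real regioselectivity data.
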