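# mmrsom — bond-level site-of-metabolism prediction for CYP3A4 / 2D6 / 2C9

Three cytochrome P450 isozymes — CYP3A4, CYP2D6, CYP2C9 — clear most
drugs in clinical use.  For a new molecule the questions that matter in
lead optimization are *which bond* is metabolized, *by which
biotransformation*, and *under which isozyme*.  `mmrsom` answers all
three at once by classifying **microsomal metabolic reaction systems
(MMRS)**: one candidate bond of a substrate paired with the isozyme
considered to act on it.

The package is aimed at computational chemists and DMPK modelers who
want an auditable, fully scripted 2D workflow: no 3D structures, no
docking, no proprietary descriptor engine.

## The method in brief

Four biotransformations are modeled, each with its own dataset and
classifier:

| type | biotransformation         | candidate bonds                                   |
|------|---------------------------|---------------------------------------------------|
| I    | aliphatic C-hydroxylation | H on non-aromatic C                               |
| II   | aromatic C-hydroxylation  | H on aromatic C                                   |
| III  | N-dealkylation            | sp3 C–N single bonds with an alpha H              |
| IV   | O-dealkylation            | sp3 C–O single bonds with an alpha H, ether-type O |

1. **Extraction** — candidate bonds are enumerated per pattern,
   collapsed to one representative per graph-automorphism orbit, and
   labeled *positive* (annotated site of metabolism) or *unlabeled*.
2. **Descriptors** — each bond (A = reacting carbon, B = partner atom)
   gets 56 descriptors computed at the pH 7.4 major microspecies: PEOE
   sigma/pi partial charges, orbital electronegativities,
   polarizabilities, charge densities, neighbor extrema and counts,
   hybridization flags, bond order — plus three enzyme indicator
   columns.
3. **Negatives screening** — experimental data has no trustworthy
   negatives, so eight classifiers (AdaBoostM1, Bagging, naive Bayes,
   1-NN, entropy tree, KStar, SVM, random forest) vote under 10-fold CV;
   an unlabeled bond predicted "unlabeled" by **more than 5 of 8**
   out-of-fold models becomes a reliable negative, the rest are
   discarded.  Positives and negatives then split 4:1 into
   train and test.
4. **Model search** — four feature scorers (chi-squared, information
   gain, gain ratio on MDL bins; ReliefF) rank the features; backward
   elimination evaluates all eight classifiers at every subset size by
   10-fold CV (plus a no-selection arm), and the cell with the highest
   accuracy among those with AUC > 0.9 wins:

   SE = TP/(TP+FN), SP = TN/(TN+FP), ACC = (TP+TN)/n,
   BACC = (SE+SP)/2, AUC = P(score⁺ > score⁻) + ½·P(tie).
5. **Prediction** — the four fitted bundles call every candidate bond of
   a new molecule under a chosen isozyme, with per-bond probabilities.

A synthetic molecule generator with planted, descriptor-separable SOM
rules makes the whole pipeline testable without any external dataset;
see the methods vignette (`vignettes/mmrsom-methods.Rmd`) for the
science, the parameter choices, and the limitations.

## Worked example

```r
library(mmrsom)

## a 60-molecule toy library with planted N-dealkylation sites
lib  <- make_toy_library(60, seed = 0)
mols <- parse_smiles_set(lib$smiles$smiles, lib$smiles$mol_id)
mm   <- extract_mmrs(mols, lib$annotations, lib$registry)
ds   <- build_reaction_datasets(mm)
ds$III$counts
#>  positive unlabeled  negative
#>        55        25         0

## promote reliable negatives by ensemble voting, split 4:1, search
scr    <- screen_negatives(ds$III, seed = 1)
length(scr$negatives)
#> [1] 25
ms     <- build_modeling_set(ds$III, scr$negatives, seed = 1)
y      <- factor(ifelse(ms$train$records$label == "positive", "pos", "neg"),
                 levels = c("neg", "pos"))
search <- run_model_search(ms$train$vectors, y, seed = 1)
sel    <- select_optimal(search)
sel[c("fs", "classifier", "size", "acc", "auc")]
#> $fs         [1] "chi"
#> $classifier [1] "AdaBoostM1"
#> $size       [1] 1
#> $acc        [1] 1
#> $auc        [1] 1

bundle <- fit_final(ms$train$vectors, y, sel, reaction_type = "III", seed = 1)
round(evaluate_bundle(bundle, ms, seed = 1), 3)
#>          SE SP ACC BACC AUC
#> training  1  1   1    1   1
#> test      1  1   1    1   1

## call sites on a new molecule under CYP3A4
new <- parse_smiles_set("CCN(C)Cc1ccccc1", "query")[[1]]
predict_molecule(new, "CYP3A4", list(III = bundle))
#>   mol_id atom_a atom_b enzyme reaction_type probability     call
#> 1  query      2      3 CYP3A4           III           0 negative
#> 2  query      4      3 CYP3A4           III           1 positive
#> 3  query      5      3 CYP3A4           III           0 negative
```

The planted rule marks N-methyls on amine nitrogens with two or more
carbon neighbors as N-dealkylation sites: the query's N-CH3 (atom 4) is
called positive, while the N-ethyl and N-benzyl alpha carbons (atoms 2
and 5) are called negative.  On this cleanly separable toy chemistry the
selected model reaches perfect CV and test scores with a single
descriptor and saturated probabilities — real metabolism data is far
noisier; the vignette spells out what these synthetic gates do and do
not show.

The pipeline driver runs all four reactions and writes every artifact
(descriptor table, screening scores, search grid, model bundles,
quality reports, run manifest):

```r
run_pipeline(list(out_dir = "artifacts", seed = 0,
                  simulate = list(n_molecules = 200)))
```

A thin command-line front end with the same stages ships in
`inst/cli/mmrs` (subcommands `simulate`, `extract`, `screen`, `train`,
`evaluate`, `predict`, `pipeline`).

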