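---
title: "Multi-label learning for drug-target prediction and repurposing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-label learning for drug-target prediction and repurposing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(brdti)
```

## The model

Most machine-learning approaches to drug-target interaction (DTI)
prediction pose a binary question -- does this (drug, gene) pair
interact? -- and must therefore sample large numbers of random
non-interacting pairs as negatives, which no experiment has ever
observed. `brdti` inverts the viewpoint: **each drug is a class
label**, and the genes it is known to target are that class's training
examples. A gene targeted by several drugs carries several labels, so
DTI prediction becomes a multi-label classification problem in which
*every* training example, positive or negative, comes from an observed
interaction.

The multi-label problem is solved by **binary relevance (BR)**: one
independent binary classifier per drug. For drug $i$ with target gene
set $G_i$, the positives are $G_i$ and the negatives are
$\bigcup_j G_j \setminus G_i$ -- the genes targeted by *other* drugs.
A candidate gene $g$ receives the predicted label set

$$L'(g) = \{\, i : f_i(g) > 0 \,\}$$

over all per-drug decision functions. The alternative label-powerset
transformation (one class per label *combination*) is rejected: with
hundreds of drugs its class space explodes combinatorially and most
combinations have almost no examples.

Genes are represented as **binary presence/absence vectors over Gene
Ontology terms**, taken exactly as annotated -- no ancestor
propagation over the GO graph. Propagating ancestors would build
strong inter-feature correlation into the encoding; semantic
relatedness between terms is deliberately left out (it belongs in
kernel methods, not in a flat feature vector). Three root terms
(`GO:0003674`, `GO:0008150`, `GO:0005575`) are uninformative and always
excluded.

Each per-drug classifier is **$\ell_2$-regularized logistic
regression**. For training pairs $(x_i, y_i)$, $y_i \in \{-1, +1\}$,
the weight vector $\omega$ minimizes

$$\min_\omega \; \tfrac12 \omega^\top \omega
  + C \sum_i \log\!\bigl(1 + e^{-y_i \omega^\top x_i}\bigr),$$

where $C > 0$ trades data fit against the ridge penalty. The posterior
$p_i(g) = 1/(1 + e^{-\omega_i^\top x})$ gives each prediction a
confidence; $f_i(g) > 0$ is equivalent to $p_i(g) > 0.5$ (strictly:
a decision value of exactly zero is negative).

### Why imbalance is a feature, not a bug

With one class per drug, each binary problem has far more negatives
than positives (ratio $|\bigcup_j G_j \setminus G_i| / |G_i|$). No
class re-weighting is applied, on purpose: the model is biased toward
the negative class, so false positives become much rarer than false
negatives, and the *positive* predictions -- the ones proposed as
repurposing candidates -- are correspondingly credible. The package
verifies this empirically: on held-out synthetic data with $\geq$ 20:1
imbalance and overlapping class signatures, the false-positive rate is
below the false-negative rate in at least 18 of 20 seeded replicates
(`class_weight`-style correction is deliberately not implemented; the
asymmetry is part of the method's logic).

## Constructing the class space

`build_label_space()` implements the corpus rules:

* **Well-studied filter.** Only genes with at least one non-root
  molecular-function or biological-process annotation are kept
  (`filter_well_studied()`); everything else would yield a null or
  meaningless feature vector. CC-only annotated genes are excluded
  entirely, although CC terms *do* participate in the feature
  vocabulary of retained genes (subcellular localization carries
  signal about where a drug acts).
* **Drug classes.** Drugs targeting strictly more than `min_targets`
  genes (default 400) become classes, numbered in descending order of
  target count. Ties are broken lexicographically by drug id -- the
  ordering rule needs a deterministic tiebreak and none is inherent in
  the data.
* **Sentinels.** An `"others"` class (a seeded uniform sample from the
  targets of the non-selected drugs, disjoint from every drug class)
  and a `"non-target"` class (a seeded uniform sample from the
  remaining gene universe) occupy the last two indices. Their sizes
  are constructor parameters (defaults 504 and 128); uniform sampling
  is used because no proportional rule is implied by the class
  definitions. Both participate in training and metrics as ordinary
  classes but are suppressed from repurposing output.

STITCH-style confidence scores may optionally be thresholded with
`min_score`; by default no score filtering happens. Identifiers are
opaque strings -- no id mapping service is consulted.

### Conflict removal

A gene targeted by drugs $i$ and $j$ is simultaneously a positive (for
$i$) and a negative (for $i$'s model, via $G_j$). Such negatives --
same gene id *or* an identical feature vector under a different id --
are removed from the negative side so the small positive class stays
intact (`binary_split()`, `compare_vectors = TRUE` by default; set it
to `FALSE` to compare ids only).

## The solver

`fit_logistic()` minimizes the primal objective directly with a damped
Newton method: the objective is smooth and strongly convex, the
Hessian $I + C X^\top D X$ is well-conditioned at GO-vector dimensions
(hundreds to a few thousand columns), and convergence takes a handful
of iterations. Armijo backtracking guards the step; iteration stops
when the primal gradient norm falls below `tol` (default `1e-6`). The
per-iteration objective trace is retained (it must be non-increasing,
and the tests assert it). An intercept is included as an appended
constant feature and regularized like every other weight -- the
objective above has no separate bias term -- and can be disabled with
`intercept = FALSE`. Any solver reaching the same optimum would be
conformant; the test suite checks the returned objective against an
independent quasi-Newton optimizer to within $10^{-6}$ relative.

## Stratified multi-label cross-validation

Classic stratified $k$-fold keeps per-class proportions but assumes
one label per example. With label sets, `stratify_folds()` uses
iterative stratification: real-valued desired counts (label count
$/k$ per label per fold, $n/k$ per fold) are maintained and clamped at
zero; the label with the fewest remaining unassigned examples is
processed first (rare labels are hardest to spread); each of its genes
goes to the fold with the largest remaining desired count for that
label, ties broken by the largest desired total, remaining ties by a
seeded uniform draw. Assigning a gene decrements the desired counts of
*all* its labels. Label-free genes are placed last into the emptiest
folds. Consequences of this design:

* folds are disjoint and covering by construction;
* with single-label data the procedure reduces to classic
  stratification within one example per class per fold;
* fold sizes can drift a little when the label structure forces it --
  a warning fires when max $-$ min exceeds `slack` (default 2);
* genes are sorted internally, so input order never changes the
  result, and identical seeds give identical folds.

`cv_brdti()` (default $k = 5$) trains on $k-1$ folds and predicts the
held-out fold; metrics are **pooled** over all held-out predictions
into a single report rather than averaged per fold, which matches
reporting one CV-wide number per metric. A class emptied by a training
split is excluded from that fold's ensemble with a warning; a class
that is empty overall (e.g. an unused sentinel) is dropped up front
with a message.

`tune_c()` selects $C$ from the grid
$\{2^{-11}, 2^{-9}, \dots, 2^{-3}, 1, 2^{3}, \dots, 2^{17}\}$
(`c_grid()`) by the best **one-hit rate** -- the HitRate aggregate at
the per-instance threshold $1/|L_i|$, i.e. the fraction of genes with
at least one drug correctly recognized. That is the method's headline
quantity, so it anchors model selection; ties go to the larger $C$
(the stronger data fit).

## Metrics

Per instance with true label set $L$ and predicted set $L'$:

$$\mathrm{HitRate} = \frac{|L \cap L'|}{|L|}, \quad
  \mathrm{NovelRate} = \frac{|L' \setminus L|}{|L'|}, \quad
  \mathrm{Jaccard} = \frac{|L \cap L'|}{|L \cup L'|}.$$

NovelRate is not an error rate: the known label set is incomplete, so
predictions beyond it are *candidate discoveries*. Conventions for
undefined corners: NovelRate with $L' = \emptyset$ is 0 (no
predictions, no novelty); per-label F with a zero denominator (a label
never true and never predicted) is 0, and the count of such labels is
reported alongside.

`threshold_aggregate()` reports, for a threshold $\xi$, the fraction
of instances whose per-instance value is $\geq \xi$. Two thresholds
have names: $\xi = 1$ (the *all-hit* rate: every true label
recovered) and the symbolic $\xi = 1/|L_i|$ (the *one-hit* rate: at
least one true label recovered, each instance compared against its own
set size). Per-label precision/recall F-measures, their unweighted
macro average, and the pooled micro average follow the standard
indicator-sum definitions; `dti_recall()` is the pooled fraction
$\sum_i |L_i \cap L_i'| \,/\, \sum_i |L_i|$ of known interactions
recovered. ROC/AUC is intentionally absent -- a per-pair ranking score
does not describe label-set prediction.

## Repurposing output

`extract_novel()` scans every gene, keeps predictions with
$p > $ `min_probability` (default 0.5, the decision rule itself;
raise it to keep only high-confidence candidates), suppresses the two
sentinel classes, and splits the rest into `known` (edge present in
the training corpus) and `novel`. `drug_phenotype_links()` joins the
novel associations with a gene-to-phenotype map: a (drug, phenotype)
link is supported by the drug's predicted novel targets carrying that
phenotype, and its `support_mode` is `"all"` when those cover every
carrier of the phenotype *within the scanned gene universe* --
judging coverage against the full external phenotype gene catalog
would be impossible from inside the analyzed gene set, and this
relative reading is the documented limitation.

## The synthetic generator

`synth_corpus()` plants recoverable structure: each drug owns a block
of signature GO terms (disjoint by default; `signature_overlap` makes
classes confusable on purpose), each gene draws 1-3 drugs and carries
each signature term of its drugs with probability `p_signal` and each
background term with probability `p_noise`, plus one guaranteed
non-root MF/BP anchor so every simulated gene passes the well-studied
filter. Aspects cycle MF/BP/CC along the synthetic vocabulary, keeping
the filter and the aspect options meaningful.

What it emulates: multi-drug genes, class-specific GO profiles,
annotation noise, background genes for a non-target class, and the
exact on-disk dialects the readers ingest (STITCH TSV, GAF, phenotype
TSV -- round-trip tested). What it does not: the GO DAG topology, the
heavy-tailed term-frequency and class-size distributions of real
corpora, correlated annotations between related genes, and incomplete
labels. Passing the recovery tests therefore demonstrates that the
machinery is correct and that planted signal of stated strength is
found -- not that real-database performance will match.

The canonical study conditions, fixed once: 10 drugs, 500 labeled
genes (1-3 labels each), 200-term vocabulary, 8-term signatures,
`p_signal = 0.9`, `p_noise = 0.05`, plus 50 background genes of which
25 form the non-target class. Under these conditions 5-fold CV
recovers essentially every label (one-hit rate $\geq$ 0.99 across
seeds) and every class's signature terms appear among its top-weighted
features. All simulated drugs qualify as classes, so the "others"
class is empty in this study and is dropped from CV ensembles by the
zero-positive rule; its structural zero is visible in the macro-F
(11/12 $\approx$ 0.92 under perfect prediction of the 11 populated
classes). The imbalance study uses 21 single-label drugs with
half-overlapping 6-term signatures and `p_signal = 0.7`, sized so the
evaluated class trains at $\geq$ 20:1 negatives to positives -- a
regime chosen a priori so the classifier makes errors whose direction
can be measured. Test and acceptance problem sizes (hundreds of genes,
tens of terms per class) are the package's choices for a
desk-reproducible demonstration; the machinery itself is sparse
throughout and scales to corpus-size inputs.

## Worked example

```{r example, eval = FALSE}
library(brdti)

sim <- synth_corpus(synth_spec(seed = 101))
universe <- well_studied_genes(sim$annotations)
ls <- build_label_space(sim$corpus, min_targets = 40, others_size = 0,
                        nontarget_size = 0, gene_universe = universe, seed = 101)
vocab <- build_vocabulary(sim$annotations, universe)
feats <- vectorize_genes(sim$annotations, vocab, label_space_genes(ls))

res <- cv_brdti(ls, feats, k = 5, C = 1, seed = 101)
res
aggregate_value(res, "hit", "1/|L|")   # one-hit rate

fit <- brdti(ls, feats, C = 1, skip_empty = TRUE)
assoc <- extract_novel(fit, feats, sim$corpus)
head(repurposed_genes(assoc, ls$labels[1]))
```

## Known limitations

* No GO ancestor propagation means two genes annotated to sibling
  terms share no features; this is a modelling stance, not an
  oversight, but it limits generalization across annotation styles.
* Evidence codes are not filtered (an `exclude_iea` hook exists on
  `build_vocabulary()` for dialects that carry them).
* The label space cannot predict drugs inside "others"; refining that
  class into further models is possible but out of scope.
* Real-corpus headline numbers depend on specific database snapshots
  and an id-mapping service; the package ships none of that and makes
  no claim about reproducing them.
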