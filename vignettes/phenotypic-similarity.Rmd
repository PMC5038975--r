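---
title: "Scoring gene-drug pairs by phenotypic similarity: model and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring gene-drug pairs by phenotypic similarity: model and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phenosim)
```

## The model

`phenosim` scores the similarity between a drug's side-effect profile and a
gene's phenotype profile (typically derived from mouse knockouts and mapped
into the same adverse-event vocabulary), on the premise that a drug
modulating a gene product should produce side effects resembling the
phenotypes of perturbing that gene. Both profiles are sets of terms from one
multi-parent phenotype ontology.

**Term specificity.** Every ontology term gets an intrinsic information
content based purely on the hierarchy, not on annotation frequency (which
would import annotation bias):

$$IC(t) = 1 - \frac{\ln(\mathrm{desc}(t) + 1)}{\ln N}$$

with $\mathrm{desc}(t)$ the number of descendants of $t$ and $N$ the total
term count. A term with fewer descendants is more specific; IC is exactly 1
at leaves and 0 at a root dominating all other terms, and is invariant to
the logarithm base. By default descendants are counted transitively; a
direct-children mode is available for sensitivity analysis
(`load_ontology(..., descendant_mode = "direct")`). Two terms are compared
through the IC of their most informative common ancestor (MICA), with
self-inclusive ancestor sets so that a term's MICA with itself is itself.

**Weighting.** Frequent and co-occurring terms carry little information
about mechanism, so each side of a term pair $(i, j)$ is weighted by
$f \cdot c$: the frequency weight $f = -\ln(k/n)$ (fraction of drugs, resp.
genes, the term is annotated to) and the co-occurrence weight
$c = -\ln J(A, B)$, the negative log Jaccard index of the two terms' entity
sets — computed over drugs for the side-effect side and over genes for the
trait side. The term-pair score is

$$s_{ij} = IC_{MICA}(i,j) \cdot \min(f_i c_i,\; f_j c_j),$$

so a pair only scores high when it is specific in *both* annotation sets.

Two boundary conventions deserve explanation:

* *Never co-occurring pairs* have $J = 0$ and an infinite $-\ln J$; we cap
  the weight at $-\ln(1/(|A \cup B| + 1))$, which is finite, exceeds every
  attainable finite co-occurrence weight at the same support, and grows only
  logarithmically with corpus support.
* *Self-matches.* The raw Jaccard of a term with itself is 1, which would
  nullify exactly the strongest evidence the method is built on — a drug and
  a gene sharing the same specific term. The co-occurrence penalty exists to
  discount *redundant pairs of distinct terms*, so the scorer waives it for
  $i = j$ and uses the maximally informative cap $-\ln(1/(|A|+1))$ instead.
  A ubiquitous term still scores 0 through its zero frequency weight. The
  corpus-level `cooccurrence_weight()` keeps the literal definition
  ($c(t,t) = 0$); only the term-pair scorer applies the convention.

**Best-match aggregation and polypharmacology.** For each gene trait the
best-matching side effect is found, and for each side effect the
best-matching trait. Because drugs typically bind several targets, their
side-effect lists pool the consequences of all of them, while a single gene
explains only a subset: the drug direction therefore keeps only the
`top_k = 20` best-scoring side effects per comparison (all of them if the
drug has fewer), selected per gene so different genes may draw on different
side effects. The raw pair score is the arithmetic mean of the pooled value
lists (the `top_k` drug-side values together with all gene-side values);
an alternative `mean_of_means` combination is available behind
`scoring_config(combine_mode = )`.

**Scaling and normalization.** Genes with very little phenotypic
information can score high by chance, so the raw score is multiplied by
$\ln(\#\text{gene terms})$ — which literally zeroes single-annotation genes;
`gene_scale_mode = "ln_n_plus_1"` retains them if needed — and by a
side-effect burden weight that downweights drugs with many side effects
(tertiles of the per-drug side-effect count: weight 1 up to the 33%
quantile, 0.66 up to the 66% quantile, 0.33 above; linear-interpolation
quantiles, boundary ties falling into the lower bin). Finally scores are
divided by the maximum scaled value over the scored set, giving a
normalized score in $[0, 1]$; the scaling happens before the
max-normalization, and the global maximum is recorded in the output
metadata so runs remain comparable.

## Evaluation measures

`confusion_curve()` sweeps thresholds from high to low with one point per
distinct score, so tied pairs always cross together and precision and lift
are well defined. At each point: precision $= TP/(TP+FP)$, recall/TPR
$= TP/P$, FPR $= FP/N$, accuracy $= (TP+TN)/(P+N)$, and lift
$=$ precision divided by the prevalence $P/(P+N)$ — the enrichment over a
random classifier, which unlike precision is comparable across benchmarks
with different prevalence. AUC is the trapezoid area over (FPR, TPR) and
equals the pairwise Mann-Whitney probability (ties counted half), which the
tests verify exhaustively. Benchmarks are built the way the drug-target
evaluation was: positives plus all other combinations of the drugs and
genes appearing in at least one positive.

The companion analyses follow the same conventions as the published
evaluation: the *causal side-effect fraction* of a scored pair is the share
of its (at most `top_k`) contributing side effects independently known to be
caused via the gene's protein, compared between high- and low-scoring pairs
with a one-sided rank-sum test (normal approximation, tie-corrected);
*PPI proximity* is the minimum hop distance from the gene's protein to any
known target of the drug, with distance 0 meaning the gene *is* a target and
1 a direct interactor; *mapping coverage* bins terms by annotation frequency
into 1, (1,5], (5,10], (10,50], (50,100], >100 (the drug side appends
(100,500] and >500) and reports the mapped fraction per bin.

## The synthetic study generator

Real inputs to this method are licensed (MedDRA-coded side-effect corpora)
or large external databases, so the package ships a generator producing
desk-scale studies with the statistical structure the method assumes, plus
planted ground truth. It emulates:

* a layered, multi-parent phenotype hierarchy (complete tree, default
  4 levels x branching 3 = 40 terms; optional SMQ-like cross links);
* gene trait profiles of specific (leaf) terms, spread across distinct
  sibling groups — knockout phenotypes span different organ systems, and at
  desk scale sibling co-traits would co-occur within a gene and be nullified
  by the co-occurrence weighting as a pure small-corpus artifact;
* drugs with 1-2 planted target genes whose traits are echoed into the
  side-effect profile, each echo blurred to a sibling term with probability
  0.25 (cross-species mapping often lands on a near-identical rather than
  the identical term);
* unrelated noise side effects drawn with Zipf-skewed popularity
  (exponent 2.5) — ubiquitous nuisance side effects are exactly why the
  frequency weighting exists — filling every profile to a common size of 8,
  reflecting that label side-effect lists have comparable lengths whatever
  the target count;
* a synthetic protein-interaction network wiring targets to decoy proteins,
  and a known causal gene-side-effect set drawn from half of the planted
  pairs.

All randomness flows through one seed with per-artifact sub-streams, so
e.g. adding drugs does not perturb gene sampling, and identical
configurations write byte-identical files.

These defaults are a calibrated positive control: under them a correct
implementation recovers planted pairs with ranking AUC above 0.9
(`seed = 7` gives 0.925), while the `copy_fraction = 0` control carries no
signal. Two statistical caveats are documented deliberately. First, a
single-run control AUC is not tightly pinned at 0.5: each drug contributes
50 correlated pairs, so the effective sample is small and the null AUC has a
standard deviation near 0.04; chance-level behaviour is therefore assessed
as a mean over five seeds. Second, top-1 recovery (is the best-ranked drug
for a planted gene its true drug?) plateaus near 55-75% here even where AUC
exceeds 0.92: with 27 leaves and 50 genes of 4 traits, trait profiles
necessarily overlap, and first-place-of-30 is a much stricter statistic than
pairwise ranking. Neither caveat applies at realistic vocabulary sizes
(thousands of terms), where random profiles share almost nothing.

What the generator does **not** emulate: realistic MedDRA term-frequency
distributions, side-effect frequencies or severities, orthology mapping
noise beyond the sibling blur, or biologically structured interaction
networks. Passing the synthetic suite therefore demonstrates correctness of
the computation and recoverability of planted signal under the stated
assumptions — not performance on real pharmacovigilance data.

## Numerical and design choices

* **IC formula.** The intrinsic IC above is the unique simple form
  consistent with a structure-only measure that is 1 at leaves, 0 at an
  all-dominating root, and decreasing in descendant count. The base of the
  logarithm cancels; "children" are counted transitively by default with a
  direct mode as a switch.
* **Tie-breaks.** MICA ties and best-match partner ties resolve to the
  lexicographically smallest term id; the top-`k` selection sorts by
  (score descending, term id ascending). All outputs are therefore
  deterministic and the reported contributing side effects reproducible.
* **Degenerate inputs.** A one-term ontology gets IC 1 with a warning
  (`ln(1)` denominator); a forest without a shared root yields a flagged
  zero-IC MICA sentinel; single-annotation genes are zeroed with a warning
  under the literal `ln(n)` scaling; an all-zero scored set normalizes to 0
  rather than dividing by zero.
* **Thresholds.** `threshold_at_precision()` returns the lowest distinct
  score whose precision meets the target (used to split associations into
  high and low scoring at the precision-10% operating point), with a
  flagged sentinel when the target is unreachable.
* **Problem sizes.** The shipped tests and the acceptance script run
  studies of 40-156 terms, 20-50 genes and 12-30 drugs, with 20-seed
  replication for the paired top-20-versus-uncorrected comparison; these
  sizes were chosen so every oracle comparison can be exhaustive while the
  whole suite stays interactive.

## Known limitations

* The self-match and J = 0 cap conventions are reconstructions at corners
  the published description leaves open; both are isolated behind documented
  functions and the alternative (literal) behaviour of the corpus-level
  weight is preserved and tested.
* The burden and gene-information corrections are heuristics tuned for
  large, heterogeneous corpora; on small homogeneous synthetic studies they
  mostly add between-entity variance, which is why the generator keeps
  profile sizes homogeneous by default.
* `score_all_pairs()` materialises the full drug-by-gene table; it is
  intended for corpora up to a few thousand entities, not for the
  multi-million-pair regime, though the per-pair arithmetic is the same.
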