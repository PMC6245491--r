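---
title: "Constructing single-chromosome ancestry-informative SNP panels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Constructing single-chromosome ancestry-informative SNP panels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Biogeographical ancestry can be inferred from genotypes at ancestry-informative
markers (AIMs): SNPs whose allele distributions differ between populations.
Continental ancestry is comparatively easy; distinguishing closely related
sub-populations of the same continent with a *small* panel is hard. `chromaim`
implements a three-stage funnel that reduces the SNPs of a single chromosome to
a small non-redundant panel, and evaluates the panel with a softmax classifier
at the continental (5-class) and pairwise sub-population (binary) levels.

## The data model

Input is a VCF of diploid SNP genotypes plus a table mapping each sample to one
of the sub-populations and one of five continental groups. Genotypes are kept
as **ordered** nucleotide pairs — 16 possible symbols AA, AC, ..., TT, encoded
1..16 — because the pipeline never needs to decide whether (A,G) and (G,A) are
"the same" genotype; treating the GT field order as part of the symbol keeps
every operation deterministic and reversible. A configuration-free alternative
(canonicalising pairs) would only merge symbols and can be emulated by
recoding the input.

Three cleaning rules remove records that cannot carry usable signal: a
multi-nucleotide reference allele, an alternate allele containing the reference
nucleotide, and records where every individual is reference-homozygous. Rule 2
is read literally: any ALT string containing the REF nucleotide disqualifies
the record; the rules are applied in order 1 → 2 → 3, and removal counts are
reported per rule among the survivors of the previous rule. Records carrying
indel alleles or missing genotypes (`./.`) are already dropped at parse time
with logged counts — every downstream formula assumes complete diploid
single-nucleotide data, and the method's sources are silent on missingness, so
exclusion is the conservative choice.

After cleaning, a per-SNP mask removes an individual's allele information when
*both* nucleotides equal the reference. Heterozygotes containing the reference
nucleotide are retained. SNPs whose retained individuals all share one symbol
form the *similarity set*; the rest form the *dissimilarity set*, and only the
latter continues, since within-similarity SNPs carry no between-individual
contrast.

## Stage 1 — parameter-based selection

For SNP $i$ and population $p$, over training individuals only:

$$\alpha = \frac{n_p^i}{n_p}, \qquad \beta = \frac{f_p^i}{n_p^i}$$

with $n_p$ the training size of $p$, $n_p^i$ the number of its members
retained at SNP $i$, and $f_p^i$ the count of the modal genotype symbol.
A SNP is *important for $p$* when $\alpha\beta = 1$: every member of $p$ is
retained and all share one symbol. The union of the per-population selections
is then stripped of SNPs whose retained training individuals, pooled across
populations, share a single symbol (uniform SNPs distinguish nothing).
$\beta$ is undefined when $n_p^i = 0$; such SNPs are simply not important for
$p$. Modal ties do not affect $\beta$, so no tie-break is needed.

One 80/20 split, stratified by population with per-stratum floor rounding and
a single seed, is shared by Stage 1 and every later classification step.
Stratification guarantees that each population appears on both sides;
sharing one split prevents test individuals from leaking into selection.

## Stage 2 — DBSCAN outlier selection

Stage-1 survivors are encoded as rows of the data matrix $D$ (one column per
training sample, entries 0–16, 0 for masked). DBSCAN with Euclidean distance,
`min_pts = 2` and radius `eps = 0.1` clusters SNPs with similar genotype
profiles; the *outliers* — SNPs no dense group absorbs — are kept as
candidates with seemingly unique ancestry information. Design choices worth
stating:

* The neighbourhood count includes the point itself, the common textbook
  convention; with `min_pts = 2` a point is core iff it has one distinct
  neighbour within `eps`.
* Masked entries participate in the distance like any coordinate (code 0).
  The matrix is not normalised; with integer codes and `eps < 1` only exact
  duplicate rows can cluster, so the default operating point keeps every
  distinct genotype profile and removes exact duplicates. A radius grid scan
  (`scan_epsilon`) is provided for choosing `eps` empirically by downstream
  multi-class accuracy, ties going to the smaller radius.
* Border points are assigned to the first-discovered cluster; discovery order
  is input order, making labels deterministic. At `min_pts = 2` no border
  points exist (any point within `eps` of another is itself core), so the
  partition is also order-invariant at the default operating point.
* Distances are computed exactly from the full distance matrix; memory is
  quadratic in the number of Stage-1 SNPs, which is adequate at the scales
  this package targets.

## Stage 3 — performance correlation pruning

Each candidate SNP is scored alone as a single-feature multi-population
classifier using its *allele-context* feature (0, 1 or 2 non-reference
nucleotides). Row $i$ of the performance matrix $X$ is
$[x_1^{(i)}\,x_2^{(i)}\cdots x_6^{(i)}]$: overall multi-population test
accuracy, then for each continent $j$ the percentage of its test individuals
whose *predicted population belongs to continent $j$*. The classifier is
population-level (26 classes); continent-level credit is used for the five
continent elements because they feed the continent-profile correlation below.
A SNP whose training feature is constant degrades gracefully to a bias-only
fit (majority-class prediction) and is logged.

Redundancy between SNPs $i$ and $k$ is the Pearson correlation of their five
continent elements (undefined for zero-variance profiles). The greedy scan
ranks SNPs by the chosen key — overall accuracy for continental panels, the
continent-$j$ element for pairwise panels within continent $j$ — and keeps a
SNP iff its correlation with *every* already-kept SNP is at most the threshold
`th`. Ranking ties break by genomic position ascending; undefined correlations
never prune. A threshold scan (default grid 0.10–0.99, step 0.01) reports the
accuracy/size trade-off and the best panel under a size cap (default 206).
Note that panel size is *not* guaranteed monotone in `th`: admitting one extra
highly-ranked SNP at a larger threshold can block many lower-ranked SNPs
through its own correlations; the scan table reports whatever sizes result.

## The classifier

All evaluations use softmax (multinomial logistic) regression — exactly the
output-layer equations $z_i = \sum_j w_{ij}x_j + b_i$, $t_i = e^{z_i}$,
$a_i = t_i/\sum_k t_k$ — with the argmax label, ties broken by class order.
Training minimises multinomial cross-entropy with a small ridge penalty by
full-batch gradient descent from zero initialisation (learning rate 0.1,
500 epochs, L2 10⁻⁴ by default), so fitting is deterministic without any
random seed. Features are the raw allele-context integers; no standardisation.
Probabilities are computed with max-subtraction, which is mathematically
identical (softmax is shift-invariant) and overflow-safe. The inner descent
loop is compiled (RcppArmadillo) since the single-SNP scoring step calls it
thousands of times; a case-weight argument lets identical (feature, label)
rows be collapsed with multiplicities, which is how single-SNP fits are run.
With two classes the model reduces exactly to binary logistic regression.

## The simulator

`simulate_population()` draws a hierarchical Balding–Nichols model: ancestral
alternate-allele frequency $p \sim U(0.05, 0.95)$ per SNP; continent
frequencies $\sim \mathrm{Beta}\!\big(p\tfrac{1-F_c}{F_c},
(1-p)\tfrac{1-F_c}{F_c}\big)$; sub-population frequencies drawn the same way
around their continent frequency with $F_s$; genotypes are two independent
allele draws. Defaults describe the study conditions used throughout the
package's tests: 26 sub-populations in 5 continents (4/5/5/5/7), 20 samples
each, 5,000 SNPs, $F_c = 0.15$, $F_s = 0.05$, seed 1 — small enough to run in
minutes on one CPU while preserving the qualitative structure of a real
26-population panel. SNPs are independent (no linkage disequilibrium): the
selection method treats SNPs marginally except through performance-profile
correlation, so LD would only make simulated panels optimistic about
independence, not change correctness. No admixed individuals are generated.

Two planted fixed-difference AIMs per population provide ground truth. Each
AIM makes its target population homozygous-ALT and one deterministic
*contrast population* — the first sub-population of the next continent —
uniformly heterozygous (REF, ALT); everyone else is reference-homozygous. The
contrast population is what keeps a planted AIM observable by the pipeline: a
marker whose only retained individuals all share one symbol would fall into
the similarity set and be discarded before Stage 1, and would equally be
removed by the pooled-uniformity filter. With the contrast population the AIM
is guaranteed to reach Stage 2 under any train/test split while the target
population still attains $\alpha = \beta = 1$. AIMs within one population
cycle through distinct (REF, ALT) pairs so that their Stage-2 code rows are
distinct — identical rows would cluster as duplicates and leave the outlier
set. A Weir–Cockerham $F_{st}$ estimator (ratio of averages across loci) is
included to validate that simulated differentiation matches the configured
$F_c$; it is a simulator check, not part of the selection method.

What passing tests on simulated data do **not** show: behaviour under linkage
disequilibrium, genotyping error, missingness, or admixture — all absent from
the generator. Real-data panel sizes and accuracies depend on those features
and on the vastly larger SNP count of a real chromosome.

## Numerical and degenerate-input choices

* Correlations are exact Pearson computations; the greedy scan treats `NA`
  (zero-variance) correlations as non-redundant because the coefficient is
  undefined and discarding a SNP on an undefined quantity is arbitrary.
* `make_split` errors on populations with fewer than 2 samples (both sides of
  the split must be populated); training errors when a class is absent.
* An empty Stage-1 selection or an outlier-free DBSCAN result aborts the
  pipeline with the stage name; artifacts of completed stages remain.
* All pipeline artifacts are plain text written in binary mode with fixed
  formatting, so identical configurations reproduce byte-identical output;
  the cleaned VCF is written uncompressed for this reason.
* The pipeline derives every stage seed from a single global seed (split seed
  = global seed); the classifier itself is deterministic.

## Scale of the shipped checks

The package's own test suite exercises the full funnel at the default
simulation scale above; clustering and pruning are additionally verified
against brute-force reference implementations on randomized instances of up
to 200 points / 60 SNPs, sizes at which exhaustive checking is itself cheap
and trustworthy. `scripts/acceptance.R` re-runs the default-scale pipeline
end to end and records the headline quantities it computes.

## Known limitations

* The selection stages assume complete diploid data; cohorts with substantial
  missingness would lose many records at parse time.
* DBSCAN's quadratic distance matrix bounds the practical Stage-1 set to a
  few tens of thousands of SNPs in memory.
* Greedy correlation pruning is order-dependent and not an optimal-subset
  search; it reproduces the intended procedure, not a global optimum.
* With the default integer encoding and `eps < 1`, Stage 2 removes only
  duplicate genotype profiles; stronger pruning requires scanning `eps`
  (or normalising the code matrix, deliberately not done by default).
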