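---
title: "Haploblock genotyping in polyploids: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Haploblock genotyping in polyploids: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

SNP arrays report, for every bi-allelic marker and individual, an allele
*dosage*: in a tetraploid, an integer between 0 and 4. Dosages are far less
informative than the underlying haplotypes. If a handful of tightly linked
SNPs — a *haploblock* — is treated as a single locus, its haplotypes act as
the alleles of a multi-allelic marker, which is far more useful for linkage
mapping, QTL detection and GWAS in polyploid crops. The difficulty is that
an observed dosage vector is compatible with many combinations of
haplotypes, and the number of combinations grows explosively: a tetraploid
block of 6 markers admits $2^6 = 64$ haplotypes and
$\binom{64+3}{4} = 766{,}480$ haplotype combinations.

`haplodose` reconstructs, for every individual, the multiset of `ploidy`
haplotypes (the *haplotype combination*, whose per-haplotype dosages sum to
the ploidy) that produced its observed marker dosages. Its distinguishing
feature is the use of full-sib (FS) families among the samples: offspring
segregation ratios sharply constrain the parental haplotype combinations,
and solved parents in turn resolve their offspring. The approach is a
decision procedure with explicit thresholds — a puzzle solved stage by
stage — rather than a global likelihood optimization; an individual is
only assigned when a single solution remains, so the output trades
completeness for a very low error rate.

## Encodings and exhaustive enumeration

A haplotype over `nmrk` markers is encoded as an integer in
$[0, 2^{nmrk})$; bit $j$ (bit 0 = first marker of the block) is the allele
at marker $j+1$. Fully observed dosage vectors are indexed by the
mixed-radix key $\sum_j g_j (p+1)^j$, which is bijective and, being
additive, lets the dosage key of a progeny genotype be computed as the sum
of its two gamete keys.

All combinations compatible with a dosage vector are enumerated exactly,
either by lookup in a precomputed table covering all
$(p+1)^{nmrk}$ dosage keys, or by a meet-in-the-middle join of
half-multisets for one vector at a time. Both routes return the identical,
lexicographically ordered solution list, so every downstream tie-break is
reproducible. Missing dosages are handled by taking the union over all
possible values of the missing entries, which guarantees that masking a
dosage never removes solutions. Tables are capped by default at 8 markers
for tetraploids and 6 for hexaploids (the tetraploid 8-marker space holds
about $1.8\times 10^8$ combinations); the pipeline builds tables only for
block sizes whose spaces hold at most $10^5$ combinations and otherwise
enumerates per dosage vector, which profiling showed to be the better
trade-off.

## Stage 1: a parsimonious haplotype inventory

Without family information, the only leverage is parsimony. Step (a)
collects haplotypes *forced* by individuals: a haplotype contained in
every solution of an individual's dosage vector is certainly present
(homozygous individuals force one haplotype; a single intermediate dosage
forces two). Forced haplotypes occurring in at least `min_frac` (default
10%) of the individuals with any data in the block enter the inventory,
together with any a-priori known haplotypes, which bypass the threshold.
Step (b) then asks, for each unexplained individual, which haplotypes are
required by *all* of its solutions that introduce the fewest unknown
haplotypes; haplotypes required in at least 10% of individuals are added,
and step (b) is iterated to a fixpoint. The iteration operates on a finite
lattice but is not monotone, so it can cycle; cycles are detected by
hashing the inventory, and on a cycle the result of the first step-(b)
execution — the one anchored in the near-certain step-(a) haplotypes — is
kept (50 iterations is a hard stop). The 10% denominator is the number of
individuals with at least one non-missing dosage in the block; individuals
with no data are excluded throughout.

An individual is assigned only when exactly one of its solutions uses
known haplotypes exclusively. Stage 1's assignments are provisional — the
pipeline uses only its inventory to seed Stage 2.

## Stage 2: full-sib families

Families linked through shared parents are solved jointly as one group.
For one family, every pair of parental haplotype combinations compatible
with the parental dosage vectors predicts an offspring segregation:

* **Gamete model.** A gamete is a uniform random subset of `ploidy`/2 of
  the parental homologs. With probability `alpha` (default 0.025) a
  *double reduction* occurs: one uniformly chosen homolog is duplicated
  and the remaining gamete slots are filled from the other homologs (for
  tetraploids the DR gamete is just the duplicated homolog twice; for
  hexaploids one of the other five homologs joins it). This
  duplicated-homolog model is the simplest consistent with a single DR
  frequency parameter; diploids have single-homolog gametes and no DR.
* **Dosage-error model.** Independently per marker, a true dosage $d$ is
  observed as $d$ with probability $1-\epsilon$ (default
  $\epsilon = 0.025$) and as an adjacent dosage otherwise, split equally
  between $d\pm1$ and folded inward at the boundaries. Array dosage errors
  are overwhelmingly off-by-one, which motivates restricting the support
  to adjacent dosages.
* **Goodness of fit.** Observed counts of fully genotyped offspring are
  compared with the expected class probabilities by a Pearson chi-squared
  test. Expected classes with fewer than one expected individual are
  pooled with all observed-but-unexpected classes into a single category;
  degrees of freedom are the pooled category count minus one, floored at
  one. When the pooled category has zero expectation but non-zero
  observations, the P value is 0. Only classes whose expected count can
  reach one individual need exact probabilities (a class at error distance
  $d$ from every error-free class has probability at most $\epsilon^d$),
  which keeps the scoring loop small; the compiled kernel and the plain-R
  reference implementation are tested to agree to $10^{-9}$.

Parental pairs built from inventory haplotypes only are scored first; if
none is acceptable, all pairs compatible with the parental dosages are
scored. Pairs survive when their P value is at least `p_ratio` (0.001)
times the best pair's P value and above the absolute floor `p_min`
($10^{-8}$); the floor is applied together with the ratio, after all pairs
are scored. A family is *demoted* to unrelated material — for that block
only — when a parent has missing dosages, when the pair count exceeds
`max_parent_combs` (150,000), or when no pair passes the filters.

Within a group, incompatible candidates are pruned iteratively: for every
parent and candidate combination, the number of FS individuals in families
it fails to explain is tallied, and the worst offender is removed from all
its families' candidate lists (ties broken by parent id, then
lexicographically, for reproducibility); a family losing its last
candidate is demoted together with its non-shared parent. The surviving
consistent solution sets are ranked by the product of family P values.
Only parents that occur in more than one family couple the choices, so the
optimizer enumerates shared-parent assignments and lets each family take
its best compatible candidate conditionally — an exact factorization that
avoids expanding ties combinatorially. Under co-optimal ties, an
individual is assigned only if its combination is identical under every
co-optimal solution.

Offspring of a solved family are assigned when exactly one progeny class
matches their genotype. Offspring with missing dosages are imputed when
the non-missing markers single out one family-possible genotype; all of a
family's imputations are rejected if half or more of the family would be
imputed or if the chi-squared P value including the imputed offspring
drops below `impute_p_ratio` (0.1) times the P value without them.

## Stage 3: unrelated material

Everything outside solved families — unrelated individuals, demoted
families, and their non-shared parents, pooled exactly once per block —
is run through the Stage-1 procedure again, seeded with the haplotypes of
the solved parents plus any a-priori haplotypes. If unexplained
individuals remain, one relaxed step-(b) cycle runs with the threshold
lowered to `max(1% of individuals, 2)`; it is accepted only if it strictly
increases the number of uniquely solved individuals and no previously
unique individual loses uniqueness, so accepting it never decreases the
assigned count. The relaxed cycle runs at most once. Individuals of
*solved* families that remained unassigned are not re-analyzed here: their
family context already constrained them, and reinterpreting them as
unrelated would invite contradictory assignments. With no (or ignored)
families the pipeline goes directly to this stage.

## Pedigree checking and summaries

The inference itself uses no pedigree beyond the FS specification. Given a
pedigree, `check_parent_offspring()` classifies each offspring with at
least one assigned parent as `match` (its combination splits into two
gametes producible by the respective parents — DR gametes count when
`alpha > 0`), `conflict`, or `non_checkable`.
`summarize_haplotyping()` reports, per block and per category of material
(FS individuals, FS parents, other), the percentage fully genotyped,
haplotyped, checkable, and matching. Because the literature is ambiguous
about whether "mean % haplotyped" averages over blocks or pools over
individuals, the overall table reports both (`mean_pct_haplotyped` and
`pooled_pct_haplotyped`).

## The simulator

`simulate_population()` emulates the validation designs: tetraploid
populations with FS families, haploblocks of 3–7 markers at a single map
position (no recombination within blocks), and founders drawn from
per-population pools. A pool holds up to `n_founder_haps` (default 16,
capped at $2^{nmrk}$) distinct haplotypes with geometrically decaying
frequencies (`pool_decay` 0.75); optional founder clusters draw from a
random 60% subset of their population's pool, mimicking groups of related
founders, and the two-population design uses two independent pools. These
defaults were chosen once to produce the haplotype diversity of a diverse
outbred breeding panel — roughly 8–16 distinct haplotypes per block
depending on block size, and individual SNP heterozygosity around
75–85% — and are not meant to be tuned per run; the validation designs
assume array-quality data, so the presets default to `epsilon_sim = 0`
and `missing_rate = 0`, with both rates available for harder scenarios. Two presets are provided: `sim_design_shared_parent()`
(nine families of 50 sharing one parent, ten parents in three clusters)
and `sim_design_two_populations()` (two families of 50 sharing one parent,
parents from two random-mating populations, plus 50 unrelated individuals
from each).

The simulator emulates meioses with the same gamete model used by the
inference. What passing recovery tests therefore demonstrate is the
correctness and power of the segregation machinery under its own genetic
model, not robustness to meiotic behaviour outside it (preferential
pairing, within-block recombination, genotype-calling artifacts beyond
±1 errors are all absent). Scoring counts an assignment as correct only
when it equals the true combination as a multiset.

## Numerical and design choices

* All candidate orderings (solution lists, parental pairs, group
  tie-breaks) are lexicographic, making every run byte-reproducible;
  block order never affects per-block results.
* P-value products over families are compared in log space with an
  absolute tolerance of $10^{-9}$ to make co-optimality robust to
  round-off.
* The validation runs use the full design sizes (460 individuals over 60
  blocks for the multi-family panel; 203 over 60 for the mixed design)
  with blocks of 3–6 markers; 7-marker
  blocks behave identically but admit so many parental combinations that
  families routinely exceed the 150,000-pair cap and are demoted rather
  than solved, so they add run time without adding signal.
* Degenerate inputs: individuals with all dosages missing are never
  assigned; blocks over the capacity limit fail individually while other
  blocks proceed; a family whose offspring are all incompletely genotyped
  cannot be tested and is demoted.

## Known limitations

Inheritance is fully polysomic with a single DR parameter — preferential
pairing and mixed inheritance systems are not modelled. Haploblocks are
phased independently; no linkage between blocks is used, and no long-range
phasing is attempted. All individuals must share one even ploidy. The
error model considers ±1 dosage errors only, which is appropriate for
array dosages but optimistic for sequencing-derived dosages.
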