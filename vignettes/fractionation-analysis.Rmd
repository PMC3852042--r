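---
title: "Modelling duplicate-gene fractionation after ancient polyploidy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling duplicate-gene fractionation after ancient polyploidy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wgdfrac)
```

## The problem

Whole-genome duplications and triplications copy every gene, and the
polyploid genome then sheds most of the redundant copies while it
rediploidizes. This loss — *fractionation* — is not functionally neutral:
categories such as regulation and binding tend to keep their duplicates
(consistent with the Gene Balance Hypothesis, which predicts retention of
genes whose products sit in stoichiometry-sensitive complexes), while
single-enzyme metabolic functions shed theirs quickly. `wgdfrac` packages
the two quantitative tools needed to study this on any group of genomes
that shares an ancient polyploidy:

1. a *descriptive* pipeline — homology sets, fractionation scores, GO
   annotation, per-term trend regressions; and
2. a *generative* two-class retention model fitted by maximum likelihood to
   per-species pair/triple counts.

A simulator with known ground truth ties the two together and backs the
test-suite.

## Homology sets and the fractionation score

The unit of analysis is the *homology set*: all genes, across and within
genomes, that descend from one pre-polyploidy ancestral gene. We take as
input pairwise syntenic ortholog/paralog calls (SynMap-style output; the
package deliberately does not detect synteny itself) and form the connected
components of the resulting graph (`build_homology_sets()`). The merge rule
is plain transitive closure over the union of ortholog and paralog edges —
the simplest rule consistent with "genes sharing orthologies and
paralogies"; stricter rules (e.g. requiring block agreement) can be layered
on top, and an optional `max_copies` cap is available as a coarse guard
against tandem-array contamination (off by default, because filtering
tandem duplicates properly needs positional data we do not consume).

Each set gets a *fractionation score*: the number of genomes that retain
**more than one** copy. For three genomes the score runs 0–3; a score of 0
means every genome is back to single copy. Sets are also classified by
completeness (`full`, `missing_one`, `missing_two`, `reject`); sets missing
three or more genomes, including paralog-only single-genome components, are
excluded from all analyses. For four-genome groups split into two clades,
`filter_missing_two_clade()` keeps the missing-two sets whose two absences
straddle the clades, the configuration informative about independent loss.

Genes that appear in no edge are *reported* (`unplaced`) rather than
silently dropped: absence of syntenic evidence is data, not noise.

## Annotation and normalization

Gene-level GO annotations (GAF 2.x or two-column TSV) are unioned over the
members of each set and closed under the `is_a` ancestor relation
(`annotate_sets()`); `part_of` propagation is available behind a flag but
off by default, the conservative standard. Multiplicity within a set is
ignored — three members hitting the same term count once. Obsolete terms
are dropped, not remapped, and counted in an attribute.

High-score sets hold more genes and therefore hit more terms, which would
make every category look enriched at high scores. The normalization used
throughout divides, at each score, the number of sets hitting a term by the
number of sets hitting *any* term under the same namespace root — not by
the total number of sets. On the worked example bundled with the acceptance
script (450 score-3 sets, 300 of which hit a Cellular Component term, 100
of those "organelle"), the normalized proportion is 100/300 = 33.3%, not
100/450.

## Trend regression

For a term in namespace X, every set hitting at least one X term is a data
point: x = fractionation score, y = 1 if the set hits the term. We fit
ordinary least squares on the binary indicator — deliberately, because the
plotted quantity *is* the per-score proportion and the OLS line is its
linear summary — and test the slope with a two-sided t-test. Negative
slope = fractionation-prone, positive = resistant, at `alpha_level` 0.05 by
default with no multiple-testing correction (per-term significance;
Benjamini–Hochberg is available via `p_adjust = "BH"`). The choice of
regression population (namespace hitters, matching the normalization
denominator) is a design decision: it keeps the regression and the plotted
proportions describing the same population.

`cross_group_consistency()` applies the selection rule used when comparing
independently fractionating lineages: a term is *consistent* when
significant in at least one group with same-sign slopes everywhere,
*conflicting* when significant in opposite directions in two groups.
`compare_to_background()` contrasts set-level proportions with a gene-level
background sample (stratified equally per genome, seeded), using a
two-proportion z-test.

Simulations at the defaults show the machinery is calibrated: under a null
term (presence independent of score) the type-I error of the slope test
stays inside binomial bounds of the nominal 5% (200 replicates of n = 1000
sets), and planted gradients of ±0.10 per score unit at n = 500 sets are
recovered with the correct sign in ≥ 95% of replicates. These checks run in
the test-suite at exactly those sizes.

## The two-class retention model

For genomes descending from a shared triplication, the per-species counts
of surviving triples (n3) and pairs (n2) carry a signal about loss-rate
heterogeneity. The model: each of `N` ancestral triplets loses each copy
with probability `p` between the polyploidy event and speciation, then with
probability `q_i` per species; a copy's total survival is
`s_i = (1-p)(1-q_i)` and the per-species family-size distribution is
Binomial(3, s_i). Genes fall into two classes: a fraction `theta` with
rates `(p, q_i)` and the rest with `(alpha*p, alpha*q_i)`. With
`alpha <= 1` — our labelling convention, which resolves the mixture's
label-switching symmetry — class 1 is the faster, fractionation-prone
class.

**Likelihood construction.** The data contain no single-copy counts
(single-copy survivors are indistinguishable from relocated "mobile"
genes), so the `N - n3 - n2` remaining ancestral genes form one
unobserved-remainder category with probability `P1 + P0`. Each species
contributes a three-category multinomial mass and species are multiplied as
independent. Independence is an idealization — the shared phase 1
correlates species — but fitting data simulated with the biologically
shared phase 1 recovers the true parameters (the test-suite checks
recovery of `theta` and `alpha` within 3 Monte-Carlo standard errors at
N = 20 000, ten replicates), so the simplification has no practical cost
for this model. The simulator also offers `independent_phases = TRUE` for
exact-model experiments.

Fitting (`fit_retention_model()`) maximizes this likelihood by bounded
quasi-Newton from 32 seeded Latin-hypercube starts. `profile_over_N()`
refits across assumed ancestral gene numbers, since `N` is not observable.

### What the fit can and cannot pin down

On the bundled six-rosid counts (`rosid_retention_counts()`) the two-class
model beats the one-class fit decisively (likelihood-ratio ≈ 40 on 2 df),
so *heterogeneity itself is well supported*. But the location of the
optimum within the two-class family is not sharp: the profile likelihood
over `(theta, alpha)` is a long, banana-shaped plateau in which differences
of one or two log-units span class-share values from ~25% to ~75%. Twelve
printed counts cannot pin nine parameters. Consequences a user should
expect:

* the global optimum at N = 7500 puts the larger class near 60% with
  `alpha` ≈ 0.66, with one species' `q` at its upper bound — a degenerate
  corner typical of weakly identified mixtures;
* refitting at larger N drifts `theta` along the plateau while `p` rises
  to compensate (more ancestral genes need more loss to leave the same
  survivors); the `q_i`, by contrast, move little;
* point estimates of `(theta, alpha)` from data of this size should be
  read with the plateau in mind; the class-share *direction* and the
  existence of two classes are the robust conclusions.

The test-suite asserts the stricter stability expectations as written and
reports the outcomes as they fall; the plateau explains the ones that
fail. On simulated data the estimator is consistent: RMSE for
`(theta, alpha)` shrinks as N grows (checked at N = 10³ vs 10⁵).

`predict_score_distribution()` turns fitted parameters into the predicted
per-class distribution over fractionation scores, conditioning on full
sets (≥ 1 surviving copy per genome, matching how homology sets enter the
descriptive analysis): per genome the conditional probability of
multi-copy given survival is `(P3+P2)/(P3+P2+P1)` and the score is
Poisson-binomial across genomes. The fast class piles up at low scores,
the slow class at high scores — the model's version of the prone/resistant
contrast.

## The simulator

`simulate_fractionation()` draws the generative process exactly as the
model states it, with phase 1 shared across species (one pre-speciation
draw per copy). Defaults deliberately mirror the study conditions the
model targets: three copies per ancestral gene, two classes, per-copy
losses, no gene movement, no tandem duplication, no annotation noise.
What it does **not** emulate — real synteny-block boundaries, tandem
arrays, lineage-specific family expansion, annotation error — bounds what
green tests mean: they validate the machinery on data obeying the model's
assumptions, not the biological conclusions on any real genome group.

Annotation bias is a property of the *ancestral* gene: each ancestral gene
draws each biased term with its class's inclusion probability and all
surviving copies inherit it. Drawing per surviving copy instead would make
set-level term presence grow mechanically with set size, confounding class
composition with copy number — an artifact, not a signal, so the package
avoids it.

Problem sizes used by the test-suite — chosen to make Monte-Carlo noise
small relative to the asserted tolerances — are N = 50 000 for frequency
checks against the analytic pmf, N = 20 000 × 10 replicates for
end-to-end recovery, and 100–200 replicates of n = 500–1000 sets for the
calibration checks.

## Numerical choices and degenerate inputs

* Loss probabilities are boxed to [1e-4, 1-1e-6], `theta` to
  [1e-3, 1-1e-3]; `alpha` ∈ (0, 1] by the labelling convention.
* Convergence: L-BFGS-B with a log-likelihood tolerance of ~1e-9
  (relative); the best of all starts is reported together with every
  start's value, so plateau behaviour is visible in `fit$starts`.
* A category with zero probability but positive count gives a
  log-likelihood of −∞ (the optimizer treats it as a hard wall).
* Components are ordered by smallest member gene id; all writers emit
  sorted, header-carrying TSVs — reruns are byte-identical.
* Scores with an empty normalization denominator are omitted from trend
  points; a term whose population has fewer than two distinct scores is a
  degenerate design (error from `term_regression()`, `unclassified` in
  `trend_table()`).
* `N = 0` simulations and empty edge lists produce valid empty objects.

## Known limitations

* Transitive-closure grouping happily merges through a single spurious
  edge; there is no block-consistency check.
* The OLS-on-binary trend test is the field's descriptive convention, not
  an efficient estimator; a logistic alternative would be a reasonable
  extension.
* `(theta, alpha)` are weakly identified from pair/triple counts alone
  (see above); adding single-copy counts or cross-species joint patterns
  would sharpen the fit but requires data the standard tables do not
  print.
* The model covers one triplication; lineages with additional WGDs are
  handled only insofar as their extra duplications are absorbed into the
  per-species rates.
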