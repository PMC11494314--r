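---
title: "Coincidence information analysis of TCR specificity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Coincidence information analysis of TCR specificity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tcrinfo)
```

## The model

A T cell receptor (TCR) feature is a random variable $X$ mapping receptor
sequences to a discrete set of categories: a V or J gene choice, a CDR3
amino acid string, a chain (the product of its V, J and CDR3), a physical
property such as CDR3 length or net charge, a bag-of-words vector, or a
CDR3 remapped through a reduced amino acid alphabet. The central quantity
is the probability of coincidence

$$p_C[X] = \sum_x P(x)^2,$$

the probability that two independent draws agree (Simpson's index;
$1/p_C$ is the effective number of distinct values). Its negative base-2
logarithm is the order-2 Rényi, or collision, entropy $H_2[X] = -\log_2
p_C[X]$. Collision entropy is attractive for repertoire data because
$p_C$ has an unbiased small-sample estimator: the fraction of unordered
clone pairs that coincide, $\sum_x n_x(n_x-1)/(N(N-1))$. Pairs are
counted over distinct clones — independently recombined lineages — never
over reads; `clone_count` is metadata unless count-weighting is
explicitly requested.

Conditional coincidence probabilities average per-group values with
$\rho_2$ weights,

$$p_C[X|Y] = \sum_y \rho_2(y)\, p_C[X|y], \qquad
  \rho_2(y) = \frac{P(y)^2}{\sum_y P(y)^2},$$

the unique weighting that preserves additivity
$H_2[X,Y] = H_2[X] + H_2[Y|X]$ and hence makes the mutual-information
analogue symmetric. The information a feature carries about epitope
specificity $\Pi$ — its *relevancy* — is

$$I_2(X,\Pi) = \log_2 \frac{p_C[X|\Pi]}{p_C[X]},$$

with $p_C[X|\Pi]$ estimated over epitope-specific groups and $p_C[X]$
over a background repertoire representing unselected recombination
output. Conditional relevancy $I_2(X,\Pi|Y) = H_2[X|Y] - H_2[X|\Pi,Y]$
measures what $X$ still adds once $Y$ is known; interaction information
$I_{2,int}(X,Y|\Pi) = I_2([X,Y],\Pi) - I_2(X,\Pi) - I_2(Y,\Pi)$ is
positive for synergy and negative for redundancy. Local variants
($i_2(X,\pi)$ etc.) restrict to a single epitope.

Bits buy classification accuracy: matching a query to an annotated
reference in a feature worth $I_2$ bits multiplies the prior odds that
the query is specific by $2^{I_2}$, so a posterior odds target $T$
requires a prior probability of at least $T 2^{-I_2}/(1 + T 2^{-I_2})$.
The same calculus extends to fuzzy matches through the near-coincidence
probability $p_C[X](\Delta)$, the probability that two draws are at
Levenshtein distance exactly $\Delta$, and its mutual information
$I_2^\Delta = \log_2 p_C[X|\Pi](\Delta)/p_C[X](\Delta)$.

## Estimation choices

* **Plug-in log ratios.** Although the pair-counting $\hat p_C$ is
  unbiased, its logarithm is not; relevancies are plug-in log ratios
  without small-sample bias correction. Uncertainty is quantified by a
  clone-level bootstrap (default 200 replicates, percentile intervals,
  resampling each epitope group and the background independently).
* **Zero coincidences.** $\hat p_C = 0$ leaves the entropy unresolved by
  the sample; affected scores are returned as `NA` with a diagnostic
  rather than infinite. Estimating full-TCR relevancy on real data
  requires epitope groups with at least one full coincidence.
* **Epitope weights.** $P(\pi)$ entering the $\rho_2$ average defaults
  to uniform over epitope groups; `weights = "size"` uses group clone
  counts; explicit vectors are accepted. Groups with fewer than two
  usable records are dropped and the weights renormalized.
* **Missing data.** Exclusion is per feature, not per record, so
  single-chain features use all available records. A product feature is
  missing where any component is; for interaction information all three
  relevancies are computed on the shared subset where both features are
  present, keeping the difference like-for-like.
* **Feature hashing.** Values are compared by exact equality of
  canonical encodings (product components joined by a non-printing
  separator; bag-of-words as the sorted letter multiset). Fractional
  net-charge conventions are binned to one decimal before hashing; the
  histidine weight defaults to 0.
* **Distance binning.** Near-coincidence probabilities bin distances
  exactly ($=\Delta$), matching the Kronecker-delta definition; a
  cumulative ($\le\Delta$) option exists but is non-default. Pairs of
  identical values form the $\Delta = 0$ class; self-pairs are excluded.
  Results are independent of record order.
* **The chain feature.** The "alpha chain" (and "beta chain") feature is
  defined as the product of V gene, J gene and CDR3 rather than a
  reconstructed full amino acid sequence; at gene-level resolution the
  two coincide whenever the reconstruction is injective, and the product
  form needs no germline reference.

## Reduced alphabets

`remap()` translates CDR3s through a surjective map of the 20 amino
acids onto $k$ group symbols (canonically labelled by each group's
lexicographically first member). Property alphabets come from
complete-linkage hierarchical clustering of a one-dimensional
biophysical scale — complete linkage on a 1-D scale yields contiguous
value intervals, i.e. grouping "by property". Five literature scales
ship as configuration data (`aa_property_scales()`): Grantham polarity,
Eisenberg–McLachlan solvation free energy, Fauchère normalized van der
Waals volume, Levitt side-chain radius of gyration, and Chothia
tripeptide accessible surface area.

`greedy_optimal_alphabet()` searches for an information-optimal
alphabet agglomeratively: starting from 20 singletons it repeatedly
merges the pair of groups whose merge maximizes the relevancy of the
remapped feature, with lexicographic tie-breaking, until $k$ groups
remain. The agglomerative direction and tie-break are this package's
choices; the search strategy is deliberately simple and pluggable. At
$k = 20$ the retained information equals the unreduced CDR3 relevancy;
at $k = 1$ only sequence length survives.

A caveat worth stating precisely: coarse-graining is *not* guaranteed to
reduce relevancy for arbitrary pairs of specific and background
distributions, because both the numerator and denominator of the
coincidence ratio grow under aggregation. Under the selection picture
the framework assumes — specific sequences are background sequences
restricted to a binding subset, with binding independent of generation
probability — we observed no violation across thousands of randomized
enumerations, and the property suite asserts the inequality in that
regime only.

## The synthetic generator

The generator provides data with the statistical structure the framework
assumes, for validation and power analysis; it does not emulate
junctional biology.

* **Background** (`background_config()`): independent categorical V and
  J usage per chain (defaults: 20 V and 12 J genes with exponentially
  decaying usage, a skew typical of gene-usage tables), a categorical
  CDR3 length distribution (discretized Gaussian on 10–18, mean 14), and
  i.i.d. amino acids from a glycine/serine-rich CDR3-like composition,
  with the leading cysteine fixed. Chains are paired at random, drawn
  once per table ("single-draw" pairing); regenerating with another seed
  resamples the pairing. Because the feature distribution is known in
  closed form, `pc_background_exact()` evaluates background coincidence
  probabilities exactly (genes from usage vectors; CDR3 as $\sum_L
  P(L)^2 q^{L-1}$ with $q$ the per-position collision probability;
  charge by convolution), mirroring the use of a generative
  recombination model for the background distribution in real analyses.
  What this background does *not* model: junctional insertion/deletion
  statistics, positional amino acid preferences, thymic or peripheral
  selection. Conclusions about those features of real data are outside
  what passing tests establish.
* **Epitope-specific sets** (`mixture_config()`): mixtures of binding
  modes, each anchoring a distinct V and J per chain plus a CDR3 motif
  template reproduced with an independent per-position substitution
  rate (default 0.1, giving within-mode coincidence probabilities large
  enough for pair counting at a few hundred clones per mode); an
  optional false-positive fraction draws clones from the background
  instead. Disjoint equal-weight modes are the default because they make
  the mixture arithmetic exact: with $M$ such modes,
  $p_C = q/M$ for within-mode coincidence $q$, so every doubling of $M$
  costs one bit of per-chain relevancy and adds one bit of chain-pairing
  synergy — the origin of the $\pm 1$ slopes between local interaction
  information and local single-chain relevancy across epitopes.
* **Random streams.** One root seed; every generator role derives an
  independent child stream, so adding epitopes does not perturb
  background draws, and all generators are pure functions of their
  configuration.

`mixture_sweep()` evaluates the slope prediction at $M \in \{1, 2, 4, 8,
16\}$ with 2000 clones per epitope — sizes at which pair counting
resolves the local scores to a few hundredths of a bit while a sweep
completes in seconds. Its background denominators use
`pc_background_exact()` because sampled background tables essentially
never contain full-TCR coincidences under a realistic synthetic
background; the background terms are constant across epitopes, so slopes
are unaffected by this choice. `spike_in_experiment()` validates the
posterior-odds law on categorical feature distributions: a uniform
background makes the cross-match probability equal $p_C[X]$ exactly,
which is the regime in which the law is exact.

`odr_slope()` fits the orthogonal distance regressions used for the
slope analyses by minimizing the effective-variance objective
$\sum_i (y_i - a - b x_i)^2 / (s_{y,i}^2 + b^2 s_{x,i}^2)$, with the
slope parameterized by angle (a coarse angular scan followed by local
refinement, so near-vertical lines and the two-minimum structure of the
objective pose no problem) and a jackknife standard error.

## Degenerate inputs and numerical conventions

Distributions passed to exact evaluators must be non-negative and sum
to 1 within $10^{-9}$. Fewer than two usable values yield an estimate
with zero total pairs and `NA` probability. `entropy2(0)` and log ratios
with zero coincidences return `NA` with a warning. The posterior-odds
and minimal-prior formulas are exact algebraic identities and
round-trip to floating-point precision. The critical distance is the
*largest* distance whose near-coincidence information still reaches the
posterior-odds target at the given prior; if none qualifies the result
is `NA`.

## Known limitations

* Only order-2 Rényi quantities are implemented; Shannon-entropy
  estimation and higher Rényi orders are out of scope.
* Relevancy scores are plug-in estimates; for very small epitope groups
  the log-ratio bias can be non-negligible even though $\hat p_C$ itself
  is unbiased.
* The greedy alphabet search optimizes merges locally and is not
  guaranteed to find the global optimum at a given $k$.
* Substitution-matrix-weighted distances (TCRdist-style) are not
  provided; near-coincidence metrics are unit-cost Levenshtein per chain
  or their sum.
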