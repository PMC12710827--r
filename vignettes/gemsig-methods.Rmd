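---
title: "Mapping metabolite signatures to genes through a metabolic model: methods and design"
author: "gemsig"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping metabolite signatures to genes through a metabolic model: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gemsig)
```

## The model behind the package

A genome-scale metabolic model (GEM) is treated here as nothing more
than a relational knowledge base. Three entity types matter:
metabolites (with a display name and a compartment), reactions (signed
stoichiometry over metabolites — negative coefficients consumed,
positive produced — a reversibility flag, and a set of associated
enzyme-coding genes), and genes. Everything the package computes is a
function of this triad; flux simulation, bounds, objective functions
and model curation are deliberately out of scope.

Two modeling commitments follow from that reading:

* **GPR flattening.** Gene–protein–reaction rules encode isoenzymes
  (OR) and complexes (AND). Because no reaction activity is ever
  predicted, evaluating that Boolean structure would add nothing: a
  gene listed anywhere in a reaction's association is evidence of a
  biochemical link. The loader therefore keeps the *set* of referenced
  genes and discards the logic.
* **Reaction classification.** Exchange reactions (single-sided
  stoichiometry or involving a boundary-condition species) are
  modeling artifacts, not biochemistry, and are never used for
  mapping. Transport reactions — the same compartment-stripped species
  multiset on both sides with differing compartments — are excluded
  only when they carry no gene, which also removes all other
  uncatalyzed reactions. A gene-carrying transporter is real enzymatic
  evidence and stays eligible.

Reversibility is taken from an explicit flag when the format provides
one, falling back to the flux-bound sign test (lower bound < 0 and
upper bound > 0) for SBML input, since SBML dialects differ in which of
the two they populate.

## Mapping rules

Given a resolved signature, the non-directional rule links a metabolite
to the genes of every eligible reaction it participates in; the
directional rule restricts to reactions *producing* it. Reversible
reactions count for both sides under either rule, which is why the
directional mapped set is always a subset of the non-directional one —
a property the test suite checks on seeded random models rather than
assumes. Currency metabolites (ATP, NADH, H₂O, H⁺) are treated like any
other metabolite: down-weighting promiscuous connections is the job of
the specificity score, not of a hand-maintained exclusion list.

Name resolution is deliberately conservative: trim, case-fold, collapse
internal whitespace, then exact match against model names (and ids).
Fuzzy matching is a correctness hazard in metabolite nomenclature —
"glucose" vs "glucose 6-phosphate" — so anything beyond exact matching
must come through an explicit user-supplied synonym table. Unresolved
names are always reported, never dropped silently. Compartment
collapsing defaults to on because measured metabolomes are
compartment-agnostic; the expert switch (`collapseCompartments =
FALSE`, `universe = "species"`) keeps every compartment instance
distinct.

## The specificity score and its weight

For gene $g_i$, let $M$ be the number of metabolites in the model
universe, $S$ the resolved signature size, $A_i$ the gene's associated
metabolites and $a_i$ its overlap with the signature. The score is the
upper-tail hypergeometric probability

$$s_i = \sum_{x=a_i}^{\min(A_i, S)}
\frac{\binom{A_i}{x}\binom{M-A_i}{S-x}}{\binom{M}{S}},$$

the chance that a random signature of the same size would overlap the
gene's neighborhood at least as strongly. Two conventions needed
deciding:

* **The universe $M$.** Published conventions mix compartmentalized
  species counts with unique-species counts. The default here is the
  compartment-collapsed count, matching the collapsed signature space
  so that $S$, $A_i$ and $a_i$ are all measured in the same units;
  `universe = "species"` switches to raw species for users who keep
  compartments distinct.
* **$A_i$ under the directional rule.** $A_i$ is computed under the
  *same* rule as the mapping (for directional: metabolites the gene can
  produce, over eligible reactions). This keeps the evidence coherent —
  every metabolite that mapped a gene is a member of that gene's $A_i$,
  so $a_i \ge 1$ holds for every mapped gene by construction rather
  than by clamping.

Scores are converted to ORA weights by the sigmoid

$$w_i = \frac{1}{1 + e^{a \log_{10} s_i - b}},$$

monotone decreasing in $s_i$ and bounded in $(0,1)$. The printed form
uses an absolute offset $b$; the equivalent half-point
parameterization $b = a\log_{10}(s_{1/2})$ is exposed via
`weightParams(halfPointS = )` because "the score at which a gene gets
half weight" is the quantity users actually reason about. Defaults are
$a = 2$ and $b = 2\log_{10}(0.05) \approx -2.602$, anchoring the
half-point at the conventional 0.05 significance level: a gene whose
neighborhood overlap would arise in 5% of random signatures counts as
half a gene. No published default exists for either parameter, so both
are plain arguments, not constants.

The tail itself is evaluated through the hypergeometric survival
function (log-space internally), so scores down to the smallest
double-precision magnitudes are representable; the test suite pins the
implementation against exhaustive enumeration of all
$\binom{M}{S}$ signatures for every configuration with $M \le 12$.

## The weighted over-representation test

The classical ORA tail $P(X \ge k)$ over background $N$, set size $K$,
query $n$ and overlap $k$ is kept exactly, with the query-side counts
replaced by rounded weighted sums:

$$n_w = \left\lfloor \tfrac12 + \sum_{i \in \text{mapped}} w_i
\right\rfloor,\qquad
k_w = \left\lfloor \tfrac12 + \sum_{i \in \text{mapped} \cap \text{set}}
w_i \right\rfloor.$$

Rounding is half-up (`floor(1/2 + x)`), not banker's rounding, and is
applied after summation. $N$ and $K$ are never weight-adjusted — the
asymmetry is intentional and documented rather than "fixed", because
adjusting only the query side is what makes the weighted test reduce
*exactly* to the classical one when all weights are 1 (a property the
suite verifies field-by-field on random configurations). After
rounding, $k_w$ is clamped to $\min(n_w, K)$ so the counts always form
a valid hypergeometric configuration. Degenerate rows ($K = 0$ in the
background, or $n_w = 0$) are reported with $p = 1$ instead of being
dropped, keeping row counts stable for downstream pathway-overlap
tests. Benjamini–Hochberg adjustment is applied within each collection
separately, matching per-compendium reporting; the default background
is the model's full enzyme-coding gene complement.

## Evaluation statistics

The concordance tests compare GEM-mapped genes against an independent
paired-omics signature. The single-molecule test restricts both sets to
the intersection of the model's genes with the measured genes/proteins
— without that restriction the test would reward the model for simply
containing many genes — and applies the one-sided upper-tail
hypergeometric. The one-sided tail was chosen over a two-sided Fisher
convention because the hypothesis is directional (more overlap than
chance); for the "greater" alternative the two coincide, which a test
checks numerically against an independent tail-sum.

The pathway-level analogue works on enriched-set *names* over an
eligible background: sets sufficiently represented on both sides. No
published numeric threshold exists for "sufficiently represented", so
`eligibleSets()` exposes it as `minGenes` (default 5, a common floor
for meaningful ORA hits) instead of hard-coding a guess.

The global uniformity test asks whether a column of such p-values is
skewed toward zero. The statistic is the one-sided
$D^+ = \max_i(i/n - x_{(i)})$ over the sorted sample, computed by a
direct sorted scan; the skew-to-zero alternative is the default since
that is the stated hypothesis, and on the bundled benchmark columns
$D^+$ equals the two-sided $D$ at the reported precision anyway.
P-values come from the standard KS sampling distribution
(`stats::ks.test`, exact where available); ties — routine in p-value
collections — only affect the p-value approximation, not $D$.

On the bundled benchmark tables, three of the four reference D values
reproduce at two decimals (0.77, 0.62, 0.33); the directional
pathway-level column computes to 0.3456 against a reference of 0.34.
The bundled table stores p-values at three significant digits, and the
maximizing order statistic sits where a third-decimal perturbation of
nearby entries moves D by about 0.006, so the residual is a
transcription-precision effect, not a statistic-convention mismatch;
the corresponding regression test records the discrepancy rather than
loosening its band.

## The synthetic generator

`generateGEM()` emulates only what the combinatorics of mapping and
scoring exercise: a connected bipartite metabolite–reaction structure
(1–3 reactants and products per reaction, every metabolite used),
boundary exchanges without genes, a reversible fraction, and 1–3 genes
per reaction with a `promiscuity` dial setting the mean number of
reaction attachments per gene. It does *not* emulate mass balance,
thermodynamics, realistic degree distributions (hub currency
metabolites), or RefMet nomenclature — fixture names are `MET0001`-style
and resolution tests use exact matching. Passing tests on these models
therefore demonstrates correctness of the mapping/scoring machinery,
not biological performance on real GEMs; the benchmark tables and the
documented Human-GEM recipe cover the latter. All sampling consumes a
single seeded RNG stream in a fixed order (topology, reversibility,
gene attachment), and the caller's RNG state is restored afterwards.

`plantSignature()` samples a fraction (`coverage`) of a target gene's
metabolite neighborhood plus `noise` random other metabolites. The
recovery property asserted in the suite — the most specific available
target ranks in the top 3 by score in at least 90% of 50 seeded
replicates at coverage 0.8 and noise 2 on 30-metabolite models — is a
regression bound on this generator, not a claim about real data.

## Numerical and degenerate-input policy

* All tail probabilities go through the survival function in log space;
  $a_i = 0$ or $k = 0$ short-circuit to exactly 1.
* Ranking ties (equal $s_i$) break by ascending catalyzed-reaction
  count, then lexicographic gene id, so output is deterministic across
  platforms.
* An entirely unresolved signature produces an *empty, flagged* mapping
  result and a warning, never an error, so batch runs survive
  individual failures; the pipeline writes an empty TSV for it and
  skips enrichment.
* Duplicate signature names are removed with a warning at construction;
  resolved/unresolved always partition the input names.
* Problem sizes used by the shipped checks (toy models of 20–40
  metabolites, 50 replicates, exhaustive enumeration up to universe
  size 12, 100 random ORA configurations) were chosen as the smallest
  sizes at which the asserted properties are non-trivial.

## Known limitations

* Name resolution is exact-match only; real metabolomics data usually
  needs upstream normalization to the model's nomenclature (RefMet for
  the human model) or a synonym table.
* The specificity score conditions on the resolved signature size $S$;
  unresolved metabolites carry no information and are reported but not
  modeled.
* The weighted test's integer rounding makes p-values step-wise in the
  weights: small weight changes that do not move a rounded count leave
  p unchanged.
* The KS p-value (unlike $D$) inherits the usual tie caveats of
  small-sample KS tests.
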