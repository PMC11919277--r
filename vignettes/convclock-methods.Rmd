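---
title: "Methods: convergence detection, rate-trait regression, and sleep-bout analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: convergence detection, rate-trait regression, and sleep-bout analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(convclock)
```

`convclock` is a desk-scale pipeline for asking whether independently
evolved sleep phenotypes — above all unihemispheric slow-wave sleep in
marine mammals — left convergent molecular signatures in circadian clock
genes, and for measuring the behavioral endpoints such signatures are
hypothesized to influence. This vignette is the package's own account of
the models it fits, the defaults it ships, and the choices made where the
design was genuinely open.

## Substitution model

Amino-acid evolution is modeled as a reversible continuous-time Markov
chain on the 20 residues. A model combines symmetric exchangeabilities
$s_{ij}$ with stationary frequencies $\pi$:

$$q_{ij} = s_{ij}\,\pi_j \ (i \neq j), \qquad
  q_{ii} = -\sum_{j \neq i} q_{ij},$$

scaled so the mean rate $-\sum_i \pi_i q_{ii}$ is 1, i.e. branch lengths
are expected substitutions per site. The packaged exchangeabilities are
the published JTT values (`inst/extdata/jtt_exchangeabilities.txt`); the
*JTT-f_genes* variant replaces the published frequencies with frequencies
estimated from the gene's own alignment (`estimate_frequencies`).

**Pseudocount (default 0.5 per residue).** Single-gene alignments are a
few hundred columns and often miss rare residues entirely; a zero
stationary frequency would make the corresponding state unreachable by
the matrix exponential. The additive pseudocount 0.5 keeps every
frequency positive while shifting observed frequencies by well under a
percentage point at typical alignment sizes.

$P(t) = e^{Qt}$ is computed from the eigendecomposition of the
symmetrized matrix $D_\pi^{1/2} Q D_\pi^{-1/2}$ (exact for reversible
models); entries within $-10^{-12}$ of zero are clamped to 0. An
`equal_rates_model()` (all $s_{ij}$ equal, uniform $\pi$) is shipped
because it has closed forms used throughout the tests:
$P_{ii}(t) = \tfrac{1}{20} + \tfrac{19}{20}e^{-20t/19}$ and the
distance formula $\hat t = -\tfrac{19}{20}\log(1 - \tfrac{20}{19}\hat p)$.

All branch-length optimizations are bounded at $t_{\max} = 20$ expected
substitutions/site, far beyond any biologically meaningful divergence;
`ml_pairwise_distance` refuses pairs with difference fraction
$\hat p \ge 19/20$, the saturation point of the 20-state symmetric model.

## Ancestral reconstruction

`tree_log_likelihood` implements Felsenstein pruning with per-site
rescaling. Tip gaps and `X` are missing data (all-ones conditionals);
this is the conservative choice — a gap neither supports nor contradicts
any ancestral state. `marginal_ancestral_states` combines the up-pass
conditionals with a standard down-pass to give, for every internal node
and site, the posterior over the 20 residues given all tips, and records
the MAP state. Posterior ties (which arise in symmetric toy models, and
have probability zero under generic models) are broken alphabetically in
the canonical residue order and flagged with a warning.

Marginal (not joint) reconstruction is used because the downstream
counting operates node by node, matching the common practice of counting
substitutions on per-node reconstructed sequences.

`optimize_branch_lengths` refits lengths by coordinate ascent (bounded
scalar maximization per branch, sweeps until the log-likelihood gain
falls below `tol = 1e-6` or 50 sweeps); the trace is non-decreasing by
construction. The convergence pipeline refits by default — expectations
should be parameterized by lengths measured on the same data and model —
but `refit_lengths = FALSE` uses the input tree's lengths verbatim, which
is both faster and the natural choice when the input lengths *are* the
truth (simulation studies, externally estimated trees).

A note on accuracy at short branches: with 2,000 sites the ML standard
error of a branch length near $t = 0.02$ is about 0.003, i.e. ~15% of the
value itself. Recovery tests therefore judge very short branches on the
absolute scale of their sampling error rather than demanding a fixed
relative accuracy.

## Convergence detection and the Poisson null

Foreground lineages are tagged on branches (`tag_branches`): a group is a
tip branch or the stem branch of a named clade (stem-only by default,
because hypotheses like "the ancestor of cetaceans" concern single
branches; `mode = "clade"` tags whole clades). `enumerate_branch_pairs`
forms all unordered pairs of tagged branches from different groups,
excluding ancestor–descendant pairs, which are not independent trials.

Following the Zhang–Kumar definitions, at a site with parent states
$p_1, p_2$ and child-end states $c_1, c_2$ (MAP for internal nodes,
observed residues for tips):

- **convergent**: $c_1 = c_2$, $p_1 \neq c_1$, $p_2 \neq c_2$, and
  $p_1 \neq p_2$;
- **parallel**: the same with $p_1 = p_2$.

Both totals are reported (and a combined total), since empirical site
lists often mix the two. Sites with a gap/`X` at either child end are
skipped in both the observed and the expected sums, keeping the
comparison like-for-like.

The expected count conditions on the reconstructed parent states
(default `condition = "map"`; `"posterior"` marginalizes over the
parent posterior product instead, which matters only when
reconstructions are uncertain):

$$E = \sum_{\text{sites}} \sum_{\text{pairs}}
  \sum_{j \notin \{p_1, p_2\}} P_{p_1 j}(t_1)\, P_{p_2 j}(t_2).$$

Significance is a one-sided upper-tail Poisson test,
$p = \Pr(X \ge C)$ with $X \sim \text{Poisson}(E)$ — the question is
whether convergence is *in excess* of the model expectation — with
Benjamini–Hochberg adjustment across genes (`fdr_adjust`,
`adjust_convergence_reports`).

## Site scanning

A column is **group-specific** when all foreground members carry the same
non-gap residue and every background residue differs from it; it is
**shared-specific** for a set of groups when all of their members carry
one residue and everyone outside differs. Background gaps/`X` are
ignored (absence of evidence is not a differing residue) but counted in
the report; a foreground gap disqualifies the column, since strict
identity cannot hold. Background residues are *not* required to be
mutually identical — only to differ from the foreground residue. Labels
follow the familiar `T699P` convention: reference residue, position in
the ungapped reference (human) coordinate system, derived residue.

## Rate–trait regression

The rate axis is the root-to-tip $\omega = d_N/d_S$. Full codon
maximum-likelihood estimation of $\omega$ belongs to dedicated tools and
is out of scope here; the pipeline either consumes a precomputed
per-species $\omega$ table or computes NG86 estimates
(`ng86_pair`, `root_to_tip_omega`) given a root codon sequence.
NG86 counting: per-codon synonymous site fractions over non-stop
single-nucleotide changes; multi-position codon differences averaged over
all stop-free orderings of single steps (with a fall-back average over
all orderings in the rare case every path crosses a stop); Jukes–Cantor
correction $d = -\tfrac34\log(1-\tfrac43 p)$. $\omega$ is flagged
undefined — never imputed — when $d_S = 0$ or a proportion reaches the
correction's domain limit.

`pgls_fit` regresses response on predictor under residual covariance
$\sigma^2 C(\lambda)$, where $C_{ij}$ is the shared root-to-MRCA path
length and $\lambda \in [0,1]$ scales the off-diagonals (Pagel's
$\lambda$; 0 = no phylogenetic signal, 1 = Brownian motion). $\lambda$
is profiled by ML on a 101-point grid with bounded refinement around the
grid optimum — the likelihood in $\lambda$ can be flat or multimodal, so
a grid-first strategy is safer than a single local search. The slope
test uses $t = \hat\beta_1/\mathrm{se}(\hat\beta_1)$ with $n-2$ degrees
of freedom, and $R^2 = 1 - (\hat e^\top C^{-1}\hat e)/(\tilde y^\top
C^{-1}\tilde y)$ with $\tilde y$ the GLS-demeaned response (reported
because GLS $R^2$ conventions vary; this one reduces to the OLS $R^2$
when $C \propto I$). By default the (log) rate is regressed on the
phenotype; natural logs are used.

## Sleep-bout analysis

An `activity_trace` is a nonnegative activity value per 60-s bin with a
clock-time origin. A **sleep bout** is a maximal run of bins with
activity at or below the inactivity threshold — default 0, the
one-minute-of-inactivity convention for larval zebrafish; the threshold
is exposed because tracking-software "freeze" settings can leave
sub-threshold jitter in nominally quiescent bins. Raising the threshold
can only add sleep bins, so total sleep is monotone in it.

`phase_summary` assigns bins to day or night by clock time under the
lights-on 09:00 / lights-off 23:00 schedule (14 h/10 h). Bouts spanning
a boundary are split at the boundary, each fragment counting as a bout
in its phase — splitting (rather than assigning the bout to its onset
phase) is what makes sleep + wake exactly equal each phase's duration,
an invariant the tests enforce; the whole-trace summary row keeps bouts
unsplit.

`compare_groups` reproduces the normality-gated recipe of behavioral
studies: every group must pass both the D'Agostino & Pearson omnibus
test and Shapiro–Wilk at $\alpha = 0.05$ for one-way ANOVA with
Holm–Šidák pairwise comparisons; otherwise Kruskal–Wallis with
Dunn–Šidák. The omnibus $K^2$ test (D'Agostino skewness and
Anscombe–Glynn kurtosis transforms) is implemented in-package; it needs
$n \ge 8$, and smaller groups are gated on Shapiro–Wilk alone. A
zero-variance group forces the nonparametric branch with a warning.
Significance labels are ns/*/**/***/**** at 0.05/0.01/0.001/0.0001.

## Synthetic study conditions

The generators in `simulate.R` stand in for the data a real study would
assemble (sequenced genes, trait compilations, video tracking), and
their defaults *are* the study conditions of the test suite:

- `simulate_alignment` draws root states from $\pi$ and propagates along
  branches with $P(t)$; gene-scale tests use 200–300 sites on 10–12-taxon
  trees with branch lengths 0.002–0.3, the scale of a single mammalian
  clock-gene alignment.
- `plant_convergent_sites` overwrites the clades below designated
  branches with a common residue chosen so the event is genuinely
  convergent (parents differ, both changed) and, under the `"exclusive"`
  policy, absent from the background. Overwriting is exactly verifiable
  and is what the detector tests need; it is *not* a draw from a
  coherent evolutionary model, and is documented as such.
- The planted-detection fixture places each foreground tip next to a
  densely sampled pair of near-identical sister taxa (branch length
  0.002). This makes the foreground parent states identifiable from
  data — the analogue of densely sequencing close relatives of the focal
  lineages, as convergence studies do — so that detection failures
  reflect the detector, not irreducible ancestral-state uncertainty. On
  sparser trees the MAP parent state is wrong at roughly 1% of
  node-sites, which is enough to misclassify some planted convergent
  events as parallel.
- `simulate_trait` draws Brownian residuals with covariance
  $\sigma^2 C(\lambda)$; recovery tests use $\lambda = 1$, slope 0.5,
  $\sigma^2 = 0.25$, $n = 100$ coalescent tips — strong phylogenetic
  signal with moderate noise, the regime reported for clock genes versus
  SWS/TST ratios.
- `simulate_codon_pair` evolves single-nucleotide changes at rate 1/9
  (synonymous) or $\omega/9$ (nonsynonymous), stop codons excluded, for
  duration $t$; neutrality checks use $t = 0.8$ (~0.8 substitutions per
  codon at $\omega = 1$), a divergence at which the NG86 estimator's
  sampling spread at 500 codons is near its minimum (sd ≈ 0.13) — small
  enough to check consistency, honest about counting-estimator noise.
- `simulate_activity_trace` alternates geometric wake/sleep runs with
  phase-dependent means (defaults: day 2-min sleep/20-min wake bouts,
  night 8-min sleep/6-min wake bouts — a diurnal larva) and gamma wake
  activity; sleep bins are exactly zero, so planted bouts are recovered
  exactly by construction.

Every generator is seeded, restores the caller's RNG state, and logs its
parameters in the returned truth object.

**What passing tests do and do not show.** The generators match the
fitted models (no among-site rate variation, no indels, no alignment
error, activity exactly zero during sleep). Passing therefore
demonstrates correctness of the machinery — likelihoods against
brute-force enumeration, expectations against closed forms and Monte
Carlo, exact recovery of planted signals, calibration of the Poisson
null under the model — not robustness to model misspecification in real
data. Real analyses additionally face alignment trimming (exposed as
configuration, not hard-coded), rate heterogeneity, and reconstruction
uncertainty that the `"posterior"` conditioning mode can partially
address.

## Numerical choices and degenerate inputs

- Per-site rescaling in the pruning pass prevents underflow on deep
  trees; site likelihoods of exactly zero raise an error naming the site.
- Matrix exponentials by symmetric eigendecomposition; transition rows
  renormalize to 1 within $10^{-10}$ and tiny negative entries are
  clamped.
- $E = 0$ Poisson cases: $C = 0$ gives $p = 1$; $C > 0$ gives $p = 0$
  with a warning (the null is then certainly violated or misspecified).
- Undefined $\omega$ rows are excluded from downstream fits with a
  logged count, never imputed.
- PGLS requires $\ge 4$ complete cases and a non-constant predictor;
  rows missing data or absent from the tree are dropped with a message.

## Problem sizes

The shipped suite runs brute-force oracle comparisons on 200 trees of
2–5 tips × 5 sites, a 500-replicate Poisson null calibration (200 sites,
12 taxa), a 2,000-replicate Monte-Carlo check of the expected-convergence
formula (500 sites), 20-seed recovery studies for planted convergence,
PGLS, and neutral $\omega$, and 50 seeded site-scan fixtures. These sizes
give the statistical resolution each check needs while keeping the full
suite in the minutes range on a single core.

## Known limitations

- Homogeneous rates across sites (no Gamma mixture), as the convergence
  expectation machinery is defined for the named JTT-f_genes model.
- NG86 is a counting estimator: at high divergence or strong codon bias
  it is biased relative to codon ML; it is offered for desk-scale work
  and ordering comparisons, not as a substitute for ML $\omega$ on real
  data.
- Joint (path-wise) ancestral reconstruction and sampling of histories
  are not implemented; MAP marginal states feed the counting.
- The activity metric is treated as an abstract nonnegative signal;
  tracker-specific settings (detection/burst/freeze thresholds) are the
  user's responsibility upstream.
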