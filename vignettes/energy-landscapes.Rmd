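---
title: "Inferring nucleation energy landscapes from deep mutational scanning"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring nucleation energy landscapes from deep mutational scanning}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dmsenergy)
```

## The model

Amyloid nucleation is the rate-limiting step converting soluble
amyloid-beta 42 (Aβ42) into growing fibrils. Transition-state theory links
the nucleation rate constant $k$ to the free energy of activation
$\Delta G^\ddagger$,

$$k = A \, e^{-\Delta G^\ddagger / RT},$$

with a pre-factor $A$ treated as mutation-invariant. A mutation's change in
activation energy, $\Delta\Delta G^\ddagger$ (kcal/mol, mutant minus wild
type), is therefore proportional to the log of its nucleation rate ratio,
and — in a selection assay where nucleation drives cell growth — to its
WT-relative log enrichment ("relative growth rate", GR).

The package fits a *global epistasis* energy model to such growth rates:
each variant's latent energy trait is the sum of its per-mutation
first-order terms plus, optionally, pairwise energetic couplings
($\Delta\Delta\Delta G^\ddagger$, the deviation of a double mutant's
activation energy from the sum of its singles). A single bounded sigmoid
maps trait to growth rate,

$$g(\phi) = L + \frac{U - L}{1 + e^{\phi}},$$

decreasing in $\phi$ because a higher barrier slows nucleation, with
learnable bounds $L < U$ reflecting the assay's dynamic range. Fitting
minimizes the error-weighted squared loss with elastic regularization
$\lambda(\lVert\theta\rVert_1 + \lVert\theta\rVert_2^2)$, $\lambda =
10^{-5}$, and reports held-out accuracy by 10-fold cross-validation.

### Identifiability and the sigmoid scale

A sigmoid with a learnable slope $s$ in $e^{s\phi}$ is degenerate with a
rescaling of all energy terms ($s\phi$ is invariant under $s \to cs$,
$\theta \to \theta/c$), and only saturation weakly breaks the tie. We
therefore fix $s = 1$ and let the trait carry arbitrary units; the kinetic
calibration step (below) restores physical units. This is a deliberate
reparameterization, not a loss of generality.

### Numerical choices

* Optimizer: L-BFGS with analytic gradients, relative-loss tolerance
  $\approx 10^{-8}$ (`factr = 4.5e7`), up to 2000 iterations, 3 random
  restarts for full-data fits. Cross-validation folds warm-start from the
  full-data optimum.
* The L1 subgradient at zero is smoothed as
  $\sqrt{\theta^2 + \epsilon}$, $\epsilon = 10^{-8}$; at
  $\lambda = 10^{-5}$ the penalty is a tie-breaker, not a sparsifier.
* Bounds are parameterized as $(L, \log(U - L))$ so $L < U$ holds
  unconstrained.
* Per-term standard errors are the dispersion of each term across the ten
  fold fits — an approximation documented as such; a parametric SE would
  require the (unavailable) noise model of the real assay.
* Degenerate inputs: tables of only WT synonyms fit all terms to zero
  (penalty dominates); zero-SE terms are flagged `untestable` rather than
  tested; constant score or distance vectors make the rank correlation
  `NA` rather than an error.

## From counts to growth rates

Sequencing counts enter as per-replicate input/output pairs. Variants with
fewer than 10 input reads in *any* replicate are discarded (inclusive
threshold). The enrichment score is the natural-log frequency ratio with a
0.5 pseudocount on raw counts, and GR is the difference to the reference's
enrichment score. One printed form of the enrichment score in the
literature subtracts frequencies inside the logarithm; a frequency
*difference* can be negative and unloggable, so the package implements the
standard log-*ratio*, the only form consistent with WT-relative log
enrichment. Counting errors are Poisson plug-ins,
$\sigma^2 = \sum 1/(n + \tfrac12)$ over the four counts involved;
replicates merge by the error-weighted mean, and growth rates are centered
so the error-weighted mean over WT synonymous variants is zero.
Combinatorial libraries lack the wild type entirely: a designated
reference variant anchors enrichment, and an artificial WT row (GR 0,
$\sigma = 100$, i.e. weight $10^{-4}$) anchors the model, whose energies
are afterwards recentered onto the double-mutant scale by an affine map
fitted over shared terms. First-order terms receive slope and intercept;
couplings, being double differences, receive the slope only.

## Calibration to kcal/mol

In vitro nucleation rate constants for a handful of variants give
experimental $\Delta\Delta G^\ddagger = RT\ln(k_{WT}/k_{var})$ at
$T = 303\,$K ($R = 1.987 \times 10^{-3}$ kcal/(mol K)). Regressing model
trait values on these energies (that orientation) gives a slope in trait
units per kcal/mol; dividing all terms by it calibrates the model.
Secondary-nucleation rate constants are the default source. Multiplicative
rate terms (nucleation × elongation) may substitute for pure nucleation
constants; the elongation factor cancels in the ratio only if elongation is
mutation-invariant, an assumption we document rather than test. The
regression includes an intercept, but only the slope is applied to terms:
energy terms are differences, which an intercept cannot shift.

## Stability ratios and couplings versus structure

Phi-value-like analysis divides each mutation's $\Delta\Delta G^\ddagger$
by its effect on mature-fibril stability ($\Delta\Delta G$, consumed as
per-structure tables, normalized per monomer by the stacked chain count — 4,
or 3 for the one trimer-only polymorph). Only moderate stability effects
contribute: $0.6 < |\Delta\Delta G| < 10$ kcal/mol. The absolute-value form
of the filter is used: the interpretation of the ratio is symmetric in the
sign of the stability change, and the band excludes both unreliable
denominators and structure-breaking mutations. Ratios are computed per
mutation, then averaged per position; polymorphs are ranked by the RMSD of
their ratios to 1 over a region mask (the C-terminal aggregation-prone
region, residues 29–42, being the analysis default; APR1 is residues
17–21).

Pairwise couplings aggregate into per-position-pair *interaction scores*
(mean $|\Delta\Delta\Delta G^\ddagger|$). Structural comparison uses the
minimal side-chain heavy-atom distance (scHA\_min): hydrogens excluded,
side chain = heavy atoms outside N/CA/C/O, glycine represented by its
C-alpha, highest-occupancy altloc kept. Monomer mode measures within one
chain; dimer mode takes two facing chains and minimizes over both
cross-chain assignments. Residue-numbering offsets of deposited fibril
structures are an explicit parameter, never inferred. Whether published
monomer-mode distances were used for the main structural figure is not
stated in the source literature; monomer is the package default and dimer
is exposed via `mode = "dimer"`. Interaction scores are compared with
1/scHA\_min by Spearman correlation (t-approximation for $n \ge 10$, exact
below), contacts are called strictly below 8 Å, and top pairs are those at
or above the 90th percentile of the score distribution
(linear-interpolation quantile, ties kept).

## The synthetic-data generator

Every downstream stage is validated against simulations with known ground
truth. The generator emulates:

* **Effect-size structure**: first-order effects from a two-component
  mixture — 72% barrier-raising (gamma, mean 1.2 kcal/mol), 14%
  barrier-lowering (gamma, mean 0.5), the rest near-neutral — matching the
  observed predominance of nucleation-slowing mutations; couplings sparse
  (default 10% of possible pairs of mutations) with heavy-tailed
  (Student-t, 3 df, scale 0.5 kcal/mol) magnitudes.
* **Selection**: one effective exponential growth round — output
  frequencies proportional to realized input frequency times $e^{GR}$.
  The real assay's plating and colony-formation steps are collapsed into
  this form because GR is defined only up to WT-relative log enrichment;
  the true growth law linking nucleation to colony counts is not
  specified beyond log-linearity, and the one-round model is an explicit
  simplification.
* **Sequencing noise**: multinomial input counts over a log-normal library
  composition (sd 0.5, shared across replicates as for a single
  transformed library), multinomial output counts, optional per-variant
  log-normal overdispersion (off by default so oracle tests see pure
  counting noise).

What the generator does *not* emulate — sequencing errors, synonymous
nucleotide-level diversity beyond tagged WT synonyms, replicate-specific
library compositions, DiMSum's full error model — bounds what passing
tests show: they certify the inference chain, not the upstream read
processing.

Default problem sizes used in the test-suite recovery checks are the five
study library designs at 100 reads per variant and 3 replicates — the
three double-mutant designs for first-order recovery (the largest spans
all 798 single and 310,821 double mutants) and the 15,625-genotype
combinatorial design for coupling recovery; these sizes keep full runs on
a single CPU in minutes while leaving counting noise realistic.

## Surrogate stability tables and structure fixtures

Published per-mutation fibril-stability predictions are inputs, not
outputs, of this package; tests use surrogate tables whose per-monomer
values track the activation-energy landscape with a configurable
correlation inside a designated region (correlation 1 makes the ratio
exactly 1 there, by construction) and are independent outside it. These
surrogates are synthetic stand-ins, labelled as such, for structure-based
stability predictions. Structure fixtures are minimal PDB files written by
the package itself — hairpins and contact islands with hand-placed
side-chain atoms — so every distance assertion is true by construction.

## Worked example

```{r example, eval = FALSE}
designs <- abeta_designs()
land <- sample_landscape(designs$cterm, coupling_density = 0, seed = 1)
vars <- enumerate_variants(designs$cterm, include_sequence = FALSE)$mutations
counts <- simulate_selection(land, vars, replicates = 3,
                             n_wt_synonyms = 10, seed = 2)
growth <- process_counts(counts)
fit <- fit_energy_model(growth, order = 1, seed = 3)
glance(fit)
head(tidy(fit))
```

## Known limitations

* Per-term SEs from fold dispersion understate correlated uncertainty;
  classifications at FDR < 0.05 are comparative, not calibrated
  guarantees.
* The compression accounting follows the 4-alternatives-per-site
  convention for combinatorial genotype spaces (the WT residue is part of
  each site's alphabet but not counted as an alternative).
* One printed count in the source literature for the N-terminal library's
  double mutants (151,200) does not match its own combinatorics
  ($\binom{28}{2} \times 19^2 = 136{,}458$); the package computes the
  latter and documents the discrepancy rather than reproducing the
  misprint.
* Three-way and higher couplings, heteroscedastic noise learning, and
  structure superposition are out of scope.
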