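---
title: "Neutrality functions for double-mutant fitness: methods and models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Neutrality functions for double-mutant fitness: methods and models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epineutral)
```

## The problem

Genetic-interaction screens measure the fitness (relative colony or
exponential growth rate, wild type = 1) of single mutants and of the
corresponding double mutants. Two mutations are said to interact when the
double-mutant fitness deviates from a *neutrality function* — the null model
predicting the double-mutant fitness of two non-interacting mutations from
the two single-mutant fitnesses. The choice of neutrality function is
therefore load-bearing: a poorly chosen null makes most of the genome appear
to interact.

`epineutral` implements the three classical candidates and one
mechanistically derived law:

* **Product**: $W_{xy} = W_x W_y$ — a mutation's absolute effect shrinks in
  a less fit background (diminishing-returns epistasis);
* **Additive**: $W_{xy} = W_x + W_y - 1$ — fitness defects add regardless
  of background;
* **Minimum**: $W_{xy} = \min(W_x, W_y)$ — the more deleterious mutation is
  rate limiting;
* **Scott–Hwa**: $W_{xy} = (1/W_x + 1/W_y - 1)^{-1}$ — the exact double
  mutant of the two-sector proteome-allocation model described below.

For all laws, residuals are **observed − predicted**, so a law that
predicts fitnesses that are too high produces negative residuals. Because
the laws are ordered pointwise on $(0,1)^2$
(additive ≤ product ≤ Scott–Hwa ≤ minimum), the residual medians of the
wrong laws deviate with a known sign; the package asserts this ordering
numerically in its test suite.

A note on colony versus liquid growth: colony expansion rate scales as the
square root of the exponential growth rate of cells at the colony edge.
The Product law is closed under power transforms,
$(W_x W_y)^p = W_x^p\,W_y^p$, so fitnesses defined from colony expansion
and from single-cell exponential growth are equivalent from the Product
law's point of view. No dedicated transformation step is needed, and none
is provided.

## The empirical pipeline

`read_sga()` reads tab-separated screen exports (the column map is
configuration — `sga_colmap()` — because column headers vary across
releases), derives gene names from strain IDs by stripping the suffix after
the first underscore, and drops unparseable rows with counts.
Preprocessing follows two rules, in either order (they commute and are
idempotent):

1. *Deleterious filter*: remove records whose **single**-mutant fitness
   exceeds 1. Double-mutant fitnesses above 1 are retained by default: the
   filter restricts the analysis to deleterious mutations, not to
   deleterious outcomes. A strict mode also drops $W_{xy} > 1$.
2. *Additive-domain filter*: remove records with $W_x + W_y < 1$, for which
   the Additive law would predict a negative fitness; all laws are then
   compared on the same records. The boundary $W_x + W_y = 1$ (prediction
   exactly 0) is retained.

Residuals are summarised by the median and quartiles in 10 equal-width bins
of the **maximum** single-mutant fitness on $[0.5, 1]$; bins are half-open
on the right except the last, so a maximum fitness of exactly 1 is
included. Quantiles use linear interpolation between order statistics (R's
default type 7); the published analyses do not state a quantile method, so
the default is used and recorded here for reproducibility. Reported
statistics "at a maximum single-mutant fitness of 72%" refer to the bin
containing 0.72, i.e. $[0.70, 0.75)$ (`bin_at()`): 0.72 is not a bin centre
of the stated binning, and whether it denoted an edge, centre or regression
point is not stated, so the containing bin is the documented choice.

`fit_neutrality()` wraps residuals + binning and ranks laws by the mean
absolute binned median — an unbiased law keeps every bin median near zero
across the whole severity range, which is robust both to the severity
profile of the screen and to heavy residual tails.

## Biological-process pairs

Gene–process annotations come from a two-column TSV or a GAF 2.x file
(biological-process aspect only; evidence-code filtering available but off
by default, since the upstream analysis did not state one). Processes are
eligible when at least 50 genes (default; counting unique genes appearing
in the fitness dataset in either screen role, which the source analysis did
not distinguish) are annotated. All unordered pairs of eligible processes
that share **no** genes are enumerated; for each pair, records with one
gene in each process (either orientation — profiles are symmetric by
construction) are binned as above. With 47 eligible processes the pair
budget is $\binom{47}{2} = 1081$; the published gene-annotation release
determines how many of those survive the disjointness filter, so
database-version-dependent counts are not asserted on synthetic data.
`intra_vs_inter_tails()` compares records whose genes share a process
(intra) against records whose genes are annotated but share none (inter),
reporting two-sided tail fractions of the residual distribution; genes with
no eligible annotation are excluded and counted.

## The two-sector growth model

The simplest mechanistic account of the Product law divides the proteome
into translational ($\phi_t$, flux $\kappa_t\phi_t$), metabolic ($\phi_n$,
flux $\kappa_n\phi_n$) and fixed housekeeping ($\phi_o$) sectors with
$\phi_t + \phi_n + \phi_o = 1$. Under growth-optimising allocation no
protein is wasted, the two fluxes balance, and

$$\lambda = (1-\phi_o)\,\frac{1}{1/\kappa_t + 1/\kappa_n}.$$

Mutations multiply $\kappa_t$ or $\kappa_n$ by a factor
$\theta \sim U(0,1)$ (the open interval: $\theta = 0$ would give zero
growth and undefined fitness ratios). The two mutations of a double mutant
always target different parameters — same-parameter double mutations are
expected to interact and are out of scope throughout the package. Because
$(1-\phi_o)$ is a pure prefactor it cancels from every fitness ratio, which
is why the wild-type values of $\kappa_t$, $\kappa_n$ (defaults 1) and
$\phi_o$ (default 0) are immaterial; the package still exposes $\phi_o$
because a mutation to it combines exactly multiplicatively with any
efficiency mutation — the one case where the Product law is exact in this
model.

Three results follow, and each is verified against an independent numeric
route (`sh_growth_numeric()` maximises the limiting flux by bisection on
which sector is limiting, never touching the closed form):

* the double-mutant fitness has the closed form
  $W_{xy} = (1/W_x + 1/W_y - 1)^{-1}$ — the Product law divided by
  $W_x + W_y - W_xW_y \le 1$ — exact to numerical precision
  ($<10^{-9}$ over $10^4$ sampled double mutants);
* with the proteome allocation frozen at the wild-type optimum (no
  feedback), $W_{xy} = \min(W_x, W_y)$ exactly: the Minimum law is the
  no-feedback limit;
* for beneficial mutations ($\theta > 1$, default upper bound 2,
  configurable — the published range is not printed) the model fitness
  exceeds every classical law, and the closed form diverges when
  $1/W_x + 1/W_y \to 1$; at equal fitnesses the divergence sits exactly at
  $W_x = W_y = 2$.

## The whole-cell ODE model

The richer model tracks 14 state variables: internal nutrient, "energy",
free ribosomes, and free mRNA / ribosome–mRNA complexes / protein for four
classes (ribosomal, transporter, metabolic enzyme, housekeeping).
Transport and catabolism are Michaelis–Menten in their substrates; energy
activates transcription through $\omega = w\,a/(\theta + a)$ (threshold
$\theta_r$ for the ribosomal class, $\theta_x$ for the others, plus a Hill
autoinhibition of the housekeeping class) and sets the translation
elongation rate $g(a) = g_{max}a/(K_p + a)$; mRNAs compete for free
ribosomes by mass action; growth is the total translation flux over the
cell mass and dilutes every species. Wild-type parameters are shipped as a
versioned YAML asset (`inst/extdata/weisse_params.yaml`). The
$\theta_r \gg \theta_x$ asymmetry is load-bearing: it down-regulates
ribosome production when energy is scarce. (A single shared transcription
threshold was tried during development and rejected: with the published
transcription capacities it lets ribosomal mRNA swamp the other classes,
over-invests the proteome in ribosomes, and makes *reduced* ribosomal
transcription beneficial, contradicting the premise that the mutable
parameters are deleterious.)

**Steady states.** Two solvers are implemented and cross-checked. The
`integrate` route runs lsoda from a standard inoculum state until the
relative growth-rate drift over the last 10% of the horizon falls below
$10^{-8}$, doubling the horizon (up to 3 times) when it has not. The
`root` route runs a damped Newton iteration on the per-capita residuals
$f(y)/y$ in log-state space (finite-difference Jacobian, step cap of 4
log-units, halving line search), warm-started from a previous steady state
during scans and falling back to an integrate+Newton ladder (warm start,
then cold start) for severe mutants. The two routes agree to better than
$10^{-6}$ relative growth rate on random deleterious parameter draws (a
property test); scan batches are solved mildest-to-severest so each solve
starts near its solution.

**Mutational scans.** Nine parameters are considered mutable, each with a
deleterious direction: rates and efficiencies shrink
($\alpha' = \theta\alpha$, $\theta \sim U(0,1)$), Michaelis constants and
the housekeeping transcription capacity grow ($\alpha' = \alpha/\theta$).
The process grouping is: nutrient metabolism
$\{v_t, K_t, v_m, K_m\}$ (import and catabolism form one serial pathway
whose members are strongly interdependent — their pairwise double mutants
follow the Minimum law almost exactly, the signature of within-process
interaction), nutrient energy yield $\{n_s\}$, transcription
$\{w_e, w_q\}$, translation $\{g_{max}, K_p\}$; this gives 28
cross-process pairs. Two grouping choices deserve explanation:

* *Why not $w_r$?* At the published wild type the model is over-invested
  in ribosomal mRNA relative to its growth optimum, so shrinking $w_r$
  *raises* the growth rate at every transcription threshold tested; no
  deleterious shrink direction exists and all its mutants would be
  discarded. Rebalancing $w_r$ to the growth optimum was tried and
  rejected: it moves the model into a saturated-translation regime that
  destroys both the translation/non-translation split and the
  monotonicity of the $\gamma$ sweep.
* *Why $w_q$ grown?* Housekeeping overexpression is a clean,
  interpretable burden mutation (it drains ribosomes and energy), is
  monotone deleterious over the whole sampled range, and completes the
  transcription process pair. (Growing $\theta_x$ or the mRNA decay rate
  $d_m$ are monotone-deleterious alternatives; $\theta_x$ doubles as the
  sweep dial below and $d_m$'s fitness effects are too small to resolve
  deviations, so both were set aside.)

Mutants whose fitness exceeds 1 by more than the solver accuracy
($10^{-6}$, relative) are discarded and counted; fitnesses within that
tolerance of 1 are clamped to 1. Per pair, the mean deviation of the
sampled double-mutant fitnesses from each law is reported both absolute
(the headline, since the published figure does not state a sign
convention) and signed. Pairs in which one parameter is effectively
buffered (e.g. $K_m$, which internal-nutrient accumulation almost fully
compensates) have deviations at the numerical noise floor ($\sim10^{-7}$)
under *every* law; group-level comparisons are therefore the robust
statement of the translation/non-translation split, and the package's
acceptance checks compare group means plus per-group majorities rather
than every noise-floor pair individually.

**The $\gamma$ sweep.** $\gamma = 1/\theta_x$ measures how saturated
(nonlinear) the energy dependence of non-ribosomal transcription is. The
sweep rescales $\theta_x$ only, recomputes the wild type per value (so
fitnesses are relative to the matched wild type), and reuses the same
mutation draws across values, which removes Monte-Carlo noise from the
comparison. For $\gamma \gtrsim 0.1$ the steady-state energy exceeds
$\theta_x$ and transcription is saturated, so the curve is flat there; the
default sweep `c(0.1, 0.03, 0.01, 0.001)` samples the responsive decades,
over which the median absolute Product residual for the canonical
transport × nutrient-yield pair $(v_t, n_s)$ falls monotonically by nearly
three orders of magnitude — as transcription becomes linear in energy, the
Product law becomes near-exact. A closed-form approximation of the growth
rate for this pair exists but is validated here numerically through the
sweep rather than re-derived.

## The synthetic-data generator

`generate_fitness_table()` draws one single-mutant fitness per gene
i.i.d., samples distinct gene pairs, and sets
$W_{xy} = \mathrm{law}(W_x, W_y) + \varepsilon$,
$\varepsilon \sim N(0, \sigma^2)$ truncated below at 0 (default
$\sigma = 0.05$; a multiplicative mode is available). With an annotation,
records whose genes share a process can receive a larger
$\sigma_\mathrm{intra}$, giving ground truth for the intra/inter tail
comparison. Everything is byte-reproducible under a seed.

The default single-fitness distribution is a piecewise-uniform mixture
(blocks $[0.44, 0.58)$, $[0.58, 0.80)$, $[0.80, 0.97)$, $[0.97, 1]$ with
weights 0.55/0.28/0.15/0.02). This shape is a deliberate design choice in
favour of *statistical power over demographic realism*: the generator's
job is to validate the pipeline, which requires every maximum-fitness bin
on $[0.5, 1]$ to be well populated after the preprocessing filters
(roughly 4,000 records per bin at 50,000 pairs, so that a bin median of an
unbiased law is resolvable to about $\pm 0.003$). A distribution piled up
near 1 — the shape of real screens — necessarily starves the lowest bins:
the additive-domain filter requires *both* fitnesses in $[1-m, m]$ for a
record with maximum $m$, an event whose probability vanishes as
$m \to 0.5$ for any near-1-piled density. The realistic shape remains one
call away (`fitness_dist = list(family = "beta", shape1 = 8, shape2 = 2,
point_mass = 0.25)`). Consequences for interpretation: passing tests show
the pipeline is unbiased and recovers the generating law across the whole
severity axis; they do not certify behaviour under real screens'
severity profile, batch structure, or shared-gene correlation (single
fitnesses here are exact, whereas real single-mutant fitnesses carry
measurement error of their own).

## Orchestration and problem sizes

`run_empirical()` and `run_models()` chain the stages with plain CSV/JSON
outputs and a manifest (package version, configuration hash, seeds); reruns
with the same configuration are byte-identical, and all randomness flows
through the recorded seeds. This package is an R library, not a shell
tool: the two functions plus this vignette are its orchestration surface.

Default problem sizes were chosen so a full check runs comfortably on one
CPU: $10^4$ two-sector double mutants for the closed-form exactness check,
200 mutants per whole-cell parameter pair (28 pairs), 500 mutants per
$\gamma$ value, and 100 replicates of 50,000 pairs per generating law for
the recovery study. The whole-cell scans dominate (a few minutes); the
compiled right-hand side and warm-started Newton continuation are what
keep 20,000-odd steady-state solves cheap.

## Known limitations

* The empirical headline numbers require the public SGA deposit (Dryad
  10.5061/dryad.4291s, hundreds of megabytes); the package ships the full
  loader and filter machinery but not the data. The corresponding check
  runs only where the download has been staged (see
  `tests/testthat/test-acceptance.R`).
* Interaction-profile correlation clustering (assigning processes from
  residual-vector correlations) and significance testing of individual
  interactions are out of scope.
* The whole-cell model's mutable-parameter identity and grouping are a
  reconstruction constrained by the printed pair count and figure
  patterns (28 cross-process pairs; translation pairs best described by
  the two-sector closed form); alternative groupings are available via
  `weisse_mutable_params("sector")`.
* GO ancestor-term propagation is not performed; annotations are used as
  given.
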