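---
title: "Estimating SNP heritability of rare binary traits: models, choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating SNP heritability of rare binary traits: models, choices and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

For rare pharmacological traits such as idiosyncratic drug-induced liver
injury (DILI), family and twin data are essentially unobtainable, so the
classical routes to heritability are closed. What can be obtained are
case-control genome-wide SNP panels. `snph2` implements the GREML route to
the quantity of interest — the proportion of variance in *liability* to the
trait captured jointly by common genotyped SNPs — together with the two
corrections that case-control data from a rare trait force on the analysis:
a post-hoc transformation from the 0/1 observed scale to the liability scale
with ascertainment correction, and principal-component adjustment for global
population structure.

## Model

Disease status enters as it is analysed: a 0/1 vector `y` in a linear mixed
model on the observed scale,

$$ y = X\beta + g + \varepsilon,\qquad
   g \sim N(0, \sigma^2_g A),\quad \varepsilon \sim N(0, \sigma^2_e I), $$

where `A` is the genetic relationship matrix (GRM) over individuals.
Off-diagonal entries average standardised-genotype products over SNPs
non-missing in both individuals; the diagonal uses the less noisy
GCTA-style estimator (see `?compute_grm` for both formulas). Fitting this
*linear* model to a binary trait and transforming afterwards — rather than a
liability-link GLMM — is deliberate: it is the procedure whose behaviour the
package is built to study and reproduce, and the one used by the standard
tooling (GCTA) in this literature.

Variance components are estimated by restricted maximum likelihood. The
restricted log-likelihood (constants dropped) is

$$ \ell_R = -\tfrac12\left[\log|V| + \log|X'V^{-1}X| + y'Py\right], $$

maximised by one EM step from equal-split starting values followed by
average-information (AI) updates. Three numerical safeguards matter in
practice:

* **Step-halving.** Any proposed move that decreases $\ell_R$ (or leaves the
  positive-definite region) is halved up to 30 times; when an AI move cannot
  improve, an EM step is tried; when nothing improves, the current point is
  accepted as the optimum. Accepted iterations therefore never decrease the
  likelihood.
* **Constraints.** By default variance components are clamped at a floor of
  $10^{-6}\,\mathrm{Var}(y)$, which also bounds observed-scale $h^2$ to
  $[0,1]$. Estimates on the floor are flagged `boundary`; their inverse-AI
  standard errors are reported but not trustworthy (and the pile-up of null
  estimates exactly at 0 is a consequence of the constraint, not of the
  optimiser — with `constrain = FALSE`, null-trait $\hat\sigma^2_g$ goes
  negative about half the time, as it should).
* **Convergence** is declared when the change in $\ell_R$ falls below
  `tol` (default 1e-8) — parameter agreement across algorithms is then at
  the ~1e-6 level, which is why cross-route tests compare at 1e-4..1e-6
  rather than machine precision.

Single-GRM fits are computed in the eigenbasis of `A`: one symmetric
eigendecomposition, after which every iteration is O(n) — this is exact, not
an approximation, because the likelihood is orthogonally invariant. Joint
multi-component fits (e.g. chromosome 6 + rest) use dense algebra. The
public `restricted_log_likelihood()` keeps an independent dense evaluation
so that grid-search cross-checks do not share code with the fit path.

## Scale transformation

With population prevalence `K`, liability threshold $t = \Phi^{-1}(1-K)$,
normal density $z = \phi(t)$ and sample case proportion `P`, estimates map
to the liability scale as

$$ h^2_l = h^2_{obs}\,\frac{K(1-K)}{z^2}\,\frac{K(1-K)}{P(1-P)}, $$

standard errors by the same factor (the map is linear). At `K = P = 0.5`
the factor is exactly $\pi/2$; with `P = K` it reduces to the
no-ascertainment form $K(1-K)/z^2$; it is strictly increasing in `K` below
0.5, which is why the same fitted model reported at a larger assumed
prevalence yields a larger liability-scale estimate. Whether published
analyses of this kind used the ascertainment-corrected or the plain factor
is usually not recoverable from a published report; both are implemented
(`ascertained = TRUE/FALSE`), the corrected form being the default since `P`
in these designs is orders of magnitude above `K`. `P` is always computed
from the analysed phenotype vector rather than typed in, to avoid
mismatches; the arguments allow overriding when reproducing printed rows.

**Known limit.** The linear transformation is first-order. Under strong
ascertainment (e.g. `P = 0.25` against `K = 0.008`) with substantial
heritability it attenuates: in this package's own recovery experiment
(20 cohorts, true liability $h^2 = 0.5$, 200 cases / 600 controls, 5,000
SNPs) the mean estimate is ~0.45, a ~9% shortfall, while the identical
pipeline with no ascertainment (`K = P`) recovers 0.50. This behaviour is a
property of the method, matches what the GREML case-control literature
reports at comparable settings, and should be kept in mind when reading
liability-scale point estimates for very rare traits.

## The synthetic-data generator

Because the real cohorts this methodology is applied to are
access-restricted, every downstream stage is exercised on synthetic cohorts
whose generative model matches the estimator's assumptions:

* SNPs independent given ancestry, ancestral frequencies uniform on
  `maf_range` (default 0.05–0.5); two-subpopulation structure, when wanted,
  via a Balding–Nichols model at a chosen $F_{st}$.
* Causal effects i.i.d. normal per chromosome, rescaled so each
  chromosome's share of liability variance is *exact* (effects act on
  dosages standardised at the generating frequency, the same standardisation
  GREML assumes), residual liability $N(0, 1-h^2)$ — liabilities have unit
  population variance by construction.
* Cases are liabilities above $\Phi^{-1}(1-K)$; ascertainment is by
  rejection sampling until the case quota is met, keeping the first
  `ratio × n_cases` controls — so case genotype distributions are exactly
  right, with no truncated-liability shortcut. A `max_draws` cap (default
  1e7) turns an infeasible quota into an informative error. During the
  rejection loop only causal genotypes are drawn; non-causal genotypes are
  filled in for retained individuals afterwards, which is exact because
  non-causal SNPs are independent of liability, and is what keeps
  `K = 0.008` with hundreds of cases affordable.
* One integer seed drives named RNG streams (frequencies / effects /
  genotypes / residuals / missingness), so toggling missingness does not
  perturb the genotypes — a property the tests assert.

What the generator does **not** emulate: linkage disequilibrium (SNPs are
exchangeable within a chromosome), realistic allele-frequency spectra,
genotyping batch effects or imputation error. Passing recovery tests here
demonstrates the estimator and transformations are implemented correctly
under their own assumptions — not that real-cohort estimates are unbiased.
The LD-shrinkage adjustment (`adjust_grm_ld()`, the
$\beta = 1-(c+1/N)/\mathrm{Var}(A_{jk})$ form of the tool option it mirrors)
is therefore exercised algebraically rather than against simulated LD.

## Experiment drivers and their conventions

* `run_partitioned()` fits the all-SNP, focal-chromosome (default "6",
  where the MHC lives) and complement GRMs as *separate single-component*
  models, then transforms at each requested prevalence. Separate fits are
  the default because published per-chromosome tables of this kind have
  components that do not sum to the genome-wide estimate, which is the
  signature of separate fits; a joint fit is available by passing both GRMs
  to `fit_reml()` in a list.
* `run_subsample()` draws cases and controls without replacement within a
  replicate (overlap across replicates allowed), re-runs the full pipeline
  per draw, and reports mean and *SD across replicates* — whereas the
  partitioned and negative-control reports carry the *model SE*. These are
  the two different "(·)" conventions used in this literature; the package
  keeps both explicit in its report columns.
* `run_negative_control()` runs the all-SNP pipeline on cohorts whose
  labels are independent of genotype by construction
  (`simulate_null_cohort()`), the analog of coding one study's controls as
  pseudo-cases against another's controls. Structure adjustment defaults to
  0 PCs for homogeneous cohorts and is worth 2 PCs when two subpopulations
  are present — the structure-confounded null in the tests shows the
  inflation without PCs and its collapse with them.

## Problem sizes

The shipped tests and the acceptance script run at desk scale, chosen to
keep every stochastic check's Monte-Carlo error well below its assertion
margin: 5,000 SNPs and 1,152 individuals for the negative control
(20 seeds), 5,000 SNPs and 800 individuals for recovery and subsampling
(20 replicates each), a few hundred SNPs for oracle-equivalence checks.
Dense algebra is used throughout — at these n there is nothing to gain from
sparse or low-rank paths, and the code stays transparent against the
formulas above.

## Defaults worth knowing

| parameter | default | why |
|---|---|---|
| `maf_min` (GRM) | 0.01 | "common variants" framing; QC thresholds of the motivating cohorts are unpublished, so this is exposed rather than hard-coded |
| `case_control_ratio` | 3 | the 1:3 design of the motivating subsampling experiments |
| `pcs` (partitioned) | 2 | the standard two-PC global-structure adjustment |
| `pcs` (subsample/negative control) | 0 | these emulate homogeneous-population designs |
| `adj_ld` | off; `c = 0` when on | the usual setting of the tool option it mirrors |
| REML `tol` | 1e-8 on $\Delta\ell_R$ | parameter agreement ~1e-6, ample for SE-scale conclusions |
| prevalence presets | 0.0001–0.0005 (DILI), 0.008 (T1D) | the literature's estimates for the motivating traits |

## Limitations

Autosomal, additive, PLINK-v1-era data model only: no dominance or
interaction components, no X-chromosome dosage model, no VCF/pgen ingestion,
no GWAS or prediction. The liability transformation supports a single
population prevalence; multiple-threshold or covariate-dependent prevalence
models are out of scope.
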