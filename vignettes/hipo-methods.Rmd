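---
title: "Power-optimized multi-trait association testing: model, estimation and simulation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Power-optimized multi-trait association testing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hipower)
```

# The model

`hipower` operates entirely on GWAS summary statistics for $K$ genetically
correlated traits, standardized so that genotypes and phenotypes have unit
variance. For SNP $j$, the vector of single-SNP regression estimates
$\hat\beta_j$ is modelled as multivariate normal around the marginal
effects $\beta_j$ with a sampling covariance $\Sigma_{\hat\beta}$ that is
the same for all SNPs on this scale. $\Sigma_{\hat\beta}$ is diagonal with
entries $1/N_k$ only when the $K$ studies are disjoint and unconfounded;
shared samples and population structure make it non-diagonal, which is why
it is estimated rather than assumed.

Marginal effects arise from "joint" (causal) effects through LD:
$\beta_j = \sum_{j'} \beta^{(J)}_{j'} r_{jj'}$, and under the standard
polygenic random-effect model $\beta^{(J)}_j \sim N(0, \Sigma_g/M)$ this
gives $E[\beta_j \beta_j^T \mid l_j] = l_j \Sigma_g / M$ with $l_j$ the LD
score. Averaged over the genome, the non-centrality parameter of the
$\chi^2$ test of a combined trait $c^T\hat\beta$ is therefore

$$E[\delta] = \frac{E[l]}{M} \,
  \frac{c^T \Sigma_g c}{c^T \Sigma_{\hat\beta} c},$$

and maximizing it is a generalized Rayleigh-quotient problem. With the
symmetric inverse square root $S = \Sigma_{\hat\beta}^{-1/2}$, the
components are $c_k = S u_k$ for the eigenvectors of $S \Sigma_g S$
(`hipo_decompose()`); eigenvalues are the average NCPs up to the common
factor $E[l]/M$ (`average_ncp()`). Per-SNP tests along each component are
plain normal z-tests because the constraint fixes the combined statistic's
sampling variance at one.

Key assumptions worth keeping in mind:

* *genome-wide* optimality — the weights maximize the **average** NCP, so
  individual SNPs whose effect pattern is atypical for the genome can be
  better detected by a single trait or by subset-search methods;
* the random-effect model ties effect variance to LD scores linearly
  (single annotation component, no MAF-dependent architecture);
* the composite null hypothesis is "no association with *any* trait": a
  significant component does not attribute the signal to a trait.

## Relationship to meta-analysis and to the moment estimator

When all traits have equal heritability, genetic correlation 1 and no
sample overlap, the first component reduces exactly to inverse-SE-weighted
fixed-effect meta-analysis (`meta_z()`); the test suite asserts this
identity at $10^{-8}$. The moment estimator of `mtag()` targets a
different quantity — an improved per-trait effect estimate — but is also a
linear combination of $\hat\beta$ and is implemented from the same inputs
($\Omega$, $\Sigma_{\hat\beta}$) for head-to-head comparison. The printed
form of its solution is the generalized-least-squares solution of the
moment condition $E[\hat\beta_j - (\omega_k/\omega_{kk})\beta_{jk}] = 0$;
the tests verify the closed form against a numeric GLS minimizer. We set
$\Omega = (\bar l / M)\,\Sigma_g$, consistent with the random-effect model
above; refinements of $\Omega$ estimation from the original moment-method
literature are out of scope.

# Estimating the covariances

`estimate_covariances()` runs cross-trait LD-score regression for all
$K(K+1)/2$ pairs: the products $z_{jk} z_{jl}$ are regressed on LD scores;
the slope scales to the genetic covariance
($\hat\rho_g = \hat s M / \sqrt{N_k N_l}$) and the intercept estimates
$N_{kl}\,\mathrm{cov}(y_k,y_l)/\sqrt{N_k N_l}$ — confounding plus
sample-overlap — giving
$\Sigma_{\hat\beta}[k,l] = \widehat{\mathrm{Int}}[k,l]/\sqrt{N_k N_l}$.

Choices made here, with rationale:

* **Weights** — a two-pass scheme: a preliminary unweighted pass yields
  $\hat h^2$ for each trait (clipped to $[0,1]$), then the final pass
  weights each SNP by $1/\max(l_j, 1)$ (over-counting of correlated SNPs)
  times $1/[(1 + N_k \hat h^2_k l_j/M)(1 + N_l \hat h^2_l l_j/M)]$
  (heteroskedasticity). This is the conventional scheme for this
  regression; we adopt it as-is.
* **Standard errors** — delete-block jackknife over 200 contiguous SNP
  blocks, reported for diagnostics (and used by the test suite's
  recovery checks); the component weights never use them.
* **PSD repair** — the pairwise-assembled matrices need not be positive
  (semi-)definite. $\Sigma_g$ is repaired by clipping eigenvalues at 0.
  $\Sigma_{\hat\beta}$ must be invertible, so it is repaired on its
  correlation scale (clip at $10^{-8}$, restore the diagonal), keeping
  per-trait sampling variances untouched. Pre-repair matrices are kept in
  the result; a repair that moves eigenvalues by more than `repair_tol`
  warns rather than errors, since downstream results remain well-defined.
* **Bypass** — `covariance_set()` lets the user supply both matrices
  directly. This is essential for simulation studies with known truth and
  for sensitivity analyses.

# The summary-statistic simulator

`simulate_sumstats()` generates studies directly at the summary level:
$\hat\beta_j = \beta_j + v_j + e_j$ with

* $\beta_j$: `m_causal` causal SNPs drawn uniformly, joint effects i.i.d.
  $N(0, \Sigma_g/m_{causal})$, spread into marginal effects through the LD
  panel over a 1 Mb window with an $r^2 > 0.01$ floor;
* $v_j$: i.i.d. $N(0, \Sigma_v)$ population-stratification effects;
* $e_j$: estimation noise drawn **exactly** from $N(0, R \otimes
  \Sigma_e)$ blockwise, where $\Sigma_e[k,l] = N_{kl}\,
  \mathrm{cov}(y_k,y_l)/(N_k N_l)$ encodes sample sizes and pairwise
  overlap. Per LD block, $E_b = L_b G \Lambda^T$ with Cholesky factors of
  $R_b$ and $\Sigma_e$ — the same target distribution as running a
  null-phenotype GWAS on a genotype reference panel, without needing one.

The LD panel (`make_ld_panel()`) is a synthetic stand-in for a sequenced
reference panel: AR(1) correlation blocks (or arbitrary user-supplied
block matrices), laid out across chromosomes with inter-block gaps larger
than the LD window. One master seed derives independent sub-streams for
the panel, effects, stratification and errors, so components can be
regenerated separately and runs are bit-reproducible.

`reference_sim_config()` encodes the reference study conditions used
throughout the tests: the blood-lipid (LDL/HDL/TG/TC) and psychiatric
(ASD/BIP/SCZ) genetic and phenotypic covariance structures, the
$h^2_{max} \in \{0.1, 0.2, 0.35, 0.5\}$ heritability scale, sample sizes
10K–500K with complete overlap by default, a 1% causal fraction, and a
stratification covariance of $7.35\times10^{-8}$ per SNP (unit diagonal,
0.5 off-diagonal pattern) — about 25% of the per-SNP heritability at
$h^2_{max} = 0.35$ over 1.2M SNPs. When a run simulates $M < 1.2$M SNPs,
$\Sigma_g$ is scaled by $M/1.2\mathrm{M}$: this holds every **per-SNP**
variance component (per-causal-variant effect size, per-SNP heritability,
stratification and sampling variances) at its full-scale value, so
calibration and inflation behave as in the full-size design while
simulations stay desk-sized.

## What the simulator does and does not emulate

It reproduces the correlation structure that matters for calibration of
the composite tests: LD between neighbouring SNPs, cross-trait phenotypic
correlation, sample overlap, and stratification acting jointly on all
traits. It does **not** emulate realistic LD-score heterogeneity (real
human LD scores average ~110 with a long tail; AR(1) blocks give a narrow
range slightly above 1), MAF-dependent architectures, or per-SNP sample
size variation. Consequently, passing tests demonstrate correct
calibration, covariance recovery and relative power of the composite
tests under the modelled structure — not the absolute locus yields of a
full-size human GWAS, which additionally depend on the LD-score
distribution of the genome.

The narrow LD-score range has one practical consequence documented here:
within a *single* reduced-size replicate, the regression's slope and
intercept are nearly collinear, so per-replicate LDSC-estimated
covariances are noisy, and the component optimizer can exploit the
anticorrelated slope/intercept errors, inflating the composite test. The
replicated type-I-error studies (`type1_study()`) therefore default to
the generating covariance pair — $\Sigma_g$ from the design and
$\Sigma_{\hat\beta} = \Sigma_e + \Sigma_v$, the exact sampling covariance
of null effect estimates and the probability limit of the LDSC intercept
matrix. This isolates the calibration property of the test itself;
accuracy of the LDSC estimates is validated separately, within jackknife
standard errors, by the covariance-recovery tests. An `"ldsc"` mode runs
the full per-replicate estimation for users who want the joint behaviour.

# Post-processing conventions

* **Clumping** (`clump()`): greedy by significance — the most significant
  remaining SNP below the threshold seeds a locus and absorbs everything
  within 0.5 Mb *or* at $r^2 \ge 0.1$; deterministic given inputs. The
  alternative 1 Mb radius used for sensitivity analyses is a parameter.
* **Novelty** (`novel_loci()`): a component locus is novel only if its
  lead is $\ge$ 0.5 Mb from *and* at $r^2 < 0.1$ with every single-trait
  lead — a conjunction, matching the definition used for reporting novel
  regions.
* **True-locus matching** (`classify_true_loci()`): a locus counts as a
  true discovery when its lead is within 0.5 Mb of, or in LD
  ($r^2 \ge 0.1$) with, any SNP of nonzero marginal effect, with
  inclusive boundaries. No standard definition exists for this matching
  rule, so it is configurable and echoed in every report.
* **Thresholds**: genome-wide significance $5\times10^{-8}$ throughout;
  `bonferroni_threshold(n_traits, n_components)` divides it by the number
  of tests actually interpreted (e.g. $8.3\times10^{-9}$ for 4 traits + 2
  components).

# Numerical choices

* $\Sigma_{\hat\beta}^{-1/2}$ via symmetric eigen-decomposition, not
  Cholesky, so the orthogonality constraints are treated symmetrically;
  eigenvalues below $10^{-12}$ of the largest raise an error pointing to
  `repair_psd()`.
* Component signs are fixed by making each weight vector's
  largest-magnitude entry positive; any sign choice is statistically
  equivalent ($|z|$ and $p$ are invariant), this one makes output
  reproducible. For coinciding eigenvalues any rotation of the eigenspace
  is statistically equivalent; the deterministic order returned by the
  symmetric eigen-solver is kept.
* All $K$ components are reported with their average NCPs; users retain
  the top ones when a few eigenvalues dominate.
* The QC sample-size rule (drop SNPs with $n < 0.67 \times$ the 90th
  percentile) computes its threshold once, from the table the filter first
  sees, and records it on the result. Recomputing the quantile on a
  filtered table can cascade (removing low-$n$ SNPs raises the
  percentile), so the recorded threshold is reused on re-application,
  making the filter idempotent.
* Strand-ambiguous (A/T, C/G) SNPs are dropped in harmonization by
  default — the conservative convention when reference and study strands
  cannot be reconciled — with a flag to keep them.
* Near-singular LD blocks get a $10^{-10}$ Cholesky jitter; exact-zero
  covariance matrices short-circuit to exact-zero draws.

# Problem sizes used by the shipped studies

The replicated studies in the test suite and in `scripts/acceptance.R`
use $M = 120{,}000$ SNPs (12,000 AR(1) blocks of 10, decay 0.5), a 1%
causal fraction, 20 replicates per design point, and the reference
covariance structures above — about $2.3\times10^6$ null-SNP draws per
design point, enough to resolve rates at the $10^{-3}$ threshold within a
few percent. Covariance-recovery checks use a heterogeneous panel (blocks
of 5 at decay 0.3 mixed with blocks of 15 at decay 0.9) to widen the
LD-score range that identifies the regression slope. These sizes are the
package's chosen reference conditions for desk-scale validation.

# Known limitations

* Average-NCP optimality is genome-wide; per-SNP optimal subset methods
  can win on atypical pleiotropy patterns.
* Significant components test the global null only; attribution to an
  individual trait needs follow-up.
* Single LD-annotation component; no partitioned heritability.
* No confidence intervals on component weights; weight instability under
  noisy $\Sigma_g$ (small $N$, weak heritability) is visible as
  replicate-to-replicate weight variation in simulations.
* The bundled LD panel is synthetic; analyses of real data should supply
  LD scores computed from an ancestry-matched reference panel.
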