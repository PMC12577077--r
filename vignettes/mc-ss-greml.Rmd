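---
title: "Monte Carlo single-step REML: model, samplers and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Monte Carlo single-step REML: model, samplers and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mcgreml)
```

## The model

mcgreml estimates (co)variance components of multi-trait animal models

$$\mathbf{y} = \mathbf{Xb} + \mathbf{Wp} + \mathbf{Zu} + \mathbf{e},$$

with fixed class effects $\mathbf b$ (contemporary groups), identity-structured
random effects $\mathbf p \sim N(0, \mathbf P_0 \otimes \mathbf I)$ (permanent
environment, maternal permanent environment), genetic effects
$\mathbf u \sim N(0, \mathbf G_0 \otimes \mathbf H)$ (direct and maternal
columns sharing one relationship structure), and residuals
$\mathbf e \sim N(0, \mathbf R_0 \otimes \mathbf I)$ with per-record
missingness handled by restricting $\mathbf R_0$ to each record's observed
traits. $\mathbf H$ is the single-step relationship matrix: pedigree
relationships $\mathbf A$ for everyone, marker-based relationships
$\mathbf G$ for the genotyped subset, joined through
$\mathbf H^{-1} = \mathbf A^{-1} + \begin{bmatrix}0&0\\0&\mathbf G^{-1}-\mathbf A_{22}^{-1}\end{bmatrix}.$

REML maximizes the likelihood of error contrasts; with
$\theta$ the collection of $\{\mathbf G_0, \mathbf P_0, \mathbf R_0\}$,

$$-2\ell(\theta) = \log|\mathbf V| + \log|\mathbf X'\mathbf V^{-1}\mathbf X| + \mathbf y'\mathbf P\mathbf y .$$

The derivative with respect to a group's covariance matrix is
$q_k\theta_k^{-1} - \theta_k^{-1}(\mathbf T_k + \mathbf S_k)\theta_k^{-1}$
with $\mathbf S_k[i,j] = \hat{\mathbf k}_i'\mathbf K^{-1}\hat{\mathbf k}_j$
(cheap, from the MME solutions) and
$\mathbf T_k[i,j] = \mathrm{tr}(\mathbf K^{-1}\mathbf C^{k_ik_j})$
(expensive: blocks of $\mathbf C^{-1}$). The residual derivative has the
analogous data term and a trace
$\mathrm{tr}(\mathbf R^{-1}\mathbf R_{ij}\mathbf R^{-1}\mathbf Q\mathbf C^{-1}\mathbf Q')$.
EM sets these derivatives to zero; AI-REML takes Newton-type steps with the
average-information matrix
$\mathrm{AI}(\theta_p,\theta_q) = \mathbf y'\mathbf P \dot{\mathbf V}_p \mathbf P \dot{\mathbf V}_q \mathbf P\mathbf y$.

## Monte Carlo traces

The traces are the only quantities that need $\mathbf C^{-1}$. They are
replaced by a Hutchinson-type estimator: since
$\mathrm{tr}(\mathbf T\mathbf C) = E(\mathbf c'\mathbf T\mathbf c)$ for any
zero-mean $\mathbf c$ with covariance $\mathbf C$, simulating data from the
current model, solving the MME, and averaging quadratic forms of the
simulated solutions estimates the traces unbiasedly:

$$\hat{\mathbf T}_k[i,j] = q_k\theta_k[i,j] - s^{-1}\sum_{l=1}^{s}
\hat{\tilde{\mathbf k}}_{i_l}'\mathbf K^{-1}\hat{\tilde{\mathbf k}}_{j_l},$$

and the residual trace term is estimated by
$n_{ij}\mathbf R_0[i,j] - s^{-1}\sum \hat{\tilde{\mathbf e}}_i'\hat{\tilde{\mathbf e}}_j$
over records with both traits observed. "Centered" variants that average
quadratic forms of (truth − estimate) are implemented behind a flag; the
primary forms are the default because the centered ones need more samples
for the same accuracy. The residual products use identity weighting between
residual vectors: residuals are independent across records given
$\mathbf R_0$, and the dense oracle confirms
$E\!\left(\sum \hat{\tilde e}_i\hat{\tilde e}_j\right) = n_{ij}\mathbf R_0[i,j] - \sum_{rec} (\mathbf Q\mathbf C^{-1}\mathbf Q')_{ij}$,
which is exactly the needed term.

One refinement relative to the aggregate formula: both the Monte Carlo and
the exact paths accumulate the matrices
$\sum_{rec \in \pi} (\mathbf Q\mathbf C^{-1}\mathbf Q')_{cd}$ *per
missingness pattern* $\pi$. The aggregate estimator is their sum, while the
full residual gradient under arbitrary missingness needs the per-pattern
form (each pattern has its own restricted $\mathbf R_\pi^{-1}$ sandwich).
With complete records the two coincide.

## Sampling $\tilde{\mathbf u} \sim N(0, \mathbf G_0 \otimes \mathbf H)$ without H

Per Monte Carlo sample, with $\mathbf L\mathbf L' = \mathbf G_0$:

1. **Gene dropping.** For each animal in pedigree order,
   $\mathbf a_i = \tfrac12(\mathbf a_{s_i} + \mathbf a_{d_i}) + \sqrt{\phi_i}\,\mathbf L\tilde{\mathbf x}$,
   where $\phi_i$ is the Mendelian sampling variance
   ($0.5 - 0.25(F_s + F_d)$ with both parents known, $0.75 - 0.25F_p$ with
   one, 1 with none; $F$ from the Meuwissen–Luo recursion). This gives
   $\mathbf a \sim N(0, \mathbf G_0 \otimes \mathbf A)$.
2. **Marker effects.** $\mathbf g_i = \mathbf L\tilde{\mathbf x}\,(2\sum p q)^{-1/2}$
   per locus, so that $\mathbf M\mathbf g$ has covariance
   $\mathbf G_0 \otimes \mathbf G_{raw}$ with the VanRaden matrix
   $\mathbf G_{raw} = \mathbf M\mathbf M'/(2\sum pq)$, $\mathbf M$ centred by
   twice the observed allele frequencies.
3. **J-factor.** $\mu = \mathbf L\tilde{\mathbf x}\sqrt{v}$ with
   $v = n^{-2}\mathbf 1'(\mathbf A_{22} - \mathbf G_{raw})\mathbf 1$, the
   base-population alignment between genomic and pedigree relationships.
4. **Combination.** For the genotyped animals
   $\tilde{\mathbf u}_2 = \sqrt{1-\alpha}(\mathbf 1\mu + \mathbf M\mathbf g) + \sqrt{\alpha}\,\mathbf a_2$
   and
   $\delta = \sqrt{1-\alpha}(\mathbf 1\mu + \mathbf M\mathbf g) + (\sqrt{\alpha}-1)\mathbf a_2$.
5. **Non-genotyped animals.**
   $\tilde{\mathbf u}_1 = \mathbf A_{12}\mathbf A_{22}^{-1}\delta + \mathbf a_1$,
   computed by default through the sparse identity
   $\mathbf A_{12}\mathbf A_{22}^{-1} = -(\mathbf A^{11})^{-1}\mathbf A^{12}$
   on the blocks of $\mathbf A^{-1}$ (a dense $\mathbf A_{22}$ solve is kept
   as a cross-check backend).

Under APY the genotyped set splits into core and non-core; steps 4–5 use the
core animals only, and non-core values are the regression
$\mathbf P_{nc}\tilde{\mathbf u}_c$ plus an independent error with the
diagonal conditional variances
$\Psi = \mathrm{diag}(\mathbf G_{nn} - \mathbf G_{nc}\mathbf G_{cc}^{-1}\mathbf G_{cn})$.
With every genotyped animal in the core, the APY sampler is bit-identical to
the full one under the same deviate stream. Residuals are drawn per record
from the pattern-restricted $N(0, \mathbf R_0[\pi,\pi])$, and
$\tilde{\mathbf y} = \sum_k \mathbf Z_k\tilde{\mathbf k} + \tilde{\mathbf e}$
(fixed effects contribute nothing to the simulated records but stay in the
fitted model).

### G blending: a deliberate convention choice

The variance of $\tilde{\mathbf u}_2$ implied by step 4 is
$(1-\alpha)(\mathbf G_{raw} + v\mathbf 1\mathbf 1') + \alpha\mathbf A_{22}$,
with weights $(1-\alpha), \alpha$ — not $\sqrt{1-\alpha}, \sqrt{\alpha}$. The
matrix used inside $\mathbf H^{-1}$ must be the covariance the sampler
realises, otherwise the simulated MME solutions do not have the sampling
distribution the trace estimator assumes; mcgreml therefore blends with the
variance-consistent weights by default (`blend = "variance"`). The
square-root convention is available as `blend = "sqrt"` for comparison. The
default residual polygenic fraction is `alpha = 0.05`, which also keeps the
blended G safely positive definite.

## Estimation loop and safeguards

Each round: solve the data MME (PCG, tolerance `1e-10`, warm-started from
the previous round); compute $\mathbf S_k$ and residual products; obtain
traces (Monte Carlo, default `s = 30` samples solved as one blocked PCG
system at tolerance `1e-6` and cold-started — warm-starting sample solves
does not help; or exact, from the dense inverse at desk scale); evaluate the
exact restricted log-likelihood; update $\theta$.

* **EM**: $\theta_k \leftarrow (\mathbf T_k + \mathbf S_k)/q_k$,
  $\mathbf R_0[i,j] \leftarrow (\hat{\mathbf e}_i'\hat{\mathbf e}_j + \text{trace term})/n_{ij}$.
  Monotone in $-2\ell$ with exact traces; linear convergence.
* **AI**: $\mathrm{vech}(\theta)^+ = \mathrm{vech}(\theta) - \mathrm{AI}^{-1}\nabla$.
  The AI matrix is built from one MME solve per free parameter
  ($f_p'\mathbf P f_q = f_p'\mathbf R^{-1}f_q - f_p'\mathbf R^{-1}\mathbf Q\,\mathbf C^{-1}\mathbf Q'\mathbf R^{-1}f_q$);
  the augmented-MME formulation that solves once for all parameters is a
  known alternative but the per-parameter form is simpler and adequate at
  the scales this package targets. If a step leaves the parameter space
  (any unmasked block or observed residual pattern loses positive
  definiteness), the AI matrix is blended with a Wishart-style expected
  information of the prior and residual terms at escalating weights
  $w \in \{0.1, 0.3, 0.5, 0.9, 1\}$; the final fallback is the plain EM
  update. The blending schedule is this package's own choice.

Structural zeros (e.g. a residual covariance fixed at zero between traits
recorded on disjoint animal sets, or zero genetic covariances between some
maternal and direct columns) are declared as symmetric masks; masked entries
are excluded from the free-parameter vector and forced to zero after every
update.

**Convergence** combines a strict round-to-round relative parameter change
($\Delta\theta < t_1 = 10^{-12}$, with $\varepsilon = 10^{-10}$ in the
denominators) with the coefficient of variation of the restricted
log-likelihood over the five most recent rounds
($\mathrm{CV} < t_2 = 10^{-4}$). Monte Carlo noise makes $\Delta\theta$
alone unattainable; the CV criterion works because the likelihood and the
trace estimates are computed from the *same deviate sequence every round*
(`reuse_sequence = TRUE`), so round-to-round variation reflects only the
parameter updates. Sequence reuse is structural here: every draw site is
keyed by `(base seed, sample index, site name)` through a counter-style
reseeding scheme, the number of deviates consumed never depends on
$\theta$, and blocked and per-sample evaluation orders consume identical
numbers. The log-likelihood itself is computed exactly from sparse
factorizations,
$-2\ell = \log|\mathbf C| + \log|\mathbf R| + \sum_k (q_k\log|\theta_k| + t_k\log|\mathbf K_k|) + \mathbf y'\mathbf P\mathbf y$
with $\log|\mathbf H| = \log|\mathbf A| - \log|\mathbf A_{22}| + \log|\mathbf G|$;
a fast stochastic likelihood approximation would serve the same role at
large scale but is not needed at desk scale and is not implemented.

**Standard errors** are $\sqrt{\mathrm{diag}(2\,\mathrm{AI}^{-1})}$ at the
optimum; the factor 2 reflects that the AI matrix tracks the curvature of
$-2\ell$. The factor is pinned by the closed-form information of the
balanced one-way design in the test suite.

Starting values are 1.0 for variances and 0.1 for covariances unless
overridden.

## Solver details

The MME coefficient matrix is assembled as one sparse matrix; the H-group
prior blocks use the scatter structure
$\mathbf A^{-1} + (\mathbf G^{-1} - \mathbf A_{22}^{-1})$, with
$\mathbf G^{-1}$ dense or the sparse APY inverse. At the scales this package
targets (a few thousand equations) materializing the genotyped-block
correction is cheap; the same code path would switch to a purely implicit
operator at production scale. PCG uses a block-diagonal preconditioner over
(level × group-column) blocks — the standard choice for multi-trait animal
models and cheap to invert — with zero pivots pseudo-inverted, so
rank-deficient fixed-effect parameterizations are solved in a least-squares
sense without reparameterization (REML is invariant to it). The exact
log-likelihood does require a full-rank fixed-effects block and says so if
factorization fails.

$\mathbf A_{22}^{-1}\mathbf x$ has two backends that cross-check each other:
a dense Cholesky of $\mathbf A_{22}$, and the sparse identity
$\mathbf A^{22}\mathbf x - \mathbf A^{21}(\mathbf A^{11})^{-1}\mathbf A^{12}\mathbf x$
with $\mathbf A^{11}$ (the non-genotyped block of $\mathbf A^{-1}$)
factorized once.

## The synthetic-data generator

`simulate_study()` emulates the structure of beef-cattle growth data:
discrete generations under random mating, a genotyped subset (youngest or
random animals), contemporary-group fixed effects assigned per generation,
multi-trait records with trait-specific recording probabilities, and any
combination of direct, maternal and permanent-environment random effects at
user-chosen true (co)variances. Genotypes arise by allele gene dropping from
founder frequencies drawn uniformly on a configurable range. Default true
breeding values are sampled from the *pedigree* covariance, keeping the
truth independent of the single-step machinery under test; `h_truth = TRUE`
switches to the ssGBLUP sampler for end-to-end recovery experiments where
the estimation model must be the generating model.

What it deliberately does not emulate: linkage and LD structure (loci are
unlinked, so G behaves like an idealized marker panel), selection
(non-random mating on phenotype), QTL architecture, heterogeneous residual
classes, and genotyping errors. Passing tests therefore demonstrate
correctness of the estimation machinery under the stated model, not
robustness to model violations in real data.

## Numerical choices and test-bed sizes

* Dense-oracle paths (exact traces, dense V, dense H) are guarded at 5000
  equations / 2000 observations.
* EM updates that leave the parameter space are projected to the nearest
  positive definite matrix (eigenvalue clipping at a 1e-6 relative floor)
  with a warning; AI steps are safeguarded as described above.
* Monomorphic loci are dropped with a message; no call-rate filtering
  (dosage matrices are assumed complete).
* Records needing a dam mapping with an unknown dam are dropped (logged) or
  raise an error, per configuration; a phantom-dam level is not offered
  because a phantom level has no pedigree row under an H-structured group.
* Maximum 100 REML rounds by default.

The validation suite exercises, among others: a ~300-animal / ~100-genotyped
/ 50-locus two-trait fixture for trace accuracy (Monte Carlo vs dense
inverse at $s = 2000$, and the $s^{-1/2}$ error-scaling law over
$s \in \{30, 100, 300, 1000\}$ from disjoint sample blocks); a 40-animal /
12-genotyped fixture with 50,000 draws for the sampler covariance against a
densely built $\mathbf G_0 \otimes \mathbf H$ (nominal 3-SE coverage per
element plus an extreme-value bound on the largest standardized deviation —
with thousands of correlated elements, *every* element within 3 SE is not
what a correct sampler produces); a ~2000-animal / ~500-genotyped dataset on
which MC-ss-GREML ($s = 30$) is required to match exact ss-GREML within
2 AI standard errors with non-significant Wald tests; and 20 simulation
replicates at known truth for parameter recovery. These sizes are the
package's chosen desk-scale test bed: large enough for the asymptotics to
show, small enough that the dense oracle remains exact and fast.

## Known limitations

Single J-factor (no metafounders or multiple genetic groups); homogeneous
marker variances (the sampler notes where a weighted variant would plug in);
no likelihood-ratio machinery; in-memory sparse solving rather than
out-of-core iteration on data, which bounds the practical problem size to
roughly $10^4$–$10^5$ equations depending on genotyped count.
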