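---
title: "Multi-trait longitudinal GWAS: model, algorithms and evaluation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-trait longitudinal GWAS: model, algorithms and evaluation design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mtlgwas)
```

## The model

For a single quantitative trait measured repeatedly, the longitudinal GWAS
model for individual $i$ at time $t_j$ (years from baseline) is

$$
Y_{ij} = \mu + a\,t_j + c\,s_i + l\,s_i t_j
       + \textstyle\sum_\tau \alpha_\tau \mathrm{Cov}_{ij\tau}
       + \sum_\gamma \beta_\gamma \mathrm{Cov}_{i\gamma}
       + g_{i0} + g_{i1} t_j + \varepsilon_{ij},
$$

where $s_i$ is the genotype dosage, $c$ the **cross-sectional (CS)** effect
of the variant on the trait's level, $l$ the **longitudinal (LT)** effect on
its rate of change, and $g_{i0}, g_{i1}$ are per-individual random intercepts
and slopes that absorb the polygenic background and the within-individual
correlation of repeated measures.

With $K$ correlated traits the model is stacked trait-major,
$y' = [y_1' \; \cdots \; y_K']$, with block-diagonal incidence matrices
$X = I \otimes X_k$ (fixed effects) and $Z$ (per-individual
$q_i \times 2$ blocks $[1, t]$; the baseline interval is always 0). The
random effects have covariance $G$ built from the $2K \times 2K$ CS/LT
covariance $C$ across traits, and the residuals have
$R = E \otimes I_n$ with a $K \times K$ residual covariance $E$. Estimates
solve the mixed-model equations

$$
\begin{bmatrix} X'R^{-1}X & X'R^{-1}Z \\ Z'R^{-1}X & Z'R^{-1}Z + G^{-1}
\end{bmatrix}
\begin{bmatrix} b \\ u \end{bmatrix} =
\begin{bmatrix} X'R^{-1}y \\ Z'R^{-1}y \end{bmatrix}.
$$

Records missing for some but not all traits are kept as all-zero rows in
$y$, $X$ and $Z$, so every per-trait block has the same row set and the same
row index addresses the same (individual, time) slot everywhere. Because
$R^{-1} = E^{-1} \otimes I_n$ couples traits at the same record, individuals
measured for only some traits still contribute to all traits' equations —
this is the mechanism by which missing records borrow strength from
correlated traits.

## Structured inversion

$R^{-1}$ follows from $(A \otimes B)^{-1} = A^{-1} \otimes B^{-1}$: only the
$K \times K$ factor is inverted. $G^{-1}$ has $(k,k')$ super-blocks
$I_N \otimes C^{kk'}$, where $C^{kk'}$ is the $2\times2$ block of $C^{-1}$.

The large block $Z'R^{-1}Z + G^{-1}$ (order $2NK$) is inverted by **recursive
partitioning**: the four-block identity

$$
\begin{bmatrix} A & B \\ C & D \end{bmatrix}^{-1} =
\begin{bmatrix}
S^{-1} & -S^{-1} B D^{-1} \\
-D^{-1} C S^{-1} & D^{-1} + D^{-1} C S^{-1} B D^{-1}
\end{bmatrix},
\qquad S = A - B D^{-1} C,
$$

applied iteratively from the lower-right corner, moving one partition
row/column per round; each round's inverse overwrites the grown $D$ block,
which is never needed again. Three structural facts make this fast here:
the matrix and its inverse share the same structurally nonzero block set;
every Schur complement stays block-diagonal, so only its atomic diagonal
blocks are inverted; and symmetry means only one off-diagonal product is
formed and mirrored.

**Recursion granularity.** The partitioning is per *individual*: after a
recorded permutation from the trait-major stacking to individual-major
order, $Z'R^{-1}Z + G^{-1}$ has contiguous $2K \times 2K$ atomic blocks (one
per individual; $G^{-1}$ becomes $I_N \otimes C^{-1}$), so the recursion
peels $N$ rounds and every Schur complement is a single $2K \times 2K$
atomic block. This choice keeps all three structural properties exact at
every round. The kernel (`recursive_partition_inverse()`) also handles
banded coupling between partitions, with block fill-in tracked explicitly;
an atomic block whose reciprocal condition number falls below $10^{-12}$
raises an error naming the block rather than silently regularizing. The
recursion is realized as a loop over rounds (not call-stack recursion) so
stack depth is bounded at large $N$; the algebra is identical.

## Per-variant testing by bordering

The null system is pre-multiplied by
$\mathrm{diag}(I, [Z'R^{-1}Z + G^{-1}]^{-1})$, replacing the large block
with an identity. The transformed (non-symmetric) system is solved once:
with $M_{11} = X'R^{-1}X$, $M_{12} = X'R^{-1}Z$, $M_{21} = B(Z'R^{-1}X)$ and
$B = (Z'R^{-1}Z + G^{-1})^{-1}$,

$$
\hat b = (M_{11} - M_{12} M_{21})^{-1}(r_1 - M_{12} r_2), \qquad
\hat u = r_2 - M_{21} \hat b .
$$

The dense fixed-effects core has order equal to the total number of
fixed-effect equations across traits, so its inverse is cheap and cached.

Each variant adds $2K$ equations ($W = I \otimes W_k$; column 1 of $W_k$ is
the dosage repeated over the individual's records, column 2 is column 1
times time). Writing the bordered system as
$[[H_{11}, H_{12}], [H_{21}, H_{22}]]$, only the variant's own coefficients
are solved for:

$$
\hat b^{\mathrm{SNP}}
  = (H_{11} - H_{12} H_{22}^{-1} H_{21})^{-1}
    (J_1 - H_{12} H_{22}^{-1} J_2), \qquad
\mathrm{SE} = \sqrt{\mathrm{diag}\,
    (H_{11} - H_{12} H_{22}^{-1} H_{21})^{-1}} .
$$

$H_{22}^{-1} J_2$ is the stored null solution; $H_{22}^{-1} H_{21}$ re-uses
the same two-step solve with a new right-hand side; $H_{22}^{-1}$ is never
formed. Both $H_{12}$ and $H_{21}$ are formed explicitly (the transformed
system is not symmetric: $H_{21}$ carries the factor $B$, $H_{12}$ does
not). P-values are two-sided standard-normal tails,
$p = 2\Phi(-|\hat b / \mathrm{SE}|)$, floored at the smallest positive
double and reported per trait and effect type (CS, LT).

Because the random-effects block decouples per individual, every
per-variant quantity is a contraction of per-individual precomputed blocks
against the dosage vector $g$ (and $g^2$). The scan therefore reduces to a
handful of dense matrix products over the whole genotype matrix plus a
batched Cholesky solve of the $2K \times 2K$ Schur systems — a vectorized
realization that is algebraically identical to per-variant bordering
(verified against a dense generalized-least-squares oracle to $10^{-8}$
relative in the tests). Variants are independent given the null system;
output files are sorted by (chrom, pos, variant id) so results are
bit-identical under any processing order.

## Variance components

$C$ and $E$ are estimated on the null model (no variants) by **pairwise
bivariate AI-REML**: for each of the $K(K-1)/2$ trait pairs, the 10 genetic
and 3 residual covariance parameters maximize the observed-data restricted
likelihood. The average-information matrix
$\tfrac12 \dot V_m' P \dot V_l P$-type products and the exact REML score are
accumulated per individual (the marginal covariance is block-diagonal per
individual). Newton steps use Levenberg–Marquardt damping plus step
halving: a step that would leave the positive-definite cone or decrease the
restricted likelihood is shortened, so accepted iterations are monotone.
Convergence requires both a restricted-log-likelihood change below
$10^{-6}$ and a maximum relative parameter change below $10^{-6}$ (default
cap 100 iterations; non-convergence is an error carrying the iteration
trace). Initialization is moment-based: per-trait residuals from an
ordinary least-squares fit of the fixed effects are split into
baseline/follow-up (co)variances. Variances that collapse toward zero are
held at a positivity floor and flagged rather than erroring.

Zero-filled alignment rows are excluded from the REML likelihood — they
carry no information, and including them would count phantom records in the
residual log-determinant. (They are retained in the association system,
whose construction is defined on the padded row set.)

Across pairs, each trait's within-trait $2\times2$ CS/LT block and residual
variance are averaged over its $K-1$ pairwise fits; cross-trait covariances
are unique to their pair. The assembled $C$ and $E$ can be indefinite after
averaging, so eigenvalues are floored at $10^{-8} \lambda_{\max}$ and the
adjustment magnitude is reported. Polygenic heritabilities are
$\mathrm{var}_{CS}/(\mathrm{var}_{CS}+\mathrm{var}_{LT}+\mathrm{var}_{Res})$
per trait (and analogously for LT) — no genomic relationship matrix is
involved.

Components may also be supplied from a labeled TSV file
(`read_variance_components()`), so the association engine is usable and
testable independently of estimation.

## The simulation framework

The generator (`sim_config()`, `simulate_dataset()`) emulates a two-visit
biobank design with three correlated traits:

* allele frequencies $\sim \mathrm{Beta}(2, 10) + 0.01$ (the offset imposes
  a 1% frequency floor); dosages drawn per variant under Hardy–Weinberg
  probabilities $\{(1-f)^2,\, 2f(1-f),\, f^2\}$;
* per-variant effect vectors $a_r = (\beta_{r1..3}, \delta_{r1..3})$ from
  $\mathrm{MVN}(\mu, \Sigma)$ for 100 causal variants out of 10,000, with
  $E(\beta) = 10$, $E(\delta) = E(\beta)/L$,
  $\mathrm{var}(\beta)$ the fixed $3\times3$ matrix
  $[[10,8,-7],[8,12,-1],[-7,-1,18]]$, $\mathrm{var}(\delta) =
  \mathrm{var}(\beta)/L$ and a fixed CS–LT covariance; non-causal variants
  carry infinitesimal background effects from
  $\mathrm{MVN}(\mu/1000, \Sigma/1000)$;
* two time points per individual: baseline 0 and a continuous
  $\mathrm{Uniform}(4, 9)$-year interval (the interval distribution is a
  package choice; only its 4–9-year range is prescribed);
* phenotype $\alpha_0 + \alpha_1 t + \alpha_2 \mathrm{Cov}_i + \sum_r
  \beta_r g_{ir} + t \sum_r \delta_r g_{ir} + \varepsilon$, with one
  standard-normal time-independent covariate and residuals drawn
  independently per (individual, time) from
  $\mathrm{MVN}(0, \mathrm{var}(\beta))$ — i.e. the residual covariance
  equals the CS effect covariance. $(\alpha_0, \alpha_1, \alpha_2) =
  (0, 1, 1)$ by default: under a correctly specified model their
  location/scale does not affect power or type-I error;
* independence of residuals across the two visits is assumed (the
  alternative — serial residual correlation — is indistinguishable from the
  random-intercept component with two visits);
* optional missingness: a fraction of records, or of individuals, of one
  trait (seeded, reproducible).

**Truth components.** The analysis model's random intercept/slope absorbs
the *aggregate* of all simulated variant effects, so the generating
("truth") covariance used by the fast evaluation path is
$C = \sum_r \mathrm{var}(g_r)\, a_r a_r'$ (realized dosage variances,
trait-interleaved) — about 300-fold larger than the per-variant effect
covariance — with $E = \mathrm{var}(\beta)$. Supplying the per-variant
matrix instead would misspecify the model by two orders of magnitude and
destroy type-I error. In configured-matrix terms the baseline heritability
is $10/(10+10) = 50\%$ per trait, slightly exceeded once the LT component
contributes; in aggregate terms the simulated traits are strongly heritable
and strongly genetically correlated (the common effect mean dominates
$\Sigma + \mu\mu'$).

**Variant filter.** A variant is tested only if every carrier genotype
class (dosage 1 and dosage 2) contains at least 3 individuals within every
genotype-by-time category, where time categories are follow-up intervals
rounded to whole years. This category-count reading reproduces the
realized Bonferroni thresholds implied by the evaluation design
($0.05/\text{tested} \approx 7.3\times10^{-6}$ at $n = 3000$ and
$\approx 8.9\times10^{-6}$ averaged over the sample-size family) to within
1%; two frequency-based readings of the same rule are available as
configurable alternatives (`mac_rule = "dosage_time"` or `"both"`).

## Evaluation design and problem sizes

`run_scenario()` loops simulate → components → scan → metrics with
per-replicate seeds `seed + counter`. Three families: LT-ratio
($L \in \{1,5,20,50,100\}$ at $n=3000$), sample size
($n \in \{1000, 2000, 3000, 10000\}$ at $L=5$), and missingness (15% / 50%
of individuals losing one of three traits, with a single-trait comparator
and paired standard-error slopes). Power is the fraction of causal variants
below the per-replicate Bonferroni threshold ($0.05/\text{tested}$),
averaged over traits; type-I error the analogous fraction over non-causal
tested variants — the background variants' tiny real effects are counted
as false positives by construction, which is why LT type-I error sits
mildly above nominal and grows with $n$.

The packaged evaluation runs 20 replicates per LT-ratio value, 10 per
sample size (4 at $n = 10000$) and 8 per missingness fraction, with
variance components taken as the generating truth; these sizes give
Monte-Carlo standard errors small enough for three-sigma comparisons while
keeping the suite fast. Per-replicate AI-REML estimation (`vc_mode =
"estimate"`) is exposed and exercised separately by the parameter-recovery
study (50 bivariate fits at $n = 2000$).

## What the simulation does and does not capture

Variants are simulated independently (no linkage disequilibrium), without
population structure or relatedness, with exactly two visits, Gaussian
residuals, and effects on the raw phenotype scale. Passing tests therefore
demonstrate the correctness of the estimator and its calibration under the
stated generative model — not robustness to LD, stratification, irregular
visit schedules (the model itself accepts arbitrary per-individual time
grids), or non-normal traits (for which a rank-based inverse-normal
transformation is the usual preprocessing).

## Numerical choices

* Atomic-block singularity threshold: reciprocal condition number
  $10^{-12}$ → error with the block index, never silent regularization.
* Monomorphic (zero-dosage-variance) variants: filtered with a status, not
  an error; the null system is unaffected.
* P-value floor: $\approx 4.94 \times 10^{-324}$ (double underflow).
* PD repair floor for assembled covariance matrices:
  $10^{-8}\lambda_{\max}$.
* Wald z-tests against the standard normal exactly; no t-approximation.
* The transformed and untransformed null systems agree to $10^{-10}$; the
  bordered solver agrees with dense GLS ($V = ZGZ' + R$ on the zero-padded
  system) to $10^{-8}$ relative — both asserted in the test-suite.

## Known limitations

Binary traits, score/likelihood-ratio tests, saddlepoint approximations,
genomic-control correction, LD-aware conditional analysis and
GRM-based heritability are out of scope. Runtime of the joint analysis
grows faster than linearly in $K$; the single-trait reduction
(`single_trait_scan()`) is the right tool when traits are nearly
uncorrelated. The rate-of-change comparator (`rate_of_change_gwas()`) is
included as a baseline precisely because collapsing trajectories into one
rate discards information; on simulated data its discoveries are a subset
of the longitudinal engine's cross-sectional hits.
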