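---
title: "Twin models for fMRI head motion and ADHD symptom scores"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Twin models for fMRI head motion and ADHD symptom scores}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

# Scope

`twinmotion` implements a complete analysis path for asking whether
in-scanner head motion (HM) and ADHD-type symptom scores (SWAN Inattention
and Hyperactivity-Impulsivity, rated by mothers and by the participants
themselves) share genetic influences, using the classical twin design:

1. summarise each subject's rigid-body realignment parameters into a single
   head-motion number with exclusion flags (`motion_metrics` layer);
2. decompose trait variances and cross-trait covariances into additive
   genetic (A), shared-environment (C) or dominance (D), and unique
   environment (E) components by full-information maximum likelihood (FIML)
   on pair-structured family data (`twin_likelihood` + `inference` layers);
3. generate synthetic twin cohorts with the same statistical structure so
   that every stage is testable without access to restricted cohort data
   (`synthetic_data` layer).

# Head-motion summarisation

Realignment software (SPM `rp_*.txt`, FSL `.par`) reports, per frame, three
translations (mm) and three rotations (radians) relative to the first,
reference, frame. We fix the SPM convention
`T = Translate(t) %*% Rx %*% Ry %*% Rz` with right-handed rotations; the
displacement metric is insensitive to this choice at the small angles seen
in practice, but the convention must be fixed for the affine composition to
be well defined.

The per-frame-pair displacement is the root-mean-square displacement of the
brain, modelled as a ball of radius $R = 80$ mm centred at $x_c$, induced by
the relative transform between consecutive frames: with
$[A\,|\,t] = T_{d+1} T_d^{-1} - I$,

$$ d = \sqrt{\tfrac{1}{5} R^2\,\mathrm{tr}(A^\top A) +
             (t + A x_c)^\top (t + A x_c)}. $$

The $R^2/5$ term is the mean squared norm of a point uniform in the ball,
which is why the metric equals the Monte-Carlo RMS displacement of random
brain voxels (a property the test suite checks to 1%), and reduces exactly
to $\lVert t\rVert$ for pure translations.

Per-subject summary choices the upstream literature leaves open, fixed here
and recorded in output metadata:

* the summary is the **arithmetic mean** of the $n-1$ consecutive-frame
  displacements (a median variant would be trivial to add; the mean is the
  common choice for this metric);
* the log transform is the **natural log**;
* the ball centre $x_c$ defaults to the scanner origin `(0,0,0)`
  (configurable), as the realignment coordinates are software specific;
* gross-motion exclusion uses **strict** inequalities: any frame with a
  translation > 3 mm on any axis or a rotation > 2 degrees about any axis;
* the 4-standard-deviation cohort outlier rule is applied on the **log**
  scale and is a flag only, never an exclusion;
* zero-motion traces (possible only synthetically) floor the mean at
  $10^{-6}$ mm before the log, with a warning;
* a sanity warning fires when any |rotation| exceeds 0.5 rad, which almost
  always means degrees-in-file or a swapped SPM/FSL column order.

# The likelihood

Each family contributes one multivariate-normal density. For $p$ traits and
two members, the model-implied $2p \times 2p$ covariance is assembled from
per-component $p\times p$ matrices $\Sigma_X = L_X L_X^\top$ (Cholesky
parameterization) as

$$ \Sigma_{\text{pair}} =
   \begin{pmatrix} \sum_X \Sigma_X & \sum_X \rho_X \Sigma_X \\
                   \sum_X \rho_X \Sigma_X^\top & \sum_X \Sigma_X
   \end{pmatrix}, $$

with the biometrical cross-member correlations $\rho_A = 1$ (MZ), $0.5$
(DZ and sibling pairs), $\rho_D = 1/0.25$, $\rho_C = 1$, $\rho_E = 0$.
Opposite-sex pairs scale $\rho_A$ by the cross-sex genetic correlation
$r_g^{mf}$, fixed to 1 except in the qualitative sex-limitation test.
Sibling pairs are pooled with the DZ group matching their sex composition.

Missing phenotypes are handled by FIML: each family's density is
marginalised to its observed entries, singletons contribute their marginal
density, and no family is imputed or dropped. This is essential because the
mother-report and self-report sub-samples overlap only partially.

Model extensions:

* **General sex limitation** — separate path sets per sex plus $r_g^{mf}$
  (identified only through opposite-sex pairs; without them it is fixed to 1
  with a warning). When the free estimate converges to the boundary
  $|r_g^{mf}| = 1$ it is re-fixed there, which leaves the fit unchanged and
  is flagged.
* **Sibling contrast** — a reciprocal rating path $s$ per trait,
  $\Sigma^* = (I-B)^{-1} \Sigma (I-B)^{-\top}$ with $B$ holding $s$ at the
  cross-member same-trait positions; means are transformed by the same
  $(I-B)^{-1}$. This is the standard resolution of negative-contrast rater
  effects, which can push DZ correlations below zero.
* **Group variance scaling** — a free multiplicative scale on the total
  covariance of selected zygosity groups (used for the observation that
  females from opposite-sex pairs move more variably than females from
  same-sex pairs).
* **Saturated models** — unstructured means/variances/cross-covariances
  with equality constraints expressed as group-class maps; these are the
  reference models for the homogeneity battery.

## Parameterizations

Three equivalent covariance parameterizations are provided because they
serve different purposes:

* `cholesky` — unconstrained lower-triangular paths per component; smooth
  everywhere, supports up to three traits (the structural form needed for
  trivariate HM x trait x imaging-phenotype decompositions), sex limitation
  and contrast. Sign indeterminacy of the paths is resolved by reporting
  component covariance matrices, not raw paths.
* `share` — per-trait total variance, per-component variance shares in
  $[0,1]$ and component correlations in $[-1,1]$. This puts heritability
  ($h^2$), $r_g$ and $r_e$ directly in the parameter vector so
  profile-likelihood confidence intervals can be computed on them by simple
  box-constrained profiling (the same reason structural-equation packages
  reparameterize for CIs).
* `share_rp` — as `share` for the bivariate AE model but with the
  phenotypic correlation $r_p$ free and $r_e$ derived through the AE
  identity $r_p = r_g\sqrt{h^2_1 h^2_2} + r_e\sqrt{e^2_1 e^2_2}$; this makes
  the $r_p = 0$ likelihood-ratio test a single-parameter constraint.

## Numerical strategy

The mean model (per-trait intercepts and covariate coefficients) enters the
likelihood linearly, so for any covariance parameter value the optimal mean
parameters solve a generalized-least-squares system in closed form. The
optimizer therefore only searches the covariance parameters; families are
grouped into patterns sharing a covariance class and missingness mask, and
the per-pattern cross-moment tensors are precomputed once per fit, so an
objective evaluation costs one small Cholesky per pattern. The kernels are
written with RcppArmadillo, as is usual for FIML engines in this field.
Contrast models, whose mean transform depends on $s$, use a per-family
kernel instead of the precomputed tensors.

Optimization uses bounded quasi-Newton (`nlminb`) with relative objective
tolerance $10^{-8}$ and a deterministic multi-start scheme: a moment-based
start (sample means/variances, double-entered cross-covariances, observed
cross-trait correlation) plus four seeded perturbations, each explored with
a short run, followed by a full-tolerance polish of the incumbent.
Convergence is declared on the optimizer's success code or a gradient-norm
check scaled by the objective; non-converged results are returned flagged,
never dropped. Out-of-model parameter values (non-PSD implied covariance,
negative variance shares, $|r_e| > 1$ in `share_rp`) map to a large finite
penalty inside the optimizer and to `+Inf` in the exported objective.

Profile CIs locate the points where the profiled $-2\ln L$ rises by the
$\chi^2_1$ quantile (3.841 at 95%) by outward bracketing and bisection
(default tolerance $10^{-4}$ on the parameter scale), warm-starting every
inner fit; an endpoint that reaches a box bound (a correlation at $\pm 1$,
a share at 0/1) is returned at the bound and flagged. Boundary mixture
corrections (50:50 $\chi^2$) for variance components tested on their
boundary are deliberately **not** applied — plain LRT degrees of freedom are
reported, matching common practice in this literature — and no
multiple-testing adjustment is made across the battery; both choices are
documented rather than configurable because they define what the reported
p-values mean.

# The homogeneity battery

`homogeneity_battery()` runs the standard preliminary tests, each a
likelihood-ratio test of the saturated model against a constrained version:
birth-order mean effect; sex differences in means/variances; quantitative
sex limitation (same-sex pair covariances equal across sexes);
qualitative sex limitation (opposite-sex pair covariance equal to same-sex
DZ); presence of genetic factors (MZ covariance equal to DZ covariance);
familial aggregation (all pair covariances zero); and one test per mean
covariate (sex, age at scan, wave, design, number of siblings — whatever is
requested). Tests whose groups are absent are skipped with a reason rather
than failing.

# The synthetic cohort generator

`simulate_families()` is the variance-component model run forward: per
family it draws component scores (A shared exactly for MZ pairs, correlated
0.5 — times $r_g^{mf}$ for opposite-sex pairs — for DZ/sibling pairs, D
correlated 1/0.25, C shared, E independent), maps them through the
component covariance structure, applies the contrast transform and the
covariate mean model, and finally applies per-trait missingness to emulate
overlapping rater sub-samples. A single seed drives one dataset; draws
follow a fixed family order, so runs are exactly reproducible (a per-family
stream split was considered and rejected as needless complexity at this
scale).

Covariate distributions emulate a young-adult twin imaging cohort: scan age
truncated-normal (mean 22, SD 3, range 18-32); mother-rating interval
truncated-normal with mean 1.2 years (range about 3 days to 3.9 years) and
self-rating interval mean 3.1 years (range to 7.1 years); family size
2 + Poisson(1) clipped to 2-7 children (mean 3, SD 1); about 64% females in
the maternal sub-sample and 58% in the self-report sub-sample.

The presets encode published summary statistics for this cohort design as
generating parameters (each preset's documentation lists its source
quantities): head motion is univariate AE with $h^2 = 0.40$ and total SD
0.35 on the log scale, with a male offset of $\log(1.032)$ (+3.2% on the
raw scale) and an age slope of $\log(0.994)$ per year; the bivariate
presets pair it with a SWAN score under an AE structure whose $r_g$ and
$r_e$ are the published values and whose SWAN heritability is chosen so the
implied $r_p$ matches the published phenotypic correlation through the AE
identity (for the self-report hyperactivity preset this forces
$h^2 \approx 0.16$ — consistent with the reported attenuation of
self-report heritability by measurement error — because the printed
$r_p = 0.12$, $r_g = 0.40$, $r_e = 0.03$ cannot coexist with a larger
heritability). The sex-limitation preset generates females under ACE
(A = 0.46, C = 0.51, implying MZ/DZ pair covariances 0.97/0.74) and males
under ADE (A = 0.44, D = 0.20, implying 0.64/0.27), since the male pattern
(MZ < 2 x DZ reversed) cannot arise with non-negative shared environment.
Univariate SWAN presets whose published MZ/DZ correlations violate the
ACE/ADE bounds (e.g. rMZ > 2 rDZ, negative DZ correlations) solve a
dominance-plus-negative-contrast structure numerically at construction so
the implied pair correlations match exactly.

Likert discretisation (9 items per scale cut at thresholds into 7-level
informant or 5-level self codes, scale score = item mean) is available but
**off by default**: the analysis treats scores as continuous, and the
item layer exists to study measurement-error attenuation, e.g. why
self-report estimates are noisier than informant reports at matched latent
signal.

What the generator does *not* emulate: item-level agreement between raters,
non-normal trait distributions, age trends in SWAN scores across waves
beyond mean shifts, attrition correlated with phenotype, and family
structures beyond pairs. Passing recovery tests therefore demonstrates the
correctness and calibration of the estimation machinery under the model's
own assumptions, not robustness to real-data violations of them.

# Problem sizes in the tests and acceptance script

The simulation studies use the cohort-sized presets (about 500 pairs plus
singletons per replicate). The acceptance script runs 200 replicates per
experiment, the test suite 50 (means of estimator distributions are then
determined to about ±0.015 for correlations, which sets the test
tolerances of ±0.05); the profile-CI coverage study uses 500 replicates and
the type-I-error study 2,000 replicates at a reduced design (4 groups of 50
pairs) where the saturated fits are cheap. One deliberate observation from
these studies: at the study's sample size the maximum-likelihood genetic
correlation is slightly biased away from zero (its replicate mean sits a
few hundredths above the generating value), a known finite-sample property
of ratio estimates of correlations between latent components; the recovery
experiments report the estimator mean as-is rather than correcting it.

# Known limitations

* Ordinal/threshold liability models are out of scope; scores are analysed
  as continuous.
* Families with more than two analysed members are rejected (the design
  selects one pair per family).
* The share parameterization covers one or two traits; three-trait models
  are available through the Cholesky parameterization only.
* Wald standard errors are not reported; interval estimation is
  profile-likelihood only.
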