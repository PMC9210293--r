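---
title: "Analytic REML for latent variance components in expression data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Analytic REML for latent variance components in expression data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(remlvc)
```

## The model

Genome-wide expression studies measure $m$ genes in $n$ samples ($m \gg n$).
Sample-to-sample correlations in such data arise partly from *known*
covariates — batch, growth condition, genotype principal components — and
partly from *hidden* confounders. remlvc fits the random-effects model

$$ Y = Z V + X W + \epsilon, $$

where $Y \in \mathbb{R}^{n\times m}$ is the (sample-centered) expression
matrix, $Z \in \mathbb{R}^{n\times d}$ holds the known covariates and
$X \in \mathbb{R}^{n\times p}$ the latent factors. The per-gene effect
vectors $(v_i, w_i)$ are jointly normal with block covariance
$\begin{bmatrix} B & D \\ D^\top & A\end{bmatrix}$ and the noise is i.i.d.
$N(0, \sigma^2)$. Integrating out the effects, each gene's sample vector is
$N(0, K)$ with

$$ K = Z B Z^\top + Z D X^\top + X D^\top Z^\top + X A X^\top + \sigma^2 I, $$

and the log-likelihood, up to additive constants, is
$\mathcal{L} = -\log\det K - \operatorname{tr}(K^{-1} C)$ with
$C = YY^\top/m$ the sample covariance matrix. Allowing $D \neq 0$ — a
covariance between known and latent effects — is what makes it possible to
choose the latent factors *orthogonal* to the known covariates without any
loss of likelihood: overlap between a candidate latent direction and
$\mathrm{span}(Z)$ can always be absorbed into $B$ and $D$ by a linear
reparameterization (`orthogonalize_latents()` performs this transformation
explicitly). $A$ can always be taken diagonal because the latent factors
carry a rotational symmetry; the known covariates, being measured
quantities, cannot be rotated.

## The analytic REML solution

Once $X^\top Z = 0$ is imposed, the log-likelihood splits as
$\mathcal{L} = \mathcal{L}_1 + \mathcal{L}_2$, where $\mathcal{L}_2$ is
exactly the probabilistic-PCA likelihood on the orthogonal complement of
$\mathrm{span}(Z)$. The solver therefore proceeds in closed form:

1. **Subspace split** (`subspace_split()`): the SVD of $Z$ gives an
   orthonormal basis $Q_1$ of $\mathrm{span}(Z)$ (rank $r$, dropping
   singular values below $10^{-10} s_{\max}$ so duplicated or collinear
   covariates do not inflate the rank) and a basis $Q_2$ of the complement.
2. **Restricted PPCA** (`restricted_ppca()`): the latent factors are the
   top-$p$ eigenvectors of $C_2 = Q_2^\top C Q_2$, mapped back to sample
   space through $Q_2$ — hence exactly orthogonal to $Z$ by construction.
3. **Variance components** (`estimate_variance_components()`): treating
   $(Z, \hat X)$ jointly as known covariates, the maximizer of the remaining
   likelihood terms is $\hat K = \tilde P C \tilde P + \hat\sigma^2 (I -
   \tilde P)$, with $\tilde P$ the projector on
   $\mathrm{span}(Z) \oplus \mathrm{span}(\hat X)$ and $\hat\sigma^2$ the
   mean of the $n - r - p$ excluded complement eigenvalues (this matches the
   $\mathcal{L}_1 + \mathcal{L}_2$ split; the excluded dimensions are the
   only ones carrying pure residual). Blockwise matching of
   $G^\top \hat K G$, $G = [Q_1, \hat X]$, then yields $A$ (diagonal),
   $D$, and $B$, the latter back-transformed to the *original* covariate
   coordinates through the SVD of $Z$ so users read effects of their natural
   variables; redundant covariate directions receive zero rows and columns.

`ppca()` and `known_covariate_solution()` expose the two classical limits
($d = 0$ and $p = 0$); the test suite verifies both against a quasi-Newton
numeric maximizer (`numeric_mle()`).

### Choosing the number of latent factors

`reml_fit()` takes a target fraction $\rho \in (0,1)$ of total variance to
explain and picks the smallest $p$ with
$(\operatorname{tr}(P_1 C P_1) + \sum_{i\le p}\lambda_i(C_2)) \ge
\rho\,\operatorname{tr}(C)$, capped at $n - r - 1$. $\rho = 1$ is rejected
because the residual variance must stay positive.

The analytic maximizer exists only when every retained direction — each
principal axis of $\mathrm{span}(Z)$ and each retained complement
eigenvalue — explains strictly more variance than $\hat\sigma^2$. When
noninformative or redundant covariates make an axis too weak,
`enforce_existence()` raises $p$ one factor at a time (which lowers
$\hat\sigma^2$) until the condition holds; the fit then overshoots $\rho$
and warns. This saturation of $p$ is itself a useful diagnostic that the
known covariates should be re-screened; if no $p \le n - r - 1$ satisfies
the condition, the fit aborts with that advice.

### Covariate screening

With many candidate covariates (e.g. genotype PCs in an eQTL study), any
$n$ linearly independent ones explain *all* the variance, so candidates are
screened one at a time first: the single-covariate model
$K = \beta^2 z z^\top + \sigma^2 I$ has the closed-form maximizer
$\hat\sigma^2 = (\operatorname{tr}(C) - z^\top C z)/(n-1)$,
$\hat\beta^2 = \max(z^\top C z - \hat\sigma^2,\, 0)$, and
`screen_covariates()` keeps candidates with
$\hat\beta^2 \ge \theta \operatorname{tr}(C)$. Interpreting $\theta$ as a
fraction of $\operatorname{tr}(C)$ makes it scale-free. Screening is
intended for genotype *principal components* (`genotype_pcs()`: L2-normalized
left-singular vectors of the sample-centered genotype matrix), which are
linearly independent by construction; a raw-marker mode exists but warns,
since one-at-a-time screening cannot see collinearity — joint redundancy is
caught later by the rank tolerance and the existence condition.

## Parameters at a glance

| parameter | meaning | default | notes |
|---|---|---|---|
| `rho` | target fraction of $\operatorname{tr}(C)$ explained | 0.5 | open interval $(0,1)$ |
| `theta` | minimum variance fraction a covariate must explain alone | none (no screening) | fraction of $\operatorname{tr}(C)$ |
| `p` | fixed latent-factor count (overrides `rho`) | `NULL` | existence checked, not raised |
| rank tolerance | singular values of $Z$ kept above $10^{-10} s_{\max}$ | fixed | collinear covariates collapse |

## Numerical conventions

* Centering is per **sample** (row of the $n \times m$ matrix); gene-wise
  centering is deliberately not applied.
* The likelihood is implemented exactly as
  $-\log\det K - \operatorname{tr}(K^{-1}C)$, omitting additive constants
  and the overall $m/2$ factor; every comparison in the package uses
  likelihood *differences*, which are invariant to that convention.
* All decompositions use the symmetric eigensolver or the SVD; $K^{-1}$ is
  never formed explicitly. Eigenvalues of $C$ below
  $-10^{-10}\operatorname{tr}(C)/n$ abort with an error (a PSD matrix
  cannot produce them unless the input is corrupt); small negatives are
  clipped to zero. Positive definiteness requires the smallest eigenvalue
  to exceed $10^{-12}$ times the largest.
* Eigenvector signs follow a fixed convention (largest-magnitude component
  positive) so factors are reproducible across platforms. Ties between
  degenerate eigenvalues are broken by the eigensolver's stable ordering;
  factors within a degenerate eigenspace are unique only up to rotation.
* With $m \le n$, $C$ is singular and the unconstrained optimum $K = C$ is
  unattainable; `sample_covariance()` flags this prominently but fitting
  proceeds.

## What the simulator does and does not emulate

`simulate_expression()` draws data exactly from the generative model:
orthonormal (or optionally correlated) covariates, latent factors
orthogonal to them, jointly normal effects with the requested
$[B, D; D^\top, A]$, i.i.d. Gaussian noise, then row-centering as applied
to real data. It reproduces the features the solver relies on — a spiked
sample covariance with known ground truth — and is bit-reproducible under
its seed. It does **not** emulate count noise, gene–gene correlation,
nonlinear confounding, or outlying samples, so passing tests demonstrate
correctness of the estimator under its own model assumptions, not
robustness to real-data violations of them.

Row-centering introduces a small $O(1/m)$ rank-one correction to $C$
relative to the population covariance; convergence checks therefore state
errors relative to the noiseless model covariance and use $m$ large enough
that this correction is below the asserted tolerances.

## The numeric oracle and what "dominance" means

`numeric_mle()` maximizes the same likelihood by BFGS with an analytic
gradient over the factor parameterization $K = FF^\top + \sigma^2 I$, the
first $r$ columns of $F$ constrained to $\mathrm{span}(Z)$, with multiple
random restarts. It exists purely as a cross-check. Like classical REML for
linear mixed models, the analytic solution maximizes $\mathcal{L}_2$ on the
complement rather than the total likelihood, so it is not guaranteed to be
the global maximizer; it *is* guaranteed to leave minimal unexplained
variance among all choices of $p$ latent factors, and the $p = 0$ analytic
solution is the exact maximizer (the suite verifies both). In the regime
the method targets ($m \gg n$, covariates genuinely informative) the
likelihood gap to the numeric maximizer is below $10^{-6}$; the oracle
suite runs 50 generative instances at $n = 8\ldots15$, $d \le 2$,
$p \le 3$, $m = 5000$ — the desk-scale analogue of a bulk study with a few
thousand genes.

## Problem sizes used in the validation suite

The shift-identity study uses one synthetic dataset of $n = 100$ samples
and $m = 1000$ genes with ten planted latent factors of linearly decreasing
variance ($20 \to 2$) over unit residual noise — large enough that thirty
eigenvalue gaps are well resolved, small enough to run in seconds.
Parameter recovery uses $n = 50$, $d = 2$, $p = 3$ and
$m \in \{500, 5000, 50000\}$ to exhibit convergence of $\hat K$ to the
ground-truth $K$. These sizes are the package's own validation choices and
are easily edited in `tests/testthat/test-acceptance.R`.

## Known limitations

* Latent factors are identifiable only up to the model's inherent
  symmetries; in particular the method cannot (no method can) recover the
  "true" overlap between hidden confounders and known covariates — it
  reports the canonical orthogonal representative.
* Missing values are rejected, not imputed; fixed effects on the mean are
  removed by centering rather than modeled.
* The existence condition ties the minimal retained eigenvalue to
  $\hat\sigma^2$; data whose complement spectrum is nearly flat can force
  $p$ close to its cap, a sign the model adds little beyond isotropic
  noise.
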