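---
title: "Mutation-response scanning with elastic network models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mutation-response scanning with elastic network models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrscan)
```

## The model

A protein of $N$ residues is coarse-grained to its C$_\alpha$ trace and
represented as an anisotropic network model (ANM): every pair of sites
within a cutoff $R_0$ is joined by a harmonic spring of force constant $k$,
with energy

$$V(\mathbf r) = \tfrac12 \sum_{jl \in \text{contacts}}
  k\,\big(\lVert \mathbf r_j - \mathbf r_l\rVert -
          \lVert \mathbf r^0_j - \mathbf r^0_l\rVert\big)^2 .$$

Expanding to second order about the native structure $\mathbf r^0$ gives the
$3N \times 3N$ Hessian $\mathbf K$, whose six zero eigenvalues are the rigid
translations and rotations. Thermal fluctuations of the native ensemble are
then characterized by the covariance matrix
$\mathbf C = k_B T\,\mathbf K^{+}$ (pseudo-inverse), and the structural
response to a small applied force $\mathbf f$ follows from the linear
response approximation (LRA),
$\Delta\mathbf r^0 = (\mathbf C / k_B T)\,\mathbf f$.

A point mutation at site $j$ is modelled as a random force on the contacts
of $j$: one scalar $f(jl) \sim \mathcal N(0, \sigma^2)$ per contact $jl$,
applied as $f(jl)\,\mathbf e_{jl}$ on the partner $l$ with the reaction
$-f(jl)\,\mathbf e_{jl}$ on $j$, where $\mathbf e_{jl}$ is the contact unit
vector. Net force and net torque vanish by construction, so mutation forces
never excite the rigid-body modes.

## Sensitivity matrix S

The sensitivity matrix collects the mean squared displacement of each
response site $i$ over random mutations at each site $j$:
$S_{ij} = \langle \lVert \Delta\mathbf r^0_i(j) \rVert^2 \rangle$.

Two routes compute it:

* **Simulation (`smrs_sensitivity`)** — draw $M$ mutations per site,
  assemble each $3N$ force vector, apply the LRA, and average the per-site
  squared displacements.
* **Closed form (`amrs_sensitivity`)** — because the contact scalars are
  i.i.d. with $\langle f(jk) f(jl)\rangle = \sigma^2\delta_{kl}$, the
  expectation evaluates exactly to
  $$S_{ij} = \sigma^2 \sum_{jl \in C(j)}
    \mathbf e_{jl}^{\mathsf T} (\mathbf C_{il}-\mathbf C_{ij})^{\mathsf T}
    (\mathbf C_{il}-\mathbf C_{ij})\, \mathbf e_{jl},$$
  with $\mathbf C_{xy}$ the $3\times3$ site-pair block of $\mathbf C$. The
  implementation computes $(\mathbf C_l - \mathbf C_j)\mathbf e_{jl}$ once
  per contact from the $3N\times3$ site column-blocks and reuses it for all
  response sites — algebraically identical, and $O(N \sum_j CN(j))$.

The two routes deliberately share no code beyond the covariance matrix:
the simulated route goes through explicit force assembly and a full-matrix
LRA product, so their agreement (tested at 3 Monte-Carlo standard errors
elementwise) is an end-to-end check of both.

Row averages of $S$ give the *influence profile* $S_j$ (how strongly
mutations at $j$ deform the rest of the structure); column averages give
the *sensitivity profile* $S_i$.

## Compensation matrix D

For double scanning the question is how well a second mutation at $j$ can
cancel the deformation of a first mutation at $i$. The overlap of two
deformations is a bilinear form in the contact scalars,
$\Delta\mathbf r^0(i)^{\mathsf T}\Delta\mathbf r^0(j)
 = \mathbf f(i)^{\mathsf T}\mathbf A_{ij}\,\mathbf f(j)$, with the
$CN(i)\times CN(j)$ block
$A_{ik,jl} = \mathbf e_{ik}^{\mathsf T}(\mathbf C_k-\mathbf C_i)^{\mathsf T}
(\mathbf C_l-\mathbf C_j)\mathbf e_{jl}$ (`overlap_block`).

Unconstrained Gaussian forces make the maximal overlap unbounded, so
second-mutation forces are renormalized onto the sphere
$\lVert\mathbf f(x)\rVert^2 = \sigma^2 CN(x)$ — applied to the
$CN(x)$-vector of contact scalars, the space in which the maximization is
posed. Given the first force, the constrained maximum has the closed form
$\sigma^2 CN(j)\,\lVert \mathbf A_{ij}^{\mathsf T}\mathbf f(i)\rVert^2$
(Cauchy–Schwarz; `max_compensation_given_first`), and averaging over
renormalized first mutations (isotropic with
$\langle \mathbf f \mathbf f^{\mathsf T}\rangle = \sigma^2 \mathbf I$)
yields

$$D_{ij} = \sigma^2 \sqrt{CN(j)\, \mathrm{Tr}\,
  \mathbf A_{ij}\mathbf A_{ij}^{\mathsf T}}.$$

The outer square root keeps $D$ on the same (displacement) scale as the
definition $D_{ij} = \langle \max_\nu [\cdot]^2\rangle_\mu^{1/2}$. This
reading is validated computationally rather than assumed: the simulated
estimator (`sdmrs_compensation`, which draws $M$ renormalized forces per
site once, reuses them across pairs, maximizes over the second index and
averages over the first) approaches exactly this matrix from below with a
gap that shrinks in $M$ — a finite sample of directions can only
under-estimate a supremum, and the square root is concave. $D$ is not
symmetrized; the analytical matrix satisfies the reciprocity
$D_{ij}/\sqrt{CN(j)} = D_{ji}/\sqrt{CN(i)}$, which the tests check to
1e-10.

## Parameters

| parameter | default | units | role |
|---|---|---|---|
| `cutoff` ($R_0$) | 12.5 | Å | contact definition; distance $\le R_0$ is a contact (inclusive — the boundary only matters at exact ties, which the fixture generator avoids) |
| `k` | 1 | energy/Å$^2$ | spring constant; pure scale factor |
| `kBT` | 1 | energy | thermal scale; pure scale factor |
| `sigma` ($\sigma$) | 0.3 | Å$^{-1}$ (force) | mutation force scale; pure scale factor |
| `M` | 200 | — | mutations per site in simulation routes |
| `seed` | 1 | — | RNG seed; one seeded generator per scan, draws consumed site-major |

Both $S$ and $D$ are proportional to $\sigma^2/k^2$, so the defaults fix
only the overall scale; all comparisons operate on mean-one-normalized
matrices and are scale-free. Note one convention: the closed-form
expressions act on the $\mathbf C$ blocks directly while the LRA divides by
$k_BT$, so simulated and analytical matrices coincide exactly under the
default $k_BT = 1$; with $k_BT \ne 1$ the analytical matrices simply carry
the extra $k_BT^2$ factor, which normalization removes.

## Numerical choices

* **Pseudo-inverse**: full symmetric eigendecomposition; eigenvalues
  $\lambda \le 10^{-8}\lambda_{\max}$ are treated as zero. Exactly six such
  modes are required; any other count raises a rank-deficiency error naming
  the count, rather than silently dropping modes. Collinear or coincident
  geometries are rejected by this check (a pendant site with one contact,
  for instance, adds soft modes), which is why valid networks need
  connectivity and generic geometry.
* **Connectivity** is verified at contact-building time (isolated site or
  disconnected graph are structured errors), since the six-mode rule
  assumes a single connected component.
* **Determinism**: every stochastic routine takes an explicit seed and
  restores the caller's RNG state; repeated runs are bit-identical, and
  output files embed the full parameter set and seed.
* **Degenerate draws**: an all-zero scalar vector cannot be renormalized;
  the scan redraws it (a probability-zero guard).
* **Log-scale correlations** (`log_pearson`) mean-normalize both inputs,
  drop nonpositive pairs with a recorded count, and warn when more than 1%
  are dropped. The diagonal is included by default (self-response and
  self-compensation are well defined); `exclude_diagonal` removes it.

## The synthetic fixture

`generate_helix` places site $t$ at
$(r\cos t\theta,\, r\sin t\theta,\, t\cdot\text{rise})$ with rise 1.5 Å,
radius 2.3 Å and turn 100°, giving consecutive C$_\alpha$ spacings of
~3.83 Å. At the default cutoff this yields a connected, non-collinear
network with contact numbers of ~8–11 at $N = 12$ (toward 10–20 for longer
helices), i.e. realistic local geometry and contact density. What it does
**not** emulate: real fold topologies, long-range tertiary contacts,
secondary-structure heterogeneity, or the contact-number contrast between
core and surface. Green tests on the helix therefore establish the
*algebraic correctness* of the pipeline (closed forms equal to simulation
expectations, scaling laws, reciprocity, convergence rates) — not
biological accuracy of the mutation-as-force model, which is outside this
package's claims.

## A worked example

```{r example}
s <- generate_helix(12)
topo <- build_contacts(s, cutoff = 12.5)
covar <- covariance_from_hessian(build_hessian(s, topo, k = 1))

Sa <- amrs_sensitivity(covar, topo, sigma = 0.3)
Ss <- smrs_sensitivity(covar, topo, force_model(sigma = 0.3, seed = 1), M = 200)
log_pearson(Ss, Sa)

Da <- admrs_compensation(covar, topo, sigma = 0.3)
Ds <- sdmrs_compensation(covar, topo, force_model(sigma = 0.3, seed = 1), M = 200)
log_pearson(Ds, Da)
```

The sensitivity comparison converges quickly with $M$ (correlations near 1
by $M \sim 200$); the compensation comparison converges markedly more
slowly, because estimating a maximum by sampling is harder than estimating
a mean — `convergence_curve` quantifies both on any fixture.

## Known limitations

* The LRA is first order: mutations that trigger large conformational
  changes are outside its validity.
* The ANM covariance assumes a single native basin; multi-state proteins
  are not represented.
* Forces on contacts are a generic mutation model; no residue-specific
  chemistry is encoded.
* The PDB reader handles the common single-model/altloc/insertion-code
  cases of C$_\alpha$ records only; it is not a general PDB parser.
* `sdmrs_compensation` is $O(N^2 M^2)$ in the pair loop; large proteins
  with large $M$ are expensive — which is precisely the argument for the
  analytical route.
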