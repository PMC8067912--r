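# mrscan

Fast mutation-response scanning of protein structures over anisotropic
network models (ANM).

## What problem this solves

Modelling a point mutation as a random force on the contacts of the mutated
residue, and predicting the resulting deformation with the linear response
approximation, is a standard way to study how protein structure reacts to
mutations — from pathological-variant analysis to patterns of structural
evolution and the search for rescue (compensatory) sites. The classical way
to get scan-level statistics is simulation: draw many random mutations per
site, compute each deformation, and average (sensitivity) or maximize over
mutation pairs (compensation). That cost grows quickly with protein size
and with the number of sampled mutations.

`mrscan` implements both the simulation estimators and exact closed-form
replacements, for structural bioinformaticians who need scan matrices for
large proteins or large structure sets — and for anyone who wants the
simulation and analytical routes side by side so each validates the other.

## The quantities

With `C = kBT * K⁺` the ANM covariance (pseudo-inverse of the Hessian `K`,
contacts at distance ≤ R0, springs `k`), and mutations at site `j` modelled
by contact forces `f(jl) ~ N(0, σ²)` along unit vectors `e_jl`:

- **Sensitivity matrix** `S_ij = ⟨‖Δr⁰_i(j)‖²⟩`, mean squared displacement
  of site `i` over mutations at `j`. Closed form:
  `S_ij = σ² Σ_{jl∈C(j)} e_jlᵀ (C_il − C_ij)ᵀ (C_il − C_ij) e_jl`.
- **Compensation matrix**
  `D_ij = ⟨max_ν (Δr⁰(iμ)ᵀ Δr⁰(jν))²⟩_μ^{1/2}`, the best structural
  cancellation a second mutation at `j` can offer a first mutation at `i`,
  with second-mutation forces renormalized to `‖f(j)‖² = σ² CN(j)`.
  Closed form: `D_ij = σ² √( CN(j) · Tr(A_ij A_ijᵀ) )`, where `A_ij` is the
  contact-space overlap block
  `A_{ik,jl} = e_ikᵀ (C_k − C_i)ᵀ (C_l − C_j) e_jl`.

Row/column averages give the influence/sensitivity profiles of `S` and the
compensating-power/compensability profiles of `D`. Simulated and analytical
matrices are compared via Pearson correlation of log-transformed, mean-one
normalized values (`log_pearson`, `comparison_report`,
`convergence_curve`).

## Worked example

```r
library(mrscan)

s     <- generate_helix(12)                 # synthetic Cα trace, ~3.8 Å spacing
topo  <- build_contacts(s, cutoff = 12.5)
covar <- covariance_from_hessian(build_hessian(s, topo, k = 1))

Sa <- amrs_sensitivity(covar, topo, sigma = 0.3)      # analytical S
Ss <- smrs_sensitivity(covar, topo, force_model(sigma = 0.3, seed = 1), M = 200)
Da <- admrs_compensation(covar, topo, sigma = 0.3)    # analytical D
Ds <- sdmrs_compensation(covar, topo, force_model(sigma = 0.3, seed = 1), M = 200)

print(topo)
#> ANM contact topology: 12 sites, 60 contacts, cutoff 12.5 A, CN in [8, 11]
print(Sa)
#> amrs matrix: 12 x 12 (sigma = 0.3, k = 1, kBT = 1, R0 = 12.5)
#>   mean 0.02105, range [0.003786, 0.1333]
as.numeric(log_pearson(Ss, Sa))   # 0.994
as.numeric(log_pearson(Ds, Da))   # 0.979
round(marginal_profiles(Sa)$influence, 4)
#>    A:1    A:2    A:3    A:4    A:5    A:6    A:7    A:8    A:9   A:10   A:11   A:12
#> 0.0206 0.0191 0.0226 0.0223 0.0217 0.0200 0.0200 0.0217 0.0223 0.0226 0.0191 0.0206
```

`S` entries are in Å² (scale set by σ²/k²); the log-Pearson correlations
show the 200-mutation simulation already matching the closed form closely
for `S` (0.994) and somewhat less tightly for `D` (0.979) — estimating a
maximum converges more slowly than estimating a mean, which is exactly why
the analytical route exists.

For real structures, replace the fixture with a PDB file:

```r
s <- parse_ca_structure("protein.pdb", chain = "A")
```

or use the command-line wrapper:

```sh
Rscript $(Rscript -e 'cat(system.file("scripts", "mrscan.R", package = "mrscan"))') \
  scan --method amrs --fixture helix:12 -o out/
```

which writes the raw and mean-one-normalized matrix TSVs, profile TSVs, a
structure summary and a run log (all parameters and seed embedded).

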