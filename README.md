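# colfibril

Analytical multiscale mechanics of type I collagen fibrils: closed-form
piecewise stress–strain laws for a single tropocollagen molecule and for
non-, partially- and fully-crosslinked fibrils, plus a Lennard-Jones
lattice-sum estimator of the intermolecular energy barrier that controls
molecular sliding.

## Who this is for

Type I collagen gives tendon, bone and skin their tensile strength.
Molecular-dynamics studies of fibril mechanics are limited to small
diameters (~25 nm, versus up to 500 nm in vivo) and to strain rates many
orders of magnitude above physiological. This package implements the
complementary analytical route: a quasi-static, closed-form constitutive
model built from a coarse-grained bead-spring force field, for anyone
who needs fibril-level stress–strain laws — e.g. as inputs to
tissue-scale models — without running molecular simulation.

## The model in brief

A tropocollagen molecule is a chain of n = 218 beads (equilibrium bond
length r₀ = 14 Å, end-to-end length L₀ = 3011 Å) with

* a hyperelastic bond potential — stiffness K_T0 = 17.13 kcal mol⁻¹ Å⁻²
  up to r₁ = 18.2 Å, then K_T1 = 97.66 about a shifted centre r̄₁ (set
  by force continuity) up to the breaking length r_b = 21 Å;
* harmonic bending K_θ(θ − θ₀)², K_θ = 14.98 kcal mol⁻¹ rad⁻²,
  θ₀ ∈ [164°, 180°];
* 12-6 Lennard-Jones interactions between beads of different molecules
  (ε = 6.87 kcal/mol, σ = 14.72 Å).

The molecule's tensile response has three regimes — uncoiling up to
ε₁ = n·r₀/L₀ − 1 ≈ 1.36 %, soft backbone stretching to ε₂ ≈ 31.8 %,
stiff (hyperelastic) stretching to rupture at ε₃ ≈ 52.0 %. In a fibril,
strength is set instead by molecular sliding: a bead must cross the
intermolecular energy barrier ΔE of hopping one lattice site, which the
backbone bond compensates at elongation Δr = √(2ΔE/K_T0) and pull-out
force F = K_T0·Δr. The fibril stress follows as

σ = σ₁ + C_pack · C_surf(φ) · F / A_mol,

with the hexagonal packing fraction C_pack = π/(2√3) ≈ 90.7 %, the
bulk-molecule fraction C_surf = ((φ − 2D_mol)/φ)² for diameter φ, and
A_mol the molecular cross-section (diameter 16.52 Å). Crosslinked
molecules (both terminals bonded, probability β² at terminal occupancy
β) slide against a ~16× larger barrier, adding a stiff stage and a
terminal stress drop; the partially crosslinked law is the pointwise
mixture σ = β²σ_CF + (1 − β²)σ_UF.

## Worked example

```r
library(colfibril)

molecule_curve()
#> Piecewise-linear stress-strain curve (model = molecule)
#>   unfold             strain   0.000% ->   1.362%  stress      0.0 MPa +     0.71 GPa x d-eps
#>   stretch_pre_hyper  strain   1.362% ->  31.770%  stress      9.7 MPa +     7.67 GPa x d-eps
#>   stretch_post_hyper strain  31.770% ->  52.043%  stress   2341.7 MPa +    43.72 GPa x d-eps
#>   drop               strain  52.043% ->      Inf  stress      0.0 MPa +     0.00 GPa x d-eps
```

The uncoiling stage ends at 1.36 % strain; the soft and stiff stretching
stages have moduli 7.67 and 43.72 GPa and end at 31.77 % and 52.04 %.

```r
barrier_to_pullout(11.36)       # published relaxed barrier, kcal/mol
#> Sliding barrier 11.360 kcal/mol (published, harmonic regime):
#>   bond elongation 1.152 A (r_sliding = 15.152 A), pull-out force 1.37e-09 N

fibril_summary(uncrosslinked_curve(25))   # 25 nm fibril, beta = 0
#>   phi beta    UTS_Pa yield_strain     E1_Pa      E2_Pa E3_Pa
#> 1  25    0 446454698   0.09699853 711277110 5238187112    NA
```

A 25 nm uncrosslinked fibril yields and fails at the same ~446 MPa
plateau (perfect plasticity), reached at 9.7 % strain with a stretching
modulus of 5.24 GPa. Crosslinks raise the strength quadratically in β:

```r
sweep_beta(seq(0, 1, 0.25), phi = 25)[, c("beta", "UTS_Pa", "yield_strain")]
#>   beta     UTS_Pa yield_strain
#> 1 0.00  446454698   0.09699853
#> 2 0.25  622012092   0.34621898
#> 3 0.50 1148684273   0.34621898
#> 4 0.75 2026471241   0.34621898
#> 5 1.00 3255372996   0.34621898
```

The frozen-lattice barrier itself can be recomputed from first
principles rather than taken from `published_barriers()`:

```r
fixed_lattice_barrier(build_hex_lattice())
#> [1] 6.187036
```

A thin command-line front end wraps the same functions:

```sh
Rscript exec/colfibril fibril --phi 25 --beta 0.5 --csv curve.csv
Rscript exec/colfibril sweep --phi-range 20,500,25 --csv sweep.csv
Rscript exec/colfibril barrier-profile --csv profile.csv
```

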