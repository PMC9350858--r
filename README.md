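# photonsdf

Meshless Monte Carlo radiation transfer (MCRT) for light transport in
turbid media, with all geometry represented by **signed distance functions
(SDFs)** and photon packets advanced by **sphere tracing**.

## The problem

MCRT is the gold standard for modelling how light propagates through
scattering and absorbing media — tissue optics, biophotonics, food and
drink packaging. Conventional codes approximate the geometry with voxels
(which cannot represent smooth curved surfaces, so reflections and
refractions off spheres, vessels or bottles become staircase artefacts) or
tetrahedral meshes (expensive to build and still piecewise-planar at
interfaces). `photonsdf` instead represents every shape implicitly as a
signed distance field: negative inside, zero on the surface, positive
outside. Curved refractive interfaces are then *exact*: the boundary is hit
on the true implicit surface and the normal is the field's gradient.

Intended users: researchers in tissue optics / computational biophotonics
who need fluence maps, boundary physics at curved interfaces, or a clean
reference implementation to validate other transport codes against.

## The algorithm

A photon packet in a medium with scattering and absorption coefficients
μs, μa (cm⁻¹), anisotropy g and refractive index n:

1. draws an optical depth **τ = −log ξ**, giving an interaction distance
   τ/μt with μt = μs + μa;
2. compares it with **d_sdf**, the distance to the nearest implicit surface
   (the minimum of |D| over all shapes and the bounding box). Because exact
   SDFs are 1-Lipschitz, a step of d_sdf can never cross a surface — this
   is sphere tracing;
3. interacts (scatters with probability μs/μt via the Henyey–Greenstein
   phase function, else is absorbed) or marches, decrementing τ;
4. on reaching a surface (d_sdf < δ_s) where n changes, computes the
   normal from the SDF gradient by central differences and the unpolarised
   Fresnel reflectance R, then reflects with probability R or refracts by
   the vector Snell law.

Fluence is tallied with a path-length estimator: each traversed segment is
split exactly at voxel faces (3D DDA) and credited as weight × length, so
Φ_voxel = accumulator / (N · V_voxel) per unit source power.

Shapes: sphere, box, capsule, cylinder, plus CSG (union, smooth union,
intersection, subtraction) and rigid transforms. Scenes, sources and grids
can also be given as JSON configs and driven from a CLI.

## Worked example

```r
library(photonsdf)

# diffusion-theory penetration depth for dermis
penetration_depth(0.23, 21)   # 630 nm -> 0.261 cm
penetration_depth(1.8, 82)    # 420 nm -> 0.047 cm

# scattering statistics in an isotropic sphere (tau_r = 10)
r <- run_isotropic_sphere(10, n_photons = 2e4, seed = 1)
#> mean scatterings 57.32 +/- 0.27   (closed form tau^2/2 + tau = 60)

# semi-infinite dermis slab, uniform illumination, two-exponential fit
f <- run_jacques_slab("630", n_photons = 5e4, seed = 1)
print(f)
#> <slab_fit> Psi(z) = Psi0 (C1 e^(-z k1/delta) - C2 e^(-z k2/delta)), delta = 0.261 cm
#>   C1 = 6.339, k1 = 1.031, C2 = 1.154, k2 = 13.58  (50000 packets)
#>   reference: C1 = 6.27, k1 = 1.00, C2 = 1.18, k2 = 14.4

# free-form scene: glass bottle = CSG subtraction of two cylinders
b <- build_bottle_scene()
print(b$scene)
#> <mcrt_scene> 2 region(s), bbox half = (2.2, 2.2, 2.3) cm, delta_s = 1e-06 cm
#>   [1] glass layer 0: mu_s = 0, mu_a = 0.01, g = 0.7, n = 1.5
#>   [2] contents layer 0: mu_s = 2.5, mu_a = 0.01, g = 0.7, n = 1.3
run <- mcrt_run(b$scene, b$source, n_photons = 2e4, seed = 1,
                grid = fluence_grid(c(-2.2, -2.2, -0.05), c(2.2, 2.2, 0.05),
                                    c(88, 88, 1)))
print(run)
#> <mcrt_run> 20000 packets (seed 1): 880 absorbed, 19120 escaped, 0 capped, 0 degenerate
#>   mean scatterings per packet: 9.756
fv <- finalize_fluence(run)          # fluence cross-section of the bottle
```

What the numbers mean: the slab's fitted `k1 = 1.03` says the deep fluence
decays with exactly the diffusion-theory penetration depth δ (the published
benchmark value is 1.00 ± a few %); `C1`/`C2`/`k2` shape the near-surface
build-up caused by backscatter and internal reflection at the n = 1.38/1.0
surface. In the sphere benchmark the simulated 57.3 scatterings sit below
the approximate closed form 60 — see below.

## Validation honesty

The closed form N ≈ τ²/2 + τ for the mean number of scatterings in an
isotropic sphere is an interpolation between ballistic and diffusive
limits. An independent brute-force random walk (plain R, no shared code)
gives 1.3966 ± 0.0026 at τ = 1 and 57.33 ± 0.06 at τ = 10 — about 7% and
4.5% below the closed form — and the simulator agrees with that oracle to
within one standard error at τ ∈ {0.1, 1, 10, 100}. The acceptance test
asserts the closed form at a 2% band as specified and is therefore red at
τ = 1 and 10 by construction; details in
`vignettes/sdf-monte-carlo.Rmd`.

## Command line

```sh
Rscript inst/cli/photonsdf run config.json --out results/
Rscript inst/cli/photonsdf scenario slab --n 200000 --seed 1 --out results/
Rscript inst/cli/photonsdf make-vessels --n 50 --seed 1 --out vessels.tsv
Rscript inst/cli/photonsdf rasterize config.json --dims 100,100,100 --out labels.raw
```

All lengths are cm, coefficients cm⁻¹; right-handed world frame; runs are
bit-reproducible for a given seed (one RNG substream per packet).
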