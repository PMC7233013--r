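# tcindex — two-colour auto-indexing of still X-ray diffraction patterns

In two-colour serial femtosecond crystallography (SFX), each XFEL exposure
carries a *pair* of pulses at two photon energies, so every detector image
superimposes two diffraction patterns of the same microcrystal — and every
Bragg peak belongs to an unknown colour. With a large energy separation
(e.g. 7 and 9 keV) the two Ewald spheres sample disjoint slices of
reciprocal space and monochromatic auto-indexers break down. tcindex is for
crystallographers processing such data: it recovers the crystal orientation
**U** and the per-peak colour labels jointly, from peak positions alone
(no intensity sorting), given prior unit-cell parameters.

## Method in brief

With the orthogonalization matrix **B** of the reference cell (columns =
reciprocal basis vectors, crystallographic convention, d = 1/|q|), a trial
orientation **U** gives every observed scattering vector a fractional
Miller index h_f = (UB)⁻¹ q. A peak is *matched* when

    max_k | h_f,k − round(h_f,k) | ≤ δ        (δ = 0.25 by default)

under **either** photon energy, and the score S(U) is the number of matched
peaks. Candidate rotations come from a pre-computed, orientation-invariant
reference table: each reference reflection pair is stored as a triple
(|q_a|, |q_b|, angle), observed peak-pair triples are looked up within
tolerances (0.0025 Å⁻¹, 1°), and each hit yields a rotation by aligning
orthonormal triads over the two vector pairs. The best-scoring rotation
splits the peaks into colour groups via the probabilities
p_i1 = e_i2/(e_i1+e_i2) (smaller residual ⇒ larger probability), and a
global refinement minimizes the summed squared fractional-index deviations
of both groups over rotations only.

The package also ships the geometric two-colour pattern simulator used for
validation (Ewald-interception model with spherical lattice points,
ground-truth orientations and colour labels), evaluation metrics
(orientation error, indexing rate, colour accuracy, utility vs search
budget), plain-text I/O and a small CLI (`inst/cli/tcindex`).

## Worked example

```r
library(tcindex)

cell  <- unit_cell(64.3, 72.0, 89.2, 110.6, 107.5, 85.8)  # triclinic, P1
table <- reference_table(cell, d_min = 5)                  # 12,316 reflections
cfg   <- simulation_config(cell = cell)                    # 1440x1440 px, 7/9 keV

pat <- simulate_pattern(cfg, euler_to_matrix(c(10, 20, 30)))
pat
#> Simulated pattern: 778 peaks (398 colour-1, 380 colour-2, 60 dual-excitable), 0 dropped off-detector

sol <- index_two_color(pat$peaks, table, cfg$geometry, cfg$beam)
sol
#> Two-colour indexing solution (7 / 9 keV)
#>   matched 778 / 778 peaks (delta = 0.25)
#>   colour groups: 400 / 378 peaks, 0 unassigned
#>   refinement objective: 19.88 -> 7.162
#>   rotation U:
#>           [,1]     [,2]      [,3]
#> [1,]  0.924453 0.019140  0.380816
#> [2,]  0.164028 0.881640 -0.442500
#> [3,] -0.344212 0.471534  0.811895

orientation_error(coef(sol), euler_to_matrix(c(10, 20, 30)))$total
#> [1] 0.1926861
```

All 778 peaks match (S = 778), the recovered orientation is 0.19° from the
ground truth, and the 400 / 378 colour split recovers the true
7 keV / 9 keV label of every unambiguously separated peak (60 reflections
are excitable by both spheres and flagged `dual`). `plot(sol)` draws the detector view coloured
by assigned energy; `summary(sol)`, `residuals(sol)` and `predict(sol)`
expose the fit in the usual R idiom.

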