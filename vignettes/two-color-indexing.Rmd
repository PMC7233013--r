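---
title: "Two-colour auto-indexing: model, algorithm and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-colour auto-indexing: model, algorithm and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tcindex)
```

## The problem

In serial femtosecond crystallography (SFX) every microcrystal yields a
single still diffraction pattern before it is destroyed. In *two-colour*
operation the X-ray free-electron laser emits pulse pairs at two photon
energies, so each detector image superimposes two diffraction patterns of
the same crystal -- one per wavelength -- and each Bragg peak belongs to an
unknown colour. With a large energy separation (e.g. 7 and 9 keV) the two
Ewald spheres sample very different slices of reciprocal space, and
monochromatic indexers fail. tcindex recovers the crystal orientation and
the per-peak colour labels jointly, given prior unit-cell parameters.

## Model and algorithm

**Reciprocal geometry.** We use the crystallographic convention without the
$2\pi$ factor: the incident wavevector is $k_{in} = (0, 0, 1/\lambda)$ in
$\mathring{A}^{-1}$, a detector peak maps to the scattering vector
$q = k_{out} - k_{in}$ with $|k_{out}| = 1/\lambda$, and the resolution is
$d = 1/|q|$ (so a 5 A cutoff is $|q| \le 0.2\,\mathring{A}^{-1}$). The prior
cell enters through the orthogonalization matrix $B$ in the Busing--Levy
frame ($a^*$ along $x$, $b^*$ in the $x$--$y$ plane), whose columns are the
reciprocal basis vectors: $q_{hkl} = B\,h$. The orientation is a proper
rotation $U$, and $A = U B$ is the oriented reciprocal basis.

**Scoring.** For a trial rotation $U$, each observed vector gets a
fractional Miller index $h_f = (U B)^{-1} q$. The peak is *matched* when the
largest component deviation from the nearest integers is at most
$\delta$ (default 0.25). The score $S$ is the number of matched peaks; in
two-colour mode each detector peak is converted under both wavelengths and
a peak matched under *either* colour counts. The solution maximizing $S$
wins; ties are broken by the smaller summed residual over matched peaks,
then by earlier candidate rank, so the output is fully deterministic.

**Reference table.** Orientations never have to be sampled: each pair of
reference reflections is reduced to an orientation-invariant triple -- the
two vector lengths and the inter-vector angle. Observed peak-pair triples
are matched against the table within tolerances (defaults
0.0025 $\mathring{A}^{-1}$ and 1 degree), and every matched entry yields a
candidate rotation by aligning right-handed orthonormal triads built over
the observed and reference vector pairs. Friedel mates are enumerated
explicitly (space group P1, no symmetry reduction), and near-collinear
pairs (within 10 degrees of 0 or 180) are excluded because they leave the
rotation about the common axis undetermined.

With the default cell and a 5 A cutoff the table has ~12,300 reflections
and would have ~7.6e7 pair entries -- too many to materialize. The
`reference_table` object therefore stores the reflections sorted by vector
length and answers each query lazily: a binary-search length window per
observed length, then an exact angle filter. This is provably equivalent to
scanning a materialized pair list (the test suite checks the equivalence
against `table_entries()` on small tables), at a tiny fraction of the
memory.

**Colour probabilities and refinement.** After the best rotation is found,
peak $i$ carries residuals $e_{i1}, e_{i2}$ under the two colours and
receives colour probabilities
$p_{i1} = e_{i2}/(e_{i1}+e_{i2})$, $p_{i2} = 1 - p_{i1}$: the colour with
the smaller deviation gets the larger probability, the two always sum to
one, and equal residuals give an uninformative 0.5/0.5. Peaks with
$p > 0.5$ (and residual within $\delta$) form the two colour groups; the
rest stay unassigned. The rotation is then refined by minimizing
$$f(U) = \sum_{i \in G_1} \lVert h_{f,i}(\lambda_1) - h_i \rVert^2
       + \sum_{i \in G_2} \lVert h_{f,i}(\lambda_2) - h_i \rVert^2$$
over rotations only (the prior cell is never refit), with the integer
targets frozen at their values under the unrefined rotation. $U$ is
parametrized as an axis-angle perturbation composed with the start, so
every evaluated matrix is exactly orthonormal; BFGS does the minimization
and the start is returned (with a flag) if the optimizer fails to improve
-- the objective never increases, and the re-scored solution is never worse
than the unrefined one.

## The search in detail, and two design choices that matter

Peak pairs are ranked by the summed sorting key (SNR by default) and the
top $k$ (default 5) are used as seeds, as a search-budget control.
Two details are deliberate design choices of this implementation:

* **Seed-pair tie-breaking.** Noise-free simulated peaks all carry the same
  SNR, so the key alone does not order the pairs. Ties are broken toward
  pairs whose vector lengths lie closest to 85% of the table's maximum
  length. The rationale is geometric: the angular uncertainty of an
  observed Bragg vector scales inversely with its length (very short
  vectors make the observed triple's angle unreliable), while vectors at
  the very edge of the reference resolution range risk lying just
  *outside* the table, so their true entry does not exist. 85% of the
  maximum balances the two failure modes. Seeds are also restricted to
  peaks whose converted length falls inside the table's length range
  (within the length tolerance) -- pairs outside it provably cannot match
  any entry; scoring always uses all peaks.

* **Dual-hypothesis pair matching.** The colour of a seed pair is unknown,
  and the two conversions of the same pixel differ by the wavelength ratio
  in length. A same-colour pair selected under the wrong conversion would
  never meet its true table entry. Every selected pair is therefore
  queried under *both* wavelength hypotheses (skipping hypotheses whose
  lengths leave the table range). With at least three seed peaks the
  pigeonhole principle then guarantees a same-colour pair among the tried
  seeds, which removed an observed ~10% per-pattern failure mode.

All rotation candidates from both searches are scored with the two-colour
rule (not just each search's winner), which costs at most a factor of two
and removes the failure mode where the correct solution is second-best
monochromatically.

**Two-stage scoring.** Patterns simulated at the default settings carry
several hundred peaks, and a single seed pair can produce ~10^4 candidate
rotations at the default tolerances. Scoring every candidate against every
peak is wasteful, so candidates are first scored on a deterministic,
permutation-invariant subset of 60 peaks stratified across resolution
(every k-th peak of the length-sorted list); the best 50 candidates per
query are then re-scored against all peaks, and the winner is chosen from
the re-scored pool. Patterns with at most 60 peaks are scored in a single
exact stage, which is the regime of the brute-force equivalence tests. The
subset size and shortlist length are exposed in `indexer_params()`.

`min_score`, the acceptance threshold on $S$, defaults to
$\max(6, \lceil 0.4\,N \rceil)$: six matched peaks prevent a two-peak seed
from "indexing" pure noise, and the 40% fraction scales with dense
patterns.

## What the simulator does and does not emulate

The generator implements a purely geometric excitation model: reciprocal
lattice points are spheres of fixed radius $r$ (default
0.0015 $\mathring{A}^{-1}$), a reflection is excited when either colour's
Ewald sphere surface passes within $r$ of it, the registered position is
the radial projection of the lattice point onto the intercepting sphere
(the detector records where the sphere cuts the spot), and the spot is
projected onto a 1440 x 1440 panel of 100 um pixels 0.1 m downstream.
Defaults reproduce the validation conditions: triclinic P1 cell
$a=64.3$, $b=72.0$, $c=89.2$ A, $\alpha=110.6$, $\beta=107.5$,
$\gamma=85.8$ degrees, photon energies 7 and 9 keV, 100 patterns at
uniformly random orientations (unit-quaternion sampling). Euler angles use
the intrinsic z--y--x convention throughout.

Simulated spots are enumerated to 3 A while the reference table stops at
5 A -- deliberately different, so the indexer must digest peaks it can
never match directly. With these defaults a typical pattern carries
roughly 750--820 peaks (about 380--420 per colour, of which some 5--8% are
excitable by both spheres at once and are flagged `dual`).

The model excludes -- intentionally -- structure factors, partiality,
mosaicity, excitation-error weighting, detector noise, photon statistics
and peak-centroiding error (an optional Gaussian pixel jitter exists but
defaults to 0). Intensities and SNR are therefore constant. Consequently,
passing tests demonstrate the geometric correctness and robustness of the
search, colour assignment and refinement; they do not probe
intensity-dependent peak detection or centroiding noise, which real
experiments add on top.

## Numerical choices

* Nearest-integer rounding is half-away-from-zero, pinned for determinism
  (residuals at exactly 0.5 are measure-zero).
* Lab frame: beam along $+z$, detector plane at $z = $ distance, fast axis
  $+x$, slow axis $+y$; 0-based pixel coordinates with centres on
  integers; default beam centre (719.5, 719.5) is the panel centre.
* Wavelengths from $\lambda[\mathring{A}] = 12.398419/E[\mathrm{keV}]$.
* The "length tolerance" is interpreted in $\mathring{A}^{-1}$ (the
  quantities compared are reciprocal-vector lengths).
* The resolution sort key ranks pairs by ascending summed d-spacing
  ("best resolution first").
* Equal photon energies are accepted and degrade the pipeline to
  monochromatic behaviour: both residuals coincide, all probabilities are
  0.5, no peak is confidently assigned, and refinement is skipped in
  favour of the unrefined rotation.
* Zero excited spots, empty query results, and patterns with fewer than
  two peaks are valid outcomes (flagged or `NULL`), not errors; degenerate
  cells, collinear seed pairs and absurd enumeration requests are errors.

## Problem sizes used in the shipped checks

The validation suite indexes the full 100-pattern default simulation plus
20 patterns at 9/9.1 keV (the small-separation regime, where the spheres
nearly coincide and two-colour scoring degrades gracefully toward
monochromatic indexing), and compares the indexer against an exhaustive
reference search on a cubic 10 A toy cell (32 reflections at 5 A, 50
six-peak patterns); unit tests run on an 8 A variant of the default cell
to stay fast. On the cubic toy cell the lattice's 24 proper symmetries
make symmetry-equivalent orientations legitimately tie, so orientation
comparisons there are made modulo that group or on scores only; the
triclinic production cell has a trivial rotation group and needs no such
treatment.

## Known limitations

* Single-lattice indexing only; multi-crystal patterns are out of scope.
* The prior unit cell is trusted, never refined; a wrong cell fails
  cleanly (low $S$) rather than being corrected.
* P1 reference enumeration only -- no systematic-absence filtering, no
  symmetry-aware resolution of indexing ambiguity for symmetric lattices.
* Exactly two colours; pink-beam/bandwidth models and overlapped-spot
  intensity deconvolution at small energy separation are not addressed.
* The simulator's constant intensities make intensity-based sort keys
  inert on synthetic data (they matter on real peak lists).
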