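---
title: "Correcting superimposed mass isotopologue distributions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Correcting superimposed mass isotopologue distributions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(midfit)
library(dplyr)
```

## The problem

In a ¹³C tracer experiment the quantity of interest is the mass
isotopologue distribution (MID) of a metabolite: the fractions M0…Mn of
molecules carrying 0…n labeled carbon atoms, where n is the number of
*biological* carbons. What a GC-APCI-MS instrument delivers is an
intensity vector across consecutive nominal masses (the *rawMID*), and
three effects stand between the two:

1. **Natural isotope abundance.** Every unlabeled carbon carries ¹³C at
   about 1.1%, and the trimethylsilyl (TMS) groups attached during
   derivatization contribute three carbons and one silicon each. Silicon
   is only 92.2% ²⁸Si, with 4.7% ²⁹Si and 3.1% ³⁰Si, so silylated
   analytes have a broad natural pattern even without any tracer.
2. **In-source fragmentation.** Soft ionization produces mainly
   [M+H]⁺, but proton and hydrogen losses give [M]⁺ and [M-H]⁺ at one
   and two mass units below, and carboxylic acids often add water while
   losing methane, [M+H₃O−CH₄]⁺, which lands ~30 mDa below the M+2 peak
   of [M+H]⁺ — unresolved at QTOF resolution (R ≈ 35,000), hence in the
   same nominal bin.
3. **Superposition.** The measured intensity at each nominal mass is
   therefore a sum over fragments: the peak at the [M+H]⁺ position also
   contains [M]⁺+1 and [M-H]⁺+2.

Ignoring the fragments corrupts enrichment estimates in a characteristic
way: a fully labeled hexose forming 10% [M-H]⁺, corrected under the
assumption of pure [M+H]⁺, yields a spurious M4 = 10% (the [M-H]⁺ label
mass sits two bins low, which after correction looks like losing two
labels). This package models the superposition explicitly and inverts
it.

## The model

Let `mid` = (M0…Mn) be the label distribution and `r` the fragment
ratios over the configured fragment set (both simplex-constrained:
entries in [0,1], summing to 1). The reconstructed spectrum is

    recMID = sum_k  r_k * shift(A_k %*% mid, offset_k)

where column j of `A_k` is the natural-abundance isotope pattern of
fragment k's formula with j carbons excluded from the convolution (those
j carbons are fixed ¹³C under the label hypothesis; the remaining
biological carbons still draw natural ¹³C — toggleable via
`na_in_unlabeled`). Patterns are computed by discrete convolution of
per-element multinomial shift distributions at nominal-mass (1 Da bin)
resolution; exact masses only enter bookkeeping (isotopologue spacing
1.003355 Da). Each pattern column is renormalized over the measured
axis window after clipping — measured intensities of an isotopologue
are whatever falls inside the window — which makes `recMID` exactly
linear in both `mid` and `r` and normalized to sum 1.

The estimator minimizes `err = sum((rawMID − recMID)^2)` after clipping
negative raw intensities at zero and normalizing to sum 1.

## The search

Both unknowns live on simplices, and the minimization follows a grid
refinement scheme: candidates start on the coarse simplex grid of step
0.5 (for three isotopologues: {1,0,0}, {0,1,0}, {0,0,1}, {0.5,0.5,0},
{0.5,0,0.5}, {0,0.5,0.5}), then the incumbent is refined by moving
`step` of mass between coordinate pairs (clipped at 0, renormalized),
halving the step whenever no move improves, down to `step_min`.

When both vectors are free the search is nested — each `mid` candidate
is scored with its own best `r` — and several robustness devices are
layered on top, all deterministic and all within the grid-search family:

* **Beam refinement.** Descents start from the best few coarse seeds,
  not just the single best, because the degenerate geometry (below)
  creates distinct basins.
* **Shift moves.** Shifting the whole label distribution by ±1 mass
  unit is offered as an extra move; it is the known degeneracy
  direction.
* **Dual nesting.** The search is also run with `r` outside and the
  well-conditioned fixed-`r` label fit inside; the two nestings explore
  different basins.
* **Polish.** Endpoints are refined by alternating single-vector refits
  and finally by coupled small-step moves in both vectors
  simultaneously, which track the degeneracy valley that alternating
  refits zigzag along. The coupled stage continues below `step_min`
  (to `step_min/16`) because the residual is quadratic in the coupled
  displacement: certifying residuals at the 1e-8 scale needs parameter
  resolution finer than the nominal convergence step.

### Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `c13` | 0.0107 | fractional ¹³C abundance; 0.011 reproduces the coarser “1.1%” convention |
| `step_init` | 0.5 | coarse grid spacing of the first candidate set |
| `step_min` | 1e-4 | smallest refinement step; fixed-vector fits resolve parameters to about half the last step used (~6e-5) |
| `penalty` | 0 | λ of the multiplicative weight `1 + λ(1 − r_[M+H]+)` on `err`, disfavouring fragment-shifted solutions |
| `qc_m0_min` | 0.95 | stage-1 screen: free-fit M0 below this marks a control as suspect |

`step_min = 1e-4` rather than a looser stop is deliberate: the residual
is quadratic around the optimum, so a parameter resolution of 1e-4
certifies residuals near 1e-9, the scale at which solution families must
be compared.

## Degeneracy, ties, and the [M+H]⁺ preference

The joint problem is underdetermined in a structured way: a label
distribution shifted up by one mass unit, paired with a fragment one
unit lighter, reproduces the same spectrum (with natural abundance
switched off, `reconstruct_mid({0,1,0}, [M]⁺)` is bit-identical to
`reconstruct_mid({1,0,0}, [M+H]⁺)`). With natural abundance on, the
families differ only through second-order pattern differences, and with
measurement noise the residuals at their respective minima are
interpolation artifacts rather than evidence: a handful of observations
minus almost as many free parameters leaves residuals that reflect how
a particular noise realization projects, not which family is true.

The package therefore treats solutions whose penalized residuals agree
within a factor of 3 (plus 1e-9 absolute) as observationally
equivalent, resolves them toward the largest [M+H]⁺ share — the
dominant species in soft ionization, and the same direction the
explicit `penalty` pushes — and reports `ambiguous = TRUE` whenever
equivalent solutions with clearly different label distributions exist.
Inside the search itself, moves are accepted only on strict improvement
(beyond 1e-12), so fixed-vector fits remain exact; the wider window
applies only when comparing polished families of the free fit.

None of this replaces the robust protocol: estimate `r` on unlabeled
controls with the MID fixed at M0 = 100%, then fit labeled samples with
`r` fixed (`calibrate_then_correct()`). With either vector fixed the
minimizer is unique and the machinery above reduces to a plain,
well-behaved refinement.

### The QC screen

Stage 1 also refits each control with both vectors free and compares
the fitted M0 against `qc_m0_min`. Because the free fit can wander into
a label-shifted family on perfectly clean data (see above), M0 < 95%
alone does not condemn a compound: the flag is raised only if, in
addition, the fixed-M0 explanation misfits by more than three times the
noise level estimated from the spread of the control replicates. A
genuine spectral impurity — intensity at a position no unlabeled
fragment can produce — fails both tests.

## The synthetic-data generator

`simulate_mids()` produces intensity tables for testing and workflow
validation: the noiseless model spectrum, perturbed per position by
multiplicative lognormal noise (CV 2% by default, roughly the
replicate spread of well-measured peaks) plus a uniform additive
baseline (default ceiling 1e-4 of normalized intensity, emulating
detector floor), clipped at zero and renormalized. Replicates share the
true fragment vector, mirroring the observed stability of in-source
fragmentation within a measurement series. The generator does *not*
emulate chromatographic peak shapes, scan-to-scan correlation,
co-eluting contaminants, detector saturation, or tracer impurity — so
passing round-trip tests demonstrate correctness of the inversion under
the model's own assumptions, not robustness to everything a real
instrument does.

## Numerical choices

* Isotope patterns are truncated where the tail mass drops below 1e-9
  and renormalized; an explicit `max_shift` errors if it would discard
  more than 1e-6.
* Minor isotopes (²H, ¹⁵N, ¹⁷O/¹⁸O, ³³S/³⁴S/³⁶S) are in the default
  table but can be dropped (`minor = FALSE`); at nominal-mass
  resolution their effect is far below the fragment effects being
  corrected.
* The methane lost by [M+H₃O−CH₄]⁺ is taken from a TMS methyl, so that
  fragment's pattern uses one fewer derivatization carbon and the
  biological carbon count is unchanged.
* Raw spectra: negatives clipped to 0, normalized to sum 1; an all-zero
  vector is an error.
* Ties inside a candidate batch resolve toward the largest [M+H]⁺
  share, making results deterministic; repeated calls are bit-identical.

## Validation scale

The test suite validates the fit against independent oracles at sizes
where exhaustive enumeration is feasible: brute-force grid search on a
0.01 simplex grid for two-carbon joint fits and three-carbon fixed-`r`
fits, exhaustive isotope-placement enumeration for patterns up to
C9H20O3Si3, and 100 noiseless recovery simulations at n = 2–4. Larger
problems exercise the same code paths; only the oracle comparisons are
kept small.

## Known limitations

* With more than about four fragments or very short axes the joint fit
  approaches interpolation and `r` estimates become decorative; fix one
  vector.
* Compounds whose derivatized formula contains no silicon and few
  carbons give narrow patterns; the QC screen then has little power.
* Tracer impurity (the labeled substrate not being 100% labeled) is out
  of scope and should be corrected upstream or downstream with a
  dedicated tool.
* Fine-structure-resolving instruments (FT-ICR class) separate the
  species this package folds together; the nominal-bin model does not
  apply there.

## A worked example

```{r example}
# fragment ratios and labeling to recover
r_true <- c("[M-H]+" = 0.10, "[M]+" = 0.45, "[M+H]+" = 0.45)
controls <- simulate_mids("C9H22O3Si2", 3, c(1, 0, 0, 0), r_true,
                          n_rep = 3, seed = 1,
                          compound = "lactate_2TMS", sample_prefix = "C")
labeled <- simulate_mids("C9H22O3Si2", 3, c(0.10, 0, 0.20, 0.70), r_true,
                         n_rep = 3, seed = 2,
                         compound = "lactate_2TMS", sample_prefix = "L")
res <- calibrate_then_correct(controls, labeled)
res |> filter(component == "mid") |> head(8)
```

The stage-1 calibration is attached:

```{r calibration}
attr(res, "calibration")
```
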