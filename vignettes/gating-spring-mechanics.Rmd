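---
title: "Mechanics of the NompC gating spring: models, pipeline and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mechanics of the NompC gating spring}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gatingspring)
```

## The system and the model

NompC is a homotetrameric mechanosensitive channel whose long
ankyrin-repeat domains (ARDs, 29 repeats of 33 residues per subunit) act
as the gating spring that transmits cytoskeletal force to the channel
gate. This package models a single nanodisc-embedded NompC complex held
between two optically trapped beads through a pair of dsDNA handles, and
implements the analyses that turn pulling and force-clamp trajectories
of that tether into the spring's mechanical parameters.

The tether is an ordered series of mechanical elements sharing one
tension \(F\):

* **Worm-like chains** (DNA handles, unfolded polypeptide), with the
  interpolation formula
  \(F = \frac{k_BT}{P}\left[\frac{1}{4(1-x/L)^2} + \frac{x}{L} -
  \frac{1}{4}\right]\)
  and its exact integral for the entropic stretching energy
  \(E = \frac{k_BT}{P}\frac{L}{4}\,
  \frac{3(x/L)^2 - 2(x/L)^3}{1-x/L}\).
* **An elastic rod** for the structured protein portion,
  \(x = x_0 + F/k\).
* **A rigid offset** for the nanodisc (constant ~5 nm below 7 pN).
* **Parallel bundles** of identical elements (the four disordered
  N-terminal chains), which share a common extension and split the
  tension equally, so a bundle's compliance is the member compliance
  divided by its multiplicity.

Series extensions add at common force; series compliances add, so the
tether stiffness is the reciprocal summed compliance. All inverses
(extension at force, force at extension) are solved by safeguarded
vectorized bisection far below the 1e-9 relative tolerance the analyses
need, and every module above builds on these primitives.

Defaults follow the experimental system: \(k_BT = 4.1\) pN nm, 0.365
nm/residue of unfolded polypeptide, 0.338 nm/bp of B-DNA (so the 2 x
2260 bp handles give \(L = 1527.8\) nm — the rise itself is not stated
by the study, so it is a configurable package choice), persistence
lengths 40 nm (DNA) and 0.6 nm (polypeptide). The WLC is inextensible
(no stretch modulus): forces stay below ~20 pN where enthalpic
stretching is minor.

## The differential force-extension pipeline

Absolute protein extension comes from a *differential* measurement: the
same DNA tether is measured alone, the protein is swapped in by
toehold-mediated strand displacement, and the DNA contribution is
subtracted per force bin. The pipeline is:

1. **Box filtering** (100 ms default; the experimental range is 50-200
   ms) of force and extension.
2. **Force binning** (0.2 pN bins over 0.5-20 pN): per-bin mean,
   population SD, and count of extension. Sample SD is used for
   across-molecule statistics (the two conventions are recorded in the
   objects).
3. **Differential subtraction**: protein-tether minus DNA-only
   extension per shared bin, minus the WLC extension of the disordered
   tail (123 residues per pulled subunit) and the nanodisc offset; SDs
   propagate in quadrature.
4. **Pooling** across molecules by exact moment accumulation.
5. **Linear stiffness fit** over the folded-state range (1-7 pN, below
   the first unfolding force; 1-5 pN for the constructs that unfold
   near 5 pN). Because the curve is binned *by force*, force is the
   nearly noise-free predictor, so the fit regresses extension on force
   (weighted by bin counts) and reports \(k\) as the reciprocal slope.
   Regressing force on extension instead attenuates stiff springs badly
   once the extension change across the fit range approaches the bin
   noise. This is the one place the package deliberately transposes the
   textbook "fit F against x" phrasing; the fitted law is identical.

A simultaneous (global) weighted fit of the DNA-only curve and any
number of tether branches shares the handle and rod parameters and
gives one unfolded contour length per branch. Branch contour *gains*
are referenced to the first branch's fitted contour, not to the nominal
tail length: errors in the shared parameters then cancel between
branches, which is what makes the 29-repeat assignment of the fully
unfolded state stable from single traces.

## Rips, states and refolding

Discrete transitions are detected on the filtered trace as jumps
between drift-corrected baseline windows (0.2 s on each side, with a
guard for the filter's smearing). The drift correction uses 2-s secant
slopes on both sides of the candidate, keeping whichever is smaller in
magnitude, so one nearby rip cannot bias it; candidates without full
window support at the trace edges are not evaluated. The default 3-nm
threshold sits several noise SDs above the post-filter floor while the
smallest reported discrete features are about 5 nm. One caveat the
generator makes explicit: at trap stiffnesses of 0.1-0.3 pN/nm the
tether is much more compliant than the traps, so a contour release of
\(a\) nm appears in the recorded extension as only
\(a \cdot C_{trap}/(C_{trap}+C_{tether})\) — rip sizes quoted from raw
traces are trap-geometry-dependent, which is why state assignment works
on fitted contour gains instead.

Contour gains convert to unfolded residues (gain / 0.365 nm, rounded
half-to-even) and ankyrin repeats (residues / 33); gains matching ~10,
~20 and 29 repeats within +/-2 get the intermediate labels I1/I2/I3.
Occurrence profiles count each visited gain once per molecule on a
uniform gain grid and normalize to unit mass. A repull is classified as
refolded when its binned curve deviates from the first pull by at most
2 nm RMS over 2-6 pN — below the smallest inter-state extension
difference there; the study itself states no quantitative criterion, so
this is a package decision.

## Constant-force gating analysis

The putative gating transition appears as two-state flicker at constant
mean force. The extension histogram (0.25-nm bins, normalized density)
is fit with a sum of two Gaussians by Levenberg-Marquardt from two
initializations (the two most prominent local maxima, and the 20%/80%
mass quantiles), keeping the lower-residual fit; labels are
canonicalized so the high-extension mean is always `mu_high`, and fits
whose components collapse (separation under one bin, or a vanishing
weight) are flagged degenerate rather than reported.

State *occupancy*, used for the equilibrium-force ladder, comes from a
shared-variance two-component EM on the raw samples (`two_state_em`):
with a 4.7-nm swing and 1.5-2 nm of measurement noise the modes overlap
strongly, and an unconstrained curve fit of a skewed density is
ill-conditioned where the sample-based EM with quantile initialization
remains stable (it is cross-checked against an independent mixture
fitter in the test suite). The equilibrium force interpolates the zero
crossing of the occupancy log-odds versus force, which is exact for a
two-state system with constant swing. The gating energy is the
reversible work \(F_{eq}\,\Delta x\), reported in pN nm, \(k_BT\)
(/4.1) and kcal/mol (/6.9477; \(k_BT\) = 0.59 kcal/mol at room
temperature); a per-transition entry point averages the products
instead of multiplying the means. The reported swing is the raw
Gaussian-mean separation — no handle-compliance correction is applied,
matching how the measurement is presented.

## The coupled-spring and Boltzmann gating model

Each ARD is a uniform elastic rod (segment stiffness inversely
proportional to repeat count); the four subunits are joined at the
N-terminal contact site after repeat 9. The C-terminal 20-repeat
segments of all four subunits act in parallel, the N-terminal segments
of the \(N\) pulled subunits act in parallel, and the two groups are in
series, giving
\(k_T(N) = \frac{29N}{9+5N}k_a\)
— always evaluated from the segment rule, never hard-coded, and checked
against a brute-force network reduction. Calibrating \(k_a\) from the
measured single-subunit value 0.7 pN/nm gives 0.34 pN/nm per isolated
ARD and 1.35 -> ~1.4 pN/nm with all four subunits pulled.

A gating state is a rod (stiffness 1.4 pN/nm; intrinsic length 20 nm
folded / 14.5 nm partially unfolded, +4.6 nm when open) in series with
the bundle of disordered chains (123 residues per subunit folded; 442
per subunit in the partial state — the study's "442 disordered
residues" is ambiguous between per-subunit and total, and the
per-subunit reading is exposed as configuration). The state energy is
\(E = F^2/2k + E_u + V\) with \(V = 8\,k_BT\) for the open state, and
the opening probability is Boltzmann,
\(P = 1/(1+e^{\Delta E/k_BT})\). \(\partial E/\partial x = F\) holds to
1e-5 by construction and is tested. In the chain-free configuration the
average branch tension at \(P = 1/2\) is exactly
\(V k_BT/\text{swing} = 7.13\) pN independent of the rod stiffness;
with the chains the model's gating force lands at ~7.1 pN, consistent
with the measured 6.9 +/- 0.6 pN equilibrium force. The "gating force"
is reported as the average of the branch tensions at the \(P = 1/2\)
extension, with both branch tensions returned so other conventions can
be checked.

The loading-rate estimate treats a sinusoidal stimulus as traversing
its amplitude once per half-period (rate \(= 2fAk\); the
\(2\pi f A k\) instantaneous-peak convention is available behind a
flag): 1 kHz and 1 nm on 1.4 pN/nm give 2800, i.e. ~3e3 pN/s at one
significant figure. Rupture kinetics use the standard one-barrier
Bell-Evans law with configurable \(k_0\) and \(x^\ddagger\), validated
against its own closed-form mode and normalization; the study's fitted
kinetic parameters are unpublished, so none of its kinetic predictions
are reproduced numerically and the defaults are placeholders.

## The synthetic-data generator

The generator is the package's stand-in for raw instrument data and
defines the conditions every recovery test runs under. Pulls are
quasi-static: one trap moves at 10 nm/s, the two traps (0.3 pN/nm each,
in series) balance the tether at every separation, and rips switch the
unfolded-residue count either at a programmed force (deterministic
tests) or by a per-step Bell-rate draw (distribution tests). Noise is
i.i.d. Gaussian per raw sample at 100 Hz — 2 nm on extension, 0.2 pN on
force — calibrated so filtered traces show the noise scale the study's
figures suggest; clamp traces are exact-dwell two-state Markov chains
whose stationary occupancy obeys the Boltzmann relation, with a rate
scale of 2/s per direction so a 60-s trace holds on the order of 100
transitions (the study reports no rates). Every simulated object
carries its full truth (and files a `.truth.json` sidecar), and a given
seed reproduces traces byte-for-byte.

What the generator does *not* emulate — bead Langevin dynamics,
correlated low-frequency drift, anti-correlated force/extension noise
from the shared detector, misfolded-state mechanics beyond a trapped
unfolded segment — bounds what passing recovery tests show about real
data: they validate the estimators against the model's own assumptions,
not against instrument pathologies.

## Problem sizes and statistical power

Recovery tests run at the study's scale where that scale is stated: 10
molecules for the stiffness cohorts, 60-s clamps, a 5-force ladder. For
the stiffness-measurability sweep (0.1-30 pN/nm within 20%) the
dominant error is not the extension noise but the force noise acting
through the handle compliance (~65 nm/pN at low force): each
molecule-bin localizes the curve only to about 1 nm, so the relative
error of a fitted compliance grows roughly in proportion to \(k\) and
falls as \(1/\sqrt{n}\). The sweep therefore scales its cohorts with
stiffness (10 molecules up to 1 pN/nm, 50 at 3, 500 at 10, 2500 at 30)
— the same reason measuring a stiff spring through soft handles needs
far more pooled pulls in a real experiment. These sizes were fixed by
this power analysis before the tests were frozen.

## Known limitations

* The inextensible WLC overestimates handle tension above ~20 pN.
* Heterogeneous parallel bundles (unequal members) are out of scope.
* Rip sizes reported from traces are trap-geometry-dependent (see
  above); cross-instrument comparisons should use contour gains.
* The Bell-Evans module is generic; no claim is made to reproduce the
  study's kinetic fits.
* Hidden-Markov segmentation, drift correction beyond box filtering,
  and dwell-time kinetics from clamps are deliberately not implemented.
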