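---
title: "Designing dose-range covering AEC profiles for dual-energy CT"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing dose-range covering AEC profiles for dual-energy CT}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gsiprofile)
```

## The model

Fast kV-switching dual-energy acquisitions run both tube currents fixed for
the whole scan: there is no longitudinal or angular current modulation. The
scanner's automatic exposure control therefore reduces to a discrete choice.
Each *preset family* fixes the scan field of view, focal spot, collimation,
rotation time $T$ and helical pitch $p$, and offers a finite list of tube
currents; the dose it delivers is

$$\mathrm{CTDI_{vol}} = k \cdot \mathrm{mA} \cdot T / p,$$

the standard helical scaling, with $k$ a per-family coefficient (mGy per
mA·s at pitch 1) that absorbs everything this package deliberately does not
model — kV-pair spectra, bowtie filtration, focal-spot dependence. A family
is thus a discrete dose grid bounded by `ctdi_min` and `ctdi_max`. Vendor
documentation typically prints only those bounds; bounds-only families are
first-class here, with a uniform synthetic grid of `n_grid` points (default
20) standing in for the unpublished current list. Every published headline
quantity the package reproduces depends only on the range endpoints, not on
the grid interior.

Doses are compared and displayed at one-decimal mGy precision, matching how
such tables are printed; internal arithmetic is full precision. SFOV and
collimation matching is exact equality — there is no fuzzy matching of
labels.

## The greedy covering procedure

A *profile* bundles up to four role-labelled families. The builder works on
the constraint-filtered candidate list in canonical order (ascending
`ctdi_min`, ties by ascending `ctdi_max`, then input order — the order such
tables are printed in):

1. **small** = the first candidate;
2. **medium** = the *last* Large-focal candidate with
   `ctdi_min < ctdi_max(small)`;
3. **large** = the *last* Large-focal candidate with
   `ctdi_min < ctdi_max(medium)`;
4. **xlarge** = the candidate with the highest `ctdi_max` among all
   permitted focal spots.

Reading "first"/"last" against the canonical order, and taking "minimum
less than" as *strict* inequality, follows the procedure's wording;
equality excludes a candidate. The extra-large search compares `ctdi_max`
with ties broken toward lower `ctdi_min` (a smaller range floor costs
nothing at the top of the ladder) and then canonical order. The source
procedure leaves the extra-large focal-spot condition slightly open; this
implementation admits the XLarge spot for that role whenever the
constraints allow it, consistent with every published example, where the
extra-large row is the only XLarge one.

When a later search lands on a family already holding a role, the role is
dropped — the published procedure states this for the extra-large role and
we extend it to the earlier searches so degenerate tables (down to a single
family) still build valid profiles. The primary role is metadata only: it
never changes the selection, just which member is listed first on
serialization (a bariatric facility might designate large, a paediatric one
small). If a collapse removed the requested primary role, the primary
remaps to the surviving role of the same family.

`validate_profile()` checks the design goal — consecutive ranges that
overlap, but barely: it flags every gap between consecutive role ranges and
reports the total overlap fraction. Note that the published four-family
tables themselves contain one such gap (45.5 → 49.7 mGy below the XLarge
family), so a gap diagnostic is information, not an error.

No exhaustive or optimal profile search is attempted; the greedy procedure
*is* the artifact, and the brute-force literal re-read exists only as a test
oracle.

## The coverage statistic

For an achievable-dose set $A$ and target $t$, the signed fractional
mismatch is

$$f(t) = \frac{t - \mathrm{nearest}_A(t)}{t},$$

zero exactly when the target is achievable, negative when the nearest grid
value overshoots, and tending to 1 as $t$ grows beyond the range maximum.
`coverage_report()` pools the member grids and evaluates $f$ on a target
grid — by default 200 log-spaced points from half the union minimum to 1.5
times the union maximum, chosen to show both the covered interior and the
degradation outside. The coverage tolerance defaults to 0.05 and is applied
two-sided ($|f| \le 0.05$), since "within ±5%" claims are two-sided; the
signed values remain available in the tidy output. Whether a scanner's
closest-dose search breaks exact midpoint ties up or down is not public;
this package resolves ties to the *lower* dose, a recorded convention
rather than a vendor fact, applied consistently in the selector, the
simulator and the oracles.

Noise propagates to dose through the inverse-square law
$\sigma \propto D^{-1/2}$: a fractional noise-index deviation $\delta$
corresponds, to first order, to a $2\delta$ dose mismatch. The exact
mismatch $1 - (1+\delta)^{-2}$ agrees with $2\delta$ to within $3\delta^2$
for the positive deviations relevant here, which the tests verify
numerically. At the operating point (noise index 18 HU, switching threshold
2 HU) this gives the 11% noise / 22% dose figures; the named constant
`CTDI_INSIGNIFICANT_CHANGE` (0.25) marks the dose change below which noise
differences are not clinically noticeable, and reports annotate against it.

## The scan-time simulator

The simulator needs a thickness-to-dose law the source procedure does not
publish; the package adopts

$$\mathrm{CTDI}(d, NI) = \mathrm{CTDI}_{ref}\cdot
  \left(\frac{NI_{ref}}{NI}\right)^2 \cdot 2^{(d - d_{ref})/d_{double}}$$

with defaults $d_{ref} = 30$ cm water-equivalent thickness,
$\mathrm{CTDI}_{ref} = 15$ mGy, $NI_{ref} = 18$ HU and $d_{double} = 5$ cm.
The exponential form and the 5 cm doubling distance are anchored to the
observation that patient size commonly changes by ~5 cm along an
abdomen/pelvis scan, roughly halving transmission; the reference point is a
typical adult-abdomen operating point. All four are per-patient parameters,
not hidden constants, because the simulator's purpose is self-consistency
of the workflow, not replication of any scanner's calibration curve.

The single per-scan target dose is the unweighted mean of per-slice
requirements; how a real scanner aggregates thickness into one target is
unpublished, so `max` and quantile rules are available behind the
`aggregate` argument. The projected noise index is
$pni(z) = NI\sqrt{\mathrm{required}(d(z))/\mathrm{delivered}}$ and AvgPNI is
its unweighted mean over the sampled positions — also an assumption, flagged
as such. (Note $pni$ is independent of the prescribed NI once expanded: the
$NI^{-2}$ inside `required` cancels the prefactor, as it should — the
projected noise is a property of the delivered dose.) The switching rule is
strict: deviations of *exactly* the threshold keep the primary family.
`switch_large` selects the profile's large role, falling back to xlarge and
then to keeping the primary when absent; the published instruction names
only the large preset, so the fallback is this package's choice. Dual-energy
noise is treated as a single channel, on the stated equivalence between
70 keV monochromatic image noise and a dose-matched single-energy
acquisition; no spectral modeling is attempted.

For constant-thickness patients the pipeline collapses to the closed form
$\mathrm{AvgPNI} = NI\sqrt{\mathrm{target}/\mathrm{actual}}$, which the
tests check to $10^{-9}$ relative — a strong end-to-end identity because the
two sides travel different code paths.

## Synthetic data

The generators exist so every stage is testable without scanner access, and
they emulate structure, not physics:

* `generate_family_table()` draws pitches from {0.508, 0.992, 1.375, 1.531}
  and rotation times from {0.5, 0.6, 0.8, 1.0} s (the discrete options of
  the scanner class being modelled), mostly Large focal spots, explicit mA
  grids of 10–40 steps at 5 mA increments, and log-normal dose coefficients
  centred near 0.02 mGy/mA·s so ranges land in the clinical few-to-tens of
  mGy. Identical seeds give identical tables, byte-for-byte through CSV.
* `generate_patient()` builds a smooth thickness profile: linear taper plus
  a random-phase low-frequency sinusoid of amplitude `d_sd`, so the
  deviation from trend is strictly bounded — useful for tests that need
  hard bounds rather than probabilistic ones. 20 axial samples by default.
* `generate_cohort()` samples mean thicknesses from a truncated normal and
  is the basis of the monotonicity checks (with within-patient variation
  switched off, so patient ordering is unambiguous).

What the generators do *not* emulate: real mA lists (vendor appendices are
not public, and any claim depending on grid granularity — such as matching
a vendor profile's ~1% precision — cannot be checked), scout-image
segmentation, tube-heating current caps, or anatomical asymmetry. Passing
tests therefore demonstrate the procedure's internal correctness and its
stated properties on realistic ranges, not agreement with any specific
scanner.

## Numerical and testing choices

Problem sizes were chosen to make the statistical checks decisive yet quick:
$10^4$ random grids for the nearest-value oracle, 200 seeded random tables
for the builder-vs-literal-procedure comparison, 400 interior targets for
coverage, a 60-patient cohort for monotonicity. The interior-coverage check
uses the overlapping three-family profile with 20-point uniform grids, where
the worst-case relative spacing stays under the 5% tolerance by
construction; the measured covered fraction is 1.0. Degenerate inputs are
exercised explicitly: single-family tables, empty candidate sets (a named
error listing the violated constraints), bounds-only families with equal
endpoints, and targets outside every range (which clamp to the nearest
endpoint).

## Known limitations

* The dose model is a two-parameter abstraction; absolute doses are only as
  meaningful as the user's calibration of `ctdi_ref`/`ni_ref`.
* Bounds-only families use a uniform synthetic grid; real mA lists are
  denser at the low end on some scanners, so interior coverage numbers for
  bounds-only families are approximations.
* Reconstruction-series parameters, material-decomposition accuracy and
  focal-spot resolution trade-offs are selectable constraints only
  (`allow_xlarge`, rotation-time limits), never modelled physically.
* The "tube current" of a dual-energy preset is treated as one abstract
  current; low- and high-kV currents are not separated.
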