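---
title: "Methods: Kendrick mass defect analysis of fingerprint lipid aging"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: Kendrick mass defect analysis of fingerprint lipid aging}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kmdaging)
```

## The problem

Sebaceous fingerprints are deposited as a fairly simple lipid film --
mostly triacylglycerols (TGs), with squalene (SQ), wax esters (WEs), free
fatty acids (FAs) and diacylglycerols (DGs). Exposed to ambient air, every
C=C double bond in these lipids is attacked by ozone (ozonolysis) and, on
the topmost monolayer, by singlet-oxygen-driven epoxidation. Within a week
the film becomes a complex mixture of substrates and oxidation products
whose composition encodes the time since deposition. High-resolution
MALDI-MS resolves this mixture, and Kendrick mass defect (KMD) analysis
organizes it: this package implements the full desk-side workflow, from
the theoretical product library to the aging markers, together with a
ground-truthed spectrum simulator so that every stage is testable without
access to real fingerprint data.

## Mass arithmetic and conventions

All masses derive from a table of monoisotopic atomic masses
(`atomic_masses()`) pinned in code at the CODATA/IUPAC values for
^12^C, ^13^C, ^1^H, ^16^O, ^23^Na and ^39^K plus the electron mass.
Ion m/z subtracts one electron mass per charge: at m/z 800 the electron
amounts to 0.7 ppm, which would consume a third of the 2 ppm annotation
budget if ignored.

Unsaturation bookkeeping uses a *neutral-parent* convention
(`dbe()`, `z_value()`): the cationizing Na or K of an adduct contributes
nothing, while a salt-forming sodium (the Na of a sodium carboxylate)
counts as one hydrogen. This makes the heteroatom classes come out at the
values used throughout the analysis: saturated TGs at DBE 3 (three ester
carbonyls), monounsaturated sodiated TGs C~c~H~2c-Z~O~6~Na at DBE 4, and
disodiated saturated FAs C~c~H~2c-Z~O~2~Na~2~ at DBE 1. Z = 2(DBE - 1) is
even by construction; a fully saturated acyclic parent (C~n~H~2n+2~) has
Z = -2.

## The oxidation product library

`build_target_list()` enumerates, per substrate class, the theoretical
ions of five product stages:

* **substrate** -- the intact lipid;
* **A** -- the head aldehyde of ozonolysis (substrate - C~w~H~2w~ + O for
  cleavage at omega-w);
* **B/C** -- the isomeric head Criegee carbonyl oxide / acid
  (substrate - C~w~H~2w~ + 2O), emitted both as the monosodiated ion and,
  in its acid form (**C**), as the disodiated sodium-carboxylate adduct;
* **AA** -- double ozonolysis on two acyl chains (DG/WE/TG only);
* **E** -- the epoxide (substrate + O, chain intact, DBE conserved).

Sodium adducts are primary (sodium acetate cationization); FAs and all
acid products are additionally emitted as [M - H + 2Na]^+^; every entry
gets a one-K-substituted twin. Entries whose ion formulas coincide are
collapsed into multi-label entries: the A and E products of one substrate
necessarily share a heteroatom class (one extra O, same Z), which is why
the aldehyde and epoxide series can only be separated along the mass
axis, not in the KMD dimension.

Default carbon ranges (formula carbons: FA 8--26, DG 26--44, TG 40--60,
WE 26--46; products reaching 16 carbons further down) span the
instrument's m/z 100--1200 window. The class grid's minimum Z values are
reconstructed from ester-count logic; squalene is enumerated as a single
species (substrate and epoxide only), since it has no homologous series
and its ozonolysis products are volatile. Tail aldehydes (e.g. decanal)
are excluded by default -- they evaporate and are observed by GC-MS, not
MALDI -- but a configuration flag restores them.

## Kendrick analysis

`kendrick_mass()` rescales m/z by 14/14.01565 (the CH~2~ base mass taken
from the same atomic-mass table) and `kendrick_mass_defect()` returns
round(KM) - KM with round-half-up. Two conventions deserve note:

* the sign convention (rounded KM minus KM) puts the lipids in a positive
  0.05--0.35 window, which is the default plot range;
* the literature sometimes uses KM - floor(KM); with the convention here,
  series one double bond apart are offset by exactly 0.0133994 (0.0134 at
  the usual print precision).

The rounding rule at the half-integer boundary is round-half-up; no
species in the library sits near the boundary, so the choice is
documentation rather than substance. `group_homologous_series()` connects
peaks whose KMDs agree within 0.0005 (about 2 ppm in KMD units at m/z
250) and whose spacing is an integer multiple of CH~2~ within 2 ppm,
closing membership transitively with a union-find pass over the sorted
KMD axis.

## Annotation and class profiles

`annotate_peaks()` assigns each centroid to the minimum-|ppm| target
within +-2 ppm via binary search. Ties prefer Na over K adducts, substrate
over product tags, then fewer oxygens -- potassium adducts are real but
minor, and must never displace a sodium assignment. Unassigned peaks are
kept with NA fields; annotation is deterministic and independent of input
order.

Type-II isotopic interference -- the M+2 ^13^C isotopologue of a lipid
with one more double bond landing 0.0089 Da (2 x 1.003355 - 2 x 1.007825)
below a monoisotopic peak -- is resolved at the simulated resolving
power, but `flag_type2_interference()` still marks assignments whose
expected isotopologue contamination (binomial ^13^C statistics at the
interferer's carbon count) reaches 20% of the assigned intensity; the
threshold is a package choice, configurable.

`class_intensity_profile()` extracts one heteroatom class (fixed O/Na/K
and DBE) as intensity versus carbon number, zero-filled so valleys are
explicit. `split_bimodal_profile()` smooths with a 3-point moving
average, requires a secondary mode of at least 5% relative height
(smaller bumps are baseline), and splits at the interior minimum between
the two largest maxima -- the algorithmic version of reading the
aldehyde/epoxide separation off the profile. Modes at least 8 carbons
apart are labelled A (low) and E (high), consistent with omega-10
dominated cleavage.

## Spectra: normalization and subtraction

Deposition amount varies between fingerprints, so spectra are normalized
to the summed signal of annotated saturated TG substrates
(`normalize_to_saturated_tg()`), which aging leaves untouched.
`subtract_spectra()` pairs peaks of two normalized spectra by mutual
nearest neighbour within 2 ppm (the pairing rule is a package choice) and
reports aged minus fresh, keeping unmatched peaks with the absent side at
zero. S/N uses the peak list's noise-level metadata when present and the
median peak intensity otherwise; the S/N > 30 plot filter therefore has a
defined meaning for data without a noise model.

## Aging markers

* `epoxide_ratio_series()`: TG(E) c:r normalized to the saturated TG c:0
  of the same carbon count, averaged over monitored carbons, then mean
  +- 1 sd over replicates per age. Because TG(A) shares the epoxide's
  heteroatom class at lower mass, the monitored window defaults to the
  high-mass mode found by the bimodal split of the replicate-pooled class
  profile.
* `fa_profile_series()`: disodiated FA intensity versus chain length
  (8--20) per age, separately for saturated and monounsaturated FAs.
* `fa10_marker()`: FA 10:0 (the accumulating omega-10 tail acid, m/z
  217.117) over an endogenous long-chain FA. FA 15:0 is the default
  normalizer -- odd-chain, constant over aging and with little
  contamination risk.

All markers are intensity ratios and hence invariant to deposition
scaling; missing peaks enter as zero intensity rather than being dropped,
keeping series lengths equal. Replicates aggregate as arithmetic mean
+- 1 sd with no outlier rejection.

## The simulator: what it emulates, and what not

`default_sebum_profile()` builds a TG-dominated composition: TGs over
acyl carbons 42--56 (Gaussian weights centered at 48, matching the most
abundant TG ions in the 770--900 m/z region, with the named species
TG 47:1 prominent), 0--3 double bonds; WEs, DGs, endogenous FAs 13:0--18:1
(sapienic-type 16:1 prominent) and squalene. Double-bond omega positions
are drawn from a distribution with weight 0.65 at omega-10 and the rest
shared by omega-8/9/11; medium-chain FAs start at zero.

`age_profile()` evolves the profile with deterministic expectation
kinetics:

* ozonolysis is first-order per C=C with a single ambient rate constant
  (default 0.3 per C=C per day) -- only relative trends are meaningful,
  no absolute rate is claimed;
* epoxidation is an instantaneous capped conversion (default 5% of each
  unsaturated species) encoding the top-monolayer hypothesis: epoxides
  form fast, then stop, and those with residual C=C keep ozonolyzing;
* species with one reacted bond accumulate as (relatively stable)
  secondary ozonides; with two or more, as double ozonides (DG/WE/TG);
  reacted squalene is lost to volatiles;
* species mass balance holds to 1e-9 at every time point by construction.

`render_spectrum()` is the measurement model: sodiated (acids:
disodiated) ions at exact m/z; the ozonide pool split by a detection
branching (60% intact ozonide ion, 25% in-source head aldehyde, 15%
in-source Criegee products including the tail acid -- free parameters,
exposed in the configuration and deliberately excluded from quantitative
claims); binomial M+1/M+2 ^13^C isotopologues; 5% one-K-substituted
twins; Gaussian ppm jitter (0.5 ppm sd, clipped at 2); lognormal per-peak
intensity noise (sdlog 0.1) and additive uniform-m/z noise peaks.
Everything is seeded and byte-reproducible. `generate_timecourse()`
produces the default study design -- ages 0/1/3/5/7 days, four replicates,
lognormal per-replicate deposition factors.

A `sparse_ozone_params()` preset (ozonolysis / 5, epoxide cap x 2)
mimics a low-ozone, UV-lit chamber: under it the summed TG epoxide signal
exceeds the TG Criegee acid signal, while the ambient preset gives the
reverse -- the qualitative contrast used to attribute the epoxide series
to singlet oxygen rather than ozone.

What the simulator does *not* emulate: spatial (imaging) structure,
humidity/temperature covariates, kinetics of volatile squalene products,
isotope fine structure beyond ^13^C, and profile-mode peak shapes (all
spectra are centroids). Passing the end-to-end tests therefore shows the
analysis correctly recovers trends from data with this statistical
structure, not that real fingerprints will be as well behaved.

## Numerical choices and degenerate inputs

* Annotation tolerance 2 ppm, subtraction pairing 2 ppm, S/N filter 30,
  KMD window 0.05--0.35 -- the printed operating points of the analysis.
* Duplicate m/z rows in a peak list merge by intensity sum with a
  warning; malformed rows fail with their line number.
* Normalization with no saturated-TG signal is an error (undefined), and
  it is idempotent once applied.
* An empty peak list annotates to an empty table, and an empty class
  yields an empty profile; an unknown class is an error.
* `fa10_marker()` with a zero normalizer is an error rather than an
  infinite marker.

## Problem sizes

The default target list holds about 3,300 entries. The default simulated
time course (5 ages x 4 replicates, roughly 4,000 peaks per spectrum)
generates in about a minute and annotates in a few seconds on one CPU;
the test suite runs the full design once and reuses it across checks.

## Known limitations

Hydroxyl isomers of the epoxides are isobaric at this resolution and are
not separate entries; the Criegee acid/carbonyl-oxide split between mono-
and disodiated detection is a free parameter; double ozonolysis within a
single FA chain is not enumerated; and the branching fractions of
in-source ozonide fragmentation are unknown in reality -- the package
treats them as configuration, and no quantitative acceptance rests on
them.
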