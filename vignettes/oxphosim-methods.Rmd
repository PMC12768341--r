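---
title: "Modelling mitochondrial bioenergetics and matching defect phenotypes with oxphosim"
author: "oxphosim authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling mitochondrial bioenergetics and matching defect phenotypes with oxphosim}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The model

`oxphosim` implements a flux-based, thermokinetic ordinary differential
equation model of oxidative phosphorylation in intact cells, in the lineage
of the Beard-type biophysical models of the respiratory chain.  Three
compartments are represented (mitochondrial matrix, inter-membrane space
(IMS), cytosol) with 22 state variables: the mitochondrial membrane potential
$\Delta\Psi_m$ (mV); matrix NADH/NAD$^+$, ubiquinol/ubiquinone, cytochrome
c$_{red}$/c$_{ox}$ (IMS), adenine nucleotides and phosphate in matrix and
cytosol, protons and potassium per compartment, oxygen, and H$_2$O$_2$ in
matrix and cytosol.  Oxygen, cytosolic pH and cytosolic K$^+$ are clamped
(oxygen non-limiting; the cytosol is treated as pH- and K-statted by
processes outside the model).

Fluxes are mass-action rates with thermodynamic driving terms.  Each proton
pump (complexes I, III, IV and the F$_1$F$_o$ ATP synthase) uses the
symmetric thermokinetic form
$$ J = x\,c\,\bigl(S_f\,e^{\Delta/2} - S_r\,e^{-\Delta/2}\bigr),\qquad
   \Delta = \kappa - n\,\Delta G_H/RT, $$
where $S_f, S_r$ are the mass-action substrate/product terms, $\kappa$ the
standard redox span in units of RT, $n$ the translocated charge per reaction
turnover (4, 2, 4 and $-3$ for CI, CIII, CIV, F1), and
$\Delta G_H = F\Delta\Psi_m + RT\ln([H^+]_i/[H^+]_m)$ the proton-motive
energy.  The symmetric form shares the voltage sensitivity between forward
and reverse directions; with a one-sided form, depolarization releases so
much thermodynamic back-pressure that even a 200-fold inhibited complex
regains near-normal flux, which contradicts the near-complete loss of
respiration seen experimentally after rotenone or antimycin A.  The
remaining transporters are electrogenic or electroneutral mass action: the
adenine nucleotide transporter (one charge), the phosphate carrier
(H$^+$-cotransport, electroneutral), a Goldman-type proton leak and K$^+$
uniporter, and a K$^+$/H$^+$ exchanger.  The model input is a lumped
dehydrogenase flux $J_{DH} = x_{DH}\,c_{DH}\,(r\,[\mathrm{NAD}] -
[\mathrm{NADH}])$ representing all NADH-regenerating supply upstream of the
chain (complex-II substrates included); cytosolic ATP turnover is
coarse-grained as production $\propto$ ADP$_c$ (`K_ADTP_dyn`) and
consumption $\propto$ ATP$_c$ (`K_ADTP_cons`).  H$_2$O$_2$ metabolism is
phenomenological: production from an NADH-proportional site (80% of the
physiological share) and a ubiquinol-proportional site (20%), first-order
matrix clearance, diffusion to the cytosol, and cytosolic clearance.  The
site split makes complex-I inhibition raise H$_2$O$_2$ moderately (NADH
accumulates while the Q pool oxidizes) and complex-III/IV inhibition raise
it strongly (NADH and QH$_2$ both accumulate), reproducing the much larger
oxidative response to downstream blockade.

### Calibration

The physiological condition (PC) is *constructed*, not fitted: we specify a
physiologically motivated PC state (150 mV; matrix pH 7.7 / cytosolic 7.2;
NADH/NAD poise 0.5; Q pool 20% reduced; matrix ATP/ADP 3/7 mM; cytosolic
ATP 2.5 mM vs free ADP 50 µM) and PC flux targets that balance charge,
protons, phosphate and adenine exactly (electron-pair flux
$2.5\times10^{-4}$ mol/s/l mito; proton leak carrying 30% of the basal
proton current; glycolysis supplying 20% of cytosolic ATP; H$_2$O$_2$
production 0.5% of electron flux).  Every kinetic scale constant $c_i$ is
then derived analytically so the PC state is an exact fixed point given the
eight user-facing activity multipliers at their default (100%-activity)
values.  The resulting PC
behaviour gives basal OCR 2 pmol O$_2$/min/µg protein, leak/basal $\approx$
0.39 and maximal/basal $\approx$ 1.9–2.0, in the range of primary-neuron
respirometry.  The DH poise constant $r=20$ sets the uncoupled supply
ceiling about twice basal flux, which makes maximal OCR substrate-limited:
this is what leaves maximal OCR nearly unchanged by F1 impairment or raised
proton leak, while mild DH defects cut it steeply.

## Numerics

Integration uses the stiff BDF solver (`deSolve::vode`, compiled C
right-hand side, `rtol` $10^{-8}$, `atol` $10^{-12}$) with an `lsoda`
fallback.  Steady states are found by relaxation integration followed by a
damped Newton polish on states scaled by their PC magnitudes; one member of
each conserved pool (NADH+NAD, Q+QH$_2$, cytochrome c, matrix and cytosolic
adenine, total exchangeable phosphate) is eliminated through its
conservation total, without which the Jacobian is exactly singular.  A state
is accepted when the maximum normalized derivative falls below $10^{-8}$
s$^{-1}$ within $10^4$ model-seconds.  This tolerance admits tiny offsets
along the slowest (potassium-cycle) mode, so "the" steady state is defined
to about 1%.  Conserved pools drift by less than $10^{-6}$ relative along
accepted trajectories.  Numerical instability (solver failure, non-finite or
negative concentrations) is flagged per population member; if at least three
members of a population are unstable, the impairment-adjusted parameter is
varied in its fourth significant decimal (0.009 becomes 0.009001) and the
population rerun.

## Virtual experiments

Drugs are parameter events: oligomycin, rotenone and antimycin A multiply
`x_F1`, `x_CI`, `x_CIII` by $5\times10^{-4}$ (a depth chosen to reproduce
near-complete inhibition in the thermokinetic setting, where depolarization
partially re-opens an inhibited pump); FCCP multiplies the *current* proton
leak by 10, so an Hle-impaired condition uncouples from its impaired level —
this is what suppresses maximal OCR under reduced leak.  The simulated
stress test injects oligomycin/FCCP/antimycin A at 20/40/60 min and takes
each phase's OCR as the median over its final 5 min; OCR is the complex-IV
oxygen flux converted to experimental units via mitochondrial volume
$4\times10^{-14}$ l, 300,000 neurons and 45 µg protein per well.
Fold-change experiments use a 20-min baseline (mean over the final 8 min)
and the value 20 min after the event, mirroring fluorescence protocols.

## Population variability

Cell-to-cell variability multiplies every rate parameter and every initial
concentration by an independent truncated-normal factor, mean 1, sd 0.2,
truncated at 2 sd — i.e. the nominal "±20%" biological variability is read
as the dispersion scale, not a hard envelope.  Under this generator the
basal-OCR population has a coefficient of variation of ~0.17, so the value
25% below the median sits near the lower few percentiles of the PC
distribution rather than at the first quartile; analyses that assume the
±25% categorization thresholds coincide with the PC quartiles would need
roughly twice this output dispersion.  We report the honestly measured
percentile rather than inflating the input variability beyond a defensible
reading of ±20%.  Because variability factors are drawn from
the seed alone, two conditions run with the same seed have *paired* members;
the test suite exploits this for direction checks on high-dispersion
readouts (matrix ATP has CV ≈ 0.6).

## Activity and calibration of impairments

A component's *activity* is its steady-state baseline flux as a percentage
of the PC flux — not its parameter value; flux control is distributed, so
activity is strongly non-linear in the parameter (complex I must fall to
~0.5% of its PC parameter to reach 2% flux).  `calibrate_activity()`
resolves a target activity by exponential bracketing plus bisection in
log-parameter space to within 0.5 percentage points.  Activities span 2–100%
for all components and up to 1000% for the proton leak.  Below ~2% the model
(like any mass-action description) cannot represent realistic biological
variability, so sweeps stop there.

## Categorization and matching

Outputs are categorized against a PC reference population (default
$n=1000$): thresholds at ±10/25/40% of the PC median define seven categories
coded $-3\ldots+3$, with boundaries assigned to the more extreme bin;
deviations of at least 25% (|code| ≥ 2) are considered experimentally
detectable.  Fold-change readouts are categorized against the PC
fold-change distribution of the same drug and readout.  Phenotype matching
clusters integer-coded rows (Euclidean distance, average linkage by
default — complete and single linkage give the same separation scores within
tolerance) with silhouette and, where component labels are known, V-measure;
an experimental phenotype "clusters with" a defect when it shares the flat
cluster *and* ranks in the top-5 distances.  Experimental fixtures are coded
±2 for significant, visually large changes and 0 otherwise; inhibitor
"sensitivity" features are coded on the membrane-potential response
magnitude $|1-\mathrm{FC}|$ so that a blunted depolarization codes as a
decrease.  Whole-cell ATP measurements are mapped to matrix ATP in the
feature schema.

## What the synthetic generator does and does not emulate

`make_synthetic_phenotype()` generates coded phenotypes from known defects
through exactly the simulation–categorization pipeline, optionally flipping
codes by ±1 with a set probability.  It emulates population medians of a
defined molecular lesion under multiplicative parameter variability; it does
not emulate measurement noise models, batch effects, fluorophore
calibration, or biological processes outside the modelled components
(beta-oxidation, explicit TCA reactions, NAD(P)H-dependent scavenging,
saturation kinetics).  Recovery tests passing therefore show the pipeline is
self-consistent, not that real experiments will always be as clean.

## Known limitations

* Mass action cannot represent complete blockade: an inhibited pump retains
  a small depolarization-dependent flux, which is why inhibitor presets use
  a very deep multiplier.
* The maximal-OCR ceiling is nearly, but not exactly, independent of leak
  activity (about +10% at Hle 350%); "unchanged" claims are read at the
  detectability threshold.
* The membrane-potential response magnitude to inhibitors is only weakly
  sensitive to mild DH impairment in this parameterization, so the
  five-feature Pink1 combination (DH 84% + KCons 40%) reproduces three of
  five coded features exactly (basal OCR, leak OCR, rotenone response), with
  maximal OCR one grade stronger and the antimycin-A response one to two
  grades weaker than the experimental coding.
* Problem sizes in the tests (populations of 10–30, reference populations of
  150–200) are the package's chosen defaults for routine verification; the
  headline analyses use populations of 50 and references of 200–1000.
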