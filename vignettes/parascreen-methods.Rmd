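---
title: "Diagnostic fragment-ion screening: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Diagnostic fragment-ion screening: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(parascreen)
```

This vignette is the package's own account of the science it implements:
the fragmentation model behind the diagnostic-ion registry, the screening
rules and their parameters, the synthetic-data model used to validate
them, and the choices made where the design was genuinely open.

## 1. The fragmentation model

Parabens are esters of 4-hydroxybenzoic acid. In negative electrospray,
the deprotonated molecule fragments in an HCD cell along two competing
channels: heterolytic elimination of the alkyl/benzyl group as an olefin
(R−H loss), giving the 4-hydroxybenzoate anion **A1** (C₇H₅O₃⁻, *m/z*
137.0239), and homolytic loss of R• giving the distonic radical anion
**A2** (C₇H₄O₃⁻•, 136.0160). Both decarboxylate; the resulting phenolate
ions lose H• and CO stepwise down to the didehydrophenoxide biradical
anion **B3** (91.0184) and the small oxo-ions **C** (108.0211), **D2**
(123.0082) and **E** (95.0133). Ring-hydroxylated metabolites (alkyl
protocatechuates) repeat the same graph shifted by one oxygen: **F1/F2**
(153.0188/152.0110), **G1–G3**, **H**, **J**, **K**. Four ions (**B3**,
**C**, **D2**, **E**) are shared between the two series; three of them
plus the class extras form the published screening sets (3 common + 4
paraben + 5 protocatechuate ions).

Two structural facts matter for screening:

* **Methyl and benzyl paraben cannot perform the olefin loss** (methyl
  has no β-hydrogen; benzyl would need a benzyne-like product), so
  **A1** — and therefore its decarboxylation product **B1** — never
  forms for MeP and BzP. Their applicable screening set has 5 ions, not
  7: the pathway graph admits no route to B1 that does not pass through
  A1, so both are excluded together.
* **A3 and F3** are resonance-rearranged intermediates at the same
  composition as A2/F2. They are nodes of the pathway graph (the CO-loss
  channel runs through them) but not observable distinct m/z values, so
  they are flagged non-screening.

The registry stores *formulas*, not masses: `deuterated_analog()` and
`conjugate_mass()` derive labeled-standard and phase II masses by
formula arithmetic, and construction aborts unless every edge is mass
balanced to 1 mTh.

### Mass conventions

Ion m/z values subtract one hydrogen-atom mass (1.007825 u) and neglect
the electron (−0.000549 u). This convention reproduces the registry's
reference values exactly (137.0239, not the 137.0244 that
proton-subtraction-plus-electron would give); the systematic offset of
~0.00055 Th is far below the 5–10 ppm tolerances at these masses, but
users comparing against electron-mass-aware tools should be aware of it.
RDBE is computed on the neutral-formula basis, C − (H+D)/2 + N/2 + 1, and
applied only to precursor composition: fragment radical ions routinely
violate even-electron parity and are not RDBE-screened.

### Formula decomposition

`decompose_mass()` enumerates neutral CHOS formulas with bounds C 7–30,
H 6–60, O 3–10, S 0–1, RDBE 5–10 and 5 ppm tolerance. The tolerance is
applied on the *ion* mass axis (the deprotonated species is what the
instrument measured); whether the original protocol applied it to neutral
or ionic mass is not documented, and at 5 ppm the difference is
negligible (< 0.1 ppm equivalent). Hydrogen counts are solved from the
mass residual rather than looped over, which is why the suite can verify
the output against a literal quadruple-loop oracle. Ties are ordered by
|ppm|, then even-electron sanity (integral non-negative RDBE), then
formula string.

## 2. Screening rules and parameters

| Parameter | Default | Unit | Meaning |
|---|---|---|---|
| `min_diagnostic_ions` | 4 | count | distinct labels required |
| `fragment_tol` | 10 | ppm | MS2 match window |
| `precursor_tol` | 5 | ppm | MS1/EIC window |
| `blank_ratio` | 3 | fold | sample/blank peak height |
| `coelution_window` | 0.1 | min | apex coherence |
| `dia_min_intensity` | 1e5 | a.u. | DIA full-scan floor |
| `dia_decrease_slack` | 0 | fraction | CE-decrease tolerance |
| `ce_scheme` | 10/20/40 | eV | collision energies |

Decisions taken where the rules were underspecified:

* **Counting across CEs.** The ≥ 4-ion rule counts distinct labels in
  MS2 spectra *merged across the three collision energies* of one
  precursor peak — low-CE spectra contribute A/F ions, high-CE spectra
  the ring fragments. Counting within single scans would double the
  effective threshold.
* **Coelution.** MS2 scans are attributed to an MS1 peak when their RT
  falls inside the peak bounds widened by `coelution_window` (0.1 min,
  matching the instrument-stability RT-shift bound used in QC).
* **Blank comparison** uses EIC peak *height*, not area; a silent blank
  channel yields an infinite, passing ratio.
* **"Consistently decreased"** in the DIA rule is implemented as
  strictly decreasing at every step of the sequence (CE 0, 10, 20, 40);
  `dia_decrease_slack` can relax this, but the default is strict because
  the simulated survival fractions (0.55/0.30/0.08) and counting noise
  never produce inversions at the intensities the floor admits.
* **Interferences** are handled by the rules themselves, not by
  exclusion lists: the benzophenone-like channel that floods *m/z*
  91.0184 matches one label and is rejected by the 4-ion rule in DDA. In
  DIA it legitimately passes preselection (it is a real, decreasing
  precursor at a diagnostic-ion RT) and is left to the reacquisition
  step — the behavior that motivates the DDA-first design.

## 3. The retention-time model

`fit_qsrr()` is a deliberately transparent linear model. The descriptor
pool is a fixed set of ten standard 2D descriptors computed with Open
Babel (MW, logP, TPSA, HBD, HBA, molar refractivity, heavy atoms, ring
and aromatic-ring counts, fluorine count). The original descriptor list
used for the in-house model is not public; we rely on forward stepwise
selection minimizing leave-one-out RMSE (computed exactly via PRESS
residuals) to make the model robust to the exact pool. Ties break
lexicographically so the fit is independent of row and column order.
With the bundled eleven reference standards the selected model
(logP + HBD + TPSA) explains R² ≈ 0.99 with RMSE ≈ 0.16 min on a
reversed-phase-style gradient; ΔRT then feeds `assign_confidence()`.
The level-2 threshold defaults to ΔRT ≤ 1.0 min; a stricter 0.5 min is
exposed because conjugate proposals benefit from it.

## 4. The synthetic-data model

`generate_run()` emulates the acquisition design of a spiked-biofluid
study: 80–1000 m/z full scans, either TopN-5 ddMS2 (1.5 Th isolation,
7 s dynamic exclusion, 1e5 trigger threshold) or AIF scans, at
10/20/40 eV. The defaults *are* the study conditions: spike levels
1/5/25 ng/mL with three replicates and three process blanks
(`generate_spike_series()`), a response factor of 4e4 counts per ng/mL
(so 25 ng/mL sits at 1e6, an order of magnitude above the trigger, and
1 ng/mL at 3.4e4 reproduces the missed-trigger failure mode), 15%
multiplicative matrix suppression (middle of the 10–30% band typical of
these extracts), 0.15 min FWHM Gaussian peaks, 2 ppm m/z jitter clamped
at 6 ppm, and Poisson-like intensity noise. CE-dependent fragment
profiles follow the qualitative pattern of the measured spectra — A/F
ions dominate at 10–20 eV, ring fragments grow at 40 eV — and are
config-driven because the quantitative CE tables are not public.

What the simulator does *not* model: profile peak shapes, isotope
patterns beyond explicit deuterated species, C-trap competition and AGC
dynamics, retention drift between runs, and the dense chemical background
of real biofluid (its background is sparse exponential-tailed noise).
Passing tests therefore demonstrate the *logic* of the rules — recovery,
false-positive control, monotonicity, speciation calls — under ideal
chromatography, not detection limits or identification rates in real
matrices, which depend on the instrument and sample.

Problem sizes were chosen for fast, deterministic validation: screening
tests use 6-minute windows at 0.02 min cycle time (~300 full scans per
run), 20-run batches for recovery/false-positive rates, 50 random masses
for the decomposition oracle, and n = 30 for QSRR noise recovery.

## 5. Numerical choices and degenerate inputs

* **Peak detection** smooths with a 3-point moving average for apex
  finding only (heights stay raw), estimates baseline and noise as
  median and MAD of the peak-masked trace, and requires ≥ 3 scans above
  half height — single-scan spikes are not chromatographic peaks. S/N is
  (smoothed apex − baseline)/noise; an all-zero or too-short trace
  returns an empty table rather than an error.
* **mzML round trips** go through Bioconductor `mzR`; AIF scans are
  encoded with a full-range isolation window and recognized by width
  (> 10 Th) on reading. Profile-mode files are rejected loudly. A run
  with zero spectra writes a minimal hand-built mzML because the
  serializer cannot emit an empty spectrum list.
* **Spectral matching** is a square-root-intensity-weighted cosine on
  ppm-matched peaks scaled to 0–100 — a transparent stand-in for
  commercial library scores with the conventional threshold of 70.
  Self-matches score exactly 100; unmatched peaks on either side dilute
  the score.
* **Degenerate QA/QC inputs** (zero denominators, single values,
  all-failing levels) return `NA` with flags or precondition errors, as
  noted in each function's documentation.
* **Glycine conjugation** is encoded as +C₂H₃NO on the free acid (the
  hippurate relationship), computed by formula arithmetic like the other
  moieties.

## 6. Known limitations

The registry covers the paraben/protocatechuate/phenolic-acid chemical
space in negative mode only; other EDC families pass through untouched.
The 17th family fragment reported in supplementary CE tables we could
not obtain is absent — the CSV export/import hooks exist so users can
extend the registry. DIA candidates are preselected, not deconvoluted;
quantitation (beyond QA/QC estimators) and positive-mode adducts are out
of scope.

```{r example}
reg <- build_registry()
diagnostic_set(reg, "paraben", "MeP")$label
decompose_mass(137.0239)
```
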