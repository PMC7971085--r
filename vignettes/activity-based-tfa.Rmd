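---
title: "Activity-based thermodynamic feasibility analysis with ePC-SAFT"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Activity-based thermodynamic feasibility analysis with ePC-SAFT}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

A reaction proceeds spontaneously in its stated direction when its Gibbs
energy of reaction is negative,

$$\Delta^R g = \Delta^R g^0 + RT \ln Q_a, \qquad
  Q_a = \prod_i a_i^{\nu_i}, \qquad
  \Delta^R g^0 = -RT \ln K_a .$$

Activities are built on the molality scale, $a_i = (m_i/m^0)\,\gamma^*_{m,i}$
with $m^0 = 1\ \mathrm{mol/kg}$, so a measured molality ratio $K_m$ and the
predicted activity-coefficient ratio multiply directly:
$K_a = K_m K_\gamma$ with $K_\gamma = \prod_i (\gamma^*_{m,i})^{\nu_i}$.
The asymmetric activity coefficient is defined through fugacity
coefficients of the electrolyte PC-SAFT equation of state,

$$\gamma^*_i = \frac{\varphi_i(T, P, \mathbf{x})}{\varphi_i^{\infty}(T, P)},$$

where $\varphi_i^{\infty}$ refers to species $i$ infinitely diluted in pure
water: $\gamma^*_i \to 1$ in the ideally diluted aqueous reference state.
The molality-scale coefficient is $\gamma^*_{m,i} = \gamma^*_i\, x_w$; a
mole-fraction-scale evaluation is available behind
`k_gamma(..., mole_fraction_scale = TRUE)` for sensitivity analysis, since
the two conventions differ by $x_w^{\sum\nu_i}$ (about 1% per unit of
$\sum \nu_i$ in the media used here).

The residual Helmholtz energy sums four contributions,
$a^{res} = a^{hc} + a^{disp} + a^{assoc} + a^{ion}$:

* **hard chain** — Boublík–Mansoori hard-sphere mixture plus chain
  connectivity, with temperature-dependent segment diameters
  $d_i = \sigma_i\,[1 - 0.12\exp(-3u_i/k_BT)]$ applied uniformly to all
  species (water's $\sigma$ follows its own temperature correlation);
* **dispersion** — second-order perturbation theory with the standard
  universal constant sets and Lorentz–Berthelot combining,
  $u_{ij} = \sqrt{u_i u_j}\,[1 - k_{ij}(T)]$, $k_{ij}(T)$ linear in $T$
  from the bundled binary table (absent pairs default to 0);
* **association** — Wertheim first-order theory on a donor/acceptor site
  scheme: a species with sites written "X + Y" in the parameter table
  carries X donor and Y acceptor sites; donors bond only acceptors.
  Cross-association uses the arithmetic mean of the association energies
  and the geometric mean of the association volumes with the
  $\bigl(\sqrt{\sigma_i\sigma_j}/\tfrac12(\sigma_i+\sigma_j)\bigr)^3$ size
  correction. This is the convention under which the bundled parameters
  were regressed in their sources, and it keeps "induced association"
  species ($\varepsilon^{AB}=0$, $\kappa^{AB}>0$, e.g. pyruvate)
  cross-bonding with water. Association between an associating and a
  non-associating species is zero.
* **ion** — a finite-ion-size Debye–Hückel term,
  $$a^{ion} = -\frac{\kappa}{12\pi\,\varepsilon_0\varepsilon_r k_B T}
    \sum_j x_j q_j^2\, \tau(\kappa\sigma_j), \qquad
    \tau(x) = \frac{3}{x^3}\Bigl[\ln(1+x) - x + \tfrac{x^2}{2}\Bigr],$$
  with the inverse Debye length $\kappa$ from the full ionic strength and
  the static permittivity of pure water from an empirical temperature
  correlation (78.4 at 298.15 K; not composition dependent — the parameter
  sets were regressed under a solvent-permittivity convention).

### The Debye–Hückel prefactor

The $1/(12\pi)$ prefactor above is the exact Debye charging result: it
recovers the limiting law $\ln\gamma_i \to -z_i^2 A\sqrt{I}$, which the
test suite verifies to within 3% at $I \le 10^{-4}$ mol/kg. Parts of the
equation-of-state literature print the same expression with $1/(24\pi)$,
i.e. half the limiting slope. The choice matters for multivalent
metabolite ions: with the exact term the package predicts
$K_\gamma(\mathrm{PFK}) = 0.067$ and $K_\gamma(\mathrm{aldolase}) = 4.42$
for the bundled reference media, while the halved variant
(`options(actipath.dh_scale = 0.5)`) moves them to 0.26 and 1.65. Neither
convention reproduces both of the values these media are known for (0.19
and 5.8) simultaneously; the package ships the thermodynamically exact
convention as default and exposes the other as a sensitivity switch. The
discrepancy is concentrated in the activity coefficient of the triply
charged fructose-1,6-bisphosphate ion; every surrounding step of the
standard-data chain is convention-independent.

## Parameters

`epcsaft_registry()` loads four plain-text tables
(`inst/extdata/parameters/`, schema in `schema.yaml`):

* `pure.csv` — per species: segment number, segment diameter (Å),
  dispersion energy (K), donor/acceptor site counts, association energy
  (K) and volume, and valence. Ions carry no association sites and no
  temperature-dependent diameter correlation; metabolite valences are the
  effective charges their sources fitted (e.g. FBP $-3$, ATP neutral).
* `binary.csv` — $k_{ij}$ slope and intercept ($k_{ij}$ at $T = 0$ K).
* `standard_data.csv` — standard Gibbs energies (298.15 K, pH 7) and
  reaction enthalpies of the ten glycolytic reactions; enthalpies are
  treated as temperature independent over 298.15–311.15 K, so standard
  energies move between temperatures only through
  $K_a \to$ van 't Hoff $\to K_a$, never by interpolating
  $\Delta^R g^0$ directly.
* `pka.csv` — acid–base ladders used by the speciation layer. These are
  literature apparent constants chosen near the ionic strengths of the
  underlying measurements (ATP 6.95, ADP 6.68, F6P 6.11, FBP 6.40,
  phosphate 6.75, Tris 8.07, ...); their temperature dependence is
  neglected over the 13 K span used here. The file is a declared
  replacement point: editing it changes every pH transform with no code
  change, and the test suite reports the sensitivity of the PFK
  standard-energy chain to ±0.3 pKa units (about ±1 kJ/mol).

## Proton bookkeeping

Standard Gibbs energies of the bundled table are pH-7 apparent values with
the proton absorbed — except GAPDH, whose value is on the chemical scale
with H$^+$ an explicit participant, so $a_{H^+} = 10^{-\mathrm{pH}}$ enters
its reaction quotient. This split is forced by internal consistency: the
GAPDH equilibrium position at pH 7 and the conditions-B feasibility are
only reproduced with the explicit proton, while the PFK chain
($K_m = 2290$ at pH 8 $\to$ pH 7 $\to$ 298.15 K $\to$ $-9.3$ kJ/mol) is
only reproduced when the transform carries the chemical proton
($\nu_H = +1$) while the apparent quotient does not. The pH transform is

$$K(\mathrm{pH}_2) = K(\mathrm{pH}_1)\,
  \prod_i \Bigl[\frac{P_i(\mathrm{pH}_2)}{P_i(\mathrm{pH}_1)}\Bigr]^{\nu_i}
  \; 10^{\,\nu_H (\mathrm{pH}_2 - \mathrm{pH}_1)},$$

with binding polynomials $P_i$ referenced to the fully deprotonated state;
it is a pure function, exactly invertible and composable (tested to
1e-12). Water is excluded from reaction quotients (enolase), and the
phosphate pool enters as one participant whose effective activity
coefficient is the speciation-weighted mean of H$_2$PO$_4^-$ and
HPO$_4^{2-}$ — the isofractionation assumption that the speciation is the
same in the actual medium as in the reference state.

## Numerical choices

* Pressure is fixed at 101325 Pa (the sources do not state it);
  configurable per medium.
* Liquid density roots start at packing fraction 0.45 (vapor at 1e-10),
  Newton with a bracketing fallback, converged to $|\Delta P|/P <$ 1e-9;
  the stable branch is verified by a positive-compressibility test.
* Association site fractions: damped successive substitution (damping 0.5)
  to 1e-12 with an iteration cap of 500, then an undamped polish towards
  machine precision so that finite-difference cross-checks of the analytic
  derivatives are noise-free. Mass-action residuals at convergence are
  below 1e-10 (tested).
* Pressure and chemical potentials use fully analytic derivatives of
  $a^{res}$; the association part uses the stationarity of the Wertheim
  free-energy functional at the converged site fractions, so no implicit
  derivative solve is needed. Analytic and central-difference derivatives
  agree to 1e-6 relative at 50 randomized mixtures (tested).
* The infinite-dilution reference uses a trace mole fraction of 1e-10 and
  takes the exact $\kappa \to 0$ limit for the ion term, so the reference
  of a charged species carries no spurious self-screening; for neutral
  species the reference is insensitive to the trace level to 1e-6, for
  ions the mixture-side Debye term vanishes only as $\sqrt{x}$ (tested as
  a convergence trend).
* Media are electroneutral by construction: salts split into tabulated
  ions, Tris/HCl and phosphate buffers speciate at the stated pH, and any
  residual metabolite charge is closed by the declared counter-ion (K$^+$
  by default) — never by an invented species. Trace-level imbalance from
  1e-10 metabolites is tolerated (1e-8 on the mole-fraction-weighted
  charge).

## The feasibility scenarios

`load_conditions("A")` and `"B"` implement the two-step analysis.
Scenario A evaluates each reaction at its best case — substrates at their
maximum, products at their minimum declared molality, with only the
participants present in water for the $Q_\gamma$ prediction. A positive
$\Delta^R g$ under A means the reaction is infeasible at *any*
concentration ratio inside the declared ranges (verified against 200
random range samples per reaction in concentration mode, where the bound
is exact). Scenario B keeps the same quotient molalities but predicts
$Q_\gamma$ with all other glycolytic metabolites at their maxima plus
1 mmol/kg MgCl$_2$ and 100 mmol/kg KCl.

The per-metabolite ranges shipped in the condition files are editable
placeholders: printed values are used where the sources state them
(salts, temperatures, pH), and the remaining minima/maxima are
literature-informed cytosolic concentration windows (e.g. ATP 1–10,
GAP 0.002–0.1, 1,3-BPG 0.05–0.5 mmol/kg) selected once, consistent with
the known qualitative outcome of the analysis: GAPDH infeasible under A
(+5.8 kJ/mol here), all ten reactions feasible under B, and
concentration-based evaluation disagreeing in sign. Exact
condition-B energies (e.g. GAPDH $-2.4$ kJ/mol here) depend on those
windows; with the original per-study concentration tables they would
shift by several kJ/mol, which is why the test suite asserts the pattern
strictly but treats the exact values as conditional.

## The synthetic-condition generator

`synthesize_conditions()` draws reproducible random scenarios (metabolite
ranges 0.01–20 mmol/kg, KCl 0–300 mmol/kg, MgCl$_2$ 0–10 mmol/kg, T in
{298.15, 310.15} K, pH 7) for property testing. It emulates the
*composition* variability of cytosol-like media — ionic strength, salt
identity, metabolite windows — but not macromolecular crowding, explicit
Mg$^{2+}$–nucleotide complexation, compartmentation, or enzyme effects;
passing tests therefore demonstrate the thermodynamic machinery, not
biological completeness.

## Known limitations

* Single-ion activity coefficients are model quantities, not observables;
  only the stoichiometric combinations ($K_\gamma$, $Q_\gamma$) are
  physically meaningful.
* No Born/solvation term and no composition-dependent permittivity; at
  ionic strengths well above ~0.3 mol/kg the electrolyte description
  degrades (the bundled media stay at or below 0.25 mol/kg).
* Mg$^{2+}$ acts only through its activity-coefficient contributions;
  explicit complexation equilibria with nucleotides are not modelled.
* pKa values are fixed apparent constants; no ionic-strength-dependent
  (extended Alberty) transformation beyond the pH transform.
* Stoichiometric coefficients are integers (sufficient for glycolysis).

## Problem sizes

The shipped test suite exercises: 50 randomized mixtures for the
derivative cross-checks, 25 randomized acid–base ladders, 20 synthetic
condition sets, 200 range samples per reaction for the best-case bound,
and the full ten-reaction pathway under four scenario/mode combinations —
about half a minute end to end on one core.
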