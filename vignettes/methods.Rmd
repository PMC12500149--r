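---
title: "Timescale decomposition of brain energy metabolism: model, criterion and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Timescale decomposition of brain energy metabolism}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

`neurocsp` implements a kinetic model of cortical energy metabolism with
four compartments — neurons (`_n`), astrocytes (`_g`), extracellular space
(`_e`) and capillaries (`_c`) — plus a venous balloon. The 29 state
variables (`state_names()`) are intracellular sodium, glucose,
glyceraldehyde-3-phosphate, phosphoenolpyruvate, pyruvate, lactate,
cytosolic and mitochondrial NADH, ATP, phosphocreatine and oxygen in the
two cell types, the capillary and extracellular metabolite pools, the
venous volume fraction `Vv` and deoxyhemoglobin `dHb`. All concentrations
are mM, time is in seconds, and every rate is expressed per unit volume of
the compartment in which it is defined; exchange fluxes between
compartments of different size are rescaled by the volume ratios
`r1 = Vn/Vcap`, `r2 = Vg/Vcap`, `r3 = Ve/Vcap`, `r4 = Vn/Ve`,
`r5 = Vg/Ve`, and the cytosolic/mitochondrial sub-volumes by
`c1 = (1-ξ)^-1`, `c2 = ξ^-1` with mitochondrial fraction ξ = 0.07. These
ratios are the unique choice under which the resting state closes the
glucose, oxygen and lactate balances to a fraction of a percent, which the
tests verify.

The 67 unidirectional rates (`reaction_registry()`) comprise: sodium leak
and Na,K-ATPase pumps (1–4); carrier-mediated glucose (5–8) and lactate
(17–20) transport, each reversible pair split into non-negative
forward/backward parts; lumped hexokinase–phosphofructokinase (9–10),
phosphoglycerate kinase (11–12), pyruvate kinase (13–14) and lactate
dehydrogenase (15–16); TCA influx (21, 23), electron transport (22, 24)
and NADH shuttles (25–26); creatine kinase (27–28); capillary oxygen,
glucose and lactate exchange (29–33); constant ATPase loads (34–36); the
venous balloon and deoxyhemoglobin (37–39); the stimulation inputs
(40–41); and ATP-equation copies of the energy-coupled rates (54–65).

Two closures eliminate ADP and AMP: the adenylate kinase equilibrium
`ADP² = q_AK · ATP · AMP` with conserved pool `A = ATP + ADP + AMP`
(so `ADP = (ATP/2)(−q_AK + √(q_AK² + 4 q_AK (A/ATP − 1)))`), and the
derived factor `S = (1 − dAMP/dATP)^-1` that converts a nominal one-ATP
flux into its effect on free ATP. Multiplying the energy-coupled rates by
`S1(ATP_n)`/`S2(ATP_g)` — rather than putting state-dependent entries into
the stoichiometry — keeps the stoichiometric matrix constant, which the
per-reaction decomposition of the Jacobian requires. Note that `ADP(ATP)`
is only monotone decreasing on the physiological branch (ATP ≳ 1 mM); the
closed form rises like `√ATP` near zero.

Three modelling details deserve flagging because printed sources of such
models are often ambiguous about them, and the package settles each by a
conservation or self-consistency argument (all verified in tests):

* the total NAD pool is `N_tot = 0.212` mM (a mM-scale pool; a
  thousand-fold larger value is dimensionally inconsistent with the PGK and
  LDH rate constants and the resting NADH levels);
* capillary lactate *gains* the glia→capillary export,
  `+r2·(R19f − R19b)` — the opposite sign would violate mass balance
  between the glial and capillary pools;
* deoxyhemoglobin production uses the same Fick form as capillary oxygen,
  `R38 = 2 F(t) (O2_a − O2_c)`; the factor 2 (mean-capillary vs
  arterio-venous concentration) is required for the printed baseline
  `dHb0 ≈ 0.058` to be near-stationary. The capillary→extracellular glucose
  affinity, not separately tabulated, is taken as 8 mM like every other
  glucose carrier in the model.

## Baseline state

The tabulated resting values are given to 2–4 significant digits and are
not an exact fixed point of the equations. `resting_steady_state()`
refines them by a damped Newton iteration on the analytic Jacobian
(residual < 1e-12 mM/s). The refined fixed point agrees with the printed
values within their rounding for the slow pools (sodium, glucose, lactate,
ATP, phosphocreatine, oxygen all move < 6 %); the glial glycolytic
intermediates GAP and PEP, for which the table prints one shared value for
both cell types, settle a few-fold away — they are fast, low-concentration
species whose steady level is set by the strongly different glial kinase
constants. The scenario starts from the refined state, as an experiment
starts from a subject at rest; starting from the raw printed values
instead changes the diagnostics only through a brief induced transient.

## The activation scenario

`activation_protocol()` encodes: constant sodium-influx stimulation
`vstim_n = 0.15290`, `vstim_g = 0.059823` mM/s on `[0, 900)` s; a
trapezoidal cerebral blood flow `F(t)` from `F0 = 0.012 1/s` to
`1.4·F0`, rising linearly over 30 s after a 2 s onset lag; and, after a
10 s offset lag, a linear return. Only the rise duration is specified by
the protocol the model targets; the fall is taken symmetric (30 s) and is
configurable (`ramp_off`). Sensitivity runs with an instantaneous fall, a
fall starting at 900 s, and a 60 s fall leave the recovery-epoch
diagnostics essentially unchanged, so this ambiguity is immaterial here.
The venous balloon outflow is implicit in `dVv/dt`; substituting
`dVv/dt = F − Fout` yields a linear scalar equation solved in closed form
(`venous_outflow()`), and the BOLD signal is
`Vv0[(k1+k2)(1 − dHb/dHb0) − (k2+k3)(1 − Vv/Vv0)]` with
`k1 = 2.22, k2 = 0.46, k3 = 0.43`, baseline-normalized to the trajectory's
own initial state.

Integration uses `deSolve::lsoda` with the analytic Jacobian, in segments
split at the protocol breakpoints (2, 32, 900, 910, 940 s) so the adaptive
solver never steps across a kink. Default tolerances are `rtol = 1e-8`,
`atol = 1e-10`: tight, because the downstream eigenanalysis amplifies
trajectory error; halving them changes the trajectory by < 0.1 %
(tested). The default output grid is 1 s up to 1000 s and 10 s beyond, to
10 000 s — about 1900 points, each carrying a 29×29 eigendecomposition in
the scan; the full pipeline runs in ~15 s on one CPU.

## The decomposition and the exhausted-mode criterion

At each grid point the engine eigendecomposes the Jacobian
(`eigendecompose()`), sorts modes by decreasing `|λ|` (ties broken by real
part, then original index, for reproducible numbering), takes left vectors
as the matrix inverse of the right ones (bi-orthonormal to round-off), and
flips `(a_n, b^n)` jointly so all amplitudes `f^n = b^n·g` are
non-negative. A complex conjugate pair is represented by its real
invariant-subspace basis (real and imaginary parts of one member); the
pair shares `τ = |λ|^-1`, every diagnostic stays real, and the identity
"TPI contributions sum to the eigenvalue" holds with the real part. A
near-defective basis triggers a warning with a condition estimate; in this
model the spectrum is well separated almost everywhere (one transient
conjugate pair appears during activation).

`count_exhausted_modes()` implements the accuracy criterion
`|τ_{m+1} Σ_{i≤m} a_i f^i| < e_rel|y| + e_abs` and returns the longest
prefix of the fastest-first ordering over which it holds at *every* level
`m ≤ M`. The prefix (rather than "largest passing `m`") reading is
deliberate: each nesting level must itself be a valid fast/slow split,
otherwise a still-active intermediate mode could be silently absorbed when
the inequality happens to hold again at larger `m`. A prefix is never cut
between the two members of a conjugate pair.

### Tolerance calibration

`e_rel` and `e_abs` are accuracy targets, not physical constants, and the
resulting count depends on them logarithmically through the decaying mode
amplitudes. `calibrate_tolerances()` makes the choice transparent: it
tabulates `M` at probe times across a tolerance grid. For this scenario
the count structure at the representative times (17 at 25 s; 26 at 500 s;
27 at 850 s; 22 at 1000 s; 26 at 1300 s; 27 at 2000 s; 28 at 6500 s) is
reproduced on a plateau `e_rel ∈ [0.55, 0.675]` with `e_abs ≤ 1e-5` mM,
and within that plateau the mid-activation boundary (the step from 26 to
27 exhausted modes, at 627 s with the defaults) moves by ~±25 s. The
shipped defaults are `e_rel = 0.65`, `e_abs = 1e-6` mM. The large relative
tolerance reflects that the leading-order (eigenvector) basis is being
asked a qualitative question — is this mode's residual displacement small
compared with the state — not a trajectory-accuracy question.

Two aspects of the period structure are intrinsically tolerance-sensitive
and should be read with care. First, the very first count plateau ends
when the sodium/vascular modes (τ ≈ 13–17 s) fall below the criterion,
roughly 20–30 s after onset at the default tolerances; tightening the
tolerances lengthens it. Second, the onset of the final recovery period
(the last equilibrium, the astrocytic creatine-kinase pair) shifts by
`Δt ≈ τ · Δln(1/e_rel)` with `τ ≈ 800` s, so order-unity tolerance changes
move it by thousands of seconds; the packaged defaults place it at
~3300 s. No single global tolerance can place this boundary much later
without simultaneously destroying the early-epoch counts — a genuine
limitation of a one-parameter accuracy criterion on a spectrum whose
amplitudes decay at such different rates.

### Periods, representative times and reports

`segment_periods()` run-length encodes `M(t)` per epoch (the epochs are
split at the stimulation offset, where the count necessarily drops) and
debounces runs shorter than `min_dwell = 5` s into the neighbour with the
closer count — enough to suppress single-point flickers near criterion
boundaries without hiding real structure. Short genuine reversals (the
count is not strictly monotone mid-transition, because modes reorder as
eigenvalues cross) are retained. Representative times default to the
canonical probe set (25, 500, 850, 950, 1000, 1300, 2000, 6500 s) when one
falls inside a period, else the midpoint; diagnostics for a period are
evaluated at its representative time with its dominant mode `M + 1`, even
if debouncing places that time marginally outside the period.

`dominant_mode_report()` filters the Pointer at 0.03 and the TPI at 3 %
(recorded in the output, with the pre-filter normalization sums);
`equilibria_graph()` aggregates the API over a period's exhausted modes
(strong > 9 %, weak 2–9 %) and lists species with any exhausted-mode
pointer above 45 %, retaining per-mode provenance. One caveat the package
reports honestly rather than smoothing over: near avoided crossings of
eigenvalues the dominant mode's species content mixes with its spectral
neighbours (early in the second recovery period the sodium mode, τ ≈ 61 s,
mixes with a glucose-transport mode, τ ≈ 86 s, so its sodium pointer reads
~0.65 rather than ~0.9, recovering later in the period). Pointer values
near such crossings are sensitive to per-mille trajectory differences;
TPI rows, which aggregate over reactions, are far more stable.

## Toy benchmarks: what they do and do not show

`linear_two_scale_system(eps, angle)` has eigenvalues `−1/eps` and `−1`
with configurable eigenvector angle and closed forms for every CSP
quantity; on it the leading-order basis is exact, so the engine's outputs
are checked against analytic values, not against another numerical method.
`enzyme_qssa_system()` (substrate + enzyme–substrate complex, reversible
binding, catalysis) supplies the canonical nonlinear benchmark: the
fast-mode API splits ±0.5 over the binding pair, the fast-mode pointer on
the complex approaches 1 as `E0 → 0`, and the trajectory tracks the
quasi-steady-state manifold `C = E0·S/(Km + S)` with error that shrinks
with the gap parameter. Passing these tests validates the *engine*
(bases, indices, criterion) — it does not validate the brain model's
kinetics, which rest on the resting-state closure and Jacobian tests, nor
does it say anything about biological variability: the model is a single
deterministic parameterization of an average human cortex.

## Known limitations

* The exhausted-mode count is a calibrated quantity; only its plateau
  structure, not every boundary, is robust (see above).
* Leading-order CSP only: the eigenvector basis is not refined, and the
  reduced slow model is diagnosed, not integrated.
* Pointer attributions lose sharpness near eigenvalue crossings.
* The electrophysiology that would drive the stimulation currents
  mechanistically (membrane voltage, gating, calcium) is outside scope;
  stimulation enters as prescribed sodium-influx constants.
* The printed resting values are treated as a near-fixed-point and refined;
  scenarios other than the single in-vivo activation protocol (different
  stimulation strengths, hypoxia, exercise) would need their own baseline
  and calibration.
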