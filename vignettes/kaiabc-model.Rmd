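---
title: "The multifold-feedback KaiABC oscillator model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The multifold-feedback KaiABC oscillator model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

The in vitro KaiABC system — KaiA, KaiB, and KaiC incubated with ATP —
produces a self-sustained, roughly 24-hour rhythm in the phosphorylation
level of KaiC. `kaiabc` simulates an ensemble of KaiC hexamers in which
three layers of dynamics feed back on one another through a single
structural variable per hexamer, and in which the only interaction
between hexamers is competition for a shared pool of free KaiA and KaiB.
This vignette describes the model, the numerical scheme, the choices we
made where the design was genuinely open, and what the synthetic test
conditions do and do not establish.

## State of one hexamer

Each of the `N` KaiC hexamers `k` carries:

* **A binding distribution** over 29 states: the `C6A2` complex (a KaiA
  dimer on the CII ring) and the complexes `C6BiA2j` with `i = 0..6`
  KaiB monomers on the CI ring, `j <= i` of them holding a KaiA dimer
  (`(0,0)` is free C6). Within a hexamer the distribution is a
  probability vector evolved by master-equation ODEs; the ensemble
  treatment is factorized (Hartree-like): hexamers are statistically
  independent given the shared free concentrations. The reactions and
  their mass-action rates are:
  * `C6 + 2A <-> C6A2` at `h_A A^2` / `f_A`,
  * KaiB binding/unbinding on the CI at `(6 - i) h_B B` and
    `(i - j) f_B` (KaiB carrying a KaiA dimer cannot leave),
  * KaiA binding on bound KaiB at `(i - j) h_BA A^2` and `j f_BA`.
* **A phosphorylation level** `D`, continuous, near 0 when the 12 CII
  sites are dephosphorylated and near 1 when fully phosphorylated:
  `dD/dt = k_p P(C6A2) - k_dp (1 - P(C6A2)) - g'(D)` with the soft-spin
  potential `g(D) = a D (D - 1/2)^2 (D - 1)` confining `D` near 0 and 1.
  At the reference rates `k_p = k_dp = a/4`, `D = 0` (no KaiA drive) and
  `D = 1` (full KaiA drive) are exact fixed points.
* **A structural order parameter** `X` in (0, 1): the gs state
  (`X` near 1, phosphorylation-competent) versus the cs state (`X` near
  0, dephosphorylation/KaiB-binding-competent). The six subunits flip
  cooperatively; in the strong-coupling limit of a 6-ring Ising model
  the hexamer behaves as one collective two-state unit, giving the
  mean-field form
  `X = tanh(beta (c0 - c1 D + c2 pA - c3 pB - q)) / 2 + 1/2`,
  where `pA = P(C6A2)`, `pB = sum_i tanh(i/n_B) P(i KaiB bound)`
  saturates in the number of bound KaiB, and `q` is the ATPase
  perturbation below. The exact ring enumeration is implemented as
  `ising_ring_mean()` and used in the tests to validate this limit.
  Structure is treated as infinitely fast (an algebraic relation
  re-evaluated after every step), never integrated.
* **Six ATPase subunits.** Each CI releases Pi at random with frequency
  `f0` when it is not already ADP-bound; after a release the subunit is
  ADP-bound, contributing `q0` to `q = q0 x (number of ADP-bound
  subunits)`, and is refractory. The ADP leaves when the age of the
  bound state exceeds the structure-dependent lifetime
  `delta = delta0 (gamma - X(t))` — shorter in the gs state, so ATP
  turnover is fastest during the phosphorylation phase.

The rate laws couple structure and binding in both directions:
`h_A = h_A0 X`, `f_A = f_A0 (1 - X)`, `h_B = h_B0 (1 - X)`,
`f_B = f_B0 X`, while `h_BA`, `f_BA` are structure independent (that
KaiA dimer touches KaiB, not KaiC). Free KaiA and KaiB follow from
exact conservation: every `C6A2` holds 2 KaiA monomers, every `C6BiA2j`
holds `2j` KaiA and `i` KaiB, summed over the ensemble and divided by
the volume. KaiA sequestration into the `C6BiA2j` complexes depletes
free KaiA and is the sole synchronizing interaction.

## The ADP lifetime: why it tracks the structure continuously

The lifetime expression `delta = delta0 (gamma - X)` admits two
readings: freeze `delta` for each ADP at the moment of its release, or
let the bound interval end when the age first exceeds the lifetime
evaluated with the *current* `X(t)`. We implement the second. The two
agree whenever the structure is steady (so every frozen-lifetime oracle
— the renewal rate `1/(1/f0 + delta)`, the saturation limit — holds
unchanged), but they differ crucially during the structural transition:
with continuous tracking, a fluctuation that lowers `X` lengthens the
residence of the ADP already on board, which raises `q`, which lowers
`X` further. This regenerative loop sharpens the gs-to-cs flip and, at
the reference parameter set, is what places the system robustly inside
the oscillatory regime. With frozen-at-release lifetimes the same
parameter set sits marginally outside the oscillatory domain (the mean
ADP load plateaus near `6 q0 delta/(1/f0 + delta) ~ 3.6 k_BT`, short of
the ~4 k_BT needed to destabilize the phosphorylated plateau), the
ensemble dephases, and neither the KaiA threshold nor the
activity-frequency correlation is reproduced. We therefore regard
continuous tracking as the mechanistically correct reading and use it
throughout; `step_subunits()` documents the exact per-step rule.

## Hybrid integration scheme

Binding and phosphorylation are advanced by explicit Euler; ATPase
events are per-subunit Bernoulli draws with probability
`1 - exp(-f0 dt)` per step; the structure is recomputed algebraically
after the other operators. The fixed operator order per step is:

1. free `A`, `B` from the conservation laws;
2. one Euler step of the 29-state master equation for every hexamer,
   with rates from its current `X`; negative entries (if any) are
   clipped and the vector renormalized, with the correction tracked and
   an error raised above `1e-3`;
3. one Euler step of `D`;
4. ADP releases (age vs. current lifetime), then Pi-release draws for
   unbound subunits;
5. `X` re-evaluated from the updated `D`, binding, and `q`; time
   advances by `dt`.

**Step size.** The default `dt = 0.002 h` keeps `dt` times the fastest
rate (KaiA binding, `h_A0 A_T^2 ~ 64 /h`) near 0.13. Accuracy is
certified empirically: with hydrolysis off the dynamics are
deterministic and step-halving changes the ensemble mean at `t = 100 h`
by less than `1e-3` (a tested invariant). With hydrolysis on,
step-halving changes the *number* of Bernoulli draws, so trajectories
differ by resampling noise rather than truncation error; convergence is
therefore assessed on the deterministic subsystem. The per-step
Bernoulli approximation biases the event rate by less than
`f0 dt / 2 < 0.4%` at the defaults. Qualitative sweep analyses in the
test suite use `dt = 0.004 h`, which reproduces the `dt = 0.002 h`
amplitudes, periods, and orderings within seed-to-seed noise; the
quantitative threshold and slope computations keep the default step.

**Random numbers.** One R random stream drives a whole run: the
desynchronized initial phosphorylation draw, then the event draws in a
fixed documented order (hexamer-major, subunit-minor, unbound subunits
only). The compiled engine and the pure-R reference stepper consume the
stream draw for draw, so the two produce identical event sequences and
near-identical trajectories (a tested invariant, `1e-10`); this is a
stronger reproducibility guarantee than per-hexamer substreams and is
why we use a single stream.

**Initial conditions.** All hexamers start free (no KaiA/KaiB bound, no
ADP), with `D` drawn uniformly on [0, 1]. Starting desynchronized makes
the coherent rhythm an emergent property of KaiA sequestration rather
than an artifact of identical initial states; the `transient` window
(default 500 h) is discarded before any analysis.

## Parameters

The reference set (the package defaults) uses units of hours, `V = 1`,
and `k_B T = 1`: `N = 1000` hexamers (`C6T = N/V = 1000`), totals
`A_T = 2 C6T`, `B_T = 20 C6T`; binding `h_A0 = 1.6e-5`,
`f_A0 = 0.8`, `h_B0 = 7.2e-6`, `f_B0 = 0.32`, `h_BA = 1.0e-6`,
`f_BA = 0.2`; phosphorylation `k_p = k_dp = 0.4`, `a = 1.6`; structure
couplings `c0 = 10`, `c1 = 6`, `c2 = 0`, `c3 = 3`, `beta = 1`,
`n_B = 1`; ATPase `f0 = 2.4 /h`, `q0 = 0.8`, `delta0 = 2.5 h`,
`gamma = 1.5`. KaiA binding is minutes-fast at full affinity while KaiB
binding is hours-slow; the ATPase timescales `1/f0` and `delta0` are
0.4-2.5 h. `c2 = 0` disables the direct KaiA-binding term in the
structural field at the defaults, but the term is implemented and
tested. `rescale_ensemble()` changes `N` with the volume, holding every
concentration fixed, so desk-scale runs (we use `N = 200` for sweeps
and `N = 50` in quick tests) differ from the full ensemble only by
ensemble-average noise.

## Observables

* `amplitude()`: difference of the 97.5th and 2.5th percentiles of the
  post-transient ensemble mean. Percentiles rather than extreme peaks
  make the measure robust to small-`N` jitter; for a pure sinusoid the
  measure recovers 99.7% of the peak-to-trough range.
* `period_fft()`: the peak of the Hann-windowed power spectrum of the
  mean-removed series, with quadratic interpolation around the maximum
  bin; `tau = 1/f_p`. A series whose maximum power does not exceed five
  times the median power is flagged as having no peak.
* A run is classified as oscillating when the amplitude exceeds 0.1,
  about a sixth of the full-scale rhythm.
* `atpase_activity()`: ADP released per CI subunit per 24 h with
  `A_T = B_T = 0` — the non-oscillatory condition used to characterize
  intrinsic hydrolysis. At (effectively) frozen structure the release
  process is a renewal process with rate `1/(1/f0 + delta)`, a tested
  2% oracle.
* `phase_diagram()`, `sweep_amplitude_period()`,
  `activity_frequency_slope()` drive the concentration, ATPase, and
  correlation sweeps; the KaiA onset threshold is defined as the
  smallest scanned ratio whose mean amplitude exceeds half the
  reference amplitude at `A_T/C6T = 2`, `B_T/C6T = 20`.

## What the model reproduces

At the reference point the ensemble settles into a coherent rhythm with
a period near 20 h and amplitude near 0.7 in `Dbar`; the `C6A2` and
KaiB-sequestered complexes oscillate in antiphase (correlation below
-0.9). Oscillation requires hydrolysis: `q0 = 0` or `f0 = 0`
extinguishes it, and it exists only within a window of `q0` (roughly
0.8-1.0 at desk scale) within which the period decreases as `q0` grows.
The KaiA onset sits near `A_T/C6T = 1.5` at desk scale. Synchronization
weakens at low hydrolysis frequency (`f0 = 1.2 /h` gives roughly a
sixth of the amplitude at `2.4 /h`). The period spread across
`f0 = 1.6-3.2 /h` shrinks by more than half when `f0 delta0` is held at
4 — increasing `f0` shortens the period while shortening `delta0`
lengthens it — the model's surrogate for temperature compensation.
Frequency of the ensemble rhythm correlates with single-molecule
ATPase activity with a slope near 0.04 cycles per day per
(ADP CI^-1 day^-1). Every number above is computed by the test suite or
the acceptance script, not asserted from memory.

## Limitations

The synthetic conditions probe the model's own behavior, not real
time-course data: passing tests show internal consistency and
reproduction of the model's published phenomenology at desk scale, not
agreement with any particular experimental trace. The model does not
distinguish the two phosphorylation sites (Ser431/Thr432) or the CI and
CII structural states separately, does not track nucleotide exchange
beyond the binary ADP-bound flag, ignores monomer shuffling, and treats
KaiA strictly as a dimer with mass-action `A^2`. The factorized
treatment makes each hexamer's binding state a probability vector, so
binding noise is averaged within a hexamer; the only stochasticity is
the ATPase event train. Ensemble sizes of 200 (sweeps) and 50 (quick
tests) inflate ensemble-average noise relative to the reference
`N = 1000`; thresholds quoted at desk scale carry a corresponding
uncertainty of roughly one scan step.
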