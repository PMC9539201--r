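---
title: "Fuzzy-logic network dynamics of CD4+ T-cell differentiation: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fuzzy-logic network dynamics of CD4+ T-cell differentiation: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

`fuzzynet` turns a set of Boolean interaction rules into a continuous
dynamical system. Each node $k$ of a regulatory network carries an
expression level $q_k \in [0,1]$ and one fuzzy proposition
$v_k(q_1,\dots,q_n)$ obtained from its Boolean update rule through the
multiplicative t-norm:

$$p \wedge q \to p\,q, \qquad p \vee q \to p + q - p\,q, \qquad
\neg q \to 1 - q .$$

Restricted to $\{0,1\}$ this is ordinary Boolean algebra; on the interior
of the unit interval it admits graded truth, with $\theta = 1/2$ the
boundary between falsity and truth (the fuzzy solution of $q = \neg q$).
The proposition is converted into a categorical drive by the sigmoid
characteristic function

$$\mu[v_k] = \frac{1}{1 + e^{-\beta (v_k - \theta)}},$$

and each node relaxes with first-order kinetics

$$\frac{dq_k}{dt} = \mu[v_k(q)] - \alpha_k q_k .$$

Defaults are $\beta = 10$, $\theta = 1/2$, $\alpha_k = 1$; the
characteristic expression time of a node is $\tau_k = 1/\alpha_k$.
Because $0 < \mu < 1$, the derivative points inward on the boundary of the
unit hypercube, so with unit decay rates all trajectories remain in
$[0,1]^n$. Steady states satisfy $q_k^{st} = \mu[v_k(q^{st})]/\alpha_k$;
the package calls this the steady-state residual condition and uses it
both as a classification invariant and as an independent check
(`fixed_point_oracle()`).

Inputs are not integrated: clamped inputs hold their microenvironment
level for all time, while the two stimulation inputs (antigen presentation
and co-stimulation) follow a step-like depletion schedule
$s(t) = A - D/(1 + e^{-\beta_s (t - T)})$ with defaults
$A = D = 1$, $T = 15$, $\beta_s = 1$: full engagement that wanes around
$t = 15$ time units. Time is dimensionless throughout.

## Tunable parameters

| parameter | meaning | default | why |
|---|---|---|---|
| `beta` | gate slope (dimensionless) | 10 | steep enough that propositions behave switch-like while staying smooth |
| `theta` | truth threshold | 0.5 | the fuzzy midpoint; also the phenotype call threshold |
| `alpha` | node decay rate (per time unit) | 1 | makes $\tau = 1$ the common expression timescale |
| `T` (stimulus) | onset of stimulus depletion | 15 | sustained priming long enough to close the IL-2 feedback loop |
| `t_ctla4` | CTLA-4 expression time, realized as $\alpha_{CTLA4} = 1/T$ | 1 | values $\le 1$ permit sustained activation; larger values let CTLA-4 accumulate and arrest the activation core |
| `t_end` | integration horizon | 30 | the activation transient completes well before 30; the scenario runner extends the horizon automatically (below) |

## The bundled CD4+ T-cell network

The package ships a 68-node model of early CD4+ T-cell activation in eight
modules: stimulation inputs, nine exogenous cytokines, nutrient/oxygen
inputs (glutamine, tryptophan, glucose, fatty acids, hypoxia), the
TCR/CD28 activation core with the IL-2/CD25 feedback loop, a metabolic
module (PI3K–AKT–mTOR, AMPK, mTORC1/2, glycolysis, oxidative
phosphorylation, α-ketoglutarate, HIF-1α), a regulatory module (CTLA-4,
its dimerized form, and the anergy factor NDRG1), the five
lineage-defining transcription factors (T-bet, GATA3, RORγt, Foxp3,
Bcl-6) with their STAT inputs, and the output cytokines.

**The rule set is a synthetic reconstruction.** It was curated from the
published description of the network's topology and reported behaviour,
not transcribed from a machine-readable rule list; the file
(`inst/extdata/cd4_tcell_synthetic.net`) is labelled accordingly. The
engine is rule-set-agnostic — any model file in the same line-oriented
format can be loaded with `read_network()` — and all scenario logic reads
node names from a role manifest (`cd4_manifest()`), so replacing the
bundled file with a different transcription requires no code changes.

Numeric literals inside rules (e.g. `CTLA4 & 0.4`, `!(TBET & 0.8)`)
encode graded regulatory strength under the product norm: a weighted
inhibition `!(X & w)` contributes the factor $1 - wX$, a partial route
`Y & w` saturates at $w$. The grammar admits constants in $[0,1]$
precisely for this purpose.

Behaviour the reconstruction reproduces, all of it exercised by the test
suite:

* stimulation without exogenous cytokines yields a sustained activation
  core maintained by the IL-2/CD25 loop after stimulus withdrawal, a
  transient proximal band (LCK through SOS), an initial oxidative burst
  that decays, and middle-level steady glycolysis;
* the five polarizing cytokine presets produce their expected
  transcription-factor and cytokine signatures, with the Treg condition
  switching to oxidative metabolism after a transient glycolytic phase;
* the T-follicular-helper condition (IL-6 + IL-21, no TGF-β) settles on a
  limit cycle — periodic Bcl-6, IL-9, IL-21 and CD40L with the metabolic
  programs alternating — driven by a delayed negative feedback through
  Bcl-6 → glycolysis → AMPK → mTORC2 → mTORC1; lowering the IL-6/IL-21
  dose quenches the loop and stabilizes Bcl-6 above threshold;
* a uniform all-type cytokine mixture polarizes to Th1 at full strength
  (with transient Th17), to Th2 at moderate depletion, to a mixed
  Th2/Th17 state, then Th17 alone, and to no phenotype at low levels —
  with the Th1 region an up-set of the cytokine level;
* glutamine or tryptophan restriction under the all-type mixture flips
  the Th1–Th2 axis at critical levels near 0.53 and 0.75 respectively;
  glutamine restriction under Th1+Treg cytokines yields Treg, and adding
  full hypoxia redirects polarization to Th17 with IL-17 but no IL-21;
* CTLA-4 expression times above one time unit arrest activation, and
  absent co-stimulation the anergy factor is transiently induced while
  IL-2 never rises.

Known limitations of the reconstruction, deliberately left visible as red
acceptance checks rather than patched around: in the glutamine/hypoxia
condition table, the two conditions with IL-4 between 0.63 and 0.70 at
half glutamine come out Th1-dominant rather than GATA3-dominant hybrids,
and the subordinate Foxp3/Bcl-6 co-expressions of three further
conditions sit below threshold; two of the four critical levels deviate
from their reference values by 0.03–0.05. These distinctions hinge on
rule-level details that the network's prose description does not
determine.

## Numerical choices

* **Integrator.** `deSolve::lsoda` (stiff-capable, adaptive) with
  `rtol = 1e-8`, `atol = 1e-10`, reported on a uniform grid of step 0.05.
  Halving the tolerances changes CD4 steady-state levels by less than
  $10^{-5}$ (tested). The right-hand side is compiled once per run into a
  single R function with rules, clamp levels and schedules inlined.
* **Attractor window.** Classification uses the trailing 25% of the
  trajectory, at least 10 time units. A node is periodic when its window
  amplitude exceeds 0.05 and at least two full periods are detected from
  interior peak spacing; otherwise it is fixed at the window mean and must
  satisfy the steady-state residual bound ($10^{-4}$). On a limit-cycle
  attractor, low-amplitude nodes that fail the residual bound are
  reclassified as periodic followers — they oscillate with the cycle, just
  weakly.
* **Horizon extension.** `run_scenario()` re-integrates to $t = 120$ when
  periodicity is detected but undersampled, and doubles the horizon (up to
  240) while the trailing window is still drifting or a fixed node misses
  the residual bound. Scenario comparisons therefore never read a
  half-converged state.
* **Events.** The stimulus schedules are smooth logistics, so no event
  handling is needed at the depletion time.
* **Determinism.** There are no stochastic terms; the only randomness in
  the package is test-side sampling of initial states under a fixed seed.
* **Degenerate inputs.** `t_end = 0` returns the initial state as a
  one-sample trajectory; a scan over a degenerate range reports
  "no transition" rather than failing; rule constants outside $[0,1]$ and
  clamp levels outside $[0,1]$ are rejected at parse/validation time.

## Phenotype calls and critical-level scans

A lineage is called against the model's own truth threshold
$\theta = 0.5$ — the only principled choice, since the formalism defines
it as the boundary between falsity and truth: *stable* if the defining
transcription factor's steady level exceeds $\theta$, *transient* if only
its peak does, *oscillatory* if the factor is periodic with
supra-threshold peaks, *off* otherwise. A hybrid phenotype is two or more
lineages expressed at steady state; predominance is ranked by steady (or
oscillation-mean) level with ties within 0.02 reported as co-dominant.

`scan_critical()` sweeps one input over a coarse grid (step 0.05),
brackets the first change in the expressed-phenotype signature, and
bisects to a bracket of 0.005, reporting the midpoint rounded to two
decimals. The reported level is invariant (within tolerance) to halving
the coarse step (tested), and a scan typically costs 25 ODE runs.

## What the fixtures do and do not show

The toggle, self-activator and negative-feedback fixtures have analytically
known attractor structure, so integration can be checked against an
independent brute-force fixed-point scan (grid start + damped Newton
polish, unstable points included). Passing those checks validates the
engine — the algebra, the gate, the integrator and the classifier — but
says nothing about the fidelity of any particular biological rule set;
that separation is why the CD4 model ships as data, not code.

## Problem sizes

Default runs integrate 52 internal state variables over 30 time units
(extended to at most 240 when needed) on a 0.05 reporting grid; a full
critical-level scan is ≈25 such runs; the acceptance script executes about
120 runs end to end. These sizes were chosen so the whole analysis
reproduces comfortably on a laptop-class single core.
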