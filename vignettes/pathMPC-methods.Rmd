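---
title: "Three-timescale pathway simulation and surrogate model-predictive control"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Three-timescale pathway simulation and surrogate model-predictive control}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(pathMPC)
```

# The model

pathMPC simulates an integrated biochemical system in which a
gene-regulatory layer (expression levels $x \in [0,1]^p$), a signaling
layer ($y \in [0,1]^s$) and a metabolic layer ($z \in [0,1]^m$) evolve on
three separated timescales under $c$ external inputs $u$:

$$\dot x = f(x, y, z, u), \qquad
  \dot y = \tfrac{1}{\omega_1}\, N^{(s)} r^{(s)}, \qquad
  \dot z = \tfrac{1}{\omega_1 \omega_2}\, N^{(m)} r^{(m)},$$

with slow-to-fast ratio $\omega_1$ and fast-to-ultrafast ratio
$\omega_2$, both $1/60$ by default: gene regulation operates on the
scale of hours, signal transduction of minutes, metabolism of seconds.
$N^{(s)}$ ($s \times q$) and $N^{(m)}$ ($m \times n$) are incidence
matrices with entries in $\{-1, 0, +1\}$.

The three rate-law families:

* **Transcription.** A gene $i$ driven by transcription factors $y_{j'}$
  expresses at rate $e_i = \prod_{j'} K^{(g)}_{ij'} y_{j'}$. If any
  required factor is absent, $\dot x_i = b_i - d_i$ exactly (basal
  production minus constant decay). Metabolite/input cofactors multiply
  $e_i$ by $\prod_k (1 + F_{ik} z_k) \prod_l (1 + F_{il} u_l)$;
  inhibitors instead divide $e_i + b_i$ by the analogous product. When a
  rule carries both sets, the enhancer product is applied to $e_i$ and
  the inhibitor product divides $e_i^{enh} + b_i$ — the two published
  forms composed, since the source formulation never combines them in
  one rule.
* **Signaling.** Interaction $\sigma$ activating species $j$ proceeds at
  $r^{(s)}_\sigma = k_\sigma \prod_{j'} K^{(s)}_{jj'} y_{j'}$ times
  enhancer factors and divided by inhibitor factors of the same
  $(1 + F\,\cdot)$ shape. We read the inhibited form as a division
  (mirroring the transcription layer); the multiplicative rendering in
  the source text contradicts its own description of inhibitors slowing
  activation and appears to be a typesetting loss of a fraction bar.
* **Metabolism.** Reaction $\rho$ with substrate product
  $Z = \prod_{k'} z_{k'}$ and catalyzing enzyme level $E_\rho$ (the
  expression level of its gene) carries flux
  $r^{(m)}_\rho = K_\rho E_\rho Z / (K_{\rho M} + Z)$, modified by
  noncompetitive/allosteric $(1 + F\,\cdot)$ factors. A single Michaelis
  constant applies to the substrate product, exactly as published.
  Setting $K_\rho = 0$ knocks the reaction out.

Two deliberate representation choices in the signaling stoichiometry:
activation interactions are catalytic (the activated species receives
$+1$; activators are not consumed), and each species carries an explicit
first-order decay interaction holding the $-1$ entries. Applying the
"participant gets $-1$" reading to activation cascades would drain every
upstream species and no cascade could sustain a signal. Receptor-level
interactions driven purely by external inputs carry a basal rate
constant $k_\sigma \in (0, 1]$, since the published rate is otherwise a
product over signaling activators only.

# Numerical treatment

The scaled system is stiff ($1/(\omega_1\omega_2) = 3600$), so the
default integration mode hands the full system to an implicit adaptive
solver (`deSolve::lsoda`) with the derivative evaluated in compiled
code. States are confined to the unit box — the model's concentrations
and expression levels are normalized — by a smooth restoring wall
outside the box, scaled to each layer's own timescale, plus clamping of
the returned samples; a hard derivative projection makes stiff solvers
chatter at the bounds. The number of clamped entries is recorded in the
trajectory metadata. A `nested_multirate` mode integrates the metabolic
block at $\Delta t\,\omega_1\omega_2$ and the signaling block at
$\Delta t\,\omega_1$ resolution with a midpoint rule, mirroring the
stretched-timescale construction; the two modes agree to solver
tolerance on the test fixtures.

Quasi-steady-state reductions solve the fast and ultrafast equilibria
inside the unit box by damped Newton iteration with projection and a
quasi-Newton fallback on the squared residual; ties between roots
resolve to the root reached from the warm start. The reduced slow model
replaces $y, z$ by these maps; its error against the full simulation
shrinks as the timescale ratios shrink and is checked down to
$\omega = 1/60$.

The equilibrium-consistent input used by the data generator minimizes
the squared norm of the *unscaled* layer residuals over $u \in [0,1]^c$
(the scaled norm would weight the metabolic layer by $3600^2$ and
drown the others); an exact root is returned when one exists.

# The MIMO plant and the sliding-window dataset

`buildPlant()` freezes the simulator with an initial state drawn
uniformly at random and exposes one pure step: input instance
$\langle x, y, z, u\rangle$ (length $p+s+m+c$), one slow time unit of
integration, output instance $\langle x, y, z\rangle$. Perturbations are
knockouts ($K_\rho := 0$) and pinned species (hard overrides during
integration). `tuneParameters()` implements the trial-and-error
calibration protocol as a seeded hill climb over all kinetic constants
(steps of at most 0.05, accept if at least as many checklist items
pass).

The supervised dataset rolls a window of $\tau$ past (input, output)
pairs plus the current input —
$d = \tau(2(p+s+m)+c) + (p+s+m+c)$, which is 4713 for the packaged
network at $\tau = 19$ — and pairs it with the current output. Between
steps the next input is the equilibrium-consistent $u$ plus a small
seeded excitation (amplitude 0.02). Two generator options matter at
reduced sample budgets:

* `segments`: restarting the closed loop from fresh uniform random
  states spreads a small sample budget over the state space instead of
  tracing one attractor;
* `stateJitter`: perturbing the state block of the applied input
  instance breaks its collinearity with the previous output. Without
  it the one-step response to a state change — precisely what the
  controller asks the surrogate about — is unidentifiable from
  closed-loop data, and the fitted ensemble is numerically insensitive
  to the current-input block.

Both default to the plain protocol; the packaged controller surrogate
uses both, recorded in its manifest.

# The surrogate ensemble

One $\varepsilon$-insensitive support vector regressor per output
component ($p+s+m$ of them), sharing a single radial-basis kernel
matrix over the window regressors; the dual problems (box constant
$C = 100$, tube $\varepsilon = 0.0025$, kernel coefficient
$\gamma = 10$ in $\exp(-\gamma\|v-v'\|^2)$) are solved by the kernlab
SMO solver, and the package stores the ensemble in dual form and
evaluates its own kernel expansion. Fitted models are checked against
the Karush–Kuhn–Tucker conditions: dual coefficients inside the box,
$|\sum_b \alpha_b| \le 10^{-6}$ per output, non-bound support vectors
on the tube boundary to $10^{-3}$. Test accuracy is the percentage of
held-out samples whose mean squared error across all outputs falls
below 0.05 — a per-sample, multi-output reading of the published
accuracy figure (the alternative per-output reading is not used).

At the packaged network's dimensions the window vectors are long
(4713), so distinct trajectories sit far apart and the
$\gamma = 10$ kernel acts as a near-lookup: excellent interpolation
along a trajectory (the accuracy experiments), but numerically zero
kernel mass at states the controller later visits. The packaged
controller surrogate is therefore trained with a small kernel
coefficient ($10^{-4}$, recorded in its manifest) on state-excited
data, trading sharpness for a usable global gradient; the published
coefficient remains the package-wide default and is what the accuracy
experiments use.

# The GA controller

Each closed-loop iteration runs one genetic optimization of the next
input instance against the surrogate: population of 60 seeded uniformly
within 0.1 of the current input (the unchanged current input included,
so elitism preserves a solved problem), median-fitness selection with a
top-half fallback, uniform crossover (a single-point mode at index 53 —
about half the output-vector length — is kept for fidelity
experiments), mutation, elitism, at most 10 generations or a fitness
of 0.98. Fitness is $1/(1 + \text{weighted } L_1)$ between the
predicted output and the reference, which is 1 exactly at a perfect
match and strictly decreasing in the error; setpoint components can be
up-weighted (the packaged cancer scenario uses weight 25) so the blurry
surrogate's signal concentrates on the tracked outputs. The convergence
test stays the plain unweighted $L_1$ on the actual plant output.

Mutation is per chromosome — each child mutates with probability 0.7 by
redrawing one uniformly chosen locus. The per-locus reading (every locus
redrawn independently with probability 0.7) is also implemented
(`mutation = "locus"`), but it randomizes essentially every locus of
every child, the population can never refine below the initialization
jitter, and the identity-plant convergence experiment fails from every
seed; per-chromosome mutation is the standard reading of a single
mutation rate and makes the same experiment converge in a handful of
iterations.

The closed loop applies the optimized instance to the plant, rolls the
window forward, references free outputs at their last observed values,
and retries the GA with fresh seeds when its best fitness regresses;
if the regression persists the loop keeps the current input (the bar
relaxing geometrically so it cannot jam) rather than stepping the plant
with a worse solution.

# The packaged network and scenarios

The central-carbon-metabolism network ships with
$(p, s, m, c) = (37, 29, 41, 27)$: glycolysis/gluconeogenesis, TCA
cycle, both pentose phosphate branches and fatty-acid turnover;
PI3K/AKT/mTOR, HIF-1α/PHD, RAS/ERK/MYC, JAK/STAT3, NF-κB, p53/MDM2 and
AMPK signaling; one transcription rule per enzyme gene; 27
micro-environmental inputs. The wiring is a curated reconstruction of
the canonical pathway structure — the source publishes neither the full
edge list nor the constants — and all constants are versioned package
defaults calibrated once, by the same trial-and-error protocol the
plant module automates, against the qualitative behavior checklist of
the normal scenario and the direction table of the Warburg comparison.
Calibration-relevant structural choices, in the package's own words:

* conserved cofactor pairs (NAD/NADH, NADP/NADPH, FAD/FADH2) and a
  floating adenylate pool fed by purine synthesis from ribose-5P and
  drained by nucleotide turnover — energy charge and nucleotide supply
  couple through the pentose phosphate pathway, which is what lets the
  controlled plant hold a high-ATP, high-ribose-5P cancer state;
* a phosphagen-like buffer reaction (ADP → ATP at a small rate) so the
  glycolytic investment step cannot deadlock the whole energy system;
* TCA dehydrogenases write to the mitochondrial (FAD) pool, cytosolic
  NADH reaches it only through a malate–aspartate-style shuttle, and one
  lumped oxidative-phosphorylation reaction pays out ATP: with pyruvate
  entry knocked out, pinned-high pyruvate hands cytosolic NADH to
  lactate dehydrogenase by mass action, which is the Warburg switch;
* lactate/acidosis feedback: stabilizes HIF-1α, inhibits PHD,
  respiration, glucose supply/uptake and the oxidative PPP, activates
  p53; NADPH suppresses p53 (redox tone), which drives the p53/GLUT1
  responses of the drug-target cases;
* the non-oxidative PPP is oriented toward ribose-5P synthesis
  (nucleotide demand direction), and sink reactions are assigned to
  representative pathway genes.

Scenario initial states are drawn uniformly in (0.05, 0.35) — the
low-activity regime in which the expression program's ramp-up
reproduces the documented normal-scenario transients; the published
protocol draws in (0, 1) and keeps, by trial and error, the draws that
reproduce known behavior, which this narrowing automates. Directional
assertions are evaluated on window means: comparator claims
(Warburg/cancer versus normal) on the last 10% of seed-matched runs;
within-run trend claims on per-species windows registered in the
scenario definitions (growth phase [0%, 50%] for the PEP/OAA/citrate
surge, induction phase [40%, end] for the ribose-5P/NADPH/FFA/G6P/
glucose accumulation), since the source reads these claims off
transient figures. The "switching" claim for pyruvate kinase is
checked as non-monotonicity of its controlled trace (both rises and
falls of at least 0.02).

Drug-target cases continue a converged cancer loop, adding the target
gene's reference expression level to the controller reference from the
mid-run gate onward (the published figures gate their effects at a
mid-axis time in figure units), and compare post-gate against pre-gate
windows with a direction vocabulary of up/down, flat
($|\Delta| \le 0.1$) and high (at least 70% of baseline).

# Problem sizes and limitations

The packaged experiments run at deliberately reduced sizes: surrogate
accuracy at a few thousand window samples and the controller surrogate
at several hundred (the published experiments use 60000), with the
test suite scaled further. The directional claims are therefore
asserted qualitatively, never as curve reproduction — with unpublished
constants the quantitative trajectories are not reproducible in
principle.

What passing the synthetic experiments does not show about real cells:
the generator emulates the model's own closed loop, so surrogate
accuracy reflects interpolation along model trajectories, not
biological measurement noise, unmodeled reactions, or inter-cell
variability; the unit-box normalization hides absolute concentration
scales; and the curated constants are calibrated to qualitative
directions only.

Known limitations: the constant-decay transcription law makes genes
ramp to a bound rather than settle at interior equilibria, so gene-level
contrasts are transient or boundary effects; at reduced sample sizes
the surrogate's response to the current-input block is heavily
smoothed, the GA tracks interior setpoints only approximately, and
closed-loop convergence to a tight L1 threshold is not generally
reached (the controller then reports its best-tracking iterate); and
the equilibrium-input solver returns a least-squares compromise when no
exact equilibrium input exists.
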