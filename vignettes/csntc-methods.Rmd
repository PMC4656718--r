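---
title: "Selection of cortical reservoir dynamics by a dopamine-gated basal ganglia circuit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Selection of cortical reservoir dynamics by a dopamine-gated basal ganglia circuit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(csntc)
```

## The model

`csntc` simulates cortico-striato-nigro-thalamo-cortical (CSNTC) loops: a
cortical module, modelled as an echo-state reservoir, whose internal
dynamics are *selected* by a multi-channel basal ganglia circuit through
disinhibition of thalamo-cortical loops. The hypothesis the simulator
expresses is that the basal ganglia do not choose between cortical
assemblies but between *dynamical regimes of the same population*: when a
channel's tonic pallidal inhibition is lifted, the corresponding cortical
sub-population switches to an up state, and the whole reservoir — one
uniformly connected recurrent network — thereafter computes a different
temporal function of the same sensory input. Linear read-out units can
then be trained to decode each selected regime into a different movement
of a simulated arm.

### Units

Every unit in every layer is a leaky rate population,

$$\tau \dot u = -u + d, \qquad z = \left[\tanh(\alpha (u - th))\right]^+,$$

where $d$ collects the unit's synaptic drive. The positive-part transfer
keeps rates in $[0, 1)$, as appropriate for population activity. The
integrator is explicit (forward) Euler with a fixed step. Defaults:
$\tau = 10$ ms for every layer, $\alpha = 2$, $th = 0.1$, $dt = 1$ ms.
None of these values is dictated by data; they give a silent resting
state (`transfer(0) = 0`), a graded response over the drive range the
circuit produces, and a comfortable stability margin ($dt \ll \tau$). The
step-halving test in the suite confirms the integrator's first-order
convergence against the exact linear-ODE solution.

### Cortex: the reservoir

`build_reservoir()` draws a sparse random recurrent matrix (connection
probability 0.1, standard-normal weights), optionally removes part of its
symmetric component, and rescales it so that the *leaky-effective*
one-step propagator $(1 - dt/\tau) I + (dt/\tau) W_u$ has a prescribed
spectral radius — the echo-state normalization appropriate for leaky
units. Because the eigenvalues of the effective matrix are affine in the
scale factor, the normalization is exact (a 1-D root solve), and the
suite checks the radius to $10^{-6}$.

Two non-obvious choices:

* **Asymmetry transformation.** The construction can subtract a fraction
  `asymmetry` of the symmetric part, $W \leftarrow W - c\,(W + W^\top)/2$
  (default $c = 0.5$), before renormalizing. Removing symmetric structure
  is the standard lever for richer, longer-lived transients in linearized
  recurrent dynamics; the flag isolates this choice, and `asymmetry = 0`
  recovers plain echo-state normalization.
* **Effective radius 0.93.** With the positive-part transfer, a locked-in
  (saturated) sub-population injects a large static recurrent drive into
  the rest of the network. At radii very close to 1 this splash can
  spontaneously ignite a *second* sub-population in some random
  reservoirs, corrupting the selection. At 0.93 the lock-in of a single
  channel is robust across reservoir seeds while the fading-memory
  property (activity decays to zero within tens of $\tau$ after input
  offset) is retained. The radius remains a `reservoir_spec` parameter.

Units are partitioned into thalamo-cortical *loop* units (50%, split
equally among the channels), *input* units (20%, the only ones reached by
external cortico-cortical input, with uniform $[-1, 1]$ weights), and
*free* units (30%).

### Basal ganglia: selection by disinhibition

The selection circuit has five layers of C units each (StrD1, StrD2,
STN, GPe, GPi), wired one-to-one per channel except the STN, whose
excitatory efferents reach every GPe and GPi unit (the diffuse
hyper-direct pathway). GPi carries a tonic drive, so at rest it inhibits
the thalamus. Dopamine acts multiplicatively on the striatal input:

$$\tau \dot s_{D1} = -s_{D1} + (bl_{D1} + da_{D1}\,da) \cdot (W_{sc} c + W_{sx} x),$$
$$\tau \dot s_{D2} = -s_{D2} + \frac{W_{sc} c + W_{sx} x}{bl_{D2} + da_{D2}\,da}.$$

High dopamine amplifies the direct pathway (D1, which inhibits GPi) and
silences the indirect one (D2, which inhibits GPe); low dopamine does the
opposite, re-arming the GPe–STN feedback and restoring tonic GPi output.
Per-channel cortical input $c$ is the mean rate of the corresponding
loop sub-population (the pooling rule is not constrained by anatomy; the
mean is scale-stable in the sub-population size).

The full loop closes through one thalamic unit per channel, with drive
`tha_tonic + w_cttha * c_k - w_gpitha * gpi_k`. Three regimes follow,
and they are what the scripted-schedule test checks as ordered threshold
crossings:

1. **Onset.** Dopamine high plus a biased striatal channel: that
   channel's StrD1 rises, its GPi is selectively silenced, its thalamic
   unit is released and — *only if the cortex carries background
   activity* — the thalamo-cortical positive feedback ignites the up
   state.
2. **Lock-in.** The up-state sub-population feeds its own striatal and
   STN channel, so the selection persists after the biasing input ends.
3. **Unlock.** When dopamine falls, D2 activity silences GPe, the STN
   and GPi recover their tonic activity, the thalamus is re-inhibited
   and the loop returns to the down state.

None of the inter-layer gains is published; they were tuned (script in
the repository history; values in `bg_params()`) to produce exactly this
qualitative regime — no selection under symmetric input, selection under
a biased input, lock-in conditional on cortical background, unlock on
dopamine fall — before any behavioural experiment was run. Two derived
quantities are worth knowing when retuning: the *lock-in threshold* (a
sustained striatal bias of about 0.17 with the defaults) and the
*thalamic inhibition margin* `w_gpitha * z_gpi_max`, which must exceed
`tha_tonic + w_cttha * c_up` for the unlock to succeed; `tha_tonic` must
stay below `th` or the circuit violates the requirement that no thalamic
activity exists without cortical background.

### Read-out learning

Batch mode trains the linear read-out $o = W_{oz} z$ by Tikhonov-regularized
regression over the reservoir states recorded inside the task windows of a
single storage session,

$$W_{oz} = (X^\top X + \lambda^2 I)^{-1} X^\top Y, \qquad \lambda = 0.5.$$

Online mode uses the simplified backpropagation–decorrelation rule for
feed-forward read-outs (dynamic leaky units without lateral connections),

$$\Delta W = \frac{\eta}{\Delta t} g_{t+1} d_t^\top,\quad
d_t = \frac{z_t}{z_t^\top z_t + x_t^\top x_t + \beta},\quad
g_{t+1} = (1 - \Delta t) e_t - e_{t+1},$$

with $\eta = 0.01$, $\beta = 1$ and $\Delta t = dt/\tau = 0.1$ (the rule's
step is dimensionless; using the integrator step in milliseconds would
zero the $(1-\Delta t)$ term). Both rules are checked against hand-computed
values and an independent solver in the test suite.

For the amplitude-generalization experiment the read-out is trained with
$\lambda = 5$: interpolation along the constant-input continuum benefits
from a smoother map, whereas recall of trained trajectories tolerates
(and slightly prefers) the lighter default shrinkage.

## The experiments

### Trial protocol

A trial lasts 4000 ms: dopamine on at 500 ms and off at 3500 ms; the
binary striatal bias on from 500 to 1500 ms (so the scored behaviour
demonstrates lock-in, not input following); the scored *task window* from
1200 to 3200 ms — after the selection transient, which completes at about
1050–1150 ms, and inside the dopamine interval. The sinusoidal context
input (period 1000 ms, amplitude 0.5, always the same across tasks) is a
function of global time, and the trial length is a multiple of its
period, so targets indexed by sinusoid phase are consistent across
trials. A session recalls each of the three tasks once in random order,
and **nothing is ever reset**: training and test sessions are one
continuous simulation, which is itself a test of the dynamics' ability to
handle transitions. Three test sessions are run and only the last is
scored; the preceding ones verify stability.

Targets are closed planar curves (rounded square, sideways figure-eight
Lissajous, crescent) traced once per sinusoid period, converted to
joint-angle series for a planar 3-segment arm (unit lengths, joint limits
$[-\pi/2, \pi]$) by damped-least-squares inverse kinematics warm-started
sample to sample, then mapped affinely to read-out rates. The error
measure is NRMSE: per-joint RMSE divided by the target's range, averaged
over joints (the normalization convention is not fixed by precedent; the
range makes errors comparable across joints with different excursions).
End-point tasks use constant postures and report the absolute per-joint
angle error at the end of the task window.

### The two-module lesion study

The system model chains a high-level motor CSNTC module, a primary motor
CSNTC module and a somatosensory reservoir (no basal ganglia). A
9-channel binary task code in three groups drives the high-level module:
a hardwired category map (each group onto one striatal channel — the
stand-in for reward-based learning, which is out of scope) and fixed
random weights onto the high-level cortex. The high-level cortex projects
to the primary cortex (fixed random weights, gain 0.5) and to the primary
striatum through the only plastic matrix in the system, trained by the
Oja rule with k-winner-take-all filters,

$$\Delta W_{sx} = \eta_{sx}\left(s c^\top - ((s \odot s) 1^\top) \odot W_{sx}\right),$$

with $s$ the noisy striatal rates after kWTA ($k = 1$) and $c$ the
high-level cortical rates after kWTA.

Several implementation choices here were genuinely open and matter:

* **Source of the cortico-striatal pathway.** The learnable projection
  originates from the high-level *loop sub-populations* only (the
  deep-layer projection neurons of the module), not from its
  input-receiving units. The pathway then carries the coarse,
  code-independent task signature — which sub-population is locked in —
  rather than the identity of the particular code bit. Without the
  restriction, the Oja winners include code-driven input units and the
  learned selection collapses under the orthogonal (DIFF) code.
* **Lateral inhibition of the learned pathway.** The learned striatal
  drive is delivered with its channel mean subtracted,
  $g\,(W_{sx} z - \overline{W_{sx} z})$. Competitive Hebbian learning
  from random exploration inevitably gives all rows a large shared
  component; delivered raw, that common mode pushes *every* channel past
  the lock-in threshold and selection collapses. Mean subtraction — the
  network analogue of feedforward striatal lateral inhibition — makes
  only the task-specific deviations compete. The flag
  `center_hl_drive = FALSE` disables it.
* **kWTA size of the cortical vector.** $k$ matches the size of one loop
  sub-population (16 of 100 units at the default module size), so a
  winner's weights concentrate on a single locked sub-population. (At the
  reference cortex sizes implied elsewhere, $k = 30$ plays the same
  role.)
* **Learning-phase perturbation and rate.** Gaussian noise on the primary
  striatal input (per-trial draws, $\sigma = 0.4$, applied while dopamine
  is on) lets selection happen randomly before $W_{sx}$ carries
  information; the Oja step adds its own small Gaussian perturbation
  ($\sigma = 0.1$) to the striatal vector before the kWTA. The learning
  rate $\eta_{sx} = 10^{-3}$ consolidates a captured task-to-channel
  association within a few trials while leaving the early trials
  noise-driven; the association is consistent across test repetitions in
  essentially every run, and bijective (three tasks on three distinct
  channels) in most, with occasional two-on-one collisions that raise
  that simulation's error.
* **Gains and regularization.** The high-level to primary cortico-cortical
  gain is deliberately weak (`g_hl = 0.15`) and the system read-out uses
  a stiff ridge ($\lambda = 5$): together they make the read-out lean on
  the strong, selected primary dynamics. In the intact system the
  orthogonal-code test then degrades performance only mildly, while a
  lesioned system — forced to exploit weak, code-bound components with
  large read-out weights — is disproportionately sensitive to the code
  change. This is the mechanism behind the TEST × LESION interaction.

The three phases follow the protocol above with a later task window
(1900–3400 ms; the selection must propagate through two chained modules)
and with the task code held on until the end of the window (the code is
part of the behavioural context, and the SAME/DIFF contrast is empty if
it vanishes before the scored behaviour): 30 sessions of cortico-striatal
learning under perturbation, one read-out storage session, then three
SAME-code and three DIFF-code test sessions (last of each scored).
Lesions — PARTIAL: the high-level-cortex to primary-striatum bundle;
FULL: additionally the code-to-high-level-striatum map — are applied
before any learning. Within a repeat, all three lesion groups share
identical networks and trial orders (structural and protocol seeds come
from separate streams), so the lesion is the only difference. The
TEST × LESION analysis is a balanced two-way fixed-effects ANOVA on
per-simulation mean NRMSE, computed from sums of squares
(`anova_two_way()`) and cross-checked against `aov()` in the suite.

## What the synthetic inputs do and do not emulate

All inputs are generated internally: the sinusoid stands in for
fine-grained somatosensory drive, the binary vectors for categorical
task information, and the parametric shapes for motor targets. Passing
tests therefore show that the *selection-and-decoding architecture*
works as claimed under clean, stationary, low-dimensional inputs. They
do not show robustness to rich sensory statistics, closed-loop
proprioceptive feedback (the arm is kinematic; no forces, no sensory
consequences of movement), reward-driven acquisition of the category
map, or neural noise outside the one learning phase that uses it.

## Numerical and scale choices

Module sizes are 200 units for the single-module experiments and 100
units per cortical module (three modules) for the lesion study, with 25
repeats per lesion group in the acceptance script; these sizes keep a
full three-group study in the minutes range on one core while leaving
every qualitative behaviour intact. The compiled kernels replicate the R
step functions exactly (a parity test asserts agreement at $10^{-12}$),
and every stochastic element — reservoir draws, trial orders,
perturbations — derives from explicit seeds, so identical configurations
reproduce byte-identical result records. kWTA ties break toward the
lowest index; kWTA keeps surviving magnitudes (the Oja rule multiplies
by them, so binarizing would change the fixed points).

## Known limitations

* The basal ganglia gains implement one qualitative regime; far outside
  the tuned region (e.g. thalamic tonic bias above the transfer
  threshold) the circuit violates its own preconditions, and the
  constructors do not guard every such combination.
* The task-to-channel map learned by the Oja phase is consistent within
  a simulation but occasionally non-bijective (two tasks captured by one
  channel in a minority of runs); the headline lesion ordering is robust
  to this, but per-simulation errors are visibly bimodal and the
  BASELINE-vs-PARTIAL interaction is the weakest of the study's
  contrasts.
* With three channels, claims about scaling to many tasks rest on a
  single four-task check, not on a systematic capacity study.
* The two-way ANOVA assumes balanced cells; it warns and degrades to a
  cell-means approximation when mildly unbalanced.
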