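---
title: "Modeling the effective sign of transcriptional feedback in bacterial two-component systems"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling the effective sign of transcriptional feedback in bacterial two-component systems}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The biological problem

Bacterial two-component systems (TCSs) couple an environmental cue to a
transcriptional program through two proteins: a sensor histidine kinase (SHK)
and a response regulator (RR). The SHK autophosphorylates, transfers the
phosphate to RR within a transient complex, and — being bifunctional — also
catalyzes dephosphorylation of phospho-RR (RRP). Phosphorylated RR dimerizes,
and the dimer (RRP2) activates transcription. In the most common architecture
both genes sit in one operon whose promoter is activated by RRP2, closing a
transcriptional autoregulation loop.

The wiring diagram suggests positive feedback, but the *effective* sign of
the loop is a quantitative question: raising expression of the operon raises
both the kinase supply and the phosphatase drain. When some RR
phosphorylation comes from sources other than the cognate SHK (cross-talk,
small-molecule phosphodonors), extra SHK can disproportionately increase the
drain, so higher expression can *lower* the activated fraction — effectively
negative feedback. `tcsfeedback` implements a deterministic reaction-network
model of this system together with the full analysis suite needed to
characterize the feedback sign and its dynamical consequences.

## The model

Ten species are tracked (`tcsSpecies()`): the TCS and downstream operon
mRNAs, free SHK and SHKP, free RR and RRP, the two enzyme–substrate complexes
`C_t` (SHK·RRP, the phosphatase complex) and `C_p` (SHKP·RR, the
phosphotransfer complex), the transcriptionally active dimer RRP2, and a
downstream reporter protein DS. Twenty-two reactions connect them:

* **Expression.** Regulated transcription of each operon is saturating in
  the activator, $v = k_{txn}\,[A]/(K + [A])$ with $A = \mathrm{RRP}_2$,
  $K = K_m$ (TCS operon) or $K_{mDS}$ (downstream operon); a Hill
  coefficient of 1 is used because dimerization of RRP already supplies the
  cooperativity, and both operons share $k_{txn}$ and the basal rate
  $k_{txnbasal}$ because the printed parameter set carries no separate
  downstream $V_{max}$. Translation is first-order in mRNA
  ($k_{SKtsn}$ per transcript); RR is translated `tsn_mult`-fold faster than
  SHK from the shared transcript, consistent with response regulators
  outnumbering their kinases in real systems. mRNAs decay at $k_{mRNAdeg}$
  (growth dilution of mRNA is treated as lumped into this decay constant);
  all proteins, complexes and the dimer are diluted at the growth rate
  $k_{dil}$.
* **Phospho-cycle.** Autophosphorylation ($k_{ap}$) and
  autodephosphorylation ($k_{ad}$) act on free SHK only. Binding/dissociation
  (SHK + RRP $\leftrightarrow$ C$_t$ with $k_b, k_d$; SHKP + RR
  $\leftrightarrow$ C$_p$ with $k_{b1}, k_{d1}$), reversible
  phosphotransfer within the complex ($k_{pt}, k_{tp}$), and phosphatase
  catalysis on C$_t$ ($k_{ph}$, releasing SHK + RR) follow mass action.
  Exogenous phosphorylation of free RR and dephosphorylation of free RRP are
  Michaelis–Menten ($k_{exp}, K_{mexp}$; $k_{exd}, K_{mexd}$), the form
  consistent with a cross-talk mechanism.
* **Dimerization.** $2\,\mathrm{RRP} \leftrightarrow \mathrm{RRP}_2$ with
  $k_{RRPdm}, k_{RRPmd}$.

Units are µM and seconds throughout. The signal is the phosphatase rate
$k_{ph}$: held at 10 s⁻¹ the system rests at a low-activity state;
dropping it activates the system. Kinase modulation through $k_{ap}$ is also
supported (`gainScan` can map the full $k_{ap} \times k_{ph}$ signal plane).

Two constants are not part of the published kinetic set and are package
defaults, both configurable: the growth dilution rate
$k_{dil} = 2\times10^{-4}$ s⁻¹ (~58 min doubling, a typical moderate growth
rate) and the unit conversion of 1000 molecules per cell per µM (a ~1.66 fL
cell), which is used only by the molecule-per-cell feasibility thresholds.

Internally the two pooled loss rows of the reaction table (mRNA decay,
protein dilution) are expanded per species, giving 30 elementary fluxes and
a 10×30 stoichiometry matrix for which
`timeDerivative == stoichiometryMatrix() %*% reactionFluxes(expanded = TRUE)`
holds exactly; the 22-row table view reports pooled totals for those rows.

## Circuit variants

`makeTopology()` builds five wirings. Besides the wild type: an *open-loop*
form in which a fixed exogenous regulator concentration $R_0$ replaces RRP2
at the TCS promoter only (the downstream operon stays RRP2-controlled so
downstream readouts remain signal-responsive); a *no-feedback* control with
constitutive TCS transcription; and *Circuit I / Circuit II*, in which only
the RR or only the SHK gene is under feedback and the other is produced at a
constant rate. Every constitutive rate is calibrated to equal the
corresponding wild-type production flux at the wild-type steady state under
$k_{ph} = 0.1$ s⁻¹, an expression level away from both saturation extremes;
as a consequence the wild-type activated state is a fixed point of each
calibrated variant, which the test suite checks.

## Numerical methods

Time integration uses `deSolve::lsoda` on a compiled right-hand side
(relative tolerance $10^{-8}$, absolute $10^{-12}$); protocol segment
boundaries are integration restart points, and each segment is sampled on a
mixed log/linear output grid (dense early points resolve the fast
phospho-relaxation, seconds-to-minutes, while the linear tail covers protein
accumulation over hours). Steady states are found by integrating toward the
attractor (horizon 40 dilution times, extended tenfold on failure) and
polishing the endpoint with a damped Newton iteration on a finite-difference
Jacobian until the residual derivative norm falls below
$10^{-10}\max(1, \lVert x\rVert)$; failures are reported as explicit flags
and never silently zeroed. Saturating rate laws clamp their substrate at
zero so the integrator's tiny transient negative excursions cannot flip a
production flux.

The open-loop gain
$g = \mathrm{d}\ln [\mathrm{RRP}_2]_{open} / \mathrm{d}\ln R_0$ is computed
by central difference with a 1% multiplicative perturbation of $R_0$ around
$R_0^* = [\mathrm{RRP}_2]_{closed}$, with the perturbed steady states
polished to a residual of $10^{-13}$ — necessary because near promoter
saturation the physical response to the perturbation can be orders of
magnitude smaller than the default solver tolerance. Gains below $10^{-4}$
in magnitude are labeled `"zero"` rather than signed. The test suite
cross-checks the central difference against an implicit-differentiation
sensitivity solution of the linearized steady-state system.

Response times interpolate the first upward crossing of the target level
linearly between output points. A trajectory that starts at or above the
level has $\tau = 0$; a level never attained is reported as `NA` (serialized
as the explicit sentinel `"undefined"`).

### Choice of the activation level, and a subtlety about the gain sign

All activation kinetics, the feasibility criteria, and the circuit
calibrations use the 10 → 0.1 s⁻¹ signal step. For the *sign* of feedback
the picture is more delicate: the effective sign depends on the signal level
itself, and at strong activation the TCS promoter can saturate, driving the
gain toward zero from either side. The two shipped example parameter sets
separate cleanly by sign (the negative set at
$g \approx -1.6\times10^{-3}$, the positive set at positive gain an order
of magnitude larger) when the gain is evaluated at the moderate
activation level $k_{ph} = 1$ s⁻¹, which is therefore what the example-set
checks use; at $k_{ph} = 0.1$ the negative set sits in deep promoter
saturation where its gain collapses toward zero.
Survey-level sign statistics are evaluated at the standard activated level
$k_{ph} = 0.1$, where sampled sets — which span a wide range of expression
scales — show both signs robustly. Both levels are plain function arguments.

## The synthetic model population

Because the model has 21 kinetic constants and no general analytical
solution, population-level claims are evaluated on Monte Carlo samples.
`samplingIntervals()` assigns each constant a log-uniform interval spanning
from one tenth of the smaller to ten times the larger of the two shipped
example values, which guarantees both published regimes are interior points;
all intervals are overridable. `feasibilityFilter()` keeps only sets that
are physically sensible and TCS-like (seven criteria: mRNA below 100
copies/cell; mRNA decay faster than dilution; basal below regulated
transcription; more than 1 molecule/cell of induction headroom; at most
1 molecule/cell of basal RRP2 with and without feedback; basal downstream
expression insensitive to the feedback; and at least 2-fold induction of
DS, RRP2 and total RR). Feasibility rates with the default intervals are a
few percent, so a 500-set survey examines roughly 15,000 draws.

What the generator emulates is the *kinetic diversity* of TCS operating
points; what it does not emulate is everything a real cell adds on top:
stochastic gene expression, growth-rate feedback on dilution, regulatory
inputs beyond one phosphatase-modulated signal, and mRNA processing
differences between the co-transcribed genes. Passing population-level tests
therefore demonstrates properties of the deterministic model class, not
quantitative predictions for any particular organism.

The genetic algorithm (`gaEvolve`) selects parameter sets by a product of
saturating fold-change scores (`gaFitness`): 2-fold activated/resting RRP2,
2-fold total RR, and 2-fold peak-over-steady-state RRP2 (overshoot), each
contributing $\min(\mathrm{fold}/\mathrm{threshold}, 1)$. Defaults are a
population of 50, log-normal perturbations with $\sigma = 0.2$ on the
natural-log scale, top-20% truncation selection and one elite individual —
modest settings that recover a known surrogate optimum within 10% in a few
hundred generations in the test suite.

## Problem sizes used by the tests and the acceptance script

The shipped checks run a 500-set survey (seed 1) for the population claims —
overshoot occurring only under negative gain, the exogenous flux fraction of
negative-gain sets, and the Spearman correlation between SHK accumulation
over a 45-minute signal interruption and the speed-up of the second
response — plus a 200-set survey for the Circuit I/II trade-offs, and
smaller property suites (1000 random states for the stoichiometry identity,
50 sets for the open-loop fixed point, 20-point dose-response grids, $10^5$
draws for sampler uniformity). These sizes were chosen to keep sampling
error on rank correlations near ±0.04 while completing in minutes on one
core.

Population-level *magnitudes* depend on the population. With the default
reconstructed intervals the sampled sets are dominated by positive-gain
systems, many operating near promoter saturation, and the second response
time after an interruption is phospho-dominated (seconds) while the first
is transcription-dominated (hours) — so the learning correlation measures
near 0.3 rather than the ~0.6 a narrower, less saturation-prone population
yields, and the Circuit I slow-down, characteristic of negative-gain
systems, does not hold for the positive-gain majority. Mechanistic claims
(overshoot only under negative gain, negative gain only with appreciable
exogenous flux, Circuit II's narrowed induction range) are robust to the
population composition; headline correlation magnitudes are not, and should
be expected to shift under different interval choices.

## Known limitations

* The effective feedback sign near promoter saturation is a ratio of tiny
  numbers; although steady states are polished to near machine precision,
  gains of magnitude below ~$10^{-5}$ should be treated as zero (the
  `"zero"` sign label is deliberately conservative at $10^{-4}$).
* The published sampling intervals of the original study are not available;
  the default intervals here are a documented reconstruction anchored at the
  two printed example sets, so population-level statistics reproduce the
  published values only approximately.
* The linear (non-saturating) exogenous-flux variant, stochastic kinetics,
  SHK maturation intermediates and ATP-coupled SHK mechanisms are out of
  scope.
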