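---
title: "Modelling the photothermal pathway of infrared neural stimulation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling the photothermal pathway of infrared neural stimulation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

Infrared neural stimulation (INS) modulates neural activity by heating
tissue: absorbed infrared light produces a local thermal transient that
changes ion-channel kinetics and membrane capacitance without any genetic
or chemical modification of the cell. `insnet` implements a biophysical
model of this pathway — a thermally modulated Hodgkin–Huxley neuron,
short-term-plastic glutamatergic synapses, and a recurrent
excitatory/inhibitory network — plus the spike-train statistics used to
quantify dose–response behaviour. This vignette is the package's account
of the model, its assumptions, the numerical choices, and what the
simulations can and cannot show.

## The temperature-dependent neuron

The membrane obeys a single-compartment conductance-based equation
(per-area units throughout: mV, ms, mS/cm², µA/cm², µF/cm²):

$$C_m(T)\,\frac{dv_m}{dt} = -\bar g_{leak}(v_m - E_{leak})
  - \bar g_{Na} m^3 h (v_m - E_{Na}) - \bar g_K n^4 (v_m - E_K)
  + I_{ext} + I_{syn} - I_m$$

Temperature enters in three places.

**Gating kinetics.** Every opening/closing rate is multiplied by the
Q10-style factor $\varphi(T) = 3^{(T - 6.3)/10}$, unity at the 6.3 °C
reference and tripling per 10 °C. The rate functions are the classic
Traub–Miles family referenced to a kinetics threshold of −63 mV, written
with the regularised $x/(e^x - 1)$ form so they are finite at their
removable singularities (see `gating_rates()`). Because $\varphi$ cancels
in $\alpha/(\alpha+\beta)$, steady-state activation curves are
temperature-independent while every time constant shrinks as
$1/\varphi(T)$ — heating makes the channels faster, not different.

**Curie–Weiss capacitance.** Following the ferroelectric description of
the bilayer, $C_m(T) = C_0 + k/(T_c - T)$ with $C_0 = 0.824$ µF/cm²,
$k = 2.2$ µF·°C/cm², and a Curie temperature $T_c$ admissible in
31–50 °C. The default is $T_c = 50$ °C, the top of the admissible range,
which keeps every protocol used here (elevations up to +30 °C above
6.3 °C) safely below the pole; `membrane_capacitance()` refuses
temperatures at or beyond $T_c$, and `check_protocol()` screens a whole
protocol before a run.

**Thermally induced capacitive current.** A thermal transient changes
$C_m$ in time and displaces charge:
$I_m = (v_m - V_s)\,dC_m/dt \approx 3.13\times10^{-3}\,
\frac{dT}{dt}(v_m - V_s)$, with $V_s = 28$ mV the asymmetric
surface-charge potential and $dT/dt$ in °C/ms (`capacitive_current()`,
`"literal"` mode). The sign convention follows charge conservation: with
$v_m < V_s$, a rising temperature yields an inward (depolarizing)
contribution. A `"fractional"` mode reads the coefficient as a relative
capacitance change of 0.313 %/°C and multiplies by the instantaneous
$C_m$, for sensitivity studies. The capacitance law and the capacitive
current are switched independently, so either mechanism can be studied in
isolation.

### The tonic drive

With the conductances and reversal potentials above, the neuron is
intrinsically oscillatory: at zero external drive it fires tonically at
about 14 Hz. The shipped default drive is therefore a small
hyperpolarizing constant, $I_{ext} = -0.0368812$ µA/cm² (about −7.4 pA
over the 2×10⁻⁴ cm² membrane), fixed once by a calibration run so that
the baseline neuron fires with a mean inter-spike interval of 84.5 ms
(11.8 Hz), the reference tonic rhythm. The constant lives in the default
configuration and is never recomputed at run time.

### What constant heating does — and a known limitation

Under a *constant* elevated temperature (the protocol used by
`run_single_neuron()`, with an equilibration discard), the only active
pathways are $\varphi(T)$ and $C_m(T)$, since $dT/dt = 0$. In this regime
the model's firing rate is a *monotone increasing* function of the
elevation up to roughly +24 °C: +10 °C raises the rate by a few percent,
+20 °C by most of a factor of two. Beyond ≈ +24 °C full action potentials
give way to fast (hundreds of Hz) low-amplitude oscillations around a
depolarized state — spike amplitude falls continuously with temperature
(peaks near +80 mV at baseline, +26 mV at +20 °C, below −16 mV at
+30 °C), so at +30 °C nothing resembling an action potential remains and,
at the default integration step, no −20 mV upward crossings are detected.

Two consequences are worth stating plainly. First, the qualitative
*suppression* of spiking at large heating and the continuous loss of
spike amplitude are robust model behaviours. Second, a genuinely
*biphasic* rate curve peaking at a moderate elevation (+10 °C above
+20 °C) does **not** emerge from the constant-temperature pathway of this
model under the shipped defaults; we verified this across the admissible
Curie-temperature range and across integration steps down to 0.005 ms.
A biphasic ordering of that kind requires the transient pathway (the
capacitive current, active only while $dT/dt \neq 0$) or different
kinetics, and the corresponding expectations are encoded in the test
suite as red until such a mechanism is justified. The network-level
biphasic effect (below) *is* reproduced: moderate heating raises network
activity, strong heating collapses it.

## The synapse

Presynaptic release follows the Tsodyks–Markram two-variable scheme: a
docked fraction $u$ (facilitation, decay $\tau_f = 0.3$ s) and an
available fraction $x$ (depression, recovery $\tau_r = 0.5$ s). At each
presynaptic spike $u \mathrel{+}= U_0(1-u)$ *first*, then the released
fraction is $r_s = u_{after} x_{before}$, then $x \mathrel{-}= r_s$. This
jump ordering is the convention of the release framework the parameters
come from; the differential form alone does not fix it, so it is pinned
here and in the tests (first spike from rest releases exactly
$U_0 = 0.6$). Released transmitter raises the cleft concentration by
$r_s Q_c Y_T$ (1500 µM for a full first release), which clears at
$\Omega_c = 40$ s⁻¹. Receptor open fractions follow first-order binding
kinetics driven by the cleft concentration; AMPA
($\alpha = 1.1$ µM⁻¹s⁻¹, $\beta = 190$ s⁻¹, $\bar g = 0.35$ nS) and NMDA
($\alpha = 0.072$, $\beta = 6.6$, $\bar g = 0.026$ nS) currents share
$E = 0$ mV, with the NMDA conductance additionally gated by the
Jahr–Stevens magnesium block
$\mathrm{Mg}(v_m) = 1/(1 + e^{-0.062 v_m}[\mathrm{Mg}^{2+}]/3.57)$ at
1 mM.

Three interpretation choices are documented rather than silent:

* the facilitation/recovery constants 0.3 and 0.5 are *time constants in
  seconds* (their printed unit "s⁻¹" conflicts with the framework's usage);
* the NMDA maximal conductance is read in the same nS family as AMPA
  (its printed "0.026 mS" would exceed the whole-cell conductance by
  orders of magnitude); it is configurable;
* inhibitory connections use a GABA\_A channel of the same first-order
  form ($\alpha = 5$ µM⁻¹s⁻¹, $\beta = 180$ s⁻¹, $\bar g = 1$ nS,
  $E = -80$ mV). This receptor is a package addition — the glutamatergic
  model family specifies no inhibitory receptor — and is fully
  configurable.

Per-synapse currents (pA) convert to the per-area membrane equation
through the postsynaptic membrane area, 2×10⁻⁴ cm² by default.
Temperature touches the synapse only through presynaptic spike timing;
the receptor and release constants themselves are temperature-independent
here.

## The network

The default network is 3,200 excitatory and 800 inhibitory neurons (the
4:1 cortical ratio). Every ordered pair receives an edge independently
with probability 5% (excitatory source) or 20% (inhibitory source) — the
stated percentages are read as connection probabilities, not weight
scalings; separate `w_exc`/`w_inh` multipliers exist for the latter.
Neurons are embedded uniformly in the unit square for visualisation only;
connectivity is position-independent. Construction is seeded and
reproducible edge-for-edge.

The engine advances all neurons and synapses on one fixed clock:
exponential updates for gating variables (rates frozen at the step's
start), an explicit midpoint (RK2) step for the voltage, exact
exponential relaxations for $u$, $x$, cleft transmitter and receptor
states, with presynaptic spikes applied to outgoing synapses at the end
of the step in which they cross −20 mV (2 ms dead time, no axonal delay
by default). Temperature is spatially uniform. Between spikes the
presynaptic variables are relaxed lazily in closed form, which is exact
and keeps the cost proportional to active synapses.

Identical neurons with identical drive would start in exact lockstep, so
the initial membrane potentials carry a small seeded uniform jitter
(up to 5 mV below rest, gates at the corresponding steady state); this
only randomizes initial phases. Optional ±5% drive heterogeneity exists
but is off by default and off in all headline runs. Given a configuration
and seed, reruns are bit-identical.

## Numerical choices

* **Step size.** Default $dt = 0.025$ ms, chosen for the fast AMPA
  kinetics; halving it moves baseline single-neuron spike times by well
  under 0.5 ms over 2 s. At extreme heating (elevations ≳ +24 °C,
  $\varphi \gtrsim 15$) the sub-spike oscillation regime is *not*
  converged at this step — the fast micro-oscillations are numerically
  damped. Since those oscillations are not action potentials, the default
  step yields the physiologically sensible spike count (zero) there; users
  probing that regime quantitatively should reduce `dt` to ≤ 0.005 ms and
  interpret −20 mV crossings with care.
* **Protocols.** Temperature protocols are analytic; the engine samples
  $T$ and $dT/dt$ at half-step resolution so the midpoint voltage stage
  sees midpoint temperatures. Rectangular pulses get linear edge ramps
  (default 0.1 s) because the capacitive current needs finite $dT/dt$;
  the saturating kind mimics the exponential approach of continuous-wave
  heating.
* **Detection.** Spikes are upward crossings of −20 mV with a 2 ms dead
  time; the −63 mV kinetics threshold plays no role in detection.
* **Degenerate inputs.** Empty networks, spikeless trains and
  header-only outputs are all defined; ISI statistics return an explicit
  undefined marker below 2 spikes (CV below 3) rather than zero.

## What the generator emulates — and what it does not

The temperature protocols stand in for the *measured* thermal response of
irradiated tissue: rectangular-with-ramp pulses idealise switched
continuous-wave irradiation; the saturating kind matches the
rapid-rise-then-plateau curves seen in bath-heating measurements. The
package deliberately does not model the laser–tissue transduction itself
(absorption, heat diffusion, spatial gradients), photochemical or
optoacoustic effects, additional thermosensitive channels (TRP family),
or temperature shifts of the reversal potentials — for the last, an
optional `nernst_scaling = "linear"` hook scales $E_{Na}$ and $E_K$ by
the absolute-temperature ratio, off by default because it goes beyond the
core model. Passing tests on synthetic protocols
therefore demonstrate the *electrophysiological* consequences of an
imposed temperature trace, not the optics that produce it.

## Problem sizes used in the shipped checks

The packaged tests run the single neuron for up to 20.5 s windows,
synapse pairs for a few seconds, and a reduced-scale network of 400E/100I
(same 5%/20% probabilities) for 18 s under the pulse schedule +10 °C at
3–6 s, +20 °C at 9–12 s, +30 °C at 15–18 s. At that scale the network
shows the headline effect: mean population rate ≈ 5.4 Hz at baseline,
elevated during the +10 and +20 epochs, collapsed (≈ 0.2 Hz) during the
+30 epoch, and returning to baseline after each epoch. The full
3,200/800 network runs in tens of minutes on one core and behaves the
same way qualitatively.

```{r example}
library(insnet)

# single-neuron dose-response table
run_single_neuron(c(0, 10, 20, 30), window = 2)

# reduced-scale network under the default pulse schedule
net <- build_network(network_spec(400, 100, seed = 42))
sim <- run_network(net, duration = 18, seed = 7)
write_outputs(sim, "network_run")
```

## Known limitations

* The constant-temperature single-neuron dose–response is monotone up to
  breakdown (see above); a biphasic single-cell ordering with its peak at
  a moderate elevation is not reproduced by this pathway, and the
  corresponding checks are left failing by design rather than tuned away.
* The physically scaled capacitive current is small for realistic bath
  heating rates (order 10⁻³ µA/cm² at 10 °C/s); it matters for fast
  pulsed transients, not for the slow protocols shipped as defaults.
* Percent-change measures inherit the discreteness of spike counts; with
  2 s windows a single spike is ≈ 4 percentage points.
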