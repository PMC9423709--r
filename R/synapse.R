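#' Receptor kinetics parameters
#'
#' First-order receptor scheme: the open fraction r obeys
#' `dr/dt = alpha * Gs * (1 - r) - beta * r` with Gs the cleft transmitter
#' concentration.
#'
#' @param alpha Forward (binding) rate, uM^-1 s^-1.
#' @param beta Backward (unbinding) rate, s^-1.
#' @param g_max Maximal synaptic conductance, nS.
#' @param E Reversal potential, mV.
#' @return A plain list used inside [synapse_params()].
#' @export
receptor_params <- function(alpha, beta, g_max, E) {
  stopifnot(alpha >= 0, beta >= 0, g_max >= 0)
  list(alpha = alpha, beta = beta, g_max = g_max, E = E)
}

#' Synapse model parameters
#'
#' Tsodyks-Markram short-term presynaptic dynamics plus cleft transmitter
#' and receptor kinetics. Concentrations are carried internally in uM.
#'
#' @param U0 Resting release probability (increment of the docked fraction
#'   per spike), dimensionless in (0, 1].
#' @param tau_f Facilitation decay time constant, seconds: between spikes
#'   the docked fraction u relaxes to 0 at rate `1/tau_f`.
#' @param tau_r Recovery time constant, seconds: the available fraction x
#'   relaxes to 1 at rate `1/tau_r`.
#' @param Omega_c Cleft transmitter clearance rate, s^-1.
#' @param Q_c Vesicular-to-mixing volume ratio, dimensionless.
#' @param Y_T Total vesicular transmitter concentration, mM. A release of
#'   fraction `r_s` raises the cleft concentration by `r_s * Q_c * Y_T`
#'   (1500 uM for a full-resource first spike with the defaults).
#' @param ampa,nmda,gaba [receptor_params()] for each receptor class.
#'   AMPA and NMDA defaults follow the glutamatergic scheme
#'   (NMDA conductance read in the same nS family as AMPA); the GABA-A
#'   channel is a package addition for inhibitory connections, using the
#'   same first-order kinetics.
#' @param mg_conc Extracellular magnesium concentration, mM (NMDA block).
#' @param membrane_area Postsynaptic membrane area, cm^2, used to convert
#'   per-synapse currents (pA) into the per-area membrane equation
#'   (uA/cm^2).
#' @return An object of class `synapse_params`.
#' @export
synapse_params <- function(U0 = 0.6, tau_f = 0.3, tau_r = 0.5,
                           Omega_c = 40, Q_c = 0.005, Y_T = 500,
                           ampa = receptor_params(1.1, 190, 0.35, 0),
                           nmda = receptor_params(0.072, 6.6, 0.026, 0),
                           gaba = receptor_params(5, 180, 1, -80),
                           mg_conc = 1, membrane_area = 2e-4) {
  stopifnot(U0 > 0, U0 <= 1, tau_f > 0, tau_r > 0, Omega_c >= 0,
            Q_c >= 0, Y_T >= 0, mg_conc >= 0, membrane_area > 0)
  structure(list(U0 = U0, tau_f = tau_f, tau_r = tau_r, Omega_c = Omega_c,
                 Q_c = Q_c, Y_T = Y_T, ampa = ampa, nmda = nmda,
                 gaba = gaba, mg_conc = mg_conc,
                 membrane_area = membrane_area),
            class = "synapse_params")
}

#' Resting synapse state
#'
#' @param params A [synapse_params()] object (unused, kept for symmetry).
#' @return A list with `u` (docked fraction, 0), `x` (available fraction,
#'   1), `Gs` (cleft transmitter, uM, 0) and `r` (named open fractions,
#'   all 0).
#' @export
synapse_state <- function(params = synapse_params()) {
  list(u = 0, x = 1, Gs = 0, r = c(ampa = 0, nmda = 0, gaba = 0))
}

#' Apply a presynaptic spike to the synapse
#'
#' Jump rules at a spike time: the docked fraction is incremented first,
#' `u <- u + U0 (1 - u)`; the released fraction is the product of the
#' post-jump u and the pre-jump x, `r_s = u * x`; the available pool is
#' depleted, `x <- x - r_s`; and the cleft concentration jumps by
#' `r_s * Q_c * Y_T` (converted from mM to uM).
#'
#' @param state A [synapse_state()] list.
#' @param params A [synapse_params()] object.
#' @return The updated state with an extra element `r_s`, the released
#'   fraction of transmitter resources for this spike.
#' @export
syn_spike <- function(state, params = synapse_params()) {
  u_new <- state$u + params$U0 * (1 - state$u)
  r_s <- u_new * state$x
  state$u <- u_new
  state$x <- state$x - r_s
  state$Gs <- state$Gs + r_s * params$Q_c * params$Y_T * 1000  # mM -> uM
  state$r_s <- r_s
  state
}

#' Inter-spike relaxation of the presynaptic variables
#'
#' Exact exponential updates (not Euler): u decays toward 0 with time
#' constant `tau_f` and x recovers toward 1 with time constant `tau_r`.
#'
#' @param state A [synapse_state()] list.
#' @param dt Elapsed time, ms.
#' @param params A [synapse_params()] object.
#' @return The updated state.
#' @export
syn_decay <- function(state, dt, params = synapse_params()) {
  stopifnot(dt > 0)
  state$u <- state$u * exp(-dt / (params$tau_f * 1000))
  state$x <- 1 - (1 - state$x) * exp(-dt / (params$tau_r * 1000))
  state
}

#' Cleft transmitter clearance
#'
#' First-order decay of the cleft concentration at rate `Omega_c` between
#' release events (exact exponential update).
#'
#' @param Gs Cleft transmitter concentration, uM.
#' @param dt Elapsed time, ms.
#' @param params A [synapse_params()] object.
#' @return Updated concentration, uM.
#' @export
cleft_update <- function(Gs, dt, params = synapse_params()) {
  stopifnot(dt > 0)
  Gs * exp(-params$Omega_c * dt / 1000)
}

#' Receptor open-fraction update
#'
#' With the cleft concentration held at `Gs` over the step, the open
#' fraction relaxes exactly toward `r_inf = alpha Gs / (alpha Gs + beta)`
#' at rate `alpha Gs + beta`; the update keeps r in `[0, 1]`.
#'
#' @param r Current open fraction.
#' @param Gs Cleft transmitter concentration over the step, uM.
#' @param dt Step, ms.
#' @param receptor A [receptor_params()] list.
#' @return Updated open fraction.
#' @export
receptor_update <- function(r, Gs, dt, receptor) {
  stopifnot(dt > 0)
  rate <- (receptor$alpha * Gs + receptor$beta) / 1000   # ms^-1
  if (rate == 0) return(r)
  r_inf <- receptor$alpha * Gs / (receptor$alpha * Gs + receptor$beta)
  r_inf + (r - r_inf) * exp(-rate * dt)
}

#' Voltage-dependent magnesium block of the NMDA receptor
#'
#' `Mg(vm) = 1 / (1 + exp(-0.062 vm) [Mg2+] / 3.57)`, a sigmoid increasing
#' from 0 (hyperpolarized, pore blocked) to 1 (depolarized, unblocked).
#'
#' @param vm Membrane potential, mV (vectorised).
#' @param mg_conc Magnesium concentration, mM.
#' @return Unblocked fraction in (0, 1).
#' @export
mg_block <- function(vm, mg_conc = 1) {
  1 / (1 + exp(-0.062 * vm) * mg_conc / 3.57)
}

#' Postsynaptic receptor current
#'
#' `I = g_max * r * (vm - E)` (NMDA additionally multiplied by the
#' magnesium unblock factor). Positive values are outward; an EPSC at a
#' hyperpolarized potential is negative (inward). In the membrane equation
#' this current enters with a minus sign so that inward currents
#' depolarize.
#'
#' @param type One of `"ampa"`, `"nmda"`, `"gaba"`.
#' @param r Open fraction.
#' @param vm Postsynaptic membrane potential, mV.
#' @param params A [synapse_params()] object.
#' @param per_area If `TRUE`, also convert to uA/cm^2 via `membrane_area`.
#' @return A list with `pA` (per-synapse current) and, if requested,
#'   `uA_cm2`.
#' @export
postsyn_current <- function(type, r, vm, params = synapse_params(),
                            per_area = TRUE) {
  rec <- switch(type,
                ampa = params$ampa,
                nmda = params$nmda,
                gaba = params$gaba,
                stop("unknown receptor kind '", type,
                     "'; expected ampa, nmda or gaba"))
  i_pA <- rec$g_max * r * (vm - rec$E)       # nS * mV = pA
  if (type == "nmda") i_pA <- i_pA * mg_block(vm, params$mg_conc)
  out <- list(pA = i_pA)
  if (per_area)
    out$uA_cm2 <- i_pA * 1e-6 / params$membrane_area
  out
}
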