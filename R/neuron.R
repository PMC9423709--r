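#' Neuron model parameters
#'
#' Constants of the single-compartment thermally modulated Hodgkin-Huxley
#' neuron. All quantities follow the per-area convention (mS/cm^2, uA/cm^2,
#' uF/cm^2, mV, ms).
#'
#' @param g_leak,g_Na,g_K Maximal leak / sodium / potassium conductances,
#'   mS/cm^2.
#' @param E_leak,E_Na,E_K Reversal potentials, mV.
#' @param V_th Kinetics reference threshold, mV. The gating rate formulas
#'   are referenced to this value; it is not used for spike detection.
#' @param V_rest Resting potential, mV (initial condition).
#' @param I_ext Tonic external drive, uA/cm^2. The shipped default was
#'   fixed by a one-time calibration so that the neuron at reference
#'   temperature fires tonically with a mean inter-spike interval of about
#'   84.5 ms.
#' @param V_detect Spike-detection level, mV (upward crossing).
#' @param dead_time Spike-detection dead time, ms.
#' @param nernst_scaling `"off"` (default) or `"linear"`: optionally scale
#'   `E_Na` and `E_K` by the absolute-temperature ratio
#'   `(T + 273.15)/(T_ref + 273.15)` during simulation. Off by default;
#'   this hook goes beyond the core model.
#' @return An object of class `neuron_params`.
#' @export
neuron_params <- function(g_leak = 0.05, g_Na = 50, g_K = 30,
                          E_leak = -60, E_Na = 90, E_K = -85,
                          V_th = -63, V_rest = -70,
                          I_ext = -0.0368812, V_detect = -20, dead_time = 2,
                          nernst_scaling = c("off", "linear")) {
  nernst_scaling <- match.arg(nernst_scaling)
  stopifnot(g_leak >= 0, g_Na >= 0, g_K >= 0, dead_time >= 0)
  if (!(E_K < E_leak && E_leak < 0 && 0 < E_Na))
    stop("reversal potentials must satisfy E_K < E_leak < 0 < E_Na")
  structure(list(g_leak = g_leak, g_Na = g_Na, g_K = g_K,
                 E_leak = E_leak, E_Na = E_Na, E_K = E_K,
                 V_th = V_th, V_rest = V_rest, I_ext = I_ext,
                 V_detect = V_detect, dead_time = dead_time,
                 nernst_scaling = nernst_scaling),
            class = "neuron_params")
}

# x/(e^x - 1) evaluated stably; equals 1 at x = 0.  This is 1/exprel(x) and
# regularises the linear-over-expm1 gating rates at their removable
# singularity.
inv_exprel <- function(x) {
  out <- ifelse(abs(x) < 1e-8, 1 - x / 2, x / expm1(x))
  out
}

#' Voltage- and temperature-dependent gating rates
#'
#' Opening/closing rates for the potassium activation gate n, sodium
#' activation gate m and sodium inactivation gate h, each multiplied by the
#' temperature factor `phi(T)`. The linear-over-exponential rates use the
#' regularised form `x/(e^x - 1)` so they are finite for every membrane
#' potential:
#'
#' * `alpha_n = 0.032 phi (vm+48) / (1 - exp(-(vm+48)/5))`
#' * `beta_n  = 0.5   phi exp((-53 - vm)/40)`
#' * `alpha_m = 0.32  phi (vm+50) / (1 - exp(-(vm+50)/4))`
#' * `beta_m  = 0.28  phi (vm+23) / (exp((vm+23)/5) - 1)`
#' * `alpha_h = 0.128 phi exp((-46 - vm)/18)`
#' * `beta_h  = 4     phi / (1 + exp((-23 - vm)/5))`
#'
#' All voltage offsets are referenced to the kinetics threshold
#' `V_th = -63` mV.
#'
#' @param vm Membrane potential, mV (vectorised).
#' @param T Temperature, degC.
#' @param thermal A [thermal_params()] object (supplies `phi`).
#' @return A data.frame with columns `alpha_n, beta_n, alpha_m, beta_m,
#'   alpha_h, beta_h`, all in ms^-1.
#' @export
gating_rates <- function(vm, T = 6.3, thermal = thermal_params()) {
  ph <- phi(T, thermal)
  data.frame(
    alpha_n = 0.032 * ph * 5 * inv_exprel((-48 - vm) / 5),
    beta_n  = 0.5 * ph * exp((-53 - vm) / 40),
    alpha_m = 0.32 * ph * 4 * inv_exprel((-50 - vm) / 4),
    beta_m  = 0.28 * ph * 5 * inv_exprel((vm + 23) / 5),
    alpha_h = 0.128 * ph * exp((-46 - vm) / 18),
    beta_h  = 4 * ph / (1 + exp((-23 - vm) / 5))
  )
}

#' Gating steady states and time constants
#'
#' `x_inf = alpha/(alpha + beta)` and `tau_x = 1/(alpha + beta)` for each
#' gate. The temperature factor cancels in `x_inf`, so steady states are
#' temperature-independent, while every time constant scales as
#' `1/phi(T)`.
#'
#' @inheritParams gating_rates
#' @return A data.frame with columns `m_inf, n_inf, h_inf` (dimensionless)
#'   and `tau_m, tau_n, tau_h` (ms).
#' @export
gating_steady <- function(vm, T = 6.3, thermal = thermal_params()) {
  r <- gating_rates(vm, T, thermal)
  data.frame(
    m_inf = r$alpha_m / (r$alpha_m + r$beta_m),
    n_inf = r$alpha_n / (r$alpha_n + r$beta_n),
    h_inf = r$alpha_h / (r$alpha_h + r$beta_h),
    tau_m = 1 / (r$alpha_m + r$beta_m),
    tau_n = 1 / (r$alpha_n + r$beta_n),
    tau_h = 1 / (r$alpha_h + r$beta_h)
  )
}

#' Initial neuron state
#'
#' Membrane potential at `V_rest` with gates at their steady-state values
#' for that potential.
#'
#' @param params A [neuron_params()] object.
#' @param T Temperature, degC (irrelevant to the steady states, kept for
#'   symmetry).
#' @return A named list with elements `vm, m, n, h`.
#' @export
neuron_state <- function(params = neuron_params(), T = 6.3) {
  ss <- gating_steady(params$V_rest, T)
  list(vm = params$V_rest, m = ss$m_inf, n = ss$n_inf, h = ss$h_inf)
}

# reversal potentials after the optional Nernst temperature scaling
effective_reversals <- function(params, T, T_ref) {
  if (params$nernst_scaling == "linear") {
    s <- (T + 273.15) / (T_ref + 273.15)
    list(E_Na = params$E_Na * s, E_K = params$E_K * s)
  } else {
    list(E_Na = params$E_Na, E_K = params$E_K)
  }
}

#' Membrane equation right-hand side
#'
#' Time derivatives of the thermally modulated Hodgkin-Huxley state:
#'
#' `Cm(T) dvm/dt = -g_leak (vm - E_leak) - g_Na m^3 h (vm - E_Na)
#'                 - g_K n^4 (vm - E_K) + I_ext + I_syn - Im`
#'
#' with `Cm(T)` the Curie-Weiss capacitance and `Im` the thermally induced
#' capacitive current (charge-conservation form `d[Cm (vm - Vs)]/dt`): a
#' rising temperature with `vm < Vs` yields `Im < 0`, hence `-Im`
#' depolarizes. Gates follow `dx/dt = alpha_x (1 - x) - beta_x x`.
#'
#' @param state A list with `vm, m, n, h` (see [neuron_state()]).
#' @param T Temperature, degC (must be below the Curie temperature).
#' @param dT_dt Temperature ramp rate, degC/ms.
#' @param I_syn Synaptic current, uA/cm^2 (positive depolarizes; the
#'   receptor-current sign flip is the caller's responsibility).
#' @param params A [neuron_params()] object.
#' @param thermal A [thermal_params()] object.
#' @return A named list `dvm, dm, dn, dh` (mV/ms and ms^-1).
#' @export
membrane_rhs <- function(state, T = 6.3, dT_dt = 0, I_syn = 0,
                         params = neuron_params(),
                         thermal = thermal_params()) {
  Cm <- membrane_capacitance(T, thermal)
  Im <- capacitive_current(state$vm, dT_dt, thermal, Cm)
  rev <- effective_reversals(params, T, thermal$T_ref)
  i_ion <- -params$g_leak * (state$vm - params$E_leak) -
    params$g_Na * state$m^3 * state$h * (state$vm - rev$E_Na) -
    params$g_K * state$n^4 * (state$vm - rev$E_K)
  r <- gating_rates(state$vm, T, thermal)
  list(dvm = (i_ion + params$I_ext + I_syn - Im) / Cm,
       dm = r$alpha_m * (1 - state$m) - r$beta_m * state$m,
       dn = r$alpha_n * (1 - state$n) - r$beta_n * state$n,
       dh = r$alpha_h * (1 - state$h) - r$beta_h * state$h)
}
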