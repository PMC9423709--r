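# Experiment runners: thin R orchestration over the compiled integrators.
# All runners share the fixed-clock scheme (exponential gate update, RK2
# midpoint voltage step) and sample the temperature protocol analytically
# at half-step resolution.

sample_protocol_half <- function(protocol, duration_s, dt_ms) {
  n_steps <- round(duration_s * 1000 / dt_ms)
  t_half <- seq(0, by = dt_ms / 2000, length.out = 2 * n_steps + 1)
  ev <- protocol_eval(protocol, t_half)
  list(n_steps = n_steps, T = ev$T_degC, dTdt = ev$dT_dt_degC_ms)
}

#' Simulate one isolated neuron under a temperature protocol
#'
#' Integrates the thermally modulated Hodgkin-Huxley neuron with tonic
#' drive `I_ext` under an arbitrary temperature protocol.
#'
#' @param duration Run duration, seconds.
#' @param protocol A [temperature_protocol()]; default constant at the
#'   reference temperature.
#' @param neuron A [neuron_params()] object.
#' @param thermal A [thermal_params()] object.
#' @param dt Integration step, ms (default 0.025).
#' @param record Record the voltage/gate trace (default `FALSE`).
#' @return A list of class `insnet_sim` with `spikes` (spike times,
#'   seconds), optional `trace` (data.frame `time_s, vm_mV, m, n, h`), and
#'   `metadata`.
#' @export
simulate_neuron <- function(duration, protocol = NULL,
                            neuron = neuron_params(),
                            thermal = thermal_params(), dt = 0.025,
                            record = FALSE) {
  stopifnot(duration > 0, dt > 0)
  if (is.null(protocol))
    protocol <- temperature_protocol("constant", baseline = thermal$T_ref)
  check_protocol(protocol, thermal, duration)
  ph <- sample_protocol_half(protocol, duration, dt)
  st <- neuron_state(neuron)
  res <- cpp_sim_neuron(ph$T, ph$dTdt, dt, ph$n_steps, neuron, thermal,
                        neuron$I_ext, st$vm, st$m, st$n, st$h, record)
  out <- list(spikes = res$spikes_ms / 1000,
              metadata = list(duration_s = duration, dt_ms = dt,
                              protocol = unclass(protocol),
                              neuron = unclass(neuron),
                              thermal = unclass(thermal)))
  if (record) {
    out$trace <- data.frame(
      time_s = seq(0, by = dt / 1000, length.out = ph$n_steps + 1),
      vm_mV = res$trace$vm, m = res$trace$m, n = res$trace$n,
      h = res$trace$h)
  }
  class(out) <- "insnet_sim"
  out
}

#' Single-neuron temperature dose-response
#'
#' Runs one isolated tonically driven neuron at a set of constant
#' temperature elevations and tabulates spike counts and mean rates over a
#' recording window. Each run is held at `T_ref + dT` throughout; the
#' first `discard` seconds are dropped so the counts reflect the
#' equilibrated rhythm.
#'
#' @param dT_values Temperature elevations above the reference, degC.
#' @param window Recording window length, seconds (after the discard).
#' @param discard Equilibration time discarded at the start, seconds.
#' @param neuron,thermal,dt As in [simulate_neuron()].
#' @return A data.frame with columns `dT`, `n_spikes`, `rate_hz`,
#'   `mean_isi_ms`, `cv_isi` and attribute `spikes` (list of spike-time
#'   vectors within the window).
#' @examples
#' \donttest{
#' run_single_neuron(c(0, 10, 20, 30), window = 2)
#' }
#' @export
run_single_neuron <- function(dT_values = c(0, 10, 20, 30), window = 2,
                              discard = 0.5, neuron = neuron_params(),
                              thermal = thermal_params(), dt = 0.025) {
  stopifnot(window > 0, discard >= 0)
  spikes_list <- vector("list", length(dT_values))
  rows <- lapply(seq_along(dT_values), function(i) {
    dT <- dT_values[i]
    prot <- temperature_protocol("constant",
                                 baseline = thermal$T_ref + dT)
    sim <- simulate_neuron(discard + window, prot, neuron, thermal, dt)
    sp <- sim$spikes[sim$spikes > discard]
    spikes_list[[i]] <<- sp - discard
    st <- isi_stats(spike_train(sp, c(discard, discard + window)))
    data.frame(dT = dT, n_spikes = length(sp),
               rate_hz = length(sp) / window,
               mean_isi_ms = if (is.null(st)) NA_real_ else st$mean_isi_ms,
               cv_isi = if (is.null(st) || is.na(st$cv)) NA_real_ else st$cv)
  })
  out <- do.call(rbind, rows)
  attr(out, "spikes") <- spikes_list
  attr(out, "window_s") <- window
  out
}

#' Synapse-pair experiment
#'
#' One thermally modulated presynaptic neuron drives a single
#' glutamatergic (AMPA + NMDA) synapse onto a voltage-clamped postsynaptic
#' compartment. Temperature modulates the synapse only through the
#' presynaptic spike timing.
#'
#' @param dT Constant temperature elevation, degC.
#' @param duration Run duration, seconds.
#' @param v_clamp Postsynaptic clamp level, mV (default the neuron's
#'   resting potential).
#' @param neuron,thermal,dt As in [simulate_neuron()].
#' @param synapse A [synapse_params()] object.
#' @return A list with `events` (data.frame `time_s`, `r_s`: one row per
#'   presynaptic release), `epsc` (data.frame `time_s`, `epsc_pA`,
#'   `Gs_uM`), and `presyn_spikes` (seconds).
#' @export
run_synapse_pair <- function(dT = 0, duration = 10, v_clamp = NULL,
                             neuron = neuron_params(),
                             synapse = synapse_params(),
                             thermal = thermal_params(), dt = 0.025) {
  stopifnot(duration > 0)
  if (is.null(v_clamp)) v_clamp <- neuron$V_rest
  prot <- temperature_protocol("constant", baseline = thermal$T_ref + dT)
  pre <- simulate_neuron(duration, prot, neuron, thermal, dt)
  n_steps <- round(duration * 1000 / dt)
  syn <- cpp_sim_synapse(pre$spikes * 1000, dt, n_steps, synapse, v_clamp)
  list(events = data.frame(time_s = syn$event_t_ms / 1000,
                           r_s = syn$event_r_s),
       epsc = data.frame(time_s = seq(0, by = dt / 1000,
                                      length.out = n_steps + 1),
                         epsc_pA = syn$epsc_pA, Gs_uM = syn$Gs_uM),
       presyn_spikes = pre$spikes)
}

#' Simulate the recurrent network
#'
#' Co-integrates all neurons and synapses on a shared clock under a
#' spatially uniform temperature protocol. Temperature acts on every
#' neuron through the gating kinetics, the Curie-Weiss capacitance and the
#' capacitive current; synapses feel it through presynaptic spike timing.
#' Presynaptic spikes reach their outgoing synapses at the end of the step
#' in which they are detected (no axonal delay).
#'
#' @param network An [build_network()] result.
#' @param duration Run duration, seconds.
#' @param protocol A [temperature_protocol()]; defaults to the
#'   rectangular-pulse stimulus schedule `+10` degC at 3-6 s, `+20` at
#'   9-12 s, `+30` at 15-18 s over the reference baseline.
#' @param neuron,synapse,thermal,dt As in the other runners.
#' @param seed Integer seed for the run (initial-phase jitter and optional
#'   drive heterogeneity).
#' @param v_init_jitter Width (mV) of the uniform negative jitter applied
#'   to initial membrane potentials so that identical neurons do not start
#'   in exact lockstep (default 5 mV; set 0 to disable).
#' @param drive_heterogeneity Relative half-width of seeded per-neuron
#'   tonic-drive variation (e.g. 0.05 for +/-5%); 0 (default) gives an
#'   identical drive to every neuron.
#' @param w_exc,w_inh Dimensionless weight scalings of the excitatory /
#'   inhibitory conductances (default 1).
#' @param record Indices of neurons whose voltage traces to record.
#' @param rate_bin Width of the population-rate bins, seconds.
#' @return A list of class `insnet_sim` with `spikes` (data.frame
#'   `neuron`, `time_s`, `population`), `rate` (data.frame `t_s`,
#'   `rate_hz`: population mean rate), optional `traces`, and `metadata`.
#' @export
run_network <- function(network, duration = 18, protocol = NULL,
                        neuron = neuron_params(),
                        synapse = synapse_params(),
                        thermal = thermal_params(), dt = 0.025,
                        seed = 1L, v_init_jitter = 5,
                        drive_heterogeneity = 0, w_exc = 1, w_inh = 1,
                        record = integer(0), rate_bin = 0.05) {
  stopifnot(inherits(network, "insnet_network"), duration > 0)
  if (is.null(protocol))
    protocol <- temperature_protocol(
      "rectangular", baseline = thermal$T_ref,
      segments = list(c(3, 6, 10), c(9, 12, 20), c(15, 18, 30)))
  check_protocol(protocol, thermal, duration)
  n <- network$n
  ph <- sample_protocol_half(protocol, duration, dt)

  old_seed <- if (exists(".Random.seed", .GlobalEnv)) .Random.seed else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         .GlobalEnv))
  set.seed(as.integer(seed))
  v0 <- rep(neuron$V_rest, n) - stats::runif(n, 0, v_init_jitter)
  ss <- gating_steady(v0)
  i_ext <- rep(neuron$I_ext, n)
  if (drive_heterogeneity > 0)
    i_ext <- i_ext * stats::runif(n, 1 - drive_heterogeneity,
                                  1 + drive_heterogeneity)

  if (n == 0) {
    res <- list(neuron = integer(0), time_ms = numeric(0))
  } else {
    res <- cpp_sim_network(ph$T, ph$dTdt, dt, ph$n_steps, neuron, thermal,
                           synapse, i_ext,
                           as.integer(network$edges$pre - 1L),
                           as.integer(network$edges$post - 1L),
                           network$edges$exc, w_exc, w_inh,
                           v0, ss$m_inf, ss$n_inf, ss$h_inf,
                           as.integer(record - 1L))
  }
  spikes <- data.frame(neuron = res$neuron, time_s = res$time_ms / 1000)
  spikes$population <- as.character(network$type[spikes$neuron])
  rate <- population_rate(spikes$time_s, n_neurons = max(n, 1),
                          bin = rate_bin, window = c(0, duration))
  out <- list(spikes = spikes, rate = rate,
              metadata = list(duration_s = duration, dt_ms = dt,
                              seed = as.integer(seed),
                              n_exc = network$spec$n_exc,
                              n_inh = network$spec$n_inh,
                              v_init_jitter_mV = v_init_jitter,
                              drive_heterogeneity = drive_heterogeneity,
                              w_exc = w_exc, w_inh = w_inh,
                              protocol = unclass(protocol),
                              neuron = unclass(neuron),
                              synapse = unclass(synapse),
                              thermal = unclass(thermal)))
  if (length(record) > 0) {
    tr <- as.data.frame(res$traces)
    names(tr) <- paste0("neuron_", record)
    tr <- cbind(time_s = seq(0, by = dt / 1000, length.out = ph$n_steps + 1),
                tr)
    out$traces <- tr
  }
  class(out) <- "insnet_sim"
  out
}

#' @export
print.insnet_sim <- function(x, ...) {
  if (is.data.frame(x$spikes)) {
    cat("network simulation:", nrow(x$spikes), "spikes from",
        length(unique(x$spikes$neuron)), "neurons over",
        x$metadata$duration_s, "s\n")
  } else {
    cat("single-neuron simulation:", length(x$spikes), "spikes over",
        x$metadata$duration_s, "s\n")
  }
  invisible(x)
}
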