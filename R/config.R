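# Configuration handling: a single nested list mirrors every module's
# parameters, fully defaulted to the model's reference values. Unknown
# keys are rejected so typos cannot silently fall back to defaults.

#' Default run configuration
#'
#' The fully materialised configuration with every parameter at its
#' default value: the reference neuron and synapse constants, the
#' 3200E/800I network with 5%/20% connectivity, and the rectangular-pulse
#' stimulus schedule (+10 degC at 3-6 s, +20 at 9-12 s, +30 at 15-18 s).
#'
#' @return A nested named list with sections `thermal`, `neuron`,
#'   `synapse`, `network`, `protocol`, `sim` and `analysis`.
#' @export
default_config <- function() {
  list(
    thermal = list(t_ref = 6.3, q_base = 3, c0 = 0.824, k = 2.2, tc = 50,
                   vs = 28, cap_coeff = 3.13e-3, cap_mode = "literal"),
    neuron = list(g_leak = 0.05, g_na = 50, g_k = 30, e_leak = -60,
                  e_na = 90, e_k = -85, v_th = -63, v_rest = -70,
                  i_ext = neuron_params()$I_ext, v_detect = -20,
                  dead_time_ms = 2, nernst_scaling = "off"),
    synapse = list(u0 = 0.6, tau_f_s = 0.3, tau_r_s = 0.5, omega_c = 40,
                   q_c = 0.005, y_t_mM = 500,
                   ampa = list(alpha = 1.1, beta = 190, g_max = 0.35, e = 0),
                   nmda = list(alpha = 0.072, beta = 6.6, g_max = 0.026,
                               e = 0),
                   gaba = list(alpha = 5, beta = 180, g_max = 1, e = -80),
                   mg_mM = 1, membrane_area_cm2 = 2e-4),
    network = list(n_exc = 3200, n_inh = 800, p_exc = 0.05, p_inh = 0.20,
                   allow_self = FALSE, seed = 1),
    protocol = list(kind = "rectangular", baseline_dT = 0,
                    segments = list(c(3, 6, 10), c(9, 12, 20),
                                    c(15, 18, 30)),
                    edge_ramp_s = 0.1, tau_s = 0.5),
    sim = list(dt_ms = 0.025, duration_s = 18, seed = 1,
               v_init_jitter_mV = 5, drive_heterogeneity = 0,
               w_exc = 1, w_inh = 1),
    analysis = list(window_s = 2, discard_s = 0.5, rate_bin_s = 0.05)
  )
}

merge_config <- function(defaults, user, path = "") {
  if (!is.list(user)) stop("config section '", path, "' must be a mapping")
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown))
    stop("unknown config key", if (length(unknown) > 1) "s", ": ",
         paste0(path, unknown, collapse = ", "))
  for (key in names(user)) {
    full <- paste0(path, key)
    if (is.list(defaults[[key]]) && !is.null(names(defaults[[key]])) &&
        full != "protocol.segments") {
      defaults[[key]] <- merge_config(defaults[[key]], user[[key]],
                                      paste0(full, "."))
    } else {
      defaults[[key]] <- user[[key]]
    }
  }
  defaults
}

validate_config <- function(cfg) {
  # constructors carry the range checks; building them validates the config
  tp <- as_thermal_params(cfg)
  as_neuron_params(cfg)
  as_synapse_params(cfg)
  as_network_spec(cfg)
  prot <- protocol_from_config(cfg)
  if (cfg$sim$dt_ms <= 0) stop("sim.dt_ms must be positive")
  if (cfg$sim$duration_s <= 0) stop("sim.duration_s must be positive")
  check_protocol(prot, tp, cfg$sim$duration_s)
  invisible(cfg)
}

#' Load and validate a run configuration
#'
#' Reads a YAML (or JSON, a YAML subset) document, overlays it on
#' [default_config()], rejects unknown keys, and validates every range
#' constraint. An empty document yields the full default configuration.
#'
#' @param path Path to a YAML config file (ignored when `text` given).
#' @param text Literal YAML text.
#' @return The fully resolved configuration list.
#' @export
load_config <- function(path = NULL, text = NULL) {
  user <- if (!is.null(text)) yaml::yaml.load(text)
          else if (!is.null(path)) yaml::read_yaml(path)
          else NULL
  cfg <- default_config()
  if (!is.null(user)) cfg <- merge_config(cfg, user)
  validate_config(cfg)
  cfg
}

#' @rdname load_config
#' @param cfg A configuration list.
#' @export
as_thermal_params <- function(cfg) {
  th <- cfg$thermal
  thermal_params(T_ref = th$t_ref, q_base = th$q_base, C0 = th$c0,
                 k = th$k, Tc = th$tc, Vs = th$vs,
                 cap_coeff = th$cap_coeff, cap_mode = th$cap_mode)
}

#' @rdname load_config
#' @export
as_neuron_params <- function(cfg) {
  ne <- cfg$neuron
  neuron_params(g_leak = ne$g_leak, g_Na = ne$g_na, g_K = ne$g_k,
                E_leak = ne$e_leak, E_Na = ne$e_na, E_K = ne$e_k,
                V_th = ne$v_th, V_rest = ne$v_rest, I_ext = ne$i_ext,
                V_detect = ne$v_detect, dead_time = ne$dead_time_ms,
                nernst_scaling = ne$nernst_scaling)
}

#' @rdname load_config
#' @export
as_synapse_params <- function(cfg) {
  sy <- cfg$synapse
  rp <- function(x) receptor_params(x$alpha, x$beta, x$g_max, x$e)
  synapse_params(U0 = sy$u0, tau_f = sy$tau_f_s, tau_r = sy$tau_r_s,
                 Omega_c = sy$omega_c, Q_c = sy$q_c, Y_T = sy$y_t_mM,
                 ampa = rp(sy$ampa), nmda = rp(sy$nmda),
                 gaba = rp(sy$gaba), mg_conc = sy$mg_mM,
                 membrane_area = sy$membrane_area_cm2)
}

#' @rdname load_config
#' @export
as_network_spec <- function(cfg) {
  nw <- cfg$network
  network_spec(n_exc = nw$n_exc, n_inh = nw$n_inh, p_exc = nw$p_exc,
               p_inh = nw$p_inh, allow_self = isTRUE(nw$allow_self),
               seed = nw$seed)
}

#' @rdname load_config
#' @export
protocol_from_config <- function(cfg) {
  pr <- cfg$protocol
  baseline <- cfg$thermal$t_ref + pr$baseline_dT
  temperature_protocol(kind = pr$kind, baseline = baseline,
                       segments = pr$segments,
                       edge_ramp = pr$edge_ramp_s, tau = pr$tau_s)
}
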