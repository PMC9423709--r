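#' Thermal biophysics parameters
#'
#' Bundles every constant of the temperature-dependent membrane physics:
#' the Q10-style rate multiplier phi(T), the Curie-Weiss capacitance law,
#' and the thermally induced capacitive (displacement) current.
#'
#' @param T_ref Reference temperature in degrees C at which `phi(T) == 1`.
#' @param q_base Dimensionless base of the Q10-style factor
#'   `phi(T) = q_base^((T - T_ref)/10)`.
#' @param C0 Baseline membrane capacitance, uF/cm^2.
#' @param k Curie constant of the capacitance law, uF * degC / cm^2.
#' @param Tc Curie temperature in degrees C; the capacitance
#'   `C0 + k/(Tc - T)` diverges as `T` approaches `Tc` from below. The
#'   physiologically admissible range is 31-50 degrees C; values outside it
#'   are accepted but flagged with a warning.
#' @param Vs Asymmetric surface-charge potential, mV. The capacitive current
#'   vanishes when the membrane potential equals `Vs`.
#' @param cap_coeff Capacitive-current coefficient, uF/(cm^2 * degC). In
#'   `"literal"` mode the current is `cap_coeff * dT/dt * (vm - Vs)`.
#' @param cap_mode Either `"literal"` (absolute coefficient) or
#'   `"fractional"` (coefficient read as fractional capacitance change per
#'   degree C, multiplying the instantaneous capacitance).
#'
#' @return An object of class `thermal_params`.
#' @examples
#' tp <- thermal_params()
#' phi(16.3, tp)               # 3: one decade above reference
#' membrane_capacitance(6.3, tp)
#' @export
thermal_params <- function(T_ref = 6.3, q_base = 3, C0 = 0.824, k = 2.2,
                           Tc = 50, Vs = 28, cap_coeff = 3.13e-3,
                           cap_mode = c("literal", "fractional")) {
  cap_mode <- match.arg(cap_mode)
  stopifnot(C0 > 0, k >= 0, cap_coeff >= 0, q_base > 0)
  if (Tc <= T_ref)
    stop("Curie temperature Tc (", Tc, ") must exceed T_ref (", T_ref, ")")
  if (Tc < 31 || Tc > 50)
    warning("Tc = ", Tc,
            " degC lies outside the admissible Curie range 31-50 degC")
  structure(list(T_ref = T_ref, q_base = q_base, C0 = C0, k = k, Tc = Tc,
                 Vs = Vs, cap_coeff = cap_coeff, cap_mode = cap_mode),
            class = "thermal_params")
}

#' Temperature factor for gating kinetics
#'
#' The multiplicative Q10-style scaling applied to every channel opening and
#' closing rate: `phi(T) = q_base^((T - T_ref)/10)`, equal to 1 at the
#' reference temperature and multiplied by `q_base` for every 10 degC rise.
#'
#' @param T Temperature, degrees C (vectorised).
#' @param params A [thermal_params()] object.
#' @return Dimensionless positive rate multiplier, same length as `T`.
#' @export
phi <- function(T, params = thermal_params()) {
  params$q_base^((T - params$T_ref) / 10)
}

#' Curie-Weiss membrane capacitance
#'
#' `Cm(T) = C0 + k/(Tc - T)`: capacitance grows with temperature and
#' diverges at the Curie temperature `Tc`.
#'
#' @inheritParams phi
#' @return Capacitance in uF/cm^2, same length as `T`.
#' @export
membrane_capacitance <- function(T, params = thermal_params()) {
  if (any(T >= params$Tc))
    stop("temperature reaches the Curie temperature Tc = ", params$Tc,
         " degC where the Curie-Weiss capacitance diverges")
  params$C0 + params$k / (params$Tc - T)
}

#' Thermally induced capacitive current
#'
#' The displacement current that appears when membrane capacitance changes
#' during a thermal transient, `Im = (vm - Vs) * dCm/dt`. In `"literal"`
#' mode (default) `dCm/dt` is taken as `cap_coeff * dT/dt`; in
#' `"fractional"` mode the coefficient is a fractional change per degC so
#' `dCm/dt = cap_coeff * Cm * dT/dt`.
#'
#' Positive current is outward. With `vm < Vs` and rising temperature the
#' current is negative (inward contribution once subtracted in the membrane
#' equation), i.e. depolarizing.
#'
#' @param vm Membrane potential, mV (vectorised).
#' @param dT_dt Temperature ramp rate, degrees C per millisecond.
#' @param params A [thermal_params()] object.
#' @param Cm Instantaneous capacitance, uF/cm^2; only used in
#'   `"fractional"` mode (defaults to `C0` if missing there).
#' @return Current in uA/cm^2.
#' @export
capacitive_current <- function(vm, dT_dt, params = thermal_params(),
                               Cm = NULL) {
  coeff <- params$cap_coeff
  if (params$cap_mode == "fractional") {
    if (is.null(Cm)) Cm <- params$C0
    coeff <- coeff * Cm
  }
  coeff * dT_dt * (vm - params$Vs)
}

#' Temperature protocols
#'
#' A temperature protocol maps time (seconds) to temperature (degC) and its
#' analytic rate of change (degC/ms). Three kinds are supported:
#' `constant` (baseline forever), `rectangular` (pulse segments with linear
#' edge ramps so that `dT/dt` stays finite), and `saturating`
#' (exponential approach `dT * (1 - exp(-(t - onset)/tau))` toward a plateau
#' within each segment, mimicking continuous-wave irradiation heating).
#'
#' @param kind One of `"constant"`, `"rectangular"`, `"saturating"`.
#' @param baseline Baseline temperature, degC.
#' @param segments For pulsed kinds, a list of `c(onset_s, offset_s, dT)`
#'   triples (or an n-by-3 matrix). Segments must not overlap.
#' @param edge_ramp Rectangular edge ramp duration, seconds. Edges are
#'   linearly ramped over this duration starting at onset/offset.
#' @param tau Saturation time constant, seconds (saturating kind).
#' @return A `temperature_protocol` object.
#' @examples
#' # the default network stimulus schedule: +10, +20, +30 degC pulses
#' p <- temperature_protocol("rectangular", baseline = 6.3,
#'                           segments = list(c(3, 6, 10), c(9, 12, 20),
#'                                           c(15, 18, 30)))
#' protocol_eval(p, c(0, 4.5, 3.05))
#' @export
temperature_protocol <- function(kind = c("constant", "rectangular",
                                          "saturating"),
                                 baseline = 6.3, segments = list(),
                                 edge_ramp = 0.1, tau = 0.5) {
  kind <- match.arg(kind)
  if (is.matrix(segments)) segments <- asplit(segments, 1)
  segments <- lapply(segments, function(s) {
    s <- as.numeric(s)
    if (length(s) != 3) stop("each segment must be (onset_s, offset_s, dT)")
    if (s[2] <= s[1]) stop("segment offset must follow onset")
    s
  })
  if (length(segments) > 1) {
    on <- vapply(segments, `[`, 0, 1)
    off <- vapply(segments, `[`, 0, 2)
    o <- order(on)
    segments <- segments[o]
    if (any(on[o][-1] < off[o][-length(off)]))
      stop("protocol segments overlap")
  }
  stopifnot(edge_ramp > 0, tau > 0)
  structure(list(kind = kind, baseline = baseline, segments = segments,
                 edge_ramp = edge_ramp, tau = tau),
            class = "temperature_protocol")
}

#' Evaluate a temperature protocol
#'
#' @param protocol A [temperature_protocol()] object.
#' @param t Time points, seconds (vectorised), all non-negative.
#' @return A data.frame with columns `t_s`, `T_degC`, and `dT_dt_degC_ms`
#'   (analytic derivative of the temperature trace, degC per millisecond).
#' @export
protocol_eval <- function(protocol, t) {
  stopifnot(inherits(protocol, "temperature_protocol"), all(t >= 0))
  T <- rep(protocol$baseline, length(t))
  dTdt_s <- numeric(length(t))            # degC per second, converted below
  for (seg in protocol$segments) {
    on <- seg[1]; off <- seg[2]; dT <- seg[3]
    if (protocol$kind == "rectangular") {
      er <- protocol$edge_ramp
      rise <- t >= on & t < on + er
      plateau <- t >= on + er & t < off
      fall <- t >= off & t < off + er
      T[rise] <- T[rise] + dT * (t[rise] - on) / er
      dTdt_s[rise] <- dTdt_s[rise] + dT / er
      T[plateau] <- T[plateau] + dT
      T[fall] <- T[fall] + dT * (1 - (t[fall] - off) / er)
      dTdt_s[fall] <- dTdt_s[fall] - dT / er
    } else if (protocol$kind == "saturating") {
      # exponential rise toward the plateau during [on, off), exponential
      # relaxation back to baseline afterwards (continuous at the offset)
      rise <- t >= on & t < off
      u <- t[rise] - on
      T[rise] <- T[rise] + dT * (1 - exp(-u / protocol$tau))
      dTdt_s[rise] <- dTdt_s[rise] + dT * exp(-u / protocol$tau) / protocol$tau
      post <- t >= off
      T_off <- dT * (1 - exp(-(off - on) / protocol$tau))
      v <- t[post] - off
      T[post] <- T[post] + T_off * exp(-v / protocol$tau)
      dTdt_s[post] <- dTdt_s[post] - T_off * exp(-v / protocol$tau) / protocol$tau
    }
  }
  data.frame(t_s = t, T_degC = T, dT_dt_degC_ms = dTdt_s / 1000)
}

#' Validate a protocol against the Curie temperature
#'
#' Scans the protocol over `[0, duration]` and errors if the temperature
#' would reach the capacitance pole at `Tc`.
#'
#' @param protocol A [temperature_protocol()] object.
#' @param params A [thermal_params()] object.
#' @param duration Run duration, seconds.
#' @param resolution Scan step, seconds.
#' @return Invisibly `TRUE` on success.
#' @export
check_protocol <- function(protocol, params, duration, resolution = 1e-3) {
  ev <- protocol_eval(protocol, seq(0, duration, by = resolution))
  # segment plateaus are the analytic extrema; the scan guards ramp overlap
  peak <- max(ev$T_degC)
  if (peak >= params$Tc)
    stop("protocol reaches ", signif(peak, 4),
         " degC, at or beyond the Curie temperature Tc = ", params$Tc,
         " degC; the capacitance law has a pole there")
  invisible(TRUE)
}
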