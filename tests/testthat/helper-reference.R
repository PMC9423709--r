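# Independent straight-line reference integrators, coded directly from the
# model equations in plain R. They deliberately share nothing with the
# package's compiled engine beyond the mathematical definitions, and serve
# as oracles for the integration tests.

ref_rates <- function(v, ph) {
  iexprel <- function(x) if (abs(x) < 1e-8) 1 - x / 2 else x / expm1(x)
  list(an = 0.032 * ph * 5 * iexprel((-48 - v) / 5),
       bn = 0.5 * ph * exp((-53 - v) / 40),
       am = 0.32 * ph * 4 * iexprel((-50 - v) / 4),
       bm = 0.28 * ph * 5 * iexprel((v + 23) / 5),
       ah = 0.128 * ph * exp((-46 - v) / 18),
       bh = 4 * ph / (1 + exp((-23 - v) / 5)))
}

# One neuron, fixed temperature, optional per-step synaptic current vector.
# Same scheme as the engine (exponential gates at v_k, RK2 midpoint voltage)
# so trajectories are comparable step by step.
ref_sim_neuron <- function(n_steps, dt, T, np, tp, i_syn = NULL,
                           fixed_cm = NULL) {
  ph <- tp$q_base^((T - tp$T_ref) / 10)
  Cm <- if (is.null(fixed_cm)) tp$C0 + tp$k / (tp$Tc - T) else fixed_cm
  rhs <- function(v, m, n, h, is) {
    (-np$g_leak * (v - np$E_leak) - np$g_Na * m^3 * h * (v - np$E_Na) -
       np$g_K * n^4 * (v - np$E_K) + np$I_ext + is) / Cm
  }
  r0 <- ref_rates(np$V_rest, 1)
  v <- np$V_rest
  m <- r0$am / (r0$am + r0$bm)
  n <- r0$an / (r0$an + r0$bn)
  h <- r0$ah / (r0$ah + r0$bh)
  vs <- numeric(n_steps + 1); vs[1] <- v
  spikes <- numeric(0); last <- -Inf
  for (k in seq_len(n_steps)) {
    r <- ref_rates(v, ph)
    sm <- r$am + r$bm; sn <- r$an + r$bn; sh <- r$ah + r$bh
    m <- r$am / sm + (m - r$am / sm) * exp(-dt * sm)
    n <- r$an / sn + (n - r$an / sn) * exp(-dt * sn)
    h <- r$ah / sh + (h - r$ah / sh) * exp(-dt * sh)
    is <- if (is.null(i_syn)) 0 else i_syn[k]
    k1 <- rhs(v, m, n, h, is)
    vmid <- v + 0.5 * dt * k1
    k2 <- rhs(vmid, m, n, h, is)
    v_new <- v + dt * k2
    t_new <- k * dt
    if (v < np$V_detect && v_new >= np$V_detect &&
        t_new - last >= np$dead_time) {
      spikes <- c(spikes, t_new); last <- t_new
    }
    v <- v_new
    vs[k + 1] <- v
  }
  list(vm = vs, spikes_ms = spikes)
}

# Two-neuron excitatory chain (1 -> 2 and optionally 2 -> 1), constant
# temperature, full synapse model, same update ordering as the engine.
ref_sim_two_neuron <- function(n_steps, dt, T, np, tp, sp,
                               edges = rbind(c(1, 2), c(2, 1))) {
  ph <- tp$q_base^((T - tp$T_ref) / 10)
  Cm <- tp$C0 + tp$k / (tp$Tc - T)
  rhs <- function(v, m, n, h, is) {
    (-np$g_leak * (v - np$E_leak) - np$g_Na * m^3 * h * (v - np$E_Na) -
       np$g_K * n^4 * (v - np$E_K) + np$I_ext + is) / Cm
  }
  r0 <- ref_rates(np$V_rest, 1)
  v <- rep(np$V_rest, 2)
  m <- rep(r0$am / (r0$am + r0$bm), 2)
  n <- rep(r0$an / (r0$an + r0$bn), 2)
  h <- rep(r0$ah / (r0$ah + r0$bh), 2)
  ne <- nrow(edges)
  u <- numeric(ne); x <- rep(1, ne); Gs <- numeric(ne)
  r1 <- numeric(ne); r2 <- numeric(ne); last_ev <- numeric(ne)
  spikes <- list(numeric(0), numeric(0)); last <- c(-Inf, -Inf)
  a_a <- sp$ampa$alpha / 1000; b_a <- sp$ampa$beta / 1000
  a_n <- sp$nmda$alpha / 1000; b_n <- sp$nmda$beta / 1000
  conv <- 1e-6 / sp$membrane_area
  for (k in seq_len(n_steps)) {
    i_syn <- c(0, 0)
    for (e in seq_len(ne)) {
      post <- edges[e, 2]
      mg <- 1 / (1 + exp(-0.062 * v[post]) * sp$mg_conc / 3.57)
      i_pA <- sp$ampa$g_max * r1[e] * (v[post] - sp$ampa$E) +
        sp$nmda$g_max * mg * r2[e] * (v[post] - sp$nmda$E)
      i_syn[post] <- i_syn[post] - i_pA * conv
      rel <- function(r, aG, b) {
        rate <- aG + b
        if (rate <= 0) return(r)
        rinf <- aG / rate
        rinf + (r - rinf) * exp(-rate * dt)
      }
      r1[e] <- rel(r1[e], a_a * Gs[e], b_a)
      r2[e] <- rel(r2[e], a_n * Gs[e], b_n)
      Gs[e] <- Gs[e] * exp(-sp$Omega_c / 1000 * dt)
    }
    t_new <- k * dt
    for (i in 1:2) {
      r <- ref_rates(v[i], ph)
      sm <- r$am + r$bm; sn <- r$an + r$bn; sh <- r$ah + r$bh
      m[i] <- r$am / sm + (m[i] - r$am / sm) * exp(-dt * sm)
      n[i] <- r$an / sn + (n[i] - r$an / sn) * exp(-dt * sn)
      h[i] <- r$ah / sh + (h[i] - r$ah / sh) * exp(-dt * sh)
      k1 <- rhs(v[i], m[i], n[i], h[i], i_syn[i])
      vmid <- v[i] + 0.5 * dt * k1
      v_new <- v[i] + dt * rhs(vmid, m[i], n[i], h[i], i_syn[i])
      if (v[i] < np$V_detect && v_new >= np$V_detect &&
          t_new - last[i] >= np$dead_time) {
        spikes[[i]] <- c(spikes[[i]], t_new); last[i] <- t_new
        for (e in which(edges[, 1] == i)) {
          gap <- t_new - last_ev[e]
          if (gap > 0) {
            u[e] <- u[e] * exp(-gap / (sp$tau_f * 1000))
            x[e] <- 1 - (1 - x[e]) * exp(-gap / (sp$tau_r * 1000))
          }
          last_ev[e] <- t_new
          u[e] <- u[e] + sp$U0 * (1 - u[e])
          r_s <- u[e] * x[e]
          x[e] <- x[e] - r_s
          Gs[e] <- Gs[e] + r_s * sp$Q_c * sp$Y_T * 1000
        }
      }
      v[i] <- v_new
    }
  }
  spikes
}

# Step-by-step Tsodyks-Markram oracle: closed-form inter-spike decay plus
# the jump rules, evaluated per spike (no clock).
ref_tm_train <- function(spike_times_ms, sp) {
  u <- 0; x <- 1; t_prev <- NULL
  r_s <- numeric(length(spike_times_ms))
  for (i in seq_along(spike_times_ms)) {
    if (!is.null(t_prev)) {
      gap <- spike_times_ms[i] - t_prev
      u <- u * exp(-gap / (sp$tau_f * 1000))
      x <- 1 - (1 - x) * exp(-gap / (sp$tau_r * 1000))
    }
    u <- u + sp$U0 * (1 - u)
    r_s[i] <- u * x
    x <- x - r_s[i]
    t_prev <- spike_times_ms[i]
  }
  r_s
}
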