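#include <Rcpp.h>
using namespace Rcpp;

// Fixed-step Euler-Maruyama steppers for the two neuron models.  Noise
// deviates come from R's seeded generator (RNGScope), so trajectories are
// reproducible from set.seed / the seed argument on the R side.

static inline double logistic_gate(double V, double Vh, double s) {
  return 1.0 / (1.0 + std::exp(-(V - Vh) / s));
}

// [[Rcpp::export]]
NumericMatrix hr_integrate_cpp(NumericVector p, NumericVector state0,
                               double dt, int n_steps, int decimation) {
  const double a = p[0], b = p[1], c = p[2], d = p[3], r = p[4], s = p[5],
               V_R = p[6], gamma_u = p[7], alpha_z = p[8], gamma_d = p[9],
               x_V = p[10], x_z = p[11], k_n = p[12], k_h = p[13],
               I_app = p[14], sV = p[15], sy = p[16], sz = p[17],
               su = p[18], t_scale = p[19];
  double V = state0[0], y = state0[1], z = state0[2], u = state0[3];
  const bool noisy = (sV > 0) || (sy > 0) || (sz > 0) || (su > 0);
  // drift is per HR time unit; h converts to physical steps and the
  // Wiener increment scales with the same clock (sigma per sqrt HR unit)
  const double h = t_scale * dt, sq = std::sqrt(h);
  const int n_rec = n_steps / decimation;
  NumericMatrix out(n_rec, 4);
  RNGScope scope;
  for (int k = 1; k <= n_steps; ++k) {
    const double n_inf = 0.5 * (1.0 + std::tanh((V - x_V) / k_n));
    const double h_inf = 0.5 * (1.0 + std::tanh((z - x_z) / k_h));
    double dV = (y - a * V * V * V + b * V * V - z - u + I_app) * h;
    double dy = (c - d * V * V - y) * h;
    double dz = (r * (s * (V - V_R) - z)) * h;
    double du = (-gamma_u * n_inf + alpha_z * h_inf - gamma_d * u) * h;
    if (noisy) {
      if (sV > 0) dV += sV * sq * norm_rand();
      if (sy > 0) dy += sy * sq * norm_rand();
      if (sz > 0) dz += sz * sq * norm_rand();
      if (su > 0) du += su * sq * norm_rand();
    }
    V += dV; y += dy; z += dz; u += du;
    if (!std::isfinite(V) || !std::isfinite(y) || !std::isfinite(z) ||
        !std::isfinite(u))
      stop("non-finite state at step %d", k);
    if (k % decimation == 0) {
      const int i = k / decimation - 1;
      out(i, 0) = V; out(i, 1) = y; out(i, 2) = z; out(i, 3) = u;
    }
  }
  return out;
}

// [[Rcpp::export]]
NumericMatrix biophys_integrate_cpp(NumericVector p, NumericVector state0,
                                    double dt_ms, int n_steps,
                                    int decimation, NumericVector I_syn,
                                    NumericVector glu) {
  const double C_m = p[0], g_c = p[1], kappa = p[2], g_Na_S = p[3],
               g_K_S = p[4], g_Na_D = p[5], g_K_D = p[6], g_SK = p[7],
               g_NMDA = p[8], g_leak = p[9], I_app = p[10], V_Na = p[11],
               V_K = p[12], V_Ca = p[13], V_leak = p[14], k_Ca = p[15],
               Mg_out = p[16];
  const double mS_Vh = p[17], mS_s = p[18], nS_Vh = p[19], nS_s = p[20],
               nS_tau = p[21], mD_Vh = p[22], mD_s = p[23], hD_Vh = p[24],
               hD_s = p[25], hD_tau = p[26], nD_Vh = p[27], nD_s = p[28],
               nD_tau = p[29], pD_Vh = p[30], pD_s = p[31], pD_tau = p[32];
  const double f_c = p[33], f_ER = p[34], gamma_v = p[35], alpha = p[36],
               nu_PMCA = p[37], K_PMCA = p[38], nu_SERCA = p[39],
               K_SERCA = p[40], nu_IP3R = p[41], nu_INleak = p[42],
               nu_ERleak = p[43], iota = p[44], d1 = p[45], d2 = p[46],
               d3 = p[47], d5 = p[48], a_h = p[49], IP3 = p[50],
               Ca_out = p[51];
  const double l_b = p[52], l_u = p[53], l_o = p[54], l_c = p[55],
               l_d = p[56], l_r = p[57];

  double V_S = state0[0], V_D = state0[1], n_S = state0[2], n_D = state0[3],
         h_D = state0[4], p_D = state0[5], C0 = state0[6], C1 = state0[7],
         C2 = state0[8], O = state0[9], Dst = state0[10], Ca_i = state0[11],
         Ca_ER = state0[12], h_IP = state0[13];

  const bool has_syn = I_syn.size() == n_steps;
  const bool has_glu = glu.size() == n_steps;
  const double m_ip3 = IP3 / (IP3 + d1);
  const double Q2 = d2 * (IP3 + d1) / (IP3 + d3);
  const int n_rec = n_steps / decimation;
  NumericMatrix out(n_rec, 14);

  for (int k = 1; k <= n_steps; ++k) {
    const double syn = has_syn ? I_syn[k - 1] : 0.0;
    const double g = has_glu ? glu[k - 1] : 0.0;

    const double m_S = logistic_gate(V_S, mS_Vh, mS_s);
    const double m_D = logistic_gate(V_D, mD_Vh, mD_s);
    const double hill = Ca_i * Ca_i / (Ca_i * Ca_i + k_Ca * k_Ca);
    const double B = 1.0 / (1.0 + std::exp(-0.062 * V_D) * Mg_out / 3.57);

    const double I_Na_S = g_Na_S * m_S * m_S * (1.0 - n_S) * (V_S - V_Na);
    const double I_K_S = g_K_S * n_S * n_S * (V_S - V_K);
    const double I_Na_D = g_Na_D * m_D * m_D * h_D * (V_D - V_Na);
    const double I_K_D = g_K_D * n_D * n_D * p_D * (V_D - V_K);
    const double I_SK = g_SK * hill * (V_D - V_K);
    const double I_NMDA = g_NMDA * B * O * (V_D - V_Ca);
    const double I_leak_S = g_leak * (V_S - V_leak);
    const double I_leak_D = g_leak * (V_D - V_leak);
    const double I_cpl_S = g_c / kappa * (V_S - V_D);
    const double I_cpl_D = g_c / (1.0 - kappa) * (V_D - V_S);

    const double dV_S = (I_app - I_Na_S - I_K_S - I_cpl_S - I_leak_S) / C_m;
    const double dV_D = (syn - I_Na_D - I_K_D - I_SK - I_NMDA - I_cpl_D -
                         I_leak_D) / C_m;
    const double dn_S = (logistic_gate(V_S, nS_Vh, nS_s) - n_S) / nS_tau;
    const double dn_D = (logistic_gate(V_D, nD_Vh, nD_s) - n_D) / nD_tau;
    const double dh_D = (logistic_gate(V_D, hD_Vh, hD_s) - h_D) / hD_tau;
    const double dp_D = (logistic_gate(V_D, pD_Vh, pD_s) - p_D) / pD_tau;

    // NMDA master equation (per ms)
    const double bglu = l_b * g;
    const double dC0 = l_u * C1 - bglu * C0;
    const double dC1 = bglu * C0 + l_u * C2 - (l_u + bglu) * C1;
    const double dC2 = bglu * C1 + l_c * O + l_r * Dst -
                       (l_u + l_o + l_d) * C2;
    const double dO = l_o * C2 - l_c * O;
    const double dD = l_d * C2 - l_r * Dst;

    // calcium fluxes (uM/s), converted to per-ms below
    const double J_NMDA = -alpha * I_NMDA;
    const double ca_i = std::pow(Ca_i, iota);
    const double J_PMCA = nu_PMCA * ca_i / (ca_i + std::pow(K_PMCA, iota));
    const double J_SERCA = nu_SERCA * ca_i / (ca_i + std::pow(K_SERCA, iota));
    const double n_ip3 = Ca_i / (Ca_i + d5);
    const double J_IP3R = nu_IP3R * m_ip3 * m_ip3 * m_ip3 * n_ip3 * n_ip3 *
                          n_ip3 * h_IP * h_IP * h_IP * (Ca_ER - Ca_i);
    const double J_INleak = nu_INleak * (Ca_out - Ca_i);
    const double J_ERleak = nu_ERleak * (Ca_ER - Ca_i);
    const double dCa_i = f_c * (J_NMDA - J_PMCA + J_IP3R + J_ERleak -
                                J_SERCA - J_INleak) / 1000.0;
    const double dCa_ER = f_ER * gamma_v * (J_SERCA - J_IP3R - J_ERleak) /
                          1000.0;
    const double h_inf = Q2 / (Q2 + Ca_i);
    const double tau_h = 1.0 / (a_h * (Q2 + Ca_i));
    const double dh_IP = (h_inf - h_IP) / tau_h / 1000.0;

    V_S += dV_S * dt_ms; V_D += dV_D * dt_ms;
    n_S += dn_S * dt_ms; n_D += dn_D * dt_ms;
    h_D += dh_D * dt_ms; p_D += dp_D * dt_ms;
    C0 += dC0 * dt_ms; C1 += dC1 * dt_ms; C2 += dC2 * dt_ms;
    O += dO * dt_ms; Dst += dD * dt_ms;
    Ca_i += dCa_i * dt_ms; Ca_ER += dCa_ER * dt_ms; h_IP += dh_IP * dt_ms;

    if (!std::isfinite(V_S) || !std::isfinite(V_D) || !std::isfinite(Ca_i))
      stop("non-finite state at step %d", k);

    if (k % decimation == 0) {
      const int i = k / decimation - 1;
      out(i, 0) = V_S; out(i, 1) = V_D; out(i, 2) = n_S; out(i, 3) = n_D;
      out(i, 4) = h_D; out(i, 5) = p_D; out(i, 6) = C0; out(i, 7) = C1;
      out(i, 8) = C2; out(i, 9) = O; out(i, 10) = Dst; out(i, 11) = Ca_i;
      out(i, 12) = Ca_ER; out(i, 13) = h_IP;
    }
  }
  return out;
}
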