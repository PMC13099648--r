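#include <Rcpp.h>
using namespace Rcpp;

// Leaky integrate-and-fire forward integration (Euler) with threshold,
// reset and absolute refractory period. Noise is supplied pre-drawn so
// all randomness flows through R's RNG.
//
// Units: R_in in MOhm, C_m in pF (tau_s = R*C*1e-6), I in pA, V in mV.
// [[Rcpp::export(name = ".lif_integrate_cpp")]]
List lif_integrate_cpp(NumericVector I, double dt,
                       double r_in, double c_m,
                       double v_rest, double v_thresh, double v_reset,
                       double refr_s, NumericVector noise) {
  const int n = I.size();
  const double tau = r_in * c_m * 1e-6; // seconds
  const int refr_steps = (int) std::ceil(refr_s / dt);
  NumericVector v(n);
  std::vector<int> spikes;
  double vcur = v_rest;
  int hold = 0;
  const bool has_noise = noise.size() == n;
  for (int i = 0; i < n; ++i) {
    if (hold > 0) {
      vcur = v_reset;
      --hold;
    } else {
      // exponential (exact) update for piecewise-constant input
      double vinf = v_rest + I[i] * r_in * 1e-3;
      vcur = vinf + (vcur - vinf) * std::exp(-dt / tau);
      if (has_noise) vcur += noise[i];
      if (vcur >= v_thresh) {
        spikes.push_back(i + 1); // 1-based index of threshold crossing
        vcur = v_reset;
        hold = refr_steps;
      }
    }
    v[i] = vcur;
  }
  return List::create(_["v"] = v, _["spike_idx"] = wrap(spikes));
}

// Sliding optimally-scaled-template fit (Clements-Bekkers). For every
// window the template is fitted as data ~ scale * template + offset and
// the detection criterion scale / SE(scale) is returned (0 where the
// window runs off the end).
// [[Rcpp::export(name = ".cb_criterion_cpp")]]
NumericVector cb_criterion_cpp(NumericVector x, NumericVector tmpl) {
  const int n = x.size(), m = tmpl.size();
  NumericVector crit(n);
  if (m < 3 || n < m) return crit;
  double st = 0.0, stt = 0.0;
  for (int j = 0; j < m; ++j) { st += tmpl[j]; stt += tmpl[j] * tmpl[j]; }
  const double denom = stt - st * st / m;
  if (denom <= 0) stop("template has zero variance");
  for (int i = 0; i + m <= n; ++i) {
    double sd = 0.0, sdd = 0.0, std_ = 0.0;
    for (int j = 0; j < m; ++j) {
      double d = x[i + j];
      sd += d; sdd += d * d; std_ += d * tmpl[j];
    }
    double scale = (std_ - st * sd / m) / denom;
    double offset = (sd - scale * st) / m;
    double sse = sdd + scale * scale * stt + m * offset * offset
               - 2.0 * scale * std_ - 2.0 * offset * sd
               + 2.0 * scale * offset * st;
    if (sse < 0) sse = 0;
    double se2 = sse / (m - 2) / denom;
    crit[i] = se2 > 0 ? scale / std::sqrt(se2) : (scale > 0 ? R_PosInf : 0.0);
  }
  return crit;
}
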