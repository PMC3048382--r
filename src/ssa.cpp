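// Exact stochastic simulation (Gillespie direct method) of the joint
// promoter-state / mRNA / protein process. Uses R's RNG so trajectories
// are reproducible via set.seed() from the R side.

#include <Rcpp.h>
using namespace Rcpp;

namespace {

struct Model {
  int n_states;
  std::vector<int> tr_from, tr_to;    // 0-based promoter transitions
  std::vector<double> tr_rate;
  std::vector<double> r;              // per-state transcription rates
  double gamma_m;
  bool protein;
  bool burst;                         // geometric bursts at transcription
  double ktl;                         // translation rate per mRNA
  double gamma_p;
  double burst_mean;
};

// one SSA step; returns waiting time, updates (s, m, n); dt < 0 if stuck
double step(const Model& mod, int& s, double& m, double& n) {
  const int nt = static_cast<int>(mod.tr_rate.size());
  double a0 = 0.0;
  for (int i = 0; i < nt; ++i) if (mod.tr_from[i] == s) a0 += mod.tr_rate[i];
  const double a_tx = mod.r[s];
  const double a_dm = mod.gamma_m * m;
  double a_tl = 0.0, a_dn = 0.0;
  if (mod.protein) {
    if (!mod.burst) a_tl = mod.ktl * m;
    a_dn = mod.gamma_p * n;
  }
  a0 += a_tx + a_dm + a_tl + a_dn;
  if (!(a0 > 0.0)) return -1.0;
  if (!R_finite(a0)) stop("propensity sum is not finite");
  const double dt = -std::log(unif_rand()) / a0;
  double u = unif_rand() * a0;
  for (int i = 0; i < nt; ++i) {
    if (mod.tr_from[i] != s) continue;
    if (u < mod.tr_rate[i]) { s = mod.tr_to[i]; return dt; }
    u -= mod.tr_rate[i];
  }
  if (u < a_tx) {
    m += 1.0;
    if (mod.protein && mod.burst)
      n += R::rgeom(1.0 / (1.0 + mod.burst_mean));
    return dt;
  }
  u -= a_tx;
  if (u < a_dm) { m -= 1.0; return dt; }
  u -= a_dm;
  if (u < a_tl) { n += 1.0; return dt; }
  n -= 1.0;
  return dt;
}

Model build_model(int n_states, IntegerVector tr_from, IntegerVector tr_to,
                  NumericVector tr_rate, NumericVector r, double gamma_m,
                  List protein_opts) {
  Model mod;
  mod.n_states = n_states;
  mod.tr_from = as<std::vector<int>>(tr_from);
  mod.tr_to = as<std::vector<int>>(tr_to);
  mod.tr_rate = as<std::vector<double>>(tr_rate);
  mod.r = as<std::vector<double>>(r);
  mod.gamma_m = gamma_m;
  mod.protein = protein_opts.size() > 0;
  mod.burst = false;
  mod.ktl = 0.0; mod.gamma_p = 0.0; mod.burst_mean = 0.0;
  if (mod.protein) {
    mod.burst = as<bool>(protein_opts["burst"]);
    mod.ktl = as<double>(protein_opts["ktl"]);
    mod.gamma_p = as<double>(protein_opts["gamma_p"]);
    mod.burst_mean = as<double>(protein_opts["b"]);
  }
  return mod;
}

} // namespace

// [[Rcpp::export]]
List ssa_path_cpp(int n_states, IntegerVector tr_from, IntegerVector tr_to,
                  NumericVector tr_rate, NumericVector r, double gamma_m,
                  double t_end, int s0, double m0, double n0,
                  List protein_opts, double max_events) {
  Model mod = build_model(n_states, tr_from, tr_to, tr_rate, r, gamma_m,
                          protein_opts);
  std::vector<double> times, mrna, prot;
  std::vector<int> states;
  times.reserve(1024); states.reserve(1024); mrna.reserve(1024);
  int s = s0; double m = m0, n = n0, t = 0.0;
  times.push_back(0.0); states.push_back(s); mrna.push_back(m);
  if (mod.protein) prot.push_back(n);
  double ev = 0.0;
  while (ev < max_events) {
    const double dt = step(mod, s, m, n);
    if (dt < 0.0) break;                       // no reaction possible
    t += dt;
    if (t > t_end) break;
    times.push_back(t); states.push_back(s); mrna.push_back(m);
    if (mod.protein) prot.push_back(n);
    ev += 1.0;
  }
  List out = List::create(_["times"] = wrap(times),
                          _["states"] = wrap(states),
                          _["mrna"] = wrap(mrna),
                          _["t_end"] = t_end,
                          _["n_events"] = ev);
  if (mod.protein) out["protein"] = wrap(prot);
  return out;
}

// Streaming long-run time averages: no path storage, so runs of 1e7+
// events are cheap. Burn-in and batch boundaries are event-counted;
// averages are time-weighted within batches.
// [[Rcpp::export]]
List ssa_longrun_cpp(int n_states, IntegerVector tr_from, IntegerVector tr_to,
                     NumericVector tr_rate, NumericVector r, double gamma_m,
                     double n_events, int s0, double m0, double n0,
                     List protein_opts, double burn_frac, int n_batches,
                     int hist_max) {
  Model mod = build_model(n_states, tr_from, tr_to, tr_rate, r, gamma_m,
                          protein_opts);
  const double burn = std::floor(burn_frac * n_events);
  const double per_batch = std::max(1.0, (n_events - burn) / n_batches);
  int s = s0; double m = m0, n = n0;
  double T = 0.0, sum_m = 0.0, sum_m2 = 0.0, sum_n = 0.0, sum_n2 = 0.0;
  std::vector<double> occ(n_states, 0.0);
  std::vector<double> hist(hist_max + 1, 0.0);
  NumericMatrix batch(n_batches, 4); // T, m dt, m^2 dt, n dt
  double switches = 0.0;

  for (double ev = 0.0; ev < n_events; ev += 1.0) {
    const int s_before = s;
    double m_before = m, n_before = n;
    const double dt = step(mod, s, m, n);
    if (dt < 0.0) break;
    if (s != s_before) switches += 1.0;
    if (ev >= burn) {
      T += dt;
      occ[s_before] += dt;
      sum_m += m_before * dt; sum_m2 += m_before * m_before * dt;
      sum_n += n_before * dt; sum_n2 += n_before * n_before * dt;
      const int mi = m_before < hist_max ? static_cast<int>(m_before)
                                         : hist_max;
      hist[mi] += dt;
      int bi = static_cast<int>((ev - burn) / per_batch);
      if (bi >= n_batches) bi = n_batches - 1;
      batch(bi, 0) += dt;
      batch(bi, 1) += m_before * dt;
      batch(bi, 2) += m_before * m_before * dt;
      batch(bi, 3) += n_before * dt;
    }
  }
  return List::create(_["T"] = T, _["occupancy"] = wrap(occ),
                      _["sum_m"] = sum_m, _["sum_m2"] = sum_m2,
                      _["sum_n"] = sum_n, _["sum_n2"] = sum_n2,
                      _["hist"] = wrap(hist), _["batch"] = batch,
                      _["switches"] = switches);
}
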