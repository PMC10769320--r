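#include <Rcpp.h>
using namespace Rcpp;

// Two-state HMM over the chain of adenine sites of one fiber.
// State 0 = accessible, state 1 = inaccessible.
// obs[t] in {0,1}: site methylated? pm(t,s) = P(methylated | state s) at site t.

static inline double emit(int obs, double p) {
  return obs ? p : 1.0 - p;
}

// Scaled forward pass; returns log-likelihood. Empty chain -> 0 by convention.
// [[Rcpp::export]]
double fhmm_forward_cpp(const IntegerVector& obs, const NumericMatrix& pm,
                        const NumericVector& start, const NumericMatrix& trans) {
  const int L = obs.size();
  if (L == 0) return 0.0;
  double a0 = start[0] * emit(obs[0], pm(0, 0));
  double a1 = start[1] * emit(obs[0], pm(0, 1));
  double c = a0 + a1;
  if (c <= 0.0) return R_NegInf;
  double ll = std::log(c);
  a0 /= c; a1 /= c;
  for (int t = 1; t < L; ++t) {
    double n0 = (a0 * trans(0, 0) + a1 * trans(1, 0)) * emit(obs[t], pm(t, 0));
    double n1 = (a0 * trans(0, 1) + a1 * trans(1, 1)) * emit(obs[t], pm(t, 1));
    c = n0 + n1;
    if (c <= 0.0) return R_NegInf;
    ll += std::log(c);
    a0 = n0 / c; a1 = n1 / c;
  }
  return ll;
}

// Forward-backward: posterior state probabilities (gamma), expected transition
// counts summed over the chain (xi), gamma at t=0, and log-likelihood.
// [[Rcpp::export]]
List fhmm_fwdbwd_cpp(const IntegerVector& obs, const NumericMatrix& pm,
                     const NumericVector& start, const NumericMatrix& trans) {
  const int L = obs.size();
  NumericMatrix gamma(L, 2), xi(2, 2);
  if (L == 0) {
    return List::create(_["loglik"] = 0.0, _["gamma"] = gamma,
                        _["xi"] = xi, _["gamma1"] = NumericVector::create(0.0, 0.0));
  }
  NumericMatrix alpha(L, 2), beta(L, 2);
  NumericVector sc(L);
  alpha(0, 0) = start[0] * emit(obs[0], pm(0, 0));
  alpha(0, 1) = start[1] * emit(obs[0], pm(0, 1));
  sc[0] = alpha(0, 0) + alpha(0, 1);
  alpha(0, 0) /= sc[0]; alpha(0, 1) /= sc[0];
  double ll = std::log(sc[0]);
  for (int t = 1; t < L; ++t) {
    alpha(t, 0) = (alpha(t - 1, 0) * trans(0, 0) + alpha(t - 1, 1) * trans(1, 0)) *
                  emit(obs[t], pm(t, 0));
    alpha(t, 1) = (alpha(t - 1, 0) * trans(0, 1) + alpha(t - 1, 1) * trans(1, 1)) *
                  emit(obs[t], pm(t, 1));
    sc[t] = alpha(t, 0) + alpha(t, 1);
    alpha(t, 0) /= sc[t]; alpha(t, 1) /= sc[t];
    ll += std::log(sc[t]);
  }
  beta(L - 1, 0) = 1.0; beta(L - 1, 1) = 1.0;
  for (int t = L - 2; t >= 0; --t) {
    double e0 = emit(obs[t + 1], pm(t + 1, 0)), e1 = emit(obs[t + 1], pm(t + 1, 1));
    beta(t, 0) = (trans(0, 0) * e0 * beta(t + 1, 0) + trans(0, 1) * e1 * beta(t + 1, 1)) / sc[t + 1];
    beta(t, 1) = (trans(1, 0) * e0 * beta(t + 1, 0) + trans(1, 1) * e1 * beta(t + 1, 1)) / sc[t + 1];
  }
  for (int t = 0; t < L; ++t) {
    double g0 = alpha(t, 0) * beta(t, 0), g1 = alpha(t, 1) * beta(t, 1);
    double z = g0 + g1;
    gamma(t, 0) = g0 / z; gamma(t, 1) = g1 / z;
  }
  for (int t = 0; t < L - 1; ++t) {
    double e0 = emit(obs[t + 1], pm(t + 1, 0)), e1 = emit(obs[t + 1], pm(t + 1, 1));
    double x00 = alpha(t, 0) * trans(0, 0) * e0 * beta(t + 1, 0) / sc[t + 1];
    double x01 = alpha(t, 0) * trans(0, 1) * e1 * beta(t + 1, 1) / sc[t + 1];
    double x10 = alpha(t, 1) * trans(1, 0) * e0 * beta(t + 1, 0) / sc[t + 1];
    double x11 = alpha(t, 1) * trans(1, 1) * e1 * beta(t + 1, 1) / sc[t + 1];
    double z = x00 + x01 + x10 + x11;
    xi(0, 0) += x00 / z; xi(0, 1) += x01 / z;
    xi(1, 0) += x10 / z; xi(1, 1) += x11 / z;
  }
  return List::create(_["loglik"] = ll, _["gamma"] = gamma, _["xi"] = xi,
                      _["gamma1"] = NumericVector::create(gamma(0, 0), gamma(0, 1)));
}

// Viterbi decoding in log space; ties broken toward the accessible state (0).
// [[Rcpp::export]]
IntegerVector fhmm_viterbi_cpp(const IntegerVector& obs, const NumericMatrix& pm,
                               const NumericVector& start, const NumericMatrix& trans) {
  const int L = obs.size();
  IntegerVector path(L);
  if (L == 0) return path;
  const double lt00 = std::log(trans(0, 0)), lt01 = std::log(trans(0, 1));
  const double lt10 = std::log(trans(1, 0)), lt11 = std::log(trans(1, 1));
  std::vector<double> d0(L), d1(L);
  std::vector<int> b0(L), b1(L);
  d0[0] = std::log(start[0]) + std::log(emit(obs[0], pm(0, 0)));
  d1[0] = std::log(start[1]) + std::log(emit(obs[0], pm(0, 1)));
  for (int t = 1; t < L; ++t) {
    double from0 = d0[t - 1] + lt00, from1 = d1[t - 1] + lt10;
    // ties prefer previous state 0 (accessible)
    if (from0 >= from1) { d0[t] = from0; b0[t] = 0; } else { d0[t] = from1; b0[t] = 1; }
    d0[t] += std::log(emit(obs[t], pm(t, 0)));
    from0 = d0[t - 1] + lt01; from1 = d1[t - 1] + lt11;
    if (from0 >= from1) { d1[t] = from0; b1[t] = 0; } else { d1[t] = from1; b1[t] = 1; }
    d1[t] += std::log(emit(obs[t], pm(t, 1)));
  }
  int s = (d0[L - 1] >= d1[L - 1]) ? 0 : 1;
  path[L - 1] = s;
  for (int t = L - 1; t > 0; --t) {
    s = (s == 0) ? b0[t] : b1[t];
    path[t - 1] = s;
  }
  return path;
}

// One full Baum-Welch run with emissions frozen: updates start and transition
// probabilities only. Returns the per-iteration log-likelihood trace (the
// likelihood under the parameters entering each iteration; non-decreasing).
// Observation likelihoods are precomputed once into flat per-state arrays;
// forward/backward scratch buffers are reused across fibers and iterations.
// [[Rcpp::export]]
List fhmm_bw_em_cpp(const List& obs_list, const List& pm_list,
                    const NumericVector& start0, const NumericMatrix& trans0,
                    int max_iter, double tol) {
  const int N = obs_list.size();
  std::vector<int> off(N + 1, 0);
  for (int i = 0; i < N; ++i) {
    IntegerVector obs = obs_list[i];
    off[i + 1] = off[i] + obs.size();
  }
  const int M = off[N];
  std::vector<double> e0(M), e1(M);   // P(obs_t | state) per site
  int maxL = 0;
  for (int i = 0; i < N; ++i) {
    IntegerVector obs = obs_list[i];
    NumericMatrix pm = pm_list[i];
    const int L = obs.size();
    if (L > maxL) maxL = L;
    for (int t = 0; t < L; ++t) {
      e0[off[i] + t] = emit(obs[t], pm(t, 0));
      e1[off[i] + t] = emit(obs[t], pm(t, 1));
    }
  }
  std::vector<double> a0v(maxL), a1v(maxL), scv(maxL), b0v(maxL), b1v(maxL);
  double s0 = start0[0], s1 = start0[1];
  double t00 = trans0(0, 0), t01 = trans0(0, 1);
  double t10 = trans0(1, 0), t11 = trans0(1, 1);
  std::vector<double> trace;
  bool converged = false;
  for (int it = 0; it < max_iter; ++it) {
    double ll = 0.0;
    double g1_0 = 0.0, g1_1 = 0.0;
    double x00 = 0.0, x01 = 0.0, x10 = 0.0, x11 = 0.0;
    for (int i = 0; i < N; ++i) {
      const int L = off[i + 1] - off[i];
      if (L == 0) continue;
      const double* E0 = &e0[off[i]];
      const double* E1 = &e1[off[i]];
      // scaled forward
      double a0 = s0 * E0[0], a1 = s1 * E1[0];
      double c = a0 + a1;
      a0 /= c; a1 /= c;
      a0v[0] = a0; a1v[0] = a1; scv[0] = c;
      ll += std::log(c);
      for (int t = 1; t < L; ++t) {
        double n0 = (a0 * t00 + a1 * t10) * E0[t];
        double n1 = (a0 * t01 + a1 * t11) * E1[t];
        c = n0 + n1;
        a0 = n0 / c; a1 = n1 / c;
        a0v[t] = a0; a1v[t] = a1; scv[t] = c;
        ll += std::log(c);
      }
      // backward with transition accumulation
      double b0 = 1.0, b1 = 1.0;
      b0v[L - 1] = b0; b1v[L - 1] = b1;
      for (int t = L - 2; t >= 0; --t) {
        const double f0 = E0[t + 1] * b0v[t + 1], f1 = E1[t + 1] * b1v[t + 1];
        b0 = (t00 * f0 + t01 * f1) / scv[t + 1];
        b1 = (t10 * f0 + t11 * f1) / scv[t + 1];
        b0v[t] = b0; b1v[t] = b1;
        const double w = 1.0 / scv[t + 1];
        x00 += a0v[t] * t00 * f0 * w;
        x01 += a0v[t] * t01 * f1 * w;
        x10 += a1v[t] * t10 * f0 * w;
        x11 += a1v[t] * t11 * f1 * w;
      }
      const double z = a0v[0] * b0v[0] + a1v[0] * b1v[0];
      g1_0 += a0v[0] * b0v[0] / z;
      g1_1 += a1v[0] * b1v[0] / z;
    }
    trace.push_back(ll);
    if (it > 0 && (ll - trace[it - 1]) < tol) { converged = true; break; }
    double sz = g1_0 + g1_1;
    if (sz > 0) { s0 = g1_0 / sz; s1 = g1_1 / sz; }
    double r0 = x00 + x01, r1 = x10 + x11;
    if (r0 > 0) { t00 = x00 / r0; t01 = x01 / r0; }
    if (r1 > 0) { t10 = x10 / r1; t11 = x11 / r1; }
  }
  NumericMatrix trans(2, 2);
  trans(0, 0) = t00; trans(0, 1) = t01; trans(1, 0) = t10; trans(1, 1) = t11;
  return List::create(_["start"] = NumericVector::create(s0, s1),
                      _["trans"] = trans,
                      _["loglik_trace"] = wrap(trace), _["converged"] = converged);
}
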