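#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Recursions for a left-right hidden semi-Markov chain with an absorbing end
// state. Convention: the last visited zone's occupancy ends exactly at the
// final node (no right-censoring), after which the chain jumps to the end
// state. All arithmetic is in natural-log space; -Inf propagates cleanly.
//
// Shared argument layout:
//   logpi : K            initial log-probabilities over transient states
//   logA  : K x (K+1)    transition log-probs; column K (0-based) is "end"
//   logd  : K x Dmax     occupancy log-pmf over durations 1..Dmax
//   logB  : K x T        per-node emission log-prob of the observed pair

static const double NEG_INF = -std::numeric_limits<double>::infinity();

static inline double lse(const std::vector<double>& v, int n) {
  double m = NEG_INF;
  for (int i = 0; i < n; ++i) if (v[i] > m) m = v[i];
  if (m == NEG_INF) return NEG_INF;
  double s = 0.0;
  for (int i = 0; i < n; ++i) s += std::exp(v[i] - m);
  return m + std::log(s);
}

// alpha(t, j) = log P(obs 1..t, zone of state j ends exactly at node t)
static void forward_pass(const NumericVector& logpi, const NumericMatrix& logA,
                         const NumericMatrix& logd, const NumericMatrix& logB,
                         NumericMatrix& alpha) {
  const int K = logpi.size(), T = logB.ncol(), Dmax = logd.ncol();
  std::vector<double> buf(Dmax);
  for (int t = 1; t <= T; ++t) {
    for (int j = 0; j < K; ++j) {
      const int umax = std::min(t, Dmax);
      double emis = 0.0;
      int nb = 0;
      for (int u = 1; u <= umax; ++u) {
        emis += logB(j, t - u);                 // adds node t-u+1 (1-based)
        double head;
        if (u == t) {
          head = logpi[j];
        } else {
          // zone of some earlier state i < j ended at t-u
          double m = NEG_INF;
          for (int i = 0; i < j; ++i) {
            double v = alpha(t - u - 1, i) + logA(i, j);
            if (v > m) m = v;
          }
          if (m == NEG_INF) { head = NEG_INF; }
          else {
            double s = 0.0;
            for (int i = 0; i < j; ++i)
              s += std::exp(alpha(t - u - 1, i) + logA(i, j) - m);
            head = m + std::log(s);
          }
        }
        buf[nb++] = head + logd(j, u - 1) + emis;
      }
      alpha(t - 1, j) = lse(buf, nb);
    }
  }
}

// [[Rcpp::export]]
double hsmc_forward_cpp(NumericVector logpi, NumericMatrix logA,
                        NumericMatrix logd, NumericMatrix logB) {
  const int K = logpi.size(), T = logB.ncol();
  NumericMatrix alpha(T, K);
  forward_pass(logpi, logA, logd, logB, alpha);
  std::vector<double> fin(K);
  for (int j = 0; j < K; ++j) fin[j] = alpha(T - 1, j) + logA(j, K);
  return lse(fin, K);
}

// E-step for one sequence: posterior expected counts of initial states,
// transitions (incl. to end), occupancy durations, and per-node state
// membership (gamma). Uses the segment-posterior decomposition
//   P(state j occupies [s, e] | obs) =
//     head(s, j) * d_j(e-s+1) * emis(j, s..e) * beta(e, j) / L
// where beta(t, j) = log P(obs t+1..T, end reached | zone of j ends at t).
// [[Rcpp::export]]
List hsmc_estep_cpp(NumericVector logpi, NumericMatrix logA,
                    NumericMatrix logd, NumericMatrix logB) {
  const int K = logpi.size(), T = logB.ncol(), Dmax = logd.ncol();
  NumericMatrix alpha(T, K);
  forward_pass(logpi, logA, logd, logB, alpha);

  std::vector<double> fin(K);
  for (int j = 0; j < K; ++j) fin[j] = alpha(T - 1, j) + logA(j, K);
  const double loglik = lse(fin, K);

  NumericVector init(K);
  NumericMatrix trans(K, K + 1), dur(K, Dmax), gamma(K, T);
  if (loglik == NEG_INF) {
    return List::create(_["loglik"] = loglik, _["init"] = init,
                        _["trans"] = trans, _["dur"] = dur, _["gamma"] = gamma);
  }

  // beta(t, j), t = 1..T (index t-1). beta(T, j) = logA(j, end).
  NumericMatrix beta(T, K);
  std::vector<double> buf(K * Dmax + 1);
  for (int j = 0; j < K; ++j) beta(T - 1, j) = logA(j, K);
  for (int t = T - 1; t >= 1; --t) {
    for (int j = 0; j < K; ++j) {
      int nb = 0;
      for (int k = j + 1; k < K; ++k) {
        const int umax = std::min(T - t, Dmax);
        double emis = 0.0;
        for (int u = 1; u <= umax; ++u) {
          emis += logB(k, t + u - 1);          // node t+u (1-based)
          buf[nb++] = logA(j, k) + logd(k, u - 1) + emis + beta(t + u - 1, k);
        }
      }
      beta(t - 1, j) = lse(buf, nb);
    }
  }

  // accumulate segment posteriors
  for (int j = 0; j < K; ++j) {
    for (int s = 1; s <= T; ++s) {
      const int umax = std::min(T - s + 1, Dmax);
      double emis = 0.0;
      for (int u = 1; u <= umax; ++u) {
        const int e = s + u - 1;
        emis += logB(j, e - 1);
        const double tail = logd(j, u - 1) + emis + beta(e - 1, j) - loglik;
        if (s == 1) {
          double w = logpi[j] + tail;
          if (w != NEG_INF) {
            const double p = std::exp(w);
            init[j] += p;
            dur(j, u - 1) += p;
            for (int q = s; q <= e; ++q) gamma(j, q - 1) += p;
          }
        } else {
          for (int i = 0; i < j; ++i) {
            double w = alpha(s - 2, i) + logA(i, j) + tail;
            if (w != NEG_INF) {
              const double p = std::exp(w);
              trans(i, j) += p;
              dur(j, u - 1) += p;
              for (int q = s; q <= e; ++q) gamma(j, q - 1) += p;
            }
          }
        }
      }
    }
    // transition to end: the last zone is j
    double w = alpha(T - 1, j) + logA(j, K) - loglik;
    if (w != NEG_INF) trans(j, K) += std::exp(w);
  }

  return List::create(_["loglik"] = loglik, _["init"] = init,
                      _["trans"] = trans, _["dur"] = dur, _["gamma"] = gamma);
}

// Most probable (state, duration) path under the end-state convention.
// Ties are broken deterministically: at every dynamic-programming cell,
// candidates are scanned in order of increasing duration u then increasing
// predecessor state, and replaced only on strict improvement; the final state
// is scanned in increasing index. Hence among equal-probability paths the
// restoration prefers shorter zone durations, earliest-indexed states.
// [[Rcpp::export]]
List hsmc_viterbi_cpp(NumericVector logpi, NumericMatrix logA,
                      NumericMatrix logd, NumericMatrix logB) {
  const int K = logpi.size(), T = logB.ncol(), Dmax = logd.ncol();
  NumericMatrix delta(T, K);
  IntegerMatrix back_u(T, K), back_i(T, K);
  for (int t = 1; t <= T; ++t) {
    for (int j = 0; j < K; ++j) {
      double best = NEG_INF;
      int bu = -1, bi = -1;
      double emis = 0.0;
      const int umax = std::min(t, Dmax);
      for (int u = 1; u <= umax; ++u) {
        emis += logB(j, t - u);
        const double seg = logd(j, u - 1) + emis;
        if (seg == NEG_INF) continue;
        if (u == t) {
          const double v = logpi[j] + seg;
          if (v > best) { best = v; bu = u; bi = -1; }
        } else {
          for (int i = 0; i < j; ++i) {
            const double v = delta(t - u - 1, i) + logA(i, j) + seg;
            if (v > best) { best = v; bu = u; bi = i; }
          }
        }
      }
      delta(t - 1, j) = best;
      back_u(t - 1, j) = bu;
      back_i(t - 1, j) = bi;
    }
  }
  double best = NEG_INF;
  int bj = -1;
  for (int j = 0; j < K; ++j) {
    const double v = delta(T - 1, j) + logA(j, K);
    if (v > best) { best = v; bj = j; }
  }
  if (bj < 0) {
    return List::create(_["state"] = IntegerVector(0),
                        _["start"] = IntegerVector(0),
                        _["length"] = IntegerVector(0),
                        _["logprob"] = NEG_INF);
  }
  std::vector<int> st, len;
  int t = T, j = bj;
  while (t > 0) {
    const int u = back_u(t - 1, j);
    st.push_back(j + 1);
    len.push_back(u);
    const int i = back_i(t - 1, j);
    t -= u;
    j = i;
  }
  const int R = st.size();
  IntegerVector state(R), start(R), length(R);
  int pos = 1;
  for (int r = 0; r < R; ++r) {
    state[r] = st[R - 1 - r];
    length[r] = len[R - 1 - r];
    start[r] = pos;
    pos += length[r];
  }
  return List::create(_["state"] = state, _["start"] = start,
                      _["length"] = length, _["logprob"] = best);
}
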