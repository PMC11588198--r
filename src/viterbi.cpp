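// Duration-explicit Viterbi decoding for a cyclic-topology hidden
// semi-Markov model.  States form a single deterministic cycle, so the only
// free structure is the segment boundaries and the entry state/phase.
//
// Score of a segmentation = sum of per-frame log observation scores plus a
// log duration density for every *complete* segment.  The first and last
// segments may be partial (the recording starts and ends mid-state): they
// contribute observation cost but no duration term, and their observed
// length is capped at the duration-support maximum.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static const double NEG_INF = -std::numeric_limits<double>::infinity();

// [[Rcpp::export]]
List viterbi_duration_cpp(const arma::mat& logB, const IntegerVector& dmin,
                          const IntegerVector& dmax, const List& logdur) {
  const int T = logB.n_rows, S = logB.n_cols;
  if (T < 2) stop("recording too short to decode (need at least 2 frames)");

  // cum(t, s) = sum of logB rows 0..t for state s
  arma::mat cum = arma::cumsum(logB, 0);
  auto seg = [&](int a, int b, int s) { // obs sum over frames a..b (0-based)
    return a == 0 ? cum(b, s) : cum(b, s) - cum(a - 1, s);
  };
  std::vector<arma::vec> ld(S);
  for (int s = 0; s < S; ++s) ld[s] = as<arma::vec>(logdur[s]);

  // delta(t, s): best score of frames 0..t with a segment in s ending at t
  // bp(t, s): duration of that segment; 0 = partial entry segment from 0
  arma::mat delta(T, S);
  delta.fill(NEG_INF);
  arma::imat bp(T, S, arma::fill::zeros);

  for (int t = 0; t < T; ++t) {
    for (int s = 0; s < S; ++s) {
      double best = NEG_INF;
      int bestd = 0;
      if (t + 1 <= dmax[s]) best = seg(0, t, s); // entry partial, no penalty
      const int prev = (s + S - 1) % S;
      const int hi = std::min<int>(dmax[s], t); // need >= 1 frame before
      for (int d = dmin[s]; d <= hi; ++d) {
        double cand = delta(t - d, prev) + seg(t - d + 1, t, s) +
                      ld[s][d - dmin[s]];
        if (cand > best) { best = cand; bestd = d; }
      }
      delta(t, s) = best;
      bp(t, s) = bestd;
    }
  }

  // final segment: either a segment ending exactly at T-1 (delta), an exit
  // partial of length < dmax, or a single partial segment spanning all T
  double best = NEG_INF;
  int best_s = -1, best_t0 = -1; // best_t0 = start of exit partial; -1: delta
  bool best_whole = false;
  for (int s = 0; s < S; ++s) {
    if (delta(T - 1, s) > best) {
      best = delta(T - 1, s); best_s = s; best_t0 = -1; best_whole = false;
    }
    const int prev = (s + S - 1) % S;
    for (int t0 = std::max(1, T - dmax[s]); t0 <= T - 1; ++t0) {
      double cand = delta(t0 - 1, prev) + seg(t0, T - 1, s);
      if (cand > best) {
        best = cand; best_s = s; best_t0 = t0; best_whole = false;
      }
    }
    if (T <= 2 * dmax[s]) { // entry and exit within one state dwell
      double cand = seg(0, T - 1, s);
      if (cand > best) {
        best = cand; best_s = s; best_t0 = 0; best_whole = true;
      }
    }
  }
  if (!std::isfinite(best)) stop("no feasible duration-valid path");

  IntegerVector path(T);
  int s = best_s, t = T - 1;
  if (best_whole) {
    for (int u = 0; u < T; ++u) path[u] = s + 1;
    return List::create(_["path"] = path, _["score"] = best);
  }
  if (best_t0 >= 0) { // exit partial
    for (int u = best_t0; u <= T - 1; ++u) path[u] = s + 1;
    t = best_t0 - 1;
    s = (s + S - 1) % S;
  }
  while (t >= 0) {
    int d = bp(t, s);
    if (d == 0) { // entry partial reaches frame 0
      for (int u = 0; u <= t; ++u) path[u] = s + 1;
      break;
    }
    for (int u = t - d + 1; u <= t; ++u) path[u] = s + 1;
    t -= d;
    s = (s + S - 1) % S;
  }
  return List::create(_["path"] = path, _["score"] = best);
}
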