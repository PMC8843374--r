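// Aligned-fragment-pair (AFP) scan and twist-aware chaining for the flexible
// structural aligner. Fragment RMSDs use the closed-form Kabsch solution
// (singular values of the 3x3 cross-covariance, reflection-corrected).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Kabsch fit of fragment b onto fragment a (both Lx3, not centered).
// Returns rmsd; fills R (3x3) and t (3) with the transform b -> a.
static double kabsch_fit(const arma::mat& a, const arma::mat& b,
                         arma::mat& R, arma::vec& t) {
  const arma::rowvec ca = arma::mean(a, 0), cb = arma::mean(b, 0);
  arma::mat ac = a.each_row() - ca, bc = b.each_row() - cb;
  arma::mat H = bc.t() * ac;
  arma::mat U, V; arma::vec s;
  if (!arma::svd(U, s, V, H)) return arma::datum::inf;
  double d = arma::det(V * U.t()) < 0 ? -1.0 : 1.0;
  arma::mat D = arma::eye(3, 3); D(2, 2) = d;
  R = V * D * U.t();
  t = ca.t() - R * cb.t();
  double e0 = arma::accu(ac % ac) + arma::accu(bc % bc);
  double e = e0 - 2.0 * (s(0) + s(1) + d * s(2));
  if (e < 0) e = 0;
  return std::sqrt(e / a.n_rows);
}

// Scan all gapless fragment pairs of length L with superposed RMSD <= cutoff.
// A, B: n x 3 Calpha coordinates. Rows with NA must be pre-filtered in R.
// [[Rcpp::export(name = ".afp_scan_cpp")]]
List afp_scan_cpp(const arma::mat& A, const arma::mat& B, int L,
                  double cutoff) {
  const int nA = A.n_rows, nB = B.n_rows;
  std::vector<int> sa, sb;
  std::vector<double> rm;
  std::vector<double> Rs, Ts;
  if (nA >= L && nB >= L) {
    arma::mat R(3, 3); arma::vec t(3);
    for (int i = 0; i + L <= nA; ++i) {
      arma::mat fa = A.rows(i, i + L - 1);
      for (int j = 0; j + L <= nB; ++j) {
        arma::mat fb = B.rows(j, j + L - 1);
        double r = kabsch_fit(fa, fb, R, t);
        if (r <= cutoff) {
          sa.push_back(i + 1); sb.push_back(j + 1); rm.push_back(r);
          for (int k = 0; k < 9; ++k) Rs.push_back(R(k % 3, k / 3));
          for (int k = 0; k < 3; ++k) Ts.push_back(t(k));
        }
      }
    }
  }
  const int K = sa.size();
  NumericMatrix Rmat(K, 9), Tmat(K, 3);
  for (int q = 0; q < K; ++q) {
    for (int k = 0; k < 9; ++k) Rmat(q, k) = Rs[q * 9 + k];
    for (int k = 0; k < 3; ++k) Tmat(q, k) = Ts[q * 3 + k];
  }
  return List::create(_["startA"] = wrap(sa), _["startB"] = wrap(sb),
                      _["rmsd"] = wrap(rm), _["R"] = Rmat, _["t"] = Tmat);
}

static double rot_angle(const arma::mat& R1, const arma::mat& R2) {
  double tr = arma::trace(R1.t() * R2);
  double c = (tr - 1.0) / 2.0;
  if (c > 1) c = 1; if (c < -1) c = -1;
  return std::acos(c) * 180.0 / M_PI;
}

// Chain AFPs by dynamic programming, monotone in both sequences, charging a
// twist whenever consecutive chained AFPs are incompatible with one rigid
// transform (rotation-angle difference > angle_max degrees or translation
// difference > trans_max angstroms). At most max_twists twists.
// Returns 1-based indices of the chained AFPs plus a twist flag per link.
// [[Rcpp::export(name = ".chain_afps_cpp")]]
List chain_afps_cpp(const IntegerVector& startA, const IntegerVector& startB,
                    const NumericVector& rmsd, const NumericMatrix& Rmat,
                    const NumericMatrix& Tmat, int L, double cutoff,
                    double gap_open, double gap_extend, double twist_penalty,
                    int max_twists, double angle_max, double trans_max) {
  const int K = startA.size();
  if (K == 0) return List::create(_["chain"] = IntegerVector(0),
                                  _["twist"] = LogicalVector(0),
                                  _["score"] = 0.0);
  // order by (startA, startB)
  std::vector<int> ord(K);
  for (int i = 0; i < K; ++i) ord[i] = i;
  std::sort(ord.begin(), ord.end(), [&](int x, int y) {
    if (startA[x] != startA[y]) return startA[x] < startA[y];
    return startB[x] < startB[y];
  });
  std::vector<arma::mat> Rl(K);
  std::vector<arma::vec> Tl(K);
  for (int q = 0; q < K; ++q) {
    arma::mat R(3, 3);
    for (int k = 0; k < 9; ++k) R(k % 3, k / 3) = Rmat(q, k);
    Rl[q] = R;
    arma::vec t(3);
    for (int k = 0; k < 3; ++k) t(k) = Tmat(q, k);
    Tl[q] = t;
  }
  const int T = max_twists + 1;
  std::vector<double> best(K * T, -1e18);
  std::vector<int> prev(K * T, -1), ptw(K * T, 0);
  for (int q = 0; q < K; ++q)
    best[q * T] = L * (cutoff - rmsd[ord[q]]);
  for (int jj = 0; jj < K; ++jj) {
    const int j = ord[jj];
    const int aj = startA[j], bj = startB[j];
    for (int ii = 0; ii < jj; ++ii) {
      const int i = ord[ii];
      const int ai = startA[i], bi = startB[i];
      if (aj <= ai || bj <= bi) continue;
      const bool same_diag = (aj - ai) == (bj - bi);
      if (!same_diag && (aj < ai + L || bj < bi + L)) continue;
      double gA = std::max(0, aj - (ai + L));
      double gB = std::max(0, bj - (bi + L));
      double g = gA + gB;
      double gap_cost = g > 0 ? gap_open + gap_extend * (g - 1) : 0.0;
      int newlen = same_diag ? std::min(L, aj - ai) : L;
      double node = newlen * (cutoff - rmsd[j]);
      bool twist = rot_angle(Rl[i], Rl[j]) > angle_max ||
                   arma::norm(Tl[i] - Tl[j]) > trans_max;
      for (int t = 0; t < T; ++t) {
        double base = best[ii * T + t];
        if (base <= -1e17) continue;
        int tn = t + (twist ? 1 : 0);
        if (tn >= T) continue;
        double cand = base + node - gap_cost -
                      (twist ? twist_penalty : 0.0);
        if (cand > best[jj * T + tn]) {
          best[jj * T + tn] = cand;
          prev[jj * T + tn] = ii * T + t;
          ptw[jj * T + tn] = twist ? 1 : 0;
        }
      }
    }
  }
  double bs = -1e18; int bq = -1;
  for (int q = 0; q < K * T; ++q)
    if (best[q] > bs) { bs = best[q]; bq = q; }
  std::vector<int> chain;
  std::vector<int> twists;
  int cur = bq;
  while (cur >= 0) {
    chain.push_back(ord[cur / T] + 1);
    twists.push_back(ptw[cur]);
    cur = prev[cur];
  }
  std::reverse(chain.begin(), chain.end());
  std::reverse(twists.begin(), twists.end());
  // twist flag belongs to the link *into* each AFP; first has none
  LogicalVector tw(chain.size());
  for (size_t k = 0; k < chain.size(); ++k) tw[k] = twists[k] == 1;
  tw[0] = false;
  return List::create(_["chain"] = wrap(chain), _["twist"] = tw,
                      _["score"] = bs);
}
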