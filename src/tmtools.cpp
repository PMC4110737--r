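// Rigid-body superposition and TM-score machinery.
//
// Coordinates are row-vector matrices (n x 3, Angstroms). A transform
// (R, t) maps model coordinates into the reference frame as x * R + t.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// Least-squares proper rotation of A onto B (Kabsch via SVD).
static void kabsch_core(const mat& A, const mat& B, mat& R, rowvec& t,
                        double& rmsd) {
  rowvec ca = mean(A, 0), cb = mean(B, 0);
  mat Ac = A.each_row() - ca, Bc = B.each_row() - cb;
  mat C = Ac.t() * Bc;
  mat U, V;
  vec s;
  if (!svd(U, s, V, C)) Rcpp::stop("SVD failed in Kabsch superposition");
  double d = det(U * V.t());
  mat D = eye<mat>(3, 3);
  D(2, 2) = (d < 0) ? -1.0 : 1.0;
  R = U * D * V.t();
  t = cb - ca * R;
  mat diff = Ac * R - Bc;
  rmsd = std::sqrt(accu(diff % diff) / A.n_rows);
}

// [[Rcpp::export]]
Rcpp::List cpp_kabsch(const arma::mat& A, const arma::mat& B) {
  if (A.n_rows != B.n_rows)
    Rcpp::stop("coordinate sets must have equal length");
  if (A.n_rows < 3)
    Rcpp::stop("at least 3 points are required");
  mat R;
  rowvec t;
  double rmsd;
  kabsch_core(A, B, R, t, rmsd);
  return Rcpp::List::create(Rcpp::Named("rotation") = R,
                            Rcpp::Named("translation") = t,
                            Rcpp::Named("rmsd") = rmsd);
}

static inline double tm_sum(const mat& A, const mat& B, const mat& R,
                            const rowvec& t, double d0, vec& d) {
  mat Af = A * R;
  Af.each_row() += t;
  mat diff = Af - B;
  d = sqrt(sum(diff % diff, 1));
  double s = 0.0, d02 = d0 * d0;
  for (uword i = 0; i < d.n_elem; ++i) s += 1.0 / (1.0 + d(i) * d(i) / d02);
  return s;
}

// TM-score style superposition search over an established correspondence:
// fragment seeds of several lengths, each refined by iterative
// close-residue reselection; the returned transform maximizes
// sum_i 1/(1+(d_i/d0)^2) over all pairs.
static double tm_search(const mat& A, const mat& B, double d0, mat& Rbest,
                        rowvec& tbest, int seed_min) {
  int n = A.n_rows;
  if (n < 3) Rcpp::stop("chain too short");
  std::vector<int> lens;
  for (int L = n; L >= std::max(4, seed_min); L /= 2) lens.push_back(L);
  if (lens.empty() || lens.back() > 4) lens.push_back(std::min(n, 4));
  double best = -1.0;
  vec d;
  mat R;
  rowvec t;
  for (size_t li = 0; li < lens.size(); ++li) {
    int L = lens[li];
    int step = std::max(1, (n - L) / 40 + 1);
    for (int s0 = 0; s0 + L <= n; s0 += step) {
      mat As = A.rows(s0, s0 + L - 1), Bs = B.rows(s0, s0 + L - 1);
      double rms;
      kabsch_core(As, Bs, R, t, rms);
      uvec prev;
      for (int it = 0; it < 20; ++it) {
        double sc = tm_sum(A, B, R, t, d0, d);
        if (sc > best) {
          best = sc;
          Rbest = R;
          tbest = t;
        }
        double dcut = std::max(d0, 3.0);
        uvec sel = find(d < dcut);
        while (sel.n_elem < 3 && dcut < 50.0) {
          dcut += 0.5;
          sel = find(d < dcut);
        }
        if (sel.n_elem < 3) break;
        if (prev.n_elem == sel.n_elem && all(prev == sel)) break;
        prev = sel;
        kabsch_core(A.rows(sel), B.rows(sel), R, t, rms);
      }
    }
  }
  return best;
}

// [[Rcpp::export]]
Rcpp::List cpp_tmscore(const arma::mat& A, const arma::mat& B, double d0,
                       double Ln, int seed_min = 4) {
  if (A.n_rows != B.n_rows) Rcpp::stop("paired coordinates required");
  mat R;
  rowvec t;
  double best = tm_search(A, B, d0, R, t, seed_min);
  vec d;
  tm_sum(A, B, R, t, d0, d);
  double rmsd = std::sqrt(accu(d % d) / d.n_elem);
  return Rcpp::List::create(Rcpp::Named("tm") = best / Ln,
                            Rcpp::Named("rotation") = R,
                            Rcpp::Named("translation") = t,
                            Rcpp::Named("rmsd") = rmsd,
                            Rcpp::Named("distances") = d);
}

// Needleman-Wunsch with a flat gap penalty and free end gaps
// (semi-global); ties resolved toward the diagonal so the traceback is
// deterministic.
static void nwdp(const mat& S, double gap, std::vector<int>& ai,
                 std::vector<int>& bi) {
  int n = S.n_rows, m = S.n_cols;
  mat H(n + 1, m + 1, fill::zeros);
  Mat<int> P(n + 1, m + 1, fill::zeros);  // 1 diag, 2 up, 3 left
  for (int i = 1; i <= n; ++i) P(i, 0) = 2;
  for (int j = 1; j <= m; ++j) P(0, j) = 3;
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      double dg = H(i - 1, j - 1) + S(i - 1, j - 1);
      double up = H(i - 1, j) + gap;
      double lf = H(i, j - 1) + gap;
      if (dg >= up && dg >= lf) {
        H(i, j) = dg;
        P(i, j) = 1;
      } else if (up >= lf) {
        H(i, j) = up;
        P(i, j) = 2;
      } else {
        H(i, j) = lf;
        P(i, j) = 3;
      }
    }
  }
  // trailing gaps are free: start traceback at the best edge cell
  int si = n, sj = m;
  double bestH = H(n, m);
  for (int i = 1; i <= n; ++i)
    if (H(i, m) > bestH) {
      bestH = H(i, m);
      si = i;
      sj = m;
    }
  for (int j = 1; j <= m; ++j)
    if (H(n, j) > bestH) {
      bestH = H(n, j);
      si = n;
      sj = j;
    }
  ai.clear();
  bi.clear();
  int i = si, j = sj;
  while (i > 0 || j > 0) {
    int p = P(i, j);
    if (p == 1) {
      ai.push_back(i);
      bi.push_back(j);
      --i;
      --j;
    } else if (p == 2) {
      --i;
    } else {
      --j;
    }
  }
  std::reverse(ai.begin(), ai.end());
  std::reverse(bi.begin(), bi.end());
}

// [[Rcpp::export]]
Rcpp::IntegerMatrix cpp_nwdp(const arma::mat& S, double gap) {
  std::vector<int> ai, bi;
  nwdp(S, gap, ai, bi);
  Rcpp::IntegerMatrix out(ai.size(), 2);
  for (size_t k = 0; k < ai.size(); ++k) {
    out(k, 0) = ai[k];
    out(k, 1) = bi[k];
  }
  return out;
}

// Coarse CA-distance secondary-structure states used only to seed the
// aligner: 2 helix, 4 strand, 1 coil.
static Col<int> sec_ca(const mat& X) {
  int n = X.n_rows;
  Col<int> s(n, fill::ones);
  for (int i = 2; i < n - 2; ++i) {
    double d13 = norm(X.row(i - 2) - X.row(i));
    double d14 = norm(X.row(i - 2) - X.row(i + 1));
    double d15 = norm(X.row(i - 2) - X.row(i + 2));
    double d24 = norm(X.row(i - 1) - X.row(i + 1));
    double d25 = norm(X.row(i - 1) - X.row(i + 2));
    double d35 = norm(X.row(i) - X.row(i + 2));
    if (std::fabs(d15 - 6.37) < 1.42 && std::fabs(d14 - 5.18) < 1.42 &&
        std::fabs(d25 - 5.18) < 1.42 && std::fabs(d13 - 5.45) < 1.42 &&
        std::fabs(d24 - 5.45) < 1.42 && std::fabs(d35 - 5.45) < 1.42)
      s(i) = 2;
    else if (d15 > 10.0 && d13 > 5.0 && d35 > 5.0)
      s(i) = 4;
  }
  return s;
}

struct AlnState {
  std::vector<int> ai, bi;
  double tm;
  mat R;
  rowvec t;
};

static double score_pairs(const mat& A, const mat& B,
                          const std::vector<int>& ai,
                          const std::vector<int>& bi, double d0, double Ln,
                          mat& R, rowvec& t) {
  int L = ai.size();
  if (L < 3) return -1.0;
  mat Aa(L, 3), Bb(L, 3);
  for (int k = 0; k < L; ++k) {
    Aa.row(k) = A.row(ai[k] - 1);
    Bb.row(k) = B.row(bi[k] - 1);
  }
  double s = tm_search(Aa, Bb, d0, R, t, 4);
  return s / Ln;
}

// Sequence-independent structural alignment: gapless-threading, secondary
// structure and combined seeds, each refined by iterating
// {TM-optimal superposition -> distance score matrix -> DP} to a fixed
// point (cap 30 iterations); the highest-TM alignment wins.
// [[Rcpp::export]]
Rcpp::List cpp_tmalign(const arma::mat& A, const arma::mat& B, double d0,
                       double Ln, double gap = -0.6, int maxit = 30) {
  int n = A.n_rows, m = B.n_rows;
  if (n < 5 || m < 5) Rcpp::stop("both chains need at least 5 residues");
  std::vector<AlnState> inits;

  // 1) gapless threading: keep the two best offsets by quick TM sum
  {
    double b1 = -1, b2 = -1;
    int o1 = 0, o2 = 0;
    for (int off = -(m - 5); off <= n - 5; ++off) {
      int lo_a = std::max(1, 1 + off), hi_a = std::min(n, m + off);
      int L = hi_a - lo_a + 1;
      if (L < 5) continue;
      mat Aa(L, 3), Bb(L, 3);
      for (int k = 0; k < L; ++k) {
        Aa.row(k) = A.row(lo_a - 1 + k);
        Bb.row(k) = B.row(lo_a - off - 1 + k);
      }
      mat R;
      rowvec t;
      double rms;
      kabsch_core(Aa, Bb, R, t, rms);
      vec d;
      double sc = tm_sum(Aa, Bb, R, t, d0, d);
      if (sc > b1) {
        b2 = b1;
        o2 = o1;
        b1 = sc;
        o1 = off;
      } else if (sc > b2) {
        b2 = sc;
        o2 = off;
      }
    }
    for (int which = 0; which < 2; ++which) {
      int off = which == 0 ? o1 : o2;
      if ((which == 1 && b2 < 0) || (which == 0 && b1 < 0)) continue;
      AlnState st;
      int lo_a = std::max(1, 1 + off), hi_a = std::min(n, m + off);
      for (int i = lo_a; i <= hi_a; ++i) {
        st.ai.push_back(i);
        st.bi.push_back(i - off);
      }
      inits.push_back(st);
    }
  }

  // 2) secondary-structure DP seed
  {
    Col<int> sa = sec_ca(A), sb = sec_ca(B);
    mat S(n, m);
    for (int i = 0; i < n; ++i)
      for (int j = 0; j < m; ++j) S(i, j) = (sa(i) == sb(j)) ? 1.0 : 0.0;
    AlnState st;
    nwdp(S, 0.0, st.ai, st.bi);
    if ((int)st.ai.size() >= 3) inits.push_back(st);
  }

  // 3) combined distance + SS seed from the best threading superposition
  if (!inits.empty()) {
    mat R;
    rowvec t;
    double tm0 = score_pairs(A, B, inits[0].ai, inits[0].bi, d0, Ln, R, t);
    if (tm0 > 0) {
      Col<int> sa = sec_ca(A), sb = sec_ca(B);
      mat Af = A * R;
      Af.each_row() += t;
      mat S(n, m);
      double d02 = d0 * d0;
      for (int i = 0; i < n; ++i)
        for (int j = 0; j < m; ++j) {
          double dd = accu(square(Af.row(i) - B.row(j)));
          S(i, j) = 1.0 / (1.0 + dd / d02) + (sa(i) == sb(j) ? 0.5 : 0.0);
        }
      AlnState st;
      nwdp(S, gap, st.ai, st.bi);
      if ((int)st.ai.size() >= 3) inits.push_back(st);
    }
  }

  AlnState best;
  best.tm = -1.0;
  double d02 = d0 * d0;
  for (size_t s0 = 0; s0 < inits.size(); ++s0) {
    std::vector<int> ai = inits[s0].ai, bi = inits[s0].bi;
    std::vector<int> pa, pb;
    for (int it = 0; it < maxit; ++it) {
      mat R;
      rowvec t;
      double tm = score_pairs(A, B, ai, bi, d0, Ln, R, t);
      if (tm < 0) break;
      if (tm > best.tm) {
        best.tm = tm;
        best.ai = ai;
        best.bi = bi;
        best.R = R;
        best.t = t;
      }
      mat Af = A * R;
      Af.each_row() += t;
      mat S(n, m);
      for (int i = 0; i < n; ++i)
        for (int j = 0; j < m; ++j) {
          double dd = accu(square(Af.row(i) - B.row(j)));
          S(i, j) = 1.0 / (1.0 + dd / d02);
        }
      std::vector<int> nai, nbi;
      nwdp(S, gap, nai, nbi);
      if (nai == ai && nbi == bi) break;
      if (nai == pa && nbi == pb) break;  // 2-cycle
      pa = ai;
      pb = bi;
      ai = nai;
      bi = nbi;
    }
  }
  if (best.tm < 0) Rcpp::stop("alignment failed: degenerate input");

  Rcpp::IntegerMatrix pairs(best.ai.size(), 2);
  for (size_t k = 0; k < best.ai.size(); ++k) {
    pairs(k, 0) = best.ai[k];
    pairs(k, 1) = best.bi[k];
  }
  return Rcpp::List::create(Rcpp::Named("pairs") = pairs,
                            Rcpp::Named("tm") = best.tm,
                            Rcpp::Named("rotation") = best.R,
                            Rcpp::Named("translation") = best.t);
}
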