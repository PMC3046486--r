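#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <vector>

using namespace Rcpp;

// Metric codes shared with R/similarity.R: 0 = pearson, 1 = spearman,
// 2 = euclidean.  "Better" means larger for correlations, smaller for
// euclidean distance; all searches are arg-best under that orientation.

static inline bool better(double a, double b, int metric) {
  return metric == 2 ? (a < b) : (a > b);
}

// Pearson correlation from sufficient statistics over a window of length w.
// A (numerically) zero-variance side yields the defined degenerate score 0.
static inline double pearson_from_sums(double sx, double sxx, double sy,
                                       double syy, double sxy, int w) {
  double vx = w * sxx - sx * sx;
  double vy = w * syy - sy * sy;
  double tolx = 1e-12 * (std::fabs(w * sxx) + sx * sx + 1.0);
  double toly = 1e-12 * (std::fabs(w * syy) + sy * sy + 1.0);
  if (vx <= tolx || vy <= toly) return 0.0;
  return (w * sxy - sx * sy) / std::sqrt(vx * vy);
}

// mid-ranks (average rank for ties)
static std::vector<double> rank_avg(const double* x, int n) {
  std::vector<int> idx(n);
  for (int i = 0; i < n; ++i) idx[i] = i;
  std::sort(idx.begin(), idx.end(),
            [&](int a, int b) { return x[a] < x[b]; });
  std::vector<double> r(n);
  int i = 0;
  while (i < n) {
    int j = i;
    while (j + 1 < n && x[idx[j + 1]] == x[idx[i]]) ++j;
    double avg = 0.5 * (i + j) + 1.0;  // ranks are 1-based
    for (int k = i; k <= j; ++k) r[idx[k]] = avg;
    i = j + 1;
  }
  return r;
}

static double score_vectors(const double* x, const double* y, int w,
                            int metric) {
  if (metric == 2) {
    double s = 0.0;
    for (int k = 0; k < w; ++k) {
      double d = x[k] - y[k];
      s += d * d;
    }
    return std::sqrt(s);
  }
  std::vector<double> rx, ry;
  const double *px = x, *py = y;
  if (metric == 1) {
    rx = rank_avg(x, w);
    ry = rank_avg(y, w);
    px = rx.data();
    py = ry.data();
  }
  double sx = 0, sy = 0, sxx = 0, syy = 0, sxy = 0;
  for (int k = 0; k < w; ++k) {
    sx += px[k];
    sy += py[k];
    sxx += px[k] * px[k];
    syy += py[k] * py[k];
    sxy += px[k] * py[k];
  }
  return pearson_from_sums(sx, sxx, sy, syy, sxy, w);
}

// [[Rcpp::export]]
double cpp_score(NumericVector x, NumericVector y, int metric) {
  if (x.size() != y.size()) stop("length mismatch");
  return score_vectors(REAL(x), REAL(y), x.size(), metric);
}

struct Hit {
  int region = -1;   // 0-based
  int start = -1;    // 0-based bin offset
  bool rev = false;
  double score = NA_REAL;
  bool set = false;
};

// Scan all placements of one region (a column of Zt, m x n) against profile
// p (length w).  Enumeration order within the region: un-reversed placements
// at ascending start, then reversed placements at ascending start; only a
// strictly better score replaces the incumbent, so the first-encountered
// placement wins ties.
static void scan_one_region(const double* z, int m, const double* p,
                            const double* pr, double sp, double spp, int w,
                            int metric, bool allow_rev, int region, Hit& best,
                            long long& n_cand) {
  int S = m - w;
  if (metric == 1) {
    // spearman: rank each candidate window, then pearson against rank(p)
    for (int rev = 0; rev <= (allow_rev ? 1 : 0); ++rev) {
      const double* prof = rev ? pr : p;
      for (int s = 0; s < S; ++s) {
        std::vector<double> rz = rank_avg(z + s, w);
        // reversed window == window scored against reversed profile ranks
        double sx = 0, sxx = 0, sxy = 0;
        for (int k = 0; k < w; ++k) {
          sx += rz[k];
          sxx += rz[k] * rz[k];
          sxy += rz[k] * prof[k];
        }
        double sc = pearson_from_sums(sx, sxx, sp, spp, sxy, w);
        ++n_cand;
        if (!best.set || better(sc, best.score, metric)) {
          best.set = true;
          best.region = region;
          best.start = s;
          best.rev = rev != 0;
          best.score = sc;
        }
      }
    }
    return;
  }
  // pearson / euclidean: prefix sums over z for window sums; sliding dot
  // products against p (forward score) and reversed p (score of the
  // reversed window), accumulated start-major so the inner loop vectorizes
  std::vector<double> cs1(m + 1, 0.0), cs2(m + 1, 0.0);
  for (int k = 0; k < m; ++k) {
    cs1[k + 1] = cs1[k] + z[k];
    cs2[k + 1] = cs2[k] + z[k] * z[k];
  }
  std::vector<double> dotf(S, 0.0), dotr;
  if (allow_rev) dotr.assign(S, 0.0);
  if (allow_rev) {
    for (int k = 0; k < w; ++k) {
      const double pk = p[k], qk = pr[k];
      const double* zk = z + k;
      double* df = dotf.data();
      double* dr = dotr.data();
      for (int s = 0; s < S; ++s) {
        df[s] += zk[s] * pk;
        dr[s] += zk[s] * qk;
      }
    }
  } else {
    for (int k = 0; k < w; ++k) {
      const double pk = p[k];
      const double* zk = z + k;
      double* df = dotf.data();
      for (int s = 0; s < S; ++s) df[s] += zk[s] * pk;
    }
  }
  for (int rev = 0; rev <= (allow_rev ? 1 : 0); ++rev) {
    const double* dots = rev ? dotr.data() : dotf.data();
    for (int s = 0; s < S; ++s) {
      double sx = cs1[s + w] - cs1[s];
      double sxx = cs2[s + w] - cs2[s];
      double dot = dots[s];
      double sc;
      if (metric == 2) {
        double d2 = sxx - 2.0 * dot + spp;
        sc = std::sqrt(d2 > 0 ? d2 : 0.0);
      } else {
        sc = pearson_from_sums(sx, sxx, sp, spp, dot, w);
      }
      ++n_cand;
      if (!best.set || better(sc, best.score, metric)) {
        best.set = true;
        best.region = region;
        best.start = s;
        best.rev = rev != 0;
        best.score = sc;
      }
    }
  }
}

static void profile_stats(const double* p, int w, int metric,
                          std::vector<double>& pf, std::vector<double>& pr,
                          double& sp, double& spp) {
  pf.assign(p, p + w);
  if (metric == 1) {
    pf = rank_avg(p, w);
  }
  pr.assign(pf.rbegin(), pf.rend());
  sp = spp = 0.0;
  for (int k = 0; k < w; ++k) {
    sp += pf[k];
    spp += pf[k] * pf[k];
  }
}

// Best placement of each eligible region (1-based indices, scanned in the
// given order) against profile p; returns the single best hit overall.
// [[Rcpp::export]]
List cpp_best_vs_profile(NumericMatrix Zt, NumericVector p,
                         IntegerVector regions, int w, int metric,
                         bool allow_rev) {
  int m = Zt.nrow();
  if (p.size() != w) stop("profile length must equal frame_bins");
  if (m - w <= 0) stop("frame_bins must be smaller than the region length");
  std::vector<double> pf, pr;
  double sp, spp;
  profile_stats(REAL(p), w, metric, pf, pr, sp, spp);
  Hit best;
  long long n_cand = 0;
  for (int ii = 0; ii < regions.size(); ++ii) {
    int r = regions[ii] - 1;
    scan_one_region(&Zt(0, r), m, pf.data(), pr.data(), sp, spp, w, metric,
                    allow_rev, r, best, n_cand);
  }
  return List::create(_["region"] = best.region + 1, _["start"] = best.start,
                      _["rev"] = best.rev, _["score"] = best.score,
                      _["n_candidates"] = (double)n_cand);
}

// Anchor-and-slide pair search: the anchor region i sits fixed at the
// centered placement (start = S %/% 2, un-reversed); every region in js
// slides over all S starts (and reversed copies when allowed).
// [[Rcpp::export]]
List cpp_best_pair(NumericMatrix Zt, int i, IntegerVector js, int w,
                   int metric, bool allow_rev) {
  int m = Zt.nrow();
  int S = m - w;
  if (S <= 0) stop("frame_bins must be smaller than the region length");
  int anchor_start = S / 2;
  std::vector<double> win(w);
  for (int k = 0; k < w; ++k) win[k] = Zt(anchor_start + k, i - 1);
  std::vector<double> pf, pr;
  double sp, spp;
  profile_stats(win.data(), w, metric, pf, pr, sp, spp);
  Hit best;
  long long n_cand = 0;
  for (int jj = 0; jj < js.size(); ++jj) {
    int r = js[jj] - 1;
    if (r == i - 1) stop("anchor region cannot be its own partner");
    scan_one_region(&Zt(0, r), m, pf.data(), pr.data(), sp, spp, w, metric,
                    allow_rev, r, best, n_cand);
  }
  return List::create(_["anchor_start"] = anchor_start,
                      _["region"] = best.region + 1, _["start"] = best.start,
                      _["rev"] = best.rev, _["score"] = best.score,
                      _["n_candidates"] = (double)n_cand);
}

static void copy_window(const double* z, int start, bool rev, int w,
                        double* out) {
  if (rev) {
    for (int k = 0; k < w; ++k) out[k] = z[start + w - 1 - k];
  } else {
    for (int k = 0; k < w; ++k) out[k] = z[start + k];
  }
}

// Progressive greedy alignment from a fixed seed placement (Scheme:
// consensus = mean of the two seed windows; then repeatedly commit the
// single best (region, placement) against the running consensus P and fold
// it in by the running mean P <- (P*(i-1) + window)/i).
// [[Rcpp::export]]
List cpp_greedy_from_seed(NumericMatrix Zt, int si, int sj, int start_i,
                          int start_j, bool rev_i, bool rev_j,
                          double seed_score, int w, int metric,
                          bool allow_rev) {
  int m = Zt.nrow();
  int n = Zt.ncol();
  if (m - w <= 0) stop("frame_bins must be smaller than the region length");
  if (si == sj) stop("seed regions must differ");
  IntegerVector start(n, NA_INTEGER);
  LogicalVector rev(n);
  NumericVector score(n, NA_REAL);
  IntegerVector order(n);
  std::vector<bool> done(n, false);

  std::vector<double> P(w), wi(w), wj(w);
  copy_window(&Zt(0, si - 1), start_i, rev_i, w, wi.data());
  copy_window(&Zt(0, sj - 1), start_j, rev_j, w, wj.data());
  for (int k = 0; k < w; ++k) P[k] = 0.5 * (wi[k] + wj[k]);
  start[si - 1] = start_i;
  rev[si - 1] = rev_i;
  start[sj - 1] = start_j;
  rev[sj - 1] = rev_j;
  score[si - 1] = seed_score;
  score[sj - 1] = seed_score;
  order[0] = si;
  order[1] = sj;
  done[si - 1] = done[sj - 1] = true;

  std::vector<double> win(w);
  for (int committed = 2; committed < n; ++committed) {
    std::vector<double> pf, pr;
    double sp, spp;
    profile_stats(P.data(), w, metric, pf, pr, sp, spp);
    Hit best;
    long long n_cand = 0;
    for (int r = 0; r < n; ++r) {
      if (done[r]) continue;
      scan_one_region(&Zt(0, r), m, pf.data(), pr.data(), sp, spp, w, metric,
                      allow_rev, r, best, n_cand);
    }
    int r = best.region;
    done[r] = true;
    start[r] = best.start;
    rev[r] = best.rev;
    score[r] = best.score;
    order[committed] = r + 1;
    copy_window(&Zt(0, r), best.start, best.rev, w, win.data());
    double inv = 1.0 / (committed + 1);
    for (int k = 0; k < w; ++k) P[k] = (P[k] * committed + win[k]) * inv;
  }
  return List::create(_["start"] = start, _["rev"] = rev, _["score"] = score,
                      _["order"] = order,
                      _["consensus"] = NumericVector(P.begin(), P.end()));
}

// Orientation-resolved aligned windows, w x n (one column per region).
// [[Rcpp::export]]
NumericMatrix cpp_aligned_windows(NumericMatrix Zt, IntegerVector start,
                                  LogicalVector rev, int w) {
  int n = Zt.ncol();
  NumericMatrix W(w, n);
  for (int r = 0; r < n; ++r)
    copy_window(&Zt(0, r), start[r], rev[r], w, &W(0, r));
  return W;
}

// Mean pairwise metric over all C(n,2) unordered pairs of aligned windows.
// [[Rcpp::export]]
double cpp_quality(NumericMatrix Wt, int metric) {
  int w = Wt.nrow();
  int n = Wt.ncol();
  if (n < 2) stop("need at least two aligned windows");
  NumericMatrix R = Wt;
  if (metric == 1) {
    R = NumericMatrix(w, n);
    for (int c = 0; c < n; ++c) {
      std::vector<double> rk = rank_avg(&Wt(0, c), w);
      std::copy(rk.begin(), rk.end(), &R(0, c));
    }
  }
  int eff_metric = (metric == 1) ? 0 : metric;  // ranks already taken
  double total = 0.0;
  for (int a = 0; a < n - 1; ++a)
    for (int b = a + 1; b < n; ++b)
      total += score_vectors(&R(0, a), &R(0, b), w, eff_metric);
  return total / (0.5 * n * (n - 1));
}
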