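#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <limits>
using namespace Rcpp;

// Diagonal-covariance Gaussian mixture fitted by expectation-maximization.
// Restarts use R's RNG stream so results are governed by set.seed(). The
// log-likelihood trace of the winning restart is returned so callers can
// assert its monotonicity. The E and M steps are fused into one pass over
// a row-major copy of the data, accumulating weighted first and second
// moments instead of materializing the responsibility matrix.

static const double LOG2PI = 1.8378770664093454836;

// [[Rcpp::export]]
List fit_em_gmm_cpp(NumericMatrix X, int k, int n_init = 10,
                    int max_iter = 500, double tol = 1e-6,
                    double var_floor = 1e-6) {
  const int n = X.nrow(), d = X.ncol();
  if (k < 1) stop("k must be >= 1");
  if (k > n) stop("k (%d) exceeds the number of rows (%d)", k, n);

  // row-major copy: point i occupies Xb[i*d .. i*d+d-1]
  std::vector<double> Xb(n * d);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < d; ++j) Xb[i * d + j] = X(i, j);

  // overall column variances for initialization
  std::vector<double> col_var(d);
  for (int j = 0; j < d; ++j) {
    double m = 0.0;
    for (int i = 0; i < n; ++i) m += Xb[i * d + j];
    m /= n;
    double v = 0.0;
    for (int i = 0; i < n; ++i) {
      double diff = Xb[i * d + j] - m;
      v += diff * diff;
    }
    col_var[j] = std::max(v / n, var_floor);
  }

  double best_ll = -std::numeric_limits<double>::infinity();
  std::vector<double> best_w, best_mu, best_var, best_trace;
  std::vector<int> best_lab(n);
  int best_iter = 0;
  bool have_fit = false;

  std::vector<double> w(k), mu(k * d), var(k * d);
  std::vector<double> lconst(k), inv_var(k * d), lp(k);
  std::vector<double> acc_n(k), acc_x(k * d), acc_x2(k * d);
  std::vector<int> lab(n);
  std::vector<double> mind2(n);

  for (int init = 0; init < n_init; ++init) {
    for (int attempt = 0; attempt < 5; ++attempt) {
      // k-means++-style seeding: first center uniform, later centers
      // drawn proportional to squared distance from the nearest one
      std::vector<int> idx(k);
      std::fill(mind2.begin(), mind2.end(),
                std::numeric_limits<double>::infinity());
      idx[0] = std::min((int)std::floor(unif_rand() * n), n - 1);
      for (int c = 1; c < k; ++c) {
        double total = 0.0;
        const double *prev = &Xb[idx[c - 1] * d];
        for (int i = 0; i < n; ++i) {
          double s = 0.0;
          const double *xi = &Xb[i * d];
          for (int j = 0; j < d; ++j) {
            double diff = xi[j] - prev[j];
            s += diff * diff;
          }
          if (s < mind2[i]) mind2[i] = s;
          total += mind2[i];
        }
        double u = unif_rand() * total, acc = 0.0;
        int pick = n - 1;
        for (int i = 0; i < n; ++i) {
          acc += mind2[i];
          if (acc >= u) { pick = i; break; }
        }
        idx[c] = pick;
      }
      for (int c = 0; c < k; ++c) {
        w[c] = 1.0 / k;
        for (int j = 0; j < d; ++j) {
          mu[c * d + j] = Xb[idx[c] * d + j];
          var[c * d + j] = col_var[j];
        }
      }

      std::vector<double> trace;
      double prev_ll = -std::numeric_limits<double>::infinity();
      bool degenerate = false, converged = false;
      int it = 0;
      for (it = 0; it < max_iter; ++it) {
        for (int c = 0; c < k; ++c) {
          double lv = 0.0;
          for (int j = 0; j < d; ++j) {
            lv += std::log(var[c * d + j]);
            inv_var[c * d + j] = 1.0 / var[c * d + j];
          }
          lconst[c] = std::log(w[c]) - 0.5 * (d * LOG2PI + lv);
        }
        std::fill(acc_n.begin(), acc_n.end(), 0.0);
        std::fill(acc_x.begin(), acc_x.end(), 0.0);
        std::fill(acc_x2.begin(), acc_x2.end(), 0.0);
        double ll = 0.0;
        for (int i = 0; i < n; ++i) {
          const double *xi = &Xb[i * d];
          double mx = -std::numeric_limits<double>::infinity();
          int arg = 0;
          for (int c = 0; c < k; ++c) {
            double v = lconst[c];
            const double *mc = &mu[c * d];
            const double *ic = &inv_var[c * d];
            for (int j = 0; j < d; ++j) {
              double diff = xi[j] - mc[j];
              v -= 0.5 * diff * diff * ic[j];
            }
            lp[c] = v;
            if (v > mx) { mx = v; arg = c; }
          }
          double s = 0.0;
          for (int c = 0; c < k; ++c) s += std::exp(lp[c] - mx);
          double lse = mx + std::log(s);
          ll += lse;
          lab[i] = arg + 1;
          for (int c = 0; c < k; ++c) {
            double r = std::exp(lp[c] - lse);
            acc_n[c] += r;
            double *ax = &acc_x[c * d];
            double *ax2 = &acc_x2[c * d];
            for (int j = 0; j < d; ++j) {
              double rx = r * xi[j];
              ax[j] += rx;
              ax2[j] += rx * xi[j];
            }
          }
        }
        trace.push_back(ll);
        if (it > 0 && ll - prev_ll < tol) { prev_ll = ll; converged = true; break; }
        prev_ll = ll;
        // M-step from accumulated moments
        for (int c = 0; c < k; ++c) {
          if (acc_n[c] < 1e-8) { degenerate = true; break; }
          w[c] = acc_n[c] / n;
          for (int j = 0; j < d; ++j) {
            double m = acc_x[c * d + j] / acc_n[c];
            mu[c * d + j] = m;
            var[c * d + j] = std::max(acc_x2[c * d + j] / acc_n[c] - m * m,
                                      var_floor);
          }
        }
        if (degenerate) break;
      }
      if (degenerate) continue;  // re-seeded restart
      (void)converged;

      if (prev_ll > best_ll) {
        best_ll = prev_ll;
        best_w.assign(w.begin(), w.end());
        best_mu.assign(mu.begin(), mu.end());
        best_var.assign(var.begin(), var.end());
        best_trace = trace;
        best_iter = it + 1;
        best_lab = lab;
        have_fit = true;
      }
      break;  // successful attempt for this restart
    }
  }
  if (!have_fit) stop("all EM restarts collapsed to an empty component");

  NumericMatrix means(k, d), vars(k, d);
  for (int c = 0; c < k; ++c)
    for (int j = 0; j < d; ++j) {
      means(c, j) = best_mu[c * d + j];
      vars(c, j) = best_var[c * d + j];
    }
  return List::create(
    _["labels"] = IntegerVector(best_lab.begin(), best_lab.end()),
    _["loglik"] = best_ll,
    _["loglik_trace"] = NumericVector(best_trace.begin(), best_trace.end()),
    _["weights"] = NumericVector(best_w.begin(), best_w.end()),
    _["means"] = means,
    _["variances"] = vars,
    _["n_iter"] = best_iter,
    _["k"] = k);
}

// Clustering validity indices: mean silhouette, Davies-Bouldin,
// Calinski-Harabasz and the between/within symmetry ratio (minimum
// between-centroid distance over maximum mean within-cluster distance to
// centroid). Labels must be 1..k with at least two non-empty clusters.

// [[Rcpp::export]]
NumericVector validity_indices_cpp(NumericMatrix X, IntegerVector labels,
                                   int k) {
  const int n = X.nrow(), d = X.ncol();
  if (labels.size() != n) stop("labels length must match rows of X");
  std::vector<int> size(k, 0);
  for (int i = 0; i < n; ++i) {
    int c = labels[i] - 1;
    if (c < 0 || c >= k) stop("labels must lie in 1..k");
    size[c]++;
  }
  int nonempty = 0;
  for (int c = 0; c < k; ++c) if (size[c] > 0) nonempty++;
  if (nonempty < 2) stop("validity indices need at least 2 non-empty clusters");

  // pairwise distances
  std::vector<double> dist(n * n, 0.0);
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j) {
      double s = 0.0;
      for (int m = 0; m < d; ++m) {
        double diff = X(i, m) - X(j, m);
        s += diff * diff;
      }
      double dd = std::sqrt(s);
      dist[i * n + j] = dd;
      dist[j * n + i] = dd;
    }

  // silhouette (s = 0 for singleton clusters)
  double sil = 0.0;
  for (int i = 0; i < n; ++i) {
    int ci = labels[i] - 1;
    if (size[ci] == 1) continue;
    std::vector<double> sums(k, 0.0);
    for (int j = 0; j < n; ++j)
      if (j != i) sums[labels[j] - 1] += dist[i * n + j];
    double a = sums[ci] / (size[ci] - 1);
    double b = std::numeric_limits<double>::infinity();
    for (int c = 0; c < k; ++c)
      if (c != ci && size[c] > 0) b = std::min(b, sums[c] / size[c]);
    double mx = std::max(a, b);
    sil += (mx > 0) ? (b - a) / mx : 0.0;
  }
  sil /= n;

  // centroids, scatters
  std::vector<double> cen(k * d, 0.0);
  for (int i = 0; i < n; ++i) {
    int c = labels[i] - 1;
    for (int m = 0; m < d; ++m) cen[c * d + m] += X(i, m);
  }
  for (int c = 0; c < k; ++c)
    if (size[c] > 0)
      for (int m = 0; m < d; ++m) cen[c * d + m] /= size[c];
  std::vector<double> S(k, 0.0);
  double W = 0.0;
  for (int i = 0; i < n; ++i) {
    int c = labels[i] - 1;
    double s = 0.0;
    for (int m = 0; m < d; ++m) {
      double diff = X(i, m) - cen[c * d + m];
      s += diff * diff;
    }
    W += s;
    S[c] += std::sqrt(s);
  }
  for (int c = 0; c < k; ++c) if (size[c] > 0) S[c] /= size[c];

  std::vector<double> gmean(d, 0.0);
  for (int i = 0; i < n; ++i)
    for (int m = 0; m < d; ++m) gmean[m] += X(i, m);
  for (int m = 0; m < d; ++m) gmean[m] /= n;
  double B = 0.0;
  for (int c = 0; c < k; ++c) {
    if (size[c] == 0) continue;
    double s = 0.0;
    for (int m = 0; m < d; ++m) {
      double diff = cen[c * d + m] - gmean[m];
      s += diff * diff;
    }
    B += size[c] * s;
  }

  double db = 0.0;
  double min_between = std::numeric_limits<double>::infinity();
  for (int c = 0; c < k; ++c) {
    if (size[c] == 0) continue;
    double worst = 0.0;
    for (int l = 0; l < k; ++l) {
      if (l == c || size[l] == 0) continue;
      double m2 = 0.0;
      for (int m = 0; m < d; ++m) {
        double diff = cen[c * d + m] - cen[l * d + m];
        m2 += diff * diff;
      }
      double M = std::sqrt(m2);
      if (l > c) min_between = std::min(min_between, M);
      if (M > 0) worst = std::max(worst, (S[c] + S[l]) / M);
    }
    db += worst;
  }
  db /= nonempty;

  double ch = NA_REAL;
  if (nonempty > 1 && n > nonempty && W > 0)
    ch = (B / (nonempty - 1)) / (W / (n - nonempty));

  double maxS = 0.0;
  for (int c = 0; c < k; ++c) maxS = std::max(maxS, S[c]);
  double sym = (maxS > 0) ? min_between / maxS : NA_REAL;

  NumericVector out = NumericVector::create(
    _["silhouette"] = sil, _["davies_bouldin"] = db,
    _["calinski_harabasz"] = ch, _["sym_between_within"] = sym);
  return out;
}
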