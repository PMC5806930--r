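// Compiled kernels: VAR surrogate recursion, pairwise Granger causality over
// lag embeddings, and the k-NN conditional mutual information estimator used
// for directed information. All loops are deterministic; randomness (innovations,
// block starts) is injected from R so seeds behave identically across platforms.
#include <RcppArmadillo.h>
#include <vector>
#include <algorithm>
#include <limits>
// [[Rcpp::depends(RcppArmadillo)]]
#define RESTRICT __restrict__
using namespace Rcpp;

// ---------------------------------------------------------------------------
// VAR simulation with a rest/ictal regime switch.
// innov: (burn + T) x N innovations; A_rest/A_ictal: lists of N x N lag
// matrices ordered lag 1..p, acting as x_t = sum_l A[l] x_{t-l} + e_t.
// ictal: length-T 0/1 flag for the post-burn samples (burn-in always rest).
// [[Rcpp::export]]
arma::mat var_simulate_cpp(const arma::mat& innov, const List& A_rest,
                           const List& A_ictal, const arma::uvec& ictal,
                           int burn) {
  const int p = A_rest.size();
  const int n_tot = innov.n_rows;
  const int N = innov.n_cols;
  const int T = n_tot - burn;
  if (T != (int)ictal.n_elem) stop("ictal flag length mismatch");
  std::vector<arma::mat> Ar(p), Ai(p);
  for (int l = 0; l < p; ++l) {
    Ar[l] = as<arma::mat>(A_rest[l]);
    Ai[l] = as<arma::mat>(A_ictal[l]);
  }
  arma::mat X(n_tot, N, arma::fill::zeros);
  for (int t = 0; t < n_tot; ++t) {
    arma::rowvec acc = innov.row(t);
    const bool ict = (t >= burn) && ictal[t - burn] == 1u;
    for (int l = 0; l < p; ++l) {
      if (t - 1 - l < 0) break;
      const arma::mat& A = ict ? Ai[l] : Ar[l];
      acc += X.row(t - 1 - l) * A.t();
    }
    X.row(t) = acc;
  }
  return X.rows(burn, n_tot - 1);
}

// ---------------------------------------------------------------------------
// Granger causality machinery. Regressions run on the common sample
// t = pmax .. T-1 via Gram submatrices of the stacked lag design.

// Residual sum of squares of y ~ cols (no intercept; inputs are standardized).
static double rss_sub(const arma::mat& G, const arma::vec& gy, double yy,
                      const arma::uvec& idx) {
  arma::mat Gs = G.submat(idx, idx);
  arma::vec gs = gy.elem(idx);
  arma::vec beta;
  if (!arma::solve(beta, Gs, gs, arma::solve_opts::no_approx))
    stop("rank-deficient regression");
  double r = yy - arma::dot(beta, gs);
  return r > 0 ? r : 1e-300;
}

// Per-target reduced-model RSS for orders 1..pmax on the common sample,
// used by the BIC order resolution. Returns N x pmax matrix.
// [[Rcpp::export]]
arma::mat gc_reduced_rss_cpp(const arma::mat& X, int pmax) {
  const int T = X.n_rows, N = X.n_cols;
  const int Te = T - pmax;
  if (Te <= 2 * pmax) stop("block too short for requested order");
  arma::mat out(N, pmax);
  for (int j = 0; j < N; ++j) {
    arma::vec y = X.col(j).subvec(pmax, T - 1);
    arma::mat L(Te, pmax);
    for (int l = 1; l <= pmax; ++l)
      L.col(l - 1) = X.col(j).subvec(pmax - l, T - 1 - l);
    arma::mat G = L.t() * L;
    arma::vec gy = L.t() * y;
    double yy = arma::dot(y, y);
    for (int p = 1; p <= pmax; ++p) {
      arma::uvec idx = arma::regspace<arma::uvec>(0, p - 1);
      out(j, p - 1) = rss_sub(G, gy, yy, idx);
    }
  }
  return out;
}

// Pairwise GC graph. orders: length-N vector, order used for target channel j.
// G[i,j] = log(rss_reduced_j / rss_full_ij), negatives clipped in R.
// [[Rcpp::export]]
arma::mat gc_graph_cpp(const arma::mat& X, const arma::ivec& orders) {
  const int T = X.n_rows, N = X.n_cols;
  const int pmax = arma::max(orders);
  if (pmax < 1) stop("order must be >= 1");
  const int Te = T - pmax;
  if (Te <= 2 * pmax) stop("block too short for requested order");
  // stacked lag design over the common sample: column (c*pmax + l-1) = lag l of channel c
  arma::mat L(Te, N * pmax);
  for (int c = 0; c < N; ++c)
    for (int l = 1; l <= pmax; ++l)
      L.col(c * pmax + l - 1) = X.col(c).subvec(pmax - l, T - 1 - l);
  arma::mat Gram = L.t() * L;
  arma::mat Y = X.rows(pmax, T - 1);
  arma::mat GY = L.t() * Y;   // (N*pmax) x N
  arma::mat out(N, N, arma::fill::zeros);
  for (int j = 0; j < N; ++j) {
    const int p = orders[j];
    arma::uvec jidx(p);
    for (int l = 0; l < p; ++l) jidx[l] = j * pmax + l;
    double yy = arma::dot(Y.col(j), Y.col(j));
    double rss_red = rss_sub(Gram, GY.col(j), yy, jidx);
    for (int i = 0; i < N; ++i) {
      if (i == j) continue;
      arma::uvec fidx(2 * p);
      for (int l = 0; l < p; ++l) { fidx[l] = jidx[l]; fidx[p + l] = i * pmax + l; }
      double rss_full = rss_sub(Gram, GY.col(j), yy, fidx);
      out(i, j) = std::log(rss_red / rss_full);
    }
  }
  return out;
}

// ---------------------------------------------------------------------------
// k-NN conditional mutual information I(Y_t ; X_{t-m..t-1} | Y_{t-m..t-1})
// (Frenzel-Pompe / KSG family): max-norm balls, digamma correction, averaged
// over a strided subset of evaluation centers with neighbours searched over
// all embedded points. Single-precision coordinate arrays keep the O(M*T)
// scans cache-friendly.

struct Embedding {
  // SoA float arrays, each of length np
  std::vector<float> cur;                 // channel value at t
  std::vector<std::vector<float> > lag;   // m arrays, lag 1..m
};

static void embed_channel(const double* x, int T, int m, Embedding& e) {
  const int np = T - m;
  e.cur.resize(np);
  e.lag.assign(m, std::vector<float>(np));
  for (int t = 0; t < np; ++t) {
    e.cur[t] = (float)x[t + m];
    for (int l = 1; l <= m; ++l) e.lag[l - 1][t] = (float)x[t + m - l];
  }
}

// CMI for source embedding ex (past only) -> target embedding ey (cur + past).
// Distance evaluation is organised as branchless passes over contiguous float
// arrays (one pass per embedding coordinate) so the compiler can vectorize.
static double cmi_pair(const Embedding& ex, const Embedding& ey, int m, int k,
                       const std::vector<int>& centers,
                       const std::vector<double>& digam,
                       std::vector<float>& dyp, std::vector<float>& dcur,
                       std::vector<float>& dxp, std::vector<float>& scratch) {
  const int np = (int)ey.cur.size();
  const bool m2 = (m == 2);  // fast path for the default memory order
  double acc = 0.0;
  std::vector<float> kbuf(k);
  for (size_t ci = 0; ci < centers.size(); ++ci) {
    const int c = centers[ci];
    // one fused branchless sweep: marginal distances + joint max-norm
    {
      const float c0 = ey.cur[c];
      const float cy0 = ey.lag[0][c], cx0 = ex.lag[0][c];
      const float cy1 = m2 ? ey.lag[1][c] : 0.f, cx1 = m2 ? ex.lag[1][c] : 0.f;
      const float* RESTRICT s0 = ey.cur.data();
      const float* RESTRICT sy0 = ey.lag[0].data();
      const float* RESTRICT sx0 = ex.lag[0].data();
      const float* RESTRICT sy1 = m2 ? ey.lag[1].data() : sy0;
      const float* RESTRICT sx1 = m2 ? ex.lag[1].data() : sx0;
      float* RESTRICT a = dyp.data();
      float* RESTRICT b = dcur.data();
      float* RESTRICT x = dxp.data();
      float* RESTRICT j = scratch.data();
      if (m2) {
        for (int t = 0; t < np; ++t) {
          const float dy = std::max(std::fabs(sy0[t] - cy0), std::fabs(sy1[t] - cy1));
          const float dx = std::max(std::fabs(sx0[t] - cx0), std::fabs(sx1[t] - cx1));
          const float d0 = std::fabs(s0[t] - c0);
          a[t] = dy; b[t] = d0; x[t] = dx;
          j[t] = std::max(dy, std::max(d0, dx));
        }
      } else {
        for (int t = 0; t < np; ++t) {
          float dy = std::fabs(sy0[t] - cy0), dx = std::fabs(sx0[t] - cx0);
          for (int l = 1; l < m; ++l) {
            dy = std::max(dy, std::fabs(ey.lag[l][t] - ey.lag[l][c]));
            dx = std::max(dx, std::fabs(ex.lag[l][t] - ex.lag[l][c]));
          }
          const float d0 = std::fabs(s0[t] - c0);
          a[t] = dy; b[t] = d0; x[t] = dx;
          j[t] = std::max(dy, std::max(d0, dx));
        }
      }
    }
    // k-th smallest joint distance, excluding the center itself (distance 0)
    float eps;
    {
      const float* RESTRICT j = scratch.data();
      float* RESTRICT kb = kbuf.data();  // kb[0] = current k-th smallest
      for (int q = 0; q < k; ++q) kb[q] = std::numeric_limits<float>::infinity();
      for (int t = 0; t < np; ++t) {
        if (t == c) continue;
        const float d = j[t];
        if (d < kb[0]) {
          int q = 1;
          while (q < k && d < kb[q]) { kb[q - 1] = kb[q]; ++q; }
          kb[q - 1] = d;
        }
      }
      eps = kb[0];
    }
    // strict-inequality neighbour counts in the marginal spaces; the joint
    // array was permuted by nth_element, so recount from the marginals.
    int n_yz = 0, n_xz = 0, n_z = 0;
    {
      const float* RESTRICT a = dyp.data();
      const float* RESTRICT b = dcur.data();
      const float* RESTRICT x = dxp.data();
      for (int t = 0; t < np; ++t) {
        const int bz = a[t] < eps;
        n_z += bz;
        n_yz += bz & (b[t] < eps);
        n_xz += bz & (x[t] < eps);
      }
      // the center itself has all-zero distances; remove it from each count
      --n_z; --n_yz; --n_xz;
    }
    acc += digam[k] + digam[n_z + 1] - digam[n_yz + 1] - digam[n_xz + 1];
  }
  return acc / (double)centers.size();
}

static std::vector<int> stride_centers(int np, int ncenters) {
  if (ncenters >= np) {
    std::vector<int> all(np);
    for (int i = 0; i < np; ++i) all[i] = i;
    return all;
  }
  std::vector<int> cs(ncenters);
  for (int i = 0; i < ncenters; ++i)
    cs[i] = (int)((double)i * np / ncenters);
  return cs;
}

static std::vector<double> digamma_table(int n) {
  std::vector<double> d(n + 2);
  for (int i = 1; i <= n + 1; ++i) d[i] = R::digamma((double)i);
  return d;
}

// [[Rcpp::export]]
double cmi_knn_cpp(const NumericVector& x, const NumericVector& y, int m,
                   int k, int ncenters) {
  const int T = x.size();
  const int np = T - m;
  if (np < k + 1) stop("too few samples for k-NN estimation");
  Embedding ex, ey;
  embed_channel(REAL(x), T, m, ex);
  embed_channel(REAL(y), T, m, ey);
  std::vector<int> centers = stride_centers(np, ncenters);
  std::vector<double> digam = digamma_table(np);
  std::vector<float> dyp(np), dcur(np), dxp(np), scratch(np);
  return cmi_pair(ex, ey, m, k, centers, digam, dyp, dcur, dxp, scratch);
}

// Full N x N directed-information graph: out[i,j] = CMI(i -> j), diagonal 0.
// [[Rcpp::export]]
NumericMatrix di_graph_cpp(const NumericMatrix& X, int m, int k, int ncenters) {
  const int T = X.nrow(), N = X.ncol();
  const int np = T - m;
  if (np < k + 1) stop("too few samples for k-NN estimation");
  std::vector<Embedding> emb(N);
  for (int c = 0; c < N; ++c) embed_channel(&X(0, c), T, m, emb[c]);
  std::vector<int> centers = stride_centers(np, ncenters);
  std::vector<double> digam = digamma_table(np);
  std::vector<float> dyp(np), dcur(np), dxp(np), scratch(np);
  NumericMatrix out(N, N);
  for (int i = 0; i < N; ++i)
    for (int j = 0; j < N; ++j) {
      if (i == j) continue;
      out(i, j) = cmi_pair(emb[i], emb[j], m, k, centers, digam,
                           dyp, dcur, dxp, scratch);
    }
  return out;
}

// ---------------------------------------------------------------------------
// Zero-phase IIR filtering: odd-reflection padding at both ends, one forward
// and one backward pass of the direct-form transfer function b/a, columns
// filtered independently.
// [[Rcpp::export]]
arma::mat iir_filtfilt_cpp(const arma::vec& b, const arma::vec& a,
                           const arma::mat& X, int pad) {
  const int n = X.n_rows, nc = X.n_cols;
  const int nb = b.n_elem, na = a.n_elem;
  if (pad >= n) pad = n - 1;
  const int ne = n + 2 * pad;
  arma::vec ext(ne), fwd(ne);
  arma::mat out(n, nc);
  for (int j = 0; j < nc; ++j) {
    const double* x = X.colptr(j);
    for (int t = 0; t < pad; ++t) ext[t] = 2.0 * x[0] - x[pad - t];
    for (int t = 0; t < n; ++t) ext[pad + t] = x[t];
    for (int t = 0; t < pad; ++t) ext[pad + n + t] = 2.0 * x[n - 1] - x[n - 2 - t];
    for (int dir = 0; dir < 2; ++dir) {
      // direct form II transposed, zero initial state
      arma::vec w(std::max(nb, na) - 1, arma::fill::zeros);
      const int m = w.n_elem;
      for (int t = 0; t < ne; ++t) {
        const double xt = dir == 0 ? ext[t] : ext[ne - 1 - t];
        const double yt = b[0] * xt + (m > 0 ? w[0] : 0.0);
        for (int q = 0; q < m; ++q) {
          double wn = (q + 1 < m) ? w[q + 1] : 0.0;
          if (q + 1 < nb) wn += b[q + 1] * xt;
          if (q + 1 < na) wn -= a[q + 1] * yt;
          w[q] = wn;
        }
        fwd[t] = yt;
      }
      if (dir == 0) ext = fwd;
    }
    for (int t = 0; t < n; ++t) out(t, j) = fwd[ne - 1 - (pad + t)];
  }
  return out;
}
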