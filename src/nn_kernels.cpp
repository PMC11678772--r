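// Hot kernels for network training: batched 1-D convolution, ReLU, and
// dropout mask generation from R's RNG.
//
// Activations are stored stacked: a batch of B signals of length L with C
// channels is an (B*L) x C matrix, sample-major (rows [b*L, (b+1)*L) belong
// to sample b).  A convolution tap with offset o contributes
//   Y[i, ] += X[i + o, ] * W_o        for i + o inside the same sample,
// so "same" padding with kernel 3 uses offsets {-1, 0, +1} and a causal
// dilated kernel-2 convolution uses offsets {0, -d}.
//
// Each tap is computed as one full-size contiguous dgemm (P = X * W_o) and
// the within-sample shift is applied while accumulating P into the output,
// which keeps BLAS on fast paths and avoids materializing shifted inputs.
// R matrices are wrapped as Armadillo views without copying.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static arma::mat view(const NumericMatrix& m) {
  return arma::mat(const_cast<double*>(m.begin()), m.nrow(), m.ncol(),
                   false, true);
}

// dst[i + o, ] += src[i, ] for i and i + o within the same sample
static void shifted_add(const arma::mat& src, arma::mat& dst, int o,
                        int B, int L) {
  const int lo = std::max(0, -o), hi = L - 1 - std::max(0, o);
  if (lo > hi) return;
  const int len = hi - lo + 1;
  for (arma::uword c = 0; c < src.n_cols; ++c) {
    const double* s = src.colptr(c);
    double* d = dst.colptr(c);
    for (int b = 0; b < B; ++b) {
      const double* sp = s + b * L + lo;
      double* dp = d + b * L + lo + o;
      for (int i = 0; i < len; ++i) dp[i] += sp[i];
    }
  }
}

// dst[i, ] = src[i + o, ] (zero outside the sample)
static void shifted_copy(const arma::mat& src, arma::mat& dst, int o,
                         int B, int L) {
  const int lo = std::max(0, -o), hi = L - 1 - std::max(0, o);
  dst.zeros();
  if (lo > hi) return;
  const int len = hi - lo + 1;
  for (arma::uword c = 0; c < src.n_cols; ++c) {
    const double* s = src.colptr(c);
    double* d = dst.colptr(c);
    for (int b = 0; b < B; ++b)
      std::copy(s + b * L + lo + o, s + b * L + lo + o + len,
                d + b * L + lo);
  }
}

// W is (k*Cin) x Cout with the tap-t block in rows [t*Cin, (t+1)*Cin).
// [[Rcpp::export]]
NumericMatrix cpp_conv1d_fwd(const NumericMatrix& X, const NumericMatrix& W,
                             const NumericVector& bias,
                             const IntegerVector& offsets, int B, int L,
                             bool relu = false) {
  const int n = X.nrow(), cin = X.ncol(), cout = W.ncol(),
            k = offsets.size();
  if (W.nrow() != k * cin) stop("conv weight shape mismatch");
  if (n != B * L) stop("conv input shape mismatch");
  const arma::mat Xv = view(X), Wv = view(W);
  NumericMatrix Yr(n, cout);
  arma::mat Y = view(Yr);
  Y.each_row() = arma::rowvec(const_cast<double*>(bias.begin()),
                              cout, false, true);
  for (int t = 0; t < k; ++t) {
    const arma::mat Wt = Wv.rows(t * cin, (t + 1) * cin - 1);
    if (offsets[t] == 0) {
      Y += Xv * Wt;
    } else {
      const arma::mat P = Xv * Wt;           // P[i,] = X[i,] * W_t
      shifted_add(P, Y, -offsets[t], B, L);  // Y[i,] += P[i + o,]
    }
  }
  if (relu) {
    double* y = Yr.begin();
    const int nel = Yr.size();
    for (int i = 0; i < nel; ++i) if (y[i] < 0) y[i] = 0.0;
  }
  return Yr;
}

// When `Yact` (the layer's post-ReLU output) is supplied, the incoming
// gradient is masked through the ReLU first, fusing the activation backward
// into the convolution backward.
// [[Rcpp::export]]
List cpp_conv1d_bwd(const NumericMatrix& X, const NumericMatrix& W,
                    const NumericMatrix& dY, const IntegerVector& offsets,
                    int B, int L,
                    Rcpp::Nullable<Rcpp::NumericMatrix> Yact = R_NilValue) {
  const int n = X.nrow(), cin = X.ncol(), cout = W.ncol(),
            k = offsets.size();
  const arma::mat Xv = view(X), Wv = view(W);
  NumericMatrix dZr;
  if (Yact.isNotNull()) {
    NumericMatrix Ya(Yact);
    dZr = NumericMatrix(dY.nrow(), dY.ncol());
    const double* g = dY.begin(); const double* y = Ya.begin();
    double* d = dZr.begin();
    const int nel = dY.size();
    for (int i = 0; i < nel; ++i) d[i] = y[i] > 0 ? g[i] : 0.0;
  } else {
    dZr = dY;
  }
  const arma::mat dYv = view(dZr);
  NumericMatrix dXr(n, cin), dWr(W.nrow(), cout);
  arma::mat dX = view(dXr), dW = view(dWr);
  arma::mat dYs(n, cout);
  for (int t = 0; t < k; ++t) {
    const int o = offsets[t];
    const arma::mat Wt = Wv.rows(t * cin, (t + 1) * cin - 1);
    if (o == 0) {
      dW.rows(t * cin, (t + 1) * cin - 1) = Xv.t() * dYv;
      dX += dYv * Wt.t();
    } else {
      // dX[i + o, ] += dY[i, ] * W_t'
      const arma::mat P = dYv * Wt.t();
      shifted_add(P, dX, o, B, L);
      // dW_t = sum_i X[i + o, ]' dY[i, ] = X' * (dY shifted by -o)
      shifted_copy(dYv, dYs, -o, B, L);
      dW.rows(t * cin, (t + 1) * cin - 1) = Xv.t() * dYs;
    }
  }
  NumericVector db(cout);
  arma::rowvec dbv(db.begin(), cout, false, true);
  dbv = arma::sum(dYv, 0);
  return List::create(_["dX"] = dXr, _["dW"] = dWr, _["db"] = db);
}

// [[Rcpp::export]]
NumericMatrix cpp_relu_fwd(const NumericMatrix& X) {
  const int n = X.size();
  NumericMatrix Y(X.nrow(), X.ncol());
  const double* x = X.begin();
  double* y = Y.begin();
  for (int i = 0; i < n; ++i) y[i] = x[i] > 0 ? x[i] : 0.0;
  return Y;
}

// dX = dY where the forward output was positive, else 0
// [[Rcpp::export]]
NumericMatrix cpp_relu_bwd(const NumericMatrix& dY, const NumericMatrix& Y) {
  const int n = Y.size();
  NumericMatrix dX(dY.nrow(), dY.ncol());
  const double* g = dY.begin(); const double* y = Y.begin();
  double* d = dX.begin();
  for (int i = 0; i < n; ++i) d[i] = y[i] > 0 ? g[i] : 0.0;
  return dX;
}

// Inverted-dropout mask: entries are 1/(1-p) with probability 1-p, else 0.
// Uses R's RNG so masks are reproducible under set.seed().
// [[Rcpp::export]]
NumericVector cpp_dropout_mask(int n, double p) {
  NumericVector m(n);
  const double scale = 1.0 / (1.0 - p);
  GetRNGstate();
  for (int i = 0; i < n; ++i) m[i] = (unif_rand() < p) ? 0.0 : scale;
  PutRNGstate();
  return m;
}

// Draw an inverted-dropout mask and apply it in one pass.
// [[Rcpp::export]]
List cpp_dropout_fwd(const NumericMatrix& X, double p) {
  const int n = X.size();
  NumericMatrix Y(X.nrow(), X.ncol()), M(X.nrow(), X.ncol());
  const double scale = 1.0 / (1.0 - p);
  const double* x = X.begin();
  double* y = Y.begin(); double* m = M.begin();
  GetRNGstate();
  for (int i = 0; i < n; ++i) {
    m[i] = (unif_rand() < p) ? 0.0 : scale;
    y[i] = x[i] * m[i];
  }
  PutRNGstate();
  return List::create(_["Y"] = Y, _["mask"] = M);
}

// elementwise product (dropout backward)
// [[Rcpp::export]]
NumericMatrix cpp_elemmul(const NumericMatrix& A, const NumericMatrix& B) {
  const int n = A.size();
  NumericMatrix C(A.nrow(), A.ncol());
  const double* a = A.begin(); const double* b = B.begin();
  double* c = C.begin();
  for (int i = 0; i < n; ++i) c[i] = a[i] * b[i];
  return C;
}

#ifdef __GLIBC__
#include <malloc.h>
#endif

// Large activation buffers are allocated and freed once per minibatch; with
// glibc's default mmap threshold every cycle returns the pages to the OS and
// re-faults them on the next batch, which dominates runtime on slow-fault
// systems.  Keep large chunks on the heap so they are reused.
// [[Rcpp::export]]
void cpp_tune_allocator() {
#ifdef __GLIBC__
  mallopt(M_MMAP_MAX, 0);
  mallopt(M_TRIM_THRESHOLD, 2147483647);
#endif
}
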