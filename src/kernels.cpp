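// Hot numerical kernels for the network: dilated 3x3 convolution on the
// flattened pair map (column-major im2col + BLAS) and the tanh-form GELU.
// Shapes follow the R-side conventions (pair index p = i + (j-1)*n).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// idx: (n2 x 9) integer matrix of source rows (0 = zero padding).
// Returns list(out = cols %*% W + b, cols); cols is reused by the backward.
// [[Rcpp::export(rng = false)]]
List conv2d_fwd_cpp(const NumericMatrix x, const NumericMatrix W,
                    const NumericVector b, const IntegerMatrix idx) {
  const int n2 = idx.nrow(), cin = x.ncol(), cout = W.ncol();
  NumericMatrix cols(n2, 9 * cin);
  for (int k = 0; k < 9; ++k) {
    const int* ik = &idx(0, k);
    for (int c = 0; c < cin; ++c) {
      const double* src = &x(0, c);
      double* dst = &cols(0, k * cin + c);
      for (int r = 0; r < n2; ++r)
        dst[r] = ik[r] > 0 ? src[ik[r] - 1] : 0.0;
    }
  }
  arma::mat C(cols.begin(), n2, 9 * cin, false, true);
  arma::mat Wm(const_cast<double*>(W.begin()), 9 * cin, cout, false, true);
  NumericMatrix out(n2, cout);
  arma::mat O(out.begin(), n2, cout, false, true);
  O = C * Wm;
  for (int c = 0; c < cout; ++c) {
    double* oc = &out(0, c);
    const double bc = b[c];
    for (int r = 0; r < n2; ++r) oc[r] += bc;
  }
  return List::create(_["out"] = out, _["cols"] = cols);
}

// [[Rcpp::export(rng = false)]]
List conv2d_bwd_cpp(const NumericMatrix g, const NumericMatrix cols,
                    const NumericMatrix W, const IntegerMatrix idx,
                    const int nrow_x, const bool need_gx) {
  const int n2 = idx.nrow(), cout = W.ncol();
  const int cin = cols.ncol() / 9;
  arma::mat G(const_cast<double*>(g.begin()), n2, cout, false, true);
  arma::mat C(const_cast<double*>(cols.begin()), n2, 9 * cin, false, true);
  arma::mat Wm(const_cast<double*>(W.begin()), 9 * cin, cout, false, true);
  NumericMatrix gW(9 * cin, cout);
  arma::mat GW(gW.begin(), 9 * cin, cout, false, true);
  GW = C.t() * G;
  NumericVector gb(cout);
  for (int c = 0; c < cout; ++c) {
    const double* gc = &g(0, c);
    double acc = 0.0;
    for (int r = 0; r < n2; ++r) acc += gc[r];
    gb[c] = acc;
  }
  List res = List::create(_["gW"] = gW, _["gb"] = gb);
  if (need_gx) {
    arma::mat dcols = G * Wm.t();          // n2 x 9cin
    NumericMatrix gx(nrow_x, cin);
    for (int k = 0; k < 9; ++k) {
      const int* ik = &idx(0, k);
      for (int c = 0; c < cin; ++c) {
        const double* src = dcols.colptr(k * cin + c);
        double* dst = &gx(0, c);
        for (int r = 0; r < n2; ++r)
          if (ik[r] > 0) dst[ik[r] - 1] += src[r];
      }
    }
    res["gx"] = gx;
  }
  return res;
}

// [[Rcpp::export(rng = false)]]
NumericMatrix gelu_fwd_cpp(const NumericMatrix x) {
  const double c0 = 0.7978845608028654;
  NumericMatrix out(x.nrow(), x.ncol());
  const R_xlen_t n = x.size();
  const double* xi = x.begin();
  double* oi = out.begin();
  for (R_xlen_t i = 0; i < n; ++i) {
    const double v = xi[i];
    const double th = std::tanh(c0 * (v + 0.044715 * v * v * v));
    oi[i] = 0.5 * v * (1.0 + th);
  }
  return out;
}

// [[Rcpp::export(rng = false)]]
NumericMatrix gelu_bwd_cpp(const NumericMatrix g, const NumericMatrix x) {
  const double c0 = 0.7978845608028654;
  NumericMatrix out(x.nrow(), x.ncol());
  const R_xlen_t n = x.size();
  const double* xi = x.begin();
  const double* gi = g.begin();
  double* oi = out.begin();
  for (R_xlen_t i = 0; i < n; ++i) {
    const double v = xi[i];
    const double th = std::tanh(c0 * (v + 0.044715 * v * v * v));
    const double sech2 = 1.0 - th * th;
    const double dinner = c0 * (1.0 + 0.134145 * v * v);
    oi[i] = gi[i] * (0.5 * (1.0 + th) + 0.5 * v * sech2 * dinner);
  }
  return out;
}

// row gather with zero padding (idx 0 -> zero row)
// [[Rcpp::export(rng = false)]]
NumericMatrix gather_rows_cpp(const NumericMatrix x, const IntegerVector idx) {
  const int n = idx.size(), nc = x.ncol();
  NumericMatrix out(n, nc);
  const int* ix = idx.begin();
  for (int c = 0; c < nc; ++c) {
    const double* src = &x(0, c);
    double* dst = &out(0, c);
    for (int r = 0; r < n; ++r)
      dst[r] = ix[r] > 0 ? src[ix[r] - 1] : 0.0;
  }
  return out;
}

// scatter-add rows of g back (backward of gather)
// [[Rcpp::export(rng = false)]]
NumericMatrix gather_rows_bwd_cpp(const NumericMatrix g,
                                  const IntegerVector idx, const int nrow_x) {
  const int n = idx.size(), nc = g.ncol();
  NumericMatrix out(nrow_x, nc);
  const int* ix = idx.begin();
  for (int c = 0; c < nc; ++c) {
    const double* src = &g(0, c);
    double* dst = &out(0, c);
    for (int r = 0; r < n; ++r)
      if (ix[r] > 0) dst[ix[r] - 1] += src[r];
  }
  return out;
}

// group row-sum for sorted complete groups rep(1:ngroups, each = k)
// [[Rcpp::export(rng = false)]]
NumericMatrix group_rowsum_cpp(const NumericMatrix x, const int ngroups) {
  const int n = x.nrow(), nc = x.ncol();
  const int k = n / ngroups;
  NumericMatrix out(ngroups, nc);
  for (int c = 0; c < nc; ++c) {
    const double* src = &x(0, c);
    double* dst = &out(0, c);
    for (int gidx = 0; gidx < ngroups; ++gidx) {
      double acc = 0.0;
      const int base = gidx * k;
      for (int r = 0; r < k; ++r) acc += src[base + r];
      dst[gidx] = acc;
    }
  }
  return out;
}

// ---- fused decoder trunk ---------------------------------------------------
// A stack of residual blocks on the flat pair map:
//   y = x + W3' * gelu(conv2(gelu(conv1(gelu(LN(x))))))   (biases implied)
// conv* are dilated 3x3 convolutions (im2col) with offset-major weight rows.
// Forward stashes every intermediate needed by the analytic backward.

static void im2col(const arma::mat& x, const IntegerMatrix& idx,
                   arma::mat& cols) {
  const int n2 = idx.nrow(), cin = x.n_cols;
  for (int k = 0; k < 9; ++k) {
    const int* ik = &idx(0, k);
    for (int c = 0; c < cin; ++c) {
      const double* src = x.colptr(c);
      double* dst = cols.colptr(k * cin + c);
      for (int r = 0; r < n2; ++r)
        dst[r] = ik[r] > 0 ? src[ik[r] - 1] : 0.0;
    }
  }
}

static void col2im_add(const arma::mat& dcols, const IntegerMatrix& idx,
                       arma::mat& gx) {
  const int n2 = idx.nrow(), cin = gx.n_cols;
  for (int k = 0; k < 9; ++k) {
    const int* ik = &idx(0, k);
    for (int c = 0; c < cin; ++c) {
      const double* src = dcols.colptr(k * cin + c);
      double* dst = gx.colptr(c);
      for (int r = 0; r < n2; ++r)
        if (ik[r] > 0) dst[ik[r] - 1] += src[r];
    }
  }
}

static inline void gelu_inplace(arma::mat& x, arma::mat& pre) {
  pre = x;
  const double c0 = 0.7978845608028654;
  for (arma::uword i = 0; i < x.n_elem; ++i) {
    const double v = x(i);
    x(i) = 0.5 * v * (1.0 + std::tanh(c0 * (v + 0.044715 * v * v * v)));
  }
}

static inline arma::mat gelu_grad(const arma::mat& g, const arma::mat& pre) {
  const double c0 = 0.7978845608028654;
  arma::mat out(g.n_rows, g.n_cols);
  for (arma::uword i = 0; i < g.n_elem; ++i) {
    const double v = pre(i);
    const double th = std::tanh(c0 * (v + 0.044715 * v * v * v));
    const double sech2 = 1.0 - th * th;
    const double dinner = c0 * (1.0 + 0.134145 * v * v);
    out(i) = g(i) * (0.5 * (1.0 + th) + 0.5 * v * sech2 * dinner);
  }
  return out;
}

// layer norm over rows with gain/offset; stashes xhat and inv
static void ln_fwd(const arma::mat& x, const arma::rowvec& gain,
                   const arma::rowvec& off, arma::mat& out, arma::mat& xhat,
                   arma::vec& inv) {
  const double eps = 1e-5;
  arma::vec mu = arma::mean(x, 1);
  arma::mat xc = x.each_col() - mu;
  arma::vec va = arma::mean(arma::square(xc), 1);
  inv = 1.0 / arma::sqrt(va + eps);
  xhat = xc.each_col() % inv;
  out = xhat.each_row() % gain;
  out.each_row() += off;
}

static arma::mat ln_bwd(const arma::mat& g, const arma::mat& xhat,
                        const arma::vec& inv, const arma::rowvec& gain,
                        arma::rowvec& dgain, arma::rowvec& doff) {
  dgain = arma::sum(g % xhat, 0);
  doff = arma::sum(g, 0);
  arma::mat gg = g.each_row() % gain;
  arma::vec m1 = arma::mean(gg, 1);
  arma::vec m2 = arma::mean(gg % xhat, 1);
  arma::mat dx = gg;
  dx.each_col() -= m1;
  dx -= xhat.each_col() % m2;
  dx.each_col() %= inv;
  return dx;
}

// params: per block list(lng, lno, W1, b1, W2, b2, W3, b3); idxs: per block
// im2col index matrix for that block's dilation. Intermediates are stashed
// behind an external pointer so nothing large crosses back into R.

struct BlockStash {
  arma::mat xhat, pre0, cols1, pre1, cols2, pre2, a2;
  arma::vec inv;
};

// [[Rcpp::export(rng = false)]]
List decoder_fwd_cpp(const NumericMatrix x0, const List params,
                     const List idxs) {
  const int nb = params.size();
  arma::mat x(const_cast<double*>(x0.begin()), x0.nrow(), x0.ncol(),
              false, true);
  arma::mat cur = x;
  XPtr<std::vector<BlockStash>> stash(new std::vector<BlockStash>(nb), true);
  for (int b = 0; b < nb; ++b) {
    List P = params[b];
    IntegerMatrix idx = idxs[b];
    arma::rowvec lng = as<arma::rowvec>(P["lng"]);
    arma::rowvec lno = as<arma::rowvec>(P["lno"]);
    arma::mat W1 = as<arma::mat>(P["W1"]);
    arma::rowvec b1 = as<arma::rowvec>(P["b1"]);
    arma::mat W2 = as<arma::mat>(P["W2"]);
    arma::rowvec b2 = as<arma::rowvec>(P["b2"]);
    arma::mat W3 = as<arma::mat>(P["W3"]);
    arma::rowvec b3 = as<arma::rowvec>(P["b3"]);
    BlockStash& S = (*stash)[b];
    arma::mat ln_out;
    ln_fwd(cur, lng, lno, ln_out, S.xhat, S.inv);
    gelu_inplace(ln_out, S.pre0);                     // a0
    const int cin = ln_out.n_cols;
    S.cols1.set_size(ln_out.n_rows, 9 * cin);
    im2col(ln_out, idx, S.cols1);
    arma::mat z1 = S.cols1 * W1; z1.each_row() += b1;
    gelu_inplace(z1, S.pre1);                         // a1
    S.cols2.set_size(z1.n_rows, 9 * (int)z1.n_cols);
    im2col(z1, idx, S.cols2);
    arma::mat z2 = S.cols2 * W2; z2.each_row() += b2;
    gelu_inplace(z2, S.pre2);                         // a2
    S.a2 = z2;
    arma::mat z3 = z2 * W3; z3.each_row() += b3;
    cur += z3;
  }
  return List::create(_["out"] = cur, _["stash"] = stash);
}

// [[Rcpp::export(rng = false)]]
List decoder_bwd_cpp(const NumericMatrix gout, const List params,
                     const List idxs, SEXP stash_ptr) {
  XPtr<std::vector<BlockStash>> stash(stash_ptr);
  const int nb = params.size();
  arma::mat cur_g(const_cast<double*>(gout.begin()), gout.nrow(),
                  gout.ncol(), false, true);
  arma::mat gacc = cur_g;
  List grads(nb);
  for (int b = nb - 1; b >= 0; --b) {
    List P = params[b];
    BlockStash& S = (*stash)[b];
    IntegerMatrix idx = idxs[b];
    arma::mat W1 = as<arma::mat>(P["W1"]);
    arma::mat W2 = as<arma::mat>(P["W2"]);
    arma::mat W3 = as<arma::mat>(P["W3"]);
    arma::rowvec lng = as<arma::rowvec>(P["lng"]);
    arma::mat dW3 = S.a2.t() * gacc;
    arma::rowvec db3 = arma::sum(gacc, 0);
    arma::mat da2 = gacc * W3.t();
    arma::mat dz2 = gelu_grad(da2, S.pre2);
    arma::mat dW2 = S.cols2.t() * dz2;
    arma::rowvec db2 = arma::sum(dz2, 0);
    arma::mat dcols2 = dz2 * W2.t();
    arma::mat da1(S.pre1.n_rows, S.pre1.n_cols, arma::fill::zeros);
    col2im_add(dcols2, idx, da1);
    arma::mat dz1 = gelu_grad(da1, S.pre1);
    arma::mat dW1 = S.cols1.t() * dz1;
    arma::rowvec db1 = arma::sum(dz1, 0);
    arma::mat dcols1 = dz1 * W1.t();
    arma::mat da0(S.pre0.n_rows, S.pre0.n_cols, arma::fill::zeros);
    col2im_add(dcols1, idx, da0);
    arma::mat dln = gelu_grad(da0, S.pre0);
    arma::rowvec dlng, dlno;
    arma::mat dx_ln = ln_bwd(dln, S.xhat, S.inv, lng, dlng, dlno);
    grads[b] = List::create(_["lng"] = dlng, _["lno"] = dlno,
                            _["W1"] = dW1, _["b1"] = db1,
                            _["W2"] = dW2, _["b2"] = db2,
                            _["W3"] = dW3, _["b3"] = db3);
    gacc += dx_ln;   // residual path
  }
  return List::create(_["gx"] = gacc, _["grads"] = grads);
}
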