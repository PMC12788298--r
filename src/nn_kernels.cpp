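// Compiled kernels for the sequence model: length-preserving temporal
// convolution, GRU recursion (forward and backward-through-time), and
// multi-head scaled dot-product attention.
//
// R-side batches are sample-major (row (b-1)*T + t holds step t of sample
// b). Kernels permute to time-major internally (row t*B + b) so that each
// timestep, and each shifted tap window, is one contiguous block usable as
// a BLAS operand without gathers. Every kernel is templated on the element
// type: the training path runs in single precision (the pipeline's stated
// compute precision), while a double-precision path is kept for gradient
// verification.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// Opaque forward caches live on the C++ side (behind external pointers)
// so single-precision activations never round-trip through R doubles.
struct ConvCache {
  fmat Xt_f; mat Xt_d; bool single; int T, B;
};
struct GruCache {
  fmat Xf, R_f, Z_f, N_f, P_f, H_f;
  mat Xd, R_d, Z_d, N_d, P_d, H_d;
  bool single; int T, B; bool reverse;
};

template <typename eT>
static inline eT sigm1(eT x) { return eT(1) / (eT(1) + std::exp(-x)); }

template <typename eT>
static Mat<eT> to_time_major(const Mat<eT>& X, int T, int B) {
  Mat<eT> Xt(X.n_rows, X.n_cols);
  for (int b = 0; b < B; ++b)
    for (int t = 0; t < T; ++t)
      Xt.row((uword)t * B + b) = X.row((uword)b * T + t);
  return Xt;
}

template <typename eT>
static Mat<eT> to_sample_major(const Mat<eT>& Xt, int T, int B) {
  Mat<eT> X(Xt.n_rows, Xt.n_cols);
  for (int b = 0; b < B; ++b)
    for (int t = 0; t < T; ++t)
      X.row((uword)b * T + t) = Xt.row((uword)t * B + b);
  return X;
}

template <typename eT>
static Mat<eT> as_et(const mat& X) { return conv_to<Mat<eT>>::from(X); }

// ---------------------------------------------------------------- conv1d

template <typename eT>
static mat conv1d_fwd_t(Mat<eT>& Xt_store, const mat& X,
                        const Rcpp::List& Ws, const rowvec& b,
                        int T, int B) {
  const int k = Ws.size();
  const int k2 = (k - 1) / 2;
  Xt_store = to_time_major(as_et<eT>(X), T, B);
  const Mat<eT>& Xt = Xt_store;
  Mat<eT> Yt(X.n_rows, b.n_elem, fill::zeros);
  Yt.each_row() += conv_to<Row<eT>>::from(b);
  for (int s = -k2; s <= k2; ++s) {
    const Mat<eT> W = as_et<eT>(Rcpp::as<mat>(Ws[s + k2]));
    int t0 = std::max(0, -s), t1 = T - 1 - std::max(0, s);
    if (t0 > t1) continue;
    Yt.rows((uword)t0 * B, (uword)(t1 + 1) * B - 1) +=
        Xt.rows((uword)(t0 + s) * B, (uword)(t1 + s + 1) * B - 1) * W;
  }
  return conv_to<mat>::from(to_sample_major(Yt, T, B));
}

// [[Rcpp::export(name = ".conv1d_fwd_cpp")]]
Rcpp::List conv1d_fwd_cpp(const arma::mat& X, const Rcpp::List& Ws,
                          const arma::rowvec& b, int T, int B, bool single,
                          bool keep) {
  Rcpp::XPtr<ConvCache> ptr(new ConvCache, true);
  ptr->single = single; ptr->T = T; ptr->B = B;
  mat Y = single ? conv1d_fwd_t<float>(ptr->Xt_f, X, Ws, b, T, B)
                 : conv1d_fwd_t<double>(ptr->Xt_d, X, Ws, b, T, B);
  if (!keep) { ptr->Xt_f.reset(); ptr->Xt_d.reset(); }
  return Rcpp::List::create(Rcpp::Named("Y") = Y, Rcpp::Named("ptr") = ptr);
}

template <typename eT>
static Rcpp::List conv1d_bwd_t(const Mat<eT>& Xt, const mat& dY,
                               const Rcpp::List& Ws, int T, int B) {
  const int k = Ws.size();
  const int k2 = (k - 1) / 2;
  Mat<eT> dYt = to_time_major(as_et<eT>(dY), T, B);
  Mat<eT> dXt(Xt.n_rows, Xt.n_cols, fill::zeros);
  Rcpp::List dWs(k);
  for (int s = -k2; s <= k2; ++s) {
    const Mat<eT> W = as_et<eT>(Rcpp::as<mat>(Ws[s + k2]));
    int t0 = std::max(0, -s), t1 = T - 1 - std::max(0, s);
    if (t0 > t1) {
      dWs[s + k2] = mat(W.n_rows, W.n_cols, fill::zeros);
      continue;
    }
    uword o0 = (uword)t0 * B, o1 = (uword)(t1 + 1) * B - 1;
    uword i0 = (uword)(t0 + s) * B, i1 = (uword)(t1 + s + 1) * B - 1;
    dXt.rows(i0, i1) += dYt.rows(o0, o1) * W.t();
    dWs[s + k2] = conv_to<mat>::from(
        Mat<eT>(Xt.rows(i0, i1).t() * dYt.rows(o0, o1)));
  }
  return Rcpp::List::create(
      Rcpp::Named("dX") = conv_to<mat>::from(to_sample_major(dXt, T, B)),
      Rcpp::Named("dW") = dWs,
      Rcpp::Named("db") = conv_to<rowvec>::from(Row<eT>(sum(dYt, 0))));
}

// [[Rcpp::export(name = ".conv1d_bwd_cpp")]]
Rcpp::List conv1d_bwd_cpp(SEXP cache, const arma::mat& dY,
                          const Rcpp::List& Ws) {
  Rcpp::XPtr<ConvCache> ptr(cache);
  Rcpp::List out = ptr->single
      ? conv1d_bwd_t<float>(ptr->Xt_f, dY, Ws, ptr->T, ptr->B)
      : conv1d_bwd_t<double>(ptr->Xt_d, dY, Ws, ptr->T, ptr->B);
  ptr->Xt_f.reset();
  ptr->Xt_d.reset();
  return out;
}

// ------------------------------------------------------------------- GRU
// Gate convention (r = reset, z = update, n = candidate):
//   r = sigmoid(Wr x + Ur h + br + cr)
//   z = sigmoid(Wz x + Uz h + bz + cz)
//   n = tanh(Wn x + bn + r % (Un h + cn))
//   h = (1 - z) % n + z % h_prev
// Wx stacks [Wr Wz Wn] (D x 3H); Wh stacks [Ur Uz Un] (H x 3H). Caches are
// returned time-major and passed back verbatim to the backward kernel.

template <typename eT>
static mat gru_fwd_t(Mat<eT>& Xs, Mat<eT>& R, Mat<eT>& Z,
                     Mat<eT>& N, Mat<eT>& HPn, Mat<eT>& Hprev,
                     const mat& X, const mat& Wx, const mat& Wh,
                     const rowvec& bx, const rowvec& bh,
                     int T, int B, bool reverse) {
  const int H = Wh.n_cols / 3;
  const uword n = X.n_rows;
  Mat<eT> Wxf = as_et<eT>(Wx), Whf = as_et<eT>(Wh);
  Row<eT> bxf = conv_to<Row<eT>>::from(bx), bhf = conv_to<Row<eT>>::from(bh);
  Xs = as_et<eT>(X);
  Mat<eT> Xpt = to_time_major(Mat<eT>(Xs * Wxf), T, B);
  Xpt.each_row() += bxf;
  R.set_size(n, H); Z.set_size(n, H); N.set_size(n, H);
  HPn.set_size(n, H); Hprev.set_size(n, H);
  Mat<eT> Houtt(n, H);
  Mat<eT> h(B, H, fill::zeros), hp(B, 3 * H);
  for (int s = 0; s < T; ++s) {
    int t = reverse ? (T - 1 - s) : s;
    uword r0 = (uword)t * B;
    hp = h * Whf;
    for (int c = 0; c < H; ++c) {
      const eT* xr = Xpt.colptr(c) + r0;
      const eT* xz = Xpt.colptr(H + c) + r0;
      const eT* xn = Xpt.colptr(2 * H + c) + r0;
      const eT* hr = hp.colptr(c);
      const eT* hz = hp.colptr(H + c);
      const eT* hcn = hp.colptr(2 * H + c);
      const eT br = bhf[c], bz = bhf[H + c], bn = bhf[2 * H + c];
      eT* hcol = h.colptr(c);
      eT* Rc = R.colptr(c) + r0;
      eT* Zc = Z.colptr(c) + r0;
      eT* Nc = N.colptr(c) + r0;
      eT* Pc = HPn.colptr(c) + r0;
      eT* Hc = Hprev.colptr(c) + r0;
      eT* Oc = Houtt.colptr(c) + r0;
      for (int b = 0; b < B; ++b) {
        const eT r = sigm1<eT>(xr[b] + hr[b] + br);
        const eT z = sigm1<eT>(xz[b] + hz[b] + bz);
        const eT hn = hcn[b] + bn;
        const eT nn = std::tanh(xn[b] + r * hn);
        const eT hprev = hcol[b];
        Rc[b] = r; Zc[b] = z; Nc[b] = nn; Pc[b] = hn; Hc[b] = hprev;
        const eT hnew = (eT(1) - z) * nn + z * hprev;
        hcol[b] = hnew;
        Oc[b] = hnew;
      }
    }
  }
  return conv_to<mat>::from(to_sample_major(Houtt, T, B));
}

// [[Rcpp::export(name = ".gru_fwd_cpp")]]
Rcpp::List gru_fwd_cpp(const arma::mat& X, const arma::mat& Wx,
                       const arma::mat& Wh, const arma::rowvec& bx,
                       const arma::rowvec& bh, int T, int B, bool reverse,
                       bool single, bool keep) {
  Rcpp::XPtr<GruCache> ptr(new GruCache, true);
  ptr->single = single; ptr->T = T; ptr->B = B; ptr->reverse = reverse;
  mat Y = single
      ? gru_fwd_t<float>(ptr->Xf, ptr->R_f, ptr->Z_f, ptr->N_f,
                         ptr->P_f, ptr->H_f, X, Wx, Wh, bx, bh, T, B,
                         reverse)
      : gru_fwd_t<double>(ptr->Xd, ptr->R_d, ptr->Z_d, ptr->N_d,
                          ptr->P_d, ptr->H_d, X, Wx, Wh, bx, bh, T, B,
                          reverse);
  if (!keep) *ptr = GruCache();
  return Rcpp::List::create(Rcpp::Named("Y") = Y, Rcpp::Named("ptr") = ptr);
}

template <typename eT>
static Rcpp::List gru_bwd_t(const Mat<eT>& Xs, const Mat<eT>& Rf,
                            const Mat<eT>& Zf, const Mat<eT>& Nf,
                            const Mat<eT>& Pf, const Mat<eT>& Hf,
                            const mat& dY, const mat& Wx, const mat& Wh,
                            int T, int B, bool reverse) {
  const int H = Wh.n_cols / 3;
  const uword n = Xs.n_rows;
  Mat<eT> Wxf = as_et<eT>(Wx), Whf = as_et<eT>(Wh);
  Mat<eT> dYt = to_time_major(as_et<eT>(dY), T, B);
  Mat<eT> dXpt(n, 3 * H, fill::zeros);
  Mat<eT> dWh(H, 3 * H, fill::zeros);
  Row<eT> dbh(3 * H, fill::zeros);
  Mat<eT> dh_carry(B, H, fill::zeros);
  Mat<eT> dhp(B, 3 * H), hprev_t(B, H);
  for (int s = T - 1; s >= 0; --s) {
    int t = reverse ? (T - 1 - s) : s;
    uword r0 = (uword)t * B;
    for (int c = 0; c < H; ++c) {
      const eT* dy = dYt.colptr(c) + r0;
      const eT* Rc = Rf.colptr(c) + r0;
      const eT* Zc = Zf.colptr(c) + r0;
      const eT* Nc = Nf.colptr(c) + r0;
      const eT* Pc = Pf.colptr(c) + r0;
      const eT* Hc = Hf.colptr(c) + r0;
      eT* carry = dh_carry.colptr(c);
      eT* dhp_r = dhp.colptr(c);
      eT* dhp_z = dhp.colptr(H + c);
      eT* dhp_n = dhp.colptr(2 * H + c);
      eT* dx_r = dXpt.colptr(c) + r0;
      eT* dx_z = dXpt.colptr(H + c) + r0;
      eT* dx_n = dXpt.colptr(2 * H + c) + r0;
      eT* hpv = hprev_t.colptr(c);
      for (int b = 0; b < B; ++b) {
        const eT dh = dy[b] + carry[b];
        const eT r = Rc[b], z = Zc[b], nn = Nc[b];
        const eT dn_pre = dh * (eT(1) - z) * (eT(1) - nn * nn);
        const eT dz_pre = dh * (Hc[b] - nn) * z * (eT(1) - z);
        const eT dr_pre = dn_pre * Pc[b] * r * (eT(1) - r);
        dhp_r[b] = dr_pre; dhp_z[b] = dz_pre; dhp_n[b] = dn_pre * r;
        dx_r[b] = dr_pre; dx_z[b] = dz_pre; dx_n[b] = dn_pre;
        carry[b] = dh * z;  // recurrent gemm contribution added below
        hpv[b] = Hc[b];
      }
    }
    dh_carry += dhp * Whf.t();
    dWh += hprev_t.t() * dhp;
    dbh += sum(dhp, 0);
  }
  Mat<eT> dXp = to_sample_major(dXpt, T, B);
  return Rcpp::List::create(
      Rcpp::Named("dX") = conv_to<mat>::from(Mat<eT>(dXp * Wxf.t())),
      Rcpp::Named("dWx") = conv_to<mat>::from(Mat<eT>(Xs.t() * dXp)),
      Rcpp::Named("dbx") = conv_to<rowvec>::from(Row<eT>(sum(dXp, 0))),
      Rcpp::Named("dWh") = conv_to<mat>::from(dWh),
      Rcpp::Named("dbh") = conv_to<rowvec>::from(dbh));
}

// [[Rcpp::export(name = ".gru_bwd_cpp")]]
Rcpp::List gru_bwd_cpp(SEXP cache, const arma::mat& dY, const arma::mat& Wx,
                       const arma::mat& Wh) {
  Rcpp::XPtr<GruCache> p(cache);
  Rcpp::List out = p->single
      ? gru_bwd_t<float>(p->Xf, p->R_f, p->Z_f, p->N_f, p->P_f, p->H_f,
                         dY, Wx, Wh, p->T, p->B, p->reverse)
      : gru_bwd_t<double>(p->Xd, p->R_d, p->Z_d, p->N_d, p->P_d, p->H_d,
                          dY, Wx, Wh, p->T, p->B, p->reverse);
  bool single = p->single; int T = p->T, B = p->B; bool rev = p->reverse;
  *p = GruCache();
  p->single = single; p->T = T; p->B = B; p->reverse = rev;
  return out;
}

// ------------------------------------------------------- multi-head attn
// Scaled dot-product attention per (sample, head) with optional inverted
// dropout on the post-softmax weights (mask drawn from R's RNG so runs are
// reproducible under set.seed). P and M are (T x T x B*heads) cubes.

template <typename eT>
static Rcpp::List mha_fwd_t(const mat& q_in, const mat& k_in,
                            const mat& v_in, int T, int B, int heads,
                            double p_drop, bool train) {
  const int H = q_in.n_cols;
  const int dh = H / heads;
  const eT scale = eT(1) / std::sqrt((eT)dh);
  Mat<eT> q = as_et<eT>(q_in), k = as_et<eT>(k_in), v = as_et<eT>(v_in);
  Mat<eT> O(q.n_rows, H, fill::zeros);
  cube P(T, T, (uword)B * heads);
  const bool use_drop = train && p_drop > 0;
  cube M;
  if (use_drop) M.set_size(T, T, (uword)B * heads);
  for (int b = 0; b < B; ++b) {
    uword s0 = (uword)b * T, s1 = s0 + T - 1;
    for (int h = 0; h < heads; ++h) {
      uword c0 = (uword)h * dh, c1 = c0 + dh - 1;
      Mat<eT> S = q.submat(s0, c0, s1, c1) *
                  k.submat(s0, c0, s1, c1).t() * scale;
      S.each_col() -= max(S, 1);
      Mat<eT> Pm = exp(S);
      Pm.each_col() /= sum(Pm, 1);
      uword cell = (uword)b * heads + h;
      P.slice(cell) = conv_to<mat>::from(Pm);
      if (use_drop) {
        mat& Mm = M.slice(cell);
        for (uword j = 0; j < Mm.n_elem; ++j)
          Mm[j] = (R::unif_rand() >= p_drop) ? 1.0 / (1.0 - p_drop) : 0.0;
        Pm %= as_et<eT>(Mm);
      }
      O.submat(s0, c0, s1, c1) = Pm * v.submat(s0, c0, s1, c1);
    }
  }
  return Rcpp::List::create(Rcpp::Named("O") = conv_to<mat>::from(O),
                            Rcpp::Named("P") = P, Rcpp::Named("M") = M);
}

// [[Rcpp::export(name = ".mha_fwd_cpp")]]
Rcpp::List mha_fwd_cpp(const arma::mat& q, const arma::mat& k,
                       const arma::mat& v, int T, int B, int heads,
                       double p_drop, bool train, bool single) {
  return single ? mha_fwd_t<float>(q, k, v, T, B, heads, p_drop, train)
                : mha_fwd_t<double>(q, k, v, T, B, heads, p_drop, train);
}

template <typename eT>
static Rcpp::List mha_bwd_t(const mat& dO_in, const mat& q_in,
                            const mat& k_in, const mat& v_in,
                            const cube& P, const cube& M,
                            int T, int B, int heads) {
  const int H = q_in.n_cols;
  const int dh = H / heads;
  const eT scale = eT(1) / std::sqrt((eT)dh);
  const bool use_drop = M.n_elem > 0;
  Mat<eT> q = as_et<eT>(q_in), k = as_et<eT>(k_in), v = as_et<eT>(v_in);
  Mat<eT> dO = as_et<eT>(dO_in);
  Mat<eT> dq(q.n_rows, H, fill::zeros), dk(q.n_rows, H, fill::zeros),
      dv(q.n_rows, H, fill::zeros);
  for (int b = 0; b < B; ++b) {
    uword s0 = (uword)b * T, s1 = s0 + T - 1;
    for (int h = 0; h < heads; ++h) {
      uword c0 = (uword)h * dh, c1 = c0 + dh - 1;
      uword cell = (uword)b * heads + h;
      Mat<eT> Pm = as_et<eT>(P.slice(cell));
      Mat<eT> dOb = dO.submat(s0, c0, s1, c1);
      Mat<eT> vb = v.submat(s0, c0, s1, c1);
      Mat<eT> dPd = dOb * vb.t();
      Mat<eT> Pd = Pm;
      Mat<eT> dP = dPd;
      if (use_drop) {
        Mat<eT> Mm = as_et<eT>(M.slice(cell));
        Pd = Pm % Mm;
        dP = dPd % Mm;
      }
      dv.submat(s0, c0, s1, c1) = Pd.t() * dOb;
      // softmax backward: dS = P % (dP - rowsum(dP % P))
      Mat<eT> dS = Pm % dP;
      Col<eT> rs = sum(dS, 1);
      dS -= Pm.each_col() % rs;
      dS *= scale;
      dq.submat(s0, c0, s1, c1) = dS * k.submat(s0, c0, s1, c1);
      dk.submat(s0, c0, s1, c1) = dS.t() * q.submat(s0, c0, s1, c1);
    }
  }
  return Rcpp::List::create(Rcpp::Named("dq") = conv_to<mat>::from(dq),
                            Rcpp::Named("dk") = conv_to<mat>::from(dk),
                            Rcpp::Named("dv") = conv_to<mat>::from(dv));
}

// [[Rcpp::export(name = ".mha_bwd_cpp")]]
Rcpp::List mha_bwd_cpp(const arma::mat& dO, const arma::mat& q,
                       const arma::mat& k, const arma::mat& v,
                       const arma::cube& P, const arma::cube& M,
                       int T, int B, int heads, bool single) {
  return single ? mha_bwd_t<float>(dO, q, k, v, P, M, T, B, heads)
                : mha_bwd_t<double>(dO, q, k, v, P, M, T, B, heads);
}
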