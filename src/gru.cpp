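// Bidirectional GRU frame classifier: forward pass, weighted cross-entropy
// loss and analytic backpropagation-through-time gradients.
//
// Layout: L stacked bidirectional GRU layers (forward/backward outputs
// concatenated between layers), dropout on the final concatenated output,
// then FC(tanh) -> FC(tanh) -> linear -> softmax over the frame states.
// Gate row blocks within the 3H-row input/hidden weight matrices are
// ordered (reset, update, candidate); the candidate's hidden projection is
// gated by reset *after* its bias is added.
//
// A batch is a set of equal-length sequences, held as cubes with dims
// (features, batch, time) so each time slice is one BLAS-friendly matrix.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;
using arma::cube;
using arma::mat;
using arma::vec;

static inline mat sigm(const mat& x) { return 1.0 / (1.0 + arma::exp(-x)); }

static void gru_dir_forward(const mat& Wi, const mat& Wh, const vec& bi,
                            const vec& bh, const cube& In, cube& R, cube& Z,
                            cube& Nn, cube& S, cube& H, bool fwd) {
  const int T = In.n_slices, B = In.n_cols, Hn = Wh.n_cols;
  mat h_prev(Hn, B, arma::fill::zeros);
  for (int i = 0; i < T; ++i) {
    const int t = fwd ? i : (T - 1 - i);
    mat a = Wi * In.slice(t);
    a.each_col() += bi;
    mat hh = Wh * h_prev;
    hh.each_col() += bh;
    mat r = sigm(a.rows(0, Hn - 1) + hh.rows(0, Hn - 1));
    mat z = sigm(a.rows(Hn, 2 * Hn - 1) + hh.rows(Hn, 2 * Hn - 1));
    mat s = hh.rows(2 * Hn, 3 * Hn - 1);
    mat n = arma::tanh(a.rows(2 * Hn, 3 * Hn - 1) + r % s);
    mat h = (1.0 - z) % n + z % h_prev;
    R.slice(t) = r; Z.slice(t) = z; Nn.slice(t) = n; S.slice(t) = s;
    H.slice(t) = h;
    h_prev = h;
  }
}

static void gru_dir_backward(const mat& Wi, const mat& Wh, const cube& In,
                             const cube& R, const cube& Z, const cube& Nn,
                             const cube& S, const cube& H, const cube& dHpart,
                             bool fwd, mat& gWi, mat& gWh, vec& gbi, vec& gbh,
                             cube& dIn) {
  const int T = In.n_slices, B = In.n_cols, Hn = Wh.n_cols;
  mat carry(Hn, B, arma::fill::zeros);
  for (int i = 0; i < T; ++i) {
    const int t = fwd ? (T - 1 - i) : i; // reverse of forward order
    const bool at_start = fwd ? (t == 0) : (t == T - 1);
    mat h_prev = at_start ? mat(Hn, B, arma::fill::zeros)
                          : mat(H.slice(fwd ? t - 1 : t + 1));
    const mat& r = R.slice(t);
    const mat& z = Z.slice(t);
    const mat& n = Nn.slice(t);
    const mat& s = S.slice(t);
    mat dh = dHpart.slice(t) + carry;
    mat dz = dh % (h_prev - n);
    mat dn = dh % (1.0 - z);
    mat da_n = dn % (1.0 - n % n);
    mat dr = da_n % s;
    mat ds = da_n % r;
    mat da_z = dz % z % (1.0 - z);
    mat da_r = dr % r % (1.0 - r);
    mat dA = arma::join_cols(da_r, da_z, da_n);
    gWi += dA * In.slice(t).t();
    gbi += arma::sum(dA, 1);
    gWh.rows(0, Hn - 1) += da_r * h_prev.t();
    gWh.rows(Hn, 2 * Hn - 1) += da_z * h_prev.t();
    gWh.rows(2 * Hn, 3 * Hn - 1) += ds * h_prev.t();
    gbh.subvec(0, Hn - 1) += arma::sum(da_r, 1);
    gbh.subvec(Hn, 2 * Hn - 1) += arma::sum(da_z, 1);
    gbh.subvec(2 * Hn, 3 * Hn - 1) += arma::sum(ds, 1);
    carry = dh % z + Wh.rows(0, Hn - 1).t() * da_r +
            Wh.rows(Hn, 2 * Hn - 1).t() * da_z +
            Wh.rows(2 * Hn, 3 * Hn - 1).t() * ds;
    dIn.slice(t) += Wi.t() * dA;
  }
}

// [[Rcpp::export]]
List gru_run(List params, List xlist, Nullable<IntegerMatrix> y_,
             NumericVector class_w, double dropout, bool training,
             bool want_grad, bool want_probs) {
  const int B = xlist.size();
  NumericMatrix x0 = xlist[0];
  const int T = x0.nrow(), F0 = x0.ncol();
  const int n_layers = 3;

  // batch cube (features, batch, time)
  cube X(F0, B, T);
  for (int b = 0; b < B; ++b) {
    NumericMatrix xb = xlist[b];
    if (xb.nrow() != T || xb.ncol() != F0)
      stop("all sequences in a batch must share dimensions");
    for (int t = 0; t < T; ++t)
      for (int f = 0; f < F0; ++f) X(f, b, t) = xb(t, f);
  }

  auto P = [&](const std::string& nm) -> mat {
    return as<mat>(params[nm]);
  };
  auto Pv = [&](const std::string& nm) -> vec {
    return as<vec>(params[nm]);
  };

  std::vector<mat> Wi(6), Wh(6);
  std::vector<vec> bi(6), bh(6);
  const char* dirs = "fb";
  for (int l = 0; l < n_layers; ++l)
    for (int d = 0; d < 2; ++d) {
      std::string suf = std::to_string(l + 1) + std::string(1, dirs[d]);
      Wi[2 * l + d] = P("Wi" + suf);
      Wh[2 * l + d] = P("Wh" + suf);
      bi[2 * l + d] = Pv("bi" + suf);
      bh[2 * l + d] = Pv("bh" + suf);
    }
  const int Hn = Wh[0].n_cols;
  mat W1 = P("Wfc1"), W2 = P("Wfc2"), W3 = P("Wout");
  vec b1 = Pv("bfc1"), b2 = Pv("bfc2"), b3 = Pv("bout");
  const int C = W3.n_rows;

  // forward through the GRU stack
  std::vector<cube> R(6), Z(6), Nn(6), S(6), H(6), Ins(n_layers + 1);
  Ins[0] = X;
  for (int l = 0; l < n_layers; ++l) {
    for (int d = 0; d < 2; ++d) {
      int k = 2 * l + d;
      R[k].set_size(Hn, B, T); Z[k].set_size(Hn, B, T);
      Nn[k].set_size(Hn, B, T); S[k].set_size(Hn, B, T);
      H[k].set_size(Hn, B, T);
      gru_dir_forward(Wi[k], Wh[k], bi[k], bh[k], Ins[l], R[k], Z[k], Nn[k],
                      S[k], H[k], d == 0);
    }
    Ins[l + 1].set_size(2 * Hn, B, T);
    Ins[l + 1].rows(0, Hn - 1) = H[2 * l];
    Ins[l + 1].rows(Hn, 2 * Hn - 1) = H[2 * l + 1];
  }

  // dropout between the GRU stack and the FC head (inverted scaling)
  cube D = Ins[n_layers];
  cube mask;
  const bool use_drop = training && dropout > 0;
  if (use_drop) {
    mask.set_size(D.n_rows, B, T);
    const double keep = 1.0 - dropout;
    for (arma::uword i = 0; i < mask.n_elem; ++i)
      mask(i) = (R::unif_rand() < keep) ? 1.0 / keep : 0.0;
    D %= mask;
  }

  // FC head on the flattened (features x batch*time) view
  mat Dm(D.memptr(), D.n_rows, B * T, false, true);
  mat A1 = W1 * Dm; A1.each_col() += b1; A1 = arma::tanh(A1);
  mat A2 = W2 * A1; A2.each_col() += b2; A2 = arma::tanh(A2);
  mat Logits = W3 * A2; Logits.each_col() += b3;
  mat Pm = Logits;
  Pm.each_row() -= arma::max(Pm, 0);
  Pm = arma::exp(Pm);
  Pm.each_row() /= arma::sum(Pm, 0);

  List out;
  double loss = NA_REAL;
  mat dLogits;
  if (y_.isNotNull()) {
    IntegerMatrix y(y_);
    if (y.nrow() != T || y.ncol() != B) stop("label matrix must be T x B");
    double lsum = 0, wsum = 0;
    for (int t = 0; t < T; ++t)
      for (int b = 0; b < B; ++b) {
        int cls = y(t, b) - 1;
        double w = class_w[cls];
        lsum += -w * std::log(std::max(Pm(cls, t * B + b), 1e-300));
        wsum += w;
      }
    loss = lsum / wsum;
    if (want_grad) {
      dLogits = Pm;
      for (int t = 0; t < T; ++t)
        for (int b = 0; b < B; ++b) {
          int col = t * B + b;
          int cls = y(t, b) - 1;
          dLogits(cls, col) -= 1.0;
          dLogits.col(col) *= class_w[cls] / wsum;
        }
    }
  }
  out["loss"] = loss;

  if (want_probs) {
    List probs(B);
    for (int b = 0; b < B; ++b) {
      NumericMatrix pb(T, C);
      for (int t = 0; t < T; ++t)
        for (int c = 0; c < C; ++c) pb(t, c) = Pm(c, t * B + b);
      probs[b] = pb;
    }
    out["probs"] = probs;
  }

  if (want_grad && y_.isNotNull()) {
    List grads;
    mat gW3 = dLogits * A2.t();
    vec gb3 = arma::sum(dLogits, 1);
    mat dA2 = W3.t() * dLogits;
    dA2 %= (1.0 - A2 % A2);
    mat gW2 = dA2 * A1.t();
    vec gb2 = arma::sum(dA2, 1);
    mat dA1 = W2.t() * dA2;
    dA1 %= (1.0 - A1 % A1);
    mat gW1 = dA1 * Dm.t();
    vec gb1 = arma::sum(dA1, 1);
    mat dDm = W1.t() * dA1;
    cube dOut(dDm.memptr(), 2 * Hn, B, T);
    if (use_drop) dOut %= mask;

    for (int l = n_layers - 1; l >= 0; --l) {
      cube dIn(Ins[l].n_rows, B, T, arma::fill::zeros);
      for (int d = 0; d < 2; ++d) {
        int k = 2 * l + d;
        mat gWik(arma::size(Wi[k]), arma::fill::zeros);
        mat gWhk(arma::size(Wh[k]), arma::fill::zeros);
        vec gbik(bi[k].n_elem, arma::fill::zeros);
        vec gbhk(bh[k].n_elem, arma::fill::zeros);
        cube dHpart = d == 0 ? dOut.rows(0, Hn - 1)
                             : dOut.rows(Hn, 2 * Hn - 1);
        gru_dir_backward(Wi[k], Wh[k], Ins[l], R[k], Z[k], Nn[k], S[k], H[k],
                         dHpart, d == 0, gWik, gWhk, gbik, gbhk, dIn);
        std::string suf = std::to_string(l + 1) + std::string(1, dirs[d]);
        grads["Wi" + suf] = gWik;
        grads["Wh" + suf] = gWhk;
        grads["bi" + suf] = NumericVector(gbik.begin(), gbik.end());
        grads["bh" + suf] = NumericVector(gbhk.begin(), gbhk.end());
      }
      dOut = dIn;
    }
    grads["Wfc1"] = gW1;
    grads["bfc1"] = NumericVector(gb1.begin(), gb1.end());
    grads["Wfc2"] = gW2;
    grads["bfc2"] = NumericVector(gb2.begin(), gb2.end());
    grads["Wout"] = gW3;
    grads["bout"] = NumericVector(gb3.begin(), gb3.end());
    out["grads"] = grads;
  }
  return out;
}
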