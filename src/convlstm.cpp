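// Batched ConvLSTM forward/backward used by the training loop.
//
// Convolutions are realized as im2col patch extraction followed by a dense
// multiply. Frames are flattened column-major (pixel p = r + c*rows); patch
// column ch*k2 + o holds the neighbour at offset o, where offset o maps to
// (dr, dc) = (o % k - pad, o / k - pad). A batch of B samples is stacked to
// B*P rows, so one GEMM serves the whole batch. Gate order: i, f, g, o.
// Arithmetic is single precision (the deep-learning convention); the R
// boundary is double.
//
// Peephole connections are not supported on this path (the cell-level R
// implementation provides them); the training network uses the mainstream
// peephole-free variant.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using arma::fmat;
using arma::fvec;
using arma::frowvec;
using arma::umat;
using arma::uword;

namespace {

// neighbour index table, sentinel = BP (points at an implicit zero row)
umat make_index(int rows, int cols, int k, int B) {
  const int P = rows * cols, BP = B * P, pad = k / 2, k2 = k * k;
  umat idx(BP, k2);
  for (int o = 0; o < k2; ++o) {
    int dr = o % k - pad, dc = o / k - pad;
    for (int b = 0; b < B; ++b)
      for (int c = 0; c < cols; ++c)
        for (int r = 0; r < rows; ++r) {
          int p = r + c * rows;
          int rr = r + dr, cc = c + dc;
          idx(b * P + p, o) =
              (rr >= 0 && rr < rows && cc >= 0 && cc < cols)
                  ? (uword)(b * P + rr + cc * rows)
                  : (uword)BP;
        }
  }
  return idx;
}

fmat im2col(const fmat& X, const umat& idx, int k2) {
  const uword BP = X.n_rows, C = X.n_cols;
  fmat out(BP, C * k2);
  for (int o = 0; o < k2; ++o)
    for (uword ch = 0; ch < C; ++ch) {
      float* dst = out.colptr(ch * k2 + o);
      const float* src = X.colptr(ch);
      for (uword r = 0; r < BP; ++r) {
        uword s = idx(r, o);
        dst[r] = (s < BP) ? src[s] : 0.0f;
      }
    }
  return out;
}

fmat col2im(const fmat& dP, const umat& idx, int k2, uword C) {
  const uword BP = dP.n_rows;
  fmat out(BP, C, arma::fill::zeros);
  for (int o = 0; o < k2; ++o)
    for (uword ch = 0; ch < C; ++ch) {
      const float* src = dP.colptr(ch * k2 + o);
      float* dst = out.colptr(ch);
      for (uword r = 0; r < BP; ++r) {
        uword s = idx(r, o);
        if (s < BP) dst[s] += src[r];
      }
    }
  return out;
}

inline fmat sigm(const fmat& z) { return 1.0f / (1.0f + exp(-z)); }

struct Cache {
  fmat Px, Ph, I, F, G, O, Cprev, TC;
};

// x: (P, L, B) cube; weights: per layer Wx (k2*Cin x 4F), Wh (k2*F x 4F),
// b (4F). Head: Whead (k2*F x 1), bhead scalar.
Rcpp::List run(const arma::cube& x, const Rcpp::List& layers,
               const arma::vec& Whead_d, double bhead, int rows, int cols,
               int k, const arma::mat& target, bool backward) {
  const int P = rows * cols, L = x.n_cols, B = x.n_slices, BP = B * P;
  const int k2 = k * k, nl = layers.size();
  const umat idx = make_index(rows, cols, k, B);
  const fvec Whead = arma::conv_to<fvec>::from(Whead_d);

  std::vector<fmat> Wx(nl), Wh(nl);
  std::vector<fvec> bias(nl);
  for (int l = 0; l < nl; ++l) {
    Rcpp::List lay = layers[l];
    Wx[l] = arma::conv_to<fmat>::from(Rcpp::as<arma::mat>(lay["Wx"]));
    Wh[l] = arma::conv_to<fmat>::from(Rcpp::as<arma::mat>(lay["Wh"]));
    bias[l] = arma::conv_to<fvec>::from(Rcpp::as<arma::vec>(lay["b"]));
  }
  const int F4 = Wx[0].n_cols, F = F4 / 4;

  // stacked input frames for layer 0
  std::vector<fmat> Xin(L, fmat(BP, 1));
  for (int t = 0; t < L; ++t)
    for (int b = 0; b < B; ++b)
      for (int p = 0; p < P; ++p)
        Xin[t](b * P + p, 0) = (float)x(p, t, b);

  std::vector<std::vector<Cache>> cache(nl);
  std::vector<std::vector<fmat>> Hseq(nl);
  fmat Hlast;
  for (int l = 0; l < nl; ++l) {
    fmat H(BP, F, arma::fill::zeros), C(BP, F, arma::fill::zeros);
    cache[l].resize(L);
    Hseq[l].resize(L);
    for (int t = 0; t < L; ++t) {
      const fmat& X = (l == 0) ? Xin[t] : Hseq[l - 1][t];
      fmat Px = im2col(X, idx, k2);
      fmat Ph = im2col(H, idx, k2);
      fmat Z = Px * Wx[l] + Ph * Wh[l];
      Z.each_row() += bias[l].t();
      fmat I = sigm(Z.cols(0, F - 1));
      fmat Fg = sigm(Z.cols(F, 2 * F - 1));
      fmat G = tanh(Z.cols(2 * F, 3 * F - 1));
      fmat O = sigm(Z.cols(3 * F, 4 * F - 1));
      fmat Cprev = C;
      C = Fg % Cprev + I % G;
      fmat TC = tanh(C);
      H = O % TC;
      Hseq[l][t] = H;
      if (backward) cache[l][t] = {std::move(Px), std::move(Ph), std::move(I),
                                   std::move(Fg), std::move(G), std::move(O),
                                   std::move(Cprev), std::move(TC)};
    }
    Hlast = H;
  }

  fmat Phd = im2col(Hlast, idx, k2);
  fvec y = Phd * Whead + (float)bhead;

  auto unstack = [&](const fvec& v) {
    arma::mat out(P, B);
    for (int b = 0; b < B; ++b)
      for (int p = 0; p < P; ++p) out(p, b) = v(b * P + p);
    return out;
  };

  double loss = NA_REAL;
  if (target.n_elem) {
    fvec targ(BP);
    for (int b = 0; b < B; ++b)
      for (int p = 0; p < P; ++p) targ(b * P + p) = (float)target(p, b);
    loss = arma::accu(arma::square(y - targ)) / (double)BP;
    if (backward) {
      fvec dy = 2.0f * (y - targ) / (float)BP;
      fvec dWhead = Phd.t() * dy;
      double dbhead = arma::accu(dy);
      fmat dPhd = dy * Whead.t();
      std::vector<std::vector<fmat>> dHabove(nl);
      for (int l = 0; l < nl; ++l)
        dHabove[l].assign(L, fmat(BP, F, arma::fill::zeros));
      dHabove[nl - 1][L - 1] = col2im(dPhd, idx, k2, F);

      Rcpp::List gl(nl);
      for (int l = nl - 1; l >= 0; --l) {
        const uword Cin = (l == 0) ? 1 : F;
        fmat dWx(Wx[l].n_rows, F4, arma::fill::zeros);
        fmat dWh(Wh[l].n_rows, F4, arma::fill::zeros);
        frowvec db(F4, arma::fill::zeros);
        fmat dHrec(BP, F, arma::fill::zeros), dCrec(BP, F, arma::fill::zeros);
        for (int t = L - 1; t >= 0; --t) {
          const Cache& cc = cache[l][t];
          fmat dH = dHabove[l][t] + dHrec;
          fmat dO = dH % cc.TC;
          fmat dC = dCrec + dH % cc.O % (1.0f - arma::square(cc.TC));
          fmat dI = dC % cc.G;
          fmat dG = dC % cc.I;
          fmat dF = dC % cc.Cprev;
          dCrec = dC % cc.F;
          fmat dZ(BP, F4);
          dZ.cols(0, F - 1) = dI % cc.I % (1.0f - cc.I);
          dZ.cols(F, 2 * F - 1) = dF % cc.F % (1.0f - cc.F);
          dZ.cols(2 * F, 3 * F - 1) = dG % (1.0f - arma::square(cc.G));
          dZ.cols(3 * F, 4 * F - 1) = dO % cc.O % (1.0f - cc.O);
          dWx += cc.Px.t() * dZ;
          dWh += cc.Ph.t() * dZ;
          db += sum(dZ, 0);
          fmat dPh = dZ * Wh[l].t();
          dHrec = col2im(dPh, idx, k2, F);
          if (l > 0) {
            fmat dPx = dZ * Wx[l].t();
            dHabove[l - 1][t] += col2im(dPx, idx, k2, Cin);
          }
        }
        gl[l] = Rcpp::List::create(
            Rcpp::Named("Wx") = arma::conv_to<arma::mat>::from(dWx),
            Rcpp::Named("Wh") = arma::conv_to<arma::mat>::from(dWh),
            Rcpp::Named("b") = arma::conv_to<arma::vec>::from(db.t()));
      }
      return Rcpp::List::create(
          Rcpp::Named("pred") = unstack(y), Rcpp::Named("loss") = loss,
          Rcpp::Named("grad_layers") = gl,
          Rcpp::Named("grad_Whead") = arma::conv_to<arma::vec>::from(dWhead),
          Rcpp::Named("grad_bhead") = dbhead);
    }
  }
  return Rcpp::List::create(Rcpp::Named("pred") = unstack(y),
                            Rcpp::Named("loss") = loss);
}

}  // namespace

// [[Rcpp::export]]
Rcpp::List clstm_grad_cpp(const arma::cube& x, const Rcpp::List& layers,
                          const arma::vec& Whead, double bhead, int rows,
                          int cols, int k, const arma::mat& target) {
  return run(x, layers, Whead, bhead, rows, cols, k, target, true);
}

// [[Rcpp::export]]
Rcpp::List clstm_predict_cpp(const arma::cube& x, const Rcpp::List& layers,
                             const arma::vec& Whead, double bhead, int rows,
                             int cols, int k) {
  return run(x, layers, Whead, bhead, rows, cols, k, arma::mat(), false);
}

// [[Rcpp::export]]
Rcpp::List clstm_loss_cpp(const arma::cube& x, const Rcpp::List& layers,
                          const arma::vec& Whead, double bhead, int rows,
                          int cols, int k, const arma::mat& target) {
  return run(x, layers, Whead, bhead, rows, cols, k, target, false);
}
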