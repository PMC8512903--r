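// Batched LSTM sequence forward/backward with per-gate layer normalization.
// Mirrors the reference R implementation (gate order: input, forget, cell
// candidate, output); the R-level tests check the kernel against the
// reference and its analytic gradients against finite differences.
//
// Inputs arrive as (B*T) x C matrices whose row block t holds the batch at
// timestep t. The input-side products (X * Wx, and the gradient
// accumulations X' dq, Hprev' dq) are single large GEMMs outside the
// timestep loop; only the recurrent products stay inside it.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;
using namespace arma;

static const double LN_EPS = 1e-5;

// Layer norm over each of the four gate blocks of `pre` (rows = batch),
// in place; writes xhat and per-row inverse sd per block. Hand-fused
// column loops: row-wise statistics are accumulated over contiguous
// columns to stay cache-friendly in arma's column-major layout.
static void ln4_fwd(mat& pre, const vec& gamma, const vec& beta, uword M,
                    mat& xhat, mat& istd) {
  const uword B = pre.n_rows;
  vec mu(B), var(B), is(B);
  for (uword k = 0; k < 4; ++k) {
    const uword c0 = k * M;
    mu.zeros();
    for (uword j = 0; j < M; ++j) mu += pre.unsafe_col(c0 + j);
    mu /= (double)M;
    var.zeros();
    for (uword j = 0; j < M; ++j) {
      double* xh = xhat.colptr(c0 + j);
      const double* pz = pre.colptr(c0 + j);
      const double* pm = mu.memptr();
      double* pv = var.memptr();
      for (uword i = 0; i < B; ++i) {
        const double d = pz[i] - pm[i];
        xh[i] = d;
        pv[i] += d * d;
      }
    }
    double* pis = is.memptr();
    const double* pv = var.memptr();
    for (uword i = 0; i < B; ++i) {
      pis[i] = 1.0 / std::sqrt(pv[i] / (double)M + LN_EPS);
    }
    istd.col(k) = is;
    for (uword j = 0; j < M; ++j) {
      double* xh = xhat.colptr(c0 + j);
      double* pz = pre.colptr(c0 + j);
      const double g = gamma(c0 + j), bb = beta(c0 + j);
      for (uword i = 0; i < B; ++i) {
        xh[i] *= pis[i];
        pz[i] = g * xh[i] + bb;
      }
    }
  }
}

static void ln4_bwd(mat& dq, const mat& xhat, const mat& istd,
                    const vec& gamma, uword M, vec& dgamma, vec& dbeta) {
  const uword B = dq.n_rows;
  vec m1(B), m2(B);
  for (uword k = 0; k < 4; ++k) {
    const uword c0 = k * M;
    m1.zeros();
    m2.zeros();
    for (uword j = 0; j < M; ++j) {
      double* pd = dq.colptr(c0 + j);
      const double* xh = xhat.colptr(c0 + j);
      const double g = gamma(c0 + j);
      double sg = 0.0, sb = 0.0;
      double* pm1 = m1.memptr();
      double* pm2 = m2.memptr();
      for (uword i = 0; i < B; ++i) {
        const double d = pd[i];
        sg += d * xh[i];
        sb += d;
        const double dxh = d * g;
        pd[i] = dxh;              // dq now holds dxhat
        pm1[i] += dxh;
        pm2[i] += dxh * xh[i];
      }
      dgamma(c0 + j) += sg;
      dbeta(c0 + j) += sb;
    }
    m1 /= (double)M;
    m2 /= (double)M;
    const double* pis = istd.colptr(k);
    for (uword j = 0; j < M; ++j) {
      double* pd = dq.colptr(c0 + j);
      const double* xh = xhat.colptr(c0 + j);
      const double* pm1 = m1.memptr();
      const double* pm2 = m2.memptr();
      for (uword i = 0; i < B; ++i) {
        pd[i] = pis[i] * (pd[i] - pm1[i] - xh[i] * pm2[i]);
      }
    }
  }
}

// [[Rcpp::export(name = ".lstm_seq_fwd_cpp")]]
List lstm_seq_fwd_cpp(const arma::mat& Xbig, int B_, int Tn_,
                      const arma::mat& Wx, const arma::mat& Wh,
                      const arma::vec& b, const arma::vec& gamma,
                      const arma::vec& beta, bool layer_norm) {
  const uword B = B_, Tn = Tn_;
  const uword M = Wh.n_rows;

  mat PRE = Xbig * Wx;            // one GEMM for the whole window
  PRE.each_row() += b.t();

  mat Hbig(B * Tn, M), GI(B * Tn, M), GF(B * Tn, M), GG(B * Tn, M),
      GO(B * Tn, M), TC(B * Tn, M), CPREV(B * Tn, M), HPREV(B * Tn, M);
  mat XHAT, ISTD;
  if (layer_norm) {
    XHAT.set_size(B * Tn, 4 * M);
    ISTD.set_size(B * Tn, 4);
  }

  mat h_prev(B, M, fill::zeros), c_prev(B, M, fill::zeros);
  for (uword t = 0; t < Tn; ++t) {
    const uword r0 = t * B, r1 = (t + 1) * B - 1;
    mat pre = PRE.rows(r0, r1) + h_prev * Wh;
    if (layer_norm) {
      mat xh(B, 4 * M), is(B, 4);
      ln4_fwd(pre, gamma, beta, M, xh, is);
      XHAT.rows(r0, r1) = xh;
      ISTD.rows(r0, r1) = is;
    }
    mat gi = 1.0 / (1.0 + exp(-pre.cols(0, M - 1)));
    mat gf = 1.0 / (1.0 + exp(-pre.cols(M, 2 * M - 1)));
    mat gg = tanh(pre.cols(2 * M, 3 * M - 1));
    mat go = 1.0 / (1.0 + exp(-pre.cols(3 * M, 4 * M - 1)));
    mat cst = gf % c_prev + gi % gg;
    mat tc = tanh(cst);

    HPREV.rows(r0, r1) = h_prev;
    CPREV.rows(r0, r1) = c_prev;
    GI.rows(r0, r1) = gi;
    GF.rows(r0, r1) = gf;
    GG.rows(r0, r1) = gg;
    GO.rows(r0, r1) = go;
    TC.rows(r0, r1) = tc;

    h_prev = go % tc;
    c_prev = cst;
    Hbig.rows(r0, r1) = h_prev;
  }

  return List::create(
      _["H"] = Hbig, _["GI"] = GI, _["GF"] = GF, _["GG"] = GG, _["GO"] = GO,
      _["TC"] = TC, _["CPREV"] = CPREV, _["HPREV"] = HPREV,
      _["XHAT"] = XHAT, _["ISTD"] = ISTD);
}

// [[Rcpp::export(name = ".lstm_seq_bwd_cpp")]]
List lstm_seq_bwd_cpp(const arma::mat& dHbig, const arma::mat& Xbig, int B_,
                      int Tn_, const arma::mat& Wx, const arma::mat& Wh,
                      const arma::vec& gamma, bool layer_norm,
                      const arma::mat& GI, const arma::mat& GF,
                      const arma::mat& GG, const arma::mat& GO,
                      const arma::mat& TC, const arma::mat& CPREV,
                      const arma::mat& HPREV, const arma::mat& XHAT,
                      const arma::mat& ISTD, bool need_dx) {
  const uword B = B_, Tn = Tn_;
  const uword M = Wh.n_rows;

  vec ggamma(4 * M, fill::zeros), gbeta(4 * M, fill::zeros);
  mat DQ(B * Tn, 4 * M);
  mat tWh = Wh.t();

  mat dh_next(B, M, fill::zeros), dc_next(B, M, fill::zeros);
  for (uword t = Tn; t-- > 0;) {
    const uword r0 = t * B, r1 = (t + 1) * B - 1;
    mat dh = dHbig.rows(r0, r1) + dh_next;
    const mat gi = GI.rows(r0, r1);
    const mat gf = GF.rows(r0, r1);
    const mat gg = GG.rows(r0, r1);
    const mat go = GO.rows(r0, r1);
    const mat tc = TC.rows(r0, r1);

    mat dgo = dh % tc;
    mat dc = dc_next + dh % go % (1.0 - square(tc));
    mat dgf = dc % CPREV.rows(r0, r1);
    mat dgi = dc % gg;
    mat dgg = dc % gi;
    dc_next = dc % gf;

    mat dq(B, 4 * M);
    dq.cols(0, M - 1) = dgi % gi % (1.0 - gi);
    dq.cols(M, 2 * M - 1) = dgf % gf % (1.0 - gf);
    dq.cols(2 * M, 3 * M - 1) = dgg % (1.0 - square(gg));
    dq.cols(3 * M, 4 * M - 1) = dgo % go % (1.0 - go);

    if (layer_norm) {
      ln4_bwd(dq, XHAT.rows(r0, r1), ISTD.rows(r0, r1), gamma, M,
              ggamma, gbeta);
    }
    DQ.rows(r0, r1) = dq;
    dh_next = dq * tWh;
  }

  // parameter gradients as single GEMMs over all timesteps
  mat gWx = Xbig.t() * DQ;
  mat gWh = HPREV.t() * DQ;
  vec gb = sum(DQ, 0).t();
  mat dXbig;
  if (need_dx) dXbig = DQ * Wx.t();

  return List::create(_["Wx"] = gWx, _["Wh"] = gWh, _["b"] = gb,
                      _["gamma"] = ggamma, _["beta"] = gbeta,
                      _["dX"] = dXbig);
}
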