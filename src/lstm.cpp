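// Batched LSTM core used by the actor and critic encoders. The forward
// pass returns only the final hidden state; the gradient pass recomputes
// the forward trajectory locally (cheaper than shipping caches across the
// R/C++ boundary) and backpropagates through time. Gate math is fused into
// explicit loops: the gemms go through BLAS, the pointwise cell update
// touches each element once.
//
// Layout contract (must match the R reference implementation in R/lstm.R):
//   Wx: d x 4h, Wh: h x 4h, b: 4h, gate order [input, forget, cell, output]
//   Xf: (B*T) x d with row index b + t*B (t-major blocks)

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;
using arma::mat;
using arma::vec;

static inline double sigm1(double x) { return 1.0 / (1.0 + std::exp(-x)); }

// one fused cell step: z (B x 4h, pre-bias) -> updates C, H in place and
// optionally records the gate values for the backward pass
static void cell_step(mat& z, const vec& b, mat& C, mat& H,
                      double* ip, double* fp, double* gp, double* op,
                      double* tCp, double* CPp, double* HPp) {
  const int B = z.n_rows;
  const int h = z.n_cols / 4;
  double* zp = z.memptr();
  const double* bp = b.memptr();
  double* Cp = C.memptr();
  double* Hp = H.memptr();
  for (int j = 0; j < h; ++j) {
    const double bi = bp[j], bf = bp[h + j], bg = bp[2 * h + j],
                 bo = bp[3 * h + j];
    const double* zi = zp + (size_t)j * B;
    const double* zf = zp + (size_t)(h + j) * B;
    const double* zg = zp + (size_t)(2 * h + j) * B;
    const double* zo = zp + (size_t)(3 * h + j) * B;
    double* cc = Cp + (size_t)j * B;
    double* hh = Hp + (size_t)j * B;
    const size_t off = (size_t)j * B;
    for (int r = 0; r < B; ++r) {
      const double ig = sigm1(zi[r] + bi);
      const double fg = sigm1(zf[r] + bf);
      const double gg = std::tanh(zg[r] + bg);
      const double og = sigm1(zo[r] + bo);
      if (CPp) { CPp[off + r] = cc[r]; HPp[off + r] = hh[r]; }
      const double c = fg * cc[r] + ig * gg;
      const double tc = std::tanh(c);
      cc[r] = c;
      hh[r] = og * tc;
      if (ip) {
        ip[off + r] = ig; fp[off + r] = fg; gp[off + r] = gg;
        op[off + r] = og; tCp[off + r] = tc;
      }
    }
  }
}

// [[Rcpp::export]]
arma::mat lstm_H_cpp(const arma::mat& Wx, const arma::mat& Wh,
                     const arma::vec& b, const arma::mat& Xf,
                     const int B, const int T) {
  const int h = Wh.n_rows;
  mat Zx = Xf * Wx;
  mat H(B, h, arma::fill::zeros), C(B, h, arma::fill::zeros);
  mat z(B, 4 * h);
  for (int t = 0; t < T; ++t) {
    z = Zx.rows(t * B, t * B + B - 1) + H * Wh;
    cell_step(z, b, C, H, nullptr, nullptr, nullptr, nullptr, nullptr,
              nullptr, nullptr);
  }
  return H;
}

// [[Rcpp::export]]
List lstm_grad_cpp(const arma::mat& Wx, const arma::mat& Wh,
                   const arma::vec& b, const arma::mat& Xf,
                   const int B, const int T, const arma::mat& dHfinal) {
  const int h = Wh.n_rows;
  mat Zx = Xf * Wx;
  arma::cube I(B, h, T), F(B, h, T), G(B, h, T), O(B, h, T),
             TC(B, h, T), CP(B, h, T), HP(B, h, T);
  mat H(B, h, arma::fill::zeros), C(B, h, arma::fill::zeros);
  mat z(B, 4 * h);
  for (int t = 0; t < T; ++t) {
    z = Zx.rows(t * B, t * B + B - 1) + H * Wh;
    cell_step(z, b, C, H,
              I.slice_memptr(t), F.slice_memptr(t), G.slice_memptr(t),
              O.slice_memptr(t), TC.slice_memptr(t),
              CP.slice_memptr(t), HP.slice_memptr(t));
  }

  mat dH = dHfinal;
  mat dC(B, h, arma::fill::zeros);
  mat dWh(h, 4 * h, arma::fill::zeros);
  vec db(4 * h, arma::fill::zeros);
  mat dZx(B * T, 4 * h);
  mat dz(B, 4 * h);
  const mat tWh = Wh.t();
  for (int t = T - 1; t >= 0; --t) {
    const double* ip = I.slice_memptr(t); const double* fp = F.slice_memptr(t);
    const double* gp = G.slice_memptr(t); const double* op = O.slice_memptr(t);
    const double* tCp = TC.slice_memptr(t);
    const double* CPp = CP.slice_memptr(t);
    double* dHp = dH.memptr(); double* dCp = dC.memptr();
    double* dzp = dz.memptr();
    const size_t n = (size_t)B * h;
    for (size_t k = 0; k < n; ++k) {
      const double dOv = dHp[k] * tCp[k];
      const double dCv = dCp[k] + dHp[k] * op[k] * (1.0 - tCp[k] * tCp[k]);
      dzp[k]           = (dCv * gp[k]) * ip[k] * (1.0 - ip[k]);
      dzp[n + k]       = (dCv * CPp[k]) * fp[k] * (1.0 - fp[k]);
      dzp[2 * n + k]   = (dCv * ip[k]) * (1.0 - gp[k] * gp[k]);
      dzp[3 * n + k]   = dOv * op[k] * (1.0 - op[k]);
      dCp[k] = dCv * fp[k];
    }
    dZx.rows(t * B, t * B + B - 1) = dz;
    dWh += HP.slice(t).t() * dz;
    db += arma::sum(dz, 0).t();
    dH = dz * tWh;
  }
  mat dWx = Xf.t() * dZx;
  return List::create(_["Wx"] = dWx, _["Wh"] = dWh, _["b"] = db);
}
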