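// GRU sequence kernels. Sequences are "stacked" matrices of shape
// [B*T, features] with rows grouped time-major: rows t*B .. t*B+B-1
// (0-based) hold timestep t. Gate order is reset, update, candidate:
//   r_t = s(Wi_r x + bi_r + Wh_r h + bh_r)
//   z_t = s(Wi_z x + bi_z + Wh_z h + bh_z)
//   n_t = tanh(Wi_n x + bi_n + r_t * (Wh_n h + bh_n))
//   h_t = (1 - z_t) * n_t + z_t * h_{t-1}
// Only the matrix products go through BLAS; the gate nonlinearities are
// fused elementwise loops writing straight into preallocated caches.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// [[Rcpp::export]]
Rcpp::List gru_fwd_cpp(const arma::mat& Wi, const arma::mat& Wh,
                       const arma::vec& bi, const arma::vec& bh,
                       const arma::mat& Xmat, const int B, const int Tn) {
  const int H = Wh.n_cols / 3;
  const std::size_t BT = (std::size_t)B * Tn;
  mat Gi = Xmat * Wi;
  Gi.each_row() += bi.t();
  mat Hmat(BT, H), R(BT, H), Z(BT, H), N(BT, H), M(BT, H);
  mat h(B, H, fill::zeros);
  mat gh(B, 3 * H);
  const double* bhp = bh.memptr();
  for (int t = 0; t < Tn; ++t) {
    const std::size_t r0 = (std::size_t)t * B;
    gh = h * Wh;
    const double* gi = Gi.memptr();
    const double* g = gh.memptr();
    double* rp = R.memptr(); double* zp = Z.memptr();
    double* np = N.memptr(); double* mp = M.memptr();
    double* hp = h.memptr();
    double* ho = Hmat.memptr();
    for (int j = 0; j < H; ++j) {
      const std::size_t oc = (std::size_t)j * BT + r0;     // cache column j
      const std::size_t ob = (std::size_t)j * B;           // state column j
      const std::size_t gr = ob;                           // gh col j
      const std::size_t gz = (std::size_t)(H + j) * B;
      const std::size_t gn = (std::size_t)(2 * H + j) * B;
      const std::size_t cr = (std::size_t)j * BT + r0;     // Gi col j
      const std::size_t cz = (std::size_t)(H + j) * BT + r0;
      const std::size_t cn = (std::size_t)(2 * H + j) * BT + r0;
      const double br = bhp[j], bz = bhp[H + j], bn = bhp[2 * H + j];
      for (int b = 0; b < B; ++b) {
        const double vr = 1.0 / (1.0 + std::exp(-(gi[cr + b] + g[gr + b] + br)));
        const double vz = 1.0 / (1.0 + std::exp(-(gi[cz + b] + g[gz + b] + bz)));
        const double vm = g[gn + b] + bn;
        const double vn = std::tanh(gi[cn + b] + vr * vm);
        const double vh = (1.0 - vz) * vn + vz * hp[ob + b];
        rp[oc + b] = vr; zp[oc + b] = vz; mp[oc + b] = vm; np[oc + b] = vn;
        hp[ob + b] = vh;
        ho[oc + b] = vh;
      }
    }
  }
  return Rcpp::List::create(Rcpp::Named("Hmat") = Hmat,
                            Rcpp::Named("R") = R, Rcpp::Named("Z") = Z,
                            Rcpp::Named("N") = N, Rcpp::Named("M") = M);
}

// [[Rcpp::export]]
Rcpp::List gru_bwd_cpp(const arma::mat& Wi, const arma::mat& Wh,
                       const arma::mat& Xmat, const arma::mat& Hmat,
                       const arma::mat& R, const arma::mat& Z,
                       const arma::mat& N, const arma::mat& M,
                       const arma::mat& dHmat, const int B, const int Tn) {
  const int H = Wh.n_cols / 3;
  const std::size_t BT = (std::size_t)B * Tn;
  const mat tWh = Wh.t();
  mat dWh(H, 3 * H, fill::zeros);
  rowvec dbh(3 * H, fill::zeros);
  mat dGi(BT, 3 * H);
  mat dh(B, H, fill::zeros);
  mat dgh(B, 3 * H);
  mat hprev(B, H);
  const double* rp = R.memptr(); const double* zp = Z.memptr();
  const double* np = N.memptr(); const double* mp = M.memptr();
  const double* hm = Hmat.memptr();
  const double* dHp = dHmat.memptr();
  double* dGp = dGi.memptr();
  for (int t = Tn - 1; t >= 0; --t) {
    const std::size_t r0 = (std::size_t)t * B;
    double* dhp = dh.memptr();
    double* dg = dgh.memptr();
    double* hq = hprev.memptr();
    for (int j = 0; j < H; ++j) {
      const std::size_t oc = (std::size_t)j * BT + r0;
      const std::size_t ob = (std::size_t)j * B;
      const std::size_t gz = (std::size_t)(H + j) * B;
      const std::size_t gn = (std::size_t)(2 * H + j) * B;
      const std::size_t cz = (std::size_t)(H + j) * BT + r0;
      const std::size_t cn = (std::size_t)(2 * H + j) * BT + r0;
      for (int b = 0; b < B; ++b) {
        const double r = rp[oc + b], z = zp[oc + b];
        const double n = np[oc + b], m = mp[oc + b];
        const double hpv = (t > 0) ? hm[oc - B + b] : 0.0;
        const double dht = dhp[ob + b] + dHp[oc + b];
        const double dn = dht * (1.0 - z);
        const double dz = dht * (hpv - n);
        const double dan = dn * (1.0 - n * n);
        const double dar = dan * m * r * (1.0 - r);
        const double daz = dz * z * (1.0 - z);
        const double dm = dan * r;
        dg[ob + b] = dar;
        dg[gz + b] = daz;
        dg[gn + b] = dm;
        dGp[oc + b] = dar;
        dGp[cz + b] = daz;
        dGp[cn + b] = dan;
        dhp[ob + b] = dht * z;           // part of d h_{t-1}
        hq[ob + b] = hpv;
      }
    }
    dWh += hprev.t() * dgh;
    dbh += sum(dgh, 0);
    dh += dgh * tWh;
  }
  return Rcpp::List::create(
      Rcpp::Named("dWi") = mat(Xmat.t() * dGi),
      Rcpp::Named("dWh") = dWh,
      Rcpp::Named("dbi") = vec(sum(dGi, 0).t()),
      Rcpp::Named("dbh") = vec(dbh.t()),
      Rcpp::Named("dXmat") = mat(dGi * Wi.t()));
}
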