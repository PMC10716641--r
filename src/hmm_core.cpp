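// Core numerics for the context hidden Markov model: scaled forward /
// forward-backward recursions over per-dive observation vectors, mixture over
// discrete random-effect contexts, analytic score via the Fisher identity.
// The working-parameter packing order must match hmm_pack()/hmm_unpack() on
// the R side: emissions (9N), transition intercepts (K blocks of row-major
// off-diagonals), covariate coefficients, initial-distribution logits,
// mixing logits.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

namespace {

struct Params {
  arma::mat gs, gr;        // 3 x N gamma shape / rate
  arma::vec lambda, mu, kappa;
  arma::cube eta0;         // N x N x K (row i = origin state)
  arma::field<arma::cube> beta; // Kb cubes of P x N x N
  arma::mat delta;         // K x N
  arma::vec pik;           // K
  int N, K, P, Kb;
};

Params unpack(const arma::vec& w, int N, int K, int P, bool per_context) {
  Params pa;
  pa.N = N; pa.K = K; pa.P = P; pa.Kb = (P > 0 && per_context) ? K : (P > 0 ? 1 : 0);
  pa.gs.set_size(3, N); pa.gr.set_size(3, N);
  pa.lambda.set_size(N); pa.mu.set_size(N); pa.kappa.set_size(N);
  int pos = 0;
  auto take = [&](int n) { arma::vec v = w.subvec(pos, pos + n - 1); pos += n; return v; };
  pa.gs.row(0) = arma::exp(take(N)).t(); pa.gr.row(0) = arma::exp(take(N)).t();
  pa.gs.row(1) = arma::exp(take(N)).t(); pa.gr.row(1) = arma::exp(take(N)).t();
  pa.lambda = arma::exp(take(N));
  pa.gs.row(2) = arma::exp(take(N)).t(); pa.gr.row(2) = arma::exp(take(N)).t();
  pa.mu = take(N); pa.kappa = arma::exp(take(N));
  pa.eta0.zeros(N, N, K);
  for (int k = 0; k < K; ++k)
    for (int i = 0; i < N; ++i)
      for (int j = 0; j < N; ++j)
        if (j != i) pa.eta0(i, j, k) = w(pos++);
  if (pa.Kb > 0) {
    pa.beta.set_size(pa.Kb);
    for (int k = 0; k < pa.Kb; ++k) {
      pa.beta(k).zeros(P, N, N);
      for (int p = 0; p < P; ++p)
        for (int i = 0; i < N; ++i)
          for (int j = 0; j < N; ++j)
            if (j != i) pa.beta(k)(p, i, j) = w(pos++);
    }
  }
  pa.delta.set_size(K, N);
  for (int k = 0; k < K; ++k) {
    arma::rowvec lg(N, arma::fill::zeros);
    for (int j = 1; j < N; ++j) lg(j) = w(pos++);
    arma::rowvec e = arma::exp(lg - lg.max());
    pa.delta.row(k) = e / arma::accu(e);
  }
  pa.pik.set_size(K);
  if (K > 1) {
    arma::vec lg(K, arma::fill::zeros);
    for (int k = 1; k < K; ++k) lg(k) = w(pos++);
    arma::vec e = arma::exp(lg - lg.max());
    pa.pik = e / arma::accu(e);
  } else pa.pik(0) = 1.0;
  return pa;
}

// transition matrix for context k at covariate row x (length P, may be empty)
arma::mat tpm_at(const Params& pa, int k, const arma::rowvec& x) {
  arma::mat G(pa.N, pa.N);
  int kb = (pa.Kb == pa.K) ? k : 0;
  for (int i = 0; i < pa.N; ++i) {
    arma::rowvec lg(pa.N, arma::fill::zeros);
    for (int j = 0; j < pa.N; ++j) {
      if (j == i) continue;
      double v = pa.eta0(i, j, k);
      for (int p = 0; p < pa.P; ++p) v += pa.beta(kb)(p, i, j) * x(p);
      lg(j) = v;
    }
    lg -= lg.max();
    arma::rowvec e = arma::exp(lg);
    G.row(i) = e / arma::accu(e);
  }
  return G;
}

} // namespace

// [[Rcpp::export]]
List hmm_core_cpp(const arma::vec& w, int N, int K, int P, bool per_context,
                  const arma::mat& y, const arma::ivec& wid,
                  const arma::mat& X, bool want_grad, bool want_post) {
  const int T = y.n_rows;
  Params pa = unpack(w, N, K, P, per_context);

  // observation transforms (stream order: time, depth, lunges, speed, angle)
  arma::vec ly1 = arma::log(y.col(0)), ly2 = arma::log(y.col(1)),
            ly4 = arma::log(y.col(3));
  arma::vec lf(T), cx = arma::cos(y.col(4)), sx = arma::sin(y.col(4));
  for (int t = 0; t < T; ++t) lf(t) = R::lgammafn(y(t, 2) + 1.0);

  // per-state emission log densities, T x N
  arma::mat lp(T, N);
  arma::vec lI0(N), A1(N);
  for (int n = 0; n < N; ++n) {
    double a1 = pa.gs(0, n), b1 = pa.gr(0, n), a2 = pa.gs(1, n), b2 = pa.gr(1, n),
           a3 = pa.gs(2, n), b3 = pa.gr(2, n), lam = pa.lambda(n),
           mu = pa.mu(n), kap = pa.kappa(n);
    double c1 = a1 * std::log(b1) - R::lgammafn(a1),
           c2 = a2 * std::log(b2) - R::lgammafn(a2),
           c3 = a3 * std::log(b3) - R::lgammafn(a3);
    double i0s = R::bessel_i(kap, 0.0, 2.0); // exp(-kap) * I0(kap)
    lI0(n) = std::log(i0s) + kap;
    A1(n) = R::bessel_i(kap, 1.0, 2.0) / i0s;
    double llam = std::log(lam), cmu = std::cos(mu), smu = std::sin(mu);
    lp.col(n) = c1 + (a1 - 1.0) * ly1 - b1 * y.col(0)
              + c2 + (a2 - 1.0) * ly2 - b2 * y.col(1)
              + y.col(2) * llam - lam - lf
              + c3 + (a3 - 1.0) * ly4 - b3 * y.col(3)
              + kap * (cmu * cx + smu * sx) - std::log(2.0 * M_PI) - lI0(n);
  }
  arma::vec mrow = arma::max(lp, 1);          // per-dive scaling
  arma::mat b = arma::exp(lp.each_col() - mrow);

  // whale segments (wid assumed contiguous, 1-based)
  const int W = wid.max();
  std::vector<int> seg0(W, -1), seg1(W, -1);
  for (int t = 0; t < T; ++t) {
    int wI = wid(t) - 1;
    if (seg0[wI] < 0) seg0[wI] = t;
    seg1[wI] = t;
  }

  arma::rowvec zx(std::max(P, 1), arma::fill::zeros);
  std::vector<arma::mat> G0(K);
  for (int k = 0; k < K; ++k) G0[k] = (N > 1) ? tpm_at(pa, k, zx) : arma::mat(1, 1, arma::fill::ones);

  arma::mat llmat(W, K);          // per-whale per-context loglik
  // stored normalized forward variables per whale/context (reused in backward)
  arma::field<arma::mat> phi(W, K);
  arma::field<arma::vec> cvec(W, K);

  for (int wI = 0; wI < W; ++wI) {
    int t0 = seg0[wI], t1 = seg1[wI], Tw = t1 - t0 + 1;
    for (int k = 0; k < K; ++k) {
      arma::mat ph(Tw, N);
      arma::vec cc(Tw);
      arma::rowvec al = pa.delta.row(k) % b.row(t0);
      double c = arma::accu(al);
      ph.row(0) = al / c; cc(0) = c;
      double ll = std::log(c) + mrow(t0);
      for (int t = 1; t < Tw; ++t) {
        int tt = t0 + t;
        bool zero = true;
        for (int p = 0; p < P; ++p) if (X(tt, p) != 0.0) { zero = false; break; }
        const arma::mat G = (N == 1) ? G0[k] : (zero ? G0[k] : tpm_at(pa, k, X.row(tt)));
        al = (ph.row(t - 1) * G) % b.row(tt);
        c = arma::accu(al);
        ph.row(t) = al / c; cc(t) = c;
        ll += std::log(c) + mrow(tt);
      }
      llmat(wI, k) = ll;
      if (want_grad || want_post) { phi(wI, k) = ph; cvec(wI, k) = cc; }
    }
  }

  // mixture loglik and context weights
  arma::vec lpi = arma::log(pa.pik);
  double total = 0.0;
  arma::mat Wctx(W, K);
  for (int wI = 0; wI < W; ++wI) {
    arma::rowvec lw = llmat.row(wI) + lpi.t();
    double m = lw.max();
    double L = m + std::log(arma::accu(arma::exp(lw - m)));
    total += L;
    Wctx.row(wI) = arma::exp(lw - L);
  }

  List out = List::create(_["loglik"] = total, _["llmat"] = llmat,
                          _["context_post"] = Wctx);
  if (!(want_grad || want_post)) return out;

  arma::mat post(T, N, arma::fill::zeros);   // mixture-weighted smoothed probs
  arma::cube geta(N, N, K, arma::fill::zeros);
  arma::field<arma::cube> gbeta;
  if (pa.Kb > 0) {
    gbeta.set_size(pa.Kb);
    for (int k = 0; k < pa.Kb; ++k) gbeta(k).zeros(P, N, N);
  }
  arma::mat gdelta(K, N, arma::fill::zeros); // d ll / d delta logits (full, ref col 0)
  arma::vec gpi(K, arma::fill::zeros);

  for (int wI = 0; wI < W; ++wI) {
    int t0 = seg0[wI], Tw = seg1[wI] - t0 + 1;
    for (int k = 0; k < K; ++k) {
      double wk = Wctx(wI, k);
      gpi(k) += wk - pa.pik(k);
      if (wk < 1e-14 && !want_post) continue;
      const arma::mat& ph = phi(wI, k);
      const arma::vec& cc = cvec(wI, k);
      int kb = (pa.Kb == pa.K) ? k : 0;
      arma::rowvec bv(N, arma::fill::ones);   // scaled backward variable at t
      // gamma_t computed from t = Tw-1 down to 0
      arma::mat gam(Tw, N);
      gam.row(Tw - 1) = ph.row(Tw - 1);
      for (int t = Tw - 1; t >= 1; --t) {
        int tt = t0 + t;
        bool zero = true;
        for (int p = 0; p < P; ++p) if (X(tt, p) != 0.0) { zero = false; break; }
        const arma::mat G = (N == 1) ? G0[k] : (zero ? G0[k] : tpm_at(pa, k, X.row(tt)));
        arma::rowvec bb = b.row(tt) % bv;     // b_t(j) * beta_t(j)
        // xi_t(i,j) = phi_{t-1}(i) G(i,j) bb(j) / c_t
        if (want_grad && N > 1) {
          arma::mat xi = (ph.row(t - 1).t() * bb) % G / cc(t);
          arma::vec rs = arma::sum(xi, 1);    // = gamma_{t-1}(i)
          arma::mat dG = xi - (G.each_col() % rs);
          geta.slice(k) += wk * dG;
          if (pa.Kb > 0) {
            for (int p = 0; p < P; ++p) {
              double xv = X(tt, p);
              if (xv != 0.0)
                for (int i = 0; i < N; ++i)
                  for (int j = 0; j < N; ++j)
                    if (j != i) gbeta(kb)(p, i, j) += wk * dG(i, j) * xv;
            }
          }
          gam.row(t - 1) = rs.t();
        } else {
          // still need gamma for posteriors
          arma::mat xi = (ph.row(t - 1).t() * bb) % G / cc(t);
          gam.row(t - 1) = arma::sum(xi, 1).t();
        }
        bv = (G * bb.t()).t() / cc(t);
      }
      if (want_grad) {
        // initial distribution: d ll / d logit_j = gamma_1(j) - delta_j
        gdelta.row(k) += wk * (gam.row(0) - pa.delta.row(k));
      }
      for (int t = 0; t < Tw; ++t) post.row(t0 + t) += wk * gam.row(t);
    }
  }

  if (want_post) out["state_post"] = post;
  if (!want_grad) return out;

  // emission gradients on the working scale
  arma::vec g(w.n_elem, arma::fill::zeros);
  int pos = 0;
  arma::vec pn = arma::sum(post, 0).t();     // total posterior mass per state
  // stream helper sums
  arma::mat s_ly1 = post.t() * ly1, s_y1 = post.t() * y.col(0),
            s_ly2 = post.t() * ly2, s_y2 = post.t() * y.col(1),
            s_y3 = post.t() * y.col(2),
            s_ly4 = post.t() * ly4, s_y4 = post.t() * y.col(3),
            s_cx = post.t() * cx, s_sx = post.t() * sx;
  auto gam_grad = [&](int row) {
    for (int n = 0; n < N; ++n) {
      double a = pa.gs(row, n), bb = pa.gr(row, n);
      g(pos + n) = a * ((std::log(bb) - R::digamma(a)) * pn(n) +
                        (row == 0 ? s_ly1(n) : (row == 1 ? s_ly2(n) : s_ly4(n))));
      g(pos + N + n) = a * pn(n) - bb * (row == 0 ? s_y1(n) : (row == 1 ? s_y2(n) : s_y4(n)));
    }
    pos += 2 * N;
  };
  gam_grad(0);
  gam_grad(1);
  for (int n = 0; n < N; ++n) g(pos + n) = s_y3(n) - pa.lambda(n) * pn(n);
  pos += N;
  gam_grad(2);
  for (int n = 0; n < N; ++n) {
    double kap = pa.kappa(n), cmu = std::cos(pa.mu(n)), smu = std::sin(pa.mu(n));
    g(pos + n) = kap * (cmu * s_sx(n) - smu * s_cx(n));          // d/d mu
    g(pos + N + n) = kap * (cmu * s_cx(n) + smu * s_sx(n) - A1(n) * pn(n)); // d/d log kappa
  }
  pos += 2 * N;
  for (int k = 0; k < K; ++k)
    for (int i = 0; i < N; ++i)
      for (int j = 0; j < N; ++j)
        if (j != i) g(pos++) = geta(i, j, k);
  if (pa.Kb > 0)
    for (int k = 0; k < pa.Kb; ++k)
      for (int p = 0; p < P; ++p)
        for (int i = 0; i < N; ++i)
          for (int j = 0; j < N; ++j)
            if (j != i) g(pos++) = gbeta(k)(p, i, j);
  for (int k = 0; k < K; ++k)
    for (int j = 1; j < N; ++j) g(pos++) = gdelta(k, j);
  if (K > 1) for (int k = 1; k < K; ++k) g(pos++) = gpi(k);

  out["grad"] = g;
  return out;
}
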