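// Core message-passing kernels for clone-structured cognitive graphs.
//
// Conventions (internal to the compiled layer):
//  - observations, actions and states are 0-based here; the R layer is 1-based.
//  - the transition tensor is an (H x Na x H) array with element (i,k,j) =
//    P(z' = j, a = k | z = i); clones of symbol s occupy the contiguous state
//    range [offsets[s], offsets[s] + clones[s]).
//  - forward/backward messages are rescaled at every step; log-likelihoods are
//    accumulated from the scales so 50,000-step sequences do not underflow.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

namespace {

struct Alloc {
  arma::ivec clones;   // clones per symbol
  arma::ivec offsets;  // 0-based start of each symbol's block
  int H;
};

Alloc make_alloc(const IntegerVector& clones) {
  Alloc a;
  const int E = clones.size();
  a.clones = arma::ivec(E);
  a.offsets = arma::ivec(E);
  int off = 0;
  for (int s = 0; s < E; ++s) {
    a.clones[s] = clones[s];
    a.offsets[s] = off;
    off += clones[s];
  }
  a.H = off;
  return a;
}

inline arma::cube as_cube(NumericVector trans, int H, int Na) {
  return arma::cube(trans.begin(), H, Na, H, false, true);
}

}  // namespace

// Forward pass restricted to clone blocks; returns loglik, scales and
// (optionally) the per-step scaled forward messages, concatenated.
// [[Rcpp::export]]
List cscg_forward_cpp(NumericVector trans, NumericVector prior,
                      IntegerVector clones, IntegerVector obs,
                      IntegerVector act, int n_actions,
                      bool keep_messages) {
  Alloc al = make_alloc(clones);
  arma::cube T = as_cube(trans, al.H, n_actions);
  const int N = obs.size();

  std::vector<arma::vec> alphas;
  if (keep_messages) alphas.reserve(N);
  arma::vec scales(N);
  double loglik = 0.0;
  bool impossible = false;

  int s0 = obs[0];
  arma::vec alpha(al.clones[s0]);
  for (int i = 0; i < al.clones[s0]; ++i) alpha[i] = prior[al.offsets[s0] + i];
  double sc = arma::accu(alpha);
  scales[0] = sc;
  if (sc <= 0.0) { impossible = true; } else { alpha /= sc; loglik += std::log(sc); }
  if (keep_messages) alphas.push_back(alpha);

  double block_ops = 0.0;
  for (int n = 0; n + 1 < N && !impossible; ++n) {
    const int si = obs[n], sj = obs[n + 1], a = act[n];
    const int oi = al.offsets[si], oj = al.offsets[sj];
    const int Mi = al.clones[si], Mj = al.clones[sj];
    arma::vec next(Mj, arma::fill::zeros);
    for (int j = 0; j < Mj; ++j) {
      double acc = 0.0;
      for (int i = 0; i < Mi; ++i) acc += alpha[i] * T(oi + i, a, oj + j);
      next[j] = acc;
    }
    block_ops += (double)Mi * Mj;
    sc = arma::accu(next);
    scales[n + 1] = sc;
    if (sc <= 0.0) { impossible = true; break; }
    next /= sc;
    loglik += std::log(sc);
    alpha = next;
    if (keep_messages) alphas.push_back(alpha);
  }

  if (impossible) loglik = R_NegInf;

  List out = List::create(_["loglik"] = loglik,
                          _["scales"] = NumericVector(scales.begin(), scales.end()),
                          _["impossible"] = impossible,
                          _["block_ops"] = block_ops);
  if (keep_messages) {
    List msg(alphas.size());
    for (size_t n = 0; n < alphas.size(); ++n)
      msg[n] = NumericVector(alphas[n].begin(), alphas[n].end());
    out["alphas"] = msg;
  }
  return out;
}

// Full E-step: forward-backward with expected transition counts accumulated
// into an (H x Na x H) array, plus gamma(1) for the prior update.
// Hot path: raw pointer arithmetic on the (H, Na, H) tensor; element (i,k,j)
// lives at i + k*H + j*H*Na, so inner loops over i are stride-1.
// [[Rcpp::export]]
List cscg_estep_cpp(NumericVector trans, NumericVector prior,
                    IntegerVector clones, IntegerVector obs,
                    IntegerVector act, int n_actions,
                    bool keep_gammas) {
  Alloc al = make_alloc(clones);
  const double* Tp = trans.begin();
  const int H = al.H, Na = n_actions;
  const R_xlen_t colStride = (R_xlen_t)H * Na;  // stride between j slices
  const int N = obs.size();
  int maxM = 0;
  for (arma::uword s = 0; s < al.clones.n_elem; ++s)
    if (al.clones[s] > maxM) maxM = al.clones[s];

  // forward messages stored in one flat buffer (N x maxM)
  std::vector<double> alphaBuf((size_t)N * maxM);
  double loglik = 0.0;
  double block_ops = 0.0;

  {
    const int s0 = obs[0], M0 = al.clones[s0], o0 = al.offsets[s0];
    double* a0 = alphaBuf.data();
    double sc = 0.0;
    for (int i = 0; i < M0; ++i) { a0[i] = prior[o0 + i]; sc += a0[i]; }
    if (sc <= 0.0) return List::create(_["loglik"] = R_NegInf,
                                       _["impossible"] = true);
    const double inv = 1.0 / sc;
    for (int i = 0; i < M0; ++i) a0[i] *= inv;
    loglik += std::log(sc);
  }
  for (int n = 0; n + 1 < N; ++n) {
    const int si = obs[n], sj = obs[n + 1], a = act[n];
    const int oi = al.offsets[si], oj = al.offsets[sj];
    const int Mi = al.clones[si], Mj = al.clones[sj];
    const double* alpha = alphaBuf.data() + (size_t)n * maxM;
    double* next = alphaBuf.data() + (size_t)(n + 1) * maxM;
    const double* base = Tp + (R_xlen_t)a * H + (R_xlen_t)oj * colStride + oi;
    double sc = 0.0;
    for (int j = 0; j < Mj; ++j) {
      const double* col = base + (R_xlen_t)j * colStride;
      double acc = 0.0;
      for (int i = 0; i < Mi; ++i) acc += alpha[i] * col[i];
      next[j] = acc;
      sc += acc;
    }
    block_ops += (double)Mi * Mj;
    if (sc <= 0.0) return List::create(_["loglik"] = R_NegInf,
                                       _["impossible"] = true);
    const double inv = 1.0 / sc;
    for (int j = 0; j < Mj; ++j) next[j] *= inv;
    loglik += std::log(sc);
  }

  // --- backward with count accumulation ---
  NumericVector cnt((R_xlen_t)H * Na * H);
  double* Cp = cnt.begin();
  NumericVector gamma1(H);
  List gammas(keep_gammas ? N : 0);

  std::vector<double> beta(maxM, 1.0), nb(maxM), xi((size_t)maxM * maxM);
  {
    const int ML = al.clones[obs[N - 1]];
    std::fill(beta.begin(), beta.begin() + ML, 1.0);
    if (keep_gammas) {
      const double* aL = alphaBuf.data() + (size_t)(N - 1) * maxM;
      NumericVector g(ML);
      double z = 0.0;
      for (int i = 0; i < ML; ++i) { g[i] = aL[i]; z += g[i]; }
      for (int i = 0; i < ML; ++i) g[i] /= z;
      gammas[N - 1] = g;
    }
  }
  for (int n = N - 2; n >= 0; --n) {
    const int si = obs[n], sj = obs[n + 1], a = act[n];
    const int oi = al.offsets[si], oj = al.offsets[sj];
    const int Mi = al.clones[si], Mj = al.clones[sj];
    const double* alpha = alphaBuf.data() + (size_t)n * maxM;
    const double* base = Tp + (R_xlen_t)a * H + (R_xlen_t)oj * colStride + oi;

    // single pass: xi_ij = alpha_i * T(i,a,j) * beta_j (unnormalized),
    // nb_i = sum_j T(i,a,j) * beta_j (new backward message)
    std::fill(nb.begin(), nb.begin() + Mi, 0.0);
    double z = 0.0;
    for (int j = 0; j < Mj; ++j) {
      const double* col = base + (R_xlen_t)j * colStride;
      const double bj = beta[j];
      double* xcol = xi.data() + (size_t)j * Mi;
      for (int i = 0; i < Mi; ++i) {
        const double tb = col[i] * bj;
        nb[i] += tb;
        const double v = alpha[i] * tb;
        xcol[i] = v;
        z += v;
      }
    }
    block_ops += 2.0 * (double)Mi * Mj;
    if (z <= 0.0) return List::create(_["loglik"] = R_NegInf,
                                      _["impossible"] = true);
    const double invz = 1.0 / z;
    double* Cbase = Cp + (R_xlen_t)a * H + (R_xlen_t)oj * colStride + oi;
    for (int j = 0; j < Mj; ++j) {
      double* ccol = Cbase + (R_xlen_t)j * colStride;
      const double* xcol = xi.data() + (size_t)j * Mi;
      for (int i = 0; i < Mi; ++i) ccol[i] += xcol[i] * invz;
    }
    double bs = 0.0;
    for (int i = 0; i < Mi; ++i) bs += nb[i];
    if (bs <= 0.0) return List::create(_["loglik"] = R_NegInf,
                                       _["impossible"] = true);
    const double invb = 1.0 / bs;
    for (int i = 0; i < Mi; ++i) beta[i] = nb[i] * invb;

    if (n == 0 || keep_gammas) {
      NumericVector g(Mi);
      double gz = 0.0;
      for (int i = 0; i < Mi; ++i) { g[i] = alpha[i] * beta[i]; gz += g[i]; }
      for (int i = 0; i < Mi; ++i) g[i] /= gz;
      if (n == 0) for (int i = 0; i < Mi; ++i) gamma1[oi + i] = g[i];
      if (keep_gammas) gammas[n] = g;
    }
  }
  if (N == 1) {
    const int s0 = obs[0], M0 = al.clones[s0], o0 = al.offsets[s0];
    const double* a0 = alphaBuf.data();
    for (int i = 0; i < M0; ++i) gamma1[o0 + i] = a0[i];
    if (keep_gammas) {
      NumericVector g(M0);
      for (int i = 0; i < M0; ++i) g[i] = a0[i];
      gammas[0] = g;
    }
  }

  cnt.attr("dim") = IntegerVector::create(H, Na, H);
  List out = List::create(_["loglik"] = loglik, _["impossible"] = false,
                          _["counts"] = cnt, _["gamma1"] = gamma1,
                          _["block_ops"] = block_ops);
  if (keep_gammas) out["gammas"] = gammas;
  return out;
}

// MAP clone path (Viterbi) under hard evidence; ties broken toward the lowest
// state index. Returns 0-based global state ids.
// [[Rcpp::export]]
List cscg_viterbi_cpp(NumericVector trans, NumericVector prior,
                      IntegerVector clones, IntegerVector obs,
                      IntegerVector act, int n_actions) {
  Alloc al = make_alloc(clones);
  arma::cube T = as_cube(trans, al.H, n_actions);
  const int N = obs.size();

  std::vector<arma::vec> delta(N);
  std::vector<arma::ivec> argmx(N);

  {
    int s0 = obs[0];
    arma::vec d(al.clones[s0]);
    for (int i = 0; i < al.clones[s0]; ++i)
      d[i] = std::log(prior[al.offsets[s0] + i]);
    delta[0] = d;
  }
  for (int n = 0; n + 1 < N; ++n) {
    const int si = obs[n], sj = obs[n + 1], a = act[n];
    const int oi = al.offsets[si], oj = al.offsets[sj];
    const int Mi = al.clones[si], Mj = al.clones[sj];
    arma::vec d(Mj);
    arma::ivec am(Mj);
    const arma::vec& dp = delta[n];
    for (int j = 0; j < Mj; ++j) {
      double best = R_NegInf;
      int bi = 0;
      for (int i = 0; i < Mi; ++i) {
        double v = dp[i] + std::log(T(oi + i, a, oj + j));
        if (v > best) { best = v; bi = i; }
      }
      d[j] = best;
      am[j] = bi;
    }
    delta[n + 1] = d;
    argmx[n + 1] = am;
  }

  // terminal argmax, lowest index on ties
  const arma::vec& dl = delta[N - 1];
  double best = R_NegInf;
  int bj = 0;
  for (arma::uword j = 0; j < dl.n_elem; ++j)
    if (dl[j] > best) { best = dl[j]; bj = (int)j; }
  if (!std::isfinite(best)) {
    return List::create(_["path"] = IntegerVector(0), _["logprob"] = R_NegInf);
  }
  IntegerVector path(N);
  int cur = bj;
  path[N - 1] = al.offsets[obs[N - 1]] + cur;
  for (int n = N - 1; n >= 1; --n) {
    cur = argmx[n][cur];
    path[n - 1] = al.offsets[obs[n - 1]] + cur;
  }
  return List::create(_["path"] = path, _["logprob"] = best);
}

// Predictive distribution over observation symbols at every step, i.e. column
// n holds P(x_n | x_{1:n-1}, a_{1:n-1}); column 1 is the clone-marginalized
// prior. Used for next-symbol prediction accuracy and reward prediction.
// [[Rcpp::export]]
List cscg_predict_cpp(NumericVector trans, NumericVector prior,
                      IntegerVector clones, IntegerVector obs,
                      IntegerVector act, int n_actions) {
  Alloc al = make_alloc(clones);
  arma::cube T = as_cube(trans, al.H, n_actions);
  const int N = obs.size();
  const int E = clones.size();

  arma::mat pred(E, N, arma::fill::zeros);
  for (int s = 0; s < E; ++s)
    for (int i = 0; i < al.clones[s]; ++i)
      pred(s, 0) += prior[al.offsets[s] + i];

  int s0 = obs[0];
  arma::vec alpha(al.clones[s0]);
  for (int i = 0; i < al.clones[s0]; ++i) alpha[i] = prior[al.offsets[s0] + i];
  double sc = arma::accu(alpha);
  double loglik = sc > 0 ? std::log(sc) : R_NegInf;
  if (sc > 0) alpha /= sc;

  for (int n = 0; n + 1 < N; ++n) {
    const int si = obs[n], a = act[n];
    const int oi = al.offsets[si];
    const int Mi = al.clones[si];
    // full predictive state vector, then collapse per symbol
    arma::vec full(al.H, arma::fill::zeros);
    for (int j = 0; j < al.H; ++j) {
      double acc = 0.0;
      for (int i = 0; i < Mi; ++i) acc += alpha[i] * T(oi + i, a, j);
      full[j] = acc;
    }
    double tot = arma::accu(full);
    if (tot <= 0.0) { loglik = R_NegInf; break; }
    for (int s = 0; s < E; ++s) {
      double acc = 0.0;
      for (int i = 0; i < al.clones[s]; ++i) acc += full[al.offsets[s] + i];
      pred(s, n + 1) = acc / tot;
    }
    const int sj = obs[n + 1];
    const int oj = al.offsets[sj], Mj = al.clones[sj];
    arma::vec next(Mj);
    for (int j = 0; j < Mj; ++j) next[j] = full[oj + j];
    double z = arma::accu(next);
    if (z <= 0.0) { loglik = R_NegInf; break; }
    loglik += std::log(z / tot);
    alpha = next / z;
  }
  return List::create(_["pred"] = wrap(pred), _["loglik"] = loglik);
}

// E-step for the dense-emission variant (schema transfer): transitions fixed,
// expected observation counts per state accumulated for the emission M-step.
// [[Rcpp::export]]
List dense_estep_cpp(NumericVector trans, NumericVector prior,
                     NumericMatrix emission, IntegerVector obs,
                     IntegerVector act, int n_actions) {
  const int H = emission.nrow(), E = emission.ncol();
  arma::cube T = as_cube(trans, H, n_actions);
  arma::mat em(emission.begin(), H, E, false, true);
  arma::vec pi(prior.begin(), H, false, true);
  const int N = obs.size();

  std::vector<arma::mat> Ta(n_actions);
  for (int a = 0; a < n_actions; ++a) {
    arma::mat M(H, H);
    for (int j = 0; j < H; ++j)
      for (int i = 0; i < H; ++i) M(i, j) = T(i, a, j);
    Ta[a] = M;
  }

  arma::mat alphas(H, N);
  double loglik = 0.0;
  arma::vec alpha = pi % em.col(obs[0]);
  double sc = arma::accu(alpha);
  if (sc <= 0.0) return List::create(_["loglik"] = R_NegInf, _["impossible"] = true);
  alpha /= sc;
  loglik += std::log(sc);
  alphas.col(0) = alpha;
  for (int n = 0; n + 1 < N; ++n) {
    arma::vec next = Ta[act[n]].t() * alpha;
    next %= em.col(obs[n + 1]);
    sc = arma::accu(next);
    if (sc <= 0.0) return List::create(_["loglik"] = R_NegInf, _["impossible"] = true);
    next /= sc;
    loglik += std::log(sc);
    alphas.col(n + 1) = next;
    alpha = next;
  }

  arma::mat obs_counts(H, E, arma::fill::zeros);
  arma::vec beta(H, arma::fill::ones);
  {
    arma::vec g = alphas.col(N - 1);
    obs_counts.col(obs[N - 1]) += g;
  }
  for (int n = N - 2; n >= 0; --n) {
    arma::vec tmp = em.col(obs[n + 1]) % beta;
    beta = Ta[act[n]] * tmp;
    double bs = arma::accu(beta);
    if (bs <= 0.0) return List::create(_["loglik"] = R_NegInf, _["impossible"] = true);
    beta /= bs;
    arma::vec g = alphas.col(n) % beta;
    g /= arma::accu(g);
    obs_counts.col(obs[n]) += g;
  }
  return List::create(_["loglik"] = loglik, _["impossible"] = false,
                      _["obs_counts"] = wrap(obs_counts));
}

// Predictive observation distribution for the dense-emission variant.
// [[Rcpp::export]]
List dense_predict_cpp(NumericVector trans, NumericVector prior,
                       NumericMatrix emission, IntegerVector obs,
                       IntegerVector act, int n_actions) {
  const int H = emission.nrow(), E = emission.ncol();
  arma::cube T = as_cube(trans, H, n_actions);
  arma::mat em(emission.begin(), H, E, false, true);
  arma::vec pi(prior.begin(), H, false, true);
  const int N = obs.size();

  std::vector<arma::mat> Ta(n_actions);
  for (int a = 0; a < n_actions; ++a) {
    arma::mat M(H, H);
    for (int j = 0; j < H; ++j)
      for (int i = 0; i < H; ++i) M(i, j) = T(i, a, j);
    Ta[a] = M;
  }

  arma::mat pred(E, N);
  pred.col(0) = em.t() * pi;
  arma::vec alpha = pi % em.col(obs[0]);
  double sc = arma::accu(alpha);
  double loglik = sc > 0 ? std::log(sc) : R_NegInf;
  if (sc > 0) alpha /= sc;
  for (int n = 0; n + 1 < N; ++n) {
    arma::vec ap = Ta[act[n]].t() * alpha;
    double tot = arma::accu(ap);
    if (tot <= 0.0) { loglik = R_NegInf; break; }
    pred.col(n + 1) = em.t() * (ap / tot);
    arma::vec next = ap % em.col(obs[n + 1]);
    double z = arma::accu(next);
    if (z <= 0.0) { loglik = R_NegInf; break; }
    loglik += std::log(z / tot);
    alpha = next / z;
  }
  return List::create(_["pred"] = wrap(pred), _["loglik"] = loglik);
}
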