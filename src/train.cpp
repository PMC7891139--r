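// Fast training loops for the two model stages. These mirror the pure-R
// reference implementations in R/stage1.R and R/stage2.R (kept for
// verification); the arithmetic is identical up to an algebraically
// equivalent form of the Mish activation. All randomness is drawn from R's
// RNG so seeded runs are reproducible.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

// The training engine runs in single precision: GEMM and the elementwise
// activation kernels are ~2x faster, and optimiser noise dwarfs float32
// rounding. Interfaces stay double; conversion happens at the boundary.
typedef arma::fmat FMat;
typedef arma::fvec FVec;
typedef float Real;

// activation codes: 0 = linear, 1 = mish, 2 = relu

// Mish value and derivatives from a single exponential:
// with E = e^x, q = (1+E)^2, tanh(softplus(x)) = (q-1)/(q+1), sigma = E/(1+E).
static void mish_all(const FMat& x, FMat* h, FMat* d1, FMat* d2) {
  const uword n = x.n_elem;
  if (h) h->set_size(x.n_rows, x.n_cols);
  if (d1) d1->set_size(x.n_rows, x.n_cols);
  if (d2) d2->set_size(x.n_rows, x.n_cols);
  for (uword i = 0; i < n; ++i) {
    Real xi = x[i];
    Real E = std::exp(std::min(xi, 30.0f));
    Real q = (1.0f + E) * (1.0f + E);
    Real t = (q - 1.0f) / (q + 1.0f);
    Real s = E / (1.0f + E);
    Real u = 1.0f - t * t;
    if (h) (*h)[i] = xi * t;
    if (d1) (*d1)[i] = t + xi * u * s;
    if (d2) (*d2)[i] = 2.0f * u * s + xi * (u * s * (1.0f - s) - 2.0f * t * u * s * s);
  }
}

struct Net {
  std::vector<FMat> W;
  std::vector<FVec> b;
  std::vector<int> acts;
};

static Net net_from_R(const Rcpp::List& net) {
  Net out;
  Rcpp::List Ws = net["W"], bs = net["b"];
  Rcpp::CharacterVector acts = net["acts"];
  for (int i = 0; i < Ws.size(); ++i) {
    out.W.push_back(conv_to<FMat>::from(Rcpp::as<arma::mat>(Ws[i])));
    out.b.push_back(conv_to<FVec>::from(Rcpp::as<arma::vec>(bs[i])));
    std::string a = Rcpp::as<std::string>(acts[i]);
    out.acts.push_back(a == "linear" ? 0 : (a == "mish" ? 1 : 2));
  }
  return out;
}

static Rcpp::List net_to_R(const Net& net, const Rcpp::List& proto) {
  Rcpp::List out = Rcpp::clone(proto);  // never mutate the caller's model
  Rcpp::List Ws(net.W.size()), bs(net.b.size());
  for (size_t i = 0; i < net.W.size(); ++i) {
    Ws[i] = Rcpp::wrap(conv_to<arma::mat>::from(net.W[i]));
    bs[i] = Rcpp::wrap(conv_to<arma::vec>::from(net.b[i]));
  }
  out["W"] = Ws;
  out["b"] = bs;
  return out;
}

struct Cache {
  std::vector<FMat> H;  // activations per layer
  std::vector<FMat> D;  // activation derivatives per layer (empty for linear)
  const FMat* X;
};

static FMat net_forward(const Net& net, const FMat& X, Cache* cache) {
  FMat h = X;
  if (cache) {
    cache->H.resize(net.W.size());
    cache->D.resize(net.W.size());
    cache->X = &X;
  }
  for (size_t i = 0; i < net.W.size(); ++i) {
    FMat z = h * net.W[i];
    z.each_row() += net.b[i].t();
    if (net.acts[i] == 1) {
      if (cache) {
        mish_all(z, &h, &cache->D[i], nullptr);
      } else {
        mish_all(z, &h, nullptr, nullptr);
      }
    } else if (net.acts[i] == 2) {
      if (cache) cache->D[i] = conv_to<FMat>::from(z > 0.0f);
      h = clamp(z, 0.0f, std::numeric_limits<Real>::infinity());
    } else {
      h = z;
      if (cache) cache->D[i].reset();
    }
    if (cache) cache->H[i] = h;
  }
  return h;
}

struct Grads {
  std::vector<FMat> gW;
  std::vector<FVec> gb;
  FMat dX;
};

static void net_backward(const Net& net, const Cache& cache, const FMat& d_out,
                         Grads* g, bool need_dx) {
  size_t L = net.W.size();
  g->gW.resize(L);
  g->gb.resize(L);
  FMat dH = d_out;
  for (size_t ii = L; ii-- > 0;) {
    FMat dZ = cache.D[ii].n_elem ? FMat(dH % cache.D[ii]) : dH;
    const FMat& h_prev = (ii > 0) ? cache.H[ii - 1] : *cache.X;
    g->gW[ii] = h_prev.t() * dZ;
    g->gb[ii] = sum(dZ, 0).t();
    if (ii > 0 || need_dx) dH = dZ * net.W[ii].t();
  }
  if (need_dx) g->dX = dH;
}

struct Adam {
  std::vector<FMat> mW, vW;
  std::vector<FVec> mb, vb;
  long t = 0;
};

static Adam adam_init(const Net& net) {
  Adam st;
  for (size_t i = 0; i < net.W.size(); ++i) {
    st.mW.push_back(zeros<FMat>(net.W[i].n_rows, net.W[i].n_cols));
    st.vW.push_back(zeros<FMat>(net.W[i].n_rows, net.W[i].n_cols));
    st.mb.push_back(zeros<FVec>(net.b[i].n_elem));
    st.vb.push_back(zeros<FVec>(net.b[i].n_elem));
  }
  return st;
}

static void adam_step(Net& net, const Grads& g, Adam& st, double lr,
                      double beta1, double beta2, double eps = 1e-8) {
  st.t += 1;
  Real c1 = (Real)(1.0 - std::pow(beta1, (double)st.t));
  Real c2 = (Real)(1.0 - std::pow(beta2, (double)st.t));
  for (size_t i = 0; i < net.W.size(); ++i) {
    st.mW[i] = (Real)beta1 * st.mW[i] + (Real)(1 - beta1) * g.gW[i];
    st.vW[i] = (Real)beta2 * st.vW[i] + (Real)(1 - beta2) * square(g.gW[i]);
    net.W[i] -= (Real)lr * (st.mW[i] / c1) / (sqrt(st.vW[i] / c2) + (Real)eps);
    st.mb[i] = (Real)beta1 * st.mb[i] + (Real)(1 - beta1) * g.gb[i];
    st.vb[i] = (Real)beta2 * st.vb[i] + (Real)(1 - beta2) * square(g.gb[i]);
    net.b[i] -= (Real)lr * (st.mb[i] / c1) / (sqrt(st.vb[i] / c2) + (Real)eps);
  }
}

static void grads_accum(Grads& a, const Grads& b) {
  for (size_t i = 0; i < a.gW.size(); ++i) {
    a.gW[i] += b.gW[i];
    a.gb[i] += b.gb[i];
  }
}

// uniform integer in [0, n): uses R's RNG
static uword runif_int(uword n) {
  double u;
  do { u = R::unif_rand(); } while (u >= 1.0);
  return (uword)(u * n);
}

static uvec sample_rows(uword n, uword size) {
  uvec idx(size);
  for (uword i = 0; i < size; ++i) idx[i] = runif_int(n);
  return idx;
}

// gradient of the critic output wrt its input, plus intermediates
// (critic layout: two smooth hidden layers + linear scalar output)
struct CriticIG {
  FMat G, a1, p1, p2, p1dd, p2dd;
  FVec w3;
};

static CriticIG critic_input_grad(const Net& D, const FMat& X, bool second) {
  CriticIG ig;
  FMat z1 = X * D.W[0];
  z1.each_row() += D.b[0].t();
  FMat z2;
  if (D.acts[0] == 1) {
    mish_all(z1, &ig.a1, &ig.p1, second ? &ig.p1dd : nullptr);
  } else {
    ig.a1 = z1;
    ig.p1 = ones<FMat>(z1.n_rows, z1.n_cols);
    if (second) ig.p1dd = zeros<FMat>(z1.n_rows, z1.n_cols);
  }
  z2 = ig.a1 * D.W[1];
  z2.each_row() += D.b[1].t();
  if (D.acts[1] == 1) {
    mish_all(z2, nullptr, &ig.p2, second ? &ig.p2dd : nullptr);
  } else {
    ig.p2 = ones<FMat>(z2.n_rows, z2.n_cols);
    if (second) ig.p2dd = zeros<FMat>(z2.n_rows, z2.n_cols);
  }
  ig.w3 = D.W[2].col(0);
  FMat Q = ig.p2.each_row() % ig.w3.t();
  FMat P = (Q * D.W[1].t()) % ig.p1;
  ig.G = P * D.W[0].t();
  return ig;
}

// parameter gradients of gp_weight * mean((||grad_x D|| - 1)^2) at Xhat
static double critic_gp_grads(const Net& D, const FMat& Xhat, double gp_weight,
                              Grads* out) {
  uword B = Xhat.n_rows;
  CriticIG ig = critic_input_grad(D, Xhat, true);
  FVec gn = sqrt(sum(square(ig.G), 1));
  double penalty = gp_weight * accu(square(gn - 1.0f)) / B;
  FVec coef = 2.0f * (gn - 1.0f) / clamp(gn, (Real)1e-12, std::numeric_limits<Real>::infinity()) * (Real)(gp_weight / B);
  FMat u = ig.G.each_col() % coef;
  FMat v1 = u * D.W[0];
  FMat s = v1 % ig.p1;
  FMat tt = s * D.W[1];
  FMat p2w3 = ig.p2.each_row() % ig.w3.t();
  out->gW.resize(3);
  out->gb.resize(3);
  out->gW[2] = sum(tt % ig.p2, 0).t();
  out->gb[2] = zeros<FVec>(1);
  FMat ttdd = tt % ig.p2dd;
  FMat dz2 = ttdd.each_row() % ig.w3.t();
  out->gW[1] = s.t() * p2w3 + ig.a1.t() * dz2;
  out->gb[1] = sum(dz2, 0).t();
  FMat da1 = dz2 * D.W[1].t();
  FMat ds = p2w3 * D.W[1].t();
  FMat dz1 = ds % v1 % ig.p1dd + da1 % ig.p1;
  out->gW[0] = u.t() * (ds % ig.p1) + Xhat.t() * dz1;
  out->gb[0] = sum(dz1, 0).t();
  return penalty;
}

// residual generator forward: relu(F(x) + x)
static FMat gen_forward(const Net& F, const FMat& X, Cache* cache, FMat* pre_out) {
  FMat pre = net_forward(F, X, cache) + X;
  if (pre_out) *pre_out = pre;
  return clamp(pre, 0.0f, std::numeric_limits<Real>::infinity());
}

// [[Rcpp::export]]
Rcpp::List cpp_train_stage2(Rcpp::List Fnet_r, Rcpp::List Dnet_r,
                            const arma::uvec& pairs_a,
                            const arma::uvec& pairs_b,
                            const arma::mat& Xsrc, const arma::mat& Xanc,
                            int epochs, int minibatch, int critic_steps,
                            double gp_weight, double lr_gen, double lr_critic,
                            double beta1, double beta2) {
  Net F = net_from_R(Fnet_r), D = net_from_R(Dnet_r);
  Adam stF = adam_init(F), stD = adam_init(D);
  FMat Xsrc_f = conv_to<FMat>::from(Xsrc), Xanc_f = conv_to<FMat>::from(Xanc);
  uword n_pairs = pairs_a.n_elem;
  uword B = std::min<uword>(minibatch, n_pairs);
  int steps_per_epoch = (int)std::ceil((double)n_pairs / minibatch);
  int n_steps = epochs * steps_per_epoch;
  vec log_gen(n_steps), log_critic(n_steps), log_gp(n_steps);
  int step = 0;
  for (int ep = 0; ep < epochs; ++ep) {
    for (int it = 0; it < steps_per_epoch; ++it) {
      double c_loss = 0, gp_val = 0;
      for (int csi = 0; csi < critic_steps; ++csi) {
        uvec mb = sample_rows(n_pairs, B);
        FMat x_src = Xsrc_f.rows(pairs_a.elem(mb));
        FMat x_real = Xanc_f.rows(pairs_b.elem(mb));
        FMat x_fake = gen_forward(F, x_src, nullptr, nullptr);
        // wasserstein gradients
        Cache cf, cr;
        FMat sf = net_forward(D, x_fake, &cf);
        FMat sr = net_forward(D, x_real, &cr);
        Grads gf, gr;
        net_backward(D, cf, FMat(x_fake.n_rows, 1, fill::value((Real)(1.0 / B))), &gf, false);
        net_backward(D, cr, FMat(x_real.n_rows, 1, fill::value((Real)(-1.0 / B))), &gr, false);
        FVec epsv(B);
        for (uword i = 0; i < B; ++i) epsv[i] = (Real)R::unif_rand();
        FMat xhat = (x_real.each_col() % epsv) + (x_fake.each_col() % (1.0f - epsv));
        Grads gp;
        double pen = critic_gp_grads(D, xhat, gp_weight, &gp);
        grads_accum(gf, gr);
        grads_accum(gf, gp);
        adam_step(D, gf, stD, lr_critic, beta1, beta2);
        c_loss = mean(sf.col(0)) - mean(sr.col(0)) + pen;
        gp_val = pen;
      }
      // generator update
      uvec mb = sample_rows(n_pairs, B);
      FMat x_src = Xsrc_f.rows(pairs_a.elem(mb));
      Cache cF;
      FMat pre;
      FMat fake = gen_forward(F, x_src, &cF, &pre);
      Cache cD;
      FMat sD = net_forward(D, fake, &cD);
      Grads gD;
      net_backward(D, cD, FMat(fake.n_rows, 1, fill::value((Real)(-1.0 / B))), &gD, true);
      FMat dPre = gD.dX % conv_to<FMat>::from(pre > 0.0f);
      Grads gF;
      net_backward(F, cF, dPre, &gF, false);
      adam_step(F, gF, stF, lr_gen, beta1, beta2);
      double g_loss = -mean(sD.col(0));
      if (!std::isfinite(g_loss) || !std::isfinite(c_loss))
        Rcpp::stop("non-finite stage-two loss at step %d", step + 1);
      log_gen[step] = g_loss;
      log_critic[step] = c_loss;
      log_gp[step] = gp_val;
      ++step;
    }
    Rcpp::checkUserInterrupt();
  }
  return Rcpp::List::create(
    Rcpp::Named("F") = net_to_R(F, Fnet_r),
    Rcpp::Named("D") = net_to_R(D, Dnet_r),
    Rcpp::Named("gen_loss") = log_gen,
    Rcpp::Named("critic_loss") = log_critic,
    Rcpp::Named("gp") = log_gp);
}

// one stage-one minibatch: forward, both losses, gradients, in-place Adam
// [[Rcpp::export]]
Rcpp::List cpp_train_stage1(Rcpp::List E_r, Rcpp::List G1_r, Rcpp::List G2_r,
                            const arma::mat& X, const arma::uvec& bidx,
                            int n_batches, double lambda_c, double lambda_r,
                            double lr, int epochs, int minibatch,
                            double beta1, double beta2) {
  Net E = net_from_R(E_r), G1 = net_from_R(G1_r), G2 = net_from_R(G2_r);
  Adam stE = adam_init(E), st1 = adam_init(G1), st2 = adam_init(G2);
  FMat Xf = conv_to<FMat>::from(X);
  uword n = X.n_rows;
  uword l = E.W.back().n_cols;
  vec rep_lr(epochs), rep_lc(epochs);
  for (int ep = 0; ep < epochs; ++ep) {
    // R-style shuffled epoch: permutation via R RNG (Fisher-Yates)
    uvec ord = regspace<uvec>(0, n - 1);
    for (uword i = n - 1; i > 0; --i) {
      uword j = runif_int(i + 1);
      std::swap(ord[i], ord[j]);
    }
    double lr_sum = 0, lc_sum = 0;
    for (uword start = 0; start < n; start += minibatch) {
      uword end = std::min<uword>(start + minibatch, n) - 1;
      uvec mb = ord.subvec(start, end);
      uword B = mb.n_elem;
      FMat Xb = Xf.rows(mb);
      FMat Bmat = zeros<FMat>(B, n_batches), Btil = zeros<FMat>(B, n_batches);
      for (uword i = 0; i < B; ++i) {
        Bmat(i, bidx[mb[i]] - 1) = 1.0f;
        Btil(i, runif_int(n_batches)) = 1.0f;
      }
      // forward
      Cache cE;
      FMat C = net_forward(E, Xb, &cE);
      Cache c1r, c2r;
      FMat in2r = join_rows(C, Bmat);
      FMat Sr = net_forward(G1, Bmat, &c1r) + net_forward(G2, in2r, &c2r);
      FMat R = clamp(Sr, 0.0f, std::numeric_limits<Real>::infinity());
      double L_r = accu(square(R - Xb)) / B;
      Cache c1t, c2t;
      FMat in2t = join_rows(C, Btil);
      FMat St = net_forward(G1, Btil, &c1t) + net_forward(G2, in2t, &c2t);
      FMat Rt = clamp(St, 0.0f, std::numeric_limits<Real>::infinity());
      Cache cEt;
      FMat Ct = net_forward(E, Rt, &cEt);
      double L_c = accu(square(Ct - C)) / B;
      if (!std::isfinite(L_r) || !std::isfinite(L_c))
        Rcpp::stop("non-finite stage-one loss at epoch %d", ep + 1);
      // backward: reconstruction term
      FMat dR = (Real)(2.0 * lambda_r / B) * (R - Xb);
      FMat dSr = dR % conv_to<FMat>::from(Sr > 0.0f);
      Grads g2r, g1r;
      net_backward(G2, c2r, dSr, &g2r, true);
      net_backward(G1, c1r, dSr, &g1r, false);
      FMat dC = g2r.dX.cols(0, l - 1);
      // backward: content term
      FMat dCt = (Real)(2.0 * lambda_c / B) * (Ct - C);
      Grads gEt;
      net_backward(E, cEt, dCt, &gEt, true);
      FMat dSt = gEt.dX % conv_to<FMat>::from(St > 0.0f);
      Grads g2t, g1t;
      net_backward(G2, c2t, dSt, &g2t, true);
      net_backward(G1, c1t, dSt, &g1t, false);
      dC += g2t.dX.cols(0, l - 1) - dCt;
      Grads gE;
      net_backward(E, cE, dC, &gE, false);
      grads_accum(gE, gEt);
      grads_accum(g1r, g1t);
      grads_accum(g2r, g2t);
      adam_step(E, gE, stE, lr, beta1, beta2);
      adam_step(G1, g1r, st1, lr, beta1, beta2);
      adam_step(G2, g2r, st2, lr, beta1, beta2);
      lr_sum += L_r * B;
      lc_sum += L_c * B;
    }
    rep_lr[ep] = lr_sum / n;
    rep_lc[ep] = lc_sum / n;
    Rcpp::checkUserInterrupt();
  }
  return Rcpp::List::create(
    Rcpp::Named("E") = net_to_R(E, E_r),
    Rcpp::Named("G1") = net_to_R(G1, G1_r),
    Rcpp::Named("G2") = net_to_R(G2, G2_r),
    Rcpp::Named("L_r") = rep_lr,
    Rcpp::Named("L_c") = rep_lc);
}

// --- deterministic single-evaluation exports used by the test suite to ---
// --- verify the compiled engine against the pure-R reference            ---

// [[Rcpp::export]]
Rcpp::List cpp_stage1_eval(Rcpp::List E_r, Rcpp::List G1_r, Rcpp::List G2_r,
                           const arma::mat& X, const arma::mat& Bmat,
                           const arma::mat& Btil,
                           double lambda_c, double lambda_r) {
  Net E = net_from_R(E_r), G1 = net_from_R(G1_r), G2 = net_from_R(G2_r);
  FMat Xb = conv_to<FMat>::from(X);
  FMat Bm = conv_to<FMat>::from(Bmat), Bt = conv_to<FMat>::from(Btil);
  uword B = Xb.n_rows;
  uword l = E.W.back().n_cols;
  Cache cE;
  FMat C = net_forward(E, Xb, &cE);
  Cache c1r, c2r;
  FMat in2r = join_rows(C, Bm);
  FMat Sr = net_forward(G1, Bm, &c1r) + net_forward(G2, in2r, &c2r);
  FMat R = clamp(Sr, 0.0f, std::numeric_limits<Real>::infinity());
  double L_r = accu(square(R - Xb)) / B;
  Cache c1t, c2t;
  FMat in2t = join_rows(C, Bt);
  FMat St = net_forward(G1, Bt, &c1t) + net_forward(G2, in2t, &c2t);
  FMat Rt = clamp(St, 0.0f, std::numeric_limits<Real>::infinity());
  Cache cEt;
  FMat Ct = net_forward(E, Rt, &cEt);
  double L_c = accu(square(Ct - C)) / B;
  FMat dR = (Real)(2.0 * lambda_r / B) * (R - Xb);
  FMat dSr = dR % conv_to<FMat>::from(Sr > 0.0f);
  Grads g2r, g1r;
  net_backward(G2, c2r, dSr, &g2r, true);
  net_backward(G1, c1r, dSr, &g1r, false);
  FMat dC = g2r.dX.cols(0, l - 1);
  FMat dCt = (Real)(2.0 * lambda_c / B) * (Ct - C);
  Grads gEt;
  net_backward(E, cEt, dCt, &gEt, true);
  FMat dSt = gEt.dX % conv_to<FMat>::from(St > 0.0f);
  Grads g2t, g1t;
  net_backward(G2, c2t, dSt, &g2t, true);
  net_backward(G1, c1t, dSt, &g1t, false);
  dC += g2t.dX.cols(0, l - 1) - dCt;
  Grads gE;
  net_backward(E, cE, dC, &gE, false);
  grads_accum(gE, gEt);
  return Rcpp::List::create(
    Rcpp::Named("L_r") = L_r, Rcpp::Named("L_c") = L_c,
    Rcpp::Named("gE_W1") = conv_to<arma::mat>::from(gE.gW[0]),
    Rcpp::Named("gG2_W1") = conv_to<arma::mat>::from(g2r.gW[0] + g2t.gW[0]));
}

// [[Rcpp::export]]
Rcpp::List cpp_critic_eval(Rcpp::List Dnet_r, const arma::mat& x_real,
                           const arma::mat& x_fake, const arma::vec& eps,
                           double gp_weight) {
  Net D = net_from_R(Dnet_r);
  FMat xr = conv_to<FMat>::from(x_real), xf = conv_to<FMat>::from(x_fake);
  FVec ev = conv_to<FVec>::from(eps);
  uword B = xr.n_rows;
  Cache cf, cr;
  FMat sf = net_forward(D, xf, &cf);
  FMat sr = net_forward(D, xr, &cr);
  Grads gf, gr;
  net_backward(D, cf, FMat(B, 1, fill::value((Real)(1.0 / B))), &gf, false);
  net_backward(D, cr, FMat(B, 1, fill::value((Real)(-1.0 / B))), &gr, false);
  FMat xhat = (xr.each_col() % ev) + (xf.each_col() % (1.0f - ev));
  Grads gp;
  double pen = critic_gp_grads(D, xhat, gp_weight, &gp);
  grads_accum(gf, gr);
  grads_accum(gf, gp);
  double wass = mean(sf.col(0)) - mean(sr.col(0));
  return Rcpp::List::create(
    Rcpp::Named("wasserstein") = wass, Rcpp::Named("gp") = pen,
    Rcpp::Named("loss") = wass + pen,
    Rcpp::Named("gW1") = conv_to<arma::mat>::from(gf.gW[0]),
    Rcpp::Named("gW3") = conv_to<arma::mat>::from(gf.gW[2]));
}
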