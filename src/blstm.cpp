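// Bidirectional-LSTM text classifier: float32 forward/backward, Adam with
// time-based learning-rate decay, early stopping on validation loss.
// Sequences are bucketed by exact length so no padded timestep is ever
// processed; batches are homogeneous in length.
// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
#include <vector>
#include <random>
using namespace arma;

namespace {

struct Cfg {
  int vocab_rows = 0;   // embedding rows = max token index + 1
  int e = 0;            // embedding dim
  int d = 0;            // LSTM dim per direction
  float lstm_drop = 0;  // non-recurrent (input) dropout
  float dense_drop = 0;
  std::vector<int> dense_dims;  // hidden dense widths (halving cascade)
};

Cfg read_cfg(const Rcpp::List& cfg) {
  Cfg c;
  c.vocab_rows = Rcpp::as<int>(cfg["vocab_rows"]);
  c.e = Rcpp::as<int>(cfg["embedding_dim"]);
  c.d = Rcpp::as<int>(cfg["lstm_dim"]);
  c.lstm_drop = Rcpp::as<double>(cfg["lstm_dropout"]);
  c.dense_drop = Rcpp::as<double>(cfg["dense_dropout"]);
  c.dense_dims = Rcpp::as<std::vector<int>>(cfg["dense_dims"]);
  return c;
}

// deterministic RNG helpers (avoid stdlib distribution differences)
inline float runif01(std::mt19937& eng) {
  return (eng() >> 8) * (1.0f / 16777216.0f);
}
void fill_uniform(fmat& m, float lo, float hi, std::mt19937& eng) {
  for (uword i = 0; i < m.n_elem; ++i) m(i) = lo + (hi - lo) * runif01(eng);
}

// parameter vector layout: E, Wf, Uf, bf, Wb, Ub, bb, [dense W,b]..., out W,b
std::vector<std::string> param_names(const Cfg& c) {
  std::vector<std::string> nm = {"embedding", "w_fwd", "u_fwd", "b_fwd",
                                 "w_bwd", "u_bwd", "b_bwd"};
  for (size_t k = 0; k < c.dense_dims.size(); ++k) {
    nm.push_back("dense_w" + std::to_string(k + 1));
    nm.push_back("dense_b" + std::to_string(k + 1));
  }
  nm.push_back("out_w");
  nm.push_back("out_b");
  return nm;
}

std::vector<fmat> init_params(const Cfg& c, std::mt19937& eng) {
  std::vector<fmat> P;
  fmat E(c.vocab_rows, c.e);
  fill_uniform(E, -0.05f, 0.05f, eng);
  E.row(0).zeros();  // padding row
  P.push_back(E);
  for (int dir = 0; dir < 2; ++dir) {
    float lw = std::sqrt(6.0f / (c.e + 4.0f * c.d));
    float lu = std::sqrt(6.0f / (c.d + 4.0f * c.d));
    fmat W(4 * c.d, c.e), U(4 * c.d, c.d), b(4 * c.d, 1, fill::zeros);
    fill_uniform(W, -lw, lw, eng);
    fill_uniform(U, -lu, lu, eng);
    b.rows(c.d, 2 * c.d - 1).ones();  // forget-gate bias 1
    P.push_back(W); P.push_back(U); P.push_back(b);
  }
  int prev = 2 * c.d;
  for (size_t k = 0; k < c.dense_dims.size(); ++k) {
    int w = c.dense_dims[k];
    float l = std::sqrt(6.0f / (prev + w));
    fmat W(w, prev), b(w, 1, fill::zeros);
    fill_uniform(W, -l, l, eng);
    P.push_back(W); P.push_back(b);
    prev = w;
  }
  float l = std::sqrt(6.0f / (prev + 1));
  fmat W(1, prev), b(1, 1, fill::zeros);
  fill_uniform(W, -l, l, eng);
  P.push_back(W); P.push_back(b);
  return P;
}

Rcpp::List params_to_r(const std::vector<fmat>& P, const Cfg& c) {
  std::vector<std::string> nm = param_names(c);
  Rcpp::List out(P.size());
  for (size_t i = 0; i < P.size(); ++i)
    out[i] = Rcpp::wrap(conv_to<mat>::from(P[i]));
  out.names() = nm;
  return out;
}

std::vector<fmat> params_from_r(const Rcpp::List& L) {
  std::vector<fmat> P;
  for (int i = 0; i < L.size(); ++i)
    P.push_back(conv_to<fmat>::from(Rcpp::as<mat>(L[i])));
  return P;
}

// fast float exp (range-reduced 5th-order polynomial, ~1e-7 relative error);
// the standard library exp is the bottleneck at these matrix sizes
inline float fast_exp(float x) {
  x = std::min(87.0f, std::max(-87.0f, x));
  float n = std::floor(x * 1.44269504f + 0.5f);
  float r = x - n * 0.693147181f;
  float p = 1.0f + r * (1.0f + r * (0.5f + r * (0.166666667f +
            r * (0.0416666667f + r * 0.00833333333f))));
  union { float f; int32_t i; } u;
  u.i = (int32_t)((n + 127.0f)) << 23;
  return p * u.f;
}

inline fmat sigm(fmat x) {
  float* ptr = x.memptr();
  for (uword i = 0; i < x.n_elem; ++i) ptr[i] = 1.0f / (1.0f + fast_exp(-ptr[i]));
  return x;
}

inline fmat fast_tanh(fmat x) {
  float* ptr = x.memptr();
  for (uword i = 0; i < x.n_elem; ++i)
    ptr[i] = 1.0f - 2.0f / (fast_exp(2.0f * ptr[i]) + 1.0f);
  return x;
}

// one direction of the LSTM over a length-T bucket.
// X is the embedded (and dropout-masked) input stacked over timesteps:
// rows [t*B, (t+1)*B) hold timestep t. The input projection X * W' is one
// large gemm; only the recurrent part runs per timestep.
struct LstmCache {
  std::vector<fmat> i, f, g, o, c, tc, h;  // per processed step (B x d)
};

fmat lstm_forward(const fmat& X, int B, int T, const fmat& W, const fmat& U,
                  const fmat& b, bool reverse, LstmCache* cache) {
  int d = U.n_cols;
  if (T == 0) return fmat();
  fmat Gin = X * W.t();
  Gin.each_row() += frowvec(b.t());
  fmat h(B, d, fill::zeros), cst(B, d, fill::zeros);
  for (int s = 0; s < T; ++s) {
    int t = reverse ? T - 1 - s : s;
    fmat a = Gin.rows(t * B, (t + 1) * B - 1) + h * U.t();
    fmat gi = sigm(a.cols(0, d - 1));
    fmat gf = sigm(a.cols(d, 2 * d - 1));
    fmat gg = tanh(a.cols(2 * d, 3 * d - 1));
    fmat go = sigm(a.cols(3 * d, 4 * d - 1));
    cst = gf % cst + gi % gg;
    fmat tc = tanh(cst);
    h = go % tc;
    if (cache) {
      cache->i.push_back(gi); cache->f.push_back(gf); cache->g.push_back(gg);
      cache->o.push_back(go); cache->c.push_back(cst); cache->tc.push_back(tc);
      cache->h.push_back(h);
    }
  }
  return h;
}

// backward through one direction; fills dW,dU,db and the stacked input grads
void lstm_backward(const LstmCache& cc, const fmat& X, int B, int T,
                   const fmat& W, const fmat& U, const fmat& dh_last,
                   bool reverse, fmat& dW, fmat& dU, fmat& db, fmat& dX) {
  if (T == 0) return;
  int d = U.n_cols;
  fmat Da(B * T, 4 * d);
  fmat dh = dh_last, dc(B, d, fill::zeros);
  for (int s = T - 1; s >= 0; --s) {
    int t = reverse ? T - 1 - s : s;  // original timestep index
    const fmat &gi = cc.i[s], &gf = cc.f[s], &gg = cc.g[s], &go = cc.o[s];
    fmat dco = dc + dh % go % (1.0f - cc.tc[s] % cc.tc[s]);
    fmat dgo = dh % cc.tc[s];
    fmat dgi = dco % gg;
    fmat dgg = dco % gi;
    fmat cprev = (s > 0) ? cc.c[s - 1] : fmat(B, d, fill::zeros);
    fmat dgf = dco % cprev;
    dc = dco % gf;
    fmat da(B, 4 * d);
    da.cols(0, d - 1)         = dgi % gi % (1.0f - gi);
    da.cols(d, 2 * d - 1)     = dgf % gf % (1.0f - gf);
    da.cols(2 * d, 3 * d - 1) = dgg % (1.0f - gg % gg);
    da.cols(3 * d, 4 * d - 1) = dgo % go % (1.0f - go);
    fmat hprev = (s > 0) ? cc.h[s - 1] : fmat(B, d, fill::zeros);
    dU += da.t() * hprev;
    dh = da * U;
    Da.rows(t * B, (t + 1) * B - 1) = da;
  }
  dW += Da.t() * X;
  db += sum(Da, 0).t();
  dX += Da * W;
}

struct Batch { std::vector<int> idx; int T; };

// bucket rows by sequence length
std::vector<Batch> make_batches(const std::vector<int>& len, int batch_size,
                                std::mt19937* eng) {
  std::map<int, std::vector<int>> buckets;
  for (size_t i = 0; i < len.size(); ++i) buckets[len[i]].push_back((int)i);
  std::vector<Batch> batches;
  for (auto& kv : buckets) {
    std::vector<int>& v = kv.second;
    if (eng)
      for (int i = (int)v.size() - 1; i > 0; --i)
        std::swap(v[i], v[(int)(runif01(*eng) * (i + 1))]);
    for (size_t s = 0; s < v.size(); s += batch_size) {
      Batch b; b.T = kv.first;
      for (size_t j = s; j < std::min(v.size(), s + batch_size); ++j)
        b.idx.push_back(v[j]);
      batches.push_back(b);
    }
  }
  if (eng)
    for (int i = (int)batches.size() - 1; i > 0; --i)
      std::swap(batches[i], batches[(int)(runif01(*eng) * (i + 1))]);
  return batches;
}

// forward a batch; if grads != nullptr, do backward too (training mode).
// Returns per-sample probabilities (order of b.idx).
fvec run_batch(const std::vector<fmat>& P, const Cfg& c, const imat& X,
               const Batch& b, const fvec* y, float pos_weight,
               std::vector<fmat>* grads, std::mt19937* eng, double* loss_sum) {
  int B = (int)b.idx.size(), T = b.T, d = c.d;
  bool train = grads != nullptr;
  // embed: rows [t*B, (t+1)*B) of E hold timestep t for the whole batch
  fmat E(std::max(B * T, 1), c.e, fill::zeros);
  for (int t = 0; t < T; ++t)
    for (int s = 0; s < B; ++s) E.row(t * B + s) = P[0].row(X(b.idx[s], t));
  // non-recurrent dropout: per-sample mask, constant over time, per direction
  fmat mf, mb, Ef, Eb;
  float keep = 1.0f - c.lstm_drop;
  bool drop_in = train && c.lstm_drop > 0;
  if (drop_in) {
    mf.set_size(B, c.e); mb.set_size(B, c.e);
    for (uword i = 0; i < mf.n_elem; ++i) mf(i) = runif01(*eng) < keep ? 1.0f / keep : 0.0f;
    for (uword i = 0; i < mb.n_elem; ++i) mb(i) = runif01(*eng) < keep ? 1.0f / keep : 0.0f;
    Ef.set_size(size(E)); Eb.set_size(size(E));
    for (int t = 0; t < T; ++t) {
      Ef.rows(t * B, (t + 1) * B - 1) = E.rows(t * B, (t + 1) * B - 1) % mf;
      Eb.rows(t * B, (t + 1) * B - 1) = E.rows(t * B, (t + 1) * B - 1) % mb;
    }
  }
  const fmat& Xf = drop_in ? Ef : E;
  const fmat& Xb = drop_in ? Eb : E;

  LstmCache cf, cb;
  fmat hf = lstm_forward(Xf, B, T, P[1], P[2], P[3], false, train ? &cf : nullptr);
  fmat hb = lstm_forward(Xb, B, T, P[4], P[5], P[6], true, train ? &cb : nullptr);
  fmat z(B, 2 * d, fill::zeros);
  if (T > 0) { z.cols(0, d - 1) = hf; z.cols(d, 2 * d - 1) = hb; }

  // dense cascade
  int nd = (int)c.dense_dims.size();
  std::vector<fmat> act(nd + 1), masks(nd);
  act[0] = z;
  float dkeep = 1.0f - c.dense_drop;
  for (int k = 0; k < nd; ++k) {
    fmat& W = const_cast<fmat&>(P[7 + 2 * k]);
    fmat a = act[k] * W.t();
    a.each_row() += P[7 + 2 * k + 1].t();
    a = clamp(a, 0.0f, std::numeric_limits<float>::max());  // ReLU
    if (train && c.dense_drop > 0) {
      fmat m(size(a));
      for (uword i = 0; i < m.n_elem; ++i) m(i) = runif01(*eng) < dkeep ? 1.0f / dkeep : 0.0f;
      masks[k] = m; a = a % m;
    }
    act[k + 1] = a;
  }
  int iw = 7 + 2 * nd;
  fvec logit = act[nd] * P[iw].t() + P[iw + 1](0, 0);
  fvec p = 1.0f / (1.0f + exp(-logit));

  if (y != nullptr && loss_sum != nullptr) {
    for (int s = 0; s < B; ++s) {
      float ps = std::min(std::max(p(s), 1e-7f), 1.0f - 1e-7f);
      float w = ((*y)(s) > 0.5f) ? pos_weight : 1.0f;
      *loss_sum += -w * ((*y)(s) * std::log(ps) + (1.0f - (*y)(s)) * std::log(1.0f - ps));
    }
  }
  if (!train) return p;

  // ---- backward ----
  std::vector<fmat>& G = *grads;
  fvec dlogit(B);
  for (int s = 0; s < B; ++s) {
    float w = ((*y)(s) > 0.5f) ? pos_weight : 1.0f;
    dlogit(s) = w * (p(s) - (*y)(s));
  }
  G[iw] += dlogit.t() * act[nd];
  G[iw + 1](0, 0) += accu(dlogit);
  fmat dact = dlogit * P[iw];
  for (int k = nd - 1; k >= 0; --k) {
    if (c.dense_drop > 0) dact = dact % masks[k];
    dact = dact % conv_to<fmat>::from(act[k + 1] > 0);  // ReLU grad
    G[7 + 2 * k] += dact.t() * act[k];
    G[7 + 2 * k + 1] += sum(dact, 0).t();
    dact = dact * P[7 + 2 * k];
  }
  if (T > 0) {
    fmat dXf(B * T, c.e, fill::zeros), dXb(B * T, c.e, fill::zeros);
    lstm_backward(cf, Xf, B, T, P[1], P[2], fmat(dact.cols(0, d - 1)), false,
                  G[1], G[2], G[3], dXf);
    lstm_backward(cb, Xb, B, T, P[4], P[5], fmat(dact.cols(d, 2 * d - 1)), true,
                  G[4], G[5], G[6], dXb);
    for (int t = 0; t < T; ++t) {
      int r0 = t * B;
      for (int s = 0; s < B; ++s) {
        if (drop_in) {
          G[0].row(X(b.idx[s], t)) +=
              dXf.row(r0 + s) % mf.row(s) + dXb.row(r0 + s) % mb.row(s);
        } else {
          G[0].row(X(b.idx[s], t)) += dXf.row(r0 + s) + dXb.row(r0 + s);
        }
      }
    }
  }
  return p;
}

double eval_loss(const std::vector<fmat>& P, const Cfg& c, const imat& X,
                 const std::vector<int>& len, const fvec& y, float pos_weight) {
  std::vector<Batch> batches = make_batches(len, 512, nullptr);
  double ls = 0;
  for (auto& b : batches) {
    fvec yb(b.idx.size());
    for (size_t s = 0; s < b.idx.size(); ++s) yb(s) = y(b.idx[s]);
    run_batch(P, c, X, b, &yb, pos_weight, nullptr, nullptr, &ls);
  }
  return ls / y.n_elem;
}

}  // namespace

// [[Rcpp::export]]
Rcpp::List cpp_blstm_init(Rcpp::List cfg, int seed) {
  Cfg c = read_cfg(cfg);
  std::mt19937 eng(seed);
  return params_to_r(init_params(c, eng), c);
}

// [[Rcpp::export]]
Rcpp::NumericVector cpp_blstm_predict(Rcpp::List weights, Rcpp::List cfg,
                                      Rcpp::IntegerMatrix ids,
                                      Rcpp::IntegerVector lens) {
  Cfg c = read_cfg(cfg);
  std::vector<fmat> P = params_from_r(weights);
  imat X = conv_to<imat>::from(Rcpp::as<Mat<int>>(ids));
  std::vector<int> len = Rcpp::as<std::vector<int>>(lens);
  std::vector<Batch> batches = make_batches(len, 512, nullptr);
  Rcpp::NumericVector out(len.size());
  for (auto& b : batches) {
    fvec p = run_batch(P, c, X, b, nullptr, 1.0f, nullptr, nullptr, nullptr);
    for (size_t s = 0; s < b.idx.size(); ++s) out[b.idx[s]] = p(s);
  }
  return out;
}

// mean loss and analytic gradients over one full batch (no update); used to
// verify backpropagation against finite differences
// [[Rcpp::export]]
Rcpp::List cpp_blstm_grad(Rcpp::List weights, Rcpp::List cfg,
                          Rcpp::IntegerMatrix ids, Rcpp::IntegerVector lens,
                          Rcpp::NumericVector y) {
  Cfg c = read_cfg(cfg);
  c.lstm_drop = 0; c.dense_drop = 0;  // deterministic loss surface
  std::vector<fmat> P = params_from_r(weights);
  imat X = conv_to<imat>::from(Rcpp::as<Mat<int>>(ids));
  std::vector<int> len = Rcpp::as<std::vector<int>>(lens);
  fvec yy = conv_to<fvec>::from(Rcpp::as<vec>(y));
  std::vector<fmat> G;
  for (auto& p : P) G.emplace_back(size(p), fill::zeros);
  std::vector<Batch> batches = make_batches(len, (int)len.size(), nullptr);
  double ls = 0;
  for (auto& b : batches) {
    fvec yb(b.idx.size());
    for (size_t s = 0; s < b.idx.size(); ++s) yb(s) = yy(b.idx[s]);
    run_batch(P, c, X, b, &yb, 1.0f, &G, nullptr, &ls);
  }
  for (auto& g : G) g /= (float)len.size();
  return Rcpp::List::create(Rcpp::Named("loss") = ls / len.size(),
                            Rcpp::Named("grads") = params_to_r(G, c));
}

// [[Rcpp::export]]
Rcpp::List cpp_blstm_fit(Rcpp::List weights, Rcpp::List cfg,
                         Rcpp::IntegerMatrix ids, Rcpp::IntegerVector lens,
                         Rcpp::NumericVector y, Rcpp::IntegerMatrix val_ids,
                         Rcpp::IntegerVector val_lens, Rcpp::NumericVector val_y,
                         Rcpp::List fit_cfg, int seed) {
  Cfg c = read_cfg(cfg);
  std::vector<fmat> P = params_from_r(weights);
  imat X = conv_to<imat>::from(Rcpp::as<Mat<int>>(ids));
  imat Xv = conv_to<imat>::from(Rcpp::as<Mat<int>>(val_ids));
  std::vector<int> len = Rcpp::as<std::vector<int>>(lens);
  std::vector<int> lenv = Rcpp::as<std::vector<int>>(val_lens);
  fvec yt = conv_to<fvec>::from(Rcpp::as<vec>(y));
  fvec yv = conv_to<fvec>::from(Rcpp::as<vec>(val_y));

  double lr0 = Rcpp::as<double>(fit_cfg["initial_lr"]);
  double decay = Rcpp::as<double>(fit_cfg["decay"]);
  int max_epochs = Rcpp::as<int>(fit_cfg["max_epochs"]);
  int patience = Rcpp::as<int>(fit_cfg["patience"]);
  double min_delta = Rcpp::as<double>(fit_cfg["min_delta"]);
  int batch_size = Rcpp::as<int>(fit_cfg["batch_size"]);
  float pos_weight = Rcpp::as<double>(fit_cfg["pos_weight"]);

  std::mt19937 eng(seed);
  std::vector<fmat> M, V, G;
  for (auto& p : P) {
    M.emplace_back(size(p), fill::zeros);
    V.emplace_back(size(p), fill::zeros);
    G.emplace_back(size(p), fill::zeros);
  }
  const float b1 = 0.9f, b2 = 0.999f, eps = 1e-7f;
  long step = 0;
  std::vector<double> tr_hist, val_hist;
  double best_val = datum::inf;
  std::vector<fmat> best_P = P;
  int best_epoch = 0, wait = 0;

  for (int epoch = 1; epoch <= max_epochs; ++epoch) {
    std::vector<Batch> batches = make_batches(len, batch_size, &eng);
    double loss_sum = 0;
    for (auto& b : batches) {
      int B = (int)b.idx.size();
      fvec yb(B);
      for (int s = 0; s < B; ++s) yb(s) = yt(b.idx[s]);
      for (auto& g : G) g.zeros();
      run_batch(P, c, X, b, &yb, pos_weight, &G, &eng, &loss_sum);
      ++step;
      float lr = (float)(lr0 / (1.0 + decay * step));
      float bc1 = 1.0f - std::pow(b1, (float)step);
      float bc2 = 1.0f - std::pow(b2, (float)step);
      for (size_t i = 0; i < P.size(); ++i) {
        fmat g = G[i] / (float)B;
        M[i] = b1 * M[i] + (1.0f - b1) * g;
        V[i] = b2 * V[i] + (1.0f - b2) * (g % g);
        P[i] -= lr * (M[i] / bc1) / (sqrt(V[i] / bc2) + eps);
      }
      P[0].row(0).zeros();  // keep padding embedding fixed at zero
    }
    tr_hist.push_back(loss_sum / yt.n_elem);
    double vl = eval_loss(P, c, Xv, lenv, yv, pos_weight);
    val_hist.push_back(vl);
    if (vl < best_val - min_delta) {
      best_val = vl; best_P = P; best_epoch = epoch; wait = 0;
    } else if (++wait >= patience) break;
    Rcpp::checkUserInterrupt();
  }
  return Rcpp::List::create(
      Rcpp::Named("weights") = params_to_r(best_P, c),
      Rcpp::Named("train_loss") = tr_hist,
      Rcpp::Named("val_loss") = val_hist,
      Rcpp::Named("best_epoch") = best_epoch,
      Rcpp::Named("best_val_loss") = best_val);
}
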