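// Multitask 1D convolutional network over one-hot DNA, scoring each input
// window as enhancer/silencer/control in nine cellular contexts.
//
// Layer stack: conv(width k1, n1 kernels, ReLU) -> maxpool(w,s) ->
// dropout -> conv(width k2, n2 kernels, ReLU) -> dropout -> dense(100,
// sigmoid) -> dense(50, sigmoid) -> output logits grouped per context with
// a 3-way softmax. Two output topologies: 27 nodes (independent
// enhancer/silencer/control triple per context) or 19 nodes (per-context
// enhancer and silencer logits plus one control logit shared by all nine
// softmax groups).
//
// Single precision throughout; convolutions are im2col + GEMM so the heavy
// work runs in BLAS. All randomness (shuffling, dropout) comes from one
// std::mt19937 seeded from R, so training is reproducible for a fixed
// thread configuration.

#include <RcppArmadillo.h>
#include <random>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;
using arma::fmat;
using arma::frowvec;
using arma::fvec;
using arma::uword;

namespace {

struct Net {
  fmat W1, W2, W3, W4, W5;
  frowvec b1, b2, b3, b4, b5;
};

struct Dims {
  int L;        // input length
  int nch;      // input channels (4 for one-hot DNA)
  int k1, n1;   // conv1 kernel width / count
  int pw, ps;   // pool width / stride
  int k2, n2;   // conv2 kernel width / count
  int L1, Lp, L2, flat;
  int d1, d2;   // dense layer sizes
  int K;        // output nodes (19 or 27)
  int n_ctx;    // contexts (9)
};

frowvec as_rowvec(SEXP x) {
  fmat m = as<fmat>(x);
  return arma::conv_to<frowvec>::from(m);
}

Net as_net(const List& w) {
  Net n;
  n.W1 = as<fmat>(w["W1"]); n.b1 = as_rowvec(w["b1"]);
  n.W2 = as<fmat>(w["W2"]); n.b2 = as_rowvec(w["b2"]);
  n.W3 = as<fmat>(w["W3"]); n.b3 = as_rowvec(w["b3"]);
  n.W4 = as<fmat>(w["W4"]); n.b4 = as_rowvec(w["b4"]);
  n.W5 = as<fmat>(w["W5"]); n.b5 = as_rowvec(w["b5"]);
  return n;
}

List net_to_list(const Net& n) {
  return List::create(
      _["W1"] = wrap(arma::conv_to<arma::mat>::from(n.W1)),
      _["b1"] = wrap(arma::conv_to<arma::rowvec>::from(n.b1)),
      _["W2"] = wrap(arma::conv_to<arma::mat>::from(n.W2)),
      _["b2"] = wrap(arma::conv_to<arma::rowvec>::from(n.b2)),
      _["W3"] = wrap(arma::conv_to<arma::mat>::from(n.W3)),
      _["b3"] = wrap(arma::conv_to<arma::rowvec>::from(n.b3)),
      _["W4"] = wrap(arma::conv_to<arma::mat>::from(n.W4)),
      _["b4"] = wrap(arma::conv_to<arma::rowvec>::from(n.b4)),
      _["W5"] = wrap(arma::conv_to<arma::mat>::from(n.W5)),
      _["b5"] = wrap(arma::conv_to<arma::rowvec>::from(n.b5)));
}

Dims infer_dims(const Net& net, int L, int pw, int ps, int mode) {
  Dims d;
  d.L = L;
  d.nch = 4;
  d.k1 = net.W1.n_rows / d.nch;
  d.n1 = net.W1.n_cols;
  d.pw = pw; d.ps = ps;
  d.k2 = net.W2.n_rows / d.n1;
  d.n2 = net.W2.n_cols;
  d.L1 = d.L - d.k1 + 1;
  d.Lp = (d.L1 - d.pw) / d.ps + 1;
  d.L2 = d.Lp - d.k2 + 1;
  d.flat = d.L2 * d.n2;
  d.d1 = net.W3.n_cols;
  d.d2 = net.W4.n_cols;
  d.K = net.W5.n_cols;
  d.n_ctx = (mode == 19) ? 9 : d.K / 3;
  if ((uword)d.flat != net.W3.n_rows)
    stop("weight shapes inconsistent with input length %d (flat %d vs W3 rows %d)",
         L, d.flat, (int)net.W3.n_rows);
  if (mode == 19 && d.K != 19) stop("mode 19 requires 19 output nodes");
  if (mode == 27 && d.K != 27) stop("mode 27 requires 27 output nodes");
  return d;
}

// Per-batch workspace; all matrices sized for the current batch.
struct Work {
  fmat P1, H1, Pool, D1mask, P2, H2, D2mask, Xf, A3, A4, Z5, Prob;
  fmat dZ5, dA4g, dZ4, dA3g, dZ3, dXf, dH2, dP2, dPool, dH1;
};

// logit index of (context c, class k) for the given mode; k: 0 enh, 1 sil,
// 2 control
inline int logit_idx(int mode, int c, int k) {
  if (mode == 27) return 3 * c + k;
  return (k == 2) ? 18 : 2 * c + k;
}

void forward(const Net& net, const Dims& d, const arma::imat& seqs,
             const arma::uvec& idx, bool train, float drop1, float drop2,
             std::mt19937& rng, Work& w, int mode) {
  const int B = idx.n_elem;
  // conv1 as one-hot im2col: P1 is (B*L1) x (k1*4)
  w.P1.zeros(B * d.L1, d.k1 * d.nch);
  for (int b = 0; b < B; ++b) {
    const uword s = idx[b];
    const int base = b * d.L1;
    for (int i = 0; i < d.L1; ++i) {
      for (int k = 0; k < d.k1; ++k) {
        const int code = (int)seqs(i + k, s);
        if (code < 4) w.P1(base + i, k * d.nch + code) = 1.0f;
      }
    }
  }
  w.H1 = w.P1 * net.W1;
  w.H1.each_row() += net.b1;
  w.H1.transform([](float v) { return v > 0.0f ? v : 0.0f; });

  // maxpool
  w.Pool.set_size(B * d.Lp, d.n1);
  for (int b = 0; b < B; ++b) {
    const int b1 = b * d.L1, bp = b * d.Lp;
    for (int ch = 0; ch < d.n1; ++ch) {
      for (int j = 0; j < d.Lp; ++j) {
        float m = w.H1(b1 + j * d.ps, ch);
        for (int t = 1; t < d.pw; ++t) {
          const float v = w.H1(b1 + j * d.ps + t, ch);
          if (v > m) m = v;
        }
        w.Pool(bp + j, ch) = m;
      }
    }
  }
  if (train && drop1 > 0.0f) {
    std::uniform_real_distribution<float> unif(0.0f, 1.0f);
    w.D1mask.set_size(w.Pool.n_rows, w.Pool.n_cols);
    const float keep = 1.0f - drop1;
    for (uword i = 0; i < w.D1mask.n_elem; ++i)
      w.D1mask(i) = unif(rng) < keep ? 1.0f / keep : 0.0f;
    w.Pool %= w.D1mask;
  }

  // conv2 im2col: P2 is (B*L2) x (k2*n1)
  w.P2.set_size(B * d.L2, d.k2 * d.n1);
  for (int b = 0; b < B; ++b) {
    const int bp = b * d.Lp, b2 = b * d.L2;
    for (int k = 0; k < d.k2; ++k) {
      w.P2.submat(b2, k * d.n1, b2 + d.L2 - 1, (k + 1) * d.n1 - 1) =
          w.Pool.rows(bp + k, bp + k + d.L2 - 1);
    }
  }
  w.H2 = w.P2 * net.W2;
  w.H2.each_row() += net.b2;
  w.H2.transform([](float v) { return v > 0.0f ? v : 0.0f; });
  if (train && drop2 > 0.0f) {
    std::uniform_real_distribution<float> unif(0.0f, 1.0f);
    w.D2mask.set_size(w.H2.n_rows, w.H2.n_cols);
    const float keep = 1.0f - drop2;
    for (uword i = 0; i < w.D2mask.n_elem; ++i)
      w.D2mask(i) = unif(rng) < keep ? 1.0f / keep : 0.0f;
    w.H2 %= w.D2mask;
  }

  // flatten (column-major within each sample block)
  w.Xf.set_size(B, d.flat);
  for (int b = 0; b < B; ++b) {
    const fmat block = w.H2.rows(b * d.L2, (b + 1) * d.L2 - 1);
    fvec v = arma::vectorise(block);
    for (int jj = 0; jj < d.flat; ++jj) w.Xf(b, jj) = v[jj];
  }

  w.A3 = w.Xf * net.W3;
  w.A3.each_row() += net.b3;
  w.A3.transform([](float v) { return 1.0f / (1.0f + std::exp(-v)); });
  w.A4 = w.A3 * net.W4;
  w.A4.each_row() += net.b4;
  w.A4.transform([](float v) { return 1.0f / (1.0f + std::exp(-v)); });
  w.Z5 = w.A4 * net.W5;
  w.Z5.each_row() += net.b5;

  // per-context softmax over (enh, sil, control) logits
  w.Prob.set_size(B, 3 * d.n_ctx);
  for (int b = 0; b < B; ++b) {
    for (int c = 0; c < d.n_ctx; ++c) {
      float z[3];
      for (int k = 0; k < 3; ++k) z[k] = w.Z5(b, logit_idx(mode, c, k));
      const float mx = std::max(z[0], std::max(z[1], z[2]));
      float s = 0.0f, e[3];
      for (int k = 0; k < 3; ++k) { e[k] = std::exp(z[k] - mx); s += e[k]; }
      for (int k = 0; k < 3; ++k) w.Prob(b, 3 * c + k) = e[k] / s;
    }
  }
}

// weighted multitask cross-entropy; fills w.dZ5 when grad = true
double loss_and_grad(const Dims& d, const arma::imat& labels,
                     const arma::uvec& idx, const fmat& cls_w, Work& w,
                     int mode, bool grad) {
  const int B = idx.n_elem;
  double loss = 0.0;
  if (grad) w.dZ5.zeros(B, d.K);
  const float invB = 1.0f / (float)B;
  for (int b = 0; b < B; ++b) {
    const uword s = idx[b];
    for (int c = 0; c < d.n_ctx; ++c) {
      const int y = (int)labels(s, c);  // 0 enh, 1 sil, 2 control
      const float wt = cls_w(c, y);
      const float py = std::max(w.Prob(b, 3 * c + y), 1e-12f);
      loss += -wt * std::log(py);
      if (grad) {
        for (int k = 0; k < 3; ++k) {
          const float p = w.Prob(b, 3 * c + k);
          const float g = wt * (p - (k == y ? 1.0f : 0.0f)) * invB;
          w.dZ5(b, logit_idx(mode, c, k)) += g;
        }
      }
    }
  }
  return loss / B;
}

void backward(const Net& net, const Dims& d, const arma::uvec& idx,
              bool drop1_on, bool drop2_on, Work& w, Net& g) {
  const int B = idx.n_elem;
  g.W5 = w.A4.t() * w.dZ5;
  g.b5 = arma::sum(w.dZ5, 0);
  w.dA4g = w.dZ5 * net.W5.t();
  w.dZ4 = w.dA4g % w.A4 % (1.0f - w.A4);
  g.W4 = w.A3.t() * w.dZ4;
  g.b4 = arma::sum(w.dZ4, 0);
  w.dA3g = w.dZ4 * net.W4.t();
  w.dZ3 = w.dA3g % w.A3 % (1.0f - w.A3);
  g.W3 = w.Xf.t() * w.dZ3;
  g.b3 = arma::sum(w.dZ3, 0);
  w.dXf = w.dZ3 * net.W3.t();

  // unflatten
  w.dH2.set_size(B * d.L2, d.n2);
  for (int b = 0; b < B; ++b) {
    for (int jj = 0; jj < d.flat; ++jj) {
      const int j = jj % d.L2, ch = jj / d.L2;
      w.dH2(b * d.L2 + j, ch) = w.dXf(b, jj);
    }
  }
  if (drop2_on) w.dH2 %= w.D2mask;
  // ReLU mask of conv2 (post-dropout H2 kept; zero iff pre-dropout zero or
  // dropped, either way gradient is zero after the mask products)
  w.dH2.elem(arma::find(w.H2 <= 0.0f)).zeros();

  g.W2 = w.P2.t() * w.dH2;
  g.b2 = arma::sum(w.dH2, 0);
  w.dP2 = w.dH2 * net.W2.t();

  // col2im back to pooled map
  w.dPool.zeros(B * d.Lp, d.n1);
  for (int b = 0; b < B; ++b) {
    const int bp = b * d.Lp, b2 = b * d.L2;
    for (int k = 0; k < d.k2; ++k) {
      w.dPool.rows(bp + k, bp + k + d.L2 - 1) +=
          w.dP2.submat(b2, k * d.n1, b2 + d.L2 - 1, (k + 1) * d.n1 - 1);
    }
  }
  if (drop1_on) w.dPool %= w.D1mask;

  // route through maxpool (first-max tie break, recomputed from H1)
  w.dH1.zeros(B * d.L1, d.n1);
  for (int b = 0; b < B; ++b) {
    const int b1 = b * d.L1, bp = b * d.Lp;
    for (int ch = 0; ch < d.n1; ++ch) {
      for (int j = 0; j < d.Lp; ++j) {
        const float gv = w.dPool(bp + j, ch);
        if (gv == 0.0f) continue;
        int arg = 0;
        float m = w.H1(b1 + j * d.ps, ch);
        for (int t = 1; t < d.pw; ++t) {
          const float v = w.H1(b1 + j * d.ps + t, ch);
          if (v > m) { m = v; arg = t; }
        }
        w.dH1(b1 + j * d.ps + arg, ch) += gv;
      }
    }
  }
  w.dH1.elem(arma::find(w.H1 <= 0.0f)).zeros();
  g.W1 = w.P1.t() * w.dH1;
  g.b1 = arma::sum(w.dH1, 0);
}

struct Adam {
  Net m, v;
  double b1 = 0.9, b2 = 0.999, eps = 1e-8;
  long t = 0;
  void init(const Net& n) {
    m.W1.zeros(arma::size(n.W1)); v.W1.zeros(arma::size(n.W1));
    m.W2.zeros(arma::size(n.W2)); v.W2.zeros(arma::size(n.W2));
    m.W3.zeros(arma::size(n.W3)); v.W3.zeros(arma::size(n.W3));
    m.W4.zeros(arma::size(n.W4)); v.W4.zeros(arma::size(n.W4));
    m.W5.zeros(arma::size(n.W5)); v.W5.zeros(arma::size(n.W5));
    m.b1.zeros(arma::size(n.b1)); v.b1.zeros(arma::size(n.b1));
    m.b2.zeros(arma::size(n.b2)); v.b2.zeros(arma::size(n.b2));
    m.b3.zeros(arma::size(n.b3)); v.b3.zeros(arma::size(n.b3));
    m.b4.zeros(arma::size(n.b4)); v.b4.zeros(arma::size(n.b4));
    m.b5.zeros(arma::size(n.b5)); v.b5.zeros(arma::size(n.b5));
  }
  template <class M>
  void upd(M& w, M& mm, M& vv, const M& g, float lr) {
    mm = (float)b1 * mm + (float)(1 - b1) * g;
    vv = (float)b2 * vv + (float)(1 - b2) * (g % g);
    const float c1 = 1.0f - std::pow((float)b1, (float)t);
    const float c2 = 1.0f - std::pow((float)b2, (float)t);
    w -= lr * (mm / c1) / (arma::sqrt(vv / c2) + (float)eps);
  }
  // decoupled weight decay applies to the dense weight matrices only;
  // convolution kernels and biases are left unpenalised. The convolution
  // layers optionally run at a higher learning rate than the dense stack
  // (conv_mult) so motif detectors sharpen before the wide dense layer
  // can overfit.
  // w3_mult throttles the flatten-to-dense matrix alone: with 63k inputs
  // per unit, full-rate Adam steps on W3 move the sigmoid pre-activations
  // by several units per update (saturation) and let W3 memorise the
  // training windows; the other layers are small enough to train at the
  // base rate.
  void step(Net& n, Net& g, float lr, float decay, float conv_mult,
            float w3_mult) {
    ++t;
    const float lrc = lr * conv_mult;
    upd(n.W1, m.W1, v.W1, g.W1, lrc); upd(n.b1, m.b1, v.b1, g.b1, lrc);
    upd(n.W2, m.W2, v.W2, g.W2, lrc); upd(n.b2, m.b2, v.b2, g.b2, lrc);
    upd(n.W3, m.W3, v.W3, g.W3, lr * w3_mult);
    upd(n.b3, m.b3, v.b3, g.b3, lr);
    upd(n.W4, m.W4, v.W4, g.W4, lr); upd(n.b4, m.b4, v.b4, g.b4, lr);
    upd(n.W5, m.W5, v.W5, g.W5, lr); upd(n.b5, m.b5, v.b5, g.b5, lr);
    if (decay > 0.0f) {
      n.W3 *= (1.0f - lr * decay);
      n.W4 *= (1.0f - lr * decay);
      n.W5 *= (1.0f - lr * decay);
    }
  }
};

double eval_loss(const Net& net, const Dims& d, const arma::imat& seqs,
                 const arma::imat& labels, const fmat& cls_w, int mode,
                 std::mt19937& rng, int batch) {
  const int n = seqs.n_cols;
  Work w;
  double tot = 0.0;
  int nb = 0;
  for (int off = 0; off < n; off += batch) {
    const int B = std::min(batch, n - off);
    arma::uvec idx = arma::regspace<arma::uvec>(off, off + B - 1);
    forward(net, d, seqs, idx, false, 0.0f, 0.0f, rng, w, mode);
    tot += loss_and_grad(d, labels, idx, cls_w, w, mode, false) * B;
    nb += B;
  }
  return tot / nb;
}

}  // namespace

// [[Rcpp::export(name = ".cnn_train")]]
List cnn_train_cpp(IntegerMatrix seqs_r, IntegerMatrix labels_r,
                   IntegerMatrix val_seqs_r, IntegerMatrix val_labels_r,
                   List weights, List hyper) {
  arma::imat seqs = as<arma::imat>(seqs_r);
  arma::imat labels = as<arma::imat>(labels_r);
  arma::imat vseqs = as<arma::imat>(val_seqs_r);
  arma::imat vlabels = as<arma::imat>(val_labels_r);
  Net net = as_net(weights);

  const int epochs = as<int>(hyper["epochs"]);
  const int batch = as<int>(hyper["batch_size"]);
  const float lr = (float)as<double>(hyper["learning_rate"]);
  const float drop1 = (float)as<double>(hyper["dropout1"]);
  const float drop2 = (float)as<double>(hyper["dropout2"]);
  const int mode = as<int>(hyper["mode"]);
  const int pw = as<int>(hyper["pool_width"]);
  const int ps = as<int>(hyper["pool_stride"]);
  const int patience = as<int>(hyper["patience"]);
  const float decay = hyper.containsElementNamed("weight_decay")
                          ? (float)as<double>(hyper["weight_decay"]) : 0.0f;
  const float conv_mult = hyper.containsElementNamed("lr_conv_mult")
                              ? (float)as<double>(hyper["lr_conv_mult"]) : 1.0f;
  const float w3_mult = hyper.containsElementNamed("lr_w3_mult")
                            ? (float)as<double>(hyper["lr_w3_mult"]) : 1.0f;
  const unsigned seed = (unsigned)as<int>(hyper["seed"]);
  fmat cls_w = as<fmat>(hyper["class_weights"]);

  const Dims d = infer_dims(net, seqs.n_rows, pw, ps, mode);
  if ((int)labels.n_cols != d.n_ctx) stop("labels must have %d columns", d.n_ctx);

  const int restart = hyper.containsElementNamed("adam_restart")
                          ? as<int>(hyper["adam_restart"]) : 0;

  std::mt19937 rng(seed);
  Adam opt; opt.init(net);
  Work w; Net g;
  const int n = seqs.n_cols;
  const bool has_val = vseqs.n_cols > 0;

  std::vector<uword> perm(n);
  for (int i = 0; i < n; ++i) perm[i] = i;

  std::vector<double> tr_loss, va_loss;
  Net best = net;
  double best_val = std::numeric_limits<double>::infinity();
  int best_epoch = 0, bad = 0;

  for (int ep = 1; ep <= epochs; ++ep) {
    // periodic warm restarts: clearing the moment estimates every few
    // epochs briefly enlarges the normalised steps, which reliably kicks
    // the network off the uniform-prediction plateau
    if (restart > 0 && ep > 1 && ((ep - 1) % restart) == 0) {
      opt.init(net);
      opt.t = 0;
    }
    std::shuffle(perm.begin(), perm.end(), rng);
    double ep_loss = 0.0;
    int nseen = 0;
    for (int off = 0; off < n; off += batch) {
      const int B = std::min(batch, n - off);
      arma::uvec idx(B);
      for (int b = 0; b < B; ++b) idx[b] = perm[off + b];
      forward(net, d, seqs, idx, true, drop1, drop2, rng, w, mode);
      ep_loss += loss_and_grad(d, labels, idx, cls_w, w, mode, true) * B;
      nseen += B;
      backward(net, d, idx, drop1 > 0.0f, drop2 > 0.0f, w, g);
      opt.step(net, g, lr, decay, conv_mult, w3_mult);
    }
    ep_loss /= nseen;
    tr_loss.push_back(ep_loss);
    double vl = NA_REAL;
    if (has_val) {
      vl = eval_loss(net, d, vseqs, vlabels, cls_w, mode, rng, 256);
      va_loss.push_back(vl);
      if (vl < best_val) {
        best_val = vl; best = net; best_epoch = ep; bad = 0;
      } else if (++bad >= patience) {
        break;
      }
    } else {
      best = net; best_epoch = ep;
    }
    Rcpp::checkUserInterrupt();
  }

  List hist = List::create(
      _["epoch"] = seq_len(tr_loss.size()),
      _["train_loss"] = wrap(tr_loss),
      _["val_loss"] = has_val ? wrap(va_loss) : R_NilValue);
  return List::create(_["weights"] = net_to_list(best),
                      _["history"] = hist,
                      _["best_epoch"] = best_epoch);
}

// Loss and analytic gradients for one full batch; used by the
// finite-difference gradient tests.
// [[Rcpp::export(name = ".cnn_grad")]]
List cnn_grad_cpp(IntegerMatrix seqs_r, IntegerMatrix labels_r, List weights,
                  List hyper) {
  arma::imat seqs = as<arma::imat>(seqs_r);
  arma::imat labels = as<arma::imat>(labels_r);
  Net net = as_net(weights);
  const int mode = as<int>(hyper["mode"]);
  const int pw = as<int>(hyper["pool_width"]);
  const int ps = as<int>(hyper["pool_stride"]);
  fmat cls_w = as<fmat>(hyper["class_weights"]);
  const Dims d = infer_dims(net, seqs.n_rows, pw, ps, mode);
  std::mt19937 rng(0);
  Work w; Net g;
  arma::uvec idx = arma::regspace<arma::uvec>(0, seqs.n_cols - 1);
  forward(net, d, seqs, idx, false, 0.0f, 0.0f, rng, w, mode);
  double loss = loss_and_grad(d, labels, idx, cls_w, w, mode, true);
  backward(net, d, idx, false, false, w, g);
  return List::create(_["loss"] = loss, _["grad"] = net_to_list(g));
}

// [[Rcpp::export(name = ".cnn_predict")]]
NumericMatrix cnn_predict_cpp(IntegerMatrix seqs_r, List weights, List hyper) {
  arma::imat seqs = as<arma::imat>(seqs_r);
  Net net = as_net(weights);
  const int mode = as<int>(hyper["mode"]);
  const int pw = as<int>(hyper["pool_width"]);
  const int ps = as<int>(hyper["pool_stride"]);
  const Dims d = infer_dims(net, seqs.n_rows, pw, ps, mode);
  const int n = seqs.n_cols;
  std::mt19937 rng(0);
  Work w;
  arma::mat out(n, 3 * d.n_ctx);
  const int batch = 256;
  for (int off = 0; off < n; off += batch) {
    const int B = std::min(batch, n - off);
    arma::uvec idx = arma::regspace<arma::uvec>(off, off + B - 1);
    forward(net, d, seqs, idx, false, 0.0f, 0.0f, rng, w, mode);
    out.rows(off, off + B - 1) = arma::conv_to<arma::mat>::from(w.Prob);
  }
  return wrap(out);
}
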