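// Bidirectional stacked GRU regressor for sequence-to-scalar prediction.
// One-hot input (L x 20), final forward/backward states of the top layer
// pooled through a linear head to a single scalar. L1 training objective,
// Adam optimizer, full backpropagation through time. Weights live in one
// flat parameter vector so the whole model round-trips as an R numeric.

#include <Rcpp.h>
#include <cmath>
#include <random>
#include <vector>
#include <algorithm>

using namespace Rcpp;

static inline double sigmoid(double x) { return 1.0 / (1.0 + std::exp(-x)); }

struct GruDims {
  int layers, hidden, input;
  // per (layer, direction) block size
  int block(int l) const {
    int d = (l == 0) ? input : 2 * hidden;
    return 3 * hidden * d + 3 * hidden * hidden + 3 * hidden;
  }
  int offset(int l, int dir) const {
    int off = 0;
    for (int i = 0; i < l; ++i) off += 2 * block(i);
    return off + dir * block(l);
  }
  int head_offset() const { return offset(layers - 1, 1) + block(layers - 1); }
  int total() const { return head_offset() + 2 * hidden + 1; }
  int in_dim(int l) const { return (l == 0) ? input : 2 * hidden; }
};

// Views into a (layer, direction) parameter block.
struct GruBlock {
  const double *Wz, *Wr, *Wn, *Uz, *Ur, *Un, *bz, *br, *bn;
  GruBlock(const double* p, const GruDims& dm, int l, int dir) {
    int H = dm.hidden, D = dm.in_dim(l);
    const double* q = p + dm.offset(l, dir);
    Wz = q; Wr = q + H * D; Wn = q + 2 * H * D;
    Uz = q + 3 * H * D; Ur = Uz + H * H; Un = Uz + 2 * H * H;
    bz = q + 3 * H * D + 3 * H * H; br = bz + H; bn = bz + 2 * H;
  }
};
struct GruBlockGrad {
  double *Wz, *Wr, *Wn, *Uz, *Ur, *Un, *bz, *br, *bn;
  GruBlockGrad(double* p, const GruDims& dm, int l, int dir) {
    int H = dm.hidden, D = dm.in_dim(l);
    double* q = p + dm.offset(l, dir);
    Wz = q; Wr = q + H * D; Wn = q + 2 * H * D;
    Uz = q + 3 * H * D; Ur = Uz + H * H; Un = Uz + 2 * H * H;
    bz = q + 3 * H * D + 3 * H * H; br = bz + H; bn = bz + 2 * H;
  }
};

// Cached activations for one direction of one layer on one sequence.
struct DirCache {
  // per time step (in processing order): z, r, n, h, and Un*h_prev
  std::vector<double> z, r, n, h, unh;
};

// Process one direction; input X is T x D row-major in original order;
// dir = 0 forward, 1 backward (processes reversed). Outputs h states in
// processing order.
static void run_dir(const GruBlock& B, const std::vector<double>& X, int T,
                    int D, int H, DirCache& C) {
  C.z.assign((size_t)T * H, 0.0); C.r.assign((size_t)T * H, 0.0);
  C.n.assign((size_t)T * H, 0.0); C.h.assign((size_t)T * H, 0.0);
  C.unh.assign((size_t)T * H, 0.0);
  std::vector<double> hprev(H, 0.0);
  for (int s = 0; s < T; ++s) {
    const double* x = &X[(size_t)s * D];
    for (int i = 0; i < H; ++i) {
      double az = B.bz[i], ar = B.br[i], an_x = B.bn[i];
      const double *wz = B.Wz + (size_t)i * D, *wr = B.Wr + (size_t)i * D,
                   *wn = B.Wn + (size_t)i * D;
      for (int j = 0; j < D; ++j) {
        double xj = x[j];
        if (xj != 0.0) { az += wz[j] * xj; ar += wr[j] * xj; an_x += wn[j] * xj; }
      }
      double uz = 0, ur = 0, un = 0;
      const double *Uzr = B.Uz + (size_t)i * H, *Urr = B.Ur + (size_t)i * H,
                   *Unr = B.Un + (size_t)i * H;
      for (int j = 0; j < H; ++j) {
        double hj = hprev[j];
        uz += Uzr[j] * hj; ur += Urr[j] * hj; un += Unr[j] * hj;
      }
      double z = sigmoid(az + uz), r = sigmoid(ar + ur);
      double nn = std::tanh(an_x + r * un);
      C.z[(size_t)s * H + i] = z; C.r[(size_t)s * H + i] = r;
      C.n[(size_t)s * H + i] = nn; C.unh[(size_t)s * H + i] = un;
      C.h[(size_t)s * H + i] = (1.0 - z) * nn + z * hprev[i];
    }
    for (int i = 0; i < H; ++i) hprev[i] = C.h[(size_t)s * H + i];
  }
}

// Backprop one direction. dH (T x H, processing order) holds dL/dh_s from
// above; dX (T x D, original-layer order handled by caller) accumulates
// input gradients; G accumulates parameter gradients.
static void back_dir(const GruBlock& B, GruBlockGrad& G,
                     const std::vector<double>& X, const DirCache& C,
                     std::vector<double>& dH, std::vector<double>& dX,
                     int T, int D, int H) {
  std::vector<double> dhnext(H, 0.0);
  std::vector<double> hprev(H), daz(H), dar(H), dan(H);
  for (int s = T - 1; s >= 0; --s) {
    if (s == 0) std::fill(hprev.begin(), hprev.end(), 0.0);
    else std::copy(C.h.begin() + (size_t)(s - 1) * H,
                   C.h.begin() + (size_t)s * H, hprev.begin());
    const double* x = &X[(size_t)s * D];
    std::vector<double> dhprev(H, 0.0);
    for (int i = 0; i < H; ++i) {
      double dh = dH[(size_t)s * H + i] + dhnext[i];
      double z = C.z[(size_t)s * H + i], r = C.r[(size_t)s * H + i],
             nn = C.n[(size_t)s * H + i], un = C.unh[(size_t)s * H + i];
      double dz = dh * (hprev[i] - nn);
      double dn = dh * (1.0 - z);
      dhprev[i] += dh * z;
      double da_n = dn * (1.0 - nn * nn);
      double dr = da_n * un;
      daz[i] = dz * z * (1.0 - z);
      dar[i] = dr * r * (1.0 - r);
      dan[i] = da_n;                   // applied to W/b path
      // U-path for n gate carries the reset factor
      G.bz[i] += daz[i]; G.br[i] += dar[i]; G.bn[i] += da_n;
      double dan_u = da_n * r;
      double *uzr = G.Uz + (size_t)i * H, *urr = G.Ur + (size_t)i * H,
             *unr = G.Un + (size_t)i * H;
      for (int j = 0; j < H; ++j) {
        uzr[j] += daz[i] * hprev[j];
        urr[j] += dar[i] * hprev[j];
        unr[j] += dan_u * hprev[j];
      }
      double *wz = G.Wz + (size_t)i * D, *wr = G.Wr + (size_t)i * D,
             *wn = G.Wn + (size_t)i * D;
      for (int j = 0; j < D; ++j) {
        double xj = x[j];
        if (xj != 0.0) {
          wz[j] += daz[i] * xj; wr[j] += dar[i] * xj; wn[j] += da_n * xj;
        }
      }
    }
    // dhprev += U^T contributions; dX += W^T contributions
    for (int i = 0; i < H; ++i) {
      double dan_u = dan[i] * C.r[(size_t)s * H + i];
      const double *Uzr = B.Uz + (size_t)i * H, *Urr = B.Ur + (size_t)i * H,
                   *Unr = B.Un + (size_t)i * H;
      for (int j = 0; j < H; ++j)
        dhprev[j] += Uzr[j] * daz[i] + Urr[j] * dar[i] + Unr[j] * dan_u;
      const double *Wzr = B.Wz + (size_t)i * D, *Wrr = B.Wr + (size_t)i * D,
                   *Wnr = B.Wn + (size_t)i * D;
      double* dx = &dX[(size_t)s * D];
      for (int j = 0; j < D; ++j)
        dx[j] += Wzr[j] * daz[i] + Wrr[j] * dar[i] + Wnr[j] * dan[i];
    }
    dhnext.swap(dhprev);
  }
}

// Forward pass for one sequence given type indices; optionally fill caches
// and per-layer inputs for backprop.
static double forward_seq(const double* par, const GruDims& dm,
                          const std::vector<int>& types,
                          std::vector<std::vector<double>>* layer_in,
                          std::vector<DirCache>* caches) {
  int T = (int)types.size(), H = dm.hidden;
  std::vector<double> X((size_t)T * dm.input, 0.0);
  for (int s = 0; s < T; ++s) X[(size_t)s * dm.input + types[s]] = 1.0;
  std::vector<double> cur = X;
  std::vector<DirCache> local(2);
  double hf_last = 0.0;
  std::vector<double> top(2 * H, 0.0);
  for (int l = 0; l < dm.layers; ++l) {
    int D = dm.in_dim(l);
    if (layer_in) (*layer_in)[l] = cur;
    // reversed copy for the backward direction
    std::vector<double> rev((size_t)T * D);
    for (int s = 0; s < T; ++s)
      std::copy(cur.begin() + (size_t)(T - 1 - s) * D,
                cur.begin() + (size_t)(T - s) * D, rev.begin() + (size_t)s * D);
    DirCache &cf = caches ? (*caches)[l * 2] : local[0];
    DirCache &cb = caches ? (*caches)[l * 2 + 1] : local[1];
    GruBlock Bf(par, dm, l, 0), Bb(par, dm, l, 1);
    run_dir(Bf, cur, T, D, H, cf);
    run_dir(Bb, rev, T, D, H, cb);
    // concat outputs in original order: [h_f(s); h_b(T-1-s processed)]
    std::vector<double> nxt((size_t)T * 2 * H);
    for (int s = 0; s < T; ++s) {
      std::copy(cf.h.begin() + (size_t)s * H, cf.h.begin() + (size_t)(s + 1) * H,
                nxt.begin() + (size_t)s * 2 * H);
      int sb = T - 1 - s;
      std::copy(cb.h.begin() + (size_t)sb * H,
                cb.h.begin() + (size_t)(sb + 1) * H,
                nxt.begin() + (size_t)s * 2 * H + H);
    }
    if (l == dm.layers - 1) {
      std::copy(cf.h.begin() + (size_t)(T - 1) * H, cf.h.begin() + (size_t)T * H,
                top.begin());
      std::copy(cb.h.begin() + (size_t)(T - 1) * H, cb.h.begin() + (size_t)T * H,
                top.begin() + H);
    }
    cur.swap(nxt);
  }
  (void)hf_last;
  const double* head = par + dm.head_offset();
  double out = head[2 * H];
  for (int i = 0; i < 2 * H; ++i) out += head[i] * top[i];
  return out;
}

// Backward for one sequence; adds gradients into grad. dpred = dL/dpred.
static void backward_seq(const double* par, double* grad, const GruDims& dm,
                         const std::vector<int>& types, double dpred,
                         std::vector<std::vector<double>>& layer_in,
                         std::vector<DirCache>& caches) {
  int T = (int)types.size(), H = dm.hidden;
  const double* head = par + dm.head_offset();
  double* ghead = grad + dm.head_offset();
  // top-layer final states
  DirCache &tf = caches[(dm.layers - 1) * 2], &tb = caches[(dm.layers - 1) * 2 + 1];
  ghead[2 * H] += dpred;
  for (int i = 0; i < H; ++i) {
    ghead[i] += dpred * tf.h[(size_t)(T - 1) * H + i];
    ghead[H + i] += dpred * tb.h[(size_t)(T - 1) * H + i];
  }
  // gradient flowing into each layer's output sequence (original order)
  std::vector<double> dout;
  for (int l = dm.layers - 1; l >= 0; --l) {
    int D = dm.in_dim(l);
    std::vector<double> dHf((size_t)T * H, 0.0), dHb((size_t)T * H, 0.0);
    if (l == dm.layers - 1) {
      for (int i = 0; i < H; ++i) {
        dHf[(size_t)(T - 1) * H + i] += dpred * head[i];
        dHb[(size_t)(T - 1) * H + i] += dpred * head[H + i];
      }
    }
    if (!dout.empty()) {
      // dout is T x 2H in original order; forward half maps directly,
      // backward half maps to processing order T-1-s
      for (int s = 0; s < T; ++s) {
        for (int i = 0; i < H; ++i) {
          dHf[(size_t)s * H + i] += dout[(size_t)s * 2 * H + i];
          dHb[(size_t)(T - 1 - s) * H + i] += dout[(size_t)s * 2 * H + H + i];
        }
      }
    }
    GruBlock Bf(par, dm, l, 0), Bb(par, dm, l, 1);
    GruBlockGrad Gf(grad, dm, l, 0), Gb(grad, dm, l, 1);
    std::vector<double>& Xf = layer_in[l];
    std::vector<double> Xb((size_t)T * D);
    for (int s = 0; s < T; ++s)
      std::copy(Xf.begin() + (size_t)(T - 1 - s) * D,
                Xf.begin() + (size_t)(T - s) * D, Xb.begin() + (size_t)s * D);
    std::vector<double> dXf((size_t)T * D, 0.0), dXb((size_t)T * D, 0.0);
    back_dir(Bf, Gf, Xf, caches[l * 2], dHf, dXf, T, D, H);
    back_dir(Bb, Gb, Xb, caches[l * 2 + 1], dHb, dXb, T, D, H);
    if (l > 0) {
      dout.assign((size_t)T * D, 0.0);
      for (int s = 0; s < T; ++s)
        for (int j = 0; j < D; ++j)
          dout[(size_t)s * D + j] = dXf[(size_t)s * D + j] +
                                    dXb[(size_t)(T - 1 - s) * D + j];
    }
  }
}

static std::vector<std::vector<int>> decode_seqs(const List& seqs) {
  std::vector<std::vector<int>> out(seqs.size());
  for (int i = 0; i < seqs.size(); ++i) {
    IntegerVector v = seqs[i];
    out[i].assign(v.begin(), v.end());
  }
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_gru_predict(NumericVector params, List seqs, int layers,
                              int hidden, int input) {
  GruDims dm{layers, hidden, input};
  if ((int)params.size() != dm.total()) stop("parameter vector size mismatch");
  auto ts = decode_seqs(seqs);
  NumericVector out(ts.size());
  for (size_t i = 0; i < ts.size(); ++i)
    out[i] = forward_seq(&params[0], dm, ts[i], nullptr, nullptr);
  return out;
}

// Analytic gradient of L1 loss for one (sequence, label); for testing.
// [[Rcpp::export]]
List cpp_gru_loss_grad(NumericVector params, IntegerVector seq, double label,
                       int layers, int hidden, int input) {
  GruDims dm{layers, hidden, input};
  if ((int)params.size() != dm.total()) stop("parameter vector size mismatch");
  std::vector<int> types(seq.begin(), seq.end());
  std::vector<std::vector<double>> layer_in(layers);
  std::vector<DirCache> caches(2 * layers);
  double pred = forward_seq(&params[0], dm, types, &layer_in, &caches);
  NumericVector grad(dm.total());
  double dpred = (pred > label) ? 1.0 : (pred < label ? -1.0 : 0.0);
  backward_seq(&params[0], &grad[0], dm, types, dpred, layer_in, caches);
  return List::create(_["loss"] = std::fabs(pred - label),
                      _["pred"] = pred, _["grad"] = grad);
}

// [[Rcpp::export]]
int cpp_gru_nparams(int layers, int hidden, int input) {
  GruDims dm{layers, hidden, input};
  return dm.total();
}

// Train with Adam on L1 loss. Returns the weights of the epoch with the
// lowest validation loss, plus both loss curves.
// [[Rcpp::export]]
List cpp_gru_train(List train_seqs, NumericVector train_y, List val_seqs,
                   NumericVector val_y, int layers, int hidden, int input,
                   int epochs, int batch_size, double lr, int seed) {
  GruDims dm{layers, hidden, input};
  int np = dm.total();
  std::mt19937_64 rng((uint64_t)seed);
  std::uniform_real_distribution<double> unif(-1.0, 1.0);
  std::vector<double> par(np);
  double s0 = std::sqrt(1.0 / hidden);
  for (int i = 0; i < np; ++i) par[i] = s0 * unif(rng);
  // head bias starts at the training-label mean so early epochs are sane
  double ymean = 0.0;
  for (int i = 0; i < train_y.size(); ++i) ymean += train_y[i];
  ymean /= std::max(1, (int)train_y.size());
  par[np - 1] = ymean;

  auto ts_train = decode_seqs(train_seqs), ts_val = decode_seqs(val_seqs);
  int ntr = (int)ts_train.size();
  std::vector<double> m(np, 0.0), v(np, 0.0), grad(np, 0.0);
  std::vector<int> order(ntr);
  for (int i = 0; i < ntr; ++i) order[i] = i;
  double b1 = 0.9, b2 = 0.999, epsa = 1e-8;
  long long t_adam = 0;
  NumericVector train_curve(epochs), val_curve(epochs);
  double best_val = R_PosInf;
  int best_epoch = -1;
  std::vector<double> best_par = par;

  std::vector<std::vector<double>> layer_in(layers);
  std::vector<DirCache> caches(2 * layers);

  for (int ep = 0; ep < epochs; ++ep) {
    std::shuffle(order.begin(), order.end(), rng);
    double tr_loss = 0.0;
    for (int b0 = 0; b0 < ntr; b0 += batch_size) {
      int bn = std::min(batch_size, ntr - b0);
      std::fill(grad.begin(), grad.end(), 0.0);
      for (int k = 0; k < bn; ++k) {
        int idx = order[b0 + k];
        double pred = forward_seq(par.data(), dm, ts_train[idx], &layer_in,
                                  &caches);
        double diff = pred - train_y[idx];
        tr_loss += std::fabs(diff);
        double dpred = (diff > 0 ? 1.0 : (diff < 0 ? -1.0 : 0.0)) / bn;
        backward_seq(par.data(), grad.data(), dm, ts_train[idx], dpred,
                     layer_in, caches);
      }
      ++t_adam;
      double c1 = 1.0 - std::pow(b1, (double)t_adam);
      double c2 = 1.0 - std::pow(b2, (double)t_adam);
      for (int i = 0; i < np; ++i) {
        m[i] = b1 * m[i] + (1 - b1) * grad[i];
        v[i] = b2 * v[i] + (1 - b2) * grad[i] * grad[i];
        par[i] -= lr * (m[i] / c1) / (std::sqrt(v[i] / c2) + epsa);
      }
      if (!std::isfinite(par[0]))
        stop("NaN encountered during training at epoch %d", ep + 1);
    }
    tr_loss /= std::max(1, ntr);
    double vl = 0.0;
    for (size_t i = 0; i < ts_val.size(); ++i)
      vl += std::fabs(forward_seq(par.data(), dm, ts_val[i], nullptr, nullptr) -
                      val_y[i]);
    vl /= std::max((size_t)1, ts_val.size());
    if (!std::isfinite(tr_loss) || !std::isfinite(vl))
      stop("NaN loss at epoch %d; lower the learning rate", ep + 1);
    train_curve[ep] = tr_loss;
    val_curve[ep] = vl;
    if (vl < best_val) { best_val = vl; best_epoch = ep; best_par = par; }
  }
  return List::create(_["weights"] = NumericVector(best_par.begin(), best_par.end()),
                      _["train_loss"] = train_curve, _["val_loss"] = val_curve,
                      _["best_epoch"] = best_epoch + 1,
                      _["best_val_loss"] = best_val);
}
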