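// Numerical core: small U-Net (forward, backprop, Adam) built on im2col +
// BLAS GEMM, plus connected-component labelling, nearest-two-seed distance
// fields for the Voronoi renderer, and a separable blur.
//
// Conventions shared with the R side:
//   * images are H x W matrices (row = y, column = x), feature maps are
//     H x W x C cubes;
//   * a conv layer's weights are a (k*k*cin) x cout matrix whose rows are
//     ordered (ky fastest, then kx, then input channel) to match im2col;
//   * "same" padding: pad_lo = (k-1)/2, pad_hi = k-1-pad_lo, so k=3 pads
//     1/1, k=2 pads 0/1, k=1 pads nothing — output size always equals input.
//
// cpp_unet_train_step updates the weight/moment lists IN PLACE (borrowed
// memory); the R trainer owns those lists and never aliases them.

#include <RcppArmadillo.h>
#include <queue>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;
using arma::cube;
using arma::mat;
using arma::vec;

namespace {

struct LayerDef {
  std::string name;
  int k, cin, cout;
  bool relu;
};

// Layer sequence for a given depth/base; must match unet_init_weights() in R.
std::vector<LayerDef> arch_layers(int depth, int base, int in_ch, int n_classes) {
  std::vector<LayerDef> defs;
  std::vector<int> ch(depth + 1);
  for (int l = 1; l <= depth; ++l) ch[l] = base << (l - 1);
  for (int l = 1; l <= depth; ++l) {
    int cin = (l == 1) ? in_ch : ch[l - 1];
    defs.push_back({"enc" + std::to_string(l) + "_conv1", 3, cin, ch[l], true});
    defs.push_back({"enc" + std::to_string(l) + "_conv2", 3, ch[l], ch[l], true});
  }
  for (int l = depth - 1; l >= 1; --l) {
    defs.push_back({"up" + std::to_string(l), 2, ch[l + 1], ch[l], true});
    defs.push_back({"dec" + std::to_string(l) + "_conv1", 3, 2 * ch[l], ch[l], true});
    defs.push_back({"dec" + std::to_string(l) + "_conv2", 3, ch[l], ch[l], true});
  }
  defs.push_back({"final", 1, ch[1], n_classes, false});
  return defs;
}

void im2col(const cube& x, int k, mat& X) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  const int pad_lo = (k - 1) / 2;
  X.zeros(H * W, k * k * C);
  for (int c = 0; c < C; ++c) {
    for (int kx = 0; kx < k; ++kx) {
      for (int ky = 0; ky < k; ++ky) {
        const int col = (c * k + kx) * k + ky;
        const int dr = ky - pad_lo, dc = kx - pad_lo;
        // destination pixel (r,cc) reads source (r+dr, cc+dc)
        const int r0d = std::max(0, -dr), r1d = std::min(H, H - dr) - 1;
        const int c0d = std::max(0, -dc), c1d = std::min(W, W - dc) - 1;
        if (r1d < r0d || c1d < c0d) continue;
        mat view(X.colptr(col), H, W, false, true);
        view.submat(r0d, c0d, r1d, c1d) =
            x.slice(c).submat(r0d + dr, c0d + dc, r1d + dr, c1d + dc);
      }
    }
  }
}

void col2im(const mat& dXcol, int k, cube& dx) {
  const int H = dx.n_rows, W = dx.n_cols, C = dx.n_slices;
  const int pad_lo = (k - 1) / 2;
  dx.zeros();
  for (int c = 0; c < C; ++c) {
    for (int kx = 0; kx < k; ++kx) {
      for (int ky = 0; ky < k; ++ky) {
        const int col = (c * k + kx) * k + ky;
        const int dr = ky - pad_lo, dc = kx - pad_lo;
        const int r0d = std::max(0, -dr), r1d = std::min(H, H - dr) - 1;
        const int c0d = std::max(0, -dc), c1d = std::min(W, W - dc) - 1;
        if (r1d < r0d || c1d < c0d) continue;
        const mat view(const_cast<double*>(dXcol.colptr(col)), H, W, false, true);
        dx.slice(c).submat(r0d + dr, c0d + dc, r1d + dr, c1d + dc) +=
            view.submat(r0d, c0d, r1d, c1d);
      }
    }
  }
}

cube conv_fwd(const cube& x, const mat& W, const vec& b, int k, mat& Xcol) {
  im2col(x, k, Xcol);
  mat Y = Xcol * W;
  Y.each_row() += b.t();
  const int H = x.n_rows, Wd = x.n_cols, cout = W.n_cols;
  cube y(H, Wd, cout);
  std::memcpy(y.memptr(), Y.memptr(), sizeof(double) * Y.n_elem);
  return y;
}

// dy -> (dx, dW, db); Xcol is the cached im2col of the layer input.
cube conv_bwd(const mat& Xcol, const mat& W, int k, const cube& dy,
              int Hin, int Win, int Cin, mat& dW, vec& db) {
  const mat dY(const_cast<double*>(dy.memptr()), dy.n_rows * dy.n_cols,
               dy.n_slices, false, true);
  dW = Xcol.t() * dY;
  db = arma::sum(dY, 0).t();
  mat dXcol = dY * W.t();
  cube dx(Hin, Win, Cin);
  col2im(dXcol, k, dx);
  return dx;
}

cube maxpool_fwd(const cube& x, arma::ucube& amax) {
  const int H2 = x.n_rows / 2, W2 = x.n_cols / 2, C = x.n_slices;
  cube y(H2, W2, C);
  amax.set_size(H2, W2, C);
  for (int c = 0; c < C; ++c)
    for (int j = 0; j < W2; ++j)
      for (int i = 0; i < H2; ++i) {
        double best = -1e300;
        unsigned arg = 0;
        for (int dj = 0; dj < 2; ++dj)
          for (int di = 0; di < 2; ++di) {
            const int r = 2 * i + di, cc = 2 * j + dj;
            const double v = x(r, cc, c);
            if (v > best) { best = v; arg = r + cc * x.n_rows; }
          }
        y(i, j, c) = best;
        amax(i, j, c) = arg;
      }
  return y;
}

cube maxpool_bwd(const cube& dy, const arma::ucube& amax, int H, int W) {
  cube dx(H, W, dy.n_slices, arma::fill::zeros);
  for (arma::uword c = 0; c < dy.n_slices; ++c)
    for (arma::uword j = 0; j < dy.n_cols; ++j)
      for (arma::uword i = 0; i < dy.n_rows; ++i)
        dx.slice(c)(amax(i, j, c)) += dy(i, j, c);
  return dx;
}

cube upsample2(const cube& x) {
  cube y(2 * x.n_rows, 2 * x.n_cols, x.n_slices);
  for (arma::uword c = 0; c < x.n_slices; ++c)
    for (arma::uword j = 0; j < x.n_cols; ++j)
      for (arma::uword i = 0; i < x.n_rows; ++i) {
        const double v = x(i, j, c);
        y(2 * i, 2 * j, c) = v;
        y(2 * i + 1, 2 * j, c) = v;
        y(2 * i, 2 * j + 1, c) = v;
        y(2 * i + 1, 2 * j + 1, c) = v;
      }
  return y;
}

cube upsample2_bwd(const cube& dy) {
  cube dx(dy.n_rows / 2, dy.n_cols / 2, dy.n_slices);
  for (arma::uword c = 0; c < dx.n_slices; ++c)
    for (arma::uword j = 0; j < dx.n_cols; ++j)
      for (arma::uword i = 0; i < dx.n_rows; ++i)
        dx(i, j, c) = dy(2 * i, 2 * j, c) + dy(2 * i + 1, 2 * j, c) +
                      dy(2 * i, 2 * j + 1, c) + dy(2 * i + 1, 2 * j + 1, c);
  return dx;
}

struct Cache {
  cube in;        // layer input (post previous activation)
  cube pre;       // pre-activation output (for ReLU backward)
  mat Xcol;       // im2col of `in`
};

struct FwdState {
  std::vector<Cache> caches;              // one per conv layer, in defs order
  std::vector<cube> enc_out;              // skip sources, enc_out[l-1]
  std::vector<arma::ucube> pool_amax;     // per pooled level
  std::vector<cube> up_in;                // inputs to each upsample (deepest first)
  cube logits;
};

void get_params(const List& weights, const LayerDef& d, mat& W, vec& b) {
  NumericMatrix Wr = weights[d.name + ".W"];
  NumericVector br = weights[d.name + ".b"];
  W = mat(Wr.begin(), Wr.nrow(), Wr.ncol(), false, true);
  b = vec(br.begin(), br.size(), false, true);
}

cube relu(const cube& x) { return arma::clamp(x, 0.0, arma::datum::inf); }

// Full forward pass; caches only filled when want_cache (training).
cube forward_pass(const List& weights, int depth, int base, const mat& x,
                  FwdState* st) {
  const auto defs = arch_layers(depth, base, 1, 2);
  std::map<std::string, const LayerDef*> bynm;
  for (const auto& d : defs) bynm[d.name] = &d;
  if (st) st->caches.resize(defs.size());

  auto run = [&](const cube& in, const std::string& name, int idx) {
    const LayerDef& d = *bynm[name];
    mat W; vec b;
    get_params(weights, d, W, b);
    mat Xcol;
    cube pre = conv_fwd(in, W, b, d.k, Xcol);
    cube out = d.relu ? relu(pre) : pre;
    if (st) {
      st->caches[idx].in = in;
      st->caches[idx].pre = pre;
      st->caches[idx].Xcol = std::move(Xcol);
    }
    return out;
  };

  int idx = 0;
  cube a(x.n_rows, x.n_cols, 1);
  a.slice(0) = x;
  std::vector<cube> enc(depth);
  for (int l = 1; l <= depth; ++l) {
    a = run(a, "enc" + std::to_string(l) + "_conv1", idx++);
    a = run(a, "enc" + std::to_string(l) + "_conv2", idx++);
    enc[l - 1] = a;
    if (l < depth) {
      arma::ucube amax;
      a = maxpool_fwd(a, amax);
      if (st) st->pool_amax.push_back(std::move(amax));
    }
  }
  cube d = enc[depth - 1];
  for (int l = depth - 1; l >= 1; --l) {
    if (st) st->up_in.push_back(d);
    cube u = run(upsample2(d), "up" + std::to_string(l), idx++);
    cube cat(u.n_rows, u.n_cols, u.n_slices + enc[l - 1].n_slices);
    cat.slices(0, u.n_slices - 1) = u;
    cat.slices(u.n_slices, cat.n_slices - 1) = enc[l - 1];
    d = run(cat, "dec" + std::to_string(l) + "_conv1", idx++);
    d = run(d, "dec" + std::to_string(l) + "_conv2", idx++);
  }
  cube logits = run(d, "final", idx++);
  if (st) { st->enc_out = std::move(enc); st->logits = logits; }
  return logits;
}

cube softmax2(const cube& logits) {
  cube p(logits.n_rows, logits.n_cols, logits.n_slices);
  mat m = arma::max(logits.slice(0), logits.slice(1));
  mat e0 = arma::exp(logits.slice(0) - m), e1 = arma::exp(logits.slice(1) - m);
  mat s = e0 + e1;
  p.slice(0) = e0 / s;
  p.slice(1) = e1 / s;
  return p;
}

// Weighted pixel cross-entropy; mask in {0,1}, foreground weight fgw.
double ce_loss(const cube& probs, const arma::umat& mask, double fgw,
               cube* dlogits) {
  const mat w = arma::ones<mat>(mask.n_rows, mask.n_cols) +
                (fgw - 1.0) * arma::conv_to<mat>::from(mask);
  const double wsum = arma::accu(w);
  const mat ym = arma::conv_to<mat>::from(mask);
  mat ptrue = probs.slice(1) % ym + probs.slice(0) % (1.0 - ym);
  double loss = arma::accu(w % (-arma::log(arma::clamp(ptrue, 1e-12, 1.0)))) / wsum;
  if (dlogits) {
    dlogits->set_size(probs.n_rows, probs.n_cols, 2);
    dlogits->slice(0) = w % (probs.slice(0) - (1.0 - ym)) / wsum;
    dlogits->slice(1) = w % (probs.slice(1) - ym) / wsum;
  }
  return loss;
}

void backward_pass(const List& weights, int depth, int base, FwdState& st,
                   const cube& dlogits, std::map<std::string, mat>& dWs,
                   std::map<std::string, vec>& dbs) {
  const auto defs = arch_layers(depth, base, 1, 2);
  std::map<std::string, const LayerDef*> bynm;
  std::map<std::string, int> idx_of;
  for (size_t i = 0; i < defs.size(); ++i) {
    bynm[defs[i].name] = &defs[i];
    idx_of[defs[i].name] = (int)i;
  }

  auto back = [&](const std::string& name, const cube& dy_in) {
    const LayerDef& d = *bynm[name];
    const Cache& c = st.caches[idx_of[name]];
    cube dy = dy_in;
    if (d.relu) {
      for (arma::uword s = 0; s < dy.n_slices; ++s)
        dy.slice(s) %= arma::conv_to<mat>::from(c.pre.slice(s) > 0);
    }
    mat W; vec b;
    get_params(weights, d, W, b);
    mat dW; vec db;
    cube dx = conv_bwd(c.Xcol, W, d.k, dy, c.in.n_rows, c.in.n_cols,
                       c.in.n_slices, dW, db);
    dWs[name] = std::move(dW);
    dbs[name] = std::move(db);
    return dx;
  };

  std::vector<cube> denc(depth);  // grads flowing into enc outputs via skips
  cube d = back("final", dlogits);
  for (int l = 1; l <= depth - 1; ++l) {
    d = back("dec" + std::to_string(l) + "_conv2", d);
    d = back("dec" + std::to_string(l) + "_conv1", d);
    const int cu = (base << (l - 1));  // channels in the up-conv output
    cube du = d.slices(0, cu - 1);
    denc[l - 1] = d.slices(cu, d.n_slices - 1);
    cube dup = back("up" + std::to_string(l), du);
    d = upsample2_bwd(dup);
    // d now matches the resolution of the next-deeper decoder stage
  }
  // deepest encoder output: gradient from decoder chain (+ none, no skip)
  cube g = d;
  for (int l = depth; l >= 1; --l) {
    if (l < depth) {
      g = maxpool_bwd(g, st.pool_amax[l - 1],
                      st.enc_out[l - 1].n_rows, st.enc_out[l - 1].n_cols);
      g += denc[l - 1];
    }
    g = back("enc" + std::to_string(l) + "_conv2", g);
    g = back("enc" + std::to_string(l) + "_conv1", g);
  }
}

}  // namespace

// [[Rcpp::export]]
arma::cube cpp_unet_probs(List weights, int depth, int base,
                          const arma::mat& x) {
  cube logits = forward_pass(weights, depth, base, x, nullptr);
  return softmax2(logits);
}

// [[Rcpp::export]]
double cpp_unet_loss(List weights, int depth, int base, const arma::mat& x,
                     const arma::umat& mask, double fg_weight) {
  cube logits = forward_pass(weights, depth, base, x, nullptr);
  return ce_loss(softmax2(logits), mask, fg_weight, nullptr);
}

// One SGD/Adam step on a single image. Mutates weights, m, v in place.
// [[Rcpp::export]]
double cpp_unet_train_step(List weights, List m, List v, int depth, int base,
                           const arma::mat& x, const arma::umat& mask,
                           double fg_weight, double lr, double beta1,
                           double beta2, double eps, int t) {
  FwdState st;
  forward_pass(weights, depth, base, x, &st);
  cube probs = softmax2(st.logits);
  cube dlogits;
  double loss = ce_loss(probs, mask, fg_weight, &dlogits);
  if (!std::isfinite(loss)) return loss;

  std::map<std::string, mat> dWs;
  std::map<std::string, vec> dbs;
  backward_pass(weights, depth, base, st, dlogits, dWs, dbs);

  const double bc1 = 1.0 - std::pow(beta1, t);
  const double bc2 = 1.0 - std::pow(beta2, t);
  auto adam = [&](double* w, double* mm, double* vv, const double* g, int n) {
    for (int i = 0; i < n; ++i) {
      mm[i] = beta1 * mm[i] + (1 - beta1) * g[i];
      vv[i] = beta2 * vv[i] + (1 - beta2) * g[i] * g[i];
      w[i] -= lr * (mm[i] / bc1) / (std::sqrt(vv[i] / bc2) + eps);
    }
  };
  for (const auto& kv : dWs) {
    NumericMatrix Wr = weights[kv.first + ".W"];
    NumericMatrix mr = m[kv.first + ".W"];
    NumericMatrix vr = v[kv.first + ".W"];
    adam(Wr.begin(), mr.begin(), vr.begin(), kv.second.memptr(), Wr.size());
    NumericVector br = weights[kv.first + ".b"];
    NumericVector mb = m[kv.first + ".b"];
    NumericVector vb = v[kv.first + ".b"];
    adam(br.begin(), mb.begin(), vb.begin(), dbs.at(kv.first).memptr(),
         br.size());
  }
  return loss;
}

// Gradient check helper: loss and all gradients without updating anything.
// [[Rcpp::export]]
List cpp_unet_grads(List weights, int depth, int base, const arma::mat& x,
                    const arma::umat& mask, double fg_weight) {
  FwdState st;
  forward_pass(weights, depth, base, x, &st);
  cube dlogits;
  double loss = ce_loss(softmax2(st.logits), mask, fg_weight, &dlogits);
  std::map<std::string, mat> dWs;
  std::map<std::string, vec> dbs;
  backward_pass(weights, depth, base, st, dlogits, dWs, dbs);
  List out;
  for (const auto& kv : dWs) {
    out[kv.first + ".W"] = wrap(kv.second);
    out[kv.first + ".b"] = wrap(dbs.at(kv.first));
  }
  return List::create(_["loss"] = loss, _["grads"] = out);
}

// Connected components of a binary mask; labels assigned in column-major
// scan order of each component's first-seen pixel (deterministic).
// [[Rcpp::export]]
arma::imat cpp_label_components(const arma::umat& mask, int connectivity) {
  const int H = mask.n_rows, W = mask.n_cols;
  arma::imat lab(H, W, arma::fill::zeros);
  const int n4r[] = {-1, 1, 0, 0}, n4c[] = {0, 0, -1, 1};
  const int n8r[] = {-1, 1, 0, 0, -1, -1, 1, 1}, n8c[] = {0, 0, -1, 1, -1, 1, -1, 1};
  const int* nr = connectivity == 8 ? n8r : n4r;
  const int* nc = connectivity == 8 ? n8c : n4c;
  const int nn = connectivity == 8 ? 8 : 4;
  int next = 0;
  std::queue<std::pair<int, int>> q;
  for (int c = 0; c < W; ++c)
    for (int r = 0; r < H; ++r) {
      if (!mask(r, c) || lab(r, c)) continue;
      lab(r, c) = ++next;
      q.push({r, c});
      while (!q.empty()) {
        auto [cr, cc] = q.front();
        q.pop();
        for (int i = 0; i < nn; ++i) {
          const int rr = cr + nr[i], c2 = cc + nc[i];
          if (rr < 0 || rr >= H || c2 < 0 || c2 >= W) continue;
          if (mask(rr, c2) && !lab(rr, c2)) {
            lab(rr, c2) = next;
            q.push({rr, c2});
          }
        }
      }
    }
  return lab;
}

// For every pixel: index (1-based) of nearest seed, distance to nearest and
// to second-nearest seed. Pixel coordinates are 0-based (x = column).
// [[Rcpp::export]]
List cpp_nearest2(const arma::mat& centers, int height, int width) {
  const int n = centers.n_rows;
  arma::imat idx(height, width);
  mat d1(height, width), d2(height, width);
  for (int c = 0; c < width; ++c)
    for (int r = 0; r < height; ++r) {
      double b1 = 1e300, b2 = 1e300;
      int bi = 0;
      for (int i = 0; i < n; ++i) {
        const double dx = c - centers(i, 0), dy = r - centers(i, 1);
        const double d = dx * dx + dy * dy;
        if (d < b1) { b2 = b1; b1 = d; bi = i + 1; }
        else if (d < b2) { b2 = d; }
      }
      idx(r, c) = bi;
      d1(r, c) = std::sqrt(b1);
      d2(r, c) = n > 1 ? std::sqrt(b2) : arma::datum::inf;
    }
  return List::create(_["index"] = idx, _["d1"] = d1, _["d2"] = d2);
}

// Separable blur with edge replication; kernel must be normalized, odd length.
// [[Rcpp::export]]
arma::mat cpp_sep_blur(const arma::mat& img, const arma::vec& kernel) {
  const int H = img.n_rows, W = img.n_cols, k = kernel.n_elem, h = k / 2;
  mat tmp(H, W), out(H, W);
  for (int c = 0; c < W; ++c)
    for (int r = 0; r < H; ++r) {
      double s = 0;
      for (int i = 0; i < k; ++i) {
        int rr = std::min(std::max(r + i - h, 0), H - 1);
        s += kernel(i) * img(rr, c);
      }
      tmp(r, c) = s;
    }
  for (int c = 0; c < W; ++c)
    for (int r = 0; r < H; ++r) {
      double s = 0;
      for (int i = 0; i < k; ++i) {
        int cc = std::min(std::max(c + i - h, 0), W - 1);
        s += kernel(i) * tmp(r, cc);
      }
      out(r, c) = s;
    }
  return out;
}
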