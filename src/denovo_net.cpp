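// De novo B-scan classifier: 7 conv layers (3x3, pad 1, stride 1), ReLU,
// concatenating skip connections (pool(concat(x_i, c_i)) -> x_{i+1}),
// global average pooling, 2-way softmax.  Single precision; convolution via
// im2col + GEMM.  All entry points are deterministic (no RNG in C++).
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

namespace {

const int KH = 3, KW = 3, KK = KH * KW;

// im2col with zero padding 1: output (KK * C) x (H * W), column j = pixel
// (r, c) in column-major order; row block ch*KK + (dc+1)*KH-col layout below.
fmat im2col_pad1(const fcube& x) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  fmat K(KK * C, (size_t)H * W, fill::zeros);
  for (int ch = 0; ch < C; ++ch) {
    const fmat& sl = x.slice(ch);
    for (int dc = -1; dc <= 1; ++dc) {
      for (int dr = -1; dr <= 1; ++dr) {
        const int krow = ch * KK + (dc + 1) * KH + (dr + 1);
        for (int c = 0; c < W; ++c) {
          const int cc = c + dc;
          if (cc < 0 || cc >= W) continue;
          const int r0 = std::max(0, -dr), r1 = std::min(H, H - dr);
          float* dst = K.colptr((size_t)c * H) ;
          for (int r = r0; r < r1; ++r)
            K((size_t)krow, (size_t)c * H + r) = sl(r + dr, cc);
        }
      }
    }
  }
  return K;
}

// adjoint of im2col_pad1: scatter-add dK back onto an image cube
void col2im_pad1(const fmat& dK, fcube& dx) {
  const int H = dx.n_rows, W = dx.n_cols, C = dx.n_slices;
  for (int ch = 0; ch < C; ++ch) {
    fmat& sl = dx.slice(ch);
    for (int dc = -1; dc <= 1; ++dc) {
      for (int dr = -1; dr <= 1; ++dr) {
        const int krow = ch * KK + (dc + 1) * KH + (dr + 1);
        for (int c = 0; c < W; ++c) {
          const int cc = c + dc;
          if (cc < 0 || cc >= W) continue;
          const int r0 = std::max(0, -dr), r1 = std::min(H, H - dr);
          for (int r = r0; r < r1; ++r)
            sl(r + dr, cc) += dK((size_t)krow, (size_t)c * H + r);
        }
      }
    }
  }
}

// 2x2 max pooling, stride 2, floor semantics (minimum output size 1 so
// degenerate dimensions pass through); argmax recorded as linear indices
// into the input cube for the backward pass
fcube maxpool2(const fcube& x, ucube& argmax) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  const int H2 = std::max(1, H / 2), W2 = std::max(1, W / 2);
  fcube out(H2, W2, C);
  argmax.set_size(H2, W2, C);
  for (int ch = 0; ch < C; ++ch) {
    for (int c = 0; c < W2; ++c) {
      for (int r = 0; r < H2; ++r) {
        const int rr = 2 * r, cc = 2 * c;
        const size_t chOff = (size_t)ch * H * W;
        float best = x(rr, cc, ch);
        uword bi = chOff + (size_t)cc * H + rr;
        const int rmax = std::min(rr + 2, H), cmax = std::min(cc + 2, W);
        for (int c2 = cc; c2 < cmax; ++c2)
          for (int r2 = rr; r2 < rmax; ++r2) {
            const float v = x(r2, c2, ch);
            if (v > best) { best = v; bi = chOff + (size_t)c2 * H + r2; }
          }
        out(r, c, ch) = best;
        argmax(r, c, ch) = bi;
      }
    }
  }
  return out;
}

struct LayerCache {
  fcube x;        // layer input
  fmat  col;      // im2col of x
  fmat  c;        // post-ReLU conv output, f x (H*W)
  fcube cat;      // concat(x, c)
  ucube argmax;   // pooling argmax (empty if not pooled)
  bool  pooled;
};

struct Params {
  std::vector<fmat> W;   // f_i x (9 * ch_in)
  std::vector<fvec> b;
  fmat fcW;              // n_classes x n_channels_final
  fvec fcb;
};

Params unpack(const Rcpp::List& convW, const Rcpp::List& convB,
              const arma::mat& fcW, const arma::vec& fcB) {
  Params p;
  const int L = convW.size();
  for (int i = 0; i < L; ++i) {
    p.W.push_back(conv_to<fmat>::from(Rcpp::as<arma::mat>(convW[i])));
    p.b.push_back(conv_to<fvec>::from(Rcpp::as<arma::vec>(convB[i])));
  }
  p.fcW = conv_to<fmat>::from(fcW);
  p.fcb = conv_to<fvec>::from(fcB);
  return p;
}

fcube concat_channels(const fcube& x, const fmat& c) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices, f = c.n_rows;
  fcube cat(H, W, C + f);
  cat.slices(0, C - 1) = x;
  for (int k = 0; k < f; ++k) {
    fvec ck = c.row(k).t();
    cat.slice(C + k) = reshape(ck, H, W);
  }
  return cat;
}

// forward pass for one image; fills caches if keep = true
void forward_one(const Params& p, const fmat& img,
                 const std::vector<bool>& poolAfter, bool keep,
                 std::vector<LayerCache>& caches, fcube& final_x,
                 fvec& gap, fvec& probs, fvec& logits) {
  const int L = p.W.size();
  fcube x(img.n_rows, img.n_cols, 1);
  x.slice(0) = img;
  caches.clear();
  for (int i = 0; i < L; ++i) {
    LayerCache lc;
    fmat col = im2col_pad1(x);
    fmat pre = p.W[i] * col;
    pre.each_col() += p.b[i];
    pre.transform([](float v) { return v > 0.0f ? v : 0.0f; });  // ReLU
    fcube cat = concat_channels(x, pre);
    lc.pooled = poolAfter[i];
    fcube nx;
    if (lc.pooled) nx = maxpool2(cat, lc.argmax); else nx = cat;
    if (keep) {
      lc.x = std::move(x); lc.col = std::move(col);
      lc.c = std::move(pre); lc.cat = std::move(cat);
      caches.push_back(std::move(lc));
    }
    x = std::move(nx);
  }
  final_x = x;
  const int C = final_x.n_slices;
  gap.set_size(C);
  for (int ch = 0; ch < C; ++ch) gap(ch) = accu(final_x.slice(ch)) / final_x.slice(ch).n_elem;
  logits = p.fcW * gap + p.fcb;
  fvec z = logits - logits.max();
  fvec e = exp(z);
  probs = e / accu(e);
}

}  // namespace

// [[Rcpp::export]]
Rcpp::List cpp_net_forward(Rcpp::List convW, Rcpp::List convB,
                           arma::mat fcW, arma::vec fcB,
                           arma::cube images, Rcpp::LogicalVector poolAfter) {
  Params p = unpack(convW, convB, fcW, fcB);
  std::vector<bool> pool(poolAfter.begin(), poolAfter.end());
  const int N = images.n_slices;
  arma::mat probs(N, p.fcW.n_rows), gaps(N, p.fcW.n_cols);
  std::vector<LayerCache> caches;
  for (int n = 0; n < N; ++n) {
    fmat img = conv_to<fmat>::from(images.slice(n));
    fcube fx; fvec gap, pr, lo;
    forward_one(p, img, pool, false, caches, fx, gap, pr, lo);
    probs.row(n) = conv_to<rowvec>::from(pr);
    gaps.row(n) = conv_to<rowvec>::from(gap);
  }
  return Rcpp::List::create(Rcpp::Named("probs") = probs,
                            Rcpp::Named("gap") = gaps);
}

// [[Rcpp::export]]
arma::cube cpp_net_features(Rcpp::List convW, Rcpp::List convB,
                            arma::mat fcW, arma::vec fcB,
                            arma::mat image, Rcpp::LogicalVector poolAfter) {
  Params p = unpack(convW, convB, fcW, fcB);
  std::vector<bool> pool(poolAfter.begin(), poolAfter.end());
  std::vector<LayerCache> caches;
  fcube fx; fvec gap, pr, lo;
  forward_one(p, conv_to<fmat>::from(image), pool, false, caches, fx, gap, pr, lo);
  return conv_to<cube>::from(fx);
}

// Weighted softmax cross-entropy over a batch: loss_i = -w_i * log p_{y_i},
// with p clipped to [epsClip, 1 - epsClip] for the loss value.  y is 0/1
// (class index); w_i is the per-sample class-balance weight.
// [[Rcpp::export]]
Rcpp::List cpp_net_grad(Rcpp::List convW, Rcpp::List convB,
                        arma::mat fcW, arma::vec fcB,
                        arma::cube images, Rcpp::IntegerVector y,
                        Rcpp::NumericVector sampleW,
                        Rcpp::LogicalVector poolAfter, double epsClip) {
  Params p = unpack(convW, convB, fcW, fcB);
  std::vector<bool> pool(poolAfter.begin(), poolAfter.end());
  const int N = images.n_slices, L = p.W.size();
  std::vector<fmat> dW(L); std::vector<fvec> db(L);
  for (int i = 0; i < L; ++i) {
    dW[i].zeros(size(p.W[i]));
    db[i].zeros(p.b[i].n_elem);
  }
  fmat dfcW(size(p.fcW), fill::zeros);
  fvec dfcb(p.fcb.n_elem, fill::zeros);
  arma::mat probs_out(N, p.fcW.n_rows);
  double loss = 0.0;

  std::vector<LayerCache> caches;
  for (int n = 0; n < N; ++n) {
    fmat img = conv_to<fmat>::from(images.slice(n));
    fcube fx; fvec gap, pr, lo;
    forward_one(p, img, pool, true, caches, fx, gap, pr, lo);
    probs_out.row(n) = conv_to<rowvec>::from(pr);
    const int cls = y[n];
    const float w = (float)sampleW[n];
    double pc = std::min(std::max((double)pr(cls), epsClip), 1.0 - epsClip);
    loss += -(double)w * std::log(pc);

    // softmax + weighted NLL gradient wrt logits
    fvec dlog = pr * w;
    dlog(cls) -= w;
    dfcW += dlog * gap.t();
    dfcb += dlog;
    fvec dgap = p.fcW.t() * dlog;

    // spread GAP gradient over the final tensor
    fcube dx(size(fx));
    const float inv = 1.0f / (fx.n_rows * fx.n_cols);
    for (uword ch = 0; ch < fx.n_slices; ++ch)
      dx.slice(ch).fill(dgap(ch) * inv);

    for (int i = L - 1; i >= 0; --i) {
      LayerCache& lc = caches[i];
      fcube dcat;
      if (lc.pooled) {
        dcat.zeros(size(lc.cat));
        for (uword k = 0; k < lc.argmax.n_elem; ++k)
          dcat(lc.argmax(k)) += dx(k);
      } else {
        dcat = std::move(dx);
      }
      const int C = lc.x.n_slices, f = lc.c.n_rows;
      const int H = lc.x.n_rows, W = lc.x.n_cols;
      // conv branch gradient
      fmat dpre(f, (size_t)H * W);
      for (int k = 0; k < f; ++k)
        dpre.row(k) = conv_to<frowvec>::from(vectorise(dcat.slice(C + k)));
      dpre %= conv_to<fmat>::from(lc.c > 0.0f);  // ReLU mask
      dW[i] += dpre * lc.col.t();
      db[i] += sum(dpre, 1);
      fmat dK = p.W[i].t() * dpre;
      // input gradient: skip branch + conv adjoint
      fcube dxi(H, W, C);
      for (int ch = 0; ch < C; ++ch) dxi.slice(ch) = dcat.slice(ch);
      col2im_pad1(dK, dxi);
      dx = std::move(dxi);
    }
  }

  Rcpp::List gW(L), gb(L);
  for (int i = 0; i < L; ++i) {
    gW[i] = conv_to<arma::mat>::from(dW[i]);
    gb[i] = conv_to<arma::vec>::from(db[i]);
  }
  return Rcpp::List::create(
      Rcpp::Named("loss") = loss,
      Rcpp::Named("probs") = probs_out,
      Rcpp::Named("convW") = gW, Rcpp::Named("convB") = gb,
      Rcpp::Named("fcW") = conv_to<arma::mat>::from(dfcW),
      Rcpp::Named("fcB") = conv_to<arma::vec>::from(dfcb));
}
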