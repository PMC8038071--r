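// Three-branch multimodal CNN on continuous recurrence plots.
//
// Feature maps live as (H*W) x C matrices (pixel-major, one column per
// channel).  A 3x3 same-padding convolution is lowered to one BLAS GEMM per
// pixel chunk via im2col; chunking bounds the im2col buffer so the 476x476
// plots of 30-s windows never allocate more than ~64 MB of scratch.

#include <RcppArmadillo.h>
#include <cstring>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;
using arma::fmat;
using arma::frowvec;
using arma::fvec;
using arma::mat;
using arma::rowvec;
using arma::uvec;
using arma::uword;
using arma::vec;

struct ConvLayer {
  fmat Wmat;  // (9 * c_in) x c_out; row o * c_in + ci = kernel offset o
  frowvec b;
  int c_in, c_out;
};

typedef std::vector<ConvLayer> Branch;

static const double CHUNK_BYTES = 64e6;

static uword chunk_rows_for(uword npix, int K) {
  uword cr = (uword)std::max(4096.0, CHUNK_BYTES / (8.0 * K));
  return std::min(npix, cr);
}

// fill rows [p0, p0 + pr) of the im2col matrix M (pr x 9*c_in) from the
// feature map X ((H*W) x c_in); M must be zeroed (supplies the padding)
static void fill_im2col(const fmat &X, int H, int W, uword p0, uword pr,
                        int c_in, fmat &M) {
  for (int o = 0; o < 9; ++o) {
    int dr = o % 3 - 1, dc = o / 3 - 1;
    int r0 = std::max(0, -dr), r1 = H - 1 - std::max(0, dr);
    int c0 = std::max(0, -dc), c1 = W - 1 - std::max(0, dc);
    if (r1 < r0 || c1 < c0) continue;
    int cstart = std::max((long)c0, (long)(p0 / H));
    int cend = std::min((long)c1, (long)((p0 + pr - 1) / H));
    for (int ci = 0; ci < c_in; ++ci) {
      const float *src = X.colptr(ci);
      float *dstcol = M.colptr((uword)o * c_in + ci);
      for (int c = cstart; c <= cend; ++c) {
        long colbase = (long)c * H;
        int rlo = std::max((long)r0, (long)p0 - colbase);
        int rhi = std::min((long)r1, (long)(p0 + pr - 1) - colbase);
        if (rhi < rlo) continue;
        std::memcpy(dstcol + (colbase + rlo - (long)p0),
                    src + ((rlo + dr) + (long)(c + dc) * H),
                    (size_t)(rhi - rlo + 1) * sizeof(float));
      }
    }
  }
}

// scatter-add rows [p0, p0 + pr) of dM (pr x 9*c_in) back into dX
static void col2im_add(const fmat &dM, int H, int W, uword p0, uword pr,
                       int c_in, fmat &dX) {
  for (int o = 0; o < 9; ++o) {
    int dr = o % 3 - 1, dc = o / 3 - 1;
    int r0 = std::max(0, -dr), r1 = H - 1 - std::max(0, dr);
    int c0 = std::max(0, -dc), c1 = W - 1 - std::max(0, dc);
    if (r1 < r0 || c1 < c0) continue;
    int cstart = std::max((long)c0, (long)(p0 / H));
    int cend = std::min((long)c1, (long)((p0 + pr - 1) / H));
    for (int ci = 0; ci < c_in; ++ci) {
      const float *srccol = dM.colptr((uword)o * c_in + ci);
      float *dst = dX.colptr(ci);
      for (int c = cstart; c <= cend; ++c) {
        long colbase = (long)c * H;
        int rlo = std::max((long)r0, (long)p0 - colbase);
        int rhi = std::min((long)r1, (long)(p0 + pr - 1) - colbase);
        if (rhi < rlo) continue;
        const float *s = srccol + (colbase + rlo - (long)p0);
        float *d = dst + ((rlo + dr) + (long)(c + dc) * H);
        int len = rhi - rlo + 1;
        for (int k = 0; k < len; ++k) d[k] += s[k];
      }
    }
  }
}

static fmat conv_forward(const fmat &X, int H, int W, const ConvLayer &L) {
  uword npix = (uword)H * W;
  int K = 9 * L.c_in;
  fmat Y(npix, (uword)L.c_out);
  uword cr = chunk_rows_for(npix, K);
  fmat M(cr, (uword)K);
  for (uword p0 = 0; p0 < npix; p0 += cr) {
    uword pr = std::min(cr, npix - p0);
    M.zeros();
    fill_im2col(X, H, W, p0, pr, L.c_in, M);
    Y.rows(p0, p0 + pr - 1) = M.rows(0, pr - 1) * L.Wmat;
  }
  Y.each_row() += L.b;
  return Y;
}

// accumulate weight gradients; optionally produce the input gradient
static void conv_backward(const fmat &Xin, const fmat &dY, int H, int W,
                          const ConvLayer &L, ConvLayer &G, fmat *dXin) {
  uword npix = (uword)H * W;
  int K = 9 * L.c_in;
  G.b += arma::sum(dY, 0);
  if (dXin) dXin->zeros(Xin.n_rows, Xin.n_cols);
  uword cr = chunk_rows_for(npix, K);
  fmat M(cr, (uword)K);
  for (uword p0 = 0; p0 < npix; p0 += cr) {
    uword pr = std::min(cr, npix - p0);
    M.zeros();
    fill_im2col(Xin, H, W, p0, pr, L.c_in, M);
    G.Wmat += M.rows(0, pr - 1).t() * dY.rows(p0, p0 + pr - 1);
    if (dXin) {
      fmat dM = dY.rows(p0, p0 + pr - 1) * L.Wmat.t();
      col2im_add(dM, H, W, p0, pr, L.c_in, *dXin);
    }
  }
}

// 2x2 stride-2 max pool (floor); sides < 2 pass through unchanged
static fmat pool_forward(const fmat &X, int H, int W, int &Ho, int &Wo,
                        arma::umat &argmax) {
  Ho = H / 2; Wo = W / 2;
  if (Ho < 1 || Wo < 1) { Ho = H; Wo = W; argmax.reset(); return X; }
  uword C = X.n_cols;
  fmat Y((uword)Ho * Wo, C);
  argmax.set_size((uword)Ho * Wo, C);
  for (uword c = 0; c < C; ++c) {
    const float *xc = X.colptr(c);
    for (int co = 0; co < Wo; ++co)
      for (int ro = 0; ro < Ho; ++ro) {
        uword p00 = (uword)(2 * ro) + (uword)(2 * co) * H;
        uword best = p00;
        float v = xc[p00];
        uword cand[3] = {p00 + 1, p00 + (uword)H, p00 + (uword)H + 1};
        for (int k = 0; k < 3; ++k)
          if (xc[cand[k]] > v) { v = xc[cand[k]]; best = cand[k]; }
        uword po = (uword)ro + (uword)co * Ho;
        Y(po, c) = v;
        argmax(po, c) = best;
      }
  }
  return Y;
}

struct BranchCache {
  std::vector<fmat> conv_in, conv_out;    // per conv layer
  std::vector<int> Hs, Ws;               // grid at each conv layer
  std::vector<arma::umat> pool_arg;      // per block
  std::vector<int> preH, preW;           // grid before each pool
  uvec gmax_arg;
  fvec feat;
};

static fvec branch_forward(const Branch &layers, const IntegerVector &cpb,
                          const mat &img, bool keep, BranchCache &cache) {
  int H = img.n_rows, W = img.n_cols;
  fmat X = arma::conv_to<fmat>::from(img);
  X.reshape((uword)H * W, 1);  // single input channel
  int li = 0;
  if (keep) {
    cache.conv_in.resize(layers.size());
    cache.conv_out.resize(layers.size());
    cache.Hs.resize(layers.size());
    cache.Ws.resize(layers.size());
    cache.pool_arg.resize(cpb.size());
    cache.preH.resize(cpb.size());
    cache.preW.resize(cpb.size());
  }
  for (int b = 0; b < cpb.size(); ++b) {
    for (int k = 0; k < cpb[b]; ++k, ++li) {
      if (keep) { cache.conv_in[li] = X; cache.Hs[li] = H; cache.Ws[li] = W; }
      X = conv_forward(X, H, W, layers[li]);
      X.transform([](float v) { return v > 0.0f ? v : 0.0f; });  // ReLU
      if (keep) cache.conv_out[li] = X;
    }
    if (keep) { cache.preH[b] = H; cache.preW[b] = W; }
    int Ho, Wo;
    arma::umat am;
    X = pool_forward(X, H, W, Ho, Wo, am);
    if (keep) cache.pool_arg[b] = am;
    H = Ho; W = Wo;
  }
  // global max pool over remaining pixels
  uword C = X.n_cols;
  fvec feat(C);
  uvec arg(C);
  for (uword c = 0; c < C; ++c) {
    uword i = X.col(c).index_max();
    arg(c) = i;
    feat(c) = X(i, c);
  }
  if (keep) { cache.gmax_arg = arg; cache.feat = feat; }
  return feat;
}

static void branch_backward(const Branch &layers, const IntegerVector &cpb,
                            const fvec &dfeat, const BranchCache &cache,
                            Branch &grads) {
  int nb = cpb.size();
  int li = (int)layers.size() - 1;
  // through the global max pool
  const fmat &last = cache.conv_out[layers.size() - 1];
  bool pooled = cache.pool_arg[nb - 1].n_elem > 0;
  uword npix_post = pooled
    ? (uword)(cache.preH[nb - 1] / 2) * (cache.preW[nb - 1] / 2)
    : last.n_rows;
  fmat dX(npix_post, last.n_cols, arma::fill::zeros);
  for (uword c = 0; c < dX.n_cols; ++c) dX(cache.gmax_arg(c), c) = dfeat(c);
  for (int b = nb - 1; b >= 0; --b) {
    // through the block's max pool
    if (cache.pool_arg[b].n_elem > 0) {
      uword npre = (uword)cache.preH[b] * cache.preW[b];
      fmat dPre(npre, dX.n_cols, arma::fill::zeros);
      const arma::umat &am = cache.pool_arg[b];
      for (uword c = 0; c < dX.n_cols; ++c)
        for (uword p = 0; p < am.n_rows; ++p)
          dPre(am(p, c), c) += dX(p, c);
      dX = dPre;
    }
    for (int k = cpb[b] - 1; k >= 0; --k, --li) {
      // ReLU mask from stored activations
      dX %= arma::conv_to<fmat>::from(cache.conv_out[li] > 0);
      fmat dIn;
      conv_backward(cache.conv_in[li], dX, cache.Hs[li], cache.Ws[li],
                    layers[li], grads[li], li > 0 ? &dIn : nullptr);
      if (li > 0) dX = std::move(dIn);
    }
  }
}

// ---- R <-> C++ weight conversion -------------------------------------------

static ConvLayer parse_layer(const List &layer) {
  NumericVector Wv = layer["W"];
  NumericVector bv = layer["b"];
  IntegerVector dim = Wv.attr("dim");
  int c_in = dim[2], c_out = dim[3];
  ConvLayer L;
  L.c_in = c_in; L.c_out = c_out;
  L.b = arma::conv_to<frowvec>::from(rowvec(bv.begin(), c_out));
  L.Wmat.set_size((uword)9 * c_in, (uword)c_out);
  for (int o = 0; o < 9; ++o) {
    int dy = o % 3, dx = o / 3;
    for (int co = 0; co < c_out; ++co)
      for (int ci = 0; ci < c_in; ++ci)
        L.Wmat((uword)o * c_in + ci, co) = Wv[dy + 3 * dx + 9 * ci + 9 * c_in * co];
  }
  return L;
}

static Branch parse_branch(const List &branch) {
  Branch out;
  for (int i = 0; i < branch.size(); ++i)
    out.push_back(parse_layer(branch[i]));
  return out;
}

static List layer_to_r(const ConvLayer &L) {
  NumericVector Wv(9 * L.c_in * L.c_out);
  Wv.attr("dim") = IntegerVector::create(3, 3, L.c_in, L.c_out);
  for (int o = 0; o < 9; ++o) {
    int dy = o % 3, dx = o / 3;
    for (int co = 0; co < L.c_out; ++co)
      for (int ci = 0; ci < L.c_in; ++ci)
        Wv[dy + 3 * dx + 9 * ci + 9 * L.c_in * co] = L.Wmat((uword)o * L.c_in + ci, co);
  }
  NumericVector bv(L.b.begin(), L.b.end());
  return List::create(Named("W") = Wv, Named("b") = bv);
}

static List branch_to_r(const Branch &br) {
  List out(br.size());
  for (size_t i = 0; i < br.size(); ++i) out[i] = layer_to_r(br[i]);
  return out;
}

static Branch zero_like(const Branch &br) {
  Branch g = br;
  for (auto &L : g) {
    L.Wmat.zeros();
    L.b.zeros();
  }
  return g;
}

static double sigmoid(double z) { return 1.0 / (1.0 + std::exp(-z)); }

static mat as_mat(SEXP s) {
  NumericMatrix m(s);
  return mat(m.begin(), m.nrow(), m.ncol());  // copy; images are modest
}

// ---- exported entry points -------------------------------------------------

// Forward pass over a list of (fgsr, hgsr, hr) image triples.
// [[Rcpp::export]]
List cnn_forward_cpp(List branches, arma::vec head_w, double head_b,
                     List triples, IntegerVector cpb, bool want_repr) {
  std::vector<Branch> B;
  for (int i = 0; i < 3; ++i) B.push_back(parse_branch(branches[i]));
  int n = triples.size();
  int fd = B[0].back().c_out;
  fvec hw = arma::conv_to<fvec>::from(head_w);
  vec p(n);
  mat repr;
  if (want_repr) repr.set_size(n, 3 * fd);
  BranchCache scratch;
  for (int i = 0; i < n; ++i) {
    List tr = triples[i];
    fvec feat(3 * fd);
    for (int j = 0; j < 3; ++j) {
      mat img = as_mat(tr[j]);
      feat.subvec(j * fd, (j + 1) * fd - 1) =
        branch_forward(B[j], cpb, img, false, scratch);
    }
    if (want_repr) repr.row(i) = arma::conv_to<rowvec>::from(feat);
    p(i) = sigmoid((double)arma::dot(hw, feat) + head_b);
  }
  List out = List::create(Named("p") = NumericVector(p.begin(), p.end()));
  if (want_repr) out["repr"] = wrap(repr);
  return out;
}

// Minibatch SGD training with binary cross-entropy loss.
// `orders` is an epochs x n matrix of 1-based sample indices (one permutation
// per row), generated in R so all randomness is seed-controlled there.
// [[Rcpp::export]]
List cnn_train_cpp(List branches, arma::vec head_w, double head_b,
                   List triples, arma::vec y, double lr, int batch_size,
                   arma::imat orders, IntegerVector cpb, double momentum) {
  std::vector<Branch> B;
  for (int i = 0; i < 3; ++i) B.push_back(parse_branch(branches[i]));
  int n = triples.size();
  int fd = B[0].back().c_out;
  int epochs = orders.n_rows;
  fvec hw = arma::conv_to<fvec>::from(head_w);
  float hb = (float)head_b;
  float flr = (float)lr, fmom = (float)momentum;
  vec loss_trace(epochs, arma::fill::zeros);

  std::vector<Branch> G, V;  // gradient accumulators and momentum buffers
  for (int j = 0; j < 3; ++j) G.push_back(zero_like(B[j]));
  bool use_mom = momentum != 0.0;
  if (use_mom) for (int j = 0; j < 3; ++j) V.push_back(zero_like(B[j]));
  fvec vw(hw.n_elem, arma::fill::zeros);
  float vb = 0.0f;

  std::vector<BranchCache> caches(3);
  for (int e = 0; e < epochs; ++e) {
    double ep_loss = 0.0;
    for (int start = 0; start < n; start += batch_size) {
      int bs = std::min(batch_size, n - start);
      for (int j = 0; j < 3; ++j)
        for (size_t l = 0; l < G[j].size(); ++l) {
          G[j][l].Wmat.zeros();
          G[j][l].b.zeros();
        }
      fvec gw(hw.n_elem, arma::fill::zeros);
      float gb = 0.0f;
      for (int k = 0; k < bs; ++k) {
        int idx = orders(e, start + k) - 1;
        List tr = triples[idx];
        fvec feat(3 * fd);
        for (int j = 0; j < 3; ++j) {
          mat img = as_mat(tr[j]);
          feat.subvec(j * fd, (j + 1) * fd - 1) =
            branch_forward(B[j], cpb, img, true, caches[j]);
        }
        double z = (double)arma::dot(hw, feat) + hb;
        double p = sigmoid(z);
        double pc = std::min(std::max(p, 1e-12), 1.0 - 1e-12);
        ep_loss += -(y(idx) * std::log(pc) + (1.0 - y(idx)) * std::log(1.0 - pc));
        float dz = (float)(p - y(idx));
        gw += dz * feat;
        gb += dz;
        for (int j = 0; j < 3; ++j) {
          fvec dfeat = dz * hw.subvec(j * fd, (j + 1) * fd - 1);
          branch_backward(B[j], cpb, dfeat, caches[j], G[j]);
        }
      }
      float scale = 1.0f / bs;  // mean gradient over the minibatch
      if (use_mom) {
        vw = fmom * vw - flr * scale * gw;
        hw += vw;
        vb = fmom * vb - flr * scale * gb;
        hb += vb;
        for (int j = 0; j < 3; ++j)
          for (size_t l = 0; l < B[j].size(); ++l) {
            V[j][l].Wmat = fmom * V[j][l].Wmat - flr * scale * G[j][l].Wmat;
            B[j][l].Wmat += V[j][l].Wmat;
            V[j][l].b = fmom * V[j][l].b - flr * scale * G[j][l].b;
            B[j][l].b += V[j][l].b;
          }
      } else {
        hw -= flr * scale * gw;
        hb -= flr * scale * gb;
        for (int j = 0; j < 3; ++j)
          for (size_t l = 0; l < B[j].size(); ++l) {
            B[j][l].Wmat -= flr * scale * G[j][l].Wmat;
            B[j][l].b -= flr * scale * G[j][l].b;
          }
      }
      Rcpp::checkUserInterrupt();
    }
    loss_trace(e) = ep_loss / n;
  }
  List rb(3);
  for (int j = 0; j < 3; ++j) rb[j] = branch_to_r(B[j]);
  rb.attr("names") = CharacterVector::create("fgsr", "hgsr", "hr");
  return List::create(
    Named("branches") = rb,
    Named("head_w") = NumericVector(hw.begin(), hw.end()),
    Named("head_b") = (double)hb,
    Named("loss") = NumericVector(loss_trace.begin(), loss_trace.end()));
}
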