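// Fused forward/backward pass of the 1D residual network.
//
// This mirrors the R reference implementation in R/nn.R and R/model.R layer
// for layer (same parameter traversal order, same arithmetic); the test suite
// asserts numerical agreement between the two paths. Activations are
// arma::cube of shape (channels, length, batch), matching R's array layout,
// and convolutions are im2col + one GEMM through the BLAS R links against.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;
using arma::cube;
using arma::mat;
using arma::vec;

static inline int conv_out_len(int L, int k, int stride, int pad) {
  return (L + 2 * pad - k) / stride + 1;
}

// (C, L, B) -> (C * k, L_out * B); row index c + C * j, zero padding
static mat im2col(const cube &X, int k, int stride, int pad) {
  const int C = X.n_rows, L = X.n_cols, B = X.n_slices;
  const int Lo = conv_out_len(L, k, stride, pad);
  mat out(C * k, (size_t)Lo * B, arma::fill::zeros);
  for (int b = 0; b < B; ++b) {
    const mat &S = X.slice(b);
    for (int lo = 0; lo < Lo; ++lo) {
      const int start = lo * stride - pad;
      double *col = out.colptr((size_t)b * Lo + lo);
      for (int j = 0; j < k; ++j) {
        const int pos = start + j;
        if (pos >= 0 && pos < L) {
          std::memcpy(col + (size_t)C * j, S.colptr(pos), C * sizeof(double));
        }
      }
    }
  }
  return out;
}

// adjoint of im2col: scatter-add patch gradients back into (C, L, B)
static cube col2im(const mat &G, int C, int k, int L, int B, int stride,
                   int pad) {
  const int Lo = conv_out_len(L, k, stride, pad);
  cube dX(C, L, B, arma::fill::zeros);
  for (int b = 0; b < B; ++b) {
    mat &S = dX.slice(b);
    for (int lo = 0; lo < Lo; ++lo) {
      const int start = lo * stride - pad;
      const double *col = G.colptr((size_t)b * Lo + lo);
      for (int j = 0; j < k; ++j) {
        const int pos = start + j;
        if (pos >= 0 && pos < L) {
          double *dst = S.colptr(pos);
          const double *src = col + (size_t)C * j;
          for (int c = 0; c < C; ++c) dst[c] += src[c];
        }
      }
    }
  }
  return dX;
}

static const double INV_SQRT2 = 0.7071067811865475244;
static const double INV_SQRT2PI = 0.3989422804014326779;

static inline double phi_cdf(double x) {
  return 0.5 * std::erfc(-x * INV_SQRT2);
}
static inline double phi_pdf(double x) {
  return INV_SQRT2PI * std::exp(-0.5 * x * x);
}

static void gelu_inplace(double *y, const double *x, size_t n) {
  for (size_t i = 0; i < n; ++i) y[i] = x[i] * phi_cdf(x[i]);
}
static void gelu_grad_inplace(double *dx, const double *x, const double *dy,
                              size_t n) {
  for (size_t i = 0; i < n; ++i) {
    dx[i] = dy[i] * (phi_cdf(x[i]) + x[i] * phi_pdf(x[i]));
  }
}

// ---- layer caches ----------------------------------------------------------

struct ConvCache { mat Xc; int C, L, B; };
struct BnCache { mat xhat; vec inv_sd; int C, L, B; bool training; };
struct PoolCache { arma::icube arg; int C, L, B, k, stride, pad, Lo; };

// parameter/buffer streams consumed positionally in the canonical traversal
struct ParamStream {
  const List &params; int i = 0;
  explicit ParamStream(const List &p) : params(p) {}
  mat next_mat() { return as<mat>(params[i++]); }
  vec next_vec() { return as<vec>(params[i++]); }
};

struct Spec {
  int in_channels, input_len, out_dim;
  int stem_channels, stem_kernel, stem_stride, stem_pad;
  int pool_kernel, pool_stride, pool_pad;
  arma::ivec stage_channels, stage_strides;
  int blocks_per_stage;
  arma::ivec head_widths;
  double dropout;
};

static Spec read_spec(const List &s) {
  Spec sp;
  sp.in_channels = as<int>(s["in_channels"]);
  sp.input_len = as<int>(s["input_len"]);
  sp.out_dim = as<int>(s["out_dim"]);
  List stem = s["stem"];
  sp.stem_channels = as<int>(stem["channels"]);
  sp.stem_kernel = as<int>(stem["kernel"]);
  sp.stem_stride = as<int>(stem["stride"]);
  sp.stem_pad = as<int>(stem["pad"]);
  List pool = s["pool"];
  sp.pool_kernel = as<int>(pool["kernel"]);
  sp.pool_stride = as<int>(pool["stride"]);
  sp.pool_pad = as<int>(pool["pad"]);
  sp.stage_channels = as<arma::ivec>(s["stage_channels"]);
  sp.stage_strides = as<arma::ivec>(s["stage_strides"]);
  sp.blocks_per_stage = as<int>(s["blocks_per_stage"]);
  sp.head_widths = as<arma::ivec>(s["head_widths"]);
  sp.dropout = as<double>(s["dropout"]);
  return sp;
}




static cube pool_fw(const cube &X, int k, int stride, int pad,
                    PoolCache &cache) {
  const int C = X.n_rows, L = X.n_cols, B = X.n_slices;
  const int Lo = conv_out_len(L, k, stride, pad);
  cube Y(C, Lo, B);
  cache.arg.set_size(C, Lo, B);
  for (int b = 0; b < B; ++b) {
    for (int lo = 0; lo < Lo; ++lo) {
      const int start = lo * stride - pad;
      for (int c = 0; c < C; ++c) {
        double best = -arma::datum::inf;
        int bestj = 0;
        for (int j = 0; j < k; ++j) {
          const int pos = start + j;
          if (pos >= 0 && pos < L) {
            const double v = X(c, pos, b);
            if (v > best) { best = v; bestj = j; }
          }
        }
        Y(c, lo, b) = best;
        cache.arg(c, lo, b) = bestj;
      }
    }
  }
  cache.C = C; cache.L = L; cache.B = B;
  cache.k = k; cache.stride = stride; cache.pad = pad; cache.Lo = Lo;
  return Y;
}

static cube pool_bw(const PoolCache &cache, const cube &dY) {
  cube dX(cache.C, cache.L, cache.B, arma::fill::zeros);
  for (int b = 0; b < cache.B; ++b) {
    for (int lo = 0; lo < cache.Lo; ++lo) {
      const int start = lo * cache.stride - cache.pad;
      for (int c = 0; c < cache.C; ++c) {
        const int pos = start + cache.arg(c, lo, b);
        if (pos >= 0 && pos < cache.L) dX(c, pos, b) += dY(c, lo, b);
      }
    }
  }
  return dX;
}


struct BlockCache {
  ConvCache c1, c2, cds;
  BnCache b1, b2, bds;
  cube g1x, g2x;           // gelu inputs
  bool has_ds;
  int stride;
};

// ---- full fused pass --------------------------------------------------------

struct Workspace {
  ConvCache stem_conv;
  BnCache stem_bn;
  cube stem_gelu_x;
  PoolCache pool;
  std::vector<BlockCache> blocks;
  std::vector<mat> head_in;      // inputs to each linear
  std::vector<mat> head_gelu_x;  // pre-activation of head GELUs
  std::vector<mat> head_mask;    // dropout masks (scaled)
  mat out_in;
};

static mat bn_backward_mat(const vec &gamma, const BnCache &bc, const mat &dYm,
                           vec &dgamma, vec &dbeta) {
  dgamma = arma::sum(dYm % bc.xhat, 1);
  dbeta = arma::sum(dYm, 1);
  const size_t N = dYm.n_cols;
  mat dX;
  if (bc.training) {
    vec mean_dy = arma::mean(dYm, 1);
    vec mean_dyx = arma::mean(dYm % bc.xhat, 1);
    dX = dYm;
    dX.each_col() -= mean_dy;
    dX -= bc.xhat.each_col() % mean_dyx;
    dX.each_col() %= (gamma % bc.inv_sd);
  } else {
    dX = dYm;
    dX.each_col() %= (gamma % bc.inv_sd);
  }
  return dX;
}

// forward pass shared by training (with caches) and prediction
static mat forward_pass(const Spec &sp, const List &params, List &buffers,
                        const cube &X, bool training,
                        const NumericVector &dropout_draws, Workspace *ws) {
  ParamStream ps(params);
  int bi = 0;
  const double momentum = 0.1, eps = 1e-5;

  // stem
  mat Wstem = ps.next_mat();
  mat Xc = im2col(X, sp.stem_kernel, sp.stem_stride, sp.stem_pad);
  const int L0 = conv_out_len(sp.input_len, sp.stem_kernel, sp.stem_stride,
                              sp.stem_pad);
  mat Hm = Wstem * Xc;
  cube H(Hm.memptr(), sp.stem_channels, L0, X.n_slices);
  if (ws) ws->stem_conv = {std::move(Xc), (int)X.n_rows, (int)X.n_cols,
                           (int)X.n_slices};
  // stem bn (consumes gamma/beta from stream)
  {
    vec gamma = ps.next_vec(), beta = ps.next_vec();
    vec rmean = as<vec>(buffers[bi]), rvar = as<vec>(buffers[bi + 1]);
    const int C = H.n_rows;
    const size_t N = (size_t)H.n_cols * H.n_slices;
    mat Hm2(H.memptr(), C, N, false, true);
    vec mu(C), v(C);
    if (training) {
      mu = arma::mean(Hm2, 1);
      v = arma::mean(Hm2 % Hm2, 1) - mu % mu;
      vec unb = (N > 1) ? vec(v * ((double)N / (N - 1))) : v;
      buffers[bi] = wrap(vec((1 - momentum) * rmean + momentum * mu));
      buffers[bi + 1] = wrap(vec((1 - momentum) * rvar + momentum * unb));
    } else { mu = rmean; v = rvar; }
    vec inv_sd = 1.0 / arma::sqrt(v + eps);
    mat xhat = Hm2;
    xhat.each_col() -= mu;
    xhat.each_col() %= inv_sd;
    mat Ym = xhat;
    Ym.each_col() %= gamma;
    Ym.each_col() += beta;
    std::memcpy(H.memptr(), Ym.memptr(), Ym.n_elem * sizeof(double));
    if (ws) ws->stem_bn = {std::move(xhat), inv_sd, C, (int)H.n_cols,
                           (int)H.n_slices, training};
    bi += 2;
  }
  if (ws) ws->stem_gelu_x = H;
  {
    cube G(H.n_rows, H.n_cols, H.n_slices);
    gelu_inplace(G.memptr(), H.memptr(), H.n_elem);
    H = std::move(G);
  }
  {
    PoolCache pc;
    H = pool_fw(H, sp.pool_kernel, sp.pool_stride, sp.pool_pad, pc);
    if (ws) ws->pool = std::move(pc);
  }

  // residual stages
  int in_ch = sp.stem_channels;
  for (arma::uword s = 0; s < sp.stage_channels.n_elem; ++s) {
    const int out_ch = sp.stage_channels(s);
    for (int b = 0; b < sp.blocks_per_stage; ++b) {
      const int stride = (b == 0) ? (int)sp.stage_strides(s) : 1;
      const bool has_ds = (stride != 1 || in_ch != out_ch);
      BlockCache bc;
      bc.has_ds = has_ds;
      bc.stride = stride;
      const cube Xin = H;   // keep for skip path

      // conv1 + bn1 + gelu
      {
        mat W = ps.next_mat();
        const int L = Xin.n_cols, B = Xin.n_slices;
        const int Lo = conv_out_len(L, 3, stride, 1);
        mat Xc1 = im2col(Xin, 3, stride, 1);
        mat Ym = W * Xc1;
        H = cube(Ym.memptr(), out_ch, Lo, B);
        if (ws) bc.c1 = {std::move(Xc1), in_ch, L, B};
      }
      {
        vec gamma = ps.next_vec(), beta = ps.next_vec();
        vec rmean = as<vec>(buffers[bi]), rvar = as<vec>(buffers[bi + 1]);
        const int C = H.n_rows;
        const size_t N = (size_t)H.n_cols * H.n_slices;
        mat Hm2(H.memptr(), C, N, false, true);
        vec mu(C), v(C);
        if (training) {
          mu = arma::mean(Hm2, 1);
          v = arma::mean(Hm2 % Hm2, 1) - mu % mu;
          vec unb = (N > 1) ? vec(v * ((double)N / (N - 1))) : v;
          buffers[bi] = wrap(vec((1 - momentum) * rmean + momentum * mu));
          buffers[bi + 1] = wrap(vec((1 - momentum) * rvar + momentum * unb));
        } else { mu = rmean; v = rvar; }
        vec inv_sd = 1.0 / arma::sqrt(v + eps);
        mat xhat = Hm2;
        xhat.each_col() -= mu;
        xhat.each_col() %= inv_sd;
        mat Ym = xhat;
        Ym.each_col() %= gamma;
        Ym.each_col() += beta;
        std::memcpy(H.memptr(), Ym.memptr(), Ym.n_elem * sizeof(double));
        if (ws) bc.b1 = {std::move(xhat), inv_sd, C, (int)H.n_cols,
                         (int)H.n_slices, training};
        bi += 2;
      }
      if (ws) bc.g1x = H;
      {
        cube G(H.n_rows, H.n_cols, H.n_slices);
        gelu_inplace(G.memptr(), H.memptr(), H.n_elem);
        H = std::move(G);
      }
      // conv2 + bn2
      {
        mat W = ps.next_mat();
        const int L = H.n_cols, B = H.n_slices;
        const int Lo = conv_out_len(L, 3, 1, 1);
        mat Xc2 = im2col(H, 3, 1, 1);
        mat Ym = W * Xc2;
        cube H2(Ym.memptr(), out_ch, Lo, B);
        if (ws) bc.c2 = {std::move(Xc2), out_ch, L, B};
        H = std::move(H2);
      }
      {
        vec gamma = ps.next_vec(), beta = ps.next_vec();
        vec rmean = as<vec>(buffers[bi]), rvar = as<vec>(buffers[bi + 1]);
        const int C = H.n_rows;
        const size_t N = (size_t)H.n_cols * H.n_slices;
        mat Hm2(H.memptr(), C, N, false, true);
        vec mu(C), v(C);
        if (training) {
          mu = arma::mean(Hm2, 1);
          v = arma::mean(Hm2 % Hm2, 1) - mu % mu;
          vec unb = (N > 1) ? vec(v * ((double)N / (N - 1))) : v;
          buffers[bi] = wrap(vec((1 - momentum) * rmean + momentum * mu));
          buffers[bi + 1] = wrap(vec((1 - momentum) * rvar + momentum * unb));
        } else { mu = rmean; v = rvar; }
        vec inv_sd = 1.0 / arma::sqrt(v + eps);
        mat xhat = Hm2;
        xhat.each_col() -= mu;
        xhat.each_col() %= inv_sd;
        mat Ym = xhat;
        Ym.each_col() %= gamma;
        Ym.each_col() += beta;
        std::memcpy(H.memptr(), Ym.memptr(), Ym.n_elem * sizeof(double));
        if (ws) bc.b2 = {std::move(xhat), inv_sd, C, (int)H.n_cols,
                         (int)H.n_slices, training};
        bi += 2;
      }
      // skip path
      cube shortcut;
      if (has_ds) {
        mat W = ps.next_mat();
        const int L = Xin.n_cols, B = Xin.n_slices;
        const int Lo = conv_out_len(L, 1, stride, 0);
        mat Xcd = im2col(Xin, 1, stride, 0);
        mat Ym = W * Xcd;
        shortcut = cube(Ym.memptr(), out_ch, Lo, B);
        if (ws) bc.cds = {std::move(Xcd), in_ch, L, B};
        vec gamma = ps.next_vec(), beta = ps.next_vec();
        vec rmean = as<vec>(buffers[bi]), rvar = as<vec>(buffers[bi + 1]);
        const int C = shortcut.n_rows;
        const size_t N = (size_t)shortcut.n_cols * shortcut.n_slices;
        mat Hm2(shortcut.memptr(), C, N, false, true);
        vec mu(C), v(C);
        if (training) {
          mu = arma::mean(Hm2, 1);
          v = arma::mean(Hm2 % Hm2, 1) - mu % mu;
          vec unb = (N > 1) ? vec(v * ((double)N / (N - 1))) : v;
          buffers[bi] = wrap(vec((1 - momentum) * rmean + momentum * mu));
          buffers[bi + 1] = wrap(vec((1 - momentum) * rvar + momentum * unb));
        } else { mu = rmean; v = rvar; }
        vec inv_sd = 1.0 / arma::sqrt(v + eps);
        mat xhat = Hm2;
        xhat.each_col() -= mu;
        xhat.each_col() %= inv_sd;
        mat Ym2 = xhat;
        Ym2.each_col() %= gamma;
        Ym2.each_col() += beta;
        std::memcpy(shortcut.memptr(), Ym2.memptr(),
                    Ym2.n_elem * sizeof(double));
        if (ws) bc.bds = {std::move(xhat), inv_sd, C, (int)shortcut.n_cols,
                          (int)shortcut.n_slices, training};
        bi += 2;
      } else {
        shortcut = Xin;
      }
      H += shortcut;
      if (ws) bc.g2x = H;
      {
        cube G(H.n_rows, H.n_cols, H.n_slices);
        gelu_inplace(G.memptr(), H.memptr(), H.n_elem);
        H = std::move(G);
      }
      if (ws) ws->blocks.push_back(std::move(bc));
      in_ch = out_ch;
    }
  }

  // global average pooling over time -> (C, B)
  const int B = H.n_slices;
  mat Z(in_ch, B);
  for (int b = 0; b < B; ++b) Z.col(b) = arma::mean(H.slice(b), 1);

  // head
  size_t draw_at = 0;
  for (arma::uword i = 0; i < sp.head_widths.n_elem; ++i) {
    mat W = ps.next_mat();
    vec bvec = ps.next_vec();
    if (ws) ws->head_in.push_back(Z);
    mat A = W * Z;
    A.each_col() += bvec;
    if (ws) ws->head_gelu_x.push_back(A);
    mat G(A.n_rows, A.n_cols);
    gelu_inplace(G.memptr(), A.memptr(), A.n_elem);
    if (training && sp.dropout > 0) {
      mat maskm(G.n_rows, G.n_cols);
      const double scale = 1.0 / (1.0 - sp.dropout);
      for (size_t j = 0; j < G.n_elem; ++j) {
        maskm(j) = (dropout_draws[draw_at++] >= sp.dropout) ? scale : 0.0;
      }
      G %= maskm;
      if (ws) ws->head_mask.push_back(std::move(maskm));
    } else if (ws) {
      ws->head_mask.push_back(mat());
    }
    Z = std::move(G);
  }
  mat Wout = ps.next_mat();
  vec bout = ps.next_vec();
  if (ws) ws->out_in = Z;
  mat out = Wout * Z;
  out.each_col() += bout;
  return out;
}

// [[Rcpp::export]]
arma::mat cpp_predict(List params, List buffers, arma::cube X, List spec) {
  Spec sp = read_spec(spec);
  NumericVector no_draws(0);
  return forward_pass(sp, params, buffers, X, false, no_draws, nullptr);
}

// [[Rcpp::export]]
List cpp_train_batch(List params, List buffers, arma::cube X, arma::mat Y,
                     List spec, double delta, NumericVector dropout_draws) {
  Spec sp = read_spec(spec);
  Workspace ws;
  mat out = forward_pass(sp, params, buffers, X, true, dropout_draws, &ws);

  // Huber loss on standardized targets, averaged over all elements
  mat E = out - Y;
  const double n_elem = (double)E.n_elem;
  double loss = 0.0;
  mat dOut(E.n_rows, E.n_cols);
  for (size_t i = 0; i < E.n_elem; ++i) {
    const double e = E(i), a = std::fabs(e);
    if (a <= delta) {
      loss += 0.5 * e * e;
      dOut(i) = e / n_elem;
    } else {
      loss += delta * (a - 0.5 * delta);
      dOut(i) = delta * ((e > 0) - (e < 0)) / n_elem;
    }
  }
  loss /= n_elem;

  List grads(params.size());
  auto Wat = [&](int i) { return as<mat>(params[i]); };

  // ---- backward: head -------------------------------------------------------
  int pi = params.size();
  mat dZ;
  {
    pi -= 2;                                // out W, out b
    const mat W = Wat(pi);
    grads[pi + 1] = wrap(vec(arma::sum(dOut, 1)));
    grads[pi] = wrap(mat(dOut * ws.out_in.t()));
    dZ = W.t() * dOut;
  }
  for (int i = (int)sp.head_widths.n_elem - 1; i >= 0; --i) {
    if (ws.head_mask[i].n_elem > 0) dZ %= ws.head_mask[i];
    mat dA(dZ.n_rows, dZ.n_cols);
    gelu_grad_inplace(dA.memptr(), ws.head_gelu_x[i].memptr(), dZ.memptr(),
                      dZ.n_elem);
    pi -= 2;
    const mat W = Wat(pi);
    grads[pi + 1] = wrap(vec(arma::sum(dA, 1)));
    grads[pi] = wrap(mat(dA * ws.head_in[i].t()));
    dZ = W.t() * dA;
  }

  // ---- backward: global average pool ---------------------------------------
  // recover last stage dims from the final block's g2 cache
  const cube &lastg = ws.blocks.back().g2x;
  const int Lc = lastg.n_cols, Bc = lastg.n_slices, Cc = lastg.n_rows;
  cube dH(Cc, Lc, Bc);
  for (int b = 0; b < Bc; ++b) {
    for (int l = 0; l < Lc; ++l) dH.slice(b).col(l) = dZ.col(b) / (double)Lc;
  }

  // ---- backward: residual stages (reverse order) ----------------------------
  // walk parameter indices backwards per block
  std::vector<int> block_param_start;   // start index of each block's params
  {
    int idx = 3;                        // stem conv W + bn gamma/beta
    int in_ch = sp.stem_channels;
    for (arma::uword s = 0; s < sp.stage_channels.n_elem; ++s) {
      const int out_ch = sp.stage_channels(s);
      for (int b = 0; b < sp.blocks_per_stage; ++b) {
        const int stride = (b == 0) ? (int)sp.stage_strides(s) : 1;
        block_param_start.push_back(idx);
        idx += 6;                       // conv1 W, bn1 g/b, conv2 W, bn2 g/b
        if (stride != 1 || in_ch != out_ch) idx += 3;  // ds conv W, ds bn g/b
        in_ch = out_ch;
      }
    }
  }
  for (int bidx = (int)ws.blocks.size() - 1; bidx >= 0; --bidx) {
    BlockCache &bc = ws.blocks[bidx];
    const int p0 = block_param_start[bidx];
    // gelu at the block output
    cube dS(dH.n_rows, dH.n_cols, dH.n_slices);
    gelu_grad_inplace(dS.memptr(), bc.g2x.memptr(), dH.memptr(), dH.n_elem);
    // bn2 backward
    cube dC2;
    {
      const vec gamma = as<vec>(params[p0 + 4]);
      mat dYm(dS.memptr(), dS.n_rows, (size_t)dS.n_cols * dS.n_slices, false,
              true);
      vec dgamma, dbeta;
      mat dXm = bn_backward_mat(gamma, bc.b2, dYm, dgamma, dbeta);
      grads[p0 + 4] = wrap(dgamma);
      grads[p0 + 5] = wrap(dbeta);
      dC2 = cube(dXm.memptr(), dS.n_rows, dS.n_cols, dS.n_slices);
    }
    // conv2 backward
    cube dG1;
    {
      const mat W = Wat(p0 + 3);
      mat dYm(dC2.memptr(), dC2.n_rows, (size_t)dC2.n_cols * dC2.n_slices,
              false, true);
      grads[p0 + 3] = wrap(mat(dYm * bc.c2.Xc.t()));
      mat dXc = W.t() * dYm;
      dG1 = col2im(dXc, bc.c2.C, 3, bc.c2.L, bc.c2.B, 1, 1);
    }
    // gelu after bn1
    cube dB1(dG1.n_rows, dG1.n_cols, dG1.n_slices);
    gelu_grad_inplace(dB1.memptr(), bc.g1x.memptr(), dG1.memptr(),
                      dG1.n_elem);
    // bn1 backward
    cube dC1;
    {
      const vec gamma = as<vec>(params[p0 + 1]);
      mat dYm(dB1.memptr(), dB1.n_rows, (size_t)dB1.n_cols * dB1.n_slices,
              false, true);
      vec dgamma, dbeta;
      mat dXm = bn_backward_mat(gamma, bc.b1, dYm, dgamma, dbeta);
      grads[p0 + 1] = wrap(dgamma);
      grads[p0 + 2] = wrap(dbeta);
      dC1 = cube(dXm.memptr(), dB1.n_rows, dB1.n_cols, dB1.n_slices);
    }
    // conv1 backward
    cube dXmain;
    {
      const mat W = Wat(p0);
      mat dYm(dC1.memptr(), dC1.n_rows, (size_t)dC1.n_cols * dC1.n_slices,
              false, true);
      grads[p0] = wrap(mat(dYm * bc.c1.Xc.t()));
      mat dXc = W.t() * dYm;
      dXmain = col2im(dXc, bc.c1.C, 3, bc.c1.L, bc.c1.B, bc.stride, 1);
    }
    // skip path
    if (bc.has_ds) {
      const vec gamma = as<vec>(params[p0 + 7]);
      mat dYm(dS.memptr(), dS.n_rows, (size_t)dS.n_cols * dS.n_slices, false,
              true);
      vec dgamma, dbeta;
      mat dXm = bn_backward_mat(gamma, bc.bds, dYm, dgamma, dbeta);
      grads[p0 + 7] = wrap(dgamma);
      grads[p0 + 8] = wrap(dbeta);
      const mat W = Wat(p0 + 6);
      grads[p0 + 6] = wrap(mat(dXm * bc.cds.Xc.t()));
      mat dXc = W.t() * dXm;
      cube dXskip = col2im(dXc, bc.cds.C, 1, bc.cds.L, bc.cds.B, bc.stride, 0);
      dH = dXmain + dXskip;
    } else {
      dH = dXmain + dS;
    }
  }

  // ---- backward: stem -------------------------------------------------------
  dH = pool_bw(ws.pool, dH);
  {
    cube dG0(dH.n_rows, dH.n_cols, dH.n_slices);
    gelu_grad_inplace(dG0.memptr(), ws.stem_gelu_x.memptr(), dH.memptr(),
                      dH.n_elem);
    dH = std::move(dG0);
  }
  {
    const vec gamma = as<vec>(params[1]);
    mat dYm(dH.memptr(), dH.n_rows, (size_t)dH.n_cols * dH.n_slices, false,
            true);
    vec dgamma, dbeta;
    mat dXm = bn_backward_mat(gamma, ws.stem_bn, dYm, dgamma, dbeta);
    grads[1] = wrap(dgamma);
    grads[2] = wrap(dbeta);
    mat dW = dXm * ws.stem_conv.Xc.t();
    grads[0] = wrap(dW);
  }

  return List::create(_["loss"] = loss, _["grads"] = grads,
                      _["buffers"] = buffers);
}
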