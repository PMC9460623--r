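#include <RcppArmadillo.h>
#include <vector>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Single-precision training engine for the two-stage planner network:
// three 3x3 'same' convolutions (ReLU, 2x2 max pool after each), batch
// normalization over the final feature maps, flatten, three dense layers,
// mean-absolute-error loss. Feature maps are (channels x pixels) matrices
// with pixel index p = r + c*H (column-major); convolutions are im2col +
// GEMM so the heavy lifting runs through BLAS.
//
// Patch-row ordering inside im2col output: q = ch + Cin*((dr+1) + 3*(dc+1)).

static arma::fmat im2col(const arma::fmat& in, int H, int W) {
  const int Cin = in.n_rows;
  arma::fmat out(9 * Cin, H * W, arma::fill::zeros);
  for (int dc = -1; dc <= 1; ++dc)
    for (int dr = -1; dr <= 1; ++dr) {
      const int q0 = Cin * ((dr + 1) + 3 * (dc + 1));
      for (int c = 0; c < W; ++c) {
        const int cs = c + dc;
        if (cs < 0 || cs >= W) continue;
        const int rlo = std::max(0, -dr), rhi = std::min(H, H - dr);
        for (int r = rlo; r < rhi; ++r) {
          const int p = r + c * H, ps = (r + dr) + cs * H;
          for (int ch = 0; ch < Cin; ++ch)
            out(q0 + ch, p) = in(ch, ps);
        }
      }
    }
  return out;
}

static arma::fmat col2im(const arma::fmat& dcols, int H, int W, int Cin) {
  arma::fmat out(Cin, H * W, arma::fill::zeros);
  for (int dc = -1; dc <= 1; ++dc)
    for (int dr = -1; dr <= 1; ++dr) {
      const int q0 = Cin * ((dr + 1) + 3 * (dc + 1));
      for (int c = 0; c < W; ++c) {
        const int cs = c + dc;
        if (cs < 0 || cs >= W) continue;
        const int rlo = std::max(0, -dr), rhi = std::min(H, H - dr);
        for (int r = rlo; r < rhi; ++r) {
          const int p = r + c * H, ps = (r + dr) + cs * H;
          for (int ch = 0; ch < Cin; ++ch)
            out(ch, ps) += dcols(q0 + ch, p);
        }
      }
    }
  return out;
}

static void relu_(arma::fmat& z) {
  z.for_each([](arma::fmat::elem_type& v) { if (v < 0.0f) v = 0.0f; });
}

static void maxpool(const arma::fmat& in, int H, int W,
                    arma::fmat& out, arma::umat& arg) {
  const int C = in.n_rows, H2 = H / 2, W2 = W / 2;
  out.set_size(C, H2 * W2);
  arg.set_size(C, H2 * W2);
  for (int c2 = 0; c2 < W2; ++c2)
    for (int r2 = 0; r2 < H2; ++r2) {
      const int p2 = r2 + c2 * H2;
      const int ps[4] = {2 * r2 + 2 * c2 * H, 2 * r2 + 1 + 2 * c2 * H,
                         2 * r2 + (2 * c2 + 1) * H,
                         2 * r2 + 1 + (2 * c2 + 1) * H};
      for (int ch = 0; ch < C; ++ch) {
        float best = in(ch, ps[0]);
        int bi = ps[0];
        for (int k = 1; k < 4; ++k)
          if (in(ch, ps[k]) > best) { best = in(ch, ps[k]); bi = ps[k]; }
        out(ch, p2) = best;
        arg(ch, p2) = (arma::uword)bi;
      }
    }
}

// Route pooled-output gradients back to argmax positions; the pooled value
// is max(relu(.)), so gradient flows only where it is strictly positive.
static arma::fmat unpool(const arma::fmat& dpool, const arma::fmat& pooled,
                         const arma::umat& arg, int P) {
  arma::fmat out(dpool.n_rows, P, arma::fill::zeros);
  for (arma::uword c = 0; c < dpool.n_cols; ++c)
    for (arma::uword ch = 0; ch < dpool.n_rows; ++ch)
      if (pooled(ch, c) > 0.0f) out(ch, arg(ch, c)) += dpool(ch, c);
  return out;
}

struct Params {
  arma::fmat W1, W2, W3, Wd1, Wd2, Wd3;
  arma::fvec b1, b2, b3, bd1, bd2, bd3, gamma, beta, rmean, rvar;
};

static arma::fmat getm(const List& p, const char* n) {
  return arma::conv_to<arma::fmat>::from(as<arma::mat>(p[n]));
}
static arma::fvec getv(const List& p, const char* n) {
  return arma::conv_to<arma::fvec>::from(as<arma::vec>(p[n]));
}

static Params load_params(const List& p) {
  Params q;
  q.W1 = getm(p, "W1");   q.b1 = getv(p, "b1");
  q.W2 = getm(p, "W2");   q.b2 = getv(p, "b2");
  q.W3 = getm(p, "W3");   q.b3 = getv(p, "b3");
  q.gamma = getv(p, "gamma"); q.beta = getv(p, "beta");
  q.rmean = getv(p, "run_mean"); q.rvar = getv(p, "run_var");
  q.Wd1 = getm(p, "Wd1"); q.bd1 = getv(p, "bd1");
  q.Wd2 = getm(p, "Wd2"); q.bd2 = getv(p, "bd2");
  q.Wd3 = getm(p, "Wd3"); q.bd3 = getv(p, "bd3");
  return q;
}

struct Shapes {
  int H1, W1, H2, W2, H3, W3, H4, W4, C1, C2, C3, F;
};

static Shapes make_shapes(const Params& q, int H, int W) {
  Shapes s;
  s.H1 = H; s.W1 = W;
  s.H2 = H / 2;    s.W2 = W / 2;
  s.H3 = s.H2 / 2; s.W3 = s.W2 / 2;
  s.H4 = s.H3 / 2; s.W4 = s.W3 / 2;
  s.C1 = q.W1.n_rows; s.C2 = q.W2.n_rows; s.C3 = q.W3.n_rows;
  s.F = s.C3 * s.H4 * s.W4;
  if (s.H4 < 1 || s.W4 < 1)
    stop("input grid too small for three 2x2 pooling stages");
  if ((int)q.Wd1.n_cols != s.F)
    stop("dense layer expects %d features but conv stack yields %d",
         (int)q.Wd1.n_cols, s.F);
  return s;
}

// Conv stack for one sample: input (1 x H*W) row, returns pooled outputs and
// argmax tables (needed for backprop).
struct SampleCache {
  arma::fmat p1, p2, p3;
  arma::umat a1, a2, a3;
};

static void conv_stack(const Params& q, const Shapes& s,
                       const arma::fmat& x0, SampleCache& sc) {
  arma::fmat z1 = q.W1 * im2col(x0, s.H1, s.W1);
  z1.each_col() += q.b1;
  relu_(z1);
  maxpool(z1, s.H1, s.W1, sc.p1, sc.a1);
  arma::fmat z2 = q.W2 * im2col(sc.p1, s.H2, s.W2);
  z2.each_col() += q.b2;
  relu_(z2);
  maxpool(z2, s.H2, s.W2, sc.p2, sc.a2);
  arma::fmat z3 = q.W3 * im2col(sc.p2, s.H3, s.W3);
  z3.each_col() += q.b3;
  relu_(z3);
  maxpool(z3, s.H3, s.W3, sc.p3, sc.a3);
}

static const float BN_EPS = 1e-5f;

// [[Rcpp::export]]
NumericMatrix cpp_cnn_predict(List params, NumericVector x) {
  IntegerVector xd = x.attr("dim");
  if (xd.size() != 3) stop("x must be a (H, W, B) array");
  const int H = xd[0], W = xd[1], B = xd[2];
  Params q = load_params(params);
  Shapes s = make_shapes(q, H, W);
  arma::fvec inv_sd = 1.0f / arma::sqrt(q.rvar + BN_EPS);
  arma::fmat out(q.Wd3.n_rows, B);
  SampleCache sc;
  arma::fmat x0(1, H * W);
  for (int b = 0; b < B; ++b) {
    for (int i = 0; i < H * W; ++i)
      x0(0, i) = (float)x[(R_xlen_t)b * H * W + i];
    conv_stack(q, s, x0, sc);
    arma::fmat xh = sc.p3;
    xh.each_col() -= q.rmean;
    xh.each_col() %= inv_sd;
    xh.each_col() %= q.gamma;
    xh.each_col() += q.beta;
    arma::fvec f = arma::vectorise(xh);
    arma::fvec a4 = q.Wd1 * f + q.bd1;
    a4.for_each([](float& v) { if (v < 0.0f) v = 0.0f; });
    arma::fvec a5 = q.Wd2 * a4 + q.bd2;
    a5.for_each([](float& v) { if (v < 0.0f) v = 0.0f; });
    out.col(b) = q.Wd3 * a5 + q.bd3;
  }
  arma::mat outd = arma::conv_to<arma::mat>::from(out.t());
  return wrap(outd);
}

// [[Rcpp::export]]
List cpp_cnn_grad(List params, NumericVector x, NumericMatrix y) {
  IntegerVector xd = x.attr("dim");
  if (xd.size() != 3) stop("x must be a (H, W, B) array");
  const int H = xd[0], W = xd[1], B = xd[2];
  if (y.nrow() != B) stop("labels must have one row per sample");
  Params q = load_params(params);
  Shapes s = make_shapes(q, H, W);
  const int O = q.Wd3.n_rows;
  if (y.ncol() != O) stop("label width does not match output size");
  const int p4 = s.H4 * s.W4;

  // ---- forward: conv stacks per sample
  std::vector<SampleCache> cache(B);
  arma::fmat x0(1, H * W);
  std::vector<arma::fmat> xs(B);
  for (int b = 0; b < B; ++b) {
    for (int i = 0; i < H * W; ++i)
      x0(0, i) = (float)x[(R_xlen_t)b * H * W + i];
    xs[b] = x0;
    conv_stack(q, s, x0, cache[b]);
  }

  // ---- batch norm over (spatial x batch) per channel
  const double n_bn = (double)p4 * B;
  arma::fvec mu(s.C3, arma::fill::zeros), var(s.C3, arma::fill::zeros);
  for (int b = 0; b < B; ++b) mu += arma::sum(cache[b].p3, 1);
  mu /= (float)n_bn;
  for (int b = 0; b < B; ++b) {
    arma::fmat d = cache[b].p3;
    d.each_col() -= mu;
    var += arma::sum(arma::square(d), 1);
  }
  var /= (float)n_bn;
  arma::fvec inv_sd = 1.0f / arma::sqrt(var + BN_EPS);

  std::vector<arma::fmat> xhat(B);
  arma::fmat Xf(s.F, B);
  for (int b = 0; b < B; ++b) {
    arma::fmat xh = cache[b].p3;
    xh.each_col() -= mu;
    xh.each_col() %= inv_sd;
    xhat[b] = xh;
    arma::fmat yb = xh;
    yb.each_col() %= q.gamma;
    yb.each_col() += q.beta;
    Xf.col(b) = arma::vectorise(yb);
  }

  // ---- dense forward
  arma::fmat A4 = q.Wd1 * Xf;
  A4.each_col() += q.bd1;
  relu_(A4);
  arma::fmat A5 = q.Wd2 * A4;
  A5.each_col() += q.bd2;
  relu_(A5);
  arma::fmat Out = q.Wd3 * A5;
  Out.each_col() += q.bd3;

  arma::fmat Yt(O, B);
  for (int b = 0; b < B; ++b)
    for (int o = 0; o < O; ++o) Yt(o, b) = (float)y(b, o);
  arma::fmat R = Out - Yt;
  const double loss = arma::accu(arma::abs(
      arma::conv_to<arma::mat>::from(R))) / ((double)B * O);

  // ---- backward: MAE subgradient
  arma::fmat dOut = arma::sign(R) / (float)((double)B * O);
  arma::fmat dWd3 = dOut * A5.t();
  arma::fvec dbd3 = arma::sum(dOut, 1);
  arma::fmat dA5 = q.Wd3.t() * dOut;
  dA5.elem(arma::find(A5 <= 0.0f)).zeros();
  arma::fmat dWd2 = dA5 * A4.t();
  arma::fvec dbd2 = arma::sum(dA5, 1);
  arma::fmat dA4 = q.Wd2.t() * dA5;
  dA4.elem(arma::find(A4 <= 0.0f)).zeros();
  arma::fmat dWd1 = dA4 * Xf.t();
  arma::fvec dbd1 = arma::sum(dA4, 1);
  arma::fmat dXf = q.Wd1.t() * dA4;

  // ---- batch-norm backward
  arma::fvec dgamma(s.C3, arma::fill::zeros), dbeta(s.C3, arma::fill::zeros);
  std::vector<arma::fmat> dxhat(B);
  for (int b = 0; b < B; ++b) {
    arma::fmat dyb(dXf.colptr(b), s.C3, p4, true);
    dgamma += arma::sum(dyb % xhat[b], 1);
    dbeta += arma::sum(dyb, 1);
    dyb.each_col() %= q.gamma;
    dxhat[b] = dyb;
  }
  arma::fvec m1(s.C3, arma::fill::zeros), m2(s.C3, arma::fill::zeros);
  for (int b = 0; b < B; ++b) {
    m1 += arma::sum(dxhat[b], 1);
    m2 += arma::sum(dxhat[b] % xhat[b], 1);
  }
  m1 /= (float)n_bn;
  m2 /= (float)n_bn;

  // ---- conv backward per sample
  arma::fmat dW1(arma::size(q.W1), arma::fill::zeros);
  arma::fmat dW2(arma::size(q.W2), arma::fill::zeros);
  arma::fmat dW3(arma::size(q.W3), arma::fill::zeros);
  arma::fvec db1(q.b1.n_elem, arma::fill::zeros);
  arma::fvec db2(q.b2.n_elem, arma::fill::zeros);
  arma::fvec db3(q.b3.n_elem, arma::fill::zeros);
  for (int b = 0; b < B; ++b) {
    arma::fmat dp3 = dxhat[b];
    dp3.each_col() -= m1;
    arma::fmat xm = xhat[b];
    xm.each_col() %= m2;
    dp3 -= xm;
    dp3.each_col() %= inv_sd;

    arma::fmat dz3 = unpool(dp3, cache[b].p3, cache[b].a3, s.H3 * s.W3);
    arma::fmat cols3 = im2col(cache[b].p2, s.H3, s.W3);
    dW3 += dz3 * cols3.t();
    db3 += arma::sum(dz3, 1);
    arma::fmat dp2 = col2im(q.W3.t() * dz3, s.H3, s.W3, s.C2);

    arma::fmat dz2 = unpool(dp2, cache[b].p2, cache[b].a2, s.H2 * s.W2);
    arma::fmat cols2 = im2col(cache[b].p1, s.H2, s.W2);
    dW2 += dz2 * cols2.t();
    db2 += arma::sum(dz2, 1);
    arma::fmat dp1 = col2im(q.W2.t() * dz2, s.H2, s.W2, s.C1);

    arma::fmat dz1 = unpool(dp1, cache[b].p1, cache[b].a1, s.H1 * s.W1);
    arma::fmat cols1 = im2col(xs[b], s.H1, s.W1);
    dW1 += dz1 * cols1.t();
    db1 += arma::sum(dz1, 1);
  }

  List grads = List::create(
    _["W1"] = arma::conv_to<arma::mat>::from(dW1),
    _["b1"] = arma::conv_to<arma::vec>::from(db1),
    _["W2"] = arma::conv_to<arma::mat>::from(dW2),
    _["b2"] = arma::conv_to<arma::vec>::from(db2),
    _["W3"] = arma::conv_to<arma::mat>::from(dW3),
    _["b3"] = arma::conv_to<arma::vec>::from(db3),
    _["gamma"] = arma::conv_to<arma::vec>::from(dgamma),
    _["beta"] = arma::conv_to<arma::vec>::from(dbeta),
    _["Wd1"] = arma::conv_to<arma::mat>::from(dWd1),
    _["bd1"] = arma::conv_to<arma::vec>::from(dbd1),
    _["Wd2"] = arma::conv_to<arma::mat>::from(dWd2),
    _["bd2"] = arma::conv_to<arma::vec>::from(dbd2),
    _["Wd3"] = arma::conv_to<arma::mat>::from(dWd3),
    _["bd3"] = arma::conv_to<arma::vec>::from(dbd3));
  return List::create(_["loss"] = loss, _["grads"] = grads,
                      _["bn_mean"] = arma::conv_to<arma::vec>::from(mu),
                      _["bn_var"] = arma::conv_to<arma::vec>::from(var));
}
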