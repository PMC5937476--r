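// Two-layer 3D convolutional network: conv(9^3, stride 2) -> LeakyReLU ->
// dropout -> conv(5^3) -> LeakyReLU -> maxpool(2^3) -> dropout -> dense(128)
// -> LeakyReLU -> dropout -> dense(n_classes) -> softmax.
//
// Convolutions run as im2col gathers followed by BLAS GEMM; activations are
// stored channels x positions so a layer's output feeds the next layer's
// gather directly.  The compute path is single precision (weights and
// optimizer state stay double on the R side); dropout draws from R's RNG so
// runs are reproducible from set.seed().  Layer sizes come from the `dims`
// list so the same kernels serve non-default architecture specs.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

namespace {

struct Dims {
  int l, k1, s1, c1, o1, np1;
  int k2, s2, c2, o2, np2;
  int pool, o3, np3, flat, d1, nc;
  float alpha;
};

Dims read_dims(const List& d) {
  Dims m;
  m.l = d["l"]; m.k1 = d["k1"]; m.s1 = d["s1"]; m.c1 = d["c1"];
  m.k2 = d["k2"]; m.s2 = d["s2"]; m.c2 = d["c2"];
  m.pool = d["pool"]; m.d1 = d["d1"]; m.nc = d["nc"];
  m.alpha = (float)as<double>(d["alpha"]);
  m.o1 = (m.l - m.k1) / m.s1 + 1;
  m.o2 = (m.o1 - m.k2) / m.s2 + 1;
  m.o3 = m.o2 / m.pool;
  m.np1 = m.o1 * m.o1 * m.o1;
  m.np2 = m.o2 * m.o2 * m.o2;
  m.np3 = m.o3 * m.o3 * m.o3;
  m.flat = m.c2 * m.np3;
  return m;
}

// Linear gather indices mapping an input activation (c_in x l_in^3,
// column-major) onto the im2col patch matrix (c_in*k^3 x l_out^3).
arma::uvec im2col_idx(int l_in, int c_in, int k, int stride, int l_out) {
  const size_t pr = (size_t)c_in * k * k * k;
  const size_t np = (size_t)l_out * l_out * l_out;
  arma::uvec idx(pr * np);
  size_t t = 0;
  for (int zo = 0; zo < l_out; ++zo)
    for (int yo = 0; yo < l_out; ++yo)
      for (int xo = 0; xo < l_out; ++xo) {
        const int x0 = xo * stride, y0 = yo * stride, z0 = zo * stride;
        for (int dz = 0; dz < k; ++dz)
          for (int dy = 0; dy < k; ++dy)
            for (int dx = 0; dx < k; ++dx) {
              const size_t pin = (size_t)(x0 + dx) +
                (size_t)l_in * ((size_t)(y0 + dy) + (size_t)l_in * (z0 + dz));
              for (int c = 0; c < c_in; ++c)
                idx[t++] = (size_t)c + (size_t)c_in * pin;
            }
      }
  return idx;
}

inline arma::fmat gather(const arma::fmat& a, const arma::uvec& idx,
                         size_t pr, size_t np) {
  arma::fmat p(pr, np);
  float* out = p.memptr();
  const float* in = a.memptr();
  const arma::uword* id = idx.memptr();
  const arma::uword n = idx.n_elem;
  for (arma::uword i = 0; i < n; ++i) out[i] = in[id[i]];
  return p;
}

// Scatter-add of the patch-matrix gradient back onto the activation grid.
inline void scatter_add(arma::fmat& acc, const arma::fmat& dP,
                        const arma::uvec& idx) {
  float* out = acc.memptr();
  const float* in = dP.memptr();
  const arma::uword n = idx.n_elem;
  const arma::uword* id = idx.memptr();
  for (arma::uword i = 0; i < n; ++i) out[id[i]] += in[i];
}

inline void leaky_inplace(arma::fmat& z, float alpha) {
  float* p = z.memptr();
  const arma::uword n = z.n_elem;
  for (arma::uword i = 0; i < n; ++i) if (p[i] < 0.0f) p[i] *= alpha;
}

// Max pooling over non-overlapping pool^3 windows; records winner indices.
void maxpool(const arma::fmat& h2, const Dims& m, arma::fmat& h3,
             arma::umat& amax) {
  for (int zq = 0; zq < m.o3; ++zq)
    for (int yq = 0; yq < m.o3; ++yq)
      for (int xq = 0; xq < m.o3; ++xq) {
        const int q = xq + m.o3 * (yq + m.o3 * zq);
        for (int c = 0; c < m.c2; ++c) {
          float best = -std::numeric_limits<float>::infinity();
          int bpos = 0;
          for (int cz = 0; cz < m.pool; ++cz)
            for (int cy = 0; cy < m.pool; ++cy)
              for (int cx = 0; cx < m.pool; ++cx) {
                const int pin = (m.pool * xq + cx) +
                  m.o2 * ((m.pool * yq + cy) + m.o2 * (m.pool * zq + cz));
                const float v = h2(c, pin);
                if (v > best) { best = v; bpos = pin; }
              }
          h3(c, q) = best;
          amax(c, q) = bpos;
        }
      }
}

arma::fvec softmax(const arma::fvec& z) {
  arma::fvec e = arma::exp(z - z.max());
  return e / arma::accu(e);
}

struct Params {
  arma::fmat W1, W2, W3, W4;
  arma::fvec b1, b2, b3, b4;
};

Params read_params(const List& p) {
  Params w;
  w.W1 = arma::conv_to<arma::fmat>::from(as<arma::mat>(p["W1"]));
  w.b1 = arma::conv_to<arma::fvec>::from(as<arma::vec>(p["b1"]));
  w.W2 = arma::conv_to<arma::fmat>::from(as<arma::mat>(p["W2"]));
  w.b2 = arma::conv_to<arma::fvec>::from(as<arma::vec>(p["b2"]));
  w.W3 = arma::conv_to<arma::fmat>::from(as<arma::mat>(p["W3"]));
  w.b3 = arma::conv_to<arma::fvec>::from(as<arma::vec>(p["b3"]));
  w.W4 = arma::conv_to<arma::fmat>::from(as<arma::mat>(p["W4"]));
  w.b4 = arma::conv_to<arma::fvec>::from(as<arma::vec>(p["b4"]));
  return w;
}

arma::fmat draw_keep_mask(int nr, int nc_, double rate) {
  arma::fmat mk(nr, nc_);
  const float keep = 1.0f - (float)rate;
  float* p = mk.memptr();
  for (arma::uword i = 0; i < mk.n_elem; ++i)
    p[i] = (R::unif_rand() >= rate) ? 1.0f / keep : 0.0f;
  return mk;
}

} // namespace

//' @noRd
// [[Rcpp::export(name = ".cnn_forward_cpp")]]
arma::mat cnn_forward_cpp(const arma::mat& X, const List& params,
                          const List& dims) {
  const Dims m = read_dims(dims);
  const Params w = read_params(params);
  const arma::uvec idx1 = im2col_idx(m.l, 1, m.k1, m.s1, m.o1);
  const arma::uvec idx2 = im2col_idx(m.o1, m.c1, m.k2, m.s2, m.o2);
  const arma::fmat Xf = arma::conv_to<arma::fmat>::from(X);
  const int n = Xf.n_rows;
  arma::mat probs(n, m.nc);
  arma::fmat h3(m.c2, m.np3);
  arma::umat amax(m.c2, m.np3);
  for (int s = 0; s < n; ++s) {
    arma::fmat x = arma::reshape(Xf.row(s).t(), 1, Xf.n_cols);
    arma::fmat P1 = gather(x, idx1, (size_t)m.k1 * m.k1 * m.k1, m.np1);
    arma::fmat H1 = w.W1 * P1;
    H1.each_col() += w.b1;
    leaky_inplace(H1, m.alpha);
    arma::fmat P2 = gather(H1, idx2, (size_t)m.c1 * m.k2 * m.k2 * m.k2, m.np2);
    arma::fmat H2 = w.W2 * P2;
    H2.each_col() += w.b2;
    leaky_inplace(H2, m.alpha);
    maxpool(H2, m, h3, amax);
    arma::fvec v = arma::vectorise(h3);
    arma::fvec z3 = w.W3 * v + w.b3;
    { arma::fmat tmp(z3.memptr(), z3.n_elem, 1, false); leaky_inplace(tmp, m.alpha); }
    probs.row(s) = arma::conv_to<arma::rowvec>::from(
      softmax(w.W4 * z3 + w.b4).t());
  }
  return probs;
}

//' @noRd
// [[Rcpp::export(name = ".cnn_backprop_cpp")]]
List cnn_backprop_cpp(const arma::mat& X, const arma::mat& Y,
                      const arma::vec& class_weights, const List& params,
                      const List& dims, const arma::vec& dropout_rates,
                      const double l2) {
  const Dims m = read_dims(dims);
  const Params w = read_params(params);
  const arma::uvec idx1 = im2col_idx(m.l, 1, m.k1, m.s1, m.o1);
  const arma::uvec idx2 = im2col_idx(m.o1, m.c1, m.k2, m.s2, m.o2);
  const arma::fmat Xf = arma::conv_to<arma::fmat>::from(X);
  const int n = Xf.n_rows;

  arma::fmat gW1(arma::size(w.W1), arma::fill::zeros);
  arma::fmat gW2(arma::size(w.W2), arma::fill::zeros);
  arma::fmat gW3(arma::size(w.W3), arma::fill::zeros);
  arma::fmat gW4(arma::size(w.W4), arma::fill::zeros);
  arma::fvec gb1(arma::size(w.b1), arma::fill::zeros);
  arma::fvec gb2(arma::size(w.b2), arma::fill::zeros);
  arma::fvec gb3(arma::size(w.b3), arma::fill::zeros);
  arma::fvec gb4(arma::size(w.b4), arma::fill::zeros);

  double loss = 0.0;
  arma::mat probs(n, m.nc);
  arma::fmat h3(m.c2, m.np3);
  arma::umat amax(m.c2, m.np3);

  for (int s = 0; s < n; ++s) {
    // ---- forward with dropout ----
    arma::fmat x = arma::reshape(Xf.row(s).t(), 1, Xf.n_cols);
    arma::fmat P1 = gather(x, idx1, (size_t)m.k1 * m.k1 * m.k1, m.np1);
    arma::fmat Z1 = w.W1 * P1;
    Z1.each_col() += w.b1;
    arma::fmat H1 = Z1;
    leaky_inplace(H1, m.alpha);
    arma::fmat M1 = draw_keep_mask(m.c1, m.np1, dropout_rates[0]);
    H1 %= M1;

    arma::fmat P2 = gather(H1, idx2, (size_t)m.c1 * m.k2 * m.k2 * m.k2, m.np2);
    arma::fmat Z2 = w.W2 * P2;
    Z2.each_col() += w.b2;
    arma::fmat H2 = Z2;
    leaky_inplace(H2, m.alpha);
    maxpool(H2, m, h3, amax);
    arma::fmat M2 = draw_keep_mask(m.c2, m.np3, dropout_rates[1]);
    arma::fmat H3d = h3 % M2;

    arma::fvec v = arma::vectorise(H3d);
    arma::fvec z3 = w.W3 * v + w.b3;
    arma::fvec h4 = z3;
    { arma::fmat tmp(h4.memptr(), h4.n_elem, 1, false); leaky_inplace(tmp, m.alpha); }
    arma::fvec M3 = arma::vectorise(draw_keep_mask(m.d1, 1, dropout_rates[2]));
    arma::fvec h4d = h4 % M3;
    arma::fvec p = softmax(w.W4 * h4d + w.b4);
    probs.row(s) = arma::conv_to<arma::rowvec>::from(p.t());

    const arma::uword t = arma::index_max(Y.row(s));
    const float wt = (float)class_weights[t];
    loss += -(double)wt * std::log(std::max((double)p[t], 1e-12)) / n;

    // ---- backward ----
    arma::fvec y = arma::conv_to<arma::fvec>::from(Y.row(s).t());
    arma::fvec dlogit = (wt / n) * (p - y);
    gW4 += dlogit * h4d.t();
    gb4 += dlogit;
    arma::fvec dh4 = (w.W4.t() * dlogit) % M3;
    for (arma::uword i = 0; i < dh4.n_elem; ++i)
      if (z3[i] <= 0.0f) dh4[i] *= m.alpha;
    gW3 += dh4 * v.t();
    gb3 += dh4;
    arma::fvec dv = w.W3.t() * dh4;
    arma::fmat dH3 = arma::reshape(dv, m.c2, m.np3) % M2;

    // unpool: route gradient to the max winner, through LeakyReLU of Z2
    arma::fmat dZ2(m.c2, m.np2, arma::fill::zeros);
    for (int q = 0; q < m.np3; ++q)
      for (int c = 0; c < m.c2; ++c) {
        const int pin = amax(c, q);
        float g = dH3(c, q);
        if (Z2(c, pin) <= 0.0f) g *= m.alpha;
        dZ2(c, pin) += g;
      }
    gW2 += dZ2 * P2.t();
    gb2 += arma::sum(dZ2, 1);
    arma::fmat dP2 = w.W2.t() * dZ2;
    arma::fmat dH1(m.c1, m.np1, arma::fill::zeros);
    scatter_add(dH1, dP2, idx2);
    dH1 %= M1;
    {
      const float* z1p = Z1.memptr();
      float* d1p = dH1.memptr();
      for (arma::uword i = 0; i < dH1.n_elem; ++i)
        if (z1p[i] <= 0.0f) d1p[i] *= m.alpha;
    }
    gW1 += dH1 * P1.t();
    gb1 += arma::sum(dH1, 1);
  }

  // L2 penalty on kernels only (not biases)
  loss += l2 * (arma::accu(arma::square(w.W1)) + arma::accu(arma::square(w.W2)) +
                arma::accu(arma::square(w.W3)) + arma::accu(arma::square(w.W4)));
  const float l2f = (float)l2;
  gW1 += 2.0f * l2f * w.W1;
  gW2 += 2.0f * l2f * w.W2;
  gW3 += 2.0f * l2f * w.W3;
  gW4 += 2.0f * l2f * w.W4;

  auto dm = [](const arma::fmat& a) {
    return arma::conv_to<arma::mat>::from(a);
  };
  auto dvv = [](const arma::fvec& a) {
    return arma::conv_to<arma::vec>::from(a);
  };
  return List::create(
    _["loss"] = loss, _["probs"] = probs,
    _["gW1"] = dm(gW1), _["gb1"] = dvv(gb1), _["gW2"] = dm(gW2),
    _["gb2"] = dvv(gb2), _["gW3"] = dm(gW3), _["gb3"] = dvv(gb3),
    _["gW4"] = dm(gW4), _["gb4"] = dvv(gb4));
}

// Single-pass isolated-voxel removal: clear occupied voxels that have no
// occupied neighbor under 6/18/26-connectivity.
//' @noRd
// [[Rcpp::export(name = ".remove_isolated_cpp")]]
IntegerVector remove_isolated_cpp(const IntegerVector& grid, const int l,
                                  const int connectivity) {
  IntegerVector out(clone(grid));
  auto at = [&](int x, int y, int z) -> int {
    return grid[x + l * (y + l * z)];
  };
  for (int z = 0; z < l; ++z)
    for (int y = 0; y < l; ++y)
      for (int x = 0; x < l; ++x) {
        if (!at(x, y, z)) continue;
        bool has = false;
        for (int dz = -1; dz <= 1 && !has; ++dz)
          for (int dy = -1; dy <= 1 && !has; ++dy)
            for (int dx = -1; dx <= 1 && !has; ++dx) {
              const int man = std::abs(dx) + std::abs(dy) + std::abs(dz);
              if (man == 0) continue;
              if (connectivity == 6 && man > 1) continue;
              if (connectivity == 18 && man > 2) continue;
              const int nx = x + dx, ny = y + dy, nz = z + dz;
              if (nx < 0 || ny < 0 || nz < 0 || nx >= l || ny >= l || nz >= l)
                continue;
              if (at(nx, ny, nz)) has = true;
            }
        if (!has) out[x + l * (y + l * z)] = 0;
      }
  return out;
}
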