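#include <Rcpp.h>
using namespace Rcpp;

// Pixel layout: one video frame is a column of the pixel matrix, stored
// plane-major (all of channel 1, then channel 2, ...), column-major within
// a plane (row index fastest), i.e. linear index = r + c*h + ch*h*w.

// Render disk-shaped flies on a flat background. Jitter offsets are
// precomputed in R (one row per fly, one column per frame) so all
// randomness stays under R's RNG. flash_frame is 1-based; 0 means none.
// [[Rcpp::export]]
IntegerMatrix cpp_render(int h, int w, int n, int channels,
                         IntegerVector bg_level, IntegerVector fly_level,
                         IntegerVector disk_dr, IntegerVector disk_dc,
                         IntegerVector anchor_r, IntegerVector anchor_c,
                         IntegerMatrix jit_r, IntegerMatrix jit_c,
                         int flash_frame, IntegerVector flash_shift) {
  const int hw = h * w;
  const int npx = hw * channels;
  const int k = anchor_r.size();
  const int nd = disk_dr.size();
  IntegerMatrix M(npx, n);
  int* m = INTEGER(M);

  for (int t = 0; t < n; ++t) {
    int* col = m + (R_xlen_t)t * npx;
    bool flashed = flash_frame > 0 && t >= flash_frame - 1;
    for (int ch = 0; ch < channels; ++ch) {
      int v = bg_level[ch];
      if (flashed) {
        v += flash_shift[ch];
        if (v < 0) v = 0; else if (v > 255) v = 255;
      }
      std::fill(col + ch * hw, col + (ch + 1) * hw, v);
    }
    for (int f = 0; f < k; ++f) {
      int cr = anchor_r[f] - 1 + jit_r(f, t);
      int cc = anchor_c[f] - 1 + jit_c(f, t);
      for (int ch = 0; ch < channels; ++ch) {
        int v = fly_level[ch];
        if (flashed) {
          v += flash_shift[ch];
          if (v < 0) v = 0; else if (v > 255) v = 255;
        }
        int off = ch * hw;
        for (int d = 0; d < nd; ++d) {
          int r = cr + disk_dr[d];
          int c = cc + disk_dc[d];
          if (r >= 0 && r < h && c >= 0 && c < w) col[off + r + c * h] = v;
        }
      }
    }
  }
  return M;
}

// In-place salt-and-pepper noise: per frame, n_salt + n_pepper distinct
// pixel sites (all channels of a site set together), positions drawn from
// R's RNG for reproducibility. Salt (=255) first, then pepper (=0).
// [[Rcpp::export]]
void cpp_sp_noise(IntegerMatrix M, int h, int w, int channels,
                  int n_salt, int n_pepper) {
  const int hw = h * w;
  const int npx = hw * channels;
  const int n = M.ncol();
  const int nn = n_salt + n_pepper;
  if (nn == 0) return;
  int* m = INTEGER(M);
  std::vector<int> pick(nn);
  std::vector<char> used(hw);
  GetRNGstate();
  for (int t = 0; t < n; ++t) {
    std::fill(used.begin(), used.end(), 0);
    int got = 0;
    while (got < nn) {
      int p = (int)(unif_rand() * hw);
      if (p >= hw) continue;
      if (!used[p]) { used[p] = 1; pick[got++] = p; }
    }
    int* col = m + (R_xlen_t)t * npx;
    for (int i = 0; i < nn; ++i) {
      int v = i < n_salt ? 255 : 0;
      for (int ch = 0; ch < channels; ++ch) col[ch * hw + pick[i]] = v;
    }
  }
  PutRNGstate();
}

// Mean absolute grayscale difference between frames t and t-stride over a
// fixed set of pixel sites (0-based within-plane indices). Grayscale is
// the weighted channel sum (luma weights for RGB, weight 1 for gray).
// [[Rcpp::export]]
NumericVector cpp_region_trace(IntegerMatrix M, IntegerVector idx0,
                               int hw, int channels, NumericVector weights,
                               int stride) {
  const int n = M.ncol();
  const int m = idx0.size();
  const int npx = hw * channels;
  if (n <= stride) stop("need more than 'stride' frames");
  const int* px = INTEGER(M);
  NumericVector out(n - stride);
  for (int t = stride; t < n; ++t) {
    const int* a = px + (R_xlen_t)(t - stride) * npx;
    const int* b = px + (R_xlen_t)t * npx;
    double acc = 0.0;
    for (int i = 0; i < m; ++i) {
      int p = idx0[i];
      double ga = 0.0, gb = 0.0;
      for (int ch = 0; ch < channels; ++ch) {
        ga += weights[ch] * a[ch * hw + p];
        gb += weights[ch] * b[ch * hw + p];
      }
      acc += std::fabs(gb - ga);
    }
    out[t - stride] = acc / m;
  }
  return out;
}

// Per-frame mean of each channel over a fixed set of pixel sites.
// [[Rcpp::export]]
NumericMatrix cpp_region_channel_means(IntegerMatrix M, IntegerVector idx0,
                                       int hw, int channels) {
  const int n = M.ncol();
  const int m = idx0.size();
  const int npx = hw * channels;
  const int* px = INTEGER(M);
  NumericMatrix out(n, channels);
  for (int t = 0; t < n; ++t) {
    const int* col = px + (R_xlen_t)t * npx;
    for (int ch = 0; ch < channels; ++ch) {
      double acc = 0.0;
      const int* pl = col + ch * hw;
      for (int i = 0; i < m; ++i) acc += pl[idx0[i]];
      out(t, ch) = acc / m;
    }
  }
  return out;
}
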