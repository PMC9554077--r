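#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

static inline int lin(int i, int j, int k, int nx, int ny) {
  return i + nx * (j + ny * k);
}

// Label connected components of a binary 3D array (column-major, dims nx,ny,nz).
// connectivity: 6 or 26. Returns integer labels, 0 = background.
// [[Rcpp::export]]
IntegerVector cpp_label_components(IntegerVector mask, IntegerVector dims,
                                   int connectivity) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  int n = nx * ny * nz;
  IntegerVector lab(n, 0);
  std::vector<int> offs_i, offs_j, offs_k;
  for (int dk = -1; dk <= 1; ++dk)
    for (int dj = -1; dj <= 1; ++dj)
      for (int di = -1; di <= 1; ++di) {
        if (di == 0 && dj == 0 && dk == 0) continue;
        int ad = std::abs(di) + std::abs(dj) + std::abs(dk);
        if (connectivity == 6 && ad != 1) continue;
        offs_i.push_back(di); offs_j.push_back(dj); offs_k.push_back(dk);
      }
  int noff = offs_i.size();
  std::vector<int> stack;
  int next_label = 0;
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        int v = lin(i, j, k, nx, ny);
        if (!mask[v] || lab[v]) continue;
        ++next_label;
        lab[v] = next_label;
        stack.clear();
        stack.push_back(v);
        while (!stack.empty()) {
          int cur = stack.back(); stack.pop_back();
          int ci = cur % nx, cj = (cur / nx) % ny, ck = cur / (nx * ny);
          for (int o = 0; o < noff; ++o) {
            int ii = ci + offs_i[o], jj = cj + offs_j[o], kk = ck + offs_k[o];
            if (ii < 0 || jj < 0 || kk < 0 || ii >= nx || jj >= ny || kk >= nz)
              continue;
            int w = lin(ii, jj, kk, nx, ny);
            if (mask[w] && !lab[w]) { lab[w] = next_label; stack.push_back(w); }
          }
        }
      }
  return lab;
}

// Fill interior holes slice-by-slice (slices along the 3rd dim): background
// is flood-filled 4-connected from the slice border; unreached zeros become 1.
// [[Rcpp::export]]
IntegerVector cpp_fill_holes_2d(IntegerVector mask, IntegerVector dims) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  IntegerVector out = clone(mask);
  std::vector<char> reach((size_t)nx * ny);
  std::vector<int> stack;
  for (int k = 0; k < nz; ++k) {
    std::fill(reach.begin(), reach.end(), 0);
    stack.clear();
    int base = nx * ny * k;
    for (int i = 0; i < nx; ++i) {
      for (int j : {0, ny - 1}) {
        int v = i + nx * j;
        if (!mask[base + v] && !reach[v]) { reach[v] = 1; stack.push_back(v); }
      }
    }
    for (int j = 0; j < ny; ++j) {
      for (int i : {0, nx - 1}) {
        int v = i + nx * j;
        if (!mask[base + v] && !reach[v]) { reach[v] = 1; stack.push_back(v); }
      }
    }
    while (!stack.empty()) {
      int cur = stack.back(); stack.pop_back();
      int ci = cur % nx, cj = cur / nx;
      const int di[4] = {1, -1, 0, 0}, dj[4] = {0, 0, 1, -1};
      for (int o = 0; o < 4; ++o) {
        int ii = ci + di[o], jj = cj + dj[o];
        if (ii < 0 || jj < 0 || ii >= nx || jj >= ny) continue;
        int w = ii + nx * jj;
        if (!mask[base + w] && !reach[w]) { reach[w] = 1; stack.push_back(w); }
      }
    }
    for (int v = 0; v < nx * ny; ++v)
      if (!mask[base + v] && !reach[v]) out[base + v] = 1;
  }
  return out;
}

// Binary dilation/erosion with an arbitrary offset neighbourhood (m x 3,
// voxel offsets). Outside the array counts as background; callers that need
// exact closing semantics pad the array first.
// [[Rcpp::export]]
IntegerVector cpp_binary_morph(IntegerVector mask, IntegerVector dims,
                               IntegerMatrix offsets, bool dilate) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  int n = nx * ny * nz, m = offsets.nrow();
  IntegerVector out(n);
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        int v = lin(i, j, k, nx, ny);
        bool any = false, all = true;
        for (int o = 0; o < m; ++o) {
          int ii = i + offsets(o, 0), jj = j + offsets(o, 1),
              kk = k + offsets(o, 2);
          bool val = false;
          if (ii >= 0 && jj >= 0 && kk >= 0 && ii < nx && jj < ny && kk < nz)
            val = mask[lin(ii, jj, kk, nx, ny)] != 0;
          if (val) any = true; else all = false;
          if (dilate && any) break;
          if (!dilate && !all) break;
        }
        out[v] = dilate ? (any ? 1 : 0) : (all ? 1 : 0);
      }
  return out;
}

// Trilinear interpolation of a 3D volume at 0-based fractional coordinates.
// Samples outside the grid return `background`.
// [[Rcpp::export]]
NumericVector cpp_trilinear(NumericVector vol, IntegerVector dims,
                            NumericVector xs, NumericVector ys,
                            NumericVector zs, double background) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  int n = xs.size();
  NumericVector out(n);
  for (int v = 0; v < n; ++v) {
    double x = xs[v], y = ys[v], z = zs[v];
    if (x < 0 || y < 0 || z < 0 || x > nx - 1 || y > ny - 1 || z > nz - 1) {
      out[v] = background;
      continue;
    }
    int i0 = (int)std::floor(x), j0 = (int)std::floor(y),
        k0 = (int)std::floor(z);
    if (i0 == nx - 1) --i0;
    if (j0 == ny - 1) --j0;
    if (k0 == nz - 1) --k0;
    if (nx == 1) i0 = 0;
    if (ny == 1) j0 = 0;
    if (nz == 1) k0 = 0;
    double tx = x - i0, ty = y - j0, tz = z - k0;
    int i1 = std::min(i0 + 1, nx - 1), j1 = std::min(j0 + 1, ny - 1),
        k1 = std::min(k0 + 1, nz - 1);
    double c000 = vol[lin(i0, j0, k0, nx, ny)], c100 = vol[lin(i1, j0, k0, nx, ny)];
    double c010 = vol[lin(i0, j1, k0, nx, ny)], c110 = vol[lin(i1, j1, k0, nx, ny)];
    double c001 = vol[lin(i0, j0, k1, nx, ny)], c101 = vol[lin(i1, j0, k1, nx, ny)];
    double c011 = vol[lin(i0, j1, k1, nx, ny)], c111 = vol[lin(i1, j1, k1, nx, ny)];
    double c00 = c000 * (1 - tx) + c100 * tx, c10 = c010 * (1 - tx) + c110 * tx;
    double c01 = c001 * (1 - tx) + c101 * tx, c11 = c011 * (1 - tx) + c111 * tx;
    double c0 = c00 * (1 - ty) + c10 * ty, c1 = c01 * (1 - ty) + c11 * ty;
    out[v] = c0 * (1 - tz) + c1 * tz;
  }
  return out;
}

// Nearest-neighbour sampling; outside the grid returns `background`.
// [[Rcpp::export]]
NumericVector cpp_nearest(NumericVector vol, IntegerVector dims,
                          NumericVector xs, NumericVector ys,
                          NumericVector zs, double background) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  int n = xs.size();
  NumericVector out(n);
  for (int v = 0; v < n; ++v) {
    int i = (int)std::lround(xs[v]), j = (int)std::lround(ys[v]),
        k = (int)std::lround(zs[v]);
    if (i < 0 || j < 0 || k < 0 || i >= nx || j >= ny || k >= nz)
      out[v] = background;
    else
      out[v] = vol[lin(i, j, k, nx, ny)];
  }
  return out;
}

// Parzen-window NMI between a hard-binned fixed image (0-based bins) and a
// moving image given in continuous bin units m in [0, nbins-1] (linear hat
// kernel). Returns NMI = (H_f + H_m) / H_joint and the per-voxel derivative
// dNMI/dm used for gradient-ascent registration.
// [[Rcpp::export]]
List cpp_nmi_parzen(IntegerVector fixed_bin, NumericVector moving,
                    int nbins, bool want_grad) {
  int n = fixed_bin.size();
  if (n != moving.size()) stop("length mismatch");
  std::vector<double> joint((size_t)nbins * nbins, 0.0);
  std::vector<int> b0(n);
  std::vector<double> tfrac(n);
  for (int v = 0; v < n; ++v) {
    double m = moving[v];
    if (m < 0) m = 0;
    if (m > nbins - 1) m = nbins - 1;
    int b = (int)std::floor(m);
    if (b > nbins - 2) b = nbins - 2;
    double t = m - b;
    b0[v] = b; tfrac[v] = t;
    int f = fixed_bin[v];
    joint[(size_t)f + nbins * b] += (1.0 - t);
    joint[(size_t)f + nbins * (b + 1)] += t;
  }
  double N = (double)n;
  std::vector<double> pf(nbins, 0.0), pm(nbins, 0.0);
  for (int b = 0; b < nbins; ++b)
    for (int f = 0; f < nbins; ++f) {
      double p = joint[(size_t)f + nbins * b] / N;
      joint[(size_t)f + nbins * b] = p;
      pf[f] += p; pm[b] += p;
    }
  double Hf = 0, Hm = 0, Hj = 0;
  for (int f = 0; f < nbins; ++f) if (pf[f] > 0) Hf -= pf[f] * std::log(pf[f]);
  for (int b = 0; b < nbins; ++b) if (pm[b] > 0) Hm -= pm[b] * std::log(pm[b]);
  for (size_t q = 0; q < joint.size(); ++q)
    if (joint[q] > 0) Hj -= joint[q] * std::log(joint[q]);
  double nmi = (Hj > 0) ? (Hf + Hm) / Hj : 2.0;
  if (!want_grad)
    return List::create(_["nmi"] = nmi);
  // dNMI/dp_{f,b} = (dHm/dp * Hj - (Hf+Hm) * dHj/dp) / Hj^2
  const double eps = 1e-12;
  NumericVector grad(n);
  double Hj2 = Hj * Hj;
  if (Hj2 < eps) {
    return List::create(_["nmi"] = nmi, _["grad"] = grad);
  }
  std::vector<double> D((size_t)nbins * nbins);
  for (int b = 0; b < nbins; ++b) {
    double dHm = -(std::log(std::max(pm[b], eps)) + 1.0);
    for (int f = 0; f < nbins; ++f) {
      double p = joint[(size_t)f + nbins * b];
      double dHj = -(std::log(std::max(p, eps)) + 1.0);
      D[(size_t)f + nbins * b] = (dHm * Hj - (Hf + Hm) * dHj) / Hj2;
    }
  }
  for (int v = 0; v < n; ++v) {
    int f = fixed_bin[v], b = b0[v];
    grad[v] = (D[(size_t)f + nbins * (b + 1)] - D[(size_t)f + nbins * b]) / N;
  }
  return List::create(_["nmi"] = nmi, _["grad"] = grad);
}
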