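#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// neighbour offsets for 6/18/26-connectivity on a 3D grid
static void make_offsets(int connectivity,
                         std::vector<int> &dx, std::vector<int> &dy,
                         std::vector<int> &dz) {
  dx.clear(); dy.clear(); dz.clear();
  for (int a = -1; a <= 1; ++a)
    for (int b = -1; b <= 1; ++b)
      for (int c = -1; c <= 1; ++c) {
        int nz = std::abs(a) + std::abs(b) + std::abs(c);
        if (nz == 0) continue;
        if (connectivity == 6 && nz > 1) continue;
        if (connectivity == 18 && nz > 2) continue;
        dx.push_back(a); dy.push_back(b); dz.push_back(c);
      }
}

static void label_core(const std::vector<char> &in, const int *d,
                       int connectivity, std::vector<int> &labels,
                       std::vector<int> &sizes) {
  const int n = d[0] * d[1] * d[2];
  labels.assign(n, 0);
  sizes.clear();
  std::vector<int> dx, dy, dz;
  make_offsets(connectivity, dx, dy, dz);
  std::vector<int> stack;
  int next = 0;
  for (int v = 0; v < n; ++v) {
    if (!in[v] || labels[v]) continue;
    ++next;
    int size = 0;
    stack.push_back(v);
    labels[v] = next;
    while (!stack.empty()) {
      int cur = stack.back();
      stack.pop_back();
      ++size;
      int x = cur % d[0];
      int y = (cur / d[0]) % d[1];
      int z = cur / (d[0] * d[1]);
      for (size_t k = 0; k < dx.size(); ++k) {
        int nx = x + dx[k], ny = y + dy[k], nz = z + dz[k];
        if (nx < 0 || nx >= d[0] || ny < 0 || ny >= d[1] ||
            nz < 0 || nz >= d[2]) continue;
        int w = nx + d[0] * (ny + d[1] * nz);
        if (in[w] && !labels[w]) {
          labels[w] = next;
          stack.push_back(w);
        }
      }
    }
    sizes.push_back(size);
  }
}

// [[Rcpp::export]]
IntegerVector label_components_3d(LogicalVector mask, IntegerVector dims,
                                  int connectivity) {
  if (dims.size() != 3)
    stop("dims must have length 3");
  const int n = dims[0] * dims[1] * dims[2];
  if (mask.size() != n)
    stop("mask length does not match dims");
  std::vector<char> in(n);
  for (int i = 0; i < n; ++i) in[i] = (mask[i] == TRUE);
  std::vector<int> labels, sizes;
  int d[3] = {dims[0], dims[1], dims[2]};
  label_core(in, d, connectivity, labels, sizes);
  IntegerVector out(n);
  for (int i = 0; i < n; ++i) out[i] = labels[i];
  return out;
}

// Maximum suprathreshold cluster size per column of a V x P statistic
// matrix, pooling positive (> thr) and negative (< -thr) components.
// Drives the sign-flip permutation null without allocating label arrays
// on the R side.
// [[Rcpp::export]]
IntegerVector max_cluster_size_cols(NumericMatrix stat, IntegerVector dims,
                                    double thr, int connectivity) {
  if (dims.size() != 3)
    stop("dims must have length 3");
  const int n = dims[0] * dims[1] * dims[2];
  if (stat.nrow() != n)
    stop("stat rows do not match dims");
  int d[3] = {dims[0], dims[1], dims[2]};
  const int p = stat.ncol();
  IntegerVector out(p);
  std::vector<char> in(n);
  std::vector<int> labels, sizes;
  for (int j = 0; j < p; ++j) {
    int best = 0;
    for (int sign = 0; sign < 2; ++sign) {
      bool any = false;
      for (int i = 0; i < n; ++i) {
        double v = stat(i, j);
        char keep = sign == 0 ? (v > thr) : (v < -thr);
        in[i] = keep;
        any = any || keep;
      }
      if (!any) continue;
      label_core(in, d, connectivity, labels, sizes);
      for (size_t k = 0; k < sizes.size(); ++k)
        if (sizes[k] > best) best = sizes[k];
    }
    out[j] = best;
  }
  return out;
}
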