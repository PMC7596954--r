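#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// neighbor offsets for 6/18/26 connectivity on a 3D grid
static std::vector<std::array<int, 3>> neighbor_offsets(int connectivity) {
  std::vector<std::array<int, 3>> offs;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        int nz = std::abs(dx) + std::abs(dy) + std::abs(dz);
        if (nz == 0) continue;
        if (connectivity == 6 && nz > 1) continue;
        if (connectivity == 18 && nz > 2) continue;
        offs.push_back({dx, dy, dz});
      }
  return offs;
}

// label connected components of `above` (flattened column-major 3D);
// labels are 1-based, 0 = background; sizes[l-1] = voxel count of label l
static int label_clusters(const std::vector<char>& above,
                          int n1, int n2, int n3, int connectivity,
                          std::vector<int>& labels,
                          std::vector<int>& sizes) {
  const std::vector<std::array<int, 3>>& offs = *[&] {
    static std::vector<std::array<int, 3>> o6 = neighbor_offsets(6);
    static std::vector<std::array<int, 3>> o18 = neighbor_offsets(18);
    static std::vector<std::array<int, 3>> o26 = neighbor_offsets(26);
    if (connectivity == 6) return &o6;
    if (connectivity == 18) return &o18;
    return &o26;
  }();
  int n = n1 * n2 * n3;
  std::fill(labels.begin(), labels.end(), 0);
  sizes.clear();
  int cur = 0;
  std::vector<int> stack;
  for (int start = 0; start < n; ++start) {
    if (!above[start] || labels[start]) continue;
    ++cur;
    int size = 0;
    stack.push_back(start);
    labels[start] = cur;
    while (!stack.empty()) {
      int v = stack.back();
      stack.pop_back();
      ++size;
      int x = v % n1, y = (v / n1) % n2, z = v / (n1 * n2);
      for (const auto& o : offs) {
        int xx = x + o[0], yy = y + o[1], zz = z + o[2];
        if (xx < 0 || xx >= n1 || yy < 0 || yy >= n2 || zz < 0 || zz >= n3)
          continue;
        int w = xx + n1 * (yy + n2 * zz);
        if (above[w] && !labels[w]) {
          labels[w] = cur;
          stack.push_back(w);
        }
      }
    }
    sizes.push_back(size);
  }
  return cur;
}

// [[Rcpp::export(name = ".label_components_cpp")]]
IntegerVector label_components_cpp(LogicalVector mask, IntegerVector dims,
                                   int connectivity) {
  int n1 = dims[0], n2 = dims[1], n3 = dims[2];
  int n = n1 * n2 * n3;
  std::vector<char> above(n);
  for (int i = 0; i < n; ++i) above[i] = mask[i] == TRUE;
  std::vector<int> labels(n), sizes;
  label_clusters(above, n1, n2, n3, connectivity, labels, sizes);
  IntegerVector out(n);
  for (int i = 0; i < n; ++i) out[i] = labels[i];
  return out;
}

// one-tailed TFCE of a non-negative map: for each voxel,
// sum over thresholds h = dh, 2dh, ... of e(h,v)^E * h^H * dh
// [[Rcpp::export(name = ".tfce_pos_cpp")]]
NumericVector tfce_pos_cpp(NumericVector stat, IntegerVector dims,
                           double E, double H, double dh, int connectivity) {
  int n1 = dims[0], n2 = dims[1], n3 = dims[2];
  int n = n1 * n2 * n3;
  NumericVector out(n);
  double mx = 0;
  for (int i = 0; i < n; ++i) if (stat[i] > mx) mx = stat[i];
  if (mx <= 0 || dh <= 0) return out;
  std::vector<char> above(n);
  std::vector<int> labels(n), sizes;
  int nsteps = (int) std::floor(mx / dh + 1e-12);
  for (int s = 1; s <= nsteps; ++s) {
    double h = s * dh;
    for (int i = 0; i < n; ++i) above[i] = stat[i] >= h;
    label_clusters(above, n1, n2, n3, connectivity, labels, sizes);
    double hH = std::pow(h, H);
    std::vector<double> add(sizes.size());
    for (size_t c = 0; c < sizes.size(); ++c)
      add[c] = std::pow((double) sizes[c], E) * hH * dh;
    for (int i = 0; i < n; ++i)
      if (labels[i]) out[i] += add[labels[i] - 1];
  }
  return out;
}
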