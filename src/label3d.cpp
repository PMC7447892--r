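#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// 3D connected-component labeling on a (nz, ny, nx) logical array stored in
// R's column-major order: linear index = k + nz*(j + ny*i), 0-based (k,j,i).
// connectivity: 6 (faces), 18 (faces+edges) or 26 (faces+edges+corners).
// Labels are assigned in raster-scan seed order, 1..K.
// [[Rcpp::export(name = ".label3d_cpp")]]
IntegerVector label3d_cpp(LogicalVector vol, int nz, int ny, int nx,
                          int connectivity) {
  if (connectivity != 6 && connectivity != 18 && connectivity != 26)
    stop("connectivity must be 6, 18 or 26");
  const R_xlen_t n = (R_xlen_t)nz * ny * nx;
  if (vol.size() != n) stop("volume size does not match dimensions");

  // neighbor offsets as (dk, dj, di) triples
  std::vector<int> dk, dj, di;
  for (int a = -1; a <= 1; ++a)
    for (int b = -1; b <= 1; ++b)
      for (int c = -1; c <= 1; ++c) {
        int s = std::abs(a) + std::abs(b) + std::abs(c);
        if (s == 0) continue;
        if ((connectivity == 6 && s > 1) || (connectivity == 18 && s > 2))
          continue;
        dk.push_back(a); dj.push_back(b); di.push_back(c);
      }
  const int nnb = (int)dk.size();

  IntegerVector labels(n, 0);
  std::vector<R_xlen_t> queue;
  int next_label = 0;

  for (R_xlen_t seed = 0; seed < n; ++seed) {
    if (!vol[seed] || labels[seed] != 0) continue;
    ++next_label;
    labels[seed] = next_label;
    queue.clear();
    queue.push_back(seed);
    while (!queue.empty()) {
      R_xlen_t idx = queue.back();
      queue.pop_back();
      int k = (int)(idx % nz);
      int j = (int)((idx / nz) % ny);
      int i = (int)(idx / ((R_xlen_t)nz * ny));
      for (int t = 0; t < nnb; ++t) {
        int kk = k + dk[t], jj = j + dj[t], ii = i + di[t];
        if (kk < 0 || kk >= nz || jj < 0 || jj >= ny || ii < 0 || ii >= nx)
          continue;
        R_xlen_t nb = kk + (R_xlen_t)nz * (jj + (R_xlen_t)ny * ii);
        if (vol[nb] && labels[nb] == 0) {
          labels[nb] = next_label;
          queue.push_back(nb);
        }
      }
    }
  }
  labels.attr("n_components") = next_label;
  return labels;
}
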