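#include <Rcpp.h>
#include <vector>
#include <array>
#include <cmath>
using namespace Rcpp;

// ---------------------------------------------------------------------------
// Connected components (union-find), 6/18/26 neighbourhoods, flat 3D arrays
// in R's column-major layout.
// ---------------------------------------------------------------------------

static inline int flat_index(int x, int y, int z, const int *d) {
  return x + d[0] * (y + d[1] * z);
}

static void neighbour_offsets(int connectivity,
                              std::vector<std::array<int,3>> &offs) {
  offs.clear();
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        int manh = std::abs(dx) + std::abs(dy) + std::abs(dz);
        if (manh == 0) continue;
        if (connectivity == 6 && manh > 1) continue;
        if (connectivity == 18 && manh > 2) continue;
        offs.push_back({dx, dy, dz});
      }
}

struct UnionFind {
  std::vector<int> parent;
  explicit UnionFind(int n) : parent(n) {
    for (int i = 0; i < n; ++i) parent[i] = i;
  }
  int find(int a) {
    while (parent[a] != a) { parent[a] = parent[parent[a]]; a = parent[a]; }
    return a;
  }
  void unite(int a, int b) {
    a = find(a); b = find(b);
    if (a != b) parent[b] = a;
  }
};

// core labelling over an arbitrary included-voxel indicator
static void label_core(const std::vector<char> &inc, const int *d,
                       int connectivity, std::vector<int> &labels,
                       int &ncomp) {
  const int n = d[0] * d[1] * d[2];
  std::vector<std::array<int,3>> offs;
  neighbour_offsets(connectivity, offs);
  UnionFind uf(n);
  for (int z = 0; z < d[2]; ++z)
    for (int y = 0; y < d[1]; ++y)
      for (int x = 0; x < d[0]; ++x) {
        int i = flat_index(x, y, z, d);
        if (!inc[i]) continue;
        for (auto &o : offs) {
          int nx = x + o[0], ny = y + o[1], nz = z + o[2];
          if (nx < 0 || ny < 0 || nz < 0 ||
              nx >= d[0] || ny >= d[1] || nz >= d[2]) continue;
          int j = flat_index(nx, ny, nz, d);
          if (inc[j]) uf.unite(i, j);
        }
      }
  labels.assign(n, 0);
  std::vector<int> remap(n, 0);
  ncomp = 0;
  for (int i = 0; i < n; ++i) {
    if (!inc[i]) continue;
    int r = uf.find(i);
    if (remap[r] == 0) remap[r] = ++ncomp;
    labels[i] = remap[r];
  }
}

// [[Rcpp::export]]
IntegerVector label_components_cpp(LogicalVector mask, IntegerVector dim,
                                   int connectivity) {
  int d[3] = {dim[0], dim[1], dim[2]};
  const int n = d[0] * d[1] * d[2];
  if ((int)mask.size() != n) stop("mask length does not match dim");
  std::vector<char> inc(n);
  for (int i = 0; i < n; ++i) inc[i] = mask[i] == TRUE;
  std::vector<int> labels;
  int ncomp;
  label_core(inc, d, connectivity, labels, ncomp);
  return IntegerVector(labels.begin(), labels.end());
}

// ---------------------------------------------------------------------------
// Threshold-free cluster enhancement on a mask-restricted adjacency.
// Per voxel, sum over thresholds h of extent(h)^E * h^H * dh where extent(h)
// is the voxel count of the cluster (at threshold h) containing the voxel.
// The caller precomputes the CSR adjacency among mask voxels once (the
// permutation loop re-enhances thousands of maps on the same mask) and
// handles signed maps by enhancing the negated map separately.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List mask_adjacency_cpp(IntegerVector dim, IntegerVector mask_flat,
                        int connectivity) {
  int d[3] = {dim[0], dim[1], dim[2]};
  const int n = d[0] * d[1] * d[2];
  const int m = mask_flat.size();
  std::vector<int> local(n, -1);
  for (int i = 0; i < m; ++i) {
    int f = mask_flat[i];
    if (f < 0 || f >= n) stop("mask index out of range");
    local[f] = i;
  }
  std::vector<std::array<int,3>> offs;
  neighbour_offsets(connectivity, offs);
  std::vector<int> ptr(m + 1, 0), idx;
  idx.reserve((size_t)m * offs.size() / 2);
  for (int i = 0; i < m; ++i) {
    int f = mask_flat[i];
    int x = f % d[0], y = (f / d[0]) % d[1], z = f / (d[0] * d[1]);
    for (auto &o : offs) {
      int nx = x + o[0], ny = y + o[1], nz = z + o[2];
      if (nx < 0 || ny < 0 || nz < 0 ||
          nx >= d[0] || ny >= d[1] || nz >= d[2]) continue;
      int j = local[flat_index(nx, ny, nz, d)];
      if (j >= 0) idx.push_back(j);
    }
    ptr[i + 1] = (int)idx.size();
  }
  return List::create(_["ptr"] = IntegerVector(ptr.begin(), ptr.end()),
                      _["idx"] = IntegerVector(idx.begin(), idx.end()));
}

// [[Rcpp::export]]
NumericVector tfce_masked_cpp(NumericVector stat, IntegerVector ptr,
                              IntegerVector idx, double E, double H,
                              double dh) {
  const int m = stat.size();
  if (dh <= 0) stop("dh must be positive");
  NumericVector out(m, 0.0);
  double hmax = 0.0;
  for (int i = 0; i < m; ++i) if (stat[i] > hmax) hmax = stat[i];
  if (hmax <= 0) return out;
  std::vector<int> labels(m), remap(m);
  // integer-stepped thresholds h = k*dh with a tolerance at the boundary,
  // so that voxels whose statistic equals a threshold are always included
  int nsteps = (int)std::floor(hmax / dh + 1e-9);
  for (int kk = 1; kk <= nsteps; ++kk) {
    double h = kk * dh;
    double hlo = h - 1e-9 * dh;
    UnionFind uf(m);
    for (int i = 0; i < m; ++i) {
      if (stat[i] < hlo) continue;
      for (int k = ptr[i]; k < ptr[i + 1]; ++k) {
        int j = idx[k];
        if (stat[j] >= hlo) uf.unite(i, j);
      }
    }
    std::fill(remap.begin(), remap.end(), 0);
    int ncomp = 0;
    for (int i = 0; i < m; ++i) {
      if (stat[i] < hlo) { labels[i] = 0; continue; }
      int r = uf.find(i);
      if (remap[r] == 0) remap[r] = ++ncomp;
      labels[i] = remap[r];
    }
    std::vector<double> extent(ncomp + 1, 0.0);
    for (int i = 0; i < m; ++i) if (labels[i]) extent[labels[i]] += 1.0;
    double hH = std::pow(h, H);
    for (int i = 0; i < m; ++i)
      if (labels[i]) out[i] += std::pow(extent[labels[i]], E) * hH * dh;
  }
  return out;
}

// ---------------------------------------------------------------------------
// Probabilistic streamline tracker.
//
// The orientation field is a per-voxel categorical mixture over K attractor
// points: a drawn component r yields the unit direction from the current
// voxel's centre toward attractor r (piecewise-constant per voxel, i.e.
// nearest-voxel field lookup). Streamlines start at a uniformly jittered
// position inside the seed voxel, step a fixed length, and terminate by
// first-touch target crediting, avoid-mask entry, curvature violation
// (minimum cosine between successive unit steps; one bounded redraw, with
// optional antipodal flip because orientation is sign-ambiguous), field exit,
// or step exhaustion. Uses R's RNG so results are reproducible via set.seed.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List track_cpp(IntegerVector dim,
               NumericMatrix weights,      // V x K mixture weights
               NumericMatrix centers,      // K x 3 attractor points (0-based voxel coords)
               IntegerVector seed_idx,     // 0-based flat indices of seed voxels
               IntegerVector target_id,    // length V, 0 = none, 1..T
               int n_targets,
               LogicalVector avoid,        // length V
               LogicalVector defined,      // length V, field defined here
               LogicalVector waypoint,     // length V (empty semantics: all TRUE)
               bool require_waypoint,
               int samples, int max_steps,
               double step_vox,            // step length in voxel units
               double curvature_threshold,
               int retries,
               bool symmetrize) {
  RNGScope scope;
  int d[3] = {dim[0], dim[1], dim[2]};
  const int V = d[0] * d[1] * d[2];
  const int K = centers.nrow();
  if (weights.nrow() != V || weights.ncol() != K)
    stop("weights must be V x K");
  const int S = seed_idx.size();
  IntegerMatrix counts(S, n_targets);
  IntegerVector launched(S);

  // per-voxel cumulative weights for fast categorical draws
  std::vector<double> cum(static_cast<size_t>(V) * K);
  std::vector<double> tot(V, 0.0);
  for (int v = 0; v < V; ++v) {
    double c = 0.0;
    for (int k = 0; k < K; ++k) {
      c += weights(v, k);
      cum[(size_t)v * K + k] = c;
    }
    tot[v] = c;
  }

  for (int s = 0; s < S; ++s) {
    int sv = seed_idx[s];
    if (sv < 0 || sv >= V) stop("seed index out of range");
    int sx = sv % d[0];
    int sy = (sv / d[0]) % d[1];
    int sz = sv / (d[0] * d[1]);
    for (int m = 0; m < samples; ++m) {
      launched[s]++;
      double px = sx + unif_rand() - 0.5;
      double py = sy + unif_rand() - 0.5;
      double pz = sz + unif_rand() - 0.5;
      double ux = 0, uy = 0, uz = 0;       // previous unit step
      bool have_prev = false;
      bool hit_way = !require_waypoint;
      for (int st = 0; st < max_steps; ++st) {
        int vx = (int)std::lround(px);
        int vy = (int)std::lround(py);
        int vz = (int)std::lround(pz);
        if (vx < 0 || vy < 0 || vz < 0 ||
            vx >= d[0] || vy >= d[1] || vz >= d[2]) break;
        int v = flat_index(vx, vy, vz, d);
        double tw = tot[v];
        if (tw <= 0.0) break;              // field undefined in practice
        bool ok = false;
        double dx = 0, dy = 0, dz = 0;
        for (int attempt = 0; attempt <= retries; ++attempt) {
          double u = unif_rand() * tw;
          const double *cv = &cum[(size_t)v * K];
          int k = 0;
          while (k < K - 1 && u > cv[k]) ++k;
          dx = centers(k, 0) - vx;
          dy = centers(k, 1) - vy;
          dz = centers(k, 2) - vz;
          double nrm = std::sqrt(dx * dx + dy * dy + dz * dz);
          if (nrm <= 0) continue;
          dx /= nrm; dy /= nrm; dz /= nrm;
          if (have_prev) {
            double dot = dx * ux + dy * uy + dz * uz;
            if (symmetrize && -dot > dot) { dx = -dx; dy = -dy; dz = -dz; dot = -dot; }
            if (dot < curvature_threshold) continue;  // redraw (bounded)
          }
          ok = true;
          break;
        }
        if (!ok) break;                    // curvature violation -> discard
        px += dx * step_vox;
        py += dy * step_vox;
        pz += dz * step_vox;
        ux = dx; uy = dy; uz = dz;
        have_prev = true;
        int nx = (int)std::lround(px);
        int ny = (int)std::lround(py);
        int nz = (int)std::lround(pz);
        if (nx < 0 || ny < 0 || nz < 0 ||
            nx >= d[0] || ny >= d[1] || nz >= d[2]) break;  // exits grid
        int nv = flat_index(nx, ny, nz, d);
        if (!defined[nv]) break;           // exits defined field
        if (avoid[nv]) break;              // discarded
        if (require_waypoint && waypoint[nv]) hit_way = true;
        int t = target_id[nv];
        if (t > 0) {                       // first-touch wins
          if (hit_way) counts(s, t - 1)++;
          break;
        }
      }
    }
  }
  return List::create(_["counts"] = counts, _["launched"] = launched);
}
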