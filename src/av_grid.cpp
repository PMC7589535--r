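#include <Rcpp.h>
#include <queue>
#include <vector>
#include <cmath>
#include <limits>

using namespace Rcpp;

// Accessible-volume grid search for a dye on a flexible linker.
//
// A cubic grid of the requested spacing is centred on the attachment atom and
// covers a sphere of radius linker_length + max dye radius.  For every node we
// record the distance from the node to the nearest obstacle van-der-Waals
// surface (min over atoms of |x - atom| - vdw).  A node is traversable by the
// linker if that clearance is at least half the linker width; shortest
// obstacle-avoiding path lengths from the attachment node are then computed by
// Dijkstra over the 26-connected traversable subgraph with Euclidean edge
// lengths.  Dye placement feasibility per radius is decided in R from the
// returned clearances and path lengths.
//
// [[Rcpp::export]]
List av_grid_cpp(NumericMatrix atom_xyz,   // obstacle heavy atoms (n x 3)
                 NumericVector atom_vdw,   // per-atom vdW radii
                 NumericVector attach,     // attachment point (length 3)
                 double linker_length,
                 double linker_width,
                 double max_dye_radius,
                 double spacing) {
  const double L = linker_length + max_dye_radius;
  const int half = (int)std::ceil(L / spacing);
  const int n_side = 2 * half + 1;
  const long n_nodes = (long)n_side * n_side * n_side;

  std::vector<double> clearance((size_t)n_nodes,
                                std::numeric_limits<double>::infinity());

  const int n_atoms = atom_xyz.nrow();
  // Only atoms that can influence the box matter.
  double max_vdw = 0.0;
  for (int a = 0; a < n_atoms; ++a) max_vdw = std::max(max_vdw, atom_vdw[a]);
  const double reach = L * std::sqrt(3.0) + max_vdw + spacing;

  std::vector<int> near_atoms;
  near_atoms.reserve(n_atoms);
  for (int a = 0; a < n_atoms; ++a) {
    const double dx = atom_xyz(a, 0) - attach[0];
    const double dy = atom_xyz(a, 1) - attach[1];
    const double dz = atom_xyz(a, 2) - attach[2];
    if (std::sqrt(dx * dx + dy * dy + dz * dz) <= reach) near_atoms.push_back(a);
  }

  auto node_coord = [&](long idx, double *xyz) {
    const int iz = (int)(idx % n_side);
    const int iy = (int)((idx / n_side) % n_side);
    const int ix = (int)(idx / ((long)n_side * n_side));
    xyz[0] = attach[0] + (ix - half) * spacing;
    xyz[1] = attach[1] + (iy - half) * spacing;
    xyz[2] = attach[2] + (iz - half) * spacing;
  };

  for (long idx = 0; idx < n_nodes; ++idx) {
    double p[3];
    node_coord(idx, p);
    double best = std::numeric_limits<double>::infinity();
    for (size_t k = 0; k < near_atoms.size(); ++k) {
      const int a = near_atoms[k];
      const double dx = p[0] - atom_xyz(a, 0);
      const double dy = p[1] - atom_xyz(a, 1);
      const double dz = p[2] - atom_xyz(a, 2);
      const double d = std::sqrt(dx * dx + dy * dy + dz * dz) - atom_vdw[a];
      if (d < best) best = d;
    }
    clearance[(size_t)idx] = best;
  }

  // The linker emerges from the attachment atom between its bonded
  // neighbours, so obstacles cannot block the path right at the source: a
  // free bubble of one linker width around the attachment point is always
  // traversable.
  const double half_width = linker_width / 2.0;
  const double bubble = linker_width;
  std::vector<double> dist((size_t)n_nodes,
                           std::numeric_limits<double>::infinity());

  // 26-neighbourhood offsets with Euclidean step lengths.
  std::vector<int> off_x, off_y, off_z;
  std::vector<double> off_len;
  for (int dx = -1; dx <= 1; ++dx)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dz = -1; dz <= 1; ++dz) {
        if (dx == 0 && dy == 0 && dz == 0) continue;
        off_x.push_back(dx);
        off_y.push_back(dy);
        off_z.push_back(dz);
        off_len.push_back(spacing * std::sqrt((double)(dx * dx + dy * dy + dz * dz)));
      }

  typedef std::pair<double, long> QN;
  std::priority_queue<QN, std::vector<QN>, std::greater<QN> > pq;
  const long start = ((long)half * n_side + half) * n_side + half;
  // The attachment node starts the linker path even if it sits inside an
  // obstacle's clearance shell (the linker emerges from the attachment atom).
  dist[(size_t)start] = 0.0;
  pq.push(QN(0.0, start));

  while (!pq.empty()) {
    const QN top = pq.top();
    pq.pop();
    const double d = top.first;
    const long u = top.second;
    if (d > dist[(size_t)u]) continue;
    if (d > linker_length) continue;
    const int iz = (int)(u % n_side);
    const int iy = (int)((u / n_side) % n_side);
    const int ix = (int)(u / ((long)n_side * n_side));
    for (size_t k = 0; k < off_x.size(); ++k) {
      const int jx = ix + off_x[k];
      const int jy = iy + off_y[k];
      const int jz = iz + off_z[k];
      if (jx < 0 || jy < 0 || jz < 0 || jx >= n_side || jy >= n_side || jz >= n_side)
        continue;
      const long v = ((long)jx * n_side + jy) * n_side + jz;
      if (clearance[(size_t)v] < half_width) {  // linker cannot pass ...
        const double bx = (jx - half) * spacing;
        const double by = (jy - half) * spacing;
        const double bz = (jz - half) * spacing;
        if (bx * bx + by * by + bz * bz > bubble * bubble)
          continue;  // ... unless inside the source bubble
      }
      const double nd = d + off_len[k];
      if (nd < dist[(size_t)v] && nd <= linker_length + 1e-12) {
        dist[(size_t)v] = nd;
        pq.push(QN(nd, v));
      }
    }
  }

  // Return only nodes reachable within the linker length, with coordinates,
  // clearances and path lengths; R applies the per-radius dye clash test.
  std::vector<long> keep;
  for (long idx = 0; idx < n_nodes; ++idx)
    if (dist[(size_t)idx] <= linker_length + 1e-12) keep.push_back(idx);

  const int n_keep = (int)keep.size();
  NumericMatrix pts(n_keep, 3);
  NumericVector clear_out(n_keep), path_out(n_keep);
  for (int i = 0; i < n_keep; ++i) {
    double p[3];
    node_coord(keep[(size_t)i], p);
    pts(i, 0) = p[0];
    pts(i, 1) = p[1];
    pts(i, 2) = p[2];
    clear_out[i] = clearance[(size_t)keep[(size_t)i]];
    path_out[i] = dist[(size_t)keep[(size_t)i]];
  }

  return List::create(_["points"] = pts,
                      _["clearance"] = clear_out,
                      _["path_length"] = path_out,
                      _["spacing"] = spacing,
                      _["n_side"] = n_side);
}

// Weighted average of |x_i - y_j| over all point pairs of two clouds.
// [[Rcpp::export]]
double pair_mean_distance_cpp(NumericMatrix a, NumericVector wa,
                              NumericMatrix b, NumericVector wb) {
  const int na = a.nrow(), nb = b.nrow();
  double acc = 0.0;
  for (int i = 0; i < na; ++i) {
    const double xi = a(i, 0), yi = a(i, 1), zi = a(i, 2), wi = wa[i];
    if (wi == 0.0) continue;
    double row = 0.0;
    for (int j = 0; j < nb; ++j) {
      const double dx = xi - b(j, 0);
      const double dy = yi - b(j, 1);
      const double dz = zi - b(j, 2);
      row += wb[j] * std::sqrt(dx * dx + dy * dy + dz * dz);
    }
    acc += wi * row;
  }
  return acc;
}
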