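#include <Rcpp.h>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// Plain (bisector-plane) Voronoi cell volumes.
//
// Each atom's cell is the intersection of the half-spaces bounded by the
// perpendicular bisector planes with its neighbours, computed in coordinates
// centred on the atom.  The cell is additionally clipped by a bounding cube
// of half-width `box`; a cell with a vertex on that cube extends beyond it
// in the true tessellation and is reported as unbounded (volume NA).
// Vertices are enumerated as intersections of plane triples and filtered by
// the full half-space system; the volume is assembled face by face
// (polygon area times plane offset over three).
//
// Only the `max_neighbors` nearest atoms contribute candidate planes; for
// molecular point densities the Voronoi faces of an interior atom come from
// atoms within a few angstroms, so this bound is generous.

struct Plane { double nx, ny, nz, d; bool box; };

// [[Rcpp::export]]
List voronoi_cpp(NumericMatrix coords, double box = 12.0,
                 int max_neighbors = 48) {
  const int n = coords.nrow();
  NumericVector vol(n, NA_REAL);
  LogicalVector bounded(n, false);
  const double tol = 1e-6;

  for (int i = 0; i < n; ++i) {
    // nearest neighbours by squared distance
    std::vector<std::pair<double, int> > dist;
    dist.reserve(n);
    for (int j = 0; j < n; ++j) {
      if (j == i) continue;
      double dx = coords(j, 0) - coords(i, 0);
      double dy = coords(j, 1) - coords(i, 1);
      double dz = coords(j, 2) - coords(i, 2);
      double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 < 4.0 * box * box) dist.push_back(std::make_pair(d2, j));
    }
    int k = std::min((int) dist.size(), max_neighbors);
    std::partial_sort(dist.begin(), dist.begin() + k, dist.end());

    std::vector<Plane> pl;
    pl.reserve(k + 6);
    for (int q = 0; q < k; ++q) {
      int j = dist[q].second;
      double ux = coords(j, 0) - coords(i, 0);
      double uy = coords(j, 1) - coords(i, 1);
      double uz = coords(j, 2) - coords(i, 2);
      double len = std::sqrt(ux * ux + uy * uy + uz * uz);
      if (len < 1e-9) continue;  // coincident atoms: no bisector
      Plane p; p.nx = ux / len; p.ny = uy / len; p.nz = uz / len;
      p.d = len / 2.0; p.box = false;
      pl.push_back(p);
    }
    for (int s = 0; s < 6; ++s) {
      Plane p; p.nx = p.ny = p.nz = 0.0; p.d = box; p.box = true;
      if (s == 0) p.nx = 1; else if (s == 1) p.nx = -1;
      else if (s == 2) p.ny = 1; else if (s == 3) p.ny = -1;
      else if (s == 4) p.nz = 1; else p.nz = -1;
      pl.push_back(p);
    }
    const int np = (int) pl.size();

    // vertex enumeration over plane triples
    std::vector<double> vx, vy, vz;
    std::vector<bool> on_box;
    for (int a = 0; a < np; ++a) {
      for (int b = a + 1; b < np; ++b) {
        for (int c = b + 1; c < np; ++c) {
          double det =
            pl[a].nx * (pl[b].ny * pl[c].nz - pl[b].nz * pl[c].ny) -
            pl[a].ny * (pl[b].nx * pl[c].nz - pl[b].nz * pl[c].nx) +
            pl[a].nz * (pl[b].nx * pl[c].ny - pl[b].ny * pl[c].nx);
          if (std::fabs(det) < 1e-9) continue;
          // Cramer's rule
          double px =
            (pl[a].d * (pl[b].ny * pl[c].nz - pl[b].nz * pl[c].ny) -
             pl[a].ny * (pl[b].d * pl[c].nz - pl[b].nz * pl[c].d) +
             pl[a].nz * (pl[b].d * pl[c].ny - pl[b].ny * pl[c].d)) / det;
          double py =
            (pl[a].nx * (pl[b].d * pl[c].nz - pl[b].nz * pl[c].d) -
             pl[a].d * (pl[b].nx * pl[c].nz - pl[b].nz * pl[c].nx) +
             pl[a].nz * (pl[b].nx * pl[c].d - pl[b].d * pl[c].nx)) / det;
          double pz =
            (pl[a].nx * (pl[b].ny * pl[c].d - pl[b].d * pl[c].ny) -
             pl[a].ny * (pl[b].nx * pl[c].d - pl[b].d * pl[c].nx) +
             pl[a].d * (pl[b].nx * pl[c].ny - pl[b].ny * pl[c].nx)) / det;
          if (std::fabs(px) > box + tol || std::fabs(py) > box + tol ||
              std::fabs(pz) > box + tol) continue;
          bool inside = true;
          for (int q = 0; q < np; ++q) {
            if (pl[q].nx * px + pl[q].ny * py + pl[q].nz * pz >
                pl[q].d + tol) { inside = false; break; }
          }
          if (!inside) continue;
          bool dup = false;
          for (size_t q = 0; q < vx.size(); ++q) {
            if (std::fabs(vx[q] - px) < 1e-5 &&
                std::fabs(vy[q] - py) < 1e-5 &&
                std::fabs(vz[q] - pz) < 1e-5) { dup = true; break; }
          }
          if (dup) continue;
          vx.push_back(px); vy.push_back(py); vz.push_back(pz);
          bool ob = (pl[a].box || pl[b].box || pl[c].box);
          // a vertex may also sit on a box plane via a near-coincidence
          if (!ob) {
            ob = (std::fabs(std::fabs(px) - box) < tol ||
                  std::fabs(std::fabs(py) - box) < tol ||
                  std::fabs(std::fabs(pz) - box) < tol);
          }
          on_box.push_back(ob);
        }
      }
    }
    const int nv = (int) vx.size();
    if (nv < 4) continue;  // degenerate: leave NA/unbounded
    bool touches_box = false;
    for (int q = 0; q < nv; ++q) if (on_box[q]) { touches_box = true; break; }
    bounded[i] = !touches_box;

    // volume: sum over faces of area * offset / 3 (atom centre is interior)
    double v = 0.0;
    for (int a = 0; a < np; ++a) {
      std::vector<int> face;
      for (int q = 0; q < nv; ++q) {
        if (std::fabs(pl[a].nx * vx[q] + pl[a].ny * vy[q] +
                      pl[a].nz * vz[q] - pl[a].d) < 10 * tol)
          face.push_back(q);
      }
      if ((int) face.size() < 3) continue;
      // orthonormal basis in the face plane
      double ax = pl[a].nx, ay = pl[a].ny, az = pl[a].nz;
      double ux, uy, uz;
      if (std::fabs(ax) < 0.9) { ux = 1; uy = 0; uz = 0; }
      else { ux = 0; uy = 1; uz = 0; }
      double dotp = ux * ax + uy * ay + uz * az;
      ux -= dotp * ax; uy -= dotp * ay; uz -= dotp * az;
      double ul = std::sqrt(ux * ux + uy * uy + uz * uz);
      ux /= ul; uy /= ul; uz /= ul;
      double wx = ay * uz - az * uy;
      double wy = az * ux - ax * uz;
      double wz = ax * uy - ay * ux;
      // order vertices by angle about the face centroid
      double cx = 0, cy = 0, cz = 0;
      for (size_t q = 0; q < face.size(); ++q) {
        cx += vx[face[q]]; cy += vy[face[q]]; cz += vz[face[q]];
      }
      cx /= face.size(); cy /= face.size(); cz /= face.size();
      std::vector<std::pair<double, int> > ang;
      for (size_t q = 0; q < face.size(); ++q) {
        double rx = vx[face[q]] - cx, ry = vy[face[q]] - cy,
               rz = vz[face[q]] - cz;
        double s = rx * ux + ry * uy + rz * uz;
        double t = rx * wx + ry * wy + rz * wz;
        ang.push_back(std::make_pair(std::atan2(t, s), face[q]));
      }
      std::sort(ang.begin(), ang.end());
      double area2 = 0.0;  // twice the polygon area (shoelace in-plane)
      for (size_t q = 0; q < ang.size(); ++q) {
        size_t r = (q + 1) % ang.size();
        double rx1 = vx[ang[q].second] - cx, ry1 = vy[ang[q].second] - cy,
               rz1 = vz[ang[q].second] - cz;
        double rx2 = vx[ang[r].second] - cx, ry2 = vy[ang[r].second] - cy,
               rz2 = vz[ang[r].second] - cz;
        double s1 = rx1 * ux + ry1 * uy + rz1 * uz;
        double t1 = rx1 * wx + ry1 * wy + rz1 * wz;
        double s2 = rx2 * ux + ry2 * uy + rz2 * uz;
        double t2 = rx2 * wx + ry2 * wy + rz2 * wz;
        area2 += s1 * t2 - s2 * t1;
      }
      v += std::fabs(area2) / 2.0 * pl[a].d / 3.0;
    }
    if (bounded[i]) vol[i] = v;
  }
  return List::create(_["volume"] = vol, _["bounded"] = bounded);
}
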