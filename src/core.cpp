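#include <Rcpp.h>
#include <queue>
#include <vector>
#include <set>
#include <algorithm>
#include <cmath>
#include <cstdint>

using namespace Rcpp;

// Matrices follow the R convention used throughout the package:
// element (i, j) is row i (the y coordinate) and column j (the x
// coordinate); coordinates reported to R are 0-based (x, y).

// ---------------------------------------------------------------------------
// Grayscale dilation by reconstruction, 4-connectivity.
//
// Hybrid algorithm: forward/backward raster sweeps followed by a FIFO
// queue pass. Values are only ever copied or combined with min/max, so
// the result is bit-identical to naive iteration of the geodesic
// dilation until stability.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
NumericMatrix reconstruct_dilate_cpp(NumericMatrix seed, NumericMatrix mask) {
  const int nr = seed.nrow(), nc = seed.ncol();
  if (mask.nrow() != nr || mask.ncol() != nc)
    stop("seed and mask must have identical dimensions");
  NumericMatrix J(nr, nc);
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i)
      J(i, j) = std::min(seed(i, j), mask(i, j));

  // forward raster scan: neighbors already visited are up and left
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      double v = J(i, j);
      if (i > 0) v = std::max(v, J(i - 1, j));
      if (j > 0) v = std::max(v, J(i, j - 1));
      J(i, j) = std::min(v, mask(i, j));
    }
  }
  // backward raster scan, queueing pixels whose propagation is unfinished
  std::queue<int> fifo;
  for (int j = nc - 1; j >= 0; --j) {
    for (int i = nr - 1; i >= 0; --i) {
      double v = J(i, j);
      if (i < nr - 1) v = std::max(v, J(i + 1, j));
      if (j < nc - 1) v = std::max(v, J(i, j + 1));
      J(i, j) = std::min(v, mask(i, j));
      const double jij = J(i, j);
      bool push = false;
      if (i < nr - 1 && J(i + 1, j) < jij && J(i + 1, j) < mask(i + 1, j)) push = true;
      if (!push && j < nc - 1 && J(i, j + 1) < jij && J(i, j + 1) < mask(i, j + 1)) push = true;
      if (push) fifo.push(i + nr * j);
    }
  }
  const int di[4] = {-1, 1, 0, 0};
  const int dj[4] = {0, 0, -1, 1};
  while (!fifo.empty()) {
    const int p = fifo.front(); fifo.pop();
    const int i = p % nr, j = p / nr;
    const double jp = J(i, j);
    for (int k = 0; k < 4; ++k) {
      const int qi = i + di[k], qj = j + dj[k];
      if (qi < 0 || qi >= nr || qj < 0 || qj >= nc) continue;
      if (J(qi, qj) < jp && J(qi, qj) != mask(qi, qj)) {
        J(qi, qj) = std::min(jp, mask(qi, qj));
        fifo.push(qi + nr * qj);
      }
    }
  }
  return J;
}

// ---------------------------------------------------------------------------
// Seeded watershed: Meyer's flooding from labeled seeds on a topographic
// surface (high values = ridges). 4-connected regions; pixels where two
// floods meet become watershed lines (label 0). Priority queue ordered by
// surface height with FIFO tie-breaking, so results are fully
// deterministic for a given input.
// ---------------------------------------------------------------------------

struct QElem {
  double prio;
  std::uint64_t order;
  int idx;
};
struct QCmp {
  bool operator()(const QElem& a, const QElem& b) const {
    if (a.prio != b.prio) return a.prio > b.prio;    // min-heap on height
    return a.order > b.order;                        // FIFO on ties
  }
};

// [[Rcpp::export]]
IntegerMatrix seeded_watershed_cpp(NumericMatrix surface, IntegerMatrix seeds) {
  const int nr = surface.nrow(), nc = surface.ncol();
  if (seeds.nrow() != nr || seeds.ncol() != nc)
    stop("surface and seeds must have identical dimensions");
  const int WSHED = -1;
  std::vector<int> lab(static_cast<size_t>(nr) * nc, 0);
  std::vector<char> queued(static_cast<size_t>(nr) * nc, 0);
  std::priority_queue<QElem, std::vector<QElem>, QCmp> pq;
  std::uint64_t counter = 0;
  const int di[4] = {-1, 1, 0, 0};
  const int dj[4] = {0, 0, -1, 1};

  int nseeds = 0;
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i)
      if (seeds(i, j) > 0) { lab[i + nr * j] = seeds(i, j); ++nseeds; }
  if (nseeds == 0) stop("at least one seed pixel is required");

  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      if (lab[i + nr * j] <= 0) continue;
      for (int k = 0; k < 4; ++k) {
        const int qi = i + di[k], qj = j + dj[k];
        if (qi < 0 || qi >= nr || qj < 0 || qj >= nc) continue;
        const int q = qi + nr * qj;
        if (lab[q] == 0 && !queued[q]) {
          queued[q] = 1;
          pq.push({surface(qi, qj), counter++, q});
        }
      }
    }
  }

  while (!pq.empty()) {
    const QElem e = pq.top(); pq.pop();
    const int p = e.idx;
    if (lab[p] != 0) continue;
    const int i = p % nr, j = p / nr;
    int found = 0;
    bool conflict = false;
    for (int k = 0; k < 4; ++k) {
      const int qi = i + di[k], qj = j + dj[k];
      if (qi < 0 || qi >= nr || qj < 0 || qj >= nc) continue;
      const int lq = lab[qi + nr * qj];
      if (lq > 0) {
        if (found == 0) found = lq;
        else if (found != lq) { conflict = true; break; }
      }
    }
    if (conflict || found == 0) {
      lab[p] = WSHED;
      continue;
    }
    lab[p] = found;
    for (int k = 0; k < 4; ++k) {
      const int qi = i + di[k], qj = j + dj[k];
      if (qi < 0 || qi >= nr || qj < 0 || qj >= nc) continue;
      const int q = qi + nr * qj;
      if (lab[q] == 0 && !queued[q]) {
        queued[q] = 1;
        pq.push({surface(qi, qj), counter++, q});
      }
    }
  }

  IntegerMatrix out(nr, nc);
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i) {
      const int l = lab[i + nr * j];
      out(i, j) = (l == WSHED) ? 0 : l;
    }
  return out;
}

// ---------------------------------------------------------------------------
// Regional minima of a grayscale surface: connected plateaus (4-conn,
// equal value) with no strictly lower 4-neighbor. Returns a label image,
// one positive label per minimum, 0 elsewhere.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
IntegerMatrix regional_minima_cpp(NumericMatrix x) {
  const int nr = x.nrow(), nc = x.ncol();
  IntegerMatrix lab(nr, nc);  // 0 = unvisited
  const int di[4] = {-1, 1, 0, 0};
  const int dj[4] = {0, 0, -1, 1};
  int next_label = 0;
  std::vector<int> plateau;
  for (int j0 = 0; j0 < nc; ++j0) {
    for (int i0 = 0; i0 < nr; ++i0) {
      if (lab(i0, j0) != 0) continue;
      // flood the plateau containing (i0, j0)
      const double v = x(i0, j0);
      plateau.clear();
      bool is_min = true;
      std::queue<int> fifo;
      lab(i0, j0) = -1;  // mark visited, classification pending
      fifo.push(i0 + nr * j0);
      while (!fifo.empty()) {
        const int p = fifo.front(); fifo.pop();
        plateau.push_back(p);
        const int i = p % nr, j = p / nr;
        for (int k = 0; k < 4; ++k) {
          const int qi = i + di[k], qj = j + dj[k];
          if (qi < 0 || qi >= nr || qj < 0 || qj >= nc) continue;
          const double vq = x(qi, qj);
          if (vq < v) { is_min = false; continue; }
          if (vq == v && lab(qi, qj) == 0) {
            lab(qi, qj) = -1;
            fifo.push(qi + nr * qj);
          }
        }
      }
      const int l = is_min ? ++next_label : -2;  // -2: visited, not minimum
      for (size_t k = 0; k < plateau.size(); ++k) {
        const int p = plateau[k];
        lab(p % nr, p / nr) = l;
      }
    }
  }
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i)
      if (lab(i, j) < 0) lab(i, j) = 0;
  return lab;
}

// ---------------------------------------------------------------------------
// Voronoi rendering of a point process on the pixel grid. For each pixel
// center, finds the nearest and second-nearest generating points; the
// pixel is a boundary pixel if its Euclidean distance to the bisector of
// those two generators is below half the requested boundary width.
// centers: n x 2 matrix of (x, y), 0-based pixel coordinates.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List voronoi_render_cpp(int nrow, int ncol, NumericMatrix centers,
                        double boundary_width) {
  const int n = centers.nrow();
  if (n < 2) stop("need at least two generating points");
  IntegerMatrix lab(nrow, ncol);
  LogicalMatrix boundary(nrow, ncol);
  const double half_w = boundary_width / 2.0;
  for (int j = 0; j < ncol; ++j) {
    const double px = j;
    for (int i = 0; i < nrow; ++i) {
      const double py = i;
      double d1 = R_PosInf, d2 = R_PosInf;
      int i1 = -1, i2 = -1;
      for (int c = 0; c < n; ++c) {
        const double dx = centers(c, 0) - px, dy = centers(c, 1) - py;
        const double d = dx * dx + dy * dy;
        if (d < d1) { d2 = d1; i2 = i1; d1 = d; i1 = c; }
        else if (d < d2) { d2 = d; i2 = c; }
      }
      lab(i, j) = i1 + 1;
      // distance from pixel to the bisector of the two nearest centers:
      // (d2^2 - d1^2) / (2 |c1 - c2|), with d squared distances here
      const double cx = centers(i1, 0) - centers(i2, 0);
      const double cy = centers(i1, 1) - centers(i2, 1);
      const double cc = std::sqrt(cx * cx + cy * cy);
      const double dist_edge = (d2 - d1) / (2.0 * cc);
      boundary(i, j) = dist_edge < half_w;
    }
  }
  return List::create(_["labels"] = lab, _["boundary"] = boundary);
}

// ---------------------------------------------------------------------------
// Region adjacency from a label image with boundary lines: two regions
// are neighbors iff they touch a common boundary (0-labeled) pixel,
// where "touch" reaches through the boundary line: each boundary pixel
// first collects the region labels in its 8-neighborhood, then unions
// the collections of adjacent boundary pixels. This makes the relation
// robust to boundary lines up to ~3 px wide (a 1-px line resolves in
// the first pass alone). Returns a 2-column matrix of unique pairs.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
IntegerMatrix neighbor_pairs_cpp(IntegerMatrix labels) {
  const int nr = labels.nrow(), nc = labels.ncol();
  std::set<std::pair<int, int> > pairs;
  const int di[8] = {-1, -1, -1, 0, 0, 1, 1, 1};
  const int dj[8] = {-1, 0, 1, -1, 1, -1, 0, 1};
  // pass 1: labels directly adjacent to each boundary pixel
  std::vector<std::vector<int> > touch(static_cast<size_t>(nr) * nc);
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      if (labels(i, j) != 0) continue;
      std::vector<int>& f = touch[i + nr * j];
      for (int k = 0; k < 8; ++k) {
        const int qi = i + di[k], qj = j + dj[k];
        if (qi < 0 || qi >= nr || qj < 0 || qj >= nc) continue;
        const int l = labels(qi, qj);
        if (l > 0) f.push_back(l);
      }
      std::sort(f.begin(), f.end());
      f.erase(std::unique(f.begin(), f.end()), f.end());
    }
  }
  // pass 2: union with adjacent boundary pixels' collections
  std::vector<int> found;
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      if (labels(i, j) != 0) continue;
      found = touch[i + nr * j];
      for (int k = 0; k < 8; ++k) {
        const int qi = i + di[k], qj = j + dj[k];
        if (qi < 0 || qi >= nr || qj < 0 || qj >= nc) continue;
        if (labels(qi, qj) == 0) {
          const std::vector<int>& g = touch[qi + nr * qj];
          found.insert(found.end(), g.begin(), g.end());
        }
      }
      std::sort(found.begin(), found.end());
      found.erase(std::unique(found.begin(), found.end()), found.end());
      for (size_t a = 0; a + 1 < found.size(); ++a)
        for (size_t b = a + 1; b < found.size(); ++b)
          pairs.insert(std::make_pair(found[a], found[b]));
    }
  }
  IntegerMatrix out(pairs.size(), 2);
  int r = 0;
  for (std::set<std::pair<int, int> >::const_iterator it = pairs.begin();
       it != pairs.end(); ++it, ++r) {
    out(r, 0) = it->first;
    out(r, 1) = it->second;
  }
  return out;
}
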