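#include <Rcpp.h>
#include <queue>
#include <vector>
#include <tuple>
#include <cmath>
using namespace Rcpp;

// Neighbor offsets: first 4 are the axial moves, last 4 the diagonals.
static const int DR[8] = {-1, 1, 0, 0, -1, -1, 1, 1};
static const int DC[8] = {0, 0, -1, 1, -1, 1, -1, 1};

// Connected component labeling of a binary mask. Labels are assigned in
// column-major scan order of each component's first pixel, so the result is
// deterministic and independent of any prior labeling.
// [[Rcpp::export]]
IntegerMatrix cc_label_cpp(LogicalMatrix mask, int connectivity) {
  int nr = mask.nrow(), nc = mask.ncol();
  int nn = (connectivity == 4) ? 4 : 8;
  IntegerMatrix lab(nr, nc);
  int next = 0;
  std::vector<int> stack;
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      if (!mask(r, c) || lab(r, c) != 0) continue;
      ++next;
      stack.clear();
      stack.push_back(r + c * nr);
      lab(r, c) = next;
      while (!stack.empty()) {
        int p = stack.back(); stack.pop_back();
        int pr = p % nr, pc = p / nr;
        for (int k = 0; k < nn; ++k) {
          int qr = pr + DR[k], qc = pc + DC[k];
          if (qr < 0 || qr >= nr || qc < 0 || qc >= nc) continue;
          if (mask(qr, qc) && lab(qr, qc) == 0) {
            lab(qr, qc) = next;
            stack.push_back(qr + qc * nr);
          }
        }
      }
    }
  }
  return lab;
}

// Multi-source shortest path over the traversable mask from every labeled
// pixel (distance 0 at sources). Axial steps cost 1, diagonal steps cost
// `diag_cost` (1 for pure step counting, sqrt(2) for Euclidean-weighted
// chains). Ties in distance are resolved toward the smaller label, which
// makes the assignment deterministic and enumeration-order independent.
// Unreached traversable pixels get dist -1 / label 0.
// [[Rcpp::export]]
List grow_assign_cpp(LogicalMatrix trav, IntegerMatrix labels,
                     double diag_cost, int connectivity) {
  int nr = trav.nrow(), nc = trav.ncol();
  int n = nr * nc;
  int nn = (connectivity == 4) ? 4 : 8;
  NumericMatrix dist(nr, nc);
  IntegerMatrix lab(nr, nc);
  std::fill(dist.begin(), dist.end(), -1.0);
  const int* trv = LOGICAL(trav);
  const int* src = INTEGER(labels);
  double* d = REAL(dist);
  int* lb = INTEGER(lab);

  if (diag_cost == 1.0) {
    // unit-cost: layered breadth-first search, min label wins on ties
    std::vector<int> cur, nxt;
    cur.reserve(n); nxt.reserve(n);
    for (int p = 0; p < n; ++p)
      if (src[p] > 0 && trv[p]) { d[p] = 0.0; lb[p] = src[p]; cur.push_back(p); }
    double level = 0.0;
    while (!cur.empty()) {
      ++level;
      nxt.clear();
      for (size_t i = 0; i < cur.size(); ++i) {
        int p = cur[i];
        int pr = p % nr, pc = p / nr, l = lb[p];
        for (int k = 0; k < nn; ++k) {
          int qr = pr + DR[k], qc = pc + DC[k];
          if (qr < 0 || qr >= nr || qc < 0 || qc >= nc) continue;
          int q = qr + qc * nr;
          if (!trv[q]) continue;
          if (d[q] < 0.0) {            // first claim at this layer
            d[q] = level; lb[q] = l; nxt.push_back(q);
          } else if (d[q] == level && l < lb[q]) {
            lb[q] = l;                 // same layer, smaller label wins
          }
        }
      }
      cur.swap(nxt);
    }
  } else {
    // weighted diagonals: Dijkstra; (dist, label) ordering keeps ties
    // deterministic toward the smaller label
    typedef std::tuple<double, int, int> Node; // (dist, label, pixel index)
    std::priority_queue<Node, std::vector<Node>, std::greater<Node> > pq;
    for (int p = 0; p < n; ++p)
      if (src[p] > 0 && trv[p]) pq.push(Node(0.0, src[p], p));
    while (!pq.empty()) {
      Node nd = pq.top(); pq.pop();
      double dd = std::get<0>(nd);
      int l = std::get<1>(nd), p = std::get<2>(nd);
      if (d[p] >= 0.0) continue;
      d[p] = dd;
      lb[p] = l;
      int pr = p % nr, pc = p / nr;
      for (int k = 0; k < nn; ++k) {
        int qr = pr + DR[k], qc = pc + DC[k];
        if (qr < 0 || qr >= nr || qc < 0 || qc >= nc) continue;
        int q = qr + qc * nr;
        if (!trv[q] || d[q] >= 0.0) continue;
        double step = (k < 4) ? 1.0 : diag_cost;
        pq.push(Node(dd + step, l, q));
      }
    }
  }
  return List::create(_["dist"] = dist, _["label"] = lab);
}

// For each candidate pixel (1-based row/col), the label of the Euclidean
// nearest labeled pixel, searching only boundary pixels of the labeled
// regions. Ties go to the smaller label. Returns 0 when no labeled pixel
// exists.
// [[Rcpp::export]]
IntegerVector nearest_label_euclid_cpp(IntegerMatrix labels, IntegerMatrix cand) {
  int nr = labels.nrow(), nc = labels.ncol();
  std::vector<int> br, bc, bl;
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      int l = labels(r, c);
      if (l <= 0) continue;
      bool boundary = false;
      for (int k = 0; k < 8 && !boundary; ++k) {
        int qr = r + DR[k], qc = c + DC[k];
        if (qr < 0 || qr >= nr || qc < 0 || qc >= nc) { boundary = true; break; }
        if (labels(qr, qc) != l) boundary = true;
      }
      if (boundary) { br.push_back(r); bc.push_back(c); bl.push_back(l); }
    }
  }
  int n = cand.nrow(), m = (int) br.size();
  IntegerVector out(n);
  for (int i = 0; i < n; ++i) {
    if (m == 0) { out[i] = 0; continue; }
    double best = R_PosInf; int bestl = 0;
    int r = cand(i, 0) - 1, c = cand(i, 1) - 1;
    for (int j = 0; j < m; ++j) {
      double dr = r - br[j], dc = c - bc[j];
      double d2 = dr * dr + dc * dc;
      if (d2 < best || (d2 == best && bl[j] < bestl)) { best = d2; bestl = bl[j]; }
    }
    out[i] = bestl;
  }
  return out;
}

// True for positively labeled pixels that have, within Chebyshev radius
// `radius`, a pixel of a different label (or, when include_zero, a
// background/outside pixel). Used to paint membrane ridges along region
// interfaces in the synthetic sheet generator.
// [[Rcpp::export]]
LogicalMatrix interface_mask_cpp(IntegerMatrix labels, int radius, bool include_zero) {
  int nr = labels.nrow(), nc = labels.ncol();
  LogicalMatrix out(nr, nc);
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      int l = labels(r, c);
      if (l <= 0) continue;
      bool hit = false;
      for (int dr = -radius; dr <= radius && !hit; ++dr) {
        for (int dc = -radius; dc <= radius && !hit; ++dc) {
          int qr = r + dr, qc = c + dc;
          if (qr < 0 || qr >= nr || qc < 0 || qc >= nc) {
            if (include_zero) hit = true;
            continue;
          }
          int ql = labels(qr, qc);
          if (ql != l && (ql > 0 || include_zero)) hit = true;
        }
      }
      out(r, c) = hit;
    }
  }
  return out;
}
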