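#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <limits>

using namespace Rcpp;

// Numerical floors shared with the R layer (documented in the package):
// squared distances are floored at DIST2_FLOOR so coincident points stay
// finite, and probabilities are floored at PROB_FLOOR inside log terms.
static const double DIST2_FLOOR = 1e-12;
static const double PROB_FLOOR  = 1e-12;

// ---------------------------------------------------------------------------
// Perplexity calibration: per-point bisection on the Gaussian precision
// beta_i = 1/(2 sigma_i^2) so that the Shannon entropy of the conditional
// distribution over the k listed neighbours matches log2(perplexity) bits.
// Distances come in squared, one row per point, nearest first.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List cpp_perplexity_search(NumericMatrix nn_dist2, double perplexity,
                           double tol, int max_iter) {
  const int n = nn_dist2.nrow();
  const int k = nn_dist2.ncol();
  const double log_u = std::log(perplexity); // target entropy in nats

  NumericMatrix P(n, k);
  NumericVector beta(n);
  LogicalVector converged(n);
  std::vector<double> d(k), p(k);

  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < k; ++j) d[j] = nn_dist2(i, j);

    double b = 1.0;
    double b_lo = -std::numeric_limits<double>::infinity();
    double b_hi =  std::numeric_limits<double>::infinity();
    double H = 0.0, sumP = 0.0;
    bool ok = false;

    for (int it = 0; it < max_iter; ++it) {
      // H(beta) = log(sumP) + beta * <d>_P  (nats)
      sumP = 0.0;
      double sumDP = 0.0;
      for (int j = 0; j < k; ++j) {
        p[j] = std::exp(-b * d[j]);
        sumP += p[j];
      }
      if (sumP < std::numeric_limits<double>::min())
        sumP = std::numeric_limits<double>::min();
      for (int j = 0; j < k; ++j) sumDP += d[j] * p[j];
      H = std::log(sumP) + b * sumDP / sumP;

      double diff = H - log_u;
      if (std::fabs(diff) < tol) { ok = true; break; }
      if (diff > 0) { // entropy too high -> sharpen kernel
        b_lo = b;
        b = std::isfinite(b_hi) ? 0.5 * (b + b_hi) : b * 2.0;
      } else {
        b_hi = b;
        b = std::isfinite(b_lo) ? 0.5 * (b + b_lo) : b * 0.5;
      }
    }

    for (int j = 0; j < k; ++j) P(i, j) = p[j] / sumP;
    beta[i] = b;
    converged[i] = ok;
  }

  return List::create(_["prob"] = P, _["beta"] = beta,
                      _["converged"] = converged);
}

// ---------------------------------------------------------------------------
// Barnes-Hut quadtree over the 2-D embedding. Cells accumulate a centre of
// mass; during force evaluation a cell is summarised whenever
// (cell width / distance) < theta, i.e. width^2 < theta^2 * dist^2.
// ---------------------------------------------------------------------------

struct Cell {
  double cx, cy, hw, hh;        // cell centre and half-extents
  double com_x, com_y;          // centre of mass
  int    cum;                   // points in the subtree
  int    child;                 // arena index of the first of 4 children;
                                // -1 marks a leaf
  double px, py;                // stored point (filled leaf)
  bool   filled;
  Cell(double cx_, double cy_, double hw_, double hh_)
    : cx(cx_), cy(cy_), hw(hw_), hh(hh_), com_x(0), com_y(0),
      cum(0), child(-1), px(0), py(0), filled(false) {}
};

// Flat, arena-allocated quadtree: contiguous cells keep the per-iteration
// tree rebuild and the 4n traversals cache-friendly.
class QuadTree {
  std::vector<Cell> cells;

public:
  QuadTree(double cx, double cy, double hw, double hh, int n) {
    cells.reserve(4 * n + 64);
    cells.emplace_back(cx, cy, hw, hh);
  }

  void insert(double x, double y) { insert_at(0, x, y); }

  void insert_at(int idx, double x, double y) {
    for (;;) {
      Cell& c = cells[idx];
      ++c.cum;
      c.com_x += (x - c.com_x) / c.cum;
      c.com_y += (y - c.com_y) / c.cum;

      if (c.child < 0) {
        if (!c.filled) { c.px = x; c.py = y; c.filled = true; return; }
        // coincident points (or vanishing cells) merge into the leaf
        if ((c.px == x && c.py == y) || (c.hw < 1e-10 && c.hh < 1e-10))
          return;
        const double qw = 0.5 * c.hw, qh = 0.5 * c.hh;
        const double ccx = c.cx, ccy = c.cy;
        const double ox = c.px, oy = c.py;
        const int base = static_cast<int>(cells.size());
        cells.emplace_back(ccx - qw, ccy - qh, qw, qh);  // invalidates c
        cells.emplace_back(ccx + qw, ccy - qh, qw, qh);
        cells.emplace_back(ccx - qw, ccy + qh, qw, qh);
        cells.emplace_back(ccx + qw, ccy + qh, qw, qh);
        cells[idx].child = base;
        cells[idx].filled = false;
        insert_at(base + (ox > ccx ? 1 : 0) + (oy > ccy ? 2 : 0), ox, oy);
        idx = base + (x > ccx ? 1 : 0) + (y > ccy ? 2 : 0);
      } else {
        idx = c.child + (x > c.cx ? 1 : 0) + (y > c.cy ? 2 : 0);
      }
    }
  }

  // Repulsive contribution on (x, y); self-interaction is excluded for a
  // singleton leaf holding the target's own coordinates. A cell is
  // summarised by its centre of mass when (cell width / distance) < theta.
  void non_edge_forces(double x, double y, double theta2,
                       double& fx, double& fy, double& sumQ) const {
    int stack[1024];
    int sp = 0;
    stack[sp++] = 0;
    while (sp) {
      const Cell& c = cells[stack[--sp]];
      if (c.cum == 0) continue;
      if (c.child < 0 && c.cum == 1 && c.px == x && c.py == y) continue;

      double dx = x - c.com_x, dy = y - c.com_y;
      double d2 = dx * dx + dy * dy;
      double w = 2.0 * (c.hw > c.hh ? c.hw : c.hh);

      if (c.child < 0 || w * w < theta2 * d2) {
        if (d2 < DIST2_FLOOR) d2 = DIST2_FLOOR;
        double q = 1.0 / (1.0 + d2);
        double mult = c.cum * q;
        sumQ += mult;
        mult *= q;
        fx += mult * dx;
        fy += mult * dy;
      } else {
        stack[sp] = c.child;
        stack[sp + 1] = c.child + 1;
        stack[sp + 2] = c.child + 2;
        stack[sp + 3] = c.child + 3;
        sp += 4;
      }
    }
  }
};

// ---------------------------------------------------------------------------
// One gradient + KLD evaluation at the current coordinates.
//   P is passed as 0-based triplets (pi, pj, px) of the symmetric sparse
//   affinity matrix, possibly exaggerated (sum = alpha). With `half = true`
//   the triplets cover only the upper triangle (i < j) and each entry
//   stands for the unordered pair, halving the hot loop.
//   `sum_plogp` is the constant term sum_ij p_ij log(max(p_ij, floor)) over
//   ALL stored pairs; it only changes when P is (de-)exaggerated, so the
//   caller precomputes it.
//   theta == 0 selects the exact O(n^2) repulsion; theta > 0 the quadtree.
// Returns grad (n x 2, the t-SNE gradient 4*(F_attr - F_rep)), the KLD over
// stored pairs, and the normalisation constant Z.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List cpp_gradient_kld(IntegerVector pi, IntegerVector pj, NumericVector px,
                      NumericMatrix Y, double theta, double sum_plogp,
                      bool half) {
  const int n = Y.nrow();
  const R_xlen_t m = px.size();
  const double* y1 = REAL(Y);
  const double* y2 = y1 + n;

  std::vector<double> repx(n, 0.0), repy(n, 0.0);
  double Z = 0.0;

  if (theta > 0) {
    double minx = y1[0], maxx = y1[0], miny = y2[0], maxy = y2[0];
    for (int i = 1; i < n; ++i) {
      if (y1[i] < minx) minx = y1[i];
      if (y1[i] > maxx) maxx = y1[i];
      if (y2[i] < miny) miny = y2[i];
      if (y2[i] > maxy) maxy = y2[i];
    }
    double cx = 0.5 * (minx + maxx), cy = 0.5 * (miny + maxy);
    double hw = 0.5 * (maxx - minx) + 1e-5, hh = 0.5 * (maxy - miny) + 1e-5;
    QuadTree tree(cx, cy, hw, hh, n);
    for (int i = 0; i < n; ++i) tree.insert(y1[i], y2[i]);

    const double theta2 = theta * theta;
    for (int i = 0; i < n; ++i) {
      double fx = 0.0, fy = 0.0;
      tree.non_edge_forces(y1[i], y2[i], theta2, fx, fy, Z);
      repx[i] = fx;
      repy[i] = fy;
    }
  } else {
    for (int i = 0; i < n; ++i) {
      for (int j = i + 1; j < n; ++j) {
        double dx = y1[i] - y1[j], dy = y2[i] - y2[j];
        double d2 = dx * dx + dy * dy;
        if (d2 < DIST2_FLOOR) d2 = DIST2_FLOOR;
        double q = 1.0 / (1.0 + d2);
        Z += 2.0 * q;
        double mult = q * q;
        repx[i] += mult * dx;  repy[i] += mult * dy;
        repx[j] -= mult * dx;  repy[j] -= mult * dy;
      }
    }
  }

  // attractive term over stored pairs; KLD falls out as a by-product:
  // KLD = sum p log p - sum p log q with log q = -log1p(d^2) - log Z,
  // clamped below at log(PROB_FLOOR).
  std::vector<double> attx(n, 0.0), atty(n, 0.0);
  const double logZ = std::log(Z);
  const double log_floor = std::log(PROB_FLOOR);
  const int* ip = INTEGER(pi);
  const int* jp = INTEGER(pj);
  const double* pp = REAL(px);
  double plogq = 0.0;

  for (R_xlen_t e = 0; e < m; ++e) {
    const int i = ip[e], j = jp[e];
    double dx = y1[i] - y1[j], dy = y2[i] - y2[j];
    double d2 = dx * dx + dy * dy;
    if (d2 < DIST2_FLOOR) d2 = DIST2_FLOOR;
    const double qnum = 1.0 / (1.0 + d2);
    const double p = pp[e];
    const double f = p * qnum;
    attx[i] += f * dx;
    atty[i] += f * dy;
    if (half) {
      attx[j] -= f * dx;
      atty[j] -= f * dy;
    }
    double lq = -std::log1p(d2) - logZ;
    if (lq < log_floor) lq = log_floor;
    plogq += p * lq;
  }
  const double kld = sum_plogp - (half ? 2.0 : 1.0) * plogq;

  NumericMatrix grad(n, 2);
  for (int i = 0; i < n; ++i) {
    grad(i, 0) = 4.0 * (attx[i] - repx[i] / Z);
    grad(i, 1) = 4.0 * (atty[i] - repy[i] / Z);
  }

  return List::create(_["grad"] = grad, _["kld"] = kld, _["Z"] = Z);
}
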