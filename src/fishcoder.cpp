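#include <Rcpp.h>
#include <vector>
#include <map>
#include <queue>
#include <array>
#include <functional>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// ---------------------------------------------------------------------------
// Combinatorial barcode decoding
//
// Spots arrive in canonical order (sorted by pseudocolor, y, x); indices
// into that order serve as deterministic tie-breakers, which makes the
// decoder invariant to the caller's input ordering and to global
// translation of the field.
// ---------------------------------------------------------------------------

struct Cand {
  int seed;                  // canonical spot index of the seed
  int gene;                  // gene row (0-based)
  std::vector<int> spots;    // constituent spots (seed first)
  std::vector<double> dists; // seed-to-spot distance (0 for the seed)
  double total;
};

// [[Rcpp::export]]
List cpp_decode(IntegerVector pc, NumericVector x, NumericVector y,
                IntegerMatrix codes, double radius, int minPos) {
  const int n = pc.size();
  const int G = codes.nrow();
  const double r2max = radius * radius;

  int npc = 0;
  for (int i = 0; i < n; ++i) npc = std::max(npc, pc[i] + 1);
  for (int g = 0; g < G; ++g)
    for (int k = 0; k < 4; ++k) npc = std::max(npc, codes(g, k) + 1);

  std::vector<std::vector<int>> byPC(npc), genesByPC(npc);
  for (int i = 0; i < n; ++i) byPC[pc[i]].push_back(i);
  for (int g = 0; g < G; ++g)
    for (int k = 0; k < 4; ++k) genesByPC[codes(g, k)].push_back(g);

  // nearest spot of pseudocolor p to (sx, sy) within radius (inclusive);
  // exact distance ties keep the smaller canonical index (byPC is sorted)
  auto nearest = [&](int p, double sx, double sy, int& id, double& dist) {
    id = -1; double best = 0.0;
    for (int j : byPC[p]) {
      double dx = x[j] - sx, dy = y[j] - sy;
      double d2 = dx * dx + dy * dy;
      if (d2 <= r2max && (id < 0 || d2 < best)) { best = d2; id = j; }
    }
    dist = (id >= 0) ? std::sqrt(best) : -1.0;
  };

  // 1-3: seed every spot, try every gene carrying the seed's pseudocolor,
  // keep the minimum-total-distance viable gene; exact ties drop the seed
  std::vector<Cand> cands;
  for (int s = 0; s < n; ++s) {
    int bestGene = -1; bool tie = false;
    Cand best;
    for (int g : genesByPC[pc[s]]) {
      Cand c; c.seed = s; c.gene = g;
      c.spots.push_back(s); c.dists.push_back(0.0); c.total = 0.0;
      for (int k = 0; k < 4; ++k) {
        int p = codes(g, k);
        if (p == pc[s]) continue;
        int id; double d;
        nearest(p, x[s], y[s], id, d);
        if (id >= 0) {
          c.spots.push_back(id); c.dists.push_back(d); c.total += d;
        }
      }
      if ((int)c.spots.size() < minPos) continue;
      if (bestGene < 0 || c.total < best.total) {
        bestGene = g; best = c; tie = false;
      } else if (c.total == best.total) {
        tie = true;
      }
    }
    if (bestGene >= 0 && !tie) cands.push_back(best);
  }

  // 5: merge candidates of one gene that share a spot (union-find);
  // representative = most positions, then smallest total, then seed index
  int m = cands.size();
  std::vector<int> parent(m);
  for (int i = 0; i < m; ++i) parent[i] = i;
  std::function<int(int)> find = [&](int a) {
    while (parent[a] != a) { parent[a] = parent[parent[a]]; a = parent[a]; }
    return a;
  };
  auto unite = [&](int a, int b) {
    a = find(a); b = find(b);
    if (a != b) parent[std::max(a, b)] = std::min(a, b);
  };
  {
    std::map<std::pair<int,int>, int> firstSeen; // (gene, spot) -> cand
    for (int i = 0; i < m; ++i) {
      for (int sp : cands[i].spots) {
        auto key = std::make_pair(cands[i].gene, sp);
        auto it = firstSeen.find(key);
        if (it == firstSeen.end()) firstSeen[key] = i;
        else unite(it->second, i);
      }
    }
  }
  std::map<int, int> repOf; // root -> representative candidate
  for (int i = 0; i < m; ++i) {
    int r = find(i);
    auto it = repOf.find(r);
    if (it == repOf.end()) { repOf[r] = i; continue; }
    const Cand& a = cands[i];
    const Cand& b = cands[it->second];
    bool better = a.spots.size() > b.spots.size() ||
      (a.spots.size() == b.spots.size() &&
       (a.total < b.total || (a.total == b.total && a.seed < b.seed)));
    if (better) it->second = i;
  }

  struct Call {
    int gene; std::vector<int> spots; std::vector<double> dists;
    double total; bool alive;
  };
  std::vector<Call> calls;
  for (auto& kv : repOf) {
    const Cand& c = cands[kv.second];
    calls.push_back({c.gene, c.spots, c.dists, c.total, true});
  }

  // 6: spots claimed by calls of different genes go to the call with the
  // smaller total distance; losers shrink and die below minPos
  for (int iter = 0; iter < 1000; ++iter) {
    std::map<int, std::vector<int>> owners;
    for (int i = 0; i < (int)calls.size(); ++i) {
      if (!calls[i].alive) continue;
      for (int sp : calls[i].spots) owners[sp].push_back(i);
    }
    bool any = false;
    for (auto& kv : owners) {
      if (kv.second.size() < 2) continue;
      any = true;
      int win = kv.second[0];
      for (int i : kv.second) {
        const Call& a = calls[i];
        const Call& w = calls[win];
        if (a.total < w.total ||
            (a.total == w.total && (a.gene < w.gene ||
             (a.gene == w.gene && i < win))))
          win = i;
      }
      for (int i : kv.second) {
        if (i == win) continue;
        Call& c = calls[i];
        for (size_t j = 0; j < c.spots.size(); ++j) {
          if (c.spots[j] == kv.first) {
            c.total -= c.dists[j];
            c.spots.erase(c.spots.begin() + j);
            c.dists.erase(c.dists.begin() + j);
            break;
          }
        }
      }
    }
    for (auto& c : calls)
      if (c.alive && (int)c.spots.size() < minPos) c.alive = false;
    if (!any) break;
  }

  List out;
  for (auto& c : calls) {
    if (!c.alive) continue;
    out.push_back(List::create(
      _["gene"] = c.gene + 1,
      _["spots"] = IntegerVector(c.spots.begin(), c.spots.end()) + 1,
      _["dists"] = NumericVector(c.dists.begin(), c.dists.end()),
      _["total"] = c.total));
  }
  return out;
}

// ---------------------------------------------------------------------------
// Local maxima with non-maximum suppression
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
NumericMatrix cpp_local_maxima(NumericMatrix img, double threshold, int d) {
  const int nr = img.nrow(), nc = img.ncol();
  std::vector<std::array<double,3>> cand; // val, r, c
  for (int r = 0; r < nr; ++r) {
    for (int c = 0; c < nc; ++c) {
      double v = img(r, c);
      if (v <= threshold) continue;
      bool ismax = true;
      for (int dr = -d; dr <= d && ismax; ++dr) {
        int rr = r + dr;
        if (rr < 0 || rr >= nr) continue;
        for (int dc = -d; dc <= d; ++dc) {
          int cc = c + dc;
          if (cc < 0 || cc >= nc || (dr == 0 && dc == 0)) continue;
          if (img(rr, cc) > v) { ismax = false; break; }
        }
      }
      if (ismax) cand.push_back({v, (double)r, (double)c});
    }
  }
  // suppress the dimmer of any pair within d (Euclidean); ties keep the
  // first in (row, col) order
  std::sort(cand.begin(), cand.end(), [](const std::array<double,3>& a,
                                         const std::array<double,3>& b) {
    if (a[0] != b[0]) return a[0] > b[0];
    if (a[1] != b[1]) return a[1] < b[1];
    return a[2] < b[2];
  });
  std::vector<std::array<double,3>> keep;
  const double d2 = (double)d * d;
  for (auto& p : cand) {
    bool ok = true;
    for (auto& q : keep) {
      double dr = p[1] - q[1], dc = p[2] - q[2];
      if (dr * dr + dc * dc <= d2) { ok = false; break; }
    }
    if (ok) keep.push_back(p);
  }
  NumericMatrix out(keep.size(), 3);
  for (size_t i = 0; i < keep.size(); ++i) {
    out(i, 0) = keep[i][1]; out(i, 1) = keep[i][2]; out(i, 2) = keep[i][0];
  }
  colnames(out) = CharacterVector::create("row", "col", "value");
  return out;
}

// ---------------------------------------------------------------------------
// Total-variation (ROF) denoising, Chambolle dual projection
//   min_u  TV(u) + ||u - g||^2 / (2*lambda)
// Forward-difference gradient, Neumann boundaries; the divergence has zero
// sum so the mean of u equals the mean of g exactly.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List cpp_rof(NumericMatrix g, double lambda, int maxIter, double tol) {
  const int nr = g.nrow(), nc = g.ncol();
  NumericMatrix p1(nr, nc), p2(nr, nc), u(nr, nc), div(nr, nc);
  const double tau = 0.125;
  double gmin = g[0], gmax = g[0];
  for (int i = 0; i < nr * nc; ++i) {
    gmin = std::min(gmin, g[i]); gmax = std::max(gmax, g[i]);
  }
  const double range = std::max(gmax - gmin, 1e-12);
  NumericMatrix uprev(nr, nc);
  int it = 0; bool converged = false;
  for (it = 0; it < maxIter; ++it) {
    for (int r = 0; r < nr; ++r)
      for (int c = 0; c < nc; ++c) {
        double v = p1(r, c) + p2(r, c);
        if (r > 0) v -= p1(r - 1, c);
        if (c > 0) v -= p2(r, c - 1);
        div(r, c) = v;
      }
    for (int i = 0; i < nr * nc; ++i) u[i] = g[i] - lambda * div[i];
    double diff = 0.0;
    for (int i = 0; i < nr * nc; ++i) {
      double dd = u[i] - uprev[i];
      diff += dd * dd;
      uprev[i] = u[i];
    }
    if (it > 0 && std::sqrt(diff / (nr * nc)) / range < tol) {
      converged = true; break;
    }
    // p += tau * grad(div p - g / lambda), then pointwise projection
    for (int r = 0; r < nr; ++r)
      for (int c = 0; c < nc; ++c) {
        double w = div(r, c) - g(r, c) / lambda;
        double gx = (r + 1 < nr) ? (div(r + 1, c) - g(r + 1, c) / lambda) - w : 0.0;
        double gy = (c + 1 < nc) ? (div(r, c + 1) - g(r, c + 1) / lambda) - w : 0.0;
        double n1 = p1(r, c) + tau * gx;
        double n2 = p2(r, c) + tau * gy;
        double nor = 1.0 + tau * std::sqrt(gx * gx + gy * gy);
        p1(r, c) = n1 / nor;
        p2(r, c) = n2 / nor;
      }
  }
  return List::create(_["u"] = u, _["iterations"] = it + 1,
                      _["converged"] = converged);
}

// ---------------------------------------------------------------------------
// Render isotropic Gaussian spots (peak amplitude parameterization)
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
NumericMatrix cpp_add_spots(int nrow, int ncol, NumericVector xs,
                            NumericVector ys, NumericVector amps,
                            double sigma) {
  NumericMatrix plane(nrow, ncol);
  const int w = (int)std::ceil(4.0 * sigma);
  const double s2 = 2.0 * sigma * sigma;
  for (int i = 0; i < xs.size(); ++i) {
    const double cx = xs[i], cy = ys[i], a = amps[i];
    const int r0 = std::max(0, (int)std::floor(cy) - w);
    const int r1 = std::min(nrow - 1, (int)std::ceil(cy) + w);
    const int c0 = std::max(0, (int)std::floor(cx) - w);
    const int c1 = std::min(ncol - 1, (int)std::ceil(cx) + w);
    for (int r = r0; r <= r1; ++r) {
      const double dy = r - cy;
      for (int c = c0; c <= c1; ++c) {
        const double dx = c - cx;
        plane(r, c) += a * std::exp(-(dx * dx + dy * dy) / s2);
      }
    }
  }
  return plane;
}

// ---------------------------------------------------------------------------
// Label expansion: multi-source BFS (4-connected) into background, capped
// at npix steps. Labels only grow into 0 pixels, so expansion can never
// merge two labels; first-come (row-major seeding) breaks ties.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
IntegerMatrix cpp_expand_labels(IntegerMatrix labels, int npix) {
  const int nr = labels.nrow(), nc = labels.ncol();
  IntegerMatrix out(nr, nc);
  std::vector<int> dist(nr * nc, -1);
  std::queue<int> q;
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r) {
      int i = c * nr + r;
      out[i] = labels[i];
      if (labels[i] > 0) { dist[i] = 0; q.push(i); }
    }
  const int dr[4] = {-1, 1, 0, 0};
  const int dc[4] = {0, 0, -1, 1};
  while (!q.empty()) {
    int i = q.front(); q.pop();
    if (dist[i] >= npix) continue;
    int r = i % nr, c = i / nr;
    for (int k = 0; k < 4; ++k) {
      int rr = r + dr[k], cc = c + dc[k];
      if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
      int j = cc * nr + rr;
      if (out[j] == 0 && dist[j] < 0) {
        out[j] = out[i];
        dist[j] = dist[i] + 1;
        q.push(j);
      }
    }
  }
  return out;
}
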