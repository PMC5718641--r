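// Immersion-based watershed transform over the 8-connected pixel graph,
// plus the geodesic primitives it is built from (connected-component
// labelling and geodesic influence zones).
//
// Flooding semantics, level by level over the distinct altitude values h:
//   X_hmin = T_hmin, its 8-connected components seeding the first basins;
//   at each later level, pixels of T_h not yet assigned are attached to the
//   geodesic influence zone of the nearest existing basin (paths confined
//   to T_h minus committed dam pixels, unit cost per 8-neighbour step).
//   Zone growth is synchronous first-contact wave propagation (the classic
//   realization of geodesic influence zones on the discrete grid): at each
//   wave step, every still-unassigned pixel of T_h adjacent to exactly one
//   basin label joins that basin, and a pixel contacted in the same step by
//   two or more distinct basins becomes a permanent dam (watershed) pixel;
//   dams do not propagate labels. The update is simultaneous, so the result
//   does not depend on any traversal order. The regional minima whose
//   plateau value is h seed fresh basins (they are always isolated
//   components of T_h: every neighbour of a minimum plateau is strictly
//   higher, hence outside T_h), labelled in raster order. Pixels never
//   assigned when the flood reaches hmax are watershed pixels (label 0),
//   and the basin count equals the number of regional minima of f.

#include <Rcpp.h>
#include <queue>
#include <vector>
#include <algorithm>

using namespace Rcpp;

static const int DR[8] = {-1, -1, -1, 0, 0, 1, 1, 1};
static const int DC[8] = {-1, 0, 1, -1, 1, -1, 0, 1};

// raster index: p = r + c * nr (column-major like R); neighbour iteration
// helper below keeps bounds checks in one place.
struct Grid {
  int nr, nc;
  Grid(int nr_, int nc_) : nr(nr_), nc(nc_) {}
  inline int size() const { return nr * nc; }
  inline int row(int p) const { return p % nr; }
  inline int col(int p) const { return p / nr; }
  inline int at(int r, int c) const { return r + c * nr; }
  template <class F> inline void neighbours(int p, F f) const {
    int r = row(p), c = col(p);
    for (int k = 0; k < 8; ++k) {
      int rr = r + DR[k], cc = c + DC[k];
      if (rr >= 0 && rr < nr && cc >= 0 && cc < nc) f(at(rr, cc));
    }
  }
};

// 8-connected components of a pixel set (mask true); labels assigned in
// raster order (column-major to match R matrix traversal by column? no --
// raster order here means row-major visual order, i.e. by row then column,
// matching the documented "raster-scan order of the first pixel").
static void label_components_of(const Grid& g, const std::vector<char>& mask,
                                std::vector<int>& lab, int& next_label) {
  std::vector<int> stack;
  for (int r = 0; r < g.nr; ++r) {
    for (int c = 0; c < g.nc; ++c) {
      int p = g.at(r, c);
      if (!mask[p] || lab[p] != 0) continue;
      int id = next_label++;
      lab[p] = id;
      stack.push_back(p);
      while (!stack.empty()) {
        int q = stack.back();
        stack.pop_back();
        g.neighbours(q, [&](int nb) {
          if (mask[nb] && lab[nb] == 0) {
            lab[nb] = id;
            stack.push_back(nb);
          }
        });
      }
    }
  }
}

// [[Rcpp::export(name = ".cc_label_cpp")]]
IntegerMatrix cc_label_cpp(LogicalMatrix mask) {
  Grid g(mask.nrow(), mask.ncol());
  std::vector<char> m(g.size());
  for (int p = 0; p < g.size(); ++p) m[p] = mask[p] ? 1 : 0;
  std::vector<int> lab(g.size(), 0);
  int next = 1;
  label_components_of(g, m, lab, next);
  IntegerMatrix out(g.nr, g.nc);
  for (int p = 0; p < g.size(); ++p) out[p] = lab[p];
  return out;
}

// Multi-source layered BFS. domain: pixels traversable; markers: >0 basin
// labels acting as sources (distance 0). On return: dist (-1 unreachable),
// state (0 none, -1 tie, >0 unique nearest label) for non-source pixels.
static void influence_bfs(const Grid& g, const std::vector<char>& domain,
                          const std::vector<int>& markers,
                          std::vector<int>& dist, std::vector<int>& state) {
  const int n = g.size();
  dist.assign(n, -1);
  state.assign(n, 0);
  std::vector<int> layer, next;
  for (int p = 0; p < n; ++p) {
    if (markers[p] > 0 && domain[p]) {
      dist[p] = 0;
      state[p] = markers[p];
      layer.push_back(p);
    }
  }
  int d = 0;
  while (!layer.empty()) {
    ++d;
    next.clear();
    for (int p : layer) {
      g.neighbours(p, [&](int nb) {
        if (domain[nb] && markers[nb] == 0 && dist[nb] == -1) {
          dist[nb] = d;
          next.push_back(nb);
        }
      });
    }
    // aggregate states after the layer is complete: every distance-(d-1)
    // pixel is final, so scanning neighbours sees all shortest paths
    for (int p : next) {
      int s = 0;
      g.neighbours(p, [&](int nb) {
        if (dist[nb] == d - 1 && state[nb] != 0) {
          int ns = state[nb];
          if (s == 0) s = ns;
          else if (s != ns || ns == -1) s = -1;
        }
      });
      state[p] = s;
    }
    layer.swap(next);
  }
}

// [[Rcpp::export(name = ".influence_zones_cpp")]]
IntegerMatrix influence_zones_cpp(LogicalMatrix domain,
                                  IntegerMatrix markers) {
  Grid g(domain.nrow(), domain.ncol());
  std::vector<char> dom(g.size());
  std::vector<int> mk(g.size());
  for (int p = 0; p < g.size(); ++p) {
    dom[p] = domain[p] ? 1 : 0;
    mk[p] = markers[p];
  }
  std::vector<int> dist, state;
  influence_bfs(g, dom, mk, dist, state);
  IntegerMatrix out(g.nr, g.nc);
  for (int p = 0; p < g.size(); ++p) {
    if (mk[p] > 0 && dom[p]) out[p] = mk[p];
    else out[p] = (dist[p] >= 0 && state[p] > 0) ? state[p] : 0;
  }
  return out;
}

// [[Rcpp::export(name = ".immersion_watershed_cpp")]]
List immersion_watershed_cpp(IntegerMatrix f) {
  Grid g(f.nrow(), f.ncol());
  const int n = g.size();
  std::vector<int> alt(n);
  for (int p = 0; p < n; ++p) alt[p] = f[p];

  std::vector<int> levels(alt);
  std::sort(levels.begin(), levels.end());
  levels.erase(std::unique(levels.begin(), levels.end()), levels.end());

  std::vector<int> lab(n, 0);        // basin labels, 0 = unassigned
  std::vector<char> dam(n, 0);       // committed watershed pixels
  int next_label = 1;

  // base level: components of T_hmin are the first minima
  {
    std::vector<char> base(n);
    for (int p = 0; p < n; ++p) base[p] = alt[p] == levels[0];
    label_components_of(g, base, lab, next_label);
  }

  std::vector<int> assigned_per_level;
  assigned_per_level.reserve(levels.size());
  {
    int cnt = 0;
    for (int p = 0; p < n; ++p) if (lab[p] > 0) ++cnt;
    assigned_per_level.push_back(cnt);
  }

  // pixels grouped by altitude level, in raster order within a level
  std::vector<std::vector<int>> by_level(levels.size());
  {
    std::vector<int> level_of(n);
    for (int p = 0; p < n; ++p) {
      level_of[p] = int(std::lower_bound(levels.begin(), levels.end(),
                                         alt[p]) - levels.begin());
    }
    for (int r = 0; r < g.nr; ++r) {
      for (int c = 0; c < g.nc; ++c) {
        int p = g.at(r, c);
        by_level[level_of[p]].push_back(p);
      }
    }
  }

  int assigned_total = assigned_per_level.back();
  std::vector<int> leftover;           // unresolved candidates carried on
  std::vector<char> cand(n, 0), queued(n, 0);
  std::vector<int> frontier, touched, newly, decided;

  for (size_t li = 1; li < levels.size(); ++li) {
    const int h = levels[li];
    // candidates: pixels surfacing at this level plus unresolved
    // leftovers from lower levels (never dams, never labelled)
    std::vector<int> cand_list;
    cand_list.reserve(leftover.size() + by_level[li].size());
    for (int p : leftover) cand_list.push_back(p);
    for (int p : by_level[li]) cand_list.push_back(p);
    leftover.clear();
    if (cand_list.empty()) {
      assigned_per_level.push_back(assigned_total);
      continue;
    }
    for (int p : cand_list) cand[p] = 1;

    // synchronous wave growth: the frontier holds pixels assigned in the
    // previous step (initially the labelled pixels bordering the
    // candidate set); every candidate contacted by the frontier is
    // decided against the labels as of the end of the previous step, so
    // the update is simultaneous and traversal-order independent
    frontier.clear();
    for (int p : cand_list) {
      g.neighbours(p, [&](int nb) {
        if (lab[nb] > 0 && !queued[nb]) {
          queued[nb] = 1;
          frontier.push_back(nb);
        }
      });
    }
    for (int p : frontier) queued[p] = 0;
    while (!frontier.empty()) {
      touched.clear();
      for (int p : frontier) {
        g.neighbours(p, [&](int nb) {
          if (cand[nb] && lab[nb] == 0 && !dam[nb] && !queued[nb]) {
            queued[nb] = 1;
            touched.push_back(nb);
          }
        });
      }
      decided.assign(touched.size(), 0);
      for (size_t i = 0; i < touched.size(); ++i) {
        int first = 0;
        bool multi = false;
        g.neighbours(touched[i], [&](int nb) {
          int l = lab[nb];
          if (l > 0) {
            if (first == 0) first = l;
            else if (first != l) multi = true;
          }
        });
        decided[i] = multi ? -1 : first;  // first == 0 cannot occur
      }
      newly.clear();
      for (size_t i = 0; i < touched.size(); ++i) {
        int p = touched[i];
        if (decided[i] == -1) {
          dam[p] = 1;
        } else {
          lab[p] = decided[i];
          ++assigned_total;
          newly.push_back(p);
        }
        queued[p] = 0;
      }
      frontier.swap(newly);
    }

    // fresh basins: unreached components that are regional minima of f at
    // this level (all pixels at altitude h with no strictly lower
    // 8-neighbour); dam-enclosed leftovers are not minima and stay
    // unassigned. Components are collected by flood fill in raster order
    // of their first pixel (cand_list keeps raster order within a level;
    // leftovers precede, but leftovers are never minima at this level).
    for (int p0 : cand_list) {
      if (lab[p0] != 0 || dam[p0] || queued[p0]) continue;
      // flood the unreached component containing p0; queued marks visited
      std::vector<int> comp{p0};
      queued[p0] = 1;
      bool is_min = true;
      for (size_t i = 0; i < comp.size(); ++i) {
        int p = comp[i];
        if (alt[p] != h) is_min = false;
        g.neighbours(p, [&](int nb) {
          if (alt[nb] < alt[p]) is_min = false;
          if (cand[nb] && lab[nb] == 0 && !dam[nb] && !queued[nb]) {
            queued[nb] = 1;
            comp.push_back(nb);
          }
        });
      }
      if (is_min) {
        // the component must be a maximal plateau of f: an equal-altitude
        // neighbour outside it (a dam pixel carved from the same plateau)
        // means the true plateau extends further and touches lower ground
        for (size_t i = 0; i < comp.size() && is_min; ++i) {
          g.neighbours(comp[i], [&](int nb) {
            if (alt[nb] == h && !queued[nb]) is_min = false;
          });
        }
      }
      if (is_min) {
        for (int p : comp) {
          lab[p] = next_label;
          ++assigned_total;
        }
        ++next_label;
      } else {
        for (int p : comp) leftover.push_back(p);
      }
    }
    for (int p : cand_list) {
      cand[p] = 0;
      queued[p] = 0;
    }
    assigned_per_level.push_back(assigned_total);
  }

  IntegerMatrix out(g.nr, g.nc);
  for (int p = 0; p < n; ++p) out[p] = lab[p];
  return List::create(_["labels"] = out,
                      _["n_basins"] = next_label - 1,
                      _["levels"] = IntegerVector(levels.begin(),
                                                  levels.end()),
                      _["assigned_per_level"] =
                        IntegerVector(assigned_per_level.begin(),
                                      assigned_per_level.end()));
}
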