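// Monte Carlo engine for the off-lattice three-species cyclic-competition
// model.  The full simulation loop lives here; R-level reference
// implementations of the same microscopic rules exist for micro-tests.
//
// RNG draw order per elementary step (fixed contract, relied on by the
// backend-equivalence tests): (1) actor index, (2) action, then
// action-specific draws: move -> angle; predation -> none; reproduction ->
// angle, radius (only when the capacity check passes).

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <cstdint>

using namespace Rcpp;

// splitmix64: tiny, platform-stable generator; quality is ample for these
// simulations and identical streams are guaranteed across compilers.
struct SplitMix64 {
  uint64_t s;
  explicit SplitMix64(uint64_t seed) : s(seed) {}
  uint64_t next() {
    uint64_t z = (s += 0x9E3779B97F4A7C15ULL);
    z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
    z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
    return z ^ (z >> 31);
  }
  // uniform double in [0, 1)
  double runif() { return (next() >> 11) * (1.0 / 9007199254740992.0); }
};

static inline double wrap1(double v, double L) {
  v -= L * std::floor(v / L);
  // rounding can land exactly on L; the interval is half-open
  if (v >= L) v = 0.0;
  if (v < 0) v = 0.0;
  return v;
}

static inline double tdist2(double x1, double y1, double x2, double y2,
                            double L) {
  double dx = std::fabs(x1 - x2);
  if (dx > 0.5 * L) dx = L - dx;
  double dy = std::fabs(y1 - y2);
  if (dy > 0.5 * L) dy = L - dy;
  return dx * dx + dy * dy;
}

// Population container with swap-with-last compaction and an optional
// uniform cell grid kept in sync with positions.
struct Pop {
  std::vector<double> x, y;
  std::vector<int> sp;          // 0 = A, 1 = B, 2 = C
  int counts[3];
  double L;
  bool use_grid;
  int nside;
  double cellw;
  std::vector<std::vector<int>> cells;  // indices of individuals per cell
  std::vector<int> cell_of, pos_in_cell;

  int size() const { return (int)x.size(); }

  int cell_index(double px, double py) const {
    int cx = (int)(px / cellw);
    int cy = (int)(py / cellw);
    if (cx >= nside) cx = nside - 1;
    if (cy >= nside) cy = nside - 1;
    return cy * nside + cx;
  }

  void init_grid(double cell_size) {
    nside = (int)std::floor(L / cell_size);
    use_grid = nside >= 3;  // 3x3 block logic needs >= 3 cells per side
    if (!use_grid) return;
    cellw = L / nside;
    cells.assign((size_t)nside * nside, {});
    cell_of.assign(x.size(), -1);
    pos_in_cell.assign(x.size(), -1);
    for (int i = 0; i < size(); ++i) grid_add(i);
  }

  void grid_add(int i) {
    int c = cell_index(x[i], y[i]);
    cell_of[i] = c;
    pos_in_cell[i] = (int)cells[c].size();
    cells[c].push_back(i);
  }

  void grid_remove(int i) {
    int c = cell_of[i], p = pos_in_cell[i];
    int last = cells[c].back();
    cells[c][p] = last;
    pos_in_cell[last] = p;
    cells[c].pop_back();
  }

  void add(int s, double px, double py) {
    x.push_back(px);
    y.push_back(py);
    sp.push_back(s);
    counts[s]++;
    if (use_grid) {
      cell_of.push_back(-1);
      pos_in_cell.push_back(-1);
      grid_add(size() - 1);
    }
  }

  void remove(int i) {
    counts[sp[i]]--;
    if (use_grid) grid_remove(i);
    int j = size() - 1;
    if (i != j) {
      x[i] = x[j];
      y[i] = y[j];
      sp[i] = sp[j];
      if (use_grid) {
        cell_of[i] = cell_of[j];
        pos_in_cell[i] = pos_in_cell[j];
        cells[cell_of[j]][pos_in_cell[j]] = i;
      }
    }
    x.pop_back();
    y.pop_back();
    sp.pop_back();
    if (use_grid) {
      cell_of.pop_back();
      pos_in_cell.pop_back();
    }
  }

  void move_to(int i, double nx, double ny) {
    x[i] = nx;
    y[i] = ny;
    if (use_grid) {
      int c = cell_index(nx, ny);
      if (c != cell_of[i]) {
        grid_remove(i);
        cell_of[i] = c;
        pos_in_cell[i] = (int)cells[c].size();
        cells[c].push_back(i);
      }
    }
  }

  // closest individual of species `want` within `radius` of individual i
  // (excluding i itself); -1 if none.  Strict < on squared distance keeps
  // grid and brute scans identical (exact ties have measure zero).
  int closest_of(int i, int want, double radius) const {
    double r2 = radius * radius, best = R_PosInf;
    int who = -1;
    if (use_grid) {
      int c = cell_of[i], cx = c % nside, cy = c / nside;
      for (int oy = -1; oy <= 1; ++oy) {
        int yy = cy + oy;
        if (yy < 0) yy += nside; else if (yy >= nside) yy -= nside;
        for (int ox = -1; ox <= 1; ++ox) {
          int xx = cx + ox;
          if (xx < 0) xx += nside; else if (xx >= nside) xx -= nside;
          const std::vector<int>& cc = cells[(size_t)yy * nside + xx];
          for (int j : cc) {
            if (j == i || sp[j] != want) continue;
            double d2 = tdist2(x[i], y[i], x[j], y[j], L);
            if (d2 <= r2 && d2 < best) { best = d2; who = j; }
          }
        }
      }
    } else {
      for (int j = 0; j < size(); ++j) {
        if (j == i || sp[j] != want) continue;
        double d2 = tdist2(x[i], y[i], x[j], y[j], L);
        if (d2 <= r2 && d2 < best) { best = d2; who = j; }
      }
    }
    return who;
  }

  // number of individuals within `radius` of individual i, i included
  int count_within(int i, double radius) const {
    double r2 = radius * radius;
    int n = 0;
    if (use_grid) {
      int c = cell_of[i], cx = c % nside, cy = c / nside;
      for (int oy = -1; oy <= 1; ++oy) {
        int yy = cy + oy;
        if (yy < 0) yy += nside; else if (yy >= nside) yy -= nside;
        for (int ox = -1; ox <= 1; ++ox) {
          int xx = cx + ox;
          if (xx < 0) xx += nside; else if (xx >= nside) xx -= nside;
          const std::vector<int>& cc = cells[(size_t)yy * nside + xx];
          for (int j : cc)
            if (tdist2(x[i], y[i], x[j], y[j], L) <= r2) ++n;
        }
      }
    } else {
      for (int j = 0; j < size(); ++j)
        if (tdist2(x[i], y[i], x[j], y[j], L) <= r2) ++n;
    }
    return n;
  }
};

// Run the full simulation.  `backend`: 0 = cell list, 1 = brute force.
// Returns the recorded counts series, extinction steps (first MC step at
// which each species' count hit zero; -1 if never, relaxation steps count
// negatively from -relax+1..0 and measurement steps 1..measure), the final
// state, and optionally N after every elementary step (small runs only).
// [[Rcpp::export]]
List cpp_run_simulation(double box_length, double pred_radius,
                        double repro_radius, double move_length,
                        double offspring_radius, int capacity,
                        double prob_move, double prob_predate,
                        int init_per_species, int relax_steps,
                        int measure_steps, double seed, int backend,
                        bool return_state, bool record_elementary) {
  Pop pop;
  pop.L = box_length;
  pop.counts[0] = pop.counts[1] = pop.counts[2] = 0;
  pop.use_grid = false;

  SplitMix64 rng((uint64_t)seed + 0x5851F42D4C957F2DULL);

  int k = init_per_species;
  pop.x.reserve(6 * k);
  pop.y.reserve(6 * k);
  pop.sp.reserve(6 * k);
  for (int s = 0; s < 3; ++s)
    for (int i = 0; i < k; ++i) {
      double px = rng.runif() * box_length;
      double py = rng.runif() * box_length;
      pop.x.push_back(px);
      pop.y.push_back(py);
      pop.sp.push_back(s);
      pop.counts[s]++;
    }

  if (backend == 0)
    pop.init_grid(std::max(pred_radius, repro_radius));

  int total = relax_steps + measure_steps;
  IntegerMatrix series(measure_steps, 5);
  IntegerVector extinct(3, -1);
  std::vector<int> elemN;
  if (record_elementary)
    elemN.reserve((size_t)total * (size_t)std::max(3 * k, 1));

  double two_pi = 2.0 * M_PI;

  for (int step = 1; step <= total; ++step) {
    int N0 = pop.size();
    int mc_label = step - relax_steps;  // <=0 during relaxation
    for (int e = 0; e < N0; ++e) {
      int n = pop.size();
      if (n == 0) break;
      int actor = (int)(rng.runif() * n);
      if (actor >= n) actor = n - 1;
      double u = rng.runif();
      if (u < prob_move) {
        double ang = rng.runif() * two_pi;
        double nx = wrap1(pop.x[actor] + move_length * std::cos(ang), box_length);
        double ny = wrap1(pop.y[actor] + move_length * std::sin(ang), box_length);
        pop.move_to(actor, nx, ny);
      } else if (u < prob_move + prob_predate) {
        int prey_sp = (pop.sp[actor] + 1) % 3;
        int victim = pop.closest_of(actor, prey_sp, pred_radius);
        if (victim >= 0) {
          pop.remove(victim);
          if (pop.counts[prey_sp] == 0 && extinct[prey_sp] < 0)
            extinct[prey_sp] = mc_label;
        }
      } else {
        if (pop.count_within(actor, repro_radius) < capacity) {
          double ang = rng.runif() * two_pi;
          double rad = offspring_radius * std::sqrt(rng.runif());
          double nx = wrap1(pop.x[actor] + rad * std::cos(ang), box_length);
          double ny = wrap1(pop.y[actor] + rad * std::sin(ang), box_length);
          pop.add(pop.sp[actor], nx, ny);
        }
      }
      if (record_elementary) elemN.push_back(pop.size());
    }
    if (mc_label >= 1) {
      series(mc_label - 1, 0) = mc_label;
      series(mc_label - 1, 1) = pop.counts[0];
      series(mc_label - 1, 2) = pop.counts[1];
      series(mc_label - 1, 3) = pop.counts[2];
      series(mc_label - 1, 4) = pop.size();
    }
  }

  List out = List::create(_["series"] = series, _["extinct"] = extinct);
  if (return_state) {
    int n = pop.size();
    NumericVector fx(n), fy(n);
    IntegerVector fs(n);
    for (int i = 0; i < n; ++i) {
      fx[i] = pop.x[i];
      fy[i] = pop.y[i];
      fs[i] = pop.sp[i];
    }
    out["x"] = fx;
    out["y"] = fy;
    out["species"] = fs;
  }
  if (record_elementary) out["elementary_N"] = wrap(elemN);
  return out;
}

// Fraction of a probe grid (nprobe x nprobe) farther than `range` from every
// individual: the empty-space metric for coarse-interaction snapshots.
// [[Rcpp::export]]
double cpp_empty_fraction(NumericVector x, NumericVector y, double range,
                          double box_length, int nprobe) {
  int n = x.size();
  double r2 = range * range;
  // bin individuals into a grid with cell width >= range for 3x3 queries
  int nside = (int)std::floor(box_length / range);
  long empty = 0;
  if (nside >= 3) {
    double cellw = box_length / nside;
    std::vector<std::vector<int>> cells((size_t)nside * nside);
    for (int i = 0; i < n; ++i) {
      int cx = (int)(x[i] / cellw);
      int cy = (int)(y[i] / cellw);
      if (cx >= nside) cx = nside - 1;
      if (cy >= nside) cy = nside - 1;
      cells[(size_t)cy * nside + cx].push_back(i);
    }
    for (int a = 0; a < nprobe; ++a)
      for (int b = 0; b < nprobe; ++b) {
        double px = (a + 0.5) * box_length / nprobe;
        double py = (b + 0.5) * box_length / nprobe;
        int cx = (int)(px / cellw);
        if (cx >= nside) cx = nside - 1;
        int cy = (int)(py / cellw);
        if (cy >= nside) cy = nside - 1;
        bool found = false;
        for (int oy = -1; oy <= 1 && !found; ++oy) {
          int yy = cy + oy;
          if (yy < 0) yy += nside; else if (yy >= nside) yy -= nside;
          for (int ox = -1; ox <= 1 && !found; ++ox) {
            int xx = cx + ox;
            if (xx < 0) xx += nside; else if (xx >= nside) xx -= nside;
            for (int j : cells[(size_t)yy * nside + xx])
              if (tdist2(px, py, x[j], y[j], box_length) <= r2) {
                found = true;
                break;
              }
          }
        }
        if (!found) ++empty;
      }
  } else {
    for (int a = 0; a < nprobe; ++a)
      for (int b = 0; b < nprobe; ++b) {
        double px = (a + 0.5) * box_length / nprobe;
        double py = (b + 0.5) * box_length / nprobe;
        bool found = false;
        for (int j = 0; j < n; ++j)
          if (tdist2(px, py, x[j], y[j], box_length) <= r2) {
            found = true;
            break;
          }
        if (!found) ++empty;
      }
  }
  return (double)empty / ((double)nprobe * nprobe);
}
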