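#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Radius-limited animal-trap pair search.
//
// Traps are binned into square cells whose side equals the search radius,
// so every trap within `radius` of an animal lies in the 3x3 cell
// neighbourhood of the animal's own cell.  Animals may fall outside the
// trap bounding box (buffer dwellers); their cell indices are allowed to
// be out of range and only in-range neighbour cells are scanned.
//
// Returns a CSR layout: row_ptr (length n_animals + 1, 0-based offsets),
// trap (0-based trap index per pair) and dist (metres).
// [[Rcpp::export(name = ".pair_search")]]
List pair_search(NumericMatrix animals, NumericMatrix traps, double radius) {
  const int na = animals.nrow(), nt = traps.nrow();
  IntegerVector row_ptr(na + 1);
  if (na == 0 || nt == 0) {
    return List::create(_["row_ptr"] = row_ptr,
                        _["trap"]    = IntegerVector(0),
                        _["dist"]    = NumericVector(0));
  }
  if (!(radius > 0)) stop("search radius must be positive");

  double minx = traps(0, 0), miny = traps(0, 1);
  double maxx = minx, maxy = miny;
  for (int j = 1; j < nt; ++j) {
    minx = std::min(minx, traps(j, 0)); maxx = std::max(maxx, traps(j, 0));
    miny = std::min(miny, traps(j, 1)); maxy = std::max(maxy, traps(j, 1));
  }
  const int nx = (int) std::floor((maxx - minx) / radius) + 1;
  const int ny = (int) std::floor((maxy - miny) / radius) + 1;

  std::vector< std::vector<int> > cells((size_t) nx * ny);
  for (int j = 0; j < nt; ++j) {
    int cx = std::min((int) std::floor((traps(j, 0) - minx) / radius), nx - 1);
    int cy = std::min((int) std::floor((traps(j, 1) - miny) / radius), ny - 1);
    cells[(size_t) cx * ny + cy].push_back(j);
  }

  const double r2 = radius * radius;
  std::vector<int> out_trap;
  std::vector<double> out_dist;
  out_trap.reserve((size_t) na * 4);
  out_dist.reserve((size_t) na * 4);

  std::vector<int> hits;
  for (int i = 0; i < na; ++i) {
    const double ax = animals(i, 0), ay = animals(i, 1);
    const int cx = (int) std::floor((ax - minx) / radius);
    const int cy = (int) std::floor((ay - miny) / radius);
    hits.clear();
    for (int dx = -1; dx <= 1; ++dx) {
      const int gx = cx + dx;
      if (gx < 0 || gx >= nx) continue;
      for (int dy = -1; dy <= 1; ++dy) {
        const int gy = cy + dy;
        if (gy < 0 || gy >= ny) continue;
        const std::vector<int>& cell = cells[(size_t) gx * ny + gy];
        for (size_t k = 0; k < cell.size(); ++k) {
          const int j = cell[k];
          const double ddx = ax - traps(j, 0), ddy = ay - traps(j, 1);
          if (ddx * ddx + ddy * ddy <= r2) hits.push_back(j);
        }
      }
    }
    // canonical within-row order (by trap index): pair order must not
    // depend on the binning geometry, or conditional trap assignment
    // would change with the truncation radius
    std::sort(hits.begin(), hits.end());
    for (size_t k = 0; k < hits.size(); ++k) {
      const int j = hits[k];
      const double ddx = ax - traps(j, 0), ddy = ay - traps(j, 1);
      out_trap.push_back(j);
      out_dist.push_back(std::sqrt(ddx * ddx + ddy * ddy));
    }
    row_ptr[i + 1] = (int) out_trap.size();
  }
  return List::create(_["row_ptr"] = row_ptr,
                      _["trap"]    = wrap(out_trap),
                      _["dist"]    = wrap(out_dist));
}

// One animal's nightly capture attempt against the currently active traps.
// mode 0: competing hazards -- captured with prob 1 - exp(-sum h) over
//         active traps, the capturing trap drawn proportional to hazard.
// mode 1: independent Bernoulli per active pair, captured if any success,
//         the trap drawn uniformly among that night's successes.
// Returns the 0-based trap index, or -1 for no capture.
static inline int attempt_capture(int a, const int* rp, const int* tr,
                                  const double* hz, const double* pb,
                                  const int* remaining, int mode,
                                  std::vector<int>& scratch) {
  const int s = rp[a], e = rp[a + 1];
  if (mode == 0) {
    double H = 0.0;
    for (int k = s; k < e; ++k) if (remaining[tr[k]] > 0) H += hz[k];
    if (H <= 0.0) return -1;
    if (unif_rand() >= 1.0 - std::exp(-H)) return -1;
    const double target = unif_rand() * H;
    double cum = 0.0;
    int jsel = -1;
    for (int k = s; k < e; ++k) {
      const int j = tr[k];
      if (remaining[j] > 0) {
        jsel = j;                     // guards against FP shortfall at the tail
        cum += hz[k];
        if (cum >= target) break;
      }
    }
    return jsel;
  }
  scratch.clear();
  for (int k = s; k < e; ++k) {
    const int j = tr[k];
    if (remaining[j] > 0 && unif_rand() < pb[k]) scratch.push_back(j);
  }
  if (scratch.empty()) return -1;
  int idx = (int) (unif_rand() * scratch.size());
  if (idx >= (int) scratch.size()) idx = (int) scratch.size() - 1;
  return scratch[idx];
}

// Resolve a single night.  `remaining` and `status` are modified in place
// (R callers pass freshly allocated copies).  `order` holds the 0-based ids
// of the at-large animals in processing order; status codes are
// 0 = pending (not yet immigrated), 1 = at large, 2 = captured.
// [[Rcpp::export(name = ".night_kernel")]]
List night_kernel(IntegerVector row_ptr, IntegerVector trap,
                  NumericVector hazard, NumericVector prob,
                  IntegerVector remaining, IntegerVector status,
                  IntegerVector order, int mode) {
  const int* rp = INTEGER(row_ptr);
  const int* tr = trap.size() ? INTEGER(trap) : NULL;
  const double* hz = hazard.size() ? REAL(hazard) : NULL;
  const double* pb = prob.size() ? REAL(prob) : NULL;
  int* rem = INTEGER(remaining);
  int* st = INTEGER(status);
  std::vector<int> scratch;
  std::vector<int> cap_a, cap_t;
  for (int i = 0; i < order.size(); ++i) {
    const int a = order[i];
    if (st[a] != 1) continue;
    const int j = attempt_capture(a, rp, tr, hz, pb, rem, mode, scratch);
    if (j >= 0) {
      rem[j] -= 1;
      st[a] = 2;
      cap_a.push_back(a + 1);
      cap_t.push_back(j + 1);
    }
  }
  return List::create(_["animal"] = wrap(cap_a), _["trap"] = wrap(cap_t));
}

// Full replicate: activates animals on their entry night, shuffles the
// at-large animals uniformly each night (trap saturation earlier in a night
// affects animals processed later), and removes captured animals.
// [[Rcpp::export(name = ".run_replicate_kernel")]]
List run_replicate_kernel(IntegerVector row_ptr, IntegerVector trap,
                          NumericVector hazard, NumericVector prob,
                          int n_traps, int capacity,
                          IntegerVector entry_night, int nights, int mode) {
  const int n = row_ptr.size() - 1;
  const int* rp = INTEGER(row_ptr);
  const int* tr = trap.size() ? INTEGER(trap) : NULL;
  const double* hz = hazard.size() ? REAL(hazard) : NULL;
  const double* pb = prob.size() ? REAL(prob) : NULL;

  std::vector<int> rem((size_t) n_traps, capacity);
  std::vector<int> st((size_t) n, 0);
  IntegerVector trap_counts(n_traps);
  IntegerVector fate_night(n, NA_INTEGER), fate_trap(n, NA_INTEGER);

  std::vector<int> alive;
  alive.reserve((size_t) n);
  std::vector<int> scratch;

  for (int night = 1; night <= nights; ++night) {
    for (int a = 0; a < n; ++a)
      if (st[a] == 0 && entry_night[a] == night) { st[a] = 1; alive.push_back(a); }
    // Fisher-Yates over the current at-large list
    for (int i = (int) alive.size() - 1; i > 0; --i) {
      int j = (int) (unif_rand() * (i + 1));
      if (j > i) j = i;
      std::swap(alive[i], alive[j]);
    }
    size_t keep = 0;
    for (size_t i = 0; i < alive.size(); ++i) {
      const int a = alive[i];
      const int j = attempt_capture(a, rp, tr, hz, pb, rem.data(), mode, scratch);
      if (j >= 0) {
        rem[j] -= 1;
        st[a] = 2;
        trap_counts[j] += 1;
        fate_night[a] = night;
        fate_trap[a] = j + 1;
      } else {
        alive[keep++] = a;
      }
    }
    alive.resize(keep);
  }
  return List::create(_["trap_counts"] = trap_counts,
                      _["fate_night"] = fate_night,
                      _["fate_trap"]  = fate_trap);
}
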