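// Hard-rectangle Monte Carlo core: separating-axis overlap tests, random
// sequential insertion, and Metropolis translation/rotation sweeps on a
// periodic square box. Positions in nm; orientations in radians.
#include <Rcpp.h>
#include <random>
using namespace Rcpp;

static inline double min_image(double d, double box) {
  if (d > 0.5 * box) d -= box;
  else if (d < -0.5 * box) d += box;
  return d;
}

// Separating-axis test for two rectangles (centre, orientation, half-length,
// half-width) under minimal-image convention. Touching counts as separated.
static bool rects_overlap(double x1, double y1, double t1, double hl1, double hw1,
                          double x2, double y2, double t2, double hl2, double hw2,
                          double box) {
  double dx = min_image(x2 - x1, box);
  double dy = min_image(y2 - y1, box);
  // circumcircle prefilter
  double rc = std::sqrt(hl1 * hl1 + hw1 * hw1) + std::sqrt(hl2 * hl2 + hw2 * hw2);
  if (dx * dx + dy * dy >= rc * rc) return false;

  double c1 = std::cos(t1), s1 = std::sin(t1);
  double c2 = std::cos(t2), s2 = std::sin(t2);
  // axes: u1, v1, u2, v2
  double ax[4][2] = {{c1, s1}, {-s1, c1}, {c2, s2}, {-s2, c2}};
  for (int k = 0; k < 4; ++k) {
    double a0 = ax[k][0], a1 = ax[k][1];
    double proj = std::fabs(dx * a0 + dy * a1);
    double ext = hl1 * std::fabs(c1 * a0 + s1 * a1) +
                 hw1 * std::fabs(-s1 * a0 + c1 * a1) +
                 hl2 * std::fabs(c2 * a0 + s2 * a1) +
                 hw2 * std::fabs(-s2 * a0 + c2 * a1);
    if (proj >= ext) return false;
  }
  return true;
}

// [[Rcpp::export]]
bool rect_pair_overlap_cpp(NumericVector p1, NumericVector p2,
                           double hl1, double hw1, double hl2, double hw2,
                           double box) {
  return rects_overlap(p1[0], p1[1], p1[2], hl1, hw1,
                       p2[0], p2[1], p2[2], hl2, hw2, box);
}

static bool overlaps_any(const NumericMatrix& st, const NumericVector& hl,
                         const NumericVector& hw, double box, int i,
                         double xi, double yi, double ti) {
  int n = st.nrow();
  for (int j = 0; j < n; ++j) {
    if (j == i) continue;
    if (rects_overlap(xi, yi, ti, hl[i], hw[i],
                      st(j, 0), st(j, 1), st(j, 2), hl[j], hw[j], box))
      return true;
  }
  return false;
}

// Index (1-based) of the first particle overlapping any other, or 0.
// [[Rcpp::export]]
int first_overlap_cpp(NumericMatrix st, NumericVector hl, NumericVector hw,
                      double box) {
  int n = st.nrow();
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j)
      if (rects_overlap(st(i, 0), st(i, 1), st(i, 2), hl[i], hw[i],
                        st(j, 0), st(j, 1), st(j, 2), hl[j], hw[j], box))
        return i + 1;
  return 0;
}

// [[Rcpp::export]]
bool particle_overlaps_cpp(NumericMatrix st, NumericVector hl, NumericVector hw,
                           double box, int i) {
  return overlaps_any(st, hl, hw, box, i - 1,
                      st(i - 1, 0), st(i - 1, 1), st(i - 1, 2));
}

// Random sequential insertion of n rectangles; returns n x 3 (x, y, theta)
// or throws after max_attempts failed placements.
// [[Rcpp::export]]
NumericMatrix rsa_insert_cpp(int n, double hl, double hw, double box,
                             int seed, double max_attempts) {
  std::mt19937_64 rng(static_cast<uint64_t>(seed));
  std::uniform_real_distribution<double> U(0.0, 1.0);
  NumericMatrix st(n, 3);
  NumericVector hls(n, hl), hws(n, hw);
  double attempts = 0;
  int placed = 0;
  while (placed < n) {
    if (++attempts > max_attempts)
      stop("random sequential insertion failed after %g attempts: "
           "requested coverage too high for these rectangles", max_attempts);
    double x = U(rng) * box, y = U(rng) * box, t = U(rng) * M_PI;
    bool ok = true;
    for (int j = 0; j < placed && ok; ++j)
      if (rects_overlap(x, y, t, hl, hw,
                        st(j, 0), st(j, 1), st(j, 2), hl, hw, box))
        ok = false;
    if (ok) {
      st(placed, 0) = x; st(placed, 1) = y; st(placed, 2) = t;
      ++placed;
    }
  }
  return st;
}

// Metropolis sweeps: each sweep makes n single-particle moves, alternating
// translation and rotation proposals at random; hard-core rejection only.
// [[Rcpp::export]]
List mc_sweeps_cpp(NumericMatrix state, NumericVector hl, NumericVector hw,
                   double box, double tstep, double rstep, int sweeps,
                   int seed) {
  NumericMatrix st = clone(state);
  int n = st.nrow();
  std::mt19937_64 rng(static_cast<uint64_t>(seed));
  std::uniform_real_distribution<double> U(0.0, 1.0);
  long long accepted = 0, total = 0;
  for (int s = 0; s < sweeps; ++s) {
    for (int m = 0; m < n; ++m) {
      int i = static_cast<int>(U(rng) * n);
      if (i == n) i = n - 1;
      double xi = st(i, 0), yi = st(i, 1), ti = st(i, 2);
      if (U(rng) < 0.5) {
        xi += (U(rng) - 0.5) * 2.0 * tstep;
        yi += (U(rng) - 0.5) * 2.0 * tstep;
        xi -= box * std::floor(xi / box);
        yi -= box * std::floor(yi / box);
      } else {
        ti += (U(rng) - 0.5) * 2.0 * rstep;
      }
      ++total;
      if (!overlaps_any(st, hl, hw, box, i, xi, yi, ti)) {
        st(i, 0) = xi; st(i, 1) = yi; st(i, 2) = ti;
        ++accepted;
      }
    }
  }
  return List::create(_["state"] = st,
                      _["acceptance"] = total ? double(accepted) / double(total) : NA_REAL);
}
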