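#include <Rcpp.h>
using namespace Rcpp;

// Minimum Euclidean distance from each query point to a vertex cloud.
// [[Rcpp::export(name = ".min_dist_to_vertices_cpp")]]
NumericVector min_dist_to_vertices_cpp(NumericMatrix points,
                                       NumericMatrix vertices) {
  int n = points.nrow(), m = vertices.nrow();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    double best = R_PosInf;
    double px = points(i, 0), py = points(i, 1);
    for (int j = 0; j < m; ++j) {
      double dx = px - vertices(j, 0), dy = py - vertices(j, 1);
      double d2 = dx * dx + dy * dy;
      if (d2 < best) best = d2;
    }
    out[i] = std::sqrt(best);
  }
  return out;
}

// Fraction of path vertices closer than d to previous-path vertices or to
// non-neighbouring vertices of the same path (index gap > skip).
// [[Rcpp::export(name = ".path_overlap_fraction_cpp")]]
double path_overlap_fraction_cpp(NumericMatrix path,
                                 Nullable<NumericMatrix> prev_,
                                 double d, int skip) {
  int n = path.nrow();
  if (n == 0) return 0.0;
  double d2max = d * d;
  int n_near = 0;
  NumericMatrix prev;
  int m = 0;
  if (prev_.isNotNull()) { prev = prev_.get(); m = prev.nrow(); }
  for (int i = 0; i < n; ++i) {
    bool near = false;
    double px = path(i, 0), py = path(i, 1);
    for (int j = 0; j < m && !near; ++j) {
      double dx = px - prev(j, 0), dy = py - prev(j, 1);
      if (dx * dx + dy * dy < d2max) near = true;
    }
    for (int j = 0; j < n && !near; ++j) {
      if (std::abs(i - j) <= skip) continue;
      double dx = px - path(j, 0), dy = py - path(j, 1);
      if (dx * dx + dy * dy < d2max) near = true;
    }
    if (near) ++n_near;
  }
  return (double)n_near / n;
}

// Smoothed random walk for one axis path: AR(1)-correlated heading
// increments, boundary steering, and a summed soft repulsion from already
// placed vertices and the walk's own earlier vertices. Uses R's RNG.
// [[Rcpp::export(name = ".axis_walk_cpp")]]
NumericMatrix axis_walk_cpp(NumericVector centre, double R,
                            NumericVector start, double h0, int n_steps,
                            Nullable<NumericMatrix> blocked_,
                            double step, double turn_sd, double ar,
                            double max_turn, double rep_dist,
                            double k_rep, double k_bnd, int own_guard) {
  NumericMatrix out(n_steps + 1, 2);
  double posx = start[0], posy = start[1];
  out(0, 0) = posx; out(0, 1) = posy;
  double h = h0, dh_prev = 0.0;
  NumericMatrix blocked;
  int m = 0;
  if (blocked_.isNotNull()) { blocked = blocked_.get(); m = blocked.nrow(); }
  double noise_sd = turn_sd * std::sqrt(1.0 - ar * ar);
  double rep2 = rep_dist * rep_dist;

  for (int t = 1; t <= n_steps; ++t) {
    double dh = ar * dh_prev + R::rnorm(0.0, noise_sd);
    // boundary steering back toward the centre
    double vx = centre[0] - posx, vy = centre[1] - posy;
    double r = std::sqrt(vx * vx + vy * vy);
    if (r > 0.75 * R) {
      double want = std::atan2(vy, vx);
      double dd = std::atan2(std::sin(want - h), std::cos(want - h));
      double mag = std::min(std::fabs(dd), 0.5);
      dh += k_bnd * ((r - 0.75 * R) / (0.25 * R)) *
        (dd >= 0 ? mag : -mag);
    }
    // summed repulsion from blocked vertices and own earlier vertices
    double rx = 0.0, ry = 0.0, dmin2 = R_PosInf;
    for (int j = 0; j < m; ++j) {
      double dx = posx - blocked(j, 0), dy = posy - blocked(j, 1);
      double d2 = dx * dx + dy * dy;
      if (d2 < rep2 && d2 > 1e-18) {
        double d = std::sqrt(d2);
        double w = (1.0 - d / rep_dist) * (1.0 - d / rep_dist) / d;
        rx += dx * w; ry += dy * w;
        if (d2 < dmin2) dmin2 = d2;
      }
    }
    int lim = t - 1 - own_guard;
    for (int j = 0; j <= lim; ++j) {
      double dx = posx - out(j, 0), dy = posy - out(j, 1);
      double d2 = dx * dx + dy * dy;
      if (d2 < rep2 && d2 > 1e-18) {
        double d = std::sqrt(d2);
        double w = (1.0 - d / rep_dist) * (1.0 - d / rep_dist) / d;
        rx += dx * w; ry += dy * w;
        if (d2 < dmin2) dmin2 = d2;
      }
    }
    if (R_finite(dmin2)) {
      double away = std::atan2(ry, rx);
      double dd = std::atan2(std::sin(away - h), std::cos(away - h));
      double mag = std::min(std::sqrt(rx * rx + ry * ry), 2.0);
      double cap = std::min(std::fabs(dd), 0.6);
      dh += k_rep * mag * (dd >= 0 ? cap : -cap) / 2.0;
      if (dmin2 < 0.09) {  // 0.3 um emergency turn
        dh = (dd >= 0 ? max_turn : -max_turn);
        dh_prev = dh;
      }
    }
    if (dh > max_turn) dh = max_turn;
    if (dh < -max_turn) dh = -max_turn;
    h += dh; dh_prev = dh;
    posx += step * std::cos(h);
    posy += step * std::sin(h);
    double rrx = posx - centre[0], rry = posy - centre[1];
    double rr = std::sqrt(rrx * rrx + rry * rry);
    if (rr > 0.95 * R) {
      posx = centre[0] + rrx * (0.95 * R / rr);
      posy = centre[1] + rry * (0.95 * R / rr);
    }
    out(t, 0) = posx; out(t, 1) = posy;
  }
  return out;
}
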