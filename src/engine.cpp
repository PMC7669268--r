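// Agent-based swarming engine.
//
// Agents are non-overlapping spheres in a cylindrical well containing a
// concentric tumouroid disc region. Outside the tumouroid they re-enact
// bootstrapped motility blocks (rotated about z toward the sensed chemokine
// gradient when chemotactic); inside they drift toward the centre and, in
// the positive-attraction scenario, secrete chemokine. Concentrations are
// resolved by free-space heat-kernel superposition over the secretion-event
// log.
//
// All randomness flows from one std::mt19937_64 seeded from the config;
// uniform/normal/shuffle transforms are written out below (rather than
// std:: distributions) so runs are bit-reproducible across compilers.

#include <Rcpp.h>
#include <cmath>
#include <cstdint>
#include <random>
#include <vector>

using namespace Rcpp;

namespace {

constexpr double GRAD_EPS = 1e-30; // gradient norms below this count as zero

struct Rng {
  std::mt19937_64 g;
  bool have_spare = false;
  double spare = 0.0;
  explicit Rng(uint64_t seed) : g(seed) {}
  double unif() { // [0, 1)
    return (g() >> 11) * (1.0 / 9007199254740992.0);
  }
  double normal() { // Box-Muller, cached pair
    if (have_spare) { have_spare = false; return spare; }
    double u1, u2;
    do { u1 = unif(); } while (u1 <= 0.0);
    u2 = unif();
    double r = std::sqrt(-2.0 * std::log(u1));
    spare = r * std::sin(2.0 * M_PI * u2);
    have_spare = true;
    return r * std::cos(2.0 * M_PI * u2);
  }
  int randint(int n) { // uniform on 0..n-1 (rejection)
    uint64_t span = static_cast<uint64_t>(n);
    uint64_t lim = UINT64_MAX - UINT64_MAX % span;
    uint64_t v;
    do { v = g(); } while (v >= lim);
    return static_cast<int>(v % span);
  }
  template <typename T> void shuffle(std::vector<T>& v) { // Fisher-Yates
    for (int i = static_cast<int>(v.size()) - 1; i > 0; --i)
      std::swap(v[i], v[randint(i + 1)]);
  }
};

// ---------------------------------------------------------------------------
// heat-kernel sums (shared by the R-level chemokine_field API and the engine)

struct EventLog {
  std::vector<double> x, y, z, t, q;
  size_t size() const { return x.size(); }
};

double kernel_sum(const EventLog& ev, double px, double py, double pz,
                  double t, double D) {
  double c = 0.0;
  for (size_t i = 0; i < ev.size(); ++i) {
    double tau = t - ev.t[i];
    if (tau <= 0.0) continue;
    double denom = 4.0 * M_PI * D * tau;
    double f = ev.q[i] / (denom * std::sqrt(denom));
    double dx = px - ev.x[i], dy = py - ev.y[i], dz = pz - ev.z[i];
    double r2 = dx * dx + dy * dy + dz * dz;
    c += f * std::exp(-r2 / (4.0 * D * tau));
  }
  return c;
}

// six probe points on the sphere extremity (+x,-x,+y,-y,+z,-z); central
// differences give the gradient, max of the six values the perceived peak
void probe_sum(const EventLog& ev, double px, double py, double pz,
               double radius, double t, double D,
               double c[6], double grad[3], double& maxc) {
  for (int p = 0; p < 6; ++p) c[p] = 0.0;
  const double ox[6] = {radius, -radius, 0, 0, 0, 0};
  const double oy[6] = {0, 0, radius, -radius, 0, 0};
  const double oz[6] = {0, 0, 0, 0, radius, -radius};
  for (size_t i = 0; i < ev.size(); ++i) {
    double tau = t - ev.t[i];
    if (tau <= 0.0) continue;
    double denom = 4.0 * M_PI * D * tau;
    double f = ev.q[i] / (denom * std::sqrt(denom));
    double inv4dt = 1.0 / (4.0 * D * tau);
    double dx = px - ev.x[i], dy = py - ev.y[i], dz = pz - ev.z[i];
    for (int p = 0; p < 6; ++p) {
      double ddx = dx + ox[p], ddy = dy + oy[p], ddz = dz + oz[p];
      double r2 = ddx * ddx + ddy * ddy + ddz * ddz;
      c[p] += f * std::exp(-r2 * inv4dt);
    }
  }
  grad[0] = (c[0] - c[1]) / (2.0 * radius);
  grad[1] = (c[2] - c[3]) / (2.0 * radius);
  grad[2] = (c[4] - c[5]) / (2.0 * radius);
  maxc = c[0];
  for (int p = 1; p < 6; ++p) maxc = std::max(maxc, c[p]);
}

EventLog as_event_log(const NumericMatrix& events) {
  EventLog ev;
  size_t n = events.nrow();
  ev.x.resize(n); ev.y.resize(n); ev.z.resize(n);
  ev.t.resize(n); ev.q.resize(n);
  for (size_t i = 0; i < n; ++i) {
    ev.x[i] = events(i, 0); ev.y[i] = events(i, 1); ev.z[i] = events(i, 2);
    ev.t[i] = events(i, 3); ev.q[i] = events(i, 4);
  }
  return ev;
}

// ---------------------------------------------------------------------------

class SwarmEngine {
 public:
  // geometry / parameters
  double wellR, tumR, height, cx, cy;
  double agentD, agentR;
  double dt;            // s
  int scenario;         // 0 = no_attraction, 1 = positive_attraction
  double intraSpeed;    // um/min
  double secretionRate; // molecules/min
  double D;             // um^2/s
  double coalesceWin;   // s
  double actMed, desMed, sigmaLog;
  // pools: n_blocks x 3k step matrices
  NumericMatrix undB, cheB;
  int k; // steps per block
  double undRef[2], cheRef[2];
  // agents
  int n;
  std::vector<double> px, py, pz, act, des;
  std::vector<int> mode, cursor; // mode 0 undirected, 1 chemotactic, 2 intra
  std::vector<double> blk;       // n * 3k rotated current-block steps
  std::vector<char> hasBlk;
  // field
  EventLog ev;
  std::vector<int> lastEv;
  double totSecreted = 0.0;
  long long chemoSteps = 0, blockedMoves = 0;
  double t = 0.0; // s
  Rng rng;
  // collision grid
  double cell, gx0, gy0;
  int ngx, ngy, ngz;
  std::vector<int> head, nxt, cellOf;

  SwarmEngine(List cfg, NumericMatrix und, NumericMatrix che,
              NumericVector undRefV, NumericVector cheRefV)
      : undB(und), cheB(che), rng(static_cast<uint64_t>(as<int>(cfg["seed"]))) {
    wellR = as<double>(cfg["well_radius"]);
    tumR = as<double>(cfg["tumouroid_radius"]);
    height = as<double>(cfg["height"]);
    cx = as<double>(cfg["cx"]);
    cy = as<double>(cfg["cy"]);
    agentD = as<double>(cfg["agent_diameter"]);
    agentR = agentD / 2.0;
    dt = as<double>(cfg["dt"]);
    scenario = as<int>(cfg["scenario"]);
    intraSpeed = as<double>(cfg["intratumoural_speed"]);
    secretionRate = as<double>(cfg["secretion_rate"]);
    D = as<double>(cfg["diffusion_coefficient"]);
    coalesceWin = as<double>(cfg["coalescing_window_s"]);
    actMed = as<double>(cfg["actuation_median"]);
    desMed = as<double>(cfg["desensitisation_median"]);
    sigmaLog = as<double>(cfg["sigma_log"]);
    n = as<int>(cfg["n_agents"]);
    k = und.ncol() / 3;
    if (che.ncol() != und.ncol())
      stop("pools must share the same block length");
    undRef[0] = undRefV[0]; undRef[1] = undRefV[1];
    cheRef[0] = cheRefV[0]; cheRef[1] = cheRefV[1];

    cell = agentD;
    gx0 = cx - wellR; gy0 = cy - wellR;
    ngx = static_cast<int>(std::ceil(2.0 * wellR / cell)) + 2;
    ngy = ngx;
    ngz = static_cast<int>(std::ceil(height / cell)) + 2;
    head.assign(static_cast<size_t>(ngx) * ngy * ngz, -1);
    nxt.assign(n, -1);
    cellOf.assign(n, -1);

    px.assign(n, 0); py.assign(n, 0); pz.assign(n, 0);
    act.assign(n, 0); des.assign(n, 0);
    mode.assign(n, 0);
    cursor.assign(n, 0);
    blk.assign(static_cast<size_t>(n) * 3 * k, 0.0);
    hasBlk.assign(n, 0);
    lastEv.assign(n, -1);
    place_agents();
    sample_thresholds();
  }

  int cell_index(double x, double y, double z) const {
    int ix = static_cast<int>((x - gx0) / cell);
    int iy = static_cast<int>((y - gy0) / cell);
    int iz = static_cast<int>(z / cell);
    ix = std::min(std::max(ix, 0), ngx - 1);
    iy = std::min(std::max(iy, 0), ngy - 1);
    iz = std::min(std::max(iz, 0), ngz - 1);
    return (iz * ngy + iy) * ngx + ix;
  }

  void grid_insert(int i) {
    int ci = cell_index(px[i], py[i], pz[i]);
    cellOf[i] = ci;
    nxt[i] = head[ci];
    head[ci] = i;
  }

  void grid_remove(int i) {
    int ci = cellOf[i];
    int j = head[ci];
    if (j == i) { head[ci] = nxt[i]; return; }
    while (nxt[j] != i) j = nxt[j];
    nxt[j] = nxt[i];
  }

  bool blocked(int self, double x, double y, double z) const {
    int ix = static_cast<int>((x - gx0) / cell);
    int iy = static_cast<int>((y - gy0) / cell);
    int iz = static_cast<int>(z / cell);
    double d2min = agentD * agentD;
    for (int a = ix - 1; a <= ix + 1; ++a) {
      if (a < 0 || a >= ngx) continue;
      for (int b = iy - 1; b <= iy + 1; ++b) {
        if (b < 0 || b >= ngy) continue;
        for (int c = iz - 1; c <= iz + 1; ++c) {
          if (c < 0 || c >= ngz) continue;
          for (int j = head[(c * ngy + b) * ngx + a]; j >= 0; j = nxt[j]) {
            if (j == self) continue;
            double dx = px[j] - x, dy = py[j] - y, dz = pz[j] - z;
            if (dx * dx + dy * dy + dz * dz < d2min) return true;
          }
        }
      }
    }
    return false;
  }

  void place_agents() {
    // uniform over the annulus (outside tumouroid, inside well), z in
    // [0, height]; rejection keeps agents non-overlapping
    long long attempts = 0, max_attempts = 200LL * n + 1000;
    double rt2 = tumR * tumR, rw2 = wellR * wellR;
    for (int i = 0; i < n; ++i) {
      for (;;) {
        if (++attempts > max_attempts)
          stop("packing infeasible: could not place %d non-overlapping "
               "agents of diameter %g in the annular arena", n, agentD);
        double rho = std::sqrt(rt2 + rng.unif() * (rw2 - rt2));
        if (rho <= tumR) continue; // strictly outside the tumouroid
        double th = 2.0 * M_PI * rng.unif();
        double x = cx + rho * std::cos(th);
        double y = cy + rho * std::sin(th);
        double z = rng.unif() * height;
        if (blocked(i, x, y, z)) continue;
        px[i] = x; py[i] = y; pz[i] = z;
        grid_insert(i);
        break;
      }
    }
  }

  void sample_thresholds() {
    for (int i = 0; i < n; ++i) {
      double a, d;
      do {
        a = actMed * std::exp(sigmaLog * rng.normal());
        d = desMed * std::exp(sigmaLog * rng.normal());
      } while (!(a < d));
      act[i] = a;
      des[i] = d;
    }
  }

  void secrete(int i, double q) {
    int le = lastEv[i];
    if (le >= 0 && coalesceWin > 0.0 && (t - ev.t[le]) <= coalesceWin) {
      double dx = px[i] - ev.x[le], dy = py[i] - ev.y[le],
             dz = pz[i] - ev.z[le];
      if (dx * dx + dy * dy + dz * dz <= agentR * agentR) {
        double w1 = ev.q[le], tot = w1 + q;
        ev.x[le] = (w1 * ev.x[le] + q * px[i]) / tot;
        ev.y[le] = (w1 * ev.y[le] + q * py[i]) / tot;
        ev.z[le] = (w1 * ev.z[le] + q * pz[i]) / tot;
        ev.t[le] = (w1 * ev.t[le] + q * t) / tot;
        ev.q[le] = tot;
        totSecreted += q;
        return;
      }
    }
    ev.x.push_back(px[i]); ev.y.push_back(py[i]); ev.z.push_back(pz[i]);
    ev.t.push_back(t); ev.q.push_back(q);
    lastEv[i] = static_cast<int>(ev.size()) - 1;
    totSecreted += q;
  }

  void project_boundary(double& x, double& y, double& z) const {
    if (z < 0.0) z = 0.0;
    if (z > height) z = height;
    double dx = x - cx, dy = y - cy;
    double r = std::sqrt(dx * dx + dy * dy);
    if (r > wellR) {
      double s = wellR / r;
      x = cx + dx * s;
      y = cy + dy * s;
    }
  }

  void try_move(int i, double x, double y, double z) {
    if (blocked(i, x, y, z)) { ++blockedMoves; return; }
    grid_remove(i);
    px[i] = x; py[i] = y; pz[i] = z;
    grid_insert(i);
  }

  void load_block(int i, const NumericMatrix& pool, int b, double theta) {
    double ct = std::cos(theta), st = std::sin(theta);
    double* dst = &blk[static_cast<size_t>(i) * 3 * k];
    for (int s = 0; s < k; ++s) {
      double sx = pool(b, 3 * s), sy = pool(b, 3 * s + 1),
             sz = pool(b, 3 * s + 2);
      dst[3 * s] = ct * sx - st * sy;
      dst[3 * s + 1] = st * sx + ct * sy;
      dst[3 * s + 2] = sz;
    }
    cursor[i] = 0;
    hasBlk[i] = 1;
  }

  void step_agent(int i) {
    double dxc = px[i] - cx, dyc = py[i] - cy;
    double rxy = std::sqrt(dxc * dxc + dyc * dyc);
    if (mode[i] == 2 || rxy < tumR) {
      // intratumoural: drift toward the centre in xy, z held; no exit path
      mode[i] = 2;
      hasBlk[i] = 0;
      double step = intraSpeed * dt / 60.0;
      double nx, ny;
      if (rxy <= step) {
        nx = cx; ny = cy;
      } else {
        nx = px[i] - step * dxc / rxy;
        ny = py[i] - step * dyc / rxy;
      }
      try_move(i, nx, ny, pz[i]);
      if (scenario == 1) secrete(i, secretionRate * dt / 60.0);
      return;
    }
    if (!hasBlk[i] || cursor[i] >= k) {
      // block boundary: re-evaluate behavioural mode from the field
      int m = 0;
      double tgx = 0.0, tgy = 0.0;
      if (ev.size() > 0) {
        double c[6], grad[3], maxc;
        probe_sum(ev, px[i], py[i], pz[i], agentR, t, D, c, grad, maxc);
        double gnorm = std::sqrt(grad[0] * grad[0] + grad[1] * grad[1] +
                                 grad[2] * grad[2]);
        double gxy = std::sqrt(grad[0] * grad[0] + grad[1] * grad[1]);
        if (maxc > act[i] && maxc < des[i] && gnorm > GRAD_EPS &&
            gxy > GRAD_EPS) {
          m = 1;
          tgx = grad[0] / gxy;
          tgy = grad[1] / gxy;
        }
      }
      mode[i] = m;
      if (m == 1) {
        int b = rng.randint(cheB.nrow());
        double theta =
            std::atan2(tgy, tgx) - std::atan2(cheRef[1], cheRef[0]);
        load_block(i, cheB, b, theta);
      } else {
        // undirected blocks get a uniform z-rotation so replays do not
        // inherit the source arena's anisotropy
        int b = rng.randint(undB.nrow());
        load_block(i, undB, b, 2.0 * M_PI * rng.unif());
      }
    }
    if (mode[i] == 1) ++chemoSteps;
    const double* s = &blk[static_cast<size_t>(i) * 3 * k + 3 * cursor[i]];
    ++cursor[i]; // cursor advances even if the move is rejected
    double nx = px[i] + s[0], ny = py[i] + s[1], nz = pz[i] + s[2];
    project_boundary(nx, ny, nz);
    try_move(i, nx, ny, nz);
  }

  void do_steps(int n_steps) {
    std::vector<int> order(n);
    for (int i = 0; i < n; ++i) order[i] = i;
    for (int s = 0; s < n_steps; ++s) {
      rng.shuffle(order);
      for (int i : order) step_agent(i);
      t += dt;
      if (s % 64 == 0) Rcpp::checkUserInterrupt();
    }
  }
};

}  // namespace

// ---------------------------------------------------------------------------
// exported helpers

// [[Rcpp::export]]
NumericVector cpp_concentration(NumericMatrix events, NumericMatrix points,
                                double t, double D) {
  EventLog ev = as_event_log(events);
  int np = points.nrow();
  NumericVector out(np);
  for (int i = 0; i < np; ++i)
    out[i] = kernel_sum(ev, points(i, 0), points(i, 1), points(i, 2), t, D);
  return out;
}

// [[Rcpp::export]]
List cpp_gradient_probe(NumericMatrix events, NumericVector centre,
                        double radius, double t, double D) {
  EventLog ev = as_event_log(events);
  double c[6], grad[3], maxc;
  probe_sum(ev, centre[0], centre[1], centre[2], radius, t, D, c, grad, maxc);
  return List::create(_["gradient"] = NumericVector::create(grad[0], grad[1],
                                                            grad[2]),
                      _["max_concentration"] = maxc,
                      _["probe_values"] = NumericVector(c, c + 6));
}

// ---------------------------------------------------------------------------
// engine lifecycle

// [[Rcpp::export]]
SEXP engine_create(List cfg, NumericMatrix und, NumericMatrix che,
                   NumericVector und_ref, NumericVector che_ref) {
  XPtr<SwarmEngine> ptr(new SwarmEngine(cfg, und, che, und_ref, che_ref),
                        true);
  return ptr;
}

// [[Rcpp::export]]
void engine_steps(SEXP eng, int n_steps) {
  XPtr<SwarmEngine> p(eng);
  p->do_steps(n_steps);
}

// [[Rcpp::export]]
List engine_state(SEXP eng) {
  XPtr<SwarmEngine> p(eng);
  int n = p->n;
  NumericMatrix pos(n, 3);
  IntegerVector mode(n), cursor(n);
  NumericVector act(n), des(n);
  for (int i = 0; i < n; ++i) {
    pos(i, 0) = p->px[i]; pos(i, 1) = p->py[i]; pos(i, 2) = p->pz[i];
    mode[i] = p->mode[i];
    cursor[i] = p->cursor[i];
    act[i] = p->act[i];
    des[i] = p->des[i];
  }
  size_t ne = p->ev.size();
  NumericMatrix events(ne, 5);
  for (size_t i = 0; i < ne; ++i) {
    events(i, 0) = p->ev.x[i]; events(i, 1) = p->ev.y[i];
    events(i, 2) = p->ev.z[i]; events(i, 3) = p->ev.t[i];
    events(i, 4) = p->ev.q[i];
  }
  colnames(events) = CharacterVector::create("x", "y", "z", "t", "q");
  return List::create(
      _["t"] = p->t, _["positions"] = pos, _["mode"] = mode,
      _["cursor"] = cursor, _["actuation"] = act, _["desensitisation"] = des,
      _["events"] = events, _["total_secreted"] = p->totSecreted,
      _["chemotactic_steps"] = static_cast<double>(p->chemoSteps),
      _["blocked_moves"] = static_cast<double>(p->blockedMoves));
}

// [[Rcpp::export]]
void engine_set_positions(SEXP eng, NumericMatrix pos) {
  // test/checkpoint hook: overwrite agent positions and rebuild the grid
  XPtr<SwarmEngine> p(eng);
  if (pos.nrow() != p->n || pos.ncol() != 3)
    stop("positions must be an n_agents x 3 matrix");
  std::fill(p->head.begin(), p->head.end(), -1);
  for (int i = 0; i < p->n; ++i) {
    p->px[i] = pos(i, 0);
    p->py[i] = pos(i, 1);
    p->pz[i] = pos(i, 2);
    p->nxt[i] = -1;
    p->grid_insert(i);
  }
}

// [[Rcpp::export]]
NumericMatrix engine_frame(SEXP eng, double plane_z, double slab_half) {
  XPtr<SwarmEngine> p(eng);
  std::vector<int> sel;
  for (int i = 0; i < p->n; ++i)
    if (std::fabs(p->pz[i] - plane_z) <= slab_half) sel.push_back(i);
  NumericMatrix out(sel.size(), 2);
  for (size_t j = 0; j < sel.size(); ++j) {
    out(j, 0) = p->px[sel[j]];
    out(j, 1) = p->py[sel[j]];
  }
  colnames(out) = CharacterVector::create("x", "y");
  return out;
}
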