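// Event-driven Monte-Carlo engine for corneal basal-layer homeostasis.
//
// The tissue is a fixed disk lattice (built in R, passed in as coordinate
// vectors). Each event picks one dividing cell (rate lambda_s for stem cells,
// lambda_p for progenitors below their replicative lifespan), one removed
// corneal cell (from the local inward sector in the coupled model, from the
// central disk in the uncoupled model), deletes the removed cell, pulls cells
// into the vacancy along the replication-removal vector, and places the
// daughter next to the parent. The clock advances by 1 / (total rate) per
// event, so normalized time t * lambda_p counts corneal replication times.

#include <Rcpp.h>
#include <random>
#include <vector>
#include <cmath>
#include <climits>

using namespace Rcpp;

namespace {

struct Offset { int dx, dy; double dist; };

struct Engine {
  // geometry
  int n = 0;
  std::vector<int> sx, sy;
  std::vector<double> sr;
  std::vector<bool> limbus;
  double R = 0, R_total = 0;
  int half = 0, side = 0;
  std::vector<int> lut;          // (x+half)*side + (y+half) -> site+1
  std::vector<int> nbr;          // 8 entries per site, -1 padded
  std::vector<int> cornea_sites, limbal_sites;
  std::vector<int> ring_order, ring_pos;  // limbal ring sorted by angle
  int n_cornea = 0;

  // config
  bool coupled = true;
  double alpha = 2 * M_PI, rho = 0, m = 5, sigma = 1;
  double lambda_s = 1, lambda_p = 1, afrac = 0.85;
  int rls = INT_MAX;
  bool equipotent = true;
  double cos_half_alpha = -1;
  bool biased_sector = false;

  std::vector<Offset> disk_off;
  std::vector<int> central_sites;

  // state
  std::vector<int> type;   // 0 = S, 1 = P_L, 2 = P_C
  std::vector<int> clone;  // -1 = unlabeled
  std::vector<int> divs;
  double t = 0;
  long long event_count = 0;
  long long fallback_count = 0;
  int renewed = 0;

  // competence bookkeeping
  std::vector<int> s_sites;
  std::vector<int> compP, compPos;

  std::mt19937_64 rng;
  std::uniform_real_distribution<double> dist01{0.0, 1.0};

  // scratch
  std::vector<int> cand;
  std::vector<double> wts;
  std::vector<int> chain_path;

  double runif() { return dist01(rng); }
  int pick(int k) {
    return (int)std::uniform_int_distribution<int>(0, k - 1)(rng);
  }

  int site_at(int x, int y) const {
    if (x < -half || x > half || y < -half || y > half) return -1;
    return lut[(size_t)(x + half) * side + (y + half)] - 1;
  }

  void build_geometry(const List& grid) {
    IntegerVector gx = grid["x"], gy = grid["y"];
    LogicalVector gl = grid["is_limbus"];
    R = as<double>(grid["R"]);
    R_total = as<double>(grid["R_total"]);
    n = gx.size();
    sx.assign(gx.begin(), gx.end());
    sy.assign(gy.begin(), gy.end());
    limbus.resize(n);
    sr.resize(n);
    half = (int)std::floor(R_total);
    side = 2 * half + 1;
    lut.assign((size_t)side * side, 0);
    for (int i = 0; i < n; ++i) {
      limbus[i] = gl[i];
      sr[i] = std::sqrt((double)sx[i] * sx[i] + (double)sy[i] * sy[i]);
      lut[(size_t)(sx[i] + half) * side + (sy[i] + half)] = i + 1;
      if (!limbus[i]) cornea_sites.push_back(i);
      else limbal_sites.push_back(i);
    }
    n_cornea = (int)cornea_sites.size();
    ring_order = limbal_sites;
    std::sort(ring_order.begin(), ring_order.end(), [&](int a, int b) {
      return std::atan2((double)sy[a], (double)sx[a]) <
             std::atan2((double)sy[b], (double)sx[b]);
    });
    ring_pos.assign(n, -1);
    for (size_t i = 0; i < ring_order.size(); ++i) ring_pos[ring_order[i]] = (int)i;
    nbr.assign((size_t)n * 8, -1);
    for (int i = 0; i < n; ++i) {
      int k = 0;
      for (int dx = -1; dx <= 1; ++dx)
        for (int dy = -1; dy <= 1; ++dy) {
          if (dx == 0 && dy == 0) continue;
          int j = site_at(sx[i] + dx, sy[i] + dy);
          if (j >= 0) nbr[(size_t)i * 8 + (k++)] = j;
        }
    }
  }

  void build_config(const List& config) {
    std::string mc = as<std::string>(config["model_class"]);
    coupled = (mc == "coupled");
    alpha = as<double>(config["alpha"]);
    rho = as<double>(config["rho"]);
    m = as<double>(config["m"]);
    sigma = as<double>(config["displacement_sigma"]);
    lambda_s = as<double>(config["lambda_s"]);
    lambda_p = as<double>(config["lambda_p"]);
    afrac = as<double>(config["a"]);
    double r = as<double>(config["rls"]);
    rls = (!std::isfinite(r) || r > (double)INT_MAX) ? INT_MAX : (int)r;
    equipotent = as<std::string>(config["stem_model"]) == "equipotent";
    cos_half_alpha = std::cos(alpha / 2.0);
    biased_sector = alpha < 2 * M_PI - 1e-12;

    int mi = (int)std::ceil(m);
    for (int dx = -mi; dx <= mi; ++dx)
      for (int dy = -mi; dy <= mi; ++dy) {
        double d = std::sqrt((double)dx * dx + (double)dy * dy);
        if (d > 1e-12 && d <= m + 1e-9) disk_off.push_back({dx, dy, d});
      }
    if (!coupled) {
      for (int i : cornea_sites)
        if (sr[i] <= rho + 1e-9) central_sites.push_back(i);
      if (central_sites.empty())
        stop("uncoupled removal disk contains no corneal site");
    }
  }

  void comp_update(int i) {
    bool want = (type[i] == 1 || type[i] == 2) && divs[i] < rls;
    bool have = compPos[i] >= 0;
    if (want && !have) {
      compPos[i] = (int)compP.size();
      compP.push_back(i);
    } else if (!want && have) {
      int p = compPos[i], last = compP.back();
      compP[p] = last;
      compPos[last] = p;
      compP.pop_back();
      compPos[i] = -1;
    }
  }

  void build_state(const List& state) {
    IntegerVector ty = state["type"], cl = state["clone"], dv = state["divisions"];
    t = as<double>(state["t"]);
    if ((int)ty.size() != n) stop("state size does not match grid");
    type.assign(ty.begin(), ty.end());
    divs.assign(dv.begin(), dv.end());
    clone.resize(n);
    compPos.assign(n, -1);
    renewed = 0;
    for (int i = 0; i < n; ++i) {
      clone[i] = (cl[i] == NA_INTEGER) ? -1 : cl[i];
      if (type[i] == 0 || type[i] == 1) {
        if (!limbus[i]) stop("S and P_L cells must sit on limbal sites");
      } else if (limbus[i]) {
        stop("P_C cells must sit on corneal sites");
      }
      if (type[i] == 0) s_sites.push_back(i);
      else comp_update(i);
      if (!limbus[i] && clone[i] >= 0) ++renewed;
    }
  }

  bool adjacent(int i, int j) const {
    return std::abs(sx[i] - sx[j]) <= 1 && std::abs(sy[i] - sy[j]) <= 1;
  }

  // corneal sites in the removal sector of `div` (excluding `div`)
  void sector_candidates(int div, bool with_bias) {
    cand.clear();
    double ux = 0, uy = 0;
    bool use_bias = with_bias && biased_sector && sr[div] > 1e-9;
    if (use_bias) { ux = -sx[div] / sr[div]; uy = -sy[div] / sr[div]; }
    for (const Offset& o : disk_off) {
      int j = site_at(sx[div] + o.dx, sy[div] + o.dy);
      if (j < 0 || limbus[j] || j == div) continue;
      if (use_bias) {
        double dot = o.dx * ux + o.dy * uy;
        if (dot + 1e-9 < cos_half_alpha * o.dist) continue;
      }
      cand.push_back(j);
    }
  }

  int select_removal(int div) {
    if (coupled) {
      sector_candidates(div, true);
      if (cand.empty()) {
        ++fallback_count;
        sector_candidates(div, false);
      }
      if (cand.empty()) stop("no removable corneal site near dividing cell");
      return cand[pick((int)cand.size())];
    }
    if ((int)central_sites.size() == 1 && central_sites[0] == div) {
      ++fallback_count;
      int s;
      do { s = cornea_sites[pick(n_cornea)]; } while (s == div);
      return s;
    }
    int s;
    do { s = central_sites[pick((int)central_sites.size())]; } while (s == div);
    return s;
  }

  double dist_to_segment(int p, double ax, double ay, double bx, double by) const {
    double abx = bx - ax, aby = by - ay;
    double len2 = abx * abx + aby * aby;
    double px = sx[p], py = sy[p];
    if (len2 < 1e-300) return std::hypot(px - ax, py - ay);
    double tt = ((px - ax) * abx + (py - ay) * aby) / len2;
    if (tt < 0) tt = 0; else if (tt > 1) tt = 1;
    return std::hypot(px - (ax + tt * abx), py - (ay + tt * aby));
  }

  // hole-pulling displacement chain from rem towards div; returns final hole.
  // in_limbus selects the domain the chain may move through: the cornea for
  // corneal removals, the limbal ring for hierarchical stem divisions.
  int run_chain(int div, int rem, bool trace, bool in_limbus = false) {
    int hole = rem;
    if (trace) { chain_path.clear(); chain_path.push_back(hole); }
    double ax = sx[div], ay = sy[div], bx = sx[rem], by = sy[rem];
    double inv2s2 = 1.0 / (2.0 * sigma * sigma);
    int guard = 0;
    while (!adjacent(hole, div)) {
      if (++guard > 8 * (side + 2)) stop("displacement chain failed to terminate");
      double dh = std::hypot((double)sx[hole] - ax, (double)sy[hole] - ay);
      cand.clear(); wts.clear();
      for (int k = 0; k < 8; ++k) {
        int j = nbr[(size_t)hole * 8 + k];
        if (j < 0 || limbus[j] != in_limbus || j == div) continue;
        double dj = std::hypot((double)sx[j] - ax, (double)sy[j] - ay);
        if (dj < dh - 1e-12) {
          double ds = dist_to_segment(j, ax, ay, bx, by);
          cand.push_back(j);
          wts.push_back(std::exp(-ds * ds * inv2s2));
        }
      }
      int nxt;
      if (cand.empty()) {
        // boundary corner: take the corneal neighbour closest to div
        double best = 1e300; nxt = -1;
        for (int k = 0; k < 8; ++k) {
          int j = nbr[(size_t)hole * 8 + k];
          if (j < 0 || limbus[j] != in_limbus || j == div) continue;
          double dj = std::hypot((double)sx[j] - ax, (double)sy[j] - ay);
          if (dj < best) { best = dj; nxt = j; }
        }
        if (nxt < 0) stop("displacement chain trapped with no neighbour in its domain");
        ++fallback_count;
      } else {
        double tot = 0;
        for (double w : wts) tot += w;
        double u = runif() * tot;
        nxt = cand.back();
        for (size_t k = 0; k < cand.size(); ++k) {
          u -= wts[k];
          if (u <= 0) { nxt = cand[k]; break; }
        }
      }
      // pull the cell at nxt into the hole
      clone[hole] = clone[nxt];
      divs[hole] = divs[nxt];
      type[hole] = type[nxt];
      comp_update(hole);
      hole = nxt;
      if (trace) chain_path.push_back(hole);
    }
    return hole;
  }

  // division of the cell at div whose daughter (clone c, division count d)
  // is pushed into the cornea, removing the cell chosen by the model class
  void corneal_division(int div, int c, int d, int rem = -1, bool trace = false) {
    if (rem < 0) rem = select_removal(div);
    if (clone[rem] >= 0) --renewed;
    int hole = run_chain(div, rem, trace);
    type[hole] = 2;
    clone[hole] = c;
    divs[hole] = d;
    if (c >= 0) ++renewed;
    comp_update(hole);
  }

  // one Monte-Carlo event; returns false when no competent cell remains
  bool step() {
    double totS = (double)s_sites.size() * lambda_s;
    double totP = (double)compP.size() * lambda_p;
    double tot = totS + totP;
    if (tot <= 0) return false;
    t += 1.0 / tot;
    ++event_count;
    double u = runif() * tot;
    if (u < totS) {
      int div = s_sites[pick((int)s_sites.size())];
      if (equipotent) {
        if (runif() < afrac) {
          corneal_division(div, clone[div], 0);  // asymmetric: new P_C
        } else {
          // symmetric: daughter S replaces a neighbouring limbal S
          cand.clear();
          for (int k = 0; k < 8; ++k) {
            int j = nbr[(size_t)div * 8 + k];
            if (j >= 0 && limbus[j]) cand.push_back(j);
          }
          if (cand.empty()) { ++fallback_count; return true; }
          int j = cand[pick((int)cand.size())];
          clone[j] = clone[div];
          divs[j] = 0;
        }
      } else {
        // hierarchical: asymmetric S division seeds a limbal progenitor.
        // The replication-removal pair lives on the limbal ring: the removed
        // cell is drawn uniformly from the contiguous arc of non-stem cells
        // on a random side of the parent (S cells are never replaced), the
        // arc shifts away from the parent, and the daughter P_L lands next
        // to it.
        int L = (int)ring_order.size();
        int p0 = ring_pos[div];
        auto at = [&](int off) { return ring_order[((p0 + off) % L + L) % L]; };
        auto arc_len = [&](int dir) {
          int len = 0;
          for (int s = 1; s < L; ++s) {
            if (type[at(dir * s)] == 0) break;
            ++len;
          }
          return len;
        };
        int dir = runif() < 0.5 ? 1 : -1;
        int len = arc_len(dir);
        if (len == 0) { dir = -dir; len = arc_len(dir); }
        if (len == 0) { ++fallback_count; return true; }
        int kk = 1 + pick(len);  // arc position of the removed cell
        for (int s = kk; s >= 2; --s) {
          int dst = at(dir * s), src = at(dir * (s - 1));
          type[dst] = type[src];
          clone[dst] = clone[src];
          divs[dst] = divs[src];
          comp_update(dst);
        }
        int first = at(dir);
        type[first] = 1;
        clone[first] = clone[div];
        divs[first] = 0;
        comp_update(first);
      }
    } else {
      int div = compP[pick((int)compP.size())];
      ++divs[div];            // lineage depth: both cells carry parent + 1
      comp_update(div);
      corneal_division(div, clone[div], divs[div]);
    }
    return true;
  }

  // ---- observables -------------------------------------------------------
  int count_clones(bool in_limbus, std::vector<int>& mark, int& version) const {
    ++version;
    int cnt = 0;
    for (int i = 0; i < n; ++i) {
      if (limbus[i] != in_limbus) continue;
      int c = clone[i];
      if (c >= 0 && mark[c] != version) { mark[c] = version; ++cnt; }
    }
    return cnt;
  }

  IntegerVector clone_out() const {
    IntegerVector out(n);
    for (int i = 0; i < n; ++i) out[i] = clone[i] < 0 ? NA_INTEGER : clone[i];
    return out;
  }

  List state_out() const {
    return List::create(
      _["type"] = IntegerVector(type.begin(), type.end()),
      _["clone"] = clone_out(),
      _["divisions"] = IntegerVector(divs.begin(), divs.end()),
      _["t"] = t,
      _["event_count"] = (double)event_count,
      _["fallbacks"] = (double)fallback_count);
  }
};

Engine make_engine(const List& grid, const List& config, const List& state,
                   int seed) {
  Engine e;
  e.build_geometry(grid);
  e.build_config(config);
  e.build_state(state);
  e.rng.seed((unsigned long long)seed);
  return e;
}

}  // namespace

// [[Rcpp::export]]
List cpp_simulate(List grid, List config, List state0, int seed, List control) {
  Engine e = make_engine(grid, config, state0, seed);

  double max_tnorm = as<double>(control["max_tnorm"]);
  double cp_dt = as<double>(control["checkpoint_dt"]);
  double stall_window = as<double>(control["stall_window"]);
  bool stop_when_renewed = as<bool>(control["stop_when_renewed"]);
  double max_events = as<double>(control["max_events"]);
  bool record_snapshots = as<bool>(control["record_snapshots"]);

  std::vector<double> cp_t, cp_tnorm, cp_frac;
  std::vector<int> cp_cl_limb, cp_cl_corn;
  std::vector<int> mark((size_t)e.n + 2, 0);
  int version = 0;
  List snapshots;

  auto record = [&](double tnorm) {
    if (!cp_tnorm.empty() && tnorm <= cp_tnorm.back() + 1e-12) return;
    cp_t.push_back(e.t);
    cp_tnorm.push_back(tnorm);
    cp_frac.push_back((double)e.renewed / e.n_cornea);
    cp_cl_limb.push_back(e.count_clones(true, mark, version));
    cp_cl_corn.push_back(e.count_clones(false, mark, version));
    if (record_snapshots) snapshots.push_back(e.clone_out());
  };

  record(e.t * e.lambda_p);
  double next_cp = e.t * e.lambda_p + cp_dt;
  double renewal_tnorm = -1;
  int best_renewed = e.renewed;
  double last_improve = e.t * e.lambda_p;
  std::string reason = "max_time";

  while (true) {
    if (!e.step()) { reason = "no_competent"; break; }
    double tnorm = e.t * e.lambda_p;
    if (e.renewed > best_renewed) { best_renewed = e.renewed; last_improve = tnorm; }
    while (tnorm >= next_cp - 1e-12) { record(next_cp); next_cp += cp_dt; }
    if (e.renewed == e.n_cornea && renewal_tnorm < 0) {
      renewal_tnorm = tnorm;
      if (stop_when_renewed) { record(tnorm); reason = "renewed"; break; }
    }
    if (tnorm - last_improve >= stall_window) { record(tnorm); reason = "stalled"; break; }
    if (tnorm >= max_tnorm) { record(tnorm); reason = "max_time"; break; }
    if ((double)e.event_count >= max_events) { record(tnorm); reason = "max_events"; break; }
    if (e.event_count % 65536 == 0) Rcpp::checkUserInterrupt();
  }

  List cps = List::create(
    _["t"] = NumericVector(cp_t.begin(), cp_t.end()),
    _["tnorm"] = NumericVector(cp_tnorm.begin(), cp_tnorm.end()),
    _["renewed_fraction"] = NumericVector(cp_frac.begin(), cp_frac.end()),
    _["n_clones_limbus"] = IntegerVector(cp_cl_limb.begin(), cp_cl_limb.end()),
    _["n_clones_cornea"] = IntegerVector(cp_cl_corn.begin(), cp_cl_corn.end()));

  List out = e.state_out();
  out["checkpoints"] = cps;
  out["snapshots"] = snapshots;
  out["stop_reason"] = reason;
  out["renewal_tnorm"] = renewal_tnorm < 0 ? NA_REAL : renewal_tnorm;
  return out;
}

// [[Rcpp::export]]
IntegerVector cpp_sample_division(List grid, List config, List state, int seed,
                                  int n_draws) {
  Engine e = make_engine(grid, config, state, seed);
  IntegerVector out(n_draws);
  double totS = (double)e.s_sites.size() * e.lambda_s;
  double totP = (double)e.compP.size() * e.lambda_p;
  if (totS + totP <= 0) stop("no mitotically competent cell in the tissue");
  for (int i = 0; i < n_draws; ++i) {
    double u = e.runif() * (totS + totP);
    int site = (u < totS)
      ? e.s_sites[e.pick((int)e.s_sites.size())]
      : e.compP[e.pick((int)e.compP.size())];
    out[i] = site + 1;
  }
  return out;
}

// [[Rcpp::export]]
IntegerVector cpp_sample_removal(List grid, List config, List state,
                                 int div_site, int seed, int n_draws) {
  Engine e = make_engine(grid, config, state, seed);
  IntegerVector out(n_draws);
  for (int i = 0; i < n_draws; ++i) out[i] = e.select_removal(div_site - 1) + 1;
  return out;
}

// [[Rcpp::export]]
List cpp_apply_event(List grid, List config, List state, int div_site,
                     int rem_site, int seed) {
  Engine e = make_engine(grid, config, state, seed);
  int div = div_site - 1, rem = rem_site - 1;
  if (div < 0 || div >= e.n || rem < 0 || rem >= e.n || div == rem)
    stop("invalid division/removal pair");
  if (e.limbus[rem]) stop("removed cell must be corneal");
  double tot = (double)e.s_sites.size() * e.lambda_s +
               (double)e.compP.size() * e.lambda_p;
  if (e.type[div] == 0) {
    e.t += 1.0 / tot; ++e.event_count;
    e.corneal_division(div, e.clone[div], 0, rem, true);
  } else {
    if (e.divs[div] >= e.rls) stop("dividing cell is post-mitotic");
    e.t += 1.0 / tot; ++e.event_count;
    ++e.divs[div];
    e.comp_update(div);
    e.corneal_division(div, e.clone[div], e.divs[div], rem, true);
  }
  List out = e.state_out();
  IntegerVector path(e.chain_path.size());
  for (size_t i = 0; i < e.chain_path.size(); ++i) path[i] = e.chain_path[i] + 1;
  out["chain"] = path;
  out["renewed"] = e.renewed;
  return out;
}
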