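// Fixed-timestep 1D loop-extrusion engine.
//
// Lattice sites are 1 kb wide. Each extruder holds a left and a right
// anchor; unstalled arms accumulate fractional progress (speed/2 * dt kb
// per step) and move one site outward per accumulated kb. Arms never cross
// another extruder's anchor (they block at the adjacent site, which keeps
// all loop intervals nested or disjoint) and stall permanently at CTCF
// sites whose orientation faces them. Unloading removes the extruder and
// records its final loop size. Uses R's RNG: seeding is done from R.

#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

namespace {

struct Extruder {
  long id;
  int sp;
  int left, right;
  double lprog, rprog;
  bool lstall, rstall;   // permanent CTCF stalls
  long paired_with;      // id of encounter partner, -1 if none
  double load_time;
};

}  // namespace

// [[Rcpp::export(name = ".simulate_extrusion_cpp")]]
List simulate_extrusion_cpp(int n_sites,
                            NumericVector loading_rate,   // per species, events/s on whole lattice
                            NumericVector koff,
                            NumericVector speed,          // kb/s total loop growth
                            NumericVector ctcf_stall_prob,
                            LogicalVector pair_on_encounter,
                            IntegerVector ctcf_pos,       // 0-based sites
                            IntegerVector ctcf_dir,       // +1: '+' (stalls left-moving arm), -1: '-'
                            double duration, double dt,
                            double record_every) {
  const int n_sp = loading_rate.size();
  std::vector<int> occ(n_sites, -1);
  std::vector<char> stall_left(n_sites, 0), stall_right(n_sites, 0);
  for (int k = 0; k < ctcf_pos.size(); ++k) {
    if (ctcf_pos[k] < 0 || ctcf_pos[k] >= n_sites)
      stop("CTCF site outside lattice");
    if (ctcf_dir[k] > 0) stall_left[ctcf_pos[k]] = 1;
    else stall_right[ctcf_pos[k]] = 1;
  }

  std::vector<Extruder> ext;
  long next_id = 0;
  const int n_steps = (int)std::ceil(duration / dt);
  const int rec_stride = std::max(1, (int)std::round(record_every / dt));

  std::vector<double> loop_sizes;
  std::vector<int> loop_species;
  std::vector<double> rec_time;
  std::vector<std::vector<int>> rec_counts(n_sp);

  // Time-averaged extruder count per species (steady-state density check).
  std::vector<double> count_sum(n_sp, 0.0);
  long count_n = 0;

  auto erase_extruder = [&](int idx) {
    occ[ext[idx].left] = -1;
    occ[ext[idx].right] = -1;
    ext.erase(ext.begin() + idx);
    for (int j = idx; j < (int)ext.size(); ++j) {
      occ[ext[j].left] = j;
      occ[ext[j].right] = j;
    }
  };

  for (int step = 0; step < n_steps; ++step) {
    const double t = step * dt;

    // (i) loading, one Bernoulli attempt per species per step
    for (int s = 0; s < n_sp; ++s) {
      double p = loading_rate[s] * dt;
      if (p > 0 && unif_rand() < std::min(p, 1.0)) {
        for (int attempt = 0; attempt < 50; ++attempt) {
          int site = (int)(unif_rand() * n_sites);
          if (site >= n_sites) site = n_sites - 1;
          if (occ[site] == -1) {
            Extruder e;
            e.id = next_id++;
            e.sp = s;
            e.left = e.right = site;
            e.lprog = e.rprog = 0.0;
            e.lstall = e.rstall = false;
            e.paired_with = -1;
            e.load_time = t;
            ext.push_back(e);
            occ[site] = (int)ext.size() - 1;
            break;
          }
        }
      }
    }

    // (ii)-(iv) arm movement with CTCF and collision stalling, id order
    for (int i = 0; i < (int)ext.size(); ++i) {
      Extruder &e = ext[i];
      const double step_kb = speed[e.sp] * 0.5 * dt;
      const bool pair_flag = pair_on_encounter[e.sp];
      const double stall_p = ctcf_stall_prob[e.sp];

      if (!e.lstall) {
        e.lprog += step_kb;
        while (e.lprog >= 1.0) {
          int target = e.left - 1;
          if (target < 0) { e.lprog = 0.0; break; }           // lattice edge
          if (occ[target] != -1) {                            // collision
            e.lprog = 0.0;
            int j = occ[target];
            if (pair_flag && j != i) {
              e.paired_with = ext[j].id;
              ext[j].paired_with = e.id;
            }
            break;
          }
          if (e.left != e.right) occ[e.left] = -1;
          e.left = target;
          occ[target] = i;
          e.lprog -= 1.0;
          if (stall_left[target] && stall_p > 0 && unif_rand() < stall_p) {
            e.lstall = true;
            e.lprog = 0.0;
            break;
          }
        }
      }
      if (!e.rstall) {
        e.rprog += step_kb;
        while (e.rprog >= 1.0) {
          int target = e.right + 1;
          if (target >= n_sites) { e.rprog = 0.0; break; }
          if (occ[target] != -1) {
            e.rprog = 0.0;
            int j = occ[target];
            if (pair_flag && j != i) {
              e.paired_with = ext[j].id;
              ext[j].paired_with = e.id;
            }
            break;
          }
          if (e.left != e.right) occ[e.right] = -1;
          e.right = target;
          occ[target] = i;
          e.rprog -= 1.0;
          if (stall_right[target] && stall_p > 0 && unif_rand() < stall_p) {
            e.rstall = true;
            e.rprog = 0.0;
            break;
          }
        }
      }
    }

    // (v) unloading
    for (int i = (int)ext.size() - 1; i >= 0; --i) {
      if (unif_rand() < koff[ext[i].sp] * dt) {
        loop_sizes.push_back((double)(ext[i].right - ext[i].left));
        loop_species.push_back(ext[i].sp + 1);
        erase_extruder(i);
      }
    }

    // bookkeeping
    std::vector<int> counts(n_sp, 0);
    for (const Extruder &e : ext) counts[e.sp]++;
    for (int s = 0; s < n_sp; ++s) count_sum[s] += counts[s];
    count_n++;
    if (step % rec_stride == 0) {
      rec_time.push_back(t);
      for (int s = 0; s < n_sp; ++s) rec_counts[s].push_back(counts[s]);
    }
  }

  // final state
  const int n_fin = (int)ext.size();
  IntegerVector f_id(n_fin), f_sp(n_fin), f_left(n_fin), f_right(n_fin),
      f_pair(n_fin);
  LogicalVector f_ls(n_fin), f_rs(n_fin), f_adj(n_fin);
  NumericVector f_lt(n_fin);
  for (int i = 0; i < n_fin; ++i) {
    const Extruder &e = ext[i];
    f_id[i] = (int)e.id;
    f_sp[i] = e.sp + 1;
    f_left[i] = e.left;
    f_right[i] = e.right;
    f_ls[i] = e.lstall;
    f_rs[i] = e.rstall;
    f_pair[i] = (e.paired_with >= 0) ? (int)e.paired_with : NA_INTEGER;
    f_lt[i] = e.load_time;
    bool adj = false;  // anchor adjacent-stalled against another extruder
    for (int d : {-1, 1}) {
      for (int a : {e.left, e.right}) {
        int nb = a + d;
        if (nb >= 0 && nb < n_sites && occ[nb] != -1 && occ[nb] != i)
          adj = true;
      }
    }
    f_adj[i] = adj;
  }

  NumericMatrix dens(rec_time.size(), n_sp);
  for (int s = 0; s < n_sp; ++s)
    for (size_t r = 0; r < rec_time.size(); ++r)
      dens(r, s) = rec_counts[s][r];

  NumericVector mean_count(n_sp);
  for (int s = 0; s < n_sp; ++s)
    mean_count[s] = count_n > 0 ? count_sum[s] / count_n : 0.0;

  return List::create(
      _["final"] = DataFrame::create(
          _["id"] = f_id, _["species_idx"] = f_sp,
          _["left_anchor"] = f_left, _["right_anchor"] = f_right,
          _["left_stalled"] = f_ls, _["right_stalled"] = f_rs,
          _["paired_with"] = f_pair, _["adjacent"] = f_adj,
          _["load_time"] = f_lt),
      _["loop_sizes"] = NumericVector(loop_sizes.begin(), loop_sizes.end()),
      _["loop_species"] = IntegerVector(loop_species.begin(), loop_species.end()),
      _["record_time"] = NumericVector(rec_time.begin(), rec_time.end()),
      _["record_counts"] = dens,
      _["mean_count"] = mean_count);
}
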