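// Continuous-time (Gillespie) TASEP simulation of translation.
//
// Convention: a ribosome at codon i (1-based) covers the `footprint` codons
// [i, i + footprint - 1].  It advances to i+1 at rate rates[i] iff codon
// i + footprint is vacant (equivalently, the headway to the ribosome ahead
// exceeds `footprint`); at the last codon it terminates at rate rates[L]
// and is released.  Initiation places a ribosome at codon 1 at rate ir iff
// codons 1..footprint are all vacant.  In the whole-cell mode a finite
// ribosome pool throttles initiation (coupling 1: ir * free/total) and
// free + bound is conserved exactly as integer bookkeeping.

#include <Rcpp.h>
#include <deque>
#include <random>
#include <vector>
using namespace Rcpp;

namespace {

struct Mrna {
  int gene;                    // index into gene table
  std::deque<int> ribs;        // A-site positions, front = most advanced (3')
  double move_sum;             // sum of rates of currently mobile ribosomes
  bool start_open;
  double ir;                   // per-mRNA initiation rate (unscaled)
};

// is ribosome k (index into ribs) free to advance?
inline bool can_move(const Mrna& m, int k, int L, int fp) {
  int pos = m.ribs[k];
  if (k == 0) return true;  // front ribosome: termination or free advance
  return m.ribs[k - 1] - pos > fp;
}

inline bool start_open_f(const Mrna& m, int fp) {
  return m.ribs.empty() || m.ribs.back() > fp;
}

void refresh_mrna(Mrna& m, const std::vector<double>& rates, int L, int fp) {
  m.move_sum = 0.0;
  for (size_t k = 0; k < m.ribs.size(); ++k) {
    if (can_move(m, (int)k, L, fp)) m.move_sum += rates[m.ribs[k] - 1];
  }
  m.start_open = start_open_f(m, fp);
}

}  // namespace

// Core engine shared by the single-mRNA and whole-cell entry points.
// gene_len / gene_rates describe each distinct gene; copies replicates it.
// pool_size < 0 means an unlimited ribosome supply (single-mRNA mode).
// coupling: 0 = none, 1 = ir * free/pool_total, 2 = ir * free (mass action).
static List tasep_engine(const IntegerVector& gene_of_mrna,
                         const std::vector<std::vector<double>>& gene_rates,
                         const NumericVector& ir_of_mrna, int footprint,
                         double burn_in, double measure_time, int pool_size,
                         int coupling, uint64_t seed, bool check_exclusion) {
  const int n_mrna = gene_of_mrna.size();
  const int n_gene = (int)gene_rates.size();
  std::mt19937_64 rng(seed);
  std::uniform_real_distribution<double> unif(0.0, 1.0);

  std::vector<Mrna> mrnas(n_mrna);
  for (int m = 0; m < n_mrna; ++m) {
    mrnas[m].gene = gene_of_mrna[m];
    mrnas[m].move_sum = 0.0;
    mrnas[m].start_open = true;
    mrnas[m].ir = ir_of_mrna[m];
  }

  long long free_pool = pool_size;  // ignored when pool_size < 0
  long long bound = 0;
  const double pool_total = pool_size > 0 ? (double)pool_size : 1.0;

  double t = 0.0;
  const double t_end = burn_in + measure_time;
  double occ_integral_all = 0.0;      // sum over mRNAs of ribosomes * dt
  std::vector<double> occ_integral(n_mrna, 0.0);
  std::vector<long long> terms(n_mrna, 0);
  double free_integral = 0.0;
  long long events = 0;
  bool exclusion_ok = true;
  bool pool_exhausted_warn = false;
  long long conservation_ok = 1;

  double init_sum = 0.0;  // sum of ir over open-start mRNAs
  double move_sum = 0.0;  // global mobile-rate sum
  for (int m = 0; m < n_mrna; ++m) init_sum += mrnas[m].ir;

  auto pool_factor = [&]() -> double {
    if (pool_size < 0) return 1.0;
    if (free_pool <= 0) return 0.0;
    if (coupling == 2) return (double)free_pool;
    return (double)free_pool / pool_total;
  };

  long long resync_counter = 0;
  while (t < t_end) {
    double pf = pool_factor();
    double total = move_sum + init_sum * pf;
    if (total <= 0.0) {
      // frozen system: advance to end, integrating the static state
      double from = std::max(t, burn_in);
      double dt = t_end - from;
      if (dt > 0) {
        occ_integral_all += (double)bound * dt;
        free_integral += (double)(pool_size < 0 ? 0 : free_pool) * dt;
        for (int m = 0; m < n_mrna; ++m)
          occ_integral[m] += (double)mrnas[m].ribs.size() * dt;
      }
      t = t_end;
      break;
    }
    double dt = -std::log(1.0 - unif(rng)) / total;
    double t_new = std::min(t + dt, t_end);
    double t_from = std::max(t, burn_in);
    if (t_new > burn_in) {
      double span = t_new - t_from;
      occ_integral_all += (double)bound * span;
      free_integral += (double)(pool_size < 0 ? 0 : free_pool) * span;
      for (int m = 0; m < n_mrna; ++m)
        occ_integral[m] += (double)mrnas[m].ribs.size() * span;
    }
    t += dt;
    if (t >= t_end) break;
    ++events;

    double pick = unif(rng) * total;
    if (pick < init_sum * pf) {
      // initiation event: select an open mRNA proportional to ir
      if (pool_size >= 0 && free_pool <= 0) { pool_exhausted_warn = true; continue; }
      double target = pick / pf;
      double acc = 0.0;
      int chosen = -1;
      for (int m = 0; m < n_mrna; ++m) {
        if (!mrnas[m].start_open) continue;
        acc += mrnas[m].ir;
        if (acc >= target) { chosen = m; break; }
      }
      if (chosen < 0) continue;  // float slack; no-op
      Mrna& mm = mrnas[chosen];
      const std::vector<double>& rates = gene_rates[mm.gene];
      int L = (int)rates.size();
      // place A-site at codon 1; the start is then blocked
      double old_move = mm.move_sum;
      mm.ribs.push_back(1);
      if (pool_size >= 0) { --free_pool; }
      ++bound;
      refresh_mrna(mm, rates, L, footprint);
      move_sum += mm.move_sum - old_move;
      if (!mm.start_open) init_sum -= mm.ir;
    } else {
      // movement event: select mRNA proportional to move_sum
      double target = pick - init_sum * pf;
      double acc = 0.0;
      int chosen = -1;
      for (int m = 0; m < n_mrna; ++m) {
        acc += mrnas[m].move_sum;
        if (acc >= target && mrnas[m].move_sum > 0.0) { chosen = m; break; }
      }
      if (chosen < 0) continue;
      Mrna& mm = mrnas[chosen];
      const std::vector<double>& rates = gene_rates[mm.gene];
      int L = (int)rates.size();
      // select mobile ribosome within mRNA proportional to its rate
      double target2 = mm.move_sum - (acc - target);
      if (target2 <= 0.0 || target2 > mm.move_sum) target2 = mm.move_sum;
      double acc2 = 0.0;
      int kchosen = -1;
      for (size_t k = 0; k < mm.ribs.size(); ++k) {
        if (!can_move(mm, (int)k, L, footprint)) continue;
        acc2 += rates[mm.ribs[k] - 1];
        if (acc2 >= target2) { kchosen = (int)k; break; }
      }
      if (kchosen < 0) {
        // numerical slack: pick last mobile
        for (int k = (int)mm.ribs.size() - 1; k >= 0; --k)
          if (can_move(mm, k, L, footprint)) { kchosen = k; break; }
        if (kchosen < 0) continue;
      }
      bool start_was_open = mm.start_open;
      double old_move = mm.move_sum;
      if (mm.ribs[kchosen] == L) {
        // termination
        mm.ribs.pop_front();
        if (pool_size >= 0) ++free_pool;
        --bound;
        ++terms[chosen];
      } else {
        mm.ribs[kchosen] += 1;
      }
      refresh_mrna(mm, rates, L, footprint);
      move_sum += mm.move_sum - old_move;
      if (mm.start_open != start_was_open) {
        init_sum += mm.start_open ? mm.ir : -mm.ir;
      }
      if (check_exclusion) {
        // footprints [pos - fp + 1, pos] must not overlap: headway >= fp
        for (size_t k = 1; k < mm.ribs.size(); ++k) {
          if (mm.ribs[k - 1] - mm.ribs[k] < footprint) exclusion_ok = false;
        }
      }
    }
    if (pool_size >= 0 && free_pool + bound != pool_size) conservation_ok = 0;

    // periodically rebuild the float accumulators to cancel drift
    if (++resync_counter % 100000 == 0) {
      move_sum = 0.0;
      init_sum = 0.0;
      for (int m = 0; m < n_mrna; ++m) {
        const std::vector<double>& rates = gene_rates[mrnas[m].gene];
        refresh_mrna(mrnas[m], rates, (int)rates.size(), footprint);
        move_sum += mrnas[m].move_sum;
        if (mrnas[m].start_open) init_sum += mrnas[m].ir;
      }
    }
  }

  NumericVector mean_ribs(n_mrna), prod(n_mrna);
  for (int m = 0; m < n_mrna; ++m) {
    mean_ribs[m] = occ_integral[m] / measure_time;
    prod[m] = (double)terms[m] / measure_time;
  }
  return List::create(
      _["mean_ribosomes"] = mean_ribs, _["production_rate"] = prod,
      _["mean_bound"] = occ_integral_all / measure_time,
      _["mean_free"] = pool_size < 0 ? NA_REAL : free_integral / measure_time,
      _["final_free"] = pool_size < 0 ? NA_INTEGER : (int)free_pool,
      _["final_bound"] = (double)bound, _["events"] = (double)events,
      _["exclusion_ok"] = exclusion_ok,
      _["conservation_ok"] = conservation_ok == 1,
      _["pool_exhausted"] = pool_exhausted_warn);
}

// [[Rcpp::export(name = ".tasep_single_cpp")]]
List tasep_single_cpp(NumericVector rates, double ir, int footprint,
                      double burn_in, double measure_time, double seed,
                      bool check_exclusion) {
  std::vector<std::vector<double>> gr(1);
  gr[0] = std::vector<double>(rates.begin(), rates.end());
  IntegerVector gene_of(1, 0);
  NumericVector irs(1, ir);
  return tasep_engine(gene_of, gr, irs, footprint, burn_in, measure_time, -1,
                      0, (uint64_t)seed, check_exclusion);
}

// [[Rcpp::export(name = ".tasep_cell_cpp")]]
List tasep_cell_cpp(IntegerVector gene_of_mrna, List gene_rates,
                    NumericVector ir_of_mrna, int footprint, double burn_in,
                    double measure_time, int pool_size, int coupling,
                    double seed, bool check_exclusion) {
  std::vector<std::vector<double>> gr(gene_rates.size());
  for (int g = 0; g < gene_rates.size(); ++g) {
    NumericVector r = gene_rates[g];
    gr[g] = std::vector<double>(r.begin(), r.end());
  }
  return tasep_engine(gene_of_mrna, gr, ir_of_mrna, footprint, burn_in,
                      measure_time, pool_size, coupling, (uint64_t)seed,
                      check_exclusion);
}
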