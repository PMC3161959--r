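// Forward-time Wright-Fisher simulator with selection and recombination.
//
// Chromosomes are sorted vectors of mutation ids (sorted by position on the
// unit interval, infinite-sites). Fitness is multiplicative over non-neutral
// sites: 1 + h*s heterozygous, 1 + s homozygous. Each offspring chromosome
// picks a parent individual with probability proportional to fitness and
// receives one gamete; a Poisson(rho) number of crossover events per
// population generation is assigned to uniformly chosen gametes at uniform
// positions. New mutations arrive at Poisson(theta_x / 2) per class per
// generation (theta_x = 4 N u_x, so 2 N u_x = theta_x / 2). Mutations that
// reach count 2N are stripped from chromosomes and logged as fixed.
//
// Each chromosome additionally carries the sorted subset of its non-neutral
// mutation ids, so per-individual fitness scales with the number of selected
// sites rather than all sites.

#include <Rcpp.h>
#include <vector>
#include <unordered_map>
#include <unordered_set>
#include <algorithm>
using namespace Rcpp;

namespace {

struct Mut {
  double pos;
  double s;    // homozygote selection coefficient; 0 iff neutral
  int cls;     // 0 neutral, 1 deleterious, 2 advantageous
  int gen;     // generation of origin
};

struct Chrom {
  std::vector<int> all;  // all mutation ids, sorted by position
  std::vector<int> sel;  // non-neutral subset, sorted by position
};

struct Params {
  int N;
  double theta_n, theta_d, theta_a;
  double gamma_d, gamma_a;
  double h, rho;
};

struct Pop {
  int N;
  int gen = 0;
  std::vector<Chrom> chr;               // 2N chromosomes
  std::vector<Mut> muts;                // id -> mutation (monotone, never shrunk)
  std::unordered_set<double> positions; // collision guard (historic superset)
  long fixed[3] = {0, 0, 0};
  // per-generation scratch
  std::vector<int> cnt;
  std::vector<int> touched;
  explicit Pop(int N_) : N(N_), chr(2 * N_) {}
};

inline double runif01() { return unif_rand(); }

double draw_pos(Pop& P) {
  double p;
  do {
    p = runif01();
  } while (p <= 0.0 || p >= 1.0 || P.positions.count(p));
  P.positions.insert(p);
  return p;
}

void insert_sorted(Pop& P, std::vector<int>& v, int id, double pos) {
  std::vector<int>::iterator it = std::lower_bound(
      v.begin(), v.end(), pos,
      [&](int id2, double p2) { return P.muts[id2].pos < p2; });
  v.insert(it, id);
}

int add_mutation(Pop& P, int cls, double s, double fixed_pos = -1.0) {
  double pos = (fixed_pos >= 0.0) ? fixed_pos : draw_pos(P);
  if (fixed_pos >= 0.0) P.positions.insert(pos);
  int id = (int)P.muts.size();
  P.muts.push_back(Mut{pos, s, cls, P.gen});
  int c = std::min((int)(runif01() * 2 * P.N), 2 * P.N - 1);
  insert_sorted(P, P.chr[c].all, id, pos);
  if (cls != 0) insert_sorted(P, P.chr[c].sel, id, pos);
  return id;
}

// splice a gamete from A/B given sorted crossover breakpoints
void splice(const Pop& P, const std::vector<int>& A, const std::vector<int>& B,
            const std::vector<double>& bp, bool startA, std::vector<int>& out) {
  out.clear();
  out.reserve(A.size() + B.size());
  bool useA = startA;
  size_t a = 0, b = 0;
  for (size_t k = 0; k < bp.size(); ++k) {
    double hi = bp[k];
    if (useA) {
      while (a < A.size() && P.muts[A[a]].pos < hi) { out.push_back(A[a]); ++a; }
      while (b < B.size() && P.muts[B[b]].pos < hi) ++b;
    } else {
      while (b < B.size() && P.muts[B[b]].pos < hi) { out.push_back(B[b]); ++b; }
      while (a < A.size() && P.muts[A[a]].pos < hi) ++a;
    }
    useA = !useA;
  }
}

// One Wright-Fisher generation. If track_id >= 0, *track_count receives the
// post-reproduction allele count of that mutation (0 = lost, 2N = fixed).
// If seg_out != 0 it receives live segregating-site counts per class.
void step(Pop& P, const Params& par, bool recurrent_adv,
          int track_id = -1, int* track_count = 0, long* seg_out = 0) {
  const int twoN = 2 * P.N;

  // fitness of each diploid (merge walk over the two selected-site lists)
  std::vector<double> cum(P.N);
  double tot = 0.0;
  for (int i = 0; i < P.N; ++i) {
    const std::vector<int>& A = P.chr[2 * i].sel;
    const std::vector<int>& B = P.chr[2 * i + 1].sel;
    double w = 1.0;
    size_t a = 0, b = 0;
    while (a < A.size() || b < B.size()) {
      double pa = a < A.size() ? P.muts[A[a]].pos : 2.0;
      double pb = b < B.size() ? P.muts[B[b]].pos : 2.0;
      if (pa == pb) {  // same id: homozygous (positions unique across ids)
        w *= (1.0 + P.muts[A[a]].s);
        ++a; ++b;
      } else if (pa < pb) {
        w *= (1.0 + par.h * P.muts[A[a]].s);
        ++a;
      } else {
        w *= (1.0 + par.h * P.muts[B[b]].s);
        ++b;
      }
    }
    if (w < 0.0) w = 0.0;
    tot += w;
    cum[i] = tot;
  }
  if (!(tot > 0.0))
    stop("degenerate parameters: all individual fitnesses <= 0 in generation %d", P.gen);

  // population-level crossover events, assigned to uniformly chosen gametes
  std::unordered_map< int, std::vector<double> > xov;
  if (par.rho > 0.0) {
    int K = (int)R::rpois(par.rho);
    for (int k = 0; k < K; ++k) {
      int g = std::min((int)(runif01() * twoN), twoN - 1);
      xov[g].push_back(runif01());
    }
  }

  // offspring chromosomes
  std::vector<Chrom> off(twoN);
  for (int j = 0; j < twoN; ++j) {
    double u = runif01() * tot;
    int p = (int)(std::lower_bound(cum.begin(), cum.end(), u) - cum.begin());
    if (p >= P.N) p = P.N - 1;
    const Chrom& A = P.chr[2 * p];
    const Chrom& B = P.chr[2 * p + 1];
    std::unordered_map< int, std::vector<double> >::iterator it = xov.find(j);
    if (it == xov.end()) {
      off[j] = (runif01() < 0.5) ? A : B;
    } else {
      std::vector<double> bp = it->second;
      std::sort(bp.begin(), bp.end());
      bp.push_back(1.0);
      bool startA = runif01() < 0.5;
      splice(P, A.all, B.all, bp, startA, off[j].all);
      splice(P, A.sel, B.sel, bp, startA, off[j].sel);
    }
  }
  P.chr.swap(off);
  ++P.gen;

  // new mutations on offspring chromosomes
  struct ClsSpec { double theta; int cls; double s; };
  const ClsSpec specs[3] = {
    {par.theta_n, 0, 0.0},
    {par.theta_d, 1, par.gamma_d / (4.0 * par.N)},
    {recurrent_adv ? par.theta_a : 0.0, 2, par.gamma_a / (4.0 * par.N)}
  };
  for (int sidx = 0; sidx < 3; ++sidx) {
    if (specs[sidx].theta <= 0.0) continue;
    int m = (int)R::rpois(specs[sidx].theta / 2.0);
    for (int t = 0; t < m; ++t) add_mutation(P, specs[sidx].cls, specs[sidx].s);
  }

  // allele counts; strip and log fixed mutations
  if (P.cnt.size() < P.muts.size()) P.cnt.resize(P.muts.size(), 0);
  P.touched.clear();
  for (int c = 0; c < twoN; ++c)
    for (size_t k = 0; k < P.chr[c].all.size(); ++k) {
      int id = P.chr[c].all[k];
      if (P.cnt[id]++ == 0) P.touched.push_back(id);
    }
  std::unordered_set<int> fixed;
  for (size_t k = 0; k < P.touched.size(); ++k)
    if (P.cnt[P.touched[k]] == twoN) fixed.insert(P.touched[k]);
  if (track_id >= 0 && track_count)
    *track_count = (track_id < (int)P.cnt.size()) ? P.cnt[track_id] : 0;
  if (seg_out) {
    seg_out[0] = seg_out[1] = seg_out[2] = 0;
    for (size_t k = 0; k < P.touched.size(); ++k) {
      int id = P.touched[k];
      if (P.cnt[id] < twoN) seg_out[P.muts[id].cls]++;
    }
  }
  for (size_t k = 0; k < P.touched.size(); ++k) P.cnt[P.touched[k]] = 0;
  if (!fixed.empty()) {
    for (int c = 0; c < twoN; ++c) {
      std::vector<int>& v = P.chr[c].all;
      v.erase(std::remove_if(v.begin(), v.end(),
                             [&](int id) { return fixed.count(id) > 0; }),
              v.end());
      std::vector<int>& vs = P.chr[c].sel;
      vs.erase(std::remove_if(vs.begin(), vs.end(),
                              [&](int id) { return fixed.count(id) > 0; }),
               vs.end());
    }
    for (std::unordered_set<int>::iterator f = fixed.begin(); f != fixed.end(); ++f)
      P.fixed[P.muts[*f].cls]++;
  }
}

// Sample sample_n chromosomes without replacement; tally the per-class SFS
// over derived counts 1..n-1 (sites fixed in the sample are excluded).
// max_gen >= 0 restricts to mutations with birth generation <= max_gen.
IntegerMatrix sample_sfs(Pop& P, int n, int max_gen = -1) {
  const int twoN = 2 * P.N;
  if (n > twoN) stop("sample_n exceeds 2N");
  std::vector<int> idx(twoN);
  for (int i = 0; i < twoN; ++i) idx[i] = i;
  for (int i = 0; i < n; ++i) {  // partial Fisher-Yates
    int j = i + std::min((int)(runif01() * (twoN - i)), twoN - i - 1);
    std::swap(idx[i], idx[j]);
  }
  if (P.cnt.size() < P.muts.size()) P.cnt.resize(P.muts.size(), 0);
  P.touched.clear();
  for (int i = 0; i < n; ++i)
    for (size_t k = 0; k < P.chr[idx[i]].all.size(); ++k) {
      int id = P.chr[idx[i]].all[k];
      if (P.cnt[id]++ == 0) P.touched.push_back(id);
    }
  IntegerMatrix sfs(3, n - 1);
  for (size_t k = 0; k < P.touched.size(); ++k) {
    int id = P.touched[k];
    int c = P.cnt[id];
    if (c >= 1 && c <= n - 1 && (max_gen < 0 || P.muts[id].gen <= max_gen))
      sfs(P.muts[id].cls, c - 1)++;
    P.cnt[id] = 0;
  }
  return sfs;
}

void census_seg(Pop& P, long* seg_end) {
  const int twoN = 2 * P.N;
  if (P.cnt.size() < P.muts.size()) P.cnt.resize(P.muts.size(), 0);
  P.touched.clear();
  for (int c = 0; c < twoN; ++c)
    for (size_t k = 0; k < P.chr[c].all.size(); ++k) {
      int id = P.chr[c].all[k];
      if (P.cnt[id]++ == 0) P.touched.push_back(id);
    }
  seg_end[0] = seg_end[1] = seg_end[2] = 0;
  for (size_t k = 0; k < P.touched.size(); ++k) {
    int id = P.touched[k];
    if (P.cnt[id] < twoN) seg_end[P.muts[id].cls]++;
    P.cnt[id] = 0;
  }
}

Params make_params(int N, double theta_n, double theta_d, double theta_a,
                   double gamma_d, double gamma_a, double h, double rho) {
  if (N < 2) stop("N must be >= 2");
  if (theta_n < 0 || theta_d < 0 || theta_a < 0) stop("theta parameters must be >= 0");
  if (gamma_d > 0) stop("gamma_d must be <= 0");
  if (gamma_a < 0) stop("gamma_a must be >= 0");
  if (h < 0 || h > 1) stop("h must be in [0, 1]");
  if (rho < 0) stop("rho must be >= 0");
  Params par;
  par.N = N; par.theta_n = theta_n; par.theta_d = theta_d; par.theta_a = theta_a;
  par.gamma_d = gamma_d; par.gamma_a = gamma_a; par.h = h; par.rho = rho;
  return par;
}

}  // namespace

//' @noRd
// [[Rcpp::export]]
List wf_cpp_burn(int N, double theta_n, double theta_d, double theta_a,
                 double gamma_d, double gamma_a, double h, double rho,
                 int burn_gens, int sample_n, bool recurrent_adv,
                 bool log_trajectory) {
  Params par = make_params(N, theta_n, theta_d, theta_a, gamma_d, gamma_a, h, rho);
  Pop P(N);
  IntegerMatrix traj;
  if (log_trajectory) traj = IntegerMatrix(burn_gens, 3);
  long seg[3] = {0, 0, 0};
  for (int g = 0; g < burn_gens; ++g) {
    step(P, par, recurrent_adv, -1, 0, log_trajectory ? seg : (long*)0);
    if (log_trajectory) {
      traj(g, 0) = (int)seg[0]; traj(g, 1) = (int)seg[1]; traj(g, 2) = (int)seg[2];
    }
  }
  long seg_end[3];
  census_seg(P, seg_end);
  IntegerMatrix sfs = sample_sfs(P, sample_n);
  return List::create(
      _["sfs"] = sfs,
      _["trajectory"] = traj,
      _["n_seg"] = IntegerVector::create((int)seg_end[0], (int)seg_end[1], (int)seg_end[2]),
      _["n_fixed"] = IntegerVector::create((int)P.fixed[0], (int)P.fixed[1], (int)P.fixed[2]),
      _["generation"] = P.gen);
}

//' @noRd
// [[Rcpp::export]]
List wf_cpp_single_sweep(int N, double theta_n, double theta_d,
                         double gamma_d, double gamma_a, double h, double rho,
                         int burn_gens, int sample_n, int max_attempts) {
  Params par = make_params(N, theta_n, theta_d, 0.0, gamma_d, gamma_a, h, rho);
  if (gamma_a <= 0) stop("single-sweep mode requires gamma_a > 0");
  Pop P(N);
  for (int g = 0; g < burn_gens; ++g) step(P, par, false);

  IntegerMatrix pre_sfs = sample_sfs(P, sample_n);

  // snapshot of the pre-injection state (mutation table only grows, so
  // restoring the chromosomes, generation counter, and fixation log suffices)
  std::vector<Chrom> snap_chr = P.chr;
  int snap_gen = P.gen;
  long snap_fixed[3] = {P.fixed[0], P.fixed[1], P.fixed[2]};

  int attempts = 0;
  int inject_gen = 0, fix_gen = 0;
  double s_a = gamma_a / (4.0 * N);
  for (;;) {
    ++attempts;
    if (attempts > max_attempts)
      stop("advantageous mutation failed to fix within %d attempts", max_attempts);
    int sweep_id = add_mutation(P, 2, s_a, 0.5);
    inject_gen = P.gen;
    bool fixed_now = false, lost = false;
    while (!fixed_now && !lost) {
      int cnt = 0;
      step(P, par, false, sweep_id, &cnt);
      if (cnt == 0) lost = true;
      else if (cnt == 2 * N) fixed_now = true;
    }
    if (fixed_now) { fix_gen = P.gen; break; }
    P.chr = snap_chr;  // restore and re-inject with fresh randomness
    P.gen = snap_gen;
    P.fixed[0] = snap_fixed[0]; P.fixed[1] = snap_fixed[1]; P.fixed[2] = snap_fixed[2];
  }

  IntegerMatrix post_sfs = sample_sfs(P, sample_n);
  IntegerMatrix post_standing = sample_sfs(P, sample_n, inject_gen);
  return List::create(
      _["pre_sfs"] = pre_sfs,
      _["post_sfs"] = post_sfs,
      _["post_standing_sfs"] = post_standing,
      _["attempts"] = attempts,
      _["sweep_generations"] = fix_gen - inject_gen,
      _["sweep_final_count"] = 2 * N,
      _["n_fixed"] = IntegerVector::create((int)P.fixed[0], (int)P.fixed[1], (int)P.fixed[2]));
}

//' @noRd
// [[Rcpp::export]]
List wf_cpp_recurrent(int N, double theta_n, double theta_d, double theta_a,
                      double gamma_d, double gamma_a, double h, double rho,
                      int burn_gens, int sample_n, int n_epochs, int epoch_gens) {
  Params par = make_params(N, theta_n, theta_d, theta_a, gamma_d, gamma_a, h, rho);
  Pop P(N);
  for (int g = 0; g < burn_gens; ++g) step(P, par, true);
  List out(n_epochs);
  IntegerVector adv_fixed(n_epochs);
  for (int e = 0; e < n_epochs; ++e) {
    for (int g = 0; g < epoch_gens; ++g) step(P, par, true);
    out[e] = sample_sfs(P, sample_n);
    adv_fixed[e] = (int)P.fixed[2];
  }
  return List::create(
      _["sfs_by_epoch"] = out,
      _["adv_fixed_cum"] = adv_fixed,
      _["n_fixed"] = IntegerVector::create((int)P.fixed[0], (int)P.fixed[1], (int)P.fixed[2]),
      _["generation"] = P.gen);
}

//' @noRd
// [[Rcpp::export]]
double wf_cpp_diploid_fitness(NumericVector s, LogicalVector homozygous, double h) {
  if (s.size() != homozygous.size())
    stop("s and homozygous must have equal length");
  double w = 1.0;
  for (int i = 0; i < s.size(); ++i)
    w *= homozygous[i] ? (1.0 + s[i]) : (1.0 + h * s[i]);
  return w;
}
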