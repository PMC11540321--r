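// Forward-time individual-based Wright-Fisher engine.
//
// Storage: neutral diallelic alleles as uint8 (one byte per copy), selected
// allele effects as double, in parallel haplotype-major arrays per patch
// (haplotype h owns neutral row h*Ln.. and selected row h*Ls..). Individual
// i owns haplotypes 2i and 2i+1. The byte layout matters: gamete assembly
// is memory-bandwidth-bound, and neutral loci dominate the genome.
//
// Life cycle per generation (soft selection, fixed patch size N):
//   1. fitness of every adult against its *resident* patch optimum;
//   2. each offspring slot draws a source patch from the backward-migration
//      row of its destination patch;
//   3. two parents drawn (with replacement) from the source patch with
//      probability proportional to fitness; each contributes one recombined
//      gamete;
//   4. mutation on the offspring pool.
//
// Recombination uses the cumulative-hazard representation of independent
// per-interval Bernoulli crossovers: hazards h_i = -log(1 - r_i) accumulate
// along the map and successive Exp(1) draws locate switch intervals by
// binary search. Each interval fires at most once and
// P(no switch in interval i) = exp(-h_i) = 1 - r_i exactly, so the scheme
// is equivalent to per-interval Bernoulli draws at ~(1 + E[#crossovers])
// RNG draws per gamete.

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <cstdint>
#include <cstring>
#include <algorithm>

using namespace Rcpp;

namespace {

inline std::uint64_t splitmix64(std::uint64_t x) {
  x += 0x9e3779b97f4a7c15ULL;
  x = (x ^ (x >> 30)) * 0xbf58476d1ce4e5b9ULL;
  x = (x ^ (x >> 27)) * 0x94d049bb133111ebULL;
  return x ^ (x >> 31);
}

// xoshiro256++ (public-domain construction): fast, high-quality 64-bit RNG.
struct Rng {
  std::uint64_t s[4];
  void seed(std::uint64_t x) {
    for (int i = 0; i < 4; ++i) { x = splitmix64(x); s[i] = x; }
  }
  static inline std::uint64_t rotl(std::uint64_t v, int k) {
    return (v << k) | (v >> (64 - k));
  }
  inline std::uint64_t next() {
    const std::uint64_t result = rotl(s[0] + s[3], 23) + s[0];
    const std::uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3]; s[2] ^= t;
    s[3] = rotl(s[3], 45);
    return result;
  }
  inline double unif() {             // in [0, 1)
    return (next() >> 11) * 0x1.0p-53;
  }
  inline double expo() {             // Exp(1), strictly positive
    return -std::log(1.0 - unif());
  }
  double normal() {                  // Box-Muller, one value per call pair
    if (have_spare) { have_spare = false; return spare; }
    double u1, u2;
    do { u1 = unif(); } while (u1 <= 0.0);
    u2 = unif();
    const double r = std::sqrt(-2.0 * std::log(u1));
    spare = r * std::sin(6.283185307179586 * u2);
    have_spare = true;
    return r * std::cos(6.283185307179586 * u2);
  }
  long binom(long n, double p) {     // exact inversion-by-waiting for small np
    if (p <= 0.0 || n <= 0) return 0;
    // geometric skips: count successes among n Bernoulli(p)
    const double log1mp = std::log1p(-p);
    long k = 0;
    double i = 0;
    while (true) {
      double u;
      do { u = unif(); } while (u <= 0.0);
      i += std::floor(std::log(u) / log1mp) + 1;
      if (i > n) break;
      ++k;
    }
    return k;
  }
  bool have_spare = false;
  double spare = 0.0;
};

struct Engine {
  int d = 0, N = 0, L = 0, hapn = 0;
  int Ln = 0, Ls = 0;                          // neutral / selected counts
  std::vector<int> kind_sel;                   // 0/1 per global locus
  std::vector<int> col_of;                     // global locus -> column in its array
  std::vector<int> ncum, scum;                 // #neutral/#selected loci before index
  std::vector<int> sel_global;                 // selected global indices
  std::vector<std::vector<std::uint8_t>> popN, bufN;  // hapn * Ln
  std::vector<std::vector<double>> popS, bufS;        // hapn * Ls
  std::vector<double> cumhaz;                  // size L
  std::vector<double> theta;
  double VS = 5.0;
  double mu_n = 0.0, mu_a = 0.0;
  int adaptive_model = 0;                      // 0 continuum, 1 diallelic flip
  int sel_on_dest = 0;                         // fitness vs natal (0) or destination (1) optimum
  std::vector<double> mig_cum;                 // d*d cumulative rows
  long generation = 0;
  bool uniform_fallback_warned = false;
  Rng rng;
  std::vector<std::vector<double>> cumw;
  std::vector<int> switch_buf;

  // Crossover switch points (global locus indices at which the source
  // haplotype flips), plus the starting haplotype. The Exp(1) clock E can
  // be tested against the remaining hazard H without taking a log:
  // E = -log(u) < H  <=>  u > exp(-H), and exp(-total) is precomputed, so
  // the (dominant) no-crossover path costs a single uniform draw.
  double p_no_crossover = 1.0;
  inline int sample_switches(std::vector<int>& out) {
    out.clear();
    const double total = cumhaz[L - 1];
    int pos = 0;
    double base = 0.0;
    double pnone = p_no_crossover;
    while (true) {
      const double u = 1.0 - rng.unif();      // in (0, 1]
      if (u <= pnone) break;                  // clock outlives the chromosome
      const double target = base - std::log(u);
      int j = int(std::upper_bound(cumhaz.begin() + pos + 1, cumhaz.end(),
                                   target) - cumhaz.begin());
      if (j >= L) break;
      out.push_back(j);
      pos = j;
      base = cumhaz[pos];
      pnone = std::exp(base - total);
    }
    return (rng.next() & 1) ? 1 : 0;
  }

  // Copy loci [a, b) of haplotype `hap` of parent individual `pi` in patch
  // src into offspring haplotype row `oh` of patch dest buffers. Column
  // ranges come from the neutral/selected prefix counts.
  inline void copy_span(int src, int pi, int hap, int dest, int oh,
                        int a, int b) {
    const int row = 2 * pi + hap;
    const int na = ncum[a], nb = ncum[b];
    if (nb > na)
      std::memcpy(bufN[dest].data() + (std::size_t)oh * Ln + na,
                  popN[src].data() + (std::size_t)row * Ln + na,
                  (std::size_t)(nb - na));
    const int sa = scum[a], sb = scum[b];
    if (sb > sa)
      std::memcpy(bufS[dest].data() + (std::size_t)oh * Ls + sa,
                  popS[src].data() + (std::size_t)row * Ls + sa,
                  (std::size_t)(sb - sa) * sizeof(double));
  }

  inline void make_gamete(int src, int pi, int dest, int oh) {
    int cur = sample_switches(switch_buf);
    int a = 0;
    for (int j : switch_buf) {
      copy_span(src, pi, cur, dest, oh, a, j);
      cur ^= 1;
      a = j;
    }
    copy_span(src, pi, cur, dest, oh, a, L);
  }

  // cumw is indexed by (optimum patch, source patch): under natal-patch
  // selection only the diagonal is used; under destination-patch selection
  // parents for an offspring landing in q are weighted by fitness against
  // theta[q].
  // Fitness tables are indexed by (optimum patch, source patch): under
  // natal-patch selection only the diagonal is used; under
  // destination-patch selection parents for an offspring landing in q are
  // weighted by fitness against theta[q]. Parent choice is by rejection
  // sampling against the table maximum (O(1) per draw; acceptance equals
  // mean/max fitness, which stays near 1 for Gaussian stabilizing
  // selection on an adapted patch).
  std::vector<double> zbuf;
  std::vector<double> wmax, wsum;              // per (optimum, source) table
  void compute_fitness() {
    zbuf.resize((std::size_t)d * N);
    wmax.assign((std::size_t)d * d, 0.0);
    wsum.assign((std::size_t)d * d, 0.0);
    for (int p = 0; p < d; ++p) {
      const double* sp = popS[p].data();
      for (int i = 0; i < N; ++i) {
        const double* a = sp + (std::size_t)(2 * i) * Ls;
        const double* b = sp + (std::size_t)(2 * i + 1) * Ls;
        double z = 0.0;
        for (int s = 0; s < Ls; ++s) z += a[s] + b[s];
        zbuf[(std::size_t)p * N + i] = z;
      }
    }
    for (int q = 0; q < d; ++q) {              // optimum patch
      const double th = theta[q];
      for (int p = 0; p < d; ++p) {            // source patch
        if (!sel_on_dest && p != q) continue;
        std::vector<double>& w = cumw[(std::size_t)q * d + p];
        double mx = 0.0, sm = 0.0;
        for (int i = 0; i < N; ++i) {
          const double dz = zbuf[(std::size_t)p * N + i] - th;
          const double wi = std::exp(-(dz * dz) / (2.0 * VS));
          w[i] = wi;
          sm += wi;
          if (wi > mx) mx = wi;
        }
        wmax[(std::size_t)q * d + p] = mx;
        wsum[(std::size_t)q * d + p] = sm;
      }
    }
  }

  inline int sample_parent(int p, int dest) {
    const std::size_t tab = (std::size_t)(sel_on_dest ? dest : p) * d + p;
    const std::vector<double>& w = cumw[tab];
    const double mx = wmax[tab];
    if (!(wsum[tab] > 0.0) || !std::isfinite(wsum[tab])) {
      if (!uniform_fallback_warned) {
        Rcpp::warning("all fitness values ~0 in a patch; falling back to uniform parent choice");
        uniform_fallback_warned = true;
      }
      int i = int(rng.unif() * N);
      return i >= N ? N - 1 : i;
    }
    while (true) {
      int i = int(rng.unif() * N);
      if (i >= N) i = N - 1;
      if (rng.unif() * mx <= w[i]) return i;
    }
  }

  inline int sample_source(int dest) {
    const double u = rng.unif();
    const double* row = mig_cum.data() + (std::size_t)dest * d;
    for (int q = 0; q < d - 1; ++q)
      if (u < row[q]) return q;
    return d - 1;
  }

  void mutate_neutral() {
    if (mu_n <= 0.0 || Ln == 0) return;
    const long copies = (long)d * hapn * Ln;
    long nmut = rng.binom(copies, mu_n);
    std::vector<long> chosen;
    for (long k = 0; k < nmut; ++k) {
      long pick;
      bool dup;
      int guard = 0;
      do {
        pick = (long)(rng.unif() * copies);
        if (pick >= copies) pick = copies - 1;
        dup = std::find(chosen.begin(), chosen.end(), pick) != chosen.end();
      } while (dup && ++guard < 100);
      chosen.push_back(pick);
      const int li = int(pick % Ln);
      const long rest = pick / Ln;
      const int h = int(rest % hapn);
      const int p = int(rest / hapn);
      std::uint8_t& v = bufN[p][(std::size_t)h * Ln + li];
      v = 1 - v;
    }
  }

  void mutate_selected() {
    if (mu_a <= 0.0 || Ls == 0) return;
    const long copies = (long)d * hapn * Ls;
    long nmut = rng.binom(copies, mu_a);
    std::vector<long> chosen;
    for (long k = 0; k < nmut; ++k) {
      long pick;
      bool dup;
      int guard = 0;
      do {
        pick = (long)(rng.unif() * copies);
        if (pick >= copies) pick = copies - 1;
        dup = std::find(chosen.begin(), chosen.end(), pick) != chosen.end();
      } while (dup && ++guard < 100);
      chosen.push_back(pick);
      const int li = int(pick % Ls);
      const long rest = pick / Ls;
      const int h = int(rest % hapn);
      const int p = int(rest / hapn);
      double& v = bufS[p][(std::size_t)h * Ls + li];
      if (adaptive_model == 1) v = -v;        // house of cards: opposite allele
      else v += rng.normal();                 // continuum of alleles
    }
  }

  void step() {
    compute_fitness();
    for (int dest = 0; dest < d; ++dest) {
      for (int k = 0; k < N; ++k) {
        const int src = sample_source(dest);
        const int i1 = sample_parent(src, dest);
        const int i2 = sample_parent(src, dest);
        make_gamete(src, i1, dest, 2 * k);
        make_gamete(src, i2, dest, 2 * k + 1);
      }
    }
    mutate_neutral();
    mutate_selected();
    popN.swap(bufN);
    popS.swap(bufS);
    ++generation;
  }
};

void set_cumhaz(Engine& e, NumericVector rec_fractions);
void finish_cumhaz(Engine& e) {
  e.p_no_crossover = std::exp(-e.cumhaz[e.L - 1]);
}
void set_cumhaz(Engine& e, NumericVector rec_fractions) {
  if ((int)rec_fractions.size() != e.L - 1)
    stop("rec_fractions must have length nloci - 1");
  e.cumhaz.assign(e.L, 0.0);
  for (int i = 1; i < e.L; ++i) {
    const double r = rec_fractions[i - 1];
    if (r < 0.0 || r > 0.5) stop("recombination fractions must lie in [0, 0.5]");
    e.cumhaz[i] = e.cumhaz[i - 1] + (r >= 0.5 ? std::log(2.0) : -std::log1p(-r));
  }
  finish_cumhaz(e);
}

}  // namespace

// [[Rcpp::export]]
SEXP engine_create(List pop0, NumericVector rec_fractions,
                   IntegerVector selected, List par, double seed) {
  Engine* e = new Engine();
  XPtr<Engine> ptr(e, true);
  e->d = pop0.size();
  NumericMatrix m0 = pop0[0];
  e->hapn = m0.nrow();
  e->N = e->hapn / 2;
  e->L = m0.ncol();
  set_cumhaz(*e, rec_fractions);

  e->kind_sel.assign(e->L, 0);
  for (int i = 0; i < selected.size(); ++i) {
    const int s = selected[i] - 1;
    if (s < 0 || s >= e->L) stop("selected locus index out of range");
    e->kind_sel[s] = 1;
  }
  e->col_of.assign(e->L, 0);
  e->ncum.assign(e->L + 1, 0);
  e->scum.assign(e->L + 1, 0);
  for (int l = 0; l < e->L; ++l) {
    e->ncum[l] = e->Ln; e->scum[l] = e->Ls;
    if (e->kind_sel[l]) { e->col_of[l] = e->Ls++; e->sel_global.push_back(l); }
    else e->col_of[l] = e->Ln++;
  }
  e->ncum[e->L] = e->Ln; e->scum[e->L] = e->Ls;

  e->theta = as<std::vector<double>>(par["theta"]);
  if ((int)e->theta.size() != e->d) stop("theta must have one entry per patch");
  e->VS = as<double>(par["V_S"]);
  e->mu_n = as<double>(par["mu_neutral"]);
  e->mu_a = as<double>(par["mu_adaptive"]);
  e->adaptive_model = as<int>(par["adaptive_model"]);
  e->sel_on_dest = par.containsElementNamed("selection_on_destination")
    ? as<int>(par["selection_on_destination"]) : 0;
  NumericMatrix mig = par["migration"];
  if (mig.nrow() != e->d || mig.ncol() != e->d) stop("migration matrix must be d x d");
  e->mig_cum.assign((std::size_t)e->d * e->d, 0.0);
  for (int i = 0; i < e->d; ++i) {
    double acc = 0.0;
    for (int j = 0; j < e->d; ++j) {
      acc += mig(i, j);
      e->mig_cum[(std::size_t)i * e->d + j] = acc;
    }
    if (std::abs(acc - 1.0) > 1e-9) stop("migration matrix rows must sum to 1");
  }

  e->popN.resize(e->d); e->bufN.resize(e->d);
  e->popS.resize(e->d); e->bufS.resize(e->d);
  e->cumw.assign((std::size_t)e->d * e->d, std::vector<double>(e->N));
  for (int p = 0; p < e->d; ++p) {
    NumericMatrix mp = pop0[p];
    if (mp.nrow() != e->hapn || mp.ncol() != e->L)
      stop("all patch matrices must have identical dimensions");
    e->popN[p].resize((std::size_t)e->hapn * e->Ln);
    e->bufN[p].resize((std::size_t)e->hapn * e->Ln);
    e->popS[p].resize((std::size_t)e->hapn * e->Ls);
    e->bufS[p].resize((std::size_t)e->hapn * e->Ls);
    for (int h = 0; h < e->hapn; ++h)
      for (int l = 0; l < e->L; ++l) {
        const double v = mp(h, l);
        if (e->kind_sel[l]) {
          e->popS[p][(std::size_t)h * e->Ls + e->col_of[l]] = v;
        } else {
          if (v != 0.0 && v != 1.0)
            stop("neutral allele values must be 0 or 1");
          e->popN[p][(std::size_t)h * e->Ln + e->col_of[l]] = (std::uint8_t)v;
        }
      }
  }
  e->rng.seed((std::uint64_t)seed);
  return ptr;
}

// [[Rcpp::export]]
void engine_run(SEXP ptr, int ngens) {
  XPtr<Engine> e(ptr);
  for (int g = 0; g < ngens; ++g) {
    e->step();
    if ((g & 1023) == 1023) Rcpp::checkUserInterrupt();
  }
}

// [[Rcpp::export]]
List engine_state(SEXP ptr) {
  XPtr<Engine> e(ptr);
  List out(e->d);
  for (int p = 0; p < e->d; ++p) {
    NumericMatrix mp(e->hapn, e->L);
    for (int h = 0; h < e->hapn; ++h)
      for (int l = 0; l < e->L; ++l)
        mp(h, l) = e->kind_sel[l]
          ? e->popS[p][(std::size_t)h * e->Ls + e->col_of[l]]
          : (double)e->popN[p][(std::size_t)h * e->Ln + e->col_of[l]];
    out[p] = mp;
  }
  return out;
}

// [[Rcpp::export]]
double engine_generation(SEXP ptr) {
  XPtr<Engine> e(ptr);
  return (double)e->generation;
}

// Stand-alone gamete sampler for unit tests: n gametes from one diploid
// parent given per-interval recombination fractions. Allele values are
// arbitrary doubles here (no neutral/selected split).
// [[Rcpp::export]]
NumericMatrix sim_gametes_cpp(NumericMatrix parent, NumericVector rec_fractions,
                              int n, double seed) {
  if (parent.nrow() != 2) stop("parent must be a 2 x L haplotype matrix");
  Engine e;
  e.L = parent.ncol();
  set_cumhaz(e, rec_fractions);
  e.rng.seed((std::uint64_t)seed);
  NumericMatrix out(n, e.L);
  std::vector<int> sw;
  for (int k = 0; k < n; ++k) {
    int cur = e.sample_switches(sw);
    int a = 0;
    for (int j : sw) {
      for (int l = a; l < j; ++l) out(k, l) = parent(cur, l);
      cur ^= 1;
      a = j;
    }
    for (int l = a; l < e.L; ++l) out(k, l) = parent(cur, l);
  }
  return out;
}
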