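#include <Rcpp.h>
#include <cstdint>
#include <set>
#include <utility>
#include <vector>

using namespace Rcpp;

// A chromosome selects a row subset and a column subset; both axes are held
// as 64-bit masks, which bounds GA grids at 64 rows and 64 columns (the
// exhaustive optimizer in R has no such limit but its own R + C cap).
struct Chrom {
  uint64_t rows;
  uint64_t cols;
  bool operator<(const Chrom &o) const {
    return rows != o.rows ? rows < o.rows : cols < o.cols;
  }
  bool operator==(const Chrom &o) const {
    return rows == o.rows && cols == o.cols;
  }
};

struct Profile {
  int R, C, n;
  std::vector<uint64_t> rowbits;  // per row: column occupancy of the 1 cells
  std::vector<int> rs, cs;        // row / column sums
};

static Profile make_profile(const IntegerMatrix &E) {
  Profile p;
  p.R = E.nrow();
  p.C = E.ncol();
  p.n = 0;
  p.rowbits.assign(p.R, 0);
  p.rs.assign(p.R, 0);
  p.cs.assign(p.C, 0);
  for (int i = 0; i < p.R; ++i)
    for (int j = 0; j < p.C; ++j) {
      if (!E(i, j)) continue;
      p.rowbits[i] |= (uint64_t(1) << j);
      ++p.rs[i];
      ++p.cs[j];
      ++p.n;
    }
  return p;
}

// d = covered - 2 * (ones inside the covered cells) + n
static int chrom_distance(const Profile &p, const Chrom &ch) {
  int sizeS = __builtin_popcountll(ch.rows);
  int sizeT = __builtin_popcountll(ch.cols);
  int ones = 0, cross = 0;
  for (uint64_t m = ch.rows; m; m &= m - 1) {
    int i = __builtin_ctzll(m);
    ones += p.rs[i];
    cross += __builtin_popcountll(p.rowbits[i] & ch.cols);
  }
  for (uint64_t m = ch.cols; m; m &= m - 1) ones += p.cs[__builtin_ctzll(m)];
  int covered = sizeS * p.C + sizeT * p.R - sizeS * sizeT;
  return covered - 2 * (ones - cross) + p.n;
}

static int rand_below(int k) {
  int v = (int)(unif_rand() * k);
  return v >= k ? k - 1 : v;
}

static uint64_t rand_bits(int k) {
  uint64_t out = 0;
  for (int off = 0; off < k; off += 32)
    out |= (uint64_t)(unif_rand() * 4294967296.0) << off;
  return k == 64 ? out : (out & ((uint64_t(1) << k) - 1));
}

// Any chromosome covering the whole grid materializes to the all-one matrix;
// use the everything-selected encoding as its canonical representative.
static Chrom canonical(const Chrom &ch, int R, int C) {
  uint64_t fullR = (R == 64) ? ~uint64_t(0) : ((uint64_t(1) << R) - 1);
  uint64_t fullC = (C == 64) ? ~uint64_t(0) : ((uint64_t(1) << C) - 1);
  if (__builtin_popcountll(ch.rows) == R || __builtin_popcountll(ch.cols) == C)
    return Chrom{fullR, fullC};
  return ch;
}

struct GAResult {
  int dist;
  std::set<Chrom> ties;
  bool tie_overflow;
};

static GAResult ga_core(const Profile &p, int pop_size, int max_gen,
                        double pcross, double pmut, int tour, int elitism,
                        int stagnation, int max_ties, bool track_ties) {
  const int R = p.R, C = p.C, B = R + C;

  // Initial population: null chromosome, every one-hot, random fill.
  std::vector<Chrom> pop;
  pop.reserve(pop_size);
  pop.push_back(Chrom{0, 0});
  for (int b = 0; b < B && (int)pop.size() < pop_size; ++b) {
    Chrom c{0, 0};
    if (b < R) c.rows = uint64_t(1) << b; else c.cols = uint64_t(1) << (b - R);
    pop.push_back(c);
  }
  while ((int)pop.size() < pop_size)
    pop.push_back(Chrom{rand_bits(R), rand_bits(C)});

  GAResult res;
  res.dist = INT32_MAX;
  res.tie_overflow = false;

  auto record = [&](const Chrom &ch, int d) {
    if (d < res.dist) {
      res.dist = d;
      res.ties.clear();
      res.tie_overflow = false;
      res.ties.insert(canonical(ch, R, C));
      return true;
    }
    if (d == res.dist && track_ties) {
      Chrom cc = canonical(ch, R, C);
      if ((int)res.ties.size() < max_ties)
        res.ties.insert(cc);
      else if (res.ties.find(cc) == res.ties.end())
        res.tie_overflow = true;
    }
    return false;
  };

  std::vector<int> fit(pop_size);
  for (int k = 0; k < pop_size; ++k) {
    fit[k] = chrom_distance(p, pop[k]);
    record(pop[k], fit[k]);
  }

  int stagnant = 0;
  std::vector<Chrom> next;
  next.reserve(pop_size);
  std::vector<int> order(pop_size);
  for (int gen = 0; gen < max_gen && stagnant < stagnation; ++gen) {
    next.clear();
    for (int k = 0; k < pop_size; ++k) order[k] = k;
    std::partial_sort(order.begin(), order.begin() + elitism, order.end(),
                      [&](int a, int b) { return fit[a] < fit[b]; });
    for (int e = 0; e < elitism; ++e) next.push_back(pop[order[e]]);

    auto tournament = [&]() -> const Chrom & {
      int best = rand_below(pop_size);
      for (int t = 1; t < tour; ++t) {
        int cand = rand_below(pop_size);
        if (fit[cand] < fit[best]) best = cand;
      }
      return pop[best];
    };

    while ((int)next.size() < pop_size) {
      const Chrom &pa = tournament();
      Chrom child;
      if (unif_rand() < pcross) {  // uniform crossover via random bit masks
        const Chrom &pb = tournament();
        uint64_t mr = rand_bits(R), mc = rand_bits(C);
        child.rows = (pa.rows & mr) | (pb.rows & ~mr);
        child.cols = (pa.cols & mc) | (pb.cols & ~mc);
      } else {
        child = pa;
      }
      // Per-bit flip mutation: draw the flip count, then distinct positions.
      int nmut = (int)R::rbinom(B, pmut);
      uint64_t fr = 0, fc = 0;
      while (__builtin_popcountll(fr) + __builtin_popcountll(fc) < nmut) {
        int b = rand_below(B);
        if (b < R) fr |= uint64_t(1) << b; else fc |= uint64_t(1) << (b - R);
      }
      child.rows ^= fr;
      child.cols ^= fc;
      next.push_back(child);
    }
    pop.swap(next);

    bool improved = false;
    for (int k = 0; k < pop_size; ++k) {
      fit[k] = chrom_distance(p, pop[k]);
      if (record(pop[k], fit[k])) improved = true;
    }
    stagnant = improved ? 0 : stagnant + 1;
  }
  return res;
}

// [[Rcpp::export]]
List cpp_ga_optimize(IntegerMatrix E, int pop_size, int max_gen, double pcross,
                     double pmut, int tour, int elitism, int stagnation,
                     int max_ties) {
  const int R = E.nrow(), C = E.ncol();
  if (R > 64 || C > 64)
    stop("the genetic algorithm supports at most 64 rows and 64 columns");
  Profile p = make_profile(E);
  GAResult res = ga_core(p, pop_size, max_gen, pcross, pmut, tour, elitism,
                         stagnation, max_ties, true);
  IntegerMatrix ties(res.ties.size(), R + C);
  int r = 0;
  for (const Chrom &c : res.ties) {
    for (int i = 0; i < R; ++i) ties(r, i) = (c.rows >> i) & 1;
    for (int j = 0; j < C; ++j) ties(r, R + j) = (c.cols >> j) & 1;
    ++r;
  }
  return List::create(Named("distance") = res.dist, Named("ties") = ties,
                      Named("tie_overflow") = res.tie_overflow);
}

// Exact minimum pattern distance by enumerating every subset of the shorter
// axis; for a fixed column set the optimal row choice separates per row.
static int exact_min(const Profile &p) {
  const int R = p.R, C = p.C;
  if (C > 25) stop("grid too large for exact enumeration (shorter axis > 25)");
  const uint64_t full = (uint64_t(1) << C) - 1;
  int best = p.n;  // null pattern
  for (uint64_t mask = 0; mask <= full; ++mask) {
    int sizeT = __builtin_popcountll(mask);
    int colsum = 0;
    for (uint64_t m = mask; m; m &= m - 1) colsum += p.cs[__builtin_ctzll(m)];
    int d = sizeT * R - 2 * colsum + p.n;
    const int width = C - sizeT;
    for (int i = 0; i < R; ++i) {
      int outside = __builtin_popcountll(p.rowbits[i] & ~mask & full);
      int delta = width - 2 * outside;
      if (delta < 0) d += delta;
    }
    if (d < best) best = d;
  }
  return best;
}

static Profile transpose_profile(const Profile &p) {
  Profile t;
  t.R = p.C; t.C = p.R; t.n = p.n;
  t.rowbits.assign(t.R, 0);
  t.rs = p.cs;
  t.cs = p.rs;
  for (int i = 0; i < p.R; ++i)
    for (uint64_t m = p.rowbits[i]; m; m &= m - 1) {
      int j = __builtin_ctzll(m);
      t.rowbits[j] |= uint64_t(1) << i;
    }
  return t;
}

// [[Rcpp::export]]
int cpp_exact_min_distance(IntegerMatrix E) {
  Profile p = make_profile(E);
  if (E.ncol() > E.nrow()) p = transpose_profile(p);
  return exact_min(p);
}

// Optimal distances of L uniformly drawn profiles with exactly n ones.
// [[Rcpp::export]]
IntegerVector cpp_null_distances(int n, int R, int C, int L, bool use_ga,
                                 int pop_size, int max_gen, double pcross,
                                 double pmut, int tour, int elitism,
                                 int stagnation) {
  const int cells = R * C;
  if (n < 0 || n > cells) stop("n must lie in [0, R*C]");
  if (use_ga && (R > 64 || C > 64))
    stop("the genetic algorithm supports at most 64 rows and 64 columns");
  const bool flip = !use_ga && C > R;  // exact path enumerates the short axis
  std::vector<int> idx(cells);
  IntegerVector out(L);
  Profile p;
  p.R = flip ? C : R;
  p.C = flip ? R : C;
  for (int k = 0; k < L; ++k) {
    for (int c = 0; c < cells; ++c) idx[c] = c;
    p.n = n;
    p.rowbits.assign(p.R, 0);
    p.rs.assign(p.R, 0);
    p.cs.assign(p.C, 0);
    for (int i = 0; i < n; ++i) {  // partial Fisher-Yates draw of n cells
      int j = i + rand_below(cells - i);
      std::swap(idx[i], idx[j]);
      int row = idx[i] % R, col = idx[i] / R;  // column-major like R matrices
      int ii = flip ? col : row, jj = flip ? row : col;
      p.rowbits[ii] |= uint64_t(1) << jj;
      ++p.rs[ii];
      ++p.cs[jj];
    }
    out[k] = use_ga
      ? ga_core(p, pop_size, max_gen, pcross, pmut, tour, elitism, stagnation,
                1, false).dist
      : exact_min(p);
  }
  return out;
}
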