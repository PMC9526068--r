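// Kingman coalescent simulator.
//
// Waiting time with k active lineages is Exponential(rate k(k-1)/2), time in
// coalescent units of N generations; the merging pair is uniform over the
// k-choose-2 unordered pairs.
//
// Randomness comes from a counter-based generator: replicate r of a run with
// seed s draws from its own SplitMix64 stream, so replicate streams are
// independent of chunking and identical trees are reproduced from
// (n, seed, replicate) alone.

#include <Rcpp.h>
#include <cstdint>
#include <cmath>

namespace {

struct SplitMix64 {
  uint64_t state;
  explicit SplitMix64(uint64_t s) : state(s) {}
  uint64_t next() {
    uint64_t z = (state += 0x9E3779B97F4A7C15ULL);
    z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
    z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
    return z ^ (z >> 31);
  }
  // uniform double in [0, 1)
  double unif() { return (next() >> 11) * 0x1.0p-53; }
  // exponential with given rate, strictly positive
  double rexp(double rate) {
    double u = unif();
    return -std::log1p(-u) / rate;
  }
  // uniform integer in {0, ..., m-1}
  int unif_int(int m) {
    int v = static_cast<int>(unif() * m);
    return v >= m ? m - 1 : v;
  }
};

inline uint64_t mix64(uint64_t z) {
  z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
  z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
  return z ^ (z >> 31);
}

inline SplitMix64 replicate_stream(int seed, int replicate) {
  // hash the seed nonlinearly before deriving the stream: SplitMix64
  // advances its state linearly, so an affine function of the seed would
  // make nearby seeds produce shifted copies of the same draw sequence
  uint64_t s = mix64(static_cast<uint64_t>(static_cast<uint32_t>(seed)) +
                     0x9E3779B97F4A7C15ULL) +
               static_cast<uint64_t>(replicate) * 0xD1B54A32D192ED03ULL;
  return SplitMix64(mix64(s));
}

}  // namespace

// Simulate one genealogy and return its full description.
// Leaves are labelled 1..n; internal nodes n+1..2n-1 in coalescence order,
// so node 2n-1 is the root. times[j] is the waiting time while n-j lineages
// are active (j = 0 gives T_n, the last entry gives T_2).
// [[Rcpp::export(name = ".sim_tree")]]
Rcpp::List sim_tree(int n, int seed, int replicate) {
  if (n < 2) Rcpp::stop("a coalescent tree needs at least n = 2 leaves");
  SplitMix64 g = replicate_stream(seed, replicate);

  std::vector<int> active(n);
  std::vector<double> node_age(2 * n - 1, 0.0);
  for (int i = 0; i < n; ++i) active[i] = i + 1;

  Rcpp::NumericVector times(n - 1);
  Rcpp::IntegerMatrix merges(n - 1, 2);
  double t = 0.0;
  for (int k = n; k >= 2; --k) {
    double rate = k * (k - 1) / 2.0;
    double wait = g.rexp(rate);
    t += wait;
    times[n - k] = wait;
    int i = g.unif_int(k);
    int j = g.unif_int(k - 1);
    if (j >= i) ++j;
    if (i > j) std::swap(i, j);
    int a = active[i], b = active[j];
    int parent = n + (n - k) + 1;
    node_age[parent - 1] = t;
    merges(n - k, 0) = a;
    merges(n - k, 1) = b;
    active[i] = parent;
    active.erase(active.begin() + j);
  }

  return Rcpp::List::create(
      Rcpp::Named("n") = n,
      Rcpp::Named("times") = times,
      Rcpp::Named("merges") = merges,
      Rcpp::Named("node_age") = Rcpp::NumericVector(node_age.begin(), node_age.end()));
}

// Batch simulation returning per-tree summary statistics only.
// Columns: H, L, E, I, B, T_2, ..., T_n. B is NA_real_ when n < 4 unless
// basal_always is set.
// [[Rcpp::export(name = ".sim_stats")]]
Rcpp::NumericMatrix sim_stats(int n, int reps, int seed, bool basal_always) {
  if (n < 2) Rcpp::stop("a coalescent tree needs at least n = 2 leaves");
  if (reps < 1) Rcpp::stop("reps must be >= 1");
  int ncol = 5 + (n - 1);
  Rcpp::NumericMatrix out(reps, ncol);

  std::vector<double> birth(n);   // age at which each active lineage was created
  std::vector<char> is_leaf(n);

  for (int r = 0; r < reps; ++r) {
    SplitMix64 g = replicate_stream(seed, r + 1);
    for (int i = 0; i < n; ++i) { birth[i] = 0.0; is_leaf[i] = 1; }
    int m = n;
    double t = 0.0, H = 0.0, L = 0.0, E = 0.0;
    double basal = NA_REAL;
    int leaves_active = n;
    for (int k = n; k >= 2; --k) {
      double rate = k * (k - 1) / 2.0;
      double wait = g.rexp(rate);
      H += wait;
      L += k * wait;
      E += leaves_active * wait;
      t += wait;
      out(r, 5 + (n - k)) = wait;  // T_k stored at column 5 + (n - k)? see below
      int i = g.unif_int(m);
      int j = g.unif_int(m - 1);
      if (j >= i) ++j;
      if (i > j) std::swap(i, j);
      if (k == 2) {
        basal = ((t - birth[i]) + (t - birth[j])) / 2.0;
      }
      leaves_active -= (is_leaf[i] ? 1 : 0) + (is_leaf[j] ? 1 : 0);
      birth[i] = t;
      is_leaf[i] = 0;
      birth.erase(birth.begin() + j);
      is_leaf.erase(is_leaf.begin() + j);
      --m;
    }
    birth.resize(n);
    is_leaf.resize(n);
    out(r, 0) = H;
    out(r, 1) = L;
    out(r, 2) = E;
    out(r, 3) = L - E;
    out(r, 4) = (n >= 4 || basal_always) ? basal : NA_REAL;
  }

  // column order for T: stored above at 5 + (n - k), i.e. T_n first; reorder
  // to T_2..T_n for a friendlier interface.
  Rcpp::NumericMatrix res(reps, ncol);
  for (int r = 0; r < reps; ++r) {
    for (int c = 0; c < 5; ++c) res(r, c) = out(r, c);
    for (int k = 2; k <= n; ++k) res(r, 5 + (k - 2)) = out(r, 5 + (n - k));
  }
  Rcpp::CharacterVector nm(ncol);
  nm[0] = "H"; nm[1] = "L"; nm[2] = "E"; nm[3] = "I"; nm[4] = "B";
  for (int k = 2; k <= n; ++k) nm[5 + (k - 2)] = "T" + std::to_string(k);
  Rcpp::colnames(res) = nm;
  return res;
}
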