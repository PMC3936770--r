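#include <Rcpp.h>
#include <cmath>
#include <string>
#include <vector>

using namespace Rcpp;

// Site states are coded 0 = u, 1 = h, 2 = m.
//
// Reactions are indexed in the canonical catalogue order used throughout
// the package:
//   0 u+    u -> h          1 h+    h -> m
//   2 h-    h -> u          3 m-    m -> h
//   4 u+m   u -> h | med m  5 u+h   u -> h | med h
//   6 h+m   h -> m | med m  7 h+h   h -> m | med h
//   8 m-u   m -> h | med u  9 m-h   m -> h | med h
//  10 h-u   h -> u | med u 11 h-h   h -> u | med h
// The four self-destruction combinations (u-mediated methylation,
// m-mediated demethylation) are not representable.

namespace {

const int R_TARGET[12] = {0, 1, 1, 2, 0, 0, 1, 1, 2, 2, 1, 1};
const int R_PRODUCT[12] = {1, 2, 0, 1, 1, 1, 2, 2, 1, 1, 0, 0};
const int R_MED[12] = {-1, -1, -1, -1, 2, 1, 2, 1, 0, 1, 0, 1};

inline int rand_index(int n) {
  int k = (int)(unif_rand() * n);
  return (k >= n) ? n - 1 : k;
}

struct SpatialCtx {
  bool enabled;
  const double *coords;
  const int *island;
  double alpha;
  bool restrict_demeth;
  std::vector<int> island_idx; // indices of island sites
};

// One reaction attempt on state s. Returns the completed reaction index,
// or -1 if the attempt was a no-op / failed the applicability test.
// Counts n (length 3) are kept in sync when non-null.
inline int do_attempt(std::vector<int> &s, int L, const double *cum,
                      double tot, const SpatialCtx &sp, int *n) {
  double r = unif_rand();
  if (r >= tot) return -1; // unassigned probability mass: no-op attempt
  int k = 0;
  while (r >= cum[k]) ++k;
  int t = rand_index(L);
  if (s[t] != R_TARGET[k]) return -1;
  if (k >= 4) {
    const int medstate = R_MED[k];
    if (!sp.enabled) {
      // mediator: uniform over all sites excluding the target
      int med = rand_index(L - 1);
      if (med >= t) ++med;
      if (s[med] != medstate) return -1;
    } else if (k < 8) {
      // collaborative methylation: nearest-neighbour mediator
      int med;
      if (t == 0)
        med = 1;
      else if (t == L - 1)
        med = L - 2;
      else
        med = (unif_rand() < 0.5) ? t - 1 : t + 1;
      if (s[med] != medstate) return -1;
    } else {
      // collaborative demethylation: with the island restriction on, the
      // mediating enzyme is recruited at the island, so the mediator is
      // drawn uniformly over island sites (excluding the target);
      // otherwise uniformly over all other sites as in the global model.
      // The mediator must match the reaction's mediator state, and the
      // interaction then succeeds with the contact probability
      // alpha/(x + alpha) -- the 1/(x + alpha) looping decay normalized
      // to 1 at zero separation.
      int med;
      if (sp.restrict_demeth) {
        const int ni = (int)sp.island_idx.size();
        if (ni == 0 || (ni == 1 && sp.island_idx[0] == t)) return -1;
        do {
          med = sp.island_idx[rand_index(ni)];
        } while (med == t);
      } else {
        med = rand_index(L - 1);
        if (med >= t) ++med;
      }
      if (s[med] != medstate) return -1;
      double x = std::fabs(sp.coords[med] - sp.coords[t]);
      if (unif_rand() * (x + sp.alpha) >= sp.alpha) return -1;
    }
  }
  if (n) {
    n[s[t]]--;
    n[R_PRODUCT[k]]++;
  }
  s[t] = R_PRODUCT[k];
  return k;
}

// Semiconservative replication: u -> u, m -> h, h -> h or u with
// probability 1/2 each (one daughter strand is followed).
inline void replicate_inplace(std::vector<int> &s) {
  for (size_t i = 0; i < s.size(); ++i) {
    if (s[i] == 2)
      s[i] = 1;
    else if (s[i] == 1 && unif_rand() < 0.5)
      s[i] = 0;
  }
}

inline int classify_counts(const int *n, int L, double lower, double upper) {
  double f = (2.0 * n[2] + n[1]) / (2.0 * L);
  if (f < lower) return 0;
  if (f > upper) return 2;
  return 1;
}

} // namespace

// [[Rcpp::export]]
IntegerVector cpp_replicate(IntegerVector state) {
  std::vector<int> s(state.begin(), state.end());
  replicate_inplace(s);
  return IntegerVector(s.begin(), s.end());
}

// Core generation loop. Each generation applies replication first, then
// A reaction attempts (A = N_t * L fixed, or Poisson with that mean), and
// records end-of-generation counts, per-reaction completion counts and
// within-generation time-averaged densities.
//
// stop_class: -1 = run the full horizon; otherwise stop at the end of the
// first generation whose classification (thresholds lower/upper on the
// methylation level) equals stop_class (0 = U, 1 = intermediate, 2 = M).
// [[Rcpp::export]]
List cpp_simulate(IntegerVector init, NumericVector rates, int n_gen,
                  double n_attempts_per_site, bool poisson_attempts,
                  bool record_full, bool track_tavg, bool spatial,
                  NumericVector coords, IntegerVector island, double alpha,
                  bool restrict_demeth, int stop_class, double lower,
                  double upper) {
  const int L = init.size();
  std::vector<int> s(init.begin(), init.end());
  double cum[12];
  double tot = 0.0;
  for (int k = 0; k < 12; ++k) {
    tot += rates[k];
    cum[k] = tot;
  }
  SpatialCtx sp;
  sp.enabled = spatial;
  sp.coords = spatial ? REAL(coords) : (double *)nullptr;
  sp.island = spatial ? INTEGER(island) : (int *)nullptr;
  sp.alpha = alpha;
  sp.restrict_demeth = spatial && restrict_demeth;
  if (sp.restrict_demeth)
    for (int j = 0; j < (int)island.size(); ++j)
      if (island[j]) sp.island_idx.push_back(j);

  NumericMatrix rec(n_gen, 20);
  std::vector<std::string> fullstates;
  if (record_full) fullstates.reserve(n_gen);
  static const char CODE[3] = {'u', 'h', 'm'};

  int done = 0;
  bool stopped = false;
  for (int g = 0; g < n_gen; ++g) {
    replicate_inplace(s);
    int n[3] = {0, 0, 0};
    for (int i = 0; i < L; ++i) n[s[i]]++;
    long A = poisson_attempts
                 ? (long)R::rpois(n_attempts_per_site * L)
                 : (long)std::llround(n_attempts_per_site * L);
    double comp[12] = {0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0};
    double tavg[3] = {0.0, 0.0, 0.0};
    for (long a = 0; a < A; ++a) {
      if (track_tavg) {
        tavg[0] += n[0];
        tavg[1] += n[1];
        tavg[2] += n[2];
      }
      int k = do_attempt(s, L, cum, tot, sp, n);
      if (k >= 0) comp[k] += 1.0;
    }
    rec(g, 0) = g + 1;
    rec(g, 1) = n[0];
    rec(g, 2) = n[1];
    rec(g, 3) = n[2];
    rec(g, 4) = (double)A;
    for (int k = 0; k < 12; ++k) rec(g, 5 + k) = comp[k];
    if (track_tavg && A > 0) {
      rec(g, 17) = tavg[0] / ((double)A * L);
      rec(g, 18) = tavg[1] / ((double)A * L);
      rec(g, 19) = tavg[2] / ((double)A * L);
    } else {
      rec(g, 17) = n[0] / (double)L;
      rec(g, 18) = n[1] / (double)L;
      rec(g, 19) = n[2] / (double)L;
    }
    if (record_full) {
      std::string row(L, 'u');
      for (int i = 0; i < L; ++i) row[i] = CODE[s[i]];
      fullstates.push_back(row);
    }
    done = g + 1;
    if (stop_class >= 0 &&
        classify_counts(n, L, lower, upper) == stop_class) {
      stopped = true;
      break;
    }
  }

  NumericMatrix out(done, 20);
  for (int g = 0; g < done; ++g)
    for (int c = 0; c < 20; ++c) out(g, c) = rec(g, c);
  List res = List::create(
      Named("records") = out,
      Named("final_state") = IntegerVector(s.begin(), s.end()),
      Named("stopped") = stopped);
  if (record_full) res["full_states"] = wrap(fullstates);
  return res;
}

// n_trials independent single attempts, each starting from the same
// initial state (no replication). Returns the matrix of end states, one
// trial per row. Used to compare the engine's one-attempt transition
// kernel against a brute-force enumerated transition matrix.
// [[Rcpp::export]]
IntegerMatrix cpp_attempt_trials(IntegerVector init, NumericVector rates,
                                 int n_trials, bool spatial,
                                 NumericVector coords, IntegerVector island,
                                 double alpha, bool restrict_demeth) {
  const int L = init.size();
  double cum[12];
  double tot = 0.0;
  for (int k = 0; k < 12; ++k) {
    tot += rates[k];
    cum[k] = tot;
  }
  SpatialCtx sp;
  sp.enabled = spatial;
  sp.coords = spatial ? REAL(coords) : (double *)nullptr;
  sp.island = spatial ? INTEGER(island) : (int *)nullptr;
  sp.alpha = alpha;
  sp.restrict_demeth = spatial && restrict_demeth;
  if (sp.restrict_demeth)
    for (int j = 0; j < (int)island.size(); ++j)
      if (island[j]) sp.island_idx.push_back(j);

  IntegerMatrix out(n_trials, L);
  std::vector<int> s(L);
  for (int i = 0; i < n_trials; ++i) {
    std::copy(init.begin(), init.end(), s.begin());
    do_attempt(s, L, cum, tot, sp, (int *)nullptr);
    for (int j = 0; j < L; ++j) out(i, j) = s[j];
  }
  return out;
}
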