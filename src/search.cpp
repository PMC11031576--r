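// Simulated-annealing structure search and exhaustive DAG enumeration
// under the BDeu score. Structures are parent-set bitmasks (<= 64
// variables); family scores are memoized per (child, parent mask). All
// randomness comes from R's RNG so set.seed() governs the whole search.
#include <Rcpp.h>
#include <vector>
#include <set>
#include <unordered_map>
#include <cstdint>
using namespace Rcpp;

typedef std::vector<uint64_t> Masks;

static int popcount64(uint64_t x) {
  int c = 0;
  while (x) { x &= x - 1; ++c; }
  return c;
}

// BDeu local score of (child | parents given by mask).
static double family_score_raw(const IntegerMatrix& data,
                               const IntegerVector& card,
                               int child, uint64_t mask, double ess) {
  const int n = data.nrow();
  std::vector<int> parents;
  for (int i = 0; i < data.ncol(); ++i)
    if ((mask >> i) & 1ULL) parents.push_back(i);
  long q = 1;
  for (size_t i = 0; i < parents.size(); ++i) q *= card[parents[i]];
  const int r = card[child];
  std::vector<int> counts((size_t)q * r, 0);
  for (int row = 0; row < n; ++row) {
    long j = 0, mult = 1;
    for (size_t i = 0; i < parents.size(); ++i) {
      j += data(row, parents[i]) * mult;
      mult *= card[parents[i]];
    }
    counts[(size_t)j * r + data(row, child)]++;
  }
  const double a_jk = ess / (double)(q * (long)r);
  const double a_j = ess / (double)q;
  const double lg_ajk = ::Rf_lgammafn(a_jk);
  const double lg_aj = ::Rf_lgammafn(a_j);
  double s = 0.0;
  for (long j = 0; j < q; ++j) {
    int nj = 0;
    for (int k = 0; k < r; ++k) {
      const int c = counts[(size_t)j * r + k];
      if (c) { nj += c; s += ::Rf_lgammafn(a_jk + c) - lg_ajk; }
    }
    if (nj) s += lg_aj - ::Rf_lgammafn(a_j + nj);
  }
  return s;
}

struct ScoreCache {
  std::vector< std::unordered_map<uint64_t, double> > maps;
  const IntegerMatrix& data;
  const IntegerVector& card;
  double ess;
  ScoreCache(const IntegerMatrix& d, const IntegerVector& c, double e)
    : maps(d.ncol()), data(d), card(c), ess(e) {}
  double get(int child, uint64_t mask) {
    std::unordered_map<uint64_t, double>& m = maps[child];
    std::unordered_map<uint64_t, double>::iterator it = m.find(mask);
    if (it != m.end()) return it->second;
    double s = family_score_raw(data, card, child, mask, ess);
    m.insert(std::make_pair(mask, s));
    return s;
  }
};

struct Move { int kind; int from; int to; };  // 0 add, 1 delete, 2 reverse

// Descendant bitmask per node (excluding the node itself), by memoized DFS;
// valid because the graph is acyclic.
static void descendant_masks(const Masks& pa, int p, Masks& desc) {
  Masks children(p, 0ULL);
  for (int u = 0; u < p; ++u)
    for (int v = 0; v < p; ++v)
      if ((pa[u] >> v) & 1ULL) children[v] |= (1ULL << u);
  std::vector<char> state(p, 0);  // 0 unvisited, 1 done
  // iterative post-order over the DAG
  for (int start = 0; start < p; ++start) {
    if (state[start]) continue;
    std::vector<int> stack;
    stack.push_back(start);
    while (!stack.empty()) {
      int v = stack.back();
      uint64_t pending = 0ULL;
      for (int u = 0; u < p; ++u)
        if (((children[v] >> u) & 1ULL) && !state[u]) pending |= (1ULL << u);
      if (pending) {
        for (int u = 0; u < p; ++u)
          if ((pending >> u) & 1ULL) stack.push_back(u);
      } else {
        desc[v] = children[v];
        for (int u = 0; u < p; ++u)
          if ((children[v] >> u) & 1ULL) desc[v] |= desc[u];
        state[v] = 1;
        stack.pop_back();
      }
    }
  }
}

static void enumerate_moves(const Masks& pa, int p, int max_parents,
                            std::vector<Move>& out) {
  out.clear();
  Masks desc(p, 0ULL);
  descendant_masks(pa, p, desc);
  for (int x = 0; x < p; ++x) {
    const bool x_has_room = popcount64(pa[x]) + 1 <= max_parents;
    for (int y = 0; y < p; ++y) {
      if (x == y) continue;
      if ((pa[y] >> x) & 1ULL) {                  // arc x -> y present
        Move del = {1, x, y}; out.push_back(del);
        // reverse legal iff x can take a parent and no alternative
        // x ~> y path runs through another child of x (such a path cannot
        // use the arc x -> y itself: revisiting x would close a cycle)
        if (x_has_room) {
          bool alt = false;
          for (int c = 0; c < p && !alt; ++c) {
            if (c == y || !((pa[c] >> x) & 1ULL)) continue;
            if ((desc[c] >> y) & 1ULL) alt = true;
          }
          if (!alt) { Move rev = {2, x, y}; out.push_back(rev); }
        }
      } else if (!((pa[x] >> y) & 1ULL)) {        // no arc either way
        if (popcount64(pa[y]) + 1 <= max_parents &&
            !((desc[y] >> x) & 1ULL)) {
          Move add = {0, x, y}; out.push_back(add);
        }
      }
    }
  }
}

// Arc list of a structure sorted by (from, to) — canonical order used for
// deterministic tie-breaking among equal-scoring networks.
static std::vector<std::pair<int,int> > arc_list(const Masks& pa, int p) {
  std::vector<std::pair<int,int> > arcs;
  for (int from = 0; from < p; ++from)
    for (int to = 0; to < p; ++to)
      if ((pa[to] >> from) & 1ULL)
        arcs.push_back(std::make_pair(from, to));
  return arcs;
}

struct TopEntry {
  double score;
  std::vector<std::pair<int,int> > arcs;
  Masks masks;
};

// Orders entries worst-first: lower score first; on score ties the
// lexicographically LARGER arc list is "worse" so the kept set matches a
// descending (score, then ascending arc-list) ranking.
struct WorstFirst {
  bool operator()(const TopEntry& a, const TopEntry& b) const {
    if (a.score != b.score) return a.score < b.score;
    return a.arcs > b.arcs;
  }
};

class TopSet {
public:
  TopSet(size_t n) : capacity(n) {}
  void offer(double score, const Masks& pa, int p) {
    if (entries.size() == capacity) {
      const TopEntry& worst = *entries.begin();
      if (score < worst.score) return;  // cheap reject, no key needed
    }
    if (keys.count(pa)) return;
    TopEntry e; e.score = score; e.arcs = arc_list(pa, p); e.masks = pa;
    if (entries.size() == capacity) {
      const TopEntry& worst = *entries.begin();
      WorstFirst cmp;
      if (!cmp(worst, e)) return;       // not better than current worst
      keys.erase(worst.masks);
      entries.erase(entries.begin());
    }
    keys.insert(pa);
    entries.insert(e);
  }
  List as_list(int p) const {
    // best first
    List out(entries.size());
    int i = 0;
    for (std::set<TopEntry, WorstFirst>::const_reverse_iterator it =
           entries.rbegin(); it != entries.rend(); ++it, ++i) {
      IntegerMatrix am(it->arcs.size(), 2);
      for (size_t a = 0; a < it->arcs.size(); ++a) {
        am(a, 0) = it->arcs[a].first + 1;   // 1-based for R
        am(a, 1) = it->arcs[a].second + 1;
      }
      out[i] = List::create(Named("arcs") = am,
                            Named("log_score") = it->score);
    }
    return out;
  }
private:
  size_t capacity;
  std::set<TopEntry, WorstFirst> entries;
  std::set<Masks> keys;
};

// [[Rcpp::export]]
IntegerMatrix legal_moves_cpp(IntegerMatrix arcs, int p, int max_parents) {
  Masks pa(p, 0ULL);
  for (int i = 0; i < arcs.nrow(); ++i)
    pa[arcs(i, 1) - 1] |= (1ULL << (arcs(i, 0) - 1));
  std::vector<Move> moves;
  enumerate_moves(pa, p, max_parents, moves);
  IntegerMatrix out(moves.size(), 3);
  for (size_t i = 0; i < moves.size(); ++i) {
    out(i, 0) = moves[i].kind;
    out(i, 1) = moves[i].from + 1;
    out(i, 2) = moves[i].to + 1;
  }
  return out;
}

// [[Rcpp::export]]
List sa_search_cpp(IntegerMatrix data, IntegerVector card, double ess,
                   int max_parents, double t0, double cooling,
                   int moves_per_temp, double max_evals, int top_n) {
  const int p = data.ncol();
  if (p > 64) stop("at most 64 variables are supported");
  ScoreCache cache(data, card, ess);
  Masks pa(p, 0ULL);
  double current = 0.0;
  for (int v = 0; v < p; ++v) current += cache.get(v, 0ULL);
  TopSet top((size_t)top_n);
  top.offer(current, pa, p);
  double evals = 1.0;
  double T = t0;
  double best = current;
  double accepted = 0.0;
  std::vector<Move> moves;
  bool moves_valid = false;  // the move set only changes on acceptance
  while (evals < max_evals) {
    if (!moves_valid) {
      enumerate_moves(pa, p, max_parents, moves);
      moves_valid = true;
    }
    if (moves.empty()) break;
    int k = (int)(unif_rand() * moves.size());
    if (k >= (int)moves.size()) k = (int)moves.size() - 1;
    const Move& mv = moves[k];
    Masks cand = pa;
    double delta = 0.0;
    if (mv.kind == 0) {
      cand[mv.to] |= (1ULL << mv.from);
      delta = cache.get(mv.to, cand[mv.to]) - cache.get(mv.to, pa[mv.to]);
    } else if (mv.kind == 1) {
      cand[mv.to] &= ~(1ULL << mv.from);
      delta = cache.get(mv.to, cand[mv.to]) - cache.get(mv.to, pa[mv.to]);
    } else {
      cand[mv.to] &= ~(1ULL << mv.from);
      cand[mv.from] |= (1ULL << mv.to);
      delta = cache.get(mv.to, cand[mv.to]) - cache.get(mv.to, pa[mv.to]) +
        cache.get(mv.from, cand[mv.from]) - cache.get(mv.from, pa[mv.from]);
    }
    const double cand_score = current + delta;
    evals += 1.0;
    top.offer(cand_score, cand, p);
    bool accept = delta > 0.0;
    if (!accept) accept = unif_rand() < std::exp(delta / T);
    if (accept) {
      pa.swap(cand);
      current = cand_score;
      accepted += 1.0;
      moves_valid = false;
      if (current > best) best = current;
    }
    if (((long long)evals) % moves_per_temp == 0) T *= cooling;
    if (((long long)evals) % 65536 == 0) Rcpp::checkUserInterrupt();
  }
  return List::create(Named("top") = top.as_list(p),
                      Named("n_evaluations") = evals,
                      Named("accepted") = accepted,
                      Named("best_score") = best,
                      Named("final_temperature") = T);
}

// [[Rcpp::export]]
List exhaustive_cpp(IntegerMatrix data, IntegerVector card, double ess) {
  const int p = data.ncol();
  if (p > 5) stop("exhaustive enumeration is limited to 5 variables");
  // all candidate parent masks per child, and their scores
  std::vector< std::vector<uint64_t> > cand_masks(p);
  std::vector< std::vector<double> > cand_scores(p);
  for (int v = 0; v < p; ++v) {
    for (uint64_t m = 0; m < (1ULL << p); ++m) {
      if ((m >> v) & 1ULL) continue;
      cand_masks[v].push_back(m);
      cand_scores[v].push_back(family_score_raw(data, card, v, m, ess));
    }
  }
  Masks pa(p, 0ULL);
  std::vector<size_t> idx(p, 0);
  double n_dags = 0.0;
  double best_score = R_NegInf;
  Masks best_pa(p, 0ULL);
  std::vector<std::pair<int,int> > best_arcs;
  bool done = false;
  while (!done) {
    for (int v = 0; v < p; ++v) pa[v] = cand_masks[v][idx[v]];
    // acyclic iff repeatedly removing parentless nodes empties the graph
    uint64_t removed = 0ULL;
    bool progress = true;
    int left = p;
    while (progress && left > 0) {
      progress = false;
      for (int v = 0; v < p; ++v) {
        if ((removed >> v) & 1ULL) continue;
        if ((pa[v] & ~removed) == 0ULL) {
          removed |= (1ULL << v); --left; progress = true;
        }
      }
    }
    if (left == 0) {
      n_dags += 1.0;
      double s = 0.0;
      for (int v = 0; v < p; ++v) s += cand_scores[v][idx[v]];
      bool better = s > best_score;
      if (!better && s == best_score) {
        std::vector<std::pair<int,int> > arcs = arc_list(pa, p);
        better = arcs < best_arcs;
      }
      if (better) {
        best_score = s;
        best_pa = pa;
        best_arcs = arc_list(pa, p);
      }
    }
    // odometer increment
    int v = 0;
    for (; v < p; ++v) {
      if (++idx[v] < cand_masks[v].size()) break;
      idx[v] = 0;
    }
    if (v == p) done = true;
  }
  IntegerMatrix am(best_arcs.size(), 2);
  for (size_t a = 0; a < best_arcs.size(); ++a) {
    am(a, 0) = best_arcs[a].first + 1;
    am(a, 1) = best_arcs[a].second + 1;
  }
  return List::create(Named("arcs") = am,
                      Named("log_score") = best_score,
                      Named("n_dags") = n_dags);
}
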