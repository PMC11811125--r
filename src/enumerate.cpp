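// Bounded search over BFB derivations.
//
// Every BFB string has a growth-only derivation from a reference prefix
// 1+2+...k+ (a cycle with break length <= |s| just takes a prefix), and the
// per-segment copy and foldback counts are monotone along such a derivation:
// appending the mirrored suffix of length d adds the suffix's counts plus
// exactly one new fold at the junction.  A depth-first search over growth
// moves, pruned by componentwise upper bounds on (C, L, R), therefore visits
// every BFB string within the bounds given enough budget; with a node budget
// it returns the best candidates found so far and a truncation flag.

#include <Rcpp.h>
#include <unordered_set>
#include <unordered_map>
#include <string>
#include <vector>
#include <cmath>
using namespace Rcpp;

namespace {

struct State {
  std::vector<int> elem;           // signed: +i / -i
  std::vector<int> c, l, r;        // per-segment counts (1-based stored at i-1)
};

struct Best {
  std::string enc;                 // lexicographically smallest string encoding
  std::vector<int> c, l, r;
  double disc;
  double lrdist;                   // distance to the foldback guide (0 if none)
};

std::string encode(const std::vector<int> &elem) {
  std::string out;
  out.reserve(elem.size() * 3);
  for (int e : elem) {
    out += std::to_string(std::abs(e));
    out += (e > 0 ? '+' : '-');
  }
  return out;
}

std::string class_key(const std::vector<int> &c, const std::vector<int> &l,
                      const std::vector<int> &r) {
  std::string k;
  for (size_t i = 0; i < c.size(); ++i) {
    k += std::to_string(c[i]); k += ',';
    k += std::to_string(l[i]); k += ',';
    k += std::to_string(r[i]); k += ';';
  }
  return k;
}

double copy_disc(const std::vector<int> &c, const IntegerVector &target) {
  double d = 0.0;
  for (int i = 0; i < target.size(); ++i) {
    int ci = (i < (int)c.size()) ? c[i] : 0;
    d += std::abs((double)target[i] - ci) / std::max(ci, 1);
  }
  return d;
}

class Searcher {
public:
  Searcher(const IntegerVector &target, const IntegerVector &cmax,
           const IntegerVector &lmax, const IntegerVector &rmax,
           const NumericVector &ltarget, const NumericVector &rtarget,
           int max_cycles, int node_budget, int max_classes)
    : target_(target), cmax_(cmax), lmax_(lmax), rmax_(rmax),
      ltarget_(ltarget), rtarget_(rtarget),
      max_cycles_(max_cycles), budget_(node_budget),
      max_classes_(max_classes), nodes_(0), truncated_(false) {}

  void run() {
    rng_ = 0;                         // deterministic pass
    pass(budget_);
  }

  // randomized restarts: fresh visited set and shuffled move order per
  // restart, until the target class is hit or the restarts are exhausted
  void run_restarts(int restarts, long per_budget, unsigned long long seed) {
    for (int r = 0; r < restarts && !target_hit(); ++r) {
      seen_.clear();
      nodes_ = 0;
      truncated_ = false;
      rng_ = seed * 2862933555777941757ULL + (unsigned long long)(r + 1);
      pass(per_budget);
    }
  }

  bool target_hit() const {
    for (auto &kv : classes_)
      if (kv.second.disc == 0.0 &&
          (ltarget_.size() == 0 || kv.second.lrdist == 0.0))
        return true;
    return false;
  }

  void pass(long budget) {
    long save = budget_;
    budget_ = budget;
    int n = cmax_.size();
    // start from each admissible reference prefix 1+..k+
    for (int k = 1; k <= n; ++k) {
      bool ok = true;
      for (int i = 0; i < k; ++i) if (cmax_[i] < 1) { ok = false; break; }
      if (!ok) break;
      State s;
      s.c.assign(n, 0); s.l.assign(n, 0); s.r.assign(n, 0);
      for (int i = 1; i <= k; ++i) { s.elem.push_back(i); s.c[i - 1] = 1; }
      visit(s);
      dfs(s, 0);
    }
    budget_ = save;
  }

  bool truncated() const { return truncated_; }

  List results(int max_candidates) const {
    std::vector<const Best*> v;
    v.reserve(classes_.size());
    for (auto &kv : classes_) v.push_back(&kv.second);
    std::sort(v.begin(), v.end(), [](const Best *a, const Best *b) {
      if (a->disc != b->disc) return a->disc < b->disc;
      if (a->lrdist != b->lrdist) return a->lrdist < b->lrdist;
      return a->enc < b->enc;
    });
    int m = std::min<int>(max_candidates, v.size());
    List out(m);
    for (int i = 0; i < m; ++i) {
      out[i] = List::create(
        _["string"] = v[i]->enc,
        _["C"] = IntegerVector(v[i]->c.begin(), v[i]->c.end()),
        _["L"] = IntegerVector(v[i]->l.begin(), v[i]->l.end()),
        _["R"] = IntegerVector(v[i]->r.begin(), v[i]->r.end()),
        _["copy_discrepancy"] = v[i]->disc);
    }
    return out;
  }

private:
  void visit(const State &s) {
    std::string key = class_key(s.c, s.l, s.r);
    std::string enc = encode(s.elem);
    auto it = classes_.find(key);
    if (it == classes_.end()) {
      if ((int)classes_.size() >= max_classes_) return;
      Best b; b.enc = enc; b.c = s.c; b.l = s.l; b.r = s.r;
      b.disc = copy_disc(s.c, target_);
      b.lrdist = 0.0;
      if (ltarget_.size() == (int)s.l.size()) {
        for (size_t i = 0; i < s.l.size(); ++i) {
          b.lrdist += (ltarget_[i] - s.l[i]) * (ltarget_[i] - s.l[i]);
          b.lrdist += (rtarget_[i] - s.r[i]) * (rtarget_[i] - s.r[i]);
        }
      }
      classes_.emplace(std::move(key), std::move(b));
    } else if (enc < it->second.enc) {
      it->second.enc = enc;
    }
  }

  void dfs(State &s, int depth) {
    if (depth >= max_cycles_) return;
    if (nodes_ >= budget_) { truncated_ = true; return; }
    int len = (int)s.elem.size();
    // feasible growth extensions d = 1..dmax (added counts are monotone in d)
    std::vector<int> addc(s.c.size(), 0), addl(s.c.size(), 0), addr(s.c.size(), 0);
    int dmax = 0;
    {
      // junction fold at the last element
      int last = s.elem[len - 1];
      int seg0 = std::abs(last) - 1;
      bool right0 = last > 0;
      for (int d = 1; d <= len; ++d) {
        int e = s.elem[len - d];            // element being mirrored at step d
        int seg = std::abs(e) - 1;
        addc[seg]++;
        if (d == 1) {
          if (right0) addr[seg0]++; else addl[seg0]++;
        } else {
          // adjacency between mirrored copies of elements len-d+1 and len-d
          int prev = s.elem[len - d + 1];
          if (std::abs(prev) == std::abs(e)) {
            if (e > 0 && prev < 0) addr[seg]++;        // (i,+)(i,-) mirrored stays right
            else if (e < 0 && prev > 0) addl[seg]++;   // (i,-)(i,+) stays left
          }
        }
        bool ok = s.c[seg] + addc[seg] <= cmax_[seg];
        for (size_t i = 0; ok && i < s.c.size(); ++i)
          if (s.l[i] + addl[i] > lmax_[i] || s.r[i] + addr[i] > rmax_[i]) ok = false;
        if (!ok) break;
        dmax = d;
      }
    }
    // try the exact-total completion first, then larger extensions first
    long total_target = 0;
    for (int i = 0; i < target_.size(); ++i) total_target += target_[i];
    long need = total_target - len;
    std::vector<int> order;
    order.reserve(dmax);
    if (need >= 1 && need <= dmax) order.push_back((int)need);
    for (int d = dmax; d >= 1; --d)
      if (d != (int)need) order.push_back(d);
    if (rng_ != 0 && order.size() > 2) {
      // Fisher-Yates on everything after the completion move
      for (size_t i = order.size() - 1; i > 1; --i) {
        rng_ ^= rng_ << 13; rng_ ^= rng_ >> 7; rng_ ^= rng_ << 17;
        size_t j = 1 + rng_ % i;
        std::swap(order[i], order[j]);
      }
    }
    for (int d : order) {
      // build child in place: append mirror of last d elements
      State child = s;
      for (int j = 1; j <= d; ++j) child.elem.push_back(-s.elem[len - j]);
      // recompute counts incrementally
      for (int j = 1; j <= d; ++j) {
        int seg = std::abs(s.elem[len - j]) - 1;
        child.c[seg]++;
      }
      {
        int last = s.elem[len - 1];
        int seg0 = std::abs(last) - 1;
        if (last > 0) child.r[seg0]++; else child.l[seg0]++;
        for (int j = 2; j <= d; ++j) {
          int e = s.elem[len - j], prev = s.elem[len - j + 1];
          if (std::abs(e) == std::abs(prev)) {
            int seg = std::abs(e) - 1;
            if (e > 0 && prev < 0) child.r[seg]++;
            else if (e < 0 && prev > 0) child.l[seg]++;
          }
        }
      }
      std::string enc = encode(child.elem);
      if (!seen_.insert(enc).second) continue;
      ++nodes_;
      visit(child);
      dfs(child, depth + 1);
      if (nodes_ >= budget_) { truncated_ = true; return; }
    }
  }

  IntegerVector target_, cmax_, lmax_, rmax_;
  NumericVector ltarget_, rtarget_;
  int max_cycles_;
  long budget_;
  int max_classes_;
  unsigned long long rng_ = 0;
  long nodes_;
  bool truncated_;
  std::unordered_set<std::string> seen_;
  std::unordered_map<std::string, Best> classes_;
};

} // namespace

// [[Rcpp::export(name = ".enum_bfb_cpp")]]
List enum_bfb_cpp(IntegerVector target, IntegerVector cmax,
                  IntegerVector lmax, IntegerVector rmax,
                  NumericVector ltarget, NumericVector rtarget,
                  int max_cycles, int node_budget, int max_candidates,
                  int max_classes, int restarts = 0, int restart_budget = 0,
                  int restart_seed = 1) {
  Searcher s(target, cmax, lmax, rmax, ltarget, rtarget,
             max_cycles, node_budget, max_classes);
  s.run();
  if (restarts > 0 && !s.target_hit())
    s.run_restarts(restarts, restart_budget,
                   (unsigned long long)restart_seed);
  List res = s.results(max_candidates);
  res.attr("truncated") = s.truncated();
  return res;
}
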